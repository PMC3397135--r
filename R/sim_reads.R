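#' Simulate tagged amplicon reads for one diploid individual
#'
#' Per amplicon the read count is Poisson(coverage_mean); a count of zero is
#' a legitimate outcome (missing amplicon). Each read is drawn from one of
#' the individual's two haplotypes or, with probability \code{chimera_rate},
#' from a single-crossover PCR chimera of both (uniform breakpoint inside
#' the amplicon; both parents are the same individual's haplotypes, because
#' template switching happens within the per-individual PCR). The read is
#' then truncated to a Normal(read_length_mean, read_length_sd) length from
#' a uniformly chosen end, substitution errors are applied per base,
#' single-base insertion/deletion errors are applied per homopolymer run of
#' length >= 3, and the individual's full tag adapter (see [build_tag()]) is
#' prepended.
#'
#' @param haplotypes Character vector of the individual's two contig-length
#'   haplotype sequences.
#' @param design Amplicon design data.frame from [amplicon_design()].
#' @param config A [sim_config()].
#' @param tag Optional 8-mer tag; when given the 24-base adapter is prepended.
#' @param individual Individual identifier carried in the output.
#' @return data.frame with columns read_id, individual, contig, amplicon,
#'   sequence, source (hap1/hap2/chimera).
#' @export
simulate_reads <- function(haplotypes, design, config, tag = NULL,
                           individual = "ind1") {
  stopifnot(length(haplotypes) == 2)
  hap_chars <- strsplit(toupper(haplotypes), "", fixed = TRUE)
  if (any(nchar(haplotypes) < max(design$end)))
    stop("haplotypes must cover every amplicon interval")
  adapter <- if (!is.null(tag)) build_tag(tag)$full_adapter else ""

  out <- vector("list", nrow(design))
  for (ai in seq_len(nrow(design))) {
    a_start <- design$start[ai]; a_end <- design$end[ai]
    amp_len <- a_end - a_start
    n_reads <- stats::rpois(1, config$coverage_mean)
    if (n_reads == 0) { out[[ai]] <- NULL; next }
    seqs <- character(n_reads); src <- character(n_reads)
    for (r in seq_len(n_reads)) {
      h <- sample.int(2, 1)
      if (stats::runif(1) < config$chimera_rate && amp_len >= 2) {
        bp <- sample.int(amp_len - 1, 1)  # crossover after position bp
        left <- hap_chars[[h]][(a_start + 1):(a_start + bp)]
        right <- hap_chars[[3 - h]][(a_start + bp + 1):a_end]
        tmpl <- c(left, right)
        src[r] <- "chimera"
      } else {
        tmpl <- hap_chars[[h]][(a_start + 1):a_end]
        src[r] <- paste0("hap", h)
      }
      len <- round(stats::rnorm(1, config$read_length_mean, config$read_length_sd))
      len <- max(30L, min(amp_len, as.integer(len)))
      if (stats::runif(1) < 0.5) tmpl <- tmpl[seq_len(len)]
      else tmpl <- tmpl[(amp_len - len + 1):amp_len]
      tmpl <- apply_sub_errors(tmpl, config$sub_error_rate)
      tmpl <- apply_homopolymer_indels(tmpl, config$homopolymer_indel_rate)
      seqs[r] <- paste(tmpl, collapse = "")
    }
    out[[ai]] <- data.frame(
      read_id = sprintf("%s|%s|r%03d", individual, design$amplicon[ai],
                        seq_len(n_reads)),
      individual = individual, contig = design$contig[ai],
      amplicon = design$amplicon[ai],
      sequence = paste0(adapter, seqs), source = src,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out) %||% data.frame(
    read_id = character(0), individual = character(0), contig = character(0),
    amplicon = character(0), sequence = character(0), source = character(0))
}

apply_sub_errors <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) == 0) return(chars)
  bases <- c("A", "C", "G", "T")
  chars[hit] <- vapply(chars[hit],
                       function(b) sample(setdiff(bases, b), 1), character(1))
  chars
}

apply_homopolymer_indels <- function(chars, rate) {
  if (rate <= 0) return(chars)
  r <- rle(chars)
  runs <- which(r$lengths >= 3)
  if (length(runs) == 0) return(chars)
  hit <- runs[stats::runif(length(runs)) < rate]
  if (length(hit) == 0) return(chars)
  ends <- cumsum(r$lengths)
  # apply right-to-left so earlier indices stay valid
  for (ri in rev(hit)) {
    pos <- ends[ri]  # last base of the run
    if (stats::runif(1) < 0.5) {
      chars <- append(chars, r$values[ri], after = pos)   # insertion
    } else {
      chars <- chars[-pos]                                 # deletion
    }
  }
  chars
}

#' Generate a set of unique 8-mer tags
#'
#' @param n Number of tags.
#' @param seed Optional seed.
#' @return Character vector of n distinct 8-base tags.
#' @export
make_tags <- function(n, seed = NULL) {
  maybe_seed(seed)
  tags <- character(0)
  while (length(tags) < n) {
    cand <- replicate(n, paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                               collapse = ""))
    tags <- unique(c(tags, cand))
  }
  tags[seq_len(n)]
}
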