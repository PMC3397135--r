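#' Build an individual tag adapter
#'
#' A tag is eight unique bases followed by the SrfI recognition site
#' (GCCCGGGC) and the eight complementary bases, forming a self-annealing
#' hairpin: full_adapter = tag + GCCCGGGC + reverse-complement(tag).
#'
#' @param tag 8-base string over A/C/G/T.
#' @return List with \code{tag} and \code{full_adapter} (24 bases).
#' @export
build_tag <- function(tag) {
  tag <- toupper(tag)
  if (nchar(tag) != 8 || grepl("[^ACGT]", tag))
    stop("invalid argument: tag must be 8 bases over A/C/G/T")
  structure(list(tag = tag,
                 full_adapter = paste0(tag, "GCCCGGGC", revcomp(tag))),
            class = "tag_spec")
}

#' Demultiplex tagged reads
#'
#' A read is assigned to the unique tag whose leading 8-mer matches within
#' \code{max_mismatch} mismatches; ties between tags or no match send the
#' read to the unassigned bin. The 24 adapter bases are trimmed from
#' assigned reads.
#'
#' @param reads data.frame with a \code{sequence} column (adapter-prefixed).
#' @param tags Named character vector of 8-mer tags (names = individuals).
#' @param max_mismatch Maximum mismatches allowed in the tag, >= 0.
#' @return List with \code{assigned} (reads with an \code{individual} column
#'   and trimmed sequences) and \code{unassigned}.
#' @export
demultiplex <- function(reads, tags, max_mismatch = 0) {
  if (anyDuplicated(tags)) stop("invalid argument: duplicate tags")
  if (max_mismatch < 0) stop("invalid argument: max_mismatch must be >= 0")
  if (nrow(reads) == 0) return(list(assigned = reads, unassigned = reads))
  prefix <- substr(reads$sequence, 1, 8)
  pm <- matrix(unlist(strsplit(prefix, "", fixed = TRUE), use.names = FALSE),
               ncol = 8, byrow = TRUE)
  mm <- vapply(tags, function(tg) {
    tc <- strsplit(tg, "", fixed = TRUE)[[1]]
    rowSums(pm != matrix(tc, nrow(pm), 8, byrow = TRUE))
  }, numeric(nrow(reads)))
  mm <- matrix(mm, nrow = nrow(reads))
  best <- apply(mm, 1, min)
  n_best <- rowSums(mm == best)
  ok <- best <= max_mismatch & n_best == 1
  idx <- apply(mm, 1, which.min)
  assigned <- reads[ok, , drop = FALSE]
  assigned$individual <- names(tags)[idx[ok]]
  assigned$sequence <- substr(assigned$sequence, 25, nchar(assigned$sequence))
  list(assigned = assigned, unassigned = reads[!ok, , drop = FALSE])
}

# Try placing a read ungapped against the amplicon reference at both
# anchorings (truncation happens from one end, so an indel-free read sits
# flush with one amplicon end). Returns NULL when neither anchoring reaches
# `min_ident` identity, in which case the caller falls back to gapped DP.
anchor_ungapped <- function(read_chars, ref_chars, min_ident = 0.90) {
  len <- length(read_chars); alen <- length(ref_chars)
  if (len > alen) return(NULL)
  idL <- mean(read_chars == ref_chars[seq_len(len)])
  idR <- mean(read_chars == ref_chars[(alen - len + 1):alen])
  if (max(idL, idR) < min_ident) return(NULL)
  offset <- if (idL >= idR) 0L else alen - len
  list(offset = offset, identity = max(idL, idR))
}

#' Align reads to their amplicon reference intervals and build a pileup
#'
#' Each read is anchored to one amplicon (the \code{amplicon} column; reads
#' lacking it are anchored to the best-matching amplicon by ungapped end
#' placement). Indel-free reads are placed by exact end-anchoring; reads
#' that do not place ungapped are globally aligned to the amplicon interval
#' (match +1, mismatch -1, gap open -3, gap extend -1; read global, interval
#' local). Columns accumulate base, deletion ("-") and insertion counts.
#' Reads aligning with identity below \code{min_identity} are discarded with
#' a warning.
#'
#' @param reads data.frame for one individual and one contig with columns
#'   \code{sequence} and (optionally) \code{amplicon}.
#' @param reference Contig reference sequence (string).
#' @param design Amplicon design for this contig.
#' @param min_identity Identity below which a read is discarded.
#' @return Object of class \code{"pileup"}: \code{counts} (L x 5 matrix over
#'   A,C,G,T,-), \code{depth}, \code{insertions} (per-position tables),
#'   \code{read_base} (reads x L base matrix in contig coordinates),
#'   \code{read_amplicon}, \code{n_discarded}.
#' @export
align_and_pileup <- function(reads, reference, design, min_identity = 0.7) {
  reference <- toupper(reference)
  L <- nchar(reference)
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  nr <- nrow(reads)
  read_base <- matrix(NA_character_, nrow = nr, ncol = L)
  ins_records <- list()
  discarded <- logical(nr)

  amp_of <- if ("amplicon" %in% names(reads)) reads$amplicon else rep(NA, nr)
  seqs <- toupper(reads$sequence)

  for (ai in seq_len(nrow(design))) {
    a_start <- design$start[ai]; a_end <- design$end[ai]
    amp_ref <- ref_chars[(a_start + 1):a_end]
    rows <- which(amp_of == design$amplicon[ai])
    need_dp <- integer(0)
    for (r in rows) {
      rc <- strsplit(seqs[r], "", fixed = TRUE)[[1]]
      hit <- if (length(rc) <= length(amp_ref)) anchor_ungapped(rc, amp_ref) else NULL
      if (is.null(hit)) { need_dp <- c(need_dp, r); next }
      pos <- a_start + hit$offset + seq_along(rc)
      read_base[r, pos] <- rc
    }
    if (length(need_dp) > 0) {
      res <- align_batch_dp(seqs[need_dp], paste(amp_ref, collapse = ""))
      for (k in seq_along(need_dp)) {
        r <- need_dp[k]; al <- res[[k]]
        if (al$identity < min_identity) { discarded[r] <- TRUE; next }
        read_base[r, a_start + al$ref_pos] <- al$base
        if (nrow(al$insertions) > 0) {
          al$insertions$position <- a_start + al$insertions$position
          ins_records[[length(ins_records) + 1]] <- al$insertions
        }
      }
    }
  }
  # reads without a recognised amplicon label: anchor by best ungapped score
  un <- which(is.na(amp_of) | !(amp_of %in% design$amplicon))
  for (r in un) {
    rc <- strsplit(seqs[r], "", fixed = TRUE)[[1]]
    best <- NULL; best_ai <- NA
    for (ai in seq_len(nrow(design))) {
      amp_ref <- ref_chars[(design$start[ai] + 1):design$end[ai]]
      if (length(rc) > length(amp_ref)) next
      hit <- anchor_ungapped(rc, amp_ref, min_ident = 0)
      if (is.null(best) || hit$identity > best$identity) { best <- hit; best_ai <- ai }
    }
    if (is.null(best) || best$identity < min_identity) { discarded[r] <- TRUE; next }
    pos <- design$start[best_ai] + best$offset + seq_along(rc)
    read_base[r, pos] <- rc
    amp_of[r] <- design$amplicon[best_ai]
  }

  if (any(discarded))
    warning(sum(discarded), " read(s) discarded (identity < ", min_identity, ")")
  keep <- !discarded
  read_base <- read_base[keep, , drop = FALSE]
  amp_of <- amp_of[keep]

  counts <- matrix(0L, nrow = L, ncol = 5,
                   dimnames = list(NULL, c("A", "C", "G", "T", "-")))
  symbols <- c("A", "C", "G", "T", "-")
  for (j in seq_len(L)) {
    col <- read_base[, j]
    col <- col[!is.na(col)]
    if (length(col)) counts[j, ] <- tabulate(match(col, symbols), 5L)
  }
  insertions <- list()
  if (length(ins_records) > 0) {
    insdf <- do.call(rbind, ins_records)
    insertions <- split(insdf$inserted, insdf$position)
    insertions <- lapply(insertions, table)
  }
  structure(list(counts = counts, depth = rowSums(counts),
                 insertions = insertions, read_base = read_base,
                 read_amplicon = amp_of, n_discarded = sum(discarded),
                 reference = reference, design = design),
            class = "pileup")
}

# gapped alignment fallback; read global, amplicon interval local (fitting
# alignment, compiled; scoring +1/-1, gap open 3, gap extend 1)
align_batch_dp <- function(read_seqs, amp_ref) {
  res <- fit_align_batch_cpp(read_seqs, amp_ref)
  lapply(res, function(al) {
    list(ref_pos = al$ref_pos, base = al$base,
         insertions = data.frame(position = al$ins_pos,
                                 inserted = al$ins_base,
                                 stringsAsFactors = FALSE),
         identity = al$identity)
  })
}

#' Call SNP and indel variants from a pileup with a low-frequency filter
#'
#' At each column with positive depth, allele frequencies are read
#' frequencies (counts / depth). Non-reference alleles below
#' \code{maf_threshold} are eliminated as likely sequencing error (the
#' classic <0.05 rule for 454 homopolymer noise). Columns retaining two or
#' more alleles become variants; the consensus carries the IUPAC ambiguity
#' code of the retained bases at heterozygous SNP columns, "-" where a
#' deletion is the single retained allele, and "N" at zero-depth columns.
#' Insertion alleles are filtered identically and reported as indel
#' variants.
#'
#' @param pileup A \code{"pileup"} object.
#' @param maf_threshold Frequency below which alleles are eliminated.
#' @return Object of class \code{"variant_table"}: data.frame(position
#'   (1-based), ref, alleles, freqs, maf, type) with attributes
#'   \code{consensus} (contig-length string, coordinate-preserving: deleted
#'   columns appear as "-") and \code{insertions}.
#' @export
call_variants <- function(pileup, maf_threshold = 0.05) {
  stopifnot(inherits(pileup, "pileup"))
  counts <- pileup$counts
  L <- nrow(counts)
  ref_chars <- strsplit(pileup$reference, "", fixed = TRUE)[[1]]
  cons <- character(L)
  rows <- list()
  for (j in seq_len(L)) {
    depth <- sum(counts[j, ])
    if (depth == 0) { cons[j] <- "N"; next }
    freq <- counts[j, ] / depth
    keep <- names(freq)[freq >= maf_threshold & counts[j, ] > 0]
    # the reference allele is subject to the same evidence rule: only
    # observed alleles are retained
    if (length(keep) == 0) { cons[j] <- "N"; next }
    kept_bases <- setdiff(keep, "-")
    if (length(keep) >= 2) {
      f <- freq[keep]
      rows[[length(rows) + 1]] <- data.frame(
        position = j, ref = ref_chars[j],
        alleles = paste(keep, collapse = ","),
        freqs = paste(signif(f, 4), collapse = ","),
        maf = min(f),
        type = if ("-" %in% keep) "indel" else "SNP",
        stringsAsFactors = FALSE)
    }
    cons[j] <- if (length(kept_bases) == 0) "-" else iupac_code(kept_bases)
  }
  ins_rows <- list()
  retained_ins <- list()
  for (posc in names(pileup$insertions)) {
    pos <- as.integer(posc)
    if (pos < 1 || pos > L) next  # insertion hanging off the interval
    depth <- pileup$depth[pos]
    if (is.na(depth) || depth == 0) next
    tab <- pileup$insertions[[posc]]
    f <- as.numeric(tab) / depth
    keep <- f >= maf_threshold
    if (any(keep)) {
      ins_rows[[length(ins_rows) + 1]] <- data.frame(
        position = pos, ref = ref_chars[pos],
        alleles = paste(paste0("+", names(tab)[keep]), collapse = ","),
        freqs = paste(signif(f[keep], 4), collapse = ","),
        maf = min(f[keep]), type = "indel", stringsAsFactors = FALSE)
      if (any(f[keep] > 0.5))
        retained_ins[[posc]] <- names(tab)[keep][which.max(f[keep])]
    }
  }
  vt <- do.call(rbind, c(rows, ins_rows)) %||% data.frame(
    position = integer(0), ref = character(0), alleles = character(0),
    freqs = character(0), maf = numeric(0), type = character(0))
  vt <- vt[order(vt$position), , drop = FALSE]
  rownames(vt) <- NULL
  structure(vt, class = c("variant_table", "data.frame"),
            consensus = paste(cons, collapse = ""),
            insertions = retained_ins)
}

# second-slot tie break: lexicographically smallest among equally supported
top_two_vectors <- function(vec_counts) {
  cnt <- sort(vec_counts, decreasing = TRUE)
  nm <- names(cnt)
  top1 <- sort(nm[cnt == cnt[1]])[1]
  rest <- cnt[nm != top1]
  if (length(rest) == 0) return(c(top1, top1))
  top2 <- sort(names(rest)[rest == max(rest)])[1]
  c(top1, top2)
}

#' Resolve the two diploid haplotypes from per-read allele vectors
#'
#' Within each amplicon, reads covering all of the amplicon's heterozygous
#' SNP sites are grouped by their allele vector over those sites and the two
#' most frequent vectors are taken as the non-chimeric parental
#' combinations (PCR chimeras are recombinants of the two and are rarer
#' than either parent at realistic chimera rates). One vector is kept twice
#' if the individual is homozygous throughout the amplicon. Amplicon-level
#' pairs are then chained across overlaps using heterozygous sites shared
#' between adjacent amplicons; junctions with no shared heterozygous site
#' are flagged \code{ambiguous} and joined by support rank. Substituting the
#' chosen alleles into the individual's IUPAC consensus yields the two
#' haplotypes (in contig coordinates; homozygous deletions appear as "-").
#'
#' @param pileup A \code{"pileup"} object for one individual and contig.
#' @param variants The matching \code{"variant_table"}.
#' @param design Amplicon design for the contig.
#' @param min_coverage Mean contig depth below which the pair is flagged
#'   \code{low_coverage} (haplotypes are still emitted).
#' @param individual,contig Identifiers carried into the result.
#' @return Object of class \code{"haplotype_pair"}.
#' @export
resolve_haplotypes <- function(pileup, variants, design, min_coverage = 35,
                               individual = NA_character_,
                               contig = NA_character_) {
  cons <- strsplit(attr(variants, "consensus"), "", fixed = TRUE)[[1]]
  covered <- unlist(lapply(seq_len(nrow(design)), function(ai)
    (design$start[ai] + 1):design$end[ai]))
  covered <- sort(unique(covered))
  mean_depth <- if (length(covered)) mean(pileup$depth[covered]) else 0

  if (nrow(pileup$read_base) == 0) {
    return(structure(list(individual = individual, contig = contig,
                          haplotype_1 = NULL, haplotype_2 = NULL,
                          support_1 = 0L, support_2 = 0L,
                          amplicon_supports = NULL, het_positions = integer(0),
                          junctions = character(0),
                          coverage_flag = "missing"),
                     class = "haplotype_pair"))
  }

  snp_rows <- variants[variants$type == "SNP", , drop = FALSE]
  het_pos <- snp_rows$position

  hap_alleles <- list(h1 = character(0), h2 = character(0))
  assigned_pos <- integer(0)
  junctions <- character(0)
  amp_supports <- list()
  sup1 <- 0L; sup2 <- 0L

  for (ai in seq_len(nrow(design))) {
    a_pos <- het_pos[het_pos > design$start[ai] & het_pos <= design$end[ai]]
    rows <- which(pileup$read_amplicon == design$amplicon[ai])
    if (length(a_pos) == 0) {
      amp_supports[[design$amplicon[ai]]] <- c(length(rows), length(rows))
      if (ai > 1) junctions <- c(junctions, "joined")  # nothing to phase
      next
    }
    sub <- pileup$read_base[rows, a_pos, drop = FALSE]
    complete <- apply(sub, 1, function(z)
      all(!is.na(z)) && all(z %in% c("A", "C", "G", "T")))
    sub <- sub[complete, , drop = FALSE]
    if (nrow(sub) == 0) {
      # no read spans every het site; fall back to per-site major/minor with
      # arbitrary phase, flagged ambiguous
      pair <- vapply(a_pos, function(p) {
        cc <- pileup$counts[p, c("A", "C", "G", "T")]
        nm <- names(sort(cc[cc > 0], decreasing = TRUE))
        c(nm[1], nm[min(2, length(nm))])
      }, character(2))
      v1 <- paste(pair[1, ], collapse = ""); v2 <- paste(pair[2, ], collapse = "")
      cnts <- c(0L, 0L)
      if (ai > 1) junctions <- c(junctions, "ambiguous")
    } else {
      vecs <- apply(sub, 1, paste, collapse = "")
      tab <- table(vecs)
      tops <- top_two_vectors(tab)
      v1 <- tops[1]; v2 <- tops[2]
      cnts <- c(as.integer(tab[v1]), if (v2 == v1) as.integer(tab[v1])
                else as.integer(tab[v2]))
    }
    a1 <- strsplit(v1, "", fixed = TRUE)[[1]]
    a2 <- strsplit(v2, "", fixed = TRUE)[[1]]

    if (length(assigned_pos) == 0) {
      hap_alleles$h1 <- a1; hap_alleles$h2 <- a2
      assigned_pos <- a_pos
      sup1 <- cnts[1]; sup2 <- cnts[2]
    } else {
      shared <- intersect(assigned_pos, a_pos)
      straight <- TRUE
      if (length(shared) > 0) {
        i_old <- match(shared, assigned_pos); i_new <- match(shared, a_pos)
        agree_straight <- sum(hap_alleles$h1[i_old] == a1[i_new]) +
          sum(hap_alleles$h2[i_old] == a2[i_new])
        agree_cross <- sum(hap_alleles$h1[i_old] == a2[i_new]) +
          sum(hap_alleles$h2[i_old] == a1[i_new])
        if (agree_cross > agree_straight) straight <- FALSE
        junctions <- c(junctions,
                       if (agree_cross == agree_straight) "ambiguous" else "joined")
      } else {
        junctions <- c(junctions, "ambiguous")
      }
      if (!straight) { tmp <- a1; a1 <- a2; a2 <- tmp; cnts <- rev(cnts) }
      new_pos <- setdiff(a_pos, assigned_pos)
      i_new <- match(new_pos, a_pos)
      hap_alleles$h1 <- c(hap_alleles$h1, a1[i_new])
      hap_alleles$h2 <- c(hap_alleles$h2, a2[i_new])
      assigned_pos <- c(assigned_pos, new_pos)
      sup1 <- sup1 + cnts[1]; sup2 <- sup2 + cnts[2]
    }
    amp_supports[[design$amplicon[ai]]] <- cnts
  }

  h1 <- cons; h2 <- cons
  if (length(assigned_pos)) {
    o <- order(assigned_pos)
    h1[assigned_pos[o]] <- hap_alleles$h1[o]
    h2[assigned_pos[o]] <- hap_alleles$h2[o]
  }
  if (sup2 > sup1) {
    tmp <- h1; h1 <- h2; h2 <- tmp
    tmp <- sup1; sup1 <- sup2; sup2 <- tmp
    amp_supports <- lapply(amp_supports, rev)
  }
  structure(list(individual = individual, contig = contig,
                 haplotype_1 = paste(h1, collapse = ""),
                 haplotype_2 = paste(h2, collapse = ""),
                 support_1 = sup1, support_2 = sup2,
                 amplicon_supports = amp_supports,
                 het_positions = sort(assigned_pos),
                 junctions = junctions,
                 coverage_flag = if (mean_depth < min_coverage) "low_coverage"
                                 else "ok"),
            class = "haplotype_pair")
}

#' @export
print.haplotype_pair <- function(x, ...) {
  cat("haplotype_pair", x$individual, "/", x$contig,
      "| het sites:", length(x$het_positions),
      "| support:", x$support_1, "/", x$support_2,
      "| flag:", x$coverage_flag, "\n")
  invisible(x)
}

#' Run the full per-individual haplotyping chain for one contig
#'
#' align -> call variants -> resolve haplotypes.
#'
#' @inheritParams align_and_pileup
#' @inheritParams call_variants
#' @inheritParams resolve_haplotypes
#' @return A \code{"haplotype_pair"} with the \code{"variant_table"}
#'   attached as attribute \code{variants}.
#' @export
haplotype_individual <- function(reads, reference, design,
                                 maf_threshold = 0.05, min_coverage = 35,
                                 min_identity = 0.7,
                                 individual = NA_character_,
                                 contig = NA_character_) {
  pu <- align_and_pileup(reads, reference, design, min_identity = min_identity)
  vt <- call_variants(pu, maf_threshold = maf_threshold)
  hp <- resolve_haplotypes(pu, vt, design, min_coverage = min_coverage,
                           individual = individual, contig = contig)
  attr(hp, "variants") <- vt
  hp
}

#' Haplotype a whole cohort of demultiplexed reads
#'
#' @param reads data.frame with columns individual, contig, amplicon,
#'   sequence (post-demultiplexing).
#' @param references Named character vector of contig reference sequences.
#' @param design Combined amplicon design table (all contigs).
#' @inheritParams haplotype_individual
#' @return List of \code{"haplotype_pair"} objects keyed
#'   "individual|contig".
#' @export
call_haplotypes <- function(reads, references, design, maf_threshold = 0.05,
                            min_coverage = 35, min_identity = 0.7) {
  out <- list()
  for (ct in unique(design$contig)) {
    d <- design[design$contig == ct, , drop = FALSE]
    for (ind in unique(reads$individual)) {
      sub <- reads[reads$individual == ind & reads$contig == ct, , drop = FALSE]
      hp <- haplotype_individual(sub, references[[ct]], d,
                                 maf_threshold = maf_threshold,
                                 min_coverage = min_coverage,
                                 min_identity = min_identity,
                                 individual = ind, contig = ct)
      out[[paste(ind, ct, sep = "|")]] <- hp
    }
  }
  out
}

#' Unphased SNP genotype matrix from resolved haplotype pairs
#'
#' Collects every contig position where any individual's haplotype differs
#' from the reference base, scores each individual's unordered genotype
#' (e.g. "A/G"), recomputes the sample minor allele frequency over
#' non-missing alleles, and drops variants with sample MAF at or below
#' \code{maf_threshold}.
#'
#' @param hap_pairs List of \code{"haplotype_pair"} objects.
#' @param references Named character vector of contig references.
#' @param maf_threshold Sample MAF at or below which variants are dropped.
#' @return List with \code{genotypes} (individuals x variants matrix of
#'   "X/Y" strings, NA = missing) and \code{info} data.frame(contig,
#'   position, ref, maf).
#' @export
genotype_matrix <- function(hap_pairs, references, maf_threshold = 0.05) {
  inds <- unique(vapply(hap_pairs, function(h) h$individual, character(1)))
  cols <- list(); info <- list()
  for (ct in unique(vapply(hap_pairs, function(h) h$contig, character(1)))) {
    ref_chars <- strsplit(toupper(references[[ct]]), "", fixed = TRUE)[[1]]
    pairs <- Filter(function(h) identical(h$contig, ct), hap_pairs)
    hm1 <- hm2 <- matrix(NA_character_, length(inds), length(ref_chars),
                         dimnames = list(inds, NULL))
    for (h in pairs) {
      if (h$coverage_flag == "missing" || is.null(h$haplotype_1)) next
      hm1[h$individual, ] <- strsplit(h$haplotype_1, "", fixed = TRUE)[[1]]
      hm2[h$individual, ] <- strsplit(h$haplotype_2, "", fixed = TRUE)[[1]]
    }
    for (j in seq_along(ref_chars)) {
      al <- c(hm1[, j], hm2[, j])
      ok <- !is.na(al) & al %in% c("A", "C", "G", "T")
      if (!any(ok)) next
      tab <- table(al[ok])
      if (length(tab) < 2 && names(tab)[1] == ref_chars[j]) next
      maf <- if (length(tab) < 2) 0 else
        (sum(tab) - max(tab)) / sum(tab)
      if (length(tab) >= 2 && maf <= maf_threshold) next
      if (length(tab) < 2) {
        # all individuals homozygous non-reference: fixed difference, MAF 0
        next
      }
      g <- vapply(inds, function(ind) {
        a <- c(hm1[ind, j], hm2[ind, j])
        if (any(is.na(a)) || !all(a %in% c("A", "C", "G", "T")))
          return(NA_character_)
        paste(sort(a), collapse = "/")
      }, character(1))
      cols[[length(cols) + 1]] <- g
      info[[length(info) + 1]] <- data.frame(
        contig = ct, position = j, ref = ref_chars[j], maf = maf,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cols) == 0) {
    return(list(genotypes = matrix(NA_character_, length(inds), 0,
                                   dimnames = list(inds, NULL)),
                info = data.frame(contig = character(0), position = integer(0),
                                  ref = character(0), maf = numeric(0))))
  }
  gm <- do.call(cbind, cols)
  info <- do.call(rbind, info)
  colnames(gm) <- paste(info$contig, info$position, sep = ":")
  rownames(gm) <- inds
  list(genotypes = gm, info = info)
}

#' Additive dosage encoding of an unphased SNP genotype matrix
#'
#' @param genotypes Individuals x variants matrix of "X/Y" strings.
#' @return Numeric matrix of minor-allele counts (0/1/2), NA for missing.
#' @export
dosage_matrix <- function(genotypes) {
  out <- matrix(NA_real_, nrow(genotypes), ncol(genotypes),
                dimnames = dimnames(genotypes))
  for (j in seq_len(ncol(genotypes))) {
    al <- unlist(strsplit(genotypes[, j], "/", fixed = TRUE))
    tab <- sort(table(al))
    if (length(tab) == 0) next
    minor <- names(tab)[1]
    g <- genotypes[, j]
    out[, j] <- vapply(g, function(x) {
      if (is.na(x)) return(NA_real_)
      sum(strsplit(x, "/", fixed = TRUE)[[1]] == minor)
    }, numeric(1))
  }
  out
}
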