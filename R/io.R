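#' Read / write FASTA and FASTQ
#'
#' Thin wrappers over Biostrings keeping the package's in-memory contract:
#' named character vectors of sequences.
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, format = "fasta")
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fastq <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  # simulated reads carry no base-quality model: uniform high quality
  qs <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qs)
  invisible(path)
}

#' Read a TSV with required-column validation
#'
#' Tab-separated, UTF-8, "." for missing, one header line.
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @return data.frame.
#' @export
read_tsv2 <- function(path, required = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", "."), check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss) > 0)
      stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' @rdname read_tsv2
#' @param df data.frame to write.
#' @export
write_tsv2 <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Minimal VCF writer / reader
#'
#' Fixed 8-column VCFv4.2 contract: CHROM, POS (1-based), ID, REF, ALT,
#' QUAL, FILTER, INFO with an AF key. Intended for the package's SNP/indel
#' tables, not as a general VCF engine.
#'
#' @param variants data.frame(contig, position, ref, alt, af).
#' @param path Output path.
#' @export
write_vcf_min <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants) > 0) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tAF=%s",
                       variants$contig, as.integer(variants$position),
                       variants$ref, variants$alt,
                       vapply(variants$af, function(a)
                         paste(format(a, trim = TRUE), collapse = ","),
                         character(1))), con)
  }
  invisible(path)
}

#' @rdname write_vcf_min
#' @export
read_vcf_min <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0)
    return(data.frame(contig = character(0), position = integer(0),
                      ref = character(0), alt = character(0), af = numeric(0)))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 8)
  if (length(bad) > 0)
    stop("malformed VCF record at line ",
         which(!startsWith(lines, "#"))[bad[1]])
  af <- vapply(parts, function(x) {
    m <- regmatches(x[8], regexpr("AF=[^;]+", x[8]))
    if (length(m) == 0) NA_real_ else as.numeric(strsplit(sub("AF=", "", m),
                                                          ",")[[1]][1])
  }, numeric(1))
  data.frame(contig = vapply(parts, `[`, "", 1),
             position = as.integer(vapply(parts, `[`, "", 2)),
             ref = vapply(parts, `[`, "", 4),
             alt = vapply(parts, `[`, "", 5),
             af = af, stringsAsFactors = FALSE)
}

#' Write resolved haplotypes as FASTA
#'
#' Headers follow \code{individual|contig|hap1|support|flag}.
#'
#' @param hap_pairs List of \code{"haplotype_pair"} objects.
#' @param path Output path.
#' @export
write_haplotypes_fasta <- function(hap_pairs, path) {
  seqs <- character(0)
  for (h in hap_pairs) {
    if (is.null(h$haplotype_1)) next
    nm1 <- paste(h$individual, h$contig, "hap1", h$support_1,
                 h$coverage_flag, sep = "|")
    nm2 <- paste(h$individual, h$contig, "hap2", h$support_2,
                 h$coverage_flag, sep = "|")
    # Biostrings cannot hold alignment gaps from homozygous deletions in a
    # DNAStringSet written per coordinate; strip them on output
    seqs[nm1] <- gsub("-", "", h$haplotype_1, fixed = TRUE)
    seqs[nm2] <- gsub("-", "", h$haplotype_2, fixed = TRUE)
  }
  write_fasta(seqs, path)
}
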