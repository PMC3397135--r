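`%||%` <- function(a, b) if (is.null(a)) b else a

# IUPAC nucleotide ambiguity codes keyed by the sorted set of bases they stand for
IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)

#' IUPAC ambiguity code for a set of bases
#'
#' @param bases Character vector of bases from \{A,C,G,T\}.
#' @return Single ambiguity character ("N" for the full set or invalid input).
#' @export
iupac_code <- function(bases) {
  key <- paste(sort(unique(toupper(bases))), collapse = "")
  code <- IUPAC_MAP[key]
  if (is.na(code)) "N" else unname(code)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of sequences over A/C/G/T (case preserved).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' Each pipeline stage draws its randomness from a sub-stream derived
#' deterministically from (seed, label), so stages can be toggled without
#' perturbing each other.
#'
#' @param seed Integer master seed.
#' @param label Character stage label.
#' @return An integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 2654435761) %% 2147483647
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

#' Convert sequences to an alignment character matrix
#'
#' @param x Character vector of equal-length sequences, or a character matrix
#'   (rows = sequences), which is returned unchanged.
#' @return Character matrix, one row per sequence, one column per site.
#' @export
seq_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot(is.character(x), length(x) >= 1)
  nc <- nchar(x)
  if (length(unique(nc)) != 1) stop("sequences must have equal length")
  m <- matrix(unlist(strsplit(toupper(x), "", fixed = TRUE), use.names = FALSE),
              nrow = length(x), byrow = TRUE)
  rownames(m) <- names(x)
  m
}

matrix_to_seq <- function(m) {
  apply(m, 1L, paste, collapse = "")
}

random_dna <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# set.seed only when a seed is supplied; NULL leaves the RNG stream alone
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
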