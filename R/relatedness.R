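#' Ritland moment-estimator kinship matrix from multi-allelic genotypes
#'
#' For locus l with A_l observed alleles, the pairwise estimate is
#' F_ij,l = [ sum_a (x_ia x_ja) / p_a - 1 ] / (A_l - 1), where x_ia is the
#' dosage of allele a in individual i divided by 2 and p_a its reference
#' frequency. The multilocus estimate is the weighted average over loci
#' with w_l = A_l - 1; loci with a missing genotype in either individual
#' drop out of that pair's average. Allele frequencies default to the
#' full-sample estimates.
#'
#' @param genotypes Individuals x loci matrix of "a/b" genotype strings
#'   (NA = missing).
#' @param freqs Optional list (one per locus) of named allele frequency
#'   vectors; every observed allele must have positive frequency.
#' @return List with \code{K} (symmetric kinship matrix, untruncated) and
#'   \code{freqs}.
#' @export
ritland_kinship <- function(genotypes, freqs = NULL) {
  n <- nrow(genotypes); Lc <- ncol(genotypes)
  if (n < 2) stop("at least 2 individuals required")
  split_geno <- function(g) if (is.na(g)) c(NA, NA) else
    strsplit(g, "/", fixed = TRUE)[[1]]

  alleles_by_locus <- vector("list", Lc)
  dosage <- vector("list", Lc)  # per locus: n x A_l matrix of x_ia
  for (l in seq_len(Lc)) {
    parts <- lapply(genotypes[, l], split_geno)
    obs <- unlist(parts)
    obs <- obs[!is.na(obs)]
    al <- sort(unique(obs))
    alleles_by_locus[[l]] <- al
    x <- matrix(NA_real_, n, length(al), dimnames = list(NULL, al))
    for (i in seq_len(n)) {
      p <- parts[[i]]
      if (any(is.na(p))) next
      x[i, ] <- 0
      for (a in p) x[i, a] <- x[i, a] + 0.5
    }
    dosage[[l]] <- x
  }
  if (is.null(freqs)) {
    freqs <- lapply(seq_len(Lc), function(l) {
      x <- dosage[[l]]
      cs <- colSums(x, na.rm = TRUE)
      cs / sum(cs)
    })
  } else {
    for (l in seq_len(Lc)) {
      pl <- freqs[[l]]
      if (any(!(alleles_by_locus[[l]] %in% names(pl))) ||
          any(pl[alleles_by_locus[[l]]] <= 0))
        stop("invalid frequency table: observed allele with zero frequency")
    }
  }

  num <- matrix(0, n, n); den <- matrix(0, n, n)
  for (l in seq_len(Lc)) {
    al <- alleles_by_locus[[l]]
    A <- length(al)
    if (A < 2) next
    x <- dosage[[l]]
    p <- freqs[[l]][al]
    xw <- sweep(x, 2, sqrt(p), "/")          # x_ia / sqrt(p_a)
    cross <- tcrossprod(ifelse(is.na(xw), 0, xw))
    typed <- !is.na(x[, 1])
    tt <- tcrossprod(as.numeric(typed))       # 1 when both typed
    Fl <- (cross - 1) / (A - 1)
    w <- A - 1
    num <- num + w * Fl * tt
    den <- den + w * tt
  }
  K <- num / den
  if (any(den == 0)) {
    warning("pairs with no shared typed loci set to kinship 0")
    K[den == 0] <- 0
  }
  ids <- rownames(genotypes) %||% sprintf("ind%03d", seq_len(n))
  dimnames(K) <- list(ids, ids)
  list(K = (K + t(K)) / 2, freqs = freqs)
}

#' Zero out negative kinship estimates
#'
#' Moment-estimator kinship can go negative for unrelated pairs; for use as
#' a mixed-model covariance the usual practice is to truncate at zero.
#'
#' @param K Kinship matrix (or list as returned by [ritland_kinship()]).
#' @return Truncated kinship matrix (symmetry preserved).
#' @export
truncate_negative <- function(K) {
  if (is.list(K)) K <- K$K
  pmax(K, 0)
}

#' Mixed-model relationship covariance from a kinship matrix
#'
#' Returns 2K with the diagonal floored at 1, the unit-scale relationship
#' matrix expected by the unified Q+K mixed model.
#'
#' @param K (Truncated) kinship matrix.
#' @return Covariance matrix 2K, diag >= 1.
#' @export
kinship_to_covariance <- function(K) {
  G <- 2 * K
  diag(G) <- pmax(diag(G), 1)
  G
}
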