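#' Simulate haplotypes under the standard neutral coalescent
#'
#' Kingman n-coalescent with exponential waiting times, no recombination,
#' and infinite-sites mutations dropped on branches as a Poisson process
#' (rate theta_per_site * L / 2 per lineage per unit of coalescent time) and
#' placed at uniformly drawn distinct sites. The ancestral sequence is
#' i.i.d. uniform over \{A,C,G,T\}; each mutation substitutes a uniformly
#' chosen different base.
#'
#' Under this model the expected number of segregating sites is
#' theta_per_site * L * a1 with a1 = sum_\{i=1\}^\{n-1\} 1/i, and the expected
#' per-site mean pairwise difference equals theta_per_site.
#'
#' @param n Sample size (number of haplotypes), >= 2.
#' @param theta_per_site Scaled mutation rate per site, >= 0.
#' @param L Sequence length in bp, >= 1.
#' @param seed Optional integer seed.
#' @param ancestral Optional ancestral sequence (length-L string).
#' @return List with elements \code{sequences} (character vector of n
#'   strings), \code{positions} (1-based variant columns), \code{ancestral},
#'   and \code{snp_matrix} (n x S matrix of bases at the variant columns).
#' @export
simulate_coalescent_haplotypes <- function(n, theta_per_site, L, seed = NULL,
                                           ancestral = NULL) {
  if (n < 2) stop("invalid argument: n must be >= 2")
  if (L < 1) stop("invalid argument: L must be >= 1")
  if (theta_per_site < 0) stop("invalid argument: theta_per_site must be >= 0")
  maybe_seed(seed)

  if (is.null(ancestral)) ancestral <- random_dna(L)
  anc <- strsplit(toupper(ancestral), "", fixed = TRUE)[[1]]
  if (length(anc) != L) stop("ancestral sequence must have length L")

  mut_rate <- theta_per_site * L / 2
  active <- lapply(seq_len(n), identity)  # descendant tip sets per lineage
  carriers <- list()
  k <- n
  while (k >= 2) {
    t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
    n_mut <- stats::rpois(1, lambda = k * t_k * mut_rate)
    if (n_mut > 0) {
      lin <- sample.int(k, n_mut, replace = TRUE)
      carriers <- c(carriers, active[lin])
    }
    pair <- sample.int(k, 2)
    merged <- c(active[[pair[1]]], active[[pair[2]]])
    active[[min(pair)]] <- merged
    active[[max(pair)]] <- NULL
    k <- k - 1
  }

  S <- length(carriers)
  if (S > L) stop("more mutations than sites; increase L or lower theta")
  pos <- sort(sample.int(L, S))
  # shuffle carrier-to-position assignment so position order is uninformative
  carriers <- carriers[sample.int(max(S, 1), S)]

  seqm <- matrix(rep(anc, each = n), nrow = n)
  bases <- c("A", "C", "G", "T")
  snp <- matrix(character(0), nrow = n, ncol = S)
  for (j in seq_len(S)) {
    ref <- anc[pos[j]]
    derived <- sample(setdiff(bases, ref), 1)
    col <- rep(ref, n)
    col[carriers[[j]]] <- derived
    seqm[, pos[j]] <- col
    snp[, j] <- col
  }
  colnames(snp) <- if (S > 0) as.character(pos) else NULL

  list(sequences = matrix_to_seq(seqm),
       positions = pos,
       ancestral = paste(anc, collapse = ""),
       snp_matrix = snp)
}
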