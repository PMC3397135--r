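analyzed_columns <- function(m) {
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  which(colSums(ok) == nrow(m))
}

# per-column pairwise-difference bookkeeping shared by k, S and D
aln_site_stats <- function(aln) {
  m <- seq_matrix(aln)
  n <- nrow(m)
  if (n < 2) stop("at least 2 sequences required")
  cols <- analyzed_columns(m)
  L_eff <- length(cols)
  npairs <- n * (n - 1) / 2
  diff_sum <- 0
  S <- 0L
  for (j in cols) {
    tab <- tabulate(match(m[, j], c("A", "C", "G", "T")), 4L)
    same <- sum(tab * (tab - 1) / 2)
    if (sum(tab > 0) > 1) S <- S + 1L
    diff_sum <- diff_sum + (npairs - same)
  }
  list(n = n, L_eff = L_eff, S = S, k = diff_sum / npairs, m = m, cols = cols)
}

#' Nucleotide diversity
#'
#' Mean number of pairwise differences (k) over all sequence pairs, counted
#' over analyzed columns, and its per-site value pi = k / L_eff. Columns
#' containing any gap, N or ambiguity code are excluded ("complete
#' deletion"); pass \code{deletion = "pairwise"} to count each pair over its
#' own complete columns instead.
#'
#' @param aln Character vector of aligned sequences or character matrix.
#' @param deletion "complete" (default) or "pairwise".
#' @return List with \code{k} (absolute) and \code{pi} (per analyzed site).
#' @export
nucleotide_diversity <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  if (deletion == "complete") {
    st <- aln_site_stats(aln)
    if (st$L_eff == 0) stop("undefined statistic: no analyzed sites")
    return(list(k = st$k, pi = st$k / st$L_eff))
  }
  m <- seq_matrix(aln)
  n <- nrow(m)
  if (n < 2) stop("at least 2 sequences required")
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = n)
  tot_d <- 0; tot_p <- 0; npairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- ok[i, ] & ok[j, ]
    if (!any(use)) next
    d <- sum(m[i, use] != m[j, use])
    tot_d <- tot_d + d
    tot_p <- tot_p + d / sum(use)
    npairs <- npairs + 1
  }
  if (npairs == 0) stop("undefined statistic: no comparable pairs")
  list(k = tot_d / npairs, pi = tot_p / npairs)
}

#' Watterson's estimator of the population mutation rate
#'
#' theta_w = S / (a1 * L_eff) with a1 = sum_\{i=1\}^\{n-1\} 1/i.
#'
#' @inheritParams nucleotide_diversity
#' @return theta_w per site.
#' @export
watterson_theta <- function(aln) {
  st <- aln_site_stats(aln)
  if (st$L_eff == 0) stop("undefined statistic: no analyzed sites")
  a1 <- sum(1 / seq_len(st$n - 1))
  st$S / (a1 * st$L_eff)
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D with beta-approximation significance
#'
#' D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1)). The two-tailed p-value uses
#' the scaled beta approximation of the null density of D over its support
#' [Dmin, Dmax] (Dmin = (2/n - 1/a1)/sqrt(e2); Dmax = (n/(2(n-1)) - 1/a1) /
#' sqrt(e2) for even n, ((n+1)/(2n) - 1/a1)/sqrt(e2) for odd n).
#'
#' @inheritParams nucleotide_diversity
#' @return List with \code{D}, \code{p_value} (two-tailed), \code{S},
#'   \code{k}, and the constants used.
#' @export
tajimas_d <- function(aln) {
  st <- aln_site_stats(aln)
  if (st$S == 0) stop("undefined statistic: no segregating sites")
  n <- st$n
  cc <- tajima_constants(n)
  D <- (st$k - st$S / cc$a1) / sqrt(cc$e1 * st$S + cc$e2 * st$S * (st$S - 1))
  dmin <- (2 / n - 1 / cc$a1) / sqrt(cc$e2)
  dmax <- (if (n %% 2 == 0) n / (2 * (n - 1)) else (n + 1) / (2 * n)) -
    1 / cc$a1
  dmax <- dmax / sqrt(cc$e2)
  alpha <- -(1 + dmin * dmax) * dmax / (dmax - dmin)
  beta <- (1 + dmin * dmax) * dmin / (dmax - dmin)
  cdf <- function(x) {
    u <- (x - dmin) / (dmax - dmin)
    stats::pbeta(min(max(u, 0), 1), shape1 = beta, shape2 = alpha)
  }
  p <- cdf(-abs(D)) + (1 - cdf(abs(D)))
  list(D = D, p_value = min(p, 1), S = st$S, k = st$k, constants = cc)
}

#' Simulated null distribution of Tajima's D conditional on S
#'
#' Draws replicate genealogies under the standard neutral coalescent and
#' places exactly S mutations on each (branch chosen proportional to its
#' length, carriers = the branch's descendant tips), yielding the null
#' distribution of D conditional on the observed number of segregating
#' sites. This is the calibrated alternative to the beta approximation,
#' whose tails are known to be mildly conservative.
#'
#' @param n Number of sequences.
#' @param S Number of segregating sites (>= 1).
#' @param nrep Number of null replicates.
#' @param seed Optional seed.
#' @return Numeric vector of simulated D values.
#' @export
tajima_null_d <- function(n, S, nrep = 1000, seed = NULL) {
  stopifnot(n >= 4, S >= 1)
  maybe_seed(seed)
  cc <- tajima_constants(n)
  denom <- sqrt(cc$e1 * S + cc$e2 * S * (S - 1))
  vapply(seq_len(nrep), function(i) {
    active <- rep(1L, n)
    seg_sizes <- vector("list", n - 1)
    seg_w <- numeric(n - 1)
    k <- n
    while (k >= 2) {
      t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
      seg_sizes[[n - k + 1]] <- active
      seg_w[n - k + 1] <- k * t_k
      pair <- sample.int(k, 2)
      active[min(pair)] <- active[pair[1]] + active[pair[2]]
      active <- active[-max(pair)]
      k <- k - 1L
    }
    seg <- sample.int(n - 1, S, replace = TRUE, prob = seg_w)
    carriers <- vapply(seg, function(s) {
      sz <- seg_sizes[[s]]
      sz[sample.int(length(sz), 1)]
    }, integer(1))
    k_pi <- sum(2 * carriers * (n - carriers)) / (n * (n - 1))
    (k_pi - S / cc$a1) / denom
  }, numeric(1))
}

#' Equal-tail simulation p-value for Tajima's D
#'
#' @param D Observed statistic.
#' @param null_d Simulated null draws (see [tajima_null_d()]).
#' @return Two-tailed p-value with add-one correction.
#' @export
tajima_sim_pvalue <- function(D, null_d) {
  B <- length(null_d)
  lo <- (1 + sum(null_d <= D)) / (B + 1)
  hi <- (1 + sum(null_d >= D)) / (B + 1)
  min(1, 2 * min(lo, hi))
}

#' Haplotype count and haplotype diversity with standard deviation
#'
#' Hd = n (1 - sum p_i^2) / (n - 1); the standard deviation is the square
#' root of Nei's (1987) sampling variance of Hd.
#'
#' @inheritParams nucleotide_diversity
#' @return List with \code{n_haplotypes}, \code{Hd}, \code{sd}.
#' @export
haplotype_stats <- function(aln) {
  m <- seq_matrix(aln)
  n <- nrow(m)
  if (n < 2) stop("at least 2 sequences required")
  cols <- analyzed_columns(m)
  haps <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
  tab <- table(haps)
  p <- as.numeric(tab) / n
  sp2 <- sum(p^2)
  Hd <- n * (1 - sp2) / (n - 1)
  V <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - sp2^2) + sp2 - sp2^2)
  list(n_haplotypes = length(tab), Hd = Hd, sd = sqrt(max(V, 0)))
}

#' Sliding-window Tajima's D
#'
#' @inheritParams nucleotide_diversity
#' @param window_bp,step_bp Window and step size in alignment columns.
#' @return data.frame(start, end, S, D, p_value); windows without
#'   segregating sites carry NA.
#' @export
sliding_tajima <- function(aln, window_bp = 100, step_bp = 25) {
  stopifnot(window_bp >= 1, step_bp >= 1)
  m <- seq_matrix(aln)
  L <- ncol(m)
  if (window_bp > L) { window_bp <- L; step_bp <- L }
  starts <- seq(1, max(L - window_bp + 1, 1), by = step_bp)
  out <- lapply(starts, function(s) {
    e <- min(s + window_bp - 1, L)
    sub <- m[, s:e, drop = FALSE]
    res <- tryCatch(tajimas_d(sub), error = function(err) NULL)
    data.frame(start = s, end = e,
               S = if (is.null(res)) 0L else res$S,
               D = if (is.null(res)) NA_real_ else res$D,
               p_value = if (is.null(res)) NA_real_ else res$p_value)
  })
  do.call(rbind, out)
}

#' Per-group sequence diversity summary table
#'
#' One row per group (plus "overall"): n sequences, segregating sites, pi,
#' Watterson's theta, Tajima's D with its p-value, haplotype count and
#' haplotype diversity with SD.
#'
#' @param aln Aligned sequences (two per individual).
#' @param groups Optional character vector (one label per sequence).
#' @return data.frame in diversity-table layout.
#' @export
diversity_summary <- function(aln, groups = NULL) {
  m <- seq_matrix(aln)
  grp <- if (is.null(groups)) list(overall = seq_len(nrow(m)))
         else c(split(seq_len(nrow(m)), groups),
                list(overall = seq_len(nrow(m))))
  out <- lapply(names(grp), function(g) {
    sub <- m[grp[[g]], , drop = FALSE]
    nd <- nucleotide_diversity(sub)
    th <- watterson_theta(sub)
    td <- tryCatch(tajimas_d(sub), error = function(e) NULL)
    hs <- haplotype_stats(sub)
    st <- aln_site_stats(sub)
    data.frame(group = g, n_sequences = nrow(sub), S = st$S,
               pi = nd$pi, theta_w = th,
               tajima_d = if (is.null(td)) NA_real_ else td$D,
               d_pvalue = if (is.null(td)) NA_real_ else td$p_value,
               n_haplotypes = hs$n_haplotypes,
               hap_diversity = hs$Hd, hap_diversity_sd = hs$sd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
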