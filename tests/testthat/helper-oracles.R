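# Independent brute-force oracles; deliberately naive implementations kept
# separate from the package's code paths.

oracle_pairwise <- function(aln) {
  m <- seq_matrix(aln)
  ok <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, ok, drop = FALSE]
  n <- nrow(m)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(m[i, ] != m[j, ])
    np <- np + 1
  }
  list(k = tot / np, S = sum(apply(m, 2, function(c) length(unique(c)) > 1)),
       L_eff = ncol(m))
}

oracle_hd <- function(aln) {
  m <- seq_matrix(aln)
  ok <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  haps <- apply(m[, ok, drop = FALSE], 1, paste, collapse = "")
  n <- length(haps)
  p <- as.numeric(table(haps)) / n
  sp2 <- sum(p^2)
  Hd <- n / (n - 1) * (1 - sp2)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (sum(p^3) - sp2^2) + sp2 - sp2^2)
  list(n_haplotypes = length(p), Hd = Hd, sd = sqrt(max(V, 0)))
}

random_alignment <- function(n, L, n_var = max(1, round(L / 10))) {
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(rep(anc, each = n), nrow = n)
  vpos <- sample.int(L, n_var)
  for (p in vpos) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), anc[p]), 1)
    carriers <- sample.int(n, sample.int(n - 1, 1))
    m[carriers, p] <- alt
  }
  m
}

# Weir & Cockerham (1984) theta for diploid multi-allelic data
oracle_wc_fst <- function(genotypes, pops) {
  num <- 0; den <- 0
  for (l in seq_len(ncol(genotypes))) {
    gl <- genotypes[, l]
    al <- strsplit(gl, "/", fixed = TRUE)
    alleles <- unique(unlist(al))
    pops_u <- unique(pops)
    r <- length(pops_u)
    n_i <- vapply(pops_u, function(p) sum(pops == p & !is.na(gl)), numeric(1))
    nbar <- mean(n_i)
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    for (a in alleles) {
      cnt <- vapply(al, function(x) sum(x == a), numeric(1))
      p_i <- vapply(pops_u, function(p) {
        idx <- pops == p & !is.na(gl)
        sum(cnt[idx]) / (2 * sum(idx))
      }, numeric(1))
      h_i <- vapply(pops_u, function(p) {
        idx <- pops == p & !is.na(gl)
        mean(cnt[idx] == 1)
      }, numeric(1))
      pbar <- sum(n_i * p_i) / sum(n_i)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / sum(n_i)
      a_comp <- nbar / nc * (s2 - 1 / (nbar - 1) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
      b_comp <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r - (2 * nbar - 1) / (4 * nbar) * hbar)
      c_comp <- hbar / 2
      num <- num + a_comp
      den <- den + a_comp + b_comp + c_comp
    }
  }
  num / den
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in 0:(n - 1)) out[[length(out) + 1]] <- append(p, n, after = k)
  }
  out
}

# G statistic of a two-locus genotype table, naive version
oracle_g_stat <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  cells <- tab > 0
  2 * sum(tab[cells] * log(tab[cells] / E[cells]))
}

# explicit restricted log-likelihood for y = Xb + u + e, u ~ N(0, sg2 G),
# evaluated on a delta grid (delta = se2/sg2)
oracle_reml_grid <- function(y, X, G, logdelta_grid) {
  n <- length(y); p <- qr(X)$rank
  vapply(logdelta_grid, function(ld) {
    V <- G + exp(ld) * diag(n)
    Vi <- solve(V)
    XtVX <- t(X) %*% Vi %*% X
    b <- solve(XtVX, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    rss <- drop(t(r) %*% Vi %*% r)
    -0.5 * ((n - p) * log(rss) + determinant(V)$modulus +
              determinant(XtVX)$modulus)
  }, numeric(1))
}

make_small_study <- function(n = 8, seed = 5, ...) {
  simulate_study(sim_config(n_individuals = n, seed = seed, ...))
}
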