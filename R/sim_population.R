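#' Simulate multi-allelic SSR genotypes in a structured population
#'
#' Global allele frequencies per locus are drawn from a flat Dirichlet;
#' per-population frequencies follow a Balding-Nichols style Dirichlet
#' centred on the global frequencies with concentration (1 - fst) / fst, so
#' the expected Weir-Cockerham differentiation approximates \code{fst}.
#' Each individual draws its two allele copies independently; for admixed
#' individuals each copy first draws a source population from the
#' individual's row of \code{Q_true}.
#'
#' @param config A [sim_config()].
#' @param n_individuals Optional override of config$n_individuals (the SSR
#'   panel of a study is often larger than the sequencing panel).
#' @param Q_true Optional individuals x populations membership matrix (rows
#'   sum to 1). Default: balanced one-hot assignment.
#' @param seed Optional seed.
#' @return List with \code{genotypes} (individuals x loci matrix of "a/b"
#'   strings), \code{Q_true}, \code{global_freqs}, \code{pop_freqs}.
#' @export
simulate_ssr_genotypes <- function(config, n_individuals = NULL, Q_true = NULL,
                                   seed = NULL) {
  maybe_seed(seed)
  n <- n_individuals %||% config$n_individuals
  P <- config$n_populations
  Lc <- config$n_ssr_loci
  A <- config$alleles_per_locus
  if (A < 2) stop("alleles_per_locus must be >= 2")
  fst <- config$fst

  if (is.null(Q_true)) {
    pop <- rep(seq_len(P), length.out = n)
    Q_true <- matrix(0, n, P)
    Q_true[cbind(seq_len(n), pop)] <- 1
  }
  stopifnot(nrow(Q_true) == n, ncol(Q_true) == P,
            all(abs(rowSums(Q_true) - 1) < 1e-8))
  rownames(Q_true) <- sprintf("ind%03d", seq_len(n))

  rdirichlet1 <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha)
    if (sum(g) == 0) g <- rep(1, length(alpha))
    g / sum(g)
  }

  global <- vector("list", Lc)
  popf <- vector("list", Lc)
  for (l in seq_len(Lc)) {
    p0 <- rdirichlet1(rep(1, A))
    # keep all global frequencies usable as Dirichlet centres
    p0 <- (p0 + 0.05) / sum(p0 + 0.05)
    global[[l]] <- p0
    if (fst == 0) {
      popf[[l]] <- matrix(rep(p0, each = P), nrow = P)
    } else {
      conc <- (1 - fst) / fst
      popf[[l]] <- t(vapply(seq_len(P), function(k) rdirichlet1(p0 * conc),
                            numeric(A)))
    }
  }

  geno <- matrix(NA_character_, n, Lc,
                 dimnames = list(rownames(Q_true), sprintf("ssr%03d", seq_len(Lc))))
  for (i in seq_len(n)) {
    for (l in seq_len(Lc)) {
      src <- sample.int(P, 2, replace = TRUE, prob = Q_true[i, ])
      a1 <- sample.int(A, 1, prob = popf[[l]][src[1], ])
      a2 <- sample.int(A, 1, prob = popf[[l]][src[2], ])
      geno[i, l] <- paste(sort(c(a1, a2)), collapse = "/")
    }
  }
  list(genotypes = geno, Q_true = Q_true, global_freqs = global,
       pop_freqs = popf)
}

#' Simulate a quantitative phenotype with structure, polygenic and QTN parts
#'
#' y = Q_true v + g + beta * dosage + e, with g ~ MVN(0, sigma_g^2 * 2K) and
#' e i.i.d. Normal(0, noise_sd^2). sigma_g^2 is chosen so that the polygenic
#' share of (polygenic + noise) variance equals \code{heritability}:
#' sigma_g^2 = h2 / ((1 - h2) * mean(diag(2K))) * noise_sd^2.
#'
#' @param Q_true Individuals x populations membership matrix.
#' @param kinship Individuals x individuals kinship matrix (K, not 2K).
#' @param dosage Numeric QTN dosage vector (0/1/2).
#' @param v Population effect vector (length = ncol(Q_true)).
#' @param beta QTN effect size.
#' @param heritability Polygenic heritability in [0, 1).
#' @param noise_sd Residual standard deviation.
#' @param seed Optional seed.
#' @return List with \code{y} and \code{components} (structure, polygenic,
#'   qtn, noise vectors).
#' @export
simulate_phenotype <- function(Q_true, kinship, dosage, v = NULL, beta = 0,
                               heritability = 0.3, noise_sd = 1, seed = NULL) {
  if (heritability >= 1 || heritability < 0)
    stop("invalid argument: heritability must lie in [0, 1)")
  n <- nrow(Q_true)
  stopifnot(nrow(kinship) == n, ncol(kinship) == n, length(dosage) == n)
  maybe_seed(seed)
  if (is.null(v)) v <- rep(0, ncol(Q_true))
  structure_part <- as.numeric(Q_true %*% v)

  G <- 2 * kinship
  if (heritability > 0) {
    sg2 <- heritability / (1 - heritability) / mean(diag(G)) * noise_sd^2
    # zero-truncated kinship need not be PSD; clip negative eigenvalues
    eg <- eigen(G, symmetric = TRUE)
    rt <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
    polygenic <- as.numeric(rt %*% stats::rnorm(n)) * sqrt(sg2)
  } else {
    polygenic <- rep(0, n)
  }
  qtn_part <- beta * dosage
  noise <- stats::rnorm(n, sd = noise_sd)
  y <- structure_part + polygenic + qtn_part + noise
  names(y) <- rownames(Q_true)
  list(y = y, components = list(structure = structure_part,
                                polygenic = polygenic,
                                qtn = qtn_part, noise = noise))
}

#' Simulate a complete study: sequences, reads, SSRs, kinship truth, phenotype
#'
#' One seeded generator drives everything: per contig a neutral coalescent
#' sample of 2n haplotypes is paired into individuals, tagged amplicon reads
#' are generated per individual, SSR genotypes and the true Q matrix are
#' simulated, and a phenotype with structure + polygenic + QTN components is
#' built on top. The QTN is the variant closest to the requested position on
#' the requested contig (or the highest-MAF variant when no position is
#' given).
#'
#' @param config A [sim_config()].
#' @return List with \code{truth} (haplotypes, variant positions, SSR
#'   genotypes, Q_true, phenotype components, qtn), \code{reads} (one
#'   data.frame), \code{tags} (named vector), \code{references} (named
#'   vector of contig reference sequences = coalescent ancestral sequences),
#'   \code{design} (combined design table) and \code{config}.
#' @export
simulate_study <- function(config) {
  set.seed(config$seed)
  n <- config$n_individuals
  inds <- sprintf("ind%03d", seq_len(n))
  tags <- make_tags(n)
  names(tags) <- inds

  truth_haps <- list(); references <- character(0)
  variant_positions <- list()
  designs <- list()
  reads <- vector("list", length(config$contigs) * n)
  ri <- 1
  for (ct in config$contigs) {
    sim <- simulate_coalescent_haplotypes(2 * n, config$theta_per_site, ct$length)
    references[ct$id] <- sim$ancestral
    variant_positions[[ct$id]] <- sim$positions
    hp <- lapply(seq_len(n), function(i) sim$sequences[c(2 * i - 1, 2 * i)])
    names(hp) <- inds
    truth_haps[[ct$id]] <- hp
    designs[[ct$id]] <- ct$design
    for (i in seq_len(n)) {
      reads[[ri]] <- simulate_reads(hp[[i]], ct$design, config,
                                    tag = tags[i], individual = inds[i])
      ri <- ri + 1
    }
  }
  reads <- do.call(rbind, reads)
  design <- do.call(rbind, designs)
  rownames(design) <- NULL

  ssr <- simulate_ssr_genotypes(config, n_individuals = n)
  rownames(ssr$Q_true) <- inds
  rownames(ssr$genotypes) <- inds

  K <- ritland_kinship(ssr$genotypes)$K
  Kt <- truncate_negative(K)

  qtn <- config$qtn
  qcontig <- qtn$contig %||% config$contigs[[1]]$id
  pos <- variant_positions[[qcontig]]
  if (length(pos) == 0) {
    dosage <- rep(0, n); qtn_pos <- NA_integer_
  } else {
    hapm <- seq_matrix(unlist(lapply(truth_haps[[qcontig]], identity)))
    freqs <- vapply(pos, function(p) {
      col <- hapm[, p]; tab <- table(col); min(tab) / length(col)
    }, numeric(1))
    if (!is.null(qtn$position)) {
      qtn_pos <- pos[which.min(abs(pos - qtn$position))]
    } else {
      qtn_pos <- pos[which.max(freqs)]
    }
    ref <- substr(references[qcontig], qtn_pos, qtn_pos)
    dosage <- vapply(truth_haps[[qcontig]], function(h) {
      sum(substr(h, qtn_pos, qtn_pos) != ref)
    }, numeric(1))
  }

  pheno <- simulate_phenotype(ssr$Q_true, Kt, dosage,
                              v = seq_len(config$n_populations) - 1,
                              beta = qtn$effect %||% 1,
                              heritability = config$heritability_polygenic)

  list(truth = list(haplotypes = truth_haps,
                    variant_positions = variant_positions,
                    ssr_genotypes = ssr$genotypes,
                    Q_true = ssr$Q_true,
                    kinship = Kt,
                    phenotype = pheno,
                    qtn = list(contig = qcontig, position = qtn_pos,
                               dosage = dosage,
                               effect = qtn$effect %||% 1)),
       reads = reads, tags = tags, references = references,
       design = design, config = config)
}
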