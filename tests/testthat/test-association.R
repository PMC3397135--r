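test_that("with zero kinship and no Q the fit collapses to one-way OLS", {
  set.seed(601)
  for (rep in 1:5) {
    n <- 40
    marker <- sample(c("A/A", "A/G", "G/G"), n, TRUE)
    y <- rnorm(n) + 0.5 * (marker == "G/G")
    fit <- fit_mlm_single_marker(y, marker, Q = NULL,
                                 K2 = matrix(0, n, n), min_class_size = 1)
    av <- anova(lm(y ~ factor(marker)))
    expect_equal(fit$F, av$`F value`[1], tolerance = 1e-8)
    expect_equal(fit$p_value, av$`Pr(>F)`[1], tolerance = 1e-8)
    expect_equal(fit$marker_r2,
                 av$`Sum Sq`[1] / sum(av$`Sum Sq`), tolerance = 1e-8)
  }
})

test_that("profiled REML maximum matches a grid-search oracle", {
  set.seed(602)
  n <- 50
  K <- tcrossprod(matrix(rnorm(n * 3), n)) / 3 / 2
  G <- kinship_to_covariance(K)
  X <- cbind(1, rnorm(n))
  eg <- eigen(G, symmetric = TRUE)
  u <- drop(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(n)))
  y <- drop(X %*% c(1, 0.5)) + u + rnorm(n)
  fit <- amplipop:::reml_profile(y, X, G)
  grid <- seq(log(1e-5), log(1e5), length.out = 4001)
  ll <- oracle_reml_grid(y, X, G, grid)
  expect_lt(abs(fit$logdelta - grid[which.max(ll)]), 0.01)
})

test_that("null p-values are uniform under a pure-noise phenotype", {
  set.seed(603)
  n <- 60
  K2 <- diag(n)
  p <- vapply(1:300, function(i) {
    marker <- sample(c("A/A", "A/G", "G/G"), n, TRUE, prob = c(0.36, 0.48, 0.16))
    y <- rnorm(n)
    tryCatch(fit_mlm_single_marker(y, marker, K2 = K2)$p_value,
             error = function(e) NA)
  }, numeric(1))
  p <- p[!is.na(p)]
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("Q+K controls structure confounding where naive OLS inflates", {
  set.seed(604)
  n <- 90; n_pop <- 3
  pop <- rep(seq_len(n_pop), each = n / n_pop)
  Q <- matrix(0, n, n_pop); Q[cbind(1:n, pop)] <- 1
  # population-differentiated null markers + structured phenotype
  n_tests <- 400
  p_mlm <- p_ols <- numeric(n_tests)
  K2 <- kinship_to_covariance(tcrossprod(Q) * 0.2)
  for (i in seq_len(n_tests)) {
    pf <- rbeta(n_pop, 0.8, 0.8) * 0.6 + 0.2
    dos <- rbinom(n, 2, pf[pop])
    marker <- c("A/A", "A/G", "G/G")[dos + 1]
    y <- pop * 1.0 + drop(K2 %*% rnorm(n)) * 0.4 + rnorm(n)
    p_mlm[i] <- tryCatch(
      fit_mlm_single_marker(y, marker, Q = Q, K2 = K2)$p_value,
      error = function(e) NA)
    p_ols[i] <- tryCatch(
      fit_mlm_single_marker(y, marker, Q = NULL,
                            K2 = matrix(0, n, n))$p_value,
      error = function(e) NA)
  }
  rate_mlm <- mean(p_mlm < 0.01, na.rm = TRUE)
  rate_ols <- mean(p_ols < 0.01, na.rm = TRUE)
  expect_lt(rate_mlm, 0.01 + 3 * sqrt(0.01 * 0.99 / n_tests))
  expect_gt(rate_ols, rate_mlm)
  expect_gt(rate_ols, 0.05)  # structure confounding inflates naive OLS
})

test_that("a large-effect QTN tops the scan under polygenic background", {
  set.seed(605)
  hits <- 0
  for (rep in 1:20) {
    n <- 60
    K <- tcrossprod(matrix(rnorm(n * 4), n)) / 4 / 2
    K2 <- kinship_to_covariance(truncate_negative(K))
    markers <- matrix(sample(c("A/A", "A/G", "G/G"), n * 20, TRUE), n, 20,
                      dimnames = list(NULL, paste0("m", 1:20)))
    qdos <- vapply(markers[, 7], function(g)
      sum(strsplit(g, "/")[[1]] == "G"), numeric(1))
    eg <- eigen(K2, symmetric = TRUE)
    u <- drop(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(n)))
    y <- 1.5 * qdos + u + rnorm(n)
    scan <- association_scan(data.frame(y = y), markers, K2 = K2,
                             maf_threshold = 0)
    if (scan$marker[which.min(scan$p_value)] == "m7") hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("scan shape, monomorphic dropping and q-value families", {
  set.seed(606)
  n <- 40
  markers <- cbind(m1 = sample(c("A/A", "A/G", "G/G"), n, TRUE),
                   m2 = sample(c("C/C", "C/T"), n, TRUE),
                   m3 = rep("T/T", n))
  ph <- data.frame(t1 = rnorm(n), t2 = rnorm(n))
  scan <- association_scan(ph, markers, K2 = diag(n), maf_threshold = 0)
  expect_equal(nrow(scan), 4)  # 2 traits x 2 polymorphic markers
  expect_false("m3" %in% scan$marker)
  glob <- association_scan(ph, markers, K2 = diag(n), maf_threshold = 0,
                           family = "global")
  expect_equal(nrow(glob), 4)
  expect_true(all(glob$q_value >= 0 & glob$q_value <= 1))
})

test_that("scan results are invariant to marker order", {
  set.seed(607)
  n <- 40
  markers <- matrix(sample(c("A/A", "A/G", "G/G"), n * 5, TRUE), n, 5,
                    dimnames = list(NULL, paste0("m", 1:5)))
  ph <- data.frame(y = rnorm(n))
  s1 <- association_scan(ph, markers, K2 = diag(n), maf_threshold = 0)
  s2 <- association_scan(ph, markers[, 5:1], K2 = diag(n), maf_threshold = 0)
  s2 <- s2[match(s1$marker, s2$marker), ]
  expect_equal(s1$p_value, s2$p_value)
})

test_that("qq data follows the plotting-position convention", {
  qq <- qq_data(0.5)
  expect_equal(qq$expected, 0.5)
  expect_equal(qq$observed, 0.5)
  set.seed(608)
  qq2 <- qq_data(runif(1000))
  expect_lt(max(abs(qq2$observed - qq2$expected)), 1.63 / sqrt(1000) + 0.01)
  qq3 <- qq_data(rep(1, 4))
  expect_true(all(qq3$observed == 1))
  expect_equal(qq3$expected, (1:4 - 0.5) / 4)
})

test_that("genotype class summaries report shares and means", {
  y <- c(rnorm(56, 10), rnorm(5, 14))
  marker <- c(rep("C/C", 56), rep("C/T", 5))
  gs <- genotype_class_summary(y, marker)
  minor <- gs[gs$class == "C/T", ]
  expect_equal(round(minor$pct), 8)  # 5 of 61
  expect_equal(minor$n, 5)
  expect_equal(minor$mean_phenotype, mean(y[57:61]))
  one <- genotype_class_summary(rnorm(10), rep("A/A", 10))
  expect_equal(one$pct, 100)
  grp <- genotype_class_summary(y, marker,
                                groups = rep(c("ca", "fa"), length.out = 61))
  expect_true("overall" %in% grp$group)
  expect_equal(grp$mean_phenotype[grp$group == "ca" & grp$class == "C/C"],
               mean(y[marker == "C/C" & rep(c("ca", "fa"),
                                            length.out = 61) == "ca"]))
})

test_that("degenerate inputs raise the documented errors", {
  n <- 30
  expect_error(fit_mlm_single_marker(rep(1, n),
                                     sample(c("A/A", "A/G"), n, TRUE),
                                     K2 = diag(n)),
               "constant phenotype")
  expect_error(fit_mlm_single_marker(rnorm(n), rep("A/A", n), K2 = diag(n)),
               "fewer than 2 classes")
})
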