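# profiled REML machinery for y = Xb + u + e, u ~ N(0, sg2 * G),
# e ~ N(0, sg2 * delta * I); one eigendecomposition of G, 1-D optimisation
# of the REML log-likelihood in log(delta)
reml_profile <- function(y, X, G, logdelta_range = c(log(1e-5), log(1e5))) {
  n <- length(y)
  p <- qr(X)$rank
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)

  crit <- function(logdelta) {
    delta <- exp(logdelta)
    w <- 1 / (d + delta)
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    b <- solve(XtWX, XtWy)
    r <- ys - drop(Xs %*% b)
    rss <- sum(w * r^2)
    # restricted log-likelihood up to delta-free constants
    -0.5 * ((n - p) * log(rss) + sum(log(d + delta)) +
              determinant(XtWX, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(crit, interval = logdelta_range, maximum = TRUE)
  delta <- exp(opt$maximum)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xs, Xs * w)
  b <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - drop(Xs %*% b)
  rss <- sum(w * r^2)
  sg2 <- rss / (n - p)
  list(delta = delta, sg2 = sg2, se2 = sg2 * delta, b = drop(b),
       XtWX = XtWX, rss = rss, n = n, rank = p,
       ys = ys, Xs = Xs, w = w, logdelta = opt$maximum)
}

encode_marker <- function(marker, encoding = c("genotype", "additive"),
                          min_class_size = 3, pool_other = FALSE) {
  encoding <- match.arg(encoding)
  if (encoding == "additive") {
    m <- as.numeric(marker)
    return(list(design = matrix(m, ncol = 1,
                                dimnames = list(NULL, "dosage")),
                keep = !is.na(m), classes = NULL))
  }
  f <- genotype_classes(as.character(marker))
  tab <- table(f)
  small <- names(tab)[tab < min_class_size]
  if (length(small) > 0) {
    if (pool_other && sum(tab[small]) >= min_class_size) {
      levels(f) <- c(levels(f), "other")
      f[f %in% small] <- "other"
      f <- droplevels(f)
    } else {
      f[f %in% small] <- NA
      f <- droplevels(f)
    }
  }
  keep <- !is.na(f)
  if (nlevels(droplevels(f[keep])) < 2)
    return(list(design = NULL, keep = keep, classes = levels(f)))
  ff <- droplevels(f[keep])
  mm <- stats::model.matrix(~ff)[, -1, drop = FALSE]
  design <- matrix(NA_real_, length(f), ncol(mm),
                   dimnames = list(NULL, colnames(mm)))
  design[keep, ] <- mm
  list(design = design, keep = keep, classes = levels(ff), factor = f)
}

#' Fit the unified Q+K mixed linear model for a single marker
#'
#' Model: y = mu + marker + Q v + u + e with u ~ N(0, sigma_g^2 * G) for
#' G = 2K (diagonal floored at 1) and e ~ N(0, sigma_e^2 I). The variance
#' ratio delta = sigma_e^2 / sigma_g^2 is estimated by REML via a spectral
#' decomposition of G and a 1-D search of the profiled restricted
#' likelihood in log delta over [1e-5, 1e5]. The marker is tested by a Wald
#' F on its coefficients with denominator df = n - rank(fixed effects);
#' marker R^2 is the marker sum of squares over the total sum of squares on
#' the GLS-whitened scale.
#'
#' @param y Phenotype vector.
#' @param marker Genotype strings ("A/G") for genotype-class encoding or
#'   numeric dosages for additive encoding.
#' @param Q Optional structure covariate matrix; one column is dropped
#'   internally to avoid collinearity with the intercept.
#' @param K2 Relationship covariance G = 2K (see
#'   [kinship_to_covariance()]); a zero matrix collapses the fit to
#'   ordinary least squares.
#' @param encoding "genotype" (default) or "additive".
#' @param min_class_size Genotype classes smaller than this are dropped
#'   (SNPs) or pooled into "other" (set \code{pool_other = TRUE}, SSR use).
#' @param pool_other Pool rare classes instead of dropping them.
#' @return List (class "mlm_fit") with F, p_value, marker_r2, df1, df2,
#'   delta, sigma_g2, sigma_e2, class_means, n.
#' @export
fit_mlm_single_marker <- function(y, marker, Q = NULL, K2 = NULL,
                                  encoding = c("genotype", "additive"),
                                  min_class_size = 3, pool_other = FALSE) {
  encoding <- match.arg(encoding)
  enc <- encode_marker(marker, encoding, min_class_size, pool_other)
  if (is.null(enc$design)) stop("marker skipped: fewer than 2 classes")
  use <- enc$keep & !is.na(y)
  if (!is.null(Q)) use <- use & stats::complete.cases(Q)
  yv <- y[use]
  if (stats::var(yv) == 0) stop("degenerate model: constant phenotype")
  Xq <- if (!is.null(Q)) {
    qm <- as.matrix(Q)[use, , drop = FALSE]
    qm[, -1, drop = FALSE]  # drop the first structure column
  } else NULL
  M <- enc$design[use, , drop = FALSE]
  X0 <- cbind(`(Intercept)` = rep(1, nrow(M)), Xq)
  X <- cbind(X0, M)
  if (nrow(X) < qr(X)$rank + 2) stop("too few complete observations")
  G <- if (is.null(K2)) matrix(0, sum(use), sum(use)) else
    as.matrix(K2)[use, use, drop = FALSE]

  fit <- reml_profile(yv, X, G)
  q1 <- ncol(M)
  idx <- (ncol(X) - q1 + 1):ncol(X)
  Cinv <- solve(fit$XtWX)
  bm <- fit$b[idx]
  Vm <- fit$sg2 * Cinv[idx, idx, drop = FALSE]
  Fstat <- drop(t(bm) %*% solve(Vm, bm)) / q1
  df2 <- fit$n - fit$rank
  p <- stats::pf(Fstat, q1, df2, lower.tail = FALSE)

  # marker R^2 on the whitened scale, at the full model's delta
  w <- fit$w
  rss_full <- fit$rss
  X0s <- fit$Xs[, seq_len(ncol(X0)), drop = FALSE]
  b0 <- solve(crossprod(X0s, X0s * w), crossprod(X0s, fit$ys * w))
  rss_red <- sum(w * (fit$ys - drop(X0s %*% b0))^2)
  ones <- fit$Xs[, 1, drop = FALSE]
  bI <- solve(crossprod(ones, ones * w), crossprod(ones, fit$ys * w))
  tss <- sum(w * (fit$ys - drop(ones %*% bI))^2)
  r2 <- max(0, min(1, (rss_red - rss_full) / tss))

  class_means <- if (encoding == "genotype") {
    f <- droplevels(enc$factor[use])
    tapply(yv, f, mean)
  } else NULL

  structure(list(F = Fstat, p_value = p, marker_r2 = r2,
                 df1 = q1, df2 = df2, delta = fit$delta,
                 sigma_g2 = fit$sg2, sigma_e2 = fit$se2,
                 coefficients = fit$b, class_means = class_means,
                 n = fit$n),
            class = "mlm_fit")
}

#' Mixed-model association scan over traits and markers
#'
#' One record per (trait, marker); markers with sample MAF at or below 0.05
#' or fewer than two usable genotype classes are skipped. Storey q-values
#' are appended per family: per trait (default) or globally across all
#' trait x marker tests.
#'
#' @param phenotypes Individuals x traits data.frame or matrix.
#' @param markers Individuals x markers matrix (genotype strings or
#'   dosages, per \code{encoding}).
#' @param Q,K2 As in [fit_mlm_single_marker()].
#' @param encoding,min_class_size,pool_other Marker encoding controls.
#' @param maf_threshold Sample MAF filter for genotype-string markers.
#' @param family "per-trait" or "global" q-value family.
#' @return data.frame(trait, marker, F, p_value, marker_r2, q_value, n).
#' @export
association_scan <- function(phenotypes, markers, Q = NULL, K2 = NULL,
                             encoding = c("genotype", "additive"),
                             min_class_size = 3, pool_other = FALSE,
                             maf_threshold = 0.05,
                             family = c("per-trait", "global")) {
  encoding <- match.arg(encoding)
  family <- match.arg(family)
  phenotypes <- as.data.frame(phenotypes)
  if (!is.null(rownames(markers)) && !is.null(rownames(phenotypes)) &&
      !identical(rownames(markers), rownames(phenotypes)))
    stop("invalid input: misaligned individual ids")
  rows <- list()
  for (tr in colnames(phenotypes)) {
    for (mk in colnames(markers)) {
      mcol <- markers[, mk]
      if (encoding == "genotype") {
        al <- unlist(strsplit(stats::na.omit(as.character(mcol)), "/",
                              fixed = TRUE))
        tab <- table(al)
        if (length(tab) < 2) next
        maf <- (sum(tab) - max(tab)) / sum(tab)
        if (maf <= maf_threshold) next
      }
      fit <- tryCatch(
        fit_mlm_single_marker(phenotypes[[tr]], mcol, Q = Q, K2 = K2,
                              encoding = encoding,
                              min_class_size = min_class_size,
                              pool_other = pool_other),
        error = function(e) NULL)
      if (is.null(fit)) next
      rows[[length(rows) + 1]] <- data.frame(
        trait = tr, marker = mk, F = fit$F, p_value = fit$p_value,
        marker_r2 = fit$marker_r2, n = fit$n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  if (family == "global") {
    out$q_value <- storey_qvalues(out$p_value)
  } else {
    out$q_value <- NA_real_
    for (tr in unique(out$trait)) {
      i <- out$trait == tr
      out$q_value[i] <- storey_qvalues(out$p_value[i])
    }
  }
  rownames(out) <- NULL
  out
}

#' Quantile-quantile plot data for a p-value set
#'
#' @param p P-values.
#' @return data.frame(expected, observed, neg_log10_expected,
#'   neg_log10_observed) with expected_i = (i - 0.5) / m and observed the
#'   sorted p-values.
#' @export
qq_data <- function(p) {
  m <- length(p)
  stopifnot(m >= 1)
  obs <- sort(p)
  exp <- (seq_len(m) - 0.5) / m
  data.frame(expected = exp, observed = obs,
             neg_log10_expected = -log10(exp),
             neg_log10_observed = -log10(pmax(obs, .Machine$double.xmin)))
}

#' Phenotype means and class shares per marker genotype class
#'
#' @param y Phenotype vector.
#' @param marker Genotype strings.
#' @param groups Optional group labels (e.g. subspecies).
#' @return data.frame(group, class, n, pct, mean_phenotype); empty classes
#'   are omitted. Group "overall" is always present.
#' @export
genotype_class_summary <- function(y, marker, groups = NULL) {
  f <- genotype_classes(as.character(marker))
  use <- !is.na(f) & !is.na(y)
  grp <- if (is.null(groups)) rep("overall", length(y)) else as.character(groups)
  labels <- unique(c(grp[use], "overall"))
  out <- list()
  for (g in labels) {
    i <- use & (g == "overall" | grp == g)
    tab <- table(droplevels(f[i]))
    for (cl in names(tab)) {
      j <- i & f == cl
      out[[length(out) + 1]] <- data.frame(
        group = g, class = cl, n = sum(j),
        pct = 100 * sum(j) / sum(i),
        mean_phenotype = mean(y[j]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
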