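#' Same-chromosome marker pairs with physical distances
#'
#' @param markers Character vector of marker ids to pair.
#' @param map data.frame(marker, chrom, position_mb).
#' @param exclude Optional data.frame(marker1, marker2) of pairs to drop
#'   (unordered).
#' @return data.frame(marker1, marker2, chrom, distance_mb).
#' @export
same_chromosome_pairs <- function(markers, map, exclude = NULL) {
  missing <- setdiff(markers, map$marker)
  if (length(missing) > 0) {
    warning("markers absent from map skipped: ", paste(missing, collapse = ", "))
    markers <- setdiff(markers, missing)
  }
  map <- map[map$marker %in% markers, , drop = FALSE]
  out <- list()
  for (ch in unique(map$chrom)) {
    mk <- map[map$chrom == ch, , drop = FALSE]
    if (nrow(mk) < 2) next
    idx <- utils::combn(nrow(mk), 2)
    out[[length(out) + 1]] <- data.frame(
      marker1 = mk$marker[idx[1, ]], marker2 = mk$marker[idx[2, ]],
      chrom = ch,
      distance_mb = abs(mk$position_mb[idx[1, ]] - mk$position_mb[idx[2, ]]),
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, out) %||% data.frame(
    marker1 = character(0), marker2 = character(0), chrom = character(0),
    distance_mb = numeric(0))
  if (!is.null(exclude) && nrow(exclude) > 0 && nrow(pairs) > 0) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    pairs <- pairs[!(key(pairs$marker1, pairs$marker2) %in%
                       key(exclude$marker1, exclude$marker2)), , drop = FALSE]
  }
  rownames(pairs) <- NULL
  pairs
}

# genotype strings ("a/b", unordered) to integer class codes; NA-safe
genotype_classes <- function(g) {
  norm <- vapply(g, function(x) {
    if (is.na(x) || x == "" || x == ".") return(NA_character_)
    paste(sort(strsplit(x, "/", fixed = TRUE)[[1]]), collapse = "/")
  }, character(1), USE.NAMES = FALSE)
  factor(norm)
}

# log-likelihood-ratio (G) statistic of a two-locus genotype table via the
# margin-fixed decomposition: only sum O*log(O) changes under permutation
g_stat_parts <- function(codeA, codeB, nA, nB) {
  n <- length(codeA)
  cnt <- tabulate(codeA + nA * (codeB - 1L), nA * nB)
  obs_term <- sum(cnt[cnt > 0] * log(cnt[cnt > 0]))
  ra <- tabulate(codeA, nA); cb <- tabulate(codeB, nB)
  margin_term <- sum(ra[ra > 0] * log(ra[ra > 0])) +
    sum(cb[cb > 0] * log(cb[cb > 0]))
  list(G = 2 * (obs_term - margin_term + n * log(n)), obs_term = obs_term,
       margin_term = margin_term, n = n)
}

#' Genotypic linkage disequilibrium permutation test for two loci
#'
#' The statistic is the log-likelihood-ratio G of the two-locus genotype
#' contingency table (rows = genotype classes at locus A, columns = at
#' locus B; empty cells contribute nothing). Significance comes from
#' permuting locus-B genotypes among individuals, with the add-one p-value
#' estimator p = (1 + #\{G_perm >= G_obs\}) / (n_permutations + 1).
#' Individuals missing either genotype are dropped.
#'
#' @param genoA,genoB Character vectors of genotype strings ("a/b";
#'   unordered, NA or "." = missing).
#' @param n_permutations Number of permutations (default 10000).
#' @param seed Optional seed.
#' @return List with \code{G}, \code{p_value}, \code{n} (individuals used).
#' @export
genotypic_ld_test <- function(genoA, genoB, n_permutations = 10000,
                              seed = NULL) {
  fa <- genotype_classes(genoA); fb <- genotype_classes(genoB)
  use <- !is.na(fa) & !is.na(fb)
  fa <- droplevels(fa[use]); fb <- droplevels(fb[use])
  if (length(fa) < 2 || nlevels(fa) < 2 || nlevels(fb) < 2)
    stop("test undefined: fewer than 2 genotype classes at a locus")
  maybe_seed(seed)
  codeA <- as.integer(fa); codeB <- as.integer(fb)
  nA <- nlevels(fa); nB <- nlevels(fb)
  obs <- g_stat_parts(codeA, codeB, nA, nB)
  n <- obs$n
  # margins are permutation-invariant, so only the joint-count term moves
  const <- -obs$margin_term + n * log(n)
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    pb <- codeB[sample.int(n)]
    cnt <- tabulate(codeA + nA * (pb - 1L), nA * nB)
    Gp <- 2 * (sum(cnt[cnt > 0] * log(cnt[cnt > 0])) + const)
    if (Gp >= obs$G - 1e-12) hits <- hits + 1L
  }
  list(G = obs$G, p_value = (1 + hits) / (n_permutations + 1), n = n)
}

#' Squared allele-frequency correlation between two SNPs
#'
#' r^2 is the squared Pearson correlation of additive dosage vectors
#' (0/1/2) over pairwise-complete individuals; invariant to allele-label
#' swaps.
#'
#' @param dosA,dosB Numeric dosage vectors.
#' @return r^2 in [0, 1].
#' @export
snp_r2 <- function(dosA, dosB) {
  use <- !is.na(dosA) & !is.na(dosB)
  if (sum(use) < 2) stop("undefined: fewer than 2 complete individuals")
  a <- dosA[use]; b <- dosB[use]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("undefined: zero variance at a SNP")
  stats::cor(a, b)^2
}

#' Pairwise r^2 table for all SNPs within each contig
#'
#' @param dosages Individuals x SNPs dosage matrix; column names
#'   "contig:position".
#' @return data.frame(contig, snp1, snp2, distance_bp, r2); undefined pairs
#'   are skipped.
#' @export
snp_r2_table <- function(dosages) {
  cn <- colnames(dosages)
  contig <- sub(":.*$", "", cn)
  pos <- as.numeric(sub("^.*:", "", cn))
  out <- list()
  for (ct in unique(contig)) {
    idx <- which(contig == ct)
    if (length(idx) < 2) next
    cmb <- utils::combn(idx, 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      r2 <- tryCatch(snp_r2(dosages[, i], dosages[, j]),
                     error = function(e) NA_real_)
      if (is.na(r2)) next
      out[[length(out) + 1]] <- data.frame(
        contig = ct, snp1 = cn[i], snp2 = cn[j],
        distance_bp = abs(pos[i] - pos[j]), r2 = r2,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out) %||% data.frame(
    contig = character(0), snp1 = character(0), snp2 = character(0),
    distance_bp = numeric(0), r2 = numeric(0))
}

#' LD decay summary per contig
#'
#' Pairs are binned by distance (fixed-width bins); LD is considered to
#' have decayed at the first bin whose mean r^2 falls below
#' \code{r2_threshold}.
#'
#' @param records data.frame(contig, distance_bp, r2).
#' @param r2_threshold Decay threshold (conventionally 0.1).
#' @param bin_width Distance bin width in bp.
#' @return data.frame(contig, n_pairs, mean_r2, decay_bin_start, decayed).
#' @export
ld_decay_summary <- function(records, r2_threshold = 0.1, bin_width = 50) {
  out <- lapply(unique(records$contig), function(ct) {
    sub <- records[records$contig == ct, , drop = FALSE]
    bin <- floor(sub$distance_bp / bin_width)
    mr <- tapply(sub$r2, bin, mean)
    bins <- as.numeric(names(mr))
    o <- order(bins)
    hit <- which(mr[o] < r2_threshold)
    data.frame(contig = ct, n_pairs = nrow(sub), mean_r2 = mean(sub$r2),
               decay_bin_start = if (length(hit)) bins[o][hit[1]] * bin_width
                                 else NA_real_,
               decayed = length(hit) > 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Filter LD records at a significance threshold, with per-group summaries
#'
#' @param records data.frame of LD records including the column named by
#'   \code{stat_col} and optionally a \code{group} column.
#' @param alpha Threshold (records with stat <= alpha are significant).
#' @param stat_col Column holding the FDR-adjusted value (default
#'   "q_value").
#' @return List with \code{significant} (subset) and \code{summary}
#'   data.frame(group, n_tested, n_significant, pct).
#' @export
significance_filter <- function(records, alpha = 1e-4, stat_col = "q_value") {
  stopifnot(stat_col %in% names(records))
  grp <- if ("group" %in% names(records)) records$group else
    rep("overall", nrow(records))
  sig <- records[[stat_col]] <= alpha
  groups <- unique(grp)
  summary <- do.call(rbind, lapply(groups, function(g) {
    nt <- sum(grp == g); ns <- sum(sig & grp == g)
    data.frame(group = g, n_tested = nt, n_significant = ns,
               pct = 100 * ns / nt, stringsAsFactors = FALSE)
  }))
  list(significant = records[sig, , drop = FALSE], summary = summary)
}

#' SSR pairwise LD scan with permutation tests and q-values
#'
#' Runs [genotypic_ld_test()] on every mapped same-chromosome pair and
#' appends Storey q-values and -log10(q).
#'
#' @param genotypes Individuals x loci matrix of "a/b" genotype strings.
#' @param map data.frame(marker, chrom, position_mb).
#' @param exclude Optional pair exclusion table (see
#'   [same_chromosome_pairs()]).
#' @param n_permutations Permutations per test.
#' @param seed Optional seed.
#' @return data.frame(marker1, marker2, chrom, distance_mb, G, p_value,
#'   q_value, neg_log10_q).
#' @export
ssr_ld_scan <- function(genotypes, map, exclude = NULL,
                        n_permutations = 10000, seed = NULL) {
  maybe_seed(seed)
  pairs <- same_chromosome_pairs(colnames(genotypes), map, exclude)
  res <- vector("list", nrow(pairs))
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    r <- tryCatch(
      genotypic_ld_test(genotypes[, pairs$marker1[i]],
                        genotypes[, pairs$marker2[i]],
                        n_permutations = n_permutations),
      error = function(e) NULL)
    if (is.null(r)) next
    keep[i] <- TRUE
    res[[i]] <- data.frame(pairs[i, ], G = r$G, p_value = r$p_value,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[keep])
  if (is.null(out)) return(NULL)
  out$q_value <- storey_qvalues(out$p_value)
  out$neg_log10_q <- -log10(out$q_value)
  rownames(out) <- NULL
  out
}
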