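#' Amplicon design table for one contig
#'
#' Coordinates are 0-based half-open in contig space. Consecutive amplicons
#' must overlap by at least 1 bp so diploid phase can be chained across
#' amplicon junctions via shared heterozygous sites.
#'
#' @param contig_id Contig identifier.
#' @param starts,ends Integer vectors of amplicon interval bounds.
#' @param ids Optional amplicon identifiers.
#' @return data.frame with columns contig, amplicon, start, end.
#' @export
amplicon_design <- function(contig_id, starts, ends, ids = NULL) {
  stopifnot(length(starts) == length(ends), all(ends > starts), all(starts >= 0))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (is.null(ids)) ids <- paste0(contig_id, "_amp", seq_along(starts))
  if (length(starts) > 1) {
    ov <- ends[-length(ends)] - starts[-1]
    if (any(ov < 1)) stop("consecutive amplicons must overlap by >= 1 bp")
  }
  data.frame(contig = contig_id, amplicon = ids[o], start = starts, end = ends,
             stringsAsFactors = FALSE)
}

#' Default desk-scale contig layout
#'
#' Contigs of overlapping ~450 bp amplicons (200 bp overlap), the layout a
#' candidate-gene amplicon study tiles over exons.
#'
#' @param n_contigs,contig_length,amplicon_length,overlap Layout controls
#'   (bp).
#' @return List of contig specs consumable by [sim_config()].
#' @export
default_contigs <- function(n_contigs = 2, contig_length = 700,
                            amplicon_length = 450, overlap = 200) {
  lapply(seq_len(n_contigs), function(i) {
    id <- paste0("contig", i)
    step <- amplicon_length - overlap
    starts <- c(0, step)
    ends <- pmin(starts + amplicon_length, contig_length)
    list(id = id, length = contig_length,
         design = amplicon_design(id, starts, ends))
  })
}

#' Published candidate-gene contig layout
#'
#' Rebuilds the seven-contig, sixteen-amplicon layout of the diploid
#' alfalfa lignin-pathway candidate-gene panel (CCoAoMT, F5H, COMT, PAL1)
#' from the packaged per-contig summary table: contig alignment lengths and
#' amplicon counts are the published values; within a contig, amplicons
#' tile the alignment with equal lengths and the given overlap.
#'
#' @param overlap Overlap between consecutive amplicons in bp.
#' @return List of contig specs consumable by [sim_config()].
#' @export
study_contigs <- function(overlap = 200) {
  path <- system.file("extdata", "contig_summary.tsv", package = "amplipop")
  tab <- read_tsv2(path, required = c("contig", "n_amplicons",
                                      "alignment_length_bp"))
  lapply(seq_len(nrow(tab)), function(i) {
    L <- tab$alignment_length_bp[i]
    k <- tab$n_amplicons[i]
    ov <- if (k > 1) min(overlap, floor(L / k)) else 0
    alen <- ceiling((L + (k - 1) * ov) / k)
    starts <- round(seq(0, L - alen, length.out = k))
    ends <- pmin(starts + alen, L)
    ends[k] <- L
    list(id = tab$contig[i], length = L,
         design = amplicon_design(tab$contig[i], starts, ends))
  })
}

#' Simulation configuration
#'
#' Defaults are desk-scale versions of a diploid candidate-gene amplicon
#' resequencing study: ~450 bp amplicons overlapping by ~200 bp grouped into
#' contigs, 453 bp mean read length, per-amplicon coverage ~100, a
#' per-site scaled mutation rate of 0.0142 (the average Watterson theta of
#' the lignin-pathway candidate genes this package models), SSR loci scored
#' on the same individuals in a small number of differentiated
#' subpopulations, and quantitative traits with structure, polygenic and
#' single-QTN components.
#'
#' @param n_individuals Number of diploid individuals.
#' @param contigs List of contig specs (id, length, design data.frame); see
#'   [amplicon_design()].
#' @param theta_per_site Scaled mutation rate per bp.
#' @param read_length_mean,read_length_sd Read length distribution (bp).
#' @param coverage_mean Mean reads per amplicon per individual (Poisson).
#' @param sub_error_rate Per-base substitution error probability.
#' @param homopolymer_indel_rate Per-homopolymer-run (length >= 3) single-base
#'   indel probability per read.
#' @param chimera_rate Per-read probability of a single-crossover PCR chimera
#'   between the individual's two haplotypes.
#' @param n_populations Number of SSR subpopulations.
#' @param fst Differentiation parameter in [0, 1).
#' @param n_ssr_loci Number of SSR loci.
#' @param alleles_per_locus Alleles per SSR locus (>= 2).
#' @param qtn list(contig, position, effect): the single causal SNP used by
#'   the phenotype simulator.
#' @param heritability_polygenic Polygenic heritability in [0, 1).
#' @param seed Integer master seed.
#' @return Object of class "sim_config".
#' @export
sim_config <- function(n_individuals = 24,
                       contigs = default_contigs(),
                       theta_per_site = 0.0142,
                       read_length_mean = 453,
                       read_length_sd = 30,
                       coverage_mean = 100,
                       sub_error_rate = 0.005,
                       homopolymer_indel_rate = 0.01,
                       chimera_rate = 0.1,
                       n_populations = 5,
                       fst = 0.1,
                       n_ssr_loci = 40,
                       alleles_per_locus = 4,
                       qtn = list(contig = "contig1", position = NULL, effect = 1),
                       heritability_polygenic = 0.3,
                       seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals), contigs = contigs,
              theta_per_site = theta_per_site,
              read_length_mean = read_length_mean, read_length_sd = read_length_sd,
              coverage_mean = coverage_mean, sub_error_rate = sub_error_rate,
              homopolymer_indel_rate = homopolymer_indel_rate,
              chimera_rate = chimera_rate, n_populations = as.integer(n_populations),
              fst = fst, n_ssr_loci = as.integer(n_ssr_loci),
              alleles_per_locus = as.integer(alleles_per_locus), qtn = qtn,
              heritability_polygenic = heritability_polygenic,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  rates <- c(sub_error_rate = cfg$sub_error_rate,
             homopolymer_indel_rate = cfg$homopolymer_indel_rate,
             chimera_rate = cfg$chimera_rate)
  if (any(rates < 0 | rates > 1)) stop("error/chimera rates must lie in [0, 1]")
  if (cfg$fst < 0 || cfg$fst >= 1) stop("fst must lie in [0, 1)")
  if (cfg$heritability_polygenic < 0 || cfg$heritability_polygenic >= 1)
    stop("heritability_polygenic must lie in [0, 1)")
  if (cfg$n_individuals < 1) stop("n_individuals must be positive")
  if (cfg$theta_per_site < 0) stop("theta_per_site must be >= 0")
  if (cfg$alleles_per_locus < 2) stop("alleles_per_locus must be >= 2")
  for (ct in cfg$contigs) {
    if (ct$length <= 0) stop("contig lengths must be positive")
    d <- ct$design
    if (any(d$start < 0) || any(d$end > ct$length))
      stop("amplicon intervals must lie within the contig")
    if (nrow(d) > 1 && any(d$end[-nrow(d)] - d$start[-1] < 1))
      stop("consecutive amplicons must overlap by >= 1 bp")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_individuals, "diploid individuals,",
      length(x$contigs), "contig(s),",
      sum(vapply(x$contigs, function(ct) nrow(ct$design), 1L)), "amplicons\n")
  cat("  theta/site =", x$theta_per_site,
      "| coverage =", x$coverage_mean,
      "| sub err =", x$sub_error_rate,
      "| hp indel =", x$homopolymer_indel_rate,
      "| chimera =", x$chimera_rate, "\n")
  cat("  SSR:", x$n_ssr_loci, "loci,", x$n_populations,
      "populations, fst =", x$fst, "| seed =", x$seed, "\n")
  invisible(x)
}
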