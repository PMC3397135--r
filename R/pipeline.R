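#' Run the full simulate -> haplotype -> diversity/LD -> kinship ->
#' association -> q-value pipeline
#'
#' Stages run in dependency order into a run-specific output directory;
#' every output file is listed in a manifest with its content hash and the
#' seed, so a rerun with the same configuration and seed reproduces
#' byte-identical numeric outputs.
#'
#' @param config A [sim_config()] (its seed drives every stage through
#'   derived sub-streams).
#' @param outdir Output directory (created if needed).
#' @param stages Character vector of stage toggles, a subset of
#'   c("simulate", "haplotype", "diversity", "ld", "kinship",
#'   "association").
#' @param n_permutations Permutations for the SSR LD tests.
#' @return Invisibly, the manifest data.frame.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "haplotype", "diversity",
                                    "ld", "kinship", "association"),
                         n_permutations = 1000) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(path) { written <<- c(written, path); path }

  study <- NULL; haps <- NULL; gm <- NULL
  if ("simulate" %in% stages) {
    study <- simulate_study(config)
    write_fasta(study$references, emit(file.path(outdir, "references.fasta")))
    rd <- study$reads
    write_fastq(stats::setNames(rd$sequence, rd$read_id),
                emit(file.path(outdir, "reads.fastq")))
    write_tsv2(study$design, emit(file.path(outdir, "amplicon_design.tsv")))
    write_tsv2(data.frame(individual = names(study$tags), tag = study$tags),
               emit(file.path(outdir, "tags.tsv")))
    write_tsv2(data.frame(individual = rownames(study$truth$ssr_genotypes),
                          study$truth$ssr_genotypes, check.names = FALSE),
               emit(file.path(outdir, "ssr_genotypes.tsv")))
    write_tsv2(data.frame(individual = rownames(study$truth$Q_true),
                          study$truth$Q_true),
               emit(file.path(outdir, "Q_true.tsv")))
    write_tsv2(data.frame(individual = names(study$truth$phenotype$y),
                          trait1 = study$truth$phenotype$y),
               emit(file.path(outdir, "phenotypes.tsv")))
  }
  if ("haplotype" %in% stages) {
    stopifnot(!is.null(study))
    dm <- demultiplex(study$reads, study$tags)
    haps <- call_haplotypes(dm$assigned, study$references, study$design)
    write_haplotypes_fasta(haps, emit(file.path(outdir, "haplotypes.fasta")))
    gm <- genotype_matrix(haps, study$references)
    write_tsv2(data.frame(individual = rownames(gm$genotypes),
                          gm$genotypes, check.names = FALSE),
               emit(file.path(outdir, "snp_genotypes.tsv")))
    if (nrow(gm$info) > 0) {
      alt <- vapply(seq_len(nrow(gm$info)), function(i) {
        al <- unlist(strsplit(stats::na.omit(
          gm$genotypes[, i]), "/", fixed = TRUE))
        tb <- table(al)
        paste(setdiff(names(tb), gm$info$ref[i]), collapse = ",")
      }, character(1))
      write_vcf_min(data.frame(contig = gm$info$contig,
                               position = gm$info$position,
                               ref = gm$info$ref,
                               alt = ifelse(alt == "", ".", alt),
                               af = gm$info$maf),
                    emit(file.path(outdir, "variants.vcf")))
    }
  }
  if ("diversity" %in% stages) {
    stopifnot(!is.null(study))
    tabs <- list()
    for (ct in names(study$truth$haplotypes)) {
      seqs <- unlist(study$truth$haplotypes[[ct]])
      ds <- diversity_summary(seqs)
      ds$contig <- ct
      tabs[[ct]] <- ds
    }
    write_tsv2(do.call(rbind, tabs), emit(file.path(outdir, "diversity.tsv")))
  }
  if ("ld" %in% stages) {
    stopifnot(!is.null(study))
    set.seed(derive_seed(config$seed, "ld"))
    map <- data.frame(marker = colnames(study$truth$ssr_genotypes),
                      chrom = rep(seq_len(8),
                                  length.out = config$n_ssr_loci),
                      position_mb = round(stats::runif(config$n_ssr_loci,
                                                       0, 60), 2))
    ld <- ssr_ld_scan(study$truth$ssr_genotypes, map,
                      n_permutations = n_permutations)
    if (!is.null(ld)) write_tsv2(ld, emit(file.path(outdir, "ld_ssr.tsv")))
    if (!is.null(gm) && ncol(gm$genotypes) >= 2) {
      r2 <- snp_r2_table(dosage_matrix(gm$genotypes))
      write_tsv2(r2, emit(file.path(outdir, "ld_snp_r2.tsv")))
      write_tsv2(ld_decay_summary(r2),
                 emit(file.path(outdir, "ld_decay.tsv")))
    }
  }
  K2 <- NULL
  if ("kinship" %in% stages) {
    stopifnot(!is.null(study))
    K <- truncate_negative(ritland_kinship(study$truth$ssr_genotypes)$K)
    K2 <- kinship_to_covariance(K)
    write_tsv2(data.frame(individual = rownames(K), K, check.names = FALSE),
               emit(file.path(outdir, "kinship.tsv")))
  }
  if ("association" %in% stages && !is.null(gm) && ncol(gm$genotypes) > 0) {
    scan <- association_scan(
      data.frame(trait1 = study$truth$phenotype$y),
      gm$genotypes, Q = study$truth$Q_true, K2 = K2)
    if (!is.null(scan)) {
      write_tsv2(scan, emit(file.path(outdir, "association.tsv")))
      write_tsv2(qq_data(scan$p_value),
                 emit(file.path(outdir, "association_qq.tsv")))
    }
  }
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         seed = config$seed, stringsAsFactors = FALSE)
  write_tsv2(manifest, file.path(outdir, "manifest.tsv"))
  invisible(manifest)
}
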