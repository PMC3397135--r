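test_that("tag adapters follow the tag + SrfI site + hairpin layout", {
  expect_equal(build_tag("AAAAAAAA")$full_adapter, "AAAAAAAAGCCCGGGCTTTTTTTT")
  # ACGTACGT is its own reverse complement
  expect_equal(build_tag("ACGTACGT")$full_adapter, "ACGTACGTGCCCGGGCACGTACGT")
  expect_error(build_tag("ACGTACG"), "8 bases")
  expect_error(build_tag("ACGTACGN"), "8 bases")
})

test_that("demultiplexing assigns exact matches, ties go unassigned", {
  tags <- c(ind1 = "AAAACCCC", ind2 = "AAAACCCG", ind3 = "GGGGTTTT")
  mk <- function(tag, body) paste0(build_tag(tag)$full_adapter, body)
  reads <- data.frame(
    sequence = c(mk("AAAACCCC", "ACGTACGT"),
                 paste0("AAAACCCA", substr(mk("AAAACCCC", "ACGTACGT"), 9, 32)),
                 mk("GGGGTTTT", "TTTT")),
    stringsAsFactors = FALSE)
  d0 <- demultiplex(reads, tags, max_mismatch = 0)
  expect_equal(d0$assigned$individual, c("ind1", "ind3"))
  expect_equal(d0$assigned$sequence[1], "ACGTACGT")
  # read 2's leading 8-mer is 1 mismatch from both ind1 and ind2: tie
  d1 <- demultiplex(reads, tags, max_mismatch = 1)
  expect_false(any(grepl("AAAACCCA", d1$assigned$sequence)))
  expect_equal(nrow(d1$unassigned), 1)
  expect_error(demultiplex(reads, c(a = "AAAACCCC", b = "AAAACCCC")),
               "duplicate")
})

test_that("error-free simulated libraries demultiplex perfectly", {
  st <- make_small_study(n = 6, seed = 21, sub_error_rate = 0,
                         homopolymer_indel_rate = 0, chimera_rate = 0)
  d <- demultiplex(st$reads, st$tags)
  expect_equal(nrow(d$unassigned), 0)
  expect_identical(d$assigned$individual, st$reads$individual)
})

test_that("pileup columns reflect truth for error-free reads and indels", {
  ref <- paste(rep("ACGTT", 20), collapse = "")  # length 100
  des <- amplicon_design("c", 0, 100)
  reads <- data.frame(amplicon = "c_amp1",
                      sequence = c(rep(ref, 3),
                                   paste0(substr(ref, 1, 49), substr(ref, 51, 100))),
                      stringsAsFactors = FALSE)
  pu <- align_and_pileup(reads, ref, des)
  expect_equal(unname(pu$depth[1]), 4)
  # one read deleted base 50 (inside the TT homopolymer); one deletion count
  # lands in that run
  del_cols <- which(pu$counts[, "-"] > 0)
  expect_length(del_cols, 1)
  expect_true(del_cols %in% 49:50)
  expect_true(all(pu$counts[cbind(1:100, match(strsplit(ref, "")[[1]],
                                               colnames(pu$counts)))] >= 3))
})

test_that("heterozygous sites show balanced allele counts (binomial)", {
  set.seed(31)
  cfg <- sim_config(sub_error_rate = 0, homopolymer_indel_rate = 0,
                    chimera_rate = 0, coverage_mean = 100, seed = 31)
  ct <- cfg$contigs[[1]]
  sim <- simulate_coalescent_haplotypes(2, 0.01, ct$length)
  reads <- simulate_reads(sim$sequences, ct$design, cfg)
  pu <- align_and_pileup(reads, sim$ancestral, ct$design)
  het <- which(sim$snp_matrix[1, ] != sim$snp_matrix[2, ])
  skip_if(length(het) == 0)
  p <- sim$positions[het[1]]
  cc <- pu$counts[p, c("A", "C", "G", "T")]
  d <- pu$depth[p]
  expect_lt(abs(max(cc) / d - 0.5), 3 * sqrt(0.25 / d) + 0.05)
})

test_that("variant calling applies the <0.05 frequency rule", {
  mk_pileup <- function(countA, countG, depth_only = FALSE) {
    counts <- matrix(0L, nrow = 1, ncol = 5,
                     dimnames = list(NULL, c("A", "C", "G", "T", "-")))
    counts[1, "A"] <- countA; counts[1, "G"] <- countG
    structure(list(counts = counts, depth = rowSums(counts),
                   insertions = list(),
                   read_base = matrix("A", 1, 1), read_amplicon = "a1",
                   n_discarded = 0, reference = "A",
                   design = amplicon_design("c", 0, 1)),
              class = "pileup")
  }
  v1 <- call_variants(mk_pileup(96, 4))   # 0.04 < 0.05: error, monomorphic
  expect_equal(nrow(v1), 0)
  expect_equal(attr(v1, "consensus"), "A")
  v2 <- call_variants(mk_pileup(90, 10))  # 0.10 >= 0.05: het SNP
  expect_equal(nrow(v2), 1)
  expect_equal(v2$maf, 0.10)
  expect_equal(attr(v2, "consensus"), "R")  # R = A/G
  v3 <- call_variants(mk_pileup(0, 0))
  expect_equal(nrow(v3), 0)
  expect_equal(attr(v3, "consensus"), "N")
})

test_that("top-two vector selection resolves chimeras as specified", {
  # forced counts {ACT:40, GAG:38, ACG:5, GAT:3} over 3 het sites
  ref <- paste(rep("A", 10), collapse = "")
  des <- amplicon_design("c", 0, 10)
  vecs <- c(rep("ACT", 40), rep("GAG", 38), rep("ACG", 5), rep("GAT", 3))
  rb <- matrix(NA_character_, length(vecs), 10)
  rb[, 2] <- substr(vecs, 1, 1)
  rb[, 5] <- substr(vecs, 2, 2)
  rb[, 8] <- substr(vecs, 3, 3)
  rb[, c(1, 3, 4, 6, 7, 9, 10)] <- "A"
  counts <- matrix(0L, 10, 5, dimnames = list(NULL, c("A", "C", "G", "T", "-")))
  for (j in 1:10) {
    tab <- table(factor(rb[, j], levels = c("A", "C", "G", "T", "-")))
    counts[j, ] <- as.integer(tab)
  }
  pu <- structure(list(counts = counts, depth = rowSums(counts),
                       insertions = list(), read_base = rb,
                       read_amplicon = rep("c_amp1", length(vecs)),
                       n_discarded = 0, reference = ref, design = des),
                  class = "pileup")
  vt <- call_variants(pu)
  expect_equal(vt$position, c(2, 5, 8))
  hp <- resolve_haplotypes(pu, vt, des, min_coverage = 35)
  al1 <- paste(strsplit(hp$haplotype_1, "")[[1]][c(2, 5, 8)], collapse = "")
  al2 <- paste(strsplit(hp$haplotype_2, "")[[1]][c(2, 5, 8)], collapse = "")
  expect_setequal(c(al1, al2), c("ACT", "GAG"))
  expect_equal(hp$support_1, 40)
  expect_equal(hp$support_2, 38)
  expect_equal(hp$coverage_flag, "ok")
})

test_that("homozygous individuals give identical haplotypes; depth flags", {
  st <- make_small_study(n = 4, seed = 41, sub_error_rate = 0,
                         homopolymer_indel_rate = 0, chimera_rate = 0,
                         coverage_mean = 20)  # mean depth < 35
  dm <- demultiplex(st$reads, st$tags)
  haps <- call_haplotypes(dm$assigned, st$references, st$design)
  flags <- vapply(haps, function(h) h$coverage_flag, character(1))
  expect_true(all(flags %in% c("low_coverage", "ok")))
  expect_true(any(flags == "low_coverage"))
  for (h in haps) {
    expect_false(is.null(h$haplotype_1))  # still emitted at low coverage
    if (length(h$het_positions) == 0)
      expect_identical(h$haplotype_1, h$haplotype_2)
  }
})

test_that("no reads for a contig yields a missing flag and no haplotypes", {
  ref <- random_dna_str <- paste(rep("ACGT", 25), collapse = "")
  des <- amplicon_design("c", 0, 100)
  empty <- data.frame(amplicon = character(0), sequence = character(0))
  hp <- haplotype_individual(empty, ref, des)
  expect_equal(hp$coverage_flag, "missing")
  expect_null(hp$haplotype_1)
})

test_that("zero-noise round trip recovers truth exactly (haps + genotypes)", {
  st <- make_small_study(n = 10, seed = 51, sub_error_rate = 0,
                         homopolymer_indel_rate = 0, chimera_rate = 0)
  dm <- demultiplex(st$reads, st$tags)
  haps <- call_haplotypes(dm$assigned, st$references, st$design)
  for (ct in names(st$truth$haplotypes)) {
    for (ind in names(st$truth$haplotypes[[ct]])) {
      h <- haps[[paste(ind, ct, sep = "|")]]
      expect_identical(sort(c(h$haplotype_1, h$haplotype_2)),
                       sort(st$truth$haplotypes[[ct]][[ind]]))
    }
  }
  gm <- genotype_matrix(haps, st$references)
  truth_g <- vapply(seq_len(nrow(gm$info)), function(i) {
    ct <- gm$info$contig[i]; p <- gm$info$position[i]
    vapply(rownames(gm$genotypes), function(ind)
      paste(sort(substr(st$truth$haplotypes[[ct]][[ind]], p, p)),
            collapse = "/"), character(1))
  }, character(nrow(gm$genotypes)))
  expect_identical(unname(gm$genotypes), unname(truth_g))
})

test_that("genotype matrix applies the sample MAF filter", {
  ref <- c(c1 = "AAAA")
  mk_hp <- function(ind, h1, h2) structure(
    list(individual = ind, contig = "c1", haplotype_1 = h1, haplotype_2 = h2,
         support_1 = 10L, support_2 = 10L, het_positions = integer(0),
         junctions = character(0), coverage_flag = "ok"),
    class = "haplotype_pair")
  # site 2: one T among 4 alleles -> MAF 0.25, retained
  hp <- list(mk_hp("i1", "AAAA", "AAAA"), mk_hp("i2", "AAAA", "ATAA"))
  gm <- genotype_matrix(hp, ref)
  expect_equal(gm$info$position, 2)
  expect_equal(gm$info$maf, 0.25)
  expect_equal(unname(gm$genotypes[, 1]), c("A/A", "A/T"))
  # all ref/ref: no variant at all
  hp2 <- list(mk_hp("i1", "AAAA", "AAAA"), mk_hp("i2", "AAAA", "AAAA"))
  expect_equal(ncol(genotype_matrix(hp2, ref)$genotypes), 0)
})

test_that("support never exceeds depth and support_1 >= support_2", {
  st <- make_small_study(n = 6, seed = 61, chimera_rate = 0.2)
  dm <- demultiplex(st$reads, st$tags)
  haps <- call_haplotypes(dm$assigned, st$references, st$design)
  for (h in haps) {
    expect_gte(h$support_1, h$support_2)
    for (amp in names(h$amplicon_supports)) {
      n_amp <- sum(dm$assigned$individual == h$individual &
                     dm$assigned$amplicon == amp)
      expect_lte(max(h$amplicon_supports[[amp]]), n_amp)
    }
  }
})

test_that("top-2 selection equals exhaustive enumeration (<= 6 het sites)", {
  set.seed(71)
  for (rep in 1:25) {
    n_sites <- sample(1:6, 1)
    n_vec <- sample(2:6, 1)
    pool <- replicate(n_vec, paste(sample(c("A", "C"), n_sites, TRUE),
                                   collapse = ""))
    counts <- table(sample(pool, 60, replace = TRUE))
    # oracle: enumerate all vector frequencies, take the two largest with
    # the lexicographic tie rule
    cnt <- sort(counts, decreasing = TRUE)
    o_top1 <- sort(names(cnt)[cnt == max(cnt)])[1]
    rest <- cnt[names(cnt) != o_top1]
    o_top2 <- if (length(rest) == 0) o_top1 else
      sort(names(rest)[rest == max(rest)])[1]
    got <- amplipop:::top_two_vectors(counts)
    expect_identical(got, c(o_top1, o_top2))
  }
})

test_that("recovery is non-increasing in the chimera rate", {
  rates <- c(0, 0.3, 0.6)
  rec <- vapply(seq_along(rates), function(i) {
    st <- simulate_study(sim_config(
      n_individuals = 20, contigs = default_contigs(n_contigs = 1),
      chimera_rate = rates[i], coverage_mean = 40, seed = 500))
    dm <- demultiplex(st$reads, st$tags)
    haps <- call_haplotypes(dm$assigned, st$references, st$design)
    ok <- 0
    for (ind in names(st$truth$haplotypes[[1]])) {
      h <- haps[[paste(ind, "contig1", sep = "|")]]
      if (identical(sort(c(h$haplotype_1, h$haplotype_2)),
                    sort(st$truth$haplotypes[[1]][[ind]]))) ok <- ok + 1
    }
    ok / 20
  }, numeric(1))
  expect_true(all(diff(rec) <= 0.05 + 1e-9))  # non-increasing up to MC noise
  expect_gt(rec[1], rec[3] - 1e-9)
})

test_that("compiled fitting aligner matches Biostrings scores exactly", {
  set.seed(81)
  ref <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  mk_read <- function() {
    len <- sample(200:300, 1)
    s <- if (runif(1) < 0.5) substr(ref, 1, len) else
      substr(ref, 300 - len + 1, 300)
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < 0.01
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    for (k in seq_len(sample(0:2, 1))) {
      pos <- sample(seq_along(ch), 1)
      ch <- if (runif(1) < 0.5)
        append(ch, sample(c("A", "C", "G", "T"), 1), after = pos)
      else ch[-pos]
    }
    paste(ch, collapse = "")
  }
  reads <- replicate(25, mk_read())
  mine <- vapply(amplipop:::fit_align_batch_cpp(reads, ref),
                 function(a) a$score, numeric(1))
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads), Biostrings::DNAString(ref),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 3, gapExtension = 1)
  expect_equal(mine, Biostrings::score(pa))
})
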