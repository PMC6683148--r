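test_that("config validation rejects impossible settings", {
  expect_error(sim_config(error_rate = 0.2), "error_rate")
  expect_error(sim_config(frac24_by_stage = c("0" = 1.2, "3" = 0.2,
                                              "4B" = 0.2, "5" = 0.2,
                                              "7" = 0.2)), "frac24")
  d <- default_library_design()
  d$n_replicates[1] <- 0L
  expect_error(sim_config(design = d), "zero replicates")
  cfg <- sim_config(genome_length = 2000)
  expect_error(simulate_genome(cfg), "deficit")
})

test_that("forcing zero novel loci yields zero novel truth records", {
  cfg <- mini_sim_config()
  cfg$n_novel_loci <- 0L
  g <- simulate_genome(cfg)
  expect_equal(sum(g$truth$loci$class == "novel_mir"), 0)
})

test_that("the generator is deterministic: same config, same bytes", {
  cfg <- mini_sim_config(seed = 13, reads = 1500)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  s1 <- simulate_all(cfg, d1)
  s2 <- simulate_all(cfg, d2)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth$loci, s2$truth$loci)
  for (lb in names(s1$truth$files)) {
    expect_identical(unname(tools::md5sum(s1$truth$files[[lb]])),
                     unname(tools::md5sum(s2$truth$files[[lb]])))
  }
  expect_identical(unname(tools::md5sum(s1$paths$genome)),
                   unname(tools::md5sum(s2$paths$genome)))
})

test_that("planted hairpins fold into stem-loops that pass evaluation", {
  sim <- tiny_sim()
  mir <- sim$truth$loci[sim$truth$loci$class %in%
                          c("conserved_mir", "novel_mir"), ]
  for (i in seq_len(nrow(mir))) {
    r <- mir[i, ]
    f <- fold_hairpin(r$precursor_seq)
    ev <- evaluate_hairpin(f$structure, r$mature_start, r$mature_end)
    expect_true(ev$pass, label = paste(r$locus_id, "hairpin pass"))
    expect_gte(ev$paired_frac, 0.75)
    st <- infer_star(r$precursor_seq, f$structure, r$mature_start,
                     r$mature_end)
    expect_identical(st$sequence, r$star_seq)
  }
})

test_that("planted sequences occur at their recorded coordinates,
          strand-aware", {
  sim <- tiny_sim()
  genome <- as.character(sim$genome)[["chr1"]]
  loci <- sim$truth$loci
  for (i in seq_len(nrow(loci))) {
    r <- loci[i, ]
    g <- substr(genome, r$start, r$end)
    if (r$strand == "-") g <- revcomp(g)
    expect_identical(g, r$precursor_seq, label = r$locus_id)
    if (!is.na(r$mature_seq) && r$class != "sirna") {
      expect_identical(substr(r$precursor_seq, r$mature_start,
                              r$mature_end), r$mature_seq)
    }
    if (!is.na(r$star_seq)) {
      expect_identical(substr(r$precursor_seq, r$star_start, r$star_end),
                       r$star_seq)
    }
  }
})

test_that("every library holds exactly reads_per_library reads", {
  sim <- tiny_sim()
  for (f in sim$truth$files) {
    n <- length(Biostrings::readDNAStringSet(f, format = "fastq"))
    expect_equal(n, tiny_sim_config()$reads_per_library)
  }
})

test_that("star_to_mature_ratio = 0 emits no star reads", {
  cfg <- mini_sim_config(seed = 23, reads = 1500)
  cfg$star_to_mature_ratio <- 0
  cfg$error_rate <- 0
  dir <- file.path(tempdir(), "nostar")
  g <- simulate_genome(cfg)
  truth <- simulate_libraries(g$truth, cfg, dir)
  stars <- truth$loci$star_seq[!is.na(truth$loci$star_seq)]
  for (f in truth$files) {
    reads <- as.character(Biostrings::readDNAStringSet(f,
                                                       format = "fastq"))
    expect_false(any(stars %in% reads))
  }
})

test_that("realized locus counts track negative-binomial means over
          seeds", {
  base_cfg <- sim_config(
    seed = 1, genome_length = 40000, n_conserved_loci = 3,
    n_novel_loci = 2, n_sirna_loci = 2, n_contaminant_loci = 2,
    design = data.frame(tissue = "ZE", stage = "3", n_replicates = 1L),
    reads_per_library = 2000, frac24_by_stage = c("3" = 0.15),
    error_rate = 0)
  g <- simulate_genome(base_cfg)
  lib <- "ZE3_R1"
  n_seeds <- 200
  realized <- expected <- numeric(n_seeds)
  locus <- g$truth$loci$locus_id[g$truth$loci$class == "conserved_mir"][1]
  mat_seq <- g$truth$loci$mature_seq[g$truth$loci$locus_id == locus]
  for (s in seq_len(n_seeds)) {
    cfg <- base_cfg
    cfg$seed <- 1000L + s
    dir <- file.path(tempdir(), "nbmc")
    truth <- simulate_libraries(g$truth, cfg, dir)
    reads <- as.character(Biostrings::readDNAStringSet(
      truth$files[[lib]], format = "fastq"))
    realized[s] <- sum(reads == mat_seq)
    expected[s] <- truth$expression[locus, lib]
  }
  mu <- mean(expected)
  # marginal variance of an NB draw with dispersion phi
  v <- mu + base_cfg$nb_dispersion * mu^2
  se <- sqrt(v / n_seeds)
  expect_lt(abs(mean(realized) - mu), 3 * se)
})

test_that("the 24-nt read fraction rises through embryo development", {
  sim <- tiny_sim()
  li <- sim$truth$library_info
  ze <- li[li$tissue == "ZE", ]
  frac24 <- vapply(ze$library, function(lb) {
    reads <- as.character(Biostrings::readDNAStringSet(
      sim$truth$files[[lb]], format = "fastq"))
    mean(nchar(reads) == 24)
  }, numeric(1))
  by_stage <- tapply(frac24, ze$stage, mean)
  by_stage <- by_stage[order(names(by_stage))]
  expect_true(all(diff(by_stage) > 0))
})

test_that("reference homologs are recoverable and decoys are not", {
  sim <- tiny_sim()
  ref <- read_mature_ref(sim$paths$mature_ref)
  cons <- sim$truth$loci[sim$truth$loci$class == "conserved_mir", ]
  ann <- annotate_conserved(cons$mature_seq, ref)
  expect_setequal(ann$sequence, cons$mature_seq)
  expect_identical(setNames(ann$family, ann$sequence)[cons$mature_seq],
                   setNames(cons$family, cons$mature_seq))
  planted_d <- sim$truth$mature_ref$planted_distance
  decoys <- sim$truth$mature_ref$sequence[is.na(planted_d)]
  expect_equal(nrow(annotate_conserved(decoys, ref[!is.na(planted_d), ])),
               0)
  # annotated distances match what was planted
  by_fam <- setNames(sim$truth$mature_ref$planted_distance,
                     sim$truth$mature_ref$family)
  expect_equal(unname(setNames(ann$best_mismatches,
                               ann$family)[names(by_fam)[!is.na(by_fam)]]),
               unname(by_fam[!is.na(by_fam)]))
})

test_that("planted target sites score exactly as recorded", {
  sim <- tiny_sim()
  ts <- sim$truth$target_sites
  for (i in seq_len(nrow(ts))) {
    hit <- align_site(ts$mature_seq[i],
                      sim$truth$transcriptome[[ts$transcript_id[i]]],
                      ts$transcript_id[i], max_e = 5)
    at_site <- hit[hit$start <= ts$site_start[i] &
                     hit$end >= ts$site_end[i] - 1, ]
    expect_gte(nrow(at_site), 1)
    expect_equal(min(at_site$expectation),
                 ts$planted_expectation_score[i])
  }
})

test_that("a perfect-complement planted site scores zero", {
  m <- "TGGATTGAAGGGAGCTCTACA"
  tx <- paste0(strrep("C", 30), revcomp(m), strrep("C", 30))
  hit <- align_site(m, tx, max_e = 5)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$expectation, 0)
  expect_equal(hit$start, 31)
})
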