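test_that("the folder finds forced structures", {
  f <- fold_hairpin("GGGAAAACCC")
  expect_equal(f$structure, "(((....)))")
  expect_equal(f$score, 9)
  expect_equal(fold_hairpin("AAAAAAAAAA")$structure, strrep(".", 10))
  expect_error(fold_hairpin("ACGTX"), "invalid character")
})

test_that("the folding DP equals exhaustive structure enumeration", {
  # all two-letter sequences up to length 9, plus random 4-letter ones
  seqs <- unlist(lapply(6:9, all_seqs, alphabet = c("A", "U")))
  set.seed(31)
  seqs <- c(seqs, random_reads(60, c(10, 14)))
  for (sq in seqs) {
    expect_equal(fold_hairpin(sq)$score, oracle_fold_score(sq),
                 label = sq)
  }
})

test_that("dot-bracket partners are consistent with the score", {
  set.seed(32)
  for (sq in random_reads(20, c(30, 60))) {
    f <- fold_hairpin(sq)
    partner <- seedmir:::pairing_partners(f$structure)
    # involution; paired bases are complementary or wobble
    idx <- which(partner > 0)
    expect_true(all(partner[partner[idx]] == idx))
    chars <- strsplit(sq, "")[[1]]
    w <- 0
    for (i in idx[idx < partner[idx]]) {
      pair <- paste0(chars[i], chars[partner[i]])
      expect_true(pair %in% c("GC", "CG", "AT", "TA", "GT", "TG"))
      w <- w + c(GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1)[[pair]]
    }
    expect_equal(w, f$score)
  }
})

test_that("mature reference parsing extracts families", {
  ref <- read_mature_ref(c("pta-miR156a" = "UGACAGAAGAGAGUGAGCACA",
                           "ath-miR166-5p" = "GGAAUGUUGUCUGGCUCGAGG"))
  expect_equal(ref$family, c("MIR156", "MIR166"))
  expect_equal(ref$sequence[1], "TGACAGAAGAGAGTGAGCACA")
  expect_error(read_mature_ref(c(x = "ACGUACGUACGUACGUACGUA")),
               "family")
})

test_that("conserved annotation honours the two-mismatch boundary", {
  ref <- read_mature_ref(c("pta-miR156a" = "TGACAGAAGAGAGTGAGCACA",
                           "pta-miR166a" = "TCGGACCAGGCTTCATTCCCC"))
  expect_equal(annotate_conserved("TGACAGAAGAGAGTGAGCACA", ref)$family,
               "MIR156")
  expect_equal(annotate_conserved("TGACAGAAGAGAGTGAGCACA",
                                  ref)$best_mismatches, 0)
  two <- "AGACAGAAGAGAGTGAGCACT"   # 2 mismatches
  expect_equal(annotate_conserved(two, ref)$best_mismatches, 2)
  three <- "AGACAGAAGAGAGTGAGCTCT" # 3 mismatches
  expect_equal(nrow(annotate_conserved(three, ref)), 0)
  expect_error(annotate_conserved("ACGT", ref[0, ]), "empty")
})

test_that("length differences slide with overhang counted as
          mismatches", {
  ref <- read_mature_ref(c("pta-miR156a" = "TGACAGAAGAGAGTGAGCACA"))
  # 20-nt read = reference minus its first base: distance 1
  short <- substr("TGACAGAAGAGAGTGAGCACA", 2, 21)
  expect_equal(annotate_conserved(short, ref)$best_mismatches, 1)
  # 19-nt inner window: distance 2 (two overhanging bases)
  inner <- substr("TGACAGAAGAGAGTGAGCACA", 2, 20)
  expect_equal(annotate_conserved(inner, ref)$best_mismatches, 2)
  # a 3-nt length difference is incomparable
  outer <- substr("TGACAGAAGAGAGTGAGCACA", 3, 20)
  expect_equal(nrow(annotate_conserved(outer, ref)), 0)
})

test_that("annotation equals the exhaustive distance-matrix oracle", {
  set.seed(33)
  refs <- random_reads(15, c(20, 22))
  ref <- read_mature_ref(setNames(refs, sprintf("pta-miR%d", 200 + 1:15)))
  reads <- c(vapply(sample(refs, 40, replace = TRUE), function(r)
    seedmir:::mutate_positions(r, sample(0:3, 1)), character(1)),
    random_reads(20))
  ann <- annotate_conserved(reads, ref)
  for (sq in unique(reads)) {
    d <- vapply(ref$sequence, oracle_ungapped_distance, numeric(1),
                a = sq)
    if (min(d) <= 2) {
      row <- ann[ann$sequence == sq, ]
      expect_equal(row$best_mismatches, min(d))
      expect_equal(row$family, sort(ref$family[d == min(d)])[1])
    } else {
      expect_false(sq %in% ann$sequence)
    }
  }
})

test_that("tied families are all recorded with the smallest as
          primary", {
  ref <- read_mature_ref(c("pta-miR319a" = "TGACAGAAGAGAGTGAGCACA",
                           "pta-miR156a" = "TGACAGAAGAGAGTGAGCACA"))
  ann <- annotate_conserved("TGACAGAAGAGAGTGAGCACA", ref)
  expect_true(ann$ambiguous)
  expect_equal(ann$family, "MIR156")
  expect_equal(ann$families_all, "MIR156;MIR319")
})

test_that("family isoform counting is by distinct sequence", {
  ann <- data.frame(sequence = c("A", "B", "C", "C"),
                    family = c("MIR166", "MIR166", "MIR166", "MIR166"))
  expect_equal(count_family_isoforms(ann), c(MIR166 = 3L))
  expect_length(count_family_isoforms(ann[0, ]), 0)
})

test_that("isoform counts on an error-free synthetic run equal the
          planted family table", {
  cfg <- mini_sim_config(seed = 77, reads = 4000)
  cfg$error_rate <- 0
  dir <- file.path(tempdir(), "iso")
  sim <- simulate_all(cfg, dir)
  rc <- run_config(libraries = sim$truth$files, genome = sim$paths$genome,
                   mature_ref = sim$paths$mature_ref,
                   contaminants = sim$paths$contaminants,
                   design = sim$truth$library_info)
  rep <- run_all(rc)
  cons <- sim$truth$loci[sim$truth$loci$class == "conserved_mir", ]
  planted <- table(cons$family)
  got <- count_family_isoforms(rep$conserved)
  expect_equal(got[sort(names(planted))],
               setNames(as.integer(planted), sort(names(planted))))
})

test_that("precursor windows always contain the read and stay in
          bounds", {
  set.seed(35)
  g <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 2000,
                             replace = TRUE), collapse = ""))
  locus <- data.frame(chrom = "chr1", start = 900, end = 920,
                      strand = "+")
  wins <- excise_precursors(locus, g)
  expect_gte(nrow(wins), 2)
  expect_true(all(wins$win_start <= 900 & wins$win_end >= 920))
  expect_true(all(wins$win_end - wins$win_start + 1 <= 250))
  # mature substring extraction matches the genome
  for (i in seq_len(nrow(wins))) {
    expect_equal(substr(wins$seq[i], wins$mature_start[i],
                        wins$mature_end[i]), unname(substr(g, 900, 920)))
  }
  edge <- data.frame(chrom = "chr1", start = 5, end = 25, strand = "+")
  wedge <- excise_precursors(edge, g)
  expect_true(all(wedge$win_start >= 1))
  # minus-strand windows carry the transcribed frame
  minus <- data.frame(chrom = "chr1", start = 900, end = 920,
                      strand = "-")
  wm <- excise_precursors(minus, g)
  for (i in seq_len(nrow(wm))) {
    expect_equal(substr(wm$seq[i], wm$mature_start[i], wm$mature_end[i]),
                 unname(revcomp(substr(g, 900, 920))))
  }
})

test_that("at least one window contains the full planted precursor", {
  sim <- tiny_sim()
  g <- setNames(as.character(sim$genome), names(sim$genome))
  mir <- sim$truth$loci[sim$truth$loci$class %in%
                          c("conserved_mir", "novel_mir"), ]
  for (i in seq_len(nrow(mir))) {
    r <- mir[i, ]
    m <- seedmir:::locus_feature_coords(r, r$mature_start, r$mature_end)
    locus <- data.frame(chrom = r$chrom, start = m[1], end = m[2],
                        strand = r$strand)
    wins <- excise_precursors(locus, g)
    expect_true(any(wins$win_start <= r$start & wins$win_end >= r$end),
                label = r$locus_id)
  }
})

test_that("hairpin evaluation enforces the duplex geometry criteria", {
  # perfect inverted repeat, mature on the 5' arm
  stem <- "GCATGCAAGCTTGCAGTCAGG"
  core <- paste0(stem, "ATACGATTACGA", revcomp(stem))
  f <- fold_hairpin(core)
  ev <- evaluate_hairpin(f$structure, 1, nchar(stem))
  expect_true(ev$pass)
  expect_equal(ev$paired_frac, 1.0)
  expect_equal(ev$arm, "5p")
  # mature straddling the terminal loop fails with the loop reason
  mid <- nchar(stem) + 3
  ev2 <- evaluate_hairpin(f$structure, mid, mid + 18)
  expect_false(ev2$pass)
  expect_true("mature in loop" %in% ev2$reasons)
  expect_error(evaluate_hairpin(f$structure, 0, 10), "outside")
})

test_that("star inference follows the 2-nt 3' overhang rule on a
          perfect stem", {
  lower <- "GGACAT"
  arm <- paste0(lower, "TGGATTGAAGGGAGCTCTACA", "CGA")
  core <- paste0(arm, "GAATCTTATACG", revcomp(arm))
  f <- fold_hairpin(core)
  a <- nchar(lower) + 1; b <- nchar(lower) + 21
  st <- infer_star(core, f$structure, a, b)
  n <- nchar(core)
  # perfect palindromic stem: P(i) = n + 1 - i, star = [P(b)+2, P(a)+2]
  expect_equal(c(st$start, st$end), c(n - b + 3, n - a + 3))
  expect_equal(st$sequence, substr(core, n - b + 3, n - a + 3))
  # geometry: intervals must not overlap
  expect_gt(st$start, b)
  # fully unpaired mature yields no star
  f2 <- fold_hairpin("AAAAAAAAAAAAAAAAAAAAAA")
  expect_null(infer_star("AAAAAAAAAAAAAAAAAAAAAA", f2$structure, 1, 10))
})

test_that("novel classification separates hairpin loci from siRNA loci
          and keys high confidence on the star", {
  sim <- tiny_sim()
  rep <- tiny_report()
  truth <- sim$truth
  novel_truth <- truth$loci[truth$loci$class == "novel_mir", ]
  called <- rep$novel
  nv <- called[called$status == "novel", ]
  # all planted novels recovered, no siRNA locus called
  expect_setequal(nv$sequence, novel_truth$mature_seq)
  sirna <- truth$loci$mature_seq[truth$loci$class == "sirna"]
  expect_false(any(sirna %in% nv$sequence))
  # high confidence iff the star was sequenced
  seq_reads <- rep$tables$filtered$sequence
  star_seen <- setNames(novel_truth$star_seq %in% seq_reads,
                        novel_truth$mature_seq)
  expect_equal(setNames(nv$high_confidence, nv$sequence)[names(star_seen)],
               star_seen)
  # conserved matures never reappear as novel
  expect_false(any(rep$conserved$sequence %in% nv$sequence))
  # star records point at their mature
  stars <- called[called$status == "star", ]
  expect_true(all(!is.na(stars$star_of)))
})

test_that("5' nucleotide composition sums to one", {
  p <- five_prime_composition(c("TGGA", "TTAA", "ACGT", "CCGT"))
  expect_equal(p, c(A = 0.25, U = 0.5, C = 0.25, G = 0))
  expect_equal(sum(five_prime_composition("GATTACA")), 1)
  expect_equal(five_prime_composition("GATTACA")[["G"]], 1)
  expect_error(five_prime_composition(character(0)), "empty")
})

test_that("the planted 5' nucleotide bias is recovered within
          multinomial error", {
  cfg <- sim_config(seed = 19, genome_length = 200000,
                    n_conserved_loci = 20, n_novel_loci = 60,
                    n_sirna_loci = 2, n_contaminant_loci = 2,
                    design = mini_design(), reads_per_library = 1000)
  g <- simulate_genome(cfg)
  mir <- g$truth$loci[g$truth$loci$class %in%
                        c("conserved_mir", "novel_mir"), ]
  p <- five_prime_composition(mir$mature_seq)
  expected <- c(A = 0.40, U = 0.45, C = 0.08, G = 0.07)
  se <- sqrt(expected * (1 - expected) / nrow(mir))
  expect_true(all(abs(p[names(expected)] - expected) < 3.5 * se + 1e-9))
})
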