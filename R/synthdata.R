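# Synthetic-data module: a toy genome with planted MIR hairpins, siRNA
# loci and contaminant loci, plus simulated tissue x stage x replicate
# sRNA libraries with full ground truth, so every downstream stage of the
# pipeline can be exercised and scored without external downloads.

CONSERVED_FAMILY_POOL <- c(
  "MIR156", "MIR159", "MIR162", "MIR166", "MIR167", "MIR168", "MIR171",
  "MIR172", "MIR319", "MIR390", "MIR394", "MIR396", "MIR397", "MIR408",
  "MIR482", "MIR946", "MIR947", "MIR950", "MIR951", "MIR1311", "MIR1312",
  "MIR3711")

#' Default library design: five zygotic-embryo stages, three
#' megagametophyte stages and two somatic-embryo stages
#'
#' Mirrors the sixteen-library design of the study system: zygotic embryos
#' ZE0 and ZE3-ZE7 (duplicated except the earliest stage), the surrounding
#' megagametophytes MG0, MG4B and MG7, and somatic embryos SE4B and SE7
#' (single samples).
#'
#' @return data.frame with columns `tissue`, `stage`, `n_replicates`.
#' @export
default_library_design <- function() {
  data.frame(
    tissue = c("ZE", "ZE", "ZE", "ZE", "ZE", "MG", "MG", "MG", "SE", "SE"),
    stage = c("0", "3", "4B", "5", "7", "0", "4B", "7", "4B", "7"),
    n_replicates = c(1L, 2L, 2L, 2L, 2L, 1L, 2L, 2L, 1L, 1L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Parameters of the synthetic sRNA study. Defaults emulate the real
#' study's conditions at desk scale: a 100-kb toy genome hosting ~30
#' planted loci, the sixteen-library tissue x stage x replicate design,
#' 200,000 reads per library, negative-binomial locus abundances, a 24-nt
#' read fraction that rises through embryo development, miRNA-star reads
#' at a quarter of mature abundance, and a 0.1% per-base substitution
#' error rate.
#'
#' @param seed integer RNG seed; all generator stages derive their streams
#'   from it, so identical configs give byte-identical outputs.
#' @param genome_length toy genome size in nt.
#' @param n_conserved_loci,n_novel_loci,n_sirna_loci,n_contaminant_loci
#'   numbers of planted conserved-homolog MIR hairpins, novel MIR
#'   hairpins, 24-nt siRNA loci, and t/rRNA + low-complexity contaminant
#'   loci.
#' @param design data.frame as [default_library_design()].
#' @param reads_per_library reads emitted per library (exactly).
#' @param nb_dispersion negative-binomial dispersion (var = mu + disp*mu^2).
#' @param frac24_by_stage named vector, stage -> expected fraction of
#'   non-contaminant reads drawn from 24-nt siRNA loci.
#' @param star_to_mature_ratio expected star read abundance relative to
#'   its mature miRNA.
#' @param error_rate per-base substitution probability (0 to 0.05).
#' @param contaminant_frac expected fraction of reads from contaminant
#'   loci (t/rRNA fragments and low-complexity repeats).
#' @param de_fraction fraction of MIR loci given a stage-varying
#'   expression profile (the remainder are flat across stages).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 101L,
                       genome_length = 100000L,
                       n_conserved_loci = 12L,
                       n_novel_loci = 8L,
                       n_sirna_loci = 6L,
                       n_contaminant_loci = 4L,
                       design = default_library_design(),
                       reads_per_library = 200000L,
                       nb_dispersion = 0.15,
                       frac24_by_stage = c("0" = 0.10, "3" = 0.15,
                                           "4B" = 0.25, "5" = 0.30,
                                           "7" = 0.35),
                       star_to_mature_ratio = 0.25,
                       error_rate = 0.001,
                       contaminant_frac = 0.15,
                       de_fraction = 0.6) {
  fail_if(genome_length <= 0, "genome_length must be positive")
  fail_if(reads_per_library <= 0, "reads_per_library must be positive")
  fail_if(any(c(n_conserved_loci, n_novel_loci, n_sirna_loci,
                n_contaminant_loci) < 0), "locus counts must be >= 0")
  fail_if(n_conserved_loci > length(CONSERVED_FAMILY_POOL),
          "n_conserved_loci exceeds the %d available MIR families",
          length(CONSERVED_FAMILY_POOL))
  fail_if(nb_dispersion < 0, "nb_dispersion must be >= 0")
  fail_if(any(frac24_by_stage < 0) || any(frac24_by_stage > 1),
          "frac24_by_stage values must lie in [0, 1]")
  fail_if(star_to_mature_ratio < 0 || star_to_mature_ratio > 1,
          "star_to_mature_ratio must lie in [0, 1]")
  fail_if(error_rate < 0 || error_rate > 0.05,
          "error_rate must lie in [0, 0.05]")
  fail_if(!all(c("tissue", "stage", "n_replicates") %in% names(design)),
          "design needs columns tissue, stage, n_replicates")
  fail_if(any(design$n_replicates < 1), "design with zero replicates")
  fail_if(!all(design$stage %in% names(frac24_by_stage)),
          "every design stage needs a frac24_by_stage entry")
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    n_conserved_loci = as.integer(n_conserved_loci),
    n_novel_loci = as.integer(n_novel_loci),
    n_sirna_loci = as.integer(n_sirna_loci),
    n_contaminant_loci = as.integer(n_contaminant_loci),
    design = design, reads_per_library = as.integer(reads_per_library),
    nb_dispersion = nb_dispersion, frac24_by_stage = frac24_by_stage,
    star_to_mature_ratio = star_to_mature_ratio, error_rate = error_rate,
    contaminant_frac = contaminant_frac, de_fraction = de_fraction),
    class = "sim_config")
}

# Library table expanded from the design: one row per sequenced library.
library_table <- function(design) {
  rows <- lapply(seq_len(nrow(design)), function(i) {
    r <- design[i, ]
    data.frame(library = paste0(r$tissue, r$stage, "_R",
                                seq_len(r$n_replicates)),
               tissue = r$tissue, stage = r$stage,
               condition = paste0(r$tissue, r$stage),
               replicate = seq_len(r$n_replicates),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Build one hairpin precursor around a mature sequence.
# Geometry: flank-free core = arm5 + loop + revcomp(arm5), with the mature
# set back 6 nt from the stem base so the inferred star (canonical Dicer
# 2-nt 3' overhang) stays inside the precursor.
build_hairpin <- function(mature, arm = c("5p", "3p"), lower = 6L,
                          ext = 4L, loop_len = 12L) {
  arm <- match.arg(arm)
  L <- nchar(mature)
  lower_seq <- random_dna(1, lower)
  ext_seq <- random_dna(1, ext)
  loop <- random_dna(1, loop_len)
  block <- if (arm == "5p") mature else revcomp(mature)
  arm5 <- paste0(lower_seq, block, ext_seq)
  core <- paste0(arm5, loop, revcomp(arm5))
  n <- nchar(core)
  if (arm == "5p") {
    a <- lower + 1L; b <- lower + L
  } else {
    a <- n - lower - L + 1L; b <- n - lower
  }
  # Perfect palindromic stem: position i pairs n + 1 - i; star interval
  # under the 2-nt 3' overhang rule is [P(b) + 2, P(a) + 2].
  s1 <- n - b + 3L; s2 <- n - a + 3L
  list(core = core, mature_start = a, mature_end = b,
       star_start = s1, star_end = s2,
       star_seq = substr(core, s1, s2), arm = arm)
}

#' Simulate a toy genome with planted loci
#'
#' Plants conserved-homolog MIR hairpins, novel MIR hairpins, 24-nt siRNA
#' loci, t/rRNA fragment loci and low-complexity repeat loci into a random
#' background genome, and records the full ground truth (classes,
#' coordinates, strands, mature and star sequences, families).
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a [Biostrings::DNAStringSet] of one
#'   chromosome) and `truth` (class `ground_truth`: a `loci` data.frame
#'   plus generator bookkeeping; expression, reference and target truth
#'   are appended by [simulate_libraries()] and [simulate_references()]).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_mir <- config$n_conserved_loci + config$n_novel_loci
    n_contam <- config$n_contaminant_loci
    n_trna <- ceiling(n_contam / 2)
    n_lowc <- n_contam - n_trna
    n_loci <- n_mir + config$n_sirna_loci + n_contam

    # locus payload sequences -------------------------------------------
    fam <- sample(CONSERVED_FAMILY_POOL, config$n_conserved_loci)
    loci <- list()
    five_prime_pool <- c("T", "A", "C", "G")
    five_prime_prob <- c(0.45, 0.40, 0.08, 0.07)
    for (i in seq_len(n_mir)) {
      L <- sample(c(20L, 21L, 21L, 21L, 22L), 1)
      first <- sample(five_prime_pool, 1, prob = five_prime_prob)
      mature <- paste0(first, random_dna(1, L - 1L))
      hp <- build_hairpin(mature, arm = sample(c("5p", "3p"), 1),
                          loop_len = sample(10:14, 1))
      cls <- if (i <= config$n_conserved_loci) "conserved_mir" else
        "novel_mir"
      loci[[length(loci) + 1]] <- list(
        locus_id = sprintf("%s_locus_%02d", sub("_mir", "", cls), i),
        class = cls,
        family = if (cls == "conserved_mir") fam[i] else NA_character_,
        seq = hp$core, mature_seq = mature, star_seq = hp$star_seq,
        mature_start = hp$mature_start, mature_end = hp$mature_end,
        star_start = hp$star_start, star_end = hp$star_end,
        arm = hp$arm)
    }
    for (i in seq_len(config$n_sirna_loci)) {
      s <- random_dna(1, 24L)
      loci[[length(loci) + 1]] <- list(
        locus_id = sprintf("sirna_locus_%02d", i), class = "sirna",
        family = NA_character_, seq = s, mature_seq = s,
        star_seq = NA_character_, mature_start = 1L, mature_end = 24L,
        star_start = NA_integer_, star_end = NA_integer_,
        arm = NA_character_)
    }
    for (i in seq_len(n_trna)) {
      s <- random_dna(1, sample(90:140, 1))
      loci[[length(loci) + 1]] <- list(
        locus_id = sprintf("trna_rrna_locus_%02d", i), class = "trna_rrna",
        family = NA_character_, seq = s, mature_seq = NA_character_,
        star_seq = NA_character_, mature_start = NA_integer_,
        mature_end = NA_integer_, star_start = NA_integer_,
        star_end = NA_integer_, arm = NA_character_)
    }
    lowc_units <- c("A", "T", "AT", "GA")
    for (i in seq_len(n_lowc)) {
      unit <- lowc_units[((i - 1) %% length(lowc_units)) + 1]
      s <- substr(strrep(unit, 70), 1, 60)
      loci[[length(loci) + 1]] <- list(
        locus_id = sprintf("low_complexity_locus_%02d", i),
        class = "low_complexity", family = NA_character_, seq = s,
        mature_seq = NA_character_, star_seq = NA_character_,
        mature_start = NA_integer_, mature_end = NA_integer_,
        star_start = NA_integer_, star_end = NA_integer_,
        arm = NA_character_)
    }

    # placement ----------------------------------------------------------
    lens <- vapply(loci, function(x) nchar(x$seq), integer(1))
    gap <- 300L
    required <- sum(lens) + gap * (n_loci + 1L)
    fail_if(config$genome_length < required,
            paste0("genome_length too small to host requested loci: ",
                   "need at least %d nt, got %d (deficit %d nt)"),
            required, config$genome_length,
            required - config$genome_length)
    genome <- random_dna(1, config$genome_length)
    slack <- config$genome_length - sum(lens) - 2L * gap
    cuts <- sort(sample.int(slack, n_loci))
    starts <- cuts + gap + c(0L, cumsum(lens))[seq_len(n_loci)]
    ord <- sample(n_loci)  # random class order along the chromosome

    rows <- vector("list", n_loci)
    for (j in seq_len(n_loci)) {
      lc <- loci[[ord[j]]]
      start <- starts[j]
      end <- start + nchar(lc$seq) - 1L
      strand <- if (lc$class %in% c("conserved_mir", "novel_mir", "sirna"))
        sample(c("+", "-"), 1) else "+"
      insert <- if (strand == "+") lc$seq else revcomp(lc$seq)
      substr(genome, start, end) <- insert
      rows[[ord[j]]] <- data.frame(
        locus_id = lc$locus_id, class = lc$class, chrom = "chr1",
        start = start, end = end, strand = strand,
        mature_seq = lc$mature_seq, star_seq = lc$star_seq,
        family = lc$family, precursor_seq = lc$seq,
        mature_start = lc$mature_start, mature_end = lc$mature_end,
        star_start = lc$star_start, star_end = lc$star_end,
        arm = lc$arm, stringsAsFactors = FALSE)
    }
    loci_df <- do.call(rbind, rows)
    genome_set <- Biostrings::DNAStringSet(setNames(genome, "chr1"))
    truth <- structure(list(loci = loci_df, config = config),
                       class = "ground_truth")
    list(genome = genome_set, truth = truth)
  })
}

# Genomic coordinates of a feature given within the planted locus frame.
locus_feature_coords <- function(row, feat_start, feat_end) {
  if (row$strand == "+") {
    c(row$start + feat_start - 1L, row$start + feat_end - 1L)
  } else {
    c(row$end - feat_end + 1L, row$end - feat_start + 1L)
  }
}

#' Write ground-truth loci as GFF3
#'
#' Emits precursor loci with mature and star subfeatures (1-based
#' inclusive coordinates, strand-aware).
#'
#' @param truth a `ground_truth` object.
#' @param path output GFF3 path.
#' @return the path, invisibly.
#' @export
write_truth_gff3 <- function(truth, path) {
  df <- truth$loci
  feats <- list()
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    feats[[length(feats) + 1]] <- data.frame(
      chrom = r$chrom, start = r$start, end = r$end, strand = r$strand,
      type = switch(r$class, conserved_mir = , novel_mir = "MIR_precursor",
                    sirna = "siRNA_locus", trna_rrna = "tRNA_rRNA",
                    low_complexity = "low_complexity_region"),
      ID = r$locus_id, class = r$class, stringsAsFactors = FALSE)
    if (r$class %in% c("conserved_mir", "novel_mir")) {
      m <- locus_feature_coords(r, r$mature_start, r$mature_end)
      s <- locus_feature_coords(r, r$star_start, r$star_end)
      feats[[length(feats) + 1]] <- data.frame(
        chrom = r$chrom, start = m[1], end = m[2], strand = r$strand,
        type = "miRNA", ID = paste0(r$locus_id, "_mature"), class = r$class,
        stringsAsFactors = FALSE)
      feats[[length(feats) + 1]] <- data.frame(
        chrom = r$chrom, start = s[1], end = s[2], strand = r$strand,
        type = "miRNA_star", ID = paste0(r$locus_id, "_star"),
        class = r$class, stringsAsFactors = FALSE)
    }
  }
  fdf <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = fdf$chrom,
    ranges = IRanges::IRanges(start = fdf$start, end = fdf$end),
    strand = fdf$strand, type = fdf$type, ID = fdf$ID, class = fdf$class)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# Per-locus expression programme: lognormal base abundance, a stage
# profile (flat, single-stage peak, or late-increasing) and an optional
# tissue preference. Stage-varying loci are the planted truth for the
# differential-expression stage.
draw_expression_programme <- function(truth) {
  config <- truth$config
  loci <- truth$loci
  stages <- sort(unique(config$design$stage))
  mir <- loci$class %in% c("conserved_mir", "novel_mir")
  n <- nrow(loci)
  base <- rlnorm(n, meanlog = 0, sdlog = 1)
  profile <- rep("flat", n)
  peak_stage <- rep(NA_character_, n)
  tissue_pref <- rep("none", n)
  for (i in which(mir)) {
    if (runif(1) < config$de_fraction) {
      if (runif(1) < 0.75) {
        profile[i] <- "peak"
        peak_stage[i] <- sample(stages, 1)
      } else {
        profile[i] <- "increasing"
      }
    }
    u <- runif(1)
    tissue_pref[i] <- if (u < 0.6) "none" else if (u < 0.8) "embryo" else
      "mg"
  }
  stage_mult <- matrix(1, n, length(stages),
                       dimnames = list(loci$locus_id, stages))
  for (i in seq_len(n)) {
    if (profile[i] == "peak") {
      stage_mult[i, peak_stage[i]] <- 6
    } else if (profile[i] == "increasing") {
      stage_mult[i, ] <- 1.6 ^ (seq_along(stages) - 1)
    }
  }
  # Note: the "flat" programme refers to absolute locus activity. CPM is
  # compositional, so stage peaks of other loci (and the rising 24-nt
  # fraction) still compress a flat locus's relative abundance; the
  # expression truth matrix records the exact expected counts, and
  # differential-expression truth is defined on expected CPM from it.
  list(base = base, profile = profile, peak_stage = peak_stage,
       tissue_pref = tissue_pref, stage_mult = stage_mult)
}

tissue_multiplier <- function(pref, tissue) {
  embryo <- tissue %in% c("ZE", "SE")
  ifelse(pref == "none", 1,
         ifelse(pref == "embryo", ifelse(embryo, 1, 0.05),
                ifelse(embryo, 0.05, 1)))
}

# Apply per-base substitution errors to a character vector of reads.
apply_read_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  lens <- nchar(reads)
  k <- rbinom(length(reads), lens, error_rate)
  hit <- which(k > 0)
  for (i in hit) {
    chars <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(lens[i], k[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Simulate sRNA libraries from the planted truth
#'
#' Per library, the configured number of reads is allocated across planted
#' loci: locus intensities are gamma-distributed around negative-binomial
#' means shaped by the stage/tissue programme (so marginal counts are
#' NB-dispersed), and reads are drawn multinomially so that each library
#' contains exactly `reads_per_library` reads. Star reads are emitted at
#' `star_to_mature_ratio` times mature abundance; contaminant loci emit
#' random fragments; per-base substitution errors are applied last.
#'
#' @param truth `ground_truth` from [simulate_genome()].
#' @param config the same [sim_config()].
#' @param outdir directory for FASTQ files (created if needed).
#' @return updated `ground_truth` with elements `library_info`, `files`,
#'   `expression` (locus x library expected counts), `star_expression`,
#'   `programme` (per-locus profile flags) appended.
#' @export
simulate_libraries <- function(truth, config, outdir) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  fail_if(any(config$design$n_replicates < 1), "design with zero replicates")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  libs <- library_table(config$design)
  loci <- truth$loci
  with_seed(config$seed + 1L, {
    prog <- draw_expression_programme(truth)
    n <- nrow(loci)
    N <- config$reads_per_library
    is_mir <- loci$class %in% c("conserved_mir", "novel_mir")
    is_sirna <- loci$class == "sirna"
    is_contam <- loci$class %in% c("trna_rrna", "low_complexity")

    expression <- matrix(0, n, nrow(libs),
                         dimnames = list(loci$locus_id, libs$library))
    star_expression <- expression
    files <- character(nrow(libs))

    for (j in seq_len(nrow(libs))) {
      lb <- libs[j, ]
      frac24 <- config$frac24_by_stage[[lb$stage]]
      w <- prog$base * prog$stage_mult[, lb$stage] *
        tissue_multiplier(prog$tissue_pref, lb$tissue)
      mu <- numeric(n)
      # class budget: contaminants, then 24-nt siRNA vs MIR split
      mir_budget <- N * (1 - config$contaminant_frac) * (1 - frac24)
      sirna_budget <- N * (1 - config$contaminant_frac) * frac24
      contam_budget <- N * config$contaminant_frac
      r <- config$star_to_mature_ratio
      if (any(is_mir) && sum(w[is_mir]) > 0) {
        # mature + star reads jointly fill the MIR budget
        mu[is_mir] <- mir_budget / (1 + r) * w[is_mir] / sum(w[is_mir])
      }
      if (any(is_sirna) && sum(w[is_sirna]) > 0) {
        mu[is_sirna] <- sirna_budget * w[is_sirna] / sum(w[is_sirna])
      }
      if (any(is_contam)) {
        mu[is_contam] <- contam_budget / sum(is_contam)
      }
      mu_star <- ifelse(is_mir, mu * r, 0)

      item_mu <- c(mu, mu_star[is_mir])
      item_kind <- c(rep("locus", n), rep("star", sum(is_mir)))
      item_locus <- c(seq_len(n), which(is_mir))
      lambda <- if (config$nb_dispersion > 0) {
        shape <- 1 / config$nb_dispersion
        ifelse(item_mu > 0,
               rgamma(length(item_mu), shape = shape,
                      scale = item_mu / shape), 0)
      } else item_mu
      counts <- as.vector(rmultinom(1, N, prob = lambda + 1e-12))

      expression[, j] <- item_mu[item_kind == "locus"]
      star_expression[is_mir, j] <- item_mu[item_kind == "star"]

      reads <- vector("list", length(counts))
      for (it in seq_along(counts)) {
        ct <- counts[it]
        if (ct == 0) next
        li <- item_locus[it]
        cls <- loci$class[li]
        if (item_kind[it] == "star") {
          reads[[it]] <- rep(loci$star_seq[li], ct)
        } else if (cls %in% c("conserved_mir", "novel_mir")) {
          reads[[it]] <- rep(loci$mature_seq[li], ct)
        } else if (cls == "sirna") {
          reads[[it]] <- rep(loci$mature_seq[li], ct)
        } else {
          src <- loci$precursor_seq[li]
          rl <- sample(18:26, ct, replace = TRUE)
          st <- vapply(rl, function(l)
            sample.int(nchar(src) - l + 1L, 1), integer(1))
          reads[[it]] <- substr(rep(src, ct), st, st + rl - 1L)
        }
      }
      reads <- unlist(reads)
      reads <- apply_read_errors(reads, config$error_rate)
      reads <- reads[sample.int(length(reads))]
      stopifnot(length(reads) == N)

      path <- file.path(outdir, paste0(lb$library, ".fastq"))
      xs <- Biostrings::DNAStringSet(reads)
      names(xs) <- sprintf("r%07d", seq_along(reads))
      quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
      Biostrings::writeXStringSet(xs, path, format = "fastq",
                                  qualities = quals)
      files[j] <- path
    }

    truth$library_info <- libs
    truth$files <- setNames(files, libs$library)
    truth$expression <- expression
    truth$star_expression <- star_expression
    truth$programme <- data.frame(
      locus_id = loci$locus_id, class = loci$class,
      base = prog$base, profile = prog$profile,
      peak_stage = prog$peak_stage, tissue_pref = prog$tissue_pref,
      stringsAsFactors = FALSE)
    truth
  })
}
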