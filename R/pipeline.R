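# Pipeline orchestration: one configuration object whose defaults are
# the study's printed thresholds (18-26 nt, abundance >= 5, 0 genome
# mismatches, 2 reference mismatches, alpha 0.05 without correction,
# CPM cutoff 100, expectation <= 5), a run_all() driver executing the
# stages in order with conservative read accounting, and a
# validate_against_truth() harness scoring a synthetic run against its
# planted ground truth.

#' Pipeline run configuration
#'
#' Defaults equal the study's printed thresholds.
#'
#' @param libraries named character vector, library id -> FASTQ path.
#' @param genome genome FASTA path or DNAStringSet.
#' @param mature_ref mature miRNA reference FASTA path or named vector.
#' @param transcriptome transcriptome FASTA path or named vector.
#' @param go_map gene -> GO TSV path or data.frame.
#' @param contaminants contaminant FASTA path or named vector.
#' @param design data.frame (`library`, `tissue`, `stage`, `condition`,
#'   `replicate`).
#' @param min_len,max_len,min_abundance read filters.
#' @param genome_mismatches must be 0 (exact mapping).
#' @param ref_mismatches conserved-annotation mismatch allowance.
#' @param alpha significance level for DE tests.
#' @param cpm_threshold high-expression shortlist cutoff.
#' @param max_e target-prediction expectation threshold.
#' @param cluster_k number of profile clusters or "auto".
#' @param rng_seed seed for the clustering stage.
#' @return object of class `run_config`.
#' @export
run_config <- function(libraries, genome, mature_ref, transcriptome = NULL,
                       go_map = NULL, contaminants = NULL, design = NULL,
                       min_len = 18L, max_len = 26L, min_abundance = 5L,
                       genome_mismatches = 0L, ref_mismatches = 2L,
                       alpha = 0.05, cpm_threshold = 100, max_e = 5,
                       cluster_k = "auto", rng_seed = 1L) {
  fail_if(genome_mismatches != 0,
          "only exact (0-mismatch) genome mapping is supported")
  structure(list(
    libraries = libraries, genome = genome, mature_ref = mature_ref,
    transcriptome = transcriptome, go_map = go_map,
    contaminants = contaminants, design = design,
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    min_abundance = as.integer(min_abundance),
    genome_mismatches = as.integer(genome_mismatches),
    ref_mismatches = as.integer(ref_mismatches), alpha = alpha,
    cpm_threshold = cpm_threshold, max_e = max_e, cluster_k = cluster_k,
    rng_seed = as.integer(rng_seed)), class = "run_config")
}

# Detected miRNA sequences per library (count > 0 rows of the matrix).
detected_by_library <- function(counts) {
  lapply(setNames(colnames(counts), colnames(counts)),
         function(lb) rownames(counts)[counts[, lb] > 0])
}

#' Run the full pipeline
#'
#' Stages in order: collapse -> length/abundance filter -> contaminant
#' filter -> exact genome mapping -> conserved annotation -> novel/star
#' prediction -> CPM + ln transform -> PCA / replicate clustering ->
#' ANOVA (ZE stages) and t-test (MG4B vs MG7) -> profile clustering ->
#' presence Venn + shortlist -> target prediction -> GO enrichment.
#' Stages needing inputs that are absent (e.g. no transcriptome) are
#' skipped with a note in `report$skipped`.
#'
#' @param config a [run_config()].
#' @return list of class `run_report`; see elements in the source and
#'   the accounting table in `report$accounting`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- list(config = config, skipped = character(0))

  # 1. collapse + filters ------------------------------------------------
  raw <- collapse_reads(config$libraries, design = config$design)
  filtered <- filter_length_abundance(raw, config$min_len, config$max_len,
                                      config$min_abundance)
  if (!is.null(config$contaminants)) {
    filtered <- filter_contaminants(filtered, config$contaminants,
                                    min_len = config$min_len,
                                    max_len = config$max_len)
  }

  # 2. exact mapping ------------------------------------------------------
  index <- build_index(config$genome, k = config$min_len)
  hits <- map_exact(filtered$sequence, index)
  mapped_seqs <- unique(hits$sequence)
  mapped <- urt_keep(filtered, filtered$sequence %in% mapped_seqs)

  report$accounting <- data.frame(
    library = urt_libraries(raw),
    raw = as.numeric(library_totals(raw)),
    filtered = as.numeric(library_totals(filtered)),
    mapped = as.numeric(library_totals(mapped)))
  report$accounting$filtered_pct <-
    100 * report$accounting$filtered / report$accounting$raw
  report$accounting$mapped_pct <-
    100 * report$accounting$mapped / report$accounting$raw
  report$size_profiles <- size_profile(list(raw = raw,
                                            filtered = filtered,
                                            mapped = mapped))
  report$tables <- list(raw = raw, filtered = filtered, mapped = mapped)
  report$hits <- hits

  # 3. annotation ---------------------------------------------------------
  ref <- read_mature_ref(config$mature_ref)
  conserved <- annotate_conserved(mapped$sequence, ref,
                                  config$ref_mismatches)
  novel <- classify_novel(hits, genome_store(config$genome), filtered,
                          conserved = conserved)
  report$conserved <- conserved
  report$novel <- novel
  report$family_isoforms <- count_family_isoforms(conserved)
  report$annotation_summary <- c(
    conserved = nrow(conserved),
    novel = sum(novel$status == "novel"),
    high_confidence = sum(novel$high_confidence),
    stars = sum(novel$status == "star"))
  mirna_seqs <- c(conserved$sequence,
                  novel$sequence[novel$status == "novel"])
  status <- c(rep("conserved", nrow(conserved)),
              rep("novel", sum(novel$status == "novel")))
  report$five_prime <- list(
    conserved = if (nrow(conserved) > 0)
      five_prime_composition(conserved$sequence) else NULL,
    novel = if (any(novel$status == "novel"))
      five_prime_composition(novel$sequence[novel$status == "novel"])
    else NULL)

  # 4. expression ---------------------------------------------------------
  libs <- urt_libraries(filtered)
  counts <- as.matrix(mapped[mapped$sequence %in% mirna_seqs, libs,
                             drop = FALSE])
  rownames(counts) <- mapped$sequence[mapped$sequence %in% mirna_seqs]
  totals <- library_totals(filtered)
  cpm_full <- cpm_normalize(as.matrix(filtered[, libs, drop = FALSE]),
                            totals)
  rownames(cpm_full) <- filtered$sequence
  cpm <- cpm_normalize(counts, totals)
  lncpm <- ln_transform(cpm)
  report$cpm <- cpm
  report$cpm_full <- cpm_full
  report$mirna_status <- setNames(status, mirna_seqs)

  design <- config$design
  if (nrow(counts) >= 2 && ncol(counts) >= 2) {
    report$pca <- tryCatch(pca_correlation(lncpm), error = function(e) {
      report$skipped <<- c(report$skipped, paste("pca:", e$message))
      NULL
    })
    report$hcl <- if (ncol(lncpm) >= 3)
      replicate_hcl(lncpm, design) else NULL
  }

  # 5. differential expression -------------------------------------------
  if (!is.null(design)) {
    ze <- design[design$tissue == "ZE", ]
    ze_sizes <- table(ze$condition)
    ze_keep <- ze[ze$condition %in% names(ze_sizes)[ze_sizes >= 2], ]
    if (nrow(ze_keep) >= 4 && nrow(lncpm) > 0) {
      de <- suppressMessages(
        de_anova(lncpm[, ze_keep$library, drop = FALSE],
                 ze_keep$condition, alpha = config$alpha))
      report$de_ze <- de
      de_seqs <- de$feature[de$de]
      if (length(de_seqs) >= 3) {
        ze_all <- design[design$tissue == "ZE", ]
        prof <- sapply(split(ze_all$library, ze_all$condition),
                       function(ls) rowMeans(lncpm[de_seqs, ls,
                                                   drop = FALSE]))
        prof <- prof[, order(colnames(prof)), drop = FALSE]
        report$ze_clusters <- cluster_profiles(prof,
                                               k = config$cluster_k,
                                               seed = config$rng_seed)
        report$ze_profiles <- prof
      }
    }
    mg1 <- design$library[design$condition == "MG4B"]
    mg2 <- design$library[design$condition == "MG7"]
    if (length(mg1) >= 2 && length(mg2) >= 2 && nrow(lncpm) > 0) {
      report$de_mg <- de_ttest(lncpm, mg1, mg2, labels = c("MG4B", "MG7"),
                               alpha = config$alpha)
    }
    detected <- detected_by_library(counts)
    report$venn <- list()
    for (st in intersect(c("4B", "7"), unique(design$stage))) {
      ts <- unique(design$tissue[design$stage == st])
      if (length(ts) == 3) {
        report$venn[[paste0("T", st)]] <-
          presence_venn(detected, design, st, tissues = c("ZE", "MG", "SE"))
      }
    }
    report$shortlist <- shortlist_high_expression(cpm, design,
                                                  config$cpm_threshold)
  }

  # 6. targets + enrichment ----------------------------------------------
  if (!is.null(config$transcriptome)) {
    de_seqs <- unique(c(
      if (!is.null(report$de_ze)) report$de_ze$feature[report$de_ze$de],
      if (!is.null(report$de_mg)) report$de_mg$feature[report$de_mg$de]))
    if (length(de_seqs) > 0) {
      tx <- fasta_store(config$transcriptome)
      report$targets <- predict_targets(
        setNames(de_seqs, de_seqs), tx, max_e = config$max_e)
      report$targets <- select_targets(report$targets,
                                       max_e = config$max_e)
      if (!is.null(config$go_map) && nrow(report$targets) > 0) {
        study <- unique(report$targets$transcript_id)
        report$enrichment <- enrich_go(study, config$go_map,
                                       alpha = config$alpha)
      }
    } else {
      report$skipped <- c(report$skipped, "targets: no DE miRNAs")
    }
  } else {
    report$skipped <- c(report$skipped, "targets: no transcriptome")
  }

  class(report) <- "run_report"
  report
}

genome_store <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  setNames(as.character(genome), names(genome))
}

fasta_store <- genome_store

#' Score a synthetic run against its planted ground truth
#'
#' Strict set comparisons: conserved annotation accuracy (every planted
#' conserved mature recovered with its planted family), novel
#' high-confidence precision/recall against planted novel loci whose
#' stars were sequenced, star-sequence agreement, DE sensitivity and
#' false-positive rate against the planted stage-varying programme, and
#' whether the planted GO term is the top-ranked significant term.
#'
#' @param report a `run_report` from a synthetic run.
#' @param truth the completed `ground_truth`.
#' @return named list of metrics (NA where undefined, e.g. recall with
#'   zero planted novels).
#' @export
validate_against_truth <- function(report, truth) {
  loci <- truth$loci
  fail_if(!identical(sort(names(report$config$libraries)),
                     sort(truth$library_info$library)),
          "report and truth disagree on the library design")
  cons_truth <- loci[loci$class == "conserved_mir", ]
  out <- list()

  # conserved: planted mature recovered with the planted family
  ann <- report$conserved
  fam_of <- setNames(ann$family, ann$sequence)
  recovered <- cons_truth$mature_seq %in% ann$sequence
  correct <- recovered &
    fam_of[cons_truth$mature_seq] == cons_truth$family
  out$conserved_recall <- mean(recovered)
  out$conserved_family_accuracy <-
    if (any(recovered)) mean(correct[recovered]) else NA_real_

  # novel high-confidence vs planted novels whose stars were sequenced
  novel_truth <- loci[loci$class == "novel_mir", ]
  seq_reads <- report$tables$filtered$sequence
  star_seen <- novel_truth$star_seq %in% seq_reads
  expected_hc <- novel_truth$mature_seq[star_seen]
  called_hc <- report$novel$sequence[report$novel$high_confidence]
  if (nrow(novel_truth) == 0) {
    out$novel_hc_precision <- NA_real_
    out$novel_hc_recall <- NA_real_
  } else {
    out$novel_hc_precision <- if (length(called_hc) > 0)
      mean(called_hc %in% expected_hc) else NA_real_
    out$novel_hc_recall <- if (length(expected_hc) > 0)
      mean(expected_hc %in% called_hc) else NA_real_
  }

  # inferred star sequences vs planted stars, over recovered novels
  nv <- report$novel[report$novel$status == "novel", ]
  truth_star <- setNames(novel_truth$star_seq, novel_truth$mature_seq)
  common <- intersect(nv$sequence, names(truth_star))
  out$star_match_rate <- if (length(common) > 0) {
    called_star <- setNames(nv$star_seq, nv$sequence)[common]
    mean(called_star == truth_star[common])
  } else NA_real_

  # DE against expected-CPM truth (ZE ANOVA). CPM is relative, so the
  # ground truth for differential expression is the expected CPM profile
  # implied by the full generative model (including compositional
  # compression), not the absolute-activity programme: a miRNA is truly
  # DE iff its expected CPM varies at least `de_fold_truth`-fold across
  # the tested ZE conditions.
  if (!is.null(report$de_ze)) {
    de_fold_truth <- 2
    mir_rows <- loci$class %in% c("conserved_mir", "novel_mir")
    keep_rows <- loci$class %in% c("conserved_mir", "novel_mir", "sirna")
    denom <- colSums(truth$expression[keep_rows, , drop = FALSE]) +
      colSums(truth$star_expression)
    ecpm <- sweep(truth$expression[mir_rows, , drop = FALSE], 2, denom,
                  "/") * 1e6
    li <- truth$library_info
    ze <- li[li$tissue == "ZE", ]
    cond_sizes <- table(ze$condition)
    tested <- names(cond_sizes)[cond_sizes >= 2]
    cond_means <- sapply(tested, function(cn)
      rowMeans(ecpm[, ze$library[ze$condition == cn], drop = FALSE]))
    fold <- apply(cond_means, 1, function(x) {
      if (max(x) == 0) 1 else if (min(x) == 0) Inf else max(x) / min(x)
    })
    mature_of <- setNames(loci$mature_seq[mir_rows],
                          loci$locus_id[mir_rows])
    de_truth <- setNames(fold >= de_fold_truth,
                         mature_of[rownames(cond_means)])
    de_call <- setNames(report$de_ze$de, report$de_ze$feature)
    shared <- intersect(names(de_call), names(de_truth))
    if (length(shared) > 0) {
      tp <- sum(de_call[shared] & de_truth[shared])
      fp <- sum(de_call[shared] & !de_truth[shared])
      out$de_sensitivity <- if (sum(de_truth[shared]) > 0)
        tp / sum(de_truth[shared]) else NA_real_
      out$de_fpr <- if (sum(!de_truth[shared]) > 0)
        fp / sum(!de_truth[shared]) else NA_real_
    }
  }

  # planted GO term top-ranked among significant terms
  if (!is.null(report$enrichment)) {
    sig <- report$enrichment[report$enrichment$significant, ]
    out$go_planted_top <- nrow(sig) > 0 &&
      sig$term[1] == truth$enriched_term
  }
  out
}
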