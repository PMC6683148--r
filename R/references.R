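# Synthetic reference sets: a mature-miRNA reference FASTA in miRBase
# dialect (homologs of the planted conserved matures at 0-2 mismatches
# plus distant decoys), a transcriptome with planted target sites of
# known expectation score, a gene -> GO map with one planted enriched
# term, and the contaminant reference.

# Expectation-score penalty for one duplex position (see targets module):
# psRNAtarget-style, doubled in the 5' seed/core region.
planted_penalty <- function(kind, pos, seed_lo = 2, seed_hi = 13) {
  base <- switch(kind, wobble = 0.5, mismatch = 1)
  if (pos >= seed_lo && pos <= seed_hi) 2 * base else base
}

# Modify a perfect-complement site to carry planted wobbles/mismatches at
# given miRNA positions; returns the site and its expectation score.
plant_site <- function(mature, mods) {
  L <- nchar(mature)
  m <- strsplit(mature, "")[[1]]
  site <- strsplit(revcomp(mature), "")[[1]]  # sense transcript site
  E <- 0
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (md in mods) {
    p <- md$pos
    j <- L - p + 1L  # site index opposite miRNA position p
    if (md$kind == "wobble") {
      # G:U wobble needs miRNA G (site T) or miRNA U (site G)
      if (m[p] == "G") site[j] <- "T"
      else if (m[p] == "T") site[j] <- "G"
      else md$kind <- "mismatch"
    }
    if (md$kind == "mismatch") {
      bad <- setdiff(c("A", "C", "G", "T"),
                     c(comp[[m[p]]],
                       if (m[p] == "G") "T" else if (m[p] == "T") "G"))
      site[j] <- sample(bad, 1)
    }
    E <- E + planted_penalty(md$kind, p)
  }
  list(site = paste(site, collapse = ""), E = E)
}

# Catalogue of planted-site modification templates (miRNA positions are
# chosen to exist for mature lengths >= 20).
site_templates <- function() {
  list(
    list(),                                              # E = 0
    list(list(kind = "wobble", pos = 16)),               # E = 0.5
    list(list(kind = "mismatch", pos = 17)),             # E = 1
    list(list(kind = "wobble", pos = 5)),                # E = 1 (seed x2)
    list(list(kind = "mismatch", pos = 3)),              # E = 2
    list(list(kind = "mismatch", pos = 3),
         list(kind = "wobble", pos = 16)),               # E = 2.5
    list(list(kind = "mismatch", pos = 5),
         list(kind = "mismatch", pos = 17)),             # E = 3
    list(list(kind = "mismatch", pos = 3),
         list(kind = "mismatch", pos = 9)),              # E = 4
    list(list(kind = "mismatch", pos = 3),
         list(kind = "mismatch", pos = 9),
         list(kind = "wobble", pos = 18)))               # E = 4.5
}

#' Simulate a gene-to-GO map with one planted enriched term
#'
#' Every gene carries a root term; background terms are assigned
#' uniformly; the planted term is strongly over-represented among the
#' study genes unless `uniform = TRUE` (the null map used for
#' calibration).
#'
#' @param genes population gene ids.
#' @param study_genes genes among which the planted term is enriched.
#' @param enriched_term GO id of the planted term.
#' @param n_background_terms number of uniform background terms.
#' @param enrich_prob,background_prob membership probabilities for the
#'   planted term in study vs non-study genes.
#' @param term_prob membership probability of each background term.
#' @param uniform if TRUE the planted term uses `background_prob`
#'   everywhere (no enrichment).
#' @return data.frame with columns `gene`, `terms` (comma-joined).
#' @export
simulate_go_map <- function(genes, study_genes,
                            enriched_term = "GO:0006790",
                            n_background_terms = 9,
                            enrich_prob = 0.9, background_prob = 0.08,
                            term_prob = 0.15, uniform = FALSE) {
  terms <- sprintf("GO:%07d", seq_len(n_background_terms))
  rows <- lapply(genes, function(g) {
    mine <- "GO:0008150"
    hit <- terms[runif(n_background_terms) < term_prob]
    p_enr <- if (!uniform && g %in% study_genes) enrich_prob else
      background_prob
    if (runif(1) < p_enr) mine <- c(mine, enriched_term)
    data.frame(gene = g, terms = paste(c(mine, hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate reference sets from the planted truth
#'
#' @param truth `ground_truth` from [simulate_genome()].
#' @param config the same [sim_config()].
#' @param n_transcripts,transcript_len_range transcriptome size.
#' @param sites_per_mirna planted target sites per planted mature miRNA.
#' @param decoys number of decoy mature-reference entries at Hamming
#'   distance >= 4 from every planted mature.
#' @return updated `ground_truth` with `mature_ref` (data.frame:
#'   accession, family, sequence, planted_distance), `transcriptome`
#'   (named character), `target_sites` (data.frame with planted
#'   expectation scores), `go_map`, `enriched_term` and `contaminants`.
#' @export
simulate_references <- function(truth, config, n_transcripts = 40,
                                transcript_len_range = c(300, 500),
                                sites_per_mirna = 2, decoys = 3) {
  stopifnot(inherits(truth, "ground_truth"))
  loci <- truth$loci
  with_seed(config$seed + 2L, {
    cons <- loci[loci$class == "conserved_mir", ]
    mir <- loci[loci$class %in% c("conserved_mir", "novel_mir"), ]

    # mature reference: one homolog per family at d in {0,1,2} ----------
    ref <- list()
    if (nrow(cons) > 0) {
      d_plan <- rep(0:2, length.out = nrow(cons))
      for (i in seq_len(nrow(cons))) {
        fam_num <- sub("MIR", "", cons$family[i])
        seq_i <- mutate_positions(cons$mature_seq[i], d_plan[i])
        ref[[length(ref) + 1]] <- data.frame(
          accession = paste0("pta-miR", fam_num, "a"),
          family = cons$family[i], sequence = seq_i,
          planted_distance = d_plan[i], stringsAsFactors = FALSE)
      }
    }
    # decoys: >= 4 mismatches from every planted mature
    all_matures <- mir$mature_seq
    min_dist <- function(s) {
      cand <- all_matures[nchar(all_matures) == nchar(s)]
      if (length(cand) == 0) return(Inf)
      min(vapply(cand, function(m) hamming(m, s), numeric(1)))
    }
    decoy_fams <- c("9601", "9602", "9603", "9604", "9605")
    for (i in seq_len(decoys)) {
      repeat {
        s <- random_dna(1, 21L)
        if (min_dist(s) >= 4) break
      }
      ref[[length(ref) + 1]] <- data.frame(
        accession = paste0("pta-miR", decoy_fams[i], "a"),
        family = paste0("MIR", decoy_fams[i]), sequence = s,
        planted_distance = NA_integer_, stringsAsFactors = FALSE)
    }
    mature_ref <- do.call(rbind, ref)

    # transcriptome with planted target sites ---------------------------
    tx_len <- sample(transcript_len_range[1]:transcript_len_range[2],
                     n_transcripts, replace = TRUE)
    tx <- setNames(random_dna(n_transcripts, tx_len),
                   sprintf("transcript_%03d", seq_len(n_transcripts)))
    templates <- site_templates()
    sites <- list()
    # planted sites live in a dedicated pool of transcripts (40% of the
    # transcriptome); the remainder are site-free controls, so target
    # sets can actually be enriched relative to the whole annotation
    pool <- max(2L, ceiling(0.4 * n_transcripts))
    occupied <- setNames(vector("list", n_transcripts), names(tx))
    tx_slot <- 1L
    for (i in seq_len(nrow(mir))) {
      for (s in seq_len(sites_per_mirna)) {
        tid <- names(tx)[tx_slot]
        tx_slot <- if (tx_slot >= pool) 1L else tx_slot + 1L
        tmpl <- templates[[sample(length(templates), 1)]]
        ps <- plant_site(mir$mature_seq[i], tmpl)
        L <- nchar(ps$site)
        # place away from already-planted sites on this transcript
        repeat {
          pos <- sample.int(nchar(tx[[tid]]) - L + 1L, 1)
          clash <- any(vapply(occupied[[tid]], function(iv)
            pos <= iv[2] && (pos + L - 1L) >= iv[1], logical(1)))
          if (!clash) break
        }
        occupied[[tid]] <- c(occupied[[tid]],
                             list(c(pos, pos + L - 1L)))
        substr(tx[[tid]], pos, pos + L - 1L) <- ps$site
        sites[[length(sites) + 1]] <- data.frame(
          mature_seq = mir$mature_seq[i], locus_id = mir$locus_id[i],
          transcript_id = tid, site_start = pos, site_end = pos + L - 1L,
          planted_expectation_score = ps$E, stringsAsFactors = FALSE)
      }
    }
    target_sites <- do.call(rbind, sites)

    # GO map with one planted enriched term ------------------------------
    enriched_term <- "GO:0006790"
    go_map <- simulate_go_map(names(tx),
                              unique(target_sites$transcript_id),
                              enriched_term = enriched_term)

    contam <- loci[loci$class == "trna_rrna", ]
    contaminants <- setNames(contam$precursor_seq, contam$locus_id)

    truth$mature_ref <- mature_ref
    truth$transcriptome <- tx
    truth$target_sites <- target_sites
    truth$go_map <- go_map
    truth$enriched_term <- enriched_term
    truth$contaminants <- contaminants
    truth
  })
}

#' Write simulated inputs to disk
#'
#' Writes the genome, mature reference (miRBase-dialect headers, RNA
#' alphabet), transcriptome, contaminant FASTA, GO map TSV and truth GFF3.
#'
#' @param genome DNAStringSet from [simulate_genome()].
#' @param truth completed `ground_truth`.
#' @param dir output directory.
#' @return named list of file paths.
#' @export
write_simulated_inputs <- function(genome, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    mature_ref = file.path(dir, "mature_ref.fa"),
    transcriptome = file.path(dir, "transcriptome.fa"),
    contaminants = file.path(dir, "contaminants.fa"),
    go_map = file.path(dir, "go_map.tsv"),
    truth_gff = file.path(dir, "truth.gff3"))
  Biostrings::writeXStringSet(genome, paths$genome)
  ref <- Biostrings::RNAStringSet(chartr("T", "U",
    setNames(truth$mature_ref$sequence, truth$mature_ref$accession)))
  Biostrings::writeXStringSet(ref, paths$mature_ref)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(truth$transcriptome), paths$transcriptome)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(truth$contaminants), paths$contaminants)
  write.table(truth$go_map, paths$go_map, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_truth_gff3(truth, paths$truth_gff)
  paths
}

#' Run the whole generator
#'
#' Convenience wrapper: genome, libraries and references in one call.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (FASTQ under `outdir/libraries`).
#' @return list with `genome`, `truth`, `paths`.
#' @export
simulate_all <- function(config, outdir) {
  g <- simulate_genome(config)
  truth <- simulate_libraries(g$truth, config,
                              file.path(outdir, "libraries"))
  truth <- simulate_references(truth, config)
  paths <- write_simulated_inputs(g$genome, truth, outdir)
  paths$libraries <- truth$files
  list(genome = g$genome, truth = truth, paths = paths)
}
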