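# Shared synthetic fixtures, built once per test run.

tiny_sim_config <- function(seed = 7) {
  sim_config(seed = seed, genome_length = 60000, n_conserved_loci = 6,
             n_novel_loci = 4, n_sirna_loci = 3, n_contaminant_loci = 4,
             reads_per_library = 8000)
}

# Minimal design for fast determinism / generator checks.
mini_design <- function() {
  data.frame(tissue = c("ZE", "ZE"), stage = c("3", "7"),
             n_replicates = c(2L, 2L), stringsAsFactors = FALSE)
}

mini_sim_config <- function(seed = 11, reads = 3000) {
  sim_config(seed = seed, genome_length = 40000, n_conserved_loci = 3,
             n_novel_loci = 2, n_sirna_loci = 2, n_contaminant_loci = 2,
             design = mini_design(), reads_per_library = reads,
             frac24_by_stage = c("3" = 0.15, "7" = 0.35))
}

local({
  cache <- new.env(parent = emptyenv())
  tiny_sim <<- function() {
    if (is.null(cache$sim)) {
      dir <- file.path(tempdir(), "seedmir_tiny_sim")
      cache$sim <- simulate_all(tiny_sim_config(), dir)
    }
    cache$sim
  }
  tiny_report <<- function() {
    if (is.null(cache$report)) {
      sim <- tiny_sim()
      rc <- run_config(
        libraries = sim$truth$files, genome = sim$paths$genome,
        mature_ref = sim$paths$mature_ref,
        transcriptome = sim$paths$transcriptome,
        go_map = sim$paths$go_map, contaminants = sim$paths$contaminants,
        design = sim$truth$library_info)
      cache$report <- run_all(rc)
    }
    cache$report
  }
})

# Small unique-read table built directly from reads (no files).
urt_from_reads <- function(reads_by_lib, design = NULL) {
  collapse_reads(reads_by_lib, design = design)
}
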