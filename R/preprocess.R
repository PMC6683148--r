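# Preprocessing: collapse raw reads to unique sequences with per-library
# counts, apply the length / absolute-abundance / contaminant filters,
# and compute size-class profiles at the raw, filtered and mapped
# checkpoints.

#' Collapse FASTQ libraries to a unique-read table
#'
#' One row per distinct sequence with per-library counts and the total
#' across libraries. U is normalized to T internally; reads containing N
#' or other non-ACGTU characters are dropped (and counted in the
#' `dropped` attribute).
#'
#' @param files named character vector: library id -> FASTQ path. A list
#'   of character vectors of raw reads (named by library) is also
#'   accepted, which is convenient in tests.
#' @param design optional data.frame with columns `library`, `tissue`,
#'   `stage`, `condition`, `replicate`; attached as the `design`
#'   attribute.
#' @return data.frame of class `unique_read_table`: columns `sequence`,
#'   `length`, one count column per library, `total`.
#' @export
collapse_reads <- function(files, design = NULL) {
  if (is.list(files) && !is.data.frame(files)) {
    reads_by_lib <- files
  } else {
    fail_if(is.null(names(files)) || any(names(files) == ""),
            "files must be named by library id")
    reads_by_lib <- lapply(files, function(f) {
      fail_if(!file.exists(f), "FASTQ file not found: %s", f)
      as.character(Biostrings::readDNAStringSet(f, format = "fastq"))
    })
  }
  libs <- names(reads_by_lib)
  fail_if(is.null(libs), "libraries must be named")
  dropped <- integer(length(libs))
  tabs <- vector("list", length(libs))
  for (i in seq_along(libs)) {
    r <- toupper(chartr("U", "T", reads_by_lib[[i]]))
    ok <- !grepl("[^ACGT]", r)
    dropped[i] <- sum(!ok)
    r <- r[ok]
    if (length(r) == 0) {
      tabs[[i]] <- data.table(sequence = character(0), count = integer(0),
                              library = character(0))
    } else {
      dt <- data.table(sequence = r)[, list(count = .N), by = "sequence"]
      dt[, library := libs[i]]
      tabs[[i]] <- dt
    }
  }
  long <- rbindlist(tabs)
  if (nrow(long) == 0) {
    wide <- data.frame(sequence = character(0), length = integer(0))
    for (lb in libs) wide[[lb]] <- integer(0)
    wide$total <- integer(0)
  } else {
    w <- data.table::dcast(long, sequence ~ library, value.var = "count",
                           fill = 0L)
    for (lb in setdiff(libs, names(w))) w[[lb]] <- 0L
    data.table::setcolorder(w, c("sequence", libs))
    wide <- as.data.frame(w)
    wide$length <- nchar(wide$sequence)
    wide$total <- rowSums(wide[, libs, drop = FALSE])
    wide <- wide[, c("sequence", "length", libs, "total")]
  }
  structure(wide, class = c("unique_read_table", "data.frame"),
            libraries = libs, design = design,
            dropped = setNames(dropped, libs))
}

urt_libraries <- function(tab) attr(tab, "libraries")

# Rebuild class/attrs after row subsetting.
urt_keep <- function(tab, keep) {
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(tab), libraries = attr(tab, "libraries"),
            design = attr(tab, "design"), dropped = attr(tab, "dropped"))
}

#' Per-library redundant read totals of a unique-read table
#' @param tab a `unique_read_table`.
#' @return named numeric vector of totals.
#' @export
library_totals <- function(tab) {
  libs <- urt_libraries(tab)
  colSums(tab[, libs, drop = FALSE])
}

#' Length and absolute-abundance filter
#'
#' Retains sequences inside `[min_len, max_len]` whose abundance is at
#' least `min_abundance` ("lower than 5" is removed, so a count of 5
#' passes). Abundance is assessed on the per-sequence total across all
#' co-processed libraries by default; `scope = "per_library"` keeps a
#' sequence if any single library reaches the threshold.
#'
#' @param tab a `unique_read_table`.
#' @param min_len,max_len retained length range (nt), inclusive.
#' @param min_abundance minimum retained count.
#' @param scope "total" (default) or "per_library".
#' @return filtered `unique_read_table`.
#' @export
filter_length_abundance <- function(tab, min_len = 18L, max_len = 26L,
                                    min_abundance = 5L,
                                    scope = c("total", "per_library")) {
  scope <- match.arg(scope)
  fail_if(min_len > max_len, "min_len must be <= max_len")
  len_ok <- tab$length >= min_len & tab$length <= max_len
  ab_ok <- if (scope == "total") {
    tab$total >= min_abundance
  } else {
    libs <- urt_libraries(tab)
    apply(tab[, libs, drop = FALSE] >= min_abundance, 1, any)
  }
  urt_keep(tab, len_ok & ab_ok)
}

# TRUE for reads failing the low-complexity rules: any single nucleotide
# above `max_frac` of the read, or a pure dinucleotide repeat.
is_low_complexity <- function(seqs, max_frac = 0.8) {
  if (length(seqs) == 0) return(logical(0))
  m <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs),
                                     baseOnly = TRUE, as.prob = TRUE)
  mono <- apply(m[, c("A", "C", "G", "T"), drop = FALSE], 1, max) >
    max_frac
  dinit <- substr(seqs, 1, 2)
  reps <- strrep(dinit, ceiling(nchar(seqs) / 2))
  di <- substr(reps, 1, nchar(seqs)) == seqs &
    substr(seqs, 1, 1) != substr(seqs, 2, 2) & nchar(seqs) >= 4
  mono | di
}

#' Contaminant and low-complexity filter
#'
#' Removes sequences that occur as an exact substring of any contaminant
#' reference sequence (either strand), and low-complexity reads (one
#' nucleotide above `low_complexity_max_frac` of the read, or a pure
#' dinucleotide repeat).
#'
#' @param tab a `unique_read_table`.
#' @param contaminants contaminant reference: FASTA path, DNAStringSet or
#'   named character vector.
#' @param low_complexity_max_frac maximum allowed mononucleotide
#'   fraction.
#' @param min_len,max_len read length range used to enumerate contaminant
#'   substrings.
#' @return filtered `unique_read_table`.
#' @export
filter_contaminants <- function(tab, contaminants,
                                low_complexity_max_frac = 0.8,
                                min_len = 18L, max_len = 26L) {
  if (is.character(contaminants) && length(contaminants) == 1 &&
      file.exists(contaminants)) {
    contaminants <- Biostrings::readDNAStringSet(contaminants)
  } else if (is.character(contaminants) && length(contaminants) == 1 &&
             grepl("[.](fa|fasta)$", contaminants)) {
    stop("contaminant reference file not found: ", contaminants)
  }
  refs <- as.character(contaminants)
  refs <- c(refs, revcomp(refs))
  # hash set of every substring in the read length range
  subs <- unlist(lapply(refs, function(s) {
    n <- nchar(s)
    unlist(lapply(min_len:min(max_len, n), function(l) {
      substring(s, 1:(n - l + 1), l:n)
    }))
  }))
  contam_hit <- tab$sequence %in% subs
  lowc <- is_low_complexity(tab$sequence, low_complexity_max_frac)
  urt_keep(tab, !(contam_hit | lowc))
}

#' Size-class profiles at pipeline checkpoints
#'
#' Per checkpoint (e.g. raw, filtered, mapped), library and read length:
#' the percentage of redundant reads of that length relative to the
#' library total at that checkpoint. When the design is attached,
#' per-condition replicate mean and min-max range are also returned.
#'
#' @param checkpoints named list of `unique_read_table`s sharing the same
#'   library set (e.g. `list(raw = ..., filtered = ..., mapped = ...)`).
#' @return list with `per_library` (checkpoint, library, length, reads,
#'   percent) and, when a design is attached, `per_condition` with mean
#'   and range across replicates.
#' @export
size_profile <- function(checkpoints) {
  stopifnot(is.list(checkpoints), !is.null(names(checkpoints)))
  libs <- urt_libraries(checkpoints[[1]])
  for (cp in checkpoints) {
    fail_if(!identical(urt_libraries(cp), libs),
            "checkpoint tables must share the library set")
  }
  per_lib <- list()
  for (nm in names(checkpoints)) {
    tab <- checkpoints[[nm]]
    for (lb in libs) {
      tot <- sum(tab[[lb]])
      fail_if(tot == 0,
              "size profile undefined: zero total for library %s at %s",
              lb, nm)
      agg <- tapply(tab[[lb]], tab$length, sum)
      per_lib[[length(per_lib) + 1]] <- data.frame(
        checkpoint = nm, library = lb,
        length = as.integer(names(agg)), reads = as.numeric(agg),
        percent = 100 * as.numeric(agg) / tot, stringsAsFactors = FALSE)
    }
  }
  per_lib <- do.call(rbind, per_lib)
  design <- attr(checkpoints[[1]], "design")
  per_cond <- NULL
  if (!is.null(design)) {
    d <- merge(per_lib, design[, c("library", "condition")],
               by = "library")
    per_cond <- aggregate(percent ~ checkpoint + condition + length, d,
                          function(x) c(mean = mean(x), min = min(x),
                                        max = max(x)))
    per_cond <- cbind(per_cond[, 1:3], as.data.frame(per_cond$percent))
  }
  list(per_library = per_lib, per_condition = per_cond)
}
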