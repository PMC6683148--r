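#' Reverse complement of DNA strings
#'
#' Strand-aware helpers used throughout the pipeline. The internal alphabet
#' is DNA (U is normalized to T on input); mature miRNA sequences are
#' reported with U in user-facing tables to match the miRBase dialect.
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @rdname revcomp
#' @export
dna_to_rna <- function(x) chartr("T", "U", x)

#' @rdname revcomp
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Random DNA of given lengths.
random_dna <- function(n, len) {
  if (length(len) == 1L) len <- rep(len, n)
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Mutate exactly `d` positions of a sequence (each to a different base).
mutate_positions <- function(seq, d) {
  if (d == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), d)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# stopifnot with a formatted message
fail_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
}
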