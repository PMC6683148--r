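# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: full scans, explicit enumeration, closed forms.

# Exact mapping by scanning both strands with Biostrings::matchPattern.
oracle_map_scan <- function(seqs, genome) {
  chroms <- setNames(as.character(genome), names(genome))
  out <- list()
  for (sq in unique(seqs)) {
    for (ch in names(chroms)) {
      subject <- Biostrings::DNAString(chroms[[ch]])
      fwd <- Biostrings::matchPattern(sq, subject)
      for (i in seq_along(fwd)) {
        out[[length(out) + 1]] <- data.frame(
          sequence = sq, chrom = ch,
          start = Biostrings::start(fwd)[i],
          end = Biostrings::end(fwd)[i], strand = "+",
          stringsAsFactors = FALSE)
      }
      rev <- Biostrings::matchPattern(revcomp(sq), subject)
      for (i in seq_along(rev)) {
        out[[length(out) + 1]] <- data.frame(
          sequence = sq, chrom = ch,
          start = Biostrings::start(rev)[i],
          end = Biostrings::end(rev)[i], strand = "-",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(sequence = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$sequence, df$chrom, df$start, df$strand), ]
  rownames(df) <- NULL
  df
}

# Brute-force read-vs-reference distance: all offsets, overhang of the
# longer sequence counted as mismatches, incomparable beyond 2 nt
# length difference.
oracle_ungapped_distance <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (abs(la - lb) > 2) return(Inf)
  s <- if (la <= lb) a else b
  l <- if (la <= lb) b else a
  sc <- strsplit(s, "")[[1]]; lc <- strsplit(l, "")[[1]]
  d <- Inf
  for (off in 0:(length(lc) - length(sc))) {
    mm <- sum(sc != lc[(off + 1):(off + length(sc))]) +
      (length(lc) - length(sc))
    d <- min(d, mm)
  }
  d
}

# Exhaustive enumeration of nested pairings (no memoization): maximum
# total weight with GC=3, AU=2, GU=1 and a minimum loop of `min_loop`.
oracle_fold_score <- function(seq, min_loop = 3) {
  chars <- strsplit(toupper(seq), "")[[1]]
  w <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(3)
    au <- function(x, y) (x == "A" && y %in% c("T", "U")) ||
      (x %in% c("T", "U") && y == "A")
    gu <- function(x, y) (x == "G" && y %in% c("T", "U")) ||
      (x %in% c("T", "U") && y == "G")
    if (au(a, b)) return(2)
    if (gu(a, b)) return(1)
    0
  }
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      wk <- w(chars[i], chars[k])
      if (wk > 0) {
        inner <- rec(i + 1, k - 1)
        outer <- if (k + 1 <= j) rec(k + 1, j) else 0
        best <- max(best, wk + inner + outer)
      }
    }
    best
  }
  if (length(chars) == 0) return(0)
  rec(1, length(chars))
}

# Upper-tail hypergeometric probability by explicit combinatorial sums.
oracle_hypergeom <- function(k, K, N, n) {
  xs <- k:min(n, K)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Expectation score by a direct per-position loop over the aligned
# duplex (miRNA 5'->3' against reversed site).
oracle_score_duplex <- function(mirna_aln, site_aln) {
  m <- strsplit(toupper(chartr("U", "T", mirna_aln)), "")[[1]]
  s <- rev(strsplit(toupper(chartr("U", "T", site_aln)), "")[[1]])
  stopifnot(length(m) == length(s))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  e <- 0
  mpos <- 0
  for (i in seq_along(m)) {
    if (m[i] != "-") mpos <- mpos + 1
    pos <- if (m[i] == "-") mpos + 1 else mpos
    pen <- if (m[i] == "-" || s[i] == "-") 2
    else if (s[i] == comp[[m[i]]]) 0
    else if ((m[i] == "G" && s[i] == "T") ||
             (m[i] == "T" && s[i] == "G")) 0.5
    else 1
    if (pos >= 2 && pos <= 13) pen <- 2 * pen
    e <- e + pen
  }
  e
}

# All sequences of a given length over an alphabet.
all_seqs <- function(len, alphabet) {
  if (len == 0) return("")
  grid <- do.call(expand.grid, rep(list(alphabet), len))
  apply(grid, 1, paste, collapse = "")
}

random_reads <- function(n, len_range = c(18, 26)) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  vapply(lens, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE),
          collapse = ""), character(1))
}
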