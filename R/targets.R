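# Target prediction: expectation-score complementarity between a miRNA
# and transcript sites (psRNAtarget-style penalties: Watson-Crick match
# 0, G:U wobble 0.5, mismatch 1, gap 2, doubled at miRNA positions 2-13),
# site scanning with at most one gap per duplex, threshold selection, and
# hypergeometric GO-term enrichment with Benjamini-Hochberg correction.

default_scoring <- function() {
  list(match = 0, wobble = 0.5, mismatch = 1, gap = 2,
       seed_lo = 2L, seed_hi = 13L, seed_factor = 2)
}

# Pair class of one duplex column: miRNA base vs transcript (sense) base.
# A match means the site base is the Watson-Crick complement; wobble is
# G:U (miRNA G with site T, or miRNA U/T with site G).
pair_class <- function(m, s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ifelse(m == "-" | s == "-", "gap",
         ifelse(s == comp[m], "match",
                ifelse((m == "G" & s == "T") | (m == "T" & s == "G"),
                       "wobble", "mismatch")))
}

#' Expectation score of a miRNA-site duplex
#'
#' The duplex aligns the miRNA 5'->3' against the transcript site 3'->5'.
#' `site` is given in transcript sense orientation (5'->3') and is
#' reversed internally, so a site equal to the reverse complement of the
#' miRNA scores 0. Gaps are written as `-` in either sequence; each
#' column's penalty is doubled when its miRNA position falls in the 5'
#' seed/core region (positions 2-13).
#'
#' @param mirna miRNA sequence 5'->3' (gaps allowed as `-`).
#' @param site transcript site 5'->3', same aligned length.
#' @param scoring penalty table, see `default_scoring()`.
#' @return expectation score E (>= 0).
#' @export
score_duplex <- function(mirna, site, scoring = default_scoring()) {
  fail_if(nchar(mirna) == 0 || nchar(site) == 0, "empty sequences")
  m <- strsplit(toupper(rna_to_dna(mirna)), "")[[1]]
  s <- rev(strsplit(toupper(rna_to_dna(site)), "")[[1]])
  fail_if(length(m) != length(s),
          "aligned miRNA and site must have equal length")
  cls <- pair_class(m, s)
  # miRNA position of each column: gaps in the miRNA take the position
  # they interrupt (the next miRNA base).
  pos <- cumsum(m != "-")
  pos[m == "-"] <- pos[m == "-"] + 1L
  pen <- unname(c(match = scoring$match, wobble = scoring$wobble,
                  mismatch = scoring$mismatch, gap = scoring$gap)[cls])
  seed <- pos >= scoring$seed_lo & pos <= scoring$seed_hi
  sum(pen * ifelse(seed, scoring$seed_factor, 1))
}

# Score many windows at once. `m_chars` are the duplex columns' miRNA
# characters ("-" for a miRNA gap), `site_mat` the site characters per
# column (rows) and window (columns, "-" for a site gap), `pos` each
# column's miRNA position (for the seed multiplier).
score_windows <- function(m_chars, site_mat, scoring,
                          pos = seq_along(m_chars)) {
  L <- length(m_chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cmp <- comp[m_chars]
  cmp[is.na(cmp)] <- "?"
  pen <- matrix(scoring$mismatch, L, ncol(site_mat))
  wob <- (m_chars == "G" & site_mat == "T") |
    (m_chars == "T" & site_mat == "G")
  pen[wob] <- scoring$wobble
  pen[site_mat == cmp] <- scoring$match
  pen[m_chars == "-" | site_mat == "-"] <- scoring$gap
  mult <- ifelse(pos >= scoring$seed_lo & pos <= scoring$seed_hi,
                 scoring$seed_factor, 1)
  colSums(pen * mult)
}

#' Scan a transcript for miRNA target sites
#'
#' Scans every transcript window, allowing at most one gap on either
#' strand of the duplex, and returns hits with expectation score at most
#' `max_e`. Overlapping hits are reduced to the best-scoring one per site
#' (ties to the leftmost).
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param transcript transcript sequence (sense).
#' @param transcript_id id carried into the result.
#' @param max_e maximum expectation score retained.
#' @param scoring penalty table, see `default_scoring()`.
#' @return data.frame of class `target_hits`: `mirna`, `transcript_id`,
#'   `start`, `end`, `expectation`, `mirna_aln`, `site_aln`.
#' @export
align_site <- function(mirna, transcript, transcript_id = "tx",
                       max_e = 5, scoring = default_scoring()) {
  mirna <- toupper(rna_to_dna(mirna))
  transcript <- toupper(rna_to_dna(transcript))
  L <- nchar(mirna)
  fail_if(nchar(transcript) < L, "transcript shorter than miRNA")
  m_chars <- strsplit(mirna, "")[[1]]
  t_chars <- strsplit(transcript, "")[[1]]
  n <- length(t_chars)
  hits <- list()

  # One duplex configuration = miRNA column characters, per-column miRNA
  # positions, per-column site offsets within the window (NA = site gap),
  # and the window width. Scored vectorized over all window starts.
  run_config <- function(cols, pos, offs, width) {
    if (n < width) return(NULL)
    starts <- seq_len(n - width + 1L)
    sm <- matrix("-", length(cols), length(starts))
    for (j in seq_along(cols)) {
      if (!is.na(offs[j])) sm[j, ] <- t_chars[starts + offs[j]]
    }
    e <- score_windows(cols, sm, scoring, pos)
    keep <- which(e <= max_e)
    if (length(keep) == 0) return(NULL)
    data.frame(
      mirna = mirna, transcript_id = transcript_id,
      start = starts[keep], end = starts[keep] + width - 1L,
      expectation = e[keep], mirna_aln = paste(cols, collapse = ""),
      site_aln = substring(transcript, starts[keep],
                           starts[keep] + width - 1L),
      stringsAsFactors = FALSE)
  }

  # ungapped: duplex column j pairs miRNA base j with site offset L - j
  hits[[length(hits) + 1]] <- run_config(m_chars, seq_len(L),
                                         L - seq_len(L), L)

  if (L >= 4) {
    # one gap in the site: miRNA base g is bulged (window width L - 1);
    # non-gap columns map to site offsets width - rank in duplex order
    for (g in 2:(L - 1L)) {
      offs <- integer(L)
      j <- seq_len(L)
      offs[j < g] <- (L - 1L) - j[j < g]
      offs[j > g] <- L - j[j > g]
      offs[g] <- NA_integer_
      hits[[length(hits) + 1]] <- run_config(m_chars, seq_len(L), offs,
                                             L - 1L)
    }
    # one gap in the miRNA: an extra site base is bulged (width L + 1);
    # the gap column takes the miRNA position it interrupts
    for (g in 2:L) {
      cols <- append(m_chars, "-", after = g - 1L)
      pos <- c(seq_len(g - 1L), g, g:L)
      width <- L + 1L
      offs <- width - seq_len(width)
      hits[[length(hits) + 1]] <- run_config(cols, pos, offs, width)
    }
  }

  hits <- Filter(Negate(is.null), hits)
  if (length(hits) == 0) {
    return(structure(data.frame(
      mirna = character(0), transcript_id = character(0),
      start = integer(0), end = integer(0), expectation = numeric(0),
      mirna_aln = character(0), site_aln = character(0)),
      class = c("target_hits", "data.frame")))
  }
  df <- do.call(rbind, hits)
  df <- df[order(df$expectation, df$start), ]
  # reduce overlapping hits to the best per site
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    ov <- which(keep & seq_len(nrow(df)) > i &
                  df$start <= df$end[i] & df$end >= df$start[i])
    keep[ov] <- FALSE
  }
  df <- df[keep, ]
  df <- df[order(df$start), ]
  rownames(df) <- NULL
  structure(df, class = c("target_hits", "data.frame"))
}

#' Scan a whole transcriptome for one or more miRNAs
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param transcripts named character vector / DNAStringSet.
#' @param max_e maximum expectation score retained.
#' @param scoring penalty table.
#' @return combined `target_hits` data.frame.
#' @export
predict_targets <- function(mirnas, transcripts, max_e = 5,
                            scoring = default_scoring()) {
  tx <- setNames(as.character(transcripts), names(transcripts))
  out <- list()
  for (mi in seq_along(mirnas)) {
    for (ti in seq_along(tx)) {
      h <- align_site(mirnas[[mi]], tx[[ti]], names(tx)[ti],
                      max_e = max_e, scoring = scoring)
      if (nrow(h) > 0) out[[length(out) + 1]] <- h
    }
  }
  if (length(out) == 0) {
    return(structure(data.frame(
      mirna = character(0), transcript_id = character(0),
      start = integer(0), end = integer(0), expectation = numeric(0),
      mirna_aln = character(0), site_aln = character(0)),
      class = c("target_hits", "data.frame")))
  }
  structure(do.call(rbind, out), class = c("target_hits", "data.frame"))
}

#' Select targets by expectation score
#'
#' Default mode retains E <= `max_e` (5); the literal mode retains
#' 3 <= E <= 5, the narrower reading of an "expectation 3-to-5"
#' selection. The mode used is recorded in the `mode` attribute.
#'
#' @param hits `target_hits` data.frame.
#' @param mode "threshold" (E <= max) or "literal" (range).
#' @param e_range numeric length-2 range used by the literal mode.
#' @param max_e threshold for the default mode.
#' @return filtered hits with attribute `mode`.
#' @export
select_targets <- function(hits, mode = c("threshold", "literal"),
                           e_range = c(3, 5), max_e = 5) {
  mode <- match.arg(mode)
  fail_if(length(e_range) != 2 || e_range[1] > e_range[2],
          "invalid expectation range")
  keep <- if (mode == "threshold") hits$expectation <= max_e else
    hits$expectation >= e_range[1] & hits$expectation <= e_range[2]
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  out
}

#' Hypergeometric GO-term enrichment
#'
#' Per term with population count K: upper-tail hypergeometric
#' p = P(X >= k | N, K, n) for k study hits among n study genes drawn
#' from N population genes, Benjamini-Hochberg correction across all
#' tested terms, significant iff q <= alpha. The population is all genes
#' with at least one GO annotation.
#'
#' @param study_genes character vector (subset of the population).
#' @param go_map data.frame `gene`, `terms` (comma-joined) as written by
#'   [simulate_go_map()], or a path to such a TSV (no header).
#' @param alpha significance level.
#' @return data.frame: `term`, `k`, `n`, `K`, `N`, `p`, `q`,
#'   `significant`, ordered by p.
#' @export
enrich_go <- function(study_genes, go_map, alpha = 0.05) {
  if (is.character(go_map) && length(go_map) == 1) {
    go_map <- read.table(go_map, sep = "\t", header = FALSE,
                         col.names = c("gene", "terms"),
                         stringsAsFactors = FALSE)
  }
  fail_if(length(study_genes) == 0, "empty study set")
  population <- unique(go_map$gene[nzchar(go_map$terms)])
  study_genes <- unique(study_genes)
  fail_if(!all(study_genes %in% population),
          "study genes must be annotated members of the population")
  term_list <- strsplit(go_map$terms, ",", fixed = TRUE)
  long <- data.frame(gene = rep(go_map$gene, lengths(term_list)),
                     term = unlist(term_list), stringsAsFactors = FALSE)
  long <- unique(long)
  N <- length(population)
  n <- length(study_genes)
  terms <- unique(long$term)
  rows <- lapply(terms, function(tm) {
    members <- long$gene[long$term == tm]
    K <- length(members)
    k <- length(intersect(members, study_genes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q <= alpha
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}
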