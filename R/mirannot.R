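# miRNA annotation: conserved annotation against a mature reference
# (ungapped, up to two mismatches, length difference <= 2 with
# overhanging bases counted as mismatches), novel miRNA prediction from
# genomic hairpin precursors (maximum-weight pairing fold, duplex
# geometry criteria), miRNA-star inference under the canonical Dicer
# 2-nt 3' overhang rule, high-confidence calls when the star is
# observed among sequenced reads, and 5'-nucleotide composition.

#' Read a mature miRNA reference FASTA (miRBase dialect)
#'
#' Family labels are parsed from entry names, e.g. `pta-miR156a` ->
#' `MIR156`. U is normalized to T internally.
#'
#' @param path FASTA path, or a named character vector of sequences.
#' @return data.frame: `accession`, `family`, `sequence`.
#' @export
read_mature_ref <- function(path) {
  if (is.character(path) && length(path) == 1 && file.exists(path)) {
    xs <- Biostrings::readBStringSet(path)
    seqs <- setNames(as.character(xs), names(xs))
  } else {
    seqs <- path
  }
  fail_if(length(seqs) == 0, "empty mature reference")
  acc <- sub("\\s.*$", "", names(seqs))
  m <- regmatches(acc, regexpr("[Mm][Ii][Rr]-?([0-9]+)", acc))
  fail_if(any(lengths(regmatches(acc,
    gregexpr("[Mm][Ii][Rr]-?[0-9]+", acc))) == 0),
    "cannot parse a MIR family from every reference name")
  family <- paste0("MIR", sub("^[Mm][Ii][Rr]-?", "", m))
  out <- data.frame(accession = acc, family = family,
                    sequence = toupper(chartr("U", "T", seqs)),
                    stringsAsFactors = FALSE)
  fail_if(any(nchar(out$sequence) < 18 | nchar(out$sequence) > 26),
          "reference mature sequences must be 18-26 nt")
  rownames(out) <- NULL
  out
}

# Ungapped distance between a read and one reference sequence: equal
# lengths use Hamming distance; a length difference of up to 2 slides the
# shorter inside the longer, counting the overhang of the longer as
# mismatches; larger differences are incomparable (Inf).
ungapped_distance <- function(read, ref) {
  lr <- nchar(read); lf <- nchar(ref)
  d <- abs(lr - lf)
  if (d > 2) return(Inf)
  shorter <- if (lr <= lf) read else ref
  longer <- if (lr <= lf) ref else read
  ls <- nchar(shorter); ll <- nchar(longer)
  sc <- strsplit(shorter, "")[[1]]
  lc <- strsplit(longer, "")[[1]]
  best <- Inf
  for (off in 0:(ll - ls)) {
    mm <- sum(sc != lc[(1 + off):(off + ls)]) + (ll - ls)
    if (mm < best) best <- mm
  }
  best
}

#' Annotate reads as conserved miRNA isoforms
#'
#' Compares each read against every reference mature (ungapped; see
#' [read_mature_ref()]). A read is annotated when its best distance is at
#' most `max_mismatches`; ties across families record all tied families,
#' with the lexicographically smallest as primary and an `ambiguous`
#' flag.
#'
#' @param seqs character vector of (mapped, filtered) read sequences.
#' @param ref data.frame from [read_mature_ref()].
#' @param max_mismatches maximum allowed distance (default 2).
#' @return data.frame with one row per annotated read: `sequence`,
#'   `family`, `best_mismatches`, `families_all`, `ambiguous`.
#' @export
annotate_conserved <- function(seqs, ref, max_mismatches = 2L) {
  fail_if(is.null(ref) || nrow(ref) == 0, "empty mature reference")
  seqs <- unique(seqs)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    dists <- vapply(ref$sequence, function(rs)
      ungapped_distance(seqs[i], rs), numeric(1))
    best <- min(dists)
    if (!is.finite(best) || best > max_mismatches) next
    fams <- sort(unique(ref$family[dists == best]))
    out[[i]] <- data.frame(
      sequence = seqs[i], family = fams[1], best_mismatches = best,
      families_all = paste(fams, collapse = ";"),
      ambiguous = length(fams) > 1, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(sequence = character(0), family = character(0),
                      best_mismatches = numeric(0),
                      families_all = character(0), ambiguous = logical(0))
  }
  res
}

#' Count distinct isoforms per conserved miRNA family
#'
#' An isoform is a distinct mature sequence assigned to the family,
#' counted over all libraries jointly.
#'
#' @param annotations data.frame from [annotate_conserved()].
#' @return named integer vector, family -> isoform count.
#' @export
count_family_isoforms <- function(annotations) {
  if (is.null(annotations) || nrow(annotations) == 0)
    return(setNames(integer(0), character(0)))
  tab <- tapply(annotations$sequence, annotations$family,
                function(x) length(unique(x)))
  setNames(as.integer(tab), names(tab))
}

#' Candidate precursor windows around a mapped read
#'
#' Windows place the read wholly inside, trying both read-near-5'-end and
#' read-near-3'-end geometries at increasing flank sizes up to
#' `max_precursor` nt, truncated at contig edges. For minus-strand loci
#' the window sequence is the reverse complement of the genomic window
#' and the read offsets are given in that transcribed frame.
#'
#' @param locus one-row data.frame (`chrom`, `start`, `end`, `strand`).
#' @param genome named character vector / DNAStringSet of chromosomes.
#' @param max_precursor maximum window length (nt).
#' @param flank_step flank size increment (nt).
#' @param near_flank flank on the near side of the read (nt).
#' @return data.frame: `win_start`, `win_end` (genomic),
#'   `seq` (transcribed frame), `mature_start`, `mature_end` (within
#'   `seq`).
#' @export
excise_precursors <- function(locus, genome, max_precursor = 250L,
                              flank_step = 25L, near_flank = 15L) {
  seqs <- setNames(as.character(genome), names(genome))
  chrom_seq <- seqs[[locus$chrom]]
  fail_if(is.null(chrom_seq), "unknown chromosome: %s", locus$chrom)
  n <- nchar(chrom_seq)
  fail_if(locus$start < 1 || locus$end > n || locus$start > locus$end,
          "locus outside contig bounds")
  read_len <- locus$end - locus$start + 1L
  max_far <- max_precursor - read_len - near_flank
  fars <- seq(flank_step, max(flank_step, max_far), by = flank_step)
  wins <- list()
  for (f in fars) {
    # read near the 5' end of the (plus-frame) window: flank downstream
    wins[[length(wins) + 1]] <- c(max(1L, locus$start - near_flank),
                                  min(n, locus$end + f))
    # read near the 3' end: flank upstream
    wins[[length(wins) + 1]] <- c(max(1L, locus$start - f),
                                  min(n, locus$end + near_flank))
  }
  wm <- unique(do.call(rbind, wins))
  out <- vector("list", nrow(wm))
  for (i in seq_len(nrow(wm))) {
    ws <- wm[i, 1]; we <- wm[i, 2]
    s <- substr(chrom_seq, ws, we)
    if (locus$strand == "+") {
      ms <- locus$start - ws + 1L
    } else {
      s <- revcomp(s)
      ms <- we - locus$end + 1L
    }
    out[[i]] <- data.frame(win_start = ws, win_end = we, seq = s,
                           mature_start = ms,
                           mature_end = ms + read_len - 1L,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Fold a candidate precursor
#'
#' Maximum-weighted nested base pairing (GC = 3, AU = 2, GU = 1; minimum
#' hairpin loop 3 nt), computed by dynamic programming in compiled code.
#' The backend is pluggable: any function returning a dot-bracket string
#' for a sequence can be substituted via the `backend` argument of the
#' downstream steps.
#'
#' @param seq sequence (A/C/G/T/U), length <= 400.
#' @return list: `structure` (dot-bracket), `score`.
#' @export
fold_hairpin <- function(seq) {
  fail_if(nchar(seq) > 400, "fold_hairpin supports sequences up to 400 nt")
  .nussinov_fold(toupper(seq), min_loop = 3L)
}

# Partner vector from a dot-bracket string (0 = unpaired).
pairing_partners <- function(db) {
  chars <- strsplit(db, "")[[1]]
  partner <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  partner
}

longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Evaluate hairpin geometry around a mature read
#'
#' Pass criteria (defaults follow community plant-miRNA annotation
#' practice; all configurable): the mature lies entirely on one arm (no
#' base pairs within the mature, i.e. it does not straddle the terminal
#' loop); at least `min_paired_frac` of mature bases are paired; at most
#' `max_unpaired_run` consecutive unpaired mature bases; the paired
#' mature bases form a single dominant stem (partners monotone, on one
#' side, spanning at most the mature length plus `max_bulge_span`); and
#' the loop between mature and its partner region is at most `max_loop`
#' nt.
#'
#' @param fold dot-bracket string from [fold_hairpin()].
#' @param mature_start,mature_end mature position within the folded
#'   sequence (1-based inclusive).
#' @param min_paired_frac,max_unpaired_run,max_bulge_span,max_loop
#'   criteria thresholds.
#' @return list: `pass`, `reasons`, `paired_frac`, `unpaired_run`,
#'   `arm` ("5p"/"3p"), `loop_size`, `partner_range`.
#' @export
evaluate_hairpin <- function(fold, mature_start, mature_end,
                             min_paired_frac = 0.75,
                             max_unpaired_run = 4L,
                             max_bulge_span = 10L,
                             max_loop = 150L) {
  n <- nchar(fold)
  fail_if(mature_start < 1 || mature_end > n || mature_start > mature_end,
          "mature position outside precursor")
  partner <- pairing_partners(fold)
  idx <- mature_start:mature_end
  p <- partner[idx]
  paired <- p > 0
  reasons <- character(0)

  paired_frac <- mean(paired)
  if (paired_frac < min_paired_frac) {
    reasons <- c(reasons, "mature insufficiently paired")
  }
  run <- longest_run(!paired)
  if (run > max_unpaired_run) {
    reasons <- c(reasons, "long unpaired stretch in mature")
  }
  arm <- NA_character_
  loop_size <- NA_integer_
  prange <- c(NA_integer_, NA_integer_)
  if (any(paired)) {
    pp <- p[paired]
    if (any(pp >= mature_start & pp <= mature_end)) {
      reasons <- c(reasons, "mature in loop")
    } else {
      if (any(diff(pp) >= 0)) {
        reasons <- c(reasons, "mature partners not a single stem")
      }
      if (!(all(pp < mature_start) || all(pp > mature_end))) {
        reasons <- c(reasons, "mature pairs to both sides")
      }
      prange <- range(pp)
      span <- prange[2] - prange[1] + 1L
      if (span > length(idx) + max_bulge_span) {
        reasons <- c(reasons, "partner region too dispersed")
      }
      arm <- if (prange[1] > mature_end) "5p" else "3p"
      loop_size <- if (arm == "5p") prange[1] - mature_end - 1L else
        mature_start - prange[2] - 1L
      if (!is.na(loop_size) && loop_size > max_loop) {
        reasons <- c(reasons, "loop too large")
      }
    }
  } else {
    reasons <- c(reasons, "mature unpaired")
  }
  list(pass = length(reasons) == 0, reasons = reasons,
       paired_frac = paired_frac, unpaired_run = run, arm = arm,
       loop_size = loop_size, partner_range = prange)
}

#' Infer the miRNA-star of a mature within a folded precursor
#'
#' The star is the duplex partner of the mature on the opposite arm,
#' shifted to leave the canonical Dicer 2-nt 3' overhang on each duplex
#' strand: star interval = `[P(mature_end) + 2, P(mature_start) + 2]`,
#' where P is the pairing-partner map and unpaired mature ends are
#' interpolated from the nearest paired position. Undeclared when fewer
#' than half the mature bases are paired.
#'
#' @param seq the folded precursor sequence.
#' @param fold its dot-bracket structure.
#' @param mature_start,mature_end mature position within `seq`.
#' @return list (`start`, `end`, `sequence`) or NULL when undeclared.
#' @export
infer_star <- function(seq, fold, mature_start, mature_end) {
  n <- nchar(fold)
  partner <- pairing_partners(fold)
  idx <- mature_start:mature_end
  p <- partner[idx]
  if (mean(p > 0) < 0.5) return(NULL)
  interp <- function(pos) {
    if (partner[pos] > 0) return(partner[pos])
    paired_pos <- idx[p > 0]
    near <- paired_pos[which.min(abs(paired_pos - pos))]
    partner[near] - (pos - near)  # partners run antiparallel
  }
  s1 <- interp(mature_end) + 2L
  s2 <- interp(mature_start) + 2L
  s1 <- max(1L, min(n, s1)); s2 <- max(1L, min(n, s2))
  if (s1 > s2) return(NULL)
  list(start = s1, end = s2, sequence = substr(seq, s1, s2))
}

# Candidate star sequences allowing a +/-1 nt shift at either end.
star_variants <- function(seq, s1, s2) {
  n <- nchar(seq)
  out <- character(0)
  for (da in -1:1) for (db in -1:1) {
    a <- s1 + da; b <- s2 + db
    if (a >= 1 && b <= n && a < b) out <- c(out, substr(seq, a, b))
  }
  unique(out)
}

#' Classify novel miRNAs (and miRNA-stars) from mapped reads
#'
#' Each mapped, filtered, non-conserved sequence is tested at each of its
#' genomic loci: candidate precursor windows are excised, folded and
#' evaluated; for passing windows the star is inferred. Calls whose
#' inferred star matches a conserved mature are re-classified as the star
#' of that conserved miRNA; reciprocal novel calls (each the other's
#' star) keep the more abundant sequence as the novel mature and mark the
#' partner as its star. A novel miRNA is high-confidence iff its star
#' (with a 1-nt end-shift tolerance) is present among the filtered reads.
#'
#' @param hits data.frame from [map_exact()] for candidate sequences.
#' @param genome named character vector / DNAStringSet of chromosomes.
#' @param read_table `unique_read_table` of filtered reads (counts used
#'   for mature-vs-star arbitration and star observation).
#' @param conserved data.frame from [annotate_conserved()] (may be empty).
#' @param max_precursor,flank_step window geometry, see
#'   [excise_precursors()].
#' @param criteria named list overriding [evaluate_hairpin()] thresholds.
#' @return data.frame: `sequence`, `status` ("novel" or "star"),
#'   `star_of`, `star_seq`, `star_observed`, `high_confidence`, `chrom`,
#'   `start`, `end`, `strand`, `precursor_start`, `precursor_end`,
#'   `precursor_seq`, `fold`, `paired_frac`, `arm`.
#' @export
classify_novel <- function(hits, genome, read_table, conserved = NULL,
                           max_precursor = 250L, flank_step = 25L,
                           criteria = list()) {
  seqs <- setNames(as.character(genome), names(genome))
  reads <- read_table$sequence
  totals <- setNames(read_table$total, read_table$sequence)
  conserved_seqs <- if (is.null(conserved)) character(0) else
    conserved$sequence
  cand_seqs <- setdiff(unique(hits$sequence), conserved_seqs)
  calls <- list()
  for (sq in cand_seqs) {
    locs <- hits[hits$sequence == sq, , drop = FALSE]
    best <- NULL
    for (li in seq_len(nrow(locs))) {
      wins <- excise_precursors(locs[li, ], seqs,
                                max_precursor = max_precursor,
                                flank_step = flank_step)
      for (wi in seq_len(nrow(wins))) {
        w <- wins[wi, ]
        fold <- fold_hairpin(w$seq)
        ev <- do.call(evaluate_hairpin,
                      c(list(fold$structure, w$mature_start,
                             w$mature_end), criteria))
        if (!ev$pass) next
        st <- infer_star(w$seq, fold$structure, w$mature_start,
                         w$mature_end)
        if (is.null(st)) next
        score <- ev$paired_frac
        if (is.null(best) || score > best$score) {
          best <- list(score = score, locus = locs[li, ], win = w,
                       fold = fold$structure, ev = ev, star = st)
        }
      }
    }
    if (is.null(best)) next
    stv <- star_variants(best$win$seq, best$star$start, best$star$end)
    calls[[length(calls) + 1]] <- data.frame(
      sequence = sq, star_seq = best$star$sequence,
      star_variants = paste(stv, collapse = ";"),
      star_observed = any(stv %in% reads),
      chrom = best$locus$chrom, start = best$locus$start,
      end = best$locus$end, strand = best$locus$strand,
      precursor_start = best$win$win_start,
      precursor_end = best$win$win_end, precursor_seq = best$win$seq,
      fold = best$fold, paired_frac = best$ev$paired_frac,
      arm = best$ev$arm, stringsAsFactors = FALSE)
  }
  if (length(calls) == 0) {
    return(data.frame(sequence = character(0), status = character(0),
                      star_of = character(0), star_seq = character(0),
                      star_observed = logical(0),
                      high_confidence = logical(0)))
  }
  df <- do.call(rbind, calls)
  df$status <- "novel"
  df$star_of <- NA_character_

  variants_of <- strsplit(df$star_variants, ";", fixed = TRUE)

  # a call whose inferred star is a conserved mature is that miRNA's star
  if (length(conserved_seqs) > 0) {
    for (i in seq_len(nrow(df))) {
      hit <- intersect(variants_of[[i]], conserved_seqs)
      if (length(hit) > 0) {
        df$status[i] <- "star"
        df$star_of[i] <- hit[1]
      }
    }
  }
  # reciprocal pairs: the more abundant sequence is the mature
  abundance <- function(s) {
    t <- totals[s]
    if (is.na(t)) 0 else as.numeric(t)
  }
  for (i in which(df$status == "novel")) {
    if (df$status[i] != "novel") next
    for (j in which(df$status == "novel")) {
      if (j == i) next
      if (df$sequence[j] %in% variants_of[[i]]) {
        if (abundance(df$sequence[i]) >= abundance(df$sequence[j])) {
          df$status[j] <- "star"; df$star_of[j] <- df$sequence[i]
        } else {
          df$status[i] <- "star"; df$star_of[i] <- df$sequence[j]
        }
      }
    }
  }
  df$high_confidence <- df$status == "novel" & df$star_observed
  rownames(df) <- NULL
  df
}

#' 5'-nucleotide composition of a miRNA set
#'
#' The first 5'-end nucleotide of a small RNA marks its preferential
#' ARGONAUTE association, so the composition is a standard annotation
#' summary (reported separately for conserved and novel sets by the
#' pipeline).
#'
#' @param seqs character vector of mature sequences.
#' @return named numeric vector over A, U, C, G summing to 1.
#' @export
five_prime_composition <- function(seqs) {
  fail_if(length(seqs) == 0, "empty miRNA set")
  first <- chartr("T", "U", toupper(substr(seqs, 1, 1)))
  tab <- table(factor(first, levels = c("A", "U", "C", "G")))
  as.vector(tab / sum(tab)) -> v
  setNames(v, c("A", "U", "C", "G"))
}
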