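# Expression analysis: CPM normalization against per-library filtered
# totals, ln(CPM + 1) transform, correlation-matrix PCA, replicate
# hierarchical clustering, per-miRNA ANOVA across zygotic-embryo stages
# and t-test between megagametophyte stages (p < 0.05, no multiple
# testing correction), expression-profile k-means clustering, tissue
# presence Venn counts, and the high-expression (CPM >= 100) shortlist.

#' CPM-normalize a count matrix
#'
#' `cpm[i, j] = 1e6 * count[i, j] / total[j]`, where totals are the
#' complete per-library filtered read totals (so CPM over the full read
#' table sums to one million per library).
#'
#' @param counts numeric matrix, features x libraries.
#' @param totals named per-library totals (defaults to column sums).
#' @return CPM matrix with attribute `transform = "cpm"`.
#' @export
cpm_normalize <- function(counts, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  fail_if(any(totals <= 0), "zero library total")
  fail_if(length(totals) != ncol(counts),
          "totals must have one entry per library")
  cpm <- sweep(counts, 2, totals, "/") * 1e6
  attr(cpm, "transform") <- "cpm"
  cpm
}

#' ln(CPM + 1) transform
#'
#' Zero counts occur, so a pseudocount of 1 keeps zeros at 0 and
#' preserves ordering.
#'
#' @param cpm CPM matrix.
#' @return transformed matrix with attribute `transform = "ln_cpm"`.
#' @export
ln_transform <- function(cpm) {
  fail_if(any(cpm < 0), "negative CPM input")
  out <- log(cpm + 1)
  attr(out, "transform") <- "ln_cpm"
  out
}

#' PCA of libraries via the feature correlation matrix
#'
#' Principal components are computed on standardized features
#' (equivalently, eigen-decomposition of the feature correlation matrix);
#' zero-variance features are dropped. Component signs are fixed by
#' making the largest-magnitude loading positive.
#'
#' @param mat feature x library matrix (ln CPM).
#' @return list: `scores` (library x component), `var_frac`, `loadings`.
#' @export
pca_correlation <- function(mat) {
  fail_if(ncol(mat) < 2, "need at least 2 libraries")
  v <- apply(mat, 1, var)
  keep <- v > 0
  fail_if(!any(keep), "all features are constant")
  m <- t(mat[keep, , drop = FALSE])  # libraries x features
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  var_frac <- pc$sdev ^ 2 / sum(pc$sdev ^ 2)
  scores <- pc$x
  loadings <- pc$rotation
  for (k in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(scores = scores, var_frac = var_frac, loadings = loadings)
}

#' Replicate consistency by hierarchical clustering
#'
#' Average-linkage clustering of libraries on 1 - Pearson correlation
#' distances; reports, per replicate pair, whether the pair merges before
#' any cross-condition pair (cophenetic distance smaller than to any
#' other library).
#'
#' @param mat feature x library matrix (ln CPM).
#' @param design data.frame with `library` and `condition`.
#' @return list: `hclust`, `replicate_pairs` (condition, lib1, lib2,
#'   merged_first).
#' @export
replicate_hcl <- function(mat, design = NULL) {
  fail_if(ncol(mat) < 3, "need at least 3 libraries")
  d <- as.dist(1 - cor(mat))
  hc <- hclust(d, method = "average")
  pairs <- NULL
  if (!is.null(design)) {
    coph <- as.matrix(cophenetic(hc))
    conds <- split(design$library, design$condition)
    rows <- list()
    for (cn in names(conds)) {
      libs <- intersect(conds[[cn]], colnames(mat))
      if (length(libs) < 2) next
      cmb <- utils::combn(libs, 2)
      for (k in seq_len(ncol(cmb))) {
        a <- cmb[1, k]; b <- cmb[2, k]
        others <- setdiff(colnames(mat), libs)
        merged_first <- coph[a, b] < min(coph[a, others], coph[b, others])
        rows[[length(rows) + 1]] <- data.frame(
          condition = cn, lib1 = a, lib2 = b,
          merged_first = merged_first, stringsAsFactors = FALSE)
      }
    }
    pairs <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  list(hclust = hc, replicate_pairs = pairs)
}

# One-way fixed-effects ANOVA p-value for one feature, with the
# degenerate cases pinned: all values equal -> p = 1; zero within-group
# variance with differing means -> p = 0.
anova_p <- function(values, groups) {
  if (all(values == values[1])) return(c(statistic = 0, p = 1))
  fit <- tryCatch(oneway.test(values ~ groups, var.equal = TRUE),
                  error = function(e) NULL)
  if (is.null(fit) || is.na(fit$p.value)) {
    gm <- tapply(values, groups, mean)
    wv <- tapply(values, groups, var)
    if (all(wv < 1e-12, na.rm = TRUE) && var(gm) > 0)
      return(c(statistic = Inf, p = 0))
    return(c(statistic = 0, p = 1))
  }
  c(statistic = unname(fit$statistic), p = fit$p.value)
}

#' Per-miRNA one-way ANOVA across developmental stages
#'
#' A fixed-effects ANOVA per feature over the stage groups with at least
#' two replicates (single-replicate stages are excluded from the test
#' statistic and noted); a feature is differentially expressed iff
#' p < alpha, with no multiple-testing correction.
#'
#' @param mat feature x library matrix (ln CPM).
#' @param groups factor/character of group (stage) per library.
#' @param alpha significance level.
#' @return data.frame: `feature`, `statistic`, `p`, `de`; attribute
#'   `excluded_groups` lists groups dropped for having < 2 replicates.
#' @export
de_anova <- function(mat, groups, alpha = 0.05) {
  groups <- as.character(groups)
  fail_if(length(groups) != ncol(mat),
          "groups must have one entry per library")
  sizes <- table(groups)
  excluded <- names(sizes)[sizes < 2]
  if (length(excluded) > 0) {
    message("excluding groups with < 2 replicates: ",
            paste(excluded, collapse = ", "))
  }
  keep <- groups %in% names(sizes)[sizes >= 2]
  g <- factor(groups[keep])
  fail_if(nlevels(g) < 2, "need >= 2 groups with >= 2 replicates")
  m <- mat[, keep, drop = FALSE]
  res <- t(apply(m, 1, anova_p, groups = g))
  out <- data.frame(feature = rownames(mat), statistic = res[, 1],
                    p = res[, 2], de = res[, 2] < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded_groups") <- excluded
  out
}

#' Per-miRNA pooled-variance t-test between two conditions
#'
#' Two-sided pooled-variance t-test per feature (n = 2 per group makes
#' Welch degrees of freedom degenerate). Zero pooled variance with equal
#' means gives p = 1; with differing means, p = 0. Direction reports the
#' up-regulated group.
#'
#' @param mat feature x library matrix (ln CPM).
#' @param cols1,cols2 column names/indices of the two groups.
#' @param labels group labels for the `direction` column.
#' @param alpha significance level.
#' @return data.frame: `feature`, `statistic`, `p`, `de`, `direction`.
#' @export
de_ttest <- function(mat, cols1, cols2, labels = c("group1", "group2"),
                     alpha = 0.05) {
  x <- mat[, cols1, drop = FALSE]
  y <- mat[, cols2, drop = FALSE]
  fail_if(ncol(x) < 2 || ncol(y) < 2, "both groups need >= 2 replicates")
  n <- nrow(mat)
  stat <- p <- numeric(n)
  for (i in seq_len(n)) {
    xi <- x[i, ]; yi <- y[i, ]
    if (var(xi) + var(yi) < 1e-24) {
      if (abs(mean(xi) - mean(yi)) < 1e-12) {
        stat[i] <- 0; p[i] <- 1
      } else {
        stat[i] <- Inf * sign(mean(xi) - mean(yi)); p[i] <- 0
      }
    } else {
      tt <- t.test(xi, yi, var.equal = TRUE)
      stat[i] <- unname(tt$statistic); p[i] <- tt$p.value
    }
  }
  up <- ifelse(rowMeans(x) >= rowMeans(y), labels[1], labels[2])
  out <- data.frame(feature = rownames(mat), statistic = stat, p = p,
                    de = p < alpha, direction = up,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cluster differential-expression profiles
#'
#' Profiles (per-stage replicate means of ln CPM) are z-scored per
#' feature and clustered by k-means with 50 restarts under a fixed seed;
#' when `k = "auto"` the number of clusters maximizing the mean
#' silhouette width over k = 2..8 is chosen, with a near-zero silhouette
#' flagged as unstructured.
#'
#' @param profiles feature x stage matrix of mean ln CPM.
#' @param k integer number of clusters, or "auto".
#' @param seed RNG seed for k-means restarts.
#' @param k_range candidate k values in auto mode.
#' @return list: `cluster` (named vector), `centers` (cluster mean
#'   profiles, z-scored), `k`, `silhouette`, `unstructured`.
#' @export
cluster_profiles <- function(profiles, k = "auto", seed = 1L,
                             k_range = 2:8) {
  profiles <- as.matrix(profiles)
  sds <- apply(profiles, 1, sd)
  z <- (profiles - rowMeans(profiles)) / ifelse(sds > 0, sds, 1)
  n <- nrow(z)
  run_k <- function(kk) {
    fail_if(kk > n, "k (%d) exceeds the number of profiles (%d)", kk, n)
    with_seed(seed, kmeans(z, centers = kk, nstart = 50, iter.max = 100))
  }
  sil_width <- function(fit) {
    if (length(unique(fit$cluster)) < 2) return(NA_real_)
    mean(cluster::silhouette(fit$cluster, dist(z))[, "sil_width"])
  }
  if (identical(k, "auto")) {
    cand <- k_range[k_range <= n - 1]
    fail_if(length(cand) == 0, "too few profiles for auto k")
    fits <- lapply(cand, run_k)
    sils <- vapply(fits, sil_width, numeric(1))
    best <- which.max(sils)
    fit <- fits[[best]]
    sil <- sils[best]
    k <- cand[best]
  } else {
    fit <- run_k(k)
    sil <- sil_width(fit)
  }
  # z-profiles live on a fixed scale (unit variance per feature), so a
  # set of near-identical shapes shows up as negligible absolute spread
  # even when k-means finds a split in the residual noise
  spread <- mean(dist(z))
  list(cluster = setNames(fit$cluster, rownames(z)),
       centers = fit$centers, k = k, silhouette = sil,
       spread = spread,
       unstructured = is.na(sil) || sil < 0.25 || spread < 0.5)
}

#' Tissue presence overlap (Venn region counts)
#'
#' Presence of a miRNA in a tissue at a stage requires detection in every
#' replicate of that tissue/stage; miRNAs present only in tissues with a
#' single replicate are excluded from the totals. Emits the seven Venn
#' region counts for the tissue triple at the given stage.
#'
#' @param detected named list: library -> character vector of detected
#'   miRNA sequences.
#' @param design data.frame with `library`, `tissue`, `stage`,
#'   `n_replicates` implied by rows.
#' @param stage stage label (e.g. "4B").
#' @param tissues tissue triple.
#' @return named integer vector of the 7 Venn regions plus `total`.
#' @export
presence_venn <- function(detected, design, stage,
                          tissues = c("ZE", "MG", "SE")) {
  present <- list()
  single_rep <- character(0)
  for (ts in tissues) {
    libs <- design$library[design$tissue == ts & design$stage == stage]
    if (length(libs) == 0) {
      present[[ts]] <- character(0)
      next
    }
    sets <- detected[libs]
    present[[ts]] <- Reduce(intersect, sets)
    if (length(libs) < 2) single_rep <- c(single_rep, ts)
  }
  # miRNAs present only in single-replicate tissues are excluded
  multi <- setdiff(tissues, single_rep)
  backed <- unique(unlist(present[multi]))
  for (ts in single_rep) {
    present[[ts]] <- intersect(present[[ts]], backed)
  }
  a <- present[[tissues[1]]]; b <- present[[tissues[2]]]
  c_ <- present[[tissues[3]]]
  regions <- c(
    setNames(length(setdiff(setdiff(a, b), c_)),
             paste0(tissues[1], "_only")),
    setNames(length(setdiff(setdiff(b, a), c_)),
             paste0(tissues[2], "_only")),
    setNames(length(setdiff(setdiff(c_, a), b)),
             paste0(tissues[3], "_only")),
    setNames(length(setdiff(intersect(a, b), c_)),
             paste0(tissues[1], "_", tissues[2])),
    setNames(length(setdiff(intersect(a, c_), b)),
             paste0(tissues[1], "_", tissues[3])),
    setNames(length(setdiff(intersect(b, c_), a)),
             paste0(tissues[2], "_", tissues[3])),
    setNames(length(intersect(intersect(a, b), c_)),
             paste0(tissues[1], "_", tissues[2], "_", tissues[3])))
  c(regions, total = length(unique(c(a, b, c_))))
}

#' Shortlist highly expressed miRNAs
#'
#' A miRNA is shortlisted iff its replicate-mean CPM reaches `threshold`
#' in at least one in-scope tissue/stage condition (inclusive boundary:
#' CPM = 100.0 passes at the default threshold).
#'
#' @param cpm feature x library CPM matrix.
#' @param design data.frame with `library`, `tissue`, `stage`.
#' @param threshold CPM cutoff.
#' @param tissues,stages the scope (defaults: ZE or MG at 4B and 7).
#' @return character vector of shortlisted feature names.
#' @export
shortlist_high_expression <- function(cpm, design, threshold = 100,
                                      tissues = c("ZE", "MG"),
                                      stages = c("4B", "7")) {
  conds <- design[design$tissue %in% tissues & design$stage %in% stages, ]
  fail_if(nrow(conds) == 0, "no libraries in scope")
  hits <- rep(FALSE, nrow(cpm))
  for (cn in unique(conds$condition)) {
    libs <- conds$library[conds$condition == cn]
    mu <- rowMeans(cpm[, libs, drop = FALSE])
    hits <- hits | (mu >= threshold)
  }
  rownames(cpm)[hits]
}
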