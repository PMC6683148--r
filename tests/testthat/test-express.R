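test_that("CPM normalization is exact and conserves one million per
          library", {
  expect_equal(cpm_normalize(matrix(5), totals = 1e6)[1, 1], 5)
  expect_equal(cpm_normalize(matrix(0), totals = 10)[1, 1], 0)
  set.seed(41)
  counts <- matrix(rpois(300, 20), 50, 6)
  totals <- colSums(counts) + rpois(6, 1000)  # full-table totals
  cpm <- cpm_normalize(counts, totals)
  expect_equal(cpm, sweep(counts, 2, totals, "/") * 1e6,
               ignore_attr = TRUE)
  # over the complete table, CPM sums to 1e6
  full <- cpm_normalize(counts)
  expect_equal(unname(colSums(full)), rep(1e6, 6), tolerance = 1e-9)
  expect_error(cpm_normalize(counts, totals = c(totals[-6], 0)), "zero")
})

test_that("the ln transform is anchored at zero and monotone", {
  expect_equal(ln_transform(matrix(0))[1, 1], 0)
  expect_equal(ln_transform(matrix(exp(1) - 1))[1, 1], 1)
  set.seed(42)
  x <- matrix(runif(100, 0, 1000), 10)
  expect_equal(order(ln_transform(x)), order(x))
  expect_error(ln_transform(matrix(-1)), "negative")
})

test_that("correlation PCA matches the eigen-decomposition oracle", {
  # rank-1: two perfectly correlated features
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  p <- pca_correlation(m)
  expect_equal(p$var_frac[1], 1.0)
  # symmetric two-feature toy
  m2 <- rbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  expect_equal(pca_correlation(m2)$var_frac, c(0.5, 0.5))
  # random matrix vs an independent eigen route
  set.seed(43)
  m3 <- matrix(rnorm(240), 30, 8)
  rownames(m3) <- paste0("f", 1:30)
  p3 <- pca_correlation(m3)
  expect_equal(sum(p3$var_frac), 1)
  ev <- eigen(cor(t(m3)), symmetric = TRUE)$values
  expect_equal(p3$var_frac, (ev / sum(ev))[seq_along(p3$var_frac)],
               tolerance = 1e-10)
  # scores reproduce pairwise library distances
  z <- scale(t(m3))
  expect_equal(as.matrix(dist(p3$scores)), as.matrix(dist(z)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_correlation(matrix(1, 3, 4)), "constant")
})

test_that("replicate clustering merges duplicates first and agrees
          with the 3-leaf closed form", {
  set.seed(44)
  base <- matrix(rnorm(60), 20, 3)
  m <- cbind(L1 = base[, 1], L1b = base[, 1], L2 = base[, 2])
  d <- data.frame(library = c("L1", "L1b", "L2"),
                  condition = c("c1", "c1", "c2"))
  hc <- replicate_hcl(m, d)
  expect_true(all(hc$replicate_pairs$merged_first))
  # closed form: first merge is the most correlated pair
  m2 <- cbind(A = base[, 1], B = base[, 1] + 0.1 * base[, 2],
              C = base[, 3])
  r <- cor(m2)
  best <- which(r == max(r[upper.tri(r)]), arr.ind = TRUE)[1, ]
  hc2 <- replicate_hcl(m2)$hclust
  expect_setequal(colnames(m2)[abs(hc2$merge[1, ])],
                  colnames(m2)[best])
  expect_equal(hc2$height[1], 1 - max(r[upper.tri(r)]))
})

test_that("synthetic replicates cluster together almost always", {
  set.seed(45)
  ok <- 0
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    truthp <- matrix(rnorm(40 * 3, sd = 2), 40, 3)  # 3 conditions
    m <- truthp[, rep(1:3, each = 2)] + matrix(rnorm(240, sd = 0.3),
                                               40, 6)
    colnames(m) <- paste0(rep(c("A", "B", "C"), each = 2), "_", 1:2)
    d <- data.frame(library = colnames(m),
                    condition = rep(c("A", "B", "C"), each = 2))
    ok <- ok + all(replicate_hcl(m, d)$replicate_pairs$merged_first)
  }
  expect_gte(ok / n_rep, 0.95)
})

test_that("the per-feature ANOVA pins its degenerate cases", {
  m <- rbind(flat = rep(1, 8), sep = c(0, 0, 10, 10, 0, 0, 10, 10.01))
  g <- rep(c("a", "b", "c", "d"), each = 2)
  de <- de_anova(m, g)
  expect_equal(de$statistic[1], 0)
  expect_equal(de$p[1], 1)
  expect_false(de$de[1])
  expect_true(de$de[2])
  # single-replicate groups are excluded with a note
  m2 <- cbind(m, extra = c(1, 5))
  expect_message(de_anova(m2, c(g, "e")), "excluding")
})

test_that("the pooled t-test pins its degenerate cases and reports
          direction", {
  m <- rbind(flat = c(1, 1, 1, 1), up2 = c(1, 1, 9, 9.01),
             down2 = c(9, 9.01, 1, 1))
  de <- de_ttest(m, 1:2, 3:4, labels = c("MG4B", "MG7"))
  expect_equal(de$p[1], 1)
  expect_false(de$de[1])
  expect_true(all(de$de[2:3]))
  expect_equal(de$direction, c("MG4B", "MG7", "MG4B"))
})

test_that("profile clustering recovers planted groups and flags
          unstructured input", {
  prof <- rbind(matrix(rep(c(1, 0, 0, 0, 0), 10), 10, byrow = TRUE),
                matrix(rep(c(0, 0, 0, 0, 1), 10), 10, byrow = TRUE))
  rownames(prof) <- paste0("m", 1:20)
  prof <- prof + matrix(rnorm(100, sd = 1e-4), 20)
  cl <- cluster_profiles(prof, k = 2, seed = 9)
  expect_equal(length(unique(cl$cluster[1:10])), 1)
  expect_equal(length(unique(cl$cluster[11:20])), 1)
  expect_gt(cl$silhouette, 0.99)
  expect_false(cl$unstructured)
  # a single profile shape has no structure
  one <- matrix(rep(c(1, 2, 3, 4, 5), 12), 12, byrow = TRUE) +
    matrix(rnorm(60, sd = 0.01), 12)
  rownames(one) <- paste0("x", 1:12)
  cl1 <- cluster_profiles(one, k = "auto", seed = 9)
  expect_true(cl1$unstructured)
  expect_error(cluster_profiles(prof, k = 50), "exceeds")
})

test_that("presence requires every replicate and excludes
          single-replicate-only miRNAs", {
  design <- data.frame(
    library = c("ZE4B_R1", "ZE4B_R2", "MG4B_R1", "MG4B_R2", "SE4B_R1"),
    tissue = c("ZE", "ZE", "MG", "MG", "SE"),
    stage = "4B", stringsAsFactors = FALSE)
  detected <- list(
    ZE4B_R1 = c("a", "b", "c"), ZE4B_R2 = c("b", "c"),
    MG4B_R1 = c("b", "d"), MG4B_R2 = c("b"),
    SE4B_R1 = c("b", "c", "e"))
  v <- presence_venn(detected, design, "4B")
  # "a" only in one ZE replicate: absent; "e" only in single-rep SE:
  # excluded from totals
  expect_equal(unname(v["ZE_MG_SE"]), 1)  # "b"
  expect_equal(unname(v["ZE_SE"]), 1)     # "c"
  expect_equal(unname(v["total"]), 2)
  expect_equal(sum(v[setdiff(names(v), "total")]), unname(v["total"]))
})

test_that("venn regions equal brute-force set algebra on random
          presence tables", {
  set.seed(46)
  design <- data.frame(
    library = c("ZE7_R1", "ZE7_R2", "MG7_R1", "MG7_R2", "SE7_R1"),
    tissue = c("ZE", "ZE", "MG", "MG", "SE"),
    stage = "7", stringsAsFactors = FALSE)
  universe <- paste0("mir", 1:40)
  for (rep_i in 1:20) {
    detected <- lapply(setNames(design$library, design$library),
                       function(x) sample(universe, sample(5:30, 1)))
    v <- presence_venn(detected, design, "7")
    ze <- intersect(detected$ZE7_R1, detected$ZE7_R2)
    mg <- intersect(detected$MG7_R1, detected$MG7_R2)
    se <- intersect(detected$SE7_R1, union(ze, mg))
    expect_equal(unname(v["ZE_only"]),
                 length(setdiff(setdiff(ze, mg), se)))
    expect_equal(unname(v["MG_SE"]),
                 length(setdiff(intersect(mg, se), ze)))
    expect_equal(unname(v["total"]), length(unique(c(ze, mg, se))))
  }
})

test_that("the CPM-100 shortlist boundary is inclusive", {
  design <- data.frame(
    library = c("ZE4B_R1", "ZE4B_R2", "MG7_R1", "MG7_R2"),
    tissue = c("ZE", "ZE", "MG", "MG"),
    stage = c("4B", "4B", "7", "7"),
    condition = c("ZE4B", "ZE4B", "MG7", "MG7"),
    stringsAsFactors = FALSE)
  cpm <- rbind(at_boundary = c(100, 100, 0, 0),
               just_below = c(99.9, 99.9, 99.9, 99.9),
               in_mg = c(0, 0, 150, 150))
  colnames(cpm) <- design$library
  sl <- shortlist_high_expression(cpm, design)
  expect_setequal(sl, c("at_boundary", "in_mg"))
  # replicate mean is what counts
  cpm2 <- rbind(mean_ok = c(90, 110, 0, 0))
  colnames(cpm2) <- design$library
  expect_equal(shortlist_high_expression(cpm2, design), "mean_ok")
  # brute-force agreement on random matrices
  set.seed(47)
  r <- matrix(runif(200, 0, 200), 50, 4,
              dimnames = list(paste0("m", 1:50), design$library))
  sl2 <- shortlist_high_expression(r, design)
  brute <- rownames(r)[rowMeans(r[, 1:2]) >= 100 |
                         rowMeans(r[, 3:4]) >= 100]
  expect_setequal(sl2, brute)
})

test_that("DE miRNA count is monotone in alpha", {
  set.seed(48)
  m <- matrix(rnorm(800), 100, 8)
  rownames(m) <- paste0("m", 1:100)
  g <- rep(c("a", "b", "c", "d"), each = 2)
  counts <- vapply(c(0.01, 0.05, 0.2, 0.5),
                   function(a) sum(de_anova(m, g, alpha = a)$de),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})
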