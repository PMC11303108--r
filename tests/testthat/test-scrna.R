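make_cm <- function(counts, groups = NULL) {
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("c%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("g%03d", seq_len(ncol(counts)))
  if (is.null(groups)) groups <- rep("OIR", nrow(counts))
  cell_matrix(counts, data.frame(cell_id = rownames(counts), group = groups,
                                 timepoint = "P14", stringsAsFactors = FALSE))
}

test_that("normalization scales each cell to 10,000 and drops empty cells", {
  m <- rbind(c(10, 0, 90), c(0, 0, 0), c(5, 5, 0))
  cm <- make_cm(m)
  expect_warning(nm <- normalize_counts(cm), "zero total")
  expect_equal(nrow(nm$mat), 2L)
  expect_equal(unname(as.vector(nm$mat[1, ])), log1p(c(1000, 0, 9000)))
  # pre-log row sums are exactly 1e4 for random matrices
  set.seed(31)
  m2 <- matrix(rpois(200 * 50, 2), 200, 50)
  m2[1, ] <- m2[1, ] + 1  # no all-zero rows wanted here
  nm2 <- normalize_counts(make_cm(m2))
  expect_equal(unname(Matrix::rowSums(expm1(nm2$mat))), rep(1e4, nrow(nm2$mat)),
               tolerance = 1e-8)
})

test_that("marker scoring labels forced cells and leaves ties unassigned", {
  m <- rbind(c(10, 10, 0, 0),   # pure rod
             c(0, 0, 10, 10),   # pure bipolar
             c(5, 5, 5, 5))     # tie
  colnames(m) <- c("r1", "r2", "b1", "b2")
  nm <- normalize_counts(make_cm(m))
  lab <- classify_cells(nm, list(rod = c("r1", "r2"), bipolar = c("b1", "b2")))
  expect_equal(unname(lab), c("rod", "bipolar", "unassigned"))
  expect_error(classify_cells(nm, list(rod = c("absent1", "absent2"))),
               "no marker genes")
})

test_that("marker classification recovers planted types with >= 95% accuracy", {
  b <- simulate_bundle(small_config(seed = 7))
  nm <- normalize_counts(b$cells)
  lab <- classify_cells(nm, b$truth$marker_map)
  truth <- b$truth$cell_types[names(lab)]
  acc <- mean(lab == truth)
  expect_gte(acc, 0.95)
})

test_that("TF split partitions the subset at the count threshold", {
  m <- matrix(0, 4, 2, dimnames = list(sprintf("c%d", 1:4), c("tf", "g2")))
  m[, "tf"] <- c(0, 1, 3, 0)
  m[, "g2"] <- 1
  cm <- make_cm(m)
  cfg <- deg_config(tf_gene_id = "tf")
  sp <- split_by_tf(cm, rownames(m), cfg)
  expect_setequal(sp$positive, c("c2", "c3"))
  expect_setequal(sp$negative, c("c1", "c4"))
  expect_error(split_by_tf(cm, rownames(m),
                           deg_config(tf_gene_id = "tf", positive_threshold = 4)),
               "no TF-positive")
  # partition property over random inputs
  set.seed(32)
  for (i in 1:5) {
    mm <- matrix(rpois(60 * 3, 1), 60, 3)
    mm[, 1] <- rbinom(60, 3, 0.5)
    if (!any(mm[, 1] >= 1) || all(mm[, 1] >= 1)) next
    cmr <- make_cm(mm)
    cfg2 <- deg_config(tf_gene_id = colnames(cmr$counts)[1])
    spr <- split_by_tf(cmr, rownames(cmr$counts), cfg2)
    expect_setequal(c(spr$positive, spr$negative), rownames(cmr$counts))
    expect_length(intersect(spr$positive, spr$negative), 0)
  }
})

test_that("constant identical groups give p = 1 and zero fold change", {
  m <- matrix(5, 8, 2, dimnames = list(sprintf("c%d", 1:8), c("g1", "g2")))
  nm <- normalize_counts(make_cm(m))
  dt <- diff_expr(nm, sprintf("c%d", 1:4), sprintf("c%d", 5:8), deg_config())
  expect_equal(dt$p_value, c(1, 1))
  expect_equal(dt$log2_fold_change, c(0, 0))
  expect_equal(dt$direction, c("none", "none"))
})

test_that("4-vs-4 separated groups reproduce the exact enumeration p = 2/70", {
  rs <- rank_sum_matrix(matrix(c(1, 2, 3, 4), ncol = 1),
                        matrix(c(5, 6, 7, 8), ncol = 1))
  expect_equal(rs$p_value, 2 / 70)
  # and the brute-force enumeration over all 70 labelings agrees
  vals <- 1:8
  obs_w <- sum(rank(vals)[1:4])
  e <- 4 * 9 / 2
  combs <- utils::combn(8, 4)
  wperm <- apply(combs, 2, function(ix) sum(rank(vals)[ix]))
  expect_equal(rs$p_value, mean(abs(wperm - e) >= abs(obs_w - e)))
})

test_that("the exact small-group path matches a permutation oracle under ties", {
  set.seed(33)
  for (i in 1:10) {
    a <- rpois(5, 1); b <- rpois(6, 2)
    rs <- rank_sum_matrix(matrix(a, ncol = 1), matrix(b, ncol = 1))
    vals <- c(a, b); n <- length(vals); nA <- length(a)
    r <- rank(vals)
    obs <- sum(r[seq_len(nA)]); e <- nA * (n + 1) / 2
    wperm <- apply(utils::combn(n, nA), 2, function(ix) sum(r[ix]))
    expect_equal(rs$p_value, mean(abs(wperm - e) >= abs(obs - e) - 1e-9))
  }
})

test_that("the large-sample path agrees with wilcox.test on tie-free data", {
  set.seed(34)
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(25, 0.5)
    rs <- rank_sum_matrix(matrix(a, ncol = 1), matrix(b, ncol = 1))
    ref <- stats::wilcox.test(a, b, correct = FALSE, exact = FALSE)
    expect_equal(rs$p_value, unname(ref$p.value), tolerance = 1e-10)
    expect_equal(rs$U, unname(ref$statistic))
  }
})

test_that("diff_expr is label-symmetric: swapping groups flips the fold change", {
  set.seed(35)
  m <- matrix(rpois(40 * 10, 2), 40, 10)
  m[, 1] <- m[, 1] + rep(c(3L, 0L), each = 20)
  nm <- normalize_counts(make_cm(m))
  ga <- rownames(nm$mat)[1:20]; gb <- rownames(nm$mat)[21:40]
  d1 <- diff_expr(nm, ga, gb, deg_config())
  d2 <- diff_expr(nm, gb, ga, deg_config())
  expect_equal(d1$log2_fold_change, -d2$log2_fold_change)
  expect_equal(d1$p_value, d2$p_value, tolerance = 1e-12)
  expect_error(diff_expr(nm, ga, c(gb, ga[1]), deg_config()), "overlap")
})

test_that("BH q-values match an independent step-up oracle and rejections are a
           p-sorted prefix", {
  set.seed(36)
  for (i in 1:10) {
    p <- c(runif(80), runif(20)^3)
    expect_equal(stats::p.adjust(p, method = "BH"), oracle_bh(p))
  }
  m <- matrix(rpois(30 * 50, 2), 30, 50)
  m[, 1:5] <- m[, 1:5] + rep(c(6L, 0L), each = 15)
  nm <- normalize_counts(make_cm(m))
  dt <- diff_expr(nm, rownames(nm$mat)[1:15], rownames(nm$mat)[16:30],
                  deg_config())
  expect_equal(dt$q_value, oracle_bh(dt$p_value))
  rej <- dt$q_value < 0.05
  if (any(rej)) expect_lte(max(dt$p_value[rej]), min(dt$p_value[!rej]))
})

test_that("expressed_genes applies the detection-fraction rule exactly", {
  m <- matrix(0, 100, 3, dimnames = list(sprintf("c%03d", 1:100),
                                         c("always", "rare", "never")))
  m[, "always"] <- 1
  m[1, "rare"] <- 1  # exactly 1% of cells
  cm <- make_cm(m)
  expect_setequal(expressed_genes(cm, rownames(m), deg_config()),
                  c("always", "rare"))
  # brute-force fraction oracle on random fixtures
  set.seed(37)
  mm <- matrix(rbinom(50 * 30, 1, 0.05), 50, 30)
  cmr <- make_cm(mm)
  frac <- colMeans(mm > 0)
  expect_setequal(expressed_genes(cmr, rownames(cmr$counts), deg_config()),
                  colnames(cmr$counts)[frac >= 0.01])
})

test_that("panel summaries give group means and two-point rows z-score to +/-1", {
  # equal per-cell libraries so normalization preserves the planted pattern
  m <- matrix(0, 4, 3, dimnames = list(sprintf("c%d", 1:4),
                                       c("gA", "gB", "gC")))
  m[, "gA"] <- c(2, 2, 8, 8)
  m[, "gB"] <- c(8, 8, 2, 2)
  m[, "gC"] <- 5
  cm <- make_cm(m, groups = rep(c("normal", "OIR"), each = 2))
  nm <- normalize_counts(cm)
  labels <- stats::setNames(rep("rod", 4), rownames(m))
  expect_warning(
    ps <- summarize_panel(nm, labels, c("gA", "gB", "gC", "missing")),
    "missing")
  expect_equal(ps$missing_genes, "missing")
  # means equal brute-force group means of the normalized matrix
  for (cc in c("normal_P14", "OIR_P14")) {
    cells <- nm$cell_meta$cell_id[paste(nm$cell_meta$group, "P14", sep = "_") == cc]
    expect_equal(unname(ps$means[, cc]),
                 unname(Matrix::colMeans(nm$mat[cells, c("gA", "gB", "gC")])))
  }
  # two distinct condition means z-score to -1, +1 (population sd)
  expect_equal(unname(ps$zscores["gA", ]), c(-1, 1))
  expect_equal(unname(ps$zscores["gB", ]), c(1, -1))
  expect_equal(unname(ps$zscores["gC", ]), c(0, 0))
})

test_that("a condition without focal cells yields NA summary entries", {
  m <- matrix(1:8, 4, 2, dimnames = list(sprintf("c%d", 1:4), c("gA", "gB")))
  cm <- make_cm(m, groups = rep(c("normal", "OIR"), each = 2))
  nm <- normalize_counts(cm)
  labels <- stats::setNames(c("rod", "rod", "bipolar", "bipolar"), rownames(m))
  ps <- summarize_panel(nm, labels, c("gA", "gB"))
  expect_true(all(is.na(ps$means[, "OIR_P14"])))  # no OIR rods
})
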