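# Small synthetic count matrices are built in-line; none of these tests need
# real scRNA-seq data.

make_counts <- function(n_cells = 20, n_genes = 30, seed = 1, lambda = 8) {
  set.seed(seed)
  expression_matrix(matrix(rpois(n_cells * n_genes, lambda), n_cells, n_genes))
}

test_that("qc filter applies the cell-then-gene thresholds", {
  # cell A expresses 1001 genes, cells B and C only 10
  v <- matrix(0, 3, 1100)
  v[1, 1:1001] <- 10
  v[2, 1:10] <- 10
  v[3, 5:14] <- 10
  x <- expression_matrix(v)
  f <- qc_filter(x)
  expect_equal(nrow(f$values), 1L)
  expect_equal(f$cell_ids, "cell1")

  # boundary: count 6 (> 5) in exactly 10% of retained cells is kept
  v2 <- matrix(50, 10, 1200)  # all cells pass the expressed-gene filter
  v2[, 1] <- c(6, rep(0, 9))    # gene 1: count 6 in exactly 1 of 10 cells
  v2[, 2] <- c(5, rep(0, 9))    # gene 2: count 5 never exceeds the threshold
  f2 <- qc_filter(expression_matrix(v2))
  expect_true("gene1" %in% f2$gene_names)
  expect_false("gene2" %in% f2$gene_names)

  expect_error(qc_filter(expression_matrix(matrix(0, 3, 5))), "cells")
})

test_that("qc filter is idempotent", {
  set.seed(2)
  v <- matrix(rpois(50 * 1500, 8), 50, 1500)
  v[1:5, ] <- 0  # some empty cells
  x <- expression_matrix(v)
  once <- qc_filter(x)
  twice <- qc_filter(once)
  expect_identical(once$values, twice$values)
})

test_that("log normalisation is log2(x + 1) with a layer guard", {
  x <- expression_matrix(matrix(c(0, 1, 3, 7), 2, 2))
  ln <- log_normalize(x)
  expect_equal(as.vector(ln$values), c(0, 1, 2, 3))
  expect_equal(ln$layer, "lognorm")
  expect_error(log_normalize(ln), "counts")
  # monotone
  x2 <- make_counts(seed = 3)
  l2 <- log_normalize(x2)
  ord <- order(x2$values[1, ])
  expect_true(all(diff(l2$values[1, ord]) >= 0))
  # library-size scaling preserves shape
  l3 <- log_normalize(x2, library_size_scale = TRUE)
  expect_equal(dim(l3$values), dim(x2$values))
})

test_that("fano and cv2 scores match hand computations and two-pass oracles", {
  x <- expression_matrix(matrix(c(0, 2,    # gene 1: var 2, mean 1
                                  5, 5),   # gene 2: constant
                                2, 2))
  ff <- fano_factor(x)
  expect_equal(ff$score, c(2, 0))
  cv <- cv2_index(x)
  expect_equal(cv$score, c(2, 0))
  # all-zero gene scores 0 by convention
  x0 <- expression_matrix(cbind(c(0, 0), c(1, 3)))
  expect_equal(fano_factor(x0)$score[1], 0)

  # scale invariance of cv2, scale covariance of fano
  set.seed(4)
  v <- matrix(rexp(200), 10, 20)
  s1 <- cv2_index(expression_matrix(v))$score
  s2 <- cv2_index(expression_matrix(v * 10))$score
  expect_equal(s1, s2, tolerance = 1e-12)

  # agreement with direct two-pass mean/variance oracles
  mu <- colMeans(v)
  va <- colSums((sweep(v, 2, mu))^2) / (nrow(v) - 1)
  expect_equal(fano_factor(expression_matrix(v))$score, va / mu,
               tolerance = 1e-10)
  expect_equal(cv2_index(expression_matrix(v))$score, va / mu^2,
               tolerance = 1e-10)
})

test_that("binned-dispersion HVG ranks an inflated-variance spike-in first", {
  set.seed(5)
  n <- 40
  v <- matrix(rnorm(n * 60, mean = 5, sd = 1), n, 60)
  v[, 7] <- 5 + rnorm(n, sd = 6)  # same mean, inflated variance
  x <- expression_matrix(pmax(v, 0), layer = "lognorm")
  tab <- hvg_dispersion(x, n_bins = 5, n_top = 10)
  expect_equal(tab$gene[tab$rank == 1], "gene7")
  expect_equal(sum(tab$selected), 10L)
  # degenerate input: identical genes all get z-score 0
  xid <- expression_matrix(matrix(rep(c(1, 2, 3, 4), 8), 4, 8),
                           layer = "lognorm")
  tid <- hvg_dispersion(xid, n_bins = 2, n_top = 3)
  expect_true(all(tid$score == 0))
  expect_equal(sum(tid$selected), 3L)
})

test_that("select_genes returns the requested number of top genes", {
  x <- log_normalize(make_counts(seed = 6))
  g <- select_genes(x, method = "fano", n_top = 5)
  expect_length(g, 5L)
  expect_true(all(g %in% x$gene_names))
  expect_length(select_genes(x, method = "hvg", n_top = 8, n_bins = 5), 8L)
})

test_that("augmentation reaches the cell:gene ratio and preserves real cells", {
  gm <- make_gaussian_mixture(n_samples = 30, n_features = 40, seed = 7)
  fit <- lsh_gan(gm$values, k = 3, epochs = 50, seed = 1)
  x <- expression_matrix(gm$values, labels = gm$labels, layer = "lognorm")
  aug <- augment_to_ratio(x, fit, ratio = 1.5, seed = 2)
  expect_equal(nrow(aug$values), 60L)  # ceil(1.5 * 40)
  expect_gte(nrow(aug$values) / ncol(aug$values), 1.5)
  expect_identical(aug$values[1:30, ], x$values)
  expect_equal(sum(startsWith(aug$cell_ids, "gen_")), 30L)
  expect_true(all(is.na(aug$labels[31:60])))
  # already above target: warning, unchanged
  expect_warning(out <- augment_to_ratio(x, fit, ratio = 0.5), "nothing")
  expect_identical(out$values, x$values)
})

test_that("clustering scores are exact for perfect labels and near zero for noise", {
  gm <- make_gaussian_mixture(n_samples = 60, n_features = 30, seed = 8)
  x <- expression_matrix(gm$values, layer = "lognorm")
  sc <- cluster_and_score(x, seq_len(30), 2, gm$labels, seed = 1)
  expect_equal(sc$ari, 1)
  expect_equal(sc$nmi, 1)

  # ARI/NMI invariant under label permutation of the prediction
  flip <- 3 - sc$cluster
  expect_equal(mclust::adjustedRandIndex(flip, gm$labels), sc$ari)
  expect_equal(nmi_score(flip, gm$labels), sc$nmi)

  # random labels are chance-corrected to ~0
  set.seed(9)
  for (s in 1:5) {
    rand <- sample(1:2, 500, replace = TRUE)
    truth <- sample(1:2, 500, replace = TRUE)
    expect_lt(abs(mclust::adjustedRandIndex(rand, truth)), 0.1)
  }
  expect_error(cluster_and_score(x, c("nope"), 2, gm$labels), "unknown gene")
})

test_that("top Fano genes from the separable mixture support near-perfect clustering", {
  gm <- make_gaussian_mixture(n_samples = 80, n_features = 100, seed = 10)
  x <- expression_matrix(gm$values, layer = "lognorm")
  genes <- select_genes(x, method = "fano", n_top = 50)
  sc <- cluster_and_score(x, genes, 2, gm$labels, seed = 3)
  expect_gte(sc$ari, 0.95)
  sc_sp <- cluster_and_score(x, genes, 2, gm$labels, method = "spectral",
                             seed = 3)
  expect_gte(sc_sp$ari, 0.95)
})

test_that("expression matrices round-trip through CSV and MTX", {
  x <- log_normalize(make_counts(6, 5, seed = 11))
  x$labels <- rep(c("a", "b"), 3)
  csv <- tempfile(fileext = ".csv")
  write_expression_csv(x, csv)
  back <- read_expression_csv(csv, layer = "lognorm")
  expect_equal(back$values, x$values, tolerance = 1e-12)
  expect_equal(back$labels, x$labels)

  stem <- tempfile()
  write_expression_mtx(x, stem)
  back2 <- read_expression_mtx(stem, layer = "lognorm")
  expect_equal(back2$values, x$values, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back2$gene_names, x$gene_names)
  expect_equal(back2$labels, x$labels)
})
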