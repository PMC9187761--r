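# Evaluation of generated samples: per-feature Wasserstein distance,
# real-vs-generated classifier AUC, and the (k, t, epoch) selection and
# benchmark-grid experiments.

# Order-1 empirical Wasserstein distance between two 1-D samples of possibly
# different sizes: the integral of |F_a^{-1}(u) - F_b^{-1}(u)| over u in
# (0, 1), evaluated exactly on the merged quantile grid.
w1_1d <- function(a, b) {
  a <- sort(a); b <- sort(b)
  na <- length(a); nb <- length(b)
  u <- sort(unique(c(seq_len(na) / na, seq_len(nb) / nb)))
  lo <- c(0, u[-length(u)])
  mid <- (lo + u) / 2
  sum((u - lo) * abs(a[ceiling(mid * na)] - b[ceiling(mid * nb)]))
}

#' Wasserstein distance between two sample sets
#'
#' The default (\code{method = "feature"}) is the mean over features of the
#' 1-D empirical order-1 Wasserstein distance between the two samples'
#' feature marginals -- a cheap, deterministic pseudometric on sample sets.
#' \code{method = "sliced"} instead averages the 1-D distance over
#' \code{n_proj} random unit projections (seeded), for sensitivity analysis.
#'
#' @param A,B Numeric matrices with the same number of columns.
#' @param method \code{"feature"} (per-feature marginals, default) or
#'   \code{"sliced"} (random projections).
#' @param n_proj Number of projections for the sliced variant.
#' @param seed Seed for the sliced projections.
#' @return A single non-negative number.
#' @examples
#' wasserstein_metric(matrix(c(0, 1)), matrix(c(1, 2)))  # 1
#' @export
wasserstein_metric <- function(A, B, method = c("feature", "sliced"),
                               n_proj = 50, seed = 1L) {
  method <- match.arg(method)
  if (!is.matrix(A)) A <- as.matrix(A)
  if (!is.matrix(B)) B <- as.matrix(B)
  if (ncol(A) != ncol(B))
    stop(sprintf("feature mismatch: %d vs %d columns", ncol(A), ncol(B)),
         call. = FALSE)
  if (nrow(A) < 1L || nrow(B) < 1L)
    stop("both sample sets must be non-empty", call. = FALSE)
  if (method == "feature") {
    mean(vapply(seq_len(ncol(A)), function(j) w1_1d(A[, j], B[, j]), 0))
  } else {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    P <- matrix(stats::rnorm(ncol(A) * n_proj), ncol(A), n_proj)
    P <- sweep(P, 2L, sqrt(colSums(P^2)), "/")
    pa <- A %*% P
    pb <- B %*% P
    mean(vapply(seq_len(n_proj), function(j) w1_1d(pa[, j], pb[, j]), 0))
  }
}

# Stratified fold assignment: shuffle within class, deal round-robin.
stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Real-versus-generated classifier AUC
#'
#' How easily a random forest tells generated samples from real ones: real
#' rows are labelled 1, generated rows 0, and the stratified k-fold
#' cross-validated area under the ROC curve is returned. An AUC near 0.5
#' means the classifier is at chance, i.e. the generated samples are
#' statistically indistinguishable from real ones.
#'
#' @param real,generated Numeric matrices with equal feature dimension.
#' @param folds Number of cross-validation folds (default 5).
#' @param ntree Trees in the random forest (default 100).
#' @param seed Integer seed (folds and forest).
#' @return A list with \code{mean}, \code{sd} and the per-fold \code{auc}.
#' @export
discriminability_auc <- function(real, generated, folds = 5, ntree = 100,
                                 seed = 1L) {
  if (!is.matrix(real)) real <- as.matrix(real)
  if (!is.matrix(generated)) generated <- as.matrix(generated)
  if (ncol(real) != ncol(generated))
    stop("feature mismatch between real and generated", call. = FALSE)
  folds <- check_count(folds, "folds", min = 2L)
  if (nrow(real) < folds || nrow(generated) < folds)
    stop(sprintf("need at least %d samples per class for %d-fold CV",
                 folds, folds), call. = FALSE)
  X <- rbind(real, generated)
  y <- factor(rep(c(1L, 0L), c(nrow(real), nrow(generated))), levels = c(0L, 1L))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  fold_of <- stratified_folds(y, folds)
  aucs <- vapply(seq_len(folds), function(f) {
    test <- fold_of == f
    fit <- randomForest::randomForest(X[!test, , drop = FALSE], y[!test],
                                      ntree = ntree)
    prob <- stats::predict(fit, X[test, , drop = FALSE], type = "prob")[, "1"]
    as.numeric(pROC::auc(pROC::roc(response = y[test], predictor = prob,
                                   levels = c("0", "1"), direction = "<",
                                   quiet = TRUE)))
  }, 0)
  list(mean = mean(aucs), sd = stats::sd(aucs), auc = aucs)
}

#' Full quality report for a generated sample set
#'
#' @inheritParams discriminability_auc
#' @return A list of class \code{"eval_report"}: Wasserstein distance,
#'   mean/sd AUC, and the sample sizes.
#' @export
eval_report <- function(real, generated, folds = 5, ntree = 100, seed = 1L) {
  auc <- discriminability_auc(real, generated, folds = folds, ntree = ntree,
                              seed = seed)
  structure(list(wasserstein = wasserstein_metric(real, generated),
                 auc_mean = auc$mean, auc_sd = auc$sd,
                 n_real = nrow(real), n_generated = nrow(generated),
                 folds = folds, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("real vs generated: %d vs %d samples\n", x$n_real, x$n_generated))
  cat(sprintf("  Wasserstein distance: %.4f\n", x$wasserstein))
  cat(sprintf("  %d-fold RF AUC: %.3f +/- %.3f\n", x$folds, x$auc_mean, x$auc_sd))
  invisible(x)
}

#' Select LSH sampling parameters and training epoch by Wasserstein distance
#'
#' Trains one model per (k, t) cell of the grid, tracks the Wasserstein
#' distance to a held-out split at every checkpoint of a single training run,
#' and returns the (k, t, epoch) triple attaining the grid minimum.
#'
#' @param X Data matrix (samples x features).
#' @param k_grid,t_grid Candidate values (paper grid: k in 5/10/15/20,
#'   t in 1/2).
#' @param epochs Training epochs per model.
#' @param holdout_frac Held-out fraction for evaluation (default 0.2).
#' @param checkpoints Epochs at which the distance is measured (default ~10
#'   evenly spaced points).
#' @param seed Integer seed (split and training).
#' @param ... Passed to \code{\link{lsh_gan}}.
#' @return A list of class \code{"param_selection"}: \code{k_star},
#'   \code{t_star}, \code{e_opt}, the full \code{grid} data frame, and the
#'   held-out indices.
#' @export
select_sampling_params <- function(X, k_grid = c(5, 10, 15, 20),
                                   t_grid = c(1, 2), epochs = 2000,
                                   holdout_frac = 0.2, checkpoints = NULL,
                                   seed = 1L, ...) {
  if (!is.matrix(X)) X <- as.matrix(X)
  stopifnot(length(k_grid) >= 1L, length(t_grid) >= 1L)
  old <- local_seed(derive_seed(seed, 11L))
  test_idx <- sample.int(nrow(X), max(1L, round(holdout_frac * nrow(X))))
  restore_seed(old)
  train <- X[-test_idx, , drop = FALSE]
  test <- X[test_idx, , drop = FALSE]
  if (is.null(checkpoints)) {
    by <- max(1L, epochs %/% 10L)
    checkpoints <- unique(c(seq(by, epochs, by = by), epochs))
  }
  rows <- list()
  for (tt in t_grid) for (kk in k_grid) {
    fit <- lsh_gan(train, k = kk, t = tt, epochs = epochs, holdout = test,
                   checkpoints = checkpoints, seed = seed, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      k = kk, t = tt, epoch = fit$history$epoch,
      wasserstein = fit$history$wasserstein)
  }
  grid <- do.call(rbind, rows)
  best <- grid[which.min(grid$wasserstein), ]
  structure(list(k_star = best$k, t_star = best$t, e_opt = best$epoch,
                 wasserstein_min = best$wasserstein, grid = grid,
                 test_idx = test_idx),
            class = "param_selection")
}

#' @export
print.param_selection <- function(x, ...) {
  cat(sprintf("selected k = %d, t = %d, epoch = %d (Wasserstein %.4f) over %d grid cells\n",
              x$k_star, x$t_star, x$e_opt, x$wasserstein_min,
              nrow(unique(x$grid[, c("k", "t")]))))
  invisible(x)
}

#' Benchmark grid: LSH-GAN at several k versus the vanilla GAN
#'
#' Reproduces the simulated-data comparison: generate the two-class Gaussian
#' mixture, split 80:20 (stratified by class), train one LSH-GAN per \code{k}
#' and one vanilla GAN, and record the Wasserstein distance between the test
#' split and a test-sized generated sample at each checkpoint epoch of the
#' same training run.
#'
#' @param n_samples,n_features Mixture dimensions (paper scale 100 x 1000;
#'   \code{scale = "reduced"} preset uses 100 x 100).
#' @param k_grid LSH neighbour counts to compare (default 5/10/15/20).
#' @param checkpoints Evaluation epochs (default 10k/15k/20k/25k; the reduced
#'   preset uses 1k/2k).
#' @param t Subsampling passes (default 1).
#' @param scale \code{"full"} or \code{"reduced"}; the reduced preset
#'   overrides \code{n_features} and \code{checkpoints} for a fast run.
#' @param seed Integer seed for data, split and all trainings.
#' @param ... Passed to \code{\link{lsh_gan}} (e.g. \code{mix_fraction}).
#' @return A list of class \code{"table2_grid"}: \code{grid} (matrix, rows =
#'   models, columns = checkpoint epochs), the test indices, and settings.
#' @export
table2_experiment <- function(n_samples = 100, n_features = 1000,
                              k_grid = c(5, 10, 15, 20),
                              checkpoints = c(10000, 15000, 20000, 25000),
                              t = 1, scale = c("full", "reduced"),
                              seed = 1L, ...) {
  scale <- match.arg(scale)
  if (scale == "reduced") {
    n_features <- min(n_features, 100L)
    checkpoints <- c(1000L, 2000L)
  }
  checkpoints <- sort(unique(as.integer(checkpoints)))
  gm <- make_gaussian_mixture(n_samples = n_samples, n_features = n_features,
                              seed = derive_seed(seed, 21L))
  split <- train_test_split(gm$values, gm$labels, test_frac = 0.2,
                            seed = derive_seed(seed, 22L))
  epochs <- max(checkpoints)
  grid <- matrix(NA_real_, length(k_grid) + 1L, length(checkpoints),
                 dimnames = list(c(paste0("lshgan_k", k_grid), "gan"),
                                 as.character(checkpoints)))
  for (i in seq_along(k_grid)) {
    fit <- lsh_gan(split$train, k = k_grid[i], t = t, epochs = epochs,
                   holdout = split$test, checkpoints = checkpoints,
                   seed = seed, ...)
    grid[i, ] <- fit$history$wasserstein
  }
  fit <- lsh_gan(split$train, lsh = FALSE, epochs = epochs,
                 holdout = split$test, checkpoints = checkpoints,
                 seed = seed, ...)
  grid[length(k_grid) + 1L, ] <- fit$history$wasserstein
  structure(list(grid = grid, k_grid = k_grid, checkpoints = checkpoints,
                 test_idx = split$test_idx, n_samples = n_samples,
                 n_features = n_features, seed = seed, scale = scale),
            class = "table2_grid")
}

#' @export
print.table2_grid <- function(x, ...) {
  cat(sprintf("Wasserstein(test, generated), %d x %d mixture, 80:20 split (%s scale)\n",
              x$n_samples, x$n_features, x$scale))
  print(round(x$grid, 3))
  invisible(x)
}

#' Stratified train/test split of a labelled matrix
#'
#' @param X Matrix, samples in rows.
#' @param labels Optional class labels; when given the split is stratified.
#' @param test_frac Held-out fraction (default 0.2).
#' @param seed Integer seed.
#' @return List with \code{train}, \code{test}, \code{test_idx}, and the
#'   per-split labels.
#' @export
train_test_split <- function(X, labels = NULL, test_frac = 0.2, seed = 1L) {
  if (!is.matrix(X)) X <- as.matrix(X)
  stopifnot(test_frac > 0, test_frac < 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  n <- nrow(X)
  if (is.null(labels)) {
    test_idx <- sort(sample.int(n, max(1L, round(test_frac * n))))
  } else {
    stopifnot(length(labels) == n)
    test_idx <- sort(unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, max(1L, round(test_frac * length(idx))))
    }), use.names = FALSE))
  }
  list(train = X[-test_idx, , drop = FALSE],
       test = X[test_idx, , drop = FALSE],
       test_idx = test_idx,
       train_labels = if (!is.null(labels)) labels[-test_idx],
       test_labels = if (!is.null(labels)) labels[test_idx])
}
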