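#' Kac-Murdock-Szego (AR(1)) covariance matrix
#'
#' Builds the p x p covariance matrix with entries \eqn{\Sigma_{ij} =
#' \rho^{|i-j|}}, the autoregressive correlation structure used for the
#' two-class Gaussian-mixture benchmark. The matrix is symmetric and positive
#' definite for any \eqn{|\rho| < 1}.
#'
#' @param p Number of features (matrix dimension), a positive integer.
#' @param rho Autocorrelation parameter, a real number with \code{abs(rho) < 1}.
#' @return A \code{p x p} numeric matrix.
#' @examples
#' kms_covariance(3, 0.5)
#' @export
kms_covariance <- function(p, rho) {
  p <- check_count(p, "p", min = 1L)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || abs(rho) >= 1)
    stop("'rho' must be a single finite number with abs(rho) < 1", call. = FALSE)
  idx <- seq_len(p)
  rho ^ abs(outer(idx, idx, "-"))
}

#' Simulate the two-class Gaussian-mixture benchmark
#'
#' Draws a samples x features matrix from a two-component multivariate-normal
#' mixture with widely separated class means, the synthetic benchmark used to
#' compare LSH-GAN against a vanilla GAN. Per-feature class means are drawn
#' once, uniformly from each class's mean range; all samples share the AR(1)
#' covariance \code{kms_covariance(n_features, rho)}.
#'
#' @param n_samples Total number of samples (default 100).
#' @param n_features Number of features (default 1000).
#' @param mean_range_class1,mean_range_class2 Length-2 numeric ranges from
#'   which the per-feature class means are drawn (defaults \code{c(5, 15)} and
#'   \code{c(-15, -5)}).
#' @param rho AR(1) correlation between neighbouring features (default 0.5).
#' @param class_proportions Length-2 positive proportions summing to 1
#'   (default 50/50).
#' @param seed Integer seed; the draw is fully determined by it.
#' @return A list of class \code{"labeled_matrix"} with elements
#'   \code{values} (the numeric matrix) and \code{labels} (integer class
#'   labels, 1 or 2, one per row).
#' @examples
#' gm <- make_gaussian_mixture(n_samples = 20, n_features = 10, seed = 1)
#' table(gm$labels)
#' @export
make_gaussian_mixture <- function(n_samples = 100, n_features = 1000,
                                  mean_range_class1 = c(5, 15),
                                  mean_range_class2 = c(-15, -5),
                                  rho = 0.5,
                                  class_proportions = c(0.5, 0.5),
                                  seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  n_features <- check_count(n_features, "n_features", min = 1L)
  stopifnot(length(mean_range_class1) == 2L, length(mean_range_class2) == 2L)
  if (!is.numeric(class_proportions) || length(class_proportions) != 2L ||
      any(class_proportions <= 0) || any(class_proportions >= 1) ||
      abs(sum(class_proportions) - 1) > 1e-8)
    stop("'class_proportions' must be two values in (0,1) summing to 1",
         call. = FALSE)

  n1 <- round(n_samples * class_proportions[1L])
  n1 <- max(1L, min(n_samples - 1L, n1))
  n2 <- n_samples - n1

  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  mu1 <- stats::runif(n_features, mean_range_class1[1L], mean_range_class1[2L])
  mu2 <- stats::runif(n_features, mean_range_class2[1L], mean_range_class2[2L])
  R <- chol(kms_covariance(n_features, rho))  # upper triangular, Sigma = R'R

  draw_class <- function(n, mu) {
    z <- matrix(stats::rnorm(n * n_features), n, n_features)
    sweep(z %*% R, 2L, mu, "+")
  }
  values <- rbind(draw_class(n1, mu1), draw_class(n2, mu2))
  colnames(values) <- paste0("feature", seq_len(n_features))
  rownames(values) <- paste0("sample", seq_len(n_samples))

  structure(list(values = values,
                 labels = rep(1:2, c(n1, n2)),
                 class_means = rbind(class1 = mu1, class2 = mu2)),
            class = "labeled_matrix")
}

#' Simulate a two-dimensional correlated-normal toy dataset
#'
#' A small bivariate-normal sample (unit marginal variances, correlation
#' \code{rho}) used to visualise and smoke-test adversarial training in two
#' dimensions.
#'
#' @param n Number of points (at least 2).
#' @param center Length-2 mean vector.
#' @param rho Correlation between the two coordinates.
#' @param seed Integer seed.
#' @return An \code{n x 2} numeric matrix.
#' @export
make_toy_2d <- function(n, center = c(0, 0), rho = 0.5, seed = 1L) {
  n <- check_count(n, "n", min = 2L)
  stopifnot(length(center) == 2L, abs(rho) < 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  R <- chol(matrix(c(1, rho, rho, 1), 2, 2))
  z <- matrix(stats::rnorm(2L * n), n, 2L)
  sweep(z %*% R, 2L, center, "+")
}

#' Write a labelled matrix to CSV
#'
#' Samples x features layout with a header row of feature names and the class
#' label as the first column.
#'
#' @param x A \code{"labeled_matrix"} (or any matrix plus a \code{labels}
#'   vector).
#' @param path Output file path.
#' @param labels Optional labels when \code{x} is a bare matrix.
#' @return \code{path}, invisibly.
#' @export
write_labeled_csv <- function(x, path, labels = NULL) {
  if (inherits(x, "labeled_matrix")) {
    labels <- x$labels
    x <- x$values
  }
  df <- data.frame(label = labels, x, check.names = FALSE)
  utils::write.csv(df, path, row.names = TRUE)
  invisible(path)
}

#' Write a labelled matrix as Matrix Market files
#'
#' Writes \code{<stem>.mtx} plus \code{<stem>_rows.tsv} (sample ids and
#' labels) and \code{<stem>_cols.tsv} (feature names) sidecars.
#'
#' @inheritParams write_labeled_csv
#' @param stem Output path stem (no extension).
#' @return The \code{.mtx} path, invisibly.
#' @export
write_labeled_mtx <- function(x, stem, labels = NULL) {
  if (inherits(x, "labeled_matrix")) {
    labels <- x$labels
    x <- x$values
  }
  mtx <- paste0(stem, ".mtx")
  Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), mtx)
  utils::write.table(
    data.frame(id = rownames(x) %||% paste0("sample", seq_len(nrow(x))),
               label = labels %||% NA),
    paste0(stem, "_rows.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(name = colnames(x) %||% paste0("feature", seq_len(ncol(x)))),
    paste0(stem, "_cols.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mtx)
}
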