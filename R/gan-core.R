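# Adversarial core: multilayer-perceptron generator/discriminator, ADAM, and
# the LSH-GAN training loop. Networks are small (default hidden 16-16), so all
# algebra is plain BLAS-backed matrix arithmetic.

LRELU_SLOPE <- 0.2
PROB_EPS <- 1e-7

lrelu <- function(x) x * (LRELU_SLOPE + (1 - LRELU_SLOPE) * (x > 0))
lrelu_grad <- function(pre) LRELU_SLOPE + (1 - LRELU_SLOPE) * (pre > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# column-broadcast bias add, cheaper than sweep() in the training loop
add_bias <- function(M, b) M + rep(b, each = nrow(M))

# Scaled-normal (He) initialisation, variance 2/fan_in; consumes the current
# RNG stream. `act` is the hidden activation ("tanh" or "lrelu"); the output
# layer is always linear (callers apply sigmoid where needed).
mlp_init <- function(dims, act = "lrelu") {
  L <- length(dims) - 1L
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    layers[[l]] <- list(
      W = matrix(stats::rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
                 dims[l], dims[l + 1L]),
      b = numeric(dims[l + 1L]))
  }
  attr(layers, "act") <- act
  layers
}

# Forward pass keeping intermediates for backprop.
mlp_forward <- function(layers, X) {
  L <- length(layers)
  act <- attr(layers, "act") %||% "lrelu"
  h <- vector("list", L + 1L)
  pre <- vector("list", L)
  h[[1L]] <- X
  for (l in seq_len(L)) {
    pre[[l]] <- add_bias(h[[l]] %*% layers[[l]]$W, layers[[l]]$b)
    h[[l + 1L]] <- if (l < L) {
      if (act == "tanh") tanh(pre[[l]]) else lrelu(pre[[l]])
    } else pre[[l]]
  }
  list(out = h[[L + 1L]], h = h, pre = pre)
}

# Backprop from d(loss)/d(output). Returns per-layer gradients and, when
# `input_grad`, the gradient with respect to the input matrix (needed to push
# the generator gradient through a frozen discriminator).
mlp_backward <- function(layers, fwd, dout, input_grad = FALSE) {
  L <- length(layers)
  act <- attr(layers, "act") %||% "lrelu"
  grads <- vector("list", L)
  delta <- dout
  for (l in seq(L, 1L)) {
    if (l < L) {
      delta <- delta * (if (act == "tanh") 1 - fwd$h[[l + 1L]]^2
                        else lrelu_grad(fwd$pre[[l]]))
    }
    grads[[l]] <- list(W = crossprod(fwd$h[[l]], delta),
                       b = colSums(delta))
    if (l > 1L || input_grad) delta <- delta %*% t(layers[[l]]$W)
  }
  list(grads = grads, dinput = if (input_grad) delta else NULL)
}

adam_init <- function(layers) {
  lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0, t = 0L))
}

adam_step <- function(layers, grads, state, lr, betas, eps = 1e-8) {
  for (l in seq_along(layers)) {
    s <- state[[l]]
    s$t <- s$t + 1L
    s$mW <- betas[1L] * s$mW + (1 - betas[1L]) * grads[[l]]$W
    s$vW <- betas[2L] * s$vW + (1 - betas[2L]) * grads[[l]]$W^2
    s$mb <- betas[1L] * s$mb + (1 - betas[1L]) * grads[[l]]$b
    s$vb <- betas[2L] * s$vb + (1 - betas[2L]) * grads[[l]]$b^2
    c1 <- 1 - betas[1L]^s$t
    c2 <- 1 - betas[2L]^s$t
    layers[[l]]$W <- layers[[l]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

clamp_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

#' Discriminator objective on a batch
#'
#' The quantity ascended by the discriminator step: the summed log-likelihood
#' of calling real samples real and generated samples generated,
#' \eqn{\Delta_d = \sum_i \log D(x_i) + \log(1 - D(G(\hat z)_i))}.
#' Probabilities are clamped to \code{[1e-7, 1 - 1e-7]} before the logs.
#'
#' @param d_real,d_fake Discriminator output probabilities on real and
#'   generated batches (values in \code{[0, 1]}).
#' @return A single number (non-positive up to clamping).
#' @export
discriminator_update_value <- function(d_real, d_fake) {
  check_probs(d_real, "d_real")
  check_probs(d_fake, "d_fake")
  sum(log(clamp_prob(d_real))) + sum(log(1 - clamp_prob(d_fake)))
}

#' Generator objective on a batch
#'
#' The saturating generator objective descended by the generator step,
#' \eqn{\Delta_g = \sum_i \log(1 - D(G(\hat z)_i))}. With
#' \code{non_saturating = TRUE} returns the standard stabilised form
#' \eqn{-\sum_i \log D(G(\hat z)_i)} instead.
#'
#' @param d_fake Discriminator probabilities on generated samples.
#' @param non_saturating Use the non-saturating variant.
#' @return A single number.
#' @export
generator_update_value <- function(d_fake, non_saturating = FALSE) {
  check_probs(d_fake, "d_fake")
  if (non_saturating) -sum(log(clamp_prob(d_fake)))
  else sum(log(1 - clamp_prob(d_fake)))
}

check_probs <- function(p, name) {
  if (!is.numeric(p) || length(p) < 1L || any(!is.finite(p)) ||
      any(p < 0) || any(p > 1))
    stop(sprintf("'%s' must be probabilities in [0, 1]", name), call. = FALSE)
  invisible(p)
}

#' Augmented generator input
#'
#' Draws one generator-input batch from the mixture distribution
#' \eqn{p_{\hat z}}: a fraction \code{mix_fraction} of the rows are prior
#' noise (standard normal per coordinate) and the remainder are rows drawn
#' uniformly with replacement from the LSH subsample \code{x_s}; both live in
#' the feature space of the data, so the generator maps
#' \eqn{\hat z \rightarrow x} directly.
#'
#' @param x_s Subsample matrix (rows are retained real samples); may be
#'   \code{NULL} when \code{mix_fraction = 1}.
#' @param batch_size Number of rows to draw.
#' @param n_features Feature dimension; defaults to \code{ncol(x_s)}.
#' @param mix_fraction Fraction of the batch that is pure noise, in
#'   \code{[0, 1]} (default 0.5; 1 reduces to the vanilla-GAN input).
#' @param seed Optional integer seed; when \code{NULL} the current RNG stream
#'   is used (as inside the training loop).
#' @return A \code{batch_size x n_features} matrix.
#' @export
augment_generator_input <- function(x_s, batch_size, n_features = NULL,
                                    mix_fraction = 0.5, seed = NULL) {
  batch_size <- check_count(batch_size, "batch_size", min = 1L)
  if (!is.numeric(mix_fraction) || mix_fraction < 0 || mix_fraction > 1)
    stop("'mix_fraction' must lie in [0, 1]", call. = FALSE)
  if (is.null(n_features)) {
    if (is.null(x_s)) stop("'n_features' required when 'x_s' is NULL", call. = FALSE)
    n_features <- ncol(x_s)
  }
  if (!is.null(x_s) && ncol(x_s) != n_features)
    stop(sprintf("'x_s' has %d features but 'n_features' is %d",
                 ncol(x_s), n_features), call. = FALSE)
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  n_noise <- round(mix_fraction * batch_size)
  n_data <- batch_size - n_noise
  if (n_data > 0L && (is.null(x_s) || nrow(x_s) < 1L))
    stop("'x_s' must have rows when mix_fraction < 1", call. = FALSE)
  parts <- list()
  if (n_noise > 0L)
    parts$noise <- matrix(stats::rnorm(n_noise * n_features), n_noise, n_features)
  if (n_data > 0L)
    parts$data <- x_s[sample.int(nrow(x_s), n_data, replace = TRUE), , drop = FALSE]
  z <- do.call(rbind, parts)
  rownames(z) <- NULL
  if (n_noise > 0L && n_data > 0L) z <- z[sample.int(batch_size), , drop = FALSE]
  z
}

#' Fit an LSH-GAN (or vanilla GAN) to an expression matrix
#'
#' Trains the adversarial pair on the rows of \code{x}. With
#' \code{lsh = TRUE} the generator input is the augmented distribution
#' \eqn{p_{\hat z}}: prior noise mixed (on the batch axis) with the greedy LSH
#' subsample of the data, recomputed once per fit (the subsampler is
#' deterministic given its seed). Each epoch performs \code{d_steps}
#' discriminator ascent steps on \eqn{\Delta_d} and \code{g_steps} generator
#' descent steps on \eqn{\Delta_g}, full-batch, with ADAM updates.
#'
#' @param x Numeric matrix, samples in rows (cells x genes).
#' @param k,t LSH subsampling parameters: neighbours discarded per kept
#'   sample, and number of subsampling passes (defaults 5 and 1).
#' @param epochs Training epochs (one D + one G update each by default).
#' @param lsh Logical; \code{FALSE} trains the vanilla-GAN baseline on pure
#'   noise input (equivalently \code{mix_fraction = 1}).
#' @param mix_fraction Fraction of generator-input rows that are noise
#'   (default 0.5).
#' @param hidden Hidden-layer widths of both networks (default \code{c(16, 16)}).
#' @param lr,betas ADAM learning rate (default 3e-4) and momentum parameters
#'   (default \code{c(0.5, 0.999)}, the usual adversarial-training setting).
#' @param d_steps,g_steps Updates per epoch for each network (defaults 2 and
#'   1: a slightly ahead discriminator gives the generator a cleaner
#'   gradient).
#' @param non_saturating Use the non-saturating generator objective
#'   \eqn{-\sum \log D(G(\hat z))} for the updates (default \code{TRUE}; the
#'   saturating form stalls as soon as the discriminator is ahead). The
#'   recorded \eqn{\Delta_g} follows the same convention.
#' @param n_tables,hash_bits Hash-forest shape for the subsampler.
#' @param holdout Optional matrix of held-out samples; at every checkpoint the
#'   per-feature Wasserstein distance between a generated sample (of the
#'   holdout's size) and the holdout is recorded.
#' @param checkpoints Integer epochs at which to record history (and snapshot
#'   the generator when \code{snapshot = TRUE}); defaults to ~20 evenly spaced
#'   epochs including the last.
#' @param snapshot Keep generator parameter snapshots at each checkpoint so
#'   intermediate-epoch models can be sampled later.
#' @param ema Exponential-moving-average decay for the generator weights used
#'   at sampling time (default 0.999; \code{NULL} disables averaging). The
#'   raw generator keeps training; averaging only smooths the sampled model
#'   across the adversarial oscillation.
#' @param lr_decay Per-epoch multiplicative learning-rate decay factor
#'   (\code{NULL} keeps the rate constant).
#' @param g_activation,d_activation Hidden activations (\code{"tanh"} or
#'   \code{"lrelu"}). Default tanh generator / leaky-ReLU discriminator: the
#'   saturating generator units are what snap prior noise onto tight
#'   expression clusters, while a tanh discriminator loses its gradient.
#' @param seed Integer seed; subsampling, initialisation and the training
#'   stream derive independent sub-seeds from it.
#' @param verbose Print checkpoint progress.
#' @return An object of class \code{"lsh_gan"}; see
#'   \code{\link{simulate.lsh_gan}}, \code{\link{predict.lsh_gan}},
#'   \code{\link{plot.lsh_gan}}.
#' @examples
#' X <- make_gaussian_mixture(n_samples = 40, n_features = 20, seed = 1)$values
#' fit <- lsh_gan(X, k = 3, epochs = 50, seed = 1)
#' fit
#' new_cells <- simulate(fit, nsim = 10, seed = 2)
#' @export
lsh_gan <- function(x, k = 5, t = 1, epochs = 2000, lsh = TRUE,
                    mix_fraction = 0.5, hidden = c(16, 16),
                    lr = 3e-4, betas = c(0.5, 0.999),
                    d_steps = 2, g_steps = 1, non_saturating = TRUE,
                    n_tables = 8, hash_bits = 16,
                    holdout = NULL, checkpoints = NULL, snapshot = FALSE,
                    ema = 0.999, lr_decay = NULL,
                    g_activation = "tanh", d_activation = "lrelu",
                    seed = 1L, verbose = FALSE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 2L || any(!is.finite(x)))
    stop("'x' must be a finite matrix with at least 2 rows", call. = FALSE)
  epochs <- check_count(epochs, "epochs", min = 1L)
  stopifnot(lr > 0, length(betas) == 2L)
  p <- ncol(x)

  if (!lsh) mix_fraction <- 1
  x_s <- NULL
  if (lsh && mix_fraction < 1) {
    x_s <- lsh_sampling(x, k = k, t = t, n_tables = n_tables,
                        hash_bits = hash_bits, seed = derive_seed(seed, 1L))
  }

  # features are standardised for the adversarial optimisation (the networks
  # and ADAM are badly conditioned on raw expression scales); generated
  # samples are mapped back before they leave the model
  center <- colMeans(x)
  scal <- apply(x, 2L, stats::sd)
  scal[!is.finite(scal) | scal == 0] <- 1
  xz <- sweep(sweep(x, 2L, center, "-"), 2L, scal, "/")
  xz_s <- if (!is.null(x_s))
    sweep(sweep(x_s, 2L, center, "-"), 2L, scal, "/")

  if (is.null(checkpoints)) {
    by <- max(1L, epochs %/% 20L)
    checkpoints <- unique(c(seq(by, epochs, by = by), epochs))
  }
  checkpoints <- sort(unique(as.integer(checkpoints)))
  if (any(checkpoints < 1L | checkpoints > epochs))
    stop("'checkpoints' must lie in [1, epochs]", call. = FALSE)

  old <- local_seed(derive_seed(seed, 2L))
  on.exit(restore_seed(old), add = TRUE)
  G <- mlp_init(c(p, hidden, p), act = g_activation)
  D <- mlp_init(c(p, hidden, 1L), act = d_activation)
  set.seed(derive_seed(seed, 3L))
  adG <- adam_init(G)
  adD <- adam_init(D)

  n <- nrow(x)
  hist_rows <- vector("list", length(checkpoints))
  snaps <- if (snapshot) vector("list", length(checkpoints)) else NULL
  ci <- 1L
  delta_d <- delta_g <- NA_real_
  use_ema <- !is.null(ema) && ema < 1
  Gema <- if (use_ema) G
  lr_t <- lr

  for (epoch in seq_len(epochs)) {
    if (!is.null(lr_decay)) lr_t <- lr * lr_decay^epoch
    for (s in seq_len(d_steps)) {
      zhat <- augment_generator_input(xz_s, n, n_features = p,
                                      mix_fraction = mix_fraction)
      fake <- mlp_forward(G, zhat)$out
      fr <- mlp_forward(D, xz)
      ff <- mlp_forward(D, fake)
      pr <- sigmoid(fr$out)
      pf <- sigmoid(ff$out)
      delta_d <- sum(log(clamp_prob(pr))) + sum(log(1 - clamp_prob(pf)))
      # ascend delta_d == descend -delta_d; gradients w.r.t. logits:
      gr <- mlp_backward(D, fr, pr - 1)
      gf <- mlp_backward(D, ff, pf)
      grads <- mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                      gr$grads, gf$grads, SIMPLIFY = FALSE)
      upd <- adam_step(D, grads, adD, lr_t, betas)
      D <- upd$layers; adD <- upd$state
    }
    for (s in seq_len(g_steps)) {
      zhat <- augment_generator_input(xz_s, n, n_features = p,
                                      mix_fraction = mix_fraction)
      gfwd <- mlp_forward(G, zhat)
      dfwd <- mlp_forward(D, gfwd$out)
      pf <- sigmoid(dfwd$out)
      delta_g <- if (non_saturating) -sum(log(clamp_prob(pf)))
                 else sum(log(1 - clamp_prob(pf)))
      dlogit <- if (non_saturating) pf - 1 else -pf
      dx <- mlp_backward(D, dfwd, dlogit, input_grad = TRUE)$dinput
      gg <- mlp_backward(G, gfwd, dx)
      upd <- adam_step(G, gg$grads, adG, lr_t, betas)
      G <- upd$layers; adG <- upd$state
    }
    if (use_ema) {
      for (l in seq_along(G)) {
        Gema[[l]]$W <- ema * Gema[[l]]$W + (1 - ema) * G[[l]]$W
        Gema[[l]]$b <- ema * Gema[[l]]$b + (1 - ema) * G[[l]]$b
      }
    }
    if (!is.finite(delta_d) || !is.finite(delta_g))
      stop(sprintf("non-finite adversarial loss at epoch %d", epoch), call. = FALSE)

    if (ci <= length(checkpoints) && epoch == checkpoints[ci]) {
      Guse <- if (use_ema) Gema else G
      w <- NA_real_
      if (!is.null(holdout)) {
        gen <- sample_generator(Guse, xz_s, mix_fraction, nrow(holdout), p,
                                center, scal)
        w <- wasserstein_metric(gen, holdout)
      }
      hist_rows[[ci]] <- data.frame(epoch = epoch, delta_d = delta_d,
                                    delta_g = delta_g, wasserstein = w)
      if (snapshot) snaps[[ci]] <- Guse
      if (verbose)
        message(sprintf("epoch %d: delta_d = %.3f, delta_g = %.3f%s",
                        epoch, delta_d, delta_g,
                        if (is.na(w)) "" else sprintf(", W1 = %.3f", w)))
      ci <- ci + 1L
    }
  }

  history <- do.call(rbind, hist_rows)
  if (snapshot) names(snaps) <- as.character(checkpoints)
  structure(list(
    generator = if (use_ema) Gema else G, generator_raw = G,
    discriminator = D, subsample = x_s,
    subsample_std = xz_s, center = center, scale = scal,
    history = history, snapshots = snaps,
    config = list(k = k, t = t, epochs = epochs, lsh = lsh,
                  mix_fraction = mix_fraction, hidden = hidden, lr = lr,
                  betas = betas, d_steps = d_steps, g_steps = g_steps,
                  non_saturating = non_saturating, n_tables = n_tables,
                  hash_bits = hash_bits, ema = ema, lr_decay = lr_decay,
                  g_activation = g_activation, d_activation = d_activation,
                  seed = seed,
                  n_samples = n, n_features = p,
                  feature_names = colnames(x))),
    class = "lsh_gan")
}

# Draw from the generator using the stored (standardised) input distribution
# and map back to the data scale; consumes the current RNG stream.
sample_generator <- function(G, xz_s, mix_fraction, n, p, center, scal) {
  zhat <- augment_generator_input(xz_s, n, n_features = p,
                                  mix_fraction = mix_fraction)
  out <- mlp_forward(G, zhat)$out
  sweep(sweep(out, 2L, scal, "*"), 2L, center, "+")
}

#' Train an LSH-GAN (operation-style wrapper)
#'
#' @inheritParams lsh_gan
#' @param ... Passed to \code{\link{lsh_gan}}.
#' @return An \code{"lsh_gan"} object.
#' @export
train_lsh_gan <- function(x, ...) lsh_gan(x, lsh = TRUE, ...)

#' Train the vanilla-GAN baseline (pure-noise generator input)
#'
#' Identical networks, optimiser and loop as \code{\link{lsh_gan}} but the
#' generator sees only prior noise.
#'
#' @inheritParams train_lsh_gan
#' @return An \code{"lsh_gan"} object with \code{config$lsh = FALSE}.
#' @export
train_vanilla_gan <- function(x, ...) lsh_gan(x, lsh = FALSE, ...)

#' Generate cells from a trained model
#'
#' Draws \code{nsim} generator inputs from the stored augmented distribution
#' and maps them through the generator.
#'
#' @param object A fitted \code{"lsh_gan"}.
#' @param nsim Number of samples to generate.
#' @param seed Integer seed (required for reproducibility; default 1).
#' @param epoch Optional checkpoint epoch: when the model was fitted with
#'   \code{snapshot = TRUE}, sample from the generator as it was at that
#'   checkpoint instead of the final one.
#' @param ... Unused.
#' @return An \code{nsim x n_features} matrix of generated samples.
#' @export
simulate.lsh_gan <- function(object, nsim = 1, seed = 1L, epoch = NULL, ...) {
  nsim <- check_count(nsim, "nsim", min = 1L)
  G <- object$generator
  if (!is.null(epoch)) {
    key <- as.character(epoch)
    if (is.null(object$snapshots) || is.null(object$snapshots[[key]]))
      stop(sprintf("no generator snapshot stored for epoch %s", key), call. = FALSE)
    G <- object$snapshots[[key]]
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  out <- sample_generator(G, object$subsample_std, object$config$mix_fraction,
                          nsim, object$config$n_features,
                          object$center, object$scale)
  colnames(out) <- object$config$feature_names
  out
}

#' @rdname simulate.lsh_gan
#' @param model A fitted \code{"lsh_gan"}.
#' @param n Number of samples.
#' @export
generate_cells <- function(model, n, seed = 1L, epoch = NULL)
  simulate.lsh_gan(model, nsim = n, seed = seed, epoch = epoch)

#' Discriminator scores for new samples
#'
#' @param object A fitted \code{"lsh_gan"}.
#' @param newdata Matrix of samples (same feature dimension as training).
#' @param ... Unused.
#' @return Numeric vector of probabilities that each row is real.
#' @export
predict.lsh_gan <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$config$n_features)
    stop("feature dimension mismatch", call. = FALSE)
  z <- sweep(sweep(newdata, 2L, object$center, "-"), 2L, object$scale, "/")
  as.vector(sigmoid(mlp_forward(object$discriminator, z)$out))
}

#' @export
coef.lsh_gan <- function(object, ...)
  list(generator = object$generator, discriminator = object$discriminator)

#' @export
print.lsh_gan <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%s fit: %d samples x %d features, %d epochs\n",
              if (cfg$lsh) "LSH-GAN" else "vanilla GAN",
              cfg$n_samples, cfg$n_features, cfg$epochs))
  if (cfg$lsh && !is.null(x$subsample))
    cat(sprintf("LSH subsample: %d of %d samples (k = %d, t = %d)\n",
                nrow(x$subsample), cfg$n_samples, cfg$k, cfg$t))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("final delta_d = %.3f, delta_g = %.3f", last$delta_d, last$delta_g))
    if (!is.na(last$wasserstein))
      cat(sprintf(", Wasserstein(holdout) = %.3f", last$wasserstein))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.lsh_gan <- function(object, ...) {
  structure(list(config = object$config, history = object$history,
                 subsample_size = if (is.null(object$subsample)) 0L
                                  else nrow(object$subsample)),
            class = "summary.lsh_gan")
}

#' @export
print.summary.lsh_gan <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%s: %d x %d data, hidden (%s), lr %g, mix_fraction %.2f\n",
              if (cfg$lsh) "LSH-GAN" else "vanilla GAN",
              cfg$n_samples, cfg$n_features,
              paste(cfg$hidden, collapse = ", "), cfg$lr, cfg$mix_fraction))
  if (cfg$lsh)
    cat(sprintf("subsample size %d (k = %d, t = %d)\n",
                x$subsample_size, cfg$k, cfg$t))
  if (!is.null(x$history)) {
    cat("training history (checkpoints):\n")
    print(utils::tail(x$history, 5L), row.names = FALSE)
    if (any(!is.na(x$history$wasserstein))) {
      b <- x$history[which.min(x$history$wasserstein), ]
      cat(sprintf("best checkpoint: epoch %d, Wasserstein %.4f\n",
                  b$epoch, b$wasserstein))
    }
  }
  invisible(x)
}

#' Plot the training history of a fitted model
#'
#' Adversarial objectives per checkpoint, and the holdout Wasserstein
#' trajectory when one was tracked.
#'
#' @param x A fitted \code{"lsh_gan"}.
#' @param ... Passed to \code{matplot}.
#' @export
plot.lsh_gan <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("no history recorded", call. = FALSE)
  has_w <- any(!is.na(h$wasserstein))
  if (has_w) {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  }
  graphics::matplot(h$epoch, cbind(h$delta_d, h$delta_g), type = "l",
                    lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "epoch", ylab = "objective", ...)
  graphics::legend("bottomright", c(expression(Delta[d]), expression(Delta[g])),
                   lty = 1, col = c("firebrick", "steelblue"), bty = "n")
  if (has_w)
    graphics::plot(h$epoch, h$wasserstein, type = "b", pch = 16,
                   xlab = "epoch", ylab = "Wasserstein to holdout")
  invisible(x)
}
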