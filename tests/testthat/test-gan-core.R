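test_that("adversarial objectives evaluate exactly on known probabilities", {
  eps <- 1e-7
  expect_equal(discriminator_update_value(1 - eps, eps), 0, tolerance = 1e-5)
  expect_equal(discriminator_update_value(c(0.5, 0.5), c(0.5, 0.5)),
               4 * log(0.5))
  expect_equal(discriminator_update_value(0.8, 0.3), log(0.8) + log(0.7))
  expect_equal(generator_update_value(c(0.5, 0.5)), 2 * log(0.5))
  expect_equal(generator_update_value(eps), 0, tolerance = 1e-5)
  expect_equal(generator_update_value(0.9), log(0.1))
  expect_equal(generator_update_value(0.9, non_saturating = TRUE), -log(0.9))
  # clamping keeps the objectives finite at the boundary
  expect_true(is.finite(discriminator_update_value(c(0, 1), c(0, 1))))
  expect_true(is.finite(generator_update_value(c(0, 1))))
  expect_error(discriminator_update_value(1.2, 0.5), "probabilities")
  expect_error(generator_update_value(-0.1), "probabilities")
})

test_that("augmented generator input mixes noise rows with subsample rows", {
  x_s <- matrix(100 + seq_len(12), 3, 4)
  z1 <- augment_generator_input(x_s, 10, mix_fraction = 1, seed = 1)
  expect_equal(dim(z1), c(10L, 4L))
  expect_true(all(abs(z1) < 50))  # pure standard-normal rows

  z0 <- augment_generator_input(x_s, 10, mix_fraction = 0, seed = 1)
  in_xs <- apply(z0, 1, function(r)
    any(apply(x_s, 1, function(s) identical(unname(r), unname(s)))))
  expect_true(all(in_xs))

  zh <- augment_generator_input(x_s, 10, mix_fraction = 0.5, seed = 2)
  from_xs <- apply(zh, 1, function(r)
    any(apply(x_s, 1, function(s) identical(unname(r), unname(s)))))
  expect_equal(sum(from_xs), 5L)

  expect_identical(augment_generator_input(x_s, 8, seed = 3),
                   augment_generator_input(x_s, 8, seed = 3))
  expect_error(augment_generator_input(x_s, 10, n_features = 7), "features")
  expect_error(augment_generator_input(NULL, 5, n_features = 4,
                                       mix_fraction = 0.5), "rows")
})

test_that("single-epoch fit honours the history contract", {
  X <- make_gaussian_mixture(n_samples = 20, n_features = 10, seed = 1)$values
  fit <- lsh_gan(X, k = 2, epochs = 1, seed = 1)
  expect_s3_class(fit, "lsh_gan")
  expect_equal(nrow(fit$history), 1L)
  expect_true(all(is.finite(fit$history$delta_d)))
  expect_true(all(is.finite(fit$history$delta_g)))
  fit2 <- lsh_gan(X, k = 2, epochs = 10, checkpoints = c(3, 7, 10), seed = 1)
  expect_equal(fit2$history$epoch, c(3L, 7L, 10L))
})

test_that("training is reproducible and mix_fraction = 1 reduces to the vanilla GAN", {
  X <- make_gaussian_mixture(n_samples = 30, n_features = 12, seed = 2)$values
  a <- lsh_gan(X, k = 3, epochs = 40, seed = 9)
  b <- lsh_gan(X, k = 3, epochs = 40, seed = 9)
  expect_identical(a$history, b$history)
  expect_identical(a$generator, b$generator)

  mix1 <- lsh_gan(X, k = 3, epochs = 40, mix_fraction = 1, seed = 9)
  van <- train_vanilla_gan(X, epochs = 40, seed = 9)
  expect_identical(mix1$history, van$history)
  expect_identical(mix1$generator, van$generator)
})

test_that("holdout Wasserstein improves over training on the mixture benchmark", {
  gm <- make_gaussian_mixture(n_samples = 100, n_features = 200, seed = 21)
  sp <- train_test_split(gm$values, gm$labels, seed = 22)
  fit <- lsh_gan(sp$train, k = 5, epochs = 2000, holdout = sp$test,
                 checkpoints = c(100, 1000, 2000), seed = 1)
  w <- fit$history$wasserstein
  expect_true(all(is.finite(w)))
  expect_lt(w[3], w[1])
})

test_that("the LSH generator input is at least as good as pure noise on 2-D toy data", {
  X <- make_toy_2d(200, center = c(3, -2), rho = 0.5, seed = 5)
  sp <- train_test_split(X, seed = 6)
  lsh <- lsh_gan(sp$train, k = 5, epochs = 1500, holdout = sp$test,
                 checkpoints = 1500, seed = 2)
  van <- train_vanilla_gan(sp$train, epochs = 1500, holdout = sp$test,
                           checkpoints = 1500, seed = 2)
  expect_gte(van$history$wasserstein, lsh$history$wasserstein)
})

test_that("generated samples have the right shape, determinism and scale", {
  gm <- make_gaussian_mixture(n_samples = 60, n_features = 40, seed = 31)
  fit <- lsh_gan(gm$values, k = 5, epochs = 2000, seed = 3)
  g <- simulate(fit, nsim = 50, seed = 7)
  expect_equal(dim(g), c(50L, 40L))
  expect_identical(g, simulate(fit, nsim = 50, seed = 7))
  expect_identical(g, generate_cells(fit, 50, seed = 7))
  expect_true(all(is.finite(g)))
  # feature means land inside (a tolerance around) the class-mean hull
  expect_true(all(colMeans(g) > -17 & colMeans(g) < 17))
  expect_error(generate_cells(fit, 0), "nsim")
})

test_that("snapshots expose intermediate-epoch generators", {
  X <- make_gaussian_mixture(n_samples = 20, n_features = 8, seed = 4)$values
  fit <- lsh_gan(X, k = 2, epochs = 30, checkpoints = c(10, 30),
                 snapshot = TRUE, seed = 1)
  g10 <- simulate(fit, nsim = 5, seed = 1, epoch = 10)
  g30 <- simulate(fit, nsim = 5, seed = 1, epoch = 30)
  expect_equal(dim(g10), c(5L, 8L))
  expect_false(identical(g10, g30))
  # final snapshot equals the final generator
  expect_identical(fit$snapshots[["30"]], fit$generator)
  expect_error(simulate(fit, nsim = 2, epoch = 20), "snapshot")
})

test_that("discriminator scores and coefficients are exposed", {
  X <- make_gaussian_mixture(n_samples = 30, n_features = 10, seed = 6)$values
  fit <- lsh_gan(X, k = 3, epochs = 100, seed = 2)
  p <- predict(fit, X)
  expect_length(p, 30L)
  expect_true(all(p >= 0 & p <= 1))
  cf <- coef(fit)
  expect_named(cf, c("generator", "discriminator"))
  expect_length(cf$generator, 3L)  # three layers
  expect_output(print(fit), "LSH-GAN fit")
  expect_output(print(summary(fit)), "subsample size")
})
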