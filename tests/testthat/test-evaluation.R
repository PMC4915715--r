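test_that("CV plans partition samples into near-equal folds", {
  plan <- make_cv_plan(121, 6, 10, seed = 1)
  for (r in 1:10) {
    sizes <- as.integer(table(plan$assignments[[r]]))
    expect_equal(sort(sizes), c(20, 20, 20, 20, 20, 21))
    # every sample held out exactly once per repetition
    expect_equal(sum(sizes), 121)
  }
  # largest held-out fold leaves 100 training samples
  expect_equal(121 - max(table(plan$assignments[[1]])), 100L)

  # leave-one-out degenerate case
  loo <- make_cv_plan(6, 6, 1, seed = 1)
  expect_equal(sort(as.integer(table(loo$assignments[[1]]))), rep(1L, 6))

  expect_identical(make_cv_plan(30, 5, 3, seed = 9)$assignments,
                   make_cv_plan(30, 5, 3, seed = 9)$assignments)
  expect_false(identical(make_cv_plan(30, 5, 3, seed = 1)$assignments,
                         make_cv_plan(30, 5, 3, seed = 2)$assignments))
  expect_error(make_cv_plan(4, 6), "n < k")
})

test_that("pooled Pearson R matches the textbook formula", {
  expect_equal(pearson_r(matrix(1:6, 2), matrix(1:6, 2)), 1)
  truth <- matrix(runif(12), 3)
  expect_equal(pearson_r(2.5 * truth + 0.3, truth), 1)

  pred <- c(0, 1, 0, 1); truth4 <- c(0, 1, 2, 3)
  n <- 4
  hand <- (n * sum(pred * truth4) - sum(pred) * sum(truth4)) /
    sqrt((n * sum(pred^2) - sum(pred)^2) * (n * sum(truth4^2) - sum(truth4)^2))
  expect_equal(pearson_r(pred, truth4), hand)

  expect_error(pearson_r(rep(0.5, 4), truth4), "zero variance")
  expect_error(pearson_r(1:4, 1:3), "shapes")
})

test_that("PCA reconstruction behaves like truncated SVD on held-out rows", {
  set.seed(1)
  train <- matrix(runif(60), 10, 6)
  test <- matrix(runif(30), 5, 6)
  # full rank: lossless
  expect_lt(pca_reconstruction_error(train, test, 6), 1e-8)
  # zero components: reconstruction is the training mean row
  expect_equal(pca_reconstruction_error(train, test, 0),
               sum(abs(sweep(test, 2, colMeans(train)))))
  # nested subspaces: training error non-increasing in component count
  errs <- sapply(0:6, function(k) pca_reconstruction_error(train, train, k))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("PLS recovers exact linear maps and matches least squares at full rank", {
  d <- gen_dataset(synth_config(n_samples = 60, n_mz_bins = 30,
                                n_descriptors = 10, latent_dim = 3,
                                nonlinearity = "linear", noise_sd = 0,
                                seed = 2))
  plan <- make_cv_plan(60, 4, 1, seed = 3)
  res <- pls_baseline(d$spectra, d$sensory, n_latent = 3, plan = plan)
  expect_gte(min(res$fits$r), 0.999)

  # full latent rank equals ordinary least squares (small-instance oracle)
  set.seed(4)
  X <- matrix(rnorm(100), 20, 5); colnames(X) <- paste0("x", 1:5)
  Y <- X %*% matrix(rnorm(15), 5, 3) + matrix(rnorm(60), 20, 3) * 0.1
  colnames(Y) <- paste0("y", 1:3)
  m <- odormap:::fit_pls(X, Y, 5)
  pls_pred <- odormap:::predict_pls(m, X)
  ols_pred <- cbind(1, X) %*% qr.coef(qr(cbind(1, X)), Y)
  expect_equal(unname(pls_pred), unname(ols_pred), tolerance = 1e-8)

  # zero latent variables: prediction collapses to the training mean; for a
  # single response the pooled scatter then has zero variance and the guard
  # fires
  m0 <- odormap:::fit_pls(X, Y, 0)
  p0 <- odormap:::predict_pls(m0, X)
  expect_equal(unname(p0[1, ]), unname(colMeans(Y)))
  expect_error(pearson_r(p0[, 1], Y[, 1]), "zero variance")
})

test_that("latent-variable count is selected by the shared CV criterion", {
  d <- gen_dataset(synth_config(n_samples = 50, n_mz_bins = 24,
                                n_descriptors = 8, latent_dim = 2,
                                nonlinearity = "linear", noise_sd = 0.02,
                                seed = 5))
  plan <- make_cv_plan(50, 5, 1, seed = 6)
  res <- pls_baseline(d$spectra, d$sensory, n_latent = c(1, 2, 5), plan = plan)
  expect_s3_class(res, "cv_result")
  expect_equal(nrow(res$selection), 3)
  best <- res$selection$n_latent[which.min(res$selection$median_gen_error)]
  expect_gte(best, 2)  # needs at least the true latent dimension
})

test_that("the cross-validation harness holds every sample out once", {
  d <- tiny_dataset(7, n = 12)
  plan <- make_cv_plan(12, 2, 1, seed = 8)
  res <- run_cv(d$spectra, d$sensory, train_config(epochs = 10, seed = 1),
                plan = plan)
  expect_equal(nrow(res$fits), 2)
  expect_true(all(res$err_count == 1))
  expect_true(all(is.finite(res$fits$r)))
  expect_true(all(res$fits$n_test == 6))
  expect_true(all(c("recon_spectrum", "recon_sensory") %in% names(res$fits)))
})

test_that("fit counting follows the k-fold-times-repetitions protocol", {
  d <- gen_dataset(synth_config(n_samples = 40, n_mz_bins = 20,
                                n_descriptors = 12, seed = 9))
  plan <- make_cv_plan(40, 4, 3, seed = 10)
  res <- pls_baseline(d$spectra, d$sensory, n_latent = 3, plan = plan)
  expect_equal(nrow(res$fits), 12)  # 4 folds x 3 repetitions
  expect_equal(sort(unique(res$fits$rep)), 1:3)
  expect_equal(res$median_r, median(res$fits$r))
})

test_that("median summaries shrug off one anomalous fit", {
  fits <- data.frame(rep = 1, fold = 1:5, n_test = 4,
                     r = c(0.7, 0.72, 0.68, 0.75, 0.71),
                     gen_error = c(1, 2, 3, 4, 100), converged = TRUE)
  base <- odormap:::new_cv_result(fits, matrix(0, 20, 3), rep(1L, 20), 20,
                                  "toy", NULL)
  fits2 <- fits; fits2$gen_error[5] <- Inf
  blown <- odormap:::new_cv_result(fits2, matrix(0, 20, 3), rep(1L, 20), 20,
                                   "toy", NULL)
  expect_equal(blown$median_gen_error, base$median_gen_error)

  # non-converged fits are excluded from the medians
  fits3 <- fits; fits3$converged[5] <- FALSE; fits3$r[5] <- NA
  part <- odormap:::new_cv_result(fits3, matrix(0, 20, 3), rep(1L, 20), 20,
                                  "toy", NULL)
  expect_equal(part$median_r, median(fits$r[1:4]))
  expect_equal(part$n_excluded, 1)
})

test_that("per-sample errors aggregate and flag the worst tail", {
  set.seed(11)
  err_sum <- matrix(runif(121 * 144), 121, 144)
  counts <- rep(10L, 121)
  fits <- data.frame(rep = 1, fold = 1, n_test = 121, r = 0.7,
                     gen_error = 1, converged = TRUE)
  res <- odormap:::new_cv_result(fits, err_sum, counts, 121, "toy", NULL)
  pe <- per_sample_errors(res, q = 0.05)
  expect_length(pe$flagged, 6)  # top 5% of 121 samples
  expect_equal(pe$per_sample, rowMeans(pe$per_descriptor))
  expect_equal(dim(pe$per_descriptor), c(121, 144))
  expect_true(all(pe$per_sample[pe$flagged] >=
                  max(pe$per_sample[-pe$flagged])))

  # perfect predictions flag nothing
  perfect <- odormap:::new_cv_result(fits, err_sum * 0, counts, 121, "toy", NULL)
  expect_length(per_sample_errors(perfect)$flagged, 0)
})

test_that("width sweeps report the best outer width per bottleneck size", {
  set.seed(12)
  # rank-2 data in [0,1] with two strongly expressed factors
  Zl <- matrix(runif(36 * 2), 36, 2)
  G <- rbind(seq(-0.45, 0.45, length.out = 8),
             rep(c(-0.4, 0.4), 4))
  X <- pmin(pmax(Zl %*% G + 0.5, 0), 1)
  plan <- make_cv_plan(36, 3, 1, seed = 13)
  cfg <- train_config(epochs = 120, seed = 14)
  sweep_tab <- dimension_sweep(X, "spectrum", K_grid = 5, D_grid = c(1, 2, 4),
                               config = cfg, plan = plan)
  expect_equal(nrow(sweep_tab), 3)
  expect_equal(sweep_tab$K_best, rep(5L, 3))
  grid <- attr(sweep_tab, "grid")
  expect_equal(dim(grid), c(3, 1))
  # intrinsic dimension is 2: the drop from D = 1 to D = 2 dominates any
  # wiggle beyond it (the plateau of the width-sweep curves)
  expect_lt(sweep_tab$error[2], sweep_tab$error[1])
  expect_lt(abs(sweep_tab$error[3] - sweep_tab$error[2]),
            sweep_tab$error[1] - sweep_tab$error[2])

  single <- dimension_sweep(X, "spectrum", K_grid = 4, D_grid = 2,
                            config = train_config(epochs = 5, seed = 1),
                            plan = plan)
  expect_equal(nrow(single), 1)
})
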