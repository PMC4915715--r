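#' Repeated k-fold cross-validation plan
#'
#' Builds `reps` independent random partitions of `n` samples into `k` folds
#' with sizes differing by at most one (121 samples in 6 folds gives one
#' fold of 21 and five of 20, so each fit trains on 100 samples).
#'
#' @param n Number of samples.
#' @param k Number of folds (default 6).
#' @param reps Number of repeated random splittings (default 10).
#' @param seed Optional integer seed.
#' @return List with class `"cv_plan"`: `n`, `k`, `reps`, `seed` and
#'   `assignments`, a list of length-`n` integer fold labels per repetition.
#' @export
make_cv_plan <- function(n, k = 6, reps = 10, seed = NULL) {
  if (n < k) stop("make_cv_plan: n < k")
  stopifnot(k >= 2, reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  assignments <- lapply(seq_len(reps), function(r)
    sample(rep(seq_len(k), length.out = n)))
  structure(list(n = as.integer(n), k = as.integer(k),
                 reps = as.integer(reps), seed = seed,
                 assignments = assignments),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("Cross-validation plan: ", x$k, "-fold x ", x$reps, " repetitions on ",
      x$n, " samples (", x$k * x$reps, " fits)\n", sep = "")
  invisible(x)
}

#' Pooled Pearson correlation between predictions and truth
#'
#' One coefficient over all flattened descriptor-by-sample points (for a
#' held-out fold of 21 samples and 144 descriptors, 3024 points pool into a
#' single scatter).
#'
#' @param pred Predicted matrix (or vector).
#' @param truth True matrix of the same shape.
#' @return Scalar in `[-1, 1]`.
#' @export
pearson_r <- function(pred, truth) {
  p <- as.vector(as.matrix(pred)); t <- as.vector(as.matrix(truth))
  if (length(p) != length(t)) stop("pearson_r: shapes differ")
  if (length(p) < 2) stop("pearson_r: need at least 2 points")
  if (sd(p) == 0 || sd(t) == 0)
    stop("pearson_r: zero variance; correlation undefined")
  cor(p, t)
}

new_cv_result <- function(fits, err_sum, err_count, n, method, plan) {
  ok <- fits$converged
  structure(list(fits = fits, err_sum = err_sum, err_count = err_count,
                 n = n, method = method, plan = plan,
                 n_excluded = sum(!ok),
                 median_r = median(fits$r[ok]),
                 mean_r = mean(fits$r[ok]),
                 median_gen_error = median(fits$gen_error[ok])),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validated evaluation (", x$method, "): ",
      nrow(x$fits), " fits\n", sep = "")
  cat("  pooled Pearson R: median", format(x$median_r, digits = 3),
      " mean", format(x$mean_r, digits = 3), "\n")
  cat("  generalization error (median):",
      format(x$median_gen_error, digits = 4), "\n")
  if (x$n_excluded)
    cat("  non-converged fits excluded:", x$n_excluded, "\n")
  invisible(x)
}

# Shared CV loop. fit_fun(xtr, ytr, fold_seed) -> model;
# predict_fun(model, xte) -> matrix. Extra per-fit metrics via extra_fun.
cv_harness <- function(spectra, sensory, plan, fit_fun, predict_fun,
                       method, extra_fun = NULL, progress = FALSE) {
  spectra <- as.matrix(spectra); sensory <- as.matrix(sensory)
  if (nrow(spectra) != plan$n || nrow(sensory) != plan$n)
    stop("cv_harness: plan was built for ", plan$n, " samples")
  P <- ncol(sensory)
  err_sum <- matrix(0, plan$n, P,
                    dimnames = list(rownames(sensory), colnames(sensory)))
  err_count <- integer(plan$n)
  rows <- vector("list", plan$k * plan$reps)
  i <- 0L
  for (r in seq_len(plan$reps)) {
    folds <- plan$assignments[[r]]
    for (f in seq_len(plan$k)) {
      i <- i + 1L
      te <- which(folds == f); tr <- which(folds != f)
      model <- fit_fun(spectra[tr, , drop = FALSE],
                       sensory[tr, , drop = FALSE], r * 1000L + f)
      pred <- predict_fun(model, spectra[te, , drop = FALSE])
      converged <- all(is.finite(pred))
      rr <- if (converged) pearson_r(pred, sensory[te, , drop = FALSE]) else NA_real_
      gen <- if (converged) sum((pred - sensory[te, , drop = FALSE])^2) else NA_real_
      extra <- if (!is.null(extra_fun))
        extra_fun(model, spectra[te, , drop = FALSE],
                  sensory[te, , drop = FALSE]) else NULL
      if (converged) {
        err_sum[te, ] <- err_sum[te, ] + abs(pred - sensory[te, , drop = FALSE])
        err_count[te] <- err_count[te] + 1L
      }
      rows[[i]] <- c(list(rep = r, fold = f, n_test = length(te), r = rr,
                          gen_error = gen, converged = converged), extra)
      if (progress)
        message(sprintf("[%s] rep %d fold %d: R = %s", method, r, f,
                        format(rr, digits = 3)))
    }
  }
  fits <- do.call(rbind, lapply(rows, function(z) as.data.frame(z)))
  if (any(!fits$converged))
    message("cv_harness: ", sum(!fits$converged),
            " non-converged fit(s) excluded from summaries")
  new_cv_result(fits, err_sum, err_count, plan$n, method, plan)
}

#' Cross-validate the nine-layer pipeline
#'
#' For every repetition and fold: pretrain and fine-tune both autoencoders
#' on the training rows, train the latent-space mapper, assemble the
#' nine-layer network, fine-tune it end to end, then predict the held-out
#' fold. Records the pooled Pearson R, the generalization error (sum of
#' per-sample squared-error losses plus the L1 penalty over the held-out
#' fold), and the held-out reconstruction error of each autoencoder. With
#' the default 6 folds and 10 repetitions this is 60 fits; a fit whose
#' predictions are not finite is recorded as non-converged and excluded
#' from the median summaries.
#'
#' @param spectra `N x M` spectrum matrix in `[0, 1]`.
#' @param sensory `N x P` sensory matrix in `[0, 1]`, same rows.
#' @param config A [train_config()].
#' @param plan A [make_cv_plan()]; defaults to 6-fold, 10 repetitions.
#' @param arch Architecture (see [default_architecture()]); derived from the
#'   data when `NULL`.
#' @param progress Print per-fit progress messages.
#' @return A `"cv_result"`: per-fit table (`fits`), accumulated per-sample
#'   absolute errors, and median/mean summaries.
#' @export
run_cv <- function(spectra, sensory, config = train_config(),
                   plan = make_cv_plan(nrow(spectra)), arch = NULL,
                   progress = FALSE) {
  if (is.null(arch)) arch <- default_architecture(ncol(spectra), ncol(sensory))
  base_seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  fit_fun <- function(xtr, ytr, fold_seed) {
    cfg <- config
    cfg$seed <- base_seed + fold_seed
    odor_model(xtr, ytr, cfg, arch = arch)
  }
  extra_fun <- function(model, xte, yte) {
    list(recon_spectrum = reconstruction_error(model$spec_ae, xte),
         recon_sensory = reconstruction_error(model$sens_ae, yte))
  }
  cv_harness(spectra, sensory, plan, fit_fun,
             function(m, x) predict(m, x), "nine_layer",
             extra_fun, progress)
}

#' PCA reconstruction error on held-out data
#'
#' Fits PCA (column centering + SVD) on the training rows, reconstructs the
#' test rows from the top `n_components` scores, and reports the sum of
#' absolute deviations — the same criterion used for the autoencoders, which
#' makes the two compression methods directly comparable. With 0 components
#' the reconstruction is the training mean row.
#'
#' @param train Training matrix (samples in rows).
#' @param test Held-out matrix with the same columns.
#' @param n_components Number of principal components kept.
#' @return Nonnegative scalar error on `test`.
#' @export
pca_reconstruction_error <- function(train, test, n_components) {
  train <- as.matrix(train); test <- as.matrix(test)
  stopifnot(ncol(train) == ncol(test),
            n_components >= 0, n_components <= min(dim(train)))
  ctr <- colMeans(train)
  recon <- matrix(ctr, nrow(test), ncol(test), byrow = TRUE)
  if (n_components > 0) {
    sv <- svd(sweep(train, 2, ctr), nu = 0, nv = n_components)
    V <- sv$v
    recon <- recon + sweep(test, 2, ctr) %*% V %*% t(V)
  }
  sum(abs(test - recon))
}

fit_pls <- function(xtr, ytr, ncomp) {
  if (is.null(colnames(xtr))) colnames(xtr) <- paste0("x", seq_len(ncol(xtr)))
  if (is.null(colnames(ytr))) colnames(ytr) <- paste0("y", seq_len(ncol(ytr)))
  if (ncomp > 0) {
    # NIPALS deflation breaks down past the rank of the centered block
    rank_x <- qr(sweep(xtr, 2, colMeans(xtr)))$rank
    ncomp <- min(ncomp, rank_x, nrow(xtr) - 1L)
  }
  if (ncomp == 0)
    return(list(mean_y = colMeans(ytr), ncomp = 0L, xnames = colnames(xtr)))
  fit <- suppressWarnings(
    mixOmics::pls(xtr, ytr, ncomp = ncomp, mode = "regression",
                  scale = FALSE))
  list(fit = fit, ncomp = ncomp, xnames = colnames(xtr))
}

predict_pls <- function(model, xte) {
  xte <- as.matrix(xte)
  colnames(xte) <- model$xnames
  if (model$ncomp == 0)
    return(matrix(model$mean_y, nrow(xte), length(model$mean_y),
                  byrow = TRUE))
  pr <- suppressWarnings(predict(model$fit, xte))
  pr$predict[, , model$ncomp, drop = TRUE]
}

#' Cross-validated PLS baseline
#'
#' Two-block partial least-squares regression (PLS2) from spectra to
#' sensory profiles, evaluated under the identical cross-validation plan and
#' pooled Pearson-R criterion as the nine-layer model. When `n_latent` has
#' several values the number of latent variables is selected by the same
#' criterion: the value with the smallest median generalization error is
#' reported (the selection table is attached as `selection`). PLS is
#' deterministic, so differences across the fits come only from the random
#' splittings.
#'
#' @param spectra `N x M` spectrum matrix.
#' @param sensory `N x P` sensory matrix.
#' @param n_latent Number of latent variables, or a vector of candidates.
#' @param plan A [make_cv_plan()].
#' @return A `"cv_result"` (with a `selection` data frame when `n_latent`
#'   had several candidates).
#' @export
pls_baseline <- function(spectra, sensory, n_latent = 45,
                         plan = make_cv_plan(nrow(spectra))) {
  run_one <- function(nc) {
    cv_harness(spectra, sensory, plan,
               function(xtr, ytr, fs) fit_pls(xtr, ytr, nc),
               predict_pls, sprintf("pls(%d)", nc))
  }
  if (length(n_latent) == 1L) return(run_one(n_latent))
  results <- lapply(n_latent, run_one)
  sel <- data.frame(n_latent = n_latent,
                    median_gen_error = vapply(results, function(r)
                      r$median_gen_error, 0),
                    median_r = vapply(results, function(r) r$median_r, 0))
  best <- which.min(sel$median_gen_error)
  out <- results[[best]]
  out$selection <- sel
  out
}

#' Per-sample and per-descriptor prediction errors
#'
#' Averages, for each sample, the absolute prediction error over every fold
#' and repetition in which the sample was held out; also reports the full
#' sample-by-descriptor mean-error matrix and flags the worst
#' `floor(q * N)` samples, at least one (the top 5% of 121 samples is 6).
#'
#' @param result A `"cv_result"` from [run_cv()] or [pls_baseline()].
#' @param q Flagging fraction (default 0.05).
#' @return List with class `"sample_errors"`: `per_sample` (length-`N` mean
#'   absolute error), `per_descriptor` (`N x P` matrix whose row means equal
#'   `per_sample`), `flagged` (indices of the worst samples, largest error
#'   first) and `q`.
#' @export
per_sample_errors <- function(result, q = 0.05) {
  stopifnot(inherits(result, "cv_result"), q > 0, q <= 1)
  cnt <- pmax(result$err_count, 1L)
  per_desc <- result$err_sum / cnt
  per_sample <- rowMeans(per_desc)
  n_flag <- max(1L, floor(q * result$n))
  flagged <- order(per_sample, decreasing = TRUE)[seq_len(n_flag)]
  if (all(per_sample == 0)) flagged <- integer(0)
  structure(list(per_sample = per_sample, per_descriptor = per_desc,
                 flagged = flagged, q = q),
            class = "sample_errors")
}

#' @export
print.sample_errors <- function(x, ...) {
  cat("Per-sample mean absolute prediction errors (n = ",
      length(x$per_sample), ")\n", sep = "")
  cat("  worst ", length(x$flagged), " samples (top ", 100 * x$q, "%): ",
      paste(x$flagged, collapse = ", "), "\n", sep = "")
  cat("  max per-sample error:", format(max(x$per_sample), digits = 3), "\n")
  invisible(x)
}

#' Sweep autoencoder widths and report held-out reconstruction errors
#'
#' For every bottleneck width `D` in `D_grid` and outer width `K` in
#' `K_grid`, pretrains and fine-tunes a five-layer autoencoder on each
#' training fold of `plan` and scores the held-out absolute reconstruction
#' error; the median across fits is recorded. For each `D` the `K` with the
#' minimum error is reported, mirroring how the reference widths were
#' picked. Configurations with `K <= D` are skipped (not a bottleneck).
#'
#' @param data Matrix in `[0, 1]`, samples in rows.
#' @param role `"spectrum"` or `"sensory"` (label only).
#' @param K_grid,D_grid Integer grids of outer and bottleneck widths.
#' @param config A [train_config()].
#' @param plan A [make_cv_plan()].
#' @return Data frame with one row per `D`: `D`, `K_best`, `error`; the full
#'   `D x K` median-error table is attached as attribute `"grid"`.
#' @export
dimension_sweep <- function(data, role = "spectrum", K_grid, D_grid,
                            config = train_config(),
                            plan = make_cv_plan(nrow(data))) {
  stopifnot(length(K_grid) >= 1, length(D_grid) >= 1)
  K_grid <- as.integer(K_grid)
  D_grid <- as.integer(D_grid)
  data <- as.matrix(data)
  grid <- matrix(NA_real_, length(D_grid), length(K_grid),
                 dimnames = list(as.character(D_grid), as.character(K_grid)))
  base_seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  for (di in seq_along(D_grid)) for (ki in seq_along(K_grid)) {
    D <- D_grid[di]; K <- K_grid[ki]
    if (K <= D) next
    arch <- suppressWarnings(ae_architecture(ncol(data), K, D, role))
    errs <- numeric(0)
    for (r in seq_len(plan$reps)) {
      folds <- plan$assignments[[r]]
      for (f in seq_len(plan$k)) {
        set.seed(base_seed + r * 1000L + f)
        model <- fit_autoencoder(data[folds != f, , drop = FALSE], arch,
                                 config)
        errs <- c(errs,
                  reconstruction_error(model, data[folds == f, , drop = FALSE]))
      }
    }
    grid[di, ki] <- median(errs[is.finite(errs)])
  }
  out <- data.frame(
    D = D_grid,
    K_best = vapply(seq_along(D_grid), function(di) {
      row <- grid[di, ]
      if (all(is.na(row))) NA_integer_ else K_grid[which.min(row)]
    }, 0L),
    error = vapply(seq_along(D_grid), function(di) {
      row <- grid[di, ]
      if (all(is.na(row))) NA_real_ else min(row, na.rm = TRUE)
    }, 0))
  attr(out, "grid") <- grid
  out
}
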