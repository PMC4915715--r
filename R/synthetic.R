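#' Synthetic-dataset configuration
#'
#' Describes a paper-shaped paired dataset: sparse nonnegative EI-like
#' spectra and bounded sensory profiles, both driven by a low-dimensional
#' latent variable through a known (recorded) link, so every pipeline stage
#' can be exercised and checked without any external download.
#'
#' @param n_samples Number of paired samples (default 121).
#' @param n_mz_bins Spectrum width (default 212, the 51-262 m/z window).
#' @param n_descriptors Sensory width (default 144).
#' @param latent_dim Dimension of the latent variable `z` (default 3).
#' @param peaks_per_spectrum Peaks retained per spectrum (default 10).
#' @param nonlinearity Link from `z` to the sensory profile:
#'   `"sigmoid-mixture"` (default; sparse convex mixture of saturating
#'   radial sigmoid units, each switching on inside a region of the latent
#'   space — smooth, bounded, and non-monotone, so the map has no good
#'   global linear approximation), `"linear"` (exactly affine on both
#'   blocks, the regime a linear method recovers perfectly), or `"rbf"`
#'   (sparse convex mixture of Gaussian bumps).
#' @param noise_sd Additive sensory noise standard deviation on the 0-1
#'   applicability scale; also scales the multiplicative log-normal spectrum
#'   noise (default 0.05).
#' @param outlier_frac Fraction of samples pushed far from the latent
#'   centroid (default 0; set to 0.05 to emulate hard-to-predict outliers).
#' @param seed Optional integer seed.
#' @return List with class `"synth_config"`.
#' @export
synth_config <- function(n_samples = 121, n_mz_bins = 212,
                         n_descriptors = 144, latent_dim = 3,
                         peaks_per_spectrum = 10,
                         nonlinearity = c("sigmoid-mixture", "linear", "rbf"),
                         noise_sd = 0.05, outlier_frac = 0, seed = NULL) {
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(n_samples >= 2, n_mz_bins >= 2, n_descriptors >= 1,
            latent_dim >= 1, peaks_per_spectrum >= 1, noise_sd >= 0,
            outlier_frac >= 0, outlier_frac < 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_mz_bins = as.integer(n_mz_bins),
                 n_descriptors = as.integer(n_descriptors),
                 latent_dim = as.integer(latent_dim),
                 peaks_per_spectrum = as.integer(peaks_per_spectrum),
                 nonlinearity = nonlinearity, noise_sd = noise_sd,
                 outlier_frac = outlier_frac, seed = seed),
            class = "synth_config")
}

#' Generate a paired synthetic spectrum/sensory dataset
#'
#' Draws a latent `z ~ N(0, I)` per sample and derives both blocks from it.
#' Spectra: a fixed set of candidate fragment bins (about four times
#' `peaks_per_spectrum`) receives bounded logistic latent-driven heights
#' with multiplicative log-normal noise; each sample keeps its
#' `peaks_per_spectrum` tallest peaks (compound-specific fragment sets, as
#' in real EI libraries), and the matrix is max-normalized.
#' Sensory: the configured link `g(z)` maps into `(0, 1)` by construction,
#' Gaussian noise is added, values are clipped to `[0, 1]` and the matrix is
#' max-normalized. In `"linear"` mode the spectra are affine-positive in `z`
#' with additive noise and no top-k gate, so the spectrum-to-sensory map is
#' exactly linear.
#'
#' @param cfg A [synth_config()].
#' @return List with `spectra` (`N x n_mz_bins`, in `[0, 1]`, global max 1),
#'   `sensory` (`N x n_descriptors`, in `[0, 1]`), and `truth` (latent `z`,
#'   active bins and all link parameters, for recovery checks).
#' @export
gen_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_samples; L <- cfg$latent_dim
  Z <- matrix(rnorm(n * L), n, L)
  if (cfg$outlier_frac > 0) {
    n_out <- max(1L, floor(cfg$outlier_frac * n))
    idx <- sample(n, n_out)
    Z[idx, ] <- 4 * Z[idx, , drop = FALSE]
  }

  n_active <- min(4L * cfg$peaks_per_spectrum, cfg$n_mz_bins)
  bins <- sort(sample(cfg$n_mz_bins, n_active))
  X <- matrix(0, n, cfg$n_mz_bins,
              dimnames = list(sprintf("synth-%03d", seq_len(n)),
                              as.character(seq_len(cfg$n_mz_bins) + 50L)))
  if (cfg$nonlinearity == "linear") {
    A <- matrix(rnorm(n_active * L, sd = 0.5), n_active, L)
    c0 <- runif(n_active, 3, 6)
    H <- sweep(Z %*% t(A), 2, c0, "+")
    if (cfg$noise_sd > 0)
      H <- H + matrix(rnorm(n * n_active, sd = cfg$noise_sd), n, n_active)
    H[H < 0.01] <- 0.01
    X[, bins] <- H
  } else {
    A <- matrix(rnorm(n_active * L, sd = 0.8), n_active, L)
    c0 <- rnorm(n_active)
    # bounded logistic heights: smooth in z without the extreme dynamic
    # range of log-linear intensities, which a single global max-
    # normalization would otherwise crush to near-zero
    H <- sigmoid(sweep(Z %*% t(A), 2, c0, "+"))
    if (cfg$noise_sd > 0)
      H <- H * exp(matrix(rnorm(n * n_active, sd = cfg$noise_sd),
                          n, n_active))
    keep_k <- min(cfg$peaks_per_spectrum, n_active)
    for (i in seq_len(n)) {
      thr <- sort(H[i, ], decreasing = TRUE)[keep_k]
      H[i, H[i, ] < thr] <- 0
    }
    X[, bins] <- H
  }
  X <- normalize_max(X)

  # Both nonlinear links use localized (radial) mixture components: a
  # monotone ridge function correlates ~0.8 with its own best linear
  # approximation under a Gaussian latent, so only non-monotone components
  # give a nonlinear model a genuine advantage over a linear baseline.
  n_mix <- 8L
  sparse_loadings <- function() {
    V <- matrix(rgamma(cfg$n_descriptors * n_mix, shape = 0.3),
                cfg$n_descriptors, n_mix)
    V / rowSums(V)
  }
  link <- switch(cfg$nonlinearity,
    "linear" = {
      G <- matrix(rnorm(cfg$n_descriptors * L), cfg$n_descriptors, L)
      raw <- Z %*% t(G)
      list(G = G, scale = max(abs(raw)))
    },
    "sigmoid-mixture" = {
      list(C = matrix(rnorm(n_mix * L), n_mix, L), gain = 4, radius = 1,
           V = sparse_loadings())
    },
    "rbf" = {
      list(C = matrix(rnorm(n_mix * L), n_mix, L), len = 1,
           V = sparse_loadings())
    })
  latent_dist <- function(C) {
    sqrt(pmax(outer(rowSums(Z^2), rowSums(C^2), "+") - 2 * Z %*% t(C), 0))
  }
  Y0 <- switch(cfg$nonlinearity,
    "linear" = 0.5 + 0.45 * (Z %*% t(link$G)) / link$scale,
    "sigmoid-mixture" = {
      S <- sigmoid(link$gain * (link$radius - latent_dist(link$C)))
      S %*% t(link$V)
    },
    "rbf" = {
      exp(-latent_dist(link$C)^2 / (2 * link$len^2)) %*% t(link$V)
    })
  if (cfg$noise_sd > 0)
    Y0 <- Y0 + matrix(rnorm(length(Y0), sd = cfg$noise_sd), nrow(Y0))
  Y0[Y0 < 0] <- 0; Y0[Y0 > 1] <- 1
  Y <- normalize_max(Y0)
  dimnames(Y) <- list(rownames(X),
                      sprintf("descriptor_%03d", seq_len(cfg$n_descriptors)))
  list(spectra = X, sensory = Y,
       truth = list(z = Z, active_bins = bins, link = link,
                    nonlinearity = cfg$nonlinearity))
}

#' Curved one-dimensional manifold data for compression benchmarks
#'
#' Samples points along a smooth closed curve embedded in a
#' higher-dimensional space (random harmonics of a circular parameter),
#' with small additive noise, scaled into `[0, 1]`. The intrinsic dimension
#' is 1 but the curve is not contained in any low-dimensional linear
#' subspace, which is the regime where a nonlinear compressor (autoencoder
#' bottleneck) beats PCA at a matched number of components.
#'
#' @param n Number of samples.
#' @param ambient_dim Embedding dimension (default 20).
#' @param noise_sd Additive noise before rescaling (default 0.02).
#' @param seed Optional integer seed.
#' @return Matrix `n x ambient_dim` with entries in `[0, 1]`.
#' @export
gen_curved_manifold <- function(n = 120, ambient_dim = 20, noise_sd = 0.02,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- runif(n, 0, 2 * pi)
  k <- sample(1:3, ambient_dim, replace = TRUE)
  phi <- runif(ambient_dim, 0, 2 * pi)
  amp <- runif(ambient_dim, 0.5, 1)
  X <- sapply(seq_len(ambient_dim), function(j) amp[j] * sin(k[j] * t + phi[j]))
  X <- X + matrix(rnorm(n * ambient_dim, sd = noise_sd), n)
  X <- 0.5 + 0.4 * X / max(abs(X))
  X
}

#' Tiny hand-checkable paired fixture
#'
#' Eight samples, ten m/z bins and five descriptors with fixed constants
#' embedded in code — small enough that windowing, normalization, absolute
#' reconstruction error and Pearson R can be verified against hand sums.
#'
#' @return List with unnormalized `spectra` (8 x 10, integer counts, m/z
#'   columns 51-60) and `sensory` (8 x 5, in `[0, 1]`).
#' @export
gen_toy_fixture <- function() {
  spectra <- matrix(c(
    0, 40,  0, 100,  0, 15,  0,  0,  5,  0,
    10,  0, 60,   0, 80,  0,  0, 20,  0,  0,
    0,  0,  0,  30,  0, 90,  0,  0, 45,  0,
    25,  5,  0,   0, 70,  0, 35,  0,  0, 10,
    0, 55,  0,  65,  0,  0,  0, 85,  0,  0,
    15,  0, 95,   0,  0, 40,  0,  0, 60,  0,
    0, 20,  0,  50,  0,  0, 75,  0,  0, 30,
    5,  0, 35,   0, 25,  0,  0, 55,  0, 80),
    nrow = 8, byrow = TRUE,
    dimnames = list(sprintf("toy-%d", 1:8), as.character(51:60)))
  sensory <- matrix(c(
    0.2, 0.0, 0.8, 0.1, 0.5,
    0.9, 0.3, 0.0, 0.4, 0.2,
    0.1, 0.7, 0.2, 1.0, 0.0,
    0.6, 0.5, 0.4, 0.3, 0.8,
    0.0, 0.9, 0.6, 0.2, 0.3,
    0.4, 0.1, 1.0, 0.0, 0.7,
    0.8, 0.6, 0.3, 0.5, 0.1,
    0.3, 0.2, 0.5, 0.7, 0.9),
    nrow = 8, byrow = TRUE,
    dimnames = list(sprintf("toy-%d", 1:8), paste0("descr_", 1:5)))
  list(spectra = spectra, sensory = sensory)
}
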