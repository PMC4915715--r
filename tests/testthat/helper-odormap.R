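# Shared test utilities: independent finite-difference gradient oracle and
# small dataset builders.

# Central finite differences of the per-sample loss over every weight and
# bias. Deliberately built on net_forward()/sample_loss() only, so it stays
# independent of the backpropagation path it checks.
fd_gradients <- function(params, x, target, lambda_l1 = 0, h = 1e-6) {
  loss_at <- function(p) {
    act <- net_forward(p, x)
    sample_loss(act[[length(act)]], target, p, lambda_l1)
  }
  gW <- lapply(params$W, function(w) w * 0)
  gb <- lapply(params$b, function(v) v * 0)
  for (l in seq_along(params$W)) {
    for (k in seq_along(params$W[[l]])) {
      pp <- params; pp$W[[l]][k] <- pp$W[[l]][k] + h
      pm <- params; pm$W[[l]][k] <- pm$W[[l]][k] - h
      gW[[l]][k] <- (loss_at(pp) - loss_at(pm)) / (2 * h)
    }
    for (k in seq_along(params$b[[l]])) {
      pp <- params; pp$b[[l]][k] <- pp$b[[l]][k] + h
      pm <- params; pm$b[[l]][k] <- pm$b[[l]][k] - h
      gb[[l]][k] <- (loss_at(pp) - loss_at(pm)) / (2 * h)
    }
  }
  list(W = gW, b = gb)
}

grad_rel_err <- function(g1, g2) {
  v1 <- c(unlist(g1$W), unlist(g1$b))
  v2 <- c(unlist(g2$W), unlist(g2$b))
  sqrt(sum((v1 - v2)^2)) / max(sqrt(sum(v2^2)), 1e-8)
}

# Small paired dataset for pipeline tests (dimensions kept tiny on purpose).
tiny_dataset <- function(seed = 1, n = 16) {
  gen_dataset(synth_config(n_samples = n, n_mz_bins = 16, n_descriptors = 6,
                           latent_dim = 2, peaks_per_spectrum = 4,
                           seed = seed))
}

# A zeroed network: every non-input activation is sigmoid(0) = 0.5.
zero_net <- function(sizes) {
  p <- net_params(sizes, 0.01)
  p$W <- lapply(p$W, function(w) w * 0)
  p$b <- lapply(p$b, function(v) v * 0)
  p
}

# Untrained (epochs = 0) autoencoder of the given architecture: the greedy
# copy structure is present but no training has run — cheap scaffolding for
# structural tests.
blank_ae <- function(M, K, D, role = "spectrum", seed = 1) {
  set.seed(seed)
  cfg0 <- train_config(epochs = 0)
  data <- matrix(runif(4 * M), 4, M)
  suppressWarnings(pretrain_ae5(data, ae_architecture(M, K, D, role), cfg0))
}
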