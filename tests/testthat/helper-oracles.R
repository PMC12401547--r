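# Small fixtures and independent reference implementations used as oracles.

# A tiny fully specified grid with hand-set covariates.
tiny_grid <- function(rows = 2, cols = 2, ncov = 1, area = 1, seed = 11,
                      mask = NULL) {
  set.seed(seed)
  n <- rows * cols
  covs <- matrix(round(rnorm(n * ncov), 2), n, ncov)
  colnames(covs) <- paste0("env", seq_len(ncov))
  cell_grid(rows, cols, covs, bias = round(rnorm(n), 2), area = area,
            mask = mask)
}

# Brute-force marginal likelihood of detection histories: enumerate every
# latent occupancy configuration Z over the surveyed cells and sum
# P(histories | Z) P(Z). Independent of the analytic marginalization.
brute_pa_loglik <- function(histories, grid, beta, alpha) {
  if (nrow(histories) == 0L) return(0)
  keep <- !grid$mask
  X <- cbind(1, grid$covariates[keep, , drop = FALSE])
  pos <- match(histories$cell_id, which(keep))
  lam <- exp(drop(X[pos, , drop = FALSE] %*% beta))
  mu <- lam * grid$area[keep][pos]
  psi <- 1 - exp(-mu)
  p <- plogis(alpha)
  m <- nrow(histories)
  total <- 0
  for (code in 0:(2^m - 1)) {
    z <- as.integer(intToBits(code))[seq_len(m)]
    pr <- prod(ifelse(z == 1, psi, 1 - psi))
    like <- 1
    for (j in seq_len(m)) {
      d <- histories$detections[j]; w <- histories$nights[j]
      pj <- p * z[j]
      like <- like * pj^d * (1 - pj)^(w - d)
    }
    total <- total + pr * like
  }
  log(total)
}

# Independent re-implementation of the joint log-likelihood with plain
# per-cell loops (no shared code with the package internals).
brute_joint_loglik <- function(po_cells, histories, grid, params) {
  keep <- which(!grid$mask)
  ll_po <- 0
  for (k in keep) {
    x <- c(1, grid$covariates[k, ])
    lam <- exp(sum(x * params$beta))
    b <- 1 / (1 + exp(-(params$delta[1] + params$delta[2] * grid$bias[k])))
    ll_po <- ll_po - lam * b * grid$area[k]
  }
  for (k in po_cells) {
    x <- c(1, grid$covariates[k, ])
    lam <- exp(sum(x * params$beta))
    b <- 1 / (1 + exp(-(params$delta[1] + params$delta[2] * grid$bias[k])))
    ll_po <- ll_po + log(lam * b)
  }
  ll_po + brute_pa_loglik(histories, grid, params$beta, params$alpha)
}

# Short MCMC schedule for desk-scale fits in tests.
test_mcmc <- function(seed = 1L, chains = 2L) {
  mcmc_config(n_chains = chains, adaptation_steps = 600, burn_in = 600,
              sampling_steps = 1800, thin = 3, rng_seed = seed)
}

# Compact simulation conditions for plumbing tests (not the standard scale).
small_config <- function(...) {
  sim_config(grid_rows = 30, grid_cols = 30, true_beta = c(-1, 0.75, -0.5),
             n_binary = 0, n_cameras = 25, n_clusters = 5,
             cameras_per_cluster = 5, covariate_smoothness = 3, ...)
}

# Row-major fine-to-coarse cell mapping, independent of the package internals.
coarsen_cells_for_test <- function(cell_id, grid, f) {
  r <- (cell_id - 1L) %/% grid$cols + 1L
  cc <- (cell_id - 1L) %% grid$cols + 1L
  (ceiling(r / f) - 1L) * ceiling(grid$cols / f) + ceiling(cc / f)
}
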