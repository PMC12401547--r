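#' MCMC configuration
#'
#' Chain schedule for the adaptive Metropolis-within-Gibbs sampler. The
#' defaults are the production schedule: 4 chains with a 1000-step
#' adaptation phase, a 10,000-step burn-in and 25,000 sampling steps
#' thinned by 5, retaining 5000 draws per chain (20,000 in total).
#'
#' @param n_chains Number of chains.
#' @param adaptation_steps Steps during which per-parameter proposal widths
#'   are tuned toward `target_acceptance` and then frozen.
#' @param burn_in Discarded post-adaptation steps.
#' @param sampling_steps Retained-phase steps; must be divisible by `thin`.
#' @param thin Thinning interval.
#' @param rng_seed Integer seed; chain `c` uses `rng_seed + c`.
#' @param target_acceptance Adaptation target for per-parameter acceptance.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, adaptation_steps = 1000,
                        burn_in = 10000, sampling_steps = 25000, thin = 5,
                        rng_seed = 1L, target_acceptance = 0.44) {
  if (sampling_steps %% thin != 0)
    stop("sampling_steps must be divisible by thin", call. = FALSE)
  structure(
    list(n_chains = as.integer(n_chains),
         adaptation_steps = as.integer(adaptation_steps),
         burn_in = as.integer(burn_in),
         sampling_steps = as.integer(sampling_steps),
         thin = as.integer(thin), rng_seed = as.integer(rng_seed),
         target_acceptance = target_acceptance),
    class = "mcmc_config")
}

#' Retained posterior draws implied by a schedule
#'
#' @param config An [mcmc_config].
#' @return `n_chains * sampling_steps / thin`.
#' @export
retained_draws <- function(config) {
  config$n_chains * (config$sampling_steps %/% config$thin)
}

# Flatten model inputs for the compiled sampler.
build_model_data <- function(po, histories, grid) {
  keep <- !grid$mask
  X <- design_matrix(grid)
  unmasked_ids <- which(keep)
  include_po <- !is.null(po)
  cells <- po_cells(po)
  if (length(cells) && any(grid$mask[cells]))
    stop("presence-only point in a masked cell", call. = FALSE)
  po_tab <- table(factor(cells, levels = unmasked_ids))
  po_idx <- which(po_tab > 0)
  po_n <- as.numeric(po_tab[po_idx])
  if (!is.null(histories) && nrow(histories) > 0L) {
    if (anyDuplicated(histories$cell_id))
      stop("at most one detection history per cell (subsample first)",
           call. = FALSE)
    if (any(histories$detections > histories$nights))
      stop("invalid history: detections exceed nights", call. = FALSE)
    pa_cell <- match(histories$cell_id, unmasked_ids)
    if (anyNA(pa_cell))
      stop("detection history in a masked cell", call. = FALSE)
    pa_d <- as.numeric(histories$detections)
    pa_w <- as.numeric(histories$nights)
  } else {
    pa_cell <- integer(0); pa_d <- numeric(0); pa_w <- numeric(0)
  }
  list(X = X, area = grid$area[keep], bias = grid$bias[keep],
       po_idx = as.integer(po_idx - 1L), po_n = po_n,
       include_po = include_po,
       pa_cell = as.integer(pa_cell - 1L), pa_d = pa_d, pa_w = pa_w,
       cov_names = colnames(grid$covariates))
}

#' Fit the integrated model by MCMC
#'
#' Posterior sampling of the intensity coefficients, thinning parameters
#' and detection intercept by adaptive Gaussian random-walk
#' Metropolis-within-Gibbs on the joint log-posterior. Per-parameter step
#' sizes are tuned during the adaptation phase (Robbins-Monro, toward the
#' target acceptance rate) and frozen afterwards. Chains start from
#' independent prior draws unless `init` is given, providing the
#' overdispersion the Gelman-Rubin diagnostic needs.
#'
#' Passing `po = NULL` or `histories = NULL` omits that likelihood
#' component entirely (a zero-length presence-only set, by contrast, still
#' contributes its void-probability term).
#'
#' @param po Presence-only points (cell ids or data frame with `cell_id`),
#'   or `NULL`.
#' @param histories Per-cell detection histories (`cell_id`, `nights`,
#'   `detections`), or `NULL`.
#' @param grid A [cell_grid] with standardized covariates.
#' @param config An [mcmc_config].
#' @param init Optional [model_params] used to start every chain.
#' @param beta_prior_sd Prior standard deviation for the intensity
#'   coefficients.
#' @return An object of class `isdm_fit`: list with `draws` (array chains x
#'   retained x parameters), `parameter_names`, `rhat`, `acceptance`
#'   (chains x parameters), `config` and `cov_names`.
#' @export
run_mcmc <- function(po, histories, grid, config = mcmc_config(),
                     init = NULL, beta_prior_sd = 2.5) {
  stopifnot(inherits(config, "mcmc_config"))
  md <- build_model_data(po, histories, grid)
  p <- ncol(md$X)
  npar <- p + 3L
  par_names <- c("beta0", paste0("beta_", md$cov_names), "delta0", "delta1",
                 "alpha")
  n_keep <- config$sampling_steps %/% config$thin
  draws <- array(NA_real_, c(config$n_chains, n_keep, npar),
                 dimnames = list(NULL, NULL, par_names))
  acceptance <- matrix(NA_real_, config$n_chains, npar,
                       dimnames = list(NULL, par_names))
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$rng_seed + ch)
    theta0 <- chain_init(init, p, beta_prior_sd, md)
    res <- run_chain_cpp(md$X, md$area, md$bias, md$po_idx, md$po_n,
                         md$include_po, md$pa_cell, md$pa_d, md$pa_w,
                         theta0, config$adaptation_steps, config$burn_in,
                         config$sampling_steps, config$thin,
                         config$target_acceptance, beta_prior_sd)
    draws[ch, , ] <- res$draws
    acceptance[ch, ] <- res$acceptance
  }
  fit <- structure(
    list(draws = draws, parameter_names = par_names, rhat = NULL,
         acceptance = acceptance, config = config, cov_names = md$cov_names,
         scaler = attr(grid, "scaler")),
    class = "isdm_fit")
  if (config$n_chains >= 2L && n_keep >= 10L) fit$rhat <- gelman_rubin(fit)
  fit
}

# Draw a finite-posterior starting point: prior draws, retried up to 100
# times if the joint log-posterior is not finite there.
chain_init <- function(init, p, beta_prior_sd, md) {
  if (!is.null(init)) {
    return(c(init$beta, init$delta, init$alpha))
  }
  for (i in 1:100) {
    theta <- c(stats::rnorm(p, 0, beta_prior_sd), stats::rlogis(2),
               stats::rlogis(1))
    eta <- drop(md$X %*% theta[1:p])
    lam <- exp(eta)
    if (any(!is.finite(lam))) next
    b <- stats::plogis(theta[p + 1] + theta[p + 2] * md$bias)
    ll <- 0
    if (md$include_po)
      ll <- sum(md$po_n * (log(lam[md$po_idx + 1]) + log(b[md$po_idx + 1]))) -
        sum(lam * b * md$area)
    if (length(md$pa_cell)) {
      mu <- lam[md$pa_cell + 1] * md$area[md$pa_cell + 1]
      psi <- -expm1(-mu)
      pdet <- stats::plogis(theta[p + 3])
      contrib <- ifelse(md$pa_d > 0,
                        log(psi) + md$pa_d * log(pdet) +
                          (md$pa_w - md$pa_d) * log1p(-pdet),
                        log(exp(-mu) + psi * (1 - pdet)^md$pa_w))
      ll <- ll + sum(contrib)
    }
    if (is.finite(ll)) return(theta)
  }
  stop("initialization error: no finite log-posterior in 100 prior draws",
       call. = FALSE)
}

#' Split Gelman-Rubin diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift also registers as disagreement. Constant
#' chains (zero within-chain variance everywhere) report 1 by convention.
#'
#' @param fit An `isdm_fit`, or an array chains x draws x parameters.
#' @return Named vector of per-parameter split R-hat values.
#' @export
gelman_rubin <- function(fit) {
  a <- if (inherits(fit, "isdm_fit")) fit$draws else fit
  if (length(dim(a)) != 3L) stop("draws must be chains x draws x parameters",
                                 call. = FALSE)
  n_chains <- dim(a)[1]; n_draws <- dim(a)[2]; npar <- dim(a)[3]
  if (n_chains < 2L)
    stop("diagnostic error: at least 2 chains required", call. = FALSE)
  if (n_draws < 10L)
    stop("diagnostic error: at least 10 draws per chain required",
         call. = FALSE)
  half <- n_draws %/% 2L
  out <- numeric(npar)
  for (j in seq_len(npar)) {
    segs <- vector("list", 2L * n_chains)
    for (ch in seq_len(n_chains)) {
      segs[[2 * ch - 1]] <- a[ch, seq_len(half), j]
      segs[[2 * ch]] <- a[ch, seq.int(n_draws - half + 1L, n_draws), j]
    }
    means <- vapply(segs, mean, 0)
    vars <- vapply(segs, stats::var, 0)
    W <- mean(vars)
    B <- half * stats::var(means)
    if (W == 0) {
      out[j] <- 1
    } else {
      var_plus <- (half - 1) / half * W + B / half
      out[j] <- sqrt(var_plus / W)
    }
  }
  names(out) <- if (inherits(fit, "isdm_fit")) fit$parameter_names else
    dimnames(a)[[3]]
  out
}

# Flatten draws across chains into a matrix (draws x parameters).
flatten_draws <- function(fit) {
  a <- fit$draws
  m <- matrix(aperm(a, c(2, 1, 3)), dim(a)[1] * dim(a)[2], dim(a)[3])
  colnames(m) <- fit$parameter_names
  m
}

#' Posterior summary table
#'
#' Per-parameter posterior median, central 95% credible interval
#' (type-7 linearly interpolated quantiles), an evidence flag (interval
#' excludes zero), the split R-hat and the mean post-adaptation acceptance
#' rate. The `converged` attribute is `TRUE` when every R-hat is below
#' 1.05.
#'
#' @param object An `isdm_fit`.
#' @param prob Credible-interval mass.
#' @param ... Unused.
#' @return Data frame, one row per parameter.
#' @export
summary.isdm_fit <- function(object, prob = 0.95, ...) {
  m <- flatten_draws(object)
  lo <- (1 - prob) / 2
  qs <- apply(m, 2, stats::quantile, probs = c(lo, 0.5, 1 - lo), type = 7)
  out <- data.frame(
    parameter = object$parameter_names,
    median = qs[2, ],
    lower = qs[1, ],
    upper = qs[3, ],
    excludes_zero = qs[1, ] > 0 | qs[3, ] < 0,
    rhat = if (is.null(object$rhat)) NA_real_ else object$rhat,
    acceptance = colMeans(object$acceptance),
    row.names = NULL)
  attr(out, "converged") <- !is.null(object$rhat) && all(object$rhat < 1.05)
  out
}

#' @export
print.isdm_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("<isdm_fit> %d chains x %d retained draws x %d parameters\n",
              d[1], d[2], d[3]))
  if (!is.null(x$rhat))
    cat(sprintf("  max split R-hat: %.3f (%s)\n", max(x$rhat),
                if (all(x$rhat < 1.05)) "converged" else "NOT converged"))
  invisible(x)
}
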