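#' Intensity of the latent point process
#'
#' The expected number of individuals per hectare at a cell, log-linear in
#' the environmental covariates: `lambda = exp(beta %*% c(1, x))`.
#'
#' @param x Covariate vector for one cell (without intercept), or a matrix
#'   with one row per cell.
#' @param beta Coefficient vector, intercept first; length must be
#'   `1 + ncol(x)`.
#' @return Positive intensity value(s).
#' @export
intensity <- function(x, beta) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (length(beta) != 1L + ncol(x))
    stop("beta must have length 1 + number of covariates", call. = FALSE)
  eta <- drop(cbind(1, x) %*% beta)
  lam <- exp(eta)
  if (any(!is.finite(lam)))
    stop("intensity overflow: standardize covariates or shrink beta",
         call. = FALSE)
  lam
}

#' Expected abundance of a cell
#'
#' Discretized intensity integral: `mu_k = lambda_k * A_k`. Summing over
#' cells approximates the expected total abundance over the extent.
#'
#' @param lambda Intensity (per hectare).
#' @param area Cell area in hectares.
#' @return Expected count `mu_k`.
#' @export
expected_cell_abundance <- function(lambda, area) {
  if (any(area <= 0)) stop("area must be positive", call. = FALSE)
  lambda * area
}

#' Occupancy probability from expected abundance
#'
#' Probability that a cell holds at least one individual when the latent
#' count is Poisson with mean `mu`: `psi = 1 - exp(-mu)`. This is the
#' saturating abundance-occupancy link: near-linear for small `mu`,
#' approaching 1 as `mu` grows.
#'
#' @param mu Nonnegative expected cell abundance.
#' @return Occupancy probability in `[0, 1)`.
#' @export
occupancy_prob <- function(mu) {
  if (any(mu < 0)) stop("mu must be nonnegative", call. = FALSE)
  -expm1(-mu)
}

#' Presence-only thinning probability
#'
#' Probability that a truly present individual enters the sighting record,
#' absorbing observation bias (e.g. proximity to roads):
#' `b = plogis(delta[1] + delta[2] * bias)`.
#'
#' @param bias Observation-bias covariate value(s).
#' @param delta Length-2 vector: logit intercept and bias slope.
#' @return Thinning probability in `(0, 1)`.
#' @export
thinning_prob <- function(bias, delta) {
  if (length(delta) != 2L) stop("delta must have length 2", call. = FALSE)
  stats::plogis(delta[1] + delta[2] * bias)
}

#' Camera detection probability
#'
#' Per-night detection probability given an occupied cell, constant across
#' cameras and nights: `p = plogis(alpha)`.
#'
#' @param alpha Logit-scale detection intercept.
#' @return Detection probability.
#' @export
detection_prob <- function(alpha) stats::plogis(alpha)

#' Presence-only log-likelihood (thinned Poisson point process)
#'
#' Discretized log-likelihood of the sighting records under the thinned
#' inhomogeneous Poisson process:
#' `sum_i log(lambda_k(i) * b_k(i)) - sum_k lambda_k * b_k * A_k`,
#' where the first sum runs over points and the second over unmasked cells.
#'
#' @param po Presence-only points: integer cell ids or a data frame with a
#'   `cell_id` column. May be empty.
#' @param grid A [cell_grid].
#' @param beta Intensity coefficients (intercept first).
#' @param delta Thinning parameters (length 2).
#' @return Log-likelihood value.
#' @export
po_loglik <- function(po, grid, beta, delta) {
  cells <- po_cells(po)
  if (length(cells) && any(grid$mask[cells]))
    stop("presence-only point in a masked cell", call. = FALSE)
  keep <- !grid$mask
  lam <- intensity(grid$covariates[keep, , drop = FALSE], beta)
  b <- thinning_prob(grid$bias[keep], delta)
  void <- sum(lam * b * grid$area[keep])
  if (length(cells) == 0L) return(-void)
  # map fine cell ids to their position among unmasked cells
  pos <- match(cells, which(keep))
  sum(log(lam[pos]) + log(b[pos])) - void
}

#' Presence-absence log-likelihood (occupancy with imperfect detection)
#'
#' Marginal log-likelihood of per-cell detection histories with the latent
#' occupancy state summed out analytically. For a surveyed cell with `d`
#' detections over `w` nights, occupancy probability `psi` and detection
#' probability `p`, the contribution is
#' `log(psi * p^d * (1-p)^(w-d) + (1-psi) * I(d == 0))`.
#'
#' @param histories Data frame with one row per surveyed cell: columns
#'   `cell_id`, `nights`, `detections`. At most one row per cell.
#'   `detections` may be fractional (mean-aggregated histories) but must not
#'   exceed `nights`.
#' @param grid A [cell_grid].
#' @param beta Intensity coefficients.
#' @param alpha Detection intercept (logit scale).
#' @return Log-likelihood value.
#' @export
pa_loglik <- function(histories, grid, beta, alpha) {
  if (is.null(histories) || nrow(histories) == 0L) return(0)
  if (anyDuplicated(histories$cell_id))
    stop("at most one detection history per cell (subsample first)",
         call. = FALSE)
  if (any(grid$mask[histories$cell_id]))
    stop("detection history in a masked cell", call. = FALSE)
  d <- histories$detections; w <- histories$nights
  if (any(d > w) || any(d < 0))
    stop("invalid history: detections must lie in [0, nights]", call. = FALSE)
  keep <- !grid$mask
  pos <- match(histories$cell_id, which(keep))
  lam <- intensity(grid$covariates[keep, , drop = FALSE][pos, , drop = FALSE],
                   beta)
  mu <- lam * grid$area[keep][pos]
  psi <- occupancy_prob(mu)
  logp <- stats::plogis(alpha, log.p = TRUE)
  log1mp <- stats::plogis(-alpha, log.p = TRUE)
  # occupied branch on the log scale; zero-detection histories add the
  # unoccupied branch (both mixture terms are in [0,1], safe to mix directly)
  occ <- log(psi) + d * logp + (w - d) * log1mp
  out <- ifelse(d > 0, occ, log(exp(-mu) + psi * exp(w * log1mp)))
  sum(out)
}

#' Joint log-likelihood of the integrated model
#'
#' The two data streams are assumed independent given the parameters, so the
#' joint likelihood is the product of the sub-model likelihoods; on the log
#' scale this is a sum.
#'
#' @param po Presence-only points (see [po_loglik]).
#' @param histories Per-cell detection histories (see [pa_loglik]).
#' @param grid A [cell_grid].
#' @param params A [model_params] object.
#' @return `po_loglik + pa_loglik`.
#' @export
joint_loglik <- function(po, histories, grid, params) {
  po_loglik(po, grid, params$beta, params$delta) +
    pa_loglik(histories, grid, params$beta, params$alpha)
}

#' Log-prior density of the model parameters
#'
#' Weakly informative defaults: independent Normal(0, 2.5) on the intensity
#' coefficients (log scale) and independent standard Logistic on the
#' logit-scale parameters (thinning intercept and slope, detection
#' intercept).
#'
#' @param params A [model_params] object.
#' @param beta_sd Prior standard deviation for the intensity coefficients.
#' @return Log-prior density.
#' @export
log_prior <- function(params, beta_sd = 2.5) {
  sum(stats::dnorm(params$beta, 0, beta_sd, log = TRUE)) +
    sum(stats::dlogis(params$delta, log = TRUE)) +
    stats::dlogis(params$alpha, log = TRUE)
}
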