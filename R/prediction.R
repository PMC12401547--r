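#' Posterior prediction of total abundance
#'
#' Samples parameter sets from the retained posterior draws (without
#' replacement) and, for each, sums the expected abundance
#' `lambda_k * A_k` over the unmasked cells of the prediction grid. The
#' grid must carry the same covariates (and scaler, if standardized) as
#' the fit.
#'
#' @param fit An `isdm_fit`.
#' @param grid A [cell_grid], standardized with the fit-time scaler.
#' @param n_draws Number of posterior parameter sets (capped at the number
#'   retained).
#' @param seed Integer seed for the subsample.
#' @param quantile_levels Quantiles reported alongside the median.
#' @return An object of class `abundance_prediction`: list with `totals`,
#'   `median`, `quantiles`, `aggregation_factor`, `cell_area`, `n_draws`.
#' @export
predict_abundance <- function(fit, grid, n_draws = 1000, seed = 1L,
                              quantile_levels = c(0.025, 0.25, 0.5, 0.75,
                                                  0.975)) {
  gnames <- colnames(grid$covariates)
  if (is.null(gnames)) gnames <- character(0)
  if (!identical(fit$cov_names, gnames))
    stop("prediction error: grid covariates do not match the fit",
         call. = FALSE)
  if (!is.null(fit$scaler) &&
      !identical(fit$scaler$names, attr(grid, "scaler")$names))
    stop("prediction error: grid scaler does not match the fit",
         call. = FALSE)
  m <- flatten_draws(fit)
  set.seed(seed)
  take <- if (n_draws >= nrow(m)) seq_len(nrow(m)) else
    sample.int(nrow(m), n_draws)
  keep <- !grid$mask
  X <- design_matrix(grid)
  p <- ncol(X)
  betas <- m[take, seq_len(p), drop = FALSE]
  # totals: for each draw, sum_k exp(X beta) * A_k
  lam <- exp(X %*% t(betas))
  totals <- as.numeric(crossprod(lam, grid$area[keep]))
  fct <- attr(grid, "aggregation_factor")
  structure(
    list(totals = totals,
         median = stats::median(totals),
         quantiles = stats::quantile(totals, quantile_levels, type = 7),
         aggregation_factor = if (is.null(fct)) 1L else fct,
         cell_area = max(grid$area[keep]),
         n_draws = length(totals)),
    class = "abundance_prediction")
}

#' @export
print.abundance_prediction <- function(x, ...) {
  cat(sprintf(
    "<abundance_prediction> median %.0f (95%% interval %.0f-%.0f), %d draws, cell area %.0f ha\n",
    x$median, x$quantiles[["2.5%"]], x$quantiles[["97.5%"]], x$n_draws,
    x$cell_area))
  invisible(x)
}

#' Posterior detectability estimate
#'
#' Back-transforms the detection intercept draws through the inverse logit
#' and reports the posterior median and central credible interval as
#' percentages. Because the link is monotone, the median of the
#' transformed draws equals the transform of the median.
#'
#' @param fit An `isdm_fit`.
#' @param prob Credible-interval mass.
#' @return Named vector (percent): `median`, `lower`, `upper`.
#' @export
detectability_estimate <- function(fit, prob = 0.95) {
  m <- flatten_draws(fit)
  p <- stats::plogis(m[, "alpha"])
  lo <- (1 - prob) / 2
  qs <- stats::quantile(p, c(lo, 0.5, 1 - lo), type = 7)
  100 * c(median = unname(qs[2]), lower = unname(qs[1]),
          upper = unname(qs[3]))
}

#' Density-times-area abundance extrapolation
#'
#' Simple range-wide extrapolation: habitat area multiplied by a density
#' estimate, rounded to the nearest individual.
#'
#' @param area Habitat area, hectares.
#' @param density Individuals per hectare.
#' @return Extrapolated individuals (integer-valued numeric).
#' @export
extrapolate_abundance <- function(area, density) {
  if (any(area < 0) || any(density < 0))
    stop("area and density must be nonnegative", call. = FALSE)
  round(area * density)
}

#' Compare abundance predictions across home-range scenarios
#'
#' Assembles one row per aggregation factor (home-range scenario) with the
#' cell area, posterior median and interval bounds of total abundance.
#'
#' @param predictions List of [predict_abundance] results, one per
#'   aggregation factor.
#' @return Data frame with columns `factor`, `cell_area`, `median` and one
#'   column per reported quantile.
#' @export
scenario_table <- function(predictions) {
  fcts <- vapply(predictions, function(p) as.integer(p$aggregation_factor),
                 0L)
  if (anyDuplicated(fcts))
    stop("table error: duplicate aggregation factors", call. = FALSE)
  qmat <- do.call(rbind, lapply(predictions, function(p) p$quantiles))
  out <- data.frame(
    factor = fcts,
    cell_area = vapply(predictions, function(p) p$cell_area, 0),
    median = vapply(predictions, function(p) p$median, 0))
  out <- cbind(out, as.data.frame(qmat, check.names = FALSE))
  out[order(out$factor), , drop = FALSE]
}
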