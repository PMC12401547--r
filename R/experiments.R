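#' Prepare one simulated survey at a working resolution and fit the model
#'
#' Aggregates the landscape to the requested factor, maps the sighting
#' records to coarse cells, subsamples the cameras with the given method
#' and runs the MCMC. If the fit fails the convergence gate (any split
#' R-hat at or above 1.05) it is re-run once with a fresh seed and flagged.
#'
#' @param sim A simulated survey from [simulate_survey].
#' @param factor Aggregation factor (1 = native resolution).
#' @param method Camera subsampling method (see [assign_and_subsample]).
#' @param mcmc An [mcmc_config].
#' @return List with `fit`, `summary`, `grid` (working grid), `po_cells`,
#'   `histories`, `converged` (logical), `reran` (logical).
#' @export
fit_simulated_survey <- function(sim, factor = 1L,
                                 method = c("max", "mean", "sum"),
                                 mcmc = mcmc_config()) {
  method <- match.arg(method)
  spec <- aggregation_spec(factor, method,
                           base_pixel_area = sim$grid$area[1])
  grid_f <- aggregate_grid(sim$grid, spec)
  po_c <- coarsen_cells(sim$po$cell_id, sim$grid$rows, sim$grid$cols,
                        spec$factor)
  hist_f <- assign_and_subsample(sim$histories, sim$grid, spec)
  fit <- run_mcmc(po_c, hist_f, grid_f, mcmc)
  reran <- FALSE
  if (!is.null(fit$rhat) && any(fit$rhat >= 1.05)) {
    mcmc2 <- mcmc
    mcmc2$rng_seed <- mcmc$rng_seed + 7777L
    fit <- run_mcmc(po_c, hist_f, grid_f, mcmc2)
    reran <- TRUE
  }
  list(fit = fit, summary = summary(fit), grid = grid_f, po_cells = po_c,
       histories = hist_f,
       converged = is.null(fit$rhat) || all(fit$rhat < 1.05), reran = reran)
}

# Number of coarse cells whose aggregated latent count is positive.
occupied_cells_truth <- function(truth, grid, factor) {
  coarse <- coarsen_cells(seq_len(grid$n_cells), grid$rows, grid$cols,
                          factor)
  sum(tapply(truth$latent_N, coarse, sum) > 0)
}

# Posterior summary of the expected number of occupied cells and of total
# abundance on the working grid, from a subsample of draws.
derived_posteriors <- function(fit, grid, n_draws = 400, seed = 1L) {
  m <- flatten_draws(fit)
  set.seed(seed)
  take <- if (n_draws >= nrow(m)) seq_len(nrow(m)) else
    sample.int(nrow(m), n_draws)
  keep <- !grid$mask
  X <- design_matrix(grid)
  lam <- exp(X %*% t(m[take, seq_len(ncol(X)), drop = FALSE]))
  mu <- lam * grid$area[keep]
  totals <- colSums(mu)
  occ <- colSums(1 - exp(-mu))
  list(total = stats::quantile(totals, c(0.025, 0.5, 0.975), type = 7),
       occupied = stats::quantile(occ, c(0.025, 0.5, 0.975), type = 7))
}

# Tidy rows for one fitted replicate: one row per parameter plus the two
# derived metrics.
replicate_rows <- function(scenario, replicate, res, sim, true_params,
                           factor) {
  s <- res$summary
  truth_vec <- c(true_params$beta, true_params$delta, true_params$alpha)
  rows <- data.frame(
    scenario = scenario, replicate = replicate, metric = s$parameter,
    truth = truth_vec, estimate = s$median, lower = s$lower,
    upper = s$upper,
    covered = s$lower <= truth_vec & truth_vec <= s$upper,
    width = s$upper - s$lower, converged = res$converged)
  dp <- derived_posteriors(res$fit, res$grid)
  occ_truth <- occupied_cells_truth(sim$truth, sim$grid, factor)
  extra <- data.frame(
    scenario = scenario, replicate = replicate,
    metric = c("occupied_cells", "total_abundance"),
    truth = c(occ_truth, sim$truth$expected_total),
    estimate = c(dp$occupied[[2]], dp$total[[2]]),
    lower = c(dp$occupied[[1]], dp$total[[1]]),
    upper = c(dp$occupied[[3]], dp$total[[3]]),
    converged = res$converged)
  extra$covered <- extra$lower <= extra$truth & extra$truth <= extra$upper
  extra$width <- extra$upper - extra$lower
  rbind(rows, extra[names(rows)])
}

experiment_report <- function(rows) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("experiment_report", "data.frame")
  out
}

true_params_of <- function(config) {
  model_params(config$true_beta, config$true_delta,
               stats::qlogis(config$true_p_det))
}

rep_seed <- function(seed, r) as.integer(seed + 101L * r)

#' Camera-placement experiment: even versus clustered deployments
#'
#' For each replicate, one landscape with its latent abundance and sighting
#' records is generated and surveyed twice — once with an even camera
#' lattice and once with clustered cameras — using matched seeds, so the
#' two arms differ only in camera placement. Both arms are fitted and the
#' per-parameter credible-interval coverage of the true values and CI
#' widths are reported side by side.
#'
#' @param base A [sim_config]; its `n_cameras`, cluster geometry and other
#'   conditions are shared by both arms.
#' @param replicates Number of replicate landscapes (>= 2).
#' @param seed Integer master seed.
#' @param factor Working aggregation factor.
#' @param mcmc An [mcmc_config] template; per-replicate seeds are derived.
#' @return An `experiment_report` data frame with scenarios `"even"` and
#'   `"clustered"`.
#' @export
placement_experiment <- function(base, replicates = 25, seed = 1L,
                                 factor = 1L, mcmc = mcmc_config()) {
  if (replicates < 2) stop("replicates must be >= 2", call. = FALSE)
  tp <- true_params_of(base)
  rows <- list()
  for (r in seq_len(replicates)) {
    sr <- rep_seed(seed, r)
    for (design in c("even", "clustered")) {
      cfg <- base
      cfg$design <- design
      sim <- simulate_survey(cfg, seed = sr)
      mc <- mcmc
      mc$rng_seed <- sr + 50L
      res <- fit_simulated_survey(sim, factor = factor, method = "max",
                                  mcmc = mc)
      rows[[length(rows) + 1L]] <-
        replicate_rows(design, r, res, sim, tp, factor)
    }
  }
  experiment_report(rows)
}

#' Subsampling experiment: the sample-size effect of camera loss
#'
#' Isolates the sample-size consequence of aggregation-driven subsampling
#' from the aggregation itself: for each factor, one camera per would-be
#' coarse cell is retained — chosen by camera id, blind to its detections,
#' so the retained observations are unaltered and unselected — and the
#' model is fitted at the native resolution. Factor 1 keeps every camera.
#' (Selecting survivors by detection count, as the max rule does in the
#' real pipeline, would add the detectability-inflating selection effect
#' on top of the sample-size change; this experiment deliberately measures
#' the sample-size change alone.) Arms share each replicate's generated
#' data byte-for-byte.
#'
#' @param base A [sim_config].
#' @param factors Aggregation factors whose camera loss is emulated
#'   (factor 1 = no subsampling).
#' @param replicates,seed,mcmc As in [placement_experiment].
#' @return An `experiment_report` with scenarios `"factor<k>"`.
#' @export
subsampling_experiment <- function(base, factors = c(1L, 3L),
                                   replicates = 25, seed = 1L,
                                   mcmc = mcmc_config()) {
  if (!length(factors)) stop("factors must be nonempty", call. = FALSE)
  tp <- true_params_of(base)
  rows <- list()
  for (r in seq_len(replicates)) {
    sr <- rep_seed(seed, r)
    sim <- simulate_survey(base, seed = sr)
    for (f in factors) {
      sim_f <- sim
      if (f > 1L) {
        coarse <- coarsen_cells(sim$histories$cell_id, sim$grid$rows,
                                sim$grid$cols, f)
        survivors <- as.integer(tapply(sim$histories$unit_id, coarse, min))
        sim_f$histories <-
          sim$histories[sim$histories$unit_id %in% survivors, , drop = FALSE]
      }
      mc <- mcmc
      mc$rng_seed <- sr + 50L
      res <- fit_simulated_survey(sim_f, factor = 1L, method = "max",
                                  mcmc = mc)
      rows[[length(rows) + 1L]] <-
        replicate_rows(paste0("factor", f), r, res, sim_f, tp, 1L)
    }
  }
  experiment_report(rows)
}

#' Aggregation-method experiment: max versus mean versus sum
#'
#' Compares the three within-cell camera aggregation methods on clustered
#' deployments, where several cameras can fall in one coarse cell. The sum
#' method can pool more detections than there are survey nights; such
#' assumption violations abort that arm for the replicate and are counted
#' in the report's `"violations"` attribute.
#'
#' @param base A [sim_config]; the detection probability of 0.3 keeps the
#'   sum method mostly below the survey-night ceiling.
#' @param methods Aggregation methods to compare.
#' @param replicates,seed,mcmc As in [placement_experiment].
#' @param factor Working aggregation factor.
#' @return An `experiment_report` with one scenario per method and an
#'   attribute `violations` (count of aborted sum-method replicates).
#' @export
aggregation_method_experiment <- function(base,
                                          methods = c("max", "mean", "sum"),
                                          replicates = 25, seed = 1L,
                                          factor = 3L,
                                          mcmc = mcmc_config()) {
  tp <- true_params_of(base)
  rows <- list()
  violations <- 0L
  for (r in seq_len(replicates)) {
    sr <- rep_seed(seed, r)
    sim <- simulate_survey(base, seed = sr)
    for (mth in methods) {
      mc <- mcmc
      mc$rng_seed <- sr + 50L
      res <- tryCatch(
        fit_simulated_survey(sim, factor = factor, method = mth, mcmc = mc),
        error = function(e) {
          if (grepl("assumption violation", conditionMessage(e))) NULL
          else stop(e)
        })
      if (is.null(res)) { violations <- violations + 1L; next }
      rows[[length(rows) + 1L]] <-
        replicate_rows(mth, r, res, sim, tp, factor)
    }
  }
  out <- experiment_report(rows)
  attr(out, "violations") <- violations
  out
}

#' Scale sweep: abundance and occupancy estimates across resolutions
#'
#' Re-prepares each replicate's survey at an ascending series of
#' aggregation factors and tracks the estimated number of occupied cells
#' and total abundance against the (resolution-invariant) truth, exposing
#' the scale dependency of grid-based abundance estimates.
#'
#' @param base A [sim_config].
#' @param factors Ascending aggregation factors.
#' @param replicates,seed,mcmc As in [placement_experiment].
#' @return An `experiment_report` with scenarios `"factor<k>"`.
#' @export
scale_sweep <- function(base, factors = c(3L, 4L, 5L), replicates = 25,
                        seed = 1L, mcmc = mcmc_config()) {
  if (is.unsorted(factors))
    stop("factors must be ascending", call. = FALSE)
  tp <- true_params_of(base)
  rows <- list()
  for (r in seq_len(replicates)) {
    sr <- rep_seed(seed, r)
    sim <- simulate_survey(base, seed = sr)
    for (f in factors) {
      mc <- mcmc
      mc$rng_seed <- sr + 50L
      res <- fit_simulated_survey(sim, factor = f, method = "max", mcmc = mc)
      rows[[length(rows) + 1L]] <-
        replicate_rows(paste0("factor", f), r, res, sim, tp, f)
    }
  }
  experiment_report(rows)
}

#' Summarize an experiment report
#'
#' Per scenario and metric: the fraction of replicates whose 95% credible
#' interval covered the truth, the mean interval width, the mean posterior
#' median and the replicate count.
#'
#' @param report An `experiment_report`.
#' @return Data frame with columns `scenario`, `metric`, `coverage`,
#'   `mean_width`, `mean_estimate`, `n`.
#' @export
coverage_summary <- function(report) {
  key <- interaction(report$scenario, report$metric, drop = TRUE)
  rows <- lapply(split(report, key), function(d) {
    data.frame(scenario = d$scenario[1], metric = d$metric[1],
               coverage = mean(d$covered), mean_width = mean(d$width),
               mean_estimate = mean(d$estimate), n = nrow(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$scenario, out$metric), , drop = FALSE]
}

#' Write / read an experiment report as CSV
#'
#' @param report An `experiment_report`.
#' @param file Path to a CSV file.
#' @return `read_experiment_report` returns the report; the writer returns
#'   `file` invisibly.
#' @export
write_experiment_report <- function(report, file) {
  utils::write.csv(as.data.frame(report), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_experiment_report
#' @export
read_experiment_report <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE)
  class(out) <- c("experiment_report", "data.frame")
  out
}
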