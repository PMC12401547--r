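#' Simulation configuration
#'
#' Study conditions for the synthetic-data generator. The defaults define
#' the standard desk-scale scenario used throughout the simulation
#' experiments: a 100 x 100 grid of 1-ha pixels, 100 cameras run for 40
#' nights at a per-night detectability of 0.3, with sighting records thinned
#' by a road-proximity-like bias field.
#'
#' @param grid_rows,grid_cols Grid dimensions.
#' @param base_pixel_area Area of one fine pixel, hectares.
#' @param true_beta Intensity coefficients (intercept first); its length
#'   fixes the number of environmental covariates to
#'   `length(true_beta) - 1`.
#' @param true_delta Thinning parameters (logit intercept, bias slope).
#' @param true_p_det Per-night camera detection probability in (0, 1).
#' @param n_cameras Number of cameras.
#' @param design `"even"` (near-uniform lattice) or `"clustered"`.
#' @param n_clusters,cameras_per_cluster Clustered-design geometry; must
#'   multiply to `n_cameras` when `design = "clustered"`. Each cluster's
#'   cameras occupy distinct cells within a 3 x 3-cell bounding box.
#' @param n_nights Survey duration per camera, nights.
#' @param covariate_smoothness Standard deviation (in cells) of the
#'   isotropic Gaussian kernel that smooths the white-noise covariate
#'   fields; larger values give longer-range spatial autocorrelation.
#' @param n_binary Number of trailing covariates rendered as binary habitat
#'   indicators (smoothed field thresholded at its 0.6 quantile); the rest
#'   are continuous and standardized.
#' @param rng_seed Integer seed; every generator is deterministic given the
#'   config and its seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid_rows = 100, grid_cols = 100, base_pixel_area = 1,
                       true_beta = c(-2.2, 0.75, -0.5, 0.25),
                       true_delta = c(-1, -1),
                       true_p_det = 0.3,
                       n_cameras = 100, design = c("even", "clustered"),
                       n_clusters = 25, cameras_per_cluster = 4,
                       n_nights = 40, covariate_smoothness = 6,
                       n_binary = 1, rng_seed = 1L) {
  design <- match.arg(design)
  grid_rows <- as.integer(grid_rows); grid_cols <- as.integer(grid_cols)
  if (is.na(grid_rows) || is.na(grid_cols) || grid_rows < 1L || grid_cols < 1L)
    stop("invalid config: grid dimensions must be positive", call. = FALSE)
  if (covariate_smoothness <= 0)
    stop("invalid config: covariate_smoothness must be positive",
         call. = FALSE)
  if (true_p_det <= 0 || true_p_det >= 1)
    stop("invalid config: true_p_det must lie in (0, 1)", call. = FALSE)
  if (length(true_delta) != 2L)
    stop("invalid config: true_delta must have length 2", call. = FALSE)
  if (length(true_beta) < 1L + n_binary)
    stop("invalid config: true_beta too short for n_binary", call. = FALSE)
  if (grid_rows * grid_cols < n_cameras)
    stop("invalid config: more cameras than cells", call. = FALSE)
  if (design == "clustered" && n_clusters * cameras_per_cluster != n_cameras)
    stop("invalid config: n_clusters * cameras_per_cluster must equal ",
         "n_cameras", call. = FALSE)
  structure(
    list(grid_rows = grid_rows, grid_cols = grid_cols,
         base_pixel_area = base_pixel_area, true_beta = true_beta,
         true_delta = true_delta, true_p_det = true_p_det,
         n_cameras = as.integer(n_cameras), design = design,
         n_clusters = as.integer(n_clusters),
         cameras_per_cluster = as.integer(cameras_per_cluster),
         n_nights = as.integer(n_nights),
         covariate_smoothness = covariate_smoothness,
         n_binary = as.integer(n_binary), rng_seed = as.integer(rng_seed)),
    class = "sim_config")
}

# Separable Gaussian-kernel smoothing of a rows x cols white-noise matrix.
smooth_field <- function(m, sd) {
  gauss_smoother <- function(n) {
    d <- outer(seq_len(n), seq_len(n), function(i, j) (i - j)^2)
    S <- exp(-d / (2 * sd^2))
    S / rowSums(S)
  }
  gauss_smoother(nrow(m)) %*% m %*% t(gauss_smoother(ncol(m)))
}

#' Generate a synthetic covariate landscape
#'
#' Continuous covariates are spatially autocorrelated Gaussian fields
#' (white noise convolved with an isotropic Gaussian kernel of standard
#' deviation `covariate_smoothness` cells), standardized to mean 0 and
#' standard deviation 1 across cells. Trailing covariates may be rendered
#' binary by thresholding. The observation-bias covariate is built the same
#' way as the continuous fields. All cells are unmasked.
#'
#' @param config A [sim_config].
#' @return A [cell_grid].
#' @export
gen_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  n_cov <- length(config$true_beta) - 1L
  rows <- config$grid_rows; cols <- config$grid_cols
  one_field <- function() {
    f <- smooth_field(matrix(stats::rnorm(rows * cols), rows, cols),
                      config$covariate_smoothness)
    # flatten row-major to match cell ids
    as.vector(t(f))
  }
  covs <- matrix(0, rows * cols, n_cov)
  cov_type <- rep("continuous", n_cov)
  for (j in seq_len(n_cov)) {
    f <- one_field()
    if (j > n_cov - config$n_binary) {
      covs[, j] <- as.numeric(f > stats::quantile(f, 0.6))
      cov_type[j] <- "binary"
    } else {
      covs[, j] <- (f - mean(f)) / stats::sd(f)
    }
  }
  colnames(covs) <- ifelse(cov_type == "binary",
                           paste0("habitat", seq_len(n_cov)),
                           paste0("env", seq_len(n_cov)))
  b <- one_field()
  bias <- (b - mean(b)) / stats::sd(b)
  cell_grid(rows, cols, covs, bias, area = config$base_pixel_area,
            cov_type = cov_type)
}

#' Simulate latent abundance over a landscape
#'
#' Draws the per-cell latent counts `N_k ~ Poisson(lambda_k * A_k)` with
#' `log(lambda_k) = beta . x_k`, and derives the occupancy indicators
#' `Z_k = I(N_k > 0)`.
#'
#' @param grid A [cell_grid].
#' @param beta Intensity coefficients (intercept first).
#' @param seed Integer seed.
#' @return An object of class `sim_truth`: list with `beta`, `latent_N`,
#'   `latent_Z`, `lambda`, `expected_total` (sum of `lambda_k * A_k` over
#'   unmasked cells) and `realized_total`.
#' @export
sim_latent_abundance <- function(grid, beta, seed = 1L) {
  if (length(beta) != 1L + ncol(grid$covariates))
    stop("beta length must be 1 + number of covariates", call. = FALSE)
  set.seed(seed)
  lam <- rep(0, grid$n_cells)
  keep <- !grid$mask
  lam[keep] <- intensity(grid$covariates[keep, , drop = FALSE], beta)
  mu <- lam * grid$area
  N <- integer(grid$n_cells)
  N[keep] <- stats::rpois(sum(keep), mu[keep])
  structure(
    list(beta = beta, lambda = lam, latent_N = N, latent_Z = as.integer(N > 0),
         expected_total = sum(mu[keep]), realized_total = sum(N)),
    class = "sim_truth")
}

#' Simulate presence-only sighting records by thinning
#'
#' Each of the `N_k` latent individuals in cell `k` is retained in the
#' sighting record independently with thinning probability
#' `b_k = plogis(delta[1] + delta[2] * bias_k)` — binomial thinning of the
#' latent point pattern, equivalent in distribution to thinning the Poisson
#' process itself.
#'
#' @param truth A `sim_truth` from [sim_latent_abundance].
#' @param grid The [cell_grid] the truth was simulated on.
#' @param delta Thinning parameters (length 2).
#' @param seed Integer seed.
#' @return Data frame of class `po_points` with columns `po_id`, `cell_id`.
#' @export
sim_po_points <- function(truth, grid, delta, seed = 1L) {
  set.seed(seed)
  b <- thinning_prob(grid$bias, delta)
  kept <- stats::rbinom(grid$n_cells, truth$latent_N, b)
  cells <- rep.int(seq_len(grid$n_cells), kept)
  structure(
    data.frame(po_id = seq_along(cells), cell_id = cells),
    class = c("po_points", "data.frame"))
}

#' Place cameras on a landscape
#'
#' `"even"` places cameras on a near-uniform lattice over the grid;
#' `"clustered"` draws `n_clusters` non-overlapping 3 x 3-cell cluster
#' boxes uniformly at random and fills `cameras_per_cluster` distinct cells
#' within each. No two cameras share a cell.
#'
#' @param grid A [cell_grid].
#' @param config A [sim_config]; uses `design`, `n_cameras`, cluster
#'   geometry and `rng_seed`.
#' @param seed Integer seed; defaults to the config's `rng_seed`.
#' @return Data frame with columns `camera_id`, `cell_id`, `row`, `col`,
#'   `cluster` (NA for the even design).
#' @export
place_cameras <- function(grid, config, seed = config$rng_seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_cameras
  if (sum(!grid$mask) < n)
    stop("placement error: fewer unmasked cells than cameras", call. = FALSE)
  if (config$design == "even") {
    nr <- max(1L, round(sqrt(n * grid$rows / grid$cols)))
    nc <- ceiling(n / nr)
    while (nr > grid$rows || nc > grid$cols) {
      if (nr > grid$rows) { nr <- nr - 1L; nc <- ceiling(n / nr) }
      if (nc > grid$cols)
        stop("placement error: grid too small for an even lattice",
             call. = FALSE)
    }
    rows <- floor((seq_len(nr) - 0.5) * grid$rows / nr) + 1L
    cols <- floor((seq_len(nc) - 0.5) * grid$cols / nc) + 1L
    pos <- expand.grid(row = rows, col = cols)[seq_len(n), ]
    cells <- cell_index(pos$row, pos$col, grid)
    cluster <- rep(NA_integer_, n)
  } else {
    if (config$cameras_per_cluster > 9L)
      stop("placement error: more than 9 cameras per 3x3 cluster box",
           call. = FALSE)
    if (grid$rows < 3L || grid$cols < 3L)
      stop("placement error: grid too small for clustered design",
           call. = FALSE)
    centers <- matrix(NA_integer_, config$n_clusters, 2)
    tries <- 0L
    k <- 1L
    while (k <= config$n_clusters) {
      r <- sample(2:(grid$rows - 1L), 1L)
      c <- sample(2:(grid$cols - 1L), 1L)
      clash <- k > 1L &&
        any(abs(centers[seq_len(k - 1L), 1] - r) <= 2 &
            abs(centers[seq_len(k - 1L), 2] - c) <= 2)
      if (!clash) { centers[k, ] <- c(r, c); k <- k + 1L }
      tries <- tries + 1L
      if (tries > 1000L * config$n_clusters)
        stop("placement error: could not fit non-overlapping clusters",
             call. = FALSE)
    }
    cells <- integer(0); cluster <- integer(0)
    for (k in seq_len(config$n_clusters)) {
      box <- as.matrix(expand.grid(row = centers[k, 1] + (-1:1),
                                   col = centers[k, 2] + (-1:1)))
      pick <- box[sample(nrow(box), config$cameras_per_cluster), , drop = FALSE]
      cells <- c(cells, cell_index(pick[, "row"], pick[, "col"], grid))
      cluster <- c(cluster, rep(k, config$cameras_per_cluster))
    }
  }
  if (anyDuplicated(cells))
    stop("placement error: duplicate camera cells", call. = FALSE)
  if (any(grid$mask[cells]))
    stop("placement error: camera in a masked cell", call. = FALSE)
  data.frame(camera_id = seq_along(cells), cell_id = cells,
             row = cell_row(cells, grid), col = cell_col(cells, grid),
             cluster = cluster)
}

#' Simulate nightly camera detection histories
#'
#' For a camera in cell `k`, the nightly records are independent
#' `Bernoulli(p_det * Z_k)` draws: cameras in unoccupied cells record
#' nothing, cameras in occupied cells detect each night with probability
#' `p_det`.
#'
#' @param truth A `sim_truth`.
#' @param cameras Camera deployment data frame from [place_cameras].
#' @param p_det Per-night detection probability in (0, 1].
#' @param n_nights Number of survey nights per camera.
#' @param seed Integer seed.
#' @return Long-format data frame with columns `camera_id`, `cell_id`,
#'   `night_index`, `detected`.
#' @export
sim_detection_histories <- function(truth, cameras, p_det, n_nights,
                                    seed = 1L) {
  if (p_det <= 0 || p_det > 1) stop("p_det must lie in (0, 1]", call. = FALSE)
  if (n_nights < 1L) stop("n_nights must be at least 1", call. = FALSE)
  set.seed(seed)
  z <- truth$latent_Z[cameras$cell_id]
  y <- stats::rbinom(nrow(cameras) * n_nights, 1L,
                     p_det * rep(z, each = n_nights))
  data.frame(camera_id = rep(cameras$camera_id, each = n_nights),
             cell_id = rep(cameras$cell_id, each = n_nights),
             night_index = rep.int(seq_len(n_nights), nrow(cameras)),
             detected = y)
}

#' Tally nightly histories to per-camera totals
#'
#' @param nightly Long-format histories from [sim_detection_histories] or
#'   [read_detections].
#' @return Data frame with one row per camera: `unit_id`, `cell_id`,
#'   `nights`, `detections`.
#' @export
tally_detections <- function(nightly) {
  ids <- sort(unique(nightly$camera_id))
  f <- factor(nightly$camera_id, levels = ids)
  data.frame(unit_id = ids,
             cell_id = as.integer(tapply(nightly$cell_id, f, function(v) v[1])),
             nights = as.integer(tabulate(f, nbins = length(ids))),
             detections = as.numeric(tapply(nightly$detected, f, sum)))
}

#' Run the full generator pipeline for one replicate
#'
#' Convenience wrapper: landscape, latent abundance, presence-only records,
#' camera placement and detection histories, with per-stage seeds derived
#' from `seed`.
#'
#' @param config A [sim_config].
#' @param seed Integer master seed; defaults to the config's `rng_seed`.
#' @return List with elements `grid`, `truth`, `po`, `cameras`, `nightly`,
#'   `histories` (per-camera totals) and `seed`.
#' @export
simulate_survey <- function(config, seed = config$rng_seed) {
  cfg <- config
  cfg$rng_seed <- as.integer(seed)
  grid <- gen_landscape(cfg)
  truth <- sim_latent_abundance(grid, cfg$true_beta, seed = seed + 1L)
  po <- sim_po_points(truth, grid, cfg$true_delta, seed = seed + 2L)
  cameras <- place_cameras(grid, cfg, seed = seed + 3L)
  nightly <- sim_detection_histories(truth, cameras, cfg$true_p_det,
                                     cfg$n_nights, seed = seed + 4L)
  list(grid = grid, truth = truth, po = po, cameras = cameras,
       nightly = nightly, histories = tally_detections(nightly),
       seed = seed)
}
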