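#' Collapse camera images into detection incidents
#'
#' A detection incident is an image taken at least `window_minutes` after
#' the preceding image of the same species at the same camera (the boundary
#' is inclusive, and the gap is measured from the preceding image, not the
#' preceding incident). The first image of a species at a camera always
#' opens an incident.
#'
#' @param images Data frame with columns `camera_id`, `species`,
#'   `timestamp` (POSIXct, or strings parseable by [as.POSIXct]).
#' @param window_minutes Quiet window, minutes.
#' @return The incident rows of `images`, ordered by camera, species and
#'   time, with an attribute `n_rejected` counting unparseable timestamps.
#' @export
filter_incidents <- function(images, window_minutes = 30) {
  ts <- images$timestamp
  if (!inherits(ts, "POSIXct")) {
    raw <- as.character(ts)
    ts <- as.POSIXct(strptime(raw, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
    retry <- is.na(ts)
    if (any(retry))
      ts[retry] <- as.POSIXct(strptime(raw[retry], "%Y-%m-%d %H:%M",
                                       tz = "UTC"))
  }
  bad <- is.na(ts)
  n_rejected <- sum(bad)
  images <- images[!bad, , drop = FALSE]
  ts <- ts[!bad]
  ord <- order(images$camera_id, images$species, ts)
  images <- images[ord, , drop = FALSE]
  ts <- ts[ord]
  gap_min <- c(Inf, as.numeric(difftime(ts[-1], ts[-length(ts)],
                                        units = "mins")))
  new_group <- c(TRUE, images$camera_id[-1] != images$camera_id[-nrow(images)] |
                   images$species[-1] != images$species[-nrow(images)])
  keep <- new_group | gap_min >= window_minutes
  if (nrow(images) == 0L) keep <- logical(0)
  out <- images[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Trapping effort per site
#'
#' Effort is the total number of camera-nights at a site, respecting
#' per-camera variation in operating duration.
#'
#' @param cameras Data frame with columns `nights` and optionally `site`
#'   (defaults to a single site) and `camera_id`.
#' @return Data frame with one row per site: `site`, `cameras`,
#'   `camera_nights`.
#' @export
compute_effort <- function(cameras) {
  if (is.null(cameras) || nrow(cameras) == 0L)
    return(data.frame(site = character(0), cameras = integer(0),
                      camera_nights = numeric(0)))
  site <- if ("site" %in% names(cameras)) cameras$site else
    rep("site", nrow(cameras))
  f <- factor(site)
  data.frame(site = levels(f),
             cameras = as.integer(tabulate(f)),
             camera_nights = as.numeric(tapply(cameras$nights, f, sum)))
}

#' Naive capture rate
#'
#' Detections per 100 camera-nights, uncorrected for detectability:
#' `100 * detections / effort`, reported to two decimal places.
#'
#' @param detections Detection incident count.
#' @param effort Trapping effort in camera-nights; must be positive.
#' @return Percentage, rounded to 2 decimals.
#' @export
naive_capture_rate <- function(detections, effort) {
  if (any(effort <= 0))
    stop("undefined rate: effort must be positive", call. = FALSE)
  round(100 * detections / effort, 2)
}

#' Clean presence-only records
#'
#' Applies the sighting-record retention rules: drop records with
#' incomplete information, drop records before the cutoff year, and convert
#' any reported animal count to a single presence.
#'
#' @param records Data frame with columns `year`, `complete` (logical) and
#'   a location column (`cell_id` or coordinates); a `count` column, if
#'   present, is discarded after coercion to presence.
#' @param cutoff_year Earliest retained year.
#' @return The retained rows, one presence each, with a `retention`
#'   attribute: list with `n_input`, `n_retained`, `n_incomplete`,
#'   `n_pre_cutoff`.
#' @export
clean_po <- function(records, cutoff_year = 1990) {
  if (is.null(records) || nrow(records) == 0L) {
    out <- records[0, , drop = FALSE]
    attr(out, "retention") <- list(n_input = 0L, n_retained = 0L,
                                   n_incomplete = 0L, n_pre_cutoff = 0L)
    return(out)
  }
  complete <- !is.na(records$complete) & records$complete &
    !is.na(records$year)
  old <- complete & records$year < cutoff_year
  keep <- complete & !old
  out <- records[keep, , drop = FALSE]
  out$count <- NULL
  out$presence <- 1L
  rownames(out) <- NULL
  attr(out, "retention") <- list(
    n_input = nrow(records), n_retained = nrow(out),
    n_incomplete = sum(!complete), n_pre_cutoff = sum(old))
  out
}

#' Standardize grid covariates
#'
#' Continuous covariates are centred and scaled to unit standard deviation
#' over unmasked cells; binary covariates pass through untouched. The
#' scaler (per-covariate means and standard deviations) is attached so that
#' prediction grids can be standardized identically.
#'
#' @param grid A [cell_grid] with declared `cov_type`.
#' @param scaler Optional scaler from a previous call, to reuse fit-time
#'   statistics on a prediction grid.
#' @return The grid with standardized covariates and a `scaler` attribute
#'   (list with `names`, `mean`, `sd`; `NA` entries for binary columns).
#' @export
standardize_covariates <- function(grid, scaler = NULL) {
  keep <- !grid$mask
  p <- ncol(grid$covariates)
  if (is.null(scaler)) {
    mu <- sdv <- rep(NA_real_, p)
    for (j in seq_len(p)) {
      if (grid$cov_type[j] == "binary") next
      mu[j] <- mean(grid$covariates[keep, j])
      sdv[j] <- stats::sd(grid$covariates[keep, j])
      if (!is.finite(sdv[j]) || sdv[j] == 0)
        stop("zero-variance continuous covariate: ",
             colnames(grid$covariates)[j], call. = FALSE)
    }
    scaler <- list(names = colnames(grid$covariates), mean = mu, sd = sdv)
  } else {
    if (!identical(scaler$names, colnames(grid$covariates)))
      stop("scaler mismatch: covariate names differ", call. = FALSE)
  }
  for (j in seq_len(p)) {
    if (is.na(scaler$mean[j])) next
    grid$covariates[, j] <- (grid$covariates[, j] - scaler$mean[j]) /
      scaler$sd[j]
  }
  attr(grid, "scaler") <- scaler
  grid
}

#' Aggregation specification
#'
#' @param factor Side multiple `k >= 1` by which fine pixels are merged
#'   into coarse analysis cells; the coarse cell area is
#'   `k^2 * base_pixel_area` (factor 3 on 1-ha pixels gives 9-ha cells,
#'   factor 5 gives 25 ha — the home-range scenarios).
#' @param method Camera subsampling method within a coarse cell: `"max"`
#'   (keep the camera with the most detections), `"mean"` (per-night
#'   fractional mean; diagnostic only) or `"sum"` (pool detections and
#'   nights).
#' @param base_pixel_area Fine-pixel area, hectares.
#' @return An object of class `aggregation_spec` with the derived
#'   `cell_area`.
#' @export
aggregation_spec <- function(factor, method = c("max", "mean", "sum"),
                             base_pixel_area = 1) {
  method <- match.arg(method)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("invalid spec: aggregation factor must be >= 1", call. = FALSE)
  structure(list(factor = factor, method = method,
                 base_pixel_area = base_pixel_area,
                 cell_area = factor^2 * base_pixel_area),
            class = "aggregation_spec")
}

# Map fine row-major cell ids to coarse row-major cell ids.
coarsen_cells <- function(cell_id, rows, cols, factor) {
  r <- (cell_id - 1L) %/% cols + 1L
  c <- (cell_id - 1L) %% cols + 1L
  ccols <- ceiling(cols / factor)
  (ceiling(r / factor) - 1L) * ccols + ceiling(c / factor)
}

#' Aggregate a grid to a coarser resolution
#'
#' Merges `factor x factor` blocks of fine cells into coarse cells. Coarse
#' covariates are means over the unmasked constituent cells (binary
#' covariates therefore become habitat fractions in `[0, 1]`), coarse area
#' is the sum of unmasked constituent areas, and a coarse cell is masked
#' only when all constituents are masked. Edges not divisible by the factor
#' are padded with masked cells.
#'
#' @param grid A [cell_grid].
#' @param spec An [aggregation_spec].
#' @return The coarse [cell_grid]; any scaler attribute is carried along.
#' @export
aggregate_grid <- function(grid, spec) {
  stopifnot(inherits(spec, "aggregation_spec"))
  f <- spec$factor
  if (f == 1L) return(grid)
  crows <- ceiling(grid$rows / f); ccols <- ceiling(grid$cols / f)
  id <- seq_len(grid$n_cells)
  coarse <- coarsen_cells(id, grid$rows, grid$cols, f)
  g <- factor(coarse, levels = seq_len(crows * ccols))
  w <- as.numeric(!grid$mask)
  n_un <- tapply(w, g, sum)
  n_un[is.na(n_un)] <- 0
  covs <- matrix(0, crows * ccols, ncol(grid$covariates),
                 dimnames = list(NULL, colnames(grid$covariates)))
  for (j in seq_len(ncol(covs))) {
    s <- tapply(grid$covariates[, j] * w, g, sum)
    s[is.na(s)] <- 0
    covs[, j] <- ifelse(n_un > 0, s / n_un, 0)
  }
  bsum <- tapply(grid$bias * w, g, sum); bsum[is.na(bsum)] <- 0
  asum <- tapply(grid$area * w, g, sum); asum[is.na(asum)] <- 0
  mask_c <- unname(n_un == 0)
  out <- cell_grid(crows, ccols, covs,
                   bias = as.numeric(ifelse(n_un > 0, bsum / n_un, 0)),
                   area = as.numeric(ifelse(mask_c, spec$cell_area, asum)),
                   mask = mask_c, cov_type = grid$cov_type)
  attr(out, "scaler") <- attr(grid, "scaler")
  attr(out, "aggregation_factor") <- f
  out
}

#' Assign cameras to aggregated cells and subsample
#'
#' Maps each camera's fine cell to its coarse cell, then collapses multiple
#' cameras per coarse cell according to the aggregation method: `"max"`
#' keeps the single camera with the highest detection total (ties broken by
#' lowest camera id); `"mean"` averages detection totals and nights across
#' the cell's cameras, giving fractional histories that violate Bernoulli
#' support (flagged via the `non_bernoulli` attribute, diagnostic use
#' only); `"sum"` pools detections and nights. The sum method validates
#' that pooled detections do not exceed the survey duration (the longest
#' single-camera deployment in the cell) — pooled counts beyond that exceed
#' the number of survey nights and violate the occupancy-model assumption
#' of at most one detection per night.
#'
#' @param histories Per-camera totals (`unit_id`, `cell_id`, `nights`,
#'   `detections`), with `cell_id` on the fine grid.
#' @param grid The fine [cell_grid] the cameras were placed on.
#' @param spec An [aggregation_spec].
#' @return One history per camera-occupied coarse cell: data frame with
#'   `unit_id`, `cell_id` (coarse), `nights`, `detections`, `n_cameras`.
#' @export
assign_and_subsample <- function(histories, grid, spec) {
  stopifnot(inherits(spec, "aggregation_spec"))
  coarse <- coarsen_cells(histories$cell_id, grid$rows, grid$cols,
                          spec$factor)
  split_idx <- split(seq_len(nrow(histories)), coarse)
  rows <- lapply(split_idx, function(ix) {
    h <- histories[ix, , drop = FALSE]
    cc <- coarse[ix[1]]
    switch(spec$method,
      max = {
        best <- ix[order(-h$detections, h$unit_id)][1]
        hb <- histories[best, , drop = FALSE]
        data.frame(unit_id = hb$unit_id, cell_id = cc, nights = hb$nights,
                   detections = hb$detections, n_cameras = nrow(h))
      },
      mean = data.frame(unit_id = h$unit_id[1], cell_id = cc,
                        nights = mean(h$nights),
                        detections = mean(h$detections),
                        n_cameras = nrow(h)),
      sum = {
        d <- sum(h$detections)
        if (d > max(h$nights))
          stop("assumption violation: pooled detections (", d,
               ") exceed the number of survey nights (", max(h$nights),
               ")", call. = FALSE)
        data.frame(unit_id = h$unit_id[1], cell_id = cc,
                   nights = sum(h$nights), detections = d,
                   n_cameras = nrow(h))
      })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "non_bernoulli") <- spec$method == "mean"
  out
}
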