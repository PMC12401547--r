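#' Write / read a cell grid as CSV with a JSON metadata sidecar
#'
#' The grid is stored as a plain CSV (one row per cell: `cell_id`, `row`,
#' `col`, `area`, `mask`, `bias`, then one column per covariate) next to a
#' `<file>.json` sidecar recording the dimensions, pixel area, covariate
#' names and roles, and any scaler.
#'
#' @param grid A [cell_grid].
#' @param file Path to the CSV file; the sidecar is written to
#'   `paste0(file, ".json")`.
#' @return `read_cell_grid` returns the grid; the writer returns `file`
#'   invisibly.
#' @export
write_cell_grid <- function(grid, file) {
  df <- data.frame(cell_id = seq_len(grid$n_cells),
                   row = cell_row(seq_len(grid$n_cells), grid),
                   col = cell_col(seq_len(grid$n_cells), grid),
                   area = grid$area, mask = grid$mask, bias = grid$bias)
  df <- cbind(df, as.data.frame(grid$covariates))
  utils::write.csv(df, file, row.names = FALSE)
  meta <- list(rows = grid$rows, cols = grid$cols,
               covariates = colnames(grid$covariates),
               cov_type = grid$cov_type,
               scaler = attr(grid, "scaler"))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_cell_grid
#' @export
read_cell_grid <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(file)
  covs <- as.matrix(df[, meta$covariates, drop = FALSE])
  out <- cell_grid(meta$rows, meta$cols, covs, bias = df$bias,
                   area = df$area, mask = df$mask, cov_type = meta$cov_type)
  if (!is.null(meta$scaler) && length(meta$scaler))
    attr(out, "scaler") <- meta$scaler
  out
}

#' Write / read presence-only records as CSV
#'
#' Column schema: `po_id`, `cell_id`, and optionally `year`, `count`,
#' `complete` for raw sighting exports.
#'
#' @param po Data frame of presence-only records.
#' @param file CSV path.
#' @return `read_po` returns the data frame.
#' @export
write_po <- function(po, file) {
  utils::write.csv(as.data.frame(po), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_po
#' @export
read_po <- function(file) utils::read.csv(file)

#' Write / read nightly detection histories as CSV
#'
#' Column schema: `camera_id`, `cell_id`, `night_index`, `detected`.
#'
#' @param nightly Long-format detection data frame.
#' @param file CSV path.
#' @return `read_detections` returns the data frame.
#' @export
write_detections <- function(nightly, file) {
  utils::write.csv(nightly, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_detections
#' @export
read_detections <- function(file) utils::read.csv(file)
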