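#' Gridded covariate landscape
#'
#' Container for a discretized study extent: a `rows` by `cols` raster of
#' cells, each carrying a vector of environmental covariates, one
#' observation-bias covariate (e.g. distance to road), a cell area in
#' hectares, and a mask flag. Cells are indexed row-major:
#' `cell_id = (row - 1) * cols + col`.
#'
#' @param rows,cols Grid dimensions (positive integers).
#' @param covariates Numeric matrix, one row per cell (`rows * cols`) and one
#'   named column per environmental covariate.
#' @param bias Numeric vector of the observation-bias covariate, one value
#'   per cell.
#' @param area Cell areas in hectares; a scalar is recycled to all cells.
#' @param mask Logical vector, `TRUE` for cells excluded from the landscape
#'   (e.g. ocean); defaults to all `FALSE`.
#' @param cov_type Character vector, `"continuous"` or `"binary"`, one per
#'   covariate column. Binary covariates are left untouched by
#'   standardization.
#'
#' @return An object of class `cell_grid`: a list with elements `rows`,
#'   `cols`, `n_cells`, `covariates`, `bias`, `area`, `mask`, `cov_type`.
#' @export
cell_grid <- function(rows, cols, covariates, bias, area = 1, mask = NULL,
                      cov_type = NULL) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L)
    stop("invalid grid: dimensions must be positive integers", call. = FALSE)
  n <- rows * cols
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n)
    stop("covariate matrix must have one row per cell", call. = FALSE)
  if (is.null(colnames(covariates)) && ncol(covariates) > 0L)
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  if (length(bias) != n)
    stop("bias covariate must have one value per cell", call. = FALSE)
  if (length(area) == 1L) area <- rep(as.numeric(area), n)
  if (length(area) != n)
    stop("area must be scalar or one value per cell", call. = FALSE)
  if (is.null(mask)) mask <- rep(FALSE, n)
  mask <- as.logical(mask)
  if (length(mask) != n) stop("mask must have one value per cell", call. = FALSE)
  if (any(area[!mask] <= 0))
    stop("areas must be positive on unmasked cells", call. = FALSE)
  if (is.null(cov_type)) cov_type <- rep("continuous", ncol(covariates))
  if (length(cov_type) != ncol(covariates))
    stop("cov_type must name one role per covariate column", call. = FALSE)
  structure(
    list(rows = rows, cols = cols, n_cells = n,
         covariates = covariates, bias = as.numeric(bias),
         area = area, mask = mask, cov_type = cov_type),
    class = "cell_grid")
}

#' @export
print.cell_grid <- function(x, ...) {
  cat(sprintf("<cell_grid> %d x %d cells (%d unmasked), %d covariates: %s\n",
              x$rows, x$cols, sum(!x$mask), ncol(x$covariates),
              paste(colnames(x$covariates), collapse = ", ")))
  cat(sprintf("  cell area: %s ha\n",
              paste(format(unique(range(x$area[!x$mask]))), collapse = "-")))
  invisible(x)
}

# row/col of a row-major cell id
cell_row <- function(cell_id, grid) (cell_id - 1L) %/% grid$cols + 1L
cell_col <- function(cell_id, grid) (cell_id - 1L) %% grid$cols + 1L

cell_index <- function(row, col, grid) (row - 1L) * grid$cols + col

#' Model parameter set
#'
#' Bundles the three parameter blocks of the integrated model: `beta`, the
#' log-linear intensity coefficients (intercept first); `delta`, the
#' presence-only thinning parameters (intercept and observation-bias slope
#' on the logit scale); and `alpha`, the camera detection intercept on the
#' logit scale.
#'
#' @param beta Numeric vector, intercept followed by one coefficient per
#'   environmental covariate.
#' @param delta Numeric vector of length 2.
#' @param alpha Numeric scalar.
#' @return An object of class `model_params`.
#' @export
model_params <- function(beta, delta, alpha) {
  beta <- as.numeric(beta); delta <- as.numeric(delta)
  alpha <- as.numeric(alpha)
  if (length(delta) != 2L) stop("delta must have length 2", call. = FALSE)
  if (length(alpha) != 1L) stop("alpha must be a scalar", call. = FALSE)
  if (!all(is.finite(c(beta, delta, alpha))))
    stop("parameters must be finite", call. = FALSE)
  structure(list(beta = beta, delta = delta, alpha = alpha),
            class = "model_params")
}

# Design matrix over unmasked cells: leading intercept column.
design_matrix <- function(grid) {
  X <- cbind(1, grid$covariates[!grid$mask, , drop = FALSE])
  colnames(X)[1] <- "(Intercept)"
  X
}

# Coerce presence-only input (integer cell ids, or a data frame with a
# cell_id column) to a vector of cell ids.
po_cells <- function(po) {
  if (is.null(po)) return(integer(0))
  if (is.data.frame(po)) {
    if (!"cell_id" %in% names(po))
      stop("presence-only data frame needs a cell_id column", call. = FALSE)
    return(as.integer(po$cell_id))
  }
  as.integer(po)
}
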