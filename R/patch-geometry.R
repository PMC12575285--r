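#' Construct a soil-depth grid
#'
#' A `soil_grid` is a rectangular raster of soil depths (cm) sampled on a
#' regular grid, as produced by augering a plot at fixed spacing. A depth of
#' 0 encodes exposed rock; positive depths are soil.
#'
#' @param depths Numeric matrix of depths in cm; all values must be >= 0.
#'   Row 1 is the top of the plot (raster origin top-left, row-major).
#' @param cell_side Physical side length of one grid cell in metres.
#' @return An object of class `soil_grid` with elements `depths` and
#'   `cell_side`.
#' @examples
#' g <- soil_grid(matrix(c(5, 0, 0, 5), 2, 2), cell_side = 0.39)
#' @export
soil_grid <- function(depths, cell_side) {
  depths <- as.matrix(depths)
  if (length(depths) == 0L) stop("'depths' must be a non-empty matrix")
  if (!is.numeric(depths) || anyNA(depths)) {
    stop("'depths' must be numeric with no missing values")
  }
  if (any(depths < 0)) stop("soil depths must be >= 0 (0 = rock)")
  if (!is.numeric(cell_side) || length(cell_side) != 1L || cell_side <= 0) {
    stop("'cell_side' must be a single positive number (metres)")
  }
  structure(list(depths = unname(depths), cell_side = cell_side),
            class = "soil_grid")
}

#' @export
print.soil_grid <- function(x, ...) {
  d <- dim(x$depths)
  soil <- sum(x$depths > 0)
  cat(sprintf("<soil_grid> %d x %d cells (%.2f m side), %d soil / %d rock\n",
              d[1], d[2], x$cell_side, soil, length(x$depths) - soil))
  invisible(x)
}

#' Delineate soil patches by connected-component labelling
#'
#' Partitions the soil cells (depth > 0) of a grid into maximal connected
#' components under 4- or 8-adjacency. Rock cells receive label 0; patches
#' are labelled 1..n in raster scan order (row-major) of their first cell.
#' The default 4-connectivity treats edge contact as the continuity
#' criterion; diagonal-only contact starts a new patch.
#'
#' @param grid A [soil_grid()].
#' @param connectivity Either 4 (edge-sharing, default) or 8 (edges and
#'   corners).
#' @return An object of class `patch_map`: list with `labels` (integer
#'   matrix, 0 = rock), `n_patches`, and `cell_side`.
#' @examples
#' g <- soil_grid(matrix(c(5, 0, 0, 5), 2, 2), cell_side = 0.39)
#' delineate_patches(g, connectivity = 4)$n_patches  # 2
#' delineate_patches(g, connectivity = 8)$n_patches  # 1
#' @export
delineate_patches <- function(grid, connectivity = 4) {
  stopifnot(inherits(grid, "soil_grid"))
  if (!connectivity %in% c(4, 8)) stop("'connectivity' must be 4 or 8")
  depths <- grid$depths
  nr <- nrow(depths); nc <- ncol(depths)
  labels <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  soil <- depths > 0
  lab <- 0L
  # scan row-major (top-left origin) so labels follow first-cell order
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!soil[i, j] || labels[i, j] != 0L) next
      lab <- lab + 1L
      # iterative flood fill (stack), avoids recursion depth limits
      stack_i <- integer(64L); stack_j <- integer(64L)
      stack_i[1L] <- i; stack_j[1L] <- j; top <- 1L
      labels[i, j] <- lab
      while (top > 0L) {
        ci <- stack_i[top]; cj <- stack_j[top]; top <- top - 1L
        for (k in seq_along(dr)) {
          ni <- ci + dr[k]; nj <- cj + dc[k]
          if (ni < 1L || ni > nr || nj < 1L || nj > nc) next
          if (soil[ni, nj] && labels[ni, nj] == 0L) {
            labels[ni, nj] <- lab
            top <- top + 1L
            if (top > length(stack_i)) {
              length(stack_i) <- 2L * top; length(stack_j) <- 2L * top
            }
            stack_i[top] <- ni; stack_j[top] <- nj
          }
        }
      }
    }
  }
  structure(list(labels = labels, n_patches = lab, cell_side = grid$cell_side),
            class = "patch_map")
}

#' @export
print.patch_map <- function(x, ...) {
  cat(sprintf("<patch_map> %d x %d cells, %d patch(es)\n",
              nrow(x$labels), ncol(x$labels), x$n_patches))
  invisible(x)
}

#' Patch area from cell count
#'
#' Area of a raster patch: number of cells times the cell area. With the
#' field protocol's 0.39 m cells a single cell covers 0.39^2 = 0.1521,
#' i.e. 0.15 m2 at the reported precision.
#'
#' @param n_cells Number of cells in the patch (>= 1).
#' @param cell_side Cell side length in metres.
#' @return Area in m2.
#' @export
patch_area <- function(n_cells, cell_side) {
  if (any(n_cells < 1)) stop("'n_cells' must be >= 1")
  if (cell_side <= 0) stop("'cell_side' must be positive")
  n_cells * cell_side^2
}

#' Patch perimeter by exposed-edge counting
#'
#' Perimeter of a labelled raster patch: the number of cell edges adjacent
#' to rock or to the raster boundary, times the cell side. This is the
#' standard raster convention; a single cell has perimeter `4 * cell_side`.
#'
#' @param patch_map A `patch_map` from [delineate_patches()].
#' @param id Patch label (1..n_patches). If missing, perimeters for all
#'   patches are returned as a named vector.
#' @return Perimeter(s) in metres.
#' @export
patch_perimeter <- function(patch_map, id = NULL) {
  stopifnot(inherits(patch_map, "patch_map"))
  labels <- patch_map$labels
  nr <- nrow(labels); nc <- ncol(labels)
  # pad with rock so boundary edges count as exposed
  padded <- matrix(0L, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- labels
  core <- padded[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
  exposed <- (core != padded[1:nr, 2:(nc + 1L), drop = FALSE]) +
             (core != padded[3:(nr + 2L), 2:(nc + 1L), drop = FALSE]) +
             (core != padded[2:(nr + 1L), 1:nc, drop = FALSE]) +
             (core != padded[2:(nr + 1L), 3:(nc + 2L), drop = FALSE])
  # edges between two distinct patches cannot occur under 4- or 8-labelling,
  # so every mismatching edge of a soil cell faces rock or the boundary
  ids <- seq_len(patch_map$n_patches)
  edges <- vapply(ids, function(k) sum(exposed[core == k]), numeric(1))
  pm <- edges * patch_map$cell_side
  names(pm) <- ids
  if (is.null(id)) pm else {
    if (!id %in% ids) stop("no patch with id ", id)
    unname(pm[as.character(id)])
  }
}

#' Fractal dimension of a patch
#'
#' Perimeter-area fractal dimension, `PFD = 2 * ln(PM / 4) / ln(PA)`,
#' a landscape-ecology measure of boundary complexity. Squares with
#' `PM = 4 * s`, `PA = s^2` give exactly 1. The formula is singular at
#' `PA = 1` m2 (ln PA = 0): there it returns `NaN` with a warning.
#'
#' @param PA Patch area in m2 (> 0).
#' @param PM Patch perimeter in m (> 0).
#' @return Dimensionless fractal dimension (vectorised).
#' @export
fractal_dimension <- function(PA, PM) {
  if (any(PA <= 0) || any(PM <= 0)) stop("PA and PM must be positive")
  out <- 2 * log(PM / 4) / log(PA)
  if (any(PA == 1)) {
    warning("PFD undefined for PA = 1 m^2 (ln PA = 0); returning NaN")
    out[PA == 1] <- NaN
  }
  out
}

#' Per-patch geometry table
#'
#' Computes cell count, area (PA), perimeter (PM), fractal dimension (PFD)
#' and the perimeter-to-area ratio for every patch in a map.
#'
#' @param patch_map A `patch_map`.
#' @return A data.frame with columns `patch_id`, `n_cells`, `PA_m2`, `PM_m`,
#'   `PFD`, `PA_ratio` (PM/PA), one row per patch.
#' @export
patch_metrics <- function(patch_map) {
  stopifnot(inherits(patch_map, "patch_map"))
  n <- patch_map$n_patches
  if (n == 0L) {
    return(data.frame(patch_id = integer(), n_cells = integer(),
                      PA_m2 = numeric(), PM_m = numeric(), PFD = numeric(),
                      PA_ratio = numeric()))
  }
  tab <- tabulate(patch_map$labels[patch_map$labels > 0L], nbins = n)
  pa <- patch_area(tab, patch_map$cell_side)
  pm <- unname(patch_perimeter(patch_map))
  pfd <- suppressWarnings(fractal_dimension(pa, pm))
  data.frame(patch_id = seq_len(n), n_cells = tab, PA_m2 = pa, PM_m = pm,
             PFD = pfd, PA_ratio = pm / pa)
}

#' Summary statistics for a patch property
#'
#' Min, max, arithmetic mean, sample SD (n - 1 denominator) and coefficient
#' of variation CV = SD/mean, the row format used for patch-property and
#' diversity summary tables. Non-finite values are dropped (their count is
#' returned in `n_excluded`).
#'
#' @param values Numeric vector (>= 2 finite values for SD).
#' @param digits Rounding applied to the returned row; `NULL` for full
#'   precision. Reported tables use 2 decimals.
#' @param population_sd Use the n-denominator SD instead of the sample SD.
#' @return A one-row data.frame: `min`, `max`, `mean`, `SD`, `CV`, `n`,
#'   `n_excluded`.
#' @examples
#' summarize_patch_properties(c(1, 2, 3), digits = NULL)  # mean 2, SD 1, CV 0.5
#' @export
summarize_patch_properties <- function(values, digits = 2,
                                       population_sd = FALSE) {
  keep <- is.finite(values)
  x <- values[keep]
  if (length(x) < 2L) stop("need >= 2 finite values to summarize")
  s <- stats::sd(x)
  if (population_sd) s <- s * sqrt((length(x) - 1) / length(x))
  m <- mean(x)
  cv <- if (m == 0) NaN else s / m
  row <- data.frame(min = min(x), max = max(x), mean = m, SD = s, CV = cv)
  if (!is.null(digits)) row[] <- lapply(row, round, digits = digits)
  row$n <- length(x)
  row$n_excluded <- sum(!keep)
  row
}
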