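#' Read a soil-depth grid from CSV
#'
#' Plain rectangular numeric CSV, no header: one value per cell in cm,
#' 0 = rock, row 1 = top of the plot.
#'
#' @param path CSV file path.
#' @param cell_side Cell side in metres.
#' @return A [soil_grid()].
#' @export
read_soil_grid <- function(path, cell_side = 0.39) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  soil_grid(m, cell_side)
}

#' Write a soil-depth grid to CSV
#' @param grid A [soil_grid()].
#' @param path Output path.
#' @export
write_soil_grid <- function(grid, path) {
  stopifnot(inherits(grid, "soil_grid"))
  utils::write.table(grid$depths, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a patch label map to CSV (integer labels, 0 = rock)
#' @param patch_map A `patch_map`.
#' @param path Output path.
#' @export
write_patch_map <- function(patch_map, path) {
  stopifnot(inherits(patch_map, "patch_map"))
  utils::write.table(patch_map$labels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a quadrat sample table from CSV
#'
#' Expects the header `patch_id,Sd_cm,SWC_pct,TC_gkg,TN_gkg` (extra columns
#' are kept).
#'
#' @param path CSV file path.
#' @return Validated sample data.frame with a derived `TCTN` column.
#' @export
read_sample_table <- function(path) {
  validate_sample_table(utils::read.csv(path))
}

#' Read a community matrix from CSV
#'
#' Rows = patches (first column = patch id), columns = species, integer
#' abundances.
#'
#' @param path CSV file path.
#' @return Integer matrix with patch-id rownames and species colnames.
#' @export
read_community_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "integer"
  if (any(m < 0, na.rm = TRUE)) stop("abundances must be >= 0")
  m
}

#' Write a community matrix to CSV
#' @param comm Community matrix with dimnames.
#' @param path Output path.
#' @export
write_community_matrix <- function(comm, path) {
  df <- data.frame(patch_id = rownames(comm), comm, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
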