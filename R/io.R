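#' Write a per-cell surface as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a six-line header followed by rows of cell
#' values, top row first.
#'
#' @param values Numeric vector of per-cell values in row-major order
#'   (bottom row first, as produced throughout the package).
#' @param grid The [grid_spec()] the values live on.
#' @param path Output file path.
#' @param digits Significant digits written (default 8).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, grid, path, digits = 8) {
  stopifnot(inherits(grid, "grid_spec"),
            length(values) == n_cells(grid))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    paste("xllcorner", grid$origin[1]),
    paste("yllcorner", grid$origin[2]),
    paste("cellsize", grid$cell_size),
    "NODATA_value -9999"
  ), con)
  m <- matrix(values, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  for (r in rev(seq_len(grid$n_rows))) {
    writeLines(paste(signif(m[r, ], digits), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#'
#' @param path File path.
#' @return A list with `grid` (a [grid_spec()]) and `values` (row-major,
#'   bottom row first).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  val <- function(i) as.numeric(hdr[[i]][2])
  grid <- grid_spec(val(1), val(2), cell_size = val(5),
                    origin = c(val(3), val(4)))
  rows <- lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  m <- do.call(rbind, rev(rows))
  list(grid = grid, values = as.numeric(t(m)))
}
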