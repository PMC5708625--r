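#' Define a regular analysis grid
#'
#' The simulation landscape is a regular grid of square cells (1 degree by
#' default, mimicking the common resolution of global bio-climatic layers).
#' Cells are indexed row-major from the bottom-left corner and all
#' coordinates refer to cell centres.
#'
#' @param n_cols,n_rows Number of cells along x and y. Both must be >= 8 so
#'   that spatial structure (gradients, humps, Voronoi regions) is resolvable.
#' @param cell_size Cell edge length in degrees.
#' @param origin Numeric length-2, (x, y) of the lower-left corner of the grid.
#'
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' g <- grid_spec(90, 45)
#' n_cells(g)
grid_spec <- function(n_cols, n_rows, cell_size = 1, origin = c(0, 0)) {
  n_cols <- as.integer(n_cols)
  n_rows <- as.integer(n_rows)
  if (is.na(n_cols) || is.na(n_rows) || n_cols < 8L || n_rows < 8L) {
    stop("`n_cols` and `n_rows` must both be >= 8", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(origin) || length(origin) != 2L) {
    stop("`origin` must be a numeric vector of length 2", call. = FALSE)
  }
  structure(
    list(n_cols = n_cols, n_rows = n_rows,
         cell_size = as.numeric(cell_size), origin = as.numeric(origin)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g degrees, origin (%g, %g)\n",
              x$n_cols, x$n_rows, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Number of cells in a grid
#' @param grid A [grid_spec()].
#' @return Integer cell count.
#' @export
n_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  grid$n_cols * grid$n_rows
}

#' Cell-centre coordinates of every grid cell
#'
#' @param grid A [grid_spec()].
#' @return A tibble with columns `cell` (row-major index, bottom row first),
#'   `col`, `row`, `x`, `y`.
#' @export
cell_centres <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  tibble::tibble(
    cell = seq_len(n_cells(grid)),
    col = col,
    row = row,
    x = grid$origin[1] + (col - 0.5) * grid$cell_size,
    y = grid$origin[2] + (row - 0.5) * grid$cell_size
  )
}

grid_extent <- function(grid) {
  c(xmin = grid$origin[1],
    xmax = grid$origin[1] + grid$n_cols * grid$cell_size,
    ymin = grid$origin[2],
    ymax = grid$origin[2] + grid$n_rows * grid$cell_size)
}

#' Map point coordinates to containing cells
#'
#' Points on the exact upper/right boundary are assigned to the last cell so
#' that the closed extent maps onto valid indices.
#'
#' @param grid A [grid_spec()].
#' @param x,y Numeric coordinate vectors.
#' @return Integer vector of row-major cell indices; `NA` for points outside
#'   the grid extent.
#' @export
point_to_cell <- function(grid, x, y) {
  ext <- grid_extent(grid)
  col <- floor((x - ext["xmin"]) / grid$cell_size) + 1
  row <- floor((y - ext["ymin"]) / grid$cell_size) + 1
  col[x == ext["xmax"]] <- grid$n_cols
  row[y == ext["ymax"]] <- grid$n_rows
  out <- (row - 1) * grid$n_cols + col
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows |
    is.na(x) | is.na(y)
  out[bad] <- NA_integer_
  as.integer(out)
}

points_in_grid <- function(grid, x, y) {
  ext <- grid_extent(grid)
  x >= ext["xmin"] & x <= ext["xmax"] & y >= ext["ymin"] & y <= ext["ymax"]
}

# Total landscape area in squared coordinate units.
grid_area <- function(grid) {
  n_cells(grid) * grid$cell_size^2
}
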