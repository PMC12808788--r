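# Discrete 2-D grid-world geometry: coordinates, movement, vision, the 3x3
# region partition of the predator-prey arena, and object placement.
#
# Cells are length-2 integer vectors c(x, y), 0-based, x rightward and
# y downward (y = 0 is the top row). With 8-directional single-cell moves,
# the number of steps between two cells equals the Chebyshev distance, so
# "vision < 2" means the 3x3 neighbourhood and "vision < 4" the 7x7 one.

# the 8 king-move directions, row-major over dx then dy
DIRS <- cbind(dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
              dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L))

#' Grid specification
#'
#' @param width,height Grid dimensions in cells.
#' @return A `grid_spec` list with `width`, `height` and `n_cells`.
#' @export
grid_spec <- function(width, height) {
  stopifnot(width >= 1, height >= 1)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_cells = as.integer(width * height)),
            class = "grid_spec")
}

#' Chebyshev distance between two cells
#'
#' `max(|dx|, |dy|)`: the number of 8-directional single-cell steps needed to
#' travel between the cells.
#'
#' @param a,b Cells as `c(x, y)`.
#' @return Non-negative integer.
#' @export
distance <- function(a, b) {
  as.integer(max(abs(a[1L] - b[1L]), abs(a[2L] - b[2L])))
}

#' One greedy step toward a target
#'
#' Moves one cell, `sign(dx)` and `sign(dy)` applied independently per axis,
#' so the target is reached in exactly `distance(pos, target)` steps.
#'
#' @param pos,target Cells as `c(x, y)`.
#' @return The next cell (unchanged when already at the target).
#' @export
step_toward <- function(pos, target) {
  c(pos[1L] + sign(target[1L] - pos[1L]),
    pos[2L] + sign(target[2L] - pos[2L]))
}

#' One uniform random 8-directional step
#'
#' Chooses uniformly among the 8 neighbours, then clips each coordinate to
#' the grid (so from a boundary cell some directions collapse onto in-bounds
#' cells, possibly the current one). Optional `xlim`/`ylim` restrict the walk
#' to a sub-rectangle, e.g. one region. Uses R's global RNG.
#'
#' @param pos Cell as `c(x, y)`.
#' @param grid A [grid_spec()].
#' @param xlim,ylim Optional inclusive 0-based bounds `c(lo, hi)` overriding
#'   the grid boundary.
#' @return An in-bounds cell.
#' @export
random_step <- function(pos, grid, xlim = NULL, ylim = NULL) {
  if (is.null(xlim)) xlim <- c(0L, grid$width - 1L)
  if (is.null(ylim)) ylim <- c(0L, grid$height - 1L)
  d <- DIRS[sample.int(8L, 1L), ]
  as.integer(c(min(max(pos[1L] + d[1L], xlim[1L]), xlim[2L]),
               min(max(pos[2L] + d[2L], ylim[1L]), ylim[2L])))
}

# --- 3x3 region partition of the 12x12 predator-prey arena ----------------
# Regions are the nine 4x4 blocks, numbered row-major 0..8:
#   0 1 2
#   3 4 5
#   6 7 8
# so the start cell (6, 0) lies in region 1, the shrimp block (bottom-left)
# is region 6, and the crab block (bottom-right) is region 8.

REGION_BLOCK <- 4L
REGIONS_PER_ROW <- 3L

check_region_id <- function(region) {
  if (length(region) != 1L || !is.finite(region) || region < 0 || region > 8 ||
      region != as.integer(region))
    stop("region id must be an integer in 0..8", call. = FALSE)
  as.integer(region)
}

#' Region containing a cell
#' @param cell Cell as `c(x, y)` on the 12x12 grid.
#' @return Region id 0..8.
#' @export
region_of <- function(cell) {
  as.integer((cell[2L] %/% REGION_BLOCK) * REGIONS_PER_ROW +
               cell[1L] %/% REGION_BLOCK)
}

#' Center cell of a region
#'
#' A 4x4 block has no exact center cell; the floor convention picks the cell
#' at offset (+1, +1) inside the block. Any fixed interior cell serves, since
#' an agent roams the region after arriving.
#'
#' @param region Region id 0..8.
#' @return Cell as `c(x, y)`.
#' @export
region_center <- function(region) {
  region <- check_region_id(region)
  c((region %% REGIONS_PER_ROW) * REGION_BLOCK + 1L,
    (region %/% REGIONS_PER_ROW) * REGION_BLOCK + 1L)
}

#' All 16 cells of a region
#' @param region Region id 0..8.
#' @return 16 x 2 integer matrix of (x, y) rows.
#' @export
region_cells <- function(region) {
  region <- check_region_id(region)
  x0 <- (region %% REGIONS_PER_ROW) * REGION_BLOCK
  y0 <- (region %/% REGIONS_PER_ROW) * REGION_BLOCK
  cbind(x = rep(x0:(x0 + 3L), times = 4L),
        y = rep(y0:(y0 + 3L), each = 4L))
}

#' Inclusive x/y bounds of a region (for clipped within-region roaming)
#' @param region Region id 0..8.
#' @return List with `xlim` and `ylim`, each `c(lo, hi)` 0-based inclusive.
#' @export
region_bounds <- function(region) {
  region <- check_region_id(region)
  x0 <- (region %% REGIONS_PER_ROW) * REGION_BLOCK
  y0 <- (region %/% REGIONS_PER_ROW) * REGION_BLOCK
  list(xlim = c(x0, x0 + 3L), ylim = c(y0, y0 + 3L))
}

#' Uniform random cell within a region
#' @param region Region id 0..8.
#' @return Cell as `c(x, y)`; uses R's global RNG.
#' @export
place_in_region <- function(region) {
  cells <- region_cells(region)
  cells[sample.int(nrow(cells), 1L), ]
}

#' Uniform random predator placement
#'
#' The predator enters on the left side of the arena: uniform over cells with
#' `x <= xmax` (default `xmax = 5`, i.e. x < 6) across all rows.
#'
#' @param xmax Largest allowed x (inclusive).
#' @param height Number of rows.
#' @return Cell as `c(x, y)`; uses R's global RNG.
#' @export
place_predator <- function(xmax = 5L, height = 12L) {
  c(sample.int(xmax + 1L, 1L) - 1L, sample.int(height, 1L) - 1L)
}

# flat cell index helpers (0-based, row-major: cell = y*width + x)
cell_to_flat <- function(cell, width) cell[2L] * width + cell[1L]
flat_to_cell <- function(flat, width) c(flat %% width, flat %/% width)
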