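# Episodic memory core: a 3-D value matrix indexed (what, when, where),
# delta-rule learning, and softmax action selection.

#' Create an empty episodic memory
#'
#' The memory is a three-dimensional array of expected values indexed by
#' `what` (object kind), `when` (hour of day) and `where` (flattened grid
#' cell). All public indices are 0-based; the flat cell index follows the
#' row-major convention `cell = y * width + x` with `y = 0` the top row.
#' All entries start at exactly 0.
#'
#' @param n_what Number of object kinds (>= 1).
#' @param n_when Number of hours per day (>= 1).
#' @param n_where Number of grid cells (>= 1).
#' @param what_names Optional character vector of length `n_what` naming the
#'   object kinds (e.g. `c("crab", "shrimp")`); named lookup is then allowed
#'   wherever a `what` index is taken.
#' @param width,height Optional grid dimensions with
#'   `width * height == n_where`; required by [landscape()] to recover
#'   (x, y) coordinates from flat cell indices.
#' @return An object of class `epimem`: the zero-filled value array with the
#'   grid metadata attached as attributes.
#' @examples
#' mem <- make_memory(2, 3, 64, what_names = c("crab", "shrimp"),
#'                    width = 8, height = 8)
#' dim(mem)
#' @export
make_memory <- function(n_what, n_when, n_where, what_names = NULL,
                        width = NULL, height = NULL) {
  for (d in c(n_what = n_what, n_when = n_when, n_where = n_where)) {
    if (length(d) != 1L || !is.finite(d) || d < 1 || d != as.integer(d))
      stop("memory dimensions must be positive integers", call. = FALSE)
  }
  if (!is.null(what_names) && length(what_names) != n_what)
    stop("'what_names' must have length n_what", call. = FALSE)
  if (xor(is.null(width), is.null(height)))
    stop("give both 'width' and 'height' or neither", call. = FALSE)
  if (!is.null(width) && width * height != n_where)
    stop("width * height must equal n_where", call. = FALSE)
  structure(array(0, dim = c(n_what, n_when, n_where)),
            what_names = what_names,
            width = if (is.null(width)) NULL else as.integer(width),
            height = if (is.null(height)) NULL else as.integer(height),
            class = "epimem")
}

#' @export
print.epimem <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<epimem> %d what x %d when x %d where; %d nonzero entries\n",
              d[1L], d[2L], d[3L], sum(x != 0)))
  wn <- attr(x, "what_names")
  if (!is.null(wn)) cat("  what:", paste(wn, collapse = ", "), "\n")
  invisible(x)
}

# Resolve a 0-based (or named, for `what`) index to 1-based, with bounds check.
resolve_index <- function(mem, i, axis) {
  n <- dim(mem)[axis]
  if (axis == 1L && is.character(i)) {
    wn <- attr(mem, "what_names")
    j <- match(i, wn)
    if (is.na(j)) stop("unknown object name: ", i, call. = FALSE)
    return(j)
  }
  if (length(i) != 1L || !is.finite(i) || i != as.integer(i))
    stop("index must be a single integer", call. = FALSE)
  if (i < 0 || i >= n)
    stop(sprintf("index %d out of bounds [0, %d)", as.integer(i), n),
         call. = FALSE)
  as.integer(i) + 1L
}

#' Query the episodic memory
#'
#' Reads out expected values with any combination of the three indices fixed;
#' free dimensions are returned in full. The result is a snapshot: later
#' updates to the memory do not alter a previously returned slice.
#'
#' @param mem An `epimem` object.
#' @param what,when,where Optional 0-based indices (`what` may also be an
#'   object name). Omitted dimensions are left free.
#' @return A `value_slice`: numeric data over the free dimensions (a scalar
#'   when all three are fixed) with a `selector` attribute recording which
#'   indices were fixed.
#' @examples
#' mem <- make_memory(2, 3, 64)
#' mem <- delta_update(mem, 0, 1, 5, r = 4, alpha = 0.1)
#' query(mem, what = 0, when = 1)[6]   # 0.4 at flat cell 5
#' @export
query <- function(mem, what = NULL, when = NULL, where = NULL) {
  stopifnot(inherits(mem, "epimem"))
  sel <- list(what = what, when = when, where = where)
  i <- if (is.null(what)) TRUE else resolve_index(mem, what, 1L)
  j <- if (is.null(when)) TRUE else resolve_index(mem, when, 2L)
  k <- if (is.null(where)) TRUE else resolve_index(mem, where, 3L)
  v <- unclass(mem)[i, j, k, drop = TRUE]
  structure(as.vector(v) + 0, dim = dim(v), selector = sel,
            class = "value_slice")
}

#' Delta-rule (Rescorla-Wagner) update of one memory entry
#'
#' Applies `v <- v + alpha * (r - v)` to the single entry at
#' (`what`, `when`, `where`); every other entry is untouched. Iterated with a
#' constant reward the entry converges to `r`.
#'
#' @inheritParams query
#' @param r Signed reward (penalties are negative).
#' @param alpha Learning rate in (0, 1].
#' @return The updated `epimem`. The new stored value is retrievable with
#'   `query(mem, what, when, where)`.
#' @export
delta_update <- function(mem, what, when, where, r, alpha) {
  stopifnot(inherits(mem, "epimem"))
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]", call. = FALSE)
  i <- resolve_index(mem, what, 1L)
  j <- resolve_index(mem, when, 2L)
  k <- resolve_index(mem, where, 3L)
  mem[i, j, k] <- mem[i, j, k] + alpha * (r - mem[i, j, k])
  mem
}

#' Softmax choice probabilities
#'
#' `P_i = exp(beta * v_i) / sum_j exp(beta * v_j)`, computed with
#' max-subtraction so large values cannot overflow. `beta = 0` gives the
#' uniform distribution.
#'
#' @param values Finite numeric vector of action values.
#' @param beta Inverse temperature, >= 0.
#' @return Probability vector of the same length.
#' @export
softmax_probs <- function(values, beta = 1) {
  if (length(values) == 0L) stop("empty value vector", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (!is.finite(beta) || beta < 0) stop("beta must be >= 0", call. = FALSE)
  z <- beta * values
  e <- exp(z - max(z))
  e / sum(e)
}

#' Sample an action by softmax
#'
#' Draws one index from the softmax distribution over `values` using R's
#' global random number stream (seed with [set.seed()] for reproducibility).
#'
#' @inheritParams softmax_probs
#' @return A single 1-based index into `values`.
#' @export
softmax_choice <- function(values, beta = 1) {
  p <- softmax_probs(values, beta)
  # inverse-CDF draw: one uniform, first index whose cumulative prob covers it
  u <- stats::runif(1)
  cp <- cumsum(p)
  which(u <= cp)[1L]
}

#' Most valuable cell for an object at an hour
#'
#' Returns the flat (0-based) cell index with the largest stored value in the
#' `(what, when, :)` slice. Ties break deterministically to the smallest
#' index, so a fresh all-zero memory yields cell 0.
#'
#' @inheritParams query
#' @return A single 0-based flat cell index.
#' @export
argmax_cell <- function(mem, what, when) {
  stopifnot(inherits(mem, "epimem"))
  i <- resolve_index(mem, what, 1L)
  j <- resolve_index(mem, when, 2L)
  which.max(unclass(mem)[i, j, ]) - 1L
}

#' Summed expected value over a set of cells
#'
#' Arithmetic (signed) sum of the `(what, when)` slice over the given cells:
#' the "what"-query aggregate when `cells` spans the grid, or a region
#' aggregate when it spans one region. Negatively stored predator entries
#' contribute negatively.
#'
#' @inheritParams query
#' @param cells Integer vector of 0-based flat cell indices (possibly empty).
#' @return A scalar; 0 for an empty cell set.
#' @export
summed_value <- function(mem, what, when, cells) {
  stopifnot(inherits(mem, "epimem"))
  i <- resolve_index(mem, what, 1L)
  j <- resolve_index(mem, when, 2L)
  if (length(cells) == 0L) return(0)
  if (any(cells < 0 | cells >= dim(mem)[3L]))
    stop("cell index out of bounds", call. = FALSE)
  sum(unclass(mem)[i, j, cells + 1L])
}

#' Expected-value landscape of the whole memory
#'
#' Enumerates every nonzero entry as one row, giving the full what/when/where
#' value landscape. Querying a fixed hour column of this table is the
#' "mental time travel" readout: the same persistent memory inspected forward
#' or backward in time. The `magnitude` column carries `abs(value)` as a
#' rendering hint (marker size proportional to expected value).
#'
#' @param mem An `epimem` with grid `width`/`height` metadata (or pass them).
#' @param width,height Grid dimensions; default to the memory's attributes.
#' @return A data.frame with columns `what`, `when`, `cell`, `x`, `y`,
#'   `value`, `magnitude`, sorted by (`when`, `what`, `cell`). Empty for an
#'   all-zero memory.
#' @export
landscape <- function(mem, width = attr(mem, "width"),
                      height = attr(mem, "height")) {
  stopifnot(inherits(mem, "epimem"))
  if (is.null(width) || is.null(height))
    stop("grid width/height unknown; pass them explicitly", call. = FALSE)
  nz <- which(unclass(mem) != 0, arr.ind = TRUE)
  wn <- attr(mem, "what_names")
  cell <- nz[, 3L] - 1L
  out <- data.frame(
    what = if (is.null(wn)) nz[, 1L] - 1L else wn[nz[, 1L]],
    when = nz[, 2L] - 1L,
    cell = cell,
    x = cell %% width,
    y = cell %/% width,
    value = unclass(mem)[nz],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$when, nz[, 1L], out$cell), , drop = FALSE]
  out$magnitude <- abs(out$value)
  rownames(out) <- NULL
  out
}
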