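#' Build an elliptical in-plane voxel mask
#'
#' Defines the analysis domain: a 2D grid of cells of which an elliptical
#' central region counts as "brain". Cells are ranked by scaled elliptical
#' distance from the grid center (semi-axes proportional to the grid
#' dimensions) and the closest `target_voxels` cells are taken, so the
#' in-mask voxel count is exact. Ties in distance are broken in row-major
#' order, making the mask fully deterministic.
#'
#' @param shape Integer vector of length 2, `(rows, cols)` of the grid.
#' @param target_voxels Number of in-mask voxels required (default 4713,
#'   the size of the simulated horizontal brain slice).
#' @return An object of class `grid_mask`: a list with `shape`, `inside`
#'   (logical rows x cols matrix), `n_voxels`, and `idx` (column-major
#'   linear indices of in-mask cells, the canonical voxel ordering used by
#'   every per-voxel vector in the package).
#' @examples
#' m <- make_mask(c(90, 70), 4713)
#' m$n_voxels
#' @export
make_mask <- function(shape = c(90L, 70L), target_voxels = 4713L) {
  if (length(shape) != 2L || any(shape < 1) || any(shape != round(shape))) {
    stop_invalid("`shape` must be two positive integers (rows, cols)")
  }
  shape <- as.integer(shape)
  target_voxels <- check_count(target_voxels, "target_voxels", lower = 1L)
  if (target_voxels > prod(shape)) {
    stop_invalid("target_voxels (%d) exceeds grid capacity (%d)",
                 target_voxels, prod(shape))
  }
  nr <- shape[1L]; nc <- shape[2L]
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  row <- rep(seq_len(nr), times = nc)
  col <- rep(seq_len(nc), each = nr)
  d <- ((row - cr) / (nr / 2))^2 + ((col - cc) / (nc / 2))^2
  # rank by distance, ties row-major (row varies slowest in row-major order)
  ord <- order(d, row, col)
  keep <- ord[seq_len(target_voxels)]
  inside <- matrix(FALSE, nr, nc)
  inside[keep] <- TRUE
  structure(
    list(shape = shape, inside = inside,
         n_voxels = target_voxels, idx = which(inside)),
    class = "grid_mask"
  )
}

#' @export
print.grid_mask <- function(x, ...) {
  cat(sprintf("<grid_mask> %d x %d grid, %d in-mask voxels (%.1f%%)\n",
              x$shape[1L], x$shape[2L], x$n_voxels,
              100 * x$n_voxels / prod(x$shape)))
  invisible(x)
}

# Map a per-voxel vector back onto the full grid (NA outside the mask,
# or `fill` if given).
voxels_to_grid <- function(values, mask, fill = NA_real_) {
  stopifnot(inherits(mask, "grid_mask"), length(values) == mask$n_voxels)
  g <- matrix(fill, mask$shape[1L], mask$shape[2L])
  g[mask$idx] <- values
  g
}
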