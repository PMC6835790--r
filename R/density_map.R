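#' Scott-rule bandwidth for a 2-D kernel density
#'
#' h = n^(-1/6), the bivariate Scott plug-in rule applied directly to the
#' (unstandardized) map coordinates.
#'
#' @param n Number of consumers (>= 1).
#' @return Bandwidth h > 0.
#' @examples
#' scott_bandwidth(64) # 0.5
#' @export
scott_bandwidth <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    stop("scott_bandwidth: n must be a single integer >= 1", call. = FALSE)
  }
  as.numeric(n)^(-1 / 6)
}

#' Evaluation grid over an embedding
#'
#' A regular grid spanning the consumer bounding box expanded by a margin on
#' every side; the same grid is shared by the density field and every
#' acceptance surface so the maps superimpose exactly.
#'
#' @param embedding An `lpl_embedding`, or an n x 2 coordinate matrix.
#' @param n Number of grid points per axis (default 200).
#' @param expand Fractional bounding-box expansion per side (default 0.15).
#' @return A list of class `lpl_grid` with monotone vectors `x`, `y`.
#' @export
make_grid <- function(embedding, n = 200L, expand = 0.15) {
  coords <- if (inherits(embedding, "lpl_embedding")) embedding$coords else as.matrix(embedding)
  stopifnot(ncol(coords) == 2L, n >= 2L, expand >= 0)
  rng_x <- range(coords[, 1]); rng_y <- range(coords[, 2])
  pad <- function(r) {
    w <- diff(r)
    if (w == 0) w <- max(abs(r[1]), 1) # degenerate axis: open up a unit box
    r + c(-1, 1) * expand * w
  }
  rng_x <- pad(rng_x); rng_y <- pad(rng_y)
  structure(list(x = seq(rng_x[1], rng_x[2], length.out = n),
                 y = seq(rng_y[1], rng_y[2], length.out = n)),
            class = "lpl_grid")
}

#' Consumer distribution map (Gaussian kernel density)
#'
#' Estimates the consumer density on the map as a sum of isotropic bivariate
#' Gaussian kernels centered on the consumer points:
#' p(x) = 1/(2 pi n h^2) * sum_i exp(-||x - x_i||^2 / (2 h^2)),
#' with the Scott-rule bandwidth by default.
#'
#' @param embedding An `lpl_embedding`.
#' @param grid An `lpl_grid` (default [make_grid()] of the embedding).
#' @param h Bandwidth; default [scott_bandwidth()] of the consumer count.
#' @param as_printed If `TRUE`, divide the exponent by `2h` instead of
#'   `2h^2`. This variant does not integrate to one under the stated
#'   prefactor; it exists only for side-by-side fidelity comparisons.
#' @return An object of class `lpl_density`: `grid`, `values` (matrix,
#'   rows indexed by `grid$x`, columns by `grid$y`), `bandwidth_h`,
#'   `n_consumers`.
#' @export
estimate_density <- function(embedding, grid = NULL, h = NULL,
                             as_printed = FALSE) {
  stopifnot(inherits(embedding, "lpl_embedding"))
  pts <- embedding$coords
  n <- nrow(pts)
  if (n < 1L) stop("empty embedding", call. = FALSE)
  if (is.null(grid)) grid <- make_grid(embedding)
  if (is.null(h)) h <- scott_bandwidth(n)
  stopifnot(h > 0)
  denom <- if (as_printed) 2 * h else 2 * h^2
  vals <- matrix(0, length(grid$x), length(grid$y))
  for (i in seq_len(n)) {
    dx2 <- (grid$x - pts[i, 1])^2
    dy2 <- (grid$y - pts[i, 2])^2
    vals <- vals + exp(-outer(dx2, dy2, `+`) / denom)
  }
  vals <- vals / (2 * pi * n * h^2)
  structure(
    list(grid = grid, values = vals, bandwidth_h = h, n_consumers = n,
         as_printed = as_printed),
    class = "lpl_density"
  )
}

#' Evaluate the kernel density at arbitrary points
#'
#' Same estimator as [estimate_density()] but at the given points rather
#' than on a grid.
#'
#' @param embedding An `lpl_embedding`.
#' @param points m x 2 matrix of map coordinates.
#' @param h Bandwidth (default Scott rule).
#' @return Numeric vector of densities.
#' @export
density_at <- function(embedding, points, h = NULL) {
  pts <- embedding$coords
  n <- nrow(pts)
  if (is.null(h)) h <- scott_bandwidth(n)
  points <- matrix(as.numeric(points), ncol = 2L)
  d2 <- outer(points[, 1], pts[, 1], `-`)^2 + outer(points[, 2], pts[, 2], `-`)^2
  rowSums(exp(-d2 / (2 * h^2))) / (2 * pi * n * h^2)
}

#' Numeric integral of a density field
#'
#' Trapezoid quadrature over the field's grid; close to 1 when the grid
#' covers the consumers with a generous margin.
#'
#' @param field An `lpl_density`.
#' @return The integral estimate.
#' @export
integrate_density <- function(field) {
  stopifnot(inherits(field, "lpl_density"))
  trap_w <- function(g) {
    w <- c(diff(g), 0) / 2 + c(0, diff(g)) / 2
    w
  }
  wx <- trap_w(field$grid$x)
  wy <- trap_w(field$grid$y)
  as.numeric(wx %*% field$values %*% wy)
}

#' Contour levels for a density field
#'
#' n equally spaced positive levels strictly inside (0, max p]; a single
#' level sits at half the peak density.
#'
#' @param field An `lpl_density`.
#' @param n_levels Number of levels (>= 1).
#' @return Strictly increasing numeric vector of length `n_levels`.
#' @export
density_contours <- function(field, n_levels = 5L) {
  stopifnot(inherits(field, "lpl_density"), n_levels >= 1L)
  peak <- max(field$values)
  if (peak <= 0) stop("degenerate field: density is identically zero",
                      call. = FALSE)
  peak * seq_len(n_levels) / (n_levels + 1)
}

#' Connected components of a super-level set
#'
#' Counts the 4-connected components of the grid region where the density
#' is at least `level` — a discrete mode count, e.g. the number of distinct
#' consumer clusters visible at a contour level.
#'
#' @param field An `lpl_density`.
#' @param level Density threshold.
#' @return Integer component count.
#' @export
contour_components <- function(field, level) {
  stopifnot(inherits(field, "lpl_density"))
  mask <- field$values >= level
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  comp <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue) > 0L) {
      cell <- queue[[1L]]; queue <- queue[-1L]
      i <- (cell - 1L) %% nr + 1L
      j <- (cell - 1L) %/% nr + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] >= 1L && nb[1] <= nr && nb[2] >= 1L && nb[2] <= nc) {
          idx <- (nb[2] - 1L) * nr + nb[1]
          if (mask[idx] && lab[idx] == 0L) {
            lab[idx] <- comp
            queue <- c(queue, idx)
          }
        }
      }
    }
  }
  comp
}
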