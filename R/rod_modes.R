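## Vibratory feature space of a cantilever rod.
##
## A straight rod clamped at the hand behaves as a clamped-free beam: each
## contact location excites its resonant bending modes with a unique
## combination of amplitudes (the "vibratory motif").  Only the first few
## modes fall inside the mechanoreceptor bandwidth, so five modes are used
## throughout.  The map location -> motif is injective, which makes the
## motif space isomorphic to the physical space of the rod and lets it
## stand in for it during localization.

# cache for eigenvalues and shape normalization constants
.rod_cache <- new.env(parent = emptyenv())

#' Eigenvalues of a clamped-free beam
#'
#' Returns the first `n_modes` roots \eqn{\beta_n L} of the characteristic
#' equation of a clamped-free (cantilever) Euler--Bernoulli beam,
#' \eqn{\cosh(x)\cos(x) = -1}, in increasing order.
#'
#' @param n_modes number of modes (positive integer).
#' @return numeric vector of length `n_modes`; each root satisfies
#'   \eqn{|\cosh(\beta)\cos(\beta) + 1| < 10^{-8}}.
#' @examples
#' cantilever_eigenvalues(3) # 1.8751, 4.6941, 7.8548
#' @export
cantilever_eigenvalues <- function(n_modes) {
  n_modes <- stop_if_not_count(n_modes, "n_modes")
  key <- as.character(n_modes)
  if (!is.null(.rod_cache[[paste0("ev", key)]]))
    return(.rod_cache[[paste0("ev", key)]])
  f <- function(x) cos(x) * cosh(x) + 1
  roots <- numeric(n_modes)
  for (k in seq_len(n_modes)) {
    # the k-th root lies within 1 of (k - 1/2) * pi
    r <- stats::uniroot(f, c((k - 0.5) * pi - 1, (k - 0.5) * pi + 1),
                        tol = 1e-12)$root
    # Newton polish to push the residual to the double-precision floor
    for (i in 1:6) {
      fr <- cos(r) * cosh(r) + 1
      dfr <- -sin(r) * cosh(r) + cos(r) * sinh(r)
      r <- r - fr / dfr
    }
    roots[k] <- r
  }
  .rod_cache[[paste0("ev", key)]] <- roots
  roots
}

# normalization constants: max |shape| on [0,1] before scaling
.shape_norms <- function(n_modes = 5L) {
  key <- paste0("norm", n_modes)
  if (!is.null(.rod_cache[[key]])) return(.rod_cache[[key]])
  xs <- seq(0, 1, by = 1e-4)
  norms <- vapply(seq_len(n_modes), function(k)
    max(abs(.shape_raw(k, xs))), numeric(1))
  .rod_cache[[key]] <- norms
  norms
}

# unnormalized clamped-free mode shape
.shape_raw <- function(index, x) {
  b <- cantilever_eigenvalues(max(index, 5L))[index]
  a <- (cosh(b) + cos(b)) / (sinh(b) + sin(b))
  cosh(b * x) - cos(b * x) - a * (sinh(b * x) - sin(b * x))
}

#' Mode shape of a clamped-free beam
#'
#' Bending shape of mode `index` of a cantilever beam of unit length,
#' clamped at `x = 0` and free at `x = 1`, normalized so that the maximum
#' absolute amplitude over `[0, 1]` equals 1.
#'
#' @param index mode number (1..5).
#' @param x normalized position(s) along the beam, in `[0, 1]`.
#' @return dimensionless amplitude(s), same length as `x`.
#' @examples
#' mode_shape(1, 1) # +-1 at the free end
#' @export
mode_shape <- function(index, x) {
  index <- stop_if_not_count(index, "index")
  if (index > 5L) stop("only the first five modes are supported")
  stop_if_not_numeric(x, "x", lower = 0, upper = 1)
  .shape_raw(index, x) / .shape_norms(5L)[index]
}

#' Vibratory motif for a contact location
#'
#' The 5-vector of mode amplitudes excited by contact at location `L`,
#' expressed in percent of tool space (0 = hand/clamp, 100 = tip).  Each
#' mode shape is normalized to unit maximum amplitude and multiplied by
#' `scale`, so that with the default scale the amplitudes stay inside the
#' mode-layer tuning support `[-1.5, 1.5]`.
#'
#' @param L contact location, percent of tool space in `[0, 100]`.
#' @param scale amplitude scaling applied to all modes (default 1).
#' @return numeric 5-vector of dimensionless mode amplitudes.
#' @examples
#' motif_for_location(0)   # all zero: nothing moves at the clamp
#' motif_for_location(100) # each mode's free-end amplitude
#' @export
motif_for_location <- function(L, scale = 1) {
  stop_if_not_number(L, "L", lower = 0, upper = 100)
  stop_if_not_number(scale, "scale")
  vapply(1:5, function(k) mode_shape(k, L / 100), numeric(1)) * scale
}

#' Vibration-location feature space
#'
#' Tabulates the vibratory motif on a regular grid of tool-space locations.
#' The resulting lookup table is isomorphic to the physical space of the
#' rod: every grid location has a distinct motif, and the nearest-motif
#' lookup ([nearest_location()]) inverts the mapping exactly on the grid.
#'
#' @param grid_step grid resolution in percent of tool space (default 1).
#' @param scale amplitude scaling, as in [motif_for_location()].
#' @return an object of class `feature_space`: a list with `grid`
#'   (locations, percent) and `motifs` (matrix, one row per grid location,
#'   columns `m1..m5`).
#' @export
feature_space <- function(grid_step = 1, scale = 1) {
  stop_if_not_number(grid_step, "grid_step", lower = 1e-6, upper = 100)
  grid <- seq(0, 100, by = grid_step)
  motifs <- t(vapply(grid, motif_for_location, numeric(5), scale = scale))
  colnames(motifs) <- paste0("m", 1:5)
  structure(list(grid = grid, motifs = motifs, scale = scale),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("Vibratory feature space: %d locations (step %g%%), 5 modes\n",
              length(x$grid), diff(x$grid[1:2])))
  invisible(x)
}

#' @export
as.data.frame.feature_space <- function(x, ...) {
  data.frame(location_pct = x$grid, x$motifs)
}

#' Invert a motif to its tool-space location
#'
#' Returns the grid location whose stored motif is closest (Euclidean
#' distance) to the query motif.  Ties break toward the smaller location.
#'
#' @param motif numeric 5-vector of mode amplitudes.
#' @param space a [feature_space()] object.
#' @return location in percent of tool space.
#' @examples
#' sp <- feature_space()
#' nearest_location(motif_for_location(37), sp) # 37
#' @export
nearest_location <- function(motif, space) {
  if (!inherits(space, "feature_space") || length(space$grid) == 0L)
    stop("'space' must be a non-empty feature_space object")
  stop_if_not_numeric(motif, "motif")
  if (length(motif) != ncol(space$motifs))
    stop("motif length does not match the feature space")
  d2 <- colSums((t(space$motifs) - motif)^2)
  space$grid[which.min(d2)]
}
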