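## The probabilistic trilateration observer.
##
## Touch at location L on a bounded sensory surface is localized by
## estimating its distance from the two boundaries (landmarks) and fusing
## the two resulting location estimates by maximum likelihood.  The noise
## of each distance estimate grows linearly with distance,
## sd_i = eps_i + d_i * sigma_hat, so fusion produces an inverted-U
## variability profile across the surface: the computational signature of
## trilateration ("perceptual anchoring" at the boundaries).
##
## The canonical unit throughout is percent of tool space: 0 at the hand
## landmark, 100 at the tip.

#' Trilateration observer parameters
#'
#' The three behavioral free parameters of the distance-dependent noise
#' law: `sigma_hat`, the noise slope (SD in percent of space per percent of
#' distance), and `eps1`/`eps2`, landmark-specific intercepts (SD in
#' percent of space) reflecting uncertainty about each landmark's position.
#'
#' @param sigma_hat noise slope, `>= 0`.
#' @param eps1,eps2 intercepts for the proximal (hand) and distal (tip)
#'   landmarks, `>= 0`.
#' @return an object of class `trilateration_params`.
#' @export
trilateration_params <- function(sigma_hat, eps1 = 0, eps2 = 0) {
  stop_if_not_number(sigma_hat, "sigma_hat", lower = 0)
  stop_if_not_number(eps1, "eps1", lower = 0)
  stop_if_not_number(eps2, "eps2", lower = 0)
  structure(list(sigma_hat = sigma_hat, eps1 = eps1, eps2 = eps2),
            class = "trilateration_params")
}

#' @export
print.trilateration_params <- function(x, ...) {
  cat(sprintf(
    "Trilateration parameters: sigma_hat = %.4g, eps1 = %.4g, eps2 = %.4g\n",
    x$sigma_hat, x$eps1, x$eps2))
  invisible(x)
}

#' Surface frame (landmark positions)
#'
#' @param X1,X2 positions of the proximal and distal landmarks in percent
#'   of tool space; `X2 > X1`.
#' @return an object of class `surface_frame`.
#' @export
surface_frame <- function(X1 = 0, X2 = 100) {
  stop_if_not_number(X1, "X1")
  stop_if_not_number(X2, "X2")
  if (X2 <= X1) stop("'X2' must exceed 'X1'")
  structure(list(X1 = X1, X2 = X2), class = "surface_frame")
}

#' Distance estimates from the two landmarks
#'
#' Gaussian likelihoods over the distance between the touch and each
#' landmark.  Means are the true distances `d1 = L - X1`, `d2 = X2 - L`;
#' standard deviations follow the linear noise law
#' `sd_i = eps_i + d_i * sigma_hat`.
#'
#' @param L touch location (percent of tool space) within the frame.
#' @param params a [trilateration_params()] object.
#' @param frame a [surface_frame()] object.
#' @return a list of two distance estimates, each a list with `mean`,
#'   `sd`, `variance` and `anchor` (`"proximal"` or `"distal"`).
#' @export
distance_estimates <- function(L, params, frame = surface_frame()) {
  stopifnot(inherits(params, "trilateration_params"),
            inherits(frame, "surface_frame"))
  stop_if_not_number(L, "L", lower = frame$X1, upper = frame$X2)
  d1 <- L - frame$X1
  d2 <- frame$X2 - L
  s1 <- params$eps1 + d1 * params$sigma_hat
  s2 <- params$eps2 + d2 * params$sigma_hat
  list(
    proximal = list(mean = d1, sd = s1, variance = s1^2, anchor = "proximal"),
    distal   = list(mean = d2, sd = s2, variance = s2^2, anchor = "distal"))
}

#' Maximum-likelihood fusion of two Gaussian location estimates
#'
#' Combines two Gaussian beliefs about touch location by inverse-variance
#' weighting (the product of the two likelihoods under a flat prior):
#' `mu = (mu1/v1 + mu2/v2) * v`, `v = v1 v2 / (v1 + v2)`.  The fused
#' variance never exceeds the smaller input variance.  A zero-variance
#' input dominates and is returned unchanged.
#'
#' @param e1,e2 lists with elements `mean` and `variance` (variance
#'   `>= 0`).
#' @return a list with `mean` and `variance` of the integrated estimate.
#' @examples
#' integrate_estimates(list(mean = 30, variance = 4),
#'                     list(mean = 60, variance = 4)) # mean 45, variance 2
#' @export
integrate_estimates <- function(e1, e2) {
  v1 <- e1$variance; v2 <- e2$variance
  stop_if_not_number(v1, "e1$variance", lower = 0)
  stop_if_not_number(v2, "e2$variance", lower = 0)
  if (v1 == 0 && v2 == 0) {
    if (e1$mean != e2$mean)
      stop("inconsistent evidence: both variances are zero with different means")
    return(list(mean = e1$mean, variance = 0))
  }
  if (v1 == 0) return(list(mean = e1$mean, variance = 0))
  if (v2 == 0) return(list(mean = e2$mean, variance = 0))
  v <- v1 * v2 / (v1 + v2)
  list(mean = (e1$mean / v1 + e2$mean / v2) * v, variance = v)
}

#' Predicted variable-error curve of the trilateration observer
#'
#' The standard deviation of the integrated location estimate as a
#' function of touch location: `sigma_int(L) = sqrt(v1 v2 / (v1 + v2))`
#' with `sd_i = eps_i + d_i * sigma_hat`.  For positive parameters the
#' curve is an inverted U with a single interior maximum; unequal
#' intercepts skew the peak toward the noisier landmark.
#'
#' @param locations touch locations (percent of tool space) within the
#'   frame.
#' @inheritParams distance_estimates
#' @return numeric vector of predicted SDs (percent of tool space).
#' @examples
#' p <- trilateration_params(0.05, 1, 1)
#' predicted_sd_curve(c(0, 50, 100), p) # 0.986, 2.475, 0.986
#' @export
predicted_sd_curve <- function(locations, params, frame = surface_frame()) {
  stopifnot(inherits(params, "trilateration_params"),
            inherits(frame, "surface_frame"))
  stop_if_not_numeric(locations, "locations",
                      lower = frame$X1, upper = frame$X2)
  s1 <- params$eps1 + (locations - frame$X1) * params$sigma_hat
  s2 <- params$eps2 + (frame$X2 - locations) * params$sigma_hat
  v1 <- s1^2; v2 <- s2^2
  out <- sqrt(v1 * v2 / (v1 + v2))
  out[v1 + v2 == 0] <- 0
  out
}

#' Multisegment surface
#'
#' A rod divided into segments by interior breakpoints; trilateration then
#' operates locally within each segment, using the segment's endpoints as
#' landmarks.
#'
#' @param breakpoints strictly increasing numeric vector of segment
#'   boundaries in percent of tool space, including 0 and 100.
#' @param params a single [trilateration_params()] object (recycled to all
#'   segments) or a list with one per segment.
#' @return an object of class `segmented_surface`.
#' @export
segmented_surface <- function(breakpoints, params) {
  stop_if_not_numeric(breakpoints, "breakpoints", lower = 0, upper = 100)
  if (length(breakpoints) < 2 || any(diff(breakpoints) <= 0) ||
      breakpoints[1] != 0 || breakpoints[length(breakpoints)] != 100)
    stop("'breakpoints' must be strictly increasing, starting at 0 and ending at 100")
  n_seg <- length(breakpoints) - 1L
  if (inherits(params, "trilateration_params"))
    params <- rep(list(params), n_seg)
  if (length(params) != n_seg ||
      !all(vapply(params, inherits, logical(1), "trilateration_params")))
    stop("'params' must supply one trilateration_params per segment")
  structure(list(breakpoints = breakpoints, params = params),
            class = "segmented_surface")
}

#' Variable-error curve on a multisegment surface
#'
#' Each location's predicted SD is computed by [predicted_sd_curve()]
#' within its containing segment, with the segment endpoints as landmarks.
#' A location equal to a breakpoint belongs to the segment to its left,
#' except 0 which belongs to the first segment.  The resulting curve shows
#' one inverted-U lobe per segment, with minima at all breakpoints.
#'
#' @param surface a [segmented_surface()] object.
#' @param locations touch locations in `[0, 100]`.
#' @return numeric vector of predicted SDs.
#' @export
multisegment_sd_curve <- function(surface, locations) {
  stopifnot(inherits(surface, "segmented_surface"))
  stop_if_not_numeric(locations, "locations", lower = 0, upper = 100)
  bp <- surface$breakpoints
  # breakpoint ties go to the left segment; 0 to the first
  seg <- findInterval(locations, bp, left.open = TRUE)
  seg[locations == 0] <- 1L
  out <- numeric(length(locations))
  for (s in unique(seg)) {
    frame <- surface_frame(bp[s], bp[s + 1])
    idx <- seg == s
    out[idx] <- predicted_sd_curve(locations[idx], surface$params[[s]], frame)
  }
  out
}
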