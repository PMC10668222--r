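## Three-layer probabilistic population-coding network.
##
## Layer 1 (mode layer): five subpopulations of Poisson units with Gaussian
## tuning over the amplitude of one resonant mode each; together they
## encode the vibratory motif of the contact location.
## Layer 2 (feature layer): units with Gaussian tuning over the
## vibration-location feature space.  The synaptic drive from the mode
## layer is template-matched (winner-take-all) and the winner's preferred
## location drives the layer's own Poisson spiking.
## Layer 3 (distance layer): two decoding subpopulations, each anchored at
## one boundary of the feature space, with distance-dependent gradients in
## gain (decreasing) and tuning width (increasing).  Their non-negative
## input weights are solved so each unit realizes its prescribed tuning
## curve.  Because spiking is Poisson, summed log-tuning kernels decode a
## maximum-likelihood location from each subpopulation, and summing both
## subpopulations' log-likelihoods implements optimal fusion.

#' Distance-gradient parameters of the decoding layer
#'
#' @param kappa0 gain of the unit centered on the landmark (spikes per
#'   window).
#' @param beta gain decay per percent of distance.
#' @param sigma0 tuning width at the landmark (percent of space).
#' @param gamma logarithmic width scaling.
#' @return an object of class `gradient_params`.
#' @export
gradient_params <- function(kappa0 = 25, beta = 0.01, sigma0 = 3.40,
                            gamma = 0.5) {
  for (nm in c("kappa0", "beta", "sigma0", "gamma"))
    stop_if_not_number(get(nm), nm, lower = 1e-12)
  structure(list(kappa0 = kappa0, beta = beta, sigma0 = sigma0,
                 gamma = gamma), class = "gradient_params")
}

#' Gain gradient of a distance-tuned unit
#'
#' `kappa(d) = kappa0 / (1 + beta d)^2`: peak firing rate decays with the
#' distance `d` between a unit's tuning center and its anchor landmark, so
#' that units far from the landmark carry less spike-count information.
#'
#' @param d distance from the anchor (percent of space, `>= 0`);
#'   vectorized.
#' @param g a [gradient_params()] object.
#' @return gain(s) in spikes per window.
#' @export
gain_gradient <- function(d, g = gradient_params()) {
  stopifnot(inherits(g, "gradient_params"))
  stop_if_not_numeric(d, "d", lower = 0)
  g$kappa0 / (1 + g$beta * d)^2
}

#' Width gradient of a distance-tuned unit
#'
#' `sigma(d) = (gamma log(d + 1) + 1) sigma0`: tuning width grows with
#' log distance from the anchor, i.e. uniform tuning in log space
#' (Weber--Fechner scaling).
#'
#' @inheritParams gain_gradient
#' @return tuning width(s) in percent of space.
#' @export
width_gradient <- function(d, g = gradient_params()) {
  stopifnot(inherits(g, "gradient_params"))
  stop_if_not_numeric(d, "d", lower = 0)
  (g$gamma * log(d + 1) + 1) * g$sigma0
}

#' Network configuration
#'
#' Default tuning grids and parameters of the three layers.  Mode-layer
#' centers span the amplitude support `[-1.5, 1.5]` in steps of 0.02 (151
#' units per mode); feature-layer centers span -40..140 percent in steps
#' of 1; the two distance subpopulations span 0..140 (anchor 0, the hand)
#' and -40..100 (anchor 100, the tip).  The feature and distance grids
#' extend beyond `[0, 100]` so decoding is not truncated at the surface
#' boundaries; decoded values outside `[0, 100]` are retained.
#'
#' @param n_modes number of resonant modes encoded (5).
#' @param mode_centers,mode_sigma tuning centers and width of the mode
#'   layer (amplitude units).
#' @param kappa peak firing rate of mode- and feature-layer units.
#' @param feature_centers,feature_sigma tuning centers and width of the
#'   feature layer (percent of space).
#' @param dist1_centers,dist2_centers tuning centers of the two distance
#'   subpopulations (percent of space).
#' @param anchors landmark locations of the two subpopulations.
#' @param gradients a [gradient_params()] object for the distance layer.
#' @param input_jitter_sd SD of the Gaussian sensory noise applied to the
#'   contact location before motif lookup (percent of space).
#' @param amplitude_scale motif amplitude scaling
#'   (see [motif_for_location()]).
#' @param template_grid locations at which winner-take-all templates and
#'   decoder-weight fits are evaluated (percent of space).
#' @param decode_grid candidate locations for maximum-likelihood decoding.
#' @return a list of class `network_config`.
#' @export
network_config <- function(n_modes = 5L,
                           mode_centers = seq(-1.5, 1.5, by = 0.02),
                           mode_sigma = 0.08,
                           kappa = 25,
                           feature_centers = seq(-40, 140, by = 1),
                           feature_sigma = 3.40,
                           dist1_centers = seq(0, 140, by = 1),
                           dist2_centers = seq(-40, 100, by = 1),
                           anchors = c(0, 100),
                           gradients = gradient_params(),
                           input_jitter_sd = 0.5,
                           amplitude_scale = 1,
                           template_grid = seq(0, 100, by = 1),
                           decode_grid = seq(-40, 140, by = 1)) {
  cfg <- list(n_modes = stop_if_not_count(n_modes, "n_modes"),
              mode_centers = mode_centers, mode_sigma = mode_sigma,
              kappa = kappa, feature_centers = feature_centers,
              feature_sigma = feature_sigma,
              dist1_centers = dist1_centers, dist2_centers = dist2_centers,
              anchors = anchors, gradients = gradients,
              input_jitter_sd = input_jitter_sd,
              amplitude_scale = amplitude_scale,
              template_grid = template_grid, decode_grid = decode_grid)
  for (nm in c("mode_centers", "feature_centers", "dist1_centers",
               "dist2_centers", "template_grid", "decode_grid")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) < 2L || any(diff(v) <= 0))
      stop(sprintf("'%s' must be a strictly increasing numeric grid", nm))
  }
  stopifnot(inherits(gradients, "gradient_params"))
  class(cfg) <- "network_config"
  cfg
}

# Gaussian tuning: mean rate of units with centers `centers` for stimulus
# value(s) `stim`; returns length(stim) x length(centers) matrix
gauss_tuning <- function(stim, centers, kappa, sigma) {
  kappa * exp(-outer(stim, centers, "-")^2 / (2 * sigma^2))
}

#' Build the network's layer specifications
#'
#' @param config a [network_config()] object.
#' @return a list of four layer specs (`mode`, `feature`, `distance1`,
#'   `distance2`), each with `role`, `centers`, per-unit `kappa` and
#'   `sigma`, and (distance layers) `anchor`.
#' @export
build_layers <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  g <- config$gradients
  d1 <- abs(config$dist1_centers - config$anchors[1])
  d2 <- abs(config$dist2_centers - config$anchors[2])
  list(
    mode = list(role = "mode", n_modes = config$n_modes,
                centers = config$mode_centers,
                kappa = rep(config$kappa, length(config$mode_centers)),
                sigma = rep(config$mode_sigma, length(config$mode_centers))),
    feature = list(role = "feature", centers = config$feature_centers,
                   kappa = rep(config$kappa, length(config$feature_centers)),
                   sigma = rep(config$feature_sigma,
                               length(config$feature_centers))),
    distance1 = list(role = "distance1", centers = config$dist1_centers,
                     anchor = config$anchors[1],
                     kappa = gain_gradient(d1, g),
                     sigma = width_gradient(d1, g)),
    distance2 = list(role = "distance2", centers = config$dist2_centers,
                     anchor = config$anchors[2],
                     kappa = gain_gradient(d2, g),
                     sigma = width_gradient(d2, g)))
}

#' Independent Poisson spike counts
#'
#' Draws one spike count per unit from independent Poisson distributions
#' (Fano factor 1) with the given mean rates.
#'
#' @param means non-negative mean rates.
#' @return integer vector of spike counts.
#' @export
poisson_population_response <- function(means) {
  stop_if_not_numeric(means, "means", lower = 0)
  stats::rpois(length(means), means)
}

# mean mode-layer rates for a matrix of motifs (n trials x n_modes);
# returns n x (n_modes * n_units) matrix, subpopulations concatenated
mode_layer_means <- function(motifs, layers) {
  ml <- layers$mode
  nu <- length(ml$centers)
  out <- matrix(0, nrow(motifs), ml$n_modes * nu)
  for (m in seq_len(ml$n_modes))
    out[, (m - 1L) * nu + seq_len(nu)] <-
      gauss_tuning(motifs[, m], ml$centers, ml$kappa[1], ml$sigma[1])
  out
}

#' Mode-layer response to a vibratory motif
#'
#' Each of the five subpopulations responds to the amplitude of its mode
#' with Gaussian tuning, and spike counts are drawn from independent
#' Poisson distributions around those means.
#'
#' @param motif numeric vector of mode amplitudes
#'   (see [motif_for_location()]).
#' @param layers output of [build_layers()].
#' @return integer vector of spike counts (subpopulations concatenated in
#'   mode order).
#' @export
mode_layer_response <- function(motif, layers) {
  stop_if_not_numeric(motif, "motif")
  if (length(motif) != layers$mode$n_modes)
    stop("motif length does not match the number of mode subpopulations")
  sup <- max(abs(layers$mode$centers))
  if (any(abs(motif) > sup))
    stop("motif amplitudes fall outside the mode-layer tuning support")
  poisson_population_response(
    drop(mode_layer_means(matrix(motif, nrow = 1), layers)))
}

# winner-take-all templates: mean mode-layer response per template-grid
# location, rows normalized to unit L2 norm
build_templates <- function(config, layers) {
  motifs <- t(vapply(config$template_grid, motif_for_location, numeric(5),
                     scale = config$amplitude_scale))
  tmpl <- mode_layer_means(motifs, layers)
  tmpl / sqrt(rowSums(tmpl^2))
}

#' Feature-layer response
#'
#' The synaptic drive `WS . rM` is computed for every stored location
#' template; the winner (largest drive, ties to the smaller location)
#' selects the effective stimulus, and all feature units then spike with
#' independent Poisson noise around their tuning-curve means at the
#' winner's preferred location.
#'
#' @param r_mode mode-layer spike counts.
#' @param network a [build_network()] object.
#' @return a list with `counts`, `winner_location` and `degenerate`
#'   (`TRUE` when the drive is flat, e.g. an all-zero input, and the tie
#'   rule selected the smallest location).
#' @export
feature_layer_response <- function(r_mode, network) {
  stopifnot(inherits(network, "trilateration_network"))
  if (length(r_mode) != ncol(network$templates))
    stop("mode response length does not match the stored templates")
  drive <- drop(network$templates %*% r_mode)
  j <- which.max(drive)
  degenerate <- all(drive == drive[1])
  if (degenerate) j <- 1L
  winner <- network$config$template_grid[j]
  fl <- network$layers$feature
  means <- drop(gauss_tuning(winner, fl$centers, fl$kappa[1], fl$sigma[1]))
  list(counts = poisson_population_response(means),
       winner_location = winner, degenerate = degenerate)
}

#' Solve non-negative decoder weights for a distance subpopulation
#'
#' Each distance-layer unit must realize a prescribed Gaussian tuning
#' curve over location (gain and width set by the distance gradients).
#' Given the mean feature-layer response profile at each template-grid
#' location, the weight vector of each unit is found by non-negative least
#' squares so that `w . rS` reproduces the target curve.
#'
#' @param feature_layer,distance_layer layer specs from [build_layers()].
#' @param fit_grid locations (percent of space) over which the fit is
#'   evaluated.
#' @return a list with `weights` (units x feature units), `residual_rms`
#'   per unit, and `relative_rms` (RMS residual / unit gain).
#' @export
solve_decoder_weights <- function(feature_layer, distance_layer,
                                  fit_grid = seq(0, 100, by = 1)) {
  A <- gauss_tuning(fit_grid, feature_layer$centers, feature_layer$kappa[1],
                    feature_layer$sigma[1])
  AtA <- crossprod(A)
  n_unit <- length(distance_layer$centers)
  W <- matrix(0, n_unit, ncol(A))
  rms <- numeric(n_unit)
  for (j in seq_len(n_unit)) {
    target <- drop(gauss_tuning(fit_grid, distance_layer$centers[j],
                                distance_layer$kappa[j],
                                distance_layer$sigma[j]))
    sol <- nnls_normal(AtA, drop(crossprod(A, target)))
    W[j, ] <- sol$x
    rms[j] <- sqrt(mean((drop(A %*% sol$x) - target)^2))
  }
  rel <- rms / distance_layer$kappa
  if (max(rel) > 0.05)
    warning(sprintf(
      "decoder-weight fit exceeded 5%% relative RMS (worst %.2f%%)",
      100 * max(rel)))
  list(weights = W, residual_rms = rms, relative_rms = rel)
}

# log tuning curves on the decode grid, floored to stay finite
decoder_kernel <- function(layer, grid) {
  f <- layer$kappa * exp(-outer(layer$centers, grid, "-")^2 /
                           (2 * layer$sigma^2))
  list(grid = grid, K = log(pmax(f, 1e-12)))
}

#' Assemble the full network
#'
#' Builds the layer specs, the winner-take-all templates, the non-negative
#' decoder weights of both distance subpopulations and their
#' log-likelihood decoding kernels.  Building is deterministic; reuse the
#' returned object across simulations (the weight solve is the expensive
#' step).
#'
#' @param config a [network_config()] object.
#' @return an object of class `trilateration_network`.
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  layers <- build_layers(config)
  w1 <- solve_decoder_weights(layers$feature, layers$distance1,
                              config$template_grid)
  w2 <- solve_decoder_weights(layers$feature, layers$distance2,
                              config$template_grid)
  structure(list(
    config = config, layers = layers,
    templates = build_templates(config, layers),
    W1 = w1$weights, W2 = w2$weights,
    weight_rel_rms = c(distance1 = max(w1$relative_rms),
                       distance2 = max(w2$relative_rms)),
    kernel1 = decoder_kernel(layers$distance1, config$decode_grid),
    kernel2 = decoder_kernel(layers$distance2, config$decode_grid)),
    class = "trilateration_network")
}

#' @export
print.trilateration_network <- function(x, ...) {
  cat(sprintf(paste0(
    "Three-layer trilateration network\n",
    "  mode layer:     %d subpopulations x %d units\n",
    "  feature layer:  %d units\n",
    "  distance layer: %d + %d units (anchors %g, %g)\n",
    "  decoder-weight worst relative RMS: %.2g, %.2g\n"),
    x$layers$mode$n_modes, length(x$layers$mode$centers),
    length(x$layers$feature$centers),
    length(x$layers$distance1$centers), length(x$layers$distance2$centers),
    x$layers$distance1$anchor, x$layers$distance2$anchor,
    x$weight_rel_rms[1], x$weight_rel_rms[2]))
  invisible(x)
}

#' Maximum-likelihood decoding of a population response
#'
#' With independent Poisson spiking, the log-likelihood of location `L`
#' given counts `r` is `h(L) . r` up to terms independent of the counts,
#' where `h` is the log of the tuning curves.  The decoded location is the
#' grid argmax; ties break toward the smaller location.
#'
#' @param counts spike-count vector of one distance subpopulation.
#' @param kernel a decoder kernel as stored in a
#'   [build_network()] object (`kernel1`/`kernel2`).
#' @return a list with `location` and `degenerate` (`TRUE` for an all-zero
#'   response, which carries no information; the grid midpoint is
#'   returned).
#' @export
decode_ml <- function(counts, kernel) {
  stop_if_not_numeric(counts, "counts", lower = 0)
  if (length(counts) != nrow(kernel$K))
    stop("counts length does not match the decoder kernel")
  if (all(counts == 0))
    return(list(location = kernel$grid[(length(kernel$grid) + 1L) %/% 2L],
                degenerate = TRUE))
  ll <- drop(counts %*% kernel$K)
  list(location = kernel$grid[which.max(ll)], degenerate = FALSE)
}

#' Integrated maximum-likelihood decoding
#'
#' Sums the log-likelihood profiles of the two distance subpopulations and
#' takes the grid argmax; with Poisson population codes this implements
#' optimal (inverse-variance weighted) fusion of the two location
#' estimates.
#'
#' @param counts1,counts2 spike counts of the two subpopulations.
#' @param kernel1,kernel2 their decoder kernels (shared grid).
#' @return decoded location (percent of tool space).
#' @export
decode_integrated <- function(counts1, counts2, kernel1, kernel2) {
  if (!identical(kernel1$grid, kernel2$grid))
    stop("decoder kernels must share one location grid")
  if (length(counts1) != nrow(kernel1$K) ||
      length(counts2) != nrow(kernel2$K))
    stop("counts length does not match the decoder kernels")
  if (all(counts1 == 0))
    return(decode_ml(counts2, kernel2)$location)
  if (all(counts2 == 0))
    return(decode_ml(counts1, kernel1)$location)
  ll <- drop(counts1 %*% kernel1$K) + drop(counts2 %*% kernel2$K)
  kernel1$grid[which.max(ll)]
}

# vectorized single-location batch: n trials through all layers;
# returns matrix with columns L1, L2, Lint
run_batch <- function(L, n, network) {
  cfg <- network$config
  Lj <- L + stats::rnorm(n, 0, cfg$input_jitter_sd)
  Lj <- pmin(pmax(Lj, 0), 100)
  motifs <- t(vapply(Lj, motif_for_location, numeric(5),
                     scale = cfg$amplitude_scale))
  muM <- mode_layer_means(motifs, network$layers)
  rM <- matrix(stats::rpois(length(muM), muM), n)
  drive <- rM %*% t(network$templates)
  winner <- cfg$template_grid[max.col(drive, ties.method = "first")]
  fl <- network$layers$feature
  muS <- gauss_tuning(winner, fl$centers, fl$kappa[1], fl$sigma[1])
  rS <- matrix(stats::rpois(length(muS), muS), n)
  mu1 <- pmax(rS %*% t(network$W1), 0)
  mu2 <- pmax(rS %*% t(network$W2), 0)
  r1 <- matrix(stats::rpois(length(mu1), mu1), n)
  r2 <- matrix(stats::rpois(length(mu2), mu2), n)
  ll1 <- r1 %*% network$kernel1$K
  ll2 <- r2 %*% network$kernel2$K
  grid <- cfg$decode_grid
  cbind(L1 = grid[max.col(ll1, ties.method = "first")],
        L2 = grid[max.col(ll2, ties.method = "first")],
        Lint = grid[max.col(ll1 + ll2, ties.method = "first")])
}

#' Simulate localization through the network
#'
#' Repeatedly presents touches at each location: the location is jittered
#' by Gaussian sensory noise, converted to its vibratory motif, propagated
#' through the mode, feature and distance layers (each with Poisson
#' spiking), and decoded three ways (each subpopulation alone and
#' integrated).
#'
#' @param n_runs simulated touches per location (default 5000).
#' @param locations touch locations in percent of tool space (default
#'   10..90 in steps of 10).
#' @param network a prebuilt [build_network()] object, or `NULL` to build
#'   one from `config`.
#' @param config a [network_config()] object (used when `network` is
#'   `NULL`).
#' @param seed integer seed; required unless `allow_unseeded = TRUE`.
#' @param allow_unseeded set `TRUE` to run on the caller's RNG stream.
#' @return an object of class `network_simulation`: list with `decodes`
#'   (data frame: location, run, L1, L2, Lint) and `summary` (data frame:
#'   location, decoder, mean, bias, sd, n).
#' @export
run_simulation <- function(n_runs = 5000, locations = seq(10, 90, by = 10),
                           network = NULL, config = network_config(),
                           seed = NULL, allow_unseeded = FALSE) {
  n_runs <- stop_if_not_count(n_runs, "n_runs")
  stop_if_not_numeric(locations, "locations", lower = 0, upper = 100)
  if (is.null(seed) && !allow_unseeded)
    stop("provide a 'seed' (or set allow_unseeded = TRUE)")
  if (is.null(network)) network <- build_network(config)
  stopifnot(inherits(network, "trilateration_network"))
  decodes <- with_seed(seed, {
    do.call(rbind, lapply(locations, function(L) {
      est <- run_batch(L, n_runs, network)
      data.frame(location = L, run = seq_len(n_runs), est)
    }))
  })
  long <- do.call(rbind, lapply(c("L1", "L2", "Lint"), function(dec) {
    agg <- stats::aggregate(decodes[[dec]], list(location = decodes$location),
                            function(v) c(mean = mean(v), sd = stats::sd(v)))
    data.frame(location = agg$location, decoder = dec,
               mean = agg$x[, "mean"], bias = agg$x[, "mean"] - agg$location,
               sd = agg$x[, "sd"], n = n_runs)
  }))
  structure(list(decodes = decodes, summary = long, seed = seed,
                 network = network),
            class = "network_simulation")
}

#' @export
print.network_simulation <- function(x, ...) {
  cat(sprintf("Network simulation: %d locations x %d runs\n",
              length(unique(x$decodes$location)), x$summary$n[1]))
  s <- x$summary[x$summary$decoder == "Lint", ]
  cat("Integrated estimate (bias, sd) per location:\n")
  print(data.frame(location = s$location, bias = round(s$bias, 3),
                   sd = round(s$sd, 3)), row.names = FALSE)
  invisible(x)
}
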