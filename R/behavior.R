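## Synthetic behavioral data generator.
##
## Emulates the tool-localization study design: participants hold a 60-cm
## rod (12-cm handle) and localize touches at 10..60 cm from the hand in
## two report modalities -- on a downsized 20-cm drawing of the rod
## (responses in pixels) and in external screen space (responses in cm,
## scaled by the participant's own judged tip position).  Judgment noise
## lives in percent of tool space and follows either the trilateration
## variance law or a truncated-normal (boundary truncation) law, so that
## generated cohorts exercise the full fitting and model-selection
## pipeline.

#' Study design
#'
#' @param n_participants cohort size (default 38).
#' @param rod_length_cm,handle_length_cm rod geometry.
#' @param locations_cm touch locations in cm from the hand.
#' @param trials_per_location_per_task trials per cell (default 10, i.e.
#'   60 trials per task and 120 per participant).
#' @param drawing_length_cm length of the downsized rod drawing.
#' @param screen_length_cm width of the response screen.
#' @param pixels_per_cm display scale used for the drawing task.
#' @return a list of class `study_design`.
#' @export
study_design <- function(n_participants = 38, rod_length_cm = 60,
                         handle_length_cm = 12,
                         locations_cm = seq(10, 60, by = 10),
                         trials_per_location_per_task = 10,
                         drawing_length_cm = 20, screen_length_cm = 70,
                         pixels_per_cm = 1920 / 70) {
  d <- list(n_participants = stop_if_not_count(n_participants,
                                               "n_participants"),
            rod_length_cm = rod_length_cm,
            handle_length_cm = handle_length_cm,
            locations_cm = locations_cm,
            trials_per_location_per_task =
              stop_if_not_count(trials_per_location_per_task,
                                "trials_per_location_per_task"),
            drawing_length_cm = drawing_length_cm,
            screen_length_cm = screen_length_cm,
            pixels_per_cm = pixels_per_cm,
            tasks = c("image", "space"))
  stop_if_not_numeric(d$locations_cm, "locations_cm", lower = 1e-9,
                      upper = d$rod_length_cm)
  class(d) <- "study_design"
  d
}

#' Prior ranges for synthetic participants
#'
#' Uniform ranges for the generative trilateration parameters, the
#' truncation-law parameters, and the judged-tip distribution.  The
#' trilateration ranges put variable errors in the 1--6 percent-of-space
#' band typical of tool localization; the judged tip is drawn from a
#' normal distribution matching the reported group mean and
#' between-participant spread, truncated above the handle.
#'
#' @param sigma_hat,eps trilateration slope and intercept ranges.
#' @param sigma_t,gamma1,gamma2 truncation-law ranges (base SD and the two
#'   truncation bounds, percent of space).
#' @param judged_tip_mean_cm,judged_tip_sd_cm judged-tip distribution
#'   (cm); the default SD is the reported SEM scaled to one participant
#'   (`1.62 * sqrt(38)`).
#' @return a list of class `participant_priors`.
#' @export
participant_priors <- function(sigma_hat = c(0.02, 0.10),
                               eps = c(0.5, 5),
                               sigma_t = c(5, 15),
                               gamma1 = c(-10, 10),
                               gamma2 = c(90, 110),
                               judged_tip_mean_cm = 56.5,
                               judged_tip_sd_cm = 1.62 * sqrt(38)) {
  pr <- list(sigma_hat = sigma_hat, eps = eps, sigma_t = sigma_t,
             gamma1 = gamma1, gamma2 = gamma2,
             judged_tip_mean_cm = judged_tip_mean_cm,
             judged_tip_sd_cm = judged_tip_sd_cm)
  for (nm in c("sigma_hat", "eps", "sigma_t", "gamma1", "gamma2")) {
    v <- pr[[nm]]
    if (!is.numeric(v) || length(v) != 2L || v[2] < v[1])
      stop(sprintf("'%s' must be a range c(lo, hi) with hi >= lo", nm))
  }
  class(pr) <- "participant_priors"
  pr
}

runif_range <- function(n, r) stats::runif(n, r[1], r[2])

#' Sample a cohort of synthetic participants
#'
#' Draws each participant's generative parameters from
#' [participant_priors()].  Under `model = "trilateration"` judgments are
#' generated with the distance-dependent noise law; under
#' `model = "truncation"` with a location-independent SD truncated at the
#' sampled bounds.  An optional response miscalibration (slope/intercept
#' in percent of space) exercises the accuracy regression.
#'
#' @param design a [study_design()] object.
#' @param priors a [participant_priors()] object.
#' @param model generative law, `"trilateration"` or `"truncation"`.
#' @param response_slope,response_intercept constant-error miscalibration
#'   applied to the mean judgment (defaults 1 and 0: unbiased).
#' @param seed integer seed for reproducible rosters (optional; with
#'   `NULL` the caller's RNG stream is used).
#' @return data frame with one row per participant: `participant`,
#'   `model`, `sigma_hat`, `eps1`, `eps2`, `sigma_t`, `gamma1`, `gamma2`,
#'   `judged_tip_cm`, `pixels_per_cm`, `response_slope`,
#'   `response_intercept`.
#' @export
sample_participants <- function(design = study_design(),
                                priors = participant_priors(),
                                model = c("trilateration", "truncation"),
                                response_slope = 1,
                                response_intercept = 0,
                                seed = NULL) {
  stopifnot(inherits(design, "study_design"),
            inherits(priors, "participant_priors"))
  model <- match.arg(model)
  n <- design$n_participants
  with_seed(seed, {
    tip <- stats::rnorm(n, priors$judged_tip_mean_cm, priors$judged_tip_sd_cm)
    # resample the (vanishingly rare) draws at or below the handle
    while (any(bad <- tip <= design$handle_length_cm))
      tip[bad] <- stats::rnorm(sum(bad), priors$judged_tip_mean_cm,
                               priors$judged_tip_sd_cm)
    data.frame(
      participant = seq_len(n),
      model = model,
      sigma_hat = runif_range(n, priors$sigma_hat),
      eps1 = runif_range(n, priors$eps),
      eps2 = runif_range(n, priors$eps),
      sigma_t = runif_range(n, priors$sigma_t),
      gamma1 = runif_range(n, priors$gamma1),
      gamma2 = runif_range(n, priors$gamma2),
      judged_tip_cm = tip,
      pixels_per_cm = design$pixels_per_cm,
      response_slope = response_slope,
      response_intercept = response_intercept)
  })
}

# draw judgments (percent of space): means mu (possibly miscalibrated),
# noise set by the true location L_pct under the participant's law
draw_judgments <- function(mu, L_pct, p) {
  n <- length(mu)
  if (p$model == "trilateration") {
    sd_int <- predicted_sd_curve(
      L_pct, trilateration_params(p$sigma_hat, p$eps1, p$eps2))
    stats::rnorm(n, mu, sd_int)
  } else {
    # truncated normal via inverse-CDF sampling
    lo <- stats::pnorm(p$gamma1, mu, p$sigma_t)
    hi <- stats::pnorm(p$gamma2, mu, p$sigma_t)
    stats::qnorm(stats::runif(n, lo, hi), mu, p$sigma_t)
  }
}

#' Generate raw trials for one participant or a cohort
#'
#' For every task x location x trial, the true location is converted to
#' percent of tool space, a judgment is drawn in percent of space from the
#' participant's generative law (after applying the miscalibration
#' `slope * L + intercept` to its mean), and the judgment is mapped to raw
#' task units: pixels along the 20-cm drawing for the image task, cm along
#' the screen (scaled by the participant's judged tip) for the space task.
#'
#' @param participants one or more rows as returned by
#'   [sample_participants()].
#' @param design a [study_design()] object.
#' @param seed integer seed (optional).
#' @return data frame of trial records: `participant`, `task`,
#'   `location_cm`, `trial`, `raw_response`, `response_units`.
#' @export
generate_trials <- function(participants, design = study_design(),
                            seed = NULL) {
  stopifnot(inherits(design, "study_design"), is.data.frame(participants))
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(participants)), function(i) {
      p <- participants[i, ]
      cells <- expand.grid(
        trial = seq_len(design$trials_per_location_per_task),
        location_cm = design$locations_cm,
        task = design$tasks, stringsAsFactors = FALSE)
      L_pct <- cells$location_cm / design$rod_length_cm * 100
      mu <- p$response_intercept + p$response_slope * L_pct
      judged_pct <- draw_judgments(mu, L_pct, p)
      raw <- ifelse(
        cells$task == "image",
        judged_pct / 100 * design$drawing_length_cm * p$pixels_per_cm,
        judged_pct / 100 * p$judged_tip_cm)
      data.frame(participant = p$participant, task = cells$task,
                 location_cm = cells$location_cm, trial = cells$trial,
                 raw_response = raw,
                 response_units = ifelse(cells$task == "image", "px", "cm"))
    }))
  })
}
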