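## Behavioral analysis pipeline: normalization to percent of tool space,
## accuracy regression, variable-error summaries, trilateration and
## boundary-truncation model fits, and BIC model comparison.

#' Normalize image-task responses
#'
#' Converts pixel positions along the downsized rod drawing to percent of
#' tool space.  Off-drawing responses are clamped to `[0, 100]` (with a
#' warning and a `clamped` flag).
#'
#' @param raw_px pixel position(s) along the drawing, measured from its
#'   handle end.
#' @param drawing_length_cm length of the drawing (cm).
#' @param pixels_per_cm display scale.
#' @return data frame with `judgment_pct` and `clamped`.
#' @export
normalize_image_task <- function(raw_px, drawing_length_cm = 20,
                                 pixels_per_cm = 1920 / 70) {
  stop_if_not_numeric(raw_px, "raw_px")
  stop_if_not_number(pixels_per_cm, "pixels_per_cm", lower = 1e-9)
  stop_if_not_number(drawing_length_cm, "drawing_length_cm", lower = 1e-9)
  pct <- raw_px / (drawing_length_cm * pixels_per_cm) * 100
  clamped <- pct < 0 | pct > 100
  if (any(clamped))
    warning(sprintf("%d off-drawing response(s) clamped to [0, 100]",
                    sum(clamped)))
  data.frame(judgment_pct = pmin(pmax(pct, 0), 100), clamped = clamped)
}

#' Normalize space-task responses
#'
#' Scales on-screen responses (cm) so that the participant's judged tip
#' position corresponds to 100 percent of tool space.
#'
#' @param raw_cm response position(s) in cm along the screen.
#' @param judged_tip_cm the participant's judged tip position (cm, `> 0`).
#' @return judgment(s) in percent of tool space.
#' @export
normalize_space_task <- function(raw_cm, judged_tip_cm) {
  stop_if_not_numeric(raw_cm, "raw_cm")
  if (!is.numeric(judged_tip_cm) || any(judged_tip_cm <= 0))
    stop("'judged_tip_cm' must be positive")
  raw_cm / judged_tip_cm * 100
}

#' Normalize a trial table to percent of tool space
#'
#' Applies the task-appropriate normalization to every trial, joining the
#' per-participant display scale and judged tip from the roster.
#'
#' @param trials trial records (see [generate_trials()] /
#'   [read_trials()]).
#' @param participants roster with `participant`, `judged_tip_cm` and
#'   `pixels_per_cm` columns.
#' @param design a [study_design()] object.
#' @return data frame with `participant`, `task`, `location_pct`,
#'   `judgment_pct`.
#' @export
normalize_trials <- function(trials, participants,
                             design = study_design()) {
  stopifnot(is.data.frame(trials), is.data.frame(participants),
            inherits(design, "study_design"))
  idx <- match(trials$participant, participants$participant)
  if (any(is.na(idx)))
    stop("trials reference participants missing from the roster")
  img <- trials$task == "image"
  out <- numeric(nrow(trials))
  if (any(img))
    out[img] <- normalize_image_task(
      trials$raw_response[img], design$drawing_length_cm,
      participants$pixels_per_cm[idx][img][1])$judgment_pct
  if (any(!img))
    out[!img] <- normalize_space_task(
      trials$raw_response[!img],
      participants$judged_tip_cm[idx][!img])
  data.frame(participant = trials$participant, task = trials$task,
             location_pct = trials$location_cm / design$rod_length_cm * 100,
             judgment_pct = out)
}

#' Per-location localization summaries
#'
#' Collapses tasks within each participant x location cell: the mean
#' judgment is the plain mean over all trials, and the variable error is
#' the SD of the judgments after removing each task's own cell mean
#' (task-demeaned pooling, with one degree of freedom lost per task), so
#' a constant error difference between tasks does not inflate the SD.
#'
#' @param normalized output of [normalize_trials()].
#' @param demean_tasks pool after removing per-task means (default
#'   `TRUE`); with `FALSE` a plain pooled SD is computed.
#' @return data frame with `participant`, `location_pct`,
#'   `mean_judgment`, `variable_error`, `n`.  Cells with fewer than two
#'   usable trials are dropped with a warning.
#' @export
summarize_localization <- function(normalized, demean_tasks = TRUE) {
  stopifnot(is.data.frame(normalized))
  key <- interaction(normalized$participant, normalized$location_pct,
                     drop = TRUE)
  pieces <- lapply(split(normalized, key), function(cell) {
    n <- nrow(cell)
    n_tasks <- length(unique(cell$task))
    if (n - (if (demean_tasks) n_tasks else 1L) < 1L) return(NULL)
    if (demean_tasks) {
      res <- unlist(lapply(split(cell$judgment_pct, cell$task),
                           function(v) v - mean(v)), use.names = FALSE)
      ve <- sqrt(sum(res^2) / (n - n_tasks))
    } else {
      ve <- stats::sd(cell$judgment_pct)
    }
    data.frame(participant = cell$participant[1],
               location_pct = cell$location_pct[1],
               mean_judgment = mean(cell$judgment_pct),
               variable_error = ve, n = n)
  })
  dropped <- sum(vapply(pieces, is.null, logical(1)))
  if (dropped > 0)
    warning(sprintf("%d singleton cell(s) excluded", dropped))
  out <- do.call(rbind, pieces)
  out <- out[order(out$participant, out$location_pct), ]
  rownames(out) <- NULL
  out
}

#' Localization accuracy regression
#'
#' Ordinary least-squares regression of the mean judgment per location on
#' the true location, per participant (and per task when `by_task`), with
#' group-level t-based 95 percent confidence intervals on the slope and
#' intercept.  Accurate localization gives slopes near 1 and intercepts
#' near 0.
#'
#' @param normalized output of [normalize_trials()].
#' @param by_task fit separate regressions per task (default `TRUE`).
#' @return a list of class `accuracy_regression` with `coefficients`
#'   (per participant) and `group` (mean, lower and upper CI per
#'   coefficient and task).
#' @export
fit_accuracy_regression <- function(normalized, by_task = TRUE) {
  stopifnot(is.data.frame(normalized))
  grp <- if (by_task) list(participant = normalized$participant,
                           task = normalized$task)
         else list(participant = normalized$participant)
  cells <- split(normalized, grp, drop = TRUE)
  coefs <- do.call(rbind, lapply(cells, function(d) {
    means <- stats::aggregate(judgment_pct ~ location_pct, d, mean)
    if (nrow(means) < 2L)
      stop("need at least two distinct locations per participant")
    fit <- stats::lm(judgment_pct ~ location_pct, means)
    data.frame(participant = d$participant[1],
               task = if (by_task) d$task[1] else "both",
               intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]))
  }))
  rownames(coefs) <- NULL
  ci <- function(v) {
    m <- mean(v)
    half <- stats::qt(0.975, length(v) - 1) * stats::sd(v) / sqrt(length(v))
    c(mean = m, lower = m - half, upper = m + half)
  }
  group <- do.call(rbind, lapply(split(coefs, coefs$task), function(d)
    data.frame(task = d$task[1],
               coefficient = c("intercept", "slope"),
               rbind(ci(d$intercept), ci(d$slope)))))
  rownames(group) <- NULL
  structure(list(coefficients = coefs, group = group),
            class = "accuracy_regression")
}

#' @export
print.accuracy_regression <- function(x, ...) {
  cat("Localization accuracy (group means with 95% CI):\n")
  print(x$group, row.names = FALSE, digits = 3)
  invisible(x)
}

## ---- model fitting ----

# bounded multistart least squares on the SD profile
multistart_fit <- function(objective, starts, lower, upper) {
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(
      stats::optim(pmin(pmax(starts[i, ], lower), upper), objective,
                   method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L)
    stop("no optimizer start converged; inspect the SD profile")
  fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
}

new_model_fit <- function(model, par, locations, observed, predicted,
                          flags) {
  rss <- sum((observed - predicted)^2)
  tss <- sum((observed - mean(observed))^2)
  structure(list(model = model, par = par, locations = locations,
                 observed = observed, predicted = predicted,
                 rss = rss,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 flags = flags),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit: RSS = %.4g, R^2 = %.3f\n", x$model, x$rss,
              x$r_squared))
  cat("  parameters:",
      paste(sprintf("%s = %.4g", names(x$par), x$par), collapse = ", "),
      "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the trilateration observer to a variable-error profile
#'
#' Bounded nonlinear least squares of the predicted integrated SD
#' ([predicted_sd_curve()]) on the observed per-location variable errors,
#' over the three free parameters (`sigma_hat`, `eps1`, `eps2`, all
#' `>= 0`).  A deterministic grid of 27 starts guards against local
#' minima; the best-RSS solution wins.
#'
#' @param locations touch locations (percent of tool space), or a data
#'   frame from [summarize_localization()] (one participant).
#' @param variable_error observed SDs (ignored when `locations` is a
#'   summary data frame).
#' @return a `model_fit` object; near-flat profiles that drive
#'   `sigma_hat` to zero are flagged `"degenerate_slope"`.
#' @export
fit_trilateration <- function(locations, variable_error = NULL) {
  if (is.data.frame(locations)) {
    variable_error <- locations$variable_error
    locations <- locations$location_pct
  }
  stop_if_not_numeric(locations, "locations", lower = 0, upper = 100)
  stop_if_not_numeric(variable_error, "variable_error", lower = 0)
  if (length(locations) < 4L)
    stop("need at least 4 locations to fit 3 free parameters")
  obj <- function(p)
    sum((variable_error -
           predicted_sd_curve(locations,
                              trilateration_params(p[1], p[2], p[3])))^2)
  starts <- as.matrix(expand.grid(sigma_hat = c(0.02, 0.06, 0.12),
                                  eps1 = c(0.5, 2, 6),
                                  eps2 = c(0.5, 2, 6)))
  lower <- c(0, 0, 0); upper <- c(1, 50, 50)
  best <- multistart_fit(obj, starts, lower, upper)
  par <- stats::setNames(best$par, c("sigma_hat", "eps1", "eps2"))
  flags <- character(0)
  if (par["sigma_hat"] < 1e-4) flags <- c(flags, "degenerate_slope")
  if (any(abs(par - upper) < 1e-6)) flags <- c(flags, "at_bound")
  pred <- predicted_sd_curve(locations,
                             trilateration_params(par[1], par[2], par[3]))
  new_model_fit("trilateration", par, locations, variable_error, pred,
                flags)
}

#' Standard deviation of a boundary-truncated judgment
#'
#' Closed-form SD of a `Normal(L, sigma_t^2)` likelihood truncated to
#' `[gamma1, gamma2]`.
#'
#' @param L touch location(s), percent of tool space.
#' @param sigma_t base SD (percent of space).
#' @param gamma1,gamma2 truncation bounds, `gamma2 > gamma1`.
#' @return SD(s) of the truncated distribution.
#' @examples
#' truncated_sd(0, 10, 0, 100) # half-normal: 10 * sqrt(1 - 2/pi)
#' @export
truncated_sd <- function(L, sigma_t, gamma1, gamma2) {
  stop_if_not_numeric(L, "L")
  stop_if_not_number(sigma_t, "sigma_t", lower = 1e-12)
  stop_if_not_number(gamma1, "gamma1")
  stop_if_not_number(gamma2, "gamma2")
  if (gamma2 <= gamma1) stop("'gamma2' must exceed 'gamma1'")
  a <- (gamma1 - L) / sigma_t
  b <- (gamma2 - L) / sigma_t
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  v <- 1 + (a * da - b * db) / z - ((da - db) / z)^2
  sigma_t * sqrt(pmax(v, 0))
}

#' Fit the boundary-truncation model to a variable-error profile
#'
#' Bounded least squares of [truncated_sd()] on the observed variable
#' errors over `sigma_t` (1..40), `gamma1` (-30..30) and `gamma2`
#' (70..130), units percent of rod surface, with a deterministic
#' multistart grid.
#'
#' @inheritParams fit_trilateration
#' @return a `model_fit` object; solutions pinned at a bound are flagged
#'   `"at_bound"`.
#' @export
fit_truncation <- function(locations, variable_error = NULL) {
  if (is.data.frame(locations)) {
    variable_error <- locations$variable_error
    locations <- locations$location_pct
  }
  stop_if_not_numeric(locations, "locations", lower = 0, upper = 100)
  stop_if_not_numeric(variable_error, "variable_error", lower = 0)
  if (length(locations) < 4L)
    stop("need at least 4 locations to fit 3 free parameters")
  obj <- function(p)
    sum((variable_error - truncated_sd(locations, p[1], p[2], p[3]))^2)
  starts <- as.matrix(expand.grid(sigma_t = c(3, 8, 20),
                                  gamma1 = c(-20, 0, 20),
                                  gamma2 = c(80, 100, 120)))
  lower <- c(1, -30, 70); upper <- c(40, 30, 130)
  best <- multistart_fit(obj, starts, lower, upper)
  par <- stats::setNames(best$par, c("sigma_t", "gamma1", "gamma2"))
  flags <- if (any(abs(par - lower) < 1e-6 | abs(par - upper) < 1e-6))
    "at_bound" else character(0)
  pred <- truncated_sd(locations, par[1], par[2], par[3])
  new_model_fit("truncation", par, locations, variable_error, pred, flags)
}

#' BIC model comparison
#'
#' Gaussian-residual BIC, `n log(RSS / n) + k log(n)`, with `k = 3` free
#' parameters for both models; `delta_bic = BIC(truncation) -
#' BIC(trilateration)`, so positive values favor trilateration.  Evidence
#' classes follow the conventional cutoffs: weak below 2, moderate from 2,
#' strong from 6.
#'
#' @param fit_tri,fit_trunc `model_fit` objects for the two models, fitted
#'   to the same variable-error profile.
#' @param n_points number of variance points entering the likelihood
#'   (default: the number of fitted locations).
#' @return a list of class `bic_comparison` with `bic_trilateration`,
#'   `bic_truncation`, `delta_bic`, `evidence`
#'   (`"weak"`/`"moderate"`/`"strong"`), `winner` and `degenerate` (TRUE
#'   when an RSS of zero made a BIC `-Inf`).
#' @export
compare_bic <- function(fit_tri, fit_trunc, n_points = NULL) {
  stopifnot(inherits(fit_tri, "model_fit"), inherits(fit_trunc, "model_fit"))
  if (!identical(fit_tri$locations, fit_trunc$locations) ||
      !identical(fit_tri$observed, fit_trunc$observed))
    stop("both fits must be computed on identical data")
  if (is.null(n_points)) n_points <- length(fit_tri$locations)
  n_points <- stop_if_not_count(n_points, "n_points")
  k <- 3
  bic <- function(rss) n_points * log(rss / n_points) + k * log(n_points)
  b_tri <- bic(fit_tri$rss); b_trunc <- bic(fit_trunc$rss)
  delta <- b_trunc - b_tri
  evidence <- if (is.nan(delta) || abs(delta) < 2) "weak"
              else if (abs(delta) < 6) "moderate" else "strong"
  structure(list(
    bic_trilateration = b_tri, bic_truncation = b_trunc,
    delta_bic = delta, evidence = evidence,
    winner = if (is.nan(delta) || delta == 0) "tie"
             else if (delta > 0) "trilateration" else "truncation",
    degenerate = !is.finite(b_tri) || !is.finite(b_trunc)),
    class = "bic_comparison")
}

#' @export
print.bic_comparison <- function(x, ...) {
  cat(sprintf(
    "BIC: trilateration %.2f, truncation %.2f, delta %.2f (%s, favors %s)\n",
    x$bic_trilateration, x$bic_truncation, x$delta_bic, x$evidence,
    x$winner))
  invisible(x)
}

#' Fit and compare both models for every participant
#'
#' Runs the full per-participant pipeline on a trial table: normalization,
#' variable-error summary, trilateration and truncation fits, and BIC
#' comparison.
#'
#' @param trials trial records.
#' @param participants participant roster (for normalization).
#' @param design a [study_design()] object.
#' @param n_points BIC sample size per participant (default: number of
#'   locations).
#' @return data frame with one row per participant: fitted parameters,
#'   `r2_tri`, `r2_trunc`, `bic_tri`, `bic_trunc`, `delta_bic`,
#'   `evidence`, `winner`.
#' @export
fit_cohort <- function(trials, participants, design = study_design(),
                       n_points = NULL) {
  normalized <- normalize_trials(trials, participants, design)
  summaries <- summarize_localization(normalized)
  do.call(rbind, lapply(split(summaries, summaries$participant),
    function(s) {
      ft <- fit_trilateration(s)
      fb <- fit_truncation(s)
      cmp <- compare_bic(ft, fb, n_points)
      data.frame(participant = s$participant[1],
                 sigma_hat = ft$par["sigma_hat"], eps1 = ft$par["eps1"],
                 eps2 = ft$par["eps2"],
                 sigma_t = fb$par["sigma_t"], gamma1 = fb$par["gamma1"],
                 gamma2 = fb$par["gamma2"],
                 r2_tri = ft$r_squared, r2_trunc = fb$r_squared,
                 bic_tri = cmp$bic_trilateration,
                 bic_trunc = cmp$bic_truncation,
                 delta_bic = cmp$delta_bic, evidence = cmp$evidence,
                 winner = cmp$winner, row.names = NULL)
    }))
}

#' Tabulate evidence classes across a cohort
#'
#' @param cohort output of [fit_cohort()].
#' @return data frame counting participants per winner and evidence class.
#' @export
compare_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  tab <- as.data.frame(table(winner = cohort$winner,
                             evidence = cohort$evidence))
  tab <- tab[tab$Freq > 0, ]
  rownames(tab) <- NULL
  tab
}
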