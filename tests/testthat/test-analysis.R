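test_that("task normalizations are proportional and validated", {
  ppcm <- 1920 / 70
  # drawing midpoint and tip
  expect_equal(normalize_image_task(10 * ppcm, 20, ppcm)$judgment_pct, 50)
  expect_equal(normalize_image_task(20 * ppcm, 20, ppcm)$judgment_pct, 100)
  expect_warning(res <- normalize_image_task(21 * ppcm, 20, ppcm),
                 "clamped")
  expect_equal(res$judgment_pct, 100)
  expect_true(res$clamped)
  expect_equal(normalize_space_task(56.5, 56.5), 100)
  expect_equal(normalize_space_task(28.25, 56.5), 50)
  expect_equal(normalize_space_task(0, 56.5), 0)
  expect_error(normalize_space_task(10, -1), "positive")
})

test_that("localization summaries pool tasks with demeaning", {
  d <- data.frame(participant = 1, task = "space", location_pct = 50,
                  judgment_pct = c(48, 52))
  s <- summarize_localization(d)
  expect_equal(s$mean_judgment, 50)
  expect_equal(s$variable_error, sd(c(48, 52)))
  # a constant shift between tasks leaves the demeaned pooled SD unchanged
  base <- c(47, 49, 51, 53)
  d2 <- data.frame(participant = 1,
                   task = rep(c("image", "space"), each = 4),
                   location_pct = 50,
                   judgment_pct = c(base, base + 5))
  d3 <- d2
  d3$judgment_pct <- c(base, base)
  expect_equal(summarize_localization(d2)$variable_error,
               summarize_localization(d3)$variable_error)
  # identical judgments give zero variable error
  d4 <- data.frame(participant = 1, task = "image", location_pct = 10,
                   judgment_pct = rep(30, 5))
  expect_equal(summarize_localization(d4)$variable_error, 0)
  # singleton cells are dropped with a warning
  d5 <- rbind(d4, data.frame(participant = 1, task = "image",
                             location_pct = 99, judgment_pct = 1))
  expect_warning(s5 <- summarize_localization(d5), "singleton")
  expect_equal(nrow(s5), 1)
})

test_that("accuracy regression is exact on noiseless linear data", {
  L <- rep(seq(10, 60, 10) / 60 * 100, each = 2)
  d <- data.frame(participant = rep(1:3, each = 12),
                  task = "space", location_pct = L,
                  judgment_pct = 0.9 * L + 5)
  fit <- fit_accuracy_regression(d, by_task = FALSE)
  expect_equal(fit$coefficients$slope, rep(0.9, 3), tolerance = 1e-9)
  expect_equal(fit$coefficients$intercept, rep(5, 3), tolerance = 1e-9)
  d$judgment_pct <- L
  fit1 <- fit_accuracy_regression(d, by_task = FALSE)
  expect_equal(fit1$group$mean[fit1$group$coefficient == "slope"], 1,
               tolerance = 1e-9)
  expect_equal(fit1$group$mean[fit1$group$coefficient == "intercept"], 0,
               tolerance = 1e-9)
})

test_that("group regression CIs cover a known generative slope", {
  covered <- 0
  for (rep in 1:10) {
    p <- sample_participants(design = study_design(n_participants = 12),
                             response_slope = 0.93, seed = 100 + rep)
    tr <- generate_trials(p, design = study_design(n_participants = 12),
                          seed = 200 + rep)
    nt <- suppressWarnings(normalize_trials(tr, p))
    fit <- fit_accuracy_regression(nt, by_task = FALSE)
    g <- fit$group[fit$group$coefficient == "slope", ]
    covered <- covered + (g$lower <= 0.93 && g$upper >= 0.93)
  }
  expect_gte(covered, 9)
})

test_that("the trilateration fit recovers noise-free parameters and flags degeneracy", {
  L <- seq(10, 60, 10) / 60 * 100
  p <- trilateration_params(0.06, 1.2, 2.5)
  fit <- fit_trilateration(L, predicted_sd_curve(L, p))
  expect_lt(fit$rss, 1e-6)
  expect_equal(unname(fit$par), c(0.06, 1.2, 2.5), tolerance = 1e-2)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  # a flat profile collapses the slope to zero and is flagged
  flat <- fit_trilateration(L, rep(3, 6))
  expect_true("degenerate_slope" %in% flat$flags)
  expect_error(fit_trilateration(L[1:3], rep(1, 3)), "at least 4")
})

test_that("the truncated-normal SD matches closed forms and Monte Carlo", {
  # negligible truncation at 8 sigma
  expect_equal(truncated_sd(50, 10, -30, 130), 10, tolerance = 1e-4)
  # half-normal at the boundary
  expect_equal(truncated_sd(0, 10, 0, 100), 10 * sqrt(1 - 2 / pi),
               tolerance = 1e-6)
  # symmetric about the bounds' midpoint
  L <- seq(0, 100, 5)
  s <- truncated_sd(L, 12, 0, 100)
  expect_equal(s, rev(s))
  set.seed(1)
  expect_equal(truncated_sd(20, 8, 0, 100),
               oracle_truncated_sd(20, 8, 0, 100, n = 2e5),
               tolerance = 0.01)
  expect_error(truncated_sd(50, 10, 80, 20), "exceed")
})

test_that("the truncation fit self-recovers and trilateration data defeat it", {
  L <- seq(10, 60, 10) / 60 * 100
  gen <- truncated_sd(L, 9, 2, 98)
  fit <- fit_truncation(L, gen)
  expect_lt(fit$rss, 1e-8)
  tri_gen <- predicted_sd_curve(L, trilateration_params(0.06, 1, 2))
  ft <- fit_trilateration(L, tri_gen)
  fb <- fit_truncation(L, tri_gen)
  expect_gt(fb$rss, ft$rss)
})

test_that("BIC comparison applies the conventional evidence cutoffs", {
  L <- seq(10, 60, 10) / 60 * 100
  obs <- predicted_sd_curve(L, trilateration_params(0.05, 1, 2)) +
    c(0.1, -0.1, 0.1, -0.1, 0.1, -0.1)
  ft <- fit_trilateration(L, obs)
  fb <- fit_truncation(L, obs)
  cmp <- compare_bic(ft, fb)
  # delta = n log(rss ratio) with equal k
  expect_equal(cmp$delta_bic, 6 * log(fb$rss / ft$rss), tolerance = 1e-10)
  # the documented examples: equal RSS -> weak; ratio 2 at n=6 -> moderate
  mk <- function(rss) {
    f <- ft
    f$rss <- rss
    f
  }
  expect_equal(compare_bic(mk(1), mk(1))$evidence, "weak")
  expect_equal(compare_bic(mk(1), mk(2))$delta_bic, 6 * log(2))
  expect_equal(compare_bic(mk(1), mk(2))$evidence, "moderate")
  # rss ratio e gives delta = n, strong at n >= 6
  expect_equal(compare_bic(mk(1), mk(exp(1)))$delta_bic, 6)
  expect_equal(compare_bic(mk(1), mk(exp(1)))$evidence, "strong")
  expect_true(compare_bic(mk(0), mk(1))$degenerate)
})
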