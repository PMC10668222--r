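test_that("distance gradients follow the gain and width laws", {
  g <- gradient_params()
  expect_equal(gain_gradient(0, g), 25)
  expect_equal(gain_gradient(100, g), 6.25)
  expect_true(all(diff(gain_gradient(seq(0, 140, 5), g)) < 0))
  expect_equal(width_gradient(0, g), 3.40)
  expect_equal(width_gradient(exp(2) - 1, g), 6.80)
  expect_true(all(diff(width_gradient(seq(0, 140, 5), g)) > 0))
  expect_error(gain_gradient(-1, g), "within")
  expect_error(width_gradient(-1, g), "within")
})

test_that("build_layers realizes the default tuning grids", {
  ly <- build_layers()
  expect_equal(length(ly$mode$centers), 151)
  expect_equal(ly$mode$n_modes, 5)
  expect_equal(range(ly$mode$centers), c(-1.5, 1.5))
  expect_equal(length(ly$feature$centers), 181)
  expect_equal(range(ly$feature$centers), c(-40, 140))
  # the unit on its own anchor keeps the landmark gain and width
  i0 <- which(ly$distance1$centers == 0)
  expect_equal(ly$distance1$kappa[i0], 25)
  expect_equal(ly$distance1$sigma[i0], 3.40)
  i100 <- which(ly$distance2$centers == 100)
  expect_equal(ly$distance2$kappa[i100], 25)
  # gains fall away from each anchor
  expect_true(all(diff(ly$distance1$kappa) < 0))
  expect_true(all(diff(ly$distance2$kappa) > 0))
})

test_that("Poisson population responses have unit Fano factor and are seed-reproducible", {
  set.seed(1)
  draws <- poisson_population_response(rep(25, 10000))
  expect_equal(mean(draws), 25, tolerance = 3 * sqrt(25 / 10000) / 25 * 25)
  expect_gt(var(draws) / mean(draws), 0.9)
  expect_lt(var(draws) / mean(draws), 1.1)
  expect_equal(poisson_population_response(rep(0, 5)), rep(0L, 5))
  set.seed(7)
  a <- poisson_population_response(runif(100, 0, 30))
  set.seed(7)
  b <- poisson_population_response(runif(100, 0, 30))
  expect_identical(a, b)
  expect_error(poisson_population_response(c(1, -2)), "within")
})

test_that("mode-layer means peak at the stimulus amplitude", {
  ly <- build_layers()
  # an amplitude exactly on a unit's center drives it at the full gain
  motif <- c(0.5, 0, 0, 0, 0)
  means <- triloc:::mode_layer_means(matrix(motif, 1), ly)
  i <- which(ly$mode$centers == 0.5)
  expect_equal(means[1, i], 25)
  # 3 tuning widths away the mean falls to exp(-4.5) of the gain
  j <- which(abs(ly$mode$centers - (0.5 + 3 * 0.08)) < 1e-9)
  expect_equal(means[1, j], 25 * exp(-4.5), tolerance = 1e-9)
  expect_error(mode_layer_response(rep(2, 5), ly), "support")
})

test_that("winner-take-all template matching recovers the location from noiseless input", {
  net <- test_network()
  # noiseless mode response proportional to the stored template of 75
  motif <- motif_for_location(75)
  means <- triloc:::mode_layer_means(matrix(motif, 1), net$layers)
  resp <- feature_layer_response(round(drop(means)), net)
  expect_equal(resp$winner_location, 75)
  expect_false(resp$degenerate)
  # all-zero input: flat drive, tie broken to the smallest location
  resp0 <- feature_layer_response(rep(0, ncol(net$templates)), net)
  expect_true(resp0$degenerate)
  expect_equal(resp0$winner_location, 0)
  # stochastic winners concentrate on the true location
  set.seed(1)
  winners <- replicate(300, {
    rM <- poisson_population_response(drop(means))
    feature_layer_response(rM, net)$winner_location
  })
  expect_lt(abs(mean(winners) - 75), 0.5)
  expect_lt(sd(winners), 1.5)
})

test_that("non-negative decoder weights reproduce the prescribed tuning curves", {
  ly <- build_layers()
  sol <- solve_decoder_weights(ly$feature, ly$distance1)
  expect_true(all(sol$weights >= 0))
  expect_lt(max(sol$relative_rms), 0.05)
  # a target identical to one source profile is reproduced exactly
  one <- list(centers = 60, kappa = ly$feature$kappa[1],
              sigma = ly$feature$sigma[1])
  sol1 <- solve_decoder_weights(ly$feature, one)
  expect_lt(sol1$relative_rms, 1e-8)
  fitted_w <- sol1$weights[1, ]
  expect_equal(fitted_w[ly$feature$centers == 60], 1, tolerance = 1e-6)
  expect_lt(sum(fitted_w[ly$feature$centers != 60]), 1e-6)
})

test_that("nnls agrees with the reference active-set solver on well-conditioned problems", {
  skip_if_not_installed("pracma")
  set.seed(3)
  for (i in 1:5) {
    A <- matrix(rnorm(40 * 8), 40, 8)
    b <- rnorm(40)
    expect_equal(nnls(A, b)$x, pracma::lsqnonneg(A, b)$x, tolerance = 1e-8)
  }
})

test_that("maximum-likelihood decoding locates spikes and handles degenerate input", {
  net <- test_network()
  k1 <- net$kernel1
  # uniform-gain kernel: a single spike decodes to that unit's center
  ly <- list(centers = net$layers$distance1$centers,
             kappa = rep(25, length(net$layers$distance1$centers)),
             sigma = rep(3.4, length(net$layers$distance1$centers)))
  ku <- triloc:::decoder_kernel(ly, net$config$decode_grid)
  counts <- rep(0, length(ly$centers))
  counts[ly$centers == 40] <- 1
  expect_equal(decode_ml(counts, ku)$location, 40)
  # noiseless mean response decodes to the true location
  mu <- ly$kappa * exp(-(75 - ly$centers)^2 / (2 * ly$sigma^2))
  expect_equal(decode_ml(round(mu * 4), ku)$location, 75)
  # all-zero response is flagged degenerate at the grid midpoint
  dg <- decode_ml(rep(0, length(ly$centers)), k1)
  expect_true(dg$degenerate)
  expect_equal(dg$location, k1$grid[(length(k1$grid) + 1) %/% 2])
})

test_that("integrated decoding reduces to a single cue when the other is silent", {
  net <- test_network()
  n1 <- length(net$layers$distance1$centers)
  n2 <- length(net$layers$distance2$centers)
  set.seed(2)
  mu1 <- net$layers$distance1$kappa *
    exp(-(30 - net$layers$distance1$centers)^2 /
          (2 * net$layers$distance1$sigma^2))
  r1 <- poisson_population_response(mu1)
  expect_equal(decode_integrated(r1, rep(0, n2), net$kernel1, net$kernel2),
               decode_ml(r1, net$kernel1)$location)
  # identical evidence in both subpopulations preserves the argmax
  expect_equal(decode_integrated(r1, r1, net$kernel1, net$kernel1),
               decode_ml(r1, net$kernel1)$location)
  expect_error(decode_integrated(r1[-1], rep(0, n2), net$kernel1,
                                 net$kernel2), "length")
})

test_that("a small seeded simulation is reproducible and structurally sound", {
  net <- test_network()
  sim <- run_simulation(n_runs = 100, locations = c(20, 50, 80),
                        network = net, seed = 1)
  expect_equal(nrow(sim$decodes), 300)
  expect_equal(sort(unique(sim$summary$decoder)), c("L1", "L2", "Lint"))
  sim2 <- run_simulation(n_runs = 100, locations = c(20, 50, 80),
                         network = net, seed = 1)
  expect_identical(sim$decodes, sim2$decodes)
  # refuses to run unseeded unless explicitly allowed
  expect_error(run_simulation(n_runs = 10, network = net), "seed")
  s <- sim$summary
  expect_true(all(abs(s$bias[s$decoder == "Lint"]) < 2))
})
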