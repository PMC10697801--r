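test_that("pixels with natively zero fishing have percent potential exactly 100", {
  cg <- cached_gamma_fit()
  grid <- cg$world$grid
  fish_cols <- c("fishing_noncomm_boat_spear", "fishing_noncomm_boat_net")
  cf <- predict_counterfactual(cg$fit, grid, fishing_drivers = fish_cols,
                               max_draws = 200, moku_fallback = "population")
  zero_fish <- rowSums(as.matrix(grid[, fish_cols])) == 0
  expect_gt(sum(zero_fish), 0)
  expect_true(all(cf$percent[, zero_fish] == 100))
})

test_that("the draw-wise ratio matches the closed-form log-link expression", {
  cg <- cached_gamma_fit()
  grid <- cg$world$grid[1:40, ]
  fish_cols <- c("fishing_noncomm_boat_spear", "fishing_noncomm_boat_net")
  cf <- predict_counterfactual(cg$fit, grid, fishing_drivers = fish_cols,
                               max_draws = 150, moku_fallback = "population")
  # oracle: exp(sum_j beta_j * x_j / sd_j), the analytic log-link ratio
  p <- cg$params
  B <- cg$fit$draws[cf$draw_idx, fish_cols, drop = FALSE]
  delta <- sweep(as.matrix(grid[, fish_cols]), 2,
                 p$sd[match(fish_cols, p$driver)], "/")
  oracle <- 100 * exp(B %*% t(delta))
  expect_lt(max(abs(cf$percent - oracle)), 1e-10)
  # and the percent draws equal elementwise division of the two scenarios
  expect_equal(cf$percent, 100 * cf$expected / cf$potential, tolerance = 1e-12)
})

test_that("stronger fishing coefficients never increase percent potential", {
  cg <- cached_gamma_fit()
  grid <- cg$world$grid[1:60, ]
  fish_cols <- c("fishing_noncomm_boat_spear", "fishing_noncomm_boat_net")
  fit2 <- cg$fit
  fit2$draws[, fish_cols] <- 2 * fit2$draws[, fish_cols] -
    abs(fit2$draws[, fish_cols]) * 0   # doubled magnitudes, sign preserved
  cf1 <- predict_counterfactual(cg$fit, grid, fishing_drivers = fish_cols,
                                max_draws = 100, moku_fallback = "population")
  cf2 <- predict_counterfactual(fit2, grid, fishing_drivers = fish_cols,
                                max_draws = 100, moku_fallback = "population")
  neg <- apply(cg$fit$draws[cf1$draw_idx, fish_cols] <= 0, 1, all)
  expect_true(all(cf2$percent[neg, ] <= cf1$percent[neg, ] + 1e-12))
})

test_that("unknown moku error and population fallback behave as configured", {
  cg <- cached_gamma_fit()
  grid <- cg$world$grid[1:10, ]
  grid$moku_id <- "moku_99"
  expect_error(predict_counterfactual(cg$fit, grid, max_draws = 50),
               "prediction-level")
  cf <- predict_counterfactual(cg$fit, grid, max_draws = 50,
                               moku_fallback = "population")
  expect_equal(ncol(cf$percent), 10L)
})

test_that("pixel classification agrees with a sort-based quartile oracle", {
  set.seed(70)
  n_draws <- 120
  shifts <- runif(1000, -1, 2)
  E <- matrix(rnorm(n_draws * 1000), n_draws, 1000)
  P <- E + rep(shifts, each = n_draws) + matrix(rnorm(n_draws * 1000, 0, 0.3),
                                                n_draws, 1000)
  cls <- classify_pixel(E, P)
  oracle <- ifelse(apply(P, 2, oracle_q7, 0.25) > apply(E, 2, oracle_q7, 0.75),
                   "affected", "unaffected")
  expect_equal(as.character(cls), oracle)
  expect_true(any(cls == "affected") && any(cls == "unaffected"))

  # identical draws: unaffected; large shift: affected
  x <- rnorm(200)
  expect_equal(as.character(classify_pixel(x, x)), "unaffected")
  expect_equal(as.character(classify_pixel(x, x + 100)), "affected")
  # invariant to permuting draws within a scenario
  expect_equal(classify_pixel(E[sample(n_draws), ], P[sample(n_draws), ]), cls)
  expect_error(classify_pixel(numeric(0), numeric(0)), "empty")
})

test_that("threshold logistic inverts its fitted curve exactly", {
  set.seed(71)
  n <- 4000
  x <- runif(n, 0, 150)
  unaff <- rbinom(n, 1, plogis(-10 + 0.18 * x)) == 1
  thr <- fit_threshold_logistic(unaff, x, p_star = 0.99)
  # exact logit inversion of the fitted coefficients (closed-form oracle)
  expect_equal(thr$x_star, (log(99) - thr$intercept) / thr$slope,
               tolerance = 1e-6)
  expect_equal(plogis(thr$intercept + thr$slope * thr$x_star), 0.99,
               tolerance = 1e-9)
  # near the generating curve's analytic threshold (ln 99 + 10) / 0.18
  expect_lt(abs(thr$x_star - (log(99) + 10) / 0.18), 5)
  expect_false(thr$separation)
  expect_false(thr$unreliable)
})

test_that("degenerate threshold inputs are flagged or rejected", {
  set.seed(72)
  x <- runif(500, 0, 100)
  # labels independent of x: slope CI contains zero, flagged unreliable
  expect_warning(thr <- fit_threshold_logistic(rbinom(500, 1, 0.5) == 1, x),
                 "unreliable|slope")
  expect_true(thr$unreliable)
  # one class only: no threshold
  expect_error(fit_threshold_logistic(rep(TRUE, 500), x), "no-threshold")
  # complete separation: mid-gap threshold with flag
  xs <- c(runif(100, 0, 40), runif(100, 60, 100))
  cls <- rep(c(FALSE, TRUE), each = 100)
  thr2 <- suppressWarnings(fit_threshold_logistic(cls, xs))
  expect_true(thr2$separation)
  expect_equal(thr2$x_star, (max(xs[1:100]) + min(xs[101:200])) / 2)
})

test_that("threshold coverage matches brute-force counting", {
  pp <- c(10, 50, 79, 81, 120, 95)
  moku <- c("a", "a", "a", "b", "b", "b")
  cov <- threshold_coverage(pp, 80, moku = moku)
  expect_equal(cov$overall, mean(pp < 80))
  expect_equal(cov$by_moku$fraction_below, c(1, 0))
  expect_equal(threshold_coverage(c(90, 95), 80)$overall, 0)
  set.seed(73)
  pp2 <- runif(500, 0, 160)
  expect_equal(threshold_coverage(pp2, 80)$overall, sum(pp2 < 80) / 500)
})

test_that("benthic counterfactual responds to functional-group scenarios", {
  cg <- cached_gamma_fit()
  reps <- cg$reps
  drivers <- c("ocean_sst_mean", "habitat_depth")
  std <- standardize_drivers(reps, drivers)
  bspec <- hier_spec(
    "benthic_logratio",
    design_fun = function(d) build_design(d, drivers, std$params, "benthic"),
    family = "normal", mcmc = mcmc_schedule("ci"), seed = 8)
  bfit <- fit_normal_lm(bspec, reps)

  grid <- cg$world$grid[1:30, ]
  fg <- data.frame(grazer = rep(10, 30), scraper = 8, browser = 4)
  same <- benthic_counterfactual(bfit, grid, fg, fg, max_draws = 100,
                                 moku_fallback = "population")
  expect_identical(same$expected, same$potential)

  # raising scraper biomass with a positive scraper coefficient shifts the
  # linear predictor up by beta_scraper * dlog1p (closed-form check)
  fg_hi <- transform(fg, scraper = 30)
  cfb <- benthic_counterfactual(bfit, grid, fg, fg_hi, max_draws = 100,
                                moku_fallback = "population")
  dlog <- log1p(30) - log1p(8)
  b <- bfit$draws[cfb$draw_idx, ]
  centers <- bfit$design_meta$fg_centers
  gz <- log1p(10) - centers[["grazer"]]
  bw <- log1p(4) - centers[["browser"]]
  shift <- b[, "scraper"] * dlog + b[, "grazer:scraper"] * gz * dlog +
    b[, "scraper:browser"] * bw * dlog +
    b[, "grazer:scraper:browser"] * gz * bw * dlog
  expect_equal(unname(cfb$potential - cfb$expected),
               matrix(shift, length(shift), 30), tolerance = 1e-10)

  expect_error(benthic_counterfactual(bfit, grid, fg, NULL), "invalid argument")
  grid_bad <- grid
  grid_bad$ocean_sst_mean <- NULL
  expect_error(benthic_counterfactual(bfit, grid_bad, fg, fg), "missing column")
})
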