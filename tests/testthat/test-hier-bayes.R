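# helper: hand-built design for minimal models
manual_design <- function(X, params = NULL) {
  structure(list(
    X = X,
    groups = stats::setNames(rep("driver", ncol(X)), colnames(X)),
    meta = list(spec = "herbivore", params = params, drivers = colnames(X)[-1],
                fg_centers = NULL, habitat_levels = NULL)),
    class = "reef_design")
}

test_that("intercept-only gamma fit matches the method-of-moments oracle", {
  set.seed(10)
  n <- 1500
  y <- rgamma(n, shape = 3, rate = 3 / exp(2))
  dat <- data.frame(biomass = y, year = 2010, moku_id = "m1",
                    source_dataset = "d1")
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  spec <- hier_spec("biomass", design = manual_design(X), family = "gamma-log",
                    mcmc = mcmc_schedule("ci"), seed = 2)
  fit <- fit_gamma_glm(spec, dat)
  post_mean <- mean(exp(fit$draws[, "(Intercept)"]))
  mom <- mean(y)                          # method-of-moments oracle
  se <- sd(y) / sqrt(n)
  expect_lt(abs(post_mean - mom), 4 * se)
  expect_true(all(fit$draws[, "kappa"] > 0 & fit$draws[, "kappa"] <= 100))
  # single-level hierarchies have identically zero effects
  expect_true(all(fit$draws[, "eps_year[2010]"] == 0))
})

test_that("gamma fit rejects non-positive responses and bad specs", {
  dat <- data.frame(biomass = c(1, 0, 2), year = 1, moku_id = "m",
                    source_dataset = "d")
  X <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  spec <- hier_spec("biomass", design = manual_design(X), family = "gamma-log",
                    mcmc = mcmc_schedule("ci"))
  expect_error(fit_gamma_glm(spec, dat), "strictly positive")
  expect_error(hier_spec("y", design = manual_design(X), family = "normal",
                         mcmc = list(chains = 1, init = 1, burn = 1, keep = 1)),
               "chains")
})

test_that("sum-to-zero holds exactly in every retained draw, all hierarchies", {
  fit <- cached_gamma_fit()$fit
  for (g in c("year", "moku", "dataset")) {
    eps <- fit$draws[, paste0("eps_", g, "[", fit$levels[[g]], "]"), drop = FALSE]
    expect_lt(max(abs(rowSums(eps))), 1e-10)
  }
})

test_that("the sampler agrees with an independent JAGS fit on a small fixture", {
  set.seed(21)
  n <- 300
  X <- cbind(1, matrix(rnorm(n * 2), n, 2))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  beta <- c(2.2, 0.5, -0.4)
  moku <- sample(1:3, n, TRUE)
  em <- c(0.25, -0.1); em <- c(em, -sum(em))
  mu <- as.vector(X %*% beta) + em[moku]
  y <- rgamma(n, shape = 4, rate = 4 / exp(mu))
  dat <- data.frame(biomass = y, year = 1, moku_id = moku, source_dataset = 1)

  spec <- hier_spec("biomass", design = manual_design(X), family = "gamma-log",
                    mcmc = mcmc_schedule("ci"), seed = 3)
  fit <- fit_gamma_glm(spec, dat)

  library(rjags)
  model_str <- "model {
    eta <- X %*% beta
    for (i in 1:N) {
      y[i] ~ dgamma(kappa, kappa * exp(-(eta[i] + eps[moku[i]])))
    }
    for (j in 1:P) { beta[j] ~ dnorm(0, 0.01) }
    kappa ~ dunif(0, 100)
    for (k in 1:(NM-1)) { z[k] ~ dnorm(0, tau_m) }
    eps[1:(NM-1)] <- z
    eps[NM] <- -sum(z)
    sd_m ~ dnorm(0, 0.25) T(0,)
    tau_m <- pow(sd_m, -2)
  }"
  jm <- jags.model(textConnection(model_str),
                   data = list(y = y, X = X, N = n, P = 3, moku = moku, NM = 3),
                   n.chains = 2, n.adapt = 150, quiet = TRUE,
                   inits = lapply(1:2, function(i)
                     list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = i)))
  update(jm, 250)
  s <- coda.samples(jm, c("beta", "kappa"), n.iter = 400)
  jags_mean <- summary(s)$statistics[, "Mean"]

  ours <- colMeans(fit$draws[, c(colnames(X), "kappa")])
  ref <- jags_mean[c("beta[1]", "beta[2]", "beta[3]", "kappa")]
  post_sd <- apply(fit$draws[, c(colnames(X), "kappa")], 2, sd)
  expect_true(all(abs(ours - ref) < pmax(0.35 * post_sd, 0.02)))
})

test_that("normal model: noise gives near-zero R2, sigma positive, interaction recoverable", {
  set.seed(30)
  n <- 2000
  X <- cbind(1, matrix(rnorm(n * 3), n, 3))
  colnames(X) <- c("(Intercept)", "a", "b", "c")
  dat <- data.frame(lr = rnorm(n), year = rep(1:2, n / 2), moku_id = "m",
                    source_dataset = "d")
  spec <- hier_spec("lr", design = manual_design(X), family = "normal",
                    mcmc = mcmc_schedule("ci"), seed = 4)
  fit <- fit_normal_lm(spec, dat)
  expect_lt(median(fit$bayes_r2), 0.05)
  expect_true(all(fit$draws[, "sigma"] > 0))
  expect_true(all(fit$bayes_r2 >= 0 & fit$bayes_r2 <= 1))

  # three-way interaction recovery through the benthic design
  w <- small_world(seed = 31, n_pixels = 200, beta = c(habitat_rugosity = 0.2))
  truth <- make_truth(list(
    beta = c(habitat_rugosity = 0.2),
    benthic_beta = c(`grazer:scraper:browser` = 0.25),
    sigma_benthic = 0.5, seed = 31))
  sim <- simulate_surveys(w$grid, truth, 1200, seed = 32)
  reps <- sim$replicates
  drivers <- c("ocean_sst_mean", "habitat_depth")
  std <- standardize_drivers(reps, drivers)
  bspec <- hier_spec(
    "benthic_logratio",
    design_fun = function(d) build_design(d, drivers, std$params, "benthic"),
    family = "normal", mcmc = mcmc_schedule("ci"), seed = 33)
  bfit <- fit_normal_lm(bspec, reps)
  d3 <- bfit$draws[, "grazer:scraper:browser"]
  expect_gt(0.25, quantile(d3, 0.025))
  expect_lt(0.25, quantile(d3, 0.975))
})

test_that("Gelman-Rubin diagnostics match a direct implementation of the formula", {
  # identical chains: statistic ~ 1
  set.seed(40)
  x <- rnorm(500)
  fake <- list(draws = cbind(p = c(x, x)), chain = rep(1:2, each = 500))
  expect_lt(abs(reefherb:::gelman_rubin(fake)[["p"]] - 1), 0.01)

  # well-separated chains: statistic >> 1, equal to the split-free formula
  y <- rnorm(500, 5)
  fake2 <- list(draws = cbind(p = c(x, y)), chain = rep(1:2, each = 500))
  r <- reefherb:::gelman_rubin(fake2)[["p"]]
  # independent oracle: the published potential-scale-reduction formula,
  # sqrt(((n-1)/n W + B/n) / W), evaluated directly
  n <- 500
  ch <- list(x, y)
  means <- vapply(ch, mean, 1); vars <- vapply(ch, var, 1)
  B <- n * var(means); W <- mean(vars)
  psrf_direct <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_gt(r, 3)
  expect_equal(r, psrf_direct, tolerance = 1e-10)
})

test_that("fit diagnostics report calibrated predictive checks", {
  fit <- cached_gamma_fit()$fit
  dg <- diagnose_fit(fit, max_draws = 200)
  expect_true(dg$ppc$p_mean > 0.01 && dg$ppc$p_mean < 0.99)
  expect_true(dg$ppc$p_sd > 0.001 && dg$ppc$p_sd < 0.999)
  expect_true(all(dg$bayes_r2$draws >= 0 & dg$bayes_r2$draws <= 1))
  single <- fit
  single$chain <- rep(1L, length(fit$chain))
  expect_error(diagnose_fit(single), "diagnostics unavailable")
})

test_that("posterior summaries are invariant to row permutation", {
  cg <- cached_gamma_fit()
  set.seed(50)
  perm <- sample(nrow(cg$reps))
  fit2 <- fit_gamma_glm(cg$spec, cg$reps[perm, ])
  m1 <- apply(cg$fit$draws[, cg$fit$beta_cols], 2, median)
  m2 <- apply(fit2$draws[, fit2$beta_cols], 2, median)
  sd1 <- apply(cg$fit$draws[, cg$fit$beta_cols], 2, sd)
  expect_true(all(abs(m1 - m2) < pmax(0.5 * sd1, 0.01)))
})

test_that("reduced schedule matches the full schedule within Monte-Carlo error", {
  cg <- cached_gamma_fit()
  spec_full <- cg$spec
  spec_full$mcmc <- mcmc_schedule("full")
  fit_full <- fit_gamma_glm(spec_full, cg$reps)
  m_ci <- apply(cg$fit$draws[, cg$fit$beta_cols], 2, median)
  m_full <- apply(fit_full$draws[, fit_full$beta_cols], 2, median)
  sd_full <- apply(fit_full$draws[, fit_full$beta_cols], 2, sd)
  # 3 Monte-Carlo SEs with a conservative effective-sample floor
  mcse <- 3 * sd_full * sqrt(pi / 2) / sqrt(150)
  expect_true(all(abs(m_ci - m_full) < pmax(mcse, 0.01)))
  expect_lt(max(fit_full$rhat, na.rm = TRUE), 1.1)
})

test_that("leverage re-runs attenuate coefficients driven by a planted cluster", {
  set.seed(60)
  n <- 800
  site <- seq_len(n) <= 80
  x <- ifelse(site, 3 + rnorm(n, 0, 0.1), rnorm(n))
  mu <- 2 + 0.8 * site          # the site, not the driver, lifts biomass
  y <- rgamma(n, 4, rate = 4 / exp(mu))
  dat <- data.frame(biomass = y, x = x, year = 1, moku_id = "m",
                    source_dataset = "d")
  spec <- hier_spec(
    "biomass",
    design_fun = function(d) {
      X <- cbind(`(Intercept)` = 1, x = d$x)
      manual_design(X)
    },
    family = "gamma-log", mcmc = mcmc_schedule("ci"), seed = 6)
  lr <- leverage_rerun(spec, dat, "x", flag = site)
  before <- lr$comparison[lr$comparison$fit == "original", ]
  after <- lr$comparison[lr$comparison$fit == "modified", ]
  expect_false(before$contains_zero)          # spurious positive effect
  expect_lt(abs(after$median), abs(before$median))

  # a null driver stays null before and after
  set.seed(61)
  dat2 <- dat
  dat2$x <- rnorm(n)
  dat2$biomass <- rgamma(n, 4, rate = 4 / exp(2))
  lr2 <- leverage_rerun(spec, dat2, "x")
  expect_true(all(lr2$comparison$contains_zero))

  expect_error(leverage_rerun(spec, dat, "nope"), "missing column|schema")
})
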