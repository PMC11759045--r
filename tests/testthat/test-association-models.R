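## Shared simulated multilevel dataset
sim_bmlm_data <- function(n = 240, ns = 8, beta = 2, sd_site = 1.5,
                          sd_e = 1, seed = 1) {
  set.seed(seed)
  site <- factor(rep(seq_len(ns), each = n / ns))
  a <- rnorm(ns, 0, sd_site)
  x <- runif(n, 0, 10)
  y <- 1 + a[site] + beta * x + rnorm(n, 0, sd_e)
  list(y = y, x = x, site = site, beta = beta)
}

## A minimal hand-built fit for testing draw-based summaries exactly.
fake_fit <- function(beta_draws, family = "gaussian") {
  n <- length(beta_draws)
  half <- n / 2
  draws <- array(NA_real_, c(half, 2, 5),
                 dimnames = list(NULL, NULL,
                                 c("alpha", "beta", "sigma_site", "sigma",
                                   "a[s1]")))
  draws[, 1, "beta"] <- beta_draws[seq_len(half)]
  draws[, 2, "beta"] <- beta_draws[seq.int(half + 1, n)]
  draws[, , "alpha"] <- 0; draws[, , "sigma_site"] <- 1
  draws[, , "sigma"] <- 1; draws[, , "a[s1]"] <- 0
  structure(list(draws = draws, family = family, theta = NA,
                 par_names = dimnames(draws)[[3]]),
            class = "posterior_fit")
}

test_that("BMLM recovers a known slope with calibrated uncertainty", {
  d <- sim_bmlm_data(beta = 2, seed = 3)
  fit <- fit_bmlm(d$y, d$x, d$site, mcmc = mcmc_config(iter = 2000, seed = 1))
  expect_s3_class(fit, "posterior_fit")
  b <- fit_draws(fit, "beta")
  ci <- quantile(b, c(0.025, 0.975))
  expect_lt(ci[1], 2); expect_gt(ci[2], 2)
  expect_true(all(fit$diagnostics$rhat < 1.01))
  expect_true(all(fit$diagnostics$ess_bulk > 1000))

  ## beta = 0 simulation: CI overlaps zero
  d0 <- sim_bmlm_data(beta = 0, seed = 4)
  fit0 <- fit_bmlm(d0$y, d0$x, d0$site,
                   mcmc = mcmc_config(iter = 2000, seed = 2))
  ci0 <- quantile(fit_draws(fit0, "beta"), c(0.025, 0.975))
  expect_lt(ci0[1], 0); expect_gt(ci0[2], 0)

  ## near-noise-free y = x: posterior concentrates at 1, R2 ~ 1
  d1 <- sim_bmlm_data(beta = 1, sd_site = 0.01, sd_e = 0.01, seed = 5)
  fit1 <- fit_bmlm(d1$y, d1$x, d1$site,
                   mcmc = mcmc_config(iter = 2000, seed = 3))
  expect_equal(median(fit_draws(fit1, "beta")), 1, tolerance = 0.01)
  expect_gt(bayes_r2(fit1)$median, 0.99)

  expect_error(fit_bmlm(d$y[1:10], d$x[1:10], d$site[1:10]), "n >= 20")
  expect_error(fit_bmlm(d$y, d$x, rep(1, length(d$y))), "2 sites")
})

test_that("determinism: identical seeds give identical draws", {
  d <- sim_bmlm_data(seed = 6)
  f1 <- fit_bmlm(d$y, d$x, d$site, mcmc = mcmc_config(iter = 600, seed = 9),
                 strict = FALSE)
  f2 <- fit_bmlm(d$y, d$x, d$site, mcmc = mcmc_config(iter = 600, seed = 9),
                 strict = FALSE)
  expect_identical(f1$draws, f2$draws)
})

test_that("quantile fits match the median and order heteroskedastic slopes", {
  d <- sim_bmlm_data(beta = 2, seed = 7)
  bm <- fit_bmlm(d$y, d$x, d$site, mcmc = mcmc_config(iter = 2000, seed = 4))
  ci <- quantile(fit_draws(bm, "beta"), c(0.025, 0.975))
  q5 <- fit_bqlm(d$y, d$x, d$site, theta = 0.5,
                 mcmc = mcmc_config(iter = 2000, seed = 5),
                 strict = FALSE)$theta_0.5
  bq <- median(fit_draws(q5, "beta"))
  expect_gt(bq, ci[1]); expect_lt(bq, ci[2])

  ## variance increasing with x: upper-quantile slope exceeds lower
  set.seed(8)
  n <- 240; site <- factor(rep(1:8, each = 30))
  x <- runif(n, 0, 10)
  y <- 1 + 0.5 * x + rnorm(n, 0, 0.2 + 0.4 * x)
  qf <- fit_bqlm(y, x, site, theta = c(0.05, 0.95),
                 mcmc = mcmc_config(iter = 2500, seed = 6), strict = FALSE)
  b05 <- median(fit_draws(qf$theta_0.05, "beta"))
  b95 <- median(fit_draws(qf$theta_0.95, "beta"))
  expect_gt(b95, b05)
  expect_error(fit_bqlm(y, x, site, theta = c(0, 0.5)), "theta")
})

test_that("evidence ratio counts posterior draws exactly", {
  expect_equal(evidence_ratio(fake_fit(c(rep(1, 3999), -1))), 3999)
  expect_equal(evidence_ratio(fake_fit(rep(1, 2000))), Inf)
  expect_equal(evidence_ratio(fake_fit(c(rep(1, 2000), rep(-1, 2000)))), 1)
  ## complementary hypothesis is the reciprocal
  f <- fake_fit(c(rep(1, 3000), rep(-1, 1000)))
  expect_equal(evidence_ratio(f, ">"), 1 / evidence_ratio(f, "<"))
  expect_error(evidence_ratio(fake_fit(rep(1, 100))), "1000")
})

test_that("Bayesian R2 separates signal from noise and levels", {
  ## pure noise, no site structure: R2 near zero
  set.seed(9)
  n <- 200; site <- factor(rep(1:8, each = 25))
  y <- rnorm(n); x <- runif(n, 0, 10)
  fit <- fit_bmlm(y, x, site, mcmc = mcmc_config(iter = 2000, seed = 7),
                  strict = FALSE)
  expect_lt(bayes_r2(fit)$median, 0.08)

  ## with real site spread, conditional >= marginal
  d <- sim_bmlm_data(beta = 1, sd_site = 2, seed = 10)
  fit2 <- fit_bmlm(d$y, d$x, d$site, mcmc = mcmc_config(iter = 2000, seed = 8))
  expect_gte(bayes_r2(fit2, TRUE)$median, bayes_r2(fit2, FALSE)$median)
})

test_that("posterior predictive checks calibrate and flag misspecification", {
  d <- sim_bmlm_data(seed = 11)
  fit <- fit_bmlm(d$y, d$x, d$site, mcmc = mcmc_config(iter = 2000, seed = 9))
  ppc <- posterior_predictive_check(fit, n_rep = 150, seed = 1)
  expect_identical(nrow(ppc$yrep), 150L)
  expect_gt(ppc$p_mean, 0.05); expect_lt(ppc$p_mean, 0.95)
  expect_gt(ppc$p_sd, 0.05); expect_lt(ppc$p_sd, 0.95)

  ## skewed errors: the skewness statistic lands in the tail (the fitted
  ## Gaussian absorbs mean and sd, so those stay calibrated)
  set.seed(12)
  n <- 240; site <- factor(rep(1:8, each = 30))
  x <- runif(n, 0, 10)
  y <- 1 + x + (rlnorm(n, 0, 1) - exp(0.5))
  fit_t <- fit_bmlm(y, x, site, mcmc = mcmc_config(iter = 2000, seed = 10),
                    strict = FALSE)
  ppc_t <- posterior_predictive_check(fit_t, n_rep = 150, seed = 2)
  expect_true(ppc_t$p_skew < 0.05 || ppc_t$p_skew > 0.95)
})

test_that("prediction scores match hand arithmetic and degenerate contracts", {
  s <- prediction_scores(c(1, 2, 3), c(1, 2, 3))
  expect_equal(s$rho, 1)
  expect_equal(s$smape, 0)
  expect_equal(s$rmsle, 0)
  expect_true(all(s$deviation == 0))

  y <- c(1, 2, 3, 4); yhat <- c(2, 3, 4, 5)
  s2 <- prediction_scores(y, yhat)
  expect_equal(s2$smape, mean(c(2 / 3, 2 / 5, 2 / 7, 2 / 9)))
  expect_equal(s2$rmsle,
               sqrt(mean(log(c(3 / 2, 4 / 3, 5 / 4, 6 / 5))^2)))
  expect_equal(s2$deviation, rep(0.25, 4))

  expect_warning(s3 <- prediction_scores(y, rep(2, 4)), "rho")
  expect_true(is.na(s3$rho))
  expect_warning(s4 <- prediction_scores(c(-1, 2, 3, 4), yhat), "rmsle")
  expect_true(is.na(s4$rmsle))
})

test_that("train/test prediction pipeline scores a recoverable pair", {
  d <- sim_bmlm_data(n = 320, ns = 8, beta = 2, sd_e = 1, seed = 13)
  r <- train_test_predict(d$y, d$x, d$site, seed = 2,
                          mcmc = mcmc_config(iter = 1200, seed = 11))
  expect_gt(r$rho, 0.9)
  expect_lt(r$mean_deviation, 0.2)
  expect_error(train_test_predict(d$y[1:30], d$x[1:30], d$site[1:30]),
               "n >= 40")
})

test_that("model pair registry pairs only analogous metrics", {
  reg <- model_pair_registry()
  ## taxonomic responses: the three Hill metrics against SS at matching q
  tax <- reg[reg$response_dimension == "taxonomic", ]
  expect_identical(nrow(tax), 3L)
  expect_true(all(tax$covariate_metric == "SS"))
  expect_identical(tax$response_q, tax$covariate_q)

  ## trait dimension, distance group: 5 response models
  trait_dist <- reg[reg$response_dimension == "trait" &
                      reg$group == "distance", ]
  expect_identical(nrow(trait_dist), 5L)
  phylo_dist <- reg[reg$response_dimension == "phylogenetic" &
                      reg$group == "distance", ]
  expect_gte(nrow(phylo_dist), 6L)

  ## no cross-family pairs: distance responses never meet SS covariates
  expect_false(any(reg$response_metric %in%
                     c("MTD", "MTDz", "MPD", "MPDz", "PD", "PDz") &
                     reg$covariate_metric == "SS"))
  expect_false(any(reg$response_metric %in% c("S", "H", "D") &
                     reg$covariate_metric != "SS"))

  ## round-trips through YAML serialization
  rt <- yaml::yaml.load(yaml::as.yaml(reg))
  expect_equal(as.data.frame(rt)$response_metric, reg$response_metric)
})
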