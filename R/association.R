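## Bayesian multilevel (Gaussian) and quantile (asymmetric-Laplace)
## regressions linking ground metrics to spectral metrics, fitted by Gibbs
## sampling: conjugate updates throughout, with half-t priors on scale
## parameters via the Huang-Wand inverse-gamma parameter expansion and the
## Kozumi-Kobayashi exponential scale mixture for the quantile likelihood.

#' MCMC configuration
#'
#' @param chains number of chains (default 4).
#' @param iter total iterations per chain (default 5000).
#' @param warmup burn-in discarded per chain (default 20% of `iter`).
#' @param seed root seed; chains use derived child seeds.
#' @return a list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, iter = 5000, warmup = NULL, seed = 1) {
  if (is.null(warmup)) warmup <- ceiling(iter * 0.2)
  if (warmup >= iter) stop("warmup must be < iter", call. = FALSE)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed)),
            class = "mcmc_config")
}

## Prior constants: Normal(0, 5^2) on alpha and beta; half-t(3, 2.5) on
## scales (sigma, sigma_site) through the Huang-Wand expansion.
.PRIOR <- list(b_sd = 5, t_nu = 3, t_scale = 2.5)

## One inverse-gamma draw: shape a, rate b.
.rinvgamma <- function(a, b) 1 / stats::rgamma(1, shape = a, rate = b)

## Inverse-Gaussian sampler (Michael, Schucany & Haas).
.rinvgauss <- function(n, mean, shape) {
  nu <- stats::rnorm(n)
  y <- nu^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  z <- stats::runif(n)
  ifelse(z <= mean / (mean + x), x, mean^2 / x)
}

## --- Gaussian multilevel Gibbs ---------------------------------------------
## (alpha, beta, a_1..a_S) are drawn as one conjugate block to avoid the
## poor mixing of the intercept against the site effects.
.gibbs_bmlm_chain <- function(y, x, site, cfg_iter, warmup, seed) {
  n <- length(y)
  ns <- nlevels(site)
  si <- as.integer(site)
  b_prec <- 1 / .PRIOR$b_sd^2
  nu <- .PRIOR$t_nu; A <- .PRIOR$t_scale
  keep <- cfg_iter - warmup
  out <- matrix(NA_real_, keep, 4 + ns)
  Z <- cbind(1, x, outer(si, seq_len(ns), "=="))   # n x (2 + ns)
  ZtZ <- crossprod(Z)
  Zty <- crossprod(Z, y)
  p <- 2 + ns
  with_seed(seed, {
    theta <- rep(0, p)
    sig2 <- stats::var(y) * exp(stats::runif(1, -1, 1))
    sig2_s <- sig2 / 2
    g_e <- g_s <- 1
    for (it in seq_len(cfg_iter)) {
      prior_prec <- c(b_prec, b_prec, rep(1 / sig2_s, ns))
      prec <- ZtZ / sig2
      diag(prec) <- diag(prec) + prior_prec
      ch <- chol(prec)
      m <- backsolve(ch, forwardsolve(t(ch), Zty / sig2))
      theta <- as.numeric(m + backsolve(ch, stats::rnorm(p)))
      a <- theta[-(1:2)]
      resid <- as.numeric(y - Z %*% theta)
      ## residual scale (half-t via Huang-Wand)
      sig2 <- .rinvgamma((nu + n) / 2, nu / g_e + sum(resid^2) / 2)
      g_e <- .rinvgamma((nu + 1) / 2, nu / sig2 + 1 / A^2)
      ## site scale
      sig2_s <- .rinvgamma((nu + ns) / 2, nu / g_s + sum(a^2) / 2)
      g_s <- .rinvgamma((nu + 1) / 2, nu / sig2_s + 1 / A^2)
      if (it > warmup)
        out[it - warmup, ] <- c(theta[1:2], sqrt(sig2_s), sqrt(sig2), a)
    }
  })
  out
}

#' Fit a Bayesian multilevel linear model by Gibbs sampling
#'
#' `y = alpha + a_site + beta * x + e`, with `a_site ~ N(0, sigma_site^2)`
#' and `e ~ N(0, sigma^2)`; priors Normal(0, 5) on alpha and beta and
#' half-t(3, 0, 2.5) on both scales.  Convergence is assessed with
#' split-Rhat and bulk-ESS on the core parameters.
#'
#' @param y,x numeric response and covariate.
#' @param site factor (or coercible) of group ids; >= 2 groups.
#' @param mcmc an [mcmc_config()].
#' @param strict if `TRUE` (default) an unconverged fit (any core Rhat >=
#'   1.01) returns a typed `fit_failure` carrying the diagnostics.
#' @return a `posterior_fit`: draw array (iterations x chains x parameters:
#'   alpha, beta, sigma_site, sigma, site intercepts), diagnostics table,
#'   and the model data.
#' @export
fit_bmlm <- function(y, x, site, mcmc = mcmc_config(), strict = TRUE) {
  site <- droplevels(as.factor(site))
  if (length(y) < 20) stop("need n >= 20", call. = FALSE)
  if (nlevels(site) < 2) stop("need >= 2 sites", call. = FALSE)
  chains <- lapply(seq_len(mcmc$chains), function(c)
    .gibbs_bmlm_chain(y, x, site, mcmc$iter, mcmc$warmup,
                      child_seed(mcmc$seed, "mcmc", c)))
  par_names <- c("alpha", "beta", "sigma_site", "sigma",
                 paste0("a[", levels(site), "]"))
  draws <- array(NA_real_, c(nrow(chains[[1]]), mcmc$chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (c in seq_along(chains)) draws[, c, ] <- chains[[c]]
  fit <- structure(list(
    draws = draws, par_names = par_names, family = "gaussian", theta = NA,
    data = list(y = y, x = x, site = site), mcmc = mcmc,
    diagnostics = .fit_diagnostics(draws, par_names[1:4])),
    class = "posterior_fit")
  .maybe_fail(fit, strict)
}

.maybe_fail <- function(fit, strict) {
  bad <- any(fit$diagnostics$rhat >= 1.01, na.rm = TRUE)
  fit$converged <- !bad
  if (bad && strict)
    return(structure(list(diagnostics = fit$diagnostics,
                          message = "Rhat >= 1.01 on a core parameter"),
                     class = "fit_failure"))
  fit
}

## --- quantile (asymmetric-Laplace) Gibbs -----------------------------------
.gibbs_bqlm_chain <- function(y, x, site, theta, cfg_iter, warmup, seed) {
  n <- length(y)
  ns <- nlevels(site)
  si <- as.integer(site)
  t1 <- (1 - 2 * theta) / (theta * (1 - theta))
  t2 <- 2 / (theta * (1 - theta))
  b_prec <- 1 / .PRIOR$b_sd^2
  nu <- .PRIOR$t_nu; A <- .PRIOR$t_scale
  keep <- cfg_iter - warmup
  out <- matrix(NA_real_, keep, 4 + ns)
  Z <- cbind(1, x, outer(si, seq_len(ns), "=="))
  with_seed(seed, {
    beta <- stats::rnorm(2, 0, 1)
    a <- rep(0, ns)
    sig <- stats::mad(y) + 0.1
    sig2_s <- stats::var(y) / 4 + 0.1
    g_s <- 1
    v <- rep(1, n)
    for (it in seq_len(cfg_iter)) {
      mu <- as.numeric(Z %*% c(beta, a))
      ## latent exponential mixture weights
      chi <- pmax((y - mu)^2 / (t2 * sig), 1e-12)
      psi <- t1^2 / (t2 * sig) + 2 / sig
      vinv <- .rinvgauss(n, mean = sqrt(psi / chi), shape = psi)
      v <- 1 / pmax(vinv, 1e-12)
      ## joint block draw of (alpha, beta, site intercepts), weighted
      w <- 1 / (t2 * sig * v)
      z <- y - t1 * v
      sw <- sqrt(w)
      prec <- crossprod(Z * sw)
      diag(prec) <- diag(prec) + c(b_prec, b_prec, rep(1 / sig2_s, ns))
      ch <- chol(prec)
      m <- backsolve(ch, forwardsolve(t(ch), crossprod(Z, w * z)))
      theta <- as.numeric(m + backsolve(ch, stats::rnorm(2 + ns)))
      beta <- theta[1:2]
      a <- theta[-(1:2)]
      ## ALD scale (conjugate inverse-gamma prior IG(2, 2))
      mu <- as.numeric(Z %*% theta)
      rate <- sum((y - mu - t1 * v)^2 / (t2 * v)) / 2 + sum(v) + 2
      sig <- .rinvgamma(2 + 3 * n / 2, rate)
      ## site scale (half-t via Huang-Wand)
      sig2_s <- .rinvgamma((nu + ns) / 2, nu / g_s + sum(a^2) / 2)
      g_s <- .rinvgamma((nu + 1) / 2, nu / sig2_s + 1 / A^2)
      if (it > warmup)
        out[it - warmup, ] <- c(beta, sqrt(sig2_s), sig, a)
    }
  })
  out
}

#' Fit Bayesian quantile regressions with site intercepts
#'
#' Asymmetric-Laplace likelihood at each requested quantile, with random
#' site intercepts and the same sampler contract as [fit_bmlm()].  The
#' asymmetric Laplace is sampled through its exponential scale mixture; the
#' ALD scale takes a conjugate inverse-gamma prior.
#'
#' @param y,x,site as in [fit_bmlm()].
#' @param theta quantile levels in (0, 1); default the seven levels
#'   0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95.
#' @param mcmc an [mcmc_config()].
#' @param strict as in [fit_bmlm()].
#' @return named list of `posterior_fit` objects, one per quantile.
#' @export
fit_bqlm <- function(y, x, site,
                     theta = c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95),
                     mcmc = mcmc_config(), strict = TRUE) {
  if (any(theta <= 0 | theta >= 1)) stop("theta must be in (0, 1)", call. = FALSE)
  site <- droplevels(as.factor(site))
  out <- lapply(seq_along(theta), function(ti) {
    chains <- lapply(seq_len(mcmc$chains), function(c)
      .gibbs_bqlm_chain(y, x, site, theta[ti], mcmc$iter, mcmc$warmup,
                        child_seed(mcmc$seed, "mcmc", 100 * ti + c)))
    par_names <- c("alpha", "beta", "sigma_site", "sigma",
                   paste0("a[", levels(site), "]"))
    draws <- array(NA_real_,
                   c(nrow(chains[[1]]), mcmc$chains, length(par_names)),
                   dimnames = list(NULL, NULL, par_names))
    for (c in seq_along(chains)) draws[, c, ] <- chains[[c]]
    fit <- structure(list(
      draws = draws, par_names = par_names, family = "ald", theta = theta[ti],
      data = list(y = y, x = x, site = site), mcmc = mcmc,
      diagnostics = .fit_diagnostics(draws, par_names[1:4])),
      class = "posterior_fit")
    .maybe_fail(fit, strict)
  })
  names(out) <- paste0("theta_", theta)
  out
}

#' Extract stacked posterior draws of one parameter
#'
#' @param fit a `posterior_fit`.
#' @param par parameter name (e.g. `"beta"`).
#' @return numeric vector of all post-warmup draws, chains stacked.
#' @export
fit_draws <- function(fit, par) {
  as.numeric(fit$draws[, , par])
}

#' @export
print.posterior_fit <- function(x, ...) {
  b <- fit_draws(x, "beta")
  cat(sprintf("posterior_fit (%s%s): %d draws x %d chains\n", x$family,
              if (!is.na(x$theta)) sprintf(", theta=%g", x$theta) else "",
              dim(x$draws)[1], dim(x$draws)[2]))
  cat(sprintf("  beta: median %.4f [%.4f, %.4f]\n", stats::median(b),
              stats::quantile(b, 0.025), stats::quantile(b, 0.975)))
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

## --- convergence diagnostics ------------------------------------------------
## Split-Rhat (Gelman-Rubin on half-chains) and rank-normalized bulk-ESS.
.split_chains <- function(mat) {
  n <- nrow(mat)
  h <- floor(n / 2)
  cbind(mat[seq_len(h), , drop = FALSE],
        mat[seq.int(n - h + 1, n), , drop = FALSE])
}

.rhat <- function(mat) {   # mat: iterations x chains
  mat <- .split_chains(mat)
  n <- nrow(mat); m <- ncol(mat)
  mu <- colMeans(mat)
  B <- n * stats::var(mu)
  W <- mean(apply(mat, 2, stats::var))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.rank_normalize <- function(mat) {
  r <- rank(as.numeric(mat), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(mat), ncol(mat))
}

.ess_bulk <- function(mat) {
  mat <- .rank_normalize(.split_chains(mat))
  n <- nrow(mat); m <- ncol(mat)
  if (n < 4) return(NA_real_)
  acov <- apply(mat, 2, function(ch) {
    a <- stats::acf(ch, lag.max = n - 1, plot = FALSE, type = "covariance")
    as.numeric(a$acf)
  })
  mean_acov <- rowMeans(acov)
  W <- mean(apply(mat, 2, stats::var))
  var_plus <- W * (n - 1) / n + n * stats::var(colMeans(mat)) / n
  rho <- 1 - (W - mean_acov) / var_plus
  ## Geyer initial monotone positive sequence over lag pairs
  total <- 0
  t <- 1
  prev <- Inf
  while (t + 1 < length(rho)) {
    pair <- rho[t + 1] + rho[t + 2]
    if (pair < 0) break
    pair <- min(pair, prev)
    prev <- pair
    total <- total + pair
    t <- t + 2
  }
  m * n / (1 + 2 * total)
}

.fit_diagnostics <- function(draws, pars) {
  data.frame(
    parameter = pars,
    rhat = vapply(pars, function(p) .rhat(draws[, , p]), numeric(1)),
    ess_bulk = vapply(pars, function(p) .ess_bulk(draws[, , p]), numeric(1)),
    row.names = NULL)
}

## --- posterior summaries -----------------------------------------------------

#' Evidence ratio for a directional slope hypothesis
#'
#' `ER = P(beta > 0) / P(beta <= 0)` from the posterior draws (or the
#' reciprocal for `direction = "<"`); all draws on one side give `Inf`.
#'
#' @param fit a `posterior_fit`.
#' @param direction `">"` (default) or `"<"`.
#' @return a single number, possibly `Inf`.
#' @export
evidence_ratio <- function(fit, direction = c(">", "<")) {
  direction <- match.arg(direction)
  b <- fit_draws(fit, "beta")
  if (length(b) < 1000) stop("need >= 1000 draws", call. = FALSE)
  npos <- sum(b > 0)
  nneg <- length(b) - npos
  if (direction == ">") {
    if (nneg == 0) Inf else npos / nneg
  } else {
    if (npos == 0) Inf else nneg / npos
  }
}

#' Bayesian R-squared
#'
#' Per draw, `R2 = Var(mu) / (Var(mu) + sigma^2)`, where `mu` includes the
#' site intercepts for the conditional version and omits them for the
#' marginal one.
#'
#' @param fit a Gaussian `posterior_fit`.
#' @param conditional include site intercepts (default `TRUE`).
#' @return list with `median`, `ci` (95%), and the per-draw values.
#' @export
bayes_r2 <- function(fit, conditional = TRUE) {
  if (fit$family != "gaussian")
    stop("Bayesian R2 is defined here for Gaussian fits", call. = FALSE)
  d <- fit$data
  si <- as.integer(d$site)
  n_draw <- dim(fit$draws)[1] * dim(fit$draws)[2]
  alpha <- fit_draws(fit, "alpha")
  beta <- fit_draws(fit, "beta")
  sigma <- fit_draws(fit, "sigma")
  amat <- sapply(levels(d$site), function(l) fit_draws(fit, paste0("a[", l, "]")))
  r2 <- vapply(seq_len(n_draw), function(i) {
    mu <- alpha[i] + beta[i] * d$x
    if (conditional) mu <- mu + amat[i, si]
    v <- stats::var(mu)
    v / (v + sigma[i]^2)
  }, numeric(1))
  list(median = stats::median(r2),
       ci = stats::quantile(r2, c(0.025, 0.975), names = FALSE), draws = r2)
}

#' Posterior predictive check
#'
#' Draws `n_rep` replicated response vectors from the posterior predictive
#' and compares observed and replicated summaries (tail probabilities
#' `P(T_rep >= T_obs)`) for the mean, the standard deviation and the
#' skewness.  The mean and sd are largely absorbed by the fitted location
#' and scale; the skewness statistic is the sharper probe of distributional
#' misspecification for a Gaussian likelihood.
#'
#' @param fit a Gaussian `posterior_fit`.
#' @param n_rep number of replicated datasets.
#' @param seed seed for the replication draws.
#' @return list with `yrep` (n_rep x n), `p_mean`, `p_sd`, `p_skew`.
#' @export
posterior_predictive_check <- function(fit, n_rep = 200, seed = 1) {
  if (fit$family != "gaussian")
    stop("PPC implemented for Gaussian fits", call. = FALSE)
  d <- fit$data
  si <- as.integer(d$site)
  alpha <- fit_draws(fit, "alpha")
  beta <- fit_draws(fit, "beta")
  sigma <- fit_draws(fit, "sigma")
  amat <- sapply(levels(d$site), function(l) fit_draws(fit, paste0("a[", l, "]")))
  n <- length(d$y)
  idx <- with_seed(seed, sample(length(alpha), n_rep))
  yrep <- with_seed(seed + 1, t(vapply(idx, function(i) {
    mu <- alpha[i] + amat[i, si] + beta[i] * d$x
    stats::rnorm(n, mu, sigma[i])
  }, numeric(n))))
  skew <- function(v) mean((v - mean(v))^3) / stats::sd(v)^3
  list(yrep = yrep,
       p_mean = mean(rowMeans(yrep) >= mean(d$y)),
       p_sd = mean(apply(yrep, 1, stats::sd) >= stats::sd(d$y)),
       p_skew = mean(apply(yrep, 1, skew) >= skew(d$y)))
}

#' Posterior-mean predictions for new data
#'
#' Site intercepts are applied where the site was seen in training and set
#' to zero for unseen sites.
#'
#' @param fit a `posterior_fit`.
#' @param x covariate values.
#' @param site site ids.
#' @return posterior-mean predictions.
#' @export
predict_posterior_mean <- function(fit, x, site) {
  alpha <- mean(fit_draws(fit, "alpha"))
  beta <- mean(fit_draws(fit, "beta"))
  a <- vapply(levels(fit$data$site),
              function(l) mean(fit_draws(fit, paste0("a[", l, "]"))), numeric(1))
  aa <- ifelse(as.character(site) %in% names(a), a[as.character(site)], 0)
  as.numeric(alpha + aa + beta * x)
}

#' Prediction scores: rho, smape, rmsle, predictive deviation
#'
#' `smape = mean(2 |yhat - y| / (|y| + |yhat|))`,
#' `rmsle = sqrt(mean((log1p(yhat) - log1p(y))^2))` (skipped with a warning
#' when either vector has negative values), and predictive deviation is
#' `|yhat - y| / max(y)` (its mean is reported).
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return list with `rho`, `smape`, `rmsle`, `deviation` (vector),
#'   `mean_deviation`.
#' @export
prediction_scores <- function(y, yhat) {
  rho <- if (stats::sd(yhat) == 0 || stats::sd(y) == 0) {
    warning("constant predictions or observations; rho undefined")
    NA_real_
  } else stats::cor(y, yhat)
  denom <- abs(y) + abs(yhat)
  sm <- mean(ifelse(denom == 0, 0, 2 * abs(yhat - y) / denom))
  rmsle <- if (any(y < 0) || any(yhat < 0)) {
    warning("negative values; rmsle skipped")
    NA_real_
  } else sqrt(mean((log1p(yhat) - log1p(y))^2))
  dev <- abs(yhat - y) / max(y)
  list(rho = rho, smape = sm, rmsle = rmsle, deviation = dev,
       mean_deviation = mean(dev))
}

#' Train/test predictive assessment of a metric pair
#'
#' Random 50/50 split (seeded), BMLM fit on the training half, posterior-
#' mean prediction on the held-out half, scored with
#' [prediction_scores()].
#'
#' @param y,x,site as in [fit_bmlm()] (n >= 40).
#' @param split training fraction.
#' @param seed split seed.
#' @param mcmc an [mcmc_config()].
#' @return scores list plus `split_seed` and the fitted model.
#' @export
train_test_predict <- function(y, x, site, split = 0.5, seed = 1,
                               mcmc = mcmc_config()) {
  n <- length(y)
  if (n < 40) stop("need n >= 40", call. = FALSE)
  idx <- with_seed(child_seed(seed, "split"), sample(n, floor(n * split)))
  train <- sort(idx)
  test <- setdiff(seq_len(n), train)
  fit <- fit_bmlm(y[train], x[train], droplevels(factor(site[train])),
                  mcmc = mcmc, strict = FALSE)
  yhat <- predict_posterior_mean(fit, x[test], site[test])
  c(prediction_scores(y[test], yhat), list(split_seed = seed, fit = fit))
}

#' Registry of analogous metric pairs
#'
#' Only mathematically analogous response/covariate pairs are modeled:
#' spectral-species metrics predict the taxonomic Hill metrics and the
#' dispersion metrics at matching q; distance-based spectral metrics predict
#' distance-based ground metrics (MTD/MPD ~ MSD, PD ~ SD, dispersion ~
#' spectral dispersion).  No pair crosses metric families.
#'
#' @return data.frame with columns `response_dimension`, `response_metric`,
#'   `response_q`, `covariate_metric`, `covariate_q`, `group`.
#' @export
model_pair_registry <- function() {
  rows <- rbind(
    data.frame(response_dimension = "taxonomic",
               response_metric = c("S", "H", "D"), response_q = c(0, 1, 2),
               covariate_metric = "SS", covariate_q = c(0, 1, 2),
               group = "spectral_species"),
    data.frame(response_dimension = "trait", response_metric = "qDTM",
               response_q = c(0, 1, 2), covariate_metric = "SS",
               covariate_q = c(0, 1, 2), group = "spectral_species"),
    data.frame(response_dimension = "phylogenetic", response_metric = "qDPM",
               response_q = c(0, 1, 2), covariate_metric = "SS",
               covariate_q = c(0, 1, 2), group = "spectral_species"),
    data.frame(response_dimension = "trait",
               response_metric = c("MTD", "MTDz", "qDTM", "qDTM", "qDTM"),
               response_q = c(NA, NA, 0, 1, 2),
               covariate_metric = c("MSD", "MSD", "qDSM", "qDSM", "qDSM"),
               covariate_q = c(NA, NA, 0, 0, 0), group = "distance"),
    data.frame(response_dimension = "phylogenetic",
               response_metric = c("MPD", "MPDz", "PD", "PDz",
                                   "qDPM", "qDPM", "qDPM"),
               response_q = c(NA, NA, NA, NA, 0, 1, 2),
               covariate_metric = c("MSD", "MSD", "SD", "SD",
                                    "qDSM", "qDSM", "qDSM"),
               covariate_q = c(NA, NA, NA, NA, 0, 0, 0), group = "distance"))
  rows
}
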