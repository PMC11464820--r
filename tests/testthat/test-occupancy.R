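test_that("naive occupancy tallies per-season detection fractions", {
  y1 <- array(1L, c(4, 3, 2))
  expect_equal(unname(naive_occupancy(detection_history(y1))$per_season),
               c(1, 1, 1))
  y0 <- array(0L, c(4, 3, 2))
  expect_equal(naive_occupancy(detection_history(y0))$average, 0)

  # 4 sites x 2 seasons hand-countable history
  y <- array(0L, c(4, 2, 3))
  y[1, 1, 2] <- 1L            # site 1 detected in season 1
  y[2, 1, ] <- c(1L, 0L, 1L)  # site 2 detected in season 1
  y[3, 2, 3] <- 1L            # site 3 detected in season 2
  y[4, , ] <- NA              # site 4 never sampled
  h <- detection_history(y)
  nv <- naive_occupancy(h)
  expect_equal(unname(nv$per_season), c(2 / 3, 1 / 3))
  expect_equal(nv$average, mean(c(2 / 3, 1 / 3)))
})

test_that("long-format records build the right detection array", {
  rec <- data.frame(site = c("a", "a", "b", "b"),
                    season = c(1, 1, 1, 2),
                    week = c(1, 2, 1, 1),
                    detected = c(0, 1, 0, 1))
  h <- build_detection_history(rec)
  expect_equal(dim(h$y), c(2L, 2L, 2L))
  expect_equal(h$y[1, 1, ], c(0L, 1L))
  expect_true(is.na(h$y[1, 2, 1]))  # site a not sampled in season 2
  expect_equal(h$y[2, 2, 1], 1L)
})

test_that("covariate summaries average the in-radius cells", {
  # radial gradient: value = distance from a corner
  v <- outer(1:20, 1:20, function(i, j) sqrt(i^2 + j^2))
  idx <- mk_num_raster(v)
  sites <- data.frame(site = "s1", x = 300, y = 300)
  sc <- summarize_covariate(idx, sites, radius = 100, standardize = FALSE)
  # brute-force enumeration of cells with centers within 100 m
  xs <- (1:20 - 0.5) * 30
  ys <- 20 * 30 - (1:20 - 0.5) * 30
  m <- outer(ys, xs, function(yy, xx) (xx - 300)^2 + (yy - 300)^2 <= 100^2)
  expect_equal(sc$raw_mean, mean(v[m]))

  # a radius smaller than a cell, containing only the site's own cell center
  at_center <- data.frame(site = "c", x = xs[10], y = ys[10])
  sc1 <- summarize_covariate(idx, at_center, radius = 10,
                             standardize = FALSE)
  expect_equal(sc1$raw_mean, v[10, 10])

  expect_error(summarize_covariate(idx, data.frame(site = "far", x = 1e6,
                                                   y = 1e6), 100),
               "no raster cells")
  const <- mk_num_raster(matrix(2, 20, 20))
  expect_error(summarize_covariate(const, data.frame(site = 1:2,
                                                     x = c(100, 400),
                                                     y = c(100, 400))),
               "zero variance")
})

test_that("the forward likelihood equals exhaustive latent enumeration", {
  set.seed(12)
  for (rep in 1:12) {
    sim <- simulate_detections(occ_sim_recipe(seed = rep, n_sites = 3,
                                              n_seasons = 2,
                                              weeks_per_season = 2))
    pars <- rnorm(4)
    ll <- loglik_autologistic(sim$history, sim$cov, beta = pars[1:2],
                              theta = pars[3], alpha = pars[4])
    oracle <- enum_loglik(sim$history, sim$cov$x, pars[1:2], pars[3], pars[4])
    expect_equal(ll, oracle, tolerance = 1e-10)
    expect_lte(ll, 0)
  }
})

test_that("theta = 0 reduces to independent single-season products", {
  set.seed(21)
  sim <- simulate_detections(occ_sim_recipe(seed = 2, n_sites = 20,
                                            n_seasons = 3,
                                            weeks_per_season = 4))
  pars <- c(-0.3, 0.6, 0, 0.4)
  ll <- loglik_autologistic(sim$history, sim$cov, beta = pars[1:2],
                            theta = 0, alpha = pars[4])
  # independent seasons: sum of single-season marginal likelihoods
  single <- 0
  p <- 1 / (1 + exp(-pars[4]))
  for (t in 1:3) {
    d <- apply(sim$history$y[, t, , drop = FALSE], 1,
               function(v) sum(v == 1, na.rm = TRUE))
    J <- apply(sim$history$y[, t, , drop = FALSE], 1,
               function(v) sum(!is.na(v)))
    psi <- 1 / (1 + exp(-(pars[1] + pars[2] * sim$cov$x)))
    lik <- psi * p^d * (1 - p)^(J - d) + (1 - psi) * (d == 0)
    single <- single + sum(log(lik))
  }
  expect_equal(ll, single, tolerance = 1e-10)
})

test_that("site likelihoods sum to one over all possible histories", {
  # 1 site, 2 seasons x 1 week: four possible detection histories
  x <- site_covariates(0.7, standardize = FALSE)
  total <- 0
  for (y1 in 0:1) for (y2 in 0:1) {
    y <- array(c(y1, y2), c(1, 2, 1))
    h <- detection_history(y)
    total <- total + exp(loglik_autologistic(h, x, beta = c(0.2, 0.5),
                                             theta = 0.8, alpha = -0.3))
  }
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("near-perfect detection reduces to logistic occupancy", {
  # with p -> 1, a site's history is informative only through "ever detected"
  set.seed(33)
  sim <- simulate_detections(occ_sim_recipe(seed = 3, n_sites = 50,
                                            n_seasons = 2,
                                            weeks_per_season = 3,
                                            beta = c(0.4, 0.9), theta = 0,
                                            alpha = 10))
  pars <- c(0.4, 0.9)
  ll <- loglik_autologistic(sim$history, sim$cov, beta = pars, theta = 0,
                            alpha = 10)
  psi <- 1 / (1 + exp(-(pars[1] + pars[2] * sim$cov$x)))
  occ <- apply(sim$history$y, c(1, 2), function(v) any(v == 1))
  logistic_ll <- sum(log(ifelse(occ, psi, 1 - psi)))
  expect_equal(ll, logistic_ll, tolerance = 1e-3)
})

test_that("fitting recovers simulated parameters and honors contracts", {
  sim <- simulate_detections(occ_sim_recipe(seed = 101, n_sites = 200,
                                            n_seasons = 4,
                                            weeks_per_season = 6,
                                            beta = c(-0.5, 0.8), theta = 1,
                                            alpha = 0.5))
  cov <- site_covariates(sim$cov$raw_mean, standardize = FALSE)
  fit <- fit_autologistic(sim$history, cov, "covariate")
  expect_true(fit$converged)
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$K)
  truth <- c(-0.5, 0.8, 1, 0.5)
  est <- fit$coef
  expect_true(all(abs(est - truth) <= 3 * fit$se))

  # single-season data names the identification problem
  y1 <- sim$history$y[, 1, , drop = FALSE]
  expect_error(fit_autologistic(detection_history(y1), cov, "covariate"),
               "theta is not identified")
  expect_error(fit_autologistic(sim$history, NULL, "covariate"),
               "site_covariates")
})

test_that("maximized likelihood is invariant to covariate rescaling", {
  sim <- simulate_detections(occ_sim_recipe(seed = 55, n_sites = 80,
                                            n_seasons = 3,
                                            weeks_per_season = 4))
  c1 <- site_covariates(sim$cov$raw_mean, standardize = FALSE)
  c2 <- site_covariates(10 + 4 * sim$cov$raw_mean, standardize = FALSE)
  f1 <- fit_autologistic(sim$history, c1, "covariate")
  f2 <- fit_autologistic(sim$history, c2, "covariate")
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-4)
  # slope transforms by the inverse scale
  expect_equal(f2$params$beta[2], f1$params$beta[2] / 4, tolerance = 0.02)
})

test_that("AIC competition table reproduces closed-form weights", {
  mk_fit <- function(aic, k = 3) {
    structure(list(AIC = aic, K = k, logLik = -(aic - 2 * k) / 2,
                   formula = "null"), class = "occ_fit")
  }
  one <- compare_aic(list(m = mk_fit(100)))
  expect_equal(one$dAIC, 0)
  expect_equal(one$weight, 1)

  two <- compare_aic(list(a = mk_fit(100), b = mk_fit(100)))
  expect_equal(two$weight, c(0.5, 0.5))
  expect_equal(two$cum_weight, c(0.5, 1.0))
  expect_true(all(two$competitive))

  pair <- compare_aic(list(top = mk_fit(50), worse = mk_fit(54)))
  w <- exp(-2) / (1 + exp(-2))
  expect_equal(pair$weight, c(1 - w, w), tolerance = 1e-12)
  expect_equal(pair$competitive, c(TRUE, FALSE))
})

test_that("occupancy ratios follow the stationary chain", {
  mk_fit <- function(beta, theta) {
    structure(list(params = list(beta = beta, theta = theta, alpha = 0),
                   formula = "covariate"), class = "occ_fit")
  }
  # flat covariate effect: ratio 1
  expect_equal(occupancy_ratio(mk_fit(c(0.3, 0), 1.2), -2, 2), 1)

  # theta = 0: closed-form logistic ratio
  f0 <- mk_fit(c(-0.5, 0.8), 0)
  inv <- function(x) 1 / (1 + exp(-x))
  expect_equal(occupancy_ratio(f0, -1, 2),
               inv(-0.5 + 0.8 * 2) / inv(-0.5 - 0.8))

  # long-run simulation oracle for theta != 0
  set.seed(61)
  f <- mk_fit(c(-0.4, 0.7), 1.1)
  for (xv in c(-1, 0.5, 1.5)) {
    eta <- -0.4 + 0.7 * xv
    z <- 0L
    hits <- 0
    n <- 60000
    for (t in 1:n) {
      z <- rbinom(1, 1, inv(eta + 1.1 * z))
      hits <- hits + z
    }
    expect_equal(stationary_occupancy(c(-0.4, 0.7), 1.1, xv), hits / n,
                 tolerance = 0.02)
  }
  nul <- structure(list(params = list(beta = 0, theta = 0, alpha = 0),
                        formula = "null"), class = "occ_fit")
  expect_error(occupancy_ratio(nul, 0, 1), "covariate")
})
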