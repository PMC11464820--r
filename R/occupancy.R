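#' Detection histories
#'
#' A site x season x week binary array of weekly detections; `NA` marks weeks
#' not sampled (seasons have unequal effort in real camera-trap data). Every
#' included site-season either has at least one observed week or is entirely
#' `NA` (site not sampled that season).
#'
#' @param y 3-D array `[site, season, week]` in `{0, 1, NA}`.
#' @param sites optional data.frame with columns `site`, `x`, `y`
#'   (coordinates).
#' @param seasons optional ordered season labels.
#' @return An object of class `detection_history`.
#' @export
detection_history <- function(y, sites = NULL, seasons = NULL) {
  if (length(dim(y)) != 3) um_stop("y must be a site x season x week array")
  if (!all(y %in% c(0L, 1L, NA))) um_stop("y must contain only 0, 1, NA")
  structure(list(y = y, sites = sites,
                 seasons = seasons %||% seq_len(dim(y)[2])),
            class = "detection_history")
}

#' @export
print.detection_history <- function(x, ...) {
  d <- dim(x$y)
  cat("<detection_history> ", d[1], " sites x ", d[2], " seasons x ",
      d[3], " weeks (", sum(!is.na(x$y)), " sampled weeks, ",
      sum(x$y, na.rm = TRUE), " detections)\n", sep = "")
  invisible(x)
}

#' Build a detection history from long-format records
#'
#' @param records data.frame with columns `site`, `season`, `week`,
#'   `detected` (0/1); weeks absent from the records are treated as not
#'   sampled.
#' @param sites optional site data.frame (`site`, `x`, `y`).
#' @return A [detection_history()].
#' @export
build_detection_history <- function(records, sites = NULL) {
  need <- c("site", "season", "week", "detected")
  if (!all(need %in% names(records))) {
    um_stop("records needs columns: ", paste(need, collapse = ", "))
  }
  site_ids <- sort(unique(records$site))
  season_ids <- sort(unique(records$season))
  weeks <- sort(unique(records$week))
  y <- array(NA_integer_, c(length(site_ids), length(season_ids),
                            max(weeks)))
  i <- match(records$site, site_ids)
  j <- match(records$season, season_ids)
  y[cbind(i, j, records$week)] <- as.integer(records$detected)
  if (!is.null(sites)) sites <- sites[match(site_ids, sites$site), ]
  detection_history(y, sites = sites, seasons = season_ids)
}

#' Naive occupancy by season
#'
#' The proportion of sampled sites with at least one detection in each
#' season, and the average across seasons — uncorrected for imperfect
#' detection. Seasons with zero sampled sites are excluded from the average
#' with a warning.
#'
#' @param h a [detection_history()].
#' @return List with `per_season` (named vector) and `average`.
#' @export
naive_occupancy <- function(h) {
  stopifnot(inherits(h, "detection_history"))
  T_ <- dim(h$y)[2]
  per <- rep(NA_real_, T_)
  for (t in seq_len(T_)) {
    yt <- h$y[, t, , drop = FALSE]
    sampled <- apply(!is.na(yt), 1, any)
    if (!any(sampled)) {
      um_warn("season ", t, " has no sampled sites; excluded from average")
      next
    }
    det <- apply(yt == 1, 1, any, na.rm = TRUE)
    per[t] <- sum(det & sampled) / sum(sampled)
  }
  list(per_season = stats::setNames(per, h$seasons),
       average = mean(per, na.rm = TRUE))
}

#' Summarize a covariate raster at camera sites
#'
#' Averages the raster over cells whose centers lie within `radius` of each
#' site, then centers and scales the site means (the form in which spatial
#' covariates enter the occupancy models).
#'
#' @param idx a [num_raster()] (e.g. the urbanization index).
#' @param sites data.frame with columns `site`, `x`, `y`.
#' @param radius summary radius in meters (default 1000).
#' @param standardize center and scale the site means (the default; raw
#'   means stay available either way).
#' @return An object of class `site_covariates` with `site`, `raw_mean`,
#'   `x` (standardized values), `center`, `scale`.
#' @export
summarize_covariate <- function(idx, sites, radius = 1000,
                                standardize = TRUE) {
  stopifnot(inherits(idx, "num_raster"))
  xs <- cell_center_x(idx)
  ys <- cell_center_y(idx)
  raw <- vapply(seq_len(nrow(sites)), function(i) {
    dx2 <- (xs - sites$x[i])^2
    dy2 <- (ys - sites$y[i])^2
    # in-radius mask: outer sum of squared offsets
    m <- outer(dy2, dx2, "+") <= radius^2
    if (!any(m)) {
      um_stop("site ", sites$site[i], " has no raster cells within ",
              radius, " m")
    }
    mean(idx$values[m], na.rm = TRUE)
  }, 0)
  site_covariates(raw, standardize = standardize, site = sites$site)
}

#' Bundle already-computed covariate values for model fitting
#'
#' @param x numeric site covariate values.
#' @param standardize center and scale across sites first.
#' @param site optional site ids.
#' @return A `site_covariates` object.
#' @export
site_covariates <- function(x, standardize = TRUE, site = seq_along(x)) {
  raw <- as.numeric(x)
  if (standardize) {
    s <- stats::sd(raw)
    if (!is.finite(s) || s == 0) {
      um_stop("covariate has zero variance across sites; ",
              "standardization is undefined")
    }
    val <- (raw - mean(raw)) / s
  } else {
    val <- raw
  }
  structure(list(site = site, raw_mean = raw, x = val,
                 center = if (standardize) mean(raw) else 0,
                 scale = if (standardize) stats::sd(raw) else 1,
                 standardized = standardize),
            class = "site_covariates")
}

# per-site-season sufficient statistics: detections d and sampled weeks J
detection_stats <- function(h) {
  y <- h$y
  d <- apply(y, c(1, 2), function(v) sum(v == 1, na.rm = TRUE))
  J <- apply(y, c(1, 2), function(v) sum(!is.na(v)))
  list(d = d, J = J)
}

# design matrix: intercept only (null) or intercept + covariate
occ_design <- function(n, cov, formula) {
  if (formula == "null") matrix(1, n, 1)
  else cbind(1, cov$x)
}

#' Autologistic multi-season occupancy log-likelihood
#'
#' The model: first-season occupancy probability
#' `psi_1 = invlogit(x' beta)`; later seasons gain a first-order autologistic
#' term for the latent occupancy state of the previous season,
#' `psi_t = invlogit(x' beta + theta * z_{t-1})`; weekly detections are
#' Bernoulli(`p * z_t`) with `p = invlogit(alpha)` and unsampled weeks
#' skipped. The latent states are marginalized exactly by the forward
#' algorithm over `z_t` in `{0, 1}`, per site, and site log-likelihoods are
#' summed.
#'
#' @param h a [detection_history()].
#' @param cov a `site_covariates` object (ignored for the null design).
#' @param beta occupancy coefficients (intercept first).
#' @param theta autologistic carry-over on the logit scale.
#' @param alpha detection intercept (logit of weekly detection probability).
#' @param formula `"covariate"` or `"null"`.
#' @return The log-likelihood (scalar).
#' @export
loglik_autologistic <- function(h, cov, beta, theta, alpha,
                                formula = c("covariate", "null")) {
  formula <- match.arg(formula)
  if (any(!is.finite(c(beta, theta, alpha)))) {
    um_stop("parameters must be finite")
  }
  st <- detection_stats(h)
  X <- occ_design(dim(h$y)[1], cov, formula)
  if (ncol(X) != length(beta)) {
    um_stop("beta has length ", length(beta), " but the design has ",
            ncol(X), " columns")
  }
  ll_autologistic_core(st$d, st$J, X, beta, theta, alpha)
}

# forward algorithm, vectorized over sites; d, J are site x season matrices
ll_autologistic_core <- function(d, J, X, beta, theta, alpha) {
  n <- nrow(d); T_ <- ncol(d)
  p <- invlogit(alpha)
  eta <- as.vector(X %*% beta)
  psi0 <- invlogit(eta)          # colonization-from-empty / initial
  psi1 <- invlogit(eta + theta)  # persistence given occupied
  # emission: probability of the observed weekly record given z
  e_z1 <- p^d * (1 - p)^(J - d)
  e_z0 <- ifelse(d > 0, 0, 1)
  a0 <- (1 - psi0) * e_z0[, 1]
  a1 <- psi0 * e_z1[, 1]
  logscale <- numeric(n)
  if (T_ > 1) {
    for (t in 2:T_) {
      tot <- a0 + a1
      bad <- tot <= 0
      if (any(bad)) return(-Inf)
      logscale <- logscale + log(tot)
      a0s <- a0 / tot; a1s <- a1 / tot
      new_a1 <- (a0s * psi0 + a1s * psi1) * e_z1[, t]
      new_a0 <- (a0s * (1 - psi0) + a1s * (1 - psi1)) * e_z0[, t]
      a0 <- new_a0; a1 <- new_a1
    }
  }
  tot <- a0 + a1
  if (any(tot <= 0)) return(-Inf)
  sum(log(tot) + logscale)
}

#' Fit an autologistic occupancy model by maximum likelihood
#'
#' Maximizes [loglik_autologistic()] with quasi-Newton (BFGS) optimization
#' from multiple documented starting points (all-zero, then seeded uniform
#' perturbations in `[-1, 1]`), keeping the best finite optimum. Standard
#' errors come from the inverse observed information (numerical Hessian at
#' the optimum). Needs at least two seasons, otherwise the autologistic term
#' is not identified.
#'
#' @inheritParams loglik_autologistic
#' @param n_starts number of optimizer starts (>= 1, default 5).
#' @param seed seed for the perturbed starts.
#' @return An object of class `occ_fit`: `params` (`beta`, `theta`, `alpha`),
#'   `logLik`, `K`, `AIC`, `vcov`, `se`, `converged`, `formula`.
#' @export
fit_autologistic <- function(h, cov = NULL,
                             formula = c("covariate", "null"),
                             n_starts = 5, seed = 1L) {
  formula <- match.arg(formula)
  stopifnot(inherits(h, "detection_history"))
  if (dim(h$y)[2] < 2) {
    um_stop("at least 2 seasons are required: with a single season the ",
            "autologistic term theta is not identified")
  }
  if (formula == "covariate" && is.null(cov)) {
    um_stop("the covariate model needs a site_covariates object")
  }
  st <- detection_stats(h)
  X <- occ_design(dim(h$y)[1], cov, formula)
  npar <- ncol(X) + 2L  # beta..., theta, alpha
  negll <- function(par) {
    ll <- ll_autologistic_core(st$d, st$J, X,
                               beta = par[seq_len(ncol(X))],
                               theta = par[ncol(X) + 1L],
                               alpha = par[ncol(X) + 2L])
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  set.seed(seed)
  starts <- list(rep(0, npar))
  if (n_starts > 1) {
    for (s in seq_len(n_starts - 1)) {
      starts[[s + 1]] <- stats::runif(npar, -1, 1)
    }
  }
  best <- NULL
  for (p0 in starts) {
    opt <- tryCatch(
      stats::optim(p0, negll, method = "BFGS",
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) um_stop("all optimizer starts failed")
  hess <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
  vcov <- tryCatch(solve(hess), error = function(e) NULL)
  se <- if (!is.null(vcov) && all(diag(vcov) > 0)) sqrt(diag(vcov))
        else rep(NA_real_, npar)
  converged <- best$convergence == 0 && !is.null(vcov) &&
    all(is.finite(se))
  ll <- -best$value
  par_names <- c(paste0("beta", seq_len(ncol(X)) - 1L), "theta", "alpha")
  params <- stats::setNames(best$par, par_names)
  structure(list(
    params = list(beta = unname(params[seq_len(ncol(X))]),
                  theta = unname(params[ncol(X) + 1L]),
                  alpha = unname(params[ncol(X) + 2L])),
    coef = params, logLik = ll, K = npar, AIC = -2 * ll + 2 * npar,
    vcov = vcov, se = stats::setNames(se, par_names),
    converged = converged, formula = formula
  ), class = "occ_fit")
}

#' @export
print.occ_fit <- function(x, ...) {
  cat("<occ_fit> ", x$formula, " model: logLik ", round(x$logLik, 3),
      ", K ", x$K, ", AIC ", round(x$AIC, 3),
      if (!x$converged) " [NOT converged]", "\n", sep = "")
  est <- cbind(estimate = x$coef, se = x$se)
  print(round(est, 4))
  invisible(x)
}

#' AIC model competition table
#'
#' Ranks fits by AIC and reports `dAIC`, Akaike weights and the cumulative
#' weight down the ranking; fits within 2 dAIC of the top model are flagged
#' competitive.
#'
#' @param fits named list of `occ_fit` objects.
#' @return data.frame with columns `model`, `K`, `logLik`, `AIC`, `dAIC`,
#'   `weight`, `cum_weight`, `competitive`.
#' @export
compare_aic <- function(fits) {
  if (!length(fits)) um_stop("no fits to compare")
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  aic <- vapply(fits, function(f) f$AIC, 0)
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w <- w / sum(w)
  ord <- order(aic)
  data.frame(
    model = names(fits)[ord],
    K = as.integer(vapply(fits, function(f) as.numeric(f$K), 0))[ord],
    logLik = vapply(fits, function(f) f$logLik, 0)[ord],
    AIC = aic[ord],
    dAIC = d[ord],
    weight = w[ord],
    cum_weight = cumsum(w[ord]),
    competitive = d[ord] <= 2,
    row.names = NULL
  )
}

#' Stationary occupancy of the autologistic chain
#'
#' The long-run occupancy probability of the two-state Markov chain with
#' `P(z_t = 1 | z_{t-1} = 0) = invlogit(x' beta)` and
#' `P(z_t = 1 | z_{t-1} = 1) = invlogit(x' beta + theta)`:
#' `pi = psi0 / (psi0 + 1 - psi1)`. Reduces to `invlogit(x' beta)` at
#' `theta = 0`.
#'
#' @param beta occupancy coefficients (intercept first).
#' @param theta autologistic term.
#' @param x covariate value(s) (standardized scale); recycled against beta's
#'   non-intercept terms.
#' @return Stationary occupancy probability (vectorized over `x`).
#' @export
stationary_occupancy <- function(beta, theta, x = 0) {
  eta <- beta[1] + if (length(beta) > 1) beta[2] * x else 0
  psi0 <- invlogit(eta)
  psi1 <- invlogit(eta + theta)
  psi0 / (psi0 + 1 - psi1)
}

#' Occupancy ratio between two covariate values
#'
#' Expected (stationary) occupancy at `x_high` divided by that at `x_low` —
#' the "occupancy changed by a factor of k between the least and most urban
#' sites" summary.
#'
#' @param fit a covariate-model `occ_fit`.
#' @param x_low,x_high covariate values on the scale the model was fit on.
#' @return The occupancy ratio (scalar).
#' @export
occupancy_ratio <- function(fit, x_low, x_high) {
  stopifnot(inherits(fit, "occ_fit"))
  if (fit$formula != "covariate") {
    um_stop("occupancy_ratio needs a covariate-model fit")
  }
  b <- fit$params$beta
  th <- fit$params$theta
  stationary_occupancy(b, th, x_high) / stationary_occupancy(b, th, x_low)
}
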