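# Maximum-likelihood fitting of DFE models to paired spectra.
#
# Likelihood: independent Poisson per folded class (Poisson random field
# style). Expected counts are
#   syn:    lambda_i = L_s * theta * r_i * a_i          (neutral shape)
#   nonsyn: mu_i     = L_n * theta * r_i * b_i(model)   (DFE shape)
# with r_1 = 1. For fixed DFE parameters the products t_i = theta * r_i
# maximize class-wise in closed form, t_i = (s_i + q_i)/(L_s a_i + L_n b_i),
# so the numerical optimization runs over the DFE parameters only; theta and
# the nuisance vector are profiled out exactly.

#' Poisson log-likelihood of paired spectra under a DFE model
#'
#' Sum over synonymous and non-synonymous folded classes of independent
#' Poisson log-likelihoods (dropping the data-only factorial term, so
#' fractional observed counts are handled as `c log(lambda) - lambda`).
#'
#' @param data A `paired_sfs`.
#' @param model A `dfe_model`.
#' @param theta_site Per-site population mutation rate.
#' @param r Nuisance multipliers per folded class (`r[1] = 1`).
#' @return Log-likelihood (numeric scalar; `-Inf` if a zero expectation
#'   meets a positive count).
#' @export
loglik <- function(data, model, theta_site, r = NULL) {
  stopifnot(inherits(data, "paired_sfs"))
  n <- data$syn$sample_size
  lam <- expected_folded_sfs(theta_site = theta_site, r = r, n = n,
                             L = data$syn$n_sites, neutral = TRUE)
  mu <- expected_folded_sfs(model, theta_site, r, n, data$nonsyn$n_sites)
  poisson_kernel(data$syn$counts, lam) +
    poisson_kernel(data$nonsyn$counts, mu)
}

poisson_kernel <- function(obs, lam) {
  if (any(lam <= 0 & obs > 0)) return(-Inf)
  ok <- obs > 0
  sum(obs[ok] * log(lam[ok])) - sum(lam)
}

# Per-family transformation between the optimizer's unconstrained scale and
# natural DFE parameters.
par_transform <- function(family) {
  switch(family,
    GammaZero = list(
      npar = 2L,
      to_model = function(p) dfe_gamma_zero(-exp(p[1]), exp(p[2])),
      from_model = function(m) c(log(-m$params[["mean_S"]]),
                                 log(m$params[["shape"]])),
      default = c(log(1000), log(0.3)),
      lower = c(log(1e-3), log(0.02)), upper = c(log(1e7), log(10)),
      sample = function() c(stats::runif(1, log(1), log(1e5)),
                            stats::runif(1, log(0.05), log(2)))),
    GammaExpo = list(
      npar = 4L,
      to_model = function(p) dfe_gamma_expo(-exp(p[1]), exp(p[2]),
                                            stats::plogis(p[3]), exp(p[4])),
      from_model = function(m) c(log(-m$params[["mean_S"]]),
                                 log(m$params[["shape"]]),
                                 stats::qlogis(min(max(m$params[["p_pos"]],
                                                       1e-6), 1 - 1e-6)),
                                 log(m$params[["mean_S_pos"]])),
      default = c(log(1000), log(0.3), stats::qlogis(0.02), log(1)),
      lower = c(log(1e-3), log(0.02), -18, log(1e-3)),
      upper = c(log(1e7), log(10), stats::qlogis(0.99), log(1e3)),
      sample = function() c(stats::runif(1, log(1), log(1e5)),
                            stats::runif(1, log(0.05), log(2)),
                            stats::runif(1, -8, 0),
                            stats::runif(1, log(0.05), log(20)))),
    ScaledBeta = list(
      npar = 2L,
      to_model = function(p) dfe_scaled_beta(exp(p[1]), exp(p[2])),
      from_model = function(m) log(unname(m$params)),
      default = c(log(2), log(1)),
      lower = c(log(0.02), log(0.02)), upper = c(log(200), log(200)),
      sample = function() stats::runif(2, log(0.1), log(20))),
    stop("unknown family: ", family))
}

#' Fitting options
#'
#' @param n_starts Number of optimizer starts (1 default + seeded random).
#' @param seed Seed controlling the random restarts (full determinism).
#' @param maxit Maximum Nelder-Mead iterations per start.
#' @param reltol Convergence tolerance on the log-likelihood.
#' @param start Optional `dfe_model` used as an extra warm start.
#' @return List of options for [fit_model()].
#' @export
fit_opts <- function(n_starts = 10L, seed = 1L, maxit = 500L,
                     reltol = 1e-10, start = NULL) {
  list(n_starts = n_starts, seed = seed, maxit = maxit, reltol = reltol,
       start = start)
}

#' Fit a DFE model to paired spectra by maximum likelihood
#'
#' Maximizes the Poisson likelihood over the DFE parameters with `theta` and
#' the per-class nuisance multipliers `r_i` (shared between the synonymous
#' and non-synonymous spectra, `r_1 = 1`) profiled out in closed form.
#' Optimization uses Nelder-Mead with box clamping and seeded multistarts,
#' deterministic for a given seed.
#'
#' @param data A `paired_sfs`.
#' @param family `"GammaZero"`, `"GammaExpo"` or `"ScaledBeta"`.
#' @param opts Options from [fit_opts()].
#' @return Object of class `fit_result`: `model`, `theta_site`, `r`, `logL`,
#'   `k` (free parameters: DFE + theta + free `r_i`), `AIC`, `family`,
#'   `converged`.
#' @export
fit_model <- function(data, family = c("GammaZero", "GammaExpo",
                                       "ScaledBeta"),
                      opts = fit_opts()) {
  family <- match.arg(family)
  stopifnot(inherits(data, "paired_sfs"))
  n <- data$syn$sample_size
  K <- n %/% 2L
  s_obs <- data$syn$counts
  q_obs <- data$nonsyn$counts
  Ls <- data$syn$n_sites
  Ln <- data$nonsyn$n_sites
  a <- neutral_folded_shape(n)
  tf <- par_transform(family)
  i <- seq_len(K)

  profiled <- function(b_fold) {
    den <- Ls * a + Ln * b_fold
    t_i <- (s_obs + q_obs) / den
    lam <- Ls * t_i * a
    mu <- Ln * t_i * b_fold
    list(t = t_i, ll = poisson_kernel(s_obs, lam) + poisson_kernel(q_obs, mu))
  }
  fold_shape <- function(e) (e[i] + e[n - i]) / (1 + as.numeric(i == n - i))
  objective <- function(p) {
    p <- pmin(pmax(p, tf$lower), tf$upper)
    m <- tf$to_model(p)
    b <- fold_shape(dfe_unfolded_shape(m, n))
    ll <- profiled(b)$ll
    if (!is.finite(ll)) 1e12 else -ll
  }

  starts <- list(tf$default)
  if (!is.null(opts$start)) starts <- c(starts, list(tf$from_model(opts$start)))
  extra <- max(0L, opts$n_starts - length(starts))
  if (extra > 0L) {
    rand <- with_seed(opts$seed,
                      lapply(seq_len(extra), function(k) tf$sample()))
    starts <- c(starts, rand)
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, objective, method = "Nelder-Mead",
                   control = list(maxit = opts$maxit,
                                  reltol = opts$reltol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("all optimizer starts failed for family ", family)

  p <- pmin(pmax(best$par, tf$lower), tf$upper)
  model <- tf$to_model(p)
  b <- fold_shape(dfe_unfolded_shape(model, n))
  pr <- profiled(b)
  theta <- pr$t[1L]
  r <- if (theta > 0) pr$t / theta else rep(1, K)
  k <- tf$npar + 1L + (K - 1L)
  logL <- pr$ll
  structure(list(model = model, theta_site = theta, r = r, logL = logL,
                 k = k, AIC = 2 * k - 2 * logL, family = family,
                 converged = best$convergence == 0L),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("DFE fit [%s]: logL = %.3f, AIC = %.3f, theta = %.4g%s\n",
              x$family, x$logL, x$AIC, x$theta_site,
              if (x$converged) "" else " (not converged)"))
  print(x$model)
  invisible(x)
}

#' Fit several DFE families to the same spectra
#'
#' @param data A `paired_sfs`.
#' @param families Character vector of family names.
#' @param opts Options from [fit_opts()].
#' @return Named list of `fit_result`.
#' @export
fit_dfe_models <- function(data,
                           families = c("GammaZero", "GammaExpo",
                                        "ScaledBeta"),
                           opts = fit_opts()) {
  out <- lapply(families, function(f)
    tryCatch(fit_model(data, f, opts), error = function(e) NULL))
  names(out) <- families
  failed <- vapply(out, is.null, logical(1))
  if (all(failed)) stop("all DFE model fits failed")
  if (any(failed))
    warning("fit failed for: ", paste(families[failed], collapse = ", "))
  out[!failed]
}
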