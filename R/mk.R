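# McDonald-Kreitman estimation: alpha, omega_a, omega_na from a fitted DFE
# and divergence counts, AIC model averaging, and SNP-bootstrap intervals.

#' Divergence counts
#'
#' The divergence half of an MK contrast: non-synonymous and synonymous
#' substitution counts with their site denominators, for a single species
#' branch or summed over a whole group tree.
#'
#' @param dN,dS Substitution counts (`dS > 0` required for omega).
#' @param L_nonsyn,L_syn Site counts of the divergence data.
#' @param scope `"species_branch"` or `"group_tree"`.
#' @param subset `"all"` or `"gc_conservative"`.
#' @return Object of class `divergence_counts`.
#' @export
divergence_counts <- function(dN, dS, L_nonsyn, L_syn,
                              scope = c("species_branch", "group_tree"),
                              subset = c("all", "gc_conservative")) {
  scope <- match.arg(scope)
  subset <- match.arg(subset)
  if (dN < 0 || dS < 0 || L_nonsyn <= 0 || L_syn <= 0)
    stop("invalid divergence counts")
  structure(list(dN = dN, dS = dS, L_nonsyn = L_nonsyn, L_syn = L_syn,
                 scope = scope, subset = subset),
            class = "divergence_counts")
}

#' Observed dN/dS of a divergence record
#' @param div A `divergence_counts`.
#' @return `(dN/L_nonsyn) / (dS/L_syn)`.
#' @export
omega_obs <- function(div) {
  if (div$dS <= 0) stop("dS must be positive to compute omega")
  (div$dN / div$L_nonsyn) / (div$dS / div$L_syn)
}

mk_estimate <- function(alpha, omega_a, omega_na, omega, per_model = NULL,
                        ci = NULL) {
  structure(list(alpha = alpha, omega_a = omega_a, omega_na = omega_na,
                 omega_obs = omega, per_model = per_model, ci = ci),
            class = "mk_estimate")
}

#' @export
print.mk_estimate <- function(x, ...) {
  cat(sprintf("MK estimate: alpha = %.4f, omega_a = %.4f, omega_na = %.4f (omega = %.4f)\n",
              x$alpha, x$omega_a, x$omega_na, x$omega_obs))
  if (!is.null(x$per_model)) {
    cat("per-model:\n")
    print(x$per_model, row.names = FALSE)
  }
  if (!is.null(x$ci)) {
    cat("95% bootstrap CI:\n")
    print(x$ci)
  }
  invisible(x)
}

#' Adaptive substitution rate from one fitted model
#'
#' Contrasts the observed `omega = dN/dS` with the non-adaptive expectation
#' of the fitted DFE: `alpha = 1 - omega_na_pred / omega_obs`,
#' `omega_a = alpha * omega_obs`, `omega_na = omega_na_pred`. `alpha` may be
#' negative when the predicted non-adaptive rate exceeds the observed one.
#'
#' @param fit A `fit_result`.
#' @param div A `divergence_counts` with `dS > 0`.
#' @param include_weak_positive Passed to [predicted_omega_na()].
#' @return An `mk_estimate`.
#' @export
estimate_mk <- function(fit, div, include_weak_positive = FALSE) {
  stopifnot(inherits(fit, "fit_result"), inherits(div, "divergence_counts"))
  w <- omega_obs(div)
  ona <- predicted_omega_na(fit$model, include_weak_positive)
  alpha <- 1 - ona / w
  mk_estimate(alpha, alpha * w, ona, w)
}

#' Akaike weights
#' @param aic Numeric vector of AIC values.
#' @return Weights `exp(-dAIC/2) / sum(exp(-dAIC/2))`, summing to 1.
#' @export
aic_weights <- function(aic) {
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' AIC-weighted model average of MK estimates
#'
#' Averages `alpha`, `omega_a` and `omega_na` across fitted DFE families
#' using Akaike weights:
#' `alpha = sum_m alpha_m AICw_m`, and likewise for `omega_a`, `omega_na`.
#'
#' @param fits Named list of `fit_result` (one per family).
#' @param estimates Matching list of `mk_estimate` from [estimate_mk()].
#' @return An `mk_estimate` with a `per_model` table (alpha, omega_a,
#'   omega_na, logL, AICw per family).
#' @export
model_average <- function(fits, estimates) {
  if (length(fits) == 0L) stop("no successful fits to average")
  stopifnot(length(fits) == length(estimates))
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  if (any(!is.finite(aic))) stop("non-finite AIC in model set")
  w <- aic_weights(aic)
  al <- vapply(estimates, `[[`, numeric(1), "alpha")
  oa <- vapply(estimates, `[[`, numeric(1), "omega_a")
  on <- vapply(estimates, `[[`, numeric(1), "omega_na")
  per <- data.frame(
    family = vapply(fits, `[[`, character(1), "family"),
    alpha = al, omega_a = oa, omega_na = on,
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    AICw = w, row.names = NULL)
  mk_estimate(sum(w * al), sum(w * oa), sum(w * on),
              estimates[[1L]]$omega_obs, per_model = per)
}

#' Full MK analysis of one species
#'
#' Fits the requested DFE families, derives per-model estimates and the
#' AIC-weighted average.
#'
#' @param data A `paired_sfs`.
#' @param div A `divergence_counts`.
#' @param families DFE families to fit.
#' @param opts Options from [fit_opts()].
#' @param include_weak_positive Passed to [predicted_omega_na()].
#' @return An `mk_estimate` with per-model table; the fits are attached as
#'   attribute `"fits"`.
#' @export
mk_analysis <- function(data, div,
                        families = c("GammaZero", "GammaExpo", "ScaledBeta"),
                        opts = fit_opts(), include_weak_positive = FALSE) {
  fits <- fit_dfe_models(data, families, opts)
  ests <- lapply(fits, estimate_mk, div = div,
                 include_weak_positive = include_weak_positive)
  out <- model_average(fits, ests)
  attr(out, "fits") <- fits
  out
}

#' Bootstrap confidence intervals for MK statistics
#'
#' Each replicate resamples the synonymous and non-synonymous SFS class
#' counts multinomially (SNP totals fixed) and the divergence counts dN, dS
#' Poisson-wise, then reruns the full fit-and-average pipeline. Replicate
#' fits warm-start from the point-estimate models. Percentile 2.5%/97.5%
#' bounds are returned; deterministic for a given seed.
#'
#' @param data A `paired_sfs`.
#' @param div A `divergence_counts`.
#' @param families DFE families to fit.
#' @param B Number of replicates (>= 100 recommended).
#' @param seed Integer seed.
#' @param opts Point-estimate fitting options.
#' @param boot_starts Optimizer starts per replicate fit.
#' @param include_weak_positive Passed to [predicted_omega_na()].
#' @return List: `estimate` (point `mk_estimate` with `ci` matrix),
#'   `replicates` (data frame of replicate statistics), `n_failed`,
#'   `flagged` (TRUE when > 20% of replicates failed).
#' @export
bootstrap_ci <- function(data, div,
                         families = c("GammaZero", "GammaExpo",
                                      "ScaledBeta"),
                         B = 200L, seed = 1L, opts = fit_opts(),
                         boot_starts = 2L, include_weak_positive = FALSE) {
  if (B < 1L) stop("B must be positive")
  point <- mk_analysis(data, div, families, opts, include_weak_positive)
  fits <- attr(point, "fits")
  n <- data$syn$sample_size
  resample_counts <- function(counts) {
    tot <- round(sum(counts))
    if (tot <= 0) return(counts)
    as.numeric(stats::rmultinom(1, tot, prob = counts / sum(counts)))
  }
  reps <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      d2 <- data
      d2$syn$counts <- resample_counts(data$syn$counts)
      d2$nonsyn$counts <- resample_counts(data$nonsyn$counts)
      div2 <- div
      div2$dN <- stats::rpois(1, div$dN)
      div2$dS <- stats::rpois(1, div$dS)
      if (div2$dS == 0) return(NULL)
      res <- tryCatch({
        f2 <- lapply(fits, function(f)
          fit_model(d2, f$family,
                    fit_opts(n_starts = boot_starts, seed = seed,
                             start = f$model)))
        e2 <- lapply(f2, estimate_mk, div = div2,
                     include_weak_positive = include_weak_positive)
        avg <- model_average(f2, e2)
        c(alpha = avg$alpha, omega_a = avg$omega_a, omega_na = avg$omega_na)
      }, error = function(e) NULL)
      res
    })
  })
  ok <- !vapply(reps, is.null, logical(1))
  n_failed <- sum(!ok)
  repdf <- as.data.frame(do.call(rbind, reps[ok]))
  ci <- apply(repdf, 2, stats::quantile, probs = c(0.025, 0.975),
              names = TRUE)
  point$ci <- ci
  list(estimate = point, replicates = repdf, n_failed = n_failed,
       flagged = n_failed > 0.2 * B)
}

#' Group-level pooled-SFS estimator (omega_a[P])
#'
#' Pools the species spectra with equal weights, fits the DFE families to
#' the pooled spectrum, model-averages, and contrasts with the group-tree
#' divergence.
#'
#' @param spectra List of `paired_sfs` (one per species in the group).
#' @param group_div A `divergence_counts` with `scope = "group_tree"`.
#' @param families,opts,include_weak_positive As in [mk_analysis()].
#' @return An `mk_estimate`.
#' @export
group_pooled_estimate <- function(spectra, group_div,
                                  families = c("GammaZero", "GammaExpo",
                                               "ScaledBeta"),
                                  opts = fit_opts(),
                                  include_weak_positive = FALSE) {
  stopifnot(inherits(group_div, "divergence_counts"))
  if (group_div$scope != "group_tree")
    stop("group_pooled_estimate requires group-tree divergence")
  pooled <- pool_sfs(spectra)
  mk_analysis(pooled, group_div, families, opts, include_weak_positive)
}

#' Group-level averaged estimator (omega_a[A])
#'
#' Arithmetic mean of species-level `omega_na` subtracted from the
#' group-tree `omega`: `omega_a[A] = omega_group - mean(omega_na)`. With
#' slow population-size fluctuations this buffers species-specific
#' selection/drift disequilibrium.
#'
#' @param species_mk List of `mk_estimate` (or numeric vector of species
#'   `omega_na`).
#' @param group_div A `divergence_counts` for the group tree.
#' @return Numeric scalar `omega_a[A]`.
#' @export
group_averaged_estimate <- function(species_mk, group_div) {
  if (length(species_mk) == 0L) stop("no species estimates supplied")
  ona <- if (is.numeric(species_mk)) species_mk
         else vapply(species_mk, `[[`, numeric(1), "omega_na")
  omega_obs(group_div) - mean(ona)
}
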