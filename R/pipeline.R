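# Orchestration: species-level estimates, group-level estimators and the
# comparative statistics report, with per-species failure isolation.

#' Per-species MK estimation over a set of spectra
#'
#' Runs the DFE fit and AIC-averaged MK estimation for every species
#' spectrum against its divergence record, optionally with bootstrap
#' confidence intervals. Species are processed independently: a failing
#' species is reported in the output and does not abort the run.
#'
#' @param spectra List of `paired_sfs` (any mix of subsets; each species'
#'   estimate is computed for the subset its spectrum carries).
#' @param divergence Either a named list of `divergence_counts` (names =
#'   species ids) or a data frame as returned by [read_divergence()].
#' @param families,opts,include_weak_positive Passed to [mk_analysis()].
#' @param bootstrap_B If > 0, bootstrap CIs with this many replicates.
#' @param seed Seed for the bootstrap.
#' @return Data frame with one row per species: identifiers, subset, SNP
#'   totals, `alpha`, `omega_a`, `omega_na`, `omega_obs`, per-family Akaike
#'   weights, optional CI bounds, and `status` (`"ok"` or the error
#'   message).
#' @export
run_species <- function(spectra, divergence,
                        families = c("GammaZero", "GammaExpo", "ScaledBeta"),
                        opts = fit_opts(), bootstrap_B = 0L, seed = 1L,
                        include_weak_positive = FALSE) {
  div_for <- function(id, subset) {
    if (is.data.frame(divergence)) {
      row <- divergence[divergence$id == id &
                          (is.null(divergence$subset) |
                             divergence$subset == subset), , drop = FALSE]
      if (nrow(row) == 0L) return(NULL)
      divergence_counts(row$dN[1L], row$dS[1L], row$L_nonsyn[1L],
                        row$L_syn[1L], subset = subset)
    } else divergence[[id]]
  }
  rows <- lapply(spectra, function(ps) {
    id <- ps$species_id
    subset <- ps$syn$subset
    base <- data.frame(
      species = id, group = ps$group_id, subset = subset,
      n = ps$syn$sample_size,
      snps_syn = sum(ps$syn$counts), snps_nonsyn = sum(ps$nonsyn$counts),
      pi_s = compute_pi(ps$syn), pi_n = compute_pi(ps$nonsyn),
      stringsAsFactors = FALSE)
    res <- tryCatch({
      div <- div_for(id, subset)
      if (is.null(div)) stop("no divergence record for species ", id)
      if (bootstrap_B > 0L) {
        bs <- bootstrap_ci(ps, div, families, B = bootstrap_B, seed = seed,
                           opts = opts,
                           include_weak_positive = include_weak_positive)
        est <- bs$estimate
        ci <- est$ci
        cbind(base, data.frame(
          alpha = est$alpha, omega_a = est$omega_a,
          omega_na = est$omega_na, omega_obs = est$omega_obs,
          omega_a_lo = ci["2.5%", "omega_a"],
          omega_a_hi = ci["97.5%", "omega_a"],
          status = "ok", stringsAsFactors = FALSE))
      } else {
        est <- mk_analysis(ps, div, families, opts, include_weak_positive)
        cbind(base, data.frame(
          alpha = est$alpha, omega_a = est$omega_a,
          omega_na = est$omega_na, omega_obs = est$omega_obs,
          omega_a_lo = NA_real_, omega_a_hi = NA_real_,
          status = "ok", stringsAsFactors = FALSE))
      }
    }, error = function(e) {
      cbind(base, data.frame(
        alpha = NA_real_, omega_a = NA_real_, omega_na = NA_real_,
        omega_obs = NA_real_, omega_a_lo = NA_real_, omega_a_hi = NA_real_,
        status = conditionMessage(e), stringsAsFactors = FALSE))
    })
    res
  })
  do.call(rbind, rows)
}

#' Group-level estimates from species spectra
#'
#' Computes both group estimators for each group: the pooled-SFS estimate
#' `omega_a[P]` (equal-weight pooling, then fit against the group-tree
#' divergence) and the averaged estimate `omega_a[A]` (group omega minus the
#' mean species `omega_na`).
#'
#' @param spectra List of `paired_sfs` with `group_id` set.
#' @param species_estimates Output of [run_species()] (provides the species
#'   `omega_na` entering `omega_a[A]`).
#' @param group_divergence Named list of `divergence_counts` (scope
#'   `group_tree`), one per group.
#' @param families,opts,include_weak_positive Passed to the fitting layer.
#' @return Data frame: group, subset, `omega_group`, `omega_a_pooled`,
#'   `omega_a_averaged`, `n_species`, `status`.
#' @export
run_group <- function(spectra, species_estimates, group_divergence,
                      families = c("GammaZero", "GammaExpo", "ScaledBeta"),
                      opts = fit_opts(), include_weak_positive = FALSE) {
  groups <- unique(vapply(spectra, function(s) s$group_id, character(1)))
  rows <- lapply(groups, function(g) {
    sub <- Filter(function(s) s$group_id == g, spectra)
    subset <- sub[[1L]]$syn$subset
    tryCatch({
      gdiv <- group_divergence[[g]]
      if (is.null(gdiv)) stop("missing group divergence for ", g)
      pooled <- group_pooled_estimate(sub, gdiv, families, opts,
                                      include_weak_positive)
      ona <- species_estimates$omega_na[
        species_estimates$group == g &
          species_estimates$status == "ok" &
          species_estimates$subset == subset]
      oaa <- if (length(ona)) group_averaged_estimate(ona, gdiv) else NA_real_
      data.frame(group = g, subset = subset,
                 omega_group = omega_obs(gdiv),
                 omega_a_pooled = pooled$omega_a,
                 omega_na_pooled = pooled$omega_na,
                 omega_a_averaged = oaa,
                 n_species = length(sub), status = "ok",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(group = g, subset = subset, omega_group = NA_real_,
                 omega_a_pooled = NA_real_, omega_na_pooled = NA_real_,
                 omega_a_averaged = NA_real_, n_species = length(sub),
                 status = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

TRAIT_COLUMNS <- c("longevity", "fecundity", "propagule_size", "adult_size",
                   "body_mass")

#' Comparative statistics report
#'
#' Reproduces the comparative layer on a species table: OLS regressions of
#' the response on `pi_s` and on log10-transformed life-history traits,
#' within-group common-slope ANCOVA on `pi_s` (raw and log10), and the
#' slope-versus-group-diversity Spearman meta-analysis. Trait tests are
#' skipped when the trait column is absent or entirely missing.
#'
#' @param table A `species_table`.
#' @param response Response column (default `"omega_a"`).
#' @return List: `regressions` (data frame), `ancova` (data frame),
#'   `slopes_meta` (from [slopes_vs_group_pi()]), `warnings` (character).
#' @export
run_comparative <- function(table, response = "omega_a") {
  warns <- character(0)
  y <- table[[response]]
  regs <- list()
  add_reg <- function(name, x, log10_x) {
    r <- tryCatch(ols_regression(x, y, log10_x = log10_x),
                  error = function(e) NULL)
    if (is.null(r)) {
      warns <<- c(warns, paste("regression skipped:", name))
      return()
    }
    regs[[length(regs) + 1L]] <<- data.frame(
      predictor = name, slope = r$slope, r2 = r$r2, p_value = r$p_value,
      n = r$n, stringsAsFactors = FALSE)
  }
  add_reg("pi_s", table$pi_s, FALSE)
  add_reg("log10_pi_s", table$pi_s, TRUE)
  for (tr in TRAIT_COLUMNS) {
    if (!tr %in% names(table) || all(!is.finite(table[[tr]]))) {
      warns <- c(warns, paste("trait absent:", tr))
      next
    }
    add_reg(paste0("log10_", tr), table[[tr]], TRUE)
  }
  anc <- lapply(c(FALSE, TRUE), function(lg) {
    a <- tryCatch(ancova(table, response, "pi_s", log10_cov = lg),
                  error = function(e) NULL)
    if (is.null(a)) {
      warns <<- c(warns, paste("ANCOVA skipped (log10 =", lg, ")"))
      return(NULL)
    }
    data.frame(covariate = if (lg) "log10_pi_s" else "pi_s",
               common_slope = a$common_slope, p_slope = a$p_slope,
               p_intercepts = a$p_intercepts,
               p_interaction = a$p_interaction, n = a$n,
               stringsAsFactors = FALSE)
  })
  meta <- tryCatch(slopes_vs_group_pi(table, response = response),
                   error = function(e) {
                     warns <<- c(warns, paste("slope meta-analysis skipped:",
                                              conditionMessage(e)))
                     NULL
                   })
  list(regressions = do.call(rbind, regs),
       ancova = do.call(rbind, anc),
       slopes_meta = meta,
       warnings = warns)
}
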