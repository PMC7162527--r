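# Comparative layer: regressions on (log-transformed) traits, Spearman
# tests, within-group common-slope ANCOVA, and the slope-vs-diversity
# meta-analysis. All model fitting goes through stats::lm / cor.test; these
# wrappers fix the contrasts, transforms and missing-data policy (listwise
# deletion per test, no multiple-testing correction — matching how such
# comparative results are conventionally reported; see the vignette).

#' Ordinary least-squares regression
#'
#' Simple OLS of `y` on `x` (optionally log10-transformed) with the
#' two-sided t-test on the slope and unadjusted r-squared.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @param log10_x Apply `log10` to `x` first (non-positive values dropped).
#' @return List: `slope`, `intercept`, `r2`, `p_value`, `n`.
#' @export
ols_regression <- function(x, y, log10_x = FALSE) {
  if (log10_x) {
    x[!is.na(x) & x <= 0] <- NA_real_
    x <- log10(x)
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = sm$r.squared,
       p_value = sm$coefficients[2L, 4L],
       n = length(x))
}

#' Spearman rank correlation test
#'
#' Rank correlation with tie-corrected ranks; the p-value is exact
#' (permutation distribution) for `n <= 9` without ties and uses the
#' t-approximation otherwise.
#'
#' @param x,y Numeric vectors; incomplete pairs dropped.
#' @return List: `rho`, `p_value`, `n`; `rho` is `NA` for a constant vector.
#' @export
spearman_test <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) stop("need >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x)))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = length(x) <= 9L && !anyDuplicated(x) &&
                      !anyDuplicated(y)))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Common-slope analysis of covariance across taxonomic groups
#'
#' Fits the additive model `response ~ covariate + group` — a set of
#' parallel regression lines, one intercept per group — and reports: the
#' common slope with its two-sided test (`p_slope`), an F-test of the group
#' intercepts against the covariate-only model (`p_intercepts`), and an
#' F-test of the covariate-by-group interaction added to the additive model
#' (`p_interaction`, i.e. whether slopes differ between groups).
#'
#' @param table A `species_table` (or data frame) with the response,
#'   covariate and a `group` column.
#' @param response,covariate Column names.
#' @param group Grouping column name.
#' @param log10_cov Apply `log10` to the covariate.
#' @return List: `common_slope`, `p_slope`, `p_intercepts`, `p_interaction`,
#'   `n`, `n_groups`.
#' @export
ancova <- function(table, response, covariate, group = "group",
                   log10_cov = FALSE) {
  df <- data.frame(y = table[[response]], x = table[[covariate]],
                   g = factor(table[[group]]))
  if (log10_cov) {
    df$x[!is.na(df$x) & df$x <= 0] <- NA_real_
    df$x <- log10(df$x)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df$g <- droplevels(df$g)
  sizes <- table(df$g)
  if (length(sizes) < 1L || any(sizes < 2L))
    stop("ANCOVA needs >= 2 observations per group; offending group(s): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  single <- length(sizes) == 1L
  fit_add <- if (single) stats::lm(y ~ x, df) else stats::lm(y ~ x + g, df)
  sm <- summary(fit_add)
  p_slope <- sm$coefficients["x", 4L]
  if (single) {
    p_int <- NA_real_
    p_ix <- NA_real_
  } else {
    fit_x <- stats::lm(y ~ x, df)
    p_int <- stats::anova(fit_x, fit_add)[2L, "Pr(>F)"]
    fit_full <- stats::lm(y ~ x * g, df)
    p_ix <- stats::anova(fit_add, fit_full)[2L, "Pr(>F)"]
  }
  list(common_slope = unname(stats::coef(fit_add)["x"]),
       p_slope = p_slope, p_intercepts = p_int, p_interaction = p_ix,
       n = nrow(df), n_groups = length(sizes))
}

#' Within-group slopes against group-level diversity
#'
#' Estimates the per-group OLS slope of the response (default `omega_a`) on
#' the covariate (default `pi_s`), then tests whether those slopes decrease
#' with group mean diversity via a Spearman correlation. Groups with fewer
#' than `min_species` complete cases get a flagged (`NA`) slope and are
#' excluded from the meta-correlation.
#'
#' @param table A `species_table`.
#' @param response,covariate Column names.
#' @param group Grouping column name.
#' @param min_species Minimum complete cases per group (default 3).
#' @return List: `slopes` (data frame with group, slope, n, group mean of
#'   the covariate), `rho`, `p_value`.
#' @export
slopes_vs_group_pi <- function(table, response = "omega_a",
                               covariate = "pi_s", group = "group",
                               min_species = 3L) {
  df <- data.frame(y = table[[response]], x = table[[covariate]],
                   g = factor(table[[group]]))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  gs <- levels(droplevels(df$g))
  if (length(gs) < 4L) stop("need >= 4 groups for the meta-correlation")
  rows <- lapply(gs, function(g) {
    sub <- df[df$g == g, , drop = FALSE]
    slope <- if (nrow(sub) >= min_species && stats::sd(sub$x) > 0)
      unname(stats::coef(stats::lm(y ~ x, sub))[2L]) else NA_real_
    data.frame(group = g, slope = slope, n = nrow(sub),
               group_pi = mean(sub$x))
  })
  slopes <- do.call(rbind, rows)
  ok <- is.finite(slopes$slope)
  if (sum(ok) < 4L)
    return(list(slopes = slopes, rho = NA_real_, p_value = NA_real_))
  st <- spearman_test(slopes$group_pi[ok], slopes$slope[ok])
  list(slopes = slopes, rho = st$rho, p_value = st$p_value)
}
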