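test_that("OLS handles exact, null and oracle cases", {
  x <- 1:20
  r <- ols_regression(x, 2 * x)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$r2, 1, tolerance = 1e-12)

  # independence: r2 near zero for a large null sample
  set.seed(31)
  rn <- ols_regression(rnorm(1000), rnorm(1000))
  expect_lt(rn$r2, 0.01)

  # normal-equations oracle agreement to 1e-10
  set.seed(32)
  x <- rnorm(40)
  y <- 1.5 * x + rnorm(40)
  got <- ols_regression(x, y)
  want <- normal_equations_ols(cbind(1, x), y)
  expect_equal(got$intercept, want$beta[1], tolerance = 1e-10)
  expect_equal(got$slope, want$beta[2], tolerance = 1e-10)
  expect_equal(got$r2, want$r2, tolerance = 1e-10)
  expect_equal(got$p_value, want$p[2], tolerance = 1e-10)

  # log10 transform drops non-positive x
  rl <- ols_regression(c(10, 100, 1000, -5), c(1, 2, 3, 9), log10_x = TRUE)
  expect_equal(rl$n, 3L)
  expect_equal(rl$slope, 1, tolerance = 1e-12)

  expect_error(ols_regression(rep(1, 5), 1:5), "zero variance")
  expect_error(ols_regression(1:2, 1:2), ">= 3")
})

test_that("Spearman test matches monotonicity and exact enumeration", {
  expect_equal(spearman_test(1:6, c(2, 3, 5, 8, 9, 20))$rho, 1)
  expect_equal(spearman_test(6:1, c(2, 3, 5, 8, 9, 20))$rho, -1)
  expect_true(is.na(spearman_test(rep(1, 5), 1:5)$rho))

  # exact p for n = 7 vs full permutation enumeration of the null
  set.seed(41)
  x <- rnorm(7)
  y <- rnorm(7)
  got <- spearman_test(x, y)
  rho_obs <- stats::cor(rank(x), rank(y))
  perms <- all_perms(7L)
  rho_null <- apply(perms, 1, function(p) stats::cor(rank(x), rank(y)[p]))
  p_exact <- mean(abs(rho_null) >= abs(rho_obs) - 1e-12)
  expect_lt(abs(got$p_value - p_exact), 0.01)
})

test_that("ANCOVA recovers parallel-line structure", {
  mk_groups <- function(slope, intercepts, noise, seed, m = 6L) {
    set.seed(seed)
    do.call(rbind, lapply(seq_along(intercepts), function(g) {
      x <- runif(m, 0, 1)
      data.frame(x = x, group = sprintf("g%d", g),
                 y = intercepts[g] + slope * x + rnorm(m, 0, noise))
    }))
  }
  ok_slope <- 0L
  ok_ix <- 0L
  for (s in 1:40) {
    df <- mk_groups(5, c(0, 1, 2, 3), 0.1, seed = s)
    a <- ancova(df, "y", "x")
    if (a$common_slope > 4.8 && a$common_slope < 5.2 &&
        a$p_slope < 1e-6) ok_slope <- ok_slope + 1L
    if (a$p_interaction > 0.05) ok_ix <- ok_ix + 1L
  }
  expect_gte(ok_slope, 36L)
  expect_gte(ok_ix, 36L)

  # identical intercepts: intercept test is null (p roughly uniform)
  ps <- vapply(1:60, function(s) {
    df <- mk_groups(2, c(1, 1, 1, 1), 0.5, seed = 100 + s)
    ancova(df, "y", "x")$p_intercepts
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lte(mean(ps < 0.05), 0.15)

  # zero-slope data: slope test is null
  ps0 <- vapply(1:60, function(s) {
    df <- mk_groups(0, c(0, 1, 2, 3), 0.5, seed = 200 + s)
    ancova(df, "y", "x")$p_slope
  }, numeric(1))
  expect_gt(stats::ks.test(ps0, "punif")$p.value, 0.01)
})

test_that("single-group ANCOVA degenerates to simple OLS", {
  set.seed(51)
  df <- data.frame(x = rnorm(12), group = "only")
  df$y <- 2 + 3 * df$x + rnorm(12, 0, 0.5)
  a <- ancova(df, "y", "x")
  o <- ols_regression(df$x, df$y)
  expect_equal(a$common_slope, o$slope, tolerance = 1e-12)
  expect_equal(a$p_slope, o$p_value, tolerance = 1e-12)
  expect_true(is.na(a$p_intercepts))
})

test_that("ANCOVA and oracle agree; unit rescaling only rescales the slope", {
  set.seed(52)
  df <- do.call(rbind, lapply(1:3, function(g)
    data.frame(x = rnorm(8), group = sprintf("g%d", g),
               y = rnorm(8) + g)))
  a <- ancova(df, "y", "x")
  X <- stats::model.matrix(~ x + factor(group), df)
  want <- normal_equations_ols(X, df$y)
  expect_equal(a$common_slope, want$beta[2], tolerance = 1e-10)
  expect_equal(a$p_slope, want$p[2], tolerance = 1e-10)

  df2 <- df
  df2$x <- df$x * 1000
  a2 <- ancova(df2, "y", "x")
  expect_equal(a2$common_slope * 1000, a$common_slope, tolerance = 1e-9)
  expect_equal(a2$p_slope, a$p_slope, tolerance = 1e-12)
  expect_equal(a2$p_interaction, a$p_interaction, tolerance = 1e-12)
})

test_that("within-group slopes correlate with group diversity as built", {
  tab <- generate_species_table(4, 6, group_pi_means = c(0.001, 0.005,
                                                         0.01, 0.02),
                                slopes = c(10, 5, 2, 1), noise_sd = 1e-4,
                                seed = 61)
  res <- slopes_vs_group_pi(tab)
  expect_equal(res$rho, -1, tolerance = 1e-12)

  # a two-species group is flagged and excluded
  tab_small <- tab[-(which(tab$group == "group01")[1:4]), ]
  res2 <- slopes_vs_group_pi(tab_small)
  expect_true(is.na(res2$slopes$slope[res2$slopes$group == "group01"]))

  # equal slopes: meta-correlation behaves as a null test
  sig <- 0L
  for (s in 1:50) {
    tabn <- generate_species_table(6, 5,
                                   group_pi_means = seq(0.002, 0.02,
                                                        length.out = 6),
                                   slopes = rep(3, 6), noise_sd = 0.01,
                                   seed = 500 + s)
    r <- slopes_vs_group_pi(tabn)
    if (!is.na(r$p_value) && r$p_value < 0.05) sig <- sig + 1L
  }
  expect_lte(sig, 5L)
})
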