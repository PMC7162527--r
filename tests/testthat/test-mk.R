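fake_fit <- function(model, aic, logl = -aic / 2) {
  structure(list(model = model, theta_site = 0.01, r = 1, logL = logl,
                 k = 3L, AIC = aic, family = model$family,
                 converged = TRUE), class = "fit_result")
}

test_that("alpha and omega_a follow the MK arithmetic", {
  div <- divergence_counts(dN = 200, dS = 1000, L_nonsyn = 1000,
                           L_syn = 1000)
  expect_equal(omega_obs(div), 0.2)

  # omega_na_pred = 0.15 -> alpha = 0.25, omega_a = 0.05
  fit <- fake_fit(dfe_discrete(c(0, -1e9), c(0.15, 0.85)), aic = 10)
  expect_equal(predicted_omega_na(fit$model), 0.15, tolerance = 1e-9)
  est <- estimate_mk(fit, div)
  expect_equal(est$alpha, 0.25, tolerance = 1e-8)
  expect_equal(est$omega_a, 0.05, tolerance = 1e-8)
  expect_equal(est$omega_a + est$omega_na, est$omega_obs, tolerance = 1e-12)

  # boundary: omega_na_pred == omega_obs -> alpha = 0
  fit0 <- fake_fit(dfe_discrete(c(0, -1e9), c(0.2, 0.8)), aic = 10)
  expect_equal(predicted_omega_na(fit0$model), 0.2, tolerance = 1e-9)
  est0 <- estimate_mk(fit0, div)
  expect_equal(est0$alpha, 0, tolerance = 1e-8)
  expect_equal(est0$omega_a, 0, tolerance = 1e-8)

  # omega_na_pred = 0.25 > omega_obs -> negative alpha allowed
  fit_neg <- fake_fit(dfe_discrete(c(0, -1e9), c(0.25, 0.75)), aic = 10)
  est_neg <- estimate_mk(fit_neg, div)
  expect_equal(est_neg$alpha, -0.25, tolerance = 1e-7)

  expect_error(estimate_mk(fit, divergence_counts(1, 0, 10, 10)))
})

test_that("Akaike weights and model averaging follow the printed formulas", {
  expect_equal(aic_weights(c(5, 5, 5)), rep(1 / 3, 3))
  # dAIC = (0, 2, 4): weights exp(-d/2) normalized
  w <- aic_weights(c(10, 12, 14))
  expect_equal(w, exp(-c(0, 1, 2)) / sum(exp(-c(0, 1, 2))),
               tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)

  div <- divergence_counts(200, 1000, 1000, 1000)
  models <- list(dfe_discrete(0, 1),
                 dfe_discrete(c(0, -1e9), c(0.5, 0.5)),
                 dfe_discrete(c(0, -1e9), c(0.25, 0.75)))
  fits <- Map(fake_fit, models, list(10, 12, 14))
  ests <- lapply(fits, estimate_mk, div = div)
  avg <- model_average(fits, ests)
  al <- vapply(ests, `[[`, numeric(1), "alpha")
  expect_equal(avg$alpha, sum(w * al), tolerance = 1e-12)
  # averaging is convex and preserves the identity
  expect_gte(avg$alpha, min(al))
  expect_lte(avg$alpha, max(al))
  expect_equal(avg$omega_a + avg$omega_na, avg$omega_obs, tolerance = 1e-9)

  # single model: identity
  one <- model_average(fits[1], ests[1])
  expect_equal(one$alpha, ests[[1]]$alpha)
})

test_that("bootstrap intervals are deterministic and honor degeneracy", {
  gen <- tiny_paired_sfs(n = 8L, seed = 5L)
  b1 <- bootstrap_ci(gen$data, gen$div, families = "GammaZero", B = 100,
                     seed = 4, opts = fit_opts(n_starts = 4),
                     boot_starts = 1L)
  b2 <- bootstrap_ci(gen$data, gen$div, families = "GammaZero", B = 100,
                     seed = 4, opts = fit_opts(n_starts = 4),
                     boot_starts = 1L)
  expect_identical(b1$estimate$ci, b2$estimate$ci)
  expect_false(b1$flagged)
  expect_true(b1$estimate$ci["2.5%", "omega_a"] <=
                b1$estimate$ci["97.5%", "omega_a"])

  # all SNPs in one class: multinomial resampling cannot move them, so the
  # SFS part of the uncertainty collapses
  d <- gen$data
  d$syn$counts <- c(500, 0, 0, 0)
  d$nonsyn$counts <- c(300, 0, 0, 0)
  div <- gen$div
  div$dN <- 1e6
  div$dS <- 3e6   # huge counts: negligible Poisson spread
  bd <- bootstrap_ci(d, div, families = "GammaZero", B = 100, seed = 1,
                     opts = fit_opts(n_starts = 4), boot_starts = 1L)
  w <- bd$estimate$ci["97.5%", "omega_na"] - bd$estimate$ci["2.5%", "omega_na"]
  expect_lt(w, 1e-6)
})

test_that("group estimators reduce correctly in degenerate designs", {
  gen <- tiny_paired_sfs(n = 8L, seed = 6L)
  gdiv <- divergence_counts(gen$div$dN, gen$div$dS, gen$div$L_nonsyn,
                            gen$div$L_syn, scope = "group_tree")
  single <- mk_analysis(gen$data, gdiv, families = "GammaZero",
                        opts = fit_opts(n_starts = 4))
  pooled <- group_pooled_estimate(list(gen$data, gen$data, gen$data), gdiv,
                                  families = "GammaZero",
                                  opts = fit_opts(n_starts = 4))
  expect_equal(pooled$omega_a, single$omega_a, tolerance = 1e-3)

  # a zero-SNP species changes nothing
  z <- gen$data
  z$syn$counts[] <- 0
  z$nonsyn$counts[] <- 0
  expect_warning(
    pooled_z <- group_pooled_estimate(list(gen$data, gen$data, gen$data, z),
                                      gdiv, families = "GammaZero",
                                      opts = fit_opts(n_starts = 4)),
    "zero SNPs")
  expect_equal(pooled_z$omega_a, pooled$omega_a, tolerance = 1e-6)

  expect_error(group_pooled_estimate(list(gen$data), gen$div),
               "group-tree")

  # averaged estimator arithmetic
  expect_equal(group_averaged_estimate(c(0.12, 0.14, 0.16),
                                       divergence_counts(200, 1000, 1000,
                                                         1000,
                                                         scope = "group_tree")),
               0.06, tolerance = 1e-12)
  expect_error(group_averaged_estimate(list(), gdiv))
})
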