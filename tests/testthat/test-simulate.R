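# Forward-simulation checks run at reduced scale (small gene panels, N of
# a few hundred at most) so the whole file stays within a few minutes.

neutral_cfg <- function(seed, n_genes = 20L, t_sample = 600L) {
  sim_config(n_genes = n_genes, gene_length = 999L, mu = 1.25e-5,
             rec = 2.5e-6, dfe_neg_mean = -1e-9, dfe_neg_shape = 0.14,
             p_pos = 0, n_ref = 100L, sample_n = 20L,
             sample_times = t_sample, burn_in = 800L, seed = seed)
}

test_that("neutral runs match diffusion expectations", {
  outs <- lapply(1:6, function(s) simulate_wf(neutral_cfg(s)))
  pis <- vapply(outs, function(o) o$timepoints[[1]]$pi_s, numeric(1))
  theta <- 4 * 100 * 1.25e-5
  # mean pi_s across replicates within 15% of 4 N mu
  expect_lt(abs(mean(pis) - theta) / theta, 0.15)

  # pooled substitution counts: neutral dN/dS in [0.9, 1.1]
  dN <- sum(vapply(outs, function(o) o$timepoints[[1]]$dN, numeric(1)))
  dS <- sum(vapply(outs, function(o) o$timepoints[[1]]$dS, numeric(1)))
  Ln <- outs[[1]]$L_nonsyn
  Ls <- outs[[1]]$L_syn
  ratio <- (dN / Ln) / (dS / Ls)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)

  # substitution log consistent with the per-timepoint divergence counts
  o <- outs[[1]]
  sub <- o$substitutions
  tp <- o$timepoints[[1]]
  expect_equal(tp$dS, sum(sub$class == 1L & sub$gen > o$burn_in &
                            sub$gen <= tp$gen))
})

test_that("strong purifying selection suppresses dN/dS and skews the SFS", {
  cfg <- sim_config(n_genes = 20L, gene_length = 999L, mu = 1.25e-5,
                    rec = 2.5e-6, dfe_neg_mean = -2000, dfe_neg_shape = 0.8,
                    p_pos = 0, n_ref = 100L, sample_n = 20L,
                    sample_times = 600L, burn_in = 800L, seed = 3)
  out <- simulate_wf(cfg)
  tp <- out$timepoints[[1]]
  ratio <- (tp$dN / out$L_nonsyn) / (tp$dS / out$L_syn)
  expect_lt(ratio, 0.2)
  # relative singleton excess in the non-synonymous spectrum
  syn_prop <- tp$pairs$syn$counts[1] / sum(tp$pairs$syn$counts)
  non_prop <- tp$pairs$nonsyn$counts[1] / sum(tp$pairs$nonsyn$counts)
  expect_gt(non_prop, syn_prop)
})

test_that("simulation output is deterministic given the seed", {
  a <- simulate_wf(neutral_cfg(9, n_genes = 5L, t_sample = 100L))
  b <- simulate_wf(neutral_cfg(9, n_genes = 5L, t_sample = 100L))
  expect_identical(a$substitutions, b$substitutions)
  expect_identical(a$timepoints[[1]]$pairs$syn$counts,
                   b$timepoints[[1]]$pairs$syn$counts)
  expect_identical(a$timepoints[[1]]$pi_s, b$timepoints[[1]]$pi_s)
})

test_that("rescaling preserves scaled parameters and round-trips", {
  cfg <- sim_config(mu = 2.2e-9, rec = 1e-8, n_ref = 1000L,
                    sample_times = c(2000L, 4000L),
                    burn_in = 10000L,
                    demography = demography_schedule(c(4000, 2000),
                                                     c(1000L, 200L)))
  small <- rescale_parameters(cfg, 100L)
  expect_equal(small$mu * small$n_ref, cfg$mu * cfg$n_ref)
  expect_equal(small$rec * small$n_ref, cfg$rec * cfg$n_ref)
  expect_equal(small$dfe_pos_mean / small$mu, cfg$dfe_pos_mean / cfg$mu)
  expect_equal(small$demography$sizes, c(100L, 20L))
  back <- rescale_parameters(small, 1000L)
  expect_equal(back$mu, cfg$mu)
  expect_equal(back$rec, cfg$rec)
  expect_equal(back$sample_times, cfg$sample_times)
  expect_equal(back$burn_in, cfg$burn_in)
  expect_equal(back$rescale_factor, 1)
  expect_error(rescale_parameters(cfg, 10L), ">= 50")
})

test_that("demography schedules cycle through their phases", {
  d <- demography_schedule(c(3, 2), c(100L, 50L))
  ns <- vapply(1:10, function(g) mkadapt:::demography_n_at(d, g), integer(1))
  expect_equal(ns, c(100L, 100L, 100L, 50L, 50L,
                     100L, 100L, 100L, 50L, 50L))
  expect_equal(mkadapt:::demography_n_at(constant_demography(80L), 999L),
               80L)
})

test_that("beneficial input raises the estimated adaptive rate", {
  base <- sim_config(n_genes = 30L, gene_length = 999L, mu = 1.25e-5,
                     rec = 2.5e-6, dfe_neg_mean = -740,
                     dfe_neg_shape = 0.14, p_pos = 0, n_ref = 100L,
                     sample_n = 20L, sample_times = seq(600L, 1400L, 200L),
                     burn_in = 800L, seed = 21)
  adap <- base
  adap$p_pos <- 0.1
  adap$dfe_pos_mean <- 0.05      # S_b = 20 at N = 100
  out0 <- simulate_wf(base)
  out1 <- simulate_wf(adap)
  mk0 <- mk_on_simulation(out0)
  mk1 <- mk_on_simulation(out1)
  expect_gte(nrow(mk1$table), 5L)
  expect_gt(mean(mk1$table$omega_a), mean(mk0$table$omega_a))
  # regression output exists once >= 3 usable points accumulate
  expect_false(is.null(mk1$regression))
})
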