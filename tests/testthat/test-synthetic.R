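test_that("generators are deterministic and record the truth", {
  m <- dfe_gamma_zero(-500, 0.2)
  a <- generate_sfs_dataset(m, 0.01, 10, 1e5, 1e5, 0.05, seed = 3)
  b <- generate_sfs_dataset(m, 0.01, 10, 1e5, 1e5, 0.05, seed = 3)
  expect_identical(a$data$syn$counts, b$data$syn$counts)
  expect_identical(a$div$dN, b$div$dN)
  expect_s3_class(a$truth, "truth_record")
  expect_equal(a$truth$omega_a, 0.05)

  g1 <- generate_genotype_matrix(rep(0.4, 50), 20, seed = 5)
  g2 <- generate_genotype_matrix(rep(0.4, 50), 20, seed = 5)
  expect_identical(g1$genotypes, g2$genotypes)

  t1 <- generate_species_table(3, 4, c(0.01, 0.02, 0.03), c(1, 2, 3),
                               seed = 8)
  t2 <- generate_species_table(3, 4, c(0.01, 0.02, 0.03), c(1, 2, 3),
                               seed = 8)
  expect_identical(t1$pi_s, t2$pi_s)
})

test_that("generated class counts match their Poisson expectations", {
  m <- dfe_gamma_zero(-500, 0.2)
  theta <- 0.01
  n <- 10L
  L <- 1e5
  r <- seq(1, 0.8, length.out = 5)
  exp_syn <- expected_folded_sfs(theta_site = theta, r = r, n = n, L = L,
                                 neutral = TRUE)
  exp_non <- expected_folded_sfs(m, theta, r, n, L)
  B <- 100L
  syn <- matrix(0, B, 5)
  non <- matrix(0, B, 5)
  for (i in seq_len(B)) {
    g <- generate_sfs_dataset(m, theta, n, L, L, 0.05,
                              r_distortion = r, seed = 1000 + i)
    syn[i, ] <- g$data$syn$counts
    non[i, ] <- g$data$nonsyn$counts
  }
  # mean of B replicates within 3 sigma/sqrt(B) Poisson bands, classwise
  expect_true(all(abs(colMeans(syn) - exp_syn) <=
                    3 * sqrt(exp_syn / B) + 1e-9))
  expect_true(all(abs(colMeans(non) - exp_non) <=
                    3 * sqrt(exp_non / B) + 1e-9))

  # neutral construction: E[dN/dS] = 1 when omega_a_true = 0
  dnds <- vapply(1:60, function(s) {
    g <- generate_sfs_dataset(dfe_discrete(0, 1), theta, n, L, L, 0,
                              seed = 2000 + s)
    omega_obs(g$div)
  }, numeric(1))
  expect_equal(mean(dnds), 1, tolerance = 0.02)
})

test_that("genotype generator matches HWE and round-trips through the SFS", {
  gt <- generate_genotype_matrix(rep(0.5, 2000), n_ind = 200, seed = 12)
  het <- mean(gt$genotypes == 1L)
  expect_equal(het, 0.5, tolerance = 0.01)

  # missingness thins called chromosomes proportionally
  gtm <- generate_genotype_matrix(rep(0.3, 500), n_ind = 50,
                                  missing_rate = 0.3, seed = 13)
  called <- mean(!is.na(gtm$genotypes)) * 2 * 50
  expect_equal(called, 0.7 * 2 * 50, tolerance = 2)

  # exact class recovery at missing_rate = 0: allele counts among 2n
  # chromosomes map to folded classes untouched by projection at m = 2n
  n_ind <- 10L
  gt0 <- generate_genotype_matrix(c(0.2, 0.5, 0.9), n_ind, seed = 14)
  counts <- colSums(gt0$genotypes)
  minor <- pmin(counts, 2L * n_ind - counts)
  keep <- counts > 0 & counts < 2 * n_ind
  ps <- build_paired_sfs(gt0, "GGGGGGGGG", m = 2L * n_ind)
  expect_equal(ps$syn$counts, tabulate(minor[keep], n_ind))

  # rare alleles produce mostly singletons
  gts <- generate_genotype_matrix(rep(1 / (2 * 50), 300), n_ind = 50,
                                  seed = 15)
  pss <- build_paired_sfs(gts, "GGG", m = 100)
  expect_gt(pss$syn$counts[1], 0.4 * sum(pss$syn$counts))
})

test_that("species tables reproduce the prescribed comparative structure", {
  # noiseless: ANCOVA recovers a common slope exactly
  tab <- generate_species_table(3, 5, c(0.01, 0.01, 0.01), rep(4, 3),
                                noise_sd = 0, seed = 16)
  a <- suppressWarnings(ancova(tab, "omega_a", "pi_s"))
  expect_equal(a$common_slope, 4, tolerance = 1e-9)

  # decreasing slopes against increasing diversity: rho = -1
  tab2 <- generate_species_table(5, 5, seq(0.002, 0.03, length.out = 5),
                                 c(20, 10, 5, 2, 1), noise_sd = 1e-5,
                                 seed = 17)
  expect_equal(slopes_vs_group_pi(tab2)$rho, -1)

  # the published design shape: 10 groups x 5 species = 50 rows
  tab3 <- generate_species_table(10, 5, rep(0.01, 10), rep(1, 10),
                                 seed = 18)
  expect_equal(nrow(tab3), 50L)
  expect_length(unique(tab3$group), 10L)
  expect_true(all(c("longevity", "fecundity", "propagule_size",
                    "adult_size", "body_mass") %in% names(tab3)))
})
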