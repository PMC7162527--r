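test_that("hypergeometric projection drops monomorphic mass and folds", {
  # one SNP at minor count 2 of 4 projected to m = 2: the drawn pair is
  # heterozygous with probability 2/3; both monomorphic outcomes (1/6 each)
  # are dropped
  s <- folded_sfs(c(0, 1), 4, 100, "synonymous")
  p <- project_sfs(s, 2)
  expect_equal(p$counts, 2 / 3)
  expect_equal(p$sample_size, 2L)

  # projection with m == c is the identity
  s <- folded_sfs(c(3, 1), 4, 100, "synonymous")
  expect_equal(project_sfs(s, 4)$counts, c(3, 1))

  # linearity: 6 SNPs all at 2 of 4
  s6 <- folded_sfs(c(0, 6), 4, 100, "synonymous")
  expect_equal(project_sfs(s6, 2)$counts, 4)

  # per-SNP projection mass over classes 0..m sums to one
  for (k in 1:3) expect_equal(sum(mkadapt:::project_one(k, 6, 4)), 1)

  expect_error(project_sfs(s, 6), "more chromosomes")
})

test_that("pooling follows the three-step equal-weight recipe", {
  A <- paired_sfs(folded_sfs(c(6, 2), 4, 100, "synonymous"),
                  folded_sfs(c(2, 0), 4, 300, "nonsynonymous"),
                  "A", "g")
  B <- paired_sfs(folded_sfs(c(15, 5), 4, 200, "synonymous"),
                  folded_sfs(c(8, 2), 4, 600, "nonsynonymous"),
                  "B", "g")
  pooled <- pool_sfs(list(A, B))
  expect_equal(pooled$syn$counts, c(22, 22 / 3))
  expect_equal(pooled$nonsyn$counts, c(28 / 3, 4 / 3))
  # total SNP mass conserved; each species contributes half of it
  expect_equal(sum(pooled$syn$counts) + sum(pooled$nonsyn$counts), 40,
               tolerance = 1e-9)
  # site counts summed
  expect_equal(pooled$syn$n_sites, 300)
  expect_equal(pooled$nonsyn$n_sites, 900)

  # single species: identity
  one <- pool_sfs(list(A))
  expect_equal(one$syn$counts, A$syn$counts)

  # K identical spectra: pooled = K x each
  many <- pool_sfs(list(A, A, A))
  expect_equal(many$syn$counts, 3 * A$syn$counts)

  # zero-SNP species excluded with a warning
  Z <- paired_sfs(folded_sfs(c(0, 0), 4, 100, "synonymous"),
                  folded_sfs(c(0, 0), 4, 300, "nonsynonymous"),
                  "Z", "g")
  expect_warning(pz <- pool_sfs(list(A, B, Z)), "zero SNPs")
  expect_equal(pz$syn$counts, pooled$syn$counts)
})

test_that("pooling projects unequal sample sizes to the shared minimum", {
  A <- paired_sfs(folded_sfs(c(6, 2), 4, 100, "synonymous"),
                  folded_sfs(c(2, 1), 4, 300, "nonsynonymous"), "A", "g")
  C <- paired_sfs(folded_sfs(c(9, 4, 2), 6, 100, "synonymous"),
                  folded_sfs(c(3, 1, 0), 6, 300, "nonsynonymous"), "C", "g")
  pooled <- pool_sfs(list(A, C))
  expect_equal(pooled$syn$sample_size, 4L)
  # mass conservation holds up to the projection loss of species C
  expect_true(sum(pooled$syn$counts) + sum(pooled$nonsyn$counts) <= 30)
})

test_that("pi matches hand cases and brute-force pairwise differences", {
  # two sequences differing at 1 of 100 sites
  expect_equal(compute_pi(folded_sfs(1, 2, 100, "synonymous")), 0.01)
  expect_equal(compute_pi(folded_sfs(c(0, 0), 4, 100, "synonymous")), 0)

  # n = 4, counts {1: 3, 2: 1}, L = 1000 vs mean pairwise difference on an
  # explicitly constructed haplotype alignment (4 haplotypes x 4 SNPs)
  haps <- rbind(c(1, 0, 0, 1),
                c(0, 1, 0, 1),
                c(0, 0, 1, 0),
                c(0, 0, 0, 0))
  pair_diffs <- utils::combn(4, 2, function(ij)
    sum(haps[ij[1], ] != haps[ij[2], ]))
  pi_bf <- mean(pair_diffs) / 1000
  sfs <- folded_sfs(c(3, 1), 4, 1000, "synonymous")
  expect_equal(compute_pi(sfs), pi_bf, tolerance = 1e-12)

  expect_error(compute_pi(folded_sfs(1, 2, 0, "synonymous")))
})

test_that("Tajima's D is zero at neutrality, negative with singleton excess", {
  n <- 10L
  neutral <- mkadapt:::neutral_folded_shape(n) * 50
  expect_equal(tajimas_d(folded_sfs(neutral, n, 1e4, "synonymous")), 0,
               tolerance = 1e-12)

  skew <- c(200, rep(1, 4))
  expect_lt(tajimas_d(folded_sfs(skew, n, 1e4, "synonymous")), 0)

  expect_true(is.na(tajimas_d(folded_sfs(rep(0, 5), n, 1e4, "synonymous"))))

  # neutral sampling oracle: frequencies iid proportional to 1/j, folded
  set.seed(5)
  dvals <- replicate(500, {
    j <- sample(1:(n - 1), 60, replace = TRUE, prob = 1 / (1:(n - 1)))
    f <- pmin(j, n - j)
    tajimas_d(folded_sfs(tabulate(f, n %/% 2L), n, 1e4, "synonymous"))
  })
  expect_lt(abs(mean(dvals)), 0.1)
})

test_that("SFS files round-trip bit-exactly", {
  ps <- tiny_paired_sfs()$data
  ps$syn$counts[2] <- ps$syn$counts[2] + 1 / 3   # fractional counts
  path <- tempfile(fileext = ".sfs")
  write_sfs(list(ps, ps), path)
  back <- read_sfs(path)
  expect_length(back, 2L)
  expect_identical(back[[1]]$syn$counts, ps$syn$counts)
  expect_identical(back[[1]]$nonsyn$n_sites, ps$nonsyn$n_sites)
  expect_identical(back[[1]]$species_id, ps$species_id)
})
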