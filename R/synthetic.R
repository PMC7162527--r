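# Synthetic-data generators: model-consistent inputs with recorded ground
# truth for every pipeline stage.

#' Generate a synthetic SFS + divergence dataset with known truth
#'
#' Inverts the estimation model: folded class counts are drawn Poisson from
#' the expected spectra under the supplied DFE (with an optional nuisance
#' distortion vector acting as the generating `r_i`), synonymous divergence
#' is Poisson with per-site rate `d_s`, and non-synonymous divergence is
#' Poisson with rate `d_s * (omega_na(model) + omega_a_true)`, so the true
#' adaptive rate is injected exactly.
#'
#' @param model A `dfe_model` generating the non-synonymous spectrum.
#' @param theta Per-site population mutation rate.
#' @param n Sample size in chromosomes.
#' @param L_s,L_n Synonymous / non-synonymous site counts.
#' @param omega_a_true True adaptive rate (>= 0).
#' @param d_s Synonymous divergence per site (default 0.1, within the range
#'   of within-group divergence the method is meant for).
#' @param r_distortion Optional nuisance vector (length `floor(n/2)`);
#'   `"mild"` (default) applies a monotone +/-20% distortion, `NULL` none.
#' @param seed Integer seed (full determinism).
#' @return List with `data` (`paired_sfs`), `div` (`divergence_counts`) and
#'   `truth` (a `truth_record` of everything used to generate).
#' @export
generate_sfs_dataset <- function(model, theta, n, L_s, L_n, omega_a_true,
                                 d_s = 0.1, r_distortion = "mild",
                                 seed = 1L) {
  if (omega_a_true < 0) stop("omega_a_true must be >= 0")
  n <- as.integer(n)
  K <- n %/% 2L
  r <- if (is.null(r_distortion)) rep(1, K)
       else if (identical(r_distortion, "mild"))
         seq(1, 0.8, length.out = K)      # monotone within-20% distortion
       else as.numeric(r_distortion)
  r <- r / r[1L]
  ona <- predicted_omega_na(model)
  exp_syn <- expected_folded_sfs(theta_site = theta, r = r, n = n, L = L_s,
                                 neutral = TRUE)
  exp_non <- expected_folded_sfs(model, theta, r, n, L_n)
  out <- with_seed(seed, {
    syn <- stats::rpois(K, exp_syn)
    non <- stats::rpois(K, exp_non)
    dS <- stats::rpois(1, L_s * d_s)
    dN <- stats::rpois(1, L_n * d_s * (ona + omega_a_true))
    list(syn = syn, non = non, dS = dS, dN = dN)
  })
  data <- paired_sfs(
    folded_sfs(out$syn, n, L_s, "synonymous"),
    folded_sfs(out$non, n, L_n, "nonsynonymous"),
    species_id = sprintf("synth_seed%d", seed))
  div <- divergence_counts(out$dN, out$dS, L_n, L_s)
  truth <- structure(list(
    model = model, theta = theta, omega_a = omega_a_true,
    omega_na = ona, r = r, d_s = d_s, seed = seed), class = "truth_record")
  list(data = data, div = div, truth = truth)
}

#' Generate a diploid genotype matrix under Hardy-Weinberg
#'
#' Genotypes are binomially sampled per site from supplied allele
#' frequencies; calls are set missing independently at `missing_rate`.
#' Codon contexts are attached so the result feeds directly into
#' [build_paired_sfs()].
#'
#' @param freqs Data frame with columns `freq` (alternate-allele frequency
#'   in (0,1)), `codon`, `pos_in_codon`, `ref`, `alt`; or a bare numeric
#'   vector of frequencies (contexts then default to a synonymous
#'   GGG -> GGA change).
#' @param n_ind Number of diploid individuals.
#' @param missing_rate Per-call missingness probability in [0, 1).
#' @param seed Integer seed.
#' @return A `genotype_table`.
#' @export
generate_genotype_matrix <- function(freqs, n_ind, missing_rate = 0,
                                     seed = 1L) {
  if (is.numeric(freqs))
    freqs <- data.frame(freq = freqs, codon = "GGG", pos_in_codon = 3L,
                        ref = "G", alt = "A")
  stopifnot(all(freqs$freq > 0 & freqs$freq < 1),
            missing_rate >= 0, missing_rate < 1)
  S <- nrow(freqs)
  g <- with_seed(seed, {
    m <- matrix(stats::rbinom(n_ind * S, 2L, rep(freqs$freq, each = n_ind)),
                nrow = n_ind)
    if (missing_rate > 0)
      m[stats::runif(n_ind * S) < missing_rate] <- NA_integer_
    m
  })
  sites <- data.frame(
    contig = "chr1", position = seq_len(S), codon = freqs$codon,
    pos_in_codon = freqs$pos_in_codon, ref = freqs$ref, alt = freqs$alt,
    stringsAsFactors = FALSE)
  genotype_table(sites, g)
}

#' Generate a multi-group species table with prescribed slope structure
#'
#' Emulates the comparative layer's input: `K` taxonomic groups of `m`
#' species each, per-species synonymous diversity drawn around the group
#' mean, and `omega_a = intercept_g + slope_g * pi_s + noise`. Life-history
#' traits are generated log-linearly in `pi_s` (more diverse species are
#' smaller, shorter-lived and more fecund), mimicking the trait correlations
#' the comparative tests target.
#'
#' @param groups Number of groups `K >= 2`.
#' @param species_per_group Species per group `m >= 3`.
#' @param group_pi_means Vector of group mean `pi_s` (length `K`).
#' @param slopes Within-group slopes of `omega_a` on `pi_s` (length `K`).
#' @param intercepts Optional group intercepts (default 0.02).
#' @param noise_sd Gaussian noise on `omega_a`.
#' @param seed Integer seed.
#' @return A `species_table` data frame with attribute `"truth"`.
#' @export
generate_species_table <- function(groups, species_per_group,
                                   group_pi_means, slopes,
                                   intercepts = NULL, noise_sd = 0.005,
                                   seed = 1L) {
  K <- as.integer(groups)
  m <- as.integer(species_per_group)
  if (K < 2L || m < 3L) stop("need >= 2 groups and >= 3 species per group")
  stopifnot(length(group_pi_means) == K, length(slopes) == K)
  if (is.null(intercepts)) intercepts <- rep(0.02, K)
  df <- with_seed(seed, {
    rows <- lapply(seq_len(K), function(g) {
      pi_s <- group_pi_means[g] *
        exp(stats::rnorm(m, 0, 0.35))
      omega_a <- intercepts[g] + slopes[g] * pi_s +
        stats::rnorm(m, 0, noise_sd)
      omega_na <- pmax(0.02, 0.25 - 8 * pi_s + stats::rnorm(m, 0, 0.02))
      data.frame(
        species = sprintf("g%d_sp%d", g, seq_len(m)),
        group = sprintf("group%02d", g),
        pi_s = pi_s, pi_n = pi_s * omega_na,
        omega_a = omega_a, omega_na = omega_na,
        alpha = omega_a / (omega_a + omega_na),
        fis = stats::rnorm(m, 0, 0.05),
        tajd = stats::rnorm(m, 0, 0.3),
        longevity = exp(2 - 120 * pi_s + stats::rnorm(m, 0, 0.3)),
        fecundity = exp(-1 + 250 * pi_s + stats::rnorm(m, 0, 0.4)),
        propagule_size = exp(1 - 150 * pi_s + stats::rnorm(m, 0, 0.3)),
        adult_size = exp(3 - 100 * pi_s + stats::rnorm(m, 0, 0.4)),
        body_mass = exp(4 - 300 * pi_s + stats::rnorm(m, 0, 0.5)),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  class(df) <- c("species_table", "data.frame")
  attr(df, "truth") <- list(group_pi_means = group_pi_means,
                            slopes = slopes, intercepts = intercepts,
                            noise_sd = noise_sd, seed = seed)
  df
}
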