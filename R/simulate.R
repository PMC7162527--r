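# Forward Wright-Fisher simulation of coding sequences under a gamma +
# exponential DFE and stepwise population-size fluctuations. Desk-scale
# replacement for large forward simulators: populations are run at reduced N
# with diffusion-invariant rescaling (4N*mu, 4N*r, 4N*s and durations in
# units of N held constant).
#
# Representation is mutation-centric: each haplotype is a sorted integer
# vector of segregating-mutation ids; a registry stores position, class
# (syn/nonsyn/stop), fitness effect and alternate base per mutation. Fitness
# is multiplicative per allele copy (factor 1 + s/2 per copy, exact
# semidominance in the multiplicative sense). Fixed mutations are swept into
# a substitution log periodically and the registry compacted.

#' Demography schedule
#'
#' A cyclic sequence of (duration, N) phases. A single phase gives a
#' constant-size population.
#'
#' @param durations Phase durations in generations (recycled cyclically).
#' @param sizes Diploid population sizes per phase (all >= 10).
#' @return Object of class `demography_schedule`.
#' @export
demography_schedule <- function(durations, sizes) {
  stopifnot(length(durations) == length(sizes), all(durations >= 1),
            all(sizes >= 10))
  structure(list(durations = as.numeric(durations),
                 sizes = as.integer(sizes)),
            class = "demography_schedule")
}

#' @rdname demography_schedule
#' @param N Constant diploid size.
#' @export
constant_demography <- function(N) demography_schedule(1, N)

#' @rdname demography_schedule
#' @param N_low,N_high Low/high diploid sizes (intensity ratios of 3 or 30
#'   mirror the fluctuation regimes the simulator is meant to probe).
#' @param period_low,period_high Phase durations in generations.
#' @export
fluctuating_demography <- function(N_low, N_high, period_low, period_high) {
  demography_schedule(c(period_high, period_low), c(N_high, N_low))
}

# N at a 1-based generation index, cycling through phases.
demography_n_at <- function(demog, gen) {
  period <- sum(demog$durations)
  t <- (gen - 1) %% period
  phase <- findInterval(t, cumsum(c(0, demog$durations)),
                        rightmost.closed = TRUE)
  demog$sizes[min(phase, length(demog$sizes))]
}

#' Forward-simulation configuration
#'
#' Defaults mirror the published control experiment: 1500 coding sequences
#' of 999 bp, mutation rate 2.2e-9 /bp/generation, recombination 1e-8 /bp,
#' deleterious DFE gamma with mean -740 and shape 0.14 in `S = 4 Ne s`
#' units, and an exponential beneficial DFE of mean 1e-4 in `s` units
#' (proportion `p_pos`, default 0 = null control). Use
#' [rescale_parameters()] to bring a configuration to desk scale.
#'
#' @param n_genes Number of coding sequences.
#' @param gene_length Gene length in bp (multiple of 3).
#' @param mu Per-bp per-generation mutation rate.
#' @param rec Per-bp recombination rate.
#' @param dfe_neg_mean,dfe_neg_shape Gamma DFE of deleterious effects; the
#'   mean is in scaled `S = 4 Ne s` units at `n_ref` (negative).
#' @param p_pos Proportion of new non-synonymous mutations that are
#'   beneficial.
#' @param dfe_pos_mean Mean beneficial effect in raw `s` units.
#' @param n_ref Reference diploid size at which `S` converts to `s`.
#' @param sample_n Individuals sampled per time point.
#' @param sample_times Sampling generations, counted after burn-in.
#' @param burn_in Burn-in generations (default `10 * max(N)` of the
#'   demography).
#' @param fix_interval Generations between fixation sweeps.
#' @param demography A `demography_schedule` (default constant `n_ref`).
#' @param seed Integer seed; simulation output is fully reproducible.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1500L, gene_length = 999L, mu = 2.2e-9,
                       rec = 1e-8, dfe_neg_mean = -740, dfe_neg_shape = 0.14,
                       p_pos = 0, dfe_pos_mean = 1e-4, n_ref = 1000L,
                       sample_n = 20L, sample_times = seq(200L, 1000L, 200L),
                       burn_in = NULL, fix_interval = 20L,
                       demography = NULL, seed = 1L) {
  if (gene_length %% 3L != 0L) stop("gene_length must be divisible by 3")
  if (mu < 0 || mu >= 1 || rec < 0 || rec >= 1)
    stop("rates must lie in [0, 1)")
  if (dfe_neg_mean >= 0) stop("dfe_neg_mean must be negative")
  if (p_pos < 0 || p_pos > 1) stop("p_pos must be in [0, 1]")
  if (is.null(demography)) demography <- constant_demography(n_ref)
  structure(list(
    n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
    mu = mu, rec = rec, dfe_neg_mean = dfe_neg_mean,
    dfe_neg_shape = dfe_neg_shape, p_pos = p_pos,
    dfe_pos_mean = dfe_pos_mean, n_ref = as.integer(n_ref),
    sample_n = as.integer(sample_n), sample_times = as.integer(sample_times),
    burn_in = if (is.null(burn_in)) NULL else as.integer(burn_in),
    fix_interval = as.integer(fix_interval), demography = demography,
    seed = as.integer(seed)), class = "sim_config")
}

#' Diffusion-invariant rescaling of a simulation configuration
#'
#' Reduces the population size while holding `4 N mu`, `4 N r`, `4 N s` and
#' phase durations in units of `N` constant, so diversity, scaled selection
#' and fixation probabilities are preserved. The rescaling factor is
#' recorded in the output metadata; rescaling back recovers the original
#' configuration.
#'
#' @param config A `sim_config`.
#' @param target_N New reference diploid size (>= 50).
#' @return The rescaled `sim_config`.
#' @export
rescale_parameters <- function(config, target_N) {
  stopifnot(inherits(config, "sim_config"))
  target_N <- as.integer(target_N)
  if (target_N < 50L) stop("target_N must be >= 50")
  f <- config$n_ref / target_N
  if (config$mu * f >= 1) stop("rescaled mutation rate would reach 1")
  out <- config
  out$mu <- config$mu * f
  out$rec <- config$rec * f
  out$dfe_pos_mean <- config$dfe_pos_mean * f   # s units; 4Ns held constant
  out$n_ref <- target_N
  out$sample_times <- as.integer(round(config$sample_times / f))
  if (!is.null(config$burn_in))
    out$burn_in <- as.integer(round(config$burn_in / f))
  d <- config$demography
  out$demography <- demography_schedule(pmax(1, round(d$durations / f)),
                                        pmax(10L, as.integer(round(d$sizes / f))))
  out$rescale_factor <- (config$rescale_factor %||% 1) * f
  out
}

# Base-code helpers for the engine (bases coded 1..4 = A,C,G,T).
ALTB_CODE <- matrix(match(t(ALT_BASES), BASES), nrow = 4L, byrow = TRUE,
                    dimnames = list(BASES, NULL))

# Random coding sequence with no stop codons, as integer base codes.
random_coding_sequence <- function(n_codons, code = "standard") {
  ok <- which(codon_aa(code) != "*")
  picks <- sample(ok, n_codons, replace = TRUE)
  ci <- picks - 1L
  as.integer(rbind(ci %/% 16L + 1L, (ci %/% 4L) %% 4L + 1L, ci %% 4L + 1L))
}

# classtab[p, j]: class (1 syn, 2 nonsyn, 3 stop) of changing position p to
# its j-th alternative base, given reference `ref` (integer codes).
build_class_table <- function(ref, code = "standard") {
  L <- length(ref)
  tab <- codon_change_table(code)
  cod <- matrix(ref, nrow = 3L)
  ci <- codon_index(cod[1L, ], cod[2L, ], cod[3L, ])
  ci_rep <- rep(ci, each = 3L)
  w_rep <- rep_len(1:3, L)
  cbind(tab[cbind(ci_rep, w_rep, 1L)],
        tab[cbind(ci_rep, w_rep, 2L)],
        tab[cbind(ci_rep, w_rep, 3L)])
}

#' Run a forward Wright-Fisher simulation
#'
#' Discrete generations, diploid panmictic population, multiplicative
#' per-allele fitness with semidominance, per-bp crossover recombination,
#' codon-level mutation classification against the (updating) reference
#' sequence: synonymous changes are neutral, non-synonymous changes draw
#' their effect from the configured DFE, stop-gaining changes are treated as
#' effectively lethal (`s = -1`) and excluded from spectra and divergence.
#' Deleterious effects are converted from `S` units at `n_ref` and truncated
#' at `s = -1`. Polymorphism and divergence are sampled for `sample_n`
#' individuals at each requested time point; divergence counts fixations
#' accumulated since the end of burn-in.
#'
#' @param config A `sim_config`.
#' @param demog A `demography_schedule` (default the one in `config`).
#' @return Object of class `sim_output`: list with `timepoints` (each with
#'   `gen`, `N`, `pairs` (`paired_sfs`), `div` (`divergence_counts`),
#'   `pi_s`), `substitutions` data frame, `L_syn`, `L_nonsyn`, `config`.
#' @export
simulate_wf <- function(config, demog = config$demography) {
  stopifnot(inherits(config, "sim_config"),
            inherits(demog, "demography_schedule"))
  with_seed(config$seed, simulate_wf_impl(config, demog))
}

simulate_wf_impl <- function(config, demog) {
  L <- config$n_genes * config$gene_length
  ref <- random_coding_sequence(L %/% 3L)
  classtab <- build_class_table(ref)
  altb <- ALTB_CODE[ref, , drop = FALSE]

  N_max <- max(demog$sizes)
  burn_in <- config$burn_in %||% (10L * N_max)
  total_gens <- burn_in + max(config$sample_times)
  sample_gens <- burn_in + config$sample_times

  U <- config$mu * L
  R <- config$rec * max(L - 1L, 0L)
  s_of_S <- function(S) S / (4 * config$n_ref)

  draw_s <- function(cls, m) {
    s <- numeric(m)
    non <- cls == CLASS_NONSYN
    if (any(non)) {
      nn <- sum(non)
      pos <- stats::runif(nn) < config$p_pos
      sv <- numeric(nn)
      if (any(pos))
        sv[pos] <- stats::rexp(sum(pos), rate = 1 / config$dfe_pos_mean)
      if (any(!pos))
        sv[!pos] <- pmax(-1, s_of_S(-stats::rgamma(
          sum(!pos), shape = config$dfe_neg_shape,
          scale = -config$dfe_neg_mean / config$dfe_neg_shape)))
      s[non] <- sv
    }
    s[cls == CLASS_STOP] <- -1
    s
  }

  # mutation registry (compacted at every fixation sweep)
  reg_pos <- integer(0)
  reg_cls <- integer(0)
  reg_alt <- integer(0)
  reg_lw <- numeric(0)

  N0 <- demography_n_at(demog, 1L)
  pop <- rep(list(integer(0)), 2L * N0)
  logw <- numeric(2L * N0)

  sub_gen <- integer(0)
  sub_cls <- integer(0)

  sweep_fixations <- function(gen) {
    twoN <- length(pop)
    nreg <- length(reg_pos)
    if (nreg == 0L) return(invisible())
    tb <- tabulate(unlist(pop, use.names = FALSE), nbins = nreg)
    fixed <- which(tb == twoN)
    if (length(fixed)) {
      sub_gen <<- c(sub_gen, rep(gen, length(fixed)))
      sub_cls <<- c(sub_cls, reg_cls[fixed])
      ref[reg_pos[fixed]] <<- reg_alt[fixed]
      altb[reg_pos[fixed], ] <<- ALTB_CODE[reg_alt[fixed], ]
      # rebuild classification rows of every affected codon in one shot
      tab <- codon_change_table()
      c0 <- unique((reg_pos[fixed] - 1L) %/% 3L)
      pp <- rep(c0 * 3L, each = 3L) + 1:3
      p1 <- c0 * 3L + 1L
      ci <- codon_index(ref[p1], ref[p1 + 1L], ref[p1 + 2L])
      ci_rep <- rep(ci, each = 3L)
      w_rep <- rep_len(1:3, length(pp))
      classtab[pp, ] <<- cbind(tab[cbind(ci_rep, w_rep, 1L)],
                               tab[cbind(ci_rep, w_rep, 2L)],
                               tab[cbind(ci_rep, w_rep, 3L)])
      logw <<- logw - sum(reg_lw[fixed])
    }
    keep <- tb > 0L
    keep[fixed] <- FALSE
    map <- integer(nreg)
    map[keep] <- seq_len(sum(keep))
    reg_pos <<- reg_pos[keep]
    reg_cls <<- reg_cls[keep]
    reg_alt <<- reg_alt[keep]
    reg_lw <<- reg_lw[keep]
    pop <<- lapply(pop, function(h) map[h[keep[h]]])
    invisible()
  }

  site_counts_from_table <- function() {
    list(L_syn = sum(classtab == CLASS_SYN) / 3,
         L_nonsyn = sum(classtab == CLASS_NONSYN) / 3)
  }

  timepoints <- list()
  anc_L <- NULL
  div_start <- NULL

  for (gen in seq_len(total_gens)) {
    N_new <- demography_n_at(demog, gen)
    twoN_new <- 2L * N_new
    n_old <- length(pop) %/% 2L

    lw_ind <- logw[seq(1L, 2L * n_old, 2L)] + logw[seq(2L, 2L * n_old, 2L)]
    W <- exp(lw_ind - max(lw_ind))     # normalized: avoids joint underflow
    parents <- sample.int(n_old, twoN_new, replace = TRUE, prob = W)
    nx <- stats::rpois(twoN_new, R)
    nm <- stats::rpois(twoN_new, U)

    # batch-draw all new mutations of this generation
    m_tot <- sum(nm)
    if (m_tot > 0L) {
      mpos <- sample.int(L, m_tot, replace = TRUE)
      aidx <- sample.int(3L, m_tot, replace = TRUE)
      mcls <- classtab[cbind(mpos, aidx)]
      malt <- altb[cbind(mpos, aidx)]
      ms <- draw_s(mcls, m_tot)
      base_id <- length(reg_pos)
      reg_pos <- c(reg_pos, mpos)
      reg_cls <- c(reg_cls, mcls)
      reg_alt <- c(reg_alt, malt)
      mlw <- log1p(ms / 2)
      reg_lw <- c(reg_lw, mlw)
      mut_of <- split(base_id + seq_len(m_tot),
                      factor(rep.int(seq_len(twoN_new), nm),
                             levels = seq_len(twoN_new)))
    }

    newpop <- vector("list", twoN_new)
    newlogw <- numeric(twoN_new)
    pos_l <- reg_pos
    lw_l <- reg_lw
    coin <- stats::runif(twoN_new)
    for (i in seq_len(twoN_new)) {
      p <- parents[i]
      i1 <- 2L * p - 1L
      k <- nx[i]
      if (k == 0L) {
        if (coin[i] < 0.5) { g <- pop[[i1]]; gl <- logw[i1] }
        else { g <- pop[[i1 + 1L]]; gl <- logw[i1 + 1L] }
      } else {
        h1 <- pop[[i1]]; h2 <- pop[[i1 + 1L]]
        bp <- sort.int(stats::runif(k)) * L
        odd1 <- findInterval(pos_l[h1], bp) %% 2L
        odd2 <- findInterval(pos_l[h2], bp) %% 2L
        if (coin[i] < 0.5) { k1 <- odd1 == 0L; k2 <- odd2 == 1L }
        else { k1 <- odd1 == 1L; k2 <- odd2 == 0L }
        g <- c(h1[k1], h2[k2])
        gl <- sum(lw_l[g])
      }
      if (nm[i] > 0L) {
        ids <- mut_of[[i]]
        g <- c(g, ids)
        gl <- gl + sum(reg_lw[ids])
      }
      newpop[[i]] <- g
      newlogw[i] <- gl
    }
    pop <- newpop
    logw <- newlogw

    at_sample <- gen %in% sample_gens
    if (gen %% config$fix_interval == 0L || at_sample || gen == burn_in)
      sweep_fixations(gen)

    if (gen == burn_in) {
      anc_L <- site_counts_from_table()
      div_start <- gen
    }

    if (at_sample) {
      N_cur <- length(pop) %/% 2L
      ids <- sample.int(N_cur, min(config$sample_n, N_cur))
      haps <- pop[c(2L * ids - 1L, 2L * ids)]
      n2 <- 2L * length(ids)
      cnt <- tabulate(unlist(haps, use.names = FALSE),
                      nbins = length(reg_pos))
      seg <- which(cnt > 0L & cnt < n2)
      minor <- pmin(cnt[seg], n2 - cnt[seg])
      cls <- reg_cls[seg]
      K <- n2 %/% 2L
      syn_c <- tabulate(minor[cls == CLASS_SYN], nbins = K)
      non_c <- tabulate(minor[cls == CLASS_NONSYN], nbins = K)
      keep_sub <- sub_gen > div_start & sub_gen <= gen
      dS <- sum(sub_cls[keep_sub] == CLASS_SYN)
      dN <- sum(sub_cls[keep_sub] == CLASS_NONSYN)
      pair <- paired_sfs(
        folded_sfs(syn_c, n2, anc_L$L_syn, "synonymous"),
        folded_sfs(non_c, n2, anc_L$L_nonsyn, "nonsynonymous"),
        species_id = sprintf("sim_gen%d", gen))
      div <- if (dS > 0)
        divergence_counts(dN, dS, anc_L$L_nonsyn, anc_L$L_syn)
      else NULL
      timepoints[[length(timepoints) + 1L]] <- list(
        gen = gen, N = N_cur, pairs = pair, div = div,
        pi_s = compute_pi(pair$syn), dN = dN, dS = dS)
    }
  }

  structure(list(timepoints = timepoints,
                 substitutions = data.frame(gen = sub_gen, class = sub_cls),
                 L_syn = anc_L$L_syn %||% site_counts_from_table()$L_syn,
                 L_nonsyn = anc_L$L_nonsyn %||%
                   site_counts_from_table()$L_nonsyn,
                 burn_in = burn_in, config = config),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("WF simulation: %d timepoints, L = %d bp, burn-in %d gens\n",
              length(x$timepoints),
              x$config$n_genes * x$config$gene_length, x$burn_in))
  invisible(x)
}

#' MK analysis of simulation output
#'
#' Runs the DFE-based MK estimation at every sampled time point and
#' regresses the estimated `omega_a` on `pi_s` across time points — the
#' diagnostic for spurious adaptive-rate signal generated by demographic
#' fluctuations alone.
#'
#' @param out A `sim_output` (or list of them, pooled as replicates).
#' @param families DFE families to fit (default GammaZero for speed).
#' @param opts Fitting options.
#' @param include_weak_positive Passed to [predicted_omega_na()].
#' @return List: `table` (data frame gen, N, pi_s, omega_a, alpha,
#'   omega_na), `regression` (OLS of omega_a on pi_s; `NULL` with < 3
#'   usable points), `n_failed`.
#' @export
mk_on_simulation <- function(out, families = "GammaZero",
                             opts = fit_opts(n_starts = 4L),
                             include_weak_positive = FALSE) {
  outs <- if (inherits(out, "sim_output")) list(out) else out
  rows <- list()
  n_failed <- 0L
  for (o in outs) {
    for (tp in o$timepoints) {
      if (is.null(tp$div)) { n_failed <- n_failed + 1L; next }
      est <- tryCatch(
        mk_analysis(tp$pairs, tp$div, families, opts,
                    include_weak_positive),
        error = function(e) NULL)
      if (is.null(est)) { n_failed <- n_failed + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        gen = tp$gen, N = tp$N, pi_s = tp$pi_s, omega_a = est$omega_a,
        omega_na = est$omega_na, alpha = est$alpha)
    }
  }
  tab <- do.call(rbind, rows)
  reg <- if (!is.null(tab) && nrow(tab) >= 3L &&
             stats::sd(tab$pi_s) > 0)
    ols_regression(tab$pi_s, tab$omega_a) else NULL
  list(table = tab, regression = reg, n_failed = n_failed)
}
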