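# Distribution-of-fitness-effects models and expected site frequency
# spectra under the Poisson random field / Wright-Fisher diffusion.

#' DFE model constructors
#'
#' Three families of distributions of fitness effects of new non-synonymous
#' mutations, parameterized in scaled selection coefficients `S = 4 Ne s`:
#'
#' * `GammaZero`: a reflected gamma on `S < 0` (mean `mean_S < 0`, shape
#'   `shape`); no beneficial mutations.
#' * `GammaExpo`: the gamma deleterious component plus, with probability
#'   `p_pos`, an exponential distribution of beneficial effects of mean
#'   `mean_S_pos > 0`.
#' * `ScaledBeta`: a Beta distribution rescaled to `S` in `[-25, 25]` with
#'   shape parameters `beta_a`, `beta_b`, covering weakly selected mutations
#'   of both signs.
#'
#' `dfe_discrete` builds a finite mixture of point masses, used as ground
#' truth in simulations and as an exactly integrable case for oracle checks.
#'
#' @param mean_S Mean of the deleterious component, negative.
#' @param shape Gamma shape parameter, positive.
#' @param p_pos Proportion of beneficial mutations in `[0, 1]`.
#' @param mean_S_pos Mean of the exponential beneficial component, positive.
#' @param beta_a,beta_b Beta shape parameters, positive.
#' @param S,w Point-mass locations and weights (`w` normalized to sum 1).
#' @return Object of class `dfe_model`.
#' @export
dfe_gamma_zero <- function(mean_S, shape) {
  if (mean_S >= 0) stop("mean_S must be negative")
  if (shape <= 0) stop("shape must be positive")
  structure(list(family = "GammaZero",
                 params = c(mean_S = mean_S, shape = shape)),
            class = "dfe_model")
}

#' @rdname dfe_gamma_zero
#' @export
dfe_gamma_expo <- function(mean_S, shape, p_pos, mean_S_pos) {
  if (mean_S >= 0) stop("mean_S must be negative")
  if (shape <= 0) stop("shape must be positive")
  if (p_pos < 0 || p_pos > 1) stop("p_pos must be in [0, 1]")
  if (mean_S_pos <= 0) stop("mean_S_pos must be positive")
  structure(list(family = "GammaExpo",
                 params = c(mean_S = mean_S, shape = shape,
                            p_pos = p_pos, mean_S_pos = mean_S_pos)),
            class = "dfe_model")
}

#' @rdname dfe_gamma_zero
#' @export
dfe_scaled_beta <- function(beta_a, beta_b) {
  if (beta_a <= 0 || beta_b <= 0) stop("beta shapes must be positive")
  structure(list(family = "ScaledBeta",
                 params = c(beta_a = beta_a, beta_b = beta_b)),
            class = "dfe_model")
}

#' @rdname dfe_gamma_zero
#' @export
dfe_discrete <- function(S, w = rep(1 / length(S), length(S))) {
  if (length(S) != length(w) || any(w < 0) || sum(w) <= 0)
    stop("invalid point-mass specification")
  structure(list(family = "Discrete",
                 params = list(S = as.numeric(S), w = w / sum(w))),
            class = "dfe_model")
}

#' @export
print.dfe_model <- function(x, ...) {
  cat("DFE model:", x$family, "\n")
  if (x$family == "Discrete") {
    print(data.frame(S = x$params$S, w = x$params$w))
  } else {
    print(x$params)
  }
  invisible(x)
}

SCALED_BETA_RANGE <- c(-25, 25)

#' Expected sojourn density of a selected allele
#'
#' Density (up to the mutational influx constant) of time a new semidominant
#' mutation of scaled effect `S = 4 Ne s` spends at population frequency `x`
#' under the Wright-Fisher diffusion:
#' `H(x; S) = (1 - exp(-S (1 - x))) / (x (1 - x) (1 - exp(-S)))`,
#' with the neutral limit `1/x` at `S = 0`. Computed via `expm1` so it is
#' stable for `|S|` up to at least 1e5.
#'
#' @param x Frequencies in (0, 1); vectorized.
#' @param S Scaled selection coefficient (scalar).
#' @return Numeric vector of densities.
#' @export
sojourn_density <- function(x, S) {
  if (any(x <= 0 | x >= 1)) stop("x must lie strictly in (0, 1)")
  stopifnot_scalar(S, "S")
  if (abs(S) < 1e-8) return(1 / x)
  # (1 - e^{-S(1-x)}) / (1 - e^{-S}) = e^{-Sx} * expm1(S(1-x)) / expm1(S)
  # written to avoid overflow for large |S| of either sign
  if (S > 0) {
    num <- -expm1(-S * (1 - x))
    den <- -expm1(-S)
    num / (x * (1 - x) * den)
  } else {
    T <- -S
    exp(-T * x) * (-expm1(-T * (1 - x))) / (x * (1 - x) * (-expm1(-T)))
  }
}

#' Relative fixation rate of a selected mutation
#'
#' `S / (1 - exp(-S))`: the fixation probability of a semidominant mutation
#' of scaled effect `S` relative to a neutral one. Equals 1 at `S = 0`.
#'
#' @param S Scaled selection coefficients; vectorized.
#' @return Numeric vector.
#' @export
fixation_ratio <- function(S) {
  out <- S / (-expm1(-S))
  out[S == 0] <- 1
  out[is.nan(out)] <- 1          # tiny |S| underflow
  out
}

# Expected unfolded binomial-sampled spectrum entry:
# B(j; n, S) = int_0^1 H(x; S) C(n,j) x^j (1-x)^(n-j) dx, j = 1..n-1.
# Gauss-Legendre quadrature with an interval split adapted to the boundary
# layer of strongly deleterious alleles (H concentrates below x ~ 1/|S|).
binom_sojourn <- function(n, S, nodes = 64L) {
  if (abs(S) < 1e-8) return(1 / seq_len(n - 1L))
  split <- if (S < 0) min(0.5, max(40 / abs(S), 1e-4)) else 0.5
  g1 <- pracma::gaussLegendre(nodes, 0, split)
  g2 <- pracma::gaussLegendre(nodes, split, 1)
  x <- c(g1$x, g2$x)
  w <- c(g1$w, g2$w)
  h <- sojourn_density(x, S) * w
  j <- seq_len(n - 1L)
  xm <- outer(x, j, function(x, j) stats::dbinom(j, n, x))
  as.numeric(crossprod(h, xm))
}

# Matrix of B(j; n, S) for a vector of S values (rows = S, cols = j).
sojourn_kernel <- function(n, S, nodes = 64L) {
  t(vapply(S, function(s) binom_sojourn(n, s, nodes), numeric(n - 1L)))
}

# --- fixed integration grids -------------------------------------------------
# Log-spaced bins over |S|; node = geometric bin midpoint. Grids are fixed so
# the sojourn kernel can be cached per sample size n.

grid_spec <- function(lo, hi, nbin) {
  edges <- 10^seq(log10(lo), log10(hi), length.out = nbin + 1L)
  list(edges = edges, mid = sqrt(edges[-1] * edges[-(nbin + 1L)]))
}

GRID_NEG <- local(grid_spec(1e-7, 3e5, 256L))
GRID_POS <- local(grid_spec(1e-7, 1e4, 128L))
GRID_BETA_N <- 250L

cached_kernel <- function(n, grid_id, S) {
  key <- sprintf("kern:%d:%s:%d", n, grid_id, length(S))
  k <- .mk_cache[[key]]
  if (is.null(k)) {
    k <- sojourn_kernel(n, S)
    .mk_cache[[key]] <- k
  }
  k
}

# Discretize a DFE model onto the fixed grids. Returns list(S, w, kernel_id)
# where kernel_id names the cached kernel ("neg", "pos", "beta" or NULL for
# exact discrete models).
dfe_discretization <- function(model) {
  fam <- model$family
  p <- model$params
  if (fam == "Discrete")
    return(list(list(S = p$S, w = p$w, id = NULL)))
  if (fam %in% c("GammaZero", "GammaExpo")) {
    shape <- p[["shape"]]
    scale <- -p[["mean_S"]] / shape
    e <- GRID_NEG$edges
    w <- diff(stats::pgamma(e, shape = shape, scale = scale))
    w[1] <- w[1] + stats::pgamma(e[1], shape = shape, scale = scale)
    w[length(w)] <- w[length(w)] +
      stats::pgamma(e[length(e)], shape = shape, scale = scale,
                    lower.tail = FALSE)
    comps <- list(list(S = -GRID_NEG$mid, w = w, id = "neg"))
    if (fam == "GammaExpo" && p[["p_pos"]] > 0) {
      comps[[1]]$w <- comps[[1]]$w * (1 - p[["p_pos"]])
      ep <- GRID_POS$edges
      wp <- diff(stats::pexp(ep, rate = 1 / p[["mean_S_pos"]]))
      wp[1] <- wp[1] + stats::pexp(ep[1], rate = 1 / p[["mean_S_pos"]])
      wp[length(wp)] <- wp[length(wp)] +
        stats::pexp(ep[length(ep)], rate = 1 / p[["mean_S_pos"]],
                    lower.tail = FALSE)
      comps <- c(comps,
                 list(list(S = GRID_POS$mid, w = wp * p[["p_pos"]],
                           id = "pos")))
    }
    return(comps)
  }
  if (fam == "ScaledBeta") {
    lo <- SCALED_BETA_RANGE[1]; hi <- SCALED_BETA_RANGE[2]
    e <- seq(lo, hi, length.out = GRID_BETA_N + 1L)
    mid <- (e[-1] + e[-(GRID_BETA_N + 1L)]) / 2
    u <- (e - lo) / (hi - lo)
    w <- diff(stats::pbeta(u, p[["beta_a"]], p[["beta_b"]]))
    return(list(list(S = mid, w = w, id = "beta")))
  }
  stop("unknown DFE family: ", fam)
}

# Expected unfolded spectrum shape under a DFE, per unit theta*L:
# e_j = int phi(S) B(j; n, S) dS, j = 1..n-1.
dfe_unfolded_shape <- function(model, n) {
  comps <- dfe_discretization(model)
  e <- numeric(n - 1L)
  for (cp in comps) {
    if (is.null(cp$id)) {
      K <- sojourn_kernel(n, cp$S)
    } else {
      K <- cached_kernel(n, cp$id, cp$S)
    }
    e <- e + as.numeric(crossprod(cp$w, K))
  }
  e
}

#' Expected folded SFS class counts
#'
#' Expected counts of the folded spectrum under the Poisson random field
#' model. With `neutral = TRUE` the class expectations are
#' `E[c_i] = L theta r_i (1/i + 1/(n-i)) / (1 + [i == n-i])`; under a DFE
#' the neutral `1/j` shape is replaced by the selection-weighted sojourn
#' integral `B(j; n, S)` averaged over the DFE, folded the same way.
#'
#' @param model A `dfe_model` (ignored when `neutral = TRUE`).
#' @param theta_site Per-site population mutation rate `4 Ne mu`.
#' @param r Nuisance multipliers per folded class (`r[1]` conventionally 1);
#'   `NULL` for no distortion.
#' @param n Sample size in chromosomes (`>= 4` recommended).
#' @param L Number of sites.
#' @param neutral Logical; if `TRUE`, the neutral expectation.
#' @return Numeric vector of expected folded counts, length `floor(n/2)`.
#' @export
expected_folded_sfs <- function(model = NULL, theta_site, r = NULL, n, L,
                                neutral = FALSE) {
  n <- as.integer(n)
  K <- n %/% 2L
  if (is.null(r)) r <- rep(1, K)
  if (length(r) != K) stop("r must have length floor(n/2)")
  if (neutral) {
    shape <- neutral_folded_shape(n)
  } else {
    e <- dfe_unfolded_shape(model, n)
    i <- seq_len(K)
    shape <- (e[i] + e[n - i]) / (1 + as.numeric(i == n - i))
  }
  L * theta_site * r * shape
}

#' Expected non-adaptive dN/dS of a fitted DFE
#'
#' Integrates the relative fixation rate `S / (1 - exp(-S))` over the
#' non-adaptive component of the DFE (the `S <= 0` part, including any
#' neutral point mass). Fixations driven by the fitted beneficial component
#' are counted as adaptive and excluded; set
#' `include_weak_positive = TRUE` to count them as non-adaptive instead
#' (alternative accounting).
#'
#' @param model A `dfe_model`.
#' @param include_weak_positive Logical; include the positive component's
#'   fixations in the non-adaptive expectation.
#' @return Expected dN/dS under near-neutrality (numeric scalar).
#' @export
predicted_omega_na <- function(model, include_weak_positive = FALSE) {
  fam <- model$family
  p <- model$params
  int_gamma_neg <- function(shape, scale) {
    # E[ t / (e^t - 1) ], t ~ Gamma(shape, scale); the fixation factor is
    # negligible beyond t = 60, and the upper bound shrinks with the gamma
    # quantile so narrow near-neutral spikes are not missed
    f <- function(t) stats::dgamma(t, shape = shape, scale = scale) *
      fixation_ratio(-t)
    hi <- min(60, stats::qgamma(1e-14, shape, scale = scale,
                                lower.tail = FALSE))
    stats::integrate(f, 0, hi, rel.tol = 1e-10, abs.tol = 0,
                     subdivisions = 500L)$value
  }
  if (fam == "GammaZero") {
    return(int_gamma_neg(p[["shape"]], -p[["mean_S"]] / p[["shape"]]))
  }
  if (fam == "GammaExpo") {
    neg <- int_gamma_neg(p[["shape"]], -p[["mean_S"]] / p[["shape"]])
    out <- (1 - p[["p_pos"]]) * neg
    if (include_weak_positive && p[["p_pos"]] > 0) {
      f <- function(t) stats::dexp(t, rate = 1 / p[["mean_S_pos"]]) *
        fixation_ratio(t)
      hi <- max(60, 20 * p[["mean_S_pos"]])
      pos <- stats::integrate(f, 0, hi, rel.tol = 1e-10,
                              subdivisions = 500L)$value
      out <- out + p[["p_pos"]] * pos
    }
    return(out)
  }
  if (fam == "ScaledBeta") {
    lo <- SCALED_BETA_RANGE[1]; hi <- SCALED_BETA_RANGE[2]
    dens <- function(S) stats::dbeta((S - lo) / (hi - lo),
                                     p[["beta_a"]], p[["beta_b"]]) / (hi - lo)
    f <- function(S) dens(S) * fixation_ratio(S)
    out <- stats::integrate(f, lo, 0, rel.tol = 1e-10,
                            subdivisions = 500L)$value
    if (include_weak_positive)
      out <- out + stats::integrate(f, 0, hi, rel.tol = 1e-10,
                                    subdivisions = 500L)$value
    return(out)
  }
  if (fam == "Discrete") {
    keep <- if (include_weak_positive) rep(TRUE, length(p$S)) else p$S <= 0
    return(sum(p$w[keep] * fixation_ratio(p$S[keep])))
  }
  stop("unknown DFE family: ", fam)
}
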