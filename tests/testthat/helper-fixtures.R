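# Shared helpers: small deterministic fixtures and independent oracles.

# Dense-trapezoid brute-force evaluation of the unfolded sojourn-binomial
# integral, independent of the package's Gauss-Legendre implementation.
brute_force_unfolded <- function(n, S, grid_n = 200001L) {
  x <- seq(1e-7, 1 - 1e-7, length.out = grid_n)
  H <- sojourn_density(x, S)
  vapply(seq_len(n - 1L), function(j)
    pracma::trapz(x, H * stats::dbinom(j, n, x)), numeric(1))
}

# Expected folded spectrum for a discrete DFE via the brute-force integral.
brute_force_folded <- function(S, w, theta, r, n, L) {
  e <- Reduce(`+`, Map(function(s, wt) wt * brute_force_unfolded(n, s),
                       S, w))
  i <- seq_len(n %/% 2L)
  shape <- (e[i] + e[n - i]) / (1 + as.numeric(i == n - i))
  L * theta * r * shape
}

# Normal-equations OLS oracle (slope, intercept, r2, two-sided slope p).
normal_equations_ols <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(beta = as.numeric(beta), se = as.numeric(se), p = as.numeric(p),
       r2 = r2)
}

# All permutations of 1..n (for the exact Spearman null), n small.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# A tiny deterministic paired SFS.
tiny_paired_sfs <- function(n = 8L, seed = 42L) {
  gen <- generate_sfs_dataset(dfe_gamma_zero(-500, 0.2), theta = 0.01,
                              n = n, L_s = 5e4, L_n = 5e4,
                              omega_a_true = 0.05, seed = seed)
  gen
}
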