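#' Folded site frequency spectrum
#'
#' Container for a folded SFS: SNP counts indexed by minor-allele count
#' `i = 1..floor(n/2)` together with the mutational-opportunity site count
#' `L`. Counts may be fractional (hypergeometric projection and cross-species
#' pooling both produce non-integer counts).
#'
#' @param counts Numeric vector of length `floor(sample_size/2)`,
#'   non-negative.
#' @param sample_size Integer number of chromosomes `n >= 2`.
#' @param n_sites Positive number of sites `L` the spectrum is drawn from.
#' @param mutation_class `"synonymous"` or `"nonsynonymous"`.
#' @param subset `"all"` or `"gc_conservative"`.
#' @return An object of class `folded_sfs`.
#' @export
folded_sfs <- function(counts, sample_size, n_sites,
                       mutation_class = c("synonymous", "nonsynonymous"),
                       subset = c("all", "gc_conservative")) {
  mutation_class <- match.arg(mutation_class)
  subset <- match.arg(subset)
  sample_size <- as.integer(sample_size)
  if (sample_size < 2L) stop("sample_size must be >= 2")
  K <- sample_size %/% 2L
  counts <- as.numeric(counts)
  if (length(counts) != K)
    stop(sprintf("counts must have length floor(n/2) = %d", K))
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  if (!is.numeric(n_sites) || n_sites <= 0) stop("n_sites must be > 0")
  structure(list(counts = counts, sample_size = sample_size,
                 n_sites = as.numeric(n_sites),
                 mutation_class = mutation_class, subset = subset),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat(sprintf("folded %s SFS (%s): n = %d, L = %g, %d classes, %g SNPs\n",
              x$mutation_class, x$subset, x$sample_size, x$n_sites,
              length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Paired synonymous/non-synonymous spectra
#'
#' The polymorphism half of a McDonald-Kreitman contrast: a synonymous and a
#' non-synonymous folded SFS sharing sample size and mutation subset.
#'
#' @param syn,nonsyn `folded_sfs` objects of the respective mutation classes.
#' @param species_id,group_id Identifier strings.
#' @return An object of class `paired_sfs`.
#' @export
paired_sfs <- function(syn, nonsyn, species_id = "species",
                       group_id = "group") {
  stopifnot(inherits(syn, "folded_sfs"), inherits(nonsyn, "folded_sfs"))
  if (syn$mutation_class != "synonymous" ||
      nonsyn$mutation_class != "nonsynonymous")
    stop("syn/nonsyn halves have wrong mutation classes")
  if (syn$sample_size != nonsyn$sample_size)
    stop("syn and nonsyn spectra must share sample_size")
  if (syn$subset != nonsyn$subset)
    stop("syn and nonsyn spectra must share subset")
  structure(list(syn = syn, nonsyn = nonsyn,
                 species_id = species_id, group_id = group_id),
            class = "paired_sfs")
}

#' @export
print.paired_sfs <- function(x, ...) {
  cat(sprintf("paired SFS for %s (%s), n = %d, subset = %s\n",
              x$species_id, x$group_id, x$syn$sample_size, x$syn$subset))
  cat(sprintf("  syn:    L = %g, SNPs = %g\n", x$syn$n_sites,
              sum(x$syn$counts)))
  cat(sprintf("  nonsyn: L = %g, SNPs = %g\n", x$nonsyn$n_sites,
              sum(x$nonsyn$counts)))
  invisible(x)
}

# Hypergeometric projection of a single allele observed at count k among c
# called chromosomes down to m chromosomes. Returns the vector of expected
# contributions to projected counts j = 0..m.
project_one <- function(k, c, m) {
  stats::dhyper(0:m, k, c - k, m)
}

#' Project a spectrum to a smaller sample size
#'
#' Downsamples an SFS to `m` chromosomes using hypergeometric expectations:
#' every SNP observed at `k` copies among `c` called chromosomes contributes
#' its expected sampling distribution over classes of size `m`. Mass falling
#' in the monomorphic classes (0 and `m` copies) is dropped, classes above
#' `m/2` are folded onto their minor-allele class, and the resulting counts
#' are fractional.
#'
#' @param sfs A `folded_sfs`, or a numeric vector of per-class counts indexed
#'   by allele count `1..(c-1)` (unfolded) with `c` given via `from`.
#' @param m Target number of chromosomes, `2 <= m <= c`.
#' @param from Number of chromosomes of the input when `sfs` is a bare
#'   numeric vector of unfolded counts.
#' @return A `folded_sfs` at sample size `m` (metadata preserved when the
#'   input was a `folded_sfs`).
#' @export
project_sfs <- function(sfs, m, from = NULL) {
  m <- as.integer(m)
  if (inherits(sfs, "folded_sfs")) {
    c_from <- sfs$sample_size
    counts <- sfs$counts
    ks <- seq_along(counts)           # minor-allele counts
  } else {
    if (is.null(from)) stop("'from' is required for bare count vectors")
    c_from <- as.integer(from)
    counts <- as.numeric(sfs)
    if (length(counts) != c_from - 1L)
      stop("unfolded counts must have length from - 1")
    ks <- seq_along(counts)           # derived-allele counts
  }
  if (m < 2L) stop("m must be >= 2")
  if (m > c_from) stop("cannot project to more chromosomes than observed")
  Kout <- m %/% 2L
  out <- numeric(Kout)
  for (i in seq_along(ks)) {
    if (counts[i] == 0) next
    pj <- project_one(ks[i], c_from, m)        # classes 0..m
    for (j in seq_len(m - 1L)) {
      f <- min(j, m - j)
      out[f] <- out[f] + counts[i] * pj[j + 1L]
    }
  }
  if (inherits(sfs, "folded_sfs"))
    folded_sfs(out, m, sfs$n_sites, sfs$mutation_class, sfs$subset)
  else
    folded_sfs(out, m, 1, "synonymous", "all")$counts
}

#' @rdname project_sfs
#' @export
project_paired_sfs <- function(sfs, m) {
  stopifnot(inherits(sfs, "paired_sfs"))
  paired_sfs(project_sfs(sfs$syn, m), project_sfs(sfs$nonsyn, m),
             sfs$species_id, sfs$group_id)
}

#' Pool spectra across species with equal weights
#'
#' Combines per-species paired spectra into a group spectrum using the
#' unweighted three-step recipe: (1) divide the synonymous and non-synonymous
#' counts of each SFS class of each species by that species' total SNP count,
#' (2) sum the normalized spectra across species, and (3) rescale the sums so
#' that the pooled total SNP count equals the summed SNP count across
#' species. Each species therefore contributes equal mass regardless of its
#' SNP number, which buffers species-specific demography. Site counts are
#' summed. Spectra with unequal sample sizes are first projected to the
#' smallest shared even sample size.
#'
#' @param spectra List of `paired_sfs` objects sharing `subset`.
#' @param group_id Group label of the pooled spectrum.
#' @return A `paired_sfs` holding the pooled spectra.
#' @export
pool_sfs <- function(spectra, group_id = NULL) {
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, logical(1), "paired_sfs")))
  subsets <- vapply(spectra, function(s) s$syn$subset, character(1))
  if (length(unique(subsets)) != 1L)
    stop("all spectra must share the same subset")
  totals <- vapply(spectra, function(s)
    sum(s$syn$counts) + sum(s$nonsyn$counts), numeric(1))
  if (any(totals == 0)) {
    warning(sum(totals == 0), " species with zero SNPs excluded from pooling")
    spectra <- spectra[totals > 0]
    totals <- totals[totals > 0]
    if (length(spectra) == 0L) stop("no species with SNPs to pool")
  }
  ns <- vapply(spectra, function(s) s$syn$sample_size, integer(1))
  if (length(unique(ns)) != 1L) {
    m <- min(ns)
    if (m %% 2L == 1L) m <- m - 1L
    spectra <- lapply(spectra, project_paired_sfs, m = m)
    totals <- vapply(spectra, function(s)
      sum(s$syn$counts) + sum(s$nonsyn$counts), numeric(1))
  }
  n <- spectra[[1L]]$syn$sample_size
  syn_norm <- Reduce(`+`, Map(function(s, t) s$syn$counts / t,
                              spectra, totals))
  non_norm <- Reduce(`+`, Map(function(s, t) s$nonsyn$counts / t,
                              spectra, totals))
  scale <- sum(totals) / (sum(syn_norm) + sum(non_norm))
  Ls <- sum(vapply(spectra, function(s) s$syn$n_sites, numeric(1)))
  Ln <- sum(vapply(spectra, function(s) s$nonsyn$n_sites, numeric(1)))
  gid <- group_id %||% spectra[[1L]]$group_id
  paired_sfs(
    folded_sfs(syn_norm * scale, n, Ls, "synonymous", subsets[1L]),
    folded_sfs(non_norm * scale, n, Ln, "nonsynonymous", subsets[1L]),
    species_id = paste0("pooled:", gid), group_id = gid)
}

#' Per-site nucleotide diversity from a folded spectrum
#'
#' Computes pi with the `n/(n-1)` small-sample correction:
#' `pi = (n/(n-1)) * sum_i 2 (i/n)(1 - i/n) c_i / L`.
#'
#' @param sfs A `folded_sfs`.
#' @return Per-site diversity (numeric scalar).
#' @export
compute_pi <- function(sfs) {
  stopifnot(inherits(sfs, "folded_sfs"))
  if (sfs$n_sites <= 0) stop("n_sites must be positive")
  n <- sfs$sample_size
  i <- seq_along(sfs$counts)
  sum(2 * (i / n) * (1 - i / n) * sfs$counts) * n / (n - 1) / sfs$n_sites
}

#' Tajima's D from a folded spectrum
#'
#' Standard Tajima (1989) D contrasting mean pairwise diversity with the
#' Watterson estimator, using the usual `a1, a2, b1, b2, c1, c2, e1, e2`
#' constants. Returns `NA` when there are no segregating sites.
#'
#' @param sfs A `folded_sfs` with `sample_size >= 4`.
#' @return Numeric scalar (or `NA` if undefined).
#' @export
tajimas_d <- function(sfs) {
  stopifnot(inherits(sfs, "folded_sfs"))
  n <- sfs$sample_size
  if (n < 4L) stop("tajimas_d requires sample_size >= 4")
  S <- sum(sfs$counts)
  if (S <= 0) return(NA_real_)
  i <- seq_along(sfs$counts)
  pi_total <- sum(2 * i * (n - i) / (n * (n - 1)) * sfs$counts)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Neutral folded class shape (per unit theta*L): a_i = (1/i + 1/(n-i)),
# halved when i == n - i so the symmetric class is not double counted.
neutral_folded_shape <- function(n) {
  K <- n %/% 2L
  i <- seq_len(K)
  (1 / i + 1 / (n - i)) / (1 + as.numeric(i == n - i))
}
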