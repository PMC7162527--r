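#' @importFrom Biostrings GENETIC_CODE
NULL

# 64 x 3 x 3 array: class of the single-base change of codon `c` at position
# `w` to its j-th alternative base. Cached per genetic-code id.
codon_change_table <- function(code = "standard") {
  key <- paste0("cct:", code)
  if (!is.null(.mk_cache[[key]])) return(.mk_cache[[key]])
  gc <- genetic_code(code)
  codons <- canonical_codons()
  tab <- array(NA_integer_, dim = c(64L, 3L, 3L),
               dimnames = list(codons, NULL, NULL))
  for (ci in seq_along(codons)) {
    cod <- strsplit(codons[ci], "")[[1]]
    aa <- gc[[codons[ci]]]
    for (w in 1:3) {
      alts <- ALT_BASES[cod[w], ]
      for (j in 1:3) {
        new <- cod
        new[w] <- alts[j]
        aa2 <- gc[[paste(new, collapse = "")]]
        tab[ci, w, j] <-
          if (aa == "*" || aa2 == "*") CLASS_STOP
          else if (aa == aa2) CLASS_SYN else CLASS_NONSYN
      }
    }
  }
  .mk_cache[[key]] <- tab
  tab
}

genetic_code <- function(code = "standard") {
  if (identical(code, "standard")) return(Biostrings::GENETIC_CODE)
  Biostrings::getGeneticCode(code)
}

# Codons in ACGT-lexicographic order, matching codon_index() numbering
# (Biostrings tables come in TCAG order).
canonical_codons <- function() {
  if (is.null(.mk_cache[["codons"]])) {
    g <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                     stringsAsFactors = FALSE)
    .mk_cache[["codons"]] <- paste0(g$b1, g$b2, g$b3)
  }
  .mk_cache[["codons"]]
}

# Amino acid (or "*") per codon, indexed in canonical codon_index order.
codon_aa <- function(code = "standard") {
  key <- paste0("aa:", code)
  if (is.null(.mk_cache[[key]])) {
    gc <- genetic_code(code)
    .mk_cache[[key]] <- unname(gc[canonical_codons()])
  }
  .mk_cache[[key]]
}

codon_index <- function(b1, b2, b3) (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3

#' Classify a single-nucleotide change within a codon
#'
#' Determines whether replacing the base at `pos_in_codon` of `codon` with
#' `alt` is a synonymous, non-synonymous or stop-involving change, and whether
#' the change is GC-conservative (A<->T or C<->G), i.e. immune to GC-biased
#' gene conversion.
#'
#' @param codon Character scalar, a 3-letter codon (A/C/G/T).
#' @param pos_in_codon Integer in 1..3, position of the changed base.
#' @param alt Character scalar, the alternative base; must differ from the
#'   reference base at that position.
#' @param code Genetic code identifier (`"standard"` or a name understood by
#'   [Biostrings::getGeneticCode()]).
#' @return A list with `class` (one of `"synonymous"`, `"nonsynonymous"`,
#'   `"stop"`; stop-involving changes are excluded from downstream spectra)
#'   and logical `gc_conservative`.
#' @examples
#' classify_snp("GGG", 3, "C")  # synonymous, GC-conservative
#' @export
classify_snp <- function(codon, pos_in_codon, alt, code = "standard") {
  codon <- toupper(codon)
  alt <- toupper(alt)
  bases <- strsplit(codon, "")[[1]]
  if (length(bases) != 3L || !all(bases %in% BASES))
    stop("'codon' must be a 3-letter A/C/G/T string")
  if (!alt %in% BASES) stop("'alt' must be one of A, C, G, T")
  ref <- bases[pos_in_codon]
  if (alt == ref) stop("'alt' equals the reference base")
  tab <- codon_change_table(code)
  j <- match(alt, ALT_BASES[ref, ])
  cls <- tab[codon, pos_in_codon, j]
  list(
    class = c("synonymous", "nonsynonymous", "stop")[cls],
    gc_conservative = identical(unname(GC_PARTNER[ref]), alt)
  )
}

#' Mutational-opportunity site counts of a coding sequence
#'
#' Counts synonymous and non-synonymous sites of a coding sequence by codon
#' enumeration: each position contributes, for each of its three possible
#' single-base changes, 1/3 of a site to the synonymous or non-synonymous
#' total; stop-involving changes contribute to neither. GC-conservative
#' totals count the single GC-conservative change possible at each position
#' (A<->T or C<->G) as one full site, assigned to its class (or dropped when
#' stop-involving).
#'
#' @param cds Coding sequence: a character string or `DNAString`. Length must
#'   be a multiple of 3 with no internal stop codons; a terminal stop codon
#'   is allowed and skipped. Codons containing non-ACGT symbols are excluded
#'   with a warning.
#' @param code Genetic code identifier.
#' @return A list of class `site_counts` with elements `L_syn`, `L_nonsyn`,
#'   `L_syn_gc`, `L_nonsyn_gc`.
#' @examples
#' count_sites("TTT")  # L_syn = 1/3, L_nonsyn = 8/3
#' @export
count_sites <- function(cds, code = "standard") {
  cds <- toupper(as.character(cds))
  if (length(cds) > 1L) {
    parts <- lapply(cds, count_sites, code = code)
    out <- Reduce(function(a, b) Map(`+`, a, b), parts)
    class(out) <- "site_counts"
    return(out)
  }
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("coding sequence length not divisible by 3")
  bases <- strsplit(cds, "")[[1]]
  ok <- bases %in% BASES
  ncod <- n %/% 3L
  codon_ok <- .colSums(matrix(ok, nrow = 3L), 3L, ncod) == 3L
  if (!all(codon_ok))
    warning(sum(!codon_ok), " codon(s) with non-ACGT symbols excluded")
  b <- match(bases, BASES)
  aa <- codon_aa(code)
  tab <- codon_change_table(code)
  cod_mat <- matrix(b, nrow = 3L)
  idx <- which(codon_ok)
  if (length(idx) == 0L) {
    out <- list(L_syn = 0, L_nonsyn = 0, L_syn_gc = 0, L_nonsyn_gc = 0)
    class(out) <- "site_counts"
    return(out)
  }
  ci <- codon_index(cod_mat[1L, idx], cod_mat[2L, idx], cod_mat[3L, idx])
  is_stop <- aa[ci] == "*"
  if (any(is_stop)) {
    if (any(is_stop[-length(is_stop)]) ||
        (is_stop[length(is_stop)] && idx[length(idx)] != ncod))
      stop("internal stop codon in coding sequence")
    # terminal stop codon: skipped
    keep <- !is_stop
    ci <- ci[keep]
  }
  if (length(ci) == 0L) {
    out <- list(L_syn = 0, L_nonsyn = 0, L_syn_gc = 0, L_nonsyn_gc = 0)
    class(out) <- "site_counts"
    return(out)
  }
  # all-mutation opportunities: 1/3 site per possible change
  cls <- tab[ci, , , drop = FALSE]          # ncod x 3pos x 3alt
  L_syn <- sum(cls == CLASS_SYN) / 3
  L_nonsyn <- sum(cls == CLASS_NONSYN) / 3
  # GC-conservative: exactly one such change per position; find its alt index
  codm <- rbind((ci - 1L) %/% 16L + 1L,
                ((ci - 1L) %/% 4L) %% 4L + 1L,
                (ci - 1L) %% 4L + 1L)
  L_syn_gc <- 0
  L_nonsyn_gc <- 0
  for (w in 1:3) {
    refb <- BASES[codm[w, ]]
    gcalt <- unname(GC_PARTNER[refb])
    j <- vapply(seq_along(refb),
                function(k) match(gcalt[k], ALT_BASES[refb[k], ]), integer(1))
    cw <- cls[cbind(seq_along(ci), w, j)]
    L_syn_gc <- L_syn_gc + sum(cw == CLASS_SYN)
    L_nonsyn_gc <- L_nonsyn_gc + sum(cw == CLASS_NONSYN)
  }
  out <- list(L_syn = L_syn, L_nonsyn = L_nonsyn,
              L_syn_gc = L_syn_gc, L_nonsyn_gc = L_nonsyn_gc)
  class(out) <- "site_counts"
  out
}

#' @export
print.site_counts <- function(x, ...) {
  cat(sprintf(
    "site counts: L_syn = %.4f, L_nonsyn = %.4f (GC-conservative: %g / %g)\n",
    x$L_syn, x$L_nonsyn, x$L_syn_gc, x$L_nonsyn_gc))
  invisible(x)
}
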