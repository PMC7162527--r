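#' Diploid genotype table
#'
#' Stand-in for upstream genotype-calling output: per-site metadata (with the
#' codon context needed to classify each SNP) and a matrix of diploid
#' alternate-allele dosages.
#'
#' @param sites Data frame with columns `contig`, `position` (1-based),
#'   `codon` (3-mer reference codon), `pos_in_codon` (1..3), `ref`, `alt`.
#' @param genotypes Integer matrix individuals x sites with values 0, 1, 2
#'   (alternate-allele copies) or `NA` (missing call).
#' @return Object of class `genotype_table`.
#' @export
genotype_table <- function(sites, genotypes) {
  need <- c("contig", "position", "codon", "pos_in_codon", "ref", "alt")
  if (!all(need %in% names(sites)))
    stop("sites must contain columns: ", paste(need, collapse = ", "))
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != nrow(sites))
    stop("genotypes must have one column per site")
  if (any(!genotypes %in% c(0L, 1L, 2L, NA)))
    stop("genotypes must be 0, 1, 2 or NA")
  if (anyDuplicated(sites[, c("contig", "position")]))
    stop("positions must be unique per contig")
  if (!all(c(sites$ref, sites$alt) %in% BASES))
    stop("alleles must be A, C, G or T")
  structure(list(sites = sites, genotypes = genotypes),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype table: %d individuals x %d sites\n",
              nrow(x$genotypes), nrow(x$sites)))
  invisible(x)
}

#' Choose the SFS sample size that maximizes projected SNP counts
#'
#' With uneven coverage, the number of called chromosomes varies across
#' sites; projecting to a large `m` keeps more frequency resolution but
#' drops every SNP called in fewer than `m` chromosomes. This scans even
#' `m <= 2 * individuals` and returns the value maximizing the number of
#' SNPs retained after projection.
#'
#' @param gt A `genotype_table`.
#' @return Even integer target sample size.
#' @export
choose_sample_size <- function(gt) {
  g <- gt$genotypes
  called <- 2L * colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  poly <- alt > 0L & alt < called
  called <- called[poly]
  alt <- alt[poly]
  if (length(called) == 0L) return(2L)
  cand <- seq(2L, max(called), by = 2L)
  # fractional SNP mass surviving projection to m: SNPs called in fewer
  # chromosomes are dropped, and projected SNPs lose their monomorphic mass
  kept <- vapply(cand, function(m) {
    keep <- called >= m
    if (!any(keep)) return(0)
    sum(1 - stats::dhyper(0, alt[keep], called[keep] - alt[keep], m) -
          stats::dhyper(m, alt[keep], called[keep] - alt[keep], m))
  }, numeric(1))
  cand[which.max(kept)]
}

#' Build paired folded spectra from a genotype table
#'
#' Classifies every SNP through its codon context, drops stop-involving
#' changes, optionally restricts to GC-conservative changes, computes
#' minor-allele counts among called chromosomes, and projects every SNP to a
#' common sample size `m` by hypergeometric expectation. SNPs with fewer
#' than `m` called chromosomes are dropped with a warning, as are sites with
#' all genotypes missing or monomorphic calls. Site counts come from codon
#' enumeration of the supplied coding sequences, matching the chosen subset.
#'
#' @param gt A `genotype_table`.
#' @param cds Character vector of coding sequences (the mutational
#'   opportunity denominator).
#' @param m Target chromosomes; default [choose_sample_size()].
#' @param subset `"all"` or `"gc_conservative"`.
#' @param species_id,group_id Identifiers attached to the output.
#' @param code Genetic code identifier.
#' @return A `paired_sfs`.
#' @export
build_paired_sfs <- function(gt, cds, m = NULL,
                             subset = c("all", "gc_conservative"),
                             species_id = "species", group_id = "group",
                             code = "standard") {
  subset <- match.arg(subset)
  stopifnot(inherits(gt, "genotype_table"))
  if (is.null(m)) m <- choose_sample_size(gt)
  m <- as.integer(m)
  sc <- count_sites(cds, code = code)
  if (subset == "all") {
    Ls <- sc$L_syn; Ln <- sc$L_nonsyn
  } else {
    Ls <- sc$L_syn_gc; Ln <- sc$L_nonsyn_gc
  }
  g <- gt$genotypes
  called <- 2L * colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  K <- m %/% 2L
  syn_counts <- numeric(K)
  non_counts <- numeric(K)
  dropped <- 0L
  for (s in seq_len(nrow(gt$sites))) {
    cc <- called[s]
    if (cc == 0L) next                               # all missing
    a <- alt[s]
    if (a == 0L || a == cc) next                     # monomorphic in calls
    cl <- classify_snp(gt$sites$codon[s], gt$sites$pos_in_codon[s],
                       gt$sites$alt[s], code = code)
    if (cl$class == "stop") next
    if (subset == "gc_conservative" && !cl$gc_conservative) next
    if (cc < m) { dropped <- dropped + 1L; next }
    pj <- project_one(a, cc, m)
    for (j in seq_len(m - 1L)) {
      f <- min(j, m - j)
      if (cl$class == "synonymous") syn_counts[f] <- syn_counts[f] + pj[j + 1L]
      else non_counts[f] <- non_counts[f] + pj[j + 1L]
    }
  }
  if (dropped > 0L)
    warning(dropped, " SNP(s) with fewer called chromosomes than m dropped")
  paired_sfs(
    folded_sfs(syn_counts, m, Ls, "synonymous", subset),
    folded_sfs(non_counts, m, Ln, "nonsynonymous", subset),
    species_id = species_id, group_id = group_id)
}

#' Inbreeding coefficient from genotypes
#'
#' `F_is = 1 - mean(H_obs) / mean(H_exp)` over polymorphic sites, with
#' `H_exp = 2 p (1 - p) * 2 n_c / (2 n_c - 1)` and `n_c` the number of
#' called individuals at the site. Positive values indicate a deficit of
#' heterozygotes (inbreeding or substructure), negative values an excess.
#'
#' @param gt A `genotype_table`.
#' @return Numeric scalar (`NA` with no polymorphic site).
#' @export
compute_fis <- function(gt) {
  g <- gt$genotypes
  nc <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  p <- alt / (2 * nc)
  poly <- !is.na(p) & p > 0 & p < 1 & nc > 0
  if (!any(poly)) return(NA_real_)
  hobs <- colMeans(g[, poly, drop = FALSE] == 1L, na.rm = TRUE)
  ncp <- nc[poly]
  hexp <- 2 * p[poly] * (1 - p[poly]) * 2 * ncp / (2 * ncp - 1)
  1 - mean(hobs) / mean(hexp)
}

#' Read and write genotype tables as TSV
#'
#' Columns `contig`, `position`, `codon`, `pos_in_codon`, `ref`, `alt`
#' followed by one column per individual holding 0/1/2/NA dosages.
#'
#' @param gt A `genotype_table`; `path` a file path.
#' @return `read_genotypes_tsv` returns a `genotype_table`.
#' @export
write_genotypes_tsv <- function(gt, path) {
  g <- t(gt$genotypes)
  colnames(g) <- rownames(gt$genotypes) %||%
    paste0("ind", seq_len(nrow(gt$genotypes)))
  df <- cbind(gt$sites, as.data.frame(g))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  meta <- c("contig", "position", "codon", "pos_in_codon", "ref", "alt")
  gcols <- setdiff(names(df), meta)
  g <- t(as.matrix(df[, gcols, drop = FALSE]))
  rownames(g) <- gcols
  genotype_table(df[, meta], g)
}

#' Read genotypes from a VCF file
#'
#' Reads biallelic SNPs from a VCF (quality filtering is assumed to have
#' been applied upstream) and attaches codon contexts from a codon map.
#' Requires the vcfR package.
#'
#' @param path VCF file path.
#' @param codon_map Data frame with columns `contig`, `position`, `codon`,
#'   `pos_in_codon`; VCF records without a codon context are dropped.
#' @return A `genotype_table`.
#' @export
read_genotypes_vcf <- function(path, codon_map) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gtm <- vcfR::extract.gt(v)
  biall <- fix$REF %in% BASES & fix$ALT %in% BASES
  fix <- fix[biall, , drop = FALSE]
  gtm <- gtm[biall, , drop = FALSE]
  dosage <- function(x) {
    out <- rep(NA_integer_, length(x))
    x <- gsub("|", "/", x, fixed = TRUE)
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out
  }
  g <- apply(gtm, 2, dosage)
  if (is.null(dim(g))) g <- matrix(g, nrow = 1L)
  key <- paste(fix$CHROM, fix$POS)
  mkey <- paste(codon_map$contig, codon_map$position)
  hit <- match(key, mkey)
  keep <- !is.na(hit)
  sites <- data.frame(
    contig = fix$CHROM[keep], position = as.integer(fix$POS[keep]),
    codon = codon_map$codon[hit[keep]],
    pos_in_codon = codon_map$pos_in_codon[hit[keep]],
    ref = fix$REF[keep], alt = fix$ALT[keep], stringsAsFactors = FALSE)
  genotype_table(sites, t(g[keep, , drop = FALSE]))
}
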