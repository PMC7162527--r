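# Plain-text readers/writers for the pipeline's exchange formats.

#' Read and write paired-SFS files
#'
#' The SFS exchange format is tab-separated text: a header line
#' `#species<TAB>group<TAB>n<TAB>subset` followed by two data lines
#' `SYN<TAB>L<TAB>count_1 ... count_floor(n/2)` and `NONSYN<TAB>L<TAB>...`.
#' Counts are written at full precision so a write/read cycle is bit-exact.
#' Several spectra may be concatenated in one file.
#'
#' @param x A `paired_sfs` or list of them.
#' @param path File path.
#' @return `read_sfs` returns a list of `paired_sfs`; `write_sfs` returns
#'   `path` invisibly.
#' @export
write_sfs <- function(x, path) {
  if (inherits(x, "paired_sfs")) x <- list(x)
  lines <- unlist(lapply(x, function(ps) {
    c(paste0("#", paste(ps$species_id, ps$group_id, ps$syn$sample_size,
                        ps$syn$subset, sep = "\t")),
      paste(c("SYN", fmt_num(ps$syn$n_sites), fmt_num(ps$syn$counts)),
            collapse = "\t"),
      paste(c("NONSYN", fmt_num(ps$nonsyn$n_sites), fmt_num(ps$nonsyn$counts)),
            collapse = "\t"))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^#", lines)
  if (length(starts) == 0L) stop("no spectra found in ", path)
  out <- lapply(starts, function(s) {
    hd <- strsplit(sub("^#", "", lines[s]), "\t", fixed = TRUE)[[1]]
    if (length(hd) != 4L) stop("malformed SFS header: ", lines[s])
    n <- as.integer(hd[3])
    parse_line <- function(l, what) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (f[1] != what) stop("expected ", what, " line, got: ", l)
      list(L = as.numeric(f[2]), counts = as.numeric(f[-(1:2)]))
    }
    syn <- parse_line(lines[s + 1L], "SYN")
    non <- parse_line(lines[s + 2L], "NONSYN")
    paired_sfs(
      folded_sfs(syn$counts, n, syn$L, "synonymous", hd[4]),
      folded_sfs(non$counts, n, non$L, "nonsynonymous", hd[4]),
      species_id = hd[1], group_id = hd[2])
  })
  out
}

#' Read and write divergence-count tables
#'
#' Tab-separated with columns `id`, `scope` (`species_branch` or
#' `group_tree`), `subset`, `dN`, `dS`, `L_nonsyn`, `L_syn`.
#'
#' @param x Data frame with the columns above, or a list of
#'   `divergence_counts`.
#' @param path File path.
#' @return `read_divergence` returns a data frame; `write_divergence`
#'   returns `path` invisibly.
#' @export
write_divergence <- function(x, path) {
  if (!is.data.frame(x)) {
    x <- do.call(rbind, lapply(names(x), function(id) {
      d <- x[[id]]
      data.frame(id = id, scope = d$scope, subset = d$subset, dN = d$dN,
                 dS = d$dS, L_nonsyn = d$L_nonsyn, L_syn = d$L_syn)
    }))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_divergence
#' @export
read_divergence <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read coding sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning plain
#' character sequences named by record.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Read a species table for the comparative layer
#'
#' Accepts tab-separated text or XLSX (via the readxl package). Expected
#' columns: `species`, `group`, `pi_s`, and any of `pi_n`, `omega_a`,
#' `omega_na`, `alpha`, `fis`, `tajd`, `longevity`, `fecundity`,
#' `propagule_size`, `adult_size`, `body_mass`. A `col_map` named vector can
#' rename arbitrary source columns (e.g. a supplementary-table layout) onto
#' these canonical names.
#'
#' @param path File path (`.tsv`/`.txt` or `.xlsx`).
#' @param col_map Optional named character vector `c(canonical = "source")`.
#' @return Data frame of class `species_table`.
#' @export
read_species_table <- function(path, col_map = NULL) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX species tables requires the 'readxl' package")
    df <- as.data.frame(readxl::read_excel(path))
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  }
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (src %in% names(df)) names(df)[names(df) == src] <- canon
    }
  }
  if (!all(c("species", "group") %in% names(df)))
    stop("species table must contain 'species' and 'group' columns")
  class(df) <- c("species_table", "data.frame")
  df
}

#' @rdname read_species_table
#' @export
write_species_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a YAML analysis configuration
#'
#' Configuration keys mirror the function arguments of the fitting layer:
#' `families`, `n_starts`, `seed`, `bootstrap_B`, `include_weak_positive`,
#' `subset`, `target_m`. Unknown keys are kept and passed through.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
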