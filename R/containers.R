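#' Genotype matrix container
#'
#' Bundles a samples-by-variants matrix of alternate-allele dosages with the
#' variant coordinates. Dosages are 0, 1, 2 or `NA` (missing). Variants must be
#' biallelic SNPs sorted by position within chromosome.
#'
#' @param dosage Numeric matrix, samples in rows (rownames = sample ids),
#'   variants in columns.
#' @param variants Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, one row per dosage column.
#' @return An object of class `geno_matrix`: a list with elements `dosage`
#'   (matrix) and `variants` (tibble).
#' @export
geno_matrix <- function(dosage, variants) {
  variants <- tibble::as_tibble(variants)
  stopifnot(is.matrix(dosage), nrow(variants) == ncol(dosage))
  if (is.null(rownames(dosage))) {
    stop("dosage matrix must carry sample ids as rownames", call. = FALSE)
  }
  if (nrow(dosage) < 1L) stop("at least one sample is required", call. = FALSE)
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("variant positions must be strictly increasing within chromosome ",
           ch, call. = FALSE)
    }
  }
  structure(list(dosage = dosage, variants = variants), class = "geno_matrix")
}

#' @exportS3Method print geno_matrix
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d variants on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

sample_ids <- function(x) rownames(x$dosage)

#' Subset a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param samples Optional character vector of sample ids to keep.
#' @param keep_variants Optional logical or integer index over variants.
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(x, samples = NULL, keep_variants = NULL) {
  d <- x$dosage
  v <- x$variants
  if (!is.null(samples)) {
    missing_ids <- setdiff(samples, rownames(d))
    if (length(missing_ids)) {
      stop("unknown sample id(s): ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    }
    d <- d[samples, , drop = FALSE]
  }
  if (!is.null(keep_variants)) {
    d <- d[, keep_variants, drop = FALSE]
    v <- v[keep_variants, , drop = FALSE]
  }
  geno_matrix(d, v)
}

#' Phased haplotype panel container
#'
#' Holds 2N haplotype rows of 0/1 alleles over the same variant table as a
#' [geno_matrix()]. Rows `2i - 1` and `2i` are the two haplotypes of sample
#' `i`.
#'
#' @param haps Integer matrix of 0/1 alleles, 2N rows.
#' @param variants Variant table as for [geno_matrix()].
#' @param samples Character vector of N sample ids.
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(haps, variants, samples) {
  variants <- tibble::as_tibble(variants)
  stopifnot(is.matrix(haps), nrow(haps) == 2L * length(samples),
            ncol(haps) == nrow(variants))
  if (!all(haps %in% c(0L, 1L))) {
    stop("haplotype alleles must be 0 or 1", call. = FALSE)
  }
  structure(list(haps = haps, variants = variants, samples = samples,
                 hap_sample = rep(samples, each = 2L)),
            class = "hap_panel")
}

#' @exportS3Method print hap_panel
print.hap_panel <- function(x, ...) {
  cat(sprintf("<hap_panel> %d haplotypes (%d samples) x %d variants\n",
              nrow(x$haps), length(x$samples), ncol(x$haps)))
  invisible(x)
}

#' Collapse a haplotype panel to dosages
#'
#' @param panel A [hap_panel()].
#' @return A [geno_matrix()] whose dosage is the per-sample haplotype sum.
#' @export
panel_to_geno <- function(panel) {
  n <- length(panel$samples)
  d <- panel$haps[seq(1, 2 * n, by = 2), , drop = FALSE] +
    panel$haps[seq(2, 2 * n, by = 2), , drop = FALSE]
  rownames(d) <- panel$samples
  geno_matrix(d, panel$variants)
}

# 1-based inclusive [start, end] -> 0-based half-open [start0, end0)
to_bed_coords <- function(start, end) {
  list(start = start - 1L, end = end)
}

# 0-based half-open -> 1-based inclusive
from_bed_coords <- function(start0, end0) {
  list(start = start0 + 1L, end = end0)
}
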