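#' SNP quality-control filter
#'
#' Removes a SNP iff its genotype missing rate is strictly above
#' `max_missing` or its minor allele frequency is strictly below `min_maf`
#' (computed over non-missing genotypes).
#'
#' @param genotypes A [geno_matrix()].
#' @param max_missing Maximum tolerated missing rate (default 0.05).
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @return The filtered [geno_matrix()].
#' @export
qc_filter_snps <- function(genotypes, max_missing = 0.05, min_maf = 0.01) {
  d <- genotypes$dosage
  miss <- colMeans(is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep <- miss <= max_missing & maf >= min_maf
  if (!any(keep)) stop("QC removed every SNP", call. = FALSE)
  subset_geno(genotypes, keep_variants = keep)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of two dosage vectors over pairwise-complete
#' samples.
#'
#' @param a,b Numeric dosage vectors of equal length.
#' @return r-squared, or `NA` when fewer than two complete pairs remain or a
#'   vector is constant.
#' @export
pairwise_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' LD-pruning parameters
#'
#' The classical sliding-window pairwise prune: windows of `window_snps`
#' advancing by `step_snps`; within a window, while any retained pair has
#' r-squared above `r2_max`, the later SNP of the offending pair is removed.
#'
#' @param window_snps Window size in SNPs (default 50).
#' @param step_snps Step size in SNPs (default 5).
#' @param r2_max Pruning threshold (default 0.5).
#' @return A list of class `prune_params`.
#' @export
prune_params <- function(window_snps = 50, step_snps = 5, r2_max = 0.5) {
  stopifnot(window_snps >= step_snps, step_snps >= 1,
            r2_max > 0, r2_max <= 1)
  structure(list(window_snps = window_snps, step_snps = step_snps,
                 r2_max = r2_max), class = "prune_params")
}

#' Prune SNPs in high LD
#'
#' Deterministic per-chromosome scan (left to right, lowest index first):
#' within each window the first offending retained pair is located and its
#' later SNP removed, repeating until no retained pair in the window exceeds
#' the threshold.
#'
#' @param genotypes A [geno_matrix()].
#' @param params A [prune_params()].
#' @return Integer vector of retained variant column indices (sorted).
#' @export
ld_prune <- function(genotypes, params = prune_params()) {
  v <- genotypes$variants
  d <- genotypes$dosage
  keep_all <- integer(0)
  for (ch in unique(v$chrom)) {
    cols <- which(v$chrom == ch)
    n <- length(cols)
    keep <- rep(TRUE, n)
    s <- 1L
    while (s <= n) {
      w <- seq(s, min(s + params$window_snps - 1L, n))
      repeat {
        act <- w[keep[w]]
        offender <- NULL
        if (length(act) >= 2) {
          for (ii in seq_len(length(act) - 1L)) {
            for (jj in seq(ii + 1L, length(act))) {
              r2 <- pairwise_r2(d[, cols[act[ii]]], d[, cols[act[jj]]])
              if (!is.na(r2) && r2 > params$r2_max) {
                offender <- act[jj]
                break
              }
            }
            if (!is.null(offender)) break
          }
        }
        if (is.null(offender)) break
        keep[offender] <- FALSE
      }
      if (s + params$window_snps - 1L >= n) break
      s <- s + params$step_snps
    }
    keep_all <- c(keep_all, cols[keep])
  }
  sort(keep_all)
}

#' SNP-based inbreeding coefficient F_snp
#'
#' Method-of-moments excess-homozygosity estimator (the conventional
#' `--het`-style statistic): per sample,
#' `F = (O_hom - E_hom) / (N - E_hom)` where `E_hom` sums
#' `1 - 2 p (1 - p) n/(n - 1)` over the SNPs non-missing in that sample, with
#' `p` the cohort allele frequency and `n` the non-missing allele count at
#' the SNP. SNPs with fewer than two non-missing alleles are excluded.
#'
#' @param genotypes A (pruned) [geno_matrix()].
#' @return Tibble `sample`, `observed_hom`, `expected_hom`, `n_nonmissing`,
#'   `f_snp`.
#' @export
compute_fsnp <- function(genotypes) {
  d <- genotypes$dosage
  n_allele <- 2 * colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / n_allele
  usable <- n_allele >= 2
  eh_snp <- 1 - 2 * p * (1 - p) * n_allele / (n_allele - 1)
  purrr::map_dfr(rownames(d), function(s) {
    ok <- !is.na(d[s, ]) & usable
    obs <- sum(d[s, ok] != 1)
    exp_h <- sum(eh_snp[ok])
    nn <- sum(ok)
    f <- if (nn - exp_h > 0) (obs - exp_h) / (nn - exp_h) else NA_real_
    tibble::tibble(sample = s, observed_hom = obs, expected_hom = exp_h,
                   n_nonmissing = nn, f_snp = f)
  })
}

#' LD decay curve
#'
#' Scores every intra-chromosomal SNP pair within `max_dist` and averages
#' r-squared in non-overlapping distance bins of width `step` (midpoints
#' reported).
#'
#' @param genotypes A [geno_matrix()].
#' @param max_dist Maximum pair distance in bp (default 20 kb).
#' @param step Distance-bin width in bp (default 5 kb).
#' @return Tibble `dist_mid`, `mean_r2`, `n_pairs`; zero rows when no pair
#'   qualifies.
#' @export
ld_decay_curve <- function(genotypes, max_dist = 20000, step = 5000) {
  v <- genotypes$variants
  d <- genotypes$dosage
  dist <- double(0); r2 <- double(0)
  for (ch in unique(v$chrom)) {
    cols <- which(v$chrom == ch)
    pos <- v$pos[cols]
    for (i in seq_along(cols)) {
      j <- i + 1L
      while (j <= length(cols) && pos[j] - pos[i] <= max_dist) {
        val <- pairwise_r2(d[, cols[i]], d[, cols[j]])
        if (!is.na(val)) {
          dist <- c(dist, pos[j] - pos[i])
          r2 <- c(r2, val)
        }
        j <- j + 1L
      }
    }
  }
  if (!length(dist)) {
    return(tibble::tibble(dist_mid = double(), mean_r2 = double(),
                          n_pairs = integer()))
  }
  bin <- pmin(floor(dist / step), ceiling(max_dist / step) - 1)
  tibble::tibble(bin = bin, r2 = r2) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(dist_mid = (unique(bin) + 0.5) * step,
                     mean_r2 = mean(r2), n_pairs = dplyr::n(),
                     .groups = "drop") |>
    dplyr::select(dist_mid, mean_r2, n_pairs)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum p_k (1 - p_k))` where `Z` is the dosage matrix with
#' each column centred by twice its allele frequency. Missing dosages are
#' mean-imputed per SNP; monomorphic SNPs are excluded.
#'
#' @param genotypes A QC-filtered [geno_matrix()].
#' @return A symmetric N x N matrix with sample ids as dimnames, class `grm`.
#' @export
compute_grm <- function(genotypes) {
  d <- genotypes$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic", call. = FALSE)
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  for (k in which(colSums(is.na(d)) > 0)) {
    d[is.na(d[, k]), k] <- 2 * p[k]
  }
  Z <- sweep(d, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(genotypes$dosage), rownames(genotypes$dosage))
  class(G) <- c("grm", class(G))
  G
}

#' Write a GRM as a symmetric text matrix
#'
#' First line holds the sample ids (tab-separated); following lines the
#' matrix rows.
#'
#' @param G A matrix from [compute_grm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grm <- function(G, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(rownames(G), collapse = "\t"), con, sep = "\n")
  writeLines(apply(unclass(G), 1, function(r) {
    paste(format(r, digits = 10, trim = TRUE), collapse = "\t")
  }), con, sep = "\n")
  invisible(path)
}
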