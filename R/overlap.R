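#' Maximal-coverage ("complete overlap") ROH regions
#'
#' Sweeps the segment endpoints to compute, at every position of the query
#' interval, how many distinct samples have at least one ROH covering it
#' (per-sample segments are merged first so a sample counts once per
#' position). Returns the maximal interval(s) attaining the maximum depth.
#'
#' @param segments ROH tibble (`sample`, `chrom`, `start`, `end`).
#' @param chrom Chromosome of the query (required when `segments` spans
#'   several chromosomes).
#' @param region Optional `c(start, end)` restricting the sweep.
#' @return Tibble `chrom`, `start`, `end`, `n_samples`, `samples`
#'   (comma-separated covering sample ids); zero rows for empty input.
#' @export
max_overlap_region <- function(segments, chrom = NULL, region = NULL) {
  if (is.null(chrom)) {
    ch <- unique(segments$chrom)
    if (length(ch) > 1) stop("specify chrom for multi-chromosome input",
                             call. = FALSE)
    chrom <- ch
  }
  seg <- segments[segments$chrom == chrom, , drop = FALSE]
  if (!is.null(region)) {
    seg <- seg[seg$end >= region[1] & seg$start <= region[2], , drop = FALSE]
    seg$start <- pmax(seg$start, region[1])
    seg$end <- pmin(seg$end, region[2])
  }
  if (!nrow(seg)) {
    return(tibble::tibble(chrom = character(), start = double(),
                          end = double(), n_samples = integer(),
                          samples = character()))
  }
  merged <- seg |>
    dplyr::group_by(sample) |>
    dplyr::reframe(tibble::as_tibble(merge_intervals(start, end)))
  ev <- rbind(cbind(merged$start, 1), cbind(merged$end + 1, -1))
  ev <- ev[order(ev[, 1], -ev[, 2]), , drop = FALSE]
  pos <- unique(ev[, 1])
  depth <- cumsum(tapply(ev[, 2], factor(ev[, 1], levels = pos), sum))
  max_d <- max(depth)
  at_max <- depth == max_d
  r <- rle(as.vector(at_max))
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  out <- purrr::map_dfr(which(r$values), function(k) {
    s <- pos[starts_idx[k]]
    e <- pos[ends_idx[k] + 1L] - 1   # depth changes at the next event
    covering <- merged$sample[merged$start <= s & merged$end >= e]
    tibble::tibble(chrom = chrom, start = s, end = e,
                   n_samples = as.integer(max_d),
                   samples = paste(sort(unique(covering)), collapse = ","))
  })
  out
}

#' Group-wise LD and inbreeding curves across a region
#'
#' For each sample group and sliding window: mean pairwise r-squared among
#' the window's SNPs, and a window inbreeding coefficient
#' `F = 1 - mean(observed het) / mean(expected het)` over SNPs polymorphic in
#' the group (expected heterozygosity `2 p (1-p) n/(n-1)` from the group
#' allele frequency). Windows without polymorphic SNPs in a group yield NA.
#'
#' @param genotypes A [geno_matrix()].
#' @param chrom,start,end Query region (1-based inclusive).
#' @param groups Tibble `sample`, `group` partitioning (a subset of) the
#'   samples.
#' @param window Window width in bp (default 50 kb).
#' @param step Window step in bp (default 10 kb).
#' @return Tibble `group`, `win_mid`, `mean_r2`, `f_coef`, `n_snps`.
#' @export
region_group_curves <- function(genotypes, chrom, start, end, groups,
                                window = 50000, step = 10000) {
  stopifnot(all(c("sample", "group") %in% names(groups)))
  if (!nrow(groups)) stop("empty group table", call. = FALSE)
  v <- genotypes$variants
  cols <- which(v$chrom == chrom & v$pos >= start & v$pos <= end)
  if (!length(cols)) stop("no variants in the region", call. = FALSE)
  pos <- v$pos[cols]
  win_starts <- seq(start, max(start, end - window + 1), by = step)
  out <- list()
  for (g in unique(groups$group)) {
    ids <- groups$sample[groups$group == g]
    if (!length(ids)) stop("empty group: ", g, call. = FALSE)
    d <- genotypes$dosage[ids, cols, drop = FALSE]
    for (ws in win_starts) {
      we <- ws + window - 1
      in_w <- which(pos >= ws & pos <= we)
      mean_r2 <- NA_real_
      f_coef <- NA_real_
      if (length(in_w)) {
        dw <- d[, in_w, drop = FALSE]
        n_nm <- colSums(!is.na(dw))
        p <- colSums(dw, na.rm = TRUE) / (2 * n_nm)
        poly <- !is.na(p) & p > 0 & p < 1 & n_nm >= 2
        if (any(poly)) {
          o_het <- colMeans(dw[, poly, drop = FALSE] == 1, na.rm = TRUE)
          nn <- 2 * n_nm[poly]
          e_het <- 2 * p[poly] * (1 - p[poly]) * nn / (nn - 1)
          f_coef <- 1 - mean(o_het) / mean(e_het)
        }
        if (length(in_w) >= 2) {
          vals <- double(0)
          for (i in seq_len(length(in_w) - 1L)) {
            for (j in seq(i + 1L, length(in_w))) {
              r2 <- pairwise_r2(dw[, i], dw[, j])
              if (!is.na(r2)) vals <- c(vals, r2)
            }
          }
          if (length(vals)) mean_r2 <- mean(vals)
        }
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        group = g, win_mid = (ws + we) / 2, mean_r2 = mean_r2,
        f_coef = f_coef, n_snps = length(in_w))
    }
  }
  dplyr::bind_rows(out)
}

#' Cross-cohort confirmation of an overlap region
#'
#' Counts, in a primary and a validation segment set, how many samples carry
#' at least one ROH overlapping the query region.
#'
#' @param segments_primary,segments_validation ROH tibbles.
#' @param chrom,start,end Query region.
#' @return Tibble `cohort`, `n_samples` (with any segment anywhere),
#'   `n_with_segment` (with a segment overlapping the region).
#' @export
confirm_overlap <- function(segments_primary, segments_validation,
                            chrom, start, end) {
  count_one <- function(seg, name) {
    hit <- seg$chrom == chrom & seg$end >= start & seg$start <= end
    tibble::tibble(cohort = name,
                   n_samples = length(unique(seg$sample)),
                   n_with_segment = length(unique(seg$sample[hit])))
  }
  dplyr::bind_rows(count_one(segments_primary, "primary"),
                   count_one(segments_validation, "validation"))
}
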