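#' Extended haplotype homozygosity around a core SNP
#'
#' EHH at offset x is the probability that two random carriers of the core
#' allele are identical over every SNP from the core out to x:
#' `sum_g C(n_g, 2) / C(n, 2)` over groups of identical extended haplotypes.
#' Ancestral allele is the REF (0) allele by default; `allele = "derived"`
#' selects the ALT (1) carriers.
#'
#' @param panel A [hap_panel()].
#' @param core Variant column index of the core SNP.
#' @param allele `"derived"` or `"ancestral"`.
#' @return Tibble `pos`, `offset` (bp, negative upstream), `ehh`, covering
#'   the core's chromosome; `NULL` semantics: fewer than 2 carriers is an
#'   error (skip such cores upstream).
#' @export
ehh <- function(panel, core, allele = c("derived", "ancestral")) {
  allele <- match.arg(allele)
  av <- if (allele == "derived") 1L else 0L
  v <- panel$variants
  ch <- v$chrom[core]
  cols <- which(v$chrom == ch)
  core_local <- match(core, cols)
  H <- panel$haps[, cols, drop = FALSE]
  carriers <- which(H[, core_local] == av)
  if (length(carriers) < 2) {
    stop("fewer than 2 carriers of the ", allele, " allele", call. = FALSE)
  }
  right <- ehh_walk(H, core_local, carriers, +1L)
  left <- ehh_walk(H, core_local, carriers, -1L)
  pos <- v$pos[cols]
  at <- c(rev(left$idx), core_local, right$idx)
  at_pos <- pos[at]
  at_offset <- at_pos - pos[core_local]
  tibble::tibble(
    pos = at_pos,
    offset = at_offset,
    ehh = c(rev(left$ehh), 1, right$ehh)
  )
}

# Stepwise EHH in one direction; stops early when EHH < stop_below (if set)
# and, when pos/max_extend are given, one SNP past the extension cap.
ehh_walk <- function(H, core_local, carriers, dir, stop_below = NULL,
                     pos = NULL, max_extend = NULL) {
  n <- length(carriers)
  denom <- choose(n, 2)
  g <- rep(1L, n)
  idx <- integer(0); vals <- double(0)
  j <- core_local + dir
  n_col <- ncol(H)
  while (j >= 1L && j <= n_col) {
    key <- g * 2L + H[carriers, j]
    g <- match(key, unique(key))
    tab <- tabulate(g)
    e <- sum(choose(tab, 2)) / denom
    idx <- c(idx, j); vals <- c(vals, e)
    if (!is.null(stop_below) && e < stop_below) break
    if (e == 0) break
    if (!is.null(max_extend) && abs(pos[j] - pos[core_local]) > max_extend) {
      break
    }
    j <- j + dir
  }
  list(idx = idx, ehh = vals)
}

# Trapezoidal integral of EHH over physical distance for one allele class.
# Returns NA if a gap > max_gap is hit, or the chromosome edge is reached
# before EHH drops below cutoff. Integration is truncated (score kept) when
# the extension exceeds max_extend bp from the core, as selection-scan tools
# conventionally do on long shared haplotypes.
ihh_one_class <- function(H, pos, core_local, carriers, cutoff, max_gap,
                          max_extend = 1e6) {
  total <- 0
  for (dir in c(-1L, 1L)) {
    walk <- ehh_walk(H, core_local, carriers, dir, stop_below = cutoff,
                     pos = pos, max_extend = max_extend)
    e_prev <- 1
    p_prev <- pos[core_local]
    reached <- FALSE
    if (length(walk$idx)) {
      for (k in seq_along(walk$idx)) {
        p_cur <- pos[walk$idx[k]]
        if (abs(p_cur - pos[core_local]) > max_extend) {
          reached <- TRUE   # truncate the integral at the extension cap
          break
        }
        if (abs(p_cur - p_prev) > max_gap) return(NA_real_)
        e_cur <- walk$ehh[k]
        total <- total + (e_prev + e_cur) / 2 * abs(p_cur - p_prev)
        if (e_cur < cutoff) { reached <- TRUE; break }
        e_prev <- e_cur
        p_prev <- p_cur
      }
    }
    if (!reached) return(NA_real_)   # ran off the chromosome still above cutoff
  }
  total
}

#' Unstandardized iHS at one core SNP
#'
#' `ln(iHH_derived / iHH_ancestral)` where iHH is the trapezoidal integral of
#' EHH over physical distance, extended in both directions until EHH falls
#' below `ehh_cutoff`. The core is undefined (NA) when its MAF is below
#' `min_maf`, either allele has fewer than 2 carriers, an inter-SNP gap
#' exceeds `max_gap` before the cutoff is reached, or a chromosome edge is
#' hit first. On long shared haplotypes the integral is truncated at
#' `max_extend` bp per side (score kept), the conventional cap.
#'
#' @param panel A [hap_panel()].
#' @param core Variant column index.
#' @param ehh_cutoff EHH truncation level (default 0.05).
#' @param max_gap Maximum tolerated inter-SNP gap in bp (default 200 kb).
#' @param min_maf Minimum core minor allele frequency (default 0.01).
#' @param max_extend Maximum integration distance per side in bp (default
#'   1 Mb).
#' @return A single numeric value or `NA`.
#' @export
ihs_unstandardized <- function(panel, core, ehh_cutoff = 0.05,
                               max_gap = 200000, min_maf = 0.01,
                               max_extend = 1e6) {
  v <- panel$variants
  ch <- v$chrom[core]
  cols <- which(v$chrom == ch)
  core_local <- match(core, cols)
  H <- panel$haps[, cols, drop = FALSE]
  pos <- v$pos[cols]
  daf <- mean(H[, core_local])
  if (min(daf, 1 - daf) < min_maf) return(NA_real_)
  der <- which(H[, core_local] == 1L)
  anc <- which(H[, core_local] == 0L)
  if (length(der) < 2 || length(anc) < 2) return(NA_real_)
  ihh_d <- ihh_one_class(H, pos, core_local, der, ehh_cutoff, max_gap,
                         max_extend)
  ihh_a <- ihh_one_class(H, pos, core_local, anc, ehh_cutoff, max_gap,
                         max_extend)
  if (is.na(ihh_d) || is.na(ihh_a) || ihh_a == 0 || ihh_d == 0) {
    return(NA_real_)
  }
  log(ihh_d / ihh_a)
}

#' Genome-wide unstandardized iHS track
#'
#' Applies [ihs_unstandardized()] at every SNP.
#'
#' @inheritParams ihs_unstandardized
#' @return Tibble `chrom`, `pos`, `daf`, `ihs_raw` (NA where undefined).
#' @export
ihs_scan <- function(panel, ehh_cutoff = 0.05, max_gap = 200000,
                     min_maf = 0.01, max_extend = 1e6) {
  v <- panel$variants
  daf <- colMeans(panel$haps)
  raw <- vapply(seq_len(nrow(v)), function(i) {
    ihs_unstandardized(panel, i, ehh_cutoff, max_gap, min_maf, max_extend)
  }, 0)
  tibble::tibble(chrom = v$chrom, pos = v$pos, daf = daf, ihs_raw = raw)
}

#' Standardize an iHS track within derived-allele-frequency bins
#'
#' SNPs are binned by derived allele frequency into `n_bins` equal-width
#' bins; within each bin raw scores are centred and scaled to unit SD.
#' Bins with fewer than 2 defined scores or zero SD are left unstandardized
#' and flagged.
#'
#' @param track Tibble from [ihs_scan()].
#' @param n_bins Number of frequency bins (default 100).
#' @return The track with added `freq_bin`, `ihs_std`, `bin_flagged`.
#' @export
standardize_ihs <- function(track, n_bins = 100) {
  if (!any(!is.na(track$ihs_raw))) {
    stop("no defined unstandardized scores", call. = FALSE)
  }
  bin <- pmin(floor(track$daf * n_bins), n_bins - 1L) + 1L
  std <- rep(NA_real_, nrow(track))
  flagged <- rep(FALSE, nrow(track))
  for (b in unique(bin)) {
    sel <- which(bin == b & !is.na(track$ihs_raw))
    if (!length(sel)) next
    mu <- mean(track$ihs_raw[sel])
    sd_ <- stats::sd(track$ihs_raw[sel])
    if (length(sel) < 2 || sd_ == 0) {
      std[sel] <- track$ihs_raw[sel]
      flagged[sel] <- TRUE
    } else {
      std[sel] <- (track$ihs_raw[sel] - mu) / sd_
    }
  }
  track$freq_bin <- bin
  track$ihs_std <- std
  track$bin_flagged <- flagged
  track
}

#' Flag candidate sweep windows from an iHS track
#'
#' Tiles each chromosome with non-overlapping windows, computes per window
#' the proportion of SNPs with `|iHS| > abs_cut`, drops windows with fewer
#' than `min_snps` scored SNPs, and flags windows whose proportion reaches
#' the empirical `1 - top_frac` quantile (inverse-ECDF; ties at the
#' threshold are included).
#'
#' @param track Standardized track from [standardize_ihs()].
#' @param window Window width in bp (default 100 kb).
#' @param min_snps Minimum scored SNPs per retained window (default 10).
#' @param abs_cut |iHS| cut-off defining an extreme SNP (default 2).
#' @param top_frac Flagged fraction (default 0.01).
#' @return Tibble `chrom`, `start`, `end`, `n_snps`, `prop_extreme`,
#'   `flagged`.
#' @export
sweep_windows <- function(track, window = 100000, min_snps = 10,
                          abs_cut = 2, top_frac = 0.01) {
  t <- track[!is.na(track$ihs_std), , drop = FALSE]
  if (!nrow(t)) {
    return(tibble::tibble(chrom = character(), start = double(),
                          end = double(), n_snps = integer(),
                          prop_extreme = double(), flagged = logical()))
  }
  t$win <- floor((t$pos - 1) / window)
  agg <- t |>
    dplyr::group_by(chrom, win) |>
    dplyr::summarise(n_snps = dplyr::n(),
                     prop_extreme = mean(abs(ihs_std) > abs_cut),
                     .groups = "drop") |>
    dplyr::filter(n_snps >= min_snps)
  if (!nrow(agg)) {
    return(tibble::tibble(chrom = character(), start = double(),
                          end = double(), n_snps = integer(),
                          prop_extreme = double(), flagged = logical()))
  }
  sorted <- sort(agg$prop_extreme)
  thr <- sorted[ceiling((1 - top_frac) * length(sorted))]
  tibble::tibble(chrom = agg$chrom, start = agg$win * window + 1,
                 end = (agg$win + 1) * window, n_snps = agg$n_snps,
                 prop_extreme = agg$prop_extreme,
                 flagged = agg$prop_extreme >= thr)
}

#' Flag the per-SNP top fraction of |iHS|
#'
#' Second flagging mode: marks SNPs whose |standardized iHS| reaches the
#' empirical `1 - top_frac` quantile of all defined |iHS| values.
#'
#' @param track Standardized track.
#' @param top_frac Flagged fraction (default 0.01).
#' @return The track with added logical `top_snp` (NA scores are `FALSE`)
#'   and the threshold in `attr(, "abs_ihs_threshold")`.
#' @export
ihs_top_snps <- function(track, top_frac = 0.01) {
  a <- abs(track$ihs_std)
  sorted <- sort(a[!is.na(a)])
  thr <- sorted[ceiling((1 - top_frac) * length(sorted))]
  track$top_snp <- !is.na(a) & a >= thr
  attr(track, "abs_ihs_threshold") <- thr
  track
}
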