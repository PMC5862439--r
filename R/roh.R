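#' Parameters for the run-based ROH caller
#'
#' The caller scans each sample's sorted genotype track and extends maximal
#' runs of homozygous calls, tolerating a bounded number of heterozygous and
#' missing calls per run and breaking a run wherever two consecutive SNPs are
#' further apart than `max_gap`.
#'
#' @param min_snps Minimum homozygous SNPs in a reported run.
#' @param max_het_in_run Heterozygous calls tolerated inside one run.
#' @param max_missing_in_run Missing calls tolerated inside one run.
#' @param max_gap Maximum distance (bp) between consecutive SNPs within a run.
#' @param min_length Minimum segment length (bp) at call time; length
#'   filtering to the autozygosity threshold is usually applied afterwards
#'   with [filter_autozygous()].
#' @return A list of class `roh_call_params`.
#' @export
roh_call_params <- function(min_snps = 20, max_het_in_run = 0,
                            max_missing_in_run = 2, max_gap = 500000,
                            min_length = 0) {
  stopifnot(min_snps >= 1, max_het_in_run >= 0, max_missing_in_run >= 0,
            max_gap > 0, min_length >= 0)
  structure(list(min_snps = min_snps, max_het_in_run = max_het_in_run,
                 max_missing_in_run = max_missing_in_run, max_gap = max_gap,
                 min_length = min_length),
            class = "roh_call_params")
}

# Greedy left-to-right maximal-run caller on one chromosome track.
# cls: 0 = homozygous, 1 = heterozygous, 2 = missing.
roh_runs_track <- function(pos, cls, params) {
  n <- length(pos)
  out_start <- double(0); out_end <- double(0); out_n <- integer(0)
  i <- 1L
  while (i <= n) {
    if (cls[i] != 0L) { i <- i + 1L; next }
    het <- 0L; mis <- 0L; j <- i
    while (j < n) {
      nxt <- cls[j + 1L]
      if (pos[j + 1L] - pos[j] > params$max_gap) break
      if (nxt == 1L && het + 1L > params$max_het_in_run) break
      if (nxt == 2L && mis + 1L > params$max_missing_in_run) break
      j <- j + 1L
      if (nxt == 1L) het <- het + 1L else if (nxt == 2L) mis <- mis + 1L
    }
    jh <- j
    while (cls[jh] != 0L) jh <- jh - 1L
    n_hom <- sum(cls[i:jh] == 0L)
    if (n_hom >= params$min_snps &&
        (pos[jh] - pos[i] + 1) >= params$min_length) {
      out_start <- c(out_start, pos[i])
      out_end <- c(out_end, pos[jh])
      out_n <- c(out_n, n_hom)
    }
    i <- j + 1L
  }
  tibble::tibble(start = out_start, end = out_end, n_snps = out_n)
}

#' Call runs of homozygosity
#'
#' Deterministic run-based ROH detection (in the spirit of sliding-run
#' callers, not an HMM): per sample and chromosome, maximal runs of
#' consecutive homozygous calls are extended left to right under the
#' heterozygote/missing budgets and the inter-SNP gap rule of
#' [roh_call_params()]. Reported segments start and end at homozygous SNPs.
#'
#' @param genotypes A [geno_matrix()].
#' @param params A [roh_call_params()].
#' @return Tibble `sample`, `chrom`, `start`, `end`, `n_snps`, `length`
#'   (end - start + 1).
#' @export
call_roh <- function(genotypes, params = roh_call_params()) {
  stopifnot(inherits(genotypes, "geno_matrix"),
            inherits(params, "roh_call_params"))
  v <- genotypes$variants
  samples <- rownames(genotypes$dosage)
  chroms <- unique(v$chrom)
  res <- list()
  for (ch in chroms) {
    cols <- which(v$chrom == ch)
    pos <- v$pos[cols]
    for (s in samples) {
      d <- genotypes$dosage[s, cols]
      cls <- integer(length(d))
      cls[is.na(d)] <- 2L
      cls[!is.na(d) & d == 1] <- 1L
      runs <- roh_runs_track(pos, cls, params)
      if (nrow(runs)) {
        runs$sample <- s
        runs$chrom <- ch
        res[[length(res) + 1L]] <- runs
      }
    }
  }
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) {
    return(tibble::tibble(sample = character(), chrom = character(),
                          start = double(), end = double(),
                          n_snps = integer(), length = double()))
  }
  out$length <- out$end - out$start + 1
  out[, c("sample", "chrom", "start", "end", "n_snps", "length")]
}

#' Keep segments long enough to be called autozygous
#'
#' Retains segments with `length >= min_length`; segments exactly at the
#' threshold are kept (only strictly shorter ones are dropped).
#'
#' @param segments ROH tibble as from [call_roh()].
#' @param min_length Length threshold in bp (default 500 kb).
#' @return The filtered tibble.
#' @export
filter_autozygous <- function(segments, min_length = 500000) {
  segments[segments$end - segments$start + 1 >= min_length, , drop = FALSE]
}

#' ROH summary across a grid of length thresholds
#'
#' For each threshold: mean per-sample segment count, mean per-sample total
#' length, and carrier frequency (fraction of samples with at least one
#' qualifying segment). Samples with no qualifying segment contribute zeros.
#'
#' @param segments ROH tibble.
#' @param thresholds Numeric vector of length thresholds in bp (default 0 to
#'   2000 kb in 100 kb steps).
#' @param samples Character vector of all cohort samples (defaults to the
#'   samples present in `segments`; pass explicitly so segment-free samples
#'   are counted).
#' @return Tibble `threshold`, `mean_count`, `mean_total_length`,
#'   `carrier_frequency`.
#' @export
threshold_profile <- function(segments, thresholds = seq(0, 2e6, by = 1e5),
                              samples = NULL) {
  if (!length(thresholds)) stop("empty threshold list", call. = FALSE)
  if (is.null(samples)) samples <- unique(segments$sample)
  n <- length(samples)
  if (n < 1) stop("no samples", call. = FALSE)
  len <- segments$end - segments$start + 1
  purrr::map_dfr(thresholds, function(t) {
    q <- segments[len >= t, , drop = FALSE]
    cnt <- table(factor(q$sample, levels = samples))
    tot <- tapply(q$end - q$start + 1, factor(q$sample, levels = samples),
                  sum, default = 0)
    tibble::tibble(threshold = t,
                   mean_count = mean(as.numeric(cnt)),
                   mean_total_length = mean(as.numeric(tot)),
                   carrier_frequency = mean(as.numeric(cnt) > 0))
  })
}

merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- double(0); out_e <- double(0)
  if (length(start) > 1) {
    for (i in 2:length(start)) {
      if (start[i] <= me + 1) {
        me <- max(me, end[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Genome-wide autozygosity coefficient F_roh
#'
#' F_roh = total length of (merged) qualifying ROH divided by the total
#' autosome length from `chrom_sizes`.
#'
#' @param segments Length-filtered ROH tibble.
#' @param chrom_sizes Tibble `chrom`, `length` as from [load_chrom_sizes()].
#' @param samples Optional full cohort sample vector (segment-free samples
#'   get F_roh = 0).
#' @return Tibble `sample`, `f_roh`, `total_roh_bp`, `n_segments`.
#' @export
compute_froh <- function(segments, chrom_sizes, samples = NULL) {
  if (is.null(samples)) samples <- unique(segments$sample)
  unknown <- setdiff(unique(segments$chrom), chrom_sizes$chrom)
  if (length(unknown)) {
    stop("segment(s) on chromosome(s) absent from chrom_sizes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  genome_bp <- sum(chrom_sizes$length)
  per_sample <- function(s) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    if (!nrow(seg)) {
      return(tibble::tibble(sample = s, f_roh = 0, total_roh_bp = 0,
                            n_segments = 0L))
    }
    tot <- 0
    for (ch in unique(seg$chrom)) {
      m <- merge_intervals(seg$start[seg$chrom == ch], seg$end[seg$chrom == ch])
      tot <- tot + sum(m$end - m$start + 1)
    }
    tibble::tibble(sample = s, f_roh = tot / genome_bp, total_roh_bp = tot,
                   n_segments = nrow(seg))
  }
  purrr::map_dfr(samples, per_sample)
}

#' Compare group autozygosity by Wilcoxon rank-sum test
#'
#' @param selected,unselected Numeric vectors of per-sample F_roh (or any
#'   per-sample statistic).
#' @return One-row tibble: `mean_selected`, `mean_unselected`, `statistic`
#'   (rank-sum W), `p_value` (two-sided).
#' @export
froh_group_comparison <- function(selected, unselected) {
  if (!length(selected) || !length(unselected)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  # ties are routine in F_roh data; the tie-corrected normal approximation
  # is used automatically in that case
  wt <- suppressWarnings(
    stats::wilcox.test(selected, unselected, alternative = "two.sided"))
  tibble::tibble(mean_selected = mean(selected),
                 mean_unselected = mean(unselected),
                 statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Subsample the selected group and re-test against the unselected group
#'
#' Draws `reps` subsets of size `k` without replacement from the selected
#' group; records each subset's mean F_roh and its Wilcoxon rank-sum p-value
#' against the unselected group. Deterministic under `seed`.
#'
#' @param selected,unselected Numeric vectors of per-sample F_roh.
#' @param k Subset size (default 10).
#' @param reps Number of subsets (default 1000).
#' @param seed Integer seed.
#' @return Tibble `rep`, `mean_froh`, `p_value`.
#' @export
froh_resampling <- function(selected, unselected, k = 10, reps = 1000,
                            seed = 1L) {
  if (k > length(selected)) {
    stop("k exceeds the selected group size", call. = FALSE)
  }
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(reps), function(r) {
      sub <- sample(selected, k)
      wt <- suppressWarnings(
        stats::wilcox.test(sub, unselected, alternative = "two.sided"))
      tibble::tibble(rep = r, mean_froh = mean(sub), p_value = wt$p.value)
    })
  })
}
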