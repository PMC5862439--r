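#' Plot the ROH length-threshold profile
#'
#' Mean per-sample segment count, mean total length and carrier frequency as
#' functions of the length threshold.
#'
#' @param profile Tibble from [threshold_profile()].
#' @return A ggplot object (facetted, one panel per statistic).
#' @export
plot_threshold_profile <- function(profile) {
  long <- tidyr::pivot_longer(profile, -threshold,
                              names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(threshold / 1e3, value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "ROH length threshold (kb)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Compare per-group autozygosity distributions
#'
#' @param froh Tibble from [compute_froh()].
#' @param meta Sample metadata with `sample` and `selected`.
#' @return A ggplot boxplot of F_roh by group.
#' @export
plot_froh_groups <- function(froh, meta) {
  d <- dplyr::inner_join(froh, meta, by = "sample")
  d$group <- ifelse(d$selected, "selected", "unselected")
  ggplot2::ggplot(d, ggplot2::aes(group, f_roh)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = expression(F[roh])) +
    ggplot2::theme_minimal()
}

#' Plot a standardized iHS track
#'
#' @param track Tibble from [standardize_ihs()].
#' @param abs_cut Reference |iHS| line (default 2).
#' @return A ggplot of |standardized iHS| along the genome, one facet per
#'   chromosome.
#' @export
plot_ihs_track <- function(track, abs_cut = 2) {
  t <- track[!is.na(track$ihs_std), ]
  ggplot2::ggplot(t, ggplot2::aes(pos / 1e6, abs(ihs_std))) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = abs_cut, linetype = 2,
                        colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "|standardized iHS|") +
    ggplot2::theme_minimal()
}

#' Plot per-bin association results along the genome
#'
#' @param assoc Tibble from the pipeline's Analysis 1 or Analysis 2 table
#'   (`bin_id`, `chrom`, `start`, `p_value`).
#' @param alpha Significance line (default 0.01).
#' @return A ggplot of -log10 p per bin.
#' @export
plot_bin_association <- function(assoc, alpha = 0.01) {
  a <- assoc[!is.na(assoc$p_value), ]
  ggplot2::ggplot(a, ggplot2::aes(bin_id, -log10(p_value), colour = chrom)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = "bin", y = expression(-log[10](p))) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a REML mixed-model fit
#'
#' @param x An `lmm_fit` from [reml_fit()].
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `se`, `statistic`, `p_value`.
#' @export
tidy.lmm_fit <- function(x, ...) {
  x$beta
}

#' One-row summary of a REML mixed-model fit
#'
#' @param x An `lmm_fit` from [reml_fit()].
#' @param ... Unused.
#' @return Tibble `sigma2_g`, `sigma2_e`, `delta`, `heritability`
#'   (sigma2_g / (sigma2_g + sigma2_e)), `loglik_reml`, `n`.
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e,
                 delta = x$delta,
                 heritability = x$sigma2_g / (x$sigma2_g + x$sigma2_e),
                 loglik_reml = x$loglik_reml, n = x$n)
}
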