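#' Tile chromosomes into fixed-width bins
#'
#' Per chromosome: `[1, w]`, `[w+1, 2w]`, ..., with the final bin truncated
#' at the chromosome length.
#'
#' @param chrom_sizes Tibble `chrom`, `length`.
#' @param width Bin width in bp (default 10 Mb).
#' @return Tibble `bin_id`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
make_bins <- function(chrom_sizes, width = 1e7) {
  if (width <= 0) stop("bin width must be positive", call. = FALSE)
  out <- purrr::map_dfr(seq_len(nrow(chrom_sizes)), function(i) {
    L <- chrom_sizes$length[i]
    n <- ceiling(L / width)
    tibble::tibble(chrom = chrom_sizes$chrom[i],
                   start = (seq_len(n) - 1) * width + 1,
                   end = pmin(seq_len(n) * width, L))
  })
  out$bin_id <- seq_len(nrow(out))
  out[, c("bin_id", "chrom", "start", "end")]
}

#' Per-sample, per-bin ROH status and length
#'
#' `roh_length` is the total overlap (bp) between a sample's segments and the
#' bin; a segment spanning a bin boundary contributes to both bins.
#' `status = 1` iff the overlap is at least 1 bp.
#'
#' @param segments Length-filtered ROH tibble.
#' @param bins Tibble from [make_bins()].
#' @param samples Optional full cohort sample vector (zero rows added for
#'   samples without segments).
#' @return Long tibble `sample`, `bin_id`, `chrom`, `start`, `end`,
#'   `roh_length`, `status`, complete over samples x bins.
#' @export
bin_roh_matrix <- function(segments, bins, samples = NULL) {
  if (is.null(samples)) samples <- unique(segments$sample)
  if (nrow(segments)) {
    chrom_max <- tapply(bins$end, bins$chrom, max)
    bad <- !(segments$chrom %in% bins$chrom) |
      segments$end > chrom_max[segments$chrom] | segments$start < 1
    if (any(bad)) {
      stop("segment(s) outside the binned genome", call. = FALSE)
    }
  }
  grid <- tidyr::expand_grid(sample = samples, bin_id = bins$bin_id)
  if (nrow(segments)) {
    ov <- dplyr::inner_join(segments, bins, by = "chrom",
                            suffix = c("", ".bin"),
                            relationship = "many-to-many")
    ov$overlap <- pmin(ov$end, ov$end.bin) - pmax(ov$start, ov$start.bin) + 1
    ov <- ov[ov$overlap > 0, c("sample", "bin_id", "overlap")]
    lens <- ov |>
      dplyr::group_by(sample, bin_id) |>
      dplyr::summarise(roh_length = sum(overlap), .groups = "drop")
  } else {
    lens <- tibble::tibble(sample = character(), bin_id = integer(),
                           roh_length = double())
  }
  out <- dplyr::left_join(grid, lens, by = c("sample", "bin_id"))
  out$roh_length[is.na(out$roh_length)] <- 0
  out$status <- as.integer(out$roh_length > 0)
  dplyr::left_join(out, bins, by = "bin_id")[
    , c("sample", "bin_id", "chrom", "start", "end", "roh_length", "status")]
}

#' Drop bins carrying no information
#'
#' Removes bins where every sample has an identical ROH length (including
#' the all-zero case).
#'
#' @param bin_matrix Long tibble from [bin_roh_matrix()].
#' @return The filtered tibble.
#' @export
filter_uninformative_bins <- function(bin_matrix) {
  keep <- bin_matrix |>
    dplyr::group_by(bin_id) |>
    dplyr::summarise(informative = dplyr::n_distinct(roh_length) > 1,
                     .groups = "drop")
  out <- dplyr::semi_join(bin_matrix, keep[keep$informative, ], by = "bin_id")
  if (!nrow(out)) stop("no informative bins remain", call. = FALSE)
  out
}

#' Analysis 1: logistic trend of bin ROH status over selection order
#'
#' Maximum-likelihood logit fit of per-sample ROH status (0/1) on the KPN
#' selection-order number (intercept + slope); reports the slope, its Wald
#' (or likelihood-ratio) p-value, and McFadden pseudo-R-squared. Constant
#' status or complete separation flags the bin as non-converged.
#'
#' @param status 0/1 vector, one entry per selected sample.
#' @param kpn KPN numbers, same order.
#' @param test `"wald"` (default) or `"lrt"`.
#' @return One-row tibble `coefficient`, `fit_r2`, `p_value`, `significant`
#'   (p < 0.01), `converged`.
#' @export
analysis1_logistic <- function(status, kpn, test = c("wald", "lrt")) {
  test <- match.arg(test)
  stopifnot(length(status) == length(kpn))
  flagged <- tibble::tibble(coefficient = NA_real_, fit_r2 = NA_real_,
                            p_value = NA_real_, significant = NA,
                            converged = FALSE)
  if (length(unique(status)) < 2) return(flagged)
  fit <- suppressWarnings(
    stats::glm(status ~ kpn, family = stats::binomial()))
  mu <- stats::fitted(fit)
  separated <- all(abs(mu - status) < 1e-8)
  if (!fit$converged || separated) return(flagged)
  co <- summary(fit)$coefficients
  beta <- co["kpn", "Estimate"]
  if (test == "wald") {
    p <- co["kpn", "Pr(>|z|)"]
  } else {
    null_fit <- stats::glm(status ~ 1, family = stats::binomial())
    p <- stats::pchisq(as.numeric(2 * (stats::logLik(fit) -
                                         stats::logLik(null_fit))),
                       df = 1, lower.tail = FALSE)
  }
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(stats::glm(status ~ 1,
                                             family = stats::binomial())))
  tibble::tibble(coefficient = beta, fit_r2 = 1 - ll1 / ll0, p_value = p,
                 significant = p < 0.01, converged = TRUE)
}

#' REML fit of a single-kinship linear mixed model
#'
#' Fits `y = X b + g + e`, `g ~ N(0, s2g G)`, `e ~ N(0, s2e I)`, by restricted
#' maximum likelihood. The variance ratio `delta = s2g / s2e` is profiled on
#' the eigenbasis of `G` (one 1-D optimization); `b` follows by generalized
#' least squares at the optimum and each coefficient gets a Wald chi-square
#' test.
#'
#' @param y Response vector.
#' @param X Fixed-effects design matrix (full column rank, with intercept).
#' @param G Symmetric kinship matrix (ignored when `eigen_G` given).
#' @param eigen_G Optional precomputed `eigen(G, symmetric = TRUE)`; pass it
#'   when fitting many models on the same samples.
#' @param fix_delta Optionally fix the variance ratio (e.g. 0 collapses the
#'   fit to ordinary least squares).
#' @return Object of class `lmm_fit`: list with `beta` (tibble `term`,
#'   `estimate`, `se`, `statistic`, `p_value`), `sigma2_g`, `sigma2_e`,
#'   `delta`, `loglik_reml`, `n`, `p`.
#' @export
reml_fit <- function(y, X, G = NULL, eigen_G = NULL, fix_delta = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < ncol(X)) stop("X is rank-deficient", call. = FALSE)
  if (is.null(eigen_G)) {
    if (is.null(G)) stop("supply G or eigen_G", call. = FALSE)
    G <- unclass(G)
    stopifnot(nrow(G) == n, ncol(G) == n)
    if (max(abs(G - t(G))) > 1e-8) {
      stop("G is not symmetric", call. = FALSE)
    }
    eigen_G <- eigen((G + t(G)) / 2, symmetric = TRUE)
  }
  U <- eigen_G$vectors
  lam <- pmax(eigen_G$values, 0)
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  p <- ncol(X)

  reml_ll <- function(log_delta) {
    delta <- exp(log_delta)
    V <- delta * lam + 1
    w <- 1 / V
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    beta <- solve(XtWX, XtWy)
    r <- ys - Xs %*% beta
    rss <- sum(w * r^2)
    s2e <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2e) + sum(log(V)) +
              determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
  }

  if (!is.null(fix_delta)) {
    delta <- fix_delta
    ll <- if (delta > 0) reml_ll(log(delta)) else reml_ll(-Inf)
  } else {
    opt <- stats::optimize(reml_ll, interval = c(-20, 20), maximum = TRUE,
                           tol = 1e-8)
    delta <- exp(opt$maximum)
    ll <- opt$objective
    # boundary: allow exact collapse to delta = 0
    ll0 <- reml_ll(-Inf)
    if (ll0 >= ll) { delta <- 0; ll <- ll0 }
  }
  V <- delta * lam + 1
  w <- 1 / V
  XtWX <- crossprod(Xs, Xs * w)
  beta <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% beta
  s2e <- sum(w * r^2) / (n - p)
  s2g <- delta * s2e
  vcov_beta <- s2e * solve(XtWX)
  se <- unname(sqrt(diag(vcov_beta)))
  stat <- (as.numeric(beta) / se)^2
  pv <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  terms <- colnames(X)
  if (is.null(terms)) terms <- paste0("x", seq_len(p))
  structure(list(
    beta = tibble::tibble(term = terms, estimate = as.numeric(beta), se = se,
                          statistic = stat, p_value = pv),
    sigma2_g = s2g, sigma2_e = s2e, delta = delta,
    loglik_reml = as.numeric(ll), n = n, p = p
  ), class = "lmm_fit")
}

#' @exportS3Method print lmm_fit
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> n = %d, REML logLik = %.4f\n", x$n, x$loglik_reml))
  cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g (delta = %.4g)\n",
              x$sigma2_g, x$sigma2_e, x$delta))
  print(x$beta)
  invisible(x)
}

#' Analysis 2: kinship mixed model of body weight on bin ROH length
#'
#' Fixed effects: intercept, bin ROH length (bp) and rearing facility
#' (reference-coded factor; dropped when only one level remains); random
#' effect: the genomic relationship matrix. Reports the ROH-length
#' coefficient (kg per bp) and its Wald p-value. Samples with missing weight
#' are excluded (subset `eigen_G` to the complete samples before calling).
#'
#' @param roh_length Bin ROH lengths (bp), one per sample.
#' @param weight Body weight at 12 months (kg), same order.
#' @param facility Facility labels, same order.
#' @param G Kinship matrix over the same samples (or pass `eigen_G`).
#' @param eigen_G Optional precomputed eigendecomposition.
#' @return One-row tibble `coefficient`, `p_value`, `significant` (p < 0.01),
#'   `sigma2_g`, `sigma2_e`, `converged`.
#' @export
analysis2_lmm <- function(roh_length, weight, facility, G = NULL,
                          eigen_G = NULL) {
  stopifnot(length(roh_length) == length(weight),
            length(facility) == length(weight))
  if (anyNA(weight)) {
    stop("drop samples with missing weight (and subset G) before fitting",
         call. = FALSE)
  }
  if (length(unique(roh_length)) < 2) {
    return(tibble::tibble(coefficient = NA_real_, p_value = NA_real_,
                          significant = NA, sigma2_g = NA_real_,
                          sigma2_e = NA_real_, converged = FALSE))
  }
  X <- cbind(`(Intercept)` = 1, roh_length = roh_length)
  if (length(unique(facility)) > 1) {
    f <- stats::model.matrix(~ factor(facility))[, -1, drop = FALSE]
    colnames(f) <- paste0("facility", seq_len(ncol(f)))
    X <- cbind(X, f)
  }
  fit <- reml_fit(weight, X, G = G, eigen_G = eigen_G)
  row <- fit$beta[fit$beta$term == "roh_length", ]
  tibble::tibble(coefficient = row$estimate, p_value = row$p_value,
                 significant = row$p_value < 0.01, sigma2_g = fit$sigma2_g,
                 sigma2_e = fit$sigma2_e, converged = TRUE)
}

#' Per-bin change in mean ROH length between early and late groups
#'
#' Splits selected samples at a KPN cutoff (group A: KPN <= cutoff, group B:
#' KPN > cutoff) and reports `mean(B) - mean(A)` of bin ROH length.
#'
#' @param bin_matrix Long tibble from [bin_roh_matrix()] (selected samples).
#' @param kpn Named or ordered KPN vector aligned to the samples appearing
#'   in `bin_matrix` (a tibble `sample`, `kpn` is also accepted).
#' @param cutoff KPN split point (default 486).
#' @return Tibble `bin_id`, `mean_a`, `mean_b`, `change` (bp).
#' @export
group_mean_length_change <- function(bin_matrix, kpn, cutoff = 486) {
  if (is.data.frame(kpn)) {
    key <- stats::setNames(kpn$kpn, kpn$sample)
  } else if (!is.null(names(kpn))) {
    key <- kpn
  } else {
    stop("kpn must be a named vector or a sample/kpn tibble", call. = FALSE)
  }
  bm <- bin_matrix[bin_matrix$sample %in% names(key)[!is.na(key)], ]
  bm$group <- ifelse(key[bm$sample] <= cutoff, "A", "B")
  if (length(unique(bm$group)) < 2) {
    stop("one of the KPN groups is empty at this cutoff", call. = FALSE)
  }
  bm |>
    dplyr::group_by(bin_id) |>
    dplyr::summarise(
      mean_a = mean(roh_length[group == "A"]),
      mean_b = mean(roh_length[group == "B"]),
      change = mean_b - mean_a, .groups = "drop")
}

#' Spearman correlations among selection order, autozygosity and weight
#'
#' Tie-corrected Spearman rho (asymptotic p) for the three pairs
#' (KPN, F_roh), (F_roh, weight), (KPN, weight).
#'
#' @param f_roh,kpn,weight Aligned numeric vectors; rows with any NA are
#'   dropped.
#' @return Tibble `pair`, `rho`, `p_value`, `n`.
#' @export
cohort_correlations <- function(f_roh, kpn, weight) {
  ok <- !is.na(f_roh) & !is.na(kpn) & !is.na(weight)
  if (sum(ok) < 3) stop("need at least 3 complete samples", call. = FALSE)
  f_roh <- f_roh[ok]; kpn <- kpn[ok]; weight <- weight[ok]
  one <- function(name, a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(tibble::tibble(pair = name, rho = NA_real_, p_value = NA_real_,
                            n = length(a)))
    }
    ct <- suppressWarnings(
      stats::cor.test(a, b, method = "spearman", exact = FALSE))
    tibble::tibble(pair = name, rho = unname(ct$estimate),
                   p_value = ct$p.value, n = length(a))
  }
  dplyr::bind_rows(
    one("kpn_froh", kpn, f_roh),
    one("froh_weight", f_roh, weight),
    one("kpn_weight", kpn, weight)
  )
}
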