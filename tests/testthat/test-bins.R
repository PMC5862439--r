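test_that("bins tile chromosomes exactly", {
  cs <- tibble::tibble(chrom = c("1", "2"), length = c(25e6, 1e7))
  b <- make_bins(cs)
  b1 <- b[b$chrom == "1", ]
  expect_equal(b1$start, c(1, 1e7 + 1, 2e7 + 1))
  expect_equal(b1$end, c(1e7, 2e7, 25e6))
  expect_equal(nrow(b[b$chrom == "2", ]), 1)
  # total count and exact tiling
  expect_equal(nrow(b), sum(ceiling(cs$length / 1e7)))
  widths <- b |>
    dplyr::group_by(chrom) |>
    dplyr::summarise(w = sum(end - start + 1))
  expect_equal(widths$w, cs$length)
  expect_error(make_bins(cs, width = 0), "positive")
})

test_that("the bundled cattle autosomes give 269 ten-megabase bins", {
  expect_equal(nrow(make_bins(load_chrom_sizes("umd3.1_autosomes"))), 269)
})

test_that("bin ROH lengths follow interval-intersection arithmetic", {
  cs <- tibble::tibble(chrom = "1", length = 25e6)
  bins <- make_bins(cs)
  seg <- tibble::tibble(sample = c("a", "b"), chrom = "1",
                        start = c(9500001, 10000001), end = c(10600000, 2e7))
  bm <- bin_roh_matrix(seg, bins, samples = c("a", "b", "c"))
  a <- bm[bm$sample == "a", ]
  expect_equal(a$roh_length, c(500000, 600000, 0))
  expect_equal(a$status, c(1L, 1L, 0L))
  b <- bm[bm$sample == "b", ]
  expect_equal(b$roh_length, c(0, 1e7, 0))  # exact containment
  expect_equal(bm$roh_length[bm$sample == "c"], rep(0, 3))
  expect_error(bin_roh_matrix(
    tibble::tibble(sample = "a", chrom = "1", start = 1, end = 3e7),
    bins), "outside")
})

test_that("uninformative bins are removed by the equal-length rule", {
  bm <- tibble::tibble(
    sample = rep(c("a", "b", "c"), 3),
    bin_id = rep(1:3, each = 3),
    chrom = "1", start = 1, end = 10,
    roh_length = c(0, 0, 0,        # all equal zero -> drop
                   0, 0, 5000,     # keep
                   1e7, 1e7, 1e7), # equal non-zero -> drop
    status = c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
  out <- filter_uninformative_bins(bm)
  expect_equal(unique(out$bin_id), 2)
  expect_error(filter_uninformative_bins(bm[bm$bin_id == 1, ]), "remain")
})

test_that("logistic trend fit matches direct likelihood maximization", {
  # balanced null design
  st <- rep(c(0, 1), 20)
  kpn <- rep(1:20, each = 2)
  null_fit <- analysis1_logistic(st, kpn)
  expect_lt(abs(null_fit$coefficient), 0.05)
  expect_gt(null_fit$p_value, 0.9)

  # 12-sample toy vs Nelder-Mead on the exact Bernoulli log-likelihood
  st <- c(0, 0, 1, 0, 1, 0, 1, 1, 0, 1, 1, 1)
  kpn <- c(3, 8, 11, 15, 21, 24, 30, 33, 38, 42, 47, 55)
  got <- analysis1_logistic(st, kpn)
  nll <- function(par) {
    eta <- par[1] + par[2] * kpn
    -sum(st * eta - log(1 + exp(eta)))
  }
  opt <- stats::optim(c(0, 0), nll, control = list(reltol = 1e-14,
                                                   maxit = 5000))
  expect_equal(got$coefficient, opt$par[2], tolerance = 1e-4)
  ll0 <- -nll(c(stats::qlogis(mean(st)), 0))
  expect_equal(got$fit_r2, 1 - (-opt$value) / ll0, tolerance = 1e-6)

  # flagged cases: constant status and complete separation
  expect_false(analysis1_logistic(rep(1, 12), kpn)$converged)
  expect_false(analysis1_logistic(as.integer(kpn > 25), kpn)$converged)

  # LRT mode agrees with a hand-built deviance test
  lrt <- analysis1_logistic(st, kpn, test = "lrt")
  p_hand <- stats::pchisq(2 * ((-opt$value) - ll0), 1, lower.tail = FALSE)
  expect_equal(lrt$p_value, p_hand, tolerance = 1e-6)
})

test_that("logistic slope rescales exactly under affine KPN recoding", {
  st <- c(0, 0, 1, 0, 1, 1, 0, 1, 1, 1)
  kpn <- c(2, 5, 7, 11, 13, 17, 19, 23, 29, 31)
  base <- analysis1_logistic(st, kpn)
  rec <- analysis1_logistic(st, 3 * kpn + 100)
  expect_equal(rec$coefficient, base$coefficient / 3, tolerance = 1e-8)
  expect_equal(rec$p_value, base$p_value, tolerance = 1e-8)
})

test_that("REML optimum matches a dense grid on the restricted likelihood", {
  withr::with_seed(101, {
    for (rep in 1:4) {
      n <- 20
      A <- matrix(stats::rnorm(n * n), n)
      G <- crossprod(A) / n
      X <- cbind(1, stats::rnorm(n))
      g <- t(chol(G + diag(1e-8, n))) %*% stats::rnorm(n)
      y <- X %*% c(2, 1) + g + stats::rnorm(n)
      fit <- reml_fit(as.numeric(y), X, G = G)
      grid <- exp(seq(-12, 8, length.out = 4001))
      yv <- as.numeric(y)
      ll_grid <- vapply(grid, function(d) oracle_reml_ll(d, yv, X, G), 0)
      best <- which.max(ll_grid)
      expect_lt(abs(fit$loglik_reml - ll_grid[best]), 1e-3)
      if (best > 1 && best < length(grid)) {
        expect_lt(abs(log(fit$delta) - log(grid[best])), 0.02)
      }
    }
  })
})

test_that("REML collapses to ordinary least squares when sigma2_g is zero", {
  withr::with_seed(111, {
    n <- 40
    G <- diag(n) * 0 + tcrossprod(matrix(stats::rnorm(n * n), n)) / n
    X <- cbind(`(Intercept)` = 1, x = stats::rnorm(n))
    y <- X %*% c(1, 0.5) + stats::rnorm(n)
    fit0 <- reml_fit(as.numeric(y), X, G = G, fix_delta = 0)
    ols <- stats::lm(y ~ X[, 2])
    expect_equal(fit0$beta$estimate, unname(stats::coef(ols)),
                 tolerance = 1e-6)
    expect_equal(fit0$sigma2_g, 0)
    # Wald p equals the normal-theory p from the identical OLS quantities
    se_ols <- sqrt(diag(stats::vcov(ols)))
    p_ols <- stats::pchisq((stats::coef(ols) / se_ols)^2, 1,
                           lower.tail = FALSE)
    expect_equal(fit0$beta$p_value, unname(p_ols), tolerance = 1e-6)

    # iid-generated data: the free fit drives sigma2_g to ~0 and matches OLS
    fit <- reml_fit(as.numeric(y), X, G = G)
    expect_lt(fit$sigma2_g / fit$sigma2_e, 0.2)
  })
  expect_error(reml_fit(1:5, cbind(1, c(1, 1, 1, 1, 1))), "rank")
})

test_that("REML Wald p-values are calibrated under the null", {
  withr::with_seed(121, {
    n <- 60
    A <- matrix(stats::rnorm(n * n), n)
    G <- tcrossprod(A) / n
    eg <- eigen(G, symmetric = TRUE)
    X <- cbind(1, stats::rnorm(n))
    L <- t(chol(G + diag(1e-8, n)))
    pv <- vapply(1:500, function(i) {
      y <- 0.8 * (L %*% stats::rnorm(n)) + stats::rnorm(n)
      reml_fit(as.numeric(y), X, eigen_G = eg)$beta$p_value[2]
    }, 0)
    ks <- stats::ks.test(pv, "punif")
    expect_lt(unname(ks$statistic), 0.08)
  })
})

test_that("the kinship model recovers a bin-local weight depression", {
  withr::with_seed(131, {
    n <- 100
    A <- matrix(stats::rnorm(n * 30), n)
    G <- tcrossprod(A) / 30
    eg <- eigen(G, symmetric = TRUE)
    fac <- sample(c("F1", "F2"), n, replace = TRUE)
    hits <- 0
    for (b in 1:10) {
      len <- stats::rexp(n, 1 / 2e6) * stats::rbinom(n, 1, 0.6)
      w <- 320 - 2e-5 * len + 5 * (fac == "F2") + stats::rnorm(n, 0, 8)
      out <- analysis2_lmm(len, w, fac, eigen_G = eg)
      hits <- hits + (out$coefficient < 0)
    }
    expect_gte(hits, 8)
    # constant length is flagged, not fitted
    expect_false(analysis2_lmm(rep(1e6, n), stats::rnorm(n, 320, 5), fac,
                               eigen_G = eg)$converged)
  })
})

test_that("group mean length change is the difference of group means", {
  bm <- tibble::tibble(
    sample = rep(c("a", "b", "c", "d"), 2),
    bin_id = rep(1:2, each = 4), chrom = "1", start = 1, end = 10,
    roh_length = c(1e6, 1e6, 1.5e6, 1.5e6, 2e6, 2e6, 2e6, 2e6),
    status = 1L)
  kpn <- tibble::tibble(sample = c("a", "b", "c", "d"),
                        kpn = c(100, 400, 500, 600))
  chg <- group_mean_length_change(bm, kpn, cutoff = 486)
  expect_equal(chg$change, c(0.5e6, 0))
  expect_error(group_mean_length_change(bm, kpn, cutoff = 10), "empty")
})

test_that("rank correlations use the tie-corrected Spearman formula", {
  x <- c(1, 2, 3, 4, 5)
  out <- cohort_correlations(x, x, x)
  expect_equal(out$rho, rep(1, 3), tolerance = 1e-12)

  # toy with a tie, against direct rank arithmetic
  f <- c(0.1, 0.2, 0.2, 0.4, 0.7)
  k <- c(1, 2, 3, 4, 5)
  w <- c(300, 310, 305, 330, 320)
  got <- cohort_correlations(f, k, w)
  rho_hand <- function(a, b) stats::cor(rank(a), rank(b))
  expect_equal(got$rho[got$pair == "kpn_froh"], rho_hand(k, f),
               tolerance = 1e-12)
  expect_equal(got$rho[got$pair == "froh_weight"], rho_hand(f, w),
               tolerance = 1e-12)
  # constant vector flagged as undefined
  cc <- cohort_correlations(rep(1, 5), k, w)
  expect_true(is.na(cc$rho[cc$pair == "kpn_froh"]))
  expect_error(cohort_correlations(c(1, NA), c(1, 2), c(1, 2)), "at least 3")
})
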