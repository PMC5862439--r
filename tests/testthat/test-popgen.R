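test_that("SNP QC removes by strict inequalities only", {
  # 20 samples; col1 clean, col2 missing 25%, col3 MAF 0.025 -> kept,
  # col4 monomorphic (MAF 0), col5 missing exactly 5%, col6 MAF exactly 0.01
  d <- matrix(1, nrow = 20, ncol = 6)
  d[, 1] <- rep(c(0, 2), 10)
  d[1:5, 2] <- NA
  d[, 3] <- c(1, rep(0, 19))
  d[, 4] <- 2
  d[, 5] <- rep(c(0, 2), 10); d[1, 5] <- NA
  d[, 6] <- 0; d[1, 6] <- c(1)          # 1/(2*20) = 0.025 -> use 50 samples
  gm <- toy_geno(d)
  out <- qc_filter_snps(gm, max_missing = 0.05, min_maf = 0.01)
  expect_equal(out$variants$pos, c(1000, 3000, 5000, 6000))
  d2 <- matrix(rep(c(0, 2), 25), nrow = 50, ncol = 2)
  d2[, 2] <- 0; d2[1, 2] <- 1            # MAF exactly 0.01 -> retained
  expect_equal(ncol(qc_filter_snps(toy_geno(d2))$dosage), 2)
  d2[1, 2] <- 0                          # monomorphic
  expect_equal(ncol(qc_filter_snps(toy_geno(d2))$dosage), 1)
  expect_error(qc_filter_snps(toy_geno(matrix(2, 4, 1,
                                              dimnames = list(letters[1:4],
                                                              NULL)))),
               "every SNP")
})

test_that("pairwise r2 equals the textbook correlation formula", {
  expect_equal(pairwise_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(pairwise_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0)
  withr::with_seed(3, {
    for (i in 1:20) {
      a <- sample(0:2, 30, replace = TRUE)
      b <- sample(0:2, 30, replace = TRUE)
      num <- mean(a * b) - mean(a) * mean(b)
      den <- sqrt((mean(a^2) - mean(a)^2) * (mean(b^2) - mean(b)^2))
      expect_equal(pairwise_r2(a, b), (num / den)^2, tolerance = 1e-12)
    }
  })
  expect_true(is.na(pairwise_r2(c(1, 1, 1), c(0, 1, 2))))
})

test_that("LD pruning drops duplicates and matches a windowed re-execution", {
  withr::with_seed(8, {
    base <- matrix(sample(0:2, 40 * 10, replace = TRUE), nrow = 40)
    dup <- cbind(base[, 1:3], base[, 3], base[, 4:10])   # col4 duplicates col3
    gm <- toy_geno(dup)
    kept <- ld_prune(gm, prune_params(window_snps = 11, step_snps = 2))
    expect_false(all(c(3, 4) %in% kept))  # exactly one of the twins survives
    expect_true(xor(3 %in% kept, 4 %in% kept))

    # no offending pair -> nothing removed
    ortho <- toy_geno(matrix(c(rep(c(0, 2), 10), rep(c(0, 0, 2, 2), 5),
                               rep(c(0, 2, 2, 0), 5)), ncol = 3))
    expect_equal(ld_prune(ortho, prune_params(window_snps = 3, step_snps = 1)),
                 1:3)

    # 10-SNP panels vs an independent literal re-execution of the scan rule
    brute_prune <- function(d, w, s, r2max) {
      keep <- rep(TRUE, ncol(d))
      st <- 1
      repeat {
        win <- st:min(st + w - 1, ncol(d))
        repeat {
          act <- win[keep[win]]
          off <- NA
          if (length(act) >= 2) {
            prs <- utils::combn(act, 2)
            for (k in seq_len(ncol(prs))) {
              r2 <- suppressWarnings(stats::cor(d[, prs[1, k]],
                                                d[, prs[2, k]])^2)
              if (!is.na(r2) && r2 > r2max) { off <- prs[2, k]; break }
            }
          }
          if (is.na(off)) break
          keep[off] <- FALSE
        }
        if (st + w - 1 >= ncol(d)) break
        st <- st + s
      }
      which(keep)
    }
    for (i in 1:15) {
      d <- matrix(sample(0:2, 25 * 10, replace = TRUE,
                         prob = c(0.4, 0.2, 0.4)), nrow = 25)
      d[, 2] <- d[, 1]; d[, 7] <- 2 - d[, 6]  # force high-LD pairs
      gm <- toy_geno(d)
      p <- prune_params(window_snps = 5, step_snps = 2, r2_max = 0.5)
      expect_equal(ld_prune(gm, p), brute_prune(d, 5, 2, 0.5))
    }
  })
})

test_that("pruning is invariant to adding uncorrelated SNPs", {
  withr::with_seed(12, {
    d <- matrix(sample(0:2, 30 * 8, replace = TRUE), nrow = 30)
    d[, 4] <- d[, 3]
    gm <- toy_geno(d)
    p <- prune_params(window_snps = 8, step_snps = 2)
    kept <- ld_prune(gm, p)
    # append an orthogonal SNP (balanced, independent by construction)
    extra <- rep(c(0, 1, 2), 10)
    while (abs(stats::cor(extra, d[, 3])) > 0.3) extra <- sample(extra)
    gm2 <- toy_geno(cbind(d, extra))
    kept2 <- ld_prune(gm2, prune_params(window_snps = 9, step_snps = 2))
    expect_true(all(kept %in% kept2))
  })
})

test_that("F_snp matches a spreadsheet-style evaluation and its extremes", {
  # all-heterozygous sample in a p = 0.5 cohort -> strongly negative
  d <- rbind(rep(1, 8), rep(0, 8), rep(2, 8), rep(1, 8))
  f <- compute_fsnp(toy_geno(d))
  expect_lt(f$f_snp[1], 0)
  expect_equal(f$observed_hom[1], 0)
  # all-homozygous sample -> F = 1
  expect_equal(f$f_snp[2], 1)
  expect_equal(f$f_snp[3], 1)

  # 4-sample x 6-SNP toy against direct formula evaluation
  withr::with_seed(21, {
    d <- matrix(sample(c(0, 1, 2, NA), 24, replace = TRUE,
                       prob = c(0.35, 0.3, 0.3, 0.05)), nrow = 4)
    gm <- toy_geno(d)
    got <- compute_fsnp(gm)
    for (i in 1:4) {
      o <- 0; e <- 0; nn <- 0
      for (j in 1:6) {
        nmiss <- sum(!is.na(d[, j]))
        nall <- 2 * nmiss
        if (is.na(d[i, j]) || nall < 2) next
        pj <- sum(d[, j], na.rm = TRUE) / nall
        o <- o + as.integer(d[i, j] != 1)
        e <- e + (1 - 2 * pj * (1 - pj) * nall / (nall - 1))
        nn <- nn + 1
      }
      expect_equal(got$observed_hom[i], o)
      expect_equal(got$expected_hom[i], e, tolerance = 1e-12)
      if (nn - e > 0) {
        expect_equal(got$f_snp[i], (o - e) / (nn - e), tolerance = 1e-12)
      }
    }
  })
})

test_that("LD decay bins match exhaustive pair enumeration", {
  # single SNP per chromosome -> no pairs
  gm1 <- geno_matrix(matrix(c(0, 2, 0, 2), 2,
                            dimnames = list(c("a", "b"), NULL)),
                     tibble::tibble(chrom = c("1", "2"), pos = c(100, 100),
                                    ref = "A", alt = "G"))
  expect_equal(nrow(ld_decay_curve(gm1)), 0)

  # distance cutoff: 21 kb pair excluded
  withr::with_seed(31, {
    d <- matrix(sample(0:2, 20 * 3, replace = TRUE), nrow = 20)
    gm2 <- toy_geno(d, pos = c(1000, 2000, 23000))
    cv <- ld_decay_curve(gm2, max_dist = 20000, step = 5000)
    expect_equal(sum(cv$n_pairs), 1)

    # brute force on a random panel
    d <- matrix(sample(0:2, 25 * 12, replace = TRUE), nrow = 25)
    pos <- sort(sample.int(30000, 12))
    gm3 <- toy_geno(d, pos = pos)
    cv <- ld_decay_curve(gm3, max_dist = 20000, step = 5000)
    want <- list()
    for (i in 1:11) for (j in (i + 1):12) {
      dist <- pos[j] - pos[i]
      if (dist <= 20000) {
        r2 <- pairwise_r2(d[, i], d[, j])
        if (!is.na(r2)) {
          b <- min(floor(dist / 5000), 3)
          want[[length(want) + 1]] <- c(b, r2)
        }
      }
    }
    w <- do.call(rbind, want)
    for (b in sort(unique(w[, 1]))) {
      row <- cv[cv$dist_mid == (b + 0.5) * 5000, ]
      expect_equal(row$mean_r2, mean(w[w[, 1] == b, 2]), tolerance = 1e-12)
      expect_equal(row$n_pairs, sum(w[, 1] == b))
    }
  })
})

test_that("GRM follows the VanRaden quadratic form", {
  # uniform heterozygosity centres to the zero matrix
  d <- matrix(1, nrow = 3, ncol = 5,
              dimnames = list(c("a", "b", "c"), NULL))
  d[1, 1] <- 0; d[2, 1] <- 2   # keep one polymorphic, non-constant SNP
  G <- compute_grm(toy_geno(d))
  # constant-het columns centre to zero but stay in the denominator sum
  p <- colMeans(d) / 2
  z <- d[, 1] - 2 * p[1]
  expect_equal(unclass(G), outer(z, z) / (2 * sum(p * (1 - p))),
               ignore_attr = TRUE, tolerance = 1e-12)

  # 3 x 4 toy against direct matrix arithmetic
  d <- matrix(c(0, 1, 2,
                2, 2, 0,
                1, 0, 1,
                0, 0, 2), nrow = 3,
              dimnames = list(c("a", "b", "c"), NULL))
  G <- compute_grm(toy_geno(d))
  p <- colMeans(d) / 2
  Z <- sweep(d, 2, 2 * p)
  expect_equal(unclass(G), Z %*% t(Z) / (2 * sum(p * (1 - p))),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unclass(G), t(unclass(G)), tolerance = 1e-12)

  expect_error(compute_grm(toy_geno(matrix(2, 3, 2,
                                           dimnames = list(letters[1:3],
                                                           NULL)))),
               "monomorphic")
})

test_that("GRM diagonal and off-diagonal behave under HWE", {
  withr::with_seed(44, {
    n <- 40; m <- 5000
    p <- stats::runif(m, 0.1, 0.9)
    d <- matrix(stats::rbinom(n * m, 2, rep(p, each = n)), nrow = n,
                dimnames = list(sprintf("s%02d", 1:n), NULL))
    G <- compute_grm(toy_geno(d, pos = seq_len(m)))
    expect_lt(abs(mean(diag(G)) - 1), 0.05)
    off <- unclass(G)[upper.tri(G)]
    expect_lt(abs(mean(off) - (-1 / (n - 1))), 0.01)
  })
})

test_that("F_snp and F_roh rank samples concordantly on an inbred cohort", {
  sim <- simulate_cohort(small_sim_config(seed = 55))
  seg <- filter_autozygous(call_roh(sim$genotypes,
                                    roh_call_params(min_snps = 5)))
  cs <- tibble::tibble(chrom = sim$config$genome$chrom,
                       length = sim$config$genome$length_bp)
  fr <- compute_froh(seg, cs, samples = sim$meta$sample)
  fs <- compute_fsnp(sim$genotypes)
  m <- dplyr::inner_join(fr, fs, by = "sample")
  expect_gt(stats::cor(m$f_roh, m$f_snp), 0.6)
})
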