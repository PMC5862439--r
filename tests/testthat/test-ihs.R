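# Panel where the 4 derived-allele carriers split into groups {2,2} one SNP
# right of the core, and {2,1,1} two SNPs right.
split_panel <- function() {
  h <- rbind(
    c(0, 1, 0, 0),   # derived carriers: rows 1-4 (core = col 2)
    c(0, 1, 0, 1),
    c(1, 1, 1, 0),
    c(1, 1, 1, 1),
    c(0, 0, 0, 0),
    c(1, 0, 1, 1))
  toy_panel(h, pos = c(1000, 2000, 3000, 4000))
}

test_that("EHH equals pair counting over identical extended haplotypes", {
  p <- split_panel()
  curve <- ehh(p, core = 2, allele = "derived")
  expect_equal(curve$ehh[curve$offset == 0], 1)
  # one SNP right: groups {2,2} -> (1+1)/C(4,2) = 1/3
  expect_equal(curve$ehh[curve$offset == 1000], 1 / 3)
  # two SNPs right: groups {1,1,1,1} here, so extend left instead
  expect_equal(curve$ehh[curve$offset == 1000],
               oracle_ehh_at(p$haps, 2, 3, 1))
  # a {2,1,1} split two SNPs right of the core
  p2 <- toy_panel(rbind(c(0, 1, 0, 0), c(0, 1, 0, 0), c(1, 1, 1, 1),
                        c(0, 1, 1, 0), c(1, 0, 0, 0), c(0, 0, 1, 0)),
                  pos = c(1000, 2000, 3000, 4000))
  # derived carriers rows 1:4; prefixes to col4: 00,00,11,10 -> {2,1,1}
  c2 <- ehh(p2, core = 2, allele = "derived")
  expect_equal(c2$ehh[c2$offset == 2000], 1 / 6)
  expect_equal(oracle_ehh_at(p2$haps, 2, 4, 1), 1 / 6)
  expect_error(ehh(toy_panel(rbind(c(0, 1), c(0, 0), c(0, 0), c(0, 0)),
                             pos = c(1, 2)), core = 2), "carriers")
})

test_that("EHH curves are monotone non-increasing away from the core", {
  withr::with_seed(61, {
    for (i in 1:20) {
      h <- matrix(sample(0:1, 12 * 15, replace = TRUE), nrow = 12)
      core <- sample(3:13, 1)
      for (al in c("derived", "ancestral")) {
        n_car <- sum(h[, core] == (al == "derived"))
        if (n_car < 2) next
        curve <- ehh(toy_panel(h), core, al)
        up <- curve[curve$offset >= 0, ]
        dn <- curve[curve$offset <= 0, ]
        expect_true(all(diff(up$ehh) <= 1e-12))
        expect_true(all(diff(rev(dn$ehh)) <= 1e-12))
      }
    }
  })
})

test_that("iHS is zero on label-symmetric panels and antisymmetric under swaps", {
  # derived rows 1-3 and ancestral rows 4-6 carry identical flank patterns;
  # flanks split carriers to singletons before either chromosome edge
  flank <- rbind(c(0, 0, 0, 0),
                 c(1, 0, 0, 1),
                 c(0, 1, 1, 0))
  h <- rbind(cbind(flank[, 1:2], 1, flank[, 3:4]),
             cbind(flank[, 1:2], 0, flank[, 3:4]))
  p <- toy_panel(h, pos = c(1000, 2000, 3000, 4000, 5000))
  v <- ihs_unstandardized(p, core = 3, min_maf = 0.01)
  expect_equal(v, 0, tolerance = 1e-12)

  withr::with_seed(71, {
    checked <- 0
    for (i in 1:30) {
      h <- matrix(sample(0:1, 16 * 21, replace = TRUE), nrow = 16)
      p1 <- toy_panel(h)
      p2 <- toy_panel(1 - h)   # swap ancestral/derived labels everywhere
      core <- 11
      a <- ihs_unstandardized(p1, core, min_maf = 0.01)
      b <- ihs_unstandardized(p2, core, min_maf = 0.01)
      if (!is.na(a) && !is.na(b)) {
        expect_equal(a, -b, tolerance = 1e-10)
        checked <- checked + 1
      }
    }
    expect_gt(checked, 5)
  })
})

test_that("iHS matches the independent trapezoidal small-panel calculator", {
  withr::with_seed(81, {
    checked <- 0
    for (i in 1:60) {
      n_hap <- sample(c(6, 8, 10), 1)
      h <- matrix(sample(0:1, n_hap * 13, replace = TRUE), nrow = n_hap)
      pos <- sort(sample.int(150000, 13))
      p <- toy_panel(h, pos = pos)
      core <- 7
      got <- ihs_unstandardized(p, core, min_maf = 0.01)
      n_d <- sum(h[, core]); n_a <- n_hap - n_d
      want <- if (n_d < 2 || n_a < 2 || min(n_d, n_a) / n_hap < 0.01) {
        NA_real_
      } else {
        der <- oracle_ihh(h, pos, core, 1)
        anc <- oracle_ihh(h, pos, core, 0)
        if (is.na(der) || is.na(anc) || der == 0 || anc == 0) {
          NA_real_
        } else {
          log(der / anc)
        }
      }
      expect_equal(got, want, tolerance = 1e-10)
      if (!is.na(want)) checked <- checked + 1
    }
    expect_gt(checked, 10)
  })
})

test_that("cores below the MAF floor are skipped", {
  h <- matrix(sample(0:1, 40 * 5, replace = TRUE), nrow = 40)
  h[, 3] <- 0; h[1, 3] <- 1   # MAF 1/40 = 0.025 < 0.05
  p <- toy_panel(h)
  expect_true(is.na(ihs_unstandardized(p, 3, min_maf = 0.05)))
})

test_that("frequency-bin standardization centres and scales, flagging degenerates", {
  tr <- tibble::tibble(
    chrom = "1", pos = 1:12 * 1000,
    daf = c(rep(0.105, 6), rep(0.855, 4), 0.255, 0.255),
    ihs_raw = c(1, 2, 3, 4, 5, 6, -1, -2, -3, -4, 7, 7))
  out <- standardize_ihs(tr, n_bins = 10)
  b1 <- out$ihs_std[1:6]
  expect_equal(mean(b1), 0, tolerance = 1e-12)
  expect_equal(stats::sd(b1), 1, tolerance = 1e-12)
  expect_equal(b1, (tr$ihs_raw[1:6] - mean(tr$ihs_raw[1:6])) /
                 stats::sd(tr$ihs_raw[1:6]))
  b2 <- out$ihs_std[7:10]
  expect_equal(mean(b2), 0, tolerance = 1e-12)
  # zero-SD bin left unstandardized and flagged
  expect_true(all(out$bin_flagged[11:12]))
  expect_equal(out$ihs_std[11:12], c(7, 7))
  expect_error(standardize_ihs(tibble::tibble(chrom = "1", pos = 1,
                                              daf = 0.5,
                                              ihs_raw = NA_real_)),
               "no defined")
})

test_that("sweep windows drop sparse windows and flag by sort-and-threshold", {
  withr::with_seed(91, {
    n_win <- 300
    snps_per <- sample(c(8, 9, 12, 20), n_win, replace = TRUE)
    rows <- list()
    for (w in seq_len(n_win)) {
      k <- snps_per[w]
      n_ext <- stats::rbinom(1, k, 0.04)
      vals <- c(rep(3, n_ext), rep(0.5, k - n_ext))
      rows[[w]] <- tibble::tibble(
        chrom = "1", pos = (w - 1) * 100000 + seq_len(k) * 1000,
        daf = 0.5, ihs_raw = vals, freq_bin = 50L, ihs_std = vals,
        bin_flagged = FALSE)
    }
    tr <- dplyr::bind_rows(rows)
    sw <- sweep_windows(tr, window = 100000, min_snps = 10, abs_cut = 2,
                        top_frac = 0.01)
    # windows with fewer than 10 scored SNPs are gone
    expect_equal(nrow(sw), sum(snps_per >= 10))
    # oracle: proportions by direct counting, threshold by sorting
    props <- vapply(which(snps_per >= 10), function(w) {
      k <- snps_per[w]
      mean(tr$ihs_std[tr$pos > (w - 1) * 1e5 & tr$pos <= w * 1e5] > 2)
    }, 0)
    thr <- sort(props)[ceiling(0.99 * length(props))]
    expect_equal(sort(sw$prop_extreme), sort(props), tolerance = 1e-12)
    expect_equal(sw$flagged, sw$prop_extreme >= thr)
    expect_gte(sum(sw$flagged), 1)
  })
  # degenerate null: all proportions zero -> every window ties at the threshold
  tr0 <- tibble::tibble(chrom = "1", pos = 1:40 * 1000, daf = 0.5,
                        ihs_raw = 0.1, freq_bin = 50L, ihs_std = 0.1,
                        bin_flagged = FALSE)
  sw0 <- sweep_windows(tr0, window = 20000, min_snps = 10)
  expect_true(all(sw0$prop_extreme == 0))
  expect_true(all(sw0$flagged))
})

test_that("per-SNP top-fraction flagging matches its quantile definition", {
  tr <- tibble::tibble(chrom = "1", pos = 1:200 * 1000, daf = 0.5,
                       ihs_raw = 0, freq_bin = 1L,
                       ihs_std = c(seq(-3, 3, length.out = 199), NA),
                       bin_flagged = FALSE)
  out <- ihs_top_snps(tr, top_frac = 0.05)
  a <- abs(tr$ihs_std)
  thr <- sort(a[!is.na(a)])[ceiling(0.95 * sum(!is.na(a)))]
  expect_equal(out$top_snp, !is.na(a) & a >= thr)
  expect_equal(attr(out, "abs_ihs_threshold"), thr)
})
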