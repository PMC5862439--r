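# Independent oracles used across the suite. These deliberately re-derive
# results by brute force (per-base marking, exhaustive enumeration, dense
# matrix algebra) rather than calling the package's own code paths.

# Brute-force greedy maximal-run ROH enumerator: for each run start, the
# qualifying end is found by re-checking the whole candidate interval from
# scratch (no incremental state shared with the package implementation).
oracle_roh <- function(pos, cls, params) {
  n <- length(pos)
  qualifies <- function(i, j) {
    if (cls[i] != 0L) return(FALSE)
    idx <- i:j
    if (sum(cls[idx] == 1L) > params$max_het_in_run) return(FALSE)
    if (sum(cls[idx] == 2L) > params$max_missing_in_run) return(FALSE)
    if (j > i && any(diff(pos[idx]) > params$max_gap)) return(FALSE)
    TRUE
  }
  res <- list()
  i <- 1L
  while (i <= n) {
    if (cls[i] != 0L) { i <- i + 1L; next }
    j <- i
    while (j < n && qualifies(i, j + 1L)) j <- j + 1L
    jh <- max(which(cls[i:j] == 0L)) + i - 1L
    n_hom <- sum(cls[i:jh] == 0L)
    if (n_hom >= params$min_snps &&
        pos[jh] - pos[i] + 1 >= params$min_length) {
      res[[length(res) + 1L]] <- data.frame(start = pos[i], end = pos[jh],
                                            n_snps = n_hom)
    }
    i <- j + 1L
  }
  if (!length(res)) {
    return(data.frame(start = double(), end = double(), n_snps = integer()))
  }
  do.call(rbind, res)
}

# Recursive memoised kinship; F(x) = kinship(sire, dam).
oracle_pedigree_f <- function(ped) {
  memo <- new.env()
  kin <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- paste(sort(c(a, b)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    ia <- match(a, ped$id); ib <- match(b, ped$id)
    val <- if (a == b) {
      0.5 * (1 + kin(ped$sire[ia], ped$dam[ia]))
    } else if (ia > ib) {
      0.5 * (kin(ped$sire[ia], b) + kin(ped$dam[ia], b))
    } else {
      0.5 * (kin(ped$sire[ib], a) + kin(ped$dam[ib], a))
    }
    memo[[key]] <- val
    val
  }
  vapply(seq_len(nrow(ped)), function(i) {
    kin(ped$sire[i], ped$dam[i])
  }, 0)
}

# Per-base distinct-sample coverage over a small range.
oracle_coverage <- function(segments, lo, hi) {
  depth <- integer(hi - lo + 1L)
  for (s in unique(segments$sample)) {
    covered <- logical(hi - lo + 1L)
    seg <- segments[segments$sample == s, ]
    for (k in seq_len(nrow(seg))) {
      a <- max(seg$start[k], lo); b <- min(seg$end[k], hi)
      if (a <= b) covered[(a:b) - lo + 1L] <- TRUE
    }
    depth <- depth + covered
  }
  depth
}

# Per-base F_roh on a small genome.
oracle_froh_perbase <- function(segments, chrom_sizes) {
  samples <- unique(segments$sample)
  total <- sum(chrom_sizes$length)
  vapply(samples, function(s) {
    covered <- 0
    for (i in seq_len(nrow(chrom_sizes))) {
      mask <- logical(chrom_sizes$length[i])
      seg <- segments[segments$sample == s &
                        segments$chrom == chrom_sizes$chrom[i], ]
      for (k in seq_len(nrow(seg))) mask[seg$start[k]:seg$end[k]] <- TRUE
      covered <- covered + sum(mask)
    }
    covered / total
  }, 0)
}

# Dense-matrix restricted log-likelihood for y = Xb + g + e, g ~ s2g*G:
# computed on the original scale with solve(), independent of the
# eigen-profile shortcut in the package.
oracle_reml_ll <- function(delta, y, X, G) {
  n <- length(y); p <- ncol(X)
  V <- delta * G + diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  s2e <- as.numeric(t(r) %*% Vi %*% r) / (n - p)
  as.numeric(-0.5 * ((n - p) * log(2 * pi * s2e) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       (n - p)))
}

# Pair-counting EHH by explicit haplotype-string grouping.
oracle_ehh_at <- function(haps, core, j, allele) {
  carriers <- which(haps[, core] == allele)
  n <- length(carriers)
  span <- min(core, j):max(core, j)
  keys <- apply(haps[carriers, span, drop = FALSE], 1, paste, collapse = "")
  tab <- table(keys)
  sum(choose(tab, 2)) / choose(n, 2)
}

# Trapezoidal iHH for one allele class, by direct evaluation of the
# pair-counting EHH at every SNP (stops below the cutoff; NA at edges/gaps).
oracle_ihh <- function(haps, pos, core, allele, cutoff = 0.05,
                       max_gap = 200000) {
  total <- 0
  for (dir in c(-1L, 1L)) {
    e_prev <- 1; p_prev <- pos[core]; j <- core + dir
    reached <- FALSE
    while (j >= 1 && j <= length(pos)) {
      if (abs(pos[j] - p_prev) > max_gap) return(NA_real_)
      e_cur <- oracle_ehh_at(haps, core, j, allele)
      total <- total + (e_prev + e_cur) / 2 * abs(pos[j] - p_prev)
      if (e_cur < cutoff) { reached <- TRUE; break }
      e_prev <- e_cur; p_prev <- pos[j]; j <- j + dir
    }
    if (!reached) return(NA_real_)
  }
  total
}

# Random small genotype track (positions + classes) for property tests.
random_track <- function(n_snps, p_het = 0.2, p_miss = 0.1,
                         max_spacing = 120000) {
  pos <- cumsum(sample.int(max_spacing, n_snps, replace = TRUE))
  cls <- sample(0:2, n_snps, replace = TRUE,
                prob = c(1 - p_het - p_miss, p_het, p_miss))
  list(pos = pos, cls = as.integer(cls))
}

# Wrap a single-sample track as a geno_matrix on one chromosome.
track_to_geno <- function(pos, cls, sample_id = "S1", chrom = "1") {
  d <- ifelse(cls == 0L, 2, ifelse(cls == 1L, 1, NA))
  m <- matrix(d, nrow = 1, dimnames = list(sample_id, NULL))
  geno_matrix(m, tibble::tibble(chrom = chrom, pos = pos,
                                ref = "A", alt = "G"))
}

# Small deterministic multi-sample geno_matrix from a dosage matrix.
toy_geno <- function(dosage, pos = NULL, chrom = "1") {
  if (is.null(pos)) pos <- seq_len(ncol(dosage)) * 1000
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%02d", seq_len(nrow(dosage)))
  }
  geno_matrix(dosage, tibble::tibble(chrom = chrom, pos = pos,
                                     ref = "A", alt = "G"))
}

toy_panel <- function(haps, pos = NULL, chrom = "1") {
  if (is.null(pos)) pos <- seq_len(ncol(haps)) * 1000
  samples <- sprintf("S%02d", seq_len(nrow(haps) / 2))
  hap_panel(haps, tibble::tibble(chrom = chrom, pos = pos,
                                 ref = "A", alt = "G"), samples)
}

small_sim_config <- function(seed = 1L, ...) {
  sim_config(n_founders = 20, n_generations = 5, n_sires_selected = 2,
             offspring_per_round = 12, n_unselected = 5,
             genome = tibble::tibble(chrom = c("1", "2"),
                                     length_bp = c(30e6, 30e6),
                                     cm = c(30, 30)),
             snp_density = 10, seed = seed, ...)
}
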