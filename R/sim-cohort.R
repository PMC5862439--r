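#' Configuration for the breeding-program simulator
#'
#' Describes a forward-time truncation-selection breeding program: unrelated
#' founders, a fixed number of candidate offspring per round, and a small
#' number of top-phenotype sires kept each round (the classical
#' performance-test design). Defaults give a desk-scale cohort of
#' 18 rounds x 7 selected sires = 126 selected bulls plus 10 unselected
#' founder-pool offspring on a 3 x 50 Mb genome.
#'
#' @param n_founders Number of unrelated founders (half male, half female).
#' @param n_generations Breeding rounds.
#' @param n_sires_selected Males kept (and registered) per round.
#' @param offspring_per_round Candidates produced per round.
#' @param n_unselected Size of the random-mating control group.
#' @param genome Data frame with columns `chrom`, `length_bp`, `cm` (genetic
#'   map length in centimorgans).
#' @param snp_density SNPs per Mb.
#' @param founder_maf_law Length-2 numeric: uniform bounds for founder
#'   alternate-allele frequency.
#' @param h2 Narrow-sense heritability of 12-month body weight.
#' @param mu_weight Population mean 12-month weight, kg.
#' @param sigma_p Phenotypic standard deviation, kg.
#' @param selection_mode `"phenotype_truncation"` or `"random"` (sires drawn
#'   at random; disables selection while keeping the mating structure).
#' @param n_facilities Number of rearing facilities.
#' @param facility_effect_sd SD of facility effects, kg.
#' @param seed Integer RNG seed; the same seed gives bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 60, n_generations = 18,
                       n_sires_selected = 7, offspring_per_round = 40,
                       n_unselected = 10,
                       genome = default_genome(),
                       snp_density = 50,
                       founder_maf_law = c(0.05, 0.5),
                       h2 = 0.4, mu_weight = 320, sigma_p = 30,
                       selection_mode = c("phenotype_truncation", "random"),
                       n_facilities = 3, facility_effect_sd = 10,
                       seed = 1L) {
  selection_mode <- match.arg(selection_mode)
  genome <- tibble::as_tibble(genome)
  stopifnot(n_founders >= 4, n_founders %% 2 == 0, n_generations >= 0,
            n_sires_selected >= 1, offspring_per_round >= 1,
            n_unselected >= 0, snp_density > 0,
            h2 >= 0, h2 <= 1, sigma_p > 0, n_facilities >= 1,
            facility_effect_sd >= 0, all(genome$cm > 0),
            all(genome$length_bp > 0))
  if (n_sires_selected > offspring_per_round) {
    stop("n_sires_selected cannot exceed offspring_per_round", call. = FALSE)
  }
  if (any(round(genome$length_bp * snp_density / 1e6) < 1)) {
    stop("snp_density leaves a chromosome with zero SNPs", call. = FALSE)
  }
  structure(list(
    n_founders = n_founders, n_generations = n_generations,
    n_sires_selected = n_sires_selected,
    offspring_per_round = offspring_per_round, n_unselected = n_unselected,
    genome = genome, snp_density = snp_density,
    founder_maf_law = founder_maf_law, h2 = h2, mu_weight = mu_weight,
    sigma_p = sigma_p, selection_mode = selection_mode,
    n_facilities = n_facilities, facility_effect_sd = facility_effect_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default toy genome: 3 chromosomes of 50 Mb / 50 cM
#' @return Tibble with `chrom`, `length_bp`, `cm`.
#' @export
default_genome <- function() {
  tibble::tibble(chrom = c("1", "2", "3"), length_bp = rep(50e6, 3),
                 cm = rep(50, 3))
}

new_hap <- function(alleles, breaks, labels) {
  list(alleles = alleles, breaks = breaks, labels = labels)
}

# Piece together a gamete mosaic from two parental mosaics and crossover
# positions. Mosaics are run-length interval lists: `breaks` are segment end
# positions in bp (last = chromosome length), `labels` the founder-haplotype
# label of each segment.
combine_mosaic <- function(brA, laA, brB, laB, xo, L, start) {
  cuts <- sort(unique(c(xo, brA, brB)))
  cuts <- cuts[cuts <= L & cuts > 0]
  if (!length(cuts) || cuts[length(cuts)] < L) cuts <- c(cuts, L)
  starts <- c(0, cuts[-length(cuts)])
  mid <- (starts + cuts) / 2
  from_b <- ((start + findInterval(mid, xo)) %% 2L) == 1L
  lab <- integer(length(mid))
  lab[!from_b] <- laA[findInterval(mid[!from_b], brA) + 1L]
  lab[from_b] <- laB[findInterval(mid[from_b], brB) + 1L]
  n <- length(lab)
  change <- which(lab[-n] != lab[-1])
  list(breaks = c(cuts[change], L), labels = lab[c(change, n)])
}

# One meiosis: Poisson crossover count at the chromosome map length (Haldane,
# no interference), crossover positions uniform in bp (constant cM/Mb rate).
gamete <- function(ind, map) {
  n_chrom <- nrow(map$genome)
  alleles <- integer(length(ind$hap1$alleles))
  breaks <- vector("list", n_chrom)
  labels <- vector("list", n_chrom)
  for (c in seq_len(n_chrom)) {
    L <- map$genome$length_bp[c]
    idx <- map$snp_idx[[c]]
    pos <- map$snp_pos[[c]]
    n_xo <- stats::rpois(1L, map$genome$cm[c] / 100)
    xo <- sort(stats::runif(n_xo, 0, L))
    start <- sample.int(2L, 1L) - 1L
    src <- (start + findInterval(pos, xo)) %% 2L
    al <- ind$hap1$alleles[idx]
    al[src == 1L] <- ind$hap2$alleles[idx][src == 1L]
    alleles[idx] <- al
    mz <- combine_mosaic(ind$hap1$breaks[[c]], ind$hap1$labels[[c]],
                         ind$hap2$breaks[[c]], ind$hap2$labels[[c]],
                         xo, L, start)
    breaks[[c]] <- mz$breaks
    labels[[c]] <- mz$labels
  }
  new_hap(alleles, breaks, labels)
}

#' Founder population for the simulator
#'
#' Draws founder haplotypes (alleles per SNP from the founder frequency law,
#' one unique founder-origin label per haplotype) and lays out the SNP map.
#' Uses the current RNG stream; wrap in [withr::with_seed()] or call
#' [simulate_cohort()] for seeded end-to-end runs.
#'
#' @param config A [sim_config()].
#' @return A population object of class `sim_pop` (list of individuals plus
#'   map); extend it with [sim_mate()].
#' @export
sim_founders <- function(config) {
  g <- config$genome
  n_snps <- pmax(1L, as.integer(round(g$length_bp * config$snp_density / 1e6)))
  snp_pos <- lapply(seq_len(nrow(g)), function(c) {
    sort(sample.int(g$length_bp[c], n_snps[c]))
  })
  offs <- cumsum(c(0L, n_snps[-length(n_snps)]))
  snp_idx <- lapply(seq_len(nrow(g)), function(c) offs[c] + seq_len(n_snps[c]))
  total <- sum(n_snps)
  freqs <- stats::runif(total, config$founder_maf_law[1], config$founder_maf_law[2])
  map <- list(genome = g, snp_pos = snp_pos, snp_idx = snp_idx, freqs = freqs)

  inds <- list()
  sigma_a <- sqrt(config$h2) * config$sigma_p
  for (i in seq_len(config$n_founders)) {
    hap_of <- function(lab) {
      new_hap(as.integer(stats::rbinom(total, 1L, freqs)),
              breaks = lapply(seq_len(nrow(g)), function(c) g$length_bp[c]),
              labels = lapply(seq_len(nrow(g)), function(c) lab))
    }
    id <- sprintf("F%03d", i)
    inds[[id]] <- list(id = id, sire = NA_character_, dam = NA_character_,
                       gen = 0L, sex = if (i %% 2 == 1) "M" else "F",
                       hap1 = hap_of(2L * i - 1L), hap2 = hap_of(2L * i),
                       bv = stats::rnorm(1, 0, sigma_a))
    }
  structure(list(map = map, inds = inds, config = config), class = "sim_pop")
}

#' Mate two individuals in a simulated population
#'
#' Produces `n` offspring of the named sire and dam, appending them to the
#' population with pedigree records and breeding values (mid-parent plus
#' Mendelian-sampling deviation).
#'
#' @param pop A `sim_pop` from [sim_founders()].
#' @param sire,dam Individual ids.
#' @param n Number of offspring.
#' @param ids Optional character vector of offspring ids.
#' @param gen Generation number recorded for the offspring.
#' @return The extended `sim_pop`; new ids in `attr(, "new_ids")`.
#' @export
sim_mate <- function(pop, sire, dam, n = 1L, ids = NULL, gen = NULL) {
  stopifnot(sire %in% names(pop$inds), dam %in% names(pop$inds))
  s <- pop$inds[[sire]]
  d <- pop$inds[[dam]]
  if (is.null(gen)) gen <- max(s$gen, d$gen) + 1L
  if (is.null(ids)) {
    ids <- sprintf("X%05d", length(pop$inds) + seq_len(n))
  }
  sigma_ms <- sqrt(0.5 * pop$config$h2) * pop$config$sigma_p
  for (k in seq_len(n)) {
    ind <- list(id = ids[k], sire = sire, dam = dam, gen = gen,
                sex = if (stats::runif(1) < 0.5) "M" else "F",
                hap1 = gamete(s, pop$map), hap2 = gamete(d, pop$map),
                bv = 0.5 * (s$bv + d$bv) + stats::rnorm(1, 0, sigma_ms))
    pop$inds[[ids[k]]] <- ind
  }
  attr(pop, "new_ids") <- ids
  pop
}

#' True autozygous (IBD) segments of a simulated individual
#'
#' Maximal intervals where the two haplotype mosaics carry the same
#' founder-haplotype label, at crossover-breakpoint (bp) resolution.
#'
#' @param pop A `sim_pop`.
#' @param id Individual id.
#' @return Tibble `chrom`, `start`, `end` (1-based inclusive bp); zero rows
#'   for non-inbred individuals.
#' @export
realized_ibd_segments <- function(pop, id) {
  ind <- pop$inds[[id]]
  if (is.null(ind)) stop("unknown individual: ", id, call. = FALSE)
  g <- pop$map$genome
  out <- vector("list", nrow(g))
  for (c in seq_len(nrow(g))) {
    br1 <- ind$hap1$breaks[[c]]; la1 <- ind$hap1$labels[[c]]
    br2 <- ind$hap2$breaks[[c]]; la2 <- ind$hap2$labels[[c]]
    cuts <- sort(unique(c(br1, br2)))
    starts <- c(0, cuts[-length(cuts)])
    mid <- (starts + cuts) / 2
    ib <- la1[findInterval(mid, br1) + 1L] == la2[findInterval(mid, br2) + 1L]
    if (!any(ib)) next
    r <- rle(ib)
    seg_end_idx <- cumsum(r$lengths)
    seg_start_idx <- seg_end_idx - r$lengths + 1L
    keep <- r$values
    out[[c]] <- tibble::tibble(
      chrom = g$chrom[c],
      start = floor(starts[seg_start_idx[keep]]) + 1,
      end = floor(cuts[seg_end_idx[keep]])
    )
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(chrom = character(), start = double(), end = double())
  }
  res
}

#' Pedigree inbreeding coefficients (tabular method)
#'
#' Builds the additive relationship matrix over a sorted pedigree
#' (parents before offspring) by the standard recursion and returns
#' `F = A_ii - 1`.
#'
#' @param pedigree Tibble with `id`, `sire`, `dam` (`NA` for unknown),
#'   ordered so parents precede offspring.
#' @return Tibble `id`, `f`.
#' @export
pedigree_f <- function(pedigree) {
  n <- nrow(pedigree)
  si <- match(pedigree$sire, pedigree$id)
  di <- match(pedigree$dam, pedigree$id)
  if (any(!is.na(si) & si >= seq_len(n)) || any(!is.na(di) & di >= seq_len(n))) {
    stop("pedigree must list parents before offspring", call. = FALSE)
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[s, prev] else rep(0, i - 1L)
      ad_ <- if (!is.na(d)) A[d, prev] else rep(0, i - 1L)
      A[i, prev] <- A[prev, i] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  tibble::tibble(id = pedigree$id, f = diag(A) - 1)
}

#' Simulate a selected-plus-unselected cohort
#'
#' Runs the breeding program of a [sim_config()]: each round produces
#' candidate offspring from the current sires and dams, ranks the males by
#' 12-month weight, keeps the top `n_sires_selected` as next-round sires and
#' registers them with sequential KPN numbers (round order, ties broken by
#' phenotype rank). A control group is produced by random mating within the
#' founder pool. Every haplotype allele carries its founder-origin label, so
#' true autozygous segments and pedigree inbreeding are returned exactly.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort`: `genotypes` ([geno_matrix()]),
#'   `haplotypes` ([hap_panel()]), `meta` (sample metadata tibble),
#'   `truth` (list: `pedigree`, `true_ibd_segments`, `pedigree_f`,
#'   `true_breeding_values`), `pop` (the full `sim_pop`), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  pop <- sim_founders(config)
  founder_ids <- names(pop$inds)
  founder_m <- founder_ids[vapply(pop$inds, function(x) x$sex == "M", TRUE)]
  founder_f <- setdiff(founder_ids, founder_m)
  fac_levels <- sprintf("FAC%d", seq_len(config$n_facilities))
  fac_eff <- stats::rnorm(config$n_facilities, 0, config$facility_effect_sd)
  names(fac_eff) <- fac_levels
  sigma_e <- sqrt(1 - config$h2) * config$sigma_p

  phenotype <- function(id, fac) {
    config$mu_weight + pop$inds[[id]]$bv + fac_eff[[fac]] +
      stats::rnorm(1, 0, sigma_e)
  }

  meta <- list()
  selected_ids <- character()
  kpn_next <- 1L

  sires <- sample(founder_m, min(config$n_sires_selected, length(founder_m)))
  dams <- founder_f
  for (g in seq_len(config$n_generations)) {
    ids <- sprintf("G%02d_%02d", g, seq_len(config$offspring_per_round))
    for (k in seq_len(config$offspring_per_round)) {
      pop <- sim_mate(pop, sample(sires, 1L), sample(dams, 1L),
                      ids = ids[k], gen = g)
    }
    sexes <- vapply(ids, function(i) pop$inds[[i]]$sex, "")
    males <- ids[sexes == "M"]
    if (length(males) < config$n_sires_selected) {
      flip <- sample(setdiff(ids, males),
                     config$n_sires_selected - length(males))
      for (i in flip) pop$inds[[i]]$sex <- "M"
      males <- c(males, flip)
    }
    facs <- sample(fac_levels, length(ids), replace = TRUE)
    names(facs) <- ids
    phen <- vapply(ids, function(i) phenotype(i, facs[[i]]), 0)
    if (config$selection_mode == "phenotype_truncation") {
      winners <- males[order(-phen[males])][seq_len(config$n_sires_selected)]
      next_sires <- winners
    } else {
      # selection disabled: registration is a random draw and every male of
      # the round stays in the sire pool
      winners <- sample(males, config$n_sires_selected)
      winners <- winners[order(-phen[winners])]
      next_sires <- males
    }
    for (w in winners) {
      meta[[w]] <- tibble::tibble(sample = w, kpn = kpn_next, selected = TRUE,
                                  facility = facs[[w]],
                                  weight12m = unname(phen[w]))
      kpn_next <- kpn_next + 1L
    }
    selected_ids <- c(selected_ids, winners)
    sires <- next_sires
    fem <- ids[vapply(ids, function(i) pop$inds[[i]]$sex == "F", TRUE)]
    dams <- if (length(fem) >= 2L) fem else founder_f
  }

  unsel_ids <- character()
  if (config$n_unselected > 0) {
    unsel_ids <- sprintf("U%02d", seq_len(config$n_unselected))
    for (k in seq_len(config$n_unselected)) {
      pop <- sim_mate(pop, sample(founder_m, 1L), sample(founder_f, 1L),
                      ids = unsel_ids[k], gen = 1L)
      fac <- sample(fac_levels, 1L)
      meta[[unsel_ids[k]]] <- tibble::tibble(
        sample = unsel_ids[k], kpn = NA_integer_, selected = FALSE,
        facility = fac, weight12m = phenotype(unsel_ids[k], fac))
    }
  }

  cohort <- c(selected_ids, unsel_ids)
  if (!length(cohort)) {
    # degenerate run (no rounds, no controls): the founders are the cohort
    cohort <- founder_ids
    for (id in founder_ids) {
      fac <- sample(fac_levels, 1L)
      meta[[id]] <- tibble::tibble(sample = id, kpn = NA_integer_,
                                   selected = FALSE, facility = fac,
                                   weight12m = phenotype(id, fac))
    }
  }
  meta <- dplyr::bind_rows(meta[cohort])

  total_snps <- length(pop$map$freqs)
  haps <- matrix(0L, nrow = 2L * length(cohort), ncol = total_snps)
  for (j in seq_along(cohort)) {
    ind <- pop$inds[[cohort[j]]]
    haps[2L * j - 1L, ] <- ind$hap1$alleles
    haps[2L * j, ] <- ind$hap2$alleles
  }
  variants <- tibble::tibble(
    chrom = rep(pop$map$genome$chrom,
                vapply(pop$map$snp_pos, length, 0L)),
    pos = unlist(pop$map$snp_pos),
    ref = "A", alt = "G"
  )
  panel <- hap_panel(haps, variants, cohort)
  gm <- panel_to_geno(panel)

  ped <- tibble::tibble(
    id = names(pop$inds),
    sire = vapply(pop$inds, function(x) x$sire, ""),
    dam = vapply(pop$inds, function(x) x$dam, ""),
    generation = vapply(pop$inds, function(x) x$gen, 0L)
  )
  pf <- pedigree_f(ped)
  ibd <- dplyr::bind_rows(lapply(cohort, function(id) {
    seg <- realized_ibd_segments(pop, id)
    if (nrow(seg)) seg$sample <- id
    seg
  }))
  if (!nrow(ibd)) {
    ibd <- tibble::tibble(chrom = character(), start = double(),
                          end = double(), sample = character())
  }
  ibd <- ibd[, c("sample", "chrom", "start", "end")]

  truth <- list(
    pedigree = ped,
    true_ibd_segments = ibd,
    pedigree_f = pf,
    true_breeding_values = tibble::tibble(
      sample = cohort,
      bv = vapply(cohort, function(i) pop$inds[[i]]$bv, 0))
  )
  structure(list(genotypes = gm, haplotypes = panel, meta = meta,
                 truth = truth, pop = pop, config = config),
            class = "sim_cohort")
}

#' Write simulator outputs to disk
#'
#' Emits `genotypes.vcf` (unphased), `phased.vcf`, `metadata.tsv`,
#' `truth_ibd.bed` (0-based half-open, sample id in column 4) and
#' `chrom_sizes.tsv` into `dir`.
#'
#' @param sim A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
export_cohort <- function(sim, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    stop("cannot write to directory: ", dir, call. = FALSE)
  }
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    phased_vcf = file.path(dir, "phased.vcf"),
    metadata = file.path(dir, "metadata.tsv"),
    truth_bed = file.path(dir, "truth_ibd.bed"),
    chrom_sizes = file.path(dir, "chrom_sizes.tsv")
  )
  write_vcf(sim$genotypes, paths$vcf)
  write_vcf(sim$haplotypes, paths$phased_vcf)
  m <- sim$meta
  m$selected <- as.integer(m$selected)
  readr::write_tsv(m, paths$metadata)
  seg <- sim$truth$true_ibd_segments
  write_bed(tibble::tibble(chrom = seg$chrom, start = seg$start,
                           end = seg$end, sample = seg$sample),
            paths$truth_bed)
  readr::write_tsv(
    tibble::tibble(chrom = sim$config$genome$chrom,
                   length = sim$config$genome$length_bp),
    paths$chrom_sizes)
  invisible(paths)
}

#' Impose a hard selective sweep on a haplotype panel
#'
#' Emulates a completed/partial hard sweep by copy-replacement: within the
#' given interval, a random fraction of haplotypes is overwritten with one
#' template haplotype, driving that haplotype to high local frequency while
#' leaving the rest of the genome untouched.
#'
#' @param panel A [hap_panel()].
#' @param chrom,start,end Swept interval (1-based inclusive).
#' @param carrier_frac Fraction of haplotypes carrying the swept haplotype.
#' @param template Row index of the template haplotype.
#' @return The modified [hap_panel()].
#' @export
apply_sweep <- function(panel, chrom, start, end, carrier_frac = 0.8,
                        template = 1L) {
  stopifnot(carrier_frac > 0, carrier_frac <= 1)
  cols <- which(panel$variants$chrom == chrom &
                  panel$variants$pos >= start & panel$variants$pos <= end)
  if (!length(cols)) stop("no variants in the swept interval", call. = FALSE)
  n_hap <- nrow(panel$haps)
  n_carrier <- max(2L, round(carrier_frac * n_hap))
  carriers <- sample.int(n_hap, n_carrier)
  panel$haps[carriers, cols] <-
    matrix(panel$haps[template, cols], nrow = n_carrier, ncol = length(cols),
           byrow = TRUE)
  panel
}
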