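#' Write / read ROH segments as BED
#'
#' BED columns: chrom, start (0-based), end, sample, n_snps.
#'
#' @param segments ROH tibble.
#' @param path File path.
#' @return The path (write) or segment tibble (read).
#' @export
write_roh_bed <- function(segments, path) {
  write_bed(segments[, c("chrom", "start", "end", "sample", "n_snps")], path)
}

#' @rdname write_roh_bed
#' @export
read_roh_bed <- function(path) {
  b <- read_bed(path)
  names(b)[4:5] <- c("sample", "n_snps")
  b$sample <- as.character(b$sample)
  b$length <- b$end - b$start + 1
  b[, c("sample", "chrom", "start", "end", "n_snps", "length")]
}

#' Full-analysis configuration
#'
#' Collects every stage parameter of [run_pipeline()]. Exactly one of
#' `input` (paths to a VCF, metadata TSV and chromosome-sizes TSV) or
#' `simulation` (a [sim_config()]) must be supplied.
#'
#' @param input `list(vcf =, metadata =, chrom_sizes =)` or `NULL`.
#' @param simulation A [sim_config()] or `NULL`.
#' @param roh A [roh_call_params()].
#' @param min_length Autozygosity length threshold in bp (default 500 kb).
#' @param prune A [prune_params()].
#' @param max_missing,min_maf SNP QC thresholds.
#' @param bin_width Association bin width in bp (default 10 Mb).
#' @param kpn_cutoff KPN split for the early/late group contrast (`NULL` =
#'   median of the selected samples' KPN).
#' @param ihs_min_maf,ihs_cutoff,ihs_max_gap iHS scan parameters.
#' @param resampling_reps Subsampling replicates (default 1000).
#' @param alpha Per-bin significance level (default 0.01).
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            roh = roh_call_params(), min_length = 500000,
                            prune = prune_params(), max_missing = 0.05,
                            min_maf = 0.01, bin_width = 1e7,
                            kpn_cutoff = NULL, ihs_min_maf = 0.01,
                            ihs_cutoff = 0.05, ihs_max_gap = 200000,
                            resampling_reps = 1000, alpha = 0.01, seed = 1L,
                            out_dir = tempfile("rohselect_run_")) {
  if (is.null(input) == is.null(simulation)) {
    stop("exactly one of `input` or `simulation` must be given",
         call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1)
  structure(list(input = input, simulation = simulation, roh = roh,
                 min_length = min_length, prune = prune,
                 max_missing = max_missing, min_maf = min_maf,
                 bin_width = bin_width, kpn_cutoff = kpn_cutoff,
                 ihs_min_maf = ihs_min_maf, ihs_cutoff = ihs_cutoff,
                 ihs_max_gap = ihs_max_gap,
                 resampling_reps = resampling_reps, alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

log_stage <- function(name, ...) {
  message(sprintf("[%s] %s", name, paste0(...)))
}

#' Run the full ROH / selection-signature analysis
#'
#' Executes, in order: cohort acquisition (simulation or file input), ROH
#' calling and the length-threshold profile, autozygosity filtering, F_roh
#' and F_snp with the group comparison and subsampling distribution, the
#' GRM, the two bin association analyses, the iHS scan with sweep windows,
#' maximal-overlap regions in the top trend bin, cohort correlations, and a
#' machine-readable run manifest. All tables are written under
#' `config$out_dir` with fixed names; reruns with the same config are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly; per-stage results as attribute
#'   `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  res <- list()

  if (!is.null(config$simulation)) {
    sim <- stage("simulate", simulate_cohort(config$simulation))
    stage("simulate", export_cohort(sim, config$out_dir))
    gm <- sim$genotypes
    panel <- sim$haplotypes
    meta <- sim$meta
    chrom_sizes <- tibble::tibble(chrom = config$simulation$genome$chrom,
                                  length = config$simulation$genome$length_bp)
    log_stage("simulate", nrow(meta), " cohort samples, ",
              ncol(gm$dosage), " SNPs")
  } else {
    inp <- stage("input", {
      vc <- read_vcf(config$input$vcf, quiet = TRUE)
      list(vc = vc, meta = read_sample_metadata(config$input$metadata),
           cs = load_chrom_sizes(config$input$chrom_sizes))
    })
    gm <- inp$vc$genotypes
    panel <- inp$vc$haplotypes
    meta <- inp$meta
    chrom_sizes <- inp$cs
    filt <- stage("filter", hard_filter_variants(inp$vc$sites, quiet = TRUE))
    readr::write_tsv(filt$tally, out("filter_summary.tsv"))
    log_stage("input", nrow(meta), " samples, ", ncol(gm$dosage), " SNPs; ",
              filt$tally$n[filt$tally$criterion == "n_removed"],
              " records fail hard filter")
  }
  samples <- rownames(gm$dosage)

  segments <- stage("roh", call_roh(gm, config$roh))
  write_roh_bed(segments, out("roh.bed"))
  prof <- stage("roh", threshold_profile(segments, samples = samples))
  readr::write_tsv(prof, out("threshold_profile.tsv"))
  auto <- stage("roh", filter_autozygous(segments, config$min_length))
  write_roh_bed(auto, out("autozygous.bed"))
  log_stage("roh", nrow(segments), " raw segments -> ", nrow(auto),
            " autozygous (>= ", config$min_length, " bp)")

  froh <- stage("froh", compute_froh(auto, chrom_sizes, samples = samples))
  readr::write_tsv(froh, out("froh.tsv"))
  sel <- froh$f_roh[match(meta$sample[meta$selected], froh$sample)]
  uns <- froh$f_roh[match(meta$sample[!meta$selected], froh$sample)]
  if (length(sel) && length(uns)) {
    cmp <- stage("froh", froh_group_comparison(sel, uns))
    readr::write_tsv(cmp, out("group_comparison.tsv"))
    rs <- stage("froh", froh_resampling(
      sel, uns, k = min(10, length(sel)), reps = config$resampling_reps,
      seed = config$seed + 1L))
    readr::write_tsv(rs, out("froh_resampling.tsv"))
    res$group_comparison <- cmp
  }

  qc <- stage("qc", qc_filter_snps(gm, config$max_missing, config$min_maf))
  log_stage("qc", ncol(gm$dosage), " -> ", ncol(qc$dosage), " SNPs")
  pruned_idx <- stage("fsnp", ld_prune(qc, config$prune))
  fsnp <- stage("fsnp",
                compute_fsnp(subset_geno(qc, keep_variants = pruned_idx)))
  readr::write_tsv(fsnp, out("fsnp.tsv"))
  log_stage("fsnp", length(pruned_idx), " SNPs after pruning")

  G <- stage("grm", compute_grm(qc))
  write_grm(G, out("grm.tsv"))

  bins <- stage("bins", make_bins(chrom_sizes, config$bin_width))
  bm_all <- stage("bins", bin_roh_matrix(auto, bins, samples = samples))
  sel_samples <- meta$sample[meta$selected]
  res$analysis1 <- NULL
  if (length(sel_samples) >= 3) {
    bm <- stage("bins", filter_uninformative_bins(
      bm_all[bm_all$sample %in% sel_samples, ]))
    log_stage("bins", nrow(bins), " bins -> ",
              length(unique(bm$bin_id)), " informative")
    kpn <- stats::setNames(meta$kpn, meta$sample)
    a1 <- stage("assoc1", bm |>
                  dplyr::group_by(bin_id, chrom, start, end) |>
                  dplyr::group_modify(~ analysis1_logistic(
                    .x$status, kpn[.x$sample])) |>
                  dplyr::ungroup())
    a1$significant <- !is.na(a1$p_value) & a1$p_value < config$alpha
    readr::write_tsv(a1, out("analysis1.tsv"))
    res$analysis1 <- a1

    w_ok <- sel_samples[!is.na(meta$weight12m[match(sel_samples,
                                                    meta$sample)])]
    if (length(w_ok) >= 5) {
      eg <- eigen(unclass(G[w_ok, w_ok]), symmetric = TRUE)
      mw <- meta[match(w_ok, meta$sample), ]
      bm2 <- bm[bm$sample %in% w_ok, ]
      a2 <- stage("assoc2", bm2 |>
                    dplyr::group_by(bin_id, chrom, start, end) |>
                    dplyr::group_modify(function(d, key) {
                      d <- d[match(w_ok, d$sample), ]
                      analysis2_lmm(d$roh_length, mw$weight12m, mw$facility,
                                    eigen_G = eg)
                    }) |>
                    dplyr::ungroup())
      a2$significant <- !is.na(a2$p_value) & a2$p_value < config$alpha
      readr::write_tsv(a2, out("analysis2.tsv"))
      res$analysis2 <- a2
    }

    cutoff <- config$kpn_cutoff
    if (is.null(cutoff)) cutoff <- stats::median(kpn[sel_samples])
    chg <- stage("bins", group_mean_length_change(
      bm_all[bm_all$sample %in% sel_samples, ],
      meta[meta$selected, c("sample", "kpn")], cutoff = cutoff))
    readr::write_tsv(chg, out("group_length_change.tsv"))
  }

  if (!is.null(panel)) {
    track <- stage("ihs", standardize_ihs(ihs_scan(
      panel, ehh_cutoff = config$ihs_cutoff, max_gap = config$ihs_max_gap,
      min_maf = config$ihs_min_maf)))
    readr::write_tsv(track, out("ihs_track.tsv"))
    sw <- stage("ihs", sweep_windows(track))
    readr::write_tsv(sw, out("sweep_windows.tsv"))
    log_stage("ihs", sum(!is.na(track$ihs_std)), " scored SNPs, ",
              sum(sw$flagged), " flagged windows")
    res$sweep_windows <- sw
  }

  if (!is.null(res$analysis1) && nrow(auto)) {
    a1 <- res$analysis1
    cand <- a1[order(a1$p_value), ][1, ]
    ov <- stage("overlap", max_overlap_region(
      auto[auto$chrom == cand$chrom, ], chrom = cand$chrom,
      region = c(cand$start, cand$end)))
    if (nrow(ov)) {
      write_bed(ov[, c("chrom", "start", "end", "n_samples")],
                out("overlap_regions.bed"))
      res$overlap <- ov
    }
  }

  fm <- froh[match(meta$sample, froh$sample), ]
  corr <- stage("correlations", cohort_correlations(
    fm$f_roh, meta$kpn, meta$weight12m))
  readr::write_tsv(corr, out("correlations.tsv"))
  res$correlations <- corr

  manifest <- list(
    package = "rohselect",
    version = as.character(utils::packageVersion("rohselect")),
    seed = config$seed,
    parameter_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_samples = length(samples),
    n_snps = ncol(gm$dosage),
    n_roh_segments = nrow(segments),
    n_autozygous_segments = nrow(auto)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  attr(config$out_dir, "results") <- res
  invisible(config$out_dir)
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) {
      stop("unexpected argument: ", args[i], call. = FALSE)
    }
    key <- gsub("-", "_", substring(args[i], 3))
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher over the package functions, for shell use via
#' `Rscript -e 'rohselect::pipeline_cli()' <cmd> ...` or the bundled script
#' `inst/cli/rohselect.R`. Subcommands: `simulate`, `filter`, `roh`, `froh`,
#' `fsnp`, `grm`, `ihs`, `assoc1`, `assoc2`, `overlap`, `report`.
#'
#' @param args Character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 success), invisibly.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: rohselect <simulate|filter|roh|froh|fsnp|grm|ihs|",
            "assoc1|assoc2|overlap|report> [--key value ...]")
    return(invisible(2L))
  }
  cmd <- args[1]
  o <- tryCatch(parse_cli_args(args[-1]),
                error = function(e) { message(conditionMessage(e)); NULL })
  if (is.null(o)) return(invisible(2L))
  num <- function(x, default = NULL) {
    if (is.null(x)) default else as.numeric(x)
  }
  status <- tryCatch({
    switch(
      cmd,
      simulate = {
        cfg <- sim_config(seed = num(o$seed, 1))
        export_cohort(simulate_cohort(cfg), o$out)
      },
      filter = {
        vc <- read_vcf(o$vcf, quiet = TRUE)
        fl <- hard_filter_variants(vc$sites, quiet = TRUE)
        readr::write_tsv(fl$retained, o$out)
        readr::write_tsv(fl$tally, paste0(o$out, ".tally"))
      },
      roh = {
        vc <- read_vcf(o$vcf, quiet = TRUE)
        p <- roh_call_params(
          min_snps = num(o$min_snps, 20),
          max_het_in_run = num(o$max_het, 0),
          max_missing_in_run = num(o$max_missing, 2),
          max_gap = num(o$max_gap, 500000))
        write_roh_bed(call_roh(vc$genotypes, p), o$out)
      },
      froh = {
        seg <- filter_autozygous(read_roh_bed(o$roh),
                                 num(o$min_length, 500000))
        cs <- load_chrom_sizes(o$chrom_sizes)
        readr::write_tsv(compute_froh(seg, cs), o$out)
      },
      fsnp = {
        vc <- read_vcf(o$vcf, quiet = TRUE)
        qc <- qc_filter_snps(vc$genotypes)
        idx <- ld_prune(qc)
        readr::write_tsv(compute_fsnp(subset_geno(qc, keep_variants = idx)),
                         o$out)
      },
      grm = {
        vc <- read_vcf(o$vcf, quiet = TRUE)
        write_grm(compute_grm(qc_filter_snps(vc$genotypes)), o$out)
      },
      ihs = {
        vc <- read_vcf(o$vcf, quiet = TRUE)
        if (is.null(vc$haplotypes)) stop("ihs requires a fully phased VCF")
        tr <- standardize_ihs(ihs_scan(vc$haplotypes,
                                       min_maf = num(o$maf, 0.01)))
        readr::write_tsv(tr, o$out)
        readr::write_tsv(sweep_windows(tr), paste0(o$out, ".windows"))
      },
      assoc1 = {
        seg <- filter_autozygous(read_roh_bed(o$roh),
                                 num(o$min_length, 500000))
        meta <- read_sample_metadata(o$meta)
        bins <- make_bins(load_chrom_sizes(o$chrom_sizes),
                          num(o$bin_width, 1e7))
        sel <- meta$sample[meta$selected]
        bm <- filter_uninformative_bins(
          bin_roh_matrix(seg, bins, samples = sel))
        kpn <- stats::setNames(meta$kpn, meta$sample)
        alpha <- num(o$alpha, 0.01)
        a1 <- bm |>
          dplyr::group_by(bin_id, chrom, start, end) |>
          dplyr::group_modify(~ analysis1_logistic(.x$status,
                                                   kpn[.x$sample])) |>
          dplyr::ungroup()
        a1$significant <- !is.na(a1$p_value) & a1$p_value < alpha
        readr::write_tsv(a1, o$out)
      },
      assoc2 = {
        seg <- filter_autozygous(read_roh_bed(o$roh),
                                 num(o$min_length, 500000))
        meta <- read_sample_metadata(o$meta)
        vc <- read_vcf(o$vcf, quiet = TRUE)
        bins <- make_bins(load_chrom_sizes(o$chrom_sizes),
                          num(o$bin_width, 1e7))
        sel <- meta$sample[meta$selected & !is.na(meta$weight12m)]
        G <- compute_grm(qc_filter_snps(vc$genotypes))
        eg <- eigen(unclass(G[sel, sel]), symmetric = TRUE)
        mw <- meta[match(sel, meta$sample), ]
        bm <- filter_uninformative_bins(
          bin_roh_matrix(seg, bins, samples = sel))
        alpha <- num(o$alpha, 0.01)
        a2 <- bm |>
          dplyr::group_by(bin_id, chrom, start, end) |>
          dplyr::group_modify(function(d, key) {
            d <- d[match(sel, d$sample), ]
            analysis2_lmm(d$roh_length, mw$weight12m, mw$facility,
                          eigen_G = eg)
          }) |>
          dplyr::ungroup()
        a2$significant <- !is.na(a2$p_value) & a2$p_value < alpha
        readr::write_tsv(a2, o$out)
      },
      overlap = {
        seg <- read_roh_bed(o$roh)
        ov <- max_overlap_region(seg, chrom = o$chrom,
                                 region = c(num(o$start), num(o$end)))
        write_bed(ov[, c("chrom", "start", "end", "n_samples")], o$out)
      },
      report = {
        cfg_raw <- yaml::read_yaml(o$config)
        sim <- if (!is.null(cfg_raw$simulation)) {
          do.call(sim_config, cfg_raw$simulation)
        }
        cfg <- pipeline_config(
          input = cfg_raw$input, simulation = sim,
          seed = if (!is.null(cfg_raw$seed)) cfg_raw$seed else 1L,
          out_dir = if (!is.null(o$out)) o$out else cfg_raw$out_dir)
        run_pipeline(cfg)
      },
      stop("unknown subcommand: ", cmd)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
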