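#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF (v4.x, plain or gzip) and returns alternate-allele dosages for
#' autosomal-style biallelic SNP records. Multiallelic and non-SNP records are
#' skipped and counted. Missing genotypes (`./.`) become `NA`. When every
#' genotype in the file is phased (`|` separator) the phased haplotypes are
#' returned as well.
#'
#' @param path Path to a VCF file.
#' @param region Optional list `list(chrom =, start =, end =)` restricting the
#'   variants returned (1-based inclusive).
#' @param quiet Suppress the skipped-record message.
#' @return A list with elements `genotypes` (a [geno_matrix()]), `haplotypes`
#'   (a [hap_panel()] or `NULL` when the file is not fully phased),
#'   `n_skipped` (count of multiallelic / non-SNP records), and `sites`
#'   (per-retained-record tibble of `chrom`, `pos`, `qual`, `dp`, `mq0`, `fs`
#'   for hard filtering).
#' @export
read_vcf <- function(path, region = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("no such VCF: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF has no sample columns", call. = FALSE)
  ref <- fix$REF
  alt <- fix$ALT
  snp <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (!quiet && n_skipped > 0) {
    message("read_vcf: skipped ", n_skipped, " multiallelic/non-SNP record(s)")
  }
  keep <- which(snp)
  pos <- as.integer(fix$POS)
  if (!is.null(region)) {
    keep <- keep[fix$CHROM[keep] == region$chrom &
                   pos[keep] >= region$start & pos[keep] <= region$end]
  }
  if (!length(keep)) stop("no biallelic SNP records retained", call. = FALSE)

  gt_raw <- v@gt[keep, -1L, drop = FALSE]
  fmt <- v@gt[keep, 1L]
  gt_field <- function(cell, fmt) {
    idx <- match("GT", strsplit(fmt, ":", fixed = TRUE)[[1L]])
    vapply(strsplit(cell, ":", fixed = TRUE), function(p) p[[idx]], "")
  }
  samples <- colnames(v@gt)[-1L]
  gt <- matrix("", nrow = length(keep), ncol = length(samples))
  for (j in seq_along(samples)) gt[, j] <- gt_field(gt_raw[, j], fmt)

  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  dim(a1) <- dim(a2) <- dim(sep) <- dim(gt)
  d1 <- suppressWarnings(as.numeric(a1))
  d2 <- suppressWarnings(as.numeric(a2))
  dosage <- matrix(d1 + d2, nrow = length(keep))
  dosage <- t(dosage)                      # samples x variants
  rownames(dosage) <- samples

  variants <- tibble::tibble(
    chrom = fix$CHROM[keep], pos = pos[keep],
    ref = ref[keep], alt = alt[keep]
  )
  ord <- order(match(variants$chrom, unique(variants$chrom)), variants$pos)
  variants <- variants[ord, ]
  dosage <- dosage[, ord, drop = FALSE]
  gm <- geno_matrix(dosage, variants)

  phased <- all(sep[!is.na(d1 + d2)] == "|") && any(!is.na(d1 + d2))
  panel <- NULL
  if (phased && !anyNA(dosage)) {
    h <- matrix(0L, nrow = 2L * length(samples), ncol = length(keep))
    for (j in seq_along(samples)) {
      h[2L * j - 1L, ] <- as.integer(a1[, j])
      h[2L * j, ] <- as.integer(a2[, j])
    }
    h <- h[, ord, drop = FALSE]
    panel <- hap_panel(h, variants, samples)
  }

  info <- fix$INFO[keep][ord]
  info_num <- function(key) {
    pat <- paste0("(^|;)", key, "=[^;]+")
    out <- rep(NA_real_, length(info))
    hit <- grepl(pat, info)
    out[hit] <- as.numeric(sub(paste0(".*", key, "="), "",
                               regmatches(info, regexpr(pat, info))))
    out
  }
  sites <- tibble::tibble(
    chrom = variants$chrom, pos = variants$pos,
    qual = suppressWarnings(as.numeric(fix$QUAL[keep][ord])),
    dp = info_num("DP"), mq0 = info_num("MQ0"), fs = info_num("FS")
  )
  list(genotypes = gm, haplotypes = panel, n_skipped = n_skipped, sites = sites)
}

#' Hard-filter thresholds for variant records
#'
#' The conventional post-calling hard filter: records failing any criterion
#' are removed. Defaults follow the usual short-read resequencing practice
#' (Phred site quality at least 30, total depth at least 5, at most 4
#' mapping-quality-zero reads, Fisher-strand score at most 200).
#'
#' @param min_qual Minimum Phred-scaled site quality (records with
#'   `QUAL < min_qual` removed).
#' @param min_depth Minimum total read depth (`DP < min_depth` removed).
#' @param max_mq0 Maximum count of mapping-quality-zero reads (`MQ0 > max_mq0`
#'   removed).
#' @param max_fs Maximum Phred-scaled Fisher-strand score (`FS > max_fs`
#'   removed).
#' @return A list of class `variant_filter_thresholds`.
#' @export
variant_filter_thresholds <- function(min_qual = 30, min_depth = 5,
                                      max_mq0 = 4, max_fs = 200) {
  stopifnot(min_qual >= 0, min_depth >= 0, max_mq0 >= 0, max_fs >= 0)
  structure(list(min_qual = min_qual, min_depth = min_depth,
                 max_mq0 = max_mq0, max_fs = max_fs),
            class = "variant_filter_thresholds")
}

#' Apply the hard filter to variant site records
#'
#' A record is removed iff `qual < min_qual` OR `dp < min_depth` OR
#' `mq0 > max_mq0` OR `fs > max_fs` — strict inequalities, so records exactly
#' at a boundary are retained. A missing field passes its criterion (logged).
#'
#' @param records Data frame with columns `qual`, `dp`, `mq0`, `fs` (other
#'   columns are carried through).
#' @param thresholds A [variant_filter_thresholds()].
#' @param quiet Suppress the missing-field message.
#' @return A list: `retained` (tibble of surviving records) and `tally`
#'   (tibble of per-criterion rejection counts; a record failing several
#'   criteria is counted under each, and `n_removed` gives distinct removals).
#' @export
hard_filter_variants <- function(records, thresholds = variant_filter_thresholds(),
                                 quiet = FALSE) {
  records <- tibble::as_tibble(records)
  need <- c("qual", "dp", "mq0", "fs")
  miss_cols <- setdiff(need, names(records))
  if (length(miss_cols)) {
    stop("records lack field(s): ", paste(miss_cols, collapse = ", "),
         call. = FALSE)
  }
  n_na <- sum(vapply(records[need], function(x) sum(is.na(x)), 0L))
  if (n_na > 0 && !quiet) {
    message("hard_filter_variants: ", n_na,
            " missing field value(s) treated as passing")
  }
  fail_qual <- !is.na(records$qual) & records$qual < thresholds$min_qual
  fail_dp <- !is.na(records$dp) & records$dp < thresholds$min_depth
  fail_mq0 <- !is.na(records$mq0) & records$mq0 > thresholds$max_mq0
  fail_fs <- !is.na(records$fs) & records$fs > thresholds$max_fs
  removed <- fail_qual | fail_dp | fail_mq0 | fail_fs
  tally <- tibble::tibble(
    criterion = c("qual", "depth", "mq0", "fs", "n_removed"),
    n = c(sum(fail_qual), sum(fail_dp), sum(fail_mq0), sum(fail_fs),
          sum(removed))
  )
  list(retained = records[!removed, , drop = FALSE], tally = tally)
}

#' Read the per-sample covariate table
#'
#' Tab-separated with header `sample`, `kpn`, `selected`, `facility`,
#' `weight12m`. Unselected animals have an empty/NA registration (KPN) number;
#' a selected animal without one is an error, as is a duplicated sample id.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `sample` (chr), `kpn` (int, `NA` for
#'   unselected), `selected` (logical), `facility` (chr), `weight12m` (dbl kg,
#'   may be `NA`).
#' @export
read_sample_metadata <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(),
    kpn = readr::col_integer(),
    selected = readr::col_integer(),
    facility = readr::col_character(),
    weight12m = readr::col_double()
  ), na = c("", "NA"))
  need <- c("sample", "kpn", "selected", "facility", "weight12m")
  if (!identical(names(m)[seq_along(need)], need)) {
    stop("metadata header must be: ", paste(need, collapse = "\t"),
         call. = FALSE)
  }
  if (anyDuplicated(m$sample)) {
    stop("duplicate sample id(s) in metadata", call. = FALSE)
  }
  m$selected <- m$selected == 1L
  if (any(m$selected & is.na(m$kpn))) {
    stop("selected animal(s) lack a KPN number", call. = FALSE)
  }
  m
}

#' Chromosome sizes
#'
#' Loads either the bundled cattle UMD3.1 autosome table (29 chromosomes) or a
#' two-column TSV `chrom`, `length`.
#'
#' @param source `"umd3.1_autosomes"` or a file path.
#' @return Tibble `chrom` (chr), `length` (dbl bp).
#' @export
load_chrom_sizes <- function(source = "umd3.1_autosomes") {
  path <- if (identical(source, "umd3.1_autosomes")) {
    system.file("extdata", "umd3.1_autosomes.tsv", package = "rohselect",
                mustWork = TRUE)
  } else if (file.exists(source)) {
    source
  } else {
    stop("unknown chromosome-sizes source: ", source, call. = FALSE)
  }
  cs <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), length = readr::col_double()
  ))
  if (any(cs$length <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  if (anyDuplicated(cs$chrom)) stop("duplicate chromosome names", call. = FALSE)
  cs
}

#' Write a genotype matrix or haplotype panel as VCF v4.2
#'
#' Deterministic plain-text writer: identical inputs give identical bytes.
#' Unphased output uses `/` with `NA` dosage written as `./.`; phased output
#' writes each sample's two haplotypes joined by `|`.
#'
#' @param x A [geno_matrix()] or, for phased output, a [hap_panel()].
#' @param path Output path.
#' @param sites Optional site table (as from [read_vcf()]) supplying `qual`,
#'   `dp`, `mq0`, `fs` for the QUAL/INFO columns; otherwise `.` is written.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, sites = NULL) {
  phased <- inherits(x, "hap_panel")
  v <- x$variants
  n_var <- nrow(v)
  if (phased) {
    samples <- x$samples
    n <- length(samples)
    h1 <- x$haps[seq(1, 2 * n, by = 2), , drop = FALSE]
    h2 <- x$haps[seq(2, 2 * n, by = 2), , drop = FALSE]
    gt <- matrix(paste0(h1, "|", h2), nrow = n)
  } else {
    samples <- rownames(x$dosage)
    d <- x$dosage
    gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
    gt[!is.na(d) & d == 0] <- "0/0"
    gt[!is.na(d) & d == 1] <- "0/1"
    gt[!is.na(d) & d == 2] <- "1/1"
  }
  qual <- rep(".", n_var)
  info <- rep(".", n_var)
  if (!is.null(sites)) {
    qual <- format(sites$qual, trim = TRUE)
    info <- sprintf("DP=%s;MQ0=%s;FS=%s",
                    format(sites$dp, trim = TRUE),
                    format(sites$mq0, trim = TRUE),
                    format(sites$fs, trim = TRUE))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writer <- function(lines) writeLines(lines, con, sep = "\n")
  writer(c("##fileformat=VCFv4.2",
           "##source=rohselect",
           paste0("##contig=<ID=", unique(v$chrom), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t")))
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, qual, ".", info, "GT",
                sep = "\t")
  gt_cols <- apply(gt, 2, paste, collapse = "\t")
  writer(paste(body, gt_cols, sep = "\t"))
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based inclusive)
#'   and optional extra columns written after the three coordinates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  bed <- to_bed_coords(intervals$start, intervals$end)
  out <- dplyr::bind_cols(
    tibble::tibble(chrom = intervals$chrom, start = bed$start, end = bed$end),
    intervals[setdiff(names(intervals), c("chrom", "start", "end"))]
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file into 1-based inclusive intervals
#'
#' @param path BED path; the first three columns are chrom/start/end, any
#'   further columns are kept with names `x4`, `x5`, ...
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive) plus extras.
#' @export
read_bed <- function(path) {
  b <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols())
  names(b)[1:3] <- c("chrom", "start0", "end0")
  coords <- from_bed_coords(b$start0, b$end0)
  out <- tibble::tibble(chrom = as.character(b$chrom),
                        start = coords$start, end = coords$end)
  extra <- b[-(1:3)]
  if (ncol(extra)) {
    names(extra) <- paste0("x", 3 + seq_len(ncol(extra)))
    out <- dplyr::bind_cols(out, extra)
  }
  out
}
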