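# Repeat-expansion screening: leave-one-out outlier z on motif count profiles
# and intersection with known disease STR loci.

#' Read a motif count profile
#'
#' @param path TSV with columns `sample_id, motif, region, count` (long
#'   format; `region` as `chrom:start-end`).
#' @return data.frame of normalized anchored-repeat read counts.
#' @export
read_str_profile <- function(path) {
  if (!file.exists(path)) trioppv_stop("STR profile not found: ", path)
  prof <- read_tsv(path)
  need <- c("sample_id", "motif", "region", "count")
  if (length(setdiff(need, names(prof))))
    trioppv_stop("STR profile needs columns: ", paste(need, collapse = ", "))
  prof
}

#' Leave-one-out outlier scan over a motif count matrix
#'
#' For each (motif, region) column, each sample's count is compared with the
#' mean and standard deviation of all *other* samples:
#' `z_i = (x_i - mean_{j != i}) / sd_{j != i}`. A sample is flagged when its z
#' strictly exceeds the threshold (default 10). Columns with fewer than 3
#' samples or zero variance among the others yield no flags.
#'
#' @param profile long-format data.frame from [read_str_profile()].
#' @param z_threshold outlier threshold (strict >).
#' @return data.frame of flags: `sample_id, motif, region, count, z`.
#' @export
motif_outlier_scan <- function(profile, z_threshold = 10) {
  empty <- data.frame(sample_id = character(), motif = character(),
                      region = character(), count = numeric(), z = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(profile) == 0) return(empty)
  out <- list()
  for (key in unique(paste(profile$motif, profile$region))) {
    col <- profile[paste(profile$motif, profile$region) == key, , drop = FALSE]
    n <- nrow(col)
    if (n < 3) next
    x <- col$count
    s <- sum(x); ss <- sum(x^2)
    for (i in seq_len(n)) {
      m_loo <- (s - x[i]) / (n - 1)
      var_loo <- (ss - x[i]^2 - (n - 1) * m_loo^2) / (n - 2)
      if (is.na(var_loo) || var_loo <= 0) next
      z <- (x[i] - m_loo) / sqrt(var_loo)
      if (z > z_threshold)
        out[[length(out) + 1]] <- data.frame(
          sample_id = col$sample_id[i], motif = col$motif[i],
          region = col$region[i], count = x[i], z = z,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$sample_id, res$motif, res$region), , drop = FALSE]
}

#' Annotate repeat flags with known disease STR loci
#'
#' @param flags data.frame from [motif_outlier_scan()].
#' @param loci data.frame with columns `gene, chrom, start, end`; defaults to
#'   the packaged table of 10 ASD-associated STR loci (approximate synthetic
#'   coordinates).
#' @return `flags` with a `known_locus` column (gene symbol or NA).
#' @export
known_locus_overlap <- function(flags, loci = default_str_loci()) {
  flags$known_locus <- rep(NA_character_, nrow(flags))
  if (nrow(flags) == 0 || nrow(loci) == 0) return(flags)
  m <- regmatches(flags$region,
                  regexec("^([^:]+):([0-9]+)-([0-9]+)$", flags$region))
  bad <- lengths(m) != 4
  if (any(bad))
    trioppv_stop("malformed STR region: ", flags$region[bad][1])
  fchrom <- vapply(m, `[`, "", 2)
  fstart <- as.numeric(vapply(m, `[`, "", 3))
  fend <- as.numeric(vapply(m, `[`, "", 4))
  gr_f <- GenomicRanges::GRanges(fchrom, IRanges::IRanges(fstart, fend))
  gr_l <- GenomicRanges::GRanges(loci$chrom,
                                 IRanges::IRanges(loci$start, loci$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_f, gr_l, select = "first"))
  flags$known_locus <- ifelse(is.na(hits), NA_character_, loci$gene[hits])
  flags
}

#' Packaged known ASD-associated STR loci
#'
#' Ten STR loci screened for in the repeat analysis (DMPK, FGF14, CACNB1,
#' FXN, CDON, MYOCD, MBOAT7, IL1RAPL1, FMR1, IGF1), with approximate
#' synthetic hg38 coordinates.
#'
#' @return data.frame with `gene, chrom, start, end`.
#' @export
default_str_loci <- function() {
  path <- system.file("extdata", "asd_str_loci_synthetic.tsv",
                      package = "trioppv")
  if (!nzchar(path)) trioppv_stop("packaged STR locus table not found")
  read_tsv(path)
}
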