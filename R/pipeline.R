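# End-to-end pipeline: from the cohort file set to PPV records, inherited
# findings, noncoding hits, repeat flags and the cohort summary.

#' Run the full trio prioritization pipeline
#'
#' @param ped PED file path.
#' @param vcf small-variant multi-sample VCF path.
#' @param annot annotation sidecar TSV path.
#' @param sv_a,sv_b SV VCFs of the primary and secondary caller (the
#'   secondary caller is additionally gated on PRECISE).
#' @param cnv CNV log2-ratio segment TSV path.
#' @param mito chrM VCF path.
#' @param mito_pathogenic pathogenicity table TSV path.
#' @param panel gene panel TSV path.
#' @param cre fetal brain CRE BED path.
#' @param str_profile motif count profile TSV path (optional; NULL skips the
#'   repeat stage).
#' @param str_loci known STR locus table (defaults to the packaged list).
#' @param out_dir if non-NULL, [write_report()] is called on the results.
#' @param config [trioppv_config()].
#' @return object of class `trioppv_result`: list with `ppv_records`,
#'   `summary`, `inherited_findings`, `noncoding`, `repeat_flags`,
#'   `smallvar_qc` (record tallies), `classified` (the classified small-variant
#'   table), `sv_labeled`, `mito_classified`, and `pedigree`.
#' @export
run_trio_pipeline <- function(ped, vcf, annot, sv_a, sv_b, cnv, mito,
                              mito_pathogenic, panel, cre,
                              str_profile = NULL,
                              str_loci = default_str_loci(),
                              out_dir = NULL,
                              config = trioppv_config()) {
  config <- as_trioppv_config(config)
  pedigree <- read_pedigree(ped)
  pan <- read_panel_and_intervals(panel, cre)

  calls <- read_small_variants(vcf, annot, pedigree)
  classified <- classify_smallvar_calls(calls, config)
  pairs <- cohort_compound_hets(classified, config)
  ppv_small <- prioritize_small_variants(classified, pairs, pan$panel, config)

  set_a <- read_sv_calls(sv_a, "caller_a")
  set_b <- read_sv_calls(sv_b, "caller_b")
  cons <- consensus_intersect(set_a, set_b, config)
  cnv_set <- cnv_from_log2(read_cnv_segments(cnv), config = config)
  pooled <- pool_sv_calls(cons, cnv_set, config)
  sv_labeled <- classify_sv_inheritance(pooled, pedigree, config)
  sv_out <- prioritize_svs(sv_labeled, pan$exons, config)

  mito_calls <- read_mito_calls(mito, mito_pathogenic)
  mito_classified <- classify_mito_cohort(mito_calls, pedigree,
                                          config$mito_heteroplasmy_pct)
  ppv_mito <- prioritize_mito(mito_classified)

  ppv <- rbind(ppv_small, sv_out$ppv, ppv_mito)
  ppv <- ppv[order(ppv$patient_id, ppv$chrom, ppv$pos, ppv$details), ,
             drop = FALSE]
  rownames(ppv) <- NULL

  noncoding <- noncoding_cre_overlap(classified, pan$cre, pan$panel, ppv)

  repeat_flags <- NULL
  if (!is.null(str_profile)) {
    prof <- read_str_profile(str_profile)
    repeat_flags <- known_locus_overlap(
      motif_outlier_scan(prof, config$str_z_threshold), str_loci)
  }

  summary <- summarize_cohort(ppv, pedigree, noncoding)
  res <- structure(list(
    ppv_records = ppv, summary = summary,
    inherited_findings = sv_out$inherited, noncoding = noncoding,
    repeat_flags = repeat_flags,
    smallvar_qc = list(
      n_records_total = attr(calls, "n_records_total"),
      n_multiallelic = attr(calls, "n_multiallelic"),
      n_sites_kept = attr(calls, "n_sites_kept")),
    classified = classified, sv_labeled = sv_labeled,
    mito_classified = mito_classified, pedigree = pedigree),
    class = "trioppv_result")
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

#' @export
print.trioppv_result <- function(x, ...) {
  cat("trioppv pipeline result\n")
  cat(sprintf("  small-variant records: %d kept (%d multi-allelic excluded of %d)\n",
              x$smallvar_qc$n_sites_kept, x$smallvar_qc$n_multiallelic,
              x$smallvar_qc$n_records_total))
  print(x$summary)
  if (!is.null(x$repeat_flags))
    cat(sprintf("  repeat outlier flags: %d (%d at known STR loci)\n",
                nrow(x$repeat_flags),
                sum(!is.na(x$repeat_flags$known_locus))))
  if (nrow(x$inherited_findings))
    cat(sprintf("  inherited panel-gene SV findings: %d\n",
                nrow(x$inherited_findings)))
  invisible(x)
}

#' Write the per-patient and cohort reports
#'
#' Writes `ppv_records.tsv` (one row per PPV record, ordered by patient id
#' then chrom/pos), `inherited_findings.tsv`, `noncoding_hits.tsv` and
#' `cohort_summary.json`. Output is deterministic: identical results give
#' byte-identical files regardless of input record order.
#'
#' @param result `trioppv_result` (or a list with `ppv_records` and
#'   `summary`).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ord <- function(d) {
    if (is.null(d) || nrow(d) == 0) return(d)
    d <- d[order(d$patient_id, d$chrom, d$pos, d$details), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  paths <- c(
    ppv = file.path(out_dir, "ppv_records.tsv"),
    inherited = file.path(out_dir, "inherited_findings.tsv"),
    noncoding = file.path(out_dir, "noncoding_hits.tsv"),
    summary = file.path(out_dir, "cohort_summary.json"))
  write_tsv(ord(result$ppv_records), paths["ppv"])
  inh <- result$inherited_findings %||% .ppv_frame()
  write_tsv(ord(inh), paths["inherited"])
  nc <- if (!is.null(result$noncoding)) result$noncoding$hits else
    data.frame(patient_id = character(), variant_id = character(),
               chrom = character(), pos = numeric(),
               linked_gene = character())
  nc <- nc[order(nc$patient_id, nc$chrom, nc$pos), , drop = FALSE]
  rownames(nc) <- NULL
  write_tsv(nc, paths["noncoding"])
  jsonlite::write_json(unclass(result$summary), paths["summary"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
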