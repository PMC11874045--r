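# Prioritization of potentially pathogenic variants (PPVs): combines the
# engine outputs under the inheritance-stratified panel rules, runs the
# noncoding CRE overlap, and produces the cohort summary.

.ppv_frame <- function() {
  data.frame(patient_id = character(), variant_class = character(),
             inheritance = character(), gene = character(),
             rule_fired = character(), details = character(),
             chrom = character(), pos = numeric(), stringsAsFactors = FALSE)
}

#' Prioritize small variants
#'
#' De novo SNVs/INDELs in ASD/IDD panel genes are PPVs when protein-altering
#' (PTV, qualifying splice, or missense; synonymous and other consequences are
#' excluded). Homozygous-recessive and maternally inherited hemizygous
#' variants in panel genes are PPVs when PTV-equivalent or missense with
#' MPC > 2. Compound-heterozygous pairs from [cohort_compound_hets()] in panel
#' genes yield one PPV record per pair.
#'
#' @param classified output of [classify_smallvar_calls()] (QC, labels and
#'   rarity columns present).
#' @param comphet_pairs output of [cohort_compound_hets()].
#' @param panel panel data.frame from [read_panel_and_intervals()].
#' @param config [trioppv_config()].
#' @return data.frame of PPV records (`patient_id, variant_class, inheritance,
#'   gene, rule_fired, details, chrom, pos`).
#' @export
prioritize_small_variants <- function(classified, comphet_pairs, panel,
                                      config = trioppv_config()) {
  config <- as_trioppv_config(config)
  panel_genes <- panel$gene_symbol[panel$is_asd_idd]
  v <- classified[classified$rarity_pass & !is.na(classified$gene) &
                    classified$gene %in% panel_genes, , drop = FALSE]
  out <- list()

  dn <- v[v$label == "de_novo" &
            v$conseq_class %in% c("ptv", "qualifying_splice", "missense"), ,
          drop = FALSE]
  if (nrow(dn))
    out[[length(out) + 1]] <- data.frame(
      patient_id = dn$family_id, variant_class = "smallvar",
      inheritance = "de_novo", gene = dn$gene, rule_fired = "denovo_panel",
      details = dn$variant_id, chrom = dn$chrom, pos = dn$pos,
      stringsAsFactors = FALSE)

  ptv_like <- function(cc) cc %in% c("ptv", "qualifying_splice")
  strong <- function(x) ptv_like(x$conseq_class) |
    (x$conseq_class == "missense" & !is.na(x$mpc) & x$mpc > config$mpc_single)
  for (lb in c("homozygous_recessive", "hemizygous_maternal")) {
    sel <- v[v$label == lb, , drop = FALSE]
    sel <- sel[strong(sel), , drop = FALSE]
    if (nrow(sel))
      out[[length(out) + 1]] <- data.frame(
        patient_id = sel$family_id, variant_class = "smallvar",
        inheritance = lb, gene = sel$gene,
        rule_fired = ifelse(ptv_like(sel$conseq_class),
                            paste0(sub("_.*", "", lb), "_ptv"),
                            paste0(sub("_.*", "", lb), "_mpc")),
        details = sel$variant_id, chrom = sel$chrom, pos = sel$pos,
        stringsAsFactors = FALSE)
  }

  ch <- comphet_pairs[comphet_pairs$gene %in% panel_genes, , drop = FALSE]
  if (nrow(ch)) {
    mpos <- classified$pos[match(ch$maternal_id, classified$variant_id)]
    mchrom <- classified$chrom[match(ch$maternal_id, classified$variant_id)]
    out[[length(out) + 1]] <- data.frame(
      patient_id = ch$family_id, variant_class = "smallvar",
      inheritance = "compound_het", gene = ch$gene,
      rule_fired = paste0("comphet_", ch$clause),
      details = paste(ch$maternal_id, ch$paternal_id, sep = "|"),
      chrom = mchrom, pos = mpos, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(.ppv_frame())
  res[order(res$patient_id, res$chrom, res$pos), , drop = FALSE]
}

#' Prioritize structural variants
#'
#' SVs passing the rarity filter whose interval overlaps exonic regions of
#' ASD/IDD panel genes are PPVs when de novo, homozygous recessive, or
#' maternally inherited hemizygous. Inherited (single-parent or biparental)
#' panel-gene SVs are returned separately as inherited findings, never counted
#' as PPVs.
#'
#' @param sv_labeled output of [classify_sv_inheritance()].
#' @param panel_exons panel exon GRanges.
#' @param config [trioppv_config()].
#' @return list with `ppv` (PPV records) and `inherited` (inherited-findings
#'   records of the same shape).
#' @export
prioritize_svs <- function(sv_labeled, panel_exons,
                           config = trioppv_config()) {
  config <- as_trioppv_config(config)
  if (nrow(sv_labeled) == 0)
    return(list(ppv = .ppv_frame(), inherited = .ppv_frame()))
  rare <- sv_rarity_filter(sv_labeled$label, sv_labeled$maf,
                           sv_labeled$n_carrier_families, config)
  v <- sv_labeled[rare, , drop = FALSE]
  genes <- exonic_gene_overlap(v, panel_exons)
  hit <- lengths(genes) > 0
  v <- v[hit, , drop = FALSE]
  genes <- genes[hit]
  if (nrow(v) == 0) return(list(ppv = .ppv_frame(), inherited = .ppv_frame()))
  rec <- data.frame(
    patient_id = v$family_id, variant_class = "sv", inheritance = v$label,
    gene = vapply(genes, paste, "", collapse = ","),
    rule_fired = paste0("sv_", v$label),
    details = paste0(v$sv_type, ":", v$chrom, ":", v$start, "-", v$end),
    chrom = v$chrom, pos = v$start, stringsAsFactors = FALSE)
  is_ppv <- v$label %in% c("de_novo", "homozygous_recessive",
                           "hemizygous_maternal")
  is_inh <- v$label %in% c("inherited_maternal", "inherited_paternal",
                           "inherited_biparental")
  ord <- function(d) d[order(d$patient_id, d$chrom, d$pos), , drop = FALSE]
  list(ppv = ord(rec[is_ppv, , drop = FALSE]),
       inherited = ord(rec[is_inh, , drop = FALSE]))
}

#' Prioritize mitochondrial variants
#'
#' One PPV record per reportable classification from
#' [classify_mito_cohort()] (known pathogenic, proband heteroplasmy above
#' threshold).
#'
#' @param mito_classified output of [classify_mito_cohort()].
#' @return data.frame of PPV records.
#' @export
prioritize_mito <- function(mito_classified) {
  m <- mito_classified[mito_classified$class != "not_reportable", ,
                       drop = FALSE]
  if (nrow(m) == 0) return(.ppv_frame())
  inh <- c(ppv_de_novo = "de_novo", ppv_maternal = "inherited_maternal",
           ppv_maternal_unknown = "uninformative")[m$class]
  rec <- data.frame(
    patient_id = m$family_id, variant_class = "mito",
    inheritance = unname(inh), gene = NA_character_,
    rule_fired = "mito_pathogenic_heteroplasmy",
    details = paste0("m.", m$pos, m$ref, ">", m$alt, " (",
                     m$proband_pct, "%)"),
    chrom = "chrM", pos = m$pos, stringsAsFactors = FALSE)
  rec[order(rec$patient_id, rec$pos), , drop = FALSE]
}

#' Noncoding overlap of de novo variants with fetal brain CREs
#'
#' Reports de novo small variants lying inside a fetal brain-specific
#' cis-regulatory element whose linked gene is an ASD/IDD panel gene. These
#' hits are reported, not counted as PPVs. The summary counts distinct
#' patients with a hit and, among them, those without any coding PPV.
#'
#' @param classified output of [classify_smallvar_calls()].
#' @param cre CRE GRanges (`linked_gene` metadata).
#' @param panel panel data.frame.
#' @param ppv_records combined PPV records (to determine which hit patients
#'   lack coding PPVs; mitochondrial records are not coding).
#' @return list with `hits` (data.frame `patient_id, variant_id, chrom, pos,
#'   linked_gene`), `n_patients`, `n_without_coding_ppv`.
#' @export
noncoding_cre_overlap <- function(classified, cre, panel, ppv_records) {
  dn <- classified[classified$label == "de_novo" & classified$rarity_pass, ,
                   drop = FALSE]
  panel_genes <- panel$gene_symbol[panel$is_asd_idd]
  hits <- data.frame(patient_id = character(), variant_id = character(),
                     chrom = character(), pos = numeric(),
                     linked_gene = character(), stringsAsFactors = FALSE)
  if (nrow(dn) > 0 && length(cre) > 0) {
    gr <- GenomicRanges::GRanges(dn$chrom, IRanges::IRanges(dn$pos, dn$pos))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(gr, cre))
    if (length(ov)) {
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      keep <- cre$linked_gene[s] %in% panel_genes
      q <- q[keep]; s <- s[keep]
      if (length(q))
        hits <- unique(data.frame(
          patient_id = dn$family_id[q], variant_id = dn$variant_id[q],
          chrom = dn$chrom[q], pos = dn$pos[q],
          linked_gene = cre$linked_gene[s], stringsAsFactors = FALSE))
    }
  }
  hits <- hits[order(hits$patient_id, hits$chrom, hits$pos), , drop = FALSE]
  coding_carriers <- unique(
    ppv_records$patient_id[ppv_records$variant_class %in% c("smallvar", "sv")])
  pats <- unique(hits$patient_id)
  list(hits = hits, n_patients = length(pats),
       n_without_coding_ppv = sum(!(pats %in% coding_carriers)))
}

#' Cohort summary
#'
#' Counts PPV records and carrier patients, stratifies by comorbid IDD
#' (two-sided Fisher exact test on the IDD x carrier 2x2 table), breaks
#' records down by variant class, and attaches the noncoding CRE counts.
#' Percentages are rounded half-up to one decimal.
#'
#' @param ppv_records combined PPV record data.frame.
#' @param pedigree pedigree data.frame.
#' @param noncoding result of [noncoding_cre_overlap()] (optional).
#' @return a list of class `cohort_summary`.
#' @export
summarize_cohort <- function(ppv_records, pedigree, noncoding = NULL) {
  trios <- trio_members(pedigree)
  carriers <- unique(ppv_records$patient_id)
  n_pat <- nrow(trios)
  idd <- trios$idd
  carrier <- trios$family_id %in% carriers
  pct <- function(num, den) if (den > 0) round_half_up(100 * num / den, 1) else 0.0
  tab <- matrix(c(sum(idd & carrier), sum(idd & !carrier),
                  sum(!idd & carrier), sum(!idd & !carrier)),
                nrow = 2, byrow = TRUE)
  comparison_p <- if (length(carriers) == 0) 1.0 else
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  cls <- c(smallvar = 0L, sv = 0L, mito = 0L)
  tc <- table(ppv_records$variant_class)
  cls[names(tc)] <- as.integer(tc)
  out <- list(
    n_patients = n_pat,
    n_ppv_records = nrow(ppv_records),
    n_patients_with_ppv = length(carriers),
    pct_with_ppv = pct(length(carriers), n_pat),
    by_idd = list(
      n_idd = sum(idd), n_idd_with_ppv = sum(idd & carrier),
      pct_idd = pct(sum(idd & carrier), sum(idd)),
      n_noidd = sum(!idd), n_noidd_with_ppv = sum(!idd & carrier),
      pct_noidd = pct(sum(!idd & carrier), sum(!idd))),
    class_breakdown = as.list(cls),
    comparison_p = comparison_p,
    noncoding = list(
      n_denovo_cre_hits = if (is.null(noncoding)) 0L else nrow(noncoding$hits),
      n_patients = if (is.null(noncoding)) 0L else noncoding$n_patients,
      n_without_coding_ppv = if (is.null(noncoding)) 0L else
        noncoding$n_without_coding_ppv))
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  cat(sprintf("  patients: %d\n", x$n_patients))
  cat(sprintf("  PPV records: %d (smallvar %d, sv %d, mito %d)\n",
              x$n_ppv_records, x$class_breakdown$smallvar,
              x$class_breakdown$sv, x$class_breakdown$mito))
  cat(sprintf("  patients with >=1 PPV: %d (%.1f%%)\n",
              x$n_patients_with_ppv, x$pct_with_ppv))
  cat(sprintf("  with IDD: %d/%d (%.1f%%); without IDD: %d/%d (%.1f%%); Fisher p = %.4g\n",
              x$by_idd$n_idd_with_ppv, x$by_idd$n_idd, x$by_idd$pct_idd,
              x$by_idd$n_noidd_with_ppv, x$by_idd$n_noidd,
              x$by_idd$pct_noidd, x$comparison_p))
  cat(sprintf("  de novo CRE hits: %d in %d patients (%d without coding PPV)\n",
              x$noncoding$n_denovo_cre_hits, x$noncoding$n_patients,
              x$noncoding$n_without_coding_ppv))
  invisible(x)
}
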