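# Orchestration of the small-variant engine over the long (site x trio) table.

#' Run QC, DQ scoring and inheritance classification over all trio calls
#'
#' Applies [site_qc()], per-member [genotype_qc()], DQ scoring
#' ([denovo_quality()] / [denovo_quality_hemi()] for candidate de novo
#' configurations), [classify_inheritance()], [classify_consequence()] and
#' [rarity_filter()] to the table produced by [read_small_variants()].
#' A label that relies on a member whose carrier genotype failed QC is
#' downgraded to `uninformative`.
#'
#' @param calls `smallvar_calls` data.frame from [read_small_variants()].
#' @param config [trioppv_config()].
#' @return the input with added columns `variant_id`, `site_pass`,
#'   `site_reason`, `qc_child`, `qc_mother`, `qc_father`, `dq`, `label`,
#'   `conseq_class`, `rarity_pass`.
#' @export
classify_smallvar_calls <- function(calls, config = trioppv_config()) {
  config <- as_trioppv_config(config)
  n <- nrow(calls)
  calls$variant_id <- paste(calls$chrom, calls$pos, calls$ref, calls$alt,
                            sep = ":")
  if (n == 0) {
    for (col in c("site_pass", "site_reason", "qc_child", "qc_mother",
                  "qc_father", "dq", "label", "conseq_class", "rarity_pass"))
      calls[[col]] <- logical(0)
    return(calls)
  }

  sq <- site_qc(calls$filter_pass, calls$dp_child, calls$dp_mother,
                calls$dp_father, calls$gt_child, calls$gt_mother,
                calls$gt_father, config)
  calls$site_pass <- sq$pass
  calls$site_reason <- sq$reason

  qc_member <- function(sfx) {
    genotype_qc(calls[[paste0("gt_", sfx)]], calls[[paste0("gq_", sfx)]],
                calls[[paste0("ad_ref_", sfx)]],
                calls[[paste0("ad_alt_", sfx)]],
                calls$variant_class, config)$pass
  }
  calls$qc_child <- qc_member("child")
  calls$qc_mother <- qc_member("mother")
  calls$qc_father <- qc_member("father")

  # DQ for candidate de novo configurations (child carrier, parents no-alt)
  maf <- pmax(ifelse(is.na(calls$maf_gnomad_eas), 0, calls$maf_gnomad_eas),
              ifelse(is.na(calls$maf_tommo), 0, calls$maf_tommo))
  p <- pmax(maf, config$p_floor)
  calls$dq <- NA_real_
  noalt <- function(gt) gt %in% c("hom_ref", "hemi_ref")
  cand <- calls$gt_child %in% c("het", "hemi_alt") &
    noalt(calls$gt_mother) & noalt(calls$gt_father)
  dip <- cand & calls$gt_child == "het" & !is.na(calls$pl3_child)
  if (any(dip)) {
    calls$dq[dip] <- denovo_quality(
      as.matrix(calls[dip, c("pl1_child", "pl2_child", "pl3_child")]),
      as.matrix(calls[dip, c("pl1_mother", "pl2_mother", "pl3_mother")]),
      as.matrix(calls[dip, c("pl1_father", "pl2_father", "pl3_father")]),
      mu = config$mu, p = p[dip])
  }
  hem <- cand & calls$gt_child == "hemi_alt"
  if (any(hem)) {
    calls$dq[hem] <- denovo_quality_hemi(
      as.matrix(calls[hem, c("pl1_child", "pl2_child")]),
      as.matrix(calls[hem, c("pl1_mother", "pl2_mother", "pl3_mother")]),
      as.matrix(calls[hem, c("pl1_father", "pl2_father")]),
      mu = config$mu, p = p[hem])
  }

  lab <- classify_inheritance(calls$gt_child, calls$gt_mother,
                              calls$gt_father, calls$chrom, calls$pos,
                              calls$proband_sex, calls$dq, config)

  # downgrade labels whose supporting genotypes failed QC
  need_m <- lab %in% c("homozygous_recessive", "hemizygous_maternal",
                       "inherited_maternal", "inherited_biparental")
  need_f <- lab %in% c("homozygous_recessive", "inherited_paternal",
                       "inherited_biparental")
  bad <- !calls$site_pass | !calls$qc_child |
    (need_m & !calls$qc_mother) | (need_f & !calls$qc_father)
  lab[bad] <- "uninformative"
  calls$label <- lab

  calls$conseq_class <- classify_consequence(calls$consequence,
                                             calls$spliceai_delta, config)
  calls$rarity_pass <- rarity_filter(calls$label, calls$maf_gnomad_eas,
                                     calls$maf_tommo, calls$cohort_ac, config)
  calls
}

#' Compound-heterozygote pairs across the cohort
#'
#' Groups classified calls by (family, gene) and applies
#' [find_compound_hets()] to the inherited variants that passed QC and the
#' inherited rarity filter.
#'
#' @param classified output of [classify_smallvar_calls()].
#' @param config [trioppv_config()].
#' @return data.frame of pairs with `family_id`, `gene`, `maternal_id`,
#'   `paternal_id`, `clause`.
#' @export
cohort_compound_hets <- function(classified, config = trioppv_config()) {
  config <- as_trioppv_config(config)
  inh <- classified[classified$label %in%
                      c("inherited_maternal", "inherited_paternal") &
                      classified$rarity_pass & !is.na(classified$gene), ,
                    drop = FALSE]
  empty <- data.frame(family_id = character(), gene = character(),
                      maternal_id = character(), paternal_id = character(),
                      clause = character(), stringsAsFactors = FALSE)
  if (nrow(inh) == 0) return(empty)
  pieces <- lapply(split(inh, paste(inh$family_id, inh$gene)), function(g) {
    pr <- find_compound_hets(g, config)
    if (nrow(pr) == 0) return(NULL)
    cbind(family_id = g$family_id[1], pr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$family_id, out$gene, out$maternal_id, out$paternal_id), ,
      drop = FALSE]
}
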