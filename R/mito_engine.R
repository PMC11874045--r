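# Mitochondrial engine: heteroplasmy fractions and the >5% pathogenic rule.

#' Heteroplasmy fraction from allele depths
#'
#' `100 * alt / (ref + alt)`, reported to 0.1% precision. Zero total depth is
#' undefined (NA); callers flag such records unusable.
#'
#' @param ad_ref,ad_alt reference / alternate read counts.
#' @return percent in [0, 100], rounded to one decimal; NA at zero depth.
#' @export
heteroplasmy_fraction <- function(ad_ref, ad_alt) {
  depth <- ad_ref + ad_alt
  out <- ifelse(!is.na(depth) & depth > 0, 100 * ad_alt / depth, NA_real_)
  round_half_up(out, 1)
}

#' Classify a mitochondrial variant
#'
#' A record is reportable only when it is a known pathogenic variant and the
#' proband's heteroplasmy strictly exceeds the threshold (default 5%). A
#' reportable variant is de novo when the maternal heteroplasmy is below the
#' same threshold (detection floors make a strict 0% requirement unrealistic),
#' otherwise maternally inherited. Paternal chrM genotypes are ignored. A
#' missing maternal depth yields `maternal_unknown` provenance with
#' uninformative inheritance.
#'
#' @param pathogenic logical known-pathogenic flag.
#' @param proband_pct,mother_pct heteroplasmy percentages
#'   ([heteroplasmy_fraction()]); NA maternal value = unknown.
#' @param threshold_pct reporting threshold in percent (default 5).
#' @return data.frame with `class` (`not_reportable`, `ppv_de_novo`,
#'   `ppv_maternal`, `ppv_maternal_unknown`) and `provenance`.
#' @export
classify_mito_variant <- function(pathogenic, proband_pct, mother_pct,
                                  threshold_pct = 5) {
  n <- length(pathogenic)
  proband_pct <- rep_len(proband_pct, n)
  mother_pct <- rep_len(mother_pct, n)
  cls <- rep("not_reportable", n)
  prov <- rep("", n)
  reportable <- pathogenic & !is.na(proband_pct) &
    proband_pct > threshold_pct
  known_m <- reportable & !is.na(mother_pct)
  cls[known_m & mother_pct < threshold_pct] <- "ppv_de_novo"
  cls[known_m & mother_pct >= threshold_pct] <- "ppv_maternal"
  low_m <- known_m & mother_pct > 0 & mother_pct < threshold_pct
  prov[low_m] <- "low_level_maternal_heteroplasmy"
  unk <- reportable & is.na(mother_pct)
  cls[unk] <- "ppv_maternal_unknown"
  prov[unk] <- "maternal_unknown"
  data.frame(class = cls, provenance = prov, stringsAsFactors = FALSE)
}

#' Classify all cohort mitochondrial records
#'
#' @param mito `mito_calls` object from [read_mito_calls()].
#' @param pedigree pedigree data.frame.
#' @param threshold_pct reporting threshold in percent.
#' @return data.frame with one row per (record, trio): position, alleles,
#'   pathogenicity, proband and maternal heteroplasmy, classification.
#' @export
classify_mito_cohort <- function(mito, pedigree, threshold_pct = 5) {
  trios <- trio_members(pedigree)
  rec <- mito$records
  pieces <- list()
  for (t in seq_len(nrow(trios))) {
    pr <- trios$proband[t]; mo <- trios$mother[t]
    if (!(pr %in% colnames(mito$ad_ref))) next
    ppct <- heteroplasmy_fraction(mito$ad_ref[, pr], mito$ad_alt[, pr])
    mpct <- if (mo %in% colnames(mito$ad_ref))
      heteroplasmy_fraction(mito$ad_ref[, mo], mito$ad_alt[, mo])
    else rep(NA_real_, nrow(rec))
    cl <- classify_mito_variant(rec$pathogenic, ppct, mpct, threshold_pct)
    keep <- which(cl$class != "not_reportable")
    if (!length(keep)) next
    pieces[[length(pieces) + 1]] <- data.frame(
      family_id = trios$family_id[t], pos = rec$pos[keep],
      ref = rec$ref[keep], alt = rec$alt[keep],
      disease_label = rec$disease_label[keep],
      proband_pct = ppct[keep], mother_pct = mpct[keep],
      class = cl$class[keep], provenance = cl$provenance[keep],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(family_id = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      disease_label = character(), proband_pct = numeric(),
                      mother_pct = numeric(), class = character(),
                      provenance = character(), stringsAsFactors = FALSE)
  out
}
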