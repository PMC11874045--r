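# SNV/INDEL engine: site/genotype QC, Bayes-factor de novo quality,
# inheritance classification, rarity filtering, consequence classing and
# compound-heterozygote pairing. All operations are vectorized over records.

#' Site-level QC for a trio call
#'
#' A site passes when it survived VQSR (FILTER PASS), all three members have a
#' genotype, and sequencing depth is at least `min_depth` (default 10) in all
#' three members. Bi-allelic representation is guaranteed upstream by
#' [read_small_variants()], which drops multi-allelic sites.
#'
#' @param filter_pass logical; FALSE for VQSR-failed records.
#' @param dp_child,dp_mother,dp_father per-member read depths.
#' @param gt_child,gt_mother,gt_father genotype codes (`"missing"` fails).
#' @param config [trioppv_config()].
#' @return data.frame with logical `pass` and character `reason`
#'   (`"pass"`, `"missing_genotype"`, `"vqsr"`, `"depth"`).
#' @export
site_qc <- function(filter_pass, dp_child, dp_mother, dp_father,
                    gt_child, gt_mother, gt_father,
                    config = trioppv_config()) {
  config <- as_trioppv_config(config)
  n <- length(filter_pass)
  reason <- rep("pass", n)
  dp_ok <- !is.na(dp_child) & !is.na(dp_mother) & !is.na(dp_father) &
    dp_child >= config$min_depth & dp_mother >= config$min_depth &
    dp_father >= config$min_depth
  reason[!dp_ok] <- "depth"
  reason[!filter_pass] <- "vqsr"
  miss <- gt_child == "missing" | gt_mother == "missing" |
    gt_father == "missing" | is.na(gt_child) | is.na(gt_mother) |
    is.na(gt_father)
  reason[miss] <- "missing_genotype"
  data.frame(pass = reason == "pass", reason = reason,
             stringsAsFactors = FALSE)
}

#' Genotype-level QC
#'
#' Applies the zygosity- and class-specific thresholds: heterozygous SNVs need
#' GQ >= 99 and 0.3 <= AF < 0.8; heterozygous INDELs GQ >= 90 with the same AF
#' window; homozygous (and hemizygous) alternate calls need GQ >= 25 and
#' AF >= 0.8. AF is the allele-depth fraction `ad_alt / (ad_ref + ad_alt)`.
#' Reference genotypes carry no rule and pass.
#'
#' @param gt genotype code (`hom_ref`, `het`, `hom_alt`, `hemi_ref`,
#'   `hemi_alt`, `missing`).
#' @param gq genotype quality (phred).
#' @param ad_ref,ad_alt allele depths.
#' @param variant_class `"snv"` or `"indel"`.
#' @param config [trioppv_config()].
#' @return data.frame with logical `pass` and `reason` (`pass`, `ref`,
#'   `missing`, `no_reads`, `gq`, `af`).
#' @export
genotype_qc <- function(gt, gq, ad_ref, ad_alt, variant_class,
                        config = trioppv_config()) {
  config <- as_trioppv_config(config)
  n <- length(gt)
  variant_class <- rep_len(variant_class, n)
  reason <- rep("pass", n)
  is_ref <- gt %in% c("hom_ref", "hemi_ref")
  reason[is_ref] <- "ref"
  is_miss <- gt == "missing" | is.na(gt)
  depth <- ifelse(is.na(ad_ref), 0, ad_ref) + ifelse(is.na(ad_alt), 0, ad_alt)
  af <- ifelse(depth > 0, ifelse(is.na(ad_alt), 0, ad_alt) / depth, NA_real_)

  het <- gt == "het"
  hom <- gt %in% c("hom_alt", "hemi_alt")
  gq_min <- ifelse(het, ifelse(variant_class == "indel",
                               config$gq_het_indel, config$gq_het_snv),
                   config$gq_hom)
  af_bad <- (het & (is.na(af) | af < config$af_het_low |
                      af >= config$af_het_high)) |
            (hom & (is.na(af) | af < config$af_hom_min))
  gq_bad <- (het | hom) & (is.na(gq) | gq < gq_min)
  reason[(het | hom) & af_bad] <- "af"
  reason[(het | hom) & gq_bad] <- "gq"
  reason[(het | hom) & depth == 0] <- "no_reads"
  reason[is_miss] <- "missing"
  data.frame(pass = reason %in% c("pass", "ref"), reason = reason,
             stringsAsFactors = FALSE)
}

# Mendelian transmission table T[gc | gm, gf] for diploid autosomes.
.transmission_array <- function() {
  al <- list(c(1, 0), c(0.5, 0.5), c(0, 1))  # P(transmit alt allele) per gt
  Tt <- array(0, c(3, 3, 3))                 # [gm, gf, gc]
  for (gm in 1:3) for (gf in 1:3) for (am in 0:1) for (af in 0:1) {
    gc <- am + af + 1
    Tt[gm, gf, gc] <- Tt[gm, gf, gc] + al[[gm]][am + 1] * al[[gf]][af + 1]
  }
  Tt
}

.norm_lik <- function(pl) {
  pl <- as.matrix(pl)
  pl <- pl - apply(pl, 1, min)
  10^(-pl / 10)
}

#' De novo quality (DQ) score
#'
#' Log10 Bayes factor of the canonical de novo trio configuration (both
#' parents homozygous reference, child heterozygous, weighted by the
#' per-generation mutation prior `mu`) against the full Mendelian model:
#' `DQ = log10[ mu * Lm(RR) Lf(RR) Lc(RA) ] - log10[ sum over parental pairs
#' pi(gm) pi(gf) sum over child T(gc|gm,gf) Lm Lf Lc ]`, where `L = 10^(-PL/10)`
#' with PLs normalized to minimum 0, `pi` are Hardy-Weinberg genotype priors
#' at population frequency `p`, and `T` is the Mendelian transmission table.
#' The result is capped to [-20, 20].
#'
#' @param child_pl,mother_pl,father_pl numeric length-3 vectors (RR, RA, AA)
#'   or n x 3 matrices of phred-scaled genotype likelihoods.
#' @param mu mutation prior (default 1e-8).
#' @param p population allele frequency; recycled; floored at `p_floor` by
#'   callers that derive it from annotation.
#' @return numeric DQ vector.
#' @export
denovo_quality <- function(child_pl, mother_pl, father_pl,
                           mu = 1e-8, p = 1e-4) {
  if (is.null(dim(child_pl))) child_pl <- matrix(child_pl, nrow = 1)
  if (is.null(dim(mother_pl))) mother_pl <- matrix(mother_pl, nrow = 1)
  if (is.null(dim(father_pl))) father_pl <- matrix(father_pl, nrow = 1)
  lc <- .norm_lik(child_pl)
  lm <- .norm_lik(mother_pl)
  lf <- .norm_lik(father_pl)
  n <- nrow(lc)
  p <- rep_len(p, n)
  pri <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)
  Tt <- .transmission_array()
  num <- mu * lm[, 1] * lf[, 1] * lc[, 2]
  den <- numeric(n)
  for (gm in 1:3) for (gf in 1:3) for (gc in 1:3) {
    w <- Tt[gm, gf, gc]
    if (w > 0)
      den <- den + pri[, gm] * pri[, gf] * w * lm[, gm] * lf[, gf] * lc[, gc]
  }
  pmax(pmin(log10(num) - log10(den), 20), -20)
}

#' De novo quality for hemizygous (chrX male) calls
#'
#' Same Bayes factor as [denovo_quality()] with a haploid child and father:
#' the child's allele is transmitted from the mother only, the father's
#' haploid genotype enters through his likelihood and a haploid
#' Hardy-Weinberg prior.
#'
#' @param child_pl,father_pl length-2 vectors (R, A) or n x 2 matrices.
#' @param mother_pl length-3 vector (RR, RA, AA) or n x 3 matrix.
#' @inheritParams denovo_quality
#' @return numeric DQ vector, capped to [-20, 20].
#' @export
denovo_quality_hemi <- function(child_pl, mother_pl, father_pl,
                                mu = 1e-8, p = 1e-4) {
  if (is.null(dim(child_pl))) child_pl <- matrix(child_pl, nrow = 1)
  if (is.null(dim(mother_pl))) mother_pl <- matrix(mother_pl, nrow = 1)
  if (is.null(dim(father_pl))) father_pl <- matrix(father_pl, nrow = 1)
  lc <- .norm_lik(child_pl)
  lm <- .norm_lik(mother_pl)
  lf <- .norm_lik(father_pl)
  n <- nrow(lc)
  p <- rep_len(p, n)
  pri_m <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)
  pri_f <- cbind(1 - p, p)
  Th <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1))  # T[gc | gm] maternal transmission
  num <- mu * lm[, 1] * lf[, 1] * lc[, 2]
  den <- numeric(n)
  for (gm in 1:3) for (gf in 1:2) for (gc in 1:2) {
    w <- Th[gm, gc]
    if (w > 0)
      den <- den + pri_m[, gm] * pri_f[, gf] * w *
        lm[, gm] * lf[, gf] * lc[, gc]
  }
  pmax(pmin(log10(num) - log10(den), 20), -20)
}

#' Classify trio inheritance of a small variant
#'
#' Assigns exactly one label per (variant, trio). On autosomes (and the chrX
#' pseudoautosomal regions, and chrX in female probands): a heterozygous child
#' with both parents homozygous reference is `de_novo` when DQ passes the
#' threshold; a homozygous-alternate child with both parents heterozygous is
#' `homozygous_recessive`; a carrier child whose allele is present in exactly
#' one parent is `inherited_maternal` / `inherited_paternal`, in both parents
#' `inherited_biparental`; anything else `uninformative`. On non-PAR chrX in a
#' male proband, a hemizygous-alternate child with a carrier mother is
#' `hemizygous_maternal`, and with both parents reference is `de_novo` when
#' the hemizygous DQ passes.
#'
#' @param gt_child,gt_mother,gt_father genotype codes.
#' @param chrom,pos variant coordinates (PAR handling).
#' @param proband_sex `"male"` or `"female"`; an NA sex with a chrX call is an
#'   error, since hemizygous logic depends on it.
#' @param dq precomputed DQ score (NA treated as below threshold).
#' @param config [trioppv_config()].
#' @return character vector of inheritance labels.
#' @export
classify_inheritance <- function(gt_child, gt_mother, gt_father, chrom, pos,
                                 proband_sex, dq,
                                 config = trioppv_config()) {
  config <- as_trioppv_config(config)
  n <- length(gt_child)
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  proband_sex <- rep_len(proband_sex, n)
  dq <- rep_len(dq, n)

  is_x <- chrom %in% c("chrX", "X")
  par <- config$par_intervals
  in_par <- rep(FALSE, n)
  for (k in seq_len(nrow(par)))
    in_par <- in_par | (is_x & pos >= par$start[k] & pos <= par$end[k])
  if (any(is_x & is.na(proband_sex)))
    trioppv_stop("proband sex missing for a chrX call")
  hemi_ctx <- is_x & !in_par & proband_sex == "male"

  carrier <- function(gt) gt %in% c("het", "hom_alt", "hemi_alt")
  noalt <- function(gt) gt %in% c("hom_ref", "hemi_ref")
  cc <- carrier(gt_child); cm <- carrier(gt_mother); cf <- carrier(gt_father)
  rc <- noalt(gt_child); rm_ <- noalt(gt_mother); rf <- noalt(gt_father)
  dq_ok <- !is.na(dq) & dq >= config$dq_threshold

  lab <- rep("uninformative", n)
  aut <- !hemi_ctx
  lab[aut & gt_child == "het" & rm_ & rf & dq_ok] <- "de_novo"
  lab[aut & gt_child == "hom_alt" & gt_mother == "het" &
        gt_father == "het"] <- "homozygous_recessive"
  plain_inh <- aut & cc & lab == "uninformative"
  lab[plain_inh & cm & !cf & rf] <- "inherited_maternal"
  lab[plain_inh & cf & !cm & rm_] <- "inherited_paternal"
  lab[aut & cc & lab == "uninformative" & cm & cf] <- "inherited_biparental"

  hx <- hemi_ctx & gt_child %in% c("hemi_alt", "hom_alt")
  lab[hx & cm] <- "hemizygous_maternal"
  lab[hx & rm_ & rf & dq_ok] <- "de_novo"
  lab
}

#' Rarity filter
#'
#' The population MAF is the maximum over available sources (gnomAD East
#' Asian, ToMMo), a missing source contributing 0. De novo variants must be
#' below `maf_denovo` (default 0.001) AND be cohort singletons (allele count 1
#' across all cohort members); all other labels must be below `maf_inherited`
#' (default 0.01).
#'
#' @param label inheritance label vector.
#' @param maf_gnomad_eas,maf_tommo per-source population frequencies (NA = 0).
#' @param cohort_ac cohort-wide allele count.
#' @param config [trioppv_config()].
#' @return logical pass vector.
#' @export
rarity_filter <- function(label, maf_gnomad_eas, maf_tommo, cohort_ac,
                          config = trioppv_config()) {
  config <- as_trioppv_config(config)
  maf <- pmax(ifelse(is.na(maf_gnomad_eas), 0, maf_gnomad_eas),
              ifelse(is.na(maf_tommo), 0, maf_tommo))
  ifelse(label == "de_novo",
         maf < config$maf_denovo & !is.na(cohort_ac) & cohort_ac == 1,
         maf < config$maf_inherited)
}

#' Consequence class of an annotation bundle
#'
#' Protein-truncating variants (PTV) are stopgain, frameshift, canonical
#' splice-site and startloss annotations. A non-coding annotation whose
#' SpliceAI delta score strictly exceeds 0.5 is a `qualifying_splice` variant.
#' Missense and synonymous pass through; everything else (including
#' unannotated records) is `other`.
#'
#' @param consequence annotation consequence vocabulary (`stopgain`,
#'   `frameshift`, `splice_canonical`, `startloss`, `missense`, `synonymous`,
#'   `intronic`, `intergenic`, `other`, or NA).
#' @param spliceai_delta SpliceAI delta score in [0, 1] or NA.
#' @param config [trioppv_config()].
#' @return character vector over `{ptv, qualifying_splice, missense,
#'   synonymous, other}`.
#' @export
classify_consequence <- function(consequence, spliceai_delta = NA_real_,
                                 config = trioppv_config()) {
  config <- as_trioppv_config(config)
  n <- length(consequence)
  spliceai_delta <- rep_len(spliceai_delta, n)
  out <- rep("other", n)
  ptv <- c("stopgain", "frameshift", "splice_canonical", "startloss")
  out[consequence %in% ptv] <- "ptv"
  out[consequence %in% "missense"] <- "missense"
  out[consequence %in% "synonymous"] <- "synonymous"
  noncoding <- !(consequence %in% c(ptv, "missense", "synonymous"))
  splice <- noncoding & !is.na(spliceai_delta) &
    spliceai_delta > config$spliceai_min
  out[splice] <- "qualifying_splice"
  out
}

#' Compound-heterozygote pairing within one gene
#'
#' Pairs one maternally with one paternally inherited variant of the same gene
#' (trans configuration). Only protein-altering members are eligible (PTV,
#' qualifying splice, missense). A pair qualifies when (a) at least one member
#' is a PTV-equivalent (PTV or qualifying splice) or a missense variant with
#' MPC > 2, or (b) both members are PTV-equivalents or missense variants with
#' MPC > 1. Each returned pair records which clause fired (clause (a) takes
#' precedence); pairs are deduplicated and returned in deterministic order.
#'
#' @param variants data.frame with columns `variant_id`, `gene`, `label`
#'   (`inherited_maternal` / `inherited_paternal`), `conseq_class` (from
#'   [classify_consequence()]) and `mpc`. Callers are expected to pass only
#'   variants that survived QC and the inherited rarity filter.
#' @param config [trioppv_config()].
#' @return data.frame with one row per qualifying pair: `gene`, `maternal_id`,
#'   `paternal_id`, `clause`.
#' @export
find_compound_hets <- function(variants, config = trioppv_config()) {
  config <- as_trioppv_config(config)
  empty <- data.frame(gene = character(), maternal_id = character(),
                      paternal_id = character(), clause = character(),
                      stringsAsFactors = FALSE)
  if (is.null(variants) || nrow(variants) == 0) return(empty)
  v <- variants[variants$conseq_class %in%
                  c("ptv", "qualifying_splice", "missense"), , drop = FALSE]
  v <- v[!duplicated(v$variant_id), , drop = FALSE]
  mat <- v[v$label == "inherited_maternal", , drop = FALSE]
  pat <- v[v$label == "inherited_paternal", , drop = FALSE]
  if (nrow(mat) == 0 || nrow(pat) == 0) return(empty)

  ptv_like <- function(x) x$conseq_class %in% c("ptv", "qualifying_splice")
  strong <- function(x) ptv_like(x) |
    (x$conseq_class == "missense" & !is.na(x$mpc) & x$mpc > config$mpc_single)
  weak <- function(x) ptv_like(x) |
    (x$conseq_class == "missense" & !is.na(x$mpc) & x$mpc > config$mpc_pair)

  out <- list()
  for (i in seq_len(nrow(mat))) for (j in seq_len(nrow(pat))) {
    if (mat$gene[i] != pat$gene[j]) next
    a <- strong(mat[i, ]) || strong(pat[j, ])
    b <- weak(mat[i, ]) && weak(pat[j, ])
    if (!a && !b) next
    out[[length(out) + 1]] <- data.frame(
      gene = mat$gene[i], maternal_id = mat$variant_id[i],
      paternal_id = pat$variant_id[j],
      clause = if (a) "one_ptv_or_mpc_gt2" else "both_ptv_or_mpc_gt1",
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  pairs <- unique(do.call(rbind, out))
  pairs <- pairs[order(pairs$gene, pairs$maternal_id, pairs$paternal_id), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}
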