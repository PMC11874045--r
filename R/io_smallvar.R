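# Reading the multi-sample SNV/INDEL VCF plus its annotation sidecar into the
# long per-(site, trio) table every downstream small-variant operation consumes.

# Fast field extraction from a possibly-ragged geno list-matrix: returns the
# k-th element of every cell (NA when absent).
.geno_elt <- function(m, k) {
  if (is.array(m) && length(dim(m)) == 3) {
    out <- if (k <= dim(m)[3]) m[, , k] else
      matrix(NA_integer_, nrow(m), ncol(m))
    return(out)
  }
  lens <- lengths(m)
  flat <- unlist(m, use.names = FALSE)
  first <- cumsum(c(1L, lens[-length(lens)]))
  val <- rep(NA_integer_, length(m))
  ok <- lens >= k
  val[ok] <- flat[first[ok] + (k - 1L)]
  matrix(val, nrow = nrow(m), ncol = ncol(m), dimnames = dimnames(m))
}

# genotype string -> canonical code
.gt_code <- function(gt) {
  out <- rep("missing", length(gt))
  out[gt %in% c("0/0", "0|0")] <- "hom_ref"
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- "het"
  out[gt %in% c("1/1", "1|1")] <- "hom_alt"
  out[gt == "0"] <- "hemi_ref"
  out[gt == "1"] <- "hemi_alt"
  out
}

.alt_dose <- function(code) {
  c(hom_ref = 0, het = 1, hom_alt = 2, hemi_ref = 0, hemi_alt = 1,
    missing = NA_real_)[code]
}

#' Read small variants (SNVs/INDELs) for all trios
#'
#' Reads a multi-sample VCF (FORMAT GT/GQ/DP/AD/PL) together with an annotation
#' sidecar table, and returns one row per (variant, trio) for every trio whose
#' proband carries the alternate allele. Multi-allelic sites are excluded, not
#' decomposed, and counted; the cohort allele count (`cohort_ac`) is computed
#' across all samples in the VCF before any per-trio filtering.
#'
#' @param vcf_path path to the VCF (plain or bgzipped).
#' @param annotation_path path to a TSV with header columns `chrom, pos, ref,
#'   alt, gene, consequence, mpc, spliceai_delta, maf_gnomad_eas, maf_tommo,
#'   clinvar`; variants without an annotation row are kept with NA annotation.
#' @param pedigree pedigree data.frame from [read_pedigree()]; every trio
#'   member must be a VCF sample.
#' @return a data.frame of class `smallvar_calls`, one row per (site, trio)
#'   with site fields (`chrom, pos, ref, alt, variant_class, filter_pass,
#'   cohort_ac`), the annotation bundle, `family_id`, `proband_sex`, and for
#'   each member (`child`, `mother`, `father`) the genotype call columns
#'   `gt_*, gq_*, dp_*, ad_ref_*, ad_alt_*, pl1_*, pl2_*, pl3_*` (`pl3` is NA
#'   for haploid chrX male calls). Attributes `n_records_total`,
#'   `n_multiallelic` and `n_sites_kept` carry the QC tally.
#' @export
read_small_variants <- function(vcf_path, annotation_path, pedigree) {
  if (!file.exists(vcf_path)) trioppv_stop("VCF not found: ", vcf_path)
  trios <- trio_members(pedigree)
  vcf <- VariantAnnotation::readVcf(
    vcf_path, genome = "hg38",
    param = VariantAnnotation::ScanVcfParam(
      info = NA, geno = c("GT", "GQ", "DP", "AD", "PL")))
  samples <- colnames(vcf)
  need <- unique(c(trios$proband, trios$mother, trios$father))
  absent <- setdiff(need, samples)
  if (length(absent))
    trioppv_stop("pedigree sample(s) absent from VCF header: ",
                 paste(absent, collapse = ", "))

  n_total <- nrow(vcf)
  multi <- lengths(VariantAnnotation::alt(vcf)) != 1L
  n_multi <- sum(multi)
  vcf <- vcf[!multi, ]

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  filter_pass <- rr$FILTER %in% c("PASS", ".")
  variant_class <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "snv", "indel")

  g <- VariantAnnotation::geno(vcf)
  gt <- g$GT
  gq <- g$GQ
  dp <- g$DP
  ad_ref <- .geno_elt(g$AD, 1L)
  ad_alt <- .geno_elt(g$AD, 2L)
  pl1 <- .geno_elt(g$PL, 1L)
  pl2 <- .geno_elt(g$PL, 2L)
  pl3 <- .geno_elt(g$PL, 3L)

  code <- matrix(.gt_code(gt), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose <- matrix(.alt_dose(code), nrow(gt), ncol(gt))
  cohort_ac <- as.integer(rowSums(dose, na.rm = TRUE))

  ann <- .read_annotation(annotation_path)
  key <- paste(chrom, pos, ref, alt, sep = ":")
  ann_idx <- match(key, ann$key)

  member_cols <- function(sample_ids, idx, suffix) {
    j <- match(sample_ids, samples)
    out <- data.frame(
      gt = code[cbind(idx, j)], gq = as.numeric(gq[cbind(idx, j)]),
      dp = as.numeric(dp[cbind(idx, j)]),
      ad_ref = as.numeric(ad_ref[cbind(idx, j)]),
      ad_alt = as.numeric(ad_alt[cbind(idx, j)]),
      pl1 = as.numeric(pl1[cbind(idx, j)]),
      pl2 = as.numeric(pl2[cbind(idx, j)]),
      pl3 = as.numeric(pl3[cbind(idx, j)]),
      stringsAsFactors = FALSE)
    names(out) <- paste0(names(out), "_", suffix)
    out
  }

  pieces <- vector("list", nrow(trios))
  for (i in seq_len(nrow(trios))) {
    jc <- match(trios$proband[i], samples)
    carrier <- which(!is.na(dose[, jc]) & dose[, jc] > 0)
    if (!length(carrier)) next
    site <- data.frame(
      chrom = chrom[carrier], pos = pos[carrier], ref = ref[carrier],
      alt = alt[carrier], variant_class = variant_class[carrier],
      filter_pass = filter_pass[carrier], cohort_ac = cohort_ac[carrier],
      stringsAsFactors = FALSE)
    ai <- ann_idx[carrier]
    site$gene <- ann$gene[ai]
    site$consequence <- ann$consequence[ai]
    site$mpc <- ann$mpc[ai]
    site$spliceai_delta <- ann$spliceai_delta[ai]
    site$maf_gnomad_eas <- ann$maf_gnomad_eas[ai]
    site$maf_tommo <- ann$maf_tommo[ai]
    site$clinvar <- ann$clinvar[ai]
    site$family_id <- trios$family_id[i]
    site$proband_sex <- trios$proband_sex[i]
    rep_i <- rep(trios$family_id[i], length(carrier))
    pieces[[i]] <- cbind(site,
      member_cols(rep(trios$proband[i], length(carrier)), carrier, "child"),
      member_cols(rep(trios$mother[i], length(carrier)), carrier, "mother"),
      member_cols(rep(trios$father[i], length(carrier)), carrier, "father"))
  }
  calls <- do.call(rbind, pieces)
  if (is.null(calls)) calls <- .empty_smallvar_calls()
  rownames(calls) <- NULL
  class(calls) <- c("smallvar_calls", "data.frame")
  attr(calls, "n_records_total") <- n_total
  attr(calls, "n_multiallelic") <- n_multi
  attr(calls, "n_sites_kept") <- n_total - n_multi
  calls
}

.read_annotation <- function(path) {
  if (is.null(path) || !file.exists(path))
    trioppv_stop("annotation table not found: ", path)
  # ref/alt columns must never be type-inferred ("T" is not a logical)
  ann <- read_tsv(path, colClasses = c(chrom = "character",
                                       ref = "character",
                                       alt = "character"))
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "mpc",
            "spliceai_delta", "maf_gnomad_eas", "maf_tommo", "clinvar")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols))
    trioppv_stop("annotation table lacks column(s): ",
                 paste(missing_cols, collapse = ", "))
  ann$key <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = ":")
  if (anyDuplicated(ann$key))
    trioppv_stop("annotation key collision at ",
                 ann$key[duplicated(ann$key)][1])
  ann
}

.empty_smallvar_calls <- function() {
  cols <- c("chrom", "pos", "ref", "alt", "variant_class", "filter_pass",
            "cohort_ac", "gene", "consequence", "mpc", "spliceai_delta",
            "maf_gnomad_eas", "maf_tommo", "clinvar", "family_id",
            "proband_sex",
            paste0(rep(c("gt_", "gq_", "dp_", "ad_ref_", "ad_alt_",
                         "pl1_", "pl2_", "pl3_"), 3),
                   rep(c("child", "mother", "father"), each = 8)))
  df <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  df
}
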