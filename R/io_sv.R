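# Structural-variant call-set input: one VCF per caller, symbolic ALT alleles
# (<DEL>/<DUP>/<INV>/<INS>) or breakend (BND) notation, multi-sample genotypes.

#' Read a structural-variant call set
#'
#' @param vcf_path path to an SV VCF with symbolic ALT alleles or BND records;
#'   INFO fields `SVTYPE` and `END` are used when present, and the `IMPRECISE`
#'   flag marks imprecise calls (absence means precise). A numeric INFO `MAF`
#'   is consumed as the population frequency annotation when present.
#' @param caller_label label recorded on every call (e.g. `"manta"`).
#' @return an object of class `sv_calls`: a list with `calls` (data.frame with
#'   `caller, sv_type, chrom, start, end, chrom2, pos2, filter_pass, precise,
#'   maf, bnd_unresolved`) and `geno`, a calls x samples character matrix of
#'   genotype codes (`hom_ref`, `het`, `hom_alt`, `hemi_ref`, `hemi_alt`,
#'   `missing`). Unresolvable breakend mates are kept as single-breakend
#'   translocation (`TRA`) calls and flagged.
#' @export
read_sv_calls <- function(vcf_path, caller_label) {
  if (!file.exists(vcf_path)) trioppv_stop("SV VCF not found: ", vcf_path)
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "hg38")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  start <- GenomicRanges::start(rr)
  info <- VariantAnnotation::info(vcf)

  alt_list <- VariantAnnotation::alt(vcf)
  alt1 <- vapply(alt_list, function(a) as.character(a)[1], character(1))

  sv_type <- rep(NA_character_, length(alt1))
  symb <- regmatches(alt1, regexec("^<([A-Z]+)(:[^>]+)?>$", alt1))
  for (i in seq_along(symb)) {
    if (length(symb[[i]]) >= 2) sv_type[i] <- symb[[i]][2]
  }
  if ("SVTYPE" %in% names(info)) {
    st <- as.character(info$SVTYPE)
    sv_type[is.na(sv_type) & !is.na(st)] <- st[is.na(sv_type) & !is.na(st)]
  }

  # breakend records: keep as single-breakend translocations, flagged
  is_bnd <- grepl("[\\[\\]]", alt1, perl = TRUE)
  chrom2 <- rep(NA_character_, length(alt1))
  pos2 <- rep(NA_real_, length(alt1))
  bnd_unresolved <- rep(FALSE, length(alt1))
  if (any(is_bnd)) {
    mate <- regmatches(alt1,
                       regexec("[\\[\\]]([^:\\[\\]]+):([0-9]+)[\\[\\]]",
                               alt1, perl = TRUE))
    for (i in which(is_bnd)) {
      sv_type[i] <- "TRA"
      if (length(mate[[i]]) == 3) {
        chrom2[i] <- mate[[i]][2]
        pos2[i] <- as.numeric(mate[[i]][3])
      } else {
        bnd_unresolved[i] <- TRUE
      }
    }
  }
  sv_type[sv_type == "BND"] <- "TRA"

  end <- start
  if ("END" %in% names(info)) {
    e <- suppressWarnings(as.numeric(unlist(info$END)))
    if (length(e) == length(end)) end[!is.na(e)] <- e[!is.na(e)]
  }
  end[sv_type %in% c("INS", "TRA")] <- start[sv_type %in% c("INS", "TRA")]

  precise <- rep(TRUE, length(alt1))
  if ("IMPRECISE" %in% names(info)) precise <- !info$IMPRECISE

  maf <- rep(NA_real_, length(alt1))
  if ("MAF" %in% names(info)) maf <- suppressWarnings(as.numeric(info$MAF))

  calls <- data.frame(
    caller = caller_label, sv_type = sv_type, chrom = chrom, start = start,
    end = end, chrom2 = chrom2, pos2 = pos2,
    filter_pass = rr$FILTER %in% c("PASS", "."),
    precise = precise, maf = maf, bnd_unresolved = bnd_unresolved,
    stringsAsFactors = FALSE)

  gt <- VariantAnnotation::geno(vcf)$GT
  geno <- matrix(.gt_code(gt), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  structure(list(calls = calls, geno = geno), class = "sv_calls")
}

#' Read CNV log2-ratio segments
#'
#' @param path TSV with header columns `sample_id, chrom, start, end, log2`.
#' @return data.frame of segments (1-based inclusive coordinates).
#' @export
read_cnv_segments <- function(path) {
  if (!file.exists(path)) trioppv_stop("CNV segment file not found: ", path)
  seg <- read_tsv(path)
  need <- c("sample_id", "chrom", "start", "end", "log2")
  if (length(setdiff(need, names(seg))))
    trioppv_stop("CNV segment table needs columns: ", paste(need, collapse = ", "))
  if (any(seg$start > seg$end))
    trioppv_stop("CNV segment with start > end")
  seg
}
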