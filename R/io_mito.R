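# Mitochondrial (chrM) VCF input plus the ClinVar-style pathogenicity table.

#' Read mitochondrial variant calls
#'
#' Reads a chrM VCF carrying per-sample allele depths (FORMAT AD) and attaches
#' the known-pathogenic flag from a ClinVar-style table keyed by
#' (pos, ref, alt). Heteroplasmy fractions are computed downstream by
#' [heteroplasmy_fraction()], not here.
#'
#' @param vcf_path chrM VCF path.
#' @param clinvar_table TSV with columns `pos, ref, alt, clinvar_significance,
#'   disease_label`.
#' @return object of class `mito_calls`: list with `records` (data.frame
#'   `pos, ref, alt, pathogenic, disease_label`) and allele-depth matrices
#'   `ad_ref`, `ad_alt` (records x samples; NA where AD is missing, which
#'   flags the record unusable for that sample).
#' @export
read_mito_calls <- function(vcf_path, clinvar_table) {
  if (!file.exists(vcf_path)) trioppv_stop("mito VCF not found: ", vcf_path)
  tab <- read_tsv(clinvar_table,
                  colClasses = c(ref = "character", alt = "character"))
  need <- c("pos", "ref", "alt", "clinvar_significance", "disease_label")
  if (length(setdiff(need, names(tab))))
    trioppv_stop("pathogenicity table needs columns: ",
                 paste(need, collapse = ", "))
  vcf <- VariantAnnotation::readVcf(
    vcf_path, genome = "hg38",
    param = VariantAnnotation::ScanVcfParam(info = NA,
                                            geno = c("GT", "AD", "DP")))
  rr <- SummarizedExperiment::rowRanges(vcf)
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(VariantAnnotation::alt(vcf),
                function(a) as.character(a)[1], character(1))
  key <- paste(pos, ref, alt)
  tkey <- paste(tab$pos, tab$ref, tab$alt)
  idx <- match(key, tkey)
  pathogenic <- !is.na(idx) &
    grepl("pathogenic", tolower(tab$clinvar_significance[idx]))
  records <- data.frame(
    pos = pos, ref = ref, alt = alt, pathogenic = pathogenic,
    disease_label = ifelse(pathogenic, tab$disease_label[idx], NA_character_),
    stringsAsFactors = FALSE)
  ad <- VariantAnnotation::geno(vcf)$AD
  structure(list(records = records,
                 ad_ref = .geno_elt(ad, 1L),
                 ad_alt = .geno_elt(ad, 2L)),
            class = "mito_calls")
}
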