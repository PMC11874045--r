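# Ground-truth fixture variants planted by the synthetic cohort generator.
# Coordinates, alleles, genes and inheritance modes follow the published
# case tables; per-variant attributes the tables do not print (MPC, SpliceAI
# delta, population MAFs, PLs, heteroplasmy read counts) are synthesized
# minimally beyond the decision thresholds and recorded in the provenance
# column of the truth table the generator writes.

#' Fixture variant tables
#'
#' The planted ground truth of the default synthetic cohort: 12 de novo
#' small variants, 6 compound-heterozygous pairs, 1 maternally inherited
#' hemizygous missense variant, 2 structural variants (a homozygous 212-kb
#' deletion covering ARHGAP11B, a hemizygous 12-kb deletion covering TMLHE
#' exon 2), 2 inherited panel-gene duplications (reported as inherited
#' findings, not PPVs), 2 pathogenic mitochondrial variants, and 8 de novo
#' SNVs inside fetal brain CRE intervals of panel genes (6 of them in
#' patients with no coding PPV).
#'
#' @param overrides optional data.frame with columns `id, field, value`
#'   patching individual fixture attributes (e.g. degrade `gq_child` of one
#'   variant); values are coerced to the field's type.
#' @return list of data.frames: `smallvar`, `sv`, `mito`, `cre`.
#' @export
fixture_variants <- function(overrides = NULL) {
  sv_row <- function(id, family, gene, chrom, pos, ref, alt, vclass, cons,
                     mpc, splice, maf, inh, hgvs, rule, idd) {
    data.frame(id = id, family = family, gene = gene, chrom = chrom,
               pos = pos, ref = ref, alt = alt, variant_class = vclass,
               consequence = cons, mpc = mpc, spliceai = splice, maf = maf,
               inheritance = inh, hgvs = hgvs, expected_rule = rule,
               idd = idd, gq_child = 99, stringsAsFactors = FALSE)
  }
  smallvar <- rbind(
    # de novo PPVs
    sv_row("dn_PTEN", 1, "PTEN", "chr10", 87961051, "T", "C", "snv",
           "missense", 2.8, NA, 0, "de_novo", "p.L320S", "denovo_panel",
           "profound"),
    sv_row("dn_CHD7", 2, "CHD7", "chr8", 60852995, "G", "A", "snv",
           "stopgain", NA, NA, 0, "de_novo", "p.W2090X", "denovo_panel",
           "mild"),
    sv_row("dn_HNRNPH2", 3, "HNRNPH2", "chrX", 101412410, "T", "A", "snv",
           "missense", 2.5, NA, 0, "de_novo", "p.M141K", "denovo_panel",
           "severe"),
    sv_row("dn_BSN", 4, "BSN", "chr3", 49654526, "A", "AC", "indel",
           "frameshift", NA, NA, 0, "de_novo", "p.R1659Qfs*23",
           "denovo_panel", "moderate"),
    sv_row("dn_HNRNPR", 6, "HNRNPR", "chr1", 23318521, "C", "T", "snv",
           "missense", 2.2, NA, 0, "de_novo", "p.D327N", "denovo_panel",
           "none"),
    sv_row("dn_MKX", 7, "MKX", "chr10", 27741428, "G", "A", "snv",
           "missense", 1.6, NA, 0, "de_novo", "p.L89F", "denovo_panel",
           "none"),
    sv_row("dn_SMARCA4", 8, "SMARCA4", "chr19", 11041349, "C", "T", "snv",
           "missense", 2.9, NA, 0, "de_novo", "p.R1405W", "denovo_panel",
           "none"),
    sv_row("dn_RPS6KA3", 9, "RPS6KA3", "chrX", 20165002, "G", "A", "snv",
           "missense", 2.1, NA, 0, "de_novo", "p.P554L", "denovo_panel",
           "borderline"),
    sv_row("dn_GLUL", 10, "GLUL", "chr1", 182386318, "G", "A", "snv",
           "missense", 1.9, NA, 0, "de_novo", "p.T138I", "denovo_panel",
           "none"),
    sv_row("dn_TRIP12", 11, "TRIP12", "chr2", 229802327, "G", "A", "snv",
           "missense", 2.4, NA, 0, "de_novo", "p.T1044I", "denovo_panel",
           "none"),
    sv_row("dn_TEK", 12, "TEK", "chr9", 27183504, "T", "C", "snv",
           "missense", 1.8, NA, 0, "de_novo", "p.I359T", "denovo_panel",
           "mild"),
    sv_row("dn_PCLO", 13, "PCLO", "chr7", 82914875, "T", "C", "snv",
           "missense", 1.7, NA, 0, "de_novo", "p.M4371V", "denovo_panel",
           "mild"),
    # compound-heterozygous pairs (maternal + paternal, trans)
    sv_row("ch_HLCS_m", 14, "HLCS", "chr21", 36759828, "C", "T", "snv",
           "missense", 2.3, NA, 0.005, "maternal", "p.R712Q", "comphet",
           "mild"),
    sv_row("ch_HLCS_p", 14, "HLCS", "chr21", 36966576, "GA", "G", "indel",
           "frameshift", NA, NA, 0.005, "paternal", "p.L21Pfs*32", "comphet",
           "mild"),
    sv_row("ch_EPPK1_m", 1, "EPPK1", "chr8", 143873145, "T", "TG", "indel",
           "frameshift", NA, NA, 0.004, "maternal", "p.R37Qfs*80", "comphet",
           "profound"),
    sv_row("ch_EPPK1_p", 1, "EPPK1", "chr8", 143872401, "C", "T", "snv",
           "missense", 1.4, NA, 0.004, "paternal", "p.G285S", "comphet",
           "profound"),
    sv_row("ch_MADD_m", 15, "MADD", "chr11", 47289788, "G", "A", "snv",
           "intronic", NA, 0.8, 0.006, "maternal", "c.2553-79G>A", "comphet",
           "moderate"),
    sv_row("ch_MADD_p", 15, "MADD", "chr11", 47289022, "G", "A", "snv",
           "missense", 1.5, NA, 0.006, "paternal", "p.G903D", "comphet",
           "moderate"),
    sv_row("ch_SLC25A10_m", 15, "SLC25A10", "chr17", 81720046, "G", "A",
           "snv", "missense", 1.5, NA, 0.007, "maternal", "p.R278H",
           "comphet", "moderate"),
    sv_row("ch_SLC25A10_p", 15, "SLC25A10", "chr17", 81715055, "G", "A",
           "snv", "missense", 1.2, NA, 0.007, "paternal", "p.A66T", "comphet",
           "moderate"),
    sv_row("ch_CHD5_m", 6, "CHD5", "chr1", 6142258, "T", "A", "snv",
           "missense", 1.5, NA, 0.005, "maternal", "p.E769V", "comphet",
           "none"),
    sv_row("ch_CHD5_p", 6, "CHD5", "chr1", 6154701, "T", "C", "snv",
           "missense", 1.2, NA, 0.005, "paternal", "p.Q235R", "comphet",
           "none"),
    sv_row("ch_JARID2_m", 16, "JARID2", "chr6", 15487405, "C", "T", "snv",
           "missense", 1.5, NA, 0.006, "maternal", "p.R257W", "comphet",
           "none"),
    sv_row("ch_JARID2_p", 16, "JARID2", "chr6", 15517216, "T", "C", "snv",
           "missense", 1.2, NA, 0.006, "paternal", "p.V1169A", "comphet",
           "none"),
    # maternally inherited hemizygous missense
    sv_row("hemi_GLRA2", 17, "GLRA2", "chrX", 14690789, "C", "T", "snv",
           "missense", 2.4, NA, 0.003, "hemi_maternal", "p.A337V",
           "hemi_mpc", "mild"))

  sv <- data.frame(
    id = c("sv_ARHGAP11B", "sv_TMLHE", "sv_RHEB", "sv_NF1"),
    family = c(18, 18, 25, 26),
    gene = c("ARHGAP11B", "TMLHE", "RHEB", "NF1"),
    chrom = c("chr15", "chrX", "chr7", "chr17"),
    start = c(30500000, 154743001, 151466000, 31090000),
    end = c(30711999, 154755000, 151520000, 31290000),
    sv_type = c("DEL", "DEL", "DUP", "DUP"),
    inheritance = c("hom_recessive", "hemi_maternal", "inherited_maternal",
                    "inherited_paternal"),
    maf = c(0.15, 0.005, 0.004, 0.005),
    expected_rule = c("sv_homozygous_recessive", "sv_hemizygous_maternal",
                      "inherited_finding", "inherited_finding"),
    idd = c("none", "none", "none", "none"),
    stringsAsFactors = FALSE)

  mito <- data.frame(
    id = c("mt_5540", "mt_14674"),
    family = c(5, 1),
    pos = c(5540, 14674),
    ref = c("G", "T"), alt = c("A", "C"),
    gene = c("MT-TW", "MT-TE"),
    proband_pct = c(6.7, 100),
    mother_pct = c(0, 100),
    disease = c("MELAS", "Primary mitochondrial disease"),
    expected_rule = c("mito_de_novo", "mito_maternal"),
    idd = c("mild", "none"),
    stringsAsFactors = FALSE)

  cre <- data.frame(
    id = paste0("cre_", c("FOXP2", "DMWD", "EXT2", "DPP10", "CNTN3",
                          "RAB2A", "NTRK2", "MOCS1")),
    family = c(2, 4, 19, 20, 21, 22, 23, 24),
    gene = c("FOXP2", "DMWD", "EXT2", "DPP10", "CNTN3", "RAB2A", "NTRK2",
             "MOCS1"),
    chrom = c("chr7", "chr19", "chr11", "chr2", "chr3", "chr8", "chr9",
              "chr6"),
    pos = c(114001000, 45770500, 44100700, 115200600, 74300800, 60500700,
            84600900, 39900400),
    ref = c("G", "C", "A", "T", "G", "C", "A", "G"),
    alt = c("A", "T", "G", "C", "A", "G", "T", "A"),
    gq_child = 99,
    stringsAsFactors = FALSE)

  fx <- list(smallvar = smallvar, sv = sv, mito = mito, cre = cre)
  if (!is.null(overrides)) {
    for (k in seq_len(nrow(overrides))) {
      id <- overrides$id[k]; field <- overrides$field[k]
      val <- overrides$value[k]
      found <- FALSE
      for (tab in names(fx)) {
        hit <- fx[[tab]]$id == id
        if (any(hit) && field %in% names(fx[[tab]])) {
          cls <- class(fx[[tab]][[field]])[1]
          fx[[tab]][[field]][hit] <- switch(cls,
            numeric = as.numeric(val), integer = as.integer(val),
            logical = as.logical(val), as.character(val))
          found <- TRUE
        }
      }
      if (!found)
        trioppv_stop("fixture override not applicable: ", id, "/", field)
    }
  }
  fx
}

# CRE interval geometry (BED half-open 0-based written by the generator).
.fixture_cre_intervals <- function() {
  data.frame(
    chrom = c("chr7", "chr19", "chr11", "chr2", "chr3", "chr8", "chr9",
              "chr6"),
    start0 = c(114000000, 45770000, 44100000, 115200000, 74300000, 60500000,
               84600000, 39900000),
    end0 = c(114002000, 45771500, 44101500, 115201500, 74301500, 60501500,
             84601500, 39901500),
    gene = c("FOXP2", "DMWD", "EXT2", "DPP10", "CNTN3", "RAB2A", "NTRK2",
             "MOCS1"),
    stringsAsFactors = FALSE)
}

# Panel gene models. Small-variant panel genes get a 40-kb window with five
# 200-bp exons around the fixture position; SV panel genes have hand-placed
# exons so that the planted deletions/duplications hit (or miss) them as the
# case reports describe; CRE-linked genes sit downstream of their CRE.
.panel_gene_table <- function() {
  fx <- fixture_variants()
  sm <- fx$smallvar[!duplicated(fx$smallvar$gene), ]
  mk_exons <- function(chrom, center) {
    starts <- center - 16000 + (0:4) * 8000
    paste(sprintf("%s:%d-%d", chrom, starts, starts + 199), collapse = ";")
  }
  small <- data.frame(
    gene_symbol = sm$gene,
    chrom = sm$chrom,
    exons = mapply(mk_exons, sm$chrom, sm$pos),
    stringsAsFactors = FALSE)
  # exon models for the SV and CRE panel genes
  manual <- data.frame(
    gene_symbol = c("ARHGAP11B", "TMLHE", "RHEB", "NF1",
                    "FOXP2", "DMWD", "EXT2", "DPP10", "CNTN3", "RAB2A",
                    "NTRK2", "MOCS1"),
    chrom = c("chr15", "chrX", "chr7", "chr17", "chr7", "chr19", "chr11",
              "chr2", "chr3", "chr8", "chr9", "chr6"),
    exons = c(
      paste(sprintf("chr15:%d-%d", 30620000 + (0:4) * 8000,
                    30620199 + (0:4) * 8000), collapse = ";"),
      # TMLHE exon 2 lies inside the planted 12-kb deletion; exons 1/3 outside
      "chrX:154756000-154756199;chrX:154748000-154748199;chrX:154760000-154760199",
      paste(sprintf("chr7:%d-%d", 151480000 + (0:3) * 5000,
                    151480199 + (0:3) * 5000), collapse = ";"),
      paste(sprintf("chr17:%d-%d", 31150000 + (0:4) * 20000,
                    31150199 + (0:4) * 20000), collapse = ";"),
      mk_exons("chr7", 114030000), mk_exons("chr19", 45800000),
      mk_exons("chr11", 44130000), mk_exons("chr2", 115230000),
      mk_exons("chr3", 74330000), mk_exons("chr8", 60530000),
      mk_exons("chr9", 84630000), mk_exons("chr6", 39930000)),
    stringsAsFactors = FALSE)
  panel <- rbind(small, manual)
  pli <- c(PTEN = 0.048, CHD7 = 1, BSN = 1, HNRNPR = 1, MKX = 0.782,
           SMARCA4 = 1, GLUL = 0.999, TRIP12 = 1, TEK = 1, PCLO = 1,
           HLCS = 1.26e-11, EPPK1 = 0.123, MADD = 0, SLC25A10 = 2.42e-10,
           CHD5 = 1, JARID2 = 1)
  sfari <- c(PTEN = "1S", CHD7 = "1S", HNRNPH2 = "1", HNRNPR = "2S",
             MKX = "1", SMARCA4 = "1", RPS6KA3 = "2S", TRIP12 = "1S",
             TEK = "1", PCLO = "2", EPPK1 = "2", JARID2 = "2", GLRA2 = "2")
  panel$pli <- unname(pli[panel$gene_symbol])
  panel$sfari_score <- unname(sfari[panel$gene_symbol])
  panel$is_asd_idd <- 1L
  panel[, c("gene_symbol", "is_asd_idd", "sfari_score", "pli", "exons",
            "chrom")]
}

# Non-panel background gene windows: 40-kb windows in the 95-99 Mb band of
# chr1-chr12, clear of every fixture feature and within real chromosome
# lengths.
.background_gene_windows <- function(n = 40) {
  k <- seq_len(n) - 1L
  chrom <- paste0("chr", (k %% 12L) + 1L)
  start <- 95e6 + (k %/% 12L) * 1e6
  data.frame(gene_symbol = sprintf("BG%03d", k + 1L), chrom = chrom,
             start = start, end = start + 39999, stringsAsFactors = FALSE)
}
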