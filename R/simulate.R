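# Synthetic trio cohort generator: emits the complete file set the pipeline
# consumes (PED, small-variant VCF + annotation sidecar, two SV call sets,
# CNV log2 segments, chrM VCF + pathogenicity table, STR profile, gene panel,
# CRE BED), with background variation drawn under Hardy-Weinberg/Mendelian
# structure and the published case variants planted as ground truth.

#' Simulation configuration
#'
#' Defaults describe the study cohort: 57 trios, 44 male probands, 23
#' probands with comorbid IDD, an expected 72 de novo small variants per
#' genome, mean depth 35x. Background variants are constrained to non-panel
#' genes and intergenic space so that planted fixtures are the only source of
#' PPVs.
#'
#' @param ... named overrides of: `n_trios`, `n_male_probands`, `n_idd`,
#'   `n_background_sites`, `denovo_rate_per_genome`, `depth_mean`,
#'   `n_background_svs`, `n_background_cnvs`, `n_background_mito`,
#'   `n_str_columns`, `n_multiallelic`, `n_vqsr_fail`, `include_fixtures`,
#'   `fixture_overrides` (data.frame `id, field, value`).
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_trios = 57L, n_male_probands = 44L, n_idd = 23L,
    n_background_sites = 1500L, denovo_rate_per_genome = 72,
    depth_mean = 35, n_background_svs = 24L, n_background_cnvs = 10L,
    n_background_mito = 8L, n_str_columns = 24L, n_multiallelic = 8L,
    n_vqsr_fail = 10L, include_fixtures = TRUE, fixture_overrides = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    trioppv_stop("unknown sim_config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

.vcf_contig_header <- function() {
  chroms <- c(paste0("chr", 1:22), "chrX", "chrM")
  paste0("##contig=<ID=", chroms, ">")
}

.chrom_order <- function(chrom) {
  match(chrom, c(paste0("chr", 1:22), "chrX", "chrM"))
}

# one genotype cell "GT:GQ:DP:AD:PL"; vectorized over cells
.cell_strings <- function(dose, ploidy, dp, ad_alt, gq) {
  ad_ref <- dp - ad_alt
  gt <- ifelse(ploidy == 1L, ifelse(dose > 0, "1", "0"),
               ifelse(dose == 0, "0/0", ifelse(dose == 1, "0/1", "1/1")))
  pl <- character(length(dose))
  dip <- ploidy == 2L
  pl[dip & dose == 0] <- paste0("0,", 5 * dp[dip & dose == 0], ",",
                                30 * dp[dip & dose == 0])
  i <- dip & dose == 1
  pl[i] <- paste0(30 * ad_alt[i], ",0,", 30 * ad_ref[i])
  i <- dip & dose == 2
  pl[i] <- paste0(30 * ad_alt[i], ",", 5 * ad_alt[i], ",0")
  hap <- ploidy == 1L
  pl[hap & dose == 0] <- paste0("0,", 30 * dp[hap & dose == 0])
  i <- hap & dose > 0
  pl[i] <- paste0(30 * ad_alt[i], ",0")
  paste0(gt, ":", gq, ":", dp, ":", ad_ref, ",", ad_alt, ":", pl)
}

#' Generate a synthetic trio cohort
#'
#' Writes the full cohort file set under `out_dir` and returns the manifest.
#' Background variation is Mendelian-consistent (parental genotypes from
#' Hardy-Weinberg at per-site frequencies, child genotypes by transmission)
#' with de novo variants injected at the configured per-genome rate but
#' constrained to non-panel genes and intergenic space; the published case
#' variants are planted as ground truth unless `include_fixtures = FALSE`.
#' Output is deterministic given `seed`.
#'
#' @param out_dir output directory (created).
#' @param seed integer RNG seed.
#' @param config [sim_config()].
#' @return invisibly, a list with `paths` (named file paths), `fixtures`
#'   (the planted truth tables) and `config`.
#' @export
simulate_trio_cohort <- function(out_dir, seed = 1,
                                 config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  old <- options(scipen = 999)  # coordinates must never print scientifically
  on.exit(options(old))
  set.seed(as.integer(seed))
  n <- as.integer(config$n_trios)
  if (n < 1) trioppv_stop("n_trios must be positive")
  if (config$n_male_probands > n)
    trioppv_stop("n_male_probands exceeds n_trios")
  fx <- if (config$include_fixtures)
    fixture_variants(config$fixture_overrides) else NULL
  if (!is.null(fx)) {
    max_fam <- max(fx$smallvar$family, fx$sv$family, fx$mito$family,
                   fx$cre$family)
    if (n < 39L)
      trioppv_stop("fixtures require n_trios >= 39 (fixture carriers and ",
                   "IDD stratification); got ", n)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  fam <- sprintf("F%02d", seq_len(n))
  pro <- paste0(fam, "-P"); mot <- paste0(fam, "-M"); fat <- paste0(fam, "-F")
  samples <- as.vector(rbind(pro, mot, fat))

  ## ---- sex and IDD assignment -------------------------------------------
  sex <- rep(NA_character_, n)
  sev <- rep("none", n)
  if (!is.null(fx)) {
    sex[c(1, 3, 4, 5, 9, 17, 18)] <- "male"
    sex[2] <- "female"
    all_idd <- rbind(
      data.frame(family = fx$smallvar$family, idd = fx$smallvar$idd),
      data.frame(family = fx$sv$family, idd = fx$sv$idd),
      data.frame(family = fx$mito$family, idd = fx$mito$idd))
    for (k in seq_len(nrow(all_idd)))
      if (all_idd$idd[k] != "none") sev[all_idd$family[k]] <- all_idd$idd[k]
  }
  need_m <- config$n_male_probands - sum(sex == "male", na.rm = TRUE)
  if (need_m < 0) trioppv_stop("n_male_probands below fixture requirement")
  free <- which(is.na(sex))
  sex[free[seq_len(need_m)]] <- "male"
  sex[is.na(sex)] <- "female"
  idd_now <- sum(sev %in% c("mild", "moderate", "severe", "profound"))
  need_idd <- config$n_idd - idd_now
  if (need_idd < 0)
    trioppv_stop("n_idd below the IDD count implied by fixtures")
  fill_from <- if (is.null(fx)) 1L else 27L
  free_idd <- setdiff(seq(fill_from, n), which(sev != "none"))
  if (length(free_idd) < need_idd)
    trioppv_stop("not enough families to reach n_idd")
  sev[free_idd[seq_len(need_idd)]] <-
    rep(c("mild", "moderate"), length.out = need_idd)

  ## ---- PED ---------------------------------------------------------------
  ped_lines <- c(
    paste(fam, fat, 0, 0, 1, 1, ".", sep = "\t"),
    paste(fam, mot, 0, 0, 2, 1, ".", sep = "\t"),
    paste(fam, pro, fat, mot, ifelse(sex == "male", 1, 2), 2, sev, sep = "\t"))
  ord <- as.vector(rbind(2 * n + seq_len(n), n + seq_len(n), seq_len(n)))
  ped_path <- file.path(out_dir, "cohort.ped")
  writeLines(ped_lines[ord], ped_path)

  ## ---- panel and CRE -----------------------------------------------------
  panel <- .panel_gene_table()
  bg <- .background_gene_windows()
  panel_out <- rbind(
    panel[, c("gene_symbol", "is_asd_idd", "sfari_score", "pli", "exons")],
    data.frame(gene_symbol = bg$gene_symbol, is_asd_idd = 0L,
               sfari_score = NA_character_, pli = NA_real_, exons = "",
               stringsAsFactors = FALSE))
  panel_path <- file.path(out_dir, "panel.tsv")
  write_tsv(panel_out, panel_path)

  cre <- .fixture_cre_intervals()
  decoys <- data.frame(chrom = c("chr1", "chr2"),
                       start0 = c(95050000, 95060000),
                       end0 = c(95051000, 95061000),
                       gene = c("BG001", "BG002"), stringsAsFactors = FALSE)
  cre_all <- rbind(cre, decoys)
  cre_path <- file.path(out_dir, "cre.bed")
  writeLines(paste(cre_all$chrom, cre_all$start0, cre_all$end0, cre_all$gene,
                   sep = "\t"), cre_path)

  ## ---- small-variant site table -----------------------------------------
  bases <- c("A", "C", "G", "T")
  n_bgs <- config$n_background_sites
  n_vq <- config$n_vqsr_fail
  n_inh <- n_bgs + n_vq
  win_idx <- sample.int(nrow(bg), n_inh, replace = TRUE)
  q_bg <- 10^stats::runif(n_inh, -4, -0.6)
  cons_pool <- c("missense", "synonymous", "intronic", "other")
  cons_bg <- sample(cons_pool, n_inh, replace = TRUE,
                    prob = c(0.30, 0.25, 0.35, 0.10))

  dn_counts <- stats::rpois(n, config$denovo_rate_per_genome)
  n_dn <- sum(dn_counts)
  dn_family <- rep(seq_len(n), dn_counts)
  dn_in_gene <- stats::runif(n_dn) < 0.1
  dn_win <- rep(NA_integer_, n_dn)
  dn_win[dn_in_gene] <- sample.int(nrow(bg), sum(dn_in_gene), replace = TRUE)

  # unique positions per background window (shared by inherited + de novo)
  pos_inh <- integer(n_inh); chrom_inh <- bg$chrom[win_idx]
  pos_dng <- integer(n_dn)
  for (w in seq_len(nrow(bg))) {
    ii <- which(win_idx == w); jj <- which(!is.na(dn_win) & dn_win == w)
    k <- length(ii) + length(jj)
    if (!k) next
    p <- bg$start[w] + sample.int(40000L, k) - 1L
    if (length(ii)) pos_inh[ii] <- p[seq_along(ii)]
    if (length(jj)) pos_dng[jj] <- p[length(ii) + seq_along(jj)]
  }
  # intergenic pool for the remaining de novos and the multi-allelic rows
  n_ma <- config$n_multiallelic
  inter_need <- which(!dn_in_gene)
  inter_chrom_idx <- sample.int(12L, length(inter_need) + n_ma,
                                replace = TRUE)
  inter_pos <- integer(length(inter_need) + n_ma)
  for (cc in 1:12) {
    kk <- which(inter_chrom_idx == cc)
    if (length(kk))
      inter_pos[kk] <- 99500000L + sample.int(400000L, length(kk)) - 1L
  }
  dn_chrom <- character(n_dn)
  dn_pos <- integer(n_dn)
  dn_gene <- rep(NA_character_, n_dn)
  dn_cons <- rep("intergenic", n_dn)
  dn_chrom[dn_in_gene] <- bg$chrom[dn_win[dn_in_gene]]
  dn_pos[dn_in_gene] <- pos_dng[dn_in_gene]
  dn_gene[dn_in_gene] <- bg$gene_symbol[dn_win[dn_in_gene]]
  dn_cons[dn_in_gene] <- sample(c("missense", "synonymous"),
                                sum(dn_in_gene), replace = TRUE)
  dn_chrom[!dn_in_gene] <- paste0("chr",
                                  inter_chrom_idx[seq_along(inter_need)])
  dn_pos[!dn_in_gene] <- inter_pos[seq_along(inter_need)]
  ma_chrom <- paste0("chr", inter_chrom_idx[length(inter_need) + seq_len(n_ma)])
  ma_pos <- inter_pos[length(inter_need) + seq_len(n_ma)]

  ref_of <- function(k) sample(bases, k, replace = TRUE)
  alt_of <- function(ref) {
    vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  }
  ref_inh <- ref_of(n_inh); alt_inh <- alt_of(ref_inh)
  ref_dn <- ref_of(n_dn); alt_dn <- alt_of(ref_dn)

  site <- data.frame(
    chrom = c(chrom_inh, dn_chrom),
    pos = c(pos_inh, dn_pos),
    id = ".",
    ref = c(ref_inh, ref_dn),
    alt = c(alt_inh, alt_dn),
    filter = c(rep("PASS", n_bgs),
               rep("VQSRTrancheSNP99.90to100.00", n_vq),
               rep("PASS", n_dn)),
    gene = c(bg$gene_symbol[win_idx], dn_gene),
    consequence = c(cons_bg, dn_cons),
    mpc = NA_real_, spliceai = NA_real_,
    maf = c(q_bg, rep(0, n_dn)),
    kind = c(rep("inherited", n_bgs), rep("vqsr_fail", n_vq),
             rep("denovo", n_dn)),
    family = c(rep(NA_integer_, n_inh), dn_family),
    fixture_id = NA_character_,
    gq_child_override = NA_real_,
    stringsAsFactors = FALSE)
  site$mpc[site$consequence == "missense"] <-
    round(stats::runif(sum(site$consequence == "missense"), 0, 0.95), 2)

  if (!is.null(fx)) {
    fs <- fx$smallvar
    fix_rows <- data.frame(
      chrom = fs$chrom, pos = fs$pos, id = fs$id, ref = fs$ref, alt = fs$alt,
      filter = "PASS", gene = fs$gene, consequence = fs$consequence,
      mpc = fs$mpc, spliceai = fs$spliceai, maf = fs$maf,
      kind = paste0("fixture_", fs$inheritance), family = fs$family,
      fixture_id = fs$id, gq_child_override = fs$gq_child,
      stringsAsFactors = FALSE)
    fc <- fx$cre
    cre_rows <- data.frame(
      chrom = fc$chrom, pos = fc$pos, id = fc$id, ref = fc$ref, alt = fc$alt,
      filter = "PASS", gene = NA_character_, consequence = "intergenic",
      mpc = NA_real_, spliceai = NA_real_, maf = 0,
      kind = "fixture_de_novo", family = fc$family, fixture_id = fc$id,
      gq_child_override = fc$gq_child, stringsAsFactors = FALSE)
    site <- rbind(site, fix_rows, cre_rows)
  }
  if (anyDuplicated(paste(site$chrom, site$pos)))
    trioppv_stop("internal: fixture conflicts with an existing site")

  ## ---- genotype doses ----------------------------------------------------
  ns <- nrow(site)
  n_samp <- length(samples)
  dose <- matrix(0L, ns, n_samp, dimnames = list(NULL, samples))
  i_pro <- match(pro, samples); i_mot <- match(mot, samples)
  i_fat <- match(fat, samples)

  inh_rows <- which(site$kind %in% c("inherited", "vqsr_fail"))
  if (length(inh_rows)) {
    q <- site$maf[inh_rows]
    dm <- matrix(stats::rbinom(length(inh_rows) * n, 2, rep(q, n)),
                 ncol = n)
    df_ <- matrix(stats::rbinom(length(inh_rows) * n, 2, rep(q, n)),
                  ncol = n)
    am <- matrix(stats::rbinom(length(dm), 1, dm / 2), ncol = n)
    af <- matrix(stats::rbinom(length(df_), 1, df_ / 2), ncol = n)
    dose[inh_rows, i_mot] <- dm
    dose[inh_rows, i_fat] <- df_
    dose[inh_rows, i_pro] <- am + af
  }
  dn_rows <- which(site$kind == "denovo")
  dose[cbind(dn_rows, i_pro[site$family[dn_rows]])] <- 1L

  if (!is.null(fx)) {
    frows <- which(!is.na(site$fixture_id))
    for (r in frows) {
      f <- site$family[r]
      kind <- site$kind[r]
      if (kind %in% c("fixture_de_novo", "fixture_hemi_de_novo")) {
        dose[r, i_pro[f]] <- 1L
      } else if (kind == "fixture_maternal") {
        dose[r, i_pro[f]] <- 1L; dose[r, i_mot[f]] <- 1L
      } else if (kind == "fixture_paternal") {
        dose[r, i_pro[f]] <- 1L; dose[r, i_fat[f]] <- 1L
      } else if (kind == "fixture_hemi_maternal") {
        dose[r, i_pro[f]] <- 1L; dose[r, i_mot[f]] <- 1L
      }
    }
  }

  ## ---- ploidy, depth, strings -------------------------------------------
  sample_sex <- c(rbind(sex, rep("female", n), rep("male", n)))
  is_x_row <- site$chrom == "chrX"
  ploidy <- matrix(2L, ns, n_samp)
  ploidy[is_x_row, sample_sex == "male"] <- 1L

  dp <- matrix(stats::rpois(ns * n_samp, config$depth_mean), ns, n_samp)
  dp[dp < 12] <- 12L
  gq <- matrix(0L, ns, n_samp)
  ad_alt <- matrix(0L, ns, n_samp)

  # fixture trios sequenced deep; deterministic QC outcome
  if (!is.null(fx)) {
    for (r in which(!is.na(site$fixture_id))) {
      f <- site$family[r]
      dp[r, c(i_pro[f], i_mot[f], i_fat[f])] <- 50L
    }
  }

  car1 <- dose == 1L & ploidy == 2L
  ad_alt[car1] <- pmin(pmax(stats::rbinom(sum(car1), dp[car1], 0.5),
                            ceiling(0.36 * dp[car1])),
                       floor(0.64 * dp[car1]))
  car2 <- dose == 2L | (dose == 1L & ploidy == 1L)
  ad_alt[car2] <- dp[car2] - stats::rbinom(sum(car2), dp[car2], 0.02)

  gq[dose == 0L] <- pmin(99L, 5L * dp[dose == 0L])
  gq[dose > 0L] <- 99L
  # a small fraction of background inherited carrier calls have marginal GQ
  bg_car <- which(dose > 0L &
                    matrix(site$kind %in% c("inherited", "vqsr_fail"),
                           ns, n_samp))
  if (length(bg_car)) {
    low <- bg_car[stats::runif(length(bg_car)) < 0.05]
    gq[low] <- sample(50:98, length(low), replace = TRUE)
  }
  if (!is.null(fx)) {
    for (r in which(!is.na(site$fixture_id))) {
      f <- site$family[r]
      gq[r, c(i_pro[f], i_mot[f], i_fat[f])] <- 99L
      if (!is.na(site$gq_child_override[r]))
        gq[r, i_pro[f]] <- as.integer(site$gq_child_override[r])
    }
  }

  cells <- matrix(.cell_strings(as.vector(dose), as.vector(ploidy),
                                as.vector(dp), as.vector(ad_alt),
                                as.vector(gq)), ns, n_samp)

  ## ---- multi-allelic rows ------------------------------------------------
  if (n_ma > 0) {
    ma_ref <- ref_of(n_ma)
    ma_alt <- vapply(ma_ref, function(r)
      paste(sample(setdiff(bases, r), 2), collapse = ","), "")
    ma_dp <- matrix(stats::rpois(n_ma * n_samp, config$depth_mean) + 12L,
                    n_ma, n_samp)
    ma_cells <- matrix(paste0("0/0:99:", ma_dp, ":", ma_dp, ",0,0:0,",
                              5L * ma_dp, ",", 30L * ma_dp, ",",
                              5L * ma_dp, ",", 30L * ma_dp, ",",
                              30L * ma_dp), n_ma, n_samp)
    ma_site <- data.frame(chrom = ma_chrom, pos = ma_pos, id = ".",
                          ref = ma_ref, alt = ma_alt, filter = "PASS",
                          stringsAsFactors = FALSE)
  }

  ## ---- write the small-variant VCF --------------------------------------
  body_cols <- data.frame(
    chrom = c(site$chrom, if (n_ma) ma_site$chrom),
    pos = c(site$pos, if (n_ma) ma_site$pos),
    id = c(site$id, if (n_ma) ma_site$id),
    ref = c(site$ref, if (n_ma) ma_site$ref),
    alt = c(site$alt, if (n_ma) ma_site$alt),
    filter = c(site$filter, if (n_ma) ma_site$filter),
    stringsAsFactors = FALSE)
  geno_str <- rbind(cells, if (n_ma) ma_cells)
  ord <- order(.chrom_order(body_cols$chrom), body_cols$pos)
  geno_lines <- do.call(paste, c(lapply(seq_len(n_samp),
                                        function(j) geno_str[ord, j]),
                                 list(sep = "\t")))
  vcf_lines <- paste(body_cols$chrom[ord], body_cols$pos[ord],
                     body_cols$id[ord], body_cols$ref[ord],
                     body_cols$alt[ord], 500, body_cols$filter[ord], ".",
                     "GT:GQ:DP:AD:PL", geno_lines, sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=trioppv-simulate",
    .vcf_contig_header(),
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FILTER=<ID=VQSRTrancheSNP99.90to100.00,Description=\"VQSR tranche failure\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=.,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  vcf_path <- file.path(out_dir, "smallvar.vcf")
  writeLines(c(header, vcf_lines), vcf_path)

  ## ---- annotation sidecar -------------------------------------------------
  ann <- site
  keep_ann <- !(ann$kind == "inherited" & stats::runif(ns) < 0.15)
  ann <- ann[keep_ann, , drop = FALSE]
  jit <- function(x) round(x * stats::runif(length(x), 0.9, 1.1), 6)
  ann_out <- data.frame(
    chrom = ann$chrom, pos = ann$pos, ref = ann$ref, alt = ann$alt,
    gene = ann$gene, consequence = ann$consequence, mpc = ann$mpc,
    spliceai_delta = ann$spliceai,
    maf_gnomad_eas = jit(ann$maf),
    maf_tommo = ifelse(stats::runif(nrow(ann)) < 0.25, NA, jit(ann$maf)),
    clinvar = NA_character_, stringsAsFactors = FALSE)
  # fixtures keep their exact MAF in both sources
  fixm <- !is.na(ann$fixture_id)
  ann_out$maf_gnomad_eas[fixm] <- ann$maf[fixm]
  ann_out$maf_tommo[fixm] <- ann$maf[fixm]
  annot_path <- file.path(out_dir, "annotations.tsv")
  write_tsv(ann_out[order(.chrom_order(ann_out$chrom), ann_out$pos), ],
            annot_path)

  ## ---- SV call sets ------------------------------------------------------
  sv_paths <- .write_sv_callsets(out_dir, fx, bg, fam, pro, mot, fat,
                                 samples, sample_sex, config)

  ## ---- CNV segments ------------------------------------------------------
  cnv_path <- .write_cnv_segments(out_dir, fx, bg, pro, mot, fat, config)

  ## ---- mitochondrial files ----------------------------------------------
  mito_paths <- .write_mito(out_dir, fx, pro, mot, fat, samples, config)

  ## ---- STR profile -------------------------------------------------------
  str_path <- .write_str_profile(out_dir, pro, config)

  ## ---- truth table -------------------------------------------------------
  truth_path <- file.path(out_dir, "truth_variants.tsv")
  if (!is.null(fx)) {
    truth <- rbind(
      data.frame(id = fx$smallvar$id, family = fx$smallvar$family,
                 class = "smallvar", gene = fx$smallvar$gene,
                 inheritance = fx$smallvar$inheritance,
                 expected_rule = fx$smallvar$expected_rule,
                 provenance = "coordinates/alleles/inheritance as published; MPC/SpliceAI/MAF/PL synthesized minimally past thresholds"),
      data.frame(id = fx$sv$id, family = fx$sv$family, class = "sv",
                 gene = fx$sv$gene, inheritance = fx$sv$inheritance,
                 expected_rule = fx$sv$expected_rule,
                 provenance = "span/genes as published; MAF synthesized"),
      data.frame(id = fx$mito$id, family = fx$mito$family, class = "mito",
                 gene = fx$mito$gene, inheritance = fx$mito$expected_rule,
                 expected_rule = fx$mito$expected_rule,
                 provenance = "position/heteroplasmy side as published; read counts synthesized"),
      data.frame(id = fx$cre$id, family = fx$cre$family, class = "cre",
                 gene = fx$cre$gene, inheritance = "de_novo",
                 expected_rule = "noncoding_cre_hit",
                 provenance = "linked gene as published; position synthesized inside CRE"))
    write_tsv(truth, truth_path)
  } else {
    write_tsv(data.frame(id = character(), family = integer(),
                         class = character(), gene = character(),
                         inheritance = character(),
                         expected_rule = character(),
                         provenance = character()), truth_path)
  }

  paths <- c(list(ped = ped_path, vcf = vcf_path, annot = annot_path,
                  panel = panel_path, cre = cre_path, cnv = cnv_path,
                  str_profile = str_path, truth = truth_path),
             sv_paths, mito_paths)
  invisible(list(paths = paths, fixtures = fx, config = config))
}

## ---- SV call-set writer ---------------------------------------------------
.write_sv_callsets <- function(out_dir, fx, bg, fam, pro, mot, fat, samples,
                               sample_sex, config) {
  n <- length(fam)
  recs <- list()
  add <- function(chrom, start, end, type, maf, geno_patch, in_a, in_b,
                  precise_b = TRUE, pass = TRUE, alt = NULL) {
    recs[[length(recs) + 1]] <<- list(
      chrom = chrom, start = start, end = end, type = type, maf = maf,
      geno_patch = geno_patch, in_a = in_a, in_b = in_b,
      precise_b = precise_b, pass = pass, alt = alt)
  }
  if (!is.null(fx)) {
    fs <- fx$sv
    for (k in seq_len(nrow(fs))) {
      f <- fs$family[k]
      gp <- switch(fs$inheritance[k],
        hom_recessive = setNames(c("1/1", "0/1", "0/1"),
                                 c(pro[f], mot[f], fat[f])),
        hemi_maternal = setNames(c("1", "0/1", "0"),
                                 c(pro[f], mot[f], fat[f])),
        inherited_maternal = setNames(c("0/1", "0/1"), c(pro[f], mot[f])),
        inherited_paternal = setNames(c("0/1", "0/1"), c(pro[f], fat[f])))
      add(fs$chrom[k], fs$start[k], fs$end[k], fs$sv_type[k], fs$maf[k],
          gp, TRUE, TRUE)
    }
  }
  n_bsv <- config$n_background_svs
  if (n_bsv > 0) {
    w <- sample.int(nrow(bg), n_bsv, replace = TRUE)
    off <- sample.int(8000L, n_bsv, replace = TRUE)
    len <- sample(5000:30000, n_bsv, replace = TRUE)
    typ <- sample(c("DEL", "DUP", "INV"), n_bsv, replace = TRUE)
    fidx <- sample.int(n, n_bsv, replace = TRUE)
    inh <- stats::runif(n_bsv) < 0.6
    which_set <- sample(c("both", "a", "b"), n_bsv, replace = TRUE,
                        prob = c(0.6, 0.2, 0.2))
    prec <- stats::runif(n_bsv) > 0.15
    pass <- stats::runif(n_bsv) > 0.08
    for (k in seq_len(n_bsv)) {
      f <- fidx[k]
      gp <- if (inh[k]) {
        par <- if (stats::runif(1) < 0.5) mot[f] else fat[f]
        setNames(c("0/1", "0/1"), c(pro[f], par))
      } else setNames("0/1", pro[f])
      add(bg$chrom[w[k]], bg$start[w[k]] + off[k],
          bg$start[w[k]] + off[k] + len[k], typ[k],
          if (stats::runif(1) < 0.3) NA else round(stats::runif(1, 0, 0.008), 5),
          gp, which_set[k] %in% c("both", "a"),
          which_set[k] %in% c("both", "b"), prec[k], pass[k])
    }
  }
  # one unresolved breakend record in caller A (kept, flagged downstream)
  add("chr5", 96000000, 96000000, "TRA", NA, setNames("0/1", pro[1]),
      TRUE, FALSE, alt = "N[chrUn_gl000220:12345[")

  write_one <- function(path, use_a) {
    lines <- character(0)
    for (r in recs) {
      if (use_a && !r$in_a) next
      if (!use_a && !r$in_b) next
      start <- r$start; end <- r$end
      if (!use_a && is.null(r$alt)) {  # caller B jitters breakpoints a little
        start <- start + sample(-60:60, 1)
        end <- end + sample(-60:60, 1)
      }
      alt <- if (!is.null(r$alt)) r$alt else paste0("<", r$type, ">")
      info <- paste0("SVTYPE=", ifelse(is.null(r$alt), r$type, "BND"),
                     ";END=", max(start, end))
      if (!is.na(r$maf)) info <- paste0(info, ";MAF=", r$maf)
      if (!use_a && !r$precise_b) info <- paste0(info, ";IMPRECISE")
      filt <- if (r$pass) "PASS" else "LowQual"
      g <- ifelse(r$chrom == "chrX" & sample_sex == "male", "0", "0/0")
      names(g) <- samples
      for (nm in names(r$geno_patch)) g[nm] <- r$geno_patch[[nm]]
      lines <- c(lines, paste(c(r$chrom, max(start, 1), ".", "N", alt, 60,
                                filt, info, "GT", g), collapse = "\t"))
    }
    header <- c(
      "##fileformat=VCFv4.2",
      .vcf_contig_header(),
      "##contig=<ID=chrUn_gl000220>",
      "##ALT=<ID=DEL,Description=\"Deletion\">",
      "##ALT=<ID=DUP,Description=\"Duplication\">",
      "##ALT=<ID=INV,Description=\"Inversion\">",
      "##ALT=<ID=INS,Description=\"Insertion\">",
      "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
      "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
      "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Population allele frequency\">",
      "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise breakpoints\">",
      "##FILTER=<ID=PASS,Description=\"All filters passed\">",
      "##FILTER=<ID=LowQual,Description=\"Low quality\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", samples), collapse = "\t"))
    # sort records by position
    if (length(lines)) {
      key <- strsplit(lines, "\t")
      ordk <- order(.chrom_order(vapply(key, `[`, "", 1)),
                    as.numeric(vapply(key, `[`, "", 2)))
      lines <- lines[ordk]
    }
    writeLines(c(header, lines), path)
    path
  }
  list(sv_a = write_one(file.path(out_dir, "sv_caller_a.vcf"), TRUE),
       sv_b = write_one(file.path(out_dir, "sv_caller_b.vcf"), FALSE))
}

## ---- CNV segment writer ---------------------------------------------------
.write_cnv_segments <- function(out_dir, fx, bg, pro, mot, fat, config) {
  n <- length(pro)
  segs <- list()
  add <- function(sample_id, chrom, start, end, log2)
    segs[[length(segs) + 1]] <<- data.frame(
      sample_id = sample_id, chrom = chrom, start = start, end = end,
      log2 = log2, stringsAsFactors = FALSE)
  all_samp <- c(pro, mot, fat)
  for (s in all_samp) {
    w <- sample.int(nrow(bg), 6)
    for (k in w)
      add(s, bg$chrom[k], bg$start[k], bg$end[k],
          round(stats::rnorm(1, 0, 0.08), 3))
  }
  if (!is.null(fx)) {
    # the homozygous 212-kb deletion is also seen by the CNV caller
    add(pro[18], "chr15", 30500500, 30711500, -3.2)
    add(mot[18], "chr15", 30500500, 30711500, -0.92)
    add(fat[18], "chr15", 30500500, 30711500, -0.88)
  }
  n_cnv <- config$n_background_cnvs
  if (n_cnv > 0) {
    w <- sample.int(nrow(bg), n_cnv, replace = TRUE)
    who <- sample(pro, n_cnv, replace = TRUE)
    for (k in seq_len(n_cnv)) {
      s0 <- bg$start[w[k]] + sample.int(5000L, 1)
      add(who[k], bg$chrom[w[k]], s0, s0 + sample(5000:25000, 1),
          round(sample(c(stats::runif(1, -0.85, -0.62),
                         stats::runif(1, 0.42, 0.6)), 1), 3))
    }
  }
  out <- do.call(rbind, segs)
  out <- out[order(out$sample_id, .chrom_order(out$chrom), out$start), ]
  path <- file.path(out_dir, "cnv_segments.tsv")
  write_tsv(out, path)
  path
}

## ---- mito writer ----------------------------------------------------------
.write_mito <- function(out_dir, fx, pro, mot, fat, samples, config) {
  n_bg <- config$n_background_mito
  used <- if (!is.null(fx)) fx$mito$pos else integer(0)
  used <- c(used, 8993L)
  bases <- c("A", "C", "G", "T")
  bg_pos <- sort(sample(setdiff(100:16400, used), n_bg))
  rows <- data.frame(pos = bg_pos,
                     ref = sample(bases, n_bg, replace = TRUE),
                     stringsAsFactors = FALSE)
  rows$alt <- vapply(rows$ref, function(r) sample(setdiff(bases, r), 1), "")
  rows$kind <- "background"
  # a known pathogenic variant below the reporting threshold (3% load)
  rows <- rbind(rows, data.frame(pos = 8993L, ref = "T", alt = "G",
                                 kind = "subthreshold"))
  if (!is.null(fx))
    rows <- rbind(rows, data.frame(pos = fx$mito$pos, ref = fx$mito$ref,
                                   alt = fx$mito$alt, kind = fx$mito$id))
  rows <- rows[order(rows$pos), ]

  n_samp <- length(samples)
  lines <- character(nrow(rows))
  fam30_pro <- pro[min(30, length(pro))]
  for (k in seq_len(nrow(rows))) {
    depth <- stats::rpois(n_samp, 200) + 50L
    altc <- stats::rbinom(n_samp, depth, 0.004)
    names(depth) <- names(altc) <- samples
    if (rows$kind[k] == "subthreshold") {
      altc[fam30_pro] <- round(depth[fam30_pro] * 0.03)
    } else if (!is.null(fx) && rows$kind[k] %in% fx$mito$id) {
      m <- fx$mito[fx$mito$id == rows$kind[k], ]
      f <- m$family
      depth[pro[f]] <- 150L
      altc[pro[f]] <- round(150 * m$proband_pct / 100)
      depth[mot[f]] <- 160L
      altc[mot[f]] <- round(160 * m$mother_pct / 100)
      altc[fat[f]] <- 0L
    }
    frac <- altc / depth
    gt <- ifelse(frac > 0.5, "1/1", ifelse(altc > 0, "0/1", "0/0"))
    cells <- paste0(gt, ":", depth - altc, ",", altc, ":", depth)
    lines[k] <- paste(c("chrM", rows$pos[k], ".", rows$ref[k], rows$alt[k],
                        500, "PASS", ".", "GT:AD:DP", cells),
                      collapse = "\t")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrM>",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=.,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  mito_path <- file.path(out_dir, "mito.vcf")
  writeLines(c(header, lines), mito_path)

  tab <- data.frame(
    pos = c(5540L, 14674L, 8993L, 3243L),
    ref = c("G", "T", "T", "A"),
    alt = c("A", "C", "G", "G"),
    clinvar_significance = "Pathogenic",
    disease_label = c("MELAS", "Primary mitochondrial disease", "NARP",
                      "MELAS"),
    stringsAsFactors = FALSE)
  tab_path <- file.path(out_dir, "mito_pathogenic.tsv")
  write_tsv(tab, tab_path)
  list(mito = mito_path, mito_pathogenic = tab_path)
}

## ---- STR profile writer ---------------------------------------------------
.write_str_profile <- function(out_dir, pro, config) {
  n_col <- config$n_str_columns
  motifs <- rep(c("CAG", "CGG", "GAA", "CTG", "ATTCT", "GGGGCC"),
                length.out = n_col)
  j <- seq_len(n_col) - 1L
  regions <- sprintf("chr%d:%d-%d", (j %% 12L) + 1L,
                     98500000L + (j %/% 12L) * 200000L + (j %% 12L) * 3000L,
                     98500060L + (j %/% 12L) * 200000L + (j %% 12L) * 3000L)
  grid <- expand.grid(sample_id = pro, k = seq_len(n_col),
                      stringsAsFactors = FALSE)
  prof <- data.frame(
    sample_id = grid$sample_id,
    motif = motifs[grid$k],
    region = regions[grid$k],
    count = round(stats::rlnorm(nrow(grid), log(3), 0.35), 3),
    stringsAsFactors = FALSE)
  prof <- prof[order(prof$sample_id, prof$motif, prof$region), ]
  path <- file.path(out_dir, "str_profile.tsv")
  write_tsv(prof, path)
  path
}
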