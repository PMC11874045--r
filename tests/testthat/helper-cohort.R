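# Shared cohort fixtures. The full 57-trio run is expensive, so it is built
# once per test session and cached.

.trioppv_test_cache <- new.env(parent = emptyenv())

cohort_paths <- function(dir) {
  list(ped = file.path(dir, "cohort.ped"),
       vcf = file.path(dir, "smallvar.vcf"),
       annot = file.path(dir, "annotations.tsv"),
       sv_a = file.path(dir, "sv_caller_a.vcf"),
       sv_b = file.path(dir, "sv_caller_b.vcf"),
       cnv = file.path(dir, "cnv_segments.tsv"),
       mito = file.path(dir, "mito.vcf"),
       mito_pathogenic = file.path(dir, "mito_pathogenic.tsv"),
       panel = file.path(dir, "panel.tsv"),
       cre = file.path(dir, "cre.bed"),
       str_profile = file.path(dir, "str_profile.tsv"))
}

run_cohort <- function(dir) {
  do.call(run_trio_pipeline, cohort_paths(dir))
}

# default 57-trio cohort at a given seed, simulated and run once per session
fixture_run <- function(seed = 1) {
  key <- paste0("run_seed", seed)
  if (is.null(.trioppv_test_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("trioppv_cohort_", seed))
    if (!file.exists(file.path(dir, "cohort.ped")))
      simulate_trio_cohort(dir, seed = seed)
    .trioppv_test_cache[[key]] <- run_cohort(dir)
  }
  .trioppv_test_cache[[key]]
}

# minimal pedigree data.frame for engine-level tests (one trio)
one_trio_ped <- function(sex = "male", fam = "F01") {
  path <- tempfile(fileext = ".ped")
  writeLines(c(
    paste(fam, paste0(fam, "-F"), 0, 0, 1, 1, ".", sep = "\t"),
    paste(fam, paste0(fam, "-M"), 0, 0, 2, 1, ".", sep = "\t"),
    paste(fam, paste0(fam, "-P"), paste0(fam, "-F"), paste0(fam, "-M"),
          ifelse(sex == "male", 1, 2), 2, "mild", sep = "\t")), path)
  read_pedigree(path)
}

# a classified small-variant table with per-row overrides
mk_classified <- function(...) {
  rows <- list(...)
  base <- data.frame(
    chrom = "chr1", pos = 1e6, ref = "A", alt = "G", variant_class = "snv",
    filter_pass = TRUE, cohort_ac = 1, gene = "PTEN",
    consequence = "missense", mpc = NA_real_, spliceai_delta = NA_real_,
    maf_gnomad_eas = 0, maf_tommo = 0, clinvar = NA_character_,
    family_id = "F01", proband_sex = "male", variant_id = "v",
    site_pass = TRUE, site_reason = "pass", qc_child = TRUE,
    qc_mother = TRUE, qc_father = TRUE, dq = 15, label = "de_novo",
    conseq_class = "missense", rarity_pass = TRUE, stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- base
    for (nm in names(rows[[i]])) r[[nm]] <- rows[[i]][[nm]]
    r$variant_id <- paste0("v", i)
    r
  }))
}

fake_panel <- data.frame(gene_symbol = c("PTEN", "GLRA2", "OFFP"),
                         is_asd_idd = c(TRUE, TRUE, FALSE),
                         stringsAsFactors = FALSE)
no_pairs <- data.frame(family_id = character(), gene = character(),
                       maternal_id = character(), paternal_id = character(),
                       clause = character(), stringsAsFactors = FALSE)

# small sv_calls object built directly
make_sv_calls <- function(df, geno = NULL, samples = NULL) {
  defaults <- data.frame(caller = "x", sv_type = "DEL", chrom = "chr1",
                         start = 1, end = 2, chrom2 = NA_character_,
                         pos2 = NA_real_, filter_pass = TRUE, precise = TRUE,
                         maf = NA_real_, bnd_unresolved = FALSE,
                         stringsAsFactors = FALSE)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  if (is.null(geno)) {
    if (is.null(samples)) samples <- character(0)
    geno <- matrix("hom_ref", nrow(df), length(samples),
                   dimnames = list(NULL, samples))
  }
  structure(list(calls = df, geno = geno), class = "sv_calls")
}
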