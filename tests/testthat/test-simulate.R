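# Synthetic cohort generator: determinism, Mendelian structure, and
# sensitivity of planted fixtures to single-attribute degradation.

test_that("the same seed yields byte-identical cohort files", {
  d1 <- tempfile(); d2 <- tempfile()
  cfg <- sim_config(n_trios = 40, n_male_probands = 30, n_idd = 15,
                    n_background_sites = 80,
                    denovo_rate_per_genome = 3, include_fixtures = TRUE)
  simulate_trio_cohort(d1, seed = 9, config = cfg)
  simulate_trio_cohort(d2, seed = 9, config = cfg)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # a different seed changes the stochastic files
  d3 <- tempfile()
  simulate_trio_cohort(d3, seed = 10, config = cfg)
  expect_false(unname(tools::md5sum(file.path(d1, "smallvar.vcf"))) ==
                 unname(tools::md5sum(file.path(d3, "smallvar.vcf"))))
})

test_that("a tiny cohort without fixtures yields zero PPVs", {
  d <- tempfile()
  simulate_trio_cohort(d, seed = 4, config = sim_config(
    n_trios = 3, n_background_sites = 60, denovo_rate_per_genome = 4,
    n_male_probands = 2, n_idd = 1, n_background_svs = 6,
    n_background_cnvs = 3, include_fixtures = FALSE))
  res <- run_cohort(d)
  expect_equal(nrow(res$ppv_records), 0)
  expect_equal(res$summary$n_patients_with_ppv, 0)
  expect_equal(res$summary$comparison_p, 1.0)
})

test_that("background variation is Mendelian-consistent or marked de novo", {
  d <- tempfile()
  simulate_trio_cohort(d, seed = 5, config = sim_config(
    n_trios = 6, n_background_sites = 150, denovo_rate_per_genome = 10,
    n_male_probands = 4, n_idd = 2, include_fixtures = FALSE))
  ped <- read_pedigree(file.path(d, "cohort.ped"))
  calls <- read_small_variants(file.path(d, "smallvar.vcf"),
                               file.path(d, "annotations.tsv"), ped)
  dose <- function(gt) c(hom_ref = 0, het = 1, hom_alt = 2, hemi_ref = 0,
                         hemi_alt = 1, missing = NA)[gt]
  dc <- dose(calls$gt_child); dm <- dose(calls$gt_mother)
  df_ <- dose(calls$gt_father)
  # a child genotype is Mendelian iff each parent can donate the needed allele
  mendelian <- (dc == 0 & dm <= 1 & df_ <= 1) |
    (dc == 1 & !(dm == 0 & df_ == 0) & !(dm == 2 & df_ == 2)) |
    (dc == 2 & dm >= 1 & df_ >= 1)
  # violations must all be canonical de novos (child het, parents hom-ref)
  viol <- which(!mendelian)
  expect_true(all(dc[viol] == 1 & dm[viol] == 0 & df_[viol] == 0))
  # and each de novo site is carried by exactly one child in the cohort
  expect_true(all(calls$cohort_ac[viol] == 1))
})

test_that("degrading single fixture attributes removes exactly those PPVs", {
  base <- fixture_run(1)$ppv_records
  d <- tempfile()
  overrides <- data.frame(
    id = c("dn_PTEN", "hemi_GLRA2", "mt_5540"),
    field = c("gq_child", "mpc", "proband_pct"),
    value = c("98", "2.0", "4.9"), stringsAsFactors = FALSE)
  simulate_trio_cohort(d, seed = 1,
                       config = sim_config(fixture_overrides = overrides))
  res <- run_cohort(d)
  got <- res$ppv_records
  expect_equal(nrow(got), nrow(base) - 3)
  expect_false(any(got$gene == "PTEN" & got$inheritance == "de_novo",
                   na.rm = TRUE))
  expect_false(any(got$gene == "GLRA2", na.rm = TRUE))
  expect_false(any(got$variant_class == "mito" & got$patient_id == "F05"))
  # everything else is untouched
  key <- function(x) sort(paste(x$patient_id, x$variant_class, x$details))
  dropped <- setdiff(key(base), key(got))
  expect_length(dropped, 3)
})

test_that("fixture configuration errors are caught before writing", {
  expect_error(simulate_trio_cohort(tempfile(), config = sim_config(
    n_trios = 20)), "n_trios")
  expect_error(simulate_trio_cohort(tempfile(), config = sim_config(
    n_trios = 57, n_male_probands = 60)), "n_male")
  expect_error(sim_config(nonsense_knob = 1), "unknown")
})
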