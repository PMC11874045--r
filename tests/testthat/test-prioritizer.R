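# Panel prioritization rules, Fisher exact cross-check and cohort summary.

test_that("de novo PPVs need a panel gene and a protein-altering consequence", {
  cl <- mk_classified(
    list(),                                         # missense, panel -> PPV
    list(conseq_class = "synonymous",
         consequence = "synonymous"),               # excluded
    list(gene = "OFFP"),                            # non-panel gene
    list(gene = NA_character_),                     # unannotated
    list(conseq_class = "qualifying_splice",
         consequence = "intronic", spliceai_delta = 0.75))
  ppv <- prioritize_small_variants(cl, no_pairs, fake_panel)
  expect_equal(nrow(ppv), 2)
  expect_setequal(ppv$details, c("v1", "v5"))
  expect_equal(unique(ppv$rule_fired), "denovo_panel")
})

test_that("hemizygous/homozygous PPVs need PTV-equivalent or MPC > 2", {
  cl <- mk_classified(
    list(label = "hemizygous_maternal", gene = "GLRA2", mpc = 2.4),
    list(label = "hemizygous_maternal", gene = "GLRA2", mpc = 2.0),
    list(label = "homozygous_recessive", conseq_class = "ptv",
         consequence = "stopgain"),
    list(label = "homozygous_recessive", conseq_class = "synonymous",
         consequence = "synonymous"))
  ppv <- prioritize_small_variants(cl, no_pairs, fake_panel)
  expect_equal(nrow(ppv), 2)
  expect_setequal(ppv$rule_fired, c("hemizygous_mpc", "homozygous_ptv"))
})

test_that("variants failing upstream filters never reach a PPV record", {
  cl <- mk_classified(
    list(rarity_pass = FALSE),
    list(label = "uninformative"),
    list(site_pass = FALSE, label = "uninformative"))
  expect_equal(nrow(prioritize_small_variants(cl, no_pairs, fake_panel)), 0)
})

test_that("Fisher exact agrees with hypergeometric enumeration", {
  cases <- list(c(10, 13, 8, 26), c(0, 23, 0, 34), c(5, 5, 5, 5),
                c(1, 0, 0, 1), c(12, 2, 3, 17), c(7, 30, 2, 41))
  for (cs in cases) {
    tab <- matrix(cs, 2, byrow = TRUE)
    expect_equal(stats::fisher.test(tab)$p.value,
                 fisher_oracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-10, info = paste(cs, collapse = ","))
  }
})

test_that("cohort summary counts patients once and stratifies by IDD", {
  path <- tempfile(fileext = ".ped")
  lines <- character(0)
  for (i in 1:6) {
    f <- sprintf("T%02d", i)
    sev <- if (i <= 3) "moderate" else "none"
    lines <- c(lines,
      paste(f, paste0(f, "-F"), 0, 0, 1, 1, ".", sep = "\t"),
      paste(f, paste0(f, "-M"), 0, 0, 2, 1, ".", sep = "\t"),
      paste(f, paste0(f, "-P"), paste0(f, "-F"), paste0(f, "-M"), 1, 2, sev,
            sep = "\t"))
  }
  writeLines(lines, path)
  ped <- read_pedigree(path)
  ppv <- data.frame(
    patient_id = c("T01", "T01", "T04"),
    variant_class = c("smallvar", "mito", "sv"),
    inheritance = "de_novo", gene = "G", rule_fired = "r", details = "d",
    chrom = "chr1", pos = 1, stringsAsFactors = FALSE)
  s <- summarize_cohort(ppv, ped)
  expect_equal(s$n_ppv_records, 3)
  expect_equal(s$n_patients_with_ppv, 2)   # T01 counted once
  expect_equal(s$by_idd$n_idd_with_ppv, 1)
  expect_equal(s$by_idd$n_noidd_with_ppv, 1)
  expect_equal(s$class_breakdown,
               list(smallvar = 1L, sv = 1L, mito = 1L))
  expect_equal(s$comparison_p, fisher_oracle(1, 2, 1, 2), tolerance = 1e-12)
  expect_equal(s$pct_with_ppv, trioppv:::round_half_up(100 * 2 / 6, 1))
})

test_that("zero PPVs give a zeroed summary with p = 1", {
  ped <- one_trio_ped()
  s <- summarize_cohort(trioppv:::.ppv_frame(), ped)
  expect_equal(s$n_ppv_records, 0)
  expect_equal(s$n_patients_with_ppv, 0)
  expect_equal(s$pct_with_ppv, 0)
  expect_equal(s$comparison_p, 1.0)
})

test_that("percentages round half-up to one decimal", {
  expect_equal(trioppv:::round_half_up(100 * 18 / 57, 1), 31.6)
  expect_equal(trioppv:::round_half_up(100 * 10 / 23, 1), 43.5)
  expect_equal(trioppv:::round_half_up(100 * 8 / 34, 1), 23.5)
  expect_equal(trioppv:::round_half_up(0.25, 1), 0.3)  # half goes up
})

test_that("noncoding overlap reports de novo hits in panel-linked CREs only", {
  cre <- GenomicRanges::GRanges(
    c("chr7", "chr7"), IRanges::IRanges(c(114000001, 200000), c(114002000, 201000)),
    linked_gene = c("PTEN", "OFFP"))
  cl <- mk_classified(
    list(chrom = "chr7", pos = 114001000),                       # hit
    list(chrom = "chr7", pos = 200500, label = "inherited_maternal"),
    list(chrom = "chr7", pos = 200500),    # de novo but non-panel CRE
    list(chrom = "chr7", pos = 300000))    # outside any CRE
  res <- noncoding_cre_overlap(cl, cre, fake_panel, trioppv:::.ppv_frame())
  expect_equal(nrow(res$hits), 1)
  expect_equal(res$hits$linked_gene, "PTEN")
  expect_equal(res$n_patients, 1)
  expect_equal(res$n_without_coding_ppv, 1)
})
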