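# QC thresholds, DQ scoring, inheritance labels, rarity, consequence classes
# and compound-het pairing.

test_that("site QC applies depth >= 10 in all members, VQSR and missingness", {
  res <- site_qc(filter_pass = c(TRUE, TRUE, FALSE, TRUE),
                 dp_child = c(10, 9, 30, 30), dp_mother = c(10, 30, 30, 30),
                 dp_father = c(10, 30, 30, 30),
                 gt_child = c("het", "het", "het", "missing"),
                 gt_mother = "hom_ref", gt_father = "hom_ref")
  expect_equal(res$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$reason, c("pass", "depth", "vqsr", "missing_genotype"))
})

test_that("genotype QC enforces the zygosity- and class-specific thresholds", {
  # het SNV boundaries: GQ 99 and AF in [0.3, 0.8)
  res <- genotype_qc(
    gt = c("het", "het", "het", "het", "het"),
    gq = c(99, 98, 99, 99, 99),
    ad_ref = c(11, 10, 14, 4, 0), ad_alt = c(9, 10, 6, 16, 0),
    variant_class = "snv")
  expect_equal(res$pass, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(res$reason[2], "gq")
  expect_equal(res$reason[4], "af")   # AF = 0.8 fails the right-open window
  expect_equal(res$reason[5], "no_reads")
  # AF = 0.3 exactly passes (left-closed)
  expect_true(genotype_qc("het", 99, 14, 6, "snv")$pass)
  # het INDEL relaxes GQ to 90
  expect_true(genotype_qc("het", 90, 10, 10, "indel")$pass)
  expect_false(genotype_qc("het", 89, 10, 10, "indel")$pass)
  # homozygous: GQ >= 25 and AF >= 0.8; hemizygous alt uses the same rule
  expect_true(genotype_qc("hom_alt", 25, 1, 9, "snv")$pass)
  expect_false(genotype_qc("hom_alt", 24, 1, 9, "snv")$pass)
  expect_false(genotype_qc("hom_alt", 99, 3, 9, "snv")$pass)  # AF 0.75
  expect_true(genotype_qc("hemi_alt", 25, 0, 10, "snv")$pass)
  # reference genotypes carry no rule
  expect_true(genotype_qc("hom_ref", 5, 30, 0, "snv")$pass)
})

test_that("DQ equals the 27-configuration enumeration oracle", {
  set.seed(42)
  n <- 1000
  cpl <- matrix(sample(0:300, 3 * n, replace = TRUE), n, 3)
  mpl <- matrix(sample(0:300, 3 * n, replace = TRUE), n, 3)
  fpl <- matrix(sample(0:300, 3 * n, replace = TRUE), n, 3)
  p <- 10^runif(n, -4, -1)
  got <- denovo_quality(cpl, mpl, fpl, mu = 1e-8, p = p)
  want <- vapply(seq_len(n), function(i)
    dq_oracle(cpl[i, ], mpl[i, ], fpl[i, ], 1e-8, p[i]), numeric(1))
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("hemizygous DQ equals its enumeration oracle", {
  set.seed(43)
  n <- 300
  cpl <- matrix(sample(0:300, 2 * n, replace = TRUE), n, 2)
  mpl <- matrix(sample(0:300, 3 * n, replace = TRUE), n, 3)
  fpl <- matrix(sample(0:300, 2 * n, replace = TRUE), n, 2)
  p <- 10^runif(n, -4, -1)
  got <- denovo_quality_hemi(cpl, mpl, fpl, mu = 1e-8, p = p)
  want <- vapply(seq_len(n), function(i)
    dq_oracle_hemi(cpl[i, ], mpl[i, ], fpl[i, ], 1e-8, p[i]), numeric(1))
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("DQ closed form with flat likelihoods, cap, and monotonicity", {
  # all PLs zero: denominator sums to 1, DQ = log10(mu) exactly
  expect_equal(denovo_quality(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
                              mu = 1e-8, p = 1e-3), -8)
  expect_equal(denovo_quality(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
                              mu = 1e-6, p = 0.1),
               log10(1e-6))
  # a confidently hom-ref child scores far below any de novo threshold
  expect_lt(denovo_quality(c(0, 60, 60), c(0, 60, 60), c(0, 60, 60),
                           p = 1e-3), -10)
  # caps engage with extreme likelihoods
  expect_equal(denovo_quality(c(900, 0, 900), c(0, 900, 900), c(0, 900, 900),
                              p = 1e-4), 20)
  expect_equal(denovo_quality(c(0, 900, 900), c(0, 0, 0), c(0, 0, 0),
                              p = 1e-4), -20)
  # raising child het confidence never decreases DQ
  dqs <- vapply(seq(60, 0, by = -10), function(ra)
    denovo_quality(c(120, ra, 300), c(0, 150, 900), c(0, 150, 900),
                   p = 1e-4), numeric(1))
  expect_true(all(diff(dqs) >= -1e-12))
})

test_that("deep well-supported trios cross the DQ >= 7 de novo threshold", {
  expect_gte(denovo_quality(c(750, 0, 750), c(0, 250, 1500), c(0, 250, 1500),
                            p = 1e-4), 7)
  expect_gte(denovo_quality_hemi(c(1500, 0), c(0, 250, 1500), c(0, 1500),
                                 p = 1e-4), 7)
  # shallow parental support does not
  expect_lt(denovo_quality(c(750, 0, 750), c(0, 90, 900), c(0, 90, 900),
                           p = 1e-4), 7)
})

test_that("inheritance labels cover the canonical configurations", {
  lab <- classify_inheritance(
    gt_child = c("het", "hom_alt", "het", "het", "het", "hom_ref"),
    gt_mother = c("hom_ref", "het", "het", "hom_ref", "het", "hom_ref"),
    gt_father = c("hom_ref", "het", "hom_ref", "het", "het", "hom_ref"),
    chrom = "chr1", pos = 1e6, proband_sex = "female",
    dq = c(12, NA, NA, NA, NA, NA))
  expect_equal(lab, c("de_novo", "homozygous_recessive", "inherited_maternal",
                      "inherited_paternal", "inherited_biparental",
                      "uninformative"))
  # below-threshold DQ blocks the de novo label
  expect_equal(classify_inheritance("het", "hom_ref", "hom_ref", "chr1", 1e6,
                                    "male", dq = 6.9), "uninformative")
})

test_that("chrX male labels: hemizygous maternal, de novo, PAR as autosomal", {
  # carrier mother -> maternally inherited hemizygous
  expect_equal(classify_inheritance("hemi_alt", "het", "hemi_ref", "chrX",
                                    14690789, "male", dq = NA),
               "hemizygous_maternal")
  # both parents reference + strong DQ -> de novo
  expect_equal(classify_inheritance("hemi_alt", "hom_ref", "hemi_ref", "chrX",
                                    101412410, "male", dq = 15), "de_novo")
  # female probands never receive hemizygous_maternal
  expect_equal(classify_inheritance("het", "het", "hemi_ref", "chrX",
                                    14690789, "female", dq = NA),
               "inherited_maternal")
  # pseudoautosomal region behaves as autosomal even in males
  expect_equal(classify_inheritance("het", "het", "hom_ref", "chrX",
                                    100000, "male", dq = NA),
               "inherited_maternal")
  expect_error(classify_inheritance("hemi_alt", "het", "hemi_ref", "chrX",
                                    14690789, NA, dq = NA), "sex")
})

test_that("labels partition: each call gets exactly one label", {
  set.seed(7)
  gts <- c("hom_ref", "het", "hom_alt", "missing")
  grid <- expand.grid(c = gts, m = gts, f = gts, stringsAsFactors = FALSE)
  lab <- classify_inheritance(grid$c, grid$m, grid$f, "chr2", 5e7, "female",
                              dq = runif(nrow(grid), -20, 20))
  expect_true(all(lab %in% c("de_novo", "homozygous_recessive",
                             "inherited_maternal", "inherited_paternal",
                             "inherited_biparental", "uninformative")))
  expect_equal(length(lab), nrow(grid))
  # de novo only ever arises from het child with hom-ref parents
  dn <- lab == "de_novo"
  expect_true(all(grid$c[dn] == "het" & grid$m[dn] == "hom_ref" &
                    grid$f[dn] == "hom_ref"))
})

test_that("rarity filter: de novo needs MAF < 0.001 and cohort AC 1", {
  expect_true(rarity_filter("de_novo", 0.0005, NA, 1))
  expect_false(rarity_filter("de_novo", 0.0005, NA, 2))
  expect_false(rarity_filter("de_novo", 0.0011, 0.0002, 1))  # max over sources
  expect_false(rarity_filter("de_novo", 0.001, NA, 1))       # strict <
  expect_true(rarity_filter("inherited_maternal", 0.009, NA, 5))
  expect_false(rarity_filter("inherited_maternal", 0.02, NA, 1))
  expect_true(rarity_filter("homozygous_recessive", NA, NA, 4))  # missing = 0
})

test_that("consequence classes map as specified", {
  expect_equal(classify_consequence("frameshift"), "ptv")
  expect_equal(classify_consequence(c("stopgain", "splice_canonical",
                                      "startloss")),
               rep("ptv", 3))
  expect_equal(classify_consequence("intronic", 0.75), "qualifying_splice")
  expect_equal(classify_consequence("intronic", 0.5), "other")  # strict >
  expect_equal(classify_consequence("missense", 0.9), "missense")
  expect_equal(classify_consequence("synonymous"), "synonymous")
  expect_equal(classify_consequence(NA_character_, NA_real_), "other")
  expect_equal(classify_consequence(NA_character_, 0.8), "qualifying_splice")
})

test_that("compound-het pairing matches the clause truth table", {
  types <- list(
    list(class = "ptv", mpc = NA),
    list(class = "qualifying_splice", mpc = NA),
    list(class = "missense", mpc = 0.5),
    list(class = "missense", mpc = 1.2),
    list(class = "missense", mpc = 2.5),
    list(class = "synonymous", mpc = NA))
  for (a in types) for (b in types) {
    v <- data.frame(
      variant_id = c("m1", "p1"), gene = "G",
      label = c("inherited_maternal", "inherited_paternal"),
      conseq_class = c(a$class, b$class), mpc = c(a$mpc, b$mpc),
      stringsAsFactors = FALSE)
    got <- nrow(find_compound_hets(v)) == 1
    want <- comphet_oracle_qualifies(a$class, a$mpc, b$class, b$mpc)
    expect_equal(got, want,
                 info = paste(a$class, a$mpc, "x", b$class, b$mpc))
  }
})

test_that("compound-het pairs are trans-only, deduplicated, order-invariant", {
  v <- data.frame(
    variant_id = c("a", "b", "c"),
    gene = "G",
    label = c("inherited_maternal", "inherited_maternal",
              "inherited_paternal"),
    conseq_class = c("ptv", "missense", "missense"),
    mpc = c(NA, 1.5, 1.5), stringsAsFactors = FALSE)
  pr <- find_compound_hets(v)
  expect_equal(nrow(pr), 2)          # a-c and b-c; never a-b (cis)
  expect_setequal(pr$maternal_id, c("a", "b"))
  expect_equal(unique(pr$paternal_id), "c")
  # permuting input order yields identical output
  for (perm in list(c(3, 1, 2), c(2, 3, 1))) {
    expect_identical(find_compound_hets(v[perm, ]), pr)
  }
  # two maternal variants alone can never pair
  cis <- v[v$label == "inherited_maternal", ]
  expect_equal(nrow(find_compound_hets(cis)), 0)
})

test_that("the published clause examples fire the expected clause", {
  # maternal missense MPC 2.3 + paternal frameshift: the one-PTV clause
  v <- data.frame(variant_id = c("m", "p"), gene = "HLCS",
                  label = c("inherited_maternal", "inherited_paternal"),
                  conseq_class = c("missense", "ptv"), mpc = c(2.3, NA),
                  stringsAsFactors = FALSE)
  expect_equal(find_compound_hets(v)$clause, "one_ptv_or_mpc_gt2")
  # two missense MPC 1.2/1.5 in trans: the both-MPC>1 clause
  v$conseq_class <- c("missense", "missense"); v$mpc <- c(1.2, 1.5)
  expect_equal(find_compound_hets(v)$clause, "both_ptv_or_mpc_gt1")
  # MPC exactly 2.0 with a weak partner is rejected (strict >)
  v$mpc <- c(2.0, 0.4)
  expect_equal(nrow(find_compound_hets(v)), 0)
})
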