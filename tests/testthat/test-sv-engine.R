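# CNV thresholds, dual-caller consensus, pooling, SV inheritance, rarity and
# exonic overlap.

test_that("CNV calling applies inclusive log2 thresholds and merges gaps", {
  seg <- data.frame(
    sample_id = "S1", chrom = "chr1",
    start = c(1e6, 2e6, 3e6, 4e6, 4.03e6),
    end = c(1.5e6, 2.5e6, 3.5e6, 4.02e6, 4.05e6),
    log2 = c(-0.7, -0.5, 0.4, -0.65, -0.62))
  out <- cnv_from_log2(seg, config = trioppv_config(merge_gap = 20000))
  expect_setequal(out$calls$sv_type, c("DEL", "DUP", "DEL"))
  # -0.5 makes no call; 0.4 is an inclusive DUP boundary
  expect_false(any(out$calls$start == 2e6))
  expect_true(any(out$calls$sv_type == "DUP" & out$calls$start == 3e6))
  # the two adjacent DEL segments 10 kb apart merged into one call
  merged <- out$calls[out$calls$start == 4e6, ]
  expect_equal(merged$end, 4.05e6)
  # deep deletions genotype as homozygous
  hom <- cnv_from_log2(data.frame(sample_id = "S1", chrom = "chr2",
                                  start = 1e6, end = 2e6, log2 = -3.2))
  expect_equal(unname(hom$geno[1, "S1"]), "hom_alt")
})

test_that("consensus keeps PASS(+PRECISE) mutual calls, one-to-one", {
  a <- make_sv_calls(data.frame(
    sv_type = c("DEL", "DEL", "DUP", "DEL"),
    chrom = c("chr1", "chr2", "chr3", "chr4"),
    start = c(1e6, 1e6, 1e6, 1e6),
    end = c(1.1e6, 1.1e6, 1.1e6, 1.1e6),
    filter_pass = c(TRUE, TRUE, TRUE, FALSE)), samples = "S1")
  b <- make_sv_calls(data.frame(
    sv_type = c("DEL", "DEL", "DUP", "DEL"),
    chrom = c("chr1", "chr2", "chr3", "chr4"),
    start = c(1.0005e6, 1.06e6, 1e6, 1e6),
    end = c(1.1005e6, 1.16e6, 1.1e6, 1.1e6),
    precise = c(TRUE, FALSE, TRUE, TRUE)), samples = "S1")
  cons <- consensus_intersect(a, b)
  # chr1 matches; chr2 excluded (imprecise B); chr4 excluded (A failed filter)
  expect_setequal(cons$calls$chrom, c("chr1", "chr3"))
  # merged coordinates are the interval union
  expect_equal(cons$calls$end[cons$calls$chrom == "chr1"], 1.1005e6)
})

# independent interval arithmetic (coarse per-base grid scan)
reciprocal_overlap_ref <- function(s1, e1, s2, e2) {
  grid <- seq(min(s1, s2), max(e1, e2), by = 37)
  in1 <- grid >= s1 & grid <= e1
  in2 <- grid >= s2 & grid <= e2
  min(sum(in1 & in2) / sum(in1), sum(in1 & in2) / sum(in2))
}

test_that("40% reciprocal overlap does not match; identical calls do", {
  mk <- function(s2, e2) {
    a <- make_sv_calls(data.frame(sv_type = "DEL", chrom = "chr1",
                                  start = 1e6, end = 1e6 + 99999),
                       samples = "S1")
    b <- make_sv_calls(data.frame(sv_type = "DEL", chrom = "chr1",
                                  start = s2, end = e2), samples = "S1")
    nrow(consensus_intersect(a, b)$calls)
  }
  # 40% shared (40000/100000): below the 0.5 criterion
  expect_lt(reciprocal_overlap_ref(1e6, 1e6 + 99999,
                                   1e6 + 60000, 1e6 + 159999), 0.5)
  expect_equal(mk(1e6 + 60000, 1e6 + 159999), 0)
  # 60% shared: matches
  expect_equal(mk(1e6 + 40000, 1e6 + 139999), 1)
  # identical intervals: matches
  expect_equal(mk(1e6, 1e6 + 99999), 1)
})

test_that("reciprocal overlap agrees with a subsampled per-base oracle", {
  set.seed(11)
  for (k in 1:25) {
    s1 <- sample(1e5, 1); e1 <- s1 + sample(5e4, 1)
    s2 <- s1 + sample(-3e4:3e4, 1); e2 <- s2 + sample(5e4, 1)
    got <- trioppv:::reciprocal_overlap(s1, e1, s2, e2)
    # brute-force on a coarse grid; tolerance reflects the grid
    ref <- reciprocal_overlap_ref(s1, e1, s2, e2)
    expect_lt(abs(got - ref), 0.02)
  }
})

test_that("matching is a partial injection bounded by the gated set sizes", {
  set.seed(5)
  mkset <- function(n) {
    make_sv_calls(data.frame(
      sv_type = sample(c("DEL", "DUP"), n, TRUE),
      chrom = sample(c("chr1", "chr2"), n, TRUE),
      start = st <- sample(1e6, n) * 10,
      end = st + sample(2e4:8e4, n, TRUE),
      filter_pass = runif(n) > 0.1,
      precise = runif(n) > 0.2), samples = "S1")
  }
  for (rep in 1:5) {
    a <- mkset(30); b <- mkset(30)
    cons <- consensus_intersect(a, b)
    n_a <- sum(a$calls$filter_pass)
    n_b <- sum(b$calls$filter_pass & b$calls$precise)
    expect_lte(nrow(cons$calls), min(n_a, n_b))
    expect_false(any(duplicated(cons$calls$a_index)))
    expect_false(any(duplicated(cons$calls$b_index)))
  }
})

test_that("SV trio inheritance labels match the case-report configurations", {
  ped <- rbind(one_trio_ped("male", "F01"))
  calls <- data.frame(
    sv_type = "DEL",
    chrom = c("chr15", "chrX", "chr15"),
    start = c(30500000, 154743001, 40000000),
    end = c(30711999, 154755000, 40010000))
  geno <- matrix("hom_ref", 3, 3,
                 dimnames = list(NULL, c("F01-P", "F01-M", "F01-F")))
  geno[1, ] <- c("hom_alt", "het", "het")       # homozygous recessive
  geno[2, ] <- c("hemi_alt", "het", "hemi_ref") # hemizygous maternal
  geno[3, ] <- c("hom_ref", "het", "hom_ref")   # child non-carrier
  svset <- make_sv_calls(calls, geno = geno)
  lab <- classify_sv_inheritance(svset, ped)
  expect_equal(nrow(lab), 2)  # child-reference calls are not emitted
  expect_equal(lab$label[lab$chrom == "chr15"], "homozygous_recessive")
  expect_equal(lab$label[lab$chrom == "chrX"], "hemizygous_maternal")
})

test_that("SV rarity: hom-recessive < 0.2; others < 0.01 and singleton", {
  expect_true(sv_rarity_filter("homozygous_recessive", 0.15, 3))
  expect_false(sv_rarity_filter("homozygous_recessive", 0.25, 1))
  expect_false(sv_rarity_filter("de_novo", 0.02, 1))
  expect_true(sv_rarity_filter("de_novo", 0.005, 1))
  expect_false(sv_rarity_filter("de_novo", 0.005, 2))   # not a singleton
  expect_true(sv_rarity_filter("hemizygous_maternal", NA, 1))  # missing = 0
})

test_that("exonic overlap agrees with a per-base scan on toy genomes", {
  set.seed(21)
  for (rep in 1:10) {
    n_ex <- 12
    exon_df <- data.frame(
      gene = sample(paste0("G", 1:4), n_ex, TRUE),
      chrom = sample(c("chrA", "chrB"), n_ex, TRUE),
      start = st <- sample(1e5, n_ex))
    exon_df$end <- st + sample(50:500, n_ex, TRUE)
    ex <- GenomicRanges::GRanges(
      exon_df$chrom, IRanges::IRanges(exon_df$start, exon_df$end),
      gene_symbol = exon_df$gene, is_asd_idd = TRUE)
    calls <- data.frame(
      sv_type = "DEL", chrom = sample(c("chrA", "chrB"), 5, TRUE),
      start = s <- sample(1e5, 5), end = s + sample(100:5000, 5, TRUE),
      chrom2 = NA_character_, pos2 = NA_real_)
    got <- exonic_gene_overlap(calls, ex)
    for (i in seq_len(nrow(calls))) {
      want <- overlap_oracle(calls$chrom[i], calls$start[i], calls$end[i],
                             exon_df)
      expect_equal(got[[i]], want)
    }
  }
})

test_that("an SV entirely intronic within a panel gene reports no overlap", {
  ex <- GenomicRanges::GRanges("chr5",
                               IRanges::IRanges(c(1000, 9000), c(1200, 9200)),
                               gene_symbol = "G1", is_asd_idd = TRUE)
  calls <- data.frame(sv_type = "DEL", chrom = "chr5", start = 2000,
                      end = 8000, chrom2 = NA_character_, pos2 = NA_real_)
  expect_equal(exonic_gene_overlap(calls, ex)[[1]], character(0))
})

test_that("pooling drops CNV calls matching a consensus call", {
  cons <- make_sv_calls(data.frame(sv_type = "DEL", chrom = "chr15",
                                   start = 30500000, end = 30711999),
                        samples = "S1")
  cnv <- make_sv_calls(data.frame(
    sv_type = c("DEL", "DUP"), chrom = c("chr15", "chr2"),
    start = c(30500500, 5e6), end = c(30711500, 5.1e6), caller = "cnv"),
    samples = "S1")
  pooled <- pool_sv_calls(cons, cnv)
  expect_equal(nrow(pooled$calls), 2)
  expect_setequal(pooled$calls$caller, c("x", "cnv"))
  expect_false(any(pooled$calls$chrom == "chr15" &
                     pooled$calls$caller == "cnv"))
})

test_that("SV VCF reading: symbolic ALTs, PRECISE flags, BND translocations", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>", "##contig=<ID=chr2>",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"i\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"m\">",
    "##FILTER=<ID=PASS,Description=\"ok\">",
    "##FILTER=<ID=LowQual,Description=\"lq\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t1000\t.\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL;END=213000;MAF=0.15\tGT\t0/1",
    "chr1\t5000\t.\tN\t<DUP>\t60\tPASS\tSVTYPE=DUP;END=9000;IMPRECISE\tGT\t0/1",
    "chr2\t7000\t.\tN\tN[chr1:9000[\t60\tPASS\tSVTYPE=BND\tGT\t0/1",
    "chr2\t8000\t.\tN\t<INV>\t60\tLowQual\tSVTYPE=INV;END=9000\tGT\t0/0"), path)
  sv <- read_sv_calls(path, "manta")
  expect_equal(sv$calls$sv_type, c("DEL", "DUP", "TRA", "INV"))
  # the 212-kb deletion spans the reported interval
  expect_equal(sv$calls$end[1] - sv$calls$start[1] + 1, 212001)
  expect_equal(sv$calls$precise, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(sv$calls$filter_pass, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(sv$calls$maf[1], 0.15)
  expect_equal(sv$calls$chrom2[3], "chr1")
  expect_equal(sv$calls$pos2[3], 9000)
  expect_equal(unname(sv$geno[1, "S1"]), "het")
})
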