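# Reading the multi-sample VCF and its annotation sidecar.

write_tiny_vcf <- function(path, body, samples = c("FA-P", "FA-M", "FA-F")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>", "##contig=<ID=chr10>", "##contig=<ID=chrX>",
    "##FILTER=<ID=PASS,Description=\"ok\">",
    "##FILTER=<ID=VQSRTrancheSNP99.90to100.00,Description=\"fail\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=AD,Number=.,Type=Integer,Description=\"ad\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"pl\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body), path)
  path
}

write_tiny_annot <- function(path, rows) {
  writeLines(c(paste("chrom", "pos", "ref", "alt", "gene", "consequence",
                     "mpc", "spliceai_delta", "maf_gnomad_eas", "maf_tommo",
                     "clinvar", sep = "\t"), rows), path)
  path
}

test_that("VCF genotype fields round-trip exactly and annotation joins", {
  vcf <- write_tiny_vcf(tempfile(fileext = ".vcf"), c(
    "chr10\t87961051\t.\tT\tC\t500\tPASS\t.\tGT:GQ:DP:AD:PL\t0/1:99:50:25,25:750,0,750\t0/0:99:48:48,0:0,240,1440\t0/0:97:46:46,0:0,230,1380",
    "chr1\t1000\t.\tG\tA,T\t500\tPASS\t.\tGT:GQ:DP:AD:PL\t0/0:99:30:30,0,0:0,90,900,90,900,900\t0/0:99:30:30,0,0:0,90,900,90,900,900\t0/0:99:30:30,0,0:0,90,900,90,900,900",
    "chr1\t2000\t.\tC\tG\t500\tPASS\t.\tGT:GQ:DP:AD:PL\t0/1:99:40:20,20:600,0,600\t0/1:99:40:21,19:570,0,630\t0/0:99:40:40,0:0,200,1200"))
  annot <- write_tiny_annot(tempfile(fileext = ".tsv"),
    "chr10\t87961051\tT\tC\tPTEN\tmissense\t2.8\tNA\t0\t0\tNA")
  ped <- one_trio_ped(fam = "FA")
  calls <- read_small_variants(vcf, annot, ped)

  # multi-allelic row excluded, counted
  expect_equal(attr(calls, "n_records_total"), 3)
  expect_equal(attr(calls, "n_multiallelic"), 1)
  expect_equal(attr(calls, "n_sites_kept") + attr(calls, "n_multiallelic"),
               attr(calls, "n_records_total"))

  ptn <- calls[calls$pos == 87961051, ]
  expect_equal(nrow(ptn), 1)
  expect_equal(ptn$gene, "PTEN")
  expect_equal(ptn$gt_child, "het")
  expect_equal(c(ptn$ad_ref_child, ptn$ad_alt_child), c(25, 25))
  expect_equal(c(ptn$pl1_child, ptn$pl2_child, ptn$pl3_child), c(750, 0, 750))
  expect_equal(ptn$gq_father, 97)
  expect_equal(ptn$dp_mother, 48)
  expect_equal(ptn$cohort_ac, 1)

  # record with no annotation row keeps explicit missing markers
  anon <- calls[calls$pos == 2000, ]
  expect_true(is.na(anon$gene) && is.na(anon$consequence))
  expect_equal(anon$cohort_ac, 2)
})

test_that("pedigree samples absent from the VCF header are an error", {
  vcf <- write_tiny_vcf(tempfile(fileext = ".vcf"),
    "chr1\t2000\t.\tC\tG\t500\tPASS\t.\tGT:GQ:DP:AD:PL\t0/1:99:40:20,20:600,0,600\t0/0:99:40:40,0:0,200,1200\t0/0:99:40:40,0:0,200,1200",
    samples = c("FA-P", "FA-M", "OTHER"))
  annot <- write_tiny_annot(tempfile(fileext = ".tsv"), character(0))
  expect_error(read_small_variants(vcf, annot, one_trio_ped(fam = "FA")),
               "absent from VCF header")
})

test_that("annotation key collisions are an error", {
  vcf <- write_tiny_vcf(tempfile(fileext = ".vcf"),
    "chr1\t2000\t.\tC\tG\t500\tPASS\t.\tGT:GQ:DP:AD:PL\t0/1:99:40:20,20:600,0,600\t0/0:99:40:40,0:0,200,1200\t0/0:99:40:40,0:0,200,1200")
  annot <- write_tiny_annot(tempfile(fileext = ".tsv"), c(
    "chr1\t2000\tC\tG\tAAA\tmissense\t1\tNA\t0\t0\tNA",
    "chr1\t2000\tC\tG\tBBB\tmissense\t1\tNA\t0\t0\tNA"))
  expect_error(read_small_variants(vcf, annot, one_trio_ped(fam = "FA")),
               "collision")
})

test_that("haploid chrX male calls parse as hemizygous with 2-entry PL", {
  vcf <- write_tiny_vcf(tempfile(fileext = ".vcf"),
    "chrX\t14690789\t.\tC\tT\t500\tPASS\t.\tGT:GQ:DP:AD:PL\t1:99:50:0,50:1500,0\t0/1:99:50:25,25:750,0,750\t0:99:50:50,0:0,1500")
  annot <- write_tiny_annot(tempfile(fileext = ".tsv"),
    "chrX\t14690789\tC\tT\tGLRA2\tmissense\t2.4\tNA\t0.003\t0.003\tNA")
  calls <- read_small_variants(vcf, annot, one_trio_ped(fam = "FA"))
  expect_equal(calls$gt_child, "hemi_alt")
  expect_equal(calls$gt_father, "hemi_ref")
  expect_equal(calls$gt_mother, "het")
  expect_true(is.na(calls$pl3_child))
  expect_equal(c(calls$pl1_child, calls$pl2_child), c(1500, 0))
})
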