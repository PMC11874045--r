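# trioppv

Trio whole-genome variant prioritization for neurodevelopmental cohorts.

`trioppv` is an R package for geneticists analyzing parent–offspring trios in
autism spectrum disorder / intellectual developmental disorder (ASD/IDD)
cohorts. Starting from caller outputs — a jointly genotyped multi-sample VCF
with an annotation sidecar, two structural-variant (SV) call sets, CNV
log2-ratio segments, a chrM VCF, and a repeat-motif count profile — it
classifies every variant's trio inheritance, applies inheritance-stratified
prioritization rules against an ASD/IDD gene panel, and reports potentially
pathogenic variants (PPVs) per patient with cohort-level summaries.

## The model in brief

* **Site/genotype QC** — bi-allelic VQSR-pass sites with DP ≥ 10 in all
  members; het SNVs at GQ ≥ 99 and 0.3 ≤ AF < 0.8, het INDELs at GQ ≥ 90,
  hom/hemizygous calls at GQ ≥ 25 and AF ≥ 0.8.
* **De novo scoring** — a log10 Bayes factor over genotype likelihoods,

  DQ = log10[ μ·L_m(RR)·L_f(RR)·L_c(RA) ] −
  log10[ Σ_{g_m,g_f} π(g_m)π(g_f) Σ_{g_c} T(g_c|g_m,g_f)·L_m·L_f·L_c ],

  with Hardy–Weinberg priors π at p = max(MAF, 1e−4), Mendelian transmission
  T, μ = 1e−8, capped to ±20; de novo calls require DQ ≥ 7. A haploid variant
  of the score handles chrX in male probands.
* **Rarity** — de novo: MAF < 0.001 and cohort singleton; inherited:
  MAF < 0.01 (MAF = max over gnomAD-EAS and ToMMo).
* **Prioritization** — de novo protein-altering variants in panel genes;
  homozygous-recessive / maternally inherited hemizygous variants that are
  PTV-equivalent or missense with MPC > 2; compound-het pairs in trans where
  one member is PTV-equivalent or MPC > 2, or both are PTV-equivalent or
  MPC > 1; consensus SVs (reciprocal overlap ≥ 0.5 between a PASS caller and
  a PASS+PRECISE caller, pooled with CNV log2 calls at −0.6/0.4) overlapping
  panel exons; known-pathogenic chrM variants above 5% heteroplasmy; repeat
  expansion outliers at leave-one-out z > 10.
* **Noncoding** — de novo SNVs in fetal brain cis-regulatory elements linked
  to panel genes are reported separately, never counted as PPVs.

See `vignette("trioppv-methods")` for assumptions, parameter rationale and
limitations.

## Worked example

The package ships a deterministic synthetic-cohort generator that emits the
complete input file set — 57 trios with the published cohort structure and
the published case variants planted as ground truth:

```r
library(trioppv)

dir <- file.path(tempdir(), "cohort")
sim <- simulate_trio_cohort(dir, seed = 1)
p <- sim$paths
res <- run_trio_pipeline(
  ped = p$ped, vcf = p$vcf, annot = p$annot, sv_a = p$sv_a, sv_b = p$sv_b,
  cnv = p$cnv, mito = p$mito, mito_pathogenic = p$mito_pathogenic,
  panel = p$panel, cre = p$cre, str_profile = p$str_profile,
  out_dir = file.path(dir, "report"))
print(res)
```

```
trioppv pipeline result
  small-variant records: 5686 kept (8 multi-allelic excluded of 5694)
Cohort summary
  patients: 57
  PPV records: 23 (smallvar 19, sv 2, mito 2)
  patients with >=1 PPV: 18 (31.6%)
  with IDD: 10/23 (43.5%); without IDD: 8/34 (23.5%); Fisher p = 0.1497
  de novo CRE hits: 8 in 8 patients (6 without coding PPV)
  repeat outlier flags: 0 (0 at known STR loci)
  inherited panel-gene SV findings: 2
```

Reading the output: of 57 patients, 18 (31.6%) carry at least one of 23 PPV
records — 19 SNVs/INDELs (12 de novo, 6 compound-het pairs, 1 maternally
inherited hemizygous), 2 SVs (a homozygous 212-kb deletion covering
ARHGAP11B, a hemizygous TMLHE exon-2 deletion) and 2 mitochondrial variants
(a 6.7%-load de novo m.5540G>A, a maternal m.14674T>C homoplasmy). The yield
is higher in patients with comorbid IDD (43.5% vs 23.5%; two-sided Fisher
exact p = 0.15). Eight de novo SNVs fall in fetal-brain regulatory elements
of panel genes, six of them in patients with no coding PPV; the repeat screen
is negative; two inherited panel-gene duplications (RHEB, NF1) are reported
outside the PPV tally. `run_trio_pipeline(..., out_dir =)` writes
`ppv_records.tsv`, `inherited_findings.tsv`, `noncoding_hits.tsv` and
`cohort_summary.json`.

A thin CLI wraps the same functions:

```sh
exec/trioppv simulate --seed 1 --out cohort/
exec/trioppv run --ped cohort/cohort.ped ... --out report/
exec/trioppv summarize --out report/
```

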