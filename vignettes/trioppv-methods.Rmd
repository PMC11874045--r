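---
title: "Methods: trio WGS variant prioritization in trioppv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio WGS variant prioritization in trioppv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`trioppv` implements a trio-based prioritization pipeline for rare,
potentially pathogenic variants (PPVs) in whole-genome data from
parent–offspring trios, of the kind used in clinical-genetics studies of
autism spectrum disorder (ASD) and intellectual developmental disorder (IDD).
The pipeline consumes caller *outputs* — a jointly genotyped multi-sample VCF
with an annotation sidecar, two structural-variant (SV) call sets, CNV
log2-ratio segments, a chrM VCF, and a repeat-motif count profile — and owns
everything downstream: quality control, de novo scoring, inheritance
classification, rarity filtering, consensus logic, the panel-based
prioritization rules, and cohort summarization. Read alignment, variant
calling, VQSR and annotation generation are out of scope by design; their
file formats are the interface.

## Small variants

A site enters the analysis only if it is bi-allelic (multi-allelic records
are dropped, not decomposed, and counted), passed VQSR, and has depth
$\mathrm{DP} \ge 10$ in all three trio members. Carrier genotypes must then
individually satisfy zygosity-specific thresholds: heterozygous SNVs need
$\mathrm{GQ} \ge 99$ and allele fraction $0.3 \le \mathrm{AF} < 0.8$
(right-open), heterozygous INDELs relax GQ to $\ge 90$, homozygous and
hemizygous alternate calls need $\mathrm{GQ} \ge 25$ and
$\mathrm{AF} \ge 0.8$. AF is computed from allele depths,
$\mathrm{AD}_{alt}/(\mathrm{AD}_{ref}+\mathrm{AD}_{alt})$. Boundary behavior
(which side of each inequality is closed) is pinned by unit tests.

### De novo quality (DQ)

De novo candidacy is decided by a single fully specified score rather than an
intersection of external callers. DQ is the log10 Bayes factor of the
canonical de novo configuration against the full Mendelian model:

$$
\mathrm{DQ} \;=\; \log_{10}\frac{\mu\, L_m(RR)\,L_f(RR)\,L_c(RA)}
{\sum_{g_m,g_f} \pi(g_m)\,\pi(g_f) \sum_{g_c} T(g_c \mid g_m,g_f)\,
L_m(g_m)\,L_f(g_f)\,L_c(g_c)}
$$

with likelihoods $L = 10^{-\mathrm{PL}/10}$ from PLs normalized to minimum 0,
Hardy–Weinberg priors $\pi$ at population frequency
$p = \max(\mathrm{MAF}, 10^{-4})$, Mendelian transmission table $T$, mutation
prior $\mu = 10^{-8}$, and the result capped to $[-20, 20]$. A variant is de
novo when the child is heterozygous, both parents are homozygous reference,
and $\mathrm{DQ} \ge 7$.

Two properties of this model matter in practice. First, it is strict: with
$\mu = 10^{-8}$, crossing $\mathrm{DQ} \ge 7$ requires strong parental
evidence against carriership (roughly $\mathrm{PL}(RA) \gtrsim 115$ in each
parent at $p = 10^{-4}$), which deep, well-genotyped trios provide but
marginal ones do not — that strictness is the point of the threshold. Second,
it is oracle-checkable: the test suite verifies the vectorized implementation
against an independent 27-configuration enumeration to within $10^{-9}$ on
the log10 scale, plus a closed form at flat likelihoods
($\mathrm{DQ} = \log_{10}\mu$) and a monotonicity property (raising child
heterozygous confidence never lowers DQ).

For chrX in male probands (outside the pseudoautosomal regions, which are
treated as autosomal), child and father are haploid. The same Bayes factor is
computed with a haploid child transmitting only the maternal allele and a
haploid Hardy–Weinberg prior for the father. This extension is needed because
X-linked de novo missense variants in male probands are a real and reportable
category; it is tested against its own enumeration oracle.

### Inheritance, rarity, consequence

Each (variant, trio) pair receives exactly one label: `de_novo`,
`homozygous_recessive` (child homozygous-alternate, both parents
heterozygous), `hemizygous_maternal` (male proband, non-PAR chrX, carrier
mother), `inherited_maternal`/`inherited_paternal` (exactly one carrier
parent), `inherited_biparental`, or `uninformative`. A label that depends on
a member whose carrier genotype failed QC is downgraded to `uninformative` —
this is what keeps near-threshold artifacts (e.g. a GQ 98 heterozygote) out
of every downstream stage.

The population MAF is the maximum over the two population sources (gnomAD
East Asian and ToMMo), with a missing source contributing 0 — conservative in
the sense of filtering more aggressively. De novo variants must have
MAF < 0.001 *and* be cohort singletons (allele count 1 across all cohort
members; the singleton rule is interpreted within the analysis cohort, since
the database frequency is filtered separately). All other labels require
MAF < 0.01.

Consequences reduce to five classes: PTV (stopgain, frameshift, canonical
splice, startloss), qualifying splice (SpliceAI delta strictly above 0.5 on a
non-coding annotation), missense, synonymous, other.

### Compound heterozygotes

Pairs are phased by parental transmission only: one variant inherited from
each parent, same gene, both surviving QC and the inherited rarity filter.
A pair qualifies when (a) at least one member is a PTV-equivalent or a
missense variant with MPC > 2, or (b) both members are PTV-equivalents or
missense variants with MPC > 1. `trioppv` counts SpliceAI-qualifying splice
variants as PTV-equivalents in these clauses: splice-disrupting intronic
variants are reported in published compound-heterozygous findings (an
intronic splice variant paired with a missense variant), and a clause set
restricted to literal PTV annotations could never produce such a pair. The
full clause truth table is verified against an independently written oracle.

## Structural variants

CNV segments call a deletion at log2 ratio $\le -0.6$ and a duplication at
$\ge 0.4$ (both inclusive; the published thresholds do not specify equality,
so the inclusive convention was fixed here and test-pinned). Same-type
segments of one sample closer than `merge_gap` (1 kb) merge. A deletion at
log2 $\le -1.5$ or duplication at $\ge 0.85$ is genotyped homozygous —
roughly the expected ratios for 0 of 2 and 4 of 2 copies with noise.

The two SV callers are reconciled exactly as their quality flags suggest:
caller A contributes FILTER-PASS calls, caller B PASS *and* PRECISE calls,
and mutual calls are extracted. "Mutual" is operationalized as same type and
chromosome with reciprocal overlap $\ge 0.5$ (breakend distance
$\le 500$ bp for insertions/translocations), matched one-to-one greedily by
descending overlap — standard SV-merging practice, exposed in the
configuration since the published description does not fix the criterion.
Consensus coordinates are the interval union; trio genotypes come from the
caller-A record (a deterministic choice). CNV-derived calls are pooled with
the consensus set and deduplicated by the same matching criterion, with the
consensus record (breakpoint-resolved) winning.

SV rarity mirrors the small-variant logic with SV-specific bounds:
homozygous-recessive events pass below MAF 0.2; everything else needs
MAF < 0.01 and must be carried by exactly one family. Prioritized SVs must
overlap (by at least one base) an exon of an ASD/IDD panel gene and be de
novo, homozygous recessive, or maternally inherited hemizygous. Inherited
panel-gene SVs are real findings but not PPVs; they are reported in a
separate inherited-findings table.

## Mitochondrial variants

Heteroplasmy is $100 \cdot \mathrm{AD}_{alt} /
(\mathrm{AD}_{ref}+\mathrm{AD}_{alt})$, reported to 0.1%. A record is
reportable when it is a known pathogenic variant (ClinVar-style table) and
the proband's load strictly exceeds 5%. Inheritance is decided against the
same threshold on the maternal side: maternal load below 5% means de novo
(flagged when it is nonzero — heteroplasmy detection floors make a strict 0%
requirement unrealistic), at or above 5% means maternally inherited. Missing
maternal depths give a reportable record with unknown inheritance. Paternal
chrM genotypes are ignored.

## Repeat expansions

The engine starts from a motif-count profile (samples × (motif, region)
columns). For each column the score is a leave-one-out z:
$z_i = (x_i - \bar{x}_{-i}) / s_{-i}$, flagged when strictly above 10.
Whether the published outlier statistic pooled or left out the tested sample
is not stated; leave-one-out was chosen because it does not let a single
extreme carrier inflate its own null. Zero-variance columns and columns with
fewer than 3 samples yield no flags. Flags are annotated against ten known
ASD-associated STR loci (packaged with approximate synthetic coordinates).

## Noncoding regulatory elements

Final de novo small variants falling inside a fetal brain-specific
cis-regulatory element (b-CRE) linked to an ASD/IDD panel gene are reported —
never counted as PPVs — together with how many distinct patients carry a hit
and how many of those have no coding PPV.

## Cohort summary

Patients are counted once regardless of PPV multiplicity. The IDD
stratification counts borderline intellectual functioning as non-IDD: that is
the standard clinical convention (IDD requires deficits roughly below IQ 70),
and it is the only reading under which the published per-stratum carrier
counts are internally consistent. The IDD × carrier comparison uses a
two-sided Fisher exact test (cross-checked in the tests against a
hypergeometric enumeration); the test used for the originally published
p-value is not identified, so that number is not treated as a reference.
Percentages are rounded half-up to one decimal.

# The synthetic cohort

Because the study's raw genomes are not redistributable, the package ships a
generator (`simulate_trio_cohort()`) that emits the complete file set with
the cohort's published structure: 57 trios, 44 male probands, 23 probands
with comorbid IDD, an expected 72 de novo small variants per genome
(Poisson per trio), and mean depth 35×. Background inherited variation is
drawn per site from Hardy–Weinberg parental genotypes at frequencies
$q \sim 10^{U(-4,-0.6)}$ with children genotyped by Mendelian transmission;
PLs follow an idealized caller model (~30 phred per discordant read, 5 phred
per concordant read against the heterozygous hypothesis), so clean deep
trios score DQ well above threshold and shallow ones do not. About 5% of
background carrier genotypes are given marginal GQ and ~15% of background
sites lack an annotation row, exercising the QC and missing-annotation
paths. Multi-allelic and VQSR-failed records are planted to exercise the
exclusion tallies.

Background variation is constrained to non-panel genes and intergenic space,
so the planted case variants are provably the only PPV sources; this is what
makes the recovery tests sharp. The planted truth comprises the published
case tables: 12 de novo small variants (two of them X-linked in male
probands), 6 compound-heterozygous pairs placed in trans, 1 maternally
inherited hemizygous missense variant, a homozygous 212-kb deletion covering
ARHGAP11B with both parents heterozygous, a hemizygous 12-kb deletion
covering TMLHE exon 2, maternally/paternally inherited RHEB and NF1
duplications (inherited findings, not PPVs), two pathogenic mitochondrial
variants (6.7% de novo load; maternal homoplasmy), and 8 de novo SNVs inside
b-CREs of eight panel genes, six of them in patients with no coding PPV.
Attributes the case tables do not print — MPC values, population MAFs, PLs,
read counts — are synthesized minimally past the relevant thresholds and
recorded in a provenance column of the emitted truth table. Coordinates are
real hg38 positions taken verbatim from the case tables; synthetic background
features are placed in coordinate bands chosen to be disjoint from every
fixture feature.

What the generator does *not* emulate: linkage disequilibrium, mutation
spectra, sequencing-error structure, population substructure, pedigree
errors, or read-level evidence. Passing the recovery tests therefore
demonstrates that the decision logic is faithful and leak-proof under the
assumed genotype model — not that the thresholds would achieve any particular
sensitivity/specificity on real genomes.

Problem sizes were chosen to keep a full simulate-plus-run cycle under about
a minute on one CPU: 1,500 background inherited sites, ~4,100 de novo
background variants (72 per genome — the published per-genome rate), 24
background SVs, 10 background CNVs, 8 background chrM sites, and a 57 × 24
repeat-count profile. All generation is deterministic given the seed; the
same seed reproduces byte-identical files.

# Numerical and degenerate-input choices

* PLs are re-normalized to minimum 0 before likelihood conversion; when all
  PLs are 0 the GT field is trusted for labeling while DQ is still computed
  (and equals $\log_{10}\mu$ minus the Mendelian normalizer).
* Zero-depth genotypes fail QC with an explicit `no_reads` reason; zero-depth
  chrM records are flagged unusable rather than dividing by zero.
* Ties in consensus matching are broken by leftmost start after the overlap
  criterion; matching is a partial injection (no call is used twice).
* Empty inputs (empty PED, empty BED, zero PPVs) produce structurally valid
  zeroed outputs, with Fisher p fixed at 1 when there are no carriers.
* Report rows are sorted by patient, chromosome and position, making reports
  byte-identical under permutation of the input.

# Known limitations

* The DQ model scores only the canonical de novo configuration; germline
  mosaicism, multi-nucleotide events and de novo INDEL realignment artifacts
  are outside its scope.
* Compound-het phasing uses parental transmission only; two variants both
  transmitted by the same parent are (correctly) never paired, but true
  trans pairs with one untransmitted allele unobserved in a parent are
  missed.
* SV genotypes are taken from caller A's record on consensus calls; caller
  disagreement on genotype is not modeled.
* The mitochondrial de novo definition (maternal load below the reporting
  threshold) is an operational choice; ultra-low-level maternal heteroplasmy
  below detection cannot be excluded.
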