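---
title: "Models and methods behind clonemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonemap)
```

# The scientific setting

Multifocal small-intestinal neuroendocrine tumors present a peculiar
genomics problem: a single patient can carry two to eighteen synchronous
primary tumors with a very low somatic mutation rate (on the order of
0.4 mutations/Mb), few recurrent drivers, and one dominant copy-number
event — loss of one entire copy of chr18 — present in over half of tumors.
Three questions structure the downstream analysis this package implements:

1. **Independence of primaries.** If synchronous primaries are clonal
   outgrowths of one ancestor they must share somatic variants; if they
   arise independently from normal mucosa they share essentially none.
2. **Metastasis seeding.** A metastasis inherits the bulk of its parent
   primary's somatic variants, so shared-variant counts identify the
   primary of origin and, with several metastases per patient, distinguish
   clonal from independent dissemination.
3. **Parental-allele identity of CNAs.** Two tumors can both "lose chr18",
   yet lose *different* parental copies — strong evidence for independent
   genomic events even when the gross CNA profile looks identical.
   Resolving which haplotype a CNA affected, without phasing data, is the
   chromosome-mapping problem.

# Chromosome mapping

At a heterozygous germline SNP the two alleles tag the two parental
haplotypes. In a tumor region with allele-specific copy-number change the
allelic read fractions tilt away from 1/2; across a segment the direction
of tilt at each SNP, combined per arm, identifies the affected haplotype
up to the (unknown) phase.

The procedure, per tumor and CNA segment:

1. Het SNPs are taken from the matched normal at read depth > 10 and VAF
   in [0.4, 0.6] (both bounds inclusive; the depth bound strict — these
   follow the wording of the underlying protocol exactly).
2. The segment is split at the centromere; each arm is analyzed
   independently, because p and q arms can carry different parental-allele
   events (the motivating cohort contains a tumor that lost haplotype
   *maternal* on 18p and *paternal* on 18q, so arm-level families are not
   optional).
3. Candidate SNPs are those inside the arm-restricted segment with tumor
   depth > 10. Each candidate gets an exact two-sided binomial p-value
   against `p = 1/2`, using the minimum-likelihood convention: the sum of
   probabilities of all outcomes no more likely than the observed one.
   This is the dominant exact-test convention; tied counts give `p = 1`,
   which is why an informative SNP always has a well-defined major allele
   (asserted, not special-cased).
4. Benjamini–Hochberg adjustment is applied across exactly this candidate
   set (one family per tumor × arm-segment; SNPs failing the tumor-depth
   gate are excluded *before* adjustment). Adjusted `P < 0.05` defines
   informative SNPs.
5. For a tumor pair on one arm, the shared set is the intersection of
   their informative positions. If it holds fewer than 1000 SNPs, both
   tumors are re-called at adjusted `P < 0.1` and the shared set is
   recomputed, with the level recorded. The underlying protocol's phrasing
   ("tumors with < 1000 shared informative SNPs") is ambiguous about
   whether one or both tumors were re-called; re-calling both keeps the
   comparison symmetric, and symmetry is a property the tests enforce.
6. Concordance is the fraction of shared informative SNPs whose major
   allele agrees. The verdict cutoffs — `same_allele` at ≥ 0.9,
   `different_allele` at ≤ 0.1, `ambiguous` between — are this package's
   own quantification of what the source analysis reported qualitatively;
   they are config-exposed (`mapping_config()`), and at realistic depth
   and purity the observed concordances sit at ≈ 1 or ≈ 0, far from the
   cutoffs.

Direction gives the interpretation: under a loss the major allele marks
the *retained* haplotype, under a gain the *amplified* one, under
copy-neutral LOH the *duplicated* one.

## Numerical choices

* The binomial p-value uses a relative tolerance of `1e-7` when comparing
  outcome probabilities, so floating-point ties on the symmetric null are
  broken consistently; for totals ≤ 30 all probabilities are exact dyadic
  rationals and the tests pin the values to 1e-12 against full
  enumeration.
* BH adjustment delegates to the standard step-up implementation; the test
  suite checks it against an independent sort-based reference on
  exhaustive short vectors and random vectors up to length 10^4.
* A segment lying entirely inside the centromere has no arm overlap and
  yields an explicit `no_call` row rather than an error; purity-0 input
  yields zero informative SNPs and `no_call`.

# Post-calling filters

All boundary sides follow the quoted protocol exactly: depth ≤ 6 removed
(7 kept), population AF > 0.001 removed (exactly 0.001 kept), |logR| must
exceed 0.15 strictly, segments < 10 kb removed (exactly 10,000 bp kept).
A missing population AF keeps the variant: absence of evidence of a
population polymorphism must not remove a somatic call.

Two rules needed interpretation:

* **Chromosome ends.** Read literally, "breakpoints within 1 Mb of a
  chromosome end" would remove every whole-chromosome event — including
  the dominant whole-chr18 loss the analysis exists to study. The package
  therefore exempts breakpoints *exactly at* position 0 or the chromosome
  length (telomeric termini of whole-chromosome and terminal events) and
  removes only internal breakpoints strictly within the margin.
* **Centromeres.** The strict interior of the centromere interval is used,
  so arm-level segments ending exactly at a centromere boundary survive.

Copy-neutral LOH segments are exempt from the logR magnitude rule: they
are logR-neutral by definition, and the motivating dataset reports nine
such events that must survive filtering. Manual IGV-style artifact review
is inherently human-in-the-loop and is not reproduced; a
`manual_exclusions` list in `filter_config()` lets a user emulate its
effect, and `consensus_variants()` provides the two-caller intersection
utility.

# Clonality from shared variants

Variants match on the full key `(chrom, pos, ref, alt)`: the motivating
data contain two different substitutions at one position in two patients,
which are *not* the same mutation. The shared fraction uses the smaller
tumor's set size as denominator (the source percentages leave this
undefined; min is conservative and symmetric; a union denominator is a
config switch). Independence requires both a fraction below 1% and a count
below 5; origin assignment requires ≥ 5 shared variants and 2× dominance
over the runner-up, an explicit restatement of what the source analysis
did by inspection. CNA parental-allele verdicts are reported alongside but
never override variant-based clonality — the motivating cohort itself
contains clonal tumor pairs whose CNA subsets affected different alleles.

The subclonal check scans every shared variant against all tumors'
allelic evidence (≥ 2 ALT reads flags support even without a call); it is
an audit by default, and promoting supported variants can only increase
shared counts (a tested monotonicity property).

# The synthetic cohort generator

The generator is first-class, tested code and defines the study
conditions the validation runs under:

* 13 patients, 2–18 primaries and 0–4 metastases each; one normal sample
  per patient.
* 0.41 somatic mutations/Mb per primary; ~1.2% of variants coding with a
  65/27/3/3/2% missense/silent/nonsense/frameshift/splice split; coding
  variants map deterministically to 100-kb gene tiles so planted
  recurrences land in the same gene.
* Tumor purity uniform on [0.2, 0.9] (the source cohort's selection floor
  is 20%; an upper bound of 0.9 reflects that perfectly pure bulk samples
  do not occur); 60× tumor / 30× normal mean depth.
* 2000 het SNPs per chromosome, each SNP's ALT placed on haplotype A or B
  by an independent fair coin — exactly the unphased situation the
  mapping procedure must resolve.
* CNA events per tumor from a probability table: whole-chr1 loss at 0.57
  (the chr18-loss analog), whole-chr2 gain at 0.13, chr3q gain at 0.10, a
  focal chr3 loss at 0.08, chr1 cn-LOH at 0.05; each event picks an
  affected haplotype at random and records it in the ground truth.
  Segment logR is derived from purity and total copy number with small
  Gaussian noise; cn-LOH is simulated as two copies of the affected
  haplotype and zero of the other, logR ≈ 0.
* Reads: depth Poisson at the mean; ALT counts beta-binomial with
  overdispersion ρ = 0.01 (ρ = 0 reduces to binomial).
* Each metastasis inherits each parent-primary variant with probability
  0.9 plus its own private variants at the primary rate times a time
  factor (default 1.0). The source cohort reports a higher metastasis
  burden (0.63 vs 0.41 mut/Mb) but no generative model linking the two;
  the inheritance-fraction-plus-time-factor model is an explicit package
  choice, and both knobs are exposed rather than tuned.
* Metastases also inherit the parent's CNA events (same affected
  haplotype); additional metastasis-private CNAs are not drawn.
* Structural variants are drawn at a mean of 1 per tumor — a desk-scale
  choice to exercise the SV filter path; per-Mb scaling of the source
  cohort's SV counts to a 30-Mb genome would produce essentially none.

The toy genome is three 10-Mb chromosomes with centromeres at 40–45% of
length. Everything scales to a real assembly through `genome_config()`;
the toy frame exists so the full pipeline, including 100-seed recovery
experiments, runs on a desk in minutes.

**What the simulator does not emulate** — and hence what passing tests do
*not* show about real data: sequencing artifacts and alignment error
(filters are exercised on their boundaries, not on realistic error
distributions), subclonal copy-number mosaics and subclonal variant
fractions, trinucleotide mutational-signature structure, germline SNP
linkage structure, and real centromere/telomere repeat context. Recovery
rates on simulated data are an upper bound on real-data performance.

# Recurrence summaries

Whole-chromosome / arm / focal classification uses fractional coverage
with a 0.8 threshold (the source analysis never defines its "whole
chromosome or chromosome arm events"; the threshold is config-exposed).
Mutation burden divides by the full configured genome length; a
callable-genome denominator would shift absolute burdens on real data.
Minimally targeted regions are computed by an atomic-interval sweep:
regions are maximal runs of intervals supported by an identical segment
set with ≥ 2 distinct patients, so each reported region is contained in
every contributing segment and outputs are disjoint; only regions < 5 Mb
are reported. Pathway enrichment is upper-tail hypergeometric (enrichment
only, as the question is posed) with BH correction at FDR 0.1.

# Validation design and problem sizes

Every statistical primitive is checked against an independent oracle:
full enumeration for the exact binomial (totals ≤ 30 at 1e-12, symmetry
to 50), a sort-based reference for BH (lengths 1–20 exhaustively by
repetition, 1000 random vectors to length 10^4), enumeration for the
hypergeometric (all universes ≤ 25). Inference is validated by
plant-and-recover against simulator ground truth: whole-chromosome-loss
mapping at purity 0.6, depth 60×, 2000 het SNPs and ρ = 0.01 over 20
seeds (≥ 99% of informative SNPs carry the truth allele; opposite-haplotype
pairs yield `different_allele` and same-haplotype pairs `same_allele` in
≥ 19/20 seeds), p/q-discordant arms over 20 seeds, and clonality over 100
simulated 13-patient cohorts (all independent pairs recovered; ≥ 95% of
metastases assigned their true parent). Cohort-scale clonality runs
disable het-SNP and SV generation (the statistics under test depend only
on variant sets), which keeps the hundred-cohort experiment inside a few
minutes; these sizes are the package's chosen validation conditions and
are stated here so they can be scaled up deliberately.

# Known limitations

* The mapping approach is not designed for subclonal CNAs or very low
  purity; below ~30% purity at 60× depth, arm-level informative-SNP
  yields drop sharply and verdicts become `no_call` rather than wrong.
* Verdict cutoffs (0.9/0.1) and origin thresholds (5 shared, 2×
  dominance) are explicit package choices where the source analysis was
  qualitative; both are config-exposed.
* No phasing, haplotype panels, absolute copy-number or purity
  estimation: the direction label is taken from the input segment.
* The gnomAD field used for the population-AF filter (global vs
  population-max) is a configurable VCF INFO key, not a baked-in choice.
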