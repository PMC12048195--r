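---
title: "Methods: long-amplicon nanopore genotyping of PAH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-amplicon nanopore genotyping of PAH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahpanel)
```

## The problem

Phenylketonuria (PKU) is an autosomal recessive deficiency of phenylalanine
hydroxylase; molecular confirmation means finding two pathogenic *PAH*
alleles. Long-amplicon Oxford Nanopore (ONT) assays amplify the gene in a
handful of 1.5–5 kb products and report, per detected variant, a read depth
and an observed allele fraction (AF). Two properties of that data drive the
package's design:

* ONT allele fractions are biased: true homozygotes are observed well below
  AF 1.0 (down to ~0.58 in the packaged cohort) and heterozygotes scatter
  widely around 0.5 (0.18–0.56). Zygosity must therefore be called against
  a data-derived cutoff, not the naive 0.5/1.0 expectation.
* A diagnosis is genotype-level: one homozygous variant, or two different
  heterozygous variants assumed in trans, explains the disease; a single
  heterozygous variant does not.

The package implements that analysis end to end — cohort I/O with a strict
HGVS `c.`-notation subset parser, in-silico PCR validation of the primer
panel, allele-fraction zygosity calling, APV/GPV phenotype prediction, and
cohort statistics — plus a simulator that generates pileup observations
with known truth so every decision rule can be benchmarked without
sequencing data.

## The packaged cohort

`pku_cohort()` ships a 40-patient PKU cohort (57 variant calls, 25 distinct
*PAH* variants) as a plain TSV with one row per (patient, variant). Choices
made at transcription:

* Qualitative pre-treatment Phe entries ("> 8 mg/dL by Guthrie test", "not
  determined") are kept as enum markers; no conversion factor to µmol/L is
  defined for a semiquantitative screen, so converting would invent data.
* Decimal commas in APV cells were normalised to points.
* ACMG evidence codes are stored verbatim per call and never combined; a
  full ACMG classification engine is out of scope.
* One patient records a BioPKU majority class but no APV/GPV; both fields
  are kept exactly as recorded, without reconciliation.

## Zygosity from allele fraction

`call_zygosity()` classifies a call homozygous iff AF ≥ threshold; the
comparison is inclusive because the smallest homozygous fraction in the
cohort (0.58) itself defines the cutoff.

`derive_threshold()` derives that cutoff from a cohort rather than taking
it on faith. Only single-variant records are candidates: a patient with two
listed variants carries each on one allele, so neither of those calls can
be homozygous. Among single-variant records, those recorded as *not*
disease-explaining (no genotypic phenotype value; simulated cohorts carry
an `explained` truth flag instead) must remain heterozygous. The threshold
is the smallest single-variant fraction strictly above the largest
must-stay-heterozygous fraction — the maximal-separation choice. On the
packaged cohort this yields 0.58, with strict separation (largest
constrained heterozygous fraction 0.56).

Two edge rules deserve a note:

* One patient carries a second variant whose AF (0.67) exceeds the derived
  cutoff. Under the bi-allelic model a two-variant patient cannot also be
  homozygous, so such calls do not move the threshold; they are reported in
  the result's `inconsistent_calls` attribute, and `assemble_genotypes()`
  flags the profile `inconsistent = TRUE` while keeping the
  compound-heterozygous category. Flag-not-fail keeps batch runs alive and
  makes the contradiction visible instead of silently resolving it.
* Two single-variant patients record a GPV as if homozygous although their
  fractions (0.36, 0.31) classify heterozygous. The threshold machinery
  treats them as unconstrained candidates (their recorded genotype does not
  force heterozygosity), and the genotype profile carries the
  threshold-based category; the recorded value stays available side by
  side in the cohort table.

Two-variant genotypes are assumed bi-allelic (in trans); the assay performs
no phasing, so every compound-heterozygous profile carries an
`assumed_trans` flag.

## Phenotype prediction (APV/GPV)

Each variant has an allelic phenotype value (APV, 0–10, 0 most severe).
The genotypic phenotype value is the maximum of the two allelic values —
the milder allele sets residual enzyme activity in a recessive disease —
and bins as 0–2.7 classic PKU, 2.8–6.6 mild PKU, 6.7–10.0 mild
hyperphenylalaninemia. Values falling between bins are rounded to one
decimal first so the bins tile the scale. Missing APVs propagate to an
"unpredictable" genotype (`NA`), never to a default severity, and
single-heterozygous profiles are always unpredictable. One cohort patient
records GPV 9.7 against an APV pair of 10/9.7; `recompute_gpv()` surfaces
it and the test suite pins it as the single known discrepancy.

Clinical typing from pre-treatment Phe uses the two-class rule: classic PKU
above 1200 µmol/L, mild PKU at 600–1200 µmol/L (1200 inclusive on the mild
side). A few cohort patients carry recorded labels that contradict the
rule; recorded labels always take precedence, and `phe_to_clinical()` is a
pure function of the number.

`concordance()` compares predicted against recorded labels only under an
explicit mapping (default: clinical cPKU ↔ BioPKU classic; clinical mPKU ↔
BioPKU mild and mild-HPA) and echoes the mapping in its result. The rule
is configuration, not convention, because agreement counts are meaningless
without knowing how three recorded classes fold onto two clinical ones;
records missing either label are excluded from the evaluable set.

## Cohort statistics

Patient frequency of a variant counts carriers of any zygosity over all
patients; allele frequency counts two chromosomes per homozygote over 2n.
Consanguinity percentages exclude records with unknown status from the
denominator and count "consanguineous, degree unknown" as consanguineous.
Percentages are rounded to one decimal, half away from zero, matching the
reporting convention of clinical summaries (17/36 → 47.2). Internal
consistency (zygosity breakdowns partition carriers; genotype categories
sum to the patient count) is asserted inside `summarize_cohort()`, so a
violated invariant is an error rather than a wrong number.

## The toy reference and panel

Real *PAH* coordinates are not needed to test the machinery, so
`build_toy_reference()` generates a deterministic ~31 kb contig carrying a
13-exon gene with the exon sizes of the 1359 bp *PAH* CDS. Using the real
CDS exon boundaries keeps the intron-anchored variant positions seen in
reports (c.168+5, c.169-13, c.353-1, c.1066-11) at genuine exon edges;
introns, UTRs (100/400 bp) and 1 kb flanks are toy-sized. The bases at all
packaged-cohort variant positions are set to those variants' reference
alleles, so every variant lifts consistently and `write_vcf()` can emit
left-anchored, position-sorted VCF 4.2 against it.

In-silico PCR uses a sequence-level specificity model: a primer site is a
window with at most `max_mismatch` mismatches (default 2, a permissive
virtual-PCR setting) whose 3′-terminal `anchor_len` bases (default 3) match
exactly, since 3′ mispairing blocks extension. Primer thermodynamics (Tm,
dimers, multiplex interactions) are deliberately out of scope — the design
question being answered is coverage and specificity of unique binding
sites, not reaction optimisation. IUPAC codes in primers match their base
sets. The site search is Biostrings-backed and the test suite proves it
equal to an exhaustive position-by-position scan on randomized instances.

`toy_panel()` derives nine 22-mer primer pairs that tile the gene body in
nine ~3.3 kb products with 120 bp overlaps. Targets are the exons, both
UTRs, ±25 bp junction flanks at every exon–intron boundary, and one-base
targets at the cohort's intronic variant positions. Coverage is interval
arithmetic on half-open intervals (IRanges-backed, cross-checked in tests
by an independent union sweep). Pool assignment is greedy interval
colouring by start coordinate: overlapping products may not share a tube,
which for the tiled layout alternates adjacent amplicons between the two
pools; infeasible requests name the offending clique.

## The simulator

The unit of observation is the per-variant pileup summary `(depth,
alt_count)` — what amplicon variant reports actually contain — not
simulated reads; basecalling error profiles and read-length distributions
are out of scope. Depth is log-uniform on [50, 2000], reflecting the
orders-of-magnitude spread of long-PCR amplicon coverage without modelling
per-amplicon bias. The variant-read count is beta-binomial: a latent AF is
drawn from a Beta distribution centred on the zygosity-specific mean with
concentration `af_concentration`, then reads are binomial.

Defaults (`sim_config()`): centres 0.72 (hom) and 0.38 (het), the
empirical means of the packaged cohort's fractions, encoding the ONT
mapping bias described above; concentration 40, chosen once so that the
simulated central 95% intervals (hom ≈ 0.58–0.86, het ≈ 0.23–0.53) match
the observed ranges. Under these defaults the 0.58 rule recovers true
zygosity on well over 95% of calls at depth ≥ 500, which the suite tests as
a property. `simulate_cohort()` samples patient genotypes from a frequency
table (default: the packaged cohort's empirical genotype tally, which
reproduces its marginals, e.g. 0.375 for the most frequent intronic
variant) and stores the generating truth alongside every call.

What passing simulator-based tests shows — and what it does not: recovery
rates certify the decision rules against the *assumed* noise model, not
against real flow-cell artefacts (homopolymer errors, strand bias,
alignment slippage around indels). The beta-binomial is a stand-in fitted
to a small set of observed fractions; its tails in particular should not
be over-interpreted.

## Numerical and testing choices

* Zygosity and Phe boundaries are inclusive as documented above; GPV gap
  values round to one decimal before binning.
* `pileup_call()` defaults: minimum depth 50 (the depth regarded as
  adequate for molecular analysis), minimum AF 0.15 — just below the
  smallest fraction retained in the cohort (0.18) — so the naive caller
  keeps everything the assay's pipeline kept. Dropped observations land in
  a drop log, not the void.
* Seeded generators restore the caller's RNG state, so reproducibility of
  a pipeline does not depend on call order.
* Monte-Carlo tests use 10,000 draws for mean-recovery checks (3 standard
  errors), 2,000–4,000 for recovery rates, and 200-patient cohorts for
  threshold recovery; the whole suite runs in well under two minutes on a
  single CPU.

## Known limitations

* The HGVS parser covers exactly the subset used in this assay's reports
  (substitution, deletion, delins, intronic offsets); everything else is a
  loud error by design.
* The naive pileup caller is a simulation instrument; it does not replace
  an alignment-based caller on real reads.
* Structural variants and deep-intronic discovery beyond the targeted
  sites are outside what a short amplicon panel — and hence this package —
  can see.
* The concordance between predicted and recorded phenotype classes depends
  entirely on the declared label mapping; the package refuses to count
  unmapped label pairs rather than guess.
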