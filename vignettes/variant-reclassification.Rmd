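---
title: "Classifying rare recessive variants: evidence model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying rare recessive variants: evidence model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acmgrare)
```

## The problem

A large fraction of rare missense variants found in diagnostic sequencing
land in the "uncertain significance" (VUS) tier of the ACMG/AMP framework,
which blocks both a conclusive molecular diagnosis and access to
genotype-specific therapy.  For autosomal-recessive retinal dystrophy genes
such as *RPE65* — where an approved gene therapy exists — moving a variant
out of the VUS tier has direct clinical consequences.

`acmgrare` implements the evidence types that can be computed from data a
diagnostic laboratory already holds: population allele-frequency records,
in silico predictor panels, gene-level variant-class statistics, family
pedigrees with genotypes, and a case-control cohort of probands.  Each
evidence module emits an ACMG/AMP criterion with a met flag and a
rationale; a combiner turns the met set into one of five tiers with an
auditable trace.

## Evidence model

### PM2 / BA1 / BS1 — population frequency

A severe recessive childhood-disease allele is expected to be absent or
extremely rare in reference panels.  PM2 (moderate) is met when every
queried database shows the variant either absent or with frequency
strictly below `af_max` and at most `hom_max` homozygotes.  "No data" in a
queried database is treated as absence: that is precisely the situation
the criterion describes, and it is what lets a variant never catalogued by
gnomAD/ExAC/ESP/1000 Genomes/ABraOM qualify.

The guideline gives no numeric cutoff, so the cutoff is explicit
configuration rather than a derived constant.  The defaults,
`af_max = 1e-4` and `hom_max = 0`, follow common curation practice for
severe recessive disease: with full penetrance and random mating, an
allele at frequency $10^{-4}$ yields about one affected homozygote per
$10^8$ births, comfortably below the prevalence of any single retinal
dystrophy genotype.  BA1 (stand-alone benign, default `>= 0.05`) and BS1
(strong benign, default `>= 0.01`) are the inclusive-threshold benign
counterparts; BA1 shadows BS1.

### PP3 / BP4 — predictor consensus

Sixteen tools are scored per variant: eleven categorical
(PolyPhen2, SIFT, PROVEAN, LRT, MutationTaster, MutationAssessor, FATHMM,
FATHMM-MKL, M-CAP, MetaSVM, MetaLR) and five numeric (DANN > 0.9,
CADD > 20, PhyloP 20way > 0.5, PhyloP 100way > 2, GERP RS > 4, higher
damaging in all five).  Numeric comparisons are strict, so a value exactly
at the cutoff is not called deleterious.  Conservation-only tools count in
the same pool as functional predictors, since conservation of the
substituted residue is itself evidence of functional constraint.

PP3 is met when the deleterious fraction among mapped (non-ambiguous)
calls reaches `tau`; BP4 mirrors it on the benign side and is suppressed
whenever PP3 holds, so the two can never be met together.  The default
`tau = 0.75` asks for a clear consensus while tolerating a dissenting tool
or two in a 16-tool panel; demanding strict unanimity would make the
criterion fragile against any single miscalibrated tool.  Unknown
categorical labels map to "ambiguous" and simply leave the consensus
denominator.

### PP2 / BP1 — gene context

PP2 needs two things: missense change must be a common disease mechanism
in the gene (highest pathogenic-missense fraction across the supplied
database summaries at least `missense_fraction_min = 0.5`), and the gene
must carry little benign variation (benign fraction at most
`benign_fraction_max = 0.10` wherever a source reports one).  These two
thresholds encode as testable numbers what curators usually argue
qualitatively; for *RPE65* the bundled summaries give missense fractions
of 52/69 ≈ 0.754 (ClinVar/UniProt) and 103/191 ≈ 0.539 (HGMD) and a
benign fraction of 8/93 ≈ 0.086 (Varsome).  When sources disagree, the
most favorable source may carry the missense condition — the practice when
curators cite several databases jointly.  BP1 is the truncating-mechanism
counterpart (missense fraction at most 0.1).

### PP1 / BS4 — co-segregation

Segregation is evaluated per family over genotyped members with known
affection only: consistent means at least one affected homozygote, no
affected member with another genotype, and no unaffected homozygote.
Reduced penetrance is deliberately not modeled — an unaffected homozygote
anywhere breaks consistency and raises BS4 — matching the full-penetrance
presentation of childhood retinal dystrophy.  PP1 is met when at least one
family is consistent and none contradicts.

PP1 enters at supporting strength.  An escalation ladder (moderate at ≥ 3
consistent families with ≥ 6 informative unaffected carriers, strong at
≥ 5 families) is implemented but off by default: counting meioses from a
single cohort of one ancestry rarely justifies upgrading the criterion,
and the worked example keeps PP1 supporting for exactly that reason.  The
what-if report shows what the escalation would change.

### PS4 — case-control enrichment

The analysis unit is the proband (one per family, enforced by the cohort
reader).  The 2×2 table crosses diagnosis group (LCA/EORD cases vs other
IRD controls) with genotype exposure (homozygous for the candidate variant
vs not).  Because a rare variant typically has a zero cell among controls,
the odds ratio uses the Haldane–Anscombe correction: when any cell is
zero, 0.5 is added to *all four* cells before forming
$\widehat{OR} = a'd' / b'c'$.  The correction is applied only in the
presence of a zero cell — applying it unconditionally would change the
estimate for clean tables.

The Wald interval is computed on the log scale from the *same* corrected
cells, $\exp(\ln \widehat{OR} \pm z\,\sqrt{1/a'+1/b'+1/c'+1/d'})$, with
$z$ the standard-normal quantile at $1-(1-\gamma)/2$ computed at double
precision (2.241403 for $\gamma = 0.975$), never read from a printed
table.  Testing two variants in one run spreads the error rate by
Bonferroni: $\gamma = 1-(1-0.95)/2 = 0.975$.  PS4 (strong) requires
$\widehat{OR} \ge 3$ with the interval excluding 1.

On 1000 null cohorts of 513 probands (exposure probability 0.005
independent of group — about the carrier-derived homozygote rate a
diagnostic cohort of this size could plausibly show by chance) the rule
triggers in well under 5% of replicates; the suite asserts this with a
three-sigma Monte-Carlo margin under a fixed seed.

### Combining rules

The combiner encodes the published combining table.  Counts are read as
"at least" the enumerated combination: the table lists minimal qualifying
patterns, and the at-least reading keeps the verdict monotone — adding
pathogenic-side evidence can never move a variant toward benign (the test
suite verifies this exhaustively against an independently coded flat-rule
oracle over all tallies with each count up to 3).  Rules are evaluated in
a fixed order (pathogenic, likely pathogenic, benign, likely benign) and
the first satisfied rule is reported as `rule_fired`; the tier itself is
order-independent, only the reported identifier is a convention.  If both
sides fire, the verdict is uncertain significance with
`rule_fired = "conflicting"`.

PP5/BP6 (reputable source without accessible data) are representable but
never emitted by any evaluator — their evidential value is questionable
and they are best left to manual assertion via `extra_evidence`.  PP4
(phenotype specificity) is narrative, not computable from the inputs this
package takes, and is likewise only available as a manual assertion.  PM1
(mutational hot spot) is not computed; for the worked example it is known
not to hold.

## The worked example

The bundled `rpe65_replica` preset runs both *RPE65* missense variants
(NM_000329.3 c.247T>C p.Phe83Leu, c.560G>A p.Gly187Glu) end to end:

```{r replica}
reports <- run_classification(list(preset = "rpe65_replica"))
reports[["p.Phe83Leu"]]
```

Both variants meet PM2 + PP2 + PP3 (a VUS on their own: one moderate plus
two supporting fires no rule) and gain PP1 and PS4 from the family and
cohort data, which lands them in likely pathogenic via one strong, one
moderate and three supporting criteria.  The what-if table shows the two
escalation paths to pathogenic: accepting PM3 (a known-pathogenic partner
in trans) or applying PP1 above supporting.

## The synthetic generator

`generate_cohort()` emulates the structure of a recessive-disease
diagnostic cohort: one proband per family, an exact (not sampled) number
of homozygous probands planted per diagnosis group, nuclear families for
exposed probands with heterozygous parents and siblings drawn by Mendelian
transmission from a carrier-by-carrier mating, and optional heterozygous
carriers among unexposed probands.  Defaults reproduce the worked cohort's
marginals: 93 case and 420 control families, no carrier alleles outside
the planted homozygotes, full penetrance.  Sibship sizes default to 2–4
children (probabilities 0.5/0.3/0.2), a realistic span for the nuclear
families in this kind of study.

What it does *not* emulate: ascertainment bias beyond
one-proband-per-family, consanguinity loops, genotyping error, reduced or
age-dependent penetrance, population structure, and linkage between
variants.  Passing tests on synthetic cohorts therefore demonstrate the
correctness of the statistical machinery under the stated model, not
robustness of the criteria against those real-data complications.

The replica pedigrees for families A–G reconstruct the published
per-family counts (two genotyped affected in families A, E and F, three
in G, one elsewhere; heterozygous unaffected parents; at least one
unaffected informative relative per family).  The full published pedigrees
are only partially recoverable from the clinical table, so these are
representative synthetic reconstructions, and per-family meiosis counts
should not be read off them.

## Numerical and design notes

* All threshold comparisons are documented per criterion: PM2 strict `<`,
  BA1/BS1 inclusive `>=`, numeric predictor cutoffs strict `>`,
  PS4 `OR >= 3`.
* Frequencies and fractions are exact ratios of the supplied integers;
  rounding happens only in display and in reported summaries (allele
  frequencies at 4 decimals, odds ratios at 3).
* The odds-ratio path refuses tables with an empty case or control margin
  rather than returning an infinite or undefined estimate.
* Validation is front-loaded in constructors (`cohort()`,
  `frequency_records()`, `pedigree()` …), so evaluators can assume clean
  inputs; errors carry the offending stage and line/identifier where
  available.
* Problem sizes in the test suite are chosen to keep the full run small:
  the exhaustive combiner audit caps counts at 3 per bucket (8,192
  tallies), the odds-ratio oracle grid spans cells 0–6, and the null
  calibration uses 1000 replicates of 513 probands.

## Limitations

The package classifies one candidate variant per run (multi-variant runs
iterate) and covers the autosomal-recessive path only; dominant and
X-linked segregation, PM3 trans-phase evaluation, quantitative
(Bayes-factor) co-segregation, popmax-style subpopulation frequency logic
and calibrated predictor strength modulation are out of scope.  PM1,
PP4, PP5 and their counterparts are accepted as manual assertions, never
computed.
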