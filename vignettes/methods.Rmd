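---
title: "Models and methods behind snpmon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind snpmon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmon)
```

`snpmon` implements a complete non-invasive genetic-monitoring workflow
for a canid-style reduced SNP panel: panel design from dense reference
genotypes, replicate quality control, species assignment, genetic sexing,
individual identification, identity-power statistics, and parentage with
pedigree inbreeding. This vignette is the package's account of the science
in each stage: the models, their assumptions, the tunable parameters and
their defaults, and the places where a design choice was genuinely open.

## The data model

All stages operate on a genotype table: one row per sample, one character
column per marker, calls written `"A/G"` with alleles sorted so unordered
pairs compare equal, `NA` for missing. Three conventions matter:

* **Hemizygous males.** Genotyping arrays report a male's single X allele
  as a homozygous-looking call. The package keeps that convention on
  input and output; sex-aware logic lives in the sex caller, not the
  container.
* **The Y marker is a presence call.** It is stored as a
  pseudo-homozygous call when detected and `NA` otherwise, so consensus,
  matching and IO treat it like any other locus while the sex caller
  interprets presence/absence.
* **Coordinates are 1-based** (MAP convention). The pseudoautosomal
  region is a configured interval flag on X markers, since no reference
  coordinates ship with a panel.

## Panel design

The selection cascade applies, in order: a per-sample genotyping-success
filter (default 0.85), a per-marker call-rate filter (0.90), windowed LD
pruning, a Hardy–Weinberg screen, then category rules. Defaults follow
standard array-QC practice; every threshold sits in `selection_config()`.

**Hardy–Weinberg.** The screen uses the exact conditional test:
conditional on the observed allele totals, a configuration with $n_{AB}$
heterozygotes has probability proportional to
$2^{n_{AB}} N! / (n_{AA}!\,n_{AB}!\,n_{BB}!)$, and the two-sided p-value
sums all configurations no more probable than the observed one. The exact
test was chosen over the $\chi^2$ approximation because design-stage
screens run on modest sample sizes where the approximation is
anticonservative; the suite verifies the implementation against a full
enumeration oracle for every configuration with $N \le 10$ and checks the
empirical type-I error under simulation (the exact test is conservative).
The design-stage level is 0.001; panel validation uses 0.05.

**LD.** r² is the squared Pearson correlation of minor-allele dosages
over jointly called samples — genotype (composite) LD rather than
EM-estimated haplotype LD. For a panel designed to be unlinked the
distinction is immaterial, and dosage r² needs no phasing model; this is
a deliberate simplification. Pruning slides a 50-marker window in steps
of 5 and removes the lower-MAF member of any pair with r² > 0.2 (ties
drop the later map position), repeating until the retained set passes its
own audit.

**F~ST~.** Per-locus divergence uses the two-population Weir–Cockerham
variance-components estimator, which handles unequal sample sizes and is
label-swap invariant; a Hudson-style estimator was considered but the
Weir–Cockerham form is what the field's standard tooling reports.
Diagnostic candidates must reach $\theta = 1$ (fixed opposite alleles).

**X markers** must combine a female MAF in 0.125–0.333 (heterozygosity to
sex females) with an apparent male MAF ≤ 0.005 (hemizygous males must
look homozygous; higher male MAF indicates cross-amplification or PAR
leakage). PAR-flagged markers are excluded before selection.

## Replicate QC and error rates

Within a replicate group, a locus keeps its call only when every
non-missing replicate agrees; any disagreement recodes the locus missing
and counts one mismatch. This conservative rule never invents a call and
makes mismatch counts order-invariant. The monitoring pass threshold is a
0.80 consensus call rate by default, per-material overrides available;
the exact operational cutoff of a monitoring programme is a policy
choice, and 0.80 reproduces the qualitative pass ordering
tissue > scat > urine > hair. Call rates are computed after consensus by
default (`consensus_first`), because the pass decision applies to the
merged genotype a season actually uses. Y markers are excluded from
female call-rate denominators — absence of Y in a female is biology, not
failure.

Error rates against a reference technology count a mismatch when one
platform calls a heterozygote and the other a homozygote, or when the two
calls are opposite homozygotes — one mismatch per locus, so a 15-sample ×
95-marker comparison yields exactly 1425 locus comparisons when the
reference is complete. Panel-missing loci are tallied separately
regardless of the reference call.

## Species assignment

Reference groups pool labelled genotypes — the intended use pools the
target species with its domestic relative into one group and the distant
canids into another, mirroring how the underlying allele-frequency
structure actually separates. When external ancestry coefficients are
supplied, members below Q = 0.85 are dropped from the counts. Group
allele frequencies are posterior means under a symmetric Dirichlet(½, ½)
prior, so no genotype has zero likelihood; a query's log-likelihood sums
log Hardy–Weinberg genotype probabilities over called autosomal loci, and
posteriors use equal group priors (the reference tool's internal priors
are not published at this grain; equal priors are the neutral choice).
Leave-one-out validation removes each member from its own group's counts
before assignment.

The admixture algorithm that produces ancestry coefficients is *not*
re-implemented: Q values are an optional input column, and the simulator
provides truth-based stand-ins. Non-target distant species (bear, lynx,
moose analogues) are screened by amplification failure, not assignment —
they fail the pass filter long before reaching the assigner.

## Genetic sexing

The X statistic is the homozygosity excess
$F = (O_{hom} - E_{hom}) / (L - E_{hom})$ with
$E_{hom} = \sum_{typed} (1 - 2p_jq_j)$ at reference female frequencies
(no small-sample correction: the reference set is treated as the
population). Hemizygous males score exactly 1; outbred females scatter
around 0, but with only nine X markers the scatter is wide — this is the
fundamental reason female sexing is the hard case, and why inbred,
X-homozygous females are *unsexable* by this statistic rather than
mis-called: the caller returns UNCERTAIN, never FEMALE-by-default.

The call rule is positive confirmation: MALE requires Y detected *and*
a male-like X pattern ($F \ge$ `f_male_min`, or undefined); FEMALE
requires Y absent *and* $F \le$ `f_female_max`. Two conflict signatures
are flagged: Y present with a sub-male X statistic (the over-marking
mixture — a female's urine over-marked by the territory male amplifies
both), and Y absent with a male-like statistic (the inbred-female mode).
The mixture flag compares against `f_male_min` rather than
`f_female_max`: a genuine male should carry *no* X heterozygosity, so any
Y-bearing sample short of the male threshold is suspect. Under the
narrower band the flag would miss mixtures whose statistic lands between
the thresholds (measured ≈17% of simulated male+female mixtures), while
the wider rule flags ≥95% of them without touching clean males.

`tune_sex_thresholds()` reproduces the operational tuning procedure: a
grid search maximising the definite-call fraction subject to zero
mis-calls on known-sex samples, ties resolved toward the widest
uncertainty band. The tuned numeric values are data-dependent by design.

## Individual identification

Identity is decided by pairwise allele matching with no genetic model:
overlap is the count of jointly called loci, mismatch the count of
differing unordered calls. Samples join the same individual when their
overlap reaches `min_overlap` (default 79 of 96 — the practical minimum
for robust identification) and their mismatches stay at or below the
threshold (default 16). Connected components under single linkage are
individuals: transitive identity is exactly the monitoring semantics
(the same animal sampled repeatedly), and the chaining risk single
linkage carries is controlled by the threshold. Pairs below the overlap
floor are never linked, only flagged.

The automatic threshold takes the histogram of mismatch counts over
qualifying pairs and places the cut at the midpoint of the widest empty
gap (width ≥ 3) between the same-individual mode near zero and the
remaining mass; with no such gap it falls back to the configured default.
The gap rule is this package's own construction — published workflows
report the threshold, not the procedure — and on simulated seasons it
lands at 15–16, bracketing the operational value.

Note the deliberate tension with the PID section below: PID-style
calculations say ~10–19 markers suffice, yet the matching rule demands 79
shared loci. Missing data, genotyping error and relatives in the
population all erode the idealised PID guarantee, which is why practical
marker requirements run a factor of three to four above PID~sib~ counts.

## Identity power

Per-locus PID and PID~sib~ use the standard formulas (implemented for
general $k$ alleles although the panel is biallelic), verified against
brute-force enumeration of genotype-pair and sib-pair distributions.
`markers_needed()` sorts loci ascending by their per-locus value (most
informative first — the published counts do not state their ordering, and
ascending order is the convention of the reference implementations) and
returns the shortest prefix whose product clears the threshold
(default 10⁻⁴). Multi-locus products assume the post-pruning panel is
independent, which the suite checks against direct two-individual
simulation.

## Parentage and pedigree inbreeding

Full-likelihood sibship reconstruction is intentionally out of scope; the
package ships a desk-scale exclusion-plus-LOD scheme. Candidates (all
females as mothers, all males as fathers, unknown-sex in both sets) are
screened by Mendelian incompatibility with tolerance
$\lceil 2\varepsilon L \rceil$ over $L$ shared loci, then scored with a
LOD summing $\log_{10}$ transmission likelihood ratios. Transmission
mixes Mendelian segregation with a per-allele error: an allele comes from
the parent with probability $1-\varepsilon$ and from the population
otherwise ($\varepsilon = 0.01$ by default, the conventional array error
allowance). With $\varepsilon = 0$ the scheme reduces to pure exclusion.
Hypotheses (each compatible pair, single parents when no pair survives,
and "parents absent") receive a posterior with the parent-absent
hypothesis weighted by $1 - 0.9$; the reported confidence is that
posterior. Without age or cohort data, parent–offspring dyads are
directionally symmetric — a known limitation shared by all
exclusion-based methods; in practice the jointly compatible true pair
dominates the likelihood.

Pedigree inbreeding uses the recursive kinship function,
$\phi(a,a) = (1+F_a)/2$,
$\phi(a,b) = (\phi(s_a,b) + \phi(d_a,b))/2$, founders unrelated and
non-inbred; $F_i$ is the kinship of $i$'s parents. A
grandfather × granddaughter pairing yields $F = 0.125$; the suite
cross-checks a multigeneration within-line pedigree (max $F = 0.219$)
against gene-dropping simulation.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions the
rest of the package is validated under.

* **Populations.** Allele frequencies follow the Balding–Nichols model:
  ancestral frequency drawn uniformly from the high-MAF design range
  (0.292–0.500; X markers 0.125–0.333), population frequency
  Beta-distributed around it with divergence $F$. Defaults — wolf 0.03,
  dog 0.08, jackal/fox/raccoon-dog 0.35 — put the domestic relative close
  to the target and the other canids far, reproducing the observed
  ordination structure (close pair vs distant pool on PC1).
* **Diagnostic markers** are fixed opposite between their species pair.
  Dogs carry the wolf allele at wolf–jackal diagnostics (at such sites
  dogs *are* wolves); distant canids sit at 0.5 for wolf–dog diagnostics
  (their state is unascertained by a within-pair design).
* **Sex linkage.** Females draw two X alleles, males one maternal allele
  reported as a homozygous call; sons never inherit a paternal X; Y is
  detected exactly in males.
* **Error model.** Per material: whole-call missingness, allelic dropout
  (heterozygote observed as a random one of its homozygotes) and false
  alleles. No per-material rates are published for this workflow, so the
  defaults are free parameters chosen once: dropout/false-allele rates
  set so duplicated scats reproduce the observed duplicate-mismatch
  magnitude (~0.1 mismatches per group over 96 markers, ~0.001 per
  marker), and missingness means (tissue 0.005, scat 0.15, urine 0.20,
  hair 0.30) set so pass rates land near the observed 100/88/66/50%
  ordering. Each physical sample additionally draws its own missing rate
  from Beta$(mk, (1-m)k)$ with $k = 1.2$: field-sample DNA quality is
  heavy-tailed (most extracts fine, a fraction degraded beyond use), and
  without this the two-replicate consensus would pass essentially every
  scat.
* **Contamination.** A urine sample becomes a two-donor mixture with
  probability 0.1; the observed call is the union of donor alleles
  truncated to a biallelic call, and Y is detected if either donor is
  male — producing exactly the Y-with-heterozygous-X conflict the sex
  caller flags.
* **Seasons.** A season draws a configured number of individuals, each
  appearing in at least one sample (a season's individual count is
  defined by its samples), with skewed resampling intensity, scats
  genotyped in duplicate.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: linkage and recombination (markers are
simulated unlinked, consistent with a post-pruning panel, so the LD
pruner is exercised on constructed correlated fixtures instead),
population substructure and ascertainment bias within the reference
groups, locus-specific amplification quality (real panels have
individually bad assays), degraded non-canid samples are represented only
as amplification failure, and genotyping-plate batch effects. Distant
non-canid species are not given genotypes at all.

## Numerical choices and degenerate inputs

* Exact HWE p-values are computed in log space and compared with a
  $1 + 10^{-9}$ relative guard when summing the tail, protecting
  tie configurations from floating-point misclassification.
* Zero-variance dosages make r² `NaN`, treated as "not linked"; a locus
  monomorphic across both populations makes θ `NaN`.
* Consensus and cluster-consensus ties recode to missing rather than
  guess.
* An all-missing query receives a flat assignment posterior; an
  undefined X statistic with Y detected still calls MALE (Y is decisive
  for males), while Y-absent samples need positive X evidence.
* Empty inputs return empty, well-formed results (empty panel with
  all-zero attrition, empty cluster set, header-only reports).
* Report writing is deterministic: identical inputs produce
  byte-identical TSV bundles.

## Problem sizes used in the tests

The suite validates statistical behaviour at sizes chosen to make
Monte-Carlo error small relative to the assertions: 10,000 draws for the
Balding–Nichols mean, 2,000 replicates for the HWE type-I error, 200
reference members for leave-one-out assignment, a 282-sample season for
partition recovery (Rand index ≥ 0.99), and 40,000 gene drops for the
pedigree cross-check. All are seeded and run in about a minute in total.
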