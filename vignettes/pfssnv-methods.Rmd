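---
title: "Methods and modeling notes for pfssnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modeling notes for pfssnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfssnv)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what a passing test does — and does not —
establish. All empirical statements here are quantities the test suite or
the acceptance script computes; nothing is quoted from external runs.

## 1. The data model

Everything is protein-coordinate: 1-based residue positions on a proteome
keyed by accession. Genomic coordinates never enter the package — mapping
from VCF/genome space is upstream tooling (ANNOVAR-class) and out of scope.

Variant rows arrive one per report (variant × patient × source). Validation
is audit-first: every failing row lands in a rejection report with a reason
code (`REF_MISMATCH`, `OUT_OF_RANGE`, ...) and `|accepted| + |rejected|`
always equals the input row count. Rows then collapse to unique variants on
the key *(accession, position, ref, alt, consequence, origin)* with sources
unioned and patients accumulated per DO-slim cancer term, so patient
frequency stays recoverable. Origin is part of the key: a variant reported
both somatic and germline stays two records, because the four analyzed
mutation classes (non-SS, SS, non-SG, SG) cross origin with consequence.
Stop gains are retained in the data but excluded from site-effect
statistics; the classes above are the analysis universe.

Heterogeneous raw cancer labels are unified to DO Cancer Slim terms through
a many-to-one mapping file; terms without a mapping go to an explicit
`unmapped` bucket rather than being dropped, and a raw term mapped to two
slims is a hard error (it would silently double-count patients).

## 2. Effect calls: tolerance sets and the sequon

A substitution at a site is a **loss** when the alternate residue cannot
carry the function. The per-modification tolerance sets default to the
chemistry: phosphorylation {S, T, Y}; acetylation, ubiquitination,
crotonylation {K}; nitrosylation {C}; O-glycosylation {S, T};
N-glycosylation {N}. Active/binding sites and unknown types tolerate only
the reference residue — any substitution is a loss — unless a curated set
is supplied. Methylation is the one deliberate restriction: the table lists
{K, R} as eligible carriers, but a K-site does not tolerate R (the two
methyl-acceptor systems are disjoint), so the per-site set collapses to the
reference residue. Synonymous variants at a site are always `retained`:
they count in occurrence statistics, never as losses.

N-glycosylation is positional, not residue-local: the asparagine is
functional only inside N-X-[S/T] with X ≠ P. Variants at the site, at +1
and at +2 are therefore all evaluated by rebuilding the post-substitution
triplet, and a broken sequon at +1/+2 is attributed to the site at N with
the provenance recorded in `sequon_role` (`N0`, `X1`, `ST2`). Whether such
+1/+2 losses should be attributed to the N position for counting purposes
is not settled by the source material; attributing them (with the role
recorded so they can be filtered) preserves the most information. Gain
calls are deterministic for N-glycosylation only (two-scan sequon
difference, reference vs mutated sequence); gain of phosphorylation is an
external ML prediction and is only ever accepted as a precomputed input
column.

## 3. Neighborhood profiles and the t-test

For each site type, variants within ±20 residues of a site (a window fixed
by the design of the analysis, configurable for sensitivity work) yield one
annotation per (site, variant) pair — overlapping windows double-count by
design, since each site is an observation unit. At offset $o$ the
occurrence is the annotation count divided by the number of sites with a
valid residue at $o$ (edge positions shrink denominators; offsets with zero
denominator are omitted, never imputed). The fold change divides occurrence
by the global per-residue rate of the class — the same denominator at every
offset, so the offset-0 value and its neighbors are directly comparable and
1.0 reads as background. Whether background residues that are themselves
sites of another type should be excluded from denominators was an open
choice; they are not excluded here.

The attached test is a one-sample t: the 40 neighbor fold changes are the
sample, the offset-0 value the hypothesized mean, two-sided p on 39 df,
with t > 0 when neighbors exceed the site. This is the only one-sample
construction with n > 1 consistent with "site versus its neighborhood",
and it reproduces the intended reading for strong effects (a planted 0.5×
depletion at 50,000 variants yields a fold change within ±0.1 of 0.5 and a
large positive t — acceptance criterion 3). **Its null calibration is
intrinsically poor**, and the package documents rather than hides this: the
site value is treated as a fixed mean but is itself an estimate with the
sampling variance of a single offset, i.e. about 40× the variance of the
neighbor mean. Under the synthetic null the test rejects at the 5% level in
roughly three quarters of replicate profiles (measured over 1,000 seeded
profiles in the acceptance suite, which asserts the 5% ± 2% band and
therefore fails honestly). Interpret the t/p pair as a descriptive effect
size for site-vs-neighborhood contrast, not as a calibrated test.

## 4. Binomial enrichment

Both enrichment constructions use the same exact tail rule: upper tail
$P(X \ge n_O)$ when the observation exceeds expectation, lower tail
$P(X \le n_O)$ below it, and the smaller tail (capped at 1) at exact
equality — the equality case is a package decision, as only the strict
cases were prescribed. Tails are exact binomial summations (no normal
approximation; cohort sizes are at most thousands) and match an
independent enumeration oracle over every N ≤ 12 grid point (criterion 1).
Because the direction is chosen from the data and a single tail is
reported, the null rejection rate at nominal α is close to 2α (≈7.8%
measured against the 5% ± 2% acceptance band — the second honest failure).
Doubling the tail would calibrate it but would no longer be the prescribed
statistic.

The amino-acid background makes each site type's expectation reflect the
composition of its donor residues: serines are abundant and often
phosphosites, so an excess of S-variants on phosphosites must clear a
higher bar than the raw proteome rate would suggest.

For patient-level enrichment the expected per-patient carriage $p_C$ was
not legible in the source (the formula survives only as a figure), so the
package implements a labeled estimator — the mean per-variant per-patient
carriage across the pfsSNVs observed in cancer *C*, which absorbs
per-cancer mutational-rate differences — plus a `global` pooled
alternative; neither is asserted to be the original form. The Bonferroni
family is all variant × cancer tests performed in the run. With the stated
planted effect (carriage 0.1 vs background 0.05, 500 patients) detection
below that cutoff occurs in ~92% of 100 seeds, short of the ≥95%
acceptance bar: at any realistic family size the cutoff demands ≥ ~42 of
500 carriers while the planted draw averages 50 ± 6.7. The criterion is
left red; the shortfall is a property of the effect size and threshold,
not of the tail computation.

## 5. Pan-cancer matrix and clustering

Per (cancer, site type), observed is the offset-0 occurrence and expected
is the mean occurrence over the 40 neighbor offsets, pooled across all site
instances of that type (pooling per site instance was the alternative; the
pooled form matches the "grey = no detected SNV" missing-cell semantics).
A window with no variants yields an explicit missing cell, never 0; an
observed > 0 over expected = 0 cell is set to a reported cap sentinel (100)
— it is a rendering convenience, not a statistic. Clustering is
agglomerative with Euclidean distance and complete linkage (the source
names neither; these were chosen for determinism and monotone merge
heights), missing cells imputed as 1.0 for the distance computation only,
and exact ties broken by lexicographic cluster label so the merge tree is
invariant to input row order. The implementation is checked against a
brute-force nearest-pair oracle (criterion 6) and exports standard
`hclust` objects and Newick strings.

Key-pfsSNV selection applies the two criteria as a union with labels:
`multi_cancer` (present in ≥5 DO-slim terms — the inclusive reading of the
threshold, where the source text wavers between "5 or more" and "more than
five"), `patient_enriched` (any test below the Bonferroni cutoff), or
`both`. SMG/CGC membership is annotation, not filtering.

## 6. Position unification between sequence revisions

When site and variant tables reference different revisions of a sequence,
positions are unified through global Needleman–Wunsch alignment with
affine gaps (Gotoh). The scoring scheme is a package default — match +1,
mismatch −1, gap open −2 covering the first gapped residue, extend −1 —
chosen to be cheap and adequate for near-identical revisions, not inferred
from the source. Traceback ties break deterministically diagonal > up >
left; the resulting position map is strictly monotone, residues opposite
gaps are dropped with a reason, and aligned-but-mismatched residues are
lifted with a `mismatch_at_site` flag rather than silently or not at all.
Maps equal an exhaustive enumeration oracle for sequences up to length 8
(criterion 5).

## 7. What the generator emulates — and what it does not

The synthetic module is first-class code, not a fixture dump. Its defaults
restate the published scale of pan-cancer compendia as per-residue rates:
non-SS 0.113, SS 0.042, non-SG 0.083, SG 0.048 (class totals of order
1.3M/0.5M/0.9M/0.5M over a ~11.3 Mres proteome), stop gains 0.008/0.002,
amino-acid frequencies from the vertebrate background, site densities of a
few per-mille to a few percent per eligible residue with N-glycosylation
placed only on existing sequons, and an eight-cancer cohort of 100–300
patients with background per-patient carriage 5 × 10⁻⁴ (so recurrent
multi-cancer variants are rare unless planted — matching the heavy
singleton tail of real compendia). Planted structure is explicit:
per-offset density multipliers per site type (composed multiplicatively
across overlapping neighborhoods, the simplest commutative rule) and
forced-carriage enriched variants.

Deliberately not modeled: trinucleotide mutational signatures, codon
structure beneath synonymous events (they are positional events with
ref = alt), linkage between variants, clonal/purity structure, and any
correlation between site density and sequence context beyond residue
eligibility. A green test on synthetic data therefore establishes that the
statistics recover what was planted under i.i.d. noise — not that real
mutational processes satisfy the independence assumptions.

Determinism: every stage derives its own stream from the master seed, so
stages reproduce identically whether run separately or via
`simulate_bundle()`, and `write_fixture_bundle()` manifests MD5 digests for
byte-level reproducibility checks.

## 8. Numerical and degenerate-input conventions

* Zero-variance neighbor sets make the t statistic undefined: a flagged
  degenerate result is returned with p = 1 if the neighbor mean equals the
  site value, p = 0 otherwise.
* A zero global rate makes profiles undefined and is an error, as is an
  empty proteome, a cancer with zero cohort size, or a Bonferroni family
  below 1.
* Curated tolerance sets are always augmented with the reference residue
  (a site that does not tolerate its own reference is curation noise).
* N-glycosylation sites whose sequon would run past the protein end are
  rejected as malformed with a report entry.
* Floating-point ties in alignment and clustering are compared with a
  1e-12 slack before the deterministic tie-break is applied.

## 9. Known limitations

The t-test and single-tail calibration issues above are the two that
matter for inference. Beyond those: isoform handling is accession-exact
(no isoform selection logic); the sequon scanner is a deterministic
stand-in for N-glycosylation prediction and does not model site occupancy;
survival analysis and figure rendering (Circos, heatmaps) are out of
scope, with plain matrix/Newick/TSV exports provided instead.
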