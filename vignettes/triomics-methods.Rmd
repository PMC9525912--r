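---
title: "Models and methods behind the triomics package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the triomics package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomics)
```

This vignette explains the quantitative models the package implements,
the defaults and why they were chosen, the numerical details, and what
the synthetic-data generators do and do not emulate. The setting is a
single-sample workflow in which one cell lysate yields three LC-MS
tracks: derivatized metabolites, histone peptides measured by parallel
reaction monitoring (PRM), and TMT-labeled tryptic peptides for protein
expression. The running biological example is macrophage polarization
(unpolarized M0, IFN-γ-polarized M1, IL-4-polarized M2), but nothing in
the code is specific to it — groups are just labels in a design table.

## Mass arithmetic and derivatization chemistry

All mass computation reduces to a monoisotopic element-mass table
(IUPAC/CODATA values) over C, H, N, O, S, P, Cl, Na, K plus the isotope
labels `[13C]`, `[2H]`, `[15N]` written as distinct symbols. Writing
labels as their own symbols, rather than as options on C/H/N, keeps the
parser trivial and makes isotope-labeled internal standards (e.g.
doubly-labeled glycine, `[13C]2[2H]2[15N]H3O2`) first-class formulas
whose masses are exact.

Two derivatization chemistries are modeled as fixed per-site neutral
shifts:

* dansylation of primary amines: dansyl chloride minus HCl,
  C12H11NO2S = +233.051049 Da per site;
* O-benzylhydroxylamine (O-BHA) on carboxyls (amide product) and
  ketones/aldehydes (oxime product): O-BHA minus H2O, C7H7N =
  +105.057849 Da per site. Both products share the net shift, so a
  single carbonyl-site count suffices.

Site counts are data (columns of the compound library), not predictions
from structure: the workflow's inputs carry no structures, and a
cheminformatics dependency for site perception would buy nothing for
quantification. For multi-amine compounds whose derivatization state is
uncertain, the library matcher tries every site count from 1 to the
declared maximum, so mono- and fully-derivatized forms are both
candidates. Only positive mode is supported (the small-molecule ions are
MH+); the proton mass is 1.00727646688 Da.

## Metabolite matching and quantification

Each observed feature is compared against the library expanded over
derivatization states; the candidate with the smallest |ppm error| is
retained and accepted when |ppm| ≤ 5.0. The boundary is inclusive — a
"threshold of 5 ppm" is read as a pass bound — and ties are broken by
fewer derivatized sites, then lexicographic compound id, which makes
matching deterministic. Unmatched features are returned with their best
(rejected) candidate rather than dropped, so the caller can audit near
misses. MS2 validation is accepted as an input annotation column only;
fragment evidence is qualitative in this workflow and is never computed
here.

Quantification divides the analyte area by the area of a spiked
isotope-labeled internal standard of known amount (default 1 nmol,
i.e. 10 µl of 0.1 mM) and scales by the sample's protein mass, giving
nmol per mg protein. Assignment of analyte to standard follows the
track's rules: dansyl compounds use the zone-matched standard (labeled
serine in the low retention-time zone, labeled glycine in the high
zone), O-BHA compounds use their exact labeled analogue when present and
otherwise the 13C4-malate standard. The standards manifest therefore
carries two optional columns beyond id/formula/amount/zone/scheme: the
standard's own derivatizable site count (needed for its theoretical m/z)
and `target_compound_id`, designating the analyte whose exact analogue
it is. When the design table lacks protein masses, 1.0 mg is assumed
with a warning, so relative comparisons stay valid at the cost of the
absolute scale.

This estimator assumes the analyte and its standard have equal detector
response. Exactly true for a labeled analogue; for zone-normalized
compounds it is an approximation the workflow accepts, and the simulator
mirrors it by sharing response factors within a retention-time zone (see
below).

Group comparisons are volcano-style: log2 fold change of group means and
a two-sided, pooled-variance (Student) t-test per compound, the
replicate unit being the injection. Pooled variance matches the t-test
as usually applied to consecutive injections of a pooled sample; Welch
is available by flag, as is Benjamini–Hochberg adjustment (raw p-values
are the default since per-compound volcano p-values are usually reported
unadjusted). Degenerate inputs are flagged rather than thrown: zero
within-group variance gives an NA p-value with a `zero_variance` flag,
a zero denominator mean gives an infinite fold change flagged for
exclusion from plots.

## Histone PTM levels and SILAC normalization

The modification level of a peptide is area(modified)/area(unmodified)
of the same peptide — the "modification percentage". It deliberately
divides by the unmodified peptide only, so values above 1 are legal; a
bounded fraction-of-total mode (modified/(modified+unmodified)) is
available behind a flag for users who expect percentages in [0, 1].
Co-eluting positional isomers reported jointly (e.g. H3K18/23ac) are one
modification label.

With SILAC heavy-arginine standard histones spiked into every sample,
the normalized level is (light ratio)/(heavy ratio). Any multiplicative
factor specific to a peptide but shared by the light and heavy channels
— ionization efficiency, digestion yield, transmission — cancels
algebraically, so cross-sample fold changes of normalized levels equal
fold changes of true modification levels. This cancellation is exact,
and the test suite asserts it to machine precision. Because heavy
standard amounts differ between preparations, only ratios, never
absolute heavy areas, enter any computation. When the heavy channel is
absent or zero the raw ratio is carried forward with a warning and the
`normalized` flag records it.

## Isotope tracing

Natural-abundance envelopes are computed by truncated polynomial
expansion of per-element isotope distributions. Carbon-only mode
(13C at 1.07%) is the default: carbon dominates the correction for the
ions involved, and the full CHNOS mode is one flag away when sulfur- or
oxygen-rich species warrant it. Probabilities are truncated at M+K
without renormalization (they sum to ≤ 1), because the correction matrix
must not inflate truncated tails.

Correction solves A·x = y, column j of A being the envelope of the
species with j tracer carbons fixed heavy and the rest natural. A is
nearly lower-triangular with diagonal entries ≈ 0.9893^(nC−j), so the
system is well-conditioned whenever K ≥ the label shift; shorter
envelopes are rejected with advice to measure more isotopologues. The
solve is non-negative least squares (`pracma::lsqnonneg`) by default —
noise can push an unconstrained solution negative — with a plain
least-squares route kept for diagnostics. Fractions are renormalized to
sum 1.

Enrichment is reported two ways, because the underlying convention is
genuinely ambiguous in practice: the literal labeled/unlabeled intensity
ratio I(M+n)/I(M+0) computed on raw intensities (the incorporation-rate
estimator as classically defined), and the corrected labeled fraction
x(M+n)/Σx (the default output). When only M+0 and M+n are populated and
correction is off, fraction = ratio/(1+ratio) exactly. Both numbers are
always returned, and `correct = FALSE` reproduces the literal
computation, so either reading is available. For histone tracing no
SILAC standard is involved (tracing runs use no heavy histones), and the
mass shift of serine-derived methyl marks is taken from the input file
rather than hard-coded, since CD2 vs CD3 transfer chemistry differs by
mark and experiment.

## TMT proteomics and the SAM statistic

PSMs are kept when their posterior error probability is strictly below
0.05, and a protein group survives only with at least one accepted
unique peptide. Aggregation is the channel-wise sum of reporter
intensities — additive, and close to what commercial pipelines do — with
a median-of-log alternative behind a flag. Channel totals are equalized
by default (loading normalization); the matrix is then log2-transformed.

The differential statistic is d = (mean_b − mean_a)/(s + s0) with s the
pooled two-sample standard error and s0 a constant in log2 units
(default 0.32 = round(log2(1.25), 2), i.e. a ~1.25-fold change floor).
s0 damps the small-variance artifacts that make ordinary t-statistics
explode and keeps zero-variance rows finite. The null distribution comes
from group-label permutations: all distinct assignments of the pooled
channels when fewer than `n_perm` exist (20 for 3-vs-3), otherwise a
seeded uniform sample without replacement. For a symmetric cutoff c, the
estimated FDR is median over permutations of #{|d*| ≥ c} divided by
#{|d| ≥ c}; proteins are significant at the smallest cutoff with
estimated FDR ≤ the target. Testing is two-sided with a symmetric
cutoff; asymmetric cutoff pairs are out of scope. The formulation
follows the t-test-with-s0 tradition of SAM-style tools; numerical
equivalence with any particular implementation is not claimed, and the
exact formula above is the contract.

## What the simulators emulate — and what they do not

The generators produce every input dialect with planted truth under the
study's design: three groups, eight injections per sample, lognormal
multiplicative intensity noise at 10% CV (5% for envelope intensities),
Gaussian m/z jitter of 1 ppm, 1 nmol spiked standards, a 15-entry
histone panel, a TMT six-plex with two channels per state, and tracer
enrichments in the observed ranges (pyruvate/succinate 1–2%, lactate
10–15%, H3K18/23 acetyl 20–25%). Where the workflow states no value,
defaults are what a practitioner would call typical for an orbitrap
instrument (sub-ppm to ~1 ppm mass error, ~10% technical CV): chosen
once, documented here, and used everywhere.

Deliberate simplifications: compound libraries are random formulas with
mutually separated m/z, so matching ambiguity, isomers and co-elution do
not occur; retention times are decorative; detector response is shared
within a retention-time zone, making the zone-normalization assumption
exactly true rather than approximately; intensity noise is lognormal
with no censoring of low-abundance features; PSM-level reporter weights
are shared across channels, so summed aggregation is exactly unbiased;
there is no ratio compression from co-isolation interference. Passing
recovery tests on these data therefore demonstrates the correctness of
the arithmetic and the statistical calibration of the tests — not
robustness to isomer interference, matrix effects, missingness, or
response-factor violations in real instrument data.

Determinism: each generator seeds the Mersenne-Twister generator with
inversion normals, so a fixed integer seed yields byte-identical TSV
output across platforms.

## Problem sizes and numerical tolerances

The test suite and the acceptance script use sizes chosen to make the
statistical assertions sharp at interactive runtimes: 100 compounds for
match-rate checks, 50 compounds × 8 injections for concentration
recovery (median relative error < 5% follows from a ~14% per-measurement
CV averaged over 8 injections), formulas up to C40 for round-trip
correction (noise-free tolerance 1e-6; mean absolute bias < 0.01 at 5%
noise, n = 8), and 1000 proteins × 20 seeds at 3-vs-3 channels with 250
requested permutations for SAM calibration (null false-positive
proportion ≤ 3% at nominal 1%, sensitivity ≥ 80% for 1-log2-unit effects
at per-channel sd 0.2). Exact identities — SILAC bias cancellation,
d-statistic antisymmetry, z-score normalization — are asserted at
machine precision (1e-12).

## Known limitations

* Matching is charge-1-centric (multiply charged features are re-derived
  from the neutral mass but the library is expanded at z = 1 only), with
  no adduct types beyond protonation and no in-source fragment
  annotation.
* Concentration accuracy for zone-normalized compounds inherits the
  equal-response assumption; only labeled-analogue standards remove it.
* Natural-abundance correction models the tracer on carbon positions
  only; deuterium-label correction uses the same machinery but
  hydrogen's tiny natural abundance makes it near-identity.
* The permutation FDR is coarse with few distinct permutations (six for
  2-vs-2 channels, as in a six-plex with duplicate channels); power at
  the default layout is accordingly limited, and calibration claims are
  made at 3-vs-3.
* No peak picking, retention-time alignment, MS2 scoring, protein
  inference, isotope-impurity correction of reporters, or pathway
  analysis: inputs are assumed to be searched, grouped, integrated
  feature/PSM tables.
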