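---
title: "Methods: effect-directed screening of LC-HRMS feature tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: effect-directed screening of LC-HRMS feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edascreen)
```

# The problem

Nontarget screening of a complex extract (wastewater effluent, house dust,
serum) yields thousands of LC-HRMS features, almost all of which are
toxicologically irrelevant. Effect-directed analysis (EDA) inverts the
problem: the LC eluate is fractionated into the wells of a bioassay plate,
the wells are assayed, and chemical identification effort is spent only on
features that co-elute with bioactivity. `edascreen` takes over once the
vendor software has produced aligned feature tables: inclusion filtering,
hierarchical suspect annotation with quality coding, bioassay hit-calling,
retention-time-window mapping, and candidate prioritization.

# Models and procedures

## Isotope patterns and the isotopic-fit score

Theoretical isotope patterns are computed by exact convolution of the
per-element isotope distributions (isotope masses and abundances are pinned
to a versioned internal IUPAC table so results are bit-stable). The full
isotopologue distribution is kept un-binned during convolution — identical
to exhaustive enumeration, which the test suite exploits as a brute-force
oracle — and only compacted at the end: peaks within `resolution_bin`
(default 0.01 Da, realistic for QTOF data; fine structure below that width
is deliberately not resolved) are merged to their abundance-weighted
centroid, peaks below `prune` (default 1e-4) of the base peak are dropped,
and intensities are renormalized to base = 1. The labels `D` and `[13C]`
are treated as isotopically pure 2H/13C, appropriate for nominally fully
labelled internal standards.

The isotopic-fit score is deliberately simple: measured peaks are paired to
the nearest theoretical peak within a ppm tolerance, an unmatched
theoretical peak contributes its full intensity as residual, and the score
is 1000 × RMS of the residuals on the base = 1 scale. Commercial
implementations of mSigma are proprietary, so our scale may differ from any
particular vendor's by a constant factor; the conventional cutoffs (≤ 100
acceptable, ≤ 25 strict) are retained as defaults *on this package's scale*
and are configurable. A perfect fit scores 0 on any scale, and the score is
strictly increasing in any single residual, which is what the downstream
tiering actually relies on.

The `monoisotopic_is_base()` diagnostic addresses a concrete failure mode of
peak deconvolution for multihalogenated compounds: with ≥ 2 Br (or several
Cl) a heavier isotopologue is the most intense peak, and software that
assumes base peak = monoisotopic mass will report a wrong m/z, leaving the
compound invisible to formula-based annotation. Any feature whose measured
envelope fails the check is flagged `polyhalo_risk` and surfaces in the
report.

## MS/MS scoring

Library similarity is 1000 × cosine over square-root-transformed
intensities with greedy, injective nearest-mass peak pairing — symmetric,
bounded, scale-invariant, and deterministic (candidate pairs are accepted in
order of absolute mass error). Whether the original software's score used
forward, reverse or composite matching is not knowable from the outside;
metric and the 600 threshold are therefore exposed as configuration.
Fragment matching filters the spectrum to peaks > 1% of the base peak
(strictly greater), then assigns each peak to at most one candidate fragment
within 5 ppm. In-silico fragmentation itself is out of scope: fragment lists
are inputs.

## Inclusion filters

A feature is included when its aggregated sample intensity is ≥ 3 × the
blank intensity (inclusive at the boundary) and its replicate CV is ≤ 20%.
Choices the upstream description leaves open, fixed here and configurable:
the blank comparison aggregates by the mean across injections (`max` is
available); the CV uses the sample SD (n − 1) over the injections in which
the feature was detected; with fewer than two detected injections the CV is
*not evaluable* (`NA`, TAQ symbol `-`) rather than a failure — the
single-injection processing mode simply carries no replicate evidence.
Replicate grouping across injections is tolerance-based (10 ppm, 6 s
defaults): exported tables are already RT-aligned upstream, so a grouper —
not an alignment algorithm — is the right tool.

## TAQ code and confidence levels

Each annotation's evidence is encoded as six symbols in fixed order — mass,
RT, isotope fit, MS/MS, blank ratio, CV — with `2` strict pass, `1` loose
pass, `0` fail, `-` not evaluable. Tiers: mass 2 at ≤ 5 ppm / 1 at ≤ 10 ppm;
RT 2 at ≤ 0.1 min / 1 at ≤ 0.2 min; isotope 2 at mSigma ≤ 25 / 1 at ≤ 100;
MS/MS 2 when recorded with a library score ≥ 600, 1 when recorded without
one, 0 when not recorded; blank and CV are pass/fail. The strict tiers match
the instrument-specification cutoffs under which spiked standards are
reported (< 5 ppm, < 0.1 min, < 25 mSigma).

The TAQ → level map is a reconstruction constrained by every published
in-text statement about the levels, implemented as an explicit rule table so
alternates can be swapped in:

* **1** — `AL+` entry, mass/RT/isotope at least loose passes, MS/MS = 2;
* **2a** — `SL` entry, mass pass, MS/MS = 2;
* **2b** — `AL+` entry, mass/RT/isotope passes, MS/MS < 2 (diagnostic
  evidence: isotope-labelled standards without library spectra land here);
* **4\*** / **4** — formula-level evidence (mass + isotope) with / without
  recorded MS/MS;
* **5** — exact mass only;
* **3** — reachable only via boosting (below). How native level-3 calls
  were produced upstream is unstated, so the package never produces one on
  its own.

Entries whose class-specific evidence is incomplete (an `SL` entry without a
qualifying spectrum, an `AL+` entry failing RT) fall through to the
formula/mass rules rather than being rejected — a deliberate design choice:
negative evidence demotes, it does not erase the mass match. A failing blank
or CV criterion annotates the TAQ code but does not cap the level; the level
expresses identification evidence, the TAQ expresses overall quality. The
map is monotone: upgrading any single symbol never lowers the level
(property-tested exhaustively).

Primary-candidate selection takes the highest level; ties are broken by the
composite score |ppm|/10 + ΔRT/0.2 + mSigma/100 − score/1000 (absent
components contribute 0), then by name — deterministic and invariant to
suspect-list input order.

## Bioassay processing

Wells A3–H12 map row-major to fractions 1–80 (A3 → 1, A12 → 10, H12 → 80);
the ordering is a convention of this package, config-overridable, since the
plate layout itself does not fix it. Growth-assay responses are normalized
to % viability against the solvent-control mean; binding-assay responses to
% inhibition = 100 × (1 − raw/control mean) — the minimal reading of a
competitive fluorescence-displacement readout. The growth-assay hit
threshold is the procedure-blank mean − 3 × sample SD over all 80 PB
fractions (mean, not median; sample SD — both unstated upstream and fixed
here); a fraction is a hit when its replicate-mean response falls below it.
The binding assay uses a fixed 20% inhibition threshold. Contiguous hits
form active regions. Under a Gaussian null with the threshold at its
analytic value μ − 3σ the per-fraction false-positive rate is Φ(−3) ≈
0.00135, which the suite verifies by Monte Carlo over 10⁵ plates.

Dose–response uses the 4PL `bottom + (top − bottom)/(1 + (x/IC50)^slope)`
fitted by Levenberg–Marquardt (`minpack.lm`), initialized from the data
range and the concentration nearest the midpoint response. A fit is flagged
non-converged — never silently defaulted — when the optimizer fails, the
curve is flat, the IC50 leaves the tested range by > 100×, or (for
inhibition-type readouts) the fitted curve is not decreasing.
`min_sample_conc()` divides a mass-concentration IC50 by the plate's
enrichment factor, back-calculating the minimum sample concentration that
could explain a half-maximal well response.

## Retention-time windows and prioritization

Fraction *i* covers the core interval [(i−1) × 13.5 s, i × 13.5 s] (offset
`t0`, default 0). Because the fraction collector and the MS clock differ by
up to a few seconds, a 6.5 s margin (≈ half a fraction) is added on both
sides, making an unclipped selection window 26.5 s. Windows are clipped at
the run bounds (clipping, rather than negative times, was the choice made
here); adjacent selection windows therefore overlap by 13 s, and a compound
eluting on a fraction boundary is intentionally reported under both
fractions — membership is a closed-interval test, so boundary features are
never dropped. Core windows tile the run exactly; both properties are
asserted in the suite.

Isomer reduction keeps applicability-domain box-1 candidates; the reduction
fraction is 1 − |box 1| / (|all| − |box 4|). Box-4 outliers are excluded
from the denominator (the predictor cannot place them) but flagged for
reconsideration; unpredicted candidates stay in the denominator. Boosting a
4\* annotation to level 3 requires box 1 *and* ≥ 2 matched in-silico
fragments (the two most intense measured fragments in the motivating case).

# The synthetic-data generator

`generate_study()` emulates the study design: three isotope-labelled
antibiotic spikes at known RTs in positive mode, triplicate injections, two
ion modes, 80 fractions, a procedure-blank plate measured once and a sample
plate in triplicate. Distributional choices are the package's own, stated
here because no published values exist for them: background intensities are
lognormal (meanlog 11, sdlog 1.2), replicate noise is multiplicative
Gaussian at a 10% target CV, retention times are uniform over the 1080 s
run, plate noise is additive Gaussian (SD 4 on the percent scale — planted
effects of 50–60 are ≥ 10 × SD), 5% of background features are
blank-contaminated, 30% carry formulas drawn from the suspect pool, and
MS/MS is recorded DDA-style for the 100 most intense features per mode.
Spiked features meet the inclusion criteria by construction (blank-free;
replicate residuals standardized so the realized CV equals the target).

What passing end-to-end tests on these studies shows: the plumbing is
correct — filters, matching, tiering, hit-calling, window mapping and
selection compose without losing a planted signal, with recall 1.0 at
default noise and degradation only as plate noise grows. What it does not
show: robustness to real-data pathologies the generator deliberately omits
— chromatographic peak-shape distortion, co-elution and ion suppression,
mass-calibration drift, isotope envelopes corrupted by overlapping features,
or retention-time nonlinearity between replicates.

# Problem sizes and determinism

Default test problem sizes were chosen to exercise every code path at
interactive scale: 120–500 background features per table in the end-to-end
tests, 10⁵ plates for the Monte-Carlo calibration, brute-force isotope
oracles at ≤ 12 atoms (where exhaustive enumeration is exact and cheap).
Every stochastic step flows from a single integer seed — the generator,
the Monte-Carlo suites, and the CLI all accept one — and same-seed runs are
byte-identical.

# Known limitations

* The mSigma and MS/MS score scales are this package's conventions;
  thresholds tuned on vendor scales may need recalibration.
* No in-silico fragmentation and no retention-time QSAR: both are consumed
  as external inputs (fragment lists; box assignments).
* Charge support is |z| = 1; multiply charged adducts and charge-state
  deconvolution are out of scope, as is fine isotope structure below the
  resolution bin.
* Level-3 annotations arise only from boosting; native tentative-candidate
  calls require evidence types this package does not model.
* The binding-assay normalization is the minimal % inhibition reading; it
  does not model quench controls.
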