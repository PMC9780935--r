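---
title: "Rule-based suspect screening of xenobiotic metabolites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based suspect screening of xenobiotic metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suspectms)
```

## The problem

When an animal is dosed with a xenobiotic such as the monoterpene
D-limonene (C10H16), the compound is oxidized by phase I enzymes
(hydroxylation, epoxidation followed by hydrolysis to a diol,
carboxylation, hydrogenation) and the oxidized products are conjugated by
phase II enzymes with glucuronic acid, sulfate, glycine or taurine before
excretion. Untargeted LC-HRMS of urine or tissue extracts yields thousands
of features (m/z, retention time, per-sample intensities), almost all of
them endogenous. Suspect screening turns the annotation problem around:
instead of identifying unknowns, it enumerates every plausible
biotransformation product of the known parent in advance and asks which
observed features match one of those candidates.

`suspectms` implements that strategy as four composable stages --
candidate enumeration, exact-mass matching, MS/MS and isotope
corroboration plus control-group exclusion, and dose-group profiling --
together with a seeded cohort simulator that makes every stage testable
without instrument data.

## Mass arithmetic

All masses derive from a fixed internal table of monoisotopic atomic
masses (C 12 exactly, H 1.00782503, N 14.00307401, O 15.99491462,
S 31.97207117 Da) and the electron mass (0.00054858 Da). Ion m/z for the
singly charged species are

* `[M-H]-` = M − m(H) + m(e)
* `[M+H]+` = M + m(H) − m(e)

The electron term matters: at m/z 350 it is worth about 1.6 ppm, and
omitting it systematically shifts all computed errors by more than the
mass accuracy of a calibrated qToF. Mass errors are reported as signed ppm
with the convention `(theoretical − observed)/theoretical × 1e6`, so an
observed ion heavier than theory gives a negative error; that convention
matches how identification tables in the xenobiotic-metabolism literature
print their error columns. Displayed errors are rounded to one decimal;
all comparisons use full precision.

Isotope patterns are simulated coarsely, aggregated by nominal mass offset
(M+0, M+1, ...) through exact convolution of the per-element natural
isotope abundance vectors, one atom at a time. Fine isotopic structure is
not resolved -- the pattern check this supports is qualitative agreement of
relative M+1/M+2 abundances, not isotopologue-level fitting. The default
pattern is truncated at offset 3 and pruned at 1e-4 of the base peak.
Pattern agreement is scored as `1 − mean(|a_obs − a_theo|)` over the
union of offsets, floored at zero. Because the underlying study states
that patterns were "checked" without giving a criterion, the score is
advisory by default: it is recorded on each hit, and only a score below a
floor (default 0.5) rejects an annotation.

## The candidate library

A biotransformation rule is a formula delta: atoms added and removed, a
phase tag, a label token, and a multiplicity bound. The default rule set
for monoterpene screening is

| rule | delta | phase | bound | gate |
|---|---|---|---|---|
| carboxylation `+COOH` | +O2 −H2 | I | 1 | provides oxygen + carboxyl handle |
| hydroxylation `+OH` | +O | I | 1 | provides oxygen handle |
| diol `+OH+OH` | +O2H2 | I | 1 | provides oxygen handle |
| hydrogenation `+H2` | +H2 | I | 2 | — |
| dehydrogenation `-H2` | −H2 | I | off | optional toggle |
| glucuronidation | +C6H8O6 | II | 1 | needs oxygen handle |
| sulfation | +SO3 | II | 1 | needs oxygen handle |
| glycine conjugation | +C2H3NO | II | 1 | needs carboxyl handle |
| taurine conjugation | +C2H5NO2S | II | 1 | needs carboxyl handle |

Enumeration forms every multiset of phase I rules within the per-rule
bounds and a global bound of four steps, then optionally appends one
conjugate whose chemical prerequisite is satisfied. The gates encode the
observation that conjugation requires a functional handle: an ester-type
conjugate (glucuronide, sulfate) needs an oxygen introduced in phase I,
and an amide-type conjugate (glycine, taurine) needs the carboxyl group.
Without the gates the library would contain chemically absurd species such
as a glucuronide of the bare hydrocarbon. With the defaults the limonene
library holds `r nrow(enumerate_candidates("C10H16", default_rules()))`
candidates. Dehydrogenation is shipped but disabled by default because no
reference metabolite requires it; enabling it roughly doubles the library.

Labels are canonical: parent id, phase I tokens in the fixed order
`+COOH`, `+OH`, `+OH+OH`, `+H2` (repeated), then the conjugate token, so
the same multiset always produces the same label and reports are
diff-stable. Candidates are formula-level objects: positional isomers
(e.g. the 1,2- versus 8,9-diol) are indistinguishable by mass, share one
label, and are suffixed I/II/III downstream purely by ascending retention
time.

## Matching and corroboration

MS1 matching accepts every (feature, candidate) pair within a ppm
tolerance (default 10 ppm, the conventional identification window for
qToF screening). Hits for one feature are ranked by absolute ppm error,
then by the number of transformations -- the parsimony assumption that a
simpler metabolic route is the more plausible explanation of an isobaric
tie -- and ties are reported rather than dropped. One consequence worth
knowing: the scaffold reached by carboxylation plus two hydrogenations is
isobaric with the one reached by diol plus hydroxylation (both net
+O3H2 on a C10 skeleton after conjugation), so a feature such as the
dihydroxylated acid glucuronide carries both candidates at identical ppm
error and the parsimony rule ranks the shorter route first. MS/MS evidence
is the instrument's way of breaking such ties; the ranked tie keeps the
alternative visible.

MS/MS corroboration is class-based. Each conjugate class has diagnostic
fragment anions and neutral losses, all derived from formulas through the
same mass kernel:

* glucuronide -- the glucuronic acid anion ladder C6H7O6⁻ 175.0248,
  C5H5O3⁻ 113.0244, C4H3O3⁻ 99.0088, C4H5O2⁻ 85.0295, C2H3O3⁻ 75.0088,
  C2H3O2⁻ 59.0139; neutral loss C6H8O6 (176.0321) reveals the aglycone.
* sulfate -- the SO3 radical anion 79.9574; neutral loss SO3.
* taurine -- C2H6NO3S⁻ 124.0074, C2H3O3S⁻ 106.9808, SO3 79.9574. The
  amide can cleave on either side of the nitrogen, so both C2H5NO2S
  (ester-type, nitrogen leaves with the conjugate) and C2H4O3S
  (amide-type, nitrogen retained on the aglycone) are accepted as
  complement-defining neutral losses.
* glycine -- the glycinate anion C2H4NO2⁻ 74.0247; losses CO2 and HCOOH.

Fragment matching uses an absolute tolerance of 0.005 Th by default;
printed fragment lists in the reference data deviate from theory by up to
about 5 mTh, and a ppm tolerance would be too tight at the low masses of
the diagnostics. A diagnostic heavier than the precursor is never matched.

Control-group exclusion operationalizes "the metabolite must be absent in
non-exposed animals" as near-absence: a hit is excluded when its mean
intensity in any control group exceeds 5% of its mean across exposed
samples. Strict zero would be brittle against integration noise; 5% is
this package's choice and is configurable.

Confidence levels follow the putative-annotation tiers of metabolomics
reporting standards: level 2 when at least one diagnostic fragment or
aglycone complement is matched, level 3 for MS1-only hits, and rejection
only on a failing isotope score. Level 1 is never assigned because the
pipeline has no concept of an authentic-standard comparison.

## Dose profiling and switching

Urinary intensities are divided by the sample's creatinine concentration
to correct for urine dilution, then summarized per metabolite and dose
group as the arithmetic mean (a non-detected metabolite contributes 0) and
expressed as percent of the group's total metabolite signal. Percent
compositions sum to 100 exactly, so the per-metabolite differences between
two dose groups sum to zero, and "metabolic switching" -- a
dose-dependent change in which routes dominate -- appears as a pattern of
compensating positive and negative percent shifts. The switching report
classifies each shift as increased/decreased/stable with a ±0.5
percentage-point dead band; the dead band is an implementation choice to
keep trace metabolites from flapping between categories.

Two-group hypothesis tests route through a Shapiro-Wilk normality check at
alpha 0.05 on both groups: both normal gives a two-sided two-sample
t test, otherwise the Wilcoxon rank-sum test; the returned record states
which branch ran. No multiple-testing correction is applied across
metabolites by default, mirroring common practice in this literature for
per-metabolite dose contrasts (a Benjamini-Hochberg adjustment can be
applied to the returned p values with `p.adjust`). Only the two-group path
is implemented; multi-group phenotype statistics are out of scope.

Dose accounting is plain arithmetic kept in one place: percent loss of the
analyte between nominal and measured feed content, and human-equivalent
doses via body-surface-area scaling (HED = dose × Km_animal / Km_human,
mouse 3, human 37). Note that an HED recomputed from a rounded printed
intake can differ from a published HED computed from the unrounded value
(90 mg/kg × 3/37 = 7.3, not 7.2); the function documents, and does not
force, agreement.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the pipeline
assumes, not raw spectra:

* planted metabolite features at theoretical `[M-H]-` m/z perturbed by
  Gaussian jitter with SD 2 ppm by default (calibrated-qToF accuracy);
* per-animal intensities log-normal around group means with CV 0.4 by
  default, the order of the high inter-individual variability reported
  for xenobiotic metabolism (sdlog = sqrt(log(1+CV²)), mean-preserving
  parameterization);
* strict zeros for planted metabolites in control groups (a `leakage`
  option exists to stress-test the exclusion stage);
* decoy background features at uniform m/z, rejection-sampled to stay at
  least 0.05 Th from every library mass so that false-positive tests are
  unambiguous (0.05 Th is far beyond 10 ppm below m/z 1000);
* per-sample creatinine log-normal with CV 0.3;
* template MS/MS spectra for conjugated candidates (class diagnostics
  plus aglycone complement) with per-fragment dropout and abundance
  jitter;
* a mandatory integer seed; identical configurations are bit-identical.

The demo preset `reference_sim_config()` plants the 16 urinary metabolite
identities of the packaged reference set with group means proportional to
the reported percent-of-total columns of the 0.1% and 0.8% dose groups,
eight animals per group -- the scale of a typical rodent feeding
experiment.

What the generator does **not** emulate: chromatographic peak shape,
retention-time structure (planted retention times are uniform draws),
in-source fragmentation, correlated isotopologue features, matrix-dependent
ionization suppression, or heavy-tailed intensity outliers. Tests passing
on synthetic cohorts therefore demonstrate the pipeline's statistical
correctness under its stated model, not robustness to every pathology of
real LC-MS data.

## Numerical choices and degenerate inputs

* Atomic masses and abundances are frozen constants; changing them is a
  code change, not a configuration, so value-level tests are stable.
* Formula subtraction and transformation application fail loudly on
  negative counts or a carbon-free product rather than silently clamping.
* `percent_of_total` refuses an all-zero group; `normalize_by_creatinine`
  refuses non-positive creatinine.
* CV = 0 and sigma = 0 are exact degenerate cases in the simulator (no
  RNG noise consumed for them beyond draw order), which the tests use to
  pin means and masses exactly.
* Isotope convolution keeps probability-weighted mass sums alongside
  probabilities, so per-offset m/z values are exact expectations, and the
  unpruned distribution conserves total probability to 1e-9 for formulas
  of up to ~30 atoms within the truncation window used by the tests.

## Problem sizes used by the test suite

The suite screens the packaged 23-feature reference set against the
85-candidate default library, checks isotope distributions against a
brute-force multinomial oracle for formulas up to ~30 atoms, estimates
m/z-jitter calibration from about 10,000 planted features, measures
recall and false-annotation counts over 10 simulated cohorts of 16 planted
metabolites and 30 decoys each, and checks switching-direction recovery
over 100 seeded replicates at 8 animals per group. These sizes keep the
whole suite under a couple of minutes on one CPU while leaving the
Monte-Carlo margins comfortable.

## Known limitations

* Candidates are molecular formulas, not structures: the library cannot
  distinguish positional isomers, cannot bound how many distinct isomers
  are chemically reachable, and cannot arbitrate isobaric multisets
  (see the parsimony note above) without MS/MS.
* Negative mode only; no rules are shipped for positive-mode adducts
  because the reference identifications are all deprotonated species.
* Only ±H adducts of singly charged ions; no multimers, no multiple
  charging.
* The creatinine model treats the assay value as exact; assay error
  propagates directly into normalized intensities.
* Retention time is never used for identity, only for isomer ordering --
  there is no retention prediction.
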