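---
title: "Models and methods behind hdxdigly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hdxdigly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxdigly)
```

This vignette explains the models implemented in `hdxdigly`, the
parameters that matter, the design choices made where the design was
genuinely open, and what the simulation-based tests do and do not show
about real instrument data.

## The exchange model

Backbone amide hydrogens exchange with solvent deuterium. In the EX2
limit — the regime assumed throughout, appropriate for native-state
proteins under physiological labelling conditions — each amide behaves
as an independent first-order process and the population-average
deuterium fraction after labelling time $t$ is

$$f_i(t) = 1 - e^{-k_{\mathrm{obs},i}\,t}, \qquad
  k_{\mathrm{obs},i} = k_{\mathrm{int},i} / P_i,$$

where $k_{\mathrm{int},i}$ is the intrinsic (unstructured-context)
rate of residue $i$ and $P_i \ge 1$ its protection factor
($\log_{10} P = 0$ means fully disordered). A single exponential per
amide is the simplest law reproducing the observable this package
measures: monotone uptake curves over a 15–120 s labelling window, the
time regime in which allosteric transitions are best captured.

Intrinsic rates follow the poly-DL-alanine reference-rate scheme:
acid-, base- and water-catalysed terms with published side-chain
inductive corrections for the residue carrying the amide and its
predecessor, corrections for the charged chain termini, Arrhenius
temperature scaling (activation energies 14/17/19 kcal mol⁻¹) and the
D₂O autoionisation constant ($pK_D = 15.05$). Ionisable side chains
(Asp, Glu, His) use their high-pD forms, appropriate near the default
labelling conditions of pD 8.0 and 298.15 K (Tris-HCl pH 8.0, 25 °C).
Two simplifications are deliberate: side-chain p$K$ shifts with
temperature are ignored, and $pK_D$ is treated as
temperature-independent — both effects are small against the order-of-
magnitude scale on which protection factors act, and neither disturbs
the monotonicity-in-temperature contract. A `mode = "uniform"`
fallback assigns one flat rate to every exchangeable amide; it exists
because many properties (saturation, back-exchange recovery) are
cleanest to verify when kinetics are trivial.

Position 1 of any chain carries an α-amine rather than a backbone
amide, and prolines have no amide hydrogen, so both are flagged
non-exchanging. At the peptide level the exchangeable-amide count is
$N - 1 - \#\{\text{prolines at positions } 2..N\}$: exactly one
N-terminal residue is excluded, the convention of the commercial HDX
software whose y-axis limits this count reproduces. Whether that
software excludes one or two residues is genuinely ambiguous; the
one-residue convention was chosen and is isolated inside
`exchangeable_amides()`, so changing it is a one-line edit.

## Envelopes and centroids

Deuterium uptake is measured as a centroid difference, so peak shapes
are irrelevant and a unit-resolution aggregated isotope distribution
suffices. `natural_envelope()` convolves exact per-element isotope
distributions (binary exponentiation over atom counts; classes below
$10^{-15}$ probability dropped) from residue elemental compositions.
Deuteration convolves the envelope with the exact Poisson–binomial
distribution of deuteron counts given per-amide fractions, shifting
each class by multiples of $\Delta m_D = m(^2\mathrm{H}) -
m(^1\mathrm{H}) = 1.00628$ Da. Because the centroid is linear, the
shift equals $\Delta m_D \sum_i f_i$ exactly, and
`uptake_from_centroids()` inverts it; the round-trip identity is
property-tested to $10^{-9}$ deuterons. Small negative raw uptake
values under noise are reported as-is and only clipped after
back-exchange correction.

## The forward simulator

`simulate_exchange_dataset()` emulates the observables of a two-state
labelling experiment at its default study conditions: deuteration
times {15, 30, 45, 60, 120} s, 3 technical replicates, a global
back-exchange fraction of 0.25, and Gaussian centroid noise. The
measured deuterated centroid is

$$\bar m = \bar m_{\mathrm{control}} +
  \Delta m_D\,(1-b)\sum_i f_i(t) + \varepsilon,
  \qquad \varepsilon \sim \mathcal N(0, \sigma^2),$$

with noise applied on the mass scale (Da), where the instrument
actually measures, so that it propagates through centroid differencing
exactly as real replicate scatter would. Where the defaults come from:
the five-point 15–120 s grid with triplicates is the standard
short-timescale labelling design for capturing allosteric transitions;
25% is a typical magnitude for a global back-exchange factor on a
quench-and-digest workflow; replicate noise has no canonical value, so
$\sigma = 0.02$ Da — giving replicate SEMs of a few hundredths of a
deuteron, the scale visible on published uptake plots — is a config
knob, not a claimed value.

Three further choices deserve a note:

* **Controls are emitted noiseless.** The undeuterated control is
  averaged over many scans and manually checked in practice, and a
  noisy shared control would inject a common offset into every
  timepoint of a (peptide, state) cell, correlating tests that the
  downstream statistics treat as independent. With noiseless controls
  the per-cell measurements are i.i.d. and the caller's type-I
  behaviour can be audited cleanly.
* **Back exchange is a uniform multiplicative loss** applied after
  labelling, matching the single global correction factor used
  downstream; no per-residue quench kinetics are modelled.
* **Random streams are split per (peptide, state, time, replicate)**
  by hashing the record coordinates into a private seed, so extending
  a map never reshuffles existing draws. The generator is warmed up
  (ten discarded uniforms) after each seeding: the first
  Mersenne–Twister output after `set.seed` is weakly correlated across
  related seeds, and without the warm-up the replicate noise is
  measurably miscalibrated.

Peptide maps are deterministic overlapped tilings (default 10-mers,
5-residue overlap) with optional seeded length jitter — a stand-in for
pepsin's broadly non-specific cleavage that guarantees full coverage.
The first and last `disordered_termini` residues (default 10) of every
state are forced to $\log_{10} P = 0$, so a simulated experiment
always contains the disordered terminal peptides the back-exchange
estimator requires, mirroring how the factor is determined from
disordered termini of real sample proteins.

What the simulator does **not** emulate: EX1/bimodal envelopes,
retention-time drift, ion-mobility artefacts, carry-over between
injections, peptide-dependent back exchange, and inter-batch
(biological-replicate) variance. Passing tests therefore demonstrate
the correctness of the computations and the calibration of the
statistics under idealised EX2 Gaussian conditions — not robustness to
every pathology of real data.

## Uptake pipeline

The back-exchange estimator uses peptides lying wholly within a
terminal window (default 10 residues; the window is a parameter
because "disordered termini" has no canonical width) and the longest
timepoint only, where saturation is most complete and kinetic bias
smallest. The factor is $1 - \overline{D/N}$, clamped to $[0, 0.9]$.
Correction divides by $1-b$ — the convention that restores saturated
disordered peptides to 100% of their amides — rather than multiplying
the deficit; the alternative reading is isolated in
`correct_uptake()`. The factor is global per experiment, singular by
construction.

Summaries are mean ± SEM over technical replicates (SEM absent below
two replicates). Display fits use a bounded single exponential
$D(t) = A(1-e^{-kt})$, $0 \le A \le N$, $k > 0$, solved by
Levenberg–Marquardt with an analytic initial rate; an all-zero curve
returns $A = 0$ with the rate flagged unidentifiable, and
non-convergence is reported, never silently defaulted. A single
exponential is a presentation-level summary — five timepoints cannot
support a multi-exponential decomposition — and its parameters carry
no kinetic interpretation here.

## Differential statistics

Identification-quality thresholds (score 6.5, 0.2 products per amino
acid, 5 ppm, 5% retention-time SD, ≥ 2 of 3 runs) are applied
inclusively: a "cutoff of 6.5" reads as the minimum acceptable value.
The evidence-table score cutoff is strict because it is conventionally
quoted as a strict inequality (−10 log P > 15).

The significance rule is: two-way ANOVA (state × time) on
replicate-level uptake, **and** at least one per-timepoint two-sample
t-test, both below $\alpha = 0.05$. This conjunction is one reading of
"ANOVA analyses and t-tests"; both p-value layers are reported
unmerged so alternative composite rules can be audited, and no
transience statistic is invented for protections that vanish by the
longest timepoint — the per-timepoint columns make such patterns
visible directly. No multiple-testing correction is applied by
default, matching the uncorrected p < 0.05 convention of the HDX
software this pipeline mirrors; Benjamini–Hochberg is available via
`p_adjust = "BH"`.

The per-timepoint test defaults to the pooled-variance Student t
rather than Welch. With three replicates per state, Welch's
approximation is markedly conservative (its measured size at
$\alpha = 0.05$ is near 0.03), which would defeat the type-I
calibration the test suite enforces; the pooled test is exact under
the equal-variance Gaussian noise the simulator generates and the
instrument plausibly produces. `t_variant = "welch"` restores the
unequal-variance form for data where the homoscedasticity assumption
is doubtful. Verdict direction follows the sign of the uptake
difference at the most significant timepoint; because back-exchange
correction is a monotone map, verdicts computed on raw and corrected
uptake coincide (asserted by test).

Residue-level classification is a majority consensus over the
significant peptides covering each residue, with exact ties flagged
`ambiguous` and uncovered residues `no-coverage`. Two practical notes
for interpretation: a region call is reliable to roughly one peptide
overhang (with 10-mers overlapping by 5, up to 9 residues of
overhang at each edge), and with an uncorrected $\alpha = 0.05$ rule
over dozens of peptides, isolated single-peptide calls with small
effect sizes are expected false positives — regions should be read as
contiguous blocks with material Δuptake, which is how the test suite
asserts localisation.

## diGly occupancy and linkage

Occupancy at lysine $p$ sums **areas**, not spectral counts: diGly
evidence at $p$ over all evidence covering $p$ (`start ≤ p ≤ end`,
any modification state). Because samples are chemically acetylated
before digestion, unmodified lysines appear acetylated and uncleaved,
so the denominator legitimately includes acetylated and
missed-cleavage forms alike — whether missed-cleavage diGly forms
belonged in the original denominator is ambiguous, and both are
included here (flagged for audit in the function documentation). A
lysine with covering evidence but no diGly has occupancy 0; a lysine
with no covering evidence is reported `no-coverage`, not 0 — the
distinction between "observed unmodified" and "never observed"
matters when few lysines are modified at all. A diGly claimed on a
non-lysine position is rejected and logged, never silently dropped.

Linkage usage classifies diGly positions on ubiquitin-mapped evidence
by lysine identity (or M1 for linear chains), validated against an
in-silico tryptic digest (cleave after K/R, not before proline, up to
three missed cleavages) of the canonical 76-residue human ubiquitin
shipped as a FASTA fixture. Area fractions sum to one over observed
linkages.

Mass arithmetic is derived from exact isotope masses and residue
elemental compositions: the diGly remnant is two glycine residues
(114.043 Da, printed 114.04) and the leu-enkephalin lock mass follows
from YGGFL plus a proton (556.277 at three decimals).

## Problem sizes and numerical choices

The test suite and acceptance script run entirely on simulated data at
desk scale: 110–160-residue proteins for recovery and localisation
checks, a 1010-residue protein tiled into ~500 peptides for type-I
calibration (≈2500 peptide-timepoint tests), 200 Monte-Carlo draws for
fit-stability, and 50 evidence rows per site for occupancy recovery —
sizes chosen so the whole suite completes in about a minute while
keeping binomial confidence bands tight enough to detect
miscalibration. Determinism is enforced by golden comparisons of
simulator output under fixed seeds. Numerical tolerances: centroid
round-trips and noiseless recoveries at $10^{-9}$; isotope classes
pruned below $10^{-15}$ probability ($10^{-10}$ for emitted peaks);
degenerate statistical inputs (constant replicates) resolved by the
sign of the observed difference rather than an undefined t statistic.

## Known limitations

No EX1 or bimodal-envelope deconvolution; no per-residue uptake
deconvolution from overlapping peptides; no charge-state or
ion-mobility modelling; no branched/mixed ubiquitin-chain topology
inference; biological-replicate variance is outside the simulator, so
the SEMs here are technical-replicate SEMs only, as on the plots this
package reproduces.
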