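---
title: "Methods: quantifying thalamocortical synapse and barrel development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying thalamocortical synapse and barrel development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barreldev)
```

## Scope and shape

`barreldev` implements the quantitative core of a developmental study of
thalamocortical (TC) synapses in mouse barrel cortex: minimal-stimulation
EPSC analysis, inference of shared presynaptic axons from paired recordings,
exact comparison of connectivity rates between genotypes, and histological
quantification of barrel segregation and axon numbers. No raw recordings or
micrographs are deposited for studies of this kind, so the package pairs
every analysis with a synthetic-data generator that reproduces the
statistical structure the analysis assumes; the generators are first-class,
tested code, not fixtures. The repository is organised as an analysis
workflow: the numbered scripts under `analysis/` are thin narrative drivers
that regenerate the whole synthetic study into `results/`, while every
computation lives in the package so the tests and the acceptance script
exercise identical code paths.

## Synthetic electrophysiology

A minimal-stimulation experiment holds one cell in voltage clamp while a
single TC axon is stimulated at low rate. Each trial either fails
(probability `p_failure`) or produces an EPSC. The generator models the EPSC
as a difference of exponentials,

$$w(t) = A\,\frac{e^{-t/\tau_{decay}} - e^{-t/\tau_{rise}}}{w_{peak}},$$

normalised so that the noiseless extremum equals the configured amplitude
exactly — amplitude semantics stay exact rather than depending on the
kinetic constants. At a holding potential of −70 mV the current is inward
(negative) and treated as purely AMPA-mediated: the NMDA component defaults
to zero there, a full-Mg²⁺-block approximation with a configurable residual
fraction. At +40 mV the current is outward and both components contribute.
Trial-to-trial amplitude variability is a lognormal scale factor with unit
mean and coefficient of variation `amp_cv`; recording noise is white
Gaussian.

Defaults are the published wild-type operating points at the start of the
critical period: failure rate 0.48 over 28 trials per experiment, AMPA decay
tau 3.3 ms, NMDA decay tau 71 ms (43 ms for the knockout-like
configuration), single-axon EPSC amplitude ≈ 40 pA and an NMDA:AMPA ratio of
0.84. Values never printed in a paper of this kind were fixed once at
field-realistic levels and not revisited: 10 kHz digitisation (`dt_ms =
0.1`), 2 pA baseline noise SD, amplitude CV 0.2, rise constants 0.5 ms
(AMPA) and 5 ms (NMDA). One explicit seed per generator call makes every
dataset bit-reproducible, and the caller's RNG stream is restored on exit.

What the generator does **not** emulate: stimulus artefacts, series-
resistance drift within a sweep, polysynaptic contamination, temperature or
liquid-junction effects, and the voltage dependence of NMDA kinetics. Green
tests therefore certify the analysis pipeline against its own statistical
assumptions, not against every failure mode of real recordings.

## Event detection and quality control

The success/failure criterion is never stated explicitly in studies of this
kind, so the package uses the conventional minimal-stimulation rule with
both constants exposed: a trial is a success if the baseline-subtracted
extremum magnitude inside a 1–15 ms post-stimulus window exceeds
`max(3 × baseline SD, 5 pA)`. Before measurement the trace is smoothed with
a 0.5 ms boxcar. This mirrors the analogue low-pass filtering of the
recording chain and matters quantitatively: an extremum search over ~140 raw
samples at 10 kHz would cross a 3 SD threshold on roughly a third of pure-
noise sweeps, whereas after smoothing the false-positive rate at the default
floor is negligible and the EPSC peak is attenuated by under 0.3%. Per-sweep
series resistance follows the whole-experiment rejection rule: any deviation
beyond 20% of the initial value discards the experiment.

Averages exclude failures, so the mean amplitude estimates potency. The
NMDA amplitude at +40 mV defaults to the peak of the failure-excluded
average; a fixed late-window mean (40–60 ms, after the AMPA component has
decayed) is available as an alternative because the original convention is
ambiguous. Decay kinetics come from a Levenberg–Marquardt fit of
$A e^{-(t-t_0)/\tau} + C$ to the averaged trace. The fit window *starts at
twice the peak latency* rather than at the extremum: at the peak of a
difference-of-exponentials waveform the rising phase still contributes a few
percent and biases a single-exponential tau by 2–5%, while one additional
peak-latency later the residual rise term is negligible (<0.6% bias for both
published taus). The offset term `C` absorbs holding-current drift; tau is
initialised from the 1/e-crossing time and fits are declared unconverged
outside (0.1, 10⁴) ms. Fitting is done on failure-excluded averages, not per
sweep, matching how example traces are presented; per-sweep fitting at these
noise levels is substantially less stable.

## Shared-axon inference

If a stimulated axon contacts both simultaneously recorded cells, successes
coincide far more often than chance. With per-cell empirical success rates
$\hat p_A, \hat p_B$ over $n$ trials and $k$ coincident successes, the
default (joint) null refers $k$ to $\mathrm{Binomial}(n, \hat p_A \hat
p_B)$ and the classifier calls the pair *shared* when the upper-tail
probability falls below α = 0.05. The published criterion names "the chance
level of coincident successes given the success rate in each cell", which is
symmetric in the two cells; that reading motivates the joint default. The
alternative conditional formulation — $k$ referred to
$\mathrm{Binomial}(\text{A-successes}, \hat p_B)$ — is implemented and
selectable because the wording also admits it. Classification is based on
coincident successes only; coincident failures, which the figure legends
mention descriptively, carry little extra information once the marginal
rates are conditioned on, and no test on them is specified. Plug-in
empirical rates are used without continuity correction.

The paired-cell generator mirrors this structure: in shared mode one release
sequence (probability `p_release`, default 0.52, the complement of the 0.48
failure rate) is thinned independently per cell by detection probabilities
(`detect_b` default 0.92, the published coincident-success proportion); in
independent mode the two cells are independent Bernoulli streams. Under the
independent-axon null at the published operating point the classifier's
type-I error is below the nominal level (the binomial tail test is
conservative at discrete counts), verified over 10,000 simulated pairs.

## Barnard's unconditional exact test

Connectivity rates are compared across genotypes with Barnard's exact test,
implemented from first principles: for a 2×2 table with fixed row totals
$n_1, n_2$, the statistic is the pooled-variance Wald score on the
difference of proportions (zero-variance tables score 0), and the p-value is
the supremum over the nuisance common success probability π of the total
probability of all outcome tables at least as extreme as the observed one.
The supremum is evaluated on a π grid of step 0.001 followed by a continuous
local optimisation around the best grid point; refining the grid further
changes the p-value by less than 10⁻⁶ (tested), and the implementation is
verified against an independent brute-force enumeration on every table with
row totals ≤ 6. Extremeness is by |score| for the two-sided test and by
signed score for directional tests.

A reproduction note that matters for this study: on the published
classification counts (5 shared of 9 wild-type pairs versus 4 of 21 knockout
pairs) the two-sided pooled-Wald Barnard p is 0.0472, which prints as 0.05
at one significant figure, while the *directional* pooled-Wald p is 0.0414,
which prints as the published 0.04. Boschloo-style variants give 0.031 and
0.061 and match neither. The package therefore defaults to the conventional
two-sided test but exposes `alternative`, and the reproduction scripts
report both, treating the directional value as the one consistent with the
published figure. Barnard's test is uniformly at least as powerful as
Fisher's exact test here; the suite checks that dominance on the published
table.

## Histology quantification

Barrel segregation is scored on nuclei point fields: the barrel is modelled
as an explicit annulus geometry (hollow disc of radius `r_hollow`, wall
annulus to `r_wall` — supplied, not inferred from staining, since no
boundary-detection algorithm is specified for such data). Per optical
section the score is (wall count / wall area) / (hollow count / hollow
area); sections with an empty hollow are undefined and skipped; the stack
score is the maximum over sections, matching the best-optical-section
convention. The maximum of noisy ratios is biased upward; at ≥10⁴ points per
section over a 5-section stack the bias stays under 10% (tested), and the
per-section ratio is a consistent density-ratio estimator. The synthetic
fields are homogeneous Poisson processes with separate densities for hollow,
wall and surround, 3 µm section spacing by default.

Axon counts use the traversal rule: a segment is counted once if it
intersects *both* long edges of a 100 × 30 µm region of interest, so each
through-running axon contributes exactly one count and terminal fragments
are excluded; an intersect-anywhere mode is exposed. Counting is performed
in the ROI's own frame and is invariant under joint rigid motion of ROI and
segments (tested). Areas of traced regions use the shoelace formula on
µm coordinates of flattened sections (converted to mm² by 10⁻⁶) after an
explicit simplicity check; the patch proportion is the summed patch area
divided by the barrel-subfield area. On the published group means (0.165 mm²
of patches within 1.21 mm²) this quotient is 0.1364 — slightly different
from the published 0.135, which is a mean of per-animal ratios rather than a
ratio of means.

## Summary statistics

Group tests run on within-animal averages (one value per animal, computed by
`within_animal_means()`) or directly on published (mean, SEM, N) triplets.
`t_from_summary()` reconstructs SDs as SEM·√N and supports both the pooled
(df = n₁+n₂−2) and Welch–Satterthwaite forms; applied to summaries computed
from raw data it matches `stats::t.test()` to 10⁻¹⁰ (tested). Because the
published triplets are rounded, p-values recomputed from them agree with
published values only to printed precision; the suite encodes this as
"within one unit in the last printed digit". The brain-mass comparison
illustrates the limit: Welch from the printed summaries gives 8.5 × 10⁻⁵
against a published 8 × 10⁻⁵. The Mann–Whitney test (used for NMDA:AMPA
ratios, which are not normally distributed) uses midranks, the exact null
for both group sizes ≤ 8 without ties, and a tie-corrected normal
approximation otherwise, without continuity correction. Paired designs
(ifenprodil block) use the paired t on differences; identical pairs return
t = 0, p = 1, while a constant non-zero shift (zero difference variance) is
reported as degenerate data rather than an infinite t. The two-way
ANOVA with Holm–Šidák post-hoc used for one kinetics figure is out of scope;
the corresponding comparisons are reported via the implemented tests and
annotated as such.

## Problem sizes and numerical choices

The test suite and reproduction scripts run at desk scale, chosen so the
Monte-Carlo error of each check is several times smaller than its tolerance:
10,000 pairs for the type-I property, 50 replicate experiments per tau for
decay recovery (≥90% within 10%, noiseless within 1%), ≥10⁴ points per
section for segregation recovery (within 10% at ratios 1.6 and 1.8),
full enumeration for Barnard (row totals ≤ 6) and Mann–Whitney
(group sizes ≤ 6) oracles. Degenerate inputs fail loudly with classed
conditions (`barreldev_config_error`, `barreldev_data_error`,
`barreldev_schema_error`, `barreldev_insufficient_data_error`,
`barreldev_geometry_error`) so the pipeline runner can attribute failures to
stages; `run_pipeline()` records a failed stage and continues with the rest.

## Known limitations

Published group differences measured on real animals (axon counts, areas,
brain mass) cannot be reproduced from deposited data because none exist;
they are covered by regenerating the effect directions synthetically and by
the printed-summary tests above. The coincidence classifier assumes
stationary success probabilities across trials; drift in release probability
would inflate coincidences under the independent null. The segregation score
depends on user-supplied annulus geometry, and the best-of-stack maximum is
a biased estimator by construction — comparisons between groups scored the
same way remain valid, absolute values should be read with the bias in mind.
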