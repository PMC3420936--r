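---
title: "Measuring and modelling chromosomal supercoil density with resolution sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling chromosomal supercoil density with resolution sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supercoilr)
```

## The measurement problem

Negative supercoiling in a bacterial chromosome comes in two forms: a
*constrained* part (sigma_C) locked up by bound proteins, and a *diffusible*
part (sigma_D) that migrates freely within topological domains of roughly
10 kb; the total density is sigma = sigma_C + sigma_D. Classical plasmid
reporters average over the whole cell and miss local structure. The
resolution-sensor assay instead inserts, at a chosen chromosomal position, a
9 kb module flanked by directly repeated gamma-delta resolvase (Res) sites.
Synapsis of the two Res sites requires slithering and branching of
plectonemic DNA, which only diffusible negative supercoiling drives, so the
fraction of cells that delete the module during a timed resolvase pulse — the
*resolution efficiency*, scored as white colonies on X-gal — is a monotone
readout of local sigma_D.

`supercoilr` implements the full quantitative chain: calibration-curve
fitting and inversion (efficiency to apparent sigma_D), replicate-count
statistics with detection-limit censoring and mutant impact factors,
transcription elongation rates from beta-galactosidase induction kinetics,
and a kinetic twin-domain simulator that connects topoisomerase catalytic
rates to the genome-wide supercoil level.

## The calibration curve

Three anchor points of the in vivo response are stated explicitly:
efficiency falls to 0 on relaxed DNA (sigma_D >= -0.004), is about 50% at
sigma_D = -0.030, and approaches 100% by sigma_D = -0.040. Between these
anchors the response must be interpolated from the genome-wide survey pairs
(efficiency, apparent sigma_D).

```{r calibration}
curve <- fit_calibration(calibration_pairs_from_survey())
curve
efficiency_at(curve, c(-0.038, -0.030, -0.012))
```

**Why a monotone interpolant rather than a parametric sigmoid.** The default
fit pools the anchors (weighted 5x, because they are stated exactly while
table pairs are rounded to integer percent) with the survey pairs by weighted
isotonic regression and interpolates with a monotone Hermite spline
(`monoH.FC`). We also provide a symmetric logistic
R(sigma) = 1/(1 + exp((sigma - sigma50)/w)) behind `method = "logistic"`.
The logistic was our first candidate, but the observed response is visibly
asymmetric: the mid-range slope implies w of about 0.0075, while the
saturated shoulder (92% at -0.041, ~100% by -0.040) requires w below about
0.0046. No single w satisfies both, so a symmetric logistic cannot
simultaneously keep efficiency above 90% at the saturation anchor and
reproduce the printed mid-range inversions to within +/-0.003. The monotone
interpolant has no such constraint, guarantees an exact numerical inverse
(round-trip error < 1e-6 across efficiencies 0.05-0.90), and is therefore
the default.

**Occluded sensors are excluded from fitting.** The terminus-region sensor
(Cs 33) sits 470 bp from *dif*, where MatP, FtsK, XerC/D and a high-affinity
Topo IV site occlude resolvase binding; its efficiencies under-report local
supercoiling at every genotype. Including those pairs visibly corrupts the
monotone fit mid-range, so `calibration_pairs_from_survey()` drops them by
default (set `include_ter = TRUE` to keep them).

**Censoring and saturation.** Efficiencies below the 1% detection limit are
not placed on the curve; `sigma_from_efficiency()` returns a magnitude upper
bound |sigma_D| <= 0.003. Efficiencies at or above 95% sit on the saturated
shoulder: point estimates are flagged `saturated`, and efficiencies beyond
the fitted plateau return a magnitude lower bound capped at -0.045. Flat
stretches of the isotonic fit map one efficiency to an interval of sigma;
the interval midpoint is returned.

**Tolerances.** Printed table values are rounded (efficiencies to integer
percent, sigma to 3 decimals) and the two published position tables map
identical efficiencies to sigma values differing by up to 0.002, so we treat
+/-0.003 supercoil-density units as the agreement tolerance for any
inversion against printed values, and +/-0.004 for leave-one-out prediction.

## Resolution statistics

Per replicate plate the deletion fraction is white/total; a measurement is
the unweighted mean over >= 3 replicates with the sample SD (n - 1), exactly
as the assay reports "average +/- 1 SD of three independent experiments" —
not a pooled binomial SE, which would understate day-to-day variation.
Efficiencies below 1% enter genome-wide averages at a fixed 0.5%
substitution (`censor_low()`), which is idempotent.

The **Mutant Impact Factor** (MIF) is WT efficiency over mutant efficiency
at the same position. Below-detection mutants yield lower bounds against the
1% limit, reported unrounded with a ">" display at 2 significant figures;
the printed tables round such bounds inconsistently (">80" for 82/1 in one
row, ">45" for 45/1 in another), so we do not attempt to reproduce those
cells digit-for-digit. Aggregate MIFs are ratios of mean efficiencies, not
means of per-site ratios, matching how the published genome-wide MIFs
(e.g. 81%/26% = 3) were formed; per-site MIFs are still emitted in reports.

Genome-wide aggregates (`aggregate_positions()`) exclude Cs 33 (occlusion,
above) and the rrnG-flanking pair Cs 57.64/57.65 (they probe one operon's
local twin domain, not the genome-wide level). When a table already carries
per-row apparent sigma_D (as the published fixtures do), the aggregate
averages those values; otherwise each position's censored-substituted
efficiency is inverted through the calibration curve. Both routes round to
the same WT summary (81%, -0.038).

## Elongation rates from induction kinetics

After IPTG induction of a chromosomal *lacZ*, enzyme activity stays at
baseline for a lag tau and then rises linearly; the coupled
transcription/translation rate is the transcript length (3072 nt) divided by
tau. Activities are Miller units,
1000 (OD420 - 1.75 OD550) / (t_min v_ml OD600).

"Start of a linear increase" is operationalized as the breakpoint of a
continuous flat-then-linear hinge, MU(t) = b + s max(0, t - t_b), fitted by
least squares. With 10-s sampling and 40-100 s lags the breakpoint falls
between samples, so the sample-resolution grid search is refined between the
two best grid points by golden-section search on the SSE. The baseline
reported is the mean of the pre-induction samples only (three background
samples precede induction), so later signal cannot shift it, and the
breakpoint is invariant to rescaling the whole trace. A square-root
linearization (straight line through sqrt(MU - baseline), lag at the
x-intercept) is available as `method = "sqrt"`: classical induction-kinetics
analyses use it because enzyme accumulation is initially quadratic when
polymerases load gradually; on the generator's piecewise-linear traces it is
biased early, which is why the hinge is the default.

Twist flux divides the elongation rate by the B-DNA helical repeat of
10.5 bp/turn; 45-60 nt/s corresponds to 4.3-5.7 supercoils/s, the demand
gyrase must match downstream of an active operon.

## The twin-domain simulator

The simulator is deliberately minimal: the aim is to reproduce observed
*regimes* (WT steady state, genome-wide relaxation in slow-gyrase mutants,
rifampicin rebound, hypersupercoiling with a slow polymerase) from stated
catalytic rates, not to fit profiles. The chromosome is a ring of 450 equal
10-kb domains (within the observed 400-500). Each transcription unit pumps
linking difference at activity x v_e / 10.5 turns/s out of its upstream
neighbour and into its downstream neighbour (the twin-domain fluxes are
exactly opposite, so transcription alone conserves total linking
difference). Density diffuses between adjacent domains at `diffusion_rate`,
zeroed across active units (highly transcribed genes are diffusion
barriers). The topoisomerase rate laws are the simplest forms consistent
with the qualitative statements about the enzymes — these are model
assumptions, not measured response curves:

* gyrase: -k_gyrase clamp((sigma - sigma_set)/|sigma_set|, 0, 1); full speed
  on relaxed DNA, zero at its set point (k_gyrase = 4.5 sc/s, the middle of
  the 4-5 sc/s processive rate at 30 C; sigma_set = -0.038, the WT survey
  mean);
* Topo I: +k_topo1 clamp((sigma_th - sigma)/|sigma_set|, 0, 1); engages only
  on hypernegative DNA below sigma_th = -0.045 (a hard threshold; a graded
  alternative is equally compatible with what is known, the threshold form
  was chosen and is flagged as an assumption), k_topo1 = 4.5 sc/s (Topo I
  removes negative supercoils at the gyrase rate);
* Topo IV: -k_topo4 clamp(sigma/|sigma_set|, 0, 1) only where sigma > 0;
  only (+)-relaxation is modelled.

Mutant presets scale the damaged catalytic rate, because the alleles act on
k_cat, not on the set point: gyrA209 halves k_gyrase, gyrB652/gyrB1820 cut
it to 10%, parE206 halves k_topo4, rpoC slows v_e to 60%, and rif zeroes all
activities and releases the barriers. Units are co-oriented with replication
(oriC near Cs 84), as the highly transcribed genes are.

**Free parameters.** The published rate statements fix the values above, but RNAP
occupancy per operon, the number of strong units, the inter-domain diffusion
rate and the Topo IV rate are not quantified. They were calibrated once, by
scanning, so that the prescribed presets land in the observed windows (WT
mean sigma_D about -0.036 +/- 0.005; gyrB-class mutants -0.005 +/- 0.003;
rebound to the set point under rif), and then frozen: 30 units at
v_e = 52.5 nt/s with activity 1.0, diffusion_rate = 0.1/s,
k_topo4 = 0.5 sc/s. With these values the WT steady-state genome mean is
about -0.041, the gyrB preset about -0.010, and the rebound returns to
within 0.001 of the set point — the package's tests assert exactly these
regime windows and nothing finer. The mechanism that makes the mutant
chromosome relax is the one the rebound experiment implies: Topo I consumes
the upstream negative flux locally while the downstream positive flux spreads
through the bulk, so when gyrase cannot re-supply turns at the transcription
rate, stored negative supercoils are run down genome-wide.

**Numerics.** Deterministic forward Euler on per-domain sigma (the
observables are population means, so single-enzyme stochasticity is out of
scope). dt <= 0.01 s is documented as the stability bound at default rates
(the actual linear-stability limits are far larger; 0.01 s keeps the
clamped, switching terms well resolved). A run aborts if any |sigma|
exceeds 0.5. Steady state is declared when max |dsigma/dt| < 1e-6/s,
checked every 100 steps; the default horizon is 2000 s, several times the
slowest relaxation time in the mutant presets (about 80 s). Convergence is a
flag, not an exception, so scans cannot die mid-way. For an isolated
downstream domain receiving flux Phi <= k_gyrase the steady state has the
closed form sigma = sigma_set (1 - Phi/k_gyrase), which the tests verify
against the integrator.

**What the simulator does not model.** Replication forks, decatenation,
(-)-relaxation by Topo IV, R-loops, macrodomain 3D structure, and the
dif-region occlusion at Cs 33 — simulator output at the terminus is not
compared with sensor data there.

## Synthetic data: what passing tests do and do not show

The generators produce every input the pipelines read. Colony counts are
binomial draws at the efficiency the calibration curve assigns to a true
sigma_D (counting statistics only; 600 colonies x 3 replicates by default,
comfortably above the >= 200 scoring rule). Induction traces are flat-plus-
linear with multiplicative Gaussian noise on the rise (5% default,
reproducing the printed SD scales of +/-1-13 efficiency points and
+/-1-10 nt/s) and are emitted as OD-level columns that reproduce the
Miller-unit trace exactly. Both are seed-deterministic.

Real plates also vary through resolvase expression, growth stage, and
plating; real induction curves bend smoothly into the linear phase rather
than kinking. Parameter-recovery tests on these generators therefore show
that the estimators are correct for the stated noise model — unbiased sigma
recovery to +/-0.003 across [-0.042, -0.015], median lag error under half a
sampling interval at 2-10% noise — not that the wet assay is free of
systematic error. The published tables themselves are carried as plain-text
fixtures and exercised by the same pipeline functions, which is the
strongest end-to-end check available without raw data.

## Problem sizes

The shipped tests run the full 450-domain simulator for the regime checks
(a handful of steady-state runs, about 1-3 s each at dt = 0.01), 50-seed
recovery scans for the stochastic estimators, and leave-one-out over the 28
usable survey pairs; the whole suite completes in well under two minutes on
one core. Larger scans (the parameter calibration above) were run once
during development and their frozen results are what `build_model()` ships.

## Known limitations

* The calibration curve below 7% efficiency rests on two fixture pairs and
  the relaxed anchor; bounds there are honest but coarse (hence the
  |sigma_D| <= 0.003 censored representation).
* Aggregate SDs across positions mix measurement error with genuine
  positional variation; no variance decomposition is attempted.
* The simulator's activity parameter conflates polymerase density and
  velocity; only their product (the twist flux) is constrained.
* MIF lower bounds depend directly on the assumed 1% detection limit.
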