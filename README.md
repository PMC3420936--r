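# supercoilr

Quantitative analysis of bacterial chromosome supercoiling measured with
gamma-delta resolvase "supercoil sensor" assays, plus a kinetic twin-domain
simulator linking topoisomerase catalytic rates to genome-wide supercoil
density.

## The problem and who this is for

Chromosomal supercoil density sigma partitions into a protein-constrained
part and a diffusible part, sigma = sigma_C + sigma_D. Only sigma_D drives
the slithering and branching of plectonemic DNA, and it varies locally:
transcription pushes negative supercoils upstream and positive supercoils
downstream of active operons (the twin-domain effect), while gyrase,
topoisomerase I and topoisomerase IV restore the balance. A 9 kb sensor
flanked by directly repeated Res sites turns local sigma_D into a measurable
deletion frequency: the fraction of cells that resolve the sensor during a
timed resolvase pulse (scored as white colonies) rises monotonically with
|sigma_D|, from 0 on relaxed DNA (sigma_D >= -0.004) through ~50% at
sigma_D = -0.030 to saturation near -0.040.

The package is for microbiologists and modellers working with such assays
(or comparable topology reporters) who need to:

* fit and invert the efficiency-to-sigma_D calibration curve, with honest
  censoring below the 1% detection limit and at saturation;
* turn replicate colony counts into efficiencies, per-position apparent
  sigma_D, Mutant Impact Factors (MIF = WT efficiency / mutant efficiency)
  and genome-wide genotype aggregates;
* estimate transcription elongation rates v_e = L_lacZ / tau from
  beta-galactosidase induction time courses, where tau is the lag to the
  onset of linear activity increase (hinge changepoint regression), and
  convert them to twist flux v_e / 10.5 supercoils per second;
* simulate a circular chromosome of ~450 10-kb domains under twin-domain
  transcription flux with saturating rate laws for gyrase (max 4.5 sc/s,
  set point sigma_set = -0.038), Topo I (engages below -0.045) and Topo IV
  ((+)-relaxation only), to reproduce the observed regimes: WT steady state,
  genome-wide relaxation when gyrase is slow, and the rebound when
  transcription is blocked by rifampicin.

All published survey tables ship as plain-text fixtures, and seeded
generators produce every input format the pipelines read, so the entire
chain is testable without external data.

## Worked example

```r
library(supercoilr)

# 1. Calibration: anchors + genome-wide survey pairs, monotone fit
curve <- fit_calibration(calibration_pairs_from_survey())
curve
#> Supercoil-sensor calibration curve (monotone fit)
#>   sigma at 50% efficiency : -0.0300
#>   relaxed cutoff          : sigma >= -0.004 -> efficiency 0
#>   fit RMS residual        : 0.0240 (efficiency units, 31 points)

sigma_from_efficiency(curve, 0.75)
#> sigma_D = -0.0369 [efficiency 0.750]

# 2. Genome-wide aggregates from the published survey table
t1  <- paper_fixture_tables()$table1
wt  <- aggregate_positions(t1[t1$genotype == "WT", ], curve)
gyrB <- aggregate_positions(t1[t1$genotype == "gyrB652", ], curve,
                            wt_summary = wt)
```

The WT summary over the 7 non-terminus positions is 81 +/- 7% efficiency and
apparent sigma_D = -0.038 +/- 0.002; the gyrB652 mutant, with censored
sub-detection rows entering at 0.5%, averages 2% for an aggregate MIF of 40 —
a near-total loss of diffusible supercoiling.

```r
# 3. Elongation rate from a synthetic induction time course (hidden lag 96 s)
tc  <- simulate_timecourse(timecourse_scenario(true_lag_s = 96,
                                               noise_fraction = 0.05,
                                               duration_s = 400, seed = 42))
fit <- estimate_lag(tc)
elongation_rate(fit$lag_s)   # 32.5 nt/s  (truth: 3072/96 = 32)
twist_flux(52.5)             # 5 supercoils/s that gyrase must match

# 4. Twin-domain simulation: slow-gyrase mutant and the rifampicin rebound
m <- build_model("gyrB1820")          # gyrase at 10% of the WT rate
s <- run_to_steady_state(m)
mean(s$sigma)                          # -0.010: genome-wide relaxation
r <- rif_experiment(m, s)
mean(r$sigma)                          # -0.038: rebound to the gyrase set point
```

The mutant chromosome relaxes because Topo I consumes the upstream negative
flux of each active operon while the downstream positive flux drains stored
supercoils faster than the crippled gyrase can replace them; silencing
transcription (`rif_experiment()`) lets even slow gyrase restore the set
point.

Command-style wrappers (`cmd_calibrate`, `cmd_resolve`, `cmd_elongation`,
`cmd_simulate`, `cmd_synth`) read JSON configs and write TSV reports; a thin
shell wrapper lives at `inst/scripts/supercoilr`. See the methods vignette
(`vignettes/supercoil-sensor-methods.Rmd`) for the model, parameter choices
and numerical details.

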