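# repaintsim

Simulation and quantitative analysis of **Repeat DNA-PAINT** experiments.

DNA-PAINT localizes targets by the transient binding of dye-labeled
"imager" oligonucleotides to target-anchored "docking" strands: each
binding event is a blink that can be fit to nanometre precision. Its
performance in biological samples is limited by three imager-concentration
effects — diffuse background from unbound imagers, non-specific binding,
and photoinduced inactivation of docking sites. Repeat DNA-PAINT counters
all three with docking motifs that carry *N* identical repeat domains
(*N*x RD): in the low-occupancy imaging regime the event rate is

```
E = rho_DS * N * [I] / K_d        (per site: N * k_on * [I])
```

so the imager concentration can be reduced *N*-fold at constant event rate,
while background, non-specific events and (for redundant domains) site loss
all drop.

`repaintsim` implements the full quantitative chain on synthetic data, for
researchers developing or validating DNA-PAINT analysis pipelines:

* **Kinetics** — continuous-time Monte Carlo of per-domain two-state
  binding, non-specific events (rate ∝ [I]), and per-event photoinduced
  domain inactivation, with closed forms for event rates, contamination
  fractions and site survival (`simulate_specific()`,
  `simulate_nonspecific()`, `expected_site_survival()`).
* **Camera** — rendering of event streams into noisy 16-bit TIFF movies
  with imager-dependent background (`render_frames()`, `psf_profile()`).
* **Localization** — SNR-relative spot detection, weighted 2D Gaussian
  fitting with covariance-based precision estimates, and event linking
  (`localize_stack()`, `link_events()`).
* **Site analysis** — per-target event rates, detected-site counting and
  site-loss statistics (`assign_events()`, `site_loss_percent()`).
* **qPAINT** — dark-time extraction, two-exponential mixture CDF fits
  (`CDF(t) = a(1-e^(-t/tau_B)) + (1-a)(1-e^(-t/tau_D))`, `tau_B < 8`
  frames), index calibration on tiles with known site counts, and site
  counting (`fit_dark_cdf()`, `calibrate_6site()`, `count_sites()`).
* **FRC** — Fourier Ring Correlation curves, the 1/7-threshold resolution,
  and tiled resolution maps (`frc_curve()`, `frc_resolution()`, `frc_map()`).
* **Tether model** — freely-jointed-chain sampling of fluorophore positions
  on multi-repeat motifs, radial averaging, Airy convolution and
  first-minimum shift (`sample_fluorophore()`, `first_minimum_shift()`).
* **FFS** — a generic Direct Forward Flux Sampling engine with exact
  mean-first-passage and committor oracles on toy chains (`run_ffs()`,
  `exact_rate_bd()`).

## Worked example

Calibrate the non-specific binding coefficient so that conventional (1x RD)
imaging at 0.4 nM carries 8% non-specific events, then predict and verify
the contamination for 10x RD at 40 pM:

```r
library(repaintsim)
res <- run_scenario("nonspecific", seed = 5)
rbind(analytic  = c(`1x` = res$fraction_1x,  `10x` = res$fraction_10x),
      simulated = c(res$measured_1x, res$measured_10x))
#>                   1x         10x
#> analytic  0.08000000 0.008620690
#> simulated 0.08737864 0.006419753
```

The 8% contamination collapses to 0.86% — the specific event rate is
preserved by the ten repeats while the non-specific rate follows the
ten-fold dilution. The simulated event streams (second row) agree within
counting noise.

Count binding sites by qPAINT on simulated origami tiles (50 six-site
calibration tiles, 80 five-site test tiles, 40,000 frames at 100 ms):

```r
qp <- run_scenario("qpaint", seed = 7)
qp$counts$median
#> [1] 5.060032
qp$counts$se_median
#> [1] 0.09855
```

The median estimate for the five-site tiles is 5.06 ± 0.10 sites/tile —
calibrated counting recovers the constructed ground truth.

The numbered scripts under `analysis/` run the remaining experiments
(event-rate scaling, background→FRC-resolution chain, site loss, tether
blurring, FFS rate validation) and write their tables under `results/`:

```sh
Rscript analysis/01_event_rates.R
Rscript analysis/04_site_loss.R   # etc.
```

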