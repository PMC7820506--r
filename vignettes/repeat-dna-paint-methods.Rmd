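---
title: "Repeat DNA-PAINT: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat DNA-PAINT: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repaintsim)
```

`repaintsim` is a simulator-plus-analysis package for Repeat DNA-PAINT, the
variant of DNA-PAINT in which each docking strand carries *N* identical
repeat domains (Nx RD) so that the imager concentration can be reduced
*N*-fold without losing binding events. This vignette explains the models
behind each stage, the parameters that matter, and the design decisions that
were genuinely open, so that results produced by the analysis scripts and
the test suite can be interpreted correctly.

## Binding kinetics

Each repeat domain of a docking site is an independent two-state (free /
bound) process. While free, the waiting time to the next imager binding is
Exponential with rate $k_{on}[I]$; bound (bright) durations are Exponential
with mean $\tau_b$. The dissociation constant follows as
$K_d = 1/(k_{on}\tau_b)$. In the super-resolution regime the occupancy
$[I]/([I]+K_d)$ is tiny, and the expected event rate of a site with $N$
active domains is

$$E = N\,k_{on}\,[I],$$

linear in both $N$ and $[I]$ — the per-target form of the event-density law
$E = \rho_{DS}\, N\, [I]/K_d$ with the association rate written explicitly.
Two consequences drive everything downstream: doubling $N$ doubles the event
rate, and an $N$-repeat motif at $[I]/N$ reproduces the single-domain rate
while the *concentration-driven* nuisances (diffuse background, non-specific
binding) drop $N$-fold.

Defaults: $k_{on} = 2\times10^6\,\mathrm{M^{-1}s^{-1}}$ and
$\tau_b = 0.5$ s for the standard 9-nt imager ($K_d = 1\,\mu$M), and
$\tau_b = 0.05$ s for the short 8-nt imager used in accelerated acquisition.
These are typical published DNA-PAINT values; the hybridization parameters
of the specific sequences used in any one experiment are not pinned down by
the data the package reproduces, so all of them are configurable
(`imager_spec()`). Time is continuous in the simulator; discretization to
camera frames happens only at the rendering and dark-time stages.

Non-specific binding is modeled as a homogeneous Poisson process of rate
$\gamma [I] A$ over a field of area $A$, with uniform positions and
Exponential durations (default mean 0.15 s — traces of non-specific events
are brief; only the rate matters for the contamination fractions).
$\gamma$ is a free coefficient calibrated per sample type
(`calibrate_nonspecific()`).

Photoinduced site loss is tied to *completed binding events*: after each
event the hosting domain is permanently inactivated with probability $q$.
This reflects the mechanism — damage by reactive states of bound,
photo-excited dyes — rather than elapsed-time decay. Lethal events thin the
binding process, so a domain survives to time $T$ with probability
$e^{-q\lambda_d T}$ ($\lambda_d = k_{on}[I]$ per domain), and an $N$-domain
site retains at least one active domain with probability
$1-(1-e^{-q\lambda_d T})^N$ — the closed form that the simulated
site-loss experiments are checked against.

## Camera model

`render_frames()` implements the forward model: an event contributes
`photon_rate × overlap` expected photons to every frame it overlaps
(pro-rata at frame boundaries, no intra-event blinking), integrated over
pixel areas with a Gaussian of the optics' FWHM. The mean background per
pixel per frame is

$$b = \mathrm{offset} + \beta\,[I] + \kappa\, r_{site},$$

with $\beta$ the free-imager coefficient (background grows linearly with
imager concentration) and $\kappa$ an out-of-focus term proportional to the
specific event rate per area $r_{site}$ — by design the same for (1x, $[I]$)
and (10x, $[I]/10$), which is why it appears as a condition-independent
offset in background comparisons. $\kappa$ is not quantified by the data
the package emulates and defaults to zero. Pixel values are
$\mathrm{Poisson}(\mathrm{signal}+b) + \mathcal{N}(0,\sigma_{read})$,
rounded and clipped at zero; units are photons (gain 1). Defaults: 108 nm
pixels (60x objective, 6.5 µm camera pixels), 64×64 fields, 100 ms frames.

The PSF profile (`psf_profile()`) is the Airy pattern
$(2J_1(v)/v)^2$, $v = (2\pi/\lambda)\,\mathrm{NA}\,r$, normalized to unit
mass over the plane. Its FWHM and first-minimum radius are located
numerically (root finding on the profile and on $J_1$); at
$\lambda = 700$ nm, NA 1.45 the FWHM is 248 nm and the first minimum
294 nm. The Gaussian kind matches the Airy FWHM and reports no first
minimum.

## Localization

Detection is SNR-relative: candidates are local maxima of the smoothed
frame exceeding `median + snr_threshold × MAD`. Because the threshold
scales with the frame noise, events of equal photon yield are detected
equally at different background levels; when two conditions with different
backgrounds must be compared at *equal* detected photon yields (as in the
background-versus-resolution chain), the threshold of the low-background
condition is raised by the ratio of noise SDs — mirroring standard practice
in SMLM pipelines. Overlapping candidates keep the brighter one.

Each ROI is fit with a five-parameter 2D Gaussian (amplitude, x, y, sigma,
constant background) by weighted least squares with Poisson-variance
weights ($w = 1/\max(\mathrm{counts},1)$), via Levenberg–Marquardt. The
per-axis precision estimate is the square root of the position diagonal of
$(J^\top W J)^{-1}$ at convergence; tests verify it scales as
$1/\sqrt{\mathrm{photons}}$, degrades with background, and agrees with the
true RMSE within a factor 1.5. Non-converged fits are dropped and counted.
Localizations in consecutive frames (gap ≤ `link_max_gap`) within
`link_radius` are merged into binding events. Drift is not simulated, so no
drift correction exists (fiducial workflows are out of scope).

## Site-level quantification

Events are assigned to the nearest known target within a radius (50 nm
default; synthetic targets are known, so no clustering). Site-loss analysis
counts a site as *detected* in a 20,000-frame window when at least
`min_events` of its events start in the window. The default is
`min_events = 1`: at the study concentrations (0.4 nM for 1x RD) a
single-domain site produces only ~1.6 events per 2000-s window, so any
higher threshold would count essentially no sites; with the minimal rule
the two windows have identical detection probability when $q = 0$
(stationary increments), so no spurious loss is introduced. The
calibration of $q$ to a target 1x loss is closed-form under this rule:
$\mathrm{loss} = 1 - e^{-q\lambda T_1}$, giving $q = 0.0806$ for 12.1%
loss at $\lambda = 8\times10^{-4}\,\mathrm{s^{-1}}$, $T_1 = 2000$ s. The
detection rule is exposed in the configuration; with richer event
statistics a higher `min_events` is appropriate.

## qPAINT

Dark times are the frame gaps between consecutive *merged* events of one
target region (simultaneous binding on two sites of a tile appears as one
bright period). Their empirical CDF is fit by least squares with the
two-exponential mixture

$$\mathrm{CDF}(t) = \alpha\left(1-e^{-t/\tau_B}\right) +
  (1-\alpha)\left(1-e^{-t/\tau_D}\right),$$

with $0<\alpha<1$ and the fast component constrained to $\tau_B < 8$
frames so that dye blinking and detection dropouts do not contaminate the
binding dark time $\tau_D$. The fit is an empirical-CDF least-squares
(not maximum likelihood) evaluated at the sorted unique dark times, with
three multistarts — matching the procedure the package reproduces. The
qPAINT index is $1/\tau_D$ per frame; six-site tiles calibrate the index
per site via the center of a Gaussian fit (unweighted `nls` on the
histogram counts, falling back to the sample mean for degenerate
histograms), and five-site tiles are summarized by the median estimate with
a bootstrap SE (1000 resamples).

The tile scenario uses $[I] = 0.2$ nM on 10x RD motifs — the origami
working range of 0.2–2 nM divided by ten for ten repeats — giving ~80–95
dark times per tile over 40,000 frames at 100 ms. That is deliberately
experiment-scale: per-tile $\tau_D$ estimates are ~10% noisy, and the accuracy
of the median over 80 tiles (±0.1 sites) comes from pooling, not from
unrealistically long traces.

## Fourier Ring Correlation

Localization tables are split into alternating 100-frame blocks (even
blocks → half A, odd → half B), each half rendered as a sum of
unit-integral Gaussians (SD = the per-localization precision estimate when
available, else 5 nm; 5 nm pixels by default), and correlated per
spatial-frequency ring of the DFTs:

$$\mathrm{FRC}(q) = \frac{\Re\sum_{ring} F_A F_B^{*}}
 {\sqrt{\sum_{ring}|F_A|^2 \sum_{ring}|F_B|^2}}.$$

Rings are one frequency sample wide, images are zero-padded to a
power-of-two square, and the resolution is $1/q^{*}$ at the first crossing
of the fixed 1/7 threshold with linear interpolation between samples (no
spurious-correlation correction). The reported resolution is floored at
twice the rendering pixel (Nyquist). Maps tile the field into 2×2 µm
squares; tiles under `min_locs` localizations are flagged rather than
reported. Ring width and interpolation rule are not dictated by the
procedure being reproduced; one-sample rings with linear interpolation are
the simplest defensible choice and are fixed here.

One caveat learned from the synthetic experiments: FRC assumes a
structure with broadband spectral content. A strictly periodic lattice of
point targets has no power between its harmonics, so low-frequency rings
contain only sampling noise and the first-crossing rule mis-fires. The
synthetic structures used in tests and scripts therefore scatter targets
randomly.

## Tether model and PSF blurring

The docking-imager complex is a coarse polymer surrogate: the unhybridized
domains between the anchor and the bound domain form a freely jointed chain
(contour 0.63 nm/nt, Kuhn length 1.8 nm — standard single-stranded DNA
values at moderate-to-high salt), the bound domain plus imager is a rigid
9-bp duplex rod (0.34 nm/bp) with uniform orientation, and the fluorophore
sits at the rod end distal to the anchor. Domains beyond the bound one
dangle past the fluorophore and are ignored. The coverslip is a reflecting
half-space at $z = 0$; reflection leaves the x–y projection — the imaged
quantity — unchanged, which is why it is preferred over rejection sampling.

The radially averaged 2D distribution of projected fluorophore positions is
convolved with the Airy PSF on a ≤1 nm grid (FFT convolution of the two
radially symmetric images; requests above 2 nm sampling are refused as
under-resolved), and the first minima of the convolved and the
grid-discretized PSF profiles are located by parabolic interpolation around
the discrete minimum — comparing both on the same grid cancels
discretization bias. All shifts for all domains of 1x/3x/6x motifs stay
below 0.12%, far below anything detectable experimentally.

A known limitation: an ideal freely jointed chain at textbook ssDNA
flexibility is substantially more compact than a nucleotide-level model
with strong base stacking. The surrogate's distal 6x distribution peaks
near 5 nm, not ~8 nm; closing that gap would require an effective Kuhn
length of 5–7 nm, i.e. a stacked, semi-rigid chain. The parameters are
deliberately left at the standard polymer-literature values rather than
re-fit to a target peak; since the blurring conclusion is an upper bound,
the narrower surrogate distributions make that bound conservative in the
sense that the true shift could be up to ~2× larger and would still be two
orders of magnitude below the PSF scale (the width sweep in the test suite
covers clouds up to 20 nm).

## Forward Flux Sampling

The FFS engine is model-agnostic: a model supplies `step(state)` and an
integer reaction coordinate `Q(state)`; the interface scheme fixes the
basin ($Q \le Q_{min}$), the flux interface ($Q_0$) and the absorbing
target ($Q_{max}$). The rate is

$$r = \Phi_{Q_{min}\to Q_0}\prod_i p(i\,|\,i-1),$$

the flux of first arrivals at $Q_0$ after a basin visit, times the
conditional probabilities of advancing one interface before falling back to
the basin, with crossing configurations stored and re-sampled uniformly
with replacement between stages.

Time bookkeeping was a genuinely open point. Excluding *all* dwell at
$Q \ge Q_0$ from the sampling time inflates the flux by the equilibrium
weight of the uncommitted transition region (+20–65% on the test chains)
and breaks agreement with the exact mean-first-passage rate. What must be
excluded is dwell in the *bound/target* basin. The engine therefore
reinstates the trajectory in the initial basin after each completed
transition, so target dwell never enters the sampling time while
reactant-side time (including failed excursions past $Q_0$) does. Under
this convention the FFS estimate matches $1/\mathrm{MFPT}$ from the exact
linear solve to within a few percent across barriers spanning three orders
of magnitude in rate.

The bundled toy model is a Metropolis birth–death chain over an energy
profile (detailed balance by construction), with exact oracles for the
rate (mean first-passage linear solve) and the per-stage probabilities
(committor linear solve). A terminal-state classifier hook labels which
basin a successful trajectory reached — the generic form of asking which
binding site an imager ended up on. The molecular reaction coordinate of
the original system (minimum distance, bond counts) is out of scope; only
the integer-Q contract is represented.

## What the synthetic data do and do not emulate

The generator reproduces: per-domain two-state kinetics with rate
$\propto N[I]$; diffuse background $\propto [I]$ plus an out-of-focus
offset $\propto$ specific event rate; non-specific events at rate
$\propto [I]$; per-event permanent domain inactivation; shot and read
noise. It does not emulate: imager depletion, diffusion-limited rebinding,
sequence-level thermodynamics, sample drift, sCMOS gain maps, 3D PSFs, or
spatial heterogeneity of tissue background. Passing tests therefore
demonstrate the internal consistency of the quantification chain under the
stated model, not robustness to these real-data effects.

## Problem sizes and reproducibility

All randomness flows through explicit seeds; identical seeds give
bit-identical event streams. The scripts and tests use desk-scale sizes
chosen to keep each experiment's statistical error comfortably inside the
assertion bands: 60 targets per condition for rate scaling, 300 six-site
tiles (×20–50 seeds) for site loss, 50+80 tiles of 40,000 frames for
qPAINT, $10^5$ tether samples per bound-domain case, $10^5$ dynamics steps
and 1000 trials per stage for FFS, and movies of a few thousand 56×56 px
frames for the localization and FRC chain.
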