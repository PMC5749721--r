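---
title: "Evaluating FLIM-FRET donor-acceptor pairs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating FLIM-FRET donor-acceptor pairs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimpair)
```

## The problem

A FRET biosensor reports a biochemical event as a change in the energy
transfer between two fluorescent proteins. When the readout is the donor's
fluorescence *lifetime* rather than intensity, the measurement is largely
immune to expression level, scattering and acceptor photobleaching — but
the choice of donor-acceptor pair still decides whether an assay built on
it can work. `flimpair` implements the desk-side part of that decision:
predicting pair performance from photophysics, modelling the two common
lifetime-measurement platforms, and scoring assay potential on per-cell
data.

## Spectral predictions

Energy transfer requires spectral overlap between donor emission and
acceptor absorption. With the donor emission spectrum area-normalised to
$f_D(\lambda)$ and the acceptor excitation spectrum scaled to its molar
extinction coefficient $\varepsilon_A(\lambda)$, the overlap integral is

$$J = \int f_D(\lambda)\, \varepsilon_A(\lambda)\, \lambda^4 \, d\lambda
\quad [\mathrm{nm^4\,M^{-1}\,cm^{-1}}],$$

computed trapezoidally on the union of the two wavelength grids with
linear interpolation and zero outside either support (spectra are smooth
and densely sampled, so this matches common practice; the default
resampling grid is 1 nm). The Förster radius — the separation at which
half the donor's excitations transfer — follows as

$$r_0 = 0.02108 \, \left( K \, \phi_D \, n^{-4} \, J \right)^{1/6}
\ \mathrm{nm},$$

with $\phi_D$ the donor quantum yield and $n = 1.4$ the refractive index
typical of cultured cells. Efficiency at separation $r$ is
$E = r_0^6 / (r_0^6 + r^6)$, and a donor of lifetime $\tau_D$ transferring
at efficiency $E$ is measured at $\tau_D (1 - E)$.

**The orientation-factor term.** For freely rotating dipoles the term $K$
inside the sixth root is the isotropic $\kappa^2 = 2/3$. The benchmark
radii bundled with the package (ten fluorescent-protein pairs,
`flim_pair_table()`) are, however, reproduced exactly — all ten to
$\pm 0.01$ nm — only when $K = (2/3)^2$, a constant factor $(3/2)^{1/6}$
(about 7%) below the $\kappa^2 = 2/3$ values. The origin of that
convention in the benchmark is not documented, so the package refuses to
guess: both modes are implemented, `table2_compat` (the default, matching
the bundled table) and `standard_two_thirds` (the textbook form). The two
differ by an exact algebraic factor, so nothing downstream depends on the
choice beyond the absolute scale of $r_0$.

For comparison against the benchmark table the package rounds $r_0$ to two
decimals and efficiencies to the nearest percent, mirroring the table's
own precision; predicted efficiencies at fixed separations are computed
from the table's radii, not from re-derived ones, so rounding of the
radius does not leak into the efficiency grid.

## Frequency-domain model

Homodyne frequency-domain FLIM modulates excitation and detector at
$f = 40$ MHz ($\omega = 2\pi f$). A decay with intensity fractions $a_i$
and lifetimes $\tau_i$ has complex response
$R = \sum_i a_i / (1 + i\omega\tau_i)$; the instrument observes the phase
shift $\varphi = -\arg R$ and demodulation $m = |R|$, from which two
apparent lifetimes follow:

$$\tau_\varphi = \tan(\varphi)/\omega, \qquad
  \tau_m = \sqrt{1/m^2 - 1}\,/\,\omega.$$

For a mono-exponential decay these agree exactly; any mixture has
$\tau_\varphi < \tau_m$ strictly, which is a useful heterogeneity
diagnostic. The phasor representation $(g, s) = (m\cos\varphi,
m\sin\varphi)$ places every mono-exponential decay on the universal
semicircle of radius $1/2$ centred at $(1/2, 0)$ — from $(1, 0)$ at 0 ns
to the origin at infinite lifetime — and every mixture strictly inside it.
(This curve is sometimes loosely called the "unit circle"; the semicircle
is the mathematically correct locus and is what the package tests
against.)

Raw phase and modulation carry arbitrary instrument offsets; measuring a
reference fluorophore of known lifetime under identical settings removes
them (`calibrate_reference()`). Following standard practice the package
defaults to fluorescein ($\tau = 4.000$ ns) for the 445 nm excitation band
and erythrosin B ($\tau = 0.086$ ns) for 491 nm, both overridable. Which
single number an instrument reports as "the" FD lifetime varies by vendor
and is rarely documented; the package defaults to the phase lifetime —
the most common single-number readout — and always carries the modulation
lifetime and phasor coordinates alongside.

**Noise model.** Measured phase and modulation are perturbed with
independent Gaussian noise of standard deviation $1/\sqrt{N}$ (relative,
for $m$) at photon budget $N$ — the simplest model with the correct
photon-statistics scaling, sufficient for the parameter-recovery tests the
package makes. It does not emulate detector-specific excess noise.

## Time-domain model

TCSPC histograms photon arrival times into 80 ps bins over a 12.5 ns
window (the 80 MHz Ti:Sapphire repetition convention; both configurable —
the true acquisition window of any given instrument is rarely published).
Simulated expected counts are the *exact* integral of the decay over each
bin, so binning introduces no model error; observed counts are Poisson.
Wrap-around of incomplete decays is not modelled, and excitation is
treated as instantaneous (no instrument response function): at the
lifetimes and window of interest here (window $\ge$ 3 lifetimes, IRF two
orders of magnitude below the lifetime) both effects are far below the
shot noise.

The mono-exponential fit maximises the Poisson likelihood of
$A e^{-t/\tau}$ (+ optional constant background), initialised from a
log-linear regression of the counts; the reduced $\chi^2$ is reported with
Neyman weighting for familiarity. Background fitting is off by default:
the offset must be non-negative, and on background-free data the
constrained estimate sits at the boundary and drags $\tau$ down by a few
tenths of a percent — measurable against the package's own consistency
tests — so it is only fitted when asked for.

The bi-exponential fit uses variable projection under Neyman-weighted
least squares: lifetimes are optimised while amplitudes (and background)
are solved linearly at each step, *deliberately unconstrained in sign*. A
decay that is truly mono-exponential often "supports" a second component
only with a negative amplitude — a physically impossible solution — and
keeping the sign free makes that failure visible instead of hiding it at a
bound. `select_decay_model()` accepts the two-component fit only when it
is physical *and* improves the reduced $\chi^2$ by more than 0.5 (the
expected improvement from two extra parameters fitting pure noise is an
order of magnitude smaller, while a genuinely missed second component
inflates $\chi^2_\nu$ by far more at realistic photon counts).

## Assay scoring

Efficiency from lifetimes is $E = 1 - \tau_{DA}/\tau_D$. Small negative
values arise from noise whenever true transfer is weak; they are returned
(with a warning), never clipped, so that population statistics remain
unbiased.

Assay potential uses the screening Z'-factor

$$Z' = 1 - \frac{3(\sigma_{max} + \sigma_{min})}{|\mu_{max} - \mu_{min}|},$$

with the donor-alone lifetimes as the maximum signal and the pair
lifetimes as the minimum. The evaluation design treats each experimental
day as one repeat: means and standard deviations (sample SD, $n-1$) are
taken across cells within a day, $Z'$ and $E$ computed per day (each
day's pair cells against that day's donor controls), and the across-day
mean $\pm$ SD reported. Static mode uses only the first timepoint;
dynamic mode pools every timepoint of every cell within the day before
taking $\mu$ and $\sigma$, so temporal drift inflates
$\sigma_{min}$ and is penalised — exactly the behaviour that
distinguishes photostable pairs from drifting ones. Averaging each cell's
trace first is available as an option (`per_cell_average`), giving a
milder penalty.

A long-lifetime donor improves leverage mechanically: the lifetime shift
per percentage point of efficiency is $\tau_D/100$, i.e. 40 ps/%E for a
4.0 ns donor against 24 ps/%E for a 2.4 ns one
(`sensitivity_ps_per_percent()`; an empirical $\Delta\tau/\Delta E$ route
is available through `stimulation_response()`, which also tests pre-
versus post-stimulation lifetime changes with a two-sided rank-sum test,
starred at 0.05/0.01/0.005).

## Time-course stability

Per-cell traces are normalised to the across-cell mean of their day's
$t = 0$ values, drift is summarised by an OLS gradient through the mean
normalised trace, and endpoint changes ($t = 10$ minus $t = 0$ per cell)
by mean, median and the 10/25/75/90th percentiles. Percentiles use linear
interpolation between closest ranks (R's type-7 definition) so they are
exactly reproducible by a sort-based oracle. The through-origin regression
of measured on predicted efficiencies uses $b = \sum xy / \sum x^2$ with
$R^2 = 1 - \sum(y - bx)^2 / \sum y^2$ — the no-intercept $R^2$ is
convention-dependent, so the definition is fixed here. Exclusion of
anomalous pairs from that regression is always an explicit argument, never
automatic.

## The synthetic generator

Real per-cell data for the bundled benchmarks are not redistributable, so
the package generates studies with the same design: 3 days $\times$ 3
dishes $\times$ 10-20 cells per dish (default 15), a donor-alone arm and a
pair arm, per-cell true donor lifetimes
$\mathcal N(\tau_D, \sigma_\tau)$ and efficiencies
$\mathcal N(E, \sigma_E)$ (defaults $3.12 \pm 0.05$ ns and
$0.241 \pm 0.02$, matching the bundled green-donor benchmark values).
Observed lifetimes are produced by the *actual measurement code paths* —
frequency-domain simulation with fixed instrument offsets, a noisy
reference measurement and calibration, or TCSPC simulation plus the
Poisson fit — so estimator biases are exercised end to end; a Gaussian
shortcut mode exists for large simulations. Heterogeneous acceptors are
modelled as a two-component mixture with a maturation-failure fraction at
$E \approx 0$ (default fraction 0.5 when enabled; the mechanism is
qualitative, chosen to reproduce high cell-to-cell variability and poor
mean efficiency, not a quantified photophysical model). Time courses add
exponential intensity bleaching and, for the pair arm only, a fractional
upward lifetime drift per minute emulating acceptor photodamage; neither
rate is taken from measured data — drift rates for unstable
yellow-acceptor pairs are not published as rates — so both default to
zero and are set explicitly per scenario. Everything is deterministic
given `rng_seed` (R's default Mersenne-Twister stream), and the caller's
RNG state is saved and restored.

What passing tests on this generator do show: the estimation pipeline
recovers its own generating parameters without bias, at the correct
photon-statistics scaling, through calibration and fitting. What they do
not show: agreement with any particular instrument's noise floor,
segmentation effects, or biology (expression-level dependence, pH,
maturation kinetics beyond the two-component caricature).

## Problem sizes and numerical choices

The shipped test suite and the acceptance script run at deliberately
desk-scale sizes — 200-cell recovery studies, 30-80 Monte-Carlo
replicates per consistency check, a 100-seed model-selection study at
$3 \times 10^4$ photons — chosen so the whole suite completes in well
under a minute while keeping every standard error small enough for 3-SE
acceptance bands. Mono fits refine a Nelder-Mead solution with BFGS
(relative tolerance $10^{-14}$), which recovers noiseless truth to better
than $10^{-6}$; bi-exponential initialisation splits the histogram into
head and tail log-linear fits, and falls back to $\tau_{slow}/3$ for the
fast component when the head fit is uninformative. Degenerate inputs
(all-zero spectra, pure-background histograms, constant vectors in rank
correlations, equal population means in $Z'$) raise errors rather than
returning silently wrong numbers.

## Known limitations

Single modulation frequency only (no multi-frequency FD); no IRF
deconvolution or incomplete-decay correction; no pixel-level images — the
unit of analysis is the cell; the $\kappa^2$ ambiguity documented above is
carried, not resolved; and the generator's drift and heterogeneity
parameters are illustrative rather than fitted to data.
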