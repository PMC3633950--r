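---
title: "Modelling polarization-transfer solid-state NMR of stratum corneum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling polarization-transfer solid-state NMR of stratum corneum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptnmr)
```

## The measurement this package models

Polarization-transfer solid-state NMR (PT ssNMR) reads molecular dynamics
out of natural-abundance ^13^C spectra by comparing three acquisition
schemes on the same sample under magic-angle spinning (MAS): direct
polarization (DP), which excites every carbon roughly uniformly;
cross polarization (CP), which transfers ^1^H magnetization through space
via dipolar couplings and therefore lights up only rigid or strongly
anisotropic segments; and refocused INEPT, which transfers through the
one-bond scalar coupling $J_{\mathrm{CH}}$ and survives only when the
transverse relaxation times $T_2^{\mathrm H}$ and $T_2^{\mathrm C}$ are
long, i.e. for mobile segments.  Overlaying the three spectra turns each
resolved peak into a dynamic-state readout: INEPT-only means nearly
isotropic mobility, CP-only means rigidity, comparable CP and INEPT means
fast but anisotropic motion, and the absence of both (with DP present)
marks the intermediate motional regime where microsecond dynamics destroys
both transfers.

Applied to stratum corneum (SC) — corneocytes filled with keratin filaments
embedded in a multilamellar lipid matrix — this readout resolves, peak by
peak, how hydration and temperature mobilize the lipid chains, the
cholesterol, and the glycine/serine-rich terminal domains of keratin, while
the coiled-coil filament core stays rigid.

## The motional model

Each C–H~n~ segment carries three motional parameters: the bond order
parameter $|S_{\mathrm{CH}}|$, the fast local correlation time $\tau_c$,
and a slow global correlation time $\tau_s$.  The orientational correlation
function is two-step,

$$C(t) = (1 - S^2)\,e^{-t/\tau_c} + S^2\,e^{-t/\tau_s},$$

and its Fourier transform is the two-Lorentzian reduced spectral density
(`spectral_density()`, with the $2/5$ powder normalization; all dipolar
prefactors live in `relaxation_parameters()`):

$$J(\omega) = \frac{2}{5}\left[(1-S^2)\frac{\tau_c}{1+\omega^2\tau_c^2}
  + S^2\frac{\tau_s}{1+\omega^2\tau_s^2}\right].$$

`tau_s` defaults to 1 s — an effectively static global environment — and
may be `Inf`.

## From spectral densities to transfer intensities

`relaxation_parameters()` converts $J(\omega)$ into the four time constants
that control the transfers, using the heteronuclear coupling
$d_{\mathrm{CH}} = (\mu_0/4\pi)\gamma_{\mathrm H}\gamma_{\mathrm C}\hbar/r_{\mathrm{CH}}^3$
(23.3 kHz at the default $r_{\mathrm{CH}} = 1.09$ Å) and the geminal
proton–proton coupling $d_{\mathrm{HH}}$ (1.78 Å):

* $T_2^{\mathrm C}$: BPP-style heteronuclear dipolar relaxation.  Under MAS
  the secular $J(0)$ terms are replaced by the mean of $J(\omega_R)$ and
  $J(2\omega_R)$ — the desk-scale stand-in for full Floquet averaging that
  captures how faster spinning narrows lines and helps INEPT.
* $T_2^{\mathrm H}$: the same Redfield terms for the proton bath (an
  effective $z = 3$ coupled neighbours), plus a coherent dephasing term
  $\zeta S^2 d_{\mathrm{HH}}^2/\omega_R$ for the quasi-static residual
  homonuclear coupling that MAS at finite rate cannot remove.
* $T_{1\rho}^{\mathrm H}$: rotating-frame relaxation with the spin-lock
  term evaluated at the ^1^H nutation frequency (the 72–88 kHz ramp
  midpoint, 80 kHz) split over the $\pm\omega_R$ MAS sidebands.
* $T_{\mathrm{CH}}$: CP build-up through the residual coupling at the
  $n = \pm 1$ Hartmann–Hahn sideband swept by the ramp,
  $1/T_{\mathrm{CH}} = (n_{\mathrm H}/2)\,S^2/T_{\mathrm{CH},0}$ with
  $T_{\mathrm{CH},0}$ the rigid-limit CH~2~ build-up time.

The intensities then follow closed forms, normalized so the single-scan DP
amplitude is 1 and bounded by the enhancement ratio
$\gamma_{\mathrm H}/\gamma_{\mathrm C} = 4$:

* CP: two-reservoir kinetics at contact time $t_{\mathrm{CP}}$,
  $I_{\mathrm{CP}} = \gamma_r(1 - T_{\mathrm{CH}}/T_{1\rho}^{\mathrm H})^{-1}
  [e^{-t_{\mathrm{CP}}/T_{1\rho}^{\mathrm H}} - e^{-t_{\mathrm{CP}}/T_{\mathrm{CH}}}]$,
  with the analytic limit at $T_{\mathrm{CH}} = T_{1\rho}^{\mathrm H}$.
* refocused INEPT:
  $I = \gamma_r \sin(\pi J \tau_2) F_n(\pi J \tau_2')\,
  e^{-\tau_2/T_2^{\mathrm H}} e^{-\tau_2'/T_2^{\mathrm C}}$ with
  $\tau_2 = 2\tau$, $\tau_2' = 2\tau'$ and the multiplicity refocusing
  factor $F_1 = \sin$, $F_2 = \sin\cos$, $F_3 = \sin\cos^2$.
* DP: 1, with an optional receiver-dead-time visibility factor (off by
  default).

### Closure constants and calibration

The relaxation closure needs four constants that no closed-form treatment
fixes a priori.  They are set once, as part of the model design, and are
not exposed as tuning knobs:

* $T_{\mathrm{CH},0} = 50\ \mu$s — a literature-typical rigid methylene CP
  build-up time at moderate MAS.
* $z = 3$ — effective number of bath protons contributing to homonuclear
  relaxation of each ^1^H.
* $\zeta = 0.035$ — the efficiency of the residual coherent dephasing
  term.  $\zeta$ is the one genuinely free scale; it is calibrated so that
  the computed map reproduces the technique's published regime boundary,
  CP/INEPT equality at $|S_{\mathrm{CH}}| \approx 0.1$ for
  $\tau_c = 1$ ns under the default acquisition settings.
* $a_{\mathrm{lib}} = 0.1$ — a floor on the fast-motion amplitude
  $1 - S^2$ used inside the relaxation model only.  Physically, even
  fully ordered segments keep small-amplitude librations; numerically it
  removes the degeneracy at exactly $|S_{\mathrm{CH}}| = 1$, where the
  literal two-step model would make every rate independent of $\tau_c$
  and the intermediate-regime dip (joint CP+INEPT loss around
  $\tau_c \sim 1\ \mu$s, driven by the $T_{1\rho}^{\mathrm H}$ minimum at
  $\omega_1 \tau_c \approx 1$) would vanish.  `spectral_density()` itself
  keeps the exact two-step form.

With these constants the map reproduces, without further adjustment, the
full set of regime statements: INEPT maximal and CP absent below
$|S_{\mathrm{CH}}| = 0.01$, equality near $0.1$, CP maximal and INEPT zero
above $0.5$, both transfers lost within a decade of $\tau_c = 1\ \mu$s,
and CP maximal in the slow regime.

```{r map, fig.width = 6, fig.height = 4, eval = FALSE}
map <- efficiency_map()
autoplot(map)
```

## Acquisition defaults

`experiment_settings()` mirrors the reference acquisition: 11.74 T
(^1^H/^13^C at 500/125 MHz), $\omega_R/2\pi = 5$ kHz MAS,
$t_{\mathrm{CP}} = 1$ ms ramped CP with $\omega_1^{\mathrm C}/2\pi = 80$ kHz
and the ^1^H ramp 72–88 kHz, INEPT delays $\tau = 1.8$ ms and
$\tau' = 1.2$ ms.  The default $J_{\mathrm{CH}} = 139$ Hz makes
$\tau \approx 1/(4J)$.  ^1^H–^1^H spin diffusion is outside the model: the
short contact time is chosen precisely so that it is negligible and CP
reflects local (one-bond) transfer.

## Spectral processing

The FID pipeline fixes the unstated details of the named processing steps:

* `apodize()`: exponential multiplication, default 10 Hz.
* `zero_fill()`: default 1597 → 8192 points.
* `transform()`: FFT with a half-weighted first point; ppm axis descending,
  built from the dwell time, the 125 MHz carbon frequency and a 110 ppm
  carrier.
* `auto_phase()`: zero- and first-order phases by minimizing the Shannon
  entropy of the derivative of the real part with a negative-intensity
  penalty; a deterministic coarse grid seeds Nelder–Mead, so identical
  input always yields identical phases.
* `baseline_correct()`: Eilers asymmetric least squares
  ($\lambda = 10^7$, $p = 10^{-3}$), with centring/scaling and two
  iterative-refinement steps so that a flat offset is removed to machine
  precision.
* `reference_to_glycine()`: constant axis shift pinning the anchor peak to
  the α-glycine methylene shift, 43.7 ppm, exactly.

## The assignment library

`sc_peak_table()` ships the shifts printed for intact pig SC: the lipid
chain markers (ωCH~3~ 14.6, (ω−1)CH~2~ 23.3, trans/gauche (CH~2~)~n~ 30.5,
(ω−2)CH~2~ 32.7, all-trans (CH~2~)~n~ 33.4 ppm), the keratin-core marker
Leu C~β~/Lys C~ε~ 40.6 ppm (stored as one compound entry) with the broad
backbone C~α~ envelope around 57 ppm, the terminal-domain markers Gly C~α~
43.7, Ser C~α~ 56.7 and Ser C~β~ 62.4 ppm, the mobile-cholesterol lines
(40.4–40.9, 42.8, 51.8, 57.6 ppm), and the 172.8 ppm carbonyl scaling
anchor.  Entries carry a `source` tag and user tables merge by precedence,
so a complete supplementary assignment can be layered on top.  The table
admits `NA` multiplicity for carbons without attached protons (carbonyls),
a deliberate relaxation of the {1,2,3} segment rule.

Two windows overlap other groups' markers by physical necessity — the
cholesterol C24/C12 line sits on the 40.6 ppm core peak, and the C~α~
envelope (default 53–60 ppm, configurable) spans the Ser C~α~ marker.
They ship flagged `use_for_calls = FALSE`: available for inspection,
excluded from default per-window state calls, which keeps the call windows
of distinct groups disjoint at the default 0.3 ppm half-width.

## The synthetic-sample generator

`sc_sample(rh, temperature)` emulates the hydration/heating narrative with
package-default abundances (the underlying study is qualitative about
them): a rigid all-trans lipid pool that melts with temperature and is gone
by 60 °C at ≥ 37 wt% water while a small solid pool survives at 24 wt%; a
mobile isotropic lipid pool ($|S_{\mathrm{CH}}| = 0.005$, ns dynamics)
present even when dry and growing with hydration and temperature; a rigid
keratin core under all conditions; terminal domains that switch abruptly
from rigid to mobile between 80 and 85 % RH and keep gaining amplitude on
further hydration; and mobile cholesterol lines only in the narrow window
around 85 % RH.  The tabulated NaCl-molality → RH pairs and the
RH → water-content pairs are available as lookups
(`rh_for_nacl_molality()`, `rh_water_content()`), and the gravimetric
definition as `water_content()`.

`simulate_fid()` renders each segment as an exponentially decaying complex
sinusoid — Lorentzian lines only, amplitude = abundance × scheme
efficiency, decay from $T_2^{\mathrm C}$ plus a per-segment static width —
with seeded circular Gaussian noise.  What the generator does *not*
emulate: MAS sidebands, chemical-exchange lineshapes, the crowded many-line
background of real SC, $B_0$ inhomogeneity, or quantitative fluid-lipid
fractions (the printed data are qualitative; the defaults are placeholders
flagged in the sample-state metadata).  Passing round-trip tests therefore
demonstrates internal consistency of model, processing and interpretation —
not quantitative fidelity to any real spectrum.

## Interpretation rules

`measure_peak()` integrates a window trapezoidally after subtracting the
local chord through the window edges; that chord is what discounts broad
underlying envelopes (e.g. the backbone C~α~ region under the sharp Ser
C~α~ line), mirroring how the overlaid spectra are read by eye.
`classify_peaks()` normalizes all areas by the sample's total DP area
(making calls invariant to common rescaling), thresholds presence at 5 % of
the per-scheme maximum, and reads INEPT presence as the operational
definition of "mobile".  CP and INEPT are "comparable" — the anisotropic
signature — when their raw ratio falls in $[0.5, 2]$; the published visual
criterion states no ratio, so the band is explicit and configurable.
A window with none of the three schemes present is `ambiguous`, and
`intermediate` requires DP to be present, so empty spectral regions are
never reported as intermediate dynamics.

`detect_transition()` scans a group's summed INEPT signature along an
RH-ordered series and reports the first adjacent pair where the area rises
from below to at least 20 % of the series maximum *and stays there* — a
state change, not a spike.  The persistence requirement is what keeps the
transient cholesterol INEPT contribution near 85 % RH (which overlaps the
40.6 ppm core window) from being mistaken for a keratin-core transition,
while the genuine terminal-domain onset between 80 and 85 % RH is
reported.  Groups whose peak INEPT never exceeds 2 % of the strongest
group's are treated as INEPT-silent.

## Problem sizes and numerical choices

The shipped tests run the full stack at the sizes a desk validation needs:
1597-point FIDs zero-filled to 8192, 100-replicate round-trip
classification at SNR 50, 100-point quadrature checks of the spectral
density (composite Simpson with steps resolving both the decay and the
oscillation), and regime scans on log grids with 8 points per decade.
Determinism is enforced throughout: every stochastic operation takes an
explicit integer seed, RNG state is restored after use, and processing is
seed-free.

## Known limitations

* The relaxation closure is semi-empirical; coefficients of the Redfield
  linear combinations and the MAS-averaging rule are committed choices,
  adequate for regime boundaries, not for quantitative relaxation-time
  prediction.
* No density-matrix/Floquet spin dynamics, TPPM decoupling effects, or CSA
  relaxation.
* The CP model treats the ramp as effective matching at the first sideband;
  Hartmann–Hahn mismatch profiles are not computed.
* Classification assumes resolved signature windows; heavily overlapped
  peaks need the context windows and human judgement, as in the visual
  analysis the method descends from.
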