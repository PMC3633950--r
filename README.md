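# ptnmr

Forward modelling and interpretation of polarization-transfer
natural-abundance ¹³C solid-state NMR (PT ssNMR) under magic-angle
spinning, built around the system the method was developed for: the
stratum corneum (SC), the outermost skin layer, whose permeability is
controlled by how hydration and temperature mobilize its lipid matrix and
keratin filaments.

PT ssNMR overlays three ¹³C acquisition schemes on one sample — DP (direct
polarization, a near-quantitative reference), CP (through-space dipolar
transfer, efficient only for rigid or anisotropic segments) and refocused
INEPT (through-bond J transfer, efficient only for mobile segments) — and
reads the dynamic state of every resolved peak from which schemes light it
up.  The package is for spectroscopists and biophysicists who want to
simulate, process and interpret such data, or to explore how the readout
depends on motional and acquisition parameters.

## The model

Each C–Hₙ segment is described by a two-step motional model: order
parameter |S_CH|, fast correlation time τ_c, slow correlation time τ_s,
with correlation function

    C(t) = (1 − S²) exp(−t/τ_c) + S² exp(−t/τ_s)

and reduced spectral density J(ω) = (2/5)[(1−S²)τ_c/(1+ω²τ_c²) +
S²τ_s/(1+ω²τ_s²)].  From J(ω) the package computes the relaxation and
transfer parameters T₂ᴴ, T₂ᶜ, T₁ρᴴ and T_CH (with MAS handled by
evaluating secular terms at ω_R and 2ω_R, and the CP ramp as effective
n = ±1 Hartmann–Hahn sideband matching), then the normalized intensities

    I_DP = 1
    I_CP = γr (1 − T_CH/T₁ρᴴ)⁻¹ [exp(−t_CP/T₁ρᴴ) − exp(−t_CP/T_CH)]
    I_INEPT = γr sin(πJτ₂) Fₙ(πJτ₂′) exp(−τ₂/T₂ᴴ) exp(−τ₂′/T₂ᶜ)

with γr = γH/γC = 4 and Fₙ the multiplicity refocusing factor.  The
resulting τ_c × |S_CH| efficiency map reproduces the regime boundaries the
technique is read by: CP/INEPT equality at |S_CH| ≈ 0.1 (τ_c = 1 ns),
INEPT-only below 0.01, CP-only above 0.5, and joint inefficiency around
τ_c ≈ 1 µs.  See the methods vignette
(`vignettes/pt-ssnmr-methods.Rmd`) for the relaxation closure and its
calibration.

Around the model sit: a curated ¹³C assignment library for SC components
with signature-peak windows; an FID→spectrum pipeline (10 Hz exponential
apodization, 1597→8192 zero-filling, FFT, deterministic entropy-based
auto-phasing, asymmetric-least-squares baseline, α-glycine referencing at
43.7 ppm); a synthetic SC-sample generator spanning hydration (RH via
NaCl-solution molalities) and temperature states; and an interpreter that
turns DP/CP/INEPT peak triplets into per-window dynamic-state calls,
hydration/temperature trend reports and transition detection.

## Worked example

Simulate a hydrated SC sample (RH 90 %, 32 °C) at a spectral
signal-to-noise ratio of 50, process the three FIDs, and classify the
signature windows:

```r
library(ptnmr)

# one segment: nearly isotropic, ns dynamics -> INEPT lights up, CP dark
efficiency_triplet(motion_model(0.005, 2e-9), spin_segment(2),
                   experiment_settings())
#>   order_parameter tau_c tau_s i_dp    i_cp i_inept
#> 1           0.005 2e-09     1    1 0.00197    1.37

spec    <- sc_sample(90, 32, seed = 1)
triplet <- simulate_triplet(spec, snr = 50, seed = 1)
classify_peaks(triplet)[, c("group", "moiety", "state_call")]
#>                 group                     moiety       state_call
#> 1              lipids           (CH2)n all-trans       rigid_slow
#> 2              lipids        (CH2)n trans/gauche mobile_isotropic
#> 3              lipids              (omega-1) CH2 mobile_isotropic
#> 4              lipids                  omega CH3 mobile_isotropic
#> 5   keratin_terminals                Gly C_alpha mobile_isotropic
#> 6   keratin_terminals                Ser C_alpha mobile_isotropic
#> 7   keratin_terminals                 Ser C_beta mobile_isotropic
#> 8        keratin_core Leu C_beta / Lys C_epsilon       rigid_slow
#> ...
```

At RH 90 % the bulk all-trans lipid pool and the keratin filament core are
rigid (CP-only), while the chain-end lipid markers and the
glycine/serine-rich keratin terminal domains reorient almost isotropically
(INEPT without a matching CP).  A hydration series recovers the abrupt
terminal-domain transition:

```r
series <- lapply(c(80, 85, 90, 93, 96), function(rh)
  simulate_triplet(sc_sample(rh, 32, seed = rh), snr = 50, seed = rh))
rep <- series_report(series)
detect_transition(rep, "keratin_terminals")
#> lo hi
#> 80 85
detect_transition(rep, "keratin_core")
#> NULL
```

The keratin terminals switch from rigid to mobile between 80 % and 85 % RH;
the filament core shows no transition at any hydration.  `autoplot(rep)`
draws the blue/red (rigid/mobile) state summary, and
`autoplot(efficiency_map())` the CP/INEPT regime map.

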