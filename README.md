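# photokin

Photokinetic modelling and analysis of dark states in fluorescent proteins.

Red fluorescent proteins illuminated at the kW/cm² intensities of confocal
microscopy do not just fluoresce and bleach: a reversibly populated
non-fluorescent **dark state** drains the bright population on
microsecond-to-millisecond timescales and, when that dark state is
*photodestructive*, funnels molecules into irreversible photobleaching.
`photokin` is for spectroscopists and protein engineers who measure
fluorescence time traces and want to turn them into microscopic rate
constants — and for anyone who needs realistic synthetic traces to validate
such an analysis.

## The model

A three-state scheme with two bleaching channels (all rates in s⁻¹):

```
        k_ex               k_dsc
   S0 ─────────▶ S1   S1 ─────────▶ D
   S0 ◀───────── S1   S0 ◀───────── D
        k_f                k_gsr
   S1 ──k_SB──▶ bleached   D ──k_DB──▶ bleached
```

Because excitation and fluorescence (`k_ex` ~ MHz, `k_f = 1/τ_fl` ~ hundreds
of MHz) vastly outpace everything else, S0/S1 stay in rapid equilibrium,
governed by `q = k_f/k_ex + 1`. Two closed forms then summarize the signal,
with `q_D = k_dsc/k_gsr`:

- sub-millisecond decay: `S1_norm(t) = a_dsc·exp(−(k_gsr + k_dsc/q)·t) + (1 − a_dsc)`
  with the **DSC amplitude** `a_dsc = k_dsc/(k_dsc + q·k_gsr)`;
- slow photobleaching at the reduced system's slow eigenvalue,
  `λ_slow ≈ (k_SB + k_DB·q_D)/(q + q_D)`.

The package provides stiff and reduced ODE integrators over continuous,
pulse-pair and Gaussian-train illumination, seeded noisy trace generation,
and the complete extraction pipeline: single/bi/tri-exponential fits with
multi-start initialization, percent-recovery fitting for the ground-state
recovery (GSR) time, DSC amplitude extraction with algebraic inversion to
`τ_dsc`, global biexponential photobleaching fits with a shared intrinsic
`τ₁ = 1/k_SB`, and pulsed-versus-continuous photostability comparison.

## Worked example

Emulate a full measurement campaign for an mCherry-like protein
(fluorescence lifetime 1.72 ns, ε = 74,000 M⁻¹cm⁻¹, τ_dsc = 60 µs,
τ_gsr = 1.0 ms, τ₁ = 10 ms, k_DB = 30 s⁻¹) and re-extract the kinetics:

```r
library(photokin)

set <- reference_parameter_sets()$mcherry_like
p <- set$params
nz <- noise_model("gaussian", gaussian_sd = 0.01, seed = 7)  # SNR 100

# 1. ground-state recovery: pulse pairs at 10 kW/cm², 14 dark times x 3 reps
td <- 1e-3 * 10^seq(log10(0.02), 1, length.out = 14)
gsr <- simulate_gsr_experiment(p, td, intensity_kw_cm2 = 10, intensity_ref = 5,
                               sampling = 2e-6, readout_n = 5,
                               noise = nz, replicates = 3)

# 2. dark-state conversion: continuous 5 kW/cm² trace over 10 ms
dsc <- simulate_trace(p, make_waveform("constant", 5, duration = 10e-3),
                      sampling = 5e-6, method = "reduced")

# 3. photobleaching decays at 1, 5, 10 kW/cm²
bleach <- simulate_bleach_family(p, c(1, 5, 10), intensity_ref = 5, noise = nz)

report <- extract_kinetics(
  gsr = gsr, dsc = dsc, bleach = bleach,
  config = list(epsilon = 74000, tau_fl_ns = 1.72, wavelength_nm = 561,
                dsc_intensity_kw_cm2 = 5))
report
#> <kinetic extraction report>
#>   tau_gsr = 0.9647 ms
#>   a_dsc = 0.0945, tau_dsc = 63.07 us
#>   shared tau1 = 10.04 ms; tau_avg (ms): 691, 147, 83.8
#>   k_DB estimates (s^-1): 31.8, 33, 32.8
```

Reading the numbers: the fitted recovery time (0.96 ms) and the
amplitude-derived dark-state conversion time (63 µs) recover the generating
1.0 ms and 60 µs within a few percent at per-point SNR 100; the shared
bleaching constant comes back at 10.0 ms; and inverting the slow bleach rate
at each intensity estimates the dark-state bleaching rate `k_DB` at ~32 s⁻¹
against a true 30 s⁻¹ — the signature of a photodestructive dark state.
`tidy(report)` returns the same numbers with 95% confidence intervals as a
tibble, and `autoplot()` methods exist for traces, trajectories, recovery
curves and global fits.

A thin command-line wrapper with `simulate`, `fit-gsr`, `fit-dsc`,
`fit-bleach`, `extract`, `compare-illumination` and `recover` subcommands is
installed at `inst/scripts/photokin.R`.

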