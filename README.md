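# pulsewave

Desk-scale haemodynamics of **arterial compliance mismatch**: pulsatile
blood flow through a straight vessel whose middle segment is far more
compliant than its ends — the mechanical situation created when a stiff
bypass graft or prosthesis joins native artery. The package quantifies, per
location, the wall shear stress, pressure, circumferential (hoop) stress
and hoop strain differences that stiffness junctions induce, the quantities
implicated in intimal thickening and graft failure.

It is written for vascular biomechanics researchers and students who want a
transparent, fully testable reduced-order counterpart of 3D fluid–structure
simulations of grafted arteries.

## What it computes

The reference configuration is a carotid-calibre tube (inner diameter
D₀ = 8 mm, outer 10 mm) of three 50 mm segments with Young's moduli
200 / 5 / 200 MPa (Poisson's ratio 0.499), a 30 mm inlet extension, and
probes at 70, 100, 140 mm; blood has ρ = 1050 kg/m³, μ = 0.0035 Pa·s, and
the inlet carries a carotid-like periodic mean-velocity waveform (T = 1 s)
whose Reynolds number Re = ρD₀V/μ spans 190 (diastole) to 500 (peak
systole), giving Womersley number α = (D₀/2)√(2πρ/(Tμ)) ≈ 5.5.

Three model layers:

1. **Womersley analytics** — the exact harmonic solution for pulsatile flow
   in a rigid tube: velocity profiles u_k(r) ∝ 1 − J₀(i^{3/2}α_k r/R)/J₀(i^{3/2}α_k),
   wall shear stress with its phase lead, and back-computed pressure
   gradient. Serves as output and as the solver's analytic oracle.
2. **1D pulse-wave solver** — the area-averaged mass/momentum system
   ∂A/∂t + ∂Q/∂x = 0, ∂Q/∂t + ∂(Q²/A)/∂x = −(A/ρ)∂p/∂x − 8πν Q/A, closed
   by the elastic tube law p = β(√A − √A₀) with segment-wise
   β = √π h E/((1−ν²)A₀). MacCormack scheme, characteristic boundaries
   (velocity inlet, non-reflecting outlet), exact volume audit. Waves
   reflect at stiffness junctions with the impedance-mismatch coefficient
   (Z₂−Z₁)/(Z₁+Z₂) ≈ −0.727 for the 40× modulus drop.
3. **Wall mechanics** — Lamé thick-cylinder hoop stress at the inner wall
   and hoop strain by both the kinematic (distension) and constitutive
   (Hooke's law) routes.

A deterministic waveform generator (diastolic plateau + Gaussian systolic
pulse, band-limited, Reynolds-anchored) provides the inlet signal; a
digitized measured waveform can be substituted via two-column CSV.

## Worked example

```r
library(pulsewave)

model    <- build_default_model()
blood    <- fluid_properties()          # 1050 kg/m^3, 0.0035 Pa s
waveform <- generate_waveform(waveform_params(), 256)

womersley_number(blood, model$geometry, 1)
#> [1] 5.491747

run <- simulate_pulse_wave(model, waveform, blood)
print(run)
#> 1D pulse-wave run: 360 cells (dx = 0.5 mm), dt = 2.52 us, 3 cycles
#>   segment wave speeds: 178.1, 28.2, 178.1 m/s
#>   cycle convergence (max rel. change, last two cycles): 2.10e-12, 3.04e-13, 1.05e-12
#>   converged: TRUE; volume audit rel. error: 1.14e-15; max CFL 0.899

summarize_run(run)
#> Per-probe final-cycle extrema:
#>  probe_mm       quantity          max          min      abs_max
#>        70         wss_Pa 7.285682e-01 2.770351e-01 7.285682e-01
#>        70    hoop_strain 5.834011e-04 2.225595e-04 5.834011e-04
#>       100         wss_Pa 6.792397e-01 2.699496e-01 6.792397e-01
#>       100    hoop_strain 2.333276e-02 8.900006e-03 2.333276e-02
#>       140         wss_Pa 7.259566e-01 2.770372e-01 7.259566e-01
#>       140    hoop_strain 5.830918e-04 2.224174e-04 5.830918e-04
#>   ...
#> largest absolute extremum per quantity:
#>   wss_Pa           70 mm
#>   pressure_Pa      70 mm
#>   hoop_stress_Pa   70 mm
#>   hoop_strain      100 mm
```

Reading the numbers: the three segments carry near-identical pressure and
wall-shear waveforms (pairwise shape similarity > 0.999), but the compliant
middle probe (100 mm) strains about **40× more** than the stiff probes —
2.3×10⁻² vs 5.8×10⁻⁴ cycle-max hoop strain — exactly the modulus ratio, the
mechanical signature of compliance mismatch. Wave speeds are 28 m/s in the
compliant segment and √40 ≈ 6.3× higher in the stiff ones.

The full pipeline with file outputs (per-probe CSVs, tidy summary, JSON
report):

```r
run_pipeline(config_from_list(list()), "out")
```

or from a shell via `Rscript inst/scripts/pulsewave.R simulate --out out`
(`womersley`, `waveform` and `compare` subcommands exist too). Runs are
configured by a unit-suffixed YAML schema, documented in `?read_config`.

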