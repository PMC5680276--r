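# flagbeat

Analysis of the planar flagellar beat of tethered sperm, and of the
steering mechanism hidden in its **second harmonic**.

A tethered sperm cell beats its flagellum and slowly revolves around the
tethering point.  A single-frequency planar beat is temporally
mirror-symmetric — `C(s,t) = -C(s, t + τ/2)` — and produces no net torque.
Rotation arises because the curvature wave carries a second harmonic:

    C(s,t) = C0 + C1 sin(ks − ω0t) + C2 sin(ks − 2ω0t + φ)

Coupled to the anisotropic drag of the slender flagellum (ξ⊥/ξ∥ ≈ 1.81),
the second harmonic yields, in the wavelength-matched limit λ → L,

    Ω = −ω0 · (3L³ / 4(2π)⁴) · ((ξ⊥ − ξ∥)/ξ⊥) · C1² C2 sin φ

so the rotation velocity tracks the *second-harmonic intensity*
`C2 sin φ`.  The package implements the full chain needed to test this on
data or in silico:

* **synthetic data** — two-harmonic curvature waves with slowly drifting
  harmonic parameters, tracked-point series of rotating cells, and
  rendered dark-field-like image stacks with stored ground truth;
* **tracking** — adaptive binarisation, skeleton-based midline ordering
  with sub-pixel refinement, head-ellipse fitting, fixed-step arclength
  resampling with the common-window rule;
* **kinematics** — three-point signed curvature fields, Gaussian-filtered
  rotation velocity, the mirror-symmetry defect, sliding-window average
  curvature;
* **modes** — principal beat modes of the arclength covariance,
  significance against a random-curvature null, limit-cycle phase and the
  conditional beat frequency ω(α), cross-cell mode alignment in
  wavelength units;
* **harmonics** — windowed Fourier estimation of ω0(t), C1(t), C2(t),
  φ(t), and the non-centred steering correlation R between Ω/ω0 and
  C2 sin(φ + φ0) with the per-recording offset φ0;
* **theory** — the RFT closed forms above (plus the intrinsic-curvature
  analogue) and an exact-shape numerical rotation oracle;
* **simulator** — an overdamped inextensible active filament driven by a
  two-harmonic torque wave, in tethered and free-swimming modes, with an
  exact discrete energy ledger and period-averaged power profiles.

## Worked example

```r
library(flagbeat)

# a synthetic tethered cell: 20 s of beating at 20 Hz with a drifting
# second harmonic, rotation driven by the second-harmonic intensity
t <- seq(0, 20, by = 1 / 500)
drift <- random_drift(t, C2_mean = 0.015, C2_sd = 0.005,
                      phi_mean = 0.8, phi_sd = 0.6,
                      noise_sd = 0.005, seed = 2)
spec <- waveform_spec(C1 = 0.1, C2 = 0.015, f0 = 20, lambda = 40, L = 40)
drag <- drag_model()
K <- spec$omega0 * (3 * spec$L^3 / (4 * (2 * pi)^4)) * (1 - 1 / drag$ratio) / (2 * pi)
omega_true <- approxfun(t, K * spec$C1^2 * drift$C2_fun(t) *
                          sin(drift$phi_fun(t) + 0.7), rule = 2)
cell <- gen_rotating_cell(spec, drift, omega_fun = omega_true,
                          s = seq(0, 36, by = 0.9), t = t, skip_points = 3,
                          seed = 3)

field <- curvature_three_point(cell)   # curvature kymograph C(s,t)
rot   <- rotation_velocity(cell)       # filtered Omega(t), rev/s
trace <- spectrogram_harmonics(field, s0 = 15)
print(trace)
#> Harmonic trace: 326 windows (0 masked)
#>   f0 = 20.00 +/- 0.08 Hz,  C1 = 0.09926,  C2 = 0.01467 1/um,  C2/C1 = 0.148
#>   phi (circular mean) = 0.818 rad

modes <- covariance_modes(field)
print(modes)
#> Mode decomposition: 36 modes over 36 arclength points
#>   leading variance fractions: 0.597, 0.402, 0.000, 0.000, 0.000
significant_modes(modes, field, seed = 4)
#> [1] 2

opt <- optimize_phase_offset(rot, trace)
sprintf("R = %.3f at phi0 = %.3f rad", opt$R_max, opt$phi0)
#> [1] "R = 0.979 at phi0 = 0.813 rad"
```

The spectrogram recovers the generator's amplitudes (C1 = 0.1,
C2 = 0.015 1/µm on average) and phase to a few percent; the first two
beat modes carry essentially all the variance and are the only
significant ones against the random-curvature null; and the
second-harmonic intensity explains the rotation velocity with R ≈ 0.98,
the optimal offset landing near the injected 0.7 rad (to about a tenth
of a radian at this record length and drift range).

The simulator side mirrors the tethered-cell experiments:

```r
sim <- simulate_filament(filament_model(), torque_spec(), duration = 0.5)
measure_rotation(sim)$Omega        # steady rotation, rev/s
power_profiles(sim)                # P_d(s), P_g(s) and their balance
sweep_drive(filament_model(), torque_spec(), "T_star",
            grid = seq(0.05, 0.3, by = 0.05))
```

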