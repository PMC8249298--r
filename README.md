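# flagbeat

Quantitative analysis of three-dimensional flagellar beat patterns and the
swimming paths they generate.

Sperm cells are propelled by bending waves traveling along the flagellum.
Seen in 3D, those waves are not always planar: human sperm flagella carry
traveling *torsion* waves whose peaks sit in the low-curvature (straight)
regions of the curvature wave, so an instantaneous flagellar shape looks
like two nearly flat segments joined with a twist. Whether the beat is
planar and asymmetric (sea-urchin-like) or non-planar and symmetric
(human-like) decides whether the cell swims in circles, on helices, or
straight ahead while rolling — the "twisted ribbon" path. This package
implements the full analysis chain needed to quantify these questions from
tracked 3D centerlines, plus a synthetic-beat generator and a
resistive-force-theory simulator so every stage can be validated against
known ground truth. It is aimed at labs doing holographic or multifocal 3D
flagellar tracking, and at modellers who need a tested beat-to-path map.

## What it computes

**Co-moving frames and non-planarity.** For each tracked shape, the
gyration tensor G = N⁻¹ Σᵢ (pᵢ − p̄)(pᵢ − p̄)ᵀ gives principal axes
e₁, e₂, e₃ (eigenvalues λ₁ ≥ λ₂ ≥ λ₃): e₁ is the elongation axis, (e₁, e₂)
the instantaneous beat plane, e₃ its normal. The non-planarity ratio is
Γ = r₃/r₂ with rᵢ = √λᵢ. Rolling vs wobbling is read from the rotation of
e₃ about e₁ (`gyration_frames()`, `nonplanarity()`, `rolling_analysis()`,
`comoving_projection()`, `mean_projected_curvature()`).

**Robust curvature and torsion.** Spline-derivative Frenet formulas
amplify tracking noise, so κ and τ are estimated geometrically: a sliding
window (default 5 µm) is fit with a least-squares line and osculating
plane, with a continuity prior (weight 0.1) on the plane-normal rotation
between adjacent windows; |κ| is the inverse radius of a Taubin circle fit
in the osculating plane, signed by the frame's rotation sense about the
binormal (the global sign of κ(s,t) is a gauge choice); τ is the rotation
rate of the binormal about the tangent (`frenet_frames()`,
`taubin_circle_fit()`, `compute_kymographs()`).

**Two-segment non-planarity.** Splitting a shape at arclength s gives
Γ̄(s) = sΓ₁/L + (L−s)Γ₂/L; its minimum Γ_ts = min Γ̄(s) and argmin s_ts
(the *torsion point*) quantify how well the shape decomposes into two flat
segments (`two_segment_nonplanarity()`).

**Wave statistics.** Normalized autocorrelation A(s, Δt) of κ gives the
beat period T; the normalized cross-correlation C(s, Δt) between |κ| and τ
gives the phase shift of the torsion wave relative to the curvature wave
(`curvature_autocorrelation()`, `curvature_torsion_crosscorrelation()`).

**Trajectory metrics.** Averaged path (beat-period moving average), speed
v_ap, circle radius r, yaw rate Ω_yaw (trend of the head-orientation
angle; geometrically Ω_yaw ≈ v_ap/r for circular swimming), out-of-plane
excursion Δz, and the beat frequency from head wiggling
(`averaged_path()`, `path_speed()`, `fit_circle_and_yaw()`,
`wiggling_metrics()`).

**Beat-to-path simulation.** Resistive-force theory (anisotropic local
drag, ξ⊥/ξ∥ = 1.81 by default) maps a prescribed body-frame beat to a
lab-frame trajectory by solving the 6×6 force- and torque-free balance per
time step (`simulate_swimming()`, `classify_path()`): an asymmetric planar
beat yields a circle, an asymmetric non-planar beat a helix, and a
symmetric beat with constant torsion a straight path with continuous
rolling (twisted ribbon).

**Filament tracking.** A cone-search tracker extracts centerlines from 3D
intensity volumes: a cone anchored at the current end is rotated over a
yaw (±45°) and pitch (±30°) grid, the orientation with the largest
intensity integral wins, and the intensity-weighted centroid becomes the
next control point (`track_filament()`, `detect_seed()`,
`render_filament_volume()`).

**Synthetic ground truth.** Traveling-wave beats are built by integrating
the Frenet–Serret equations from prescribed κ(s,t), τ(s,t)
(`shape_from_curvature_torsion()`, `make_planar_asymmetric_beat()`,
`make_symmetric_torsion_beat()`, `make_twisted_plane_beat()`,
`make_custom_beat()`, `add_tracking_noise()`).

## Worked example

A human-like twisted-plane beat — symmetric curvature wave with a negative
torsion pulse riding the descending curvature zero-crossing — analyzed end
to end:

```r
library(flagbeat)

params <- beat_params(K0 = 0, K1 = 0.08, lambda_w = 45, T_beat = 1/30,
                      tau0 = 0.1, torsion_mode = "pulse_at_low_curvature",
                      duration = 0.135, frame_rate = 1000)
rec <- make_twisted_plane_beat(params)
rec
#> <beat_recording> 136 frames, 0.135 s, 91 points/frame, L = 45.0 um

Gamma <- sapply(gyration_frames(rec), function(f) f$Gamma)
sprintf("mean non-planarity <Gamma> = %.3f (range %.3f-%.3f)",
        mean(Gamma), min(Gamma), max(Gamma))
#> "mean non-planarity <Gamma> = 0.143 (range 0.002-0.557)"

two_segment_nonplanarity(rec$frames[[40]])
#> <two_segment_result> Gamma_ts = 0.0015 at s_ts = 33.50 um

kym <- compute_kymographs(rec, T_beat = 1/30)
cc <- curvature_torsion_crosscorrelation(kym)
sprintf("beat period T = %.1f ms; torsion-curvature phase shift = %.2f T",
        1000 * cc$T_beat, cc$phase_shift)
#> "beat period T = 33.0 ms; torsion-curvature phase shift = 0.24 T"
```

The non-planarity Γ oscillates within the beat while the two-segment
non-planarity Γ_ts stays two orders of magnitude smaller — the shape is
two flat pieces joined at a torsion point (here at 33.5 µm, on the
low-curvature region). The torsion wave is phase-shifted by a quarter beat
period relative to the |curvature| wave, i.e. torsion peaks where the
flagellum is straight.

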