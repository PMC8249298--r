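---
title: "Methods: estimating 3D flagellar curvature, torsion, and swimming behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating 3D flagellar curvature, torsion, and swimming behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and numerical choices behind
`flagbeat`, in the spirit of a methods section: what is assumed, which
knobs matter, and what the validation on synthetic data does and does not
establish.

## The shape model

A flagellar shape is an arclength-parameterized space curve. Any such
curve is fully characterized, up to a rigid motion, by its curvature
profile $\kappa(s)$ and torsion profile $\tau(s)$ through the
Frenet–Serret equations
$\mathbf{t}' = \kappa\mathbf{n}$,
$\mathbf{n}' = -\kappa\mathbf{t} + \tau\mathbf{b}$,
$\mathbf{b}' = -\tau\mathbf{n}$.
A beat pattern is the pair $\kappa(s,t), \tau(s,t)$. The package treats
the forward direction (build shapes from profiles,
`shape_from_curvature_torsion()`) as the ground-truth oracle for the
inverse direction (estimate profiles from tracked points,
`frenet_frames()`); round-trip recovery is the backbone of the test
suite.

Tracked shapes are stored at uniform spacing $\Delta s = 0.5$ µm
(`flagellar_shape()` resamples raw polylines with a cubic spline and
exact chord-length marching). 0.5 µm gives at least ten points per 5 µm
estimation window while staying well above typical holographic tracking
noise (tens of nanometers).

## Robust curvature and torsion estimation

Finite differences or spline derivatives estimate
$\kappa \propto |\mathbf{r}''|$ and $\tau$ from third derivatives; on
noisy data these are hopeless. The estimator instead uses the elementary
geometric definitions:

1. **Sliding window.** For each sample, the points within
   `window_length` (default 5 µm) centered on it are collected. Samples
   within half a window of either end are masked invalid.
2. **Tangent and osculating plane.** The tangent is the principal
   direction of the windowed points. The plane normal (binormal
   direction) minimizes the squared out-of-plane residuals in the 2D
   subspace orthogonal to the tangent, *plus a continuity prior*: the
   quadratic form is augmented with
   $w\,\lambda_{\mathrm{in}}\,\sin^2\theta$, where $\theta$ is the angle
   to the previous window's normal, $\lambda_{\mathrm{in}}$ the in-plane
   window variance, and $w$ = `regularization_weight` = 0.1. Scaling by
   $\lambda_{\mathrm{in}}$ makes the penalty commensurate with the
   residual increase that rotating the plane by $\theta$ would cause, so
   the single dimensionless weight 0.1 has the same meaning on every
   window.
3. **Forward–backward sweep.** A purely sequential prior drags the plane
   normal behind the true rotation (a causal lag that biases $\tau$
   low). The fit is therefore run once head-to-tip and once tip-to-head,
   and the two binormal fields are averaged; the lags cancel by
   symmetry. On a noiseless reference helix (radius 5 µm, pitch
   parameter 2 µm) the mid-curve torsion bias is ~2% and is independent
   of the weight, so the prior can be kept active for noise robustness
   without paying a bias.
4. **Osculating circle.** $|\kappa|$ is the inverse radius of a Taubin
   algebraic circle fit to the window points projected into the
   osculating plane. Taubin's fit is exact on true circles and nearly
   unbiased on short arcs, which is why it is preferred over the Kåsa
   fit here. Collinear windows get $\kappa = 0$ and an undefined plane.
5. **Sign and gauge.** $\kappa$ is signed by the rotation sense of the
   continuous frame about the binormal (circle center on the
   $+\mathbf{n}$ side $\Rightarrow \kappa > 0$). Because
   $(\mathbf{n}, \mathbf{b}) \to (-\mathbf{n}, -\mathbf{b})$ flips
   $\kappa$ and preserves $\tau$, the global sign is a gauge choice; per
   recording it is fixed so the spatio-temporal mean of $\kappa$ over
   the first beat period is non-negative, and adjacent frames are kept
   sign-consistent.
6. **Torsion.** $\tau$ is the rotation rate of the binormal about the
   tangent per unit arclength. Adjacent windows share most of their
   points, so their normals are strongly correlated and a two-sample
   rotation rate is mostly noise; the per-step rates are therefore
   averaged over a baseline of **two** window lengths, whose endpoints
   are statistically independent windows. $\tau$ is masked where
   $|\kappa| <$ `curvature_floor` (default 0.005 µm⁻¹): at inflection
   points the normal direction is ill-conditioned and torsion estimates
   there are meaningless.

**Resolution limits.** The window must resolve the osculating circle:
for shapes bent more tightly than roughly one window length per radian
the 5 µm default materially biases $\kappa$, and the property tests
shrink the window to `min(5, 0.8/kappa)` for such helices. Similarly,
torsion is only identifiable when the out-of-plane signal inside a
window exceeds the tracking noise; with 0.05 µm point noise a nearly
straight window (lateral sagitta below ~0.05 µm) carries no recoverable
torsion, whatever the estimator. The noisy-recovery tests therefore run
at the reference helix scale (radius 5 µm, pitch parameter 2 µm), where
recovery within 15% is attainable; users should expect the same limit on
real data. The two-window torsion baseline also sets the arclength
resolution of τ: pulses narrower than ~10 µm keep their location but are
attenuated in amplitude.

## Gyration frames, non-planarity, and the two-segment statistic

The gyration tensor of the centerline points (head excluded; uniform
point weights, i.e. uniform arclength mass density) defines the
co-moving frame. Eigenvector signs are fixed on the first frame (e₁
along the proximal→distal chord, e₂ toward the lateral midpoint offset,
e₃ = e₁×e₂) and propagated by positive dot product with the previous
frame; when λ₂ ≈ λ₃ (relative gap < 1e-6) the previous (e₂, e₃)
orientation is carried to keep roll angles well defined. The
non-planarity ratio Γ = r₃/r₂ is undefined for straight shapes (λ₂ = 0);
the function returns `NA` with a warning.

The two-segment non-planarity scans all split points on the grid at
least `min_segment` (default one window, 5 µm) from the ends; segments
that are straight are treated as perfectly planar (Γ = 0) and flagged.
Ties in the minimum are broken toward the split nearest mid-flagellum.

Rolling is positive when the beat plane turns clockwise viewed from the
head toward the distal tip (right-hand rotation about e₁). A cell is
classified "rolling" when the roll rate keeps one sign for more than 90%
of samples — a pragmatic cutoff; the rolling/wobbling distinction is
qualitative in the underlying phenomenology.

## Wave statistics

The curvature autocorrelation $A(s, \Delta t)$ and the
|curvature|–torsion cross-correlation $C(s, \Delta t)$ are computed per
arclength sample and averaged over an arclength band (default
29.5–30.5 µm for $C$, mid-flagellum where torsion is most reliable).
Masked kymograph entries are handled by pairwise deletion per lag, with
means and variances taken over the same overlapping pairs — this keeps
$|C| \le 1$ exactly (Cauchy–Schwarz) and agrees with the global-moment
normalization for long stationary records. The beat period $T$ is the
first positive-lag local maximum of $A$; the torsion phase shift is the
lag of the extremum of $|C|$ nearest zero, excluding the central
(zero-lag) extremum — extrema of $|C|$ for wave signals are at least a
quarter period apart, so anything within $T/8$ of zero is treated as
central. The extremum of $|C|$ (not of $C$) is used so the estimate does
not depend on the torsion sign convention. Lags up to 1.5 $T$ are
scanned.

## Trajectory metrics

The averaged path is a centered moving average over one beat period
(endpoints trimmed). $\Omega_{\mathrm{yaw}}$ is the slope of a linear
fit to the unwrapped head-orientation angle (lab xy projection of the
head long axis) — the slow trend under the beat-frequency wiggling. Note
that a zero-mean oscillation is not exactly orthogonal to a linear trend
over a finite record; the residual slope bias is
$O(A/(n_{\mathrm{periods}} \pi T_{\mathrm{rec}}))$ and negligible for
records of many beats. $\Delta z$ is the maximal deviation of $z$ from
its one-period running mean (the underlying definition leaves the
baseline open; the running mean makes $\Delta z$ insensitive to slow
drift). The beat frequency is the dominant periodogram peak of the
detrended head-orientation angle with parabolic sub-bin refinement.

## Resistive-force-theory simulation

The simulator prescribes a periodic body-frame beat and computes the
rigid-body motion from local anisotropic drag: force density
$\mathbf{f} = -[\xi_\parallel \mathbf{t}\mathbf{t}^\top + \xi_\perp
(I - \mathbf{t}\mathbf{t}^\top)]\,\mathbf{v}$, with
$\xi_\perp/\xi_\parallel$ = 1.81 (slender-body value for a typical
flagellar aspect ratio; configurable). Per step the deformation velocity
comes from consecutive shapes, drag is evaluated on the midpoint shape
with trapezoid quadrature, and the unknown $(\mathbf{V}, \boldsymbol\Omega)$
solve the 6×6 linear system expressing zero total force and torque
(inertia-free Stokes flow). Orientation advances by the rotation
exponential of $\boldsymbol\Omega\,\mathrm{d}t$ (re-orthonormalized via
SVD each step); position uses the midpoint orientation. Because Stokes
dynamics are linear in rates, halving the beat period exactly doubles
the swimming speed — this scaling, the per-step force/torque residuals
(< 1e-9 relative), and the equivariance of the trajectory under
rotations of the initial orientation are tested invariants. An optional
isotropic head drag is off by default: the stereotypical path classes
emerge from the flagellar drag alone, and no head geometry is assumed.

Path classification uses the gyration spectrum of the averaged path:
lateral/axial extent below 0.1 → straight (with monotonic rolling:
twisted ribbon); otherwise planar (path non-planarity < 0.1, total yaw
turn > π/4) → circle; otherwise helix. The 0.1 thresholds are design
choices validated on the three generator classes; paths straddling them
return "unclassified" with diagnostics rather than a guess.

## Synthetic data: what it emulates, and what it does not

The generators produce the three beat classes the analysis
distinguishes, all as traveling waves
$\kappa(s,t) = K_0 + K_1 \sin(2\pi s/\lambda_w - 2\pi t/T)$:

* **planar asymmetric** ($K_0 > 0$, $\tau = 0$): sea-urchin-like;
  defaults $K_0 = 0.03$, $K_1 = 0.08$ µm⁻¹, $\lambda_w = 40$ µm,
  beat ~30–40 Hz.
* **symmetric with constant torsion** ($K_0 = 0$, $\tau = \tau_0$):
  the mirror symmetry $\kappa(s,t) = -\kappa(s,t+T/2)$ holds exactly;
  default $\tau_0 = 0.02$ µm⁻¹.
* **twisted-plane** ($K_0 = 0$, $\lambda_w = L$): a Gaussian torsion
  pulse (s.d. $L/20$, amplitude $-\tau_0$, default $\tau_0 = 0.1$ µm⁻¹,
  periodic images at $\pm\lambda_w$) centered on the descending
  zero-crossing of the curvature wave and traveling with it. Torsion is
  everywhere non-positive (homochiral). The pulse shape and amplitude
  are order-of-magnitude choices — the phenomenology being emulated only
  localizes torsion peaks at low-curvature regions.

Defaults $L = 45$ µm, $T = 1/30$ s and 1000 frames/s match typical sperm
scales and high-speed holographic imaging. Tracking noise is i.i.d.
isotropic Gaussian per point followed by re-resampling; real tracking
error is likely anisotropic (worse along the optical axis) and spatially
correlated, neither of which is characterized here. Passing tests on
these synthetics establishes correctness of the estimators under the
stated noise model and scales — not performance on real holograms, where
segmentation artifacts, missing segments, and depth-dependent blur
dominate. The intensity-volume phantoms (isotropic Gaussian blobs along
the centerline) likewise validate the cone-search tracker's geometry,
not hologram reconstruction, which is out of scope.

## Numerical choices and degenerate inputs

* Frenet–Serret integration: `deSolve::lsoda`, rtol = atol = 1e-11;
  planar profiles stay exactly planar because the out-of-plane
  derivatives vanish identically.
* Taubin fit: Chernov's Newton iteration on the characteristic
  polynomial, started at 0; collinear input returns infinite radius and
  a flag (treated as zero curvature).
* Resampling: natural cubic spline on the chord-length parameter,
  sampled at ≥ 20× density, then exact chord-distance marching (each
  step solves the quadratic for the segment intersection), so
  consecutive points are spaced within 1e-6 µm of $\Delta s$.
* Cone tracker: exhaustive 5° grid scan (no gradient ascent) for
  determinism; termination when the winning cone integral drops below
  0.2 × the running median, the cone leaves the volume, or `max_length`
  is reached. Cone length 3 µm and half-angle 20° are defaults exposed
  in `tracker_config()`. All thresholds are relative to the volume's own
  intensities, so tracking is invariant under global intensity
  rescaling. Tied intensity maxima in seed detection resolve
  first-in-scan-order with a warning.
* Rolling analysis requires e₁ and e₃ to stay separated (error if
  nearly parallel); the co-moving projection errors out when the head
  axis is nearly orthogonal to the beat plane (projection norm < 1e-3).

## Problem sizes

The shipped tests and the acceptance script run at deliberately small
sizes chosen to exercise every code path at the study's physical scales:
beats of 91 points (45 µm at 0.5 µm), records of 0.02–0.135 s at
500–1000 frames/s for estimator checks, resistive-force-theory
simulations of 3–20 beat periods at 60 steps per period, and phantom
volumes of ~10⁵–10⁶ voxels at 0.25 µm. The whole suite completes in a
few minutes on one CPU.

## Known limitations

* Torsion is unreliable near inflection points (masked by the curvature
  floor) and within half a window of the flagellar ends; it is reported
  only where the geometry supports it.
* The two-segment statistic assumes a single torsion point; shapes with
  several twists yield a compromise split.
* The RFT simulator neglects hydrodynamic interactions with walls and
  between flagellum and head, and all elastohydrodynamics: the beat is
  prescribed, not emergent.
* Helical averaged-path metrics (helix radius/pitch estimation) are
  limited to classification; precise helix parameter estimation is not
  implemented.
* The import adapter for externally deposited tracking data is limited
  to this package's own track schema.
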