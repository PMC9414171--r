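---
title: "Models and design of the simulated denudation workstation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the simulated denudation workstation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denudakit)
```

# The problem

Before intracytoplasmic sperm injection, each oocyte must be stripped of the
cumulus cell mass surrounding it (denudation): the cumulus-oocyte complex is
briefly exposed to hyaluronidase, then repeatedly aspirated into and expelled
from a micropipette in enzyme-free medium until the cumulus cells shear off.
A robotic workstation automates this with four coupled capabilities: locating
the micropipette tip and its contact with the dish substrate, recognizing
oocytes and cumulus cells in the camera image, compensating the rotational
misalignment between the camera and the XY stage, and choosing a pump flow
rate strong enough to strip cumulus but gentle enough not to damage the
oocyte — while watching the oocyte inside the pipette so the pump stops
before the cell is lost in the tubing.

`denudakit` implements the computational core of such a workstation and
exercises it end to end on synthetic microscopy scenes with exact ground
truth. Every claim the package makes is a property of these algorithms
measured on generated data; nothing here is a statement about wet-lab
performance.

# The synthetic scene generator

All vision modules are tested against `render_scene()` /
`render_shifted_pair()`. A scene is a flat background (default level 60 of
255) carrying:

* **oocytes** — bright discs (level ≈ 170) of radius $R$ (defaults drawn
  from 35–45 µm), each wrapped in a zona pellucida annulus of thickness
  $s = 8$ µm rendered near the background level, with optional darker
  interior blobs ("holes") that emulate the intensity variation of the
  ooplasm and exercise the hole-filling stage;
* **cumulus cells** — smaller bright discs ($r$ from 5–15 µm), either
  attached (placed so the disc overlaps only the zona annulus, at centre
  distance $d = R + s + \alpha r$, $\alpha \sim U(0.8, 0.98)$) or dispersed;
* **a micropipette** — two dark wall bands (level ≈ 20) converging at the
  tip, horizontal with the tip pointing toward $+x$, default 125 µm bore;
* **additive Gaussian noise**, clipped to $[0, 255]$ (default sd 5 for
  recognition scenes).

Edges are anti-aliased over one pixel, so sub-pixel centroids and radii are
meaningful. Pixel coordinates are 0-based, $x$ rightward, $y$ downward,
centres at pixel centres; the default scale is 1 µm/px so pixel and
micrometre coordinates coincide unless overridden.

Rendering is bit-deterministic given the seed. Frame pairs
(`render_shifted_pair`) redraw only the sensor noise in the second frame
(`noise_seed`), because two camera exposures never share noise and a
translated fixed-pattern noise field would bias sub-pixel registration
toward zero shift; the zero-noise identities ("zero shift gives identical
frames", "pure translation shifts content exactly") are tested at
`noise_sd = 0`.

The generator deliberately does **not** emulate out-of-focus blur,
phase-contrast or DIC imaging, uneven illumination, non-circular or
deformed cells, or partial occlusion of cells by the pipette walls. Passing
tests therefore demonstrate algorithmic correctness under the stated image
model, not recognition rates on real microscopy.

# Cell recognition

The segmentation pipeline is Gaussian low-pass (σ = 1.5 px) → Otsu
threshold (bright foreground) → morphological closing (disc, radius 2 px)
→ hole filling → external-contour extraction per connected component →
algebraic least-squares circle fit. Fitted radii are increased by half a
pixel to refer boundary-pixel centres back to the intensity edge.

The circle fit is the Kåsa linearization: minimize
$\sum_i (x_i^2 + y_i^2 + D x_i + E y_i + F)^2$, a linear solve whose
solution is exact on noiseless circles and equals the circumcircle for
three points. On full-circle contours it agrees with the geometric
least-squares fit to well under 0.1 px; on partial arcs any algebraic fit
is biased, which is why the test oracles sample full circles.

Classification separates oocytes from cumulus by fitted radius (threshold
25 µm, halfway between the typical cumulus and oocyte scales, configurable)
and applies the zona-pellucida attachment rule: a cumulus of radius $r$ is
attached to the nearest oocyte with $d \le R + r + s$, with a one-pixel
tolerance absorbing rasterization error. Ties go to the smaller distance,
then the lower oocyte index, making output order-independent. Two guards
matter in practice:

* **hole filling** — without it, the intensity variation inside the oocyte
  fragments the mask and each interior hole surfaces as an extra contour
  (the package exposes `fill_holes = FALSE` to demonstrate exactly this
  failure);
* **a circularity gate** — contours whose circle-fit RMS residual exceeds
  3 px are neither oocytes nor cumulus. Touching debris clumps merge into
  one large blob that would otherwise pass the radius threshold; the gate
  is what makes "zero dispersed-cumulus blobs classified as oocytes" hold
  across every generated scene.

Combined mass uses the sphere-volume form
$M + m = \tfrac{4}{3}\pi\rho_0 (R^3 + \sum_j r_j^3)$ with radii converted
to metres. The single-cumulus form is recovered for one cell; whether the
published single symbol $r$ means one effective radius or a per-cell sum is
ambiguous, so both readings are exposed (`r_mode = "sum"` is the default,
`"effective"` uses the mean radius as one cell).

# Micropipette tip and substrate contact

Tip identification mirrors the recognition pipeline with inverted polarity:
Gaussian low-pass → threshold → morphological erosion then dilation (3 × 3
square, one pass each) → connected components. The walls are the two large
elongated dark components; with bright cells in frame a single Otsu split
lands between cells and everything else, so the wall mask recurses: if the
dark class is the majority, Otsu is re-run inside it. Point A is the
rightmost point of the top edge, B of the bottom edge, and the tip is their
midpoint — the symmetric choice given that both rightmost points define the
tip. Edges further than a configurable x-gap apart (default 20 px) are
rejected as malformed.

Substrate contact is declared from a descent image sequence: the tip is
tracked per frame and contact is the first frame whose lateral displacement
from the frame-1 fix exceeds a threshold (default 3 px). The published
system delegates its contact criterion to earlier hardware work without
equations; displacement thresholding against an unchanged background is a
stand-in chosen because it is explicit and testable on synthetic descent
sequences, and it is flagged as such here.

# Stage-camera calibration

A manually installed camera is rotated by a small angle θ relative to the
stage axes. Two overlapping frames are taken along a $+x$ stage step; robust
translation registration recovers the step's apparent image direction
$(dx, dy)$, and

$$\theta = \arctan\frac{dy}{dx}.$$

The registrar is written in the package: FFT cross-correlation gives a
coarse integer shift; corner-like (Harris) keypoints from the first frame
are matched into the second by normalized cross-correlation of local
patches around that estimate; a consensus vote on the pure-translation
model rejects outliers (fewer than 3 inliers is an error — uncorrelated or
textureless frames); and a parabolic fit of the overlap sum-of-squared
differences refines the shift to sub-pixel precision. On the generator's
scenes this recovers angles from ±0.5° to ±5° within a few hundredths of a
degree, comfortably inside the 0.2° the positioning requirement implies.

`image_to_stage()` applies the rotation
$\begin{pmatrix}\cos\theta & -\sin\theta\\ \sin\theta & \cos\theta\end{pmatrix}$
to a displacement. One subtlety is deliberate and worth stating plainly:
the mosaic measures the *stage-to-image* rotation, so commanding the stage
to realize a desired image displacement uses the *inverse* rotation —
`invert_calibration()` negates the angle, and every centring move in the
simulator goes through it. Applying the forward rotation on both sides
would leave a residual of $2\lVert v\rVert\sin\theta$ and calibration would
not work; published descriptions of such systems typically absorb this in
an unstated axis-flip between the y-down image frame and the y-up physical
stage frame. With the inverse applied, a hidden 2° misalignment and a 1 µm
stage leaves all 50 targets (up to 700 µm off-centre) within 5 µm in both
axes, while uncalibrated moves err by the chord length
$2\lVert v\rVert\sin(\theta/2)$ — about 24 µm at 700 µm.

# Flow-rate control

Inside the pipette the oocyte travels with the medium; relative flow exists
only outside. The drag force of the aspiration flow is

$$F_d = \frac{\rho\, Q^2 C_d}{2A},$$

the dynamic pressure of the mean lumen velocity $Q/A$ times the drag
coefficient over the bore area $A$. (The alternative reading with $A$ in
the numerator is algebraically inconsistent with the closed-form window
below and is therefore rejected.) Newton's balance for the complex of mass
$M + m$ accelerating over the travel distance $s$ from rest to the tip,
with friction $F_f = (M+m)g\mu$, leaves the fluid shear available for
stripping cumulus:

$$F_s = \frac{\rho C_d Q^2}{2A} - \frac{2}{3}\pi\rho_0
\left(\frac{Q^2}{A^2 s} + 2 g \mu\right)(R^3 + r^3).$$

Denudation requires $m g \mu_s \le F_s \le F_{mx}$: the shear must beat the
cumulus adhesion ($m = \tfrac43\pi\rho_0 r^3$ is the cumulus mass,
$\mu_s$ the adhesion coefficient) without exceeding the physiological
limit $F_{mx}$. Solving both equalities for $Q$ gives the admissible window

$$Q_{\min} = \sqrt{\frac{8\pi A^2 s\, \rho_0 g\,(\mu R^3 + \mu r^3 + \mu_s r^3)}
{3\rho C_d A s - 4\pi\rho_0 (R^3 + r^3)}},\qquad
Q_{\max} = \sqrt{\frac{2 A^2 s\,(4\pi\rho_0 g \mu R^3 + 4\pi\rho_0 g\mu r^3 + 3F_{mx})}
{3\rho C_d A s - 4\pi\rho_0(R^3+r^3)}},$$

feasible exactly when $m g \mu_s \le F_{mx}$. The implementation keeps SI
units internally and converts to µL/min (1 µL/min = 1e-9/60 m³/s) at the
pump interface. The defining identities $F_s(Q_{\min}) = m g \mu_s$ and
$F_s(Q_{\max}) = F_{mx}$ hold to relative 1e-9 over a thousand random valid
parameter draws, and the closed forms match numeric root finding of
$F_s(Q)$ to relative 1e-6 — these identities, not any particular parameter
values, are what the module warrants.

Parameter defaults (all overridable): ρ = 1005 kg/m³ (M2 medium), ρ₀ =
1050 kg/m³, $C_d$ = 1, µ = 0.1, µ_s = 0.3, $s$ = 150 µm (the protocol's
tip offset from the field centre), $F_{mx}$ = 1e-7 N, bore 125 µm. None of
these coefficients has a published value for this system; they are
physically plausible working points, and no test outcome depends on them.
Random draws for the identity checks keep $r \ge 2$ µm: as $r \to 0$ the
adhesion force ($\propto r^3$) falls so far below the individual force
terms that the identity drowns in floating-point cancellation rather than
in any modelling error.

Note the symbol collision in the source material: $s$ is the zona thickness
in the attachment rule but the oocyte-to-tip travel distance in the
dynamics. The package keeps them apart as `s_um` (cell_vision) and
`s_travel_um` (flow_model).

# In-pipette tracking and the stop-flow guard

The lumen is located once per sequence: the dark wall mask yields two
elongated components; the inner edge pixels of each are fitted by a Hough
line transform restricted to near-horizontal angles (±5°, 0.25° bins) and
refined by least squares. The ROI is the band strictly between the lines
(3 px margins), from the left image edge to the rightmost wall column.
Lines crossing inside the frame are a malformed-walls error.

Tracking reuses the cell-segmentation pipeline restricted to the ROI — the
same circle detector, not a second algorithm — and takes the leftmost
oocyte-sized centre. The stop-flow signal is exactly
`oocyte present AND centre x < left limit`; the default limit sits 40% of
the lumen length from the tip. The online guard (which stops at the first
firing frame) provably matches a brute-force scan of all frames because
per-frame detection is deterministic; on the generator's drift sequences
the firing frame also equals the ground-truth crossing frame, with entry
phases sampled so the crossing lands at least 1.5 px beyond the limit —
sub-pixel detection error cannot flip a comparison that close to the
boundary otherwise.

# The session simulator

`run_session()` executes the four-well protocol (Q1 hyaluronidase 100 µL,
Q2–Q4 M2 80 µL) against virtual hardware: contact detection on a rendered
descent sequence, tip positioning bookkeeping (25 µm above the substrate,
150 µm left of centre, transfers 55 µm above the dish), mosaic calibration,
then per oocyte: a calibrated centring move (residual recorded), local
recognition of the complex, flow-window selection from the *estimated*
radii (visual-servo feedback), and one tracked aspiration per well
transfer. Oocyte drift speed in the lumen varies per aspiration
(4–9 px/frame, seeded); with tracking enabled the guard stops the pump at
the limit crossing and the oocyte is retained; with tracking disabled the
pump runs an open-loop duration derived from the nominal speed, so
fast-drifting oocytes cross the limit and are lost. Cumulus detach in the
M2 wells when $F_s$ at the operating rate exceeds their individual
adhesion $m_c\, g \mu_s$; with the default mid-window policy this
deterministic single-cycle rule detaches every cumulus the window was
computed to handle, so the simulator's denudation efficiency is an upper
bound, not a biological prediction. The enzyme clock charges each oocyte
its Q1 pick-up time (default 1.5 s per oocyte, so a batch of 20 stays
within the 40 s bound); an over-large batch flags `schedule_ok = FALSE`.

Yield rate is recovered/total and denudation efficiency fully-denuded/total,
following the published definitions. The wet-lab numbers those definitions
produced (97.0% and 95.0%) are biological outcomes of real oocytes and are
not simulation targets; the simulator's own loss-free property under
tracking is the reported analogue.

# Problem sizes and numerical choices

* Recognition scenes are 560 × 420 px at 1 µm/px with 3 complexes; the
  accuracy study uses 100 scenes (300 oocytes) plus 100 dispersed-only
  scenes. Angle recovery uses 6 angles × 10 seeds; sessions use 20 oocytes
  × 10 seeds; the stop-flow oracle uses 100 sequences.
* Otsu operates on 256 bins; the two-stage wall mask recurses when the dark
  class exceeds half the frame.
* The registration consensus radius is 1.5 px with ZNCC acceptance 0.6; the
  sub-pixel parabola is clamped to ±0.5 px.
* Collinearity in the circle fit is declared when the smallest eigenvalue
  of the normal matrix falls below 1e-10 of the largest; degenerate fits
  (no real radius) are errors, and blank frames segment to an empty table
  rather than erroring.
* Stage moves are quantized to the 1 µm resolution before execution; the
  stage-travel and transfer-height fields are bookkeeping (no rendering
  depends on them).

# Known limitations

* The image model is deliberately minimal (see the generator section); no
  claim transfers to real microscopy without revalidation.
* The contact criterion is a stand-in for unpublished hardware-specific
  detection methods.
* Cumulus detachment kinetics are a deterministic threshold; real
  detachment is stochastic and cycle-dependent.
* The registrar assumes a pure translation between calibration frames
  (true for a stepped stage under a rotated camera); it is not a general
  mosaic homography.
* Recognition speed targets (the published 30 Hz) are hardware statements
  and are out of scope.
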