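# denudakit

Computational core of a robotic oocyte-denudation workstation, implemented
as an R package and exercised end to end on synthetic microscopy scenes.

Before intracytoplasmic sperm injection (ICSI), every oocyte must be
stripped of its surrounding cumulus cell mass: brief hyaluronidase exposure
(≤ 40 s — the enzyme is toxic), then repeated micropipette aspiration and
deposition in enzyme-free medium. Automating this requires four coupled
pieces of computation, all provided here:

* **Micropipette tip identification and contact detection**
  (`detect_tip()`, `detect_contact()`) — the tip is the midpoint of the
  rightmost points A and B of the two dark wall edges; substrate contact is
  the first frame of a descent sequence whose tip displacement exceeds a
  threshold.
* **Oocyte and cumulus recognition** (`segment_cells()`,
  `classify_cells()`, `fit_circle()`, `combined_mass()`) — smoothing, Otsu
  thresholding, morphological closing, hole filling, contour extraction and
  Kåsa least-squares circle fitting; oocytes and cumulus separate by size,
  and a cumulus of radius *r* is attached to an oocyte of radius *R* when
  the centre distance satisfies *d ≤ R + r + s*, with *s* ≈ 8 µm the zona
  pellucida thickness. Mass follows the sphere volume,
  *M + m = (4/3)πρ₀(R³ + Σr³)*.
* **Stage–camera calibration** (`register_pair()`,
  `misalignment_angle()`, `image_to_stage()`) — two overlapping frames
  along a +x stage step are registered (keypoints + consensus +
  sub-pixel refinement); the misalignment angle is *θ = arctan(dy/dx)* and
  a 2 × 2 rotation maps image displacements to stage displacements.
* **Aspiration-flow control** (`flow_window()`, `shear_force()`,
  `safe_rate()`) — the fluid shear on the cumulus–oocyte complex,
  *F_s = ρC_dQ²/2A − (2/3)πρ₀(Q²/A²s + 2gμ)(R³ + r³)*, must exceed the
  cumulus adhesion *m g μ_s* but stay below the physiological limit
  *F_mx*; solving both in closed form gives the admissible pump window
  [*Q_min*, *Q_max*].
* **In-pipette tracking with a stop-flow guard** (`locate_lumen()`,
  `track_lumen()`) — Hough-detected wall lines bound the lumen; circle
  detection inside it tracks the oocyte, and the pump stops the moment the
  centre crosses the left limit position, preventing oocyte loss.
* **A protocol simulator** (`run_session()`, `positioning_trial()`) — the
  full four-well session (hyaluronidase → 3 × M2) against a virtual stage,
  pump and camera, with a hidden stage–camera misalignment, 1 µm stage
  quantization, seeded drift speeds and the enzyme clock enforced.

Everything runs against the bundled synthetic scene generator
(`render_scene()`, `render_shifted_pair()`, `random_scene_spec()`), which
produces bright cells, zona annuli, interior holes, dark converging pipette
walls and Gaussian noise, together with exact ground truth in both µm and
pixels. See the methods vignette (`vignettes/denudation-methods.Rmd`) for
the models, parameter defaults and design decisions.

## Worked example

```r
library(denudakit)

# a scene with 3 cumulus-oocyte complexes, and its recognition
spec  <- random_scene_spec(n_oocytes = 3, seed = 7)
scene <- render_scene(spec)
det   <- classify_cells(segment_cells(scene$image))
det
#> <cell detections: 3 oocyte(s), 11 attached cumulus, 0 dispersed>

det$oocytes[[1]]$cumulus[, c("r_um", "d_um", "attached")]
#>        r_um     d_um attached
#> 1 13.238235 56.76061     TRUE
#> 7  8.245962 50.69270     TRUE

# admissible pump window for that complex (radii straight from vision)
p <- flow_params(R_um = det$oocytes[[1]]$R_um,
                 r_um = max(det$oocytes[[1]]$cumulus$r_um))
flow_window(p)
#> <flow window: [4.974, 100.057] uL/min, feasible>

# a full simulated session: 8 oocytes, hidden 2 degree misalignment
rep <- run_session(random_well_spec(n_oocytes = 8, seed = 1),
                   protocol_config(), virtual_hardware(), seed = 1)
rep
#> <denudation session: 8 oocytes, 8 recovered (yield 100.0%), 8 fully denuded (efficiency 100.0%)>
#>   theta: true 2.00 deg, estimated 1.984 deg; stop-flow events: 24; lost: 0
#>   enzyme exposure: max 12.0 s (limit ok: TRUE)
```

The window bounds are the two roots of the shear-force constraints: at
`Q_min` the shear exactly equals the cumulus adhesion force, at `Q_max` the
physiological limit. The session report counts an oocyte as recovered when
it ends in the final well (the stop-flow guard fired on every aspiration
above), and as fully denuded when no attached cumulus remains.

A thin command-line interface wraps the same functions
(`inst/cli/denudakit`): `detect-tip`, `detect-cells`, `calibrate`,
`flow-window`, `track-lumen`, `simulate-run`, `positioning-trial`, each
printing JSON.

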