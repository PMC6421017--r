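# thermoseg

Thermally reinforced brain-tumor segmentation on synthetic phantoms.

Brain tumors are metabolic heat sources with abnormal blood perfusion, so
the steady temperature field of the brain carries a sharp gradient exactly
at the tumor boundary. `thermoseg` simulates that field on 2-D tissue label
maps, extracts the tumor contour from the thermal map with an edge
detector, and quantifies how much this thermal route improves on a purely
intensity-based level-set segmentation of pseudo-MRI images of the same
phantom. It is aimed at people studying physics-informed segmentation:
everything runs on generated phantoms, so no imaging data is required.

## The model

Tissue temperature T(x, y, t) follows the Pennes bioheat equation

```
rho Cp dT/dt = k (Txx + Tyy) + wb rho_b Cpb (Ta - T) + Qm
```

with per-tissue conductivity k, density rho, specific heat Cp, metabolic
heat generation Qm and blood perfusion rate wb; blood (rho_b = 1052 kg/m3,
Cpb = 3800 J/(kg C)) exchanges heat toward the arterial temperature
Ta = 37 °C. The solver is an explicit finite-difference scheme (5-point
Laplacian, forward Euler, default dt = 0.1 s on a 1 mm grid) with the
background held at body temperature as a Dirichlet boundary, iterated until
the largest per-pixel change drops below 1e-7 °C. The admissible time step
is bounded by

```
dt <= 2 dx^2 rho Cp / (wb rho_b Cpb dx^2 + 12 k)
```

and the solver refuses any step above the bound.

Because the tumor (Qm = 25000 W/m3, reduced perfusion) is hotter than its
surround, the temperature gradient peaks on the tumor contour; a Canny
detector with the smoothing stage applied twice delineates it, and
morphological closing plus hole filling turns the contour into a mask. The
baseline is Chan–Vese "active contours without edges" (mu = 0.5,
lambda1 = 1, lambda2 = 2) on Flair-like renderings. Both masks are scored
against the phantom ground truth with sensitivity, specificity, accuracy,
Dice = 2TP/(2TP+FP+FN) and Jaccard = TP/(TP+FP+FN).

A closed-form validation oracle is included: the steady axisymmetric
solution for a tumor disc in an infinite perfused surround, built from
modified Bessel functions I0/K0, against which the finite-difference
solver is checked to a few hundredths of a degree.

## Worked example

```r
library(thermoseg)
cfg <- pipeline_config(phantom = list(grid_size = 128,
                                      tumor_spec = list(radius = 9),
                                      seed = 2))
run <- run_pipeline(cfg, quiet = TRUE)
summary(run)
```

prints

```
thermoseg run: 128 x 128 phantom, 259 tumor pixels
thermal : sensitivity = 0.9768, specificity = 0.9993, accuracy = 0.9990, dice = 0.9675, jaccard = 0.9370
levelset: sensitivity = 1.0000, specificity = 0.9944, accuracy = 0.9944, dice = 0.8506, jaccard = 0.7400
reduced FP 0.50% of healthy area, reduced FN 0.00% of tumor area
```

The thermal route localizes the 259-pixel tumor with Dice 0.97, while the
level-set baseline over-segments (sensitivity 1 but 72 false-positive
pixels, Dice 0.85); the reduced-rate line says 0.5 % of the healthy area
was classified correctly by the thermal route only. Setting
`out_dir = "results/run1"` in the config additionally writes the label
map, both temperature fields, all masks, a metrics CSV and a YAML log of
every parameter and seed.

A command-line wrapper with the same stages (`phantom`, `render`,
`simulate`, `segment-thermal`, `segment-levelset`, `evaluate`,
`pipeline`) ships in `inst/cli/thermoseg.R`.

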