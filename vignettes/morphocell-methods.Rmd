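---
title: "morphocell: model, pipeline and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{morphocell: model, pipeline and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(morphocell)
```

## The model

`morphocell` simulates a 2D crawling cell as a phase field `phi(r, t)`
(1 inside the cell, 0 outside, diffuse interface of width `epsilon`)
coupled to three signaling fields. The membrane obeys

    tau dphi/dt = eta (lap phi - G'(phi)/epsilon^2)
                  - M (integral(phi) - A0) |grad phi|
                  + a_W W |grad phi|

with the Landau double well `G(phi) = 18 phi^2 (1 - phi)^2`. The first
term is surface tension, the second a soft area constraint around the
target area `A0` (78.83 um^2, a 5-um-radius cell), and the third an
outward protrusive force proportional to the local polarity field `W`.
Bending energy is neglected. Defaults are `tau = 0.83` pN s/um^2,
`eta = 1` pN, `epsilon = 1` um, `M = 0.5` pN/um^3, `a_W` in the explored
band 0.8-5.6 pN/um.

The signaling layer couples an excitable protrusion network (U, V) to a
mass-conserved bistable polarity field (W). All three evolve as products
`phi * X` with conservative `div(phi grad X)` diffusion, so the
chemistry lives strictly inside the cell and follows the moving
boundary:

* `U` is the substrate: basal supply `s`, decay `gamma U`, and a
  boundary flux `-chi_U U |grad phi|^2 / integral(|grad phi|^2)` that
  drains U at the interface.
* `V` is the protrusion trigger: U converts to V at rate
  `alpha U V W / (K_k + <phi V W>)` (gated by W, saturated by the
  global mean `<.>`), returns at `beta U V / (K_p + <phi U>)`, and
  decays at `mu V`. The Ornstein-Uhlenbeck edge noise (correlation time
  `theta`, stationary sd `sigma`) enters V with a plus sign and U with a
  minus sign, weighted by the interface indicator `4 phi (1 - phi)`.
* `W` follows the bistable reaction
  `k_W1 (-rho W^3 + rho W^2 W* - W) + zeta V`, where the well-mixed
  reciprocal pool `W* = (W_tot - integral(phi W)) / integral(phi)`
  enforces exact conservation of the total protrusive capacity `W_tot`.
  Under this constraint the bistable front stalls ("wave pinning"),
  which is the mathematical embodiment of stable front/rear polarity.

A single time-scale factor `tau_prime` (default 10) multiplies the
signaling time derivatives and converts simulation time to seconds when
trajectories are reported; one factor serves both roles.

### Steady states and the role of `W_tot`

The nonzero roots of `-rho W^3 + rho W* W^2 - W` are
`(rho W* +/- sqrt(rho^2 W*^2 - 4 rho)) / (2 rho)`; the reaction is
bistable iff `W*^2 > 4 / rho` (`polarity_steady_states()`). For the
default `rho = 5.5556` the Maxwell stall sits near `W* = 0.90` with the
upper plateau near `W = 0.60`, so at `W_tot = 80` a pinned front of
roughly 15-20 um^2 coexists with a quiescent rear -- the migrating
phenotype. At `W_tot = 50` the pool never reaches the bistable band and
the cell relaxes to a passive, near-circular disk; at `W_tot >= 110`
the high-W domain engulfs the entire cell and directed motion is lost.

### Choices where the design was open

**Unprinted kinetic constants.** `alpha = 1.5`, `beta = 0.3`,
`K_k = 0.3`, `K_p = 1`, `s = 0.1`, `zeta = 20` and `D_U = D_V = 0.5`
are package choices (the remaining constants are fixed reference
values). They were chosen, once, by the following reasoning. A V spot
that can sustain itself feeds on U; because the boundary has only half
the diffusive catchment of the interior (and `chi_U` drains U there),
a self-sustained spot always drifts into the cell interior and -- via
the shared pool -- drags the pinned W domain off the boundary, stopping
migration. The defaults therefore place V *subcritical inside the
polarity domain*: V is a noise-driven, transient perturbation of the
front (visible as flickering leading-edge activity) rather than an
autonomous wave. The excitable regime proper is still reachable (see
the pulse test in `tests/testthat/test-simulator.R`, which preloads the
substrate and opens the W gate), and all headline behaviors --
area control, wave pinning, the `W_tot` morphology progression and
persistent migration -- are insensitive to the exact values.

**Initial condition.** `phi` is a tanh disk of radius `sqrt(A0/pi)`,
`U = s/gamma`, `V = 0`. `W` starts as a sector patch at the upper
bistable root, sized to the wave-pinning equilibrium and oriented at a
seeded uniform random angle (`init_W = "patch"`). A `W = 0` start is
linearly stable (`f'(0) = -1`), so polarization onset from rest would
require a finite-amplitude kick that, at the documented noise size,
only occurs with couplings strong enough to flood the whole cell; the
patch start instead begins at the model's operating attractor with an
unbiased random orientation. `"zero"`, `"uniform"` and `"step"`
initializations remain available.

**Noise placement.** The model treats the noise as edge
fluctuations, so the OU field multiplies the interface indicator
`4 phi (1 - phi)` rather than `phi`; bulk-weighted noise nucleates
signaling spots at the cell center, which contradicts the intended
edge phenomenology. U and V are clipped at zero after each step: the
bilinear conversion term is unstable to sign changes, and
concentrations are non-negative quantities.

### Discretization

Five-point Laplacian, central differences for `|grad phi|`, a
conservative face-flux stencil for `div(phi grad X)`, explicit Euler
stepping. The default grid is 128 x 128 at `dx = 0.3` um (38.4-um
periodic box, ~33 grid points across the cell). `stable_dt()` takes the
tightest of the diffusive bound `dx^2 tau_prime / (4 D_max)`, the
interfacial bound `tau dx^2 epsilon^2 / (8 eta)` and a bistable
reaction bound `tau_prime / (6 k_W1 rho)`, scaled by a safety factor
(0.8). Concentrations are recovered from the products by exact division
down to `phi = 0.1`, damped division below, and zeroed outside
`phi < 1e-3` so interface residue cannot creep outward through the
diffusion stencil. `phi` leaving `[-0.05, 1.05]` or any non-finite
value raises an instability error naming the stable step. The cell is
tracked on the torus with circular-mean centroids, recentered per
sampled frame, and the centroid series is unwrapped to a continuous
track; fragments (secondary connected components of `phi >= 0.5`) are
logged per frame and the largest component is used downstream.

## The shape pipeline

`normalize_series()` reproduces the standard preprocessing: migration
direction from the centroid displacement at a five-frame interval
(frames below 0.25 px displacement are skipped), rotation aligning the
direction to the downward image axis, rescaling to the area of a
25-px-diameter circle, and centering in a 64 x 64 frame. Rotation and
scale are applied in a single inverse-mapped bilinear resampling with
2 x 2 supersampling. Binarization picks the `round(pi * 12.5^2)`
most-occupied output pixels instead of cutting at 0.5: a fixed cut
quantizes the area of axis-aligned shapes in coherent ~50-px jumps,
while rank selection pins the area to the target within a pixel for
every input.

## Feature space

The classifier is the frozen reference architecture: 64x64x1 input,
conv(16, 3x3, relu), max-pool 3x3, conv(32, 3x3, relu), max-pool 3x3,
dense(256, relu) -- the 256-dim intermediate features -- dense(32,
tanh), dense(3, linear) -- the feature vector `F` -- and softmax. It is
trained with Adam (default learning rate 1e-4, batch 64; the desk-scale
tests use 1e-3/32 for fast convergence on separable synthetic classes)
on rotation-augmented (< +/-5 deg, uniform) class-balanced datasets.
The implementation keeps activations as flat (position x sample)
matrices so convolutions are one gather plus one BLAS product; all ten
parameter gradients agree with central differences to ~1e-10. PCA
(`fit_shape_pca()`) is fitted on per-timeseries time-averaged `F`,
exactly as the similarity scores (`Score-D/H/K` roles) use Euclidean
distance between time-averaged `F` vectors (simulation means discard a
10% burn-in by default). Hand-crafted features are the motion-aligned
vertical/horizontal extents over the equivalent-circle diameter and
the contour circularity `4 pi A / P^2`.

## Morphodynamics

Contours are traced on the 0.5 level set (`grDevices::contourLines`),
resampled to equal arclength, low-pass filtered (16 Fourier harmonics
by default, then re-resampled so curvature telescopes to one turn) and
oriented counter-clockwise. Curvature is a windowed tangent-angle
derivative (window n/32 points); the closure integral is 2 pi within
2% on every valid contour. Binary (pixelated) outlines limit pointwise
curvature and protrusion-speed accuracy to roughly 20-25%; phase-field
inputs are sub-pixel accurate. Frames are registered by the cyclic
offset minimizing summed squared point displacement (FFT
cross-correlation); this keeps bands fixed under translation, while
rigid rotation is only partially absorbed into the offset -- a known
property of minimum-displacement registration, tested as such.

`msd_persistence()` computes the time-averaged centroid MSD, reports
free-slope fits of the short- and long-lag regimes, and constructs the
fixed-slope (2 and 1) lines whose intersection defines `tau0`, with
`X0 = sqrt(MSD(tau0))` in units of the mean motion-aligned cell length.
The fit windows are re-centered on the current `tau0` estimate
(short: lag <= tau0/2, long: lag >= 2 tau0, three iterations) because
windows tied to the maximum lag bias the crossover whenever the track
is much longer than the persistence time; a crossover is reported only
when the long-lag slope is genuinely sub-ballistic (< 1.5). The
synthetic `run_and_tumble_track()` defines its `tau0` parameter as the
analytic asymptote crossover (tumble rate `2/tau0`), so recovery tests
compare the estimator against an exactly known value.

Pseudopod events -- scored by eye in the original workflow -- are
detected automatically here: connected regions of the speed kymograph
above a threshold (80th percentile of positive speeds by default)
persisting >= 3 frames and spanning >= 5% of the boundary. A region
whose onset interval (dilated by 3 points) overlaps no activity in the
preceding 3 frames is `de_novo`; otherwise it is `y_split` if the
parent region remains active outside the new one after onset, else
`one_way_split`. Extension angles are measured from the displacement of
the registered onset boundary point 10 s after onset, relative to the
centroid velocity.

## Synthetic data and what passing tests show

The geometry library (11 basic objects, the 33-shape aspect expansion,
the 9-ellipse aspect series, seeded multi-edge forms) doubles as the
training fixture; `geometry_proxy_classes()` builds three linearly
separable classes (compact disks, vertically and laterally elongated
ellipses with seeded jitter). These probes exercise the full pipeline
-- normalization invariants, classifier convergence, the monotone
ellipse manifold in PC space -- but they are cleaner than microscopy
masks: no segmentation noise, no frame-to-frame shape memory, and
perfectly balanced classes. Passing them validates the machinery, not
the biological accuracy of any particular trained network, and none of
the headline real-data numbers of the original study (trained-network
accuracies, PC loadings, real-cell persistence times or event
fractions) are reproduced here, as they require the unpublished
microscopy datasets.

## Problem sizes used by the test and acceptance runs

The reference simulation is 600 s of real time on the 128 x 128 grid
(sampled every 2 s); module tests use a smaller cell (`A0 = 28.3` um^2)
on a 64 x 64 grid. Classifier checks train 10 epochs on 3 x 200
synthetic masks; persistence recovery uses 10-12 run-and-tumble tracks
of 800 points per condition. These sizes were chosen so the whole suite
exercises every pathway at full numerical fidelity while remaining
desk-scale.

## Known limitations

* At very high `W_tot` (>= 110) the simulated outline is ruffled by
  edge noise rather than smoothly circular.
* With the default (subcritical-V) kinetics, spontaneous front splits
  are rare; pseudopod statistics on default-parameter runs are sparse,
  and the event-detection machinery is validated on constructed
  kymograph fixtures.
* Binary mask inputs limit pointwise curvature/speed kymograph accuracy
  (see above); phase-field inputs do not.
* The trajectory store is an in-memory object with TIFF/CSV writers;
  no hierarchical on-disk format is provided.
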