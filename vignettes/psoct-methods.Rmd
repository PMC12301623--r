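---
title: "Depth-resolved birefringence from a rotating catheter: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved birefringence from a rotating catheter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psoct)
```

## The measurement and its model

Catheter-based polarization-sensitive OCT probes brain tissue radially from
a rotating fiber probe pulled back along a neurosurgical insertion
trajectory. White matter is birefringent: light polarized along versus
across the myelinated fibers sees refractive indices differing by
$\Delta n$, so a depth interval $\mathrm{d}z$ adds retardance
$\delta = 2\pi\,\Delta n\,\mathrm{d}z/\lambda_0$ between the two
polarization eigenstates. In the Stokes formalism a pure retarder is a
rotation of the normalized Stokes vector $s = (q, u, v)$ on the Poincaré
sphere; a *linear* retarder with fast-axis orientation $\theta$ rotates by
$\delta$ about the equatorial axis $(\cos 2\theta, \sin 2\theta, 0)$ —
physical orientation angles are halved sphere azimuths, so orientation is
defined modulo 180°.

The forward model implemented by `simulate_pullback()` treats each A-line
as a stack of one-pixel linear retarders: the catheter's protective sheath
first, then tissue. With the one-way product $P(z) = L_1 \cdots L_z$, the
round trip seen from the detector is
$C(z) = P(z)\,\mathrm{d}T\!\left(P(z)\right)$, where
$\mathrm{d}T(A) = D A^{\mathsf T} D$, $D = \mathrm{diag}(1, 1, -1)$ is the
reciprocity operator of round-trip measurements (it fixes every linear
retarder). Catheter rotation adds a per-A-line transmission
$T(\alpha)$, so the measured rotation is
$R(z) = \mathrm{d}T\!\left(T(\alpha)\right) C(z)\, T(\alpha)$. Rotations
are lifted to SU(2) field operators (half-angle lift, global phase fixed to
zero — Stokes processing is phase-insensitive) and applied to the two
alternating input states, orthogonal on the Poincaré sphere; amplitudes
carry class-dependent scattering, exponential attenuation, a circular
complex speckle factor shared by both detection channels and both states of
an A-line pair, and additive detector noise.

Two A-lines (one per input state) form one azimuthal sample; a frame is one
full rotation; the pullback advances one pitch (speed / frame rate, 0.2 mm
by default) per frame. All A-lines of a frame sample tissue at the
frame-center longitudinal position — the sub-pitch helical advance within a
frame is ignored, which matters only below the 0.2 mm pitch scale.

## Reconstruction

`reconstruct_pullback()` chains five stages, each exposed on its own:

1. **`compute_stokes()`** — Stokes vectors from the two detection channels,
   paired into (state 1, state 2) tuples, smoothed with a separable
   Gaussian (defaults: axial $\sigma$ = 1 depth pixel, lateral $\sigma$ = 2
   A-line pairs, circular over the frame) applied to the *unnormalized*
   components before renormalization; the filtered degree of polarization
   is kept for masking.
2. **`estimate_cumulative()`** — per pixel, the unique rotation mapping the
   known orthogonal input pair onto the measured pair (second state
   orthogonalized against the first). Pixels with DOP below 0.7, or pair
   orthogonality off by more than 25°, are masked, not raised. These two
   thresholds are robustness choices, both configurable.
3. **`compensate_transmission()`** — round trips through linearly retarding
   tissue are $\mathrm{d}T$-symmetric, and transmission of the reciprocal
   form $\mathrm{d}T(V)\,C\,V$ preserves that symmetry exactly; what breaks
   it in practice is estimation noise. This stage finds, per A-line, the
   correction rotation $\hat V$ (axis-angle parameters, Nelder–Mead,
   initialized from the neighboring A-line) minimizing the summed squared
   Frobenius asymmetry of
   $\hat C(z) = \mathrm{d}T(\hat V)^{-1} C(z) \hat V^{-1}$ over a
   window-averaged stack, with a small $\lambda\lVert v\rVert^2$ tie-break
   (the objective is flat along symmetry-preserving directions, so the
   smallest correction is preferred). The mean residual asymmetry is kept
   as a quality metric. Rotation angles — hence retardance — are invariant
   under this conjugation.
   One sampling consideration: with few A-lines per frame and offsets that
   vary quickly with azimuth, the two states of a pair see measurably
   different transmissions and the estimated rotation acquires an
   irreducible asymmetry proportional to the within-pair offset difference.
   At the full 2048 A-lines per rotation this is of order $10^{-3}$;
   symmetry-restoration checks are therefore run with offsets that vary
   across frames, constant within a frame.
4. **`peel_layers()`** — the depth recursion correcting for the preceding
   linearly retarding layers, one pixel thick: $N(z{+}1) = \hat C(z{+}1)
   \hat C(z)^{-1}$; the local double-pass angle is the rotation angle of
   $N$, the local retardance its half; the local axis is
   $P(z)^{-1}$ applied to the axis of $N$, projected to the equator; the
   apparent orientation is the halved axis azimuth; and
   $P(z{+}1) = P(z)\,L(\theta, \delta)$ rebuilds the one-way product from
   the recovered layers. Masked depths carry $P$ forward and the retardance
   across a gap is reported as a per-pixel rate.
   Because the per-pixel retardance of realistic white matter
   ($\Delta n \sim 2\times 10^{-4}$, ~0.5°/pixel) is smaller than the
   differential noise of neighboring rotation estimates, the raw local axes
   flip retrogradely under noise. The standard remedy follows as a distinct
   step: Gaussian averaging of the equatorial local retardance *vectors*
   $\delta\,(\cos 2\theta, \sin 2\theta)$ (defaults: axial $\sigma$ = 5
   pixels ≈ 24 µm, lateral $\sigma$ = 2 pairs; `local_*_sigma = 0`
   disables, and the noise-free recursion is exact without it).
5. **`guide_star_correct()`** — the birefringent sheath has a known, fixed
   orientation in the probe frame (0° = circumferential by default) and is
   visible on every A-line, so the circular mean (period 180°) of the
   recovered orientation over the sheath depth band, minus the known value,
   estimates the per-A-line orientation offset $\varphi(\alpha)$. The
   series is smoothed circularly along azimuth (doubled-angle mean, window
   15 pairs by default — choose a window that spans only a few degrees of
   azimuth at reduced A-line counts) and subtracted from the tissue
   orientations to give absolute orientation. A-lines without a detectable
   sheath inherit the neighborhood estimate and are flagged. Modelling
   $T(\alpha)$ as a rotation about the circular Poincaré axis by
   $-2\varphi(\alpha)$ makes this subtraction exact: conjugating the layer
   stack by a circular rotation shifts every recovered layer orientation by
   the same $\varphi$, sheath included (an induction over the peeling
   recursion, verified by test).

Brain white matter is negatively birefringent, so the measured retarder
axis is perpendicular to the fiber axis; with the (default) negative-sign
convention all reported orientations are the measured axes shifted by 90°,
and 0° means fibers circumferential to the catheter. Toggling the flag
shifts every reported orientation by exactly 90°.

## Conventions fixed where the physics leaves a choice

* **Stokes handedness.** From detected fields $(h, v)$:
  $q = (|h|^2 - |v|^2)/I$, $u = 2\,\mathrm{Re}(\bar h v)/I$,
  $v_s = -2\,\mathrm{Im}(\bar h v)/I$, so $(1, i)/\sqrt 2 \mapsto
  (0, 0, -1)$. Nothing downstream depends on which handedness is chosen,
  only on using one consistently; the SU(2) lift in the simulator is the
  representation of exactly this convention (property-tested).
* **Axis log tie-breaks.** `rotation_to_retvec()` returns angles in
  $[0, \pi]$; the identity reports axis $(1,0,0)$; at angle $\pi$ the axis
  sign makes the first nonzero component positive.
* **Longitudinal index map.** Carpet row $j$ (0-based, position
  $j \times$ pitch from the shared cortical-entry origin) maps to MRI slice
  $\lfloor j \cdot \mathrm{pitch} / 0.57 \rfloor$ — slice $i$ covers
  $[i\Delta, (i{+}1)\Delta)$ with its center at $(i{+}0.5)\Delta$ —
  nearest-neighbor, no resampling.
* **Perimeter unfolding.** The sixteen ring pixels of the 5×5 ROI
  cross-section are read starting at the pixel on the +first-axis from the
  center, counterclockwise; a 90° rotation of the cross-section cyclically
  shifts the unfolded columns by four.
* **Two-means clustering.** 1-D two-means is threshold-separable, so
  `kmeans_1d()` computes the global within-cluster-sum-of-squares optimum
  exactly by scanning every contiguous split of the sorted profile; the
  result is deterministic and is itself a fixed point of Lloyd's iteration
  (the optimal boundary lies at the midpoint of the two centers). Values
  exactly at the midpoint threshold binarize to the low (grey-matter-like)
  class.
* **Barcode profile masking.** The longitudinal profile of a retardance
  carpet uses every finite pixel: low retardance is grey-matter signal, not
  missing data. The carpet's own mask marks where *orientation* is defined
  and is used for orientation statistics only. Rows with fewer than 25%
  usable columns are flagged; fully empty rows are interpolated from
  neighbors.

## What the synthetic data does and does not emulate

The phantom is a stack of slabs transverse to a vertical trajectory —
grey-matter cortex (0–2 mm), birefringent subcortical white matter
(2–10 mm, $\Delta n = 2\times10^{-4}$), deep grey matter, and a 2 mm
highly birefringent tract ($\Delta n = 5\times10^{-4}$) with a lab-fixed
horizontal fiber direction emulating an internal-capsule-like landmark.
$\Delta n$ values are configurable order-of-magnitude choices for white
matter, not measured constants. Fiber fields come in two flavours:
`"apparent"` layers hold the apparent orientation constant in the probe
frame (circumferential/helical rings — the geometry needed for exact
recovery oracles), while `"lab"` layers fix a laboratory vector, whose
apparent orientation and effective retardance
$\propto |f_\perp|^2$ then vary with beam azimuth, producing the
characteristic two-lobe en-face signature with extinction where the beam
parallels the fiber.

The matched MRI rendering is an exact volume-weighted box average of
class intensities (white matter bright) on a 0.57 mm isotropic grid plus
Gaussian noise — partial-volume mixing is the one MRI artefact modelled.
The simulator deliberately omits: anatomically shaped structures, crossing
or sub-resolution interwoven fibers, out-of-plane fiber angles (only the
in-plane projection is measured), diattenuation and depolarization,
non-uniform rotational distortion, k-space/interferogram synthesis, and
real MRI-to-MRI registration (trajectory coordinates are known by
construction; the registration of real scans is a different problem).
Passing recovery tests therefore demonstrates the *algebraic* correctness
and noise behaviour of the chain under this model — not performance on
tissue with pathology, NURD, or fibers oblique to the imaging plane.

A note on units: the simulator's per-layer retarder angle is
$2\pi\,\Delta n\,|f_\perp|^2 (2\,\mathrm{pixel})/\lambda_0$ and the
reported local retardance (half the angle of $N$) is expressed in degrees
per 100 µm in the same double-pass convention; the mask floor of
5°/100 µm and the default sheath retardance of 0.3 rad are chosen so that
default white matter (~11°/100 µm) and the sheath (~8.5°/100 µm) clear
the floor while grey matter does not.

## Problem sizes

The full system records 2048 A-lines per rotation; the package default is
a reduced 512, and the test-suite and acceptance analyses run 64–128
A-lines per frame, 0.35–0.5 mm of tissue depth and 5–115 frames, sizes at
which a complete simulate–reconstruct–compare cycle takes seconds while
every geometric quantity (frame count, pitch, slice counts, ring span) is
computed at its printed full-scale value. Printed-geometry arithmetic is
evaluated analytically from the configuration, not by simulating 2048
A-lines.

## Known limitations

* The transmission model is reciprocal by construction
  ($\mathrm{d}T(T)\,C\,T$), so the symmetry-restoration stage acts as a
  noise regularizer and safeguard rather than removing a deterministic
  system asymmetry; independent input/output path transmissions are not
  modelled.
* Absolute-orientation accuracy under noise is set by the sheath-offset
  estimate and the local-vector averaging scale; structures smaller than
  the averaging window (~24 µm axially) are smoothed.
* Orientation is in-plane only; fibers tilted out of plane appear with
  reduced retardance and their projected azimuth.
* Trajectories are restricted to the vertical grid axis, matching the
  parallel dorsoventral insertion geometry; oblique trajectories and true
  image-based co-registration are out of scope.
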