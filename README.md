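# psoct

Catheter-based polarization-sensitive OCT (PS-OCT) birefringence mapping
along deep-brain-stimulation-style insertion trajectories, with MRI
co-registration and tissue barcoding — as a fully simulated, fully tested
R pipeline.

## The problem

DBS electrodes are placed in small deep-brain nuclei that standard T1
MRI barely resolves. A rotating OCT catheter the size of a DBS lead can
image the tissue around the insertion trajectory at micrometer
resolution, and its polarization channel measures what MRI cannot: white
matter birefringence and fiber orientation, the optical analogue of
diffusion anisotropy and principal diffusion direction. The package is for
researchers developing or validating such depth-resolved polarimetric
reconstruction: every stage of the analysis chain is driven by a
physics-based simulator with known ground truth, so each algorithm is
verifiable by forward-simulate-then-invert parameter recovery, without any
external data.

## What it computes

Retardance is modelled as a rotation of Stokes vectors on the Poincaré
sphere: a linear retarder with fast axis θ and retardance δ is the
rotation by δ about (cos 2θ, sin 2θ, 0). With the one-way layer product
P(z) = L₁⋯L_z, the round trip is C(z) = P(z)·dT(P(z)), where
dT(A) = D Aᵀ D, D = diag(1, 1, −1) is the reciprocity operator; the
rotating catheter adds a per-A-line transmission T(α), so the measurement
is dT(T)·C(z)·T. Reconstruction retrieves C(z) from the two alternating
probing states, restores reciprocity symmetry, peels the preceding
one-pixel layers (N(z+1) = C(z+1)·C(z)⁻¹, local retardance = half its
rotation angle, local axis = P(z)⁻¹-rotated and equator-projected), and
converts apparent to *absolute* optic-axis orientation with the guide-star
method: the birefringent catheter sheath, whose orientation in the probe
frame is known, is measured on every A-line and its apparent-orientation
offset is subtracted from the tissue.

Downstream, the helical pullback is unrolled into an en-face *carpet view*
(rows = longitudinal position at 0.2 mm pitch, columns = azimuth) sampled
300 µm past the sheath; a matching 5×5-voxel MRI region of interest is
extracted along the trajectory and its 16-pixel perimeter unfolded onto
the same frame; and both are collapsed into binary WM/GM *tissue barcodes*
(row means → exact 1-D 2-means → midpoint threshold) whose transition
positions and agreement are reported.

Modules: Poincaré algebra (`linear_retarder`, `rotation_to_retvec`,
`d_transpose`, `stokes_from_fields`, `rotation_from_state_pairs`) ·
synthetic data (`build_dbs_phantom`, `render_mri`, `simulate_pullback`,
`true_maps_along_trajectory`) · reconstruction (`compute_stokes`,
`estimate_cumulative`, `compensate_transmission`, `peel_layers`,
`guide_star_correct`, `reconstruct_pullback`) · co-registration
(`extract_carpet`, `extract_roi_cube`, `unfold_perimeter`,
`longitudinal_mapping`, `render_oa_hsv`) · barcoding
(`longitudinal_profile`, `kmeans_1d`, `binarize`, `compare_barcodes`) ·
pipeline (`run_pipeline`, `run_stage`, YAML config, NIfTI/TIFF/PNG/JSON
I/O). See `vignettes/psoct-methods.Rmd` for the models, conventions and
design choices.

## Worked example

```r
library(psoct)

phantom <- build_dbs_phantom(phantom_config(), seed = 1)
traj    <- trajectory()                 # 23 mm pullback, entry at the cortex

acq  <- acq_config(alines_per_frame = 64, imaging_depth_mm = 0.35)
cath <- catheter_model()                # 2.3 mm sheath, rotating offsets
raw  <- simulate_pullback(phantom, traj, cath, acq, seed = 42)
geo  <- pullback_geometry(acq, traj$length_mm)

lb     <- reconstruct_pullback(raw, recon_options(offset_smooth_window = 7))
carpet <- extract_carpet(lb)            # en-face view 300 um past the sheath

mri <- render_mri(phantom, seed = 2)
roi <- extract_roi_cube(mri, traj, length_mm = 21)

bc_ps  <- binarize(longitudinal_profile(carpet))
bc_mri <- binarize(longitudinal_profile(unfold_perimeter(roi), source = "mri"))
cmp    <- compare_barcodes(bc_ps, bc_mri)
```

Output of the run above:

```
pullback: 115 frames, 0.2 mm pitch, 1500 rpm
carpet: 115 rows x 32 azimuths, 46% orientation-valid
MRI ROI: 37 slices of 5x5 voxels, ring spans 9.12 mm
PS-OCT barcode transitions (mm): 2, 10, 13, 15
MRI barcode transitions (mm):    2.28, 10.26, 13.11, 14.82
agreement 0.953, Dice (GM, WM) = 0.956, 0.949
```

Reading it: the 23 mm pullback at 5 mm/s and 25 frames/s yields 115
B-scans at 0.2 mm pitch. Less than half the carpet is orientation-valid
because grey matter has no measurable birefringence — which is exactly the
contrast the barcode uses. The PS-OCT retardance barcode switches at the
phantom's true tissue boundaries (2, 10, 13, 15 mm from the cortical
entry: cortex → white matter → deep grey → tract → deep grey); the MRI
barcode, limited by 0.57 mm voxels and partial-volume mixing, finds the
same boundaries within one voxel. `render_oa_hsv(carpet)` turns the
orientation/retardance planes into the standard hue–brightness map (blue =
0° = circumferential fibers).

The staged pipeline with manifest and file outputs:

```sh
Rscript inst/scripts/run_pipeline.R --out run1 --seed 1
```

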