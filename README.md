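# wormwound

Quantification of wound-healing dynamics in the adult *C. elegans*
epidermis (hyp7) from single-channel fluorescence time-lapse movies.

Laser wounding of the worm epidermis triggers a stereotyped repair
programme: microtubule plus-end (EB1/EBP-2) comets accumulate around the
wound within minutes, an actin ring forms and contracts in a fast (P1) and
a slow (P2) phase, microtubule bundles reorganize orthoradially around the
wound, and slower cargo (SNF-12 clusters, RAB-11 vesicles) is recruited
over tens of minutes. `wormwound` implements the full measurement chain
behind those observations:

- **imgio** — calibrated TIFF movie I/O (`load_movie`, `write_movie` with a
  JSON calibration sidecar), ROI geometry (`roi_spec`, `roi_mask`,
  `roi_from_area`).
- **synthgen** — a deterministic synthetic-movie generator with ground
  truth for every signal class: moving comets/vesicles, persistent
  clusters, contracting rings, filament textures, plus
  Poisson/read/bleach/drift noise (`generate_preset`, `ww_presets`).
- **preprocess** — subpixel translational drift correction
  (`register_translation`), temporal-median background subtraction
  (`temporal_median_subtract`), crop/substack (`crop_substack`).
- **comets** — LoG spot detection (`detect_spots`), optimal-assignment
  (LAP) linking with gap closing (`link_tracks`), per-track kinematics
  including a jitter-corrected MSD speed (`track_stats`), the 5 px/120 s
  minimum-displacement filter (`filter_min_displacement`),
  wound-referenced directionality (`track_vectors`), densities
  (`spot_density`).
- **ringdyn** — automated wound centroid, radial profiles and the
  max-intensity radius trace (`ring_radius_trace`), normalized AP
  kymographs (`build_kymograph`), the continuous two-phase closure fit
  (`two_phase_fit`), Huang-threshold actin-ring area (`ring_area`,
  `huang_threshold`), line profiles across the wound.
- **orientfield** — structure-tensor orientation and coherency maps
  (`structure_tensor_orientation`), the wound-referenced angle
  theta in [0°, 90°] (`theta_map`), annular sector statistics R1–R3
  (`sector_stats`), permutation before/after tests
  (`compare_before_after`).
- **recruit** — mean + 3 SD thresholded RawIntDen recruitment traces
  (`thresholded_recruitment`), mean-intensity traces, temporal colour-code
  projections.

A command-line wrapper (`exec/wormwound`, or `run_cli()` from R) chains the
stages: `simulate`, `preprocess`, `track`, `ringdyn`, `orient`, `recruit`,
`report`.

## The statistics at the core

For a particle track with positions `x_t` sampled every `dt` seconds at
`p` µm/px, the package reports the mean step speed
`mean(|x_{t+1} − x_t|) p/dt`, the net speed `|x_T − x_1| p / ((T−1) dt)`,
and a jitter-corrected speed from the constant-velocity MSD relation
`v² = (MSD₂ − MSD₁) / (3 dt²)`, which cancels the `4σ²` localization-noise
offset that inflates the naive step mean (by ~20 % for particles moving
well under a pixel per frame). Ring closure is modelled as a continuous
piecewise-linear radius `r(t)` with one breakpoint found by exhaustive
search; the absolute slopes are the P1/P2 closure velocities. Local texture
orientation is the minor eigenvector axis of the Gaussian-windowed
structure tensor `J = G_σ * (∇I ∇Iᵀ)`, with coherency
`(λ₁−λ₂)/(λ₁+λ₂)`; the wound-referenced angle θ folds the axial difference
between that orientation and the pixel→wound direction into [0°, 90°]
(0° = radial, 90° = orthoradial).

## A worked example

Generate a synthetic EB1 comet movie at the unwounded-epidermis regime
(0.26 µm/s comets, 0.3 s/frame, 0.08 µm/px, SNR ≈ 5), run the tracking
pipeline, and compare the recovered grand-mean speed with the programmed
truth:

```r
library(wormwound)

r <- track_preset("eb1_unwounded", seed = 1,
                  overrides = list(geometry = movie_geometry(
                    150, 150, 150, 0.08, 0.3,
                    background = 100, background_texture_amp = 5)))
r$n_tracks
#> [1] 59
round(r$mean_speed, 4)
#> [1] 0.2532
round(mean(r$truth$objects$speed_um_s), 4)
#> [1] 0.266
```

The pipeline recovers the programmed 0.26 µm/s comet speed within a few
percent (`mean_speed` is the grand mean over tracks of the
jitter-corrected MSD speed; the per-track table is in `r$stats`). The same
interface runs the ring preset:

```r
rec <- ring_recovery(seeds = 1:2)
round(rec$v2_um_s, 5); round(rec$ratio, 1)
#> [1] 0.00807
#> [1] 10.4
```

i.e. the two-phase fit recovers the programmed slow closure speed of
0.008 µm/s and the ~10× fast/slow ratio from the noisy radius-versus-time
trace.

From a shell, the same experiment is:

```sh
exec/wormwound simulate --preset eb1_unwounded --seed 1 -o out/
exec/wormwound track -i out/movie.tif -o out/trk --diameter 3 --link 2 --gap 1
exec/wormwound report -i out -o out/report.json
```

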