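# lvfuse

Feature-based rigid registration of left-ventricular (LV) geometry between
coronary CT angiography (CCTA) and 3-D echocardiography (3DE), with the full
quality-metric suite needed to compare registration methods.

## The problem

Treatment decisions in coronary artery disease combine morphology (CCTA:
coronary tree, stenoses) with function (3DE: wall motion, strain). Fusing the
two modalities into one spatial frame requires a rigid transform mapping the
3DE dataset into the CCTA frame. Segmentation of each volume yields, per
modality, a closed triangulated LV endocardial surface (642 vertices at the
standard resolution) and three anatomical landmarks: endocardial apex `A`,
mitral valve center `M`, and LV outflow tract / aortic valve center `O`.
`lvfuse` implements three registration methods that operate on exactly these
segmentation outputs:

- **Landmark distance minimization** — the proper rigid transform (no
  scaling, no reflection) minimizing
  `|A_CCTA - T A_3DE|^2 + |M_CCTA - T M_3DE|^2 + |O_CCTA - T O_3DE|^2`,
  solved in closed form (Kabsch/SVD with sign correction so `det R = +1`).
- **Endocardial-surface ICP** — iterative closest point between the two
  642-point surfaces, initialized by the landmark fit; each iteration pairs
  every moving vertex with its closest fixed vertex (or closest surface
  point) and re-solves the least-squares rigid fit until the RMS objective
  change drops below tolerance.
- **Three-chamber alignment** — the unique rigid transform making the mitral
  centers coincide, the long axes (`M -> A`) collinear and co-directed, and
  the three-chamber planes (through `A`, `M`, `O`) coincident, realized as an
  anatomical frame-to-frame mapping.

Registration quality is quantified by seven measures per fused pair: apex /
mitral-center / aortic-center distances (cm), long-axis angle and
transverse-plane angle (deg), mean point-to-surface distance (cm), and
Dice's coefficient `2|A∩B| / (|A| + |B|)` of the two surface cross-sections
in the three-chamber plane. Cohort-level method comparison uses paired
Wilcoxon signed-rank tests (exact p-values at small n) for every measure and
method pair; observer-variability measures compare registrations from
repeated segmentations.

Because clinical datasets cannot be redistributed, the package ships a
synthetic LV phantom generator: an icosphere-derived semi-ellipsoidal
endocardium with flattened basal cap (exactly 642 vertices / 1280 triangles
at subdivision level 3), landmarks, a known ground-truth rigid transform,
and controllable surface noise, landmark jitter and inter-modality shape
mismatch. Every algorithm and metric is validated against it.

## Worked example

```r
library(lvfuse)

# a paired two-modality phantom: 1 mm surface noise, 1.5 mm landmark jitter,
# and a 10% shape difference along one short axis
pair <- make_phantom_pair(phantom_params(seed = 42, noise_sd = 1,
                                         landmark_jitter_sd = 1.5,
                                         shape_mismatch = c(0.9, 1, 1)))

t_icp <- icp_align(pair$echo$surface, pair$ccta$surface,
                   pair$echo$landmarks, pair$ccta$landmarks)$transform
evaluate_registration(pair$ccta, pair$echo, t_icp)
#> Registration quality report:
#>   Apex distance (cm)                 0.3
#>   Mitral center distance (cm)        0.3
#>   Aortic center distance (cm)        0.2
#>   Long-axis angle (deg)              2.1
#>   Transverse-plane angle (deg)       0.4
#>   Mean point-to-point distance (cm)  0.1
#>   Three-chamber Dice's coefficient   0.9

t_3ch <- three_chamber_align(pair$echo$landmarks, pair$ccta$landmarks)
evaluate_registration(pair$ccta, pair$echo, t_3ch)
#> Registration quality report:
#>   Apex distance (cm)                 0.1
#>   Mitral center distance (cm)        0.0
#>   Aortic center distance (cm)        0.1
#>   Long-axis angle (deg)              0.0
#>   Transverse-plane angle (deg)       0.0
#>   Mean point-to-point distance (cm)  0.2
#>   Three-chamber Dice's coefficient   0.9
```

Distances are reported in cm and angles in degrees (printed at one decimal;
full precision is kept internally, e.g. in `cohort_table()` /
`compare_methods()`). The example shows the characteristic trade-off: ICP,
driven by the shape-mismatched surfaces, fits them more closely (mean
point-to-point 0.1 vs 0.2 cm) but pays for it in rotational alignment
(long-axis 2.1 deg, transverse-plane 0.4 deg), while three-chamber alignment
zeroes the angle measures by construction when evaluated against the same
landmarks it aligned (independently re-marked validation landmarks — see
`make_repeated_segmentation()` — make them nonzero, as in clinical use).
On a cohort these differences are what `compare_methods()` tests (21 paired
Wilcoxon tests for 3 methods x 7 measures).

A command-line interface covering the whole pipeline
(`simulate`, `register`, `evaluate`, `variability`, `compare`) lives in
`inst/cli/lvfuse.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "lvfuse.R", package = "lvfuse"))')" \
    simulate --out phantom_01 --seed 7 --noise-sd 1
```

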