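# multipose

Computational core for **multi-animal pose estimation and tracking** in R.

Behavioral neuroscience increasingly runs on pose tracking: freely
interacting flies, mice, bees or gerbils filmed from above, with a handful
to dozens of labeled body parts per animal that must be located, grouped
into individuals, followed over time, and scored against ground truth.
Deep networks do the image-to-tensor part of that job; everything around
the network is deterministic signal processing, and that is what this
package implements — for pipeline developers who need trustworthy encoders,
decoders and metrics, and for methodologists who want every stage testable
against an oracle without a GPU in sight.

## What is inside

| Stage | Functions |
|---|---|
| Data model & container | `skeleton()`, `pose_instance()`, `labels_dataset()`, `save_labels()`/`load_labels()` (single-file HDF5), `make_splits()`, `to_point_arrays()` |
| Target encoding | `encode_confidence_maps()`, `encode_pafs()`, `encode_class_maps()`, `compute_crop_size()`, `select_anchor()`, `make_anchor_crops()` |
| Decoding | `find_global_peaks()`, `find_local_peaks()`, `refine_peaks()` (integral subpixel refinement) |
| Grouping | `score_connection()`, `match_edge()`, `assemble_instances()`, `bottomup_decode()`, `topdown_decode()`, `assign_ids_class_maps()`, `assign_ids_probabilities()` |
| Tracking | `sparse_flow()` (pyramidal Lucas–Kanade), `flow_shift()`, `track_frame()`, `run_tracker()` |
| Evaluation | `compute_oks()`, `match_frame_instances()`, `compute_map()`, `localization_errors()`, `count_id_switches()` |
| Architecture & config | `compute_receptive_field()`, `run_config()`, `save_config()`/`load_config()` |
| Closed-loop behavior | `pose_pair_features()`, `approach_trigger()`, `trigger_trace()` |
| Synthetic fixtures | `scene_spec()`, `generate_scene()`, `generate_session()`, `render_scene()` |

The core quantities, in the field's standard notation:

- **Confidence map** for part *i* at grid pixel *x_p*:
  `C_i(x_p) = exp(-||x_i - x_p||² / 2σ²) δ_i`, multi-animal maps combined by
  per-pixel max; σ scales with the output stride `s_o`.
- **Part affinity field** for edge *e*: the unit vector `u_e` from source to
  destination, weighted by `exp(-M² / 2σ²)` where *M* is the distance to the
  clamped projection onto the segment; instances combined by summation.
- **Connection score**: mean over 10 evenly spaced samples of
  `u_candidate · PAF(sample)`, matched per edge by Hungarian assignment and
  assembled greedily along the skeleton.
- **OKS**:
  `Σ_i exp(-||X_i - X̂_i||² / (2 α σ_i²)) δ_i / Σ_i δ_i` with α the GT
  visible-bbox area and σ_i = 0.025; mAP averages 101-point interpolated
  precision over OKS thresholds 0.50–0.95.
- **Receptive field**: `RF = 1 + Σ_i (K_i − 1) Π_{j≤i} S_j`.

## Worked example

Encode a synthetic three-fly scene as "perfect network output", decode it
bottom-up, and score the result:

```r
library(multipose)

skel  <- example_skeletons()$fly13       # 13 nodes, 12 edges, thorax-rooted
scene <- generate_scene(scene_spec(image_size = c(256L, 256L),
                                   skeleton = skel, n_instances = 3,
                                   min_separation = 90, pose_scale = 36,
                                   seed = 7))
grid  <- grid_spec(256, 256, output_stride = 2, sigma_base = 1)
cms   <- encode_confidence_maps(scene$instances, grid)
pafs  <- encode_pafs(scene$instances, skel, grid)
cms
#> <confidence_maps: 128 x 128 x 13 channels, stride 2>

decoded <- bottomup_decode(cms, pafs, skel)
decoded[[1]]
#> <pose_instance: 13/13 nodes visible>

m <- match_frame_instances(scene$instances, decoded)
compute_map(m)
#> <eval_result: mAP = 1.0000, mAR = 1.0000 over 10 thresholds>

le <- localization_errors(list(gt_list = scene$instances,
                               pred_list = decoded, match = m))
le$percentiles$p95[le$percentiles$node == "all"]
#> [1] 0.1014
```

All 39 (3 animals × 13 parts) landmarks are recovered and grouped to the
correct animals; after integral subpixel refinement the 95th-percentile
localization error on this half-resolution (stride 2) grid is about 0.1 px,
so the evaluation yields mAP = 1 across all ten OKS thresholds. The methods
vignette (`vignettes/multipose-methods.Rmd`) explains every stage, its
parameters and its numerical caveats.

## Command line

A small CLI wraps the main flows:

```sh
Rscript inst/cli/multipose-cli.R synth    --out scene.poses.h5 --frames 100 --animals 4
Rscript inst/cli/multipose-cli.R track    --in scene.poses.h5 --out tracked.poses.h5
Rscript inst/cli/multipose-cli.R evaluate --gt gt.poses.h5 --pred tracked.poses.h5 --out metrics.json
Rscript inst/cli/multipose-cli.R trigger  --in tracked.poses.h5 --female 1 --male 2 --px-per-mm 30.3 --out trace.csv
Rscript inst/cli/multipose-cli.R config rf --layers 3x1,3x2,3x2
```
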