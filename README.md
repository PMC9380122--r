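# ablmargin

Assessment of percutaneous thermal-ablation outcomes for liver tumors from
volumetric imaging: biomechanical deformable registration of pre- and
post-ablation scans, 3D minimum-delivered-margin computation, and a
cone-tracing test of whether later local tumor progression colocates with
the region where the intended 5-mm margin was not achieved.

## Who this is for

Medical-image-analysis researchers studying ablation-margin quantification:
the package provides the full computational chain (registration → margin →
recurrence colocation → statistics) plus a synthetic-phantom generator with
analytic ground truth, so every stage is testable without patient data.

## The model in brief

The tumor (GTV, segmented on the pre-treatment scan) is mapped onto the
post-ablation scan in two stages. A gray-level rigid registration of the
liver ROIs (normalized cross-correlation, deterministic multi-resolution
search) is followed by a biomechanical deformable registration: triangular
surface meshes of the two livers define a boundary correspondence, which is
imposed as Dirichlet conditions in a linear-elastic finite-element model of
the liver volume (Young's modulus 1000 Pa, Poisson's ratio 0.45, linear
tetrahedra), and the solved displacements are resampled to a dense
deformation vector field.

The **minimum delivered margin** is the 3D minimum distance-to-agreement
between the mapped GTV surface and the ablation-zone boundary — exact
Euclidean distances in mm, with tumor/ablation overlap scored as 0 mm and
the ablation zone expanded by 10 mm outside the liver so subcapsular tumors
are scored by their margin *within* the liver. For recurrence assessment,
liver vasculature is segmented with a multiscale Hessian vesselness filter,
the post-ablation and recurrence scans are rigidly aligned on the vessels
inside 7.5-cm spheres of interest centered on the ablation zone, and the
recurrence is expressed as a set of spherical-coordinate directions
(theta, phi) from the ablation centroid; if that cone intersects the
uncovered intended-margin region — (GTV ⊕ 5 mm) \ ablation, inside the
liver — the progression is scored as colocating with the margin defect.

Group statistics (Mann–Whitney U with midranks and exact small-sample
enumeration; ROC AUC as the rank-sum statistic) reproduce a packaged
30-patient margin table (14 with local tumor progression, 16 without).

## Worked example

```r
library(ablmargin)

# a synthetic case with known ground truth: 80^3 voxels at 1.25 mm,
# 8 mm smooth warp, ablation offset so one sector misses the 5-mm margin
case <- generate_phantom(phantom_spec(seed = 1, grid_shape = c(80, 80, 80),
                                      spacing = 1.25))

reg <- biomech_register(case$pre$volume,  case$pre$masks$liver,
                        case$post$volume, case$post$masks$liver,
                        focus = case$pre$masks$gtv)

gtv_mapped <- propagate_contour(case$pre$masks$gtv, reg$dvf, "forward",
                                case$post$masks$liver)
m <- min_margin(gtv_mapped, case$post$masks$ablation, case$post$masks$liver)
m
#> <margin_result> min margin 1.25 mm; GTV outside ablation: 0.00% (0.00 cc); uncovered 1.46 cc
```

A minimum margin of 1.25 mm with no mapped tumor outside the ablation zone
but a 1.5-cc uncovered region says: the ablation covered the whole tumor,
but on one side the intended 5-mm margin was not delivered. Cone tracing
then asks whether the (synthetic) recurrence points at that sector:

```r
vessels_post  <- segment_vessels(case$post$volume,  case$post$masks$liver)
vessels_recur <- segment_vessels(case$recur$volume, case$recur$masks$liver)
tf <- focused_vessel_registration(vessels_post, vessels_recur,
                                  case$post$masks$ablation,
                                  case$recur$masks$ablation_shrunk)
ds <- build_direction_set(mask_centroid(case$recur$masks$ablation_shrunk),
                          case$recur$masks$recurrence)
cone_overlap(ds, mask_centroid(case$post$masks$ablation),
             m$uncovered_region, tf)
#> <cone_result> overlap: yes (0.21 cc)
```

The recurrence cone intersects 0.2 cc of the uncovered region — the
progression occurred in the same relative direction as the margin defect,
which is the qualitative finding the workflow is designed to surface.

The packaged per-patient table reproduces the study-level statistics:

```r
rep <- margin_stats_report()
round(rep$auc, 2)
#>    rigid deformed
#>     0.58     0.87
rep$tests$dta_deformed$p < 0.01
#> [1] TRUE
```

`run_pipeline(pipeline_config(phantom = phantom_spec(seed = 1)))` chains
all stages and writes NIfTI/PLY/CSV/JSON artifacts; `inst/cli/ablmargin`
exposes `phantom`, `register`, `margin`, `cone`, `stats` and `pipeline`
subcommands for shell use.

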