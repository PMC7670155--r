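# acromion3d

Three-dimensional acromial morphometry from labeled shoulder bone surface
meshes.

Rotator cuff tears are often attributed to mechanical impingement between the
rotator cuff and bony prominences of the acromion. This package implements a
3D measurement pipeline for quantifying that risk: given surface meshes of
the scapula (with the acromion labeled), the distal clavicle and the proximal
humeral head, plus a small set of annotated anatomical landmarks, it builds a
reproducible scapular coordinate frame and measures eight acromial shape
parameters, including the dimensions of the **acromial anterolateral
protrusion (AALP)** — the bony lobe on the anterolateral acromion whose width
and anteroposterior extent are associated with impingement-type cuff injury.
It is aimed at musculoskeletal imaging researchers working from CT-derived
bone segmentations.

## The measurements

All measurements are expressed in a scapular frame with origin **A** (center
of the best-fit circle of the inferior glenoid rim), x pointing lateral,
y superior and z anterior. The frame is built from A, the junction of the
scapular spine with the medial scapular border (**B**), the inferior scapular
angle (**C**), and an anterior witness point that fixes the sign of z; left
shoulders are mirrored across the scapular plane so one right-handed
convention serves both sides.

| Parameter | Definition |
|---|---|
| AHI (mm) | acromiohumeral interval: min distance, in the y–z (outlet) projection, from the most superior humeral-head point to the acromial undersurface |
| AAP (mm) | anterior protrusion of the acromion beyond a line along the anterior aspect of the distal clavicle (x–z plane) |
| AIP (mm) | inferior protrusion of the anterior acromion beyond a line along the inferior aspect of the distal clavicle (x–y plane) |
| AC angle (°) | angle at the most lateral point of the acromion (MLPA) subtended by the anterior and posterior acromioclavicular joint-line margins (x–y plane) |
| a (mm) | distance from the most medial edge of the AALP to the MLPA (x–z plane) |
| b (mm) | distance from the most posteromedial edge of the AALP to the MLPA (x–z plane) |
| c (mm) | anteroposterior diameter of the AALP |
| c+d (mm) | anteroposterior diameter of the whole acromion |
| c/(c+d)×100 (%) | anteroposterior AALP proportion |

The AALP is localized by slicing the acromion with axial planes at 0.625 mm
(CT slice spacing), computing signed curvature along each closed slice
contour, and marking the concave curvature extremum on the medial ("inner")
contour arc — the crease where the lobe meets the main acromion. The marked
points, ordered across slices, form the medial AALP border.

The package also ships a parametric synthetic shoulder generator whose every
measurement has a closed-form ground truth, a cohort simulator matched to the
study group summaries (control / non-impingement injury / impingement injury,
n = 113/98/128), and the associated statistics: within-replicate CV%,
ICC(2,1)%, one-way ANOVA (raw or from printed n/mean/SD), Welch pairwise
tests, signed percent differences, and 95% reference ranges whose upper
bounds serve as risk cutoffs.

## Worked example

```r
library(acromion3d)

gen <- generate_shoulder(shoulder_spec())  # impingement-group defaults
measure_all(gen$model)
#> Acromial measurement set
#>   AHI        8.10 mm
#>   AAP        8.50 mm
#>   AIP        9.00 mm
#>   AC angle  40.80 deg
#>   (a)       14.72 mm
#>   (b)       10.97 mm
#>   (c)       11.30 mm
#>   (c+d)     35.76 mm
#>   ratio     31.60 %
```

The measured values recover the generator's ground truth (AHI 8.1, AAP 8.5,
AIP 9.0, AC 40.8°, a 14.8, b 11.0, c 11.3, ratio 31.6%) to within the
pipeline's stated tolerance of max(0.5 mm, 3%): the residual 0.08 mm error
on (a) comes from the discrete 0.625 mm slice grid sampling the oblique
crease line.

```r
co <- simulate_cohort(cohort_spec(seed = 1))  # 339 subjects, 3 groups
rep <- build_table3_report(co)
subset(rep$anova, parameter %in% c("AAP", "a", "b"))
#>   parameter         F df1 df2            p
#> 2       AAP 11.872865   2 336 1.041670e-05
#> 5         a 36.300510   2 336 5.329565e-15
#> 6         b 12.035045   2 336 8.953129e-06
```

At the published group means/SDs the simulated cohort reproduces the study's
significance pattern: AAP, a, b and the AALP ratio separate the impingement
group, while AHI and AIP do not (AHI p = 0.65, AIP p = 0.30 in this seed).

## Command line

```sh
Rscript -e 'acromion3d::cli_main()' synth --out-dir shoulder1 --seed 3
Rscript -e 'acromion3d::cli_main()' measure \
  --scapula shoulder1/scapula.obj --clavicle shoulder1/clavicle.obj \
  --humerus shoulder1/humerus.obj --landmarks shoulder1/landmarks.json \
  --out shoulder1/measures.csv
Rscript -e 'acromion3d::cli_main()' cohort --seed 2 --out cohort.csv
Rscript -e 'acromion3d::cli_main()' report --cohort cohort.csv --out report.csv
```

Meshes are STL/OBJ/PLY (units mm); bone sub-labels (acromion, distal
clavicle quarter) travel as OBJ `g` groups; landmarks are a small JSON file.

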