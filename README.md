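# ctpaindices

Automated right-heart strain indices from CTPA segmentation masks, with the
agreement statistics needed to validate them.

## The problem

On computed tomography pulmonary angiography (CTPA) — the standard test for
acute pulmonary embolism — three axial measurements summarize right-heart
dysfunction:

- **RV/LV**: the ratio of the maximal transverse (horizontal) diameters of
  the right and left ventricles, measured on the axial slice where the
  combined ventricular area is largest. RV/LV > 1 suggests right-ventricular
  dilation.
- **PA/AA**: the ratio of main pulmonary artery to ascending aorta diameters
  on the slice where the PA cross-section is largest — a surrogate for
  pulmonary hypertension.
- **SA** (septal angle): the acute angle, in degrees, between a
  spine-parallel reference axis derived from the lung mask and the line
  connecting the left and right ventricular centroids, characterizing septal
  orientation.

Measuring these by hand is slow and rater-dependent. Given labeled
segmentation volumes (from any source — a network, an atlas, a human), this
package computes all three indices deterministically and provides the
statistics used to compare automated against manual measurements.

## Measurement conventions

All diameters are **maximal same-row horizontal chords**: over every image
row intersecting a structure's mask, the chord from the row's leftmost to
rightmost pixel (a segment parallel to the x-axis) is considered, and the
longest is kept, with length `(x_right − x_left) · dx` mm measured
pixel-center to pixel-center. Chords are taken on the largest 4-connected
component after hole filling, so stray specks in network output cannot
corrupt a diameter. All tie-breaks (slice, row, extreme pixel) resolve to
the lowest index, making every measurement bit-reproducible. The septal
angle is computed in physical (mm-scaled) coordinates as
`arccos(|d₁·d₂|)`, hence always in [0°, 90°].

Agreement machinery, for n subjects measured by two sources:

- **Dice** `2|X∩Y| / (|X|+|Y|)` for mask overlap;
- **ICC(1,1)**, the one-way random-effects single-rater intraclass
  correlation `(MS_R − MS_w) / (MS_R + (k−1)MS_w)`, with an exact-F 95%
  confidence interval;
- **accuracy**: the fraction of subjects whose automated value lies within a
  relative tolerance (default 10%) of the manual one, with a bootstrap
  standard error;
- **Bland–Altman** bias and 95% limits of agreement `bias ± 1.96·SD`.

Because no clinical volumes ship with the package, a parametric **phantom
generator** builds axial chest volumes (two ventricular ellipses separated
along a controllable septum direction, two great-vessel circles with a known
peak-area slice, symmetric lungs defining the vertical reference axis) whose
three indices have closed-form ground truth — every stage of the pipeline is
testable against analytic values. A small trainable U-Net (encoder, decoder,
skip connections) closes the loop from pseudo-CT intensities back to labeled
masks at toy scale.

## Worked example

```r
library(ctpaindices)

# a phantom with known anatomy: RV semi-axis 22 mm vs LV 20 mm,
# PA radius 16 mm vs AA 14 mm, septum at 40 degrees from the lung axis
ph  <- generate_phantom(phantom_spec(a_rv = 22, a_lv = 20,
                                     r_pa = 16, r_aa = 14,
                                     theta_sep_deg = 40))
idx <- compute_indices(ph$volume)
idx
#> <index_set> RV/LV = 1.107 (slice 14), PA/AA = 1.100 (slice 6), SA = 40.7 deg

index_set_records(idx, "subj_001")
#>   subject_id index_name source     value slice_index
#> 1   subj_001      RV_LV   auto  1.107143          14
#> 2   subj_001      PA_AA   auto  1.100000           6
#> 3   subj_001         SA   auto 40.710847          14
```

The measured RV/LV of 1.107 is the rasterized analytic truth (22/20 = 1.1 up
to the 0.7 mm pixel grid), PA/AA 1.100 likewise approximates 16/14 ≈ 1.143,
and the 40.7° angle matches the pixel-snapped septum placement exactly
(`ph$truth$sa_deg_realized`).

Cohort-level agreement against simulated raters:

```r
d <- tempfile(); dir.create(d)
truths <- cmd_phantom(d, n = 10, seed = 42)                 # volumes on disk
cmd_measure(sort(Sys.glob(file.path(d, "subj_*.nii.gz"))),  # automatic arm
            file.path(d, "auto.csv"))
write_report(simulate_manual_ratings(truths, noise_cv = 0.05, seed = 7),
             file.path(d, "manual.csv"), format = "csv")    # manual arm
cmd_evaluate(file.path(d, "auto.csv"), file.path(d, "manual.csv"),
             out = file.path(d, "agreement.json"))
#> Index  ICC (95% CI)           Acc (+/- SE)   Bias [LoA]
#> RV_LV  0.93 (0.771, 0.983)    0.90 (+/- 0.10)  -0.040 [-0.147, +0.067]
#> PA_AA  0.87 (0.581, 0.965)    1.00 (+/- 0.00)  +0.015 [-0.121, +0.152]
#> SA     0.96 (0.849, 0.989)    0.80 (+/- 0.13)  -0.218 [-6.291, +5.855]
```

Each row reads like a standard consistency table: the ICC with its exact-F
confidence interval, the fraction of subjects within the 10% relative
tolerance, and the Bland–Altman bias with its limits of agreement.

The same pipeline is scriptable from a shell via the installed
`exec/ctpaindices` entry point (`measure`, `evaluate`, `phantom`,
`seg-train`, `seg-predict`); every command writes a JSON run manifest.

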