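# ewamri

Automatic quantification of myocardial infarct size in short-axis late
gadolinium enhancement (LGE) cardiovascular MR.

In LGE imaging, infarcted myocardium retains gadolinium and appears
hyperenhanced, but turning the image into an infarct size in percent of
left-ventricular mass (%LVM) has no agreed standard: n-SD-from-remote,
FWHM and Otsu thresholds disagree with each other and between magnitude
inversion-recovery (IR) and phase-sensitive (PSIR) reconstructions.
`ewamri` implements the EWA pipeline (Expectation-maximization intensity
classification, **w**eighted summation, **a**-priori territory
information) for IR, PSIR and high-resolution T1-weighted stacks, for
researchers who need reproducible, automatic infarct sizes plus the
classical comparators on identical inputs.

## The method in brief

Myocardial intensities are modelled as a two-Gaussian mixture fit by a
constrained EM algorithm (initial infarct = top decile; intensities below
the 5th / above the 95th percentile are clamped to normal / infarct each
E-step).  The working threshold is the posterior-equality point

&nbsp;&nbsp;&nbsp;&nbsp;
*&pi;<sub>n</sub> N(t; &mu;<sub>n</sub>, &sigma;<sub>n</sub>) =
&pi;<sub>i</sub> N(t; &mu;<sub>i</sub>, &sigma;<sub>i</sub>)*,

solved in closed form.  The infarct core grows from supra-threshold seeds
with a discrete level set driven by the linear speed
*S = (I − t\*)/(I<sub>max</sub> − t\*)* with curvature smoothing;
microvascular obstruction is recovered slice-wise as flood-fill holes
sealed by infarct or the endocardial border (3×3-cross morphological
closing); a-priori culprit-territory filtering and a 1.5 cm³ / 1 %LVM
small-region rule remove artifacts; and the final size is the weighted sum

&nbsp;&nbsp;&nbsp;&nbsp;
*%LVM = 100 &Sigma; w / N<sub>myo</sub>*, &nbsp;
*w = clamp((I − &mu;<sub>r</sub>) / (P90<sub>MI</sub> − &mu;<sub>r</sub>), 0, 1)*,

with MVO voxels counted as fully infarcted (*w* = 1).  Full details and
every design decision are in the methods vignette
(`vignettes/ewa-methods.Rmd`).

## Worked example

Everything runs on seeded synthetic phantoms with voxel-level ground
truth — no data downloads:

```r
library(ewamri)

ph  <- generate_phantom(phantom_spec(seed = 7, mvo = TRUE))
ph$truth$true_pct_lvm
#> [1] 22.36448

res <- run_ewa(ph$stack, ph$seg, culprit = "LAD", insertions = ph$insertions)
res
#> <ewa_result> infarct 20.55 %LVM (weighted), core+MVO 26.13 %LVM,
#>   MVO 1.64 mL, t* = 51 [IR, culprit LAD]
res$em
#> <gaussian_pair> normal N(20.5, 9.85) pi=0.750 | infarct N(98.7, 19.4)
#>   pi=0.250 | t*=51 (18 iter)
```

The phantom's true infarct is 22.36 %LVM.  The EM fit recovers the
nulled-myocardium component (mean 20.5, the generator used 20) and the
infarct component, places the threshold at 51, and the weighted size
(20.55 %LVM) lands much closer to the truth than the binary core + MVO
count (26.13 %LVM), which counts every partial-volume edge voxel as fully
infarcted.  The comparators run on the same input:

```r
run_compare(ph$stack, ph$seg, culprit = "LAD", insertions = ph$insertions,
            reference = ph$truth$fraction > 0.5)
#>        method threshold pct_lvm   dsc
#> 1         ewa      51.0    20.6 0.981
#> 2          em      52.3    25.0 0.947
#> 3         2sd      40.3    27.0 0.913
#> 4         3sd      50.3    25.1 0.945
#> 5         5sd      70.2    23.4 0.951
#> 6    fwhm-min      74.1    22.6 0.940
#> 7 fwhm-remote      84.3    20.4 0.894
#> 8        otsu      62.5    24.2 0.957
```

`dsc` is the Dice overlap with the ground-truth mask.  A thin CLI wraps
the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "ewa.R", package = "ewamri"))')" \
    phantom --seed 1 --out case/
Rscript .../ewa.R run --image case/phantom.nii.gz --contours case/contours.json \
    --culprit LAD --anterior 7.1,7.1 --inferior 7.1,57.9 --out case/out
```

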