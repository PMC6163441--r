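# olivesizer

Estimate olive-fruit size (major/minor axis, mm) and mass (g) from overhead
photographs of fruits spread on a bright conveyor mat. The package
implements the full chain — segmentation, per-fruit measurement, linear
calibration against caliper/balance references, and evaluation — plus a
seeded synthetic-scene generator with exact ground truth so everything is
testable end to end without proprietary imagery. It is aimed at
postharvest/food-engineering work on fruit grading and at anyone needing a
reproducible reference implementation of this style of morphology-based
segmentation.

## Method

Fruits are darker (low HSV value *V*) and more saturated (high *S*) than
the mat; shadows are darker but, because shadowing scales RGB channels
equally, keep the mat's saturation. Segmentation works on the fused channel

```
I_SV  = S + (255 − V)          (saturating 8-bit addition)
I_γ   = γ_β(I_SV)              (grayscale opening, 50 px disk β: background estimate)
I_HC  = max(I_SV − I_γ, 0)     (high-contrast image)
I_BIN = I_HC > t_Otsu          (Otsu's between-class-variance threshold)
```

followed by binary opening (3 px disk) and reconstruction-based hole
filling. Input images are first downscaled to 40% by bicubic interpolation
and smoothed with a 5×5 Gaussian (σ = 0.8). Each segmented component is
measured by its pixel area (8-connectivity) and by the axes of the ellipse
with the same normalized second central moments (axis length 4√λ with a
1/12 unit-pixel correction). Image units are mapped to physical units by
per-feature ordinary least squares,

```
major_mm = a·major_px + b      minor_mm = a·minor_px + b      mass_g = a·area_px + b
```

fitted on a training subset (reference protocol: 50 fruits, 150 held out
for external validation) and scored with RMSE, SE (RMSE relative to the
mean reference, %) and |E| (absolute value of the *summed* signed errors
relative to the summed references, %). Segmentation quality is scored at
pixel level with precision/recall/F against ground-truth masks. See the
methods vignette (`vignettes/olive-sizing-methods.Rmd`) for every numerical
convention and the generator's scene model.

## Worked example

```r
library(olivesizer)

# a synthetic conveyor scene with known ground truth
sc   <- generate_scene(scene_params(seed = 7))
mask <- segment(sc$image)                      # default published settings
attr(mask, "otsu_threshold")
#> [1] 107

tab <- measure_components(mask, "demo")
head(tab[, c("label", "area_px", "major_axis_px", "minor_axis_px")], 3)
#>   label area_px major_axis_px minor_axis_px
#> 1     1     453         24.33         23.77
#> 2     2     483         25.23         24.43
#> 3     3     406         23.04         22.50
nrow(tab)                                      # one component per fruit
#> [1] 10

truth <- resize_mask_nearest(sc$mask, 0.4)     # ground truth at working scale
unlist(seg_scores(confusion_counts(mask, truth)))
#> precision    recall   f_score
#>    0.9830    0.9906    0.9868
```

The axes are in working-resolution pixels (here 0.625 mm/px): component 1
is a ≈ 15.2 × 14.9 mm olive. The full pipeline segments a directory of
images, matches components to a reference CSV by position, fits the three
calibration models on 50 fruits and validates on the rest:

```r
d   <- tempfile()
man <- generate_dataset(10, scene_params(n_fruits = 20L, seed = 1500L), d)
res <- run_pipeline(file.path(d, man$images), file.path(d, "reference.csv"),
                    file.path(d, "run"), train_n = 50L, seed = 1L)
cat(readLines(res$summary_path), sep = "\n")
#> pipeline summary
#> images processed: 10
#> components measured: 200
#> reference fruits: 200, matched pairs: 200
#> training/validation split: 50/150 (seed 1)
#> major_axis: slope 0.619648 intercept 0.0592816 R^2 0.9934 | RMSE 0.2309 SE 1.22% |E| 0.03%
#> minor_axis: slope 0.61815 intercept 0.0780464 R^2 0.9922 | RMSE 0.2203 SE 1.58% |E| 0.29%
#> mass: slope 0.00427043 intercept 0.199516 R^2 0.9658 | RMSE 0.09317 SE 3.75% |E| 0.45%
```

Slopes ≈ 0.62 mm/px recover the scene's physical scale (0.25 mm/px at
capture ÷ 0.4 downscale = 0.625); the mass model recovers the generator's
affine area law. On the external validation set the axis estimates are
accurate to ≈ 0.2 mm RMSE (1–2% of the mean) and mass to ≈ 0.09 g, with
aggregate bias |E| below 0.5%.

## Command line

A thin script over the same functions is installed at
`inst/cli/olivesizer` (`system.file("cli", "olivesizer", package = "olivesizer")`):

```sh
olivesizer synth    --out data --n-images 5 --n-fruits 10 --seed 3
olivesizer segment  --in data/scene_001.png --out mask.png
olivesizer measure  --mask mask.png --out features.csv
olivesizer eval-seg --pred preds/ --truth truths/ --out scores.csv
olivesizer pipeline --images data --reference data/reference.csv --out run
```

Every run logs its fully resolved configuration; exit codes are 0 (success),
2 (validation error), 3 (degenerate image under `--strict`).

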