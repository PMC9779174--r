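# desertvi

Grading grassland desertification from visible-band (RGB) vegetation
indices.

`desertvi` is for ecologists and remote-sensing practitioners who estimate
fractional vegetation coverage (FVC) from nadir RGB imagery — typically
low-altitude UAV scenes of semi-arid grassland — and need to know *which*
visible-band index to trust at *which* degree of desertification. The
package implements the full assessment chain as tested, scriptable R:

1. **19 visible-band vegetation indices** (GLI, ExG, ExR, ExB, NGBDI,
   NGRDI, ExGR, MGRVI, RGBVI, GBRI, RGRI, CIVE, VEG, DEVI, EGRBDI,
   V-MSAVI, g, COM, COM2), computed per pixel on raw channels or chromatic
   coordinates `r = R/(R+G+B)` etc.
2. **Otsu segmentation**: each index map is binarized at the threshold `t`
   maximizing the between-class variance
   `sigma_B^2(t) = w0(t) w1(t) (mu0(t) - mu1(t))^2`,
   with data-driven polarity (the greener class is vegetation).
3. **FVC and five-grade classification**: FVC = vegetation-pixel fraction;
   grades Severe [0,5), High [5,21), Moderate [21,51), Slight [51,71),
   Non-desertification [71,100].
4. **Supervised reference**: an RBF-kernel SVM (`gamma = 0.333`) trained on
   labeled ROIs classifies every pixel; its FVC is the reference `V_SUP`.
5. **Accuracy metrics**: overall accuracy `OA = (TP+TN)/N`, the
   chance-corrected kappa coefficient
   `k = (N sum x_ii - sum x_i+ x_+i) / (N^2 - sum x_i+ x_+i)`,
   and the relative FVC error `RE = (V_SUP - V_VI)/V_SUP`.
6. **Grade-wise comparison**: per grade and metric, one-way ANOVA across
   the 19 indices (balanced 19 x 6 design: df 18/95/113) followed by
   Duncan's multiple range test letters at alpha = 0.05.

Because no public imagery accompanies the underlying survey protocol, the
package ships a seeded synthetic-scene generator (elliptical vegetation
patches over yellow-brown soil, controllable true FVC, spectral overlap,
and noise) that produces ground-truthed five-grade panels for validation.
See the methods vignette (`vignettes/desertification-assessment.Rmd`) for
the model, the generator's assumptions, and all numerical choices.

## Worked example

A dense, hard scene (80% cover, strong vegetation-soil color overlap):

```r
library(desertvi)

sc <- generate_scene(scene_spec(target_fvc = 80, spectral_overlap = 0.6, seed = 42))
sc
#> <synthetic_scene> 512 x 512, FVC 79.92% (Non-desertification), seed 42

rois  <- sample_rois(sc, seed = 42)                     # 60/60 train, 15/15 test, 80/80 validation
clf   <- fit_pixel_classifier(extract_training_samples(sc$image, rois))
ev    <- evaluate_classifier(clf, sc$image, rois)
v_sup <- compute_fvc(classify_image(clf, sc$image))$fvc
sprintf("reference FVC %.2f%% (test OA %.4f, kappa %.4f)", v_sup, ev$oa, ev$kappa)
#> "reference FVC 79.83% (test OA 0.9963, kappa 0.9926)"

idx <- evaluate_indices_on_scene(sc$image, rois, v_sup)
head(idx[order(idx$abs_re), c("index", "fvc_vi", "oa", "kappa", "abs_re")], 5)
#>     index fvc_vi    oa  kappa   abs_re
#> 11   RGRI  79.52 99.49 0.9841 0.003852
#> 14   DEVI  79.47 99.41 0.9817 0.004468
#> 15 EGRBDI  79.36 99.19 0.9751 0.005911
#> 7    ExGR  79.31 99.36 0.9801 0.006518
#> 6   NGRDI  79.27 99.27 0.9776 0.007053

assign_grade(idx$fvc_vi[idx$index == "ExG"])
#> [1] Non-desertification
```

The supervised reference is near-perfect on its test ROIs; the best
indices estimate FVC within half a percentage point of the reference
(|RE| < 0.01), while blue-heavy indices (GBRI, NGBDI, ExB) lose about ten
points of OA on this high-overlap scene. `run_full_study(default_config())`
runs the same pipeline over a balanced 30-scene five-grade panel and
returns per-grade ANOVA tables and Duncan letters; with `config$out` set it
writes every table as CSV.

A thin command-line wrapper with subcommands (`simulate`, `indices`,
`segment`, `fvc`, `grade`, `evaluate`, `anova`, `run`) is installed at
`inst/cli/desertvi.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/desertvi.R", package="desertvi"))')" \
    simulate --seed 1 --out panel
```

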