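# plbdetect

Small objects are the hardest part of object detection in medical images: in
a blood smear, platelets span a few dozen pixels while red and white blood
cells are one to two orders of magnitude larger, and the large cells dominate
the training loss of a standard two-stage detector. **plbdetect** implements
*pixel level balancing* (PLB), a dynamic per-object loss reweighting: every
detection box contributing to a loss term is weighted by

```
w_i = 2 * mean(a) / (a_i + mean(a))
```

where `a_i` is the box's pixel area and `mean(a)` the mean area of the boxes
contributing to that term in that optimisation step. A box of average size
keeps weight 1, a vanishing box approaches weight 2, and a box that dominates
the batch is damped towards `2/(n+1)` — small objects are emphasised without
any tuned per-class constants. The weight can be applied independently to
each of the four components of the Faster-R-CNN-style loss (RPN
classification `plb1c`, RPN regression `plb1b`, ROI classification `plb2c`,
ROI regression `plb2b`); with all switches off the loss is exactly the
unweighted baseline.

The package is aimed at people who want to study size-aware loss weighting
end to end without a GPU. It ships:

* the PLB weight computation and the four PLB-switchable loss components
  (`plb_weights()`, `total_loss()`);
* a desk-scale two-stage detector (tiny convolutional backbone, RPN, ROI
  head) with hand-written forward/backward passes, trainable in minutes on
  one CPU (`train_detector()`, `predict_boxes()`);
* a deterministic synthetic blood-smear generator with three cell classes
  straddling the COCO small/medium/large area bands (`generate_dataset()`);
* a size-stratified COCO-protocol evaluator, AP at IoU 0.50:0.95 overall and
  per area band (`evaluate_detections()`);
* an ablation harness comparing PLB variants against the baseline over
  replicate seeds (`experiment_plan()`, `run_plan()`), plus a thin CLI at
  `inst/cli/plbdetect`.

Everything is tidyverse-shaped: boxes, annotations, detections and results
are tibbles; fitted objects have `tidy()`/`glance()` methods and `autoplot()`
figures.

## Worked example

Train a baseline and a PLB1C detector on synthetic blood smears and compare
size-stratified AP:

```r
library(plbdetect)

train <- generate_dataset(scene_spec(seed = 100), 200)
test  <- generate_dataset(scene_spec(seed = 900), 60)
train
#> <plb_dataset> 200 images, 1793 annotations, 3 classes
#> # A tibble: 3 × 3
#>   class    band       n
#>   <chr>    <chr>  <int>
#> 1 platelet small    508
#> 2 rbc      medium  1085
#> 3 wbc      large    200

baseline <- train_detector(train, detector_config(seed = 1),
                           plb_loss_config(), epochs = 10)
plb1c    <- train_detector(train, detector_config(seed = 1),
                           plb_loss_config(plb1c = TRUE), epochs = 10)

evaluate_model(baseline, test)
#> <plb_eval> IoU 0.50:0.95
#>   mAP 0.4075 | AP_small 0.0327 | AP_medium 0.5250 | AP_large 0.6668
evaluate_model(plb1c, test)
#> <plb_eval> IoU 0.50:0.95
#>   mAP 0.4363 | AP_small 0.1332 | AP_medium 0.5524 | AP_large 0.6234
```

Turning PLB on in the RPN classification loss multiplies small-band AP
several-fold (0.03 → 0.13 here) while overall mAP improves —
the RPN stops discarding small objects as background. Medium/large AP moves
little: the reweighting redistributes attention rather than capacity.
Absolute numbers are toy-scale (a 220k-parameter detector, 128×128 images);
the orderings, not the magnitudes, are the point.

The full ablation over all four switches:

```r
plan <- experiment_plan(train, test, detector_config(),
                        variants = plb_variants(), epochs = 10, seeds = 1:3)
run_plan(plan)   # per-variant mean ± sd APs and % deltas vs baseline
```

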