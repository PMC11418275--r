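# jujubedet

Detecting winter jujubes in orchard imagery is a small-object problem:
fruit are only tens of pixels across, densely clustered, partially hidden
by leaves, and lit unevenly — while the detector has to run on embedded
hardware next to a harvesting arm. `jujubedet` implements, in pure R, a
family of lightweight anchor-free detectors built for this setting,
together with the RGB-D geometry that turns a detection into a 3D picking
point in the robot's base frame.

The package is aimed at researchers who want to study the *architecture*
of lightweight detectors — parameter and FLOP budgets, the effect of each
structural substitution, the decoding and evaluation pipeline — and the
camera-to-robot geometry, all in a scriptable environment with no GPU or
deep-learning framework.

## What is implemented

**Detector family.** The baseline is YOLOv8n (C2f backbone, FPN+PAN neck,
decoupled anchor-free head, single fruit class). Three structural changes
can be combined freely:

* **MobileViT backbone** — the convolutional backbone is rebuilt from
  MobileNetV2 inverted-residual blocks plus MobileViT hybrid
  convolution–transformer stages. A MobileViT block encodes local
  structure with an `n x n` convolution, expands to `d > C` channels,
  unfolds the map into `h x w` patches (`P = wh` positions,
  `N = HW/P` patches), runs a transformer across patches at each position,
  folds back, and fuses with the input.
* **LSK attention** — a large-selective-kernel module after the P3-scale
  neck layer: depthwise 5x5 and dilated 7x7 convolutions build multi-scale
  context; channelwise average/max pooling and a sigmoid convolution
  produce one spatial selection mask per kernel; the masked contexts are
  fused and multiply the input.
* **GSConv neck** — the neck's dense stride-2 convolutions are replaced by
  a half-dense/half-depthwise convolution whose outputs are interleaved by
  channel shuffle.

**Accounting.** `count_parameters()` sums trainable tensors exactly;
`count_flops()` evaluates one forward pass analytically (two operations
per multiply–accumulate, convolutions and matrix products plus bias adds).

**Everything around the model.** A seeded synthetic orchard-scene
generator with YOLO-format labels; split/augmentation arithmetic; a
desk-scale SGD trainer with exact backpropagation through every
convolutional module; decoding + NMS; precision/recall/AP; pinhole
deprojection and quaternion hand–eye transforms
(`P_b' = T P_c'`, `T = [[R, t], [0, 1]]`, `R` from `(qw, qx, qy, qz)`).

## Worked example

```r
library(jujubedet)

summarize_model(model_config("yolov8n", nc = 1))
#> variant: yolov8n (nc=1, imgsz=640)
#> parameters: 3,011,043
#> FLOPs: 8.08 G
#> size: 11.49 MB (fp32) / 5.74 MB (fp16)

summarize_model(model_config("mlg-yolo", nc = 1))
#> variant: mlg-yolo (nc=1, imgsz=640)
#> parameters: 1,173,429
#> FLOPs: 5.41 G
#> size: 4.48 MB (fp32) / 2.24 MB (fp16)
```

The full variant keeps the three-scale anchor-free head but needs 61%
fewer parameters than the baseline. A miniature end-to-end run — generate
scenes, overfit a reduced-width model, detect, and localize — looks like:

```r
scenes <- lapply(1:4, function(i)
  generate_scene(scene_spec(width = 64, height = 64, n_fruit = c(2, 3),
                            radius = c(6, 12), n_leaves = c(0, 0), seed = i)))
m   <- build_model(model_config("yolov8n", nc = 1, imgsz = 64,
                                width_mult = 0.25), seed = 1)
fit <- train_model(m, scenes, train_config(epochs = 60, batch_size = 4,
                                           seed = 1))
evaluate_model(fit$model, scenes)
#> TP=11 FP=0 FN=0  precision=100.00% recall=100.00% mAP=100.00%

# a detection plus a depth reading becomes a base-frame picking point
K     <- camera_intrinsics(fx = 600, fy = 600, cx = 320, cy = 240)
calib <- hand_eye_calibration(q = c(0.92, 0.10, -0.21, 0.31),
                              t = c(0.5, -0.2, 0.8), unit = "m")
locate_fruit(data.frame(xmin = 300, ymin = 220, xmax = 340, ymax = 260),
             depth_map = matrix(900, 480, 640), K, calib)$points[[1]]
#> (0.2070, -0.4837, 1.6023) [base frame, m]
```

There is also a command-line entry point (`inst/scripts/jujubedet`) with
subcommands `simulate`, `model`, `train`, `eval`, `detect` and `locate`.

## Limitations

The trainer is desk-scale by design: pure-R forward/backward at reduced
width and input size, per-image normalisation statistics, and a simplified
centre-cell assignment. It demonstrates that the architectures learn and
memorise small synthetic sets; it does not reproduce orchard-scale
accuracy figures, which require the real dataset and GPU-scale training.
MobileViT transformer stages are forward-only.
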