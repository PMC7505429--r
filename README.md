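# rfcnet

Joint segmentation of the optic disc (OD) and optic cup (OC) in
disc-centred fundus crops with a **recurrent fully convolutional network
(RFC-Net)**, implemented entirely in R + C++ (no external deep-learning
framework). The package is aimed at researchers studying the ingredients of
this architecture family — recurrent convolutions, multi-scale input /
multi-output supervision, and polar-coordinate class rebalancing — on a
reproducible CPU-scale test bench.

The vertical cup-to-disc ratio is a key glaucoma indicator, which makes the
joint OD/OC delineation a standard quantification step in fundus image
analysis. Its difficulty is concentrated in the cup: a low-contrast boundary
inside the bright disc, covering only a few percent of the crop.

## The model

Pixels are classified into three classes (0 background, 1 disc, 2 cup) by an
encoder-decoder FCN in which each level's block can be one of five variants
built from the **recurrent convolutional layer** (RCL)

    y(t) = ReLU( BN_t[ conv(x; Wx) + conv(y(t-1); Wr) ] ),   t = 0..T,

with the recurrent term absent at t = 0 and kernels shared across the T = 2
unfolding steps (a unit with equal input/output widths shares `Wr = Wx`
outright). The network adds a multi-scale input pyramid (512/256/128/64
thumbnails injected into the encoder), stride-2 convolutions instead of
pooling, transposed-convolution upsampling with skip connections, and five
deeply supervised softmax outputs combined by the weighted cross entropy

    L = sum_i  -(alpha_i / N) * sum_pixels sum_classes y log v,
    alpha = (0.1, 0.1, 0.1, 0.1, 0.6).

Before the network, the crop is resampled to polar coordinates about the
disc centre (`x = r cos(theta), y = r sin(theta)`), which turns the nested
disc/cup geometry into layered bands and raises the cup's pixel share from
~5 % to ~20 %; predictions are mapped back by the inverse transform.
Evaluation uses F1 / sensitivity / specificity / accuracy on the OD
(labels {1,2}) and OC (label 2) regions plus the **boundary localization
error** (BLE): the mean absolute radial difference, in pixels, between
predicted and reference boundaries sampled at 24 equidistant angles from a
common centre.

At the published 512-scale configuration the assembled network has exactly
11,016,684 trainable parameters with basic blocks and 18,883,436 with
stacked recurrent blocks; `scripts/calibrate_architecture.R` shows how these
two constants pin down the architecture's free widths.

## Worked example

Train the desk-scale profile (64 x 64 crops, widths 8/16/32/64) with stacked
recurrent blocks on 50 synthetic fundus crops and evaluate on held-out ones:

```r
library(rfcnet)

train <- generate_dataset(50, seed = 1000, size = 64)
test  <- generate_dataset(10, seed = 2000, size = 64)

ck <- rfc_train(train, desk_spec(variant = "stack_recurrent"),
                desk_train_config(epochs = 10, seed = 1))
count_parameters(ck$model)
#> [1] 1188887

ev <- rfc_evaluate(ck, test)
print(ev$summary, digits = 3)
#>    region metric  mean       sd
#> 1      OC     F1 0.972 0.007066
#> 2      OC    BLE 0.207 0.072411
#> 3      OC    SEN 0.972 0.012797
#> 4      OC    SPC 0.999 0.000442
#> 5      OC    ACC 0.998 0.000782
#> 6      OD     F1 0.981 0.002872
#> 7      OD    BLE 0.279 0.096825
#> 8      OD    SEN 0.989 0.005682
#> 9      OD    SPC 0.995 0.001989
#> 10     OD    ACC 0.994 0.001685

s <- test[[1]]
pred <- rfc_predict(ck, s$image, s$disc_center)
cup_fraction(s$mask); cup_fraction(pred$mask)
#> [1] 0.03173828
#> [1] 0.03198242
```

The summary rows are means/standard deviations over the test images: the
held-out disc overlap (OD F1 0.98) and cup overlap (OC F1 0.97) show the
full pipeline — polar transform, network, multi-output loss, SGD, inverse
transform — recovering both structures, with sub-pixel boundary error (BLE
well under 1 px on this clean synthetic bench; real fundus data is far
harder). The predicted cup fraction matches the ground truth's ~3 %.

A command-line interface wraps the same functions:

```sh
inst/cli/rfcnet generate --n 101 --seed 7 --size 64 --out data/
inst/cli/rfcnet train --config cfg.yaml --data data/ --out run/
inst/cli/rfcnet eval --checkpoint run/checkpoint.rds --data data/ --report report/
inst/cli/rfcnet ablate --data data/ --out ablation.csv
```

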