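# wholecellseg

Whole-cell segmentation from a **single** fluorescence channel. Many
cytoplasm markers (dsRed, TexasRed, Cy5, MitoTracker, …) stain the cell
body brightly but leave the nucleus with little or no signal, so nuclei
and background are both dark — and no separate nuclear stain is available
to seed the cells. `wholecellseg` segments whole cells (cytoplasm plus
nucleus) from such images and separates touching cells, for
image-analysis work in cell-culture assays, drug screens and live-cell
imaging where every channel is precious.

The pipeline:

1. **Pixel classification.** A compact asymmetric UNet (encoder widths
   32/64/128/128/256, ~2.4 M parameters, implemented in single-precision
   C++ over BLAS — no GPU required) predicts per-pixel probabilities
   `p_n, p_c, p_b` for nuclei, cytoplasm and background. Training
   minimizes the weighted per-channel root-mean-square deviation
   `w_n RMSD(p_n, l_n) + w_c RMSD(p_c, l_c) + w_b RMSD(p_b, l_b) +
   w RMSD(l_n + l_c + l_b, 1)` on 176×176 tiles whose 160×160 cores
   partition the image.
2. **Seed detection.** Multi-scale Laplacian-of-Gaussian blob enhancement
   of `p_n`, a five-level Otsu threshold selected by a sensitivity
   parameter (default 60 → third threshold), and a shape-based watershed
   (inverse distance transform + extended h-minima, default h = 3 µm)
   that splits touching nuclei into individual seeds.
3. **Cell delineation.** The intensity image is denoised, log-scaled and
   multiplied by `p_c`; the background is the three-level-Otsu threshold
   whose foreground area best matches `n_seeds × expected cell area`; a
   seeded watershed floods each cell from its nucleus seed. One seed, one
   cell.

Quality is measured with an object-level segmentation similarity

```
SM(R,T) = k · mean_i max_j 2|r_i ∩ t_j| / (|r_i| + |t_j|)   (best Dice per reference object)
        + (1−k) · 2|P| / (N + M)                            (fraction of one-to-one matches)
```

with `k = 0.6`, plus pixel-level ROC/AUC and accuracy of the probability
maps. A synthetic-microscopy generator with exact ground truth makes the
whole chain — training, segmentation, evaluation — runnable with no
external data.

## Worked example

```r
library(wholecellseg)
set.seed(1)

# synthetic data with exact ground truth: bright textured cytoplasm,
# near-background nuclei, touching cells, uneven illumination
train <- generate_dataset(30, synth_config(), seed = 1)
test  <- generate_dataset(1,  synth_config(), seed = 2)[[1]]

# preprocess (top-hat illumination correction) and train a short schedule
ds <- lapply(train, function(d)
  list(image = tophat_correct(d$image, 200), labels = d$labels))
model <- train_unet(ds, train_config(epochs = 5, batch_size = 4,
                                     patches_per_epoch = 160, seed = 3))
#> epoch 1/5: mean loss 0.66670
#> epoch 2/5: mean loss 0.28509
#> epoch 3/5: mean loss 0.19071
#> epoch 4/5: mean loss 0.17562
#> epoch 5/5: mean loss 0.15081

seg <- segment_image(test$image, model)
seg
#> <segmentation> 25 cell(s) on a 512 x 512 image

sm_score(test$cells, seg$cells)
#> <sm_report> SM = 0.8455 (k = 0.60)
#>   mean best Dice over 25 reference object(s): 0.7691
#>   one-to-one matches: 24 of (N + M) = 50 -> 0.9600
```

(The numbers are from an actual run; they vary a little with the seed.)
`SM = 0.85` says the held-out segmentation recovers 24 of the 25 cells
one-to-one with a mean per-cell Dice overlap of 0.77 against ground
truth, after roughly ten minutes of CPU training. `cell_table(seg)` returns a per-cell tibble (areas,
centroids, mean intensity, nucleus area); `classification_eval()` scores
the probability maps; `overlay_rgb(seg)` renders a contour overlay.

A command-line tool wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "wholecellseg", package = "wholecellseg"))')
Rscript "$CLI" synth   --out-dir data --n-images 5 --seed 1
Rscript "$CLI" train   --manifest data/manifest.csv --model model.rds --epochs 5
Rscript "$CLI" segment --image data/synth_001.tif --model model.rds --out-dir out --overlay
Rscript "$CLI" evaluate --reference data/synth_001_cells.tif --target out/synth_001_cells.tif --out sm.json
Rscript "$CLI" roceval --prob out/synth_001_prob.tif --mask data/synth_001_nuclei.tif --out roc.json
```

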