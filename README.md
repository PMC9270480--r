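# mammotile

Multi-scale tiled inference and FROC evaluation for lesion detection in
ultra-high-resolution mammograms.

## The problem

Full-field digital mammograms are nominally 3328 × 4096 px at a
50–100 µm pixel pitch, while the cancers that screening exists to catch
can be under 1 cm — often less than 1 % of the image.  A detector with
a fixed receptive field cannot have it all at once: downsampling
destroys the fine detail that makes small masses visible
(**resolution**), full-resolution crops cannot contain a large mass
whole (**scale**), and a small crop carries no surrounding-tissue cues
(**context**).

`mammotile` implements the detector-agnostic inference pipeline that
works around this: rescale the image to an X / 0.5X / 0.25X pyramid,
cut each level into systematic full-coverage strips (1024 px long at
nominal geometry, so the per-scale tile counts are 4 / 2 / 1 and the
single 0.25X strip sees the whole breast), run the detector per strip,
remap every box back into the full-resolution frame
(`c ↦ (c + offset)/s`, exactly invertible), and combine the per-scale
prediction sets with **Weighted Box Fusion**: clusters of overlapping
boxes (IoU > 0.55) are averaged with score weights,

```
fused coordinate = Σᵢ sᵢ·cᵢ / Σᵢ sᵢ ,   fused score = mean(sᵢ) · min(N, T)/T
```

with `N` the cluster size and `T` the number of scales (greedy NMS and
score-floored NMS are also provided).  Evaluation is free-response ROC:
sensitivity against false positives per image (FPI), where a prediction
counts as a detection iff its **box center falls inside the
ground-truth box** — the standard rule in mammography CAD.

Because clinical mammography datasets are private, the package includes
a seeded phantom generator (breast-shaped foreground, parenchymal
texture, raised-cosine masses of given physical diameter via the pixel
spacing, exact tight ground-truth boxes) and a classical
difference-of-Gaussians reference detector whose bounded sigma band
plays the role of a fixed receptive field.  This makes every pipeline
property — coverage, remap exactness, fusion formulas, FROC mechanics,
and the directional resolution/scale/context effects — testable end to
end on a CPU.

## Worked example

```r
library(mammotile)

# a quarter-scale phantom dataset: 4 images, sub-centimetre lesions
base <- phantom_spec(height = 1024, width = 832, pixel_spacing = 280,
                     n_lesions = 3, background_texture_sigma = 2)
ds  <- generate_dataset(4, size_mix = c(4, 5.8, 8), seed = 1, base = base)
cfg <- pipeline_config(tile_len = 256, fpi_list = c(0.15, 0.3))
res <- run_pipeline(ds$images, ds$gt, config = cfg)

res$froc
#> <FROC: 4 image(s), 12 lesion(s), 16 point(s); max sensitivity 1.000 at 0.750 FPI>
sensitivity_at_fpi(res$froc, 0.3)
#> [1] 0.9166667
res$summary$sensitivity_at_fpi
#> $fpi_0.15
#> [1] 0.6666667
#>
#> $fpi_0.3
#> [1] 0.9166667
```

Read: on this 4-image set the pipeline finds 11 of 12 inserted lesions
(sensitivity 0.92) while emitting at most 0.3 false marks per image; at
the stricter 0.15 FPI operating point, 8 of 12; all 12 are found by
0.75 FPI.  Two runs with the same config produce byte-identical
`predictions.csv`/`froc.csv`.

The ablation harnesses reproduce the qualitative phenomena on synthetic
data (`run_resolution_ablation`, `run_scale_ablation`,
`run_context_ablation`, `per_scale_analysis`): e.g. lesions caught
*only* at full resolution average ≈ 5 mm while those caught only at
0.25X average ≈ 30 mm — full resolution is what finds the small masses.

A command-line interface wraps the same machinery:

```sh
Rscript -e 'mammotile::mammotile_main()' simulate --out data --n-images 4 --seed 1
Rscript -e 'mammotile::mammotile_main()' run --in-dir data --gt data/ground_truth.csv --out-dir out
```

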