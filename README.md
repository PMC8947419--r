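# pupavision

Machine-vision sexing of melon fly (*Zeugodacus cucurbitae*) pupae from
daily stereomicroscope images.

Releasing sterile males is a mainstay of melon fly control, and it requires
separating the sexes before release — best done at the pupal stage. Male
pupae develop a comb of **pectinate setae** on the tail backplane about two
days before eclosion: the long setae (0.05–0.18 mm) occur **in males only**,
while short setae (0.02–0.05 mm) occur in both sexes. `pupavision`
implements the full image pipeline that detects this feature and calls each
pupa's sex, plus a seeded synthetic image generator that makes the whole
chain testable without microscope data.

## The pipeline

For each daily image of a single pupa (three-channel TIFF, pixel range
[0, 65520]):

1. normalize the pixel range to [0, 255] (round half up);
2. convert to HSV and take the saturation channel
   S = 255·(max−min)/max, where the colored cuticle contrasts best with
   the gray background;
3. segment: Otsu threshold (256-bin between-class variance) → keep the
   bright side → fill interior holes → open with a Euclidean disk (r = 5 px)
   → keep the largest 8-connected component;
4. pose-normalize: minimum enclosing ellipse of the mask → circumscribed
   rectangle → rotate the image by minus the rectangle angle → crop →
   resize to exactly 2800 × 1300, propagating a per-axis calibration
   µm/px so physical lengths survive the anisotropic resize;
5. tile into a 5 × 5 grid (560 × 260 cells) and track per-cell gray/texture
   features over the 11 days; the tail cell (index 17) is the one whose
   texture changes when setae appear;
6. detect elongated dark stripes in the tail cell and call
   `male_setae_detected` when any stripe is strictly longer than 0.05 mm;
   a pupa is positive if any day is positive;
7. cross-tabulate calls against eclosion outcomes
   (female / male / unfledged) and report group accuracies, excluding
   unfledged pupae from every denominator.

## Worked example

```r
library(pupavision)

# a seeded synthetic cohort: 10 pupae, half male, ~10% never emerge
gen <- generator_config(n_pupae = 10, male_fraction = 0.5,
                        unfledged_fraction = 0.1, seed = 7)
res <- run_synthetic_cohort(gen)
res
#> pupavision run: 10 pupae, 110 images, 0 failures
#> top-ranked grid cell by temporal change: 17
#> Pupal sex identification vs. eclosion outcome
#>      type observed female male unfledged accuracy
#>  no_setae        6      5    0         1      100
#>     setae        4      0    4         0      100
#> Overall accuracy (emerged pupae only): 100.0%

head(res$daily_calls[res$daily_calls$long_stripe_count > 0, ], 4)
#>    pupa_id day_index n_stripes long_stripe_count max_length_mm                call
#> 10       1        10        15                15     0.1594881 male_setae_detected
#> 11       1        11        15                15     0.1597929 male_setae_detected
#> 21       2        10        16                16     0.1759870 male_setae_detected
#> 22       2        11        17                16     0.1762251 male_setae_detected
```

Reading the output: the temporal screen ranks grid cell 17 (tail) as the
cell whose texture changes most over the series; male pupae show 16–20
detected stripes on days 10–11 (two days before eclosion on day 12) with
calibrated lengths up to ~0.18 mm, and the contingency table scores the
calls against the known outcomes. On-disk cohorts work the same way via
`write_cohort()` / `run_pipeline()`, and a thin CLI wrapper lives at
`inst/cli/pupavision.R` (`simulate`, `run`, `screen`, `evaluate`).

## Package layout

- `R/` — generator (`synthetic.R`), preprocessing, segmentation, geometry,
  grid features, setae classification, evaluation, pipeline orchestration;
- `src/` — small Rcpp kernels for the per-pixel hot loops;
- `vignettes/pupal-sexing-pipeline.Rmd` — the model, conventions, design
  decisions and limitations;
- `tests/testthat/` — unit, property and acceptance tests with brute-force
  oracles.
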