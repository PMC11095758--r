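---
title: "Whole-core HER2 quantification with phosphor-integrated dots: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-core HER2 quantification with phosphor-integrated dots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pidquant)
```

## The problem

HER2 immunohistochemistry (IHC) is scored visually by pathologists into four
ordinal categories (0, 1+, 2+, 3+) from chromogenic DAB staining. That works
well at the top of the scale, but antibody–drug conjugates have made the
*low* end clinically relevant, and visual DAB scoring is poorly calibrated
there: faint membrane staining near the detection limit is inconsistently
called 0 or 1+, and a "HER2 ultra-low" stratum inside category 0 is invisible
to the eye.

`pidquant` implements a quantitative alternative built on two ingredients:

1. **Phosphor-integrated dots (PIDs)** — bright ~130 nm fluorescent
   nanoparticles that label HER2 so that each bound particle appears as one
   sub-resolution spot, giving signal proportional to antigen over a wide
   dynamic range; and
2. **whole-slide imaging (WSI)** — so the statistic integrates over the whole
   invasive-cancer area of a tissue-microarray (TMA) core rather than a few
   hand-picked fields of view.

## The core statistic: the PID value

For one core with fluorescence raster $I$ (arbitrary units, pixel size $p$
µm) and a pathologist-drawn binary invasive-cancer mask $M$:

1. The invasive region is divided into square tiles of edge 12 µm
   ($t = \mathrm{round}(12/p)$ pixels), on a regular grid anchored at the
   top-left of the mask's bounding box. A tile is kept if at least half of
   its pixels lie inside $M$ (`inclusion_fraction = 0.5`).
2. Each tile's value is $v_j = \sum_{(r,c) \in \text{tile}_j \cap M} I_{rc}$
   — masked pixels only, so signal outside the annotation never leaks in.
3. With $n$ tiles and $k = \lceil 0.10\,n \rceil$, the **PID value** is the
   mean of the $k$ largest tile integrals.

The top-10% mean mirrors the clinical convention that the IHC category is
driven by staining in more than 10% of tumor cells: it keys the score to the
brightest tenth of the invasive area while averaging out single-tile
outliers. `top_fraction_mean()` floors $k$ at 1 so cores with very small
invasive areas still get a defined value.

Scores are then assigned by thresholding: the cut point for class $k$ is the
*minimum* PID value among analyzable cores whose consensus DAB score is $k$
(`derive_cut_points()`), and classification uses closed lower bounds
(`classify_pid()`) — closed because the cuts are themselves class minima, so
the defining core must classify into its own class. Cut points must come out
strictly increasing; a violation is an error, never silently reordered.
Previously published thresholds can be supplied instead via
`run_config(cut_point_mode = "fixed", ...)`.

A staining run with the primary antibody omitted sets the detection floor:
`negative_control_mean()` averages the control cores' PID values, and any
DAB-0 core strictly above that floor is flagged by `flag_ultra_low()` as
carrying real signal despite its null visual score — the candidate
"ultra-low" stratum.

## Concordance reporting

* `fit_score_regression()` — ordinary least squares of PID value on the DAB
  score encoded 0..3. The linear-on-ordinals form is the minimal model of a
  fitted value–score relationship; the choice is recorded in the output
  (`model = "ols_on_ordinal"`) so alternatives can be compared.
* `contingency()` — 4×4 DAB × PID counts with PV% defined as *row*
  (DAB-class-wise) percentages.
* `compare_groups()` — a two-sided F test on the variance ratio (larger
  variance in the numerator) gates the two-sample comparison: Student's
  pooled t when the F-test p ≥ 0.05, Welch's t otherwise; both two-tailed,
  significance at 0.05, with an additional strict flag at p < 0.001. The
  suite checks both branches against closed-form textbook formulas.
  `adjacent_class_comparisons()` applies this to each neighbouring class
  pair rather than guessing a single contrast.
* `reproducibility()` — per-run regression $R^2$ plus pairwise correlation
  of PID values across replicate staining runs of the same cohort.

## The synthetic cohort generator

No slide images ship with the package; every stage is exercised against a
seeded generator (`simulate_core()`, `simulate_cohort()`) that emulates the
reference cohort design: 104 cases × duplicate cores on a 13×16
letter/number grid, 8 negative controls (grid row Z), and 38 annotated
exclusions in five categories (`tma208_exclusion_plan()`).

The physical model, per core:

* the invasive annotation is a connected disc-shaped blob covering
  `mask_coverage` (default 0.6) of the core disc, placed at a random offset
  but kept a few point-spread widths inside the core rim;
* each bound nanoparticle is one point source; the number of spots is
  Poisson with mean `rate × masked area / 100 µm²`, positions uniform over
  the mask;
* a spot renders as an isotropic 2-D Gaussian of standard deviation
  `psf_sigma_um = 0.3` µm — the particles are far below pixel resolution at
  20× (`pixel_size_um = 0.46` µm), so the imaging point-spread function,
  not the 130 nm particle, sets the spot width. Peak amplitudes are
  Gaussian (mean 100, sd 10, clipped at 0). Rendering uses a ±5σ window,
  truncating < 4 × 10⁻⁶ of each spot's mass;
* autofluorescence background is additive i.i.d. Gaussian noise
  (mean 4, sd 2), clipped at zero per pixel.

Membrane geometry is deliberately **not** simulated: the whole-core
statistic integrates intensity per tile and never uses membrane
completeness, so cell-boundary structure would add cost without exercising
any code path.

### Intensity calibration (done analytically, once)

The assay reports PID values on a 0–52 × 10³ scale. The defaults were chosen
by forward calculation, not by fitting to any test output. With 0.46 µm
pixels a 12 µm tile is 26 px (676 px, 143.0 µm² realized); so:

* background floor per tile ≈ 676 × 4 ≈ 2.7 × 10³;
* one spot integrates to ≈ 100 × 2π(0.3/0.46)² ≈ 267 units;
* a tile at spot rate $\rho$ (per 100 µm²) holds Poisson($\lambda$) spots
  with $\lambda = 1.43\rho$, and the mean of the top decile of a Poisson
  count is ≈ $\lambda + 1.755\sqrt{\lambda}$ (normal approximation,
  $\phi(z_{0.9})/0.1 = 1.755$);

hence a core's PID value is approximately
$2704 + 267(\lambda + 1.755\sqrt{\lambda})$. Inverting this for the four
class ranges 0–4.3, 4.3–13.1, 13.1–32.2 and 32.2–52 (× 10³) gives the
default per-class rate bands (per 100 µm²):

| class | rate band | resulting PID range (×10³) |
|-------|-----------|----------------------------|
| 0     | 0 – 1.9   | ≈ 2.8 – 4.2 |
| 1+    | 2.2 – 20.3| ≈ 4.4 – 13.0 |
| 2+    | 20.7 – 64.8| ≈ 13.2 – 32.0 |
| 3+    | 65.6 – 113.3| ≈ 32.3 – 52 |

In the default *band* mode each **case** draws its expression level
uniformly from its class band (duplicate cores share the draw, as duplicate
cores share tissue), so PID values form a continuum within each class and
the derived class minima land near the 4.3/13.1/32.2 × 10³ thresholds.
Setting `spot_rate_band_per_class = NULL` switches to homogeneous
*separated* mode — every core of a class uses the single
`spot_rate_per_class` value (defaults 1/11/43/90) — which yields
non-overlapping class supports; the parameter-recovery checks (derive cuts,
reclassify, demand 100% agreement with the generated truth) run in this
mode, because with overlapping supports or discordant labels perfect
recovery is not a property the statistic claims.

Negative controls run at `nc_rate_scale = 0.25` of the class-0 point rate,
which puts the control mean at ≈ 3.1–3.2 × 10³ — a nonzero floor *below*
typical class-0 cores, reproducing the premise that true DAB-0 tissue still
out-glows a no-primary-antibody control.

### Pathologist readings

In band mode, each of the two simulated pathologists categorizes a
log-normally perturbed copy of the case's expression (`reader_sd = 0.1`),
so disagreements concentrate near class boundaries, as they do in visual
scoring; the default consensus policy takes the higher of the two readings
and counts discordances (no adjudication rule is standard, and the higher
read is the conservative choice for a detection-oriented assay). In
separated mode a flat `disagree_prob` (default 0.05) shifts the second
reading by one class.

### What the generator does *not* capture

* **A true zero floor.** Real cohorts contain class-0 cores with PID values
  near 0; the simulator's additive background floor (~2.8 × 10³) keeps every
  simulated core above it. With the control floor at ~3.1 × 10³ this means
  *most* simulated DAB-0 cores flag as ultra-low, a higher fraction than the
  ~40% seen in tissue. The flag logic itself is exercised against
  constructed records in the tests.
* **Reader/assay scale mismatch.** Simulated readers perceive the same
  expression scale the fluorescence measures, so the DAB × PID contingency
  comes out essentially diagonal; in tissue, visual DAB scoring undercalls
  low expression, splitting the DAB-0 row. Passing tests therefore
  demonstrate correctness of the statistics, not the clinical discordance
  pattern.
* Tissue texture, necrosis, scanner artifacts, or membrane morphology.

## Numerical and interface choices

* **Grid anchor.** Results are deterministic given inputs because the tile
  grid anchors at the mask bounding box. The statistic is phase-sensitive
  by at most one tile; the suite asserts exact invariance under
  whole-tile translations rather than hiding the effect.
* **Tile size rounding.** 12 µm is rarely an integer pixel multiple;
  `tile_size_px = round(12/p)` with the realized physical edge reported as
  `actual_tile_um`.
* **No background subtraction** anywhere: the negative-control floor is the
  interpretive baseline, matching the assay's design.
* **Degenerate inputs** fail loudly: empty masks (no-invasive-region error),
  empty value vectors, missing classes when deriving cuts, all-identical
  scores in the regression (undefined R², not 0), fewer than 2 observations
  per comparison group.
* **Serialization.** DAB categories are written exactly as `0,1+,2+,3+`;
  result rows sort in TMA-map order; images export as 16-bit grayscale TIFF
  (rounded, saturating at 65535 with a warning); missing table cells stay
  missing, never zero.

## Problem sizes

Cohort-scale simulations in the tests, analysis scripts and
`scripts/acceptance.R` use spatially scaled-down cores
(`core_diameter_um = 120` at the native 0.46 µm sampling, ~47 tiles per
core) — all per-area physics (spot rates per 100 µm², the 12 µm tile, the
point-spread width) are identical to the full-size default of 1200 µm; only
the number of tiles entering the top-decile mean shrinks. Unit tests use
60 µm cores. A full 208-core replica at 120 µm simulates and scores in
seconds.

## Worked example

```{r example, eval = FALSE}
params <- sim_params(core_diameter_um = 120)
res <- run_pipeline_sim(params, tma208_class_counts(),
                        n_negative_controls = 8,
                        exclusion_plan = tma208_exclusion_plan(), seed = 1,
                        config = run_config(pixel_size_um = params$pixel_size_um))
res$exclusion_summary   # 208 cores, 38 (18%) excluded, 170 analyzable
res$cuts                # derived per-class minima
res$ncs$mean_value      # negative-control floor
res$report$regression   # R^2 of PID value on the ordinal DAB score
res$report$contingency$table
```

## Known limitations

Beyond the generator caveats above: the pipeline consumes exported
grayscale TIFF (no proprietary scanner formats, no pyramid streaming); the
invasive mask is an input, not a segmentation this package performs; and
cut points derived from a cohort are tentative, data-derived thresholds —
clinical use would require anchoring them to treatment outcomes.
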