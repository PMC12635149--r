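# antmimic

Quantifying Batesian color and size mimicry in ants from RGB measurements.

## The problem

Some palatable ants reduce predation by resembling aggressive, chemically
defended species. A classic Mediterranean case is *Camponotus lateralis*,
whose minor workers travel on the foraging trails of *Crematogaster*
species and — region by region — resemble whichever *Crematogaster* model
occurs locally: *Cr. scutellaris* (blackish with a reddish head) in the
west, *Cr. schmidti* (reddish head, mesosoma and petiole) in the central
Balkans, and *Cr. ionia* s.l. (homogeneously brownish-black) in the
southeast. Testing such regional mimicry quantitatively requires more than
eyeballing specimens: it needs a pipeline from standardized color
measurements to statistics that separate "mimics resemble their local
model" from "mimics just vary geographically".

`antmimic` implements that pipeline for hierarchical specimen tables — one
row per worker with mean R, G, B intensities of six body parts (head,
pronotum, mesonotum, propodeum, petiole, gaster), cephalic length and width
(µm), nested in colonies (nests) within collection sites, with exactly one
model species per site. Because measurement campaigns of this kind are
expensive, the package ships a synthetic-data generator that emulates the
full study design (18 sites, site/nest/individual variance layers, a
tunable mimicry-accuracy dial), so every stage is testable end to end.

## What it computes

All color statistics run on square-root-transformed channels (raw RGB is
right-skewed). For a specimen table the package provides:

1. **Trait comparisons.** Per body part, the three sqrt-channels are
   reduced to PC1 (covariance PCA; sign fixed so larger = lighter/redder).
   Each PC1 — and cephalic size CS = (CL + CW)/2 — is compared between
   species (models) or syntopy categories (mimics) with the Gaussian mixed
   model

   `y = μ + β_group + u_site + v_nest(site) + ε` (REML, via lme4),

   followed by Wald pairwise contrasts corrected by the Holm step-down
   method at a global α = 0.05.

2. **Syntopy vs allotopy.** Nest means are reduced to the leading principal
   components explaining ≥ 80% of variance. For each site, the mean
   Euclidean distance between local mimic nests and local model nests
   (syntopic) is compared with the unweighted mean of the 17 per-foreign-site
   mean distances (allotopic); a one-sided paired t-test asks whether
   syntopic distances are smaller. The same aggregation runs on |ΔCS| for
   size mimicry.

3. **Classification.** A stepwise linear discriminant analysis (Wilks'
   lambda minimization, F-to-enter 3.84 / F-to-remove 2.71, equal priors)
   is calibrated on the model species only, evaluated by leave-one-out
   cross-validation (variable set held fixed), and the mimic individuals
   are then allocated as wild cards; "correct" means allocation to the
   syntopic model species.

4. **Reporting.** Per-site mean-color reconstructions (raw-RGB scale; the
   mesosoma card is the unweighted mean of its three regions) as CSV and a
   stylized SVG strip, group summary tables (means ± sample SD), and
   plot-ready PCA scatter tables with 95% confidence ellipses
   (χ²₂-quantile Gaussian ellipses).

## Worked example

```r
library(antmimic)

gen <- generate_dataset(synthetic_config(seed = 1))  # default study design
nrow(gen$specimens)
#> [1] 1476

mda <- mimicry_distance_analysis(gen$specimens)
round(mda$color$grand, 2)
#>  syntopic_mean    syntopic_sd allotopic_mean   allotopic_sd
#>           0.94           0.28           6.42           0.87
signif(mda$color$test$p, 3)
#> [1] 5.91e-15
```

With the generator's default mimicry accuracy (λ = 0.9), mimic nests sit
far closer in color space to their local models (mean distance 0.94) than
to models from the other 17 sites (6.42), and the one-sided paired t-test
over the 18 sites is decisive. Size mimicry (λ_size = 0.5) is a weaker
signal, as in real systems:

```r
round(mda$size$grand, 1)
#>  syntopic_mean    syntopic_sd allotopic_mean   allotopic_sd
#>           50.1           21.1           57.3           11.2
```

The discriminant stage separates the three generated model species
perfectly and sends every wild-card mimic home:

```r
da <- discriminant_analysis(gen$specimens)
round(da$loo$accuracy, 1)
#> scutellaris    schmidti       ionia
#>         100         100         100
round(da$allocation$correct, 1)
#>       ionia-syntopic    schmidti-syntopic scutellaris-syntopic
#>                  100                  100                  100
```

(Real measurement data are noisier than the generator's archetypes; on the
published system the analogous numbers are in the 66–98% range.)

The same stages are scriptable from a shell:

```sh
Rscript inst/cli/antmimic.R all --seed 1 --out runs/demo
```

writes the specimen table, latent truth, contrast tables, distance tables,
confusion/allocation tables, summary tables, SVG color cards and a
manifest under `runs/demo/`.

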