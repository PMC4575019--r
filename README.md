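# herbphylo

Tools for asking how a host plant's **phylogenetic isolation** (PI) and
**origin** (native vs. exotic, PO) shape the insect herbivore fauna it
supports, across many local plant–herbivore assemblages. The package is
aimed at community ecologists working with compiled interaction lists
(plants × herbivores per site), a dated reference phylogeny, and plant
origin / herbivore guild metadata.

## What it computes

For each plant *i* in a local assemblage:

- **Phylogenetic isolation** `PI_i = mean_j d(i, j)` over all co-occurring
  *native* plants *j* (self excluded), with `d` the patristic distance in
  Myr on an ultrametric phylogeny. Species missing from the reference tree
  are grafted as polytomies at the MRCA of their congeneric (else
  confamilial) tips, with the new pendant branch equal to the attachment
  node's age so the tree stays ultrametric.
- **Herbivore richness** (number of associated herbivore species) and the
  **mean Jaccard** `(b+c)/(a+b+c)` and **mean Simpson**
  `min(b,c)/(min(b,c)+a)` compositional dissimilarity against the
  co-occurring natives, from shared (`a`) and exclusive (`b`, `c`)
  herbivore counts.
- **Mean specialization**: the unweighted mean of Blüthgen's `d'` over the
  plant's herbivores, where `d' = (d_raw − d_min)/(d_max − d_min)` is the
  standardized Kullback–Leibler divergence between a herbivore's realized
  host use and host availability (`d_max = ln(m/A)`; `d_min` by exact
  integer enumeration on small problems, a proportional-fill + local-swap
  heuristic otherwise).

These per-plant records feed four mixed models with fixed effects
`PI + PO (+ PI×PO)` and a random intercept per assemblage: richness
(Poisson, log link, offset `log(assemblage total richness)`), the two
dissimilarities (binomial, logit link, weights = number of comparators),
and mean `d'` (Gaussian). A 1-df likelihood-ratio test decides whether the
interaction is kept; singular fits (random variance < 1e-8) are refitted
as fixed-effects GLMs with McFadden's pseudo-R²; otherwise Nakagawa
marginal/conditional R² are reported. Assemblages are analysed at three
guild scopes: all herbivores, endophages only, exophages only.

A seeded synthetic-data generator (Yule tree + distance-decay host use,
`P(attack) = p0 · exp(−λ_guild · d) · exp(u_site)`) produces complete
datasets with controllable phylogenetic signal so the whole pipeline is
testable without any downloads.

## Worked example

```r
library(herbphylo)

cfg <- simulation_config(n_assemblages = 20, plants_per_assemblage = 30,
                         regional_pool_size = 200, seed = 71)
ds  <- generate_dataset(cfg)
met <- do.call(rbind, lapply(ds$assemblages, build_plant_metrics,
                             tt = ds$tree))
res <- lrt_interaction(met, model_spec("richness"))
res$lrt
#>   chi_squared df   p_value keep_interaction
#> 1   0.5716442  1 0.4496063            FALSE
res$fit
#> <herb_fit> richness ~ PI + PO, poisson_log
#>   n = 600 plants in 20 assemblages; RE variance = 0.1929
#>          term estimate      se statistic    p_value estimate_raw
#> 1 (Intercept)  -2.2065 0.10395   -21.225 5.564e-100     -2.20646
#> 2          PI  -0.1028 0.01592    -6.460  1.047e-10     -0.01883
#> 3          PO   0.1704 0.03597     4.736  2.184e-06      0.17036
r2_nakagawa(res$fit)
#>    marginal conditional
#>   0.0396425   0.5233533
```

The interaction is dropped (LRT p = 0.45), and the reduced model recovers
the distance-decay signal the generator planted: herbivore richness
declines with phylogenetic isolation (PI z = −6.46 on the z-scored scale;
`estimate_raw` is per Myr of mean patristic distance). The positive PO
term reflects that, in this synthetic world, herbivores originate on
native hosts, so natives carry somewhat richer faunas.
`run_full_analysis()` (or the `run` subcommand of the CLI) repeats this
for all four responses and all three guild scopes and adds the R²
summaries.

Command line:

```sh
Rscript -e 'herbphylo::run_cli()' simulate --out data --seed 7
Rscript -e 'herbphylo::run_cli()' run --dataset data --out results
```

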