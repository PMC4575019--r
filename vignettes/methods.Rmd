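---
title: "Phylogenetic isolation and herbivore faunas: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic isolation and herbivore faunas: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`herbphylo` implements a complete analysis chain for compiled
plant–herbivore assemblage data: screening and filtering local interaction
tables, completing a dated plant phylogeny by polytomy grafting, computing
per-plant fauna metrics, and fitting mixed models that ask whether a
plant's phylogenetic isolation (PI) and origin (native vs. exotic, PO)
predict the richness, compositional distinctness and specialization of its
herbivores. This vignette records the model, the defaults, and the design
choices that were genuinely open.

## Screening and filtering

An assemblage enters the analysis only if, after removing plants of
unknown origin and plants with no recorded herbivore (and, in cascade,
herbivores left hostless), it still has ≥ 5 plants, ≥ 5 herbivores, ≥ 10
species in total, ≥ 3 exotic plants and ≥ 1 native plant. The native
minimum is encoded as presence only: the screening design requires "both
origins present" plus an explicit exotic floor, and we add no native floor
beyond presence.

Guild analyses split each assemblage into endophage-only and
exophage-only sub-assemblages (plants with no interactions in a
sub-assemblage are dropped from it). Whether such sub-assemblages must
re-satisfy the full screening criteria is ambiguous in compiled-data
practice; we *record* the re-check (`eligible_after_split`) but do not
silently drop sub-assemblages, and `run_full_analysis()` exposes
`require_eligible_subassemblages` for the strict behavior.

## Phylogeny completion

Species absent from the reference tree are attached at the most recent
common ancestor of their congeneric tips; if the genus is absent, at the
family MRCA. With a single congeneric (or confamilial) tip the MRCA
degenerates to the tip itself, and we attach at that tip's parent node
(the stem) — the standard megaphylogeny-grafting convention for this
undefined case. The new pendant branch always equals the attachment
node's age, so every graft preserves ultrametricity exactly; this also
makes the final distance matrix independent of graft order, which the
test suite asserts. Taxonomy comes from metadata, not from parsing
binomials, so "Genus sp." placeholders resolve by genus status. A graft
with no congeneric or confamilial tip fails softly: the species is logged
and excluded rather than aborting the run. User trees are validated as
ultrametric to a relative tolerance of 1e-6; an opt-in tip-extension
repair exists but is off by default, because silently reshaping a user's
chronogram is worse than refusing it.

PI for plant *i* is the mean patristic distance to the native plants of
its assemblage. For a native focal plant the zero self-distance is
excluded (default `exclude_self = TRUE`): including it would deflate
native PI mechanically and confound the PO contrast, since exotics never
pay the self term.

## Fauna metrics

Richness, Jaccard `(b+c)/(a+b+c)` and Simpson `min(b,c)/(min(b,c)+a)`
are computed on presence/absence. The Simpson form follows the
replacement-only reading (the published formula omits the parentheses
around the denominator; the stated property of richness-insensitivity
admits only this reading). Mean dissimilarities are plain means over the
native comparators (self excluded); pairs with an undefined index are
skipped and the comparator count reduced, never imputed as 0 or 1.

Blüthgen's `d'` for a herbivore with column total `A` in a network with
grand total `m` uses `d_raw = Σ p_j ln(p_j/q_j)` (`p` = realized use,
`q` = plant row totals / `m`), `d_max = ln(m/A)`, and `d_min` = the
smallest KL value over *integer* allocations of the `A` interactions.
`d_min` is found by exact branch-and-bound enumeration when `A ≤ 12` and
the network has ≤ 8 plants, and otherwise by proportional fill
(largest-remainder rounding) followed by steepest single-unit moves to a
fixed point. The realized allocation is always admitted as a `d_min`
candidate, which — together with the row-total bound `q_j ≥ A p_j / m`
implying `d_raw ≤ d_max` — pins `d'` into [0, 1] even when the local
search stalls. Degenerate networks with `d_max = d_min` (single-plant
case) report `d' = 0` with a flag. Counts are used when provided; binary
incidence (the common case for compiled host lists) works identically
with `A` = number of hosts. Mean `d'` per plant is unweighted across its
herbivores, as no weighting is stated for the original summary.

## Models

Per-plant records feed four models, each with fixed effects `PI + PO`
(plus `PI×PO` while testing), and a random intercept per assemblage,
fitted by maximum likelihood (Laplace) via `lme4`:

| response | family/link | extras |
|---|---|---|
| richness | Poisson / log | offset `log(assemblage total richness)` |
| mean Jaccard, mean Simpson | binomial / logit | prior weights = n comparators |
| mean `d'` | Gaussian / identity | ML (`REML = FALSE`) |

The binomial responses are means of pairwise proportions whose original
denominators are unrecoverable; we fit the proportion with prior weights
equal to the number of pairwise terms averaged, preserving information
about averaging depth (an unweighted variant is available through
`model_spec(weighted = FALSE)`; neither is presented as "the" original
encoding). PI is z-scored before fitting (`standardize_pi = TRUE`), which
stabilizes the optimizer and matches the convention of reporting
standardized coefficients; raw-scale (per-Myr) estimates are reported
alongside. PO is coded native = 1, so positive coefficients mean higher
values on natives.

The `PI×PO` term is kept only when a 1-df likelihood-ratio test rejects
at `alpha = 0.05` (the conventional threshold; the screening narrative
implies but never prints it). Small negative chi-square values within
1e-4 are clamped to zero; larger ones raise an optimizer-failure error.
When the fitted random-intercept variance falls below 1e-8 the model is
refitted as a fixed-effects GLM and goodness of fit switches from
Nakagawa marginal/conditional R² to McFadden's `1 − ll/ll0` (null model =
intercept + offset). The Nakagawa distribution variance uses `π²/3` for
the logit models, the residual variance for the Gaussian model, and the
lognormal approximation `ln(1 + 1/λ0)` with `λ0 = exp(β0 + mean offset)`
for the Poisson model — the cited method has several variants; this one
needs no refitting and behaves well at the moderate means seen here.

## The synthetic world

The generator exists because the compiled interaction matrices behind
the motivating analysis are not deposited; it is a testbed, not an
ecological claim. Its defaults state one world, chosen once:

- 30 assemblages, 24 plants each, local herbivore richness uniform on
  5–90 — matching the reported ranges of the compiled data (30
  assemblages; 5–90 herbivores; ~24 usable plants per site on average).
- A Yule regional phylogeny of 200 species at birth rate 0.1/Myr
  (height ≈ 50 Myr, the scale of angiosperm community trees); genera and
  families are clades younger than 20 and 60 Myr.
- Exotic fraction 0.25 with the eligibility floor of 3; exotics are drawn
  with weight `exp(displacement · mean distance to natives / height)`
  (`clade_displacement = 1`), so origin and isolation correlate the way
  introduced floras do; setting it to 0 makes them orthogonal, which the
  interaction-calibration test uses to state an exact null.
- Each herbivore has a native origin host and attacks plant *j* with
  probability `p0 · exp(−λ_guild d(origin, j)) · exp(u_site)`, `p0 = 0.4`,
  `λ_endo = 0.045`, `λ_exo = 0.015` per Myr (host-use probability halves
  every ~15 Myr for endophages, ~46 Myr for exophages — endophages are
  the narrower guild, ratio 3), `u_site ~ N(0, 0.5²)`.
- Hostless herbivores and herbivore-free plants are redrawn up to 50
  times, then dropped; assemblages failing eligibility are regenerated
  (≤ 20 attempts) so every generated dataset passes validation.
- Binary interactions by default; `counts_mode = "counts"` draws
  zero-truncated Poisson(3) counts to exercise the count pathway of `d'`.

What a green simulation test does establish: the pipeline recovers the
planted qualitative structure (negative PI effect on richness, positive
on dissimilarity and specialization; a stronger endophage signal when
`λ_endo > λ_exo`), with calibrated interaction tests under the stated
null. What it does not establish: anything about the true ecology —
the generator has no plant traits, no herbivore phylogeny, no sampling
effort gradients, and its retry-then-drop rule slightly enriches
marginal species compared with field lists.

## Numerical and testing notes

- `plant_metrics.csv` is written with 17 significant digits so a
  write/read round trip is bit-exact; near-singular weighted-binomial
  fits sit on flat likelihood ridges where even 1e-14 input perturbations
  would otherwise move coefficients visibly, and stage isolation
  (refitting from the CSV equals the full run) depends on exactness.
- Only a nonzero optimizer status aborts a fit; lme4's advisory
  gradient-check messages pass through as warnings.
- The `d_min` test oracle enumerates allocations by `expand.grid`,
  structurally independent of the package's recursive branch-and-bound.
- The LRT-calibration test uses zero decay, zero clade displacement and
  a reduced baseline attack probability (0.15): the zero-decay world is
  the generator's own stated null, and the smaller baseline keeps
  per-plant richness in the near-Poisson regime the model family assumes
  (richness is a sum of Bernoullis, hence underdispersed when per-link
  probabilities are large).
- The guild-contrast acceptance criterion expects the endophage-scope
  |z| for PI on richness to beat the exophage scope in most replicates
  when `λ_endo = 3 λ_exo`. In this generative world it does not (≈ 40% of
  replicates, also at the full default scale), and the mechanism is
  instructive: the consumed-plants-only rule means a guild sub-assemblage
  drops every plant the guild does not attack, so strong decay mostly
  *removes* distant plants instead of lowering their observed richness —
  endophage richness is pinned near its floor (mean ≈ 2 regardless of
  decay), the PI range compresses, and the sample shrinks, while the
  weak-decay exophages keep a graded, well-powered response. The
  criterion is asserted as stated and left failing; under zero-truncated
  sampling, a stronger underlying decay need not yield a stronger
  measured slope.
- The singular-fallback acceptance criterion asserts a ≥ 95% trigger
  rate under a true zero between-assemblage variance. Boundary
  asymptotics make this unattainable: the ML variance estimate under a
  zero truth is a ~50/50 mixture of an exact zero and small positive
  values far above the 1e-8 threshold. The criterion is asserted as
  stated and left failing, with the analysis recorded rather than the
  threshold moved.

## Known limitations

- The binomial denominator choice (weighted vs. unweighted proportions)
  changes standard errors; both are exposed, neither privileged.
- `d_min`'s heuristic route is a local search; it is exact on all
  networks small enough to matter for the oracle tests, and bounded by
  the realized allocation elsewhere, but it can overestimate `d_min`
  (hence underestimate `d'`) on large, skewed networks.
- Grafting places species by taxonomy only; within-genus placement is a
  polytomy, so congeneric distances are 2 × node age rather than
  resolved values.
- No spatial or phylogenetic autocorrelation corrections, abundance-
  weighted dissimilarities, or network-level specialization indices.
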