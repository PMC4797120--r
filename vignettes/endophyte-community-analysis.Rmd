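---
title: "Analysing culturable endophyte colonization surveys with mycodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing culturable endophyte colonization surveys with mycodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycodiv)
library(dplyr)
```

## The data and the problem

Culturable-endophyte surveys cut sterilized plant tissue into small segments,
incubate them, and record which fungal taxa emerge. The primary measurement is
the **colonization frequency** (CF): for a given taxon and sampling cell, the
percentage of incubated segments from which that taxon was cultured,

$$\mathrm{CF} = \frac{\text{segments colonized by the taxon}}{\text{segments incubated}} \times 100 .$$

mycodiv works with surveys laid out as species-by-cell CF matrices over a
fully crossed factorial design: here 3 seasons x 6 sites x 3 tissues (leaf,
stem, petiole) = 54 cells, sampled in triplicate. The package ships one such
survey of the tree *Eugenia jambolana* (24 fungal species) as plain CSV
fixtures, together with its printed diversity, ANOVA, site-similarity and
antibacterial-screening summary tables.

The questions the toolkit answers are the standard community-ecology ones:
how diverse is the community in each season, site and tissue; how similar are
sites in species composition; and do season, site, tissue or their
interactions significantly affect colonization.

```{r read}
cf <- load_survey_cf()
cf
```

## From CF percentages to abundance vectors

Diversity indices need integer isolate counts. CF values sit on a grain of
$100/n$ for $n$ incubated segments per cell; with the survey's design (45
segments per replicate, triplicates, so 135 per cell) the count is recovered
as `round(cf * 135 / 100)`. Entries that do not back-convert to within 0.01
percentage points are flagged: in the shipped tables most one-decimal values
are printed *truncations* of the grain (1.48 prints as 1.4), so flags mark
printing precision loss, not data errors.

```{r counts}
counts <- cf_to_counts(cf)
summarise(counts, isolates = sum(count), flagged = mean(flagged))
```

`marginalize()` collapses counts to one abundance vector per season, site or
tissue; the grand isolate total is conserved whichever factor is chosen.

## The diversity index suite

For an abundance vector with $S$ isolates over $N_p$ species with proportions
$p_i$:

* richness $N_p$ and Gleason's index $G = (N_p - 1)/\ln S$, a richness
  measure only weakly dependent on sampling effort;
* relative Gleason $G_R = (N_p - 1)/S$, richness per isolate;
* Simpson dominance $D = \sum p_i^2$ and its complement $1 - D$;
* Shannon–Wiener entropy $H' = -\sum p_i \ln p_i$ (natural log, nats);
* Pielou evenness $E = H'/\ln N_p$.

```{r diversity}
diversity_table(cf, "season")
```

Numerical conventions worth stating explicitly:

* **Log base.** $H'$ uses natural logarithms. This is the convention under
  which the shipped survey's printed evenness rows (summer, petiole) are
  internally consistent with $E = H'/\ln N_p$; a bits-based $H'$ is not.
* **Gleason variant.** $G = (N_p-1)/\ln S$ reproduces four of the printed
  rows exactly at the printed precision; the variants $N_p/\ln S$ and
  $\log_{10}$-based forms reproduce none, which is why this form is fixed.
* **Degenerate vectors.** A single-species community has undefined evenness;
  `diversity_profile()` reports $E = 1$ (a one-species community is trivially
  even) with a warning rather than failing. Empty vectors are an error.
* **Comparisons to printed values** are made to one unit in the last printed
  digit, because the source tables demonstrably mix rounding and truncation
  (e.g. $21/\ln 320 = 3.6406$ prints as 3.640 while $23/\ln 272 = 4.1029$
  prints as 4.103).

## Site similarity

Between-site similarity uses the presence/absence Jaccard coefficient in
percent, $J = 100\,|A \cap B|/|A \cup B|$, on per-site species sets pooled
over seasons and tissues (presence means any CF > 0). Two empty sets are
defined as identical ($J = 100$), keeping the coefficient reflexive. Values
are rounded to whole percent, the grain of the printed matrix.

```{r jaccard}
cf |> presence_absence("site") |> pairwise_jaccard()
```

## Balanced three-way ANOVA

`anova_three_way()` decomposes the per-replicate isolate count over season,
site, tissue and all their interactions. It is written from sums-of-squares
first principles on cell and marginal means — for factor $A$ with $a$ levels,

$$SS_A = bcr \sum_a (\bar y_{a\cdot\cdot} - \bar y)^2,$$

two-way terms from two-factor cell means minus main effects, the three-way
term from full cell means minus all lower-order terms, and error from
within-cell deviations. In a balanced design this is exact and equal to Type
I/II/III regression sums of squares, which is how the test suite
cross-checks it against an independent `lm()`-based oracle. Unbalanced input
is rejected with the offending cell named — the method is only valid as
stated for equal replication, and silently approximating would change the
inference. One replicate per cell is likewise rejected (no within-cell error
term). A constant response is reported as $F = 0$, $p = 1$ for every source.

p-values are the upper tail of the F distribution at the effect and error
degrees of freedom, i.e. the regularized incomplete beta ratio. The response
column is caller-supplied: the survey analysed isolate counts per replicate
sample, but any per-replicate measurement works. No transform is applied by
default (`transform = "none"`); `sqrt` and `log1p` are available because
counts are often variance-stabilized before ANOVA, and the original analysis
does not state any transform. No multiplicity correction is applied across
the seven sources, matching standard practice for a single factorial table.

```{r anova}
set.seed(7)
sim <- simulate_isolations(
  community_model(tissue_effects = c(leaf = 3, stem = 1, petiole = 1)),
  seed = 7)
fit <- anova_three_way(sim$replicates)
fit
glance(fit)
```

## The synthetic survey generator

`community_model()` + `simulate_isolations()` generate segment-level
colonization data with the survey's factorial structure. Species base
probabilities follow a geometric ranked-abundance series
$p_i = \texttt{base\_rate} \cdot k^{\,i-1}$ — the simplest ranked-abundance
model consistent with a community of a few dominant core species plus a tail
of rare ones. Factor effects act multiplicatively on the colonization
probability, so cell mean counts (what the ANOVA sees) are controlled
directly; probabilities are clamped to $[0,1]$ and clamping events are
counted and reported. Occupancy draws are independent Bernoulli per
(segment, species), aggregated binomially.

Defaults are the study conditions: 24 species, 3 x 6 x 3 design, 45 segments
per replicate, triplicates (135 segments per cell), $k = 0.75$, and
`base_rate = 0.065` calibrated once so a null model yields on the order of
1.9e3 isolates — the scale of the field survey. The rate parameters are
illustrative (the survey does not publish per-species colonization
probabilities).

What the generator deliberately does **not** emulate: spatial dependence
between neighbouring segments, co-occurrence interactions between fungi,
overdispersion beyond binomial sampling, and epiphyte contamination. Passing
recovery tests therefore demonstrate correctness of the estimators under
independent-Bernoulli colonization, not robustness to those real-data
features.

`recovery_experiment()` wraps repeated simulation: observed richness against
the species pool, Shannon/Simpson of pooled counts against the generating
distribution's indices, and per-source ANOVA rejections. Two operating
characteristics are exercised routinely (and recomputed by
`scripts/acceptance.R`): under a null model each source rejects at about the
nominal $\alpha = 0.05$; with a 3x leaf multiplier at the study design the
tissue source is rejected at $p < 0.001$ in essentially every run. The
shipped checks use 1000 null datasets and 200 effect simulations — sizes at
which the binomial Monte-Carlo error on a rate of 0.05 is about 0.7
percentage points.

## Reproduction of the shipped survey's tables

`reproduce_all()` recomputes every value of the survey's summary tables that
is derivable from printed inputs and compares it at printed precision:

```{r repro}
rep <- reproduce_all()
rep
count(as_tibble(rep), section, match)
```

The mismatches are properties of the printed tables, surfaced deliberately:

* several diversity rows are inconsistent with any single formula (the rainy
  Gleason 4.029 is not $23/\ln 635$; the rainy evenness 0.88 is not
  $2.870/\ln 24$; the leaf and petiole relative-Gleason values appear
  swapped);
* printed Shannon/Simpson values require the exact isolate-level abundances,
  which cannot be reconstructed unambiguously from truncated CF percentages;
* the printed site-similarity matrix and per-site richness cannot be
  regenerated exactly from the printed CF tables (the package treats them as
  reference values, not targets);
* in the ANOVA table, the Site and site x tissue F values differ in the third
  decimal from the ratios of the printed mean squares, indicating the printed
  MS are themselves rounded.

The self-consistent subset — four Gleason rows, the summer/petiole evenness
rows, the Simpson complements, per-season richness, four F ratios, all
p-values, and both bioassay summaries — reproduces exactly at printed
precision, and those are the values asserted in the test suite.

## Bioassay summaries

The screening module summarizes inhibition-zone and MIC tables: an extract is
*active* if it has at least one recorded zone against any strain (dashes mean
no inhibition; zone size is not thresholded), and `mic_range()` spans the
recorded MICs in mg/ml.

```{r bio}
active_fraction(read_zone_table())
mic_range(read_mic_table())
```

## Known limitations

* The ANOVA is fixed-effects only; sites-as-random, count GLMs and post-hoc
  contrasts are out of scope.
* Beta-diversity is presence/absence Jaccard only (no Bray–Curtis/Sørensen,
  no ordination).
* No rarefaction or richness extrapolation (Chao, ACE); comparisons across
  unequal sampling effort should lean on Gleason's index with that caveat in
  mind.
* The segment design is configurable but assumed homogeneous across cells;
  surveys with per-cell segment counts need pre-aggregation.
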