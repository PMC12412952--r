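---
title: "Quantifying kelp-derived carbon in marine sediments from eDNA"
author: "kelpcarbon authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying kelp-derived carbon in marine sediments from eDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kelpcarbon)
```

## The problem

Kelp farms shed blade tissue that sinks to the seabed, and a standing
question in blue-carbon accounting is how much of that biomass ends up
buried in the underlying sediment. Bulk carbon measurements rarely resolve
the kelp contribution against the sedimentary background, so this package
implements a molecular route: a species-specific digital PCR (dPCR) assay
for the mitochondrial COI gene of *Saccharina latissima* quantifies kelp
DNA in sediment cores, a laboratory biomass-spiking calibration converts
gene copies to kelp carbon, and depth-integrated core summaries are
contrasted between sites inside and outside a farm. A companion
metabarcoding layer (16S/18S count tables) asks whether farm presence
restructures the sediment community.

All stages are driven either by user-supplied tables (CSV/TSV/BIOM) or by
the built-in synthetic generator, which emulates the statistical structure
of such a survey so that every stage of the pipeline is testable without
field data.

## From partitions to copies per gram

A dPCR reaction is split into thousands of partitions of volume $v_p$
(microlitres). If the reaction mix holds $c$ copies/µL, each partition
amplifies with probability $1 - e^{-c\,v_p}$, so with a fraction $\hat p$
of positive partitions the standard estimator is

$$\hat\lambda = -\ln(1 - \hat p), \qquad \hat c = \hat\lambda / v_p .$$

Zero-positive wells report 0 with a below-LOD flag; fully saturated wells
have no finite estimate and are treated as errors (a dilution should be
rerun). The partition volume is instrument-specific and deliberately has
no default.

`copiesPerGramDry()` carries the estimate back to the sediment through an
explicit dimensional chain: copies/µL of reaction, times the
reaction/template volume ratio and any pre-dilution, times the elution
volume, divided by the extracted wet mass expressed on a dry basis via the
slice's dry:wet mass ratio. Each factor is a visible, overridable argument
because published workflows differ in whether the instrument reports
copies per µL of reaction or of template; the `dilutionFactor` absorbs
that ambiguity.

## The biomass calibration and its inverse

The spiking experiment adds known wet kelp biomass (0–5.00% of slurry
mass) to sediment slurries. Wet additions convert to dry kelp carbon
through the kelp dry:wet mass ratio (default 0.125) and the carbon
fraction of dry tissue (default 0.33), so 5.00% wet is 0.206% ≈ 0.21% dry
C. (One aside on the published dose list this emulates: the 0.01% wet
level computes to 0.0004% dry C by this arithmetic; a stray extra zero
sometimes appears in print.)

`fitThroughOrigin()` regresses copies/g dry on dry kelp carbon with the
intercept coerced to zero — a blank slurry should read zero. Conventions
that matter and are therefore fixed and documented:

* $R^2$ uses the *uncentered* total sum of squares, the standard choice
  for no-intercept models; the adjustment is $1-(1-R^2)\,n/(n-1)$.
* Doses above 0.0825% dry C (the 2.00% wet level) are excluded by
  default: at the top dose the gene-copy response saturates and sits below
  the linear extrapolation, which would bias the slope low. The threshold
  is an argument; `Inf` keeps everything.
* A Shapiro–Wilk statistic on residuals is reported, not enforced.

The inverse coefficient $1/\hat s$ (percent dry kelp C per copy·g$^{-1}$)
converts field copy densities to derived kelp carbon. The package always
derives the inverse from its own fit rather than from any published
rounded pair — note that a printed slope of $1.3\times10^{10}$ and a
printed inverse of $7.093\times10^{-11}$ are not exact reciprocals; with
rounded sources only a refit settles the value.

`regressionSummaryFromF()` back-computes $R^2$, adjusted $R^2$ and $p$
from a reported $F(df_1, df_2)$, with the $(n-1)/df_2$ (intercept) or
$n/df_2$ (through-origin) adjustment, and `qpcrStandardCurve()` covers
the qPCR-side utility: efficiency $=10^{-1/\text{slope}}-1$, so a slope of
$-3.32$ is perfect doubling.

## Depth integration

Cores are sliced into depth horizons ($[top, bottom)$ cm below the
interface), of which only a subset is assayed, leaving gaps.
`integrateProfile()` collapses a profile into a mean per 1 cm³ of
sediment down to the deepest sampled horizon bottom ($z_{max}$, per core
by default).

The interpolation rule was a genuinely open design choice. We treat each
slice measurement as the *average over its own horizon* — which is what a
homogenised slice physically is — so the profile is constant within
sampled horizons, bridges unsampled gaps linearly between the bounding
horizon values (a mid-gap step is available as `method = "nearest"`; the
two integrate identically), and extends flat beyond the outermost sampled
horizons. This slab treatment has two properties a mid-depth polyline
lacks: the integral is invariant to splitting a horizon into equal-valued
halves, and it is exact when the true profile is linear in depth.

Volume-basis concentrations use the dry bulk density computed from each
slice's dry mass and the core geometry (10 cm inner diameter by default),
since surveys rarely tabulate density directly. Both a volume basis
(copies/cm³, used for the headline derived-carbon contrast) and a mass
basis (copies/g dry) are integrated and reported. With a calibration
attached, derived kelp carbon per cm³ is
$\text{inv}\times\overline{c}_{vol}/100$ (g C cm$^{-3}$).

## Site statistics

Copy numbers and nutrients are analysed on the log10 scale
(`logTransform()`); when zeros are present (below-LOD wells) a
pseudo-count of half the smallest positive value is added, otherwise
none.

`fitNestedOls()` fits `y ~ site_type + site_type:site_number + depth`
with "inside" as the type baseline and depth continuous in cm. When a
type has a single site the nested dummies are aliased with the type
effect and drop out automatically, so a two-site survey cleanly reduces
to type + depth — with 48 observations that yields $F(2, 45)$, and the
five-site, 75-observation layout yields $F(5, 69)$. Standardised betas
are $\beta\,\mathrm{sd}(x)/\mathrm{sd}(y)$ on the model-matrix columns,
dummies included; other conventions exist, which is why the raw betas are
always reported alongside.

Because integrated per-core values tend to show unequal variance between
site types, the site contrast on derived kelp carbon uses Kruskal–Wallis
(`kruskalWallis()`, with tie correction) followed by Dunn's pairwise
z-tests with Benjamini–Hochberg adjustment (`dunnPosthoc()`,
`bhAdjust()`). The Kruskal–Wallis statistic is invariant under monotone
transforms, so testing derived carbon and testing integrated copy density
are the same test.

`powerSampleSize()` answers "how many cores next time?" for a
correlation-scale effect. It offers the Fisher-z convention
$n = ((z_{1-\alpha/2}+z_{power})/\operatorname{atanh} r)^2 + 3$ and an
F-test convention on $f^2 = r^2/(1-r^2)$, and records which was used: at
$r = 0.56$, $\alpha = 0.05$, power 0.8 the two give $n = 23$ and $n = 28$
respectively. Published "about 14 samples" figures for this effect size
are not reproduced by either standard convention; the quantity is
method-dependent and the package never asserts a particular published
value.

## The community layer

* **Rarefaction** (`rarefyTable()`): one fixed subsample without
  replacement per seed — no repeated-rarefaction averaging — dropping and
  itemising samples below the target depth.
* **Alpha diversity**: observed richness and Shannon–Wiener $H$ with
  natural log (the convention of the common ecology stacks; the base is
  an argument).
* **Aggregation** (`aggregateTaxa()`): counts summed by taxonomy rank
  (families for 16S, genera for 18S are typical), taxa ranked by overall
  relative abundance, everything beyond the top $k = 30$ pooled into
  "Other", unassigned lineages into "Unassigned".
* **Bray–Curtis** $d = \sum_i |x_i-y_i| / \sum_i (x_i+y_i)$ and **PCoA**
  by Gower double-centering and eigendecomposition. Bray–Curtis is
  semi-metric, so negative eigenvalues arise; they are reported and
  excluded from the explained-variance denominator by default.
* **PERMANOVA** (`permanova()`): McArdle–Anderson partitioning of the
  centered inner-product matrix with *sequential* (type-I) sums of
  squares in user-given term order, pseudo-F per term, and p-values from
  free (unrestricted) permutation of sample rows,
  $p = (\#\{F^\pi \ge F\}+1)/(m+1)$. Effect sizes are partial
  omega-squared, $\omega^2_t = (SS_t - df_t\,MS_{res}) /
  (SS_{total} + MS_{res})$, kept untruncated internally and truncated at
  zero in summaries. Covariate-versus-factor ordering is left to the
  caller because sequential partitioning makes it consequential.
* **Volcano screen** (`volcanoScreen()`): no standard test statistic
  exists for this display, so the choice is documented rather than
  implied: the coefficient is $\log_2$ of (mean relative abundance in the
  non-reference group + $\varepsilon$) over (reference group +
  $\varepsilon$), with $\varepsilon$ half the smallest non-zero relative
  abundance, so *negative = enriched in the reference ("inside") group*;
  p-values come from Welch's unequal-variance t-test on
  $\log(\text{rel}+\varepsilon)$, BH-adjusted, with per-taxon mean
  abundance (over samples where present) and prevalence alongside.
* **Spearman screen** (`spearmanScreen()`): per-taxon rank correlation
  (midrank ties) of relative abundance against log10 copy number,
  BH-adjusted, optionally within one site type.

## The synthetic generator

The generator exists so that every pipeline stage has a testable ground
truth; its defaults are the study conditions the package is organised
around, and they are not tuned.

* **Survey**: 3 sites inside + 2 outside, 3 cores per site, horizons
  0–1, 1–2, 2–3, 4–5, 6–7 cm (75 slices). True copies/g dry are
  $10^{\mu_{type} + s + \beta_z z + \varepsilon}$ with
  $\mu_{inside} = 4.816$, $\mu_{outside} = 4.506$ (a 0.310 log10
  contrast, about twofold in linear space),
  depth slope $\beta_z = -0.06$/cm, one "hotspot" inside site at
  $s = +0.43$, and $\varepsilon \sim N(0, 0.2^2)$ — log-normal field
  noise matching the log-scale analysis.
* **Masses**: wet bulk density uniform 1.15–1.45 g/cm³ and dry:wet mass
  ratio uniform 0.3–0.5 per slice, plausible for fine marine mud; these
  are stated assumptions (surveys rarely print per-slice densities), and
  both ranges are arguments.
* **dPCR**: positives ~ Binomial$(n, 1-e^{-c v_p})$ on 8500 partitions of
  $4\times10^{-4}$ µL — the generative counterpart of the Poisson
  estimator, so round-trip bias is a test, not an assumption.
* **Spiking**: mean response linear below 0.0825% dry C with slope
  $1.3\times10^{10}$, flat at the plateau above, multiplicative
  log-normal noise at CV 0.3, mean-corrected so the expectation stays on
  the line.
* **Nutrients**: TC% uniform 3.25–3.6, TOC = 0.939·TC (+ optional
  noise), TN Gaussian with an optional inside-site effect (off by
  default).
* **Community**: Dirichlet-multinomial counts over log-linear taxon
  weights (site, depth and copy-number effects on designated taxa),
  concentration 200, library sizes uniform 5000–15000, with a fabricated
  taxonomy (three ASVs per family) so rank aggregation is exercised.

All randomness flows from one root seed through fixed per-stream offsets
(survey, dPCR, spiking, taxa, nutrients, rarefaction, permutations), so
regenerating one stage never perturbs another and a fixed seed gives
byte-identical outputs.

What the generator does *not* emulate: taxonomic misassignment, chimeras,
raw-read error, spatial autocorrelation between cores, eDNA degradation
kinetics, or the year-to-year design changes of a real programme. A
passing recovery test therefore demonstrates that the estimators are
correct under the stated model, not that the model captures every feature
of field data.

## Numerical choices and degenerate inputs

* Saturated dPCR wells: error, not a censored value; zero wells: flagged
  zeros, handled downstream by the pseudo-count rule.
* Through-origin fits require ≥ 3 points and at least one non-zero dose.
* Profiles require ≥ 2 sampled horizons to integrate; single-slice
  profiles are valid objects but cannot be depth-averaged.
* Aliased nested terms are dropped (with the design's rank re-checked)
  rather than erroring, because one-site-per-type years are a real
  design.
* Permutation p-values are floored at $1/(m+1)$; PERMANOVA term/residual
  sums of squares are conserved to the total at validity-check precision
  ($10^{-8}$ relative).
* Bray–Curtis of two empty samples is defined as 0.

## Problem sizes used in the test suite

The suite exercises the estimators at deliberately modest sizes chosen to
make Monte-Carlo tolerances meaningful: 600–1000 simulated wells per
occupancy level for estimator bias, 500 null Kruskal–Wallis and 200 null
PERMANOVA simulations for type-I error, 200 rarefaction draws against the
hypergeometric expectation, 25–30 replicate community simulations for the
screen sign/power checks, and ten full synthetic-scenario runs for the
end-to-end contrast. These sizes give ±3 standard-error bands that the
assertions state explicitly.

## Known limitations

* The copies-to-carbon inversion assumes the spiking relationship (fresh,
  homogenised tissue) transfers to field sediments; degradation state
  will move the true coefficient and is not modelled.
* PERMANOVA uses free permutation; restricted (within-core or
  within-site) schemes are not implemented.
* The volcano statistic is one reasonable choice among several
  (compositional frameworks such as CLR models are out of scope);
  taxon-level conclusions should lean on the convergence of both screens.
* Mixed-effects or spatially explicit models are intentionally absent:
  the inferential layer mirrors a fixed-effects analysis.
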