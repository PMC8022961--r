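---
title: "Multiple-QTL model selection with X-chromosome-aware penalties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-QTL model selection with X-chromosome-aware penalties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlx)
```

## The problem

In experimental crosses between two inbred strains (a backcross or an F2
intercross), quantitative trait locus (QTL) mapping proceeds by regressing a
phenotype on genotypes along a genetic map.  The X chromosome breaks the
symmetry that makes this routine on autosomes:

* males are hemizygous (genotypes A or B), while females carry two X's;
* in an intercross, the female X genotypes depend on the cross direction —
  with a strain-A paternal grandmother the females are AA or AB, with a
  strain-B paternal grandmother AB or BB;
* a sex or cross-direction difference in the phenotype masquerades as X
  linkage unless those covariates sit in the null model;
* the X linkage test therefore has different degrees of freedom than the
  autosomal test, and deserves its own significance threshold.

`qtlx` implements multiple-QTL model selection by a penalized LOD criterion
that treats these issues explicitly, together with the simulation machinery
needed to derive the penalties and to measure type-I error and power.

## The model

For a phenotype $y$ with normal residual variation we fit, by Haley–Knott
regression, models of the form $y = X\beta + \epsilon$, where $X$ contains an
intercept, the null covariates of the design (sex and/or cross direction),
one column per backcross QTL or two indicator columns per intercross QTL,
sex-stratified genotype columns for X-linked QTL, and product columns for
pairwise epistatic interactions.  Genotype probabilities, conditional on the
observed multipoint marker data, come from a per-chromosome hidden Markov
model under the Haldane (no-interference) map function; on the X chromosome
the hidden state is the allele carried by the single recombinant X, so every
individual has a two-state chain regardless of design.

A QTL model $\gamma$ is a graph: nodes are QTL, edges are pairwise
interactions, and every edge requires both of its endpoints (the model
hierarchy).  The selection criterion is the penalized LOD

$$\mathrm{pLOD}(\gamma) = \mathrm{LOD}(\gamma)
  - T_{mA}\,|\gamma|_A - T_{mX}\,|\gamma|_X - \sum_{\text{edges}} T_i,$$

where $\mathrm{LOD}(\gamma)$ compares $\gamma$ to the null model (intercept +
null covariates), $|\gamma|_A$ and $|\gamma|_X$ count autosomal and X-linked
QTL, and each interaction edge pays a penalty by its region: autosome–autosome
(A:A), autosome–X (A:X), or X–X (X:X).  A:A edges may take a *light* penalty
$T_{iAAL}$ instead of the heavy $T_{iAAH}$, at most once per connected
component of the interaction graph; interactions involving the X chromosome
always pay their heavy penalty ($T_{iAX}$, $T_{iXX}$).  The `XeqA` variant
collapses all of this to a single main-effect penalty $T_m$ and a single
heavy/light pair ($T_{iH}$, $T_{iL}$), i.e. it treats the X chromosome like
an autosome; it is retained as the comparison method.

## Deriving the penalties

Each penalty is an empirical quantile of a null-scan maximum.  Writing
$L_A$ and $L_X$ for the autosomal and X genetic lengths and
$S_{AA}=L_A^2/2$, $S_{AX}=L_A L_X$, $S_{XX}=L_X^2/2$ for the areas of the
two-dimensional search regions, the overall level $\alpha$ is apportioned as

$$\alpha_i = 1-(1-\alpha)^{L_i/L} \quad\text{(main effects)},\qquad
  \alpha_i = 1-(1-\alpha)^{S_i/S} \quad\text{(interactions)},$$

so that $(1-\alpha_A)(1-\alpha_X) = 1-\alpha$ and
$(1-\alpha_{AA})(1-\alpha_{AX})(1-\alpha_{XX}) = 1-\alpha$ exactly.  Then

* $T_{mA}$, $T_{mX}$ are the $1-\alpha_A$ and $1-\alpha_X$ quantiles of the
  autosome-wide and X-wide maximum single-QTL LOD under the null;
* the heavy interaction penalties are the $1-\alpha_i$ quantiles of the
  region-wise maximum interaction LOD from two-dimensional two-QTL scans;
* the light penalties subtract the main-effect penalty from the quantile of
  the *full-versus-one* LOD, the evidence for a second QTL given one.

Two conventions here deserve explicit statement, because they change the
estimates by a few tenths of a LOD.  First, the interaction LOD of a
chromosome pair is computed in the condensed form
$\max(\mathrm{LOD}_{\text{full}}) - \max(\mathrm{LOD}_{\text{add}})$, each
maximized separately over the pair's two-dimensional grid, and the
full-versus-one LOD as $\max(\mathrm{LOD}_{\text{full}})$ minus the larger
single-QTL maximum of the two chromosomes; the pointwise alternative
($\max$ of per-pair differences) gives systematically larger penalties.
`scantwo()` returns the pointwise surfaces; `summary()` of a scan and the
penalty estimation use the condensed statistics.  Second, for a mixed A:X
pair the full model is the joint genotype-class cell-mean model: because the
X main effect is sex-stratified, the epistasis columns include products of
the autosomal QTL's columns with the sex/direction stratum indicators, so
the A:X interaction test has more degrees of freedom than the plain product
construction would give (three rather than two in a backcross with both
sexes).

Because $\alpha_{AX}$ and $\alpha_{XX}$ sit far out in the tail, replicates
are allocated inversely to region area: `allocate_replicates(base)` gives
the A:X region $S_{AA}/S_{AX} = L_A/(2L_X)$ times and the X:X region
$(L_A/L_X)^2$ times the base count.  The far-tail batches scan only their
region (the X:X batch simulates only the X chromosome), which leaves the
sampled distribution unchanged — under the null the phenotype is independent
of genotype — while making a third of a million X:X replicates cheap.

### Monte-Carlo design choices

`estimate_penalties()` simulates `G` genomes per batch and draws `B` null
phenotypes per genome (`phenos_per_geno`; defaults 4–200 by batch, the
far-tail batches re-using genomes most).  The estimand is unaffected, and
keeping `B` small relative to `G` keeps the between-genome component of the
quantile's Monte-Carlo error small; we observed that very large `B` (hundreds
for the main batches) adds roughly 0.1 LOD of cluster noise.  In permutation
mode the observed genotypes are fixed and the phenotype is permuted within
sex-by-direction strata, the analogue used for real data.

Null-scan maxima grow with the density of the evaluation grid: on the 10 cM
marker map, the X:X heavy penalty rises from about 4.77 (markers only)
through 4.96 (5 cM grid) and 5.05 (2.5 cM) to 5.10 (1 cM) at 80,000
replicates.  The default grid steps are 2.5 cM for the single-QTL and
X-involving batches and 5 cM for the genome-wide two-dimensional batch,
whose cost grows with the fourth power of density; on a single CPU this
keeps a full derivation (base 1056, with 18,480 / 9,240 / 323,400 replicates
for the X, A:X and X:X batches) under ten minutes.  With these choices the
derived penalties for the backcross study conditions (below) agree with
independently published values to within a few hundredths of a LOD for the
main effects and one to two tenths for the interaction penalties — the
residual being the still-coarser 5 cM grid of the genome-wide batch.

The empirical quantile is the type-7 interpolated order statistic; when the
expected number of exceedances falls below 5 the estimate is flagged as
unstable.  Estimated light penalties are floored at 0.001 (they can fall
non-positive at very small replicate counts).

## The search

`stepwise_qtl()` performs forward selection to `max_qtl` QTL (default 10):
at each step it scans for one more additive QTL and, for each QTL in the
model, for a new QTL interacting with it, taking the candidate with the
largest pLOD *even if pLOD decreases*.  Backward elimination then removes
one edge or one node (with its edges) at a time down to the null model, and
the selected model is the pLOD maximizer over everything visited.  After
each accepted step the QTL positions are refined by cyclic one-QTL-at-a-time
hill climbing (switchable; the model LOD never decreases).  Ties are broken
deterministically: earlier candidate class first, then chromosome and
position order.  New QTL may not be placed within one grid step of an
existing QTL on the same chromosome, which avoids near-collinear designs.
Adding an edge between two *existing* QTL is not among the forward moves —
the search discovers epistasis by adding an interacting partner — matching
the published description of the procedure; on toy genomes the search
recovers the exhaustive-enumeration optimum in well over 95% of simulated
datasets (it remains a heuristic).

## The simulator and its scenarios

`sim_cross()` draws genotypes as Markov chains along the marker grid with
Haldane transition probabilities — under no interference this is
distribution-identical at the markers to drawing Poisson crossover counts
with uniform locations.  The X chromosome is transmitted per design: males
hemizygous, intercross female genotypes constrained by direction.  The
default genome is mouse-like — 19 autosomes totalling 1400 cM plus an 80 cM
X, markers every 10 cM — so $L_A/L_X = 17.5$.

The eight study scenarios (`qtlx_scenarios()`) use a backcross of $n = 250$
split evenly between the sexes: a null; one, two or three additive autosomal
QTL; one or two additive X-linked QTL; two interacting autosomal QTL; and an
autosome-by-X interacting pair.  Each QTL explains approximately 8% of the
phenotypic variance: with residual SD 1, a backcross or X-linked locus
(genotype score 0/1, variance 1/4) uses effect
$a = \sqrt{\mathrm{pve}/(0.25\,(1-\mathrm{pve}))} \approx 0.59$, and an
epistatic term uses the centered product of the two locus scores with the
coefficient solving the same equation for the product's variance; the
parameterization of the epistatic effect is not pinned down by its
description beyond the per-term variance share, so the centered-product
choice is ours.  `evaluate_scenario()` reruns the full search on simulated
scenario data and tallies false positives (a selected QTL more than 15 cM
from every true QTL of its chromosome, greedily one-to-one matched) and
detections; this is the machinery behind the type-I error and power
comparisons of the two methods.

What the simulator does *not* emulate: genotyping error and missingness are
off by default (both are available as options and are handled by the HMM),
crossover interference, segregation distortion, selective genotyping,
non-normal phenotypes and covariates beyond sex/direction are absent.
Passing tests on simulated crosses therefore show the machinery is correct
under the stated model, not that real data meet the model.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
pen <- estimate_penalties(mouse_map(10), base_reps = 1056, seed = 1)
cross <- sim_scenario("2-auto-int")
fit <- stepwise_qtl(cross, pen$XneA)
fit
plot(fit)           # drop-one profile LOD curves
summary(scanone(scan_prep(cross)))
```

## Numerical notes and limitations

* All least squares goes through rank-guarded orthonormal projections
  (LAPACK QR with an SVD fallback); structurally zero columns (e.g.
  cross-stratum products) are dropped, and rank-deficient fits are the
  projection onto the column space (pseudoinverse fit), flagged on the
  model-fit object.
* LOD scores use $\tfrac{n}{2}\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$ with
  $n$ the number of individuals with observed phenotype (dropped case-wise).
* Positions are continuous cM; scan grids are the markers plus optional
  pseudomarkers at a fixed step; position identifiers are `"chr@pos"`.
* Missing sex or direction labels are an error, never imputed.
* Scope: backcross and F2 intercross only (no 4-way crosses, RIL, or
  pseudoautosomal regions); pairwise epistasis only (no three-way terms);
  Haley–Knott regression only (no EM interval mapping or imputation).
* The mouse-like map is a fixed package constant; penalties depend on the
  map, the design and $n$, and must be re-derived for other settings (use
  `estimate_penalties()` with your own map or, for real data, the
  permutation mode).
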