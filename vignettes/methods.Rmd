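---
title: "Control-based QC for low-biomass microbiome data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-based QC for low-biomass microbiome data: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(katharoseq)
```

## The problem

In low-biomass microbiome experiments (cleanroom surfaces, skin swabs,
tissue biopsies), contaminant DNA from reagents, plastics and neighbouring
wells can rival or exceed the true biological signal. Standard pipelines
give every sample a feature table regardless of whether its reads mean
anything. The workflow in this package makes that judgement quantitative by
processing *titrated positive controls* — known cell counts of a single
organism spiked before DNA extraction — and *negative controls* through the
identical wet-lab and bioinformatic pipeline, and reading three quantities
off them: the background contamination load, per-study limits of detection,
and a read-count sample-exclusion threshold.

## The Hill model and its interpretation

For a positive control with input biomass $x$, the fraction $y$ of its reads
assigned to the spiked organism is modelled by the allosteric sigmoidal
(Hill) form

$$y(x) \;=\; \frac{Y_{max}\, x^{h}}{K_{1/2}^{h} + x^{h}}, \qquad h > 0 .$$

The model's mechanistic reading is competition between a roughly constant
contaminant background and a signal that scales with input: at
$x = K_{1/2}$ exactly half of the reads are signal. Fitted with $x$ = input
cells, $K_{1/2}$ is the pipeline's background load in *cell equivalents*;
fitted with $x$ = read depth, $K_{1/2}$ is the read count at which a
sample's content is half contaminant, which is what makes it a defensible
exclusion threshold.

Assumptions worth stating: compositions are computed on raw denoised counts
(no rarefaction); the same background applies to all wells of a run; the
curve is fitted on linear $x$ (fitting on $\log x$ changes the weighting of
the low-input levels and, on the printed compositions, does not reproduce
the reported half-saturation constant, so linear $x$ is used); and $h$ is a
free shape parameter rather than a binding-cooperativity constant — here it
simply absorbs how sharply signal overtakes background.

### Fitting

`fit_hill()` minimises squared error with bounded Levenberg–Marquardt
(minpack.lm), parameters constrained to $K_{1/2} > 0$, $h \in (0.1, 10]$,
$Y_{max} \in (0, 1]$. Initialisation is deterministic: the closed-form
two-point solution (`solve_two_point()`) through the mean responses at the
smallest and largest input levels, plus a short fixed ladder of alternative
starts for the free-$Y_{max}$ case — starting exactly on the $Y_{max} = 1$
bound can trap the optimiser there, so slightly interior starts are also
tried and the best residual sum kept. Convergence tolerance is $10^{-10}$
on relative parameter change; no random restarts, so a given dataset always
yields the same fit.

$Y_{max}$ is *free* by default (bounded above by 1): real titrations
saturate below 1 when a few percent of reads are persistent contaminants
even at high input. The two-point reconstruction fixes $Y_{max} = 1$, which
is the convention under which the half-maximum threshold coincides exactly
with $K_{1/2}$. Per-point binomial weights ($d_i/(y_i(1-y_i))$, $d_i$ the
depth) are available but off by default — they up-weight the saturated
levels, which is rarely what a background-load estimate wants.

`invert_hill()` solves the curve for $x$ in closed form; round-tripping is
exact to $10^{-9}$ relative. R² is reported as $1 - SS_{res}/SS_{tot}$
about the mean response, unweighted, and can be negative for a curve worse
than the constant mean.

## Limits of detection

Each titration level is compared against the pooled negatives (extraction
negatives and blanks by default) with a two-group Kruskal–Wallis test —
equivalent to a rank-sum test, with midranks and tie correction — on either
the target-composition or the read-depth metric. For total $n < 8$ the
chi-square approximation is replaced by an exact permutation p-value
(enumeration of all group relabellings); the exact test is discrete, so its
true size at $\alpha = 0.05$ is the largest attainable level below 0.05,
never above. Benjamini–Hochberg is applied *across levels within one
metric* — the minimal defensible family; levels with fewer than two usable
points are excluded from the family and flagged. The LOD is the smallest
level from which **all larger testable levels** are also significant,
which keeps the LOD monotone under shifts of the positive-control
distribution and prevents an isolated spurious rejection at a low level
from driving the LOD down.

## Exclusion, success rates, contamination

`apply_exclusion()` is boundary-inclusive (`depth >= threshold` retained,
i.e. "at least *T* reads"), issues exactly one decision per sample, and
never touches retained counts. The default strategy is the conservative
`max_input_median` — the median depth of the top-input positives, with the
*lower* central value taken for even counts so the threshold remains an
observed integer depth; thresholds are per study/run, never global, because
they track sequencing depth. `fit_half_max` (the fitted curve inverted at
$y = 0.5$, rounded up; equals $K_{1/2}$ when $Y_{max}=1$) is the permissive
alternative, refused with a pointer to the median strategy when the fitted
$Y_{max} \le 0.5$. `gel_comparison()` quantifies the false-negativity of
gel-band QC among read-retained libraries; `contamination_report()` carries
the cells-fit $K_{1/2}$ and flags samples whose target fraction exceeds the
95th percentile (configurable) of the negatives.

## What the generator emulates — and what it does not

`generate_titration()` / `generate_study()` produce counts, not reads. Per
well with input $c$:

* depth mean $D(c) = D_0 + (D_{max} - D_0)\,\mathrm{hill}(c; k_d, h_d=1)$,
  with multiplicative $\exp(\mathcal N(0, \sigma))$ noise. The baseline
  $D_0$ (median 150 reads for negatives) reflects that blank wells still
  yield amplifiable contaminant libraries; $D_{max}$ defaults to a median
  of 2,000 reads at the 5,000-cell level, in the range of real
  top-input control medians. $\sigma = 0.5$ gives the several-fold
  depth scatter seen across replicate wells.
* target reads $\sim \mathrm{Binomial}(d, \mathrm{hill}(c))$ under the true
  parameters (defaults $K_{1/2} = 96.88$ cells, $h = 1.377$,
  $Y_{max} = 1$), so composition at $c = K_{1/2}$ averages $Y_{max}/2$ by
  construction;
* remaining reads spread over 50 background taxa by a symmetric
  Dirichlet(0.5)-multinomial — a few contaminants dominating, as kitomes
  do;
* true samples ($n = 60$ by default) draw biomass log-uniformly over
  1–10,000 cells so a realistic fraction falls below any sensible
  threshold; the target appears in samples and negatives only through the
  `leakage_rate` (default 0: leakage is a scenario to opt into, not a
  baseline assumption).

One RNG stream per call, fully determined by the seed, which the manifest
records. Not emulated: sequence errors, chimeras, taxonomy mis-annotation,
cross-level pipetting error, batch structure across plates, or
overdispersion beyond the log-normal depth term — composition noise is
purely binomial, which is cleaner than real data. Passing tests on this
generator therefore demonstrates correctness of the estimators and
decision rules, not robustness to every artefact of real sequencing; in
particular, the synthetic composition LOD typically reaches the lowest
titration level because negatives carry exactly zero target reads unless
leakage is enabled.

## Numerical conventions and degenerate inputs

Fractional counts are rejected, not rounded. Composition is undefined at
zero depth and raises a typed error rather than returning 0; zero-depth
samples are reported alongside composition points, never silently dropped.
Target and non-target fractions are formed from integer sums with a single
final division. A response vector without variance refuses the fit
(`converged = FALSE`) instead of producing an arbitrary curve. The
half-maximum threshold subtracts $10^{-8}$ before the ceiling so an
integer-valued $K_{1/2}$ maps to itself. All file outputs
(TSV, summary JSON) are byte-stable for fixed inputs; the BIOM writer
delegates to biomformat, whose container metadata carries a generation
timestamp, so byte-stability is guaranteed for the TSV dialect only.

## Test problem sizes

The suite checks the estimators at deliberately small, fast scales: grid
oracles on ≤100-point fits over a ~79,000-node lattice; exact-permutation
cross-checks at total $n \le 10$; null calibration of the per-level test
with 2,000 replicates of 5-vs-5 comparisons against the enumerated
permutation distribution; and end-to-end background-load recovery as the
median over 20 seeded studies at the default 18 replicates per level.
These sizes were chosen as the smallest at which the Monte-Carlo error
bands are meaningful; all are the package's own conventions and run in
well under a minute each.

## Known limitations

* The Hill fit treats points as independent; plate- or run-level random
  effects are not modelled.
* With free $Y_{max}$ and only four titration levels, $Y_{max}$ and
  $K_{1/2}$ are weakly identified when the top level does not saturate;
  the two-point and fixed-$Y_{max}$ modes exist for exactly that case.
* The exact Kruskal–Wallis path covers two groups only; multi-group exact
  testing is out of scope.
* Exclusion removes whole samples. Removing contaminant *features* from
  retained samples (decontamination) is a different problem and out of
  scope here.
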