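---
title: "Estimating the multiplet frequency from two-species mixing experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the multiplet frequency from two-species mixing experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barnyard)
```

## The loading model and its one assumption

In a barnyard experiment two distinguishable cell types — call them type 1
and type 2, classically human and mouse — are mixed and partitioned into
barcoded droplets (or wells). The sole modeling assumption is that loading
is Poisson: each of the $N$ droplets independently receives
$c_1 \sim \mathrm{Poisson}(\mu_1)$ cells of type 1 and
$c_2 \sim \mathrm{Poisson}(\mu_2)$ cells of type 2, so the total
$c = c_1 + c_2 \sim \mathrm{Poisson}(\mu)$ with $\mu = \mu_1 + \mu_2$. This
holds when cells enter partitions randomly and independently; clumping
violates it (see the simulator section).

The quantity of interest is the **multiplet frequency**, the probability
that a non-empty droplet contains two or more cells:

$$
M \;=\; \frac{\Pr(c \ge 2)}{\Pr(c \ge 1)}
  \;=\; 1 - \frac{\mu\, e^{-\mu}}{1 - e^{-\mu}} .
$$

$M$ depends on the two rates only through their sum, is strictly increasing
in $\mu$, and behaves as $\mu/2$ for small $\mu$.

## From observables to rates

The experiment yields three droplet counts: $N_1$ (at least one type-1
cell), $N_2$ (at least one type-2 cell) and $N_{1,2}$ (both). **$N_1$ and
$N_2$ each include the mixed droplets**, so the number of non-empty droplets
is $N_1 + N_2 - N_{1,2}$. This inclusive convention matches cellranger-style
per-species partition summaries; everything in the package — classifier,
simulator, file formats — emits and expects it, and the CLI help restates it
rather than attempting to auto-detect the alternative (exclusive) convention
that some pipeline versions might use.

The total droplet count $N$ (empty droplets included) is unobserved. Because
the two loading processes are independent,
$N_{1,2}/N = (N_1/N)(N_2/N)$, giving $N = N_1 N_2 / N_{1,2}$, and matching
observed to expected counts, $N_i = N(1 - e^{-\mu_i})$, yields

$$
\mu_i = -\log\!\frac{N - N_i}{N}, \qquad i = 1, 2 .
$$

`estimate_from_counts()` composes these steps:

```{r}
est <- estimate_from_counts(droplet_counts(3550, 550, 100))
est
```

### Numerical choices

* The inferred $N$ is generally fractional (e.g., 402,002.5 for the lightest
  worked example) and is **kept real-valued**: rounding it before the
  logarithms perturbs the rates in the fourth decimal. Counts themselves may
  also be fractional (some pipelines report estimated partition counts); a
  notice is emitted but they are accepted.
* Probabilities use `expm1` to avoid cancellation at small rates.
* Reported values are stored at full precision; only printing rounds $M$ to
  3 decimals.
* Ties and boundaries are explicit: two degenerate inputs raise *named*
  conditions rather than returning a number. $N_{1,2} = 0$ raises
  `barnyard_unidentifiable_total` ($N$ is unbounded, and a silent $M = 0$
  would hide an underpowered experiment — the message points to the
  doublet-approximation lower bound of 0). $N_{1,2} \ge \min(N_1, N_2)$
  raises `barnyard_inconsistent_counts` (an inferred rate would be
  infinite). The CLI maps both to exit code 3, other validation problems to
  exit 2.

## The equal-mix shortcut and when it fails

The classical approximation $M \approx 2 N_{1,2} / (N_1 + N_2 - N_{1,2})$
assumes all multiplets are doublets and the mix is 50/50.
`doublet_approximation()` reports it alongside the exact value. At low
loading and equal mixing the two agree within a couple of percent; at high
loading the shortcut overestimates (it ignores triplets and above), and for
unequal mixes it can err in either direction because same-type doublets
dominate:

```{r}
sapply(list(c(2005, 2005, 10), c(2500, 2500, 1000), c(3950, 150, 100)),
       function(x) {
         e <- estimate_from_counts(droplet_counts(x[1], x[2], x[3]))
         c(M = round(e$multiplet_frequency, 3),
           approx = round(e$doublet_approximation, 3))
       })
```

## Uncertainty

The three summary counts carry no per-droplet data, so a nonparametric
bootstrap is impossible. `bootstrap_interval()` instead simulates from the
*fitted* load (a parametric bootstrap), re-estimates $M$ on each replicate,
and returns the equal-tailed percentile interval. This is an extension of
the closed-form method, not part of it: its coverage inherits the Poisson
assumption, and replicates that draw zero mixed droplets are redrawn (up to
ten times) then dropped and counted in `n_degenerate`.

## What the simulator emulates — and what it does not

`simulate_droplets()` draws per-droplet cell counts, tallies the three
observables, and records the **realized** multiplet frequency — the fraction
of non-empty droplets that actually hold $\ge 2$ cells. Defining truth from
realized contents (not the analytic formula) keeps it well defined under
non-Poisson loading. Three modes:

* `poisson` — the model's assumption; used for recovery validation.
* `overdispersed` — a shared per-droplet gamma factor (mean 1, variance
  `clump_param`) scales both rates, emulating clumping that is equally
  likely across cell types. The cross-type count is inflated relative to
  independence, so the estimator **overestimates** the realized frequency.
* `intra_type_clumps` — cells arrive in same-type clumps of fixed size
  (clump counts Poisson, per-type means preserved). Clumps create multiplets
  invisible to the cross-type count, so the estimator **underestimates**.

Both clumped modes preserve the per-type mean cells per droplet, isolating
distributional shape from loading intensity. The tests assert only the
*direction* of these biases: their magnitude depends on clump parameters
that real experiments do not expose, so no magnitude claims are made.
Reproducibility contract: a `simulation_config` (including its seed) maps to
a bit-identical result; `recovery_experiment()` spawns one sub-seed per
(config, replicate) from the root seed, so tables do not depend on
evaluation order.

The simulator models cell-into-partition counting only — no transcripts,
ambient RNA, barcode collisions, or cell-viability effects. Passing recovery
tests therefore validate the *algebra* of the estimator under its stated
assumption, not its robustness on real chemistry.

Problem sizes used in the validation suite: recovery runs 20 replicates of
200,000 droplets per grid cell over equal and 9:1 mixes at total loads
0.01–1.0 cells/droplet, comparing each replicate against the analytic value
at three across-replicate standard deviations. At the lightest, most
unequal cell the expected mixed count is below 2, so a substantial minority
of replicates legitimately draw $N_{1,2} = 0$; these raise the
unidentifiable-total condition, are excluded, and are reported — an honest
reflection of an underpowered design rather than a simulation artifact.

## The species classifier

`read_species_matrix()` ingests the cellranger-style triplet (MatrixMarket
counts + features/barcodes TSVs, optionally gzipped), assigning each feature
to a species by a literal, case-sensitive identifier prefix. `call_cells()`
then applies a deliberately transparent rule: barcodes with fewer than
`min_umi` total UMIs (default 100) are background; above the floor, a
barcode is *mixed* when the minor species holds at least `minor_fraction`
(default 0.1) of its UMIs — the boundary inclusive, so an exact 50/50 split
is mixed — otherwise it takes the majority label. The defaults are a
documented choice, not a calibration: "a substantial number of transcripts
from both types" has no canonical quantification, and ambient-RNA-aware
calling is out of scope. On real data the thresholds should be checked
against the barcode-rank curve and cross-species contamination level, since
ambient contamination pushes pure barcodes toward `mixed` and inflates
$N_{1,2}$.

`simulate_species_matrix()` closes the loop for testing: it converts
simulated droplets into a synthetic UMI matrix at a chosen sequencing depth.
With depth far above `min_umi` and no ambient noise, purity calls cannot
flip, and the classifier must reproduce the simulator's droplet counts
exactly — which is what the end-to-end test asserts before comparing the
estimate with the analytic value (tolerance 0.015, about 3.5 Monte-Carlo
standard deviations of the estimator at 50,000 droplets).

## Known limitations

* Two cell types only; no genotype demultiplexing, no ambient-RNA
  correction, no per-barcode doublet scoring — the method estimates the
  *rate* of multiplets, it does not identify which barcodes are multiplets.
* The Poisson assumption is load-bearing: under clumping the estimate is
  biased in the directions described above, and the package can demonstrate
  but not correct this.
* The bootstrap interval is parametric and inherits every model assumption.
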