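---
title: "Weighted-mean pseudo-control normalization of RT-PCR CT data"
author: "ctnorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-mean pseudo-control normalization of RT-PCR CT data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctnorm)
```

## The problem

RT-PCR reports, for every assay (gene or miRNA) and sample, a Cycle
Threshold: the number of amplification cycles before the target's
fluorescence crossed detection. CT is inversely and logarithmically related
to starting abundance — one cycle fewer means roughly twice as much starting
material. Comparing CT across samples requires removing sample-to-sample
differences in the amount of loaded material. The classical recipe subtracts
a per-sample reference value $CT_0$ (an endogenous control such as RNU44,
RNU48 or U6) from every assay's CT:

$$\Delta CT = CT - CT_0, \qquad
  \Delta\Delta CT = \Delta CT - \Delta CT_{control}, \qquad
  FC = 2^{-\Delta\Delta CT}.$$

Endogenous controls are chosen for presumed stability, but several of the
standard ones are themselves deregulated in disease tissue, which corrupts
every downstream fold change. Data-driven alternatives use the per-sample
mean of all assays as a pseudo-control, but the plain mean is dominated by
the most fluctuating, low-abundance assays and by undetected wells.

A second, structural problem motivates weighting: CT data carry an
expression-level-dependent bias. Low-abundance assays (high CT) do not just
vary more — their variation *tracks* the sample loading differences with an
amplified gain. The diagnostics in this package quantify that bias; the
weighted-mean pseudo-control is designed to resist it.

## The weighted-mean pseudo-control

For each sample, every assay contributes to the reference, weighted by its
empirical stability. With $\sigma_j$ the across-sample standard deviation of
assay $j$ and $p \ge 0$ the *weighted mean power*,

$$CT_0 = \sum_j CT_j \, w_j, \qquad
  w_j = \frac{(1/\max(\sigma_j, \varepsilon))^{\,p}}
             {\sum_i (1/\max(\sigma_i, \varepsilon))^{\,p}}.$$

The power is applied in numerator and denominator alike, so the weights are
a convex combination: $p = 0$ recovers the plain arithmetic mean exactly,
$p = 1$ weights by inverse standard deviation, and as $p \to \infty$ the
$CT_0$ converges to the CT row of the single most stable assay. One
parameter therefore spans the whole family from "use everything equally" to
"use the single best reference gene", which is what lets the method emulate
mean normalization and endogenous-control normalization as limiting cases.
The printed form of a weighted mean is ambiguous about whether the power
belongs in the normalizing sum; only this convex reading makes the $p = 0$
and large-$p$ limits come out right, so it is the one implemented.

Two numerical choices matter:

* **`epsilon`** (default 0.01 cycles) floors each $\sigma_j$ so that an
  exactly constant assay cannot receive infinite weight. It is reported in
  the result's provenance.
* Weights are computed in log space (`exp(lw - max(lw))`), because
  $(1/\sigma)^{p}$ overflows double precision for small $\sigma$ and large
  $p$.

With missing wells, the weights are renormalized per sample over the assays
observed in that sample, so a dropout changes only that sample's
combination, not the weighting of every other sample. An assay needs at
least two observed values to have a standard deviation; assays below that
are excluded from weighting.

### Choosing the power

There is no closed-form optimum for $p$. `scan_wmp()` enumerates a grid
(default $0, 1, 3, \ldots, 19$ — zero plus the odd powers) and evaluates
each candidate $CT_0$ by two criteria: its across-sample standard deviation,
and its geNorm-style stability $M$ when scored as a pseudo-gene against all
assays. Ties go to the smallest power. The two criteria need not agree —
the sd criterion favours suppressing all variation in the reference, while
geNorm $M$ favours a reference that *moves with* the typical assay — and
both argmins are reported so the analyst can see the trade-off.

```{r scan}
sim <- simulate_ct(n_genes = 200, n_samples = 20, seed = 7)
scan_wmp(sim$matrix)
```

## Stability scoring

The geNorm-style measure is computed directly on the CT scale: for entries
$j, k$, the pairwise variation $V_{jk}$ is the standard deviation across
samples of $CT_j - CT_k$, and $M_j$ is the mean of $V_{jk}$ over partners
$k$. Because CT is already logarithmic in abundance, CT differences play
exactly the role log expression ratios play in the original formulation;
this is the only reading under which a candidate $CT_0$ vector can be scored
on the same footing as a gene, which is how the package compares
pseudo-controls. A candidate is appended as a pseudo-gene against the full
assay set by default; no iterative gene elimination or pairwise-variation
cutoff is performed — only the $M$ statistic itself.

Two properties worth knowing: $M$ is invariant to shifting any single gene
by a constant (all its pairwise differences shift together), and for a
two-gene set both $M$ values equal the sd of the pairwise difference.

## The bias diagnostics

Write $f_{gs} = CT_{gs} - \overline{CT}_{g\cdot}$ for a gene's fluctuation
and $m_s = \overline{CT}_{\cdot s} - \overline{CT}$ for the sample-mean
fluctuation. The package quantifies the expression-level-dependent bias
four ways:

1. **sd-vs-mean trend** — OLS of per-gene sd on per-gene mean CT; a
   positive slope says low-abundance assays are noisier.
2. **Correlation with the mean** — Pearson $r(f_{g\cdot}, m_\cdot)$ per
   gene; high values at high CT say that variation is systematic, not
   random.
3. **Sensitivity slope** — per-gene OLS slope of $f_{g\cdot}$ on
   $m_\cdot$ (both centered, no intercept). On complete matrices the slopes
   average exactly 1, since $m_s$ is the average of the $f_{gs}$; slopes
   above 1 mark over-responding (low-abundance) assays.
4. **Difference ratio** — the per-gene mean of $f_{gs} / m_s$. This is
   algebraically identical to the sensitivity slope when fluctuations are
   exact multiples of $m$, but the ratio is unstable where $|m_s|$ is
   small, so samples with $|m_s|$ below a guard (default 0.05 cycles) are
   excluded. The guard is a package choice: some threshold is required to
   keep the statistic finite, and 0.05 cycles is well below any
   biologically meaningful shift.

All regressions are ordinary least squares. For genes with missing wells,
the sample-mean fluctuation is recomputed over that gene's observed samples.

## The synthetic generator

No generative model is printed in the literature this method addresses; the
generator implements the minimal model reproducing the observed signatures:

$$CT_{gs} = \mu_g + s_g\,\delta_s + \varepsilon_{gs}, \qquad
  \varepsilon_{gs} \sim N(0, \sigma_g^2),$$

with gene means $\mu_g$, centered per-sample loading offsets $\delta_s \sim
N(0, \tau^2)$, sensitivity $s_g = a + b\mu_g$ and noise sd $\sigma_g = c +
d\mu_g$. Defaults, chosen once as representative of a TLDA-card study:
$\mu_g \sim U(15, 35)$ cycles (the usable CT range between strong expression
and the detection limit at 40); $\tau = 0.5$ cycles (loading variation of
the order the boxplots of real panels show); $s_g$ rising from 0.5 at CT 15
to 1.5 at CT 35, mean 1 over the range — the fitted sensitivity slopes must
average 1, so a generating mean of 1 makes the generating values directly
recoverable; $\sigma_g$ rising from 0.2 to 1.2 cycles, matching the
magnitude and direction of the sd-vs-mean trend in real panels; 20 samples,
the size of a typical two-group study, and 666 assays where a full panel is
emulated. All randomness sits behind one integer seed and is restored
afterwards, so generation never perturbs the caller's RNG stream.

What the generator does *not* emulate: amplification-efficiency differences
between assays, plate/card batch structure, truncation of the CT
distribution at the detection limit (undetected wells are spiked separately
by `spike_undetected()`), and any real biological differential expression.
Tests passing on this model therefore show that the methods behave as
designed under loading-offset bias — not that any particular real dataset
is free of other artifacts.

### What the method comparison shows

On this model, with replicates at full-panel scale (666 assays, 20
samples), two orderings hold in ≥ 95% of runs and are asserted as
acceptance properties: the top-8 pseudo-control has a smaller across-sample
sd than the single most stable gene (averaging cancels the independent
noise the single gene keeps), and the weighted mean at the geNorm-selected
power is at least as stable by geNorm as the plain mean. At smaller panel
sizes (say 150 assays) the first ordering weakens, because the minimum of
many noisy sd estimates is biased downward relative to the true best gene.

## Baseline methods

* **Quantile** (mean or median row statistic) forces identical per-sample
  distributions; ties receive the mean of the row statistics they span.
  Requires a complete matrix — silently imputing undetected wells would
  fabricate data, so the user is directed to `filter_genes()`.
* **Median-shift** subtracts a per-sample constant so all medians equal the
  median of medians; within-sample differences are untouched.
* **Cyclic loess** regresses, for every sample pair, the difference of log
  CT ($M$) on its average ($A$) and moves each sample half the fitted trend
  toward the other. It operates on $\log(CT)$ — CT is already a log-scale
  quantity, but the pairwise difference-vs-average construction is defined
  on the log of whatever is being normalized, and that convention is kept.
  Defaults span 0.7, at most 3 sweeps, tolerance 0.01 on the worst pair's
  mean $|F|$. In practice the residual drops to a plateau within 2–3 sweeps
  and further cycling only chases smoother noise, which is why the sweep
  count is capped; non-convergence is recorded in the result's provenance
  (with a warning), not raised as an error.
* **Rank-invariant set** keeps genes whose within-sample rank stays within
  `rank_window` (default 5% of the gene count) of their rank in a reference
  sample — by default the sample whose mean CT is the median of sample
  means, a deterministic middle-of-the-road choice — and uses the set's
  per-sample mean as $CT_0$.

## Undetected wells and degenerate inputs

A well at or above the sentinel (default CT 40) never crossed threshold: it
is censored, not measured. The default is to mark such wells missing rather
than impute the sentinel, because a pseudo-control built from sentinel
values would inherit a spurious ceiling; retaining them (flagged) is
supported for users who want the instrument convention. How a study's own
headline tables treated such wells is usually unstated, so both behaviors
are exposed and exclusion is the default. Downstream: stability statistics
use non-missing entries only; a gene needs two observed values for an sd;
pairwise geNorm terms use the samples where both entries are observed and a
pair with fewer than two shared samples is skipped.

Degenerate inputs are defined rather than left to chance: a constant matrix
has zero fluctuations everywhere, so sensitivity slopes are unidentifiable
(`bias_report()` reports them as `NA`) while the sd-vs-mean trend is the
flat line; a zero-variance gene gets an undefined (not zero) correlation;
ties in the top-k sd ranking break by gene id so results are reproducible.

## Cross-platform concordance

`pair_platforms()` inner-joins a ΔCT matrix with a positive intensity
matrix on gene id and log2-transforms the intensities; `concordance()`
reports Spearman's $\rho$ overall and within half-open bins of mean raw CT
(default 5-cycle bins from 15 to 35). The expected sign is negative: lower
ΔCT means higher expression. P-values come from a seeded permutation test
below 50 genes and the asymptotic t approximation at or above it — at small
n the permutation null is exact and cheap, while at large n the
approximation is accurate and the permutation cost pointless.

## Problem sizes used in the shipped checks

The test suite and the acceptance script size their simulations as: single
datasets of 200–666 genes × 20 samples for method comparison; 500 genes ×
40 samples for slope recovery (noise sd 0.05 cycles, so recovery tolerance
±0.1 reflects estimation error, not noise domination); 100 replicates at
666 × 20 for the ordering properties; 200 genes for concordance. These are
the package's choices of representative study dimensions.

## Limitations

* Perfect per-cycle doubling is assumed throughout the fold-change
  calculus; no amplification-efficiency correction is attempted.
* The weighted mean uses one global $CT_0$ per sample; a per-gene reference
  matched to each gene's expression level is a plausible refinement that
  this package deliberately does not implement.
* Differential-expression testing is out of scope; the package stops at
  normalized matrices, stability reports and fold changes.
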