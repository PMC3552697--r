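# ctnorm

Normalization of RT-PCR Cycle-Threshold (CT) data with a **weighted-mean
pseudo endogenous control**, for transcriptomics analysts working with
miRNA/gene qPCR panels (e.g. TLDA cards) who cannot trust a single
endogenous control gene.

## The problem and the method

RT-PCR reports a CT per well — the number of amplification cycles before
detection, inversely and logarithmically related to starting abundance.
Cross-sample comparison requires subtracting a per-sample reference CT₀:

    ΔCT = CT − CT₀        ΔΔCT = ΔCT − ΔCT_control        FC = 2^(−ΔΔCT)

Classical endogenous controls (RNU44, RNU48, U6, ...) are themselves
deregulated in many disease tissues, and the plain per-sample mean is
dominated by fluctuating low-abundance assays and undetected wells. CT data
additionally carry a systematic bias: low-abundance (high-CT) assays both
vary more and *over-respond* to sample loading differences.

`ctnorm` builds the reference from **all** assays, weighted by empirical
stability. With σⱼ the across-sample standard deviation of assay j and
p ≥ 0 the *weighted mean power*:

    CT₀ = Σⱼ CTⱼ · wⱼ,     wⱼ = (1/max(σⱼ, ε))^p / Σᵢ (1/max(σᵢ, ε))^p

p = 0 is the plain mean; p = 1 weights by inverse sd; p → ∞ converges to
the single most stable assay — one parameter spans the family from
"mean normalization" to "single reference gene". The power is chosen by
enumeration (`scan_wmp()`), scoring each candidate CT₀ by across-sample sd
and by a geNorm-style stability M.

The package also provides the baselines the method is compared against
(mean/median/geometric-mean, top-k stable genes, rank-invariant set,
quantile, median-shift, cyclic loess), the ΔCT/ΔΔCT/fold-change calculus,
bias diagnostics (sd-vs-mean trend, correlation with the mean, per-gene
sensitivity slopes, difference ratios), RT-PCR-vs-microarray Spearman
concordance with CT-range binning, and a synthetic CT generator with
recorded ground truth.

## Worked example

```r
library(ctnorm)

sim <- simulate_ct(n_genes = 200, n_samples = 20, seed = 7)  # biased CT data
x <- sim$matrix

scan_wmp(x)
#> wmp_scan: weighted-mean power selection
#>  power mean_ct0  stdev genorm
#>      0   25.577 0.4578 0.7323
#>      1   23.353 0.3898 0.7302
#>      3   19.340 0.2818 0.7415
#>      5   17.234 0.2309 0.7549
#>      7   16.359 0.2123 0.7637
#>      9   15.957 0.2066 0.7695
#>     11   15.738 0.2058 0.7736
#>     13   15.603 0.2069 0.7765
#>     15   15.514 0.2086 0.7785
#>     17   15.451 0.2107 0.7801
#>     19   15.406 0.2129 0.7814
#> best power by sd: 11   by geNorm M: 1
```

Each row is one candidate reference: the power, the mean of its CT₀ values
across the 20 samples, their standard deviation (lower = steadier
reference), and the geNorm M of the CT₀ scored as a pseudo-gene (lower =
more stable relative to the assays). Raising the power shifts weight onto
stable, here high-abundance, assays: the mean CT₀ drops from 25.6 toward 15
and the sd shrinks from 0.46 to ~0.21 cycles. The two criteria pick
different powers (11 by sd, 1 by geNorm) — the sd criterion rewards a quiet
reference, geNorm rewards one that moves with the typical assay.

```r
delta <- normalize_ct(x, method = "weighted", wmp = 11)   # ΔCT matrix

bias_report(x)
#> bias_report: 200 genes
#>   sd-vs-mean-CT trend: slope 0.0525, intercept -0.4943
#>   gene_id mean_ct     sd corr_with_mean sensitivity_slope mean_difference_ratio
#> 1 gene001   34.81 1.1295         0.4682            1.1550                0.3820
#> 2 gene002   22.85 0.7775         0.4967            0.8436                0.2455
#> 3 gene003   17.33 0.4910         0.7170            0.7691                0.8000
#>   ... 197 more genes
```

The positive trend slope (+0.05 cycles of sd per cycle of mean CT) and the
sensitivity slopes above 1 for high-CT genes are the bias signatures: the
low-abundance gene001 (mean CT 34.8) is noisier *and* over-responds to
loading differences (slope 1.16 > 1), while the abundant gene003 responds
at only 0.77.

A shell entry point covers the same ground:

```sh
exec/ctnorm simulate  --out ct.csv --n-genes 200 --n-samples 20 --seed 7
exec/ctnorm normalize --in ct.csv --out delta.csv --method weighted --wmp 11
exec/ctnorm scan-wmp  --in ct.csv --out scan.csv
```

Every run writes a `*.provenance.txt` sidecar recording the method,
parameters and seed.

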