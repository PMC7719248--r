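---
title: "Selecting endogenous-control miRNAs from RT-qPCR Ct data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting endogenous-control miRNAs from RT-qPCR Ct data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmiR)
```

## The problem and the measurement model

A cycle-threshold (Ct) value is inversely proportional to the log2 abundance
of its template. For circulating miRNAs measured across a patient cohort, an
observed Ct decomposes, to a good approximation, additively:

$$Ct_{ij} = \mu_i + \delta_{i,g(j)} + b_j + \varepsilon_{ij},$$

where $\mu_i$ is the assay baseline, $\delta_{ig}$ a diagnostic-group effect,
$b_j$ a *per-sample technical shift* common to every assay in sample $j$
(extraction yield, reverse-transcription efficiency, storage history), and
$\varepsilon_{ij}$ gene-specific noise with SD $\sigma_i$. An endogenous
control (EC) is useful exactly when $\delta_{ig} \approx 0$ and $\sigma_i$ is
small: its measured variation is then almost entirely $b_j$, the quantity one
wants to divide out. All three stability algorithms in this package are
implicitly built on this additive model, which is why the synthetic-data
generator simulates from it directly.

Everything operates on Ct rather than $-$Ct or linearized quantities: every
statistic used is built from variances and centered differences, so the sign
convention changes no value and no rank.

## Quality control

Determinations are deleted when Ct ≥ 35 cycles (the bound is inclusive), when
the instrument reported "undetected", or when the amplification curve was
flagged irregular. The irregular-curve call is an *input* flag: it comes from
visual or instrument-side curve inspection, which this package deliberately
does not attempt to recompute from fluorescence data. Removal reasons are
counted once per determination with the fixed precedence irregular >
undetected > threshold, purely so that QC reports are deterministic. No lower
Ct bound is applied. Duplicate wells are collapsed by the mean (median
available); pairs more than 1.0 cycle apart are reported as discordant but
still used — the spread threshold is a warning device, not a filter, because
silently dropping discordant duplicates would bias dispersion estimates
downward exactly for the unstable genes one is trying to detect. Candidate
genes must be detected in all samples by default (`min_fraction = 1`):
a normalizer that is sometimes missing is operationally useless.

## Candidate discovery: mean-centering and CCR

The per-sample *global mean* over all analyzed genes estimates
$\bar\mu + b_j$; subtracting it cancels $b_j$ exactly. Candidates are then
(i) the genes with the smallest sd(ΔCt), and (ii) the genes whose **raw**
profile tracks the global-mean profile, scored with Lin's concordance
correlation

$$\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$

which, unlike Pearson's $r$, also penalizes location offsets: a gene far from
the overall expression level is down-weighted even if perfectly correlated,
which restricts the selection to genes that could stand in for the global
mean — the point of the concordance-correlation-restricted (CCR) approach.
Variances in $\rho_c$ use $n-1$ denominators so that $\rho_c(x,x) = 1$
exactly at any $n$; the classical definition uses $n$, and the two only
differ through the location term (the choice is recorded here and in the
`lin_ccc()` documentation). The final candidate set is the intersection of
the $k_{max}$ smallest-SD genes and the genes with $\rho_c \ge$ `ccc_min`
(defaults 10 and 0.9; both are explicit configuration, echoed in every output,
because published workflows report candidate counts but rarely their exact
cutoffs). `ccr_select(refine = TRUE)` optionally re-scores against the mean
of the first-pass selection; the single pass against the all-gene mean is the
default and primary definition.

## The three stability algorithms

**geNorm.** $V_{jk} = \mathrm{sd}_j(Ct_k - Ct_j)$ is the SD of the log2
expression ratio at 100% amplification efficiency;
$M_j = \sum_{k \ne j} V_{jk}/(n-1)$. Both are exactly invariant to $b_j$ and
to per-gene constants. The full-set $M$ is reported per gene, and the
iterative procedure (drop the highest-$M$ gene, tie broken to the
lexicographically last id, recompute, stop at two) yields the ranking; the
final pair is unordered by construction and shares rank 1. Efficiency
correction is out of scope — with efficiency fixed at 2 the ratios are plain
Ct differences. The $V_{n/n+1}$ normalization-factor diagnostic (with its
conventional 0.15 guidance value) is provided as `genorm_vn()` but is not
part of the core workflow.

**BestKeeper.** Descriptive statistics of *raw* Ct (geometric and arithmetic
means, range, SD, CV), the per-sample index (geometric mean over candidates),
and each gene's Pearson $r$ against the index with a $t$-distribution p-value
on $n-2$ df. The dispersion is the sample SD by default; the mean absolute
deviation used by some versions of the original spreadsheet is available as
`var_measure = "mad"` and the choice is stored in the result. Ranking is by
descending $r$ ("values closer to 1.0 indicate greater stability"), with
genes whose dispersion exceeds `sd_max` = 1 cycle flagged per BestKeeper's
published exclusion guidance. Because BestKeeper works on raw Ct it is *not*
shift-invariant — a property the test suite asserts as a documented contrast
with geNorm and mean-centering. The gene-vs-index correlation is the primary
stability reading; the mean pairwise correlation is also emitted since
published tables do not always say which was used.

**NormFinder.** Within each group the matrix is double-centered,
$r_{igj} = y_{igj} - \bar y_{ig\cdot} - \bar y_{\cdot gj} + \bar y_{\cdot g\cdot}$,
giving $s^2_{ig}$ on $n_g - 1$ df. The per-sample centering injects a share
of every other gene's noise, which the cross-gene unbiasing removes:
$\hat\sigma^2_{ig} = (s^2_{ig} - \bar s^2_g/(I-1)) \cdot I/(I-2)$, floored at
zero (the subtraction can go negative in small samples, and the score takes a
square root downstream). Under the additive model this is exactly unbiased:
$E[s^2_{ig}] = \sigma^2_{ig}(1 - 2/I) + \sum_k \sigma^2_{kg}/I^2$. Intergroup
differences are double-centered so they sum to zero over genes within group
and over groups within gene; their between-gene variance is estimated on
$(I-1)(G-1)$ df — the two sum-to-zero constraints — as
$\hat\gamma^2 = \max(0, \sum d^2_{ig}/((I-1)(G-1)) - \overline{v})$ with
$v_{ig} = \hat\sigma^2_{ig}/n_g$, the differences are shrunk by
$\hat\gamma^2/(\hat\gamma^2 + v_{ig})$, and the stability value is the mean
over groups of $|\tilde d_{ig}| + \sqrt{\hat\gamma^2 v_{ig}/(\hat\gamma^2 +
v_{ig})}$. With one group the intergroup machinery is skipped and the value
reduces to $\sqrt{\hat\sigma^2_i/n}$, keeping units consistent. Published
variants of the shrinkage differ in minor details; the formulas above are the
ones frozen in this package, and they are validated by parameter-recovery
simulations (below) rather than by equality with any legacy script.

*Degenerate regime.* If $\hat\gamma^2 = 0$ — typical when no gene has any
real group effect — all $G \ge 2$ stability values collapse to 0 and ranking
falls back to gene id; for small positive $\hat\gamma^2$ the ordering is only
weakly identified (noisier genes are shrunk harder, which can invert ranks).
NormFinder's intergroup component is informative when some gene actually
differs between groups; on effect-free panels the $G = 1$ reading
($\sqrt{\hat\sigma^2/n}$) is the meaningful one. A 0/0 guard returns 0 for
the score terms when a floored variance meets $\hat\gamma^2 = 0$.

## Consensus

Each algorithm contributes a rank vector over the same genes (mean ranks on
ties; geNorm's final pair becomes 1.5/1.5). The combined score is the
geometric mean of the three ranks — the convention popularized by
RefFinder-style tools — with arithmetic mean and Borda sum as config-switchable
alternatives; since only ranks are consumed, the consensus is invariant to
monotone transformations of the underlying metrics. Per-gene Kruskal-Wallis
p-values across diagnostic groups (average-rank tie correction, $\chi^2$
approximation on $G-1$ df; an all-tied gene gets $H = 0$, $p = 1$ by
convention) are reported as supporting evidence. They do **not** veto panel
selection by default — a non-significant group difference is a desirable
property of an EC, not a selection statistic — though `kw_p_min` can turn
them into a filter.

## The synthetic-data generator

`simulate_ct_dataset()` draws from
$Ct_{igjr} = \mu_i + \delta_{ig} + b_j + e_{ij} + w_{ijr}$ with
$b_j \sim N(0, \tau^2)$, $e_{ij} \sim N(0, \sigma_i^2)$,
$w_{ijr} \sim N(0, \sigma_w^2)$ for duplicate wells, and values above the
detection limit (35 cycles) *deleted* — reported as missing with an
`undetected` flag, mirroring the QC rule — rather than censored. Gaussian
noise on the Ct scale is log-scale expression noise, the implicit model of
all three algorithms. What the generator does **not** emulate: plate/batch
structure, amplification-efficiency differences between assays, correlated
(co-regulated) miRNA modules, non-Gaussian heavy tails, and age or other
covariate gradients. Passing recovery tests therefore demonstrate that the
estimators track their own model faithfully — not that any particular
clinical dataset satisfies that model.

Two preset families fix the study conditions used throughout the tests.

**Two-cohort presets** (`screen_discovery`, `endtoend_validation`): a
60-assay screening profile on 19 single-group samples, then the same panel on
a 126-sample validation cohort (24/25/22/55 in CTL/MCI−/MCI+/AD) in
duplicate ($\sigma_w = 0.15$). Nine candidate-grade genes sit *at* the global
mean level (24.3–24.7 cycles) — by construction, since the CCR criterion's
location penalty selects exactly such genes — among 51 background assays
spanning 19–30 cycles with $\sigma$ 0.6–1.2. The screening technical shift is
$\tau = 0.8$ cycles, reflecting the large sample-to-sample variability of
plasma extraction and RT; validation uses $\tau = 0.5$. In validation the
four planted ECs keep $\sigma$ = 0.15–0.18 with zero group effects, while the
five weaker candidates get $\sigma$ = 0.40–0.65 and three of them carry
0.5–1.0-cycle shifts in single groups — the heterogeneous validation cohort
is expected to expose instability that a homogeneous 19-sample screen cannot.

**Recovery preset** (`recovery`; `paper_validation` is the same panel on the
24/25/22/55 cohort shape): nine assays, four groups of 25, $\tau = 0.8$,
baselines 20–26 cycles (candidate ECs are highly expressed; this also keeps a
>5 SD margin to the detection limit so the panel stays complete). Noise SDs
are 0.2, 0.46, 0.61, 0.74, 0.84, 0.94 for the six effect-free genes —
approximately evenly spaced in $\sigma^2$ — and 0.9, 1.0, 1.5 for the three
genes carrying group shifts of 0.8, 0.9, 1.0 cycles, each in a different
group. The layout is deliberate, not arbitrary:

- the composite ground truth (mean absolute centered group effect plus
  $\sigma_i$) is strictly increasing in gene index, and each algorithm's
  *population-level* ordering agrees with it, so rank-recovery tests measure
  estimation noise rather than model disagreement; this requires the group
  effects to sit on the least-stable genes — an effect planted on a quiet
  gene is weighted very differently by NormFinder (which sees shrunken
  $|d|$ against $\sigma/\sqrt n$) than by geNorm/BestKeeper (which see the
  variance contribution $\delta^2 p(1-p)$);
- BestKeeper's $r$-vs-index is monotone decreasing in a gene's total variance
  only while $\sigma_i^2 < 7\tau^2$ (beyond that, the gene's own share of the
  index covariance dominates and $r$ turns back up); $\tau = 0.8$ keeps even
  the noisiest gene ($\sigma^2 = 2.25$) safely inside the monotone range,
  and even $\sigma^2$ spacing matches where BestKeeper and geNorm resolve
  genes;
- the noisiest gene is separated from the rest of the pack (all other total
  variances ≤ 1.2) so that its first exclusion by geNorm is near-certain,
  and effects near the top of their range keep $\hat\gamma^2$ well away from
  its degenerate zero floor.

## Problem sizes and numerical conventions

The test suite and the acceptance script use: brute-force oracle equivalence
to 1e-12 on matrices up to 6 genes × 10 samples; shift invariance to 1e-9;
NormFinder variance calibration on a single group with 6 genes × 200 samples
(100 replicates, mean $\hat\sigma^2$ within 15% per gene); ordering recovery
on the presets above over 100 seeds; Kruskal-Wallis null calibration on 1000
effect-free genes (4 × 25 samples); and 100 replicate two-cohort studies for
end-to-end panel recovery. These sizes give stable Monte-Carlo estimates
while keeping a full run in tens of seconds on one CPU.

Conventions, collected: sample SDs use $n-1$ throughout; ranking ties break
by gene id everywhere a total order is needed, and by mean rank where rank
*values* are consumed (consensus); variance estimates are floored at zero
before square roots; the QC filter deletes Ct ≥ 35 (the bound is inclusive,
as printed), while the generator reports values strictly above its detection
limit as undetected — both boundaries are asserted in tests; matrices
are validated to [0, 45] cycles on construction, as errors rather than
silent clipping; CSV round trips are exact on identifiers and flags and
within 1e-9 on values (15 significant digits are written).

## Known limitations

No amplification-efficiency correction (Ct differences are treated as log2
ratios); geNorm accepts pairwise-complete data although the canonical
procedure assumes complete matrices (after the completeness rule this only
matters in exploratory use); BestKeeper p-values are descriptive, not
multiplicity-adjusted; NormFinder's intergroup component is weakly identified
near the null (see above) and no covariate adjustment (e.g. age) is offered
beyond reporting; the consensus weights the three algorithms equally, which
is a convention rather than an optimality result.
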