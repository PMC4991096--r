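# signsum

Heterogeneity-robust gene ranking with the **sign-sum statistic** — a
two-sample U-statistic that averages the signs of subset-mean differences
between a disease and a normal group.

## Who this is for

Anyone ranking genes (or any per-feature scores) from two-group expression
data in diseases with subtypes. Ordinary t-statistic rankings are unstable
there: a gene whose disease-group expression is a *mixture* — shifted in
one patient subset, normal-like in another — can carry exactly the same
t-score as a gene that is shifted in every patient, yet replicate far
worse across cohorts. `signsum` scores genes by how *consistently* small
disease subsamples exceed normal subsamples, which separates the two gene
types where the t-statistic cannot.

## The statistic

For gene $j$, subset sizes $a$ (disease) and $b$ (normal):

$$U^S_j \;=\; \frac{1}{k_0 k_1}\sum_{l=1}^{k_1}\sum_{m=1}^{k_0}
H\!\left(\bar X_{j1l}-\bar X_{j0m}\right),
\qquad k_1=\binom{n_1}{a},\; k_0=\binom{n_0}{b},$$

where $H$ is the Heaviside step with $H(0)=1$ and $\bar X_{jyt}$ are
subset means. $U^S_j\in[0,1]$; at $a=b=1$ it is the Mann–Whitney pair
proportion (Wilcoxon rank-sum, rescaled). Small $a$ makes the statistic
sensitive to a normal-like component in the disease group; larger $b$
stabilizes each comparison — hence the default family $s_{1,b}$ with
$b\in\{1,5,10\}$. The package also provides the Welch t, the subsample-t
benchmark $U^T$, asymptotic confidence intervals for both statistics under
normal / normal-mixture models, a calibrated simulation study, and
split-half reproducibility metrics (top-k overlap, ORRS, DLDA test-AUC).

## Worked example

Score a calibrated synthetic dataset in which 100 "homo" genes (shifted in
all disease samples) compete with 100 "hetero" genes (shifted in only half
of them) that have the *same* asymptotic t-statistic, plus 800 nulls:

```r
library(signsum)

cfg <- simulation_config("I", n = 200, n_reps = 20, master_seed = 7)
res <- run_simulation_study(cfg)
res
#> <signsum_sim> situation I, n=200, 20 reps; homo genes in top 100:
#> # A tibble: 1 × 7
#>   situation     n t           `t_1,1`     `s_1,1`     `s_1,5`     `s_1,10`
#>   <chr>     <dbl> <chr>       <chr>       <chr>       <chr>       <chr>
#> 1 I           200 49.3 (3.79) 49.4 (3.70) 61.4 (3.89) 81.2 (2.49) 83.5 (2.54)
```

Each cell is the mean (sd) number of homo genes in the top 100. The
t-statistic sits at ~50 of 100 — it cannot tell the two gene classes apart,
by construction — while the sign-sum statistic with $a=1,b=10$ ranks ~83
homo genes into the top 100. The asymptotic theory says why:

```r
mods <- situation_models("I")   # homo and hetero models with equal t
asymptotics_grid(mods$homo, mods$hetero, a = 1, b = c(1, 5, 10), n = 200)
#>   a  b   e_us e_us_hetero ucl_diff
#> 1 1  1 0.7602      0.7386   0.0173
#> 2 1  5 0.8193      0.7475   0.0644
#> 3 1 10 0.8298      0.7482   0.0734
```

`e_us` is the limiting mean of $U^S$ for the homo gene, `e_us_hetero` for
the calibrated hetero gene, and `ucl_diff` the gap between their 95 % upper
confidence limits — positive and growing with $b$, i.e. the two gene
classes separate even though their t intervals coincide exactly.

On real data, use `read_expression()` (TSV/CSV, genes × samples, plus a
two-column label file), then `sign_sum()`, `rank_genes()` and
`run_reproducibility()`; or the command-line wrapper:

```sh
exec/signsum rank --expression expr.tsv --labels labels.tsv --stat s_1,10 --out ranking.tsv
exec/signsum reproducibility --expression expr.tsv --labels labels.tsv --stats t,s_1,10 --auc
```

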