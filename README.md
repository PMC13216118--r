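# evidsat

Theme emergence and saturation modelling for early-adoption clinical
literature.

## What problem this solves

In the early adoption phase of a new medical device, randomized trials are
rare and most published evidence is descriptive: case series reporting the
device's clinical **utilities** and its workflow-related **operational
issues**. evidsat is for researchers doing structured evidence synthesis on
such corpora. It quantifies *when* descriptive themes first appear in the
literature and *whether the theme set has saturated*, by:

1. encoding articles and themes as a binary **presence matrix**
   (articles × themes);
2. checking coding reliability between two analysts (agreement rate and
   Cohen's κ with Landis–Koch interpretation);
3. building the **cumulative occurrence proportion** series under the
   first-occurrence rule,
   `y_n = 100 · T_sum,n / T_sum,End`, on two axes — elapsed months and
   cumulative publication count;
4. fitting and comparing saturation curves by nonlinear least squares:
   the exponential plateau `f(t) = 100 (1 − e^(−t/Tc))` and the logistic
   `f(t) = 100 / (1 + a e^(−bt))`, ranked by AICc, adjusted R² and RMSE;
5. inverting the selected model to estimate the time (or number of
   publications) to reach 50%, 80% and 99.9% of the eventual theme set,
   with confidence intervals;
6. validating the whole pipeline by simulation: a seeded synthetic corpus
   generator with known time constant and a parameter-recovery harness.

The package ships its study dataset: `davinci_corpus()`, the da Vinci
surgical system's early-adoption corpus — 19 clinical studies (2001–2004,
between FDA clearance and the first randomized trial) coded for 7 utility
and 9 issue themes.

## Worked example

```r
library(evidsat)

dav <- davinci_corpus()              # presence matrix + observation window
ser <- emergence_series(dav, "utility")
cmp <- compare_models(series_points(ser, "months"))
cmp$fits$exponential
#> <saturation_fit> exponential on 20 points
#>   tc  =   8.2637  (SE 0.4091, 95% CI 7.4074 to 9.1200)
#>   rss 260.821, rmse 3.611, adj. R2 0.9729, AICc 56.07
cmp$table[, c("kind", "rmse", "adj.r.squared", "AICc")]
#>   kind         rmse adj.r.squared  AICc
#> 1 exponential  3.61         0.973  56.1
#> 2 logistic     5.54         0.932  76.0
```

The utilities curve is exponential with time constant **Tc ≈ 8.26 months**:
63.2% of the utility themes that would ever be described had emerged about
eight months after the device's clearance, and the exponential clearly
outperforms the logistic on every statistic. Inverting the fit:

```r
threshold_ci(cmp$fits$exponential, c(50, 80, 99.9))
#>   target_pct estimate ci_low ci_high method
#> 1       50       5.73   5.13    6.32 transform
#> 2       80      13.3   11.9    14.7  transform
#> 3       99.9    57.1   51.2    63.0  transform
```

Half of the utility themes had surfaced by ~5.7 months; near-complete
saturation (99.9%) takes ~57 months. Issue themes are slower (Tc ≈ 16.3
months — run the same pipeline with `"issue"`), an asymmetry between how
fast favourable device features and workflow problems get described.
`fit_report(dav)` runs the full grid (both categories × both axes),
returns the threshold table and ggplot figures, and can write everything
to a directory.

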