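# sphmdl — spherical minimum description length for histogram bin selection

How many bins should a histogram have? Model-selection criteria answer by
trading goodness of fit against complexity, but the classical ones (AIC,
BIC, two-part MDL, and even the geometric "razor" MDL) carry out their
Laplace approximation in flat Euclidean parameter space. The regular
histogram's parameters are not flat: writing bin heights as squares,
$c_k = u_k^2$, the normalization constraint puts $u$ on the hypersphere
$\sum_k u_k^2 = K/R$ (with $K$ bins over range $R$). **Spherical MDL**
performs the Laplace step *on that sphere*, where the Gaussian integral
becomes a von Mises–Fisher normalizing constant, and scores a candidate
bin count $K$ by

$$\mathrm{MDL}_{\mathrm{sphere}} = -\sum_{k} 2 v_k \log \hat u_k
  \;+\; \log V_H(K) \;+\; \frac{K}{2}\log\frac{N}{2\pi}
  \;-\; \log I_{K/2-1}(4N),$$

where $v_k$ are bin counts, $\hat u_k = \sqrt{v_k K/(NR)}$ is the
constrained MLE, $V_H(K) = 2^K V_M(K)$ is the Riemannian volume of the
histogram's parameter manifold ($V_M$ = unit-sphere surface area, maximal
at $K = 7$), and $I_\nu$ is the modified Bessel function, evaluated
entirely in the log domain (the unscaled $I_{K/2-1}(4N)$ overflows doubles
near $N \approx 180$).

The package is for statisticians and data analysts who want a
geometry-aware automatic bin count, and for anyone studying how selection
criteria penalize constrained (spherical) parameter spaces. It provides:

* `select_bins()` / `histogram_score_table()` — bin selection by
  `"spherical"`, `"aic"`, `"bic"`, `"mdl2"` (two-part), or `"mdl"`
  (asymptotic/razor), with every score decomposed into fit + complexity;
* `sphere_surface_log_volume()`, `vonmises_log_normalizer()`,
  `log_bessel_i()` — the underlying log-domain geometry, stable to
  $N = 10^6$, $K = 500$ and beyond;
* `mixture_registry()` / `mixture_sample()` — the four Gaussian-mixture
  benchmark densities (bimodal, skewed unimodal, trimodal, claw) with
  seeded, stream-safe sampling;
* `deviation_study()` — the simulation comparing all criteria against
  spherical MDL over repeated trials;
* a command-line front end `inst/cli/sphmdl.R` with `select` and
  `simulate` subcommands.

## Worked example

Draw 60 points from the bimodal benchmark mixture and select bins:

```r
library(sphmdl)
x <- mixture_sample(mixture_registry()$bimodal, 60, seed = 42)
sel <- select_bins(x, 1, 30, "spherical")
sel
#> Bin selection by SPHERICAL over K in [1, 30]: K* = 1
head(sel$scores[, c("K", "fit_term", "complexity_term", "score")], 6)
#>  K fit_term complexity_term  score
#>  1    91.80          -233.8 -142.0
#>  2    91.50          -230.9 -139.4
#>  3    88.51          -228.3 -139.8
#>  4    85.51          -226.1 -140.6
#>  5    85.01          -224.0 -138.9
#>  6    81.53          -222.0 -140.4
```

The fit term (the histogram negative log-likelihood) falls as bins are
added, while the complexity term rises by roughly $2$–$3$ nats per extra
bin at $n = 60$; here the penalty wins and a single bin is chosen. The
comparators on the *same* sample choose

```r
sapply(c("aic", "bic", "mdl2", "mdl"),
       function(cr) select_bins(x, 1, 30, cr)$K_star)
#>  aic  bic mdl2  mdl
#>    6    4    6    1
```

— AIC and two-part MDL are the forgiving criteria, and spherical MDL never
chooses more bins than asymptotic MDL (a per-trial property, tested over
every trial of the study). A scaled-down deviation study:

```r
deviation_study(trials = 100, seed = 42)
#> Deviations from spherical MDL over 100 trials per density (n = 60, K in [1, 30], seed 42)
#>                 aic bic mdl2 mdl
#> bimodal          68  20   60   0
#> skewed_unimodal  57   6   52   0
#> trimodal         69  14   56   0
#> claw             75  14   60   1
#> Total           269  54  228   1
```

Each cell counts trials in which that criterion's chosen bin count differed
from spherical MDL's on the same sample: AIC and two-part MDL disagree on
more than half of all trials, BIC on roughly one in eight, asymptotic MDL
almost never.

From a shell:

```sh
Rscript inst/cli/sphmdl.R select --input data.csv --criterion spherical
Rscript inst/cli/sphmdl.R simulate --density all --trials 2500 --seed 1 --out table.tsv
```

## Acceptance script

`scripts/acceptance.R` re-runs the full simulation study from scratch —
2500 trials of $n = 60$ per benchmark density, candidate bin counts
$1..30$, all five criteria on each sample — and writes the headline
deviation totals (asymptotic-MDL, BIC and AIC totals across the four
densities, plus the bimodal asymptotic-MDL count) as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It finishes in under a minute on one CPU.

## Vignette

`vignettes/spherical-mdl.Rmd` documents the derivation, the log-domain
Bessel strategy (scaled base Bessel with Hankel and Olver expansion
fallbacks, pinned to arbitrary-precision oracles), the radius-power
convention that cancels inside the criterion, the stated simulation
configuration, and what the benchmark study does and does not establish.
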