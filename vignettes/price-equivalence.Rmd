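---
title: "Validating multi-source market price data: model, tests, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating multi-source market price data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pricequiv)
```

## The problem

Food-security monitoring increasingly mixes price data of very different
provenance: sparse observations by trained enumerators, high-volume
crowdsourced submissions from phone apps, and model-imputed monthly series
that fill gaps in intermittent surveys. Before these sources can be used
interchangeably, one has to ask whether they measure the *same* underlying
market price, or merely correlated ones. Correlation alone cannot answer
this: two different commodities can co-move tightly under shared inflation,
and a systematic markup leaves the Pearson coefficient untouched.
`pricequiv` implements a formal equivalence framework for paired price
series, together with the preprocessing that gets heterogeneous submissions
onto a comparable footing and a synthetic-data generator that lets every
statistical property of the framework be verified by Monte Carlo.

## The measurement model

Each source is modelled as a noisy observation of a latent log price:
$$X_t = x_t + \tau + e_t, \qquad Y_t = y_t + v_t,$$
with independent errors $e_t \sim N(0, \sigma_e^2)$,
$v_t \sim N(0, \sigma_v^2)$ and an optional fixed markup $\tau$ (transport
costs, packaging discounts). The latent log price is a random walk with
deterministic drift,
$$x_t = x_{t-1} + c_t + \epsilon_t,$$
whose innovations follow a skewed generalized error distribution: a
two-piece (Fernandez–Steel-type) skewing of the exponential-power kernel
$g(u) \propto \exp\{-(|u|/\sigma)^k\}$, with skewness $s$ ($s = 1$
symmetric) and shape $k$ ($k = 2$ Gaussian kernel, $k = 1$ Laplace). In this
parameterization $s = 1, k = 2$ is exactly $N(\mu, \sigma^2/2)$ — the
scaling constant $1/\sqrt{2}$ is asserted in the unit tests — and the draw
is generated exactly via a gamma transform of the half-kernel plus a
two-piece sign flip. The choice of the two-piece construction over other
skew-GED variants is deliberate: it is the minimal documented extension that
exposes exactly the four parameters $(\mu, \sigma, s, k)$ and recovers the
symmetric family at $s = 1$.

Heavy tails and skewness are not a technicality here. Commodity price
innovations in volatile markets are typically non-normal, and the entire
discriminating power of the equivalence criterion rests on that fact, as
explained below.

## The difference sequence and the three tests

For a paired series the package forms
$D_t = \ln X_t - \ln Y_t$. Two regimes matter:

* **Shared process.** If both sources track the same latent price, the walk
  cancels and $D_t = \tau + e_t - v_t$ is i.i.d.
  $N(\tau, \sigma_e^2 + \sigma_v^2)$ — regardless of how non-normal the
  latent innovations are.
* **Divergent processes.** If the sources track *different* walks that share
  a drift (common inflation), the drift cancels but the innovations do not:
  $D_t$ is itself a random walk with increments
  $\delta_t = \epsilon^x_t - \epsilon^y_t$, whose density is the convolution
  of the two innovation densities. Non-normal innovations make $\delta$ —
  and hence $D$ — non-normal.

Three tests interrogate $D$:

1. **Shapiro–Wilk on $D$** (via the standard AS R94 implementation in
   `stats::shapiro.test`): rejection indicates the sources capture different
   dynamics.
2. **Paired t against $\tau$**: $t = (\bar D - \tau)/(s_D/\sqrt n)$ with
   $n - 1$ df. $\tau$ defaults to 0 and is never estimated from the tested
   differences — testing $H_0: E[D] = \bar D$ would be circular.
3. **Variance ratio** $F = s_X^2 / s_Y^2$ with $(n_x-1, n_y-1)$ df and
   two-sided $p = 2\min\{P(F \le f), P(F \ge f)\}$ (sidedness is a package
   choice; the framework's sources do not fix it).

`classify_agreement()` combines them into six labels: `not_equivalent`
(SW rejects), then — conditional on the innovation-normality precondition —
`full_equivalence`, `equivalence_unequal_variance`,
`equivalence_fixed_markup`, or `equivalence_markup_and_variance` by the
t/F outcomes. The fourth named level is our addition: the (t rejects,
F rejects) cell is a perfectly coherent outcome that the three-level
narrative leaves unnamed.

### Why the precondition branch exists

Normality of $D$ is a *failure-to-reject* criterion, and it only carries
information when the individual series' innovations are non-normal: two
*different* Gaussian-innovation walks also produce (jointly) Gaussian
differences, so a normal-looking $D$ would be vacuous evidence. The package
therefore tests each side's first-differenced log series
(`innovation_normality()`) and returns `inconclusive_normal_innovations`
when neither side rejects. This makes explicit a caveat that is otherwise
easy to silently ignore; the power study below quantifies it.

## Concordance layer

`pearson_concordance()` reports $r$, $r^2$, $n$ and a two-sided p-value from
the exact t transform ($n-2$ df). Correlations are computed on price levels
(NGN/kg), the scale on which practitioners compare sources; equivalence
tests run on logs. Affine invariance — $r(aX+b, Y) = \mathrm{sign}(a)\,
r(X,Y)$ — is asserted exactly in the tests; it is the reason correlation is
blind to fixed markups and why the equivalence suite is needed at all.
`lag_profile()` shifts one series against the other (positive lag: second
series lags the first — the convention is printed, because lead/lag sign
ambiguity is a classic source of misread results), and `nearest_market()` /
`admin_centroid()` implement spatial matching of administrative units to the
closest market series by haversine distance, with exact ties broken by
smallest market id. Centroids are coordinate means, a planar approximation
chosen because the package carries no boundary polygons.

## Preprocessing

Raw submissions arrive in heterogeneous packaging (kg, mudu, 5–100 kg
bags). `to_price_per_kg()` divides total price by quantity × unit weight;
records with unknown units or non-positive values go to a rejects table with
reasons, never silently dropped (row conservation is a tested invariant).
`tukey_screen()` keeps values inside $[Q_1 - k\,\mathrm{IQR},\,
Q_3 + k\,\mathrm{IQR}]$, single pass, optionally intersected with
user-supplied plausibility bounds; $k$ defaults to the classic 1.5 since no
stronger prior is available, and fences are computed per
commodity–subtype–source over the full window. With fewer than 4 values the
fences are skipped (quartiles would be meaningless) and only bounds apply.
`aggregate_prices()` takes unweighted means per ISO week or calendar month
(week convention is a package choice, stated rather than hidden), suppressing
periods below `min_n` (default 1, because enumerator streams legitimately
have single monthly points).

## The synthetic-data generator

`make_scenario()` encodes four regimes: `null_same_process`,
`fixed_markup` ($\tau = 0.1$ log units by default), `unequal_variance`
($\sigma_v = 0.06$ vs $\sigma_e = 0.02$), and `divergent_walks` (two walks,
element-wise identical drift vectors, independent heavy-tailed innovations,
$k = 1$, $\sigma = 0.05$). Default horizons and noise levels — $T = 35$
periods, $x_0 = \ln 500$ NGN/kg, drift 0.005 per period, innovation scale
0.03, measurement sds 0.02 — were fixed once as plausible magnitudes for a
weekly staple-price series in a high-inflation setting (drift of 0.5% per
week ≈ 30% annualised; measurement error of ~2% per aggregated
observation). The record-level generator adds the realism the series-level
view abstracts away: Poisson submission counts, packaging mix, quantities,
market geography, multiplicative gross outliers (default magnitude 10,
emulating misplaced digits and wrong-unit entries), and a monthly OHLC
product of which only the close is consumed downstream. What it does *not*
emulate: contributor-level correlation (all submissions are independent),
attrition, spatially heterogeneous price levels across markets, or
lag structure between sources — so passing Monte-Carlo checks demonstrate
the statistical machinery is correct under its stated model, not that real
feeds satisfy that model.

## Monte-Carlo verification design

Replicate $i$ of a study with master seed $S$ uses seed
$(S + 7919\,i) \bmod (2^{31}-1)$, so any replicate can be re-run in
isolation and studies are bit-reproducible.

**Calibration** (`run_calibration`, default $R = 1000$, $T = 35$): runs the
measurement-error regime literally, holding the latent price flat (zero
drift, zero innovation scale). This choice is forced by the F test: its
$F(n-1,n-1)$ reference assumes independent samples, and with a live shared
walk both sample variances are dominated by the common walk term, making the
test radically conservative. With the latent flat, $X$ and $Y$ are i.i.d.
normal and all three tests should reject at $\alpha$; the study also checks
$\overline{\widehat{\mathrm{Var}}(D)} \approx \sigma_e^2 + \sigma_v^2$.
The SW-on-$D$ and t components are calibrated in either regime, since $D$
never contains the latent walk under the null.

**Power** (`run_power`, $R = 500$ per grid point): divergent walks with no
measurement layer (the alternative concerns the latent processes; adding
measurement noise superimposes an MA(1) nuisance on the increments). Two
rates are reported. SW applied to the *levels* of $D$ mirrors the procedure
applied to real data, but a random walk's values are far from an i.i.d.
normal sample for *any* innovation law — empirically the level-based rate
grows with $T$ even under Gaussian innovations, detecting nonstationarity
rather than non-normality. SW applied to the *increments* of $D$ isolates
the distributional claim: Gaussian innovations give exactly the nominal
rate, heavy tails ($k = 1$) give power rising in $T$. Both are computed; the
increment-based rate is the theoretically meaningful one, and the collapse
of power under Gaussian innovations is precisely why the classifier's
inconclusive branch exists.

**Convolution oracle** (`delta_convolution_oracle`): the density of
$\delta = \epsilon^x - \epsilon^y$ is computed by discretising both skewed-GED
densities on a common grid (tails cut at $10^{-9}$ per side; 8192 points per
input) and convolving via FFT; the study checks the Kolmogorov–Smirnov
distance between this quadrature CDF and $10^5$ sampled differences, and in
the Gaussian case the variance against the analytic
$(\sigma_x^2 + \sigma_y^2)/2$. The oracle errors out rather than
renormalising if the grids cover less than $1 - 10^{-6}$ of the mass.

**Markup recovery** (`run_markup_recovery`, $\tau = 0.1$, $T = 27$):
$\bar D$ is unbiased for $\tau$; the t test at the true $\tau$ is
calibrated; at $\tau = 0$ its power exceeds 0.9 (the noncentrality is
$\tau / (\sqrt{\sigma_e^2 + \sigma_v^2} / \sqrt{T}) \approx 18$, so this is
comfortably attained).

**Aggregation effect** (`run_aggregation_effect`, $R = 200$): two
crowd-style sources, 20 submissions/day each with per-submission log-noise
0.35, one year of a daily walk (drift 0.001/day, innovation scale 0.02).
Averaging within longer periods shrinks the noise share of the variance, so
the mean Pearson correlation must rise from daily through weekly to monthly;
with these magnitudes it moves from roughly 0.67 to 0.98, the same
qualitative daily-to-monthly improvement seen when real crowdsourced feeds
are benchmarked against enumerator data. A subtlety the noiseless limit
exposed during development: even at $\sigma_e = 0$ the correlation is not
exactly 1 at weekly/monthly frequency, because unweighted submission-level
means weight days by each source's own random submission counts.

The study sizes above (1000/500/200 replicates) bound the standard error of
any rejection-rate estimate below 0.008 while keeping the complete
verification suite around a minute of desk compute; they are the same sizes
the acceptance script uses.

## The demonstration pipeline

`run_pipeline()` chains the whole system on one generated dataset: 540
daily periods of one latent maize price, a noisy crowd stream (6
submissions/day, heterogeneous packaging, 2% gross outliers), a sparse
enumerator stream, and a monthly OHLC product; then standardisation,
screening, aggregation, concordance (including the monthly lead-lag profile
and per-admin2 nearest-market correlations), and two equivalence reports.
All outputs are byte-deterministic given the seed. Note that the demo's
latent innovations are Gaussian, so its equivalence reports legitimately
land in `inconclusive_normal_innovations` — a feature, not a failure: it
shows the precondition guarding against overclaiming. Set the walk's
innovation shape to $k = 1$ in a custom config to see the informative
branches on synthetic data.

## Numerical and degenerate-input choices

* $\sigma = 0$ in an innovation spec denotes a degenerate point mass (used
  for noiseless drift lines and the calibration regime); the random-variate
  functions themselves require $\sigma > 0$.
* Identical values make Shapiro–Wilk and the paired t degenerate; both raise
  informative errors instead of returning misleading p-values, and the
  calibration study reports a degenerate branch when both noise sds are 0.
* Zero denominator variance in the F test is an error, not `Inf`.
* Lag-profile cells with fewer than 3 overlapping periods report `n` with
  `NA` results rather than failing the whole profile.
* Exact spatial ties are resolved to the lexicographically smallest market
  id so results are order-independent.

## Known limitations

The framework tests *distributional* equivalence of paired aggregates; it
does not model co-integration or lagged dependence between sources (the
lead-lag profile is a diagnostic, not a model), does not estimate $\tau$,
and inherits the usual caveats of the F test's normality sensitivity. The
generator's defaults are plausible rather than calibrated: no published
estimates of Nigerian staple-price innovation parameters were available to
fit, so all preset values are documented choices, and conclusions from the
simulation studies are statements about the framework's behaviour under its
own model.
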