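---
title: "Sliding-window correlation as an order parameter for driver-response coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window correlation as an order parameter for driver-response coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swcorr)
```

## The question the method answers

In sustainable-intensification research one repeatedly needs to know not
*whether* an input (fertilizer, pesticide, mulching film, machinery, labor)
raises output, but *up to what intensity* it does. A single correlation over
the whole dataset averages a positive regime at low intensity with a flat or
negative regime at high intensity and can report anything, including zero.

`swcorr` resolves intensity-dependence by computing the (partial)
correlation between a driver $x$ and a response $y$ inside overlapping
windows of the driver's **value range**. Windows slide along the driver's
values, not along time: window $k$ spans
$[\,\mathrm{origin} + k\,l,\ \mathrm{origin} + k\,l + w\,]$, and the samples
whose driver value falls inside contribute to that window's coefficient
$r_k$. Plotted against the window's mean driver value, the sequence $r_k$
behaves like an order parameter: a change from significantly positive to
non-significant (and possibly to significantly negative) marks a regime
transition of the coupled system, and the driver value where it first occurs
is the intensity threshold.

## The statistic

Within each window:

* with no controls, $r_k$ is the sample Pearson coefficient of the member
  samples' $(x, y)$ pairs;
* with $m$ control covariates $Z$, $r_k$ is the partial correlation: $x$ and
  $y$ are each regressed on $Z$ (intercept included, least squares via QR)
  and $r_k$ is the Pearson coefficient of the two residual vectors.

Two-sided significance uses the exact $t$ distribution,
$t = r\sqrt{\nu/(1-r^2)}$ with $\nu = n - 2 - m$ degrees of freedom. We use
the exact $t$ rather than a normal approximation because windows near the
high-intensity tail can hold few samples, exactly where the approximation is
worst. The residual-regression route is the implementation; the equivalent
inverse-correlation-matrix form
$r = -\Omega_{xy}/\sqrt{\Omega_{xx}\Omega_{yy}}$ is computed independently
in the test suite and the two routes are required to agree to $10^{-10}$.

P-values are stratified into four display levels — $p \ge 0.05$ (black),
$[0.01, 0.05)$ (blue), $[0.001, 0.01)$ (green), $< 0.001$ (red). Interval
endpoints belong to the *less* significant stratum, extending the
conventional "$p = 0.05$ is not significant" rule inward; the wording of
interval-based level descriptions leaves the endpoints open, so this is
pinned explicitly and documented in `classify_significance()`.

No multiple-testing correction is applied across windows. Overlapping
windows share samples, their tests are strongly dependent, and the
per-window p-values are read as a descriptive stratification of the
order-parameter curve, not as a family of independent hypothesis tests.

## Parameters and their defaults

| parameter | units | default | rationale |
|---|---|---|---|
| `w` | driver units | 40 (CLI) | window width; larger = more samples per coefficient, less intensity resolution. 40 on the 0–100 scale balances per-window sample size against resolution for panel-sized datasets. |
| `l` | driver units | 5 (CLI) | step width; `l < w` gives overlap (consecutive windows share `w - l` of range), `l = w` tiles. |
| `min_samples` | count | `m + 3` | smallest `n` with at least one degree of freedom for the partial-correlation $t$ test; under-filled windows are reported with descriptives but an undefined coefficient, never dropped silently. |
| `alpha` | — | 0.05 | coupling is "lost" when a window's $p$ reaches `alpha`. |
| `origin` | driver units | 0 | lower bound of the first window; matches a min–max normalized driver. |
| `min_run` | count | 1 | significant-positive windows required before a loss of significance counts as a transition. |

### Normalization

Analysis columns are min–max normalized to $[0, 100]$,
$x \mapsto 100\,(x - \min x)/(\max x - \min x)$ — the unique affine map
achieving that range. The per-column extremes are retained
(`norm_params`) so a threshold found on the normalized scale is reported in
original units via the exact inverse. Normalization is per column over all
rows; there is no per-year or per-group variant, since the method treats
samples as exchangeable. Constant columns are an error, not a silent no-op.

### Window boundary and termination conventions

Two details of window arithmetic are genuinely open and are fixed here as
package conventions:

* **Boundaries** are half-open, $[\mathrm{lower}, \mathrm{upper})$, except
  the terminal window, which is closed on the right. Closed intervals
  everywhere would double-count samples sitting exactly on shared bounds of
  tiling windows; a half-open terminal window would orphan the maximum
  sample.
* **Termination**: windows are generated until the first window whose upper
  bound reaches or exceeds the driver maximum, and that window is
  *included*. Excluding it would discard the highest-intensity samples —
  the regime the analysis most cares about.

With `w = 40`, `l = 5` on a driver spanning $[0, 100]$ this yields 13
windows, $[0,40], [5,45], \dots, [60,100]$.

### Transition rule and threshold

`detect_transition()` scans defined windows in ascending driver order. After
a run of at least `min_run` windows with $r > 0$ and $p < \alpha$, the first
window with $p \ge \alpha$ is the transition window. The reported threshold
is that window's **minimum member sample value**, not its nominal lower
bound: the nominal bound is a grid artifact (a multiple of `l`), while the
sample minimum is the lowest driver value actually observed inside the
decoupled regime, and it is what the exported min/max columns contain. If
any later window has $r < 0$ with $p < 0.001$ the pattern is upgraded from
`pos_ns` to `pos_ns_neg` (input beyond the threshold actively depresses
output). A sweep with no significant positive run reports `none`; a positive
run that never loses significance reports `pos_sustained` with no
transition. A significant *negative* window immediately after a positive run
(without an intervening non-significant one) resets the scan — the rule
detects loss of significance, not mere sign change.

## The synthetic generator

Real provincial input/output panels are not redistributable, so every stage
is validated against `piecewise_model()` / `generate_coupled()`: a driver
uniform on $[0, 100]$, a **continuous** piecewise-linear response (segments
joined at the breakpoints — a discontinuous response would create window
means that jump unlike real intensity data), optional confounders, and
additive Gaussian noise. Each confounder is
$C = \gamma_d\, x/100 + \mathcal{N}(0, \sigma_c)$ and contributes
$\gamma_r C$ to the response; with both loadings nonzero this creates
classical confounding that partialling on $C$ must remove, and with loadings
zero the marginal and partial coefficients must coincide up to sampling
error — both directions are asserted in the tests. The default noise scale,
10% of the noiseless response range, is a moderate signal-to-noise typical
of annual administrative aggregates. The default shape (slopes $+1, 0, -1$
with breakpoints at 40 and 60) encodes the canonical intensification story:
input helps, stops helping, then hurts.

What the generator does **not** emulate: province-by-year panel structure
(spatial or temporal autocorrelation), heteroscedastic noise, measurement
error in the driver, and non-uniform driver distributions (a skewed driver
thins the high-intensity windows; the `min_samples` rule then blanks rather
than fabricates coefficients). Passing the synthetic benchmarks therefore
shows the machinery is correct under exchangeable sampling, not that any
particular field dataset satisfies the method's assumptions.

## Numerical choices

* Regressions use QR (`qr.resid`), not the normal equations; rank
  deficiency of the control matrix is an explicit error.
* A residual vector that is numerically zero (response fully explained by
  the controls, relative tolerance $10^{-12}$) yields $r = 0$, $p = 1$ with
  a warning rather than a 0/0.
* $|r| = 1$ maps to $p = 0$ directly, avoiding `sqrt` of a negative under
  rounding.
* Window counts are computed in closed form with a one-step floating-point
  guard, and verified against literal iteration of the stepping rule in the
  tests.
* Ties in the driver sort are stable (original row order preserved).
* The generator saves and restores the global RNG state, so calling it does
  not perturb a user's seed.
* Pairwise control collinearity above $|r| = 0.9$ produces warnings, never
  errors: the analysis proceeds, flagged.

## Validation problem sizes

The shipped suite validates: dual-route partial-correlation agreement on
1000 random instances ($n$ 30–200, $m$ 0–5, tolerance $10^{-10}$; $m = 0$
against Pearson at $10^{-12}$); window generation and membership against
exhaustive enumeration on 200 random $(w, l, \max)$ configurations;
every windowed coefficient of an $n = 2000$ sweep against independent
filter-then-correlate recomputation; breakpoint recovery over 50 seeded
replicates of the default piecewise system at $n = 5000$, $w = 10$, $l = 2$
(pattern `pos_ns_neg` in $\ge 90\%$, median threshold error within one
window width of the true breakpoint at 40); confounder removal at
$n = 5000$; CSV round-trips at $10^{-9}$; and the 13-window layout at the
`w = 40`, `l = 5` scale. These sizes keep the whole suite under a minute on
one core while leaving the statistical assertions well-powered.

## Known limitations

Inherited from correlation analysis itself: small windows give unstable
coefficients (mitigated by `min_samples` and by reporting undefined rather
than noisy values); outliers can dominate a window
(`flag_outliers()` offers an optional IQR pre-screen, off by default since
no single rule suits all data); highly collinear controls destabilize the
partial coefficient (warned at $|r| > 0.9$). Method-specific: the threshold
inherits the window grid's resolution (about one window width); overlapping
windows make neighboring coefficients strongly dependent, so the curve's
smoothness should not be over-read; and the transition rule is a scan, not
a changepoint model — it reports the first loss of significance, with no
uncertainty interval on the threshold.
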