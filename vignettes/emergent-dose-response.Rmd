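---
title: "Emergent first-order dose-response models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emergent first-order dose-response models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emergentdrf)
```

## The model and its assumptions

The package treats a quantal dose-response function (DRF) as a probability
distribution: the population CDF of the *critical dose* `D`, the minimum
dose at which a randomly selected individual crosses the clinical illness
cutoff. Illness severity is modelled as a first-order (multiplicative)
outcome, `Z = C0 · C1 · ... · Ct`: the dose `C0` compounded through `t`
random cause sizes along a mode of action — fractions of toxicant passed
at successive organs, rates at which mutations escape repair, degrees of
failure of protective mechanisms. Writing `Z = D · W` at the cutoff
`Z* = 1` identifies the severity per unit dose `W` with the reciprocal
critical dose, `D = 1/W`. When `W` is Weibull-distributed — the emergent
outcome of a multiplicative chain with *correlated* cause sizes — `D` is
Fréchet by transformation of variables, giving the single-stressor model

$$F(d) = \exp\{-[(d-d_0)/\xi]^{-\eta}\}, \qquad d > d_0 .$$

The assumptions that matter are: (i) predominantly first-order
(multiplicative) progression between dose absorption and the endpoint;
(ii) correlation among cause sizes (independence would give a lognormal
severity and hence a lognormal DRF); (iii) a fixed observation time, so
severities are magnitudes at that time, not times to event; and (iv) a
homogeneously distributed (non-microbial) stressor. Saturation kinetics at
very high doses and hormetic (beneficial low-dose) endpoints are outside
the model.

## Parameters

| Parameter | Units | Meaning | Default |
|---|---|---|---|
| `xi` (ξ) | dose | scale: dose at which the scaled dose is 1, where F = exp(−1) ≈ 0.368 | — |
| `eta` (η) | — | shape: log-scale compounding/correlation summary; monotone DRF for η ≤ 1, sigmoidal for η > 1 | — |
| `d0` | dose | threshold below which response is exactly 0 | 0 (fixed unless freed) |
| `c` | — | dissimilar-mode background (DMB) response fraction, mixed in as `c + (1−c)F` | 0 |
| `d_b` | — (scaled) | common-mode background (CMB) "dose" added inside the kernel | 0 |
| `xi_int_j_k` (ξ_jk) | mixed | pairwise interaction coefficient; > 0 synergism, < 0 antagonism | none |
| `d0_int_j_k` | kernel units | interaction threshold applied to the pair kernel value | 0 |
| `q0..qk` | dose^−i | multistage coefficients (comparison model) | degree 2 |
| `mu`, `sigma` | log dose | lognormal comparison model | — |

Thresholds are fixed (typically at zero, the conservative choice for
carcinogens) unless explicitly placed in `free`; a response observed at
zero dose makes a threshold unidentifiable anyway, which is why the
background variants exist.

## Design choices made where the design was open

**Interaction kernel.** The common-mode interaction term must be additive
with the scaled doses, of the same order as an individual dose, and zero
when either constituent dose is zero. The raw product `d_j·d_k` violates
the same-order requirement (it grows quadratically and, with the published
benzene–toluene antagonism coefficient, drives the effective dose negative
and the response to zero rather than producing the observed J-shape). The
default kernel is therefore the geometric mean `√(d_j d_k)`, which
satisfies all three requirements; the raw product remains available via
`kernel = "product"` for sensitivity analysis. The same kernel is used for
dissimilar-mode interaction adjustments, whose thresholds apply to the
kernel value before the coefficient.

**Interaction coefficient convention.** ξ_jk multiplies the kernel, as in
the benzene–toluene common-mode value −0.095; the equivalent
reciprocal-notation value (−1/0.095 ≈ −10.5) sometimes quoted for the same
surface is not used.

**Lognormal background naming.** The lognormal comparison model has no
natural additive background "dose" on its own scale, so both its
background labels (`DMB`, `CMB`) use the response-mixing form
`c + (1−c)·Φ((ln d − μ)/σ)` with the parameter named `c`, matching how
fitted lognormal background rows are conventionally tabulated. The two
labels are kept so reports can mirror either naming convention.

**Unit-scale outer kernels.** In the dissimilar-mode model the effective
doses `d'_i` are already fully scaled (divided by ξ_i), so the outer
Fréchet kernels take unit scale; any other choice would double-count ξ_i.

**p-value orientation and degrees of freedom.** The goodness-of-fit
p-value is the *upper-tail* probability `P(χ²_{I−m−1} ≥ Y*)`, so larger p
means better compatibility, with `m` counting only the parameters actually
estimated (manually fixed parameters, including interaction coefficients
pinned at 0, are excluded). The df convention `I − m − 1` subtracts one
unit beyond the asymptotic `I − m` to account for the choice of parametric
form. This makes the test deliberately *strict*: in the package's own
calibration experiment (refitting data simulated under a fitted model) the
deviance follows χ² with `I − m` df, so the reported p-values are
stochastically smaller than uniform — a conservative bias, not a defect,
but one users should know about when interpreting p near the acceptance
boundary. The test suite verifies both facts.

**Count adjustment.** The plotting position
`n → min(max(0.25, n), N − 0.25)` is applied to all groups by default (it
is the identity on interior counts). It follows the printed formula; for
`N = 10`, `n = 10` maps to 9.75. Analyses that historically used raw
counts can set `adjust = FALSE`, in which case boundary groups contribute
through the `0·log 0 = 0` convention.

## Numerical choices

- **Zero effective dose.** A scaled effective dose ≤ 0 returns response
  exactly 0 — the limit of the closed form — implemented without
  evaluating `0^−η`, so no overflow or NaN can arise.
- **Clipping.** Probabilities are clipped to `[1e−12, 1 − 1e−12]` inside
  likelihood computations only; reported predictions are never clipped.
- **Optimizer.** Deviance is minimized by L-BFGS-B within parameter boxes
  (defaults: ξ-type in [1e−6, 1e8] and η in [0.05, 50], both optimized in
  log space; `c` in [0, 0.999]; `d_b` in [0, 1e4]; thresholds in
  [0, max dose]; interaction coefficients in [−100, 100]), restarted from
  a seeded Latin-hypercube design (32 points by default) plus the model's
  construction values and any user start, with a derivative-free fallback
  (Brent for one parameter, Nelder–Mead otherwise) when the gradient
  method fails. The deviance surface can carry sharp narrow minima —
  background parameters in particular — which is why the multi-start is
  default-on. Identical data, specification and seed give bitwise
  identical results.
- **Degenerate inputs.** Single-dose datasets, all-zero or all-responder
  datasets return a best-effort fit flagged `converged = FALSE` with a
  diagnostic message; `df < 1` yields a fit with the GOF p-value set to
  `NA` rather than an error.

## What the synthetic-data generator emulates — and what it does not

`simulate_quantal()` is plain binomial sampling from any model in the
family: it emulates a dose-group experiment with independent subjects and
exact group sizes, which is what the deviance likelihood assumes. It does
not emulate litter effects, overdispersion, dose-measurement error or
time-varying exposure — so parameter-recovery and calibration results
certify the estimation machinery, not robustness to those real-data
features.

`simulate_chain()` draws severities from the multiplicative chain itself.
Correlation among log cause sizes is realized by a *common-factor*
(equicorrelated) structure: each log cause is
`μ + σ(√ρ·ε0 + √(1−ρ)·εi)` with one shared shock per subject — the
common-cause mechanism (aging, organ damage) that motivates correlation in
the first place — so every pair of cause sizes has correlation ρ. A
short-memory autoregression was rejected deliberately: any linear AR
process with summable correlations normalizes on the log scale by the
central limit theorem, making severity lognormal at *every* ρ and erasing
the emergent behaviour the chain exists to exhibit. Innovations default to
standardized left-skewed Gumbel-minimum shocks, because a Gumbel-minimum
log-severity is exactly a Weibull severity: with ρ = 0 and many increments
the CLT still yields lognormal severity (the independent-causes limit),
while strong correlation lets the common shock dominate and a
two-parameter Weibull then beats a lognormal in maximum likelihood on the
draws — tested as a relative-fit property, not a distributional identity,
since the emergence argument is asymptotic. Gaussian innovations are
available for reference and make log-severity exactly normal at every ρ.
Chain defaults (`t = 30`, `cause_log_sd = 0.1`, `autocorr_rho = 0.8`,
`Z* = 1` in arbitrary severity units) are chosen so severities span a
plausible range around the illness cutoff with strong but not degenerate
correlation; no claim is made that they match any specific biological
system, and all are user-facing.

## Problem sizes used in the validation experiments

Parameter recovery uses 100 replicate studies of 8 dose groups × 500
subjects simulated from a Fréchet truth (ξ = 1, η = 2) over doses spanning
responses from ~1.5% to ~94%; GOF calibration refits 200 such replicates
simulated under a fitted model; the distributional link between
inverse-Weibull samples and the Fréchet CDF uses 10⁵ draws per
shape–scale combination; inclusion–exclusion equivalence is checked by
exhaustive subset expansion up to four pathways. These sizes make the
Monte-Carlo error small relative to every tolerance asserted in the test
suite.

## Known limitations

- Parameter uncertainty (confidence or credible intervals) and
  benchmark-dose computation are not provided; the fit reports point
  estimates and a goodness-of-fit test only.
- Interactions are pairwise; three-way and higher-order interaction terms
  are not parameterized.
- The GOF test is asymptotic in the group sizes and, by its strict df
  convention, conservative (see above).
- Time-to-event (time-to-tumor) structure is outside the model: severities
  are magnitudes at a fixed observation time.
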