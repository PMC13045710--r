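---
title: "Methods: a microsimulation of reader error in pulmonary-nodule surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a microsimulation of reader error in pulmonary-nodule surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model implemented by **lungnodesim**: its
assumptions, every parameter with units and rationale, the numerical
choices made in the implementation, and the points where the published
literature on nodule management is ambiguous and a concrete resolution
had to be chosen. Chunks are illustrative and not evaluated at build
time; all quantitative claims below are enforced by the package's test
suite instead.

## 1. Purpose and scope

The package is a *synthetic-data* study. Nothing in it touches patient
records: it generates a population of nodules with known ground truth,
simulates how differently-erring readers would measure them on serial
CT, and tabulates the management decisions a size-threshold guideline
would then make. This design isolates one causal factor — the reader's
measurement-error profile — while holding the population, the growth
biology, and the decision rules literally identical across readers
(including the random draws, see §7). Differences between readers in
sensitivity, specificity, and surveillance burden are therefore
attributable to measurement error alone, not to confounding.

What the generator emulates, and what it does not: it reproduces the
*marginal* size distribution, subtype mixture, and size-band malignancy
prevalence of incidentally detected nodules, and plausible growth
kinetics. It does not model patient-level covariates, inter-scan
attendance, reader learning, multiple nodules per patient, or
mortality; each nodule is an independent unit.

## 2. Baseline cohort

`build_cohort(default_config())` draws, for each of `n_nodules`
(default 10^6) independent nodules:

**Subtype.** Solid with probability 0.939; the 0.061 sub-solid
remainder is split part-solid : non-solid = 4 : 5. These fractions
mirror reported incidental-nodule registries.

**True baseline diameter** (mm, maximal axial). Per subtype, a 3
mm-shifted log-normal truncated above at 30 mm:

$$ d_0 = 3 + e^{\mu + \sigma Z}, \qquad Z \sim N(0,1), \quad d_0 \le 30. $$

| subtype | $\mu$ | base $\sigma$ | $\sigma$ used |
|---|---|---|---|
| solid | −0.51 | 1.97 | 1.97² = 3.8809 |
| part-solid | 2.19 | 0.87 | 0.87² = 0.7569 |
| non-solid | 1.03 | 1.13 | 1.13² = 1.2769 |

The 3 mm shift encodes the detection floor (nodules under 3 mm are not
reported); the 30 mm ceiling is the conventional nodule/mass boundary,
enforced by rejection resampling so the density is renormalized, not
clumped at the bound.

*Why the squared $\sigma$*: the base values are quoted as log-scale
dispersion parameters, but only their squares reproduce the published
cohort summaries. With $\sigma = 1.97$ the solid distribution is far
too narrow (truncated median ≈ 3.9 mm, mean ≈ 5.9 mm before
truncation effects); with $\sigma = 1.97^2$ the truncated solid
distribution has median 3.27 mm and mean 5.50 mm, and the sub-solid
mixture has median 8.03 mm and mean 9.81 mm — exactly the reference
cohort. The closed-form check for the median: solving
$P(3 + e^{\mu+\sigma Z} \le m \mid d_0 \le 30) = 0.5$ with
$\mu=-0.51,\ \sigma=3.8809$ gives $m = 3.2707$. The interpretation
that the printed dispersions are *standard deviations whose square is
the `sdlog`* is therefore adopted; both readings are available via the
`square_sdlog` configuration switch, with squaring as the default.
`solve_sdlog()` is also provided to derive $\sigma$ from a quoted
median/IQR pair when configuring other cohorts.

**Malignancy.** Bernoulli per nodule with size-band prevalence:

| subtype | band (true $d_0$, mm) | P(malignant) |
|---|---|---|
| solid | [3, 6) | 0.009 |
| solid | [6, 8) | 0.011 |
| solid | [8, 30] | 0.094 |
| sub-solid | [3, 5) | 0.004 |
| sub-solid | [5, 30] | 0.036 |

Under the default size distributions this yields ≈ 22 500 cancers per
million nodules (≈ 2.25 % prevalence).

**Definitively benign features.** 10 % of *benign* nodules with true
diameter ≥ 5 mm (e.g. perifissural or fully calcified morphology) are
flagged; flagged nodules are discharged at the baseline read and are
exempt from the size-based referral rule. This resolves an ambiguity
about whether the benign-features fraction applies to all nodules or
only to benign ones: applying it to benign nodules ≥ 5 mm is what
reproduces the reference baseline discharge fractions (e.g. 74.5 % of
benign nodules discharged at baseline by the manual reader), and it is
also the clinically coherent reading — truly malignant nodules do not
exhibit definitively benign morphology.

## 3. Growth model

Time $t$ is in months; the surveillance horizon is 48 months with
scheduled scans at 0, 3, 12, 24, 48.

**Benign nodules never grow**: their true diameter is constant. This
deliberately ignores benign growth (inflammatory change, measurement
of scar) — see limitations.

**Malignant solid nodules** follow a Gompertz curve *in diameter
space*:

$$ d(t) = \exp\!\big(\ln d_\infty + (\ln d_0 - \ln d_\infty)\,
           e^{-\alpha t}\big), $$

with asymptote $d_\infty = 100$ mm fixed (far above every decision
threshold, so it only shapes curvature) and per-nodule rate
$\alpha \sim \mathrm{LogNormal}(\mu_\alpha, \sigma_\alpha)$,
$\sigma_\alpha = 0.75$ fixed and $\mu_\alpha$ calibrated (§4; shipped
default −5.125, i.e. median $\alpha \approx 0.0059$ /month). Gompertz
growth gives the deceleration seen in real tumours and maps cleanly
onto volume-doubling-time logic.

**Malignant sub-solid nodules** grow linearly in diameter,
$d(t) = \min(d_0 + r\,t,\ 30)$, with per-nodule rate
$r \sim \mathrm{LogNormal}(\mu_r, 1.0)$ mm/month and $\mu_r$
calibrated (shipped default −3.453125, median ≈ 0.032 mm/month —
indolent, as ground-glass lesions are). The 30 mm cap keeps sub-solid
lesions in the nodule regime for the whole horizon.

## 4. Calibration

The two free location parameters $\mu_\alpha$ and $\mu_r$ are not
taken from the literature; they are *defined* by two operational
targets: under the error-free reader the pathway must achieve
end-of-horizon sensitivity 0.635 for solid cancers and 0.168 for
sub-solid cancers. `calibrate_growth()` fits each by bisection.
Sensitivity is monotone in the location parameter, and common random
numbers (one fixed set of standard-normal growth draws and referral
uniforms reused across iterations) make the objective a smooth
deterministic function of the parameter, so bisection converges
reliably; an infeasible target fails loudly with the achieved bracket.

The shipped defaults were produced by
`calibrate_growth(n = 400000, seed = 42, tol = 0.002)` — the
population size, seed, and tolerance are this package's own choices,
sized so the Monte-Carlo error of the objective (≈ 0.004 absolute on
~14 000 solid cancers) is comparable to the tolerance. The test suite
re-runs the calibration and checks both the determinism of the fit and
that the achieved sensitivities hit the targets.

## 5. Measurement model

A reader is a pair (bias, SD) in millimetres. A measurement of true
diameter $d$ is

$$ m = \mathrm{round}_{\tfrac12\uparrow}\!\big(d + b + s\,\varepsilon\big)
       \ \vee\ 1, \qquad \varepsilon \sim N(0,1), $$

independent across scans and across readers. Default panel:

| id | profile | bias (mm) | SD (mm) | rounded |
|---|---|---|---|---|
| R0 | error-free truth | 0 | 0 | no |
| R1 | consensus reference | 0 | 0.1 | yes |
| R2 | AI alone | +0.234 | 0.771 | yes |
| R3 | AI-assisted radiologist | +0.182 | 0.639 | yes |
| R4 | manual radiologist | −0.770 | 0.959 | yes |

Numerical choices: rounding is *half-up* (`floor(x + 0.5)`), matching
how sizes are reported clinically, rather than R's banker's rounding —
with integer decision thresholds the tie-breaking rule matters at
exactly the x.5 boundary measurements. Measurements are clamped at 1 mm
so noise cannot produce zero or negative diameters. R0 is deliberately
left unrounded: it is the "perfect information" arm, and rounding it
would conflate guideline step effects with measurement error.
Measurement errors are serially independent (no per-reader random
intercept); serial correlation would attenuate the noise in measured
*growth*, so the independent model is the conservative stress case for
follow-up rules.

## 6. Management pathway

A simplified BTS-style algorithm, identical for all readers, driven
entirely by *measured* values. All thresholds live in
`pathway_constants()` and are in measured millimetres.

**Baseline (t = 0).** Measured < 5 mm, or benign-features flag →
discharge. Otherwise, solid nodules: measured ∈ [5, 6) → 12-month
scan; ∈ [6, 8) → 3-month scan; ≥ 8 mm → referral for definitive
management with probability 0.918 if malignant / 0.171 if benign
(modeling the risk-score-plus-workup step the guideline inserts
above 8 mm, without simulating its internals); if not referred, the
nodule enters the 12-month route. Sub-solid nodules ≥ 5 mm enter
surveillance at 3, 12, 24, 48 months. Note that for rounding readers
the integer bands mean: measured 5 mm → 12-month, 6–7 mm → 3-month,
≥ 8 mm → referral.

**Solid follow-up.** At each attended scan the measured volume-doubling
time against the previous scan is

$$ \mathrm{VDT} = \frac{\Delta t_{\mathrm{days}} \,\ln 2}
                       {3 \,\ln(m_2/m_1)} \ \text{days}, $$

(the factor 3 converts diameter ratio to volume ratio for a sphere).
Decisions: a measured *decrease* ($m_2 < m_1$) → discharge (resolving
lesion); VDT ≤ 400 days → definitive management; at the 3-month scan,
otherwise → continue to 12 months; at the 12-month scan,
VDT ∈ (400, 600] days → one further scan at 24 months, otherwise →
discharge; at the 24-month scan, anything not referred → discharge.
Equal measurements give VDT = ∞ (stability), never a division error.

**Sub-solid follow-up.** At each of 3/12/24/48 months, measured growth
strictly greater than 2 mm versus the previous attended scan →
definitive management; otherwise continue; still unresolved at 48
months → discharge. Two deliberate resolutions here: (i) the
comparison is *strictly* > 2 mm, so a rounded change of exactly 2 mm
does not trigger referral; (ii) there is no early shrink-discharge
for sub-solid nodules by default (ground-glass density fluctuates and
guidelines keep them under observation regardless) — both behaviours
are switchable (`subsolid_shrink`, `solid_shrink` options).

**Routing of unreferred ≥ 8 mm solid nodules** is ambiguous in
threshold-based guideline summaries (a risk model could send them to
either CT interval). The default routes them to the **12-month** scan:
with the default reader panel this reproduces the reference
discharge/referral timepoint tables, whereas 3-month routing inflates
early benign referrals. The alternative is available as
`unreferred_routing = "three_month"`.

Calendar conversion uses 30.4375 days/month (365.25/12), so the
3-to-12-month interval is 273.9 days — VDT thresholds are sensitive
to this constant, which is why it is pinned in `pathway_constants()`
rather than approximated as 30.

Every nodule resolves within the horizon to exactly one of **DC**
(discharge) or **DM** (definitive management) with a decision time in
months; sensitivity = P(DM | malignant), specificity =
P(DC | benign), and mean surveillance time is the mean decision time.

## 7. Random-number architecture and numerics

One master integer seed is hashed (31-polynomial over the stream name,
mod 2^31 − 1) into named substreams: `cohort`, `malignancy`,
`features`, `growth`, and `reader/<id>`. Consequences, all under test:

* bit-identical reruns for a given seed;
* per-reader draws are independent of which other readers run, so a
  single-reader run equals that reader's slice of a full-panel run;
* all readers measure the *same* cohort with the same growth
  trajectories — the paired design that gives `compare_readers()` its
  power.

Two pathway engines consume identical pre-generated noise matrices: a
vectorized production engine and a per-nodule event-loop reference
(`run_pathway()`). The test suite asserts field-for-field equality, so
the fast path is continuously verified against the readable one.

Other numerics: truncation by rejection (not inverse-CDF clipping);
the shifted log-normal quantile/CDF/truncated-mean helpers use closed
forms via `qnorm`/`plnorm` rather than series approximations;
`solve_sdlog()` brackets on [10⁻⁶, 20] with bisection to 10⁻⁹.

## 8. Limitations

* Benign nodules are static; transient inflammatory growth, which
  causes some real-world false referrals, is absent, so benign-side
  VDT referrals here stem from measurement noise alone.
* Measurement errors are Gaussian, homoscedastic, and serially
  independent; real reader error grows with nodule size and has a
  per-reader systematic component.
* The ≥ 8 mm referral step is a truth-conditioned Bernoulli summary of
  a risk model, not a simulation of one, so it cannot respond to
  measured size beyond the threshold itself.
* One nodule per "patient", full scan attendance, no competing
  mortality, and a hard 48-month horizon.
* Volumetry (and volume-based guidelines) are out of scope; all rules
  are diameter-derived.

These are fidelity limits on absolute outcome levels; the paired
*between-reader differences* the package is designed to estimate are
considerably more robust to them.
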