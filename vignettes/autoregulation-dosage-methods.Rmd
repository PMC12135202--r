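---
title: "Methods: steady-state inference of negative autoregulation from gene dosage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steady-state inference of negative autoregulation from gene dosage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snadosage)
```

## The model and its assumptions

The package analyzes a single-species ODE for the transcript concentration
$m$ of a self-repressing gene present in $c$ copies:

$$\frac{dm}{dt} = c\beta\,\frac{K^n}{m^n + K^n} - \gamma m
 \;=\; \frac{c\beta}{(m/K)^n + 1} - \gamma m.$$

Assumptions baked into everything downstream:

* **Steady state.** All measured levels are treated as steady states of
  this ODE. The production term is strictly decreasing and the loss term
  strictly increasing in $m$, so the steady state exists, is unique, and
  is globally attracting — `integrate_ode()` is provided purely as a
  numerical cross-check of that claim.
* **Repression proportional to transcript.** The repressor concentration
  is proxied by the mRNA level itself; protein dynamics are not modeled.
* **Constant degradation.** $\gamma$ is shared across genotypes and copy
  numbers; enhancer mutations may move $\beta$ or $K$ but not $\gamma$.
* **Copy numbers 1 and 2 only** and identical parameters for both copies.

In the cooperative limit $n \to \infty$ (represented throughout by the
`Inf` sentinel, never a large float) the production term becomes a
Heaviside step and the steady state is $m^* = K$ when $c\beta/\gamma > K$
and $m^* = c\beta/\gamma$ otherwise. We adopt $\theta(0) = 1$: repression
is active exactly at $m = K$, so the repressed steady state is a genuine
fixed point and the equality case is labeled `"boundary"` with
$m^* = K$.

## Dosage ratios and the three categories

With all levels normalized by the control's 2-copy mean, the 1-to-2-copy
ratio $\rho = m_1/m_2$ is confined to $[1/2, 1]$: exactly $1/2$ with no
feedback ($K = \infty$; `no_feedback_steady_state()`), approaching 1
under deep repression. Genotypes are classified by `categorize()`:
category 1 ($\rho \ge 0.9$, both dosages repressed), category 2
($0.6 < \rho < 0.9$, only the 2-copy dosage repressed), category 3
($\rho \le 0.6$, repression never engaged). Both boundaries are inclusive
toward the outer categories, matching the usual "at least 0.9" / "at
most 0.6" phrasing, and both are configuration options. Measured ratios
marginally above 1 (up to 1.1) are treated as measurement noise and
clipped to 1 with a warning; anything larger errors.

`infer_step_params()` then reads the step-limit geometry: category 1
yields a point estimate $K = m_2$ but only a lower bound
$\beta/\gamma > K$; category 2 yields both point estimates
($K = m_2$, $\beta/\gamma = m_1$); category 3 yields
$\beta/\gamma = m_1$ with $K$ bounded below by $m_2$, plus a consistency
check that $m_2 \approx 2 m_1$ (warning threshold 15% of $m_2$ by
default — category-3 geometry forces the 2-copy level to twice the
1-copy level, and larger deviations indicate the model does not describe
that genotype).

## Finite-$n$ inversion and the admissibility bound

For finite $n$, writing $x = (m_2/K)^n$ and dividing the two
steady-state equations gives the closed form implemented in
`solve_hill_threshold()`:

$$x = \frac{2\rho - 1}{1 - 2\rho^{\,n+1}}, \qquad
  K = m_2\,x^{-1/n}, \qquad
  \beta/\gamma = m_2\,\rho\,(1 + \rho^n x).$$

The denominator must be positive, which happens exactly when
$n > n_{\min}(\rho) = \ln(1/2)/\ln(\rho) - 1$ (`min_hill_coefficient()`).
Inadmissibility is reported as `valid = FALSE`, not an exception, so
scans over $n$ are cheap. At the control-like ratio $\rho = 0.98$ the
bound evaluates to $n_{\min} \approx 33.3$; published descriptions of
this system quote an admissible range starting at 30, which may reflect
additional constraints in a fuller treatment, so the package only
asserts (and reports) $n_{\min} \ge 30$ while returning the computed
33.3.

`hill_vs_step_error()` quantifies what the step limit costs: for the
same $(m_1, m_2)$ it compares the finite-$n$ inversion with the step
readout, reporting relative differences in $K$ and $\beta/\gamma$
(defined only where the step estimate is a point, not a bound). The
differences shrink monotonically as $n$ grows.

## Mutant-condition solver: a reconstructed assumption

Solving a mutant's $(K, n)$ from its two normalized levels requires one
more constraint than the data provide. The package's default —
**shared production**: the mutant's $\beta/\gamma$ equals the control's
inferred value $b$ — reflects the biological reading that enhancer
lesions in the repression module change the threshold, not the maximal
production. Under it the system collapses to closed form:
$x = 2b/m_2 - 1$, $n = \ln\!\big((b/m_1 - 1)/x\big)/\ln(m_1/m_2)$,
$K = m_2 x^{-1/n}$. No nested root-finding is needed; the result is
verified by forward steady-state solves to $10^{-6}$ and flagged invalid
otherwise. Two consequences worth knowing:

* any ratio strictly above $1/2$ admits a solution, but ratios close to
  $1/2$ force a tiny, effectively non-cooperative $n$ — such genotypes
  are excluded from any "strong cooperativity" statement rather than
  flagged inadmissible;
* ratios below $1/2$ (2-copy level more than twice the 1-copy level) are
  inconsistent with any positive $n$ and return
  `"no admissible solution"`.

The alternative assumption (**shared threshold**, free $\beta/\gamma$)
is available via `assumption = "shared_K"`; there the single unknown $n$
is found by scanning a log grid for a sign change of the defect function
(which is not monotone — both mutant levels can sit below $K$) and
polishing with Brent's method.

## Root finding and numerical conventions

* `steady_state_hill()` uses bisection on $(0, c\beta/\gamma]$ to
  absolute tolerance $10^{-10}$; the bracket is guaranteed because the
  residual is positive at 0 and non-positive at the unrepressed level.
  The test suite checks it against `stats::uniroot()` as an independent
  route.
* The two algebraic forms of the production term are required to agree
  to relative $10^{-12}$; the $(m/K)^n$ form is used internally because
  it avoids overflow of $K^n$ at large $n$.
* JSON serialization encodes infinite parameters as the string
  `"inf"`.
* The shifted-mean bootstrap counts ties into the tail
  ($\ge$, the more conservative choice); the strict-$>$ variant is
  exposed as `tie = "gt"` since the convention is rarely stated in
  methods sections. No $+1$ continuity correction is applied to the
  count, matching the plain count-over-iterations formula. For binary
  (more generally, two-valued) samples the bootstrap mean difference is
  an exact function of two independent binomial counts, and the
  implementation uses that reduction — this is what makes the
  documented default of $10^7$ iterations practical; the generic path
  resamples in chunks. Tests validate both paths against exhaustive
  enumeration of the full $n^n \times n^n$ resample space at small $n$.

## The synthetic-data generator: a stated world

`simulate_measurements()` draws per-embryo mean intensities around the
model steady states with multiplicative lognormal noise,
parameterized by a coefficient of variation. Defaults, chosen once:

* **`noise_cv = 0.12`** — the visual scale of embryo-to-embryo scatter
  in this kind of fixed-embryo fluorescence assay; published scatter
  plots do not report a numeric CV, so this is a modeling choice, not a
  measured value.
* **`n_embryos = 50`** per condition — typical of per-genotype embryo
  counts in such panels.
* Domain widths drawn uniformly over 112–140 µm, the natural
  population range of the ventral stripe, equal to 16–20 nuclei at the
  default **7 µm nucleus spacing** (112/16); spacing is a config option.
* Hatch outcomes are i.i.d. Bernoulli; offspring counts are multinomial
  over the surviving-class fractions of `expected_offspring()`.
* Toy images are rectangular fields with a centered ventral band plus
  additive Gaussian pixel noise, written as plain-text grids.

What the generator deliberately does **not** emulate: stage-dependent
trends within nc14, transcriptional bursting, spatial intensity profiles
within the domain, nuclear segmentation texture, optics (PSF, z-stacks),
day-to-day staining batch effects, and any maternal-effect mechanism
(the maternal genotype is carried as a label only, and panels from
different maternal directions are never pooled). A green
parameter-recovery test therefore establishes that the inference chain
is correct *for data matching the stated noise model*, not that the
model describes any particular real genotype.

One calibration claim deserves a flag: at $(K = 1, \beta/\gamma = 0.8)$,
$n = 50$ embryos/condition and CV 0.1, the delta method gives the ratio
estimator an SD of $0.8\sqrt{2}\,(0.1/\sqrt{50}) = 0.016$, so the
probability that a single estimate lands within $\pm 0.03$ of truth is
93.9% — slightly below a round 95%. The tests assert bounds consistent
with that analysis ($\ge 88\%$ within $\pm 0.03$, $\ge 97\%$ within
$\pm 0.05$) rather than the optimistic round number.

## Quantification stage

The expression-domain detection rule is a documented stand-in (the
underlying wet-lab segmentation is not specified beyond "the detected
domain"): average each dorsoventral row along the anterior–posterior
axis, smooth with a 3-pixel box filter, estimate background as the
profile median, threshold at background + 50% of the
background-subtracted maximum, and keep the largest connected band. All
three constants are arguments. A flat profile returns an empty mask
rather than erroring. The detection is monotone in the threshold
(higher threshold, smaller mask), which the suite checks as a property.

Group comparisons use textbook one-way ANOVA with Tukey–Kramer HSD via
`stats::ptukey()`; results are tested against `stats::aov()` +
`stats::TukeyHSD()` as an independent oracle, the adjusted p-value is
never below the unadjusted pairwise p-value, and the null distribution
of the ANOVA p-value is checked for uniformity. `compensation_test()`
is this machinery restricted to the 1-copy/2-copy pair: "compensated"
means *not significantly different*, so it inherits the usual caveat
that low power at small $n$ favors that label.

## Dosage records and panels

Ratios are computed as ratios of group means (matching how such figures
annotate paired conditions), not means of per-embryo ratios; the
percentile bootstrap CI (default 2,000 resamples) resamples embryos
within each group independently. Normalization by the control 2-copy
mean makes the control's $K$ identically 1 and is idempotent. The panel
table carries, per genotype: normalized levels, ratio with CI, category,
$K$ and $\beta/\gamma$ with bound flags, and $n_{\min}$ (defined only
for ratios strictly inside $(1/2, 1)$).

## Pipeline and reproducibility

`run_pipeline()` composes simulate → dosage → categorize/infer →
viability, writing CSVs and a JSON report; every stochastic stage
derives its seed deterministically from the single config seed (base,
base+1000, base+2000, base+3000 blocks), and all of them are recorded in
the report. Reruns are byte-identical. Configuration is a single JSON
file validated before any compute; the Bonferroni-corrected alpha is
computed from the number of mutant-vs-control comparisons actually
present in the run.

## Known limitations

* The single-ODE model ignores protein-level dynamics, bursting and any
  spatial structure; bistability and positive-feedback extensions are
  out of scope.
* With only relative levels, the finite-$n$ problem is underdetermined:
  a one-parameter family of $(K, \beta/\gamma)$ solutions indexed by $n$
  fits any admissible ratio, which is why the step limit (point
  estimates) and $n_{\min}$ (bound) are the primary reported
  quantities.
* The mutant-condition solver's shared-$\beta/\gamma$ constraint is a
  reconstruction of an underdetermined problem; conclusions that depend
  on it should be checked under `shared_K` as well.
* Bound estimates (category 1 $\beta/\gamma$, category 3 $K$) are
  one-sided by construction and carry no uncertainty quantification.
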