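---
title: "Effect-size analysis of AB single-case designs: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effect-size analysis of AB single-case designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sceda)
```

## The setting

A single-case experimental design (SCED) measures one subject repeatedly:
a baseline phase (A) without intervention, an intervention phase (B), and —
in the designs this package targets — an optional generalization phase (G)
in which caregivers record the behavior in the natural environment. The
dependent variable is a bounded count: the number of correct responses
(here, *mands* — requests) out of a fixed number of opportunities per
session, e.g. 0–50 correct responses out of 50 trials.

Sessions are indexed globally and 1-based across phases: a 5-session
baseline followed by 30 training sessions occupies indices 1–35 and a
subsequent generalization phase continues at 36. This convention matters
because milestones are conventionally counted on the global axis ("first
correct responses in the 8th session" counts baseline sessions too) and
because the regression below uses the session index as its time regressor.
Consequently missing sessions are not representable: the time axis must be
uniformly spaced, and data with gaps has to be re-indexed (and that decision
documented) before import.

## The detrended parametric model

The core inferential tool is a two-stage regression.

**Stage 1 — natural trend.** OLS on the baseline only:
$\hat y_t = b_0 + b_1 t$. This extrapolates how the behavior would have
evolved without intervention. It needs $n_A \ge 2$ baseline sessions and
positive time variance; with fewer, the selector (below) falls back to
non-overlap indices.

**Stage 2 — treatment effects on de-trend scores.** The de-trend score
$d_t = y_t - (b_0 + b_1 t)$ is regressed on an intercept, a phase dummy
$P_t$, and the phase-specific ramp $P_t (t - t_B)$, $t_B$ being the first
intervention session:

$$d_t = c_0 + c_1 P_t + c_2 P_t (t - t_B) + \varepsilon_t.$$

$c_1$ is the *level* change at intervention onset and $c_2$ the *slope*
change. Both are tested jointly:
$F = \frac{R^2/2}{(1-R^2)/(n-3)}$ on $(2, n-3)$ degrees of freedom, and the
signed effect size is $r = \operatorname{sign}(c_1)\sqrt{R^2}$ (mirrored
when the therapeutic goal is a decrease). At the case-study scale
($n_A = 5$, $n_B = 30$) the test has $(2, 32)$ degrees of freedom.

Choices worth stating explicitly:

- **Parameterization.** Two natural anchors exist for the interaction ramp
  (onset $t_B$, or the phase mean). They change $c_1$'s meaning but not
  $R^2$, $F$ or $p$ — the package anchors at onset, and the invariance is
  property-tested. A consequence users should know: with a sigmoidal
  acquisition curve the level-at-onset coefficient can be slightly
  *negative* (scores at onset still sit at baseline level while the B-phase
  regression line tilts upward), so $r$ — which takes $c_1$'s sign — can be
  negative for a case whose improvement is carried entirely by the slope
  effect. The slope coefficient and the interpretation band (computed on
  $|r|$) tell the real story; reports always print both coefficients.
- **Covariance assumption.** The method's stated precondition, "cov > 0",
  names no operands; we operationalize it as
  $\operatorname{cov}(P_t, d_t) > 0$ for an increase goal (< 0 for a
  decrease): the intervention must have moved the de-trend scores in the
  therapeutic direction. The check is computed on the analyzed sessions and
  reported; a violation does not abort the analysis but demotes the
  parametric route in automatic selection and adds a caveat.
- **Degenerate fits.** A constant de-trend series yields $R^2 = 0$, $F = 0$
  by convention (null model). A numerically perfect fit
  ($1 - R^2 < 10^{-12}$ with positive total variance) is flagged
  `exact_fit`, $F$ reported as infinite and $p$ as the smallest positive
  double, rather than risking a division error. A collinear design matrix is
  an error.
- **Generalization sessions are excluded** from the A-vs-B fit; the B-vs-G
  comparison is descriptive only (per-phase OLS slopes via
  `phase_trend()`), because the generalization phase changes context and
  observer simultaneously and a causal contrast would be confounded.
- **Known anti-conservatism.** Stage 2 treats the Stage-1 trend as known.
  The uncertainty of $b_0, b_1$ is not propagated, which makes the $F$ test
  anti-conservative, particularly with short baselines. Every parametric
  report carries a fixed caveat to this effect; no correction is applied.

## Non-overlap indices

Five indices are provided (NAP, PND, PEM, Tau-AB, Tau-U), all defined over
cross-phase score pairs with a configurable improvement direction. Tie
conventions: ties count 0.5 toward improvement in NAP and PEM (so
NAP(A, A) = 0.5 exactly) and zero in the Tau family. Tau-U uses the
baseline-trend correction only ($S_{AB} - S_{AA}$), without B-phase trend
augmentation — the variant most commonly meant for AB designs; it can exceed
[−1, 1] when the baseline trend opposes improvement and is then reported
unclipped with a flag. PAND and IRD are omitted: they rarely change
decisions relative to NAP/Tau and would widen the surface without adding
discriminating power.

Implementation note: NAP and Tau-AB are computed from pooled midranks
(Mann–Whitney U), and an exhaustive `pairwise_oracle()` — a transparent
enumeration of all $n_A n_B$ pairs — is part of the public API. The test
suite checks exact agreement between the two routes on 1000 random phase
pairs, plus the identities $\mathrm{NAP}(A,B) + \mathrm{NAP}(B,A) = 1$ and
$\tau_{AB} = 2\,\mathrm{NAP} - 1$.

One subtlety: all indices are invariant under strictly monotone transforms
of the scores *except* PEM when the baseline has even length — an
interpolated median does not commute with nonlinear transforms. The property
test asserts full invariance for NAP/PND/Tau and odd-baseline invariance for
PEM.

## Automatic selection and interpretation bands

The selector is a pure function of $(n_A, n_B)$ and assumption flags,
applied in order:

1. parametric detrended regression iff $n_A \ge 3$, $n_B \ge 5$, the
   baseline time variance is positive, and the covariance assumption holds;
2. otherwise Tau-U iff $n_A \ge 3$ and the baseline trend is nonzero
   (Tau-U exists precisely to absorb baseline trend);
3. otherwise NAP — the assumption-light floor.

The fired rule id is recorded in every report and logged by the CLI. All
computable indices are always reported; selection only decides which one
headlines.

Band tables (config-overridable, printed in every report) map estimates to
weak / medium / large with *closed lower bounds* — an estimate exactly at a
cut point takes the higher band:

| method | weak | medium | large |
|---|---|---|---|
| NAP | < 0.66 | [0.66, 0.93) | ≥ 0.93 |
| PND | < 50 | [50, 90) | ≥ 90 |
| PEM | < 70 | [70, 90) | ≥ 90 |
| Tau (abs) | < 0.2 | [0.2, 0.6) | ≥ 0.6 |
| parametric r (abs) | < 0.3 | [0.3, 0.5) | ≥ 0.5 |

The gauge position for speedometer rendering rescales the estimate linearly
from its native scale to [0, 1] (so Tau = 0 sits at 0.5).

## Recording procedures

Direct observation supports the three canonical ABA procedures. Frequency
counts events (instants and intervals each once). Duration sums interval
lengths after merging overlaps — union semantics, because double-counting a
behavior's duration is never meaningful; splitting an interval in two leaves
the total unchanged, and the result can never exceed the session duration.
Interval recording divides the session into bins of `interval_length`
seconds (the last bin may be short) and supports partial-interval (any
occurrence), whole-interval (full coverage) and momentary time sampling
(occurrence at the bin's endpoint); partial is the default, and
whole ≤ partial holds for every log. An "intensity" item kind is
deliberately not provided — a bounded `range` item covers that use.

## The synthetic generator

`sim_config()` encodes the acquisition process the analysis stack is
validated against, mirroring the structure of published mand-training case
studies: 50 trial opportunities per session (10 for each of 5 target items),
5 baseline sessions at success probability `p0 = 0` (children at baseline
scored zero), 30 intervention sessions, 10 home generalization sessions.
Session scores are Binomial(`trials_per_session`, $p_t$) — a bounded count,
not Gaussian noise — with $p_t$ following a logistic
$p_{\max} / (1 + e^{-k (t - t_0)})$ in within-phase session index: zero
start, first responses mid-training, then a stable plateau. A linear ramp is
available as an alternative curve. Defaults where no published value
exists were fixed once on plausibility grounds: $p_{\max} = 0.9$ (a mastered
skill short of ceiling), $k = 0.5$ per session (acquisition spread over
roughly ten sessions), $t_0 = n_B/2$, and a generalization curve of the same
family starting low with a growing trend ($g_k = 0.4$, $g_{t_0} = 2$).

`synthetic_case_studies()` instantiates two profiles whose *expected*
trajectories hit the published milestones of the two case studies — an early
acquirer (first responses around global session 8, 80% around session 20:
$p_{\max} = 0.95$, $k = 0.55$, $t_0 = 12$) and a late, steeper acquirer
(80% near session 32: $p_{\max} = 0.98$, $k = 0.9$, $t_0 = 25$). These are
clearly-labelled synthetic stand-ins for demonstration and validation; they
are not the deposited measurements, and quantities computed from them
(e.g. $F$, $r$) agree with the published ones only in magnitude, not digit
for digit.

What the generator deliberately does not emulate: serial dependence between
sessions (an AR(1) latent option is reserved in the config but rejected at
construction — sessions are independent given $p_t$), within-session trial
dynamics (prompt hierarchies, 5-second delays, reinforcer magnitudes),
observer error, and context effects beyond the phase-level curve change.
Passing Monte-Carlo checks therefore demonstrates correctness of the
statistics *under independence and binomial noise*; real session data with
autocorrelation will make the already anti-conservative F test more so.

## Monte-Carlo validation

`run_mc()` derives per-replicate seeds from a master seed through the fixed
map `(master + i * 100003) mod 2147483629`, so any replicate is reproducible
in isolation and a run is byte-reproducible end to end. Degenerate
replicates (e.g. a parametric fit impossible on a collinear design) are not
dropped: they are counted and routed through the automatic selector, and
non-parametric fallbacks never count as rejections.

The validation suite, at the problem sizes we standardize on, checks:

- **Type-I error**: 2000 null replicates (constant $p = 0.3$, i.e. mean 15
  of 50, with the known zero trend supplied so Stage-1 estimation noise is
  excluded) give an F-test rejection rate within [0.03, 0.07] at
  $\alpha = 0.05$ — binomial counts at $m = 50$ are close enough to Gaussian
  for the nominal level to hold;
- **power monotonicity**: rejection rate is non-decreasing in $p_{\max}$
  over the grid 0.1–0.9 (500 replicates per point, tolerating 0.03 MC
  jitter);
- **power under a strong effect** ($p_0 = 0$, $p_{\max} = 0.9$, $k = 1$):
  at least 0.95 over 200 replicates — the effect is enormous by
  construction, so anything less indicates a defect, not bad luck;
- **parameter recovery**: a pure level shift $\Delta$ with vanishing noise
  is recovered with $|\hat c_1 - \Delta| < 10^{-6}$.

## Data interchange

Session data travels as canonical CSV
(`case_id, session_index, phase, score, max_score, context, observer, date`;
UTF-8, LF, RFC-4180). Scores must be integers — the measure is a count of
correct responses — and fractional scores are rejected rather than rounded.
A `column_mapping()` translates foreign column layouts and phase
vocabularies ("baseline" → A, "training" → B, ...), so externally deposited
files can be imported without editing them. Measures serialize to versioned
JSON (`schema_version` field) with a bit-exact round trip. Reports serialize
to canonical-order JSON (byte-stable for identical input, which the
determinism tests rely on) or Markdown.

## Known limitations

- AB (+G) designs only: no multiple-baseline, ABAB or alternating-treatment
  support, and one behavior per series.
- Point estimates only for the non-overlap indices; inference lives in the
  parametric route.
- The two-stage regression's anti-conservatism is flagged, not corrected;
  randomization tests and multilevel models are out of scope.
- The covariance-assumption operationalization is a documented convention;
  other formalizations of "cov > 0" exist.
- No handling of missing sessions; the time axis must be complete.
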