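---
title: "Models and methods: patch depletion, foraging optimality, and delay discounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: patch depletion, foraging optimality, and delay discounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchforage)
```

# The task and its idealisation

The sequential patch depletion procedure offers a water-restricted rat a
choice between two "patches" (snout-poke receptacles). Entering a patch
delivers a full reward, and each successive *stay* delivers 20% less than
the one before (150, 120, 96, 76.8, ... uL by default). Rewards within a
patch are separated by a 4-s fixed interval. A *leave* switches to the
alternative patch: a changeover delay (COD; 0–24 s) simulates travel cost,
and the abandoned patch replenishes to its full volume. Sessions last 10
minutes or until 5 mL has been earned.

`patchforage` models the timing the task's own optimality arithmetic
assumes: the agent claims every reward at the earliest permitted instant.
Reaction, approach and drinking times are not modelled. Three consequences
deserve emphasis:

* the session's first patch entry occurs at `t = 0` with its reward
  delivered at the same instant, and a leave poke is coincident with the
  last reward consumed. Event *times* are therefore non-decreasing while
  `(time, event_index)` is strictly increasing — two events may share a
  timestamp but never an order;
* at COD 0, an agent that leaves after every reward earns at an unbounded
  instantaneous rate (the travel-free limit in which the rate of the
  first reward, volume/0, is infinite). Such sessions collapse onto a
  single timestamp, and the water-rate measure, whose denominator is the
  elapsed earning time, is then undefined and reported as missing rather
  than infinite;
* the volume cap is interpreted as in the procedure's description: the
  reward that reaches the cumulative cap is still delivered, and the
  session ends immediately after it.

# The Marginal Value Theorem solver

For a stay count $n$ at changeover delay $D$, the cumulative rate of
return is

$$R(n, D) \;=\; \frac{\sum_{i=1}^{n} A f^{\,i-1}}{D + \tau\,(n - 1)},$$

with $A = 150$ uL the fresh-patch volume, $f = 0.8$ the depletion factor
and $\tau = 4$ s the inter-reward interval. The optimal stay count
$n^{*}(D)$ maximises $R$; the optimal rejection volume is the volume
scheduled next at that point, $A f^{\,n^{*}}$. Conventions fixed here:

* **Denominator structure.** The COD precedes the first reward of a
  patch (denominators $D$, $D + \tau$, $D + 2\tau$, ...), matching the
  worked arithmetic of the procedure (25, 27, 26.14 uL/s at $D = 6$).
* **Optimal time in patch** is defined as $\tau\,(n^{*} - 1)$: the span
  from a patch's first reward to the earliest leave opportunity. The
  source material only plots this curve; users preferring a convention
  that includes the travel delay or a terminal interval can compute it
  from `n_star` directly.
* **$D = 0$.** $R(1, 0) = +\infty$, so the optimum is to leave after
  every reward; optimal time in patch is 0 there, which is why the
  percent time deviation is undefined (reported missing) at COD 0.
* **Ties** break toward smaller $n$ (leave earlier), making the solver
  deterministic; the search bound is $n \le 100$, far beyond any
  maximiser of a geometric schedule whose volumes fall below 0.1 uL by
  $n = 35$.
* Volumes are carried at full floating precision; nothing is rounded to
  a pump resolution.

The solver is validated in the test suite against exhaustive search over
$n = 1..100$ for every integer COD from 0 to 60, and the rate curve's
unimodality (first local maximum = global maximum) is checked explicitly.

# Simulated agents

Three decision policies cover the analysis needs:

* `mvt_optimal` leaves exactly at $n^{*}(D)$ — the normative benchmark;
* `volume_threshold` leaves when the next scheduled volume falls strictly
  below a fixed threshold;
* `hyperbolic_discounter` values the alternative patch's full reward
  hyperbolically discounted by travel time, $V = bA/(1 + kD)$, and leaves
  when the next volume falls strictly below $V$. This is the generative
  counterpart of the fitted indifference-point model, so the simulator has
  a closed-form oracle: a deterministic discounter's realised rejection
  volume at delay $D$ is the largest scheduled volume strictly below
  $bA/(1 + kD)$.

Decisions are evaluated once per reward opportunity. With
`choice_noise > 0` the volume comparison becomes a logistic (softmax)
choice with scale in uL; `lapse` flips each decision with a fixed
probability. Patch sides alternate deterministically (there are only two
receptacles). Per-session random streams are derived from
`(protocol_seed, session_index)`, so any session is reproducible in
isolation and the rat's identifier never enters the stream.

# Dependent measures

Five measures are extracted per session and averaged per COD following
the protocol's analysis rules (sessions from the last two of four weekly
cycles; each week's first 0-s session excluded; a session's first and
final patches, with their associated patch changes, excluded):

* **PC** — patch changes: leaves terminating included (complete) visits;
* **TIP** — mean time in patch over complete visits;
* **rejection volume** — the volume scheduled next at the moment of each
  leave, averaged over complete visits (the task's indifference point);
* **WR** — water rate: total volume earned divided by elapsed earning
  time, per kg body weight. "Time required to earn" is taken as the span
  from session start to the final reward, not the nominal session length;
  a cap-truncated session is not padded with dead time. This choice is
  localised in `session_metrics()` and easily substituted;
* **VD / TD** — percent deviations from the optimal rejection volume and
  optimal time in patch. VD is signed so that positive = overharvesting
  (staying past the optimum); TD so that positive = staying longer than
  optimal. TD is undefined at COD 0 (optimal time 0) and propagated as
  missing. Sessions with no complete visit yield missing metrics, never
  zeros.

# Discounting models

Each rat's rejection volumes across CODs form an indifference curve
fitted with the anchored hyperbola $V = bA/(1 + kD)$: $b$ is *not* a free
parameter but the 0-delay indifference point over $A$, and $k \ge 0$
minimises the residual sum of squares over the positive delays (the
0-delay residual is zero by construction and excluded). The
one-dimensional search is a deterministic bounded minimisation in
$\log k$ over $[10^{-6}, 10^{2}]$, with $k = 0$ checked explicitly so a
flat curve fits zero discounting exactly. The fit always uses the curve's
actual delays as recorded in the task configuration.

The normalized AUC is the model-free summary: delays normalised by the
maximum delay, indifference points by $A$ (clipped to $[0, A]$ with a
flag; clipping applies to the AUC only, not the hyperbolic fit), area by
the trapezoid rule. Smaller AUC means steeper discounting, i.e. more
overharvesting.

**Quantization limits identifiability.** Rejection volumes can only take
values on the geometric schedule, so the indifference curve is a
staircase in $(k, b)$: all parameter values between two threshold
crossings produce identical data. With five delays and 20% volume steps
the induced cells are wide, and zero-noise parameter recovery is
accordingly coarse — the recovery experiment reports the realised error
rather than assuming it negligible. Two practical corollaries, both
verified in the test suite: (i) the simulate-then-fit chain introduces
*no* error beyond this quantization (fits on simulated data equal fits
on the closed-form quantized volumes); (ii) small positive choice noise
dithers the staircase — per-COD means then take intermediate values — so
recovery error does not increase from zero noise, and the noise-dependence
of recovery RMSE is assessed over positive noise levels (3, 8, 15 uL),
where it grows monotonically.

# Cohort statistics

* **Composites** are sums of each measure across delays (TD across the
  delays where it is defined, i.e. excluding COD 0); `k` and AUC pass
  through unchanged. Rats with missing cells are excluded with a message.
* **Correlations** are pairwise-complete Pearson matrices per sex over
  {k, AUC, VD, TD, TIP, PC, WR}.
* **Meng z** compares two dependent correlations sharing a variable via
  Fisher transforms with the published heteroscedasticity factor
  ($f$ capped at 1). It is cross-checked in the tests against an
  independent transcription of the formula and against a simulated null
  (type-I error within 0.04–0.06 at $\alpha = 0.05$).
* **Mixed ANOVA** uses delay as the within-subject factor and sex
  between, the design described for these analyses (some summaries
  elsewhere label them "two-way between-subject"; the mixed design is
  what the factors describe, and that is what is implemented). Effect
  sizes are partial eta squared. A Greenhouse–Geisser epsilon (Box
  epsilon of the pooled within-group covariance) and adjusted p-values
  are reported for within effects, but the uncorrected F is primary,
  matching the convention of reporting uncorrected degrees of freedom.
* **Post-hocs**: per-delay independent-samples t-tests between sexes
  with a Bonferroni family of the five delays, Cohen's d from the pooled
  SD; within-subject paired comparisons over all ten delay pairs, also
  Bonferroni-corrected (the family sizes are conventions, stated here
  because no canonical choice exists for the within-subject family).
* **Normality screen**: bias-corrected sample skewness ($G_1$), gated at
  $|G_1| < 1$.

# The synthetic cohort

The generator emulates the study design, not any estimated rat
population: two sexes, heterogeneous per-rat parameters, 24 sessions per
rat. Defaults, chosen once as plausible desk-scale values:

| parameter | default | rationale |
|---|---|---|
| cohort size | 100 + 100 | desk-scale stand-in for a large outbred cohort (full scale ~900/sex) |
| k | log-normal, median 0.02 /s, sdlog 0.5, both sexes | mid-range discounting: deterministic mid-k agents overharvest at short CODs and drift to/past optimal at long CODs, the qualitative deviation-curve shape of interest |
| b | truncated normal on [0.4, 0.8]; male mean 0.62, female 0.70 (sd 0.08) | sex difference injected through stay bias, not k, mirroring patch-utilisation differences without discounting-rate differences; the 0.8 ceiling keeps 0-delay leave thresholds below the second scheduled reward so COD-0 sessions have positive duration under idealised timing |
| body weight | normal; male 0.45 (0.05), female 0.30 (0.03) kg | adult rat weights; drives the WR normalisation asymmetry |
| choice_noise | 5 uL | visible but moderate decision noise |
| lapse | 0.01 | rare attentional slips |

What the generator does *not* emulate: estrous cycles, batch or
test-order effects, response latencies, satiation dynamics beyond the
volume cap, or any genetic structure. Passing tests on these cohorts
therefore demonstrate the correctness and calibration of the pipeline's
computations, not claims about real rats; the printed F/t/r values of any
real cohort depend on data this package does not ship.

Problem sizes used in the shipped tests are deliberately modest (cohorts
of 6–40 rats for pipeline checks, 500/sex for distribution checks, 2,000+
replicates for the null calibration); all are generated in code under
fixed seeds.

# Degenerate inputs and numerical choices

* Rate at $n = 1$, COD 0 is $+\infty$ by definition (see above).
* `percent_time_deviation` returns `NA` where the optimal time is 0.
* A session with no complete visit contributes missing values;
  aggregation averages available sessions and records the count.
* Harvest classification treats $|VD| < 10^{-9}$ as optimal — adequate
  for deterministic simulations whose deviations are exact zeros up to
  float error; noisy cohorts are effectively classified by sign.
* `mixed_anova` on a constant response reports exactly null effects
  (zero SS/F/eta squared, undefined p) rather than float fuzz.
* Correlation matrices set zero-variance variables to missing with a
  warning rather than failing.
* All serialization is locale-independent CSV/JSON/YAML; event-log times
  are written with six decimals, which is exact for the integer-valued
  event times the default task produces.

# Interfaces

The package's surface is its R functions, composed by `run_study()` and
`pipeline()` (which writes a checksummed run directory with a JSON
manifest); `scripts/acceptance.R` reproduces the printed optimality
quantities from the command line. Event logs, metrics, fits and the
statistical tables all read/write plain CSV so external tooling — or
logs from real operant chambers mapped into the documented event-log
schema — can enter the pipeline at any stage.
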