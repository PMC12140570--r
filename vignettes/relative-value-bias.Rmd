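---
title: "Measuring relative value bias in bandit tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring relative value bias in bandit tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relbandit)
```

## The phenomenon and the paradigm

When humans learn option values from trial-and-error feedback, the encoded
value of an outcome depends on the other outcomes experienced alongside it:
an option that usually wins its local comparisons acquires high *relative*
value even if its absolute payoff is modest. The standard paradigm for
exposing this is a bandit task in two phases. In the **learning phase**,
options are locked into fixed contexts of two or three and presented with
*complete feedback* — the outcomes of chosen and unchosen options are both
revealed every trial. In the **transfer test**, all pairs of options are
pitted against each other without feedback. A learner that encoded absolute
values generalizes correctly; a relative encoder keeps preferring each
context's "frequent winner", which on some cross-context pairs is the
*lower*-paying option. The same paradigm has recently been applied to large
language models by translating the tasks into natural-language prompts;
this package implements that entire analysis pipeline with simulated
cognitive agents standing in for the LLM, so every stage is testable
against known ground truth.

## The task battery

Five task structures are shipped (`builtin_tasks()`), spanning 4–10
options, binary and ternary contexts, Bernoulli and Gaussian rewards, gains
and losses, and 48–60 learning trials divided evenly among contexts:

```{r tasks}
purrr::map(builtin_tasks(), ~ tidy(load_task_spec(.x)) |>
             dplyr::mutate(task = .x)) |>
  dplyr::bind_rows() |>
  dplyr::count(task, kind)
```

Two parameterizations are taken directly from published values: `V2023`
(win probabilities {0.1, 0.4} and {0.6, 0.9} on 0/1-point outcomes) and
`HW2023a`, whose Gaussian means follow the uniform $3 staircase 15–36
(sd 1) — the unique even-spacing layout consistent with the published
per-option expected values ($18, $21, $33), the ~[12, 39] reward range, the
0.625 ideal choice rate and the six incongruent transfer pairs. The other
three (`B2018`, `BP2023`, `HW2023b`) are **synthetic reconstructions**:
their exact distribution parameters are not printed in machine-readable
form, so the shipped configs were chosen, once, to satisfy every published
structural constraint (option and context counts, distribution family,
reward range and currency, presence of losses or of frequency/EV-conflict
contexts, equal-EV pairs only in `BP2023`) *and* to reproduce each task's
published ideal-agent choice rate (0.625, 0.969, 0.500). They are labelled
as reconstructions in their config files, and every analysis is
config-driven, so corrected parameters drop in without code changes.

Two schedule properties matter downstream. First, Bernoulli outcome
sequences are **exact-frequency**: over an option's learning trials the
high outcome occurs exactly `round(p * n)` times, so realized frequencies
match design probabilities exactly and the empirical mean equals the
expected value to machine precision. All built-in tasks have integral
`p * n`; a non-integral product is rounded half-up with a warning. Second,
the context sequence is a seeded random interleaving and the presentation
order of options is re-randomized every trial — the first-listed option is
the one that receives the position bias.

## Relative value, congruency, and the ideal agent

Relative value is defined by the **frequent winner** rule: within a
context, option *i* ranks above *j* when a draw from *i* beats a draw from
*j* more often than the reverse, `P(i > j) > P(j > i)`. (With Bernoulli
outcomes ties are frequent, so the one-sided probability itself can be
below ½ for the frequent winner; the majority comparison, not a fixed 0.5
threshold, is the defining criterion. For Gaussian options the two
coincide.) Ranks are normalized to {0, 1} (binary) or {0, ½, 1} (ternary).

Each transfer pair is then `congruent` (the higher-relative-value option is
also the expected-value maximizer), `incongruent` (it is not), `rel_tied`
(equal ranks), or — a logical possibility none of the built-ins realize —
`ev_tied` (distinct ranks, exactly equal EVs). The **ideal choice rate** is
the fraction of congruent pairs among congruent + incongruent ones: the
rate at which an agent that always maximizes EV would pick
higher-relative-value options. Pairs tied on relative value are excluded
because the comparison is undefined; exactly tied EVs are excluded because
the maximizing choice is undefined. The rate is invariant to
`transfer_reps` since every pair appears equally often. Observed rates
credibly above this reference — the lower bound of a run-level 95%
t-interval exceeding it — are flagged as relative value bias.

Design distributions, not realized outcome sequences, define the ranks.
With exact-frequency sampling the two coincide for Bernoulli options, and
for Gaussian options the design definition is the only deterministic one.

## The cognitive model family

Subjective values mix two range normalizations of the outcome
(`encode_outcomes()`):

$$v(x_{i,t}) = (1-\omega)\,x^{ABS}_{i,t} + \omega\,x^{REL}_{i,t},
\qquad x^{norm} = \frac{x - \min}{\max - \min},$$

with $x^{ABS}$ normalized by the running range of all outcomes experienced
so far in the run and $x^{REL}$ by the range of the current trial's
outcomes only. Two numerical conventions are pinned by tests: the running
range **absorbs the current trial's outcomes before** $x^{ABS}$ is computed
(so the first trial's extremes map to 0 and 1, and the quantity is defined
from trial one), and a degenerate range (max = min) yields 0.5, keeping
$v$ defined and symmetric. Since $v$ is a convex combination of quantities
in [0, 1] it stays in [0, 1] for any $\omega \in [0,1]$ — loss-domain
rewards (B2018's −1/0 euros) need no special handling. Expectancies update
by the delta rule with a learning rate chosen per outcome: *confirmatory*
(chosen option better than expected, or unchosen worse) outcomes use
$\alpha_{CON}$, *disconfirmatory* ones $\alpha_{DIS}$; a zero prediction
error updates nothing. The softmax response uses $\beta$ (optionally
phase-specific) plus a first-position bias $b$, evaluated with max
subtraction so utilities up to ±700 are safe. $Q$ values reset to 0.5 and
the running range resets at the start of every run.

The candidate set is the 2×2×2 factorial (encoding × learning rates ×
temperatures), eight models with $k = 3 \dots 6$ parameters. The position
bias is present in all eight: the response rule includes it
unconditionally, and the factorial quoted for the family covers encoding,
learning rates and temperatures only.

## Fitting, comparison, recovery, cross-validation

A single parameter set is estimated per dataset by pooling per-run
log-likelihoods (each run keeps its own resets). The optimizer is bounded
multi-start local search: Latin-hypercube starts over
$\omega, \alpha \in [0,1]$, $\beta \in [0,100]$, $b \in [-10,10]$, refined
by L-BFGS-B (tolerance ~1e-8, default 20 starts). Bounds, start scheme and
tolerances are this package's choices — reasonable for the smooth, low-
dimensional likelihoods involved, and the multistart design guards against
the local optima that confirmation-bias likelihoods can have. Invalid
trials (e.g. malformed language-model responses) contribute neither a
likelihood term nor an expectancy update, mirroring how such trials carry
no usable choice; dropping the row or flagging it `valid = FALSE` are
equivalent, which is test-pinned.

Models are compared by BIC with `n` = the number of valid choice trials in
the pooled dataset; exact ties break toward fewer parameters. Model
recovery (`model_recovery()`) simulates from each candidate with parameters
drawn from behaviorally plausible ranges (documented in
`default_param_sampler()`), refits all eight, and tabulates the BIC winner;
the companion check is that misselections usually retain the generating
value function (a simpler same-encoding variant winning is the
characteristic BIC failure mode). The shipped acceptance-scale run uses two
tasks, five simulations per generating model and eight pooled sessions per
dataset — sizes chosen to make the above-chance test sharp while keeping a
full recovery sweep inside a few minutes on one CPU. Leave-one-run-out
cross-validation refits on all but one run and scores the held-out run as
pseudo-R² $= 1 - LL_M / LL_0$ against a chance model (½ per binary, ⅓ per
ternary choice); the null likelihood is evaluated through the same
compiled accumulator so the chance model scores exactly zero.

## The synthetic-data generator

Synthetic agents replace language models so the pipeline is testable
without any API. `simulate_session()` runs the family generatively: choices
sampled from the softmax, expectancies evolving only during learning,
transfer choices from frozen expectancies with $\beta_{transfer}$.
`simulate_grid()` reproduces the factorial design of repeated independent
experiments (5 tasks × 4 agents × 2 prompt conditions × 30 runs = 1200
sessions at study scale), with one derived seed per session so any single
session is reproducible in isolation (the splitting rule: `set.seed(master)`
then `sample.int`, one child seed per cell/stage).

What the generator deliberately does *not* emulate: text. Synthetic agents
never see prompts, so the comparison-prompt manipulation — which magnifies
relative encoding in real models — is emulated by raising $\omega$ by 0.15
(capped at 1) in comparison cells. The boost size sits inside the shift in
fitted encoding weights reported for instruction-tuned models
(≈0.11 → ≈0.26) while being large enough to separate the conditions at 30
runs; it is a documented default of `simulate_grid()`, not a fitted
quantity. Synthetic agents also never produce invalid responses (the
`valid` flag exists for ingesting real logs), and each session draws its
own outcome schedule — schedules are not shared between prompt conditions,
since the pairing convention of the original runs is unknowable. Passing
tests on synthetic grids therefore validates the *pipeline* (likelihood
code, statistics, decision rules), not any claim about real language-model
behavior; real logs enter through `read_sessions()` and flow through the
identical code path.

The four `default_agents()` span the encoding × confirmation-bias corners,
with the confirmation-bias parameterizations placed in fitted-estimate
territory ($\alpha_{CON} \approx 0.5 > \alpha_{DIS} \approx 0.15$,
$\beta_{learn} 18 > \beta_{transfer} 11$, $b \approx 1.2$).

## The prompt harness

`render_prompt()` produces the natural-language trial text: instructions,
one block per past round (outcomes in presentation order), and the fixed
closing sentence ("... Give your answer like this: I would choose slot
machine _. Do not explain why."), with letters A–J randomly assigned per
run. The comparison template appends an explicit clause relating each
outcome to the first-listed one ("..., which is more than the $14 delivered
by slot machine C."); the published wording of that clause exists only as a
figure image, so the template is configurable and the shipped default
preserves the manipulation's semantics (explicit local more/less
comparisons) rather than claiming verbatim replication. `parse_choice()`
accepts only the canonical sentence (case-insensitive, trailing punctuation
tolerated) and returns `NA` otherwise — invalidity is a value, not an
error, and trials are skipped rather than re-prompted.

## The hidden-state probe

The probe asks whether per-trial activations (e.g. a transformer's final
hidden layer at the last prompt token) carry absolute- and relative-value
information. For each transfer trial the design holds the unsigned
difference in absolute values (expected values min-max normalized across
the task's options — the design-EV convention is the default, and
configurable) and in relative values (within-context rank values), both in
[0, 1]. Each unit is regressed separately
(`activation ~ dabs + drel`); significance is counted per regressor after
a deliberately conservative default correction, Bonferroni at family-wise
0.05 over units × 2 regressors (the exact published rule lives in
supplementary material, so the method is a config knob with Bonferroni
default). `coefficient_contrast()` compares mean unsigned coefficients
across units with a paired t-test. `synth_activations()` plants known
loadings plus Gaussian noise so the full loop — plant, synthesize, regress,
correct, count — is validated: at a signal-to-noise ratio of 10 or more
(|loading| × sd(regressor) / noise sd) the corrected counts recover the
planted sparsity pattern, and on pure noise the corrected false-positive
count stays at the expected fraction of a unit.

## Scope and limitations

* No network calls: the adapter surface for real language models is the
  session-log schema (`read_sessions()`), not a vendor client.
* Estimation is pooled maximum likelihood, as in the source analyses; no
  hierarchical or per-run estimation.
* The omnibus ANOVA / estimated-marginal-means machinery of the original
  behavioral analyses is out of scope; the bias decision rule is preserved
  with run-level t-intervals instead, which answers the same question
  (interval vs. ideal) self-containedly. Run-level rates are weighted
  equally, not by trial counts.
* `BP2023`'s published ideal rate (0.969) depends on supplementary
  parameters; the shipped reconstruction reproduces it, but treat that
  task's exact distribution values as illustrative rather than canonical.
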