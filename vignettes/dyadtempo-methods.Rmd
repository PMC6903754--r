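---
title: "Methods: temporal microstructure of dyadic agonistic behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal microstructure of dyadic agonistic behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadtempo)
```

# Scope and data model

`dyadtempo` analyses how pairs of animals (dyads) settle into
dominant–subordinate roles from coded behavioral event logs. The input
is a tidy long table, one row per behavior bout: `dyad_id`, `day`,
`subject_id`, `behavior`, `onset_s`, `offset_s`, with times in seconds
inside each day's session (default 1200 s). An ethogram maps each
behavior to one of seven states; lunge, bite and tail rattle are
*Aggressive*, flee, freeze and subordinate posture are *Subordinate*,
and these two states jointly form the *agonistic* substrate of the
analysis. Sessions on different days are physically separate trials:
no interval logic (bursts, tiles, phases) ever crosses a day boundary,
although bursts are *numbered* cumulatively across days and phase
boundaries are *located* on the cumulative clock
$(\mathrm{day}-1)\cdot 1200 + t$.

Bout overlaps within one subject (e.g. a tail rattle during a freeze)
are accepted; every downstream statistic uses onsets, except phase
proportions which use durations. Exact onset ties between the two
animals are kept — distinct animals can genuinely co-initiate — and
perturbed forward by $10^{-6}$ s only so that gap-based algorithms see
strictly positive gaps; this is far below the resolution of manual
behavior coding.

# Burst detection

Agonistic onsets of both partners are pooled per dyad-day and fed to a
finite truncation of Kleinberg's infinite-state burst automaton. For
$n$ onsets spanning $T$ seconds, the gaps $x_1,\dots,x_{n-1}$ are
modelled as exponential with state-dependent rate
$\alpha_i = (n/T)\,s^i$; emitting gap $x$ in state $i$ costs
$-\ln \alpha_i + \alpha_i x$, climbing from state $i$ to $j > i$ costs
$\gamma (j-i)\ln n$, and descending is free. The minimum-cost state
path is found by dynamic programming; *second-order bursts* are the
maximal runs of gaps in state $\ge 2$, spanning from the onset that
begins the first qualifying gap to the onset that ends the last.

Parameter choices:

* $\gamma = 0.3$ (default) — the state-climb penalty.
* $s = 2$ — the rate ratio between adjacent states. It is exposed as an
  argument because analyses of this kind rarely report it; $s = 2$ is
  the convention of the widely used reference implementation.
* The infinite automaton is truncated at the smallest state whose
  expected gap $1/\alpha_k$ falls below the minimum observed gap (such
  states can never lower the optimal cost), states $0..k$.
* $T$ is the span of the pooled series, not the session length, so the
  base rate describes the observed stream.
* Cost ties in the dynamic program break toward the lower state:
  deterministic output, fewer spurious bursts.
* Events whose onset equals a burst endpoint count as inside the burst.

The Viterbi solution is verified against exhaustive search over all
capped state sequences for small series; on synthetic dyads with
planted high-rate windows, detected level-2 intervals overlap planted
bursts essentially one-for-one (the acceptance battery requires
$\ge 90\%$).

# Relationship resolution

For every burst a $2\times 2$ matrix is tallied: $a$/$b$ are
aggressive/subordinate onset counts by the *eventual dominant*, $c$/$d$
by the *eventual subordinate*. The eventual dominant is the subject
with the higher aggressive and lower subordinate count pooled over the
last two bursts; both comparisons must agree, a tie on one side defers
to the other, and a conflict raises a role-ambiguity error (callers may
force roles).

Two criteria locate the burst at which the relationship resolves:

* **Phi-coefficient method (stringent).**
  $\phi = (ad - bc)/\sqrt{(a+b)(c+d)(a+c)(b+d)}$, significance from
  $X^2 = N\phi^2$ against $\chi^2_1$ (upper tail, no continuity
  correction — this keeps the identity $X^2 = N\phi^2$ exact). Bursts
  with $N < 6$ instances, or with a zero margin (the denominator
  vanishes; $\phi$ requires both animals to act), are *excluded*:
  they are skipped entirely when evaluating the rule, and in
  particular an excluded final burst cannot veto resolution. The
  relationship resolves at the earliest burst $k$ such that $k$ *and*
  every later evaluable burst satisfy $\phi > 0,\ p < 0.1$; with only
  one or two evaluable bursts remaining the rule degenerates to
  requiring exactly those. Reading the rule as including burst $k$
  itself is what permits a dyad to be resolved from its very first
  burst. If the final evaluable burst fails, the dyad is unresolved.
* **Difference method (lenient).** Resolution at the earliest burst
  from which $(a-c) \ge (b-d)$ holds for every remaining burst. All
  bursts are evaluated (the $N<6$ exclusion belongs to the phi
  criterion only), and the tie $(a-c) = (b-d)$ satisfies the literal
  $\ge$.

Both rules are verified against brute-force scans over every candidate
index on randomly generated burst sequences.

**Phases.** *Pre-resolution* is all session time strictly before the
start of the difference-method burst; *post-resolution* all time
strictly after the end of the phi-method burst; *middle* the remainder,
which by construction contains both boundary bursts. If phi never
resolves, the post phase is empty and the middle runs to the study end.
The difference burst starting after the phi burst ends would make the
phases ill-defined, so that ordering raises an error rather than
producing overlapping windows. Cumulative time to resolution counts
1200 s per completed prior day plus the within-day time at the
resolution burst's end.

Phase-wise behavior use is summarised as the proportion of phase time
each subject spends in each behavior (bout durations clipped to the
phase windows), compared between roles with paired Wilcoxon signed-rank
tests. The Wilcoxon policy is fixed throughout the package: zero
differences dropped, exact distribution up to 25 untied informative
pairs, otherwise the normal approximation with tie correction.

# First-order Markov transition analysis

Each subject's events in a phase are collapsed to a no-repeat sequence
(consecutive duplicate labels merged), giving a transition table with
structural zeros on the diagonal. Expected counts under
*quasi-independence* come from iterative proportional fitting: seed 1
off the diagonal, 0 on it, then alternate row and column scaling until
the largest margin discrepancy is below $10^{-10}$ (cap 10,000
iterations; rows or columns with zero observed margin are dropped from
the fit and from the degrees of freedom). The global likelihood-ratio
statistic is $G^2 = 2\sum_{O>0} O\ln(O/E)$ (natural log, as the
chi-square reference requires) on $(k-1)^2 - k$ df for $k$ observed
labels, so a two-label table ($df = -1$) is reported as
test-not-defined rather than given a fabricated p-value.

Per-transition significance uses permutation nulls that preserve the
defining structural property: the sequence is rearranged with **no
adjacent repeats**. The sampler is rejection from uniform shuffles
(unbiased) when that has a realistic chance of succeeding; a uniform
shuffle of a length-$n$ sequence avoids adjacent repeats with
probability $\approx e^{-(n-1)\sum_i p_i^2}$, which for realistic
sequences (hundreds of events) is astronomically small, so in that
regime the sampler goes directly to a constructive pass that places
labels one at a time among feasibility-preserving candidates weighted
by remaining multiplicity. The constructive sampler is not exactly
uniform over arrangements; it is used precisely where no practical
unbiased sampler exists, and the null calibration check (below) bounds
the consequence. A multiset with one label on more than
$\lceil n/2\rceil$ positions admits no arrangement and is an error.

The permutation p-value is, per the strict reading of "occurred more
frequently", $\#\{\text{count}_\text{perm} > \text{count}_\text{obs}\}
/ n_\text{perm}$ (default 1000 permutations); the conventional
$(\#\{\ge\} + 1)/(n_\text{perm}+1)$ form is available via `ge = TRUE`.
Under quasi-independent nulls the strict form is conservative: the
acceptance battery requires the fraction of $p \le 0.05$ to stay at or
below 0.075.

Group summaries (dominant/subordinate × pre/post) take medians of p and
of transition probability across all individuals in the group;
individuals lacking a transition contribute $p = 1$ and probability 0,
so the median is always over the full group rather than an unstated
subset. A transition is *significant* at median $p \le 0.01$ and
*meaningful* at median probability $\ge 0.075$. Transition matrices are
built over the labels present in each individual's sequence, not the
full 19-behavior ethogram — all-zero rows would break the IPF and the
df adjust automatically. Sequences with fewer than 10 transitions
(configurable) are excluded and flagged, mirroring the exclusion of
uninformatively short pre-resolution records. Kinetograms (directed
graphs, edge weight = median probability, node size = median relative
frequency) are exported as GraphML and DOT.

# Forward Spike Time Tiling Coefficient

For onset trains $A$ (the actor's given behavior) and $B$ (the
partner's target behavior) sharing observation windows,

$$\mathrm{FSTTC}(A \to B) = \frac{1}{2}\left(
  \frac{P - T_B}{1 - P\,T_B} + \frac{P - T_A}{1 - P\,T_A}\right)$$

where $P$ is the proportion of $B$ onsets lying within $\Delta t$
*after* some $A$ onset, and $T_A$, $T_B$ are the proportions of total
observation time covered by the forward tiles $(t, t+\Delta t]$ of each
train. $\Delta t = 2$ s throughout. The coefficient is 0 when $P$ sits
at both chance levels ($P = T_A = T_B$), exactly 1 when every $B$
onset tails an $A$ onset, and negative below chance. Unlike the
symmetric original (provided as `sttc()` for cross-checking), the
forward variant uses a single directional $P$, which makes
$A \to B$ and $B \to A$ genuinely different quantities; that asymmetry
is intentional and is what the direction comparison tests.

Boundary conventions: onset pairs count when $b - a \in [0, \Delta t]$
(co-initiation counts); tiles are half-open $(t, t+\Delta t]$ and are
clipped at window and session ends; onsets and time on different days
never interact. The $\le 2$ ms discrepancy the closed/half-open
asymmetry can cause is far below coding resolution. Undefined cells
(empty trains, zero observation time, vanishing denominator) propagate
as missing and are dropped pairwise from tests — never imputed as 0,
because 0 is a meaningful "at chance" value.

Default contingency groupings pool biting with lunging, keep tail
rattling separate (its consequences differ by status), pool the three
subordinate behaviors, and add every full ethogram state; groupings are
fully configurable. Direction differences (DOM→SUB vs SUB→DOM) per
phase are tested with paired Wilcoxon signed-rank tests across dyads.

# The synthetic world

No raw codings are distributed with this package, so every pipeline
stage is validated against a generator with planted ground truth
(`synthetic_config()` / `simulate_dyad()` / `simulate_cohort()`). Its
defaults *are* the stated world and are not tuned to test outcomes:

| parameter | default | rationale |
|---|---|---|
| dyads × days × session | 21 × 5 × 1200 s | the emulated study design |
| bursts per day | 6, 3, 2, 2, 1 | observed median daily burst counts |
| burst duration | 15–25 s day 1, +2 s/day | observed medians and their day trend |
| agonistic rate in / out of bursts | 0.5 / 0.005 events·s⁻¹·subject⁻¹ | most agonistic behavior inside bursts; rate ratio ≫ detection floor |
| resolution burst $k^*$ | 6 (first burst of day 2) | most dyads resolve after day 1 |
| pre-$k^*$ aggressive probability | 0.5 | symmetric, undifferentiated contest |
| post-$k^*$ role fidelity | 0.95 | near-exclusive role-consistent behavior |
| filler rate | 0.25 events·s⁻¹·subject⁻¹ | hundreds of events per subject-day, matching the ~10⁵-event scale |
| bout durations | lognormal, median 1.5 s (filler), 0.8 s (agonistic) | short bouts, right-skewed |

Role differentiation is indexed by burst ($k^*$), not clock time, so
the resolution criteria have a well-defined recovery target. Forward
contingency is planted by inserting, with probability $\theta$, a
responder onset at $\mathrm{Uniform}(0.1, \Delta t)$ seconds after a
given onset, displacing the responder's next scheduled bout — a
directional dependency matching exactly what the FSTTC measures.
Determinism: per-dyad seeds derive from the master seed and dyad index,
so any dyad reproduces independently of cohort order.

What the generator does *not* emulate: within-burst escalation
structure, autocorrelated bout durations, observer coding noise, or
behavior-specific baseline rates (filler labels are near-uniform unless
a kernel is supplied). A green recovery test therefore establishes that
the estimators recover the statistical structure they model — not that
real mice behave like the generator.

## A deliberately red check

The recovery battery requires both resolution criteria to land within
±1 burst of $k^*$ in ≥ 80% of replicates. The phi criterion passes
(~0.98 measured). The difference criterion measures ~0.70 and the
check is left failing rather than weakened: with symmetric pre-$k^*$
mixing, each pre-resolution burst satisfies the lenient
$(a-c) \ge (b-d)$ by chance with probability ≈ 0.55 (slightly above
one half because ties count), so two consecutive chance passes
immediately before $k^*$ — probability ≈ 0.3 — pull the earliest
qualifying index at least two bursts early. This is a property of the
lenient criterion in a symmetric world, consistent with its observed
tendency to resolve much earlier than the phi criterion; making it
pass would require changing the stated generator defaults, which would
invert the logic of the test.

# Numerical choices and edge cases

* Exact onset ties: stable order, $+10^{-6}$ s perturbation (above).
* IPF tolerance $10^{-10}$ on margins; tests require reproduction to
  $10^{-8}$; non-convergence is an error reporting the discrepancy.
* Days with fewer than two agonistic onsets contribute no bursts; days
  with zero onsets of a state report burst-coverage proportions as
  missing, not zero.
* Phases of zero duration are omitted; phase windows partition each
  day's session to machine precision (asserted in tests).
* All randomness flows through explicit seeds; pipeline stages derive
  named streams from one manifest seed.

# Worked example

```{r, eval = FALSE}
library(dyadtempo)
cfg <- synthetic_config(n_dyads = 3, n_days = 3,
                        bursts_per_day = c(4, 2, 1), resolution_burst = 4)
cohort <- simulate_cohort(cfg, seed = 9)
res <- run_pipeline(cohort$log, out_dir = "results", n_perm = 1000, seed = 9)
res$resolution
summarize_resolution(res$resolution)
```

# Limitations

* The constructive no-repeat sampler is approximately, not exactly,
  uniform; permutation p-values for extreme-multiplicity sequences
  inherit that approximation.
* The burst-boundary convention (intervals end on event onsets) and the
  rate ratio $s$ are conventions, not estimated quantities; both are
  exposed as arguments.
* Group-level inference (medians with fixed thresholds) is descriptive
  screening, not error-rate-controlled multiple testing.
* Regression modelling of day trends (burst counts, durations) is out
  of scope; the package reports descriptive medians and IQRs only.
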