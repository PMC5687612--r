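---
title: "Methods: the Bayesian pick-the-winner design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Bayesian pick-the-winner design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pickwinner)
```

## The design

A two-arm randomized phase II screening trial asks two questions at once:
*is either regimen active at all?* and *if both are, which one should go to
phase III?* The pick-the-winner design implemented here answers the first
question with a Simon two-stage futility design run independently in each
arm, and the second with a Bayesian posterior comparison of the two response
rates.

Each arm's Simon design is a quadruple $(n_1, r_1, n, r)$: enrol $n_1$
patients, stop the arm if at most $r_1$ respond; otherwise enrol $n - n_1$
more and declare the arm ineffective if the total responder count is at most
$r$. An arm exceeding $r$ is *competitive*. The decision calculus is then:

* neither arm competitive — no winner, the trial is negative;
* exactly one competitive arm — it is the winner outright;
* both competitive — compute $\Pr(B > A)$, the posterior probability that
  arm B's true response rate exceeds arm A's, and declare B the winner if
  $\Pr(B>A) > \delta$, A the winner if $\Pr(B>A) < 1 - \delta$, and no
  clear winner otherwise.

With a $\mathrm{beta}(a, b)$ prior on a response rate $\theta$ and $k$
responders among $n$ patients, the likelihood $\theta^k (1-\theta)^{n-k}$
gives the conjugate posterior $\mathrm{beta}(a + k,\, b + n - k)$, so
$\Pr(B>A) = P(X > Y)$ for independent beta variables $X$ and $Y$ with the
two arms' posterior shapes. Note that the final responder count of an arm
that passed both stages is *not* binomially distributed (the stage-1 bound
truncates the sample space), but its likelihood in $\theta$ retains the
binomial kernel, so the conjugate update is exact.

### Computing $P(X > Y)$

When either shape pair is integer-valued (every posterior arising from the
uniform, unfavorable or favorable priors is), `prob_beta_greater()` uses a
closed form: with $m = a_A + b_A - 1$ the beta CDF with integer shapes is a
binomial tail, and term-by-term integration gives

$$P(X > Y) = \sum_{j=a_A}^{m} \binom{m}{j}
  \frac{B(a_B + j,\, b_B + m - j)}{B(a_B,\, b_B)},$$

accumulated on the log scale for stability. For fractional shapes (the
moment-matched prior family produces shapes like 9.2) it falls back to
adaptive quadrature of $\int_0^1 f_X(x)\, F_Y(x)\, dx$ with relative
tolerance $10^{-8}$ (the `tol` argument). Both variables are continuous, so
$P(X>Y) = P(X \ge Y)$; tests cross-check the two routes against each other
and against Monte Carlo sampling.

## Prior families

`prior_spec()` implements four reference families:

| family | arm A | arm B | notes |
|---|---|---|---|
| `noninformative` | beta($c,c$) | beta($c,c$) | $c = 0$ Haldane, $0.5$ Jeffreys, $1$ uniform |
| `unfavorable_B`  | beta($c,0$) | beta($0,c$) | improper; tilts against B |
| `favorable_B`    | beta($0,c$) | beta($c,0$) | mirror image |
| `moments`        | matched to `mean_A`, `sd` | matched to `mean_B`, `sd` | proper, default sd 0.1 |

Improper priors are representable — the update may still give a proper
posterior — and properness is enforced at computation time with the
offending arm named in the error. The three non-informative choices give
almost identical winner probabilities (spread below 0.02 on the reference
design), which is why the package defaults to the uniform prior: it is the
least committal choice when no preliminary data exist. The unfavorable and
favorable families move $\Pr(B>A)$ monotonically down and up as $c$ grows.

A structural fact worth knowing (Altham's identity): with the unfavorable
pair at $c = 1$ — posteriors $\mathrm{beta}(k_B, f_B + 1)$ and
$\mathrm{beta}(k_A + 1, f_A)$ — the winner probability and the one-sided
Fisher exact p-value are complementary, $\Pr(B>A) = 1 - p$. The orientation
of this identity was fixed computationally against brute-force enumeration
before being asserted suite-wide (`altham_identity_check()` verifies it to
$10^{-10}$ on exhaustive small tables). It explains why the Bayesian rule
with a non-informative prior is systematically less conservative than the
Fisher test: the uniform prior removes the unfavorable tilt.

## Choosing $\delta$

$\delta$ only acts when both arms are competitive, so it shapes the *local*
power and type I error. On the reference design (Simon optimal for 20% vs
40%, $\alpha = \beta = 10\%$, i.e. $(17, 3, 37, 10)$ per arm):

* at $\delta = 0.5$ the rule is a coin flip — under the null exactly half of
  the both-pass mass misclassifies arm B;
* at $\delta = 0.8$ the local null misclassification drops below 0.02% while
  local power under 40% vs 20% only halves (from ~8% to ~4%);
* $\Pr(B>A)$ tracks the observed response-rate difference closely (see
  below), and $\delta = 0.8$ corresponds to roughly a 10 percentage-point
  difference — a clinically meaningful margin.

The package default is therefore $\delta = 0.8$, with `delta_sweep()`
available to retune the trade-off for other designs.

### The winner probability as a response-difference scale

`prob_vs_difference_map()` tabulates $\Pr(B>A)$ for every both-pass count
pair against the observed difference $(k_B - k_A)/n$. Within a distinct
difference the probability varies very little (< 0.02) across the count
pairs the trial can realistically produce, so the threshold has a direct
clinical reading. The qualifier matters: at extreme counts (e.g. 35/37 vs
36/37) the posteriors concentrate and $\Pr(B>A)$ departs from the trend, but
under the design scenarios such pairs carry joint probability below
$10^{-8}$, and the summary excludes pairs under `min_mass` when true rates
are supplied for weighting. The unweighted map (no rates given) still lists
every pair.

## Exact operating characteristics

The original evaluation of this design used simulation. The package instead
computes operating characteristics *exactly*: per-arm status probabilities
(fail stage 1 / fail stage 2 / pass) come from binomial sums, the two arms
are independent given the true rates, and the both-pass cell is decomposed
over all passing total-count pairs via `pass_total_pmf()` — at most
$27 \times 27$ pairs for the reference design — with the winner rule applied
to each pair. This removes Monte Carlo noise; agreement with the published
simulated values is asserted at their printed rounding, and a seeded
simulator (`simulate_oc()`) cross-validates the enumeration within three
Monte Carlo standard errors at $10^5$ replicates in the test suite.

Numerical conventions:

* **Strict thresholds.** B wins iff $\Pr(B>A) > \delta$, A iff
  $\Pr(B>A) < 1 - \delta$, exactly as the rule is stated; the zone between
  is "no clear winner".
* **Threshold ties in enumeration.** Count pairs with $k_A = k_B$ give
  $\Pr(B>A) = 1/2$ exactly, a positive-mass event in the enumeration. At
  $\delta = 0.5$ the indeterminate zone collapses to that single point, and
  the enumeration credits half of the tied mass to each arm — the rule
  degenerates to a coin flip there, and this convention makes the local null
  misclassification at $\delta = 0.5$ equal half the both-pass probability.
  For any $\delta > 0.5$ the tie event at the threshold has zero mass with
  integer posteriors, so the convention is inert. The data-facing
  `pick_winner()` never flips coins: real tied trials return "no clear
  winner" with the probability reported.
* **Fisher comparator.** Rejection is strict ($p < \alpha$), with the
  one-sided p-value including the observed table, the standard convention.
* **Discreteness.** The single-stage randomized benchmark (`crt_power()`)
  rejects at one-sided Fisher $p < 0.09$ when comparing against the
  two-stage design's 9% type I error; because the test is discrete its
  attained size is below the nominal level, and whether the original
  benchmark used strict or non-strict rejection is not documented — the
  strict convention reproduces the published 62% power.

## Simon design search

`simon_search()` enumerates $(n_1, r_1, n, r)$ with $n \le$ `n_max`
(default 100, comfortably above the ~40-patient arms this design targets),
keeping designs with attained pass probability $\le \alpha$ at $p_0$ and
$\ge 1 - \beta$ at $p_1$. For each $(n_1, r_1, n_2)$ the smallest feasible
$r$ maximises power, stage-1 power prunes hopeless $r_1$, and the optimal
(minimum $EN(p_0) = n_1 + (1 - \mathrm{PET}_0)\, n_2$) or minimax (minimum
$n$, then $EN$) objective is applied with deterministic tie-breaking —
smallest $n$, then $n_1$, then $r_1$ — so repeated searches always return
the same design. An infeasible search reports "search bound exceeded" rather
than silently returning the best attempt. The interpretation of "10% error
rates" is the standard one: constraints $\alpha \le 0.10$ and power
$\ge 0.90$ on the attained (exact) rates.

## Simulation contract

`simulate_oc()` draws all replicates from a single seed in a fixed order —
stage-1 responders for arm A, then arm B, then stage-2 responders for
continuing arms — using vectorised binomial generation. Results therefore
depend only on the seed, not on any internal batching, and a one-replicate
run reproduces `simulate_trial()` under the same seed exactly. The default
of $10^5$ replicates gives standard errors around 0.1–0.16 percentage points
on the probabilities of interest, ample to check whole-percent quantities;
the test suite uses the same size to keep the full run within seconds.

## What the tests do and do not show

The test suite validates the machinery against brute-force oracles (double
binomial summation, table enumeration via `choose()`, Monte Carlo sampling,
an independent grid search for the Simon designs) and against the published
operating characteristics of the reference trial. The synthetic trials
simulate exactly the idealised model: independent binomial responses at a
fixed per-arm rate, no dropout, no accrual dynamics, no response
misclassification, and futility bounds applied exactly at the planned
interim. Real trials deviate from all of these; passing tests certify the
design calculations, not robustness of the trial to protocol deviations.
Known limitations: two arms only (the posterior comparison generalises to
more arms, but the decision calculus here does not), binary endpoints,
equal randomization, and no interim superiority comparisons between arms.
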