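---
title: "Modeling double-reading screeners and comparing pairing strategies"
author: "doubleread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling double-reading screeners and comparing pairing strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doubleread)
```

## The problem

In population screening programmes with double reading, every mammogram is
assessed independently by two radiologists; under a conservative combination
rule, an examination is treated as positive for the pair when *either* reader
flags it (disagreements go to consensus or arbitration). Readers vary
substantially in their operating points, and programmes usually pair them
without regard to those differences. `doubleread` implements a latent-trait
model of individual reader decisions, fits it to double-reading count data,
and uses the fitted (or synthetic) reader population to ask a policy
question: does the *rule used to pair readers* change the programme's group
true-positive rate (TPR) and false-positive rate (FPR)?

## The reader model

Positive (cancer) and negative (non-cancer) examinations are modeled
completely independently; everything below is done once per case class. For
reader $j$ and examination $k$, the latent decision variable is

$$ q_{jk} = r_j + C_k, $$

where $r_j$ is a fixed reader effect on the logit scale (absorbing any
global intercept) and $C_k \sim N(0, \sigma_C^2)$ is a case random effect
shared by *both* readers of examination $k$ — the shared difficulty of a
case is the only source of between-reader correlation. The conditional
probability of an abnormal interpretation is the logistic transform
$a_{jk} = \mathrm{logit}^{-1}(q_{jk})$, and the reader's marginal rate (their
FPR on negatives, TPR on positives) is the expectation over case effects,

$$ a_j = E_{C}\left[\mathrm{logit}^{-1}(r_j + C)\right]. $$

For a pair $(j, j')$, the case-conditional disagreement probability is
$a_{jk}(1-a_{j'k}) + a_{j'k}(1-a_{jk})$, and its expectation $d_{jj'}$ over
the shared case effect is the pair's marginal disagreement rate. Because both
conditional probabilities are increasing functions of the same $C$,
marginalizing over a shared case effect always yields *less* disagreement
than two independent readers with the same marginal rates would show — this
association is what makes the pair data informative about $\sigma_C$.

Counts are binomial: a reader's abnormal interpretations $A_j$ out of $K_j$
examinations at rate $a_j$, and a pair's disagreements $D_{jj'}$ out of
$K_{jj'}$ jointly read examinations at rate $d_{jj'}$.

### Monte Carlo marginalization

The expectations have no closed form, so they are computed by Monte Carlo
integration: draw $n$ standard normal case effects, scale by $\sigma_C$,
average the conditional probabilities. The default is $n = 10^6$, at which
the coefficient of variation of a marginal-rate estimate at screening-typical
operating points (rates of a few percent) is well below 1% — the acceptance
script measures it directly, about 0.1%. `marginal_abnormal_rate()` and
`marginal_disagreement()` attach the Monte Carlo standard error of each
estimate, and the unit tests check both integrals against a 200-node
Gauss–Hermite quadrature oracle over a grid of effects and dispersions.

Two numerical choices matter here:

* **Common random numbers.** Within one model fit, a single case-effect
  sample per class is drawn once and reused for every likelihood evaluation
  (standard normals, scaled by the current $\sigma_C$). The likelihood
  surface is then a deterministic function of the parameters, which a
  derivative-free optimizer requires; without it, Powell's line searches
  chase Monte Carlo noise.
* **Degenerate dispersion.** $\sigma_C = 0$ short-circuits to the exact
  closed forms ($\mathrm{logit}^{-1}(r)$; $2a(1-a)$ for equal readers) rather
  than sampling a constant.

The positive- and negative-class integrals use independent streams derived
from the master seed; the two classes share nothing.

## Fitting

The objective is the binomial log-likelihood of the reader counts plus the
pair-disagreement counts, with the parameter-free log-factorial constant
dropped:

$$ \lambda = \sum_j \left[A_j \ln a_j + (K_j - A_j)\ln(1 - a_j)\right]
   + \sum_{(j,j') \in \Pi} \left[D_{jj'} \ln d_{jj'}
   + (K_{jj'} - D_{jj'})\ln(1 - d_{jj'})\right], $$

maximized jointly over $(r_1, \dots, r_J, \log \sigma_C)$, separately per
class. The pair term is essential: from single-reader counts alone, many
$(r, \sigma_C)$ combinations produce identical marginal rates, so
`fit_model()` refuses count data with no observed pairs.

Optimization is Powell's derivative-free direction-set method
(`powell_minimize()`: Brent line minimizations along a maintained direction
set, with Powell's replacement rule), converging when a full sweep improves
the objective by less than the fractional tolerance `f_tol = 1e-4`
(configurable). Design choices the data do not dictate, made once:

* all reader effects and $\log \sigma_C$ are optimized **jointly** (not in
  alternating blocks);
* $\sigma_C$ is optimized on the **log scale** so positivity never binds,
  and reported on the natural scale;
* initialization: $r_j$ at the logit of the Agresti–Coull-adjusted direct
  rate, $\sigma_C$ at 1;
* a marginal rate that reaches 0 or 1 numerically (possible when a line
  search wanders to extreme effects) returns `+Inf` to the optimizer rather
  than a log of zero; the public `negative_log_likelihood()` signals a
  dedicated degenerate-likelihood condition instead.

Direct, model-free estimates (`direct_rates()`) are raw proportions adjusted
by the Agresti–Coull procedure ($z^2/2$ pseudo-successes, $z^2$
pseudo-trials, Wald interval on the adjusted centre, clipped to $[0,1]$);
`evaluate_fit()` reports the Pearson correlations of modeled versus adjusted
observed values for reader TPR, reader FPR and the two disagreement-rate
classes, returning `NA` (never a fabricated 0) when fewer than 3 points or
zero variance make a coefficient undefined.

### Exclusion criteria

A binomial fit is impossible for a reader with no true positives, no false
positives, or with every assessment abnormal in a class.
`apply_exclusion_criteria()` removes such readers, plus pairs with fewer
than 17 jointly read positive examinations (kept configurable — the value
was calibrated on large registries and need not generalize). Removal
cascades: pairs referencing removed readers are dropped, and when the
original records are available the surviving records are re-aggregated and
re-screened to a fixed point. The filter is idempotent.

## The synthetic-data generator

The registry extracts this kind of analysis runs on are not public, so the
generator is a first-class module reproducing their *structure*: every exam
read by exactly two readers from a pool; prevalence of a few per 1,000;
heterogeneous reader operating points with positively associated TPR and
FPR; sparse pair coverage. Reader effects come from a bivariate normal on
the logit scale. Defaults (chosen once, to sit in the ranges screening
registries report — individual TPR roughly 60–80%, FPR 3.5–5%, prevalence
around 6 per 1,000): $r^-_j \sim N(-3.3, 0.3^2)$, $r^+_j \sim N(1.0, 0.5^2)$,
correlation 0.6, $\sigma_{C-} = 1.0$, $\sigma_{C+} = 1.5$, prevalence 0.006.

Records are generated exactly as the model assumes: case status first, then
one class-appropriate case effect per exam shared by both assigned readers,
then Bernoulli decisions at the conditional probabilities. Two pair
assignments are available: `"chained"` (reader $i$ with $i+1$, wrapping),
which guarantees identifiability with few overlapping pairs, and
`"random_rotation"`, which emulates registry sparsity.

What passing tests on these data do **not** show: the generator draws from
the same model family the fitter assumes, so parameter-recovery results
demonstrate correctness of the machinery, not robustness to model
misspecification. Real reading data have features the generator omits —
lesion-level difficulty structure beyond a single scalar case effect, reader
experience and volume effects, drift over time, informative pair scheduling,
and the consensus/arbitration stage that follows a discordant read.

### An information limit worth knowing about

With $K^+ \approx 200$ positive reads per reader, the binomial standard
error of a reader's raw TPR ($\approx 0.033$) is comparable to the
between-reader spread of true TPRs under the default population
($\approx 0.07$–$0.09$). Consequently the correlation between *true* and
*recovered* TPR across a 10-reader population is bounded near
$0.90$–$0.93$ in the median even for an exact maximum-likelihood estimator,
and clears $0.95$ only for favorable draws. The modeled-versus-*observed*
correlations (the comparison real registries support, since truth is never
available there) are $> 0.99$ for reader rates at the same volumes; the
positive-case disagreement correlation is lower ($\approx 0.78$ in the test
harness) because it rests on a couple of hundred positive reads per pair —
the same sparse-data effect seen on real registry fits.

## The pairing simulation

Seven strategies are compared, all operating on the *modeled* marginal
rates: pairing readers **similar** in TPR, in FPR, or in a composite score;
**opposite** in the same three metrics; and **random**. Similar pairing
sorts the pool by the metric (ties broken by reader id) and pairs adjacent
readers — the matching that provably minimizes the total within-pair metric
difference, which the tests verify against brute-force enumeration for pools
up to 8. Opposite pairing splits the sorted pool at the median and pairs
ranks across the halves. The composite score is
$\mathrm{TPR} + \mathrm{FPR} \times \text{slope}$, with the slope from an
OLS regression of TPR on FPR; by default the slope is recomputed over each
day's pool (the alternative, one global slope, is available via
`composite_slope = "global"`), since pairing operates within the day's pool.
Random pairing is a uniformly seeded perfect matching.

The scheduler mimics a programme year: each day draws 16 readers from the
population, forms 8 pairs by the strategy, and distributes 4,000 exams over
32 batches, assigned to pairs round-robin so every pair reads 4 batches of
125 exams — 1,460,000 examinations per year. All strategies share the same
days, reader pools and exam stream; sub-seeds derived from the master seed
give each stochastic component (pools, case status, case effects, random
pairing, decision sampling, bootstrap) its own stream, so strategies differ
*only* in who is paired with whom, and the per-exam stream checksum is
identical across strategy rows.

Per exam, the pair's positive probability under the either-reader-flags rule
is $p = a_1 + a_2 - a_1 a_2 \ge \max(a_1, a_2)$. Group endpoints are means
of $p$ over positive and negative exams; a single-reading comparator assigns
each batch one reader (balanced loads) and averages the single conditional
probability. Both the analytic-probability endpoints and sampled Bernoulli
decisions (for TP/FP counts and concordant/discordant classification) are
provided, since they answer different questions: expected rates versus
realized counts.

Why similar-FPR pairing lowers the group FPR: with balanced loads the sum
$\sum (a_1 + a_2)$ over exams is invariant to the matching, so the group
FPR differs across matchings only through $\sum a_1 a_2$, which pairing
similar values maximizes — concordance on negatives is highest when the two
readers' false-positive propensities match, sending fewer discordant
negatives to arbitration. The same algebra explains why similar-TPR pairing
lowers group TPR (undesirable), and why opposite pairing raises the paired
value of whatever metric it is opposite in.

Uncertainty: percentile bootstrap over exams ($n = 1{,}000$ resamples by
default), stratified by case status because TPR and FPR are means over
disjoint strata; confidence levels are Bonferroni-adjusted for the number of
planned contrasts (6 strategy-versus-random, 7 versus individual reading).
Recall rate and cancer-detection rate per 1,000 are the linear
extrapolations $1000(\pi\,\mathrm{TPR} + (1-\pi)\mathrm{FPR})$ and
$1000\,\pi\,\mathrm{TPR}$ at prevalence $\pi$.

## Problem sizes used by the test suite

The packaged tests scale the study down so the whole suite runs in a couple
of minutes: Monte Carlo sizes of $10^4$–$10^5$ for fits (the default stays
at $10^6$), a 10-reader recovery harness with 20,000 negatives and ~200
positives per reader, 30-day × 992-exam schedules with 200 replicate seeds
for the directional pairing comparison (992 rather than 1,000 because the
day must divide evenly into 32 batches), and 500 replicates × 400 exams for
bootstrap coverage. The directional finding — similar-FPR pairing yields a
lower group FPR than random pairing (sign test $p < 0.01$) with no
systematic TPR loss beyond the replicate spread — reproduces at this scale.

## Limitations

* Consensus/arbitration after a discordant read is not modeled; endpoints
  stop at the pair's combined assessment.
* No reader covariates, no per-case covariates beyond the scalar latent
  difficulty, no temporal drift.
* No standard errors on the fitted parameters themselves (only on the
  derived rates via the bootstrap machinery); the model is fitted by plain
  maximum likelihood.
* Positive-case quantities (TPR recovery, positive disagreement) are
  intrinsically noisy at screening prevalence; see the information limit
  above before reading much into per-reader TPR point estimates.
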