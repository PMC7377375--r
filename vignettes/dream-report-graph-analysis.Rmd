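---
title: "Non-semantic word-graph analysis of dream reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-semantic word-graph analysis of dream reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dream reports collected after REM awakenings are, on average, longer than
those collected after light non-REM (N2) sleep, and most traditional
quality ratings of dream mentation are confounded by that length
difference.  `dreamgraph` implements a structural, non-semantic analysis
of oral-report transcripts that controls verbosity by construction: every
report is represented as a directed word graph and every comparison is
made on fixed-length windows of exactly 30 words.

A report's graph has one node per unique word and one directed edge for
each observed transition between consecutive words.  Edges are *distinct*
ordered pairs — a transition that occurs twice contributes one edge — and
immediate repetitions contribute self-loops.  No edge crosses a paragraph
boundary, because paragraph breaks in a transcript mark turn-taking
discontinuities rather than spoken transitions.  Three connectedness
measures summarize a graph:

* **Edges** — the number of distinct directed edges;
* **LCC** — the node count of the largest connected component when edge
  direction is ignored;
* **LSC** — the node count of the largest strongly connected component
  (mutual directed reachability; an isolated node has size 1).

A note on the Edges definition: with 30-word windows, counting repeated
transitions separately would pin Edges at a near-constant 29 with no
variance across windows; only distinct-pair counting produces values
slightly below 29 that vary with word repetition, which is the behaviour
reported for this family of measures.  The package therefore counts
distinct pairs.

## The sliding window

A window of `window_length = 30` words is moved one word at a time
(overlap 29); each window's graph is measured and the per-report value is
the equal-weight mean across windows.  Reports shorter than 30 tokens
cannot host a single window and are excluded up front
(`filter_min_length()`), mirroring standard practice.  Windows slide over
the concatenated token sequence: a paragraph break inside a window still
suppresses its transition, but windows are not restarted at paragraph
boundaries — the windowed means must remain comparable between reports
with different paragraph structure, and the paragraph count is available
separately as a covariate for exactly that reason.

Whole-graph components are computed with igraph's standard linear-time
algorithms.  The per-window loop is compiled code (union-find for weak
components, Tarjan's algorithm for strong components, on stamped reusable
buffers): calibration runs visit millions of windows, and the test suite
holds the compiled route equal to the igraph route window by window, and
both equal to a brute-force reachability-closure oracle on hundreds of
random sequences.

## The shuffle null and random-likeness z-scores

To ask "does this report look like a random arrangement of its own
words?", the word order is shuffled uniformly `n_shuffles = 1000` times
(break positions stay fixed, so the paragraph covariate is identical
between observed and null), the full windowed pipeline is recomputed per
shuffle, and the observed windowed LCC/LSC are standardized against the
null mean (`mrLCC`, `mrLSC`) and SD (`sdrLCC`, `sdrLSC`; population form,
denominator n — immaterial at n = 1000 but stated for bit
reproducibility):

$$\mathrm{LCCz} = \frac{\overline{\mathrm{LCC}} - \mathrm{mrLCC}}{\mathrm{sdrLCC}}$$

Scores near 0 indicate random-like structure.  A degenerate null SD of 0
(e.g. a report consisting of one repeated word) yields an undefined z
flagged in the result rather than an error.  Shuffle randomness comes
from a per-report substream derived from `(master seed, report id)`, so
corpus-level results are independent of report order.

The calibration property that defines correctness: a report whose word
order *is* a uniform permutation is one draw from its own null, so across
such reports the mean LCCz must sit near 0 and roughly 5% must exceed
|z| > 1.96.  The acceptance suite checks exactly this at 200 reports and
1000 shuffles.

## Statistical comparison pipeline

**Participant medians + Wilcoxon.**  Reports are not independent within a
participant, so stage comparisons use one median per participant per
stage, compared with a Wilcoxon signed-rank test: zero differences
dropped, mid-ranks for ties, tie-corrected normal-approximation z (no
continuity correction by default; a documented switch), exact
sign-enumeration p (dynamic programming) by default for 12 or fewer
pairs.  The effect size is r = |z| / sqrt(n_obs).  The default n_obs
convention is twice the number of retained pairs: published (Z, r) pairs
in this literature are consistent with divisor sqrt(38) = sqrt(2 x 19)
even under an "n = 40" caption, and the convention is exposed as an
option rather than silently fixed.

**Model ledgers.**  The remaining hypotheses are organized as bottom-up
hierarchical model comparisons (`build_ledger()`): starting from a stated
baseline, each candidate predictor is added and judged by the
likelihood-ratio test, with Nagelkerke's pseudo-R²

$$R^2 = \frac{1 - \exp\{\tfrac{2}{n}(LL_0 - LL_1)\}}{1 - \exp\{\tfrac{2}{n} LL_0\}}$$

reported against the null model and its *change* reported against the
row's baseline.  Four designs are built in: time-of-night (Gaussian
outcome, baseline sleep stage), stage discernment (binomial REM/N2,
baseline null, plus TRC/LCC composites in both orders), complexity
rating (ordinal 0-9 outcome, baseline sleep stage, TRC composites,
double composites, and optional stage-by-measure interaction rows), and
stage discernment with the complexity rating partialled out.  A
`paragraph_covariate` switch adds the paragraph count to every model in a
ledger, including the null, for the turn-taking confound rerun; a
stop-word rerun repeats the whole pipeline on filtered tokens.

**Model engines.**  Gaussian and binomial mixed models use lme4 (maximum
likelihood, never REML; Laplace approximation for the binomial family),
with random intercepts for participants and, where identifiers are
nested, nights.  Grouping factors with fewer than three levels are
dropped with a message.  The ordinal family is a proportional-odds
cumulative-link model with a logit link, written directly in the package:
thresholds are kept ordered via a log-difference parameterization, an
optional participant random intercept is integrated out by 21-node
Gauss-Hermite quadrature (Golub-Welsch nodes), and the likelihood is
maximized by BFGS.  This is implemented in-package because no installed
package fits ordinal mixed models; it is validated against MASS::polr in
the fixed-effects limit (log-likelihood agreement to 1e-4) and against
`lme4::glmer(nAGQ = 21)` in the two-category case, where the
cumulative-link likelihood coincides with mixed logistic regression.

That coincidence also supplies the package's separation fallback: with
strong structural effects a binomial ledger model can separate
completely, which makes glmer's PIRLS step diverge.  `fit_model()` then
refits the identical model by the quadrature route (which degrades
gracefully under separation) and says so; non-convergence is always
flagged, never silent.  Continuous predictors are z-scaled inside the
ledger for numerical stability — this leaves log-likelihoods, LRTs and
pseudo-R² unchanged.

## The synthetic corpus generator

Real dream-report corpora of this kind are rarely shareable, so the
generator is a first-class module that produces corpora with the
statistical structure the analysis assumes, plus the ground truth needed
for recovery tests.  The study design is simulated explicitly:
participants x nights x awakenings; each awakening draws a sleep stage
(N2-heavy mix, REM probability 0.27) and a stage-dependent recall
indicator (REM 0.907, N2 0.724); recalled awakenings produce a report.

* **Length**: log-normal token counts, location log(100) for REM and
  log(68) for N2 (SDs 0.50/0.40), shifted by participant and night
  random intercepts (SD 0.15/0.10 on the log scale).  The N2 location
  was chosen from the log-normal tail formula so that ≥95% of generated
  reports meet the 30-token floor while the expected retained corpus
  stays near 133 reports with a heavy N2 majority — the corpus shape the
  analysis is designed around.
* **Word process**: a two-urn recency model.  At each step the report
  either re-emits a word drawn uniformly from its `recurrence_range` most
  recently used distinct words (probability `recurrence_prob = 0.25`) or
  introduces an unused word.  The recurrence *range* is the structural
  knob (REM 12 vs N2 4): a long-range recurrence often re-introduces a
  word whose last occurrence lies outside the current 30-word window,
  adding a distinct word to the window and thereby raising windowed LCC,
  and it closes longer directed loops, raising LSC.  This gives direct,
  monotone control over the stage effect with two interpretable
  parameters, which a full Markov chain would not.
* **Paragraphs**: 1 + Poisson counts with stage rates 3.5 (N2) vs 2.5
  (REM); break positions uniform.
* **Complexity rating**: a latent score — a fixed linear function of
  log-length and the stage's recurrence parameters plus Gaussian noise
  (SD 0.5) — discretized through fixed equal-width thresholds into the
  ordinal 0-9 rating.  Thresholds are fixed, not estimated, so the
  ground truth is known exactly for recovery tests.
* **TRC**: the generator emits no hesitation fillers, so the metadata TRC
  equals the token count; with real transcripts a supplied human-rated
  TRC always takes precedence over the filler-free proxy count.

What the generator does *not* emulate: semantic content, function-word
hubs (the synthetic LSC level, ~5-10, sits below the ~16 typical of real
speech because real function words close many long loops), researcher
interjections, or any real joint distribution of length, complexity and
connectedness.  One visible consequence: synthetic corpora show a
*negative* mean LCCz (recency-clustered recurrence concentrates
duplicates inside windows, making observed windows less connected than
shuffled ones), whereas real oral reports typically score positive.  The
calibration property — z ≈ 0 for genuinely random word orders — is
direction-agnostic and unaffected.  Passing tests therefore demonstrate that the pipeline's
machinery is correct and calibrated — not that real REM/N2 corpora will
show any particular effect.

## Numerical and design choices

* Distinct-edge counting, self-loop retention, and weak-reachability LCC
  are fixed by definition (above); a lone node has LSC 1.
* Zero-effect configurations (`preset_null_effect()`) equalize every
  stage-dependent parameter and drive all type-I calibration tests;
  the study preset (`preset_dream_study()`) drives power/recovery tests.
  Calibration scales: 200 zero-effect corpora at the 20-participant
  preset scale (100 shuffles per report for the z-measures, participant
  random intercept), 100 study-preset corpora for power, 200 permuted
  reports x 1000 shuffles for null calibration — sizes chosen once for a
  single-CPU run of the full suite.
* A breakless 30-token report has a permutation-invariant windowed LCC
  (its single window covers the whole report), so its null SD is exactly
  0 and its z is reported as undefined rather than a number; ledgers drop
  such reports with a message.  The null-calibration test consequently
  draws its permuted reports from those with ≥ 40 tokens, where the
  shuffle null has spread.
* Exact Wilcoxon enumeration switches on at ≤ 12 pairs; beyond that the
  tie-corrected normal approximation is used (they agree to ~0.06 at
  n = 12 in the suite's spot check).
* The ordinal fit starts thresholds at the logits of the observed
  cumulative proportions, slopes at 0, and log-sigma at log(0.3); BFGS
  with reltol 1e-10.  Degenerate outcomes (a single observed category)
  are rejected with an error.
* LRT chi-squares are clamped at 0 with a 0.02 tolerance; a larger
  deficit raises a refit-or-error diagnostic naming both models.
* Determinism: every stochastic step (generation, shuffling) derives
  from a master seed; rerunning an identical `run_config()` is
  byte-identical, and per-report shuffle substreams make corpus results
  order-independent.

## Known limitations

* The two-urn process yields lower LSC than real speech (no function
  words); LSC-based conclusions about real corpora need real data.
* The Laplace approximation in binomial mixed fits can differ from full
  quadrature by a few tenths of a log-likelihood unit; nested
  comparisons inherit that approximation (the quadrature route is exact
  to its node count and is used automatically when glmer fails).
* The ordinal random-intercept integration supports one grouping factor
  (participants); night-level random effects are available only for the
  Gaussian and binomial families.
* Transcripts are assumed to contain only the dreamer's speech;
  interviewer turns, if present, must be removed upstream.
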