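---
title: "Multi-word units, word learning and lexical processing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-word units, word learning and lexical processing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwulex)
```

`mwulex` asks a correlational question: does the number of multi-word
units (MWUs) a word participates in predict how early children produce it
and how fast adults recognize it, beyond what raw frequency predicts?
This vignette is the package's own account of each modelling step, the
parameters that matter, the numerical choices, and what the synthetic
test bed does and does not establish.

## The chunker

The extraction model is an incremental chunker in the Chunk-Based Learner
family. It processes a corpus utterance by utterance, word by word, and
maintains only: per-word frequency counts, per-bigram left-adjacency
counts, a running mean of all backward transitional probabilities (BTPs)
scored so far, and the *chunkatory* — the set of units discovered so far.
The BTP of a transition is `p(prev | curr)`, the probability of the left
neighbour given the current word.

For each within-utterance transition the update order is fixed:

1. increment `freq(curr)` and the `(prev, curr)` pair count;
2. compute `BTP = pair / freq(curr)`;
3. form the threshold: the running mean BTP over *prior* transitions
   (zero before the first), plus `1/freq(curr)` when the noise
   correction is on;
4. decide: if `(prev, curr)` is an adjacent pair inside any stored unit
   of length ≥ 2, attach regardless of BTP (chunkatory override);
   otherwise attach iff `BTP > threshold` (strict: a tie is a boundary);
5. add the transition's BTP to the running mean — always, including
   overridden transitions.

Counting before scoring matches an incremental learner that has, by the
time it evaluates a word, encountered it; averaging after scoring keeps a
transition from being compared against a mean that already contains it.
Utterance boundaries always close the open unit; units never span
utterances. Every closed unit — single words included — is emitted into
the inventory and stored in the chunkatory, but only members of length
≥ 2 can trigger the override.

Two consequences are worth noting. First, with the noise correction on, a
word's first-ever occurrence can never attach through the BTP rule: its
threshold is at least `mean + 1`, and no probability exceeds that. Rare,
possibly noisy words therefore only enter multi-word units after repeated
exposure (or via the chunkatory). Second, the chunkatory makes the model
self-entrenching: a grouping discovered once is re-applied on sight, so
early decisions shape later segmentation, and the output is genuinely
order-sensitive (shuffling utterance order changes the inventory; the
test suite asserts this).

**Threshold interpretation.** "The average BTP" admits two readings. The
default, `threshold_mode = "global"`, is the corpus-wide running mean over
all transitions scored so far — the original CBL formulation.
`"per_word"` instead averages `p(x | curr)` over the distinct words `x`
seen one position left of `curr`. The per-word mean is computed from the
current counts (counting precedes scoring, so the current transition is
necessarily included); the global mean excludes the current transition by
construction. Both modes are implemented and oracle-tested; all shipped
analyses use the global default.

**The random baseline.** Identical control flow, but every
non-overridden attachment decision is an independent coin toss with
probability `attach_prob` (default 0.5), one draw per decision in
processing order from a single seeded generator. By default the baseline
*keeps* the chunkatory stage (`use_chunkatory = TRUE`): entrenchment of
early random groupings lengthens baseline sequences, which matches the
observation that random-baseline sequences are not trivially short. A
memoryless baseline is available by switching the flag off.

## Word measures

`#MWUs` counts distinct unit *types* of length ≥ 2 containing a target
word (a word repeated within one unit counts that unit once); `#baseline`
is the same count over the baseline inventory; `#Freq` is the raw token
count. Single-word units are excluded by default (`min_length = 2`)
because a multi-word-unit count should count multi-word units; the
threshold is configurable, and type counts with `min_length = 1` dominate
those with `min_length = 2` (a tested invariant). Inventory summaries
report the unit-length median and IQR over types by default (each type
once), with a token-weighted variant by flag; IQR is Q3 − Q1 with
linear-interpolation quantiles.

Target words are the intersection of four availability sets: present in
both register corpora, with an AoFP estimate and an RT estimate. Words
are raw word forms throughout — tokens are split on whitespace and
optionally case-folded (default on, so *Good*/*good* are one type), but
never stemmed, lemmatized, tagged, or stripped of punctuation; inputs are
assumed to be pre-cleaned transcribed speech.

## Age of first production

Developmental stage is indexed by mean length of utterance (MLU) rather
than age: children of the same age differ widely in language development,
and MLU is the more robust yardstick. Because transcripts contain very
different numbers of utterances, each transcript's MLU is estimated by
bootstrap: 1,000 resamples (with replacement, size equal to the
transcript's utterance count) of the utterance-length sequence, with the
point estimate the mean of resample means — which converges to the plain
sample mean (tested at 3 standard errors) and equals it exactly for
constant-length transcripts. Per-transcript seeds are derived from the
master seed and transcript position, so adding transcripts never perturbs
existing estimates.

A word's AoFP is then the *minimum* MLU over transcripts whose child
utterances contain it: the earliest developmental stage at which any
child in the collection produces the word. The minimum (not the mean) is
deliberate: with uneven per-child coverage, averaging first usages of
children recorded only late artificially inflates estimates, whereas the
minimum is only ever lowered by additional data (a tested monotonicity
property). Only child utterances are scanned. AoFP is therefore measured
in MLU units (tokens per utterance), not months.

## Correlation machinery

Count predictors are non-normal and heavily tied, so association is
measured with Kendall's τ-b, which handles ties explicitly. With P
concordant pairs, Q discordant pairs, X₀ pairs tied only in X, and Y₀
pairs tied only in Y (pairs tied in both enter no term):

τ-b = (P − Q) / √((P + Q + X₀)(P + Q + Y₀))

The implementation computes the four counts exactly with Knight's
O(n log n) merge-sort formulation (discordant pairs are strict inversions
of the y-sequence after sorting by x, then y; tie totals recover the
rest). A brute-force O(n²) pair enumerator serves as the test oracle: the
counts must match bit-for-bit on hundreds of tied vectors, and the τ
value is additionally cross-checked against `stats::cor(method =
"kendall")`. A completely tied ranking makes the denominator zero; that is
signalled as a classed error, and the pipeline reports the affected cell
as `NA` and continues.

The partial coefficient removes a third ranking F:

τ-b(XY·F) = (τ_XY − τ_FX τ_FY) / √((1 − τ_FX²)(1 − τ_FY²))

undefined when |τ_FX| = 1 or |τ_FY| = 1.

Confidence intervals are percentile bootstrap — 1,000 resamples of the
word rows, sample size n — the simplest method consistent with plain
"statistical bootstrapping"; no BCa correction is applied. Resamples on
which a statistic is undefined are redrawn, capped at 10× the requested
replicates, with the redraw count reported. Comparisons between two
coefficients use *paired* resampling: each replicate draws one row
resample and evaluates both statistics on it, which respects the shared
word index whether the two statistics share a predictor, a response, or
neither. The replicate value is |A| − |B| by default (the coefficients
under comparison are negative; the magnitude difference is the
facilitation contrast), and "the coefficients differ" means the 95%
interval excludes zero. No p-values are computed anywhere.

## The synthetic study

The generator emulates the *structure* of the real inputs, with known
ground truth:

- **Corpora.** Two registers sharing one set of planted multi-word
  templates: a CDS-like register with shorter utterances (lengths 2–7)
  and an ADS-like register with longer ones (4–11), mirroring the
  characteristic register contrast. Each utterance instantiates a random
  template with probability 0.4 (padded with fillers at a random offset)
  or is all fillers. Fillers are Zipf-distributed (exponent 1) over a
  1,200-word vocabulary, so filler transitions are diffuse and the
  running mean BTP stays low, while within-template transitions are
  nearly deterministic — the separation the chunker exploits in natural
  language. Templates (60 of length 2–3) draw their words from a 100-word
  mid-frequency pool (Zipf ranks 201–1000): frequent enough to recur,
  rare enough that template transitions dominate their statistics.
  With 4,000 utterances per register, templates recur ~25 times each and
  ~1,100 words survive the four-way target intersection — the scale at
  which the correlational analyses are meant to operate.
- **Responses.** Effects are standardized: a latent score
  `beta_freq · z(log freq) + beta_mwu · z(templates containing the word)
  + noise` (both betas 1, noise SD 1 by default, i.e. each effect
  comparable to the noise) drives the word-introduction order across 60
  transcripts of increasing target MLU (1.3–6), and the same effect
  structure (scaled to 40 ms per standardized unit around a 700 ms
  baseline) generates RTs. Positive betas mean facilitation: earlier
  first production, faster recognition. Per-transcript utterance counts
  are log-normal (clamped 20–500), mimicking the heavily skewed
  per-child data volumes of pooled transcript collections. AoFP structure
  is generated directly on the MLU axis, since that is the axis the
  pipeline measures; the functional form of the frequency effect is
  irrelevant beyond monotonicity because the analysis is rank-based.

What the synthetic bed does *not* emulate: grammar, semantics, register
differences beyond length and vocabulary, longitudinal within-child
structure, or the heavy-tailed unit-length distributions of real speech.
Passing tests therefore show that the machinery recovers known effects
embedded in realistic frequency structure — not that any particular
natural-language result will replicate.

## Simulation sizes and known limitations

The shipped simulations use the default study (4,000 utterances per
register, ~1,100 targets) for effect recovery and baseline contrasts, and
a scaled configuration (300-word vocabulary, 1,200 utterances, 30
transcripts) for replicated simulations such as the 50-run null suite and
generator property checks; interval coverage of τ-b itself is verified
separately on bivariate-normal data (n = 200, 200 runs) against the
closed-form large-sample value τ = (2/π)·asin(ρ).

Two limitations are worth stating plainly:

- **Partial τ-b is an approximation, not a conditional independence
  test.** When the predictor of interest is a tie-heavy, nearly
  deterministic function of the control — as a unit-membership count is
  of frequency when corpora are small — the linear correction
  `τ_XY − τ_FX τ_FY` under-corrects, and the partial coefficient can sit
  away from zero even when the predictor carries no independent signal.
  For this reason the package's null-honesty simulation zeroes *all*
  generating effects (responses are pure noise), which is the regime in
  which "the partial correlation should be null" is actually true of the
  estimand. Users comparing partial coefficients on real data should
  remember they inherit this approximation.
- **Within-utterance shuffling only degrades, not destroys, adjacency in
  short utterances.** In a length-L utterance a planted bigram survives
  shuffling with probability about 1/L, so in a short-utterance register
  a few high-frequency two-word templates can still be rediscovered after
  shuffling. The recovery control is therefore evaluated pooled over both
  registers.

Chunker correctness is anchored two ways: a worked trace (ten one-off
filler transitions give mean BTP H₁₀/10 ≈ 0.293; a bigram repeated three
times is then rejected, accepted, and chunkatory-rechunked, in that
order), and full-inventory equivalence against a naive non-incremental
re-simulation with linear-scan data structures on random corpora.

## Reproducibility

Every stochastic component — the baseline chunker, the MLU bootstrap,
every correlation bootstrap, the generator — consumes a seed derived
deterministically from one master seed via a fixed affine map
(`derive_seed`), with component-specific indices. Rerunning any component
in isolation with its derived seed reproduces its output exactly; the
test suite asserts end-to-end determinism of `run_mwu_analysis()`.
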