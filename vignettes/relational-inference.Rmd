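---
title: "Inferring social relationships from observed conversations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring social relationships from observed conversations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convrel)
```

convrel studies a third-party judgment problem: observers passively watch
conversations among a small cast (here, seven contestants on an unscripted
competition show format) and are then asked, for every pair, who is friends
with whom, who is rivals with whom, and who would beat whom. The package
implements the full analysis chain — behavioral aggregation, an
intersubject agreement statistic, conversational language features, and
hierarchical Bayesian models linking the two — plus a synthetic-study
generator so that every stage can be exercised and validated end to end
without any external data.

## The behavioral task and percent chosen

Each observer answers forced-choice triplets: a target contestant with two
candidate choices. With $n$ contestants the full design has one trial per
(target, unordered choice pair), $n \cdot \binom{n-1}{2}$ trials per block
(105 at $n = 7$), and every condition (friend, rival, win) is run twice.

The behavioral outcome is *percent chosen*. For the relational conditions
the dyad is what matters, not who happened to be the target, so the
proportion for dyad $\{X, Y\}$ is the mean of the two directional
proportions (X chosen when Y was target, Y chosen when X was target); a
direction that was never presented contributes nothing and the other
stands alone. The win question asks who would beat the *target*, so win
proportions stay directional, keyed (likely beater, target). Missed
responses (the task allows up to 5 s) are excluded from numerator and
denominator alike. The mean-of-directions rule reproduces the canonical
worked example — 80% in one direction and 60% in the other giving 70% for
the dyad — and differs from pooling the counts when the two directional
denominators differ; a pooled-count mode is available behind a flag for
sensitivity analysis.

## Intersubject correlation

Agreement across observers is measured by intersubject correlation:
Pearson correlations between all pairs of observers' full response
vectors (length $\binom{n}{2}$ per symmetric condition, $n(n-1)$ for win;
keys an observer never saw are missing, never zero-filled), summarized by
the median of the strictly lower triangle. Pairs sharing fewer than three
defined keys, or with a constant vector, are undefined and excluded, with
the exclusion count logged.

Significance comes from a resampling null: in each of $B$ iterations every
observer's vector is independently shuffled and resampled with replacement
from that observer's own observed values. This keeps each observer's
marginal value distribution while destroying the dyad alignment across
observers — exactly the structure the statistic is meant to detect. The
p-value is the proportion of null medians at or above the observed median,
with no +1 correction by default (a $(B+1)$-rule option exists). The
wording of the source procedure admits two readings — value-level
resampling within observer, or shuffling alone — so both are implemented
(`method = "resample"` and `"permute"`); resampling is the default and the
two give indistinguishable calibration in our checks. The default is $B =
10{,}000$; tests use smaller $B$.

## Linguistic features

Three features are computed per sentence or per dyad, then aggregated.

**Sentiment** follows the valence-shifter cluster algorithm: dictionary
words carry polarity $\pm 1$; for each polarized word the surrounding
cluster (4 tokens before, 2 after) is scanned for shifters. An odd number
of negators flips the sign and converts amplifiers to de-amplifiers; each
amplifier multiplies the polarity by 1.8; each de-amplifier multiplies by
a shrink factor, default $1/1.8$ — the source material leaves the shrink
magnitude unstated, so the reciprocal of the amplifier weight is the
package's documented choice, exposed as a parameter. Adversative
conjunctions ("but", "however") weight the polarized word by
$1.85^{\#\text{before}} / 1.85^{\#\text{after}}$ over the whole sentence;
"increase by 1.8" and "1.85 times the number of conjunctions" are
formalized multiplicatively, with both weights configurable since the
prose is arithmetically ambiguous. Token scores are summed and divided by
$\sqrt{\text{token count}}$ (the referenced implementation's normalization;
switchable), yielding an unbounded sentence score. The implementation is
verified token-for-token against an independently written brute-force
scorer on 1,000 random sentences in the acceptance suite.

**Clout** — conveyed status and confidence, bounded 1–99 — has a
proprietary reference algorithm, so the package ships a transparent proxy
built on the direction pattern the status-language literature agrees on:
per-token rates of first-person-plural, second-person, and social words
raise the score; first-person-singular and negation rates lower it. The
rate contrast is mapped through `1 + 98 * plogis(gain * raw)` (gain 5 by
default), giving 50 at a neutral balance. Only ordinal behavior (bounds,
monotonicity) is asserted anywhere; numeric agreement with the proprietary
tool is explicitly a non-goal.

**Semantic similarity** is the cosine between embeddings of two pieces of
text. The default backend is a deterministic hashed bag-of-words
vectorizer: two independent polynomial rolling hashes give each token a
bucket in a 512-dimensional vector (mirroring the common pre-trained
encoder dimension) and a sign. It is exactly reproducible across platforms,
needs no model weights, and its cosine reflects token overlap — which is
also the channel through which the synthetic generator encodes similarity,
keeping generator and analyzer honest about what "similarity" means here.
Any embedder with the same `embed(text) -> numeric(dim)` contract (e.g., a
pre-trained sentence encoder) can be plugged in; no test requires one.
Dyadic similarity pools everything A said to B into one chunk and
everything B said to A into another and takes one cosine (the source's
text inputs span up to hundreds of words, indicating pooled chunks); a
cross-pair sentence-mean mode ships as the alternative reading. The score
is absent unless both directions spoke.

## Windows: gist/recent × specific/general

Every feature is aggregated at four levels. *Specific* restricts to
dyadic dialogue between the two members; *general* takes everything a
contestant said — confessionals, group talk, host exchanges included.
*Recent* uses only clip $c$; *gist* accumulates clips $1..c$. Gist
sentiment/clout is the cumulative sentence-weighted mean (equivalently, a
running mean over all selected sentences), not a mean of per-clip means;
gist-specific similarity re-pools all dialogue from clips $1..c$ before
embedding (switchable). A window that selects no qualifying dialogue gives
an absent score; absent scores propagate as missing values and the model
table keeps complete cases only, with drop counts logged.

General scores are defined per contestant, but the models need dyad-level
predictors. The combination rule is unstated in the source, so the package
uses the unweighted mean of the two members' scores (cosine of their
pooled speech for similarity) as a documented decision; a dyad with a
silent member is absent.

For the homophily question, season mode treats the clip index as an
episode number and averages each dyad's per-episode similarity over the
first five episodes (the pre-merge window), at general and specific
levels. Episode renumbering around recaps is the caller's responsibility.

## The relational model

The outcome for participant $p$, dyad $d$, condition $k$, clip $c$ is
`chosen` of `presented`, modeled beta-binomially with logit-scale mean:

$$\mathrm{logit}(\mu) = \beta_0 + \beta_k + \beta_x x + \beta_{kx} k x
  + u_{d:k} + v_{p:k}$$

with treatment coding (friend as reference — the source's coding is
unstated, so ours is documented in the output), dyad-level feature $x$,
and random intercepts for every dyad-by-condition and
participant-by-condition cell ("condition nested within dyad/participant";
random slopes are out of scope since nesting of condition, not of the
feature, is specified). The beta-binomial is parameterized by mean and
precision, $\mathrm{shape} = (\mu\phi, (1-\mu)\phi)$. Priors: Normal(0, 5)
on non-intercept fixed effects, Normal(0.5, 1) on the intercept applied on
the logit scale exactly as stated (unusual, but fidelity beats taste),
half-Cauchy(0, 5) on the random-effect scales, and — the source is silent
on $\phi$ — half-Cauchy(0, 5) on $\phi$ as a documented assumption.
Sampler defaults are 4 chains × 10,000 iterations (2,000 warmup), fixed
effects initialized at zero; when any monitored parameter's effective
sample ratio drops below 0.1 the fit escalates once (+20% iterations, +50%
warmup), and split-$\hat R > 1.05$ after escalation is a diagnostic error.

### The sampler

No pre-built engine for this likelihood/prior combination is available in
the package's dependency set, so the posterior is sampled by a
purpose-built adaptive Metropolis-within-Gibbs scheme over the fully
vectorized marginal beta-binomial likelihood:

* a joint random walk on the fixed effects, repeated a few times per
  sweep, with its proposal covariance seeded from the binomial-GLM
  coefficient covariance and adapted during warmup;
* simultaneous per-cell random walks on the dyad- and participant-cell
  intercepts (cells are conditionally independent given the rest, so
  acceptance is decided cell-wise);
* an exact Gibbs draw of whichever fixed effects are constant within
  dyad-cells: holding the cell effects $\theta = Z\beta + u$ fixed, the
  likelihood does not involve $\beta$, and normal prior × normal
  random-effect density makes $\beta \mid \theta, \sigma_d$ Gaussian. This
  decorrelates slopes from random intercepts in one move and is the main
  reason group-level predictors mix well;
* log-scale random walks on $\sigma_d, \sigma_p, \phi$, plus joint rescale
  moves (scale and intercepts multiplied together) that traverse the
  funnel at small scales.

Internally the feature is centered (an exact linear reparameterization;
priors are evaluated and draws stored on the raw scale), and the linear
predictor is clamped at $\pm 30$ so a wild proposal cannot saturate the
inverse logit. The test suite cross-checks the whole sampler against an
independent JAGS formulation of the identical model on simulated data, and
a 50-replicate simulation study verifies that the 95% credibility interval
covers a known interaction of $-2.5$ at the nominal rate. Identical seed
and table give identical draws.

Marginal effects per condition are the feature slope for friend and slope
plus interaction for rival, summarized by posterior medians with
equal-tailed 50/80/95% credibility intervals (equal-tailed vs. HDI is
unstated in the source; equal-tailed is the documented default).

### Bayes factors

Evidence for the condition-by-feature interaction compares the interaction
model against the main-effects model on the same table. The default is the
Savage–Dickey density ratio: the models are exactly nested with a
Normal(0, 5) prior on the interaction, so the Bayes factor is the prior
density at zero over the posterior density at zero (kernel estimate with a
normal-approximation fallback deep in a tail). Bridge sampling over the
full parameter vector (moment-matched normal proposal, iterative bridge
estimate) is implemented as `method = "bridge"`; Savage–Dickey is the
default because it is exact for this nested comparison and markedly more
stable than bridge estimates over a ~100-dimensional posterior from modest
draw counts. Bands follow the usual reading: > 100 very strong, 10–100
moderate, < 10 little to none.

## The synthetic-study generator

The generator is the package's test bed and defines its study conditions:
7 contestants, 6 clips, 50 observers, full design per block, every
condition twice — the scale of the emulated study (its goal sample size
was 50). Latent signed affinities $a \in [-1, 1]$ per dyad come from a
three-cluster mixture — friends near $+0.7$ (sd 0.1), rivals near $-0.7$,
neutral near 0 (sd 0.15), equal weights by default — and per-contestant
win strengths are uniform.

Dialogue is template text from controlled word pools (deliberately not a
language model, so every feature channel is analytically steerable and
tests are hermetic): per sentence, the positive-vs-negative polarity word,
the shared-vs-private topic tokens (which drive the hashed-embedding
similarity), and the we/you-vs-i pronoun and social-verb choices (which
drive the clout proxy) are Bernoulli draws whose logits scale with
affinity (slopes 1.5/2/1.5) plus Gaussian noise, sd $\sigma = 0.6$. Each
dyad exchanges a Poisson(4) number of sentence rounds per clip — so some
dyad-clips are silent, exercising the absent-score paths — and each
contestant speaks two confessional sentences per clip for the general
levels. Observers choose by $\mathrm{logistic}((a_1 - a_2)/\tau)$ with
$\tau = 0.35$, rival judgments mirror friend affinities (an option
decouples them), win judgments use strength differences, and 2% of
responses are missing. The noise values ($\tau$, $\sigma$) are not stated
by the emulated study; they were fixed once at values giving realistic
intermediate agreement (observed ISC medians in the 0.4–0.9 range
depending on $\tau$) and are not tuned against test outcomes.

What the generator does *not* emulate: real conversational syntax and
pragmatics, editing and production structure, team membership dynamics,
reaction times, and any correlation between win strength and affinity.
Passing tests therefore show that the pipeline recovers structure *when
the generating process matches the analysis assumptions*; they are not
evidence about real broadcast conversations.

## Problem sizes and numerical choices

The package's own validation runs at deliberately chosen sizes: ISC null
calibration over 500 synthetic datasets at $B = 500$; the 50-replicate
interaction-recovery study at 30 participants × 21 dyads with 2 chains ×
900 iterations per fit (the Gibbs move makes this ample — effective sizes
near the draw count); end-to-end sign recovery at the generator's default
50 observers with 2 chains × 1,500 iterations. The analysis scripts under
`analysis/` use 10 observers and 2 × 1,500 iterations for the 12-model
grid. These sizes are the package's trade-off between Monte Carlo error
and turnaround; the model's defaults remain the full 4 × 10,000 settings.

A note on what end-to-end sign recovery can show. With condition nested
within dyad as random intercepts, a dyad-level feature in the per-clip
table is identified partly by shrinkage (the regression of dyad-cell
effects on the feature) and partly by within-dyad variation of the
cumulative feature across clips — and on per-clip tables the within-dyad
channel dominates the posterior. In the generator, observers' choice
probabilities do not change across clips (relational beliefs do not
evolve with viewing), so that dominant channel carries sampling noise
around a flat truth: per-clip-table marginal effects shrink toward zero
and their median signs flip with the simulation seed at every observer
count we examined. Real observers plausibly do update as they watch,
which would put genuine signal into exactly that channel; the generator
deliberately does not model belief evolution. The package's end-to-end
sign check therefore fits the pooled-block design — one row per
participant, dyad, and condition, with the whole-episode gist score as
the predictor, the same table structure the early-similarity
(homophily) models use — where identification is purely between dyads,
the only channel the generator informs. There the direction pattern
(positive friend, negative rival marginal effects for all three
features) recovers decisively for sentiment and clout and consistently,
though with a credibility interval spanning zero, for similarity. The
recovered magnitudes are deliberately not compared against anything:
they measure the generator's assumptions as much as the pipeline.

Other numerical choices: undefined correlations are excluded (never
imputed); percent-chosen keys with zero presentations are absent (never
zero-filled); the hashed embedder uses fixed moduli (1048573, 524287) and
bases (31, 131) with all arithmetic exact below $2^{53}$; ties in the
forced-choice generator are broken by the logistic draw itself; and every
random process in the package takes an explicit seed.

## Known limitations

Clout is a proxy with ordinal guarantees only. The hashed embedder
measures token overlap, not meaning; pre-trained encoders will behave
differently on real text. The homophily stage in the analysis scripts uses
a season transcript generated independently of the focal world, so it is a
negative control rather than a homophily simulation. Bayes factors inherit
kernel-density error near zero when the posterior sits far from the null;
the bridge option inherits Monte Carlo error from its proposal. And the
sampler, while cross-checked, is a random-walk scheme: posteriors from
very small tables (a handful of dyads) mix more slowly and may trigger the
escalation path.
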