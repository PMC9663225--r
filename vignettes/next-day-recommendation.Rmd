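---
title: "Recommending next-day medical activities: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recommending next-day medical activities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

A hospital admission is modelled as an ordered sequence of *inpatient days*,
each day a set of activity identifiers drawn from a vocabulary of M
activities, together with a token sequence from the patient's free-text
medical history (past history, current history, allergy history,
concatenated in that order). Given the first K days and the history, the
model scores every activity for day K+1; the recommendation is the top-K
list of those scores. Two structural facts drive the design:

* **Long-term orders.** Some activities are issued daily regardless of the
  patient's state. Their observed frequency is an almost sufficient
  statistic; a purely learned sequence model tends to dilute it.
* **Day-to-day transfer.** Events on one day cause orders on the next
  (a surgical procedure is followed by anti-infective drugs). This is
  sequential structure a frequency count cannot capture.

The model therefore combines three branches — a learned day-sequence
encoder, a learned history encoder, and a raw frequency statistic — through
a gated additive fusion, and regularises training with an adversarial pair.

## Model components

**Day-set embedding.** A day's activity embeddings $e_i$ (rows of the
$M \times d_e$ table) are pooled with input-dependent scalar weights
$\alpha_i = q^\top \sigma(W e_i + b)$, $d_k = \sum_i \alpha_i e_i$. The
weights are *not* normalised: that is how the combining rule is defined, and
we keep it as the default even though it makes $\|d_k\|$ grow with the
basket size (`normalize = TRUE` applies a softmax for users who prefer
scale-invariance; the encoder's layer normalisation largely absorbs the
scale either way). $\sigma$ is read as the elementwise logistic function —
the same symbol denotes the logistic in the fusion head — with `tanh`
selectable. Activities inside a day are ordered by ascending id; the sum is
permutation invariant, the ordering only fixes how exported attention
weights are aligned. Mean and max pooling over the $e_i$ are provided as
the classical ablations.

**Positional encoding and encoders.** Day embeddings (positions
$1..K$ since admission) and history word embeddings (positions $1..n$ in
the text) receive sinusoidal encodings with base constant 100,
$PE_{pos,2i}=\sin(pos/100^{2i/d_e})$, $PE_{pos,2i+1}=\cos(pos/100^{2i/d_e})$,
and pass through stacks of multi-head self-attention blocks: per head
$q = W_Q x + b_Q$ (likewise $k$, $v$), row-softmaxed scaled dot-product
scores, heads concatenated and mixed by $W_o$, then a position-wise
feed-forward with ReLU, and layer normalisation. The block computes
$\mathrm{LayerNorm}(A + FFN(A))$ — a single residual around the
feed-forward, which is how this architecture defines the block; the
conventional two-residual form (`residual = "standard"`) is provided
because the surrounding text appeals to standard residual connections, and
we did not want the choice hidden. Default depths: 1 layer over days, 2
over history — deeper stacks are supported but in our experience (and in
the motivating ablations) add nothing at these sequence lengths.

**Aggregation.** Day hidden states are aggregated against the *last* day:
a one-hidden-layer ReLU MLP of width $d_e$ scores
$\mathrm{concat}(h_i, h_K)$, and scores are exponentiated and normalised
(a softmax). The defining ratio $e_{kK}/\sum_i e_{iK}$ is not guaranteed
positive for a raw MLP output, so the softmax is the default realisation;
`literal_day_aggregation = TRUE` uses the raw ratio for users who want the
formula verbatim. History hidden states are average-pooled over word
positions. (The pooling denominator is described in the source formulation
as the number of attention heads, but the sum plainly runs over word
positions; we average over the non-padding positions.)

**Adversarial pair.** A generator (two $d_e \to d_e$ linear layers with a
ReLU between, then $d_e \to M$ with sigmoid) maps the aggregated day state
to an activity-probability vector; a discriminator (two ReLU layers of
width $\lceil M/2 \rceil$, sigmoid scalar) separates generated vectors from
true multi-hot targets. Losses are the standard minimax pair plus a mean
binary cross-entropy $L_g$ on the generated vector. Each step updates the
discriminator first (generated vectors detached), then the recommendation
network and generator jointly on $L + L_\mathcal{G}$. Adversarial gradients
flow into the encoder by default (the model is trained end to end);
`adv_stop_gradient = TRUE` confines them to the generator. The
discriminator consumes probability vectors directly — no sampling or
thresholding — which keeps the whole objective differentiable.

**Fusion.** With $l^p$ the per-activity count of observed days containing
the activity, $\beta = [l^p > 0]$, and $\tilde l^p = l^p / K$,
$$\hat y = \sigma\big((1-\alpha)\odot\beta\odot(W_d z^d + b_d)
 + \alpha\odot\tilde l^p + \lambda(W_{txt} z^w + b_{txt})\big),
 \qquad \alpha = \sigma(W_p \tilde l^p + b_p).$$
Three choices here were genuinely open and are worth recording:

* *Operator grouping.* The defining expression is typeset ambiguously; we
  read it as one sigmoid over the sum of the three terms, with
  $(1-\alpha)\odot\beta$ gating only the day branch. The all-ones vector in
  the original notation supports the $(1-\alpha)$ construction.
* *Count scale.* Raw counts saturate the outer sigmoid after a handful of
  days, so both the gate and the fusion consume counts normalised by the
  number of observed days (range $[0,1]$); `counts = "raw"` restores the
  literal reading.
* *Gate shape.* $W_p$ is diagonal by default — each activity's gate depends
  on its own frequency — because an $M \times M$ gate adds $M^2$ parameters
  the planted-structure experiments never justified; `gate()` accepts a
  full matrix.

A consequence of $\beta$ as defined is that never-observed activities get no
day-branch score and must be reached through the history term or the
generator; `beta_mode = "all_ones"` removes the mask.

**Loss.** $L = \frac1N\sum \|y-\hat y\|^2 + \gamma L_g$, the inner norm
being the per-instance sum of squared errors, averaged over the batch, with
$\gamma = 0.5$. Optimisation is Adam; since no learning rate is part of the
model's definition we fixed $5\times10^{-3}$ once for all experiments.

## Preprocessing

Histories are cleaned with a configurable character whitelist (default:
letters in any script, digits, whitespace), tokenised by whitespace with
CJK characters split one token each, and mapped to a word vocabulary
(id 0 reserved for padding). Activity names pass through a synonym map (for
bilingual name unification) and duplicate activities within a day collapse
to a set. Admissions outside a 3–30 day stay window are dropped (the window
is configurable; the underlying study removed "too short or too long" stays
without stating bounds, and 3–30 comfortably brackets a 9-day mean stay).
Each admission is truncated to its first K days with K = clamp(round(f·n),
1, n−1) and f drawn uniformly from [0.70, 0.80] per record (a deterministic
f = 0.75 mode exists); the day after the cut is the ground-truth target.
Truncation is per-record rather than global because per-record draws give
the training set a mixture of cut depths at no cost to reproducibility
(everything is seeded). All ids are 1-based, R's native indexing.

## The synthetic cohort generator

Real inpatient EMR data cannot be redistributed, so the package generates
cohorts that carry exactly the statistical structure the model is built to
exploit — and nothing else:

* stay length $2 + \mathrm{Poisson}(\mu - 2)$ with $\mu = 9$ days, so every
  record can be truncated;
* a long-term-order subset (default 5 activities, each appearing daily with
  probability 0.9);
* per-condition activity clusters (4 conditions × 4 activities, each
  appearing with probability 0.7 on the days of patients with that
  condition), signalled in the history by 3 dedicated words per condition
  mixed into filler text at rate 0.15;
* transfer rules (trigger activity today → consequent tomorrow with a given
  probability; default one rule per condition at 0.8);
* uniform background noise, with the noise rate derived so the expected
  basket size matches 8 activities/day; histories average 168 tokens.

The day/basket/history means mirror the summary statistics of the hospital
cohort this model class was developed on. What the generator does *not*
emulate: vocabulary scale (thousands of activities), non-stationary care
phases (admission/surgery/discharge regimes), correlated noise, coded
ontologies, or clinically coherent narrative text. Tests passing on these
cohorts therefore demonstrate that the implementation learns the structures
it claims to learn — not that it reaches any particular accuracy on real
wards. On the fully planted test cohort (daily long-term orders, one
deterministic rule, derived noise rate 0) next-day sets are almost entirely
predictable and all methods approach ceiling metrics; that is by design:
the cohort is an instrument for verifying recovery, not a benchmark.

## Numerical choices and degenerate inputs

* Log arguments in all GAN losses are clamped to $[10^{-7}, 1-10^{-7}]$,
  keeping every loss finite on the closed unit interval.
* Layer normalisation uses population variance with $\varepsilon=10^{-5}$.
* Softmaxes subtract the row maximum before exponentiation.
* Attention scaling is $1/\sqrt{d_k}$ by default (the conventional choice;
  the source text's "1/d" is typographically ambiguous), with $1/d_k$
  selectable; $d_k = d_e/h$, default $h = 4$ heads, feed-forward width
  $4d_e$.
* Top-K ties break by ascending activity id; `personal_top` ranks by count
  then id, and pads beyond the observed activities with unseen ids in
  ascending order; `item_transfer` ranks by transfer score, then observed
  count, then id, and falls back to `personal_top` when only one day is
  observed (no adjacent pairs exist).
* Transfer matrices are built per patient from that patient's observed days
  only; no cohort pooling.
* A single-day sequence degenerates gracefully: the aggregation weight is 1
  and $z^d = h_1$. An empty history contributes nothing (the $\lambda$ term
  is dropped), which coincides with the no-history ablation.
* Weights initialise N(0, 0.1), biases 0, layer-norm gains 1; all
  randomness (initialisation, shuffling, truncation, generation, dropout)
  is seed-driven, and single-threaded runs are bit-reproducible.
* Padding, where used, is explicit: masked positions receive effectively
  $-\infty$ attention scores and are excluded from aggregation means, so a
  padded-and-masked batch reproduces per-instance forward passes exactly.
* Dropout exists in the encoder blocks but defaults to 0 — it is not part
  of the model's definition.

## Training engine

No autodiff framework for R is assumed; the package ships a small
reverse-mode tape over dense matrices (`R/autodiff.R`) with exactly the
primitives the model needs, including fused affine maps, row softmax, row
layer-norm, and scatter-add gradients for embedding-row selection. Its
gradients are pinned to central finite differences in the test suite, and
the tape's forward values are required to match the plain numeric forward
pass bit-for-bit at double precision tolerance. Training problem sizes in
the shipped tests and acceptance script (200 patients, M = 50, $d_e$ = 16,
2 heads, 50 epochs) were chosen as the smallest sizes at which all planted
structure is reliably recovered; the architecture defaults ($d_e$ = 32,
4 heads) are what a real-data run would start from.

## Known limitations

* The unnormalised day-attention weights make day-embedding magnitude grow
  with basket size; with very large baskets consider `normalize = TRUE`.
* Pure-R training is CPU-bound and practical to cohort sizes in the
  thousands, not the tens of thousands.
* The discriminator sees probability vectors versus exact multi-hot
  vectors, which it could in principle separate by saturation alone; the
  cross-entropy term keeps the generator anchored to the targets.
* `ItemTransfer` scores are pure per-patient transfer counts (frequency is
  only a tie-break). When every activity of the last day recurs daily,
  transfer counts tie across all daily activities and the frequency
  tie-break decides — episodic triggers are where the baseline is
  informative.
* Multi-day-ahead prediction and discharge-day recommendation are out of
  scope by construction of the truncation target.
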