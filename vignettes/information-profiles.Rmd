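---
title: "Information profiles: method, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information profiles: method, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infoprofile)
```

## The model

An information profile assigns to every base of a DNA sequence the number
of bits an ideal compressor would spend encoding it, given everything seen
so far: $-\log_2 P(x_n)$. Predictable sequence — tandem repeat arrays,
second and later copies of transposable elements, homopolymer runs — costs
far less than 2 bits per base; novel, high-entropy sequence sits near the
2-bit ceiling of the four-letter alphabet. Plotting this quantity along a
chromosome makes large-scale regularities (centromeric and telomeric
repeat regions, retrotransposon copies) visible at a glance, without any
annotation, alignment or repeat library.

The predictor is a mixture of $K$ finite-context models. An order-$k$
model conditions on the previous $k$ bases and estimates

$$P_k(s \mid c) = \frac{N(s \mid c) + \alpha}{N(c) + 4\alpha},$$

where $N(s \mid c)$ counts how often symbol $s$ followed context $c$ so
far and $N(c)$ is the row total. $\alpha$ interpolates between the
maximum-likelihood frequencies and the uniform law; $\alpha = 1$ is the
Laplace estimator. Counts accumulate *while* the sequence is processed —
the model is adaptive and causal: the estimate for position $n$ never uses
position $n$ itself.

The mixture combines the per-order estimates with weights that track each
model's recent predictive success:

$$P(s) = \sum_k w_k P_k(s), \qquad
  w_k \leftarrow \frac{w_k^{\gamma}\, P_k(x_n)}{\sum_j w_j^{\gamma}\, P_j(x_n)}.$$

With $\gamma = 1$ the recursion is exact Bayesian model averaging: $w_k$
is the posterior probability of model $k$ given the sequence so far,
under a uniform $1/K$ prior (the test suite verifies the streaming
weights against a batch log-space computation of that posterior). With
$\gamma < 1$ old evidence decays geometrically, which matters because DNA
is non-stationary: inside a repeat array the deep models dominate, in
unique sequence the shallow ones do, and the forgetting factor controls
how fast the mixture re-adapts at the boundaries.

Because a single scan is direction-dependent — the *second* copy of a
repeat is the cheap one, and which copy is "second" depends on the scan
direction — the sequence is processed both 5'→3' and 3'→5' with fresh
statistics each, and the profile keeps the per-position minimum. The raw
profile is then low-pass filtered with a Blackman window and subsampled
for display.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `depths` | 2, 4, 6, 8, 10, 12, 14, 16 | context orders of the 8 competing models |
| `alphas` | 1 (k ≤ 12), 1/16 (k = 14, 16) | estimator smoothing per depth |
| `gamma` | 0.99 | forgetting factor, (0, 1] |
| `window` | 1,001 bp | Blackman smoothing length (odd); 10,001–100,001 bp for chromosome-scale overviews |
| `sample_step` | 20 bp | sampling grid of the emitted track |
| `direction` | `"both"` | min of direct and reversed passes |

Two of these deserve comment, because the design was genuinely open:

* **$\alpha$ for the deep models.** An order-14 or order-16 table over a
  desk-scale sequence is extremely sparse: almost every context has been
  seen zero or one times. With $\alpha = 1$, a single prior observation
  moves the estimate only from 0.25 to 0.4 — too timid to let the deep
  models speak exactly where they are most informative (long exact
  repeats). The default $\alpha = 1/16$ lets one observation push the
  estimate to $\approx 0.85$ while still never producing a zero
  probability. Both values are per-depth overridable.
* **$\gamma = 0.99$.** At this value the effective memory of the weight
  recursion is a few hundred bases, which matches the scale of the
  structures the profiles are meant to expose (repeat units of tens to
  thousands of bp) while keeping the $\gamma = 1$ Bayesian behaviour as
  an accessible special case. Forgetting is applied to the *weights*
  only; count tables are never decayed.

Other numerical choices: each order-$k$ model answers the uniform vector
and performs no count update until $k$ valid symbols have accumulated
(start of sequence, and again after every masked run — a context must
never span a gap); non-ACGT characters (N runs, IUPAC ambiguity codes)
are masked rather than recoded, excluded from smoothing, and emitted as
gaps in WIG output; weights are renormalized after every position, which
for $\alpha > 0$ keeps them strictly positive without any explicit floor;
the "reversed (3'→5')" pass processes the reversed — not
reverse-complemented — character sequence, since the point is removing
the directionality of *processing* on the same strand (a `revcomp`
option exists for strand-symmetric analyses); the minimum is taken
*before* smoothing; smoothing at sequence edges and next to masked runs
renormalizes the truncated Blackman taps over the positions actually
available, so constants are preserved exactly and the output never
leaves the input's range.

One boundary case worth knowing: in a *conditional* profile (below), a
target context never seen in the reference yields the uniform estimate,
so a completely divergent region sits at the 2-bit ceiling — divergence
saturates at the random-DNA baseline rather than exceeding it.

## Conditional profiles

`conditional_profile()` trains all models on a reference sequence (one
counts-only pass per direction), freezes the counts, then profiles the
target with frozen counts but *live* mixture weights. Freezing keeps the
profile a pure measure of similarity to the reference: the target's own
repeats cannot make themselves cheap. Letting the weights adapt is what
localizes divergence sharply — inside a divergent segment the deep models
collapse to uniform and the weights shift within a few dozen bases. A
shared region costs a fraction of a bit per base; sequence absent from
the reference returns to ~2 bits, so peaks mark structural differences
between assemblies.

## Complexity

One pass does O(1) work per model per base (hash-table lookup of the
packed 2-bit context), so runtime is linear in sequence length —
megabases take seconds. Memory holds only the count tables: at most
$\min(L, 4^k)$ entries per model after $L$ bases, independent of how long
the sequence is kept around. Both contracts are asserted in the test
suite (runtime ratios across 0.5/1/2 Mbp inputs; stored-context bounds).

## What the synthetic generator emulates — and what it does not

`synth_generate()` plants exact structures in an i.i.d. uniform (or
order-1 Markov) background: tandem repeat arrays (e.g. 50 copies of a
6-mer, the scale of fungal telomeric units), dispersed near-identical
copies of a few kb (the scale of LTR retrotransposons, with an i.i.d.
substitution rate), homopolymers, N runs and inverted copies. Mutations
are substitutions only, so truth coordinates are exact to the base.

The validation suite runs at deliberately desk-scale sizes — 200 kb
backgrounds with 10 kb planted duplications (20 replicates), 1 Mbp
baselines, 100 kb conditional comparisons — chosen so the whole suite
recomputes in minutes while every planted structure is still one to two
orders of magnitude larger than the deepest context.

What passing these tests shows: the estimator, mixture and forgetting
recursion are implemented exactly (machine-precision agreement with naive
reference implementations); planted second copies are recovered as
low-information regions essentially always at these sizes; divergence is
localized to the planted interval. What they do not show: behaviour on
real genomic composition (isochores, CpG suppression, nested and
degenerate repeat families), which has no ground truth here. The Markov
background option probes compositional bias only crudely.

## Known limitations

* Contexts are literal: a repeat in reverse-complement orientation is
  only cheap in the pass whose direction reads it in its original
  spelling; inverted-repeat context modeling is out of scope.
* No significance calling: the profile is a descriptive signal, and
  deciding what is "low" is left to the viewer (or downstream tooling).
* Counts use plain 64-bit accumulation with no rescaling, which is exact
  at desk scale but means extremely long streams never forget at the
  count level — only the weights adapt.
* WIG/bedGraph values are written with 4 decimals; sub-1e-4-bit structure
  is below model noise and not representable in the tracks.
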