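---
title: "Designing spiking neural networks by grammatical evolution: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing spiking neural networks by grammatical evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gesnn)
```

`gesnn` evolves complete three-layer feedforward spiking neural networks —
topology, synaptic weights and delays in one genotype — for classification
of numeric tabular data. This vignette explains the underlying models, every
tunable parameter, the numerical and design decisions taken where the
method leaves room, and what the synthetic benchmark does and does not
demonstrate.

## 1. The neuron and network model

Neurons follow the Spike Response Model (SRM). A spike arriving from
presynaptic neuron $i$ at time $t_i$ through a synapse with weight $w_i$
and delay $d_i$ contributes a postsynaptic potential (PSP) shaped by

$$\varepsilon(t) = \begin{cases}
 (t/\tau)\, e^{1 - t/\tau} & t > 0,\\ 0 & t \le 0,
\end{cases}$$

a kernel that rises from zero, peaks at exactly $1$ at $t = \tau$, and
decays exponentially. The membrane potential is the weighted linear sum

$$x(t) = \sum_i w_i\, \varepsilon(t - t_i - d_i),$$

and the neuron fires at the first time $x(t) \ge \theta$. The model is
deliberately minimal: there is no reset or refractory kernel, because the
decoding scheme only ever reads a neuron's *first* spike. Networks are
strictly feedforward with three layers: one input neuron per feature, a
designed set of hidden neurons (each wired to an arbitrary subset of
inputs), and a single output neuron that every hidden neuron projects to
with one synapse. A hidden neuron that never crosses threshold simply
contributes nothing downstream; this is a legitimate network state, not an
error.

Assumptions worth making explicit: inputs are single spikes (one per
feature, no spike trains); excitation and inhibition differ only in the
sign of $w$; and the class information must be expressible in the *timing*
of one output spike.

## 2. Parameters and their defaults

| Parameter | Default | Units | Role |
|---|---|---|---|
| $\tau$ | 9 | ms | PSP decay; sets the temporal scale of integration |
| $\theta$ | 1 | mV | firing threshold, compared directly to $\sum w\varepsilon$ |
| encoding window $[a, b]$ | [0.01, 9] | ms | where input spikes live |
| class targets | $12 + 3k$ | ms | desired output time for class $k$ |
| simulation end | last target + 2 | ms | upper limit of all spike searches |
| decision start | 10 | ms | earliest admissible *output* spike |
| grid step `dt` | 0.01 | ms | spike-time resolution |
| weights | $[-999.99, 999.99]$ | — | grammar-generated range |
| delays | $[0.01, 19.99]$ | ms | grammar-generated range, clamped |

With $\tau = 9$ the PSP of the latest possible input spike (9 ms) still
peaks at 18 ms, inside the decision window of small class counts — the
encoding window, targets and $\tau$ are a matched set and should be moved
together if at all.

The search engines default to the full design protocol's settings
(population 100, 8-bit codons, 500 codons; GA: tournament $K=5$, 10%
elitism, one-point crossover, 5% per-bit negation mutation; DE: DE/Rand/1,
binomial crossover at $CR = 0.10$). Two values the protocol leaves open are
config-exposed here: the DE differential weight ($F = 0.5$, the customary
default) and the evaluation budget, which defaults to a desk-scale 10,000
calls in `gesnn()` — the full-scale protocol (1,000,000 calls, 33
repetitions) is available by argument but takes hours per run.

## 3. Temporal encoding

Each feature is mapped linearly from its design-set range $[m, M]$ onto
$[a, b]$, so the design minimum fires earliest (0.01 ms) and the design
maximum latest (9 ms). Three boundary rules complete the map:

* **Degenerate feature** ($M = m$ on the design half): every value encodes
  to the window midpoint $(a+b)/2$ and a warning is raised. This keeps the
  pattern dimension stable instead of dividing by zero.
* **Out-of-range test values** are clamped to $[m, M]$ first, so held-out
  spikes always land inside the window the SRM was designed around.
* **No leakage by construction:** $m$ and $M$ are computed by
  `fit_encoding()` from the design subset only; the held-out half can be
  perturbed arbitrarily without changing the fitted encoding or the
  designed network (this is asserted by an automated test).

## 4. Genotype-to-network mapping

Network words use a compact dialect: `{` terminates a hidden-neuron block,
`(` terminates an input-synapse config, and each config is
`id@weight@delay` with 2-decimal fixed-point numbers; the last config of a
block is the synapse onto the output neuron. The shipped grammar
(`inst/extdata/snn.bnf`) generates these words with right-branching
recursion, so both the number of hidden neurons and the number of synapses
per neuron are genotype-driven; weights take 1–3 integer digits (max
999.99) with an optional sign, delays 1–2 integer digits clamped into
[0.01, 19.99] ms at parse time, and input ids are reduced modulo the
feature count. Duplicate synapses between the same pair of neurons are
allowed — they act as parallel multi-delay connections.

The mapping is the standard depth-first grammatical-evolution derivation:
always rewrite the left-most nonterminal; at a choice point with $k > 1$
alternatives consume the next codon $c$ and take alternative $c \bmod k$;
single-alternative rules consume nothing. Two deliberate choices:

* **No wrapping.** If the codons run out while a choice point remains, the
  individual is *invalid* — invalidity is a value (a sentinel fitness), not
  an exception, so search engines handle it uniformly. The sentinels
  ($10^9$ for the squared error, $2$ for the accuracy error) are strictly
  worse than any attainable valid fitness.
* **Ordered alternatives.** The textual order of alternatives in the BNF
  file defines codon semantics, so the grammar file is part of the model
  specification, not mere syntax.

With 500 codons essentially all random genotypes derive to completion under
the shipped grammar (the exhaustion path is still exercised by tests), so
the search starts from a fully valid population.

## 5. Numerical choices

* **Grid evaluation, no root finding.** First-spike times are the earliest
  grid point (step 0.01 ms, matching the delay resolution) at which the
  potential reaches $\theta$. This makes simulation exactly reproducible
  across platforms and is accurate to one grid step, which is far below
  the 3 ms spacing of class targets. The grid solver is validated against
  a 10×-finer brute-force oracle on randomized neurons.
* **Decision window.** The protocol's simulation window `[10 ms, last
  target + 2]` is read as constraining the *output* neuron only: input
  spikes live in [0.01, 9] ms, so hidden neurons must be free to fire
  before 10 ms; the output spike search starts at 10 ms. This is one
  reading of an ambiguous convention; the alternative (discarding early
  output crossings as errors rather than ignoring them) would only differ
  for networks whose output crosses threshold before 10 ms.
* **Non-firing outputs.** Under the accuracy error a silent output is a
  rejection (always wrong). Under the squared error the actual time is
  substituted with the simulation end time — the maximally late time —
  giving a finite, monotone penalty instead of an infinite or arbitrary
  one.
* **Nearest-target decoding.** An output spike predicts the class with the
  closest target time, ties broken toward the smaller class id. The
  midpoint between 12 and 15 ms therefore predicts class 0.
* **DE ties replace.** A trial vector with fitness *equal* to its target
  replaces it. The accuracy error takes at most $T+1$ distinct values on
  $T$ design patterns, so plateaus are the norm; tie replacement lets the
  population drift across them instead of freezing.
* **GA elites are not re-evaluated**; their cached fitness is carried
  forward, and each newly created individual costs exactly one fitness
  call, so budgets are accounted exactly (a final partial generation is
  topped up with the best parents to conserve the population size).

## 6. The synthetic benchmark

`make_blobs()` generates balanced isotropic Gaussian blobs with unit noise,
consecutive class centroids a fixed `separation` apart along random
directions. The package's end-to-end checks use 40 samples, 2 features, 2
classes and `separation = 8` — far above the noise scale, so the classes
are linearly separable and a nearest-centroid rule scores 100%. The
acceptance pipeline runs the full split/design/test protocol on this data
at desk scale (DE engine, accuracy-error fitness, population 20, 4,000
evaluations, 5–10 repetitions), sizes chosen so a complete run takes a few
minutes on one CPU.

What this shows: that the whole chain — encoding, mapping, simulation,
search, decoding — can reliably design networks that solve an easy, clearly
posed problem, and that every step is deterministic per seed. What it does
not show: performance on overlapping classes, correlated or irrelevant
features, many classes, or real benchmark suites; published results on such
data rest on budgets around $10^6$ evaluations with tens of repetitions,
which this package can execute (`run_experiment()` with the default
budget) but does not bundle as a test. Note also that the encoding range is
fitted on the design half only; pipelines that normalize on the full
dataset before splitting will give slightly different results.

## 7. Known limitations

* Single-spike semantics only; no spike trains, rate codes or
  population/receptive-field encodings.
* One output neuron; classes are separated purely in time, which may become
  brittle as the target ladder grows (each extra class extends the
  simulation window by 3 ms).
* The shipped grammar is a reconstruction that reproduces the dialect's
  observable structure and numeric ranges; topology statistics under other
  grammars with the same dialect may differ.
* The evolutionary search is stochastic: per-seed variance in designed
  topologies is substantial, and summaries should always be reported over
  repetitions, as `run_experiment()` does.
* Categorical features and missing values are out of scope; datasets must
  be numeric and complete.
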