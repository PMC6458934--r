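# gesnn — grammatical evolution of partially connected spiking neural networks

`gesnn` designs small spiking neural networks (SNNs) for supervised
classification of tabular data. Instead of training the weights of a fixed,
fully connected architecture, a grammatical-evolution search designs the
whole network at once — which hidden neurons exist, which input features
each one listens to, and every synaptic weight and delay — so the finished
network needs no further training and typically touches only a subset of
the input features (implicit feature selection). The package is aimed at
researchers in neuroevolution and spiking computation who want a compact,
fully reproducible implementation of this design pipeline, from raw CSV to
a scored network.

## The method in brief

**Neuron model.** Every neuron follows the Spike Response Model. A
presynaptic spike at time *t<sub>i</sub>*, carried by a synapse with weight
*w<sub>i</sub>* and delay *d<sub>i</sub>*, contributes a postsynaptic
potential shaped by the kernel

> ε(t) = (t/τ) · e^(1 − t/τ) for t > 0, else 0,

which peaks at exactly 1 when t = τ. The membrane potential is the linear
sum x(t) = Σ<sub>i</sub> w<sub>i</sub> ε(t − t<sub>i</sub> − d<sub>i</sub>),
and the neuron emits its (single) spike at the first time x(t) reaches the
threshold θ. Defaults: τ = 9 ms, θ = 1 mV, evaluated on a 0.01 ms grid.

**Temporal encoding.** A scalar feature f with design-set range [m, M] is
mapped linearly onto the spike-time window [a, b] = [0.01, 9] ms:

> Y(f) = ((b − a)/r) · f + (a·M − b·m)/r,  r = M − m,

so Y(m) = a and Y(M) = b. Each sample becomes one input spike per feature.

**Decoding.** Class k is assigned the target firing time 12 + 3k ms
({12, 15, 18, …}); the simulation runs until the last target plus 2 ms, and
the output neuron's first spike (searched from 10 ms on) predicts the class
with the nearest target. A silent output is a rejection.

**Search.** Networks are written as words of a BNF grammar in a compact
dialect — `{` ends a hidden neuron, `(` ends an input synapse, `@`
separates each synapse's neuron id, weight and delay. Integer codon
genotypes (500 codons of 8 bits) are mapped to words by the standard
depth-first grammatical-evolution derivation (codon mod #alternatives at
each choice point, no wrapping), and optimized either by a genetic
algorithm over the 4000-bit genome (tournament K = 5, 10% elitism,
one-point crossover, 5% bit-flip mutation) or by differential evolution
over [0, 255]^500 (DE/Rand/1, CR = 0.10, F = 0.5). Two fitness functions
are available, both minimized on the design half of the data: the squared
error E<sub>s</sub> = Σ<sub>p</sub> (t<sup>a</sup>(p) − t<sup>d</sup>(p))²
between actual and target output times, and the accuracy error
E<sub>a</sub> = 1 − C/T.

## Worked example

Design a network for a separable two-class problem (desk-scale search:
population 20, 4,000 fitness evaluations — a few seconds per thousand
evaluations on one CPU):

```r
library(gesnn)

ds     <- make_blobs(40, n_features = 2, n_classes = 2, separation = 8, seed = 42)
halves <- stratified_split(ds, seed = 42)
fit    <- gesnn(halves$design$x, halves$design$y, engine = "de",
                fitness = "accuracy", budget = 4000, population = 20, seed = 42)
fit
#> Engine: DE | fitness: accuracy | evaluations: 4000
#> Designed network: 4 hidden neuron(s), 9 synapses, 2/2 feature(s) employed
#> Design accuracy: 1.0000 (best fitness 0)

table(truth = halves$test$y, predicted = predict(fit, halves$test$x))
#>      predicted
#> truth  0  1
#>     0 10  0
#>     1  0  9
```

The design accuracy (1.0000) is 1 − E<sub>a</sub> on the design half; the
held-out confusion matrix shows 19/20 correct with one rejection (a
non-firing output, counted as an error). The evolved word behind the model
is plain text:

```r
fit$word
#> "47@22.31@09.10(1@0.09@6.80(0@305.92@4.85{6@4.56@4.55(0@572.39@3.02{..."
```

`summary(fit)` prints the per-synapse topology, `coef(fit)` returns it as a
data frame, `plot(fit)` draws the best-so-far search trace, and
`run_experiment()` repeats the full split/design/test protocol over many
seeds and summarizes accuracies and topology statistics as mean ± sd.
A thin command-line front end with `generate`, `split`, `encode`, `design`,
`evaluate`, `stats` and `experiment` subcommands ships in
`inst/cli/gesnn.R`.

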