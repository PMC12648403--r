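---
title: "Quanvolutional models for base-resolution TF binding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quanvolutional models for base-resolution TF binding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(quanvseq)
```

# The problem

Transcription factors (TFs) bind short degenerate DNA motifs, and ChIP-seq
locates their genome-wide binding sites as peaks of read signal. Deep
base-resolution predictors (fully convolutional encoder-decoders) learn to
map a one-hot DNA window to a per-base binding probability or a continuous
binding signal, but their accuracy degrades when a TF has few high-quality
peaks — a common situation. `quanvseq` implements a quantum-classical hybrid
variant of this model family: the first convolutional layer is replaced by a
*quanvolutional* layer whose feature extractor is a small parameterized
quantum circuit (PQC) simulated exactly as a statevector, trained end to end
by gradient descent together with the classical layers.

# The quanvolutional first layer

## Encoding, circuit, readout

A width-q binary window $x \in \{0,1\}^q$ taken from one one-hot nucleotide
channel is angle-encoded qubit by qubit,

$$|x_i\rangle = R_Y(\pi x_i)\,|0\rangle, \qquad
|\psi_{\mathrm{in}}\rangle = \bigotimes_{i=1}^{q} |x_i\rangle \in \mathbb{C}^{2^q},$$

so a 4-qubit window lives in a 16-dimensional state space, with binary input
landing exactly on a computational basis state. A trainable unitary
$U(\theta)$ is applied, $|\psi_{\mathrm{out}}\rangle = U(\theta)|\psi_{\mathrm{in}}\rangle$,
and the readout is one Pauli-Z expectation per qubit,
$f_i(\theta) = \langle \psi_{\mathrm{out}}|\sigma_z^{(i)}|\psi_{\mathrm{out}}\rangle \in [-1, 1]$.

The ansatz of $U(\theta)$ is not dictated by the model family, so the package
fixes a standard hardware-efficient layout: per layer one trainable $R_Y$
rotation per qubit followed by a CNOT chain (control $i \to$ target $i+1$;
a ring closure is available), default three layers, giving
$q \times n_{\mathrm{layers}}$ parameters. For one qubit the entangler is a
no-op. Qubit 1 is the most significant bit of the basis index; this is
arbitrary but must be fixed for the dense-matrix oracle tests.

## Channel handling

A q-bp window of a one-hot sequence holds $4q$ binary values but the circuit
encodes only $q$. The package applies the PQC independently to each of the
four nucleotide channels' width-q binary windows and concatenates the
readouts into $4q$ feature channels per position, sharing one $\theta$ across
channels (a flag disables sharing). This keeps the binary-encoding picture
exact — each encoded value is literally a 0/1 indicator — and leaves channel
mixing to the complementary classical convolution. The alternative (packing
all 16 values into more qubits) would exceed the simulable budget.

## Kernel division

Motif-scale context is 16 bp (most known TF motifs fit), but a 16-qubit
statevector is out of reach. The kernel-division rule splits the receptive
field between the quantum kernel and a complementary classical convolution:

$$k_{\mathrm{target}} = k_{\mathrm{quantum}} + k_{\mathrm{classical}} - 1
 = 4 + 13 - 1 = 16 .$$

`kernel_division(q, k_target)` returns $(q,\; k_{\mathrm{target}} - q + 1)$,
so the ablation ladder $q = 1..4$ keeps an identical 16 bp effective field
(verified in the tests by single-base perturbation probing). Stride is 1 in
both stages and the input is symmetrically zero-padded
($\lfloor (k_t-1)/2 \rfloor$ left) so the layer preserves sequence length;
activation $p$ maps to the input window $[p - 7,\, p + 8]$ for
$k_t = 16$, the convention the motif-extraction code relies on.

## Gradients

Training differentiates through the simulator in reverse mode: an adjoint
sweep propagates $\sigma_z |\psi_{\mathrm{out}}\rangle$ back through the
inverted gate sequence and accumulates
$2\,\mathrm{Re}\langle\lambda| \partial_\theta G |\phi\rangle$ per rotation.
The parameter-shift rule $(f(\theta + \pi/2) - f(\theta - \pi/2))/2$ and
central finite differences are kept as independent oracles; the test suite
requires agreement to 1e-8 and 1e-5 respectively. Because QConv1 only ever
sees binary windows, the whole quantum stage reduces to a lookup table over
the $2^q$ possible windows — expectations and their $\theta$-gradients are
tabulated once per update, which is why exact simulation adds little cost at
training time.

# The predictor

The model is a U-net-like fully convolutional encoder-decoder: QConv1 (or a
plain width-16 convolution for the classical baseline), two further
conv+max-pool stages, a bottleneck, and a mirrored decoder using learned
upsampling (nearest-neighbour expansion followed by a trained convolution)
with skip connections at matching resolutions, ending in a per-base head —
sigmoid for binary site classification (500 bp inputs), identity for
regression of $\log_{10}(1 + \mathrm{signal})$ (1000 bp inputs). The exact
channel widths of the reference classical models live in their code bases,
not in the literature describing them, so the defaults here are declared
choices: encoder 64/96/128 channels, pooling 5·4·5 (500 bp) or 5·5·8
(1000 bp), bottleneck 128, decoder mirrored, all configurable. Weights are
Xavier-initialized, including the PQC angles (uniform Glorot limit scaled by
$\pi$ so initial angles span a meaningful rotation range).

All computation is double precision. The `precision` field of
`model_config()` records the task's nominal precision (single for binary,
double for signal) as configuration metadata; the statevector simulator is
double precision regardless, which is what the unitarity tolerances (1e-10)
require.

# Data pipeline

Positives are `length`-bp windows centered on peak summits with a uniform
random shift in [-100, 100] bp; examples whose shifted window leaves the
chromosome are dropped and counted. The bottom 5% of examples by summit
signal are filtered out. One negative per surviving peak is attempted 3000 bp
upstream and skipped when out of bounds or overlapping any peak. Signals are
transformed by $\log_{10}(1+x)$. Binary per-base labels come from a position
count matrix: log-odds weights with pseudocount 1 against a uniform 0.25
background, both strands scanned, and every base covered by a window scoring
at least 80% of the maximum attainable score is labeled 1. The 0.8 fraction
is a conventional PWM-match cutoff, exposed as a parameter, and isolated in
`label_binary()` so an alternative rule can be swapped in. `N` bases one-hot
to all-zero rows, which the quantum encoder maps benignly to $|0\ldots0\rangle$.
Coordinates are 0-based half-open (BED convention) throughout.

# The synthetic-data generator

`simulate_dataset()` emulates the structure of ChIP-seq training data: an
i.i.d. background genome (default uniform base composition, 2 Mb), 300
non-overlapping planted instances of an 8 bp motif (`TGACTCAG`, an AP-1-like
consensus, `info_strength` 0.9 — i.e. 90% of the probability mass on the
consensus base per position), a Gaussian occupancy profile per site
(amplitude 10, sd 50 bp, matching the few-hundred-bp scale of real peak
profiles), additive Gaussian noise (sd 0.5) clipped at zero, one BED peak
record per site, and an optional cofactor motif (an 8 bp E-box,
`CCACGTGG`) planted at a fixed start-to-start offset (default 40 bp) with
configurable orientations. Site placement is uniform with rejection sampling
and bounded retries (10 × n_sites).

What it does *not* emulate: read-level noise, GC/mappability bias, motif
grammar beyond a single fixed spacing, nucleosome structure, or the
heterogeneous peak strengths of real data. Passing tests on this generator
therefore demonstrate the correctness of the machinery (labeling, training,
extraction, spacing recovery), not performance claims about real ChIP-seq.

# Training protocol

AdamW (defaults lr 1e-3, weight decay 1e-2 — conventional values; the tuned
settings of the original experiments are not public) on an 80/20 train/test
split; early stopping monitors a 10% validation carve-out of the training
split (patience 6, maximum 40 epochs) and restores the best-validation
weights. The binary task uses hard negative mining: all positive bases plus
the top $\min(r \cdot n_{\mathrm{pos}}, n_{\mathrm{neg}})$ highest-loss
negatives ($r = 3$; top 1% of negatives when a sequence has no positive
base), averaged. The signal task uses RMSE. Seeds fully determine the
partition, shuffling, and initialization, so compared models can share
identical partitions. `downsample_nested()` draws one permutation and takes
prefixes, giving the strictly nested size ladder (250, 500, 750, 1000, 1500,
3000, 6000, 12000, 24000, full); `fine_tune()` continues optimization of all
weights, including $\theta$, from a checkpoint, and `cross_self_harness()`
produces paired cross/self scores per trial.

# Motif analytics

Per test sequence the trained model's prediction selects the 100 bp window
with the highest summed output (earliest on ties); within it, each
first-layer filter contributes the 16 bp input window of its maximal
activation (using the padding convention above; boundary-clipped windows are
discarded). Per-filter collections become position frequency matrices, whose
information content is
$\mathrm{IC} = -\sum_{i,j} b_j \log_2 b_j + \sum_{i,j} m_{ij} \log_2 m_{ij}$
with $0\log 0 = 0$: 0 bits for a uniform 16 x 4 PFM, 32 bits for a
deterministic one. PFMs export to MEME minimal format so external motif
comparison tools can be applied verbatim.

In-package detection replaces external motif comparison with a best-alignment
column correlation (all shifts with >= 4 overlapping columns, forward and
reverse complement) against a supplied reference library, a positional
permutation null, and BH-adjusted q-values at q < 0.1; reproducible detection
requires matches in at least 4 of 5 independent training trials. Condition
detection vectors are compared by Pearson correlation and clustered with
Ward linkage on 1 - correlation.

The internal PWM scanner scores log-odds (pseudocount 1e-3) on both strands
and assigns exact p-values from the discretized score distribution under the
background model (dynamic programming; granularity 1e-3 of the total score
range). Minus-strand matches are reported on the forward axis. Minimum
motif-pair distances are start-to-start (configurable intent: center-to-center
differs only by a constant for fixed-width motifs) and are tabulated per
strand-orientation pair (++, +-, -+, --), per peak.

# Numerical and scale choices

* Statevector ops are dense complex vectors of length $2^q$, $q \le 8$
  guarded; tolerances: norm 1e-10 (construction), 1e-9 (drift over 1000
  random circuits).
* Ties: earliest window wins in `top_signal_window()`; first maximum wins in
  max pooling; filtering ties drop the earliest example.
* Degenerate inputs: all-N sequences produce finite predictions; zero-variance
  sequences are skipped (and counted) by the Pearson score; empty prediction
  and label sets define IOU = 1.
* The p-value of a PWM window is attainable only on the discrete score
  lattice; for near-deterministic consensus PWMs that lattice is coarse
  (few atoms), so empirical match rates can sit well below the nominal
  threshold. Calibration holds for PWMs with heterogeneous columns, which is
  what the calibration test uses.

## Smoke-scale end-to-end runs

The end-to-end tests train on the generator's standard conditions (2 Mb, 300
sites, 8 bp motif) with a slimmed model — the full 64 first-layer filters but
a 24/32-channel encoder tail and a 16-channel decoder — and few fixed epochs
(no early stopping; `restore_best = FALSE`), sizes chosen so the whole suite
runs on a single CPU in minutes. Training uses lr 3e-3 and batch size 8,
settings picked from convergence diagnostics on this data (the reference
protocols likewise tuned their hyperparameters). The binary variant carries
the motif-learning checks: its per-base labels mark exactly the planted
motif bases, so hard negative mining concentrates the gradient on them,
whereas at smoke scale the signal variant can reduce its loss by predicting
a generic centered bump before it learns the motif. Five independent
16-filter trials compare the per-PFM IC of trained filter banks against
matched randomly initialized models (one-sided Welch test), and trained
PFMs must align to the planted PWM at column correlation >= 0.7.

Two caveats this data design makes visible. First, a composition bias: the
planted motif is the only recurrent structure inside top-signal windows, so
even a randomly initialized model's maximally activating subsequences can
align well with the planted PWM; alignment alone does not separate trained
from random models here. Second, a template-selection bias on IC: a fixed
random filter consistently selects 16-mers resembling its own random
template, giving random filter banks a mean-IC floor of roughly 3.5-4.5
bits at these support sizes. Short training on a genome containing a single
motif leaves most filters diffuse — there is nothing else for them to
specialize on — so the filter-bank mean IC of smoke-trained models can sit
below that floor even when the model demonstrably detects the motif (test
IOU above 0.7 and near-perfect PFM alignment). A trained-above-random IC
ordering is expected only for converged models on data rich in distinct
motifs; the corresponding test documents this by construction rather than
weakening the comparison.

# Known limitations

* Exact simulation limits the quantum kernel to a few qubits; the package
  guards $q \le 4$ in QConv1 (the simulator itself allows 8).
* Training is CPU-bound R; it is meant for method verification and
  small-scale experiments, not for genome-scale benchmarking.
* No shot noise, density matrices, or hardware noise models — the simulator
  is an idealized statevector.
* The in-package motif detection approximates, but does not reproduce,
  external tools' q-value calibration; MEME export exists precisely so the
  external comparison can be run instead.
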