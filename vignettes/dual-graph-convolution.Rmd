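---
title: "Dual graph convolution for link prediction on graphs of graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual graph convolution for link prediction on graphs of graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chemical networks — drug–drug interactions, shared indications, shared
targets, metabolic substrate–product relations — are graphs whose nodes are
themselves graphs: each compound is a molecule with its own atom/bond
structure. `gognn` treats this two-level object as a *graph of graphs* (GoG)
and poses chemical network prediction as link prediction: given some observed
compound–compound links, score the probability that an unobserved pair is
linked. The package trains a *dual graph convolutional network* end-to-end
over both levels, and ships the classical baselines the method is normally
compared against.

## The model

**Internal convolution.** Each atom $v_k$ of a molecule starts from a
trainable embedding $\mathbf v_k^{(0)} \in \mathbb R^d$, drawn once per
distinct *atom signature* (element, valence, hydrogen count, degree,
aromaticity) from $\mathcal N(0, 0.1^2)$ per component. $T$ steps of

$$\mathbf v_k^{(t+1)} = f\!\left(\mathbf W_{t,\deg(k)}\,\mathbf v_k^{(t)}
 + \sum_{m \in A_k} \mathbf M_{t,\deg(k)}\,\mathbf v_m^{(t)}\right),
 \qquad f = \mathrm{ReLU},$$

mix each atom's state with its bonded neighbors'. The weight pair
$(\mathbf W, \mathbf M)$ is specific to the step and to the receiving atom's
degree — the device that compensates for deliberately ignoring bond types.
The compound vector pools every step including the raw embedding:

$$\mathbf g = \sum_{k} \operatorname{softmax}\!\Big(\sum_{t=0}^{T} \mathbf v_k^{(t)}\Big),$$

so the components of $\mathbf g$ sum exactly to the atom count.

**External convolution.** The compound vectors are refined over the
inter-compound network with $L$ steps of the same template,
$\mathbf g_i^{(\ell+1)} = f(\mathbf U_\ell\, \mathbf g_i^{(\ell)} +
\sum_{m \in \mathcal A_i} \mathbf V_\ell\, \mathbf g_m^{(\ell)})$, followed by
$\mathbf h_i = \sigma(\sum_{\ell=0}^{L} \mathbf g_i^{(\ell)})$. No degree
distinction is made here — external degrees are large and heterogeneous — and
both $f$ and $\sigma$ default to row-wise softmax at this level. A softmax
*between* layers is unusual; it is kept as the literal default because it is
what the reference architecture prescribes, and ReLU is selectable
(`activation_external = "relu"`) for ablation.

**Link predictor.** A pair $(i, j)$ is scored from the symmetric feature
$(\mathbf h_i + \mathbf h_j) \oplus (\mathbf h_i \odot \mathbf h_j)$ through a
ReLU MLP with hidden sizes 128 and 64 and a 2-way softmax. Symmetry
$p(i,j) = p(j,i)$ is exact by construction — the two orders produce the same
computation graph bit for bit. Training minimizes the *summed*
cross-entropy $-\sum_i \log p_{t_i}$ per mini-batch (a sum, not a mean; the
learning rate absorbs the difference).

Everything — atom embeddings, $\mathbf W, \mathbf M, \mathbf U, \mathbf V$,
predictor — is trained jointly by backpropagation with Adam. The backward
passes are written by hand against the forward caches and are validated in
the test suite against central finite differences (relative error below
$10^{-3}$ end-to-end, $10^{-4}$ for the internal convolution in isolation).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `d` | 32 | compound-vector dimension; reference grid \{32, 62, 128\} (62 preserved verbatim, likely a typo for 64 — both accepted) |
| `T`, `L` | 1, 1 | internal / external steps; reference grid \{1, 3, 5\}; in dense networks `L` matters more than `T` |
| `batch_size` | 128 | reference grid \{64, 128, 256\} |
| `learning_rate` | 0.001 | Adam step size |
| `dropout` | 0.2 | after each hidden predictor ReLU (the only layer the rate is attached to) |
| `degree_max` | 5 | top degree bucket for $(\mathbf W, \mathbf M)$; degree 0 has its own bucket, degrees $> 5$ share the top one |
| `max_atoms` | 64 | load-time compound size cap, with a logged skip count |
| `validation_fraction` | 0.1 | held-out development fraction used for best-epoch selection |

Design points that were genuinely open, and how they were settled:

* **Degree indexing.** The step/degree-specific $(\mathbf W, \mathbf M)$ pair
  is selected by the *receiving* atom's degree for both matrices. Indexing
  $\mathbf M$ by the sender's degree is a defensible alternative; the
  receiver convention follows the neural-fingerprint lineage this
  architecture extends.
* **Biases.** The convolution layers are bias-free (the update equations are
  written without biases); the predictor MLP has biases, as MLP heads
  normally do. Both are explicit in the parameter containers.
* **Message edges.** At training and at prediction time the external
  convolution (and every similarity baseline) sees *training-positive edges
  only*. Messaging over the full network would leak test links into the
  representations. This is the conservative reading of an unstated protocol.
* **Embedding-only baseline.** The relational-embedding baseline replaces
  $\mathbf g$ with free trainable 64-dimensional vectors; the final softmax
  $\sigma$ is still applied so that every mode shares one forward contract
  $\mathbf h = \sigma(\mathbf g)$.
* **Negative pairs are fixed per split** rather than resampled each epoch
  (`resample_negatives` exists but defaults off), keeping runs exactly
  reproducible from one seed.
* **Loss guard.** A true-label probability of exactly zero is clamped at
  $10^{-12}$; a non-finite loss aborts training with a divergence error
  rather than continuing silently.

## Baselines

* **internal_only** — compound vectors go straight to the predictor
  ($\mathbf h = \sigma(\mathbf g)$): molecules without the network.
* **embedding_only** — free 64-d vectors: the network signal only, carried
  entirely by the training labels.
* **fingerprint** — frozen 2048-bit hashed circular fingerprints (radius 2)
  feed the predictor; only the predictor trains. The fingerprint is a
  deterministic neighborhood-hashing implementation (polynomial hash modulo
  $2^{31}-1$, exact in double arithmetic), invariant under atom relabeling.
* **Similarity indices** — common neighbors, Jaccard, and Katz
  ($(I-\beta\mathcal A)^{-1}-I$ entries, $\beta = 0.001$) computed on the
  training-positive adjacency. Katz uses sparse direct solves on the queried
  columns; the truncated power series survives only as a test oracle. The
  solve refuses $\beta \ge 1/\rho(\mathcal A)$ (power-iteration estimate),
  where the series diverges.

## The synthetic benchmark generator

Real chemical GoGs are licensed databases; the package instead generates
GoGs in which the two signal sources are *planted and separately tunable*:

* **Internal signal** — a fraction of compounds carry a triangle of three
  mutually bonded sulfur atoms; pairs in which both endpoints carry the
  motif have their link probability multiplied by `motif_boost`. Non-motif
  molecules are constructed so that the motif cannot occur by chance.
* **External signal** — compounds belong to `n_communities` blocks with
  within/between factors `p_in`/`p_out`.
* **Density and tail** — pair probabilities are rescaled so the expected
  density hits `target_density`; in `powerlaw` mode each compound gets an
  expected-degree weight from a discrete power law with exponent
  `powerlaw_gamma` (inverse-CDF draw truncated at $n-1$), giving Chung-Lu
  style heavy tails.

Setting `motif_boost = 1` removes all internal signal; `p_in = p_out`
removes the community signal; both together give a pure-noise null in which
every method should sit at ROC-AUC 0.5. With both signals on, dense and
heavy-tailed, the dual model has an advantage over single-source baselines;
at extreme sparsity the link-based methods starve while fingerprints keep
their internal signal — the qualitative ordering the architecture was
designed around.

What the generator does **not** emulate: chemically realistic molecules
(valences are typical-by-element, aromaticity is never set, ring statistics
are arbitrary), correlated noise between levels, or the exact degree
sequences of real interaction networks. Passing benchmarks here shows the
*machinery* ranks planted signal correctly, not that any particular AUC
carries over to DrugBank-scale data.

## Problem sizes and numerical choices

The shipped benchmark scripts use desk-scale settings chosen once: dense
regime $n = 300$ compounds, density 0.09, power-law tail $\gamma = 2.2$,
`motif_boost` 5, `p_in/p_out` 4, 1000 training positives, $d = 32$,
$T = L = 1$, 30 epochs, 3 seeds; sparse regime $n = 600$, density 0.0003
(tens of links), 30 training positives, 300 epochs at learning rate 0.01
with dropout off for the two trainable baselines (sixty training pairs need
a hotter, longer schedule than two thousand, and at that sample size dropout
noise swamps the fit — best-epoch selection on the development fraction does
the regularizing), 5 seeds; null regime $n = 200$, density
0.05. Training at these sizes is minutes on one CPU core; the full-data
regimes of the reference experiments are out of scope here.

Remaining numerics: softmax rows are max-shifted before exponentiation;
degree-0 atoms/compounds use only their self-term (their neighbor sum is
empty); checkpoints serialize every array at 17 significant digits, which
round-trips IEEE doubles exactly; all randomness (initialization, batch
order, dropout, sampling) flows from one integer seed per run.

## Known limitations

* Two levels only; deeper GoG nesting is out of scope.
* Full-graph external convolution per batch — fine at desk scale, quadratic
  in memory in the worst case; neighbor sampling is deliberately not
  implemented.
* Bond types, charges, stereochemistry and 3D structure are ignored by
  design; the degree-specific weights are the only compensation.
* The unseen-signature fallback vector is a blunt instrument: a test-time
  molecule full of unseen atom environments degrades toward an
  uninformative embedding (with a warning).
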