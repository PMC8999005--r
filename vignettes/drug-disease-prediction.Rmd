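---
title: "Predicting drug-disease associations from heterogeneous networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-disease associations from heterogeneous networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Drug repositioning asks which *unknown* drug-disease pairs are likely true
associations, given a small set of known associations and side information
about both entity types. `ddpred` models this as link prediction on three
drug-disease heterogeneous networks and scores every pair with two neural
branches whose outputs are mixed by a single weight:

$$\mathrm{Score}(i,j) \;=\; \lambda\,\mathrm{Score}^{\mathrm{topo}}(i,j)
\;+\; (1-\lambda)\,\mathrm{Score}^{\mathrm{attr}}(i,j).$$

## Network construction

Drugs carry three binary property matrices (chemical substructures, target
protein domains, target GO terms). Each yields a drug-drug cosine similarity
$R^m$. An all-zero property row has undefined cosine similarity; we define its
self-similarity as 1 and its similarity to every other drug as 0, with a
warning.

Disease similarity uses the decayed-ancestor (Wang-style) semantic measure on
each disease's ontology DAG: a term at depth $t$ in a disease's DAG
contributes semantic value $\Delta^t$ (default $\Delta = 0.5$), the disease's
semantic value $DV$ is the sum over its terms, and

$$D_{jk} = \frac{\sum_{t \in T_j \cap T_k} \big(S_j(t) + S_k(t)\big)}
{DV_j + DV_k}.$$

A consequence worth knowing: two diseases whose DAGs contain *exactly the same
term set* have similarity 1 even when depths differ, because the shared-term
numerator then equals $DV_j + DV_k$ identically.

Each of the three networks is the symmetric block matrix
$U^m = \begin{bmatrix} R^m & A \\ A^\top & D \end{bmatrix}$ with the binary
association matrix $A$; nodes are ordered drugs-then-diseases.

## Topology branch

For each node, each network, and each meta-path order $k = 1..K$ (default
$K = 2$), we enumerate the $2^k$ typed meta-paths and collect the nodes
reachable by at least one all-nonzero-edge walk of length $k$ (self-loops on
the unit diagonals are ignored; walks may revisit nodes). Same-type neighbors
are ranked by direct similarity $U^m[v, c]$, cross-type neighbors by walk
count; ties break by node index, and the top $N_k$ per type are retained
(defaults $N_1 = 10$, $N_2 = 20$). At order 1 the node itself heads its own
same-type list.

Each retained neighbor set is mean-aggregated in attribute space (drug
neighbors: rows of the property matrix matching the network; disease
neighbors: rows of $D$), projected by a fully connected ReLU layer to $N_f$
dimensions, fused across orders by *scale-level* attention and across the two
neighbor types by *topology-level* attention
($\alpha = \mathrm{softmax}(h^\top \tanh(W u + b))$). Attention and
projection parameters are separate per center-node type (drug vs disease) but
shared across the three networks, keeping the parameter count proportional to
$N_f^2$, not to the data size.

The six per-network representations of a pair form a $2 \times 3N_f$ matrix:
padded by one zero ring, convolved with 16 filters ($2\times2$, ReLU),
max-pooled ($2\times2$, stride 1) and flattened into a code of length
$16 \cdot 2 \cdot 3N_f$ feeding a softmax pair classifier.

## Attribute branch

A pair's attribute embedding stacks row $i$ and row $N_r + j$ of the three
networks into a $2 \times (N_r + N_d) \times 3$ tensor $P$. Crucially, the
two entries holding the pair's *own* association value are zeroed; without
this mask the branch can read the training label directly from its input and
memorizes rather than generalizes (we observed exactly that failure mode
before adding the mask).

$P$ is encoded by a convolutional autoencoder: two shape-preserving layers
(ring padding, $2\times2$ conv, ReLU, stride-1 $2\times2$ max-pool) growing
channels $3 \to 4 \to 8$, and a three-layer transposed-convolution decoder
(linear last layer) with a fixed center crop back to the input shape.
Training is staged: the autoencoder is pretrained on mean squared
reconstruction loss, then the bottleneck code is flattened into a softmax
head trained on cross-entropy with encoder fine-tuning. Staging was chosen
over joint optimization because it makes the two losses' interaction explicit
and reproducible.

## Training and evaluation

Both branch classifiers minimize cross-entropy with Adam (learning rate
`1e-3`, batch 32) on the known associations plus an equal number of sampled
unknown pairs. Cross-validation is per-drug 5-fold: each fold's test
positives are removed from $A$ *before* the networks are rebuilt, and the
test pool is the held-out positives plus every unknown pair not sampled as a
training negative in that fold (excluding them avoids testing on pairs the
model was explicitly told are negative). We report pooled per-fold AUC/AUPR
and per-drug fold-averaged metrics with top-$k$ recalls.

AUC uses the trapezoidal rule on the tie-grouped ROC curve (equivalent to
concordant-pair counting with half-credit ties); AUPR sums
precision $\times$ recall-increment over the tie-grouped step curve.

## Defaults and problem sizes

All tunables live in `dd_control()`. The package targets desk-scale problems
(tens of drugs/diseases, as in the bundled generator) on a single CPU; the
defaults were sized once, by profiling the reference 60-drug/50-disease
problem, so that a full 5-fold cross-validation finishes in minutes in plain
R:

* `n_f = 32`: the topology representation width. Widths of 64+ multiply the
  CNN's memory traffic several-fold for no measurable ranking gain at this
  scale.
* `epochs = 15`, `epochs_cae = 8`: both branch losses plateau well within
  these budgets on desk-scale data (see the training histories stored in the
  fitted object, `plot(fit)`).
* `enc_channels = c(4, 8)`, `dec_channels = c(4, 2)`: the smallest
  two-layer-encoder/three-layer-decoder configuration that reconstructs the
  reference embeddings to near machine precision when over-parameterized
  relative to the input.
* `lambda = 0.5`: equal branch weight; sweep it via `predict(fit, lambda=)`
  without refitting.

For larger problems increase `n_f`, the channel widths and the epoch budgets
together; every one of them is a free parameter of the model, not of the
data.

## Synthetic data generator

`simulate_dd_data()` plants a known low-rank signal so recovery is
measurable: drugs and diseases get cluster-indicator latent vectors with
Gaussian jitter; property matrices carry per-cluster feature blocks corrupted
by Bernoulli bit flips; disease DAGs share per-cluster ancestor chains under
a common root, swapped to a random cluster with the same noise probability;
associations are Bernoulli with probability
$\sigma(12 \langle x_i, y_j\rangle + b)$, where $b$ is calibrated by root
finding so the *expected* density hits the target exactly. The steepness 12
was fixed a priori to make the planted signal crisp but not deterministic.
The latent factors are returned (and written to disk) for audit; ranking by
the latent dot product gives an oracle AUC above 0.95 at reference settings.

## Numerical choices

All network layers are hand-written in vectorized base R on
`(height, width, channel, batch)` arrays; convolutions contract channels via
BLAS after an `aperm` reshape, and every analytic gradient is verified
against central finite differences in the test suite. Max-pooling shares
gradients equally among tied maxima; on piecewise-constant inputs this is a
subgradient, so gradient checks use smooth inputs. Softmax rows subtract the
row maximum before exponentiation. Cross-entropy clamps the true-class
probability at `1e-12` with a warning. All randomness flows from a single
`seed` argument; sub-seeds for negative sampling and the two branches are
drawn up front, which makes a single-branch fit bit-identical to the
corresponding branch inside a two-branch fit.

## Limitations

* Mini-batch CNN training in base R is orders of magnitude slower than a
  compiled tensor library; the package is for desk-scale study, not the
  763-drug scale of production repositioning databases.
* Only cosine similarity for drugs and the decayed-ancestor measure for
  diseases are implemented.
* The two branches are trained separately; no joint fine-tuning of the
  combined objective.
* Negative "unknown" pairs are treated as true negatives during training,
  the standard (and biased) assumption of this model family.
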