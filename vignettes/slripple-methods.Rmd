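---
title: "Predicting synthetic lethality from a knowledge graph: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting synthetic lethality from a knowledge graph: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slripple)
```

## The problem

Two genes are *synthetically lethal* (SL) when knocking out either alone
leaves a cell viable but knocking out both kills it — the foundation of a
class of cancer therapies that target the partner of a tumor-mutated gene.
Screening all gene pairs experimentally is infeasible, so computational
ranking of candidate pairs matters. `slripple` scores unordered gene pairs
$(m, n)$ for SL by learning gene embeddings from two sources at once:

* a labeled SL graph $G_{SL} = (V, E)$ with symmetric adjacency
  $A_{mn} \in \{0, 1\}$, and
* a heterogeneous knowledge graph (KG) of triples $(h, r, t)$ over typed
  entities (genes, pathways, diseases, compounds, ...) and typed relations.

The model estimates $\hat y_{mn} = F(m, n; \Theta, G)$, the probability of
an SL interaction, with all parameters $\Theta$ trained end to end.

## Encoder pipeline

For a pair $(m, n)$ both genes are encoded with the same machinery, each
conditioned on the other; the description below follows gene $m$ with
partner $n$.

**Seed sets and ripple sets.** The gene's known SL partners in the
*training* split form its seed set $\varepsilon^0_m$. Hop frontiers expand
head-to-tail along KG triples,
$\varepsilon^p_m = \{t \mid (h,r,t) \in G_{KG},\ h \in \varepsilon^{p-1}_m\}$,
and the hop-$p$ *ripple set* $S^p_m$ is a fixed-size sample (with
replacement) of the triples whose head lies in $\varepsilon^{p-1}_m$.
Fixed-size sampling keeps every batch tensor rectangular.

**Ripple encoder.** With $\mathbf{n}$ the partner's embedding-table row:

* hop 0 attends over the heads $h_i$ of the hop-1 triples (exactly the
  seeds): $a_i = \mathrm{softmax}_i\,
  \mathbf{w}_a^\top [\mathbf{h}_i \,\|\, \mathbf{n}]$, response
  $\mathbf{o}^0 = \sum_i a_i \mathbf{h}_i$;
* hop $p \ge 1$ weights tails by the partner's affinity to the head under
  the triple's relation matrix $R_i \in \mathbb{R}^{S \times S}$:
  $k_i = \mathrm{softmax}_i\, \mathbf{n}^\top R_i \mathbf{h}_i$, response
  $\mathbf{o}^p = \sum_i k_i \mathbf{t}_i$;
* the responses fuse affinely, with no nonlinearity:
  $\mathbf{m}_{rip} = [\mathbf{o}^0 \| \cdots \| \mathbf{o}^{l_p}] W_o +
  \mathbf{b}_o$.

**Relation attention and enhancement (gene–entity stage).** Around the
center gene, a fixed number $k$ of KG neighbors is sampled uniformly per
level. Each sampled edge is scored by a two-hidden-layer network on the
concatenation of the *partner's ripple embedding* with the relation
embedding (ReLU hidden layers, sigmoid output), the scores are
softmax-normalized over the sampled neighborhood, and neighbor entity
embeddings are averaged under those weights. The center's own entity
embedding is *enhanced* with the partner signal by one of four
aggregators — sum, concat, pool (elementwise max) or top-k (the
`k_top` largest sigmoid activations kept in place, others zeroed, ties to
the lower index) — all mapping back to dimension $S$.

**Discrepancy contrastive layer and fusion (entity–entity stage).** Depth
step $d$ mixes the current embedding with the attention-aggregated
neighborhood at distance $d$ using the same aggregator family (top-k by
default); width layer $w$ linearly maps the concatenated depth stack
through its own matrix $M_w$ (no bias). The representation set $T_m$
collects the stage input plus each width layer's output. An attention
aggregator scores each representation individually,
$\alpha_i = \mathbf{w}_6^\top \tanh(W_6\, \mathbf{rep}_i)$, softmaxes the
scores, and passes the weighted sum through the sigmoid output layer,
giving the KG-side embedding $\mathbf{m}_{kg} \in (0,1)^S$.

**Scoring.** Each orientation pairs one gene's ripple embedding with the
partner's KG-side embedding, $f_{SL}(m, n) = \mathbf{m}_{rip} \cdot
\mathbf{n}_{kg}$, and the unordered pair logit is the mean of the two
orientations, so $\hat y_{mn} = \sigma\!\big(\tfrac12 (\mathbf{m}_{rip}
\cdot \mathbf{n}_{kg} + \mathbf{n}_{rip} \cdot \mathbf{m}_{kg})\big)$ is
exactly symmetric in the pair.

Why this pairing: the KG-side embedding is sigmoid-bounded, so an inner
product of two KG-side embeddings is confined to $(0, S)$. During early
development that all-bounded variant reliably collapsed — with every logit
positive, cross-entropy is minimized fastest by shrinking all embeddings
toward zero, where the sigmoid saturates and gradients vanish. Pairing the
*unbounded* affine ripple embedding with the bounded KG-side embedding
gives the score both signs and keeps gradients alive; it is also the
pairing the encoder stack implies, since the ripple output is what plays
the "gene embedding" role in every downstream stage. A consequence worth
noting: because the symmetrized logit is invariant under argument order,
presenting training pairs in both orientations is an exact duplicate of
presenting them once, so the `augment_orders` switch defaults to off.

## Objective

Training minimizes, per batch,

$$ L = \mathrm{CE} + \gamma\, \lVert \Theta \rVert_2^2 + \lambda\, R(A), $$

where CE is the mean binary cross-entropy over the training positives and
an equal number of negatives resampled every epoch (for each positive
$(m, n)$ a partner is redrawn uniformly, avoiding self-pairs and known
positives — negatives carry label 0 and are *added* to the loss;
a subtracted negative term would make the objective unbounded below).
Evaluation negatives are a separate, fixed dataset-level sample. CE is
reported per pair (a mean); the sum form differs only by the constant
batch size.

**Label smoothness.** $R(A)$ treats a gene's known labels as boundary
values on an edge-weighted graph: for gene $m$, each labeled partner is
held out in turn, the remaining labels are propagated for `p_hop` rounds
over the row-normalized weight matrix with labeled nodes clamped, and the
held-out label's cross-entropy against its propagated estimate is
accumulated. Edge weights come from the relation-attention network
conditioned on the gene's embedding, over the subgraph of the gene's
labeled partners and their sampled KG neighbors. Genes with fewer than two
labeled partners contribute zero (leave-one-out is undefined). At the
reference weight $\lambda = 10^{-8}$ the term's gradient is orders of
magnitude below the noise floor of the stochastic CE gradient, so the
trainer adds $R(A)$ to the reported loss (estimated each epoch on a capped
gene subsample, scaled to the eligible count) without propagating
gradients through the propagation recursion; the exported
`propagate_labels_loo()` / `label_smoothness()` operations are exact and
are what the tests verify.

## Where the design was genuinely open

* **Hop-0 attention score.** The score on (seed head, candidate) is the
  smallest faithful parameterization: one trainable functional
  $\mathbf{w}_a \in \mathbb{R}^{2S}$ on the concatenation.
* **Attention conditioning.** Relation attention around gene $m$ is
  conditioned on the partner gene, carried by the partner's ripple
  embedding (its table row under the `no_ripple` ablation). A
  `attn_condition` future hook exists in spirit; only the partner
  conditioning is implemented because it is what makes the mechanism
  pair-specific.
* **Fusion scores per element.** Scoring the pooled summary alone would
  make the fusion weights constant across the representation set; each
  representation is scored individually so the softmax is informative,
  and the max-pooled summary can be added back as a shared conditioning
  term (`fuse_condition_on_pool`, off by default).
* **Top-k semantics.** Coordinate-wise: keep the `k_top` largest
  activations in place, zero the rest, ties to the lower index — output
  dimension stays $S$ for every aggregator.
* **Gene-holdout splits.** Test pairs have *both* genes in the held-out
  set; pairs straddling the boundary are discarded. Sending every pair
  that touches a held-out gene to test is incompatible with keeping the
  train and test gene sets disjoint on dense pair sets (the partners of
  held-out genes span nearly all genes), and gene-set disjointness is the
  contract this split exists to provide.
* **Cold starts.** A gene with no training SL partner seeds its ripple
  propagation with itself; an empty hop frontier is filled with
  (seed, self-relation, seed) placeholder triples; an isolated entity's
  neighbor sample is padded with (self-relation, itself). The reserved
  `.self` relation id is appended to the vocabulary at load time.
* **SL edges inside the KG.** Gene–gene KG edges that coincide with
  validation or test pairs are masked from propagation by default
  (`mask_eval_edges`), so evaluation labels cannot leak through duplicate
  KG edges.

## Numerical choices

Softmaxes are max-shifted; cross-entropy is computed from logits in the
stable $\max(z,0) - yz + \log(1+e^{-|z|})$ form; Adam uses the standard
bias correction with $\beta = (0.9, 0.999)$, $\epsilon = 10^{-8}$.
Embedding tables are initialized uniformly at the $\pm\sqrt{6/2S}$ scale
of their row dimension (a table row is gathered, not multiplied, so the
vocabulary size plays no role in its variance); weight matrices use
Glorot bounds. All sampling — ripple sets, neighbor fields, negatives,
batch order — is driven by seeds derived from `config$seed`, and two runs
with identical inputs are bit-identical. Relation matrices are full
$S \times S$ as specified; `relation_matrix = "diag"` substitutes diagonal
matrices when memory is tight.

## Reference and scaled configurations

`sl_config()` carries the reference defaults: dimension 128, batch 512,
learning rate $6 \times 10^{-5}$, 2 ripple hops, contrastive depth 2 and
width 3, $\gamma = \lambda = 10^{-8}$, Adam, 8 sampled neighbors, 8 ripple
triples per hop, early-stopping patience 5 (monitoring validation AUC —
the natural choice for a ranking objective). Those values target a KG with
millions of edges and tens of thousands of genes.

The bundled synthetic benchmark is three orders of magnitude smaller, so
`synth_protocol_config()` scales the model down: dimension 16, depth 2,
width 2, batch 64, learning rate $10^{-2}$, at most 20 epochs. The batch
and rate follow from the fixture's size — with 2,800 training examples a
512-pair batch yields about six Adam steps per epoch, far too few for 20
epochs — and one training run completes in roughly 15 seconds on a single
CPU. The test suite and the acceptance script use this protocol with a
200-gene / 800-entity / 2,000-pair benchmark and three model seeds, and a
60-gene variant for fast unit tests.

## What the synthetic benchmark does and does not emulate

The generator plants a recoverable signal: genes belong to latent
functional modules, draw most of their typed KG edges from their module's
small entity pool, and SL labels are Bernoulli with
$P(y = 1) = \sigma(\beta \cdot |\text{shared typed neighbors}| +
\mathrm{logit}(c))$, classes balanced by subsampling. Shared KG
neighborhood is therefore the *causal mediator* of SL, which is what the
encoders exploit on real biomedical KGs; a trivial shared-neighbor count
scorer verifies the signal exists (AUC $\approx 0.93$) before the model is
credited or blamed. The generator does **not** reproduce the scale, the
24-relation schema, or the heavy-tailed degree distribution of a real
SL knowledge graph, and its entities carry no features; passing the
recovery tests demonstrates that the implementation can learn
KG-structure-mediated pair labels end to end, not that it attains any
particular performance on real SL screens.

```{r baseline, eval = FALSE}
bench <- synth_benchmark(synth_config())
sh <- shared_neighbor_counts(bench$kg, bench$pairs)
auc_roc(sh, bench$pairs$pairs$label)
```

## Known limitations

* Training is CPU-bound R; the reference configuration (dim 128 on a
  multi-million-edge KG) is beyond what this implementation targets —
  the package is built for method study and desk-scale benchmarks.
* The label-smoothness term contributes value, not gradient, at its
  reference weight (see above); a differentiable propagation would be
  needed to study large $\lambda$ regimes.
* Entity and relation identities are the only inputs; there are no
  node features, no edge-feature inputs, no multi-head attention, and no
  relation-type-specific attention networks.
* Negative "pairs" are drawn uniformly from unknown pairs, so a small
  fraction may be unobserved true positives — inherent to the
  negative-sampling protocol, and shared by the evaluation convention.
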