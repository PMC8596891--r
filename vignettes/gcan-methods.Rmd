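---
title: "Father-son biased walks and the GCAN sequence model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Father-son biased walks and the GCAN sequence model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcan)
```

## The problem

Rare diseases carry very few direct therapeutic links, so ranking candidate
drugs from a rare disease's own graph neighborhood is hopeless. What rare
(subtype, "son") diseases do have is a hierarchical parent ("father")
disease within two hops that is usually much better annotated, and a drug
that treats the father frequently treats the son as well — Gaucher disease
type III versus type I, both treated by imiglucerase and taliglucerase alfa,
is the canonical example. `gcan` turns that observation into a
link-prediction pipeline:

1. two heterogeneous disease–gene–drug networks are kept side by side — one
   holding father nodes, one holding son nodes — joined by a two-column
   *bridge map* of father–son pairs;
2. a biased random walk samples alternating entity/relation token paths over
   the pair of networks, crossing the bridge with tunable probability;
3. a recurrent sequence model (GRU + cooperation + attention, "GCAN") is
   trained to predict the next token of each path under a negative-sampling
   objective;
4. a held-out therapeutic triple `(disease, relation, drug)` becomes a
   ranking query: the model embeds the `(disease, relation)` prefix and
   scores every drug entity by dot product; quality is summarized as
   Hits@k and mean reciprocal rank (MRR).

## The biased walk

At an entity $e_i$ the walker sees two candidate classes: *cross* — the
bridge partners of $e_i$ in the other network — and *within* — the graph
neighbors of $e_i$ in its current network (every edge is traversable in both
directions; a directed-only walk would strand leaf drugs and genes). The
next step obeys

$$P(e_{i+1} \mid e_i) = \begin{cases}
\alpha / n_\text{cross} & e_{i+1} \text{ a bridge partner} \\
(1-\alpha) / n_\text{within} & e_{i+1} \text{ a neighbor}
\end{cases}$$

with an empty class donating its mass to the other, so walks keep full
length at unbridged nodes. Edge weights are uniform: the data model carries
no weights, and collapsing duplicate triples (rather than counting them)
keeps multiplicity from silently biasing the kernel. Cross steps emit the
reserved relation token `__FATHER_SON__` and flip the current network.
Setting $\alpha = 0$ recovers a plain uniform single-network walk, which is
also the `biased_walk = FALSE` ablation.

Choices worth stating:

* $\alpha$ defaults to 0.5 and must be treated as a tunable — the original
  experiments never report their value.
* `depth_hops` counts relation traversals: a 15-hop walk has 31 tokens.
  15 is the published operating point of a 5–21 hop sweep; the
  `cmd_depth_sweep()` utility reproduces that sweep shape on any data.
* `walks_per_entity` (default 10) is a convention, not a published value.
* Dead ends truncate a walk; a walk that dies at its start token trains
  nothing and is dropped from the corpus.
* Walks may revisit nodes. The only bias is the cross-class mass — there is
  deliberately no node2vec-style return penalty, because the mechanism under
  study is the father–son bias alone.

## The sequence model

Each token has one tied embedding row in $E$ ($V \times d$). Per position:

* $L$ stacked GRU layers produce a top-layer output $g_t$;
* the **cooperation** transform re-injects the current token embedding:
  $h_t = \tanh(W_h\, g_t + W_x\, x_t + b)$ — the current node participates
  in the prediction directly rather than only through the gated recurrence;
* **attention** scores the within-walk history with a bilinear form
  $\alpha_{ti} = h_t^\top W_\alpha h_i$, softmax-normalized over
  $i = 1..t-1$, giving the context $c_t = \sum_i \alpha_{ti} h_i$ (zero at
  $t = 1$; attention never crosses walk boundaries);
* the prediction vector is the **linear** combination
  $z_t = W_c\,[h_t; c_t]$.

The combiner is linear by design. An earlier build squashed it with tanh;
training then drove every dimension of $z$ to $\pm 1$, the saturation
factor $(1 - z^2) \approx 10^{-4}$ cut the gradient into the recurrence,
and the prediction vector collapsed to a single context-independent corner
(score standard deviation across disease prefixes $\sim 3\times 10^{-7}$),
reducing ranking to marginal drug frequency. A linear output ahead of a
dot-product sampled-softmax objective is the standard construction and is
what the package uses.

The loss at each position contrasts the true next token against $k$
negatives drawn from a noise distribution proportional to corpus token
frequency$^\beta$ ($\beta = 1$ by default, 0.75 exposed as the common
alternative):

$$\mathcal{L} = -\sum_t \Big\{ \log \sigma(z_t^\top y_t)
  + \sum_{j=1}^{k} \log \sigma(-z_t^\top \bar y_j) \Big\}$$

Numerical choices:

* A drawn negative equal to its own target is redrawn (bounded retries).
  At realistic vocabulary sizes collisions are rare; at the desk scales
  used for testing (tens of tokens) the frequency-based noise hits the
  target so often that the negative term cancels the positive gradient and
  even single-triple memorization fails. Explicitly supplied negatives are
  always used verbatim, and a degenerate single-token noise support is kept
  as drawn (with a log message).
* Prediction is next-token over the full vocabulary — entities and
  relations alike — and type restriction to drug candidates happens only at
  evaluation.
* Input and output embeddings are tied; there is no separate output matrix.
* Optimizer: Adam at the published learning rate 0.003 with batch 512;
  initialization uniform$(-0.08, 0.08)$ for all weights, seeded. Training
  is bitwise deterministic given the seed under single-threaded execution.
* Every token ordering (entities, relations, vocabulary indices, file
  output) uses byte-order (radix) sorting, never locale collation, so the
  same seed yields the identical corpus, model and report regardless of the
  session's locale.
* Ablation flags (`cooperation`, `attention`, `biased_walk`) bypass their
  mechanism *exactly* — disabling attention sets $z_t = h_t$ with no
  residual transform — so ablated variants are the simpler models, not
  approximations of them.

Every mechanism is verified three ways in the test suite: against an
independently coded single-position reference, against central finite
differences for every parameter block (guarded relative error $\le 10^{-4}$
on a $d = 4$, $V = 8$ instance), and through exact ablation contracts.

## Ranking protocol

A therapeutic test triple yields one query; the candidate set is every
drug-typed entity of both networks (the task is drug repositioning, so
ranking the full vocabulary would only dilute the metric with entities that
can never be answers). Ties are broken pessimistically — the true drug is
ranked after every equal-scoring candidate — so tied scores can never
inflate Hits@k or MRR. Both a raw and a filtered protocol are provided;
raw is the default and the reported mode is always recorded. Queries whose
disease or relation token is out of vocabulary are unanswerable and receive
the worst rank rather than being dropped.

## The synthetic benchmark

Real data of this kind (hospital extracts joined with DrugBank) is not
redistributable, so the package ships a generator that plants exactly the
mechanism the biased walk is meant to exploit. Each father disease gets
`genes_per_disease` pathogenic gene links and `drugs_per_father`
therapeutic drug links; each son inherits half of its father's genes
(topped up with fresh genes) and, with probability `p_share`, each paternal
drug; spurious disease–drug edges appear with probability `p_noise`; a
`holdout_fraction` of the shared son–drug links is withheld for testing
while their father-side counterparts always remain in training. A withheld
link is therefore recoverable through the bridge — two hops from the son —
but invisible to a walker confined to the son's own network, which is what
makes "biased beats uniform" a falsifiable comparison rather than a vibe.

What the generator does *not* emulate: the degree distribution, relation
inventory and scale of the real hospital data (unpublished beyond counts),
literature-derived edge noise, and drug-similarity structure. Passing tests
on planted benchmarks show the pipeline recovers a planted signal; they say
nothing about performance on any particular real dataset.

The `gaucher_fixture()` miniature mirrors the motivating case: bridged
father `gaucher_type_I` and son `gaucher_type_III` sharing the gene `GBA`;
`imiglucerase` and `taliglucerase_alfa` treat type I in training, and the
two type-III links are the test queries among 20 drug candidates (9
deterministic distractor father–son pairs, each sharing both paternal drugs
in training so the sharing pattern itself is learnable).

## Problem sizes used by the tests and the acceptance script

The exported defaults are the published operating point (hidden 256,
2 layers, batch 512, learning rate 0.003, depth 15). The test suite and
`scripts/acceptance.R` run the same code at desk scale, chosen once for
single-CPU determinism: hidden width 24–32, depth 6–8 hops, 4–10 walks per
entity, 30–200 epochs, benchmarks of 5–20 fathers with 10–30 drugs. At
these sizes the memorization check reaches Hits@10 = 1.0 on training
queries, and the planted-signal comparison (p_share 0.8, 20 fathers,
5 seeds) separates biased from uniform walking in mean Hits@10. Sweeping
these sizes upward improves absolute numbers but not the directional
conclusions the tests assert.

## Known limitations

* Scores are negative-sampling logits (shifted log-odds), not calibrated
  probabilities; only their within-query order is meaningful.
* The desk-scale model under-fits sharp per-disease rankings (Hits@1 is
  modest even on training queries at width 24–32); conclusions are drawn
  from Hits@10/MRR and from paired comparisons on identical data.
* The walk sampler is O(neighbors) per step in plain R; corpora in the
  10^5-step range sample in seconds, but industrial-scale graphs would
  want a compiled kernel behind the same interface.
* Relation labels are opaque strings; no semantics are attached beyond
  identity, and DrugBank/OMIM/Orphanet parsing is out of scope (inputs are
  plain TSV triples).
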