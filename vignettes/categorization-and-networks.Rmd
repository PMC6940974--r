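---
title: "Functional categorization of candidate genes and evidence-filtered networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional categorization of candidate genes and evidence-filtered networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtornet)
```

## The problem

Autism spectrum disorder has a large, heterogeneous genetic component:
the SFARI Gene database catalogues over a thousand candidate genes,
each scored into confidence tiers (1 = "high confidence" through 7,
plus a syndromic flag). A recurring hypothesis in the field is that a
large fraction of these genes converge on a small number of regulatory
axes: translation control through the mTORC1 kinase complex, the
RNA-binding translational repressor FMRP (itself downstream of mTOR
via S6 kinase), and transcriptional regulation by the active vitamin-D
hormone (which induces the mTOR suppressors DDIT4 and PTEN). mtornet
implements the gene-set side of that question as a reusable, tested
pipeline: given a scored candidate table, four category gene lists, a
synonym table and (optionally) an interaction-score table, it computes
how many candidates fall into each functional class, the full overlap
structure among the classes, and a two-layer interaction network
linking the residual candidates to the categorized ones.

## Identifier normalization

All set algebra is performed on stable numeric gene identifiers, never
on raw symbols. A KEGG-style synonym table
(`ID<TAB>symbol1, symbol2, ...; description`, as served by
`rest.kegg.jp/list/hsa`) supplies the alias map; `normalize_symbols()`
resolves case-insensitively and whitespace-trimmed. Two deliberate
policy choices:

* **Ambiguous aliases** (one symbol claimed by several gene ids) are
  always *reported*; under the default policy `"first"` they also
  resolve to the lowest gene id, under `"drop"` they stay unresolved.
  Silent resolution is never allowed, because a single shared alias
  can silently move a gene between Venn regions.
* **Unmapped symbols** are retained under an uppercase-symbol
  surrogate key (`SYM:<SYMBOL>`) rather than discarded, so list
  cardinalities stay conservative and auditable. Surrogate entries in
  the *category* lists (typically loci rather than genes, as in
  vitamin-D response-element screens) are by default excluded from
  candidate matching, since candidates are genes; the exclusion count
  is logged.

Hyphen/underscore folding is deliberately not applied: human symbols
distinguish e.g. families and isoforms by such characters, and folding
them creates false merges.

## Category assignment and the Venn partition

Membership of a candidate in the four categories — FMRP targets, mTOR
signaling-network members, mTOR-modulated transcripts,
vitamin-D-sensitive genes — is encoded as a 4-bit mask (bit values
1/2/4/8 in that order). `venn_partition()` enumerates all 16 regions,
including the outside region (mask 0); region members are
symbol-sorted so outputs are reproducible. Percentages are rounded
half-up to integers (`percent_half_up()`), the convention under which
606/1053 prints as 58%, 179/281 as 64% and 222/281 as 79%.

The tier vocabulary (`1`–`7` plus `S`) and the "high-confidence"
subset (`{1,2,3}` by default) are arguments, not constants; dual
scores such as `"2S"` split into tier `"2"` plus an orthogonal
syndromic flag, so the syndromic annotation never changes tier
filtering.

## The two-layer network

The network stage models the construction used with STRING exports and
Cytoscape:

1. **Core layer.** Each categorized high-tier gene is linked to the
   hub elements its mask touches: FMRP targets to the FMRP hub, mTOR
   network members *and* mTOR-modulated genes to the MTOR hub,
   vitamin-D-sensitive genes to the VITD hub. The cluster taxonomy is
   the seven populated combinations of the FMRP-target, mTOR-modulated
   and vitamin-D bits; genes whose only membership is the mTOR
   signaling network carry no cluster of their own and are
   `HUB_ATTACHED` at the MTOR hub. The core edge count is therefore
   the sum over genes of distinct hubs touched.
2. **Secondary layer.** Residual (uncategorized) genes join only
   through cross-list interaction records whose *combined* score
   clears the high-confidence cutoff (default 0.7). Within-list
   records — categorized–categorized or residual–residual — are
   removed regardless of score, so the secondary layer is bipartite by
   construction (asserted on every build and export).

**Cutoff semantics.** The comparison is strict (`combined > 0.7`) by
default, matching the "more than 0.7" reading; `inclusive = TRUE`
switches to the `>= 700/1000` STRING convention. Scores are accepted
on either the 0–1 or the 0–1000 scale and auto-detected (any score
above 1 implies the integer scale).

**Edge classification.** Each retained edge is labelled by the
evidence channel (homology included as an eighth, auxiliary type) with
the maximal score among channels clearing the cutoff; homology can
therefore out-score a qualifying experimental channel and take the
label, which reproduces the known behaviour of sodium-channel paralog
pairs (e.g. SCN9A–SCN8A). When no single channel qualifies while the
combined score does, the edge is labelled `weakest_high_confidence`
and carries the combined score. Ties at the maximal qualifying score
are broken by a fixed precedence (database > experimental > homology >
textmining > coexpression > neighborhood > fusion > cooccurrence);
ties are measure-zero for continuous scores, but integer-scaled
exports can produce them, so the order is fixed and documented rather
than left to input order.

**Placement.** A connected residual gene's placement is a categorical
function of the set of clusters its partners belong to: one cluster →
`NEAR_CLUSTER`, two → `BETWEEN`, three or more → `CENTER`. Partners
confined to the MTOR hub (`HUB_ATTACHED` only) give
`NEAR_CORE(MTOR)`; when hub-attached partners mix with cluster
partners they count as touching the mTOR-modulated cluster (the
`hub_attached_counts_as` argument, since the seven-cluster taxonomy
has no pure mTOR-network cluster). A *unique* gene touching at least
six of the seven clusters — the KAT2B situation — is upgraded to
`NETWORK_CENTER`; with no unique maximum all ≥3-cluster genes stay
`CENTER`. Placement depends only on the touched-cluster set, so edge
order can never change a label. Residual genes with no qualifying
edge are reported in an `unconnected` list, never dropped silently.

## The synthetic-data generator

The generator exists so every stage has a ground-truth round trip
without any download; it is first-class, tested code.

* `generate_gene_universe()` builds a synonym table with controlled
  alias structure: a fraction `alias_rate` (default 0.3, typical of
  human symbol synonymy) of genes get 1–3 extra aliases, and each
  extra alias is shared with a second gene with probability
  `ambiguity_rate` (default 0.02), giving a binomially distributed
  ambiguous-alias count that the tests check against exact binomial
  envelopes.
* `generate_categories()` is the exact inverse of `venn_partition()`:
  it deals genes into the 16 regions at prescribed cardinalities, so
  the categorize → partition round trip must reproduce the spec
  *exactly*, on every seed. Specific symbols can be planted into
  specific regions, and a per-region high-tier plan controls the tier
  structure.
* `generate_interactions()` draws per-channel scores from
  zero-inflated scaled-beta distributions (textmining least inflated,
  fusion most, support `[0.15, 0.999]`, shapes 1.5/3) and computes the
  combined score with the prior-corrected noisy-OR forward model
  (`string_combine_score()`, prior 0.041): per channel
  $s^* = \max(0, (s - p)/(1 - p))$, then
  $\mathrm{total} = 1 - \prod_i (1 - s^*_i)$, then
  $\mathrm{combined} = \mathrm{total}\,(1 - p) + p$. Two identities
  pin the implementation: all-zero channels give exactly $p$, and a
  single active channel passes through unchanged. The model lives in
  the generator only; the filtering path always trusts the input's
  combined column. Under the default channel distributions roughly a
  quarter of random pairs clear the 0.7 cutoff, a realistic minority.
  "Weakest-high-confidence" pairs are planted by drawing several
  mid-range channels (all at or below the cutoff) whose noisy-OR
  combination exceeds it. Each record is emitted together with its
  expected retention flag and label, computed by an independently
  written scalar re-derivation, so classifier and generator cannot
  share a defect silently.

A single integer seed drives a named substream per stage
(`substream_seed()`), so identical seeds give byte-identical fixture
files while stages remain independently regenerable.

### Reference study conditions

`reference_venn_spec()` fixes the synthetic candidate structure to the
published marginal cardinalities of the SFARI release 01.15.2019
analysis: 1053 candidates, 606 categorized / 447 outside, per-category
totals 258/42/314/223, three genes (PTEN, APC, DOCK1) in the quadruple
region; `reference_high_tier_plan()` adds the tier structure (281
high-tier genes, 179 categorized, 102 outside, PTEN the only
quadruple-region gene). Only those marginals are published; the
interior region sizes are one fixed solution consistent with them,
chosen once and not tuned (the largest pairwise overlap sits on
FMRP-target ∩ mTOR-modulated, matching the published qualitative
observation). They are fixture parameters of this package, not
asserted values of the source data.

What the generator deliberately does **not** emulate: real STRING
score marginals and their channel correlations, the literature content
of the category lists, ortholog mapping, and database-snapshot
network counts. Consequently, passing round trips demonstrate the
*correctness of the set algebra, filtering, classification and
placement rules* on inputs of realistic shape — not agreement with
any particular STRING snapshot. Absolute network counts (genes added,
interactions added, weakest-edge counts) are snapshot-dependent and
are exercised structurally, never numerically.

## Numerical and degenerate-input choices

* Zero denominators in percentages yield 0 rather than an error, so
  empty candidate tables summarize cleanly.
* Self-pairs in interaction tables are dropped; duplicate pairs after
  canonicalization are an error (not averaged), because they indicate
  an ill-formed export.
* Pairs are stored in numeric-aware canonical order and tables are
  stably sorted by `(gene_a, gene_b)`, making all outputs
  order-independent.
* Synonym-table lines with an empty symbol field get the id string as
  primary symbol and a warning; duplicate gene ids are an error.
* An empty tier-filter result warns but is permitted (it is a
  legitimate query).

## Problem sizes in the test suite

The suite generates all fixtures at run time: alias-table fuzzing uses
universes of up to 200 genes over 50 seeds; Venn round trips use 100
random region specifications over universes up to 2000 genes, with a
brute-force per-gene membership oracle on the instances up to 100
genes; network ground-truth recovery uses 50 seeds of ~45 primary /
30 residual genes with ~130 generated interaction records each. These
sizes were chosen as the smallest at which every combinatorial case
(all 16 masks, all placement rules, planted weakest edges, homology
over experimental) occurs routinely.

## Known limitations

* No statistical enrichment test is attached to the overlaps; the
  pipeline reports raw counts by design, and a hypergeometric layer
  would be future work.
* No live KEGG/SFARI/STRING clients: all inputs are files, pinned by
  checksum in the run summary.
* Placement is a categorical label, not a layout; Cytoscape consumes
  the exported attribute tables for actual positioning.
* The interpretation that a residual gene whose only partners are
  hub-attached mTOR-pathway genes is placed `NEAR_CORE(MTOR)` is one
  reading of the original placement rule for "core genes"; it is an
  argument (`hub_attached_counts_as`) rather than an assertion about
  intent.
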