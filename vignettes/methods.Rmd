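---
title: "Calling deletions from long reads with a relational graph network: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## From alignments to graphs

The caller consumes coordinate-sorted SAM/BAM produced by a minimap2-style
aligner. Two filters are applied before anything else:

* **FLAG filter.** A record is kept iff `FLAG != 4` and `FLAG < 256`; this
  removes unmapped, secondary, and supplementary alignments in one rule.
  Split-read (supplementary) evidence is deliberately discarded — the
  signal the model consumes is the intra-alignment `D` operation, and a
  spanning long read carries even multi-kilobase deletions inside a single
  primary alignment.
* **50 bp rule.** Indel CIGAR operations shorter than `min_svlen` (default
  50 bp, the conventional lower bound for a structural variant) are not
  variant evidence. We absorb them: a small `D` advances the reference
  cursor, a small `I` the read cursor, and the surrounding match context is
  coalesced into a single match segment. The alternative reading — dropping
  any read containing a sub-50 bp indel — would discard essentially every
  long read at realistic error rates, so it was rejected. A coalesced match
  can therefore have unequal reference and read spans; its nominal length
  is the larger of the two (this also keeps the one-hot feature of a
  degenerate, insertion-only context nonzero).

Each surviving alignment becomes one small heterogeneous graph; there are
no cross-read edges. Every segment yields a read-side node; match and
deletion segments (the reference-consuming types) also yield a ref-side
node. Node features are six numbers: `(v1, v2, v3, v4, start, end)`, where
the slot matching the node's type holds its length and the rest are zero,
and `(start, end)` are the node's coordinates — read coordinates for
read-side nodes, alignment-anchored reference coordinates for ref-side
nodes. Raw genomic coordinates (10^5–10^7) would swamp the other feature
dimensions, so lengths and coordinates are multiplied by `length_scale`
(default 1/1000, i.e. features are in kb). The scale is recorded in every
checkpoint and a mismatch between checkpoint and graphs is a refusal, not a
silent rescale.

Edges come in three relations, each stored as its own sparse adjacency
(directed both ways): `ref-ref` chains consecutive ref-side nodes,
`read-read` chains consecutive read-side nodes, and `ref-read` joins the
two copies of each reference-consuming segment; insertion and clip
read-side nodes attach to the ref-side node of the nearest preceding
reference-consuming segment (or the following one at the left edge).
Self-loops are not stored because the convolution has an explicit
self-weight term.

Two representation choices were genuinely open. The `read-read` relation
could instead connect nodes *across* reads covering the same locus; we
implement the within-read chain, which keeps each graph a pure function of
one alignment and makes minibatching trivial. Likewise ref-side nodes could
be shared across reads in a global reference graph; they are duplicated
per read for the same reason.

## The classifier

Node embeddings pass through two relational graph convolution layers.
Layer output for node $i$ is

$$H_i^{(l+1)} = \mathrm{ReLU}\Big(\sum_{r \in R}\sum_{j \in N_i^r}
\tfrac{1}{C_{i,r}} W_r^{(l)} H_j^{(l)} + W_0^{(l)} H_i^{(l)} + b^{(l)}\Big)$$

with one trainable matrix per relation plus a self-weight. The
normalization $C_{i,r}$ is the in-degree $|N_i^r|$ — the simplest
degree-aware choice; symmetric $1/\sqrt{d_i d_j}$ normalization is a known
alternative but is not the default. A relation contributes nothing to a
node with no neighbors under it.

The head is, by default, a learnable-activation (Kolmogorov–Arnold) layer
followed by a fully connected layer. Each input–output connection of the
KAN layer carries its own univariate function

$$\phi_{qp}(x) = \mathrm{base}_{qp}\,\mathrm{silu}(x) +
\mathrm{scale}_{qp} \sum_m c_{qpm} B_m(x)$$

with $B_m$ a B-spline basis (grid $G = 5$ intervals, degree $k = 3$, hence
$G + k = 8$ basis functions) on the fixed range $[-2, 2]$. Inputs outside
the range are clamped — never an error — because post-ReLU activations at
the feature scale above rarely leave it. Three ablation heads are
selectable (`fc`, `kan`, `kan2`) to reproduce the
plain-FC / single-KAN / stacked-KAN comparison.

Default widths are $6 \to 8 \to 4$, giving a parameter budget of
$4\cdot6\cdot8+8 = 200$ (conv1), $4\cdot8\cdot4+4 = 132$ (conv2),
$16\cdot(2 + G + k) = 160$ (KAN), $4\cdot2+2 = 10$ (FC): 502 trainable
scalars. The published architecture this reconstructs reports its size
only as a headline figure (~5.1 × 10⁻⁴ M), so the exact widths are a
design choice pinned to that budget.

Training minimizes
$-\frac{1}{N}\sum_i w_{y_i}\log p_{i,y_i} + \frac{\lambda}{2}\lVert W\rVert_2^2$
with class weights $[1-\mathrm{weight}, \mathrm{weight}]$
(default weight = 0.9: deletion nodes are rare), $\lambda = 10^{-4}$ over
*all* trainable scalars including spline coefficients and biases, Adam at
learning rate $10^{-3}$, minibatches of 32 graphs, 50 epochs by default.
The forward/backward passes are implemented analytically in R (dense
layers, sparse relation aggregation) and verified against central finite
differences for every head in the test suite. Probabilities are clamped at
$10^{-12}$ before the log; prediction is the argmax with exact ties
resolved to the negative class.

## From positive nodes to calls

Every positive deletion-typed ref-side node contributes one candidate
interval per read. Consolidation proceeds per chromosome:

1. **Density clustering.** DBSCAN semantics (core point: at least
   `min_samples` neighbors within `eps`, itself included) on the Euclidean
   distance over the raw 3-vector (svlen, start, end), unscaled because
   that is the natural bp-unit space of the quantities. Defaults
   `eps = 500`, `min_samples = 2`: breakpoint jitter of long-read aligners
   is of order 100 bp, and two independent reads are the minimum credible
   support.
2. **Fragment merging.** Long deletions are sometimes reported by aligners
   as several nearby fragments that first-pass clustering leaves as noise.
   Adjacent noise fragments merge when the gap condition
   `start2 − end1 < α` (α = 3000 bp) and/or the length-ratio condition
   `min/max > 0.7` holds, transitively left-to-right to a fixpoint, taking
   the interval hull. The published rule is typeset as a conjunction but
   described as "any condition"; both are implemented (`merge_mode`,
   default `"any"` following the description — note that OR-merging two
   distant fragments of similar length is biologically questionable, which
   is why `"all"` is offered).
3. **Secondary clustering.** Merged fragments are re-clustered with the
   same procedure, each fragment weighted by its member count, so a single
   merged fragment assembled from `min_samples` or more candidates
   survives on its own. Without the weighting, a fragmented long deletion
   reassembled into one hull would always be re-discarded as noise, which
   would defeat the merge step's purpose. Secondary clustering runs on
   merged fragments alone and its calls are unioned with the first-pass
   cluster calls.

Each call takes the member-wise median start and end (a robust consensus;
the source method specifies only "accurate centers"), distinct-read
support (calls under `min_support = 2` are dropped), and the mean
classifier probability as score. Output is VCFv4.2 with symbolic `<DEL>`
records (`POS = start + 1`, INFO `SVTYPE/END/SVLEN/SUPPORT`,
`QUAL = round(100·score)`).

Evaluation matches calls to truth greedily one-to-one by descending
reciprocal overlap (ties to the leftmost) under two gates: both
breakpoints within `bp_tol = 1000` bp and reciprocal overlap
≥ `min_ro = 0.7`. The published comparisons never define their matching
rule; these are the conventional SV-benchmarking values and both are
configurable. Per-bin metrics use the five deletion-length bins [50,200),
[200,500), [500,1000), [1000,5000), [5000,∞), half-open so no event is
double-counted; recall bins by truth length, precision by predicted
length.

## What the simulator does and does not emulate

The bundled generator emulates exactly the features the pipeline consumes:
a uniform-composition multi-chromosome reference; implanted deletions
drawn log-uniformly on [50, 20000] bp so all five reporting bins are
populated; lognormal read lengths (median 10 kb, truncated to
[1, 20] kb); small-indel sequencing errors (per-base event rates, lengths
1–`small_err_max_len` ≤ 5 bp) injected strictly inside match runs so an
error op can never fuse with a true deletion op; and FLAG decoys
(secondary/supplementary truncations, unmapped records) to exercise the
filter. Alignments are computed analytically from the known
donor-to-reference map — no external aligner — so a read crossing a
deletion junction carries the event as a single exact `D` op.

Consequences to keep in mind when reading test results:

* Breakpoints in simulated data are exact, and every ≥ 50 bp `D` op is
  real. The node-classification task is therefore cleanly separable, and
  near-perfect scores on these benchmarks demonstrate correctness of the
  machinery, not performance on real ONT/PacBio data, where
  aligner-induced breakpoint jitter, fragmented representations of long
  deletions, and ≥ 50 bp error artifacts all occur.
* Deletion placement enforces a gap of twice the maximum read length, so
  events never interact; nested or adjacent deletions are out of scope.
* Substitution errors are tracked as a rate but have no CIGAR effect under
  M-semantics, and no per-chemistry (homopolymer) error structure is
  modeled.

Benchmark conditions are frozen in `benchmark_sim_config()`: the standard
set (50 deletions, 4 × 800 kb, 30×, 8% ONT-like error, seed 7) trains on
the first half of the chromosomes and validates on the rest; the
noise-free set (20 deletions, 2 × 700 kb, 20×, seed 1) checks the exact
recovery limit; the long-deletion set (ten ≥ 5 kb deletions, 2 × 500 kb,
30×, seed 1) probes the regime where conventional callers lose recall.
Validation runs train for 12 epochs — on these separable conditions the
loss plateaus well before that — while the package default for real use
remains 50.

## Numerical and degenerate-input choices

* Log probabilities clamped at 1e-12; KAN inputs clamped to the grid
  range; ReLU subgradient at 0 taken as 0.
* Empty relation (no edges): the relation term is skipped, not a NaN from
  0/0 normalization.
* Empty candidate sets, header-only VCFs, and empty truth sets all
  round-trip as empty objects rather than errors.
* DBSCAN border points join the first core point that reaches them; the
  scan order is the (chrom, start)-sorted input order, so results are
  deterministic and shuffle-invariant up to cluster labels.
* All seeds are explicit; simulation, training, and calling are pure
  functions of their configuration.

## Known limitations

Only deletions are called: insertions, duplications, inversions and
translocations would need different graph semantics (read-side evidence
and additional relations). Clustering never crosses chromosome boundaries.
MAPQ is ignored by design. Training is CPU-only and single-threaded; the
502-parameter model makes this a non-issue at desk scale, but very large
BAMs will spend most of their time in graph construction, which is linear
in the number of primary alignments.
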