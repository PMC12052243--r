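# svdelnet

Deletion structural-variant (SV) calling for microbial genomes from
long-read alignments, using a relational graph convolutional network with a
learnable-spline (Kolmogorov–Arnold) activation head and a density-based
breakpoint consolidation stage.

## The problem

Deletions ≥ 50 bp drive much of the phenotypic variation in microbes such
as *Saccharomyces cerevisiae*. Long reads (ONT/PacBio, ~10 kb) span whole
deletion junctions and carry the event as a single `D` operation in the
alignment CIGAR, but their high base-error rate litters alignments with
small spurious indels, and every read crossing an event reports slightly
different breakpoints. A caller therefore has to (i) separate true deletion
signal from alignment noise and (ii) collapse many per-read observations
into one accurate interval.

## The method

**Graph representation.** Alignments are FLAG-filtered (records with
`FLAG == 4` or `FLAG >= 256` are removed) and each CIGAR is decomposed into
typed segments — match (0), insertion (1), deletion (2), clip (3) — with
indels shorter than 50 bp absorbed into match context. Each alignment
becomes a small heterogeneous graph: every segment yields a read-side node,
every reference-consuming segment additionally a ref-side node. Node
features are 6-dimensional: a one-hot-times-length slot per type plus
scaled, anchored (start, end) coordinates. Edges come in three relations —
`ref-ref` and `read-read` chains plus `ref-read` links between the two
copies of a segment — each with its own adjacency matrix.

**Node classification.** Two relational graph convolution layers

    H_i^(l+1) = ReLU( Σ_{r∈R} Σ_{j∈N_i^r} (1/C_{i,r}) W_r^(l) H_j^(l) + W_0^(l) H_i^(l) )

with per-relation weights `W_r`, self-weight `W_0`, and in-degree
normalization `C_{i,r} = |N_i^r|`, followed by a KAN layer whose
activations are learnable univariate functions

    φ_qp(x) = base_qp · silu(x) + scale_qp · Σ_m c_qpm B_m(x)

(B-splines on a fixed grid) and a fully connected softmax head. Training
minimizes a class-weighted cross-entropy with L2 penalty,

    Loss = −(1/N) Σ_i w_{y_i} log p_{i,y_i} + (λ/2)‖W‖²,

with class weights `[1−weight, weight]`. The default architecture has 502
trainable parameters (~5×10⁻⁴ M).

**Consolidation.** Positive deletion nodes become per-read candidate
intervals. Per chromosome, candidates are density-clustered (DBSCAN
semantics) on the Euclidean distance over (svlen, start, end); unmatched
fragments are merged when adjacent pairs satisfy `start2 − end1 < α`
(α = 3000) and/or `min(svlen)/max(svlen) > 0.7`, then re-clustered. Each
surviving cluster becomes one call with median breakpoints, distinct-read
support, and a mean-probability score, emitted as VCF.

A seeded simulator generates the full test bed — random reference, implanted
deletions across the five standard length bins, long reads with exact
analytic CIGARs, small-indel errors, and FLAG decoys — so everything is
verifiable without external data.

## Worked example

```r
library(svdelnet)

cfg <- sim_config(n_chroms = 1, chrom_length = 250000, n_deletions = 3,
                  coverage = 12, seed = 21)
sim <- simulate_dataset(cfg, dir = "example")
sim$truth
#>   chrom  start    end svlen
#> 1  chr1  76232  76542   310
#> 2  chr1 130646 131506   860
#> 3  chr1 179851 199090 19239

rc     <- run_config(epochs = 6, seed = 3)
params <- sv_train("example/reads.sam", "example/truth.vcf", rc)
calls  <- sv_call("example/reads.sam", params, rc,
                  vcf_path = "example/calls.vcf", meta = sim$meta)
calls
#>   chrom  start    end svlen support     score
#> 1  chr1  76232  76542   310      14 0.6912790
#> 2  chr1 130646 131506   860       5 0.7148201
#> 3  chr1 179851 199090 19239      10 0.5244989

evaluate_calls(calls, sim$truth)
#> TP 3  FP 0  FN 0
#> precision 1.0000  recall 1.0000  f1 1.0000
```

All three implanted deletions — including the 19 kb one, much longer than
any single read — are recovered with exact breakpoints; `support` counts
the distinct reads behind each call and `score` is the mean classifier
probability. A command-line front end with the same four verbs
(`simulate`, `train`, `call`, `evaluate`) is installed at
`system.file("cli", "svdelnet.R", package = "svdelnet")`.

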