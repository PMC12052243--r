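#' Graph feature scaling
#'
#' Node features are 6-dimensional: a one-hot-times-length slot per node type
#' (match, insertion, deletion, clip) plus start/end coordinates. Raw genomic
#' coordinates would swamp the feature space, so reference coordinates are
#' anchored at the alignment start and everything is multiplied by
#' `length_scale` (default 1/1000, i.e. features are in kb).
#'
#' @param length_scale multiplicative scale applied to lengths and anchored
#'   coordinates.
#' @return a `graph_scales` list.
#' @export
graph_scales <- function(length_scale = 1 / 1000) {
  stopifnot(length_scale > 0)
  structure(list(length_scale = length_scale), class = "graph_scales")
}

#' Build the heterogeneous graph of one alignment
#'
#' Every segment yields a read-side node whose (start, end) are read
#' coordinates; every reference-consuming segment (match, deletion)
#' additionally yields a ref-side node whose (start, end) are reference
#' coordinates anchored at the alignment start. Edges come in three
#' relations, each stored directed both ways: `ref_ref` chains consecutive
#' ref-side nodes in reference order, `read_read` chains consecutive
#' read-side nodes in read order, and `ref_read` joins the two copies of
#' each reference-consuming segment; insertion and clip read-side nodes
#' attach to the ref-side node of the nearest preceding reference-consuming
#' segment (or the following one at the left edge). Self-loops are not
#' stored (the classifier has an explicit self-weight).
#'
#' @param segments a `segments` data.frame from [segment_ops()] (one
#'   alignment, read order).
#' @param chrom chromosome name.
#' @param qname read name (provenance).
#' @param scales a [graph_scales()].
#' @return an object of class `read_graph`: `chrom`, `anchor`, `feat`
#'   (N x 6 matrix), `nodes` (side/op_code/segment coordinates per node),
#'   `edges` (list of 2-column from/to matrices per relation), `labels`
#'   (NULL until [label_nodes()]), `qname`, `scales`.
#' @export
build_graph <- function(segments, chrom, qname, scales = graph_scales()) {
  if (!nrow(segments)) stop("empty-graph error: alignment yields no segments")
  if (length(chrom) != 1L) stop("invariant error: one chromosome per graph")
  s <- scales$length_scale
  ns <- nrow(segments)
  refcon <- segments$op_code %in% c(0L, 2L)
  anchor <- min(segments$ref_start)
  n_ref <- sum(refcon)
  n_read <- ns
  n <- n_ref + n_read
  feat <- matrix(0, n, 6L)
  side <- c(rep("ref", n_ref), rep("read", n_read))
  op_code <- c(segments$op_code[refcon], segments$op_code)
  seg_idx <- c(which(refcon), seq_len(ns))
  # ref-side copy id per segment (NA for non-reference-consuming segments)
  ref_id_of_seg <- rep(NA_integer_, ns)
  ref_id_of_seg[refcon] <- seq_len(n_ref)
  for (k in seq_len(n)) {
    i <- seg_idx[k]
    feat[k, segments$op_code[i] + 1L] <- segments$length[i] * s
    if (side[k] == "ref") {
      feat[k, 5L] <- (segments$ref_start[i] - anchor) * s
      feat[k, 6L] <- (segments$ref_end[i] - anchor) * s
    } else {
      feat[k, 5L] <- segments$read_start[i] * s
      feat[k, 6L] <- segments$read_end[i] * s
    }
  }
  both <- function(a, b) cbind(from = c(a, b), to = c(b, a))
  e_rr <- if (n_ref >= 2L) both(seq_len(n_ref - 1L), seq_len(n_ref - 1L) + 1L)
          else cbind(from = integer(0), to = integer(0))
  rd <- n_ref + seq_len(n_read)
  e_dd <- if (n_read >= 2L) both(rd[-n_read], rd[-1L])
          else cbind(from = integer(0), to = integer(0))
  # ref-read: each segment's read-side node to its ref-side anchor node
  anchor_ref <- integer(ns)
  last <- NA_integer_
  for (i in seq_len(ns))
    anchor_ref[i] <- last <- if (refcon[i]) ref_id_of_seg[i] else last
  if (anyNA(anchor_ref)) {       # leading insertion/clip: attach forward
    nxt <- NA_integer_
    for (i in rev(seq_len(ns))) {
      if (refcon[i]) nxt <- ref_id_of_seg[i]
      if (is.na(anchor_ref[i])) anchor_ref[i] <- nxt
    }
  }
  has_anchor <- !is.na(anchor_ref)
  e_rx <- if (any(has_anchor))
    both(anchor_ref[has_anchor], rd[has_anchor])
  else cbind(from = integer(0), to = integer(0))
  g <- list(chrom = chrom, anchor = anchor, feat = feat,
            nodes = data.frame(
              node_id = seq_len(n), side = side, op_code = op_code,
              ref_start = segments$ref_start[seg_idx],
              ref_end = segments$ref_end[seg_idx],
              read_start = segments$read_start[seg_idx],
              read_end = segments$read_end[seg_idx],
              stringsAsFactors = FALSE),
            edges = list(ref_ref = e_rr, ref_read = e_rx, read_read = e_dd),
            labels = NULL, qname = qname, scales = scales)
  class(g) <- "read_graph"
  g
}

relation_names <- c("ref_ref", "ref_read", "read_read")

#' Label graph nodes from a truth deletion set
#'
#' A node is positive (label 1) iff it is deletion-typed and its reference
#' interval has reciprocal overlap at least `min_overlap` with some truth
#' deletion; both the ref-side and read-side copies of a deletion segment are
#' labeled. All other nodes are 0.
#'
#' @param graph a `read_graph`.
#' @param truth a `truth_sv` data.frame (sorted).
#' @param min_overlap reciprocal-overlap threshold (overlap divided by the
#'   longer interval).
#' @return the graph with a `labels` integer vector attached.
#' @export
label_nodes <- function(graph, truth, min_overlap = 0.5) {
  n <- nrow(graph$nodes)
  lab <- integer(n)
  tt <- truth[truth$chrom == graph$chrom, , drop = FALSE]
  if (nrow(tt)) {
    del <- which(graph$nodes$op_code == 2L)
    for (k in del) {
      a0 <- graph$nodes$ref_start[k]; a1 <- graph$nodes$ref_end[k]
      ov <- pmin(a1, tt$end) - pmax(a0, tt$start)
      ro <- ov / pmax(a1 - a0, tt$end - tt$start)
      if (any(ro >= min_overlap)) lab[k] <- 1L
    }
  }
  graph$labels <- lab
  graph
}

#' Disjoint union of read graphs
#'
#' Concatenates node features, offsets edge ids, and keeps a per-graph index
#' map so classifier output on the batch equals the concatenation of
#' per-graph outputs.
#'
#' @param graphs non-empty list of `read_graph` objects.
#' @return an object of class `graph_batch`: `feat`, `edges`, `labels`
#'   (NULL if any input is unlabeled), `index` (list of node-id ranges),
#'   `graphs` (the inputs).
#' @export
batch_graphs <- function(graphs) {
  if (!length(graphs)) stop("usage error: empty graph list")
  sizes <- vapply(graphs, function(g) nrow(g$feat), integer(1))
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  feat <- do.call(rbind, lapply(graphs, `[[`, "feat"))
  edges <- lapply(relation_names, function(r) {
    do.call(rbind, lapply(seq_along(graphs), function(i)
      graphs[[i]]$edges[[r]] + offs[i]))
  })
  names(edges) <- relation_names
  labs <- lapply(graphs, `[[`, "labels")
  labels <- if (any(vapply(labs, is.null, logical(1)))) NULL
            else unlist(labs, use.names = FALSE)
  b <- list(feat = feat, edges = edges, labels = labels,
            index = lapply(seq_along(graphs),
                           function(i) offs[i] + seq_len(sizes[i])),
            graphs = graphs)
  class(b) <- "graph_batch"
  b
}

#' Alignments to labeled graphs
#'
#' Convenience wrapper: FLAG-filter records, segment each CIGAR, build one
#' graph per primary alignment, and (optionally) label nodes from truth.
#'
#' @param recs an `alignments` data.frame.
#' @param truth optional `truth_sv` data.frame; when given, nodes are labeled.
#' @param min_svlen minimum indel length kept as a variant segment.
#' @param scales a [graph_scales()].
#' @return list of `read_graph` objects (alignments with no segments are
#'   skipped).
#' @export
graphs_from_alignments <- function(recs, truth = NULL, min_svlen = 50L,
                                   scales = graph_scales()) {
  recs <- filter_records(recs)
  out <- vector("list", nrow(recs))
  kept <- 0L
  for (i in seq_len(nrow(recs))) {
    segs <- segment_ops(recs[i, , drop = FALSE], min_svlen = min_svlen)
    if (!nrow(segs)) next
    g <- build_graph(segs, recs$chrom[i], recs$qname[i], scales)
    if (!is.null(truth)) g <- label_nodes(g, truth)
    kept <- kept + 1L
    out[[kept]] <- g
  }
  out[seq_len(kept)]
}
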