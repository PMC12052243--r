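#' Extract per-node deletion candidates
#'
#' One candidate per deletion-typed ref-side node with hard label 1,
#' carrying the reference interval reconstructed from its source segment.
#' Non-deletion nodes never emit candidates, whatever the classifier says.
#'
#' @param graphs list of `read_graph` objects.
#' @param predictions output of [predict_nodes()] aligned with `graphs`.
#' @return data.frame of class `candidates`: `chrom`, `start`, `end`,
#'   `svlen`, `prob`, `qname`, sorted by (chrom, start).
#' @export
extract_candidates <- function(graphs, predictions) {
  stopifnot(length(graphs) == length(predictions))
  rows <- vector("list", length(graphs))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    pr <- predictions[[i]]
    hit <- which(g$nodes$side == "ref" & g$nodes$op_code == 2L &
                   pr$label == 1L)
    if (!length(hit)) next
    rows[[i]] <- data.frame(
      chrom = g$chrom,
      start = g$nodes$ref_start[hit], end = g$nodes$ref_end[hit],
      svlen = g$nodes$ref_end[hit] - g$nodes$ref_start[hit],
      prob = pr$p1[hit], qname = g$qname,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               svlen = integer(0), prob = numeric(0), qname = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidates", "data.frame")
  out
}

# Deterministic DBSCAN with brute-force neighborhoods and optional point
# weights (a point's neighborhood mass is the sum of neighbor weights,
# itself included). Border points join the first core point that reaches
# them. Returns an integer cluster id per point, 0 = noise.
dbscan_assign <- function(X, eps, min_samples, weights = NULL) {
  n <- nrow(X)
  if (n == 0L) return(integer(0))
  if (is.null(weights)) weights <- rep(1, n)
  D <- as.matrix(stats::dist(X))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  mass <- vapply(nb, function(ix) sum(weights[ix]), numeric(1))
  core <- mass >= min_samples
  cl <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (cl[i] != 0L || !core[i]) next
    cur <- cur + 1L
    queue <- i
    cl[i] <- cur
    while (length(queue)) {
      j <- queue[1L]; queue <- queue[-1L]
      if (!core[j]) next
      for (k in nb[[j]]) {
        if (cl[k] == 0L) {
          cl[k] <- cur
          queue <- c(queue, k)
        }
      }
    }
  }
  cl
}

#' Density-cluster deletion candidates
#'
#' Candidates are grouped by chromosome, then clustered with DBSCAN
#' semantics (a core point has at least `min_samples` neighbors within
#' `eps`, itself included) using the Euclidean distance over the unscaled
#' 3-vector (svlen, start, end).
#'
#' @param cands a `candidates` data.frame sorted by (chrom, start).
#' @param eps neighborhood radius in bp units on (svlen, start, end).
#' @param min_samples minimum neighborhood size of a core point.
#' @return list with `clusters` (list of `candidates` subsets, one per
#'   cluster) and `noise` (a `candidates` data.frame).
#' @export
cluster_candidates <- function(cands, eps = 500, min_samples = 2L) {
  if (eps <= 0) stop("configuration error: eps must be positive")
  clusters <- list()
  noise <- cands[0, , drop = FALSE]
  for (ch in unique(cands$chrom)) {
    cc <- cands[cands$chrom == ch, , drop = FALSE]
    cl <- dbscan_assign(cbind(cc$svlen, cc$start, cc$end), eps, min_samples)
    for (k in seq_len(max(cl, 0L)))
      clusters[[length(clusters) + 1L]] <- cc[cl == k, , drop = FALSE]
    noise <- rbind(noise, cc[cl == 0L, , drop = FALSE])
  }
  rownames(noise) <- NULL
  list(clusters = clusters, noise = noise)
}

new_fragments <- function(chrom, start, end, members) {
  f <- data.frame(chrom = chrom, start = start, end = end,
                  svlen = end - start, stringsAsFactors = FALSE)
  f$members <- members
  class(f) <- c("fragments", "data.frame")
  f
}

#' Merge unmatched candidate fragments
#'
#' Scans adjacent fragment pairs within each chromosome (sorted by start)
#' and merges them when the gap condition `start2 - end1 < alpha` and/or the
#' length-ratio condition `min(svlen1, svlen2) / max(svlen1, svlen2) >
#' ratio` holds (`mode = "any"`: either suffices; `mode = "all"`: both are
#' required). Merging spans the hull `[min(start), max(end))` and is applied
#' transitively left-to-right until a fixpoint; member candidates are
#' carried along.
#'
#' @param noise_cands a `candidates` data.frame (the clustering noise),
#'   sorted by (chrom, start).
#' @param alpha maximum start-to-end gap (bp) for the distance condition.
#' @param ratio length-ratio threshold in (0,1).
#' @param mode `"any"` (disjunction, default) or `"all"` (conjunction).
#' @return a `fragments` data.frame (`chrom`, `start`, `end`, `svlen`, and a
#'   `members` list-column of constituent candidates).
#' @export
merge_fragments <- function(noise_cands, alpha = 3000, ratio = 0.7,
                            mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (alpha <= 0) stop("alpha must be positive")
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)")
  if (nrow(noise_cands) > 1L) {
    o <- order(noise_cands$chrom, noise_cands$start, noise_cands$end)
    if (!identical(o, seq_len(nrow(noise_cands))))
      stop("invariant error: noise candidates must be sorted by (chrom, start)")
  }
  out <- list()
  for (ch in unique(noise_cands$chrom)) {
    cc <- noise_cands[noise_cands$chrom == ch, , drop = FALSE]
    frs <- lapply(seq_len(nrow(cc)), function(i)
      list(start = cc$start[i], end = cc$end[i],
           members = cc[i, , drop = FALSE]))
    repeat {
      merged_any <- FALSE
      acc <- list(frs[[1L]])
      for (f in frs[-1L]) {
        cur <- acc[[length(acc)]]
        l1 <- cur$end - cur$start; l2 <- f$end - f$start
        cond_gap <- (f$start - cur$end) < alpha
        cond_ratio <- (min(l1, l2) / max(l1, l2)) > ratio
        hit <- if (mode == "any") cond_gap || cond_ratio
               else cond_gap && cond_ratio
        if (hit) {
          cur$start <- min(cur$start, f$start)
          cur$end <- max(cur$end, f$end)
          cur$members <- rbind(cur$members, f$members)
          acc[[length(acc)]] <- cur
          merged_any <- TRUE
        } else acc[[length(acc) + 1L]] <- f
      }
      frs <- acc
      if (!merged_any) break
    }
    out[[ch]] <- new_fragments(
      chrom = ch,
      start = vapply(frs, `[[`, numeric(1), "start"),
      end = vapply(frs, `[[`, numeric(1), "end"),
      members = lapply(frs, `[[`, "members"))
  }
  if (!length(out))
    return(new_fragments(character(0), integer(0), integer(0), list()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("fragments", "data.frame")
  res
}

consensus_call <- function(chrom, starts, ends, members) {
  start <- as.integer(round(stats::median(starts)))
  end <- as.integer(round(stats::median(ends)))
  data.frame(chrom = chrom, start = start, end = end, svlen = end - start,
             support = length(unique(members$qname)),
             score = mean(members$prob), stringsAsFactors = FALSE)
}

#' Consolidate clusters and merged fragments into final calls
#'
#' First-pass clusters become calls directly (member-wise median start/end).
#' Merged fragments undergo secondary clustering with the same density
#' procedure, each fragment weighted by its member count (so a single merged
#' fragment assembled from `min_samples` or more candidates survives on its
#' own); surviving secondary clusters become calls whose members are the
#' union of their fragments' candidates. Calls with read support below
#' `min_support` are dropped.
#'
#' @param clusters list of candidate clusters from [cluster_candidates()].
#' @param merged a `fragments` data.frame from [merge_fragments()].
#' @param min_support minimum number of distinct supporting reads.
#' @param eps,min_samples secondary-clustering parameters (same semantics as
#'   [cluster_candidates()]).
#' @return data.frame of class `sv_calls`: `chrom`, `start`, `end`, `svlen`,
#'   `support`, `score`, sorted by (chrom, start).
#' @export
finalize_calls <- function(clusters, merged, min_support = 2L,
                           eps = 500, min_samples = 2L) {
  calls <- lapply(clusters, function(cc)
    consensus_call(cc$chrom[1L], cc$start, cc$end, cc))
  if (!is.null(merged) && nrow(merged)) {
    for (ch in unique(merged$chrom)) {
      mm <- merged[merged$chrom == ch, , drop = FALSE]
      w <- vapply(mm$members, nrow, integer(1))
      cl <- dbscan_assign(cbind(mm$svlen, mm$start, mm$end), eps,
                          min_samples, weights = w)
      for (k in seq_len(max(cl, 0L))) {
        ix <- which(cl == k)
        calls[[length(calls) + 1L]] <- consensus_call(
          ch, mm$start[ix], mm$end[ix], do.call(rbind, mm$members[ix]))
      }
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               svlen = integer(0), support = integer(0), score = numeric(0),
               stringsAsFactors = FALSE)
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sv_calls", "data.frame")
  out
}

#' Candidates to consensus calls
#'
#' The full consolidation stage: per-chromosome density clustering, merging
#' of unmatched fragments, secondary clustering, support filtering.
#'
#' @param cands a `candidates` data.frame.
#' @param eps,min_samples density-clustering parameters.
#' @param alpha,ratio,mode fragment-merging parameters
#'   (see [merge_fragments()]).
#' @param min_support minimum distinct-read support of a call.
#' @return an `sv_calls` data.frame.
#' @export
consolidate_candidates <- function(cands, eps = 500, min_samples = 2L,
                                   alpha = 3000, ratio = 0.7, mode = "any",
                                   min_support = 2L) {
  cl <- cluster_candidates(cands, eps = eps, min_samples = min_samples)
  merged <- merge_fragments(cl$noise, alpha = alpha, ratio = ratio,
                            mode = mode)
  finalize_calls(cl$clusters, merged, min_support = min_support,
                 eps = eps, min_samples = min_samples)
}
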