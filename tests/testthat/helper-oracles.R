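# Independent oracles and small fixture builders used across the suite.

# one alignment record as a 1-row alignments data.frame
make_record <- function(cigar, pos = 1L, chrom = "chr1", qname = "r1",
                        flag = 0L, mapq = 60L) {
  data.frame(qname = qname, flag = flag, chrom = chrom, pos = pos,
             mapq = mapq, cigar = cigar, stringsAsFactors = FALSE)
}

make_truth <- function(chrom, start, end) {
  t0 <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(end),
                   svlen = as.integer(end - start), stringsAsFactors = FALSE)
  t0 <- t0[order(t0$chrom, t0$start), , drop = FALSE]
  class(t0) <- c("truth_sv", "data.frame")
  t0
}

make_cands <- function(chrom, start, end, prob = 0.9,
                       qname = sprintf("r%d", seq_along(start))) {
  d <- data.frame(chrom = chrom, start = as.integer(start),
                  end = as.integer(end),
                  svlen = as.integer(end - start), prob = prob,
                  qname = qname, stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("candidates", "data.frame")
  d
}

# brute-force per-node evaluation of the relational convolution layer
rgcn_brute <- function(H, edges_by_relation, lp) {
  n <- nrow(H)
  out <- matrix(0, n, ncol(lp$W0))
  for (i in seq_len(n)) {
    acc <- as.numeric(H[i, , drop = FALSE] %*% lp$W0)
    if (!is.null(lp$b)) acc <- acc + lp$b
    for (r in names(edges_by_relation)) {
      e <- edges_by_relation[[r]]
      js <- e[e[, 2L] == i, 1L]
      if (!length(js)) next
      msgs <- sapply(js, function(j)
        as.numeric(H[j, , drop = FALSE] %*% lp$W[[r]]))
      acc <- acc + rowMeans(matrix(msgs, ncol = length(js)))
    }
    out[i, ] <- pmax(acc, 0)
  }
  out
}

# random multi-relation graph on n nodes (features + 3 random edge sets)
random_graph_edges <- function(n, d_in, p_edge = 0.25) {
  mk <- function() {
    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    pick <- pairs[stats::runif(nrow(pairs)) < p_edge, , drop = FALSE]
    cbind(from = c(pick[, 1], pick[, 2]), to = c(pick[, 2], pick[, 1]))
  }
  list(H = matrix(stats::rnorm(n * d_in), n, d_in),
       edges = list(ref_ref = mk(), ref_read = mk(), read_read = mk()))
}

random_layer <- function(d_in, d_out, bias = TRUE) {
  list(W = list(ref_ref = matrix(stats::rnorm(d_in * d_out), d_in, d_out),
                ref_read = matrix(stats::rnorm(d_in * d_out), d_in, d_out),
                read_read = matrix(stats::rnorm(d_in * d_out), d_in, d_out)),
       W0 = matrix(stats::rnorm(d_in * d_out), d_in, d_out),
       b = if (bias) stats::rnorm(d_out) else NULL)
}

# Cox-de Boor recursion, independent of splines::splineDesign
deboor_basis <- function(x, knots, degree, m) {
  B <- function(mm, k) {
    if (k == 0)
      return(as.numeric(x >= knots[mm] & x < knots[mm + 1L]))
    a <- 0
    if (knots[mm + k] > knots[mm])
      a <- (x - knots[mm]) / (knots[mm + k] - knots[mm]) * B(mm, k - 1L)
    b <- 0
    if (knots[mm + k + 1L] > knots[mm + 1L])
      b <- (knots[mm + k + 1L] - x) / (knots[mm + k + 1L] - knots[mm + 1L]) *
        B(mm + 1L, k - 1L)
    a + b
  }
  B(m, degree)
}

# brute-force DBSCAN partition (unweighted): returns list(sets, noise_idx)
dbscan_brute <- function(X, eps, min_samples) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  core <- vapply(seq_len(n), function(i) sum(D[i, ] <= eps) >= min_samples,
                 logical(1))
  # connected components over core points
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in which(core)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nxt <- integer(0)
      for (j in frontier) {
        reach <- which(core & D[j, ] <= eps & is.na(comp))
        comp[reach] <- cur
        nxt <- c(nxt, reach)
      }
      frontier <- nxt
    }
  }
  for (i in which(!core)) {
    near_core <- which(core & D[i, ] <= eps)
    if (length(near_core)) comp[i] <- comp[near_core[1L]]
  }
  sets <- lapply(seq_len(max(cur, 0L)), function(k) sort(which(comp == k)))
  list(sets = sets, noise = sort(which(is.na(comp))))
}

as_partition <- function(assign) {
  ks <- setdiff(sort(unique(assign)), 0L)
  list(sets = lapply(ks, function(k) sort(which(assign == k))),
       noise = sort(which(assign == 0L)))
}

same_partition <- function(a, b) {
  norm <- function(p)
    lapply(p$sets[order(vapply(p$sets, min, numeric(1)))], as.integer)
  identical(norm(a), norm(b)) &&
    identical(as.integer(a$noise), as.integer(b$noise))
}

# tiny labeled graph set with clearly separable classes, for training tests
toy_labeled_graphs <- function(n = 40, seed = 11) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    del_len <- sample(60:4000, 1L)
    pos <- sample(1000:5000, 1L)
    m1 <- sample(500:3000, 1L); m2 <- sample(500:3000, 1L)
    rec <- make_record(sprintf("%dM%dD%dM", m1, del_len, m2), pos = pos,
                       qname = sprintf("toy%03d", i))
    segs <- segment_ops(rec)
    g <- build_graph(segs, "chr1", rec$qname)
    truth <- make_truth("chr1", pos - 1L + m1, pos - 1L + m1 + del_len)
    label_nodes(g, truth)
  })
}
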