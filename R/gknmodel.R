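#' Model configuration
#'
#' Hyperparameters of the node classifier: two relational graph convolution
#' layers (widths `6 -> d1 -> d2`, one weight matrix per relation plus a
#' self-weight, ReLU activations, in-degree normalization), followed by a
#' classification head. The default head (`"kan_fc"`) is a learnable-spline
#' activation layer (KAN: per-connection SiLU base weight, spline scale, and
#' B-spline coefficients on a fixed uniform grid) followed by a fully
#' connected layer to the two classes; alternative heads `"fc"`, `"kan"` and
#' `"kan2"` reproduce the ablation variants (plain FC, single KAN layer to
#' the classes, two stacked KAN layers).
#'
#' With the defaults (d1 = 8, d2 = 4, grid = 5, degree = 3) the trainable
#' budget is 200 + 132 + 160 + 10 = 502 scalars, i.e. about 5.1e-4 M
#' parameters.
#'
#' @param d1,d2 hidden widths of the two graph convolution layers.
#' @param grid number of B-spline grid intervals (G).
#' @param degree B-spline degree (k); the basis has `grid + degree`
#'   functions.
#' @param kan_range numeric length-2 input range of the spline grid; KAN
#'   inputs are clamped to it (never an error).
#' @param head one of `"kan_fc"`, `"fc"`, `"kan"`, `"kan2"`.
#' @param length_scale feature scale the model expects (must match the
#'   graphs' [graph_scales()]).
#' @param weight positive-class weight in (0,1); class weights are
#'   `[1 - weight, weight]`.
#' @param lambda L2 regularization strength on all trainable scalars.
#' @param lr,epochs,batch_size Adam learning rate, training epochs, and
#'   graphs per minibatch.
#' @param seed default training seed.
#' @return a `model_config` list.
#' @export
model_config <- function(d1 = 8L, d2 = 4L, grid = 5L, degree = 3L,
                         kan_range = c(-2, 2), head = "kan_fc",
                         length_scale = 1 / 1000,
                         weight = 0.9, lambda = 1e-4,
                         lr = 1e-3, epochs = 50L, batch_size = 32L,
                         seed = 42L) {
  head <- match.arg(head, c("kan_fc", "fc", "kan", "kan2"))
  stopifnot(d1 >= 1L, d2 >= 1L, grid >= 1L, degree >= 1L,
            length(kan_range) == 2L, kan_range[1] < kan_range[2],
            weight > 0, weight < 1, lambda >= 0, lr > 0)
  structure(list(d_in = 6L, d1 = as.integer(d1), d2 = as.integer(d2),
                 grid = as.integer(grid), degree = as.integer(degree),
                 kan_range = as.numeric(kan_range), head = head,
                 length_scale = length_scale, weight = weight,
                 lambda = lambda, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "model_config")
}

silu <- function(x) x * stats::plogis(x)
silu_grad <- function(x) {
  s <- stats::plogis(x)
  s * (1 + x * (1 - s))
}

kan_knots <- function(cfg) {
  h <- (cfg$kan_range[2] - cfg$kan_range[1]) / cfg$grid
  seq(cfg$kan_range[1] - cfg$degree * h,
      cfg$kan_range[2] + cfg$degree * h, by = h)
}

kan_n_basis <- function(cfg) cfg$grid + cfg$degree

# B-spline basis (or its first derivative) evaluated at clamped inputs
kan_basis <- function(x, cfg, deriv = 0L) {
  splines::splineDesign(kan_knots(cfg), x, ord = cfg$degree + 1L,
                        derivs = rep(deriv, length(x)))
}

new_kan_params <- function(d_in, d_out, cfg) {
  nb <- kan_n_basis(cfg)
  list(base = matrix(stats::rnorm(d_out * d_in, sd = sqrt(1 / d_in)),
                     d_out, d_in),
       scale = matrix(stats::rnorm(d_out * d_in, sd = sqrt(1 / d_in)),
                      d_out, d_in),
       coef = array(stats::rnorm(d_out * d_in * nb, sd = 0.1),
                    dim = c(d_out, d_in, nb)))
}

new_conv_params <- function(d_in, d_out) {
  w <- function() matrix(stats::rnorm(d_in * d_out, sd = sqrt(1 / d_in)),
                         d_in, d_out)
  list(W = list(ref_ref = w(), ref_read = w(), read_read = w()),
       W0 = w(), b = numeric(d_out))
}

#' Initialize model parameters
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for the random initialization.
#' @return an object of class `gkn_params` holding `cfg` and the nested
#'   trainable arrays under `$layers`.
#' @export
init_params <- function(cfg = model_config(), seed = cfg$seed) {
  set.seed(seed)
  layers <- list(conv1 = new_conv_params(cfg$d_in, cfg$d1),
                 conv2 = new_conv_params(cfg$d1, cfg$d2))
  layers$head <- switch(cfg$head,
    fc = list(fc = list(W = matrix(stats::rnorm(cfg$d2 * 2L, sd = 0.5),
                                   cfg$d2, 2L), b = numeric(2L))),
    kan_fc = list(kan = new_kan_params(cfg$d2, cfg$d2, cfg),
                  fc = list(W = matrix(stats::rnorm(cfg$d2 * 2L, sd = 0.5),
                                       cfg$d2, 2L), b = numeric(2L))),
    kan = list(kan = new_kan_params(cfg$d2, 2L, cfg)),
    kan2 = list(kan = new_kan_params(cfg$d2, cfg$d2, cfg),
                kan_b = new_kan_params(cfg$d2, 2L, cfg)))
  structure(list(cfg = cfg, layers = layers), class = "gkn_params")
}

flatten_params <- function(layers) unlist(layers, use.names = FALSE)

unflatten_params <- function(vec, skeleton) {
  i <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    out <- vec[i + seq_len(n)]
    i <<- i + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  out <- fill(skeleton)
  stopifnot(i == length(vec))
  out
}

#' Count trainable parameters
#'
#' @param params a `gkn_params` object.
#' @return exact number of trainable scalars.
#' @export
count_params <- function(params) length(flatten_params(params$layers))

# row-normalized sparse aggregation matrix per relation:
# A[i, j] = 1 / indeg_r(i) for each stored edge j -> i
build_adjacency <- function(edges_by_relation, n) {
  lapply(edges_by_relation, function(e) {
    if (is.null(e) || nrow(e) == 0L) return(NULL)
    indeg <- tabulate(e[, 2L], nbins = n)
    Matrix::sparseMatrix(i = e[, 2L], j = e[, 1L],
                         x = 1 / indeg[e[, 2L]], dims = c(n, n))
  })
}

rgcn_affine <- function(H, A_list, lp) {
  Z <- H %*% lp$W0
  if (!is.null(lp$b)) Z <- sweep(Z, 2L, lp$b, `+`)
  for (r in names(A_list)) {
    A <- A_list[[r]]
    if (is.null(A)) next
    Z <- Z + A %*% (H %*% lp$W[[r]])
  }
  as.matrix(Z)
}

#' One relational graph convolution layer
#'
#' Computes `H'_i = ReLU( sum_r sum_{j in N_i^r} W_r H_j / C_{i,r}
#' + W_0 H_i + b )` with `C_{i,r}` the in-degree of node `i` under relation
#' `r`; a relation term is skipped for nodes with no neighbors under it.
#'
#' @param H node feature matrix (N x d_in).
#' @param edges_by_relation named list of 2-column (from, to) edge matrices.
#' @param layer_params list with `W` (named list of d_in x d_out matrices,
#'   one per relation), `W0`, and optional bias `b`.
#' @return the activated N x d_out matrix.
#' @export
rgcn_forward <- function(H, edges_by_relation, layer_params) {
  n <- nrow(H)
  bad <- vapply(edges_by_relation, function(e)
    nrow(e) > 0L && (max(e) > n || min(e) < 1L), logical(1))
  if (any(bad)) stop("index error: edge endpoint out of range")
  for (r in names(edges_by_relation))
    if (nrow(edges_by_relation[[r]]) &&
        ncol(H) != nrow(layer_params$W[[r]]))
      stop("shape error: feature width does not match relation weights")
  if (ncol(H) != nrow(layer_params$W0))
    stop("shape error: feature width does not match self-weight")
  A <- build_adjacency(edges_by_relation, n)
  pmax(rgcn_affine(H, A, layer_params), 0)
}

kan_forward_cached <- function(X, kp, cfg) {
  lo <- cfg$kan_range[1]; hi <- cfg$kan_range[2]
  mask <- X >= lo & X <= hi
  Xc <- pmin(pmax(X, lo), hi)
  n <- nrow(Xc); d_in <- ncol(Xc); d_out <- nrow(kp$base)
  S <- silu(Xc)
  Y <- matrix(0, n, d_out)
  B <- vector("list", d_in); M <- vector("list", d_in)
  for (p in seq_len(d_in)) {
    B[[p]] <- kan_basis(Xc[, p], cfg)
    M[[p]] <- B[[p]] %*% t(matrix(kp$coef[, p, ], d_out))
    Y <- Y + outer(S[, p], kp$base[, p]) +
      M[[p]] * matrix(kp$scale[, p], n, d_out, byrow = TRUE)
  }
  list(Y = Y, X = Xc, mask = mask, S = S, B = B, M = M)
}

kan_backward <- function(dY, cache, kp, cfg) {
  Xc <- cache$X
  n <- nrow(Xc); d_in <- ncol(Xc); d_out <- nrow(kp$base)
  nb <- kan_n_basis(cfg)
  Sd <- silu_grad(Xc)
  g <- list(base = t(dY) %*% cache$S,
            scale = matrix(0, d_out, d_in),
            coef = array(0, dim = c(d_out, d_in, nb)))
  dX <- matrix(0, n, d_in)
  for (p in seq_len(d_in)) {
    g$scale[, p] <- colSums(dY * cache$M[[p]])
    g$coef[, p, ] <- (t(dY) %*% cache$B[[p]]) * kp$scale[, p]
    Bd <- kan_basis(Xc[, p], cfg, deriv = 1L)
    Md <- Bd %*% t(matrix(kp$coef[, p, ], d_out))
    term_base <- as.numeric(dY %*% kp$base[, p]) * Sd[, p]
    term_spl <- rowSums(dY * (Md * matrix(kp$scale[, p], n, d_out,
                                          byrow = TRUE)))
    dX[, p] <- (term_base + term_spl) * cache$mask[, p]
  }
  list(grad = g, dX = dX)
}

#' Learnable-spline (KAN) layer forward pass
#'
#' Each output is a sum of learnable univariate functions of the inputs:
#' `phi_qp(x) = base_qp * silu(x) + scale_qp * sum_m c_qpm B_m(x)`, with
#' `B_m` a B-spline basis on a fixed uniform grid. Inputs outside the grid
#' range are clamped (documented behavior, never an error).
#'
#' @param X input matrix (N x d_in).
#' @param kan_params list with `base` (d_out x d_in), `scale` (d_out x
#'   d_in), `coef` (d_out x d_in x (grid + degree)).
#' @param cfg a [model_config()] (supplies grid geometry).
#' @return the N x d_out output matrix.
#' @export
kan_forward <- function(X, kan_params, cfg = model_config()) {
  kan_forward_cached(X, kan_params, cfg)$Y
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

forward_full <- function(feat, A, layers, cfg, keep = FALSE) {
  Z1 <- rgcn_affine(feat, A, layers$conv1); H1 <- pmax(Z1, 0)
  A1H <- lapply(A, function(a) if (is.null(a)) NULL else as.matrix(a %*% feat))
  Z2 <- rgcn_affine(H1, A, layers$conv2); H2 <- pmax(Z2, 0)
  A2H <- lapply(A, function(a) if (is.null(a)) NULL else as.matrix(a %*% H1))
  hd <- layers$head
  kc1 <- kc2 <- NULL
  if (cfg$head == "fc") {
    X_fc <- H2
    logits <- sweep(H2 %*% hd$fc$W, 2L, hd$fc$b, `+`)
  } else if (cfg$head == "kan_fc") {
    kc1 <- kan_forward_cached(H2, hd$kan, cfg)
    X_fc <- kc1$Y
    logits <- sweep(X_fc %*% hd$fc$W, 2L, hd$fc$b, `+`)
  } else if (cfg$head == "kan") {
    kc1 <- kan_forward_cached(H2, hd$kan, cfg)
    X_fc <- NULL
    logits <- kc1$Y
  } else {
    kc1 <- kan_forward_cached(H2, hd$kan, cfg)
    kc2 <- kan_forward_cached(kc1$Y, hd$kan_b, cfg)
    X_fc <- NULL
    logits <- kc2$Y
  }
  probs <- softmax_rows(logits)
  out <- list(probs = probs, logits = logits)
  if (keep)
    out$cache <- list(feat = feat, A = A, Z1 = Z1, H1 = H1, A1H = A1H,
                      Z2 = Z2, H2 = H2, A2H = A2H, kc1 = kc1, kc2 = kc2,
                      X_fc = X_fc)
  out
}

#' Classifier forward pass over a graph or batch
#'
#' Pipeline: conv1 (6 -> d1, ReLU) -> conv2 (d1 -> d2, ReLU) -> head ->
#' softmax. Deterministic given the parameters.
#'
#' @param x a `read_graph` or `graph_batch`.
#' @param params a `gkn_params` object.
#' @return data.frame with per-node `p0`, `p1` and hard `label`
#'   (argmax; exact ties resolve to class 0).
#' @export
model_forward <- function(x, params) {
  if (inherits(x, "read_graph")) x <- batch_graphs(list(x))
  if (ncol(x$feat) != params$cfg$d_in)
    stop("shape error: node features must be ", params$cfg$d_in, "-dimensional")
  A <- build_adjacency(x$edges, nrow(x$feat))
  fw <- forward_full(x$feat, A, params$layers, params$cfg)
  data.frame(p0 = fw$probs[, 1L], p1 = fw$probs[, 2L],
             label = as.integer(fw$probs[, 2L] > fw$probs[, 1L]))
}

#' Weighted cross-entropy loss with L2 penalty
#'
#' `Loss = -(1/N) sum_i w_{y_i} log(p_{i,y_i}) + (lambda/2) * ||W||_2^2`
#' where the class weights are `[1 - weight, weight]` and `||W||_2^2` is the
#' squared L2 norm over all trainable scalars. Probabilities are clamped at
#' 1e-12 before the log.
#'
#' @param probs N x 2 matrix of class probabilities (or a data.frame with
#'   `p0`, `p1`).
#' @param labels integer vector of true classes (0/1), one per node.
#' @param params optional `gkn_params`; supplies `weight`/`lambda` defaults
#'   and the weights entering the L2 term.
#' @param weight positive-class weight in (0,1).
#' @param lambda L2 strength.
#' @return scalar loss.
#' @export
compute_loss <- function(probs, labels, params = NULL,
                         weight = if (is.null(params)) 0.5 else
                           params$cfg$weight,
                         lambda = if (is.null(params)) 0 else
                           params$cfg$lambda) {
  if (is.data.frame(probs)) probs <- cbind(probs$p0, probs$p1)
  n <- nrow(probs)
  stopifnot(length(labels) == n)
  p_true <- probs[cbind(seq_len(n), labels + 1L)]
  w <- c(1 - weight, weight)[labels + 1L]
  ce <- -mean(w * log(pmax(p_true, 1e-12)))
  reg <- 0
  if (lambda > 0) {
    if (is.null(params))
      stop("lambda > 0 requires params to supply the weights")
    v <- flatten_params(params$layers)
    reg <- lambda / 2 * sum(v^2)
  }
  ce + reg
}

# full analytic gradient of compute_loss wrt all trainable scalars
backward_full <- function(fw, labels, layers, cfg) {
  n <- nrow(fw$probs)
  onehot <- matrix(0, n, 2L)
  onehot[cbind(seq_len(n), labels + 1L)] <- 1
  wvec <- c(1 - cfg$weight, cfg$weight)[labels + 1L]
  dlogits <- (fw$probs - onehot) * wvec / n
  cache <- fw$cache
  g_head <- list()
  if (cfg$head == "fc") {
    g_head$fc <- list(W = t(cache$H2) %*% dlogits, b = colSums(dlogits))
    dH2 <- dlogits %*% t(layers$head$fc$W)
  } else if (cfg$head == "kan_fc") {
    g_head$fc <- list(W = t(cache$X_fc) %*% dlogits, b = colSums(dlogits))
    dK <- dlogits %*% t(layers$head$fc$W)
    kb <- kan_backward(dK, cache$kc1, layers$head$kan, cfg)
    g_head$kan <- kb$grad
    dH2 <- kb$dX
    g_head <- g_head[c("kan", "fc")]
  } else if (cfg$head == "kan") {
    kb <- kan_backward(dlogits, cache$kc1, layers$head$kan, cfg)
    g_head$kan <- kb$grad
    dH2 <- kb$dX
  } else {
    kb2 <- kan_backward(dlogits, cache$kc2, layers$head$kan_b, cfg)
    kb1 <- kan_backward(kb2$dX, cache$kc1, layers$head$kan, cfg)
    g_head <- list(kan = kb1$grad, kan_b = kb2$grad)
    dH2 <- kb1$dX
  }
  bk_conv <- function(dH, Zpre, H_in, AH, A, lp) {
    dZ <- dH * (Zpre > 0)
    gW <- lapply(names(lp$W), function(r) {
      if (is.null(A[[r]])) matrix(0, nrow(lp$W[[r]]), ncol(lp$W[[r]]))
      else t(AH[[r]]) %*% dZ
    })
    names(gW) <- names(lp$W)
    dH_in <- dZ %*% t(lp$W0)
    for (r in names(lp$W))
      if (!is.null(A[[r]]))
        dH_in <- dH_in + as.matrix(Matrix::t(A[[r]]) %*% (dZ %*% t(lp$W[[r]])))
    list(grad = list(W = gW, W0 = t(H_in) %*% dZ, b = colSums(dZ)),
         dH_in = dH_in)
  }
  b2 <- bk_conv(dH2, cache$Z2, cache$H1, cache$A2H, cache$A, layers$conv2)
  b1 <- bk_conv(b2$dH_in, cache$Z1, cache$feat, cache$A1H, cache$A,
                layers$conv1)
  list(conv1 = b1$grad, conv2 = b2$grad, head = g_head)
}

loss_and_grad <- function(batch, A, layers, cfg) {
  fw <- forward_full(batch$feat, A, layers, cfg, keep = TRUE)
  loss <- {
    n <- nrow(fw$probs)
    p_true <- fw$probs[cbind(seq_len(n), batch$labels + 1L)]
    w <- c(1 - cfg$weight, cfg$weight)[batch$labels + 1L]
    -mean(w * log(pmax(p_true, 1e-12)))
  }
  g <- backward_full(fw, batch$labels, layers, cfg)
  gv <- flatten_params(g)
  pv <- flatten_params(layers)
  if (cfg$lambda > 0) {
    gv <- gv + cfg$lambda * pv
    loss <- loss + cfg$lambda / 2 * sum(pv^2)
  }
  list(loss = loss, grad_vec = gv)
}

#' Train the node classifier
#'
#' Adam on minibatches of whole graphs, minimizing the weighted
#' cross-entropy with L2 penalty. Fully deterministic given `seed`.
#'
#' @param graphs list of labeled `read_graph` objects (see [label_nodes()]).
#' @param cfg a [model_config()].
#' @param seed training seed (initialization and shuffling).
#' @param verbose print per-epoch loss.
#' @return a `gkn_params` object with attribute `history` (mean epoch loss).
#' @export
train_model <- function(graphs, cfg = model_config(), seed = cfg$seed,
                        verbose = FALSE) {
  if (!length(graphs)) stop("no training graphs")
  labs <- unlist(lapply(graphs, `[[`, "labels"))
  if (is.null(labs)) stop("graphs must be labeled (label_nodes)")
  if (length(unique(labs)) < 2L)
    warning("training data contain a single class; proceeding anyway")
  params <- init_params(cfg, seed = seed)
  skel <- params$layers
  ord <- sample.int(length(graphs))  # draws after init_params' set.seed
  nb <- max(1L, ceiling(length(graphs) / cfg$batch_size))
  chunks <- split(ord, rep(seq_len(nb), each = cfg$batch_size,
                           length.out = length(ord)))
  batches <- lapply(chunks, function(ix) {
    b <- batch_graphs(graphs[ix])
    list(feat = b$feat, labels = b$labels,
         A = build_adjacency(b$edges, nrow(b$feat)))
  })
  pv <- flatten_params(params$layers)
  m <- v <- numeric(length(pv))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0L
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    losses <- numeric(length(batches))
    for (bi in sample.int(length(batches))) {
      lay <- unflatten_params(pv, skel)
      lg <- loss_and_grad(batches[[bi]], batches[[bi]]$A, lay, cfg)
      losses[bi] <- lg$loss
      t <- t + 1L
      m <- b1 * m + (1 - b1) * lg$grad_vec
      v <- b2 * v + (1 - b2) * lg$grad_vec^2
      mhat <- m / (1 - b1^t)
      vhat <- v / (1 - b2^t)
      pv <- pv - cfg$lr * mhat / (sqrt(vhat) + eps)
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %3d  loss %.6f", ep, history[ep]))
  }
  params$layers <- unflatten_params(pv, skel)
  attr(params, "history") <- history
  params
}

#' Predict node classes for a list of graphs
#'
#' @param graphs list of `read_graph` objects.
#' @param params trained `gkn_params` (its `length_scale` must match the
#'   graphs').
#' @return list of per-graph data.frames (`p0`, `p1`, `label`), aligned with
#'   `graphs`.
#' @export
predict_nodes <- function(graphs, params) {
  if (!length(graphs)) return(list())
  sc <- vapply(graphs, function(g) g$scales$length_scale, numeric(1))
  if (any(abs(sc - params$cfg$length_scale) > 1e-12))
    stop("configuration error: checkpoint length_scale (",
         params$cfg$length_scale, ") does not match graph scales")
  b <- batch_graphs(graphs)
  pred <- model_forward(b, params)
  lapply(b$index, function(ix) {
    out <- pred[ix, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing JSON: configuration (including
#' `length_scale` and seed) plus every trainable array with its dimensions,
#' at full double precision.
#'
#' @param params a `gkn_params` object.
#' @param path checkpoint path (`.json`).
#' @return `path` (save) or the restored `gkn_params` (load).
#' @export
save_checkpoint <- function(params, path) {
  enc <- function(x) {
    if (is.list(x)) return(lapply(x, enc))
    list(dim = if (is.null(dim(x))) length(x) else dim(x),
         data = as.numeric(x))
  }
  obj <- list(format = "svdelnet-checkpoint-1",
              cfg = unclass(params$cfg),
              layers = enc(params$layers))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$cfg
  cfg$kan_range <- as.numeric(cfg$kan_range)
  for (f in c("d_in", "d1", "d2", "grid", "degree", "epochs", "batch_size",
              "seed"))
    cfg[[f]] <- as.integer(cfg[[f]])
  class(cfg) <- "model_config"
  dec <- function(x) {
    if (is.list(x) && !identical(sort(names(x)), c("data", "dim")))
      return(lapply(x, dec))
    out <- as.numeric(x$data)
    if (length(x$dim) > 1L) dim(out) <- as.integer(x$dim)
    out
  }
  structure(list(cfg = cfg, layers = dec(obj$layers)), class = "gkn_params")
}
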