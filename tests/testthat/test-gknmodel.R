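no_edges <- function() list(ref_ref = cbind(from = integer(0), to = integer(0)),
                            ref_read = cbind(from = integer(0), to = integer(0)),
                            read_read = cbind(from = integer(0), to = integer(0)))

test_that("graph convolution reduces to the self-term without edges", {
  H <- matrix(abs(rnorm(12)), 4, 3)
  lp <- list(W = list(ref_ref = diag(3), ref_read = diag(3),
                      read_read = diag(3)),
             W0 = diag(3), b = NULL)
  expect_equal(rgcn_forward(H, no_edges(), lp), H)
  lp0 <- lapply(lp, function(x) if (is.list(x)) lapply(x, `*`, 0) else
    if (is.null(x)) NULL else x * 0)
  expect_equal(rgcn_forward(H, no_edges(), lp0), H * 0)
})

test_that("graph convolution matches the hand-evaluated 3-node chain", {
  H <- matrix(c(1, 2, 3), 3, 1)
  e <- no_edges()
  e$ref_ref <- cbind(from = c(1L, 2L, 2L, 3L), to = c(2L, 1L, 3L, 2L))
  lp <- list(W = list(ref_ref = matrix(1), ref_read = matrix(1),
                      read_read = matrix(1)),
             W0 = matrix(1), b = NULL)
  expect_equal(as.numeric(rgcn_forward(H, e, lp)), c(3, 4, 5))
})

test_that("graph convolution matches a brute-force per-node loop on random graphs", {
  set.seed(21)
  for (rep in 1:200) {
    n <- sample(2:20, 1)
    d_in <- sample(2:5, 1); d_out <- sample(1:4, 1)
    rg <- random_graph_edges(n, d_in)
    lp <- random_layer(d_in, d_out, bias = rep %% 2 == 0)
    got <- rgcn_forward(rg$H, rg$edges, lp)
    want <- rgcn_brute(rg$H, rg$edges, lp)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("graph convolution rejects shape and index violations", {
  H <- matrix(rnorm(8), 4, 2)
  lp <- random_layer(3, 2)  # wrong input width
  expect_error(rgcn_forward(H, no_edges(), lp), "shape error")
  e <- no_edges(); e$ref_ref <- cbind(from = 1L, to = 9L)
  expect_error(rgcn_forward(H, e, random_layer(2, 2)), "index error")
})

test_that("KAN layer reduces to zero / SiLU in the documented limits", {
  cfg <- model_config()
  set.seed(3)
  X <- matrix(runif(40, -1.5, 1.5), 10, 4)
  kp <- svdelnet:::new_kan_params(4, 4, cfg)
  zero <- list(base = kp$base * 0, scale = kp$scale * 0, coef = kp$coef * 0)
  expect_equal(kan_forward(X, zero, cfg), matrix(0, 10, 4))
  # spline part off, single active connection with base weight 1 -> silu
  single <- zero
  single$base[2, 3] <- 1
  Y <- kan_forward(X, single, cfg)
  expect_equal(Y[, 2], X[, 3] * stats::plogis(X[, 3]))
  expect_true(all(Y[, -2] == 0))
})

test_that("KAN spline evaluation matches an independent de Boor oracle", {
  cfg <- model_config(grid = 5, degree = 3)
  knots <- svdelnet:::kan_knots(cfg)
  xs <- seq(-1.9, 1.9, length.out = 23)
  for (m in 1:svdelnet:::kan_n_basis(cfg)) {
    kp <- list(base = matrix(0, 1, 1), scale = matrix(1, 1, 1),
               coef = array(0, c(1, 1, svdelnet:::kan_n_basis(cfg))))
    kp$coef[1, 1, m] <- 1
    got <- kan_forward(matrix(xs, ncol = 1), kp, cfg)[, 1]
    want <- deboor_basis(xs, knots, 3L, m)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("KAN inputs outside the grid range are clamped, not an error", {
  cfg <- model_config()
  kp <- svdelnet:::new_kan_params(2, 2, cfg)
  X <- matrix(c(-50, 0.5, 3.7, 1e6), 2, 2)
  expect_silent(Y <- kan_forward(X, kp, cfg))
  Xc <- pmin(pmax(X, -2), 2)
  expect_equal(Y, kan_forward(Xc, kp, cfg))
})

test_that("the weighted cross-entropy matches hand-computed values", {
  p <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  expect_equal(compute_loss(p, c(0L, 1L), weight = 0.7, lambda = 0),
               -0.5 * (0.3 * log(0.8) + 0.7 * log(0.6)),
               tolerance = 1e-12)
  expect_equal(round(compute_loss(p, c(0L, 1L), weight = 0.7, lambda = 0), 4),
               0.2123)
  # perfect predictions, no regularizer -> zero loss
  p1 <- rbind(c(1, 0), c(0, 1))
  expect_equal(compute_loss(p1, c(0L, 1L), weight = 0.7, lambda = 0), 0)
  # lambda = 0, weight = 0.5 halves the unweighted mean cross-entropy
  set.seed(2)
  pr <- matrix(runif(20, 0.05, 0.95), 10); pr <- pr / rowSums(pr)
  y <- sample(0:1, 10, TRUE)
  ce <- -mean(log(pr[cbind(1:10, y + 1)]))
  expect_equal(compute_loss(pr, y, weight = 0.5, lambda = 0), ce / 2)
})

test_that("the regularizer-only loss equals lambda/2 times the weight norm", {
  cfg <- model_config(lambda = 0.1)
  params <- init_params(cfg, seed = 1)
  # rescale all weights so that ||W||^2 = 4
  v <- svdelnet:::flatten_params(params$layers)
  v <- v / sqrt(sum(v^2)) * 2
  params$layers <- svdelnet:::unflatten_params(v, params$layers)
  p1 <- rbind(c(1, 0), c(0, 1))
  expect_equal(compute_loss(p1, c(0L, 1L), params), 0.1 / 2 * 4,
               tolerance = 1e-12)
})

test_that("default architecture hits the published parameter budget", {
  params <- init_params(model_config(), seed = 1)
  # closed forms: conv1 4*6*8+8, conv2 4*8*4+4, KAN 16*(2+G+k), FC 4*2+2
  expect_identical(count_params(params), 200L + 132L + 160L + 10L)
  expect_lt(abs(count_params(params) - 508) / 508, 0.02)
  # FC head alone on d2 = 4: 4*2+2
  fc <- init_params(model_config(head = "fc"), seed = 1)
  expect_identical(count_params(fc) - (200L + 132L), 10L)
})

test_that("forward probabilities are normalized and deterministic", {
  g <- toy_labeled_graphs(4)
  params <- init_params(model_config(), seed = 2)
  b <- batch_graphs(g)
  pred <- model_forward(b, params)
  expect_equal(pred$p0 + pred$p1, rep(1, nrow(pred)), tolerance = 1e-9)
  expect_true(all(pred$p0 >= 0 & pred$p0 <= 1))
  expect_identical(pred, model_forward(b, params))
  expect_equal(nrow(pred), nrow(b$feat))
})

test_that("the classifier is permutation-equivariant", {
  set.seed(31)
  g <- toy_labeled_graphs(1)[[1]]
  params <- init_params(model_config(), seed = 3)
  n <- nrow(g$feat)
  perm <- sample(n)
  gp <- g
  gp$feat <- g$feat[perm, , drop = FALSE]
  inv <- integer(n); inv[perm] <- seq_len(n)
  gp$edges <- lapply(g$edges, function(e)
    cbind(from = inv[e[, "from"]], to = inv[e[, "to"]]))
  p0 <- model_forward(g, params)
  p1 <- model_forward(gp, params)
  expect_equal(as.matrix(p1[inv[seq_len(n)], c("p0", "p1")]),
               as.matrix(p0[, c("p0", "p1")]),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("batched forward equals concatenated per-graph forwards", {
  gs <- toy_labeled_graphs(5)
  for (head in c("kan_fc", "fc", "kan", "kan2")) {
    params <- init_params(model_config(head = head), seed = 4)
    batch_out <- model_forward(batch_graphs(gs), params)
    solo <- do.call(rbind, lapply(gs, model_forward, params = params))
    expect_equal(as.matrix(batch_out), as.matrix(solo),
                 ignore_attr = TRUE, tolerance = 1e-6)
  }
})

test_that("analytic gradients agree with finite differences for every head", {
  gs <- toy_labeled_graphs(3, seed = 13)
  b <- batch_graphs(gs)
  A <- svdelnet:::build_adjacency(b$edges, nrow(b$feat))
  batch <- list(feat = b$feat, labels = b$labels, A = A)
  for (head in c("kan_fc", "fc", "kan", "kan2")) {
    cfg <- model_config(head = head, lambda = 1e-3, weight = 0.8)
    params <- init_params(cfg, seed = 5)
    pv <- svdelnet:::flatten_params(params$layers)
    f <- function(v) {
      lay <- svdelnet:::unflatten_params(v, params$layers)
      svdelnet:::loss_and_grad(batch, A, lay, cfg)$loss
    }
    g_analytic <- svdelnet:::loss_and_grad(
      batch, A, params$layers, cfg)$grad_vec
    eps <- 1e-6
    idx <- seq(1, length(pv), length.out = min(40, length(pv)))
    idx <- unique(as.integer(idx))
    g_num <- vapply(idx, function(i) {
      vp <- pv; vp[i] <- vp[i] + eps
      vm <- pv; vm[i] <- vm[i] - eps
      (f(vp) - f(vm)) / (2 * eps)
    }, numeric(1))
    expect_equal(g_analytic[idx], g_num, tolerance = 1e-4,
                 label = paste("head", head))
  }
})

test_that("training descends, is seed-reproducible, and flags one-class data", {
  gs <- toy_labeled_graphs(30, seed = 17)
  cfg <- model_config(epochs = 6L, seed = 7L)
  p1 <- train_model(gs, cfg)
  h1 <- attr(p1, "history")
  expect_lt(h1[length(h1)], h1[1])
  p2 <- train_model(gs, cfg)
  expect_equal(attr(p2, "history")[cfg$epochs], h1[cfg$epochs],
               tolerance = 1e-8)
  expect_identical(svdelnet:::flatten_params(p1$layers),
                   svdelnet:::flatten_params(p2$layers))
  # single-class data: warn but proceed
  g_neg <- lapply(gs[1:3], function(g) { g$labels[] <- 0L; g })
  expect_warning(train_model(g_neg, model_config(epochs = 1L)),
                 "single class")
})

test_that("prediction uses the argmax with ties resolved to class 0", {
  gs <- toy_labeled_graphs(2)
  params <- train_model(gs, model_config(epochs = 3L, seed = 1L))
  pred <- predict_nodes(gs, params)
  expect_equal(length(pred), 2L)
  for (i in 1:2) {
    expect_equal(nrow(pred[[i]]), nrow(gs[[i]]$feat))
    expect_equal(pred[[i]]$label, as.integer(pred[[i]]$p1 > pred[[i]]$p0))
  }
  # scale mismatch is a configuration error
  params$cfg$length_scale <- 1 / 500
  expect_error(predict_nodes(gs, params), "configuration error")
})

test_that("checkpoints round-trip parameters and configuration exactly", {
  gs <- toy_labeled_graphs(4)
  params <- train_model(gs, model_config(epochs = 2L, seed = 9L))
  path <- tempfile(fileext = ".json")
  save_checkpoint(params, path)
  back <- load_checkpoint(path)
  expect_equal(svdelnet:::flatten_params(back$layers),
               svdelnet:::flatten_params(params$layers), tolerance = 1e-15)
  expect_equal(back$cfg$length_scale, params$cfg$length_scale)
  expect_equal(back$cfg$head, params$cfg$head)
  p_old <- model_forward(batch_graphs(gs), params)
  p_new <- model_forward(batch_graphs(gs), back)
  expect_equal(p_new, p_old, tolerance = 1e-12)
})
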