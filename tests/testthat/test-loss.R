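# Loss anchors and the label-smoothness regularizer.

test_that("zeroed output path forces 0.5 predictions and ln 2 cross-entropy per pair", {
  bench <- get_tiny_bench()
  adj <- build_adjacency(bench$pairs)
  cfg <- sl_config(dim = 6L, depth = 2L, width = 2L, n_samples = 3L,
                   ripple_set_size = 4L, batch_size = 32L, k_top = 3L,
                   l2_weight = 0, ls_weight = 0)
  params <- init_params(length(bench$kg$entities), length(bench$kg$relations),
                        cfg)
  # the ripple fusion is one factor of every orientation logit: zeroing it
  # forces all logits to 0
  params$W_o[] <- 0; params$b_o[] <- 0
  data <- build_model_data(bench$kg, bench$pairs$gene_universe, adj, cfg,
                           seed_rng = 4L)
  p <- bench$pairs$pairs[1:10, ]
  scores <- slripple:::score_pairs(params, data, p$a, p$b, cfg)
  expect_equal(scores, rep(0.5, 10))

  # one positive + one negative at score 0.5: ln 2 per pair
  l <- total_loss(params, data, p$a[1:2], p$b[1:2], c(1, 0), cfg)
  expect_equal(l$ce, log(2), tolerance = 1e-12)
  expect_equal(l$total, log(2), tolerance = 1e-12)
})

test_that("the L2 component equals the explicit parameter-square sum", {
  bench <- get_tiny_bench()
  adj <- build_adjacency(bench$pairs)
  cfg <- sl_config(dim = 5L, depth = 2L, width = 2L, n_samples = 2L,
                   ripple_set_size = 3L, batch_size = 8L, k_top = 3L,
                   l2_weight = 1, ls_weight = 0)
  params <- init_params(length(bench$kg$entities), length(bench$kg$relations),
                        cfg)
  data <- build_model_data(bench$kg, bench$pairs$gene_universe, adj, cfg,
                           seed_rng = 6L)
  p <- bench$pairs$pairs[1:4, ]
  l <- total_loss(params, data, p$a, p$b, p$label, cfg)
  ref <- 0
  for (nm in names(params)) for (v in as.vector(params[[nm]])) ref <- ref + v^2
  expect_lt(abs((l$total - l$ce) - ref) / ref, 1e-10)
  expect_equal(l$l2, ref, tolerance = 1e-10)
  expect_true(l$ce >= 0 && l$l2 >= 0 && l$ls >= 0)
})

test_that("perfectly separated logits drive the cross-entropy toward zero", {
  tp <- slripple:::ad_tape()
  z <- slripple:::ad_leaf(tp, matrix(c(30, -30), 2, 1))
  l <- slripple:::ad_bce_logits(z, c(1, 0))
  expect_lt(slripple:::ad_value(l)[1, 1], 1e-12)
})

test_that("constant labels are a fixed point of leave-one-out propagation", {
  # complete 3-node graph, all labeled 1
  W <- matrix(1, 3, 3) - diag(3)
  lhat <- propagate_labels_loo(W, 1:3, c(1, 1, 1), n_iter = 2)
  expect_equal(lhat, rep(1, 3))
  expect_equal(label_smoothness(W, 1:3, c(1, 1, 1), n_iter = 2), 0)
  # fewer than 2 labeled partners contribute nothing
  expect_equal(label_smoothness(W, 2L, 1, n_iter = 2), 0)
})

test_that("a 4-node toy matches explicit clamped power iteration", {
  # nodes 1..4; labeled: 1 (y=1) and 4 (y=0); hand-set weights
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.7
  W[2, 3] <- W[3, 2] <- 0.4
  W[3, 4] <- W[4, 3] <- 0.9
  W[1, 3] <- W[3, 1] <- 0.2
  labeled <- c(1L, 4L); y <- c(1, 0)
  n_iter <- 3L
  got <- propagate_labels_loo(W, labeled, y, n_iter)

  # oracle: explicit loop per left-out node
  P <- W / rowSums(W)
  ref <- numeric(2)
  for (j in 1:2) {
    x <- rep(0.5, 4)
    clamp <- labeled[-j]
    x[clamp] <- y[-j]
    for (it in seq_len(n_iter)) {
      x_new <- as.vector(P %*% x)
      x_new[clamp] <- y[-j]
      x <- x_new
    }
    ref[j] <- x[labeled[j]]
  }
  expect_lt(max(abs(got - ref)), 1e-6)
  expect_equal(label_smoothness(W, labeled, y, n_iter),
               sum(-(y * log(ref) + (1 - y) * log(1 - ref))),
               tolerance = 1e-10)
})

test_that("the trainer-facing smoothness term is finite and scales with genes", {
  bench <- get_tiny_bench()
  cfg <- sl_config(dim = 6L, depth = 2L, width = 2L, n_samples = 3L,
                   ripple_set_size = 4L, k_top = 3L, ls_sample_genes = 8L)
  params <- init_params(length(bench$kg$entities), length(bench$kg$relations),
                        cfg)
  r <- slripple:::ls_penalty(bench$kg, bench$pairs, params, cfg, seed_rng = 2L)
  expect_true(is.finite(r))
  expect_gte(r, 0)
})
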