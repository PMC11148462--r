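# Discrepancy contrastive layer (depth/width mixing) and the attention
# aggregator producing the final gene embedding.

test_that("depth mixing shares the enhancement aggregator semantics", {
  set.seed(41)
  S <- 4L
  for (mode in c("sum", "concat", "pool", "top_k")) {
    p <- rand_enhance_params(S, mode)
    e <- rnorm(S); nb <- rnorm(S)
    expect_identical(depth_mix(e, nb, p), enhance_entity(e, nb, p))
  }
  # top_k with k_top = S keeps every coordinate: identical to concat
  p_full <- rand_enhance_params(S, "top_k", k_top = S)
  p_con <- p_full; p_con$mode <- "concat"
  e <- rnorm(S); nb <- rnorm(S)
  expect_equal(depth_mix(e, nb, p_full), depth_mix(e, nb, p_con))
  # zero weights: constant sigmoid(0) before masking
  p_zero <- list(W_e = matrix(0, S, S), b_e = matrix(0, 1, S), mode = "sum")
  expect_equal(depth_mix(e, nb, p_zero), rep(0.5, S))
})

test_that("width mixing is the stated linear map", {
  set.seed(42)
  S <- 4L
  expect_equal(width_mix(list(c(1, 2, 3, 4)), diag(S)), c(1, 2, 3, 4))
  M <- rand_mat(2 * S, S)
  zero <- width_mix(list(rep(0, S), rep(0, S)), M)
  expect_equal(zero, rep(0, S))

  d1 <- rnorm(S); d2 <- rnorm(S)
  got <- width_mix(list(d1, d2), M)
  ref <- numeric(S)
  x <- c(d1, d2)
  for (j in 1:S) ref[j] <- sum(x * M[, j])
  expect_lt(max(abs(got - ref)), 1e-6)
  # homogeneity (no bias)
  expect_equal(width_mix(list(3 * d1, 3 * d2), M), 3 * got)
  expect_error(width_mix(list(d1), M), "does not match")
})

test_that("attention fusion: symmetry anchors and the step-by-step oracle", {
  set.seed(43)
  S <- 4L
  p <- rand_fuse_params(S)
  v <- rnorm(S)
  same <- attention_fuse(list(v, v, v), p)
  expect_equal(attr(same, "weights"), rep(1 / 3, 3))
  expect_equal(as.vector(same),
               plogis(as.vector(v %*% p$W7) + as.vector(p$b4)))
  single <- attention_fuse(list(v), p)
  expect_equal(attr(single, "weights"), 1)

  # random three-element set against an explicit loop evaluation
  reps <- list(rnorm(S), rnorm(S), rnorm(S))
  for (pool_flag in c(FALSE, TRUE)) {
    pp <- rand_fuse_params(S, condition_on_pool = pool_flag)
    got <- attention_fuse(reps, pp)
    pooled <- rep(0, S)
    if (pool_flag) {
      mx <- pmax(pmax(reps[[1]], reps[[2]]), reps[[3]])
      for (j in 1:S) pooled[j] <- plogis(sum(mx * pp$W_pool[, j]) + pp$b_pool[1, j])
    }
    alpha <- numeric(3)
    for (i in 1:3) {
      hi <- numeric(S)
      for (j in 1:S) hi[j] <- tanh(sum(reps[[i]] * pp$W6[, j]) + pooled[j])
      alpha[i] <- sum(hi * pp$w6)
    }
    w <- exp(alpha - max(alpha)); w <- w / sum(w)
    mixed <- w[1] * reps[[1]] + w[2] * reps[[2]] + w[3] * reps[[3]]
    ref <- numeric(S)
    for (j in 1:S) ref[j] <- plogis(sum(mixed * pp$W7[, j]) + pp$b4[1, j])
    expect_lt(max(abs(as.vector(got) - ref)), 1e-6)
    expect_equal(sum(attr(got, "weights")), 1, tolerance = 1e-10)
  }
  expect_error(attention_fuse(list(), p), "empty")
})

test_that("attention fusion is permutation-invariant and bounded", {
  set.seed(44)
  S <- 5L
  p <- rand_fuse_params(S)
  reps <- list(rnorm(S), rnorm(S), rnorm(S), rnorm(S))
  out1 <- attention_fuse(reps, p)
  out2 <- attention_fuse(reps[c(3, 1, 4, 2)], p)
  expect_equal(as.vector(out1), as.vector(out2), tolerance = 1e-12)
  expect_true(all(out1 > 0 & out1 < 1))
  # uniform mode averages
  pu <- p; pu$uniform <- TRUE
  got <- attention_fuse(reps, pu)
  mean_rep <- Reduce(`+`, reps) / 4
  expect_equal(as.vector(got),
               plogis(as.vector(mean_rep %*% p$W7) + as.vector(p$b4)))
})

test_that("the full pipeline keeps embedding length S over the depth/width sweep", {
  bench <- get_tiny_bench()
  pairs <- bench$pairs$pairs[1:3, ]
  adj <- build_adjacency(bench$pairs)
  for (depth in c(1L, 3L, 5L)) {
    for (width in c(1L, 3L, 5L)) {
      cfg <- sl_config(dim = 4L, depth = depth, width = width, n_samples = 2L,
                       ripple_set_size = 2L, p_hop = 1L, k_top = 2L,
                       batch_size = 8L)
      params <- init_params(length(bench$kg$entities),
                            length(bench$kg$relations), cfg)
      data <- build_model_data(bench$kg, bench$pairs$gene_universe, adj, cfg,
                               seed_rng = 2L)
      fw <- slripple:::forward_pairs(params, data, pairs$a, pairs$b, cfg)
      expect_equal(dim(slripple:::ad_value(fw$final)), c(6L, 4L))
      expect_equal(dim(slripple:::ad_value(fw$logits)), c(3L, 1L))
    }
  }
})
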