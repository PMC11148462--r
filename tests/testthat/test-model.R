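# The batched tape forward must equal the composition of the documented
# single-instance encoder operations, and scoring must be symmetric,
# batch-consistent and checkpoint-stable.

test_that("batched forward equals the single-instance op composition", {
  bench <- get_tiny_bench()
  kg <- bench$kg
  adj <- build_adjacency(bench$pairs)
  cfg <- sl_config(dim = 6L, p_hop = 2L, depth = 2L, width = 2L,
                   n_samples = 3L, ripple_set_size = 4L, aggregator = "top_k",
                   k_top = 3L, batch_size = 16L, seed = 3L)
  params <- init_params(length(kg$entities), length(kg$relations), cfg)
  genes <- bench$pairs$gene_universe
  data <- build_model_data(kg, genes, adj, cfg, seed_rng = 9L)
  pairs <- bench$pairs$pairs[c(2, 10, 33, 47), ]
  got <- slripple:::score_pairs(params, data, pairs$a, pairs$b, cfg)

  att <- list(W1 = params$W1, b1 = params$b1, W2 = params$W2, b2 = params$b2,
              W3 = params$W3, b3 = params$b3)
  enh <- list(W_e = params$W_e, b_e = params$b_e, mode = cfg$aggregator,
              k_top = cfg$k_top)
  dep <- list(W_e = params$W_d, b_e = params$b_d, mode = cfg$depth_agg_mode,
              k_top = cfg$k_top)
  fuse <- list(w6 = params$w6, W6 = params$W6, W7 = params$W7, b4 = params$b4)

  rip_one <- function(center, other) {
    row <- data$gene_row[as.character(center)]
    cond <- params$E[other, ]
    h1 <- data$ripple$heads[[1]][row, ]
    stack <- list(as.vector(hop0_response(params$E[h1, , drop = FALSE], cond,
                                          as.vector(params$w_a))))
    for (p in 1:cfg$p_hop) {
      stack[[p + 1]] <- as.vector(hop_response(
        data$ripple$heads[[p]][row, ], data$ripple$rels[[p]][row, ],
        data$ripple$tails[[p]][row, ], cond,
        list(entity_embeddings = params$E, relation_matrices = params$R_mat)))
    }
    fuse_responses(stack, params$W_o, as.vector(params$b_o))
  }
  kg_side_one <- function(center, signal) {
    row <- data$gene_row[as.character(center)]
    nb <- list()
    for (j in seq_len(cfg$depth - 1L)) {
      rels <- data$field[[j]]$rel[row, ]
      ents <- data$field[[j]]$ent[row, ]
      sc <- vapply(rels, function(r) {
        relation_attention_score(signal, params$R_emb[r, ], att)
      }, 0)
      nb[[j]] <- aggregate_neighbors(normalize_scores(sc),
                                     params$E[ents, , drop = FALSE])
    }
    e1 <- enhance_entity(params$E[center, ], signal, enh)
    reps <- list(e1)
    x_w <- e1
    for (w in seq_len(cfg$width)) {
      depth_embeds <- list(x_w)
      cur <- x_w
      for (dd in seq_len(cfg$depth - 1L)) {
        cur <- depth_mix(cur, nb[[dd]], dep)
        depth_embeds[[dd + 1L]] <- cur
      }
      x_w <- width_mix(depth_embeds, params[[paste0("M_", w)]])
      reps[[w + 1L]] <- x_w
    }
    as.vector(attention_fuse(reps, fuse))
  }

  ref <- vapply(seq_len(nrow(pairs)), function(i) {
    m <- pairs$a[i]; n <- pairs$b[i]
    rip_m <- rip_one(m, n); rip_n <- rip_one(n, m)
    fin_m <- kg_side_one(m, rip_n); fin_n <- kg_side_one(n, rip_m)
    plogis(0.5 * (sum(rip_m * fin_n) + sum(rip_n * fin_m)))
  }, 0)
  expect_lt(max(abs(got - ref)), 1e-6)
})

test_that("pair prediction is a symmetric sigmoid inner product", {
  expect_equal(predict_pair(rep(0, 3), rnorm(3)), 0.5)
  expect_equal(predict_pair(c(1, 0), c(2, 0)), plogis(2))
  expect_equal(predict_pair(c(1, 0), c(2, 0)), 0.8808, tolerance = 1e-4)
  set.seed(51)
  a <- rnorm(8); b <- rnorm(8)
  expect_identical(predict_pair(a, b), predict_pair(b, a))
})

test_that("model scores are order-symmetric and batch-size invariant", {
  bench <- get_tiny_bench()
  adj <- build_adjacency(bench$pairs)
  cfg <- sl_config(dim = 6L, depth = 2L, width = 2L, n_samples = 3L,
                   ripple_set_size = 4L, batch_size = 4L, k_top = 3L)
  params <- init_params(length(bench$kg$entities), length(bench$kg$relations),
                        cfg)
  data <- build_model_data(bench$kg, bench$pairs$gene_universe, adj, cfg,
                           seed_rng = 5L)
  p <- bench$pairs$pairs[1:6, ]
  s_ab <- slripple:::score_pairs(params, data, p$a, p$b, cfg)
  s_ba <- slripple:::score_pairs(params, data, p$b, p$a, cfg)
  expect_equal(s_ab, s_ba, tolerance = 1e-12)
  singles <- vapply(1:6, function(i) {
    slripple:::score_pairs(params, data, p$a[i], p$b[i], cfg)
  }, 0)
  expect_equal(s_ab, singles, tolerance = 1e-12)
})

test_that("a reloaded checkpoint reproduces identical scores", {
  bench <- get_tiny_bench()
  split <- split_random(bench$pairs, seed = 3L)
  cfg <- synth_protocol_config(seed = 1L, dim = 8L, epochs = 2L)
  model <- train_sl_model(bench$kg, split, cfg)
  path <- tempfile(fileext = ".rds")
  sl_save_model(model, path)
  back <- sl_load_model(path)
  s1 <- predict_sl_model(model, split$test)
  s2 <- predict_sl_model(back, split$test)
  expect_identical(s1, s2)
})
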