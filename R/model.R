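# Model parameters and the batched differentiable forward pass.
#
# The batched forward composes, on the autodiff tape, exactly the
# operations documented by the single-instance encoder functions
# (hop0_response, hop_response, fuse_responses, relation attention,
# enhance_entity, depth_mix, width_mix, attention_fuse); a test asserts the
# equivalence pair-by-pair. Batch layout: a batch of B gene pairs (m, n)
# becomes 2B "instances" (centers c(m, n), partners c(n, m)); per-slot
# index matrices are flattened row-major so instance i, slot k maps to row
# (i-1)*K + k.

glorot <- function(nr, nc) {
  a <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

#' Initialize all trainable tensors
#'
#' @param n_entities,n_relations vocabulary sizes (relations include
#'   inverse and self ids)
#' @param config an [sl_config()]
#' @return named list of parameter arrays
#' @export
init_params <- function(n_entities, n_relations, config) {
  S <- config$dim; H1 <- config$hidden1; H2 <- config$hidden2
  enh_in <- if (config$aggregator %in% c("concat", "top_k")) 2L * S else S
  dep_in <- if (config$depth_agg_mode %in% c("concat", "top_k")) 2L * S else S
  # embedding tables are indexed row-wise, so their init scale follows the
  # embedding dimension, not the vocabulary size
  emb_init <- function(nr) matrix(stats::runif(nr * S, -sqrt(6 / (2 * S)),
                                               sqrt(6 / (2 * S))), nr, S)
  with_seed(config$seed, {
    p <- list(
      E = emb_init(n_entities),
      R_emb = emb_init(n_relations),
      w_a = glorot(2L * S, 1L),
      W_o = glorot((config$p_hop + 1L) * S, S),
      b_o = matrix(0, 1L, S),
      W1 = glorot(2L * S, H1), b1 = matrix(0, 1L, H1),
      W2 = glorot(H1, H2), b2 = matrix(0, 1L, H2),
      W3 = glorot(H2, 1L), b3 = matrix(0, 1L, 1L),
      W_e = glorot(enh_in, S), b_e = matrix(0, 1L, S),
      W_d = glorot(dep_in, S), b_d = matrix(0, 1L, S),
      w6 = glorot(S, 1L), W6 = glorot(S, S), W7 = glorot(S, S),
      b4 = matrix(0, 1L, S),
      W_pool = glorot(S, S), b_pool = matrix(0, 1L, S)
    )
    if (config$relation_matrix == "full") {
      p$R_mat <- array(stats::runif(S * S * n_relations, -sqrt(6 / (2 * S)),
                                    sqrt(6 / (2 * S))), c(S, S, n_relations))
    } else {
      p$R_diag <- matrix(1, n_relations, S) + glorot(n_relations, S) * 0.1
    }
    for (w in seq_len(config$width)) {
      p[[paste0("M_", w)]] <- glorot(config$depth * S, S)
    }
    p
  })
}

# enhancement aggregator on the tape; e and m are N x S vars
tape_enhance <- function(e, m, W, b, mode, k_top) {
  input <- switch(mode,
    sum = ad_add(e, m),
    concat = ,
    top_k = ad_concat_cols(list(e, m)),
    pool = ad_pmax(e, m))
  out <- ad_sigmoid(ad_addbias(ad_matmul(input, W), b))
  if (mode == "top_k") out <- ad_topk_rows(out, k_top) else out
}

# relation attention scores for flattened (signal, relation) rows -> raw
# sigmoid scores, (N*K) x 1
tape_attention_scores <- function(sig_rep, rel_emb, L) {
  z0 <- ad_relu(ad_addbias(ad_matmul(ad_concat_cols(list(sig_rep, rel_emb)), L$W1), L$b1))
  z1 <- ad_relu(ad_addbias(ad_matmul(z0, L$W2), L$b2))
  ad_sigmoid(ad_addbias(ad_matmul(z1, L$W3), L$b3))
}

#' Batched forward pass over a set of gene pairs
#'
#' Builds the full computation (ripple encoding of both genes, each
#' conditioned on the partner's embedding-table row; relation-attentive
#' neighborhood aggregation and entity enhancement conditioned on the
#' partner's ripple embedding; depth/width discrepancy mixing; attention
#' fusion; inner-product scoring) on a fresh autodiff tape.
#'
#' @param params parameter list from [init_params()]
#' @param data batch index tables from [build_model_data()]
#' @param m,n integer entity ids of the two genes of each pair
#' @param config an [sl_config()]
#' @return list with `tape`, `logits` (B x 1 var; mean over both pair
#'   orientations of the ripple/KG-side inner product), `rip` and `final`
#'   (2B x S vars of ripple and KG-side gene embeddings) and `leaves`
#'   (named parameter leaves)
#' @keywords internal
forward_pairs <- function(params, data, m, n, config) {
  B <- length(m)
  S <- config$dim
  tape <- ad_tape()
  L <- lapply(stats::setNames(names(params), names(params)),
              function(nm) ad_leaf(tape, params[[nm]], name = nm))
  centers <- c(m, n)
  others <- c(n, m)
  crow <- data$gene_row[as.character(centers)]
  N2 <- 2L * B
  size <- config$ripple_set_size
  grp <- rep(seq_len(N2), each = size)

  cond <- ad_gather(L$E, others)              # conditioning vector n
  variant <- config$variant

  if (variant == "no_ripple") {
    rip <- ad_gather(L$E, centers)
  } else {
    cond_rep <- ad_index_rows(cond, grp)
    hv1 <- as.vector(t(data$ripple$heads[[1]][crow, , drop = FALSE]))
    H1v <- ad_gather(L$E, hv1)
    s0 <- ad_matmul(ad_concat_cols(list(H1v, cond_rep)), L$w_a)
    w0 <- ad_flatten_rows(ad_softmax_rows(ad_unflatten_rows(s0, size)))
    responses <- list(ad_grouprowsum(ad_colmul(H1v, w0), grp, N2))
    for (p in seq_len(config$p_hop)) {
      hv <- as.vector(t(data$ripple$heads[[p]][crow, , drop = FALSE]))
      rv <- as.vector(t(data$ripple$rels[[p]][crow, , drop = FALSE]))
      tv <- as.vector(t(data$ripple$tails[[p]][crow, , drop = FALSE]))
      Hv <- ad_gather(L$E, hv)
      Tv <- ad_gather(L$E, tv)
      RH <- if (config$relation_matrix == "full") ad_relmm(Hv, rv, L$R_mat)
            else ad_emul(Hv, ad_gather(L$R_diag, rv))
      sc <- ad_rowdot(cond_rep, RH)
      wk <- ad_flatten_rows(ad_softmax_rows(ad_unflatten_rows(sc, size)))
      responses[[p + 1L]] <- ad_grouprowsum(ad_colmul(Tv, wk), grp, N2)
    }
    rip <- ad_addbias(ad_matmul(ad_concat_cols(responses), L$W_o), L$b_o)
  }

  # gene signal for the KG side of each instance = the partner's ripple
  # embedding (table embedding under the no_ripple variant)
  signal <- ad_index_rows(rip, c(B + seq_len(B), seq_len(B)))

  # neighborhood embeddings at depths 1..(depth-1)
  nb <- list()
  if (config$depth > 1L) {
    for (j in seq_len(config$depth - 1L)) {
      K <- ncol(data$field[[j]]$rel)
      gj <- rep(seq_len(N2), each = K)
      relf <- as.vector(t(data$field[[j]]$rel[crow, , drop = FALSE]))
      entf <- as.vector(t(data$field[[j]]$ent[crow, , drop = FALSE]))
      sig_rep <- ad_index_rows(signal, gj)
      sc <- tape_attention_scores(sig_rep, ad_gather(L$R_emb, relf), L)
      wj <- ad_flatten_rows(ad_softmax_rows(ad_unflatten_rows(sc, K)))
      nb[[j]] <- ad_grouprowsum(ad_colmul(ad_gather(L$E, entf), wj), gj, N2)
    }
  }

  e_center <- ad_gather(L$E, centers)
  e1 <- if (variant == "no_enhance") e_center
        else tape_enhance(e_center, signal, L$W_e, L$b_e, config$aggregator,
                          config$k_top)

  reps <- list(e1)
  x_w <- e1
  for (w in seq_len(config$width)) {
    depth_embeds <- list(x_w)
    cur <- x_w
    if (config$depth > 1L) {
      for (dd in seq_len(config$depth - 1L)) {
        cur <- tape_enhance(cur, nb[[dd]], L$W_d, L$b_d, config$depth_agg_mode,
                            config$k_top)
        depth_embeds[[dd + 1L]] <- cur
      }
    }
    x_w <- ad_matmul(ad_concat_cols(depth_embeds), L[[paste0("M_", w)]])
    reps[[w + 1L]] <- x_w
  }

  nrep <- length(reps)
  if (variant == "no_attention_fuse") {
    mixed <- reps[[1]]
    for (i in seq.int(2L, nrep)) mixed <- ad_add(mixed, reps[[i]])
    mixed <- ad_scale(mixed, 1 / nrep)
  } else {
    scores <- lapply(reps, function(r) ad_matmul(ad_tanh(ad_matmul(r, L$W6)), L$w6))
    wts <- ad_softmax_rows(ad_concat_cols(scores))
    mixed <- ad_colmul(reps[[1]], ad_col(wts, 1L))
    for (i in seq.int(2L, nrep)) {
      mixed <- ad_add(mixed, ad_colmul(reps[[i]], ad_col(wts, i)))
    }
  }
  final <- ad_sigmoid(ad_addbias(ad_matmul(mixed, L$W7), L$b4))

  # pair score: each orientation pairs one gene's ripple embedding with the
  # partner's KG-side embedding, f_SL(m, n) = rip_m . kg_n; the unordered
  # pair logit is the mean over both orientations, making the score exactly
  # symmetric under argument swap
  i_m <- seq_len(B); i_n <- B + seq_len(B)
  logits <- ad_scale(
    ad_add(ad_rowdot(ad_index_rows(rip, i_m), ad_index_rows(final, i_n)),
           ad_rowdot(ad_index_rows(rip, i_n), ad_index_rows(final, i_m))),
    0.5)
  list(tape = tape, logits = logits, final = final, rip = rip, leaves = L)
}

#' Assemble per-gene batch index tables
#'
#' Draws the fixed-size ripple sets (from the training SL adjacency) and
#' the sampled neighbor field used by the discrepancy contrastive layer,
#' for every gene that can appear in a batch.
#'
#' @param kg a `kg` object (after any evaluation-edge masking)
#' @param genes integer ids of all genes that may appear in pairs
#' @param adj training SL adjacency from [build_adjacency()]
#' @param config an [sl_config()]
#' @param seed_rng sampling seed
#' @return list with `gene_row`, `ripple`, `field`
#' @export
build_model_data <- function(kg, genes, adj, config, seed_rng = 1L) {
  genes <- sort(unique(genes))
  list(
    gene_row = stats::setNames(seq_along(genes), genes),
    genes = genes,
    ripple = ripple_index(kg, genes, adj, config$p_hop, config$ripple_set_size,
                          seed_rng = seed_rng),
    field = if (config$depth > 1L)
      neighbor_field(kg, genes, config$n_samples, config$depth - 1L,
                     seed_rng = seed_rng + 1L)
    else list()
  )
}

#' Inner-product SL probability for a pair of embeddings
#'
#' `sigmoid(m . n)`; symmetric in its arguments.
#' @param m_embed,n_embed numeric vectors of equal length
#' @return probability in (0, 1)
#' @export
predict_pair <- function(m_embed, n_embed) {
  stopifnot(length(m_embed) == length(n_embed),
            all(is.finite(m_embed)), all(is.finite(n_embed)))
  stats::plogis(sum(m_embed * n_embed))
}

# forward pass without gradient bookkeeping; returns probabilities
score_pairs <- function(params, data, m, n, config) {
  fw <- forward_pairs(params, data, m, n, config)
  stats::plogis(as.vector(ad_value(fw$logits)))
}
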