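# Label-smoothness regularization and loss bookkeeping.
#
# The smoothness term treats a gene m's known SL labels as boundary values
# on an edge-weighted graph: each held-out labeled node is re-estimated by
# propagating the OTHER labels over the weight matrix with labeled nodes
# clamped, and the regularizer is the cross-entropy between the held-out
# label and its propagated estimate. Ideal (attention-derived) edge weights
# make known labels reproducible from their neighborhoods.

#' Leave-one-out clamped label propagation
#'
#' For each labeled node i, initializes every node at `init`, clamps all
#' labeled nodes except i to their labels, and runs `n_iter` rounds of
#' `x <- P x` (P the row-normalized weight matrix; zero-degree rows keep
#' their value) with re-clamping after every round; the estimate for i is
#' read off after the last round.
#'
#' @param W nonnegative square weight matrix (gene-conditioned attention
#'   weights over the propagation subgraph)
#' @param labeled_idx indices of the labeled nodes
#' @param labels 0/1 labels aligned with `labeled_idx`
#' @param n_iter propagation rounds (the trainer ties this to `p_hop`)
#' @param init initial value for unclamped nodes (default 0.5)
#' @return numeric vector of leave-one-out estimates, aligned with
#'   `labeled_idx`
#' @export
propagate_labels_loo <- function(W, labeled_idx, labels, n_iter, init = 0.5) {
  stopifnot(nrow(W) == ncol(W), length(labeled_idx) == length(labels),
            n_iter >= 1L, all(W >= 0))
  nn <- nrow(W)
  rs <- rowSums(W)
  P <- W / ifelse(rs > 0, rs, 1)
  keep <- rs == 0  # zero-degree rows keep their current value
  vapply(seq_along(labeled_idx), function(j) {
    x <- rep(init, nn)
    clamp <- labeled_idx[-j]
    x[clamp] <- labels[-j]
    for (it in seq_len(n_iter)) {
      x_new <- as.vector(P %*% x)
      x_new[keep] <- x[keep]
      x_new[clamp] <- labels[-j]
      x <- x_new
    }
    x[labeled_idx[j]]
  }, 0)
}

bce <- function(y, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Label-smoothness penalty for one gene
#'
#' `R(A_m) = sum_n J(y_mn, l_hat_m(n))` with `l_hat` the leave-one-out
#' propagation estimate of [propagate_labels_loo()] and J the binary
#' cross-entropy. Genes with fewer than two labeled partners contribute 0
#' (the leave-one-out estimate is undefined).
#'
#' @param W weight matrix over the gene's propagation subgraph
#' @param labeled_idx,labels labeled nodes (the gene's known partners) and
#'   their 0/1 labels
#' @param n_iter propagation rounds
#' @return scalar >= 0
#' @export
label_smoothness <- function(W, labeled_idx, labels, n_iter) {
  if (length(labeled_idx) < 2L) return(0)
  l_hat <- propagate_labels_loo(W, labeled_idx, labels, n_iter)
  sum(bce(labels, l_hat))
}

# Gene-conditioned propagation subgraph: the gene's labeled train partners
# plus their sampled KG neighbors; edge weights are the relation-attention
# scores conditioned on the gene's embedding. Returns W plus the labeled
# node bookkeeping for label_smoothness().
ls_subgraph <- function(kg, gene, labeled_genes, labels, params, config,
                        max_neighbors = 8L) {
  nodes <- labeled_genes
  edges <- list()
  for (g in labeled_genes) {
    nbm <- kg$by_head[[g]]
    if (is.null(nbm) || nrow(nbm) == 0L) next
    take <- seq_len(min(max_neighbors, nrow(nbm)))
    nodes <- c(nodes, nbm[take, "tail"])
    edges[[length(edges) + 1L]] <- cbind(from = g, nbm[take, , drop = FALSE])
  }
  nodes <- unique(nodes)
  nn <- length(nodes)
  W <- matrix(0, nn, nn)
  if (length(edges) > 0L) {
    ed <- do.call(rbind, edges)
    gene_embed <- params$E[gene, ]
    att <- list(W1 = params$W1, b1 = params$b1, W2 = params$W2, b2 = params$b2,
                W3 = params$W3, b3 = params$b3)
    rel_scores <- vapply(unique(ed[, "rel"]), function(r) {
      relation_attention_score(gene_embed, params$R_emb[r, ], att)
    }, 0)
    names(rel_scores) <- unique(ed[, "rel"])
    i <- match(ed[, "from"], nodes)
    j <- match(ed[, "tail"], nodes)
    w <- rel_scores[as.character(ed[, "rel"])]
    for (q in seq_along(i)) {
      W[i[q], j[q]] <- W[i[q], j[q]] + w[q]
      W[j[q], i[q]] <- W[j[q], i[q]] + w[q]
    }
  }
  list(W = W, labeled_idx = match(labeled_genes, nodes), labels = labels)
}

# Label-smoothness term over (a sample of) eligible train genes, scaled to
# the eligible-gene count. Value-only: at the reference weight (1e-8) the
# gradient contribution is far below the noise floor of the stochastic
# CE gradient, so it is not propagated through the tape.
ls_penalty <- function(kg, train_pairs, params, config, seed_rng) {
  p <- train_pairs$pairs
  genes <- sort(unique(c(p$a, p$b)))
  partners <- lapply(genes, function(g) {
    idx <- which(p$a == g | p$b == g)
    list(other = ifelse(p$a[idx] == g, p$b[idx], p$a[idx]), y = p$label[idx])
  })
  names(partners) <- genes
  eligible <- genes[vapply(partners, function(z) length(z$y) >= 2L, TRUE)]
  if (length(eligible) == 0L) return(0)
  take <- if (length(eligible) > config$ls_sample_genes) {
    with_seed(seed_rng, sample(eligible, config$ls_sample_genes))
  } else eligible
  tot <- 0
  for (g in take) {
    z <- partners[[as.character(g)]]
    sg <- ls_subgraph(kg, g, z$other, z$y, params, config)
    tot <- tot + label_smoothness(sg$W, sg$labeled_idx, sg$labels, config$p_hop)
  }
  tot * length(eligible) / length(take)
}

#' Decomposed training loss for a batch of labeled pairs
#'
#' Mean binary cross-entropy of the pair scores, plus `gamma * ||Theta||^2`
#' (every trainable tensor) plus `lambda * R(A)` (label smoothness). Used
#' both by the trainer and directly in tests; returns the components
#' alongside the total.
#'
#' @param params,data,config as in [forward_pairs()]
#' @param m,n,y pair gene ids and 0/1 labels
#' @param kg propagation KG (needed when `ls_weight > 0`)
#' @param train_pairs labeled training pairs for the smoothness term
#' @param seed_rng seed for the smoothness gene subsample
#' @return list with `total`, `ce`, `l2`, `ls`
#' @export
total_loss <- function(params, data, m, n, y, config, kg = NULL,
                       train_pairs = NULL, seed_rng = 1L) {
  stopifnot(length(m) > 0L, length(m) == length(n), length(m) == length(y))
  fw <- forward_pairs(params, data, m, n, config)
  z <- as.vector(ad_value(fw$logits))
  ce <- mean(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
  l2 <- sum(vapply(params, function(p) sum(p^2), 0))
  ls <- if (config$ls_weight > 0 && !is.null(kg) && !is.null(train_pairs)) {
    ls_penalty(kg, train_pairs, params, config, seed_rng)
  } else 0
  total <- ce + config$l2_weight * l2 + config$ls_weight * ls
  if (!is.finite(total)) stop("non-finite loss (ce=", ce, ", l2=", l2, ", ls=", ls, ")")
  list(total = total, ce = ce, l2 = l2, ls = ls)
}
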