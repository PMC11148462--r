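# Gene-entity interaction: relation attention over sampled neighborhoods
# and the gene-specific entity enhancement layer with four interchangeable
# aggregators (sum / concat / pool / top_k).

#' Relation attention score for a (gene, relation) pair
#'
#' A two-hidden-layer scoring network on the concatenation of the
#' conditioning gene embedding with the relation embedding:
#' `z0 = ReLU([x || r] W1 + b1)`, `score = sigmoid(ReLU(z0 W2 + b2) W3 + b3)`.
#' The sigmoid keeps every raw score in (0, 1); scores across a sampled
#' neighborhood are subsequently normalized with [normalize_scores()].
#'
#' @param gene_embed conditioning gene embedding (length S)
#' @param relation_embed relation embedding (length S)
#' @param params list with `W1` (2S x H1), `b1`, `W2` (H1 x H2), `b2`,
#'   `W3` (H2 x 1), `b3` (scalar)
#' @return scalar in (0, 1)
#' @export
relation_attention_score <- function(gene_embed, relation_embed, params) {
  x <- c(gene_embed, relation_embed)
  z0 <- pmax(as.vector(x %*% params$W1) + as.vector(params$b1), 0)
  z1 <- pmax(as.vector(z0 %*% params$W2) + as.vector(params$b2), 0)
  stats::plogis(sum(z1 * params$W3) + as.vector(params$b3))
}

#' Softmax normalization of attention scores
#'
#' Max-shifted for numerical stability; weights are positive and sum to 1.
#'
#' @param scores nonempty numeric vector of finite scores
#' @return numeric weight vector of the same length
#' @export
normalize_scores <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector")
  if (any(is.na(scores)) || any(!is.finite(scores))) {
    stop("attention scores must be finite")
  }
  softmax_vec(scores)
}

#' Attention-weighted aggregation of neighbor embeddings
#'
#' @param weights numeric weights summing to 1 (within 1e-5)
#' @param neighbor_embeds numeric matrix, one neighbor embedding per row
#' @return numeric vector of length S
#' @export
aggregate_neighbors <- function(weights, neighbor_embeds) {
  neighbor_embeds <- rbind(neighbor_embeds)
  if (length(weights) != nrow(neighbor_embeds)) {
    stop("weights and neighbor embeddings have different lengths")
  }
  if (abs(sum(weights) - 1) > 1e-5) stop("attention weights must sum to 1")
  as.vector(crossprod(neighbor_embeds, weights))
}

#' Gene-specific entity enhancement
#'
#' Aggregates an entity embedding with a gene embedding under one of four
#' aggregators, all mapping back to dimension S:
#' \describe{
#'   \item{sum}{`sigmoid((e + m) W_e + b_e)`}
#'   \item{concat}{`sigmoid([e || m] W_e + b_e)`}
#'   \item{pool}{`sigmoid(pmax(e, m) W_e + b_e)` (elementwise max over the
#'     pair stack)}
#'   \item{top_k}{the `k_top` largest coordinates of the concat output are
#'     kept in place, the rest zeroed (ties favor the lower index)}
#' }
#'
#' @param entity_embed entity embedding e (length S)
#' @param gene_embed gene embedding m (length S)
#' @param params list with `W_e` (S x S for sum/pool, 2S x S for
#'   concat/top_k), `b_e` (length S), `mode`, and `k_top` for top_k mode
#' @return numeric vector of length S with coordinates in (0, 1) (zeroed
#'   coordinates excepted in top_k mode)
#' @export
enhance_entity <- function(entity_embed, gene_embed, params) {
  mode <- params$mode
  input <- switch(mode,
    sum = entity_embed + gene_embed,
    concat = ,
    top_k = c(entity_embed, gene_embed),
    pool = pmax(entity_embed, gene_embed),
    stop("unknown enhancement mode: ", mode)
  )
  out <- stats::plogis(as.vector(input %*% params$W_e) + as.vector(params$b_e))
  if (mode == "top_k") {
    k <- params$k_top
    stopifnot(k >= 1L, k <= length(out))
    out <- out * as.vector(topk_mask(matrix(out, 1L), k))
  }
  out
}
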