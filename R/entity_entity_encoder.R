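# Entity-entity interaction: the discrepancy contrastive layer (depth and
# width mixing of neighborhood information) and the attention aggregator
# that fuses the representation set into the final gene embedding.

#' Depth mixing: next-order depth embedding
#'
#' Aggregates the current depth embedding with the neighborhood embedding
#' collected at that depth, `e^{d+1} = agg(e^d, n(N(n))^d)`, using the same
#' aggregator family as the entity enhancement layer (default top_k).
#'
#' @param entity_embed current depth embedding (length S)
#' @param neighborhood_embed aggregated neighborhood embedding (length S)
#' @param params an aggregator parameter list as for [enhance_entity()]
#' @return numeric vector of length S
#' @export
depth_mix <- function(entity_embed, neighborhood_embed, params) {
  enhance_entity(entity_embed, neighborhood_embed, params)
}

#' Width mixing: linear map of the concatenated depth embeddings
#'
#' `M_w %*% concat(e^1..e^d)` written in row convention as
#' `concat(e^1..e^d) %*% M_w`; purely linear, no bias.
#'
#' @param depth_embeds list of d vectors of length S
#' @param M_w numeric matrix with `d * S` rows and S columns
#' @return numeric vector of length S
#' @export
width_mix <- function(depth_embeds, M_w) {
  x <- unlist(depth_embeds, use.names = FALSE)
  if (length(x) != nrow(M_w)) {
    stop("depth stack length ", length(x), " does not match width matrix with ",
         nrow(M_w), " rows")
  }
  as.vector(x %*% M_w)
}

#' Attention fusion of the representation set into the final embedding
#'
#' Each representation is scored individually,
#' `alpha_i = w6' tanh(W6 rep_i)`, the scores are softmax-normalized, and
#' the weighted sum is passed through the output layer:
#' `out = sigmoid(W7 (sum_i alpha~_i rep_i) + b4)`. With
#' `condition_on_pool = TRUE` the max-pooled summary
#' `sigmoid(W_pool pool_max(T) + b_pool)` is added to each `W6 rep_i`
#' before the tanh as a shared conditioning term (off by default). With
#' `uniform = TRUE` the softmax is replaced by uniform weights (the
#' attention-fusion ablation).
#'
#' @param rep_set nonempty list of vectors of length S
#' @param params list with `w6` (length S), `W6`, `W7` (S x S), `b4`
#'   (length S), optionally `W_pool`, `b_pool`, `condition_on_pool`,
#'   `uniform`
#' @return numeric vector of length S with coordinates in (0, 1)
#'   (attribute `"weights"` holds alpha~)
#' @export
attention_fuse <- function(rep_set, params) {
  if (length(rep_set) == 0L) stop("empty representation set")
  reps <- do.call(rbind, rep_set)
  H <- reps %*% params$W6
  if (isTRUE(params$condition_on_pool)) {
    pooled <- stats::plogis(
      as.vector(apply(reps, 2L, max) %*% params$W_pool) + as.vector(params$b_pool))
    H <- sweep(H, 2L, pooled, "+")
  }
  alpha <- as.vector(tanh(H) %*% params$w6)
  w <- if (isTRUE(params$uniform)) rep(1 / length(alpha), length(alpha))
       else softmax_vec(alpha)
  mixed <- as.vector(crossprod(reps, w))
  structure(stats::plogis(as.vector(mixed %*% params$W7) + as.vector(params$b4)),
            weights = w)
}
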