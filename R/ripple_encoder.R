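# Ripple encoder: a gene's embedding from its ripple sets.
#
# Hop 0 attends over the heads of the hop-1 triples (which are exactly the
# gene's SL seeds), hops p >= 1 weight tails by the candidate gene's
# affinity to head entities under the triple's relation matrix, and the
# per-hop responses are fused by a single affine map. Throughout, the
# candidate (conditioning) vector n is the partner gene's embedding-table
# row. Vector/matrix convention: embeddings are plain numeric vectors of
# length S; a weight matrix W maps x to `x %*% W` (dims in x out).

softmax_vec <- function(x) {
  if (any(!is.finite(x))) stop("non-finite attention scores")
  e <- exp(x - max(x))
  e / sum(e)
}

#' Hop-0 SL preference response
#'
#' Attention over the seed head embeddings, scored by a linear functional
#' on the concatenation of each head with the candidate embedding:
#' `a_i = softmax_i( w_a . [h_i || n] )`, response `sum_i a_i h_i`.
#'
#' @param seed_heads numeric matrix, one seed head embedding per row
#' @param candidate numeric vector, the candidate gene embedding n
#' @param w_a numeric vector of length `2 * S`
#' @return numeric vector of length S (attribute `"weights"` holds a)
#' @export
hop0_response <- function(seed_heads, candidate, w_a) {
  seed_heads <- rbind(seed_heads)
  if (nrow(seed_heads) == 0L) stop("empty seed head set")
  S <- ncol(seed_heads)
  stopifnot(length(candidate) == S, length(w_a) == 2L * S)
  scores <- as.vector(seed_heads %*% w_a[seq_len(S)]) +
    sum(candidate * w_a[S + seq_len(S)])
  a <- softmax_vec(scores)
  structure(as.vector(crossprod(seed_heads, a)), weights = a)
}

#' Hop-p SL preference response from a ripple hop
#'
#' For each triple (h_i, r_i, t_i) in the hop, the affinity of the
#' candidate gene n to the head under the relation,
#' `k_i = softmax_i( n' R_i h_i )`, weights the tail embeddings:
#' response `sum_i k_i t_i`.
#'
#' @param heads,rels,tails integer id vectors of equal length (one triple
#'   per position)
#' @param candidate numeric vector, the candidate gene embedding n
#' @param params list with `entity_embeddings` (n_ent x S) and
#'   `relation_matrices` (S x S x n_rel array)
#' @return numeric vector of length S (attribute `"weights"` holds k)
#' @export
hop_response <- function(heads, rels, tails, candidate, params) {
  stopifnot(length(heads) == length(rels), length(rels) == length(tails),
            length(heads) >= 1L)
  E <- params$entity_embeddings
  R <- params$relation_matrices
  scores <- vapply(seq_along(heads), function(i) {
    sum(candidate * (R[, , rels[i]] %*% E[heads[i], ]))
  }, 0)
  k <- softmax_vec(scores)
  structure(as.vector(crossprod(E[tails, , drop = FALSE], k)), weights = k)
}

#' Fuse the hop responses into the gene embedding
#'
#' Affine map of the concatenated responses: `m = concat(o^0..o^lp) %*% W_o
#' + b_o`, with no nonlinearity.
#'
#' @param stack list of `l_p + 1` response vectors of length S
#' @param W_o numeric matrix, `(l_p + 1) * S` rows by S columns
#' @param b_o numeric vector of length S
#' @return numeric vector of length S
#' @export
fuse_responses <- function(stack, W_o, b_o) {
  x <- unlist(stack, use.names = FALSE)
  if (length(x) != nrow(W_o)) {
    stop("response stack length ", length(x),
         " does not match fusion map with ", nrow(W_o), " rows")
  }
  as.vector(x %*% W_o) + b_o
}
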