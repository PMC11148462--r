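# KG hierarchy propagation: per-gene seed sets, p-hop frontiers, fixed-size
# ripple (triple) sets and fixed-size neighbor samples.
#
# All sampling is with replacement so every tensor has a fixed shape: each
# ripple hop holds exactly `size` triples and each neighbor sample exactly
# `k` entries. Genes with no training SL partner fall back to themselves as
# the seed; an empty hop frontier is filled with (seed, .self, seed)
# placeholder triples; an isolated entity is padded with (.self, itself).

#' Seed set of a gene: its known SL partners in the training positives
#'
#' @param gene_id entity id of the gene
#' @param train_positives an `sl_pairs` object (only label-1 rows are used)
#' @return list with `gene_id` and `seeds` (integer entity ids). When the
#'   gene has no positive training partner, `seeds` is the gene itself.
#' @export
seed_set <- function(gene_id, train_positives) {
  p <- train_positives$pairs
  p <- p[p$label == 1L, , drop = FALSE]
  seeds <- sort(unique(c(p$b[p$a == gene_id], p$a[p$b == gene_id])))
  if (length(seeds) == 0L) seeds <- gene_id
  list(gene_id = gene_id, seeds = seeds)
}

#' p-hop extended entity sets grown from a seed set
#'
#' Hop p is the set of tail entities of KG triples whose head lies in hop
#' p-1 (hop 0 = the seeds). Sets are not deduplicated across hops.
#'
#' @param kg a `kg` object
#' @param seed a seed set from [seed_set()]
#' @param l_p number of hops (>= 1)
#' @return list of `l_p` integer vectors
#' @export
extended_entity_sets <- function(kg, seed, l_p) {
  stopifnot(l_p >= 1L)
  out <- vector("list", l_p)
  frontier <- seed$seeds
  for (p in seq_len(l_p)) {
    tails <- integer(0)
    for (h in frontier) {
      nb <- kg$by_head[[h]]
      if (!is.null(nb)) tails <- c(tails, nb[, "tail"])
    }
    out[[p]] <- sort(unique(tails))
    frontier <- out[[p]]
  }
  out
}

# candidate triples (h, r, t) with h in `heads`; NULL when none
hop_candidates <- function(kg, heads) {
  hs <- heads[lengths(kg$by_head[heads]) > 0L]
  if (length(hs) == 0L) return(NULL)
  parts <- lapply(hs, function(h) cbind(head = h, kg$by_head[[h]]))
  do.call(rbind, parts)
}

#' Fixed-size ripple sets of a gene
#'
#' Hop p holds exactly `size` triples sampled uniformly with replacement
#' from the candidates whose head lies in the hop p-1 frontier. An empty
#' candidate set is replaced by `(seed, .self, seed)` placeholder triples
#' (seed = first seed entity), keeping shapes fixed.
#'
#' @param kg a `kg` object
#' @param seed a seed set from [seed_set()]
#' @param l_p number of hops
#' @param size triples per hop
#' @param seed_rng integer seed for the sampler
#' @return list with `gene_id`, `hops` (list of `size` x 3 matrices with
#'   columns head/rel/tail) and `l_p`
#' @export
ripple_sets <- function(kg, seed, l_p, size, seed_rng = 1L) {
  stopifnot(size >= 1L, l_p >= 1L)
  hops <- vector("list", l_p)
  frontier <- seed$seeds
  anchor <- seed$seeds[1]
  with_seed(seed_rng, {
    for (p in seq_len(l_p)) {
      cand <- hop_candidates(kg, frontier)
      if (is.null(cand)) {
        hops[[p]] <- matrix(c(rep(anchor, size), rep(kg$self_relation, size),
                              rep(anchor, size)), ncol = 3L,
                            dimnames = list(NULL, c("head", "rel", "tail")))
        frontier <- anchor
      } else {
        pick <- cand[sample.int(nrow(cand), size, replace = TRUE), , drop = FALSE]
        hops[[p]] <- pick[, c("head", "rel", "tail")]
        frontier <- sort(unique(cand[, "tail"]))
      }
    }
  })
  list(gene_id = seed$gene_id, hops = hops, l_p = l_p, size = size)
}

#' Fixed-size uniform neighbor sample of an entity
#'
#' Draws exactly `k` (relation, neighbor) entries uniformly with
#' replacement from the entity's adjacency (inverse edges included when the
#' KG was indexed with `add_inverse`). A degree-0 entity is padded with
#' `(.self, entity_id)`.
#'
#' @param kg a `kg` object
#' @param entity_id entity id
#' @param k sample size
#' @param seed_rng integer seed
#' @return list with `entity_id` and `neighbors`, a `k` x 2 matrix with
#'   columns rel/tail
#' @export
sample_neighbors <- function(kg, entity_id, k, seed_rng = 1L) {
  stopifnot(k >= 1L)
  nb <- kg$by_head[[entity_id]]
  if (is.null(nb) || nrow(nb) == 0L) {
    nb <- matrix(c(kg$self_relation, entity_id), 1L, 2L,
                 dimnames = list(NULL, c("rel", "tail")))
  }
  pick <- with_seed(seed_rng, sample.int(nrow(nb), k, replace = TRUE))
  list(entity_id = entity_id, neighbors = nb[pick, , drop = FALSE])
}

# Batched index tables used by the trainer ---------------------------------

# ripple index arrays for a vector of genes: per hop, size-column matrices
# of heads/rels/tails, rows = genes (row-major expansion happens later)
ripple_index <- function(kg, genes, adj, l_p, size, seed_rng) {
  nh <- length(genes)
  heads <- rels <- tails <- lapply(seq_len(l_p), function(p) matrix(0L, nh, size))
  with_seed(seed_rng, {
    for (i in seq_len(nh)) {
      g <- genes[i]
      partners <- adjacency_partners(adj, g)
      if (length(partners) == 0L) partners <- g
      frontier <- partners
      anchor <- partners[1]
      for (p in seq_len(l_p)) {
        cand <- hop_candidates(kg, frontier)
        if (is.null(cand)) {
          heads[[p]][i, ] <- anchor
          rels[[p]][i, ] <- kg$self_relation
          tails[[p]][i, ] <- anchor
          frontier <- anchor
        } else {
          pick <- cand[sample.int(nrow(cand), size, replace = TRUE), , drop = FALSE]
          heads[[p]][i, ] <- pick[, "head"]
          rels[[p]][i, ] <- pick[, "rel"]
          tails[[p]][i, ] <- pick[, "tail"]
          frontier <- sort(unique(cand[, "tail"]))
        }
      }
    }
  })
  list(heads = heads, rels = rels, tails = tails)
}

# sampled receptive field for the KG-side encoder: level j holds k^j
# (relation, entity) columns per center; level 0 is the center itself
neighbor_field <- function(kg, centers, k, n_levels, seed_rng) {
  nh <- length(centers)
  levels <- vector("list", n_levels)
  with_seed(seed_rng, {
    parents <- matrix(centers, nh, 1L)
    for (j in seq_len(n_levels)) {
      width <- ncol(parents) * k
      rel <- ent <- matrix(0L, nh, width)
      for (i in seq_len(nh)) {
        col <- 1L
        for (p in parents[i, ]) {
          nb <- kg$by_head[[p]]
          if (is.null(nb) || nrow(nb) == 0L) {
            nb <- matrix(c(kg$self_relation, p), 1L, 2L,
                         dimnames = list(NULL, c("rel", "tail")))
          }
          pick <- nb[sample.int(nrow(nb), k, replace = TRUE), , drop = FALSE]
          rel[i, col:(col + k - 1L)] <- pick[, "rel"]
          ent[i, col:(col + k - 1L)] <- pick[, "tail"]
          col <- col + k
        }
      }
      levels[[j]] <- list(rel = rel, ent = ent)
      parents <- ent
    }
  })
  levels
}
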