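# Data model and I/O for the knowledge graph and the labeled SL pairs.
#
# Entities and relations are mapped to integer ids in first-appearance
# order. KG edges are directed (head -> tail); because genes occur as tail
# entities in many biomedical relation types, an `add_inverse` flag (default
# on) also indexes every edge in the reverse direction under a distinct
# "<relation>_inv" id for propagation. A reserved `self` relation id is
# always appended to the relation vocabulary; it backs the degree-0 and
# empty-frontier fallbacks of the neighborhood module.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers never
#' perturb the global random stream.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

new_kg <- function(entities, relations, triples, add_inverse = TRUE) {
  n_rel_orig <- length(relations)
  rel_names <- relations
  if (add_inverse) rel_names <- c(rel_names, paste0(relations, "_inv"))
  rel_names <- c(rel_names, ".self")
  kg <- structure(list(
    entities = entities,
    relations = rel_names,
    n_relations_original = n_rel_orig,
    self_relation = length(rel_names),
    add_inverse = add_inverse,
    triples = triples
  ), class = "kg")
  kg$by_head <- kg_build_index(kg)
  kg
}

# adjacency index used for propagation: for every entity id a 2-column
# matrix (relation_id, tail_id); includes inverse edges when add_inverse
kg_build_index <- function(kg) {
  tr <- kg$triples
  h <- tr$head; r <- tr$rel; t <- tr$tail
  if (kg$add_inverse) {
    h <- c(h, tr$tail); r <- c(r, tr$rel + kg$n_relations_original); t <- c(t, tr$head)
  }
  idx <- vector("list", length(kg$entities))
  ord <- order(h)
  h <- h[ord]; r <- r[ord]; t <- t[ord]
  runs <- rle(h)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (j in seq_along(runs$values)) {
    idx[[runs$values[j]]] <- cbind(rel = r[starts[j]:ends[j]], tail = t[starts[j]:ends[j]])
  }
  idx
}

#' Load a knowledge graph from a 3-column TSV of triples
#'
#' Each non-empty line must be `head<TAB>relation<TAB>tail`. Vocabularies
#' are built in first-appearance order. With `header = "auto"` the first
#' row is treated as a header and skipped when its third field never
#' reappears as an entity elsewhere in the file.
#'
#' @param path path to the TSV file
#' @param add_inverse also index each edge in the reverse direction under a
#'   distinct relation id (default `TRUE`)
#' @param header `TRUE`, `FALSE` or `"auto"`
#' @return an object of class `kg`
#' @export
load_triples <- function(path, add_inverse = TRUE, header = "auto") {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty triples file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) {
    stop("malformed triple at line ", bad[1], ": expected 3 tab-separated fields, got ",
         lengths(parts)[bad[1]])
  }
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  skip <- isTRUE(header)
  if (identical(header, "auto") && nrow(m) > 1L) {
    # a first row is a header only if none of its fields recur in the data:
    # its third field is never reused as an entity, its first field neither,
    # and its second field is not reused as a relation
    ents <- c(m[-1, 1], m[-1, 3])
    skip <- !(m[1, 3] %in% ents) && !(m[1, 1] %in% ents) &&
      !(m[1, 2] %in% m[-1, 2])
  }
  if (skip) m <- m[-1, , drop = FALSE]
  if (nrow(m) == 0L) stop("no data rows in triples file: ", path)
  entities <- unique(c(rbind(m[, 1], m[, 3])))  # first-appearance order
  relations <- unique(m[, 2])
  eid <- stats::setNames(seq_along(entities), entities)
  rid <- stats::setNames(seq_along(relations), relations)
  triples <- data.frame(head = unname(eid[m[, 1]]),
                        rel = unname(rid[m[, 2]]),
                        tail = unname(eid[m[, 3]]))
  new_kg(entities, relations, triples, add_inverse = add_inverse)
}

#' Write a knowledge graph back to a triples TSV
#' @export
write_triples <- function(kg, path) {
  rel_orig <- kg$relations[seq_len(kg$n_relations_original)]
  utils::write.table(
    data.frame(kg$entities[kg$triples$head], rel_orig[kg$triples$rel],
               kg$entities[kg$triples$tail]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write entity and relation vocabularies as sidecar TSVs
#' @export
write_vocab <- function(kg, dir) {
  utils::write.table(data.frame(id = seq_along(kg$entities), name = kg$entities),
                     file.path(dir, "entities.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(id = seq_along(kg$relations), name = kg$relations),
                     file.path(dir, "relations.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @export
print.kg <- function(x, ...) {
  cat("Knowledge graph:", length(x$entities), "entities,",
      x$n_relations_original, "relations (",
      length(x$relations), "incl. inverse/self ),",
      nrow(x$triples), "triples\n")
  invisible(x)
}

kg_entity_id <- function(kg, names) {
  id <- match(names, kg$entities)
  stats::setNames(id, names)
}

# ---- SL pair sets ---------------------------------------------------------

#' Construct a labeled SL pair set
#'
#' Pairs are unordered and stored once with `a < b`. `gene_universe` is the
#' pool of candidate genes used for negative sampling.
#' @keywords internal
new_sl_pairs <- function(a, b, label, gene_universe, n_dropped = 0L) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  structure(list(pairs = data.frame(a = lo, b = hi, label = as.integer(label)),
                 gene_universe = sort(unique(gene_universe)),
                 n_dropped = n_dropped),
            class = "sl_pairs")
}

#' @export
print.sl_pairs <- function(x, ...) {
  cat("SL pair set:", nrow(x$pairs), "pairs (",
      sum(x$pairs$label == 1L), "positive /", sum(x$pairs$label == 0L),
      "negative ),", length(x$gene_universe), "genes")
  if (x$n_dropped > 0L) cat(";", x$n_dropped, "pairs dropped (gene not in KG)")
  cat("\n")
  invisible(x)
}

pair_key <- function(a, b, n) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  as.numeric(lo) * n + hi
}

#' Load labeled SL gene pairs from a 3-column TSV
#'
#' Format: `gene_a<TAB>gene_b<TAB>label` with label in \{0,1\}. Unordered
#' duplicates are collapsed; duplicates with conflicting labels are an
#' error. Pairs whose genes are absent from the KG entity vocabulary are
#' dropped and counted in `$n_dropped`.
#'
#' @param path path to the pairs TSV
#' @param kg a `kg` object; membership filter and id space
#' @return an object of class `sl_pairs`
#' @export
load_sl_pairs <- function(path, kg) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty SL pairs file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) stop("malformed pair at line ", bad[1])
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  # header row: third field is not even numeric (a numeric non-0/1 value is
  # a label error, not a header)
  if (is.na(suppressWarnings(as.numeric(m[1, 3])))) m <- m[-1, , drop = FALSE]
  if (nrow(m) == 0L) stop("no data rows in SL pairs file: ", path)
  if (!all(m[, 3] %in% c("0", "1"))) {
    stop("SL labels must be 0 or 1; offending value: ",
         m[which(!m[, 3] %in% c("0", "1"))[1], 3])
  }
  a <- match(m[, 1], kg$entities)
  b <- match(m[, 2], kg$entities)
  keep <- !is.na(a) & !is.na(b)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " SL pair(s) dropped: gene(s) absent from the KG")
  }
  a <- a[keep]; b <- b[keep]; label <- as.integer(m[keep, 3])
  if (any(a == b)) stop("self-pair (gene_a == gene_b) in SL pairs file")
  key <- pair_key(a, b, length(kg$entities))
  first <- !duplicated(key)
  agg <- tapply(label, key, function(x) length(unique(x)))
  if (any(agg > 1L)) {
    stop("conflicting labels for a duplicated unordered gene pair")
  }
  new_sl_pairs(a[first], b[first], label[first],
               gene_universe = unique(c(a, b)), n_dropped = n_dropped)
}

#' Uniform negative sampling of unknown gene pairs
#'
#' Draws exactly `nrow(positives)` label-0 pairs uniformly without
#' replacement from the unordered gene pairs over `gene_universe` that are
#' not among the positives. Deterministic given `seed`.
#'
#' @param positives an `sl_pairs` object containing only label-1 pairs
#' @param seed integer seed
#' @return an `sl_pairs` object with the positives and the sampled
#'   negatives combined
#' @export
sample_negatives <- function(positives, seed) {
  stopifnot(inherits(positives, "sl_pairs"), all(positives$pairs$label == 1L))
  uni <- positives$gene_universe
  U <- length(uni)
  if (U < 2L) stop("gene universe too small for negative sampling")
  n_pos <- nrow(positives$pairs)
  n_cand <- U * (U - 1) / 2
  if (n_cand - n_pos < n_pos) {
    stop("candidate space (", n_cand - n_pos,
         " unknown pairs) smaller than the number of positives (", n_pos, ")")
  }
  nent <- max(uni) + 1
  pos_key <- pair_key(positives$pairs$a, positives$pairs$b, nent)
  neg <- with_seed(seed, {
    if (n_cand <= 2e6) {
      idx <- utils::combn(uni, 2L)
      key <- pair_key(idx[1, ], idx[2, ], nent)
      free <- which(!(key %in% pos_key))
      pick <- sample(free, n_pos)
      cbind(idx[1, pick], idx[2, pick])
    } else {
      got <- numeric(0)
      out <- matrix(0L, 0L, 2L)
      while (nrow(out) < n_pos) {
        a <- sample(uni, 2L * n_pos, replace = TRUE)
        b <- sample(uni, 2L * n_pos, replace = TRUE)
        ok <- a != b
        a <- a[ok]; b <- b[ok]
        key <- pair_key(a, b, nent)
        ok <- !(key %in% pos_key) & !(key %in% got) & !duplicated(key)
        a <- a[ok]; b <- b[ok]; key <- key[ok]
        take <- seq_len(min(length(a), n_pos - nrow(out)))
        out <- rbind(out, cbind(pmin(a, b)[take], pmax(a, b)[take]))
        got <- c(got, key[take])
      }
      out
    }
  })
  new_sl_pairs(c(positives$pairs$a, neg[, 1]),
               c(positives$pairs$b, neg[, 2]),
               c(positives$pairs$label, rep(0L, n_pos)),
               gene_universe = uni, n_dropped = positives$n_dropped)
}

subset_pairs <- function(pairs, idx) {
  new_sl_pairs(pairs$pairs$a[idx], pairs$pairs$b[idx], pairs$pairs$label[idx],
               gene_universe = pairs$gene_universe)
}

new_data_split <- function(train, valid, test, mode, seed, n_discarded = 0L) {
  structure(list(train = train, valid = valid, test = test,
                 mode = mode, seed = seed, n_discarded = n_discarded),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("Data split (%s, seed %d): train %d / valid %d / test %d pairs\n",
              x$mode, x$seed, nrow(x$train$pairs), nrow(x$valid$pairs),
              nrow(x$test$pairs)))
  if (x$n_discarded > 0L)
    cat("  ", x$n_discarded, "boundary pairs discarded for gene disjointness\n")
  invisible(x)
}

#' Random train/valid/test split of SL pairs
#'
#' Sizes are floor-based on `ratios` for valid and test, with the remainder
#' assigned to train (so 10 pairs at 7:1:2 give exactly 7/1/2). All three
#' ratios must be strictly positive.
#'
#' @param pairs an `sl_pairs` object
#' @param ratios length-3 numeric (train, valid, test), summing to 1
#' @param seed integer seed
#' @return a `data_split`
#' @export
split_random <- function(pairs, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(length(ratios) == 3L)
  if (abs(sum(ratios) - 1) > 1e-9) stop("split ratios must sum to 1")
  if (any(ratios <= 0)) stop("all of train/valid/test must be nonempty: ratios must be > 0")
  n <- nrow(pairs$pairs)
  if (n < 3L) stop("need at least 3 pairs to split")
  perm <- with_seed(seed, sample.int(n))
  n_valid <- max(1L, floor(ratios[2] * n))
  n_test <- max(1L, floor(ratios[3] * n))
  i_valid <- perm[seq_len(n_valid)]
  i_test <- perm[n_valid + seq_len(n_test)]
  i_train <- perm[-seq_len(n_valid + n_test)]
  new_data_split(subset_pairs(pairs, i_train), subset_pairs(pairs, i_valid),
                 subset_pairs(pairs, i_test), mode = "random", seed = seed)
}

#' Gene-holdout split: test pairs involve held-out genes only
#'
#' A random gene subset H of size `ceiling(holdout_fraction * n_genes)` is
#' held out. Pairs with both genes in H form the test set; pairs straddling
#' the boundary (exactly one gene in H) are discarded (counted in
#' `$n_discarded`) so that no held-out gene ever reaches training; the
#' remaining pairs are split into train and valid by `valid_fraction`. The
#' gene sets of train and test pairs are therefore exactly disjoint.
#'
#' @param pairs an `sl_pairs` object
#' @param holdout_fraction fraction of genes to hold out, in (0, 1)
#' @param seed integer seed
#' @param valid_fraction fraction of the retained pairs used for
#'   validation (default 1/8, the 7:1 train:valid ratio)
#' @return a `data_split`
#' @export
split_leave_out_genes <- function(pairs, holdout_fraction, seed = 1L,
                                  valid_fraction = 1 / 8) {
  if (!(holdout_fraction > 0 && holdout_fraction < 1)) {
    stop("holdout_fraction must be strictly between 0 and 1")
  }
  genes <- sort(unique(c(pairs$pairs$a, pairs$pairs$b)))
  H <- with_seed(seed, sample(genes, ceiling(holdout_fraction * length(genes))))
  a_in <- pairs$pairs$a %in% H; b_in <- pairs$pairs$b %in% H
  in_test <- a_in & b_in
  straddle <- xor(a_in, b_in)
  rest <- which(!a_in & !b_in)
  if (!any(in_test)) stop("gene holdout produced an empty test set")
  if (length(rest) == 0L) stop("no training pairs left after gene holdout")
  n_valid <- max(1L, floor(valid_fraction * length(rest)))
  if (length(rest) <= n_valid) stop("no training pairs left after gene holdout")
  perm <- with_seed(seed + 1L, sample(rest))
  i_valid <- perm[seq_len(n_valid)]
  i_train <- perm[-seq_len(n_valid)]
  new_data_split(subset_pairs(pairs, i_train), subset_pairs(pairs, i_valid),
                 subset_pairs(pairs, which(in_test)),
                 mode = "leave_out_genes", seed = seed,
                 n_discarded = sum(straddle))
}

#' Symmetric 0/1 SL adjacency over gene ids
#'
#' Returns a named list mapping each gene id (as character) to the sorted
#' integer vector of its label-1 partners; genes without positive partners
#' are absent. The attribute `n_ones` holds the number of 1-cells of the
#' implied symmetric matrix (twice the positive pair count).
#'
#' @param pairs an `sl_pairs` object
#' @export
build_adjacency <- function(pairs) {
  pos <- pairs$pairs[pairs$pairs$label == 1L, , drop = FALSE]
  adj <- list()
  if (nrow(pos) > 0L) {
    src <- c(pos$a, pos$b); dst <- c(pos$b, pos$a)
    sp <- split(dst, src)
    adj <- lapply(sp, function(v) sort(unique(v)))
  }
  attr(adj, "n_ones") <- 2L * nrow(pos)
  adj
}

#' Partners of a gene in an adjacency mapping
#' @keywords internal
adjacency_partners <- function(adj, gene) {
  p <- adj[[as.character(gene)]]
  if (is.null(p)) integer(0) else p
}

#' Mask gene-gene KG edges incident to evaluation pairs
#'
#' Removes from the propagation index every KG triple (in either direction)
#' whose head and tail form one of the given gene pairs, so that evaluation
#' labels cannot leak into propagation through equivalent KG edges.
#'
#' @param kg a `kg` object
#' @param pairs an `sl_pairs` object with the pairs to mask
#' @return a `kg` with a filtered propagation index
#' @export
mask_pair_edges <- function(kg, pairs) {
  keys <- pair_key(pairs$pairs$a, pairs$pairs$b, length(kg$entities))
  tr <- kg$triples
  drop <- pair_key(tr$head, tr$tail, length(kg$entities)) %in% keys
  if (!any(drop)) return(kg)
  kg$triples <- tr[!drop, , drop = FALSE]
  kg$by_head <- kg_build_index(kg)
  kg
}
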