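# Synthetic typed knowledge graph with planted, recoverable SL structure.
#
# Genes belong to latent functional modules; each module owns a small pool
# of typed entities (pathway-like, process-like, ...). A gene's KG edges
# go mostly to its module pool, so genes of one module share typed
# neighbors. SL labels are then drawn with probability
# logistic(beta * |shared typed neighbors| + logit(baseline_rate)), which
# makes shared KG neighborhood the causal mediator of synthetic lethality:
# a trivial shared-neighbor scorer can verify the signal exists, and the
# encoders are needed to recover it for genes held out of training.

#' Configuration of the synthetic KG generator
#'
#' @param n_genes number of genes
#' @param n_other_entities number of non-gene entities
#' @param n_entity_types total entity types including genes (default 5)
#' @param n_relations relation types; the last is a gene-gene relation,
#'   the second-to-last points entity -> gene, the rest gene -> entity
#' @param edges_per_entity mean typed out-degree of a gene (Poisson)
#' @param n_sl_pairs total labeled pairs after class balancing
#' @param signal_strength beta, the logistic coefficient on the shared
#'   typed-neighbor count
#' @param baseline_rate P(SL) for a pair with no shared neighbors
#' @param n_modules number of latent gene modules
#' @param module_pool_size typed entities owned by each module
#' @param module_affinity probability a gene edge targets its module pool
#' @param seed generator seed
#' @return list of class `synth_config`
#' @export
synth_config <- function(n_genes = 200L, n_other_entities = 800L,
                         n_entity_types = 5L, n_relations = 8L,
                         edges_per_entity = 7, n_sl_pairs = 2000L,
                         signal_strength = 2, baseline_rate = 0.02,
                         n_modules = 8L, module_pool_size = 10L,
                         module_affinity = 0.8, seed = 42L) {
  cfg <- list(n_genes = n_genes, n_other_entities = n_other_entities,
              n_entity_types = n_entity_types, n_relations = n_relations,
              edges_per_entity = edges_per_entity, n_sl_pairs = n_sl_pairs,
              signal_strength = signal_strength, baseline_rate = baseline_rate,
              n_modules = n_modules, module_pool_size = module_pool_size,
              module_affinity = module_affinity, seed = seed)
  counts <- c("n_genes", "n_other_entities", "n_entity_types", "n_relations",
              "n_sl_pairs", "n_modules", "module_pool_size")
  for (f in counts) if (cfg[[f]] < 1) stop(f, " must be >= 1")
  if (!(baseline_rate > 0 && baseline_rate < 1)) {
    stop("baseline_rate must be strictly between 0 and 1")
  }
  if (n_entity_types < 2L) stop("need at least one non-gene entity type")
  if (n_relations < 3L) stop("need at least 3 relation types")
  if (n_modules * module_pool_size > n_other_entities) {
    stop("module pools exceed the number of non-gene entities")
  }
  structure(cfg, class = "synth_config")
}

synth_type_names <- function(n) {
  base <- c("pathway", "process", "compound", "disease", "anatomy",
            "function", "component", "symptom", "class")
  if (n - 1L > length(base)) base <- c(base, paste0("type", seq_len(n)))
  base[seq_len(n - 1L)]
}

#' Generate a typed multi-relational knowledge graph
#'
#' Non-gene entities cycle over the non-gene types; each gene draws
#' Poisson(`edges_per_entity`) typed edges to non-gene entities (mostly
#' into its module pool), each non-gene entity draws Poisson(1)
#' entity->gene edges, and each gene draws Poisson(1) gene-gene edges
#' (module-biased). Deterministic given `config$seed`.
#'
#' @param config a [synth_config()]
#' @return a `kg` object; generator bookkeeping (module assignments,
#'   expected triple count) is stored in `attr(, "synth_meta")`
#' @export
generate_kg <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  nG <- config$n_genes; nO <- config$n_other_entities
  types <- synth_type_names(config$n_entity_types)
  nT <- length(types)
  gene_names <- sprintf("g%04d", seq_len(nG))
  other_type <- rep_len(seq_len(nT), nO)
  other_names <- sprintf("%s_%04d", types[other_type], seq_len(nO))
  # relations: gene->entity typed (1..nR-2), entity->gene, gene-gene
  nR <- config$n_relations
  rel_fwd <- seq_len(nR - 2L)
  rel_fwd_type <- rep_len(seq_len(nT), length(rel_fwd))
  rel_names <- c(sprintf("gene_%s_%s", c("participates", "located", "affects",
                                         "expressed", "bound", "annotated",
                                         "linked")[rep_len(seq_len(7L), length(rel_fwd))],
                         types[rel_fwd_type]),
                 "associates_gene", "interacts_gene")
  gene_module <- rep_len(seq_len(config$n_modules), nG)
  pool_of <- function(m) ((m - 1L) * config$module_pool_size) + seq_len(config$module_pool_size)

  with_seed(config$seed, {
    heads <- integer(0); rels <- integer(0); tails <- integer(0)
    # gene -> typed entity edges (module-biased)
    for (g in seq_len(nG)) {
      deg <- stats::rpois(1L, config$edges_per_entity)
      if (deg == 0L) next
      in_pool <- stats::runif(deg) < config$module_affinity
      tgt <- integer(deg)
      tgt[in_pool] <- sample(pool_of(gene_module[g]), sum(in_pool), replace = TRUE)
      tgt[!in_pool] <- sample.int(nO, sum(!in_pool), replace = TRUE)
      # relation compatible with the target's type
      rl <- vapply(other_type[tgt], function(tt) {
        ok <- rel_fwd[rel_fwd_type == tt]
        if (length(ok) == 0L) rel_fwd[1L] else ok[sample.int(length(ok), 1L)]
      }, 0L)
      heads <- c(heads, rep(g, deg)); rels <- c(rels, rl); tails <- c(tails, nG + tgt)
    }
    # entity -> gene edges
    for (o in seq_len(nO)) {
      deg <- stats::rpois(1L, 1)
      if (deg == 0L) next
      tgt <- sample.int(nG, deg, replace = TRUE)
      heads <- c(heads, rep(nG + o, deg)); rels <- c(rels, rep(nR - 1L, deg))
      tails <- c(tails, tgt)
    }
    # gene -> gene edges (module-biased)
    for (g in seq_len(nG)) {
      deg <- stats::rpois(1L, 1)
      if (deg == 0L) next
      same <- which(gene_module == gene_module[g] & seq_len(nG) != g)
      in_mod <- stats::runif(deg) < config$module_affinity
      tgt <- integer(deg)
      if (any(in_mod) && length(same) > 0L) {
        tgt[in_mod] <- same[sample.int(length(same), sum(in_mod), replace = TRUE)]
      } else {
        in_mod[] <- FALSE
      }
      tgt[!in_mod] <- sample.int(nG, sum(!in_mod), replace = TRUE)
      keep <- tgt != g
      if (!any(keep)) next
      heads <- c(heads, rep(g, sum(keep))); rels <- c(rels, rep(nR, sum(keep)))
      tails <- c(tails, tgt[keep])
    }
    kg <- new_kg(c(gene_names, other_names), rel_names,
                 data.frame(head = heads, rel = rels, tail = tails))
    attr(kg, "synth_meta") <- list(
      config = config, gene_ids = seq_len(nG), gene_module = gene_module,
      other_type = other_type,
      expected_triples = nG * config$edges_per_entity + nO * 1 + nG * 1)
    kg
  })
}

# typed out-neighbor sets of each gene (tails of original gene->entity and
# gene->gene edges, plus gene-gene in-edges to keep the relation symmetric)
gene_neighbor_sets <- function(kg, gene_ids) {
  tr <- kg$triples
  nbr <- lapply(gene_ids, function(g) {
    out <- tr$tail[tr$head == g]
    inn <- tr$head[tr$tail == g & tr$head %in% gene_ids]
    sort(unique(c(out, inn)))
  })
  names(nbr) <- gene_ids
  nbr
}

#' Shared typed-neighbor counts for gene pairs
#'
#' The trivial baseline scorer for the planted SL signal: the number of KG
#' neighbors two genes share.
#'
#' @param kg a `kg` object
#' @param pairs an `sl_pairs` object or data.frame with columns a, b
#' @return integer vector of shared-neighbor counts
#' @export
shared_neighbor_counts <- function(kg, pairs) {
  if (inherits(pairs, "sl_pairs")) pairs <- pairs$pairs
  genes <- sort(unique(c(pairs$a, pairs$b)))
  nbr <- gene_neighbor_sets(kg, genes)
  vapply(seq_len(nrow(pairs)), function(i) {
    length(intersect(nbr[[as.character(pairs$a[i])]],
                     nbr[[as.character(pairs$b[i])]]))
  }, 0L)
}

#' Plant balanced SL labels mediated by shared KG neighborhoods
#'
#' Candidate pairs (every within-module pair plus random cross-module
#' pairs) receive `P(label = 1) = logistic(signal_strength * shared +
#' logit(baseline_rate))`; classes are then balanced by subsampling the
#' majority class down to `n_sl_pairs / 2` each.
#'
#' @param kg a KG from [generate_kg()]
#' @param config the same [synth_config()]
#' @return an `sl_pairs` object with `n_sl_pairs` balanced pairs
#' @export
plant_sl_pairs <- function(kg, config) {
  meta <- attr(kg, "synth_meta")
  if (is.null(meta)) stop("kg was not produced by generate_kg()")
  nG <- config$n_genes
  gene_module <- meta$gene_module
  within <- do.call(rbind, lapply(seq_len(config$n_modules), function(m) {
    g <- which(gene_module == m)
    if (length(g) < 2L) return(NULL)
    t(utils::combn(g, 2L))
  }))
  with_seed(config$seed + 1L, {
    n_cross <- max(2L * config$n_sl_pairs, nrow(within))
    ca <- sample.int(nG, n_cross, replace = TRUE)
    cb <- sample.int(nG, n_cross, replace = TRUE)
    keep <- ca != cb
    cand <- rbind(within, cbind(pmin(ca, cb)[keep], pmax(ca, cb)[keep]))
    cand <- cand[!duplicated(pair_key(cand[, 1], cand[, 2], nG + 1L)), , drop = FALSE]
    shared <- shared_neighbor_counts(
      kg, data.frame(a = cand[, 1], b = cand[, 2]))
    p1 <- stats::plogis(config$signal_strength * shared +
                          stats::qlogis(config$baseline_rate))
    lab <- as.integer(stats::runif(length(p1)) < p1)
    n_half <- config$n_sl_pairs %/% 2L
    pos <- which(lab == 1L); neg <- which(lab == 0L)
    if (length(pos) < n_half || length(neg) < n_half) {
      stop("cannot reach ", config$n_sl_pairs, " balanced pairs: drew ",
           length(pos), " positives and ", length(neg), " negatives")
    }
    pick <- c(sample(pos, n_half), sample(neg, n_half))
    out <- new_sl_pairs(cand[pick, 1], cand[pick, 2], lab[pick],
                        gene_universe = seq_len(nG))
    # pre-balance draws, kept for calibration checks of the label mechanism
    attr(out, "calibration") <- data.frame(shared = shared, label = lab)
    out
  })
}

#' Generate the complete synthetic benchmark (KG + balanced SL pairs)
#'
#' @param config a [synth_config()]
#' @return list with `kg`, `pairs`, `config`
#' @export
synth_benchmark <- function(config = synth_config()) {
  kg <- generate_kg(config)
  list(kg = kg, pairs = plant_sl_pairs(kg, config), config = config)
}

#' Write a synthetic benchmark to TSV files plus a provenance JSON
#'
#' Writes `triples.tsv`, `pairs.tsv`, `entities.tsv`, `relations.tsv` and
#' `provenance.json` (the generator configuration and seed) into `dir`.
#' @param bench a list from [synth_benchmark()]
#' @param dir output directory (created if missing)
#' @export
synth_write <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_triples(bench$kg, file.path(dir, "triples.tsv"))
  write_vocab(bench$kg, dir)
  p <- bench$pairs$pairs
  utils::write.table(
    data.frame(bench$kg$entities[p$a], bench$kg$entities[p$b], p$label),
    file.path(dir, "pairs.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(unclass(bench$config), file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
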