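# Cross-validation harnesses (random and gene-holdout) and ablations.

# fold assignment of pairs (random mode) or genes (leave_out mode)
fold_ids <- function(n, folds, seed_rng) {
  with_seed(seed_rng, sample(rep_len(seq_len(folds), n)))
}

cv_fold_split <- function(pairs, mode, fold, fold_of, gene_fold = NULL,
                          seed_rng = 1L, valid_fraction = 1 / 8) {
  p <- pairs$pairs
  if (mode == "random") {
    in_test <- fold_of == fold
    rest <- which(!in_test)
    n_discard <- 0L
  } else {
    H <- as.integer(names(gene_fold)[gene_fold == fold])
    a_in <- p$a %in% H; b_in <- p$b %in% H
    in_test <- a_in & b_in
    rest <- which(!a_in & !b_in)
    n_discard <- sum(xor(a_in, b_in))
  }
  if (length(rest) < 2L || !any(in_test)) return(NULL)
  n_valid <- max(1L, floor(valid_fraction * length(rest)))
  perm <- with_seed(seed_rng, sample(rest))
  new_data_split(subset_pairs(pairs, perm[-seq_len(n_valid)]),
                 subset_pairs(pairs, perm[seq_len(n_valid)]),
                 subset_pairs(pairs, which(in_test)),
                 mode = if (mode == "random") "random" else "leave_out_genes",
                 seed = seed_rng, n_discarded = n_discard)
}

#' k-fold cross-validation (random or gene-holdout), with optional inner
#' hyperparameter selection
#'
#' In `random` mode the pairs are partitioned into `folds` random folds;
#' each fold in turn is the test set and the remainder is split 7:1 into
#' train and validation. In `leave_out` mode the *genes* are partitioned:
#' a fold's test set holds the pairs whose genes BOTH belong to the
#' held-out gene fold, pairs straddling the boundary are discarded, and
#' the gene sets of train and test are disjoint. When `grid` lists more
#' than one
#' candidate, each candidate is trained per fold and the one with the best
#' validation AUC is evaluated on the fold's test set (nested selection).
#'
#' @param kg a `kg` object
#' @param pairs an `sl_pairs` object (both classes present)
#' @param config base [sl_config()]
#' @param mode `"random"` or `"leave_out"`
#' @param folds number of folds (default 5)
#' @param grid optional named list of config-field vectors, expanded to
#'   the candidate grid
#' @param verbose print fold progress
#' @return list of class `sl_cv_report` with per-fold records and
#'   mean/sd summaries
#' @export
run_sl_cv <- function(kg, pairs, config = sl_config(), mode = c("random", "leave_out"),
                      folds = 5L, grid = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  candidates <- if (is.null(grid) || length(grid) == 0L) list(config) else {
    gg <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(gg)), function(i) {
      ov <- as.list(gg[i, , drop = FALSE])
      cfg <- unclass(config); cfg[names(ov)] <- ov
      do.call(sl_config, cfg)
    })
  }
  p <- pairs$pairs
  seed0 <- as.integer(config$seed)
  fold_of <- gene_fold <- NULL
  if (mode == "random") {
    fold_of <- fold_ids(nrow(p), folds, seed0)
  } else {
    genes <- sort(unique(c(p$a, p$b)))
    gene_fold <- stats::setNames(fold_ids(length(genes), folds, seed0), genes)
  }
  records <- list()
  for (fold in seq_len(folds)) {
    split <- cv_fold_split(pairs, mode, fold, fold_of, gene_fold,
                           seed_rng = seed0 + 1000L * fold)
    if (is.null(split) || length(unique(split$test$pairs$label)) < 2L) {
      warning("fold ", fold, " skipped: test set missing a class")
      next
    }
    best <- NULL
    for (ci in seq_along(candidates)) {
      cfg <- candidates[[ci]]
      model <- train_sl_model(kg, split, cfg, verbose = FALSE)
      vauc <- max(model$training_log$valid_auc)
      if (is.null(best) || vauc > best$vauc) {
        best <- list(model = model, vauc = vauc, ci = ci)
      }
    }
    met <- evaluate_sl_model(best$model, split$test)
    if (verbose) {
      message(sprintf("fold %d: test AUC %.4f AUPR %.4f (config %d)",
                      fold, met$auc_roc, met$aupr, best$ci))
    }
    records[[length(records) + 1L]] <- data.frame(
      fold = fold, auc_roc = met$auc_roc, aupr = met$aupr,
      n_test = met$n_pairs, config_id = best$ci,
      n_discarded = split$n_discarded)
  }
  if (length(records) == 0L) stop("all folds skipped")
  tab <- do.call(rbind, records)
  structure(list(mode = mode, folds = tab,
                 auc_mean = mean(tab$auc_roc), auc_sd = stats::sd(tab$auc_roc),
                 aupr_mean = mean(tab$aupr), aupr_sd = stats::sd(tab$aupr),
                 n_candidates = length(candidates)),
            class = "sl_cv_report")
}

#' @export
print.sl_cv_report <- function(x, ...) {
  cat(sprintf("%s CV over %d folds: AUC %.4f +/- %.4f | AUPR %.4f +/- %.4f\n",
              x$mode, nrow(x$folds), x$auc_mean,
              ifelse(is.na(x$auc_sd), 0, x$auc_sd),
              x$aupr_mean, ifelse(is.na(x$aupr_sd), 0, x$aupr_sd)))
  invisible(x)
}

#' Train and evaluate an ablated model variant
#'
#' Variants: `no_ripple` (gene embeddings come straight from the entity
#' table), `no_enhance` (entity enhancement skipped), `no_attention_fuse`
#' (uniform fusion weights), `drop_relation_types` (listed relations
#' removed from the KG before propagation). Training and evaluation are
#' otherwise unchanged.
#'
#' @param kg a `kg` object
#' @param split a `data_split`
#' @param variant one of the variant names above (or `"full"`)
#' @param config base [sl_config()]
#' @param drop_relations relation names for `drop_relation_types`
#' @return list with `variant`, `metrics` on the split's test set, `model`
#' @export
ablate_sl <- function(kg, split, variant, config = sl_config(),
                      drop_relations = character(0)) {
  cfg <- unclass(config)
  cfg$variant <- variant
  cfg$drop_relations <- drop_relations
  cfg <- do.call(sl_config, cfg)
  model <- train_sl_model(kg, split, cfg)
  list(variant = variant, metrics = evaluate_sl_model(model, split$test),
       model = model)
}
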