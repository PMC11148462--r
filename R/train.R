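# Training loop: Adam on the cross-entropy + L2 + label-smoothness
# objective, with per-epoch negative resampling, per-epoch redraw of the
# ripple/neighbor samples, and early stopping on validation AUC.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# per-positive corruption: for each train positive (a, b), draw a partner
# uniformly from the universe avoiding self and known train positives
draw_negatives <- function(pos, universe, nent, seed_rng) {
  pos_key <- pair_key(pos$a, pos$b, nent)
  n <- nrow(pos)
  with_seed(seed_rng, {
    a <- pos$a
    b <- sample(universe, n, replace = TRUE)
    bad <- which(b == a | pair_key(a, b, nent) %in% pos_key)
    guard <- 0L
    while (length(bad) > 0L && guard < 100L) {
      b[bad] <- sample(universe, length(bad), replace = TRUE)
      bad <- bad[b[bad] == a[bad] | pair_key(a[bad], b[bad], nent) %in% pos_key]
      guard <- guard + 1L
    }
    if (length(bad) > 0L) stop("could not draw enough negative partners")
    data.frame(a = a, b = b, label = 0L)
  })
}

#' Train the SL prediction model
#'
#' Optimizes all trainable tensors with Adam under the combined objective
#' (mean cross-entropy over the training positives and an equal number of
#' per-epoch resampled negatives, L2, label smoothness). Validation AUC is
#' evaluated every epoch; training stops early when it fails to improve
#' for `early_stop_patience` evaluations, and the best-validation
#' parameters are returned. Fully deterministic given `config$seed`.
#'
#' @param kg a `kg` object
#' @param split a `data_split`
#' @param config an [sl_config()]
#' @param verbose print per-epoch progress to stderr
#' @return an object of class `sl_model` with `params`, `config`,
#'   `training_log`, the training adjacency and the propagation KG
#' @export
train_sl_model <- function(kg, split, config = sl_config(), verbose = FALSE) {
  stopifnot(inherits(kg, "kg"), inherits(split, "data_split"))
  if (config$variant == "drop_relation_types" && length(config$drop_relations) > 0L) {
    kg <- drop_relation_types(kg, config$drop_relations)
  }
  kg_prop <- kg
  if (isTRUE(config$mask_eval_edges)) {
    ev <- new_sl_pairs(c(split$valid$pairs$a, split$test$pairs$a),
                       c(split$valid$pairs$b, split$test$pairs$b),
                       c(split$valid$pairs$label, split$test$pairs$label),
                       gene_universe = split$train$gene_universe)
    kg_prop <- mask_pair_edges(kg_prop, ev)
  }
  adj <- build_adjacency(split$train)
  genes <- sort(unique(c(split$train$pairs$a, split$train$pairs$b,
                         split$valid$pairs$a, split$valid$pairs$b,
                         split$test$pairs$a, split$test$pairs$b)))
  universe <- sort(unique(c(split$train$gene_universe, genes)))
  nent <- length(kg$entities)
  pos <- split$train$pairs[split$train$pairs$label == 1L, , drop = FALSE]
  if (nrow(pos) == 0L) stop("no positive training pairs")
  params <- init_params(nent, length(kg$relations), config)
  state <- adam_init(params)
  seed0 <- as.integer(config$seed)

  data <- NULL
  best <- list(auc = -Inf, params = params, epoch = 0L)
  wait <- 0L
  log <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    if (is.null(data) || isTRUE(config$resample_per_epoch)) {
      data <- build_model_data(kg_prop, genes, adj, config,
                               seed_rng = seed0 + 13L * epoch)
    }
    neg <- draw_negatives(pos, universe, nent, seed_rng = seed0 + 29L * epoch)
    batch_pairs <- rbind(pos, neg)
    if (isTRUE(config$augment_orders)) {
      batch_pairs <- rbind(batch_pairs,
                           data.frame(a = batch_pairs$b, b = batch_pairs$a,
                                      label = batch_pairs$label))
    }
    ord <- with_seed(seed0 + 31L * epoch, sample.int(nrow(batch_pairs)))
    batch_pairs <- batch_pairs[ord, , drop = FALSE]
    ce_sum <- 0
    nb <- 0L
    for (start in seq(1L, nrow(batch_pairs), by = config$batch_size)) {
      idx <- start:min(start + config$batch_size - 1L, nrow(batch_pairs))
      bm <- batch_pairs$a[idx]; bn <- batch_pairs$b[idx]
      by <- batch_pairs$label[idx]
      fw <- forward_pairs(params, data, bm, bn, config)
      loss <- ad_bce_logits(fw$logits, by)
      ce_b <- ad_value(loss)[1, 1]
      if (!is.finite(ce_b)) stop("loss diverged (NaN) at epoch ", epoch)
      grads <- ad_backward(loss)
      if (config$l2_weight > 0) {
        for (nm in names(grads)) {
          grads[[nm]] <- grads[[nm]] + 2 * config$l2_weight * params[[nm]]
        }
      }
      up <- adam_step(params, grads, state, config$learning_rate)
      params <- up$params; state <- up$state
      ce_sum <- ce_sum + ce_b
      nb <- nb + 1L
    }
    ce <- ce_sum / nb
    l2 <- sum(vapply(params, function(p) sum(p^2), 0))
    ls <- if (config$ls_weight > 0) {
      ls_penalty(kg_prop, split$train, params, config,
                 seed_rng = seed0 + 37L * epoch)
    } else 0
    valid_scores <- score_pairs(params, data, split$valid$pairs$a,
                                split$valid$pairs$b, config)
    vauc <- auc_roc(valid_scores, split$valid$pairs$label)
    log[[epoch]] <- data.frame(
      epoch = epoch, ce = ce,
      loss = ce + config$l2_weight * l2 + config$ls_weight * ls,
      l2 = l2, ls = ls, valid_auc = vauc)
    if (verbose) {
      message(sprintf("epoch %2d  ce %.4f  valid AUC %.4f", epoch, ce, vauc))
    }
    if (vauc > best$auc + 1e-12) {
      best <- list(auc = vauc, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
  }

  structure(list(params = best$params, config = config,
                 training_log = do.call(rbind, log[!vapply(log, is.null, TRUE)]),
                 best_epoch = best$epoch, adj = adj, kg = kg_prop,
                 genes = genes),
            class = "sl_model")
}

#' @export
print.sl_model <- function(x, ...) {
  n <- nrow(x$training_log)
  cat(sprintf(
    "SL model: dim %d, %d epochs trained (best epoch %d, valid AUC %.4f)\n",
    x$config$dim, n, x$best_epoch, max(x$training_log$valid_auc)))
  invisible(x)
}

#' Score gene pairs with a trained model
#'
#' Rebuilds deterministic ripple/neighbor samples (from the model's stored
#' training adjacency) for any genes not seen before, and scores the pairs
#' in batches. Scores are symmetric in pair order.
#'
#' @param model an `sl_model`
#' @param pairs an `sl_pairs` object or a 2-column matrix/data.frame of
#'   gene ids
#' @param kg optional propagation `kg`; defaults to the one in the model
#' @return numeric vector of SL probabilities
#' @export
predict_sl_model <- function(model, pairs, kg = NULL) {
  if (inherits(pairs, "sl_pairs")) pairs <- pairs$pairs
  if (is.null(kg)) kg <- model$kg
  cfg <- model$config
  genes <- sort(unique(c(model$genes, pairs$a, pairs$b)))
  data <- build_model_data(kg, genes, model$adj, cfg,
                           seed_rng = as.integer(cfg$seed) + 997L)
  out <- numeric(nrow(pairs))
  for (start in seq(1L, nrow(pairs), by = cfg$batch_size)) {
    idx <- start:min(start + cfg$batch_size - 1L, nrow(pairs))
    out[idx] <- score_pairs(model$params, data, pairs$a[idx], pairs$b[idx], cfg)
  }
  out
}

#' Remove relation types (and their triples) from a KG
#'
#' @param kg a `kg` object
#' @param relations character vector of relation names to drop; unknown
#'   names are ignored, an empty vector is a no-op
#' @export
drop_relation_types <- function(kg, relations) {
  if (length(relations) == 0L) return(kg)
  rid <- match(relations, kg$relations[seq_len(kg$n_relations_original)])
  rid <- rid[!is.na(rid)]
  if (length(rid) == 0L) return(kg)
  kg$triples <- kg$triples[!(kg$triples$rel %in% rid), , drop = FALSE]
  kg$by_head <- kg_build_index(kg)
  kg
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint stores the named parameter arrays, the configuration and
#' the training log; reloading reproduces identical scores.
#' @param model an `sl_model`
#' @param path file path
#' @export
sl_save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname sl_save_model
#' @export
sl_load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "sl_model"))
  m
}
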