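# Model configuration with the reference hyperparameter defaults.

#' Model configuration
#'
#' Returns the full hyperparameter set with reference defaults: batch size
#' 512, learning rate 6e-5, embedding dimension 128, 2 ripple hops, depth 2
#' and width 3 for the discrepancy contrastive layer, L2 and
#' label-smoothness weights 1e-8, Adam, 8 sampled neighbors and 8 ripple
#' triples per hop, early-stopping patience 5. Any field can be overridden
#' by name; unknown names are an error.
#'
#' @param ... named overrides of the defaults listed below
#' @return a list of class `sl_config`
#' @details Additional switches beyond the core hyperparameters:
#' \describe{
#'   \item{aggregator}{entity-enhancement aggregator: one of `"sum"`,
#'     `"concat"`, `"pool"`, `"top_k"` (default `"top_k"`)}
#'   \item{k_top}{kept coordinates in top_k mode; default `ceiling(dim/2)`}
#'   \item{depth_agg_mode}{aggregator used by the depth mixing step
#'     (default `"top_k"`)}
#'   \item{relation_matrix}{`"full"` S x S relation matrices (as stated) or
#'     `"diag"` for memory-constrained runs}
#'   \item{augment_orders}{also present each training pair in swapped
#'     order. The pair encoder is exactly symmetric in the two genes, so
#'     this only duplicates work; default `FALSE`}
#'   \item{resample_per_epoch}{redraw ripple/neighbor samples each epoch}
#'   \item{mask_eval_edges}{remove gene-gene KG edges that coincide with
#'     validation/test pairs from propagation}
#'   \item{variant}{`"full"` or an ablation: `"no_ripple"`, `"no_enhance"`,
#'     `"no_attention_fuse"`, `"drop_relation_types"`}
#'   \item{drop_relations}{relation names removed from the KG by the
#'     `drop_relation_types` variant}
#'   \item{ls_sample_genes}{genes sampled per epoch to estimate the
#'     label-smoothness term (it is scaled to the eligible-gene count)}
#' }
#' @export
sl_config <- function(...) {
  cfg <- list(
    dim = 128L,
    batch_size = 512L,
    learning_rate = 6e-5,
    p_hop = 2L,
    depth = 2L,
    width = 3L,
    l2_weight = 1e-8,
    ls_weight = 1e-8,
    optimizer = "adam",
    n_samples = 8L,
    ripple_set_size = 8L,
    aggregator = "top_k",
    k_top = NULL,
    depth_agg_mode = "top_k",
    epochs = 20L,
    early_stop_patience = 5L,
    seed = 1L,
    hidden1 = NULL,
    hidden2 = NULL,
    relation_matrix = "full",
    augment_orders = FALSE,
    resample_per_epoch = TRUE,
    mask_eval_edges = TRUE,
    fuse_condition_on_pool = FALSE,
    variant = "full",
    drop_relations = character(0),
    ls_sample_genes = 32L
  )
  over <- list(...)
  if (length(over) > 0L) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0L) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  if (is.null(cfg$k_top)) cfg$k_top <- as.integer(ceiling(cfg$dim / 2))
  if (is.null(cfg$hidden1)) cfg$hidden1 <- cfg$dim
  if (is.null(cfg$hidden2)) cfg$hidden2 <- cfg$dim
  num_pos <- c("dim", "batch_size", "p_hop", "depth", "width",
               "n_samples", "ripple_set_size", "epochs", "early_stop_patience",
               "k_top", "hidden1", "hidden2")
  for (f in num_pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) stop("config field ", f, " must be positive")
  }
  # a zero step size is legitimate (it freezes the parameters)
  if (!is.numeric(cfg$learning_rate) || cfg$learning_rate < 0) {
    stop("config field learning_rate must be >= 0")
  }
  if (cfg$l2_weight < 0 || cfg$ls_weight < 0) stop("regularization weights must be >= 0")
  if (cfg$k_top > cfg$dim) stop("k_top must not exceed dim")
  stopifnot(cfg$aggregator %in% c("sum", "concat", "pool", "top_k"),
            cfg$depth_agg_mode %in% c("sum", "concat", "pool", "top_k"),
            cfg$relation_matrix %in% c("full", "diag"),
            cfg$optimizer == "adam",
            cfg$variant %in% c("full", "no_ripple", "no_enhance",
                               "no_attention_fuse", "drop_relation_types"))
  structure(cfg, class = "sl_config")
}

#' Scaled-down configuration for the synthetic benchmark
#'
#' The reference hyperparameters target a multi-million-edge biomedical
#' KG; on the 200-gene synthetic benchmark the model is scaled down to
#' embedding dimension 16 (depth 2, width 2, batch 64, learning rate 1e-2,
#' at most 20 epochs) so a full training run takes seconds on one CPU.
#'
#' @param seed model seed
#' @param ... further [sl_config()] overrides
#' @export
synth_protocol_config <- function(seed = 1L, ...) {
  sl_config(dim = 16L, depth = 2L, width = 2L, p_hop = 2L,
            batch_size = 64L, learning_rate = 1e-2, epochs = 20L,
            n_samples = 8L, ripple_set_size = 8L,
            early_stop_patience = 5L, seed = seed, ...)
}

#' Read a model configuration from a YAML file
#'
#' Keys match the field names of [sl_config()].
#' @param path YAML file
#' @param ... further overrides applied on top of the file
#' @export
read_sl_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  do.call(sl_config, vals)
}
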