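# Shared fixtures: tiny hand-built KGs, random KGs, random parameter sets,
# and a lazily built (then cached) synthetic benchmark for the training
# and acceptance tests.

.fixtures <- new.env(parent = emptyenv())

# the full-size synthetic benchmark (200 genes / 800 entities / 2000 pairs)
get_bench <- function() {
  if (is.null(.fixtures$bench)) {
    .fixtures$bench <- synth_benchmark(synth_config())
  }
  .fixtures$bench
}

# a small benchmark for fast training tests
get_tiny_bench <- function() {
  if (is.null(.fixtures$tiny)) {
    .fixtures$tiny <- synth_benchmark(synth_config(
      n_genes = 60L, n_other_entities = 160L, n_modules = 4L,
      module_pool_size = 8L, n_sl_pairs = 400L, seed = 7L))
  }
  .fixtures$tiny
}

write_tsv_file <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# chain KG a -> b -> c (directed only, no inverse edges)
chain_kg <- function() {
  load_triples(write_tsv_file(c("a\tr\tb", "b\tr\tc")), add_inverse = FALSE)
}

# random directed KG over n_ent entities and n_rel relations
random_kg <- function(n_ent, n_rel, n_edges, seed = 1L, add_inverse = FALSE) {
  set.seed(seed)
  h <- sample.int(n_ent, n_edges, replace = TRUE)
  r <- sample.int(n_rel, n_edges, replace = TRUE)
  t <- sample.int(n_ent, n_edges, replace = TRUE)
  lines <- sprintf("e%03d\trel%02d\te%03d", h, r, t)
  load_triples(write_tsv_file(unique(lines)), add_inverse = add_inverse)
}

rand_mat <- function(nr, nc, scale = 1) {
  matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
}

# random parameter sets for the single-instance encoder ops
rand_attention_params <- function(S, H1 = S, H2 = S) {
  list(W1 = rand_mat(2 * S, H1), b1 = rand_mat(1, H1),
       W2 = rand_mat(H1, H2), b2 = rand_mat(1, H2),
       W3 = rand_mat(H2, 1), b3 = rand_mat(1, 1))
}

rand_enhance_params <- function(S, mode, k_top = max(1L, S %/% 2L)) {
  input_dim <- if (mode %in% c("concat", "top_k")) 2L * S else S
  list(W_e = rand_mat(input_dim, S), b_e = rand_mat(1, S),
       mode = mode, k_top = k_top)
}

rand_fuse_params <- function(S, condition_on_pool = FALSE, uniform = FALSE) {
  list(w6 = rand_mat(S, 1), W6 = rand_mat(S, S), W7 = rand_mat(S, S),
       b4 = rand_mat(1, S), W_pool = rand_mat(S, S), b_pool = rand_mat(1, S),
       condition_on_pool = condition_on_pool, uniform = uniform)
}

rand_ripple_params <- function(n_ent, n_rel, S) {
  list(entity_embeddings = rand_mat(n_ent, S),
       relation_matrices = array(stats::rnorm(S * S * n_rel), c(S, S, n_rel)))
}
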