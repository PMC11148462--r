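# KG and SL-pair I/O, negative sampling, splits and adjacency.

test_that("triples parse with first-appearance vocabularies and a complete index", {
  path <- write_tsv_file(c("g1\tinteracts\tg2", "g1\tparticipates\tp1",
                           "d1\tassociates\tg1"))
  kg <- load_triples(path, add_inverse = FALSE)
  expect_equal(kg$entities, c("g1", "g2", "p1", "d1"))
  expect_equal(kg$n_relations_original, 3L)
  expect_equal(nrow(kg$triples), 3L)
  expect_equal(nrow(kg$by_head[[1]]), 2L)  # g1 heads two triples
  # with inverse indexing g1 also receives d1 -> g1 reversed
  kg2 <- load_triples(path, add_inverse = TRUE)
  expect_equal(nrow(kg2$by_head[[1]]), 3L)
  expect_equal(kg2$relations[kg2$self_relation], ".self")
})

test_that("malformed and empty triple files are rejected with line numbers", {
  expect_error(load_triples(write_tsv_file(c("a\tr\tb", "a\tb"))), "line 2")
  expect_error(load_triples(write_tsv_file(character(0))), "empty")
})

test_that("header rows are auto-detected and a round trip preserves the edge multiset", {
  with_header <- write_tsv_file(c("head\trelation\ttail", "a\tr\tb", "b\tr\tc"))
  kg <- load_triples(with_header, add_inverse = FALSE)
  expect_equal(nrow(kg$triples), 2L)
  expect_false("head" %in% kg$entities)

  kg0 <- random_kg(12, 3, 30, seed = 4)
  out <- tempfile(fileext = ".tsv")
  write_triples(kg0, out)
  kg1 <- load_triples(out, add_inverse = FALSE)
  as_tuples <- function(kg) {
    sort(sprintf("%s|%s|%s", kg$entities[kg$triples$head],
                 kg$relations[kg$triples$rel], kg$entities[kg$triples$tail]))
  }
  expect_equal(as_tuples(kg1), as_tuples(kg0))
})

test_that("SL pairs deduplicate unordered, drop unknown genes, reject conflicts", {
  kg <- load_triples(write_tsv_file(c("g1\tr\tg2", "g2\tr\tg3")),
                     add_inverse = FALSE)
  p <- load_sl_pairs(write_tsv_file(c("g1\tg2\t1", "g2\tg1\t1")), kg)
  expect_equal(nrow(p$pairs), 1L)
  expect_equal(p$n_dropped, 0L)

  expect_message(
    p2 <- load_sl_pairs(write_tsv_file(c("g1\tgX\t1")), kg), "dropped")
  expect_equal(nrow(p2$pairs), 0L)
  expect_equal(p2$n_dropped, 1L)

  expect_error(load_sl_pairs(write_tsv_file(c("g1\tg2\t1", "g1\tg2\t0")), kg),
               "conflicting")
  expect_error(load_sl_pairs(write_tsv_file(c("g1\tg2\t2")), kg), "label")
})

test_that("negative sampling is balanced, collision-free and seed-deterministic", {
  pos <- slripple:::new_sl_pairs(c(1L, 2L, 5L), c(3L, 4L, 6L), c(1L, 1L, 1L),
                                 gene_universe = 1:20)
  all1 <- sample_negatives(pos, seed = 9L)
  expect_equal(sum(all1$pairs$label == 0L), 3L)
  key <- function(p) slripple:::pair_key(p$pairs$a, p$pairs$b, 21L)
  negs <- all1$pairs[all1$pairs$label == 0L, ]
  expect_length(intersect(slripple:::pair_key(negs$a, negs$b, 21L),
                          key(pos)), 0L)
  expect_identical(sample_negatives(pos, seed = 9L), all1)

  # a 100-gene universe: different seeds give different draws w.h.p.
  big <- slripple:::new_sl_pairs(1:30, 71:100, rep(1L, 30), gene_universe = 1:100)
  n1 <- sample_negatives(big, seed = 1L)
  n2 <- sample_negatives(big, seed = 2L)
  expect_false(identical(n1$pairs, n2$pairs))

  # 1 positive over a 3-gene universe: the negative comes from the 2
  # remaining pairs
  one <- slripple:::new_sl_pairs(1L, 2L, 1L, gene_universe = 1:3)
  oneneg <- sample_negatives(one, seed = 3L)$pairs
  oneneg <- oneneg[oneneg$label == 0L, ]
  expect_true(3L %in% c(oneneg$a, oneneg$b))

  # candidate space too small
  full <- slripple:::new_sl_pairs(c(1L, 1L, 2L), c(2L, 3L, 3L), rep(1L, 3),
                                  gene_universe = 1:3)
  expect_error(sample_negatives(full, seed = 1L), "smaller")
})

test_that("random splits give floor-based 7:1:2 sizes and are disjoint and reproducible", {
  pairs <- slripple:::new_sl_pairs(rep(1:10, each = 2), rep(11:20, 2),
                                   rep_len(c(1L, 0L), 20), gene_universe = 1:20)
  ten <- slripple:::subset_pairs(pairs, 1:10)
  sp <- split_random(ten, c(0.7, 0.1, 0.2), seed = 5L)
  expect_equal(nrow(sp$train$pairs), 7L)
  expect_equal(nrow(sp$valid$pairs), 1L)
  expect_equal(nrow(sp$test$pairs), 2L)

  expect_error(split_random(ten, c(1, 0, 0), seed = 1L), "nonempty")
  expect_error(split_random(slripple:::subset_pairs(pairs, 1:2), seed = 1L),
               "at least 3")

  sp2 <- split_random(pairs, seed = 5L)
  sp3 <- split_random(pairs, seed = 5L)
  expect_identical(sp2$train$pairs, sp3$train$pairs)
  key <- function(p) slripple:::pair_key(p$pairs$a, p$pairs$b, 21L)
  expect_length(intersect(key(sp2$train), key(sp2$test)), 0L)
  expect_length(intersect(key(sp2$train), key(sp2$valid)), 0L)
  expect_length(intersect(key(sp2$valid), key(sp2$test)), 0L)
})

test_that("gene-holdout splits keep train and test gene sets disjoint", {
  expect_error(split_leave_out_genes(get_tiny_bench()$pairs, 0), "between 0 and 1")
  set.seed(31)
  # synthetic 50-gene pair set (unique unordered pairs)
  a <- sample.int(50, 300, replace = TRUE)
  b <- sample.int(50, 300, replace = TRUE)
  ok <- which(a != b & !duplicated(slripple:::pair_key(a, b, 51)))
  pairs <- slripple:::new_sl_pairs(a[ok], b[ok], rep_len(c(1L, 0L), length(ok)),
                                   gene_universe = 1:50)
  sp <- split_leave_out_genes(pairs, 0.3, seed = 2L)
  train_genes <- unique(c(sp$train$pairs$a, sp$train$pairs$b,
                          sp$valid$pairs$a, sp$valid$pairs$b))
  test_genes <- unique(c(sp$test$pairs$a, sp$test$pairs$b))
  expect_length(intersect(train_genes, test_genes), 0L)
  expect_gt(sp$n_discarded, 0L)
  # all pairs accounted for
  expect_equal(nrow(sp$train$pairs) + nrow(sp$valid$pairs) +
                 nrow(sp$test$pairs) + sp$n_discarded, length(ok))
})

test_that("adjacency is symmetric, excludes negatives, and counts 1-cells", {
  p <- slripple:::new_sl_pairs(c(1L, 2L), c(2L, 3L), c(1L, 0L),
                               gene_universe = 1:3)
  adj <- build_adjacency(p)
  expect_equal(slripple:::adjacency_partners(adj, 1L), 2L)
  expect_equal(slripple:::adjacency_partners(adj, 2L), 1L)
  expect_length(slripple:::adjacency_partners(adj, 3L), 0L)

  set.seed(8)
  a <- sample.int(30, 20); b <- sample.int(30, 20) + 30L
  lab <- rbinom(20, 1, 0.5)
  rp <- slripple:::new_sl_pairs(a, b, lab, gene_universe = 1:60)
  radj <- build_adjacency(rp)
  # brute-force count of 1-cells in the implied symmetric matrix
  A <- matrix(0L, 60, 60)
  for (i in seq_len(20)) if (lab[i] == 1L) {
    A[a[i], b[i]] <- 1L; A[b[i], a[i]] <- 1L
  }
  expect_equal(attr(radj, "n_ones"), sum(A))
})
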