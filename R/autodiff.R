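# Minimal reverse-mode automatic differentiation on a linear tape.
#
# Values are numeric matrices (vectors are 1-column or 1-row matrices, 3D
# arrays are allowed for relation matrices). A "var" is a handle
# list(tape, id); node payloads live in tape$nodes[[id]]. Backward walks the
# tape in reverse creation order, so any composition of the ops below is
# differentiable without explicit graph topology bookkeeping.

#' Create an empty autodiff tape
#'
#' @return An environment holding the tape state.
#' @keywords internal
ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp
}

ad_push <- function(tape, value, parents = integer(0), bk = NULL, name = NULL) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- list(value = value, parents = parents, bk = bk, name = name)
  tape$n <- n
  list(tape = tape, id = n)
}

#' @keywords internal
ad_value <- function(x) x$tape$nodes[[x$id]]$value

#' Create a leaf variable (parameter or constant input)
#'
#' @param tape tape from [ad_tape()]
#' @param value numeric matrix or array
#' @param name optional parameter name; named leaves get their gradients
#'   collected by [ad_backward()]
#' @keywords internal
ad_leaf <- function(tape, value, name = NULL) {
  ad_push(tape, value, name = name)
}

#' Backward pass: gradients of a scalar root w.r.t. all named leaves
#'
#' @param root a var holding a 1x1 value
#' @return named list of gradients (same shapes as the leaf values)
#' @keywords internal
ad_backward <- function(root) {
  tape <- root$tape
  n <- tape$n
  grads <- vector("list", n)
  grads[[root$id]] <- matrix(1, 1L, 1L)
  out <- list()
  for (id in seq.int(n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tape$nodes[[id]]
    if (!is.null(node$name)) {
      out[[node$name]] <- if (is.null(out[[node$name]])) g else out[[node$name]] + g
    }
    if (length(node$parents) > 0L) {
      pg <- node$bk(g)
      for (j in seq_along(node$parents)) {
        p <- node$parents[j]
        if (is.null(pg[[j]])) next
        grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
      }
    }
  }
  out
}

# ---- elementwise and linear ops ------------------------------------------

ad_matmul <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_push(a$tape, A %*% B, c(a$id, b$id), function(g) {
    list(g %*% t(B), crossprod(A, g))
  })
}

ad_add <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_push(a$tape, A + B, c(a$id, b$id), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_push(a$tape, A - B, c(a$id, b$id), function(g) list(g, -g))
}

ad_emul <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_push(a$tape, A * B, c(a$id, b$id), function(g) list(g * B, g * A))
}

ad_scale <- function(a, s) {
  A <- ad_value(a)
  ad_push(a$tape, A * s, a$id, function(g) list(g * s))
}

# add a 1 x K bias row to every row of an N x K matrix
ad_addbias <- function(x, b) {
  X <- ad_value(x); B <- ad_value(b)
  ad_push(x$tape, sweep(X, 2L, as.vector(B), "+"), c(x$id, b$id), function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

ad_sigmoid <- function(x) {
  V <- 1 / (1 + exp(-ad_value(x)))
  ad_push(x$tape, V, x$id, function(g) list(g * V * (1 - V)))
}

ad_tanh <- function(x) {
  V <- tanh(ad_value(x))
  ad_push(x$tape, V, x$id, function(g) list(g * (1 - V^2)))
}

ad_relu <- function(x) {
  X <- ad_value(x)
  V <- pmax(X, 0)
  ad_push(x$tape, V, x$id, function(g) list(g * (X > 0)))
}

# row-wise softmax of an N x K matrix (max-shifted for stability)
ad_softmax_rows <- function(x) {
  X <- ad_value(x)
  E <- exp(X - apply(X, 1L, max))
  S <- E / rowSums(E)
  ad_push(x$tape, S, x$id, function(g) {
    list((g - rowSums(g * S)) * S)
  })
}

ad_concat_cols <- function(vars) {
  vals <- lapply(vars, ad_value)
  widths <- vapply(vals, ncol, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_push(vars[[1]]$tape, do.call(cbind, vals),
          vapply(vars, function(v) v$id, 0L),
          function(g) {
            lapply(seq_along(widths), function(j) g[, starts[j]:ends[j], drop = FALSE])
          })
}

# ---- gather / scatter and batching helpers -------------------------------

# rows of an embedding table: value = table[idx, ]; backward scatter-adds
ad_gather <- function(tab, idx) {
  Tb <- ad_value(tab)
  ad_push(tab$tape, Tb[idx, , drop = FALSE], tab$id, function(g) {
    d <- matrix(0, nrow(Tb), ncol(Tb))
    rs <- rowsum(g, group = idx)
    d[as.integer(rownames(rs)), ] <- rs
    list(d)
  })
}

# batched relation-matrix product: out[i, ] = H[i, ] %*% t(R[, , rel[i]])
# (i.e. out_i = R_{rel_i} h_i for row vectors), R a S x S x n_rel array
ad_relmm <- function(h, rel_ids, rmat) {
  H <- ad_value(h); R <- ad_value(rmat)
  out <- matrix(0, nrow(H), ncol(H))
  split_idx <- split(seq_len(nrow(H)), rel_ids)
  for (r in names(split_idx)) {
    i <- split_idx[[r]]
    out[i, ] <- H[i, , drop = FALSE] %*% t(R[, , as.integer(r)])
  }
  ad_push(h$tape, out, c(h$id, rmat$id), function(g) {
    dH <- matrix(0, nrow(H), ncol(H))
    dR <- array(0, dim(R))
    for (r in names(split_idx)) {
      i <- split_idx[[r]]
      ri <- as.integer(r)
      dH[i, ] <- g[i, , drop = FALSE] %*% R[, , ri]
      dR[, , ri] <- crossprod(g[i, , drop = FALSE], H[i, , drop = FALSE])
    }
    list(dH, dR)
  })
}

# row-wise dot product of two N x S matrices -> N x 1
ad_rowdot <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_push(a$tape, matrix(rowSums(A * B), ncol = 1L), c(a$id, b$id), function(g) {
    gv <- as.vector(g)
    list(B * gv, A * gv)
  })
}

# multiply each row of X (N x S) by the scalar in w (N x 1)
ad_colmul <- function(x, w) {
  X <- ad_value(x); W <- as.vector(ad_value(w))
  ad_push(x$tape, X * W, c(x$id, w$id), function(g) {
    list(g * W, matrix(rowSums(g * X), ncol = 1L))
  })
}

# sum rows of X within consecutive groups; groups must cover 1..ngroups
ad_grouprowsum <- function(x, groups, ngroups) {
  X <- ad_value(x)
  V <- rowsum(X, group = groups)
  stopifnot(nrow(V) == ngroups)
  ad_push(x$tape, V, x$id, function(g) list(g[groups, , drop = FALSE]))
}

# N x K matrix -> (N*K) x 1 column, row-major (row i slot k -> row (i-1)K+k)
ad_flatten_rows <- function(x) {
  X <- ad_value(x)
  ad_push(x$tape, matrix(as.vector(t(X)), ncol = 1L), x$id, function(g) {
    list(matrix(as.vector(g), nrow = nrow(X), byrow = TRUE))
  })
}

# (N*K) x 1 column (row-major) -> N x K matrix
ad_unflatten_rows <- function(x, K) {
  X <- ad_value(x)
  N <- nrow(X) / K
  ad_push(x$tape, matrix(as.vector(X), nrow = N, byrow = TRUE), x$id, function(g) {
    list(matrix(as.vector(t(g)), ncol = 1L))
  })
}

# select (possibly repeated) rows of a non-leaf var; backward scatter-adds
ad_index_rows <- function(x, idx) {
  X <- ad_value(x)
  ad_push(x$tape, X[idx, , drop = FALSE], x$id, function(g) {
    d <- matrix(0, nrow(X), ncol(X))
    rs <- rowsum(g, group = idx)
    d[as.integer(rownames(rs)), ] <- rs
    list(d)
  })
}

# single column of a var as an N x 1 matrix
ad_col <- function(x, j) {
  X <- ad_value(x)
  ad_push(x$tape, X[, j, drop = FALSE], x$id, function(g) {
    d <- matrix(0, nrow(X), ncol(X))
    d[, j] <- g
    list(d)
  })
}

# elementwise maximum; ties route the gradient to the first argument
ad_pmax <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  take_a <- A >= B
  ad_push(a$tape, pmax(A, B), c(a$id, b$id), function(g) {
    list(g * take_a, g * (!take_a))
  })
}

# keep the k largest entries of each row (stable order(); ties -> lower
# index), zero the rest; gradient is masked identically
ad_topk_rows <- function(x, k) {
  X <- ad_value(x)
  mask <- topk_mask(X, k)
  ad_push(x$tape, X * mask, x$id, function(g) list(g * mask))
}

#' Row-wise top-k selection mask
#'
#' Returns a 0/1 matrix marking, in every row, the `k` largest entries
#' (ties broken in favour of the lower column index, positions preserved).
#' @keywords internal
topk_mask <- function(X, k) {
  if (k >= ncol(X)) return(matrix(1, nrow(X), ncol(X)))
  mask <- matrix(0, nrow(X), ncol(X))
  for (i in seq_len(nrow(X))) {
    mask[i, order(X[i, ], decreasing = TRUE)[seq_len(k)]] <- 1
  }
  mask
}

ad_sum <- function(x) {
  X <- ad_value(x)
  ad_push(x$tape, matrix(sum(X), 1L, 1L), x$id, function(g) {
    matrix(as.vector(g), nrow(X), ncol(X)) |> list()
  })
}

# mean binary cross-entropy from logits z (N x 1) against labels y (length N);
# numerically stable: L_i = max(z,0) - y*z + log1p(exp(-|z|))
ad_bce_logits <- function(z, y) {
  Z <- as.vector(ad_value(z))
  n <- length(Z)
  li <- pmax(Z, 0) - y * Z + log1p(exp(-abs(Z)))
  ad_push(z$tape, matrix(mean(li), 1L, 1L), z$id, function(g) {
    list(matrix((plogis(Z) - y) * as.vector(g) / n, ncol = 1L))
  })
}
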