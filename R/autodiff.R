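# Reverse-mode automatic differentiation on a flat tape.
#
# Values are numeric matrices. Each operation records its parents and a
# backward closure returning the gradient contribution for each parent.
# This is the substrate for both model architectures; input-gradient
# saliency reads the gradient accumulated at input leaf nodes.

# Node values, parent ids and backward closures live in hashed environments
# keyed by node id: assignment into a long R list would copy the whole list
# on every push, which dominated the training profile.
ad_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$vals <- new.env(hash = TRUE, parent = emptyenv())
  tape$parents <- new.env(hash = TRUE, parent = emptyenv())
  tape$backfns <- new.env(hash = TRUE, parent = emptyenv())
  tape$n <- 0L
  tape
}

ad_push <- function(tape, value, parents = NULL, backfn = NULL) {
  # force the promises before reading tape$n: evaluating `value` may itself
  # push nested nodes, and this node's id must come after theirs
  force(value); force(parents); force(backfn)
  n <- tape$n + 1L
  key <- as.character(n)
  assign(key, value, envir = tape$vals)
  if (!is.null(parents)) assign(key, parents, envir = tape$parents)
  if (!is.null(backfn)) assign(key, backfn, envir = tape$backfns)
  tape$n <- n
  n
}

ad_val <- function(tape, id) tape$vals[[as.character(id)]]

# leaf (constant or differentiable input/parameter); gradient flows to any
# leaf — whether it is consumed as a parameter or an input is the caller's
# concern.
ad_leaf <- function(tape, value) ad_push(tape, value)

ad_mm <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$vals[[as.character(a)]]; B <- tape$vals[[as.character(b)]]
  ad_push(tape, A %*% B, c(a, b), function(g) list(g %*% t(B), crossprod(A, g)))
}

ad_add <- function(tape, a, b) {
  force(a); force(b)
  ad_push(tape, tape$vals[[as.character(a)]] + tape$vals[[as.character(b)]], c(a, b), function(g) list(g, g))
}

# add a 1 x k bias row to every row of an n x k matrix
ad_add_bias <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$vals[[as.character(a)]]; B <- tape$vals[[as.character(b)]]
  ad_push(tape, sweep(A, 2L, as.vector(B), "+"), c(a, b),
          function(g) list(g, matrix(colSums(g), 1L)))
}

ad_sub <- function(tape, a, b) {
  force(a); force(b)
  ad_push(tape, tape$vals[[as.character(a)]] - tape$vals[[as.character(b)]], c(a, b), function(g) list(g, -g))
}

ad_mul <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$vals[[as.character(a)]]; B <- tape$vals[[as.character(b)]]
  ad_push(tape, A * B, c(a, b), function(g) list(g * B, g * A))
}

ad_scale <- function(tape, a, k) {
  force(a)
  ad_push(tape, tape$vals[[as.character(a)]] * k, a, function(g) list(g * k))
}

# elementwise multiply by a constant matrix (dropout masks)
ad_mul_const <- function(tape, a, m) {
  force(a)
  ad_push(tape, tape$vals[[as.character(a)]] * m, a, function(g) list(g * m))
}

ad_sigmoid <- function(tape, a) {
  force(a)
  y <- 1 / (1 + exp(-tape$vals[[as.character(a)]]))
  ad_push(tape, y, a, function(g) list(g * y * (1 - y)))
}

ad_tanh <- function(tape, a) {
  force(a)
  y <- tanh(tape$vals[[as.character(a)]])
  ad_push(tape, y, a, function(g) list(g * (1 - y * y)))
}

ad_relu <- function(tape, a) {
  force(a)
  v <- tape$vals[[as.character(a)]]
  y <- v * (v > 0)
  ad_push(tape, y, a, function(g) list(g * (v > 0)))
}

ad_slice_cols <- function(tape, a, idx) {
  force(a)
  A <- tape$vals[[as.character(a)]]
  nc <- ncol(A)
  ad_push(tape, A[, idx, drop = FALSE], a, function(g) {
    G <- matrix(0, nrow(g), nc)
    G[, idx] <- g
    list(G)
  })
}

ad_cbind <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$vals[[as.character(a)]]; B <- tape$vals[[as.character(b)]]
  ka <- ncol(A)
  ad_push(tape, cbind(A, B), c(a, b), function(g)
    list(g[, seq_len(ka), drop = FALSE], g[, -seq_len(ka), drop = FALSE]))
}

# concatenate many nodes column-wise in one tape node
ad_cbindn <- function(tape, ids) {
  force(ids)
  vals <- lapply(ids, function(i) tape$vals[[as.character(i)]])
  ks <- vapply(vals, ncol, 0L)
  ends <- cumsum(ks); starts <- ends - ks + 1L
  ad_push(tape, do.call(cbind, vals), ids, function(g) {
    lapply(seq_along(ids), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

# elementwise max over a list of equally shaped nodes (max pooling).
# Gradient is routed to the first argmax on exact ties.
ad_maxn <- function(tape, ids) {
  force(ids)
  vals <- lapply(ids, function(i) tape$vals[[as.character(i)]])
  m <- vals[[1L]]
  which_max <- matrix(1L, nrow(m), ncol(m))
  if (length(vals) > 1L) {
    for (k in 2L:length(vals)) {
      upd <- vals[[k]] > m
      m[upd] <- vals[[k]][upd]
      which_max[upd] <- k
    }
  }
  ad_push(tape, m, ids, function(g) {
    lapply(seq_along(ids), function(k) g * (which_max == k))
  })
}

ad_meann <- function(tape, ids) {
  force(ids)
  s <- tape$vals[[as.character(ids[1L])]]
  if (length(ids) > 1L) for (k in 2L:length(ids)) s <- s + tape$vals[[as.character(ids[k])]]
  nk <- length(ids)
  ad_push(tape, s / nk, ids, function(g) rep(list(g / nk), nk))
}

# sum of all entries -> 1x1; seeds per-sample output gradients for saliency
ad_sum_all <- function(tape, a) {
  force(a)
  A <- tape$vals[[as.character(a)]]
  ad_push(tape, matrix(sum(A), 1L, 1L), a,
          function(g) list(matrix(g[1L], nrow(A), ncol(A))))
}

# mean squared error against a constant response vector
ad_mse <- function(tape, pred, y) {
  force(pred)
  P <- tape$vals[[as.character(pred)]]
  r <- as.vector(P) - as.vector(y)
  n <- length(r)
  ad_push(tape, matrix(mean(r * r), 1L, 1L), pred,
          function(g) list(matrix(g[1L] * 2 * r / n, nrow(P), ncol(P))))
}

# Backpropagate from scalar node `from`; returns list of gradients indexed by
# node id (NULL where no gradient flowed). `wanted` may restrict which leaf
# gradients are retained to save memory.
ad_backward <- function(tape, from, wanted = NULL) {
  grads <- new.env(hash = TRUE, parent = emptyenv())
  assign(as.character(from), matrix(1, 1L, 1L), envir = grads)
  keep <- if (is.null(wanted)) NULL else as.character(wanted)
  for (id in from:1L) {
    key <- as.character(id)
    g <- grads[[key]]
    if (is.null(g)) next
    bf <- tape$backfns[[key]]
    if (is.null(bf)) next
    pg <- bf(g)
    ps <- tape$parents[[key]]
    for (k in seq_along(ps)) {
      pk <- as.character(ps[k])
      prev <- grads[[pk]]
      if (is.null(prev)) assign(pk, pg[[k]], envir = grads)
      else assign(pk, prev + pg[[k]], envir = grads)
    }
    if (!is.null(keep) && !(key %in% keep)) rm(list = key, envir = grads)
  }
  out <- vector("list", tape$n)
  got <- if (is.null(keep)) ls(grads, all.names = TRUE) else intersect(keep, ls(grads, all.names = TRUE))
  for (key in got) out[[as.integer(key)]] <- grads[[key]]
  out
}
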