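# A small reverse-mode automatic differentiation tape over dense matrices.
# Every neural component in the package (encoder, predictor, decoder) builds
# its forward pass on this tape; gradients come from ad_backward(). All
# values are matrices (scalars are 1x1). Internal API, exercised directly by
# the gradient-check tests.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  cap <- 256L
  tp$vals <- vector("list", cap)
  tp$parents <- vector("list", cap)
  tp$backs <- vector("list", cap)
  tp$leaf_name <- character(cap)
  tp$cap <- cap
  tp
}

.ad_grow <- function(tp) {
  cap <- tp$cap * 2L
  length(tp$vals) <- cap
  length(tp$parents) <- cap
  length(tp$backs) <- cap
  tp$leaf_name <- c(tp$leaf_name, character(cap - tp$cap))
  tp$cap <- cap
}

ad_push <- function(tp, val, parents = integer(0), back = NULL, name = "") {
  id <- tp$n + 1L
  if (id > tp$cap) .ad_grow(tp)
  tp$n <- id
  tp$vals[[id]] <- val
  tp$parents[[id]] <- parents
  tp$backs[[id]] <- back
  tp$leaf_name[[id]] <- name
  id
}

ad_val <- function(tp, id) {
  force(id)
  tp$vals[[id]]
}

ad_const <- function(tp, x) ad_push(tp, .as_mat(x))

ad_leaf <- function(tp, x, name) ad_push(tp, .as_mat(x), name = name)

.as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)

# ---- elementwise ------------------------------------------------------------

ad_add <- function(tp, a, b) {
  force(a); force(b)
  ad_push(tp, tp$vals[[a]] + tp$vals[[b]], c(a, b),
          function(g) list(g, g))
}

ad_sub <- function(tp, a, b) {
  force(a); force(b)
  ad_push(tp, tp$vals[[a]] - tp$vals[[b]], c(a, b),
          function(g) list(g, -g))
}

# value * s + t with numeric scalars s, t
ad_affine <- function(tp, a, s = 1, t = 0) {
  force(a)
  ad_push(tp, tp$vals[[a]] * s + t, a, function(g) list(g * s))
}

ad_mul <- function(tp, a, b) {
  force(a); force(b)
  va <- tp$vals[[a]]; vb <- tp$vals[[b]]
  ad_push(tp, va * vb, c(a, b), function(g) list(g * vb, g * va))
}

# scale the rows of M (n x d) by the column vector v (n x 1)
ad_colscale <- function(tp, m, v) {
  force(m); force(v)
  vm <- tp$vals[[m]]; vv <- as.vector(tp$vals[[v]])
  ad_push(tp, vm * vv, c(m, v), function(g) {
    list(g * vv, matrix(rowSums(g * vm), ncol = 1))
  })
}

ad_relu <- function(tp, a) {
  force(a)
  va <- tp$vals[[a]]
  ad_push(tp, pmax(va, 0), a, function(g) list(g * (va > 0)))
}

ad_leaky_relu <- function(tp, a, alpha = 0.01) {
  force(a)
  va <- tp$vals[[a]]
  pos <- va > 0
  ad_push(tp, pmax(va, 0) + alpha * pmin(va, 0), a,
          function(g) list(g * (pos + alpha * !pos)))
}

ad_elu <- function(tp, a) {
  force(a)
  va <- tp$vals[[a]]
  out <- va
  neg <- va <= 0
  out[neg] <- exp(va[neg]) - 1
  deriv <- matrix(1, nrow(va), ncol(va))
  deriv[neg] <- out[neg] + 1
  ad_push(tp, out, a, function(g) list(g * deriv))
}

ad_sigmoid <- function(tp, a) {
  force(a)
  s <- 1 / (1 + exp(-tp$vals[[a]]))
  ad_push(tp, s, a, function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(tp, a) {
  force(a)
  t <- tanh(tp$vals[[a]])
  ad_push(tp, t, a, function(g) list(g * (1 - t^2)))
}

ad_log <- function(tp, a, clamp = 1e-12) {
  force(a)
  va <- pmax(tp$vals[[a]], clamp)
  ad_push(tp, log(va), a, function(g) list(g / va))
}

# fixed multiplicative mask (dropout); mask is plain numeric
ad_mask <- function(tp, a, mask) {
  force(a)
  ad_push(tp, tp$vals[[a]] * mask, a, function(g) list(g * mask))
}

# ---- linear algebra ---------------------------------------------------------

ad_matmul <- function(tp, a, b) {
  force(a); force(b)
  va <- tp$vals[[a]]; vb <- tp$vals[[b]]
  ad_push(tp, va %*% vb, c(a, b), function(g) {
    list(g %*% t(vb), crossprod(va, g))
  })
}

# add a 1 x d bias row to every row of an n x d matrix
ad_add_bias <- function(tp, m, b) {
  force(m); force(b)
  vb <- tp$vals[[b]]
  vm <- tp$vals[[m]]
  ad_push(tp, vm + rep(as.vector(vb), each = nrow(vm)), c(m, b),
          function(g) list(g, matrix(colSums(g), nrow = 1)))
}

ad_cbind <- function(tp, a, b) {
  force(a); force(b)
  va <- tp$vals[[a]]; vb <- tp$vals[[b]]
  ka <- ncol(va)
  ad_push(tp, cbind(va, vb), c(a, b), function(g) {
    list(g[, seq_len(ka), drop = FALSE],
         g[, -seq_len(ka), drop = FALSE])
  })
}

ad_sum <- function(tp, a) {
  force(a)
  va <- tp$vals[[a]]
  ad_push(tp, matrix(sum(va)), a, function(g) {
    list(matrix(as.numeric(g), nrow(va), ncol(va)))
  })
}

ad_rowsums <- function(tp, a) {
  force(a)
  va <- tp$vals[[a]]
  ad_push(tp, matrix(rowSums(va), ncol = 1), a, function(g) {
    list(matrix(as.vector(g), nrow(va), ncol(va)))
  })
}

ad_gather_rows <- function(tp, m, idx) {
  force(m)
  vm <- tp$vals[[m]]
  ad_push(tp, vm[idx, , drop = FALSE], m, function(g) {
    list(.rowsum_full(g, idx, nrow(vm)))
  })
}

ad_gather_entries <- function(tp, m, rows, cols) {
  force(m)
  vm <- tp$vals[[m]]
  sel <- cbind(rows, cols)
  ad_push(tp, matrix(vm[sel], ncol = 1), m, function(g) {
    out <- matrix(0, nrow(vm), ncol(vm))
    # accumulate (duplicate (row,col) pairs are not used by callers)
    out[sel] <- out[sel] + as.vector(g)
    list(out)
  })
}

ad_slice_cols <- function(tp, m, cols) {
  force(m)
  vm <- tp$vals[[m]]
  ad_push(tp, vm[, cols, drop = FALSE], m, function(g) {
    out <- matrix(0, nrow(vm), ncol(vm))
    out[, cols] <- g
    list(out)
  })
}

.rowsum_full <- function(m, group, n) {
  out <- matrix(0, n, ncol(m))
  rs <- rowsum(m, group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# rows of M summed within groups; result has n_groups rows
ad_segment_sum <- function(tp, m, group, n_groups) {
  force(m)
  ad_push(tp, .rowsum_full(tp$vals[[m]], group, n_groups), m, function(g) {
    list(g[group, , drop = FALSE])
  })
}

# ---- softmax ----------------------------------------------------------------

ad_softmax_rows <- function(tp, a) {
  force(a)
  va <- tp$vals[[a]]
  e <- exp(va - apply(va, 1, max))
  p <- e / rowSums(e)
  ad_push(tp, p, a, function(g) {
    list((g - rowSums(g * p)) * p)
  })
}

# softmax of a score column vector within groups (e.g. attention over the
# in-neighborhood of each receiving atom)
ad_segment_softmax <- function(tp, s, group) {
  force(s)
  vs <- as.vector(tp$vals[[s]])
  m <- max(abs(vs))
  if (m > 30) {
    # per-group centering only when needed for exp() range safety
    gmax <- tapply(vs, group, max)
    vs <- vs - as.numeric(gmax[as.character(group)])
  }
  e <- exp(vs)
  gsum <- .groupsum_vec(e, group)
  w <- e / gsum[group]
  ad_push(tp, matrix(w, ncol = 1), s, function(g) {
    gv <- as.vector(g)
    inner <- .groupsum_vec(gv * w, group)
    list(matrix((gv - inner[group]) * w, ncol = 1))
  })
}

# dense group sums indexed by group id (groups are 1..n integers)
.groupsum_vec <- function(x, group) {
  out <- numeric(max(group))
  rs <- rowsum(x, group)
  out[as.integer(rownames(rs))] <- rs
  out
}

# ---- backward ---------------------------------------------------------------

# Backpropagate from scalar node `id`; returns the gradients of every named
# leaf as a named list of matrices.
ad_backward <- function(tp, id) {
  grads <- vector("list", tp$n)
  grads[[id]] <- matrix(1)
  for (k in seq.int(id, 1L)) {
    g <- grads[[k]]
    if (is.null(g)) next
    bk <- tp$backs[[k]]
    if (is.null(bk)) next
    pg <- bk(g)
    ps <- tp$parents[[k]]
    for (q in seq_along(ps)) {
      p <- ps[[q]]
      if (is.null(grads[[p]])) grads[[p]] <- pg[[q]]
      else grads[[p]] <- grads[[p]] + pg[[q]]
    }
  }
  out <- list()
  leafs <- which(nzchar(tp$leaf_name[seq_len(tp$n)]))
  for (k in leafs) {
    nm <- tp$leaf_name[[k]]
    g <- grads[[k]]
    if (is.null(g)) g <- matrix(0, nrow(tp$vals[[k]]), ncol(tp$vals[[k]]))
    if (is.null(out[[nm]])) out[[nm]] <- g else out[[nm]] <- out[[nm]] + g
  }
  out
}
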