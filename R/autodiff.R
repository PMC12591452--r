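#' @useDynLib frunet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# A minimal reverse-mode differentiation tape.
#
# Every op below accepts either plain numeric arrays or tape nodes. With plain
# arrays the op just computes its value, so the same network code serves both
# inference (no tape) and training (gradients). Nodes are lightweight lists
# (tape, id, value); the tape stores, per node, its parent ids and a closure
# mapping the upstream gradient to per-parent gradients.
# ---------------------------------------------------------------------------

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

is_node <- function(x) inherits(x, "ad_node")

ad_val <- function(x) if (is_node(x)) x$value else x

ad_leaf <- function(tape, value) {
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[tape$n]] <- list(parents = NULL, bwd = NULL)
  structure(list(tape = tape, id = tape$n, value = value), class = "ad_node")
}

# Register an op result. `inputs` is the list of op arguments in the order the
# bwd closure returns gradients for; non-node inputs get no gradient.
ad_op <- function(value, inputs, bwd) {
  tape <- NULL
  for (x in inputs) if (is_node(x)) { tape <- x$tape; break }
  if (is.null(tape)) return(value)
  parents <- vapply(inputs, function(x) if (is_node(x)) x$id else 0L, integer(1))
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[tape$n]] <- list(parents = parents, bwd = bwd)
  structure(list(tape = tape, id = tape$n, value = value), class = "ad_node")
}

# Backpropagate from a scalar node; returns a list of gradients indexed by
# node id (NULL where no gradient flows).
ad_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$value) == 1L)
  tape <- loss$tape
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- 1
  for (i in seq(loss$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tape$nodes[[i]]
    if (is.null(nd$parents)) next
    pg <- nd$bwd(g)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[j]
      if (p == 0L || is.null(pg[[j]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

# gradient of a broadcast operand: collapse to scalar when it was length 1
.reduce_grad <- function(g, v) if (length(v) == 1L) sum(g) else g

# --- elementwise arithmetic -------------------------------------------------

op_add <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_op(va + vb, list(a, b),
        function(g) list(.reduce_grad(g, va), .reduce_grad(g, vb)))
}

op_sub <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_op(va - vb, list(a, b),
        function(g) list(.reduce_grad(g, va), .reduce_grad(-g, vb)))
}

op_mul <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_op(va * vb, list(a, b),
        function(g) list(.reduce_grad(g * vb, va), .reduce_grad(g * va, vb)))
}

op_div <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_op(va / vb, list(a, b),
        function(g) list(.reduce_grad(g / vb, va),
                         .reduce_grad(-g * va / (vb * vb), vb)))
}

op_abs <- function(a) {
  va <- ad_val(a)
  ad_op(abs(va), list(a), function(g) list(g * sign(va)))
}

op_mean <- function(a) {
  va <- ad_val(a)
  ad_op(mean(va), list(a), function(g) {
    gg <- array(g / length(va), dim = dim(va) %||% length(va))
    list(gg)
  })
}

op_sigmoid <- function(a) {
  va <- ad_val(a)
  s <- 1 / (1 + exp(-va))
  ad_op(s, list(a), function(g) list(g * s * (1 - s)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- per-sample reductions (arrays [d1,d2,d3,C,N] -> vector [N]) ------------

op_sample_mean <- function(a) {
  va <- ad_val(a)
  d <- dim(va)
  m <- prod(d[1:4])
  val <- colMeans(matrix(va, nrow = m))
  ad_op(val, list(a), function(g) {
    list(array(rep(g / m, each = m), dim = d))
  })
}

# --- channel-parameterised activations/normalisation ------------------------

# multiply/add per channel: arr is [d1,d2,d3,C,N], vec has length C
.chan_expand <- function(vec, d) {
  array(rep(rep(vec, each = prod(d[1:3])), times = d[5]), dim = d)
}

.chan_sum <- function(arr, d) {
  m <- matrix(arr, nrow = prod(d[1:3]))
  # columns are (C x N); fold over N
  cs <- colSums(m)
  rowSums(matrix(cs, nrow = d[4]))
}

op_prelu <- function(a, slope) {
  va <- ad_val(a); vs <- ad_val(slope)
  d <- dim(va)
  se <- .chan_expand(vs, d)
  neg <- pmin(va, 0)
  val <- pmax(va, 0) + se * neg
  ad_op(val, list(a, slope), function(g) {
    dx <- g * ((va > 0) + se * (va <= 0))
    ds <- .chan_sum(g * neg, d)
    list(dx, ds)
  })
}

# Layer normalisation per sample over all channels and voxels, with a
# per-channel affine (gain, bias). eps stabilises the variance.
op_layernorm <- function(a, gain, bias, eps = 1e-5) {
  va <- ad_val(a); vg <- ad_val(gain); vb <- ad_val(bias)
  d <- dim(va)
  m <- prod(d[1:4])
  xm <- matrix(va, nrow = m)                 # m x N
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  va_r <- colMeans(xc * xc)
  inv <- 1 / sqrt(va_r + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  xhat_a <- array(xhat, dim = d)
  ge <- .chan_expand(vg, d)
  be <- .chan_expand(vb, d)
  val <- ge * xhat_a + be
  ad_op(val, list(a, gain, bias), function(g) {
    dgain <- .chan_sum(g * xhat_a, d)
    dbias <- .chan_sum(g, d)
    dxhat <- matrix(g * ge, nrow = m)        # m x N
    t1 <- colMeans(dxhat)
    t2 <- colMeans(dxhat * xhat)
    dx <- sweep(dxhat, 2, t1) - sweep(xhat, 2, t2, `*`)
    dx <- sweep(dx, 2, inv, `*`)
    list(array(dx, dim = d), dgain, dbias)
  })
}

# --- structural ops ---------------------------------------------------------

op_conv3d <- function(a, w, b, k) {
  va <- ad_val(a); vw <- ad_val(w); vb <- ad_val(b)
  d <- dim(va)
  cout <- ncol(vw)
  val <- cpp_conv3d_fwd(as.double(va), as.integer(d), vw, as.double(vb), as.integer(k))
  dim(val) <- c(d[1:3], cout, d[5])
  ad_op(val, list(a, w, b), function(g) {
    r <- cpp_conv3d_bwd(as.double(va), as.integer(d), vw, as.double(g), as.integer(k))
    dx <- r$dx; dim(dx) <- d
    list(dx, r$dw, as.double(r$db))
  })
}

op_convt2 <- function(a, w, b) {
  va <- ad_val(a); vw <- ad_val(w); vb <- ad_val(b)
  d <- dim(va)
  cout <- nrow(vw) / 8L
  val <- cpp_convt2_fwd(as.double(va), as.integer(d), vw, as.double(vb))
  dim(val) <- c(2L * d[1:3], cout, d[5])
  ad_op(val, list(a, w, b), function(g) {
    r <- cpp_convt2_bwd(as.double(va), as.integer(d), vw, as.double(g))
    dx <- r$dx; dim(dx) <- d
    list(dx, r$dw, as.double(r$db))
  })
}

op_maxpool2 <- function(a) {
  va <- ad_val(a)
  d <- dim(va)
  r <- cpp_maxpool2_fwd(as.double(va), as.integer(d))
  val <- r$out
  dim(val) <- c(d[1:3] %/% 2L, d[4], d[5])
  ad_op(val, list(a), function(g) {
    dx <- cpp_maxpool2_bwd(as.double(g), r$arg, length(va))
    dim(dx) <- d
    list(dx)
  })
}

op_concat_ch <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  da <- dim(va); db <- dim(vb)
  d <- da; d[4] <- da[4] + db[4]
  val <- array(0, dim = d)
  ia <- seq_len(da[4])
  val[, , , ia, ] <- va
  val[, , , -ia, ] <- vb
  ad_op(val, list(a, b), function(g) {
    list(g[, , , ia, , drop = FALSE], g[, , , -ia, , drop = FALSE])
  })
}

# Local box mean over a cubic (2h+1)^3 window, edge-truncated so border
# windows average only in-bounds voxels. Self-adjoint up to the count weights.
op_boxmean <- function(a, h) {
  va <- ad_val(a)
  d <- dim(va)
  counts <- cpp_box_counts(as.integer(d[1:3]), as.integer(h))
  val <- cpp_box_sum3(as.double(va), as.integer(d), as.integer(h)) / counts
  dim(val) <- d
  ad_op(val, list(a), function(g) {
    dx <- cpp_box_sum3(as.double(g / counts), as.integer(d), as.integer(h))
    dim(dx) <- d
    list(dx)
  })
}
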