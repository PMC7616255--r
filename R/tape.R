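# Reverse-mode autodiff tape.
#
# Every network in this package (encoder, conditional decoders, Wasserstein
# critic) is built from a small set of differentiable primitives defined here.
# The backward pass of each primitive is itself expressed in terms of these
# primitives, so gradients are ordinary graph nodes and a second backward pass
# through a gradient is well defined.  That second pass is what the WGAN-GP
# critic update needs: the penalty is a function of d(score)/d(input), and its
# gradient with respect to the critic weights requires differentiating through
# the first backward pass.
#
# Values are base R matrices (features are laid out as rows = voxel-within-
# sample x sample, columns = channels); constant structural operators (patch
# gathers, poolers, up/down-samplers) may be Matrix sparse matrices.

.tg <- new.env(parent = emptyenv())
.tg$id <- 0L

new_node <- function(value, parents = list(), bwd = NULL, rg = FALSE) {
  n <- new.env(parent = emptyenv())
  .tg$id <- .tg$id + 1L
  n$id <- .tg$id
  n$v <- value
  n$parents <- parents
  n$bwd <- bwd
  n$rg <- rg
  class(n) <- "tg_node"
  n
}

#' Create a tape leaf
#'
#' @param value numeric matrix (or Matrix sparse matrix for constants).
#' @param rg logical; does this leaf require a gradient (i.e. is it a
#'   trainable parameter or a differentiation target)?
#' @return a `tg_node`.
#' @keywords internal
tg_leaf <- function(value, rg = FALSE) new_node(value, rg = rg)

tg_const <- function(value) new_node(value)

is_node <- function(x) inherits(x, "tg_node")

vof <- function(x) if (is_node(x)) x$v else x

as_mat <- function(x) {
  if (is.matrix(x)) return(x)
  matrix(as.numeric(x), nrow = length(x), ncol = 1L)
}

# elementwise add; shapes equal, or one operand is a 1x1 scalar
tg_add <- function(a, b) {
  av <- a$v; bv <- b$v
  a_sc <- length(av) == 1L && length(bv) > 1L
  b_sc <- length(bv) == 1L && length(av) > 1L
  val <- if (a_sc) as.numeric(av) + bv else if (b_sc) av + as.numeric(bv) else av + bv
  out <- new_node(val, list(a, b), rg = a$rg || b$rg)
  out$bwd <- function(g) list(
    if (a$rg) { if (a_sc) tg_sum(g) else g },
    if (b$rg) { if (b_sc) tg_sum(g) else g })
  out
}

tg_sub <- function(a, b) tg_add(a, tg_scale(b, -1))

# elementwise multiply; shapes equal, or one operand is a 1x1 scalar
tg_mul <- function(a, b) {
  av <- a$v; bv <- b$v
  a_sc <- length(av) == 1L && length(bv) > 1L
  b_sc <- length(bv) == 1L && length(av) > 1L
  val <- if (a_sc) as.numeric(av) * bv else if (b_sc) av * as.numeric(bv) else av * bv
  out <- new_node(val, list(a, b), rg = a$rg || b$rg)
  out$bwd <- function(g) list(
    if (a$rg) { ga <- tg_mul(g, b); if (a_sc) tg_sum(ga) else ga },
    if (b$rg) { gb <- tg_mul(g, a); if (b_sc) tg_sum(gb) else gb })
  out
}

# multiply / shift by a plain numeric constant
tg_scale <- function(a, k) {
  out <- new_node(a$v * k, list(a), rg = a$rg)
  out$bwd <- function(g) list(if (a$rg) tg_scale(g, k))
  out
}

tg_shift <- function(a, k) {
  out <- new_node(a$v + k, list(a), rg = a$rg)
  out$bwd <- function(g) list(if (a$rg) g)
  out
}

tg_matmul <- function(a, b) {
  out <- new_node(a$v %*% b$v, list(a, b), rg = a$rg || b$rg)
  out$bwd <- function(g) list(
    if (a$rg) tg_matmul(g, tg_t(b)),
    if (b$rg) tg_xty(a, g))
  out
}

# t(a) %*% b without materializing the transpose
tg_xty <- function(a, b) {
  out <- new_node(crossprod(a$v, b$v), list(a, b), rg = a$rg || b$rg)
  out$bwd <- function(g) list(
    if (a$rg) tg_matmul(b, tg_t(g)),
    if (b$rg) tg_matmul(a, g))
  out
}

tg_t <- function(a) {
  out <- new_node(t(a$v), list(a), rg = a$rg)
  out$bwd <- function(g) list(if (a$rg) tg_t(g))
  out
}

tg_sum <- function(a) {
  av <- a$v
  out <- new_node(matrix(sum(av), 1L, 1L), list(a), rg = a$rg)
  out$bwd <- function(g) list(
    if (a$rg) tg_mul(g, tg_const(matrix(1, nrow(av), ncol(av)))))
  out
}

# elementwise power with constant exponent
tg_powc <- function(a, p) {
  out <- new_node(a$v^p, list(a), rg = a$rg)
  out$bwd <- function(g) list(
    if (a$rg) tg_scale(tg_mul(g, tg_powc(a, p - 1)), p))
  out
}

tg_exp <- function(a) {
  out <- new_node(exp(a$v), list(a), rg = a$rg)
  out$bwd <- function(g) list(if (a$rg) tg_mul(g, out))
  out
}

tg_sigmoid <- function(a) {
  val <- 1 / (1 + exp(-a$v))
  out <- new_node(val, list(a), rg = a$rg)
  out$bwd <- function(g) list(
    if (a$rg) tg_mul(g, tg_mul(out, tg_shift(tg_scale(out, -1), 1))))
  out
}

# leaky rectifier; the slope mask is a constant of differentiation (the
# function is piecewise linear), so double backprop treats it as fixed
tg_lrelu <- function(a, slope = 0.2) {
  lr <- lrelu_cpp(a$v, slope)
  out <- new_node(lr$val, list(a), rg = a$rg)
  out$bwd <- function(g) list(if (a$rg) tg_mul(g, tg_const(lr$mask)))
  out
}

# fused elementwise a*b + c (equal shapes)
tg_fma <- function(a, b, c) {
  out <- new_node(fma_cpp(a$v, b$v, c$v), list(a, b, c),
                  rg = a$rg || b$rg || c$rg)
  out$bwd <- function(g) list(
    if (a$rg) tg_mul(g, b),
    if (b$rg) tg_mul(g, a),
    if (c$rg) g)
  out
}

# fixed permutation of the column-major element order (reshape/transpose
# composite); `perm` maps output position -> input position, `iperm` inverts
tg_perm <- function(a, perm, iperm, dims_out) {
  val <- matrix(as.vector(a$v)[perm], dims_out[1L], dims_out[2L])
  din <- dim(a$v)
  out <- new_node(val, list(a), rg = a$rg)
  out$bwd <- function(g) list(if (a$rg) tg_perm(g, iperm, perm, din))
  out
}

# row gather with duplication; idx == 0 selects an implicit zero row
tg_rowgather <- function(a, idx) {
  n_in <- nrow(a$v)
  out <- new_node(row_gather(a$v, idx), list(a), rg = a$rg)
  out$bwd <- function(g) list(if (a$rg) tg_rowscatter(g, idx, n_in))
  out
}

# adjoint of tg_rowgather: scatter-add rows of `a` into `n_out` rows
tg_rowscatter <- function(a, idx, n_out) {
  out <- new_node(row_scatter(a$v, idx, n_out), list(a), rg = a$rg)
  out$bwd <- function(g) list(if (a$rg) tg_rowgather(g, idx))
  out
}

# patch-matrix assembly for 3^3 convolutions: idx holds, tap-major, one
# 1-based source row per (tap, output row); the result is (vo x taps*C)
tg_im2col <- function(a, idx, vo, taps) {
  n_in <- nrow(a$v)
  out <- new_node(im2col_gather(a$v, idx, vo, taps), list(a), rg = a$rg)
  out$bwd <- function(g) list(if (a$rg) tg_col2im(g, idx, n_in, taps))
  out
}

tg_col2im <- function(a, idx, n_out, taps) {
  vo <- nrow(a$v)
  out <- new_node(col2im_scatter(a$v, idx, n_out, taps), list(a), rg = a$rg)
  out$bwd <- function(g) list(if (a$rg) tg_im2col(g, idx, vo, taps))
  out
}

# add a (1 x C) row vector to every row
tg_add_rowvec <- function(a, b) {
  out <- new_node(add_rowvec_cpp(a$v, as.numeric(b$v)), list(a, b),
                  rg = a$rg || b$rg)
  out$bwd <- function(g) list(if (a$rg) g, if (b$rg) tg_colsum(g))
  out
}

# column slice and its adjoint (embed into a wider zero matrix)
tg_colslice <- function(a, cols) {
  p <- ncol(a$v)
  out <- new_node(a$v[, cols, drop = FALSE], list(a), rg = a$rg)
  out$bwd <- function(g) list(if (a$rg) tg_colembed(g, cols, p))
  out
}

tg_colembed <- function(a, cols, p_total) {
  val <- matrix(0, nrow(a$v), p_total)
  val[, cols] <- a$v
  out <- new_node(val, list(a), rg = a$rg)
  out$bwd <- function(g) list(if (a$rg) tg_colslice(g, cols))
  out
}

tg_colsum <- function(a) {
  n <- nrow(a$v)
  out <- new_node(matrix(colSums(a$v), 1L), list(a), rg = a$rg)
  out$bwd <- function(g) list(if (a$rg) tg_rowgather(g, rep.int(1L, n)))
  out
}

# Reverse-mode sweep.  Returns an environment mapping node id -> gradient
# node; gradients are themselves graph nodes, so a second tg_backward() call
# on any function of them yields second-order derivatives.
tg_backward <- function(root, seed = NULL) {
  stopifnot(is_node(root), root$rg)
  # iterative DFS post-order; reversing it gives a topological order with
  # every consumer before its inputs
  topo <- vector("list", 64L); nt <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(n = root, i = 0L))
  assign(as.character(root$id), TRUE, envir = visited)
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    kids <- fr$n$parents
    pushed <- FALSE
    i <- fr$i
    while (i < length(kids)) {
      i <- i + 1L
      p <- kids[[i]]
      if (is_node(p) && p$rg) {
        key <- as.character(p$id)
        if (!exists(key, envir = visited, inherits = FALSE)) {
          assign(key, TRUE, envir = visited)
          stack[[length(stack)]]$i <- i
          stack[[length(stack) + 1L]] <- list(n = p, i = 0L)
          pushed <- TRUE
          break
        }
      }
    }
    if (pushed) next
    stack[[length(stack)]]$i <- i
    if (i >= length(kids)) {
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- fr$n
      stack[[length(stack)]] <- NULL
    }
  }
  grads <- new.env(parent = emptyenv())
  sv <- root$v
  seedn <- if (is.null(seed)) tg_const(matrix(1, nrow(sv), ncol(sv))) else seed
  assign(as.character(root$id), seedn, envir = grads)
  for (k in seq(nt, 1L)) {
    n <- topo[[k]]
    key <- as.character(n$id)
    if (!exists(key, envir = grads, inherits = FALSE)) next
    if (is.null(n$bwd)) next
    g <- get(key, envir = grads)
    pg <- n$bwd(g)
    ps <- n$parents
    for (j in seq_along(ps)) {
      if (j > length(pg)) next
      gj <- pg[[j]]
      p <- ps[[j]]
      if (is.null(gj) || !is_node(p) || !p$rg) next
      pk <- as.character(p$id)
      if (exists(pk, envir = grads, inherits = FALSE)) {
        assign(pk, tg_add(get(pk, envir = grads), gj), envir = grads)
      } else {
        assign(pk, gj, envir = grads)
      }
    }
  }
  grads
}

tg_grad <- function(grads, node) {
  key <- as.character(node$id)
  if (exists(key, envir = grads, inherits = FALSE)) get(key, envir = grads) else NULL
}

# numeric gradient value for a leaf (zero matrix if the leaf is unreachable)
tg_grad_value <- function(grads, node) {
  g <- tg_grad(grads, node)
  if (is.null(g)) matrix(0, nrow(node$v), ncol(node$v)) else g$v
}
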