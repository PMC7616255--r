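# Network layers over the autodiff tape.
#
# Feature maps live in matrices with rows indexed by (voxel within sample,
# sample) and columns by channel: row r = (b-1)*V + v for sample b in 1..B and
# voxel v in 1..V.  Voxels use the column-major linear index of an R array
# with dims (d, d, d): v = 1 + i + j*d + k*d^2 for 0-based (i, j, k).
#
# 3x3x3 convolutions are evaluated as a patch gather (27 taps, zero padding 1,
# compiled kernel) followed by one GEMM against a (27*C_in) x C_out weight
# matrix.  Up/downsampling, pooling and per-sample broadcasting are row
# gathers/scatters.  All index tables depend only on grid geometry and batch
# size and are cached.

.geom <- new.env(parent = emptyenv())

geom_cache <- function(key, build) {
  if (is.null(.geom[[key]])) .geom[[key]] <- build()
  .geom[[key]]
}

# 0-based voxel coordinates of a d^3 grid, i fastest (column-major order)
grid_coords <- function(d) {
  i <- rep.int(0:(d - 1L), d * d)
  j <- rep.int(rep(0:(d - 1L), each = d), d)
  k <- rep(0:(d - 1L), each = d * d)
  list(i = i, j = j, k = k)
}

# tap-major gather index for a 3^3 conv, kernel 3, pad 1:
# idx[(t-1)*Vo*B + (b-1)*Vo + vo] = source row (0 = zero padding)
conv_geom <- function(d_in, stride, B) {
  key <- paste("conv", d_in, stride, B, sep = "|")
  geom_cache(key, function() {
    d_out <- (d_in - 1L) %/% stride + 1L
    Vi <- d_in^3; Vo <- d_out^3
    g <- grid_coords(d_out)
    boff <- rep((0:(B - 1L)) * Vi, each = Vo)
    idx <- integer(27L * Vo * B)
    t <- 0L
    for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
      t <- t + 1L
      si <- g$i * stride + di; sj <- g$j * stride + dj; sk <- g$k * stride + dk
      ok <- si >= 0L & si < d_in & sj >= 0L & sj < d_in & sk >= 0L & sk < d_in
      v <- integer(Vo)
      v[ok] <- 1L + si[ok] + sj[ok] * d_in + sk[ok] * d_in^2
      blk <- rep.int(v, B)
      blk[blk > 0L] <- blk[blk > 0L] + boff[blk > 0L]
      idx[((t - 1L) * Vo * B + 1L):(t * Vo * B)] <- blk
    }
    list(idx = idx, d_out = d_out, VoB = Vo * B)
  })
}

#' 3x3x3 convolution parameters
#'
#' Weight layout is `(27*c_in) x c_out`, rows tap-major (taps scan the
#' kernel offsets k-slowest, matching `conv_geom`).
#' @keywords internal
conv_param <- function(c_in, c_out, sd = sqrt(2 / (27 * c_in)), zero = FALSE) {
  w <- if (zero) matrix(0, 27L * c_in, c_out) else
    matrix(stats::rnorm(27L * c_in * c_out, 0, sd), 27L * c_in, c_out)
  list(W = tg_leaf(w, rg = TRUE),
       b = tg_leaf(matrix(0, 1L, c_out), rg = TRUE),
       c_in = c_in, c_out = c_out)
}

conv3d_fwd <- function(x, p, d_in, stride, B) {
  cg <- conv_geom(d_in, stride, B)
  patches <- tg_im2col(x, cg$idx, cg$VoB, 27L)
  y <- tg_add_rowvec(tg_matmul(patches, p$W), p$b)
  list(out = y, d_out = cg$d_out)
}

linear_param <- function(n_in, n_out, sd = sqrt(1 / n_in), zero = FALSE) {
  w <- if (zero) matrix(0, n_in, n_out) else
    matrix(stats::rnorm(n_in * n_out, 0, sd), n_in, n_out)
  list(W = tg_leaf(w, rg = TRUE), b = tg_leaf(matrix(0, 1L, n_out), rg = TRUE))
}

linear_fwd <- function(x, p) tg_add_rowvec(tg_matmul(x, p$W), p$b)

# sample membership index: row r of a (V*B x C) feature matrix -> sample
samp_idx <- function(V, B) {
  key <- paste("samp", V, B, sep = "|")
  geom_cache(key, function() rep(seq_len(B), each = V))
}

# per-sample mean over voxels: (V*B x C) -> (B x C)
pool_mean <- function(x, V, B) tg_scale(tg_rowscatter(x, samp_idx(V, B), B), 1 / V)

# per-sample sum over voxels: (V*B x C) -> (B x C)
pool_sum <- function(x, V, B) tg_rowscatter(x, samp_idx(V, B), B)

# broadcast per-sample rows (B x C) back to (V*B x C)
bcast_samp <- function(x, V, B) tg_rowgather(x, samp_idx(V, B))

# instance normalization: per (sample, channel) zero mean, unit variance
# (population variance, epsilon-stabilized).  Fused primitive with a
# hand-derived first-order adjoint; normalization layers never sit inside
# the critic, so second-order differentiability is not required here.
inorm_fwd <- function(x, V, B, eps = 1e-5) {
  fw <- inorm_fwd_cpp(x$v, V, B, eps)
  out <- new_node(fw$xhat, list(x), rg = x$rg)
  out$bwd <- function(g) list(
    if (x$rg) tg_const(inorm_bwd_cpp(g$v, fw$xhat, fw$inv, V, B)))
  out
}

# nearest-neighbour upsampling by 2 in each axis
up_idx <- function(d_in, B) {
  key <- paste("up", d_in, B, sep = "|")
  geom_cache(key, function() {
    d_out <- 2L * d_in
    g <- grid_coords(d_out)
    src <- 1L + (g$i %/% 2L) + (g$j %/% 2L) * d_in + (g$k %/% 2L) * d_in^2
    rep.int(src, B) + rep((0:(B - 1L)) * d_in^3, each = d_out^3)
  })
}

upsample2_fwd <- function(x, d_in, B) {
  list(out = tg_rowgather(x, up_idx(d_in, B)), d_out = 2L * d_in)
}

# nearest-neighbour resampling between cubic grids, pixel-centre alignment:
# output voxel i draws from source index floor((i + 0.5) * d_from / d_to)
down_idx <- function(d_from, d_to, B) {
  key <- paste("down", d_from, d_to, B, sep = "|")
  geom_cache(key, function() {
    g <- grid_coords(d_to)
    f <- d_from / d_to
    pick <- function(u) pmin(as.integer(floor((u + 0.5) * f)), d_from - 1L)
    src <- 1L + pick(g$i) + pick(g$j) * d_from + pick(g$k) * d_from^2
    rep.int(src, B) + rep((0:(B - 1L)) * d_from^3, each = d_to^3)
  })
}

# permutation flattening (V*B x C) features into (B x V*C) vectors
flat_perm <- function(V, C, B) {
  key <- paste("flat", V, C, B, sep = "|")
  geom_cache(key, function() {
    n <- V * C * B
    out_lin <- seq_len(n)
    b <- (out_lin - 1L) %% B + 1L
    q <- (out_lin - 1L) %/% B + 1L
    v <- (q - 1L) %% V + 1L
    cc <- (q - 1L) %/% V + 1L
    src <- (b - 1L) * V + v + (cc - 1L) * V * B
    ip <- integer(n); ip[src] <- out_lin
    list(perm = src, iperm = ip, flat_dims = c(B, V * C), map_dims = c(V * B, C))
  })
}

flatten_fwd <- function(x, V, C, B) {
  fp <- flat_perm(V, C, B)
  tg_perm(x, fp$perm, fp$iperm, fp$flat_dims)
}

unflatten_fwd <- function(x, V, C, B) {
  fp <- flat_perm(V, C, B)
  tg_perm(x, fp$iperm, fp$perm, fp$map_dims)
}

# conversions between user-facing arrays and the internal matrix layout ------

# 3D array (d,d,d) or 4D (d,d,d,B) -> (V*B x 1) matrix
cube_to_mat <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("expected a 3D cube or a 4D batch of cubes")
  matrix(as.numeric(x), ncol = 1L)
}

batch_size_of <- function(x) {
  d <- dim(x)
  if (length(d) == 4L) d[4L] else 1L
}

mat_to_cube <- function(m, side, B) {
  if (B == 1L) array(m, dim = c(side, side, side))
  else array(m, dim = c(side, side, side, B))
}

# (d,d,d,C,B)-array <-> (V*B x C) feature matrix (C and B optional dims)
feat_to_mat <- function(a) {
  d <- dim(a)
  if (length(d) == 4L) d <- c(d, 1L)
  stopifnot(length(d) == 5L)
  V <- prod(d[1:3]); C <- d[4L]; B <- d[5L]
  m <- matrix(aperm(array(a, dim = d), c(1L, 2L, 3L, 5L, 4L)), V * B, C)
  list(m = m, V = V, C = C, B = B, side = d[1L])
}

mat_to_feat <- function(m, side, C, B) {
  a <- array(m, dim = c(side, side, side, B, C))
  aperm(a, c(1L, 2L, 3L, 5L, 4L))
}
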