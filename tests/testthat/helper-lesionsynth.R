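# Shared test utilities: tiny configurations, finite-difference gradients
# and a brute-force 3D convolution oracle.

# internal primitives exercised by white-box tests
for (.nm in c("tg_const", "tg_leaf", "tg_sum", "tg_powc", "tg_add", "tg_mul",
              "tg_sub", "tg_exp", "tg_sigmoid", "tg_lrelu", "tg_matmul",
              "tg_fma", "tg_backward", "tg_grad_value", "tg_rowgather",
              "tg_rowscatter", "tg_im2col", "tg_col2im", "tg_perm",
              "tg_colslice", "tg_add_rowvec", "conv_geom", "conv3d_fwd",
              "conv_param", "linear_param", "inorm_fwd", "flat_perm",
              "flatten_fwd", "unflatten_fwd", "encoder_fwd", "decoder_fwd",
              "critic_fwd", "gp_node", "mean_node", "collect_params",
              "ceb_block", "meb_block", "with_seed", "feat_to_mat",
              "upsample2_fwd", "down_idx", "row_gather"))
  assign(.nm, get(.nm, envir = asNamespace("lesionsynth")))

tiny_cfg <- function(side = 8L, base = 2L, levels = 2L, latent = 6L)
  network_config(side = side, base_channels = base, n_levels = levels,
                 latent_dim = latent, embed_hidden = 2L)

# central finite difference of f() with respect to entry i of param node P
fd_grad <- function(P, i, f, h = 1e-6) {
  w0 <- P$v[i]
  P$v[i] <- w0 + h; f1 <- f()
  P$v[i] <- w0 - h; f2 <- f()
  P$v[i] <- w0
  (f1 - f2) / (2 * h)
}

# direct triple-loop 3x3x3 convolution with zero padding, matching the
# tap-major weight layout of conv_param
conv3d_bruteforce <- function(x, W, bias, stride) {
  d <- dim(x)[1L]; c_in <- dim(x)[4L]
  c_out <- length(bias)
  d_out <- (d - 1L) %/% stride + 1L
  out <- array(0, c(d_out, d_out, d_out, c_out))
  taps <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  taps <- taps[order(taps$dk, taps$dj, taps$di), ]
  for (o in seq_len(c_out)) for (i in 0:(d_out - 1)) for (j in 0:(d_out - 1))
    for (k in 0:(d_out - 1)) {
      acc <- bias[o]
      for (t in seq_len(27)) for (c in seq_len(c_in)) {
        si <- i * stride + taps$di[t]; sj <- j * stride + taps$dj[t]
        sk <- k * stride + taps$dk[t]
        if (si >= 0 && si < d && sj >= 0 && sj < d && sk >= 0 && sk < d)
          acc <- acc + x[si + 1, sj + 1, sk + 1, c] * W[(t - 1) * c_in + c, o]
      }
      out[i + 1, j + 1, k + 1, o] <- acc
    }
  out
}

# small deterministic phantom training set
tiny_dataset <- function(n, side = 8L, seed = 5L) {
  spec <- phantom_spec(side = side, volume_range = c(8L, round(side^3 / 6)),
                       n_lobes = 2L, texture_contrast = 0.3,
                       background_smoothness = 1.5, seed = seed)
  phantom_dataset(n, spec)
}

tiny_train_cfg <- function(stage, epochs = 2L, seed = 11L, batch = 4L)
  train_config(learning_rate = 1e-3, batch_size = batch, epochs = epochs,
               critic_steps = 1L, seed = seed,
               weights = loss_weights(w_rec = 1, w_kl = 0.1, w_adv = 1e-2),
               stage = stage)
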