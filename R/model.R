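# The progressive adversarial VAE networks.
#
# Two stages share one backbone design.  The mask stage is a 3D VAE whose
# decoder normalizations are modulated by a condition embedding block (CEB)
# driven by the lesion-size condition.  The lesion stage replaces the CEB
# with a mask embedding block (MEB): the guiding mask is nearest-neighbour
# resized to each decoder resolution and three 3x3x3 convolutions produce
# voxel-wise scale and bias fields (SPADE-style spatially adaptive
# normalization).  A separate Wasserstein critic (no normalization layers,
# as required for a meaningful gradient penalty) scores each stage's output.

#' Network configuration
#'
#' @param side cube side in voxels; must be divisible by `2^n_levels`.
#' @param base_channels channels after the first encoder convolution;
#'   doubled at every downsampling level.
#' @param n_levels number of stride-2 downsampling levels (bottleneck grid is
#'   `side / 2^n_levels` per axis).
#' @param latent_dim length of the Gaussian latent vector.
#' @param leaky_slope negative slope of the leaky rectifier.
#' @param condition_dim length of the condition vector (1: lesion size).
#' @param embed_hidden hidden width of the CEB/MEB embedding stacks.
#' @return an object of class `network_config`.
#' @export
network_config <- function(side = 64L, base_channels = 16L, n_levels = 4L,
                           latent_dim = 128L, leaky_slope = 0.2,
                           condition_dim = 1L, embed_hidden = 16L) {
  side <- as.integer(side); n_levels <- as.integer(n_levels)
  if (side < 2L || side %% (2L^n_levels) != 0L)
    stop("side (", side, ") must be divisible by 2^n_levels (", 2L^n_levels, ")")
  if (latent_dim < 1L) stop("latent_dim must be >= 1")
  structure(list(side = side, base_channels = as.integer(base_channels),
                 n_levels = n_levels, latent_dim = as.integer(latent_dim),
                 leaky_slope = leaky_slope,
                 condition_dim = as.integer(condition_dim),
                 embed_hidden = as.integer(embed_hidden)),
            class = "network_config")
}

cfg_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$n_levels) - 1L)
cfg_bottleneck <- function(cfg) {
  d <- cfg$side %/% 2L^cfg$n_levels
  ch <- cfg_channels(cfg)
  list(d = d, V = d^3, C = ch[cfg$n_levels], D = d^3 * ch[cfg$n_levels])
}

# ---- parameter containers --------------------------------------------------

# conditional = TRUE (mask stage) appends the condition vector to the
# flattened bottleneck before the mu/logvar heads, making the posterior
# q(z | x, c) condition-aware so that z need not carry what c provides
create_encoder <- function(cfg, conditional = FALSE) {
  ch <- cfg_channels(cfg)
  convs <- vector("list", cfg$n_levels)
  c_in <- 1L
  for (l in seq_len(cfg$n_levels)) {
    convs[[l]] <- conv_param(c_in, ch[l])
    c_in <- ch[l]
  }
  bn <- cfg_bottleneck(cfg)
  d_in <- bn$D + if (conditional) cfg$condition_dim else 0L
  list(convs = convs, conditional = conditional,
       mu = linear_param(d_in, cfg$latent_dim),
       logvar = linear_param(d_in, cfg$latent_dim, zero = TRUE))
}

ceb_block <- function(condition_dim, channels, hidden) {
  list(shared = linear_param(condition_dim, hidden),
       gamma = linear_param(hidden, channels, zero = TRUE),
       beta = linear_param(hidden, channels, zero = TRUE),
       channels = channels)
}

# gamma and beta heads share one conv (columns 1..C are gamma, C+1..2C beta)
meb_block <- function(channels, hidden) {
  list(shared = conv_param(1L, hidden),
       heads = conv_param(hidden, 2L * channels, zero = TRUE),
       channels = channels)
}

create_decoder <- function(cfg, type = c("ceb", "meb")) {
  type <- match.arg(type)
  ch <- cfg_channels(cfg)
  bn <- cfg_bottleneck(cfg)
  n <- cfg$n_levels
  # level l (from deepest): conv from ch[l] down to ch[l-1] (ch[0] := ch[1])
  convs <- vector("list", n)
  blocks <- vector("list", n)
  for (l in seq(n, 1L)) {
    c_in <- ch[l]
    c_out <- if (l > 1L) ch[l - 1L] else ch[1L]
    convs[[l]] <- conv_param(c_in, c_out)
    blocks[[l]] <- if (type == "ceb") ceb_block(cfg$condition_dim, c_out, cfg$embed_hidden)
                   else meb_block(c_out, cfg$embed_hidden)
  }
  list(type = type,
       fc = linear_param(cfg$latent_dim, bn$D),
       convs = convs, blocks = blocks,
       final = conv_param(ch[1L], 1L, sd = 0.05))
}

create_critic <- function(cfg) {
  ch <- cfg_channels(cfg)
  convs <- vector("list", cfg$n_levels)
  c_in <- 1L
  for (l in seq_len(cfg$n_levels)) {
    convs[[l]] <- conv_param(c_in, ch[l])
    c_in <- ch[l]
  }
  list(convs = convs, head = linear_param(ch[cfg$n_levels], 1L))
}

#' Create the full two-network model for one stage
#'
#' @param cfg a [network_config()].
#' @param stage `"mask"` (CEB-conditioned decoder) or `"lesion"`
#'   (MEB-conditioned decoder).
#' @return a list with `encoder`, `decoder`, `critic`, `cfg`, `stage`.
#' @export
create_stage_model <- function(cfg, stage = c("mask", "lesion")) {
  stage <- match.arg(stage)
  structure(list(encoder = create_encoder(cfg, conditional = stage == "mask"),
                 decoder = create_decoder(cfg, if (stage == "mask") "ceb" else "meb"),
                 critic = create_critic(cfg),
                 cfg = cfg, stage = stage),
            class = "stage_model")
}

# all trainable leaves of a (nested) parameter container
collect_params <- function(x) {
  if (is_node(x)) return(if (x$rg) list(x) else list())
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

# structure-preserving copy with parameters wrapped as constants (used when a
# network participates in someone else's update, e.g. the critic during the
# generator step)
freeze_params <- function(x) {
  if (is_node(x)) return(if (x$rg) tg_const(x$v) else x)
  if (is.list(x)) return(lapply(x, freeze_params))
  x
}

param_values <- function(x) {
  if (is_node(x)) return(x$v)
  if (is.list(x)) return(lapply(x, param_values))
  x
}

set_param_values <- function(x, vals) {
  if (is_node(x)) { x$v <- vals; return(invisible(x)) }
  if (is.list(x)) for (i in seq_along(x)) set_param_values(x[[i]], vals[[i]])
  invisible(x)
}

# ---- forward passes (tape level) -------------------------------------------

encoder_fwd <- function(enc, x, cfg, B, c_node = NULL) {
  d <- cfg$side
  h <- x
  for (l in seq_along(enc$convs)) {
    cv <- conv3d_fwd(h, enc$convs[[l]], d, 2L, B)
    d <- cv$d_out
    h <- tg_lrelu(inorm_fwd(cv$out, d^3, B), cfg$leaky_slope)
  }
  bn <- cfg_bottleneck(cfg)
  flat <- flatten_fwd(h, bn$V, bn$C, B)
  if (isTRUE(enc$conditional)) {
    if (is.null(c_node)) stop("this encoder is condition-aware: supply c")
    D <- bn$D; C <- cfg$condition_dim
    flat <- tg_add(tg_colembed(flat, seq_len(D), D + C),
                   tg_colembed(cond_scale(c_node), D + seq_len(C), D + C))
  }
  list(mu = linear_fwd(flat, enc$mu), logvar = linear_fwd(flat, enc$logvar))
}

reparam_node <- function(mu, logvar, eps) {
  tg_fma(tg_exp(tg_scale(logvar, 0.5)), tg_const(eps), mu)
}

# centre and spread the raw condition (normalized log-volume, typically a
# narrow band around 0.5) so the embedding sees O(1) input variation
cond_scale <- function(c_node) tg_scale(tg_shift(c_node, -0.5), 4)

ceb_modulate_fwd <- function(feat, c_node, block, V, B, slope) {
  h <- tg_lrelu(linear_fwd(cond_scale(c_node), block$shared), slope)
  gamma <- linear_fwd(h, block$gamma)   # B x C
  beta <- linear_fwd(h, block$beta)
  gam_f <- bcast_samp(gamma, V, B)
  bet_f <- bcast_samp(beta, V, B)
  xn <- inorm_fwd(feat, V, B)
  tg_fma(xn, tg_shift(gam_f, 1), bet_f)
}

meb_modulate_fwd <- function(feat, m_node, block, d_feat, mask_side, B, slope) {
  md <- if (mask_side == d_feat) m_node
        else tg_rowgather(m_node, down_idx(mask_side, d_feat, B))
  h <- tg_lrelu(conv3d_fwd(md, block$shared, d_feat, 1L, B)$out, slope)
  gb <- conv3d_fwd(h, block$heads, d_feat, 1L, B)$out
  C <- block$channels
  gamma <- tg_colslice(gb, seq_len(C))
  beta <- tg_colslice(gb, C + seq_len(C))
  xn <- inorm_fwd(feat, d_feat^3, B)
  tg_fma(xn, tg_shift(gamma, 1), beta)
}

# guide: condition node (B x condition_dim) for CEB, mask node (V*B x 1) at
# full resolution for MEB
decoder_fwd <- function(dec, z, guide, cfg, B) {
  bn <- cfg_bottleneck(cfg)
  h <- tg_lrelu(linear_fwd(z, dec$fc), cfg$leaky_slope)
  h <- unflatten_fwd(h, bn$V, bn$C, B)
  d <- bn$d
  for (l in seq(cfg$n_levels, 1L)) {
    up <- upsample2_fwd(h, d, B)
    d <- up$d_out
    cv <- conv3d_fwd(up$out, dec$convs[[l]], d, 1L, B)
    blk <- dec$blocks[[l]]
    h <- if (dec$type == "ceb")
      ceb_modulate_fwd(cv$out, guide, blk, d^3, B, cfg$leaky_slope)
    else
      meb_modulate_fwd(cv$out, guide, blk, d, cfg$side, B, cfg$leaky_slope)
    h <- tg_lrelu(h, cfg$leaky_slope)
  }
  tg_sigmoid(conv3d_fwd(h, dec$final, cfg$side, 1L, B)$out)
}

critic_fwd <- function(cr, x, cfg, B) {
  d <- cfg$side
  h <- x
  for (l in seq_along(cr$convs)) {
    cv <- conv3d_fwd(h, cr$convs[[l]], d, 2L, B)
    d <- cv$d_out
    h <- tg_lrelu(cv$out, cfg$leaky_slope)
  }
  linear_fwd(pool_mean(h, d^3, B), cr$head)
}

# ---- public array-level API ------------------------------------------------

check_cube_input <- function(x, cfg) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)) || any(d[1:3] != cfg$side))
    stop("input side does not match network side ", cfg$side,
         " (got ", paste(if (is.null(d)) length(x) else d, collapse = "x"), ")")
}

#' Encode a cube (or batch of cubes) to a Gaussian latent
#'
#' @param model a [create_stage_model()] object.
#' @param x numeric array `(side, side, side)` or `(side, side, side, B)`,
#'   values in `[0, 1]`.
#' @param eps optional `B x latent_dim` matrix of standard-normal draws used
#'   by the reparameterization `z = mu + exp(logvar/2) * eps`; drawn from the
#'   current RNG when omitted.
#' @param c lesion-size condition (scalar or `B x condition_dim`); required
#'   for mask-stage models, whose posterior is condition-aware, and ignored
#'   otherwise.
#' @return list with matrices `mu`, `logvar`, `z` (each `B x latent_dim`)
#'   and the `eps` used.
#' @export
encode <- function(model, x, eps = NULL, c = NULL) {
  cfg <- model$cfg
  check_cube_input(x, cfg)
  B <- batch_size_of(x)
  c_node <- NULL
  if (isTRUE(model$encoder$conditional)) {
    if (is.null(c)) stop("mask-stage encoders are condition-aware: supply c")
    c <- if (is.matrix(c)) c else matrix(c, B, cfg$condition_dim)
    c_node <- tg_const(c)
  }
  out <- encoder_fwd(model$encoder, tg_const(cube_to_mat(x)), cfg, B, c_node)
  mu <- out$mu$v; logvar <- out$logvar$v
  if (is.null(eps)) eps <- matrix(stats::rnorm(B * cfg$latent_dim), B, cfg$latent_dim)
  stopifnot(all(dim(eps) == c(B, cfg$latent_dim)))
  list(mu = mu, logvar = logvar, z = mu + exp(0.5 * logvar) * eps, eps = eps)
}

#' Decode a latent vector into a soft lesion mask (mask stage)
#'
#' @param model mask-stage model.
#' @param z numeric vector of length `latent_dim`, or `B x latent_dim`.
#' @param c condition vector (length `condition_dim`) or `B x condition_dim`
#'   matrix; the lesion-size condition of [condition_of()].
#' @return array in `(0, 1)` of side `cfg$side` (4D when `B > 1`).
#' @export
decode_mask <- function(model, z, c) {
  cfg <- model$cfg
  if (model$decoder$type != "ceb") stop("decode_mask needs a mask-stage (CEB) model")
  z <- if (is.matrix(z)) z else matrix(z, 1L)
  c <- if (is.matrix(c)) c else matrix(c, 1L)
  if (ncol(z) != cfg$latent_dim) stop("latent length ", ncol(z), " != ", cfg$latent_dim)
  if (ncol(c) != cfg$condition_dim)
    stop("condition length ", ncol(c), " != condition_dim ", cfg$condition_dim)
  if (nrow(c) != nrow(z)) stop("z and c batch sizes differ")
  B <- nrow(z)
  y <- decoder_fwd(model$decoder, tg_const(z), tg_const(c), cfg, B)
  mat_to_cube(y$v, cfg$side, B)
}

#' Decode a latent vector into a lesion cube guided by a mask (lesion stage)
#'
#' @param model lesion-stage model.
#' @param z latent vector / matrix as in [decode_mask()].
#' @param m binary mask array `(side, side, side)` (or batch) guiding the
#'   lesion shape through the mask embedding block.
#' @return intensity array in `(0, 1)`.
#' @export
decode_lesion <- function(model, z, m) {
  cfg <- model$cfg
  if (model$decoder$type != "meb") stop("decode_lesion needs a lesion-stage (MEB) model")
  z <- if (is.matrix(z)) z else matrix(z, 1L)
  if (ncol(z) != cfg$latent_dim) stop("latent length ", ncol(z), " != ", cfg$latent_dim)
  check_cube_input(m, cfg)
  B <- batch_size_of(m)
  if (B != nrow(z)) stop("z and mask batch sizes differ")
  y <- decoder_fwd(model$decoder, tg_const(z), tg_const(cube_to_mat(m)), cfg, B)
  mat_to_cube(y$v, cfg$side, B)
}

#' Critic score of a cube (or batch)
#'
#' @param model a stage model.
#' @param x cube array (side matching the model).
#' @return numeric vector of one unbounded score per sample.
#' @export
critic_score <- function(model, x) {
  cfg <- model$cfg
  check_cube_input(x, cfg)
  B <- batch_size_of(x)
  as.numeric(critic_fwd(model$critic, tg_const(cube_to_mat(x)), cfg, B)$v)
}

#' Condition embedding modulation of a feature field
#'
#' Instance-normalizes `features` and modulates them with per-channel scale
#' and bias produced from the condition vector:
#' `out = norm(features) * (1 + gamma(c)) + beta(c)`.  With zero-initialized
#' gamma/beta heads this is exactly instance normalization.
#'
#' @param features array `(d, d, d, C)` or `(d, d, d, C, B)`.
#' @param c condition vector (length `condition_dim`) or `B x condition_dim`.
#' @param block a `ceb_block`; a fresh zero-initialized block when omitted.
#' @param leaky_slope slope of the embedding activation.
#' @return modulated array, same shape as `features`.
#' @export
ceb_modulate <- function(features, c, block = NULL, leaky_slope = 0.2) {
  fm <- feat_to_mat(features)
  c <- if (is.matrix(c)) c else matrix(c, 1L)
  if (nrow(c) == 1L && fm$B > 1L) c <- c[rep(1L, fm$B), , drop = FALSE]
  if (is.null(block)) block <- ceb_block(ncol(c), fm$C, 16L)
  out <- ceb_modulate_fwd(tg_const(fm$m), tg_const(c), block, fm$V, fm$B, leaky_slope)
  res <- mat_to_feat(out$v, fm$side, fm$C, fm$B)
  if (length(dim(features)) == 4L) res <- array(res, dim = dim(features))
  res
}

#' Mask embedding modulation of a feature field
#'
#' Nearest-neighbour resizes the mask to the feature resolution, produces
#' voxel-wise scale and bias fields through three 3x3x3 convolutions, and
#' modulates the instance-normalized features.
#'
#' @param features array `(d, d, d, C)` or `(d, d, d, C, B)`.
#' @param m binary mask array with side >= feature side.
#' @param block a `meb_block`; fresh zero-initialized heads when omitted.
#' @param leaky_slope slope of the embedding activation.
#' @return modulated array, same shape as `features`.
#' @export
meb_modulate <- function(features, m, block = NULL, leaky_slope = 0.2) {
  fm <- feat_to_mat(features)
  mside <- dim(m)[1L]
  if (mside < fm$side) stop("mask side must be >= feature side")
  if (is.null(block)) block <- meb_block(fm$C, 8L)
  out <- meb_modulate_fwd(tg_const(fm$m), tg_const(cube_to_mat(m)), block,
                          fm$side, mside, fm$B, leaky_slope)
  res <- mat_to_feat(out$v, fm$side, fm$C, fm$B)
  if (length(dim(features)) == 4L) res <- array(res, dim = dim(features))
  res
}

#' Nearest-neighbour downsampling of a mask between cubic grids
#'
#' @param m 3D array of side `d_from`.
#' @param d_to target side.
#' @return 3D array of side `d_to`.
#' @export
nn_resize <- function(m, d_to) {
  d_from <- dim(m)[1L]
  v <- row_gather(matrix(as.numeric(m), ncol = 1L), down_idx(d_from, d_to, 1L))
  array(v, dim = rep(d_to, 3L))
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a stage model checkpoint (config embedded)
#' @param model a `stage_model`.
#' @param path file path (RDS).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(cfg = model$cfg, stage = model$stage,
               values = param_values(model[c("encoder", "decoder", "critic")])),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- create_stage_model(do.call(network_config, unclass(ck$cfg)), ck$stage)
  set_param_values(model[c("encoder", "decoder", "critic")], ck$values)
  model
}
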