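# Alternating generator/critic optimization for the two stages.
#
# Per batch: `critic_steps` critic updates (Wasserstein loss with gradient
# penalty, double backprop through the input gradient) followed by one
# generator update (encoder + decoder optimized together).  Two independent
# Adam optimizers, betas (0.5, 0.9) as is standard for WGAN-GP.  All
# randomness (shuffling, reparameterization draws, interpolation draws)
# derives from the config seed, so runs are bitwise reproducible on a CPU.

#' Training configuration
#'
#' @param learning_rate Adam step size (default 5e-5, the full-scale
#'   protocol value).
#' @param batch_size mini-batch size (default 13).
#' @param epochs number of epochs (default 1000 at full scale).
#' @param critic_steps critic updates per generator update (default 5).
#' @param seed master seed for all training randomness.
#' @param weights a [loss_weights()] list.
#' @param stage `"mask"` or `"lesion"`.
#' @param reduce batch reduction of reconstruction/KL terms (`"mean"` or
#'   `"sum"`).
#' @export
train_config <- function(learning_rate = 5e-5, batch_size = 13L,
                         epochs = 1000L, critic_steps = 5L, seed = 1L,
                         weights = loss_weights(),
                         stage = c("mask", "lesion"),
                         reduce = c("mean", "sum")) {
  stage <- match.arg(stage)
  reduce <- match.arg(reduce)
  stopifnot(learning_rate > 0, epochs >= 1, critic_steps >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 critic_steps = as.integer(critic_steps),
                 seed = as.integer(seed), weights = weights,
                 stage = stage, reduce = reduce),
            class = "train_config")
}

adam_new <- function(params, lr, beta1 = 0.5, beta2 = 0.9, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p$v * 0),
       v = lapply(params, function(p) p$v * 0))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
    params[[i]]$v <- params[[i]]$v -
      opt$lr * (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + opt$eps)
  }
  opt
}

grad_values <- function(grads, params)
  lapply(params, function(p) tg_grad_value(grads, p))

check_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop("training diverged: non-finite ", what, " loss")
  x
}

# assemble the (V*B x 1) input matrix and per-stage targets for a batch
batch_tensors <- function(dataset, idx, stage) {
  B <- length(idx)
  xs <- lapply(dataset[idx], function(r)
    as.numeric(if (stage == "mask") r$mask else r$cube))
  x <- matrix(unlist(xs), ncol = 1L)
  guide <- if (stage == "mask") {
    matrix(vapply(dataset[idx], function(r) r$condition, 0), B, 1L)
  } else {
    matrix(unlist(lapply(dataset[idx], function(r) as.numeric(r$mask))), ncol = 1L)
  }
  list(x = x, guide = guide, B = B)
}

# full generator pass; for the mask stage the condition guides both the
# posterior and the decoder
gen_forward <- function(model, bt, cfg, w) {
  ncfg <- model$cfg
  guide <- tg_const(bt$guide)
  c_node <- if (isTRUE(model$encoder$conditional)) guide else NULL
  enc <- encoder_fwd(model$encoder, tg_const(bt$x), ncfg, bt$B, c_node)
  eps <- matrix(stats::rnorm(bt$B * ncfg$latent_dim), bt$B, ncfg$latent_dim)
  z <- reparam_node(enc$mu, enc$logvar, eps)
  xg <- decoder_fwd(model$decoder, z, guide, ncfg, bt$B)
  list(enc = enc, xg = xg)
}

train_impl <- function(dataset, cfg, model, opt_g, opt_c, history, epoch_from) {
  ncfg <- model$cfg
  w <- cfg$weights
  n <- length(dataset)
  gen_params <- c(collect_params(model$encoder), collect_params(model$decoder))
  cr_params <- collect_params(model$critic)
  for (epoch in (epoch_from + 1L):cfg$epochs) {
    perm <- sample.int(n)
    nb <- ceiling(n / cfg$batch_size)
    comp <- matrix(0, nb, 5L)
    for (bi in seq_len(nb)) {
      idx <- perm[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, n)]
      bt <- batch_tensors(dataset, idx, cfg$stage)

      # ---- critic updates (fake samples detached from the generator) ----
      d_loss <- gp_val <- 0
      fw <- NULL
      for (cs in seq_len(cfg$critic_steps)) {
        fw <- gen_forward(model, bt, cfg, w)  # graph reused by the last step
        fake <- fw$xg$v
        sr <- critic_fwd(model$critic, tg_const(bt$x), ncfg, bt$B)
        sf <- critic_fwd(model$critic, tg_const(fake), ncfg, bt$B)
        u <- stats::runif(bt$B)
        gp <- gp_node(function(xn) critic_fwd(model$critic, xn, ncfg, bt$B),
                      as.numeric(bt$x), as.numeric(fake), w$gp_lambda, u)
        loss_d <- tg_add(tg_sub(mean_node(sf), mean_node(sr)), gp)
        check_finite(loss_d$v, "critic")
        gr <- tg_backward(loss_d)
        opt_c <- adam_step(opt_c, cr_params, grad_values(gr, cr_params))
        d_loss <- as.numeric(loss_d$v); gp_val <- as.numeric(gp$v)
      }

      # ---- generator update (critic frozen), reusing the last forward ----
      rec <- rec_loss_node(fw$xg, tg_const(bt$x), bt$B, cfg$reduce)
      kl <- kl_loss_node(fw$enc$mu, fw$enc$logvar, cfg$reduce)
      frozen <- freeze_params(model$critic)
      sf <- critic_fwd(frozen, fw$xg, ncfg, bt$B)
      adv <- tg_scale(mean_node(sf), -1)
      loss_g <- tg_add(tg_add(tg_scale(rec, w$w_rec), tg_scale(kl, w$w_kl)),
                       tg_scale(adv, w$w_adv))
      check_finite(rec$v, "reconstruction")
      check_finite(kl$v, "KL")
      check_finite(loss_g$v, "generator")
      gr <- tg_backward(loss_g)
      opt_g <- adam_step(opt_g, gen_params, grad_values(gr, gen_params))
      comp[bi, ] <- c(as.numeric(rec$v), as.numeric(kl$v),
                      as.numeric(adv$v), d_loss, gp_val)
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, rec = mean(comp[, 1]),
                                kl = mean(comp[, 2]), adv = mean(comp[, 3]),
                                d_loss = mean(comp[, 4]), gp = mean(comp[, 5])))
  }
  list(model = model, opt_g = opt_g, opt_c = opt_c, history = history)
}

#' Train one synthesis stage
#'
#' @param dataset nonempty list of cube records (each with `cube`, `mask`
#'   and, for the mask stage, `condition`; [phantom_dataset()] provides
#'   all fields).
#' @param cfg a [train_config()].
#' @param net_cfg a [network_config()].
#' @param state_path optional RDS path; when given, the full training state
#'   (parameters, optimizer moments, RNG state, history) is checkpointed
#'   every epoch and [resume_training()] can continue from it.
#' @return a train state: list with `model`, `history` (per-epoch loss
#'   components), `epoch`, `cfg`, `net_cfg`.
#' @export
train_stage <- function(dataset, cfg, net_cfg, state_path = NULL) {
  if (length(dataset) == 0L) stop("empty training dataset")
  if (cfg$stage == "mask")
    dataset <- lapply(dataset, function(r) {
      if (is.null(r$condition)) r$condition <- condition_of(r$mask)
      r
    })
  set.seed(cfg$seed)
  model <- create_stage_model(net_cfg, cfg$stage)
  gen_params <- c(collect_params(model$encoder), collect_params(model$decoder))
  cr_params <- collect_params(model$critic)
  opt_g <- adam_new(gen_params, cfg$learning_rate)
  opt_c <- adam_new(cr_params, cfg$learning_rate)
  history <- NULL
  state <- run_epochs(dataset, cfg, model, opt_g, opt_c, history, 0L, state_path)
  state
}

run_epochs <- function(dataset, cfg, model, opt_g, opt_c, history,
                       epoch_from, state_path) {
  for (epoch in (epoch_from + 1L):cfg$epochs) {
    one <- cfg; one$epochs <- epoch
    res <- train_impl(dataset, one, model, opt_g, opt_c, history, epoch - 1L)
    model <- res$model; opt_g <- res$opt_g; opt_c <- res$opt_c
    history <- res$history
    if (!is.null(state_path)) {
      saveRDS(list(net_cfg = model$cfg, stage = model$stage,
                   values = param_values(model[c("encoder", "decoder", "critic")]),
                   opt_g = opt_g, opt_c = opt_c, history = history,
                   epoch = epoch, cfg = cfg,
                   rng = get(".Random.seed", globalenv())),
              state_path)
    }
  }
  structure(list(model = model, history = history, epoch = cfg$epochs,
                 cfg = cfg, net_cfg = model$cfg,
                 opt_g = opt_g, opt_c = opt_c),
            class = "train_state")
}

#' Resume training from a checkpointed state
#'
#' Restores parameters, optimizer moments and the RNG stream, making
#' train-k-then-resume bitwise equivalent to an uninterrupted run.
#'
#' @param state_path RDS written by [train_stage()].
#' @param dataset training dataset (must be nonempty).
#' @param cfg a [train_config()]; `epochs` is the new total epoch target.
#'   Fields other than `epochs` must match the stored run.
#' @return a train state (see [train_stage()]).
#' @export
resume_training <- function(state_path, dataset, cfg) {
  if (length(dataset) == 0L) stop("empty training dataset")
  st <- readRDS(state_path)
  stored <- st$cfg
  for (f in setdiff(names(stored), "epochs")) {
    if (!identical(stored[[f]], cfg[[f]]))
      stop("config mismatch on resume: field '", f, "' differs")
  }
  if (cfg$stage == "mask")
    dataset <- lapply(dataset, function(r) {
      if (is.null(r$condition)) r$condition <- condition_of(r$mask)
      r
    })
  model <- create_stage_model(do.call(network_config, unclass(st$net_cfg)), st$stage)
  set_param_values(model[c("encoder", "decoder", "critic")], st$values)
  # rebind optimizer state to the fresh parameter nodes
  assign(".Random.seed", st$rng, envir = globalenv())
  run_epochs(dataset, cfg, model, st$opt_g, st$opt_c, st$history,
             st$epoch, state_path)
}

#' Desk-scale study protocol
#'
#' The configuration used by the package's own toy-scale experiments:
#' 200 phantoms of side 16 with lesion volumes spanning 20-1200 voxels (a
#' wide size range, so size conditioning has dynamic range to act on),
#' networks with 2 levels and latent dimension 32, one critic step per
#' generator step, 50 epochs per stage.  Two settings differ from the
#' full-scale defaults and are part of the toy conditions: the learning
#' rate (2e-3; the full-scale 5e-5 over 50 epochs would barely move the
#' parameters) and the mask-stage KL weight (5; the information bottleneck
#' must bind for size to migrate from the latent into the condition
#' pathway).  See the methods vignette.
#'
#' @param seed master seed.
#' @param n_phantoms,epochs scale overrides.
#' @return list with `net_cfg`, `mask_cfg`, `lesion_cfg`, `phantom`.
#' @export
toy_protocol <- function(seed = 1L, n_phantoms = 200L, epochs = 50L) {
  net_cfg <- network_config(side = 16L, base_channels = 3L, n_levels = 2L,
                            latent_dim = 32L, embed_hidden = 4L)
  mask_cfg <- train_config(learning_rate = 2e-3, batch_size = 20L,
                           epochs = epochs, critic_steps = 1L, seed = seed,
                           weights = loss_weights(w_rec = 1, w_kl = 5,
                                                  w_adv = 1e-2),
                           stage = "mask")
  lesion_cfg <- train_config(learning_rate = 2e-3, batch_size = 20L,
                             epochs = epochs, critic_steps = 1L,
                             seed = seed + 1L,
                             weights = loss_weights(w_rec = 1, w_kl = 0.1,
                                                    w_adv = 1e-2),
                             stage = "lesion")
  phantom <- phantom_spec(side = 16L, volume_range = c(20L, 1200L),
                          n_lobes = 2L, texture_contrast = 0.3,
                          background_smoothness = 2, seed = seed)
  list(net_cfg = net_cfg, mask_cfg = mask_cfg, lesion_cfg = lesion_cfg,
       phantom = phantom, n_phantoms = as.integer(n_phantoms))
}
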