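# YAML run configuration and the pipeline commands behind the CLI.

default_run_config <- function() {
  list(
    network = list(side = 64L, base_channels = 16L, n_levels = 4L,
                   latent_dim = 128L, leaky_slope = 0.2,
                   condition_dim = 1L, embed_hidden = 16L),
    training = list(learning_rate = 5e-5, batch_size = 13L, epochs = 1000L,
                    critic_steps = 5L, seed = 1L,
                    weights = list(w_rec = 1, w_kl = 1e-3, w_adv = 1e-2,
                                   gp_lambda = 10),
                    reduce = "mean"),
    phantom = list(count = 50L, side = 64L, volume_min = 500L, volume_max = 8000L,
                   n_lobes = 3L, texture_contrast = 0.25,
                   background_smoothness = 2, seed = 1L),
    synthesis = list(count = 100L, threshold = 0.5, condition_min = 0.4,
                     condition_max = 0.8, seed = 1L, keep_largest = TRUE),
    paths = list(data_dir = "data", out_dir = "out"),
    log_level = "info")
}

merge_config <- function(defaults, user, path = character()) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key: ",
         paste(c(path, unknown[1L]), collapse = "."))
  for (k in names(user)) {
    if (is.list(defaults[[k]])) {
      if (!is.list(user[[k]]))
        stop("configuration key '", paste(c(path, k), collapse = "."),
             "' must be a mapping")
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      v <- user[[k]]
      if (is.numeric(defaults[[k]]) && !is.numeric(v))
        stop("configuration key '", paste(c(path, k), collapse = "."),
             "' must be numeric")
      defaults[[k]] <- if (is.integer(defaults[[k]])) as.integer(v) else v
    }
  }
  defaults
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected (typo detection), defaults are filled in, and
#' numeric fields are type-checked.  The paper-derived defaults are a
#' learning rate of 5e-5, gradient-penalty weight 10 and cube side 64.
#'
#' @param path YAML file; `NULL` returns the pure defaults.
#' @return a `run_config` list with components `network`, `training`,
#'   `phantom`, `synthesis`, `paths`, `log_level`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  structure(cfg, class = "run_config")
}

#' Save a resolved run configuration
#' @param cfg a `run_config`.
#' @param path output YAML path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

run_config_objects <- function(cfg) {
  net <- do.call(network_config, cfg$network)
  tr <- function(stage) train_config(
    learning_rate = cfg$training$learning_rate,
    batch_size = cfg$training$batch_size, epochs = cfg$training$epochs,
    critic_steps = cfg$training$critic_steps, seed = cfg$training$seed,
    weights = do.call(loss_weights, cfg$training$weights),
    stage = stage, reduce = cfg$training$reduce)
  ph <- phantom_spec(side = cfg$phantom$side,
                     volume_range = c(cfg$phantom$volume_min, cfg$phantom$volume_max),
                     n_lobes = cfg$phantom$n_lobes,
                     texture_contrast = cfg$phantom$texture_contrast,
                     background_smoothness = cfg$phantom$background_smoothness,
                     seed = cfg$phantom$seed)
  list(net = net, train = tr, phantom = ph)
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message("[lesionsynth] ", ...)
}

read_data_dir <- function(dir, side) {
  imgs <- sort(list.files(dir, pattern = "_image\\.nii(\\.gz)?$", full.names = TRUE))
  if (!length(imgs)) stop("no *_image.nii[.gz] volumes found in ", dir)
  lapply(imgs, function(ip) {
    mp <- sub("_image\\.nii", "_mask.nii", ip)
    if (!file.exists(mp)) stop("missing mask for ", ip)
    pair <- load_volume_pair(ip, mp)
    rec <- extract_cube(pair, side)
    rec$condition <- condition_of(rec$mask)
    rec
  })
}

#' Run one pipeline command
#'
#' Commands mirror the synthesis workflow: `phantom` writes NIfTI phantom
#' pairs and a manifest; `train-mask` / `train-lesion` train one stage and
#' checkpoint it; `sample` synthesizes a cohort from both checkpoints;
#' `evaluate` compares generated and reference volumes.  Every command
#' writes the resolved configuration next to its outputs.
#'
#' @param cfg a `run_config` from [load_config()].
#' @param command one of `"phantom"`, `"train-mask"`, `"train-lesion"`,
#'   `"sample"`, `"evaluate"`.
#' @return invisibly, the primary artifact path(s).
#' @export
run_pipeline <- function(cfg, command = c("phantom", "train-mask",
                                          "train-lesion", "sample", "evaluate")) {
  command <- match.arg(command)
  obj <- run_config_objects(cfg)
  out <- cfg$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  save_config(cfg, file.path(out, "resolved_config.yaml"))
  switch(command,
    "phantom" = {
      dir.create(cfg$paths$data_dir, recursive = TRUE, showWarnings = FALSE)
      ds <- phantom_dataset(cfg$phantom$count, obj$phantom)
      man <- do.call(rbind, lapply(seq_along(ds), function(i) {
        base <- sprintf("phantom_%03d", i)
        pair <- volume_pair(ds[[i]]$cube, ds[[i]]$mask)
        write_volume_pair(pair,
                          file.path(cfg$paths$data_dir, paste0(base, "_image.nii.gz")),
                          file.path(cfg$paths$data_dir, paste0(base, "_mask.nii.gz")))
        data.frame(filename = base, volume = sum(ds[[i]]$mask),
                   condition = ds[[i]]$condition, seed = ds[[i]]$seed)
      }))
      mf <- file.path(cfg$paths$data_dir, "manifest.csv")
      utils::write.csv(man, mf, row.names = FALSE)
      log_msg(cfg, "wrote ", nrow(man), " phantom pairs to ", cfg$paths$data_dir)
      invisible(mf)
    },
    "train-mask" = ,
    "train-lesion" = {
      stage <- sub("train-", "", command)
      ds <- read_data_dir(cfg$paths$data_dir, obj$net$side)
      ck_dir <- file.path(out, "checkpoints")
      dir.create(ck_dir, recursive = TRUE, showWarnings = FALSE)
      st <- train_stage(ds, obj$train(stage), obj$net)
      ck <- file.path(ck_dir, paste0(stage, "_model.rds"))
      save_checkpoint(st$model, ck)
      utils::write.csv(st$history, file.path(ck_dir, paste0(stage, "_loss.csv")),
                       row.names = FALSE)
      log_msg(cfg, "trained ", stage, " stage for ", st$epoch, " epochs")
      invisible(ck)
    },
    "sample" = {
      ck_dir <- file.path(out, "checkpoints")
      mk <- file.path(ck_dir, "mask_model.rds")
      lk <- file.path(ck_dir, "lesion_model.rds")
      if (!file.exists(mk) || !file.exists(lk))
        stop("missing checkpoint: run train-mask and train-lesion first (",
             "looked in ", ck_dir, ")")
      s_dir <- file.path(out, "samples")
      dir.create(s_dir, recursive = TRUE, showWarnings = FALSE)
      coh <- synthesize_cohort(load_checkpoint(mk), load_checkpoint(lk),
                               n = cfg$synthesis$count, seed = cfg$synthesis$seed,
                               condition_range = c(cfg$synthesis$condition_min,
                                                   cfg$synthesis$condition_max),
                               threshold = cfg$synthesis$threshold)
      for (i in seq_along(coh)) {
        r <- coh[[i]]
        if (r$empty) next
        base <- sprintf("sample_%03d", i)
        write_volume_pair(volume_pair(r$lesion, r$mask_bin),
                          file.path(s_dir, paste0(base, "_image.nii.gz")),
                          file.path(s_dir, paste0(base, "_mask.nii.gz")))
      }
      mf <- file.path(s_dir, "manifest.csv")
      utils::write.csv(cohort_manifest(coh), mf, row.names = FALSE)
      log_msg(cfg, "sampled ", length(coh), " lesions into ", s_dir)
      invisible(mf)
    },
    "evaluate" = {
      gen_dir <- file.path(out, "samples")
      ref <- read_data_dir(cfg$paths$data_dir, obj$net$side)
      gens <- sort(list.files(gen_dir, pattern = "_image\\.nii(\\.gz)?$",
                              full.names = TRUE))
      if (!length(gens)) stop("no generated volumes found in ", gen_dir)
      n <- min(length(gens), length(ref))
      pairs <- lapply(seq_len(n), function(i) {
        g <- RNifti::readNifti(gens[i])
        list(gen = array(as.numeric(g), dim(g)), ref = ref[[i]]$cube)
      })
      rep <- metric_report(pairs)
      m_dir <- file.path(out, "metrics")
      dir.create(m_dir, recursive = TRUE, showWarnings = FALSE)
      mf <- file.path(m_dir, "synthesis_metrics.csv")
      utils::write.csv(rep, mf, row.names = FALSE)
      log_msg(cfg, "evaluated ", n, " pairs; summary written to ", mf)
      invisible(mf)
    })
}
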