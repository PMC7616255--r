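# Inference: sample a mask from the mask stage, then a lesion guided by it.
#
# Shape and intensity latent vectors are drawn from N(0, I); the mask stage
# is steered by the lesion-size condition, the lesion stage by the sampled
# mask.  Every output is fully determined by (checkpoints, condition, seed).

#' Sample a lesion mask from a trained mask-stage model
#'
#' Draws `z ~ N(0, I)`, decodes under condition `c`, binarizes at
#' `threshold` and (optionally) keeps the largest connected component.
#'
#' @param model trained mask-stage model.
#' @param c lesion-size condition (scalar or `condition_dim` vector).
#' @param seed integer seed for the latent draw.
#' @param threshold binarization threshold (default 0.5).
#' @param keep_largest drop disconnected speckle (default TRUE).
#' @return list with `mask_soft`, `mask_bin`, `z`, `empty` (TRUE when no
#'   voxel survives the threshold; flagged, not an error, so callers may
#'   resample).
#' @export
sample_mask <- function(model, c, seed, threshold = 0.5, keep_largest = TRUE) {
  cfg <- model$cfg
  z <- with_seed(seed, matrix(stats::rnorm(cfg$latent_dim), 1L))
  soft <- decode_mask(model, z, matrix(c, 1L))
  bin <- (soft > threshold) * 1L
  if (keep_largest && any(bin > 0)) bin <- largest_component(bin)
  list(mask_soft = soft, mask_bin = bin, z = z, empty = !any(bin > 0))
}

#' Sample a lesion cube guided by a mask
#'
#' @param model trained lesion-stage model.
#' @param mask nonempty binary mask of the model's side.
#' @param seed integer seed for the intensity latent draw.
#' @return list with `lesion` (values in `(0, 1)`) and `z`.
#' @export
sample_lesion <- function(model, mask, seed) {
  if (!any(mask > 0)) stop("cannot synthesize a lesion for an empty mask")
  cfg <- model$cfg
  z <- with_seed(seed, matrix(stats::rnorm(cfg$latent_dim), 1L))
  list(lesion = decode_lesion(model, z, mask), z = z)
}

#' Synthesize a cohort of lesion/mask pairs
#'
#' Per-item seeds derive deterministically from the master seed; items whose
#' sampled mask is empty after thresholding are resampled up to
#' `max_retries` times, then flagged.
#'
#' @param mask_model,lesion_model trained stage models.
#' @param n cohort size.
#' @param condition_sampler function `(i) -> condition value`; default
#'   uniform over `condition_range`.
#' @param seed master seed.
#' @param condition_range range for the default condition sampler.
#' @param threshold mask binarization threshold.
#' @param max_retries resampling budget for empty masks.
#' @return list of synthesis results, each with `mask_soft`, `mask_bin`,
#'   `lesion`, `condition`, `seed_mask`, `seed_lesion`, `empty`.
#' @export
synthesize_cohort <- function(mask_model, lesion_model, n,
                              condition_sampler = NULL, seed = 1L,
                              condition_range = c(0.4, 0.8),
                              threshold = 0.5, max_retries = 4L) {
  stopifnot(n >= 1L)
  draws <- with_seed(seed, list(
    seeds = matrix(sample.int(.Machine$integer.max - 1L,
                              n * (max_retries + 1L) * 2L),
                   ncol = 2L),
    cond = stats::runif(n, condition_range[1L], condition_range[2L])))
  out <- vector("list", n)
  row <- 0L
  for (i in seq_len(n)) {
    cval <- if (is.null(condition_sampler)) draws$cond[i] else condition_sampler(i)
    res <- NULL
    for (r in 0:max_retries) {
      row <- row + 1L
      sm <- sample_mask(mask_model, cval, draws$seeds[row, 1L], threshold)
      if (!sm$empty || r == max_retries) {
        les <- if (sm$empty) NULL
               else sample_lesion(lesion_model, sm$mask_bin, draws$seeds[row, 2L])
        res <- list(mask_soft = sm$mask_soft, mask_bin = sm$mask_bin,
                    lesion = if (is.null(les)) NULL else les$lesion,
                    condition = cval,
                    seed_mask = draws$seeds[row, 1L],
                    seed_lesion = draws$seeds[row, 2L],
                    empty = sm$empty)
        break
      }
    }
    # keep per-item seed rows aligned regardless of retries used
    row <- i * (max_retries + 1L)
    out[[i]] <- res
  }
  out
}

#' Cohort manifest
#'
#' @param cohort output of [synthesize_cohort()].
#' @return data frame with condition, seeds, volume and empty flag per item.
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(seq_along(cohort), function(i) {
    r <- cohort[[i]]
    data.frame(item = i, condition = r$condition,
               seed_mask = r$seed_mask, seed_lesion = r$seed_lesion,
               volume = sum(r$mask_bin), empty = r$empty)
  }))
}
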