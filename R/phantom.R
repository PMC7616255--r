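# Synthetic lesion phantoms.
#
# The generator emulates the statistical structure the two-stage model
# assumes in post-ablation MR cubes: a compact, connected lesion of
# controllable volume (union of overlapping random ellipsoids), a smooth
# brain-like background, and a textured intensity shift inside the lesion.
# It stands in for patient data so that every module is testable without
# any download; it does not attempt MR physics (no bias field, no noise
# model beyond speckle).

#' Phantom specification
#'
#' @param side cube side in voxels (>= 8).
#' @param volume_range `(min, max)` admissible lesion volume in voxels;
#'   enforced by hard rejection.
#' @param n_lobes maximum number of overlapping ellipsoid lobes per lesion.
#' @param texture_contrast mean intensity shift of lesion over background,
#'   in `[0, 1]` intensity units.
#' @param background_smoothness Gaussian blur sigma (voxels) of the
#'   background random field.
#' @param seed integer seed; fixed seed reproduces the phantom bitwise.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(side = 64L, volume_range = c(500L, 8000L),
                         n_lobes = 3L, texture_contrast = 0.25,
                         background_smoothness = 2, seed = 1L) {
  side <- as.integer(side)
  if (side < 8L) stop("side must be >= 8")
  if (volume_range[1L] < 1L) stop("volume_range minimum must be >= 1")
  if (volume_range[2L] > side^3) stop("volume_range maximum exceeds side^3")
  if (volume_range[2L] < volume_range[1L]) stop("volume_range must be increasing")
  structure(list(side = side, volume_range = as.numeric(volume_range),
                 n_lobes = as.integer(n_lobes),
                 texture_contrast = texture_contrast,
                 background_smoothness = background_smoothness,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# one rejection-sampled connected multi-lobe mask, consuming the current RNG
gen_mask_impl <- function(spec, max_tries = 300L) {
  side <- spec$side
  gc3 <- grid_coords(side)
  xs <- gc3$i + 0.5; ys <- gc3$j + 0.5; zs <- gc3$k + 0.5
  for (try in seq_len(max_tries)) {
    v_target <- stats::runif(1, spec$volume_range[1L], spec$volume_range[2L])
    n_l <- sample.int(spec$n_lobes, 1L)
    r0 <- (3 * v_target / (4 * pi))^(1 / 3)
    r_l <- r0 * (1 / n_l)^(1 / 3)
    centers <- matrix(0, n_l, 3L)
    axes <- matrix(0, n_l, 3L)
    centers[1L, ] <- side / 2 + stats::runif(3, -side / 8, side / 8)
    axes[1L, ] <- r_l * stats::runif(3, 0.75, 1.35)
    if (n_l > 1L) for (k in 2:n_l) {
      j <- sample.int(k - 1L, 1L)
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      rad <- stats::runif(1)^(1 / 3) * 0.8
      centers[k, ] <- centers[j, ] + dir * rad * axes[j, ]
      axes[k, ] <- r_l * stats::runif(3, 0.75, 1.35)
    }
    inside <- rep(FALSE, side^3)
    for (k in seq_len(n_l)) {
      q <- ((xs - centers[k, 1L]) / axes[k, 1L])^2 +
           ((ys - centers[k, 2L]) / axes[k, 2L])^2 +
           ((zs - centers[k, 3L]) / axes[k, 3L])^2
      inside <- inside | (q <= 1)
    }
    m <- array(as.integer(inside), dim = rep(side, 3L))
    v <- sum(m)
    if (v < spec$volume_range[1L] || v > spec$volume_range[2L]) next
    if (max(label_components(m)) != 1L) next
    return(m)
  }
  stop("could not satisfy volume_range ", spec$volume_range[1L], "..",
       spec$volume_range[2L], " after ", max_tries, " tries")
}

#' Generate a synthetic lesion mask
#'
#' A single connected (26-connectivity) foreground component built from up
#' to `n_lobes` overlapping random ellipsoids, rejection-resampled until the
#' voxel count falls inside `volume_range`.
#'
#' @param spec a [phantom_spec()].
#' @param max_tries rejection-sampling budget before giving up with an
#'   error naming the unsatisfied range.
#' @return binary integer 3D array of side `spec$side`.
#' @export
generate_mask <- function(spec, max_tries = 300L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, gen_mask_impl(spec, max_tries))
}

gen_pair_impl <- function(spec) {
  side <- spec$side
  m <- gen_mask_impl(spec)
  bg <- gaussian_blur3(array(stats::rnorm(side^3), rep(side, 3L)),
                       spec$background_smoothness)
  rg <- range(bg)
  bg <- if (rg[2L] > rg[1L]) 0.3 + 0.4 * (bg - rg[1L]) / (rg[2L] - rg[1L])
        else array(0.5, dim = dim(bg))
  speckle <- 1 + 0.3 * gaussian_blur3(array(stats::rnorm(side^3), rep(side, 3L)), 0.75)
  img <- bg + spec$texture_contrast * speckle * m
  img <- pmin(pmax(img, 0), 1)
  list(cube = array(img, rep(side, 3L)), mask = m,
       origin = c(0L, 0L, 0L), intensity_window = c(0, 1))
}

#' Generate a phantom cube with paired mask
#'
#' Background: a smoothed Gaussian random field rescaled to `[0.3, 0.7]`.
#' Inside the mask the intensity is raised by `texture_contrast` carrying a
#' multiplicative speckle texture; the result is clipped to `[0, 1]`.
#'
#' @param spec a [phantom_spec()].
#' @return a cube record: list with `cube` (values in `[0, 1]`), `mask`,
#'   `origin` and `intensity_window`.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, gen_pair_impl(spec))
}

#' Generate a phantom dataset
#'
#' Per-item seeds are derived deterministically from `spec$seed`, so the
#' whole dataset is reproducible bitwise.
#'
#' @param n number of phantoms.
#' @param spec template [phantom_spec()].
#' @return list of cube records (see [generate_pair()]), each carrying its
#'   `seed` and lesion-size `condition`.
#' @export
phantom_dataset <- function(n, spec) {
  seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(seq_len(n), function(i) {
    sp <- spec; sp$seed <- seeds[i]
    rec <- generate_pair(sp)
    rec$seed <- seeds[i]
    rec$condition <- condition_of(rec$mask)
    rec
  })
}

#' Lesion-size condition of a mask
#'
#' The scalar condition is the normalized log-volume
#' `c = log(V) / log(side^3)`, mapping a single voxel to 0 and a full cube
#' to 1.  Continuous and scale-robust across cube sides.
#'
#' @param mask binary 3D array.
#' @return numeric scalar in `[0, 1]`.
#' @export
condition_of <- function(mask) {
  v <- sum(mask > 0)
  if (v == 0) stop("condition undefined for an empty mask")
  side <- dim(mask)[1L]
  log(v) / log(side^3)
}
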