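# Synthesis-quality metrics (PSNR, 3D SSIM, NMSE) and mask-agreement
# metrics (Dice, Jaccard, average surface distance, 95th percentile
# Hausdorff distance).

#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)`.  Identical inputs have zero error; the
#' sentinel `Inf` is returned.
#'
#' @param x,y numeric arrays of identical shape.
#' @param data_range dynamic range of the data (default 1 for `[0,1]` images).
#' @return PSNR in dB.
#' @export
psnr <- function(x, y, data_range = 1) {
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("shape mismatch")
  stopifnot(data_range > 0)
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Normalized mean square error (percent)
#'
#' `100 * ||x_g - x_r||^2 / ||x_r||^2`, normalizing the error energy by the
#' energy of the real image.  Asymmetric by definition.
#'
#' @param x_g generated array.
#' @param x_r real (reference) array; must not be all-zero.
#' @return NMSE in percent.
#' @export
nmse <- function(x_g, x_r) {
  if (!identical(dim(x_g), dim(x_r)) || length(x_g) != length(x_r))
    stop("shape mismatch")
  den <- sum(x_r^2)
  if (den == 0) stop("NMSE undefined for an all-zero reference")
  100 * sum((x_g - x_r)^2) / den
}

#' Structural similarity of two 3D volumes
#'
#' SSIM with Gaussian-weighted local statistics (sigma 1.5) computed fully
#' in 3D, constants `C1 = (K1*range)^2`, `C2 = (K2*range)^2` with
#' `K1 = 0.01`, `K2 = 0.03`, sample-covariance normalization
#' `N/(N-1)` with `N = window^3`, reflect boundary handling, and the mean
#' taken over the valid (border-cropped) region.  With `window = 11` this
#' reproduces the scikit-image 3D implementation.
#'
#' @param x,y numeric 3D arrays of identical cubic shape.
#' @param window odd window size; default 7 for sides <= 32, else 11.
#' @param data_range dynamic range (default 1).
#' @param sigma Gaussian weighting sigma.
#' @return mean SSIM (<= 1; 1 iff `x == y`).
#' @export
ssim3d <- function(x, y, window = NULL, data_range = 1, sigma = 1.5) {
  if (!identical(dim(x), dim(y)) || length(dim(x)) != 3L)
    stop("shape mismatch or non-3D input")
  n <- dim(x)[1L]
  if (is.null(window)) window <- if (n <= 32L) 7L else 11L
  if (window %% 2L != 1L) stop("window must be odd")
  if (window > n) stop("window (", window, ") larger than volume side (", n, ")")
  r <- (window - 1L) %/% 2L
  w <- gaussian_kernel1d(sigma, r)
  f <- function(a) separable_filter3(a, w)
  ux <- f(x); uy <- f(y)
  np <- window^3
  cov_norm <- np / (np - 1)
  vx <- cov_norm * (f(x * x) - ux * ux)
  vy <- cov_norm * (f(y * y) - uy * uy)
  vxy <- cov_norm * (f(x * y) - ux * uy)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  s <- ((2 * ux * uy + c1) * (2 * vxy + c2)) /
       ((ux^2 + uy^2 + c1) * (vx + vy + c2))
  keep <- (r + 1L):(n - r)
  mean(s[keep, keep, keep])
}

# boundary voxels: foreground with at least one 6-neighbour background voxel
surface_voxels <- function(mask) {
  d <- dim(mask)
  pad <- array(0L, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- (mask > 0) * 1L
  inner <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE] +
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE] +
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1), drop = FALSE] +
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1), drop = FALSE] +
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3], drop = FALSE] +
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2), drop = FALSE]
  which(inner == 1L & nb < 6L, arr.ind = TRUE)
}

# nearest-neighbour distances from each row of a to the point set b
nn_dists <- function(a, b, spacing) {
  a <- sweep(a, 2L, spacing, "*")
  b <- sweep(b, 2L, spacing, "*")
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
        outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(pmax(apply(d2, 1L, min), 0))
}

#' Mask-agreement metrics
#'
#' Dice, Jaccard, average surface distance (mean of bidirectional
#' nearest-surface distances) and the 95th percentile Hausdorff distance.
#' Surface voxels are foreground voxels with a 6-neighbour background voxel.
#'
#' @param a,b binary 3D arrays of identical shape.
#' @param spacing voxel spacing triple; the default `c(1, 1, 1)` reports
#'   distances in voxels.
#' @return list with `dice`, `jaccard`, `asd`, `hd95`.  If either mask is
#'   empty the surface metrics are `NA` (sentinel); `dice`/`jaccard` are 1
#'   when both are empty and 0 when exactly one is.
#' @export
mask_agreement <- function(a, b, spacing = c(1, 1, 1)) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  af <- a > 0; bf <- b > 0
  na <- sum(af); nb <- sum(bf)
  if (na == 0 && nb == 0)
    return(list(dice = 1, jaccard = 1, asd = NA_real_, hd95 = NA_real_))
  if (na == 0 || nb == 0)
    return(list(dice = 0, jaccard = 0, asd = NA_real_, hd95 = NA_real_))
  inter <- sum(af & bf)
  dice <- 2 * inter / (na + nb)
  jac <- inter / sum(af | bf)
  sa <- surface_voxels(af * 1L)
  sb <- surface_voxels(bf * 1L)
  dists <- c(nn_dists(sa, sb, spacing), nn_dists(sb, sa, spacing))
  list(dice = dice, jaccard = jac, asd = mean(dists),
       hd95 = as.numeric(stats::quantile(dists, 0.95, type = 7)))
}

#' Otsu threshold of an intensity cube
#'
#' Maximizes between-class variance over a 256-bin histogram; used to
#' delineate the high-contrast region of a generated lesion cube.
#'
#' @param x numeric array.
#' @return threshold value.
#' @export
otsu_threshold <- function(x) {
  v <- as.numeric(x)
  rg <- range(v)
  if (rg[2L] <= rg[1L]) return(rg[1L])
  nb <- 256L
  br <- seq(rg[1L], rg[2L], length.out = nb + 1L)
  h <- tabulate(pmin(findInterval(v, br, rightmost.closed = TRUE), nb), nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1L] + br[-(nb + 1L)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' High-contrast support of a generated lesion cube
#'
#' Thresholds the cube at its Otsu level and keeps the largest connected
#' component, giving the binary region a generated lesion occupies.
#'
#' @param x intensity cube in `[0, 1]`.
#' @return binary 3D array.
#' @export
lesion_support <- function(x) {
  largest_component((x > otsu_threshold(x)) * 1L)
}

#' Evaluate generated volumes against references
#'
#' @param pairs list of `list(gen =, ref =)` arrays.
#' @param data_range dynamic range passed to [psnr()] and [ssim3d()].
#' @return data frame with per-pair `psnr`, `ssim`, `nmse` plus a final
#'   `mean` row.
#' @export
metric_report <- function(pairs, data_range = 1) {
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    data.frame(pair = i,
               psnr = psnr(p$gen, p$ref, data_range),
               ssim = ssim3d(p$gen, p$ref, data_range = data_range),
               nmse = nmse(p$gen, p$ref))
  })
  df <- do.call(rbind, rows)
  fin <- df$psnr[is.finite(df$psnr)]
  rbind(df, data.frame(pair = NA,
                       psnr = if (length(fin)) mean(fin) else Inf,
                       ssim = mean(df$ssim), nmse = mean(df$nmse)))
}
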