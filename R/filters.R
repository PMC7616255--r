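# Separable 3D Gaussian filtering and connected-component labelling,
# shared by the phantom generator, the SSIM metric and mask post-processing.

gaussian_kernel1d <- function(sigma, radius) {
  x <- (-radius):radius
  w <- exp(-0.5 * (x / sigma)^2)
  w / sum(w)
}

# reflect-pad index map (edge duplicated: d c b a | a b c d | d c b a)
reflect_idx <- function(n, r) {
  p <- (-r):(n - 1L + r)
  p <- ifelse(p < 0L, -p - 1L, p)
  p <- ifelse(p >= n, 2L * n - 1L - p, p)
  p + 1L
}

# banded filtering matrix applying kernel w (length 2r+1) with reflect padding
filt_mat <- function(n, w) {
  r <- (length(w) - 1L) %/% 2L
  K <- matrix(0, n, n + 2L * r)
  for (j in seq_along(w)) K[cbind(seq_len(n), seq_len(n) + j - 1L)] <- w[j]
  pidx <- reflect_idx(n, r)
  S <- matrix(0, n + 2L * r, n)
  S[cbind(seq_len(n + 2L * r), pidx)] <- 1
  K %*% S
}

# filter a 3D array along every axis with the same 1D kernel
separable_filter3 <- function(a, w) {
  d <- dim(a)
  for (ax in 1:3) {
    K <- filt_mat(d[1L], w)
    m <- matrix(a, d[1L], d[2L] * d[3L])
    a <- array(K %*% m, dim = d)
    a <- aperm(a, c(2L, 3L, 1L))
    d <- dim(a)
  }
  a
}

#' Gaussian blur of a 3D volume
#'
#' Separable Gaussian filtering with reflect boundary handling.
#'
#' @param a 3D numeric array (cubic).
#' @param sigma standard deviation in voxels; `0` returns the input.
#' @param radius kernel half-width; defaults to `round(3.5 * sigma)`.
#' @return filtered array, same shape.
#' @export
gaussian_blur3 <- function(a, sigma, radius = NULL) {
  if (sigma <= 0) return(a)
  if (is.null(radius)) radius <- max(1L, as.integer(round(3.5 * sigma)))
  separable_filter3(a, gaussian_kernel1d(sigma, radius))
}

# 26-connectivity neighbour offsets in a padded array with dims dp
conn26_offsets <- function(dp) {
  off <- integer(0)
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1)
    if (di != 0L || dj != 0L || dk != 0L)
      off <- c(off, di + dj * dp[1L] + dk * dp[1L] * dp[2L])
  off
}

#' Label connected components of a binary 3D mask (26-connectivity)
#'
#' @param mask 3D array with values {0, 1}.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  dp <- d + 2L
  pad <- array(0L, dim = dp)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- (mask > 0) * 1L
  lab <- array(0L, dim = dp)
  off <- conn26_offsets(dp)
  fg <- which(pad == 1L)
  cur <- 0L
  queue <- integer(length(fg))
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    queue[1L] <- s; head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      for (o in off) {
        w <- v + o
        if (pad[w] == 1L && lab[w] == 0L) {
          lab[w] <- cur
          tail <- tail + 1L
          queue[tail] <- w
        }
      }
    }
  }
  lab[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
}

#' Keep only the largest connected component of a binary mask
#'
#' @param mask 3D array with values {0, 1}.
#' @return binary array; all zeros if the input is empty.
#' @export
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (all(lab == 0L)) return(array(0L, dim = dim(mask)))
  sizes <- tabulate(lab[lab > 0L])
  (lab == which.max(sizes)) * 1L
}
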