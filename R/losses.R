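# Training losses: reconstruction (MSE), closed-form Gaussian KL, and the
# Wasserstein critic/generator pair with gradient penalty.
#
# The reconstruction and KL losses are written in the literature as sums over
# the mini-batch; here the per-sample quantity (sum over voxels / latent
# dimensions) is averaged over the batch by default so magnitudes do not
# depend on batch size.  `reduce = "sum"` restores the raw batch sum.

#' Loss weights
#'
#' @param w_rec,w_kl,w_adv non-negative weights of the reconstruction, KL and
#'   adversarial generator terms.
#' @param gp_lambda gradient-penalty weight (default 10).
#' @export
loss_weights <- function(w_rec = 1, w_kl = 1e-3, w_adv = 1e-2, gp_lambda = 10) {
  stopifnot(w_rec >= 0, w_kl >= 0, w_adv >= 0, gp_lambda >= 0)
  list(w_rec = w_rec, w_kl = w_kl, w_adv = w_adv, gp_lambda = gp_lambda)
}

batch_reduce_node <- function(per_sample, reduce) {
  B <- nrow(per_sample$v)
  s <- tg_matmul(tg_const(matrix(1, 1L, B)), per_sample)
  if (reduce == "mean") tg_scale(s, 1 / B) else s
}

# node-level builders (x_g, x_r: (V*B x 1) nodes) --------------------------

rec_loss_node <- function(x_g, x_r, B, reduce = "mean") {
  V <- nrow(x_g$v) %/% B
  per <- pool_sum(tg_powc(tg_sub(x_g, x_r), 2), V, B)
  batch_reduce_node(per, reduce)
}

kl_loss_node <- function(mu, logvar, reduce = "mean") {
  term <- tg_sub(tg_add(tg_powc(mu, 2), tg_exp(logvar)), tg_shift(logvar, 1))
  per <- tg_scale(tg_matmul(term, tg_const(matrix(1, ncol(mu$v), 1L))), 0.5)
  batch_reduce_node(per, reduce)
}

mean_node <- function(x) tg_scale(tg_sum(x), 1 / length(x$v))

# gradient penalty as a graph node; critic_fn maps an input node to a
# (B x 1) score node.  The first backward pass (with graph construction)
# yields d(score)/d(x_hat) as a node; the penalty built from it remains
# differentiable with respect to the critic parameters.
gp_node <- function(critic_fn, x_real, x_fake, gp_lambda, u) {
  B <- length(u)
  V <- length(x_real) %/% B
  alpha <- rep(u, each = V)
  xhat <- tg_leaf(matrix(alpha * x_real + (1 - alpha) * x_fake, ncol = 1L), rg = TRUE)
  s <- critic_fn(xhat)
  grads <- tg_backward(tg_sum(s))
  gx <- tg_grad(grads, xhat)
  if (is.null(gx)) stop("critic is not differentiable with respect to its input")
  norms <- tg_powc(pool_sum(tg_powc(gx, 2), V, B), 0.5)
  tg_scale(mean_node(tg_powc(tg_shift(norms, -1), 2)), gp_lambda)
}

# ---- public array-level API ------------------------------------------------

# a vector or 3D array is a single sample; otherwise the last dimension is
# the batch (columns of the result)
as_batch_mat <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 3L) return(matrix(as.numeric(x), ncol = 1L))
  matrix(as.numeric(x), ncol = d[length(d)])
}

#' Reconstruction loss (mean squared error, summed within sample)
#'
#' Per sample the squared Euclidean distance between generated and real
#' cubes is taken (sum over voxels); samples are then averaged (default) or
#' summed over the batch.
#'
#' @param x_g,x_r numeric arrays of identical shape; the last dimension is
#'   the batch (a plain 3D cube is a batch of one).
#' @param reduce `"mean"` (batch-size invariant) or `"sum"`.
#' @return scalar loss.
#' @export
reconstruction_loss <- function(x_g, x_r, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  if (!identical(dim(x_g), dim(x_r)) || length(x_g) != length(x_r))
    stop("shape mismatch between generated and real batches")
  g <- as_batch_mat(x_g); r <- as_batch_mat(x_r)
  per <- colSums((g - r)^2)
  if (reduce == "mean") mean(per) else sum(per)
}

#' Closed-form KL divergence to the standard normal prior
#'
#' For a diagonal Gaussian posterior `N(mu, diag(exp(logvar)))` the KL
#' divergence to `N(0, I)` is
#' `0.5 * sum(mu^2 + exp(logvar) - 1 - logvar)` per sample.
#'
#' @param mu,logvar numeric vectors (one sample) or `B x L` matrices.
#' @param reduce `"mean"` or `"sum"` over the batch.
#' @return scalar, always `>= 0`.
#' @export
kl_loss <- function(mu, logvar, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  mu <- if (is.matrix(mu)) mu else matrix(mu, 1L)
  logvar <- if (is.matrix(logvar)) logvar else matrix(logvar, 1L)
  if (!all(dim(mu) == dim(logvar))) stop("mu and logvar shapes differ")
  if (!all(is.finite(mu)) || !all(is.finite(logvar)))
    stop("non-finite values in mu or logvar")
  per <- 0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
  if (reduce == "mean") mean(per) else sum(per)
}

#' Wasserstein critic loss
#'
#' `mean(scores_fake) - mean(scores_real) + gp`: the critic is pushed to
#' score real samples above generated ones, subject to the gradient penalty.
#'
#' @param scores_fake,scores_real numeric score vectors.
#' @param gp non-negative gradient-penalty term.
#' @export
critic_loss <- function(scores_fake, scores_real, gp = 0) {
  stopifnot(gp >= 0)
  mean(scores_fake) - mean(scores_real) + gp
}

#' Gradient penalty of a critic
#'
#' Draws `u ~ Uniform(0, 1)` per sample, forms the interpolates
#' `x_hat = u * x_real + (1 - u) * x_fake`, and penalizes the deviation of
#' the critic's input-gradient norm from 1:
#' `gp_lambda * mean((||d D(x_hat)/d x_hat||_2 - 1)^2)`.
#' Gradients are exact (reverse-mode automatic differentiation).
#'
#' @param critic a `stage_model`, or a function mapping an input tape node
#'   (`(V*B) x 1`) to a `B x 1` score node.
#' @param x_real,x_fake arrays of identical shape, last dimension = batch.
#' @param gp_lambda penalty weight (default 10).
#' @param u optional vector of interpolation draws (length B); drawn from
#'   the current RNG when omitted.
#' @return scalar penalty value.
#' @export
gradient_penalty <- function(critic, x_real, x_fake, gp_lambda = 10, u = NULL) {
  if (!identical(dim(x_real), dim(x_fake)) || length(x_real) != length(x_fake))
    stop("shape mismatch between real and fake batches")
  B <- ncol(as_batch_mat(x_real))
  if (is.null(u)) u <- stats::runif(B)
  fn <- if (is.function(critic)) critic
        else function(xn) critic_fwd(critic$critic, xn, critic$cfg, B)
  as.numeric(gp_node(fn, as.numeric(x_real), as.numeric(x_fake), gp_lambda, u)$v)
}

#' Generator loss
#'
#' `w_adv * (-mean(scores_fake)) + w_rec * rec + w_kl * kl`.
#'
#' @param scores_fake critic scores of generated samples.
#' @param rec reconstruction-loss value.
#' @param kl KL-loss value.
#' @param w a [loss_weights()] list.
#' @export
generator_loss <- function(scores_fake, rec, kl, w = loss_weights()) {
  w$w_adv * (-mean(scores_fake)) + w$w_rec * rec + w$w_kl * kl
}
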