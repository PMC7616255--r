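# Loss functions against closed forms, brute-force loops, a sampling
# estimate of the KL divergence, and finite-difference gradient norms.

test_that("reconstruction loss matches closed forms and a brute-force loop", {
  x <- array(runif(4^3), rep(4, 3))
  expect_equal(reconstruction_loss(x, x), 0)
  # batch of one two-voxel pair: (1-0)^2 + (1-0)^2 = 2
  expect_equal(reconstruction_loss(c(1, 1), c(0, 0)), 2)
  set.seed(401)
  g <- array(runif(8^3 * 3), c(8, 8, 8, 3))
  r <- array(runif(8^3 * 3), c(8, 8, 8, 3))
  brute <- 0
  for (b in 1:3) {
    s <- 0
    for (v in seq_len(8^3)) s <- s + (as.vector(g[, , , b])[v] - as.vector(r[, , , b])[v])^2
    brute <- brute + s
  }
  expect_equal(reconstruction_loss(g, r, reduce = "sum"), brute, tolerance = 1e-6)
  expect_equal(reconstruction_loss(g, r, reduce = "mean"), brute / 3, tolerance = 1e-6)
  expect_error(reconstruction_loss(g, r[, , , 1:2]), "mismatch")
})

test_that("KL loss matches the diagonal-Gaussian closed form", {
  expect_equal(kl_loss(c(0, 0), c(0, 0)), 0)
  expect_equal(kl_loss(c(1, 0), c(0, 0)), 0.5)
  # sampling oracle: KL = E_q[log q(z) - log p(z)] over 1e5 draws
  set.seed(402)
  mu <- c(0.3, -0.6); logvar <- c(0.4, -0.3)
  n <- 1e5
  z <- matrix(rnorm(2 * n, mean = rep(mu, each = n),
                    sd = rep(exp(0.5 * logvar), each = n)), n)
  lq <- dnorm(z[, 1], mu[1], exp(0.5 * logvar[1]), log = TRUE) +
        dnorm(z[, 2], mu[2], exp(0.5 * logvar[2]), log = TRUE)
  lp <- dnorm(z[, 1], log = TRUE) + dnorm(z[, 2], log = TRUE)
  expect_equal(kl_loss(mu, logvar), mean(lq - lp), tolerance = 0.02)
  expect_error(kl_loss(c(0, NA), c(0, 0)), "finite")
})

test_that("KL loss is non-negative on random inputs", {
  set.seed(403)
  for (i in 1:20) {
    mu <- matrix(rnorm(8, sd = 2), 2)
    lv <- matrix(rnorm(8, sd = 1.5), 2)
    expect_gte(kl_loss(mu, lv), 0)
  }
})

test_that("critic loss composes scores and penalty as stated", {
  expect_equal(critic_loss(c(1, 2), c(1, 2), 0), 0)
  expect_equal(critic_loss(2, 5, 40), 37)
  # lowering the real scores strictly increases the loss
  expect_gt(critic_loss(c(0, 0), c(-1, -1), 0), critic_loss(c(0, 0), c(1, 1), 0))
})

test_that("gradient penalty is exact for linear critics", {
  set.seed(404)
  B <- 2L; V <- 4^3
  xr <- array(runif(V * B), c(4, 4, 4, B))
  xf <- array(runif(V * B), c(4, 4, 4, B))
  lin_critic <- function(norm_target) {
    w <- rnorm(V); w <- norm_target * w / sqrt(sum(w^2))
    function(xn) {
      per <- lesionsynth:::pool_sum(tg_mul(xn, tg_const(matrix(rep(w, B), ncol = 1L))), V, B)
      per
    }
  }
  expect_equal(gradient_penalty(lin_critic(1), xr, xf, 10), 0, tolerance = 1e-10)
  expect_equal(gradient_penalty(lin_critic(3), xr, xf, 10), 40, tolerance = 1e-8)
})

test_that("gradient penalty matches finite-difference gradient norms", {
  set.seed(405)
  cfg <- tiny_cfg(side = 4L, base = 2L, levels = 1L, latent = 3L)
  model <- create_stage_model(cfg, "mask")
  B <- 2L; V <- 4^3
  xr <- array(runif(V * B), c(4, 4, 4, B))
  xf <- array(runif(V * B), c(4, 4, 4, B))
  u <- c(0.3, 0.8)
  got <- gradient_penalty(model, xr, xf, 10, u = u)
  # finite-difference gradient of the critic score at each interpolate
  xhat <- sweep(xr, 4, u, "*") + sweep(xf, 4, 1 - u, "*")
  h <- 1e-5
  pen <- 0
  for (b in 1:B) {
    g <- numeric(V)
    xb <- xhat[, , , b]
    for (v in seq_len(V)) {
      xp <- xb; xp[v] <- xp[v] + h
      xm <- xb; xm[v] <- xm[v] - h
      g[v] <- (critic_score(model, xp) - critic_score(model, xm)) / (2 * h)
    }
    pen <- pen + (sqrt(sum(g^2)) - 1)^2
  }
  expect_equal(got, 10 * pen / B, tolerance = 1e-3)
})

test_that("gradient penalty is symmetric under swapping real and fake with u -> 1-u", {
  set.seed(406)
  cfg <- tiny_cfg(side = 4L, base = 2L, levels = 1L, latent = 3L)
  model <- create_stage_model(cfg, "mask")
  xr <- array(runif(4^3 * 2), c(4, 4, 4, 2))
  xf <- array(runif(4^3 * 2), c(4, 4, 4, 2))
  u <- runif(2)
  expect_equal(gradient_penalty(model, xr, xf, 10, u = u),
               gradient_penalty(model, xf, xr, 10, u = 1 - u), tolerance = 1e-10)
})

test_that("generator loss combines terms linearly", {
  expect_equal(generator_loss(c(1, 3), 0, 0, loss_weights(w_adv = 0)), 0)
  expect_equal(generator_loss(4, 0, 0, loss_weights(w_rec = 0, w_kl = 0, w_adv = 1)), -4)
  w <- loss_weights(w_rec = 1, w_kl = 0.5, w_adv = 0.1)
  base <- generator_loss(c(1, 2), 3, 4, w)
  expect_equal(generator_loss(c(1, 2), 3, 4 + 2, w) - base, w$w_kl * 2)
  expect_equal(generator_loss(c(1, 2), 3 + 5, 4, w) - base, w$w_rec * 5)
})

test_that("all losses stay finite for inputs in [0, 1]", {
  set.seed(407)
  g <- array(runif(4^3 * 2), c(4, 4, 4, 2))
  r <- array(runif(4^3 * 2), c(4, 4, 4, 2))
  model <- create_stage_model(tiny_cfg(side = 4L, base = 2L, levels = 1L), "mask")
  expect_true(is.finite(reconstruction_loss(g, r)))
  expect_true(is.finite(kl_loss(runif(4), runif(4))))
  expect_true(is.finite(gradient_penalty(model, g, r, 10)))
})
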