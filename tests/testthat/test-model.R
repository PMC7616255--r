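# Network contracts: shapes, determinism, modulation-block identities,
# reparameterization statistics, checkpoint round-trips.

test_that("encode meets shape, determinism and degenerate-input contracts", {
  set.seed(301)
  cfg <- tiny_cfg()
  model <- create_stage_model(cfg, "mask")
  x <- array(runif(8^3), rep(8, 3))
  eps <- matrix(rnorm(cfg$latent_dim), 1L)
  e1 <- encode(model, x, eps = eps, c = 0.5)
  e2 <- encode(model, x, eps = eps, c = 0.5)
  expect_identical(e1$z, e2$z)
  expect_equal(ncol(e1$mu), cfg$latent_dim)
  expect_equal(e1$z, e1$mu + exp(0.5 * e1$logvar) * eps)
  ez <- encode(model, array(0, rep(8, 3)), eps = eps, c = 0.5)
  expect_true(all(is.finite(ez$mu)) && all(is.finite(ez$logvar)))
  expect_error(encode(model, array(0, rep(16, 3)), c = 0.5), "side")
  expect_error(encode(model, x, eps = eps), "condition-aware")
})

test_that("decoders are deterministic, sigmoid-bounded and shape-preserving", {
  set.seed(302)
  cfg <- tiny_cfg()
  mm <- create_stage_model(cfg, "mask")
  lm <- create_stage_model(cfg, "lesion")
  z <- rnorm(cfg$latent_dim)
  m1 <- decode_mask(mm, z, 0.5)
  expect_identical(dim(m1), rep(8L, 3L))
  expect_true(all(m1 > 0 & m1 < 1))
  expect_identical(m1, decode_mask(mm, z, 0.5))
  mask <- generate_mask(phantom_spec(side = 8, volume_range = c(5, 80), seed = 3))
  l1 <- decode_lesion(lm, z, mask)
  expect_identical(dim(l1), dim(mask))
  expect_true(all(l1 > 0 & l1 < 1))
  expect_identical(l1, decode_lesion(lm, z, mask))
  expect_error(decode_mask(mm, z, c(0.5, 0.2)), "condition")
  expect_error(decode_lesion(lm, z[-1], mask), "latent")
  expect_error(decode_mask(lm, z, 0.5), "mask-stage")
})

test_that("CEB with zero-initialized heads is exactly instance normalization", {
  set.seed(303)
  f <- array(rnorm(6^3 * 3 * 2, 1, 2), c(6, 6, 6, 3, 2))
  blk <- ceb_block(1L, 3L, 4L)
  out <- ceb_modulate(f, 0.7, blk)
  # instance-norm oracle computed directly per sample and channel
  for (b in 1:2) for (c in 1:3) {
    v <- f[, , , c, b]
    ref <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5)
    expect_equal(out[, , , c, b], ref, tolerance = 1e-10)
  }
  # per-channel moments of the normalized field
  expect_lt(max(abs(apply(out, c(4, 5), mean))), 1e-4)
  expect_lt(max(abs(apply(out, c(4, 5), function(v) mean(v^2)) - 1)), 1e-4)
  # constant-valued channel: normalized to ~0, so output is beta(c) = 0
  f[, , , 2, 1] <- 5
  out <- ceb_modulate(f, 0.7, blk)
  expect_lt(max(abs(out[, , , 2, 1])), 1e-6)
})

test_that("MEB with zero-initialized heads is exactly instance normalization", {
  set.seed(304)
  f <- array(rnorm(8^3 * 2), c(8, 8, 8, 2))
  m <- array((runif(16^3) > 0.8) * 1, rep(16, 3))
  blk <- meb_block(2L, 3L)
  out <- meb_modulate(f, m, blk)
  for (c in 1:2) {
    v <- f[, , , c]
    ref <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + 1e-5)
    expect_equal(out[, , , c], ref, tolerance = 1e-10)
  }
  # all-zero mask also reduces to instance normalization (zero conv biases)
  out0 <- meb_modulate(f, array(0, rep(16, 3)), blk)
  expect_equal(out0, out, tolerance = 1e-10)
  expect_identical(dim(out), dim(f))
})

test_that("critic returns one finite deterministic score per sample", {
  set.seed(305)
  cfg <- tiny_cfg()
  model <- create_stage_model(cfg, "mask")
  xb <- array(runif(8^3 * 3), c(8, 8, 8, 3))
  s <- critic_score(model, xb)
  expect_length(s, 3L)
  expect_identical(s, critic_score(model, xb))
  expect_true(all(is.finite(critic_score(model, array(0, rep(8, 3))))))
  expect_true(all(is.finite(critic_score(model, array(1, rep(8, 3))))))
})

test_that("reparameterized draws average to mu", {
  set.seed(306)
  cfg <- tiny_cfg()
  model <- create_stage_model(cfg, "mask")
  x <- array(runif(8^3), rep(8, 3))
  e0 <- encode(model, x, eps = matrix(0, 1L, cfg$latent_dim), c = 0.5)
  # draw in batches: the batch replicates one cube, so mu is shared
  B <- 200L; reps <- 10L
  xb <- array(rep(x, B), c(8, 8, 8, B))
  zs <- do.call(rbind, lapply(seq_len(reps), function(i) encode(model, xb, c = 0.5)$z))
  n <- B * reps
  sd_hat <- exp(0.5 * e0$logvar[1, ])
  expect_true(all(abs(colMeans(zs) - e0$mu[1, ]) < 3 * sd_hat / sqrt(n) + 1e-8))
})

test_that("checkpoints reload to an identical model", {
  set.seed(307)
  cfg <- tiny_cfg()
  model <- create_stage_model(cfg, "lesion")
  mask <- generate_mask(phantom_spec(side = 8, volume_range = c(5, 80), seed = 9))
  z <- rnorm(cfg$latent_dim)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  loaded <- load_checkpoint(path)
  expect_identical(decode_lesion(loaded, z, mask), decode_lesion(model, z, mask))
  expect_identical(loaded$cfg$latent_dim, cfg$latent_dim)
})
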