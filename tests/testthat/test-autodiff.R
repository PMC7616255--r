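# Reverse-mode tape: gradient correctness against finite differences,
# adjointness of the structural gather/scatter operators, and second-order
# differentiation through a first backward pass.

test_that("network gradients match central finite differences", {
  set.seed(101)
  cfg <- tiny_cfg(side = 4L, base = 2L, levels = 1L, latent = 3L)
  B <- 2L
  x <- matrix(runif(4^3 * B), ncol = 1L)
  enc <- lesionsynth:::create_encoder(cfg)
  fval <- function() {
    o <- encoder_fwd(enc, tg_const(x), cfg, B)
    sum(o$mu$v^2) + sum(exp(o$logvar$v))
  }
  o <- encoder_fwd(enc, tg_const(x), cfg, B)
  loss <- tg_add(tg_sum(tg_powc(o$mu, 2)), tg_sum(tg_exp(o$logvar)))
  gr <- tg_backward(loss)
  for (P in collect_params(enc)) {
    ga <- tg_grad_value(gr, P)
    for (i in sample.int(length(P$v), min(3L, length(P$v))))
      expect_equal(ga[i], fd_grad(P, i, fval), tolerance = 1e-5)
  }
})

test_that("decoder gradients (CEB and MEB paths) match finite differences", {
  set.seed(102)
  cfg <- tiny_cfg(side = 8L, base = 2L, levels = 2L, latent = 4L)
  B <- 2L
  z <- matrix(rnorm(B * 4), B)
  for (type in c("ceb", "meb")) {
    dec <- lesionsynth:::create_decoder(cfg, type)
    for (P in collect_params(dec))  # randomize zero-initialized heads too
      P$v <- matrix(rnorm(length(P$v), 0, 0.1), nrow(P$v))
    guide <- if (type == "ceb") tg_const(matrix(c(0.3, 0.8), B))
             else tg_const(matrix((runif(8^3 * B) > 0.7) * 1, ncol = 1L))
    fval <- function() sum(decoder_fwd(dec, tg_const(z), guide, cfg, B)$v^2)
    y <- decoder_fwd(dec, tg_const(z), guide, cfg, B)
    gr <- tg_backward(tg_sum(tg_powc(y, 2)))
    ps <- collect_params(dec)
    for (P in ps[seq(1L, length(ps), by = 4L)]) {
      ga <- tg_grad_value(gr, P)
      for (i in sample.int(length(P$v), min(2L, length(P$v))))
        expect_equal(ga[i], fd_grad(P, i, fval), tolerance = 1e-4)
    }
  }
})

test_that("gather and scatter are exact adjoints", {
  set.seed(103)
  for (rep in 1:3) {
    n_in <- 30L; n_out <- 50L
    idx <- sample(c(0L, seq_len(n_in)), n_out, replace = TRUE)
    x <- matrix(rnorm(n_in * 2), n_in)
    y <- matrix(rnorm(n_out * 2), n_out)
    gx <- tg_rowgather(tg_const(x), idx)$v
    sy <- tg_rowscatter(tg_const(y), idx, n_in)$v
    expect_equal(sum(gx * y), sum(x * sy), tolerance = 1e-12)
  }
  # im2col / col2im pair on a real conv geometry
  cg <- conv_geom(4L, 2L, 2L)
  x <- matrix(rnorm(4^3 * 2 * 3), ncol = 3L)
  y <- matrix(rnorm(cg$VoB * 27 * 3), nrow = cg$VoB)
  gx <- tg_im2col(tg_const(x), cg$idx, cg$VoB, 27L)$v
  sy <- tg_col2im(tg_const(y), cg$idx, nrow(x), 27L)$v
  expect_equal(sum(gx * y), sum(x * sy), tolerance = 1e-10)
})

test_that("a second backward pass through a gradient is exact", {
  # f(x) = sum_i (dD/dx_i)^2 for a small nonlinear critic; d f / d theta
  # requires differentiating through the first backward pass
  set.seed(104)
  cfg <- tiny_cfg(side = 4L, base = 2L, levels = 1L, latent = 3L)
  cr <- lesionsynth:::create_critic(cfg)
  B <- 2L
  x <- matrix(runif(4^3 * B), ncol = 1L)
  fval <- function() {
    xn <- tg_leaf(x, rg = TRUE)
    s <- critic_fwd(cr, xn, cfg, B)
    gr <- tg_backward(tg_sum(s))
    sum(tg_grad_value(gr, xn)^2)
  }
  xn <- tg_leaf(x, rg = TRUE)
  s <- critic_fwd(cr, xn, cfg, B)
  gr1 <- tg_backward(tg_sum(s))
  gx <- lesionsynth:::tg_grad(gr1, xn)
  loss <- tg_sum(tg_powc(gx, 2))
  gr2 <- tg_backward(loss)
  for (P in list(cr$convs[[1]]$W, cr$head$W)) {
    ga <- tg_grad_value(gr2, P)
    for (i in sample.int(length(P$v), min(3L, length(P$v))))
      expect_equal(ga[i], fd_grad(P, i, fval, h = 1e-5), tolerance = 1e-4)
  }
})

test_that("permutation nodes invert exactly", {
  set.seed(105)
  fp <- flat_perm(8L, 3L, 2L)
  x <- matrix(rnorm(8 * 3 * 2), 16L, 3L)
  flat <- tg_perm(tg_const(x), fp$perm, fp$iperm, fp$flat_dims)
  back <- tg_perm(flat, fp$iperm, fp$perm, fp$map_dims)
  expect_identical(back$v, x)
})
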