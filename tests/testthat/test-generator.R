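# Generator architecture contracts, SE gating, gradients.

test_that("seeded init is bit-identical and capacity grows with width", {
  a <- build_generator(tiny_gcfg(), seed = 3)
  b <- build_generator(tiny_gcfg(), seed = 3)
  expect_identical(a$params, b$params)
  c <- build_generator(tiny_gcfg(), seed = 4)
  expect_false(identical(a$params, c$params))

  n8 <- wgseg:::n_params(build_generator(
    generator_config(base_filters = 8, depth = 2, se_reduction = 4),
    seed = 1))
  n16 <- wgseg:::n_params(build_generator(
    generator_config(base_filters = 16, depth = 2, se_reduction = 4),
    seed = 1))
  expect_gt(n16, n8)
})

test_that("channel widths and parameter count match a closed form", {
  bf <- 8L; d <- 3L; red <- 4L; k <- 4L
  g <- build_generator(generator_config(base_filters = bf, depth = d,
                                        se_reduction = red,
                                        num_labels = k), seed = 0)
  # widths double per encoder level: base_filters * 2^level
  for (l in seq_len(d)) {
    cw <- bf * 2^(l - 1L)
    expect_equal(ncol(g$params[[paste0("enc", l)]]$conv1$W), cw)
    expect_equal(ncol(g$params[[paste0("enc", l)]]$conv2$W), cw)
  }
  # independently written parameter-count formula
  block_n <- function(cin, cout) {
    cb <- max(1L, cout %/% red)
    9L * cin * cout + cout +        # conv1
      9L * cout * cout + cout +     # conv2
      cout * cb + cb + cb * cout + cout + # SE bottleneck
      cin * cout + cout             # 1x1 projection shortcut
  }
  expected <- 0L
  cin <- 1L
  for (l in seq_len(d)) {
    expected <- expected + block_n(cin, bf * 2^(l - 1L))
    cin <- bf * 2^(l - 1L)
  }
  expected <- expected + block_n(cin, bf * 2^d)
  cup <- bf * 2^d
  for (l in rev(seq_len(d))) {
    cw <- bf * 2^(l - 1L)
    expected <- expected + 9L * cup * cw + cw + block_n(2L * cw, cw)
    cup <- cw
  }
  expected <- expected + (1L * bf + bf) + (bf * k + k)
  expect_equal(wgseg:::n_params(g), expected)
})

test_that("SE gate saturates to identity and to zero, and traces by hand", {
  x <- with_seed_test(1, array(runif(6 * 6 * 4), c(6, 6, 4)))
  p <- wgseg:::init_se(4L, 2L)
  p1 <- p; p1$W1[] <- 0; p1$W2[] <- 0; p1$b2[] <- 100 # sigmoid -> 1
  expect_equal(se_gate(x, p1), x, tolerance = 1e-12)
  p0 <- p; p0$W1[] <- 0; p0$W2[] <- 0; p0$b2[] <- -100 # sigmoid -> 0
  expect_equal(se_gate(x, p0), x * 0)

  # single channel, constant value v, hand-set scalar weights
  v <- 0.7; w1 <- 1.3; w2 <- -0.4
  xs <- array(v, c(5, 5, 1))
  ps <- list(W1 = matrix(w1, 1, 1), b1 = 0,
             W2 = matrix(w2, 1, 1), b2 = 0)
  gate <- 1 / (1 + exp(-(w2 * max(w1 * v, 0))))
  expect_equal(se_gate(xs, ps), xs * gate, tolerance = 1e-12)
})

test_that("forward obeys shape, normalization, purity, conv covariance", {
  g <- build_generator(tiny_gcfg(), seed = 1)
  img <- with_seed_test(2, matrix(runif(32 * 32), 32, 32))
  p <- generator_forward(g, img)[[1]]
  expect_equal(dim(p), c(32, 32, 4))
  expect_true(all(p >= 0))
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-6)

  # no cross-sample coupling: identical inputs in one batch
  pp <- generator_forward(g, list(img, img))
  expect_equal(pp[[1]], pp[[2]], tolerance = 1e-12)

  # fully convolutional: doubling the side doubles the output sides
  img2 <- with_seed_test(3, matrix(runif(64 * 64), 64, 64))
  p2 <- generator_forward(g, img2)[[1]]
  expect_equal(dim(p2), c(64, 64, 4))

  err <- expect_error(generator_forward(g, matrix(0.5, 33, 33)),
                      class = "wgseg_validation_error")
  expect_match(conditionMessage(err), "divisible")
})

test_that("translation covariance holds on a periodic harness", {
  # tile a 16x16 pattern 3x3 so the center tile's receptive fields see
  # only periodic content; shifting by 2^depth then shifts the output
  g <- build_generator(generator_config(base_filters = 4, depth = 1,
                                        se_reduction = 2), seed = 2)
  # saturate every SE gate to 1: the squeeze descriptor is a *global*
  # average, which is deliberately not shift-covariant, so the covariance
  # property is stated for the convolutional backbone
  for (nm in names(g$params)) {
    if (!is.null(g$params[[nm]]$se)) {
      g$params[[nm]]$se$W1[] <- 0
      g$params[[nm]]$se$W2[] <- 0
      g$params[[nm]]$se$b2[] <- 100
    }
  }
  pat <- with_seed_test(4, matrix(runif(16 * 16), 16, 16))
  sh <- 2L # 2^depth
  pat_s <- rbind(pat[(16 - sh + 1):16, ], pat[1:(16 - sh), ]) # row shift
  tile <- function(m) do.call(rbind, rep(list(
    do.call(cbind, rep(list(m), 3))), 3))
  out <- generator_forward(g, tile(pat))[[1]]
  out_s <- generator_forward(g, tile(pat_s))[[1]]
  ctr <- 17:32 # center tile
  a <- out[ctr, ctr, ]
  b <- out_s[ctr, ctr, ]
  b_unshift <- b[c((sh + 1):16, 1:sh), , , drop = FALSE]
  expect_equal(a, b_unshift, tolerance = 1e-8)
})

test_that("one small supervised step strictly decreases the loss", {
  g <- build_generator(tiny_gcfg(), seed = 5)
  ph <- render_phantom(tiny_spec(), seed = 1)
  f <- wgseg:::images_to_fmap(list(ph$image))
  tf <- wgseg:::masks_to_fmap(list(ph$mask), 4L)
  fw <- wgseg:::gen_forward(g, f, keep_cache = TRUE)
  sl <- wgseg:::seg_loss_fwd(fw$probs, tf, "dice+ce")
  gb <- wgseg:::gen_backward(g, fw$caches, sl$dlogits)
  flat <- wgseg:::flatten_params(g$params)
  grads <- wgseg:::flatten_params(gb$grads)
  gnorm <- sqrt(sum(vapply(grads, function(x) sum(x^2), numeric(1))))
  step <- 1e-3 / gnorm
  for (nm in names(flat)) flat[[nm]] <- flat[[nm]] - step * grads[[nm]]
  g$params <- wgseg:::assign_flat(g$params, flat)
  fw2 <- wgseg:::gen_forward(g, f)
  sl2 <- wgseg:::seg_loss_fwd(fw2$probs, tf, "dice+ce")
  expect_lt(sl2$loss, sl$loss)
})
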