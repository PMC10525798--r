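# Loss arithmetic, gradient penalty closed forms and oracles, exact 1-D
# Wasserstein distance.

test_that("wgan losses match brute-force mean computations", {
  expect_equal(critic_loss_wgan(c(1, 1), c(1, 1), 0, 10), 0)
  expect_equal(critic_loss_wgan(c(1, 1), c(0, 0), 0, 10), -1)
  expect_equal(generator_adv_loss(c(0, 0)), 0)
  expect_equal(generator_adv_loss(c(2, 4)), -3)

  for (seed in 1:5) {
    r <- with_seed_test(seed, rnorm(64))
    f <- with_seed_test(seed + 100, rnorm(64))
    gp <- abs(with_seed_test(seed + 200, rnorm(1)))
    lam <- 7.5
    # independent mean-difference oracle
    oracle <- sum(f) / length(f) - sum(r) / length(r) + lam * gp
    expect_equal(critic_loss_wgan(r, f, gp, lam), oracle,
                 tolerance = 1e-12)
    expect_equal(generator_adv_loss(f), -sum(f) / length(f),
                 tolerance = 1e-12)
  }
  # strict monotonicity: raising any fake score lowers the generator loss
  f <- c(0.5, -1, 2)
  for (i in 1:3) {
    f2 <- f; f2[i] <- f2[i] + 0.1
    expect_lt(generator_adv_loss(f2), generator_adv_loss(f))
  }
  expect_error(critic_loss_wgan(numeric(0), 1),
               class = "wgseg_validation_error")
  expect_error(generator_adv_loss(numeric(0)),
               class = "wgseg_validation_error")
})

test_that("standard GAN losses match their closed forms", {
  l0 <- adv_losses_gan(0, 0)
  expect_equal(l0$discriminator, 2 * log(2), tolerance = 1e-12)
  expect_equal(l0$generator, log(2), tolerance = 1e-12)
  # generator term vanishes as fake logits grow
  expect_lt(adv_losses_gan(50, 0)$generator, 1e-20)
  sig <- function(x) 1 / (1 + exp(-x))
  for (seed in 1:5) {
    f <- with_seed_test(seed, rnorm(16))
    r <- with_seed_test(seed + 50, rnorm(16))
    l <- adv_losses_gan(f, r)
    expect_equal(l$discriminator,
                 -mean(log(sig(r))) - mean(log(1 - sig(f))),
                 tolerance = 1e-12)
    expect_equal(l$generator, -mean(log(sig(f))), tolerance = 1e-12)
  }
})

test_that("gradient penalty attains its linear-critic closed form", {
  mk_linear <- function(wnorm, side = 8, k = 4) {
    cr <- build_critic(critic_config(in_channels = 1 + k, stages = 0,
                                     input_side = side), seed = 1)
    W <- cr$params$head$W
    cr$params$head$W <- W / sqrt(sum(W^2)) * wnorm
    cr
  }
  ph <- list(images = matrix(runif(64), 8, 8),
             masks = random_mask(8, 8, 4, 2))
  fk <- list(images = matrix(runif(64), 8, 8),
             masks = array(0.25, c(8, 8, 4)))
  # unit-norm weights: gradient is the weight vector everywhere -> 0
  expect_equal(gradient_penalty(mk_linear(1), ph, fk, seed = 3), 0,
               tolerance = 1e-10)
  # norm 3: (3 - 1)^2 = 4 regardless of inputs
  expect_equal(gradient_penalty(mk_linear(3), ph, fk, seed = 3), 4,
               tolerance = 1e-10)
})

test_that("gradient penalty matches a central-difference oracle", {
  cr <- build_critic(critic_config(in_channels = 3, base_filters = 4,
                                   stages = 1, norm_kind = "none",
                                   input_side = 8), seed = 4)
  real <- list(images = matrix(runif(64), 8, 8),
               masks = random_mask(8, 8, 2, 5))
  g <- build_generator(tiny_gcfg(num_labels = 2L), seed = 6)
  fake <- list(images = real$images,
               masks = array(runif(8 * 8 * 2), c(8, 8, 2)))
  seed <- 11
  got <- gradient_penalty(cr, real, fake, seed)
  # oracle: numeric gradient of the score at the same interpolate
  f_real <- wgseg:::critic_input(cr, real$images, real$masks)
  f_fake <- wgseg:::critic_input(cr, fake$images, fake$masks)
  u <- wgseg:::with_seed(child_seed(seed, "gp-mix"), runif(1))
  xhat <- f_real$x * u + f_fake$x * (1 - u)
  eps <- 1e-5
  num_grad <- xhat * 0
  for (i in seq_along(xhat)) {
    xp <- xhat; xp[i] <- xp[i] + eps
    xm <- xhat; xm[i] <- xm[i] - eps
    sp <- wgseg:::critic_forward(cr, wgseg:::fmap(xp, 8L, 8L, 1L),
                                 training = TRUE)$scores
    sm <- wgseg:::critic_forward(cr, wgseg:::fmap(xm, 8L, 8L, 1L),
                                 training = TRUE)$scores
    num_grad[i] <- (sp - sm) / (2 * eps)
  }
  oracle <- (sqrt(sum(num_grad^2)) - 1)^2
  expect_equal(got, oracle, tolerance = 1e-4)
})

test_that("gradient penalty is nonnegative and seed-reproducible", {
  cr <- build_critic(tiny_ccfg(), seed = 1)
  ph <- render_phantom(tiny_spec(), seed = 0)
  g <- build_generator(tiny_gcfg(), seed = 1)
  probs <- generator_forward(g, ph$image)[[1]]
  rp <- list(images = ph$image, masks = ph$mask)
  fp <- list(images = ph$image, masks = probs)
  g1 <- gradient_penalty(cr, rp, fp, seed = 2)
  expect_gte(g1, 0)
  expect_identical(g1, gradient_penalty(cr, rp, fp, seed = 2))
})

test_that("segmentation loss: perfect, uniform, and oracle cases", {
  tgt <- random_mask(8, 8, 4, 1)
  onehot <- array(0, c(8, 8, 4))
  for (k in 0:3) onehot[, , k + 1] <- (tgt == k) * 1
  expect_lt(segmentation_loss(onehot, tgt, "ce"), 1e-10)
  expect_lt(segmentation_loss(onehot, tgt, "dice"), 1e-5)

  unif <- array(0.25, c(8, 8, 4))
  expect_equal(segmentation_loss(unif, tgt, "ce"), log(4),
               tolerance = 1e-12)

  # brute-force soft-Dice oracle on random predictions
  for (seed in 1:3) {
    p <- with_seed_test(seed, array(runif(8 * 8 * 4), c(8, 8, 4)))
    p <- sweep(p, c(1, 2), apply(p, c(1, 2), sum), "/")
    s <- 1e-6
    dl <- 0
    for (k in 1:3) {
      pq <- sum(p[, , k + 1] * (tgt == k))
      dl <- dl + (2 * pq + s) / (sum(p[, , k + 1]) + sum(tgt == k) + s)
    }
    oracle <- 1 - dl / 3
    expect_equal(segmentation_loss(p, tgt, "dice"), oracle,
                 tolerance = 1e-10)
    expect_equal(segmentation_loss(p, tgt, "dice+ce"),
                 oracle + mean(-log(vapply(seq_len(64), function(i) {
                   r <- (i - 1) %% 8 + 1; c <- (i - 1) %/% 8 + 1
                   p[r, c, tgt[r, c] + 1]
                 }, numeric(1)))), tolerance = 1e-10)
  }
  expect_error(segmentation_loss(unif, tgt + 10L),
               class = "wgseg_validation_error")
})

test_that("1-D Wasserstein equals a brute-force transport optimum", {
  expect_equal(wasserstein_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein_1d(c(0, 0), c(1, 1)), 1)
  # permutation search over all assignments for n <= 8
  perm_oracle <- function(a, b) {
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      out
    }
    min(vapply(perms(seq_along(b)),
               function(p) mean(abs(a - b[p])), numeric(1)))
  }
  for (n in c(2, 4, 6)) {
    for (seed in 1:3) {
      a <- with_seed_test(seed * 10 + n, rnorm(n))
      b <- with_seed_test(seed * 10 + n + 1, rnorm(n))
      expect_equal(wasserstein_1d(a, b), perm_oracle(a, b),
                   tolerance = 1e-9)
    }
  }
  expect_error(wasserstein_1d(1:3, 1:4), class = "wgseg_validation_error")
})
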