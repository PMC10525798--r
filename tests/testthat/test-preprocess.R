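# CLAHE, resizing, paired augmentation, noise injection.

entropy256 <- function(img) {
  h <- tabulate(pmin(floor(img * 256), 255) + 1L, nbins = 256)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log2(p))
}

test_that("CLAHE keeps shape/range, fixes constants, raises entropy", {
  cp <- clahe_params()
  # a constant image stays constant: a single occupied bin gives every
  # tile the same transfer function, so no pixel can be separated
  const <- matrix(0.4, 33, 47)
  out_const <- apply_clahe(const, cp)
  expect_equal(dim(out_const), dim(const))
  expect_lt(diff(range(out_const)), 1e-12)

  img <- with_seed_test(1, matrix(runif(40 * 56), 40, 56))
  out <- apply_clahe(img, cp)
  expect_equal(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 1))

  # low-contrast gradient: with an effective clip limit the histogram
  # entropy must not decrease (at near-identity clip limits the change is
  # dominated by 8-bit requantization noise)
  g <- matrix(rep(seq(0.45, 0.55, length.out = 128), each = 128), 128, 128)
  out <- apply_clahe(g, clahe_params(clip_limit = 8, tile_grid = c(8, 8)))
  expect_gte(entropy256(out), entropy256(g))
  expect_gt(diff(range(out)), diff(range(g))) # contrast actually expands

  expect_error(clahe_params(clip_limit = 0),
               class = "wgseg_validation_error")
  expect_error(clahe_params(tile_grid = c(0, 4)),
               class = "wgseg_validation_error")
})

test_that("resize: identity, label preservation, traced nearest mapping", {
  img <- with_seed_test(2, matrix(runif(16 * 16), 16, 16))
  expect_identical(resize_to(img, 16), img)

  mask <- random_mask(32, 32, 4, 3)
  small <- resize_to(mask, 8, is_mask = TRUE)
  expect_true(all(small %in% unique(as.vector(mask))))
  expect_equal(dim(small), c(8, 8))

  # hand-traced nearest-neighbor oracle at a 2x downscale:
  # src = floor((dst + 0.5) * 2), i.e. source rows/cols 1, 3, 5, ...
  cb2 <- random_mask(16, 16, 2, 8)
  down <- resize_to(cb2, 8, is_mask = TRUE)
  expect_identical(down, cb2[seq(2, 16, 2), seq(2, 16, 2)])
  up <- resize_to(cb2, 32, is_mask = TRUE) # upscale introduces no labels
  expect_true(all(up %in% c(0L, 1L)))

  expect_error(resize_to(img, 4), class = "wgseg_validation_error")
})

test_that("augmentation applies one transform to both image and mask", {
  ph <- render_phantom(tiny_spec(noise_sigma = 0), seed = 0)
  idp <- augment_params(rotation_degrees = c(0, 0),
                        translation = c(0, 0), scale = c(1, 1))
  same <- augment_pair(ph$image, ph$mask, idp, seed = 1)
  expect_equal(same$image, ph$image, tolerance = 1e-12)
  expect_identical(same$mask, ph$mask)

  # exact -90 degree rotation: (r, c) -> (c, H-1-r)
  rot <- augment_params(rotation_degrees = c(-90, -90),
                        translation = c(0, 0), scale = c(1, 1))
  out <- augment_pair(ph$image, ph$mask, rot, seed = 2)
  h <- nrow(ph$mask)
  expected <- matrix(0L, h, h)
  for (r in 0:(h - 1)) for (c in 0:(h - 1))
    expected[c + 1, h - r] <- ph$mask[r + 1, c + 1]
  expect_identical(out$mask, expected)

  # same seed twice -> identical transform of an independent copy
  ap <- augment_params()
  a <- augment_pair(ph$image, ph$mask, ap, seed = 9)
  b <- augment_pair(ph$image, ph$mask, ap, seed = 9)
  expect_identical(a, b)
  cc <- confusion_counts(a$mask, b$mask, 1L)
  expect_equal(dice(cc), 1)

  expect_error(augment_pair(ph$image, ph$mask[1:10, ], ap, seed = 1),
               class = "wgseg_validation_error")
})

test_that("augmented mask boundaries stay on intensity edges", {
  ph <- render_phantom(tiny_spec(noise_sigma = 0), seed = 0)
  out <- augment_pair(ph$image, ph$mask, augment_params(), seed = 4)
  m <- out$mask; img <- out$image
  h <- nrow(m); w <- ncol(m)
  # boundary ring: pixels whose 4-neighborhood has a different label
  shift <- function(x, dr, dc) {
    y <- x * 0
    y[max(1, 1 + dr):min(h, h + dr), max(1, 1 + dc):min(w, w + dc)] <-
      x[max(1, 1 - dr):min(h, h - dr), max(1, 1 - dc):min(w, w - dc)]
    y
  }
  bnd <- (m != shift(m, 1, 0)) | (m != shift(m, 0, 1))
  grad <- abs(img - shift(img, 1, 0)) + abs(img - shift(img, 0, 1))
  interior <- !bnd & !shift(bnd, 1, 0) & !shift(bnd, 0, 1) &
    !shift(bnd, -1, 0) & !shift(bnd, 0, -1)
  # mean gradient on the (1-pixel dilated) boundary far exceeds interior
  expect_gt(mean(grad[bnd]), 5 * mean(grad[interior]))
})

test_that("gaussian noise has the stated moments and determinism", {
  img <- matrix(0.5, 400, 300)
  expect_identical(add_gaussian_noise(img, 0, seed = 1), img)
  sigma <- 0.05
  out <- add_gaussian_noise(img, sigma, seed = 2, clip = FALSE)
  d <- out - img # far from [0,1] edges: no clipping occurred
  expect_lt(abs(stats::var(as.vector(d)) - sigma^2) / sigma^2, 0.05)
  expect_lt(abs(mean(d)), 3 * sigma / sqrt(length(d)) + 1e-4)
  expect_identical(add_gaussian_noise(img, sigma, seed = 2),
                   add_gaussian_noise(img, sigma, seed = 2))
  expect_false(identical(add_gaussian_noise(img, sigma, seed = 2),
                         add_gaussian_noise(img, sigma, seed = 3)))
  # works on probability stacks, preserving dimensions
  arr <- array(0.25, c(8, 8, 4))
  out3 <- add_gaussian_noise(arr, 0.01, seed = 1)
  expect_equal(dim(out3), dim(arr))
  expect_true(all(out3 >= 0 & out3 <= 1))
  expect_error(add_gaussian_noise(img, -1),
               class = "wgseg_validation_error")
})
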