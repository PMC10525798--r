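# Phantom rendering and dataset generation.

test_that("rendering is deterministic and noise touches intensities only", {
  spec <- tiny_spec()
  a <- render_phantom(spec, seed = 5)
  b <- render_phantom(spec, seed = 5)
  expect_identical(a, b)

  spec0 <- tiny_spec(noise_sigma = 0)
  n0 <- render_phantom(spec0, seed = 5)
  n0b <- render_phantom(spec0, seed = 99)
  expect_identical(n0, n0b) # noiseless render ignores the seed entirely

  n1 <- render_phantom(tiny_spec(noise_sigma = 0.05), seed = 5)
  expect_identical(n0$mask, n1$mask)
  expect_gt(max(abs(n0$image - n1$image)), 0)
})

test_that("every pixel carries exactly one label and counts conserve", {
  ph <- render_phantom(tiny_spec(), seed = 1)
  counts <- tabulate(ph$mask + 1L, nbins = 4)
  expect_equal(sum(counts), 32 * 32)
  expect_true(all(ph$mask %in% 0:3))
})

test_that("organ pixel counts match a brute-force ellipse oracle", {
  spec <- tiny_spec(noise_sigma = 0)
  ph <- render_phantom(spec, seed = 0)
  # independent double-loop rasterization
  inside <- function(r, c, ctr, ax)
    ((r - ctr[1]) / ax[1])^2 + ((c - ctr[2]) / ax[2])^2 <= 1
  cnt <- c(l = 0L, r = 0L, h = 0L)
  for (r in 0:31) for (c in 0:31) {
    hh <- inside(r, c, spec$heart_center, spec$heart_axes)
    ll <- inside(r, c, spec$lung_centers$left, spec$lung_axes$left)
    rr <- inside(r, c, spec$lung_centers$right, spec$lung_axes$right)
    if (hh) cnt["h"] <- cnt["h"] + 1L
    else if (rr) cnt["r"] <- cnt["r"] + 1L  # disjoint from left at default
    else if (ll) cnt["l"] <- cnt["l"] + 1L
  }
  got <- tabulate(ph$mask + 1L, nbins = 4)[2:4]
  expect_equal(got, unname(cnt[c("l", "r", "h")]))
  # heart area within 5% of the analytic pi*a*b (no occluder above it)
  expect_lt(abs(cnt[["h"]] - pi * prod(spec$heart_axes)) /
              (pi * prod(spec$heart_axes)), 0.05)
})

test_that("heart occludes lung and interiors contrast with background", {
  spec <- tiny_spec(noise_sigma = 0)
  ph <- render_phantom(spec, seed = 0)
  # occlusion: some pixels inside both ellipses, all labelled heart
  both <- wgseg:::ellipse_mask(32, 32, spec$heart_center, spec$heart_axes) &
    wgseg:::ellipse_mask(32, 32, spec$lung_centers$left,
                         spec$lung_axes$left)
  expect_gt(sum(both), 0)
  expect_true(all(ph$mask[both] == 3L))
  # interior-vs-background contrast of at least half the configured offset
  for (lab in 1:3) {
    offset <- spec$organ_contrasts[[lab]]
    expect_gt(mean(ph$image[ph$mask == lab]) - mean(ph$image[ph$mask == 0]),
              offset / 2)
  }
})

test_that("invalid specs name the offending field", {
  err <- expect_error(phantom_spec(heart_axes = c(-1, 4)),
                      class = "wgseg_validation_error")
  expect_match(conditionMessage(err), "heart")
  expect_error(phantom_spec(lung_centers = list(left = c(200, 10),
                                                right = c(15, 22))),
               class = "wgseg_validation_error")
  expect_error(phantom_spec(noise_sigma = -0.1),
               class = "wgseg_validation_error")
  # heart moved away from the left lung violates the overlap invariant
  expect_error(phantom_spec(heart_center = c(5, 60), heart_axes = c(2, 2)),
               class = "wgseg_validation_error")
})

test_that("generate_dataset writes consistent, reproducible artifacts", {
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- generate_dataset(10, tiny_spec(), jitter = 0.15, seed = 7,
                         out_dir = d1)
  m2 <- generate_dataset(10, tiny_spec(), jitter = 0.15, seed = 7,
                         out_dir = d2)
  expect_equal(nrow(m1), 10)
  expect_true(all(file.exists(m1$image_path)))
  expect_true(all(file.exists(m1$mask_path)))
  # byte-identical across runs with the same seed
  for (i in seq_len(10)) {
    expect_identical(readBin(m1$image_path[i], "raw", 1e6),
                     readBin(m2$image_path[i], "raw", 1e6))
    expect_identical(readBin(m1$mask_path[i], "raw", 1e6),
                     readBin(m2$mask_path[i], "raw", 1e6))
  }
  # round trip: decoded masks carry only scheme labels, and the manifest
  # reloads
  man <- read_manifest(file.path(d1, "manifest.csv"))
  expect_equal(nrow(man), 10)
  msk <- decode_mask(man$mask_path[1], "multi")
  expect_true(all(msk %in% 0:3))

  # jitter = 0 freezes geometry: all masks identical, images differ in
  # noise only
  d3 <- tempfile()
  m3 <- generate_dataset(4, tiny_spec(), jitter = 0, seed = 1,
                         out_dir = d3)
  masks <- lapply(m3$mask_path, decode_mask, scheme = "multi")
  for (i in 2:4) expect_identical(masks[[i]], masks[[1]])
  imgs <- lapply(m3$image_path, read_image)
  expect_false(identical(imgs[[1]], imgs[[2]]))

  expect_error(generate_dataset(0, tiny_spec(), out_dir = tempfile()),
               class = "wgseg_validation_error")
  expect_error(generate_dataset(2, tiny_spec(), jitter = 0.6,
                                out_dir = tempfile()),
               class = "wgseg_validation_error")
})

test_that("child seeds are distinct across tags and indices", {
  seeds <- c(vapply(0:199, function(i) child_seed(3, "a", i), integer(1)),
             vapply(0:199, function(i) child_seed(3, "b", i), integer(1)),
             vapply(0:199, function(i) child_seed(4, "a", i), integer(1)))
  expect_equal(length(unique(seeds)), length(seeds))
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_identical(child_seed(1, "x", 5), child_seed(1, "x", 5))
})
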