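# Synthetic thorax phantom: a low-contrast torso with two bright elliptical
# lung fields and a heart ellipse occluding the medial-inferior left lung,
# over a smooth intensity gradient with optional rib bands and additive
# Gaussian noise. Gives every downstream module exact ground truth without
# any external radiograph data.

#' Specify a thorax phantom
#'
#' All geometry is in pixels with 0-based (row, col) coordinates. The
#' defaults draw a desk-scale 64 x 64 thorax: two vertical lung ellipses,
#' the heart overlapping the medial-inferior zone of the left lung (image
#' left), a gentle vertical illumination gradient, and mild noise. Organ
#' contrasts are additive intensity offsets relative to the local
#' background; where heart and lung overlap the heart wins (occlusion order
#' heart over lungs), so the mask stays single-valued.
#'
#' @param height,width Image size in pixels.
#' @param lung_centers List of two `c(row, col)` ellipse centers, named
#'   `left` and `right` (image-left lung first).
#' @param lung_axes List of two `c(semi_row, semi_col)` semi-axis pairs.
#' @param heart_center `c(row, col)` heart ellipse center.
#' @param heart_axes `c(semi_row, semi_col)` heart semi-axes.
#' @param organ_contrasts Named numeric `c(left_lung=, right_lung=, heart=)`
#'   mean intensity offsets in `[-1, 1]`.
#' @param background_gradient_amplitude Peak-to-trough amplitude of the
#'   smooth background gradient, in intensity units.
#' @param base_intensity Background intensity level before gradient/organs.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise
#'   (`0` gives a deterministic noiseless render).
#' @param rib_band_count Number of faint horizontal intensity bands
#'   (`0` disables them).
#' @return A validated object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec()
#' ph <- render_phantom(spec, seed = 1)
#' table(ph$mask)
#' @export
phantom_spec <- function(height = 64, width = 64,
                         lung_centers = list(left = c(30, 20),
                                             right = c(30, 44)),
                         lung_axes = list(left = c(17, 9),
                                          right = c(17, 9)),
                         heart_center = c(42, 27),
                         heart_axes = c(10, 8),
                         organ_contrasts = c(left_lung = 0.35,
                                             right_lung = 0.35,
                                             heart = 0.25),
                         background_gradient_amplitude = 0.08,
                         base_intensity = 0.25,
                         noise_sigma = 0.03,
                         rib_band_count = 0) {
  spec <- structure(list(
    height = as.integer(height), width = as.integer(width),
    lung_centers = lapply(lung_centers, as.numeric),
    lung_axes = lapply(lung_axes, as.numeric),
    heart_center = as.numeric(heart_center),
    heart_axes = as.numeric(heart_axes),
    organ_contrasts = organ_contrasts,
    background_gradient_amplitude = as.numeric(background_gradient_amplitude),
    base_intensity = as.numeric(base_intensity),
    noise_sigma = as.numeric(noise_sigma),
    rib_band_count = as.integer(rib_band_count)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  check_number(spec$height, "height", lower = 8, integer = TRUE)
  check_number(spec$width, "width", lower = 8, integer = TRUE)
  if (length(spec$lung_centers) != 2L || length(spec$lung_axes) != 2L)
    validation_error("exactly two lung ellipses are required",
                     field = "lung_centers")
  centers <- c(spec$lung_centers, list(heart = spec$heart_center))
  for (nm in names(centers)) {
    ctr <- centers[[nm]]
    if (length(ctr) != 2L || any(!is.finite(ctr)))
      validation_error(sprintf("center '%s' must be (row, col)", nm),
                       field = nm)
    if (ctr[1] < 0 || ctr[1] > spec$height - 1 ||
        ctr[2] < 0 || ctr[2] > spec$width - 1)
      validation_error(sprintf("center '%s' lies outside the image", nm),
                       field = nm)
  }
  axes <- c(spec$lung_axes, list(heart = spec$heart_axes))
  for (nm in names(axes)) {
    ax <- axes[[nm]]
    if (length(ax) != 2L || any(!is.finite(ax)) || any(ax <= 0))
      validation_error(sprintf("semi-axes '%s' must be positive", nm),
                       field = nm)
  }
  oc <- spec$organ_contrasts
  if (length(oc) != 3L || any(!is.finite(oc)) || any(abs(oc) > 1))
    validation_error("organ_contrasts must be 3 values in [-1, 1]",
                     field = "organ_contrasts")
  check_number(spec$noise_sigma, "noise_sigma", lower = 0)
  check_number(spec$rib_band_count, "rib_band_count", lower = 0,
               integer = TRUE)
  check_number(spec$background_gradient_amplitude,
               "background_gradient_amplitude", lower = 0)
  # the heart must occlude the medial-inferior left lung: require that the
  # two ellipses share at least one rasterized pixel
  if (!any(ellipse_mask(spec$height, spec$width, spec$heart_center,
                        spec$heart_axes) &
           ellipse_mask(spec$height, spec$width, spec$lung_centers[[1]],
                        spec$lung_axes[[1]])))
    validation_error("heart ellipse must overlap the left lung ellipse",
                     field = "heart_center")
  invisible(spec)
}

# logical H x W raster of ((r-r0)/ar)^2 + ((c-c0)/ac)^2 <= 1
ellipse_mask <- function(h, w, center, axes) {
  r <- matrix(0:(h - 1), h, w)
  c <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((c - center[2]) / axes[2])^2 <= 1
}

#' Render a phantom image and its ground-truth mask
#'
#' Deterministic given `(spec, seed)`: the mask depends on geometry only
#' (never on the noise draw), and `noise_sigma = 0` yields a noiseless
#' render. Labels follow the multi-organ scheme: 0 background, 1 left lung,
#' 2 right lung, 3 heart; the heart label wins where heart and lung
#' ellipses overlap.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for the noise field.
#' @return List with `image` (`H x W` in `[0, 1]`) and `mask`
#'   (`H x W` integer labels).
#' @export
render_phantom <- function(spec, seed = 0L) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  validate_phantom_spec(spec)
  h <- spec$height; w <- spec$width
  left <- ellipse_mask(h, w, spec$lung_centers[[1]], spec$lung_axes[[1]])
  right <- ellipse_mask(h, w, spec$lung_centers[[2]], spec$lung_axes[[2]])
  heart <- ellipse_mask(h, w, spec$heart_center, spec$heart_axes)
  mask <- matrix(0L, h, w)
  mask[left] <- 1L
  mask[right] <- 2L
  mask[heart] <- 3L # occlusion order: heart over lungs

  # smooth background: base + vertical half-cosine gradient
  rows <- (0:(h - 1)) / (h - 1)
  grad <- spec$background_gradient_amplitude *
    (0.5 - 0.5 * cos(pi * rows))
  img <- matrix(spec$base_intensity + grad, h, w)
  if (spec$rib_band_count > 0) {
    band <- 0.25 * min(abs(spec$organ_contrasts)) *
      sin(2 * pi * spec$rib_band_count * rows)
    img <- img + matrix(band, h, w)
  }
  oc <- spec$organ_contrasts
  img[mask == 1L] <- img[mask == 1L] + oc[["left_lung"]]
  img[mask == 2L] <- img[mask == 2L] + oc[["right_lung"]]
  img[mask == 3L] <- img[mask == 3L] + oc[["heart"]]
  if (spec$noise_sigma > 0) {
    noise <- with_seed(child_seed(seed, "phantom-noise"),
                       matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w))
    img <- img + noise
  }
  list(image = clip01(img), mask = mask)
}

# perturb a spec's geometry/contrast fields by up to +/- jitter fraction
jitter_spec <- function(spec, jitter, seed) {
  if (jitter == 0) return(spec)
  u <- function(x) x * (1 + stats::runif(length(x), -jitter, jitter))
  with_seed(seed, {
    s <- spec
    s$lung_centers <- lapply(spec$lung_centers, u)
    s$lung_axes <- lapply(spec$lung_axes, u)
    s$heart_center <- u(spec$heart_center)
    s$heart_axes <- u(spec$heart_axes)
    oc <- u(as.numeric(spec$organ_contrasts))
    names(oc) <- names(spec$organ_contrasts)
    s$organ_contrasts <- pmin(pmax(oc, -1), 1)
    s
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` grayscale image PNGs, `n` color-coded mask PNGs, and a
#' `manifest.csv` pairing them. Each sample's geometry and contrasts are
#' drawn by perturbing `spec` by up to `+/- jitter` (fraction) under a
#' per-sample substream of `seed`, so generation is reproducible and
#' order-independent.
#'
#' @param n Number of samples (>= 1).
#' @param spec Base [phantom_spec()].
#' @param jitter Fractional geometry/contrast perturbation in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return The manifest data frame (paths are absolute), invisibly also
#'   written to `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(n, spec = phantom_spec(), jitter = 0.1,
                             seed = 0L, out_dir) {
  if (!is_count(n)) validation_error("'n' must be a positive integer")
  check_number(jitter, "jitter", lower = 0, upper = 0.5 - 1e-12)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    io_error(sprintf("cannot create output directory '%s'", out_dir), out_dir)
  probe <- file.path(out_dir, ".wgseg_write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE }, error = function(e) FALSE,
                 warning = function(e) FALSE)
  if (!ok) io_error(sprintf("output directory '%s' is not writable", out_dir),
                    out_dir)
  unlink(probe)
  img_paths <- file.path(out_dir, sprintf("img_%04d.png", seq_len(n)))
  msk_paths <- file.path(out_dir, sprintf("msk_%04d.png", seq_len(n)))
  for (i in seq_len(n)) {
    # rejection-sample the jittered geometry so every sample satisfies the
    # spec invariants (heart-lung overlap, centers inside the image)
    si <- NULL
    for (k in 0:99) {
      cand <- jitter_spec(spec, jitter, child_seed(seed, "jitter", i * 100 + k))
      if (isTRUE(tryCatch({ validate_phantom_spec(cand); TRUE },
                          wgseg_validation_error = function(e) FALSE))) {
        si <- cand
        break
      }
    }
    if (is.null(si))
      validation_error(sprintf(
        "could not draw a valid jittered geometry for sample %d", i))
    ph <- render_phantom(si, seed = child_seed(seed, "render", i))
    write_image(ph$image, img_paths[i])
    encode_mask(ph$mask, "multi", msk_paths[i])
  }
  manifest <- data.frame(image_path = basename(img_paths),
                         mask_path = basename(msk_paths),
                         stringsAsFactors = FALSE)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest$image_path <- img_paths
  manifest$mask_path <- msk_paths
  manifest
}
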