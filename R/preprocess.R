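# Preprocessing: CLAHE contrast enhancement, resizing, paired geometric
# augmentation, and Gaussian noise injection. All operations preserve the
# [0,1] intensity range and never blend mask labels.

#' CLAHE parameters
#'
#' Contrast-limited adaptive histogram equalization operates on a grid of
#' contextual tiles; each tile's 256-bin histogram is clipped at
#' `clip_limit` times the uniform bin height (the de-facto standard scale),
#' the excess redistributed, and per-pixel mappings blended bilinearly
#' between neighboring tile mappings.
#'
#' @param clip_limit Positive clip factor; 2.0 is the common default.
#' @param tile_grid `c(rows, cols)` of contextual tiles, both >= 1.
#' @return Object of class `clahe_params`.
#' @export
clahe_params <- function(clip_limit = 2.0, tile_grid = c(8, 8)) {
  check_number(clip_limit, "clip_limit", lower = 0, strict_lower = TRUE)
  if (length(tile_grid) != 2L || any(tile_grid < 1) ||
      any(tile_grid != round(tile_grid)))
    validation_error("'tile_grid' must be two tile counts >= 1",
                     field = "tile_grid")
  structure(list(clip_limit = clip_limit, tile_grid = as.integer(tile_grid)),
            class = "clahe_params")
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with clipping and bilinear blending of
#' the per-tile transfer functions, the standard enhancement for
#' low-contrast radiographs. A constant image is returned unchanged.
#'
#' @param image `H x W` numeric matrix in `[0, 1]`.
#' @param params A [clahe_params()].
#' @return Enhanced `H x W` matrix in `[0, 1]`, same shape.
#' @export
apply_clahe <- function(image, params = clahe_params()) {
  if (!is.matrix(image) || !is.numeric(image))
    validation_error("'image' must be a numeric matrix")
  if (!inherits(params, "clahe_params")) params <- do.call(clahe_params, params)
  h <- nrow(image); w <- ncol(image)
  tr <- params$tile_grid[1]; tc <- params$tile_grid[2]
  nb <- 256L
  bins <- pmin(pmax(floor(image * nb), 0), nb - 1L) # 0..255

  # even partition: every tile owns floor/ceil(h/tr) rows, never empty
  tile_row <- floor((seq_len(h) - 1L) * tr / h)
  tile_col <- floor((seq_len(w) - 1L) * tc / w)

  # per-tile clipped-histogram CDF lookup tables: nb x (tr*tc)
  lut <- matrix(0, nb, tr * tc)
  for (i in 0:(tr - 1L)) {
    for (j in 0:(tc - 1L)) {
      sel <- bins[tile_row == i, tile_col == j]
      np <- length(sel)
      hst <- tabulate(as.vector(sel) + 1L, nbins = nb)
      clip <- params$clip_limit * np / nb # real-valued clip height
      excess <- sum(pmax(hst - clip, 0))
      hst <- pmin(hst, clip) + excess / nb
      cdf <- cumsum(hst) / np
      lut[, i * tc + j + 1L] <- cdf
    }
  }

  # bilinear blend between the four surrounding tile mappings
  pos_r <- (seq_len(h) - 1L)
  pos_c <- (seq_len(w) - 1L)
  ctr_r <- as.vector(tapply(pos_r, tile_row, mean)) # true tile centers
  ctr_c <- as.vector(tapply(pos_c, tile_col, mean))
  # for each pixel row: surrounding tile indices and weight
  r0 <- pmin(pmax(findInterval(pos_r, ctr_r), 1L), max(tr - 1L, 1L)) - 1L
  r1 <- pmin(r0 + 1L, tr - 1L)
  wr <- if (tr > 1L) {
    span <- ctr_r[r1 + 1L] - ctr_r[r0 + 1L]
    ifelse(span > 0, pmin(pmax((pos_r - ctr_r[r0 + 1L]) / span, 0), 1), 0)
  } else rep(0, h)
  c0 <- pmin(pmax(findInterval(pos_c, ctr_c), 1L), max(tc - 1L, 1L)) - 1L
  c1 <- pmin(c0 + 1L, tc - 1L)
  wc <- if (tc > 1L) {
    span <- ctr_c[c1 + 1L] - ctr_c[c0 + 1L]
    ifelse(span > 0, pmin(pmax((pos_c - ctr_c[c0 + 1L]) / span, 0), 1), 0)
  } else rep(0, w)

  bin1 <- as.vector(bins) + 1L
  tile_id <- function(ri, ci) {
    # ri: length-h tile row index, ci: length-w tile col index -> per pixel
    outer(ri, ci, function(a, b) a * tc + b + 1L)
  }
  gat <- function(ri, ci) {
    idx <- (as.vector(tile_id(ri, ci)) - 1L) * nb + bin1
    matrix(lut[idx], h, w)
  }
  WR <- matrix(wr, h, w); WC <- matrix(wc, h, w, byrow = TRUE)
  out <- (1 - WR) * (1 - WC) * gat(r0, c0) +
         (1 - WR) * WC       * gat(r0, c1) +
         WR       * (1 - WC) * gat(r1, c0) +
         WR       * WC       * gat(r1, c1)
  clip01(out)
}

#' Resize an image or mask to a square side
#'
#' Images are interpolated bilinearly; masks use nearest-neighbor so labels
#' are never blended. Source coordinates follow the half-pixel-center
#' convention `src = (dst + 0.5) * scale - 0.5`.
#'
#' @param x `H x W` numeric matrix (image in `[0, 1]`, or integer mask).
#' @param side Target side length in pixels (>= 8).
#' @param is_mask If `TRUE`, nearest-neighbor sampling is used and integer
#'   labels are preserved.
#' @return `side x side` matrix of the same kind as the input.
#' @export
resize_to <- function(x, side, is_mask = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    validation_error("'x' must be a numeric matrix")
  check_number(side, "side", lower = 8, integer = TRUE)
  h <- nrow(x); w <- ncol(x)
  if (h == side && w == side) return(x)
  sr <- h / side; sc <- w / side
  if (is_mask) {
    ri <- pmin(pmax(floor(((0:(side - 1)) + 0.5) * sr), 0), h - 1) + 1L
    ci <- pmin(pmax(floor(((0:(side - 1)) + 0.5) * sc), 0), w - 1) + 1L
    out <- x[ri, ci, drop = FALSE]
    storage.mode(out) <- storage.mode(x)
    return(out)
  }
  src_r <- pmin(pmax(((0:(side - 1)) + 0.5) * sr - 0.5, 0), h - 1)
  src_c <- pmin(pmax(((0:(side - 1)) + 0.5) * sc - 0.5, 0), w - 1)
  r0 <- floor(src_r); r1 <- pmin(r0 + 1, h - 1); fr <- src_r - r0
  c0 <- floor(src_c); c1 <- pmin(c0 + 1, w - 1); fc <- src_c - c0
  FR <- matrix(fr, side, side); FC <- matrix(fc, side, side, byrow = TRUE)
  (1 - FR) * (1 - FC) * x[r0 + 1, c0 + 1, drop = FALSE] +
    (1 - FR) * FC     * x[r0 + 1, c1 + 1, drop = FALSE] +
    FR * (1 - FC)     * x[r1 + 1, c0 + 1, drop = FALSE] +
    FR * FC           * x[r1 + 1, c1 + 1, drop = FALSE]
}

#' Augmentation parameters
#'
#' Geometric augmentation ranges. Defaults: rotation +/- 15 degrees,
#' translation +/- 10% of the side, scale 0.9-1.1, no horizontal flips
#' (chest radiographs are chiral: flipping would silently swap the left and
#' right lung labels), applied with probability 1.
#'
#' @param rotation_degrees `c(min, max)` rotation range in degrees.
#' @param translation `c(min, max)` translation range as a fraction of the
#'   image side (applied independently per axis).
#' @param scale `c(min, max)` multiplicative zoom range.
#' @param flip_p Probability of a horizontal flip (keep 0 for multi-organ
#'   schemes).
#' @param apply_p Probability that any transform is applied at all.
#' @return Object of class `augment_params`.
#' @export
augment_params <- function(rotation_degrees = c(-15, 15),
                           translation = c(-0.1, 0.1),
                           scale = c(0.9, 1.1),
                           flip_p = 0, apply_p = 1) {
  rng <- function(x, nm) {
    if (length(x) != 2L || any(!is.finite(x)) || x[1] > x[2])
      validation_error(sprintf("'%s' must be a finite c(min, max) range", nm),
                       field = nm)
    as.numeric(x)
  }
  check_number(flip_p, "flip_p", lower = 0, upper = 1)
  check_number(apply_p, "apply_p", lower = 0, upper = 1)
  structure(list(rotation_degrees = rng(rotation_degrees, "rotation_degrees"),
                 translation = rng(translation, "translation"),
                 scale = rng(scale, "scale"),
                 flip_p = flip_p, apply_p = apply_p),
            class = "augment_params")
}

# sample one affine transform; returns forward 2x2 matrix + translation in
# pixel units (about the image center), plus the flip flag
sample_transform <- function(params, h, w) {
  apply_it <- stats::runif(1) < params$apply_p
  if (!apply_it)
    return(list(identity = TRUE))
  th <- stats::runif(1, params$rotation_degrees[1],
                     params$rotation_degrees[2]) * pi / 180
  s <- stats::runif(1, params$scale[1], params$scale[2])
  tr <- stats::runif(1, params$translation[1], params$translation[2]) * h
  tc <- stats::runif(1, params$translation[1], params$translation[2]) * w
  flip <- stats::runif(1) < params$flip_p
  list(identity = FALSE, theta = th, s = s, tr = tr, tc = tc, flip = flip)
}

apply_transform <- function(image, mask, tf) {
  h <- nrow(image); w <- ncol(image)
  if (isTRUE(tf$identity)) return(list(image = image, mask = mask))
  # inverse-map output (row, col) -> source coordinates about the center
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  R <- matrix(0:(h - 1), h, w) - cy
  C <- matrix(0:(w - 1), h, w, byrow = TRUE) - cx
  # forward: p' = s * Rot(theta) * F * p + t  => inverse mapping
  ct <- cos(tf$theta); st <- sin(tf$theta)
  Rp <- R - tf$tr; Cp <- C - tf$tc
  src_r <- (ct * Rp + st * Cp) / tf$s
  src_c <- (-st * Rp + ct * Cp) / tf$s
  if (isTRUE(tf$flip)) src_c <- -src_c
  src_r <- src_r + cy; src_c <- src_c + cx

  inside <- src_r >= 0 & src_r <= h - 1 & src_c >= 0 & src_c <= w - 1
  # nearest-neighbor for the mask
  nr <- pmin(pmax(round(src_r), 0), h - 1)
  nc <- pmin(pmax(round(src_c), 0), w - 1)
  m_out <- matrix(0L, h, w)
  m_out[inside] <- mask[cbind(nr[inside] + 1L, nc[inside] + 1L)]
  # bilinear for the image, background fill 0 outside
  r0 <- pmin(pmax(floor(src_r), 0), h - 1); r1 <- pmin(r0 + 1, h - 1)
  c0 <- pmin(pmax(floor(src_c), 0), w - 1); c1 <- pmin(c0 + 1, w - 1)
  fr <- pmin(pmax(src_r - r0, 0), 1); fc <- pmin(pmax(src_c - c0, 0), 1)
  g <- function(ri, ci) matrix(image[cbind(as.vector(ri) + 1L,
                                           as.vector(ci) + 1L)], h, w)
  i_out <- (1 - fr) * (1 - fc) * g(r0, c0) + (1 - fr) * fc * g(r0, c1) +
    fr * (1 - fc) * g(r1, c0) + fr * fc * g(r1, c1)
  i_out[!inside] <- 0
  list(image = clip01(i_out), mask = m_out)
}

#' Apply one random geometric augmentation to an image/mask pair
#'
#' A single spatial transform (rotation, isotropic scale, translation,
#' optional flip) is sampled from `params` under `seed` and applied
#' identically to both inputs: bilinear interpolation for the image,
#' nearest-neighbor for the mask, background fill (intensity 0, label 0)
#' outside the canvas.
#'
#' @param image `H x W` numeric matrix in `[0, 1]`.
#' @param mask `H x W` integer matrix, same shape.
#' @param params An [augment_params()].
#' @param seed Integer seed for the transform draw.
#' @return List with transformed `image` and `mask`.
#' @export
augment_pair <- function(image, mask, params = augment_params(), seed = 0L) {
  if (!inherits(params, "augment_params"))
    params <- do.call(augment_params, params)
  if (!is.matrix(image) || !is.matrix(mask) ||
      !all(dim(image) == dim(mask)))
    validation_error("'image' and 'mask' must be matrices of the same shape")
  tf <- with_seed(child_seed(seed, "augment"),
                  sample_transform(params, nrow(image), ncol(image)))
  apply_transform(image, mask, tf)
}

#' Add i.i.d. Gaussian noise
#'
#' Adds zero-mean Gaussian noise of standard deviation `sigma` element-wise
#' and clips to `[0, 1]`. `sigma = 0` is the identity. Works on matrices and
#' on `H x W x C` probability stacks alike (per-pixel sums are *not*
#' renormalized: critic inputs are deliberately perturbed off the simplex,
#' which is the point of noise injection in adversarial training).
#'
#' @param x Numeric matrix or array in `[0, 1]`.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @param clip If `FALSE`, skip the `[0, 1]` clipping (used internally and
#'   by distribution tests).
#' @return Same shape as `x`.
#' @export
add_gaussian_noise <- function(x, sigma, seed = 0L, clip = TRUE) {
  if (!is.numeric(x)) validation_error("'x' must be numeric")
  check_number(sigma, "sigma", lower = 0)
  if (sigma == 0) return(x)
  noise <- with_seed(child_seed(seed, "noise"),
                     stats::rnorm(length(x), 0, sigma))
  out <- x + noise
  if (clip) out <- clip01(out)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}
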