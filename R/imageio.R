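# Image/mask I/O, label schemes, dataset manifests, train/test splitting.
#
# Conventions (fixed across the package):
#   * images are H x W numeric matrices with intensities in [0, 1]
#   * masks are H x W integer matrices of 0-based labels; background is 0
#   * pixel coordinates are 0-based (row, col), row-major in documentation
#   * mask PNGs are 8-bit RGB with exact, fully saturated legend colors

#' Built-in label schemes
#'
#' A label scheme maps integer mask labels to names and display colors.
#' `"multi"` is the multi-organ legend (background black, left lung blue,
#' right lung green, heart red); `"binary"` is background/lung
#' (black/white). Colors are exact: mask decoding tolerates no deviation,
#' so anti-aliased masks must be cleaned upstream.
#'
#' @param name `"multi"` or `"binary"`, or an existing scheme (returned
#'   unchanged).
#' @return An object of class `label_scheme`: list with `name`, `labels`
#'   (character vector, index 1 = label 0), and `colors` (n x 3 integer
#'   matrix, 0-255).
#' @examples
#' label_scheme("multi")$labels
#' @export
label_scheme <- function(name = c("multi", "binary")) {
  if (inherits(name, "label_scheme")) return(name)
  name <- match.arg(name)
  if (name == "multi") {
    labels <- c("background", "left_lung", "right_lung", "heart")
    colors <- rbind(c(0L, 0L, 0L), c(0L, 0L, 255L),
                    c(0L, 255L, 0L), c(255L, 0L, 0L))
  } else {
    labels <- c("background", "lung")
    colors <- rbind(c(0L, 0L, 0L), c(255L, 255L, 255L))
  }
  rownames(colors) <- labels
  structure(list(name = name, labels = labels, colors = colors),
            class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme:", x$name, ">\n")
  for (i in seq_along(x$labels))
    cat(sprintf("  %d %-11s rgb(%d,%d,%d)\n", i - 1L, x$labels[i],
                x$colors[i, 1], x$colors[i, 2], x$colors[i, 3]))
  invisible(x)
}

n_labels <- function(scheme) length(scheme$labels)

#' Read a grayscale image from PNG
#'
#' Accepts 8- or 16-bit grayscale PNG (or RGB/RGBA, converted to luminance
#' by the Rec. 601 weights 0.299/0.587/0.114; alpha is ignored). Intensities
#' are rescaled to `[0, 1]` by the bit-depth maximum.
#'
#' @param path PNG file path.
#' @return `H x W` numeric matrix in `[0, 1]`, with attribute `bit_depth`
#'   recording the source depth.
#' @export
read_image <- function(path) {
  p <- png_read(path)
  maxv <- 2^p$bit_depth - 1
  d <- p$data
  img <- if (p$channels == 1L) {
    d / maxv
  } else if (p$channels == 2L) {
    d[, , 1] / maxv
  } else {
    (0.299 * d[, , 1] + 0.587 * d[, , 2] + 0.114 * d[, , 3]) / maxv
  }
  attr(img, "bit_depth") <- p$bit_depth
  img
}

#' Write a grayscale image to 8-bit PNG
#'
#' @param image `H x W` numeric matrix in `[0, 1]` (values are clipped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (!is.matrix(image) || !is.numeric(image))
    validation_error("'image' must be a numeric matrix")
  png_write(round(clip01(image) * 255), path, bit_depth = 8L)
}

#' Decode a color-coded mask
#'
#' Maps each RGB pixel to its integer label under `scheme`. Any color not in
#' the scheme is an error naming the color and the first offending pixel
#' (0-based row/col).
#'
#' @param mask Path to an 8-bit RGB PNG, or an `H x W x 3` integer array.
#' @param scheme A [label_scheme()] or scheme name.
#' @return `H x W` integer matrix of labels.
#' @export
decode_mask <- function(mask, scheme = "multi") {
  scheme <- label_scheme(scheme)
  if (is.character(mask) && length(mask) == 1L) {
    p <- png_read(mask)
    if (p$channels < 3L || p$bit_depth != 8L)
      format_error(sprintf("'%s': mask must be an 8-bit RGB PNG", mask), mask)
    arr <- p$data[, , 1:3, drop = FALSE]
  } else if (is.array(mask) && length(dim(mask)) == 3L && dim(mask)[3] >= 3L) {
    arr <- mask[, , 1:3, drop = FALSE]
  } else {
    validation_error("'mask' must be a PNG path or an H x W x 3 array")
  }
  h <- dim(arr)[1]; w <- dim(arr)[2]
  # pack rgb into one integer per pixel and match against the scheme
  key <- arr[, , 1] * 65536 + arr[, , 2] * 256 + arr[, , 3]
  skey <- scheme$colors[, 1] * 65536 + scheme$colors[, 2] * 256 +
    scheme$colors[, 3]
  lab <- match(key, skey) - 1L
  if (anyNA(lab)) {
    bad <- which(is.na(lab))[1]
    r <- (bad - 1L) %% h; cc <- (bad - 1L) %/% h
    format_error(sprintf(
      "unknown mask color (%d,%d,%d) at pixel (%d,%d) for scheme '%s'",
      arr[r + 1L, cc + 1L, 1], arr[r + 1L, cc + 1L, 2],
      arr[r + 1L, cc + 1L, 3], r, cc, scheme$name))
  }
  matrix(lab, h, w)
}

#' Encode a label mask as a color image
#'
#' Inverse of [decode_mask()]: paints each label with its exact scheme color
#' (no interpolation). Optionally writes an 8-bit RGB PNG.
#'
#' @param mask `H x W` integer matrix of labels.
#' @param scheme A [label_scheme()] or scheme name.
#' @param path Optional output PNG path.
#' @return `H x W x 3` integer array of RGB values (invisibly if written).
#' @export
encode_mask <- function(mask, scheme = "multi", path = NULL) {
  scheme <- label_scheme(scheme)
  if (!is.matrix(mask) || !is.numeric(mask))
    validation_error("'mask' must be an integer matrix")
  k <- n_labels(scheme)
  if (any(mask < 0 | mask >= k | mask != round(mask)))
    validation_error(sprintf(
      "mask labels must be integers in [0, %d] for scheme '%s'",
      k - 1L, scheme$name))
  h <- nrow(mask); w <- ncol(mask)
  arr <- array(0L, c(h, w, 3L))
  for (ch in 1:3) arr[, , ch] <- scheme$colors[mask + 1L, ch]
  if (!is.null(path)) {
    png_write(arr, path, bit_depth = 8L)
    return(invisible(arr))
  }
  arr
}

#' Read or write a dataset manifest
#'
#' A manifest is comma-separated text with header `image_path,mask_path`,
#' one image/mask pair per line. Relative paths are resolved against the
#' manifest's own directory on read.
#'
#' @param path Manifest file path.
#' @return For `read_manifest`: a `data.frame` with character columns
#'   `image_path` and `mask_path`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) io_error(sprintf("manifest not found: '%s'", path),
                                   path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_path", "mask_path") %in% names(df)))
    format_error(sprintf("'%s': manifest must have header image_path,mask_path",
                         path), path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  df$image_path <- resolve(df$image_path)
  df$mask_path <- resolve(df$mask_path)
  validate_manifest(df)
  df
}

#' @rdname read_manifest
#' @param manifest Data frame with `image_path` and `mask_path` columns.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest[, c("image_path", "mask_path")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_manifest <- function(manifest) {
  if (!is.data.frame(manifest) ||
      !all(c("image_path", "mask_path") %in% names(manifest)))
    validation_error("manifest must have columns image_path and mask_path")
  if (nrow(manifest) == 0L)
    validation_error("manifest is empty")
  if (anyDuplicated(manifest$image_path))
    validation_error("manifest has duplicate image_path entries")
  if (any(!nzchar(manifest$image_path)) || any(!nzchar(manifest$mask_path)))
    validation_error("manifest records must have both paths")
  invisible(manifest)
}

#' Split a manifest into train and test sets
#'
#' Seeded uniform permutation split. The train set gets
#' `floor(train_frac * n)` records; the two sets are disjoint and their
#' union is the input.
#'
#' @param manifest Data frame from [read_manifest()] or
#'   [generate_dataset()].
#' @param train_frac Fraction in (0, 1); the conventional radiograph split
#'   is 0.7.
#' @param seed Integer seed for the permutation.
#' @return List with elements `train` and `test` (both data frames).
#' @examples
#' m <- data.frame(image_path = sprintf("i%d.png", 1:10),
#'                 mask_path = sprintf("m%d.png", 1:10))
#' s <- split_dataset(m, 0.7, seed = 1)
#' nrow(s$train); nrow(s$test)
#' @export
split_dataset <- function(manifest, train_frac = 0.7, seed = 0L) {
  validate_manifest(manifest)
  if (!is.numeric(train_frac) || length(train_frac) != 1L ||
      !is.finite(train_frac) || train_frac <= 0 || train_frac >= 1)
    validation_error("'train_frac' must lie strictly between 0 and 1")
  n <- nrow(manifest)
  n_train <- floor(train_frac * n)
  perm <- with_seed(child_seed(seed, "split"), sample.int(n))
  idx_train <- sort(perm[seq_len(n_train)])
  idx_test <- sort(perm[setdiff(seq_len(n), seq_len(n_train))])
  list(train = manifest[idx_train, , drop = FALSE],
       test = manifest[idx_test, , drop = FALSE])
}
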