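# Minimal PNG codec on base R's zlib bindings (memCompress/memDecompress
# produce and accept RFC-1950 zlib streams, which is what IDAT carries).
# Supports what the pipeline needs and nothing more: 8/16-bit grayscale,
# 8-bit RGB/RGBA (alpha dropped on read), no interlacing, no palette.

.png_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(.png_env$crc_tab)) return(.png_env$crc_tab)
  poly <- -306674912L # 0xEDB88320 as a signed 32-bit pattern
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(poly, bitwShiftR(c, 1L))
           else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  .png_env$crc_tab <- tab
  tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

int_to_be4 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

be4_to_int <- function(b) {
  v <- as.integer(b)
  v[1] * 16777216 + v[2] * 65536 + v[3] * 256 + v[4]
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32(body)
  crc_bytes <- as.raw(vapply(c(24L, 16L, 8L, 0L), function(sh)
    bitwAnd(bitwShiftR(crc, sh), 255L), integer(1)))
  c(int_to_be4(length(data)), body, crc_bytes)
}

#' Write a PNG file
#'
#' Low-level writer used by [write_image()] and [encode_mask()]. `data` holds
#' integer sample values in `[0, 2^bit_depth - 1]`: an `H x W` matrix for
#' grayscale or an `H x W x 3` array for RGB (RGB supports 8-bit only).
#'
#' @param data Integer matrix (gray) or `H x W x 3` array (RGB).
#' @param path Output file path.
#' @param bit_depth 8 or 16 (16 for grayscale only).
#' @return `path`, invisibly.
#' @keywords internal
#' @export
png_write <- function(data, path, bit_depth = 8L) {
  if (!bit_depth %in% c(8L, 16L))
    format_error("bit_depth must be 8 or 16", path)
  dm <- dim(data)
  if (is.null(dm) || !length(dm) %in% 2:3)
    validation_error("'data' must be an H x W matrix or H x W x 3 array")
  ch <- if (length(dm) == 2L) 1L else dm[3]
  if (ch == 3L && bit_depth != 8L)
    format_error("RGB output supports 8-bit only", path)
  if (!ch %in% c(1L, 3L))
    validation_error("'data' must have 1 or 3 channels")
  h <- dm[1]; w <- dm[2]
  vals <- round(as.numeric(data))
  maxv <- 2^bit_depth - 1
  if (anyNA(vals) || any(vals < 0) || any(vals > maxv))
    validation_error(sprintf("sample values must lie in [0, %d]", maxv))

  # scanlines: rows left-to-right, channels interleaved, 16-bit big-endian
  if (ch == 1L) m <- matrix(vals, h, w)
  else {
    # interleave R,G,B per pixel: rows of the byte matrix are image rows
    a <- array(vals, dm)
    m <- matrix(0, h, w * 3L)
    m[, seq(1L, w * 3L, by = 3L)] <- a[, , 1]
    m[, seq(2L, w * 3L, by = 3L)] <- a[, , 2]
    m[, seq(3L, w * 3L, by = 3L)] <- a[, , 3]
  }
  if (bit_depth == 16L) {
    hi <- m %/% 256; lo <- m %% 256
    m2 <- matrix(0, h, ncol(m) * 2L)
    m2[, seq(1L, ncol(m2), by = 2L)] <- hi
    m2[, seq(2L, ncol(m2), by = 2L)] <- lo
    m <- m2
  }
  stream <- as.raw(as.vector(t(cbind(0, m)))) # filter byte 0 per row

  ihdr <- c(int_to_be4(w), int_to_be4(h), as.raw(bit_depth),
            as.raw(if (ch == 1L) 0L else 2L), as.raw(0L), as.raw(0L),
            as.raw(0L))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(stream, type = "gzip")),
           png_chunk("IEND", raw(0)))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) io_error(
                    sprintf("cannot open '%s' for writing", path), path))
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

paeth_predict <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  if (pa <= pb && pa <= pc) a else if (pb <= pc) b else c
}

defilter_rows <- function(raw_bytes, h, rowlen, bpp) {
  stride <- rowlen + 1L
  out <- matrix(0L, h, rowlen)
  prev <- integer(rowlen)
  for (r in seq_len(h)) {
    off <- (r - 1L) * stride
    ft <- as.integer(raw_bytes[off + 1L])
    cur <- as.integer(raw_bytes[off + 1L + seq_len(rowlen)])
    if (ft == 0L) {
      # none
    } else if (ft == 1L) { # Sub: cumulative within each byte lane
      for (l in seq_len(bpp)) {
        ii <- seq(l, rowlen, by = bpp)
        cur[ii] <- cumsum(cur[ii]) %% 256
      }
    } else if (ft == 2L) { # Up
      cur <- (cur + prev) %% 256
    } else if (ft == 3L) { # Average
      for (i in seq_len(rowlen)) {
        left <- if (i > bpp) cur[i - bpp] else 0L
        cur[i] <- (cur[i] + (left + prev[i]) %/% 2L) %% 256
      }
    } else if (ft == 4L) { # Paeth
      for (i in seq_len(rowlen)) {
        left <- if (i > bpp) cur[i - bpp] else 0L
        upl <- if (i > bpp) prev[i - bpp] else 0L
        cur[i] <- (cur[i] + paeth_predict(left, prev[i], upl)) %% 256
      }
    } else {
      format_error(sprintf("unsupported PNG filter type %d", ft))
    }
    out[r, ] <- cur
    prev <- cur
  }
  out
}

#' Read a PNG file
#'
#' Low-level reader behind [read_image()] and [decode_mask()]. Returns the
#' raw integer samples plus format metadata. Gray+alpha and RGBA inputs keep
#' their alpha channel here; callers drop it.
#'
#' @param path PNG file path.
#' @return List with `data` (`H x W` matrix or `H x W x ch` array of integer
#'   samples), `bit_depth`, and `channels`.
#' @keywords internal
#' @export
png_read <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: '%s'", path), path)
  bytes <- readBin(path, "raw", n = file.size(path))
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(bytes) < 8L || !identical(bytes[1:8], sig))
    format_error(sprintf("'%s' is not a PNG file", path), path)
  pos <- 9L
  idat <- list(); ihdr <- NULL
  while (pos + 7L <= length(bytes)) {
    len <- be4_to_int(bytes[pos:(pos + 3L)])
    type <- rawToChar(bytes[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) bytes[(pos + 8L):(pos + 7L + len)] else raw(0)
    if (type == "IHDR") ihdr <- data
    else if (type == "IDAT") idat[[length(idat) + 1L]] <- data
    else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  if (is.null(ihdr) || length(idat) == 0L)
    format_error(sprintf("'%s': missing IHDR/IDAT chunk", path), path)
  w <- be4_to_int(ihdr[1:4]); h <- be4_to_int(ihdr[5:8])
  depth <- as.integer(ihdr[9]); ctype <- as.integer(ihdr[10])
  interlace <- as.integer(ihdr[13])
  if (interlace != 0L)
    format_error(sprintf("'%s': interlaced PNG not supported", path), path)
  if (ctype == 3L)
    format_error(sprintf("'%s': palette PNG not supported", path), path)
  if (!ctype %in% c(0L, 2L, 4L, 6L))
    format_error(sprintf("'%s': unsupported color type %d", path, ctype), path)
  if (!depth %in% c(8L, 16L))
    format_error(sprintf("'%s': unsupported bit depth %d", path, depth), path)
  ch <- c(`0` = 1L, `2` = 3L, `4` = 2L, `6` = 4L)[[as.character(ctype)]]
  bps <- depth %/% 8L
  bpp <- ch * bps
  rowlen <- w * bpp
  stream <- memDecompress(do.call(c, idat), type = "gzip")
  if (length(stream) != h * (rowlen + 1L))
    format_error(sprintf("'%s': corrupt pixel stream", path), path)
  m <- defilter_rows(stream, h, rowlen, bpp)
  if (depth == 16L) {
    m <- m[, seq(1L, rowlen, by = 2L), drop = FALSE] * 256L +
      m[, seq(2L, rowlen, by = 2L), drop = FALSE]
  }
  ncolm <- ncol(m)
  if (ch == 1L) data_arr <- matrix(m, h, w)
  else {
    data_arr <- array(0L, c(h, w, ch))
    for (k in seq_len(ch)) data_arr[, , k] <- m[, seq(k, ncolm, by = ch)]
  }
  list(data = data_arr, bit_depth = depth, channels = ch)
}
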