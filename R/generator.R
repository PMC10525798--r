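# The generator: a U-shaped encoder-decoder with squeeze-and-excitation
# channel gating and residual 1x1 shortcuts in every convolutional block.
# Encoder level l (0-based) carries base_filters * 2^l channels; four
# down/up steps by default. The head adds a 1x1 projection of the input
# image to the last decoder features, applies the nonlinearity, and maps to
# per-pixel label probabilities with a 1x1 convolution + softmax.

#' Generator configuration
#'
#' @param in_channels Input image channels (1 for grayscale radiographs).
#' @param num_labels Output labels (4 multi-organ, 2 binary).
#' @param base_filters Channels at the first encoder level; widths double
#'   per level. 64 for full-scale fidelity; small values (8-16) for CPU
#'   work.
#' @param depth Number of down/up sampling steps (default 4). Input sides must be divisible by `2^depth`.
#' @param se_reduction Squeeze-and-excitation bottleneck ratio (gate MLP
#'   width is `max(1, C / se_reduction)`).
#' @param activation Hidden nonlinearity; `"relu"` only.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(in_channels = 1L, num_labels = 4L,
                             base_filters = 64L, depth = 4L,
                             se_reduction = 16L, activation = "relu") {
  check_number(depth, "depth", lower = 1, integer = TRUE)
  check_number(base_filters, "base_filters", lower = 1, integer = TRUE)
  check_number(num_labels, "num_labels", lower = 2, integer = TRUE)
  check_number(in_channels, "in_channels", lower = 1, integer = TRUE)
  check_number(se_reduction, "se_reduction", lower = 1, integer = TRUE)
  if (se_reduction > base_filters)
    validation_error("'se_reduction' must not exceed 'base_filters'",
                     field = "se_reduction")
  if (!identical(activation, "relu"))
    validation_error("only the 'relu' activation is supported",
                     field = "activation")
  structure(list(in_channels = as.integer(in_channels),
                 num_labels = as.integer(num_labels),
                 base_filters = as.integer(base_filters),
                 depth = as.integer(depth),
                 se_reduction = as.integer(se_reduction),
                 activation = activation),
            class = "generator_config")
}

init_block <- function(cin, cout, reduction) {
  list(conv1 = init_conv3(cin, cout),
       conv2 = init_conv3(cout, cout),
       se = init_se(cout, reduction),
       proj = init_conv1(cin, cout))
}

#' Build a generator with seeded initial parameters
#'
#' Weights use He-normal initialization drawn in a fixed order from a
#' stream derived from `seed`, so identical `(config, seed)` gives
#' bit-identical parameters.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return Object of class `wgseg_generator`.
#' @examples
#' g <- build_generator(generator_config(base_filters = 8, se_reduction = 4),
#'                      seed = 1)
#' p <- generator_forward(g, matrix(0.5, 64, 64))
#' dim(p[[1]])
#' @export
build_generator <- function(config = generator_config(), seed = 0L) {
  if (!inherits(config, "generator_config"))
    config <- do.call(generator_config, config)
  bf <- config$base_filters; d <- config$depth; red <- config$se_reduction
  params <- with_seed(child_seed(seed, "generator-init"), {
    p <- list()
    cin <- config$in_channels
    for (l in seq_len(d)) {
      c <- bf * 2^(l - 1L)
      p[[paste0("enc", l)]] <- init_block(cin, c, red)
      cin <- c
    }
    p$bott <- init_block(cin, bf * 2^d, red)
    cup <- bf * 2^d
    for (l in rev(seq_len(d))) {
      c <- bf * 2^(l - 1L)
      p[[paste0("dec", l)]] <- c(list(upconv = init_conv3(cup, c)),
                                 init_block(2L * c, c, red))
      cup <- c
    }
    p$head <- list(inproj = init_conv1(config$in_channels, bf),
                   out = init_conv1(bf, config$num_labels))
    p
  })
  structure(list(config = config, params = params, seed = as.integer(seed)),
            class = "wgseg_generator")
}

#' @export
print.wgseg_generator <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$params), length, numeric(1)))
  cat(sprintf(
    "<wgseg_generator: depth %d, base_filters %d, %d labels, %s parameters>\n",
    x$config$depth, x$config$base_filters, x$config$num_labels,
    format(np, big.mark = ",")))
  invisible(x)
}

n_params <- function(net) {
  sum(vapply(flatten_params(net$params), length, numeric(1)))
}

block_fwd <- function(f, p) {
  c1 <- l_conv3(f, p$conv1$W, p$conv1$b)
  r1 <- l_relu(c1$out$x)
  f1 <- fmap(r1$out, f$H, f$W, f$N)
  c2 <- l_conv3(f1, p$conv2$W, p$conv2$b)
  r2 <- l_relu(c2$out$x)
  f2 <- fmap(r2$out, f$H, f$W, f$N)
  se <- l_se(f2, p$se)
  pr <- l_conv1(f, p$proj$W, p$proj$b)
  list(out = fmap(se$out$x + pr$out$x, f$H, f$W, f$N),
       cache = list(c1 = c1$cache, n1 = r1$cache, c2 = c2$cache,
                    n2 = r2$cache, se = se$cache, pr = pr$cache))
}

block_bwd <- function(cache, dout) {
  seb <- l_se_bwd(cache$se, dout)
  d2 <- l_relu_bwd(cache$n2, seb$dx)
  c2b <- l_conv3_bwd(cache$c2, d2)
  d1 <- l_relu_bwd(cache$n1, c2b$dx)
  c1b <- l_conv3_bwd(cache$c1, d1)
  prb <- l_conv1_bwd(cache$pr, dout)
  list(dx = c1b$dx + prb$dx,
       grads = list(conv1 = list(W = c1b$dW, b = c1b$db),
                    conv2 = list(W = c2b$dW, b = c2b$db),
                    se = list(W1 = seb$dW1, b1 = seb$db1,
                              W2 = seb$dW2, b2 = seb$db2),
                    proj = list(W = prb$dW, b = prb$db)))
}

check_side <- function(H, W, depth) {
  div <- 2^depth
  if (H %% div != 0L || W %% div != 0L)
    validation_error(sprintf(
      "input side %dx%d must be divisible by 2^depth = %d", H, W, div))
}

# full forward pass on an fmap; keep_cache retains everything backward needs
gen_forward <- function(g, f, keep_cache = FALSE) {
  p <- g$params; d <- g$config$depth
  check_side(f$H, f$W, d)
  if (fmap_channels(f) != g$config$in_channels)
    validation_error("input channel count does not match the generator")
  caches <- list(); skips <- list()
  x <- f
  for (l in seq_len(d)) {
    b <- block_fwd(x, p[[paste0("enc", l)]])
    skips[[l]] <- b$out
    mp <- l_maxpool(b$out)
    x <- mp$out
    if (keep_cache) caches[[paste0("enc", l)]] <-
      list(block = b$cache, pool = mp$cache)
  }
  bb <- block_fwd(x, p$bott)
  x <- bb$out
  if (keep_cache) caches$bott <- bb$cache
  for (l in rev(seq_len(d))) {
    pl <- p[[paste0("dec", l)]]
    up <- l_upsample(x)
    uc <- l_conv3(up$out, pl$upconv$W, pl$upconv$b)
    ur <- l_relu(uc$out$x)
    cat_x <- cbind(ur$out, skips[[l]]$x)
    cf <- fmap(cat_x, skips[[l]]$H, skips[[l]]$W, f$N)
    b <- block_fwd(cf, pl)
    if (keep_cache) caches[[paste0("dec", l)]] <-
      list(up = up$cache, uc = uc$cache, un = ur$cache, block = b$cache,
           c_split = ncol(ur$out))
    x <- b$out
  }
  ip <- l_conv1(f, p$head$inproj$W, p$head$inproj$b)
  hsum <- x$x + ip$out$x
  hr <- l_relu(hsum)
  hf <- fmap(hr$out, f$H, f$W, f$N)
  outc <- l_conv1(hf, p$head$out$W, p$head$out$b)
  logits <- outc$out
  probs <- softmax_rows(logits$x)
  if (keep_cache) {
    caches$head <- list(ip = ip$cache, hn = hr$cache, outc = outc$cache)
    caches$skips <- skips
  }
  list(probs = fmap(probs, f$H, f$W, f$N), logits = logits,
       caches = if (keep_cache) caches else NULL)
}

# backward from d(loss)/d(logits); returns nested grads + d(loss)/d(input)
gen_backward <- function(g, caches, dlogits) {
  p <- g$params; d <- g$config$depth
  grads <- list()
  ob <- l_conv1_bwd(caches$head$outc, dlogits)
  grads$head <- list(out = list(W = ob$dW, b = ob$db))
  dh <- l_relu_bwd(caches$head$hn, ob$dx)
  ipb <- l_conv1_bwd(caches$head$ip, dh)
  grads$head$inproj <- list(W = ipb$dW, b = ipb$db)
  dx <- dh
  dinput <- ipb$dx
  for (l in seq_len(d)) {
    cc <- caches[[paste0("dec", l)]]
    bb <- block_bwd(cc$block, dx)
    grads[[paste0("dec", l)]] <- bb$grads
    cs <- cc$c_split
    d_up <- bb$dx[, seq_len(cs), drop = FALSE]
    d_skip <- bb$dx[, (cs + 1L):ncol(bb$dx), drop = FALSE]
    du <- l_relu_bwd(cc$un, d_up)
    ucb <- l_conv3_bwd(cc$uc, du)
    grads[[paste0("dec", l)]]$upconv <- list(W = ucb$dW, b = ucb$db)
    dx <- l_upsample_bwd(cc$up, ucb$dx)
    # stash the skip gradient for the matching encoder level
    caches[[paste0("enc", l)]]$dskip <- d_skip
  }
  bb <- block_bwd(caches$bott, dx)
  grads$bott <- bb$grads
  dx <- bb$dx
  for (l in rev(seq_len(d))) {
    cc <- caches[[paste0("enc", l)]]
    dpool <- l_maxpool_bwd(cc$pool, dx)
    dtot <- dpool + cc$dskip
    bb <- block_bwd(cc$block, dtot)
    grads[[paste0("enc", l)]] <- bb$grads
    dx <- bb$dx
  }
  list(grads = grads, dinput = dx + dinput)
}

#' Run the generator on images
#'
#' @param g A [build_generator()] object.
#' @param images A single `H x W` matrix or a list of them; sides must be
#'   divisible by `2^depth`.
#' @return A list of `H x W x num_labels` probability arrays (per-pixel
#'   vectors are nonnegative and sum to 1).
#' @export
generator_forward <- function(g, images) {
  if (!inherits(g, "wgseg_generator"))
    validation_error("'g' must be a wgseg_generator")
  single <- is.matrix(images)
  if (single) images <- list(images)
  f <- images_to_fmap(images)
  out <- gen_forward(g, f)
  fmap_to_arrays(out$probs)
}

#' Apply a squeeze-and-excitation gate to a feature map
#'
#' Global-average-pools each channel to a descriptor, passes it through a
#' two-layer bottleneck ending in a sigmoid, and rescales every channel by
#' its gate in (0, 1). Exposed standalone so the gating can be inspected
#' and tested in isolation.
#'
#' @param features `H x W x C` numeric array.
#' @param params Gate parameters `list(W1, b1, W2, b2)`; if `NULL`, fresh
#'   seeded parameters with bottleneck `max(1, C / reduction)` are drawn.
#' @param reduction Bottleneck ratio used when `params` is `NULL`.
#' @param seed Seed for fresh parameters.
#' @return `H x W x C` array of gated features.
#' @export
se_gate <- function(features, params = NULL, reduction = 16L, seed = 0L) {
  if (!is.array(features) || length(dim(features)) != 3L)
    validation_error("'features' must be an H x W x C array")
  dm <- dim(features)
  if (is.null(params))
    params <- with_seed(child_seed(seed, "se-init"),
                        init_se(dm[3], reduction))
  f <- fmap(matrix(features, dm[1] * dm[2], dm[3]), dm[1], dm[2], 1L)
  array(l_se(f, params)$out$x, dm)
}
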