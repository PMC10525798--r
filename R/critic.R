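# The Wasserstein critic: stages of paired 3x3 convolutions with
# normalization and leaky-rectifier activations, each followed by 2x2 max
# pooling, then a global flatten into a single fully connected unit. The
# output is an unbounded real score per sample — no sigmoid, no log: the
# critic approximates a Wasserstein-distance witness, not a probability.

#' Critic configuration
#'
#' The default critic is conditional: it scores (image, mask) pairs with
#' the image and the mask's label channels concatenated, so
#' `in_channels = image_channels + num_labels`. Set `conditional = FALSE`
#' for a mask-only critic. The fully connected head fixes the working
#' resolution at build time (`input_side`).
#'
#' @param in_channels Input channels seen by the first convolution.
#' @param base_filters Channels at the first stage; widths double per
#'   stage.
#' @param stages Number of conv-conv-pool stages (default 4); input sides must be divisible by `2^stages`. `stages = 0` is
#'   the degenerate linear fixture (global flatten straight into the fully
#'   connected unit), used to verify the gradient penalty against its
#'   closed form.
#' @param norm_kind `"layer"`, `"batch"`, or `"none"`. Layer normalization
#'   is the default: batch normalization couples the samples in a batch,
#'   which conflicts with the per-sample gradient penalty, but it remains
#'   available for comparisons with batch-normalized discriminators.
#' @param leaky_slope Negative slope of the leaky rectifier.
#' @param input_side Square working resolution the head is sized for.
#' @param conditional Whether the critic sees the image alongside the mask.
#' @return Object of class `critic_config`.
#' @export
critic_config <- function(in_channels = 5L, base_filters = 64L, stages = 4L,
                          norm_kind = c("layer", "batch", "none"),
                          leaky_slope = 0.2, input_side = 64L,
                          conditional = TRUE) {
  norm_kind <- match.arg(norm_kind)
  check_number(stages, "stages", lower = 0, integer = TRUE)
  check_number(in_channels, "in_channels", lower = 1, integer = TRUE)
  check_number(base_filters, "base_filters", lower = 1, integer = TRUE)
  check_number(leaky_slope, "leaky_slope", lower = 0, upper = 1)
  check_number(input_side, "input_side", lower = 2^stages, integer = TRUE)
  if (input_side %% 2^stages != 0L)
    validation_error(sprintf(
      "'input_side' must be divisible by 2^stages = %d", 2^stages),
      field = "input_side")
  structure(list(in_channels = as.integer(in_channels),
                 base_filters = as.integer(base_filters),
                 stages = as.integer(stages), norm_kind = norm_kind,
                 leaky_slope = leaky_slope,
                 input_side = as.integer(input_side),
                 conditional = isTRUE(conditional)),
            class = "critic_config")
}

#' Build a critic with seeded initial parameters
#'
#' @param config A [critic_config()].
#' @param seed Integer seed.
#' @return Object of class `wgseg_critic`.
#' @export
build_critic <- function(config = critic_config(), seed = 0L) {
  if (!inherits(config, "critic_config"))
    config <- do.call(critic_config, config)
  bf <- config$base_filters; s <- config$stages
  params <- with_seed(child_seed(seed, "critic-init"), {
    p <- list()
    cin <- config$in_channels
    for (l in seq_len(s)) {
      c <- bf * 2^(l - 1L)
      st <- list(conv1 = init_conv3(cin, c), conv2 = init_conv3(c, c))
      if (config$norm_kind != "none") {
        st$n1 <- init_norm(c)
        st$n2 <- init_norm(c)
      }
      p[[paste0("stage", l)]] <- st
      cin <- c
    }
    side <- config$input_side %/% 2^s
    d_flat <- side * side * cin
    p$head <- list(W = he_init(d_flat, 1L, d_flat), b = 0)
    p
  })
  bn_state <- NULL
  if (config$norm_kind == "batch") {
    bn_state <- list()
    for (l in seq_len(s)) {
      c <- bf * 2^(l - 1L)
      bn_state[[paste0("stage", l)]] <- list(
        n1 = list(mean = numeric(c), var = rep(1, c)),
        n2 = list(mean = numeric(c), var = rep(1, c)))
    }
  }
  structure(list(config = config, params = params, bn_state = bn_state,
                 seed = as.integer(seed)),
            class = "wgseg_critic")
}

#' @export
print.wgseg_critic <- function(x, ...) {
  cat(sprintf(
    "<wgseg_critic: %d stages, base_filters %d, %s norm, %s parameters>\n",
    x$config$stages, x$config$base_filters, x$config$norm_kind,
    format(n_params(x), big.mark = ",")))
  invisible(x)
}

critic_norm_fwd <- function(cfg, f, np, state, training) {
  switch(cfg$norm_kind,
         layer = c(l_layernorm(f, np$gamma, np$beta), list(state = NULL)),
         batch = l_batchnorm(f, np$gamma, np$beta, state, training),
         none = list(out = f, cache = NULL, state = NULL))
}

critic_norm_bwd <- function(cfg, cache, dout) {
  switch(cfg$norm_kind,
         layer = l_layernorm_bwd(cache, dout),
         batch = l_batchnorm_bwd(cache, dout),
         none = list(dx = dout, dgamma = NULL, dbeta = NULL))
}

# forward pass on an fmap; returns scores (length-N vector), caches, and
# updated batch-norm state
critic_forward <- function(cr, f, training = FALSE, keep_cache = FALSE) {
  cfg <- cr$config
  if (f$H != cfg$input_side || f$W != cfg$input_side)
    validation_error(sprintf(
      "critic expects %dx%d inputs, got %dx%d",
      cfg$input_side, cfg$input_side, f$H, f$W))
  if (fmap_channels(f) != cfg$in_channels)
    validation_error(sprintf("critic expects %d input channels, got %d",
                             cfg$in_channels, fmap_channels(f)))
  p <- cr$params
  caches <- list()
  bn_state <- cr$bn_state
  x <- f
  for (l in seq_len(cfg$stages)) {
    sp <- p[[paste0("stage", l)]]
    key <- paste0("stage", l)
    c1 <- l_conv3(x, sp$conv1$W, sp$conv1$b)
    nf1 <- critic_norm_fwd(cfg, c1$out, sp$n1,
                           bn_state[[key]]$n1, training)
    if (cfg$norm_kind == "batch") bn_state[[key]]$n1 <- nf1$state
    a1 <- l_lrelu(nf1$out$x, cfg$leaky_slope)
    f1 <- fmap(a1$out, x$H, x$W, x$N)
    c2 <- l_conv3(f1, sp$conv2$W, sp$conv2$b)
    nf2 <- critic_norm_fwd(cfg, c2$out, sp$n2,
                           bn_state[[key]]$n2, training)
    if (cfg$norm_kind == "batch") bn_state[[key]]$n2 <- nf2$state
    a2 <- l_lrelu(nf2$out$x, cfg$leaky_slope)
    f2 <- fmap(a2$out, x$H, x$W, x$N)
    mp <- l_maxpool(f2)
    if (keep_cache) caches[[key]] <-
      list(c1 = c1$cache, n1 = nf1$cache, a1 = a1$cache,
           c2 = c2$cache, n2 = nf2$cache, a2 = a2$cache, pool = mp$cache)
    x <- mp$out
  }
  fl <- l_flatten(x)
  scores <- as.vector(fl$out %*% p$head$W + p$head$b)
  if (keep_cache) caches$head <- list(flat = fl$out, fcache = fl$cache)
  list(scores = scores, caches = if (keep_cache) caches else NULL,
       bn_state = bn_state)
}

# backward from d(loss)/d(score) (length-N vector); returns nested grads
# and d(loss)/d(input fmap matrix)
critic_backward <- function(cr, caches, dscores) {
  cfg <- cr$config; p <- cr$params
  grads <- list()
  ds <- matrix(dscores, ncol = 1L)
  grads$head <- list(W = crossprod(caches$head$flat, ds),
                     b = sum(ds))
  dflat <- tcrossprod(ds, p$head$W)
  dx <- l_flatten_bwd(caches$head$fcache, dflat)
  for (l in rev(seq_len(cfg$stages))) {
    cc <- caches[[paste0("stage", l)]]
    dx <- l_maxpool_bwd(cc$pool, dx)
    dx <- l_lrelu_bwd(cc$a2, dx, cfg$leaky_slope)
    nb2 <- critic_norm_bwd(cfg, cc$n2, dx)
    c2b <- l_conv3_bwd(cc$c2, nb2$dx)
    dx <- l_lrelu_bwd(cc$a1, c2b$dx, cfg$leaky_slope)
    nb1 <- critic_norm_bwd(cfg, cc$n1, dx)
    c1b <- l_conv3_bwd(cc$c1, nb1$dx)
    g <- list(conv1 = list(W = c1b$dW, b = c1b$db),
              conv2 = list(W = c2b$dW, b = c2b$db))
    if (cfg$norm_kind != "none") {
      g$n1 <- list(gamma = nb1$dgamma, beta = nb1$dbeta)
      g$n2 <- list(gamma = nb2$dgamma, beta = nb2$dbeta)
    }
    grads[[paste0("stage", l)]] <- g
    dx <- c1b$dx
  }
  list(grads = grads, dinput = dx)
}

# assemble the critic input fmap from images and masks/probability stacks
critic_input <- function(cr, images, masks, num_labels = NULL) {
  cfg <- cr$config
  if (is.matrix(images)) images <- list(images)
  if (!is.list(masks)) masks <- list(masks)
  k <- if (!is.null(num_labels)) num_labels
       else cfg$in_channels - (if (cfg$conditional) 1L else 0L)
  mf <- if (is.matrix(masks[[1]])) masks_to_fmap(masks, k)
        else {
          H <- dim(masks[[1]])[1]; W <- dim(masks[[1]])[2]
          x <- do.call(rbind, lapply(masks, function(a)
            matrix(a, H * W, dim(a)[3])))
          fmap(x, H, W, length(masks))
        }
  if (cfg$conditional) {
    imf <- images_to_fmap(images)
    if (imf$H != mf$H || imf$W != mf$W || imf$N != mf$N)
      validation_error("image and mask shapes are inconsistent")
    fmap(cbind(imf$x, mf$x), mf$H, mf$W, mf$N)
  } else {
    mf
  }
}

#' Score (image, mask) pairs with the critic
#'
#' Real masks may be supplied as hard integer labels (one-hot encoded
#' internally) and generated masks as soft probability stacks; both go
#' through the same interface. Scores are deterministic at inference
#' (batch-norm critics use their running statistics).
#'
#' @param cr A [build_critic()] object.
#' @param images `H x W` matrix or list of them (ignored when the critic is
#'   unconditional).
#' @param masks `H x W` integer mask, `H x W x K` probability array, or a
#'   list of either.
#' @return Numeric vector of unbounded per-sample scores.
#' @export
critic_score <- function(cr, images, masks) {
  if (!inherits(cr, "wgseg_critic"))
    validation_error("'cr' must be a wgseg_critic")
  f <- critic_input(cr, images, masks)
  critic_forward(cr, f, training = FALSE)$scores
}
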