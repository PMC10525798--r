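# Hand-rolled network core. A feature-map batch ("fmap") is a list
# (x, H, W, N) where x is an (N*H*W) x C matrix: one column per channel,
# rows ordered sample-major then column-major within each H x W plane.
# Every layer has an explicit forward (returning output + cache) and
# backward (cache + upstream gradient -> input gradient + parameter
# gradients); architectures compose them by hand in generator.R/critic.R.

fmap <- function(x, H, W, N) list(x = x, H = H, W = W, N = N)

fmap_channels <- function(f) ncol(f$x)

# stack a list of H x W matrices into a 1-channel fmap
images_to_fmap <- function(images) {
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  x <- matrix(unlist(lapply(images, as.vector), use.names = FALSE), ncol = 1L)
  fmap(x, H, W, length(images))
}

# one-hot encode a list of H x W label masks into a K-channel fmap
masks_to_fmap <- function(masks, k) {
  H <- nrow(masks[[1]]); W <- ncol(masks[[1]])
  v <- unlist(lapply(masks, as.vector), use.names = FALSE)
  x <- matrix(0, length(v), k)
  x[cbind(seq_along(v), v + 1L)] <- 1
  fmap(x, H, W, length(masks))
}

# split an fmap into per-sample H x W x C arrays
fmap_to_arrays <- function(f) {
  hw <- f$H * f$W
  lapply(seq_len(f$N), function(n) {
    array(f$x[((n - 1L) * hw + 1L):(n * hw), , drop = FALSE],
          c(f$H, f$W, ncol(f$x)))
  })
}

# --- cached im2col indices -------------------------------------------------

.nn_env <- new.env(parent = emptyenv())

conv3_idx <- function(N, H, W) {
  key <- paste(N, H, W, sep = "x")
  hit <- .nn_env[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  # 1-based index of padded pixel (r+1, c+1) for output pixel (r, c)
  base <- as.vector(outer(0:(H - 1L), 0:(W - 1L),
                          function(r, c) r + 2L + (c + 1L) * Hp))
  # tap order: (dr, dc) column-major over dr, dc in {-1, 0, 1}
  off <- as.vector(outer(c(-1L, 0L, 1L), c(-Hp, 0L, Hp), "+"))
  idx1 <- outer(base, off, "+")
  idx <- idx1[rep(seq_len(H * W), N), ] +
    rep((0:(N - 1L)) * Hp * Wp, each = H * W)
  storage.mode(idx) <- "integer"
  .nn_env[[key]] <- idx
  idx
}

add_bias <- function(m, b) m + rep(b, each = nrow(m))

# --- layers ----------------------------------------------------------------

l_conv3 <- function(f, W, b) {
  Xp <- nn_pad2(f$x, f$N, f$H, f$W)
  idx <- conv3_idx(f$N, f$H, f$W)
  out <- add_bias(nn_conv3_fwd(Xp, idx, W), b)
  list(out = fmap(out, f$H, f$W, f$N),
       cache = list(Xp = Xp, idx = idx, W = W, H = f$H, Wd = f$W, N = f$N))
}

l_conv3_bwd <- function(cache, dout) {
  g <- nn_conv3_bwd(cache$Xp, cache$idx, cache$W, dout)
  list(dx = nn_unpad2(g$dXp, cache$N, cache$H, cache$Wd),
       dW = g$dW, db = colSums(dout))
}

l_conv1 <- function(f, W, b) {
  list(out = fmap(add_bias(f$x %*% W, b), f$H, f$W, f$N),
       cache = list(x = f$x, W = W))
}

l_conv1_bwd <- function(cache, dout) {
  list(dx = tcrossprod(dout, cache$W),
       dW = crossprod(cache$x, dout), db = colSums(dout))
}

l_relu <- function(x) {
  neg <- x < 0
  x[neg] <- 0
  list(out = x, cache = neg)
}

l_relu_bwd <- function(neg, dout) {
  dout[neg] <- 0
  dout
}

l_lrelu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  list(out = x, cache = neg)
}

l_lrelu_bwd <- function(neg, dout, slope) {
  dout[neg] <- dout[neg] * slope
  dout
}

sigmoid <- function(x) 1 / (1 + exp(-x))

l_maxpool <- function(f) {
  p <- nn_maxpool_fwd(f$x, f$N, f$H, f$W)
  list(out = fmap(p$out, f$H %/% 2L, f$W %/% 2L, f$N),
       cache = list(which = p$which, H = f$H, W = f$W, N = f$N))
}

l_maxpool_bwd <- function(cache, dout) {
  nn_maxpool_bwd(dout, cache$which, cache$N, cache$H, cache$W)
}

l_upsample <- function(f) {
  list(out = fmap(nn_upsample_fwd(f$x, f$N, f$H, f$W),
                  2L * f$H, 2L * f$W, f$N),
       cache = list(H = f$H, W = f$W, N = f$N))
}

l_upsample_bwd <- function(cache, dout) {
  nn_upsample_bwd(dout, cache$N, cache$H, cache$W)
}

# squeeze-and-excitation: global average pool -> bottleneck FC -> sigmoid
# gates, multiplied back per channel
l_se <- function(f, p) {
  hw <- f$H * f$W
  grp <- rep(seq_len(f$N), each = hw)
  s <- rowsum(f$x, grp, reorder = FALSE) / hw      # N x C descriptors
  z1 <- add_bias(s %*% p$W1, p$b1)
  a1 <- l_relu(z1)
  z2 <- add_bias(a1$out %*% p$W2, p$b2)
  g <- sigmoid(z2)                                  # N x C gates in (0,1)
  gexp <- g[grp, , drop = FALSE]
  list(out = fmap(f$x * gexp, f$H, f$W, f$N),
       cache = list(x = f$x, s = s, neg1 = a1$cache, a1 = a1$out, g = g,
                    gexp = gexp, grp = grp, hw = hw, p = p))
}

l_se_bwd <- function(cache, dout) {
  p <- cache$p
  dx <- dout * cache$gexp
  dg <- rowsum(dout * cache$x, cache$grp, reorder = FALSE)
  dz2 <- dg * cache$g * (1 - cache$g)
  dW2 <- crossprod(cache$a1, dz2)
  db2 <- colSums(dz2)
  da1 <- tcrossprod(dz2, p$W2)
  dz1 <- l_relu_bwd(cache$neg1, da1)
  dW1 <- crossprod(cache$s, dz1)
  db1 <- colSums(dz1)
  ds <- tcrossprod(dz1, p$W1)
  dx <- dx + ds[cache$grp, , drop = FALSE] / cache$hw
  list(dx = dx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# layer normalization: per sample over all H*W*C elements, learned
# per-channel gain/bias
l_layernorm <- function(f, gamma, beta, eps = 1e-5) {
  hw <- f$H * f$W
  grp <- rep(seq_len(f$N), each = hw)
  m <- f$N # samples
  M <- hw * ncol(f$x) # elements per sample
  sums <- rowsum(f$x, grp, reorder = FALSE)
  mu <- rowSums(sums) / M
  xc <- f$x - mu[grp]
  v <- rowSums(rowsum(xc * xc, grp, reorder = FALSE)) / M
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd[grp]
  out <- add_bias(xhat * rep(gamma, each = nrow(xhat)), beta)
  list(out = fmap(out, f$H, f$W, f$N),
       cache = list(xhat = xhat, inv_sd = inv_sd, grp = grp, M = M,
                    gamma = gamma))
}

l_layernorm_bwd <- function(cache, dout) {
  xhat <- cache$xhat; grp <- cache$grp; M <- cache$M
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(cache$gamma, each = nrow(dout))
  m1 <- rowSums(rowsum(dxhat, grp, reorder = FALSE)) / M
  m2 <- rowSums(rowsum(dxhat * xhat, grp, reorder = FALSE)) / M
  dx <- (dxhat - m1[grp] - xhat * m2[grp]) * cache$inv_sd[grp]
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# batch normalization: per channel over all samples and pixels (training
# statistics; `state` carries running moments for inference)
l_batchnorm <- function(f, gamma, beta, state = NULL, training = TRUE,
                        eps = 1e-5, momentum = 0.1) {
  if (training) {
    mu <- colMeans(f$x)
    xc <- sweep(f$x, 2L, mu)
    v <- colMeans(xc * xc)
    if (!is.null(state)) {
      state$mean <- (1 - momentum) * state$mean + momentum * mu
      state$var <- (1 - momentum) * state$var + momentum * v
    }
  } else {
    mu <- state$mean; v <- state$var
    xc <- sweep(f$x, 2L, mu)
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv_sd, "*")
  out <- add_bias(sweep(xhat, 2L, gamma, "*"), beta)
  list(out = fmap(out, f$H, f$W, f$N),
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma,
                    n = nrow(f$x)),
       state = state)
}

l_batchnorm_bwd <- function(cache, dout) {
  n <- cache$n; xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, cache$gamma, "*")
  dx <- sweep(dxhat - rep(colMeans(dxhat), each = n) -
                xhat * rep(colMeans(dxhat * xhat), each = n),
              2L, cache$inv_sd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# per-sample flatten: fmap -> N x (H*W*C), channels slow axis
l_flatten <- function(f) {
  hw <- f$H * f$W
  arr <- array(f$x, c(hw, f$N, ncol(f$x)))
  list(out = matrix(aperm(arr, c(2L, 1L, 3L)), f$N, hw * ncol(f$x)),
       cache = list(H = f$H, W = f$W, N = f$N, C = ncol(f$x)))
}

l_flatten_bwd <- function(cache, dout) {
  hw <- cache$H * cache$W
  arr <- aperm(array(dout, c(cache$N, hw, cache$C)), c(2L, 1L, 3L))
  matrix(arr, hw * cache$N, cache$C)
}

# row-wise softmax over channels
softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

# --- parameter initialization & Adam ---------------------------------------

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

init_conv3 <- function(cin, cout) {
  list(W = he_init(9L * cin, cout, 9L * cin), b = numeric(cout))
}

init_conv1 <- function(cin, cout) {
  list(W = he_init(cin, cout, cin), b = numeric(cout))
}

init_se <- function(c, reduction) {
  cb <- max(1L, as.integer(c %/% reduction))
  list(W1 = he_init(c, cb, c), b1 = numeric(cb),
       W2 = he_init(cb, c, cb), b2 = numeric(c))
}

init_norm <- function(c) list(gamma = rep(1, c), beta = numeric(c))

# flatten a nested parameter list into a flat named list (and back)
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p[[nm]])) out <- c(out, flatten_params(p[[nm]], key))
    else out[[key]] <- p[[nm]]
  }
  out
}

assign_flat <- function(p, flat, prefix = "") {
  for (nm in names(p)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p[[nm]])) p[[nm]] <- assign_flat(p[[nm]], flat, key)
    else p[[nm]] <- flat[[key]]
  }
  p
}

adam_state <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

adam_step <- function(flat, grads, st, lr, beta1, beta2, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    flat[[nm]] <- flat[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = flat, state = st)
}

# elementwise sum of two structurally identical flat gradient lists
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else
    a[[nm]] + b[[nm]]
  a
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)
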