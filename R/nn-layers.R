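# Primitive neural-network layers with hand-written forward/backward passes.
# Tensors are (H, W, C, N) arrays; octave feature maps are lists
# list(high = <array>, low = <array or NULL>) where the low branch lives at
# half spatial resolution. Layers are environments; forward passes cache
# what backward needs when `training = TRUE`.

new_layer_env <- function(ptype, fields) {
  e <- new.env(parent = emptyenv())
  e$ptype <- ptype
  for (n in names(fields)) assign(n, fields[[n]], envir = e)
  e
}

# learnable field names per primitive type
layer_param_names <- function(l) {
  switch(l$ptype,
         conv = if (l$bias) c("w", "b") else "w",
         bn = c("gamma", "beta"),
         prelu = "a",
         se_fc = c("W1", "b1", "W2", "b2"),
         character(0))
}

uniform_init <- function(dims, fan_in) {
  bnd <- 1 / sqrt(fan_in)
  array(runif(prod(dims), -bnd, bnd), dims)
}

## ---- convolution ---------------------------------------------------------

new_conv <- function(k, cin, cout, bias = TRUE) {
  fan_in <- k * k * cin
  new_layer_env("conv", list(
    k = k, cin = cin, cout = cout, bias = bias,
    w = uniform_init(c(k, k, cin, cout), fan_in),
    b = if (bias) runif(cout, -1 / sqrt(fan_in), 1 / sqrt(fan_in))
        else numeric(cout)))
}

conv_fw <- function(l, x, training) {
  if (training) l$x <- x
  conv2d_fwd(x, l$w, l$b)
}

conv_bw <- function(l, dy) {
  r <- conv2d_bwd(l$x, l$w, dy)
  l$g_w <- r$dw
  if (l$bias) l$g_b <- r$db
  l$x <- NULL
  r$dx
}

## ---- batch normalization -------------------------------------------------

new_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  new_layer_env("bn", list(
    c = c, momentum = momentum, eps = eps,
    gamma = rep(1, c), beta = rep(0, c),
    rmean = rep(0, c), rvar = rep(1, c),
    recal = FALSE))
}

ch_view <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3], d[4])
  x
}

bn_fw <- function(l, x, training) {
  d <- dim(x)
  if (training) {
    st <- bn_stats(x)
    mu <- st$mean
    v <- st$var
    if (l$recal) {
      m_elems <- d[1] * d[2] * d[4]
      l$acc_s <- l$acc_s + mu * m_elems
      l$acc_ss <- l$acc_ss + (v + mu^2) * m_elems
      l$acc_n <- l$acc_n + m_elems
    } else {
      l$rmean <- (1 - l$momentum) * l$rmean + l$momentum * mu
      l$rvar <- (1 - l$momentum) * l$rvar + l$momentum * v
    }
    istd <- 1 / sqrt(v + l$eps)
    l$x <- x
    l$mu <- mu
    l$istd <- istd
    scale_shift(x, l$gamma * istd, l$beta - mu * l$gamma * istd)
  } else {
    istd <- 1 / sqrt(l$rvar + l$eps)
    scale_shift(x, l$gamma * istd, l$beta - l$rmean * l$gamma * istd)
  }
}

bn_bw <- function(l, dy) {
  r <- bn_bwd(l$x, dy, l$mu, l$istd, l$gamma)
  l$g_gamma <- r$dgamma
  l$g_beta <- r$dbeta
  l$x <- NULL
  r$dx
}

bn_reset_recal <- function(l) {
  l$recal <- TRUE
  l$acc_s <- rep(0, l$c); l$acc_ss <- rep(0, l$c); l$acc_n <- 0
}

bn_finish_recal <- function(l) {
  if (l$acc_n > 0) {
    mu <- l$acc_s / l$acc_n
    l$rmean <- mu
    l$rvar <- pmax(l$acc_ss / l$acc_n - mu^2, 0)
  }
  l$recal <- FALSE
  l$acc_s <- NULL; l$acc_ss <- NULL; l$acc_n <- NULL
}

## ---- PReLU ---------------------------------------------------------------

new_prelu <- function(c, init = 0.25) {
  new_layer_env("prelu", list(c = c, a = rep(init, c)))
}

prelu_fw <- function(l, x, training) {
  if (training) l$x <- x
  prelu_fwd_c(x, l$a)
}

prelu_bw <- function(l, dy) {
  r <- prelu_bwd_c(l$x, dy, l$a)
  l$g_a <- r$da
  l$x <- NULL
  r$dx
}

## ---- dropout -------------------------------------------------------------

new_dropout <- function(rate) new_layer_env("dropout", list(rate = rate))

dropout_fw <- function(l, x, training) {
  if (!training || l$rate <= 0 || isTRUE(l$disabled)) return(x)
  mask <- array((runif(length(x)) >= l$rate) / (1 - l$rate), dim(x))
  l$mask <- mask
  x * mask
}

dropout_bw <- function(l, dy) {
  if (l$rate <= 0 || is.null(l$mask)) return(dy)
  dx <- dy * l$mask
  l$mask <- NULL
  dx
}

## ---- concurrent spatial & channel squeeze-and-excite ---------------------
# channel path: global average pool -> FC(C -> C/r) -> ReLU -> FC(-> C) ->
# sigmoid -> per-channel scaling; spatial path: 1x1 conv -> sigmoid ->
# per-pixel scaling; the two recalibrated maps are added.

new_csse <- function(c, reduction = 2) {
  cr <- max(1L, as.integer(c / reduction))
  fc <- new_layer_env("se_fc", list(
    c = c, cr = cr,
    W1 = uniform_init(c(c, cr), c),
    b1 = runif(cr, -1 / sqrt(c), 1 / sqrt(c)),
    W2 = uniform_init(c(cr, c), cr),
    b2 = runif(c, -1 / sqrt(cr), 1 / sqrt(cr))))
  e <- new.env(parent = emptyenv())
  e$fc <- fc
  e$sconv <- new_conv(1L, c, 1L, bias = TRUE)
  e
}

sigmoid <- function(x) 1 / (1 + exp(-x))

csse_fw <- function(l, x, training) {
  d <- dim(x)
  fc <- l$fc
  z <- colMeans(ch_view(x))                        # C x N
  if (!is.matrix(z)) z <- matrix(z, d[3], d[4])
  h <- pmax(crossprod(fc$W1, z) + fc$b1, 0)        # Cr x N
  s <- sigmoid(crossprod(fc$W2, h) + fc$b2)        # C x N
  chan <- x * rep(as.vector(s), each = d[1] * d[2])
  q <- conv_fw(l$sconv, x, training)               # H x W x 1 x N
  t <- sigmoid(q)
  tb <- t[, , rep(1L, d[3]), , drop = FALSE]
  spat <- x * tb
  if (training) {
    l$x <- x; l$z <- z; l$h <- h; l$s <- s; l$t <- t
  }
  chan + spat
}

csse_bw <- function(l, dy) {
  d <- dim(dy)
  hw <- d[1] * d[2]
  fc <- l$fc
  x <- l$x; s <- l$s; t <- l$t
  # channel path
  dx <- dy * rep(as.vector(s), each = hw)
  ds <- colSums(ch_view(dy * x))                   # C x N
  if (!is.matrix(ds)) ds <- matrix(ds, d[3], d[4])
  dv <- ds * s * (1 - s)                           # pre-sigmoid
  fc$g_W2 <- l$h %*% t(dv)
  fc$g_b2 <- rowSums(dv)
  dh <- (fc$W2 %*% dv) * (l$h > 0)
  fc$g_W1 <- l$z %*% t(dh)
  fc$g_b1 <- rowSums(dh)
  dz <- fc$W1 %*% dh                               # C x N
  dx <- dx + rep(as.vector(dz) / hw, each = hw)
  # spatial path
  tb <- t[, , rep(1L, d[3]), , drop = FALSE]
  dx <- dx + dy * tb
  m <- dy * x
  dt <- m[, , 1L, , drop = FALSE]
  if (d[3] > 1L) for (cc in 2:d[3]) dt <- dt + m[, , cc, , drop = FALSE]
  dq <- dt * t * (1 - t)
  dx <- dx + conv_bw(l$sconv, dq)
  l$x <- NULL; l$z <- NULL; l$h <- NULL; l$s <- NULL; l$t <- NULL
  dim(dx) <- d
  dx
}

## ---- octave convolution --------------------------------------------------
# Four-path construction: high->high, high->low (average pool then conv),
# low->low, low->high (conv then nearest 2x upsample); path outputs are
# summed per frequency. alpha_in = 0 / alpha_out = 0 degenerate to a plain
# convolution on the high branch.

oct_split <- function(channels, alpha) {
  cl <- as.integer(round(alpha * channels))
  c(high = channels - cl, low = cl)
}

new_octconv <- function(k, cin, cout, alpha_in, alpha_out) {
  si <- oct_split(cin, alpha_in)
  so <- oct_split(cout, alpha_out)
  e <- new.env(parent = emptyenv())
  e$si <- si; e$so <- so; e$k <- k
  e$hh <- if (so["high"] > 0) new_conv(k, si[["high"]], so[["high"]], TRUE)
  e$lh <- if (si["low"] > 0 && so["high"] > 0)
    new_conv(k, si[["low"]], so[["high"]], FALSE)
  e$ll <- if (si["low"] > 0 && so["low"] > 0)
    new_conv(k, si[["low"]], so[["low"]], TRUE)
  e$hl <- if (so["low"] > 0)
    new_conv(k, si[["high"]], so[["low"]], bias = si[["low"]] == 0)
  e
}

octconv_fw <- function(l, x, training) {
  xh <- x$high; xl <- x$low
  if ((is.null(xl) && l$si[["low"]] > 0) ||
      (!is.null(xl) && l$si[["low"]] == 0))
    stopf("octave conv: channel split inconsistent with alpha_in")
  if (!is.null(xl) && dim(xl)[3] != l$si[["low"]])
    stopf("octave conv: low branch has %d channels, expected %d",
          dim(xl)[3], l$si[["low"]])
  dh <- dim(xh)
  l$dims_high <- dh[1:2]
  yh <- conv_fw(l$hh, xh, training)
  if (!is.null(l$lh)) {
    l$dims_low <- dim(xl)[1:2]
    yh <- yh + upsample2_fwd(conv_fw(l$lh, xl, training), dh[1], dh[2])
  }
  yl <- NULL
  if (!is.null(l$hl)) {
    yl <- conv_fw(l$hl, avgpool2_fwd(xh), training)
    if (!is.null(l$ll)) yl <- yl + conv_fw(l$ll, xl, training)
  }
  list(high = yh, low = yl)
}

octconv_bw <- function(l, dy) {
  dxh <- conv_bw(l$hh, dy$high)
  dxl <- NULL
  if (!is.null(l$lh)) {
    dlo <- upsample2_bwd(dy$high, l$dims_low[1], l$dims_low[2])
    dxl <- conv_bw(l$lh, dlo)
  }
  if (!is.null(l$hl)) {
    dxp <- conv_bw(l$hl, dy$low)
    dxh <- dxh + avgpool2_bwd(dxp, l$dims_high[1], l$dims_high[2])
    if (!is.null(l$ll)) dxl <- dxl + conv_bw(l$ll, dy$low)
  }
  list(high = dxh, low = dxl)
}

## ---- conv unit: BN -> PReLU -> (octave) convolution ----------------------

new_conv_unit <- function(k, cin, cout, alpha_in, alpha_out) {
  si <- oct_split(cin, alpha_in)
  e <- new.env(parent = emptyenv())
  e$bn_h <- new_bn(si[["high"]])
  e$pr_h <- new_prelu(si[["high"]])
  if (si["low"] > 0) {
    e$bn_l <- new_bn(si[["low"]])
    e$pr_l <- new_prelu(si[["low"]])
  }
  e$conv <- new_octconv(k, cin, cout, alpha_in, alpha_out)
  e
}

conv_unit_fw <- function(u, x, training) {
  h <- prelu_fw(u$pr_h, bn_fw(u$bn_h, x$high, training), training)
  lo <- NULL
  if (!is.null(u$bn_l))
    lo <- prelu_fw(u$pr_l, bn_fw(u$bn_l, x$low, training), training)
  octconv_fw(u$conv, list(high = h, low = lo), training)
}

conv_unit_bw <- function(u, dy) {
  dx <- octconv_bw(u$conv, dy)
  dh <- bn_bw(u$bn_h, prelu_bw(u$pr_h, dx$high))
  dl <- NULL
  if (!is.null(u$bn_l))
    dl <- bn_bw(u$bn_l, prelu_bw(u$pr_l, dx$low))
  list(high = dh, low = dl)
}

## ---- octave feature helpers ----------------------------------------------

oct_concat <- function(a, b) {
  list(high = cat_channels(a$high, b$high),
       low = if (!is.null(a$low)) cat_channels(a$low, b$low) else NULL)
}

oct_add <- function(a, b) {
  list(high = a$high + b$high,
       low = if (!is.null(a$low)) a$low + b$low else NULL)
}

## ---- dense block ---------------------------------------------------------
# Three BN-PReLU-conv units; the third consumes the channel concatenation of
# the first and second units' outputs; dropout closes the block.

new_dense_block <- function(cin, filters, k, a_in, a_mid, a_out,
                            dropout_rate) {
  e <- new.env(parent = emptyenv())
  e$u1 <- new_conv_unit(k, cin, filters, a_in, a_mid)
  e$u2 <- new_conv_unit(k, filters, filters, a_mid, a_mid)
  e$u3 <- new_conv_unit(k, 2L * filters, filters, a_mid, a_out)
  e$drop_h <- new_dropout(dropout_rate)
  e$drop_l <- new_dropout(dropout_rate)
  e$filters <- filters
  e
}

dense_block_fw <- function(b, x, training) {
  f1 <- conv_unit_fw(b$u1, x, training)
  f2 <- conv_unit_fw(b$u2, f1, training)
  cc <- oct_concat(f1, f2)
  f3 <- conv_unit_fw(b$u3, cc, training)
  out <- list(high = dropout_fw(b$drop_h, f3$high, training),
              low = if (!is.null(f3$low))
                dropout_fw(b$drop_l, f3$low, training) else NULL)
  out
}

dense_block_bw <- function(b, dy) {
  d3 <- list(high = dropout_bw(b$drop_h, dy$high),
             low = if (!is.null(dy$low)) dropout_bw(b$drop_l, dy$low)
                   else NULL)
  dcc <- conv_unit_bw(b$u3, d3)
  # split concat gradient back into the two unit outputs
  hi <- dcc$high; lo <- dcc$low
  ch <- dim(hi)[3] / 2
  df1a <- list(high = hi[, , seq_len(ch), , drop = FALSE],
               low = if (!is.null(lo))
                 lo[, , seq_len(dim(lo)[3] / 2), , drop = FALSE] else NULL)
  df2 <- list(high = hi[, , (ch + 1):(2 * ch), , drop = FALSE],
              low = if (!is.null(lo))
                lo[, , (dim(lo)[3] / 2 + 1):dim(lo)[3], , drop = FALSE]
              else NULL)
  df1 <- oct_add(df1a, conv_unit_bw(b$u2, df2))
  conv_unit_bw(b$u1, df1)
}

## ---- pooling helpers with odd-size padding -------------------------------

pad_even <- function(x, fill) {
  d <- dim(x)
  hp <- d[1] + d[1] %% 2L
  wp <- d[2] + d[2] %% 2L
  if (hp == d[1] && wp == d[2]) return(x)
  out <- array(fill, c(hp, wp, d[3], d[4]))
  out[seq_len(d[1]), seq_len(d[2]), , ] <- x
  out
}

crop_hw <- function(x, h, w) {
  d <- dim(x)
  if (d[1] == h && d[2] == w) return(x)
  x[seq_len(h), seq_len(w), , , drop = FALSE]
}

pad_zero_to <- function(x, h, w) {
  d <- dim(x)
  if (d[1] == h && d[2] == w) return(x)
  out <- array(0, c(h, w, d[3], d[4]))
  out[seq_len(d[1]), seq_len(d[2]), , ] <- x
  out
}

# 2x2 max pool of one branch; returns pooled map, indices, original dims
pool_branch <- function(x) {
  d <- dim(x)
  xp <- pad_even(x, -Inf)
  r <- maxpool2_fwd(xp)
  list(y = r$y, idx = r$idx, dims = d[1:2], padded = dim(xp)[1:2])
}

unpool_branch <- function(x, idx, padded, dims) {
  crop_hw(maxunpool2(x, idx, padded[1], padded[2]), dims[1], dims[2])
}

unpool_branch_bw <- function(dfull, idx, padded) {
  maxunpool2_bwd(pad_zero_to(dfull, padded[1], padded[2]), idx)
}
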