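# octave convolution, CSSE, dense blocks, pooling and the full network

ns <- asNamespace("abdomenseg")

test_that("octave convolution degenerates to a plain convolution", {
  set.seed(10)
  oc <- ns$with_seed(1, ns$new_octconv(3L, 3L, 5L, 0, 0))
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3, 1))
  y <- ns$octconv_fw(oc, list(high = x, low = NULL), FALSE)
  ref <- ns$conv2d_fwd(x, oc$hh$w, oc$hh$b)
  expect_identical(y$high, ref)
  expect_null(y$low)
})

test_that("octave channel split follows alpha and halves the low branch", {
  oc <- ns$with_seed(2, ns$new_octconv(5L, 64L, 64L, 0.5, 0.5))
  x <- list(high = array(rnorm(8 * 8 * 32), c(8, 8, 32, 1)),
            low = array(rnorm(4 * 4 * 32), c(4, 4, 32, 1)))
  y <- ns$octconv_fw(oc, x, FALSE)
  expect_equal(dim(y$high), c(8, 8, 32, 1))   # 64 * (1 - 0.5) channels
  expect_equal(dim(y$low), c(4, 4, 32, 1))    # 64 * 0.5 at half resolution

  # all-zero weights give all-zero outputs of the right shapes
  for (cv in list(oc$hh, oc$hl, oc$lh, oc$ll)) {
    cv$w[] <- 0; cv$b[] <- 0
  }
  y0 <- ns$octconv_fw(oc, x, FALSE)
  expect_true(all(y0$high == 0) && all(y0$low == 0))

  # channel mismatch is rejected
  bad <- list(high = x$high, low = x$low[, , 1:16, , drop = FALSE])
  expect_error(ns$octconv_fw(oc, bad, FALSE), "channels")
})

test_that("octave forward equals a hand-rolled four-path composition", {
  set.seed(11)
  oc <- ns$with_seed(3, ns$new_octconv(3L, 6L, 8L, 0.5, 0.5))
  x <- list(high = array(rnorm(6 * 6 * 3), c(6, 6, 3, 1)),
            low = array(rnorm(3 * 3 * 3), c(3, 3, 3, 1)))
  y <- ns$octconv_fw(oc, x, FALSE)
  # independent composition from the primitive kernels
  hh <- ns$conv2d_fwd(x$high, oc$hh$w, oc$hh$b)
  lh <- ns$upsample2_fwd(ns$conv2d_fwd(x$low, oc$lh$w, oc$lh$b), 6L, 6L)
  hl <- ns$conv2d_fwd(ns$avgpool2_fwd(x$high), oc$hl$w, oc$hl$b)
  ll <- ns$conv2d_fwd(x$low, oc$ll$w, oc$ll$b)
  expect_equal(y$high, hh + lh, tolerance = 1e-12)
  expect_equal(y$low, hl + ll, tolerance = 1e-12)
})

test_that("CSSE recalibration matches a brute-force two-path oracle", {
  set.seed(12)
  cs <- ns$with_seed(4, ns$new_csse(4L, 2))
  x <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
  y <- ns$csse_fw(cs, x, FALSE)

  # hand-rolled: channel SE path + spatial SE path, added
  oracle <- array(0, dim(x))
  for (n in 1:2) {
    z <- apply(x[, , , n, drop = FALSE], 3, mean)
    h <- pmax(t(cs$fc$W1) %*% z + cs$fc$b1, 0)
    s <- 1 / (1 + exp(-(t(cs$fc$W2) %*% h + cs$fc$b2)))
    for (c in 1:4) {
      q <- x[, , 1, n] * cs$sconv$w[1, 1, 1, 1]
      for (cc in 2:4) q <- q + x[, , cc, n] * cs$sconv$w[1, 1, cc, 1]
      t_gate <- 1 / (1 + exp(-(q + cs$sconv$b[1])))
      oracle[, , c, n] <- x[, , c, n] * s[c] + x[, , c, n] * t_gate
    }
  }
  expect_equal(y, oracle, tolerance = 1e-6)

  # forced gates: both sigmoids ~1 give csse(x) = 2x; gates ~0 give 0
  cs$fc$W2[] <- 0; cs$fc$b2[] <- 50
  cs$sconv$w[] <- 0; cs$sconv$b[] <- 50
  expect_equal(ns$csse_fw(cs, x, FALSE), 2 * x, tolerance = 1e-6)
  cs$fc$b2[] <- -50; cs$sconv$b[] <- -50
  expect_lt(max(abs(ns$csse_fw(cs, x, FALSE))), 1e-12)
})

test_that("dense blocks concatenate their first two layers' outputs", {
  db <- ns$with_seed(5, ns$new_dense_block(2L, 8L, 3L, 0, 0, 0, 0.2))
  # the third unit must consume 2 * filters channels
  expect_equal(db$u3$conv$si[["high"]], 16L)
  x <- list(high = array(rnorm(10 * 10 * 2), c(10, 10, 2, 1)), low = NULL)
  y1 <- ns$dense_block_fw(db, x, FALSE)
  expect_equal(dim(y1$high)[3], 8L)           # output channels = filters
  # dropout in eval mode is deterministic
  y2 <- ns$dense_block_fw(db, x, FALSE)
  expect_identical(y1, y2)
})

test_that("pooling indices route un-pooled values to their argmax", {
  set.seed(13)
  for (rep in 1:20) {
    x <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
    r <- ns$maxpool2_fwd(x)
    up <- ns$maxunpool2(r$y, r$idx, 8L, 8L)
    # exhaustive scan of every 2x2 window
    for (c in 1:2) for (i in 1:4) for (j in 1:4) {
      win <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, 1]
      uw <- up[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, 1]
      expect_equal(r$y[i, j, c, 1], max(win))
      expect_equal(sum(uw != 0 | (uw == 0 & max(win) == 0)), 1)
      expect_equal(which.max(win), which(uw == max(win))[1])
    }
  }
  # constant input: one nonzero per window after round trip
  xc <- array(5, c(4, 4, 1, 1))
  rc <- ns$maxpool2_fwd(xc)
  upc <- ns$maxunpool2(rc$y, rc$idx, 4L, 4L)
  expect_equal(sum(upc != 0), 4)
  expect_true(all(rc$y == 5))
})

test_that("the assembled network emits per-pixel probability simplices", {
  cfg <- model_config(in_channels = 2, n_classes = 9, filters = 8,
                      kernel_size = 5, alpha = 0.5, seed = 20)
  net <- build_abdomennet(cfg)
  set.seed(21)
  x <- array(rnorm(64 * 64 * 2 * 2), c(64, 64, 2, 2))
  out <- network_forward(net, x)
  expect_equal(dim(out$probs), c(64, 64, 9, 2))
  sums <- apply(out$probs, c(1, 2, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_true(all(out$probs >= 0))

  # same config + seed -> identical parameter count and weights
  net2 <- build_abdomennet(cfg)
  expect_identical(n_parameters(net), n_parameters(net2))
  expect_identical(get_weights(net), get_weights(net2))

  # shape covariance on other even sizes
  for (hw in list(c(16, 16), c(32, 48))) {
    xs <- array(rnorm(hw[1] * hw[2] * 2), c(hw, 2, 1))
    expect_equal(dim(network_forward(net, xs)$probs), c(hw, 9, 1))
  }
  # wrong channel count is refused
  expect_error(network_forward(net, array(0, c(16, 16, 3, 1))), "channels")
})

test_that("gradients reach every layer through skips and dense paths", {
  cfg <- model_config(in_channels = 2, n_classes = 5, filters = 16,
                      kernel_size = 3, alpha = 0.5, dropout_rate = 0,
                      seed = 22)
  net <- build_abdomennet(cfg)
  set.seed(23)
  x <- array(rnorm(16 * 16 * 2 * 4), c(16, 16, 2, 4))
  y <- array(sample(0:4, 16 * 16 * 4, TRUE), c(16, 16, 4))
  w <- array(1, c(16, 16, 4))
  r <- network_forward(net, x, training = TRUE)
  lg <- ns$loss_and_grad(r$logits, y, w, 5L)
  network_backward(net, lg$dz)
  for (nm in names(net$layers)) {
    l <- net$layers[[nm]]
    for (p in ns$layer_param_names(l)) {
      g <- l[[paste0("g_", p)]]
      expect_false(is.null(g), info = paste(nm, p))
      expect_true(any(g != 0), info = paste(nm, p))
    }
  }
})

test_that("decoders consume their paired encoder's pooling indices", {
  cfg <- model_config(in_channels = 1, n_classes = 3, filters = 8,
                      kernel_size = 3, alpha = 0.5, dropout_rate = 0,
                      seed = 24)
  net <- build_abdomennet(cfg)
  x <- array(rnorm(16 * 16), c(16, 16, 1, 1))
  network_forward(net, x, training = TRUE)
  # indices recorded per encoder level have the pooled spatial dims
  expect_equal(dim(net$idxs[[1]]$high)[1:2], c(8, 8))
  expect_equal(dim(net$idxs[[2]]$high)[1:2], c(4, 4))
  expect_equal(dim(net$idxs[[3]]$high)[1:2], c(2, 2))
  # unpooled maps are zero off the recorded positions
  set.seed(25)
  v <- array(rnorm(4 * 4 * 2), c(4, 4, 2, 1))
  r <- ns$maxpool2_fwd(v)
  up <- ns$maxunpool2(r$y, r$idx, 4L, 4L)
  expect_equal(sum(up != 0), sum(r$y != 0))
})

test_that("checkpoints round-trip weights, config and BN state", {
  cfg <- model_config(in_channels = 2, n_classes = 9, filters = 8,
                      kernel_size = 3, seed = 26)
  net <- build_abdomennet(cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, f)
  net2 <- load_checkpoint(f)
  expect_identical(get_weights(net), get_weights(net2))
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2, 1))
  expect_identical(network_forward(net, x)$probs,
                   network_forward(net2, x)$probs)
})

test_that("convolution gradients match an exact reference", {
  set.seed(27)
  H <- 6L; W <- 5L; C <- 3L; N <- 2L; K <- 3L; Cout <- 4L; pad <- 1L
  x <- array(rnorm(H * W * C * N), c(H, W, C, N))
  w <- array(rnorm(K * K * C * Cout), c(K, K, C, Cout))
  b <- rnorm(Cout)
  dy <- array(rnorm(H * W * Cout * N), c(H, W, Cout, N))
  bw <- ns$conv2d_bwd(x, w, dy)
  dw_ref <- array(0, dim(w)); dx_ref <- array(0, dim(x))
  db_ref <- rep(0, Cout)
  for (n in 1:N) for (co in 1:Cout) {
    db_ref[co] <- db_ref[co] + sum(dy[, , co, n])
    for (ci in 1:C) for (ki in 1:K) for (kj in 1:K)
      for (i in 1:H) for (j in 1:W) {
        ii <- i + ki - 1L - pad; jj <- j + kj - 1L - pad
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
          dw_ref[ki, kj, ci, co] <- dw_ref[ki, kj, ci, co] +
            x[ii, jj, ci, n] * dy[i, j, co, n]
          dx_ref[ii, jj, ci, n] <- dx_ref[ii, jj, ci, n] +
            w[ki, kj, ci, co] * dy[i, j, co, n]
        }
      }
  }
  expect_equal(bw$dw, dw_ref, tolerance = 1e-5)
  expect_equal(bw$dx, dx_ref, tolerance = 1e-5)
  expect_equal(as.numeric(bw$db), db_ref, tolerance = 1e-8)
  # forward against a direct shift-and-sum reference
  y <- ns$conv2d_fwd(x, w, b)
  y_ref <- array(0, c(H, W, Cout, N))
  for (n in 1:N) for (co in 1:Cout) {
    acc <- matrix(b[co], H, W)
    for (ci in 1:C) for (ki in 1:K) for (kj in 1:K)
      for (i in 1:H) for (j in 1:W) {
        ii <- i + ki - 1L - pad; jj <- j + kj - 1L - pad
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
          acc[i, j] <- acc[i, j] + x[ii, jj, ci, n] * w[ki, kj, ci, co]
      }
    y_ref[, , co, n] <- acc
  }
  expect_equal(y, y_ref, tolerance = 1e-5)
})
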