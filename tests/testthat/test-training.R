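# slice extraction, weight maps, the combined loss, SWA and the training loop

ns <- asNamespace("abdomenseg")

test_that("slices are taken perpendicular to each view axis", {
  pair <- tiny_training_pair()
  d <- dim(pair$study$water)
  ax <- extract_slices(pair$study, pair$labels, "axial")
  expect_equal(dim(ax$x), c(d[1], d[2], 2, d[3]))
  expect_equal(dim(ax$y), c(d[1], d[2], d[3]))
  co <- extract_slices(pair$study, pair$labels, "coronal")
  expect_equal(dim(co$x), c(d[1], d[3], 2, d[2]))
  sa <- extract_slices(pair$study, pair$labels, "sagittal")
  expect_equal(dim(sa$x), c(d[2], d[3], 2, d[1]))
  # two input channels: opposed-phase and water stacked
  expect_equal(ax$x[, , 1, 3], pair$study$opposed_phase[, , 3])
  expect_equal(ax$x[, , 2, 3], pair$study$water[, , 3])
  # reassembling slices reproduces the label volume exactly
  for (v in c("axial", "coronal", "sagittal")) {
    sl <- extract_slices(pair$study, pair$labels, v)
    expect_identical(ns$restack_slices(sl$y, v), pair$labels)
  }
  expect_error(extract_slices(pair$study, pair$labels[1:3, , ], "axial"),
               "aligned")
})

test_that("median-frequency weights grow for rarer classes", {
  lab <- array(0L, c(10, 10))
  lab[1:3, 1:3] <- 1L                    # 9 of 100
  lab[1, 10] <- 2L                       # 1 of 100
  cw <- median_frequency_weights(list(lab), n_classes = 3L)
  expect_gt(cw[3], cw[2])
  expect_gt(cw[2], cw[1])
  # counts {0: 90, 1: 10}: rarer class gets the larger weight
  lab2 <- array(0L, c(10, 10)); lab2[1:10] <- 1L
  cw2 <- median_frequency_weights(list(lab2), n_classes = 2L)
  expect_gt(cw2[2], cw2[1])
  expect_error(median_frequency_weights(list(), 3L), "voxels")
})

test_that("weight maps combine class weights and boundary emphasis", {
  cw <- c(0.5, 2, 4, rep(1, 6))
  # single-class slice: no boundaries, constant 1 + c(0)
  bg <- matrix(0L, 6, 6)
  expect_equal(compute_weight_map(bg, cw), matrix(1.5, 6, 6))

  # 2x2 foreground square: boundary exactly where the label gradient is
  # nonzero, checked pixel by pixel against a brute-force neighbour scan
  sl <- matrix(0L, 6, 6); sl[3:4, 3:4] <- 1L
  wm <- compute_weight_map(sl, cw, w_class = 1, w_edge = 1)
  for (i in 1:6) for (j in 1:6) {
    nb <- c(if (i > 1) sl[i - 1, j], if (i < 6) sl[i + 1, j],
            if (j > 1) sl[i, j - 1], if (j < 6) sl[i, j + 1])
    on_edge <- any(nb != sl[i, j])
    expect_equal(wm[i, j], 1 + cw[sl[i, j] + 1] + as.numeric(on_edge),
                 info = sprintf("pixel %d,%d", i, j))
  }
  expect_true(all(wm > 0))
})

test_that("the combined loss attains its closed-form optimum at p = g", {
  set.seed(30)
  for (rep in 1:5) {
    y <- array(sample(0:8, 7 * 7, TRUE), c(7, 7, 1))
    g <- ns$one_hot(y, 9L)
    loss <- combined_loss(array(g, c(7, 7, 9, 1)), g)
    expect_equal(as.numeric(loss), -1, tolerance = 1e-9)
    expect_equal(attr(loss, "logistic"), 0, tolerance = 1e-9)
  }
})

test_that("an absent class contributes its maximal smoothed Dice of 1", {
  y <- array(0L, c(4, 4, 1))                 # only background present
  g <- ns$one_hot(y, 3L)
  p <- g                                      # classes 1, 2 predicted absent
  loss <- combined_loss(p, g)
  dice <- attr(loss, "dice")
  expect_equal(dice[2], 1)                    # (0 + 1) / (0 + 0 + 1)
  expect_equal(dice[3], 1)
})

test_that("the loss on a 2-pixel toy matches hand arithmetic", {
  # two pixels, 9 classes, uniform p = 1/9, truth classes 0 and 3, w = 1
  p <- array(1 / 9, c(1, 2, 9, 1))
  y <- array(c(0L, 3L), c(1, 2, 1))
  g <- ns$one_hot(y, 9L)
  loss <- combined_loss(p, g, dice_aggregation = "mean",
                        pixel_reduction = "sum")
  # logistic: -log(1/9) per pixel, 2 pixels
  manual_log <- 2 * log(9)
  # Dice per class over the 2 pixels:
  #   class 0: p-sum 2/9, g-sum 1, overlap 1/9 -> (2/9 + 1)/(2/9 + 2)
  #   class 3: same; other 7 classes: (0 + 1)/(2/9 + 0 + 1)
  d_present <- (2 / 9 + 1) / (2 / 9 + 2)
  d_absent <- 1 / (2 / 9 + 1)
  manual_dice <- (2 * d_present + 7 * d_absent) / 9
  expect_equal(as.numeric(loss), manual_log - manual_dice,
               tolerance = 1e-10)
})

test_that("probabilities at zero are clamped, never NaN", {
  p <- array(0, c(2, 2, 2, 1)); p[, , 2, ] <- 1
  y <- array(0L, c(2, 2, 1))                  # truth is class 0, p(0) = 0
  g <- ns$one_hot(y, 2L)
  loss <- combined_loss(p, g)
  expect_true(is.finite(loss))
})

test_that("any perturbation away from the truth increases the loss", {
  set.seed(31)
  y <- array(sample(0:2, 16, TRUE), c(4, 4, 1))
  g <- ns$one_hot(y, 3L)
  base <- as.numeric(combined_loss(g, g))
  for (rep in 1:10) {
    eps <- array(runif(length(g), 0, 0.2), dim(g))
    p <- g + eps
    # renormalize to a simplex
    s <- array(0, c(4, 4, 1, 1))
    for (l in 1:3) s <- s + p[, , l, , drop = FALSE]
    for (l in 1:3) p[, , l, ] <- p[, , l, ] / s[, , 1, ]
    expect_gt(as.numeric(combined_loss(p, g)), base)
  }
})

test_that("loss gradients agree with finite differences", {
  set.seed(32)
  z <- array(rnorm(5 * 4 * 3 * 2), c(5, 4, 3, 2))
  y <- array(sample(0:2, 5 * 4 * 2, TRUE), c(5, 4, 2))
  w <- array(runif(5 * 4 * 2, 0.5, 2), c(5, 4, 2))
  lg <- ns$loss_and_grad(z, y, w, 3L)
  eps <- 1e-6
  for (i in sample(length(z), 12)) {
    zp <- z; zp[i] <- zp[i] + eps
    zm <- z; zm[i] <- zm[i] - eps
    num <- (ns$loss_and_grad(zp, y, w, 3L)$loss -
              ns$loss_and_grad(zm, y, w, 3L)$loss) / (2 * eps)
    expect_equal(lg$dz[i], num, tolerance = 1e-5)
  }
})

test_that("SWA is an exact running arithmetic mean of snapshots", {
  mk <- function(v) list(a = array(v, c(2, 2)), b = rep(v, 3))
  expect_identical(swa_update(NULL, mk(1), 0), mk(1))
  m <- swa_update(mk(2), mk(2), 5)
  expect_equal(m, mk(2))                      # averaging w with itself
  m3 <- Reduce(function(acc, i) swa_update(acc, mk(c(1, 2, 6)[i]), i - 1),
               1:3, accumulate = FALSE, init = NULL)
  expect_equal(m3$a[1, 1], 3)                 # mean of 1, 2, 6
  for (k in c(1, 3, 10)) {
    snaps <- lapply(seq_len(k), function(i) mk(rnorm(1)))
    run <- NULL
    for (i in seq_len(k)) run <- swa_update(run, snaps[[i]], i - 1)
    exact <- mk(0)
    exact$a <- Reduce(`+`, lapply(snaps, `[[`, "a")) / k
    exact$b <- Reduce(`+`, lapply(snaps, `[[`, "b")) / k
    expect_equal(run, exact, tolerance = 1e-12)
  }
  bad <- mk(1); bad$a <- array(1, c(3, 3))
  expect_error(swa_update(mk(1), bad, 1), "match")
})

test_that("BN recalibration recovers exact data moments, weights untouched", {
  cfg <- model_config(in_channels = 1, n_classes = 3, filters = 8,
                      kernel_size = 3, alpha = 0, seed = 40)
  net <- build_abdomennet(cfg)
  set.seed(41)
  batches <- lapply(1:3, function(i) array(rnorm(16 * 16 * 4, mean = 2),
                                           c(16, 16, 1, 4)))
  w_before <- get_weights(net)
  recalibrate_bn(net, batches)
  expect_identical(get_weights(net), w_before)
  # the entry BN layer sees the raw input: moments must match the data
  l <- net$layers[["enc1.db.u1.bn_h"]]
  all_x <- unlist(batches)
  expect_equal(l$rmean, mean(all_x), tolerance = 1e-10)
  expect_equal(l$rvar, mean((all_x - mean(all_x))^2), tolerance = 1e-10)
  # deterministic given loader order
  st1 <- ns$bn_state(net)
  recalibrate_bn(net, batches)
  expect_identical(ns$bn_state(net), st1)
  expect_error(recalibrate_bn(net, list()), "empty")
})

test_that("a single slice can be overfitted", {
  pair <- tiny_training_pair()
  k <- which.max(apply(pair$labels, 3, function(s) sum(s > 0)))
  x <- array(c(pair$study$opposed_phase[, , k], pair$study$water[, , k]),
             c(dim(pair$labels)[1:2], 2, 1))
  y <- array(pair$labels[, , k], c(dim(pair$labels)[1:2], 1))
  w <- compute_weight_map(y[, , 1],
                          median_frequency_weights(list(y), 9L))
  dim(w) <- c(dim(w), 1)
  cfg <- model_config(in_channels = 2, n_classes = 9, filters = 8,
                      kernel_size = 5, alpha = 0.5, dropout_rate = 0,
                      seed = 42)
  net <- build_abdomennet(cfg)
  losses <- numeric(200)
  ns$with_seed(43, for (step in 1:200) {
    r <- network_forward(net, x, training = TRUE)
    lg <- ns$loss_and_grad(r$logits, y, w, 9L)
    losses[step] <- lg$loss
    network_backward(net, lg$dz)
    ns$sgd_step(net, 0.02, 0.9)
  })
  expect_lt(losses[200], losses[1])
  pred <- ns$argmax_channels(network_forward(net, x, training = TRUE)$probs)
  dice <- ns$mean_foreground_dice(pred, y, 9L)
  expect_gte(dice, 0.95)
})

test_that("short training runs are reproducible and well-logged", {
  pair <- tiny_training_pair()
  sub <- function(zr) {
    st <- pair$study
    for (k in DIXON_CONTRASTS) st[[k]] <- st[[k]][, , zr, drop = FALSE]
    list(study = st, labels = pair$labels[, , zr, drop = FALSE])
  }
  tr <- sub(6:13); va <- sub(14:17)
  train_ds <- build_slice_dataset(tr$study, tr$labels, "axial")
  val_ds <- build_slice_dataset(va$study, va$labels, "axial",
                                class_weights = train_ds$class_weights)
  cfg <- model_config(in_channels = 2, n_classes = 9, filters = 8,
                      kernel_size = 3, seed = 50)
  tc <- train_config(epochs = 2, batch_size = 4, base_lr = 0.01,
                     swa_lr = 0.005, swa_start_epoch = 2, seed = 51)
  f1 <- train_view(build_abdomennet(cfg), train_ds, val_ds, tc)
  expect_equal(nrow(f1$history), 2)
  expect_named(f1$history, c("epoch", "lr", "train_loss", "val_dice"))
  expect_true(all(is.finite(f1$history$train_loss)))
  f2 <- train_view(build_abdomennet(cfg), train_ds, val_ds, tc)
  expect_identical(f1$swa_weights, f2$swa_weights)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$best_weights, f2$best_weights)
})
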