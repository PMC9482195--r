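# Slice extraction per anatomical view, the combined weighted-logistic +
# smoothed-Dice loss, and the SGD + stochastic-weight-averaging loop.

VIEW_AXES <- c(axial = 3L, coronal = 2L, sagittal = 1L)

#' Extract 2D slices from a standardized study
#'
#' Slices are taken perpendicular to the view axis (axial: third/table
#' axis; coronal: second; sagittal: first) at native voxel resolution; the
#' requested contrasts are stacked as channels.
#'
#' @param study a `standardized_study` (or plain list of contrast arrays).
#' @param labels aligned integer label array (may be `NULL`).
#' @param view one of "axial", "coronal", "sagittal".
#' @param contrasts contrasts stacked as input channels; the default is the
#'   opposed-phase + water combination.
#' @return list with `x` (H, W, C, n_slices), `y` (H, W, n_slices integer
#'   labels or `NULL`) and `view`.
#' @export
extract_slices <- function(study, labels = NULL,
                           view = c("axial", "coronal", "sagittal"),
                           contrasts = c("opposed_phase", "water")) {
  view <- match.arg(view)
  ax <- VIEW_AXES[[view]]
  vols <- lapply(contrasts, function(k) {
    v <- study[[k]]
    if (is.null(v)) stopf("study has no contrast '%s'", k)
    v
  })
  d <- dim(vols[[1]])
  if (!is.null(labels) && !all(dim(labels) == d))
    stopf("labels are not aligned with the study grid")
  perm <- switch(view, axial = c(1L, 2L, 3L), coronal = c(1L, 3L, 2L),
                 sagittal = c(2L, 3L, 1L))
  n <- d[ax]
  hw <- d[perm[1:2]]
  x <- array(0, c(hw, length(contrasts), n))
  for (ci in seq_along(vols)) {
    v <- aperm(vols[[ci]], perm)
    x[, , ci, ] <- v
  }
  y <- NULL
  if (!is.null(labels)) {
    y <- aperm(labels, perm)
    storage.mode(y) <- "integer"
  }
  list(x = x, y = y, view = view, contrasts = contrasts, grid = d,
       perm = perm)
}

# restack per-slice maps (H, W, n) into the original volume order
restack_slices <- function(s, view) {
  perm <- switch(view, axial = c(1L, 2L, 3L), coronal = c(1L, 3L, 2L),
                 sagittal = c(3L, 1L, 2L))
  aperm(s, perm)
}

#' Median-frequency class weights
#'
#' Inverse-frequency weights `c(l) = median(freq) / freq(l)` over the
#' classes present in the training labels; rarer classes get larger
#' weights. Absent classes get weight 0.
#'
#' @param label_volumes list of integer label arrays (0..8).
#' @param n_classes total number of classes.
#' @return numeric vector of length `n_classes` (index 1 = class 0).
#' @export
median_frequency_weights <- function(label_volumes, n_classes = 9L) {
  if (!is.list(label_volumes)) label_volumes <- list(label_volumes)
  counts <- rep(0, n_classes)
  for (v in label_volumes)
    counts <- counts + tabulate(as.integer(v) + 1L, nbins = n_classes)
  if (sum(counts) == 0) stopf("no labelled voxels to estimate frequencies")
  freq <- counts / sum(counts)
  present <- freq > 0
  w <- rep(0, n_classes)
  w[present] <- median(freq[present]) / freq[present]
  w
}

#' Per-slice loss weight map
#'
#' `w(x) = 1 + w_class * c(label(x)) + w_edge * [x on a label boundary]`,
#' where `c` is a (median-frequency) class weight and a boundary pixel is
#' one whose 2D label gradient is nonzero, i.e. whose label differs from a
#' 4-neighbour. Strictly positive everywhere.
#'
#' @param label_slice 2D integer matrix (0..8).
#' @param class_weights vector from [median_frequency_weights()].
#' @param w_class,w_edge coefficients of the two terms.
#' @return numeric matrix of weights.
#' @export
compute_weight_map <- function(label_slice, class_weights,
                               w_class = 1, w_edge = 1) {
  lab <- as.matrix(label_slice)
  if (any(lab < 0L) || any(lab + 1L > length(class_weights)))
    stopf("labels outside the configured class range")
  edge <- matrix(FALSE, nrow(lab), ncol(lab))
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr > 1L) {
    dif <- lab[-1L, , drop = FALSE] != lab[-nr, , drop = FALSE]
    edge[-nr, ] <- edge[-nr, ] | dif
    edge[-1L, ] <- edge[-1L, ] | dif
  }
  if (nc > 1L) {
    dif <- lab[, -1L, drop = FALSE] != lab[, -nc, drop = FALSE]
    edge[, -nc] <- edge[, -nc] | dif
    edge[, -1L] <- edge[, -1L] | dif
  }
  1 + w_class * matrix(class_weights[lab + 1L], nr, nc) + w_edge * edge
}

#' Assemble a training slice dataset for one view
#'
#' Stacks the slices of several standardized studies, estimates
#' median-frequency class weights over the whole set and attaches a weight
#' map per slice.
#'
#' @param studies list of `standardized_study`.
#' @param labels list of aligned label arrays.
#' @param view anatomical view.
#' @param contrasts input contrasts.
#' @param w_class,w_edge weight-map coefficients.
#' @param n_classes number of classes.
#' @param class_weights optional precomputed class weights (e.g. from the
#'   training set, when building a validation set).
#' @return a `slice_dataset`: `x` (H,W,C,N), `y` (H,W,N), `w` (H,W,N),
#'   `view`, `class_weights`.
#' @export
build_slice_dataset <- function(studies, labels, view = "axial",
                                contrasts = c("opposed_phase", "water"),
                                w_class = 1, w_edge = 1, n_classes = 9L,
                                class_weights = NULL) {
  if (inherits(studies, "standardized_study")) studies <- list(studies)
  if (!is.list(labels)) labels <- list(labels)
  if (is.null(class_weights))
    class_weights <- median_frequency_weights(labels, n_classes)
  parts <- Map(function(s, l) extract_slices(s, l, view, contrasts),
               studies, labels)
  hw <- dim(parts[[1]]$x)[1:2]
  for (p in parts)
    if (!all(dim(p$x)[1:2] == hw))
      stopf("all studies in one dataset must share the slice grid")
  x <- do.call(function(...) abind4(...), lapply(parts, `[[`, "x"))
  y <- do.call(function(...) abind3(...), lapply(parts, `[[`, "y"))
  n <- dim(y)[3]
  w <- array(0, dim(y))
  for (i in seq_len(n))
    w[, , i] <- compute_weight_map(y[, , i], class_weights, w_class, w_edge)
  structure(list(x = x, y = y, w = w, view = view, contrasts = contrasts,
                 n_classes = n_classes, class_weights = class_weights),
            class = "slice_dataset")
}

abind4 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[4], 0L))
  out <- array(0, c(d[1:3], n))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[4]
    out[, , , at + seq_len(k)] <- p
    at <- at + k
  }
  out
}

abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[3], 0L))
  out <- array(0L, c(d[1:2], n))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[3]
    out[, , at + seq_len(k)] <- p
    at <- at + k
  }
  out
}

one_hot <- function(y, n_classes) {
  d <- dim(y)
  g <- array(0, c(d[1], d[2], n_classes, d[3]))
  for (l in seq_len(n_classes) - 1L)
    g[, , l + 1L, ] <- (y == l)
  g
}

#' Combined weighted logistic + smoothed Dice loss
#'
#' The logistic term is the weight-map-weighted negative log-probability of
#' the true class; the Dice term per class is
#' `(2 * sum(p g) + 1) / (sum p + sum g + 1)` (the +1 smoothing leaves true
#' negatives unpenalized: an all-absent class contributes its maximum 1).
#' The total loss is the logistic term minus the Dice terms aggregated over
#' classes (mean aggregation by default, so a perfect prediction scores
#' exactly -1).
#'
#' @param p probability array (H, W, n_classes, N) or (H, W, n_classes).
#' @param g one-hot ground truth, same shape as `p`.
#' @param w weight map (H, W, N) or (H, W); default all ones.
#' @param dice_aggregation "mean" (default) or "sum" over classes.
#' @param pixel_reduction "sum" (the written form of the objective) or
#'   "mean" (the per-pixel-normalized form the optimizer uses, so the
#'   gradient scale does not depend on slice size).
#' @param eps probability clamp inside the logarithm.
#' @return scalar loss; attributes `logistic` and `dice` hold the terms.
#' @export
combined_loss <- function(p, g, w = NULL,
                          dice_aggregation = c("mean", "sum"),
                          pixel_reduction = c("sum", "mean"),
                          eps = 1e-7) {
  dice_aggregation <- match.arg(dice_aggregation)
  pixel_reduction <- match.arg(pixel_reduction)
  if (length(dim(p)) == 3L) dim(p) <- c(dim(p), 1L)
  if (length(dim(g)) == 3L) dim(g) <- c(dim(g), 1L)
  d <- dim(p)
  if (!all(dim(g) == d)) stopf("p and g shapes differ")
  if (is.null(w)) w <- array(1, c(d[1], d[2], d[4]))
  if (length(dim(w)) == 2L) dim(w) <- c(dim(w), 1L)
  pc <- pmax(p, eps)
  wv <- as.vector(w)
  wlog <- 0
  for (l in seq_len(d[3]))
    wlog <- wlog - sum(wv * as.vector(g[, , l, ]) *
                         log(as.vector(pc[, , l, ])))
  if (pixel_reduction == "mean") wlog <- wlog / (d[1] * d[2] * d[4])
  # smoothed Dice per class, pixels pooled over the batch
  dice <- numeric(d[3])
  for (l in seq_len(d[3])) {
    pl <- p[, , l, ]; gl <- g[, , l, ]
    dice[l] <- (2 * sum(pl * gl) + 1) / (sum(pl) + sum(gl) + 1)
  }
  dterm <- if (dice_aggregation == "mean") mean(dice) else sum(dice)
  structure(wlog - dterm, logistic = wlog, dice = dice)
}

# loss + gradient w.r.t. logits for the training loop; Dice pooled per
# sample, mean over classes and samples
loss_and_grad <- function(logits, y, w, n_classes,
                          pixel_reduction = "mean", eps = 1e-7) {
  d <- dim(logits)
  p <- softmax_channels(logits)
  g <- one_hot(y, n_classes)
  npx <- if (pixel_reduction == "mean") d[1] * d[2] * d[4] else 1
  wb <- array(0, d)
  for (l in seq_len(d[3])) wb[, , l, ] <- w
  dz <- wb * (p - g) / npx
  pc <- pmax(p, eps)
  wlog <- -sum(wb * g * log(pc)) / npx

  # Dice term: per class l and sample n over that sample's pixels
  S_pg <- S_p <- S_g <- matrix(0, d[3], d[4])
  for (l in seq_len(d[3])) {
    pl <- p[, , l, , drop = FALSE]; gl <- g[, , l, , drop = FALSE]
    S_pg[l, ] <- colSums(matrix(pl * gl, ncol = d[4]))
    S_p[l, ] <- colSums(matrix(pl, ncol = d[4]))
    S_g[l, ] <- colSums(matrix(gl, ncol = d[4]))
  }
  denom <- S_p + S_g + 1
  D <- (2 * S_pg + 1) / denom
  dice_loss <- -mean(D)
  # d(-mean D)/dp_l(x,n), then chain through the softmax
  dp <- array(0, d)
  scale <- 1 / (d[3] * d[4])
  for (l in seq_len(d[3])) {
    gl <- g[, , l, , drop = FALSE]
    a <- rep(2 / denom[l, ], each = d[1] * d[2])
    c2 <- rep((2 * S_pg[l, ] + 1) / denom[l, ]^2, each = d[1] * d[2])
    dp[, , l, ] <- -scale * (gl * a - c2)
  }
  sum_dp_p <- dp[, , 1L, , drop = FALSE] * p[, , 1L, , drop = FALSE]
  for (l in seq_len(d[3])[-1])
    sum_dp_p <- sum_dp_p + dp[, , l, , drop = FALSE] * p[, , l, , drop = FALSE]
  dz_dice <- p * (dp - sum_dp_p[, , rep(1L, d[3]), , drop = FALSE])
  list(loss = wlog + dice_loss, logistic = wlog, dice = dice_loss,
       dz = dz + dz_dice)
}

#' Stochastic weight averaging update
#'
#' Running equal average of weight snapshots:
#' `new_mean = (n * old_mean + current) / (n + 1)` parameterwise.
#'
#' @param running_mean_weights flat weight list (or `NULL` when `n = 0`).
#' @param current_weights flat weight list from [get_weights()].
#' @param n_models snapshots already averaged.
#' @return updated flat weight list.
#' @export
swa_update <- function(running_mean_weights, current_weights, n_models) {
  if (n_models == 0 || is.null(running_mean_weights))
    return(current_weights)
  if (!identical(names(running_mean_weights), names(current_weights)))
    stopf("weight trees do not match")
  out <- running_mean_weights
  for (k in names(out)) {
    if (length(out[[k]]) != length(current_weights[[k]]))
      stopf("weight trees do not match at %s", k)
    out[[k]] <- (n_models * out[[k]] + current_weights[[k]]) / (n_models + 1)
  }
  out
}

#' Recompute batch-norm statistics for a set of weights
#'
#' One pass over the loader in training-statistics mode; running means and
#' variances are replaced by the exact per-channel moments of the data as
#' seen by each layer. Learnable parameters are untouched. Needed after
#' weight averaging, whose averaged weights have no matching statistics.
#'
#' Dropout is disabled during the pass (the statistics should describe the
#' activations inference will see), which also keeps recalibration a pure
#' function of the loader.
#'
#' @param net the network.
#' @param batches list of input batches (H, W, C, n).
#' @return `net`, invisibly.
#' @export
recalibrate_bn <- function(net, batches) {
  if (length(batches) == 0L) stopf("empty loader")
  for (l in net$layers) if (l$ptype == "bn") bn_reset_recal(l)
  drops <- Filter(function(l) l$ptype == "dropout", net$layers)
  for (l in drops) l$disabled <- TRUE
  on.exit(for (l in drops) l$disabled <- FALSE)
  for (b in batches) network_forward(net, b, training = TRUE)
  for (l in net$layers) if (l$ptype == "bn") bn_finish_recal(l)
  net$idxs <- NULL
  invisible(net)
}

#' Training configuration
#'
#' @param epochs training epochs.
#' @param batch_size slices per SGD step.
#' @param base_lr SGD learning rate before weight averaging starts.
#' @param momentum SGD momentum.
#' @param swa_lr constant learning rate during the averaging phase.
#' @param swa_start_epoch first epoch (1-based) of the averaging phase.
#' @param seed RNG seed covering shuffling and dropout.
#' @param pixel_reduction logistic-term normalization used by the
#'   optimizer; see [combined_loss()].
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 100L, batch_size = 10L, base_lr = 0.01,
                         momentum = 0.9, swa_lr = 0.05,
                         swa_start_epoch = 75L, seed = 1L,
                         pixel_reduction = "mean") {
  if (swa_start_epoch > epochs)
    stopf("swa_start_epoch must be <= epochs")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 base_lr = base_lr, momentum = momentum, swa_lr = swa_lr,
                 swa_start_epoch = as.integer(swa_start_epoch),
                 seed = as.integer(seed),
                 pixel_reduction = pixel_reduction),
            class = "train_config")
}

# volume-level mean Dice over foreground classes present in the labels
mean_foreground_dice <- function(pred, y, n_classes) {
  scores <- c()
  for (l in seq_len(n_classes - 1L)) {
    np <- sum(pred == l); ng <- sum(y == l)
    if (ng == 0 && np == 0) next
    scores <- c(scores, 2 * sum(pred == l & y == l) / (np + ng))
  }
  if (length(scores) == 0) return(NA_real_)
  mean(scores)
}

predict_slices <- function(net, x, batch = 8L) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2], net$config$n_classes, d[4]))
  i <- 1L
  while (i <= d[4]) {
    j <- min(i + batch - 1L, d[4])
    out[, , , i:j] <-
      network_forward(net, x[, , , i:j, drop = FALSE], training = FALSE)$probs
    i <- j + 1L
  }
  out
}

argmax_channels <- function(p) {
  d <- dim(p)
  m <- matrix(aperm(p, c(1, 2, 4, 3)), ncol = d[3])
  lab <- max.col(m, ties.method = "first") - 1L
  array(lab, d[c(1, 2, 4)])
}

#' Train one view's network with SGD and stochastic weight averaging
#'
#' Plain SGD with momentum at `base_lr` until `swa_start_epoch`, then a
#' constant `swa_lr` with an equal weight average taken after every epoch.
#' The model with the highest validation Dice is checkpointed; the averaged
#' weights get their batch-norm statistics recalibrated on the training
#' data.
#'
#' @param net network from [build_abdomennet()].
#' @param train,val `slice_dataset`s from [build_slice_dataset()].
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `best_weights`, `best_bn`, `swa_weights`, `swa_bn`,
#'   `history` (data.frame epoch/lr/train_loss/val_dice),
#'   `val_dice_sgd_final`, `val_dice_swa` and `config`.
#' @export
train_view <- function(net, train, val, config = train_config(),
                       verbose = FALSE) {
  stopifnot(inherits(train, "slice_dataset"))
  nimg <- dim(train$x)[4]
  if (nimg == 0L || dim(val$x)[4] == 0L) stopf("datasets must be non-empty")
  L <- net$config$n_classes
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_dice = numeric())
  best <- list(dice = -Inf, weights = NULL, bn = NULL)
  swa_w <- NULL; swa_n <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- if (epoch < config$swa_start_epoch) config$base_lr
            else config$swa_lr
      ord <- sample(nimg)
      total_loss <- 0; nb <- 0L
      i <- 1L
      while (i <= nimg) {
        j <- min(i + config$batch_size - 1L, nimg)
        sel <- ord[i:j]
        xb <- train$x[, , , sel, drop = FALSE]
        yb <- train$y[, , sel, drop = FALSE]
        wb <- train$w[, , sel, drop = FALSE]
        r <- network_forward(net, xb, training = TRUE)
        lg <- loss_and_grad(r$logits, yb, wb, L, config$pixel_reduction)
        if (!is.finite(lg$loss))
          stopf("loss became non-finite at epoch %d; aborting", epoch)
        network_backward(net, lg$dz)
        sgd_step(net, lr, config$momentum)
        total_loss <- total_loss + lg$loss
        nb <- nb + 1L
        i <- j + 1L
      }
      pred <- argmax_channels(predict_slices(net, val$x))
      vdice <- mean_foreground_dice(pred, val$y, L)
      history[epoch, ] <- list(epoch, lr, total_loss / nb, vdice)
      if (verbose)
        message(sprintf("epoch %3d  lr %.3g  loss %8.4f  val dice %.4f",
                        epoch, lr, total_loss / nb, vdice))
      if (!is.na(vdice) && vdice > best$dice) {
        best$dice <- vdice
        best$weights <- get_weights(net)
        best$bn <- bn_state(net)
      }
      if (epoch >= config$swa_start_epoch) {
        swa_w <- swa_update(swa_w, get_weights(net), swa_n)
        swa_n <- swa_n + 1L
      }
    }
  })
  val_dice_sgd_final <- utils::tail(history$val_dice, 1)
  swa_bn <- NULL; val_dice_swa <- NA_real_
  if (!is.null(swa_w)) {
    swa_net <- clone_network(net)
    set_weights(swa_net, swa_w)
    batches <- list()
    i <- 1L
    while (i <= nimg) {
      j <- min(i + config$batch_size - 1L, nimg)
      batches[[length(batches) + 1L]] <- train$x[, , , i:j, drop = FALSE]
      i <- j + 1L
    }
    recalibrate_bn(swa_net, batches)
    swa_bn <- bn_state(swa_net)
    pred <- argmax_channels(predict_slices(swa_net, val$x))
    val_dice_swa <- mean_foreground_dice(pred, val$y, L)
  }
  list(best_weights = best$weights, best_bn = best$bn,
       best_val_dice = best$dice,
       swa_weights = swa_w, swa_bn = swa_bn,
       history = history,
       val_dice_sgd_final = val_dice_sgd_final,
       val_dice_swa = val_dice_swa,
       config = config)
}
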