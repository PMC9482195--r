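# AbdomenNet assembly: encoder blocks (dense block + CSSE + indexed 2x2 max
# pooling), a bottleneck, decoder blocks (index un-pooling + skip concat +
# dense block + CSSE) and a 1x1 softmax classifier. The first encoder and
# last decoder use plain convolutions; everything in between runs on the
# octave high/low channel split.

#' Model configuration
#'
#' @param in_channels input channels (1 for a single Dixon contrast, 2 for
#'   the default opposed-phase + water stack).
#' @param n_classes output classes (background + 8 organs).
#' @param filters convolutional filters per dense block (paper setting 64).
#' @param kernel_size odd convolution kernel size (paper setting 5).
#' @param alpha octave channel split in `[0, 1)`; `alpha * filters` must be
#'   integral. `alpha = 0` yields a plain-convolution network.
#' @param dropout_rate dropout after each dense block.
#' @param n_enc_dec number of encoder/decoder stages.
#' @param se_reduction channel squeeze-and-excite reduction ratio.
#' @param seed weight initialization seed.
#' @return a `model_config` list.
#' @export
model_config <- function(in_channels = 2L, n_classes = 9L, filters = 64L,
                         kernel_size = 5L, alpha = 0.5, dropout_rate = 0.2,
                         n_enc_dec = 3L, se_reduction = 2L, seed = 1L) {
  if (in_channels < 1L) stopf("in_channels must be >= 1")
  if (kernel_size %% 2L != 1L) stopf("kernel_size must be odd")
  if (alpha < 0 || alpha >= 1) stopf("alpha must be in [0, 1)")
  if (abs(alpha * filters - round(alpha * filters)) > 1e-9)
    stopf("alpha * filters must be integral")
  if (n_enc_dec < 2L) stopf("need at least 2 encoder/decoder stages")
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 filters = as.integer(filters),
                 kernel_size = as.integer(kernel_size),
                 alpha = alpha,
                 dropout_rate = dropout_rate,
                 n_enc_dec = as.integer(n_enc_dec),
                 se_reduction = as.integer(se_reduction),
                 seed = as.integer(seed)),
            class = "model_config")
}

new_encoder_block <- function(cin, filters, k, a_in, a_mid, a_out, dropout,
                              se_reduction) {
  so <- oct_split(filters, a_out)
  e <- new.env(parent = emptyenv())
  e$db <- new_dense_block(cin, filters, k, a_in, a_mid, a_out, dropout)
  e$cs_h <- new_csse(so[["high"]], se_reduction)
  e$cs_l <- if (so["low"] > 0) new_csse(so[["low"]], se_reduction)
  e
}

encoder_fw <- function(e, x, training) {
  f <- dense_block_fw(e$db, x, training)
  s <- list(high = csse_fw(e$cs_h, f$high, training),
            low = if (!is.null(f$low)) csse_fw(e$cs_l, f$low, training)
                  else NULL)
  ph <- pool_branch(s$high)
  pl <- if (!is.null(s$low)) pool_branch(s$low)
  e$geom <- list(high = ph[c("dims", "padded")],
                 low = if (!is.null(pl)) pl[c("dims", "padded")])
  list(skip = s,
       pooled = list(high = ph$y, low = if (!is.null(pl)) pl$y else NULL),
       idx = list(high = ph$idx, low = if (!is.null(pl)) pl$idx else NULL))
}

encoder_bw <- function(e, dskip, dpooled, idx) {
  g <- e$geom
  dh <- dskip$high
  if (!is.null(dpooled))
    dh <- dh + unpool_branch(dpooled$high, idx$high, g$high$padded,
                             g$high$dims)
  dl <- dskip$low
  if (!is.null(dl) && !is.null(dpooled) && !is.null(dpooled$low))
    dl <- dl + unpool_branch(dpooled$low, idx$low, g$low$padded, g$low$dims)
  ds <- list(high = csse_bw(e$cs_h, dh),
             low = if (!is.null(dl)) csse_bw(e$cs_l, dl) else NULL)
  dense_block_bw(e$db, ds)
}

new_decoder_block <- function(filters, k, a_in, a_mid, a_out, dropout,
                              se_reduction) {
  so <- oct_split(filters, a_out)
  e <- new.env(parent = emptyenv())
  e$db <- new_dense_block(2L * filters, filters, k, a_in, a_mid, a_out,
                          dropout)
  e$cs_h <- new_csse(so[["high"]], se_reduction)
  e$cs_l <- if (so["low"] > 0) new_csse(so[["low"]], se_reduction)
  e
}

decoder_fw <- function(d, x, skip, idx, geom, training) {
  up <- list(high = unpool_branch(x$high, idx$high, geom$high$padded,
                                  geom$high$dims),
             low = if (!is.null(x$low))
               unpool_branch(x$low, idx$low, geom$low$padded, geom$low$dims)
             else NULL)
  cc <- oct_concat(up, skip)
  d$up_channels <- dim(up$high)[3]
  d$geom <- geom
  f <- dense_block_fw(d$db, cc, training)
  list(high = csse_fw(d$cs_h, f$high, training),
       low = if (!is.null(f$low)) csse_fw(d$cs_l, f$low, training)
             else NULL)
}

decoder_bw <- function(d, dy, idx) {
  df <- list(high = csse_bw(d$cs_h, dy$high),
             low = if (!is.null(dy$low)) csse_bw(d$cs_l, dy$low) else NULL)
  dcc <- dense_block_bw(d$db, df)
  ch <- d$up_channels
  hi <- dcc$high; lo <- dcc$low
  dup <- list(high = hi[, , seq_len(ch), , drop = FALSE],
              low = if (!is.null(lo))
                lo[, , seq_len(dim(lo)[3] / 2), , drop = FALSE] else NULL)
  dskip <- list(high = hi[, , (ch + 1):dim(hi)[3], , drop = FALSE],
                low = if (!is.null(lo))
                  lo[, , (dim(lo)[3] / 2 + 1):dim(lo)[3], , drop = FALSE]
                else NULL)
  dx <- list(high = unpool_branch_bw(dup$high, idx$high, d$geom$high$padded),
             low = if (!is.null(dup$low))
               unpool_branch_bw(dup$low, idx$low, d$geom$low$padded)
             else NULL)
  list(dx = dx, dskip = dskip)
}

# register every primitive layer of a composite under hierarchical names
collect_primitives <- function(obj, prefix, acc) {
  if (is.null(obj)) return(acc)
  if (is.environment(obj) && !is.null(obj$ptype)) {
    acc[[prefix]] <- obj
    return(acc)
  }
  if (is.environment(obj)) {
    for (n in c("bn_h", "pr_h", "bn_l", "pr_l", "conv", "hh", "lh", "ll",
                "hl", "u1", "u2", "u3", "drop_h", "drop_l", "db", "cs_h",
                "cs_l", "fc", "sconv")) {
      if (!is.null(obj[[n]]))
        acc <- collect_primitives(obj[[n]], paste(prefix, n, sep = "."), acc)
    }
  }
  acc
}

#' Build an AbdomenNet segmentation network
#'
#' Encoder path: a plain-convolution entry block, octave blocks below,
#' a bottleneck dense block with CSSE; decoder path mirrors the encoders
#' with index-passing un-pooling and skip connections, merging the octave
#' branches back to a plain map before the last decoder; a 1x1 convolution
#' with softmax produces per-pixel class probabilities.
#'
#' @param config a [model_config()].
#' @return a network environment; use [network_forward()], [segment()],
#'   [train_view()].
#' @export
build_abdomennet <- function(config) {
  stopifnot(inherits(config, "model_config"))
  with_seed(config$seed, {
    F <- config$filters; k <- config$kernel_size; a <- config$alpha
    dr <- config$dropout_rate; sr <- config$se_reduction
    ne <- config$n_enc_dec
    net <- new.env(parent = emptyenv())
    net$config <- config
    net$enc <- vector("list", ne)
    net$enc[[1]] <- new_encoder_block(config$in_channels, F, k, 0, 0, 0,
                                      dr, sr)
    if (ne >= 2) for (i in 2:ne) {
      a_in <- if (i == 2) 0 else a
      net$enc[[i]] <- new_encoder_block(F, F, k, a_in, a, a, dr, sr)
    }
    net$bottleneck <- new.env(parent = emptyenv())
    net$bottleneck$db <- new_dense_block(F, F, k, a, a, a, dr)
    bo <- oct_split(F, a)
    net$bottleneck$cs_h <- new_csse(bo[["high"]], sr)
    net$bottleneck$cs_l <- if (bo["low"] > 0) new_csse(bo[["low"]], sr)
    net$dec <- vector("list", ne)
    for (i in ne:2) {
      a_out <- if (i == 2) 0 else a
      net$dec[[i]] <- new_decoder_block(F, k, a, a, a_out, dr, sr)
    }
    net$dec[[1]] <- new_decoder_block(F, k, 0, 0, 0, dr, sr)
    net$classifier <- new_conv(1L, F, config$n_classes, bias = TRUE)

    acc <- list()
    for (i in seq_len(ne))
      acc <- collect_primitives(net$enc[[i]], sprintf("enc%d", i), acc)
    acc <- collect_primitives(net$bottleneck, "bottleneck", acc)
    for (i in ne:1)
      acc <- collect_primitives(net$dec[[i]], sprintf("dec%d", i), acc)
    acc <- collect_primitives(net$classifier, "classifier", acc)
    net$layers <- acc
    net
  })
}

softmax_channels <- function(z) {
  d <- dim(z)
  m <- z[, , 1L, , drop = FALSE]
  for (l in seq_len(d[3])[-1]) m <- pmax(m, z[, , l, , drop = FALSE])
  e <- exp(z - m[, , rep(1L, d[3]), , drop = FALSE])
  s <- e[, , 1L, , drop = FALSE]
  for (l in seq_len(d[3])[-1]) s <- s + e[, , l, , drop = FALSE]
  e / s[, , rep(1L, d[3]), , drop = FALSE]
}

#' Forward pass of the network
#'
#' @param net network from [build_abdomennet()].
#' @param x input batch, array (H, W, in_channels, N).
#' @param training `TRUE` enables batch statistics, dropout and caching for
#'   a subsequent [network_backward()].
#' @return list with `probs` (H, W, n_classes, N) summing to one per pixel
#'   and `logits`.
#' @export
network_forward <- function(net, x, training = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[3] != net$config$in_channels)
    stopf("input has %d channels, network expects %d", dim(x)[3],
          net$config$in_channels)
  ne <- net$config$n_enc_dec
  feat <- list(high = x, low = NULL)
  skips <- idxs <- geoms <- vector("list", ne)
  for (i in seq_len(ne)) {
    r <- encoder_fw(net$enc[[i]], feat, training)
    skips[[i]] <- r$skip
    idxs[[i]] <- r$idx
    geoms[[i]] <- net$enc[[i]]$geom
    feat <- r$pooled
  }
  f <- dense_block_fw(net$bottleneck$db, feat, training)
  feat <- list(high = csse_fw(net$bottleneck$cs_h, f$high, training),
               low = if (!is.null(f$low))
                 csse_fw(net$bottleneck$cs_l, f$low, training) else NULL)
  for (i in ne:1)
    feat <- decoder_fw(net$dec[[i]], feat, skips[[i]], idxs[[i]],
                       geoms[[i]], training)
  logits <- conv_fw(net$classifier, feat$high, training)
  net$idxs <- if (training) idxs else NULL
  list(probs = softmax_channels(logits), logits = logits)
}

#' Backward pass (gradient of a scalar loss w.r.t. the logits)
#'
#' Populates every layer's parameter gradients; requires a preceding
#' [network_forward()] with `training = TRUE`.
#'
#' @param net the network.
#' @param dlogits gradient array shaped like the logits.
#' @return gradient w.r.t. the input batch, invisibly.
#' @export
network_backward <- function(net, dlogits) {
  ne <- net$config$n_enc_dec
  idxs <- net$idxs
  feat <- list(high = conv_bw(net$classifier, dlogits), low = NULL)
  dskips <- vector("list", ne)
  for (i in seq_len(ne)) {
    r <- decoder_bw(net$dec[[i]], feat, idxs[[i]])
    dskips[[i]] <- r$dskip
    feat <- r$dx
  }
  df <- list(high = csse_bw(net$bottleneck$cs_h, feat$high),
             low = if (!is.null(feat$low))
               csse_bw(net$bottleneck$cs_l, feat$low) else NULL)
  feat <- dense_block_bw(net$bottleneck$db, df)
  for (i in ne:1)
    feat <- encoder_bw(net$enc[[i]], dskips[[i]], feat, idxs[[i]])
  invisible(feat$high)
}

## ---- parameter utilities -------------------------------------------------

#' Extract all learnable weights as a flat named list
#' @param net the network.
#' @return named list of arrays/vectors (a deep copy).
#' @export
get_weights <- function(net) {
  out <- list()
  for (nm in names(net$layers)) {
    l <- net$layers[[nm]]
    for (p in layer_param_names(l))
      out[[paste(nm, p, sep = ":")]] <- l[[p]]
  }
  out
}

#' Load a flat weight list back into a network
#' @param net the network.
#' @param weights list from [get_weights()] (or [swa_update()]).
#' @return `net`, invisibly.
#' @export
set_weights <- function(net, weights) {
  for (key in names(weights)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    l <- net$layers[[parts[1]]]
    if (is.null(l)) stopf("no layer named %s in network", parts[1])
    cur <- l[[parts[2]]]
    new <- weights[[key]]
    if (!identical(dim(cur), dim(new)) || length(cur) != length(new))
      stopf("shape mismatch for %s", key)
    assign(parts[2], new, envir = l)
  }
  invisible(net)
}

#' Number of learnable parameters
#' @param net the network.
#' @return integer count.
#' @export
n_parameters <- function(net) {
  sum(vapply(get_weights(net), length, 0L))
}

#' Print a layer table with parameter counts
#' @param net the network.
#' @return data.frame (layer, type, n_params), invisibly; prints a summary.
#' @export
describe_network <- function(net) {
  rows <- lapply(names(net$layers), function(nm) {
    l <- net$layers[[nm]]
    np <- sum(vapply(layer_param_names(l), function(p) length(l[[p]]), 0L))
    data.frame(layer = nm, type = l$ptype, n_params = np)
  })
  tab <- do.call(rbind, rows)
  cat(sprintf("AbdomenNet: %d stages, %d filters, kernel %d, alpha %.2f\n",
              net$config$n_enc_dec, net$config$filters,
              net$config$kernel_size, net$config$alpha))
  cat(sprintf("%d layers, %d parameters\n", nrow(tab), sum(tab$n_params)))
  invisible(tab)
}

sgd_step <- function(net, lr, momentum = 0.9) {
  for (l in net$layers) {
    for (p in layer_param_names(l)) {
      g <- l[[paste0("g_", p)]]
      if (is.null(g)) next
      buf <- l[[paste0("v_", p)]]
      buf <- if (is.null(buf)) g else momentum * buf + g
      assign(paste0("v_", p), buf, envir = l)
      assign(p, l[[p]] - lr * buf, envir = l)
    }
  }
}

## ---- checkpoints ---------------------------------------------------------

#' Save network weights and config
#' @param net the network.
#' @param path output `.rds` path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path) {
  state <- list(config = net$config,
                weights = get_weights(net),
                bn_stats = bn_state(net))
  saveRDS(state, path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path `.rds` path.
#' @return a rebuilt network.
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  net <- build_abdomennet(state$config)
  set_weights(net, state$weights)
  restore_bn_state(net, state$bn_stats)
  net
}

bn_state <- function(net) {
  out <- list()
  for (nm in names(net$layers)) {
    l <- net$layers[[nm]]
    if (l$ptype == "bn")
      out[[nm]] <- list(rmean = l$rmean, rvar = l$rvar)
  }
  out
}

restore_bn_state <- function(net, state) {
  for (nm in names(state)) {
    l <- net$layers[[nm]]
    l$rmean <- state[[nm]]$rmean
    l$rvar <- state[[nm]]$rvar
  }
  invisible(net)
}

clone_network <- function(net) {
  copy <- build_abdomennet(net$config)
  set_weights(copy, get_weights(net))
  restore_bn_state(copy, bn_state(net))
  copy
}
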