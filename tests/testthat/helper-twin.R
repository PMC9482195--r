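# An independent plain-convolution forward pass sharing a network's
# weights: composes BN -> PReLU -> standard convolution, dense concat,
# CSSE, indexed pooling/unpooling and the classifier directly from the
# primitive kernels, bypassing the octave-convolution code path entirely.
# Used as the degeneracy oracle for alpha = 0 networks (eval mode).

twin_forward <- function(net, x) {
  ns <- asNamespace("abdomenseg")
  L <- net$layers
  eval_bn <- function(nm, v) {
    l <- L[[nm]]
    istd <- 1 / sqrt(l$rvar + l$eps)
    sweepv <- array(rep(l$gamma * istd, each = prod(dim(v)[1:2])),
                    dim(v))
    offv <- array(rep(l$beta - l$rmean * l$gamma * istd,
                      each = prod(dim(v)[1:2])), dim(v))
    v * sweepv + offv
  }
  eval_prelu <- function(nm, v) {
    l <- L[[nm]]
    av <- array(rep(l$a, each = prod(dim(v)[1:2])), dim(v))
    ifelse(v > 0, v, av * v)
  }
  eval_conv <- function(nm, v) ns$conv2d_fwd(v, L[[nm]]$w, L[[nm]]$b)
  eval_unit <- function(prefix, v) {
    v <- eval_bn(paste0(prefix, ".bn_h"), v)
    v <- eval_prelu(paste0(prefix, ".pr_h"), v)
    eval_conv(paste0(prefix, ".conv.hh"), v)
  }
  eval_dense <- function(prefix, v) {
    f1 <- eval_unit(paste0(prefix, ".u1"), v)
    f2 <- eval_unit(paste0(prefix, ".u2"), f1)
    cc <- array(0, c(dim(f1)[1:2], dim(f1)[3] + dim(f2)[3], dim(f1)[4]))
    cc[, , seq_len(dim(f1)[3]), ] <- f1
    cc[, , dim(f1)[3] + seq_len(dim(f2)[3]), ] <- f2
    eval_unit(paste0(prefix, ".u3"), cc)
  }
  eval_csse <- function(prefix, v) {
    fc <- L[[paste0(prefix, ".fc")]]
    d <- dim(v)
    out <- array(0, d)
    for (n in seq_len(d[4])) {
      z <- apply(v[, , , n, drop = FALSE], 3, mean)
      h <- pmax(t(fc$W1) %*% z + fc$b1, 0)
      s <- 1 / (1 + exp(-(t(fc$W2) %*% h + fc$b2)))
      q <- eval_conv(paste0(prefix, ".sconv"),
                     v[, , , n, drop = FALSE])[, , 1, 1]
      tg <- 1 / (1 + exp(-q))
      for (c in seq_len(d[3]))
        out[, , c, n] <- v[, , c, n] * s[c] + v[, , c, n] * tg
    }
    out
  }
  ne <- net$config$n_enc_dec
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  feat <- x
  skips <- idxs <- dims <- vector("list", ne)
  for (i in seq_len(ne)) {
    f <- eval_dense(sprintf("enc%d.db", i), feat)
    s <- eval_csse(sprintf("enc%d.cs_h", i), f)
    skips[[i]] <- s
    dims[[i]] <- dim(s)[1:2]
    r <- ns$maxpool2_fwd(s)
    idxs[[i]] <- r$idx
    feat <- r$y
  }
  feat <- eval_csse("bottleneck.cs_h", eval_dense("bottleneck.db", feat))
  for (i in ne:1) {
    up <- ns$maxunpool2(feat, idxs[[i]], dims[[i]][1], dims[[i]][2])
    cc <- array(0, c(dims[[i]], dim(up)[3] + dim(skips[[i]])[3],
                     dim(up)[4]))
    cc[, , seq_len(dim(up)[3]), ] <- up
    cc[, , dim(up)[3] + seq_len(dim(skips[[i]])[3]), ] <- skips[[i]]
    feat <- eval_csse(sprintf("dec%d.cs_h", i),
                      eval_dense(sprintf("dec%d.db", i), cc))
  }
  logits <- eval_conv("classifier", feat)
  d <- dim(logits)
  # per-pixel softmax over the class dimension
  p <- array(0, d)
  for (n in seq_len(d[4])) {
    z <- logits[, , , n]
    mx <- apply(z, c(1, 2), max)
    e <- exp(z - array(rep(mx, d[3]), dim(z)))
    p[, , , n] <- e / array(rep(apply(e, c(1, 2), sum), d[3]), dim(z))
  }
  p
}
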