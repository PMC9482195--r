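# internal helpers shared across modules

# run expr with a private RNG stream; restores the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_affine <- function(a) is.matrix(a) && all(dim(a) == c(4, 4))

# voxel spacing (mm per voxel step) from an axis-aligned affine
affine_spacing <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# mm coordinates of 0-based voxel indices (n x 3 matrix) under an affine
voxel_to_mm <- function(idx, affine) {
  idx <- rbind(t(idx), 1)
  t(affine %*% idx)[, 1:3, drop = FALSE]
}

# concatenate two (H, W, C, N) arrays along the channel axis
cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}
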