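# independent brute-force oracles shared across test files

# surfaces by exhaustive 6-neighbour scan (array boundary = background)
oracle_surface <- function(mask) {
  d <- dim(mask)
  out <- NULL
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!mask[i, j, k]) next
    nb <- c(i == 1 || !mask[i - 1, j, k], i == d[1] || !mask[i + 1, j, k],
            j == 1 || !mask[i, j - 1, k], j == d[2] || !mask[i, j + 1, k],
            k == 1 || !mask[i, j, k - 1], k == d[3] || !mask[i, j, k + 1])
    if (any(nb)) out <- rbind(out, c(i, j, k) - 1)
  }
  out
}

# all-pairs symmetric surface distance with direct (cancellation-free)
# per-pair differences
oracle_assd <- function(p, g, sp) {
  A <- sweep(oracle_surface(p), 2, sp, `*`)
  B <- sweep(oracle_surface(g), 2, sp, `*`)
  dab <- apply(A, 1, function(a)
    min(sqrt((B[, 1] - a[1])^2 + (B[, 2] - a[2])^2 + (B[, 3] - a[3])^2)))
  dba <- apply(B, 1, function(b)
    min(sqrt((A[, 1] - b[1])^2 + (A[, 2] - b[2])^2 + (A[, 3] - b[3])^2)))
  (sum(dab) + sum(dba)) / (nrow(A) + nrow(B))
}
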