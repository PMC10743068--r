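# Independent oracles and small factories shared across the test files.

# O(n^2) pairwise AUC with half-credit ties
auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# F1 from an explicit confusion table
f1_closed_form <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

# brute-force per-pixel axial max
mip_bruteforce <- function(v, zlo, zhi) {
  d <- dim(v)
  out <- matrix(-Inf, d[2], d[1])  # (PA, LR)
  for (x in seq_len(d[1])) for (y in seq_len(d[2]))
    out[y, x] <- max(v[x, y, (zlo + 1):(zhi + 1)])
  out
}

# symbolic output-shape propagation for conv/pool stacks
shape_conv <- function(sp, k, s, p) (sp + 2 * p - k) %/% s + 1

# small random volume helper
rand_volume <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  volume3d(array(stats::rnorm(prod(d)), d))
}

# make a mirror-symmetric volume
symmetric_volume <- function(d, seed = 1) {
  set.seed(seed)
  a <- array(stats::rnorm(prod(d)), d)
  volume3d((a + a[d[1]:1, , , drop = FALSE]) / 2)
}

# a tiny 2D image batch helper
rand_image <- function(nr, nc, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  image2d(matrix(stats::rnorm(nr * nc), nr, nc))
}
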