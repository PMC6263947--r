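# Independent brute-force oracles and small shared fixtures.

# True 2D convolution, zero-padded to 'same' size, as an explicit double loop.
conv2_oracle <- function(x, kern) {
  m <- nrow(x); n <- ncol(x)
  k1 <- nrow(kern); k2 <- ncol(kern)
  p1 <- (k1 - 1) / 2; p2 <- (k2 - 1) / 2
  at <- function(i, j) if (i >= 1 && i <= m && j >= 1 && j <= n) x[i, j] else 0
  y <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    acc <- 0
    for (u in seq_len(k1)) for (v in seq_len(k2))
      acc <- acc + kern[u, v] * at(i - u + p1 + 1, j - v + p2 + 1)
    y[i, j] <- acc
  }
  y
}

# Patch matrix by explicit loops (zero padding, column-major patches/pixels).
patches_oracle <- function(x, k1, k2) {
  m <- nrow(x); n <- ncol(x)
  p1 <- (k1 - 1) / 2; p2 <- (k2 - 1) / 2
  at <- function(i, j) if (i >= 1 && i <= m && j >= 1 && j <= n) x[i, j] else 0
  out <- matrix(0, k1 * k2, m * n)
  col <- 0
  for (j in seq_len(n)) for (i in seq_len(m)) {
    col <- col + 1
    r <- 0
    for (v in seq_len(k2)) for (u in seq_len(k1)) {
      r <- r + 1
      out[r, col] <- at(i + u - 1 - p1, j + v - 1 - p2)
    }
  }
  out
}

# Top-L eigenvectors of the pooled mean-removed patch scatter via SVD of the
# pooled matrix itself (a route independent of eigen() on the scatter).
filters_oracle <- function(images, k1, k2, L) {
  pooled <- do.call(cbind, lapply(images, function(im) {
    X <- patches_oracle(im, k1, k2)
    sweep(X, 2, colMeans(X))
  }))
  sv <- svd(pooled, nu = L, nv = 0)
  list(vectors = sv$u, values = sv$d[seq_len(L)]^2)
}

# Exhaustive count of fully-contained block positions on the stride grid.
count_blocks_oracle <- function(rows, cols, h1, h2, s1, s2) {
  length(seq(1, rows - h1 + 1, by = s1)) *
    length(seq(1, cols - h2 + 1, by = s2))
}

abs_cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# A tiny clean cohort reused by several tests.
tiny_cohort <- function(n_subjects = 3, records = 4, seed = 1,
                        noise = noise_spec(0, 0, 0, 0, 0), fs = 500,
                        rr_jitter_sd = 0) {
  generate_cohort(n_subjects, records, duration = 10, fs = fs, noise = noise,
                  seed = seed, rr_jitter_sd = rr_jitter_sd)
}

random_images <- function(n, m, nn, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix(rnorm(m * nn), m, nn))
}
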