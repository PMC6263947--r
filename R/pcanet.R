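#' Two-stage PCA filter-bank network
#'
#' Feature learning without backpropagation: the convolution kernels of each
#' stage are the leading eigenvectors of the scatter matrix of mean-removed
#' local image patches. Stage 1 learns `L1` kernels from all training images;
#' every image is convolved with each kernel (zero-padded, output same size);
#' stage 2 learns a shared bank of `L2` kernels from the patches of all
#' `N * L1` stage-1 maps and is applied to each map. The `L2` stage-2 outputs
#' of one stage-1 channel are Heaviside-binarized and collapsed into one
#' integer-valued image with weights `2^(l-1)`; overlapping blocks of that
#' image are summarized by `2^L2`-bin count histograms, concatenated over
#' blocks and channels into the final feature vector of length
#' `2^L2 * L1 * B`.
#'
#' @name pcanet
NULL

#' Filter-bank network parameters
#'
#' @param k1,k2 Patch (kernel) dimensions; odd integers with
#'   `1 <= k1 <= m`, `1 <= k2 <= n`.
#' @param L1,L2 Number of filters per stage; `1 <= L <= k1 * k2`.
#' @param h1,h2 Histogram block dimensions.
#' @param R Block overlap ratio, one of 0, 0.1, ..., 0.9. The block stride is
#'   `round((1 - R) * h)` (half-up, floored at 1), so larger `R` gives more,
#'   more overlapping blocks.
#' @param pad_before_blocks If `TRUE` (default) the integer-coded image is
#'   zero-padded by `(k - 1)/2` per side before block sliding, so the block
#'   count is taken over an `(m + k1 - 1) x (n + k2 - 1)` grid.
#' @return A validated list of class `pcanet_params`.
#' @examples
#' pcanet_params()                 # defaults: k = 7, L = 8, h = 7, R = 0.5
#' @export
pcanet_params <- function(k1 = 7, k2 = 7, L1 = 8, L2 = 8,
                          h1 = 7, h2 = 7, R = 0.5,
                          pad_before_blocks = TRUE) {
  p <- list(k1 = as.integer(k1), k2 = as.integer(k2),
            L1 = as.integer(L1), L2 = as.integer(L2),
            h1 = as.integer(h1), h2 = as.integer(h2),
            R = R, pad_before_blocks = isTRUE(pad_before_blocks))
  if (p$k1 < 1 || p$k2 < 1 || p$k1 %% 2 == 0 || p$k2 %% 2 == 0)
    abort("k1 and k2 must be odd integers >= 1")
  if (p$L1 < 1 || p$L1 > p$k1 * p$k2 || p$L2 < 1 || p$L2 > p$k1 * p$k2)
    abort("filter counts must satisfy 1 <= L <= k1 * k2")
  if (p$h1 < 1 || p$h2 < 1) abort("block dims must be >= 1")
  if (!any(abs(R - seq(0, 0.9, 0.1)) < 1e-9))
    abort("R must be one of 0, 0.1, ..., 0.9")
  structure(p, class = "pcanet_params")
}

check_dims <- function(params, m, n) {
  if (params$k1 > m || params$k2 > n)
    abort("patch size exceeds image size")
  bm <- if (params$pad_before_blocks) m + params$k1 - 1L else m
  bn <- if (params$pad_before_blocks) n + params$k2 - 1L else n
  if (params$h1 > bm || params$h2 > bn)
    abort("block size exceeds (padded) image size")
  invisible(TRUE)
}

# k1*k2 x m*n linear-index matrix into the zero-padded image; patch entries
# column-major within the patch, pixel positions column-major over the image.
patch_index <- function(m, n, k1, k2) {
  pm <- m + k1 - 1L
  base <- as.vector(outer(seq_len(k1), (seq_len(k2) - 1L) * pm, `+`))
  off <- as.vector(outer(seq_len(m) - 1L, (seq_len(n) - 1L) * pm, `+`))
  outer(base, off, `+`)
}

pad_matrix <- function(x, p1, p2) {
  if (p1 == 0 && p2 == 0) return(x)
  out <- matrix(0, nrow(x) + 2 * p1, ncol(x) + 2 * p2)
  out[p1 + seq_len(nrow(x)), p2 + seq_len(ncol(x))] <- x
  out
}

#' Extract the mean-intact patch matrix of an image
#'
#' The image is zero-padded by `(k - 1)/2` per side; one `k1 x k2` patch is
#' taken per original pixel position and vectorized column-major, giving a
#' `k1*k2 x m*n` matrix (pixel positions in column-major order).
#'
#' @param image Numeric `m x n` matrix.
#' @param k1,k2 Odd patch dimensions.
#' @return Matrix with `k1*k2` rows and `m*n` columns.
#' @export
extract_patch_matrix <- function(image, k1, k2) {
  if (k1 %% 2 == 0 || k2 %% 2 == 0) abort("k1 and k2 must be odd")
  m <- nrow(image); n <- ncol(image)
  if (k1 > m || k2 > n) abort("patch size exceeds image size")
  padded <- pad_matrix(image, (k1 - 1L) %/% 2L, (k2 - 1L) %/% 2L)
  idx <- patch_index(m, n, as.integer(k1), as.integer(k2))
  matrix(padded[idx], nrow = k1 * k2, ncol = m * n)
}

#' Subtract each patch's own mean
#'
#' @param X Patch matrix (patches as columns).
#' @return Matrix of the same shape; every column sums to zero.
#' @export
remove_patch_mean <- function(X) {
  sweep(X, 2, colMeans(X))
}

filters_from_scatter <- function(S, L, k1, k2, stage = NA_integer_) {
  if (L < 1 || L > k1 * k2) abort("L out of range: need 1 <= L <= k1 * k2")
  if (max(abs(S)) == 0)
    abort("degenerate input: patch scatter matrix is zero (constant images)")
  ee <- eigen(S, symmetric = TRUE)       # eigenvalues already descending
  filters <- lapply(seq_len(L), function(l) {
    v <- ee$vectors[, l]
    j <- which.max(abs(v))               # pin sign: largest coefficient > 0
    if (v[j] < 0) v <- -v
    matrix(v, k1, k2)                    # column-major, mirroring patch order
  })
  structure(list(filters = filters,
                 eigenvalues = ee$values[seq_len(L)],
                 k1 = as.integer(k1), k2 = as.integer(k2),
                 stage = stage),
            class = "pca_filter_bank")
}

#' Learn PCA filters from a mean-removed patch matrix
#'
#' The filters are the top-`L` eigenvectors of `Xbar %*% t(Xbar)` reshaped to
#' `k1 x k2` (inverting the column-major patch vectorization). Each filter's
#' sign is fixed so its largest-magnitude coefficient is positive, which makes
#' the bank deterministic across linear-algebra backends.
#'
#' @param Xbar Mean-removed patch matrix (`k1*k2` rows).
#' @param L Number of filters, `1 <= L <= k1 * k2`.
#' @param k1,k2 Patch dimensions.
#' @return A `pca_filter_bank`: list of `L` `k1 x k2` kernels with their
#'   descending eigenvalues (patch-scatter variances).
#' @export
learn_pca_filters <- function(Xbar, L, k1, k2) {
  stopifnot(nrow(Xbar) == k1 * k2)
  filters_from_scatter(tcrossprod(Xbar), L, k1, k2)
}

#' @export
print.pca_filter_bank <- function(x, ...) {
  cat(sprintf("<pca_filter_bank> %d filters of %d x %d%s\n",
              length(x$filters), x$k1, x$k2,
              if (!is.na(x$stage)) paste0(" (stage ", x$stage, ")") else ""))
  invisible(x)
}

# rows: flipped, vectorized kernels so that W %*% patch_matrix performs true
# 2D convolution (kernel flipped) with zero padding, output same size.
bank_matrix <- function(bank) {
  do.call(rbind, lapply(bank$filters, function(w) rev(as.vector(w))))
}

#' Convolve an image with every filter of a bank
#'
#' True 2D convolution (kernel flipped), zero-padded so each output has the
#' input's dimensions.
#'
#' @param image Numeric matrix.
#' @param bank A `pca_filter_bank`.
#' @return List of `length(bank$filters)` matrices, each `dim(image)`.
#' @export
convolve_bank <- function(image, bank) {
  m <- nrow(image); n <- ncol(image)
  X <- extract_patch_matrix(image, bank$k1, bank$k2)
  M <- bank_matrix(bank) %*% X
  lapply(seq_len(nrow(M)), function(l) matrix(M[l, ], m, n))
}

#' Fit the two-stage filter-bank network
#'
#' Stage 1 pools mean-removed patches over all training images and keeps the
#' top `L1` eigenvectors of their scatter; stage 2 pools the patches of all
#' `N * L1` stage-1 convolution maps and keeps the top `L2` (one shared bank
#' applied to every channel). Scatter matrices are accumulated image by image,
#' so memory stays at `O(k1^2 k2^2)` regardless of cohort size.
#'
#' @param images List of equal-dimension numeric matrices (beat images).
#' @param params A [pcanet_params()] object.
#' @return An `eecgnet` model: `params`, `stage1` and `stage2` filter banks,
#'   and `image_dims`.
#' @examples
#' imgs <- lapply(1:5, function(i) matrix(rnorm(64), 8, 8))
#' fit <- eecgnet_fit(imgs, pcanet_params(k1 = 3, k2 = 3, L1 = 4, L2 = 4,
#'                                        h1 = 4, h2 = 4))
#' fit
#' @export
eecgnet_fit <- function(images, params = pcanet_params()) {
  if (!length(images)) abort("need at least one training image")
  dims <- dim(images[[1]])
  if (!all(vapply(images, function(x) identical(dim(x), dims), TRUE)))
    abort("all training images must share dimensions")
  m <- dims[1]; n <- dims[2]
  check_dims(params, m, n)
  if (all(vapply(images, function(x) max(x) == min(x), TRUE)))
    abort("degenerate input: all training images are constant")
  k1 <- params$k1; k2 <- params$k2

  S1 <- matrix(0, k1 * k2, k1 * k2)
  for (img in images) {
    X <- remove_patch_mean(extract_patch_matrix(img, k1, k2))
    S1 <- S1 + tcrossprod(X)
  }
  stage1 <- filters_from_scatter(S1, params$L1, k1, k2, stage = 1L)

  W1 <- bank_matrix(stage1)
  S2 <- matrix(0, k1 * k2, k1 * k2)
  for (img in images) {
    X <- extract_patch_matrix(img, k1, k2)
    maps <- W1 %*% X                       # L1 x (m*n), each row one map
    for (l in seq_len(params$L1)) {
      Y <- remove_patch_mean(
        extract_patch_matrix(matrix(maps[l, ], m, n), k1, k2))
      S2 <- S2 + tcrossprod(Y)
    }
  }
  stage2 <- filters_from_scatter(S2, params$L2, k1, k2, stage = 2L)

  structure(list(params = params, stage1 = stage1, stage2 = stage2,
                 image_dims = c(m = m, n = n)),
            class = "eecgnet")
}

#' Collapse binarized stage-2 maps into one integer-coded image
#'
#' Applies the Heaviside step (1 for strictly positive entries, 0 otherwise)
#' to each of the `L2` maps of one stage-1 channel and sums them with weights
#' `2^(l-1)`, yielding values in `0 .. 2^L2 - 1`.
#'
#' @param maps List of `L2` equal-dimension numeric matrices.
#' @param L2 Expected number of maps.
#' @return Integer-valued matrix, same dimensions as the maps.
#' @export
binarize_and_encode <- function(maps, L2) {
  if (length(maps) != L2)
    abort(sprintf("expected %d maps, got %d", L2, length(maps)))
  out <- matrix(0, nrow(maps[[1]]), ncol(maps[[1]]))
  for (l in seq_len(L2)) out <- out + 2^(l - 1) * (maps[[l]] > 0)
  out
}

#' Block stride from the overlap ratio
#'
#' `stride = round((1 - R) * h)` with half-up rounding, floored at 1.
#'
#' @param h1,h2 Block dimensions.
#' @param R Overlap ratio in 0, 0.1, ..., 0.9.
#' @return Integer vector `c(stride1, stride2)`.
#' @examples
#' compute_strides(7, 7, 0.5)   # 4 4
#' @export
compute_strides <- function(h1, h2, R) {
  s <- pmax(1L, as.integer(floor((1 - R) * c(h1, h2) + 0.5)))
  c(stride1 = s[1], stride2 = s[2])
}

#' Number of sliding blocks on a stride grid
#'
#' Counts fully contained `h1 x h2` block positions:
#' `B = (1 + floor((rows - h1)/stride1)) * (1 + floor((cols - h2)/stride2))`.
#'
#' @param rows,cols Image dimensions the blocks slide over.
#' @param h1,h2 Block dimensions.
#' @param stride1,stride2 Steps between block origins.
#' @return Integer block count.
#' @export
count_blocks <- function(rows, cols, h1, h2, stride1, stride2) {
  if (h1 > rows || h2 > cols) abort("block larger than image")
  unname((1L + (rows - h1) %/% stride1) * (1L + (cols - h2) %/% stride2))
}

#' Extract sliding blocks of an integer-coded image
#'
#' Blocks are taken at every stride-grid position fully inside the image
#' (column-major over grid positions) and vectorized column-major.
#'
#' @param T_img Numeric/integer matrix (the integer-coded image).
#' @param params A [pcanet_params()]; `h1`, `h2` and `R` are used.
#' @return List with `blocks` (`h1*h2 x B` matrix), `B`, and `strides`.
#' @export
slide_blocks <- function(T_img, params) {
  h1 <- params$h1; h2 <- params$h2
  rows <- nrow(T_img); cols <- ncol(T_img)
  if (h1 > rows || h2 > cols) abort("block larger than image")
  s <- compute_strides(h1, h2, params$R)
  r0 <- seq(1L, rows - h1 + 1L, by = s[1])
  c0 <- seq(1L, cols - h2 + 1L, by = s[2])
  base <- as.vector(outer(seq_len(h1), (seq_len(h2) - 1L) * rows, `+`))
  off <- as.vector(outer(r0 - 1L, (c0 - 1L) * rows, `+`))
  blocks <- matrix(T_img[outer(base, off, `+`)],
                   nrow = h1 * h2, ncol = length(off))
  stopifnot(ncol(blocks) ==
              count_blocks(rows, cols, h1, h2, s[1], s[2]))
  list(blocks = blocks, B = ncol(blocks), strides = s)
}

#' Block-wise count histograms of integer codes
#'
#' One `2^L2`-bin histogram (bins `0 .. 2^L2 - 1`) per block, concatenated
#' block-major. Histograms are raw counts, so each block contributes exactly
#' `h1 * h2`.
#'
#' @param blocks `h1*h2 x B` matrix of integer codes (e.g. from
#'   [slide_blocks()]).
#' @param L2 Number of binary maps that produced the codes.
#' @return Numeric vector of length `2^L2 * B`.
#' @export
block_histograms <- function(blocks, L2) {
  nb <- as.integer(2^L2)
  if (any(blocks < 0) || any(blocks > nb - 1))
    abort("block values out of range [0, 2^L2 - 1]")
  as.vector(vapply(seq_len(ncol(blocks)),
                   function(j) tabulate(blocks[, j] + 1L, nbins = nb),
                   numeric(nb)))
}

#' Map beat images to block-histogram features
#'
#' Runs the fitted network forward: stage-1 convolutions, stage-2
#' convolutions, Heaviside binarization and integer coding per stage-1
#' channel, optional zero-padding of the coded image, block sliding, and
#' block histograms concatenated over the `L1` channels.
#'
#' @param model An `eecgnet` model from [eecgnet_fit()].
#' @param images List of matrices with the model's image dimensions.
#' @return Numeric feature matrix, one row per image, `2^L2 * L1 * B`
#'   columns; attribute `B` holds the block count.
#' @export
eecgnet_transform <- function(model, images) {
  stopifnot(inherits(model, "eecgnet"))
  p <- model$params
  m <- model$image_dims[["m"]]; n <- model$image_dims[["n"]]
  if (!all(vapply(images, function(x) identical(dim(x), c(m, n)), TRUE)))
    abort("image dimensions do not match the fitted model")
  W1 <- bank_matrix(model$stage1)
  W2 <- bank_matrix(model$stage2)
  weights <- 2^(seq_len(p$L2) - 1)
  pb1 <- if (p$pad_before_blocks) (p$k1 - 1L) %/% 2L else 0L
  pb2 <- if (p$pad_before_blocks) (p$k2 - 1L) %/% 2L else 0L

  feats <- NULL
  B <- NULL
  for (i in seq_along(images)) {
    X <- extract_patch_matrix(images[[i]], p$k1, p$k2)
    maps1 <- W1 %*% X
    per_channel <- vector("list", p$L1)
    for (l in seq_len(p$L1)) {
      Xl <- extract_patch_matrix(matrix(maps1[l, ], m, n), p$k1, p$k2)
      codes <- as.vector(weights %*% ((W2 %*% Xl) > 0))
      T_img <- pad_matrix(matrix(codes, m, n), pb1, pb2)
      sl <- slide_blocks(T_img, p)
      per_channel[[l]] <- block_histograms(sl$blocks, p$L2)
      if (is.null(B)) B <- sl$B
    }
    f <- unlist(per_channel, use.names = FALSE)
    if (is.null(feats)) feats <- matrix(0, length(images), length(f))
    feats[i, ] <- f
  }
  attr(feats, "B") <- B
  feats
}
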