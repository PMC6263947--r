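test_that("parameter validation enforces the documented constraints", {
  expect_s3_class(pcanet_params(), "pcanet_params")
  expect_error(pcanet_params(k1 = 4), "odd")
  expect_error(pcanet_params(L1 = 50), "filter counts")   # 50 > 7 * 7
  expect_error(pcanet_params(R = 0.55), "0.1")
  expect_error(pcanet_params(h1 = 0), "block")
})

test_that("patch extraction matches the explicit-loop oracle", {
  # 3x3 image with k = 3: the center column is the vectorized image and the
  # corner patch carries zeros at all out-of-range entries
  img <- matrix(1:9, 3, 3)
  X <- extract_patch_matrix(img, 3, 3)
  expect_equal(dim(X), c(9, 9))
  expect_equal(X[, 5], as.numeric(img))
  corner <- X[, 1]
  expect_equal(corner[c(1, 2, 3, 4, 7)], rep(0, 5))

  for (case in list(c(5, 7, 3, 3), c(8, 8, 3, 5), c(6, 6, 5, 5))) {
    m <- case[1]; n <- case[2]; k1 <- case[3]; k2 <- case[4]
    set.seed(m * 100 + k1)
    x <- matrix(rnorm(m * n), m, n)
    expect_equal(extract_patch_matrix(x, k1, k2), patches_oracle(x, k1, k2))
  }
  expect_error(extract_patch_matrix(img, 2, 3), "odd")
})

test_that("patch-mean removal zeroes every column mean", {
  expect_equal(remove_patch_mean(matrix(c(1, 2, 3), 3, 1)),
               matrix(c(-1, 0, 1), 3, 1))
  expect_equal(remove_patch_mean(matrix(5, 4, 3)), matrix(0, 4, 3))
  set.seed(1)
  X <- matrix(rnorm(9 * 40), 9, 40)
  expect_true(all(abs(colSums(remove_patch_mean(X))) < 1e-9))
})

test_that("learned filters solve the eigenproblem", {
  # diagonal scatter: filters are canonical basis vectors
  Xbar <- diag(c(sqrt(8), sqrt(2), rep(0, 7)))
  bank <- learn_pca_filters(Xbar, 2, 3, 3)
  expect_equal(as.vector(bank$filters[[1]]), c(1, rep(0, 8)))
  expect_equal(as.vector(bank$filters[[2]]), c(0, 1, rep(0, 7)))
  expect_equal(bank$eigenvalues, c(8, 2))

  # random case against the SVD oracle
  set.seed(7)
  Xr <- matrix(rnorm(9 * 200), 9, 200)
  Xr <- remove_patch_mean(Xr)
  bank <- learn_pca_filters(Xr, 4, 3, 3)
  sv <- svd(Xr, nu = 4, nv = 0)
  for (l in 1:4)
    expect_gte(abs_cosine(as.vector(bank$filters[[l]]), sv$u[, l]), 1 - 1e-8)
  expect_equal(bank$eigenvalues, sv$d[1:4]^2, tolerance = 1e-8)

  # complete basis: projection reconstructs exactly
  full <- learn_pca_filters(Xr, 9, 3, 3)
  V <- vapply(full$filters, as.vector, numeric(9))
  expect_equal(V %*% crossprod(V, Xr), Xr, tolerance = 1e-8)
  expect_equal(crossprod(V), diag(9), tolerance = 1e-8)

  expect_error(learn_pca_filters(Xr, 10, 3, 3), "range")
  expect_error(learn_pca_filters(matrix(0, 9, 20), 2, 3, 3), "degenerate")
})

test_that("bank convolution is true zero-padded convolution", {
  # delta kernel reproduces the image
  delta <- matrix(0, 3, 3); delta[2, 2] <- 1
  bank <- structure(list(filters = list(delta), eigenvalues = 1,
                         k1 = 3L, k2 = 3L, stage = NA),
                    class = "pca_filter_bank")
  img <- matrix(rnorm(48), 6, 8)
  expect_equal(convolve_bank(img, bank)[[1]], img)

  # all-ones kernel on an all-ones image sums to 9 away from the borders
  ones <- structure(list(filters = list(matrix(1, 3, 3)), eigenvalues = 1,
                         k1 = 3L, k2 = 3L, stage = NA),
                    class = "pca_filter_bank")
  out <- convolve_bank(matrix(1, 5, 5), ones)[[1]]
  expect_equal(out[2:4, 2:4], matrix(9, 3, 3))

  # random image and kernel against the double-loop oracle
  set.seed(11)
  x <- matrix(rnorm(64), 8, 8)
  kern <- matrix(rnorm(9), 3, 3)
  rb <- structure(list(filters = list(kern), eigenvalues = 1,
                       k1 = 3L, k2 = 3L, stage = NA),
                  class = "pca_filter_bank")
  expect_equal(convolve_bank(x, rb)[[1]], conv2_oracle(x, kern),
               tolerance = 1e-10)
})

test_that("fitting is deterministic and rejects degenerate input", {
  imgs <- random_images(6, 8, 8, seed = 2)
  params <- pcanet_params(k1 = 3, k2 = 3, L1 = 4, L2 = 4, h1 = 4, h2 = 4)
  f1 <- eecgnet_fit(imgs, params)
  f2 <- eecgnet_fit(imgs, params)
  expect_identical(f1, f2)
  expect_error(eecgnet_fit(list(), params), "at least one")
  expect_error(eecgnet_fit(list(matrix(1, 8, 8)), params), "degenerate")
})

test_that("filter banks are orthonormal with descending eigenvalues", {
  imgs <- random_images(8, 10, 10, seed = 5)
  fit <- eecgnet_fit(imgs, pcanet_params(k1 = 5, k2 = 5, L1 = 6, L2 = 6,
                                         h1 = 5, h2 = 5))
  for (bank in list(fit$stage1, fit$stage2)) {
    V <- vapply(bank$filters, as.vector, numeric(25))
    expect_equal(crossprod(V), diag(length(bank$filters)), tolerance = 1e-8)
    expect_true(all(diff(bank$eigenvalues) <= 1e-8))
  }
  # variance captured by filter l equals eigenvalue l on the training patches
  pooled <- do.call(cbind, lapply(imgs, function(im)
    remove_patch_mean(extract_patch_matrix(im, 5, 5))))
  V1 <- vapply(fit$stage1$filters, as.vector, numeric(25))
  proj_var <- rowSums((crossprod(V1, pooled))^2)
  expect_equal(proj_var, fit$stage1$eigenvalues,
               tolerance = 1e-8 * max(proj_var))
})

test_that("binary encoding follows the 2^(l-1) Heaviside weighting", {
  pos <- lapply(1:3, function(i) matrix(1, 4, 4))
  expect_equal(binarize_and_encode(pos, 3), matrix(7, 4, 4))
  nonpos <- lapply(1:3, function(i) matrix(c(0, -1), 4, 4))
  expect_equal(binarize_and_encode(nonpos, 3), matrix(0, 4, 4))
  mixed <- list(matrix(1, 2, 2), matrix(-1, 2, 2), matrix(1, 2, 2))
  expect_equal(binarize_and_encode(mixed, 3), matrix(5, 2, 2))
  expect_error(binarize_and_encode(mixed, 4), "expected 4")
})

test_that("strides and block counts match the printed arithmetic", {
  expect_equal(unname(compute_strides(7, 7, 0.5)), c(4, 4))
  expect_equal(unname(compute_strides(7, 7, 0.0)), c(7, 7))
  expect_equal(unname(compute_strides(7, 7, 0.9)), c(1, 1))

  expect_equal(count_blocks(5, 5, 5, 5, 1, 1), 1)
  expect_equal(count_blocks(34, 34, 7, 7, 4, 4), 49)
  # more overlap, more blocks
  expect_equal(count_blocks(34, 34, 7, 7, 3, 3), 100)
  expect_error(count_blocks(5, 5, 7, 7, 1, 1), "larger")
})

test_that("block sliding emits exactly the fitting blocks", {
  params <- pcanet_params(h1 = 7, h2 = 7, R = 0.5)
  set.seed(9)
  T_img <- matrix(sample(0:255, 34 * 34, TRUE), 34, 34)
  sl <- slide_blocks(T_img, params)
  expect_equal(sl$B, 49)
  expect_equal(dim(sl$blocks), c(49, 49))
  expect_true(all(sl$blocks %in% T_img))
  # block dims equal to the image: a single vectorized block
  pfull <- pcanet_params(h1 = 34, h2 = 34, R = 0.5)
  expect_equal(slide_blocks(T_img, pfull)$blocks[, 1], as.vector(T_img))
})

test_that("block histograms count codes and conserve mass", {
  blocks <- matrix(3, 16, 2)
  hh <- block_histograms(blocks, 3)
  expect_length(hh, 8 * 2)
  expect_equal(hh[4], 16)   # bin for code 3 in block 1
  expect_equal(sum(hh), 2 * 16)

  set.seed(4)
  rb <- matrix(sample(0:15, 25 * 10, TRUE), 25, 10)
  h2 <- block_histograms(rb, 4)
  expect_equal(colSums(matrix(h2, 16)), rep(25, 10))
  expect_error(block_histograms(matrix(16, 4, 1), 4), "range")
})

test_that("transform yields the promised length, conservation and determinism", {
  imgs <- random_images(6, 28, 28, seed = 13)
  fit <- eecgnet_fit(imgs, pcanet_params())
  F1 <- eecgnet_transform(fit, imgs)
  expect_equal(ncol(F1), 2^8 * 8 * 49)
  expect_equal(attr(F1, "B"), 49)
  expect_true(all(F1 >= 0 & F1 == round(F1)))
  expect_true(all(rowSums(F1) == 8 * 49 * 49))
  expect_identical(F1, eecgnet_transform(fit, imgs))
  expect_error(eecgnet_transform(fit, random_images(1, 10, 10)), "dimensions")
})
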