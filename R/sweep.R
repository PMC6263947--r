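#' Sweep network parameters over a grid
#'
#' For every grid point `(h, k, L, R)` (with `h1 = h2 = h`, `k1 = k2 = k`,
#' `L1 = L2 = L`) the network is fitted on the training split, both splits
#' are transformed, the linear classifier is trained, and the test
#' identification accuracy is recorded. Infeasible points (even `k`,
#' `L > k^2`, patch or block larger than the image) are kept in the result
#' with `NA` accuracy and the reason in `note`.
#'
#' @param preprocessed A preprocessed cohort tibble ([preprocess_cohort()])
#'   with `beat`, `split`, `subject_id` columns.
#' @param m,n Beat-image dimensions (`m * n` = beat length).
#' @param h,k,L,R Vectors defining the grid.
#' @param C Classifier regularization.
#' @param pad_before_blocks Passed to [pcanet_params()].
#' @param verbose Log each grid point with [message()].
#' @return A tibble of class `eecgnet_sweep`: columns `h`, `k`, `L`, `R`,
#'   `accuracy` (percent), `B`, `note`.
#' @export
sweep_eecgnet <- function(preprocessed, m, n,
                          h = c(6, 8), k = c(3, 5, 7), L = c(3, 5, 8),
                          R = c(0.5, 0.6), C = 1.0,
                          pad_before_blocks = TRUE, verbose = FALSE) {
  grid <- expand.grid(h = h, k = k, L = L, R = R,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!nrow(grid)) abort("empty parameter grid")
  train <- dplyr::filter(preprocessed, .data$split == "train")
  test <- dplyr::filter(preprocessed, .data$split == "test")
  imgs_train <- cohort_images(train, m, n)
  imgs_test <- cohort_images(test, m, n)

  one <- function(h, k, L, R) {
    reason <- feasibility_note(h, k, L, m, n, pad_before_blocks)
    if (!is.na(reason)) {
      if (verbose) message(sprintf("skip h=%g k=%g L=%g R=%g: %s",
                                   h, k, L, R, reason))
      return(tibble::tibble(h = h, k = k, L = L, R = R,
                            accuracy = NA_real_, B = NA_integer_,
                            note = reason))
    }
    params <- pcanet_params(k1 = k, k2 = k, L1 = L, L2 = L, h1 = h, h2 = h,
                            R = R, pad_before_blocks = pad_before_blocks)
    fit <- eecgnet_fit(imgs_train, params)
    ftr <- eecgnet_transform(fit, imgs_train)
    fte <- eecgnet_transform(fit, imgs_test)
    clf <- train_classifier(ftr, train$subject_id, C = C)
    acc <- accuracy(predict(clf, fte), test$subject_id)
    if (verbose) message(sprintf("h=%g k=%g L=%g R=%g: acc %.2f%%",
                                 h, k, L, R, acc))
    tibble::tibble(h = h, k = k, L = L, R = R, accuracy = acc,
                   B = attr(ftr, "B"), note = NA_character_)
  }
  out <- purrr::pmap_dfr(grid, one)
  class(out) <- c("eecgnet_sweep", class(out))
  out
}

feasibility_note <- function(h, k, L, m, n, pad_before_blocks) {
  if (k %% 2 == 0) return("k must be odd")
  if (k > min(m, n)) return("patch larger than image")
  if (L > k * k) return(sprintf("L = %g exceeds k^2 = %g", L, k * k))
  bm <- if (pad_before_blocks) m + k - 1 else m
  bn <- if (pad_before_blocks) n + k - 1 else n
  if (h > min(bm, bn)) return("block larger than (padded) image")
  NA_character_
}

#' Plot a parameter sweep
#'
#' @param object An `eecgnet_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot of accuracy against the filter count `L`, colored by
#'   patch size `k`, faceted by block size `h` and overlap `R`.
#' @export
autoplot.eecgnet_sweep <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$accuracy))
  ggplot2::ggplot(df, ggplot2::aes(.data$L, .data$accuracy,
                                   colour = factor(.data$k))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(h ~ R, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "filters per stage (L)", y = "test accuracy (%)",
                  colour = "patch size k")
}
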