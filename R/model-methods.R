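#' @export
print.eecgnet <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<eecgnet> %d x %d images; stage 1: %d filters %d x %d;",
                     " stage 2: %d filters; blocks %d x %d, R = %.1f\n"),
              x$image_dims[["m"]], x$image_dims[["n"]],
              p$L1, p$k1, p$k2, p$L2, p$h1, p$h2, p$R))
  invisible(x)
}

#' Tidy a fitted filter-bank network
#'
#' @param x An `eecgnet` model.
#' @param ... Unused.
#' @return A tibble with one row per filter: `stage`, `filter`,
#'   `eigenvalue`, and `variance_share` (eigenvalue over the stage's kept
#'   total).
#' @export
tidy.eecgnet <- function(x, ...) {
  one <- function(bank, stage) {
    ev <- bank$eigenvalues
    tibble::tibble(stage = stage, filter = seq_along(ev), eigenvalue = ev,
                   variance_share = ev / sum(ev))
  }
  dplyr::bind_rows(one(x$stage1, 1L), one(x$stage2, 2L))
}

#' One-row summary of a fitted network
#'
#' @param x An `eecgnet` model.
#' @param ... Unused.
#' @return A tibble with image dims, parameter values, and the feature
#'   length implied by the block grid.
#' @export
glance.eecgnet <- function(x, ...) {
  p <- x$params
  m <- x$image_dims[["m"]]; n <- x$image_dims[["n"]]
  bm <- if (p$pad_before_blocks) m + p$k1 - 1L else m
  bn <- if (p$pad_before_blocks) n + p$k2 - 1L else n
  s <- compute_strides(p$h1, p$h2, p$R)
  B <- count_blocks(bm, bn, p$h1, p$h2, s[1], s[2])
  tibble::tibble(m = m, n = n, k1 = p$k1, k2 = p$k2, L1 = p$L1, L2 = p$L2,
                 h1 = p$h1, h2 = p$h2, R = p$R, B = B,
                 feature_length = 2^p$L2 * p$L1 * B)
}

#' Plot the learned filter banks
#'
#' @param object An `eecgnet` model.
#' @param ... Unused.
#' @return A ggplot raster of every kernel, faceted by stage and filter
#'   index.
#' @export
autoplot.eecgnet <- function(object, ...) {
  one <- function(bank, stage) {
    purrr::map_dfr(seq_along(bank$filters), function(l) {
      w <- bank$filters[[l]]
      tibble::tibble(stage = paste("stage", stage), filter = l,
                     row = rep(seq_len(nrow(w)), ncol(w)),
                     col = rep(seq_len(ncol(w)), each = nrow(w)),
                     weight = as.vector(w))
    })
  }
  df <- dplyr::bind_rows(one(object$stage1, 1), one(object$stage2, 2))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_grid(stage ~ filter) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL, fill = "weight") +
    ggplot2::theme_minimal()
}
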