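#' Classifier head and baselines
#'
#' The block-histogram features go to a multi-class linear max-margin
#' classifier (SVM). Baselines for comparison operate on the averaged-beat
#' vectors directly: an eigen-PCA projection followed by the same classifier,
#' a single-hidden-layer extreme learning machine (random fixed input weights,
#' least-squares output weights), and a majority-vote ensemble of ELMs across
#' activations and seeds.
#'
#' @name classifiers
NULL

#' Train a multi-class linear max-margin classifier
#'
#' Features are passed unscaled (raw histogram counts) by default; set
#' `l2_normalize = TRUE` to project each sample to the unit sphere first.
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Class labels (>= 2 classes, each with >= 1 sample).
#' @param C Regularization (margin cost), default 1.
#' @param l2_normalize Scale each row to unit L2 norm before fitting.
#' @return An `ecg_classifier` with a [predict][stats::predict] method
#'   returning character labels.
#' @export
train_classifier <- function(features, labels, C = 1.0, l2_normalize = FALSE) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    abort("need at least 2 classes to train a classifier")
  if (nrow(features) != length(labels))
    abort("features and labels disagree in length")
  if (l2_normalize) features <- l2_rows(features)
  fit <- e1071::svm(x = features, y = factor(labels),
                    type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE)
  structure(list(svm = fit, l2_normalize = l2_normalize),
            class = "ecg_classifier")
}

l2_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  x / nrm
}

#' @export
predict.ecg_classifier <- function(object, newdata, ...) {
  if (object$l2_normalize) newdata <- l2_rows(newdata)
  as.character(stats::predict(object$svm, newdata))
}

#' Identification accuracy in percent
#'
#' Multi-class accuracy, `100 * correct / total`. Aggregated one-vs-rest this
#' is `(TP + TN) / (TP + TN + FP + FN)` micro-averaged over the per-class
#' confusion tables (see [confusion_counts()]).
#'
#' @param predictions,truth Equal-length label vectors.
#' @return Percentage in `[0, 100]`.
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    abort("predictions and truth must have equal length")
  100 * mean(as.character(predictions) == as.character(truth))
}

#' Per-class one-vs-rest confusion counts
#'
#' @inheritParams accuracy
#' @return Tibble with one row per class: `class`, `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predictions, truth) {
  predictions <- as.character(predictions); truth <- as.character(truth)
  classes <- sort(unique(c(predictions, truth)))
  purrr::map_dfr(classes, function(cl) {
    p <- predictions == cl; t <- truth == cl
    tibble::tibble(class = cl,
                   TP = sum(p & t), TN = sum(!p & !t),
                   FP = sum(p & !t), FN = sum(!p & t))
  })
}

#' Eigen-PCA feature projection baseline
#'
#' Mean and principal axes are estimated on the training rows only; both sets
#' are projected onto the top eigenvectors of the training covariance.
#'
#' @param train,test Numeric matrices with matching column counts.
#' @param n_components Number of leading components,
#'   `<= min(ncol, nrow(train))`.
#' @return List with projected `train` and `test`, the `eigenvalues`, and the
#'   `rotation` matrix (columns are eigenvectors).
#' @export
pca_features <- function(train, test, n_components) {
  d <- ncol(train)
  if (n_components < 1 || n_components > min(d, nrow(train)))
    abort("n_components out of range")
  mu <- colMeans(train)
  Xc <- sweep(train, 2, mu)
  S <- crossprod(Xc) / (nrow(train) - 1)
  ee <- eigen(S, symmetric = TRUE)
  V <- ee$vectors[, seq_len(n_components), drop = FALSE]
  list(train = Xc %*% V,
       test = sweep(test, 2, mu) %*% V,
       eigenvalues = ee$values[seq_len(n_components)],
       rotation = V)
}

elm_activations <- list(
  sigmoid = function(z) 1 / (1 + exp(-z)),
  relu = function(z) pmax(z, 0),
  sin = sin
)

#' Fit an extreme learning machine
#'
#' Input weights and biases are drawn from a seeded uniform(-1, 1) and never
#' trained; the output weights are the minimum-norm least-squares solution
#' mapping hidden activations to one-hot targets (Moore-Penrose
#' pseudoinverse).
#'
#' @param features Numeric matrix, samples in rows.
#' @param labels Class labels.
#' @param n_hidden Hidden-layer width (default 1000).
#' @param activation One of `"sigmoid"`, `"relu"`, `"sin"`.
#' @param seed Seed for the random input layer.
#' @return An `elm` model with a predict method returning labels.
#' @export
elm_fit <- function(features, labels, n_hidden = 1000,
                    activation = "sigmoid", seed = 1) {
  if (n_hidden < 1) abort("n_hidden must be >= 1")
  if (!activation %in% names(elm_activations))
    abort("activation must be one of sigmoid, relu, sin")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  set.seed(seed)
  d <- ncol(features)
  W <- matrix(runif(d * n_hidden, -1, 1), d, n_hidden)
  b <- runif(n_hidden, -1, 1)
  H <- elm_activations[[activation]](sweep(features %*% W, 2, b, `+`))
  Y <- outer(labels, classes, `==`) * 1
  beta <- MASS::ginv(H) %*% Y
  structure(list(input_weights = W, biases = b, activation = activation,
                 output_weights = beta, classes = classes, seed = seed),
            class = "elm")
}

#' @export
predict.elm <- function(object, newdata, ...) {
  H <- elm_activations[[object$activation]](
    sweep(newdata %*% object$input_weights, 2, object$biases, `+`))
  scores <- H %*% object$output_weights
  object$classes[max.col(scores, ties.method = "first")]
}

#' Fit a majority-vote ensemble of ELMs
#'
#' One member per seed and activation (`sigmoid`, `relu`, `sin`), so `seeds`
#' of length `s` gives `3 s` members. Prediction is by majority vote with
#' ties broken toward the lowest class id (sorted order).
#'
#' @inheritParams elm_fit
#' @param seeds Integer vector of member seeds (>= 1, giving >= 3 members).
#' @return An `eelm` model with a predict method.
#' @export
eelm_fit <- function(features, labels, n_hidden = 1000, seeds = 1:3) {
  grid <- expand.grid(seed = seeds, activation = names(elm_activations),
                      stringsAsFactors = FALSE)
  if (nrow(grid) < 3) abort("ensemble needs at least 3 members")
  members <- purrr::map2(grid$seed, grid$activation,
                         ~elm_fit(features, labels, n_hidden, .y, .x))
  structure(list(members = members,
                 classes = sort(unique(as.character(labels)))),
            class = "eelm")
}

#' @export
predict.eelm <- function(object, newdata, ...) {
  votes <- vapply(object$members, function(mm) predict(mm, newdata),
                  character(nrow(newdata)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  apply(votes, 1, function(v) {
    tab <- table(factor(v, levels = object$classes))
    names(tab)[which.max(tab)]     # which.max -> first (lowest) on ties
  })
}
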