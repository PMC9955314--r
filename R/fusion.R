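#' Fuse deep feature matrices by column-wise concatenation
#'
#' Combines the penultimate features of two backbones for the same image
#' set: the 512 depth-18 columns followed by the 2048 depth-50 columns give
#' the 2560-dimensional fused representation.
#'
#' @param features_a,features_b Numeric matrices with equal row counts and
#'   identical row ordering (one row per image, manifest order).
#' @return The `n x (d_a + d_b)` matrix `cbind(features_a, features_b)`.
#' @export
fuse_features <- function(features_a, features_b) {
  features_a <- as.matrix(features_a); features_b <- as.matrix(features_b)
  if (nrow(features_a) != nrow(features_b)) {
    abort(sprintf("Row mismatch: %d vs %d; fused matrices must describe the same images in the same order.",
                  nrow(features_a), nrow(features_b)))
  }
  cbind(features_a, features_b)
}

#' Train a kernel support vector machine on deep features
#'
#' Binary C-classification SVM with one of four kernels: `"linear"`,
#' `"quadratic"` and `"cubic"` (polynomial of degree 2 and 3 with unit
#' scale and offset 1), or `"gaussian"` (radial basis with length scale
#' `sqrt(d)` for `d` features, i.e. `gamma = 1/(2d)`). Features are
#' z-scored with training-set statistics before fitting (constant columns
#' are centered only), and the same statistics are applied at prediction
#' time. The fit is deterministic.
#'
#' @param features Numeric `n x d` matrix of training features.
#' @param labels Binary 0/1 labels.
#' @param kernel One of `"linear"`, `"quadratic"`, `"cubic"`, `"gaussian"`.
#' @param cost Soft-margin box constraint C.
#' @param gamma Kernel scale; defaults to 1 for the polynomial kernels and
#'   `1/(2d)` for the gaussian kernel.
#' @param coef0 Polynomial offset.
#' @return An `svm_classifier` wrapping the fitted model and the
#'   standardization statistics.
#' @export
train_svm <- function(features, labels,
                      kernel = c("linear", "quadratic", "cubic", "gaussian"),
                      cost = 1, gamma = NULL, coef0 = 1) {
  kernel <- match.arg(kernel)
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) abort("One label per feature row is required.")
  if (length(unique(labels)) < 2) abort("Labels contain a single class; a binary SVM needs both.")
  if (any(!is.finite(features))) abort("Features contain non-finite values.")

  center <- colMeans(features)
  scale_ <- apply(features, 2, stats::sd)
  scale_[scale_ == 0] <- 1          # constant columns: center only
  xs <- sweep(sweep(features, 2, center), 2, scale_, "/")

  d <- ncol(features)
  args <- switch(kernel,
    linear = list(kernel = "linear"),
    quadratic = list(kernel = "polynomial", degree = 2,
                     gamma = gamma %||% 1, coef0 = coef0),
    cubic = list(kernel = "polynomial", degree = 3,
                 gamma = gamma %||% 1, coef0 = coef0),
    gaussian = list(kernel = "radial", gamma = gamma %||% (1 / (2 * d)))
  )
  fit <- do.call(e1071::svm, c(list(
    x = xs, y = factor(labels, levels = c(0, 1)),
    type = "C-classification", cost = cost, scale = FALSE
  ), args))
  structure(list(fit = fit, kernel = kernel, center = center,
                 scale = scale_, cost = cost, d = d),
            class = "svm_classifier")
}

#' @export
print.svm_classifier <- function(x, ...) {
  cat(sprintf("<svm_classifier> %s kernel, %d features, %d support vectors\n",
              x$kernel, x$d, nrow(x$fit$SV)))
  invisible(x)
}

#' @export
predict.svm_classifier <- function(object, features, ...) {
  features <- as.matrix(features)
  xs <- sweep(sweep(features, 2, object$center), 2, object$scale, "/")
  as.integer(as.character(predict(object$fit, xs)))
}

#' Confusion counts and the six classification metrics
#'
#' Compares binary predictions with the truth (positive class = 1) and
#' computes, from the counts tp/tn/fp/fn:
#' accuracy (as a percentage), specificity `tn/(tn+fp)`, precision
#' `tp/(tp+fp)`, sensitivity `tp/(tp+fn)`, F1 `2tp/(2tp+fp+fn)` and the
#' Matthews correlation coefficient
#' `(tp*tn - fn*fp) / sqrt((tp+fn)(tn+fp)(tp+fp)(tn+fn))`.
#' A metric whose denominator is zero is reported as `NA` and named in the
#' report's `undefined` field rather than silently coerced to 0.
#'
#' @param predictions,truth Equal-length binary 0/1 vectors.
#' @return A `metrics_report`: list with `confusion` (named counts) and the
#'   six metrics; `tidy()`/`glance()` return it as a one-row tibble.
#' @examples
#' p <- toy_confusion("perfect", n = 10)
#' evaluate_predictions(p$predicted, p$truth)$mcc  # 1
#' @export
evaluate_predictions <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    abort("`predictions` and `truth` must have the same length.")
  }
  predictions <- as.integer(predictions); truth <- as.integer(truth)
  if (!all(c(predictions, truth) %in% c(0L, 1L))) {
    abort("Labels must be binary 0/1.")
  }
  tp <- sum(predictions == 1 & truth == 1)
  tn <- sum(predictions == 0 & truth == 0)
  fp <- sum(predictions == 1 & truth == 0)
  fn <- sum(predictions == 0 & truth == 1)
  metrics_from_counts(tp = tp, tn = tn, fp = fp, fn = fn)
}

#' @rdname evaluate_predictions
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  total <- tp + tn + fp + fn
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  accuracy <- (tp + tn) / total * 100
  specificity <- safe_div(tn, tn + fp)
  precision <- safe_div(tp, tp + fp)
  sensitivity <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn)
  mcc_den <- sqrt(prod(c(tp + fn, tn + fp, tp + fp, tn + fn)))
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fn * fp) / mcc_den
  vals <- c(specificity = specificity, precision = precision,
            sensitivity = sensitivity, f1_score = f1, mcc = mcc)
  structure(
    list(confusion = c(tp = tp, tn = tn, fp = fp, fn = fn),
         accuracy = accuracy, specificity = specificity,
         precision = precision, sensitivity = sensitivity,
         f1_score = f1, mcc = mcc,
         undefined = names(vals)[is.na(vals)]),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> tp %d tn %d fp %d fn %d\n",
              x$confusion["tp"], x$confusion["tn"],
              x$confusion["fp"], x$confusion["fn"]))
  print(tidy(x), ...)
  if (length(x$undefined) > 0) {
    cat("undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy, specificity = x$specificity,
    precision = x$precision, sensitivity = x$sensitivity,
    f1_score = x$f1_score, mcc = x$mcc
  )
}

#' @export
glance.metrics_report <- function(x, ...) {
  dplyr::bind_cols(tibble::as_tibble_row(as.list(x$confusion)), tidy(x))
}

#' Stratified train/test split of binary-labelled indices
#'
#' @param labels Binary 0/1 labels.
#' @param split Training fraction.
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, split = 0.8, seed = 1) {
  labels <- as.integer(labels)
  with_seed(seed, {
    train <- integer(0)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      n_tr <- round(length(idx) * split)
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' ReliefF-selected fusion classification
#'
#' The final stage of the hybrid pipeline: from a fused deep-feature matrix
#' (e.g. 2560 columns), ReliefF weights are computed, the top `n_select`
#' columns (500 by default) are kept, and a kernel SVM is trained and
#' evaluated. By default the selection weights are computed on the training
#' rows only and then applied to the test rows, which keeps the procedure
#' free of test-set leakage; `selection_scope = "all"` reproduces the
#' alternative of weighting on the full matrix.
#'
#' @param fused Numeric feature matrix (rows = images).
#' @param labels Binary 0/1 labels.
#' @param n_select Number of columns to keep; at most `ncol(fused)`. Using
#'   the full dimension makes the selection the identity.
#' @param kernel SVM kernel, as in [train_svm()].
#' @param k ReliefF neighbor count.
#' @param seed Seed for the stratified split.
#' @param split Training fraction (ignored when `train_idx` is given).
#' @param train_idx Optional explicit training-row indices.
#' @param selection_scope `"train"` (leakage-safe default) or `"all"`.
#' @param cost SVM box constraint.
#' @return A list: `report` (a `metrics_report`), `selected` (the column
#'   indices kept, in rank order), `weights` (the `relieff_weights`),
#'   `train`/`test` index vectors, and `predictions`.
#' @export
selected_fusion_classify <- function(fused, labels, n_select = 500,
                                     kernel = "cubic", k = 10, seed = 1,
                                     split = 0.8, train_idx = NULL,
                                     selection_scope = c("train", "all"),
                                     cost = 1) {
  selection_scope <- match.arg(selection_scope)
  fused <- as.matrix(fused)
  labels <- as.integer(labels)
  if (n_select > ncol(fused)) {
    abort(sprintf("Cannot select %d of %d columns.", n_select, ncol(fused)))
  }
  if (is.null(train_idx)) {
    sp <- stratified_split(labels, split = split, seed = seed)
  } else {
    sp <- list(train = sort(train_idx),
               test = setdiff(seq_len(nrow(fused)), train_idx))
  }
  if (n_select == ncol(fused)) {
    # selection is the identity; skip the weighting pass entirely
    w <- NULL
    sel <- seq_len(ncol(fused))
  } else {
    w_rows <- if (selection_scope == "train") sp$train else seq_len(nrow(fused))
    w <- relieff_weights(fused[w_rows, , drop = FALSE], labels[w_rows],
                         k = k, bounds_mode = "observed")
    sel <- select_top(w, n_select)
  }
  clf <- train_svm(fused[sp$train, sel, drop = FALSE], labels[sp$train],
                   kernel = kernel, cost = cost)
  pred <- predict(clf, fused[sp$test, sel, drop = FALSE])
  list(report = evaluate_predictions(pred, labels[sp$test]),
       selected = sel, weights = w, train = sp$train, test = sp$test,
       predictions = pred, kernel = kernel, n_select = as.integer(n_select),
       selection_scope = selection_scope)
}
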