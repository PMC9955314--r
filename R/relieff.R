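#' Bounded attribute difference between two samples
#'
#' The elementary difference function of the Relief family for numeric
#' attributes: the absolute value difference scaled by the attribute's
#' range, so that every contribution lies in \[0, 1\].
#'
#' @param value_a,value_b Attribute values of the two samples.
#' @param bounds Length-2 numeric `c(min, max)` of the attribute; the span
#'   must be positive.
#' @return `abs(value_a - value_b) / (max - min)`, in \[0, 1\] for in-bounds
#'   values.
#' @examples
#' attribute_diff(89, 197, c(0, 199))
#' @export
attribute_diff <- function(value_a, value_b, bounds) {
  stopifnot(length(bounds) == 2)
  span <- bounds[2] - bounds[1]
  if (span <= 0) abort("Attribute bounds have zero span; the difference function is undefined.")
  abs(value_a - value_b) / span
}

resolve_relieff_input <- function(data, labels, bounds_mode) {
  if (inherits(data, "feature_table")) {
    labs <- table_labels(data)
    x <- feature_matrix(data)
    b <- if (bounds_mode == "declared" && !is.null(attr(data, "bounds"))) {
      attr(data, "bounds")
    } else NULL
  } else {
    x <- as.matrix(data)
    if (is.null(labels)) abort("`labels` is required when `data` is not a feature_table.")
    labs <- as.integer(labels)
    b <- NULL
  }
  if (is.null(b)) {
    b <- tibble::tibble(
      feature = colnames(x) %||% sprintf("f%04d", seq_len(ncol(x))),
      xmin = apply(x, 2, min), xmax = apply(x, 2, max)
    )
  }
  if (is.null(colnames(x))) colnames(x) <- b$feature
  list(x = x, labels = labs, bounds = b)
}

#' ReliefF feature weights
#'
#' Distance-based feature weighting for a binary outcome. Each visited
#' sample pulls weight towards features on which its nearest misses (other
#' class) differ and away from features on which its nearest hits (same
#' class) differ:
#' \deqn{W(A) \leftarrow W(A) + \overline{\mathrm{diff}}(A, R_i, M) / m -
#'       \overline{\mathrm{diff}}(A, R_i, H) / m}
#' where the bar averages the bounded difference over the `k` nearest hits
#' `H` and `k` nearest misses `M`, found by Manhattan distance over the
#' per-attribute differences. At `k = 1` this reduces to the single
#' nearest-hit/nearest-miss update of classic Relief. All weights lie in
#' \[-1, 1\] by construction, and a feature that is constant across samples
#' gets weight exactly 0.
#'
#' Distances and differences are computed on features scaled by their
#' bounds (declared bounds when `data` is a feature table that carries
#' them and `bounds_mode = "declared"`; observed column ranges otherwise,
#' which is also the only option for arbitrary matrices such as deep
#' feature matrices).
#'
#' @param data A [feature_table()] or a numeric matrix / data frame of
#'   features.
#' @param labels Binary 0/1 outcomes; taken from `data` when it is a
#'   feature table.
#' @param k Number of nearest hits and misses (default 10). Each class must
#'   have at least `k + 1` members.
#' @param m `"all"` (default) to visit every sample once in row order, or a
#'   positive integer to visit a random subsample of that size.
#' @param seed Seed used when `m` is a number.
#' @param bounds_mode `"declared"` or `"observed"` scaling for the
#'   difference function.
#' @return A `relieff_weights` object: named weight vector plus the
#'   parameters used. `tidy()` returns a tibble with one row per feature
#'   (`feature`, `weight`, `rank`).
#' @examples
#' ft <- simulate_table(sim_spec(n_per_class = c(30, 30), informative = 2,
#'                               effect_size = 3, seed = 7))
#' w <- relieff_weights(ft, k = 5)
#' rank_features(w)
#' @export
relieff_weights <- function(data, labels = NULL, k = 10, m = "all",
                            seed = 1,
                            bounds_mode = c("declared", "observed")) {
  bounds_mode <- match.arg(bounds_mode)
  inp <- resolve_relieff_input(data, labels, bounds_mode)
  x <- inp$x; labs <- inp$labels; b <- inp$bounds
  n <- nrow(x); p <- ncol(x)
  stopifnot(k >= 1)
  counts <- table(factor(labs, levels = c(0, 1)))
  if (any(counts < k + 1)) {
    abort(sprintf(
      "Class %s has only %d member(s); k = %d nearest-neighbor averaging needs at least k + 1 per class. Use a smaller k.",
      names(counts)[which.min(counts)], min(counts), k))
  }

  span <- b$xmax - b$xmin
  live <- span > 0                       # constant features contribute 0
  xs <- x
  xs[, live] <- sweep(sweep(x[, live, drop = FALSE], 2, b$xmin[live]),
                      2, span[live], "/")
  xs[, !live] <- 0

  d <- as.matrix(stats::dist(xs, method = "manhattan"))

  visits <- if (identical(m, "all")) {
    seq_len(n)
  } else {
    stopifnot(is.numeric(m), m >= 1)
    with_seed(seed, sample.int(n, size = min(m, n), replace = FALSE))
  }
  m_eff <- length(visits)

  w <- numeric(p)
  for (i in visits) {
    same <- setdiff(which(labs == labs[i]), i)
    diff_cls <- which(labs != labs[i])
    hits <- same[order(d[i, same], same)][seq_len(k)]
    misses <- diff_cls[order(d[i, diff_cls], diff_cls)][seq_len(k)]
    dh <- abs(sweep(xs[hits, , drop = FALSE], 2, xs[i, ]))
    dm <- abs(sweep(xs[misses, , drop = FALSE], 2, xs[i, ]))
    w <- w + (colMeans(dm) - colMeans(dh)) / m_eff
  }
  names(w) <- b$feature
  structure(
    list(weights = w, k = as.integer(k), m = m, seed = seed,
         bounds = b, n = n),
    class = "relieff_weights"
  )
}

#' @export
print.relieff_weights <- function(x, ...) {
  cat(sprintf("<relieff_weights> p = %d features, k = %d, m = %s, n = %d\n",
              length(x$weights), x$k,
              if (identical(x$m, "all")) "all" else x$m, x$n))
  print(tidy(x), ...)
  invisible(x)
}

#' @export
tidy.relieff_weights <- function(x, ...) {
  tibble::tibble(
    feature = names(x$weights),
    weight = unname(x$weights),
    rank = match(seq_along(x$weights), rank_features(x))
  ) |> dplyr::arrange(.data$rank)
}

#' Rank features by descending importance weight
#'
#' @param weights A `relieff_weights` object or a bare numeric weight vector.
#' @return An integer permutation of `1:p`: feature indices sorted by
#'   descending weight, ties broken by ascending feature index.
#' @examples
#' rank_features(c(0.1, 0.3, 0.2))
#' @export
rank_features <- function(weights) {
  w <- if (inherits(weights, "relieff_weights")) weights$weights else weights
  order(-w, seq_along(w))
}

#' Select the top-n features by weight
#'
#' @inheritParams rank_features
#' @param n Number of features to keep; must not exceed the feature count.
#' @return Integer vector: the first `n` entries of [rank_features()].
#' @export
select_top <- function(weights, n) {
  w <- if (inherits(weights, "relieff_weights")) weights$weights else weights
  if (n > length(w)) {
    abort(sprintf("Cannot select %d features out of %d.", n, length(w)))
  }
  stopifnot(n >= 1)
  rank_features(w)[seq_len(n)]
}

#' Export ReliefF weights as CSV
#'
#' Writes one row per feature with columns `feature_name`, `weight`, `rank`.
#'
#' @param weights A `relieff_weights` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_weights_csv <- function(weights, path) {
  td <- tidy(weights)
  names(td)[names(td) == "feature"] <- "feature_name"
  utils::write.csv(td, path, row.names = FALSE)
  invisible(path)
}
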