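#' Specification for the class-conditional Gaussian table simulator
#'
#' Describes a synthetic clinical table shaped like the Pima Indians
#' benchmark: two outcome classes with fixed counts (default 500 negatives
#' and 268 positives, 768 records in all), eight bounded numeric features,
#' and a chosen informative subset whose class means are shifted.
#'
#' Features are drawn class-conditionally Gaussian. The baseline mean of
#' each feature sits at the midpoint of its declared range and the noise
#' standard deviation defaults to one eighth of the range width, so that
#' draws rarely hit the clipping bounds. Informative features receive a mean
#' shift of `effect_size * noise_sd` in the positive class only; all draws
#' are then clipped to the declared bounds.
#'
#' @param n_per_class Counts `c(n_negative, n_positive)`. Default `c(500, 268)`.
#' @param p Number of features; defaults to the 8-feature reference schema.
#' @param bounds Per-feature bounds tibble (`feature`, `xmin`, `xmax`).
#'   Defaults to [pima_bounds()] when `p == 8`, otherwise unit ranges.
#' @param informative Integer indices of features carrying class signal.
#' @param effect_size Standardized mean shift (in units of `noise_sd`)
#'   applied to informative features in the positive class. Scalar or one
#'   value per informative feature.
#' @param noise_sd Per-feature standard deviation; scalar or length `p`.
#'   Default: (range width) / 8.
#' @param seed Integer RNG seed; the same spec and seed reproduce the table
#'   byte for byte.
#' @return A `sim_spec` list.
#' @examples
#' spec <- sim_spec(informative = c(2, 6), effect_size = 1.5, seed = 42)
#' ft <- simulate_table(spec)
#' table(table_labels(ft))
#' @export
sim_spec <- function(n_per_class = c(500, 268), p = 8, bounds = NULL,
                     informative = integer(0), effect_size = 1,
                     noise_sd = NULL, seed = 1) {
  stopifnot(length(n_per_class) == 2, all(n_per_class >= 1), p >= 1)
  if (is.null(bounds)) {
    bounds <- if (p == 8) {
      pima_bounds()
    } else {
      tibble::tibble(feature = sprintf("f%02d", seq_len(p)),
                     xmin = 0, xmax = 1)
    }
  }
  stopifnot(nrow(bounds) == p, all(bounds$xmin < bounds$xmax))
  if (!all(is.finite(effect_size))) abort("Effect sizes must be finite.")
  if (length(informative) == 0 && any(effect_size != 0) &&
      !missing(effect_size)) {
    abort("A nonzero effect size was requested but the informative set is empty.")
  }
  if (is.null(noise_sd)) noise_sd <- (bounds$xmax - bounds$xmin) / 8
  noise_sd <- rep_len(noise_sd, p)
  structure(
    list(n_per_class = as.integer(n_per_class), p = as.integer(p),
         bounds = bounds, informative = as.integer(informative),
         effect_size = rep_len(effect_size, max(1L, length(informative))),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

#' Simulate a benchmark-shaped feature table
#'
#' Draws a [feature_table()] according to a [sim_spec()]: class-conditional
#' Gaussian features, a mean shift of `effect_size * noise_sd` on the
#' informative features in the positive class, values clipped to the
#' declared bounds. Deterministic for a given seed; clipping never alters
#' the label counts.
#'
#' @param spec A [sim_spec()].
#' @return A [feature_table()] with `sum(n_per_class)` rows, negatives first.
#' @export
simulate_table <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n0 <- spec$n_per_class[1]; n1 <- spec$n_per_class[2]
  n <- n0 + n1
  labels <- c(rep(0L, n0), rep(1L, n1))
  mid <- (spec$bounds$xmin + spec$bounds$xmax) / 2
  shift <- numeric(spec$p)
  if (length(spec$informative) > 0) {
    shift[spec$informative] <- spec$effect_size * spec$noise_sd[spec$informative]
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(spec$seed)
  vals <- matrix(0, n, spec$p, dimnames = list(NULL, spec$bounds$feature))
  for (j in seq_len(spec$p)) {
    mu <- mid[j] + shift[j] * labels
    x <- stats::rnorm(n, mean = mu, sd = spec$noise_sd[j])
    vals[, j] <- pmin(spec$bounds$xmax[j], pmax(spec$bounds$xmin[j], x))
  }
  df <- as.data.frame(vals)
  df$outcome <- labels
  feature_table(df, label_col = "outcome", bounds = spec$bounds)
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

# Run code with a temporary seed, leaving the global RNG stream untouched.
with_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Deterministic prediction/truth pairs for metric tests
#'
#' Constructs toy binary prediction problems with a known confusion
#' structure: `"perfect"` predictions equal the truth (MCC 1), `"inverted"`
#' predictions flip every label (MCC -1), `"random"` predictions are fair
#' coin flips independent of the truth (MCC near 0).
#'
#' @param kind `"perfect"`, `"inverted"` or `"random"`.
#' @param n Number of cases (balanced truth, `n >= 1`).
#' @param seed RNG seed used by `"random"`.
#' @return A list with integer vectors `truth` and `predicted`.
#' @export
toy_confusion <- function(kind = c("perfect", "inverted", "random"),
                          n = 10, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  truth <- rep_len(c(0L, 1L), n)
  predicted <- switch(kind,
    perfect = truth,
    inverted = 1L - truth,
    random = with_seed(seed, sample(c(0L, 1L), n, replace = TRUE))
  )
  list(truth = truth, predicted = predicted)
}
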