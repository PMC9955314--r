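# Shared fixtures and independent oracles for the test suite.

# Ten records matching the reference clinical schema (the published example
# rows of the benchmark table), used for exact-arithmetic checks.
example_clinical_rows <- function() {
  df <- data.frame(
    pregnancies = c(1, 2, 1, 1, 9, 5, 2, 2, 7, 7),
    glucose = c(89, 197, 189, 103, 171, 88, 141, 100, 83, 160),
    blood_pressure = c(66, 70, 60, 30, 110, 66, 58, 66, 78, 54),
    skin_thickness = c(23, 45, 23, 38, 24, 21, 34, 20, 26, 32),
    insulin = c(94, 543, 846, 83, 240, 23, 128, 90, 71, 175),
    bmi = c(28.1, 30.5, 30.1, 43.3, 45.4, 24.4, 25.4, 32.9, 29.3, 30.5),
    pedigree = c(0.167, 0.158, 0.398, 0.183, 0.721, 0.342, 0.699, 0.867,
                 0.767, 0.588),
    age = c(21, 53, 59, 33, 54, 30, 24, 28, 36, 39),
    outcome = c(0, 1, 1, 0, 1, 0, 0, 1, 0, 1)
  )
  feature_table(df, bounds = pima_bounds())
}

# Brute-force single-nearest-hit/miss Relief weights: nested loops straight
# from the weight-update recurrence, no shared code with the implementation.
relief_oracle_k1 <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  mn <- apply(x, 2, min); mx <- apply(x, 2, max)
  span <- mx - mn
  diff_a <- function(a, i1, i2) {
    if (span[a] == 0) return(0)
    abs(x[i1, a] - x[i2, a]) / span[a]
  }
  manhattan <- function(i, j) {
    s <- 0
    for (a in seq_len(p)) s <- s + diff_a(a, i, j)
    s
  }
  w <- numeric(p)
  for (i in seq_len(n)) {
    hits <- setdiff(which(labels == labels[i]), i)
    misses <- which(labels != labels[i])
    dh <- vapply(hits, function(j) manhattan(i, j), numeric(1))
    dm <- vapply(misses, function(j) manhattan(i, j), numeric(1))
    H <- hits[order(dh, hits)][1]
    M <- misses[order(dm, misses)][1]
    for (a in seq_len(p)) {
      w[a] <- w[a] + diff_a(a, i, M) / n - diff_a(a, i, H) / n
    }
  }
  w
}

# Independent confusion-metric computation: per-sample counting and longhand
# formulas, no shared code with metrics_from_counts().
count_metrics_oracle <- function(pred, truth) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
  }
  den <- function(x) if (x == 0) NA_real_ else x
  mccd <- sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tp + fp) * sqrt(tn + fn)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       accuracy = (tp + tn) / (tp + tn + fp + fn) * 100,
       specificity = tn / den(tn + fp),
       precision = tp / den(tp + fp),
       sensitivity = tp / den(tp + fn),
       f1 = 2 * tp / den(2 * tp + fp + fn),
       mcc = (tp * tn - fn * fp) / den(mccd))
}

# Small rasterized image set with separable classes for backbone tests:
# class 0 lights up the first cells, class 1 the last ones, plus noise.
separable_images <- function(n_per_class = 8, p = 6, side = 24, seed = 1) {
  lay <- build_layout(seq_len(p), width = side, height = side)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  imgs <- list(); labs <- integer(0)
  for (cl in c(0L, 1L)) {
    base <- if (cl == 0) c(rep(0.9, p %/% 2), rep(0.1, p - p %/% 2)) else
      c(rep(0.1, p %/% 2), rep(0.9, p - p %/% 2))
    for (i in seq_len(n_per_class)) {
      row <- pmin(1, pmax(0, base + runif(p, -0.05, 0.05)))
      imgs <- c(imgs, list(rasterize(row, lay)))
      labs <- c(labs, cl)
    }
  }
  list(images = imgs, labels = labs, layout = lay)
}

hash_images <- function(imgs) rlang::hash(lapply(imgs, unclass))

# raw pixel matrix of a gray_image, stripped of class and label attributes
px <- function(img) {
  m <- unclass(img)
  attributes(m) <- list(dim = dim(m))
  m
}
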