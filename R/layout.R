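# round half away from zero at .5, as opposed to base R's round-half-even;
# pinned because cell thicknesses and 0.5 * 255 intensities land on exact halves
round_half_up <- function(x) floor(x + 0.5)

#' Build the importance-ordered guillotine cell layout
#'
#' Partitions a pixel canvas (default 120 x 120) into one rectangle per
#' feature so that more important features receive larger cells. The layout
#' is a deterministic guillotine subdivision: features are visited in
#' importance order, and at each step a strip is sliced off the remaining
#' rectangle along its longer side (ties sliced vertically), with thickness
#' proportional to the feature's share of the remaining mass (rounded,
#' clamped so every later feature keeps at least one pixel of thickness);
#' the last feature absorbs the remainder. The resulting cells are pairwise
#' disjoint, tile the canvas exactly, and have areas non-increasing along
#' the ranking up to rounding slack. With unequal masses the arrangement is
#' asymmetric under a horizontal mirror for two or more cells, and under
#' both mirrors for three or more — the property the augmentation stage
#' relies on so reflected images stay distinguishable from originals. (A
#' two-cell split of a rectangle is necessarily symmetric along its cut
#' axis, and a single cell is its own mirror.)
#'
#' @param ranking Permutation of `1:p` as returned by [rank_features()]:
#'   `ranking[1]` is the most important feature.
#' @param masses `"rank-based"` (default) for masses `p, p-1, ..., 1`
#'   assigned along the ranking, or a vector of `p` positive masses indexed
#'   by feature. Rank-based masses keep the "larger cell for the more
#'   important feature" rule valid even when raw importance weights are
#'   negative.
#' @param width,height Canvas size in pixels; each must be at least `p`.
#' @return A `cell_layout`: a tibble with one row per feature in ranking
#'   order (`feature`, `rank`, `mass`, `x0`, `y0`, `x1`, `y1`, `area`;
#'   0-based, half-open on the right/bottom), with canvas dimensions and the
#'   ranking as attributes.
#' @examples
#' lay <- build_layout(c(2, 8, 6, 1, 7, 3, 5, 4))
#' sum(lay$area)  # 14400 = full 120 x 120 canvas
#' @export
build_layout <- function(ranking, masses = "rank-based",
                         width = 120, height = 120) {
  p <- length(ranking)
  stopifnot(p >= 1, setequal(ranking, seq_len(p)))
  if (identical(masses, "rank-based")) {
    mass_by_rank <- as.numeric(p:1)
  } else {
    stopifnot(length(masses) == p)
    if (any(!is.finite(masses)) || any(masses <= 0)) {
      abort("All masses must be positive and finite.")
    }
    mass_by_rank <- as.numeric(masses[ranking])
  }
  if (width < p || height < p) {
    abort(sprintf("Canvas %dx%d too small for %d features.", width, height, p))
  }

  cells <- matrix(NA_integer_, p, 4,
                  dimnames = list(NULL, c("x0", "y0", "x1", "y1")))
  x0 <- 0L; y0 <- 0L; x1 <- as.integer(width); y1 <- as.integer(height)
  remaining <- sum(mass_by_rank)
  for (i in seq_len(p)) {
    if (i == p) {
      cells[i, ] <- c(x0, y0, x1, y1)
      break
    }
    w <- x1 - x0; h <- y1 - y0
    vertical <- w >= h
    extent <- if (vertical) w else h
    t_raw <- round_half_up(extent * mass_by_rank[i] / remaining)
    thick <- max(1L, min(as.integer(t_raw), extent - (p - i)))
    if (vertical) {
      cells[i, ] <- c(x0, y0, x0 + thick, y1)
      x0 <- x0 + thick
    } else {
      cells[i, ] <- c(x0, y0, x1, y0 + thick)
      y0 <- y0 + thick
    }
    remaining <- remaining - mass_by_rank[i]
  }

  out <- tibble::tibble(
    feature = as.integer(ranking),
    rank = seq_len(p),
    mass = mass_by_rank,
    x0 = unname(cells[, 1]), y0 = unname(cells[, 2]),
    x1 = unname(cells[, 3]), y1 = unname(cells[, 4]),
    area = unname((cells[, 3] - cells[, 1]) * (cells[, 4] - cells[, 2]))
  )
  attr(out, "width") <- as.integer(width)
  attr(out, "height") <- as.integer(height)
  attr(out, "ranking") <- as.integer(ranking)
  class(out) <- c("cell_layout", class(out))
  out
}

#' @export
print.cell_layout <- function(x, ...) {
  cat(sprintf("<cell_layout> %d cells on a %dx%d canvas\n",
              nrow(x), attr(x, "width"), attr(x, "height")))
  NextMethod()
}

#' Export a cell layout as JSON
#'
#' Serializes the canvas size and the list of rectangles so an alternative
#' layout can be exchanged or audited.
#'
#' @param layout A [build_layout()] result.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @export
layout_to_json <- function(layout, path = NULL) {
  obj <- list(
    canvas = list(width = attr(layout, "width"), height = attr(layout, "height")),
    cells = as.data.frame(layout[, c("feature", "rank", "x0", "y0", "x1", "y1")])
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Rasterize one normalized record into a grayscale image
#'
#' Each feature's cell is filled with the 8-bit intensity
#' `round_half_up(255 * value)`, so a fully expressed feature is white and
#' an absent one black.
#'
#' @param row Numeric vector of `p` normalized feature values in \[0, 1\].
#' @param layout A [build_layout()] with `p` cells.
#' @param label Optional 0/1 outcome stored on the image.
#' @return A `gray_image`: integer matrix (height x width) of intensities
#'   0--255, rows indexed by y and columns by x.
#' @export
rasterize <- function(row, layout, label = NULL) {
  p <- nrow(layout)
  if (length(row) != p) {
    abort(sprintf("Row has %d values but the layout has %d cells.", length(row), p))
  }
  if (any(row < 0 | row > 1)) abort("Row values must lie in [0, 1]; normalize first.")
  w <- attr(layout, "width"); h <- attr(layout, "height")
  img <- matrix(0L, nrow = h, ncol = w)
  for (i in seq_len(p)) {
    val <- as.integer(round_half_up(255 * row[layout$feature[i]]))
    img[(layout$y0[i] + 1):layout$y1[i], (layout$x0[i] + 1):layout$x1[i]] <- val
  }
  gray_image(img, label = label)
}

gray_image <- function(pixels, label = NULL) {
  stopifnot(is.matrix(pixels))
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0L | pixels > 255L)) abort("Pixel intensities must be 0-255.")
  structure(pixels, label = label, class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %dx%d, intensities %d-%d%s\n",
              nrow(x), ncol(x), min(x), max(x),
              if (is.null(attr(x, "label"))) "" else
                sprintf(", label %s", attr(x, "label"))))
  invisible(x)
}

#' Convert a normalized table into a set of grayscale images
#'
#' Rasterizes every row with [rasterize()]; one image per record. When
#' `out_dir` is given, images are additionally written as 8-bit grayscale
#' PNGs (`sample_000001.png`, ...) together with a JSON manifest mapping
#' each file to its row index and label; re-running on the same inputs
#' yields byte-identical files.
#'
#' @param table A [minmax_normalize()] result (or any feature table whose
#'   values already lie in \[0, 1\]).
#' @param layout A [build_layout()] whose cell count matches the table.
#' @param out_dir Optional output directory for PNG files.
#' @return A tibble manifest with columns `row`, `label`, `image` (a
#'   list-column of `gray_image`s) and, when written, `file`.
#' @export
convert_dataset <- function(table, layout, out_dir = NULL) {
  stopifnot(inherits(table, "feature_table") || inherits(table, "normalized_table"))
  vals <- feature_matrix(table)
  labs <- table_labels(table)
  n <- nrow(vals)
  if (n == 0) abort("Empty table.")
  imgs <- lapply(seq_len(n), function(i) rasterize(vals[i, ], layout, label = labs[i]))
  manifest <- tibble::tibble(row = seq_len(n), label = labs, image = imgs)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    files <- file.path(out_dir, sprintf("sample_%06d.png", manifest$row))
    for (i in seq_len(n)) write_gray_png(imgs[[i]], files[i])
    manifest$file <- files
    meta <- list(layout_hash = rlang::hash(as.data.frame(layout)),
                 images = manifest[, c("file", "row", "label")])
    jsonlite::write_json(meta, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest
}

#' Read and write 8-bit grayscale PNG images
#'
#' @param image A `gray_image` (integer matrix, 0--255).
#' @param path PNG file path.
#' @return `write_gray_png()` returns `path` invisibly; `read_gray_png()`
#'   returns a `gray_image`.
#' @export
write_gray_png <- function(image, path) {
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}

#' @rdname write_gray_png
#' @export
read_gray_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  gray_image(matrix(as.integer(round_half_up(arr * 255)),
                    nrow = nrow(arr), ncol = ncol(arr)))
}

#' Plot a cell layout or a rasterized image
#'
#' `autoplot.cell_layout()` draws the rectangles annotated by feature index
#' and rank; `autoplot.gray_image()` renders the raster in grayscale.
#'
#' @param object A `cell_layout` or `gray_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cell_layout <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$x0, xmax = .data$x1,
      ymin = attr(object, "height") - .data$y1,
      ymax = attr(object, "height") - .data$y0,
      fill = factor(.data$rank)
    ), colour = "white", linewidth = 0.6, show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(
      x = (.data$x0 + .data$x1) / 2,
      y = attr(object, "height") - (.data$y0 + .data$y1) / 2,
      label = sprintf("f%d\nrank %d", .data$feature, .data$rank)
    ), colour = "white", size = 3) +
    ggplot2::scale_fill_viridis_d(option = "mako", end = 0.85) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Importance-ordered cell layout (%dx%d)",
                                  attr(object, "width"), attr(object, "height"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cell_layout
#' @export
autoplot.gray_image <- function(object, ...) {
  df <- expand.grid(y = seq_len(nrow(object)), x = seq_len(ncol(object)))
  df$value <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, nrow(object) + 1 - .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), name = "intensity") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}
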