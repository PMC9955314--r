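#' Configuration of the affine augmentation stage
#'
#' Holds the parameter ranges of the four label-preserving geometric
#' transforms used to quintuple the image set: horizontal reflection
#' (parameter-free), rotation in \[-30, 30\] degrees, isotropic scaling in
#' \[0.9, 1.1\], and per-axis translation in \[-10, 10\] pixels. Parameters
#' are drawn uniformly from these ranges, one draw per source image.
#'
#' @param rotation_deg Length-2 range of rotation angles in degrees.
#' @param scale Length-2 range of scale factors.
#' @param translation_px Length-2 range of per-axis shifts in pixels.
#' @param seed Integer RNG seed making the whole augmented set reproducible.
#' @return An `augment_config` list.
#' @export
augment_config <- function(rotation_deg = c(-30, 30), scale = c(0.9, 1.1),
                           translation_px = c(-10, 10), seed = 1) {
  stopifnot(length(rotation_deg) == 2, length(scale) == 2,
            length(translation_px) == 2,
            diff(rotation_deg) >= 0, diff(scale) >= 0,
            diff(translation_px) >= 0, all(scale > 0))
  structure(list(rotation_deg = rotation_deg, scale = scale,
                 translation_px = translation_px, seed = as.integer(seed)),
            class = "augment_config")
}

#' The four augmentation techniques
#' @return Character vector of technique names in their canonical order.
#' @export
augment_techniques <- function() c("reflection", "rotation", "scale", "translation")

# Apply a centered affine map (x, y) -> (x, y) %*% A + t to a gray image.
# Forward coordinate convention; EBImage inverse-maps with bilinear
# interpolation and fills out-of-canvas regions with 0.
affine_gray <- function(image, A, t_xy) {
  h <- nrow(image); w <- ncol(image)
  m <- rbind(A, t_xy)            # 3 x 2 matrix, rows (x, y, 1)
  src <- EBImage::Image(t(unclass(image)) / 255)  # EBImage dim1 = x
  out <- EBImage::affine(src, m, filter = "bilinear",
                         output.dim = c(w, h), bg.col = 0, antialias = TRUE)
  px <- t(EBImage::imageData(out))
  px <- pmin(1, pmax(0, px))
  gray_image(matrix(as.integer(round_half_up(px * 255)), nrow = h, ncol = w),
             label = attr(image, "label"))
}

# rotation / scaling pivot about the canvas center, in pixel coordinates
centered_affine <- function(image, A) {
  c_xy <- c(ncol(image), nrow(image)) / 2
  affine_gray(image, A, t_xy = c_xy - c_xy %*% A)
}

#' Apply one affine augmentation to a grayscale image
#'
#' Applies a single technique with explicit parameters. Rotation and
#' scaling pivot about the image center; translation shifts by `(tx, ty)`
#' pixels (positive x to the right, positive y downwards); reflection is a
#' horizontal (left-right) flip. The output has the input's dimensions;
#' regions mapped from outside the canvas are filled with intensity 0;
#' interpolation is bilinear followed by a cast back to 8 bits.
#'
#' @param image A `gray_image`.
#' @param technique One of `"reflection"`, `"rotation"`, `"scale"`,
#'   `"translation"`.
#' @param angle Rotation angle in degrees (for `"rotation"`).
#' @param factor Scale factor (for `"scale"`).
#' @param shift Length-2 pixel shift `c(tx, ty)` (for `"translation"`).
#' @return A `gray_image` of the same size, inheriting the input's label.
#' @examples
#' img <- rasterize(rep(0.5, 3), build_layout(1:3, width = 12, height = 12))
#' identical(unclass(augment_image(img, "rotation", angle = 0)), unclass(img))
#' @export
augment_image <- function(image,
                          technique = c("reflection", "rotation", "scale", "translation"),
                          angle = 0, factor = 1, shift = c(0, 0)) {
  technique <- match.arg(technique)
  stopifnot(inherits(image, "gray_image"))
  switch(technique,
    reflection = gray_image(unclass(image)[, ncol(image):1, drop = FALSE],
                            label = attr(image, "label")),
    rotation = {
      th <- angle * pi / 180
      # forward map of (x, y) row-vectors; y grows downwards
      centered_affine(image, rbind(c(cos(th), sin(th)), c(-sin(th), cos(th))))
    },
    scale = {
      stopifnot(factor > 0)
      centered_affine(image, diag(c(factor, factor)))
    },
    translation = affine_gray(image, diag(2), t_xy = shift)
  )
}

#' Quintuple an image set with the four affine augmentations
#'
#' For every source image, emits the original plus one output per
#' technique (reflection, rotation, scaling, translation), with technique
#' parameters drawn uniformly from the configured ranges. Labels are
#' inherited, so class counts scale by exactly 5 (e.g. 500/268 originals
#' become 2500/1340). The full augmented set is a deterministic function of
#' the input and the seed.
#'
#' @param manifest A tibble with columns `row`, `label` and list-column
#'   `image`, as produced by [convert_dataset()].
#' @param config An [augment_config()].
#' @return A tibble with columns `source_row`, `label`, `technique`
#'   (`"original"` or one of the four techniques), `params` (list-column of
#'   drawn parameters) and `image` (list-column of `gray_image`s), with
#'   5 x `nrow(manifest)` rows.
#' @export
augment_dataset <- function(manifest, config = augment_config()) {
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1,
            all(c("row", "label", "image") %in% names(manifest)),
            inherits(config, "augment_config"))
  n <- nrow(manifest)
  # one independent, seed-indexed draw block per source image
  draws <- with_seed(config$seed, lapply(seq_len(n), function(i) {
    list(
      rotation = list(angle = runif(1, config$rotation_deg[1], config$rotation_deg[2])),
      scale = list(factor = runif(1, config$scale[1], config$scale[2])),
      translation = list(shift = runif(2, config$translation_px[1],
                                       config$translation_px[2]))
    )
  }))
  out <- vector("list", 5L * n)
  rows <- integer(5L * n); labs <- integer(5L * n)
  tech <- character(5L * n); pars <- vector("list", 5L * n)
  k <- 0L
  for (i in seq_len(n)) {
    img <- manifest$image[[i]]
    d <- draws[[i]]
    variants <- list(
      original = img,
      reflection = augment_image(img, "reflection"),
      rotation = augment_image(img, "rotation", angle = d$rotation$angle),
      scale = augment_image(img, "scale", factor = d$scale$factor),
      translation = augment_image(img, "translation", shift = d$translation$shift)
    )
    params <- list(original = list(), reflection = list(),
                   rotation = d$rotation, scale = d$scale,
                   translation = d$translation)
    for (v in names(variants)) {
      k <- k + 1L
      out[[k]] <- variants[[v]]
      rows[k] <- manifest$row[i]
      labs[k] <- manifest$label[i]
      tech[k] <- v
      pars[[k]] <- params[[v]]
    }
  }
  tibble::tibble(source_row = rows, label = labs, technique = tech,
                 params = pars, image = out)
}
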