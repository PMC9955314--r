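#' Fine-tuning configuration for the residual backbones
#'
#' Defaults follow the reference benchmark training recipe: mini-batch size 32, 5
#' epochs, initial learning rate 0.001 dropped by a factor of 0.1 every 20
#' epochs (so it never drops within the default 5), stochastic gradient
#' descent with momentum, and an 80/20 stratified train/test split handled
#' by the pipeline. The momentum coefficient is not fixed by that
#' recipe; 0.9 is the conventional default.
#'
#' @param batch_size Mini-batch size.
#' @param max_epochs Number of epochs; training runs exactly this many.
#' @param initial_lr Initial learning rate.
#' @param lr_drop_factor Multiplicative learning-rate drop.
#' @param lr_drop_period Epochs between drops.
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 penalty on weights (0 = off).
#' @param split Training fraction used by the pipeline's stratified split.
#' @param seed RNG seed for shuffling and initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 32, max_epochs = 5, initial_lr = 0.001,
                         lr_drop_factor = 0.1, lr_drop_period = 20,
                         momentum = 0.9, weight_decay = 0,
                         split = 0.8, seed = 1) {
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 initial_lr = initial_lr, lr_drop_factor = lr_drop_factor,
                 lr_drop_period = as.integer(lr_drop_period),
                 momentum = momentum, weight_decay = weight_decay,
                 split = split, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate in effect at a given epoch
#' @param config A [train_config()].
#' @param epoch 1-based epoch number.
#' @return The piecewise-constant learning rate
#'   `initial_lr * lr_drop_factor^floor((epoch - 1) / lr_drop_period)`.
#' @export
schedule_lr <- function(config, epoch) {
  config$initial_lr * config$lr_drop_factor^((epoch - 1) %/% config$lr_drop_period)
}

basic_block <- function(c_in, c_out, stride) {
  main <- layer_seq(list(
    layer_conv(3, 3, c_in, c_out, stride = stride, pad = 1),
    layer_bn(c_out), layer_relu(),
    layer_conv(3, 3, c_out, c_out, stride = 1, pad = 1),
    layer_bn(c_out)
  ))
  shortcut <- if (stride != 1 || c_in != c_out) {
    layer_seq(list(layer_conv(1, 1, c_in, c_out, stride = stride), layer_bn(c_out)))
  }
  layer_res(main, shortcut)
}

bottleneck_block <- function(c_in, c_mid, stride) {
  c_out <- 4 * c_mid
  main <- layer_seq(list(
    layer_conv(1, 1, c_in, c_mid), layer_bn(c_mid), layer_relu(),
    layer_conv(3, 3, c_mid, c_mid, stride = stride, pad = 1),
    layer_bn(c_mid), layer_relu(),
    layer_conv(1, 1, c_mid, c_out), layer_bn(c_out)
  ))
  shortcut <- if (stride != 1 || c_in != c_out) {
    layer_seq(list(layer_conv(1, 1, c_in, c_out, stride = stride), layer_bn(c_out)))
  }
  layer_res(main, shortcut)
}

build_resnet <- function(depth, n_classes, hidden_units) {
  stem <- list(
    layer_conv(7, 7, 3, 64, stride = 2, pad = 3),
    layer_bn(64), layer_relu(),
    layer_maxpool(3, stride = 2, pad = 1)
  )
  if (depth == 18) {
    widths <- c(64, 128, 256, 512); blocks_per <- c(2, 2, 2, 2)
    make <- function(c_in, w, s) basic_block(c_in, w, s)
    out_of <- function(w) w
  } else if (depth == 50) {
    widths <- c(64, 128, 256, 512); blocks_per <- c(3, 4, 6, 3)
    make <- function(c_in, w, s) bottleneck_block(c_in, w, s)
    out_of <- function(w) 4 * w
  } else {
    abort(sprintf("Unsupported depth %s; available depths are 18 and 50.", depth))
  }
  body <- list()
  c_in <- 64
  for (st in seq_along(widths)) {
    for (b in seq_len(blocks_per[st])) {
      stride <- if (b == 1 && st > 1) 2 else 1
      body <- c(body, list(make(c_in, widths[st], stride)))
      c_in <- out_of(widths[st])
    }
  }
  d_feat <- out_of(widths[4])
  head <- list(layer_gap(),
               layer_fc(d_feat, hidden_units), layer_relu(),
               layer_fc(hidden_units, n_classes))
  list(net = layer_seq(c(stem, body, head)), feature_dim = d_feat,
       # index of the layer whose output is the penultimate feature vector
       feature_layer = length(stem) + length(body) + 1L)
}

#' Adapt a residual backbone for binary image classification
#'
#' Builds a residual convolutional network of depth 18 (basic blocks,
#' 512-dimensional penultimate features) or depth 50 (bottleneck blocks,
#' 2048-dimensional features) whose final layers are replaced by two fully
#' connected layers (a hidden layer of `hidden_units`, then the class
#' layer) followed by softmax. The output of the global average pooling
#' stage is exposed as the deep-feature tap used by [extract_features()].
#'
#' @param depth 18 or 50.
#' @param n_classes Number of output classes (default 2).
#' @param pretrained If `TRUE`, initialize from a weights file supplied via
#'   `weights_file`; no download is ever attempted. Default `FALSE`: He
#'   random initialization.
#' @param weights_file Optional RDS file containing a previously saved
#'   backbone (see [save_backbone()]).
#' @param input_size Side length of the square network input in pixels
#'   (default 224, the conventional input of these architectures). Because
#'   features are taken after global average pooling, the feature dimension
#'   does not depend on this; smaller inputs give proportionally faster
#'   training and are used in examples.
#' @param hidden_units Width of the hidden fully connected layer.
#' @param seed RNG seed for the random initialization.
#' @return A `resnet_backbone` object.
#' @examples
#' m <- adapt_backbone(18, input_size = 32, seed = 1)
#' m$feature_dim  # 512
#' @export
adapt_backbone <- function(depth, n_classes = 2, pretrained = FALSE,
                           weights_file = NULL, input_size = 224,
                           hidden_units = 64, seed = 1) {
  if (!depth %in% c(18, 50)) {
    abort(sprintf("Unsupported depth %s; available depths are 18 and 50.", depth))
  }
  if (pretrained) {
    if (is.null(weights_file)) {
      abort(paste0("pretrained = TRUE requires `weights_file`: no weights are ",
                   "bundled and none are ever downloaded. Use pretrained = FALSE ",
                   "for random initialization."))
    }
    model <- load_backbone(weights_file)
    stopifnot(model$depth == depth)
    return(model)
  }
  if (input_size < 16) abort("input_size must be at least 16 pixels.")
  built <- with_seed(seed, build_resnet(depth, n_classes, hidden_units))
  structure(
    list(net = built$net, depth = as.integer(depth),
         n_classes = as.integer(n_classes),
         feature_dim = built$feature_dim, feature_layer = built$feature_layer,
         input_size = as.integer(input_size),
         hidden_units = as.integer(hidden_units), seed = as.integer(seed),
         trained = FALSE, history = NULL),
    class = "resnet_backbone"
  )
}

#' @export
print.resnet_backbone <- function(x, ...) {
  cat(sprintf(
    "<resnet_backbone> depth %d, input %dx%dx3, features %d, head %d->%d->%d%s\n",
    x$depth, x$input_size, x$input_size, x$feature_dim, x$feature_dim,
    x$hidden_units, x$n_classes,
    if (x$trained) sprintf(", trained %d epochs", nrow(x$history)) else ", untrained"))
  invisible(x)
}

#' Save / load a backbone checkpoint
#'
#' Checkpoints carry all weights, batch-norm running statistics and the
#' architecture metadata (depth, head sizes, input size, seed, history).
#'
#' @param model A `resnet_backbone`.
#' @param path RDS file path.
#' @export
save_backbone <- function(model, path) {
  stopifnot(inherits(model, "resnet_backbone"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_backbone
#' @export
load_backbone <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "resnet_backbone"))
  model
}

#' Prepare grayscale images for a backbone
#'
#' Resizes each image to the network input size with bilinear
#' interpolation and replicates the single gray channel to the three input
#' channels the pretrained-style stem expects. Intensity convention:
#' `"unit"` (default) maps 0--255 to \[0, 1\] with no further scaling;
#' `"imagenet"` additionally standardizes each channel with the usual
#' natural-image statistics (means 0.485/0.456/0.406, SDs
#' 0.229/0.224/0.225), appropriate when starting from weights trained with
#' that convention.
#'
#' @param images A list of `gray_image`s, or a manifest tibble with an
#'   `image` list-column.
#' @param size Target side length in pixels.
#' @param normalize `"unit"` or `"imagenet"`.
#' @return A numeric array `[size, size, 3, n]`.
#' @export
preprocess_images <- function(images, size = 224,
                              normalize = c("unit", "imagenet")) {
  normalize <- match.arg(normalize)
  if (is.data.frame(images)) images <- images$image
  stopifnot(length(images) >= 1)
  n <- length(images)
  out <- array(0, dim = c(size, size, 3, n))
  for (i in seq_len(n)) {
    img <- images[[i]]
    stopifnot(inherits(img, "gray_image"))
    px <- unclass(img) / 255
    if (nrow(px) != size || ncol(px) != size) {
      eb <- EBImage::resize(EBImage::Image(t(px)), w = size, h = size,
                            filter = "bilinear", antialias = FALSE)
      px <- t(EBImage::imageData(eb))
    }
    px <- pmin(1, pmax(0, px))
    for (ch in 1:3) out[, , ch, i] <- px
  }
  if (normalize == "imagenet") {
    mu <- c(0.485, 0.456, 0.406); sg <- c(0.229, 0.224, 0.225)
    for (ch in 1:3) out[, , ch, ] <- (out[, , ch, ] - mu[ch]) / sg[ch]
  }
  out
}

#' Fine-tune a backbone with SGD and momentum
#'
#' Trains for exactly `config$max_epochs` epochs on mini-batches of
#' `config$batch_size`, shuffled with the config seed each epoch, with the
#' piecewise-constant learning-rate schedule of [schedule_lr()]. Per-epoch
#' training loss/accuracy (and validation loss/accuracy when a validation
#' set is supplied) are recorded in the returned model's `history`, which
#' `tidy()` returns as a tibble. Deterministic given the seed.
#'
#' @param model A [adapt_backbone()] result.
#' @param images Training images (list of `gray_image`s or manifest tibble).
#' @param labels Binary 0/1 labels, one per image.
#' @param config A [train_config()].
#' @param val_images,val_labels Optional held-out set evaluated each epoch.
#' @param normalize Intensity convention for [preprocess_images()].
#' @param verbose Print one line per epoch.
#' @return The trained `resnet_backbone`.
#' @export
train_backbone <- function(model, images, labels, config = train_config(),
                           val_images = NULL, val_labels = NULL,
                           normalize = "unit", verbose = FALSE) {
  stopifnot(inherits(model, "resnet_backbone"), inherits(config, "train_config"))
  if (is.data.frame(images)) {
    if (missing(labels) || is.null(labels)) labels <- images$label
    images <- images$image
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    abort("Training set contains a single class; at least two are required.")
  }
  x <- preprocess_images(images, size = model$input_size, normalize = normalize)
  y <- labels + 1L
  xv <- NULL; yv <- NULL
  if (!is.null(val_images)) {
    xv <- preprocess_images(val_images, size = model$input_size, normalize = normalize)
    yv <- as.integer(if (is.data.frame(val_images)) val_images$label else val_labels) + 1L
  }
  n <- dim(x)[4]
  net <- model$net
  vel <- NULL
  hist <- vector("list", config$max_epochs)
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      lr <- schedule_lr(config, epoch)
      ord <- sample.int(n)
      batch_starts <- seq(1, n, by = config$batch_size)
      ep_loss <- 0; ep_correct <- 0
      for (bs in batch_starts) {
        idx <- ord[bs:min(bs + config$batch_size - 1, n)]
        xb <- x[, , , idx, drop = FALSE]
        fw <- nn_forward(net, xb, training = TRUE)
        net <- fw$layer
        sm <- softmax_xent(fw$y, y[idx])
        ep_loss <- ep_loss + sm$loss * length(idx)
        ep_correct <- ep_correct + sum(max.col(sm$probs, "first") == y[idx])
        bw <- nn_backward(net, fw$cache, sm$dlogits)
        st <- nn_sgd_step(net, bw$grads, vel, lr, config$momentum,
                          config$weight_decay)
        net <- st$layer; vel <- st$vel
      }
      row <- tibble::tibble(epoch = epoch, lr = lr,
                            train_loss = ep_loss / n,
                            train_accuracy = ep_correct / n,
                            val_loss = NA_real_, val_accuracy = NA_real_)
      if (!is.null(xv)) {
        model$net <- net
        pv <- predict_logits(model, xv)
        smv <- softmax_xent(pv, yv)
        row$val_loss <- smv$loss
        row$val_accuracy <- mean(max.col(smv$probs, "first") == yv)
      }
      hist[[epoch]] <- row
      if (verbose) {
        message(sprintf("epoch %d/%d lr %.4g loss %.4f acc %.3f", epoch,
                        config$max_epochs, lr, row$train_loss, row$train_accuracy))
      }
    }
  })
  model$net <- net
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(hist)
  model$config <- config
  model
}

# forward pass in evaluation mode, batched to bound memory
predict_logits <- function(model, x, batch = 64) {
  n <- dim(x)[4]
  out <- NULL
  for (bs in seq(1, n, by = batch)) {
    idx <- bs:min(bs + batch - 1, n)
    fw <- nn_forward(model$net, x[, , , idx, drop = FALSE], training = FALSE)
    out <- rbind(out, fw$y)
  }
  out
}

#' Predict class labels for images
#'
#' @param object A trained (or freshly initialized) `resnet_backbone`.
#' @param images Images as in [train_backbone()].
#' @param normalize Intensity convention for [preprocess_images()].
#' @param ... Unused.
#' @return Integer vector of 0/1 predictions.
#' @export
predict.resnet_backbone <- function(object, images, normalize = "unit", ...) {
  if (is.data.frame(images)) images <- images$image
  x <- preprocess_images(images, size = object$input_size, normalize = normalize)
  logits <- predict_logits(object, x)
  as.integer(max.col(logits, "first") - 1L)
}

#' Extract penultimate deep features
#'
#' Runs the network in evaluation mode and returns the activation of the
#' global-average-pooling stage: 512 columns for depth 18, 2048 for depth
#' 50, one row per input image in input order. A pure function of the
#' weights and the images.
#'
#' @inheritParams predict.resnet_backbone
#' @param model A `resnet_backbone`.
#' @param batch Images per forward batch.
#' @return An `n x feature_dim` numeric matrix.
#' @export
extract_features <- function(model, images, normalize = "unit", batch = 64) {
  stopifnot(inherits(model, "resnet_backbone"))
  if (is.data.frame(images)) images <- images$image
  if (length(images) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = model$feature_dim))
  }
  x <- preprocess_images(images, size = model$input_size, normalize = normalize)
  n <- dim(x)[4]
  feats <- matrix(NA_real_, n, model$feature_dim)
  sub <- layer_seq(model$net$layers[seq_len(model$feature_layer)])
  for (bs in seq(1, n, by = batch)) {
    idx <- bs:min(bs + batch - 1, n)
    fw <- nn_forward(sub, x[, , , idx, drop = FALSE], training = FALSE)
    feats[idx, ] <- fw$y
  }
  feats
}

#' @export
tidy.resnet_backbone <- function(x, ...) {
  if (is.null(x$history)) {
    abort("The backbone has not been trained; no curves to tidy.")
  }
  x$history
}

#' @export
glance.resnet_backbone <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    depth = x$depth, feature_dim = x$feature_dim,
    epochs = if (is.null(h)) 0L else nrow(h),
    final_train_accuracy = if (is.null(h)) NA_real_ else h$train_accuracy[nrow(h)],
    final_val_accuracy = if (is.null(h)) NA_real_ else h$val_accuracy[nrow(h)]
  )
}

#' Plot training curves
#' @param object A trained `resnet_backbone`.
#' @param ... Unused.
#' @export
autoplot.resnet_backbone <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, -c("epoch", "lr"),
                              names_to = "series", values_to = "value")
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = sprintf("Depth-%d backbone fine-tuning", object$depth)) +
    ggplot2::theme_minimal()
}
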