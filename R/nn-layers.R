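# Neural-network layer primitives used by the residual backbones.
# Activations are [H, W, C, N] arrays between convolutions and N x d
# matrices after global average pooling. Each layer is a plain list with a
# `type`; nn_forward() returns the output, a cache for backprop and the
# (possibly updated) layer, nn_backward() returns the input gradient and a
# gradient list mirroring the layer's parameters.

layer_conv <- function(kh, kw, c_in, c_out, stride = 1, pad = 0) {
  sd <- sqrt(2 / (kh * kw * c_in))   # He initialization
  list(type = "conv",
       w = array(rnorm(kh * kw * c_in * c_out, sd = sd),
                 dim = c(kh, kw, c_in, c_out)),
       b = numeric(c_out), stride = as.integer(stride), pad = as.integer(pad))
}

layer_bn <- function(c_out, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", gamma = rep(1, c_out), beta = numeric(c_out),
       run_mean = numeric(c_out), run_var = rep(1, c_out),
       eps = eps, momentum = momentum)
}

layer_relu <- function() list(type = "relu")
layer_maxpool <- function(k, stride, pad = 0) {
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))
}
layer_gap <- function() list(type = "gap")
layer_fc <- function(d_in, d_out) {
  list(type = "fc",
       w = matrix(rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}
layer_seq <- function(layers) list(type = "seq", layers = layers)
layer_res <- function(main, shortcut = NULL) {
  list(type = "res", main = main, shortcut = shortcut)
}

# reshape [H,W,C,N] -> (H*W*N) x C and back, for per-channel batch norm
to_channel_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}
from_channel_mat <- function(m, d) {
  aperm(array(m, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
}

nn_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      y <- conv2d_forward_cpp(x, layer$w, layer$b, layer$stride, layer$pad)
      list(y = y, cache = list(x = x), layer = layer)
    },
    bn = {
      d <- dim(x)
      xm <- to_channel_mat(x)
      if (training) {
        mu <- colMeans(xm)
        v <- colMeans(xm^2) - mu^2
        layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
        layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
      } else {
        mu <- layer$run_mean; v <- layer$run_var
      }
      invstd <- 1 / sqrt(v + layer$eps)
      xhat <- sweep(sweep(xm, 2, mu), 2, invstd, "*")
      ym <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
      list(y = from_channel_mat(ym, d),
           cache = list(xhat = xhat, invstd = invstd, d = d), layer = layer)
    },
    relu = list(y = pmax(x, 0), cache = list(mask = x > 0), layer = layer),
    maxpool = {
      r <- maxpool_forward_cpp(x, layer$k, layer$stride, layer$pad)
      list(y = r$y, cache = list(argmax = r$argmax, xdim = dim(x)), layer = layer)
    },
    gap = {
      d <- dim(x)
      y <- t(matrix(colMeans(matrix(x, d[1] * d[2])), d[3], d[4]))
      list(y = y, cache = list(d = d), layer = layer)
    },
    fc = list(y = sweep(x %*% layer$w, 2, layer$b, "+"),
              cache = list(x = x), layer = layer),
    seq = {
      caches <- vector("list", length(layer$layers))
      for (i in seq_along(layer$layers)) {
        r <- nn_forward(layer$layers[[i]], x, training)
        x <- r$y; caches[[i]] <- r$cache; layer$layers[[i]] <- r$layer
      }
      list(y = x, cache = caches, layer = layer)
    },
    res = {
      rm_ <- nn_forward(layer$main, x, training)
      layer$main <- rm_$layer
      if (is.null(layer$shortcut)) {
        s <- x; sc <- NULL
      } else {
        rs <- nn_forward(layer$shortcut, x, training)
        s <- rs$y; sc <- rs$cache; layer$shortcut <- rs$layer
      }
      z <- rm_$y + s
      list(y = pmax(z, 0),
           cache = list(main = rm_$cache, shortcut = sc, mask = z > 0),
           layer = layer)
    },
    abort(sprintf("Unknown layer type '%s'.", layer$type))
  )
}

nn_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      g <- conv2d_backward_cpp(cache$x, layer$w, dy, layer$stride, layer$pad)
      list(dx = g$dx, grads = list(w = g$dw, b = g$db))
    },
    bn = {
      d <- cache$d
      m_rows <- nrow(cache$xhat)
      dym <- to_channel_mat(dy)
      dgamma <- colSums(dym * cache$xhat)
      dbeta <- colSums(dym)
      dxhat <- sweep(dym, 2, layer$gamma, "*")
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * cache$xhat)
      dxm <- sweep(
        dxhat * m_rows -
          matrix(s1, m_rows, ncol(dym), byrow = TRUE) -
          cache$xhat * matrix(s2, m_rows, ncol(dym), byrow = TRUE),
        2, cache$invstd / m_rows, "*")
      list(dx = from_channel_mat(dxm, d),
           grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dy * cache$mask, grads = NULL),
    maxpool = list(dx = maxpool_backward_cpp(dy, cache$argmax, cache$xdim),
                   grads = NULL),
    gap = {
      d <- cache$d
      per_pix <- t(dy) / (d[1] * d[2])                  # C x N
      dx <- array(rep(as.vector(per_pix), each = d[1] * d[2]), dim = d)
      list(dx = dx, grads = NULL)
    },
    fc = list(dx = dy %*% t(layer$w),
              grads = list(w = t(cache$x) %*% dy, b = colSums(dy))),
    seq = {
      grads <- vector("list", length(layer$layers))
      for (i in rev(seq_along(layer$layers))) {
        r <- nn_backward(layer$layers[[i]], cache[[i]], dy)
        dy <- r$dx
        grads[i] <- list(r$grads)   # keep NULL slots for parameter-free layers
      }
      list(dx = dy, grads = grads)
    },
    res = {
      dz <- dy * cache$mask
      rm_ <- nn_backward(layer$main, cache$main, dz)
      if (is.null(layer$shortcut)) {
        dx <- rm_$dx + dz
        gs <- NULL
      } else {
        rs <- nn_backward(layer$shortcut, cache$shortcut, dz)
        dx <- rm_$dx + rs$dx
        gs <- rs$grads
      }
      list(dx = dx, grads = list(main = rm_$grads, shortcut = gs))
    }
  )
}

# SGD with momentum: v <- momentum * v - lr * (g + weight_decay * w); w <- w + v.
# Walks the layer tree and the parallel gradient/velocity trees.
nn_sgd_step <- function(layer, grads, vel, lr, momentum, weight_decay = 0) {
  upd <- function(w, g, v) {
    if (is.null(v)) v <- g * 0
    v <- momentum * v - lr * (g + weight_decay * w)
    list(w = w + v, v = v)
  }
  switch(layer$type,
    conv = , fc = {
      uw <- upd(layer$w, grads$w, vel$w); ub <- upd(layer$b, grads$b, vel$b)
      layer$w <- uw$w; layer$b <- ub$w
      list(layer = layer, vel = list(w = uw$v, b = ub$v))
    },
    bn = {
      ug <- upd(layer$gamma, grads$gamma, vel$gamma)
      ub <- upd(layer$beta, grads$beta, vel$beta)
      layer$gamma <- ug$w; layer$beta <- ub$w
      list(layer = layer, vel = list(gamma = ug$v, beta = ub$v))
    },
    seq = {
      if (is.null(vel)) vel <- vector("list", length(layer$layers))
      for (i in seq_along(layer$layers)) {
        if (is.null(grads[[i]])) next
        r <- nn_sgd_step(layer$layers[[i]], grads[[i]], vel[[i]],
                         lr, momentum, weight_decay)
        layer$layers[[i]] <- r$layer; vel[[i]] <- r$vel
      }
      list(layer = layer, vel = vel)
    },
    res = {
      if (is.null(vel)) vel <- list(main = NULL, shortcut = NULL)
      rm_ <- nn_sgd_step(layer$main, grads$main, vel$main,
                         lr, momentum, weight_decay)
      layer$main <- rm_$layer; vel$main <- rm_$vel
      if (!is.null(layer$shortcut) && !is.null(grads$shortcut)) {
        rs <- nn_sgd_step(layer$shortcut, grads$shortcut, vel$shortcut,
                          lr, momentum, weight_decay)
        layer$shortcut <- rs$layer; vel$shortcut <- rs$vel
      }
      list(layer = layer, vel = vel)
    },
    list(layer = layer, vel = vel)
  )
}

# mean cross-entropy over softmax logits; labels are 1-based class indices
softmax_xent <- function(logits, labels) {
  n <- nrow(logits)
  z <- logits - apply(logits, 1, max)
  p <- exp(z) / rowSums(exp(z))
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}
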