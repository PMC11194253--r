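# Internal layer engine for the convolutional classifiers.
#
# Spatial activations are (H*W*N) x C matrices (row index h + H*(w + W*n),
# 0-based) carrying H/W/N as attributes; after flattening they are plain
# feature x sample matrices. Each layer implements a forward pass (returning
# output, a cache for the backward pass, and the possibly-updated layer —
# batch norm advances its running statistics) and a backward pass
# (returning the input gradient and parameter gradients).

# fast per-column (channel) arithmetic on (positions x channels) matrices;
# rep(v, each = nrow) is C-level and much cheaper than sweep()'s aperm
col_op <- function(x, v, op) {
  r <- op(x, rep(v, each = nrow(x)))
  dim(r) <- dim(x)
  r
}

sp_attr <- function(m, H, W, N) {
  attr(m, "H") <- H; attr(m, "W") <- W; attr(m, "N") <- N
  m
}
sp_dims <- function(m) c(H = attr(m, "H"), W = attr(m, "W"), N = attr(m, "N"))

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

layer_conv <- function(in_c, out_c, k = 3L, stride = 1L) {
  pad <- k %/% 2L
  list(type = "conv", in_c = in_c, out_c = out_c, k = as.integer(k),
       stride = as.integer(stride), pad = if (k == 1L) 0L else pad,
       Wt = he_init(k * k * in_c, out_c, k * k * in_c),
       b = numeric(out_c))
}
layer_bn <- function(channels) {
  list(type = "bn", channels = channels, gamma = rep(1, channels),
       beta = numeric(channels), rm = numeric(channels), rv = rep(1, channels),
       momentum = 0.9, eps = 1e-5)
}
layer_relu <- function() list(type = "relu")
layer_maxpool <- function() list(type = "maxpool")
layer_flatten <- function() list(type = "flatten")
layer_gap <- function() list(type = "gap")
layer_dropout <- function(rate) list(type = "dropout", rate = rate)
layer_dense <- function(in_n, out_n) {
  list(type = "dense", W = he_init(out_n, in_n, in_n), b = numeric(out_n))
}
layer_residual <- function(in_c, out_c, stride = 1L, k = 3L) {
  main <- list(layer_conv(in_c, out_c, k, stride), layer_bn(out_c), layer_relu(),
               layer_conv(out_c, out_c, k, 1L), layer_bn(out_c))
  shortcut <- if (stride != 1L || in_c != out_c) {
    list(layer_conv(in_c, out_c, 1L, stride), layer_bn(out_c))
  } else NULL
  list(type = "residual", main = main, shortcut = shortcut)
}

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv = {
      d <- sp_dims(x)
      xcol <- im2col_cpp(x, d[["H"]], d[["W"]], d[["N"]],
                         layer$k, layer$stride, layer$pad)
      y <- xcol %*% layer$Wt
      y <- col_scale_shift_cpp(y, rep(1, ncol(y)), layer$b)
      ho <- (d[["H"]] + 2 * layer$pad - layer$k) %/% layer$stride + 1L
      wo <- (d[["W"]] + 2 * layer$pad - layer$k) %/% layer$stride + 1L
      list(out = sp_attr(y, ho, wo, d[["N"]]), layer = layer,
           cache = list(xcol = xcol, in_dims = d))
    },
    bn = {
      d <- sp_dims(x)
      if (training) {
        st <- bn_stats_cpp(x)
        mu <- st$mu; va <- st$va
        inv_sd <- 1 / sqrt(va + layer$eps)
        xhat <- col_scale_shift_cpp(x, inv_sd, -mu * inv_sd)
        layer$rm <- layer$momentum * layer$rm + (1 - layer$momentum) * mu
        layer$rv <- layer$momentum * layer$rv + (1 - layer$momentum) * va
        cache <- list(xhat = xhat, mu = mu, va = va, training = TRUE)
      } else {
        inv_sd <- 1 / sqrt(layer$rv + layer$eps)
        xhat <- col_scale_shift_cpp(x, inv_sd, -layer$rm * inv_sd)
        cache <- list(training = FALSE)
      }
      y <- col_scale_shift_cpp(xhat, layer$gamma, layer$beta)
      out <- if (!is.null(d[["H"]]) && !is.na(d[["H"]])) {
        sp_attr(y, d[["H"]], d[["W"]], d[["N"]])
      } else y
      list(out = out, layer = layer, cache = cache)
    },
    relu = {
      if (is.matrix(x)) {
        y <- relu_cpp(x)
        d <- sp_dims(x)
        if (!is.null(d[["H"]])) y <- sp_attr(y, d[["H"]], d[["W"]], d[["N"]])
      } else {
        y <- pmax(x, 0)
      }
      list(out = y, layer = layer, cache = list(out = y))
    },
    maxpool = {
      d <- sp_dims(x)
      r <- maxpool2_cpp(x, d[["H"]], d[["W"]], d[["N"]])
      list(out = sp_attr(r$out, d[["H"]] %/% 2L, d[["W"]] %/% 2L, d[["N"]]),
           layer = layer,
           cache = list(argmax = r$argmax, in_rows = nrow(x)))
    },
    flatten = {
      d <- sp_dims(x)
      hw <- d[["H"]] * d[["W"]]
      a <- array(x, dim = c(hw, d[["N"]], ncol(x)))
      y <- matrix(aperm(a, c(1, 3, 2)), nrow = hw * ncol(x), ncol = d[["N"]])
      list(out = y, layer = layer, cache = list(d = d, C = ncol(x)))
    },
    gap = {
      d <- sp_dims(x)
      hw <- d[["H"]] * d[["W"]]
      a <- array(x, dim = c(hw, d[["N"]], ncol(x)))
      y <- t(colMeans(a))                       # channels x samples
      list(out = y, layer = layer, cache = list(d = d, C = ncol(x)))
    },
    dense = {
      list(out = layer$W %*% x + layer$b, layer = layer, cache = list(x = x))
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- (stats::runif(length(x)) >= layer$rate) / (1 - layer$rate)
        dim(mask) <- dim(x)
        list(out = x * mask, layer = layer, cache = list(mask = mask))
      } else {
        list(out = x, layer = layer, cache = list(mask = NULL))
      }
    },
    residual = {
      main <- seq_forward(layer$main, x, training)
      if (is.null(layer$shortcut)) {
        sc_out <- x
        sc <- NULL
      } else {
        sc <- seq_forward(layer$shortcut, x, training)
        sc_out <- sc$out
      }
      s <- main$out + sc_out
      d <- sp_dims(main$out)
      y <- s
      y[y < 0] <- 0
      layer$main <- main$layers
      if (!is.null(sc)) layer$shortcut <- sc$layers
      list(out = sp_attr(y, d[["H"]], d[["W"]], d[["N"]]), layer = layer,
           cache = list(main = main$caches, shortcut = if (is.null(sc)) NULL else sc$caches,
                        sum_pos = s > 0, identity_shortcut = is.null(sc)))
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = {
      d <- cache$in_dims
      db <- colSums(dout)
      dWt <- crossprod(cache$xcol, dout)
      dxcol <- tcrossprod(dout, layer$Wt)
      dx <- col2im_cpp(dxcol, d[["H"]], d[["W"]], layer$in_c, d[["N"]],
                       layer$k, layer$stride, layer$pad)
      list(dx = sp_attr(dx, d[["H"]], d[["W"]], d[["N"]]),
           grads = list(Wt = dWt, b = db))
    },
    bn = {
      if (cache$training) {
        r <- bn_backward_cpp(dout, cache$xhat, layer$gamma,
                             1 / sqrt(cache$va + layer$eps))
        list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
      } else {
        scale <- layer$gamma / sqrt(layer$rv + layer$eps)
        list(dx = col_op(dout, scale, `*`),
             grads = list(gamma = numeric(layer$channels),
                          beta = numeric(layer$channels)))
      }
    },
    relu = list(dx = relu_backward_cpp(dout, cache$out), grads = NULL),
    maxpool = {
      list(dx = maxpool2_backward_cpp(dout, cache$argmax, cache$in_rows),
           grads = NULL)
    },
    flatten = {
      d <- cache$d
      hw <- d[["H"]] * d[["W"]]
      a <- array(dout, dim = c(hw, cache$C, d[["N"]]))
      dx <- matrix(aperm(a, c(1, 3, 2)), nrow = hw * d[["N"]], ncol = cache$C)
      list(dx = sp_attr(dx, d[["H"]], d[["W"]], d[["N"]]), grads = NULL)
    },
    gap = {
      d <- cache$d
      hw <- d[["H"]] * d[["W"]]
      # dout is channels x samples; spread evenly over positions
      dx <- matrix(0, hw * d[["N"]], cache$C)
      for (ch in seq_len(cache$C)) {
        dx[, ch] <- rep(dout[ch, ], each = hw) / hw
      }
      list(dx = sp_attr(dx, d[["H"]], d[["W"]], d[["N"]]), grads = NULL)
    },
    dense = {
      list(dx = crossprod(layer$W, dout),
           grads = list(W = tcrossprod(dout, cache$x), b = rowSums(dout)))
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask, grads = NULL)
    },
    residual = {
      dsum <- dout * cache$sum_pos
      main_b <- seq_backward(layer$main, cache$main, dsum)
      if (cache$identity_shortcut) {
        dx <- main_b$dx + dsum
        sc_grads <- NULL
      } else {
        sc_b <- seq_backward(layer$shortcut, cache$shortcut, dsum)
        dx <- main_b$dx + sc_b$dx
        sc_grads <- sc_b$grads
      }
      list(dx = dx, grads = list(main = main_b$grads, shortcut = sc_grads))
    },
    stop("unknown layer type: ", layer$type)
  )
}

seq_forward <- function(layers, x, training, keep_activations = FALSE) {
  caches <- vector("list", length(layers))
  acts <- if (keep_activations) vector("list", length(layers) + 1L) else NULL
  if (keep_activations) acts[[1L]] <- x
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, training)
    x <- r$out
    layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    if (keep_activations) acts[[i + 1L]] <- x
  }
  list(out = x, layers = layers, caches = caches, activations = acts)
}

seq_backward <- function(layers, caches, dout, stop_at = 0L) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    if (i <= stop_at) break
    r <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[i] <- list(r$grads)          # keep NULL slots for layers without params
  }
  list(dx = dout, grads = grads)
}

# --- parameter bookkeeping -------------------------------------------------

param_fields <- function(type) {
  switch(type, conv = c("Wt", "b"), bn = c("gamma", "beta"),
         dense = c("W", "b"), NULL)
}

# list of paths (each a list of keys) addressing every trainable array
collect_param_paths <- function(layers, prefix = list()) {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "residual") {
      out <- c(out, collect_param_paths(l$main, c(prefix, list(i, "main"))))
      if (!is.null(l$shortcut)) {
        out <- c(out, collect_param_paths(l$shortcut, c(prefix, list(i, "shortcut"))))
      }
    } else {
      for (f in param_fields(l$type)) {
        out <- c(out, list(c(prefix, list(i, f))))
      }
    }
  }
  out
}

pluck_path <- function(obj, path) Reduce(function(o, k) o[[k]], path, obj)

assign_path <- function(obj, path, value) {
  if (length(path) == 1L) {
    obj[[path[[1L]]]] <- value
    return(obj)
  }
  obj[[path[[1L]]]] <- assign_path(obj[[path[[1L]]]], path[-1L], value)
  obj
}
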