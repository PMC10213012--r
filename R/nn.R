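# Compact convolutional-network engine used by the translation model.
#
# Tensors are numeric arrays in (H, W, C) layout, batch size 1 (the training
# loop follows the one-image-per-step convention of unpaired translation).
# Each layer is a plain list carrying its parameters; forward passes return
# caches that the matching backward pass consumes. Convolutions run through
# the compiled im2col/GEMM kernels.

as_tensor <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1)) else x
}

nn_rnorm <- function(n, sd = 0.02) rnorm(n, sd = sd)

layer_conv <- function(k, cin, cout, stride = 1, pad = (k - 1) %/% 2,
                       reflect = FALSE, init = c("gauss", "zero")) {
  init <- match.arg(init)
  w <- if (init == "zero") array(0, c(k, k, cin * cout))
       else array(nn_rnorm(k * k * cin * cout), c(k, k, cin * cout))
  list(type = "conv", k = as.integer(k), cin = as.integer(cin),
       cout = as.integer(cout), stride = as.integer(stride),
       pad = as.integer(pad), reflect = reflect,
       params = list(w = w, b = numeric(cout)))
}

layer_inorm <- function(c, eps = 1e-5) {
  list(type = "inorm", c = as.integer(c), eps = eps,
       params = list(gamma = rep(1, c), beta = numeric(c)))
}

layer_act <- function(kind = c("relu", "lrelu", "tanh", "sigmoid"),
                      slope = 0.2) {
  kind <- match.arg(kind)
  list(type = "act", kind = kind, slope = slope, params = list())
}

layer_up2 <- function() list(type = "up2", params = list())

layer_resblock <- function(c, reflect = TRUE) {
  list(type = "resblock", params = list(),
       sub = list(layer_conv(3, c, c, reflect = reflect),
                  layer_inorm(c),
                  layer_act("relu"),
                  layer_conv(3, c, c, reflect = reflect),
                  layer_inorm(c)))
}

upsample2_nearest <- function(x) {
  x <- as_tensor(x)
  d <- dim(x)
  idx_r <- rep(seq_len(d[1]), each = 2)
  idx_c <- rep(seq_len(d[2]), each = 2)
  x[idx_r, idx_c, , drop = FALSE]
}

upsample2_adjoint <- function(gy) {
  d <- dim(gy)
  h <- d[1] %/% 2; w <- d[2] %/% 2
  gy[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
    gy[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
    gy[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
    gy[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]
}

avgpool2 <- function(x) {
  x <- as_tensor(x)
  d <- dim(x)
  (x[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
     x[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
     x[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
     x[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]) / 4
}

avgpool2_adjoint <- function(gy) {
  upsample2_nearest(gy) / 4
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      y <- conv2d_forward_cpp(x, layer$params$w, layer$params$b, layer$k,
                              layer$cin, layer$cout, layer$stride, layer$pad,
                              layer$reflect)
      list(y = y, cache = x)
    },
    inorm = {
      d <- dim(x)
      n <- d[1] * d[2]
      xm <- matrix(x, n, d[3])
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      v <- colSums(xc^2) / n
      invstd <- 1 / sqrt(v + layer$eps)
      xhat <- sweep(xc, 2, invstd, `*`)
      y <- sweep(sweep(xhat, 2, layer$params$gamma, `*`), 2,
                 layer$params$beta, `+`)
      list(y = array(y, d), cache = list(xhat = xhat, invstd = invstd, d = d))
    },
    act = {
      y <- switch(layer$kind,
        relu = pmax(x, 0),
        lrelu = ifelse(x > 0, x, layer$slope * x),
        tanh = tanh(x),
        sigmoid = 1 / (1 + exp(-x)))
      list(y = y, cache = list(x = x, y = y))
    },
    up2 = list(y = upsample2_nearest(x), cache = NULL),
    resblock = {
      f <- net_forward(layer$sub, x)
      list(y = x + f$y, cache = f$caches)
    },
    stop("unknown layer type ", layer$type))
}

layer_backward <- function(layer, cache, gy) {
  switch(layer$type,
    conv = {
      bk <- conv2d_backward_cpp(cache, layer$params$w, gy, layer$k,
                                layer$cin, layer$cout, layer$stride,
                                layer$pad, layer$reflect)
      list(gx = bk$gx, grads = list(w = bk$gw, b = as.numeric(bk$gb)))
    },
    inorm = {
      d <- cache$d
      n <- d[1] * d[2]
      gym <- matrix(gy, n, d[3])
      ggamma <- colSums(gym * cache$xhat)
      gbeta <- colSums(gym)
      gh <- sweep(gym, 2, layer$params$gamma, `*`)
      gx <- if (isTRUE(layer$frozen)) {
        # frozen-statistics mode: treat mean/var as constants (used when
        # measuring the local connectivity of the convolutional path)
        sweep(gh, 2, cache$invstd, `*`)
      } else {
        sweep(gh - matrix(colMeans(gh), n, d[3], byrow = TRUE) -
                cache$xhat * matrix(colMeans(gh * cache$xhat), n, d[3],
                                    byrow = TRUE),
              2, cache$invstd, `*`)
      }
      list(gx = array(gx, d), grads = list(gamma = ggamma, beta = gbeta))
    },
    act = {
      gx <- switch(layer$kind,
        relu = gy * (cache$x > 0),
        lrelu = gy * ifelse(cache$x > 0, 1, layer$slope),
        tanh = gy * (1 - cache$y^2),
        sigmoid = gy * cache$y * (1 - cache$y))
      list(gx = gx, grads = list())
    },
    up2 = list(gx = upsample2_adjoint(gy), grads = list()),
    resblock = {
      bk <- net_backward(layer$sub, cache, gy)
      list(gx = gy + bk$gx, grads = bk$grads)
    })
}

net_forward <- function(layers, x, ...) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    out <- layer_forward(layers[[i]], x)
    x <- out$y
    caches[[i]] <- out$cache
  }
  list(y = x, caches = caches)
}

net_backward <- function(layers, caches, gy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bk <- layer_backward(layers[[i]], caches[[i]], gy)
    gy <- bk$gx
    grads[[i]] <- bk$grads
  }
  list(gx = gy, grads = grads)
}

# --- parameter tree utilities ----------------------------------------------
# A "tree" is an arbitrary nesting of lists whose leaves are layers
# (recognized by their $type field). Gradient trees mirror the layer trees:
# a parameterized layer maps to its named grads, a composite layer (with
# $sub) to the unnamed list of its sublayers' grads, as produced by
# net_backward.

is_nn_layer <- function(x) is.list(x) && !is.null(x$type)

net_param_count <- function(node) {
  if (is_nn_layer(node)) {
    n <- sum(vapply(node$params, length, 0L))
    if (!is.null(node$sub)) n <- n + net_param_count(node$sub)
    return(n)
  }
  if (is.list(node)) return(sum(vapply(node, net_param_count, 0)))
  0
}

# zero gradient tree matching the structure net_backward produces
zero_grads <- function(node) {
  if (is_nn_layer(node)) {
    if (!is.null(node$sub)) return(lapply(node$sub, zero_grads))
    return(lapply(node$params, function(p) p * 0))
  }
  lapply(node, zero_grads)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(tree) {
  list(t = 0, m = zero_grads(tree), v = zero_grads(tree))
}

# one Adam step over an arbitrary layer tree; NULL gradient branches (e.g.
# frozen sub-networks) are skipped
adam_step <- function(tree, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  upd <- function(node, g, m, v) {
    if (is.null(g)) return(list(node = node, m = m, v = v))
    if (is_nn_layer(node)) {
      if (!is.null(node$sub)) {
        for (i in seq_along(node$sub)) {
          r <- upd(node$sub[[i]], g[[i]], m[[i]], v[[i]])
          node$sub[[i]] <- r$node; m[[i]] <- r$m; v[[i]] <- r$v
        }
      } else {
        for (nm in names(node$params)) {
          if (is.null(g[[nm]])) next
          m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
          v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
          node$params[[nm]] <- node$params[[nm]] -
            lr * (m[[nm]] / (1 - beta1^t)) /
              (sqrt(v[[nm]] / (1 - beta2^t)) + eps)
        }
      }
    } else {
      nms <- names(node)
      for (i in seq_along(node)) {
        gi <- if (is.null(nms)) g[[i]] else g[[nms[i]]]
        if (is.null(gi)) next
        r <- upd(node[[i]], gi, m[[i]], v[[i]])
        node[[i]] <- r$node; m[[i]] <- r$m; v[[i]] <- r$v
      }
    }
    list(node = node, m = m, v = v)
  }
  out <- upd(tree, grads, state$m, state$v)
  state$m <- out$m
  state$v <- out$v
  list(tree = out$node, state = state)
}

# accumulate two grad trees of identical structure; either may be NULL
grads_add <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  if (is.null(g2)) return(g1)
  if (is.list(g1)) {
    nms <- names(g2)
    if (is.null(nms)) {
      for (i in seq_along(g2)) {
        s <- grads_add(g1[[i]], g2[[i]])
        if (!is.null(s)) g1[[i]] <- s
      }
    } else {
      for (nm in nms) {
        s <- grads_add(g1[[nm]], g2[[nm]])
        if (!is.null(s)) g1[[nm]] <- s   # assigning NULL would drop the slot
      }
    }
    g1
  } else {
    g1 + g2
  }
}
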