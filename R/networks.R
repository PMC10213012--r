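#' Receptive field of a stack of square convolutions
#'
#' Standard recurrence (the field grows by `(k - 1) * j` per layer while the
#' jump `j` doubles at each stride-2 layer) applied over
#' the stride-2 stages first and the stride-1 stages (including the 1-channel
#' output convolution) last. A 4x4-kernel patch discriminator with four
#' stride-2 and two stride-1 layers sees 142 x 142 input pixels per output
#' unit.
#'
#' @param kernel kernel size in pixels (>= 1).
#' @param stride2_layers number of stride-2 convolutions.
#' @param stride1_layers number of stride-1 convolutions (default 2: one
#'   feature layer plus the output convolution).
#' @return receptive field in pixels.
#' @export
receptive_field <- function(kernel = 4, stride2_layers = 4,
                            stride1_layers = 2) {
  stopifnot(kernel >= 1, stride2_layers >= 0, stride1_layers >= 0)
  r <- 1; j <- 1
  for (i in seq_len(stride2_layers)) {
    r <- r + (kernel - 1) * j
    j <- j * 2
  }
  for (i in seq_len(stride1_layers)) {
    r <- r + (kernel - 1) * j
  }
  r
}

#' Generator architecture specification
#'
#' An encoder of stride-2 stages, a chain of residual blocks, and a mirrored
#' nearest-upsample + convolution decoder, mapping an image to an equal-size
#' image with `out_channels` channels bounded by a final tanh. With
#' `hierarchical = TRUE` the generator is a coarse-to-fine pair: a global
#' network at the low scale plus a local enhancer at the high scale
#' (`high = 2 * low`).
#'
#' @param in_channels,out_channels channel counts (1 radiograph, K+1
#'   decomposed).
#' @param residual_blocks residual block count (9 at full scale).
#' @param downsample_layers stride-2 encoder stages (3 for the single-scale
#'   variants, 2 for the hierarchical ones).
#' @param base_width feature width of the first stage.
#' @param hierarchical logical.
#' @param scales length-2 (low, high) image sizes when hierarchical.
#' @param g2_residual_blocks residual blocks in the local enhancer.
#' @return a `generator_spec`.
#' @export
generator_spec <- function(in_channels, out_channels, residual_blocks = 9,
                           downsample_layers = 3, base_width = 64,
                           hierarchical = FALSE, scales = c(64, 128),
                           g2_residual_blocks = 3) {
  stopifnot(residual_blocks >= 1, downsample_layers %in% 2:5, base_width >= 1)
  if (hierarchical && scales[2] != 2 * scales[1])
    stop("hierarchical scales must satisfy high = 2 * low")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 residual_blocks = as.integer(residual_blocks),
                 downsample_layers = as.integer(downsample_layers),
                 base_width = as.integer(base_width),
                 hierarchical = hierarchical, scales = as.integer(scales),
                 g2_residual_blocks = as.integer(g2_residual_blocks)),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' Fully-convolutional patch classifier: `stride2_layers` stride-2 4x4
#' convolutions, one stride-1 feature convolution and a stride-1 1-channel
#' output convolution, sigmoid-bounded. Its receptive field (the "patch
#' size") follows [receptive_field()].
#'
#' @param in_channels input channels.
#' @param stride2_layers stride-2 stages (4 for the single-scale variants,
#'   3 for the hierarchical ones).
#' @param base_width first-stage width.
#' @param kernel kernel size (4).
#' @param norm `"instance"` (default) or `"none"`. Instance normalization
#'   couples all pixels through its image-wide statistics, so strict
#'   spatial locality of the score map holds only for the convolutional
#'   path (see [measure_receptive_field()]) or for a norm-free build.
#' @return a `discriminator_spec` with derived `receptive_field`.
#' @export
discriminator_spec <- function(in_channels, stride2_layers = 4,
                               base_width = 64, kernel = 4,
                               norm = c("instance", "none")) {
  norm <- match.arg(norm)
  stopifnot(stride2_layers >= 1, kernel >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 stride2_layers = as.integer(stride2_layers),
                 base_width = as.integer(base_width),
                 kernel = as.integer(kernel), norm = norm,
                 receptive_field = receptive_field(kernel, stride2_layers, 2)),
            class = "discriminator_spec")
}

generator_backbone <- function(spec) {
  w <- spec$base_width
  layers <- list(layer_conv(7, spec$in_channels, w, reflect = TRUE),
                 layer_inorm(w), layer_act("relu"))
  cw <- w
  for (i in seq_len(spec$downsample_layers)) {
    layers <- c(layers, list(layer_conv(3, cw, cw * 2, stride = 2),
                             layer_inorm(cw * 2), layer_act("relu")))
    cw <- cw * 2
  }
  for (i in seq_len(spec$residual_blocks)) {
    layers <- c(layers, list(layer_resblock(cw)))
  }
  for (i in seq_len(spec$downsample_layers)) {
    layers <- c(layers, list(layer_up2(), layer_conv(3, cw, cw %/% 2),
                             layer_inorm(cw %/% 2), layer_act("relu")))
    cw <- cw %/% 2
  }
  layers
}

#' Build a single-scale generator
#'
#' @param spec a [generator_spec()].
#' @return an `xdecomp_generator` (backbone + output head); apply it with
#'   [generator_forward()].
#' @export
build_generator <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  structure(list(backbone = generator_backbone(spec),
                 head = layer_conv(7, spec$base_width, spec$out_channels,
                                   reflect = TRUE),
                 spec = spec),
            class = "xdecomp_generator")
}

#' Run a generator on an image tensor
#'
#' Inputs and outputs live on the internal \[-1, 1\] scale; use
#' [decompose()] for the user-facing \[0, 255\] interface.
#'
#' @param gen an `xdecomp_generator`.
#' @param x (H, W, in_channels) array.
#' @param want_cache keep caches for backprop.
#' @return list with `y` (tanh output), `logits`, `feat` (pre-head feature)
#'   and caches.
#' @export
generator_forward <- function(gen, x, want_cache = FALSE) {
  b <- net_forward(gen$backbone, as_tensor(x))
  h <- layer_forward(gen$head, b$y)
  y <- tanh(h$y)
  if (want_cache) {
    list(y = y, logits = h$y, feat = b$y,
         caches = list(backbone = b$caches, head = h$cache))
  } else {
    list(y = y, logits = h$y, feat = b$y)
  }
}

# backward through a generator; gy is the gradient at the tanh output,
# g_feat an optional extra gradient injected at the pre-head feature
generator_backward <- function(gen, fw, gy, g_feat = NULL) {
  gz <- gy * (1 - fw$y^2)
  hb <- layer_backward(gen$head, fw$caches$head, gz)
  gfeat <- hb$gx
  if (!is.null(g_feat)) gfeat <- gfeat + g_feat
  bb <- net_backward(gen$backbone, fw$caches$backbone, gfeat)
  list(gx = bb$gx, grads = list(backbone = bb$grads, head = hb$grads))
}

#' Build a hierarchical (coarse-to-fine) generator pair
#'
#' The global generator `g1` works at the low scale. The local enhancer
#' `g2` consumes the high-scale input, downsamples once, adds `g1`'s
#' pre-head feature map, refines it through residual blocks, and upsamples
#' back; its output convolution is zero-initialized, so at initialization
#' the composed output equals the nearest-upsampled `g1` output exactly.
#'
#' @param spec a [generator_spec()] with `hierarchical = TRUE`.
#' @return an `xdecomp_hier_generator` with components `g1`, `g2_front`,
#'   `g2_body`, `g2_head`.
#' @export
build_hierarchical_generator <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!spec$hierarchical) stop("spec must have hierarchical = TRUE")
  w <- spec$base_width
  g1 <- build_generator(spec)
  g2_front <- list(layer_conv(7, spec$in_channels, w, reflect = TRUE),
                   layer_inorm(w), layer_act("relu"),
                   layer_conv(3, w, w, stride = 2),
                   layer_inorm(w), layer_act("relu"))
  g2_body <- c(lapply(seq_len(spec$g2_residual_blocks),
                      function(i) layer_resblock(w)),
               list(layer_up2(), layer_conv(3, w, w),
                    layer_inorm(w), layer_act("relu")))
  g2_head <- layer_conv(7, w, spec$out_channels, reflect = TRUE,
                        init = "zero")
  structure(list(g1 = g1, g2_front = g2_front, g2_body = g2_body,
                 g2_head = g2_head, spec = spec),
            class = "xdecomp_hier_generator")
}

#' Run a hierarchical generator on a high-scale input
#' @param gen an `xdecomp_hier_generator`.
#' @param x_hi (H, W, C) array at the high scale.
#' @param want_cache keep caches for backprop.
#' @return list with `y`, `logits`, and caches; `y_low` is the standalone
#'   global-generator output on the pooled input.
#' @export
hier_forward <- function(gen, x_hi, want_cache = FALSE) {
  x_hi <- as_tensor(x_hi)
  x_lo <- avgpool2(x_hi)
  f1 <- generator_forward(gen$g1, x_lo, want_cache = want_cache)
  fr <- net_forward(gen$g2_front, x_hi)
  fuse <- fr$y + f1$feat
  bd <- net_forward(gen$g2_body, fuse)
  hd <- layer_forward(gen$g2_head, bd$y)
  z <- upsample2_nearest(f1$logits) + hd$y
  y <- tanh(z)
  out <- list(y = y, logits = z, y_low = f1$y)
  if (want_cache) {
    out$caches <- list(f1 = f1, front = fr$caches, body = bd$caches,
                       head = hd$cache, x_lo = x_lo)
  }
  out
}

hier_backward <- function(gen, fw, gy, freeze_g1 = FALSE) {
  gz <- gy * (1 - fw$y^2)
  hb <- layer_backward(gen$g2_head, fw$caches$head, gz)
  bb <- net_backward(gen$g2_body, fw$caches$body, hb$gx)
  fb <- net_backward(gen$g2_front, fw$caches$front, bb$gx)
  # the fused feature receives bb$gx both through the front path (above) and
  # through g1's backbone; the upsampled g1 logits receive gz directly
  hb1 <- layer_backward(gen$g1$head, fw$caches$f1$caches$head,
                        upsample2_adjoint(gz))
  bb1 <- net_backward(gen$g1$backbone, fw$caches$f1$caches$backbone,
                      hb1$gx + bb$gx)
  gx <- fb$gx + avgpool2_adjoint(bb1$gx)
  list(gx = gx,
       grads = list(
         g1 = if (freeze_g1) NULL
              else list(backbone = bb1$grads, head = hb1$grads),
         front = fb$grads, body = bb$grads, head = hb$grads))
}

#' Build a patch discriminator
#'
#' @param spec a [discriminator_spec()].
#' @return an `xdecomp_discriminator`; apply with [discriminator_forward()].
#' @export
build_discriminator <- function(spec) {
  stopifnot(inherits(spec, "discriminator_spec"))
  w <- spec$base_width
  k <- spec$kernel
  use_norm <- (spec$norm %||% "instance") == "instance"
  norm_of <- function(c) if (use_norm) list(layer_inorm(c)) else list()
  layers <- list(layer_conv(k, spec$in_channels, w, stride = 2),
                 layer_act("lrelu"))
  cw <- w
  for (i in seq_len(spec$stride2_layers - 1)) {
    nw <- min(cw * 2, 8 * w)
    layers <- c(layers, list(layer_conv(k, cw, nw, stride = 2)),
                norm_of(nw), list(layer_act("lrelu")))
    cw <- nw
  }
  nw <- min(cw * 2, 8 * w)
  layers <- c(layers, list(layer_conv(k, cw, nw, stride = 1)),
              norm_of(nw),
              list(layer_act("lrelu"),
                   layer_conv(k, nw, 1, stride = 1),
                   layer_act("sigmoid")))
  structure(list(net = layers, spec = spec), class = "xdecomp_discriminator")
}

#' Run a discriminator, returning the sigmoid patch-score map
#' @param disc an `xdecomp_discriminator`.
#' @param x (H, W, C) input array.
#' @param want_cache keep caches for backprop.
#' @return list with `scores` (H', W', 1 array) and caches.
#' @export
discriminator_forward <- function(disc, x, want_cache = FALSE) {
  x <- as_tensor(x)
  # after the stride-2 stages the two stride-1 4x4 convolutions need at
  # least a 4-pixel feature map to emit a nonempty score map
  if (min(dim(x)[1:2]) < 2^disc$spec$stride2_layers * 4)
    stop("input too small for this discriminator depth")
  f <- net_forward(disc$net, x)
  if (want_cache) list(scores = f$y, caches = f$caches)
  else list(scores = f$y)
}

discriminator_backward <- function(disc, fw, g_scores) {
  net_backward(disc$net, fw$caches, g_scores)
}

#' Measure a discriminator's receptive field by gradient support
#'
#' Backpropagates from a single central output unit to the input and counts
#' the bounding box of pixels with nonzero gradient. Instance-normalization
#' statistics are image-wide, so they are held frozen during the backward
#' pass; the measurement then reflects the convolutional path, which is what
#' the "patch size" of a patch discriminator refers to.
#'
#' @param disc an `xdecomp_discriminator`.
#' @param input_size input side length in pixels.
#' @return measured receptive-field side length in pixels (max over u/v).
#' @export
measure_receptive_field <- function(disc, input_size) {
  x <- array(rnorm(input_size * input_size * disc$spec$in_channels),
             c(input_size, input_size, disc$spec$in_channels))
  disc$net <- lapply(disc$net, function(l) {
    if (l$type == "inorm") l$frozen <- TRUE
    l
  })
  fw <- discriminator_forward(disc, x, want_cache = TRUE)
  d <- dim(fw$scores)
  g <- array(0, d)
  g[(d[1] + 1) %/% 2, (d[2] + 1) %/% 2, 1] <- 1
  bk <- discriminator_backward(disc, fw, g)
  gin <- apply(abs(bk$gx), c(1, 2), sum)
  rows <- which(rowSums(gin) > 0)
  cols <- which(colSums(gin) > 0)
  max(diff(range(rows)) + 1, diff(range(cols)) + 1)
}

#' Total parameter count of a network object
#' @param x generator, hierarchical generator or discriminator.
#' @return integer parameter count.
#' @export
parameter_count <- function(x) {
  if (inherits(x, "xdecomp_generator"))
    return(net_param_count(x$backbone) + net_param_count(list(x$head)))
  if (inherits(x, "xdecomp_hier_generator"))
    return(parameter_count(x$g1) + net_param_count(x$g2_front) +
             net_param_count(x$g2_body) + net_param_count(list(x$g2_head)))
  if (inherits(x, "xdecomp_discriminator"))
    return(net_param_count(x$net))
  stop("unsupported object")
}
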