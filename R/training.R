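#' Training configuration for the decomposition model
#'
#' Defaults follow the full-scale study conditions: Adam with learning rate
#' 0.0002 held for the first half of 200 epochs then decayed linearly to 0,
#' batch size 1, fake-image history pool of 50, cycle weight 10 and
#' reconstruction-GC weight 1. Toy-scale runs shrink `epochs`,
#' `base_width`, `residual_blocks` and `image_size` without touching the
#' schedule's shape.
#'
#' @param variant `"conventional1"`, `"conventional2"`, `"proposed1"` or
#'   `"proposed2"` (see [variant_terms()]).
#' @param epochs total epochs per stage (even; half constant lr, half decay).
#' @param lr0 initial learning rate.
#' @param batch_size images per step (1, the unpaired-translation
#'   convention).
#' @param weights a [loss_weights()].
#' @param seed integer seed controlling initialization and sampling.
#' @param pool_size fake-image history pool size.
#' @param image_size trained (high-scale) image side; must match the
#'   dataset's detector.
#' @param base_width first-stage feature width of all networks.
#' @param residual_blocks generator residual blocks.
#' @param g1_freeze_frac fraction of local-stage epochs during which the
#'   global generator stays frozen.
#' @param adv `"log"` (as in the printed objective) or `"lsgan"`.
#' @param fresh_local_discriminators build new discriminators for the
#'   local stage (default) instead of reusing the global-stage ones.
#' @return a `training_config`.
#' @export
training_config <- function(variant = "proposed2", epochs = 200, lr0 = 2e-4,
                            batch_size = 1, weights = loss_weights(),
                            seed = 1, pool_size = 50, image_size = 64,
                            base_width = 16, residual_blocks = 9,
                            g1_freeze_frac = 0.1,
                            adv = c("log", "lsgan"),
                            fresh_local_discriminators = TRUE) {
  adv <- match.arg(adv)
  variant_terms(variant) # validates
  stopifnot(epochs >= 2, epochs %% 2 == 0, lr0 > 0, batch_size >= 1,
            pool_size >= 1, image_size >= 8, base_width >= 1,
            residual_blocks >= 1)
  structure(list(variant = variant, epochs = as.integer(epochs), lr0 = lr0,
                 batch_size = as.integer(batch_size), weights = weights,
                 seed = as.integer(seed), pool_size = as.integer(pool_size),
                 image_size = as.integer(image_size),
                 base_width = as.integer(base_width),
                 residual_blocks = as.integer(residual_blocks),
                 g1_freeze_frac = g1_freeze_frac, adv = adv,
                 fresh_local_discriminators = fresh_local_discriminators),
            class = "training_config")
}

#' Learning rate at a given epoch
#'
#' Constant `lr0` for the first half of the schedule, then linear decay to 0
#' at the final epoch.
#'
#' @param epoch integer in `\[1, epochs\]`.
#' @param config a [training_config()] (or any list with `epochs`, `lr0`).
#' @return the learning rate.
#' @export
lr_at_epoch <- function(epoch, config) {
  e <- config$epochs
  if (epoch < 1 || epoch > e) stop("epoch out of range")
  if (epoch <= e / 2) return(config$lr0)
  config$lr0 * (e - epoch) / (e / 2)
}

# --- internal scale ---------------------------------------------------------
# networks operate on \[-1, 1\]; dataset images live on the fixed \[0, 255\]
# normalized scale

to_internal <- function(x255) x255 / 127.5 - 1
from_internal <- function(y) (y + 1) * 127.5

# --- generic generator interface -------------------------------------------

g_fwd <- function(gen, x, cache = FALSE) {
  if (inherits(gen, "xdecomp_hier_generator")) hier_forward(gen, x, cache)
  else generator_forward(gen, x, cache)
}

g_bwd <- function(gen, fw, gy, freeze_g1 = FALSE) {
  if (inherits(gen, "xdecomp_hier_generator"))
    hier_backward(gen, fw, gy, freeze_g1)
  else generator_backward(gen, fw, gy)
}

g_tree <- function(gen) {
  if (inherits(gen, "xdecomp_hier_generator"))
    list(g1 = list(backbone = gen$g1$backbone, head = gen$g1$head),
         front = gen$g2_front, body = gen$g2_body, head = gen$g2_head)
  else list(backbone = gen$backbone, head = gen$head)
}

g_set_tree <- function(gen, tree) {
  if (inherits(gen, "xdecomp_hier_generator")) {
    gen$g1$backbone <- tree$g1$backbone
    gen$g1$head <- tree$g1$head
    gen$g2_front <- tree$front
    gen$g2_body <- tree$body
    gen$g2_head <- tree$head
  } else {
    gen$backbone <- tree$backbone
    gen$head <- tree$head
  }
  gen
}

# --- fake-image history pool -------------------------------------------------

pool_new <- function(size) list(size = size, imgs = list())

pool_query <- function(pool, img) {
  if (length(pool$imgs) < pool$size) {
    pool$imgs[[length(pool$imgs) + 1]] <- img
    return(list(pool = pool, img = img))
  }
  if (runif(1) > 0.5) {
    i <- sample.int(length(pool$imgs), 1)
    out <- pool$imgs[[i]]
    pool$imgs[[i]] <- img
    list(pool = pool, img = out)
  } else {
    list(pool = pool, img = img)
  }
}

# --- adversarial gradient helpers -------------------------------------------

adv_generator_grad <- function(scores, mode) {
  s <- clamp_scores(scores)
  n <- length(s)
  if (mode == "log") {
    list(value = mean(log(s)), g = -1 / (n * s))      # grad of the G loss
  } else {
    list(value = -mean((s - 1)^2), g = 2 * (s - 1) / n)
  }
}

adv_discriminator_grads <- function(s_real, s_fake, mode) {
  r <- clamp_scores(s_real); f <- clamp_scores(s_fake)
  nr <- length(r); nf <- length(f)
  if (mode == "log") {
    list(value = mean(log(r)) + mean(log(1 - f)),
         g_real = -1 / (nr * r), g_fake = 1 / (nf * (1 - f)))
  } else {
    list(value = -(mean((r - 1)^2) + mean(f^2)),
         g_real = 2 * (r - 1) / nr, g_fake = 2 * f / nf)
  }
}

broadcast_to_channels <- function(gmat, k) {
  array(rep(as.numeric(gmat), k), c(dim(gmat), k))
}

# --- one optimization step ---------------------------------------------------

train_step <- function(models, x, y, cfg, vrow, pools, lr, freeze_g1) {
  w <- cfg$weights
  k <- dim(y)[3]

  fy <- g_fwd(models$gd, x, TRUE)
  fx <- g_fwd(models$gx, y, TRUE)
  cx <- g_fwd(models$gx, fy$y, TRUE)
  cy <- g_fwd(models$gd, fx$y, TRUE)

  ddf <- discriminator_forward(models$dd, fy$y, TRUE)
  dxf <- discriminator_forward(models$dx, fx$y, TRUE)

  advd <- adv_generator_grad(ddf$scores, cfg$adv)
  advx <- adv_generator_grad(dxf$scores, cfg$adv)
  gan_g <- advd$value + advx$value

  cyc <- mean(abs(cx$y - x)) + mean(abs(cy$y - y))

  x_mat <- x[, , 1]
  sx <- channel_sum(fy$y)
  sy <- channel_sum(y)
  fx_mat <- fx$y[, , 1]
  gc1 <- gc_with_grad_b(x_mat, sx)
  gc2 <- gc_with_grad_b(sy, fx_mat)
  recon_gc <- ((1 - gc1$value) + (1 - gc2$value)) / 2
  recon_l2 <- mean((sx - x_mat)^2)

  # gradients at the generator outputs
  g_fy <- discriminator_backward(models$dd, ddf, advd$g)$gx
  g_fx <- discriminator_backward(models$dx, dxf, advx$g)$gx

  g_cx <- w$lambda_cyc * sign(cx$y - x) / length(x)
  g_cy <- w$lambda_cyc * sign(cy$y - y) / length(y)
  bk_cx <- g_bwd(models$gx, cx, g_cx, freeze_g1)
  bk_cy <- g_bwd(models$gd, cy, g_cy, freeze_g1)
  g_fy <- g_fy + bk_cx$gx
  g_fx <- g_fx + bk_cy$gx

  if (vrow$recon_gc) {
    g_fy <- g_fy + broadcast_to_channels(-w$lambda_gc * 0.5 * gc1$gb, k)
    g_fx <- g_fx - array(w$lambda_gc * 0.5 * gc2$gb, dim(g_fx))
  }
  if (vrow$recon_l2) {
    gl2 <- w$lambda_recon_l2 * 2 * (sx - x_mat) / length(x_mat)
    g_fy <- g_fy + broadcast_to_channels(gl2, k)
  }

  bk_fy <- g_bwd(models$gd, fy, g_fy, freeze_g1)
  bk_fx <- g_bwd(models$gx, fx, g_fx, freeze_g1)

  grads_gd <- grads_add(bk_cy$grads, bk_fy$grads)
  grads_gx <- grads_add(bk_cx$grads, bk_fx$grads)

  up <- adam_step(g_tree(models$gd), grads_gd, models$st_gd, lr)
  models$gd <- g_set_tree(models$gd, up$tree); models$st_gd <- up$state
  up <- adam_step(g_tree(models$gx), grads_gx, models$st_gx, lr)
  models$gx <- g_set_tree(models$gx, up$tree); models$st_gx <- up$state

  # discriminator updates on pooled fakes
  q <- pool_query(pools$dd, fy$y); pools$dd <- q$pool; fake_dd <- q$img
  q <- pool_query(pools$dx, fx$y); pools$dx <- q$pool; fake_dx <- q$img

  upd_disc <- function(disc, st, real, fake) {
    fr <- discriminator_forward(disc, real, TRUE)
    ff <- discriminator_forward(disc, fake, TRUE)
    dg <- adv_discriminator_grads(fr$scores, ff$scores, cfg$adv)
    bkr <- discriminator_backward(disc, fr, dg$g_real)
    bkf <- discriminator_backward(disc, ff, dg$g_fake)
    up <- adam_step(disc$net, grads_add(bkr$grads, bkf$grads), st, lr)
    disc$net <- up$tree
    list(disc = disc, st = up$state, value = dg$value)
  }
  ud <- upd_disc(models$dd, models$st_dd, y, fake_dd)
  models$dd <- ud$disc; models$st_dd <- ud$st
  ux <- upd_disc(models$dx, models$st_dx, x, fake_dx)
  models$dx <- ux$disc; models$st_dx <- ux$st

  terms <- list(gan = gan_g, cyc = cyc, recon_gc = recon_gc,
                recon_l2 = recon_l2)
  tl <- total_loss(terms, w, cfg$variant)
  if (!is.finite(tl$total) || !is.finite(ud$value) || !is.finite(ux$value))
    stop("non-finite loss encountered during training")

  list(models = models, pools = pools,
       losses = c(gan = gan_g, d_drr = ud$value, d_xp = ux$value, cyc = cyc,
                  recon_gc = recon_gc, recon_l2 = recon_l2,
                  total = tl$total))
}

# --- model construction ------------------------------------------------------

build_models <- function(cfg, k_channels) {
  hier <- variant_terms(cfg$variant)$local_enhancer
  size <- cfg$image_size
  if (hier) {
    gspec <- function(ci, co) generator_spec(
      ci, co, residual_blocks = cfg$residual_blocks, downsample_layers = 2,
      base_width = cfg$base_width, hierarchical = TRUE,
      scales = c(size %/% 2, size))
    gd <- build_hierarchical_generator(gspec(1, k_channels))
    gx <- build_hierarchical_generator(gspec(k_channels, 1))
    dspec <- function(ci) discriminator_spec(ci, stride2_layers = 3,
                                             base_width = cfg$base_width)
    list(gd = gd, gx = gx,
         dd_lo = build_discriminator(dspec(k_channels)),
         dx_lo = build_discriminator(dspec(1)),
         dd_hi = build_discriminator(dspec(k_channels)),
         dx_hi = build_discriminator(dspec(1)),
         hier = TRUE)
  } else {
    gspec <- function(ci, co) generator_spec(
      ci, co, residual_blocks = cfg$residual_blocks, downsample_layers = 3,
      base_width = cfg$base_width, hierarchical = FALSE)
    dspec <- function(ci) discriminator_spec(ci, stride2_layers = 4,
                                             base_width = cfg$base_width)
    list(gd = build_generator(gspec(1, k_channels)),
         gx = build_generator(gspec(k_channels, 1)),
         dd = build_discriminator(dspec(k_channels)),
         dx = build_discriminator(dspec(1)),
         hier = FALSE)
  }
}

prepare_case_tensors <- function(manifest, cfg) {
  norm <- manifest$normalization
  lapply(seq_len(nrow(manifest$cases)), function(ci) {
    rec <- manifest$data[[ci]]
    x255 <- norm_fwd(rec$radiograph$pixels, norm)
    y255 <- norm_fwd(rec$drr$channels, norm)
    if (nrow(x255) != cfg$image_size)
      stop("dataset detector size does not match config image_size")
    x <- as_tensor(to_internal(x255))
    y <- to_internal(y255)
    list(x = x, y = y, x_lo = avgpool2(x), y_lo = avgpool2(y))
  })
}

#' Train the unpaired decomposition model
#'
#' Alternating mini-max optimization of the generator pair and patch
#' discriminators on unpaired radiograph / decomposed-DRR samples, with the
#' loss terms selected by the configured ablation variant. Hierarchical
#' variants first train the global (low-resolution) generators for a full
#' learning-rate schedule, then the composed coarse-to-fine generators at
#' the high resolution with fresh discriminators, the global weights frozen
#' for the first `g1_freeze_frac` of epochs. Fake images fed to the
#' discriminators are drawn from a bounded history pool. The run is
#' deterministic for a fixed seed and can be checkpointed and resumed via
#' the returned state.
#'
#' @param manifest an `xdecomp_manifest` with a nonempty train split.
#' @param config a [training_config()].
#' @param state a previous `xdecomp_train_state` to resume from.
#' @param stop_after_epoch stop (checkpoint) after this overall epoch count
#'   (global + local stages concatenated).
#' @return an `xdecomp_train_state` with the models, optimizer states, loss
#'   `history` tibble and the dataset normalization.
#' @export
train <- function(manifest, config, state = NULL, stop_after_epoch = NULL) {
  stopifnot(inherits(manifest, "xdecomp_manifest"),
            inherits(config, "training_config"))
  train_ids <- manifest_split(manifest, "train")
  if (length(train_ids) == 0) stop("empty train split")
  k <- nrow(manifest$labels)
  vrow <- variant_terms(config$variant)
  n_stages <- if (vrow$local_enhancer) 2L else 1L
  total_epochs <- n_stages * config$epochs
  stop_after <- min(stop_after_epoch %||% total_epochs, total_epochs)

  tensors <- prepare_case_tensors(manifest, config)

  if (is.null(state)) {
    set.seed(derive_seed(config$seed, 0))
    models <- build_models(config, k)
    state <- list(config = config, models = models, pos = 0L,
                  history = list(),
                  normalization = manifest$normalization,
                  labels = manifest$labels,
                  adam = list(), pools = NULL, rng = NULL,
                  k_channels = k)
  } else {
    stopifnot(inherits(state, "xdecomp_train_state"))
    state <- unclass(state)
    if (!is.null(state$rng)) assign(".Random.seed", state$rng,
                                    envir = globalenv())
  }

  while (state$pos < stop_after) {
    pos <- state$pos + 1L
    stage <- if (n_stages == 2 && pos > config$epochs) "local"
             else if (n_stages == 2) "global" else "single"
    epoch_in_stage <- if (stage == "local") pos - config$epochs else pos
    lr <- lr_at_epoch(epoch_in_stage, config)

    # (re)assemble the per-stage working models and optimizer states
    if (stage == "global") {
      if (is.null(state$adam$global)) {
        state$adam$global <- list(
          gd = adam_init(g_tree(state$models$gd$g1)),
          gx = adam_init(g_tree(state$models$gx$g1)),
          dd = adam_init(state$models$dd_lo$net),
          dx = adam_init(state$models$dx_lo$net))
        state$pools <- list(dd = pool_new(config$pool_size),
                            dx = pool_new(config$pool_size))
      }
      m <- list(gd = state$models$gd$g1, gx = state$models$gx$g1,
                dd = state$models$dd_lo, dx = state$models$dx_lo,
                st_gd = state$adam$global$gd, st_gx = state$adam$global$gx,
                st_dd = state$adam$global$dd, st_dx = state$adam$global$dx)
      get_xy <- function(ti, yi) list(x = tensors[[ti]]$x_lo,
                                      y = tensors[[yi]]$y_lo)
      freeze_g1 <- FALSE
    } else if (stage == "local") {
      if (is.null(state$adam$local)) {
        state$adam$local <- list(
          gd = adam_init(g_tree(state$models$gd)),
          gx = adam_init(g_tree(state$models$gx)),
          dd = adam_init(state$models$dd_hi$net),
          dx = adam_init(state$models$dx_hi$net))
        state$pools <- list(dd = pool_new(config$pool_size),
                            dx = pool_new(config$pool_size))
      }
      m <- list(gd = state$models$gd, gx = state$models$gx,
                dd = state$models$dd_hi, dx = state$models$dx_hi,
                st_gd = state$adam$local$gd, st_gx = state$adam$local$gx,
                st_dd = state$adam$local$dd, st_dx = state$adam$local$dx)
      get_xy <- function(ti, yi) list(x = tensors[[ti]]$x,
                                      y = tensors[[yi]]$y)
      freeze_g1 <- epoch_in_stage <= ceiling(config$g1_freeze_frac *
                                               config$epochs)
    } else {
      if (is.null(state$adam$single)) {
        state$adam$single <- list(
          gd = adam_init(g_tree(state$models$gd)),
          gx = adam_init(g_tree(state$models$gx)),
          dd = adam_init(state$models$dd$net),
          dx = adam_init(state$models$dx$net))
        state$pools <- list(dd = pool_new(config$pool_size),
                            dx = pool_new(config$pool_size))
      }
      m <- list(gd = state$models$gd, gx = state$models$gx,
                dd = state$models$dd, dx = state$models$dx,
                st_gd = state$adam$single$gd, st_gx = state$adam$single$gx,
                st_dd = state$adam$single$dd, st_dx = state$adam$single$dx)
      get_xy <- function(ti, yi) list(x = tensors[[ti]]$x,
                                      y = tensors[[yi]]$y)
      freeze_g1 <- FALSE
    }

    order <- if (length(train_ids) == 1) train_ids else sample(train_ids)
    for (si in seq_along(order)) {
      xi <- order[si]
      yi <- if (length(train_ids) > 1) sample(setdiff(train_ids, xi), 1)
            else xi
      xy <- get_xy(xi, yi)
      st <- train_step(m, xy$x, xy$y, config, vrow, state$pools, lr,
                       freeze_g1)
      m <- st$models
      state$pools <- st$pools
      state$history[[length(state$history) + 1]] <-
        tibble::tibble(pos = pos, stage = stage, epoch = epoch_in_stage,
                       step = si, lr = lr, !!!as.list(st$losses))
    }

    # write the stage models/optimizer states back
    if (stage == "global") {
      state$models$gd$g1 <- m$gd; state$models$gx$g1 <- m$gx
      state$models$dd_lo <- m$dd; state$models$dx_lo <- m$dx
      state$adam$global <- list(gd = m$st_gd, gx = m$st_gx,
                                dd = m$st_dd, dx = m$st_dx)
    } else if (stage == "local") {
      state$models$gd <- m$gd; state$models$gx <- m$gx
      state$models$dd_hi <- m$dd; state$models$dx_hi <- m$dx
      state$adam$local <- list(gd = m$st_gd, gx = m$st_gx,
                               dd = m$st_dd, dx = m$st_dx)
    } else {
      state$models$gd <- m$gd; state$models$gx <- m$gx
      state$models$dd <- m$dd; state$models$dx <- m$dx
      state$adam$single <- list(gd = m$st_gd, gx = m$st_gx,
                                dd = m$st_dd, dx = m$st_dx)
    }
    state$pos <- pos
    state$rng <- get(".Random.seed", envir = globalenv())
  }

  structure(state, class = "xdecomp_train_state")
}

#' @export
print.xdecomp_train_state <- function(x, ...) {
  cat("<xdecomp_train_state> variant ", x$config$variant, ", ", x$pos,
      " epochs trained\n", sep = "")
  invisible(x)
}

#' Loss history of a training state as a tibble
#' @param state an `xdecomp_train_state`.
#' @return tibble with one row per optimization step.
#' @export
loss_history <- function(state) {
  dplyr::bind_rows(state$history)
}

#' Decompose a radiograph with a trained model
#'
#' @param radiograph an [radiograph()] (raw images are normalized with the
#'   training normalization first) or a matrix on the normalized \[0, 255\]
#'   scale.
#' @param state an `xdecomp_train_state`.
#' @return a normalized-scale [decomposed_set()] with K+1 channels, carrying
#'   the shared training normalization (so it can be denormalized to
#'   line-integral units).
#' @export
decompose <- function(radiograph, state) {
  stopifnot(inherits(state, "xdecomp_train_state"))
  if (inherits(radiograph, "xdecomp_radiograph")) {
    if (radiograph$raw)
      radiograph <- normalize_image(radiograph, state$normalization)
    px <- radiograph$pixels
  } else {
    px <- as_image_matrix(radiograph)
  }
  if (nrow(px) != state$config$image_size)
    stop("input size does not match the trained scale")
  x <- as_tensor(to_internal(px))
  out <- g_fwd(state$models$gd, x, cache = FALSE)
  ch <- pmin(pmax(from_internal(out$y), 0), 255)
  decomposed_set(ch, state$labels, raw = FALSE,
                 normalization = state$normalization)
}
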