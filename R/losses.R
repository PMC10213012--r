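#' Loss weights for the decomposition objective
#'
#' @param lambda_cyc weight of the cycle-consistency term (default 10).
#' @param lambda_gc weight of the reconstruction gradient-correlation term
#'   (default 1.0).
#' @param lambda_recon_l2 weight of the plain l2 reconstruction term used by
#'   the `conventional2` variant (default 0.5).
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(lambda_cyc = 10, lambda_gc = 1.0,
                         lambda_recon_l2 = 0.5) {
  stopifnot(lambda_cyc >= 0, lambda_gc >= 0, lambda_recon_l2 >= 0)
  structure(list(lambda_cyc = lambda_cyc, lambda_gc = lambda_gc,
                 lambda_recon_l2 = lambda_recon_l2),
            class = "loss_weights")
}

#' Ablation variants and the loss terms they include
#'
#' The four model variants differ in whether the generator uses the
#' hierarchical local enhancer and which reconstruction penalty (plain l2 or
#' gradient correlation) augments the adversarial + cycle objective.
#'
#' @param variant one of `"conventional1"`, `"conventional2"`, `"proposed1"`,
#'   `"proposed2"`; omit to get the full matrix.
#' @return a tibble with columns `variant`, `local_enhancer`, `recon_l2`,
#'   `recon_gc`.
#' @export
variant_terms <- function(variant = NULL) {
  m <- tibble::tibble(
    variant = c("conventional1", "conventional2", "proposed1", "proposed2"),
    local_enhancer = c(FALSE, FALSE, TRUE, TRUE),
    recon_l2 = c(FALSE, TRUE, FALSE, FALSE),
    recon_gc = c(FALSE, FALSE, FALSE, TRUE))
  if (is.null(variant)) return(m)
  row <- m[m$variant == variant, ]
  if (nrow(row) == 0) stop("unknown variant: ", variant)
  row
}

as_image_matrix <- function(x) {
  if (inherits(x, "xdecomp_radiograph")) x <- x$pixels
  if (is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 1)
    x <- x[, , 1, drop = TRUE]
  stopifnot(is.matrix(x) || (is.array(x) && length(dim(x)) == 2))
  x
}

#' Normalized cross-correlation of two images
#'
#' Zero-mean NCC with a small epsilon guarding zero-variance inputs (a
#' constant image correlates to 0 rather than raising an error).
#'
#' @param a,b numeric matrices of equal shape (>= 2 pixels).
#' @param eps denominator guard.
#' @return scalar in `\[-1, 1\]`.
#' @export
ncc <- function(a, b, eps = 1e-8) {
  a <- as_image_matrix(a); b <- as_image_matrix(b)
  if (!all(dim(a) == dim(b))) stop("shape mismatch in ncc")
  if (length(a) < 2) stop("ncc needs at least 2 pixels")
  A <- a - mean(a); B <- b - mean(b)
  sum(A * B) / sqrt(sum(A^2) * sum(B^2) + eps)
}

# NCC value plus analytic gradients with respect to both inputs
ncc_with_grad <- function(a, b, eps = 1e-8) {
  A <- a - mean(a); B <- b - mean(b)
  s <- sum(A * B)
  va <- sum(A^2); vb <- sum(B^2)
  D <- sqrt(va * vb + eps)
  v <- s / D
  ga <- B / D - s * vb * A / D^3
  gb <- A / D - s * va * B / D^3
  list(value = v, ga = ga, gb = gb)
}

sobel_kernel_u <- function() outer(c(1, 2, 1), c(-1, 0, 1))
sobel_kernel_v <- function() outer(c(-1, 0, 1), c(1, 2, 1))
central_kernel_u <- function() outer(c(0, 1, 0), c(-0.5, 0, 0.5))
central_kernel_v <- function() outer(c(-0.5, 0, 0.5), c(0, 1, 0))

grad_kernels <- function(operator = c("sobel", "central")) {
  operator <- match.arg(operator)
  if (operator == "sobel") list(u = sobel_kernel_u(), v = sobel_kernel_v())
  else list(u = central_kernel_u(), v = central_kernel_v())
}

# "same"-size correlation with reflect padding via the conv engine
image_filter <- function(x, kern) {
  w <- array(kern, c(3, 3, 1))
  y <- conv2d_forward_cpp(array(x, c(dim(x), 1)), w, 0, 3L, 1L, 1L, 1L, 1L,
                          TRUE)
  y[, , 1, drop = TRUE]
}

# adjoint of image_filter (backprop of the gradient operator)
image_filter_adjoint <- function(x, kern, gy) {
  w <- array(kern, c(3, 3, 1))
  bk <- conv2d_backward_cpp(array(x, c(dim(x), 1)),
                            w, array(gy, c(dim(gy), 1)),
                            3L, 1L, 1L, 1L, 1L, TRUE)
  bk$gx[, , 1, drop = TRUE]
}

#' Gradient correlation between two images
#'
#' Mean of the normalized cross-correlations of the horizontal (u) and
#' vertical (v) image derivatives, each pair matched by component:
#' `GC = (NCC(du A, du B) + NCC(dv A, dv B)) / 2`. Invariant to positive
#' affine intensity changes of either image.
#'
#' @param a,b numeric matrices of equal shape, at least 3x3.
#' @param operator derivative operator, `"sobel"` (default) or `"central"`.
#' @return scalar in `\[-1, 1\]`.
#' @export
gradient_correlation <- function(a, b, operator = c("sobel", "central")) {
  a <- as_image_matrix(a); b <- as_image_matrix(b)
  if (!all(dim(a) == dim(b))) stop("shape mismatch in gradient_correlation")
  if (any(dim(a) < 3)) stop("gradient_correlation needs at least 3x3 images")
  k <- grad_kernels(operator)
  (ncc(image_filter(a, k$u), image_filter(b, k$u)) +
     ncc(image_filter(a, k$v), image_filter(b, k$v))) / 2
}

# GC with gradient with respect to b
gc_with_grad_b <- function(a, b, operator = "sobel") {
  k <- grad_kernels(operator)
  au <- image_filter(a, k$u); av <- image_filter(a, k$v)
  bu <- image_filter(b, k$u); bv <- image_filter(b, k$v)
  nu <- ncc_with_grad(au, bu)
  nv <- ncc_with_grad(av, bv)
  gb <- (image_filter_adjoint(b, k$u, nu$gb) +
           image_filter_adjoint(b, k$v, nv$gb)) / 2
  list(value = (nu$value + nv$value) / 2, gb = gb)
}

clamp_scores <- function(s, eps = 1e-7) pmin(pmax(s, eps), 1 - eps)

#' Adversarial (GAN) loss terms from discriminator patch scores
#'
#' Log-form objective on post-sigmoid patch score maps. The discriminator
#' term `mean(log D(real)) + mean(log(1 - D(fake)))` is maximized by the
#' discriminator; the generator term is the non-saturating
#' `mean(log D(fake))`, maximized by the generator. Scores outside (0, 1)
#' are clamped at `1e-7`.
#'
#' @param d_real_scores,d_fake_scores numeric arrays of patch scores in (0,1).
#' @return list with `generator` and `discriminator` scalar terms.
#' @export
adversarial_loss <- function(d_real_scores, d_fake_scores) {
  r <- clamp_scores(d_real_scores)
  f <- clamp_scores(d_fake_scores)
  list(generator = mean(log(f)),
       discriminator = mean(log(r)) + mean(log(1 - f)))
}

#' Cycle-consistency loss
#'
#' Mean absolute difference between each image and its round-trip
#' translation, summed over the two directions.
#'
#' @param x,x_cycled radiograph-domain image and its cycle reconstruction.
#' @param y,y_cycled decomposed-domain image set and its cycle
#'   reconstruction.
#' @return scalar >= 0.
#' @export
cycle_loss <- function(x, x_cycled, y, y_cycled) {
  if (!all(dim(x) == dim(x_cycled)) || !all(dim(y) == dim(y_cycled)))
    stop("shape mismatch in cycle_loss")
  mean(abs(x_cycled - x)) + mean(abs(y_cycled - y))
}

channel_sum <- function(ch) {
  if (inherits(ch, "xdecomp_decomposed")) ch <- ch$channels
  if (is.matrix(ch)) return(ch)
  d <- dim(ch)
  out <- matrix(0, d[1], d[2])
  for (c in seq_len(d[3])) out <- out + ch[, , c]
  out
}

#' Reconstruction gradient-correlation loss
#'
#' Penalizes gradient misalignment between a radiograph and the channel-sum
#' of its decomposition, symmetrically in both translation directions:
#' `((1 - GC(x, sum_n G_DRR,n(x))) + (1 - GC(sum_n y_n, G_Xp(y)))) / 2`.
#' Because image gradients ignore constant offsets, the term is robust to
#' absolute-intensity shifts between domains. Range `\[0, 2\]`.
#'
#' @param x input radiograph (matrix).
#' @param g_drr_channels decomposed channels predicted from `x` (3D array).
#' @param y_channels real decomposed channel set (3D array).
#' @param g_xp_output radiograph predicted from `y_channels` (matrix).
#' @param operator derivative operator passed to [gradient_correlation()].
#' @return scalar in `\[0, 2\]`.
#' @export
reconstruction_gc_loss <- function(x, g_drr_channels, y_channels,
                                   g_xp_output, operator = "sobel") {
  x <- as_image_matrix(x); g_xp_output <- as_image_matrix(g_xp_output)
  sx <- channel_sum(g_drr_channels)
  sy <- channel_sum(y_channels)
  if (!all(dim(sx) == dim(x)) || !all(dim(sy) == dim(g_xp_output)))
    stop("shape mismatch in reconstruction_gc_loss")
  ((1 - gradient_correlation(x, sx, operator)) +
     (1 - gradient_correlation(sy, g_xp_output, operator))) / 2
}

#' Plain l2 reconstruction loss
#'
#' Mean squared difference between the channel-sum of a decomposition and
#' the input radiograph; depends on the channels only through their sum.
#'
#' @param x input radiograph (matrix).
#' @param g_drr_channels decomposed channels predicted from `x`.
#' @return scalar >= 0.
#' @export
reconstruction_l2_loss <- function(x, g_drr_channels) {
  x <- as_image_matrix(x)
  s <- channel_sum(g_drr_channels)
  if (!all(dim(s) == dim(x))) stop("shape mismatch in reconstruction_l2_loss")
  mean((s - x)^2)
}

#' Weighted total loss with per-variant term selection
#'
#' @param terms list with elements `gan`, `cyc` and optionally `recon_gc`,
#'   `recon_l2` (scalars).
#' @param weights a [loss_weights()].
#' @param variant ablation variant name; terms not included by the variant
#'   are dropped from the total (their weight column in the breakdown is 0).
#' @return list with `total` and a one-row `breakdown` tibble.
#' @export
total_loss <- function(terms, weights = loss_weights(),
                       variant = "proposed2") {
  row <- variant_terms(variant)
  gan <- terms$gan %||% 0
  cyc <- terms$cyc %||% 0
  rgc <- if (row$recon_gc) weights$lambda_gc * (terms$recon_gc %||% 0) else 0
  rl2 <- if (row$recon_l2) weights$lambda_recon_l2 * (terms$recon_l2 %||% 0)
         else 0
  total <- gan + weights$lambda_cyc * cyc + rgc + rl2
  list(total = total,
       breakdown = tibble::tibble(
         variant = variant, gan = gan,
         cyc_weighted = weights$lambda_cyc * cyc,
         recon_gc_weighted = rgc, recon_l2_weighted = rl2, total = total))
}
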