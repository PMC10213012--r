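#' Projection geometry for DRR rendering
#'
#' The imager frame has the detector plane at `z = sdd` with the horizontal
#' `u` axis along `+x` (origin top-left, principal point at the detector
#' center) and the vertical `v` axis along `-y`. For the pinhole model the
#' point source sits at the origin; for the parallel model rays run along
#' `+z`. `pose` maps volume coordinates (origin at the volume center) into
#' the imager frame; its default centers the volume halfway between source
#' and detector.
#'
#' @param model `"parallel"` or `"pinhole"`.
#' @param sdd source-detector distance `d` in mm (integration depth for the
#'   parallel model).
#' @param detector_shape integer (nu, nv) detector pixels.
#' @param pixel_pitch detector pixel size in mm.
#' @param pose a [rigid_transform()] or `NULL` for the centered default.
#' @return an object of class `projection_geometry`.
#' @export
projection_geometry <- function(model = c("parallel", "pinhole"), sdd = 1000,
                                detector_shape = c(64, 64), pixel_pitch = 1,
                                pose = NULL) {
  model <- match.arg(model)
  stopifnot(sdd > 0, pixel_pitch > 0, length(detector_shape) == 2,
            all(detector_shape >= 1))
  if (is.null(pose)) pose <- rigid_transform(translation = c(0, 0, sdd / 2))
  stopifnot(inherits(pose, "rigid_transform"))
  structure(list(model = model, sdd = sdd,
                 detector_shape = as.integer(detector_shape),
                 pixel_pitch = pixel_pitch, pose = pose),
            class = "projection_geometry")
}

#' Axis-aligned parallel geometry matched to a phantom grid
#'
#' Rays run along the volume z axis through every (x, y) voxel-column center
#' and the detector pitch equals the in-plane voxel spacing, so each pixel's
#' line integral is exactly the column sum of voxel attenuations times the
#' voxel depth. Under this geometry the pixel-sum of a uniform structure's
#' DRR times the pixel area equals its attenuation-weighted volume exactly.
#'
#' @param phantom a `vox_phantom`.
#' @return a [projection_geometry()].
#' @export
geometry_for_phantom <- function(phantom) {
  n <- dim(phantom$label)
  sp <- phantom$spacing
  if (abs(sp[1] - sp[2]) > 1e-12)
    stop("aligned geometry requires isotropic in-plane spacing")
  projection_geometry("parallel", sdd = 2 * n[3] * sp[3],
                      detector_shape = c(n[1], n[2]), pixel_pitch = sp[1])
}

#' Replace / compose the volume pose of a geometry
#'
#' @param geometry a [projection_geometry()].
#' @param perturbation a [rigid_transform()] applied in the volume frame
#'   before the geometry's own pose.
#' @return the geometry with composed pose.
#' @export
set_pose <- function(geometry, perturbation) {
  geometry$pose <- compose_transform(geometry$pose, perturbation)
  geometry
}

#' Convert Hounsfield units to linear attenuation coefficients
#'
#' Monoenergetic linear relation `mu = mu_water * (1 + HU/1000)`, clamped
#' below at zero (air maps to zero attenuation). A 10 HU decrease at
#' muscle-range HU (~50) therefore lowers the AC by 10/1050, about 1%.
#'
#' @param hu HU value, vector or array.
#' @param mu_water attenuation of water in 1/mm.
#' @return linear AC in 1/mm, same shape as `hu`.
#' @export
hu_to_attenuation <- function(hu, mu_water = 0.02) {
  stopifnot(mu_water > 0)
  if (any(!is.finite(hu))) stop("non-finite HU input")
  pmax(mu_water * (1 + hu / 1000), 0)
}

#' A single-channel radiograph image
#' @param pixels numeric matrix (rows = v, cols = u).
#' @param raw logical; `TRUE` for line-integral units, `FALSE` for the
#'   normalized \[0, 255\] scale.
#' @param normalization a [normalization()] or `NULL`.
#' @param provenance one of `"rendered"`, `"synthetic-noisy"`,
#'   `"decomposition-reconstruction"`.
#' @return an `xdecomp_radiograph`.
#' @export
radiograph <- function(pixels, raw = TRUE, normalization = NULL,
                       provenance = "rendered") {
  stopifnot(is.matrix(pixels))
  if (raw && min(pixels) < 0) stop("raw radiograph values must be >= 0")
  structure(list(pixels = pixels, raw = raw, normalization = normalization,
                 provenance = provenance),
            class = "xdecomp_radiograph")
}

#' A set of aligned per-structure projection images
#' @param channels numeric array (nv, nu, K+1).
#' @param labels tibble of structure labels (one row per channel).
#' @param raw logical, as in [radiograph()].
#' @param normalization shared [normalization()] or `NULL`.
#' @return an `xdecomp_decomposed`.
#' @export
decomposed_set <- function(channels, labels, raw = TRUE,
                           normalization = NULL) {
  stopifnot(length(dim(channels)) == 3, nrow(labels) == dim(channels)[3])
  if (raw && min(channels) < 0) stop("raw channel values must be >= 0")
  structure(list(channels = channels, labels = labels, raw = raw,
                 normalization = normalization),
            class = "xdecomp_decomposed")
}

#' @export
print.xdecomp_radiograph <- function(x, ...) {
  cat("<xdecomp_radiograph> ", paste(dim(x$pixels), collapse = "x"),
      if (x$raw) " (raw line integrals)" else " (normalized [0,255])",
      ", provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
print.xdecomp_decomposed <- function(x, ...) {
  d <- dim(x$channels)
  cat("<xdecomp_decomposed> ", d[1], "x", d[2], " pixels, ", d[3],
      " channels", if (x$raw) " (raw)" else " (normalized)", "\n", sep = "")
  invisible(x)
}

#' Render per-structure DRRs and the composite radiograph
#'
#' Each channel `n` is the line integral of the attenuation restricted to
#' structure `n` along every detector ray; the composite is the whole-volume
#' integral. Both integrators accumulate channels and composite in one
#' traversal, so the channel sum reproduces the composite. The `"exact"`
#' integrator accumulates analytic ray-voxel intersection lengths; the
#' `"sampled"` integrator steps along the ray with trilinearly interpolated
#' attenuation and nearest-voxel structure labels.
#'
#' @param phantom a `vox_phantom`.
#' @param geometry a [projection_geometry()].
#' @param mu_water water AC in 1/mm.
#' @param integrator `"exact"` or `"sampled"`.
#' @param step sampling step in mm for the sampled integrator (default half
#'   the smallest voxel spacing).
#' @param interp `"nearest"` (default) or `"trilinear"` attenuation sampling
#'   for the sampled integrator. Nearest-voxel sampling integrates the same
#'   piecewise-constant field as the exact integrator, so the only error is
#'   the step quadrature; trilinear smooths structure silhouettes, which
#'   biases grazing rays.
#' @return list with `drr` (an [decomposed_set()]) and `radiograph` (the raw
#'   composite [radiograph()]).
#' @export
render <- function(phantom, geometry, mu_water = 0.02,
                   integrator = c("exact", "sampled"), step = NULL,
                   interp = c("nearest", "trilinear")) {
  integrator <- match.arg(integrator)
  interp <- match.arg(interp)
  stopifnot(inherits(phantom, "vox_phantom"),
            inherits(geometry, "projection_geometry"))
  mu <- hu_to_attenuation(phantom$hu, mu_water)
  if (is.null(step)) step <- min(phantom$spacing) / 2
  out <- render_cpp(as.numeric(mu), as.integer(phantom$label),
                    dim(phantom$label), phantom$spacing,
                    geometry$pose$rotation, geometry$pose$translation,
                    if (geometry$model == "pinhole") 1L else 0L,
                    geometry$sdd, geometry$detector_shape[1],
                    geometry$detector_shape[2], geometry$pixel_pitch,
                    phantom$n_channels,
                    if (integrator == "exact") 0L else 1L, step,
                    interp == "trilinear")
  list(drr = decomposed_set(out$channels, phantom$labels, raw = TRUE),
       radiograph = radiograph(out$composite, raw = TRUE,
                               provenance = "rendered"))
}

#' Project one structure's per-side support regions to the detector
#'
#' Used to delineate the affected/unaffected integration regions of the
#' volume-ratio metric from ground truth side masks.
#'
#' @param phantom a `vox_phantom`.
#' @param geometry a [projection_geometry()].
#' @param label_id structure label.
#' @return list of logical images `left` and `right` (projected supports).
#' @export
project_side_supports <- function(phantom, geometry, label_id) {
  n <- dim(phantom$label)
  xi <- slice.index(phantom$label, 1)
  one_side <- function(keep) {
    m <- (phantom$label == label_id) & keep
    out <- render_cpp(as.numeric(m), as.integer(m), n, phantom$spacing,
                      geometry$pose$rotation, geometry$pose$translation,
                      if (geometry$model == "pinhole") 1L else 0L,
                      geometry$sdd, geometry$detector_shape[1],
                      geometry$detector_shape[2], geometry$pixel_pitch,
                      1L, 0L, 1, FALSE)
    out$composite > 0
  }
  list(left = one_side(xi <= n[1] / 2), right = one_side(xi > n[1] / 2))
}

#' Simulate quantum noise on a raw radiograph
#'
#' Converts line integrals `p` to expected photon counts `i0 * exp(-p)`,
#' draws Poisson counts, and log-transforms back:
#' `p' = -log(max(N, 1) / i0)`. Zero counts are clamped to one photon; the
#' number of clamped pixels is recorded in the `n_clamped` attribute.
#'
#' @param image raw [radiograph()] (line-integral units).
#' @param i0 photons per unexposed pixel (> 0).
#' @param seed integer seed.
#' @return a raw [radiograph()] with provenance `"synthetic-noisy"`.
#' @export
add_poisson_noise <- function(image, i0 = 1e4, seed = 1) {
  stopifnot(inherits(image, "xdecomp_radiograph"), image$raw, i0 > 0)
  p <- image$pixels
  if (min(p) < 0) stop("line-integral values must be >= 0")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  counts <- rpois(length(p), lambda = i0 * exp(-p))
  n_clamped <- sum(counts == 0)
  counts <- pmax(counts, 1)
  # counts above i0 would give (unphysical) negative line integrals; floor
  # at zero to keep the raw-image invariant
  out <- radiograph(matrix(pmax(-log(counts / i0), 0), nrow(p), ncol(p)),
                    raw = TRUE, normalization = image$normalization,
                    provenance = "synthetic-noisy")
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Fixed intensity normalization shared across a dataset
#'
#' Affine map sending `raw_min` to 0 and `raw_max` to 255. One instance is
#' computed from the training split and attached to every image of a
#' dataset, so decomposed images remain denormalizable to comparable
#' absolute line-integral units across cases.
#'
#' @param raw_min,raw_max raw range in line-integral units (`raw_max >
#'   raw_min`).
#' @return an `xdecomp_normalization`.
#' @export
normalization <- function(raw_min = 0, raw_max) {
  if (raw_max <= raw_min) stop("raw_max must exceed raw_min")
  structure(list(raw_min = raw_min, raw_max = raw_max),
            class = "xdecomp_normalization")
}

norm_fwd <- function(x, norm) {
  pmin(pmax((x - norm$raw_min) / (norm$raw_max - norm$raw_min) * 255, 0), 255)
}
norm_inv <- function(x, norm) {
  x / 255 * (norm$raw_max - norm$raw_min) + norm$raw_min
}

#' Normalize an image to the fixed \[0, 255\] scale
#' @param image an [radiograph()], [decomposed_set()] or numeric array.
#' @param norm a [normalization()].
#' @return object of the same kind on the normalized scale (values clipped
#'   to \[0, 255\]).
#' @export
normalize_image <- function(image, norm) {
  stopifnot(inherits(norm, "xdecomp_normalization"))
  if (inherits(image, "xdecomp_radiograph")) {
    if (!image$raw) stop("image is already normalized")
    radiograph(norm_fwd(image$pixels, norm), raw = FALSE, normalization = norm,
               provenance = image$provenance)
  } else if (inherits(image, "xdecomp_decomposed")) {
    if (!image$raw) stop("image is already normalized")
    decomposed_set(norm_fwd(image$channels, norm), image$labels, raw = FALSE,
                   normalization = norm)
  } else {
    norm_fwd(image, norm)
  }
}

#' Invert the fixed normalization back to line-integral units
#' @inheritParams normalize_image
#' @return object of the same kind in raw units; exact inverse for values
#'   that were not clipped.
#' @export
denormalize_image <- function(image, norm = NULL) {
  if (inherits(image, "xdecomp_radiograph")) {
    norm <- norm %||% image$normalization
    radiograph(norm_inv(image$pixels, norm), raw = TRUE, normalization = norm,
               provenance = image$provenance)
  } else if (inherits(image, "xdecomp_decomposed")) {
    norm <- norm %||% image$normalization
    decomposed_set(pmax(norm_inv(image$channels, norm), 0), image$labels,
                   raw = TRUE, normalization = norm)
  } else {
    stopifnot(inherits(norm, "xdecomp_normalization"))
    norm_inv(image, norm)
  }
}

# --- bi-cubic resampling ----------------------------------------------------

# Catmull-Rom (cubic convolution, a = -1/2) interpolation weights from output
# grid to input grid, with linear extrapolation beyond the edges so linear
# ramps are reproduced exactly everywhere
cubic_weight_matrix <- function(n_in, n_out) {
  a <- -0.5
  kern <- function(x) {
    x <- abs(x)
    ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
           ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
  }
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5        # 0-based input coordinate
    k0 <- floor(src)
    for (k in (k0 - 1):(k0 + 2)) {
      w <- kern(src - k)
      if (w == 0) next
      if (k < 0) {                        # linear extrapolation at the edge
        W[i, 1] <- W[i, 1] + w * (1 - k)
        W[i, 2] <- W[i, 2] + w * k
      } else if (k > n_in - 1) {
        W[i, n_in] <- W[i, n_in] + w * (1 + (k - n_in + 1))
        W[i, n_in - 1] <- W[i, n_in - 1] - w * (k - n_in + 1)
      } else {
        W[i, k + 1] <- W[i, k + 1] + w
      }
    }
  }
  W
}

#' Resize an image with bi-cubic interpolation
#'
#' Non-square inputs are first zero-padded to square (centered), then
#' resampled separably with the cubic-convolution kernel.
#'
#' @param image numeric matrix, 3D array (resized per channel),
#'   [radiograph()] or [decomposed_set()].
#' @param target integer output side length (>= 8).
#' @return resized object of the same kind.
#' @export
resize_image <- function(image, target) {
  stopifnot(target >= 8)
  if (inherits(image, "xdecomp_radiograph")) {
    out <- image
    out$pixels <- resize_image(image$pixels, target)
    return(out)
  }
  if (inherits(image, "xdecomp_decomposed")) {
    out <- image
    out$channels <- resize_image(image$channels, target)
    return(out)
  }
  if (length(dim(image)) == 3) {
    d <- dim(image)
    out <- array(0, c(target, target, d[3]))
    for (c in seq_len(d[3])) out[, , c] <- resize_image(image[, , c], target)
    return(out)
  }
  x <- image
  if (nrow(x) != ncol(x)) {
    s <- max(dim(x))
    pad <- matrix(0, s, s)
    r0 <- (s - nrow(x)) %/% 2
    c0 <- (s - ncol(x)) %/% 2
    pad[r0 + seq_len(nrow(x)), c0 + seq_len(ncol(x))] <- x
    x <- pad
  }
  if (nrow(x) == target) return(x)
  A <- cubic_weight_matrix(nrow(x), target)
  A %*% x %*% t(cubic_weight_matrix(ncol(x), target))
}
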