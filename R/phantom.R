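#' Specification of a synthetic musculoskeletal phantom
#'
#' Describes a voxelized body phantom with mirrored bone and muscle
#' structures. Muscles are bilateral: one label covers the mirrored
#' left/right pair, and the affected side's member is shrunk along its long
#' axis by `asymmetry_factor`, so the affected/unaffected volume ratio of a
#' muscle equals the factor up to voxelization. Bones are symmetric: an odd
#' count places one midline bone plus mirrored left/right pairs (each side a
#' separate label).
#'
#' @param grid_shape integer length-3 voxel counts (nx, ny, nz); nx must be
#'   even so the mirror plane falls between voxel columns.
#' @param spacing numeric length-3 voxel size in mm.
#' @param n_bones number of bone labels (>= 1).
#' @param n_muscles number of bilateral muscle labels (>= 1).
#' @param bone_hu_range,muscle_hu_range HU intervals structures are drawn from.
#' @param background_hu HU of soft-tissue background inside the body envelope.
#' @param asymmetry_factor scale in (0, 1] applied to the affected-side volume
#'   of every muscle.
#' @param affected_side `"left"` or `"right"`.
#' @param seed integer RNG seed; the phantom is a pure function of the spec.
#' @param muscle_size_frac optional length-2 range of muscle transverse
#'   semi-axes as a fraction of the half-extent of the grid. The default
#'   shrinks with the muscle count so that the default 19 muscles still pack
#'   into the body envelope.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), spacing = c(3, 3, 3),
                         n_bones = 3, n_muscles = 19,
                         bone_hu_range = c(300, 800),
                         muscle_hu_range = c(40, 80),
                         background_hu = 0,
                         asymmetry_factor = 1,
                         affected_side = c("left", "right"),
                         seed = 1,
                         muscle_size_frac = NULL) {
  affected_side <- match.arg(affected_side)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0),
            grid_shape[1] %% 2 == 0,
            length(spacing) == 3, all(spacing > 0),
            n_bones >= 1, n_muscles >= 1,
            asymmetry_factor > 0, asymmetry_factor <= 1,
            min(bone_hu_range) > max(muscle_hu_range),
            min(muscle_hu_range) > background_hu,
            background_hu > -200)
  if (is.null(muscle_size_frac)) {
    muscle_size_frac <- c(0.18, 0.30) * (5 / max(n_muscles, 5))^(1 / 3)
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 n_bones = as.integer(n_bones),
                 n_muscles = as.integer(n_muscles),
                 bone_hu_range = bone_hu_range,
                 muscle_hu_range = muscle_hu_range,
                 background_hu = background_hu,
                 asymmetry_factor = asymmetry_factor,
                 affected_side = affected_side,
                 seed = as.integer(seed),
                 muscle_size_frac = muscle_size_frac),
            class = "phantom_spec")
}

# voxelize an axis-aligned ellipsoid onto the grid; returns integer index
# vector of voxels whose centers fall inside
voxelize_ellipsoid <- function(center, semi, grid_shape, spacing) {
  n <- grid_shape
  cx <- center
  lo <- pmax(1L, as.integer(floor((cx - semi) / spacing + 0.5)))
  hi <- pmin(n, as.integer(ceiling((cx + semi) / spacing + 0.5)))
  if (any(lo > hi)) return(integer(0))
  xi <- ((lo[1]:hi[1]) - 0.5) * spacing[1]
  yi <- ((lo[2]:hi[2]) - 0.5) * spacing[2]
  zi <- ((lo[3]:hi[3]) - 0.5) * spacing[3]
  dx2 <- ((xi - cx[1]) / semi[1])^2
  dy2 <- ((yi - cx[2]) / semi[2])^2
  dz2 <- ((zi - cx[3]) / semi[3])^2
  inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  idx <- which(inside)
  if (length(idx) == 0) return(integer(0))
  a <- arrayInd(idx, dim(inside))
  (a[, 1] + lo[1] - 1L) +
    (a[, 2] + lo[2] - 2L) * n[1] +
    (a[, 3] + lo[3] - 2L) * n[1] * n[2]
}

# reflect flat voxel indices across the mirror plane between columns nx/2 and
# nx/2 + 1
mirror_indices <- function(idx, nx) {
  a0 <- idx - 1L
  i <- a0 %% nx
  (nx - 1L - i) + (a0 %/% nx) * nx + 1L
}

# quick prefilter: ellipsoid inside the body envelope, with margin
inside_body <- function(center, semi, body_c, body_semi, gap) {
  s <- body_semi - semi - gap
  if (any(s <= 0)) return(FALSE)
  sum(((center - body_c) / s)^2) <= 1
}

#' Generate a synthetic 3D musculoskeletal phantom
#'
#' Places an ellipsoidal body envelope filled with soft-tissue background,
#' then mirrored bone and muscle ellipsoids. Structure placement rejects
#' candidates whose voxels collide with already-placed structures (bounded
#' retries, with gradual size shrinkage; failure is an error naming the
#' structure), so the masks are mutually exclusive by construction. The
#' affected side of each muscle is scaled along its long axis by the spec's
#' `asymmetry_factor`, so the analytic affected/unaffected volume ratio
#' equals the factor. Per-side volumes are recorded from the final voxel
#' counts, so the bookkeeping is exact.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `vox_phantom` with elements `hu` (3D HU array),
#'   `label` (3D integer array, 0 = air, `K+1` = background), `spacing`,
#'   `labels` (tibble of structure metadata), `side_volumes` (tibble of
#'   per-structure per-side voxel volumes), `affected_side` and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$grid_shape
  nx <- n[1]
  sp <- spec$spacing
  L <- n * sp
  half <- L / 2
  body_c <- half
  body_semi <- c(0.92, 0.88, 0.96) * half
  gap <- max(sp)
  mirror_x <- function(x) L[1] - x

  n_pairs_bone <- spec$n_bones %/% 2
  has_mid_bone <- spec$n_bones %% 2 == 1
  background_id <- spec$n_bones + spec$n_muscles + 1L

  label <- array(0L, dim = n)
  hu <- array(-1000, dim = n)
  body_idx <- voxelize_ellipsoid(body_c, body_semi, n, sp)
  label[body_idx] <- background_id
  hu[body_idx] <- spec$background_hu

  structures <- list()
  label_id <- 0L
  new_label <- function() { label_id <<- label_id + 1L; label_id }

  free <- function(idx) {
    length(idx) > 0 && all(label[idx] == background_id)
  }
  claim <- function(idx, id, hu_s) {
    label[idx] <<- id
    hu[idx] <<- hu_s
  }

  # midline bone (sacrum/pelvis stand-in)
  if (has_mid_bone) {
    semi <- c(0.16, 0.16, 0.45) * half
    center <- body_c + c(0, 0, 0.18) * half
    idx <- voxelize_ellipsoid(center, semi, n, sp)
    if (!free(idx)) stop("could not place midline bone")
    hu_s <- runif(1, spec$bone_hu_range[1], spec$bone_hu_range[2])
    claim(idx, new_label(), hu_s)
    structures[[length(structures) + 1]] <- list(
      id = label_id, name = "bone_mid", kind = "bone", side = "midline",
      hu = hu_s,
      members = list(list(center = center, semi = semi, side = "midline")))
  }

  # mirrored bone pairs (femur stand-ins); left and right are separate labels
  for (q in seq_len(n_pairs_bone)) {
    semi0 <- c(runif(1, 0.10, 0.13), runif(1, 0.10, 0.13),
               runif(1, 0.32, 0.42)) * half
    semi <- semi0
    done <- FALSE
    for (try in 1:500) {
      center <- c(body_c[1] - runif(1, 0.35, 0.60) * half[1],
                  body_c[2] + runif(1, -0.25, 0.25) * half[2],
                  body_c[3] - runif(1, 0.05, 0.35) * half[3])
      if (center[1] + semi[1] + gap < body_c[1] &&
          inside_body(center, semi, body_c, body_semi, 0)) {
        idx_l <- voxelize_ellipsoid(center, semi, n, sp)
        idx_r <- mirror_indices(idx_l, nx)
        if (free(idx_l) && free(idx_r)) {
          hu_s <- runif(1, spec$bone_hu_range[1], spec$bone_hu_range[2])
          cm <- c(mirror_x(center[1]), center[2], center[3])
          claim(idx_l, new_label(), hu_s)
          structures[[length(structures) + 1]] <- list(
            id = label_id, name = sprintf("bone_L%d", q), kind = "bone",
            side = "left", hu = hu_s,
            members = list(list(center = center, semi = semi, side = "left")))
          claim(idx_r, new_label(), hu_s)
          structures[[length(structures) + 1]] <- list(
            id = label_id, name = sprintf("bone_R%d", q), kind = "bone",
            side = "right", hu = hu_s,
            members = list(list(center = cm, semi = semi, side = "right")))
          done <- TRUE
          break
        }
      }
      if (try %% 100 == 0) semi <- semi * 0.9
    }
    if (!done) stop(sprintf("could not place bone pair %d without overlap", q))
  }

  # bilateral muscles: one label spans the mirrored pair; the affected-side
  # member is scaled along z by the asymmetry factor
  f <- spec$asymmetry_factor
  for (m in seq_len(spec$n_muscles)) {
    ab <- runif(2, spec$muscle_size_frac[1], spec$muscle_size_frac[2]) *
      half[1:2]
    cc <- runif(1, 1.2, 1.8) * mean(ab)
    semi0 <- c(ab, cc)
    semi <- semi0
    done <- FALSE
    for (try in 1:600) {
      center <- c(body_c[1] - runif(1, 0.12, 0.75) * half[1],
                  body_c[2] + runif(1, -0.62, 0.62) * half[2],
                  body_c[3] + runif(1, -0.78, 0.78) * half[3])
      if (!(center[1] + semi[1] + gap < body_c[1]) ||
          !inside_body(center, semi, body_c, body_semi, 0)) {
        if (try %% 60 == 0) semi <- semi * 0.88
        next
      }
      cm <- c(mirror_x(center[1]), center[2], center[3])
      left_semi <- if (spec$affected_side == "left") semi * c(1, 1, f) else semi
      right_semi <- if (spec$affected_side == "right") semi * c(1, 1, f)
                    else semi
      idx_l <- voxelize_ellipsoid(center, left_semi, n, sp)
      idx_r <- if (f == 1) {
        # exact mirror: a symmetric pair is bit-identical under reflection
        mirror_indices(idx_l, nx)
      } else if (spec$affected_side == "left") {
        mirror_indices(voxelize_ellipsoid(center, semi, n, sp), nx)
      } else {
        mirror_indices(voxelize_ellipsoid(center, right_semi, n, sp), nx)
      }
      if (free(idx_l) && free(idx_r)) {
        hu_s <- runif(1, spec$muscle_hu_range[1], spec$muscle_hu_range[2])
        claim(c(idx_l, idx_r), new_label(), hu_s)
        structures[[length(structures) + 1]] <- list(
          id = label_id, name = sprintf("muscle_%02d", m), kind = "muscle",
          side = "bilateral", hu = hu_s,
          members = list(
            list(center = center, semi = left_semi, side = "left"),
            list(center = cm, semi = right_semi, side = "right")))
        done <- TRUE
        break
      }
      if (try %% 60 == 0) semi <- semi * 0.88
    }
    if (!done) stop(sprintf("could not place muscle %d without overlap", m))
  }
  stopifnot(label_id == background_id - 1L)

  # --- bookkeeping from the final label map ------------------------------
  vox_vol <- prod(sp)
  is_left <- slice.index(label, 1) <= nx / 2
  all_names <- c(vapply(structures, `[[`, "", "name"), "background")
  all_ids <- c(vapply(structures, function(s) s$id, 0L), background_id)
  side_rows <- lapply(seq_along(all_ids), function(k) {
    in_s <- label == all_ids[k]
    nl <- sum(in_s & is_left)
    nr <- sum(in_s & !is_left)
    tibble::tibble(label_id = all_ids[k], name = all_names[k],
                   side = c("left", "right"), voxels = c(nl, nr),
                   volume_mm3 = c(nl, nr) * vox_vol)
  })
  side_volumes <- dplyr::bind_rows(side_rows)

  # muscle grouping by longitudinal position, mimicking hip vs thigh regions
  zmid <- body_c[3]
  labels <- dplyr::bind_rows(lapply(structures, function(s) {
    grp <- if (s$kind == "bone") "bone" else {
      if (s$members[[1]]$center[3] >= zmid) "hip muscle" else "thigh muscle"
    }
    tibble::tibble(label_id = s$id, name = s$name, group = grp,
                   side = s$side, hu = s$hu,
                   asymmetric = s$kind == "muscle" && f < 1)
  }))
  labels <- dplyr::bind_rows(labels, tibble::tibble(
    label_id = background_id, name = "background", group = "background",
    side = "midline", hu = spec$background_hu, asymmetric = FALSE))

  structure(list(hu = hu, label = label, spacing = sp,
                 labels = labels, side_volumes = side_volumes,
                 structures = structures,
                 affected_side = spec$affected_side,
                 n_channels = background_id,
                 spec = spec),
            class = "vox_phantom")
}

#' @export
print.vox_phantom <- function(x, ...) {
  cat("<vox_phantom> ", paste(dim(x$label), collapse = "x"),
      " voxels, ", x$n_channels, " labels (incl. background), affected side: ",
      x$affected_side, "\n", sep = "")
  print(x$labels, n = 5)
  invisible(x)
}

#' Extract one binary structure mask from a phantom
#' @param phantom a `vox_phantom`.
#' @param label_id integer label (1..K+1).
#' @return a logical 3D array.
#' @export
phantom_mask <- function(phantom, label_id) {
  phantom$label == label_id
}

#' Draw a random rigid pose perturbation
#'
#' Emulates the pose mismatch between a supine CT scan and a standing
#' radiograph: angles and translations are drawn uniformly within symmetric
#' bounds. Zero bounds yield the identity transform.
#'
#' @param phantom a `vox_phantom` (unused geometrically; kept so the
#'   perturbation can later depend on phantom extent).
#' @param rotation numeric length-3 bound in degrees per axis.
#' @param translation numeric length-3 bound in mm per axis.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a [rigid_transform()].
#' @export
perturb_pose <- function(phantom, rotation = c(5, 5, 5),
                         translation = c(10, 10, 10), seed = 1) {
  stopifnot(all(is.finite(rotation)), all(is.finite(translation)))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  ang <- runif(3, -rotation, rotation)
  tr <- runif(3, -translation, translation)
  if (all(rotation == 0)) ang <- c(0, 0, 0)
  if (all(translation == 0)) tr <- c(0, 0, 0)
  rigid_transform(euler_xyz_matrix(ang), tr, angles_deg = ang)
}

#' Assemble an unpaired training dataset from phantom specs
#'
#' For each case the composite radiograph stand-in is rendered at a randomly
#' perturbed pose with quantum noise, while the per-structure DRRs are
#' rendered at the unperturbed pose, reproducing the roughly-aligned,
#' unpaired condition of CT-derived DRRs versus standing radiographs.
#' Normalization constants are computed from the training split only and
#' shared by every case.
#'
#' @param specs list of [phantom_spec()] (>= 2 cases; channel counts must
#'   agree across cases).
#' @param geometry a [projection_geometry()]; default is the axis-aligned
#'   parallel geometry of the first phantom.
#' @param noise list with element `i0` (photons per unexposed pixel); `NULL`
#'   or `i0 = Inf` disables noise.
#' @param pose_bounds list with `rotation` (deg) and `translation` (mm)
#'   bounds for the radiograph pose perturbation; zero bounds give exact
#'   pose agreement.
#' @param splits named fractions (train/val/test) summing to 1.
#' @param seed integer; fans out to per-case seeds.
#' @param mu_water water attenuation coefficient in 1/mm.
#' @param dir optional directory; when given, volumes and images are written
#'   to disk (NIfTI + float TIFF) and the manifest records the paths.
#' @return an object of class `xdecomp_manifest`: `cases` tibble, in-memory
#'   `data` records, shared `normalization`, `geometry` and `labels`.
#' @export
build_dataset <- function(specs, geometry = NULL, noise = list(i0 = 1e4),
                          pose_bounds = list(rotation = c(3, 3, 3),
                                             translation = c(6, 6, 6)),
                          splits = c(train = 0.5, val = 0.25, test = 0.25),
                          seed = 1, mu_water = 0.02, dir = NULL) {
  stopifnot(length(specs) >= 2)
  if (abs(sum(splits) - 1) > 1e-9) stop("split fractions must sum to 1")
  if (any(splits < 0)) stop("split fractions must be non-negative")

  n_cases <- length(specs)
  counts <- diff(c(0, round(cumsum(splits) * n_cases)))
  if (any(counts[splits > 0] == 0)) stop("empty split")
  split_of <- rep(names(splits), counts)

  data <- vector("list", n_cases)
  rows <- list()
  labels <- NULL
  for (i in seq_len(n_cases)) {
    ph <- generate_phantom(specs[[i]])
    if (is.null(geometry)) geometry <- geometry_for_phantom(ph)
    if (is.null(labels)) labels <- ph$labels
    if (nrow(ph$labels) != nrow(labels))
      stop("all cases must share the same structure layout")
    pose_drr <- rigid_transform()
    pose_xr <- perturb_pose(ph, pose_bounds$rotation, pose_bounds$translation,
                            seed = derive_seed(seed, i))
    drr <- render(ph, geometry, mu_water = mu_water, integrator = "exact")
    xr <- if (is_identity_transform(pose_xr)) {
      drr$radiograph
    } else {
      render(ph, set_pose(geometry, pose_xr), mu_water = mu_water,
             integrator = "exact")$radiograph
    }
    if (!is.null(noise) && is.finite(noise$i0 %||% Inf)) {
      xr <- add_poisson_noise(xr, i0 = noise$i0,
                              seed = derive_seed(seed, i + n_cases))
    }
    data[[i]] <- list(phantom = ph, drr = drr$drr, composite = drr$radiograph,
                      radiograph = xr, pose_xray = pose_xr,
                      pose_drr = pose_drr)
    rows[[i]] <- tibble::tibble(
      case_id = i, split = split_of[i], phantom_seed = specs[[i]]$seed,
      pose_angles = list(pose_xr$angles_deg %||% c(0, 0, 0)),
      pose_translation = list(pose_xr$translation))
  }

  train_ids <- which(split_of == "train")
  raw_max <- max(vapply(train_ids,
                        function(i) max(data[[i]]$composite$pixels),
                        numeric(1)))
  if (raw_max <= 0) stop("degenerate normalization range (max = min)")
  norm <- normalization(raw_min = 0, raw_max = raw_max)

  manifest <- structure(list(cases = dplyr::bind_rows(rows), data = data,
                             normalization = norm, geometry = geometry,
                             labels = labels, seed = seed,
                             noise = noise, pose_bounds = pose_bounds),
                        class = "xdecomp_manifest")
  if (!is.null(dir)) manifest <- write_manifest(manifest, dir)
  manifest
}

#' @export
print.xdecomp_manifest <- function(x, ...) {
  cat("<xdecomp_manifest> ", nrow(x$cases), " cases (",
      paste(sprintf("%s=%d", names(table(x$cases$split)),
                    as.integer(table(x$cases$split))), collapse = ", "),
      "), ", nrow(x$labels), " structure labels\n", sep = "")
  cat("  normalization raw range: [", x$normalization$raw_min, ", ",
      format(x$normalization$raw_max, digits = 5), "] -> [0,255]\n", sep = "")
  invisible(x)
}

manifest_split <- function(manifest, split) {
  which(manifest$cases$split == split)
}
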