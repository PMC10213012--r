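#' Derive a stage seed from a global seed
#'
#' A single experiment seed fans out to per-stage seeds through a fixed
#' integer recurrence, so each pipeline stage is independently reproducible
#' without sharing RNG streams. Results stay below 2^31.
#'
#' @param seed integer global seed.
#' @param index non-negative integer stage counter.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index), index >= 0)
  as.integer((abs(seed) * 48271 + index * 16807) %% 2147483629) + 1L
}

#' Rotation matrix from XYZ Euler angles
#'
#' @param angles_deg numeric length-3 rotation angles in degrees, applied in
#'   X, then Y, then Z order (extrinsic).
#' @return a 3x3 proper rotation matrix.
#' @export
euler_xyz_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' Construct a rigid transform
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation numeric length-3 translation in mm.
#' @param angles_deg optional Euler angles the rotation was built from.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            angles_deg = NULL) {
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-8 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 angles_deg = angles_deg),
            class = "rigid_transform")
}

#' Compose two rigid transforms (apply `inner` first, then `outer`)
#' @param outer,inner `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose_transform <- function(outer, inner) {
  rigid_transform(outer$rotation %*% inner$rotation,
                  as.numeric(outer$rotation %*% inner$translation) +
                    outer$translation)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  if (!is.null(x$angles_deg))
    cat("  angles (deg):", format(x$angles_deg, digits = 4), "\n")
  cat("  translation (mm):", format(x$translation, digits = 4), "\n")
  invisible(x)
}

is_identity_transform <- function(tf, tol = 1e-12) {
  max(abs(tf$rotation - diag(3))) < tol && max(abs(tf$translation)) < tol
}

# md5 of an arbitrary R object via its serialization (used for pipeline
# idempotence checks; no external hashing dependency available)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # version 2 serialization is stable across the R versions we target
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
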