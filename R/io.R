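# File formats: volumes as NIfTI (label map + HU volume), images as float
# TIFF (raw line integrals) or 16-bit TIFF (normalized), tables as CSV,
# manifests and sidecar metadata as JSON, configs as YAML.

# TIFF samples live in [0,1]; raw line integrals are stored divided by a
# per-image scale recorded in a JSON sidecar
write_float_tiff <- function(mat, path) {
  s <- max(max(mat), 1e-12)
  tiff::writeTIFF(mat / s, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(list(scale = s), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
}

read_float_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  s <- jsonlite::read_json(paste0(path, ".json"))$scale
  m * s
}

write_norm_tiff16 <- function(mat255, path) {
  tiff::writeTIFF(pmin(pmax(mat255 / 255, 0), 1), path, bits.per.sample = 16)
}

#' Write a phantom to disk
#'
#' The HU volume and the integer label map are written as NIfTI with the
#' voxel spacing in the header, plus CSV tables for the label metadata and
#' per-side volumes and a JSON sidecar for the remaining fields.
#'
#' @param phantom a `vox_phantom`.
#' @param dir output directory (created if needed).
#' @param id case identifier used in file names.
#' @return (invisibly) the named list of written paths.
#' @export
write_phantom <- function(phantom, dir, id = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, sprintf("case%03d", id))
  paths <- list(hu = paste0(base, "_hu.nii.gz"),
                label = paste0(base, "_label.nii.gz"),
                labels = paste0(base, "_labels.csv"),
                side_volumes = paste0(base, "_side_volumes.csv"),
                meta = paste0(base, "_meta.json"))
  hu_img <- RNifti::asNifti(phantom$hu)
  RNifti::pixdim(hu_img) <- phantom$spacing
  RNifti::writeNifti(hu_img, paths$hu)
  lab_img <- RNifti::asNifti(phantom$label + 0L)
  RNifti::pixdim(lab_img) <- phantom$spacing
  RNifti::writeNifti(lab_img, paths$label)
  utils::write.csv(phantom$labels, paths$labels, row.names = FALSE)
  utils::write.csv(phantom$side_volumes, paths$side_volumes,
                   row.names = FALSE)
  jsonlite::write_json(list(spacing = phantom$spacing,
                            affected_side = phantom$affected_side,
                            n_channels = phantom$n_channels),
                       paths$meta, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a phantom written by [write_phantom()]
#' @param dir directory holding the files.
#' @param id case identifier.
#' @return a `vox_phantom` (without the generating spec and the analytic
#'   structure geometry, which are not needed downstream).
#' @export
read_phantom <- function(dir, id = 1) {
  base <- file.path(dir, sprintf("case%03d", id))
  meta <- jsonlite::read_json(paste0(base, "_meta.json"),
                              simplifyVector = TRUE)
  hu <- array(as.numeric(RNifti::readNifti(paste0(base, "_hu.nii.gz"))),
              dim = dim(RNifti::readNifti(paste0(base, "_hu.nii.gz"))))
  lab_img <- RNifti::readNifti(paste0(base, "_label.nii.gz"))
  label <- array(as.integer(round(as.numeric(lab_img))), dim = dim(lab_img))
  structure(list(hu = hu, label = label, spacing = meta$spacing,
                 labels = tibble::as_tibble(
                   utils::read.csv(paste0(base, "_labels.csv"))),
                 side_volumes = tibble::as_tibble(
                   utils::read.csv(paste0(base, "_side_volumes.csv"))),
                 structures = NULL,
                 affected_side = meta$affected_side,
                 n_channels = as.integer(meta$n_channels),
                 spec = NULL),
            class = "vox_phantom")
}

geometry_to_list <- function(g) {
  list(model = g$model, sdd = g$sdd, detector_shape = g$detector_shape,
       pixel_pitch = g$pixel_pitch,
       pose = list(rotation = as.numeric(g$pose$rotation),
                   translation = g$pose$translation))
}

geometry_from_list <- function(l) {
  projection_geometry(l$model, l$sdd, unlist(l$detector_shape),
                      l$pixel_pitch,
                      pose = rigid_transform(
                        matrix(unlist(l$pose$rotation), 3, 3),
                        unlist(l$pose$translation)))
}

#' Write a dataset manifest and its images to a directory
#'
#' Per case: the phantom (NIfTI + CSV), the per-structure DRR channels and
#' the composite and noisy radiograph as float TIFF. The manifest JSON
#' records paths, splits, poses, the shared normalization and the geometry.
#'
#' @param manifest an `xdecomp_manifest`.
#' @param dir output directory.
#' @return the manifest with a `dir` field and per-case paths recorded.
#' @export
write_manifest <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  case_entries <- list()
  for (i in seq_len(nrow(manifest$cases))) {
    rec <- manifest$data[[i]]
    cdir <- file.path(dir, sprintf("case%03d", i))
    dir.create(cdir, showWarnings = FALSE)
    write_phantom(rec$phantom, cdir, i)
    ch <- rec$drr$channels
    ch_paths <- character(dim(ch)[3])
    for (c in seq_len(dim(ch)[3])) {
      ch_paths[c] <- file.path(cdir, sprintf("drr_ch%02d.tif", c))
      write_float_tiff(ch[, , c], ch_paths[c])
    }
    comp_path <- file.path(cdir, "composite.tif")
    xr_path <- file.path(cdir, "radiograph.tif")
    write_float_tiff(rec$composite$pixels, comp_path)
    write_float_tiff(rec$radiograph$pixels, xr_path)
    case_entries[[i]] <- list(
      case_id = i, split = manifest$cases$split[i],
      pose_angles = manifest$cases$pose_angles[[i]],
      pose_translation = manifest$cases$pose_translation[[i]],
      phantom_dir = cdir, channels = ch_paths,
      composite = comp_path, radiograph = xr_path)
  }
  jsonlite::write_json(
    list(cases = case_entries,
         normalization = list(raw_min = manifest$normalization$raw_min,
                              raw_max = manifest$normalization$raw_max),
         geometry = geometry_to_list(manifest$geometry),
         seed = manifest$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  manifest$dir <- dir
  manifest
}

#' Read a dataset manifest written by [write_manifest()]
#' @param dir directory holding `manifest.json`.
#' @return an `xdecomp_manifest`.
#' @export
read_manifest <- function(dir) {
  j <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = FALSE)
  n <- length(j$cases)
  data <- vector("list", n)
  rows <- list()
  labels <- NULL
  for (i in seq_len(n)) {
    ce <- j$cases[[i]]
    for (p in c(ce$composite, ce$radiograph, unlist(ce$channels))) {
      if (!file.exists(p)) stop("missing dataset file: ", p)
    }
    ph <- read_phantom(ce$phantom_dir, i)
    if (is.null(labels)) labels <- ph$labels
    chans <- lapply(unlist(ce$channels), read_float_tiff)
    ch <- array(0, c(dim(chans[[1]]), length(chans)))
    for (c in seq_along(chans)) ch[, , c] <- chans[[c]]
    comp <- read_float_tiff(ce$composite)
    xr <- read_float_tiff(ce$radiograph)
    data[[i]] <- list(phantom = ph,
                      drr = decomposed_set(ch, ph$labels, raw = TRUE),
                      composite = radiograph(comp, raw = TRUE),
                      radiograph = radiograph(xr, raw = TRUE,
                                              provenance = "synthetic-noisy"))
    rows[[i]] <- tibble::tibble(case_id = i, split = ce$split,
                                phantom_seed = NA_integer_,
                                pose_angles = list(unlist(ce$pose_angles)),
                                pose_translation =
                                  list(unlist(ce$pose_translation)))
  }
  structure(list(cases = dplyr::bind_rows(rows), data = data,
                 normalization = normalization(j$normalization$raw_min,
                                               j$normalization$raw_max),
                 geometry = geometry_from_list(j$geometry),
                 labels = labels, seed = j$seed, dir = dir),
            class = "xdecomp_manifest")
}

#' Write an evaluation report as CSV tables plus a JSON summary
#' @param report an `xdecomp_report`.
#' @param dir output directory.
#' @return (invisibly) the written paths.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(structures = file.path(dir, "structures.csv"),
                thresholds = file.path(dir, "thresholds.csv"),
                groups = file.path(dir, "groups.csv"),
                ratios = file.path(dir, "ratios.csv"),
                summary = file.path(dir, "summary.json"))
  utils::write.csv(report$structures, paths$structures, row.names = FALSE)
  utils::write.csv(report$thresholds, paths$thresholds, row.names = FALSE)
  utils::write.csv(report$groups, paths$groups, row.names = FALSE)
  utils::write.csv(report$ratios, paths$ratios, row.names = FALSE)
  jsonlite::write_json(list(glance = as.list(glance(report)),
                            icc = report$icc),
                       paths$summary, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
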