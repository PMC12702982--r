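#' Load a 3D image stack as a tissue state
#'
#' Reads a trabecular image volume and thresholds it into bone and marrow:
#' voxels at or above `threshold` become bone (`mineral = osteoid = 1`), the
#' rest marrow. Supported formats: NIfTI-1 (`.nii`, `.nii.gz`; spacing taken
#' from the header, which this package writes in micrometres), multipage or
#' per-slice TIFF (`.tif`/`.tiff` file, or a directory of slice files sorted
#' by name), and raw `uint8`/`uint16` with a YAML sidecar (`<file>.yaml`
#' holding `dims` in zyx order, `spacing_um`, `dtype`).
#'
#' @param path file (or slice directory) to read.
#' @param spacing voxel spacing in micrometres; required for TIFF and ignored
#'   for NIfTI/raw whose metadata carries it.
#' @param threshold greyscale threshold (on the 0-1 scale for TIFF, raw value
#'   otherwise) at or above which a voxel is bone.
#' @return A [tissue_state()].
#' @export
load_image_stack <- function(path, spacing = NULL, threshold = 0.5) {
  lower <- tolower(path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L) stop("no TIFF slices found in ", path)
    slices <- lapply(files, tiff::readTIFF)
    vol <- simplify2array(slices)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)[1:3]
    if (max(pd) - min(pd) > 1e-6 * max(pd))
      stop("anisotropic voxels: pixdim = ", paste(signif(pd, 6), collapse = " x "))
    spacing <- pd[1]
    vol <- array(as.numeric(img), dim(img))
  } else if (grepl("\\.tiff?$", lower)) {
    sl <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(sl)) sl <- list(sl)
    vol <- simplify2array(sl)
  } else if (grepl("\\.raw$", lower)) {
    meta <- yaml::read_yaml(paste0(path, ".yaml"))
    dims_zyx <- as.integer(meta$dims)
    spacing <- meta$spacing_um
    dtype <- meta$dtype %||% "uint8"
    size <- if (dtype == "uint16") 2L else 1L
    n <- prod(dims_zyx)
    v <- readBin(path, what = "integer", n = n, size = size, signed = FALSE,
                 endian = "little")
    vol <- array(as.numeric(v), rev(dims_zyx)) # stored x-fastest
  } else stop("unrecognized image format: ", path)
  if (length(dim(vol)) != 3L) stop("expected a 3D volume, got dims ",
                                   paste(dim(vol), collapse = " x "))
  if (is.null(spacing)) stop("spacing must be supplied for this format")
  bone <- vol >= threshold
  if (!any(bone)) stop("empty bone phase: threshold ", threshold,
                       " is above the image maximum ", max(vol))
  frac <- array(as.numeric(bone), dim(vol))
  tissue_state(mineral = frac, osteoid = frac, spacing = spacing)
}

#' Write a tissue state as an image stack
#'
#' Mirrors [load_image_stack()]: the bone mask is written so that a
#' write-then-read round trip reproduces the tissue voxel-identically.
#'
#' @param tissue a [tissue_state()].
#' @param path output path; format chosen from the extension (`.nii`,
#'   `.tif`, `.raw`).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(tissue, path) {
  bone <- bone_mask(tissue)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::asNifti(array(as.numeric(bone), dim(bone)))
    RNifti::pixdim(img) <- rep(tissue$spacing, 3)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.tiff?$", lower)) {
    slices <- lapply(seq_len(dim(bone)[3]),
                     function(k) matrix(as.numeric(bone[, , k]),
                                        dim(bone)[1], dim(bone)[2]))
    tiff::writeTIFF(slices, path)
  } else if (grepl("\\.raw$", lower)) {
    writeBin(as.integer(bone), path, size = 1L, endian = "little")
    yaml::write_yaml(list(dims = rev(dim(bone)), spacing_um = tissue$spacing,
                          dtype = "uint8", order = "zyx"),
                     paste0(path, ".yaml"))
  } else stop("unrecognized image format: ", path)
  invisible(path)
}

#' Save / load full simulation state snapshots
#'
#' Snapshots keep the continuous mineral and osteoid fields (not just the
#' bone mask) as a pair of NIfTI volumes plus a YAML sidecar with spacing and
#' simulation time.
#'
#' @param tissue a [tissue_state()].
#' @param dir output directory (created if missing).
#' @param label snapshot label used in filenames.
#' @param time_days simulation time recorded in the sidecar.
#' @return The sidecar path, invisibly.
#' @export
save_state_snapshot <- function(tissue, dir, label = "state", time_days = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (field in c("mineral", "osteoid")) {
    img <- RNifti::asNifti(tissue[[field]])
    RNifti::pixdim(img) <- rep(tissue$spacing, 3)
    RNifti::writeNifti(img, file.path(dir, paste0(label, "_", field, ".nii.gz")))
  }
  meta <- file.path(dir, paste0(label, ".yaml"))
  yaml::write_yaml(list(spacing_um = tissue$spacing, time_days = time_days,
                        dims = dim(tissue$osteoid),
                        bone_threshold = tissue$bone_threshold), meta)
  invisible(meta)
}

#' @rdname save_state_snapshot
#' @export
load_state_snapshot <- function(dir, label = "state") {
  meta <- yaml::read_yaml(file.path(dir, paste0(label, ".yaml")))
  rd <- function(field) {
    img <- RNifti::readNifti(file.path(dir, paste0(label, "_", field, ".nii.gz")))
    array(as.numeric(img), dim(img))
  }
  tissue_state(mineral = rd("mineral"), osteoid = rd("osteoid"),
               spacing = meta$spacing_um,
               bone_threshold = meta$bone_threshold %||% 0.5)
}
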