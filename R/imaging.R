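# DRR synthesis and patch construction.  Projections are parallel-beam line
# integrals: the coronal (anterior) view sums the volume along the
# anterior-posterior axis (dim 2) and is indexed (sagittal, axial); the
# sagittal (lateral) view sums along the left-right axis (dim 1) and is
# indexed (coronal, axial).

#' Parallel-beam projection of a volume
#'
#' Simulates an orthogonal radiograph by integrating intensity along the
#' ray axis (raw line integral, no attenuation model and no normalisation).
#'
#' @param volume Finite, nonnegative 3D numeric array in the package's
#'   (sagittal, coronal, axial) axis convention.
#' @param view `"coronal"` (integrate along dim 2) or `"sagittal"`
#'   (integrate along dim 1).
#' @param spacing Voxel spacing triple (mm); the two retained axes' spacings
#'   are recorded on the image.
#' @return A `projection_image`: list with `pixels` (2D array), `view`,
#'   `spacing` (mm pair) and `retained_axes` (which volume axes the pixel
#'   rows/columns correspond to).
#' @export
project <- function(volume, view = c("coronal", "sagittal"),
                    spacing = c(1, 1, 1)) {
  view <- match.arg(view)
  if (length(dim(volume)) != 3L) stopf("volume must be a 3D array")
  if (anyNA(volume) || any(!is.finite(volume)))
    stopf("volume contains NaN or non-finite voxels")
  if (any(volume < 0)) stopf("volume contains negative voxels")
  if (view == "coronal") {
    pixels <- apply(volume, c(1, 3), sum)
    retained <- c(1L, 3L)
  } else {
    pixels <- apply(volume, c(2, 3), sum)
    retained <- c(2L, 3L)
  }
  structure(list(pixels = pixels, view = view,
                 spacing = spacing[retained], retained_axes = retained),
            class = "projection_image")
}

#' Min-max normalisation of an image to [0, 1]
#'
#' Constant images map to all zeros (declared convention).
#'
#' @param image 2D numeric array (or a `projection_image`).
#' @return 2D array with values in `[0, 1]`.
#' @export
normalize_image <- function(image) {
  px <- if (inherits(image, "projection_image")) image$pixels else image
  if (anyNA(px) || any(!is.finite(px))) stopf("image must be finite")
  rng <- range(px)
  if (rng[1] == rng[2]) return(array(0, dim = dim(px)))
  (px - rng[1]) / (rng[2] - rng[1])
}

#' Crop a square patch around a pixel
#'
#' Extracts a `size` x `size` window centred on `center`; for even sizes
#' the centre pixel occupies 0-based window index `size/2`.  Regions falling
#' outside the image are zero-filled.
#'
#' @param image 2D numeric array or `projection_image`.
#' @param center Pixel pair (1-based); must lie inside the image.
#' @param size Window size in pixels; default 120.
#' @return `size` x `size` numeric matrix.
#' @export
crop_patch <- function(image, center, size = 120L) {
  px <- if (inherits(image, "projection_image")) image$pixels else image
  center <- as.integer(round(center))
  if (any(center < 1L) || center[1] > nrow(px) || center[2] > ncol(px))
    stopf("crop centre (%d, %d) lies outside the %dx%d image",
          center[1], center[2], nrow(px), ncol(px))
  extract_window(px, list(crop_index(center[1], size),
                          crop_index(center[2], size)))
}

#' Binary disk centroid mask
#'
#' Marks the annotated vertebra's centre on a `size` x `size` canvas: pixel
#' (i, j) is set iff its squared Euclidean distance to `center` is at most
#' `radius^2`.
#'
#' @param size Canvas size in pixels.
#' @param center Pixel pair (1-based) inside the canvas.
#' @param radius Disk radius in pixels (default 4).
#' @return `size` x `size` binary (0/1) matrix.
#' @export
centroid_mask <- function(size, center, radius = 4L) {
  center <- as.integer(round(center))
  if (any(center < 1L) || any(center > size))
    stopf("centroid (%d, %d) lies outside the %dx%d canvas",
          center[1], center[2], size, size)
  di <- seq_len(size) - center[1]
  dj <- seq_len(size) - center[2]
  (outer(di^2, dj^2, `+`) <= radius^2) * 1
}

#' Construct a patch pair sample
#'
#' @param coronal_patch,sagittal_patch `S` x `S` patches with values in
#'   `[0, 1]`.
#' @param coronal_centroid_mask,sagittal_centroid_mask `S` x `S` binary
#'   centroid masks with at least one foreground pixel.
#' @param target Optional `S`^3 binary occupancy array (training target).
#' @param vertebra_label Anatomical position code (e.g. "L1").
#' @param subject_id Subject identifier.
#' @param crop_offset Optional 1-based voxel triple: position of the
#'   target window's first voxel in the source volume (used to re-assemble
#'   reconstructed vertebrae into a spine).
#' @return An object of class `patch_pair`.
#' @export
patch_pair <- function(coronal_patch, sagittal_patch,
                       coronal_centroid_mask, sagittal_centroid_mask,
                       target = NULL, vertebra_label = "?",
                       subject_id = "subject", crop_offset = NULL) {
  S <- nrow(coronal_patch)
  arrs <- list(coronal_patch, sagittal_patch,
               coronal_centroid_mask, sagittal_centroid_mask)
  if (!all(vapply(arrs, function(a) all(dim(a) == c(S, S)), TRUE)))
    stopf("all four 2D arrays must be %dx%d", S, S)
  if (min(coronal_patch) < 0 || max(coronal_patch) > 1 ||
      min(sagittal_patch) < 0 || max(sagittal_patch) > 1)
    stopf("patch intensities must lie in [0, 1]")
  if (sum(coronal_centroid_mask) < 1 || sum(sagittal_centroid_mask) < 1)
    stopf("each centroid mask needs at least one foreground pixel")
  if (!is.null(target)) {
    if (!all(dim(target) == c(S, S, S)))
      stopf("target must be %d^3", S)
    if (sum(target) < 1) stopf("target has no foreground voxel")
  }
  structure(list(coronal_patch = coronal_patch,
                 sagittal_patch = sagittal_patch,
                 coronal_centroid_mask = coronal_centroid_mask,
                 sagittal_centroid_mask = sagittal_centroid_mask,
                 target = target, vertebra_label = vertebra_label,
                 subject_id = subject_id, crop_offset = crop_offset),
            class = "patch_pair")
}

#' Build one patch pair per annotated vertebra
#'
#' Projects the record into both orthogonal views, and for each centroid
#' row crops a per-vertebra patch from each raw projection around the
#' projected centroid (then min-max normalises the patch), builds the two
#' centroid-disk masks, and crops the `size`^3 target window from the
#' annotated vertebra's own binary label mask (never a union with
#' neighbours).  Vertebrae whose label mask is empty are skipped with a
#' warning.
#'
#' @param record A [spine_record()].
#' @param size Patch size in pixels/voxels; default 120.
#' @param radius Centroid-disk radius in pixels; default 4.
#' @return List of [patch_pair()] objects.
#' @export
build_pairs <- function(record, size = 120L, radius = 4L) {
  stopifnot(inherits(record, "spine_record"))
  cor_img <- project(record$intensity, "coronal", record$spacing)
  sag_img <- project(record$intensity, "sagittal", record$spacing)
  ctr_pix <- floor(size / 2) + 1L  # window centre, 1-based
  pairs <- list()
  for (i in seq_len(nrow(record$centroids))) {
    v <- record$centroids[i, ]
    vmask <- record$labels == v$label
    if (!any(vmask)) {
      warning(sprintf("vertebra %s of %s has an empty label mask; skipped",
                      v$vertebra_label, record$subject_id))
      next
    }
    cor_patch <- normalize_image(crop_patch(cor_img, c(v$x, v$z), size))
    sag_patch <- normalize_image(crop_patch(sag_img, c(v$y, v$z), size))
    cmask <- centroid_mask(size, c(ctr_pix, ctr_pix), radius)
    idx <- list(crop_index(v$x, size), crop_index(v$y, size),
                crop_index(v$z, size))
    target <- extract_window(vmask * 1, idx)
    offset <- vapply(idx, `[`, 0L, 1L)
    pairs[[length(pairs) + 1L]] <- patch_pair(
      cor_patch, sag_patch, cmask, cmask, target,
      vertebra_label = v$vertebra_label, subject_id = record$subject_id,
      crop_offset = offset)
  }
  pairs
}

#' Persist patch pairs to disk
#'
#' Writes each pair's coronal/sagittal patches and centroid masks as TIFF,
#' its target volume as NIfTI, and a `manifest.csv` listing subject,
#' vertebra code and crop offsets.
#'
#' @param pairs List of [patch_pair()] objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_patch_pairs <- function(pairs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    stem <- file.path(dir, sprintf("%s_%s", p$subject_id, p$vertebra_label))
    tiff::writeTIFF(p$coronal_patch, paste0(stem, "_coronal.tif"))
    tiff::writeTIFF(p$sagittal_patch, paste0(stem, "_sagittal.tif"))
    tiff::writeTIFF(p$coronal_centroid_mask, paste0(stem, "_cmask_cor.tif"))
    tiff::writeTIFF(p$sagittal_centroid_mask, paste0(stem, "_cmask_sag.tif"))
    if (!is.null(p$target))
      RNifti::writeNifti(RNifti::asNifti(p$target + 0),
                         paste0(stem, "_target.nii.gz"))
    off <- p$crop_offset
    if (is.null(off)) off <- rep(NA_integer_, 3)
    rows[[i]] <- data.frame(subject_id = p$subject_id,
                            vertebra_label = p$vertebra_label,
                            offset_x = off[1], offset_y = off[2],
                            offset_z = off[3], stringsAsFactors = FALSE)
  }
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
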