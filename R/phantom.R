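# Synthetic spine phantoms: stylised vertebrae (elliptic-cylinder body plus
# posterior and transverse processes) stacked into a labelled spine volume
# with per-vertebra centroids.  These stand in for labelled CT so that every
# downstream stage (projection, patch building, training, evaluation) is
# testable without external data.

#' Phantom generation settings
#'
#' Describes a synthetic spine: volume geometry, number of vertebrae, the
#' sampling ranges for the vertebral-body ellipse radii / height and the
#' process lengths (all in voxels), the two-level intensity model and the
#' additive noise level.
#'
#' @param volume_shape Integer triple, volume extent in voxels along the
#'   (sagittal, coronal, axial) axes.
#' @param n_vertebrae Number of vertebrae to stack (>= 1).
#' @param body_radius_range Interval (voxels) from which the two ellipse
#'   radii of each vertebral body are drawn.
#' @param body_height_range Interval (voxels) for the body height.
#' @param process_length_range Interval (voxels) for how far the spinous and
#'   transverse processes protrude beyond the body surface.
#' @param intensity_bone,intensity_background Intensity assigned to bone and
#'   background voxels; bone must exceed background.
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0);
#'   intensities are clipped at zero afterwards.
#' @param gap Minimum axial gap (voxels) between consecutive vertebrae.
#' @param start_code Anatomical position code of the most inferior vertebra;
#'   codes ascend consecutively (e.g. "T10", "T11", "T12", "L1", ...).
#' @param spacing Voxel spacing in mm (triple).
#' @param seed Integer seed making the phantom reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(64L, 64L, 96L),
                         n_vertebrae = 4L,
                         body_radius_range = c(6, 9),
                         body_height_range = c(8, 12),
                         process_length_range = c(4, 7),
                         intensity_bone = 1000,
                         intensity_background = 50,
                         noise_sd = 20,
                         gap = 3L,
                         start_code = "T10",
                         spacing = c(1, 1, 1),
                         seed = 1L) {
  if (length(volume_shape) != 3L || any(volume_shape < 8))
    stopf("volume_shape must be a triple of extents >= 8")
  if (!is_count(n_vertebrae))
    stopf("n_vertebrae must be a positive integer")
  for (rg in list(body_radius_range, body_height_range,
                  process_length_range)) {
    if (length(rg) != 2L || rg[1] > rg[2] || rg[1] < 0)
      stopf("ranges must be nonempty intervals of nonnegative values")
  }
  if (max(body_radius_range) * 2 >= min(volume_shape[1:2]))
    stopf("body_radius_range exceeds the transverse volume extent")
  if (intensity_bone <= intensity_background)
    stopf("intensity_bone must exceed intensity_background")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(
    volume_shape = as.integer(volume_shape),
    n_vertebrae = as.integer(n_vertebrae),
    body_radius_range = as.numeric(body_radius_range),
    body_height_range = as.numeric(body_height_range),
    process_length_range = as.numeric(process_length_range),
    intensity_bone = intensity_bone,
    intensity_background = intensity_background,
    noise_sd = noise_sd,
    gap = as.integer(gap),
    start_code = start_code,
    spacing = as.numeric(spacing),
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Deterministic mask for one vertebra given explicit geometry.  The body is
# the discrete elliptic cylinder (dx/rx)^2 + (dy/ry)^2 <= 1, |dz| <= h/2.
# The spinous process is a 3x3-section bar protruding `proc_len` voxels in
# the posterior (+coronal) direction, the transverse processes protrude
# laterally on both sides; all bars start inside the body so the mask is one
# connected component.  proc_len = 0 yields the bare cylinder.
build_vertebra_mask <- function(shape, center, rx, ry, h, proc_len,
                                proc_halfwidth = 1L) {
  cx <- center[1]; cy <- center[2]; cz <- center[3]
  need <- c(cx - rx, shape[1] - cx - rx,
            cy - ry, shape[2] - cy - ry - proc_len,
            cz - h / 2, shape[3] - cz - h / 2)
  if (proc_len > 0) {
    need <- c(need, cx - rx - proc_len, shape[1] - cx - rx - proc_len)
  }
  if (any(need < 1))
    stopf("vertebra at (%d, %d, %d) does not fit inside the %s volume",
          cx, cy, cz, paste(shape, collapse = "x"))
  dx <- seq_len(shape[1]) - cx
  dy <- seq_len(shape[2]) - cy
  dz <- seq_len(shape[3]) - cz
  ell <- outer((dx / rx)^2, (dy / ry)^2, `+`) <= 1
  zin <- abs(dz) <= h / 2
  mask <- array(FALSE, dim = shape)
  mask[, , which(zin)] <- ell
  if (proc_len > 0) {
    w <- proc_halfwidth
    bar_z <- abs(dz) <= w
    # spinous process: along +coronal from the body centre
    sp_x <- abs(dx) <= w
    sp_y <- dy >= 0 & dy <= ry + proc_len
    mask[sp_x, sp_y, bar_z] <- TRUE
    # transverse processes: along both sagittal directions
    tr_x <- abs(dx) <= rx + proc_len
    tr_y <- abs(dy) <= w
    mask[tr_x, tr_y, bar_z] <- TRUE
  }
  mask
}

#' Generate a single synthetic vertebra
#'
#' Draws the body radii, height and process length from the ranges in
#' `spec` (reproducibly from `spec$seed`) and rasterises the vertebra at
#' `center`.  The centroid is the rounded voxel mean of the body cylinder,
#' which by symmetry equals `center`.
#'
#' @param spec A [phantom_spec()].
#' @param center Voxel triple; must leave room for the body and processes.
#' @return List with `mask` (logical 3D array) and `centroid` (voxel triple).
#' @export
make_vertebra_phantom <- function(spec, center) {
  stopifnot(inherits(spec, "phantom_spec"))
  center <- as.integer(round(center))
  with_seed(spec$seed, {
    rx <- stats::runif(1, spec$body_radius_range[1], spec$body_radius_range[2])
    ry <- stats::runif(1, spec$body_radius_range[1], spec$body_radius_range[2])
    h  <- stats::runif(1, spec$body_height_range[1], spec$body_height_range[2])
    pl <- round(stats::runif(1, spec$process_length_range[1],
                             spec$process_length_range[2]))
    mask <- build_vertebra_mask(spec$volume_shape, center, rx, ry, h, pl)
    dx <- seq_len(spec$volume_shape[1]) - center[1]
    dy <- seq_len(spec$volume_shape[2]) - center[2]
    dz <- seq_len(spec$volume_shape[3]) - center[3]
    body <- array(FALSE, dim = spec$volume_shape)
    body[, , which(abs(dz) <= h / 2)] <-
      outer((dx / rx)^2, (dy / ry)^2, `+`) <= 1
    idx <- which(body, arr.ind = TRUE)
    centroid <- as.integer(round(colMeans(idx)))
    list(mask = mask, centroid = centroid)
  })
}

#' Construct a SpineRecord container
#'
#' @param intensity 3D numeric array.
#' @param labels 3D integer array of the same shape; 0 = background, k >= 1
#'   identifies a vertebra.
#' @param centroids Data frame with columns `vertebra_label` (anatomical
#'   code), `label` (integer id), `x`, `y`, `z` (1-based voxel coordinates).
#' @param spacing Voxel spacing in mm (triple).
#' @param subject_id Subject identifier string.
#' @return An object of class `spine_record`.
#' @export
spine_record <- function(intensity, labels, centroids, spacing = c(1, 1, 1),
                         subject_id = "subject") {
  if (!identical(dim(intensity), dim(labels)))
    stopf("intensity and labels must share their shape")
  req <- c("vertebra_label", "label", "x", "y", "z")
  if (!all(req %in% names(centroids)))
    stopf("centroids must have columns %s", paste(req, collapse = ", "))
  for (i in seq_len(nrow(centroids))) {
    v <- centroids[i, ]
    if (labels[v$x, v$y, v$z] != v$label)
      stopf("centroid of %s does not lie inside its labelled component",
            v$vertebra_label)
  }
  if (anyDuplicated(centroids$label))
    stopf("vertebra ids must be unique")
  structure(list(intensity = intensity, labels = labels,
                 centroids = centroids, spacing = as.numeric(spacing),
                 subject_id = subject_id),
            class = "spine_record")
}

#' @export
print.spine_record <- function(x, ...) {
  cat(sprintf("<spine_record %s: %s voxels, %d vertebrae (%s)>\n",
              x$subject_id, paste(dim(x$intensity), collapse = "x"),
              nrow(x$centroids),
              paste(x$centroids$vertebra_label, collapse = " ")))
  invisible(x)
}

#' Generate a synthetic spine volume
#'
#' Stacks `spec$n_vertebrae` vertebrae along the axial axis with at least
#' `spec$gap` voxels between consecutive masks, assigns each a distinct
#' integer label and a consecutive anatomical position code starting at
#' `spec$start_code`, and renders intensity as
#' `background + (bone - background) * mask` plus clipped Gaussian noise.
#'
#' @param spec A [phantom_spec()].
#' @param subject_id Subject identifier recorded on the output.
#' @return A [spine_record()].
#' @export
make_spine_phantom <- function(spec, subject_id = "phantom01") {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$volume_shape
  n <- spec$n_vertebrae
  codes <- consecutive_codes(spec$start_code, n)
  with_seed(spec$seed, {
    rx <- stats::runif(n, spec$body_radius_range[1], spec$body_radius_range[2])
    ry <- stats::runif(n, spec$body_radius_range[1], spec$body_radius_range[2])
    h  <- stats::runif(n, spec$body_height_range[1], spec$body_height_range[2])
    pl <- round(stats::runif(n, spec$process_length_range[1],
                             spec$process_length_range[2]))
    # axial placement, inferior to superior
    margin <- 2L
    total <- sum(ceiling(h)) + spec$gap * (n - 1L) + 2L * margin
    if (total > shape[3])
      stopf("%d vertebrae of total height %d exceed the axial extent %d",
            n, total, shape[3])
    cz <- numeric(n)
    z0 <- margin
    for (i in seq_len(n)) {
      cz[i] <- z0 + ceiling(h[i]) / 2 + 1
      z0 <- z0 + ceiling(h[i]) + spec$gap
    }
    cx <- rep(floor(shape[1] / 2), n)
    cy <- rep(floor(shape[2] * 0.45), n)
    labels <- array(0L, dim = shape)
    cents <- vector("list", n)
    for (i in seq_len(n)) {
      m <- build_vertebra_mask(shape, c(cx[i], cy[i], round(cz[i])),
                               rx[i], ry[i], h[i], pl[i])
      if (any(labels[m] != 0L))
        stopf("vertebrae %d and %d overlap; increase the gap or the volume",
              i - 1L, i)
      labels[m] <- i
      cents[[i]] <- data.frame(vertebra_label = codes[i], label = i,
                               x = cx[i], y = cy[i], z = round(cz[i]),
                               stringsAsFactors = FALSE)
    }
    centroids <- do.call(rbind, cents)
    intensity <- spec$intensity_background +
      (spec$intensity_bone - spec$intensity_background) * (labels > 0L)
    if (spec$noise_sd > 0) {
      intensity <- intensity + stats::rnorm(length(intensity), 0, spec$noise_sd)
      intensity <- pmax(intensity, 0)
    }
    intensity <- array(intensity, dim = shape)
    spine_record(intensity, labels, centroids, spec$spacing, subject_id)
  })
}

#' Write a spine record to disk in VerSe dialect
#'
#' Writes `<subject>_ct.nii.gz` (intensity), `<subject>_seg.nii.gz` (labels)
#' and `<subject>_ctd.json`, a centroid annotation list whose entries carry
#' an integer vertebral label code and 0-based voxel `X`/`Y`/`Z`
#' coordinates, plus a plain-text `<subject>_meta.txt` sidecar holding the
#' metal-occlusion flag.
#'
#' @param record A [spine_record()].
#' @param dir Output directory (created if missing).
#' @param has_metal Metal-occlusion flag written to the sidecar.
#' @return Invisibly, the four file paths (ct, seg, ctd, meta).
#' @export
write_spine_record <- function(record, dir, has_metal = FALSE) {
  stopifnot(inherits(record, "spine_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, record$subject_id)
  paths <- c(ct = paste0(base, "_ct.nii.gz"),
             seg = paste0(base, "_seg.nii.gz"),
             ctd = paste0(base, "_ctd.json"),
             meta = paste0(base, "_meta.txt"))
  RNifti::writeNifti(RNifti::asNifti(record$intensity,
                                     pixdim = record$spacing), paths["ct"])
  RNifti::writeNifti(RNifti::asNifti(record$labels + 0,
                                     pixdim = record$spacing), paths["seg"])
  ctd <- lapply(seq_len(nrow(record$centroids)), function(i) {
    v <- record$centroids[i, ]
    list(label = code_to_int(v$vertebra_label),
         X = v$x - 1, Y = v$y - 1, Z = v$z - 1)
  })
  jsonlite::write_json(ctd, paths["ctd"], auto_unbox = TRUE, digits = NA)
  writeLines(c(sprintf("subject_id: %s", record$subject_id),
               sprintf("has_metal: %d", as.integer(has_metal))),
             paths["meta"])
  invisible(paths)
}
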