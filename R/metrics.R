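# Evaluation metrics: Dice coefficient, 95th-percentile Hausdorff distance
# and normalised surface distance, all on voxel surfaces.  A surface voxel
# is a foreground voxel with at least one background 6-neighbour, the
# volume border counting as background.

# Logical surface map of a binary 3D mask.
surface_logical <- function(mask) {
  m <- if (is.logical(mask)) mask else mask >= 0.5
  dm <- dim(m)
  if (!any(m)) return(array(FALSE, dim = dm))
  shift <- function(ax, by) {
    out <- array(FALSE, dim = dm)
    n <- dm[ax]
    if (n == 1L) return(out)
    if (by == 1) {
      idx_dst <- 2:n; idx_src <- 1:(n - 1)
    } else {
      idx_dst <- 1:(n - 1); idx_src <- 2:n
    }
    if (ax == 1) out[idx_dst, , ] <- m[idx_src, , ]
    else if (ax == 2) out[, idx_dst, ] <- m[, idx_src, ]
    else out[, , idx_dst] <- m[, , idx_src]
    out
  }
  all_nb <- shift(1, 1) & shift(1, -1) & shift(2, 1) & shift(2, -1) &
    shift(3, 1) & shift(3, -1)
  m & !all_nb
}

#' Surface voxels of a binary mask
#'
#' @param mask Binary 3D array.
#' @return Integer matrix (n x 3) of 1-based voxel coordinates of the
#'   foreground voxels having at least one background 6-neighbour (the
#'   volume border counts as background); zero rows for an empty mask.
#' @export
surface_voxels <- function(mask) {
  which(surface_logical(mask), arr.ind = TRUE)
}

#' Dice coefficient of two binary masks
#'
#' `2 |a n b| / (|a| + |b|)`; defined as 1 when both masks are empty.
#'
#' @param a,b Binary 3D arrays of the same shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coeff <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- a >= 0.5; b <- b >= 0.5
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# Pooled symmetric surface distances (mm): each surface voxel of a to the
# nearest surface voxel of b and vice versa.  NULL if either mask is empty.
surface_distances <- function(a, b, spacing = c(1, 1, 1)) {
  sa <- surface_logical(a)
  sb <- surface_logical(b)
  if (!any(sa) || !any(sb)) return(NULL)
  spacing <- as.numeric(spacing)
  da <- cpp_edt3d(sb, spacing)[sa]  # a-surface -> nearest b-surface
  db <- cpp_edt3d(sa, spacing)[sb]
  c(da, db)
}

#' 95th-percentile Hausdorff distance
#'
#' The 95th percentile (linear interpolation) of the pooled symmetric
#' directed surface distances between the two masks, in mm.
#'
#' @param a,b Binary 3D arrays of the same shape.
#' @param spacing Voxel spacing triple in mm.
#' @return Scalar distance in mm, or `NA` (flagged) if either mask is empty.
#' @export
hd95 <- function(a, b, spacing = c(1, 1, 1)) {
  stopifnot(identical(dim(a), dim(b)))
  d <- surface_distances(a, b, spacing)
  if (is.null(d)) return(NA_real_)
  unname(quantile(d, 0.95, type = 7))
}

#' Normalised surface distance
#'
#' Fraction of surface voxels (pooled over both directions) whose distance
#' to the other mask's surface is within `tolerance_mm`.
#'
#' @param a,b Binary 3D arrays of the same shape.
#' @param tolerance_mm Agreement tolerance in mm (> 0), default 1.
#' @param spacing Voxel spacing triple in mm.
#' @return Scalar in `[0, 1]`, or `NA` (flagged) if either mask is empty.
#' @export
nsd <- function(a, b, tolerance_mm = 1, spacing = c(1, 1, 1)) {
  stopifnot(identical(dim(a), dim(b)))
  if (tolerance_mm <= 0) stopf("tolerance_mm must be positive")
  d <- surface_distances(a, b, spacing)
  if (is.null(d)) return(NA_real_)
  mean(d <= tolerance_mm)
}
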