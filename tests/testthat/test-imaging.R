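test_that("projection reproduces impulses, axis sums, linearity and mass conservation", {
  # impulse: single voxel lands at the right pixel in both views
  vol <- array(0, dim = c(8, 8, 8))
  vol[3, 5, 7] <- 7
  expect_equal(project(vol, "coronal")$pixels[3, 7], 7)
  expect_equal(sum(project(vol, "coronal")$pixels), 7)
  expect_equal(project(vol, "sagittal")$pixels[5, 7], 7)
  # all-zero volume
  expect_true(all(project(array(0, c(4, 4, 4)), "sagittal")$pixels == 0))
  # random volume equals independent axis sums; mass conserved; linear
  set.seed(1)
  v1 <- array(runif(8^3), dim = c(8, 8, 8))
  v2 <- array(runif(8^3), dim = c(8, 8, 8))
  for (view in c("coronal", "sagittal")) {
    ax <- if (view == "coronal") 2 else 1
    keep <- setdiff(1:3, ax)
    expect_equal(project(v1, view)$pixels, apply(v1, keep, sum),
                 tolerance = 1e-12)
    expect_equal(sum(project(v1, view)$pixels), sum(v1), tolerance = 1e-9)
    lin <- project(2 * v1 + 3 * v2, view)$pixels
    expect_equal(lin, 2 * project(v1, view)$pixels + 3 * project(v2, view)$pixels,
                 tolerance = 1e-9)
  }
  expect_error(project(array(-1, c(2, 2, 2)), "coronal"), "negative")
  expect_error(project(array(NaN, c(2, 2, 2)), "coronal"), "NaN")
})

test_that("min-max normalisation maps to [0,1] with the constant-image convention", {
  expect_true(all(normalize_image(matrix(5, 3, 3)) == 0))
  expect_equal(sort(unique(as.numeric(normalize_image(matrix(c(2, 6, 10), 1))))),
               c(0, 0.5, 1))
  set.seed(2)
  img <- matrix(rnorm(64), 8)
  nrm <- normalize_image(img)
  expect_equal(range(nrm), c(0, 1))
})

test_that("crop_patch matches naive indexing, zero-fills corners and defaults to 120", {
  set.seed(3)
  img <- matrix(runif(400), 20)
  # interior window equals the directly indexed sub-array (even-size parity:
  # centre at 0-based index size/2)
  p <- crop_patch(img, c(10, 12), size = 4)
  expect_identical(p, img[8:11, 10:13])
  # corner crop: exactly the out-of-bounds region is zero
  p2 <- crop_patch(img, c(1, 1), size = 4)
  expect_true(all(p2[1:2, ] == 0))
  expect_true(all(p2[, 1:2] == 0))
  expect_identical(p2[3:4, 3:4], img[1:2, 1:2])
  expect_identical(formals(crop_patch)$size, 120L)
  expect_error(crop_patch(img, c(0, 5)), "outside")
})

test_that("centroid disk mask enumerates the right pixels and is symmetric", {
  expect_equal(sum(centroid_mask(9, c(5, 5), radius = 0)), 1)
  m <- centroid_mask(11, c(6, 6), radius = 2)
  # enumeration oracle: integer offsets with dx^2 + dy^2 <= 4
  expect_equal(sum(m), sum(outer((-5:5)^2, (-5:5)^2, `+`) <= 4))
  expect_equal(sum(m), 13)
  expect_identical(m, m[11:1, ])
  expect_identical(m, m[, 11:1])
  expect_error(centroid_mask(9, c(0, 5)), "outside")
})

test_that("build_pairs yields one valid pair per vertebra", {
  rec <- desk_record(7, n_vertebrae = 3)
  pairs <- build_pairs(rec, size = 32, radius = 3)
  expect_length(pairs, 3)
  for (p in pairs) {
    expect_s3_class(p, "patch_pair")
    expect_gte(sum(p$target), 1)
    expect_true(min(p$coronal_patch) >= 0 && max(p$coronal_patch) <= 1)
    expect_gte(sum(p$coronal_centroid_mask), 1)
  }
})

test_that("target windows re-embed onto the vertebra's own voxels (round-trip oracle)", {
  rec <- desk_record(9)
  pairs <- build_pairs(rec, size = 32, radius = 3)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    idx <- lapply(1:3, function(a) p$crop_offset[a] + 0:31)
    ok <- lapply(1:3, function(a)
      which(idx[[a]] >= 1 & idx[[a]] <= dim(rec$labels)[a]))
    src <- lapply(1:3, function(a) idx[[a]][ok[[a]]])
    sub <- rec$labels[src[[1]], src[[2]], src[[3]]] == i
    win <- p$target[ok[[1]], ok[[2]], ok[[3]]]
    expect_equal(win, sub * 1, ignore_attr = TRUE)
  }
})

test_that("each target contains only the annotated vertebra, never a union", {
  rec <- desk_record(5)
  pairs <- build_pairs(rec, size = 32, radius = 3)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    off <- p$crop_offset
    idx <- lapply(1:3, function(a) pmax(pmin(off[a] + 0:31,
                                             dim(rec$labels)[a]), 1))
    # voxels of any *other* vertebra inside the window are all background in
    # the target
    other <- rec$labels[idx[[1]], idx[[2]], idx[[3]]]
    other_mask <- other != i & other != 0
    if (any(other_mask)) expect_true(all(p$target[other_mask] == 0))
    # and the target equals the annotated vertebra's own cropped mask
    expect_equal(sum(p$target), sum(rec$labels[idx[[1]], idx[[2]],
                                               idx[[3]]] == i))
  }
})

test_that("crop-pad-uncrop round-trips on interior windows", {
  set.seed(4)
  img <- matrix(runif(40 * 40), 40)
  ctr <- c(20, 21)
  p <- crop_patch(img, ctr, size = 8)
  back <- matrix(0, 40, 40)
  rows <- ctr[1] - 4 + 1:8 - 1
  cols <- ctr[2] - 4 + 1:8 - 1
  back[rows, cols] <- p
  expect_identical(back[rows, cols], img[rows, cols])
})

test_that("patch pairs persist to image files with a manifest", {
  pairs <- build_pairs(desk_record(3, n_vertebrae = 3), size = 32, radius = 3)
  dir <- withr::local_tempdir()
  manifest <- write_patch_pairs(pairs, dir)
  mf <- read.csv(manifest, stringsAsFactors = FALSE)
  expect_identical(nrow(mf), length(pairs))
  expect_true(all(c("subject_id", "vertebra_label", "offset_x") %in% names(mf)))
  for (p in pairs) {
    stem <- file.path(dir, sprintf("%s_%s", p$subject_id, p$vertebra_label))
    expect_true(file.exists(paste0(stem, "_coronal.tif")))
    expect_true(file.exists(paste0(stem, "_target.nii.gz")))
    back <- tiff::readTIFF(paste0(stem, "_coronal.tif"))
    expect_equal(dim(back), dim(p$coronal_patch))
  }
})
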