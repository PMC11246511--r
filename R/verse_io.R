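# Case ingestion in the VerSe dialect (NIfTI volumes + JSON centroid
# annotations), isotropic resampling, spine-level exclusion filtering and
# patient-wise splitting.

# Integer label codes follow the VerSe convention: C1-C7 = 1-7,
# T1-T12 = 8-19, L1-L5 = 20-24, L6 = 25, S1 = 26, S2 = 27, T13 = 28.
.code_table <- local({
  codes <- c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5),
             "L6", "S1", "S2", "T13")
  setNames(c(1:7, 8:19, 20:24, 25L, 26L, 27L, 28L), codes)
})

# Anatomically ordered alphabet used for consecutive position codes
# (anatomical variants T13/L6 and sacral codes are addressable but not part
# of the consecutive ordering).
.code_order <- c(paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5),
                 "S1", "S2")

#' Map anatomical vertebra codes to integer label codes and back
#'
#' @param code Character vector of codes such as "T12" or "L1".
#' @param label Integer vector of VerSe-style label codes.
#' @return `code_to_int` returns integers; `int_to_code` returns codes.
#'   Unknown values raise an error.
#' @export
code_to_int <- function(code) {
  out <- .code_table[code]
  if (anyNA(out))
    stopf("unknown vertebra code(s): %s",
          paste(code[is.na(out)], collapse = ", "))
  unname(out)
}

#' @rdname code_to_int
#' @export
int_to_code <- function(label) {
  idx <- match(as.integer(label), .code_table)
  if (anyNA(idx))
    stopf("unknown label code(s): %s",
          paste(label[is.na(idx)], collapse = ", "))
  names(.code_table)[idx]
}

# n consecutive position codes starting at `start` in anatomical order.
consecutive_codes <- function(start, n) {
  i <- match(start, .code_order)
  if (is.na(i)) stopf("unknown start code '%s'", start)
  if (i + n - 1L > length(.code_order))
    stopf("%d consecutive codes from %s run past the end of the spine",
          n, start)
  .code_order[i:(i + n - 1L)]
}

is_thoracic <- function(code) grepl("^T", code)
is_cervical <- function(code) grepl("^C", code)

#' Read a VerSe-style case into a spine record
#'
#' Loads the intensity and label volumes (NIfTI) and the centroid annotation
#' file (JSON entries with an integer `label` code and 0-based voxel
#' `X`/`Y`/`Z` coordinates), cross-checking that the two volumes share a
#' grid, that all label codes are known and that every centroid lies inside
#' the volume.
#'
#' @param ct_path,seg_path,centroid_path File paths.
#' @param subject_id Subject identifier; defaults to the CT file name
#'   stripped of its `_ct.nii.gz` suffix.
#' @return A [spine_record()].
#' @export
read_case <- function(ct_path, seg_path, centroid_path, subject_id = NULL) {
  for (p in c(ct_path, seg_path, centroid_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  ct <- RNifti::readNifti(ct_path)
  seg <- RNifti::readNifti(seg_path)
  if (!identical(dim(ct), dim(seg)))
    stopf("grid mismatch: CT is %s but segmentation is %s",
          paste(dim(ct), collapse = "x"), paste(dim(seg), collapse = "x"))
  spacing <- RNifti::pixdim(ct)[1:3]
  ctd <- jsonlite::read_json(centroid_path)
  ctd <- Filter(function(e) !is.null(e$label), ctd)
  if (!length(ctd)) stopf("no centroid entries in %s", centroid_path)
  cents <- do.call(rbind, lapply(ctd, function(e) {
    code <- int_to_code(e$label)
    data.frame(vertebra_label = code, label = NA_integer_,
               x = round(e$X) + 1L, y = round(e$Y) + 1L, z = round(e$Z) + 1L,
               stringsAsFactors = FALSE)
  }))
  dm <- dim(ct)
  bad <- cents$x < 1 | cents$x > dm[1] | cents$y < 1 | cents$y > dm[2] |
    cents$z < 1 | cents$z > dm[3]
  if (any(bad))
    stopf("centroid(s) outside the volume: %s",
          paste(cents$vertebra_label[bad], collapse = ", "))
  labels <- array(as.integer(round(as.array(seg))), dim = dm)
  cents$label <- labels[cbind(cents$x, cents$y, cents$z)]
  if (is.null(subject_id))
    subject_id <- sub("_ct\\.nii(\\.gz)?$", "", basename(ct_path))
  spine_record(array(as.numeric(as.array(ct)), dim = dm), labels, cents,
               spacing, subject_id)
}

#' Resample a spine record to isotropic spacing
#'
#' Intensity is resampled with trilinear interpolation, labels with nearest
#' neighbour, and centroids are mapped through the same affine.
#'
#' @param record A [spine_record()].
#' @param spacing_mm Target isotropic spacing (> 0), default 1 mm.
#' @return The resampled [spine_record()].
#' @export
resample_iso <- function(record, spacing_mm = 1.0) {
  stopifnot(inherits(record, "spine_record"))
  if (spacing_mm <= 0) stopf("spacing_mm must be positive")
  ratio <- spacing_mm / record$spacing
  dm <- dim(record$intensity)
  dims_out <- pmax(1L, as.integer(floor((dm - 1) / ratio) + 1))
  if (identical(dims_out, dm) && all(ratio == 1)) return(record)
  intensity <- cpp_resample3d(record$intensity, dims_out, ratio, TRUE)
  labels <- cpp_resample3d(record$labels + 0, dims_out, ratio, FALSE)
  labels <- array(as.integer(round(labels)), dim = dims_out)
  cents <- record$centroids
  for (i in seq_len(nrow(cents))) {
    cents$x[i] <- min(max(1L, as.integer(round((cents$x[i] - 1) / ratio[1] + 1))), dims_out[1])
    cents$y[i] <- min(max(1L, as.integer(round((cents$y[i] - 1) / ratio[2] + 1))), dims_out[2])
    cents$z[i] <- min(max(1L, as.integer(round((cents$z[i] - 1) / ratio[3] + 1))), dims_out[3])
  }
  spine_record(intensity, labels, cents, rep(spacing_mm, 3), record$subject_id)
}

#' Case-level metadata
#'
#' @param subject_id Subject identifier.
#' @param vertebra_codes Character vector of annotated anatomical codes.
#' @param has_metal Logical metal-occlusion flag (from the case sidecar).
#' @return An object of class `case_meta`.
#' @export
case_meta <- function(subject_id, vertebra_codes, has_metal = FALSE) {
  code_to_int(vertebra_codes)  # validates
  structure(list(subject_id = subject_id,
                 vertebra_codes = unique(vertebra_codes),
                 has_metal = isTRUE(has_metal)),
            class = "case_meta")
}

#' Spine-level exclusion filtering
#'
#' Screens whole-spine cases with three rules, applied in order with the
#' first match recorded: (a) exclude if the case contains T13, L6 or any
#' cervical vertebra; (b) exclude if it has no more than 2 annotated
#' thoracic vertebrae; (c) exclude if it carries the metal-occlusion flag.
#'
#' @param cases List of [case_meta()] objects.
#' @return A `filter_report`: list with `kept` (subject ids), `excluded`
#'   (data frame of subject id and rule id), `n_spines_kept` and
#'   `n_vertebrae_kept` (total annotated vertebrae over kept cases).
#' @export
apply_small_filters <- function(cases) {
  stopifnot(all(vapply(cases, inherits, TRUE, "case_meta")))
  rule_of <- function(cm) {
    codes <- cm$vertebra_codes
    if (any(codes %in% c("T13", "L6")) || any(is_cervical(codes)))
      return("cervical_or_T13_L6")
    if (sum(is_thoracic(codes)) <= 2)
      return("too_few_thoracic")
    if (cm$has_metal)
      return("metal")
    NA_character_
  }
  rules <- vapply(cases, rule_of, "")
  ids <- vapply(cases, `[[`, "", "subject_id")
  keep <- is.na(rules)
  excluded <- data.frame(subject_id = ids[!keep], rule = rules[!keep],
                         stringsAsFactors = FALSE)
  structure(list(
    kept = ids[keep],
    excluded = excluded,
    n_spines_kept = sum(keep),
    n_vertebrae_kept = sum(vapply(cases[keep], function(cm)
      length(cm$vertebra_codes), 1L))
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report: kept %d spines / %d vertebrae; excluded %d>\n",
              x$n_spines_kept, x$n_vertebrae_kept, nrow(x$excluded)))
  invisible(x)
}

#' Write a filter report as CSV
#'
#' @param report A `filter_report` from [apply_small_filters()].
#' @param path Output CSV path.
#' @export
write_filter_report <- function(report, path) {
  kept <- data.frame(subject_id = report$kept, rule = "kept",
                     stringsAsFactors = FALSE)
  write.csv(rbind(kept, report$excluded), path, row.names = FALSE)
  invisible(path)
}

#' Patient-wise train/test split
#'
#' Shuffles patients reproducibly and assigns round(n * 4/5) of them to the
#' training side; all records of one patient land on the same side.
#'
#' @param records List of [spine_record()]s, list of [case_meta()]s, or a
#'   character vector of patient ids (possibly repeated across records).
#' @param ratio Training fraction, default 4/5 (a 4:1 split).
#' @param seed Integer seed for the shuffle.
#' @return List with `train` and `test` character vectors of patient ids.
#' @export
split_by_patient <- function(records, ratio = 4 / 5, seed = 1L) {
  ids <- if (is.character(records)) records
         else vapply(records, `[[`, "", "subject_id")
  patients <- unique(ids)
  if (length(patients) < 2L) stopf("need at least 2 patients to split")
  with_seed(seed, {
    shuffled <- sample(patients)
    n_train <- round(length(patients) * ratio)
    n_train <- min(max(n_train, 1L), length(patients) - 1L)
    list(train = sort(shuffled[seq_len(n_train)]),
         test = sort(shuffled[-seq_len(n_train)]))
  })
}
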