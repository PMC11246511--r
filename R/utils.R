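# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

# Crop indices along one axis for a window of `size` centred on `center`
# (1-based).  For even sizes the centre occupies the (size/2)-th 0-based
# position of the window, i.e. offsets run from -size/2 to size/2 - 1.
crop_index <- function(center, size) {
  as.integer(center - floor(size / 2) + seq_len(size) - 1L)
}

# Extract a zero-padded window from a matrix or 3D array given per-axis
# 1-based index vectors (out-of-bounds entries filled with `fill`).
extract_window <- function(x, idx_list, fill = 0) {
  nd <- length(idx_list)
  dims <- vapply(idx_list, length, 1L)
  out <- array(fill, dim = dims)
  src <- vector("list", nd)
  dst <- vector("list", nd)
  for (a in seq_len(nd)) {
    ok <- which(idx_list[[a]] >= 1L & idx_list[[a]] <= dim(x)[a])
    if (!length(ok)) return(out)
    dst[[a]] <- ok
    src[[a]] <- idx_list[[a]][ok]
  }
  if (nd == 2L) {
    out[dst[[1L]], dst[[2L]]] <- x[src[[1L]], src[[2L]]]
  } else {
    out[dst[[1L]], dst[[2L]], dst[[3L]]] <- x[src[[1L]], src[[2L]], src[[3L]]]
  }
  out
}
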