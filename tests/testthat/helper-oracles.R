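# Shared fixtures and independent brute-force oracles used across the test
# files.  Oracles are deliberately naive (enumeration / all-pairs / dense
# matrices) and never share code with the implementation they check.

ns <- asNamespace("vertebra3d")

desk_record <- function(seed = 7, ...) {
  make_spine_phantom(phantom_spec(seed = seed, ...),
                     subject_id = sprintf("ph%02d", seed))
}

desk_pairs <- function(seeds, size = 32, radius = 3) {
  out <- list()
  for (s in seeds)
    out <- c(out, build_pairs(desk_record(s), size = size, radius = radius))
  out
}

# Connected components of a 3D binary mask by breadth-first flood fill over
# 6-neighbourhoods.
flood_fill_components <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(0L)
  dm <- dim(mask)
  lab <- array(0L, dim = dm)
  ncomp <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  coords <- which(mask, arr.ind = TRUE)
  key <- function(v) (v[, 1] - 1) + dm[1] * ((v[, 2] - 1) + dm[2] * (v[, 3] - 1))
  for (r in seq_len(nrow(coords))) {
    v <- coords[r, , drop = FALSE]
    if (lab[v] != 0L) next
    ncomp <- ncomp + 1L
    queue <- v
    lab[v] <- ncomp
    while (nrow(queue)) {
      cur <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (o in seq_len(6)) {
        nb <- cur + offs[o, , drop = FALSE]
        if (any(nb < 1) || any(nb > dm)) next
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- ncomp
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  ncomp
}

# All-pairs Euclidean distance from each row of `a` to the nearest row of
# `b`, in mm.
nearest_dists <- function(a, b, spacing = c(1, 1, 1)) {
  vapply(seq_len(nrow(a)), function(i) {
    d2 <- (sweep(b, 2, a[i, ]) %*% diag(spacing, 3))^2
    sqrt(min(rowSums(d2)))
  }, 0)
}

# Brute-force surface voxels: explicit 6-neighbour check per foreground voxel.
brute_surface <- function(mask) {
  dm <- dim(mask)
  fg <- which(mask >= 0.5, arr.ind = TRUE)
  if (!nrow(fg)) return(fg)
  keep <- vapply(seq_len(nrow(fg)), function(i) {
    v <- fg[i, ]
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      nb <- v + o
      if (any(nb < 1) || any(nb > dm) || mask[nb[1], nb[2], nb[3]] < 0.5)
        return(TRUE)
    }
    FALSE
  }, TRUE)
  fg[keep, , drop = FALSE]
}

# Brute-force pooled symmetric surface distances (the HD95/NSD oracle).
brute_surface_dists <- function(a, b, spacing = c(1, 1, 1)) {
  sa <- brute_surface(a)
  sb <- brute_surface(b)
  if (!nrow(sa) || !nrow(sb)) return(NULL)
  c(nearest_dists(sa, sb, spacing), nearest_dists(sb, sa, spacing))
}

# Brute-force distance transform to the boundary of `mask` (all-pairs).
brute_boundary_dt <- function(mask, spacing = c(1, 1, 1)) {
  surf <- brute_surface(mask)
  dm <- dim(mask)
  out <- array(0, dim = dm)
  if (!nrow(surf)) return(out)
  all_vox <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]),
                                   z = seq_len(dm[3])))
  out[all_vox] <- nearest_dists(all_vox, surf, spacing)
  out
}

# Dense attention oracle for the non-local block: explicit per-position
# loops materialising the full N x N attention matrix.
brute_nonlocal <- function(x, Wt, Wp, Ws, Wo) {
  dm <- dim(x)
  N <- dm[1] * dm[2]
  Xm <- matrix(x, nrow = N)
  theta <- Xm %*% Wt
  phi <- Xm %*% Wp
  sig <- Xm %*% Ws
  Y <- Xm
  for (i in seq_len(N)) {
    s <- vapply(seq_len(N), function(j) sum(theta[i, ] * phi[j, ]), 0)
    w <- exp(s - max(s))
    w <- w / sum(w)
    ctx <- colSums(w * sig)
    Y[i, ] <- Y[i, ] + as.numeric(ctx %*% Wo)
  }
  array(Y, dim = dm)
}

# Random small binary mask with at least one foreground voxel.
random_mask <- function(dm, p = 0.3) {
  m <- array(stats::runif(prod(dm)) < p, dim = dm)
  if (!any(m)) m[sample(length(m), 1)] <- TRUE
  m
}
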