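test_that("non-local block equals the dense-attention oracle on random inputs", {
  set.seed(31)
  for (i in 1:5) {
    x <- array(rnorm(4 * 4 * 3), dim = c(4, 4, 3))
    params <- nonlocal_params(3, 2, seed = i)
    got <- nonlocal_block(x, params)
    want <- brute_nonlocal(x, params$theta, params$phi, params$sigma,
                           params$proj)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("non-local block residual identity and single-position softmax hold", {
  set.seed(32)
  x <- array(rnorm(4 * 4 * 3), dim = c(4, 4, 3))
  params <- nonlocal_params(3, 2, seed = 1)
  params$proj[] <- 0
  expect_identical(nonlocal_block(x, params), x)
  # H = W = 1: softmax over one position is 1, so y = x + proj(sigma(x))
  params <- nonlocal_params(3, 2, seed = 2)
  x1 <- array(rnorm(3), dim = c(1, 1, 3))
  want <- x1 + array(as.numeric(matrix(x1, 1) %*% params$sigma %*% params$proj),
                     dim = c(1, 1, 3))
  expect_equal(nonlocal_block(x1, params), want, tolerance = 1e-12)
})

test_that("centroid fusion preserves spatial size and reacts to its inputs", {
  cfg <- desk_generator_config()
  G <- init_generator(cfg, seed = 3)
  S <- cfg$patch_size
  z <- matrix(0, S, S)
  out0 <- centroid_fusion(z, z, G, "coronal")
  expect_identical(dim(out0), c(S, S, cfg$fusion_channels))
  expect_true(all(is.finite(out0)))
  expect_identical(centroid_fusion(z, z, G, "coronal"), out0)
  # swapping the two input channels changes the output (channel weights
  # differ), a non-degeneracy check
  set.seed(33)
  a <- matrix(runif(S * S), S)
  b <- matrix(runif(S * S), S)
  expect_false(isTRUE(all.equal(centroid_fusion(a, b, G, "coronal"),
                                centroid_fusion(b, a, G, "coronal"))))
  # view-specific weights differ
  expect_false(isTRUE(all.equal(centroid_fusion(a, b, G, "coronal"),
                                centroid_fusion(a, b, G, "sagittal"))))
})

test_that("2D-to-3D lifting duplicates each view along its projection axis", {
  set.seed(34)
  S <- 6L
  cor <- array(rnorm(S * S * 2), dim = c(S, S, 2))
  sag <- array(rnorm(S * S * 3), dim = c(S, S, 3))
  v <- lift_to_3d(cor, sag)
  expect_identical(dim(v), c(S, S, S, 5L))
  for (y in seq_len(S))
    expect_equal(v[, y, , 1:2], cor, ignore_attr = TRUE)
  for (x in seq_len(S))
    expect_equal(v[x, , , 3:5], sag, ignore_attr = TRUE)
})

test_that("generator emits a deterministic S^3 occupancy volume in (0, 1)", {
  cfg <- desk_generator_config()
  G <- init_generator(cfg, seed = 5)
  pairs <- desk_pairs(3)
  t0 <- proc.time()
  out <- generator_forward(pairs[[1]], G)
  elapsed <- (proc.time() - t0)[3]
  expect_identical(dim(out), rep(cfg$patch_size, 3L))
  expect_true(all(out > 0 & out < 1))
  expect_identical(generator_forward(pairs[[1]], G), out)
  expect_lt(elapsed, 5)
})

test_that("discriminator shrinks the input, is deterministic and translation-covariant", {
  dcfg <- discriminator_config(patch_size = 32, base_channels = 4, n_layers = 2)
  D <- init_discriminator(dcfg, seed = 6)
  set.seed(35)
  vol <- array(runif(32^3), dim = c(32, 32, 32))
  sc <- discriminator_forward(vol, D)
  expect_true(all(dim(sc) < dim(vol)))
  expect_identical(discriminator_forward(vol, D), sc)
  # shifting the input by one stride unit (2 layers of stride 2 -> 4 voxels)
  # shifts the score map by one cell; compared on the interior, leaving a
  # 3-cell margin so no compared receptive field touches the border
  shift <- array(0, dim = dim(vol))
  shift[5:32, , ] <- vol[1:28, , ]
  sc2 <- discriminator_forward(shift, D)
  n <- dim(sc)[1]
  expect_equal(sc2[4:(n - 2), 4:(n - 3), 4:(n - 3)],
               sc[3:(n - 3), 4:(n - 3), 4:(n - 3)], tolerance = 1e-8)
})

test_that("checkpoints round-trip bit-exactly", {
  G <- init_generator(desk_generator_config(), seed = 7)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(G, path)
  G2 <- load_checkpoint(path)
  expect_identical(G2, G)
  pairs <- desk_pairs(4)
  expect_identical(generator_forward(pairs[[1]], G2),
                   generator_forward(pairs[[1]], G))
})

test_that("generator backward matches finite differences on a tiny config", {
  set.seed(36)
  S <- 8
  cfg <- generator_config(patch_size = S, base_channels = 2,
                          fusion_channels = 2, depth = 2)
  G <- init_generator(cfg, seed = 8)
  cm <- centroid_mask(S, c(4, 4), 2)
  pair <- patch_pair(matrix(runif(S * S), S), matrix(runif(S * S), S),
                     cm, cm,
                     target = array(as.numeric(runif(S^3) > 0.7),
                                    dim = c(S, S, S)))
  loss_of <- function(params) {
    penv <- list2env(params)
    out <- ns$gen_fwd(penv, cfg, pair, training = TRUE)$out
    sum(out * seq_along(out) / length(out))
  }
  penv <- list2env(G$params)
  fwd <- ns$gen_fwd(penv, cfg, pair, training = TRUE)
  dout <- array(seq_along(fwd$out) / length(fwd$out), dim = dim(fwd$out))
  grads <- ns$gen_bwd(fwd$cache, dout)
  h <- 1e-7
  for (nm in sample(names(grads), 10)) {
    p <- G$params[[nm]]
    for (i in sample(length(p), min(2, length(p)))) {
      pp <- G$params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- G$params; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (loss_of(pp) - loss_of(pm)) / (2 * h)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-3 + 1e-3 * abs(num))
    }
  }
})

test_that("discriminator backward (weights and input) matches finite differences", {
  set.seed(37)
  S <- 8
  dcfg <- discriminator_config(patch_size = S, base_channels = 2, n_layers = 2)
  D <- init_discriminator(dcfg, seed = 9)
  vol <- array(runif(S^3), dim = c(S, S, S))
  loss_of <- function(params, v) {
    penv <- list2env(params)
    sc <- ns$disc_fwd(penv, dcfg, v, training = TRUE)$out
    sum(sc * seq_along(sc))
  }
  penv <- list2env(D$params)
  fd <- ns$disc_fwd(penv, dcfg, vol, training = TRUE)
  dsc <- array(seq_along(fd$out), dim = dim(fd$out))
  db <- ns$disc_bwd(fd$cache, dsc)
  h <- 1e-7
  for (nm in sample(names(db$grads), 6)) {
    p <- D$params[[nm]]
    for (i in sample(length(p), min(2, length(p)))) {
      pp <- D$params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- D$params; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (loss_of(pp, vol) - loss_of(pm, vol)) / (2 * h)
      expect_equal(db$grads[[nm]][i], num, tolerance = 1e-3 + 1e-3 * abs(num))
    }
  }
  for (i in sample(length(vol), 4)) {
    vp <- vol; vp[i] <- vp[i] + h
    vm <- vol; vm[i] <- vm[i] - h
    num <- (loss_of(D$params, vp) - loss_of(D$params, vm)) / (2 * h)
    expect_equal(db$dx[i], num, tolerance = 1e-3 + 1e-3 * abs(num))
  }
})
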