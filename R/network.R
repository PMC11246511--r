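# The generator: per-view centroid fusion (conv stem + non-local
# self-attention), orthogonal 2D-to-3D lifting by duplication, and a 3D
# residual U-Net decoder with batch normalisation and skip connections,
# ending in a 1-channel sigmoid occupancy volume.  The discriminator is a
# patch-based fully convolutional 3D network (stride-2 convolution stack)
# emitting a spatial map of realness scores.

#' Generator configuration
#'
#' @param patch_size Patch/volume edge length S (120 at full scale, 32 for
#'   the desk preset); must be divisible by `2^(depth - 1)`.
#' @param base_channels Channels at the finest U-Net level.
#' @param fusion_channels Channels produced by each view's fusion stem.
#' @param depth Number of U-Net resolution levels (>= 2).
#' @param nonlocal_inner Inner (bottleneck) channels of the non-local
#'   block; defaults to half the fusion channels (at least 1).
#' @param use_nonlocal Include the non-local block in each fusion stem.
#' @param use_centroid_mask Feed the centroid-mask channel (FALSE zeroes it;
#'   the ablation axis).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(patch_size = 120L, base_channels = 16L,
                             fusion_channels = 8L, depth = 3L,
                             nonlocal_inner = NULL, use_nonlocal = TRUE,
                             use_centroid_mask = TRUE) {
  if (depth < 2L) stopf("depth must be >= 2")
  if (patch_size %% 2L^(depth - 1L) != 0L)
    stopf("patch_size %d is not divisible by 2^(depth-1) = %d",
          patch_size, 2L^(depth - 1L))
  if (is.null(nonlocal_inner))
    nonlocal_inner <- max(1L, fusion_channels %/% 2L)
  structure(list(patch_size = as.integer(patch_size),
                 base_channels = as.integer(base_channels),
                 fusion_channels = as.integer(fusion_channels),
                 depth = as.integer(depth),
                 nonlocal_inner = as.integer(nonlocal_inner),
                 use_nonlocal = isTRUE(use_nonlocal),
                 use_centroid_mask = isTRUE(use_centroid_mask)),
            class = "generator_config")
}

#' Desk-scale generator preset (32-voxel patches)
#'
#' @param ... Overrides passed to [generator_config()].
#' @export
desk_generator_config <- function(...) {
  args <- list(patch_size = 32L, base_channels = 8L, fusion_channels = 4L,
               depth = 3L)
  do.call(generator_config, utils::modifyList(args, list(...)))
}

#' Discriminator configuration
#'
#' @param patch_size Input volume edge length; must be divisible by
#'   `2^n_layers`.
#' @param base_channels Channels after the first convolution.
#' @param n_layers Number of stride-2 convolutions (4 at full scale, 3 at
#'   desk scale).
#' @return An object of class `discriminator_config`.
#' @export
discriminator_config <- function(patch_size = 120L, base_channels = 16L,
                                 n_layers = 4L) {
  # each stride-2 k4 p1 convolution halves the extent (rounding down);
  # the final score map must keep at least one cell per axis
  if (patch_size < 2L^n_layers)
    stopf("patch_size %d is too small for %d stride-2 layers",
          patch_size, n_layers)
  structure(list(patch_size = as.integer(patch_size),
                 base_channels = as.integer(base_channels),
                 n_layers = as.integer(n_layers)),
            class = "discriminator_config")
}

#' @rdname discriminator_config
#' @param ... Overrides passed to [discriminator_config()].
#' @export
desk_discriminator_config <- function(...) {
  args <- list(patch_size = 32L, base_channels = 8L, n_layers = 3L)
  do.call(discriminator_config, utils::modifyList(args, list(...)))
}

#' Non-local block parameters
#'
#' Weights of the three 1x1 embeddings (theta, phi, sigma) and of the
#' output projection restoring `channels_in` channels.
#'
#' @param channels_in Input feature channels.
#' @param channels_inner Bottleneck channels (default `channels_in / 2`,
#'   at least 1).
#' @param seed Seed for the normal(0, 0.02) initialisation.
#' @return An object of class `nonlocal_params`.
#' @export
nonlocal_params <- function(channels_in,
                            channels_inner = max(1L, channels_in %/% 2L),
                            seed = 1L) {
  if (channels_inner < 1L) stopf("channels_inner must be >= 1")
  with_seed(seed, {
    rn <- function(a, b) matrix(rnorm(a * b, 0, 0.02), a, b)
    structure(list(theta = rn(channels_in, channels_inner),
                   phi = rn(channels_in, channels_inner),
                   sigma = rn(channels_in, channels_inner),
                   proj = rn(channels_inner, channels_in)),
              class = "nonlocal_params")
  })
}

#' Non-local self-attention block
#'
#' For each spatial position, a softmax-weighted sum over all positions'
#' embedded features is added residually to the input:
#' `y = x + Proj(softmax(theta(x) phi(x)^T) sigma(x))`, the softmax running
#' over all `H * W` key positions for each query position.
#'
#' @param x Feature map array `(H, W, C)` (a `(C, H, W)` input is also
#'   accepted and permuted).
#' @param params A [nonlocal_params()].
#' @return Feature map of the same shape as `x`.
#' @export
nonlocal_block <- function(x, params) {
  stopifnot(inherits(params, "nonlocal_params"))
  C <- nrow(params$theta)
  dm <- dim(x)
  chan_first <- dm[1] == C && dm[3] != C
  if (chan_first) x <- aperm(x, c(2, 3, 1))
  if (dim(x)[3] != C) stopf("x has %d channels, params expect %d",
                            dim(x)[3], C)
  out <- nonlocal_fwd(x, params$theta, params$phi, params$sigma,
                      params$proj)$out
  if (chan_first) out <- aperm(out, c(3, 1, 2))
  out
}

# ---- weight initialisation --------------------------------------------------

rn_arr <- function(dims) array(rnorm(prod(dims), 0, 0.02), dim = dims)

add_conv <- function(p, name, dims) {
  p[[paste0(name, ".W")]] <- rn_arr(dims)
  p[[paste0(name, ".b")]] <- numeric(dims[length(dims)])
  p
}
add_bn <- function(p, name, C) {
  p[[paste0(name, ".gamma")]] <- rep(1, C)
  p[[paste0(name, ".beta")]] <- numeric(C)
  p[[paste0(name, ".rmean")]] <- numeric(C)
  p[[paste0(name, ".rvar")]] <- rep(1, C)
  p
}

gen_level_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L)

#' Initialise generator weights
#'
#' Convolution weights are drawn from normal(0, 0.02) under the given seed;
#' biases start at zero, batch-norm scales at one.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return An object of class `generator_weights` (config + named
#'   parameter arrays).
#' @export
init_generator <- function(config = generator_config(), seed = 1L) {
  cf <- config$fusion_channels
  ci <- config$nonlocal_inner
  ch <- gen_level_channels(config)
  with_seed(seed, {
    p <- list()
    for (v in c("cor", "sag")) {
      p <- add_conv(p, paste0(v, "_stem"), c(3, 3, 2, cf))
      p <- add_bn(p, paste0(v, "_stem_bn"), cf)
      p[[paste0(v, "_nl.theta")]] <- matrix(rnorm(cf * ci, 0, 0.02), cf, ci)
      p[[paste0(v, "_nl.phi")]] <- matrix(rnorm(cf * ci, 0, 0.02), cf, ci)
      p[[paste0(v, "_nl.sigma")]] <- matrix(rnorm(cf * ci, 0, 0.02), cf, ci)
      p[[paste0(v, "_nl.proj")]] <- matrix(rnorm(ci * cf, 0, 0.02), ci, cf)
    }
    p <- add_conv(p, "enc0", c(3, 3, 3, 2 * cf, ch[1]))
    p <- add_bn(p, "enc0_bn", ch[1])
    for (l in seq_len(config$depth)) {
      p <- add_conv(p, sprintf("res%d_conv1", l), c(3, 3, 3, ch[l], ch[l]))
      p <- add_bn(p, sprintf("res%d_bn1", l), ch[l])
      p <- add_conv(p, sprintf("res%d_conv2", l), c(3, 3, 3, ch[l], ch[l]))
      p <- add_bn(p, sprintf("res%d_bn2", l), ch[l])
      if (l < config$depth) {
        p <- add_conv(p, sprintf("down%d", l), c(3, 3, 3, ch[l], ch[l + 1]))
        p <- add_bn(p, sprintf("down%d_bn", l), ch[l + 1])
        p <- add_conv(p, sprintf("up%d", l), c(3, 3, 3, ch[l + 1], ch[l]))
        p <- add_bn(p, sprintf("up%d_bn", l), ch[l])
        p <- add_conv(p, sprintf("mix%d", l), c(3, 3, 3, 2 * ch[l], ch[l]))
        p <- add_bn(p, sprintf("mix%d_bn", l), ch[l])
      }
    }
    p <- add_conv(p, "head", c(1, 1, 1, ch[1], 1))
    structure(list(config = config, params = p), class = "generator_weights")
  })
}

#' Initialise discriminator weights
#'
#' @param config A [discriminator_config()].
#' @param seed Integer seed.
#' @return An object of class `discriminator_weights`.
#' @export
init_discriminator <- function(config = discriminator_config(), seed = 1L) {
  with_seed(seed, {
    p <- list()
    cin <- 1L
    for (l in seq_len(config$n_layers)) {
      cout <- config$base_channels * 2L^(l - 1L)
      p <- add_conv(p, sprintf("d%d", l), c(4, 4, 4, cin, cout))
      if (l > 1L) p <- add_bn(p, sprintf("d%d_bn", l), cout)
      cin <- cout
    }
    p <- add_conv(p, "dhead", c(1, 1, 1, cin, 1))
    structure(list(config = config, params = p),
              class = "discriminator_weights")
  })
}

# ---- fusion stem ------------------------------------------------------------

# Channel-concatenate (patch, centroid mask), convolutional stem, batch
# norm, ReLU, optional non-local block.  `penv` is an environment holding
# the parameter arrays (running stats are updated in place when training).
fusion_fwd <- function(penv, cfg, patch, cmask, view, training = FALSE) {
  S <- cfg$patch_size
  if (!cfg$use_centroid_mask) cmask <- array(0, dim = c(S, S))
  x <- array(c(patch, cmask), dim = c(S, S, 2))
  nm <- paste0(view, "_stem")
  cv <- conv2d_fwd(x, penv[[paste0(nm, ".W")]], penv[[paste0(nm, ".b")]])
  bnm <- paste0(view, "_stem_bn")
  bn <- bn_fwd(cv$out, penv[[paste0(bnm, ".gamma")]],
               penv[[paste0(bnm, ".beta")]], penv[[paste0(bnm, ".rmean")]],
               penv[[paste0(bnm, ".rvar")]], training)
  if (training) {
    penv[[paste0(bnm, ".rmean")]] <- bn$rmean
    penv[[paste0(bnm, ".rvar")]] <- bn$rvar
  }
  rl <- relu_fwd(bn$out)
  out <- rl$out
  nlc <- NULL
  if (cfg$use_nonlocal) {
    nlname <- paste0(view, "_nl")
    nl <- nonlocal_fwd(out, penv[[paste0(nlname, ".theta")]],
                       penv[[paste0(nlname, ".phi")]],
                       penv[[paste0(nlname, ".sigma")]],
                       penv[[paste0(nlname, ".proj")]])
    out <- nl$out
    nlc <- nl$cache
  }
  list(out = out, cache = list(conv = cv$cache, bn = bn$cache,
                               relu = rl$cache, nl = nlc, view = view))
}

fusion_bwd <- function(cfg, cache, dout, grads) {
  v <- cache$view
  if (cfg$use_nonlocal) {
    nb <- nonlocal_bwd(cache$nl, dout)
    dout <- nb$dx
    nlname <- paste0(v, "_nl")
    grads[[paste0(nlname, ".theta")]] <- nb$dWt
    grads[[paste0(nlname, ".phi")]] <- nb$dWp
    grads[[paste0(nlname, ".sigma")]] <- nb$dWs
    grads[[paste0(nlname, ".proj")]] <- nb$dWo
  }
  dout <- relu_bwd(cache$relu, dout)
  bb <- bn_bwd(cache$bn, dout)
  bnm <- paste0(v, "_stem_bn")
  grads[[paste0(bnm, ".gamma")]] <- bb$dgamma
  grads[[paste0(bnm, ".beta")]] <- bb$dbeta
  cb <- conv2d_bwd(cache$conv, bb$dx)
  nm <- paste0(v, "_stem")
  grads[[paste0(nm, ".W")]] <- cb$dW
  grads[[paste0(nm, ".b")]] <- cb$db
  grads
}

#' Centroid fusion of one view
#'
#' Channel-concatenates the patch and its centroid mask, applies the
#' view-specific convolutional stem (+ batch norm + ReLU) and the
#' non-local self-attention block, producing a 2D feature map.
#'
#' @param patch `S` x `S` patch in `[0, 1]`.
#' @param cmask `S` x `S` binary centroid mask.
#' @param weights A [init_generator()] object.
#' @param view `"coronal"` or `"sagittal"` (selects the view's weights).
#' @return Feature array `(S, S, fusion_channels)`.
#' @export
centroid_fusion <- function(patch, cmask, weights,
                            view = c("coronal", "sagittal")) {
  stopifnot(inherits(weights, "generator_weights"))
  view <- match.arg(view)
  if (!identical(dim(patch), dim(cmask)))
    stopf("patch and centroid mask shapes differ")
  penv <- list2env(weights$params)
  fusion_fwd(penv, weights$config, patch, cmask,
             if (view == "coronal") "cor" else "sag")$out
}

#' Lift two orthogonal 2D feature maps into a shared 3D frame
#'
#' The coronal feature (indexed sagittal x axial) is duplicated S times
#' along the anterior-posterior axis; the sagittal feature (coronal x
#' axial) is duplicated S times along the left-right axis.  Both then live
#' in the package's (sagittal, coronal, axial) frame and are concatenated
#' along channels.
#'
#' @param coronal_feat Array `(S, S, C1)`.
#' @param sagittal_feat Array `(S, S, C2)`.
#' @return Array `(S, S, S, C1 + C2)`.
#' @export
lift_to_3d <- function(coronal_feat, sagittal_feat) {
  S <- dim(coronal_feat)[1]
  if (dim(sagittal_feat)[1] != S || dim(coronal_feat)[2] != S ||
      dim(sagittal_feat)[2] != S)
    stopf("both features must share the spatial size S")
  c1 <- dim(coronal_feat)[3]
  c2 <- dim(sagittal_feat)[3]
  # coronal (x, z, c) -> (x, y, z, c), constant along y
  volc <- aperm(array(coronal_feat, c(S, S, c1, S)), c(1, 4, 2, 3))
  # sagittal (y, z, c) -> (x, y, z, c), constant along x
  vols <- aperm(array(sagittal_feat, c(S, S, c2, S)), c(4, 1, 2, 3))
  array(c(volc, vols), dim = c(S, S, S, c1 + c2))
}

# Adjoint of lift_to_3d for one block: sum over the duplicated axis and
# undo the permutation back to a 2D feature gradient.
unlift_coronal <- function(dvol) {
  # dvol (x, y, z, c) -> sum over y -> (x, z, c)
  d <- aperm(dvol, c(1, 3, 4, 2))
  dm <- dim(d)
  array(rowSums(array(d, c(prod(dm[1:3]), dm[4])), dims = 1), dim = dm[1:3])
}
unlift_sagittal <- function(dvol) {
  d <- aperm(dvol, c(2, 3, 4, 1))
  dm <- dim(d)
  array(rowSums(array(d, c(prod(dm[1:3]), dm[4])), dims = 1), dim = dm[1:3])
}

# ---- building blocks with caches -------------------------------------------

conv_bn_relu3d_fwd <- function(penv, name, bname, x, stride, training) {
  cv <- conv3d_fwd(x, penv[[paste0(name, ".W")]], penv[[paste0(name, ".b")]],
                   stride = stride, pad = 1L)
  bn <- bn_fwd(cv$out, penv[[paste0(bname, ".gamma")]],
               penv[[paste0(bname, ".beta")]],
               penv[[paste0(bname, ".rmean")]],
               penv[[paste0(bname, ".rvar")]], training)
  if (training) {
    penv[[paste0(bname, ".rmean")]] <- bn$rmean
    penv[[paste0(bname, ".rvar")]] <- bn$rvar
  }
  rl <- relu_fwd(bn$out)
  list(out = rl$out,
       cache = list(conv = cv$cache, bn = bn$cache, relu = rl$cache,
                    name = name, bname = bname))
}

conv_bn_relu3d_bwd <- function(cache, dout, grads) {
  dout <- relu_bwd(cache$relu, dout)
  bb <- bn_bwd(cache$bn, dout)
  grads[[paste0(cache$bname, ".gamma")]] <- bb$dgamma
  grads[[paste0(cache$bname, ".beta")]] <- bb$dbeta
  cb <- conv3d_bwd(cache$conv, bb$dx)
  grads[[paste0(cache$name, ".W")]] <- cb$dW
  grads[[paste0(cache$name, ".b")]] <- cb$db
  list(dx = cb$dx, grads = grads)
}

# Residual block: conv-BN-ReLU-conv-BN, add input, ReLU.
resblock_fwd <- function(penv, l, x, training) {
  c1 <- conv3d_fwd(x, penv[[sprintf("res%d_conv1.W", l)]],
                   penv[[sprintf("res%d_conv1.b", l)]])
  b1 <- bn_fwd(c1$out, penv[[sprintf("res%d_bn1.gamma", l)]],
               penv[[sprintf("res%d_bn1.beta", l)]],
               penv[[sprintf("res%d_bn1.rmean", l)]],
               penv[[sprintf("res%d_bn1.rvar", l)]], training)
  if (training) {
    penv[[sprintf("res%d_bn1.rmean", l)]] <- b1$rmean
    penv[[sprintf("res%d_bn1.rvar", l)]] <- b1$rvar
  }
  r1 <- relu_fwd(b1$out)
  c2 <- conv3d_fwd(r1$out, penv[[sprintf("res%d_conv2.W", l)]],
                   penv[[sprintf("res%d_conv2.b", l)]])
  b2 <- bn_fwd(c2$out, penv[[sprintf("res%d_bn2.gamma", l)]],
               penv[[sprintf("res%d_bn2.beta", l)]],
               penv[[sprintf("res%d_bn2.rmean", l)]],
               penv[[sprintf("res%d_bn2.rvar", l)]], training)
  if (training) {
    penv[[sprintf("res%d_bn2.rmean", l)]] <- b2$rmean
    penv[[sprintf("res%d_bn2.rvar", l)]] <- b2$rvar
  }
  r2 <- relu_fwd(b2$out + x)
  list(out = r2$out,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache, l = l))
}

resblock_bwd <- function(cache, dout, grads) {
  l <- cache$l
  dsum <- relu_bwd(cache$r2, dout)
  bb2 <- bn_bwd(cache$b2, dsum)
  grads[[sprintf("res%d_bn2.gamma", l)]] <- bb2$dgamma
  grads[[sprintf("res%d_bn2.beta", l)]] <- bb2$dbeta
  cb2 <- conv3d_bwd(cache$c2, bb2$dx)
  grads[[sprintf("res%d_conv2.W", l)]] <- cb2$dW
  grads[[sprintf("res%d_conv2.b", l)]] <- cb2$db
  dr1 <- relu_bwd(cache$r1, cb2$dx)
  bb1 <- bn_bwd(cache$b1, dr1)
  grads[[sprintf("res%d_bn1.gamma", l)]] <- bb1$dgamma
  grads[[sprintf("res%d_bn1.beta", l)]] <- bb1$dbeta
  cb1 <- conv3d_bwd(cache$c1, bb1$dx)
  grads[[sprintf("res%d_conv1.W", l)]] <- cb1$dW
  grads[[sprintf("res%d_conv1.b", l)]] <- cb1$db
  list(dx = cb1$dx + dsum, grads = grads)
}

# ---- generator forward / backward ------------------------------------------

gen_fwd <- function(penv, cfg, pair, training = FALSE) {
  fc <- fusion_fwd(penv, cfg, pair$coronal_patch, pair$coronal_centroid_mask,
                   "cor", training)
  fs <- fusion_fwd(penv, cfg, pair$sagittal_patch,
                   pair$sagittal_centroid_mask, "sag", training)
  x3 <- lift_to_3d(fc$out, fs$out)
  e0 <- conv_bn_relu3d_fwd(penv, "enc0", "enc0_bn", x3, 1L, training)
  enc <- vector("list", cfg$depth)
  down <- vector("list", cfg$depth - 1L)
  h <- e0$out
  for (l in seq_len(cfg$depth)) {
    rb <- resblock_fwd(penv, l, h, training)
    enc[[l]] <- rb
    h <- rb$out
    if (l < cfg$depth) {
      dn <- conv_bn_relu3d_fwd(penv, sprintf("down%d", l),
                               sprintf("down%d_bn", l), h, 2L, training)
      down[[l]] <- dn
      h <- dn$out
    }
  }
  ups <- vector("list", cfg$depth - 1L)
  for (l in rev(seq_len(cfg$depth - 1L))) {
    us <- upsample2_fwd(h)
    uc <- conv_bn_relu3d_fwd(penv, sprintf("up%d", l),
                             sprintf("up%d_bn", l), us$out, 1L, training)
    skip <- enc[[l]]$out
    cat_in <- array(c(uc$out, skip), dim = c(dim(skip)[1:3],
                                             dim(uc$out)[4] + dim(skip)[4]))
    mx <- conv_bn_relu3d_fwd(penv, sprintf("mix%d", l),
                             sprintf("mix%d_bn", l), cat_in, 1L, training)
    ups[[l]] <- list(us = us$cache, uc = uc$cache, mx = mx$cache,
                     c_up = dim(uc$out)[4])
    h <- mx$out
  }
  hd <- conv3d_fwd(h, penv[["head.W"]], penv[["head.b"]], stride = 1L,
                   pad = 0L)
  sg <- sigmoid_fwd(hd$out)
  prob <- array(sg$out, dim = dim(sg$out)[1:3])
  list(out = prob,
       cache = list(fc = fc$cache, fs = fs$cache, e0 = e0$cache,
                    enc = lapply(enc, `[[`, "cache"),
                    down = lapply(down, function(d) d$cache),
                    ups = ups, hd = hd$cache, sg = sg$cache, cfg = cfg))
}

gen_bwd <- function(cache, dprob) {
  cfg <- cache$cfg
  grads <- list()
  dlog <- sigmoid_bwd(cache$sg, array(dprob, dim = c(dim(dprob), 1)))
  hb <- conv3d_bwd(cache$hd, dlog)
  grads[["head.W"]] <- hb$dW
  grads[["head.b"]] <- hb$db
  dh <- hb$dx
  denc <- vector("list", cfg$depth)  # gradient flowing into enc[[l]]$out
  for (l in seq_len(cfg$depth - 1L)) {
    u <- cache$ups[[l]]
    mb <- conv_bn_relu3d_bwd(u$mx, dh, grads)
    grads <- mb$grads
    dcat <- mb$dx
    c_up <- u$c_up
    dup <- dcat[, , , seq_len(c_up), drop = FALSE]
    dskip <- dcat[, , , -seq_len(c_up), drop = FALSE]
    ub <- conv_bn_relu3d_bwd(u$uc, dup, grads)
    grads <- ub$grads
    dh <- upsample2_bwd(u$us, ub$dx)
    denc[[l]] <- dskip
  }
  # dh now flows into the bottleneck resblock output (or, when depth == 1,
  # nothing: depth >= 2 always holds here)
  dcur <- dh
  for (l in rev(seq_len(cfg$depth))) {
    if (l < cfg$depth) {
      db <- conv_bn_relu3d_bwd(cache$down[[l]], dcur, grads)
      grads <- db$grads
      dcur <- db$dx + denc[[l]]
    }
    rb <- resblock_bwd(cache$enc[[l]], dcur, grads)
    grads <- rb$grads
    dcur <- rb$dx
  }
  eb <- conv_bn_relu3d_bwd(cache$e0, dcur, grads)
  grads <- eb$grads
  dx3 <- eb$dx
  cf <- cfg$fusion_channels
  dcor <- unlift_coronal(dx3[, , , seq_len(cf), drop = FALSE])
  dsag <- unlift_sagittal(dx3[, , , cf + seq_len(cf), drop = FALSE])
  grads <- fusion_bwd(cfg, cache$fc, dcor, grads)
  grads <- fusion_bwd(cfg, cache$fs, dsag, grads)
  grads
}

#' Run the generator on a patch pair
#'
#' @param pair A [patch_pair()].
#' @param weights A `generator_weights` object from [init_generator()].
#' @return Occupancy probability volume `(S, S, S)` with values in (0, 1).
#' @export
generator_forward <- function(pair, weights) {
  stopifnot(inherits(weights, "generator_weights"),
            inherits(pair, "patch_pair"))
  cfg <- weights$config
  if (nrow(pair$coronal_patch) != cfg$patch_size)
    stopf("pair patch size %d does not match config patch size %d",
          nrow(pair$coronal_patch), cfg$patch_size)
  penv <- list2env(weights$params)
  gen_fwd(penv, cfg, pair, training = FALSE)$out
}

# ---- discriminator ----------------------------------------------------------

disc_fwd <- function(penv, cfg, vol, training = FALSE) {
  x <- array(vol, dim = c(dim(vol)[1:3], 1))
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    cv <- conv3d_fwd(x, penv[[sprintf("d%d.W", l)]],
                     penv[[sprintf("d%d.b", l)]], stride = 2L, pad = 1L)
    h <- cv$out
    bnc <- NULL
    if (l > 1L) {
      bname <- sprintf("d%d_bn", l)
      bn <- bn_fwd(h, penv[[paste0(bname, ".gamma")]],
                   penv[[paste0(bname, ".beta")]],
                   penv[[paste0(bname, ".rmean")]],
                   penv[[paste0(bname, ".rvar")]], training)
      if (training) {
        penv[[paste0(bname, ".rmean")]] <- bn$rmean
        penv[[paste0(bname, ".rvar")]] <- bn$rvar
      }
      h <- bn$out
      bnc <- bn$cache
    }
    lr <- lrelu_fwd(h)
    caches[[l]] <- list(conv = cv$cache, bn = bnc, lrelu = lr$cache)
    x <- lr$out
  }
  hd <- conv3d_fwd(x, penv[["dhead.W"]], penv[["dhead.b"]], stride = 1L,
                   pad = 0L)
  score <- array(hd$out, dim = dim(hd$out)[1:3])
  list(out = score, cache = list(layers = caches, hd = hd$cache, cfg = cfg))
}

disc_bwd <- function(cache, dscore) {
  cfg <- cache$cfg
  grads <- list()
  hb <- conv3d_bwd(cache$hd, array(dscore, dim = c(dim(dscore), 1)))
  grads[["dhead.W"]] <- hb$dW
  grads[["dhead.b"]] <- hb$db
  dx <- hb$dx
  for (l in rev(seq_len(cfg$n_layers))) {
    lc <- cache$layers[[l]]
    dx <- lrelu_bwd(lc$lrelu, dx)
    if (l > 1L) {
      bb <- bn_bwd(lc$bn, dx)
      grads[[sprintf("d%d_bn.gamma", l)]] <- bb$dgamma
      grads[[sprintf("d%d_bn.beta", l)]] <- bb$dbeta
      dx <- bb$dx
    }
    cb <- conv3d_bwd(lc$conv, dx)
    grads[[sprintf("d%d.W", l)]] <- cb$dW
    grads[[sprintf("d%d.b", l)]] <- cb$db
    dx <- cb$dx
  }
  list(dx = array(dx, dim = dim(dx)[1:3]), grads = grads)
}

#' Run the discriminator on an occupancy volume
#'
#' @param volume 3D array with values in `[0, 1]`.
#' @param weights A `discriminator_weights` object from
#'   [init_discriminator()].
#' @return Spatial map of realness scores (3D array, strictly smaller than
#'   the input).
#' @export
discriminator_forward <- function(volume, weights) {
  stopifnot(inherits(weights, "discriminator_weights"))
  penv <- list2env(weights$params)
  disc_fwd(penv, weights$config, volume, training = FALSE)$out
}

# ---- checkpoints ------------------------------------------------------------

#' Save / load network checkpoints
#'
#' A checkpoint holds the configuration and every named parameter array
#' (including batch-norm running statistics) and round-trips bit-exactly.
#'
#' @param weights A `generator_weights` or `discriminator_weights` object.
#' @param path File path.
#' @return `load_checkpoint` returns the weights object.
#' @export
save_checkpoint <- function(weights, path) {
  saveRDS(weights, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

# Trainable parameter names (running stats are excluded from optimisation).
trainable_names <- function(params) {
  names(params)[!grepl("\\.(rmean|rvar)$", names(params))]
}
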