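test_that("dice loss reproduces hand-computed overlaps and endpoints", {
  m <- array(0, dim = c(4, 4, 4))
  m[1:2, 1, 1] <- 1
  expect_equal(dice_loss(m, m), 0, tolerance = 1e-5)
  disj <- array(0, dim = c(4, 4, 4)); disj[3:4, 4, 4] <- 1
  expect_equal(dice_loss(m, disj), 1, tolerance = 1e-5)
  # |pred| = 4, |mask| = 4, overlap 2  ->  1 - 2*2/8 = 0.5
  pred <- array(0, dim = c(4, 4, 4)); pred[1:4, 1, 1] <- 1
  mask <- array(0, dim = c(4, 4, 4)); mask[3:4, 1, 1] <- 1; mask[1:2, 2, 1] <- 1
  expect_equal(dice_loss(pred, mask), 0.5, tolerance = 1e-5)
})

test_that("dice loss is invariant under shared voxel permutations and matches soft formula", {
  set.seed(11)
  for (i in 1:20) {
    p <- array(runif(27), dim = c(3, 3, 3))
    q <- array(runif(27) > 0.5, dim = c(3, 3, 3)) * 1
    direct <- 1 - 2 * sum(p * q) / (sum(p) + sum(q) + 1e-6)
    expect_equal(dice_loss(p, q), direct, tolerance = 1e-12)
    perm <- sample(27)
    expect_equal(dice_loss(array(p[perm], dim = c(3, 3, 3)),
                           array(q[perm], dim = c(3, 3, 3))),
                 dice_loss(p, q), tolerance = 1e-12)
  }
})

test_that("focal loss matches a high-precision independent evaluation", {
  # single foreground voxel with pred 0.5: 0.2 * 0.5^5 * ln 2
  p <- array(0.5, dim = c(1, 1, 1))
  q <- array(1, dim = c(1, 1, 1))
  expect_equal(focal_loss(p, q), 0.2 * 0.5^5 * log(2), tolerance = 1e-10)
  expect_equal(0.2 * 0.5^5 * log(2), 4.332169878499658e-3, tolerance = 1e-12)
  # p_t = 1 everywhere -> 0 (up to clamping)
  expect_equal(focal_loss(array(1, dim = c(2, 2, 2)), array(1, dim = c(2, 2, 2))),
               0, tolerance = 1e-6)
  # random instances against a direct per-voxel oracle
  set.seed(12)
  for (i in 1:30) {
    p <- array(runif(27, 0.01, 0.99), dim = c(3, 3, 3))
    q <- array(runif(27) > 0.6, dim = c(3, 3, 3)) * 1
    pt <- ifelse(q == 1, p, 1 - p)
    w <- ifelse(q == 1, 0.2, 0.8)
    oracle <- mean(-w * (1 - pt)^5 * log(pt))
    expect_equal(focal_loss(p, q), oracle, tolerance = 1e-9)
  }
})

test_that("focal loss gradient matches finite differences", {
  set.seed(13)
  p <- array(runif(8, 0.05, 0.95), dim = c(2, 2, 2))
  q <- array(c(1, 0, 1, 0, 0, 1, 0, 0), dim = c(2, 2, 2))
  g <- ns$focal_loss_grad(p, q)
  h <- 1e-6
  for (i in 1:8) {
    pp <- p; pp[i] <- pp[i] + h
    pm <- p; pm[i] <- pm[i] - h
    expect_equal(g[i], (focal_loss(pp, q) - focal_loss(pm, q)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("distance-transform Hausdorff loss matches the brute-force oracle", {
  # identical masks give zero
  m <- random_mask(c(4, 4, 4))
  expect_equal(hausdorff_dt_loss(m * 1, m * 1), 0)
  # 1D-style toy: direct evaluation with an all-pairs distance transform
  set.seed(14)
  p <- array(runif(8), dim = c(1, 1, 8))
  q <- array(c(0, 0, 1, 1, 1, 0, 0, 0), dim = c(1, 1, 8))
  dp <- brute_boundary_dt(p >= 0.5)
  dq <- brute_boundary_dt(q >= 0.5)
  oracle <- mean((p - q)^2 * (dp^2 + dq^2))
  expect_equal(hausdorff_dt_loss(p, q), oracle, tolerance = 1e-9)
  # random <= 4^3 soft/binary instances
  for (i in 1:40) {
    dm <- sample(2:4, 3, replace = TRUE)
    p <- array(runif(prod(dm)), dim = dm)
    q <- random_mask(dm) * 1
    dp <- brute_boundary_dt(p >= 0.5)
    dq <- brute_boundary_dt(q >= 0.5)
    oracle <- mean((p - q)^2 * (dp^2 + dq^2))
    expect_equal(hausdorff_dt_loss(p, q), oracle, tolerance = 1e-9)
    expect_gte(hausdorff_dt_loss(p, q), 0)
  }
})

test_that("least-squares adversarial losses evaluate the stated objectives", {
  ones <- array(1, dim = c(2, 2, 2))
  zeros <- array(0, dim = c(2, 2, 2))
  expect_equal(lsgan_losses(ones, ones)$g_loss, 0)
  expect_equal(lsgan_losses(zeros, ones)$d_loss, 0)
  half <- array(0.5, dim = c(2, 2, 2))
  expect_equal(lsgan_losses(half, half)$g_loss, 0.25)
  expect_equal(lsgan_losses(half, half)$d_loss, 0.5)
  set.seed(15)
  for (i in 1:20) {
    f <- array(rnorm(8), dim = c(2, 2, 2))
    r <- array(rnorm(8), dim = c(2, 2, 2))
    ls <- lsgan_losses(f, r)
    expect_equal(ls$g_loss, mean((f - 1)^2), tolerance = 1e-12)
    expect_equal(ls$d_loss, mean((r - 1)^2) + mean(f^2), tolerance = 1e-12)
  }
})

test_that("integrated loss is the exact weighted sum with published defaults", {
  expect_equal(integrated_loss(0, 0, 0, 0), 0)
  expect_equal(integrated_loss(1, 1, 1, 1), 20.1001, tolerance = 1e-12)
  w <- loss_weights()
  expect_equal(w$lambda, 10)
  expect_equal(w$alpha_w, 1e-4)
  expect_equal(w$beta, 10)
  expect_equal(w$gamma_adv, 0.1)
  set.seed(16)
  for (i in 1:20) {
    v <- runif(4)
    expect_equal(integrated_loss(v[1], v[2], v[3], v[4]),
                 10 * v[1] + 1e-4 * v[2] + 10 * v[3] + 0.1 * v[4],
                 tolerance = 1e-12)
  }
})

test_that("losses are nonnegative and finite on valid random inputs", {
  set.seed(17)
  for (i in 1:10) {
    p <- array(runif(27), dim = c(3, 3, 3))
    q <- random_mask(c(3, 3, 3)) * 1
    vals <- c(dice_loss(p, q), hausdorff_dt_loss(p, q), focal_loss(p, q))
    expect_true(all(is.finite(vals)))
    expect_true(all(vals >= -1e-12))
  }
})
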