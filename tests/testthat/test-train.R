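test_that("default configuration equals the published training protocol", {
  cfg <- train_config()
  expect_identical(cfg$epochs, 100L)
  expect_identical(cfg$batch_size, 8L)
  expect_equal(cfg$lr, 1e-4)
  expect_identical(cfg$lr_decay_every, 20L)
  expect_equal(cfg$lr_decay_factor, 0.1)
  expect_identical(cfg$patch_size, 120L)
  w <- cfg$loss_weights
  expect_equal(c(w$lambda, w$alpha_w, w$beta, w$gamma_adv),
               c(10, 1e-4, 10, 0.1))
  expect_equal(c(cfg$focal$alpha_t, cfg$focal$gamma_f), c(0.2, 5))
})

test_that("learning rate decays to one tenth every 20 epochs", {
  cfg <- train_config()
  expect_equal(ns$lr_at_epoch(cfg, 1), 1e-4)
  expect_equal(ns$lr_at_epoch(cfg, 20), 1e-4)
  expect_equal(ns$lr_at_epoch(cfg, 21), 1e-5)
  expect_equal(ns$lr_at_epoch(cfg, 41), 1e-6)
})

test_that("short training runs are reproducible and log the loss components", {
  pairs <- desk_pairs(2)
  cfg <- desk_train_config(seed = 42, max_steps = 3)
  r1 <- train(cfg, pairs)
  r2 <- train(cfg, pairs)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$generator, r2$generator)
  expect_identical(nrow(r1$log), 3L)
  expect_identical(r1$log$step, 1:3)
  expect_true(all(is.finite(r1$log$g_loss)))
  expect_true(all(c("dice_loss", "hausdorff_loss", "focal_loss",
                    "adv_g_loss", "d_loss", "lr") %in% names(r1$log)))
})

test_that("ablation axes switch off their components", {
  cfg <- train_config(patch_size = 32, ablate = c("dice", "adversarial",
                                                  "centroid", "nonlocal"))
  expect_equal(cfg$loss_weights$lambda, 0)
  expect_equal(cfg$loss_weights$gamma_adv, 0)
  expect_false(cfg$generator$use_centroid_mask)
  expect_false(cfg$generator$use_nonlocal)
  expect_error(train_config(ablate = "bogus"), "unknown ablation")
  # adversarial-free training runs without a discriminator update
  pairs <- desk_pairs(3)[1:2]
  r <- train(desk_train_config(seed = 1, max_steps = 2,
                               ablate = "adversarial"), pairs)
  expect_true(all(is.na(r$log$d_loss)))
})

test_that("reconstruction thresholds behave monotonically", {
  G <- init_generator(desk_generator_config(), seed = 11)
  pair <- desk_pairs(6)[[1]]
  all_on <- reconstruct(G, pair, threshold = 0)
  expect_true(all(all_on == 1))
  m1 <- reconstruct(G, pair, threshold = 0.4)
  m2 <- reconstruct(G, pair, threshold = 0.6)
  expect_true(all(m2 <= m1))            # raising threshold never adds voxels
  hi <- reconstruct(G, pair, threshold = 1)
  expect_true(all(hi == 0))
  expect_true(isTRUE(attr(hi, "empty")))
})

test_that("spine assembly pastes labels and resolves overlaps by probability", {
  m <- array(0, dim = c(3, 3, 3)); m[1:2, 1:2, 1:2] <- 1
  canvas <- assemble_spine(list(list(label = 4L, mask = m,
                                     offset = c(2, 2, 2))),
                           canvas_shape = c(8, 8, 8))
  expect_equal(sum(canvas == 4L), 8)
  expect_equal(canvas[2, 2, 2], 4L)
  # two disjoint vertebrae keep their own voxel counts
  canvas2 <- assemble_spine(list(
    list(label = 1L, mask = m, offset = c(1, 1, 1)),
    list(label = 2L, mask = m, offset = c(5, 5, 5))),
    canvas_shape = c(8, 8, 8))
  expect_equal(as.integer(table(canvas2[canvas2 > 0])), c(8L, 8L))
  # engineered 2-voxel overlap: higher probability wins
  a <- array(0, dim = c(2, 2, 2)); a[, , ] <- 1
  pa <- array(0.9, dim = c(2, 2, 2)); pa[2, 1, 1] <- 0.2
  pb <- array(0.6, dim = c(2, 2, 2)); pb[1, 1, 1] <- 0.95
  canvas3 <- assemble_spine(list(
    list(label = 1L, mask = a, prob = pa, offset = c(1, 1, 1)),
    list(label = 2L, mask = a, prob = pb, offset = c(2, 1, 1))),
    canvas_shape = c(4, 2, 2))
  # voxel (2,1,1): label 1 prob 0.2 vs label 2 prob 0.95 -> label 2
  expect_equal(canvas3[2, 1, 1], 2L)
  # partial overhang is clipped; a fully outside window is rejected
  clipped <- assemble_spine(list(list(label = 3L, mask = a,
                                      offset = c(4, 1, 1))),
                            canvas_shape = c(4, 2, 2))
  expect_equal(sum(clipped == 3L), 4)
  expect_error(assemble_spine(list(list(label = 1L, mask = a,
                                        offset = c(9, 1, 1))),
                              canvas_shape = c(4, 2, 2)),
               "outside the canvas")
})

test_that("evaluation with a perfect oracle scores perfectly and aggregates by position", {
  pairs <- desk_pairs(8)
  mt <- evaluate(NULL, pairs, predict_fn = function(p) p$target)
  per_v <- mt[mt$row_type == "vertebra", ]
  expect_identical(nrow(per_v), length(pairs))
  expect_true(all(per_v$dice == 1))
  expect_true(all(per_v$hd95 == 0))
  expect_true(all(per_v$nsd == 1))
  overall <- mt[mt$row_type == "aggregate" & mt$vertebra_label == "ALL", ]
  expect_equal(overall$dice, 1)
  # per-position aggregation matches a hand-grouped recomputation
  for (pos in unique(per_v$vertebra_label)) {
    agg <- mt[mt$row_type == "aggregate" & mt$vertebra_label == pos, ]
    expect_equal(agg$dice, mean(per_v$dice[per_v$vertebra_label == pos]))
  }
  expect_identical(nrow(mt),
                   nrow(per_v) + length(unique(per_v$vertebra_label)) + 1L)
})

test_that("training rejects degenerate inputs", {
  expect_error(train(desk_train_config(), list()), "nonempty")
  pair <- desk_pairs(4)[[1]]
  pair$target <- NULL
  expect_error(train(desk_train_config(), list(pair)), "target")
})

test_that("the ablation harness trains and evaluates every requested variant", {
  pairs <- desk_pairs(9)
  base <- desk_train_config(seed = 3, max_steps = 1)
  grid <- run_ablation_grid(base, pairs[1:2], pairs[3:4],
                            ablations = c("centroid", "adversarial"))
  expect_setequal(names(grid), c("full", "centroid", "adversarial"))
  for (v in grid) {
    expect_identical(nrow(v$log), 1L)
    expect_true(all(is.finite(v$log$g_loss)))
    expect_s3_class(v$metrics, "metrics_table")
  }
  expect_true(all(is.na(grid$adversarial$log$d_loss)))
})
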