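# Normalisation, patch grid, augmentation, loss, and the training loop.

test_that("normalisation is exact and reversible", {
  v <- array(c(0, 2), c(2, 1, 1))
  n <- normalize_video(v)
  expect_equal(n$stats$mean, 1)
  expect_equal(n$stats$sd, sd(c(0, 2)))
  set.seed(1)
  v2 <- array(rnorm(1000, 50, 4), c(10, 10, 10))
  n2 <- normalize_video(v2)
  expect_equal(mean(n2$video), 0, tolerance = 1e-12)
  expect_equal(sd(as.vector(n2$video)), 1, tolerance = 1e-12)
  expect_equal(denormalize_video(n2$video, n2$stats), v2,
               tolerance = 1e-9)
  expect_error(normalize_video(array(7, c(3, 3, 3))), "constant")
})

test_that("patch grid matches the stride arithmetic", {
  g <- extract_patches(c(100L, 256L, 256L), train_config())
  # spatial: stride 67 -> origins 1, 68, then clamped 129; temporal:
  # stride 60 -> origins 1, clamped 40
  expect_equal(nrow(g), 3 * 3 * 2)
  expect_setequal(unique(g$y0), c(1L, 68L, 129L))
  expect_setequal(unique(g$t0), c(1L, 40L))
  # single-patch movie
  g1 <- extract_patches(c(61L, 128L, 128L), train_config())
  expect_equal(nrow(g1), 1)
  # coverage: union of patches covers every coordinate
  tc <- train_config(patch_xy = 50L, overlap_xy = 13L, patch_t = 21L,
                     overlap_t = 4L)
  g2 <- extract_patches(c(90L, 120L, 75L), tc)
  covered <- rep(FALSE, 120)
  for (o in unique(g2$y0)) covered[o:(o + 49L)] <- TRUE
  expect_true(all(covered))
  expect_error(extract_patches(c(20L, 64L, 64L), train_config()),
               "temporal")
})

test_that("dihedral augmentation has group structure", {
  set.seed(2)
  p <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  expect_identical(augment_patch(p, 1), p)
  # flips are involutions
  expect_equal(augment_patch(augment_patch(p, 5), 5), p)
  # four rotations return to the identity
  r <- p
  for (i in 1:4) r <- augment_patch(r, 2)
  expect_equal(r, p)
  # all 8 images of an asymmetric marker are distinct
  marker <- array(0, c(3, 3, 1))
  marker[1, 1, 1] <- 1; marker[1, 2, 1] <- 2
  imgs <- lapply(1:8, function(d) augment_patch(marker, d))
  for (i in 1:7) for (j in (i + 1):8)
    expect_false(identical(imgs[[i]], imgs[[j]]))
  # every frame transformed identically
  q <- augment_patch(p, 6)
  expect_equal(q[, , 2], augment_patch(p[, , 2, drop = FALSE], 6)[, , 1])
  # non-square patches reject quarter turns
  pn <- array(rnorm(2 * 3 * 1), c(2, 3, 1))
  expect_error(augment_patch(pn, 2), "square")
  expect_equal(dim(augment_patch(pn, 3)), dim(pn))
})

test_that("the weighted L1/L2 loss follows its formula", {
  expect_equal(support_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(support_loss(2, 0, alpha = 0.5), 0.5 * 2 + 0.5 * 4)
  expect_equal(support_loss(c(3, -1), c(1, 1), alpha = 1), mean(c(2, 2)))
  expect_equal(support_loss(c(3, -1), c(1, 1), alpha = 0), mean(c(4, 4)))
  expect_error(support_loss(1:4, 1:3), "differ")
  # convex interpolation between the pure losses
  set.seed(3)
  p <- rnorm(50); t <- rnorm(50)
  l1 <- support_loss(p, t, 1); l2 <- support_loss(p, t, 0)
  for (a in c(0.25, 0.5, 0.75))
    expect_equal(support_loss(p, t, a), a * l1 + (1 - a) * l2)
})

test_that("training reduces the loss and is seed-reproducible", {
  cfg <- tiny_config()
  set.seed(4)
  t_n <- 40L
  base <- outer(seq_len(16), seq_len(16), function(i, j) 5 + sin(i / 2) + j / 8)
  movie <- array(0, c(t_n, 16, 16))
  for (t in seq_len(t_n)) movie[t, , ] <- base * 100 +
    rnorm(256, sd = sqrt(base * 100))
  tc <- train_config(patch_xy = 16, patch_t = 5, overlap_t = 1,
                     batch_size = 4, epochs = 5, lr = 2e-3, seed = 0)
  ck <- train_self_supervised(movie, cfg, tc)
  nup <- length(ck$loss_history)
  per_epoch <- nup / 5
  expect_lt(median(tail(ck$loss_history, per_epoch)),
            median(head(ck$loss_history, per_epoch)))
  ck2 <- train_self_supervised(movie, cfg, tc)
  expect_identical(ck$loss_history, ck2$loss_history)
  expect_identical(ck$params, ck2$params)
  # patch_t must match the temporal window
  expect_error(train_self_supervised(movie, cfg,
                                     train_config(patch_t = 7L)),
               "temporal window")
})

test_that("on pure noise the network converges to the mean", {
  # i.i.d. noise is unpredictable from the blind-spot neighbourhood: the
  # optimal prediction is a constant and the loss floor is the noise's own
  # deviation statistics
  cfg <- tiny_config()
  set.seed(6)
  movie <- array(rnorm(60 * 16 * 16, mean = 100, sd = 1), c(60, 16, 16))
  tc <- train_config(patch_xy = 16, patch_t = 5, overlap_t = 2,
                     batch_size = 8, epochs = 8, lr = 2e-3, seed = 1)
  ck <- train_self_supervised(movie, cfg, tc)
  # floor for unit-variance noise with an L1/L2 mix:
  # 0.5 E|z| + 0.5 E z^2 = 0.5 sqrt(2/pi) + 0.5 ~ 0.899
  floor <- 0.5 * sqrt(2 / pi) + 0.5
  final <- median(tail(ck$loss_history, 10))
  expect_lt(final, 1.3 * floor)
  expect_gt(final, 0.9 * floor)  # cannot beat the floor: noise unpredictable
  # prediction is near-constant: its spread is far below the noise spread
  net <- blindspot:::checkpoint_net(ck)
  norm <- normalize_video(movie)
  x <- array(aperm(norm$video[1:5, , ], c(2, 3, 1)), c(16, 16, 5, 1))
  pred <- support_predict(net, x)
  expect_lt(sd(as.vector(pred)), 0.5)
})

test_that("checkpoints round-trip through disk", {
  cfg <- tiny_config()
  set.seed(9)
  movie <- array(rnorm(30 * 12 * 12, 10), c(30, 12, 12))
  ck <- train_self_supervised(movie, cfg,
                              train_config(patch_xy = 12, patch_t = 5,
                                           overlap_t = 1, batch_size = 8,
                                           epochs = 1, lr = 1e-3, seed = 0))
  f <- tempfile(fileext = ".rds")
  save_checkpoint(ck, f)
  ck2 <- load_checkpoint(f)
  expect_identical(ck2$params, ck$params)
  expect_identical(ck2$norm_stats, ck$norm_stats)
  # the restored checkpoint denoises identically
  expect_identical(denoise_video(ck, movie, frames = 5:6),
                   denoise_video(ck2, movie, frames = 5:6))
})
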