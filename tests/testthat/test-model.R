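# Architecture guarantees: masked kernels, blind-spot exactness,
# receptive fields.

test_that("masked convolution has a zero centre response", {
  set.seed(1)
  h <- 9L
  for (k in c(3L, 5L)) {
    w <- matrix(rnorm(k * k * 1 * 3), k * k, 3)
    mask <- blindspot:::centre_mask(k, 1L, 3L)
    b <- blindspot:::ad_leaf
    g <- blindspot:::ad_graph()
    x <- array(0, c(h, h, 1, 1))
    x[5, 5, 1, 1] <- 1  # centred delta
    xn <- blindspot:::ad_leaf(g, x)
    wn <- blindspot:::ad_leaf(g, w)
    bn <- blindspot:::ad_leaf(g, rnorm(3))
    y <- blindspot:::op_conv(g, xn, wn, bn, k, 1L, mask = mask)
    bias <- blindspot:::op_conv(g, blindspot:::ad_leaf(g, x * 0), wn, bn,
                                k, 1L, mask = mask)
    # response at the delta position is exactly the bias: centre tap dead
    expect_identical(y$value[5, 5, , 1], bias$value[5, 5, , 1])
    # off-centre delta produces a response somewhere
    expect_gt(max(abs(y$value - bias$value)), 0)
  }
})

test_that("even kernels are rejected", {
  expect_error(support_config(bs_kernels = c(3, 4)))
  expect_error(support_config(blind_spot_size = 2), "odd")
})

test_that("effective centre weights stay zero through optimizer updates", {
  cfg <- tiny_config()
  net <- support_net(cfg, seed = 2)
  opt <- blindspot:::adam_init(net$params)
  set.seed(3)
  for (step in 1:10) {
    x <- random_window(cfg, 12, 12, 2, seed = step)
    fw <- blindspot:::support_forward(net, x, training = TRUE)
    tgt <- x[, , cfg$n_before + 1L, , drop = FALSE]
    loss <- blindspot:::op_l1l2_loss(fw$graph, fw$out, tgt, 0.5)
    blindspot:::ad_backward(fw$graph, loss)
    grads <- lapply(fw$params, function(p) p$grad)
    st <- blindspot:::adam_step(net$params, grads, opt, 1e-3)
    net$params <- st$params; opt <- st$state
  }
  for (k in cfg$bs_kernels) for (i in seq_len(cfg$bs_depth)) {
    w <- net$params[[paste0("p", k, "_c", i, "_w")]]
    cin <- nrow(w) / (k * k)
    mask <- blindspot:::centre_mask(k, cin, ncol(w))
    eff <- w * mask
    centre_rows <- which(!mask[, 1])
    expect_identical(max(abs(eff[centre_rows, ])), 0)
  }
})

test_that("blind-spot exactness: centre pixel cannot influence itself", {
  cfg <- tiny_config()
  net <- support_net(cfg, seed = 4)
  x <- random_window(cfg, 16, 16, 1, seed = 5)
  y <- support_predict(net, x)
  tc <- cfg$n_before + 1L
  for (pos in list(c(8, 9), c(3, 3), c(16, 1))) {
    x2 <- x
    x2[pos[1], pos[2], tc, 1] <- x2[pos[1], pos[2], tc, 1] + 1000
    y2 <- support_predict(net, x2)
    expect_identical(y2[pos[1], pos[2], 1, 1], y[pos[1], pos[2], 1, 1])
  }
  # ... while the same perturbation in an adjacent frame does propagate
  x3 <- x
  x3[8, 9, tc - 1L, 1] <- x3[8, 9, tc - 1L, 1] + 1000
  y3 <- support_predict(net, x3)
  expect_false(isTRUE(all.equal(y3[8, 9, 1, 1], y[8, 9, 1, 1])))
  # and neighbouring pixels of the centre frame do influence the centre
  x4 <- x
  x4[8, 10, tc, 1] <- x4[8, 10, tc, 1] + 1000
  y4 <- support_predict(net, x4)
  expect_false(isTRUE(all.equal(y4[8, 9, 1, 1], y[8, 9, 1, 1])))
})

test_that("blind-spot exactness survives training", {
  cfg <- tiny_config()
  set.seed(11)
  movie <- array(rnorm(30 * 12 * 12, mean = 10), c(30, 12, 12))
  tc <- train_config(patch_xy = 12, patch_t = 5, overlap_t = 1,
                     batch_size = 4, epochs = 2, lr = 1e-3, seed = 0)
  ck <- train_self_supervised(movie, cfg, tc)
  net <- blindspot:::checkpoint_net(ck)
  x <- random_window(cfg, 12, 12, 1, seed = 6)
  y <- support_predict(net, x)
  x2 <- x
  x2[6, 7, cfg$n_before + 1L, 1] <- 500
  y2 <- support_predict(net, x2)
  expect_identical(y2[6, 7, 1, 1], y[6, 7, 1, 1])
})

test_that("widened blind spot excludes the centred p x p block", {
  for (p in c(3L, 5L)) {
    cfg <- tiny_config(blind_spot_size = p)
    net <- support_net(cfg, seed = 7)
    h <- 24L
    x <- random_window(cfg, h, h, 1, seed = 8)
    y <- support_predict(net, x)
    tc <- cfg$n_before + 1L
    ctr <- h %/% 2L
    half <- p %/% 2L
    for (di in -half:half) for (dj in -half:half) {
      x2 <- x
      x2[ctr + di, ctr + dj, tc, 1] <- x2[ctr + di, ctr + dj, tc, 1] + 1000
      y2 <- support_predict(net, x2)
      expect_identical(y2[ctr, ctr, 1, 1], y[ctr, ctr, 1, 1])
    }
    # just outside the block the influence returns
    x3 <- x
    x3[ctr + half + 1L, ctr, tc, 1] <- x3[ctr + half + 1L, ctr, tc, 1] + 1000
    y3 <- support_predict(net, x3)
    expect_false(isTRUE(all.equal(y3[ctr, ctr, 1, 1], y[ctr, ctr, 1, 1])))
  }
})

test_that("widen_blind_spot with p = 1 returns the net unchanged", {
  net <- support_net(tiny_config(), seed = 1)
  expect_identical(widen_blind_spot(net, 1L), net)
  expect_error(widen_blind_spot(net, 2L), "odd")
})

test_that("analytic receptive field matches dilation arithmetic", {
  m <- compute_receptive_field(3L, depth = 1L)
  expect_equal(sum(m), 8)              # 3x3 minus centre
  expect_equal(dim(m), c(3, 3))
  expect_false(m[2, 2])
  for (d in 1:4) {
    m <- compute_receptive_field(3L, depth = d)
    expect_equal((nrow(m) - 1) / 2, sum(2^(0:(d - 1))))  # half-width
    ctr <- (nrow(m) + 1) / 2
    expect_false(m[ctr, ctr])
  }
  # depth-2 k=3 reachability against brute-force composition of the two
  # masked kernels (dilations 1 and 2), including the shortcut that
  # re-injects the first layer's features
  taps <- function(dil) {
    g <- expand.grid(di = dil * (-1:1), dj = dil * (-1:1))
    g[!(g$di == 0 & g$dj == 0), ]
  }
  reach1 <- taps(1)
  reach2 <- unique(rbind(
    do.call(rbind, lapply(seq_len(nrow(reach1)), function(i)
      data.frame(di = reach1$di[i] + taps(2)$di,
                 dj = reach1$dj[i] + taps(2)$dj)))))
  all_reach <- unique(rbind(reach1, reach2))
  m2 <- compute_receptive_field(3L, depth = 2L)
  r <- (nrow(m2) - 1) / 2
  brute <- matrix(FALSE, nrow(m2), nrow(m2))
  brute[cbind(all_reach$di + r + 1, all_reach$dj + r + 1)] <- TRUE
  expect_identical(m2, brute)
})

test_that("analytic mask equals empirical gradient support", {
  # single-path networks over the (kernel, depth) grid; empirical support
  # from the input gradient of the centre output pixel
  for (k in c(3L, 5L)) for (d in 1:3) {
    cfg <- support_config(n_before = 1L, n_after = 1L, bs_kernels = k,
                          bs_depth = d, bs_channels = 4L, unet_depth = 1L,
                          unet_base_channels = 2L)
    ana <- compute_receptive_field(k, depth = d)
    r <- (nrow(ana) - 1L) / 2L
    h <- 2L * r + 17L  # margin so the mask fits strictly inside
    net <- support_net(cfg, seed = k * 10L + d)
    x <- random_window(cfg, h, h, 1, seed = d)
    ctr <- (h + 1L) / 2L
    seed_grad <- array(0, c(h, h, 1, 1))
    seed_grad[ctr, ctr, 1, 1] <- 1
    gin <- blindspot:::support_input_gradient(net, x, seed_grad)
    gmap <- gin[, , cfg$n_before + 1L, 1]
    emp <- abs(gmap) > 1e-12
    idx <- (ctr - r):(ctr + r)
    expect_identical(emp[idx, idx], unname(ana))
    # nothing outside the analytic footprint
    emp[idx, idx] <- FALSE
    expect_false(any(emp))
  }
})

test_that("output shape equals input spatial shape, odd sizes included", {
  cfg <- tiny_config()
  net <- support_net(cfg, seed = 9)
  for (hw in list(c(16L, 16L), c(13L, 19L))) {
    x <- random_window(cfg, hw[1], hw[2], 1, seed = 10)
    y <- support_predict(net, x)
    expect_equal(dim(y), c(hw[1], hw[2], 1L, 1L))
    expect_true(all(is.finite(y)))
  }
  # zeroed adjacent frames still give finite output
  x0 <- random_window(cfg, 16, 16, 1, seed = 11)
  x0[, , -(cfg$n_before + 1L), ] <- 0
  expect_true(all(is.finite(support_predict(net, x0))))
})

test_that("blind-spot paths contain no pooled normalisation layers", {
  net <- support_net(tiny_config(), seed = 1)
  bs_params <- grep("^p[35]_", names(net$params), value = TRUE)
  expect_false(any(grepl("_g$|_be$", bs_params)))  # no BN gamma/beta
  expect_false(any(grepl("^p", names(net$bn))))    # no BN state
})

test_that("margin estimate covers the deepest path and pooling grid", {
  cfg <- support_config()
  m3 <- compute_receptive_field(3L, depth = 4L)
  expect_equal((nrow(m3) - 1) / 2, 15)  # 1 + 2 + 4 + 8
  m5 <- compute_receptive_field(5L, depth = 4L)
  expect_equal((nrow(m5) - 1) / 2, 2 * (2 + 6 + 18 + 54))
  mg <- estimate_margin(cfg)
  expect_gte(mg, (nrow(m5) - 1) / 2)
  expect_equal(mg %% 2^cfg$unet_depth, 0)
  # widening the blind spot widens the margin
  cfg5 <- support_config(blind_spot_size = 5L)
  expect_gte(estimate_margin(cfg5), mg)
})
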