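# The denoising network: a temporal U-Net over neighbouring frames plus two
# masked dilated-convolution ("blind-spot") paths over the current frame,
# joined by pointwise aggregation layers.  By construction the prediction
# at pixel (t, k) never depends on the input value at (t, k): the current
# frame is only ever touched through convolutions whose kernel centre is
# masked to zero, with dilation schedules chosen so that no composition of
# kernel taps sums to a zero displacement.

#' Network hyper-parameters
#'
#' Bundles every architectural knob of the blind-spot denoising network.
#'
#' @param n_before,n_after Number of past/future frames fed to the temporal
#'   U-Net branch (default 30/30; use 10/10 for volumetric structural stacks
#'   where the "time" axis is depth and few slices are available).
#' @param bs_kernels Kernel sizes of the blind-spot paths; each size gets
#'   its own sequential path. Supported sizes are 3 and 5.
#' @param bs_depth Number of masked convolution layers per path. Layer
#'   \eqn{i} (counting from 0) uses dilation \eqn{2^i} for the 3x3 path and
#'   \eqn{2\cdot 3^i} for the 5x5 path, which makes the receptive field grow
#'   exponentially with depth while keeping the centre pixel unreachable.
#' @param bs_channels Feature channels inside each blind-spot path.
#' @param unet_depth Number of encoder (and decoder) levels of the U-Net.
#' @param unet_base_channels Channels of the U-Net feature maps.
#' @param unet_channel_multiplier Capacity factor applied to all U-Net
#'   channels (use 4 for movies with motion).
#' @param blind_spot_size Odd width \eqn{p} of the blind spot. For
#'   \eqn{p > 1} the last masked convolution of each path receives extra
#'   dilation \eqn{\lfloor p/2\rfloor} and only the final path features are
#'   aggregated, so the whole centred \eqn{p \times p} block is excluded
#'   from the receptive field.
#' @param head_convs Number of pointwise (1x1) aggregation layers.
#' @param agg_channels Hidden width of the aggregation layers (default 64;
#'   the head mixes all retained path features with the U-Net output, and
#'   starving it throttles how much current-frame evidence reaches the
#'   prediction).
#' @return A `support_config` list, validated.
#' @export
support_config <- function(n_before = 30L, n_after = 30L,
                           bs_kernels = c(3L, 5L), bs_depth = 4L,
                           bs_channels = 16L, unet_depth = 4L,
                           unet_base_channels = 16L,
                           unet_channel_multiplier = 1L,
                           blind_spot_size = 1L, head_convs = 3L,
                           agg_channels = NULL) {
  stopifnot(n_before >= 0, n_after >= 0, n_before + n_after >= 1)
  bs_kernels <- sort(unique(as.integer(bs_kernels)))
  if (!all(bs_kernels %in% c(3L, 5L)))
    stop("bs_kernels must be a subset of {3, 5}")
  if (any(bs_kernels %% 2L == 0L)) stop("kernel sizes must be odd")
  stopifnot(bs_depth >= 1, bs_channels >= 1, unet_depth >= 1,
            unet_base_channels >= 1, unet_channel_multiplier >= 1,
            head_convs >= 1)
  p <- as.integer(blind_spot_size)
  if (p < 1L || p %% 2L == 0L) stop("blind_spot_size must be odd and >= 1")
  if (is.null(agg_channels)) agg_channels <- 64L
  structure(list(
    n_before = as.integer(n_before), n_after = as.integer(n_after),
    bs_kernels = bs_kernels, bs_depth = as.integer(bs_depth),
    bs_channels = as.integer(bs_channels),
    unet_depth = as.integer(unet_depth),
    unet_base_channels = as.integer(unet_base_channels),
    unet_channel_multiplier = as.integer(unet_channel_multiplier),
    blind_spot_size = p, head_convs = as.integer(head_convs),
    agg_channels = as.integer(agg_channels)),
    class = "support_config")
}

# Dilation of each masked layer in a path (layer index from 0).  The last
# layer gains floor(p/2) extra dilation when the blind spot is widened.
bs_dilations <- function(kernel, depth, p = 1L) {
  base <- if (kernel == 3L) 2L^(0:(depth - 1L)) else 2L * 3L^(0:(depth - 1L))
  if (p > 1L) base[depth] <- base[depth] + p %/% 2L
  as.integer(base)
}

# Multiplicative mask that zeroes the centre tap of a [k*k*Cin, Cout]
# weight matrix for every input channel.
centre_mask <- function(k, cin, cout) {
  tap <- rep(TRUE, k * k)
  tap[(k * k + 1L) / 2L] <- FALSE
  matrix(rep(tap, cin), nrow = k * k * cin, ncol = cout)
}

unet_channels <- function(config) {
  config$unet_base_channels * config$unet_channel_multiplier
}

init_conv <- function(k, cin, cout, rng_sd = NULL) {
  fan_in <- k * k * cin
  sd <- if (is.null(rng_sd)) sqrt(2 / fan_in) else rng_sd
  list(w = matrix(stats::rnorm(k * k * cin * cout, sd = sd),
                  nrow = k * k * cin, ncol = cout),
       b = numeric(cout))
}

new_bn_state <- function(channels) {
  e <- new.env(parent = emptyenv())
  e$running_mean <- numeric(channels)
  e$running_var <- rep(1, channels)
  e$momentum <- 0.1
  e$eps <- 1e-5
  e
}

#' Build the blind-spot denoising network
#'
#' Initialises all parameters (He-style normal init, seeded through R's RNG)
#' and returns a network object holding parameters, batch-normalisation
#' state and the configuration.
#'
#' @param config A [support_config()].
#' @param seed Integer seed for the parameter initialisation.
#' @return A `support_net` object.
#' @export
support_net <- function(config = support_config(), seed = 0L) {
  stopifnot(inherits(config, "support_config"))
  set.seed(seed)
  ch <- unet_channels(config)
  c0 <- config$n_before + config$n_after
  params <- list()
  bn <- list()
  # U-Net encoder / decoder (3x3 convs, BN, leaky ReLU)
  for (i in seq_len(config$unet_depth)) {
    cin <- if (i == 1L) c0 else ch
    cv <- init_conv(3L, cin, ch)
    params[[paste0("ue", i, "_w")]] <- cv$w
    params[[paste0("ue", i, "_b")]] <- cv$b
    params[[paste0("ue", i, "_g")]] <- rep(1, ch)
    params[[paste0("ue", i, "_be")]] <- numeric(ch)
    bn[[paste0("ue", i)]] <- new_bn_state(ch)
    cv <- init_conv(3L, 2L * ch, ch)
    params[[paste0("ud", i, "_w")]] <- cv$w
    params[[paste0("ud", i, "_b")]] <- cv$b
    params[[paste0("ud", i, "_g")]] <- rep(1, ch)
    params[[paste0("ud", i, "_be")]] <- numeric(ch)
    bn[[paste0("ud", i)]] <- new_bn_state(ch)
  }
  # blind-spot paths
  bsin <- 1L + ch
  bc <- config$bs_channels
  for (k in config$bs_kernels) {
    for (i in seq_len(config$bs_depth)) {
      cin <- if (i == 1L) bsin else bc
      cv <- init_conv(k, cin, bc)
      params[[paste0("p", k, "_c", i, "_w")]] <- cv$w
      params[[paste0("p", k, "_c", i, "_b")]] <- cv$b
      if (i >= 2L) {
        cv <- init_conv(1L, bc, bc)
        params[[paste0("p", k, "_s", i, "_w")]] <- cv$w
        params[[paste0("p", k, "_s", i, "_b")]] <- cv$b
      }
    }
  }
  # aggregation head (1x1 convs)
  n_feat <- if (config$blind_spot_size > 1L) length(config$bs_kernels)
            else length(config$bs_kernels) * config$bs_depth
  agg_in <- n_feat * bc + ch
  for (j in seq_len(config$head_convs)) {
    cin <- if (j == 1L) agg_in else config$agg_channels
    cout <- if (j == config$head_convs) 1L else config$agg_channels
    cv <- init_conv(1L, cin, cout)
    params[[paste0("agg", j, "_w")]] <- cv$w
    params[[paste0("agg", j, "_b")]] <- cv$b
  }
  structure(list(params = params, bn = bn, config = config),
            class = "support_net")
}

# Forward pass.  `x` is [H, W, Tw, N] with Tw = n_before + 1 + n_after.
# Returns the graph, the output node, the input leaf and the parameter leaf
# map so callers can run backprop and harvest gradients.
support_forward <- function(net, x, training = FALSE,
                            need_input_grad = FALSE) {
  cfg <- net$config
  tw <- cfg$n_before + 1L + cfg$n_after
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (d[3] != tw) stop("input window must have ", tw, " frames")
  g <- ad_graph()
  pn <- lapply(net$params, function(p) ad_leaf(g, p))
  xin <- ad_leaf(g, x)
  tc <- cfg$n_before + 1L
  neighbours <- op_slice_ch(g, xin, setdiff(seq_len(tw), tc))
  centre <- op_slice_ch(g, xin, tc)

  # --- temporal U-Net branch ---
  dep <- cfg$unet_depth
  mult <- 2L^dep
  H2 <- as.integer(ceiling(d[1] / mult) * mult)
  W2 <- as.integer(ceiling(d[2] / mult) * mult)
  if (min(H2, W2) / mult < 1)
    stop("spatial extent too small for unet_depth = ", dep)
  h <- op_pad_br(g, neighbours, H2, W2)
  enc <- vector("list", dep)
  for (i in seq_len(dep)) {
    a <- op_conv(g, h, pn[[paste0("ue", i, "_w")]],
                 pn[[paste0("ue", i, "_b")]], 3L, 1L,
                 need_input_grad = need_input_grad || i > 1L)
    a <- op_bn(g, a, pn[[paste0("ue", i, "_g")]],
               pn[[paste0("ue", i, "_be")]], net$bn[[paste0("ue", i)]],
               training)
    a <- op_lrelu(g, a)
    enc[[i]] <- a
    h <- op_maxpool(g, a)
  }
  for (i in seq_len(dep)) {
    u <- op_upsample(g, h)
    u <- op_concat(g, list(u, enc[[dep - i + 1L]]))
    h <- op_conv(g, u, pn[[paste0("ud", i, "_w")]],
                 pn[[paste0("ud", i, "_b")]], 3L, 1L)
    h <- op_bn(g, h, pn[[paste0("ud", i, "_g")]],
               pn[[paste0("ud", i, "_be")]], net$bn[[paste0("ud", i)]],
               training)
    h <- op_lrelu(g, h)
  }
  unet_out <- op_crop(g, h, d[1], d[2])

  # --- blind-spot paths over the current frame ---
  bsin <- op_concat(g, list(centre, unet_out))
  feats <- list()
  for (k in cfg$bs_kernels) {
    dils <- bs_dilations(k, cfg$bs_depth, cfg$blind_spot_size)
    cin1 <- dim(bsin$value)[3]
    mask1 <- centre_mask(k, cin1, cfg$bs_channels)
    maskh <- centre_mask(k, cfg$bs_channels, cfg$bs_channels)
    f <- op_lrelu(g, op_conv(g, bsin, pn[[paste0("p", k, "_c1_w")]],
                             pn[[paste0("p", k, "_c1_b")]], k, dils[1],
                             mask = mask1))
    path_feats <- list(f)
    f1 <- f
    if (cfg$bs_depth >= 2L) {
      for (i in 2:cfg$bs_depth) {
        s <- op_conv(g, f1, pn[[paste0("p", k, "_s", i, "_w")]],
                     pn[[paste0("p", k, "_s", i, "_b")]], 1L, 1L)
        f <- op_lrelu(g, op_conv(g, op_add(g, f, s),
                                 pn[[paste0("p", k, "_c", i, "_w")]],
                                 pn[[paste0("p", k, "_c", i, "_b")]],
                                 k, dils[i], mask = maskh))
        path_feats[[i]] <- f
      }
    }
    feats <- c(feats, if (cfg$blind_spot_size > 1L)
      path_feats[length(path_feats)] else path_feats)
  }

  # --- aggregation head ---
  h <- op_concat(g, c(feats, list(unet_out)))
  for (j in seq_len(cfg$head_convs)) {
    h <- op_conv(g, h, pn[[paste0("agg", j, "_w")]],
                 pn[[paste0("agg", j, "_b")]], 1L, 1L)
    if (j < cfg$head_convs) h <- op_lrelu(g, h)
  }
  list(graph = g, out = h, input = xin, params = pn)
}

#' Predict the denoised centre frame
#'
#' Runs the network in evaluation mode on one or more temporal windows.
#'
#' @param net A `support_net`.
#' @param x Array `[H, W, n_before + 1 + n_after, N]` (or 3-D for a single
#'   window) of normalised input frames.
#' @return Array `[H, W, 1, N]`: the prediction of each window's centre
#'   frame.
#' @export
support_predict <- function(net, x) {
  support_forward(net, x, training = FALSE)$out$value
}

# Gradient of the summed output (weighted by `seed`) with respect to the
# input window; used by the receptive-field certification.
support_input_gradient <- function(net, x, seed) {
  fw <- support_forward(net, x, training = FALSE, need_input_grad = TRUE)
  ad_backward(fw$graph, fw$out, seed)
  fw$input$grad
}

#' Widen the blind spot of a trained network
#'
#' Returns a network whose prediction ignores the whole centred `p x p`
#' block of the current frame: the last masked convolution of each path
#' receives `floor(p/2)` extra dilation and only the final path features
#' reach the aggregation head. Weights with unchanged shapes are carried
#' over; aggregation layers whose input width changes are re-initialised.
#'
#' @param net A `support_net`.
#' @param p Odd blind-spot width (>= 1). `p = 1` returns the net unchanged.
#' @param seed Seed for the re-initialised aggregation layers.
#' @return A `support_net` with blind-spot size `p`.
#' @export
widen_blind_spot <- function(net, p, seed = 0L) {
  p <- as.integer(p)
  if (p %% 2L == 0L || p < 1L) stop("p must be odd and >= 1")
  if (p == net$config$blind_spot_size) return(net)
  cfg <- net$config
  cfg$blind_spot_size <- p
  cfg <- do.call(support_config, cfg[setdiff(names(cfg), NULL)])
  out <- support_net(cfg, seed = seed)
  for (nm in names(out$params)) {
    old <- net$params[[nm]]
    if (!is.null(old) && identical(dim(old), dim(out$params[[nm]])) &&
        length(old) == length(out$params[[nm]]))
      out$params[[nm]] <- old
  }
  for (nm in names(out$bn)) {
    out$bn[[nm]]$running_mean <- net$bn[[nm]]$running_mean
    out$bn[[nm]]$running_var <- net$bn[[nm]]$running_var
  }
  out
}

#' Analytic receptive field of the current-frame pathway
#'
#' Composes the masked, dilated kernel offsets of the blind-spot paths into
#' the set of current-frame input positions that can influence the output
#' at the centre pixel. The centre itself (and, for blind-spot size `p`,
#' the whole centred `p x p` block) is provably unreachable.
#'
#' @param config A [support_config()], or a single kernel size (3 or 5) to
#'   inspect one path in isolation.
#' @param depth Path depth when `config` is a kernel size.
#' @param p Blind-spot width when `config` is a kernel size.
#' @return A logical matrix of odd extent centred on the target pixel;
#'   `TRUE` marks positions that can influence the centre output.
#' @export
compute_receptive_field <- function(config, depth = 4L, p = 1L) {
  if (inherits(config, "support_config")) {
    masks <- lapply(config$bs_kernels, function(k)
      rf_mask_path(k, config$bs_depth, config$blind_spot_size))
    r <- max(vapply(masks, function(m) (nrow(m) - 1L) %/% 2L, integer(1)))
    out <- matrix(FALSE, 2L * r + 1L, 2L * r + 1L)
    for (m in masks) {
      rm <- (nrow(m) - 1L) %/% 2L
      idx <- (r - rm + 1L):(r + rm + 1L)
      out[idx, idx] <- out[idx, idx] | m
    }
    return(out)
  }
  rf_mask_path(as.integer(config), as.integer(depth), as.integer(p))
}

# Reachability mask of a single path, mirroring the forward graph exactly:
# f1 = taps1(x);  f_i = taps_i(f_{i-1} union f1)  [shortcut];  the
# aggregated mask is the union of all layer masks (final layer only when
# the blind spot is widened).
rf_mask_path <- function(kernel, depth, p = 1L) {
  dils <- bs_dilations(kernel, depth, p)
  r <- sum(dils) * (kernel - 1L) %/% 2L
  n <- 2L * r + 1L
  taps <- function(dil) {
    off <- dil * seq.int(-(kernel - 1L) %/% 2L, (kernel - 1L) %/% 2L)
    ex <- expand.grid(di = off, dj = off)
    ex[!(ex$di == 0L & ex$dj == 0L), ]
  }
  minkowski <- function(mask, tp) {
    out <- matrix(FALSE, n, n)
    w <- which(mask, arr.ind = TRUE)
    for (t in seq_len(nrow(tp))) {
      ii <- w[, 1] + tp$di[t]
      jj <- w[, 2] + tp$dj[t]
      keep <- ii >= 1L & ii <= n & jj >= 1L & jj <= n
      out[cbind(ii[keep], jj[keep])] <- TRUE
    }
    out
  }
  delta <- matrix(FALSE, n, n)
  delta[r + 1L, r + 1L] <- TRUE
  f <- minkowski(delta, taps(dils[1]))
  f1 <- f
  layer_masks <- list(f)
  if (depth >= 2L) {
    for (i in 2:depth) {
      f <- minkowski(f | f1, taps(dils[i]))
      layer_masks[[i]] <- f
    }
  }
  keep <- if (p > 1L) layer_masks[depth] else layer_masks
  Reduce(`|`, keep)
}

#' Spatial margin that makes tiled inference exact
#'
#' The blind-spot paths convolve the U-Net output, so the spatial
#' receptive-field half-width is the half-width of the deepest blind-spot
#' path plus a conservative bound for the U-Net branch. The sum is rounded
#' up to a multiple of the U-Net pooling factor so that tiles stay aligned
#' with the pooling grid. Using at least this margin guarantees that tiled
#' inference reproduces whole-frame inference exactly on kept pixels.
#'
#' @param config A [support_config()].
#' @return Margin in pixels.
#' @export
estimate_margin <- function(config) {
  stopifnot(inherits(config, "support_config"))
  bs <- max(vapply(config$bs_kernels, function(k) {
    sum(bs_dilations(k, config$bs_depth, config$blind_spot_size)) *
      (k - 1L) %/% 2L
  }, integer(1)))
  unet <- 4L * 2L^config$unet_depth
  mult <- 2L^config$unet_depth
  as.integer(ceiling((bs + unet) / mult) * mult)
}
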