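# Self-supervised training: the network predicts each centre-frame pixel
# from its spatiotemporal neighbours, with the noisy pixel itself as the
# regression target.  Because the blind spot removes the target pixel from
# the input, the zero-mean noise cannot be reproduced and the minimiser of
# the expected loss is the clean signal.

#' Training hyper-parameters
#'
#' @param patch_xy Spatial patch size in pixels (clamped to the movie
#'   size).
#' @param patch_t Temporal patch length in frames; must be odd and equal
#'   `n_before + 1 + n_after` of the network configuration.
#' @param overlap_xy,overlap_t Patch overlaps defining the extraction grid
#'   (stride = patch - overlap; the last patch is clamped to the movie
#'   boundary so every pixel is covered).
#' @param batch_size Patches per gradient update.
#' @param lr Adam learning rate.
#' @param weight_decay L2 weight decay (0 disables).
#' @param epochs Number of passes over the patch grid.
#' @param alpha Weight of the L1 term in the loss
#'   `alpha * L1 + (1 - alpha) * L2`.
#' @param adam_beta2 Second-moment decay of Adam. The default 0.999 suits
#'   long runs; short desk-scale runs adapt faster with 0.99.
#' @param lr_schedule `"constant"` (default) or `"cosine"`: cosine decay of
#'   the learning rate from `lr` to zero over the training run, useful for
#'   short desk-scale runs where late-stage noise in the parameter updates
#'   would otherwise dominate.
#' @param seed Integer seed controlling initialisation, patch shuffling and
#'   augmentation.
#' @return A validated `train_config` list.
#' @export
train_config <- function(patch_xy = 128L, patch_t = 61L, overlap_xy = 61L,
                         overlap_t = 1L, batch_size = 16L, lr = 5e-4,
                         weight_decay = 0, epochs = 500L, alpha = 0.5,
                         adam_beta2 = 0.999,
                         lr_schedule = c("constant", "cosine"),
                         seed = 0L) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(adam_beta2 > 0, adam_beta2 < 1)
  stopifnot(alpha >= 0, alpha <= 1, patch_xy >= 1, patch_t >= 1,
            overlap_xy >= 0, overlap_t >= 0, batch_size >= 1, lr > 0,
            weight_decay >= 0, epochs >= 1)
  if (patch_t %% 2L == 0L) stop("patch_t must be odd")
  if (overlap_t >= patch_t) stop("overlap_t must be smaller than patch_t")
  structure(list(patch_xy = as.integer(patch_xy),
                 patch_t = as.integer(patch_t),
                 overlap_xy = as.integer(overlap_xy),
                 overlap_t = as.integer(overlap_t),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 alpha = alpha, adam_beta2 = adam_beta2,
                 lr_schedule = lr_schedule,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Global z-normalisation of a movie
#'
#' Subtracts the global mean and divides by the global standard deviation.
#'
#' @param video Numeric array.
#' @return List with the normalised `video` and `stats` (`mean`, `sd`).
#' @export
normalize_video <- function(video) {
  if (!all(is.finite(video))) stop("video contains non-finite values")
  mu <- mean(video)
  s <- stats::sd(as.vector(video))
  if (s == 0) stop("degenerate input: constant movie")
  list(video = (video - mu) / s, stats = list(mean = mu, sd = s))
}

#' @rdname normalize_video
#' @param stats Normalisation statistics from [normalize_video()].
#' @export
denormalize_video <- function(video, stats) {
  video * stats$sd + stats$mean
}

axis_origins <- function(size, patch, overlap) {
  patch <- min(patch, size)
  overlap <- min(overlap, patch - 1L)
  stride <- patch - overlap
  o <- seq.int(1L, size - patch + 1L, by = stride)
  last <- size - patch + 1L
  if (o[length(o)] != last) o <- c(o, last)
  list(origins = as.integer(o), patch = as.integer(patch))
}

#' Patch-extraction grid
#'
#' Origins of the training patches: a regular grid with stride
#' `patch - overlap` per axis, with the final origin clamped so the last
#' patch ends exactly at the movie boundary (every pixel is covered).
#'
#' @param dims Movie dimensions `c(T, H, W)` (or a `[T, H, W]` array).
#' @param config A [train_config()].
#' @return Data frame with columns `t0`, `y0`, `x0` and attributes
#'   `patch_t`, `patch_y`, `patch_x`.
#' @export
extract_patches <- function(dims, config = train_config()) {
  if (is.array(dims)) dims <- dim(dims)
  stopifnot(length(dims) == 3)
  if (dims[1] < config$patch_t)
    stop("movie has fewer frames than patch_t; use a smaller temporal ",
         "window (n_before/n_after)")
  at <- axis_origins(dims[1], config$patch_t, config$overlap_t)
  ay <- axis_origins(dims[2], config$patch_xy, config$overlap_xy)
  ax <- axis_origins(dims[3], config$patch_xy, config$overlap_xy)
  grid <- expand.grid(t0 = at$origins, y0 = ay$origins, x0 = ax$origins)
  attr(grid, "patch_t") <- at$patch
  attr(grid, "patch_y") <- ay$patch
  attr(grid, "patch_x") <- ax$patch
  grid
}

#' Dihedral augmentation
#'
#' Applies one of the 8 axis-aligned flips/rotations to every frame of a
#' `[H, W, T]` patch identically. Non-square patches only admit draws that
#' preserve the shape (identity, 180 degree rotation, both flips).
#'
#' @param patch `[H, W, T]` array.
#' @param draw Integer 1-8: rotation by `(draw - 1) %% 4` quarter turns,
#'   with a row flip first when `draw > 4`. Draw 1 is the identity.
#' @return Transformed patch.
#' @export
augment_patch <- function(patch, draw) {
  stopifnot(draw %in% 1:8)
  d <- dim(patch)
  square <- d[1] == d[2]
  if (!square && ((draw - 1) %% 4) %in% c(1, 3))
    stop("quarter-turn rotations need a square patch")
  x <- patch
  if (draw > 4) x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
  r <- (draw - 1) %% 4
  for (i in seq_len(r)) {
    # 90 degrees counter-clockwise: out[i, j] = in[j, W - i + 1]
    x <- aperm(x, c(2, 1, 3))[rev(seq_len(dim(x)[2])), , , drop = FALSE]
  }
  x
}

#' Self-supervised loss
#'
#' `alpha * mean(|p - t|) + (1 - alpha) * mean((p - t)^2)`. During training
#' the target is the noisy centre frame, never the clean signal.
#'
#' @param prediction,target Arrays of identical shape.
#' @param alpha L1 weight in `[0, 1]`.
#' @return Scalar loss.
#' @export
support_loss <- function(prediction, target, alpha = 0.5) {
  if (length(prediction) != length(target))
    stop("prediction and target shapes differ")
  r <- prediction - target
  alpha * mean(abs(r)) + (1 - alpha) * mean(r * r)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    if (weight_decay > 0) gr <- gr + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the denoising network on a noisy movie
#'
#' Self-supervised training: for every patch the network receives the
#' temporal window around the centre frame and regresses the noisy centre
#' frame itself. One epoch is one shuffled pass over the clamped patch
#' grid. The loss of every gradient update is recorded.
#'
#' @param video Noisy `[T, H, W]` movie.
#' @param config A [support_config()].
#' @param tconf A [train_config()]; `patch_t` must equal the network's
#'   temporal window.
#' @param verbose Print per-epoch median loss.
#' @return A `support_checkpoint`: list with `params`, `bn` (running
#'   statistics), `config`, `train_config`, `norm_stats` and
#'   `loss_history`.
#' @export
train_self_supervised <- function(video, config = support_config(),
                                  tconf = train_config(), verbose = FALSE) {
  tw <- config$n_before + 1L + config$n_after
  if (tconf$patch_t != tw)
    stop("patch_t (", tconf$patch_t, ") must equal the temporal window (",
         tw, ")")
  norm <- normalize_video(video)
  vn <- aperm(norm$video, c(2, 3, 1))  # [H, W, T] for fast window slicing
  grid <- extract_patches(dim(video), tconf)
  py <- attr(grid, "patch_y"); px <- attr(grid, "patch_x")
  net <- support_net(config, seed = tconf$seed)
  opt <- adam_init(net$params)
  set.seed(tconf$seed)
  tc <- config$n_before + 1L
  loss_history <- numeric(0)
  square <- py == px
  n_updates <- tconf$epochs * ceiling(nrow(grid) / tconf$batch_size)
  for (ep in seq_len(tconf$epochs)) {
    ord <- sample(nrow(grid))
    ep_losses <- numeric(0)
    for (b0 in seq(1, length(ord), by = tconf$batch_size)) {
      idx <- ord[b0:min(b0 + tconf$batch_size - 1L, length(ord))]
      nb <- length(idx)
      batch <- array(0, c(py, px, tw, nb))
      for (s in seq_len(nb)) {
        g <- grid[idx[s], ]
        patch <- vn[g$y0:(g$y0 + py - 1L), g$x0:(g$x0 + px - 1L),
                    g$t0:(g$t0 + tw - 1L), drop = FALSE]
        draw <- if (square) sample(8L, 1L) else sample(c(1L, 3L, 5L, 7L), 1L)
        batch[, , , s] <- augment_patch(patch, draw)
      }
      target <- batch[, , tc, , drop = FALSE]
      fw <- support_forward(net, batch, training = TRUE)
      loss <- op_l1l2_loss(fw$graph, fw$out, target, tconf$alpha)
      if (!is.finite(loss$value))
        stop("non-finite loss at update ", length(loss_history) + 1L,
             "; try a smaller learning rate")
      ad_backward(fw$graph, loss)
      grads <- lapply(fw$params, function(p)
        if (is.null(p$grad)) NULL else p$grad)
      lr_t <- if (identical(tconf$lr_schedule, "cosine"))
        tconf$lr * 0.5 * (1 + cos(pi * length(loss_history) / n_updates))
      else tconf$lr
      st <- adam_step(net$params, grads, opt, lr_t, tconf$weight_decay,
                      beta2 = tconf$adam_beta2)
      net$params <- st$params
      opt <- st$state
      loss_history <- c(loss_history, loss$value)
      ep_losses <- c(ep_losses, loss$value)
    }
    if (verbose)
      message(sprintf("epoch %d/%d  median loss %.5f", ep, tconf$epochs,
                      stats::median(ep_losses)))
  }
  structure(list(params = net$params,
                 bn = lapply(net$bn, function(e)
                   list(running_mean = e$running_mean,
                        running_var = e$running_var)),
                 config = config, train_config = tconf,
                 norm_stats = norm$stats, loss_history = loss_history),
            class = "support_checkpoint")
}

# Rebuild a live network object from a checkpoint.
checkpoint_net <- function(ckpt) {
  net <- support_net(ckpt$config, seed = 0L)
  net$params <- ckpt$params
  for (nm in names(ckpt$bn)) {
    net$bn[[nm]]$running_mean <- ckpt$bn[[nm]]$running_mean
    net$bn[[nm]]$running_var <- ckpt$bn[[nm]]$running_var
  }
  net
}

#' Save / load a training checkpoint
#'
#' The checkpoint embeds the network and training configurations and the
#' normalisation statistics, so inference needs no further information.
#'
#' @param ckpt A `support_checkpoint`.
#' @param path File path.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "support_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  stopifnot(inherits(ckpt, "support_checkpoint"))
  ckpt
}
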