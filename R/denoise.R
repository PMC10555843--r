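# Inference: apply a trained network to a whole movie.  Every frame is
# predicted from its temporal window (zero-padded, in normalised space,
# beyond the movie ends); large frames are processed in spatial tiles whose
# kept centre crops partition the frame exactly.  With a margin of at
# least the network's receptive-field half-width and pooling-grid aligned
# tiles, tiled inference is bit-identical to whole-frame inference.

#' Spatial tiling plan
#'
#' Kept regions partition the frame exactly (no gaps, no overlaps); each
#' tile's source region extends the kept region by `margin` pixels on every
#' side, clipped to the frame. Kept origins and the margin are aligned to
#' `align` (the U-Net pooling factor) so every tile sees the same pooling
#' grid as the whole frame.
#'
#' @param h,w Frame size.
#' @param tile Kept-region size (rounded up to a multiple of `align`), or
#'   `NULL` for a single tile.
#' @param margin Source margin in pixels (rounded up to a multiple of
#'   `align`).
#' @param align Grid alignment factor.
#' @return List of tiles, each with `kr`, `kc` (kept row/col range) and
#'   `sr`, `sc` (source ranges).
#' @export
plan_tiles <- function(h, w, tile = NULL, margin = 0L, align = 1L) {
  if (is.null(tile) || tile >= max(h, w))
    return(list(list(kr = c(1L, h), kc = c(1L, w), sr = c(1L, h),
                     sc = c(1L, w))))
  tile <- as.integer(ceiling(tile / align) * align)
  margin <- as.integer(ceiling(margin / align) * align)
  starts <- function(size) as.integer(seq.int(1L, size, by = tile))
  out <- list()
  for (r0 in starts(h)) {
    r1 <- min(r0 + tile - 1L, h)
    for (c0 in starts(w)) {
      c1 <- min(c0 + tile - 1L, w)
      out[[length(out) + 1L]] <- list(
        kr = c(r0, r1), kc = c(c0, c1),
        sr = c(max(1L, r0 - margin), min(h, r1 + margin)),
        sc = c(max(1L, c0 - margin), min(w, c1 + margin)))
    }
  }
  out
}

#' Denoise a movie with a trained network
#'
#' For each frame the temporal window `n_before..n_after` is assembled
#' (frames beyond the movie ends are zero in normalised space, matching the
#' training-time padding), the network predicts the centre frame, and tile
#' predictions are stitched by exact centre crops. The output is
#' denormalised back to the input intensity scale.
#'
#' @param ckpt A `support_checkpoint` from [train_self_supervised()].
#' @param video Noisy `[T, H, W]` movie (typically the training movie).
#' @param tile Kept-tile size in pixels, or `NULL` (default) to process
#'   whole frames. Movies smaller than one tile fall back to a single
#'   tile.
#' @param margin Tile margin; defaults to [estimate_margin()] of the
#'   checkpoint's configuration, which guarantees seam-free stitching.
#' @param batch_frames Frames predicted per forward pass.
#' @param frames Optional integer vector: predict only these frames (the
#'   returned movie still has one entry per requested frame, in order).
#' @param predict_fun Prediction-function override mapping an
#'   `[h, w, window, n]` batch to `[h, w, 1, n]`; used for stitching
#'   diagnostics. Defaults to the checkpoint's network.
#' @return Denoised movie `[length(frames), H, W]`.
#' @export
denoise_video <- function(ckpt, video, tile = NULL, margin = NULL,
                          batch_frames = 16L, frames = NULL,
                          predict_fun = NULL) {
  cfg <- ckpt$config
  d <- dim(video)
  stopifnot(length(d) == 3)
  if (is.null(frames)) frames <- seq_len(d[1])
  stopifnot(all(frames >= 1), all(frames <= d[1]))
  if (is.null(predict_fun)) {
    net <- checkpoint_net(ckpt)
    predict_fun <- function(x) support_predict(net, x)
  }
  if (is.null(margin)) margin <- estimate_margin(cfg)
  vn <- aperm((video - ckpt$norm_stats$mean) / ckpt$norm_stats$sd,
              c(2, 3, 1))  # [H, W, T]
  tw <- cfg$n_before + 1L + cfg$n_after
  tiles <- plan_tiles(d[2], d[3], tile, margin,
                      align = 2L^cfg$unet_depth)
  out <- array(0, c(length(frames), d[2], d[3]))
  for (tl in tiles) {
    th <- tl$sr[2] - tl$sr[1] + 1L
    tww <- tl$sc[2] - tl$sc[1] + 1L
    rows <- tl$sr[1]:tl$sr[2]
    cols <- tl$sc[1]:tl$sc[2]
    krow <- (tl$kr[1] - tl$sr[1] + 1L):(tl$kr[2] - tl$sr[1] + 1L)
    kcol <- (tl$kc[1] - tl$sc[1] + 1L):(tl$kc[2] - tl$sc[1] + 1L)
    for (b0 in seq(1, length(frames), by = batch_frames)) {
      bt <- frames[b0:min(b0 + batch_frames - 1L, length(frames))]
      nb <- length(bt)
      x <- array(0, c(th, tww, tw, nb))
      for (o in seq_len(tw)) {
        src <- bt + (o - 1L) - cfg$n_before
        ok <- src >= 1L & src <= d[1]
        if (any(ok)) x[, , o, ok] <- vn[rows, cols, src[ok]]
      }
      pred <- predict_fun(x)
      out[b0:(b0 + nb - 1L), tl$kr[1]:tl$kr[2], tl$kc[1]:tl$kc[2]] <-
        aperm(pred[krow, kcol, 1, , drop = FALSE], c(4, 1, 2, 3))
    }
  }
  out * ckpt$norm_stats$sd + ckpt$norm_stats$mean
}
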