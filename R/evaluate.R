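# Performance metrics: reference-based image quality (RMSE, SNR, PSNR,
# Pearson), a reference-free SNR for experimental data, spike-detection F1
# with temporal tolerance, subthreshold correlation, and cell-extraction
# evaluation (component filtering, IoU-thresholded F1 and the area under
# the F1-over-IoU curve).

#' Root-mean-square error
#' @param x Signal array/vector.
#' @param y Reference of the same shape.
#' @return `sqrt(mean((x - y)^2))`.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop("shapes differ")
  sqrt(mean((x - y)^2))
}

#' Signal-to-noise ratio against a reference (dB)
#'
#' `10 log10(mean(x)^2 / rmse(x, y)^2)`. Returns `Inf` when the signals are
#' identical.
#' @inheritParams rmse
#' @export
snr_ref <- function(x, y) {
  r <- rmse(x, y)
  if (r == 0) return(Inf)
  10 * log10(mean(x)^2 / r^2)
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 log10(max(x)^2 / rmse(x, y)^2)`; `Inf` for identical signals.
#' @inheritParams rmse
#' @export
psnr <- function(x, y) {
  r <- rmse(x, y)
  if (r == 0) return(Inf)
  10 * log10(max(x)^2 / r^2)
}

#' Pearson correlation coefficient
#' @inheritParams rmse
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("shapes differ")
  if (stats::sd(as.vector(x)) == 0 || stats::sd(as.vector(y)) == 0)
    stop("undefined correlation: zero-variance input")
  stats::cor(as.vector(x), as.vector(y))
}

#' Reference-free SNR (dB)
#'
#' `10 log10(max(x) / sd(x))` - used when no ground truth exists; note the
#' ratio (not its square) inside the logarithm.
#' @param x Signal vector/array, non-constant.
#' @export
snr_noref <- function(x) {
  s <- stats::sd(as.vector(x))
  if (s == 0) stop("constant trace")
  10 * log10(max(x) / s)
}

#' Spike-detection precision/recall/F1
#'
#' Greedy one-to-one matching: detected and true spikes are paired in
#' order of increasing time difference; pairs within `tol_frames` count as
#' true positives. `F1 = 2PR/(P+R)` (0 when both are empty-handed).
#'
#' @param detected,truth Integer vectors of spike frames.
#' @param tol_frames Matching tolerance (frames).
#' @return List with `precision`, `recall`, `f1`, `n_matched`.
#' @export
spike_f1 <- function(detected, truth, tol_frames = 1L) {
  stopifnot(tol_frames >= 0)
  nd <- length(detected); nt <- length(truth)
  if (nd == 0 && nt == 0)
    return(list(precision = 1, recall = 1, f1 = 1, n_matched = 0L))
  matched <- 0L
  if (nd > 0 && nt > 0) {
    dmat <- abs(outer(detected, truth, "-"))
    used_d <- logical(nd); used_t <- logical(nt)
    ord <- order(dmat)
    for (o in ord) {
      if (dmat[o] > tol_frames) break
      i <- (o - 1L) %% nd + 1L
      j <- (o - 1L) %/% nd + 1L
      if (used_d[i] || used_t[j]) next
      used_d[i] <- used_t[j] <- TRUE
      matched <- matched + 1L
    }
  }
  p <- if (nd > 0) matched / nd else 0
  r <- if (nt > 0) matched / nt else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1, n_matched = matched)
}

#' Pearson correlation restricted to subthreshold frames
#'
#' @param trace_a,trace_b Equal-length traces.
#' @param mask Logical vector; `TRUE` marks subthreshold frames to keep.
#' @export
subthreshold_correlation <- function(trace_a, trace_b, mask) {
  stopifnot(length(trace_a) == length(trace_b),
            length(mask) == length(trace_a))
  if (sum(mask) < 3) stop("mask leaves fewer than 3 frames")
  pearson(trace_a[mask], trace_b[mask])
}

component_bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  c(height = diff(range(w[, 1])) + 1L, width = diff(range(w[, 2])) + 1L)
}

#' Filter extracted spatial components
#'
#' Rejection heuristics for non-neuronal components, each independently
#' toggleable by passing `NULL`: (1) fewer than `alpha` pixels; (2)
#' bounding-box width or height larger than `beta`; (3) aspect ratio
#' (width/height) outside the open interval `(gamma, delta)`.
#'
#' @param components List of logical `H x W` masks.
#' @param alpha Minimum pixel count (or `NULL`).
#' @param beta Maximum bounding-box extent (or `NULL`).
#' @param gamma,delta Aspect-ratio bounds (both or neither `NULL`).
#' @return The surviving components, in input order.
#' @export
filter_components <- function(components, alpha = NULL, beta = NULL,
                              gamma = NULL, delta = NULL) {
  if (xor(is.null(gamma), is.null(delta)))
    stop("gamma and delta must be supplied together")
  if (!is.null(gamma) && !(gamma > 0 && gamma < delta))
    stop("need 0 < gamma < delta")
  keep <- vapply(components, function(m) {
    if (!any(m)) return(FALSE)
    if (!is.null(alpha) && sum(m) < alpha) return(FALSE)
    bb <- component_bbox(m)
    if (!is.null(beta) && max(bb) > beta) return(FALSE)
    if (!is.null(gamma)) {
      asp <- bb["width"] / bb["height"]
      if (asp <= gamma || asp >= delta) return(FALSE)
    }
    TRUE
  }, logical(1))
  components[keep]
}

#' Intersection over union of two masks
#' @param mask_a,mask_b Logical arrays of identical shape.
#' @export
iou <- function(mask_a, mask_b) {
  if (length(mask_a) != length(mask_b)) stop("shapes differ")
  u <- sum(mask_a | mask_b)
  if (u == 0) stop("both masks empty")
  sum(mask_a & mask_b) / u
}

#' Cell-extraction precision/recall/F1 at an IoU threshold
#'
#' Predicted and true components are paired greedily in descending IoU
#' order (one-to-one); a pair with IoU strictly above the threshold is a
#' true positive.
#'
#' @param predicted,truth Lists of logical masks.
#' @param iou_threshold Threshold in (0, 1).
#' @return List with `precision`, `recall`, `f1`.
#' @export
extraction_f1 <- function(predicted, truth, iou_threshold = 0.5) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  np <- length(predicted); nt <- length(truth)
  if (np == 0 && nt == 0)
    return(list(precision = 1, recall = 1, f1 = 1))
  matched <- 0L
  if (np > 0 && nt > 0) {
    im <- matrix(0, np, nt)
    for (i in seq_len(np)) for (j in seq_len(nt))
      im[i, j] <- sum(predicted[[i]] & truth[[j]]) /
        sum(predicted[[i]] | truth[[j]])
    used_p <- logical(np); used_t <- logical(nt)
    for (o in order(im, decreasing = TRUE)) {
      if (im[o] <= iou_threshold) break
      i <- (o - 1L) %% np + 1L
      j <- (o - 1L) %/% np + 1L
      if (used_p[i] || used_t[j]) next
      used_p[i] <- used_t[j] <- TRUE
      matched <- matched + 1L
    }
  }
  p <- if (np > 0) matched / np else 0
  r <- if (nt > 0) matched / nt else 0
  list(precision = p, recall = r,
       f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}

#' F1-over-IoU curve and its area
#'
#' Extraction F1 at each IoU threshold, and the trapezoidal area under the
#' curve normalised by the threshold span.
#'
#' @inheritParams extraction_f1
#' @param thresholds Increasing vector of IoU thresholds in (0, 1).
#' @return List with `curve` (data frame `iou_threshold`, `f1`) and `auc`.
#' @export
auc_f1_iou <- function(predicted, truth, thresholds = seq(0.1, 0.9, 0.1)) {
  stopifnot(length(thresholds) >= 2, !is.unsorted(thresholds),
            all(thresholds > 0), all(thresholds < 1))
  f1 <- vapply(thresholds, function(th)
    extraction_f1(predicted, truth, th)$f1, numeric(1))
  span <- diff(range(thresholds))
  area <- sum(diff(thresholds) * (head(f1, -1) + tail(f1, -1)) / 2) / span
  list(curve = data.frame(iou_threshold = thresholds, f1 = f1), auc = area)
}

#' Extract per-ROI traces from a movie
#'
#' Footprint-weighted mean intensity per frame.
#'
#' @param video `[T, H, W]` movie.
#' @param footprints `[H, W, n]` non-negative weight maps.
#' @return Matrix `[T, n]` of traces.
#' @export
extract_traces <- function(video, footprints) {
  d <- dim(video)
  fd <- dim(footprints)
  stopifnot(d[2] == fd[1], d[3] == fd[2])
  fmat <- matrix(footprints, fd[1] * fd[2], fd[3])
  vm <- matrix(video, d[1], d[2] * d[3])  # frames x pixels
  sweep(vm %*% fmat, 2, colSums(fmat), "/")
}

#' Denoising report against simulation ground truth
#'
#' Compares a denoised movie with the clean movie of a
#' [simulate_voltage_movie()] bundle, on the photon scale of the noisy
#' data (the clean movie is rescaled by `poisson_scale / max(clean)` so
#' both live in the same units).
#'
#' @param bundle A `simulation_bundle`.
#' @param denoised `[T, H, W]` movie in the noisy movie's units, covering
#'   `frames`.
#' @param frames Frames the comparison uses (default: all).
#' @return List with `rmse`, `snr_db`, `psnr_db`, `pearson_r` (movie
#'   level) and `trace_pearson` (per-neuron trace correlations with the
#'   clean traces).
#' @export
eval_report <- function(bundle, denoised, frames = NULL) {
  stopifnot(inherits(bundle, "simulation_bundle"))
  if (is.null(frames)) frames <- seq_len(dim(bundle$clean)[1])
  scale <- bundle$config$poisson_scale / max(bundle$clean)
  ref <- bundle$clean[frames, , , drop = FALSE] * scale
  x <- denoised
  stopifnot(identical(dim(x), dim(ref)))
  tr_ref <- extract_traces(ref, bundle$footprints)
  tr_x <- extract_traces(x, bundle$footprints)
  trp <- vapply(seq_len(ncol(tr_ref)), function(i)
    pearson(tr_x[, i], tr_ref[, i]), numeric(1))
  list(rmse = rmse(x, ref), snr_db = snr_ref(x, ref),
       psnr_db = psnr(x, ref), pearson_r = pearson(x, ref),
       trace_pearson = trp)
}
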