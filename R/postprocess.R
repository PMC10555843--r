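# Baseline/activity decomposition, dF/F0, spike detection and spike-region
# masking.  Voltage indicators come in two polarities: positive-going
# (brighter when depolarised: zArchon1, QuasAr6a, SomArchon, ...) where
# activity = data - baseline, and negative-going (Voltron1/2) where
# activity = baseline - data.

#' Centred moving-average baseline
#'
#' Temporal moving average with an odd window; at the movie ends the
#' window shrinks symmetrically-as-possible (it is clipped to the valid
#' range), so the output has the same length as the input.
#'
#' @param x Numeric trace, or a `[T, H, W]` movie (the average runs along
#'   time for every pixel).
#' @param window_frames Odd window length in frames.
#' @return Baseline of the same shape.
#' @export
moving_average_baseline <- function(x, window_frames) {
  window_frames <- as.integer(window_frames)
  if (window_frames %% 2L == 0L) stop("window must be odd")
  if (window_frames < 1L) stop("window must be >= 1")
  ma1 <- function(v) {
    t_n <- length(v)
    if (window_frames > t_n) stop("window longer than the trace")
    h <- (window_frames - 1L) %/% 2L
    cs <- c(0, cumsum(v))
    lo <- pmax(seq_len(t_n) - h, 1L)
    hi <- pmin(seq_len(t_n) + h, t_n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  if (is.null(dim(x))) return(ma1(x))
  d <- dim(x)
  stopifnot(length(d) == 3)
  m <- matrix(x, d[1], d[2] * d[3])
  h <- (window_frames - 1L) %/% 2L
  cs <- rbind(0, apply(m, 2, cumsum))
  lo <- pmax(seq_len(d[1]) - h, 1L)
  hi <- pmin(seq_len(d[1]) + h, d[1])
  out <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
    (hi - lo + 1L)
  array(out, d)
}

#' Default moving-average window
#'
#' Half a second of frames, forced odd.
#' @param frame_rate Hz.
#' @export
default_baseline_window <- function(frame_rate) {
  w <- max(1L, round(0.5 * frame_rate))
  as.integer(if (w %% 2L == 0L) w + 1L else w)
}

#' Least-squares B-spline baseline
#'
#' Fits a spline with `n_knots` interior knots (equally spaced in time) by
#' least squares and evaluates it at every frame; used for photobleaching
#' correction where the baseline is smooth and monotone-ish.
#'
#' @param trace Numeric trace.
#' @param n_knots Number of interior knots (default: one per second).
#' @param degree Spline degree (default cubic).
#' @param frame_rate Frames per second, used only for the default knot
#'   spacing.
#' @return Fitted baseline of the same length.
#' @export
bspline_baseline <- function(trace, n_knots = NULL, degree = 3L,
                             frame_rate = NULL) {
  t_n <- length(trace)
  if (is.null(n_knots)) {
    if (is.null(frame_rate))
      stop("supply n_knots or frame_rate for the default knot spacing")
    n_knots <- max(1L, floor(t_n / frame_rate))
  }
  if (t_n <= degree + n_knots)
    stop("underdetermined fit: need length(trace) > degree + n_knots")
  tt <- seq_len(t_n)
  knots <- seq(1, t_n, length.out = n_knots + 2L)[-c(1L, n_knots + 2L)]
  basis <- splines::bs(tt, knots = knots, degree = degree, intercept = TRUE)
  fit <- stats::lm.fit(basis, trace)
  as.numeric(basis %*% fit$coefficients)
}

#' Baseline/activity decomposition
#'
#' Splits a trace or movie into a slow baseline and the polarity-signed
#' activity: `activity = data - baseline` for positive-going indicators
#' and `activity = baseline - data` for negative-going ones, so the
#' decomposition is lossless in both cases.
#'
#' @param data Trace or `[T, H, W]` movie.
#' @param method `"moving_average"` or `"bspline"` (traces only).
#' @param polarity `"positive_going"` or `"negative_going"`.
#' @param window_frames Moving-average window (odd); defaults to
#'   [default_baseline_window()] when `frame_rate` is given.
#' @param frame_rate Hz, for default parameters.
#' @param ... Passed to [bspline_baseline()].
#' @return List with `baseline`, `activity`, `polarity`, `method`.
#' @export
decompose_baseline <- function(data,
                               method = c("moving_average", "bspline"),
                               polarity = c("positive_going",
                                            "negative_going"),
                               window_frames = NULL, frame_rate = NULL,
                               ...) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  if (method == "moving_average") {
    if (is.null(window_frames)) {
      if (is.null(frame_rate))
        stop("supply window_frames or frame_rate")
      window_frames <- default_baseline_window(frame_rate)
    }
    baseline <- moving_average_baseline(data, window_frames)
  } else {
    if (!is.null(dim(data)))
      stop("bspline baseline operates on traces")
    baseline <- bspline_baseline(data, frame_rate = frame_rate, ...)
  }
  activity <- if (polarity == "positive_going") data - baseline
              else baseline - data
  list(baseline = baseline, activity = activity, polarity = polarity,
       method = method)
}

#' dF/F0 from a trace and its baseline
#'
#' `(F - F0) / F0`, sign-flipped for negative-going indicators so that
#' spikes are positive deflections.
#'
#' @param trace Fluorescence trace.
#' @param baseline Baseline `F0`, strictly positive.
#' @param polarity Indicator polarity.
#' @return dF/F0 trace.
#' @export
compute_dff <- function(trace, baseline,
                        polarity = c("positive_going", "negative_going")) {
  polarity <- match.arg(polarity)
  if (any(baseline <= 0)) stop("baseline must be positive everywhere")
  polarity_sign(polarity) * (trace - baseline) / baseline
}

#' Detect spikes in a dF/F0 trace
#'
#' A frame is a spike if its dF/F0 exceeds the threshold and is a strict
#' local maximum (greater than both neighbours); for plateaus of equal
#' values the first frame is called. The first and last frames are never
#' called (no two-sided neighbourhood).
#'
#' @param dff dF/F0 trace.
#' @param threshold Hard threshold (> 0).
#' @return List with `frames` (sorted integer vector) and `threshold`.
#' @export
detect_spikes <- function(dff, threshold) {
  stopifnot(threshold > 0)
  t_n <- length(dff)
  frames <- integer(0)
  if (t_n >= 3) {
    r <- rle(dff)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nr <- length(r$values)
    for (i in seq_len(nr)) {
      if (r$values[i] <= threshold) next
      if (i == 1L || i == nr) next
      if (r$values[i - 1L] < r$values[i] && r$values[i + 1L] < r$values[i])
        frames <- c(frames, starts[i])
    }
  }
  list(frames = frames, threshold = threshold)
}

#' Mask subthreshold frames
#'
#' `TRUE` marks frames outside every `spike +/- pad_frames` window;
#' overlapping windows merge.
#'
#' @param n_frames Trace length (or a trace, whose length is used).
#' @param spikes Integer spike frames (or a [detect_spikes()] result).
#' @param pad_frames Non-negative padding.
#' @return Logical vector of length `n_frames`.
#' @export
mask_spike_regions <- function(n_frames, spikes, pad_frames) {
  stopifnot(pad_frames >= 0)
  if (is.list(spikes)) spikes <- spikes$frames
  if (length(n_frames) > 1) n_frames <- length(n_frames)
  mask <- rep(TRUE, n_frames)
  for (s in spikes) {
    lo <- max(1L, s - pad_frames)
    hi <- min(n_frames, s + pad_frames)
    mask[lo:hi] <- FALSE
  }
  mask
}

#' Default subthreshold padding: 10 ms worth of frames
#' @param frame_rate Hz.
#' @export
default_spike_pad <- function(frame_rate) {
  max(1L, as.integer(round(0.010 * frame_rate)))
}
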