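# Movie, trace and configuration I/O.
#
# Movies are multi-page TIFF stacks mapped to [T, H, W] arrays (volumetric
# z-stacks map z to the time axis).  Reading goes through the tiff package
# and accepts 8/16-bit unsigned integer or 32-bit float single-channel
# stacks, promoting everything to double with values preserved exactly.
# Writing emits uncompressed little-endian 32-bit float pages directly
# (the tiff package only stores values in [0, 1], which would destroy
# fluorescence intensities).

#' Read a movie from a multi-page TIFF
#'
#' @param path TIFF file with single-channel 8/16-bit integer or 32-bit
#'   float pages.
#' @return `[T, H, W]` numeric array; integer data keep their original
#'   values (no rescaling).
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e)
                      stop("cannot parse TIFF '", path, "': ",
                           conditionMessage(e)))
  if (!length(pages)) stop("empty TIFF: ", path)
  mats <- lapply(pages, function(pg) {
    if (length(dim(pg)) == 3L)
      stop("unsupported format: multi-channel/RGB TIFF; supply a ",
           "single-channel grayscale stack")
    fmt <- attr(pg, "sample.format")
    bps <- attr(pg, "bits.per.sample")
    if (!is.null(fmt) && fmt == "float") return(pg)
    if (is.null(bps)) bps <- 16L
    pg * (2^bps - 1)  # undo readTIFF's [0,1] scaling of integer data
  })
  d1 <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d1), logical(1))))
    stop("pages differ in size")
  out <- array(0, c(length(mats), d1[1], d1[2]))
  for (t in seq_along(mats)) out[t, , ] <- mats[[t]]
  out
}

#' Write a movie as a 32-bit float multi-page TIFF
#'
#' Uncompressed little-endian IEEE float pages; values are stored exactly
#' at float32 precision, so write/read round-trips are bit-exact for data
#' already representable in 32-bit floats.
#'
#' @param video `[T, H, W]` numeric array.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(video, path) {
  d <- dim(video)
  stopifnot(length(d) == 3)
  h <- d[2]; w <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  wle <- function(x, size) writeBin(as.integer(x), con, size = size,
                                    endian = "little")
  writeBin(charToRaw("II"), con); wle(42L, 2)
  data_bytes <- 4L * h * w
  # per page: [pixel data][IFD]; IFD = count + 10 tags + next pointer
  ifd_bytes <- 2L + 10L * 12L + 4L
  page_bytes <- data_bytes + ifd_bytes
  first_off <- 8L
  wle(first_off + data_bytes, 4)  # offset of first IFD
  tag <- function(id, type, count, value) {
    wle(id, 2); wle(type, 2); wle(count, 4); wle(value, 4)
  }
  for (t in seq_len(d[1])) {
    base <- first_off + (t - 1L) * page_bytes
    writeBin(as.numeric(t(video[t, , ])), con, size = 4, endian = "little")
    wle(10L, 2)                      # number of tags
    tag(256L, 3L, 1L, w)             # ImageWidth
    tag(257L, 3L, 1L, h)             # ImageLength
    tag(258L, 3L, 1L, 32L)           # BitsPerSample
    tag(259L, 3L, 1L, 1L)            # Compression: none
    tag(262L, 3L, 1L, 1L)            # Photometric: BlackIsZero
    tag(273L, 4L, 1L, base)          # StripOffsets
    tag(277L, 3L, 1L, 1L)            # SamplesPerPixel
    tag(278L, 3L, 1L, h)             # RowsPerStrip
    tag(279L, 4L, 1L, data_bytes)    # StripByteCounts
    tag(339L, 3L, 1L, 3L)            # SampleFormat: IEEE float
    nxt <- if (t < d[1]) base + page_bytes + data_bytes else 0L
    wle(nxt, 4)
  }
  invisible(path)
}

#' Write / read traces as CSV
#'
#' Column `frame` plus one column per trace.
#'
#' @param traces Matrix `[T, n]` (a vector is treated as one trace).
#' @param path CSV file.
#' @export
write_traces <- function(traces, path) {
  if (is.null(dim(traces))) traces <- matrix(traces, ncol = 1)
  df <- data.frame(frame = seq_len(nrow(traces)), traces)
  names(df) <- c("frame", paste0("trace", seq_len(ncol(traces))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path)
  as.matrix(df[, -1, drop = FALSE])
}

#' Save a simulation bundle to a directory
#'
#' Movies go to 32-bit float TIFFs, traces/spikes/trajectory to CSV
#' sidecars, and the configuration to a YAML file.
#'
#' @param bundle A `simulation_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "simulation_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(bundle$clean, file.path(dir, "clean.tif"))
  write_stack(bundle$noisy, file.path(dir, "noisy.tif"))
  fp <- bundle$footprints
  write_stack(aperm(fp, c(3, 1, 2)), file.path(dir, "footprints.tif"))
  write_traces(t(bundle$clean_traces), file.path(dir, "clean_traces.csv"))
  sp <- data.frame(
    neuron = rep(seq_along(bundle$spikes),
                 vapply(bundle$spikes, length, integer(1))),
    frame = unlist(bundle$spikes))
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  if (!is.null(bundle$trajectory))
    utils::write.csv(data.frame(frame = seq_along(bundle$trajectory$dx),
                                dx = bundle$trajectory$dx,
                                dy = bundle$trajectory$dy),
                     file.path(dir, "trajectory.csv"), row.names = FALSE)
  cfg <- bundle$config
  cfg$bleach_tau <- if (is.null(cfg$bleach_tau)) NA else cfg$bleach_tau
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
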