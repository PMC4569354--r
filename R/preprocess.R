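#' Excise intervals around event markers from a continuous recording
#'
#' Removes every sample within `pad_s` seconds of any marker (e.g.
#' epileptiform discharge times) and returns the remaining contiguous clean
#' segments. Overlapping exclusion windows merge. All interval arithmetic is
#' half-open `[start, end)` in 0-based samples.
#'
#' @param x Continuous data, channels x samples matrix.
#' @param fs Sampling rate in Hz.
#' @param markers Data frame with columns `time_s` (seconds from recording
#'   start, ascending) and optionally `label`; may have zero rows.
#' @param pad_s Exclusion halfwidth in seconds (default 10).
#' @return A list of segments; each has `data` (channels x samples),
#'   `start_s`, `end_s` (half-open, seconds).
#' @export
exclude_marked_intervals <- function(x, fs, markers, pad_s = 10) {
  stopifnot(is.matrix(x), fs > 0, pad_s >= 0)
  n <- ncol(x)
  dur <- n / fs
  times <- if (is.null(markers) || nrow(markers) == 0) numeric(0) else markers$time_s
  if (length(times) && (any(times < 0) || any(times > dur)))
    stop("marker time outside recording duration")
  keep <- rep(TRUE, n)
  for (t in times) {
    lo <- max(0L, ceiling((t - pad_s) * fs))
    hi <- min(n, floor((t + pad_s) * fs))      # exclusive upper bound
    if (hi > lo) keep[(lo + 1L):hi] <- FALSE   # keep is 1-based
  }
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths        # 0-based start of each run
  segs <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    idx <- (starts[i] + 1L):ends[i]
    segs[[length(segs) + 1L]] <- list(
      data = x[, idx, drop = FALSE],
      start_s = starts[i] / fs, end_s = ends[i] / fs)
  }
  segs
}

#' Randomly select non-overlapping fixed-length epochs from clean segments
#'
#' Each clean segment is tiled into non-overlapping epochs from its start;
#' `n_epochs` tiles are then drawn uniformly without replacement and
#' returned in randomized order. The draw is fully determined by `seed`.
#'
#' @param segments A list of clean segments (from
#'   [exclude_marked_intervals()]), or a single channels x samples matrix.
#' @param fs Sampling rate in Hz.
#' @param epoch_length_s Epoch length in seconds (default 10).
#' @param n_epochs Number of epochs to select (default 30).
#' @param seed Mandatory selection seed.
#' @param geometry Optional `sensor_array` carried into the result.
#' @return An `epoched_recording` (`data` epochs x channels x samples, `fs`,
#'   `epoch_length_s`) with attribute `epoch_start_s` giving each epoch's
#'   start time in the original recording.
#' @export
segment_epochs <- function(segments, fs, epoch_length_s = 10, n_epochs = 30,
                           seed, geometry = NULL) {
  if (is.matrix(segments))
    segments <- list(list(data = segments, start_s = 0,
                          end_s = ncol(segments) / fs))
  if (missing(seed)) stop("a selection seed is required")
  len <- round(epoch_length_s * fs)
  # candidate epoch starts: tile each segment from its beginning
  cand <- list()
  for (seg in segments) {
    n_tiles <- floor(ncol(seg$data) / len)
    if (n_tiles < 1) next
    for (t in seq_len(n_tiles))
      cand[[length(cand) + 1L]] <- list(seg = seg, offset = (t - 1L) * len)
  }
  if (length(cand) < n_epochs) {
    avail <- length(cand) * epoch_length_s
    stop(sprintf("insufficient clean data: need %.1f s, only %.1f s available (deficit %.1f s)",
                 n_epochs * epoch_length_s, avail,
                 n_epochs * epoch_length_s - avail))
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  pick <- sample(length(cand), n_epochs)
  n_chan <- nrow(segments[[1]]$data)
  data <- array(0, dim = c(n_epochs, n_chan, len))
  starts <- numeric(n_epochs)
  for (i in seq_along(pick)) {
    ci <- cand[[pick[i]]]
    data[i, , ] <- ci$seg$data[, (ci$offset + 1L):(ci$offset + len), drop = FALSE]
    starts[i] <- ci$seg$start_s + ci$offset / fs
  }
  structure(list(data = data, fs = fs, epoch_length_s = epoch_length_s,
                 geometry = geometry, epoch_start_s = starts),
            class = "epoched_recording")
}

#' Downsample an epoched recording
#'
#' Anti-alias filtering followed by band-limited interpolation at the new
#' sample times, so arbitrary (non-integer) rate ratios such as
#' 3906.2 -> 409.6 Hz are handled exactly. The anti-alias stage is a long
#' linear-phase FIR low-pass applied forward-backward (zero net phase) with
#' its passband edge at 0.8x the target Nyquist frequency; content between
#' the passband edge and the old Nyquist is strongly attenuated. Output
#' epochs have `round(epoch_length_s * target_fs)` samples.
#'
#' @param rec An `epoched_recording`.
#' @param target_fs Target rate in Hz (default 409.6); must be below `fs`.
#' @param n_taps FIR length of the anti-alias filter (default 400).
#' @return The resampled `epoched_recording`.
#' @export
downsample <- function(rec, target_fs = 409.6, n_taps = 400) {
  stopifnot(inherits(rec, "epoched_recording"))
  if (target_fs >= rec$fs) stop("target_fs must be below the current sampling rate")
  cutoff <- 0.4 * target_fs / (rec$fs / 2)   # 0.8 x target Nyquist
  fir <- signal::fir1(n_taps, cutoff, type = "low")
  n_out <- round(rec$epoch_length_s * target_fs)
  t_out <- (0:(n_out - 1)) / target_fs
  d <- dim(rec$data)
  t_in <- (0:(d[3] - 1)) / rec$fs
  out <- array(0, dim = c(d[1], d[2], n_out))
  for (e in seq_len(d[1])) for (c in seq_len(d[2])) {
    y <- signal::filtfilt(fir, rec$data[e, c, ])
    out[e, c, ] <- stats::spline(t_in, y, xout = pmin(t_out, max(t_in)))$y
  }
  res <- rec
  res$data <- out
  res$fs <- target_fs
  res
}

#' Zero-phase Butterworth band-pass filter
#'
#' Each epoch and channel is demeaned and filtered forward-backward with a
#' Butterworth band-pass, giving zero phase distortion and squared
#' magnitude response.
#'
#' @param rec An `epoched_recording`.
#' @param low,high Band edges in Hz (defaults 0.5 and 70).
#' @param order Butterworth order of the underlying one-pass design
#'   (default 4; the effective order doubles in the two-pass application).
#' @return The filtered `epoched_recording`.
#' @export
bandpass <- function(rec, low = 0.5, high = 70, order = 4) {
  stopifnot(inherits(rec, "epoched_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  d <- dim(rec$data)
  out <- rec$data
  for (e in seq_len(d[1])) for (c in seq_len(d[2])) {
    x <- rec$data[e, c, ]
    out[e, c, ] <- signal::filtfilt(bf, x - mean(x))
  }
  res <- rec
  res$data <- out
  res
}

#' Flag high-amplitude epochs
#'
#' A simple stand-in for visual artifact review: flags epochs whose maximum
#' absolute amplitude exceeds `k` times the median absolute deviation of
#' the whole recording.
#'
#' @param rec An `epoched_recording`.
#' @param k MAD multiplier (default 10).
#' @return Logical vector, `TRUE` for epochs to reject.
#' @export
flag_artifact_epochs <- function(rec, k = 10) {
  stopifnot(inherits(rec, "epoched_recording"))
  m <- stats::mad(as.numeric(rec$data))
  apply(rec$data, 1, function(ep) max(abs(ep)) > k * m)
}
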