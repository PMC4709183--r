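#' P300 analysis window
#'
#' The canonical window in which the P300 deflection is sought.
#'
#' @param start,end Window bounds in ms post-stimulus (default 220-500).
#' @return List of class `p300_window`.
#' @export
p300_window <- function(start = 220, end = 500) {
  if (start < 0 || start >= end)
    stop("need 0 <= start < end", call. = FALSE)
  structure(list(start = start, end = end), class = "p300_window")
}

#' Time-locked average ERP
#'
#' Arithmetic mean over the selected trials, then over the selected
#' channels, yielding a single waveform on the epoch time axis.
#'
#' @param epochs An `epoch_set` (normally after [zscore_baseline()]).
#' @param condition `"target"`, `"nontarget"`, or `NULL` for all trials.
#' @param channels Channel labels or indices to average; `NULL` for all.
#' @param trials Optional additional trial subset (indices into
#'   `epochs`), intersected with `condition`.
#' @return An `erp_waveform`: `values`, `time_ms`, `n_trials_averaged`,
#'   `condition`.
#' @export
average_erp <- function(epochs, condition = NULL, channels = NULL,
                        trials = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- seq_len(dim(epochs$data)[1])
  if (!is.null(trials)) sel <- sel[trials]
  if (!is.null(condition)) {
    want <- condition == "target"
    sel <- sel[epochs$events$is_target[sel] == want]
  }
  if (length(sel) < 1)
    stop("no trials match the requested condition", call. = FALSE)
  if (is.null(channels)) {
    chi <- seq_along(epochs$channel_labels)
  } else if (is.character(channels)) {
    chi <- match(channels, epochs$channel_labels)
    if (anyNA(chi)) stop("unknown channel label", call. = FALSE)
  } else chi <- channels
  if (length(chi) < 1) stop("empty channel selection", call. = FALSE)
  sub <- epochs$data[sel, chi, , drop = FALSE]
  values <- apply(sub, 3, mean)
  structure(list(values = values, time_ms = epochs$time_ms,
                 n_trials_averaged = length(sel),
                 condition = condition %||% "all"),
            class = "erp_waveform")
}

#' Peak-picking feature
#'
#' Difference between the highest point inside the P300 window and the
#' lowest point in the post-stimulus region before it
#' (`[0, window$start)` ms). The pre-window minimum is taken
#' unconstrained; if it is positive (no negative-going deflection was
#' found) the result carries attribute `pre_min_positive = TRUE`.
#'
#' @param erp An [average_erp()] waveform.
#' @param window A [p300_window()].
#' @return Scalar feature value.
#' @export
peak_picking <- function(erp, window = p300_window()) {
  stopifnot(inherits(erp, "erp_waveform"))
  t <- erp$time_ms
  in_win <- t >= window$start & t <= window$end
  pre <- t >= 0 & t < window$start
  if (!any(pre))
    stop("no samples before the P300 window to search for the negative peak",
         call. = FALSE)
  if (!any(in_win)) stop("P300 window outside the epoch", call. = FALSE)
  lo <- min(erp$values[pre])
  out <- max(erp$values[in_win]) - lo
  attr(out, "pre_min_positive") <- lo > 0
  out
}

#' Area feature
#'
#' Plain sum of the waveform samples inside the P300 window (inclusive
#' endpoints: samples with `start <= t <= end`). At 500 Hz the default
#' 220-500 ms window contains 141 samples.
#'
#' @inheritParams peak_picking
#' @return Scalar feature value.
#' @export
area_feature <- function(erp, window = p300_window()) {
  stopifnot(inherits(erp, "erp_waveform"))
  in_win <- erp$time_ms >= window$start & erp$time_ms <= window$end
  if (!any(in_win)) stop("P300 window outside the epoch", call. = FALSE)
  sum(erp$values[in_win])
}

#' Continuous wavelet transform with a complex Morlet wavelet
#'
#' L1-normalised CWT: at scale `s` the coefficient is
#' `(1/s) * integral x(t) conj(psi((t - b)/s)) dt` with the two-parameter
#' complex Morlet `psi(t) = (pi*fb)^(-1/2) exp(2i*pi*fc*t) exp(-t^2/fb)`.
#' Scales map to analysis frequencies as `f = fc / s`. With L1
#' normalisation a unit-amplitude sinusoid at an analysis frequency
#' produces coefficient magnitude 1/2 (power 1/4) at every frequency, so
#' equal-amplitude tones give equal power peaks.
#'
#' The resulting maps are descriptive output: per-trial maps are averaged
#' for display, not used as classifier features.
#'
#' @param x An `erp_waveform`, or a numeric signal (then `fs` is
#'   required).
#' @param fs Sampling rate, Hz (taken from the waveform when omitted).
#' @param freqs Analysis frequency grid, Hz, within `(0, fs/2)`.
#' @param fb Bandwidth parameter (seconds^2).
#' @param fc Wavelet center frequency, Hz.
#' @return A `tf_map`: `power` (frequencies x time), `freqs`, `time_ms`,
#'   `wavelet_params`.
#' @export
cwt_morlet <- function(x, fs = NULL, freqs = seq(1, 12, by = 0.5),
                       fb = 2, fc = 1) {
  if (inherits(x, "erp_waveform")) {
    time_ms <- x$time_ms
    fs <- 1000 / diff(time_ms[1:2])
    sig <- x$values
  } else {
    if (is.null(fs)) stop("fs required for a bare numeric signal",
                          call. = FALSE)
    sig <- as.numeric(x)
    time_ms <- (seq_along(sig) - 1) / fs * 1000
  }
  if (fb <= 0 || fc <= 0) stop("fb and fc must be positive", call. = FALSE)
  if (any(freqs <= 0 | freqs >= fs / 2))
    stop("analysis frequencies must lie in (0, fs/2)", call. = FALSE)
  n <- length(sig)
  power <- matrix(0, length(freqs), n)
  dt <- 1 / fs
  for (k in seq_along(freqs)) {
    s <- fc / freqs[k]
    half <- ceiling(4 * s * sqrt(fb / 2) * fs)
    tt <- (-half:half) * dt / s
    psi <- (pi * fb)^(-0.5) * exp(2i * pi * fc * tt) * exp(-tt^2 / fb)
    # correlation with conj(psi) == convolution with its time-reverse,
    # which on this symmetric grid is psi itself
    kern <- psi * dt / s
    nf <- nextn(n + length(kern) - 1)
    coef <- fft(fft(c(sig, rep(0, nf - n))) *
                  fft(c(kern, rep(0, nf - length(kern)))),
                inverse = TRUE) / nf
    power[k, ] <- Mod(coef[(half + 1):(half + n)])^2
  }
  structure(list(power = power, freqs = freqs, time_ms = time_ms,
                 wavelet_params = c(fb = fb, fc = fc)),
            class = "tf_map")
}

#' Export an ERP feature table to CSV
#'
#' @param features A [build_features()] table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
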