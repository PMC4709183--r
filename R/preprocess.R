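#' Continuous multichannel EEG recording
#'
#' @param data Numeric matrix, channels x samples, microvolts.
#' @param fs Sampling rate, Hz.
#' @param channel_labels One name per channel (10/20 labels for real
#'   montages).
#' @param events Flash event data frame (see [build_schedule()]): columns
#'   `onset_s`, `stimulus_id`, `is_target`, `character_index`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels, events = NULL) {
  data <- as.matrix(data)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (length(channel_labels) != nrow(data))
    stop("need one channel label per data row", call. = FALSE)
  if (!is.null(events)) {
    dur <- ncol(data) / fs
    if (any(events$onset_s < 0 | events$onset_s > dur))
      stop("event onsets must lie within the recording duration",
           call. = FALSE)
  }
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.null(x$events)) cat(sprintf(", %d events", nrow(x$events)))
  cat("\n")
  invisible(x)
}

#' Design a linear-phase band-pass FIR filter
#'
#' Windowed-sinc (Hamming) design via [signal::fir1()], with the tap count
#' set by the requested transition width (~3.3 / transition seconds of
#' filter, the Hamming main-lobe rule), rounded to an odd length so the
#' group delay is an integer number of samples.
#'
#' @param fs Sampling rate, Hz.
#' @param low,high Band edges, Hz (`0 < low < high < fs/2`).
#' @param transition Transition band width, Hz.
#' @return Numeric vector of filter taps.
#' @export
design_bandpass <- function(fs, low = 1, high = 12, transition = 1) {
  if (low <= 0 || low >= high || high >= fs / 2)
    stop("need 0 < low < high < fs/2", call. = FALSE)
  n_taps <- ceiling(3.3 * fs / transition)
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  as.numeric(signal::fir1(n_taps - 1, c(low, high) / (fs / 2),
                          type = "pass"))
}

# Zero-phase application of a linear-phase FIR: FFT convolution with
# mirror padding, then group-delay compensation. x is samples x channels.
fir_apply <- function(x, taps) {
  n <- nrow(x)
  len <- length(taps)
  d <- (len - 1) %/% 2
  if (n <= d + 1)
    stop("recording shorter than the filter; not enough samples to filter",
         call. = FALSE)
  pad <- d
  front <- x[(pad + 1):2, , drop = FALSE]
  back <- x[(n - 1):(n - pad), , drop = FALSE]
  xp <- rbind(front, x, back)
  np <- nrow(xp)
  nf <- nextn(np + len - 1)
  B <- fft(c(taps, rep(0, nf - len)))
  X <- mvfft(rbind(xp, matrix(0, nf - np, ncol(xp))))
  y <- Re(mvfft(X * B, inverse = TRUE)) / nf
  y[(pad + d + 1):(pad + d + n), , drop = FALSE]
}

#' Band-pass filter a recording (zero-phase FIR)
#'
#' Applies the 1-12 Hz (by default) linear-phase FIR per channel with
#' group-delay compensation, so filtering introduces no latency shift into
#' ERP windows. Filtering is done on the continuous recording, before
#' epoching, to keep filter edge transients out of the epochs.
#'
#' @param rec An [eeg_recording()].
#' @inheritParams design_bandpass
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, low = 1, high = 12, transition = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  taps <- design_bandpass(rec$fs, low, high, transition)
  rec$data <- t(fir_apply(t(rec$data), taps))
  rec$band <- c(low, high)
  rec
}

#' Symmetric fixed-point independent component analysis
#'
#' Whitens the data and runs symmetric FastICA-style fixed-point
#' iterations with the tanh contrast. Any decomposition producing an
#' unmixing matrix fits the blink-rejection contract; this one is compact
#' and has no external dependencies.
#'
#' @param x Numeric matrix, channels x samples.
#' @param n_comp Number of components (default: all channels).
#' @param max_iter,tol Iteration controls.
#' @param seed Optional seed for the random orthogonal start.
#' @return List of class `ica_decomposition`: `S` (components x samples),
#'   `A` (mixing, channels x components), `W` (unmixing), `means`,
#'   `converged`, `iterations`.
#' @export
fast_ica <- function(x, n_comp = nrow(x), max_iter = 200, tol = 1e-4,
                     seed = NULL) {
  x <- as.matrix(x)
  nch <- nrow(x)
  ns <- ncol(x)
  if (n_comp > nch) stop("n_comp cannot exceed channel count", call. = FALSE)
  means <- rowMeans(x)
  xc <- x - means
  cv <- tcrossprod(xc) / ns
  eg <- eigen(cv, symmetric = TRUE)
  cond <- eg$values[1] / eg$values[nch]
  if (!is.finite(cond) || eg$values[nch] <= 0 || cond > 1e12)
    stop(sprintf(
      "rank-deficient input: covariance condition number %.3g", cond),
      call. = FALSE)
  K <- diag(1 / sqrt(eg$values[1:n_comp]), n_comp) %*%
    t(eg$vectors[, 1:n_comp, drop = FALSE])
  z <- K %*% xc
  with_seed(seed, {
    W <- matrix(rnorm(n_comp^2), n_comp)
    W <- svd(W)$u %*% t(svd(W)$v)
    sym_decor <- function(W) {
      s <- svd(W)
      s$u %*% t(s$v)
    }
    W <- sym_decor(W)
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      wz <- W %*% z
      g <- tanh(wz)
      gp <- rowMeans(1 - g^2)
      W1 <- (g %*% t(z)) / ns - diag(gp, n_comp) %*% W
      W1 <- sym_decor(W1)
      delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
      W <- W1
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    U <- W %*% K               # unmixing, comp x channels
    A <- MASS_ginv(U)          # mixing, channels x comp
    structure(list(S = U %*% xc, A = A, W = U, means = means,
                   converged = converged, iterations = it),
              class = "ica_decomposition")
  })
}

# Moore-Penrose pseudoinverse (SVD), enough for the square/overdetermined
# unmixing matrices used here.
MASS_ginv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Remove blink components by frontal weight ratio
#'
#' Decomposes the recording into independent components and zeroes every
#' component whose mean absolute mixing weight over the frontal channels
#' exceeds `ratio_threshold` times its mean absolute weight over the
#' remaining channels -- the automatic signature of an ocular source,
#' which projects overwhelmingly to Fp1/Fp2. The cleaned recording is the
#' back-projection of the remaining components; channel count and duration
#' are unchanged.
#'
#' @param rec An [eeg_recording()].
#' @param frontal_labels Frontal channel names (default Fp1, Fp2).
#' @param ratio_threshold Frontal/other weight ratio above which a
#'   component is rejected; `Inf` disables rejection (identity
#'   transform).
#' @param seed Passed to [fast_ica()].
#' @param ... Further arguments to [fast_ica()].
#' @return List: `recording` (cleaned), `n_rejected`, `ratios` (one per
#'   component).
#' @export
remove_blink_components <- function(rec, frontal_labels = c("Fp1", "Fp2"),
                                    ratio_threshold = 3, seed = NULL,
                                    ...) {
  stopifnot(inherits(rec, "eeg_recording"))
  fr <- match(frontal_labels, rec$channel_labels)
  if (anyNA(fr)) stop("frontal channel not found in recording",
                      call. = FALSE)
  if (length(rec$channel_labels) - length(fr) < 2)
    stop("need at least 2 non-frontal channels", call. = FALSE)
  if (!is.finite(ratio_threshold))
    return(list(recording = rec, n_rejected = 0L,
                ratios = rep(NA_real_, nrow(rec$data))))
  ica <- fast_ica(rec$data, seed = seed, ...)
  others <- setdiff(seq_len(nrow(rec$data)), fr)
  ratios <- apply(ica$A, 2, function(a)
    mean(abs(a[fr])) / mean(abs(a[others])))
  keep <- ratios <= ratio_threshold
  clean <- ica$A[, keep, drop = FALSE] %*%
    ica$S[keep, , drop = FALSE] + ica$means
  rec$data <- clean
  list(recording = rec, n_rejected = sum(!keep), ratios = ratios)
}

#' Cut stimulus-locked epochs from a continuous recording
#'
#' One epoch per flash event over the half-open window
#' `[tmin, tmax)` seconds around onset, giving exactly
#' `round((tmax - tmin) * fs)` samples per trial (500 at 500 Hz for the
#' default -200..800 ms window). Events whose window would run past the
#' recording edge are dropped with a warning and counted in the
#' `n_dropped` attribute.
#'
#' @param rec An [eeg_recording()] carrying events.
#' @param tmin,tmax Epoch window relative to flash onset, seconds.
#' @return An `epoch_set`: `data` (trials x channels x samples),
#'   `time_ms`, `fs`, `channel_labels`, and per-trial `events` metadata.
#' @export
extract_epochs <- function(rec, tmin = -0.2, tmax = 0.8) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(rec$events) || nrow(rec$events) == 0)
    stop("recording has no events to epoch", call. = FALSE)
  fs <- rec$fs
  pre <- round(-tmin * fs)
  total <- round((tmax - tmin) * fs)
  n <- ncol(rec$data)
  i0 <- round(rec$events$onset_s * fs) + 1L
  start <- i0 - pre
  end <- start + total - 1L
  ok <- start >= 1L & end <= n
  if (any(!ok))
    warning(sum(!ok), " event(s) dropped: epoch window extends past the ",
            "recording edge", call. = FALSE)
  idx <- which(ok)
  nch <- nrow(rec$data)
  data <- array(0, dim = c(length(idx), nch, total))
  for (k in seq_along(idx)) {
    data[k, , ] <- rec$data[, start[idx[k]]:end[idx[k]]]
  }
  ev <- rec$events[idx, , drop = FALSE]
  rownames(ev) <- NULL
  structure(
    list(data = data,
         time_ms = (seq_len(total) - 1 - pre) / fs * 1000,
         fs = fs, channel_labels = rec$channel_labels, events = ev,
         normalized = FALSE),
    class = "epoch_set",
    n_dropped = sum(!ok))
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples @ %g Hz [%g, %g) ms%s\n",
    d[1], d[2], d[3], x$fs, x$time_ms[1],
    x$time_ms[length(x$time_ms)] + 1000 / x$fs,
    if (isTRUE(x$normalized)) ", baseline z-scored" else ""))
  cat(sprintf("  %d target / %d non-target trials\n",
              sum(x$events$is_target), sum(!x$events$is_target)))
  invisible(x)
}

#' Baseline z-score normalization of epochs
#'
#' Per trial and channel, every sample is transformed to
#' `(x - mean_baseline) / sd_baseline` using the pre-stimulus baseline
#' window, so the whole epoch (baseline and response) is expressed in
#' baseline standard-deviation units and the response window is directly
#' comparable across trials with different baseline variability.
#'
#' @param epochs An [extract_epochs()] result.
#' @param baseline Baseline window in ms, default `c(-200, 0)`
#'   (half-open: samples with `baseline[1] <= t < baseline[2]`).
#' @return The normalized `epoch_set`.
#' @export
zscore_baseline <- function(epochs, baseline = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  bi <- epochs$time_ms >= baseline[1] & epochs$time_ms < baseline[2]
  if (sum(bi) < 2)
    stop("baseline window contains fewer than 2 samples", call. = FALSE)
  d <- dim(epochs$data)
  nb <- sum(bi)
  bm <- matrix(epochs$data[, , bi], nrow = d[1] * d[2], ncol = nb)
  mu <- rowMeans(bm)
  sdv <- sqrt(rowSums((bm - mu)^2) / (nb - 1))
  if (any(sdv == 0)) {
    bad <- which(sdv == 0)[1]
    stop(sprintf(
      "degenerate input: zero baseline variance in trial %d, channel %s",
      (bad - 1) %% d[1] + 1,
      epochs$channel_labels[(bad - 1) %/% d[1] + 1]), call. = FALSE)
  }
  epochs$data <- (epochs$data - array(mu, d)) / array(sdv, d)
  epochs$normalized <- TRUE
  epochs
}

#' Select trials of an epoch set
#'
#' @param epochs An `epoch_set`.
#' @param trials Integer or logical trial index.
#' @return The subset `epoch_set`.
#' @export
subset_trials <- function(epochs, trials) {
  stopifnot(inherits(epochs, "epoch_set"))
  epochs$data <- epochs$data[trials, , , drop = FALSE]
  epochs$events <- epochs$events[trials, , drop = FALSE]
  rownames(epochs$events) <- NULL
  epochs
}
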