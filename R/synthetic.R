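#' Standard 19-channel 10/20 montage labels
#' @return Character vector of the 19 electrode labels.
#' @export
channels_1020 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "C3", "C4", "P3", "P4",
    "O1", "O2", "T3", "T4", "T5", "T6", "Fz", "Pz", "Cz")
}

#' Default coupled-channel pairs of the simulator
#'
#' All pairs among a posterior channel clique (P3, P4, O1, O2, Pz, Cz by
#' default) -- a closed set, so the ground-truth edge list equals the
#' configured pairs.
#'
#' @param channels Channel labels to couple pairwise.
#' @return Two-column character matrix of channel pairs.
#' @export
default_coupling_pairs <- function(channels = c("P3", "P4", "O1", "O2",
                                                "Pz", "Cz")) {
  p <- t(combn(channels, 2))
  colnames(p) <- c("ch_i", "ch_j")
  p
}

#' Simulation configuration for a synthetic speller session
#'
#' Bundles the stimulus schedule with the signal model used by
#' [simulate_session()]: 1/f (or white) background noise on every channel;
#' on target flashes only, (i) a P300-like evoked template on
#' `erp_channels` (positive deflection at `erp_latency` preceded by a
#' smaller negativity) and (ii) a band-limited oscillatory burst whose
#' phase is shared, up to independent per-channel jitter of sd
#' `phase_jitter_sd` radians, by the channels of each coupled pair. With
#' jitter 0 the coupled channels oscillate in perfect phase lock; larger
#' jitter weakens the phase-locking value downstream.
#'
#' Channels connected through `coupling_pairs` share one common phase
#' process per connected component, so all pairs within a component are
#' coupled; `true_edges` in the returned ground truth is that closure. The
#' default coupling set is already a clique (6 posterior channels), for
#' which `true_edges` equals `coupling_pairs`.
#'
#' @param plan A [build_schedule()] session plan; default: 5 x 6 matrix,
#'   14 characters, 15 repetitions, 250 ms ISI.
#' @param channel_labels Electrode names; defaults to the 19-channel 10/20
#'   set.
#' @param fs Sampling rate, Hz.
#' @param erp_amplitude Peak amplitude of the evoked template, microvolts.
#' @param erp_latency Latency of the positive peak, ms post-stimulus.
#' @param erp_width Full width at half maximum of the positive peak, ms.
#' @param erp_channels Channels receiving the evoked template.
#' @param coupling_pairs Two-column matrix of channel-label pairs coupled
#'   during target epochs; `NULL` or 0-row for no coupling.
#' @param coupling_amplitude Amplitude of the oscillatory burst,
#'   microvolts.
#' @param phase_jitter_sd Per-channel, per-trial phase jitter sd, radians.
#' @param carrier_band Frequency range (Hz, within 1-12) of the burst
#'   carrier; each trial draws its carrier uniformly from this band.
#' @param burst_window Support of the Hann-windowed burst, ms
#'   post-stimulus.
#' @param noise_sd Background noise standard deviation, microvolts.
#' @param noise_model `"one_over_f"` (default) or `"white"`.
#' @param seed Integer RNG seed for reproducible sessions.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(plan = NULL,
                       channel_labels = channels_1020(),
                       fs = 500,
                       erp_amplitude = 8,
                       erp_latency = 350,
                       erp_width = 150,
                       erp_channels = c("Fz", "Cz", "Pz", "P3", "P4"),
                       coupling_pairs = default_coupling_pairs(),
                       coupling_amplitude = 10,
                       phase_jitter_sd = 0.2,
                       carrier_band = c(4, 7),
                       burst_window = c(100, 600),
                       noise_sd = 10,
                       noise_model = c("one_over_f", "white"),
                       seed = NULL) {
  if (is.null(plan))
    plan <- build_schedule(speller_matrix(), characters = 1:14,
                           seed = if (is.null(seed)) NULL else seed + 1L)
  noise_model <- match.arg(noise_model)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (phase_jitter_sd < 0)
    stop("phase_jitter_sd must be >= 0", call. = FALSE)
  if (erp_latency <= 0 || erp_latency >= 800)
    stop("erp_latency must lie inside the (0, 800) ms response window",
         call. = FALSE)
  erp_channels <- intersect(erp_channels, channel_labels)
  if (!is.null(coupling_pairs) && nrow(coupling_pairs) > 0) {
    coupling_pairs <- as.matrix(coupling_pairs)
    if (!all(coupling_pairs %in% channel_labels))
      stop("coupling_pairs must name channels in channel_labels",
           call. = FALSE)
  } else coupling_pairs <- matrix(character(0), 0, 2)
  if (carrier_band[1] < 1 || carrier_band[2] > 12 ||
      carrier_band[1] >= carrier_band[2])
    stop("carrier_band must be an increasing range within 1-12 Hz",
         call. = FALSE)
  structure(
    list(plan = plan, channel_labels = channel_labels, fs = fs,
         erp_amplitude = erp_amplitude, erp_latency = erp_latency,
         erp_width = erp_width, erp_channels = erp_channels,
         coupling_pairs = coupling_pairs,
         coupling_amplitude = coupling_amplitude,
         phase_jitter_sd = phase_jitter_sd, carrier_band = carrier_band,
         burst_window = burst_window, noise_sd = noise_sd,
         noise_model = noise_model, seed = seed),
    class = "sim_config")
}

# Connected components of the coupling graph (small n: label propagation).
coupling_components <- function(pairs, labels) {
  comp <- stats::setNames(seq_along(labels), labels)
  if (nrow(pairs) > 0) {
    repeat {
      changed <- FALSE
      for (r in seq_len(nrow(pairs))) {
        a <- pairs[r, 1]; b <- pairs[r, 2]
        m <- min(comp[a], comp[b])
        if (comp[a] != m || comp[b] != m) {
          comp[comp == comp[a] | comp == comp[b]] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  coupled <- unique(as.vector(pairs))
  split(coupled, comp[coupled])
}

# All unordered pairs within each component (the transitive closure of the
# configured coupling).
component_edges <- function(components) {
  edges <- lapply(components, function(ch) {
    if (length(ch) < 2) return(NULL)
    t(combn(sort(ch), 2))
  })
  out <- do.call(rbind, edges)
  if (is.null(out)) out <- matrix(character(0), 0, 2)
  colnames(out) <- c("ch_i", "ch_j")
  out
}

# Background noise, channels x samples. 1/f shaping is applied in the
# frequency domain (flat below 1 Hz to keep the variance finite).
gen_noise <- function(n_channels, n_samples, fs, sd_uv, model) {
  if (sd_uv <= 0) return(matrix(0, n_channels, n_samples))
  out <- matrix(0, n_channels, n_samples)
  if (model == "white") {
    out[] <- rnorm(n_channels * n_samples, sd = sd_uv)
    return(out)
  }
  k <- 0:(n_samples - 1)
  f <- pmin(k, n_samples - k) * fs / n_samples  # folded frequency axis
  shape <- 1 / sqrt(pmax(f, 1))
  shape[1] <- 0  # no DC
  for (ch in seq_len(n_channels)) {
    w <- rnorm(n_samples)
    y <- Re(fft(fft(w) * shape, inverse = TRUE)) / n_samples
    out[ch, ] <- y / sd(y) * sd_uv
  }
  out
}

# Evoked template evaluated on a millisecond grid: positive Gaussian peak
# plus a smaller preceding negativity (so peak picking has a real
# pre-window minimum to find).
erp_template <- function(t_ms, amplitude, latency, width_fwhm) {
  sd_p <- width_fwhm / (2 * sqrt(2 * log(2)))
  sd_n <- 80 / (2 * sqrt(2 * log(2)))
  amplitude * exp(-(t_ms - latency)^2 / (2 * sd_p^2)) -
    0.35 * amplitude * exp(-(t_ms - (latency - 170))^2 / (2 * sd_n^2))
}

#' Simulate a multichannel EEG speller session
#'
#' Renders the flash schedule of `config$plan` into a continuous
#' recording: background noise everywhere, plus -- on target flashes only
#' -- the evoked template on `erp_channels` and a phase-coupled
#' oscillatory burst on the coupled channels (common random-walk carrier
#' phase per coupling component, independent per-channel jitter). Fully
#' reproducible under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with elements `recording` (an [eeg_recording()]) and
#'   `truth` (class `ground_truth`: `true_edges` channel-pair matrix,
#'   `coupled_channels`, per-event `condition` labels, and the injected
#'   `erp_template` on the epoch time axis).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  plan <- config$plan
  fs <- config$fs
  labels <- config$channel_labels
  nch <- length(labels)
  n_samples <- ceiling((max(plan$events$onset_s) + 2) * fs)
  if (n_samples * nch > 5e8)
    stop("scheduled session too long to represent in memory",
         call. = FALSE)

  with_seed(config$seed, {
    data <- gen_noise(nch, n_samples, fs, config$noise_sd,
                      config$noise_model)
    comps <- coupling_components(config$coupling_pairs, labels)
    erp_idx <- match(config$erp_channels, labels)

    # burst support and Hann envelope (ms post-stimulus)
    b0 <- round(config$burst_window[1] / 1000 * fs)
    b1 <- round(config$burst_window[2] / 1000 * fs) - 1L
    off <- b0:b1
    env <- 0.5 * (1 - cos(2 * pi * seq_along(off) / (length(off) + 1)))
    t_rel <- off / fs
    walk_sd <- sqrt(1.2 / fs)  # phase diffusion 1.2 rad^2/s

    # evoked template over the post-stimulus second
    e_off <- 0:(round(0.8 * fs) - 1L)
    tmpl <- erp_template(e_off / fs * 1000, config$erp_amplitude,
                         config$erp_latency, config$erp_width)

    targets <- which(plan$events$is_target)
    for (ev in targets) {
      i0 <- round(plan$events$onset_s[ev] * fs) + 1L
      if (length(erp_idx) > 0 && config$erp_amplitude != 0) {
        seg <- i0 + e_off
        data[erp_idx, seg] <- data[erp_idx, seg] +
          rep(tmpl, each = length(erp_idx))
      }
      if (config$coupling_amplitude != 0) {
        for (chs in comps) {
          f0 <- runif(1, config$carrier_band[1], config$carrier_band[2])
          phi <- 2 * pi * f0 * t_rel + runif(1, 0, 2 * pi) +
            cumsum(rnorm(length(off), sd = walk_sd))
          seg <- i0 + off
          for (ch in chs) {
            jit <- rnorm(1, sd = config$phase_jitter_sd)
            ci <- match(ch, labels)
            data[ci, seg] <- data[ci, seg] +
              config$coupling_amplitude * env * cos(phi + jit)
          }
        }
      }
    }

    rec <- eeg_recording(data, fs, labels, plan$events)
    truth <- structure(
      list(true_edges = component_edges(comps),
           coupled_channels = sort(unique(unlist(comps))),
           condition = ifelse(plan$events$is_target, "target",
                              "nontarget"),
           erp_template = list(
             time_ms = c(seq(-round(0.2 * fs), -1) / fs * 1000,
                         e_off / fs * 1000),
             values = c(rep(0, round(0.2 * fs)), tmpl)),
           config = config),
      class = "ground_truth")
    list(recording = rec, truth = truth)
  })
}

#' Deterministic bundled test sessions
#'
#' Named presets with fixed seeds, so repeated calls return bit-identical
#' data. `"paper_like"` is a full-scale session (19 channels, 500 Hz, 14
#' characters x 15 repetitions, strong posterior coupling on target
#' trials); `"tiny"` is a 4-channel, 2-character miniature for fast smoke
#' tests.
#'
#' @param name Preset id: `"paper_like"` or `"tiny"`.
#' @return As [simulate_session()]: list with `recording` and `truth`.
#' @export
make_fixture <- function(name) {
  if (name == "paper_like") {
    cfg <- sim_config(seed = 20160111)
  } else if (name == "tiny") {
    labels <- c("Fp1", "Fp2", "P3", "P4")
    plan <- build_schedule(speller_matrix(2, 2), characters = 1:2,
                           n_repetitions = 3, seed = 7)
    cfg <- sim_config(plan = plan, channel_labels = labels, fs = 250,
                      erp_channels = c("P3", "P4"),
                      coupling_pairs = cbind("P3", "P4"),
                      seed = 7)
  } else {
    stop("unknown fixture preset: ", name, call. = FALSE)
  }
  simulate_session(cfg)
}
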