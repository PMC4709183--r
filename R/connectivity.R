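#' Instantaneous Hilbert phase of epoched signals
#'
#' Per trial and channel, the angle of the analytic signal of the epoch,
#' wrapped to `(-pi, pi]`. Epochs should be band-limited (1-12 Hz) before
#' phase extraction; a warning is issued when the pipeline cannot confirm
#' that (no recorded band).
#'
#' @param epochs An `epoch_set` (band-pass filtered upstream).
#' @param trials Optional trial subset.
#' @return A `phase_tensor`: `phases` (trials x channels x samples,
#'   radians), `time_ms`, `fs`, `channel_labels`.
#' @export
instantaneous_phase <- function(epochs, trials = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!is.null(trials)) epochs <- subset_trials(epochs, trials)
  d <- dim(epochs$data)
  flat <- apply(abs(epochs$data), c(1, 2), max) == 0
  if (any(flat)) {
    bad <- which(flat, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "degenerate input: all-zero signal in trial %d, channel %s (phase undefined)",
      bad[1], epochs$channel_labels[bad[2]]), call. = FALSE)
  }
  # samples x (trials * channels), channel fastest
  m <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[3])
  a <- cpp_analytic(m)
  ang <- Arg(a)
  ang[ang <= -pi] <- pi  # wrap the atan2 branch point into (-pi, pi]
  phases <- aperm(array(ang, dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  structure(list(phases = phases, time_ms = epochs$time_ms,
                 fs = epochs$fs, channel_labels = epochs$channel_labels),
            class = "phase_tensor")
}

pair_index <- function(n_channels) {
  t(combn(n_channels, 2))
}

#' Across-trial phase-locking value time course
#'
#' For every channel pair (i < j) and sample t, the mean resultant length
#' of the inter-channel phase difference across trials:
#' `PLV(t) = |sum_n exp(i (phi_x,n(t) - phi_y,n(t)))| / Tr`. PLV is 1
#' when the phase difference is identical across trials and tends to 0
#' for independent phases. 19 channels give 171 pairs.
#'
#' @param phases A [instantaneous_phase()] tensor, or an `epoch_set`
#'   (phases are then extracted first).
#' @param trials Optional trial subset (at least 2 trials required).
#' @return A `plv_timecourse`: `plv` (pairs x samples in `[0, 1]`),
#'   `pairs` (index matrix, i < j), `n_trials`, `time_ms`,
#'   `channel_labels`.
#' @export
plv_timecourse <- function(phases, trials = NULL) {
  if (inherits(phases, "epoch_set"))
    phases <- instantaneous_phase(phases, trials)
  else if (!is.null(trials)) {
    phases$phases <- phases$phases[trials, , , drop = FALSE]
  }
  stopifnot(inherits(phases, "phase_tensor"))
  d <- dim(phases$phases)
  if (d[1] < 2)
    stop("PLV needs at least 2 trials (it is an across-trial statistic)",
         call. = FALSE)
  U <- matrix(exp(1i * aperm(phases$phases, c(3, 2, 1))), nrow = d[3])
  plv <- cpp_plv_unit(U, d[1], d[2])
  structure(list(plv = plv, pairs = pair_index(d[2]),
                 n_trials = d[1], time_ms = phases$time_ms,
                 fs = phases$fs, channel_labels = phases$channel_labels),
            class = "plv_timecourse")
}

#' Optional baseline normalization of PLV time courses
#'
#' Z-scores each pair's PLV(t) against its pre-stimulus baseline segment.
#' Off by default in the edge-decision pipeline; provided for display and
#' for protocols that normalise synchrony against baseline.
#'
#' @param plv A [plv_timecourse()].
#' @param baseline Baseline window, ms.
#' @return The normalized `plv_timecourse` (values no longer in [0, 1]).
#' @export
normalize_plv <- function(plv, baseline = c(-200, 0)) {
  stopifnot(inherits(plv, "plv_timecourse"))
  bi <- plv$time_ms >= baseline[1] & plv$time_ms < baseline[2]
  if (sum(bi) < 2) stop("baseline window too short", call. = FALSE)
  mu <- rowMeans(plv$plv[, bi, drop = FALSE])
  sdv <- apply(plv$plv[, bi, drop = FALSE], 1, sd)
  if (any(sdv == 0)) stop("zero baseline variance in a PLV time course",
                          call. = FALSE)
  plv$plv <- (plv$plv - mu) / sdv
  plv$normalized <- TRUE
  plv
}

#' Window-averaged connectivity matrix
#'
#' Averages each pair's PLV over the analysis window (inclusive bounds;
#' default 200-500 ms, centred on the P300 latency) and arranges the
#' result as a symmetric channels x channels matrix with zero diagonal.
#'
#' @param plv A [plv_timecourse()].
#' @param window Averaging window, ms.
#' @return A `connectivity_graph` with `weights` only (run
#'   [significant_edges()] to obtain the adjacency and edge count).
#' @export
window_average <- function(plv, window = c(200, 500)) {
  stopifnot(inherits(plv, "plv_timecourse"))
  wi <- plv$time_ms >= window[1] & plv$time_ms <= window[2]
  if (!any(wi)) stop("averaging window outside the epoch", call. = FALSE)
  wm <- rowMeans(plv$plv[, wi, drop = FALSE])
  nch <- length(plv$channel_labels)
  weights <- matrix(0, nch, nch,
                    dimnames = list(plv$channel_labels,
                                    plv$channel_labels))
  weights[plv$pairs] <- wm
  weights <- weights + t(weights)
  structure(list(weights = weights, pairs = plv$pairs,
                 pair_weights = wm, window = window,
                 n_trials = plv$n_trials,
                 channel_labels = plv$channel_labels,
                 adjacency = NULL, edge_count = NA_integer_,
                 pvalues = NULL),
            class = "connectivity_graph")
}

#' Phase-randomized surrogate distribution of window-averaged PLV
#'
#' Each surrogate multiplies the positive-frequency spectrum of every
#' trial and channel by independent random phases (preserving every
#' amplitude spectrum exactly) and re-runs the phase -> PLV ->
#' window-average pipeline, giving the null distribution of the
#' window-averaged PLV per pair under "no consistent phase relation".
#'
#' @param epochs An `epoch_set`.
#' @param trials Optional trial subset.
#' @param n_surrogates Number of surrogates (default 200; must satisfy
#'   `n_surrogates >= 1/alpha - 1`, and strict rejection at level alpha
#'   needs `n_surrogates > 1/alpha - 1`).
#' @param window Averaging window, ms.
#' @param alpha Significance level the distribution is intended for
#'   (used only to validate `n_surrogates`).
#' @param seed Optional seed; fixed seed gives an identical distribution.
#' @return A `surrogate_distribution`: `plv_surr` (n_surrogates x
#'   pairs), `pairs`, `window`, `n_surrogates`, `alpha`.
#' @export
make_surrogates <- function(epochs, trials = NULL, n_surrogates = 200,
                            window = c(200, 500), alpha = 0.01,
                            seed = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!is.null(trials)) epochs <- subset_trials(epochs, trials)
  if (n_surrogates < 1 / alpha - 1)
    stop("n_surrogates too small for the requested alpha (need >= ",
         ceiling(1 / alpha - 1), ")", call. = FALSE)
  d <- dim(epochs$data)
  if (d[1] < 2) stop("PLV needs at least 2 trials", call. = FALSE)
  wi <- which(epochs$time_ms >= window[1] & epochs$time_ms <= window[2])
  if (length(wi) == 0)
    stop("averaging window outside the epoch", call. = FALSE)
  m <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[3])
  surr <- with_seed(seed,
    cpp_surrogate_plv(m, d[1], d[2], wi - 1L, n_surrogates))
  structure(list(plv_surr = surr, pairs = pair_index(d[2]),
                 window = window, n_surrogates = n_surrogates,
                 alpha = alpha, channel_labels = epochs$channel_labels),
            class = "surrogate_distribution")
}

#' Phase-randomized surrogate of raw signals
#'
#' Amplitude-spectrum-preserving randomization of each column's spectral
#' phases (Hermitian-symmetric, so the surrogate is real). Exposed for
#' inspection and testing; [make_surrogates()] performs the same
#' randomization internally.
#'
#' @param x Numeric matrix, samples x signals.
#' @param seed Optional seed.
#' @return Matrix of the same shape.
#' @export
phase_randomize <- function(x, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  khi <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  with_seed(seed, {
    X <- mvfft(x)
    if (khi >= 1) {
      theta <- matrix(runif(khi * ncol(x), 0, 2 * pi), khi)
      rot <- exp(1i * theta)
      X[2:(khi + 1), ] <- X[2:(khi + 1), , drop = FALSE] * rot
      X[n:(n - khi + 1), ] <- Conj(X[2:(khi + 1), , drop = FALSE])
    }
    Re(mvfft(X, inverse = TRUE)) / n
  })
}

#' Threshold a connectivity graph against its surrogate distribution
#'
#' Per pair, the one-sided empirical p-value with the add-one rank
#' convention, `p = (1 + #(surrogate >= observed)) / (1 + n_surrogates)`,
#' and an edge wherever `p < alpha`. With 200 surrogates an observed
#' value exceeding all surrogates gets p = 1/201 < 0.01.
#'
#' @param graph A [window_average()] result.
#' @param surr A [make_surrogates()] distribution on the same pairs.
#' @param alpha Significance level (default 0.01).
#' @return The graph with `adjacency`, `pvalues` and `edge_count` filled
#'   in.
#' @export
significant_edges <- function(graph, surr, alpha = 0.01) {
  stopifnot(inherits(graph, "connectivity_graph"),
            inherits(surr, "surrogate_distribution"))
  if (!identical(dim(graph$pairs), dim(surr$pairs)) ||
      !all(graph$pairs == surr$pairs))
    stop("observed graph and surrogate distribution index different pairs",
         call. = FALSE)
  obs <- graph$pair_weights
  n <- surr$n_surrogates
  exceed <- colSums(surr$plv_surr >= rep(obs, each = n))
  pvals <- (1 + exceed) / (1 + n)
  sig <- pvals < alpha
  nch <- length(graph$channel_labels)
  adj <- matrix(FALSE, nch, nch,
                dimnames = dimnames(graph$weights))
  adj[graph$pairs] <- sig
  adj <- adj | t(adj)
  pm <- matrix(NA_real_, nch, nch, dimnames = dimnames(graph$weights))
  pm[graph$pairs] <- pvals
  pm[graph$pairs[, 2:1, drop = FALSE]] <- pvals
  graph$adjacency <- adj
  graph$pvalues <- pm
  graph$edge_count <- sum(sig)
  graph$alpha <- alpha
  graph$n_surrogates <- n
  graph
}

#' Full observed-plus-surrogate connectivity analysis
#'
#' Convenience wrapper running phase extraction, across-trial PLV,
#' window averaging, surrogate generation and significance thresholding
#' in one call.
#'
#' @inheritParams make_surrogates
#' @return A thresholded `connectivity_graph`.
#' @export
plv_connectivity <- function(epochs, trials = NULL, window = c(200, 500),
                             n_surrogates = 200, alpha = 0.01,
                             seed = NULL) {
  if (!is.null(trials)) epochs <- subset_trials(epochs, trials)
  g <- window_average(plv_timecourse(epochs), window)
  s <- make_surrogates(epochs, n_surrogates = n_surrogates,
                       window = window, alpha = alpha, seed = seed)
  significant_edges(g, s, alpha)
}

#' Mean PLV over all channel pairs
#'
#' @param graph A `connectivity_graph`.
#' @return Mean of the upper-triangle window-averaged PLV weights.
#' @export
mean_plv_feature <- function(graph) {
  if (is.list(graph) && !is.null(graph$pair_weights))
    return(mean(graph$pair_weights))
  if (is.list(graph) && !is.null(graph$mean_plv))
    return(graph$mean_plv)
  stop("not a connectivity graph", call. = FALSE)
}

#' Number of significant edges
#'
#' @param graph A thresholded `connectivity_graph`.
#' @return Integer edge count (half the sum of the adjacency matrix).
#' @export
edge_count <- function(graph) {
  if (is.list(graph) && !is.null(graph$edge_count))
    return(graph$edge_count)
  stop("not a connectivity graph", call. = FALSE)
}

#' Wilcoxon rank-sum contrast between conditions
#'
#' Two-sided Wilcoxon rank-sum test comparing a per-observation synchrony
#' feature (edge counts or mean PLV, one value per character or averaging
#' unit) between target and non-target conditions.
#'
#' @param target,nontarget Numeric feature vectors (>= 5 observations
#'   each), or lists of `connectivity_graph` objects from which `feature`
#'   is extracted.
#' @param feature `"edge_count"` or `"mean_plv"` (used when graphs are
#'   passed).
#' @return List: `statistic` (rank-sum W), `p_value`, `method`.
#' @export
condition_contrast <- function(target, nontarget,
                               feature = c("edge_count", "mean_plv")) {
  feature <- match.arg(feature)
  fx <- function(v) {
    if (is.numeric(v)) return(v)
    getter <- if (feature == "edge_count") edge_count else mean_plv_feature
    vapply(v, getter, numeric(1))
  }
  x <- fx(target)
  y <- fx(nontarget)
  if (length(x) < 5 || length(y) < 5)
    stop("need at least 5 observations per condition", call. = FALSE)
  ht <- wilcox.test(x, y, exact = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = "Wilcoxon rank-sum")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf(
    "<connectivity_graph> %d channels, window [%g, %g] ms, %d trials\n",
    length(x$channel_labels), x$window[1], x$window[2], x$n_trials))
  if (!is.null(x$adjacency))
    cat(sprintf("  %d significant edges (alpha = %g, %d surrogates)\n",
                x$edge_count, x$alpha, x$n_surrogates))
  else cat("  weights only (not thresholded)\n")
  invisible(x)
}

#' Export a connectivity matrix to CSV / an edge list to TSV
#'
#' `write_connectivity_csv` writes the square weight matrix with channel
#' labels; `write_edge_tsv` writes one row per pair: `ch_i`, `ch_j`,
#' `weight`, `significant`.
#'
#' @param graph A `connectivity_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_connectivity_csv <- function(graph, path) {
  utils::write.csv(graph$weights, path)
  invisible(path)
}

#' @rdname write_connectivity_csv
#' @export
write_edge_tsv <- function(graph, path) {
  sig <- if (is.null(graph$adjacency)) NA else
    graph$adjacency[graph$pairs]
  out <- data.frame(
    ch_i = graph$channel_labels[graph$pairs[, 1]],
    ch_j = graph$channel_labels[graph$pairs[, 2]],
    weight = graph$pair_weights,
    significant = as.integer(sig))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a connectivity graph on a schematic 10/20 scalp
#'
#' Draws the electrodes at standard 2-D positions (bundled montage) and
#' the significant edges (or, if not thresholded, the strongest
#' `top_n` weights).
#'
#' @param x A `connectivity_graph`.
#' @param top_n Edges to draw when no adjacency is available.
#' @param ... Unused.
#' @export
plot.connectivity_graph <- function(x, top_n = 20, ...) {
  mf <- system.file("extdata", "montage_1020.tsv",
                    package = "plvspeller")
  mon <- read.table(mf, header = TRUE, sep = "\t")
  pos <- mon[match(x$channel_labels, mon$label), ]
  plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1,
       axes = FALSE, xlab = "", ylab = "")
  symbols(0, 0, circles = 1.15, inches = FALSE, add = TRUE)
  if (is.null(x$adjacency)) {
    ord <- order(x$pair_weights, decreasing = TRUE)
    sel <- x$pairs[utils::head(ord, top_n), , drop = FALSE]
  } else {
    sel <- x$pairs[x$adjacency[x$pairs], , drop = FALSE]
  }
  if (nrow(sel) > 0)
    segments(pos$x[sel[, 1]], pos$y[sel[, 1]],
             pos$x[sel[, 2]], pos$y[sel[, 2]], col = "red3")
  points(pos$x, pos$y, pch = 21, bg = "white", cex = 2.2)
  text(pos$x, pos$y, pos$label, cex = 0.55)
  invisible(x)
}
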