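# Shared fixtures (cached across test files; test_check runs everything in
# one process) and the independent brute-force PLV oracle.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

paper_fixture <- function() cached("paper_fix", make_fixture("paper_like"))

paper_epochs <- function() cached("paper_epochs", {
  extract_epochs(bandpass_filter(paper_fixture()$recording))
})

# Brute-force across-trial PLV, written independently of the pipeline:
# explicit complex sums per pair / sample / trial.
brute_plv <- function(ph) {
  d <- dim(ph)
  pairs <- t(combn(d[2], 2))
  out <- matrix(0, nrow(pairs), d[3])
  for (p in seq_len(nrow(pairs))) {
    for (s in seq_len(d[3])) {
      z <- 0 + 0i
      for (tr in seq_len(d[1])) {
        z <- z + exp(1i * (ph[tr, pairs[p, 1], s] - ph[tr, pairs[p, 2], s]))
      }
      out[p, s] <- Mod(z) / d[1]
    }
  }
  out
}

# Wrap a raw phase array (trials x channels x samples) as a phase tensor.
fake_phase_tensor <- function(phases, fs = 500) {
  d <- dim(phases)
  structure(list(phases = phases,
                 time_ms = (seq_len(d[3]) - 1) / fs * 1000,
                 fs = fs,
                 channel_labels = paste0("C", seq_len(d[2]))),
            class = "phase_tensor")
}

# Wrap a raw signal array as an epoch set with a -200 ms pre-stimulus axis.
fake_epochs <- function(data, fs = 250, is_target = NULL) {
  d <- dim(data)
  pre <- round(0.2 * fs)
  if (is.null(is_target)) is_target <- rep(TRUE, d[1])
  structure(list(
    data = data,
    time_ms = (seq_len(d[3]) - 1 - pre) / fs * 1000,
    fs = fs,
    channel_labels = paste0("C", seq_len(d[2])),
    events = data.frame(onset_s = seq_len(d[1]), stimulus_id = 1L,
                        is_target = is_target, character_index = 1L,
                        run = 1L, block = seq_len(d[1])),
    normalized = FALSE), class = "epoch_set")
}

# Symmetric logical matrix of the ground-truth edges on a label set.
truth_matrix <- function(truth, labels) {
  tm <- matrix(FALSE, length(labels), length(labels),
               dimnames = list(labels, labels))
  e <- truth$true_edges
  tm[cbind(match(e[, 1], labels), match(e[, 2], labels))] <- TRUE
  tm | t(tm)
}
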