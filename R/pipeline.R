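#' Default analysis configuration
#'
#' All tunable defaults of the pipeline in one list: band edges, epoch
#' and analysis windows, surrogate settings, wavelet parameters, ICA
#' blink-rejection ratio, classifier settings and seeds. Values can be
#' overridden by name; unknown names are rejected.
#'
#' @param ... Named overrides.
#' @return A list of class `speller_settings`.
#' @export
speller_config <- function(...) {
  cfg <- list(
    band = c(1, 12),
    epoch_window = c(-0.2, 0.8),
    baseline_ms = c(-200, 0),
    p300_window_ms = c(220, 500),
    plv_window_ms = c(200, 500),
    n_surrogates = 200,
    alpha = 0.01,
    wavelet_fb = 2,
    wavelet_fc = 1,
    ica_ratio_threshold = 3,
    train_fraction = 0.8,
    n_repeats = 10,
    svm_cost = 1,
    seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown setting(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(modifyList(cfg, dots), class = c("speller_settings", "list"))
}

#' Read / write pipeline settings as YAML
#'
#' @param path YAML file.
#' @param cfg A [speller_config()] list.
#' @return `read_config` returns the settings list; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  do.call(speller_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full simulate -> preprocess -> features -> decode pipeline
#'
#' Convenience driver (also backing the command-line interface): takes a
#' recording (or simulates the `"paper_like"` fixture when none is
#' given), band-pass filters, epochs, computes per-stimulus connectivity
#' graphs and the feature table, evaluates the configured feature sets
#' with the linear SVM, and decodes each character by the max-edge
#' row x column rule.
#'
#' @param recording An [eeg_recording()] with events; `NULL` simulates
#'   the bundled fixture.
#' @param matrix The [speller_matrix()] of the paradigm.
#' @param settings A [speller_config()].
#' @param feature_sets Feature subsets to evaluate.
#' @param out Optional output directory: writes `report.json`,
#'   `features.csv` and `predictions.tsv`.
#' @return List: `features`, `reports` (one `evaluation_report` per
#'   feature set), `predictions`, `settings`.
#' @export
run_pipeline <- function(recording = NULL, matrix = speller_matrix(),
                         settings = speller_config(),
                         feature_sets = list(c("peak", "area"),
                                             "mean_plv", "edge_count",
                                             c("peak", "area",
                                               "mean_plv")),
                         out = NULL) {
  if (is.null(recording)) recording <- make_fixture("paper_like")$recording
  rec <- bandpass_filter(recording, settings$band[1], settings$band[2])
  epochs <- extract_epochs(rec, settings$epoch_window[1],
                           settings$epoch_window[2])
  gs <- stimulus_graphs(epochs, window = settings$plv_window_ms,
                        n_surrogates = settings$n_surrogates,
                        alpha = settings$alpha,
                        seed = settings$seed)
  feats <- build_features(epochs, gs)
  reports <- lapply(feature_sets, function(fs) {
    tab <- build_features(epochs, gs, fs)
    classify_cv(tab, n_repeats = settings$n_repeats,
                train_fraction = settings$train_fraction,
                cost = settings$svm_cost, seed = settings$seed)
  })
  names(reports) <- vapply(feature_sets, paste, "", collapse = "+")
  runs <- unique(gs$meta$run)
  preds <- do.call(rbind, lapply(runs, function(r) {
    sel <- which(gs$meta$run == r)
    sub <- structure(list(graphs = gs$graphs[sel],
                          meta = gs$meta[sel, ]), class = "graph_set")
    pred <- predict_character(sub, matrix)
    data.frame(run = r, truth = gs$meta$character_index[sel][1],
               predicted = pred$character_index,
               correct = pred$character_index ==
                 gs$meta$character_index[sel][1])
  }))
  result <- list(features = feats, reports = reports,
                 predictions = preds, settings = settings)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_feature_csv(feats, file.path(out, "features.csv"))
    write.table(preds, file.path(out, "predictions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary <- lapply(reports, function(r)
      list(accuracy = r$accuracy, auc = r$auc))
    summary$character_accuracy <- mean(preds$correct) * 100
    jsonlite::write_json(summary, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
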