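# Trial indices grouped by (character run, stimulus id). Characters are
# identified by their run so that repeated spellings of the same symbol
# stay separate observations.
stimulus_sets <- function(epochs) {
  ev <- epochs$events
  key <- interaction(ev$run %||% ev$character_index, ev$stimulus_id,
                     drop = TRUE)
  split(seq_len(nrow(ev)), key)
}

#' Per-stimulus connectivity graphs
#'
#' Computes one thresholded connectivity graph per (character run,
#' stimulus) trial set -- the averaging unit of the speller: all flashes
#' of one row or column while one character was attended.
#'
#' @param epochs A band-passed `epoch_set`.
#' @param trials_per_set Optional subsample size k per set (k >= 2);
#'   `NULL` uses every trial of the set.
#' @param window,n_surrogates,alpha As in [plv_connectivity()].
#' @param surrogates Set `FALSE` to skip surrogate thresholding (graphs
#'   then carry weights only; edge counts unavailable).
#' @param seed Optional seed covering both the subsampling and the
#'   surrogates.
#' @return A `graph_set`: list with `graphs` (one per set) and `meta`
#'   data frame (`run`, `character_index`, `stimulus_id`, `is_target`,
#'   `n_trials`).
#' @export
stimulus_graphs <- function(epochs, trials_per_set = NULL,
                            window = c(200, 500), n_surrogates = 200,
                            alpha = 0.01, surrogates = TRUE,
                            seed = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  sets <- stimulus_sets(epochs)
  with_seed(seed, {
    graphs <- vector("list", length(sets))
    meta <- vector("list", length(sets))
    for (k in seq_along(sets)) {
      idx <- sets[[k]]
      if (!is.null(trials_per_set)) {
        if (trials_per_set > length(idx))
          stop("trials_per_set exceeds available trials in a set",
               call. = FALSE)
        if (trials_per_set < length(idx))
          idx <- sort(sample(idx, trials_per_set))
      }
      sub <- subset_trials(epochs, idx)
      graphs[[k]] <- if (surrogates) {
        plv_connectivity(sub, window = window,
                         n_surrogates = n_surrogates, alpha = alpha)
      } else {
        window_average(plv_timecourse(sub), window)
      }
      ev <- sub$events[1, ]
      meta[[k]] <- data.frame(run = ev$run %||% ev$character_index,
                              character_index = ev$character_index,
                              stimulus_id = ev$stimulus_id,
                              is_target = ev$is_target,
                              n_trials = length(idx))
    }
    structure(list(graphs = graphs, meta = do.call(rbind, meta)),
              class = "graph_set")
  })
}

#' Build a per-stimulus feature table
#'
#' One row per (character run, stimulus) trial set, with any subset of
#' the features: `peak` and `area` from the trial-set average ERP
#' (baseline z-scored), `mean_plv` and `edge_count` from the set's
#' connectivity graph. Combination feature sets simply concatenate
#' columns.
#'
#' @param epochs An `epoch_set` (band-passed; z-scoring for the ERP
#'   features is applied internally when not already done).
#' @param graphs A [stimulus_graphs()] result; required for `mean_plv` /
#'   `edge_count` and must be keyed identically to `epochs`.
#' @param feature_set Non-empty subset of
#'   `c("peak", "area", "mean_plv", "edge_count")`.
#' @param trial_sets Internal: a named list of trial indices overriding
#'   the grouping (used for trial-count subsampling).
#' @return A data frame of class `feature_table`: grouping keys, `label`
#'   (target / nontarget), `n_trials`, then the features in the declared
#'   order.
#' @export
build_features <- function(epochs, graphs = NULL,
                           feature_set = c("peak", "area", "mean_plv",
                                           "edge_count"),
                           trial_sets = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  allowed <- c("peak", "area", "mean_plv", "edge_count")
  feature_set <- as.character(feature_set)
  if (length(feature_set) == 0 || !all(feature_set %in% allowed))
    stop("feature_set must be a non-empty subset of: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  need_graphs <- any(c("mean_plv", "edge_count") %in% feature_set)
  need_erp <- any(c("peak", "area") %in% feature_set)
  sets <- trial_sets %||% stimulus_sets(epochs)
  if (need_graphs) {
    if (is.null(graphs)) stop("PLV features need stimulus graphs",
                              call. = FALSE)
    if (nrow(graphs$meta) != length(sets))
      stop("graphs and epochs index different stimulus sets",
           call. = FALSE)
  }
  zep <- if (need_erp) {
    if (isTRUE(epochs$normalized)) epochs else zscore_baseline(epochs)
  } else NULL
  rows <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    idx <- sets[[k]]
    ev <- epochs$events[idx[1], ]
    row <- data.frame(run = ev$run %||% ev$character_index,
                      character_index = ev$character_index,
                      stimulus_id = ev$stimulus_id,
                      label = ifelse(ev$is_target, "target", "nontarget"),
                      n_trials = length(idx))
    if (need_erp) {
      erp <- average_erp(zep, trials = idx)
      if ("peak" %in% feature_set)
        row$peak <- as.numeric(peak_picking(erp))
      if ("area" %in% feature_set) row$area <- area_feature(erp)
    }
    if (need_graphs) {
      g <- graphs$graphs[[k]]
      gm <- graphs$meta[k, ]
      if (gm$character_index != ev$character_index ||
          gm$stimulus_id != ev$stimulus_id)
        stop("graph/epoch key mismatch at set ", k, call. = FALSE)
      if ("mean_plv" %in% feature_set) row$mean_plv <- mean_plv_feature(g)
      if ("edge_count" %in% feature_set) {
        ec <- edge_count(g)
        if (is.na(ec))
          stop("edge_count requested but graphs were not thresholded",
               call. = FALSE)
        row$edge_count <- ec
      }
    }
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  out <- out[, c("run", "character_index", "stimulus_id", "label",
                 "n_trials", feature_set)]
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  attr(out, "feature_set") <- feature_set
  out
}

fit_svm_score <- function(xtr, ytr, xte, cost = 1) {
  keep <- apply(xtr, 2, function(col) sd(col) > 0)
  if (!any(keep)) keep[1] <- TRUE
  xtr <- xtr[, keep, drop = FALSE]
  xte <- xte[, keep, drop = FALSE]
  wts <- rev(as.numeric(table(ytr))) / length(ytr)
  names(wts) <- levels(ytr)
  fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = cost,
                    scale = apply(xtr, 2, sd) > 0,
                    class.weights = wts)
  dv_tr <- attr(predict(fit, xtr, decision.values = TRUE),
                "decision.values")[, 1]
  flip <- mean(dv_tr[ytr == "target"]) < mean(dv_tr[ytr == "nontarget"])
  pr <- predict(fit, xte, decision.values = TRUE)
  score <- attr(pr, "decision.values")[, 1]
  if (flip) score <- -score
  list(pred = pr, score = score)
}

#' Repeated train/test evaluation of a linear SVM
#'
#' Splits the feature table by character run (all 11 stimulus
#' observations of a run stay on one side, preventing leakage), fits a
#' class-weighted linear SVM on the training runs, and scores accuracy
#' and AUC (from the decision function) on the held-out runs; repeated
#' `n_repeats` times with fresh random splits and averaged.
#'
#' @param table A [build_features()] table.
#' @param n_repeats Number of random splits (default 10).
#' @param train_fraction Fraction of character runs used for training.
#' @param cost SVM cost parameter.
#' @param seed Optional seed.
#' @return An `evaluation_report`: per-repeat `accuracy` (%) and `auc`,
#'   plus their means.
#' @export
classify_cv <- function(table, n_repeats = 10, train_fraction = 0.8,
                        cost = 1, seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  feats <- attr(table, "feature_set")
  y <- factor(table$label, levels = c("nontarget", "target"))
  if (nlevels(droplevels(y)) < 2)
    stop("both classes must be present", call. = FALSE)
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  x <- as.matrix(table[, feats, drop = FALSE])
  runs <- unique(table$run)
  n_train <- max(1, round(train_fraction * length(runs)))
  if (n_train >= length(runs)) n_train <- length(runs) - 1
  if (n_train < 1) stop("need at least 2 character runs", call. = FALSE)
  with_seed(seed, {
    res <- t(vapply(seq_len(n_repeats), function(r) {
      tr_runs <- sample(runs, n_train)
      tr <- table$run %in% tr_runs
      f <- fit_svm_score(x[tr, , drop = FALSE], y[tr],
                         x[!tr, , drop = FALSE], cost)
      acc <- mean(f$pred == y[!tr]) * 100
      auc <- as.numeric(pROC::auc(pROC::roc(
        response = y[!tr], predictor = f$score,
        levels = c("nontarget", "target"), direction = "<",
        quiet = TRUE)))
      c(accuracy = acc, auc = auc)
    }, c(accuracy = 0, auc = 0)))
    structure(list(per_repeat = as.data.frame(res),
                   accuracy = mean(res[, "accuracy"]),
                   auc = mean(res[, "auc"]),
                   feature_set = feats, n_repeats = n_repeats),
              class = "evaluation_report")
  })
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> features {%s}: accuracy %.1f%%, AUC %.3f (%d splits)\n",
    paste(x$feature_set, collapse = ", "), x$accuracy, x$auc,
    x$n_repeats))
  invisible(x)
}

graph_feature <- function(g, what) {
  if (what == "edge_count") edge_count(g) else mean_plv_feature(g)
}

#' Predict the attended character from per-stimulus edge counts
#'
#' The predicted row is the row stimulus with the most significant
#' edges, the predicted column likewise among column stimuli; the
#' character is their grid intersection. Ties are resolved by higher
#' mean PLV, then by lowest stimulus index, and flagged in the result.
#'
#' @param graphs List of thresholded `connectivity_graph`s named or
#'   ordered by stimulus id `1..n_rows + n_cols`, or a [stimulus_graphs()]
#'   `graph_set` restricted to one character run.
#' @param matrix The [speller_matrix()].
#' @return List: `row`, `col` (stimulus ids, 1-based), `character_index`,
#'   `tie_broken`.
#' @export
predict_character <- function(graphs, matrix) {
  stopifnot(inherits(matrix, "speller_matrix"))
  ns <- n_stimuli(matrix)
  if (inherits(graphs, "graph_set")) {
    ord <- order(graphs$meta$stimulus_id)
    glist <- graphs$graphs[ord]
  } else glist <- graphs
  if (length(glist) != ns)
    stop("need one graph per stimulus (", ns, ")", call. = FALSE)
  ec <- vapply(glist, graph_feature, numeric(1), what = "edge_count")
  mp <- vapply(glist, graph_feature, numeric(1), what = "mean_plv")
  pick <- function(ids) {
    best <- ids[ec[ids] == max(ec[ids])]
    tie <- length(best) > 1
    if (tie) best <- best[mp[best] == max(mp[best])]
    list(id = min(best), tie = tie)
  }
  r <- pick(seq_len(matrix$n_rows))
  co <- pick(matrix$n_rows + seq_len(matrix$n_cols))
  col_pos <- co$id - matrix$n_rows
  list(row = r$id, col = co$id,
       character_index = (r$id - 1L) * matrix$n_cols + col_pos,
       tie_broken = r$tie || co$tie)
}

#' Decode every character of a session
#'
#' Runs [stimulus_graphs()] per character run and predicts each attended
#' character by the max-edge row x column rule.
#'
#' @param epochs A band-passed `epoch_set` for a whole session.
#' @param matrix The [speller_matrix()].
#' @inheritParams stimulus_graphs
#' @return Data frame: one row per character run with `truth`,
#'   `predicted`, `correct`, `tie_broken`; attribute `accuracy` (%).
#' @export
predict_session <- function(epochs, matrix, window = c(200, 500),
                            n_surrogates = 200, alpha = 0.01,
                            seed = NULL) {
  gs <- stimulus_graphs(epochs, window = window,
                        n_surrogates = n_surrogates, alpha = alpha,
                        seed = seed)
  runs <- unique(gs$meta$run)
  out <- lapply(runs, function(r) {
    sel <- which(gs$meta$run == r)
    sub <- structure(list(graphs = gs$graphs[sel],
                          meta = gs$meta[sel, ]), class = "graph_set")
    pred <- predict_character(sub, matrix)
    truth <- gs$meta$character_index[sel][1]
    data.frame(run = r, truth = truth, predicted = pred$character_index,
               correct = pred$character_index == truth,
               tie_broken = pred$tie_broken)
  })
  out <- do.call(rbind, out)
  attr(out, "accuracy") <- mean(out$correct) * 100
  out
}

#' AUC as a function of the number of averaged trials
#'
#' For each trial count k, features are recomputed on random k-subsets
#' of every stimulus set, classified with [classify_cv()], and the
#' median AUC recorded per feature set. PLV-based features require
#' k >= 2 (PLV measures phase consistency across trials and is undefined
#' on a single trial).
#'
#' @param epochs A band-passed `epoch_set`.
#' @param feature_sets List of feature subsets (algorithms) to evaluate.
#' @param trial_counts Integer grid of k values.
#' @param n_subsamples Random k-subset draws per k.
#' @param n_repeats Train/test splits inside each [classify_cv()].
#' @param n_surrogates,alpha,window Connectivity settings (surrogates are
#'   only run when `edge_count` is requested).
#' @param seed Optional seed.
#' @return An `auc_trials_report`: `summary` data frame (`algorithm`,
#'   `k`, `auc_median`, `accuracy_median`) and `raw` per-draw AUCs.
#' @export
auc_vs_trials <- function(epochs,
                          feature_sets = list("mean_plv",
                                              c("peak", "area")),
                          trial_counts = c(2, 3, 5, 8, 12, 15),
                          n_subsamples = 3, n_repeats = 5,
                          n_surrogates = 200, alpha = 0.01,
                          window = c(200, 500), seed = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  sets <- stimulus_sets(epochs)
  n_avail <- min(lengths(sets))
  if (max(trial_counts) > n_avail)
    stop("trial count exceeds available trials per stimulus (",
         n_avail, ")", call. = FALSE)
  plv_based <- vapply(feature_sets, function(f)
    any(c("mean_plv", "edge_count") %in% f), logical(1))
  if (any(trial_counts < 2) && any(plv_based))
    stop("PLV features need at least 2 trials per set", call. = FALSE)
  if (any(trial_counts < 1)) stop("trial counts must be >= 1",
                                  call. = FALSE)
  with_seed(seed, {
    raw <- list()
    for (k in trial_counts) {
      for (s in seq_len(n_subsamples)) {
        sub_sets <- lapply(sets, function(idx) {
          if (k < length(idx)) sort(sample(idx, k)) else idx
        })
        need_edges <- any(vapply(feature_sets, function(f)
          "edge_count" %in% f, logical(1)))
        need_plv <- any(plv_based)
        gs <- if (need_plv) {
          flat <- unlist(sub_sets, use.names = FALSE)
          sub_ep <- subset_trials(epochs, flat)
          stimulus_graphs(sub_ep, surrogates = need_edges,
                          n_surrogates = n_surrogates, alpha = alpha,
                          window = window)
        } else NULL
        for (fi in seq_along(feature_sets)) {
          fs <- feature_sets[[fi]]
          tab <- if (any(c("mean_plv", "edge_count") %in% fs)) {
            flat <- unlist(sub_sets, use.names = FALSE)
            build_features(subset_trials(epochs, flat), gs, fs)
          } else {
            build_features(epochs, NULL, fs, trial_sets = sub_sets)
          }
          rep <- classify_cv(tab, n_repeats = n_repeats)
          raw[[length(raw) + 1]] <- data.frame(
            algorithm = paste(fs, collapse = "+"), k = k, draw = s,
            auc = rep$per_repeat$auc,
            accuracy = rep$per_repeat$accuracy)
        }
      }
    }
    raw <- do.call(rbind, raw)
    agg <- do.call(rbind, lapply(split(
      raw, list(raw$algorithm, raw$k), drop = TRUE), function(d)
        data.frame(algorithm = d$algorithm[1], k = d$k[1],
                   auc_median = median(d$auc),
                   accuracy_median = median(d$accuracy))))
    agg <- agg[order(agg$algorithm, agg$k), ]
    rownames(agg) <- NULL
    structure(list(summary = agg, raw = raw), class = "auc_trials_report")
  })
}

#' Compare two algorithms' AUC distributions
#'
#' Two-sided Wilcoxon rank-sum test on the per-draw AUC values of two
#' algorithms (named as in the report) or on two numeric AUC vectors.
#'
#' @param x An `auc_trials_report`, or a numeric AUC vector.
#' @param pair Character vector of the two algorithm names (when `x` is
#'   a report).
#' @param y Second numeric AUC vector (when `x` is numeric).
#' @return List: `statistic`, `p_value`, `method`.
#' @export
compare_algorithms <- function(x, pair = NULL, y = NULL) {
  if (inherits(x, "auc_trials_report")) {
    if (is.null(pair) || length(pair) != 2)
      stop("pair must name two algorithms", call. = FALSE)
    a <- x$raw$auc[x$raw$algorithm == pair[1]]
    b <- x$raw$auc[x$raw$algorithm == pair[2]]
  } else {
    a <- x
    b <- y
  }
  if (length(a) < 5 || length(b) < 5)
    stop("need at least 5 AUC observations per algorithm", call. = FALSE)
  ht <- wilcox.test(a, b, exact = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = "Wilcoxon rank-sum")
}
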