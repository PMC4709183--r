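# Small band-passed session shared by the decode tests (3 characters so
# the SVM split has >= 2 runs on each side).
decode_epochs <- function() cached("decode_epochs", {
  plan <- build_schedule(speller_matrix(), characters = 1:4,
                         n_repetitions = 5, seed = 71)
  sim <- simulate_session(sim_config(plan = plan, fs = 250, seed = 72))
  extract_epochs(bandpass_filter(sim$recording))
})

fake_table <- function(n_runs = 10, sep = 1) {
  rows <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
    lab <- c("target", "target", rep("nontarget", 9))
    data.frame(run = r, character_index = r, stimulus_id = 1:11,
               label = lab, n_trials = 15,
               feat = ifelse(lab == "target", sep, 0) + rnorm(11, sd = 0.01))
  }))
  class(rows) <- c("feature_table", "data.frame")
  attr(rows, "feature_set") <- "feat"
  rows
}

test_that("feature tables have one row per stimulus set in declared order", {
  ep <- decode_epochs()
  gs <- stimulus_graphs(ep, surrogates = FALSE)
  tab <- build_features(ep, gs, c("peak", "area", "mean_plv"))
  expect_identical(nrow(tab), 4L * 11L)
  expect_identical(attr(tab, "feature_set"), c("peak", "area", "mean_plv"))
  expect_identical(names(tab)[6:8], c("peak", "area", "mean_plv"))
  expect_identical(sum(tab$label == "target"), 4L * 2L)
  expect_true(all(is.finite(as.matrix(tab[, 6:8]))))
  # single-feature table
  tab1 <- build_features(ep, gs, "mean_plv")
  expect_identical(ncol(tab1), 6L)
  expect_error(build_features(ep, gs, character(0)), "non-empty")
  expect_error(build_features(ep, gs, "banana"), "non-empty subset")
  expect_error(build_features(ep, NULL, "mean_plv"), "stimulus graphs")
  expect_error(build_features(ep, gs, "edge_count"), "not thresholded")
})

test_that("perfectly separated features classify perfectly", {
  tab <- fake_table(sep = 5)
  rep <- classify_cv(tab, n_repeats = 5, seed = 1)
  expect_equal(rep$accuracy, 100)
  expect_equal(rep$auc, 1)
})

test_that("permuted labels give chance-level AUC", {
  set.seed(73)
  aucs <- vapply(1:20, function(s) {
    tab <- fake_table(sep = 0)  # feature carries no class information
    classify_cv(tab, n_repeats = 3, seed = s)$auc
  }, 0)
  expect_lt(abs(median(aucs) - 0.5), 0.1)
})

test_that("classification reports are seed-deterministic", {
  tab <- fake_table(sep = 0.3)
  a <- classify_cv(tab, n_repeats = 4, seed = 11)
  b <- classify_cv(tab, n_repeats = 4, seed = 11)
  expect_identical(a$per_repeat, b$per_repeat)
  expect_error(classify_cv(fake_table()[1:9, ], n_repeats = 2),
               "both classes|character runs")
})

test_that("character prediction takes the max-edge row and column", {
  m <- speller_matrix(5, 6)
  mk <- function(ec, mp = 0.1) list(edge_count = ec, mean_plv = mp)
  graphs <- c(lapply(c(3, 1, 9, 2, 0), mk),
              lapply(c(1, 1, 1, 8, 2, 0), mk))
  pred <- predict_character(graphs, m)
  expect_identical(pred$row, 3L)
  expect_identical(pred$col - m$n_rows, 4L)
  # row 3, column 4 -> character (3-1)*6 + 4 = 16
  expect_identical(pred$character_index, 16L)
  expect_false(pred$tie_broken)
  # all-equal counts exercise the deterministic tie path
  ties <- lapply(rep(2, 11), mk)
  pt <- predict_character(ties, m)
  expect_true(pt$tie_broken)
  expect_identical(pt$row, 1L)
  expect_identical(pt$character_index, 1L)
  # tie on edges resolved by higher mean PLV
  g2 <- c(lapply(c(5, 5, 0, 0, 0), mk), lapply(c(1, 0, 0, 0, 0, 0), mk))
  g2[[2]]$mean_plv <- 0.9
  p2 <- predict_character(g2, m)
  expect_identical(p2$row, 2L)
  expect_error(predict_character(graphs[1:5], m), "one graph per stimulus")
})

test_that("trial-count evaluation enforces the PLV trial minimum", {
  ep <- decode_epochs()
  expect_error(
    auc_vs_trials(ep, feature_sets = list("mean_plv"), trial_counts = 1),
    "at least 2 trials")
  expect_error(
    auc_vs_trials(ep, feature_sets = list("peak"), trial_counts = 99),
    "exceeds available")
})

test_that("full-count subsets reproduce the full-table features", {
  ep <- decode_epochs()
  gs <- stimulus_graphs(ep, surrogates = FALSE)
  full <- build_features(ep, gs, "mean_plv")
  # drawing k = all trials is the identity subsample
  gs2 <- stimulus_graphs(ep, trials_per_set = 5, surrogates = FALSE,
                         seed = 5)
  sub <- build_features(ep, gs2, "mean_plv")
  expect_equal(full$mean_plv, sub$mean_plv, tolerance = 1e-12)
})

test_that("feature semantics rank as their generators dictate", {
  # ERP only: peak+area must beat mean PLV; coupling only: the reverse
  mk_ep <- function(erp, coupl, seed) {
    plan <- build_schedule(speller_matrix(), characters = 1:4,
                           n_repetitions = 10, seed = seed)
    cfg <- sim_config(plan = plan, fs = 250, erp_amplitude = erp,
                      coupling_pairs = coupl, seed = seed + 1)
    extract_epochs(bandpass_filter(simulate_session(cfg)$recording))
  }
  ep_erp <- mk_ep(10, NULL, 81)
  ep_cpl <- mk_ep(0, default_coupling_pairs(), 91)
  auc_of <- function(ep, fs) {
    gs <- if ("mean_plv" %in% fs) stimulus_graphs(ep, surrogates = FALSE)
          else NULL
    classify_cv(build_features(ep, gs, fs), n_repeats = 6,
                seed = 3)$auc
  }
  expect_gt(auc_of(ep_erp, c("peak", "area")), auc_of(ep_erp, "mean_plv"))
  expect_gt(auc_of(ep_cpl, "mean_plv"), auc_of(ep_cpl, c("peak", "area")))
})

test_that("algorithm comparison runs on report AUC vectors", {
  expect_gt(compare_algorithms(rep(c(.7, .8), 5),
                               y = rep(c(.7, .8), 5))$p_value, 0.9)
  expect_lt(compare_algorithms(seq(0.9, 0.99, length.out = 10),
                               y = seq(0.5, 0.6, length.out = 10))$p_value,
            0.001)
  expect_error(compare_algorithms(1:3, y = 1:10), "at least 5")
})
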