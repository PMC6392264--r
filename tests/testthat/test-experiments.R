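# tiny lab shared across blocks (memoized: featurizations and completed runs
# accumulate in its cache, which is also what the cache tests rely on)
.tiny_env <- new.env(parent = emptyenv())
tiny_lab <- function() {
  if (is.null(.tiny_env$lab)) {
    corpora <- list(gender = make_gender_corpus(48, seed = 1),
                    words = make_word_corpus(48, n_classes = 3, seed = 2))
    .tiny_env$lab <- ci_lab(corpora,
                            experiment_config(max_epochs = 3L, art_R = 500L))
  }
  .tiny_env$lab
}

test_that("analysis 1 emits the task x arch table with exact differences", {
  lab <- tiny_lab()
  a1 <- run_analysis_1(lab, seeds = 0L, arches = "per")
  expect_equal(nrow(a1$table), 2L)   # 2 tasks x 1 arch
  expect_setequal(a1$table$task, c("gender", "words"))
  expect_equal(a1$table$diff, a1$table$high - a1$table$low)
  expect_length(a1$runs, 4L)         # 2 tasks x 2 res x 1 seed
  expect_true(all(vapply(a1$runs, function(r) r$condition == "CD", logical(1))))
})

test_that("identical models on both featurizations give diff 0 and p = 1", {
  lab <- tiny_lab()
  r <- run_regime(lab, "gender", "per", "high", "CD", seed = 0)
  art <- art_test(r$gold, r$predictions_final, r$predictions_final,
                  R = 200, seed = 0)
  expect_equal(art$d, 0)
  expect_equal(art$p, 1)
})

test_that("analysis 2 reuses cached low-res runs instead of recomputing", {
  lab <- tiny_lab()
  a1 <- run_analysis_1(lab, seeds = 0L, arches = "per")
  low_before <- run_regime(lab, "gender", "per", "low", "CD", 0)
  n_cached <- length(ls(lab$cache))
  a2 <- run_analysis_2(lab, seeds = 0L, arches = "per")
  low_after <- run_regime(lab, "gender", "per", "low", "CD", 0)
  expect_identical(low_before$predictions_final, low_after$predictions_final)
  expect_identical(low_before$history, low_after$history)
  expect_equal(a2$table$diff, a2$table$med - a2$table$low)
  # only the med-res runs were added by analysis 2
  expect_equal(length(ls(lab$cache)) - n_cached,
               2L + 2L)   # med features + med runs for 2 tasks
})

test_that("the PD regime evaluates pre-trained parameters before any update", {
  lab <- tiny_lab()
  pre <- run_regime(lab, "gender", "per", "high", "CD", seed = 3)
  pd <- run_regime(lab, "gender", "per", "med", "PD", seed = 3)
  feats_med <- cisim:::lab_features(lab, "gender", "med")
  ev <- evaluate_model(pre$model, feats_med, split = "test")
  expect_identical(pd$predictions_epoch0, ev$predictions)
  expect_equal(pd$accuracy_epoch0, ev$accuracy)
  expect_gt(pd$pretrain_epochs, 0L)
  expect_error(run_regime(lab, "gender", "per", "high", "PD", 0), "med or low")
})

test_that("analysis 3 table carries both inits and three timepoint blocks", {
  lab <- tiny_lab()
  a3 <- run_analysis_3(lab, seeds = 0L, arches = "per")
  expect_equal(nrow(a3$table), 4L)   # 2 init x 2 tasks x 1 arch
  expect_setequal(a3$table$init, c("pre-tr.", "rand."))
  for (tp in c("epoch0", "epoch1", "final")) {
    expect_equal(a3$table[[paste0("diff_", tp)]],
                 a3$table[[paste0("med_", tp)]] -
                   a3$table[[paste0("low_", tp)]])
  }
  expect_length(a3$runs, 4L)         # 2 tasks x 2 transfer res
})

test_that("aggregating a single run reproduces that run", {
  lab <- tiny_lab()
  r <- run_regime(lab, "gender", "per", "high", "CD", 0)
  agg <- aggregate_runs(list(r))
  expect_equal(nrow(agg$summary), 3L)   # three timepoints, sorted
  expect_equal(agg$summary$mean[agg$summary$timepoint == "epoch0"],
               r$accuracy_epoch0)
  expect_equal(agg$summary$mean[agg$summary$timepoint == "final"],
               r$accuracy_final)
  expect_true(all(agg$single_seed_view$seed == 0L))
})

test_that("aggregated means are seed-order invariant and match a loop", {
  lab <- tiny_lab()
  runs <- lapply(0:2, function(s)
    run_regime(lab, "gender", "per", "high", "CD", s))
  agg_fwd <- aggregate_runs(runs)
  agg_rev <- aggregate_runs(rev(runs))
  expect_equal(agg_fwd$summary$mean, agg_rev$summary$mean)
  finals <- vapply(runs, function(r) r$accuracy_final, numeric(1))
  by_hand <- sum(finals) / length(finals)
  got <- agg_fwd$summary$mean[agg_fwd$summary$timepoint == "final"]
  expect_equal(got, by_hand)
})

test_that("stored predictions recompute every reported accuracy", {
  lab <- tiny_lab()
  r <- run_regime(lab, "words", "per", "low", "CD", 0)
  expect_equal(r$accuracy_epoch0, mean(r$predictions_epoch0 == r$gold))
  expect_equal(r$accuracy_epoch1, mean(r$predictions_epoch1 == r$gold))
  expect_equal(r$accuracy_final, mean(r$predictions_final == r$gold))
})
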