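#' Experiment configuration
#'
#' Settings shared by the three analyses: the featurization front end, the
#' per-architecture learning rates, the early-stopping recipe, the
#' randomization-test replicate count, and the pre-registered
#' multiple-comparison family (18 comparisons per corpus: high-vs-low for
#' each architecture and architecture-vs-architecture at both resolutions in
#' Analysis I; med-vs-low for each architecture in Analysis II; med-vs-low
#' at three timepoints for each architecture and initialization in Analysis
#' III).
#'
#' @param feat A [feat_config()].
#' @param lr_per,lr_cnn Learning rates for the perceptron and the CNN.
#' @param batch_size Mini-batch size.
#' @param patience Early-stopping patience in epochs.
#' @param max_epochs Epoch ceiling.
#' @param monitor Early-stopping criterion, `"loss"` or `"accuracy"`.
#' @param family_size Bonferroni family size per corpus.
#' @param art_R Replicates for the approximate randomization test.
#' @param alpha Family-wise significance level.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(feat = feat_config(), lr_per = 0.01,
                              lr_cnn = 0.1, batch_size = 32L, patience = 10L,
                              max_epochs = 200L, monitor = "loss",
                              family_size = 18L, art_R = 1e5, alpha = 0.05) {
  structure(list(feat = feat, lr_per = lr_per, lr_cnn = lr_cnn,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), monitor = monitor,
                 family_size = as.integer(family_size),
                 art_R = as.integer(art_R), alpha = alpha),
            class = "experiment_config")
}

#' Create an experiment context
#'
#' Holds the corpora, the configuration, and a cache of featurizations and
#' completed training runs, so that analyses sharing a run (e.g. the low-res
#' from-scratch (CD) runs of Analyses I and II, or the high-res runs that
#' serve as pre-training for Analysis III) compute it once.
#'
#' @param corpora Named list of `ci_corpus` objects (e.g. `gender`, `words`).
#' @param config An [experiment_config()].
#' @param cache_dir Optional directory for on-disk run caching (used by
#'   [run_all()] to make stages resumable).
#' @return A `ci_lab` object.
#' @export
ci_lab <- function(corpora, config = experiment_config(), cache_dir = NULL) {
  stopifnot(is.list(corpora), length(corpora) >= 1,
            !is.null(names(corpora)))
  structure(list(corpora = corpora, config = config,
                 cache = new.env(parent = emptyenv()),
                 cache_dir = cache_dir),
            class = "ci_lab")
}

lab_key <- function(...) rlang::hash(list(...))

cache_get <- function(lab, key, compute) {
  if (!is.null(lab$cache[[key]])) return(lab$cache[[key]])
  if (!is.null(lab$cache_dir)) {
    path <- file.path(lab$cache_dir, paste0(key, ".rds"))
    if (file.exists(path)) {
      val <- readRDS(path)
      lab$cache[[key]] <- val
      return(val)
    }
  }
  val <- compute()
  lab$cache[[key]] <- val
  if (!is.null(lab$cache_dir)) {
    dir.create(lab$cache_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(val, file.path(lab$cache_dir, paste0(key, ".rds")))
  }
  val
}

lab_features <- function(lab, task, res) {
  if (is.null(lab$corpora[[task]])) stop("no corpus for task '", task, "'")
  key <- lab_key("features", task, res, lab$config$feat,
                 lab$corpora[[task]]$seed, length(lab$corpora[[task]]$waveforms))
  cache_get(lab, key, function() {
    featurize_corpus(lab$corpora[[task]], res, lab$config$feat)
  })
}

lab_train_config <- function(lab, arch, seed) {
  train_config(
    learning_rate = if (arch == "per") lab$config$lr_per else lab$config$lr_cnn,
    batch_size = lab$config$batch_size, patience = lab$config$patience,
    max_epochs = lab$config$max_epochs, monitor = lab$config$monitor,
    seed = seed)
}

new_model_for <- function(arch, feats, seed) {
  if (arch == "per") {
    perceptron(dim(feats$x)[2] * dim(feats$x)[3], feats$n_classes, seed = seed)
  } else {
    build_cnn(dim(feats$x)[2:3], feats$n_classes, seed = seed)
  }
}

#' Run one training regime
#'
#' `CD` (congenitally deaf analog): train from a fresh initialization on the
#' requested featurization. `PD` (postlingually deaf analog): take the
#' parameters of the same-seed high-resolution CD run as pre-training, then
#' continue training on the requested (med/low) featurization with a fresh
#' optimizer state. Test-set accuracy and item-level predictions are recorded
#' before any update on the target featurization (epoch 0), after the first
#' epoch, and at the best (final) epoch.
#'
#' @param lab A [ci_lab()].
#' @param task Corpus name.
#' @param arch `"per"` or `"cnn"`.
#' @param res Featurization: `"high"`, `"med"`, or `"low"`.
#' @param condition `"CD"` or `"PD"`.
#' @param seed Integer seed (model initialization and training).
#' @return A `ci_run` record with accuracies, predictions, and history.
#' @export
run_regime <- function(lab, task, arch, res, condition = c("CD", "PD"),
                       seed = 0L) {
  condition <- match.arg(condition)
  if (condition == "PD" && res == "high") {
    stop("PD regime transfers to the med or low featurization")
  }
  key <- lab_key("run", task, arch, res, condition, seed,
                 lab$config[setdiff(names(lab$config), "feat")],
                 lab$config$feat)
  cache_get(lab, key, function() {
    feats <- lab_features(lab, task, res)
    if (condition == "CD") {
      model0 <- new_model_for(arch, feats, seed)
      pretrain_epochs <- 0L
    } else {
      pre <- run_regime(lab, task, arch, "high", "CD", seed)
      model0 <- pre$model
      pretrain_epochs <- pre$n_epochs
    }
    ev0 <- evaluate_model(model0, feats, split = "test")
    fit <- train_model(model0, feats, lab_train_config(lab, arch, seed))
    ev1 <- evaluate_model(fit$model_epoch1, feats, split = "test")
    evf <- evaluate_model(fit$model, feats, split = "test")
    structure(list(
      task = task, arch = arch, res = res, condition = condition,
      seed = as.integer(seed), pretrain_epochs = pretrain_epochs,
      accuracy_epoch0 = ev0$accuracy, accuracy_epoch1 = ev1$accuracy,
      accuracy_final = evf$accuracy,
      predictions_epoch0 = ev0$predictions,
      predictions_epoch1 = ev1$predictions,
      predictions_final = evf$predictions,
      gold = feats$y[feats$split == "test"],
      history = fit$history, best_epoch = fit$best_epoch,
      n_epochs = fit$n_epochs, model = fit$model),
      class = "ci_run")
  })
}

#' @export
print.ci_run <- function(x, ...) {
  cat(sprintf(
    "<ci_run> %s/%s %s-res %s seed %d: acc %.3f -> %.3f -> %.3f (%d epochs)\n",
    x$task, x$arch, x$res, x$condition, x$seed, x$accuracy_epoch0,
    x$accuracy_epoch1, x$accuracy_final, x$n_epochs))
  invisible(x)
}

run_pair_art <- function(lab, run_a, run_b, timepoint = "final") {
  pa <- run_a[[paste0("predictions_", timepoint)]]
  pb <- run_b[[paste0("predictions_", timepoint)]]
  art_test(run_a$gold, pa, pb, R = lab$config$art_R,
           seed = run_a$seed + 104729L)
}

acc_at <- function(run, timepoint) run[[paste0("accuracy_", timepoint)]]

#' Analysis I: architecture and high- vs. low-resolution comparisons
#'
#' Trains both architectures from fresh initializations on the high- and
#' low-resolution featurizations of every corpus (the CD regime) and tests
#' the paired accuracy differences: high-vs-low within each architecture and
#' perceptron-vs-CNN within each resolution.
#'
#' @param lab A [ci_lab()].
#' @param seeds Integer vector of seeds; the comparison table is computed on
#'   the first seed (single-run view); all runs are returned for aggregation.
#' @param arches Architectures to run (default both).
#' @return List with `runs` (all `ci_run`s), `table` (task x arch rows with
#'   high, low, diff = high - low, p, stars), and `arch_comparisons`.
#' @export
run_analysis_1 <- function(lab, seeds = 0L, arches = c("per", "cnn")) {
  tasks <- names(lab$corpora)
  runs <- list()
  for (task in tasks) for (arch in arches) for (res in c("high", "low")) {
    for (seed in seeds) {
      runs[[length(runs) + 1L]] <- run_regime(lab, task, arch, res, "CD", seed)
    }
  }
  s0 <- seeds[1]
  pick <- function(task, arch, res, seed = s0, condition = "CD") {
    run_regime(lab, task, arch, res, condition, seed)
  }
  rows <- list()
  for (task in tasks) for (arch in arches) {
    hi <- pick(task, arch, "high"); lo <- pick(task, arch, "low")
    art <- run_pair_art(lab, hi, lo)
    rows[[length(rows) + 1L]] <- data.frame(
      task = task, arch = arch, high = hi$accuracy_final,
      low = lo$accuracy_final, diff = hi$accuracy_final - lo$accuracy_final,
      p = art$p, stars = star_code(art$p, lab$config$family_size),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  arch_cmp <- NULL
  if (length(arches) == 2L) {
    ac <- list()
    for (task in tasks) for (res in c("high", "low")) {
      a <- pick(task, arches[1], res); b <- pick(task, arches[2], res)
      art <- run_pair_art(lab, a, b)
      ac[[length(ac) + 1L]] <- data.frame(
        task = task, res = res, acc_a = a$accuracy_final,
        acc_b = b$accuracy_final, diff = a$accuracy_final - b$accuracy_final,
        p = art$p, stars = star_code(art$p, lab$config$family_size),
        stringsAsFactors = FALSE)
    }
    arch_cmp <- do.call(rbind, ac)
  }
  list(runs = runs, table = tab, arch_comparisons = arch_cmp)
}

#' Analysis II: effect of channel interaction without pre-training
#'
#' Trains freshly initialized models on the medium- (16 channels, no
#' interaction) and low-resolution (16 channels with interaction)
#' featurizations and compares the final accuracies. Runs already computed by
#' Analysis I under the same seeds (the low-resolution CD runs) are reused
#' from the cache, not recomputed.
#'
#' @inheritParams run_analysis_1
#' @return List with `runs` and `table` (columns med, low, diff = med - low,
#'   p, stars).
#' @export
run_analysis_2 <- function(lab, seeds = 0L, arches = c("per", "cnn")) {
  tasks <- names(lab$corpora)
  runs <- list()
  for (task in tasks) for (arch in arches) for (res in c("med", "low")) {
    for (seed in seeds) {
      runs[[length(runs) + 1L]] <- run_regime(lab, task, arch, res, "CD", seed)
    }
  }
  s0 <- seeds[1]
  rows <- list()
  for (task in tasks) for (arch in arches) {
    me <- run_regime(lab, task, arch, "med", "CD", s0)
    lo <- run_regime(lab, task, arch, "low", "CD", s0)
    art <- run_pair_art(lab, me, lo)
    rows[[length(rows) + 1L]] <- data.frame(
      task = task, arch = arch, med = me$accuracy_final,
      low = lo$accuracy_final, diff = me$accuracy_final - lo$accuracy_final,
      p = art$p, stars = star_code(art$p, lab$config$family_size),
      stringsAsFactors = FALSE)
  }
  list(runs = runs, table = do.call(rbind, rows))
}

#' Analysis III: channel interaction after high-resolution pre-training
#'
#' For every architecture and corpus, takes the high-resolution CD run of
#' the same seed as pre-training (computing it if absent), transfers to the
#' medium- and low-resolution featurizations (the PD regime), and tabulates
#' test accuracy before any transfer update (epoch 0), after the first
#' transfer epoch, and at the final epoch — alongside the randomly
#' initialized (CD) rows at the same timepoints for contrast.
#'
#' @inheritParams run_analysis_1
#' @return List with `runs` (the PD runs) and `table`: one row per
#'   init (`pre-tr.`/`rand.`) x task x arch, with a med/low/diff/p/stars
#'   block at each of the three timepoints.
#' @export
run_analysis_3 <- function(lab, seeds = 0L, arches = c("per", "cnn")) {
  tasks <- names(lab$corpora)
  runs <- list()
  for (task in tasks) for (arch in arches) for (res in c("med", "low")) {
    for (seed in seeds) {
      runs[[length(runs) + 1L]] <- run_regime(lab, task, arch, res, "PD", seed)
    }
  }
  s0 <- seeds[1]
  rows <- list()
  for (init in c("pre-tr.", "rand.")) {
    condition <- if (init == "pre-tr.") "PD" else "CD"
    for (task in tasks) for (arch in arches) {
      me <- run_regime(lab, task, arch, "med", condition, s0)
      lo <- run_regime(lab, task, arch, "low", condition, s0)
      row <- data.frame(init = init, task = task, arch = arch,
                        stringsAsFactors = FALSE)
      for (tp in c("epoch0", "epoch1", "final")) {
        art <- run_pair_art(lab, me, lo, timepoint = tp)
        row[[paste0("med_", tp)]] <- acc_at(me, tp)
        row[[paste0("low_", tp)]] <- acc_at(lo, tp)
        row[[paste0("diff_", tp)]] <- acc_at(me, tp) - acc_at(lo, tp)
        row[[paste0("p_", tp)]] <- art$p
        row[[paste0("stars_", tp)]] <- star_code(art$p, lab$config$family_size)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  list(runs = runs, table = do.call(rbind, rows))
}

#' Collect runs into a tidy accuracy table
#'
#' @param runs List of `ci_run` records.
#' @return Data frame with one row per run x timepoint.
#' @export
runs_to_frame <- function(runs) {
  do.call(rbind, lapply(runs, function(r) {
    data.frame(task = r$task, arch = r$arch, res = r$res,
               condition = r$condition, seed = r$seed,
               timepoint = c("epoch0", "epoch1", "final"),
               accuracy = c(r$accuracy_epoch0, r$accuracy_epoch1,
                            r$accuracy_final),
               n_epochs = r$n_epochs, stringsAsFactors = FALSE)
  }))
}

#' Aggregate runs across seeds
#'
#' @param runs List of `ci_run` records (possibly several seeds per cell).
#' @param single_seed Seed for the single-run view (default: smallest).
#' @return List with `summary` (per-cell mean/sd/n over seeds) and
#'   `single_seed_view` (the rows of the chosen seed).
#' @export
aggregate_runs <- function(runs, single_seed = NULL) {
  stopifnot(length(runs) >= 1)
  df <- runs_to_frame(runs)
  if (is.null(single_seed)) single_seed <- min(df$seed)
  agg <- stats::aggregate(accuracy ~ task + arch + res + condition + timepoint,
                          data = df,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  summary <- cbind(agg[setdiff(names(agg), "accuracy")],
                   as.data.frame(agg$accuracy))
  list(summary = summary,
       single_seed_view = df[df$seed == single_seed, , drop = FALSE])
}
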