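# End-to-end benchmark orchestration: dataset -> pairs/splits -> models
# (one per training objective) -> attributions -> metrics. These functions
# are the programmatic interface; inst/cli/ucnbench is a thin command-line
# wrapper over them.

#' Build pairs and leakage-free splits for every target
#'
#' Runs the full data-preparation pipeline per target: pair enumeration with
#' activity-cliff and shared-structure filters, compound-level train/test
#' split, and the minimum-training-pairs target filter. Stage counts are
#' logged per target.
#'
#' @param records `activity_records` covering one or more targets.
#' @param mcs_threshold,min_delta pair filters (defaults 0.5 and 1.0).
#' @param train_frac,split_seed split parameters (defaults 0.8, 1).
#' @param min_train_pairs target filter (default 50).
#' @param timeout_s per-pair MCS budget.
#' @return list with `splits` (named by target, filtered) and `log`
#'   (data.frame of per-target stage counts, including dropped targets).
#' @export
prepare_benchmark <- function(records, mcs_threshold = 0.5, min_delta = 1.0,
                              train_frac = 0.8, split_seed = 1L,
                              min_train_pairs = 50L, timeout_s = 10) {
  stopifnot(inherits(records, "activity_records"))
  targets <- unique(records$target_id)
  splits <- list()
  log <- NULL
  for (tid in targets) {
    recs <- records[records$target_id == tid, ]
    class(recs) <- c("activity_records", "data.frame")
    pairs <- build_pairs(recs, mcs_threshold = mcs_threshold,
                         min_delta = min_delta, timeout_s = timeout_s)
    sp <- split_pairs(pairs, train_frac = train_frac, seed = split_seed)
    kept <- length(sp$train_pairs) >= min_train_pairs
    log <- rbind(log, data.frame(
      target_id = tid, n_compounds = nrow(recs),
      n_candidate_pairs = attr(pairs, "n_candidates"),
      n_delta_pass = attr(pairs, "n_delta_pass"),
      n_pairs = length(pairs),
      n_timeout = attr(pairs, "n_timeout"),
      n_train_pairs = length(sp$train_pairs),
      n_test_pairs = length(sp$test_pairs),
      n_straddling_dropped = sp$n_dropped,
      kept = kept, stringsAsFactors = FALSE))
    if (kept) splits[[tid]] <- sp
  }
  list(splits = splits, log = log)
}

#' Train one GNN per loss mode on a split
#'
#' @param split a `BenchmarkSplit`.
#' @param config base [gnn_config()]; its `loss_mode` is overridden.
#' @param loss_modes the objectives to train (default all three).
#' @return named list of `TrainedGNN`s.
#' @export
train_loss_modes <- function(split, config = gnn_config(),
                             loss_modes = c("MSE", "MSE+AC", "MSE+UCN")) {
  models <- list()
  for (mode in loss_modes) {
    cfg <- config
    cfg$loss_mode <- mode
    models[[mode]] <- train_gnn(split, cfg)
  }
  models
}

# Attribution for every unique compound appearing in `pairs`, one list per
# compound id. `fun(mol, graph, id)` computes one Attribution.
.attribute_compounds <- function(pairs, fun) {
  out <- list()
  for (p in pairs) {
    for (side in c("i", "j")) {
      id <- if (side == "i") p$id_i else p$id_j
      if (!is.null(out[[id]])) next
      mol <- if (side == "i") p$mol_i else p$mol_j
      out[[id]] <- fun(mol, featurize(mol), id)
    }
  }
  out
}

#' Evaluate attribution methods on the test pairs of one target
#'
#' For every (model, method) combination the test pairs are scored with the
#' global-direction metric and per-compound color agreement; every model
#' also gets test-set RMSE and Pearson correlation over the unique test
#' compounds. Pairs with an empty uncommon set are excluded from the
#' explainability metrics (their count is reported).
#'
#' @param split a `BenchmarkSplit`.
#' @param models named list of `TrainedGNN`s (names = loss modes).
#' @param methods GNN attribution methods to evaluate.
#' @param rf_model optional `RFModel` for the atom-masking baseline.
#' @param random_seed seed of the random-attribution baseline; `NULL`
#'   disables it.
#' @return list with `pair_results` (one row per evaluated pair x model x
#'   method), `color_agreement` (one row per pair side), `predictive` (one
#'   row per model), `n_unevaluable`.
#' @export
evaluate_target <- function(split, models,
                            methods = c("CAM", "GradCAM", "GradInput",
                                        "IntegratedGradients",
                                        "NodeMasking"),
                            rf_model = NULL, random_seed = NULL) {
  pairs <- split$test_pairs
  evaluable <- Filter(function(p) isTRUE(p$evaluable), pairs)
  n_unev <- length(pairs) - length(evaluable)
  tid <- split$target_id

  ids <- unique(unlist(lapply(pairs, function(p) c(p$id_i, p$id_j))))
  mol_of <- list()
  y_of <- numeric(0)
  for (p in pairs) {
    mol_of[[p$id_i]] <- p$mol_i; mol_of[[p$id_j]] <- p$mol_j
    y_of[p$id_i] <- p$activity_i; y_of[p$id_j] <- p$activity_j
  }

  pair_rows <- NULL
  ca_rows <- NULL
  pred_rows <- NULL

  score_attr_set <- function(attrs, model_label, method_label) {
    for (p in evaluable) {
      gd <- global_direction(p, attrs[[p$id_i]], attrs[[p$id_j]])
      pair_rows <<- rbind(pair_rows, data.frame(
        target_id = tid, pair_id = p$pair_id, model = model_label,
        method = method_label, g_dir = gd$g_dir,
        mcs_fraction = p$mcs_fraction,
        n_sites = max(p$sites_i, p$sites_j),
        delta_activity = p$delta_activity, stringsAsFactors = FALSE))
      for (side in c("i", "j")) {
        a <- if (side == "i") attrs[[p$id_i]] else attrs[[p$id_j]]
        ca <- color_agreement(p, side, a)
        ca_rows <<- rbind(ca_rows, data.frame(
          target_id = tid, pair_id = p$pair_id, model = model_label,
          method = method_label, compound_id = ca$compound_id,
          g_atom = ca$mean, stringsAsFactors = FALSE))
      }
    }
  }

  for (mode in names(models)) {
    model <- models[[mode]]
    yhat <- vapply(ids, function(id) {
      gnn_predict(model, mol_of[[id]])
    }, numeric(1))
    pred_rows <- rbind(pred_rows, data.frame(
      target_id = tid, model = mode,
      rmse = rmse(y_of[ids], yhat),
      pcc = if (length(ids) >= 2L) suppressWarnings(pcc(y_of[ids], yhat))
            else NA_real_,
      n_test_compounds = length(ids),
      n_test_pairs = length(evaluable), stringsAsFactors = FALSE))
    for (method in methods) {
      attrs <- .attribute_compounds(pairs, function(mol, graph, id) {
        attribute(model, graph, method, compound_id = id)
      })
      score_attr_set(attrs, mode, method)
    }
  }

  if (!is.null(rf_model)) {
    attrs <- .attribute_compounds(pairs, function(mol, graph, id) {
      rf_atom_masking(rf_model, mol, compound_id = id)
    })
    score_attr_set(attrs, "RF", "RFMasking")
    yhat <- rf_predict(rf_model, mol_of[ids])
    pred_rows <- rbind(pred_rows, data.frame(
      target_id = tid, model = "RF",
      rmse = rmse(y_of[ids], yhat),
      pcc = if (length(ids) >= 2L) suppressWarnings(pcc(y_of[ids], yhat))
            else NA_real_,
      n_test_compounds = length(ids),
      n_test_pairs = length(evaluable), stringsAsFactors = FALSE))
  }

  if (!is.null(random_seed)) {
    k <- 0L
    attrs <- .attribute_compounds(pairs, function(mol, graph, id) {
      k <<- k + 1L
      attr_random(graph, seed = random_seed + k, compound_id = id)
    })
    score_attr_set(attrs, "none", "Random")
  }

  list(pair_results = pair_rows, color_agreement = ca_rows,
       predictive = pred_rows, n_unevaluable = n_unev)
}

#' Run the full synthetic benchmark
#'
#' Generates the multi-target synthetic dataset, builds pairs and splits,
#' trains one GNN per loss mode and target, computes the requested
#' attribution methods plus the random-forest and random baselines, and
#' aggregates the global-direction, color-agreement, RMSE and correlation
#' metrics per target and overall (simple and pair-count-weighted means).
#'
#' @param n_targets,n_compounds,noise_sd synthetic dataset shape
#'   (defaults 5, 80, 0.1).
#' @param seed master seed for every stage.
#' @param config base [gnn_config()].
#' @param methods GNN attribution methods.
#' @param loss_modes training objectives (default all three).
#' @param mcs_threshold,min_delta,train_frac,min_train_pairs pipeline
#'   parameters.
#' @param min_pairs qualifying-pair guarantee passed to
#'   [generate_benchmark()].
#' @param include_rf,include_random include the baselines (default TRUE).
#' @return a `BenchmarkReport`: list with `pair_results`,
#'   `color_agreement`, `predictive`, `target_summary` (per target x model
#'   x method mean g_dir / g_atom), `aggregate` (per model x method simple
#'   and weighted means), `prep_log`, `diversity`, and the echoed
#'   configuration.
#' @export
run_benchmark <- function(n_targets = 5L, n_compounds = 80L, noise_sd = 0.1,
                          seed = 1L, config = gnn_config(),
                          methods = c("CAM", "GradCAM", "GradInput",
                                      "IntegratedGradients", "NodeMasking"),
                          loss_modes = c("MSE", "MSE+AC", "MSE+UCN"),
                          mcs_threshold = 0.5, min_delta = 1.0,
                          train_frac = 0.8, min_train_pairs = 50L,
                          min_pairs = 100L,
                          include_rf = TRUE, include_random = TRUE) {
  bench <- generate_benchmark(n_targets = n_targets,
                              n_compounds = n_compounds,
                              noise_sd = noise_sd, seed = seed,
                              min_pairs = min_pairs,
                              mcs_threshold = mcs_threshold,
                              min_delta = min_delta)
  prep <- prepare_benchmark(bench$records, mcs_threshold = mcs_threshold,
                            min_delta = min_delta, train_frac = train_frac,
                            split_seed = seed,
                            min_train_pairs = min_train_pairs)
  pair_results <- NULL; ca <- NULL; pred <- NULL
  diversity <- NULL
  for (tid in names(prep$splits)) {
    split <- prep$splits[[tid]]
    cfg <- config
    cfg$seed <- (config$seed + match(tid, names(prep$splits))) %% 2147483647L
    models <- train_loss_modes(split, cfg, loss_modes)
    rf_model <- NULL
    if (include_rf) {
      recs <- bench$records[bench$records$target_id == tid &
                              bench$records$compound_id %in%
                              split$train_compounds, ]
      class(recs) <- c("activity_records", "data.frame")
      rf_model <- rf_train(recs, seed = cfg$seed)
    }
    ev <- evaluate_target(split, models, methods = methods,
                          rf_model = rf_model,
                          random_seed = if (include_random) cfg$seed else NULL)
    pair_results <- rbind(pair_results, ev$pair_results)
    ca <- rbind(ca, ev$color_agreement)
    pred <- rbind(pred, ev$predictive)
    recs_t <- bench$records[bench$records$target_id == tid, ]
    class(recs_t) <- c("activity_records", "data.frame")
    diversity <- rbind(diversity, data.frame(
      target_id = tid, diversity = chemical_diversity(recs_t),
      stringsAsFactors = FALSE))
  }
  report <- summarize_benchmark(pair_results, ca, pred)
  structure(c(report, list(
    prep_log = prep$log, diversity = diversity,
    settings = list(n_targets = n_targets, n_compounds = n_compounds,
                    noise_sd = noise_sd, seed = seed, config = config,
                    methods = methods, loss_modes = loss_modes,
                    mcs_threshold = mcs_threshold, min_delta = min_delta,
                    train_frac = train_frac,
                    min_train_pairs = min_train_pairs))),
    class = "BenchmarkReport")
}

#' Summarize raw benchmark result tables
#'
#' @param pair_results,color_agreement,predictive tables as produced by
#'   [evaluate_target()] (possibly row-bound over targets).
#' @return list with `pair_results`, `color_agreement`, `predictive`,
#'   `target_summary`, `aggregate`.
#' @export
summarize_benchmark <- function(pair_results, color_agreement, predictive) {
  ts <- stats::aggregate(g_dir ~ target_id + model + method,
                         data = pair_results, FUN = mean)
  ts$n_pairs <- stats::aggregate(g_dir ~ target_id + model + method,
                                 data = pair_results, FUN = length)$g_dir
  ca_t <- stats::aggregate(g_atom ~ target_id + model + method,
                           data = color_agreement, FUN = mean)
  ts <- merge(ts, ca_t, all.x = TRUE)

  agg <- NULL
  for (key in unique(paste(ts$model, ts$method, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- ts[ts$model == parts[1] & ts$method == parts[2], ]
    gd <- aggregate_metric(sub$g_dir, sub$n_pairs)
    ga <- aggregate_metric(sub$g_atom, sub$n_pairs)
    agg <- rbind(agg, data.frame(
      model = parts[1], method = parts[2],
      g_dir_mean = gd$simple_mean, g_dir_weighted = gd$weighted_mean,
      g_dir_sd = gd$sd,
      g_atom_mean = ga$simple_mean, g_atom_weighted = ga$weighted_mean,
      n_targets = gd$n, stringsAsFactors = FALSE))
  }
  pred_agg <- NULL
  if (!is.null(predictive)) {
    for (m in unique(predictive$model)) {
      sub <- predictive[predictive$model == m, ]
      r <- aggregate_metric(sub$rmse, sub$n_test_pairs)
      p <- aggregate_metric(sub$pcc, sub$n_test_pairs)
      pred_agg <- rbind(pred_agg, data.frame(
        model = m, rmse_mean = r$simple_mean,
        rmse_weighted = r$weighted_mean,
        pcc_mean = p$simple_mean, pcc_weighted = p$weighted_mean,
        stringsAsFactors = FALSE))
    }
  }
  list(pair_results = pair_results, color_agreement = color_agreement,
       predictive = predictive, target_summary = ts,
       aggregate = agg, predictive_aggregate = pred_agg)
}

#' @export
print.BenchmarkReport <- function(x, ...) {
  cat("Benchmark report over", length(unique(x$pair_results$target_id)),
      "targets\n\nGlobal direction (mean over targets):\n")
  print(x$aggregate[order(x$aggregate$model, x$aggregate$method),
                    c("model", "method", "g_dir_mean", "g_dir_weighted",
                      "g_atom_mean")],
        row.names = FALSE, digits = 3)
  cat("\nPredictive performance:\n")
  print(x$predictive_aggregate, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a benchmark report to disk
#'
#' One CSV with the per-pair rows plus one JSON with the per-target and
#' aggregate summaries and the full settings echo.
#'
#' @param report a `BenchmarkReport`.
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "pair_results.csv")
  utils::write.csv(report$pair_results, csv, row.names = FALSE)
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(target_summary = report$target_summary,
         aggregate = report$aggregate,
         predictive = report$predictive,
         predictive_aggregate = report$predictive_aggregate,
         prep_log = report$prep_log,
         diversity = report$diversity,
         settings = report$settings),
    js, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(csv, js))
}
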