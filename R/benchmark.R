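#' Configure an end-to-end benchmark run
#'
#' @param data A [sim_config()] for a synthetic cohort, or a directory path
#'   holding the delimited-text cohort dialect ([write_cgm_csv()]).
#' @param specs Model ids to benchmark ([zoo_spec_ids()] by default);
#'   ensemble specs automatically pull in their members.
#' @param horizons Prediction horizons in minutes.
#' @param protocol A [training_protocol()].
#' @param alpha,n_bootstrap,block_length Comparison settings (Model
#'   Confidence Set / Superior Predictive Ability).
#' @param pl_samples Posterior draws for the Plackett-Luce ranking.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param seed Global seed; one config plus one seed determines every output.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(data = sim_config(), specs = zoo_spec_ids(),
                             horizons = c(30, 60, 120),
                             protocol = training_protocol(),
                             alpha = 0.05, n_bootstrap = 1000,
                             block_length = 5, pl_samples = 2000,
                             out_dir = NULL, seed = 1L) {
  stopifnot(all(specs %in% zoo_spec_ids()))
  structure(list(data = data, specs = specs, horizons = horizons,
                 protocol = protocol, alpha = alpha,
                 n_bootstrap = n_bootstrap, block_length = block_length,
                 pl_samples = pl_samples, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "benchmark_config")
}

#' Run the full forecasting benchmark
#'
#' Orchestrates simulate/load, preprocess, cross-validated training of every
#' requested spec at every horizon, the seven-metric tables, Parkes
#' error-grid summaries, and the three loss-based comparison procedures
#' (Plackett-Luce ranking, Model Confidence Set, Superior Predictive
#' Ability) at 30, 60 and the combined 30+60 minute horizons. Ensembles are
#' evaluated from cached member predictions, so each member network is
#' trained exactly once per horizon and fold.
#'
#' @param config A [benchmark_config()].
#' @return A `benchmark_result` bundle: `predictions`, `metrics`,
#'   `metric_tables`, `peg`, `losses`, `comparison`, `manifest` and the
#'   execution `log` of training events.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  protocol <- config$protocol
  protocol$seed <- config$seed
  cohort <- if (inherits(config$data, "sim_config")) {
    cfg <- config$data
    cfg$seed <- config$seed
    simulate_cohort(cfg)
  } else {
    read_cgm_csv(config$data)
  }
  cohort <- fill_gaps(cohort)

  is_ens <- startsWith(config$specs, "ensemble_")
  singles <- unique(c(config$specs[!is_ens],
                      unlist(lapply(config$specs[is_ens], ensemble_members))))
  log <- list()
  predictions <- list()
  for (h in config$horizons) {
    for (sp in singles) {
      cv <- cross_validate(sp, cohort, horizon = h, protocol = protocol,
                           horizons = sort(unique(c(config$horizons, 30, 60))))
      predictions[[paste(sp, h)]] <- cv$predictions
      log[[length(log) + 1]] <- tibble::tibble(event = "train", spec = sp,
                                               horizon = h)
    }
    for (sp in config$specs[is_ens]) {
      members <- ensemble_members(sp)
      member_preds <- lapply(members, function(m) predictions[[paste(m, h)]])
      joined <- dplyr::bind_rows(member_preds)
      ens <- dplyr::summarise(
        dplyr::group_by(joined, .data$patient_id, .data$fold, .data$horizon,
                        .data$time, .data$actual),
        predicted = clip_predictions(mean(.data$predicted)), .groups = "drop"
      )
      ens$model <- sp
      predictions[[paste(sp, h)]] <- ens[names(member_preds[[1]])]
      log[[length(log) + 1]] <- tibble::tibble(event = "ensemble", spec = sp,
                                               horizon = h)
    }
  }
  predictions <- dplyr::bind_rows(predictions)

  metrics <- dplyr::ungroup(dplyr::group_modify(
    dplyr::group_by(predictions, .data$model, .data$horizon,
                    .data$patient_id, .data$fold),
    function(d, key) compute_metrics(d)
  ))
  metric_tables <- lapply(stats::setNames(config$horizons, config$horizons),
                          function(h) {
    aggregate_patients(metrics[metrics$horizon == h, ])
  })
  peg <- dplyr::ungroup(dplyr::group_modify(
    dplyr::group_by(predictions, .data$model, .data$horizon),
    function(d, key) {
      s <- peg_summary(d)
      tibble::tibble(zone = s$zone, count = s$count, pct = s$pct,
                     ab_pct = attr(s, "ab_pct"))
    }
  ))
  losses <- dplyr::select(
    dplyr::summarise(
      dplyr::group_by(metrics, .data$model, .data$horizon, .data$patient_id,
                      .data$fold),
      loss = .data$rmse[1], .groups = "drop"),
    "model", "horizon", "patient_id", "fold", "loss")

  comparison <- run_comparisons(losses, config)

  bundle <- structure(list(predictions = predictions, metrics = metrics,
                           metric_tables = metric_tables, peg = peg,
                           losses = losses, comparison = comparison,
                           log = dplyr::bind_rows(log), config = config),
                      class = "benchmark_result")
  bundle$manifest <- benchmark_manifest(bundle)
  if (!is.null(config$out_dir)) write_benchmark(bundle, config$out_dir)
  bundle
}

run_comparisons <- function(losses, config) {
  lm_for <- function(h) {
    loss_matrix(losses[losses$horizon == h,
                       c("patient_id", "fold", "model", "loss")])
  }
  sets <- list()
  if (30 %in% losses$horizon) sets[["30"]] <- lm_for(30)
  if (60 %in% losses$horizon) sets[["60"]] <- lm_for(60)
  if (all(c(30, 60) %in% losses$horizon)) {
    sets[["30+60"]] <- multi_horizon(sets[["30"]], sets[["60"]])
  }
  lapply(sets, function(L) {
    ok_rows <- nrow(L) >= 10
    list(
      pl = pl_ranking(L, n_samples = config$pl_samples,
                      seed = config$seed + 11L),
      mcs = if (ok_rows) mcs(L, alpha = config$alpha,
                             n_bootstrap = config$n_bootstrap,
                             block_length = config$block_length,
                             seed = config$seed + 13L),
      spa = if (ok_rows) dplyr::bind_rows(lapply(colnames(L), function(b) {
        spa(L, b, n_bootstrap = config$n_bootstrap,
            block_length = config$block_length, seed = config$seed + 17L)
      }))
    )
  })
}

benchmark_manifest <- function(bundle) {
  num <- function(x) round(unname(x), 10)
  list(
    specs = bundle$config$specs,
    horizons = bundle$config$horizons,
    seed = bundle$config$seed,
    n_predictions = nrow(bundle$predictions),
    rmse_by_model = lapply(split(bundle$losses$loss,
                                 paste(bundle$losses$model,
                                       bundle$losses$horizon)),
                           function(v) num(mean(v))),
    events = paste(bundle$log$event, bundle$log$spec, bundle$log$horizon)
  )
}

write_benchmark <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (h in names(bundle$metric_tables)) {
    readr::write_csv(bundle$metric_tables[[h]],
                     file.path(dir, paste0("metrics_", h, ".csv")))
    readr::write_csv(format_metric_table(bundle$metric_tables[[h]]),
                     file.path(dir, paste0("metrics_", h, "_wide.csv")))
  }
  readr::write_csv(bundle$peg, file.path(dir, "peg.csv"))
  readr::write_csv(bundle$losses, file.path(dir, "losses.csv"))
  for (h in names(bundle$comparison)) {
    cmp <- bundle$comparison[[h]]
    tag <- gsub("\\+", "u", h)
    readr::write_csv(cmp$pl$ranking, file.path(dir, paste0("pl_", tag, ".csv")))
    if (!is.null(cmp$mcs)) {
      readr::write_csv(cmp$mcs$p_values,
                       file.path(dir, paste0("mcs_", tag, ".csv")))
    }
    if (!is.null(cmp$spa)) {
      readr::write_csv(cmp$spa, file.path(dir, paste0("spa_", tag, ".csv")))
    }
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result> ", length(unique(x$predictions$model)), " models x ",
      length(x$config$horizons), " horizons, ",
      nrow(x$predictions), " prediction rows\n", sep = "")
  invisible(x)
}
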