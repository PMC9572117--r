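#' Read a pipeline run configuration
#'
#' YAML (or JSON) file with optional keys `pipelines`, `counts_per_class`,
#' `train_fraction`, `roi`, `epochs`, `noise_levels`, `n_seeds`, `seed`,
#' `out_dir`, and a `rig` block of [rig_config()] overrides applied to the
#' six default geometry cases. Missing keys fall back to the defaults of
#' [run_pipeline()].
#'
#' @param path Configuration file path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Run the full sway-classification pipeline
#'
#' End-to-end driver: simulate a labelled dataset on the six-geometry rig,
#' extract feature tables, split 60/40, fit the selected classifiers on the
#' training split and evaluate accuracy (`Q%`) and reliability
#' (`RI` mean/std) on both splits; optionally run the feature-noise
#' robustness protocol. When `out_dir` is given, feature tables, fitted
#' models (JSON) and reports (CSV + JSON, with a reproducibility block) are
#' written there.
#'
#' @param pipelines Subset of `c("threshold", "nf_time", "nf_dwt")`.
#' @param counts_per_class Patterns per class per geometry case (scalar or
#'   named vector; default 25, i.e. 600 patterns over six cases).
#' @param configs List of rig geometry cases (default [default_rig_cases()]).
#' @param train_fraction Training share of the split.
#' @param roi,epochs Neuro-fuzzy training parameters.
#' @param noise_levels Optional feature-noise percentages (must include 0)
#'   triggering [noise_robustness_protocol()].
#' @param n_seeds Corruption replicates per noise level.
#' @param seed Master seed controlling simulation, split and corruption.
#' @param out_dir Optional output directory.
#' @return List with `reports` (data.frame: pipeline, split, q_pct,
#'   ri_mean_pct, ri_std_pct, ...), `noise` (data.frame or NULL), `models`,
#'   `features` (list of the time/dwt tables and split indices), `seed`.
#' @export
run_pipeline <- function(pipelines = c("threshold", "nf_time", "nf_dwt"),
                         counts_per_class = 25,
                         configs = default_rig_cases(),
                         train_fraction = 0.6, roi = 0.3, epochs = 50,
                         noise_levels = NULL, n_seeds = 10,
                         seed = 1L, out_dir = NULL) {
  pipelines <- match.arg(pipelines, c("threshold", "nf_time", "nf_dwt"),
                         several.ok = TRUE)
  if (length(counts_per_class) == 1L && is.null(names(counts_per_class))) {
    counts_per_class <- stats::setNames(rep(counts_per_class, 4L),
                                        sway_classes)
  }
  message(sprintf("Simulating dataset (%d geometry cases) ...",
                  length(configs)))
  ds <- generate_dataset(configs, counts_per_class, seed = seed)
  if (!ds$N) stop("empty dataset; check counts", call. = FALSE)
  message(sprintf("  %d patterns", ds$N))

  message("Extracting features ...")
  need_time <- any(pipelines %in% c("threshold", "nf_time"))
  need_dwt <- "nf_dwt" %in% pipelines
  tab <- list()
  if (need_time) tab$time <- feature_table(ds, "time")
  if (need_dwt) tab$dwt <- feature_table(ds, "dwt")

  split <- split_dataset(ds$N, train_fraction, seed = seed)
  models <- list()
  rows <- list()
  for (p in pipelines) {
    ft <- if (p == "nf_dwt") tab$dwt else tab$time
    feat <- setdiff(names(ft), c("label", "pattern_id"))
    tr <- ft[split$train, , drop = FALSE]
    te <- ft[split$test, , drop = FALSE]
    message(sprintf("Fitting %s on %d training patterns ...", p, nrow(tr)))
    if (p == "threshold") {
      fit <- fit_thresholds(tr, tr$label, feature_names = feat,
                            or_groups = intersect_or_groups(feat))
      ev <- rbind(cbind(split = "train", eval_threshold_on(fit, tr)),
                  cbind(split = "test", eval_threshold_on(fit, te)))
    } else {
      fit <- anfis(as.matrix(tr[, feat]), tr$label, roi = roi,
                   epochs = epochs)
      ev <- rbind(cbind(split = "train", eval_anfis_on(fit, tr)),
                  cbind(split = "test", eval_anfis_on(fit, te)))
      ev$ri_jf_mean_pct <- NA_real_
      ev$ri_jf_std_pct <- NA_real_
    }
    models[[p]] <- fit
    rows[[p]] <- cbind(pipeline = p, ev)
  }
  reports <- do.call(rbind, rows)
  rownames(reports) <- NULL

  noise <- NULL
  if (!is.null(noise_levels)) {
    message("Running noise-robustness protocol ...")
    nr <- list()
    tm <- intersect(pipelines, c("threshold", "nf_time"))
    if (length(tm) && need_time) {
      nr$time <- noise_robustness_protocol(
        tab$time[split$train, ], tab$time[split$test, ], methods = tm,
        levels = noise_levels, n_seeds = n_seeds, roi = roi,
        epochs = epochs, seed = seed)
    }
    if (need_dwt) {
      nr$dwt <- noise_robustness_protocol(
        tab$dwt[split$train, ], tab$dwt[split$test, ], methods = "nf_dwt",
        levels = noise_levels, n_seeds = n_seeds, roi = roi,
        epochs = epochs, seed = seed)
    }
    noise <- do.call(rbind, nr)
    rownames(noise) <- NULL
  }

  result <- list(reports = reports, noise = noise, models = models,
                 features = c(tab, list(split = split)), seed = seed)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$reports, file.path(out_dir, "reports.csv"),
                   row.names = FALSE)
  if (!is.null(result$noise)) {
    utils::write.csv(result$noise, file.path(out_dir, "noise_reports.csv"),
                     row.names = FALSE)
  }
  for (tname in intersect(names(result$features), c("time", "dwt"))) {
    write_feature_table(result$features[[tname]],
                        file.path(out_dir, paste0("features_", tname, ".csv")))
  }
  for (m in names(result$models)) {
    path <- file.path(out_dir, paste0("model_", m, ".json"))
    if (inherits(result$models[[m]], "threshold_model")) {
      write_threshold_model(result$models[[m]], path)
    } else {
      write_anfis(result$models[[m]], path)
    }
  }
  repro <- list(
    seed = result$seed,
    package_version = as.character(utils::packageVersion("postsway")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(c(repro, list(reports = result$reports)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}
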