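#' Accuracy index Q%
#'
#' `Q% = 100 * (1 - sum(|PSpred - PSexp|) / N)` for binary prediction and
#' expectation vectors: the percentage of correctly classified patterns.
#'
#' @param predicted,expected Equal-length binary (0/1) vectors.
#' @return Accuracy in percent.
#' @examples
#' q_index(c(0, 1, 1), c(0, 1, 0)) # 66.7
#' @export
q_index <- function(predicted, expected) {
  predicted <- as.integer(predicted); expected <- as.integer(expected)
  if (length(predicted) != length(expected) || !length(predicted)) {
    stop("predicted and expected must be equal-length, non-empty",
         call. = FALSE)
  }
  100 * (1 - sum(abs(predicted - expected)) / length(predicted))
}

#' Reliability summary over a set of patterns
#'
#' Mean and sample standard deviation of per-pattern reliability indexes
#' (a single value yields std 0 by convention).
#'
#' @param ri Numeric vector of reliability percentages.
#' @return Named numeric vector `c(ri_mean, ri_std)`.
#' @export
ri_summary <- function(ri) {
  if (!length(ri)) stop("need at least one reliability value", call. = FALSE)
  s <- if (length(ri) > 1L) stats::sd(ri) else 0
  c(ri_mean = mean(ri), ri_std = s)
}

#' Randomised train/test split
#'
#' Seeded shuffle of the row indices; the first `round(train_fraction * N)`
#' go to the training set.
#'
#' @param n Number of patterns, or a data.frame whose rows are split.
#' @param train_fraction Fraction assigned to training (default 0.6).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (or, when a
#'   data.frame was given, the two row subsets).
#' @export
split_dataset <- function(n, train_fraction = 0.6, seed = 1L) {
  df <- NULL
  if (is.data.frame(n)) { df <- n; n <- nrow(df) }
  n <- as.integer(n)
  if (n < 2L) stop("need at least 2 patterns to split", call. = FALSE)
  if (train_fraction < 0 || train_fraction > 1) {
    stop("train_fraction must lie in [0, 1]", call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(n))
  n_train <- as.integer(round(train_fraction * n))
  train <- sort(idx[seq_len(n_train)])
  test <- sort(idx[setdiff(seq_len(n), seq_len(n_train))])
  if (!length(test)) warning("empty test set")
  if (is.null(df)) list(train = train, test = test)
  else list(train = df[train, , drop = FALSE], test = df[test, , drop = FALSE])
}

#' Sweep the range of influence of the neuro-fuzzy rule base
#'
#' Trains one Sugeno model per grid value on the training features and
#' evaluates accuracy and reliability on the test features. The best value
#' maximises test Q%; ties are resolved by larger reliability mean, then
#' smaller reliability std, then the smaller roi.
#'
#' @param train,test Feature data.frames with a `label` column (e.g. the
#'   two halves of a [split_dataset()] of a [feature_table()]).
#' @param roi_grid Candidate ranges of influence (default
#'   `seq(0.1, 0.6, by = 0.1)`).
#' @param epochs,step_size Training parameters per grid point.
#' @return List with `best_roi` and `reports` (one row per grid value:
#'   `roi, q_train, q_test, ri_mean, ri_std, n_rules`).
#' @export
roi_sweep <- function(train, test, roi_grid = seq(0.1, 0.6, by = 0.1),
                      epochs = 50, step_size = 0.01) {
  if (!length(roi_grid)) stop("empty roi grid", call. = FALSE)
  feat <- setdiff(names(train), c("label", "pattern_id"))
  rows <- list()
  for (roi in roi_grid) {
    rep_i <- tryCatch({
      fit <- anfis(as.matrix(train[, feat]), train$label, roi = roi,
                   epochs = epochs, step_size = step_size)
      pr_tr <- predict_status(fit, as.matrix(train[, feat]))
      pr_te <- predict_status(fit, as.matrix(test[, feat]))
      rs <- ri_summary(pr_te$ri)
      data.frame(roi = roi,
                 q_train = q_index(pr_tr$ps_round, train$label),
                 q_test = q_index(pr_te$ps_round, test$label),
                 ri_mean = rs[["ri_mean"]], ri_std = rs[["ri_std"]],
                 n_rules = nrow(fit$centers))
    }, error = function(e) {
      warning(sprintf("roi = %g failed: %s", roi, conditionMessage(e)))
      NULL
    })
    if (!is.null(rep_i)) rows[[length(rows) + 1L]] <- rep_i
  }
  if (!length(rows)) stop("every roi grid point failed", call. = FALSE)
  reports <- do.call(rbind, rows)
  ord <- order(-reports$q_test, -reports$ri_mean, reports$ri_std, reports$roi)
  list(best_roi = reports$roi[ord[1L]], reports = reports)
}

#' Corrupt a feature table with additive Gaussian noise
#'
#' Per feature column, i.i.d. zero-mean Gaussian noise is added with
#' standard deviation `level_pct`% of the column's maximum absolute value
#' over the table, so every feature is perturbed by a homogeneous relative
#' amount regardless of its units.
#'
#' @param features Feature data.frame (`label`/`pattern_id` columns are
#'   left untouched).
#' @param level_pct Noise level in percent (0 returns the table unchanged).
#' @param seed Integer seed.
#' @return The corrupted data.frame.
#' @export
add_feature_noise <- function(features, level_pct, seed = 1L) {
  if (level_pct < 0) stop("level_pct must be >= 0", call. = FALSE)
  if (level_pct == 0) return(features)
  feat <- setdiff(names(features), c("label", "pattern_id"))
  with_seed(seed, {
    for (f in feat) {
      scale <- max(abs(features[[f]]))
      features[[f]] <- features[[f]] +
        stats::rnorm(nrow(features), sd = level_pct / 100 * scale)
    }
    features
  })
}

eval_threshold_on <- function(model, features) {
  pr <- predict(model, features)
  rs <- ri_summary(pr$ri_th)
  rj <- ri_summary(pr$ri_jf)
  data.frame(q_pct = q_index(pr$ps_pred, features$label),
             ri_mean_pct = rs[["ri_mean"]], ri_std_pct = rs[["ri_std"]],
             ri_jf_mean_pct = rj[["ri_mean"]], ri_jf_std_pct = rj[["ri_std"]])
}

eval_anfis_on <- function(model, features) {
  feat <- setdiff(names(features), c("label", "pattern_id"))
  pr <- predict_status(model, as.matrix(features[, feat]))
  rs <- ri_summary(pr$ri)
  data.frame(q_pct = q_index(pr$ps_round, features$label),
             ri_mean_pct = rs[["ri_mean"]], ri_std_pct = rs[["ri_std"]])
}

#' Noise-robustness protocol
#'
#' Models are fitted once on the clean training features; the evaluation
#' features (test split by default, optionally also the training split) are
#' then corrupted at each requested noise level over several seeds, and
#' accuracy / reliability indexes are averaged across seeds. This probes how
#' gracefully each decision rule degrades when feature values drift toward
#' their class separators.
#'
#' @param train,test Clean feature data.frames with `label` columns. For
#'   the `"nf_dwt"` method pass DWT feature tables; the threshold and
#'   `"nf_time"` methods expect the six time-domain features.
#' @param methods Subset of `c("threshold", "nf_time", "nf_dwt")`. Each
#'   method is fitted on its own `train` table, so call once per feature
#'   type (the default runs `threshold` and `nf_time` which share tables).
#' @param levels Noise levels in percent; must include 0.
#' @param n_seeds Corruption replicates per level.
#' @param corrupt_train Also evaluate on the corrupted training split.
#' @param roi,epochs Neuro-fuzzy training parameters.
#' @param seed Base seed for the corruption replicates.
#' @return Data.frame with one row per (method, split, level):
#'   seed-averaged `q_pct`, `ri_mean_pct`, `ri_std_pct`.
#' @export
noise_robustness_protocol <- function(train, test,
                                      methods = c("threshold", "nf_time"),
                                      levels = c(0, 5, 10, 20),
                                      n_seeds = 10, corrupt_train = FALSE,
                                      roi = 0.3, epochs = 50, seed = 1L) {
  if (!0 %in% levels) stop("levels must include 0", call. = FALSE)
  methods <- match.arg(methods, c("threshold", "nf_time", "nf_dwt"),
                       several.ok = TRUE)
  feat <- setdiff(names(train), c("label", "pattern_id"))
  fits <- list()
  for (m in methods) {
    fits[[m]] <- if (m == "threshold") {
      fit_thresholds(train, train$label, feature_names = feat,
                     or_groups = intersect_or_groups(feat))
    } else {
      anfis(as.matrix(train[, feat]), train$label, roi = roi, epochs = epochs)
    }
  }
  splits <- list(test = test)
  if (corrupt_train) splits$train <- train
  rows <- list()
  for (m in methods) {
    for (sp in names(splits)) {
      for (lv in levels) {
        per_seed <- lapply(seq_len(n_seeds), function(s) {
          noisy <- add_feature_noise(splits[[sp]], lv,
                                     seed = seed + 1000L * s + lv)
          if (m == "threshold") eval_threshold_on(fits[[m]], noisy)
          else eval_anfis_on(fits[[m]], noisy)
        })
        agg <- as.data.frame(t(colMeans(do.call(rbind, per_seed))))
        if (is.null(agg$ri_jf_mean_pct)) {
          agg$ri_jf_mean_pct <- NA_real_
          agg$ri_jf_std_pct <- NA_real_
        }
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(method = m, split = sp, noise_level_pct = lv), agg)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# default OR grouping restricted to the features actually present
intersect_or_groups <- function(feat) {
  grps <- list(intersect(c("DAPmax", "DMLmax"), feat),
               intersect(c("DAPmin", "DMLmin"), feat))
  Filter(function(g) length(g) > 1L, grps)
}
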