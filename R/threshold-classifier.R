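#' Fit the ROC-calibrated threshold voting classifier
#'
#' For each sway feature a scalar cut-point is chosen on the training data by
#' maximising Youden's J statistic (sensitivity + specificity - 1) over all
#' candidate thresholds (midpoints between sorted unique values), the
#' standard ROC operating-point rule. Both orientations are considered, so a
#' feature whose low values indicate instability (the displacement minima)
#' gets polarity -1. Ties in J are broken toward the cut farther from the
#' unstable side (larger threshold for polarity +1), i.e. conservatively
#' toward "stable".
#'
#' At prediction time each feature casts a binary vote
#' `J_fbin = 1` iff it lies strictly on the unstable side of its threshold.
#' The two directional extrema `DAPmax` and `DMLmax` are strongly specific to
#' AP-only and ML-only instability respectively, so their votes are merged by
#' a logical OR into one effective vote; all remaining features vote
#' individually. A window is declared potentially unstable when at least 50%
#' of the effective votes are 1.
#'
#' The model also stores, per feature, the training-set maximum absolute
#' distance from the threshold; these normalisers turn feature-threshold
#' distances into the dimensionless JND used by the reliability index
#' [reliability_jf()].
#'
#' @param features Data.frame (or matrix) of training feature values; only
#'   the columns named in `feature_names` are used.
#' @param labels Binary vector (0 stable / 1 unstable), one per row.
#' @param feature_names Features entering the vote (default: the six
#'   time-domain features).
#' @param or_groups List of character vectors; each group is OR-merged into
#'   one effective vote. By default the directional extrema pairs
#'   `{DAPmax, DMLmax}` and `{DAPmin, DMLmin}` each form a group: a purely
#'   AP-unstable window moves only the AP extrema, so the paired ML extremum
#'   stays silent and would otherwise always dilute the vote.
#' @return An object of class `threshold_model` with fields `thresholds`,
#'   `directions`, `normalizers`, `feature_order`, `or_groups`, `effective`.
#' @seealso [predict.threshold_model()], [reliability_th()], [reliability_jf()]
#' @export
fit_thresholds <- function(features, labels,
                           feature_names = time_feature_names,
                           or_groups = list(c("DAPmax", "DMLmax"),
                                            c("DAPmin", "DMLmin"))) {
  features <- as.data.frame(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("features and labels disagree in length", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("training labels must contain both classes", call. = FALSE)
  }
  missing <- setdiff(feature_names, names(features))
  if (length(missing)) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (grp in or_groups) {
    if (!all(grp %in% feature_names)) {
      stop("or_groups must reference fitted features", call. = FALSE)
    }
  }
  thresholds <- directions <- normalizers <- stats::setNames(
    numeric(length(feature_names)), feature_names)
  for (f in feature_names) {
    fit <- youden_threshold(features[[f]], labels)
    thresholds[f] <- fit$threshold
    directions[f] <- fit$direction
    normalizers[f] <- max(abs(features[[f]] - fit$threshold))
    if (normalizers[f] == 0) {
      warning(sprintf("feature '%s' is constant; degenerate threshold", f))
    }
  }
  grouped <- unlist(or_groups)
  singles <- setdiff(feature_names, grouped)
  effective <- c(lapply(or_groups, identity), as.list(singles))
  names(effective) <- vapply(effective, paste, "", collapse = "|")
  structure(list(
    thresholds = thresholds, directions = directions,
    normalizers = normalizers, feature_order = feature_names,
    or_groups = or_groups, effective = effective
  ), class = "threshold_model")
}

# Youden-optimal cut over midpoints of sorted unique values, both polarities.
# Returns threshold, direction (+1: high values unstable) and J.
youden_threshold <- function(x, labels) {
  ux <- sort(unique(x))
  cand <- if (length(ux) > 1L) (ux[-1] + ux[-length(ux)]) / 2 else ux
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  best <- list(threshold = cand[1], direction = 1, j = -Inf)
  for (th in cand) {
    sens_hi <- sum(x > th & labels == 1L) / n1
    spec_hi <- sum(x <= th & labels == 0L) / n0
    j_hi <- sens_hi + spec_hi - 1
    sens_lo <- sum(x < th & labels == 1L) / n1
    spec_lo <- sum(x >= th & labels == 0L) / n0
    j_lo <- sens_lo + spec_lo - 1
    # polarity with the larger J wins; prefer +1 on polarity ties
    if (j_hi >= j_lo) {
      # tie in J across thresholds: keep the larger threshold (>= is toward
      # "stable" for direction +1)
      if (j_hi > best$j || (j_hi == best$j && best$direction == 1 && th > best$threshold)) {
        best <- list(threshold = th, direction = 1, j = j_hi)
      }
    } else if (j_lo > best$j) {
      best <- list(threshold = th, direction = -1, j = j_lo)
    }
  }
  best
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("Threshold voting posture classifier\n")
  df <- data.frame(threshold = x$thresholds,
                   direction = ifelse(x$directions > 0, "high", "low"),
                   normalizer = x$normalizers)
  print(df, digits = 4)
  cat("OR groups:",
      paste(vapply(x$or_groups, paste, "", collapse = " | "),
            collapse = "; "), "\n")
  cat(sprintf("Effective votes per window: %d\n", length(x$effective)))
  invisible(x)
}

#' @export
coef.threshold_model <- function(object, ...) object$thresholds

# signed distance toward the unstable side, per feature, for one row
signed_distance <- function(model, row) {
  vapply(model$feature_order, function(f) {
    model$directions[[f]] * (row[[f]] - model$thresholds[[f]])
  }, numeric(1))
}

#' Binary per-feature votes for one feature vector
#'
#' Applies each fitted threshold (strict inequality on the unstable side)
#' and collapses OR groups into effective votes.
#'
#' @param features Named numeric vector or one-row data.frame of feature
#'   values.
#' @param model A `threshold_model`.
#' @return A list of class `binary_vote`: `jfbin` (named 0/1 vector over
#'   effective votes), `raw` (per-feature 0/1 before grouping),
#'   `n_effective`, `fraction_over`.
#' @export
binarize <- function(features, model) {
  stopifnot(inherits(model, "threshold_model"))
  row <- as.list(as.data.frame(as.list(features)))
  missing <- setdiff(model$feature_order, names(row))
  if (length(missing)) {
    stop("missing feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dist <- signed_distance(model, row)
  raw <- as.integer(dist > 0)
  names(raw) <- model$feature_order
  jfbin <- vapply(model$effective, function(members) {
    as.integer(any(raw[members] == 1L))
  }, integer(1))
  structure(list(jfbin = jfbin, raw = raw,
                 n_effective = length(jfbin),
                 fraction_over = mean(jfbin)),
            class = "binary_vote")
}

#' Majority-vote classification of a binary vote
#'
#' Declares potential instability when at least 50% of the effective binary
#' votes are over threshold.
#'
#' @param vote A `binary_vote` from [binarize()].
#' @return Integer 0 (stable) or 1 (potentially unstable).
#' @export
classify_vote <- function(vote) {
  stopifnot(inherits(vote, "binary_vote"), vote$n_effective >= 1L)
  as.integer(vote$fraction_over >= 0.5)
}

#' Vote-based reliability index
#'
#' Distance of the mean binary vote from the class separator 0.5, rescaled
#' to a percentage: `RI_Th = 100 * |mean(J_fbin) - 0.5| / 0.5`. Unanimous
#' votes give 100; an evenly split vote gives 0.
#'
#' @param vote A `binary_vote`.
#' @return Reliability in percent, in `[0, 100]`.
#' @export
reliability_th <- function(vote) {
  stopifnot(inherits(vote, "binary_vote"), vote$n_effective >= 1L)
  100 * abs(vote$fraction_over - 0.5) / 0.5
}

#' Feature-distance reliability index
#'
#' Per effective feature, the just-noticeable distance
#' `JND = (J_F - J_th) / max|J_F - J_th|` (training-set normaliser, clipped
#' to `[-1, 1]`) measures how far the feature sits from its threshold. A
#' feature contributes `J_P = |JND|` when its binary decision agrees with
#' the predicted postural status and 0 otherwise; inside an OR group the
#' maximum member contribution is taken. `RI_JF = 100 * mean(J_P)`.
#'
#' @param features Named numeric vector or one-row data.frame.
#' @param model A `threshold_model`.
#' @param ps_pred Predicted binary postural status for this window.
#' @return Reliability in percent, in `[0, 100]`.
#' @export
reliability_jf <- function(features, model, ps_pred) {
  stopifnot(inherits(model, "threshold_model"))
  row <- as.list(as.data.frame(as.list(features)))
  dist <- signed_distance(model, row)
  jnd <- numeric(length(dist)); names(jnd) <- model$feature_order
  for (f in model$feature_order) {
    norm <- model$normalizers[[f]]
    if (norm == 0) {
      warning(sprintf("zero normaliser for '%s'; feature skipped", f))
      jnd[f] <- NA_real_
      next
    }
    jnd[f] <- pmin(1, pmax(-1, dist[[f]] / norm))
  }
  raw_bin <- as.integer(dist > 0)
  names(raw_bin) <- model$feature_order
  jp <- vapply(model$effective, function(members) {
    contrib <- vapply(members, function(f) {
      if (is.na(jnd[[f]])) return(NA_real_)
      if (raw_bin[[f]] == as.integer(ps_pred)) abs(jnd[[f]]) else 0
    }, numeric(1))
    if (all(is.na(contrib))) NA_real_ else max(contrib, na.rm = TRUE)
  }, numeric(1))
  100 * mean(jp, na.rm = TRUE)
}

#' Predict postural status with a fitted threshold model
#'
#' @param object A `threshold_model`.
#' @param newdata Data.frame of feature values (one row per window).
#' @param ... Unused.
#' @return Data.frame with columns `ps_pred` (0/1), `ri_th` and `ri_jf`
#'   (percent).
#' @export
predict.threshold_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  out <- lapply(seq_len(nrow(newdata)), function(i) {
    vote <- binarize(newdata[i, , drop = FALSE], object)
    ps <- classify_vote(vote)
    data.frame(ps_pred = ps,
               ri_th = reliability_th(vote),
               ri_jf = reliability_jf(newdata[i, , drop = FALSE], object, ps))
  })
  do.call(rbind, out)
}

#' Serialize / restore a threshold model as JSON
#'
#' @param model A `threshold_model`.
#' @param path JSON file path.
#' @return `write_threshold_model` returns `path` invisibly;
#'   `read_threshold_model` returns the model.
#' @export
write_threshold_model <- function(model, path) {
  stopifnot(inherits(model, "threshold_model"))
  jsonlite::write_json(list(
    thresholds = as.list(model$thresholds),
    directions = as.list(model$directions),
    normalizers = as.list(model$normalizers),
    feature_order = model$feature_order,
    or_groups = model$or_groups
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_threshold_model
#' @export
read_threshold_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  or_groups <- raw$or_groups
  if (is.matrix(or_groups)) {
    or_groups <- lapply(seq_len(nrow(or_groups)), function(i) or_groups[i, ])
  } else if (is.character(or_groups)) {
    or_groups <- list(or_groups)
  }
  feats <- raw$feature_order
  grouped <- unlist(or_groups)
  singles <- setdiff(feats, grouped)
  effective <- c(lapply(or_groups, identity), as.list(singles))
  names(effective) <- vapply(effective, paste, "", collapse = "|")
  structure(list(
    thresholds = unlist(raw$thresholds)[feats],
    directions = unlist(raw$directions)[feats],
    normalizers = unlist(raw$normalizers)[feats],
    feature_order = feats, or_groups = or_groups, effective = effective
  ), class = "threshold_model")
}
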