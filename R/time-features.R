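#' Confidence scaling factor for the sway ellipse
#'
#' Factor `c` such that the axis-aligned ellipse with semi-axes
#' `c * sigma_AP`, `c * sigma_ML` contains a fraction `p` of an uncorrelated
#' bivariate Gaussian scatter. Since the squared Mahalanobis radius is
#' chi-squared with 2 degrees of freedom, `c(p) = sqrt(qchisq(p, 2))`;
#' `c(0.95) = 2.4477`.
#'
#' @param p Coverage probability in (0, 1).
#' @return The scaling factor (dimensionless).
#' @examples
#' csf_for_confidence(0.95) # 2.4477
#' @export
csf_for_confidence <- function(p) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1)) {
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  }
  sqrt(stats::qchisq(p, df = 2))
}

#' Time-domain stabilogram features
#'
#' The six features used by the posture classifiers, computed on one
#' analysis window of the stabilogram:
#' * `DAPmax`, `DAPmin`, `DMLmax`, `DMLmin` — signed displacement extrema (m);
#' * `DRMS` — root-mean-square step length
#'   `sqrt(sum(dp_i^2) / Npairs)` where `dp_i` is the Euclidean distance
#'   between adjacent `(DAP, DML)` stabilogram points (m);
#' * `CEA95` — area `pi * a * b` of the ellipse containing 95% of the
#'   stabilogram scatter, with semi-axes `a = CSF * sd(DAP)`,
#'   `b = CSF * sd(DML)` and `CSF = 2.4477` (m^2).
#'
#' Invalid (`NA`) samples are dropped before computation.
#'
#' @param stab A [compute_displacements()] `stabilogram` (or any list with
#'   numeric `dap` and `dml`).
#' @param confidence Ellipse coverage probability (default 0.95).
#' @return A named numeric vector of length 6 in the canonical order
#'   `DAPmax, DAPmin, DMLmax, DMLmin, DRMS, CEA95`.
#' @export
extract_time_features <- function(stab, confidence = 0.95) {
  dap <- stab$dap; dml <- stab$dml
  keep <- is.finite(dap) & is.finite(dml)
  dap <- dap[keep]; dml <- dml[keep]
  if (length(dap) < 2L) {
    stop("need at least 2 valid stabilogram samples", call. = FALSE)
  }
  dp <- sqrt(diff(dap)^2 + diff(dml)^2)
  csf <- csf_for_confidence(confidence)
  c(DAPmax = max(dap), DAPmin = min(dap),
    DMLmax = max(dml), DMLmin = min(dml),
    DRMS = sqrt(mean(dp^2)),
    CEA95 = pi * (csf * stats::sd(dap)) * (csf * stats::sd(dml)))
}

time_feature_names <- c("DAPmax", "DAPmin", "DMLmax", "DMLmin", "DRMS", "CEA95")

#' Feature table for a whole dataset
#'
#' Runs every pattern through the pre-filter / displacement-reconstruction /
#' feature-extraction chain and assembles one row per pattern with the class
#' label attached.
#'
#' @param dataset A `sway_dataset` from [generate_dataset()].
#' @param type `"time"` for the six time-domain features, `"dwt"` for the
#'   nine wavelet features (see [extract_dwt_features()]).
#' @param cutoff Pre-filter cutoff in Hz; 0 disables filtering.
#' @param ... Passed on to the feature extractor.
#' @return A data.frame: `pattern_id`, feature columns, `label`.
#' @export
feature_table <- function(dataset, type = c("time", "dwt"), cutoff = 5, ...) {
  stopifnot(inherits(dataset, "sway_dataset"))
  type <- match.arg(type)
  rows <- lapply(dataset$patterns, function(p) {
    stab <- pattern_stabilogram(p, cutoff = cutoff)
    f <- switch(type,
                time = extract_time_features(stab, ...),
                dwt = extract_dwt_features(stab, ...))
    if (any(!is.finite(f))) {
      stop(sprintf("non-finite feature for pattern %d", p$pattern_id),
           call. = FALSE)
    }
    cbind(data.frame(pattern_id = p$pattern_id), as.data.frame(t(f)),
          data.frame(label = p$label_binary))
  })
  do.call(rbind, rows)
}

#' Write / read a feature table as CSV
#'
#' @param features Data.frame as produced by [feature_table()].
#' @param path CSV path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the data.frame.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path)
}
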