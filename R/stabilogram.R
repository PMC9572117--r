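#' Zero-phase low-pass pre-filter for acceleration series
#'
#' 4th-order Butterworth low-pass, applied forward-backward
#' ([signal::filtfilt()]) so the filtered series has zero phase lag and the
#' DC (gravity) component is preserved. Sway dynamics live well below the
#' default 5 Hz cutoff; higher-frequency sensor noise is rejected.
#'
#' @param x Numeric series (one acceleration axis), or a data.frame whose
#'   numeric columns are each filtered.
#' @param fs Sampling rate in Hz; must exceed twice the cutoff.
#' @param cutoff Low-pass cutoff frequency in Hz.
#' @param order Butterworth order.
#' @return Filtered series of the same length/shape.
#' @export
prefilter <- function(x, fs, cutoff = 5, order = 4) {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  if (fs <= 2 * cutoff) stop("fs must exceed twice the cutoff", call. = FALSE)
  if (is.data.frame(x)) {
    x[] <- lapply(x, function(col) {
      if (is.numeric(col)) prefilter(col, fs, cutoff, order) else col
    })
    return(x)
  }
  L <- length(x)
  if (L <= 3 * (order + 1)) {
    stop("series too short for the pre-filter warm-up", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # odd-reflection padding so the forward-backward passes warm up outside
  # the data; pad length chosen so the slowest pole's transient decays
  # below 1e-13 before the data starts
  rmax <- max(abs(polyroot(rev(bf$a))))
  npad <- min(L - 1L, max(50L, ceiling(log(1e-13) / log(rmax))))
  left <- 2 * x[1L] - x[(npad + 1L):2L]
  right <- 2 * x[L] - x[(L - 1L):(L - npad)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(npad + 1L):(npad + L)]
}

#' Reconstruct stabilogram displacements from tri-axial acceleration
#'
#' Antero-posterior and medio-lateral displacements of the sensor node are
#' obtained by projecting the gravity direction onto the node geometry:
#' \deqn{D_{AP} = H_1 \frac{A_z}{\sqrt{A_y^2 + A_x^2}}, \qquad
#'       D_{ML} = H_2 \frac{A_x}{\sqrt{A_y^2 + A_z^2}}}
#' with lever-arm heights `H1` (bottom joint) and `H2` (belt joint).
#' Samples with a vanishing denominator (free-fall-like) are flagged invalid
#' (`NA`) and excluded downstream.
#'
#' @param accel A data.frame with columns `ax`, `ay`, `az` (m/s^2), e.g. the
#'   output of [tilt_to_acceleration()] or [read_pattern()].
#' @param H1,H2 Lever arms in metres.
#' @param fs Sampling rate in Hz (carried along for downstream use).
#' @return An object of class `stabilogram`: list with numeric vectors
#'   `dap`, `dml` (metres), `fs`, and logical `valid`.
#' @examples
#' s <- compute_displacements(data.frame(ax = 0, ay = 9.76, az = 0.98),
#'                            H1 = 1.2, H2 = 0.5)
#' s$dap  # 1.2 * 0.98 / 9.76
#' @export
compute_displacements <- function(accel, H1, H2, fs = 100) {
  need <- c("ax", "ay", "az")
  if (!is.data.frame(accel) || !all(need %in% names(accel))) {
    stop("'accel' must be a data.frame with columns ax, ay, az", call. = FALSE)
  }
  stopifnot_scalar_number(H1, "H1", positive = TRUE)
  stopifnot_scalar_number(H2, "H2", positive = TRUE)
  ax <- accel$ax; ay <- accel$ay; az <- accel$az
  den_ap <- sqrt(ay^2 + ax^2)
  den_ml <- sqrt(ay^2 + az^2)
  valid <- den_ap > 0 & den_ml > 0
  if (!all(valid)) {
    warning(sprintf("%d sample(s) with zero denominator marked invalid",
                    sum(!valid)))
  }
  dap <- ifelse(valid, H1 * az / den_ap, NA_real_)
  dml <- ifelse(valid, H2 * ax / den_ml, NA_real_)
  structure(list(dap = dap, dml = dml, fs = fs, valid = valid),
            class = "stabilogram")
}

#' @export
print.stabilogram <- function(x, ...) {
  cat(sprintf("Stabilogram: %d samples at %g Hz (%d invalid)\n",
              length(x$dap), x$fs, sum(!x$valid)))
  cat(sprintf("  DAP range [%.4g, %.4g] m, DML range [%.4g, %.4g] m\n",
              min(x$dap, na.rm = TRUE), max(x$dap, na.rm = TRUE),
              min(x$dml, na.rm = TRUE), max(x$dml, na.rm = TRUE)))
  invisible(x)
}

#' Segment a series into overlapping analysis windows
#'
#' Maximal list of contiguous windows of `window_s * fs` samples whose
#' starts are `shift_s * fs` samples apart (10 s windows shifted by 1 s at
#' the default monitoring configuration).
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds.
#' @param shift_s Shift between successive window starts in seconds.
#' @return A list of numeric windows (possibly empty, with a warning, when
#'   the series is shorter than one window).
#' @export
sliding_windows <- function(x, fs, window_s = 10, shift_s = 1) {
  n_win <- as.integer(round(window_s * fs))
  n_shift <- as.integer(round(shift_s * fs))
  if (n_win < 1 || n_shift < 1) stop("window and shift must be positive")
  L <- length(x)
  if (L < n_win) {
    warning("series shorter than one window; returning no windows")
    return(list())
  }
  starts <- seq.int(1L, L - n_win + 1L, by = n_shift)
  lapply(starts, function(s) x[s:(s + n_win - 1L)])
}

#' Write a stabilogram to CSV
#'
#' Columns `t, dap, dml`; invalid samples are written as empty fields.
#'
#' @param stab A `stabilogram`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_stabilogram <- function(stab, path) {
  stopifnot(inherits(stab, "stabilogram"))
  df <- data.frame(t = (seq_along(stab$dap) - 1L) / stab$fs,
                   dap = stab$dap, dml = stab$dml)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# Full per-pattern chain: pre-filter raw accelerations, then reconstruct
# displacements with the pattern's own geometry.
pattern_stabilogram <- function(pattern, cutoff = 5) {
  cfg <- pattern$config
  acc <- pattern$accel
  if (cutoff > 0) acc <- prefilter(acc, fs = cfg$fs, cutoff = cutoff)
  compute_displacements(acc, H1 = cfg$H1, H2 = cfg$H2, fs = cfg$fs)
}
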