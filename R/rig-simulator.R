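#' Rig configuration for synthetic sway pattern generation
#'
#' Describes one geometry case of the mechanical rig that mimics standing
#' postural sway: a chest-height sensor on a structure that can tilt about a
#' bottom joint (antero-posterior, AP, lever arm `H1`) and a belt joint
#' (medio-lateral, ML, lever arm `H2`). Tilt dynamics are band-limited
#' stochastic rotations; the class of a pattern ("ST", "AP", "ML", "UNS")
#' decides which axes move with the large (unstable) amplitude.
#'
#' @param H1 Bottom-joint lever arm in metres (AP displacement scale).
#' @param H2 Belt-joint lever arm in metres (ML displacement scale).
#' @param fs Sampling rate in Hz.
#' @param window_s Pattern duration in seconds.
#' @param g Gravitational acceleration in m/s^2.
#' @param sway_band Two-element frequency interval (Hz) from which tilt
#'   sinusoid frequencies are drawn; must stay below the Nyquist rate.
#' @param amp_stable Peak tilt amplitude (rad) of a stable axis.
#' @param amp_unstable Peak tilt amplitude (rad) of an unstable axis; must
#'   exceed `amp_stable`.
#' @param instability_displacement Displacement (m) above which a pattern
#'   counts as unstable; used by the separability checks, not by labelling
#'   (labels follow the imposed movement class).
#' @param sensor_noise_std Standard deviation (m/s^2) of additive Gaussian
#'   accelerometer noise.
#' @param seed Integer seed associated with patterns drawn under this
#'   configuration.
#'
#' @return An object of class `rig_config` (a validated named list).
#' @examples
#' cfg <- rig_config(H1 = 1.2, H2 = 0.5)
#' cfg$fs
#' @export
rig_config <- function(H1 = 1.0, H2 = 0.5, fs = 100, window_s = 10,
                       g = 9.81, sway_band = c(0.1, 2),
                       amp_stable = 0.02, amp_unstable = 0.12,
                       instability_displacement = 0.05,
                       sensor_noise_std = 0, seed = 1L) {
  stopifnot_scalar_number(H1, "H1", positive = TRUE)
  stopifnot_scalar_number(H2, "H2", positive = TRUE)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  stopifnot_scalar_number(window_s, "window_s", positive = TRUE)
  stopifnot_scalar_number(g, "g", positive = TRUE)
  stopifnot_scalar_number(amp_stable, "amp_stable")
  stopifnot_scalar_number(amp_unstable, "amp_unstable")
  stopifnot_scalar_number(sensor_noise_std, "sensor_noise_std")
  if (amp_stable < 0 || amp_unstable <= amp_stable) {
    stop("need amp_unstable > amp_stable >= 0", call. = FALSE)
  }
  n <- window_s * fs
  if (abs(n - round(n)) > 1e-9 || round(n) < 2) {
    stop("window_s * fs must be an integer >= 2", call. = FALSE)
  }
  if (length(sway_band) != 2L || sway_band[1] <= 0 ||
      sway_band[2] <= sway_band[1] || sway_band[2] >= fs / 2) {
    stop("sway_band must be an increasing interval inside (0, fs/2)",
         call. = FALSE)
  }
  structure(list(
    H1 = H1, H2 = H2, fs = fs, window_s = window_s, g = g,
    sway_band = as.numeric(sway_band),
    amp_stable = amp_stable, amp_unstable = amp_unstable,
    instability_displacement = instability_displacement,
    sensor_noise_std = sensor_noise_std, seed = as.integer(seed)
  ), class = "rig_config")
}

#' @export
print.rig_config <- function(x, ...) {
  cat("Rig configuration\n")
  cat(sprintf("  lever arms: H1 = %.3g m (AP), H2 = %.3g m (ML)\n", x$H1, x$H2))
  cat(sprintf("  sampling: %g Hz, %g s windows (%d samples)\n",
              x$fs, x$window_s, as.integer(round(x$window_s * x$fs))))
  cat(sprintf("  tilt amplitudes: stable %.3g rad, unstable %.3g rad, band [%g, %g] Hz\n",
              x$amp_stable, x$amp_unstable, x$sway_band[1], x$sway_band[2]))
  cat(sprintf("  sensor noise sd: %g m/s^2\n", x$sensor_noise_std))
  invisible(x)
}

sway_classes <- c("ST", "AP", "ML", "UNS")

#' Simulate band-limited tilt dynamics for one sway pattern
#'
#' Each tilt axis is a superposition of five sinusoids with uniform random
#' phases and frequencies drawn inside `config$sway_band` by stratified
#' sampling — one component uniform in each fifth of the band — then
#' amplitude-normalised so the peak absolute tilt equals the class
#' amplitude: both axes stable for "ST", the named axis unstable for
#' "AP"/"ML", both unstable for "UNS". Stratification guarantees every
#' pattern carries energy across the whole sway band, so spectral and
#' path-increment features scale with the class amplitude rather than with
#' a lucky frequency draw. Two further touches emulate manual rig
#' operation: each axis amplitude is jittered by a uniform factor in
#' `[0.85, 1]` (imposed movements vary in magnitude, and exact-amplitude
#' duplicates would be an artefact of peak normalisation), and the held
#' axis of a single-axis "AP"/"ML" movement shows only residual wobble at
#' half the stable amplitude (the operator steadies the unused joint).
#' Deterministic for a fixed `(config, seed)`.
#'
#' @param label_class One of `"ST"`, `"AP"`, `"ML"`, `"UNS"`.
#' @param config A [rig_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list with numeric vectors `theta_ap` and `theta_ml` (radians)
#'   of length `window_s * fs`.
#' @export
simulate_tilt_trace <- function(label_class, config, seed = config$seed) {
  if (!inherits(config, "rig_config")) stop("'config' must be a rig_config")
  label_class <- match.arg(label_class, sway_classes)
  n <- as.integer(round(config$window_s * config$fs))
  t <- seq_len(n) / config$fs
  quiet <- 0.5 * config$amp_stable
  amp_ap <- switch(label_class, ST = config$amp_stable, ML = quiet,
                   config$amp_unstable)
  amp_ml <- switch(label_class, ST = config$amp_stable, AP = quiet,
                   config$amp_unstable)
  with_seed(seed, {
    mk <- function(amp) {
      if (amp == 0) return(numeric(n))
      edges <- seq(config$sway_band[1], config$sway_band[2], length.out = 6)
      f <- stats::runif(5, edges[-6], edges[-1])
      ph <- stats::runif(5, 0, 2 * pi)
      jitter <- stats::runif(1, 0.85, 1)
      x <- rowSums(vapply(seq_len(5),
                          function(i) sin(2 * pi * f[i] * t + ph[i]),
                          numeric(n)))
      peak <- max(abs(x))
      if (peak == 0) return(numeric(n))
      jitter * amp * x / peak
    }
    list(theta_ap = mk(amp_ap), theta_ml = mk(amp_ml))
  })
}

#' Project tilt angles onto tri-axial accelerometer readings
#'
#' Quasi-static gravity-projection model of the rig sensor: with the
#' longitudinal axis y aligned with gravity at rest, anterior axis z and
#' lateral axis x,
#' `Az = g*sin(theta_ap)`, `Ax = g*sin(theta_ml)`,
#' `Ay = g*cos(theta_ap)*cos(theta_ml)`, plus optional zero-mean Gaussian
#' sensor noise on each axis. Feeding a noiseless single-axis output through
#' the displacement reconstruction recovers `H*tan(theta)` exactly.
#'
#' @param theta_ap,theta_ml Equal-length tilt series in radians.
#' @param config A [rig_config()].
#' @param seed Seed for the sensor noise draw (defaults to `config$seed`).
#' @return A data.frame with columns `ax`, `ay`, `az` in m/s^2.
#' @export
tilt_to_acceleration <- function(theta_ap, theta_ml, config,
                                 seed = config$seed) {
  if (!inherits(config, "rig_config")) stop("'config' must be a rig_config")
  if (length(theta_ap) != length(theta_ml)) {
    stop("tilt series must have equal length", call. = FALSE)
  }
  n <- length(theta_ap)
  acc <- data.frame(
    ax = config$g * sin(theta_ml),
    ay = config$g * cos(theta_ap) * cos(theta_ml),
    az = config$g * sin(theta_ap)
  )
  if (config$sensor_noise_std > 0) {
    acc <- with_seed(seed, {
      acc + matrix(stats::rnorm(3L * n, sd = config$sensor_noise_std),
                   ncol = 3L)
    })
  }
  acc
}

#' Generate a labelled synthetic sway dataset
#'
#' Produces `counts` patterns of each movement class under each geometry
#' case. Binary labels follow the imposed movement: 0 for "ST", 1 for "AP",
#' "ML" and "UNS". Reproducible: the per-pattern seed is derived from `seed`,
#' the case index and the pattern index.
#'
#' @param configs List of [rig_config()] objects, one per geometry case.
#' @param counts Per-class pattern counts. Either a named vector applied to
#'   every case (names among ST/AP/ML/UNS) or a matrix/data.frame with one
#'   row per class (rownames ST/AP/ML/UNS) and one column per case.
#' @param seed Master integer seed.
#' @return An object of class `sway_dataset`: list with `patterns` (each a
#'   list with `accel`, `label_class`, `label_binary`, `case_id`, `config`,
#'   `seed`) and `manifest` (a data.frame summary).
#' @examples
#' ds <- generate_dataset(list(rig_config()), counts = c(ST = 2, UNS = 2),
#'                        seed = 7)
#' ds$manifest
#' @export
generate_dataset <- function(configs, counts, seed = 1L) {
  if (inherits(configs, "rig_config")) configs <- list(configs)
  if (!length(configs) || !all(vapply(configs, inherits, TRUE, "rig_config"))) {
    stop("'configs' must be a list of rig_config objects", call. = FALSE)
  }
  n_case <- length(configs)
  if (is.matrix(counts) || is.data.frame(counts)) {
    counts <- as.matrix(counts)
    if (ncol(counts) != n_case) {
      stop("counts matrix needs one column per geometry case", call. = FALSE)
    }
    cmat <- matrix(0L, nrow = 4L, ncol = n_case, dimnames = list(sway_classes))
    cmat[rownames(counts), ] <- as.integer(counts)
  } else {
    cvec <- integer(4L); names(cvec) <- sway_classes
    cvec[names(counts)] <- as.integer(counts)
    cmat <- matrix(cvec, nrow = 4L, ncol = n_case, dimnames = list(sway_classes))
  }
  if (any(cmat < 0)) stop("counts must be non-negative", call. = FALSE)

  patterns <- list()
  rows <- list()
  pat_id <- 0L
  for (case_id in seq_len(n_case)) {
    cfg <- configs[[case_id]]
    for (cls in sway_classes) {
      for (k in seq_len(cmat[cls, case_id])) {
        pat_id <- pat_id + 1L
        # distinct, reproducible sub-seed per pattern; kept inside 2^31
        pseed <- (as.integer(seed) * 7919L + case_id * 104729L +
                    match(cls, sway_classes) * 13007L + k * 31L) %% 2147483647L
        tilt <- simulate_tilt_trace(cls, cfg, seed = pseed)
        accel <- tilt_to_acceleration(tilt$theta_ap, tilt$theta_ml, cfg,
                                      seed = pseed + 1L)
        lab <- as.integer(cls != "ST")
        patterns[[pat_id]] <- list(
          pattern_id = pat_id, case_id = case_id, label_class = cls,
          label_binary = lab, accel = accel, config = cfg, seed = pseed
        )
        rows[[pat_id]] <- data.frame(
          pattern_id = pat_id, case_id = case_id, class = cls, label = lab,
          H1 = cfg$H1, H2 = cfg$H2, seed = pseed
        )
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pattern_id = integer(), case_id = integer(),
               class = character(), label = integer(),
               H1 = numeric(), H2 = numeric(), seed = integer())
  structure(list(patterns = patterns, manifest = manifest,
                 N = length(patterns)),
            class = "sway_dataset")
}

#' @export
print.sway_dataset <- function(x, ...) {
  cat(sprintf("Synthetic sway dataset: %d patterns\n", x$N))
  if (x$N) print(table(class = x$manifest$class, case = x$manifest$case_id))
  invisible(x)
}

#' Default six-case rig geometry
#'
#' Geometry cases formed by crossing bottom-joint heights
#' `H1` in {1.0, 1.1, 1.2} m with belt-joint heights `H2` in {0.5, 0.6} m.
#'
#' @param ... Further arguments passed to [rig_config()] for every case.
#' @return A list of six `rig_config` objects.
#' @export
default_rig_cases <- function(...) {
  grid <- expand.grid(H1 = c(1.0, 1.1, 1.2), H2 = c(0.5, 0.6))
  lapply(seq_len(nrow(grid)), function(i) {
    rig_config(H1 = grid$H1[i], H2 = grid$H2[i], ...)
  })
}

#' Reference per-class pattern counts of the rig campaign design
#'
#' Pattern counts per movement class (rows ST, AP, ML, UNS) and geometry
#' case (columns 1..6) of the reference acquisition design; the grand total
#' is 1239 patterns.
#'
#' @return A 4 x 6 integer matrix with class rownames.
#' @export
reference_counts <- function() {
  m <- matrix(c(
    47, 50, 58, 58, 53, 51,
    53, 51, 50, 51, 53, 58,
    52, 48, 52, 52, 47, 50,
    49, 52, 50, 50, 52, 52
  ), nrow = 4L, byrow = TRUE, dimnames = list(sway_classes, NULL))
  storage.mode(m) <- "integer"
  m
}

#' Write a sway dataset to CSV files
#'
#' One CSV per pattern (columns `t, ax, ay, az`) plus `manifest.csv`.
#'
#' @param dataset A `sway_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sway_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in dataset$patterns) {
    df <- cbind(t = (seq_len(nrow(p$accel)) - 1L) / p$config$fs, p$accel)
    utils::write.csv(df,
                     file.path(dir, sprintf("pattern_%05d.csv", p$pattern_id)),
                     row.names = FALSE)
  }
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(dataset$manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read one pattern CSV written by [write_dataset()]
#'
#' @param path CSV path with columns `t, ax, ay, az`.
#' @return A data.frame with those columns.
#' @export
read_pattern <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "ax", "ay", "az")
  if (!all(need %in% names(df))) {
    stop("pattern CSV must have columns t, ax, ay, az", call. = FALSE)
  }
  df[, need]
}
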