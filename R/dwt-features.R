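# Multilevel discrete wavelet transform (Daubechies-4, periodization mode)
# and the 9-input wavelet feature vector for posture classification.
#
# No wavelet package is available in the supported dependency set, so the
# dyadic cascade is implemented here directly. Filter taps are the standard
# Daubechies-4 (8-tap) orthogonal pair; the periodized convolution uses the
# same alignment as the common "periodization" convention, so coefficients
# are exchangeable with other implementations of that mode.

db4_lo <- c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
            -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
            0.71484657055291567, 0.23037781330889651)
db4_hi <- c(-0.23037781330889651, 0.71484657055291567, -0.63088076792985892,
            -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
            -0.032883011666885197, -0.010597401785069032)

# one analysis level on an even-length signal: periodized filter + decimate
dwt_step <- function(x) {
  N <- length(x)
  L <- 8L
  k <- seq.int(0L, N / 2L - 1L)
  a <- numeric(N / 2L); d <- numeric(N / 2L)
  for (n in seq_len(L)) {
    idx <- (2L * k + L / 2L - (n - 1L)) %% N + 1L
    a <- a + db4_lo[n] * x[idx]
    d <- d + db4_hi[n] * x[idx]
  }
  list(a = a, d = d)
}

# exact adjoint (= inverse, by orthogonality) of dwt_step
idwt_step <- function(a, d) {
  N <- 2L * length(a)
  L <- 8L
  k <- seq.int(0L, length(a) - 1L)
  x <- numeric(N)
  for (n in seq_len(L)) {
    idx <- (2L * k + L / 2L - (n - 1L)) %% N + 1L
    x[idx] <- x[idx] + db4_lo[n] * a + db4_hi[n] * d
  }
  x
}

#' Multilevel discrete wavelet transform
#'
#' Dyadic cascade with the orthogonal Daubechies-4 wavelet in periodization
#' mode. Orthogonality of the periodized transform requires an even length
#' at every analysis stage, so the leading `2^n_levels * floor(N / 2^n_levels)`
#' samples are analysed (992 of a 1000-sample window at 5 levels); the
#' analysed length is reported as `n_used`. Within the analysed stretch the
#' transform conserves energy exactly and is perfectly invertible
#' ([idwt_reconstruct()]).
#'
#' @param x Numeric signal of length at least `2^n_levels`.
#' @param n_levels Decomposition depth (default 5).
#' @return An object of class `wavelet_decomposition`: list with `levels`
#'   (named list `d1..d5, a5` of coefficient vectors, d1 = highest
#'   frequency), `wavelet_name`, `K` (per-level counts), `n_used`, `n_input`.
#' @export
dwt_decompose <- function(x, n_levels = 5) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("'x' must be a finite numeric signal", call. = FALSE)
  }
  n_levels <- as.integer(n_levels)
  block <- 2L^n_levels
  if (length(x) < block) {
    stop(sprintf("signal too short for %d levels (need >= %d samples)",
                 n_levels, block), call. = FALSE)
  }
  n_used <- block * (length(x) %/% block)
  approx <- x[seq_len(n_used)]
  levels <- list()
  for (lev in seq_len(n_levels)) {
    st <- dwt_step(approx)
    levels[[paste0("d", lev)]] <- st$d
    approx <- st$a
  }
  levels[[paste0("a", n_levels)]] <- approx
  structure(list(
    levels = levels, wavelet_name = "db4",
    K = vapply(levels, length, integer(1)),
    n_used = n_used, n_input = length(x)
  ), class = "wavelet_decomposition")
}

#' Inverse multilevel wavelet transform
#'
#' Reconstructs the analysed stretch of the original signal from a
#' [dwt_decompose()] object (exact up to floating-point rounding).
#'
#' @param dec A `wavelet_decomposition`.
#' @return Numeric vector of length `dec$n_used`.
#' @export
idwt_reconstruct <- function(dec) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  n_levels <- sum(grepl("^d", names(dec$levels)))
  approx <- dec$levels[[paste0("a", n_levels)]]
  for (lev in rev(seq_len(n_levels))) {
    approx <- idwt_step(approx, dec$levels[[paste0("d", lev)]])
  }
  approx
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("%s wavelet decomposition, %d of %d samples analysed\n",
              x$wavelet_name, x$n_used, x$n_input))
  cat("  coefficients:",
      paste(sprintf("%s[%d]", names(x$levels), x$K), collapse = " "), "\n")
  invisible(x)
}

#' Per-level wavelet coefficient features
#'
#' For the coefficient series `T(a, k)` of one level: the mean value
#' `MV = mean(T)`, the sample standard deviation `STD = sd(T)` and the
#' energy `E = sum(T^2)`.
#'
#' @param coefs Numeric coefficient vector (length >= 2).
#' @return Named numeric vector `c(MV, STD, E)`.
#' @export
level_features <- function(coefs) {
  if (!length(coefs)) stop("empty coefficient series", call. = FALSE)
  if (length(coefs) < 2L) stop("need >= 2 coefficients for STD", call. = FALSE)
  c(MV = mean(coefs), STD = stats::sd(coefs), E = sum(coefs^2))
}

# canonical ordering: feature-major (all MV, then STD, then E)
dwt_feature_names <- paste(rep(c("MV", "STD", "E"), each = 3L),
                           rep(c("d3", "d4", "d5"), times = 3L), sep = "_")

#' Nine-input wavelet feature vector of a stabilogram window
#'
#' Both displacement series are decomposed to 5 levels; for each of the
#' lower-frequency detail levels d3, d4, d5 the per-level features
#' (MV, STD, E) are computed on the DAP coefficients and on the DML
#' coefficients and summed, giving 3 features x 3 levels = 9 inputs. The
#' high-frequency levels d1/d2 carry negligible sway content and are not
#' used; neither is the approximation a5.
#'
#' @param stab A `stabilogram` (or list with numeric `dap`, `dml`).
#' @param levels Detail levels to retain (default `c(3, 4, 5)`).
#' @return Named numeric vector of length 9, canonical order
#'   `MV_d3, MV_d4, MV_d5, STD_d3, ..., E_d5`.
#' @export
extract_dwt_features <- function(stab, levels = c(3L, 4L, 5L)) {
  dap <- stab$dap; dml <- stab$dml
  keep <- is.finite(dap) & is.finite(dml)
  dap <- dap[keep]; dml <- dml[keep]
  dec_ap <- dwt_decompose(dap)
  dec_ml <- dwt_decompose(dml)
  out <- numeric(0)
  for (lev in levels) {
    nm <- paste0("d", lev)
    f <- level_features(dec_ap$levels[[nm]]) +
      level_features(dec_ml$levels[[nm]])
    names(f) <- paste(c("MV", "STD", "E"), nm, sep = "_")
    out <- c(out, f)
  }
  ord <- paste(rep(c("MV", "STD", "E"), each = length(levels)),
               rep(paste0("d", levels), times = 3L), sep = "_")
  out[ord]
}
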