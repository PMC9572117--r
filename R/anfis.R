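# Sugeno neuro-fuzzy inference engine: subtractive-clustering rule
# extraction, least-squares consequent estimation, and hybrid
# least-squares / backpropagation training.

#' Subtractive clustering
#'
#' Density-peak cluster-centre selection on data normalised to the unit
#' hypercube (Chiu's method). Each point receives a potential
#' `P_i = sum_j exp(-4 ||x_i - x_j||^2 / roi^2)`; the highest-potential
#' point becomes a centre, its neighbourhood potential is squashed with
#' radius `1.25 * roi`, and extraction repeats. A candidate is accepted
#' outright above `0.5 * P1`, rejected below `0.15 * P1`, and in between
#' accepted only if distance-to-existing-centres plus relative potential
#' reach 1 (the standard accept/reject ratios).
#'
#' @param X Numeric matrix (rows = observations) scaled to `[0, 1]` per
#'   column.
#' @param roi Range of influence of a cluster centre, in (0, 1]; smaller
#'   values yield more clusters.
#' @return Matrix of cluster centres (rows), at least one.
#' @export
subtractive_clustering <- function(X, roi) {
  X <- as.matrix(X)
  if (!nrow(X)) stop("'X' must be non-empty", call. = FALSE)
  stopifnot_scalar_number(roi, "roi", positive = TRUE)
  n <- nrow(X)
  alpha <- 4 / roi^2
  beta <- 4 / (1.25 * roi)^2
  d2 <- as.matrix(stats::dist(X))^2
  P <- rowSums(exp(-alpha * d2))
  centers <- NULL
  center_idx <- integer(0)
  p1 <- max(P)
  excluded <- rep(FALSE, n)
  repeat {
    Puse <- ifelse(excluded, -Inf, P)
    k <- which.max(Puse)
    pk <- Puse[k]
    if (!is.finite(pk) || pk <= 0) break
    accept <- FALSE
    if (pk > 0.5 * p1) {
      accept <- TRUE
    } else if (pk > 0.15 * p1) {
      dmin <- sqrt(min(d2[k, center_idx]))
      if (dmin / roi + pk / p1 >= 1) {
        accept <- TRUE
      } else {
        excluded[k] <- TRUE   # gray-zone candidate too close: discard, retry
        next
      }
    } else break
    if (accept) {
      centers <- rbind(centers, X[k, , drop = FALSE])
      center_idx <- c(center_idx, k)
      P <- P - pk * exp(-beta * d2[k, ])
      excluded[k] <- TRUE
    }
  }
  if (is.null(centers)) {
    centers <- X[which.max(P), , drop = FALSE]
  }
  rownames(centers) <- NULL
  centers
}

# Gaussian membership matrix W[i, r]: product over inputs of
# exp(-(x - c)^2 / (2 sigma^2)) — the rule firing strengths. Only ratios of
# firing strengths enter the Sugeno output and the consequent regressors,
# so each row is rescaled by its maximum (log-sum-exp style); this keeps the
# inference exact arbitrarily far from the rule centres, where raw products
# of memberships would underflow.
firing_strengths <- function(X, centers, sigmas) {
  n <- nrow(X); R <- nrow(centers)
  logW <- matrix(0, n, R)
  for (r in seq_len(R)) {
    z <- sweep(X, 2L, centers[r, ], "-")
    z <- sweep(z, 2L, sigmas[r, ], "/")
    logW[, r] <- -0.5 * rowSums(z^2)
  }
  exp(logW - apply(logW, 1L, max))
}

# Global least-squares estimate of all rule consequents given firing
# strengths; regressors are the normalised strengths times (x, 1).
fit_consequents <- function(X, y, W, warn = TRUE) {
  n <- nrow(X); d <- ncol(X); R <- ncol(W)
  wsum <- rowSums(W)
  wsum[wsum < 1e-300] <- 1e-300
  Wbar <- W / wsum
  A <- matrix(0, n, R * (d + 1L))
  X1 <- cbind(X, 1)
  for (r in seq_len(R)) {
    A[, ((r - 1L) * (d + 1L) + 1L):(r * (d + 1L))] <- Wbar[, r] * X1
  }
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    # minimum-norm solution via the pseudoinverse
    sv <- svd(A)
    tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
    pos <- sv$d > tol
    theta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    if (warn) {
      warning("rank-deficient consequent system; minimum-norm solution used")
    }
  } else {
    theta <- qr.coef(qrA, y)
  }
  matrix(theta, nrow = R, ncol = d + 1L, byrow = TRUE)
}

anfis_forward <- function(model, X) {
  X <- as.matrix(X)
  W <- firing_strengths(X, model$centers, model$sigmas)
  wsum <- rowSums(W)
  G <- cbind(X, 1) %*% t(model$consequents)   # per-rule linear outputs
  degenerate <- wsum < 1e-12
  out <- numeric(nrow(X))
  ok <- !degenerate
  if (any(ok)) out[ok] <- rowSums(W[ok, , drop = FALSE] * G[ok, , drop = FALSE]) / wsum[ok]
  if (any(degenerate)) {
    warning("input(s) outside all rule supports; returning mean consequent constant")
    out[degenerate] <- mean(model$consequents[, ncol(model$consequents)])
  }
  list(out = out, W = W, wsum = pmax(wsum, 1e-300), G = G)
}

new_anfis <- function(centers, sigmas, consequents, ranges, roi,
                      feature_names = NULL) {
  structure(list(
    n_inputs = ncol(centers), centers = centers, sigmas = sigmas,
    consequents = consequents, input_ranges = ranges, roi = roi,
    feature_names = feature_names, history = numeric(0)
  ), class = "anfis")
}

#' Initialise a Sugeno fuzzy system from data
#'
#' Rule extraction by [subtractive_clustering()] on the inputs scaled to the
#' unit hypercube: one rule per centre, with per-input Gaussian membership
#' functions centred at the (de-normalised) cluster coordinate and width
#' `sigma = roi * range / sqrt(8)`. Linear rule consequents are then fitted
#' by a single global least-squares pass.
#'
#' @param X Numeric matrix or data.frame of inputs.
#' @param y Numeric target (0/1 postural labels or any scalar response).
#' @param roi Range of influence of the cluster centres.
#' @return An unfitted-antecedent `anfis` model (see [anfis()]).
#' @export
init_fis <- function(X, y, roi = 0.3) {
  X <- as.matrix(X)
  if (!nrow(X)) stop("need at least one sample", call. = FALSE)
  y <- as.numeric(y)
  rng_lo <- apply(X, 2L, min)
  rng_hi <- apply(X, 2L, max)
  span <- pmax(rng_hi - rng_lo, .Machine$double.eps)
  Xn <- sweep(sweep(X, 2L, rng_lo, "-"), 2L, span, "/")
  centers_n <- subtractive_clustering(Xn, roi)
  centers <- sweep(sweep(centers_n, 2L, span, "*"), 2L, rng_lo, "+")
  sigmas <- matrix(rep(roi * span / sqrt(8), each = nrow(centers)),
                   nrow = nrow(centers))
  model <- new_anfis(centers, sigmas,
                     consequents = matrix(0, nrow(centers), ncol(X) + 1L),
                     ranges = rbind(min = rng_lo, max = rng_hi),
                     roi = roi, feature_names = colnames(X))
  W <- firing_strengths(X, centers, sigmas)
  model$consequents <- fit_consequents(X, y, W)
  model
}

#' Hybrid training of a Sugeno fuzzy system
#'
#' Classic two-pass scheme per epoch: with antecedents fixed, rule
#' consequents are re-estimated by global least squares; antecedent centres
#' and widths are then updated by one backpropagation gradient-descent step
#' on the squared output error. The step is taken on the normalised
#' gradient; whenever a step would increase the training error the
#' antecedents revert and the step size is halved, so the recorded error is
#' non-increasing across epochs.
#'
#' @param model An `anfis` model from [init_fis()].
#' @param X,y Training inputs and targets.
#' @param epochs Number of training epochs.
#' @param step_size Initial gradient step (in normalised-gradient units).
#' @return The trained `anfis` model with an `history` vector of per-epoch
#'   RMSE values.
#' @export
train_hybrid <- function(model, X, y, epochs = 50, step_size = 0.01) {
  stopifnot(inherits(model, "anfis"))
  X <- as.matrix(X); y <- as.numeric(y)
  if (ncol(X) != model$n_inputs) stop("input dimensionality mismatch")
  if (epochs == 0) return(model)
  rmse <- function(m) {
    fw <- anfis_forward(m, X)
    sqrt(mean((fw$out - y)^2))
  }
  err <- rmse(model)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fw <- anfis_forward(model, X)
    resid <- fw$out - y
    if (sqrt(mean(resid^2)) > 1e6) {
      stop("training diverged (error > 1e6)", call. = FALSE)
    }
    # gradient of E = sum resid^2 wrt centres and sigmas
    dF_dW <- (fw$G - fw$out) / fw$wsum          # n x R
    common <- 2 * resid * dF_dW * fw$W          # n x R
    gc_ <- matrix(0, nrow(model$centers), ncol(model$centers))
    gs_ <- gc_
    for (r in seq_len(nrow(model$centers))) {
      z <- sweep(X, 2L, model$centers[r, ], "-")
      s2 <- matrix(model$sigmas[r, ]^2, nrow(X), ncol(X), byrow = TRUE)
      gc_[r, ] <- colSums(common[, r] * z / s2)
      gs_[r, ] <- colSums(common[, r] * z^2 /
                            sweep(s2, 2L, model$sigmas[r, ], "*"))
    }
    gnorm <- sqrt(sum(gc_^2) + sum(gs_^2))
    if (gnorm > 0) {
      cand <- model
      cand$centers <- model$centers - step_size * gc_ / gnorm
      cand$sigmas <- pmax(model$sigmas - step_size * gs_ / gnorm,
                          1e-6 * model$sigmas)
      Wc <- firing_strengths(X, cand$centers, cand$sigmas)
      cand$consequents <- fit_consequents(X, y, Wc, warn = ep == 1L)
      cand_err <- rmse(cand)
      if (cand_err <= err + 1e-9) {
        model <- cand
        err <- cand_err
      } else {
        step_size <- step_size / 2
        # keep antecedents; refresh consequents for current antecedents
        model$consequents <- fit_consequents(X, y, fw$W, warn = FALSE)
        err <- min(err, rmse(model))
      }
    } else {
      model$consequents <- fit_consequents(X, y, fw$W, warn = FALSE)
      err <- min(err, rmse(model))
    }
    history[ep] <- err
  }
  model$history <- c(model$history, history)
  model
}

#' Fit a Sugeno neuro-fuzzy posture classifier
#'
#' One-call interface: rule extraction by subtractive clustering
#' ([init_fis()]) followed by hybrid least-squares / gradient training
#' ([train_hybrid()]). The continuous model output approximates the binary
#' postural status; [predict.anfis()] rounds it at 0.5 and reports a
#' reliability index.
#'
#' @param x Numeric matrix or data.frame of input features.
#' @param y Numeric/binary response (0 stable, 1 unstable).
#' @param roi Range of influence of the cluster centres (the single
#'   structural hyper-parameter; 0.3 is the tuned default for sway
#'   features).
#' @param epochs Training epochs (default 50).
#' @param step_size Initial gradient step.
#' @return An object of class `anfis` with fields `centers`, `sigmas`
#'   (per-rule Gaussian antecedents), `consequents` (per-rule linear
#'   coefficients, constant last), `input_ranges`, `history` (training
#'   RMSE per epoch).
#' @examples
#' x <- matrix(runif(100), ncol = 1)
#' fit <- anfis(x, 2 * x[, 1] + 1, roi = 0.5, epochs = 5)
#' predict(fit, matrix(0.3))
#' @export
anfis <- function(x, y, roi = 0.3, epochs = 50, step_size = 0.01) {
  x <- as.matrix(x)
  model <- init_fis(x, y, roi = roi)
  train_hybrid(model, x, y, epochs = epochs, step_size = step_size)
}

#' @export
print.anfis <- function(x, ...) {
  cat(sprintf("Sugeno neuro-fuzzy model: %d input(s), %d rule(s), roi = %g\n",
              x$n_inputs, nrow(x$centers), x$roi))
  if (length(x$history)) {
    cat(sprintf("  training RMSE: %.4g (after %d epoch(s))\n",
                utils::tail(x$history, 1), length(x$history)))
  }
  invisible(x)
}

#' @export
summary.anfis <- function(object, ...) {
  print(object)
  cat("Rule antecedent centres:\n")
  print(round(object$centers, 4))
  cat("Rule consequents (linear coefficients, constant last):\n")
  print(round(object$consequents, 4))
  invisible(object)
}

#' @export
coef.anfis <- function(object, ...) object$consequents

#' Evaluate the continuous Sugeno output
#'
#' Firing-strength-weighted average of the rule consequents at new inputs.
#' Firing strengths are normalised per sample before weighting (only their
#' ratios matter), so the output stays exact arbitrarily far from the rule
#' centres instead of underflowing; far from all rules the nearest rule's
#' consequent dominates.
#'
#' @param model An `anfis` model.
#' @param x Numeric matrix/data.frame (or a single numeric vector of length
#'   `n_inputs`).
#' @return Numeric vector of continuous outputs.
#' @export
evaluate <- function(model, x) {
  stopifnot(inherits(model, "anfis"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != model$n_inputs) stop("input dimensionality mismatch")
  anfis_forward(model, x)$out
}

#' Binary postural status and reliability from the fuzzy output
#'
#' Rounds the continuous output at the class separator 0.5 (ties round to
#' unstable — the conservative choice for a safety application) and reports
#' the reliability index `RI = 100 * |PSpred - 0.5| / 0.5`, clipped to
#' `[0, 100]` because the Sugeno output may leave `[0, 1]`.
#'
#' @param model An `anfis` model.
#' @param x Input matrix / vector as in [evaluate()].
#' @return Data.frame with `ps_pred` (continuous), `ps_round` (0/1) and
#'   `ri` (percent).
#' @export
predict_status <- function(model, x) {
  ps <- evaluate(model, x)
  data.frame(ps_pred = ps,
             ps_round = as.integer(ps >= 0.5),
             ri = pmin(100, 100 * abs(ps - 0.5) / 0.5))
}

#' Predict method for `anfis` models
#'
#' @param object An `anfis` model.
#' @param newdata Input matrix/data.frame.
#' @param type `"status"` (default) for the rounded class + reliability
#'   data.frame of [predict_status()], `"raw"` for the continuous output.
#' @param ... Unused.
#' @export
predict.anfis <- function(object, newdata, type = c("status", "raw"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    if (!is.null(object$feature_names)) {
      newdata <- newdata[, object$feature_names, drop = FALSE]
    }
    newdata <- as.matrix(newdata)
  }
  switch(type,
         raw = evaluate(object, newdata),
         status = predict_status(object, newdata))
}

#' @export
residuals.anfis <- function(object, x, y, ...) {
  evaluate(object, x) - as.numeric(y)
}

#' Serialize / restore an `anfis` model as JSON
#'
#' @param model An `anfis` model.
#' @param path JSON file path.
#' @return `write_anfis` returns `path` invisibly; `read_anfis` the model.
#' @export
write_anfis <- function(model, path) {
  stopifnot(inherits(model, "anfis"))
  jsonlite::write_json(list(
    n_inputs = model$n_inputs, roi = model$roi,
    centers = model$centers, sigmas = model$sigmas,
    consequents = model$consequents,
    input_ranges = model$input_ranges,
    feature_names = model$feature_names
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_anfis
#' @export
read_anfis <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- new_anfis(as.matrix(raw$centers), as.matrix(raw$sigmas),
                 as.matrix(raw$consequents), as.matrix(raw$input_ranges),
                 raw$roi, raw$feature_names)
  m
}
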