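# Shared fixtures and independent oracles, built in code at test time.

# Small labelled dataset + feature tables, memoised per (counts, seed) so
# expensive simulation runs once per test session.
.fixture_cache <- new.env(parent = emptyenv())

sway_fixture <- function(per_class = 10, seed = 1) {
  key <- sprintf("ds_%d_%d", per_class, seed)
  if (is.null(.fixture_cache[[key]])) {
    ds <- generate_dataset(
      default_rig_cases(),
      counts = c(ST = per_class, AP = per_class, ML = per_class,
                 UNS = per_class),
      seed = seed)
    .fixture_cache[[key]] <- list(
      dataset = ds,
      time = feature_table(ds, "time"),
      dwt = feature_table(ds, "dwt"),
      split = split_dataset(ds$N, seed = seed))
  }
  .fixture_cache[[key]]
}

# Exhaustive ROC oracle: best Youden's J over every cut between sorted
# unique values and both orientations, by brute force.
roc_oracle <- function(x, labels) {
  ux <- sort(unique(x))
  cuts <- if (length(ux) > 1) (ux[-1] + ux[-length(ux)]) / 2 else ux
  best_j <- -Inf
  for (th in cuts) {
    for (dir in c(1, -1)) {
      pred <- as.integer(dir * (x - th) > 0)
      sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
      spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
      best_j <- max(best_j, sens + spec - 1)
    }
  }
  best_j
}

youden_j_of <- function(model, feature, x, labels) {
  pred <- as.integer(model$directions[[feature]] *
                       (x - model$thresholds[[feature]]) > 0)
  sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
  spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
  sens + spec - 1
}

# Known two-rule Sugeno generator used for the parameter-recovery check.
two_rule_sugeno <- function(x) {
  w1 <- exp(-0.5 * ((x - 0.25) / 0.1)^2)
  w2 <- exp(-0.5 * ((x - 0.75) / 0.1)^2)
  (w1 * (2 * x + 0.1) + w2 * (-1 * x + 1.4)) / (w1 + w2)
}
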