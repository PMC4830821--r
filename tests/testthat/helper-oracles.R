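# Independent oracles used across the suite. Each reimplements the target
# quantity by the most direct route available (exhaustive enumeration,
# closed form, or a direct weighted least-squares solve) so the production
# path is checked against an unrelated computation.

# AUC by exhaustive pair enumeration: concordant pairs + half credit for ties.
bruteForceAUC <- function(cases, controls) {
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# Youden-optimal J by exhaustive scan over all candidate cutpoints.
bruteForceBestJ <- function(cases, controls) {
  s <- sort(unique(c(cases, controls)))
  cuts <- c(-Inf, (head(s, -1) + tail(s, -1)) / 2, Inf)
  max(vapply(cuts, function(cc)
    mean(cases > cc) + mean(controls <= cc) - 1, numeric(1)))
}

# Tie-corrected Spearman rho as Pearson on mid-ranks, p from the t
# approximation, computed from first principles.
midrankSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(rho = r, pValue = 2 * pt(-abs(tstat), n - 2))
}

# A tiny fully hand-checkable panel: two domains of two markers each.
toyPanel <- function() {
  data.frame(name = c("m1", "m2", "m3", "m4"),
             domain = rep(c("d1", "d2"), each = 2),
             direction = c("high", "high", "low", "high"),
             control_mean = 0, control_sd = 1,
             target_auc = 0.9, missing_rate = 0)
}

# Random case-control marker matrix for property loops.
randomCohort <- function(n1, n2, p, shift = 1, ties = FALSE) {
  n <- n1 + n2
  vals <- matrix(rnorm(p * n), p, n)
  vals[, seq_len(n1)] <- vals[, seq_len(n1)] + shift
  if (ties) vals <- round(vals, 1)
  rownames(vals) <- paste0("m", seq_len(p))
  colnames(vals) <- paste0("s", seq_len(n))
  list(values = vals, case = rep(c(TRUE, FALSE), c(n1, n2)))
}
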