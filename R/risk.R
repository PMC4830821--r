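# Case risk as a function of the abnormal-domain count: a single-covariate
# logistic model fitted by IRLS, and a Cleveland-style lowess smoother of
# the 0/1 labels, both evaluated on the integer count grid.

#' Fit a single-covariate logistic risk model by IRLS
#'
#' Maximum-likelihood fit of logit(p) = a + b * count via iteratively
#' reweighted least squares (Newton-Raphson on the log-likelihood).
#' Convergence is declared when the log-likelihood changes by less than
#' 1e-10; complete separation is detected (diverging coefficients with
#' fitted probabilities collapsing to 0/1) and flagged rather than left to
#' diverge silently.
#'
#' @param counts Integer covariate (abnormal-domain count per subject).
#' @param labels Case/control labels.
#' @return A [RiskCurve-class] with \code{method = "logistic"},
#'   coefficients \code{c(a, b)}, fitted risks on the integer grid
#'   0..max(counts), and convergence/separation flags.
#' @examples
#' rc <- fitLogisticRisk(rep(0:5, each = 20),
#'                       rbinom(120, 1, plogis(-4.6 + 1.9 * rep(0:5, each = 20))))
#' riskCoef(rc)
#' @export
fitLogisticRisk <- function(counts, labels) {
  y <- as.numeric(.caseLogical(labels))
  keep <- !is.na(counts) & !is.na(y)
  x <- counts[keep]; y <- y[keep]
  if (length(unique(x)) < 2)
    stop("degenerate input: counts are constant")
  if (all(y == 1) || all(y == 0))
    stop("degenerate input: single-class labels")
  X <- cbind(1, x)
  beta <- c(qlogis(mean(y)), 0)
  llOld <- -Inf; converged <- FALSE; separation <- FALSE
  for (it in seq_len(100)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
    if (abs(ll - llOld) < 1e-10) { converged <- TRUE; break }
    llOld <- ll
    w <- pmax(p * (1 - p), 1e-10)
    # Newton step: solve (X'WX) d = X'(y - p)
    XtW <- t(X * w)
    beta <- beta + solve(XtW %*% X, crossprod(X, y - p))
    if (max(abs(beta)) > 30) { separation <- TRUE; break }
  }
  if (separation)
    warning("complete or quasi-complete separation detected; ",
            "coefficients are not identified")
  grid <- seq(min(x), max(x))
  methods::new("RiskCurve", method = "logistic",
               coef = c(a = beta[1], b = beta[2]),
               fitted = data.frame(count = grid,
                                   risk = plogis(beta[1] + beta[2] * grid)),
               converged = converged, separation = separation)
}

#' Predicted logistic risk at a given count
#'
#' expit(a + b * count).
#'
#' @param a,b Logistic intercept and slope (logit scale).
#' @param count Abnormal-domain count (vectorized).
#' @return Probability in (0, 1).
#' @examples
#' a <- qlogis(0.0097); b <- qlogis(0.0613) - a
#' predictRisk(a, b, 0:5) * 100
#' @export
predictRisk <- function(a, b, count) {
  stopifnot(is.finite(a), is.finite(b))
  plogis(a + b * count)
}

#' Coefficients of a fitted risk curve
#' @param x A [RiskCurve-class].
#' @return Named numeric (empty for lowess).
#' @export
riskCoef <- function(x) x@coef

#' Fitted risks of a risk curve
#' @param x A [RiskCurve-class].
#' @return data.frame with \code{count} and \code{risk}.
#' @export
riskFitted <- function(x) x@fitted

# One tricube-weighted local linear fit at x0. robWeights multiply the
# kernel weights (bisquare robustness); falls back to a weighted mean when
# the window carries no spread in x.
.localFit <- function(x, y, x0, span, robWeights) {
  n <- length(x)
  r <- max(2L, ceiling(span * n))
  d <- abs(x - x0)
  h <- sort(d)[r]
  if (h == 0) {
    idx <- d == 0
    if (sum(robWeights[idx]) == 0) return(mean(y[idx]))
    return(sum(y[idx] * robWeights[idx]) / sum(robWeights[idx]))
  }
  idx <- d <= h
  if (sum(idx) < 2) { # widen to the two nearest points
    warning("window too narrow at x0 = ", x0, "; widening")
    idx <- rank(d, ties.method = "first") <= 2
    h <- max(d[idx])
  }
  w <- (1 - pmin(d[idx] / h, 1)^3)^3 * robWeights[idx]
  xi <- x[idx]; yi <- y[idx]
  sw <- sum(w)
  if (sw == 0) return(mean(yi))
  xb <- sum(w * xi) / sw
  sxx <- sum(w * (xi - xb)^2)
  if (sxx < 1e-12) return(sum(w * yi) / sw)
  b <- sum(w * (xi - xb) * yi) / sxx
  a <- sum(w * yi) / sw - b * xb
  a + b * x0
}

#' Locally weighted (lowess) risk regression on the domain count
#'
#' Cleveland-style locally weighted regression of the 0/1 case labels on
#' the abnormal-domain count: tricube kernel over the \code{span} fraction
#' of nearest subjects, local linear fits, and optional bisquare
#' robustness iterations. Windows are defined over subjects (not unique
#' counts), the curve is evaluated at each integer count, and fitted risks
#' are clipped to [0, 1].
#'
#' @param counts Integer covariate per subject.
#' @param labels Case/control labels.
#' @param span Bandwidth as a fraction of subjects in each window, in
#'   (0, 1]; default 2/3.
#' @param iterations Bisquare robustness iterations; default 3. (With 0/1
#'   responses the robustness step mainly down-weights label noise in
#'   otherwise pure windows.)
#' @param grid Evaluation grid; default all integers spanning the counts.
#' @return A [RiskCurve-class] with \code{method = "lowess"}.
#' @export
lowessRisk <- function(counts, labels, span = 2/3, iterations = 3,
                       grid = NULL) {
  y <- as.numeric(.caseLogical(labels))
  keep <- !is.na(counts) & !is.na(y)
  x <- counts[keep]; y <- y[keep]
  if (length(x) < 5) stop("need at least 5 observations")
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  if (is.null(grid)) grid <- seq(floor(min(x)), ceiling(max(x)))
  rw <- rep(1, length(x))
  for (it in seq_len(iterations)) {
    fit <- vapply(x, .localFit, numeric(1), x = x, y = y, span = span,
                  robWeights = rw)
    res <- y - fit
    s <- median(abs(res))
    if (s <= 0) break
    rw <- pmax(1 - (res / (6 * s))^2, 0)^2
  }
  risk <- vapply(grid, .localFit, numeric(1), x = x, y = y, span = span,
                 robWeights = rw)
  methods::new("RiskCurve", method = "lowess", coef = numeric(0),
               fitted = data.frame(count = grid,
                                   risk = pmin(1, pmax(0, risk))),
               converged = TRUE, separation = FALSE)
}

#' Risk-by-domain-count table
#'
#' Fits both risk models to a scored cohort and lays the predicted risks
#' out as percentages over the integer count grid (one row per method).
#'
#' @param counts Abnormal-domain counts (e.g. from [scorePanel()]).
#' @param labels Case/control labels.
#' @param span,iterations Lowess parameters, see [lowessRisk()].
#' @return data.frame: \code{method}, then one \code{count<k>} column per
#'   grid point with the predicted risk in percent (2 decimals).
#' @export
riskTable <- function(counts, labels, span = 2/3, iterations = 3) {
  lg <- fitLogisticRisk(counts, labels)
  lw <- lowessRisk(counts, labels, span = span, iterations = iterations,
                   grid = riskFitted(lg)$count)
  grid <- riskFitted(lg)$count
  tab <- rbind(logistic = round(100 * riskFitted(lg)$risk, 2),
               lowess = round(100 * riskFitted(lw)$risk, 2))
  colnames(tab) <- paste0("count", grid)
  data.frame(method = rownames(tab), tab, row.names = NULL)
}

setMethod("show", "RiskCurve", function(object) {
  cat("RiskCurve [", object@method, "]\n", sep = "")
  if (object@method == "logistic") {
    cat(sprintf("  logit(p) = %.4f + %.4f * count%s\n",
                object@coef["a"], object@coef["b"],
                if (object@separation) "  [separation!]" else ""))
  }
  print(transform(object@fitted, risk = round(risk, 4)), row.names = FALSE)
})
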