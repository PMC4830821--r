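# Empirical ROC machinery: the atomic computation reused at marker, domain
# and model level of the cascade. All curves are built on an "abnormality
# score" scale (the raw value for direction "high", its negation for "low"),
# so that larger scores are always more abnormal and the decision rule is
# always score > cutpoint.

#' ROCCurve: an empirical ROC curve
#'
#' @slot cutpoints Candidate cutpoints on the abnormality-score scale:
#'   \code{-Inf}, the midpoints between adjacent observed unique scores, and
#'   \code{+Inf}. A subject is called abnormal when score > cutpoint.
#' @slot sensitivity,specificity Operating characteristics at each cutpoint;
#'   sensitivity is non-increasing and specificity non-decreasing along the
#'   cutpoint grid, with endpoints (1, 0) and (0, 1).
#' @slot caseScores,controlScores The non-missing abnormality scores.
#' @slot direction \code{"high"} or \code{"low"}.
#' @export
setClass("ROCCurve", representation(
  cutpoints = "numeric", sensitivity = "numeric", specificity = "numeric",
  caseScores = "numeric", controlScores = "numeric", direction = "character"))

.caseLogical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- !labels %in% c("case", "control") & !is.na(labels)
    if (any(bad)) stop("unknown group label(s): ",
                       paste(unique(labels[bad]), collapse = ", "))
    return(labels == "case")
  }
  if (is.numeric(labels)) {
    if (!all(labels %in% 0:1 | is.na(labels)))
      stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  stop("cannot interpret group labels")
}

# Mann-Whitney AUC with half credit for ties, via mid-ranks. Exactly equals
# the trapezoid area of the empirical curve.
.rankAUC <- function(cases, controls) {
  n1 <- length(cases); n2 <- length(controls)
  r <- rank(c(cases, controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Build an empirical ROC curve
#'
#' Constructs the empirical ROC curve of a continuous (or integer) marker
#' against binary case/control labels. Missing values are excluded pairwise;
#' the abnormality direction decides which tail counts as a positive test.
#'
#' @param values Numeric vector of marker values (may contain \code{NA}).
#' @param labels Case/control labels: logical (TRUE = case), 0/1, or
#'   \code{"case"}/\code{"control"}.
#' @param direction \code{"high"} if large values are abnormal, \code{"low"}
#'   if small values are.
#' @return A [ROCCurve-class].
#' @examples
#' empiricalROC(c(3, 4, 1, 2), c(1, 1, 0, 0), "high")
#' @export
empiricalROC <- function(values, labels, direction = c("high", "low")) {
  direction <- match.arg(direction)
  case <- .caseLogical(labels)
  stopifnot(length(values) == length(case))
  keep <- !is.na(values) & !is.na(case)
  v <- values[keep]; case <- case[keep]
  if (!any(case) || !any(!case))
    stop("degenerate input: need at least one case and one control with ",
         "non-missing values")
  s <- if (direction == "high") v else -v
  u <- sort(unique(s))
  cutpoints <- c(-Inf, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2, Inf)
  cs <- s[case]; ks <- s[!case]
  sens <- vapply(cutpoints, function(cc) mean(cs > cc), numeric(1))
  spec <- vapply(cutpoints, function(cc) mean(ks <= cc), numeric(1))
  methods::new("ROCCurve", cutpoints = cutpoints, sensitivity = sens,
               specificity = spec, caseScores = cs, controlScores = ks,
               direction = direction)
}

#' AUC with Hanley-McNeil significance
#'
#' Area under the empirical curve (trapezoid rule; equivalently the rank-sum
#' statistic with half credit for ties) and a two-sided normal-approximation
#' test of AUC = 0.5 using the Hanley-McNeil standard error.
#'
#' @param curve A [ROCCurve-class].
#' @return List with \code{auc}, \code{se}, \code{pValue}.
#' @export
aucPValue <- function(curve) {
  n1 <- length(curve@caseScores); n2 <- length(curve@controlScores)
  if (n1 == 0L || n2 == 0L) stop("degenerate input: empty class")
  A <- .rankAUC(curve@caseScores, curve@controlScores)
  Q1 <- A / (2 - A); Q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (n1 - 1) * (Q1 - A^2) + (n2 - 1) * (Q2 - A^2)) /
               (n1 * n2))
  p <- if (se == 0) as.numeric(A == 0.5) else
    2 * pnorm(-abs(A - 0.5) / se)
  list(auc = A, se = se, pValue = min(p, 1))
}

#' Select an operating cutoff on an empirical ROC curve
#'
#' Default criterion maximizes Youden's J = sensitivity + specificity - 1;
#' ties are broken toward higher specificity. \code{"closest.topleft"}
#' minimizes the Euclidean distance to the (0, 1) corner instead. The
#' returned cutoff is translated back to the original measurement scale
#' (a midpoint between adjacent observed values), with the decision rule
#' value > cutoff for direction \code{"high"} and value < cutoff for
#' \code{"low"}.
#'
#' @param curve A [ROCCurve-class].
#' @param criterion \code{"youden"} (default) or \code{"closest.topleft"}.
#' @return List with \code{cutoff}, \code{sensitivity}, \code{specificity}.
#' @examples
#' selectCutoff(empiricalROC(c(3, 4, 1, 2), c(1, 1, 0, 0), "high"))
#' @export
selectCutoff <- function(curve, criterion = c("youden", "closest.topleft")) {
  criterion <- match.arg(criterion)
  sens <- curve@sensitivity; spec <- curve@specificity
  obj <- switch(criterion,
    youden = sens + spec - 1,
    closest.topleft = -((1 - sens)^2 + (1 - spec)^2))
  best <- which(obj == max(obj))
  # ties toward higher specificity; cutpoints ascend with specificity, so
  # take the last tied index
  i <- best[which.max(spec[best])]
  cp <- curve@cutpoints[i]
  cutoff <- if (curve@direction == "high") cp else -cp
  list(cutoff = cutoff, sensitivity = sens[i], specificity = spec[i])
}

#' Diagnostic odds ratio
#'
#' DOR = [sens / (1 - sens)] * [spec / (1 - spec)]: the odds of a positive
#' test in cases over the odds of a positive test in controls. Boundary
#' sensitivity/specificity (0 or 1) yield 0 or \code{Inf}; when the raw
#' 2x2 counts are supplied, a Haldane continuity correction (+0.5 in every
#' cell) can be applied instead.
#'
#' @param sensitivity,specificity Values in [0, 1] (vectorized).
#' @param counts Optional 2x2 counts \code{c(tp, fn, fp, tn)}.
#' @param haldane Apply the +0.5 correction to \code{counts} (default when
#'   any cell is zero and counts are supplied).
#' @return The diagnostic odds ratio (possibly 0 or \code{Inf}).
#' @examples
#' diagnosticOddsRatio(0.900, 0.552)  # ~11.1
#' @export
diagnosticOddsRatio <- function(sensitivity, specificity, counts = NULL,
                                haldane = NULL) {
  if (!is.null(counts)) {
    stopifnot(length(counts) == 4, all(counts >= 0))
    if (is.null(haldane)) haldane <- any(counts == 0)
    if (haldane) counts <- counts + 0.5
    return(unname((counts[1] * counts[4]) / (counts[2] * counts[3])))
  }
  if (any(sensitivity < 0 | sensitivity > 1 | specificity < 0 | specificity > 1))
    stop("sensitivity and specificity must be in [0, 1]")
  (sensitivity / (1 - sensitivity)) * (specificity / (1 - specificity))
}

#' Prevalence-adjusted predictive values
#'
#' Positive and negative predictive values at an assumed population
#' prevalence, by Bayes' rule:
#' PPV = s*pi / (s*pi + (1-sp)(1-pi)),
#' NPV = sp*(1-pi) / ((1-s)*pi + sp*(1-pi)).
#'
#' @param sensitivity,specificity Operating point in [0, 1].
#' @param prevalence Assumed disease prevalence in (0, 1); vectorized.
#' @return data.frame with columns \code{prevalence}, \code{ppv}, \code{npv}.
#' @examples
#' predictiveValues(0.923, 0.923, 0.30)
#' @export
predictiveValues <- function(sensitivity, specificity, prevalence) {
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("prevalence must lie strictly inside (0, 1)")
  if (any(sensitivity < 0 | sensitivity > 1 | specificity < 0 | specificity > 1))
    stop("sensitivity and specificity must be in [0, 1]")
  ppv <- sensitivity * prevalence /
    (sensitivity * prevalence + (1 - specificity) * (1 - prevalence))
  npv <- specificity * (1 - prevalence) /
    ((1 - sensitivity) * prevalence + specificity * (1 - prevalence))
  data.frame(prevalence = prevalence, ppv = ppv, npv = npv)
}

#' Accuracy index
#'
#' Fraction of subjects correctly classified by binary predictions.
#'
#' @param predictions Predicted positivity (logical or 0/1, or
#'   case/control labels).
#' @param labels True labels in any form accepted by [empiricalROC()].
#' @return Proportion correct in [0, 1].
#' @export
accuracyIndex <- function(predictions, labels) {
  p <- .caseLogical(predictions); y <- .caseLogical(labels)
  stopifnot(length(p) == length(y))
  keep <- !is.na(p) & !is.na(y)
  mean(p[keep] == y[keep])
}

#' Tie-corrected Spearman correlation
#'
#' Spearman's rho as Pearson correlation of mid-ranks, with a two-sided
#' p-value from the t approximation (via \code{stats::cor.test}).
#' Pairs with missing values are dropped.
#'
#' @param x,y Paired numeric vectors.
#' @return List with \code{rho}, \code{pValue}, \code{n}.
#' @export
spearmanRho <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), pValue = ct$p.value, n = length(x))
}

#' One-shot ROC analysis of a marker
#'
#' Convenience wrapper running [empiricalROC()], [aucPValue()],
#' [selectCutoff()], [diagnosticOddsRatio()] and [accuracyIndex()] on a
#' single marker, returning a complete [ROCResult-class].
#'
#' @inheritParams empiricalROC
#' @param criterion Cutoff criterion passed to [selectCutoff()].
#' @return A [ROCResult-class].
#' @export
rocAnalysis <- function(values, labels, direction = c("high", "low"),
                        criterion = "youden") {
  direction <- match.arg(direction)
  curve <- empiricalROC(values, labels, direction)
  a <- aucPValue(curve)
  cut <- selectCutoff(curve, criterion)
  case <- .caseLogical(labels)
  keep <- !is.na(values) & !is.na(case)
  v <- values[keep]; y <- case[keep]
  pred <- if (direction == "high") v > cut$cutoff else v < cut$cutoff
  methods::new("ROCResult",
    auc = a$auc, pValue = a$pValue, cutoff = cut$cutoff,
    sensitivity = cut$sensitivity, specificity = cut$specificity,
    dor = diagnosticOddsRatio(cut$sensitivity, cut$specificity),
    accuracy = mean(pred == y),
    nObs = length(v), nCases = sum(y), nControls = sum(!y),
    direction = direction)
}

setMethod("show", "ROCResult", function(object) {
  cat(sprintf(
    "ROCResult (n=%d: %d cases / %d controls, direction=%s)\n",
    object@nObs, object@nCases, object@nControls, object@direction))
  cat(sprintf("  AUC %.3f (p=%.2g)  cutoff %.4g  sens %.3f  spec %.3f\n",
              object@auc, object@pValue, object@cutoff,
              object@sensitivity, object@specificity))
  cat(sprintf("  DOR %.3g  accuracy %.3f\n", object@dor, object@accuracy))
})

#' @describeIn rocAnalysis Coerce an \code{ROCResult} to a one-row
#'   data.frame (column layout used by the variable-level report).
#' @param x An \code{ROCResult}.
#' @export
rocResultRow <- function(x) {
  data.frame(nObs = x@nObs, auc = x@auc, sensitivity = x@sensitivity,
             specificity = x@specificity, rocPValue = x@pValue,
             oddsRatio = x@dor, accuracy = x@accuracy, cutoff = x@cutoff,
             direction = x@direction)
}
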