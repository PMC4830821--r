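#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay "assay<-"
#'   assayNames colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats median qnorm pnorm plogis qlogis rnorm rbinom runif
#'   complete.cases cor.test pt quantile setNames
#' @importFrom utils head tail read.csv write.csv packageVersion
NULL

#' BiomarkerExperiment: a case-control biomarker cohort
#'
#' Container for a case-control biomarker panel, extending
#' \link[SummarizedExperiment]{SummarizedExperiment}. The single assay
#' \code{"markers"} holds the marker values (markers in rows, subjects in
#' columns, \code{NA} for missing observations). \code{rowData} carries the
#' panel structure (functional domain and abnormality direction per marker);
#' \code{colData} carries the group label (\code{control}/\code{case}) and any
#' functional measures (severity, disability, service-use scores).
#'
#' @slot .  See \code{SummarizedExperiment}; no additional slots.
#'
#' @section Validity:
#' \itemize{
#'   \item \code{colData$group} present, a factor with levels
#'     \code{control}, \code{case};
#'   \item \code{rowData$domain} and \code{rowData$direction} present;
#'     direction values are \code{"high"} or \code{"low"};
#'   \item the assay is numeric.
#' }
#'
#' @seealso [BiomarkerExperiment()] for construction,
#'   [simulateCohort()] to generate one synthetically.
#' @export
setClass("BiomarkerExperiment",
         contains = "SummarizedExperiment")

setValidity("BiomarkerExperiment", function(object) {
  msg <- character()
  if (!"markers" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'markers' is required")
  else if (!is.numeric(SummarizedExperiment::assay(object, "markers")))
    msg <- c(msg, "assay 'markers' must be numeric")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else {
    g <- cd$group
    if (!is.factor(g) || !identical(levels(g), c("control", "case")))
      msg <- c(msg, "'group' must be a factor with levels control, case")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("domain", "direction") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'domain' and 'direction'")
  else if (!all(rd$direction %in% c("high", "low")))
    msg <- c(msg, "direction must be 'high' or 'low'")
  if (length(msg)) msg else TRUE
})

#' ROCResult: empirical ROC analysis of a single score
#'
#' Holds the outcome of one empirical ROC analysis: area under the curve
#' with its normal-approximation p-value, the selected cutoff with its
#' sensitivity/specificity, the diagnostic odds ratio, the accuracy index,
#' and the observation counts the curve was built from.
#'
#' @slot auc Area under the empirical ROC curve (half credit for ties).
#' @slot pValue Two-sided p-value for AUC != 0.5 (Hanley-McNeil SE).
#' @slot cutoff Selected cutoff on the original measurement scale
#'   (midpoint between adjacent observed values; may be infinite).
#' @slot sensitivity,specificity Operating point at \code{cutoff}.
#' @slot dor Diagnostic odds ratio at the cutoff (may be \code{Inf}).
#' @slot accuracy Fraction correctly classified at the cutoff.
#' @slot nObs,nCases,nControls Non-missing observation counts.
#' @slot direction \code{"high"} or \code{"low"}: which tail is abnormal.
#' @export
setClass("ROCResult", representation(
  auc = "numeric", pValue = "numeric", cutoff = "numeric",
  sensitivity = "numeric", specificity = "numeric",
  dor = "numeric", accuracy = "numeric",
  nObs = "integer", nCases = "integer", nControls = "integer",
  direction = "character"))

#' PanelModel: a fitted hierarchical dichotomize-tally-ROC cascade
#'
#' The fitted screening rule: per-marker ROC cutoffs and directions,
#' per-domain tally thresholds (minimum abnormal markers for the domain to
#' count as abnormal), and the model-level detection threshold (minimum
#' abnormal domains to call a subject a case), with ROC performance recorded
#' at every level.
#'
#' @slot variables data.frame, one row per marker: name, domain, direction,
#'   cutoff, auc, pValue, sensitivity, specificity, dor, accuracy, nObs.
#' @slot domains data.frame, one row per domain: domain, size, threshold,
#'   auc, pValue, sensitivity, specificity, nObs.
#' @slot threshold Integer: minimum abnormal-domain count for case detection.
#' @slot modelROC [ROCResult-class] of the abnormal-domain count.
#' @slot options List of fitting options (cutoff criterion, tie rule, ...).
#' @export
setClass("PanelModel", representation(
  variables = "data.frame", domains = "data.frame",
  threshold = "integer", modelROC = "ROCResult", options = "list"))

#' RiskCurve: case risk as a function of abnormal-domain count
#'
#' @slot method \code{"logistic"} or \code{"lowess"}.
#' @slot coef For logistic: named \code{c(a, b)} on the logit scale.
#' @slot fitted data.frame with columns \code{count} and \code{risk}
#'   (probability scale, clipped to [0, 1] for lowess).
#' @slot converged,separation Logistic fit diagnostics (IRLS convergence;
#'   complete-separation flag).
#' @export
setClass("RiskCurve", representation(
  method = "character", coef = "numeric", fitted = "data.frame",
  converged = "logical", separation = "logical"))

#' CrossValResult: stratified k-fold cross-validation of the cascade
#'
#' @slot folds data.frame, one row per fold and prevalence: fold, nObs,
#'   prevalence, sensitivity, specificity, auc, dor, ppv, npv.
#' @slot pooled Same columns, computed on the concatenated test-fold
#'   predictions.
#' @slot foldMeans Same columns, the unweighted mean over folds.
#' @slot k,seed Partition parameters.
#' @export
setClass("CrossValResult", representation(
  folds = "data.frame", pooled = "data.frame", foldMeans = "data.frame",
  k = "integer", seed = "integer"))
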