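# The hierarchical cascade: dichotomize each marker at its ROC cutoff,
# tally abnormal markers within each functional domain, re-ROC the integer
# tallies for a per-domain threshold, flag abnormal domains, then re-ROC
# the abnormal-domain count for the model-level case-detection threshold.

#' Dichotomize marker values at their cutoffs
#'
#' Scores every marker 0/1 for abnormality: for direction \code{"high"} a
#' value is abnormal when strictly above its cutoff, for \code{"low"} when
#' strictly below. Missing values stay \code{NA} (impute beforehand if a
#' complete flag matrix is needed; see [imputeMissing()]).
#'
#' @param values Numeric matrix, markers in rows, subjects in columns (or a
#'   [BiomarkerExperiment-class]).
#' @param cutoffs Named numeric vector of per-marker cutoffs.
#' @param directions Named character vector, \code{"high"}/\code{"low"}.
#' @return Integer 0/1 matrix of the same shape (with \code{NA}s preserved).
#' @export
dichotomize <- function(values, cutoffs, directions) {
  if (methods::is(values, "BiomarkerExperiment")) values <- markerValues(values)
  miss <- setdiff(rownames(values), names(cutoffs))
  if (length(miss))
    stop("no cutoff configured for marker(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(rownames(values), names(directions))
  if (length(miss))
    stop("no direction configured for marker(s): ", paste(miss, collapse = ", "))
  flags <- matrix(NA_integer_, nrow(values), ncol(values),
                  dimnames = dimnames(values))
  for (m in rownames(values)) {
    flags[m, ] <- if (directions[[m]] == "high")
      as.integer(values[m, ] > cutoffs[[m]])
    else
      as.integer(values[m, ] < cutoffs[[m]])
  }
  flags
}

# Per-subject tally of abnormal markers within each domain. A missing flag
# contributes nothing to the tally (screening-conservative); the tally is NA
# only when every member flag is missing.
.domainTallies <- function(flags, domains) {
  doms <- unique(domains)
  t(vapply(doms, function(d) {
    sub <- flags[domains == d, , drop = FALSE]
    tal <- colSums(sub, na.rm = TRUE)
    tal[colSums(!is.na(sub)) == 0] <- NA_real_
    tal
  }, numeric(ncol(flags))))
}

# Youden-optimal integer threshold for the rule "abnormal iff tally >= k",
# k scanned over 1..kMax. Ties go to the smallest k (favors sensitivity;
# the rule is a screening rule) unless tieRule = "specificity".
.tallyThreshold <- function(tally, case, kMax,
                            tieRule = c("sensitivity", "specificity")) {
  tieRule <- match.arg(tieRule)
  keep <- !is.na(tally)
  t <- tally[keep]; y <- case[keep]
  if (!length(t)) stop("degenerate input: all tallies missing")
  ks <- seq_len(kMax)
  J <- vapply(ks, function(k) mean(t[y] >= k) + mean(t[!y] < k) - 1,
              numeric(1))
  best <- which(J == max(J))
  k <- if (tieRule == "sensitivity") min(best) else max(best)
  list(threshold = as.integer(k),
       sensitivity = mean(t[y] >= k),
       specificity = mean(t[!y] < k),
       J = J[k])
}

#' Fit per-domain tally thresholds
#'
#' Treats each domain's integer tally of abnormal markers as a score,
#' re-runs ROC analysis on it, and selects the Youden-optimal minimum count
#' of abnormal markers for the domain itself to be called abnormal. A
#' single-marker domain reduces to that marker's own flag (threshold 1).
#'
#' @param flags 0/1 flag matrix from [dichotomize()].
#' @param labels Case/control labels.
#' @param domains Domain assignment per marker (named or in row order).
#' @param tieRule Tie-break among equal-Youden integer thresholds:
#'   \code{"sensitivity"} (smallest count; default) or \code{"specificity"}.
#' @return data.frame, one row per domain: domain, size, threshold, auc,
#'   pValue, sensitivity, specificity, nObs.
#' @export
fitDomainThresholds <- function(flags, labels, domains,
                                tieRule = "sensitivity") {
  case <- .caseLogical(labels)
  if (!is.null(names(domains))) domains <- domains[rownames(flags)]
  domains <- as.character(domains)
  tal <- .domainTallies(flags, domains)
  out <- lapply(rownames(tal), function(d) {
    size <- sum(domains == d)
    th <- .tallyThreshold(tal[d, ], case, kMax = size, tieRule = tieRule)
    a <- aucPValue(empiricalROC(tal[d, ], case, "high"))
    data.frame(domain = d, size = size, threshold = th$threshold,
               auc = a$auc, pValue = a$pValue,
               sensitivity = th$sensitivity, specificity = th$specificity,
               nObs = sum(!is.na(tal[d, ])))
  })
  do.call(rbind, out)
}

#' Fit the full hierarchical panel model
#'
#' Runs the whole cascade on a cohort: per-marker empirical ROC cutoffs,
#' dichotomous abnormality flags, per-domain tally thresholds, abnormal
#' domain flags, and finally a ROC analysis of the abnormal-domain count
#' giving the integer case-detection threshold. ROC performance is recorded
#' at all three levels.
#'
#' @param x A [BiomarkerExperiment-class], or a numeric matrix (markers x
#'   subjects) together with \code{labels} and \code{panel}.
#' @param labels Case/control labels (taken from \code{x} if omitted).
#' @param panel data.frame with columns \code{name}, \code{domain},
#'   \code{direction} (taken from \code{rowData(x)} if omitted).
#' @param criterion Per-marker cutoff criterion (see [selectCutoff()]).
#' @param tieRule Integer-threshold tie rule (see [fitDomainThresholds()]).
#' @return A [PanelModel-class].
#' @examples
#' be <- simulateCohort(defaultPanel(15), seed = 3)
#' fitPanelModel(be)
#' @export
fitPanelModel <- function(x, labels = NULL, panel = NULL,
                          criterion = "youden", tieRule = "sensitivity") {
  if (methods::is(x, "BiomarkerExperiment")) {
    if (is.null(labels)) labels <- subjectGroups(x)
    if (is.null(panel)) {
      info <- markerInfo(x)
      panel <- data.frame(name = rownames(x), domain = info$domain,
                          direction = info$direction)
    }
    x <- markerValues(x)
  }
  case <- .caseLogical(labels)
  if (!any(case) || !any(!case))
    stop("degenerate input: cohort must contain both cases and controls")
  x <- x[panel$name, , drop = FALSE]

  vres <- lapply(seq_len(nrow(panel)), function(j) {
    r <- tryCatch(
      rocAnalysis(x[j, ], case, panel$direction[j], criterion = criterion),
      error = function(e) stop("marker '", panel$name[j], "': ",
                               conditionMessage(e), call. = FALSE))
    cbind(name = panel$name[j], domain = panel$domain[j], rocResultRow(r))
  })
  variables <- do.call(rbind, vres)

  cutoffs <- setNames(variables$cutoff, variables$name)
  directions <- setNames(variables$direction, variables$name)
  flags <- dichotomize(x, cutoffs, directions)
  domains <- tryCatch(
    fitDomainThresholds(flags, case, setNames(panel$domain, panel$name),
                        tieRule = tieRule),
    error = function(e) stop("domain level: ", conditionMessage(e),
                             call. = FALSE))

  tal <- .domainTallies(flags, panel$domain)
  abn <- tal >= domains$threshold[match(rownames(tal), domains$domain)]
  count <- colSums(abn, na.rm = TRUE)
  count[colSums(!is.na(abn)) == 0] <- NA_real_

  nDom <- nrow(domains)
  th <- tryCatch(
    .tallyThreshold(count, case, kMax = nDom, tieRule = tieRule),
    error = function(e) stop("model level: ", conditionMessage(e),
                             call. = FALSE))
  a <- aucPValue(empiricalROC(count, case, "high"))
  keep <- !is.na(count)
  pred <- count[keep] >= th$threshold
  modelROC <- methods::new("ROCResult",
    auc = a$auc, pValue = a$pValue, cutoff = th$threshold - 0.5,
    sensitivity = th$sensitivity, specificity = th$specificity,
    dor = diagnosticOddsRatio(th$sensitivity, th$specificity),
    accuracy = mean(pred == case[keep]),
    nObs = sum(keep), nCases = sum(case[keep]), nControls = sum(!case[keep]),
    direction = "high")

  methods::new("PanelModel", variables = variables, domains = domains,
               threshold = th$threshold, modelROC = modelROC,
               options = list(criterion = criterion, tieRule = tieRule))
}

#' Score a cohort against a fitted panel model
#'
#' Applies a fitted [PanelModel-class] to (possibly new) marker data:
#' dichotomizes at the stored cutoffs, tallies abnormal markers per domain,
#' flags abnormal domains at the stored thresholds, counts abnormal domains
#' and applies the model-level detection rule.
#'
#' @param model A fitted [PanelModel-class].
#' @param x A [BiomarkerExperiment-class] or marker matrix containing all
#'   model markers (rows).
#' @return List with \code{flags} (marker x subject 0/1), \code{tallies}
#'   (domain x subject), \code{abnormal} (domain x subject logical),
#'   \code{count} (abnormal-domain count per subject) and \code{label}
#'   (factor control/case).
#' @export
scorePanel <- function(model, x) {
  if (methods::is(x, "BiomarkerExperiment")) x <- markerValues(x)
  miss <- setdiff(model@variables$name, rownames(x))
  if (length(miss))
    stop("cohort lacks model marker(s): ", paste(miss, collapse = ", "))
  x <- x[model@variables$name, , drop = FALSE]
  flags <- dichotomize(x,
                       setNames(model@variables$cutoff, model@variables$name),
                       setNames(model@variables$direction,
                                model@variables$name))
  tal <- .domainTallies(flags, model@variables$domain)
  tal <- tal[model@domains$domain, , drop = FALSE]
  abn <- tal >= model@domains$threshold
  count <- colSums(abn, na.rm = TRUE)
  count[colSums(!is.na(abn)) == 0] <- NA_real_
  label <- factor(ifelse(count >= model@threshold, "case", "control"),
                  levels = c("control", "case"))
  list(flags = flags, tallies = tal, abnormal = abn, count = count,
       label = label)
}

#' Classify subjects with a fitted panel model
#'
#' @param model A fitted [PanelModel-class].
#' @param x New marker data ([BiomarkerExperiment-class] or matrix).
#' @param ... Unused.
#' @return data.frame with \code{subject}, \code{count} (abnormal domains)
#'   and predicted \code{label}.
#' @export
setGeneric("classify", function(model, x, ...) standardGeneric("classify"))

#' @rdname classify
#' @export
setMethod("classify", "PanelModel", function(model, x, ...) {
  sc <- scorePanel(model, x)
  data.frame(subject = names(sc$count), count = sc$count,
             label = sc$label, row.names = NULL)
})

setMethod("show", "PanelModel", function(object) {
  cat("PanelModel:", nrow(object@variables), "markers in",
      nrow(object@domains), "domains\n")
  cat("  detection rule: >=", object@threshold, "abnormal domains\n")
  m <- object@modelROC
  cat(sprintf("  model-level AUC %.3f  sens %.3f  spec %.3f  DOR %.3g\n",
              m@auc, m@sensitivity, m@specificity, m@dor))
  d <- object@domains
  cat("  domain thresholds:",
      paste(sprintf("%s>=%d", d$domain, d$threshold), collapse = ", "), "\n")
})
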