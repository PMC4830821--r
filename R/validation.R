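# Model validation: stratified k-fold cross-validation of the cascade,
# missing-data imputation with an imputed/complete-case comparison, and
# Spearman correlation of model scores against external functional measures.

#' Class-stratified k-fold partition
#'
#' Randomizes cases and controls separately into k near-equal folds, so
#' every fold preserves the cohort's class balance.
#'
#' @param labels Case/control labels.
#' @param k Number of folds.
#' @param seed Integer seed; the partition is deterministic given the seed.
#' @return Integer fold assignment (1..k) per subject.
#' @export
stratifiedKFold <- function(labels, k = 5, seed = 1) {
  case <- .caseLogical(labels)
  if (min(sum(case), sum(!case)) < k)
    stop("each class must have at least k = ", k, " members")
  fold <- integer(length(case))
  withr::with_seed(seed, {
    for (cl in c(TRUE, FALSE)) {
      idx <- which(case == cl)
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  fold
}

# label-blind per-marker median imputer fitted on (training) data
.fitImputer <- function(values, method, case = NULL) {
  fill <- switch(method,
    none = NULL,
    median = apply(values, 1, median, na.rm = TRUE),
    groupMedian = list(
      case = apply(values[, case, drop = FALSE], 1, median, na.rm = TRUE),
      control = apply(values[, !case, drop = FALSE], 1, median, na.rm = TRUE)),
    stop("unknown imputation method: ", method))
  list(method = method, fill = fill)
}

.applyImputer <- function(values, imp, case = NULL) {
  if (imp$method == "none") return(values)
  for (m in rownames(values)) {
    na <- is.na(values[m, ])
    if (!any(na)) next
    if (imp$method == "median" || is.null(case)) {
      f <- if (is.list(imp$fill)) {
        # group-specific fills cannot be used without labels; average them
        (imp$fill$case[m] + imp$fill$control[m]) / 2
      } else imp$fill[m]
      values[m, na] <- f
    } else {
      values[m, na & case] <- imp$fill$case[m]
      values[m, na & !case] <- imp$fill$control[m]
    }
  }
  values
}

#' Impute missing marker values
#'
#' Default method replaces each missing value with the marker's overall
#' median across all subjects -- label-blind, so no group information leaks
#' into the completed table. \code{"groupMedian"} replicates the label-aware
#' convention (per-group medians) and is flagged in the report;
#' \code{"none"} returns the table unchanged. Observed values are never
#' altered.
#'
#' @param x A [BiomarkerExperiment-class].
#' @param method \code{"median"} (default), \code{"groupMedian"},
#'   or \code{"none"}.
#' @return List with \code{cohort} (completed
#'   \code{BiomarkerExperiment}) and \code{report} (data.frame: marker,
#'   nMissing, fractionMissing, method).
#' @export
imputeMissing <- function(x, method = c("median", "groupMedian", "none")) {
  method <- match.arg(method)
  vals <- markerValues(x)
  allMiss <- rowSums(!is.na(vals)) == 0
  if (any(allMiss) && method != "none")
    stop("marker(s) with no observed values cannot be imputed: ",
         paste(rownames(vals)[allMiss], collapse = ", "))
  case <- isCase(x)
  imp <- .fitImputer(vals, method, case)
  filled <- .applyImputer(vals, imp, case)
  out <- x
  SummarizedExperiment::assay(out, "markers") <- filled
  list(cohort = out,
       report = data.frame(marker = rownames(vals),
                           nMissing = rowSums(is.na(vals)),
                           fractionMissing = rowMeans(is.na(vals)),
                           method = method, row.names = NULL))
}

#' Compare cascade performance with and without imputation
#'
#' Fits the full panel model on the imputed and on the untouched
#' (complete-pairs) cohort and reports model-level performance side by
#' side.
#'
#' @param x A [BiomarkerExperiment-class].
#' @param method Imputation method for the imputed arm.
#' @return data.frame with one row per arm: arm, auc, sensitivity,
#'   specificity, accuracy, threshold, nObs.
#' @export
compareImputation <- function(x, method = "median") {
  arm <- function(name, be) {
    m <- fitPanelModel(be)
    r <- m@modelROC
    data.frame(arm = name, auc = r@auc, sensitivity = r@sensitivity,
               specificity = r@specificity, accuracy = r@accuracy,
               threshold = m@threshold, nObs = r@nObs)
  }
  rbind(arm("complete_case", x),
        arm(method, imputeMissing(x, method)$cohort))
}

#' Stratified k-fold cross-validation of the cascade
#'
#' For each fold, the entire cascade (marker cutoffs, domain thresholds,
#' model threshold) is refit on the training four-fifths and evaluated on
#' the held-out fifth; nothing from a test subject influences the
#' thresholds applied to it. Predictive values are computed from each
#' fold's sensitivity/specificity at every configured population
#' prevalence. The pooled summary applies each fold's rule to its own test
#' fold and aggregates the concatenated predictions; the unweighted mean
#' over folds is reported alongside.
#'
#' @param x A [BiomarkerExperiment-class].
#' @param k Number of folds (default 5).
#' @param seed Seed for the stratified partition.
#' @param prevalences Population prevalences for PPV/NPV (defaults 0.0035
#'   and 0.30).
#' @param cutoffs \code{"refit"} (default; marker cutoffs refit inside each
#'   training fold -- the honest-validation choice) or \code{"frozen"}
#'   (marker cutoffs fixed from the full data; only domain and model
#'   thresholds refit per fold).
#' @param criterion,tieRule Passed to [fitPanelModel()].
#' @return A [CrossValResult-class].
#' @export
crossValidate <- function(x, k = 5, seed = 1,
                          prevalences = c(0.0035, 0.30),
                          cutoffs = c("refit", "frozen"),
                          criterion = "youden", tieRule = "sensitivity") {
  cutoffs <- match.arg(cutoffs)
  case <- isCase(x)
  fold <- stratifiedKFold(case, k = k, seed = seed)
  vals <- markerValues(x)
  info <- markerInfo(x)
  panel <- data.frame(name = rownames(x), domain = info$domain,
                      direction = info$direction)
  frozenCuts <- if (cutoffs == "frozen") {
    m <- fitPanelModel(vals, case, panel, criterion, tieRule)
    setNames(m@variables$cutoff, m@variables$name)
  }
  foldRows <- list(); allCount <- numeric(0); allPred <- logical(0)
  allCase <- logical(0)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    model <- tryCatch({
      m <- fitPanelModel(vals[, tr, drop = FALSE], case[tr], panel,
                         criterion, tieRule)
      if (!is.null(frozenCuts)) {
        m@variables$cutoff <- unname(frozenCuts[m@variables$name])
        flags <- dichotomize(vals[, tr, drop = FALSE],
                             frozenCuts,
                             setNames(panel$direction, panel$name))
        m@domains <- fitDomainThresholds(flags, case[tr],
                                         setNames(panel$domain, panel$name),
                                         tieRule)
        tal <- .domainTallies(flags, panel$domain)
        abn <- tal >= m@domains$threshold[match(rownames(tal),
                                                m@domains$domain)]
        cnt <- colSums(abn, na.rm = TRUE)
        m@threshold <- .tallyThreshold(cnt, case[tr],
                                       nrow(m@domains), tieRule)$threshold
      }
      m
    }, error = function(e) {
      warning("fold ", f, " skipped: ", conditionMessage(e)); NULL
    })
    if (is.null(model)) next
    sc <- scorePanel(model, vals[, te, drop = FALSE])
    cnt <- sc$count; yc <- case[te]
    ok <- !is.na(cnt)
    pred <- cnt[ok] >= model@threshold
    sens <- mean(pred[yc[ok]]); spec <- mean(!pred[!yc[ok]])
    auc <- tryCatch(aucPValue(empiricalROC(cnt, yc, "high"))$auc,
                    error = function(e) NA_real_)
    tp <- sum(pred & yc[ok]); fn <- sum(!pred & yc[ok])
    fp <- sum(pred & !yc[ok]); tn <- sum(!pred & !yc[ok])
    dor <- if (any(c(tp, fn, fp, tn) == 0))
      diagnosticOddsRatio(counts = c(tp, fn, fp, tn))
    else diagnosticOddsRatio(sens, spec)
    pv <- predictiveValues(sens, spec, prevalences)
    foldRows[[f]] <- data.frame(fold = f, nObs = sum(ok),
                                prevalence = pv$prevalence,
                                sensitivity = sens, specificity = spec,
                                auc = auc, dor = dor,
                                ppv = pv$ppv, npv = pv$npv)
    allCount <- c(allCount, cnt[ok]); allPred <- c(allPred, pred)
    allCase <- c(allCase, yc[ok])
  }
  if (!length(foldRows)) stop("all folds degenerate")
  folds <- do.call(rbind, foldRows)

  sens <- mean(allPred[allCase]); spec <- mean(!allPred[!allCase])
  pv <- predictiveValues(sens, spec, prevalences)
  pooled <- data.frame(fold = NA_integer_, nObs = length(allPred),
                       prevalence = pv$prevalence,
                       sensitivity = sens, specificity = spec,
                       auc = aucPValue(empiricalROC(allCount, allCase,
                                                    "high"))$auc,
                       dor = diagnosticOddsRatio(sens, spec),
                       ppv = pv$ppv, npv = pv$npv)
  num <- c("nObs", "sensitivity", "specificity", "auc", "dor", "ppv", "npv")
  foldMeans <- do.call(rbind, lapply(split(folds, folds$prevalence),
    function(d) {
      out <- d[1, ]
      out[num] <- colMeans(d[num], na.rm = TRUE)
      out$fold <- NA_integer_
      out
    }))
  rownames(foldMeans) <- NULL
  methods::new("CrossValResult", folds = folds, pooled = pooled,
               foldMeans = foldMeans, k = as.integer(k),
               seed = as.integer(seed))
}

setMethod("show", "CrossValResult", function(object) {
  cat("CrossValResult: ", object@k, "-fold, seed ", object@seed, "\n",
      sep = "")
  fmt <- function(d) transform(d, sensitivity = round(sensitivity, 3),
                               specificity = round(specificity, 3),
                               auc = round(auc, 3), dor = round(dor, 1),
                               ppv = round(ppv, 3), npv = round(npv, 3))
  print(fmt(object@folds), row.names = FALSE)
  cat("pooled:\n"); print(fmt(object@pooled), row.names = FALSE)
})

#' Spearman correlation of model scores with functional measures
#'
#' Correlates per-subject domain tallies and the abnormal-domain count
#' ("set score") with external functional measures (severity, disability,
#' service use), using tie-corrected Spearman rho with pairwise-complete
#' observations.
#'
#' @param x A [BiomarkerExperiment-class] carrying functional measures in
#'   its colData, or a numeric matrix/data.frame of scores (subjects in
#'   rows).
#' @param model A fitted [PanelModel-class] (required when \code{x} is a
#'   cohort) used to derive the scores.
#' @param measures Optional data.frame of measures (subjects in rows);
#'   defaults to the cohort's functional measures.
#' @return List of matrices \code{rho}, \code{pValue}, \code{n}
#'   (scores x measures).
#' @export
functionalCorrelates <- function(x, model = NULL, measures = NULL) {
  if (methods::is(x, "BiomarkerExperiment")) {
    if (is.null(measures)) {
      measures <- functionalMeasures(x)
      measures <- measures[, vapply(measures, is.numeric, logical(1)),
                           drop = FALSE]
      measures$latent_severity <- NULL
    }
    if (is.null(model)) stop("a fitted PanelModel is required")
    sc <- scorePanel(model, x)
    scores <- cbind(as.data.frame(t(sc$tallies)), set_score = sc$count)
  } else {
    scores <- as.data.frame(x)
    if (is.null(measures)) stop("supply 'measures' with raw scores")
  }
  measures <- as.data.frame(measures)
  rho <- p <- n <- matrix(NA_real_, ncol(scores), ncol(measures),
                          dimnames = list(colnames(scores),
                                          colnames(measures)))
  for (i in seq_len(ncol(scores))) for (j in seq_len(ncol(measures))) {
    r <- spearmanRho(scores[[i]], measures[[j]])
    rho[i, j] <- r$rho; p[i, j] <- r$pValue; n[i, j] <- r$n
  }
  list(rho = rho, pValue = p, n = n)
}
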