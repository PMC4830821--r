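#' Construct a BiomarkerExperiment
#'
#' @param values Numeric matrix of marker values, markers in rows and
#'   subjects in columns (missing values as \code{NA}), or a data.frame
#'   subjects-in-rows which is transposed.
#' @param group Character or factor of length \code{ncol(values)} with values
#'   \code{"case"}/\code{"control"}.
#' @param domain Character vector, the functional domain of each marker.
#' @param direction Character vector, \code{"high"} if abnormally high values
#'   indicate caseness, \code{"low"} for abnormally low.
#' @param functional Optional data.frame of per-subject functional measures
#'   (e.g. SIR, GAF, CGI, SOFAS, admission_rate, pension_flag).
#' @param subjectIds Optional subject identifiers (default from columns).
#' @param markerInfo Optional data.frame of further per-marker metadata
#'   merged into \code{rowData} (e.g. \code{target_auc}, \code{missing_rate}).
#'
#' @return A [BiomarkerExperiment-class].
#' @examples
#' vals <- matrix(rnorm(20), nrow = 2,
#'                dimnames = list(c("m1", "m2"), paste0("s", 1:10)))
#' be <- BiomarkerExperiment(vals, group = rep(c("case", "control"), 5),
#'                           domain = c("d1", "d1"),
#'                           direction = c("high", "low"))
#' subjectGroups(be)
#' @export
BiomarkerExperiment <- function(values, group, domain, direction,
                                functional = NULL, subjectIds = NULL,
                                markerInfo = NULL) {
  if (is.data.frame(values)) values <- t(as.matrix(values))
  storage.mode(values) <- "double"
  if (is.null(subjectIds)) {
    subjectIds <- colnames(values)
    if (is.null(subjectIds)) subjectIds <- sprintf("S%03d", seq_len(ncol(values)))
  }
  colnames(values) <- subjectIds
  group <- factor(as.character(group), levels = c("control", "case"))
  if (anyNA(group)) stop("group labels must be 'case' or 'control'")
  cd <- S4Vectors::DataFrame(group = group, row.names = subjectIds)
  if (!is.null(functional)) {
    stopifnot(nrow(functional) == ncol(values))
    cd <- cbind(cd, S4Vectors::DataFrame(functional))
  }
  rd <- S4Vectors::DataFrame(domain = as.character(domain),
                             direction = as.character(direction),
                             row.names = rownames(values))
  if (!is.null(markerInfo)) rd <- cbind(rd, S4Vectors::DataFrame(markerInfo))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(markers = values), colData = cd, rowData = rd)
  methods::new("BiomarkerExperiment", se)
}

#' @describeIn BiomarkerExperiment Marker value matrix (markers x subjects).
#' @param x,object A \code{BiomarkerExperiment}.
#' @export
markerValues <- function(x) SummarizedExperiment::assay(x, "markers")

#' @describeIn BiomarkerExperiment Group factor (levels control, case).
#' @export
subjectGroups <- function(x) SummarizedExperiment::colData(x)$group

#' @describeIn BiomarkerExperiment Logical vector: TRUE for cases.
#' @export
isCase <- function(x) subjectGroups(x) == "case"

#' @describeIn BiomarkerExperiment Per-marker metadata (domain, direction, ...).
#' @export
markerInfo <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' @describeIn BiomarkerExperiment Domain assignment, named by marker.
#' @export
domainMap <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  setNames(as.character(rd$domain), rownames(x))
}

#' @describeIn BiomarkerExperiment Per-subject functional measures
#'   (all colData columns except \code{group}), as a data.frame.
#' @export
functionalMeasures <- function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cd[, setdiff(colnames(cd), "group"), drop = FALSE]
}

setMethod("show", "BiomarkerExperiment", function(object) {
  g <- subjectGroups(object)
  cat("BiomarkerExperiment:", nrow(object), "markers x", ncol(object),
      "subjects (", sum(g == "case"), "cases /", sum(g == "control"),
      "controls )\n")
  cat("domains:", paste(unique(markerInfo(object)$domain), collapse = ", "),
      "\n")
  miss <- mean(is.na(markerValues(object)))
  cat(sprintf("missingness: %.1f%%", 100 * miss), "\n")
  fm <- colnames(functionalMeasures(object))
  if (length(fm)) cat("functional measures:", paste(fm, collapse = ", "), "\n")
})
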