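# Plain-text interchange: cohorts as CSV (missing values as empty fields),
# panel configuration and fitted models as YAML, and a set of CSV report
# tables mirroring the standard variable / domain / model / risk / CV /
# correlation layout.

#' Write a cohort to CSV
#'
#' One row per subject with header
#' \code{subject_id,group,<markers...>,<functional measures...>}; missing
#' values are written as empty fields. The written file is byte-identical
#' for identical cohorts.
#'
#' @param x A [BiomarkerExperiment-class].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(x, path) {
  vals <- t(markerValues(x))
  fm <- functionalMeasures(x)
  df <- data.frame(subject_id = colnames(markerValues(x)),
                   group = as.character(subjectGroups(x)),
                   vals, fm, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Expects a header row with \code{subject_id}, \code{group}
#' (case/control) and one column per marker; empty fields become missing
#' values. Columns not named in the panel are kept as functional measures.
#'
#' @param path CSV file path.
#' @param panel Panel specification giving marker names, domains and
#'   directions (default [defaultPanel()]; markers absent from the file
#'   are dropped from the panel with a message).
#' @return A [BiomarkerExperiment-class].
#' @export
readCohort <- function(path, panel = defaultPanel(21)) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject_id", "group")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("cohort file lacks required column(s): ",
         paste(miss, collapse = ", "))
  bad <- !df$group %in% c("case", "control")
  if (any(bad))
    stop("unknown group label in row(s) ",
         paste(head(which(bad), 5), collapse = ", "),
         ": ", paste(unique(df$group[bad]), collapse = ", "))
  absent <- setdiff(panel$name, colnames(df))
  if (length(absent)) {
    message("panel marker(s) not in file, dropped: ",
            paste(absent, collapse = ", "))
    panel <- panel[!panel$name %in% absent, ]
  }
  if (!nrow(panel)) stop("no panel markers found in file")
  for (m in panel$name) {
    v <- df[[m]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad))
        stop("non-numeric value in column '", m, "', row(s) ",
             paste(head(bad, 5), collapse = ", "))
      df[[m]] <- num
    }
  }
  vals <- t(as.matrix(df[, panel$name, drop = FALSE]))
  rownames(vals) <- panel$name
  other <- setdiff(colnames(df), c(need, panel$name))
  functional <- if (length(other)) df[, other, drop = FALSE]
  BiomarkerExperiment(vals, group = df$group, domain = panel$domain,
                      direction = panel$direction, functional = functional,
                      subjectIds = as.character(df$subject_id))
}

#' Read / write a cohort simulation configuration (YAML)
#'
#' The YAML mirrors the arguments of [simulateCohort()]: scalar keys
#' \code{n_cases}, \code{n_controls}, \code{within_domain_correlation},
#' \code{severity_loading}, \code{seed}, and a \code{variables} list with
#' per-marker \code{name}, \code{domain}, \code{direction},
#' \code{control_mean}, \code{control_sd}, \code{target_auc},
#' \code{missing_rate}. A \code{schema} key versions the layout.
#'
#' @param path YAML file path.
#' @return \code{readCohortConfig}: a list with element \code{panel}
#'   (data.frame) plus the scalar settings, directly splicable into
#'   [simulateCohort()] via \code{do.call}.
#' @export
readCohortConfig <- function(path) {
  y <- yaml::read_yaml(path)
  panel <- do.call(rbind, lapply(y$variables, function(v)
    data.frame(name = v$name, domain = v$domain, direction = v$direction,
               control_mean = v$control_mean %||% 0,
               control_sd = v$control_sd %||% 1,
               target_auc = v$target_auc,
               missing_rate = v$missing_rate %||% 0)))
  list(panel = .checkPanel(panel),
       nCases = y$n_cases %||% 67, nControls = y$n_controls %||% 67,
       withinDomainCor = y$within_domain_correlation %||% 0.2,
       severityLoading = y$severity_loading %||% 0.8,
       seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readCohortConfig
#' @param config List as returned by \code{readCohortConfig} (or with the
#'   same elements).
#' @export
writeCohortConfig <- function(config, path) {
  vars <- lapply(seq_len(nrow(config$panel)), function(i)
    as.list(config$panel[i, ]))
  yaml::write_yaml(list(schema = 1L,
                        n_cases = config$nCases,
                        n_controls = config$nControls,
                        within_domain_correlation = config$withinDomainCor,
                        severity_loading = config$severityLoading,
                        seed = config$seed,
                        variables = vars), path)
  invisible(path)
}

#' Serialize / restore a fitted panel model (YAML)
#'
#' Stores everything needed to apply the rule to new cohorts: per-marker
#' cutoffs and directions, per-domain tally thresholds, and the
#' model-level detection threshold.
#'
#' @param model A fitted [PanelModel-class].
#' @param path YAML file path.
#' @export
writePanelModel <- function(model, path) {
  v <- model@variables; d <- model@domains
  yaml::write_yaml(list(
    schema = 1L,
    threshold = model@threshold,
    options = model@options,
    domains = lapply(seq_len(nrow(d)), function(i)
      list(domain = d$domain[i], size = d$size[i],
           threshold = d$threshold[i])),
    variables = lapply(seq_len(nrow(v)), function(i)
      list(name = v$name[i], domain = v$domain[i],
           direction = v$direction[i], cutoff = v$cutoff[i]))),
    path, precision = 15)
  invisible(path)
}

#' @rdname writePanelModel
#' @return \code{readPanelModel}: a [PanelModel-class] carrying the stored
#'   rule (performance slots are empty placeholders).
#' @export
readPanelModel <- function(path) {
  y <- yaml::read_yaml(path)
  v <- do.call(rbind, lapply(y$variables, function(z)
    data.frame(name = z$name, domain = z$domain, direction = z$direction,
               cutoff = z$cutoff)))
  d <- do.call(rbind, lapply(y$domains, function(z)
    data.frame(domain = z$domain, size = z$size,
               threshold = as.integer(z$threshold))))
  empty <- methods::new("ROCResult", auc = NA_real_, pValue = NA_real_,
                        cutoff = y$threshold - 0.5, sensitivity = NA_real_,
                        specificity = NA_real_, dor = NA_real_,
                        accuracy = NA_real_, nObs = 0L, nCases = 0L,
                        nControls = 0L, direction = "high")
  methods::new("PanelModel", variables = v, domains = d,
               threshold = as.integer(y$threshold), modelROC = empty,
               options = y$options %||% list())
}

#' Write the full set of report tables
#'
#' Emits the analysis as CSV tables: marker-level ROC parameters (layout
#' No. Obs, AUC, SENS, SPEC, PPV, NPV, ROC P value, Odds ratio, Accuracy),
#' domain-level thresholds and performance, the model-level rule, the
#' risk-by-count table, cross-validation results, the functional
#' correlation matrix, plus a plain-text summary recording seed, a
#' configuration hash and the package version. Identical inputs produce
#' byte-identical files.
#'
#' @param outdir Output directory (created if needed).
#' @param model A fitted [PanelModel-class].
#' @param cv Optional [CrossValResult-class].
#' @param risk Optional risk table from [riskTable()].
#' @param correlates Optional result of [functionalCorrelates()].
#' @param prevalence Prevalence used for the marker-table PPV/NPV columns
#'   (default 0.0035).
#' @param seed Seed to record in the run log.
#' @return Character vector of files written, invisibly.
#' @export
panelReport <- function(outdir, model, cv = NULL, risk = NULL,
                        correlates = NULL, prevalence = 0.0035, seed = NA) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ok <- file.access(outdir, 2) == 0
  if (!ok) stop("output directory is not writable: ", outdir)
  files <- character(0)
  put <- function(df, name) {
    f <- file.path(outdir, name)
    write.csv(df, f, row.names = FALSE, na = "")
    files <<- c(files, f)
  }
  v <- model@variables
  pv <- predictiveValues(v$sensitivity, v$specificity, prevalence)
  put(data.frame(domain = v$domain, variable = v$name, n_obs = v$nObs,
                 auc = v$auc, sens = v$sensitivity, spec = v$specificity,
                 ppv = pv$ppv, npv = pv$npv, roc_p_value = v$rocPValue,
                 odds_ratio = v$oddsRatio, accuracy = v$accuracy,
                 cutoff = v$cutoff, direction = v$direction),
      "variables.csv")
  d <- model@domains
  dpv <- predictiveValues(d$sensitivity, d$specificity, prevalence)
  put(cbind(d, ppv = dpv$ppv, npv = dpv$npv), "domains.csv")
  m <- model@modelROC
  mpv <- predictiveValues(m@sensitivity, m@specificity, prevalence)
  put(data.frame(threshold = model@threshold, n_obs = m@nObs, auc = m@auc,
                 sens = m@sensitivity, spec = m@specificity,
                 ppv = mpv$ppv, npv = mpv$npv, roc_p_value = m@pValue,
                 odds_ratio = m@dor, accuracy = m@accuracy), "model.csv")
  if (!is.null(risk)) put(risk, "risk.csv")
  if (!is.null(cv)) {
    put(rbind(cv@folds, pooled = cv@pooled), "crossval.csv")
  }
  if (!is.null(correlates)) {
    put(data.frame(score = rownames(correlates$rho),
                   round(correlates$rho, 4), check.names = FALSE),
        "correlates.csv")
  }
  cfg <- c(model@options, list(threshold = model@threshold, seed = seed))
  hash <- sum(utf8ToInt(paste(deparse(cfg), collapse = "")) *
                seq_along(utf8ToInt(paste(deparse(cfg), collapse = "")))) %%
    1e9
  log <- file.path(outdir, "summary.txt")
  writeLines(c(
    paste0("panelROC version: ", as.character(packageVersion("panelROC"))),
    paste0("seed: ", seed),
    paste0("config hash: ", format(hash, scientific = FALSE)),
    paste0("markers: ", nrow(v), "; domains: ", nrow(d)),
    paste0("detection rule: >= ", model@threshold, " abnormal domains"),
    sprintf("model AUC %.4f, sensitivity %.4f, specificity %.4f",
            m@auc, m@sensitivity, m@specificity)), log)
  files <- c(files, log)
  invisible(files)
}
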