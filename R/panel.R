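# The default biomarker panel: 21 markers in six functional domains.
# Per-marker discrimination (target AUC) and observation counts follow the
# published panel; missing rates are derived as (134 - nObs)/134. Marker
# values are on a standardized scale (control mean 0, sd 1) because no
# per-marker distributions are published -- under the equal-variance
# binormal model the AUC alone fixes the case shift.

.panelTable <- function() {
  x <- rbind(
    c("visual_span",          "visual",                 "low",  0.862, 126),
    c("visual_speed",         "visual",                 "high", 0.875, 122),
    c("distance_vision_right","visual",                 "low",  0.597, 128),
    c("reverse_digit_span",   "auditory",               "low",  0.810, 127),
    c("competing_words",      "auditory",               "high", 0.799, 124),
    c("auditory_speed",       "auditory",               "high", 0.874, 121),
    c("dopamine",             "catecholamine",          "high", 0.702, 133),
    c("noradrenaline",        "catecholamine",          "high", 0.851, 133),
    c("adrenaline",           "catecholamine",          "high", 0.844, 133),
    c("hpl_creatinine",       "oxidative_stress",       "high", 0.696, 133),
    c("copper_zinc_ratio",    "biochemistry_nutrition", "high", 0.611, 133),
    c("b6_activation",        "biochemistry_nutrition", "low",  0.638, 129),
    c("red_cell_folate",      "biochemistry_nutrition", "low",  0.654, 133),
    c("serum_b12",            "biochemistry_nutrition", "high", 0.565, 134),
    c("vitamin_d",            "biochemistry_nutrition", "low",  0.651, 132),
    c("ear_canal_volume",     "middle_ear",             "high", 0.603, 123),
    c("peak_me_pressure",     "middle_ear",             "low",  0.617, 124),
    c("gradient_me_pressure", "middle_ear",             "high", 0.580, 124),
    c("stapes_amplitude",     "middle_ear",             "high", 0.626, 123),
    c("reflex_offset_ratio",  "middle_ear",             "low",  0.659, 122),
    c("reflex_base_duration", "middle_ear",             "high", 0.657, 122))
  data.frame(name = x[, 1], domain = x[, 2], direction = x[, 3],
             control_mean = 0, control_sd = 1,
             target_auc = as.numeric(x[, 4]),
             missing_rate = (134 - as.numeric(x[, 5])) / 134,
             stringsAsFactors = FALSE)
}

#' Default biomarker panel specification
#'
#' The built-in panel: 15 markers in five functional domains (visual,
#' auditory, catecholamine, oxidative stress, biochemistry-nutrition; sizes
#' 3, 3, 3, 1, 5), optionally extended by the six supplementary middle-ear
#' markers to the full 21-marker, six-domain set. Each row gives the marker
#' name, its domain, the abnormality direction, the control-group mean and
#' sd on the simulation scale, the target AUC it discriminates cases at,
#' and its missing-data rate.
#'
#' @param markers 15 (five domains) or 21 (adds the middle-ear domain).
#' @return data.frame with columns \code{name}, \code{domain},
#'   \code{direction}, \code{control_mean}, \code{control_sd},
#'   \code{target_auc}, \code{missing_rate}.
#' @examples
#' table(defaultPanel(21)$domain)
#' @export
defaultPanel <- function(markers = c(15, 21)) {
  markers <- match.arg(as.character(markers[1]), c("15", "21"))
  p <- .panelTable()
  if (markers == "15") p <- p[p$domain != "middle_ear", ]
  rownames(p) <- NULL
  p
}

#' Ordered domain list of a panel
#'
#' @param panel A panel data.frame as returned by [defaultPanel()].
#' @return Character vector of domain names in first-appearance order.
#' @export
panelDomains <- function(panel) unique(panel$domain)

.checkPanel <- function(panel) {
  need <- c("name", "domain", "direction", "target_auc", "missing_rate")
  miss <- setdiff(need, colnames(panel))
  if (length(miss)) stop("panel is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(panel$name)) stop("duplicate marker names in panel")
  if (!all(panel$direction %in% c("high", "low")))
    stop("panel directions must be 'high' or 'low'")
  if (any(panel$target_auc <= 0.5 | panel$target_auc >= 1))
    stop("target_auc must lie strictly in (0.5, 1)")
  if (any(panel$missing_rate < 0 | panel$missing_rate >= 0.5))
    stop("missing_rate must lie in [0, 0.5)")
  if (is.null(panel$control_mean)) panel$control_mean <- 0
  if (is.null(panel$control_sd)) panel$control_sd <- 1
  if (any(panel$control_sd <= 0)) stop("control_sd must be positive")
  panel
}
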