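#' Snellen visual acuity
#'
#' A Snellen acuity is either a ratio (test distance over letter size, e.g.
#' 20/40) or one of the categorical low-vision codes CF (counting fingers),
#' HM (hand motion), LP (light perception), NLP (no light perception).
#' LogMAR is derived as `-log10(numerator/denominator)`, so 20/20 maps to
#' 0.0 and 20/200 to 1.0; larger LogMAR is worse. Low-vision codes carry
#' conventional LogMAR values (CF 1.9, HM 2.3, LP 2.7, NLP 3.0), flagged as
#' imputed.
#'
#' @param x either a string like `"20/40"` or a low-vision code, or the
#'   numerator when `denominator` is given.
#' @param denominator optional denominator when `x` is numeric.
#' @return a `snellen_va` object with fields `numerator`, `denominator`,
#'   `code`, `logmar`, `imputed`.
#' @examples
#' snellen_va("20/20")$logmar   # 0
#' snellen_va("20/200")$logmar  # 1
#' @export
snellen_va <- function(x, denominator = NULL) {
  codes <- c(CF = 1.9, HM = 2.3, LP = 2.7, NLP = 3.0)
  if (is.character(x) && toupper(x) %in% names(codes)) {
    code <- toupper(x)
    return(structure(list(numerator = NA_real_, denominator = NA_real_,
                          code = code, logmar = unname(codes[code]),
                          imputed = TRUE), class = "snellen_va"))
  }
  if (is.character(x)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("not a Snellen ratio: ", x)
    num <- as.numeric(parts[1]); den <- as.numeric(parts[2])
  } else {
    num <- as.numeric(x); den <- as.numeric(denominator)
  }
  if (is.na(num) || is.na(den) || num <= 0 || den <= 0)
    stop("Snellen numerator and denominator must be positive")
  structure(list(numerator = num, denominator = den, code = NA_character_,
                 logmar = -log10(num / den) + 0,  # + 0 folds -0 to 0
                 imputed = FALSE),
            class = "snellen_va")
}

#' @export
format.snellen_va <- function(x, ...) {
  if (!is.na(x$code)) x$code else sprintf("%g/%g", x$numerator, x$denominator)
}

#' @export
print.snellen_va <- function(x, ...) {
  cat(format(x), sprintf(" (LogMAR %.3f)\n", x$logmar)); invisible(x)
}

#' Convert Snellen acuity to LogMAR
#'
#' @param va a [snellen_va()] or anything accepted by its constructor.
#' @return LogMAR value, exact to double precision for ratio acuities.
#' @export
snellen_to_logmar <- function(va) {
  if (!inherits(va, "snellen_va")) va <- snellen_va(va)
  va$logmar
}

#' Default Snellen chart line sequence
#'
#' Ordered best to worst; low-vision codes occupy the worst lines. The chart
#' used by [classify_stability()] is configurable — this is the conventional
#' default.
#'
#' @return character vector of chart lines.
#' @export
snellen_chart <- function() {
  c("20/10", "20/15", "20/20", "20/25", "20/30", "20/40", "20/50", "20/60",
    "20/70", "20/80", "20/100", "20/200", "20/400", "CF", "HM", "LP", "NLP")
}

# Map an acuity to its chart line index (1 = best). Off-chart acuities are
# mapped to the nearest line by LogMAR, with attribute nearest = TRUE.
chart_line_index <- function(va, chart = snellen_chart()) {
  if (!inherits(va, "snellen_va")) va <- snellen_va(va)
  lm_chart <- vapply(chart, function(s) snellen_va(s)$logmar, numeric(1))
  hit <- which(abs(lm_chart - va$logmar) < 1e-9)
  if (length(hit)) {
    out <- hit[1]
    attr(out, "nearest") <- FALSE
  } else {
    out <- which.min(abs(lm_chart - va$logmar))
    attr(out, "nearest") <- TRUE
  }
  out
}

#' Classify visual-acuity stability between two visits
#'
#' Stable acuity means changing fewer than two lines on the Snellen chart;
#' a drop of two or more lines is `"worsened"`, a gain of two or more lines
#' `"improved"`. Acuities not on the chart are mapped to the nearest line
#' (a `nearest_line` attribute marks the approximation).
#'
#' @param baseline,followup [snellen_va()] values (or constructor inputs).
#' @param chart ordered line list, best first (default [snellen_chart()]).
#' @return one of `"stable"`, `"worsened"`, `"improved"`.
#' @export
classify_stability <- function(baseline, followup, chart = snellen_chart()) {
  i_b <- chart_line_index(baseline, chart)
  i_f <- chart_line_index(followup, chart)
  d <- as.integer(i_f) - as.integer(i_b)   # positive = worse (later line)
  out <- if (d >= 2) "worsened" else if (d <= -2) "improved" else "stable"
  attr(out, "nearest_line") <- attr(i_b, "nearest") || attr(i_f, "nearest")
  out
}

#' Assign a visual acuity to a reporting category
#'
#' Default bins follow the usual clinic groupings: 20/20-20/30 (or better),
#' 20/40-20/60, 20/70-20/100, and 20/200 or worse (low-vision codes fall in
#' the worst bin).
#'
#' @param va a [snellen_va()] or constructor input.
#' @param edges upper LogMAR bounds (exclusive) of all bins but the last.
#' @param labels bin labels, one more than `edges`.
#' @return the bin label.
#' @export
categorize_va <- function(va,
                          edges = -log10(20 / c(35, 65, 150)),
                          labels = c("20/20-20/30", "20/40-20/60",
                                     "20/70-20/100", "20/200 or worse")) {
  stopifnot(length(labels) == length(edges) + 1)
  lm <- snellen_to_logmar(va)
  labels[findInterval(lm, edges) + 1]
}

#' Names of the 24 blood-panel analytes
#'
#' Serum chemistry, renal function, liver function, hematology and lipid
#' analytes as reported on standard clinical panels.
#'
#' @return character vector of analyte names.
#' @export
lab_analytes <- function() {
  c("Glucose", "A1c", "Albumin", "Cr", "EGFR", "BUN", "Protein", "Globulin",
    "Alk Phos", "ALT", "AST", "Bili", "K", "Ca", "Cl", "Na", "CO2", "Hgb",
    "RDW", "Hct", "Chol-HDL", "Chol-LDL", "Chol-Non-HDL", "Chol")
}

#' Standardize blood panels against the control group
#'
#' Per analyte, `z = (x - mean_ctrl) / sd_ctrl`, so the control group's own
#' z-scores have mean 0 and sd 1. Analytes with fewer than 2 non-missing
#' control values or zero control sd are excluded and listed in `excluded`.
#'
#' @param dm_panels data.frame of patient panels (one row per panel, analyte
#'   columns).
#' @param ctrl_panels data.frame of control panels with the same columns.
#' @param analytes columns to standardize (default: intersection with
#'   [lab_analytes()]).
#' @return list with `z` (data.frame of z-scores for `dm_panels`),
#'   `center`, `scale` (named control mean/sd), and `excluded`.
#' @export
standardize_labs <- function(dm_panels, ctrl_panels,
                             analytes = intersect(lab_analytes(),
                                                  colnames(dm_panels))) {
  center <- scale_ <- stats::setNames(numeric(0), character(0))
  excluded <- character(0)
  z <- dm_panels[intersect(analytes, colnames(dm_panels))]
  for (a in analytes) {
    v <- ctrl_panels[[a]]
    v <- v[!is.na(v)]
    if (length(v) < 2 || stats::sd(v) == 0) {
      excluded <- c(excluded, a)
      z[[a]] <- NULL
      next
    }
    center[a] <- mean(v)
    scale_[a] <- stats::sd(v)
    z[[a]] <- (dm_panels[[a]] - center[a]) / scale_[a]
  }
  list(z = z, center = center, scale = scale_, excluded = excluded)
}

#' Invert control-group standardization
#'
#' @param z data.frame of z-scores from [standardize_labs()].
#' @param std the [standardize_labs()] result carrying `center` and `scale`.
#' @return data.frame of raw values.
#' @export
unstandardize_labs <- function(z, std) {
  out <- z
  for (a in colnames(z)) out[[a]] <- z[[a]] * std$scale[a] + std$center[a]
  out
}
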