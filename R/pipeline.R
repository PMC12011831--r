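# End-to-end orchestration: quantify a directory of images, analyze a
# cohort table, or run the whole synthetic demonstration bundle.

#' Run configuration
#'
#' Exactly one input source is active: a directory of real images and/or a
#' cohort CSV, or the synthetic generators. All randomness derives from the
#' single `seed` (per-module seeds are fixed offsets of it).
#'
#' @param image_dir directory of TIFF/PNG flow images with JSON sidecars.
#' @param cohort_csv cohort table path ([read_cohort_csv()] schema).
#' @param synthetic logical: generate inputs with [phantom_spec()] /
#'   [cohort_config()] instead of reading files.
#' @param phantom a [phantom_spec()] used when `synthetic` (its seed is
#'   overridden from `seed`).
#' @param cohort a [cohort_config()] used when `synthetic` (seed likewise).
#' @param quant a [quant_config()].
#' @param family Bonferroni family for correlation matrices
#'   (`"per_matrix"` or `"global"`).
#' @param output_dir directory for reports (created if needed).
#' @param seed master integer seed.
#' @return a `run_config` object.
#' @export
run_config <- function(image_dir = NULL, cohort_csv = NULL,
                       synthetic = is.null(image_dir) && is.null(cohort_csv),
                       phantom = phantom_spec(),
                       cohort = cohort_config(),
                       quant = quant_config(),
                       family = "per_matrix",
                       output_dir = tempfile("octavasc_run_"),
                       seed = 1L) {
  real <- !is.null(image_dir) || !is.null(cohort_csv)
  if (real && synthetic)
    stop("exactly one of real inputs and synthetic generation may be active")
  if (!real && !synthetic)
    stop("no input source: give image_dir/cohort_csv or synthetic = TRUE")
  phantom$seed <- as.integer(seed) + 101L
  cohort$seed <- as.integer(seed) + 202L
  structure(list(image_dir = image_dir, cohort_csv = cohort_csv,
                 synthetic = synthetic, phantom = phantom, cohort = cohort,
                 quant = quant, family = family, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Quantify every image in a run
#'
#' QC-filters the images (signal strength), quantifies the survivors over
#' the standard annulus and sectors, and writes a tidy metrics CSV plus a
#' QC report listing every exclusion with its reason. A missing or broken
#' sidecar excludes that image and the run continues; a run in which no
#' image passes QC fails.
#'
#' @param config a [run_config()].
#' @return list with `metrics` (data.frame) and `qc_report` (data.frame);
#'   files `metrics.csv` and `qc_report.csv` under `output_dir`.
#' @export
run_quantify <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (config$synthetic) {
    dir <- file.path(config$output_dir, "synthetic_images")
    ph <- generate_phantom(config$phantom)
    write_phantom(ph, dir)
    paths <- file.path(dir, "phantom.tif")
  } else {
    paths <- list.files(config$image_dir,
                        pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (!length(paths)) stop("no images found in ", config$image_dir)
  }
  metrics <- list()
  qc <- list()
  for (p in sort(paths)) {
    id <- tools::file_path_sans_ext(basename(p))
    img <- tryCatch(read_flow_image(p), error = function(e) e)
    if (inherits(img, "error")) {
      qc[[id]] <- data.frame(image = id, included = FALSE,
                             reason = conditionMessage(img))
      next
    }
    ok <- qc_filter(img, config$quant$qc_threshold)
    if (!ok) {
      qc[[id]] <- data.frame(image = id, included = FALSE,
                             reason = attr(ok, "reason"))
      next
    }
    qc[[id]] <- data.frame(image = id, included = TRUE, reason = "")
    m <- quantify_image(img, config = config$quant)
    metrics[[id]] <- cbind(data.frame(subject = id, eye = img$eye,
                                      target = img$target), m)
  }
  qc_report <- do.call(rbind, qc)
  rownames(qc_report) <- NULL
  if (!length(metrics))
    stop("no image passed quality control; see the QC report")
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  utils::write.csv(metrics, file.path(config$output_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(qc_report, file.path(config$output_dir, "qc_report.csv"),
                   row.names = FALSE)
  list(metrics = metrics, qc_report = qc_report)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss))
    stop("cohort table is missing required ", what, " column(s): ",
         paste(miss, collapse = ", "))
}

#' Visual-acuity stability summary of a cohort
#'
#' Classifies every eye with both acuities and tabulates counts and
#' percentages (two decimals) per group and overall for the diabetic eyes.
#'
#' @param cohort cohort data.frame.
#' @return list with `per_eye`, `by_group` and `dm_overall`.
#' @export
va_stability_summary <- function(cohort) {
  require_columns(cohort, c("group", "va_baseline", "va_followup"), "acuity")
  status <- vapply(seq_len(nrow(cohort)), function(i)
    as.character(classify_stability(cohort$va_baseline[i],
                                    cohort$va_followup[i])), character(1))
  per_eye <- data.frame(cohort[c("group", "va_baseline", "va_followup")],
                        status = status)
  by_group <- do.call(rbind, lapply(split(per_eye, per_eye$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               stable = sum(d$status == "stable"),
               worsened = sum(d$status == "worsened"),
               improved = sum(d$status == "improved"),
               pct_stable = round(100 * mean(d$status == "stable"), 2),
               pct_worsened = round(100 * mean(d$status == "worsened"), 2))
  }))
  rownames(by_group) <- NULL
  dm <- per_eye[per_eye$group != "Ctrl", ]
  dm_overall <- data.frame(
    n = nrow(dm),
    stable = sum(dm$status == "stable"),
    worsened = sum(dm$status == "worsened"),
    pct_stable = round(100 * mean(dm$status == "stable"), 2),
    pct_worsened = round(100 * mean(dm$status == "worsened"), 2))
  list(per_eye = per_eye, by_group = by_group, dm_overall = dm_overall)
}

#' Visual-acuity category percentages by group
#'
#' @param cohort cohort data.frame.
#' @param at `"va_baseline"` or `"va_followup"`.
#' @return data.frame of percentages (rows: groups, columns: categories).
#' @export
va_category_table <- function(cohort, at = "va_baseline") {
  require_columns(cohort, c("group", at), "acuity")
  cats <- vapply(cohort[[at]], function(v) categorize_va(v), character(1))
  labs <- c("20/20-20/30", "20/40-20/60", "20/70-20/100", "20/200 or worse")
  out <- do.call(rbind, lapply(split(cats, cohort$group), function(v) {
    round(100 * vapply(labs, function(l) mean(v == l), numeric(1)), 2)
  }))
  data.frame(group = rownames(out), out, check.names = FALSE,
             row.names = NULL)
}

#' Analyze a cohort: acuity, labs, OCT x OCTA correlations
#'
#' Produces the full report bundle: visual-acuity stability and category
#' tables, control-standardized lab z-score matrix (group means per
#' analyte) with a heat map, disc and macula Spearman correlation matrices
#' with Bonferroni-corrected significance and strength labels (CSV + heat
#' maps), and a JSON summary of headline numbers.
#'
#' @param config a [run_config()].
#' @param cohort optional cohort data.frame (otherwise read or generated
#'   per the config).
#' @return list with `stability`, `va_categories`, `lab_z`, `cor_disc`,
#'   `cor_macula`, `summary`; files under `output_dir`.
#' @export
run_analysis <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort)) {
    cohort <- if (config$synthetic) generate_cohort(config$cohort)
              else read_cohort_csv(config$cohort_csv)
  }
  require_columns(cohort, "group", "grouping")
  if (!any(cohort$group != "Ctrl")) stop("cohort has no diabetic eyes")
  if (!any(cohort$group == "Ctrl")) stop("cohort has no control eyes")
  out_dir <- config$output_dir

  stability <- va_stability_summary(cohort)
  utils::write.csv(stability$by_group,
                   file.path(out_dir, "va_stability.csv"), row.names = FALSE)
  va_cat <- list(baseline = va_category_table(cohort, "va_baseline"),
                 followup = va_category_table(cohort, "va_followup"))
  utils::write.csv(va_cat$baseline,
                   file.path(out_dir, "va_categories_baseline.csv"),
                   row.names = FALSE)
  utils::write.csv(va_cat$followup,
                   file.path(out_dir, "va_categories_followup.csv"),
                   row.names = FALSE)

  # control-standardized labs: per-analyte z, averaged by group
  analytes <- intersect(lab_analytes(), colnames(cohort))
  require_columns(cohort, "Glucose", "lab")
  std <- standardize_labs(cohort[analytes],
                          cohort[cohort$group == "Ctrl", analytes])
  zg <- do.call(rbind, lapply(split(std$z, cohort$group), colMeans,
                              na.rm = TRUE))
  utils::write.csv(data.frame(group = rownames(zg), zg, check.names = FALSE),
                   file.path(out_dir, "lab_zscores_by_group.csv"),
                   row.names = FALSE)
  write_heatmap_png(t(zg), file.path(out_dir, "lab_zscore_heatmap.png"),
                    zlim = c(-max(abs(zg)), max(abs(zg))))

  # OCT x OCTA Spearman matrices over diabetic eyes, per-panel Bonferroni
  dm <- cohort[cohort$group != "Ctrl", ]
  rnfl_cols <- grep("^rnfl_", colnames(dm), value = TRUE)
  gcc_cols <- grep("^gcc_", colnames(dm), value = TRUE)
  octa_cols <- grep("^octa_", colnames(dm), value = TRUE)
  mocta_cols <- grep("^mocta_", colnames(dm), value = TRUE)
  require_columns(dm, c("rnfl_whole"), "OCT")
  cor_disc <- correlation_matrix(dm[rnfl_cols], dm[octa_cols],
                                 family = config$family)
  utils::write.csv(cor_disc, file.path(out_dir, "cor_disc.csv"),
                   row.names = FALSE)
  cor_macula <- if (length(gcc_cols) && length(mocta_cols))
    correlation_matrix(dm[gcc_cols], dm[mocta_cols], family = config$family)
  else NULL
  if (!is.null(cor_macula))
    utils::write.csv(cor_macula, file.path(out_dir, "cor_macula.csv"),
                     row.names = FALSE)
  # heat map of rho, masked to significance sign convention (red/blue)
  rho_mat <- matrix(cor_disc$rho, nrow = length(rnfl_cols),
                    dimnames = list(rnfl_cols, octa_cols))
  write_heatmap_png(rho_mat, file.path(out_dir, "cor_disc_heatmap.png"),
                    zlim = c(-1, 1))

  summary <- list(
    n_eyes = nrow(cohort),
    n_dm_eyes = nrow(dm),
    pct_dm_stable = stability$dm_overall$pct_stable,
    pct_dm_worsened = stability$dm_overall$pct_worsened,
    pct_ctrl_best_va_baseline =
      va_cat$baseline[va_cat$baseline$group == "Ctrl", "20/20-20/30"],
    n_significant_disc = sum(cor_disc$significant),
    n_significant_macula = if (!is.null(cor_macula))
      sum(cor_macula$significant) else NA,
    max_abs_rho_disc = max(abs(cor_disc$rho), na.rm = TRUE),
    seed = config$seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  list(stability = stability, va_categories = va_cat,
       lab_z = zg, cor_disc = cor_disc, cor_macula = cor_macula,
       summary = summary)
}

#' End-to-end synthetic demonstration run
#'
#' Generates a phantom bundle, quantifies it, generates a cohort, analyzes
#' it, and returns both result sets.
#'
#' @param config a [run_config()] with `synthetic = TRUE`.
#' @return list with `quantify` and `analysis`.
#' @export
run_demo <- function(config = run_config(synthetic = TRUE)) {
  if (!config$synthetic) stop("run_demo needs a synthetic run_config")
  list(quantify = run_quantify(config), analysis = run_analysis(config))
}
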