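# Synthetic clinical cohorts with the grade-conditional structure of real
# diabetic-retinopathy series: per-grade Gaussian labs and OCT thicknesses
# (truncated at physiologic floors), a per-eye vascular latent factor
# coupling OCTA metrics to RNFL thickness, and Snellen-chart visual-acuity
# transitions.

#' Configuration of a synthetic cohort
#'
#' Defaults mirror the scale of a single-centre series: 95 control eyes and
#' 218 diabetic eyes spread over DR grades 0-4, lab and OCT marginals from
#' [default_lab_distributions()] / [default_oct_distributions()].
#'
#' @param n_per_grade named integer vector of eye counts for
#'   `Ctrl, DR0..DR4`.
#' @param lab_distributions data.frame `analyte, grade, mean, sd` (defaults
#'   to [default_lab_distributions()]; override rows to change analytes).
#' @param oct_distributions data.frame `layer, region, grade, mean, sd`.
#' @param latent_coupling Pearson correlation injected between each RNFL
#'   quadrant thickness and the coupled OCTA disc metrics through a shared
#'   per-eye vascular factor, in \[0, 1).
#' @param renal_coupling correlation loading of the shared renal factor on
#'   the Cr/EGFR/BUN block.
#' @param va_worsening_probability per-grade probability that follow-up
#'   acuity drops two or more Snellen lines.
#' @param followup_years_range range of follow-up intervals (years).
#' @param seed integer RNG seed.
#' @return a `cohort_config` object.
#' @export
cohort_config <- function(n_per_grade = c(Ctrl = 95, DR0 = 88, DR1 = 50,
                                          DR2 = 40, DR3 = 20, DR4 = 20),
                          lab_distributions = default_lab_distributions(),
                          oct_distributions = default_oct_distributions(),
                          latent_coupling = 0.4,
                          renal_coupling = 0.5,
                          va_worsening_probability = c(Ctrl = 0.02, DR0 = 0.03,
                                                       DR1 = 0.05, DR2 = 0.08,
                                                       DR3 = 0.25, DR4 = 0.30),
                          followup_years_range = c(4, 7),
                          seed = 1L) {
  stopifnot(all(lab_distributions$sd > 0), all(oct_distributions$sd > 0),
            latent_coupling >= 0, latent_coupling < 1,
            all(va_worsening_probability >= 0),
            all(va_worsening_probability <= 1))
  known <- lab_analytes()
  extra <- setdiff(unique(lab_distributions$analyte), known)
  if (length(extra))
    stop("unknown analyte(s) in lab_distributions: ",
         paste(extra, collapse = ", "))
  structure(list(n_per_grade = n_per_grade,
                 lab_distributions = lab_distributions,
                 oct_distributions = oct_distributions,
                 latent_coupling = latent_coupling,
                 renal_coupling = renal_coupling,
                 va_worsening_probability = va_worsening_probability,
                 followup_years_range = followup_years_range,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Spearman correlation implied by the latent coupling
#'
#' The generator couples two Gaussian variables at Pearson correlation
#' `coupling`; for a bivariate normal the corresponding population Spearman
#' coefficient is `(6/pi) asin(coupling/2)`.
#'
#' @param coupling the configured `latent_coupling`.
#' @return implied Spearman rho.
#' @export
implied_spearman <- function(coupling) 6 / pi * asin(coupling / 2)

rtruncnorm1 <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  guard <- 0
  while (length(bad) && guard < 50) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower)
    guard <- guard + 1
  }
  x[x < lower] <- lower
  x
}

# Baseline visual-acuity distribution over chart lines by grade.
# Controls: 90% between 20/20 and 20/30. DR grades shift toward worse lines.
va_baseline_probs <- function(grade) {
  chart <- snellen_chart()
  p <- stats::setNames(numeric(length(chart)), chart)
  if (grade == "Ctrl") {
    p[c("20/20", "20/25", "20/30")] <- c(0.55, 0.20, 0.15)
    p[c("20/40", "20/50")] <- c(0.06, 0.04)
  } else {
    g <- as.integer(sub("DR", "", grade))
    # worsening mixture with grade: mass moves from the best lines outward
    base <- c(`20/20` = 0.42, `20/25` = 0.18, `20/30` = 0.12,
              `20/40` = 0.10, `20/50` = 0.06, `20/60` = 0.04,
              `20/70` = 0.03, `20/80` = 0.02, `20/100` = 0.015,
              `20/200` = 0.015)
    shift <- g * 0.05
    base["20/20"] <- max(base["20/20"] - shift, 0.05)
    base[c("20/60", "20/70", "20/100", "20/200")] <-
      base[c("20/60", "20/70", "20/100", "20/200")] + shift / 4
    p[names(base)] <- base
  }
  p / sum(p)
}

# Plausible OCTA disc/macula metric marginals (mean declines with grade,
# emulating progressive capillary dropout).
octa_marginal <- function(metric, grade_num) {
  base <- switch(metric,
    vad = c(0.46, 0.040), vsd = c(0.165, 0.018), vdi = c(2.8, 0.25),
    vpi = c(0.30, 0.030), vci = c(1.9, 0.30), flux = c(0.42, 0.045))
  slope <- switch(metric,
    vad = 0.012, vsd = 0.004, vdi = -0.02, vpi = 0.008, vci = 0.06,
    flux = 0.012)
  c(mean = base[1] - slope * max(grade_num, 0), sd = base[2])
}

#' Generate a synthetic per-eye cohort table
#'
#' Samples one row per eye: DR/DME grades, baseline and follow-up Snellen
#' acuity on the chart, follow-up interval, RNFL/GCC thicknesses, the six
#' OCTA metrics per disc quadrant and macular sector, and the 24-analyte
#' blood panel. A per-eye vascular latent factor is shared between RNFL
#' quadrant thickness and the coupled OCTA disc metrics (flux, VAD, VCI) so
#' their Pearson correlation equals `latent_coupling`; a renal latent
#' factor couples Cr, EGFR (negatively) and BUN. Deterministic per seed.
#'
#' @param config a [cohort_config()].
#' @return data.frame, one row per eye, with attribute `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  chart <- snellen_chart()
  labd <- config$lab_distributions
  octd <- config$oct_distributions
  floors <- lab_floors()
  a <- sqrt(config$latent_coupling)   # loading: cor(x, y) = a^2
  b <- sqrt(config$renal_coupling)
  rnfl_regions <- c("whole", "S", "N", "I", "T")
  gcc_regions <- c("whole", "S", "SN", "ST", "I", "IN", "IT")
  metrics <- c("vad", "vsd", "vdi", "vpi", "vci", "flux")
  coupled <- c("flux", "vad", "vci")
  with_seed(config$seed, {
    frames <- list()
    sid0 <- 0
    for (grade in names(config$n_per_grade)) {
      n <- config$n_per_grade[[grade]]
      if (n < 1) next
      g_num <- if (grade == "Ctrl") -1L else as.integer(sub("DR", "", grade))
      oct_grade <- if (grade == "Ctrl") "DR0" else grade  # controls ~ DR0 eyes
      pv <- va_baseline_probs(grade)
      p_worse <- config$va_worsening_probability[[grade]]
      z_vasc <- stats::rnorm(n)    # shared vascular latent factor, per eye
      z_renal <- stats::rnorm(n)
      mix <- function(z) a * z + sqrt(1 - a^2) * stats::rnorm(n)
      df <- data.frame(
        subject_id = sprintf("S%04d", sid0 + seq_len(n)),
        eye = sample(c("OD", "OS"), n, replace = TRUE),
        group = grade,
        dr_grade = if (grade == "Ctrl") NA_integer_ else g_num,
        dme_grade = if (grade == "Ctrl") 0L else
          sample(0:2, n, replace = TRUE,
                 prob = c(max(0.9 - 0.15 * g_num, 0.3),
                          0.05 + 0.1 * g_num, 0.05 + 0.05 * g_num)),
        stringsAsFactors = FALSE, check.names = FALSE)
      sid0 <- sid0 + n
      i_base <- sample(length(chart), n, replace = TRUE, prob = pv)
      worse <- stats::runif(n) < p_worse
      step <- ifelse(worse, 2L + stats::rgeom(n, 0.6),
                     sample(c(-1L, 0L, 1L), n, replace = TRUE,
                            prob = c(0.15, 0.7, 0.15)))
      i_fu <- pmin(pmax(i_base + step, 1L), length(chart))
      df$va_baseline <- chart[i_base]
      df$va_followup <- chart[i_fu]
      df$followup_years <- stats::runif(n, config$followup_years_range[1],
                                        config$followup_years_range[2])
      # OCT thicknesses; RNFL regions carry the vascular latent factor
      for (reg in rnfl_regions) {
        d <- octd[octd$layer == "RNFL" & octd$region == reg &
                  octd$grade == oct_grade, ]
        df[[paste0("rnfl_", reg)]] <- pmax(d$mean + d$sd * mix(z_vasc), 1)
      }
      for (reg in gcc_regions) {
        d <- octd[octd$layer == "GCC" & octd$region == reg &
                  octd$grade == oct_grade, ]
        df[[paste0("gcc_", reg)]] <- pmax(stats::rnorm(n, d$mean, d$sd), 1)
      }
      # OCTA metrics: disc quadrants (coupled metrics share z_vasc),
      # macular sectors (uncoupled)
      for (m in metrics) {
        mm <- octa_marginal(m, g_num)
        for (reg in rnfl_regions) {
          e <- if (m %in% coupled) mix(z_vasc) else stats::rnorm(n)
          df[[paste0("octa_", m, "_", reg)]] <-
            pmax(mm[["mean"]] + mm[["sd"]] * e, 0)
        }
        for (reg in gcc_regions) {
          df[[paste0("mocta_", m, "_", reg)]] <-
            pmax(stats::rnorm(n, mm[["mean"]], mm[["sd"]]), 0)
        }
      }
      # blood panel with a shared renal factor on the Cr/EGFR/BUN block
      for (an in unique(labd$analyte)) {
        d <- labd[labd$analyte == an & labd$grade == grade, ]
        fl <- if (an %in% names(floors)) floors[[an]] else 0
        if (an %in% c("Cr", "BUN", "EGFR")) {
          sgn <- if (an == "EGFR") -1 else 1
          e <- sgn * b * z_renal + sqrt(1 - b^2) * stats::rnorm(n)
          df[[an]] <- pmax(d$mean + d$sd * e, fl)
        } else {
          df[[an]] <- rtruncnorm1(n, d$mean, d$sd, fl)
        }
      }
      frames[[grade]] <- df
    }
    out <- do.call(rbind, frames)
    rownames(out) <- NULL
    attr(out, "config") <- config
    out
  })
}

#' Write a cohort table as CSV
#'
#' One row per eye, columns as produced by [generate_cohort()]; the seed is
#' embedded as a comment-free `seed` column so the file is self-describing.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cfg <- attr(cohort, "config")
  out <- cohort
  out$seed <- if (!is.null(cfg)) cfg$seed else NA_integer_
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort_csv()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
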