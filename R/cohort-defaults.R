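# Default grade-conditional sampling parameters for the synthetic cohort:
# per-grade mean (sd) of peripapillary RNFL / macular GCC thickness and of
# the 24 blood-panel analytes, as observed in diabetic-retinopathy cohorts.
# Grades: Ctrl (labs only), DR0 (no retinopathy) .. DR4 (proliferative DR).

#' Default OCT thickness distributions by DR grade
#'
#' Mean and standard deviation of RNFL quadrant and GCC sector thickness
#' (um) for DR grades 0-4, used by [generate_cohort()].
#'
#' @return data.frame with columns `layer, region, grade, mean, sd`.
#' @export
default_oct_distributions <- function() {
  rn <- function(region, ...) {
    v <- c(...)
    data.frame(layer = "RNFL", region = region, grade = paste0("DR", 0:4),
               mean = v[c(1, 3, 5, 7, 9)], sd = v[c(2, 4, 6, 8, 10)])
  }
  gc <- function(region, ...) {
    v <- c(...)
    data.frame(layer = "GCC", region = region, grade = paste0("DR", 0:4),
               mean = v[c(1, 3, 5, 7, 9)], sd = v[c(2, 4, 6, 8, 10)])
  }
  rbind(
    rn("T", 64.52, 12.44, 59.61, 13.42, 59.79, 13.09, 67.18, 16.35, 62.03, 9.46),
    rn("S", 115.37, 18.50, 111.39, 17.06, 101.77, 25.72, 106.75, 22.40, 106.44, 21.60),
    rn("N", 77.50, 59.55, 68.83, 12.36, 63.59, 8.47, 76.17, 23.25, 61.35, 11.05),
    rn("I", 119.56, 18.65, 114.78, 11.97, 109.08, 18.13, 106.03, 27.96, 106.57, 25.19),
    rn("whole", 92.19, 13.80, 88.61, 10.08, 84.37, 13.79, 93.87, 18.65, 84.52, 14.98),
    gc("ST", 84.51, 10.57, 82.20, 11.50, 83.94, 10.21, 95.75, 5.12, 74.53, 23.07),
    gc("S", 81.36, 9.02, 77.20, 9.46, 74.62, 16.25, 85.38, 9.62, 68.20, 22.84),
    gc("SN", 85.69, 11.51, 82.05, 11.84, 75.71, 26.83, 90.38, 9.35, 73.53, 26.91),
    gc("IT", 82.29, 10.83, 79.95, 10.88, 82.12, 11.36, 97.00, 11.88, 71.47, 22.56),
    gc("I", 79.69, 10.08, 76.35, 9.80, 76.31, 17.24, 78.75, 10.26, 65.60, 25.25),
    gc("IN", 82.16, 11.70, 76.70, 10.55, 72.41, 24.40, 85.38, 8.11, 69.87, 22.12),
    gc("whole", 80.74, 7.87, 77.95, 5.93, 73.71, 20.93, 87.50, 6.57, 70.87, 20.95)
  )
}

#' Default blood-panel distributions by group
#'
#' Mean and standard deviation of each of the 24 analytes for healthy
#' controls and DR grades 0-4, used by [generate_cohort()]. Units follow
#' clinical convention (Glucose mg/dL, A1c %, Cr mg/dL, EGFR
#' mL/min/1.73m^2, BUN mg/dL, ...).
#'
#' @return data.frame with columns `analyte, grade, mean, sd`.
#' @export
default_lab_distributions <- function() {
  row <- function(analyte, ...) {
    v <- c(...)
    data.frame(analyte = analyte,
               grade = c("Ctrl", paste0("DR", 0:4)),
               mean = v[c(1, 3, 5, 7, 9, 11)],
               sd = v[c(2, 4, 6, 8, 10, 12)])
  }
  rbind(
    row("Glucose", 118.60, 63.41, 140.80, 39.41, 143.08, 35.91, 156.14, 45.73, 180.50, 16.45, 147.30, 38.59),
    row("A1c", 6.04, 1.42, 6.91, 1.15, 7.60, 1.62, 7.60, 1.30, 9.53, 0.12, 7.65, 1.44),
    row("Albumin", 4.18, 0.33, 4.10, 0.34, 3.96, 0.41, 3.79, 0.53, 4.10, 0.35, 3.87, 0.27),
    row("Cr", 0.81, 0.19, 0.95, 0.30, 0.90, 0.29, 0.95, 0.26, 1.03, 0.40, 2.54, 2.54),
    row("EGFR", 101.26, 25.30, 87.56, 23.54, 89.62, 18.76, 81.36, 21.80, 80.67, 28.00, 41.80, 27.18),
    row("BUN", 14.66, 4.29, 18.30, 7.57, 19.00, 7.15, 18.77, 3.10, 25.00, 5.20, 39.60, 14.38),
    row("Protein", 7.32, 0.56, 7.45, 0.35, 7.32, 0.36, 7.34, 0.43, 6.77, 0.29, 7.24, 0.47),
    row("Globulin", 3.14, 0.65, 3.40, 0.58, 3.40, 0.65, 3.54, 0.78, 2.73, 0.58, 3.30, 0.58),
    row("Alk Phos", 74.26, 23.74, 76.51, 19.39, 77.58, 32.13, 86.64, 24.54, 98.00, 38.11, 80.40, 23.54),
    row("ALT", 31.96, 16.23, 30.79, 11.88, 31.08, 15.04, 22.00, 8.23, 25.17, 12.41, 32.60, 17.67),
    row("AST", 25.14, 8.47, 24.03, 6.01, 24.58, 7.32, 22.64, 4.79, 16.83, 3.18, 28.10, 12.28),
    row("Bili", 0.53, 0.22, 0.50, 0.28, 0.51, 0.27, 0.45, 0.32, 0.50, 0.05, 0.40, 0.12),
    row("K", 4.16, 0.35, 4.40, 0.36, 4.36, 0.21, 4.27, 0.38, 4.43, 0.46, 4.86, 0.46),
    row("Ca", 9.23, 0.34, 9.44, 0.38, 9.30, 0.35, 9.16, 0.43, 9.30, 0.17, 9.48, 0.48),
    row("Cl", 102.06, 2.73, 102.08, 2.49, 102.12, 2.00, 102.36, 2.51, 104.17, 0.29, 102.20, 4.31),
    row("Na", 138.64, 2.48, 138.57, 1.96, 138.85, 1.51, 138.50, 1.32, 140.33, 1.15, 138.90, 1.67),
    row("CO2", 28.22, 1.71, 27.04, 2.17, 28.15, 2.22, 27.73, 3.24, 30.00, 1.73, 27.38, 3.35),
    row("Hgb", 13.53, 0.95, 12.85, 1.90, 13.47, 0.94, 13.18, 1.73, 13.57, 0.23, 12.37, 0.85),
    row("RDW", 13.35, 0.86, 13.92, 1.28, 13.68, 1.27, 14.61, 1.41, 14.53, 0.29, 13.32, 0.29),
    row("Hct", 40.40, 2.80, 39.67, 4.63, 41.58, 2.71, 39.59, 4.78, 42.75, 2.42, 37.19, 2.63),
    row("Chol-HDL", 40.57, 14.00, 31.36, 12.69, 29.48, 14.32, 26.05, 10.61, 41.33, 1.15, 31.10, 9.34),
    row("Chol-LDL", 97.37, 25.15, 75.92, 28.82, 69.92, 22.46, 90.41, 43.48, 85.33, 21.36, 87.80, 30.47),
    row("Chol-Non-HDL", 125.94, 32.09, 104.37, 29.73, 85.69, 13.06, 114.86, 38.62, 113.67, 6.35, 111.20, 29.41),
    row("Chol", 182.32, 39.06, 146.16, 34.23, 127.19, 29.85, 143.55, 36.49, 153.83, 13.28, 147.60, 22.19)
  )
}

# Physiologic floors used when truncating the Gaussian samples.
lab_floors <- function() {
  c(Glucose = 40, A1c = 3.5, Albumin = 1, Cr = 0.2, EGFR = 5, BUN = 2,
    Protein = 3, Globulin = 0.5, `Alk Phos` = 10, ALT = 2, AST = 2,
    Bili = 0.05, K = 2.5, Ca = 6, Cl = 85, Na = 120, CO2 = 10, Hgb = 5,
    RDW = 10, Hct = 15, `Chol-HDL` = 5, `Chol-LDL` = 10,
    `Chol-Non-HDL` = 20, Chol = 50)
}
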