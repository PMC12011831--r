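test_that("phantom generation is deterministic per seed", {
  sp <- phantom_spec(grid = image_grid(128), seed = 3)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1$image$intensities, p2$image$intensities)
  expect_identical(p1$truth$vessel_mask, p2$truth$vessel_mask)
  p3 <- generate_phantom(phantom_spec(grid = image_grid(128), seed = 4))
  expect_false(identical(p1$image$intensities, p3$image$intensities))
})

test_that("phantom specs reject unsatisfiable densities and bad widths", {
  expect_error(phantom_spec(capillary_density = 0.95), "unsatisfiable")
  expect_error(phantom_spec(trunk_width_px = 0))
})

test_that("realized ground-truth density hits the requested target", {
  for (target in c(0.1, 0.2)) {
    ph <- generate_phantom(phantom_spec(grid = image_grid(256),
                                        capillary_density = target,
                                        seed = 6))
    realized <- mean(ph$truth$vessel_mask)
    expect_lt(abs(realized - target), 0.05)
  }
})

test_that("the default pipeline recovers a clean phantom nearly exactly", {
  cp <- clean_phantom()
  gt <- cp$ph$truth$vessel_mask | cp$ph$truth$large_vessel_mask
  rec <- cp$maps$vessel_mask | cp$maps$large_vessel_mask
  expect_gte(dice_coefficient(rec, gt), 0.95)
})

test_that("recovery stays strong on the default noisy phantom", {
  ph <- generate_phantom(phantom_spec(seed = 12))
  maps <- segment_vessels(ph$image)
  gt <- ph$truth$vessel_mask | ph$truth$large_vessel_mask
  expect_gte(dice_coefficient(maps$vessel_mask | maps$large_vessel_mask, gt),
             0.9)
})

test_that("grade-series dropout produces monotone vessel loss", {
  base <- generate_phantom(phantom_spec(grid = image_grid(256), seed = 8,
                                        noise_sd = 0.03))
  series <- generate_grade_series(base, c(0, 0.1, 0.2, 0.3, 0.4))
  truth_vad <- vapply(series, function(s) s$truth_vad, numeric(1))
  expect_true(all(diff(truth_vad) < -0.005))
  measured <- vapply(series, function(s) {
    maps <- segment_vessels(s$image)
    mean(maps$vessel_mask)
  }, numeric(1))
  expect_true(all(diff(measured) < 0))
  # complexity declines as the capillary bed drops out
  vci <- vapply(series, function(s) {
    roi <- matrix(TRUE, 256, 256)
    compute_metrics(s$truth, s$image, roi)$vci
  }, numeric(1))
  expect_true(all(diff(vci) < 0.05))      # nonincreasing up to raster noise
  expect_lt(vci[5], vci[1])
})

test_that("zero dropout reproduces identical statistics across grades", {
  base <- generate_phantom(phantom_spec(grid = image_grid(128), seed = 9))
  series <- generate_grade_series(base, rep(0, 3))
  imgs <- lapply(series, function(s) s$image$intensities)
  expect_identical(imgs[[1]], imgs[[2]])
  expect_identical(imgs[[1]], imgs[[3]])
  expect_error(generate_grade_series(base, c(0.2, 0.1)), "nondecreasing")
  expect_error(generate_grade_series(base, c(0, 1.2)), "0, 1")
})

test_that("cohort generation is deterministic and sized as configured", {
  cfg <- cohort_config(seed = 2)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), sum(cfg$n_per_grade))
  expect_equal(as.integer(table(c1$group)[names(cfg$n_per_grade)]),
               unname(cfg$n_per_grade))
  expect_true(all(c1$dr_grade[c1$group == "DR3"] == 3))
  expect_true(all(is.na(c1$dr_grade[c1$group == "Ctrl"])))
  expect_true(all(c1$followup_years >= 4 & c1$followup_years <= 7))
})

test_that("grade-conditional lab means match their generator parameters", {
  coh <- generate_cohort(cohort_config(n_per_grade = c(DR4 = 500), seed = 2))
  # severe-DR urea nitrogen: mean 39.60, sd 14.38 -> sample mean within 2 SE
  expect_lt(abs(mean(coh$BUN) - 39.60), 2 * 14.38 / sqrt(500) + 0.3)
  expect_lt(abs(sd(coh$BUN) - 14.38), 2)
  expect_true(all(coh$EGFR >= 5))          # physiologic floor
  expect_true(all(coh[lab_analytes()] >= 0))
})

test_that("renal analytes co-vary through the shared renal factor", {
  coh <- generate_cohort(cohort_config(n_per_grade = c(DR0 = 500), seed = 7))
  expect_gt(cor(coh$Cr, coh$BUN), 0.2)
  expect_lt(cor(coh$Cr, coh$EGFR), -0.2)
  # non-renal analytes stay uncoupled
  expect_lt(abs(cor(coh$Cr, coh$Na)), 0.15)
})

test_that("zero latent coupling leaves OCTA and RNFL independent", {
  coh <- generate_cohort(cohort_config(n_per_grade = c(DR0 = 500),
                                       latent_coupling = 0, seed = 3))
  expect_lt(abs(spearman(coh$rnfl_I, coh$octa_flux_I)$statistic), 0.1)
})

test_that("zero worsening probability gives a fully stable cohort", {
  coh <- generate_cohort(cohort_config(
    n_per_grade = c(Ctrl = 50, DR0 = 50, DR4 = 50),
    va_worsening_probability = c(Ctrl = 0, DR0 = 0, DR1 = 0, DR2 = 0,
                                 DR3 = 0, DR4 = 0), seed = 4))
  st <- va_stability_summary(coh)
  expect_equal(st$dm_overall$pct_stable, 100)
  expect_equal(st$dm_overall$worsened, 0)
})

test_that("unknown analytes in overrides are rejected", {
  bad <- default_lab_distributions()
  bad$analyte[1] <- "NotAnAnalyte"
  expect_error(cohort_config(lab_distributions = bad), "unknown analyte")
})

test_that("phantom bundles round-trip to disk with their seed", {
  dir <- withr::local_tempdir()
  ph <- generate_phantom(phantom_spec(grid = image_grid(64), seed = 5))
  write_phantom(ph, dir, "p1")
  expect_true(file.exists(file.path(dir, "p1.tif")))
  spec <- jsonlite::read_json(file.path(dir, "p1_spec.json"),
                              simplifyVector = TRUE)
  expect_equal(spec$seed, 5)
  back <- read_flow_image(file.path(dir, "p1.tif"))
  expect_lt(max(abs(back$intensities - ph$image$intensities)), 1 / 255)
})
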