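test_that("QC keeps only scans with signal strength strictly above threshold", {
  img <- flow_image(matrix(0.5, 8, 8), signal_strength_index = 8)
  expect_true(qc_filter(img))
  img$signal_strength_index <- 7
  expect_false(qc_filter(img))
  img$signal_strength_index <- 6.5
  expect_false(qc_filter(img))
  img$signal_strength_index <- NA
  ok <- qc_filter(img)
  expect_false(ok)
  expect_match(attr(ok, "reason"), "missing")
})

test_that("vesselness enhancement responds to tubes, not flat fields", {
  expect_equal(range(enhance_vessels(matrix(0.7, 64, 64))), c(0, 0))
  img <- bar_image(128, width = 3)
  enh <- enhance_vessels(img)
  centre <- mean(enh[64, 20:108])
  background <- mean(enh[c(1:40, 90:128), ])
  expect_gt(centre, 10 * max(background, 1e-9))
  expect_error(enhance_vessels(img, scales_px = numeric(0)), "nonempty")
})

test_that("enhancement commutes with 90-degree rotation", {
  img <- bar_image(96, width = 3)
  expect_lt(max(abs(rot90(enhance_vessels(img)) -
                    enhance_vessels(rot90(img)))), 1e-8)
})

test_that("binarization separates a bimodal image and honours fixed levels", {
  bi <- matrix(c(rep(0.1, 100), rep(0.9, 156)), 16)
  expect_identical(binarize(bi, "global_otsu"), bi > 0.5)
  img <- bar_image(128, width = 3)
  m <- binarize(enhance_vessels(img), "fixed", level = 0.5)
  expect_gte(dice_coefficient(m, attr(img, "gt")), 0.95)
  expect_identical(binarize(matrix(0, 8, 8), "global_otsu"),
                   matrix(FALSE, 8, 8))
  expect_error(binarize(bi, "fixed"), "level")
})

test_that("raising a fixed binarization level never increases vessel area", {
  img <- bar_image(128, width = 5)
  enh <- enhance_vessels(img)
  areas <- vapply(seq(0.1, 0.9, by = 0.1),
                  function(l) sum(binarize(enh, "fixed", level = l)),
                  numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("large-vessel removal separates a wide trunk from thin branches", {
  m <- matrix(FALSE, 100, 100)
  trunk <- matrix(FALSE, 100, 100); trunk[45:56, ] <- TRUE  # 12 px wide
  m <- trunk
  m[, 20:21] <- TRUE; m[, 70:71] <- TRUE                    # 2 px branches
  sp <- remove_large_vessels(m, 6)
  branches <- m & !trunk
  expect_true(all(sp$large[trunk]))
  expect_gt(mean(sp$capillary[branches]), 0.9)
  expect_identical(sp$capillary | sp$large, m)
  expect_false(any(sp$capillary & sp$large))
})

test_that("thin-only masks yield an empty large-vessel mask", {
  m <- matrix(FALSE, 40, 40); m[20, 5:35] <- TRUE; m[5:35, 10] <- TRUE
  for (cutoff in c(2, 4, 8)) {
    sp <- remove_large_vessels(m, cutoff)
    expect_equal(sum(sp$large), 0)
    expect_identical(sp$capillary, m)
  }
  expect_error(remove_large_vessels(m, 0), ">= 1")
})

test_that("large/capillary split is a partition on random masks", {
  set.seed(21)
  for (i in 1:8) {
    m <- matrix(runif(60 * 60) < 0.3, 60, 60)
    sp <- remove_large_vessels(m, 5)
    expect_identical(sp$capillary | sp$large, m)
    expect_false(any(sp$capillary & sp$large))
  }
})

test_that("metrics take their saturation and known-phantom values", {
  flat <- flow_image(matrix(0.5, 32, 32), signal_strength_index = 9)
  sat <- compute_metrics(vessel_maps(matrix(TRUE, 32, 32)), flat,
                         matrix(TRUE, 32, 32))
  expect_equal(sat$vad, 1)
  expect_equal(sat$flux, 0.5)
  # 3-px bar: VDI (area px / skeleton px) is the bar width
  img <- bar_image(128, width = 3)
  maps <- vessel_maps(attr(img, "gt"))
  m <- compute_metrics(maps, flow_image(img, signal_strength_index = 9),
                       matrix(TRUE, 128, 128))
  expect_gte(m$vdi, 2.5); expect_lte(m$vdi, 3.5)
  # filled disc: complexity near the isoperimetric limit
  d <- disc_mask(101, 20)
  md <- compute_metrics(vessel_maps(d),
                        flow_image(d * 0.8, signal_strength_index = 9),
                        matrix(TRUE, 101, 101))
  expect_gte(md$vci, 0.8); expect_lte(md$vci, 1.3)
})

test_that("empty and vessel-free ROIs are handled explicitly", {
  img <- bar_image(64, width = 3)
  maps <- vessel_maps(attr(img, "gt"))
  fi <- flow_image(img, signal_strength_index = 9)
  expect_error(compute_metrics(maps, fi, matrix(FALSE, 64, 64)), "empty")
  corner <- matrix(FALSE, 64, 64); corner[1:5, 1:5] <- TRUE
  m <- compute_metrics(maps, fi, corner)
  expect_equal(m$vad, 0)
  expect_true(is.na(m$vdi) && is.na(m$vci))
  expect_match(m$flags, "vdi_undefined")
})

test_that("skeleton and perimeter densities never exceed area density", {
  set.seed(31)
  cp <- clean_phantom()
  q <- quantify_image(cp$ph$image, maps = cp$maps)
  expect_true(all(q$vsd <= q$vad + 1e-12))
  expect_true(all(q$vpi <= q$vad + 1e-12))
  # also on a noisy phantom
  ph <- generate_phantom(phantom_spec(grid = image_grid(256), seed = 9))
  q2 <- quantify_image(ph$image)
  expect_true(all(q2$vsd <= q2$vad + 1e-12))
  expect_true(all(q2$vpi <= q2$vad + 1e-12))
})

test_that("parallel-bar phantoms recover their analytic densities", {
  img <- bars_image(512, w = 4, p = 16)
  fi <- flow_image(img, signal_strength_index = 10)
  maps <- segment_vessels(fi)
  m <- compute_metrics(maps, fi, matrix(TRUE, 512, 512))
  expect_lt(abs(m$vad - 4 / 16) / (4 / 16), 0.10)
  expect_lt(abs(m$vsd - 1 / 16) / (1 / 16), 0.10)
  expect_lt(abs(m$vdi - 4) / 4, 0.10)
})

test_that("phantom metrics are stable under rotations and flips", {
  img <- bars_image(256, w = 4, p = 16)
  fi0 <- flow_image(img, signal_strength_index = 10)
  roi <- matrix(TRUE, 256, 256)
  vals <- lapply(list(img, rot90(img), img[256:1, ], img[, 256:1]),
                 function(x) {
    fi <- flow_image(x, signal_strength_index = 10)
    compute_metrics(segment_vessels(fi), fi, roi)
  })
  for (metric in c("vad", "vsd", "vdi", "vpi", "flux")) {
    v <- vapply(vals, function(m) m[[metric]], numeric(1))
    expect_lt(diff(range(v)) / mean(v), 0.02)
  }
})

test_that("quantify_image returns one row per region, deterministically", {
  ph <- generate_phantom(phantom_spec(grid = image_grid(192), seed = 4))
  q1 <- quantify_image(ph$image)
  expect_equal(nrow(q1), 5)
  expect_identical(q1$region, c("whole", "S", "N", "I", "T"))
  expect_identical(q1, quantify_image(ph$image))
  mac <- flow_image(ph$image$intensities, ph$image$grid, 9, "OS", "macula")
  qm <- quantify_image(mac)
  expect_equal(nrow(qm), 7)
  expect_identical(qm$region, c("whole", "S", "SN", "ST", "I", "IN", "IT"))
})

test_that("local metric maps track the global density", {
  img <- bars_image(128, w = 4, p = 16)
  maps <- vessel_maps(attr(img, "gt"))
  lv <- local_metric_map(maps, "vad", window = 31)
  expect_lt(abs(mean(lv[40:90, 40:90]) - 0.25), 0.03)
  expect_true(all(lv >= 0 & lv <= 1))
})

test_that("flow images round-trip through TIFF and PNG with sidecars", {
  dir <- withr::local_tempdir()
  ph <- generate_phantom(phantom_spec(grid = image_grid(64), seed = 2))
  for (ext in c("tif", "png")) {
    p <- file.path(dir, paste0("im.", ext))
    write_flow_image(ph$image, p)
    back <- read_flow_image(p)
    expect_lt(max(abs(back$intensities - ph$image$intensities)), 1 / 255)
    expect_identical(back$eye, "OD")
    expect_identical(back$target, "disc")
    expect_equal(back$signal_strength_index, 10)
  }
  expect_error(read_flow_image(file.path(dir, "missing.png")))
})
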