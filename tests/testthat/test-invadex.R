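test_that("erosion follows physical radii on analytic shapes", {
  # 200 um square at 1 um/px
  m <- matrix(0, 300, 300)
  m[51:250, 51:250] <- 1
  sq <- calibrated_mask(m, 1, role = "tissue")
  expect_equal(erode_mask(sq, 0)$mask, sq$mask)          # identity
  er <- erode_mask(sq, 35)
  expect_equal(mask_area(er), 130^2, tolerance = 0.03)   # 130 um square
  # margin beyond the half-width empties the mask
  expect_equal(sum(erode_mask(sq, 101)$mask), 0)
  expect_error(erode_mask(sq, -1), "non-negative")
})

test_that("core detection keeps components by the 10,000 um^2 rule", {
  # disk r=60 um: area ~11,310 um^2 -> kept
  d60 <- disk_mask(201, 1, 60)
  c60 <- detect_core(d60)
  expect_equal(c60$n_components, 1L)
  expect_equal(c60$total_area_um2, pi * 60^2, tolerance = 0.02)
  # disk r=50 um: area ~7,854 um^2 -> discarded
  d50 <- disk_mask(201, 1, 50)
  expect_equal(detect_core(d50)$n_components, 0L)
  # 5 um specks are annihilated by the 10 um opening
  specks <- matrix(0, 200, 200)
  sp <- disk_mask(200, 1, 5, cx = 50, cy = 50)$mask +
        disk_mask(200, 1, 5, cx = 150, cy = 150)$mask
  expect_equal(detect_core(calibrated_mask(sp, 1))$n_components, 0L)
})

test_that("core opening is idempotent", {
  phantom <- gen_tumour_mask(360, 1, core_radius = 80,
                             halo = data.frame(radius = 12, count = 6),
                             seed = 61)
  once <- detect_core(phantom$staining)
  twice <- detect_core(once$mask)
  expect_equal(twice$mask$mask, once$mask$mask)
  expect_equal(twice$total_area_um2, once$total_area_um2)
})

test_that("gross detection bridges nearby staining and drops coreless islands", {
  # a solid disk passes through 75/100/25 nearly unchanged (the image
  # leaves more than the 75 um dilation as background margin)
  d <- disk_mask(751, 1, 200)
  core <- detect_core(d)
  gross <- detect_gross(d, core)
  expect_equal(gross$n_components, 1L)
  expect_equal(gross$total_area_um2, pi * 200^2, tolerance = 0.02)

  # satellite disks within 150 um gaps merge into one gross component
  m <- disk_mask(601, 1, 100)$mask
  m <- m + disk_mask(601, 1, 20, cx = 301, cy = 301 + 100 + 20 + 120)$mask
  st <- calibrated_mask(pmin(m, 1), 1)
  core2 <- detect_core(st)
  gross2 <- detect_gross(st, core2)
  expect_equal(gross2$n_components, 1L)
  expect_gt(gross2$total_area_um2, pi * 100^2)

  # a distant speck cluster with no core inside is excluded
  m3 <- disk_mask(801, 1, 100)$mask
  for (dx in c(-30, 0, 30)) {
    m3 <- m3 + disk_mask(801, 1, 12, cx = 700, cy = 650 + dx)$mask
  }
  st3 <- calibrated_mask(pmin(m3, 1), 1)
  core3 <- detect_core(st3)
  gross3 <- detect_gross(st3, core3)
  expect_equal(gross3$n_components, 1L)      # only the cored component
  expect_equal(gross3$total_area_um2, pi * 100^2, tolerance = 0.05)
})

test_that("invasiveness index is the gross/core area ratio with a guard", {
  expect_equal(invasiveness_index(100, 100), 1)
  expect_equal(invasiveness_index(100, 200), 2)
  expect_true(is.na(invasiveness_index(0, 50)))
})

test_that("full section pipeline: no halo gives II of 1, halo raises it", {
  solid <- gen_tumour_mask(400, 1, core_radius = 100, halo = NULL, seed = 71)
  res <- run_section(solid$tissue, solid$staining)
  expect_equal(res$ii, 1, tolerance = 0.02)
  expect_equal(res$core_area_um2, solid$truth$core_area_um2,
               tolerance = 0.02)

  # growing halo load increases II monotonically
  iis <- vapply(c(0, 8, 20), function(ct) {
    ph <- gen_tumour_mask(700, 1, core_radius = 100,
                          halo = if (ct > 0)
                            data.frame(radius = 15, count = ct) else NULL,
                          seed = 73)
    run_section(ph$tissue, ph$staining)$ii
  }, numeric(1))
  expect_true(all(diff(iis) > 0))
  expect_true(all(iis >= 1 - 0.01))   # gross contains core up to pixelation

  # empty staining reports no core and an undefined index
  empty <- calibrated_mask(matrix(0, 200, 200), 1)
  res0 <- run_section(full_tissue(200, 1), empty)
  expect_equal(res0$n_core_components, 0L)
  expect_true(is.na(res0$ii))
})

test_that("results are resolution-invariant within discretisation tolerance", {
  areas <- vapply(c(0.5, 1, 2), function(ps) {
    n <- round(320 / ps)
    core <- detect_core(disk_mask(n, ps, 60))
    core$total_area_um2
  }, numeric(1))
  expect_lt(max(abs(areas / (pi * 60^2) - 1)), 0.03)
})

test_that("sections aggregate to one specimen value", {
  r <- list(list(ii = 1.2), list(ii = 1.6), list(ii = NA_real_))
  expect_equal(aggregate_sections(r), 1.4)
  expect_equal(aggregate_sections(r, method = "median"), 1.4)
  expect_true(is.na(aggregate_sections(list(list(ii = NA_real_)))))
})

test_that("mask images round-trip through PNG and TIFF", {
  ph <- gen_tumour_mask(120, 2, core_radius = 40, seed = 81)
  for (ext in c(".png", ".tif")) {
    f <- withr::local_tempfile(fileext = ext)
    write_mask(ph$staining, f)
    back <- read_mask(f, pixel_size = 2)
    expect_equal(back$mask, ph$staining$mask)
    expect_equal(back$pixel_size, 2)
  }
  expect_error(read_mask("mask.bmp", 1), "unsupported")
})
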