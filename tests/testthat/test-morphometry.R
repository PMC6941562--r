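test_that("measurement constructor enforces count sanity", {
  expect_error(section_measurement(1, total_area_px = 100,
                                   infarct_area_px = 101),
               "cannot exceed")
  expect_error(section_measurement(1, 100, 10, scar_collagen_px = 5,
                                   scar_total_px = 4),
               "cannot exceed")
  expect_error(section_measurement(1, -1, 0), "nonnegative")
  m <- section_measurement(2, 65841, 21610)
  expect_s3_class(m, "section_measurement")
})

test_that("per-section infarct fraction matches the reference table", {
  # frozen from the bundled serial-section dataset
  expect_equal(
    round(infarct_fraction_section(section_measurement(2, 65841, 21610)), 2),
    32.82)
  expect_equal(
    round(infarct_fraction_section(section_measurement(5, 275569, 27678)), 2),
    10.04)
  expect_equal(infarct_fraction_section(section_measurement(3, 1000, 0)), 0)
  expect_error(infarct_fraction_section(section_measurement(1, 0, 0)),
               "undefined")
})

test_that("volumetric fraction weights by area and is spacing-invariant", {
  s <- mouse_mi_sections("auto")
  v1 <- volumetric_infarct_fraction(s)
  # uniform slab weight cancels out of the ratio
  for (n in c(1, 2, 7, 120)) {
    expect_equal(volumetric_infarct_fraction(s, n = n), v1)
  }
  # single-section series collapses to the per-section fraction
  one <- section_series(section_measurement(1, 5000, 500))
  expect_equal(volumetric_infarct_fraction(one), 10)
  expect_equal(volumetric_infarct_fraction(one),
               infarct_fraction_section(one)[1])
  # non-uniform weights shift the result toward the heavier sections
  two <- section_series(data.frame(section_index = 1:2,
                                   total_area_px = c(100, 100),
                                   infarct_area_px = c(50, 0)))
  expect_equal(volumetric_infarct_fraction(two, n = c(3, 1)), 37.5)
})

test_that("volumetric differs from the unweighted average as expected", {
  s <- mouse_mi_sections("auto")
  vol <- volumetric_infarct_fraction(s)
  avg <- average_infarct_fraction(s)
  # apical infarct: small sections carry high percentages, so the
  # area-weighted volume fraction lies below the plain average
  expect_lt(vol, avg)
  # and the volumetric value is exactly the area-weighted mean
  keep <- !is.na(s$total_area_px)
  wmean <- sum(s$infarct_area_px[keep]) / sum(s$total_area_px[keep]) * 100
  expect_equal(vol, wmean)
})

test_that("averages and volumetrics are permutation-invariant", {
  s <- mouse_mi_sections("auto")
  df <- as.data.frame(s)
  shuffled <- section_series(df[sample(nrow(df)), ])
  expect_equal(average_infarct_fraction(shuffled),
               average_infarct_fraction(s))
  expect_equal(volumetric_infarct_fraction(shuffled),
               volumetric_infarct_fraction(s))
})

test_that("ROI percentages are plain ratios with NA propagation", {
  m <- section_measurement(2, 20000, 3000,
                           scar_collagen_px = 1711, scar_total_px = 10000,
                           remote_fibrosis_px = 615, remote_total_px = 10000)
  expect_equal(collagen_content_pct(m), 17.11)
  expect_equal(interstitial_fibrosis_pct(m), 6.15)
  full <- section_measurement(2, 100, 0, remote_fibrosis_px = 50,
                              remote_total_px = 50)
  expect_equal(interstitial_fibrosis_pct(full), 100)

  set.seed(2)
  for (i in 1:20) {
    tot <- sample(1000:100000, 1)
    sub <- sample(0:tot, 1)
    m <- section_measurement(1, tot, 0, scar_collagen_px = sub,
                             scar_total_px = tot)
    expect_equal(collagen_content_pct(m), 100 * sub / tot)
  }

  none <- section_measurement(3, 100, 10)
  expect_true(is.na(collagen_content_pct(none)))
  expect_true(is.na(interstitial_fibrosis_pct(none)))
})

test_that("series summary skips unmeasured sections, never imputes zero", {
  df <- data.frame(section_index = 1:3,
                   total_area_px = c(1000, 2000, 4000),
                   infarct_area_px = c(100, 100, 0),
                   scar_collagen_px = c(50, NA, NA),
                   scar_total_px = c(500, NA, NA))
  s <- section_series(df)
  sm <- summarize_series(s)
  expect_equal(sm$avg_collagen_pct, 10) # only section 1 has a scar ROI
  expect_true(is.na(sm$avg_fibrosis_pct))

  # adding an all-missing section leaves every ROI average unchanged
  df2 <- rbind(df, data.frame(section_index = 4, total_area_px = NA,
                              infarct_area_px = NA, scar_collagen_px = NA,
                              scar_total_px = NA))
  sm2 <- summarize_series(section_series(df2))
  expect_equal(sm2$avg_collagen_pct, sm$avg_collagen_pct)
  expect_equal(sm2$average_infarct_pct, sm$average_infarct_pct)
  expect_equal(sm2$volumetric_infarct_pct, sm$volumetric_infarct_pct)

  one <- summarize_series(section_series(section_measurement(1, 200, 20)))
  expect_equal(one$average_infarct_pct, 10)
  expect_equal(one$volumetric_infarct_pct, 10)
})

test_that("every reported percentage stays within [0, 100]", {
  set.seed(9)
  for (i in 1:25) {
    k <- sample(1:8, 1)
    tot <- sample(100:10000, k, replace = TRUE)
    inf <- vapply(tot, function(t) sample(0:t, 1), numeric(1))
    s <- section_series(data.frame(section_index = seq_len(k),
                                   total_area_px = tot,
                                   infarct_area_px = inf))
    sm <- summarize_series(s)
    vals <- c(sm$per_section_pct, sm$average_infarct_pct,
              sm$volumetric_infarct_pct)
    expect_true(all(vals >= 0 & vals <= 100))
  }
})
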