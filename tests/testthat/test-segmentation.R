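test_that("classify_pixel assigns the canonical stain colours", {
  expect_equal(classify_pixel(c(255, 255, 255)), "background")
  expect_equal(classify_pixel(c(30, 30, 200)), "collagen")
  expect_equal(classify_pixel(c(200, 40, 40)), "muscle")
  # blue-to-gray gradient: low spread inside the gray window
  expect_equal(classify_pixel(c(150, 150, 155)), "collagen")
  # ambiguous mid-range colour falls through to other tissue
  expect_equal(classify_pixel(c(120, 160, 110)), "other_tissue")
  # fully transparent pixels are background whatever their colour
  expect_equal(classify_pixel(c(200, 40, 40), alpha = 0), "background")
  expect_equal(classify_pixel(c(200, 40, 40), alpha = 255), "muscle")
  expect_error(classify_pixel(c(-1, 0, 0)), "0, 255")
  expect_error(classify_pixel(c(0, 0, 300)), "0, 255")
})

test_that("segment_section matches the per-pixel reference classifier", {
  set.seed(42)
  for (rep in 1:5) {
    img <- random_stain_image(64, 64)
    map <- segment_section(img)
    expect_identical(map$labels, naive_segment(img))
    expect_identical(sum(map$counts), 64L * 64L)
    expect_identical(map$counts,
                     {
                       cnt <- tabulate(naive_segment(img), 4)
                       names(cnt) <- color_classes()
                       cnt
                     })
  }
})

test_that("segmentation is deterministic and conserves pixel count", {
  set.seed(7)
  img <- random_stain_image(40, 56)
  m1 <- segment_section(img)
  m2 <- segment_section(img)
  expect_identical(m1$labels, m2$labels)
  expect_identical(sum(m1$counts), 40L * 56L)

  white <- solid_image(10, 10, c(255, 255, 255))
  expect_equal(segment_section(white)$counts,
               c(background = 100L, collagen = 0L, muscle = 0L,
                 other_tissue = 0L))
})

test_that("alpha-zero pixels are always background", {
  img <- array(0L, dim = c(6, 6, 4))
  img[, , 1] <- 200L; img[, , 2] <- 40L; img[, , 3] <- 40L
  img[, , 4] <- 255L
  img[1:2, , 4] <- 0L
  map <- segment_section(img)
  expect_equal(map$counts[["background"]], 12L)
  expect_equal(map$counts[["muscle"]], 24L)
})

test_that("permuting precedence only relabels multi-predicate pixels", {
  set.seed(11)
  img <- random_stain_image(48, 48)
  default <- threshold_scheme()
  permuted <- threshold_scheme(precedence = c("muscle", "collagen",
                                              "other_tissue", "background"))
  l1 <- segment_section(img, default)$labels
  l2 <- segment_section(img, permuted)$labels
  changed <- which(l1 != l2)
  # every changed pixel must satisfy at least two class predicates
  # (other_tissue, the fallback, always matches)
  for (k in changed) {
    i <- (k - 1) %% 48 + 1; j <- (k - 1) %/% 48 + 1
    rgb <- img[i, j, ]
    sat <- c(
      background = min(rgb) >= default$background_min_channel,
      collagen = (rgb[3] >= rgb[1] + default$blue_margin &&
                    rgb[3] >= rgb[2]) ||
        (max(rgb) - min(rgb) <= default$gray_spread &&
           min(rgb) >= default$gray_low && max(rgb) <= default$gray_high),
      muscle = rgb[1] >= rgb[3] + default$red_margin,
      other_tissue = TRUE)
    expect_gte(sum(sat), 2)
  }
})

test_that("ROI counts equal a brute-force masked count", {
  set.seed(3)
  img <- random_stain_image(32, 32)
  map <- segment_section(img)

  all_true <- matrix(TRUE, 32, 32)
  expect_identical(count_roi_classes(map, all_true), map$counts)
  all_false <- matrix(FALSE, 32, 32)
  expect_identical(unname(count_roi_classes(map, all_false)), rep(0L, 4)) # nolint

  roi <- matrix(runif(32 * 32) < 0.4, 32, 32)
  brute <- integer(4)
  labels <- naive_segment(img)
  for (i in 1:32) for (j in 1:32) {
    if (roi[i, j]) brute[labels[i, j]] <- brute[labels[i, j]] + 1L
  }
  names(brute) <- color_classes()
  expect_identical(count_roi_classes(map, roi), brute)
  expect_identical(sum(count_roi_classes(map, roi)), sum(roi))

  expect_error(count_roi_classes(map, matrix(TRUE, 10, 10)),
               "do not match")
})

test_that("overlays paint included classes opaquely, the rest transparent", {
  set.seed(5)
  ph <- make_phantom_section(phantom_spec(canvas = c(64, 64),
                                          outer_radius = 25,
                                          inner_radius = 12, seed = 5))
  map <- segment_section(ph$image)
  ov <- render_overlay(map, include = c("collagen", "muscle"))
  expect_equal(dim(ov), c(64, 64, 4))
  opaque <- sum(ov[, , 4] == 255)
  expect_identical(opaque,
                   map$counts[["collagen"]] + map$counts[["muscle"]])
  expect_true(all(ov[, , 4] %in% c(0L, 255L)))

  # excluded-only map renders fully transparent
  muscle_map <- segment_section(solid_image(8, 8, c(200, 40, 40)))
  ov2 <- render_overlay(muscle_map, include = "collagen")
  expect_true(all(ov2[, , 4] == 0))

  expect_error(render_overlay(map, include = character(0)), "at least one")

  # writing and re-reading preserves opaque-pixel positions
  path <- withr::local_tempfile(fileext = ".png")
  write_image_png(ov, path)
  back <- read_section_image(path)
  expect_identical(back[, , 4] > 0, ov[, , 4] > 0)
})
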