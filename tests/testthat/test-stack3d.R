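make_square_map <- function(h, w, top, left, size, rgb = c(200, 40, 40)) {
  img <- solid_image(h, w, c(255, 255, 255))
  for (ch in 1:3) {
    img[top:(top + size - 1), left:(left + size - 1), ch] <- as.integer(rgb[ch])
  }
  segment_section(img)
}

test_that("centroid alignment recovers known translations", {
  base <- make_square_map(40, 40, 15, 15, 8)
  shifted <- make_square_map(40, 40, 20, 12, 8) # moved +5 rows, -3 cols
  al <- align_sections(list(base, shifted))
  # identical content translated by (dr, dc) must differ in offset by (-dr, -dc)
  expect_equal(al$offsets[2, ] - al$offsets[1, ], c(row = -5, col = 3))

  # two identical sections get identical offsets
  al2 <- align_sections(list(base, base))
  expect_equal(al2$offsets[1, ], al2$offsets[2, ])

  # a section already centred on its canvas needs no shift
  centred <- make_square_map(41, 41, 17, 17, 8)
  al3 <- align_sections(list(centred), canvas = c(41, 41))
  expect_equal(unname(al3$offsets[1, ]), c(0, 0))

  empty <- segment_section(solid_image(10, 10, c(255, 255, 255)))
  expect_warning(al4 <- align_sections(list(empty)), "no tissue")
  expect_equal(unname(al4$offsets[1, ]), c(0, 0))
})

test_that("alignment onto the canvas preserves per-class counts", {
  set.seed(4)
  phs <- make_phantom_series(phantom_spec(canvas = c(96, 96),
                                          outer_radius = 30,
                                          inner_radius = 14,
                                          fibrosis_density = 0.05,
                                          seed = 4),
                             k = 3, taper = -4)
  maps <- lapply(phs, function(p) segment_section(p$image))
  stack <- build_stack(maps, z_step_px = 1)
  for (i in seq_along(maps)) {
    slab <- stack$labels[, , i]
    slab_counts <- tabulate(slab, 4)
    tissue <- 2:4 # collagen, muscle, other
    expect_equal(slab_counts[tissue], unname(maps[[i]]$counts)[tissue])
  }
})

test_that("stack depth and voxel counts follow the slab law", {
  m <- make_square_map(20, 20, 5, 5, 6)
  st <- build_stack(list(m, m), z_step_px = 1, align = FALSE)
  expect_equal(dim(st$labels)[3], 2)

  phs <- make_phantom_series(phantom_spec(canvas = c(64, 64),
                                          outer_radius = 20,
                                          inner_radius = 10, seed = 2),
                             k = 3, taper = -2)
  maps <- lapply(phs, function(p) segment_section(p$image))
  st4 <- build_stack(maps, z_step_px = 4)
  expect_equal(dim(st4$labels)[3], 12)
  expect_equal(st4$section_of_slab, rep(1:3, each = 4))
  counts <- stack_volume_summary(st4)$voxel_counts
  expect_equal(counts[["collagen"]],
               sum(vapply(maps, function(m) m$counts[["collagen"]],
                          numeric(1))) * 4)
  expect_equal(sum(counts), prod(dim(st4$labels)))

  expect_error(build_stack(list()), "at least one")
  expect_error(build_stack(list(m, make_square_map(10, 10, 2, 2, 3)),
                           align = FALSE), "share canvas")
})

test_that("stack volumetric percent equals the series computation exactly", {
  set.seed(6)
  phs <- make_phantom_series(phantom_spec(canvas = c(96, 96),
                                          outer_radius = 30,
                                          inner_radius = 15,
                                          fibrosis_density = 0.02,
                                          seed = 6),
                             k = 4, taper = -3)
  maps <- lapply(phs, function(p) segment_section(p$image))
  series <- section_series(lapply(seq_along(maps), function(i) {
    measure_section(maps[[i]], i)
  }))
  for (z in c(1, 3)) {
    st <- build_stack(maps, z_step_px = z)
    expect_identical(stack_volume_summary(st)$volumetric_infarct_pct,
                     volumetric_infarct_fraction(series))
  }

  all_muscle <- build_stack(list(make_square_map(16, 16, 4, 4, 8)))
  expect_equal(stack_volume_summary(all_muscle)$volumetric_infarct_pct, 0)
})

test_that("slice export round-trips through PNG files", {
  m1 <- make_square_map(24, 24, 6, 6, 8)
  m2 <- make_square_map(24, 24, 8, 8, 8, rgb = c(30, 30, 200))
  st <- build_stack(list(m1, m2), z_step_px = 1)
  dir <- withr::local_tempdir()
  paths <- export_stack_slices(st, dir)
  expect_length(paths, 2)
  expect_true(all(file.exists(paths)))

  back <- import_stack_slices(dir)
  expect_identical(back$labels, st$labels)
  expect_equal(back$z_step_px, st$z_step_px)
  expect_equal(back$spacing_um, st$spacing_um)

  # opaque pixels per slice equal the slab's non-background count
  for (z in 1:2) {
    arr <- read_section_image(paths[z])
    bg <- match("background", color_classes())
    expect_equal(sum(arr[, , 4] > 0), sum(st$labels[, , z] != bg))
  }
})
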