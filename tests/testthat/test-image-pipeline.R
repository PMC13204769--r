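cfg <- pipeline_config()

test_that("a blank page is a fixed point of normalization", {
  tmpl <- default_layout("letter_cancellation")
  blank <- matrix(255, 1414, 1000)
  sheet <- load_and_normalize(blank, tmpl, cfg)
  expect_equal(sheet$width, cfg$canonical_width)
  expect_true(all(sheet$pixels == 255))
})

test_that("normalization is idempotent up to interpolation error", {
  sp <- synthetic_spec("star_cancellation", severity = 0.3, seed = 21,
                       corruption = list(rotation = 2))
  sh <- render_sheet(sp)
  s1 <- load_and_normalize(sh$sheet, sh$template, cfg)
  s2 <- load_and_normalize(s1, sh$template, cfg)
  expect_lte(max(abs(s2$pixels - s1$pixels)), 1)
})

test_that("a half-resolution scan recovers canonical geometry", {
  sp <- synthetic_spec("star_cancellation", severity = 0.4, seed = 6)
  sh <- render_sheet(sp)
  small <- neglectscore:::resize_page(sh$sheet$pixels, 620)
  sheet <- load_and_normalize(small, sh$template, cfg)
  expect_equal(sheet$width, cfg$canonical_width)
  expect_gt(neglectscore:::.registration_score(sheet$pixels, sh$template,
                                               cfg), 0.9)
  ink <- extract_ink(sheet, sh$template, cfg)
  res <- score_cancellation(detect_crossings(ink, sh$template, cfg),
                            sh$template)
  expect_equal(res$total, unname(sh$truth$counts["total"]))
})

test_that("an upside-down bisection sheet is righted by the arrow", {
  sp <- synthetic_spec("line_bisection", severity = 0.2, seed = 5,
                       corruption = list(rotation = 180))
  sh <- render_sheet(sp)
  sheet <- load_and_normalize(sh$sheet, sh$template, cfg)
  expect_gt(neglectscore:::.fiducial_cover(sheet$pixels, sh$template),
            cfg$fiducial_min_cover)
  # and the marks land where the truth says
  ink <- extract_ink(sheet, sh$template, cfg)
  l1 <- sh$template$bisection_lines[1, ]
  x <- detect_bisection_mark(ink, l1, cfg)
  expect_lt(abs(x - sh$truth$bisection$x_mark[1]), 3)
})

test_that("a bisection sheet without its arrow raises no_fiducial", {
  tmpl <- default_layout("line_bisection")
  page <- render_template(tmpl)
  f <- tmpl$fiducial
  rows <- (f$y - f$size):(f$y + f$size)
  page[rows, (f$x - f$size):(f$x + f$size)] <- 255
  expect_error(load_and_normalize(page, tmpl, cfg),
               class = "neglectscore_qc_error")
})

test_that("skews up to five degrees are recovered within tolerance", {
  for (rot in c(-5, -1.7, 2.3, 5)) {
    sp <- synthetic_spec("letter_cancellation", severity = 0.3, seed = 4,
                         corruption = list(rotation = rot))
    sh <- render_sheet(sp)
    sheet <- load_and_normalize(sh$sheet, sh$template, cfg)
    resid <- neglectscore:::estimate_skew(sheet$pixels < 160)
    expect_lt(abs(resid), 0.5)
  }
})

test_that("unreadable input files raise an input error", {
  expect_error(load_sheet(tempfile(fileext = ".png")), "unreadable")
  empty <- tempfile(fileext = ".png"); file.create(empty)
  expect_error(load_sheet(empty), "unreadable")
  unlink(empty)
})

test_that("blank printed templates leave no patient ink", {
  for (st in c("letter_cancellation", "line_bisection", "copy_diamond")) {
    tmpl <- default_layout(st)
    ink <- extract_ink(sheet_image(render_template(tmpl)), tmpl, cfg)
    expect_lte(sum(ink), cfg$noise_floor)
  }
})

test_that("a rendered stroke is recovered almost completely", {
  tmpl <- default_layout("letter_cancellation")
  page <- render_template(tmpl)
  with_stroke <- neglectscore:::draw_segment(page, 300, 300, 380, 360,
                                             width = 3, intensity = 60)
  stroke_px <- with_stroke < 160 & !(page < 160)
  ink <- extract_ink(sheet_image(with_stroke), tmpl, cfg)
  expect_gte(sum(ink & stroke_px) / sum(stroke_px), 0.9)
})

test_that("faint strokes are dropped and flagged as low contrast", {
  # contrast 0.25 leaves patient ink at intensity ~206, above the ink cut
  r <- score_synthetic("letter_cancellation", severity = 0, seed = 8,
                       corruption = list(contrast = 0.25))
  expect_equal(r$scored$result$total, 0)
  expect_true("low_contrast" %in% r$scored$qc$flags)
})

test_that("clean sheets yield an empty QC flag set", {
  for (st in c("line_crossing", "line_bisection", "copy_diamond")) {
    r <- score_synthetic(st, severity = 0.3, seed = 10)
    expect_length(r$scored$qc$flags, 0)
  }
})

test_that("salt-and-pepper speckle raises excessive_noise", {
  r <- score_synthetic("letter_cancellation", severity = 0.2, seed = 7,
                       corruption = list(noise_density = 0.001))
  expect_true("excessive_noise" %in% r$scored$qc$flags)
})

test_that("drawings spilling past the region raise out_of_region_drawing", {
  r <- score_synthetic("copy_star", seed = 9,
                       response = list(star_radius = 520))
  expect_true("out_of_region_drawing" %in% r$scored$qc$flags)
})
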