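cfg <- pipeline_config()

drawing_of <- function(subtest, ...) {
  r <- score_synthetic(subtest, ...)
  sheet <- load_and_normalize(r$sheet, r$template, cfg)
  ink <- extract_ink(sheet, r$template, cfg)
  figure <- if (subtest == "copy_star") "star" else "diamond"
  list(drawing = extract_drawing(ink, r$template$drawing_region, figure,
                                 cfg),
       result = r$scored$result, truth = r$truth)
}

test_that("an ideal star yields eight classified corners and full marks", {
  d <- drawing_of("copy_star", seed = 3, response = list(copy_angle_sd = 0))
  expect_equal(d$drawing$n_corners, 8L)
  expect_equal(sum(d$drawing$corners$class == "outer"), 4L)
  expect_equal(sum(d$drawing$corners$class == "inner"), 4L)
  expect_equal(d$result$shape, 1L)
  expect_equal(d$result$detail, 1L)
  expect_equal(d$result$arrangement, 1L)
  expect_equal(d$result$net_sum, 3L)
  expect_equal(d$result$bit_binary, 1L)
  expect_true(all(abs(d$result$diagnostics$tip_angles - 110) < 3))
})

test_that("a star with a deleted tip loses the detail point", {
  d <- drawing_of("copy_star", seed = 3,
                  response = list(copy_angle_sd = 0, delete_tips = 2))
  expect_lt(d$drawing$n_corners, 8L)
  expect_equal(d$result$detail, 0L)
  expect_equal(d$result$bit_binary, 0L)
})

test_that("edge gaps beyond the closure tolerance break the shape point", {
  ok <- drawing_of("copy_star", seed = 5,
                   response = list(copy_angle_sd = 0, gap_probability = 1,
                                   gap_width = 12))
  expect_equal(ok$result$shape, 1L)
  bad <- drawing_of("copy_star", seed = 5,
                    response = list(copy_angle_sd = 0, gap_probability = 1,
                                    gap_width = 60))
  expect_equal(bad$result$shape, 0L)
})

test_that("the archetype is equivariant under translation and scaling", {
  tmpl <- default_layout("copy_star")
  base <- blank_page_drawing <- function(cx, cy, R) {
    page <- render_template(tmpl)
    v <- neglectscore:::star_vertices(cx, cy, R, inner_angle_deg = 110)
    page <- neglectscore:::draw_polyline(page, v, width = 3,
                                         intensity = 60, closed = TRUE)
    ink <- extract_ink(sheet_image(page), tmpl, cfg)
    fit_archetype(extract_drawing(ink, tmpl$drawing_region, "star", cfg))
  }
  a1 <- base(560, 1000, 200)
  a2 <- base(560 + 60, 1000 + 40, 200)   # translated
  a3 <- base(560, 1000, 300)             # scaled x1.5
  expect_false(a1$degenerate || a2$degenerate || a3$degenerate)
  shift <- a2$vertices - a1$vertices
  expect_true(all(abs(shift[, 1] - 60) < 3))
  expect_true(all(abs(shift[, 2] - 40) < 3))
  expect_equal(a3$scale / a1$scale, 1.5, tolerance = 0.03)
})

test_that("star angle rules follow the strict and loose bands", {
  # inner angles at 150 degrees: all deviations 40 (within the loose band)
  # but none within the strict 30, so the arrangement point is lost
  wide <- drawing_of("copy_star", seed = 4,
                     response = list(copy_angle_sd = 0,
                                     star_inner_angle = 150))
  expect_equal(wide$result$arrangement, 0L)
  # 135 degrees: deviation 25, inside the strict band
  mid <- drawing_of("copy_star", seed = 4,
                    response = list(copy_angle_sd = 0,
                                    star_inner_angle = 135))
  expect_equal(mid$result$arrangement, 1L)
})

test_that("a 45-degree rotated ideal star fails the axis-aligned spans", {
  rot <- drawing_of("copy_star", seed = 3,
                    response = list(copy_angle_sd = 0, star_rotation = 45))
  expect_equal(rot$result$arrangement, 0L)
  expect_false(isTRUE(rot$result$diagnostics$span_ok))
})

test_that("an ideal diamond earns all points, plain and hierarchical", {
  d <- drawing_of("copy_diamond", seed = 3,
                  response = list(copy_angle_sd = 0))
  expect_equal(d$result$shape, 1L)
  expect_equal(d$result$detail, 1L)
  expect_equal(d$result$arrangement, 1L)
  expect_equal(d$result$net_sum, 3L)
  expect_equal(d$result$net_hierarchical, 3L)
  expect_equal(d$result$bit_binary, 1L)
  expect_true(all(abs(d$result$diagnostics$angles - 45) < 0.5))
})

test_that("one bad diamond angle is tolerated, two are not", {
  one <- drawing_of("copy_diamond", seed = 11,
                    response = list(diamond_angles = c(55, 45, 45, 45)))
  expect_equal(one$result$arrangement, 1L)
  two <- drawing_of("copy_diamond", seed = 11,
                    response = list(diamond_angles = c(55, 45, 45, 55)))
  expect_equal(two$result$arrangement, 0L)
})

test_that("a diamond without its midline loses detail and the gate", {
  d <- drawing_of("copy_diamond", seed = 3,
                  response = list(copy_angle_sd = 0, midline = FALSE))
  expect_equal(d$result$shape, 1L)
  expect_equal(d$result$detail, 0L)
  expect_equal(d$result$bit_binary, 0L)
  expect_equal(d$result$net_hierarchical, 1L)  # arrangement gated off
})

test_that("empty drawings score zero without error", {
  tmpl <- default_layout("copy_star")
  ink <- extract_ink(sheet_image(render_template(tmpl)), tmpl, cfg)
  drawing <- extract_drawing(ink, tmpl$drawing_region, "star", cfg)
  expect_equal(drawing$n_corners, 0L)
  res <- score_star(drawing, config = cfg)
  expect_equal(res$net_sum, 0L)
  expect_equal(res$bit_binary, 0L)
})

test_that("score gating invariants hold across random copies", {
  for (s in 1:6) {
    st <- drawing_of("copy_star", seed = 50 + s,
                     response = list(copy_angle_sd = 2,
                                     gap_probability = 0.25,
                                     gap_width = 45,
                                     tremor_amplitude = 1.5))$result
    expect_equal(st$bit_binary, as.integer(st$shape & st$detail))
    if (st$detail == 1L) expect_equal(st$shape, 1L)
    dm <- drawing_of("copy_diamond", seed = 70 + s,
                     response = list(copy_angle_sd = 3,
                                     gap_probability = 0.25,
                                     gap_width = 45,
                                     midline = s %% 2 == 0))$result
    expect_equal(dm$bit_binary, as.integer(dm$shape & dm$detail))
    expect_lte(dm$net_hierarchical, dm$net_sum)
  }
})
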