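test_that("rendering is deterministic given spec and seed", {
  sp <- synthetic_spec("star_cancellation", severity = 0.5, seed = 77,
                       corruption = list(rotation = 1.5,
                                         noise_density = 2e-4))
  a <- render_sheet(sp)
  b <- render_sheet(sp)
  expect_identical(a$sheet$pixels, b$sheet$pixels)
  expect_identical(a$truth$crossed, b$truth$crossed)
})

test_that("severity zero crosses every target", {
  for (st in c("line_crossing", "letter_cancellation",
               "star_cancellation")) {
    sh <- render_sheet(synthetic_spec(st, severity = 0, seed = 12))
    expect_true(all(sh$truth$crossed))
  }
})

test_that("the crossing-probability model matches its closed form", {
  expect_equal(crossing_probability(c(0, 0.5, 1), 0), c(1, 1, 1))
  # full severity, leftmost position sits below the 5% floor
  expect_lte(crossing_probability(0, 1), 0.05)
  # logistic symmetry: p(x) + p(1 - x) = 2 - s
  xs <- seq(0, 1, by = 0.1)
  for (s in c(0.2, 0.7, 1)) {
    expect_equal(crossing_probability(xs, s) +
                   crossing_probability(1 - xs, s),
                 rep(2 - s, length(xs)), tolerance = 1e-12)
  }
})

test_that("Monte-Carlo crossing rates track the model mean", {
  x <- seq(0, 1, length.out = 20)
  s <- 1
  p <- crossing_probability(x, s)
  counts <- matrix(0, 1000, length(x))
  for (seed in 1:1000) {
    counts[seed, ] <- neglect_response_model(x, s, seed = seed)
  }
  phat <- colMeans(counts)
  se <- sqrt(p * (1 - p) / 1000)
  expect_true(all(abs(phat - p) <= pmax(3 * se, 0.02)))
})

test_that("corruption draws do not perturb the response stream", {
  clean <- render_sheet(synthetic_spec("letter_cancellation", 0.5, seed = 9))
  dirty <- render_sheet(synthetic_spec("letter_cancellation", 0.5, seed = 9,
                                       corruption = list(rotation = 2,
                                                         noise_density = 1e-3)))
  expect_identical(clean$truth$crossed, dirty$truth$crossed)
})

test_that("injected corruption is recorded and measurable", {
  sh <- render_sheet(synthetic_spec("letter_cancellation", 0.3, seed = 13,
                                    corruption = list(rotation = 2.5)))
  expect_equal(sh$truth$corruption$rotation, 2.5)
  est <- neglectscore:::estimate_skew(sh$sheet$pixels < 160)
  expect_lt(abs(est - 2.5), 0.3)
})

test_that("rendering does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(render_sheet(synthetic_spec("line_bisection", 0.4, seed = 3)))
  expect_identical(.Random.seed, before)
})

test_that("expected left-side crossings are nonincreasing in severity", {
  tmpl <- default_layout("letter_cancellation")
  xs <- tmpl$targets$x[tmpl$targets$side == "L"]
  sev <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(sev, function(s) {
    tot <- 0
    for (seed in 1:300) {
      tot <- tot + sum(neglect_response_model(tmpl$targets$x, s,
                                              seed = seed)[
        tmpl$targets$side == "L"])
    }
    tot / 300
  }, numeric(1))
  expect_true(all(diff(means) <= 0.1))  # Monte-Carlo slack
})

test_that("a written synthetic set reloads and rescores identically", {
  dir <- tempfile("synth")
  specs <- list(synthetic_spec("line_crossing", 0.4, seed = 31),
                synthetic_spec("line_bisection", 0.4, seed = 32))
  man <- write_synthetic_set(specs, dir)
  expect_true(all(file.exists(file.path(dir, man$file))))
  expect_true(file.exists(file.path(dir, "layout_line_crossing.yaml")))
  sc <- score_sheet(file.path(dir, man$file[1]),
                    read_layout(file.path(dir,
                                          "layout_line_crossing.yaml")))
  truth <- jsonlite::read_json(file.path(dir,
                                         sub("\\.png$", "_truth.json",
                                             man$file[1])),
                               simplifyVector = TRUE)
  expect_equal(sc$result$total, truth$counts[["total"]])
  unlink(dir, recursive = TRUE)
})
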