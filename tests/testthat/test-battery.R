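test_that("the letter-cancellation standard-value rule is exact", {
  tab <- sv_table("letter_cancellation")
  expect_equal(sv_lookup(0, tab), 0)
  expect_equal(sv_lookup(1, tab), 0)
  expect_equal(sv_lookup(2, tab), 0.5)
  expect_equal(sv_lookup(3, tab), 0.5)
  expect_equal(sv_lookup(4, tab), 1)
  expect_equal(sv_lookup(39, tab), 9.5)
  expect_equal(sv_lookup(40, tab), 10)
  expect_error(sv_lookup(41, tab), "out of range")
  expect_error(sv_lookup(-1, tab), "out of range")
})

test_that("all standard-value tables are monotone on a half-point grid", {
  for (st in c("line_crossing", "letter_cancellation", "star_cancellation",
               "line_bisection", "copy_star", "copy_diamond")) {
    tab <- sv_table(st)
    expect_true(all(diff(tab$sv) >= 0))
    expect_true(all(tab$sv * 2 == floor(tab$sv * 2)))
    expect_equal(tab$sv[1], 0)
    expect_equal(tab$sv[tab$raw_max + 1], 10)
  }
})

test_that("subset weights reproduce the published percentages", {
  w <- subset_weights(c(letter = 40, bisection = 9, copy1 = 1, copy2 = 1,
                        copy3 = 1, clock = 1))
  expect_equal(unname(w$percent["letter"]), 75.47)
  expect_equal(unname(w$percent["bisection"]), 16.98)
  expect_equal(unname(w$percent["copy1"]), 1.89)
  expect_equal(w$subset_max, 31.79)
  expect_equal(sum(w$fraction), 1)
  expect_equal(unname(subset_weights(c(a = 7))$percent), 100)
  expect_error(subset_weights(numeric(0)), "at least one")
})

test_that("weighted totals are linear with published extremes", {
  w <- subset_weights(c(40, 9, 1, 1, 1, 1))
  expect_equal(as.numeric(weighted_total(c(40, 9, 1, 1, 1, 1), w)), 31.79)
  expect_equal(as.numeric(weighted_total(rep(0, 6), w)), 0)
  # independent arithmetic: (20*40 + 9*9 + 4) / 53
  expect_equal(as.numeric(weighted_total(c(20, 9, 1, 1, 1, 1), w)),
               round((20 * 40 + 9 * 9 + 4) / 53 + 1e-12, 2))
  expect_equal(as.numeric(weighted_total(c(20, 9, 1, 1, 1, 1), w)), 16.70)
  part <- weighted_total(c(20, NA, 1, 1, 1, 1), w)
  expect_true(attr(part, "partial"))
})

test_that("the scaled neglect cut-off reproduces the published boundary", {
  diag <- bit_diagnosis(28.09, 31.79)
  expect_equal(as.character(diag), "N+")
  expect_equal(attr(diag, "cutoff"), 28.09)
  expect_equal(as.character(bit_diagnosis(28.10, 31.79)), "N-")
  expect_equal(as.character(bit_diagnosis(0, 31.79)), "N+")
  # proportional threshold is 88.36% of the maximum
  expect_equal(neglectscore:::round_half_up(129 / 146 * 100, 2), 88.36)
})

test_that("severity bands scale from the full battery cut-offs", {
  s <- net_severity(20, 60)
  expect_equal(attr(s, "cutoffs"), c(25.41, 47.65, 58.59))
  expect_equal(as.character(net_severity(25.41, 60)), "severe")
  expect_equal(as.character(net_severity(25.42, 60)), "strong")
  expect_equal(as.character(net_severity(47.65, 60)), "strong")
  expect_equal(as.character(net_severity(47.66, 60)), "mild")
  expect_equal(as.character(net_severity(58.59, 60)), "mild")
  expect_equal(as.character(net_severity(60, 60)), "none")
  # the full 170-point battery maps to its own cut-offs
  expect_equal(attr(net_severity(100, 170), "cutoffs"), c(72, 135, 166))
  # percentage renderings of the full-battery boundaries
  expect_equal(neglectscore:::round_half_up(72 / 170 * 100, 2), 42.35)
})

test_that("band classification is exhaustive and mutually exclusive", {
  grid <- seq(0, 60, by = 0.5)
  bands <- vapply(grid, function(x) as.character(net_severity(x, 60)),
                  character(1))
  expect_true(all(bands %in% c("severe", "strong", "mild", "none")))
  expect_true(all(diff(match(bands,
                             c("severe", "strong", "mild", "none"))) >= 0))
})

test_that("the laterality index matches direct arithmetic", {
  expect_equal(laterality_index(10, 10), 0)
  expect_equal(laterality_index(0, 20), 1)
  expect_equal(laterality_index(20, 0), -1)
  expect_equal(laterality_index(18, 10), (10 - 18) / 28)
  expect_equal(round(laterality_index(18, 10), 4), -0.2857)
  expect_true(is.na(laterality_index(0, 0)))
})

test_that("battery rows recompute from their components", {
  specs <- lapply(c("line_crossing", "letter_cancellation",
                    "star_cancellation", "line_bisection", "copy_star",
                    "copy_diamond"), function(st)
    score_synthetic(st, severity = 0.25, seed = 901)$scored$result)
  names(specs) <- c("line_crossing", "letter_cancellation",
                    "star_cancellation", "line_bisection", "copy_star",
                    "copy_diamond")
  row <- as_report_row(specs, "P901")
  expect_equal(row$LineC, row$LineC_LS + row$LineC_RS)
  expect_equal(row$LetC, row$LetC_LS + row$LetC_RS)
  expect_equal(row$CopyStar_NET,
               row$CopyStar_S + row$CopyStar_D + row$CopyStar_A)
  w <- subset_weights(c(36, 40, 54, 9, 1, 1))
  raws <- c(row$LineC, row$LetC, row$StarC, row$LineB, row$CopyStar,
            row$CopyDiamond)
  expect_equal(row$BIT_weighted_total,
               as.numeric(weighted_total(raws, w)))
  svs <- c(row$LineC_SV, row$LetC_SV, row$StarC_SV, row$LineB_SV,
           row$CopyStar_SV, row$CopyDiamond_SV)
  expect_equal(row$NET_SV_total, sum(svs))
  expect_equal(row$NET_severity,
               as.character(net_severity(sum(svs), 60)))
})
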