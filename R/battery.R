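# Round half away from zero at `digits` decimals (commercial rounding, as
# used for all reported totals; R's round() would round half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Standard-value conversion tables
#'
#' Maps raw subtest scores to standard values in 0--10 (steps of 0.5). The
#' letter-cancellation table implements the published rule: raw 0--1 maps
#' to 0, raw 2--3 to 0.5, and so on in 0.5 steps up to 10 for all 40
#' targets. For the other subtests the official tables are not in the
#' public domain; the defaults use a proportional mapping
#' `floor(raw / raw_max * 20) / 2` (monotone, 0 at 0, 10 at the maximum)
#' and are shipped as editable configuration -- owners of the test manual
#' should substitute the official tables via the `values` argument.
#'
#' @param subtest_id Subtest identifier.
#' @param raw_max Maximum raw score (defaults per shipped layout: 36
#'   scoreable lines, 40 letters, 54 stars, 9 bisection points, 3 per
#'   copy figure).
#' @param values Optional explicit vector of standard values for raw
#'   scores `0:raw_max`.
#' @return List of class `sv_table` with `subtest_id`, `raw_max`, `sv`
#'   (vector indexed by raw score + 1).
#' @export
sv_table <- function(subtest_id, raw_max = NULL, values = NULL) {
  subtest_id <- match_subtest(subtest_id)
  defaults <- c(line_crossing = 36, letter_cancellation = 40,
                star_cancellation = 54, line_bisection = 9,
                copy_star = 3, copy_diamond = 3)
  if (is.null(raw_max)) raw_max <- defaults[[subtest_id]]
  raw <- 0:raw_max
  if (is.null(values)) {
    values <- if (subtest_id == "letter_cancellation") {
      floor(raw / 2) * 0.5
    } else {
      floor(raw / raw_max * 20) / 2
    }
  }
  stopifnot(length(values) == raw_max + 1,
            all(diff(values) >= 0),
            all(values >= 0), all(values <= 10),
            values[raw_max + 1] == 10 || subtest_id == "letter_cancellation")
  stopifnot(all(values * 2 == floor(values * 2)))
  structure(list(subtest_id = subtest_id, raw_max = raw_max, sv = values),
            class = "sv_table")
}

#' @export
print.sv_table <- function(x, ...) {
  cat(sprintf("<sv_table %s: raw 0..%d -> SV %s .. %s>\n", x$subtest_id,
              x$raw_max, x$sv[1], x$sv[x$raw_max + 1]))
  invisible(x)
}

#' Standard-value lookup
#'
#' @param raw Raw score, `0 <= raw <= raw_max`.
#' @param table An [sv_table()].
#' @return Standard value in 0--10 (steps of 0.5).
#' @export
sv_lookup <- function(raw, table) {
  stopifnot(inherits(table, "sv_table"))
  if (any(raw < 0 | raw > table$raw_max | raw != floor(raw)))
    stop("raw score out of range 0..", table$raw_max)
  table$sv[raw + 1]
}

#' Subtest weights from maximum raw scores
#'
#' The battery's incidental weighting: each subtest's weight is its
#' maximum possible raw score divided by the summed maxima of the subtests
#' in use. For the classic subset with maxima {40, 9, 1, 1, 1, 1} this
#' yields 75.47% (letter cancellation), 16.98% (line bisection) and 1.89%
#' for each copying/drawing subtest.
#'
#' @param maxima Named numeric vector of per-subtest maximum raw scores.
#' @return List of class `weight_config`: `maxima`, `fraction`
#'   (weights summing to 1), `percent` (rounded to 2 decimals),
#'   `subset_max` (maximum weighted total).
#' @export
subset_weights <- function(maxima) {
  if (length(maxima) == 0) stop("need at least one subtest maximum")
  stopifnot(all(maxima > 0))
  fraction <- maxima / sum(maxima)
  subset_max <- round_half_up(sum(maxima * fraction), 2)
  structure(list(maxima = maxima, fraction = fraction,
                 percent = round_half_up(100 * fraction, 2),
                 subset_max = subset_max),
            class = "weight_config")
}

#' @export
print.weight_config <- function(x, ...) {
  cat("<weight_config>\n")
  nm <- names(x$maxima)
  if (is.null(nm)) nm <- paste0("subtest", seq_along(x$maxima))
  for (i in seq_along(x$maxima))
    cat(sprintf("  %s: max %g, weight %.2f%%\n", nm[i], x$maxima[i],
                x$percent[i]))
  cat(sprintf("  maximum weighted total: %.2f\n", x$subset_max))
  invisible(x)
}

#' Weighted battery total
#'
#' Sum of raw scores times their weight fractions, reported to 2 decimals.
#' With the classic subset maxima {40, 9, 1, 1, 1, 1} a perfect protocol
#' scores 31.79 points.
#'
#' @param raw Named numeric vector of raw scores, one per weighted subtest
#'   (`NA` allowed; the result is then flagged partial).
#' @param weights A [subset_weights()] result.
#' @return Numeric weighted total (attribute `partial` = TRUE when any
#'   subtest was missing).
#' @export
weighted_total <- function(raw, weights) {
  stopifnot(inherits(weights, "weight_config"),
            length(raw) == length(weights$fraction))
  miss <- is.na(raw)
  tot <- round_half_up(sum(raw[!miss] * weights$fraction[!miss]), 2)
  attr(tot, "partial") <- any(miss)
  tot
}

#' Diagnosis configuration
#'
#' Published cut-offs: the full conventional battery has a maximum of 146
#' raw points with a neglect cut-off at 129 or less; the standard-value
#' battery has a maximum of 170 points with severity cut-offs at 72
#' (severe), 135 (strong) and 166 (mild).
#'
#' @export
diagnosis_config <- function(bit_full_cutoff = 129, bit_full_max = 146,
                             net_full_cutoffs = c(72, 135, 166),
                             net_full_max = 170) {
  stopifnot(all(diff(net_full_cutoffs) > 0),
            all(net_full_cutoffs < net_full_max),
            bit_full_cutoff < bit_full_max)
  structure(list(bit_full_cutoff = bit_full_cutoff,
                 bit_full_max = bit_full_max,
                 net_full_cutoffs = net_full_cutoffs,
                 net_full_max = net_full_max),
            class = "diagnosis_config")
}

#' Binary neglect diagnosis from the weighted total
#'
#' Scales the full-battery cut-off proportionally to the subset in use
#' (cutoff = subset maximum x 129/146, 2 decimals) and classifies totals
#' at or below it as neglect-positive. For the classic subset maximum of
#' 31.79 points the scaled cut-off is 28.09.
#'
#' @param total Weighted total from [weighted_total()].
#' @param subset_max Maximum weighted total of the subset in use.
#' @param config A [diagnosis_config()].
#' @return `"N+"` or `"N-"` (attribute `cutoff` holds the scaled value).
#' @export
bit_diagnosis <- function(total, subset_max, config = diagnosis_config()) {
  cutoff <- round_half_up(subset_max * config$bit_full_cutoff /
                            config$bit_full_max, 2)
  stopifnot(total >= 0, total <= subset_max + 1e-9)
  out <- if (total <= cutoff) "N+" else "N-"
  attr(out, "cutoff") <- cutoff
  out
}

#' Neglect severity from the standard-value total
#'
#' Scales the full-battery severity cut-offs (72/135/166 of 170)
#' proportionally to the subset's maximum standard-value total and bands
#' the score: severe, strong, mild, or none. For a six-subtest battery
#' (maximum 60) the scaled bands are 25.41 / 47.65 / 58.59.
#'
#' @param sv_total Sum of subtest standard values.
#' @param subset_sv_max Maximum possible standard-value total of the
#'   subset.
#' @param config A [diagnosis_config()].
#' @return One of `"severe"`, `"strong"`, `"mild"`, `"none"` (attribute
#'   `cutoffs` holds the scaled band boundaries).
#' @export
net_severity <- function(sv_total, subset_sv_max,
                         config = diagnosis_config()) {
  cuts <- round_half_up(config$net_full_cutoffs / config$net_full_max *
                          subset_sv_max, 2)
  stopifnot(sv_total >= 0, sv_total <= subset_sv_max + 1e-9)
  out <- if (sv_total <= cuts[1]) "severe"
         else if (sv_total <= cuts[2]) "strong"
         else if (sv_total <= cuts[3]) "mild"
         else "none"
  attr(out, "cutoffs") <- cuts
  out
}

#' Laterality index of cancellation counts
#'
#' Signed omission asymmetry `(R - L) / (R + L)` in -1..1; positive values
#' mean rightward bias (left-sided omissions, the typical neglect
#' pattern). Undefined when no target was crossed.
#'
#' @param left,right Crossed-target counts per side.
#' @return Numeric in -1..1, or `NA` when both counts are zero.
#' @export
laterality_index <- function(left, right) {
  stopifnot(left >= 0, right >= 0)
  if (left + right == 0) return(NA_real_)
  (right - left) / (right + left)
}
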