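#' Detect crossed-out targets on a cancellation sheet
#'
#' Scores each printed target by the fraction of its square neighborhood
#' window covered by patient ink; a target counts as crossed when that
#' fraction reaches the per-subtest detection threshold. Windowed coverage
#' makes multiple strokes or zigzags through one target count once, and is
#' monotone in ink: adding strokes can never un-cross a target.
#'
#' @param ink An `ink_mask` from [extract_ink()].
#' @param template The sheet's `layout_template` (must carry targets).
#' @param config A [pipeline_config()].
#' @return A data frame of target records: `id`, `x`, `y`, `side`,
#'   `excluded`, `ink_score` (window coverage fraction) and `crossed`.
#' @export
detect_crossings <- function(ink, template, config = pipeline_config()) {
  stopifnot(!is.null(template$targets))
  subtest <- match_subtest(template$subtest_id)
  hw <- config$window_halfwidth[[subtest]]
  thr <- config$detect_threshold[[subtest]]
  t <- template$targets
  h <- nrow(ink); w <- ncol(ink)
  score <- numeric(nrow(t))
  for (i in seq_len(nrow(t))) {
    r1 <- max(1L, as.integer(t$y[i] - hw)); r2 <- min(h, as.integer(t$y[i] + hw))
    c1 <- max(1L, as.integer(t$x[i] - hw)); c2 <- min(w, as.integer(t$x[i] + hw))
    win <- ink[r1:r2, c1:c2]
    score[i] <- sum(win) / length(win)
  }
  data.frame(id = t$id, x = t$x, y = t$y, side = t$side,
             excluded = t$excluded, ink_score = score,
             crossed = score >= thr, stringsAsFactors = FALSE)
}

#' Score a cancellation subtest
#'
#' Counts crossed targets split by printed side. Targets in the middle
#' column and targets flagged as excluded (the pre-crossed example stars in
#' the centre of the star-cancellation sheet) never contribute. The total
#' is converted to a standard value by table lookup.
#'
#' @param records Target records from [detect_crossings()].
#' @param template The sheet's `layout_template` (defines the expected
#'   target set).
#' @param sv_table Standard-value table; defaults to the subtest's
#'   [sv_table()].
#' @return List of class `cancellation_result` with `subtest_id`,
#'   `left_count`, `right_count`, `total`, `standard_value` and the
#'   per-target `records`.
#' @export
score_cancellation <- function(records, template, sv_table = NULL) {
  subtest <- match_subtest(template$subtest_id)
  exp_ids <- template$targets$id
  if (!setequal(records$id, exp_ids) || nrow(records) != length(exp_ids))
    stop("records do not cover the template's target set")
  if (is.null(sv_table)) sv_table <- sv_table(subtest)
  scoreable <- !records$excluded & records$side != "M"
  ls <- sum(records$crossed & scoreable & records$side == "L")
  rs <- sum(records$crossed & scoreable & records$side == "R")
  total <- ls + rs
  structure(list(subtest_id = subtest,
                 left_count = ls, right_count = rs, total = total,
                 standard_value = sv_lookup(total, sv_table),
                 records = records),
            class = "cancellation_result")
}

#' @export
print.cancellation_result <- function(x, ...) {
  cat(sprintf("<%s: L %d + R %d = %d crossed, SV %.1f>\n",
              x$subtest_id, x$left_count, x$right_count, x$total,
              x$standard_value))
  invisible(x)
}
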