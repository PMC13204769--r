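# Internal: cluster patient ink crossing a bisection line's band.
# Returns the ink-weighted x-centroids of clusters separated by more than
# the merge gap, largest clusters first retained if above the minimum size.
.bisection_clusters <- function(ink, line, config) {
  band <- config$bisection_band
  h <- nrow(ink); w <- ncol(ink)
  y0 <- (line$y1 + line$y2) / 2
  r1 <- max(1L, as.integer(y0 - band)); r2 <- min(h, as.integer(y0 + band))
  c1 <- max(1L, as.integer(line$x1 - 20)); c2 <- min(w, as.integer(line$x2 + 20))
  sub <- ink[r1:r2, c1:c2, drop = FALSE]
  colcnt <- colSums(sub)
  xs <- which(colcnt > 0)
  if (length(xs) == 0) return(list(centers = numeric(0), sizes = integer(0)))
  breaks <- which(diff(xs) > config$bisection_merge_gap)
  grp <- cumsum(c(1L, as.integer(diff(xs) > config$bisection_merge_gap)))
  centers <- numeric(0); sizes <- integer(0)
  for (g in unique(grp)) {
    cols <- xs[grp == g]
    n <- sum(colcnt[cols])
    if (n < config$bisection_min_px) next
    centers <- c(centers, sum((cols + c1 - 1) * colcnt[cols]) / n)
    sizes <- c(sizes, n)
  }
  list(centers = centers, sizes = sizes)
}

#' Locate the patient's bisection mark on one line
#'
#' Finds patient ink crossing the horizontal band around the printed line
#' and returns the ink-weighted x-centroid of the mark. Ink clusters closer
#' than the configured merge gap are treated as one mark; two or more
#' separated clusters mean the sheet violates the single-midpoint rule.
#'
#' @param ink An `ink_mask`.
#' @param line One row of the template's `bisection_lines`.
#' @param config A [pipeline_config()].
#' @return The mark's x-coordinate (canonical px).
#' @section Errors: Raises a classed error `neglectscore_no_mark` when no
#'   candidate ink is found, and `neglectscore_multiple_marks` when two or
#'   more separated candidates exist (such sheets are flagged for manual
#'   review rather than scored).
#' @export
detect_bisection_mark <- function(ink, line, config = pipeline_config()) {
  cand <- .bisection_clusters(ink, line, config)
  if (length(cand$centers) == 0) {
    stop(structure(class = c("neglectscore_no_mark", "error", "condition"),
                   list(message = sprintf("no bisection mark on line %s",
                                          line$label),
                        call = sys.call())))
  }
  if (length(cand$centers) >= 2) {
    stop(structure(class = c("neglectscore_multiple_marks", "error",
                             "condition"),
                   list(message = sprintf(
                     "%d separated marks on line %s", length(cand$centers),
                     line$label), call = sys.call())))
  }
  cand$centers[1]
}

#' Score one bisection line
#'
#' Maps the signed deviation of the detected mark from the true midpoint
#' through nested zone bands: 3 points in the innermost band, then 2, 1,
#' and 0 beyond the outermost band. Band widths are fractions of the
#' half-line length (inclusive inner boundaries). Direction is `L` for
#' leftward deviations, `R` for rightward, `center` at exactly zero.
#'
#' @param mark_x Detected mark x-position (canonical px).
#' @param line One row of the template's `bisection_lines`.
#' @param zones Increasing band fractions (defaults from `config`).
#' @param config A [pipeline_config()].
#' @return List of class `bisection_line_result`: `label`, `mark_x`,
#'   `deviation` (signed px, negative = left), `points`, `direction`.
#' @export
score_line <- function(mark_x, line, zones = NULL,
                       config = pipeline_config()) {
  if (is.null(zones)) zones <- config$zone_fractions
  stopifnot(length(zones) == 3, all(diff(zones) > 0))
  mid <- (line$x1 + line$x2) / 2
  half <- (line$x2 - line$x1) / 2
  dev <- mark_x - mid
  adev <- abs(dev)
  points <- if (adev <= zones[1] * half) 3L
            else if (adev <= zones[2] * half) 2L
            else if (adev <= zones[3] * half) 1L
            else 0L
  direction <- if (dev < 0) "L" else if (dev > 0) "R" else "center"
  structure(list(label = line$label, mark_x = mark_x, deviation = dev,
                 points = points, direction = direction),
            class = "bisection_line_result")
}

#' Score the line-bisection subtest
#'
#' Sums the three per-line point scores (top, middle, bottom; maximum 9)
#' and converts the total to a standard value. Lines that could not be
#' resolved (no mark, or multiple marks) enter as `NA` and mark the result
#' for manual review.
#'
#' @param line_results List of three `bisection_line_result` objects (or
#'   `NA` for unresolved lines), in T/M/B order.
#' @param sv_table Standard-value table; defaults to the subtest default.
#' @return List of class `bisection_result` with `lines`, `total`,
#'   `standard_value`, `needs_review`.
#' @export
score_bisection <- function(line_results, sv_table = NULL) {
  if (is.null(sv_table)) sv_table <- sv_table("line_bisection")
  ok <- vapply(line_results, function(l) inherits(l, "bisection_line_result"),
               logical(1))
  pts <- vapply(seq_along(line_results), function(i)
    if (ok[i]) line_results[[i]]$points else NA_integer_, integer(1))
  total <- if (all(ok)) sum(pts) else NA_integer_
  sv <- if (all(ok)) sv_lookup(total, sv_table) else NA_real_
  structure(list(lines = line_results, points = pts, total = total,
                 standard_value = sv, needs_review = !all(ok)),
            class = "bisection_result")
}

#' @export
print.bisection_result <- function(x, ...) {
  lab <- vapply(seq_along(x$lines), function(i) {
    l <- x$lines[[i]]
    if (!inherits(l, "bisection_line_result")) return("<unresolved>")
    dir <- if (l$direction == "center") "" else l$direction
    sprintf("%s=%d%s", l$label, l$points, dir)
  }, character(1))
  cat(sprintf("<line_bisection: %s, total %s, SV %s%s>\n",
              paste(lab, collapse = " "),
              ifelse(is.na(x$total), "NA", x$total),
              ifelse(is.na(x$standard_value), "NA", x$standard_value),
              if (x$needs_review) ", needs review" else ""))
  invisible(x)
}
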