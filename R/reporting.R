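#' Report column schema
#'
#' The fixed, ordered CSV column set of a battery report row: per-subtest
#' left/right counts, totals and standard values, per-line bisection
#' scores, the three-part copy scores with plain and hierarchical sums,
#' and the battery-level weighted total, standard-value total and
#' diagnosis columns.
#'
#' @return Character vector of column names.
#' @export
report_columns <- function() {
  c("patient_id",
    "LineC_LS", "LineC_RS", "LineC", "LineC_SV",
    "LetC_LS", "LetC_RS", "LetC", "LetC_SV",
    "StarC_LS", "StarC_RS", "StarC", "StarC_SV",
    "LineB_T", "LineB_M", "LineB_B", "LineB", "LineB_SV",
    "CopyStar_S", "CopyStar_D", "CopyStar_A", "CopyStar_NET", "CopyStar",
    "CopyStar_SV",
    "CopyDiamond_S", "CopyDiamond_D", "CopyDiamond_A", "CopyDiamond_NET",
    "CopyDiamond", "CopyDiamond_SV", "CopyD_NET_hierarchical",
    "BIT_weighted_total", "BIT_diagnosis", "NET_SV_total", "NET_severity")
}

# BIT-style maximum raw scores of the shipped six-subtest battery
.battery_maxima <- c(line_crossing = 36, letter_cancellation = 40,
                     star_cancellation = 54, line_bisection = 9,
                     copy_star = 1, copy_diamond = 1)

.fmt_line <- function(res, i) {
  l <- res$lines[[i]]
  if (!inherits(l, "bisection_line_result")) return(NA_character_)
  dir <- if (l$direction == "center") "" else l$direction
  paste0(l$points, dir)
}

#' Assemble one battery-report row
#'
#' Converts per-subtest result objects into the fixed CSV schema. Missing
#' or unresolved subtests stay `NA` (serialized as empty cells). When all
#' six subtests are present, the battery totals are added: the weighted
#' raw total with its neglect cut-off (binary scores feed the copy
#' subtests) and the standard-value total with its severity band.
#'
#' @param results Named list keyed by subtest id holding
#'   `cancellation_result`, `bisection_result` and `copy_score` objects
#'   (entries may be `NULL`).
#' @param patient_id Identifier for the row.
#' @return One-row data frame with [report_columns()].
#' @export
as_report_row <- function(results, patient_id = "P001") {
  row <- as.list(stats::setNames(rep(NA, length(report_columns())),
                                 report_columns()))
  row$patient_id <- patient_id
  put_canc <- function(prefix, res) {
    if (is.null(res)) return()
    row[[paste0(prefix, "_LS")]] <<- res$left_count
    row[[paste0(prefix, "_RS")]] <<- res$right_count
    row[[prefix]] <<- res$total
    row[[paste0(prefix, "_SV")]] <<- res$standard_value
  }
  put_canc("LineC", results$line_crossing)
  put_canc("LetC", results$letter_cancellation)
  put_canc("StarC", results$star_cancellation)
  if (!is.null(results$line_bisection)) {
    res <- results$line_bisection
    row$LineB_T <- .fmt_line(res, 1)
    row$LineB_M <- .fmt_line(res, 2)
    row$LineB_B <- .fmt_line(res, 3)
    row$LineB <- res$total
    row$LineB_SV <- res$standard_value
  }
  put_copy <- function(prefix, res) {
    if (is.null(res)) return()
    row[[paste0(prefix, "_S")]] <<- res$shape
    row[[paste0(prefix, "_D")]] <<- res$detail
    row[[paste0(prefix, "_A")]] <<- res$arrangement
    row[[paste0(prefix, "_NET")]] <<- res$net_sum
    row[[prefix]] <<- res$bit_binary
    row[[paste0(prefix, "_SV")]] <<- res$standard_value
  }
  put_copy("CopyStar", results$copy_star)
  put_copy("CopyDiamond", results$copy_diamond)
  if (!is.null(results$copy_diamond))
    row$CopyD_NET_hierarchical <- results$copy_diamond$net_hierarchical

  raws <- c(line_crossing = if (!is.null(results$line_crossing))
              results$line_crossing$total else NA,
            letter_cancellation = if (!is.null(results$letter_cancellation))
              results$letter_cancellation$total else NA,
            star_cancellation = if (!is.null(results$star_cancellation))
              results$star_cancellation$total else NA,
            line_bisection = if (!is.null(results$line_bisection))
              results$line_bisection$total else NA,
            copy_star = if (!is.null(results$copy_star))
              results$copy_star$bit_binary else NA,
            copy_diamond = if (!is.null(results$copy_diamond))
              results$copy_diamond$bit_binary else NA)
  svs <- c(if (!is.null(results$line_crossing))
             results$line_crossing$standard_value else NA,
           if (!is.null(results$letter_cancellation))
             results$letter_cancellation$standard_value else NA,
           if (!is.null(results$star_cancellation))
             results$star_cancellation$standard_value else NA,
           if (!is.null(results$line_bisection))
             results$line_bisection$standard_value else NA,
           if (!is.null(results$copy_star))
             results$copy_star$standard_value else NA,
           if (!is.null(results$copy_diamond))
             results$copy_diamond$standard_value else NA)
  if (!anyNA(raws)) {
    w <- subset_weights(.battery_maxima)
    tot <- weighted_total(raws, w)
    row$BIT_weighted_total <- as.numeric(tot)
    row$BIT_diagnosis <- as.character(bit_diagnosis(as.numeric(tot),
                                                    w$subset_max))
  }
  if (!anyNA(svs)) {
    row$NET_SV_total <- sum(svs)
    row$NET_severity <- as.character(net_severity(sum(svs),
                                                  10 * length(svs)))
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Score one sheet end to end
#'
#' Normalizes the scan, isolates patient ink, runs quality control, and
#' dispatches to the subtest's scorer.
#'
#' @param x File path, page matrix or `sheet_image`.
#' @param template The sheet's `layout_template`.
#' @param config A [pipeline_config()].
#' @return List of class `scored_sheet`: `subtest_id`, `result` (or `NULL`
#'   on unresolved bisection), `qc`, `sheet`, `ink`.
#' @export
score_sheet <- function(x, template, config = pipeline_config()) {
  sheet <- load_and_normalize(x, template, config)
  ink <- extract_ink(sheet, template, config)
  qc <- run_qc(sheet, ink, template, config)
  subtest <- match_subtest(template$subtest_id)
  result <- NULL
  if (!is.null(template$targets)) {
    rec <- detect_crossings(ink, template, config)
    result <- score_cancellation(rec, template)
  } else if (!is.null(template$bisection_lines)) {
    lines <- lapply(seq_len(3), function(i) {
      line <- template$bisection_lines[i, ]
      tryCatch(score_line(detect_bisection_mark(ink, line, config), line,
                          config = config),
               error = function(e) NA)
    })
    result <- score_bisection(lines)
  } else {
    figure <- if (subtest == "copy_star") "star" else "diamond"
    drawing <- extract_drawing(ink, template$drawing_region, figure, config)
    arch <- fit_archetype(drawing)
    result <- if (figure == "star") {
      score_star(drawing, drawing, arch, config = config)
    } else {
      score_diamond(drawing, drawing, arch, config = config)
    }
  }
  structure(list(subtest_id = subtest, result = result, qc = qc,
                 sheet = sheet, ink = ink),
            class = "scored_sheet")
}

#' Score a single sheet and print its value tuple
#'
#' Prints the per-subtest value tuple in the conventional order:
#' cancellation `(LS, RS, total, SV)`; bisection
#' `(T, M, B, total, SV)` with per-line entries like `"2L"`; star copy
#' `(S, D, A, NET, binary, SV)`; diamond copy
#' `(S, D, A, NET, binary, SV, NET_hierarchical)`.
#'
#' @param subtest Subtest identifier (must match the template).
#' @param file Scan path (or matrix / `sheet_image`).
#' @param template A `layout_template` (defaults to the shipped layout).
#' @param config A [pipeline_config()].
#' @param visualize Optional path to save an overlay PNG.
#' @return The `scored_sheet`, invisibly.
#' @export
run_single <- function(subtest, file, template = NULL,
                       config = pipeline_config(), visualize = NULL) {
  subtest <- match_subtest(subtest)
  if (is.null(template)) template <- default_layout(subtest, config)
  if (template$subtest_id != subtest)
    stop("template is for ", template$subtest_id, ", not ", subtest)
  sc <- score_sheet(file, template, config)
  res <- sc$result
  tup <- if (inherits(res, "cancellation_result")) {
    c(res$left_count, res$right_count, res$total, res$standard_value)
  } else if (inherits(res, "bisection_result")) {
    c(.fmt_line(res, 1), .fmt_line(res, 2), .fmt_line(res, 3),
      res$total, res$standard_value)
  } else if (res$figure == "star") {
    c(res$shape, res$detail, res$arrangement, res$net_sum, res$bit_binary,
      res$standard_value)
  } else {
    c(res$shape, res$detail, res$arrangement, res$net_sum, res$bit_binary,
      res$standard_value, res$net_hierarchical)
  }
  cat("(", paste(tup, collapse = ", "), ")\n", sep = "")
  if (!is.null(visualize)) {
    ov <- render_overlay(sc, template = template)
    write_overlay(ov, visualize)
  }
  invisible(sc)
}

#' Batch-score a directory of scans
#'
#' Reads `manifest.csv` (columns `patient_id`, `subtest`, `file`) from the
#' input directory, scores every sheet, assembles one report row per
#' patient, and writes the CSV. Sheets that fail or need manual review
#' (e.g. multiple bisection marks) leave their cells empty and are
#' recorded in the log; the batch continues.
#'
#' @param input_dir Directory containing the scans and `manifest.csv`.
#' @param templates Named list of layout templates per subtest (defaults
#'   to `layout_<subtest>.yaml` files in `input_dir`, then to the shipped
#'   layouts).
#' @param config A [pipeline_config()].
#' @param out_csv Output CSV path (default `scores.csv` in `input_dir`).
#' @param visualize If TRUE, writes `<file>_overlay.png` next to each scan.
#' @return List of class `batch_result`: `report` (data frame), `log`
#'   (per-sheet status/flags), `exit_code` (0 clean, 2 review flags
#'   present, 1 hard failure).
#' @export
run_batch <- function(input_dir, templates = NULL,
                      config = pipeline_config(), out_csv = NULL,
                      visualize = FALSE) {
  manifest_path <- file.path(input_dir, "manifest.csv")
  if (!file.exists(manifest_path)) stop("manifest.csv not found in ",
                                        input_dir)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  stopifnot(all(c("patient_id", "subtest", "file") %in% names(manifest)))
  if (is.null(out_csv)) out_csv <- file.path(input_dir, "scores.csv")

  get_template <- function(subtest) {
    if (!is.null(templates) && !is.null(templates[[subtest]]))
      return(templates[[subtest]])
    ly <- file.path(input_dir, paste0("layout_", subtest, ".yaml"))
    if (file.exists(ly)) return(read_layout(ly))
    default_layout(subtest, config)
  }

  patients <- unique(manifest$patient_id)
  log <- list()
  rows <- list()
  had_flag <- FALSE; had_fail <- FALSE
  for (p in patients) {
    sub <- manifest[manifest$patient_id == p, ]
    results <- list()
    for (i in seq_len(nrow(sub))) {
      st <- match_subtest(sub$subtest[i])
      tmpl <- get_template(st)
      path <- file.path(input_dir, sub$file[i])
      sc <- tryCatch(score_sheet(path, tmpl, config),
                     error = function(e) e)
      if (inherits(sc, "error")) {
        had_fail <- TRUE
        log[[length(log) + 1L]] <- data.frame(
          patient_id = p, subtest = st, file = sub$file[i],
          status = "failed", flags = conditionMessage(sc),
          stringsAsFactors = FALSE)
        next
      }
      flags <- sc$qc$flags
      review <- isTRUE(sc$result$needs_review)
      if (length(flags) || review) had_flag <- TRUE
      status <- if (review) "review" else if (length(flags)) "flagged"
                else "ok"
      log[[length(log) + 1L]] <- data.frame(
        patient_id = p, subtest = st, file = sub$file[i], status = status,
        flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
      if (review && inherits(sc$result, "bisection_result")) {
        results[[st]] <- sc$result  # partial row; totals stay NA
      } else {
        results[[st]] <- sc$result
      }
      if (visualize) {
        ov <- render_overlay(sc, template = tmpl)
        write_overlay(ov, file.path(input_dir,
                                    paste0(sub$file[i], "_overlay.png")))
      }
    }
    rows[[p]] <- as_report_row(results, patient_id = p)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(
      rep(list(character(0)), length(report_columns())), report_columns()))
  utils::write.csv(report, out_csv, row.names = FALSE, na = "")
  exit_code <- if (had_fail) 1L else if (had_flag) 2L else 0L
  structure(list(report = report, log = do.call(rbind, log),
                 exit_code = exit_code, out_csv = out_csv),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result: %d patients, exit code %d, CSV %s>\n",
              nrow(x$report), x$exit_code, x$out_csv))
  invisible(x)
}

#' Overlay color conventions
#'
#' Default mark colors for scored-sheet visualisations: crossed targets
#' green, missed targets red, excluded targets yellow; line-crossing
#' markings colored by side (left blue, right red, middle yellow) with
#' target midpoints black (missed) or grey (crossed); bisection zones and
#' endpoints black with the detected point red; copy drawings green with
#' the fitted archetype red.
#'
#' @param ... Named color overrides (any R color).
#' @return Named list of RGB triplets (class `overlay_style`).
#' @export
overlay_style <- function(...) {
  defaults <- list(crossed = "green3", uncrossed = "red", excluded = "yellow",
                   side_L = "blue", side_R = "red", side_M = "yellow",
                   midpoint_crossed = "grey50", midpoint_uncrossed = "black",
                   bisect_guide = "black", bisect_detected = "red",
                   drawing = "green3", archetype = "red")
  st <- utils::modifyList(defaults, list(...))
  structure(lapply(st, function(cl) grDevices::col2rgb(cl)[, 1] / 255),
            class = "overlay_style")
}

.ov_disc <- function(rgb, x, y, r, col) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  rows <- max(1, floor(y - r)):min(h, ceiling(y + r))
  cols <- max(1, floor(x - r)):min(w, ceiling(x + r))
  for (rr in rows) for (cc in cols) {
    if ((rr - y)^2 + (cc - x)^2 <= r^2) rgb[rr, cc, ] <- col
  }
  rgb
}

.ov_seg <- function(rgb, x1, y1, x2, y2, col, width = 2) {
  mask <- draw_segment(blank_page(dim(rgb)[2], dim(rgb)[1]),
                       x1, y1, x2, y2, width = width, intensity = 0)
  hit <- which(mask < 128)
  for (ch in 1:3) {
    plane <- rgb[, , ch]; plane[hit] <- col[ch]; rgb[, , ch] <- plane
  }
  rgb
}

#' Render a scored-sheet overlay
#'
#' Annotates the normalized sheet with the scoring outcome using the
#' conventional colors (see [overlay_style()]).
#'
#' @param scored A `scored_sheet` from [score_sheet()].
#' @param template The sheet's `layout_template`.
#' @param style An [overlay_style()].
#' @return RGB array `[height, width, 3]` in 0..1.
#' @export
render_overlay <- function(scored, template, style = overlay_style()) {
  page <- scored$sheet$pixels / 255
  rgb <- array(rep(page, 3), dim = c(nrow(page), ncol(page), 3))
  res <- scored$result
  if (inherits(res, "cancellation_result")) {
    rec <- res$records
    for (i in seq_len(nrow(rec))) {
      if (template$subtest_id == "line_crossing") {
        mid_col <- if (rec$crossed[i]) style$midpoint_crossed
                   else style$midpoint_uncrossed
        rgb <- .ov_disc(rgb, rec$x[i], rec$y[i], 4, mid_col)
        if (rec$crossed[i]) {
          side_col <- style[[paste0("side_", rec$side[i])]]
          rgb <- .ov_disc(rgb, rec$x[i] + 12, rec$y[i] - 12, 5, side_col)
        }
      } else {
        col <- if (rec$excluded[i]) style$excluded
               else if (rec$crossed[i]) style$crossed else style$uncrossed
        rgb <- .ov_disc(rgb, rec$x[i], rec$y[i], 5, col)
      }
    }
  } else if (inherits(res, "bisection_result")) {
    bl <- template$bisection_lines
    for (i in seq_len(nrow(bl))) {
      mid <- (bl$x1[i] + bl$x2[i]) / 2
      for (xx in c(bl$x1[i], mid, bl$x2[i]))
        rgb <- .ov_disc(rgb, xx, bl$y1[i], 4, style$bisect_guide)
      l <- res$lines[[i]]
      if (inherits(l, "bisection_line_result"))
        rgb <- .ov_disc(rgb, l$mark_x, bl$y1[i], 5, style$bisect_detected)
    }
  } else if (inherits(res, "copy_score")) {
    ink <- which(unclass(scored$ink))
    for (ch in 1:3) {
      plane <- rgb[, , ch]; plane[ink] <- style$drawing[ch]
      rgb[, , ch] <- plane
    }
    arch <- fit_archetype(extract_drawing(scored$ink,
                                          template$drawing_region,
                                          res$figure))
    if (!arch$degenerate) {
      v <- arch$vertices
      n <- nrow(v)
      for (i in seq_len(n)) {
        j <- (i %% n) + 1
        rgb <- .ov_seg(rgb, v[i, 1], v[i, 2], v[j, 1], v[j, 2],
                       style$archetype)
      }
      if (!is.null(arch$midline))
        rgb <- .ov_seg(rgb, arch$midline[1, 1], arch$midline[1, 2],
                       arch$midline[2, 1], arch$midline[2, 2],
                       style$archetype)
    }
  }
  rgb
}

#' @rdname render_overlay
#' @param rgb An overlay array from [render_overlay()].
#' @param path PNG output path.
#' @export
write_overlay <- function(rgb, path) {
  img <- EBImage::Image(aperm(rgb, c(2, 1, 3)), colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}
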