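#' Layout templates for the six subtests
#'
#' A layout template is the registry of everything printed on a test sheet:
#' target positions with side labels (L/M/R) and exclusion flags,
#' bisection-line endpoints, the freehand drawing region, decorative
#' distractors, and the orientation fiducial. The layouts shipped here are
#' an original dialect that reproduces the geometry *class* of the clinical
#' sheets (target grids, three staggered horizontal lines, star/diamond
#' model figures) without copying any published test material. All
#' coordinates are canonical pixels (1-based, x rightward, y downward).
#'
#' @param subtest_id One of `"line_crossing"`, `"letter_cancellation"`,
#'   `"star_cancellation"`, `"line_bisection"`, `"copy_star"`,
#'   `"copy_diamond"`.
#' @param config A [pipeline_config()].
#' @return A list of class `layout_template`.
#' @export
default_layout <- function(subtest_id, config = pipeline_config()) {
  subtest_id <- match_subtest(subtest_id)
  W <- config$canonical_width
  H <- as.integer(round(W * sqrt(2)))
  tmpl <- list(subtest_id = subtest_id,
               canonical_width = W, canonical_height = H,
               targets = NULL, decor = list(),
               bisection_lines = NULL, drawing_region = NULL,
               fiducial = NULL, middle_halfwidth = 80)
  mid_x <- W / 2
  side_of <- function(x) ifelse(abs(x - mid_x) <= tmpl$middle_halfwidth, "M",
                                ifelse(x < mid_x, "L", "R"))
  sc <- W / 1240  # layouts are authored at width 1240 and scale linearly

  if (subtest_id == "line_crossing") {
    xs <- (170 + (0:6) * 150) * sc
    ys <- (420 + (0:5) * 170) * sc
    g <- expand.grid(x = xs, y = ys)
    n <- nrow(g)
    tmpl$targets <- data.frame(
      id = sprintf("LC%02d", seq_len(n)),
      x = g$x, y = g$y,
      side = side_of(g$x),
      excluded = FALSE,
      size = 36 * sc,
      angle = ((seq_len(n) * 47) %% 140) + 20,
      stringsAsFactors = FALSE)
  } else if (subtest_id == "letter_cancellation") {
    rows_y <- (500 + (0:4) * 180) * sc
    cols_x <- (100 + (0:30) * 34) * sc
    grid <- expand.grid(col = seq_along(cols_x), row = seq_along(rows_y))
    grid$x <- cols_x[grid$col]; grid$y <- rows_y[grid$row]
    # fixed deterministic target placement (no RNG side effects): 20
    # targets on each half, scattered by a multiplicative stride,
    # alternating E and R
    left_slots <- which(grid$x < mid_x - tmpl$middle_halfwidth)
    right_slots <- which(grid$x > mid_x + tmpl$middle_halfwidth)
    pick <- function(slots, n) {
      m <- length(slots)
      sort(slots[unique((seq_len(n) * 37L) %% m) + 1L][seq_len(n)])
    }
    tl <- pick(left_slots, 20)
    tr <- pick(right_slots, 20)
    tgt <- c(tl, tr)
    letters_all <- rep("", nrow(grid))
    letters_all[tgt] <- rep(c("E", "R"), 20)
    distract <- setdiff(seq_len(nrow(grid)), tgt)
    pool <- c("A", "B", "C", "D", "F", "H", "K", "L", "N", "T", "U", "V", "Z")
    letters_all[distract] <- pool[(distract %% length(pool)) + 1L]
    tmpl$targets <- data.frame(
      id = sprintf("LT%02d", seq_along(tgt)),
      x = grid$x[tgt], y = grid$y[tgt],
      side = side_of(grid$x[tgt]),
      excluded = FALSE,
      size = 24 * sc,
      letter = letters_all[tgt],
      stringsAsFactors = FALSE)
    tmpl$decor <- list(list(kind = "letters",
                            x = grid$x[distract], y = grid$y[distract],
                            letter = letters_all[distract],
                            height = 24 * sc))
  } else if (subtest_id == "star_cancellation") {
    xs <- (150 + (0:7) * 140) * sc
    ys <- (430 + (0:6) * 180) * sc
    g <- expand.grid(x = xs, y = ys)
    n <- nrow(g)
    ex_row_y <- ys[4]
    excluded <- (g$y == ex_row_y) & (g$x %in% xs[4:5])
    tmpl$targets <- data.frame(
      id = sprintf("SC%02d", seq_len(n)),
      x = g$x, y = g$y,
      side = ifelse(g$x < mid_x, "L", "R"),
      excluded = excluded,
      size = 14 * sc,
      stringsAsFactors = FALSE)
    # distractors midway between target columns: large stars and letters
    dx <- (xs[-length(xs)] + xs[-1]) / 2
    dy <- ys - 90 * sc
    dg <- expand.grid(x = dx, y = dy)
    kind <- rep_len(c("big_star", "letter"), nrow(dg))
    tmpl$decor <- list(list(kind = "big_stars",
                            x = dg$x[kind == "big_star"],
                            y = dg$y[kind == "big_star"], radius = 26 * sc),
                       list(kind = "letters",
                            x = dg$x[kind == "letter"],
                            y = dg$y[kind == "letter"],
                            letter = rep_len(c("H", "T", "N", "U"),
                                             sum(kind == "letter")),
                            height = 20 * sc))
  } else if (subtest_id == "line_bisection") {
    len <- 800 * sc
    tmpl$bisection_lines <- data.frame(
      label = c("T", "M", "B"),
      x1 = c(180, 220, 260) * sc, y1 = c(500, 850, 1200) * sc,
      x2 = c(180, 220, 260) * sc + len, y2 = c(500, 850, 1200) * sc,
      stringsAsFactors = FALSE)
    tmpl$fiducial <- list(type = "arrow_down", x = mid_x, y = 1600 * sc,
                          size = 48 * sc)
  } else {  # copy_star / copy_diamond
    tmpl$drawing_region <- c(x1 = 120, y1 = 600, x2 = 1120, y2 = 1500) * sc
    model_cx <- 250 * sc; model_cy <- 330 * sc
    if (subtest_id == "copy_star") {
      tmpl$decor <- list(list(kind = "model_star", x = model_cx, y = model_cy,
                              radius = 120 * sc, tip_angle = 110))
    } else {
      tmpl$decor <- list(list(kind = "model_diamond", x = model_cx,
                              y = model_cy, half_height = 120 * sc))
    }
  }

  if (!is.null(tmpl$targets)) {
    stopifnot(!anyDuplicated(tmpl$targets$id))
  }
  class(tmpl) <- "layout_template"
  validate_layout(tmpl)
  tmpl
}

#' Validate a layout template
#'
#' Checks the structural invariants: unique target ids, left endpoint left
#' of the right endpoint for every bisection line, exactly three bisection
#' lines for the line-bisection subtest (none otherwise), side labels in
#' {L, M, R}.
#'
#' @param tmpl A `layout_template`.
#' @return The template, invisibly; errors on violation.
#' @export
validate_layout <- function(tmpl) {
  stopifnot(inherits(tmpl, "layout_template"))
  subtest_id <- match_subtest(tmpl$subtest_id)
  if (!is.null(tmpl$targets)) {
    t <- tmpl$targets
    if (anyDuplicated(t$id)) stop("duplicate target ids")
    if (!all(t$side %in% c("L", "M", "R"))) stop("invalid side labels")
    if (!is.logical(t$excluded)) stop("excluded must be logical")
  }
  nlines <- if (is.null(tmpl$bisection_lines)) 0L else nrow(tmpl$bisection_lines)
  if (subtest_id == "line_bisection") {
    if (nlines != 3L) stop("line_bisection layout needs exactly 3 lines")
    if (!all(tmpl$bisection_lines$x1 < tmpl$bisection_lines$x2))
      stop("bisection line endpoints must satisfy x1 < x2")
  } else if (nlines != 0L) {
    stop("only line_bisection layouts carry bisection lines")
  }
  invisible(tmpl)
}

#' Render the printed layer of a layout
#'
#' Draws the blank test sheet exactly as handed to a patient: frame,
#' targets, distractors, bisection lines, model figure and fiducial, but no
#' patient ink. The result is cached per layout so repeated template
#' subtraction is cheap.
#'
#' @param tmpl A `layout_template`.
#' @param config A [pipeline_config()].
#' @return Numeric page matrix (0--255).
#' @export
render_template <- function(tmpl, config = pipeline_config()) {
  key <- .layout_key(tmpl)
  hit <- .template_cache[[key]]
  if (!is.null(hit)) return(hit)
  W <- tmpl$canonical_width; H <- tmpl$canonical_height
  sc <- W / 1240
  page <- blank_page(W, H)
  # page frame (also the main deskew/orientation anchor)
  fr <- c(40, 40, W - 40, H - 40)
  page <- draw_polyline(page, cbind(c(fr[1], fr[3], fr[3], fr[1]),
                                    c(fr[2], fr[2], fr[4], fr[4])),
                        width = 3, intensity = 0, closed = TRUE)
  # heading bar stub (asymmetric: breaks 180-degree page symmetry)
  page <- draw_segment(page, 80 * sc, 120 * sc, 700 * sc, 120 * sc,
                       width = 4, intensity = 0)

  t <- tmpl$targets
  if (!is.null(t)) {
    for (i in seq_len(nrow(t))) {
      if (tmpl$subtest_id == "line_crossing") {
        page <- draw_line_target(page, t$x[i], t$y[i], length = t$size[i],
                                 angle_deg = t$angle[i], stroke = 3 * sc)
      } else if (tmpl$subtest_id == "letter_cancellation") {
        page <- draw_glyph(page, t$letter[i], t$x[i], t$y[i],
                           height = t$size[i], stroke = 2 * sc)
      } else if (tmpl$subtest_id == "star_cancellation") {
        page <- draw_star_glyph(page, t$x[i], t$y[i], t$size[i],
                                tip_angle = 70, stroke = 2 * sc)
      }
    }
  }
  for (d in tmpl$decor) {
    if (d$kind == "letters") {
      for (i in seq_along(d$x)) {
        page <- draw_glyph(page, d$letter[i], d$x[i], d$y[i],
                           height = d$height, stroke = 2 * sc)
      }
    } else if (d$kind == "big_stars") {
      for (i in seq_along(d$x)) {
        page <- draw_star_glyph(page, d$x[i], d$y[i], d$radius,
                                tip_angle = 70, stroke = 2.5 * sc)
      }
    } else if (d$kind == "model_star") {
      v <- star_vertices(d$x, d$y, d$radius, d$tip_angle)
      page <- draw_polyline(page, v, width = 3 * sc, closed = TRUE)
    } else if (d$kind == "model_diamond") {
      v <- diamond_vertices(d$x, d$y, d$half_height)
      page <- draw_polyline(page, v, width = 3 * sc, closed = TRUE)
      page <- draw_segment(page, v[1, 1], v[1, 2], v[3, 1], v[3, 2],
                           width = 3 * sc)
    }
  }
  bl <- tmpl$bisection_lines
  if (!is.null(bl)) {
    for (i in seq_len(nrow(bl))) {
      page <- draw_segment(page, bl$x1[i], bl$y1[i], bl$x2[i], bl$y2[i],
                           width = 4 * sc)
    }
  }
  dr <- tmpl$drawing_region
  if (!is.null(dr)) {
    page <- draw_polyline(page, cbind(c(dr[1], dr[3], dr[3], dr[1]),
                                      c(dr[2], dr[2], dr[4], dr[4])),
                          width = 2, intensity = 120, closed = TRUE)
  }
  if (!is.null(tmpl$fiducial) && tmpl$fiducial$type == "arrow_down") {
    page <- draw_arrow_down(page, tmpl$fiducial$x, tmpl$fiducial$y,
                            size = tmpl$fiducial$size)
  }
  .template_cache[[key]] <- page
  page
}

.template_cache <- new.env(parent = emptyenv())

.layout_key <- function(tmpl) {
  ntab <- if (is.null(tmpl$targets)) 0 else nrow(tmpl$targets)
  csum <- if (ntab) round(sum(tmpl$targets$x + tmpl$targets$y), 3) else 0
  paste(tmpl$subtest_id, tmpl$canonical_width, tmpl$canonical_height,
        ntab, csum, sep = "|")
}

#' @export
print.layout_template <- function(x, ...) {
  cat(sprintf("<layout_template: %s, %d x %d px>\n",
              x$subtest_id, x$canonical_width, x$canonical_height))
  if (!is.null(x$targets)) {
    cat(sprintf("  targets: %d (%d L / %d M / %d R, %d excluded)\n",
                nrow(x$targets), sum(x$targets$side == "L"),
                sum(x$targets$side == "M"), sum(x$targets$side == "R"),
                sum(x$targets$excluded)))
  }
  if (!is.null(x$bisection_lines))
    cat(sprintf("  bisection lines: %d\n", nrow(x$bisection_lines)))
  if (!is.null(x$drawing_region))
    cat(sprintf("  drawing region: [%g, %g] - [%g, %g]\n",
                x$drawing_region[1], x$drawing_region[2],
                x$drawing_region[3], x$drawing_region[4]))
  invisible(x)
}

#' Read / write layout templates
#'
#' Templates serialize to YAML (or JSON via [jsonlite]) documents holding
#' the same fields as the in-memory object; [read_layout()] validates the
#' result against the structural schema.
#'
#' @param tmpl A `layout_template`.
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @export
write_layout <- function(tmpl, path) {
  validate_layout(tmpl)
  obj <- unclass(tmpl)
  for (f in c("targets", "bisection_lines")) {
    if (!is.null(obj[[f]])) obj[[f]] <- as.list(as.data.frame(obj[[f]]))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  for (f in c("targets", "bisection_lines")) {
    if (!is.null(obj[[f]]) && length(obj[[f]]))
      obj[[f]] <- as.data.frame(obj[[f]], stringsAsFactors = FALSE)
    else obj[[f]] <- NULL
  }
  if (!is.null(obj$drawing_region)) obj$drawing_region <- unlist(obj$drawing_region)
  if (!is.null(obj$decor)) {
    obj$decor <- lapply(obj$decor, function(d) {
      for (f in c("x", "y", "letter")) if (!is.null(d[[f]])) d[[f]] <- unlist(d[[f]])
      d
    })
  }
  class(obj) <- "layout_template"
  validate_layout(obj)
  obj
}
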