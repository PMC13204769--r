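#' Scoring criteria for the copied star
#'
#' Thresholds for the three-part evaluation of the copied four-pointed
#' star, in canonical pixels and degrees: radial consistency for the shape
#' point, the eight-corner requirement for the detail point, and the
#' span/alignment/spacing/angle rules for the arrangement point.
#'
#' @param max_radial_deviation Maximum deviation of any corner radius from
#'   its class mean (outer tips and inner vertices separately).
#' @param required_corners Corner count required for the detail point.
#' @param span_difference_max Maximum difference between the horizontal
#'   (left tip to right tip) and vertical (top to bottom tip) spans.
#' @param tip_misalignment_max Maximum offset between opposing tips
#'   perpendicular to their axis.
#' @param intermediate_distance_deviation_max Maximum deviation of
#'   consecutive inner-vertex spacings from their mean.
#' @param angle_deviation_max All vertex angles must lie within this of
#'   the expected angle.
#' @param angle_deviation_strict At least `min_angles_within_strict`
#'   vertex angles must lie within this of the expected angle.
#' @param expected_angle Expected interior wedge angle at each inner
#'   vertex (the angle between the two edges meeting there). Measured at
#'   the inner vertices because only there does the printed 110-degree
#'   value describe a well-formed four-pointed star.
#' @param min_angles_within_strict See above.
#' @return List of class `star_criteria`.
#' @export
star_criteria <- function(max_radial_deviation = 100,
                          required_corners = 8L,
                          span_difference_max = 200,
                          tip_misalignment_max = 200,
                          intermediate_distance_deviation_max = 100,
                          angle_deviation_max = 40,
                          angle_deviation_strict = 30,
                          expected_angle = 110,
                          min_angles_within_strict = 2L) {
  stopifnot(angle_deviation_strict <= angle_deviation_max,
            max_radial_deviation > 0, span_difference_max > 0)
  structure(as.list(environment()), class = "star_criteria")
}

#' Scoring criteria for the copied diamond
#'
#' @param expected_half_angle Expected angle between the vertical midline
#'   and each outer edge (degrees).
#' @param angle_tolerance Tolerated deviation per angle.
#' @param max_violations_allowed The arrangement point survives at most
#'   this many out-of-tolerance angles (the criterion is "zero if at least
#'   two of the four angles exceed the tolerance").
#' @param require_all_outer_edges All four outer edges must be present and
#'   closed for the shape point.
#' @param require_midline The vertical centre line is the detail criterion.
#' @param angle_epsilon Measurement resolution of the fitted angles
#'   (degrees). The tolerance boundary is closed: a deviation within
#'   `angle_epsilon` of the tolerance counts as inside, so sub-resolution
#'   quantization bias cannot flip a borderline angle.
#' @return List of class `diamond_criteria`.
#' @export
diamond_criteria <- function(expected_half_angle = 45,
                             angle_tolerance = 7,
                             max_violations_allowed = 1L,
                             require_all_outer_edges = TRUE,
                             require_midline = TRUE,
                             angle_epsilon = 0.05) {
  stopifnot(angle_tolerance > 0, angle_epsilon >= 0)
  structure(as.list(environment()), class = "diamond_criteria")
}

# circular moving-average smoothing of a 360-bin profile, NA-aware
.circ_smooth <- function(v, halfwidth) {
  n <- length(v)
  idx <- -halfwidth:halfwidth
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- v[((i - 1 + idx) %% n) + 1]
    out[i] <- if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }
  out
}

# circular local extrema with a minimum separation window; NA bins cannot
# host or dominate a peak
.circ_peaks <- function(v, sep, maxima = TRUE) {
  n <- length(v)
  if (!maxima) v <- -v
  peaks <- integer(0)
  half <- max(1L, as.integer(sep / 2))
  for (i in seq_len(n)) {
    if (is.na(v[i])) next
    w <- v[((i - 1 + (-half:half)) %% n) + 1]
    if (v[i] >= max(w, na.rm = TRUE) - 1e-9) peaks <- c(peaks, i)
  }
  if (length(peaks) < 2) return(peaks)
  # collapse plateau runs / peaks closer than sep (circularly)
  keep <- logical(length(peaks))
  ord <- order(-v[peaks])
  taken <- integer(0)
  for (o in ord) {
    p <- peaks[o]
    d <- abs(((taken - p + 180) %% 360) - 180)
    if (all(d >= sep)) { keep[o] <- TRUE; taken <- c(taken, p) }
  }
  sort(peaks[keep])
}

#' Extract the patient's freehand copy and detect its corners
#'
#' Collects patient ink inside the drawing region, computes its centroid,
#' and detects corners on the angular radius profile: outer tips are local
#' maxima of the maximal ink radius as a function of polar angle, inner
#' star vertices are local minima. Corners are classified by radial
#' distance from the centroid (star) or by angular position (diamond) and
#' returned in angular order.
#'
#' @param ink An `ink_mask`.
#' @param region Drawing rectangle `c(x1, y1, x2, y2)` from the template.
#' @param figure `"star"` or `"diamond"`.
#' @param config A [pipeline_config()].
#' @return List of class `corner_set`: `points` (m x 2 ink coordinates),
#'   `corners` (data frame `x`, `y`, `angle`, `radius`, `class`),
#'   `centroid`, `n_corners`.
#' @export
extract_drawing <- function(ink, region, figure = c("star", "diamond"),
                            config = pipeline_config()) {
  figure <- match.arg(figure)
  m <- unclass(ink)
  r1 <- max(1L, as.integer(region[2])); r2 <- min(nrow(m), as.integer(region[4]))
  c1 <- max(1L, as.integer(region[1])); c2 <- min(ncol(m), as.integer(region[3]))
  sub <- m[r1:r2, c1:c2, drop = FALSE]
  idx <- which(sub)
  empty <- structure(list(points = cbind(x = numeric(0), y = numeric(0)),
                          corners = data.frame(x = numeric(0), y = numeric(0),
                                               angle = numeric(0),
                                               radius = numeric(0),
                                               class = character(0)),
                          centroid = c(NA_real_, NA_real_), n_corners = 0L,
                          figure = figure),
                     class = "corner_set")
  if (length(idx) < 30) return(empty)
  ys <- ((idx - 1L) %% nrow(sub)) + r1
  xs <- ((idx - 1L) %/% nrow(sub)) + c1
  cx <- mean(xs); cy <- mean(ys)
  dx <- xs - cx; dy <- ys - cy
  rad <- sqrt(dx^2 + dy^2)
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  bin <- as.integer(ang) + 1L
  rmax <- rep(NA_real_, 360)
  agg <- tapply(rad, bin, max)
  rmax[as.integer(names(agg))] <- agg
  rmin <- rep(NA_real_, 360)
  agg2 <- tapply(rad, bin, min)
  rmin[as.integer(names(agg2))] <- agg2
  sm <- .circ_smooth(rmax, config$corner_smooth_deg %/% 2)

  outer_bins <- .circ_peaks(sm, config$corner_min_sep_deg, maxima = TRUE)
  refine <- function(b, kind) {
    d <- abs(((ang - (b - 0.5) + 180) %% 360) - 180)
    sel <- d <= 4
    if (!any(sel)) return(NULL)
    rs <- rad[sel]
    pick <- if (kind == "outer") rs >= max(rs) - 6 else rs <= min(rs) + 6
    c(x = mean(xs[sel][pick]), y = mean(ys[sel][pick]),
      radius = mean(rs[pick]))
  }
  corners <- list()
  for (b in outer_bins) {
    p <- refine(b, "outer")
    if (!is.null(p)) corners[[length(corners) + 1L]] <-
        c(p, angle = b - 0.5, cls = 1)
  }
  if (figure == "star") {
    inner_bins <- .circ_peaks(sm, config$corner_min_sep_deg, maxima = FALSE)
    for (b in inner_bins) {
      p <- refine(b, "inner")
      if (!is.null(p)) corners[[length(corners) + 1L]] <-
          c(p, angle = b - 0.5, cls = 2)
    }
  }
  if (length(corners) == 0) return(empty)
  cm <- do.call(rbind, corners)
  df <- data.frame(x = cm[, "x"], y = cm[, "y"],
                   angle = (atan2(cm[, "y"] - cy, cm[, "x"] - cx) * 180 / pi) %% 360,
                   radius = sqrt((cm[, "x"] - cx)^2 + (cm[, "y"] - cy)^2),
                   class = ifelse(cm[, "cls"] == 1, "outer", "inner"),
                   stringsAsFactors = FALSE)
  if (figure == "diamond") {
    # classify by nearest cardinal direction of the corner angle
    card <- c("right", "bottom", "left", "top")
    k <- (round(df$angle / 90) %% 4) + 1
    df$class <- card[k]
    # keep at most one corner per cardinal class (largest radius wins)
    keep <- unlist(lapply(split(seq_len(nrow(df)), df$class),
                          function(ii) ii[which.max(df$radius[ii])]))
    df <- df[sort(keep), , drop = FALSE]
  }
  df <- df[order(df$angle), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(points = cbind(x = xs, y = ys), corners = df,
                 centroid = c(x = cx, y = cy), n_corners = nrow(df),
                 figure = figure),
            class = "corner_set")
}

#' @export
print.corner_set <- function(x, ...) {
  cat(sprintf("<corner_set (%s): %d corners, %d ink px, centroid (%.0f, %.0f)>\n",
              x$figure, x$n_corners, nrow(x$points),
              x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Fit the idealized archetype to detected corners
#'
#' Anchors an idealized polygon to the detected corners: the archetype's
#' vertices are the corner positions in angular order (so it translates and
#' scales exactly with the drawing), the star alternates outer tips and
#' inner vertices, and the diamond carries the vertical midline segment
#' between its top and bottom corners. Scale is anchored to the outermost
#' corners.
#'
#' @param corners A `corner_set` from [extract_drawing()].
#' @param figure `"star"` or `"diamond"` (defaults to the corner set's).
#' @return List of class `archetype`: `figure`, `vertices`, `classes`,
#'   `centroid`, `scale`, `midline` (diamond), `degenerate`.
#' @export
fit_archetype <- function(corners, figure = NULL) {
  if (is.null(figure)) figure <- corners$figure
  df <- corners$corners
  if (nrow(df) < 3) {
    return(structure(list(figure = figure, vertices = NULL, classes = NULL,
                          centroid = corners$centroid, scale = NA_real_,
                          midline = NULL, degenerate = TRUE),
                     class = "archetype"))
  }
  v <- cbind(x = df$x, y = df$y)
  scale <- max(df$radius)
  midline <- NULL
  if (figure == "diamond" && all(c("top", "bottom") %in% df$class)) {
    midline <- rbind(v[df$class == "top", , drop = FALSE][1, ],
                     v[df$class == "bottom", , drop = FALSE][1, ])
  }
  structure(list(figure = figure, vertices = v, classes = df$class,
                 centroid = corners$centroid, scale = scale,
                 midline = midline, degenerate = FALSE),
            class = "archetype")
}

#' @export
print.archetype <- function(x, ...) {
  cat(sprintf("<archetype (%s): %s, scale %.0f px>\n", x$figure,
              if (x$degenerate) "degenerate"
              else paste(nrow(x$vertices), "vertices"), x$scale))
  invisible(x)
}

# Coverage of the segment a->b by ink points within a corridor:
# returns coverage fraction, largest uncovered gap (px), and the total
# least-squares direction of the assigned ink (aligned a->b).
.edge_stats <- function(pts, a, b, corridor, bin = 5, trim = 12) {
  d <- b - a
  len <- sqrt(sum(d^2))
  if (len < 1e-9 || nrow(pts) == 0)
    return(list(coverage = 0, max_gap = len, dir = d / max(len, 1e-9), n = 0L))
  u <- d / len
  rel_x <- pts[, 1] - a[1]; rel_y <- pts[, 2] - a[2]
  t <- rel_x * u[1] + rel_y * u[2]
  perp <- abs(-rel_x * u[2] + rel_y * u[1])
  sel <- perp <= corridor & t >= -corridor & t <= len + corridor
  if (!any(sel))
    return(list(coverage = 0, max_gap = len, dir = u, n = 0L))
  ts <- pmin(len, pmax(0, t[sel]))
  nb <- max(1L, ceiling(len / bin))
  covered <- tabulate(pmin(nb, as.integer(ts / bin) + 1L), nbins = nb) > 0
  runs <- rle(covered)
  gaps <- runs$lengths[!runs$values]
  max_gap <- if (length(gaps)) max(gaps) * bin else 0
  # PCA direction on mid-edge ink (corner clusters excluded)
  core <- sel & t > trim & t < len - trim
  dir <- u
  if (sum(core) >= 10) {
    px <- pts[core, 1] - mean(pts[core, 1])
    py <- pts[core, 2] - mean(pts[core, 2])
    cv <- cbind(c(sum(px * px), sum(px * py)), c(sum(px * py), sum(py * py)))
    e <- eigen(cv, symmetric = TRUE)
    dir <- e$vectors[, 1]
    if (sum(dir * u) < 0) dir <- -dir
  }
  list(coverage = mean(covered), max_gap = max_gap, dir = dir, n = sum(sel))
}

.edge_present <- function(st, config) {
  st$coverage >= config$edge_coverage_min &&
    st$max_gap <= config$closure_gap_max
}

.angle_between <- function(u, v) {
  cosv <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

# empty copy score (degenerate input)
.zero_copy_score <- function(figure, diag = list()) {
  structure(list(figure = figure, shape = 0L, detail = 0L, arrangement = 0L,
                 net_sum = 0L,
                 net_hierarchical = if (figure == "diamond") 0L else NA_integer_,
                 bit_binary = 0L,
                 standard_value = sv_lookup(0, sv_table(
                   if (figure == "star") "copy_star" else "copy_diamond")),
                 diagnostics = diag),
            class = "copy_score")
}

#' Score the copied four-pointed star
#'
#' Three-part evaluation. Shape: every archetype edge must be covered by
#' ink (closed outline) and the corner radii must be consistent within each
#' class (outer tips, inner vertices). Detail: shape passed and exactly
#' eight corners. Arrangement: comparable axis-aligned spans, aligned
#' opposing tips, uniform inner-vertex spacing, and tip angles close to the
#' expected value (all within the loose band, at least two within the
#' strict band). The binary completeness criterion is shape AND detail.
#'
#' @param drawing,corners A `corner_set` from [extract_drawing()] (the
#'   `drawing` argument carries the ink points; pass the same object).
#' @param archetype An [fit_archetype()] result.
#' @param criteria A [star_criteria()].
#' @param config A [pipeline_config()].
#' @return List of class `copy_score`.
#' @export
score_star <- function(drawing, corners = drawing, archetype = NULL,
                       criteria = star_criteria(),
                       config = pipeline_config()) {
  if (is.null(archetype)) archetype <- fit_archetype(corners, "star")
  if (archetype$degenerate) return(.zero_copy_score("star"))
  pts <- drawing$points
  v <- archetype$vertices
  n <- nrow(v)
  edges <- lapply(seq_len(n), function(i) {
    .edge_stats(pts, v[i, ], v[(i %% n) + 1, ], config$corridor_halfwidth)
  })
  edges_ok <- all(vapply(edges, .edge_present, logical(1), config = config))

  df <- corners$corners
  rad_dev <- vapply(split(df$radius, df$class), function(r)
    max(abs(r - mean(r))), numeric(1))
  radial_ok <- all(rad_dev <= criteria$max_radial_deviation)
  shape <- as.integer(edges_ok && radial_ok)
  detail <- as.integer(shape == 1L && corners$n_corners == criteria$required_corners)

  # arrangement -----------------------------------------------------------
  arrangement <- 0L
  ang_dev <- numeric(0)
  outer <- df[df$class == "outer", , drop = FALSE]
  inner <- df[df$class == "inner", , drop = FALSE]
  span_ok <- FALSE; align_ok <- FALSE; inter_ok <- FALSE; angle_ok <- FALSE
  if (nrow(outer) >= 4) {
    i_r <- which.max(outer$x); i_l <- which.min(outer$x)
    i_t <- which.min(outer$y); i_b <- which.max(outer$y)
    distinct <- length(unique(c(i_r, i_l, i_t, i_b))) == 4
    if (distinct) {
      span_h <- outer$x[i_r] - outer$x[i_l]
      span_v <- outer$y[i_b] - outer$y[i_t]
      span_ok <- abs(span_h - span_v) <= criteria$span_difference_max
      align_ok <- abs(outer$x[i_t] - outer$x[i_b]) <=
        criteria$tip_misalignment_max &&
        abs(outer$y[i_l] - outer$y[i_r]) <= criteria$tip_misalignment_max
    }
  }
  if (nrow(inner) >= 3) {
    o <- order(inner$angle)
    ip <- inner[o, ]
    dists <- sqrt(diff(c(ip$x, ip$x[1]))^2 + diff(c(ip$y, ip$y[1]))^2)
    inter_ok <- max(abs(dists - mean(dists))) <=
      criteria$intermediate_distance_deviation_max
  }
  # inner-vertex wedge angles from fitted incident-edge directions
  ord <- order(df$angle)
  vo <- v[ord, , drop = FALSE]
  cls <- archetype$classes[ord]
  no <- nrow(vo)
  tip_angles <- numeric(0)
  for (i in which(cls == "inner")) {
    prev <- ((i - 2) %% no) + 1; nxt <- (i %% no) + 1
    e1 <- .edge_stats(pts, vo[i, ], vo[prev, ], config$corridor_halfwidth)
    e2 <- .edge_stats(pts, vo[i, ], vo[nxt, ], config$corridor_halfwidth)
    if (e1$n >= 5 && e2$n >= 5)
      tip_angles <- c(tip_angles, .angle_between(e1$dir, e2$dir))
  }
  if (length(tip_angles) >= 4) {
    ang_dev <- abs(tip_angles - criteria$expected_angle)
    angle_ok <- all(ang_dev <= criteria$angle_deviation_max) &&
      sum(ang_dev <= criteria$angle_deviation_strict) >=
        criteria$min_angles_within_strict
  }
  arrangement <- as.integer(span_ok && align_ok && inter_ok && angle_ok)

  net <- shape + detail + arrangement
  structure(list(figure = "star", shape = shape, detail = detail,
                 arrangement = arrangement, net_sum = net,
                 net_hierarchical = NA_integer_,
                 bit_binary = as.integer(shape == 1L && detail == 1L),
                 standard_value = sv_lookup(net, sv_table("copy_star")),
                 diagnostics = list(edges_ok = edges_ok,
                                    radial_deviation = rad_dev,
                                    n_corners = corners$n_corners,
                                    tip_angles = tip_angles,
                                    span_ok = span_ok, align_ok = align_ok,
                                    inter_ok = inter_ok,
                                    angle_ok = angle_ok)),
            class = "copy_score")
}

#' Score the copied diamond
#'
#' Shape: all four outer edges present and closed. Detail: vertical
#' midline present, terminating within the capture windows of the top and
#' bottom corners. Arrangement: at most one of the four midline-to-edge
#' angles deviates from the expected 45 degrees by more than the tolerance
#' (angles measured between the fitted midline and fitted edge
#' directions). Both the plain NET sum and the hierarchical variant
#' (detail gated on shape, arrangement gated on both) are reported; the
#' binary completeness criterion is shape AND detail.
#'
#' @inheritParams score_star
#' @param criteria A [diamond_criteria()].
#' @return List of class `copy_score`.
#' @export
score_diamond <- function(drawing, corners = drawing, archetype = NULL,
                          criteria = diamond_criteria(),
                          config = pipeline_config()) {
  if (is.null(archetype)) archetype <- fit_archetype(corners, "diamond")
  if (archetype$degenerate) return(.zero_copy_score("diamond"))
  pts <- drawing$points
  df <- corners$corners
  have <- c("top", "right", "bottom", "left") %in% df$class
  if (!all(have)) return(.zero_copy_score("diamond",
                                          diag = list(missing_corner = TRUE)))
  P <- function(cl) unlist(df[df$class == cl, c("x", "y")][1, ])
  top <- P("top"); right <- P("right"); bottom <- P("bottom"); left <- P("left")

  # outline ink = points near any outer edge; midline ink = the rest
  outline <- list(list(top, right), list(right, bottom),
                  list(bottom, left), list(left, top))
  est <- lapply(outline, function(e)
    .edge_stats(pts, e[[1]], e[[2]], config$corridor_halfwidth))
  shape <- as.integer(all(vapply(est, .edge_present, logical(1),
                                 config = config)))

  # midline: corridor between top and bottom corners, excluding outline ink
  near_outline <- rep(FALSE, nrow(pts))
  for (e in outline) {
    a <- e[[1]]; b <- e[[2]]
    d <- b - a; len <- sqrt(sum(d^2)); u <- d / len
    t <- (pts[, 1] - a[1]) * u[1] + (pts[, 2] - a[2]) * u[2]
    perp <- abs(-(pts[, 1] - a[1]) * u[2] + (pts[, 2] - a[2]) * u[1])
    near_outline <- near_outline |
      (perp <= config$corridor_halfwidth & t >= -5 & t <= len + 5)
  }
  mpts <- pts[!near_outline, , drop = FALSE]
  mst <- .edge_stats(mpts, top, bottom, config$corridor_halfwidth,
                     trim = config$midline_capture)
  reach_ok <- FALSE
  if (mst$n >= 10) {
    ymin <- min(mpts[, 2][.near_segment(mpts, top, bottom,
                                        config$corridor_halfwidth)])
    ymax <- max(mpts[, 2][.near_segment(mpts, top, bottom,
                                        config$corridor_halfwidth)])
    reach_ok <- (ymin - top["y"]) <= config$midline_capture &&
      (bottom["y"] - ymax) <= config$midline_capture
  }
  core_cov_ok <- mst$coverage >= config$edge_coverage_min * 0.8 &&
    mst$max_gap <= config$closure_gap_max + 2 * config$midline_capture
  detail <- as.integer(reach_ok && core_cov_ok)

  # arrangement: four midline-to-edge angles at the meeting corners
  ang <- rep(NA_real_, 4)
  if (mst$n >= 10) {
    vm <- mst$dir                      # aligned top -> bottom
    dirs <- list(est[[1]]$dir,          # top -> right
                 -est[[2]]$dir,         # bottom -> right (edge fitted r->b)
                 est[[3]]$dir,          # bottom -> left
                 -est[[4]]$dir)         # top -> left (edge fitted l->t)
    from_top <- c(TRUE, FALSE, FALSE, TRUE)
    for (i in 1:4) {
      if (est[[c(1, 2, 3, 4)[i]]]$n < 5) next
      vmi <- if (from_top[i]) vm else -vm
      ang[i] <- .angle_between(vmi, dirs[[i]])
    }
  }
  viol <- sum(abs(ang - criteria$expected_half_angle) >
                criteria$angle_tolerance + criteria$angle_epsilon,
              na.rm = TRUE) + sum(is.na(ang))
  arrangement <- as.integer(viol <= criteria$max_violations_allowed)

  net <- shape + detail + arrangement
  d_h <- as.integer(detail == 1L && shape == 1L)
  a_h <- as.integer(arrangement == 1L && shape == 1L && d_h == 1L)
  structure(list(figure = "diamond", shape = shape, detail = detail,
                 arrangement = arrangement, net_sum = net,
                 net_hierarchical = shape + d_h + a_h,
                 bit_binary = as.integer(shape == 1L && detail == 1L),
                 standard_value = sv_lookup(net, sv_table("copy_diamond")),
                 diagnostics = list(angles = ang,
                                    midline_n = mst$n,
                                    edge_coverage = vapply(est, `[[`,
                                                           numeric(1),
                                                           "coverage"))),
            class = "copy_score")
}

.near_segment <- function(pts, a, b, corridor) {
  d <- b - a; len <- sqrt(sum(d^2)); u <- d / len
  t <- (pts[, 1] - a[1]) * u[1] + (pts[, 2] - a[2]) * u[2]
  perp <- abs(-(pts[, 1] - a[1]) * u[2] + (pts[, 2] - a[2]) * u[1])
  perp <= corridor & t >= -corridor & t <= len + corridor
}

#' @export
print.copy_score <- function(x, ...) {
  cat(sprintf("<copy_%s: shape %d, detail %d, arrangement %d, NET %d%s, binary %d, SV %.1f>\n",
              x$figure, x$shape, x$detail, x$arrangement, x$net_sum,
              if (!is.na(x$net_hierarchical))
                sprintf(" (hierarchical %d)", x$net_hierarchical) else "",
              x$bit_binary, x$standard_value))
  invisible(x)
}
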