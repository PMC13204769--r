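#' Synthetic sheet specification
#'
#' Parameters for generating one simulated test sheet: the printed layout,
#' a patient-response model with a controllable neglect gradient, and scan
#' corruption. Given the same spec and seed, rendering is bit-for-bit
#' deterministic. The response, stroke-geometry and corruption draws use
#' separate derived RNG streams, so toggling corruption does not change
#' which targets the simulated patient crossed.
#'
#' @param subtest_id Subtest identifier.
#' @param severity Neglect severity `s` in 0..1. `s = 0` crosses every
#'   target and centres bisection marks; larger `s` steepens the
#'   right-to-left omission gradient and shifts bisection marks rightward.
#' @param seed Integer seed fixing every random draw.
#' @param layout A `layout_template` (defaults to [default_layout()]).
#' @param response Response-model overrides: `gradient_center`,
#'   `gradient_width` (logistic gradient of crossing probability over
#'   normalized x), `bisect_offset_sd`, `bisect_bias_max` (px),
#'   `copy_angle_sd` (degrees), `gap_probability`, `gap_width` (px),
#'   `tremor_amplitude` (px), `tremor_wavelength` (px), `delete_tips`
#'   (star tips to omit), `midline` (draw the diamond midline),
#'   `diamond_angles` / `star_rotation` (explicit geometry overrides),
#'   `stroke_width`, `ink_intensity`.
#' @param corruption Corruption overrides: `rotation` (degrees),
#'   `noise_density` (salt-and-pepper fraction), `contrast` (ink contrast
#'   factor, 1 = full black).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(subtest_id, severity = 0, seed = 1,
                           layout = NULL, response = list(),
                           corruption = list()) {
  subtest_id <- match_subtest(subtest_id)
  stopifnot(severity >= 0, severity <= 1)
  if (is.null(layout)) layout <- default_layout(subtest_id)
  resp <- utils::modifyList(list(
    gradient_center = 0.5, gradient_width = 0.15,
    bisect_offset_sd = 30, bisect_bias_max = 120,
    copy_angle_sd = 1.5, gap_probability = 0, gap_width = 50,
    tremor_amplitude = 0, tremor_wavelength = 40,
    delete_tips = integer(0), midline = TRUE,
    diamond_angles = NULL, star_rotation = 0, star_inner_angle = 110,
    star_radius = 280, diamond_half_height = 300,
    stroke_width = 3, ink_intensity = 60), response)
  corr <- utils::modifyList(list(rotation = 0, noise_density = 0,
                                 contrast = 1), corruption)
  stopifnot(corr$noise_density >= 0, corr$noise_density <= 1,
            resp$gap_probability >= 0, resp$gap_probability <= 1)
  structure(list(subtest_id = subtest_id, severity = severity,
                 seed = as.integer(seed), layout = layout,
                 response = resp, corruption = corr),
            class = "synthetic_spec")
}

#' Crossing probability of the neglect response model
#'
#' Probability that a target at normalized horizontal position `x` (0 =
#' leftmost, 1 = rightmost) is crossed out:
#' `p(x) = 1 - s * (1 - plogis((x - center) / width))`.
#' The probability is nondecreasing in `x`, equals 1 everywhere at
#' severity 0, and at full severity follows the logistic gradient itself,
#' emulating the lateralized omission pattern that defines neglect.
#'
#' @param x_norm Normalized positions in 0..1.
#' @param severity Severity `s` in 0..1.
#' @param center,width Logistic gradient parameters.
#' @return Vector of crossing probabilities.
#' @export
crossing_probability <- function(x_norm, severity, center = 0.5,
                                 width = 0.15) {
  1 - severity * (1 - stats::plogis((x_norm - center) / width))
}

#' Draw crossed flags from the neglect response model
#'
#' @param x Target x-positions (any scale; normalized internally by their
#'   range).
#' @param severity Severity in 0..1.
#' @param seed Optional seed (uses the current RNG stream when `NULL`).
#' @param center,width Gradient parameters, see [crossing_probability()].
#' @return Logical vector of crossed flags.
#' @export
neglect_response_model <- function(x, severity, seed = NULL,
                                   center = 0.5, width = 0.15) {
  if (!is.null(seed)) set.seed(seed)
  rng <- range(x)
  xn <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) else rep(0.5, length(x))
  p <- crossing_probability(xn, severity, center, width)
  stats::runif(length(x)) < p
}

# wavy (tremor) edge with an optional gap interval [t0, t1] in px along
# the edge
.draw_edge <- function(page, a, b, width, intensity, tremor_amp = 0,
                       tremor_wl = 40, phase = 0, gap = NULL) {
  d <- b - a
  len <- sqrt(sum(d^2))
  if (len < 1e-6) return(page)
  u <- d / len
  nrm <- c(-u[2], u[1])
  ts <- seq(0, len, by = 4)
  if (length(ts) < 2 || ts[length(ts)] < len) ts <- c(ts, len)
  off <- if (tremor_amp > 0)
    tremor_amp * sin(2 * pi * ts / tremor_wl + phase) else rep(0, length(ts))
  px <- a[1] + ts * u[1] + off * nrm[1]
  py <- a[2] + ts * u[2] + off * nrm[2]
  keep_seg <- rep(TRUE, length(ts) - 1)
  if (!is.null(gap)) {
    mid <- (ts[-1] + ts[-length(ts)]) / 2
    keep_seg <- !(mid > gap[1] & mid < gap[2])
  }
  for (i in which(keep_seg)) {
    page <- draw_segment(page, px[i], py[i], px[i + 1], py[i + 1],
                         width = width, intensity = intensity)
  }
  page
}

#' Render a synthetic test sheet with ground truth
#'
#' Draws the printed layout, simulates the patient's responses under the
#' spec's neglect model, renders the resulting pen strokes, applies scan
#' corruption, and returns both the page and the exact ground truth of
#' every stochastic choice.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_sheet`: `sheet` (a [sheet_image()]),
#'   `truth` (class `ground_truth`), `template` (the layout used).
#' @export
render_sheet <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tmpl <- spec$layout
  resp <- spec$response
  corr <- spec$corruption
  page <- render_template(tmpl)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, 3L)

  ink <- resp$ink_intensity
  ink_eff <- 255 - (255 - ink) * corr$contrast
  sw <- resp$stroke_width
  truth <- list(subtest_id = spec$subtest_id, seed = spec$seed,
                severity = spec$severity,
                corruption = corr)

  if (!is.null(tmpl$targets)) {
    # --- cancellation subtests -------------------------------------------
    t <- tmpl$targets
    set.seed(subseeds[1])
    crossed <- neglect_response_model(t$x, spec$severity,
                                      center = resp$gradient_center,
                                      width = resp$gradient_width)
    crossed[t$excluded] <- TRUE   # clinician pre-crosses the example targets
    set.seed(subseeds[2])
    n_t <- nrow(t)
    # strike-through geometry: roughly perpendicular to printed line
    # targets, steep diagonals through letters and stars
    ang <- if (spec$subtest_id == "line_crossing") {
      t$angle + 90 + stats::runif(n_t, -25, 25)
    } else if (spec$subtest_id == "letter_cancellation") {
      # consistent up-right strike-throughs, steep enough to stay clear of
      # the neighbouring letters and of the target glyph's own diagonals
      -stats::runif(n_t, 60, 80)
    } else {
      stats::runif(n_t, 45, 75) * sample(c(-1, 1), n_t, TRUE)
    }
    jx <- stats::rnorm(n_t, 0, 2); jy <- stats::rnorm(n_t, 0, 2)
    stroke_len <- switch(spec$subtest_id,
                         line_crossing = rep(t$size * 2.2, n_t),
                         letter_cancellation = rep(56, n_t),
                         star_cancellation = pmax(t$size * 1.8, 50))
    ci <- which(crossed)
    if (length(ci)) {
      a <- ang[ci] * pi / 180
      dx <- cos(a) * stroke_len[ci] / 2; dy <- sin(a) * stroke_len[ci] / 2
      page <- draw_segments_batch(page, cbind(t$x[ci] + jx[ci] - dx,
                                              t$y[ci] + jy[ci] - dy,
                                              t$x[ci] + jx[ci] + dx,
                                              t$y[ci] + jy[ci] + dy),
                                  width = sw, intensity = ink_eff)
    }
    scoreable <- !t$excluded & t$side != "M"
    truth$crossed <- stats::setNames(crossed, t$id)
    truth$counts <- c(L = sum(crossed & scoreable & t$side == "L"),
                      R = sum(crossed & scoreable & t$side == "R"),
                      total = sum(crossed & scoreable))
  } else if (!is.null(tmpl$bisection_lines)) {
    # --- line bisection ---------------------------------------------------
    bl <- tmpl$bisection_lines
    set.seed(subseeds[1])
    offs <- stats::rnorm(3, mean = spec$severity * resp$bisect_bias_max,
                         sd = resp$bisect_offset_sd)
    half <- (bl$x2 - bl$x1) / 2
    offs <- pmin(0.9 * half, pmax(-0.9 * half, offs))
    set.seed(subseeds[2])
    tilt <- stats::runif(3, -8, 8) * pi / 180
    for (i in 1:3) {
      mx <- (bl$x1[i] + bl$x2[i]) / 2 + offs[i]
      my <- (bl$y1[i] + bl$y2[i]) / 2
      dy <- 32; dx <- tan(tilt[i]) * dy
      page <- draw_segment(page, mx - dx, my - dy, mx + dx, my + dy,
                           width = sw, intensity = ink_eff)
    }
    truth$bisection <- data.frame(label = bl$label, offset = offs,
                                  x_mark = (bl$x1 + bl$x2) / 2 + offs)
  } else {
    # --- figure copying ---------------------------------------------------
    dr <- tmpl$drawing_region
    cx <- (dr[1] + dr[3]) / 2; cy <- (dr[2] + dr[4]) / 2
    set.seed(subseeds[1])
    if (spec$subtest_id == "copy_star") {
      v <- star_vertices(cx, cy, resp$star_radius,
                         inner_angle_deg = resp$star_inner_angle,
                         rotation_deg = resp$star_rotation)
      # angular perturbation of each vertex about the centre plus a small
      # radial jitter
      th <- atan2(v[, 2] - cy, v[, 1] - cx) +
        stats::rnorm(8, 0, resp$copy_angle_sd * pi / 180)
      rr <- sqrt((v[, 1] - cx)^2 + (v[, 2] - cy)^2) + stats::rnorm(8, 0, 2)
      v <- cbind(x = cx + rr * cos(th), y = cy + rr * sin(th))
      keep <- rep(TRUE, 8)
      if (length(resp$delete_tips)) {
        keep[2 * resp$delete_tips - 1] <- FALSE  # tips sit at odd indices
      }
      vv <- v[keep, , drop = FALSE]
      nE <- nrow(vv)
      gapped <- stats::runif(nE) < resp$gap_probability
      set.seed(subseeds[2])
      phases <- stats::runif(nE, 0, 2 * pi)
      for (i in seq_len(nE)) {
        a <- vv[i, ]; b <- vv[(i %% nE) + 1, ]
        len <- sqrt(sum((b - a)^2))
        gap <- if (gapped[i])
          (len - resp$gap_width) / 2 + c(0, resp$gap_width) else NULL
        page <- .draw_edge(page, a, b, sw, ink_eff,
                           tremor_amp = resp$tremor_amplitude,
                           tremor_wl = resp$tremor_wavelength,
                           phase = phases[i], gap = gap)
      }
      truth$copy <- list(figure = "star", vertices = vv,
                         n_corners = nE,
                         deleted_tips = resp$delete_tips,
                         gapped_edges = which(gapped),
                         gap_width = resp$gap_width,
                         tremor_amplitude = resp$tremor_amplitude)
    } else {
      angles <- resp$diamond_angles
      if (is.null(angles)) angles <- 45 + stats::rnorm(4, 0, resp$copy_angle_sd)
      v <- diamond_vertices(cx, cy, resp$diamond_half_height, angles)
      gapped <- stats::runif(4) < resp$gap_probability
      set.seed(subseeds[2])
      phases <- stats::runif(5, 0, 2 * pi)
      for (i in 1:4) {
        a <- v[i, ]; b <- v[(i %% 4) + 1, ]
        len <- sqrt(sum((b - a)^2))
        gap <- if (gapped[i])
          (len - resp$gap_width) / 2 + c(0, resp$gap_width) else NULL
        page <- .draw_edge(page, a, b, sw, ink_eff,
                           tremor_amp = resp$tremor_amplitude,
                           tremor_wl = resp$tremor_wavelength,
                           phase = phases[i], gap = gap)
      }
      if (isTRUE(resp$midline)) {
        page <- .draw_edge(page, v[1, ], v[3, ], sw, ink_eff,
                           tremor_amp = resp$tremor_amplitude,
                           tremor_wl = resp$tremor_wavelength,
                           phase = phases[5])
      }
      truth$copy <- list(figure = "diamond", vertices = v,
                         angles = angles, midline = isTRUE(resp$midline),
                         gapped_edges = which(gapped),
                         gap_width = resp$gap_width,
                         tremor_amplitude = resp$tremor_amplitude)
    }
  }

  # --- corruption ---------------------------------------------------------
  set.seed(subseeds[3])
  if (corr$noise_density > 0) {
    n <- length(page)
    k <- as.integer(round(corr$noise_density * n))
    if (k > 0) {
      at <- sample.int(n, k)
      pepper <- stats::runif(k) < 0.7
      page[at[pepper]] <- 0
      page[at[!pepper]] <- 255
    }
  }
  if (abs(corr$rotation) > 1e-9) page <- rotate_page(page, corr$rotation)

  class(truth) <- "ground_truth"
  structure(list(sheet = sheet_image(page, source_path = sprintf(
                   "<synthetic %s seed %d>", spec$subtest_id, spec$seed)),
                 truth = truth, template = tmpl),
            class = "synthetic_sheet")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth %s (seed %d, severity %.2f)>\n", x$subtest_id,
              x$seed, x$severity))
  if (!is.null(x$counts))
    cat(sprintf("  crossed: L %d, R %d, total %d\n", x$counts["L"],
                x$counts["R"], x$counts["total"]))
  if (!is.null(x$bisection))
    cat(sprintf("  bisection offsets: %s\n",
                paste(sprintf("%s=%.1f", x$bisection$label,
                              x$bisection$offset), collapse = ", ")))
  invisible(x)
}

#' Write a set of synthetic sheets to disk
#'
#' Emits, per spec: a PNG scan, a JSON ground-truth sidecar, and (once per
#' subtest) the layout YAML. Useful for building file-based fixture
#' batches for the batch scorer.
#'
#' @param specs List of [synthetic_spec()] objects.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Data frame manifest (`patient_id`, `subtest`, `file`),
#'   invisibly used by [run_batch()].
#' @export
write_synthetic_set <- function(specs, dir, prefix = "sheet") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(specs))
  written_layouts <- character(0)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sh <- render_sheet(sp)
    stem <- sprintf("%s_%03d_%s", prefix, i, sp$subtest_id)
    png_path <- file.path(dir, paste0(stem, ".png"))
    EBImage::writeImage(EBImage::Image(t(sh$sheet$pixels) / 255), png_path)
    truth <- sh$truth
    truth$crossed <- as.list(truth$crossed)
    if (!is.null(truth$counts)) truth$counts <- as.list(truth$counts)
    jsonlite::write_json(truth, file.path(dir, paste0(stem, "_truth.json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!(sp$subtest_id %in% written_layouts)) {
      write_layout(sp$layout, file.path(dir, paste0("layout_",
                                                    sp$subtest_id, ".yaml")))
      written_layouts <- c(written_layouts, sp$subtest_id)
    }
    rows[[i]] <- data.frame(patient_id = sprintf("P%03d", i),
                            subtest = sp$subtest_id,
                            file = paste0(stem, ".png"),
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
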