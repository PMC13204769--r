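#' Sheet images
#'
#' A `sheet_image` is a normalized raster page: grayscale intensities 0--255
#' (0 = black ink) in a `[height x width]` matrix, at the canonical working
#' width, with provenance metadata.
#'
#' @param pixels Numeric matrix of intensities.
#' @param mm_per_px Physical scale after normalization.
#' @param source_path Provenance string.
#' @return An object of class `sheet_image`.
#' @export
sheet_image <- function(pixels, mm_per_px = NA_real_, source_path = "<memory>") {
  stopifnot(is.matrix(pixels), nrow(pixels) > 0, ncol(pixels) > 0)
  if (min(pixels) < 0 || max(pixels) > 255) {
    pixels[pixels < 0] <- 0; pixels[pixels > 255] <- 255
  }
  structure(list(pixels = pixels,
                 width = ncol(pixels), height = nrow(pixels),
                 canonical_scale = mm_per_px,
                 source_path = source_path),
            class = "sheet_image")
}

#' @export
print.sheet_image <- function(x, ...) {
  cat(sprintf("<sheet_image %d x %d px, %.3f mm/px, source: %s>\n",
              x$width, x$height, x$canonical_scale, x$source_path))
  invisible(x)
}

#' Read a raster scan as a grayscale page
#'
#' Reads PNG/TIFF/JPEG (8-bit grayscale or RGB; RGB is converted by
#' luminance) into a 0--255 intensity matrix.
#'
#' @param path Image file path.
#' @return Numeric page matrix.
#' @export
load_sheet <- function(path) {
  if (!file.exists(path) || file.info(path)$size == 0)
    stop("unreadable or zero-size image file: ", path)
  img <- EBImage::readImage(path)
  d <- dim(img)
  a <- EBImage::imageData(img)
  if (length(d) == 3) {
    if (d[3] >= 3) {
      a <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  t(a) * 255  # EBImage stores [x, y]; pages are [y, x]
}

# Global Otsu threshold on a 0..255 page; returns the intensity t that
# maximizes between-class variance (ink is `< t`).
otsu_threshold <- function(page) {
  counts <- tabulate(as.integer(page) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, Inf)
  which.max(sigma_b) - 1L + 0.5
}

# Binarize a page: TRUE = ink. The effective threshold is the Otsu optimum
# capped at `ink_max_intensity` (or the manual override).
binarize_page <- function(page, config) {
  thr <- config$binarize_threshold
  if (is.null(thr)) thr <- min(otsu_threshold(page), config$ink_max_intensity)
  page < thr
}

# Estimate global skew (degrees) of the dominant horizontal structure by
# maximizing the concentration of the y-projection of dark pixels over a
# grid of candidate angles, followed by parabolic refinement.
estimate_skew <- function(dark, range_deg = 5, step = 0.25,
                          max_points = 30000L) {
  idx <- which(dark)
  if (length(idx) < 50) return(0)
  if (length(idx) > max_points)
    idx <- idx[as.integer(seq(1L, length(idx), length.out = max_points))]
  h <- nrow(dark)
  ys <- ((idx - 1L) %% h) + 1L
  xs <- ((idx - 1L) %/% h) + 1L
  angles <- seq(-range_deg, range_deg, by = step)
  sharp <- vapply(angles, function(a) {
    th <- a * pi / 180
    yr <- -sin(th) * xs + cos(th) * ys
    cnt <- tabulate(as.integer((yr - min(yr)) / 2) + 1L)
    sum((cnt / length(yr))^2)
  }, numeric(1))
  i <- which.max(sharp)
  best <- angles[i]
  if (i > 1 && i < length(angles)) {      # parabolic peak refinement
    y1 <- sharp[i - 1]; y2 <- sharp[i]; y3 <- sharp[i + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-12) best <- best + step * 0.5 * (y1 - y3) / den
  }
  best
}

.downsample <- function(m, f = 4L) {
  m[seq(1L, nrow(m), by = f), seq(1L, ncol(m), by = f)]
}

# Fraction of printed-template ink pixels that are dark in the page, both on
# a 4x grid. The score is ~1 for a correctly oriented scan of this layout.
.registration_score <- function(page, tmpl, config) {
  tdark <- .template_dark_small(tmpl, config)
  small <- .downsample(page)
  mean(small[tdark] < 160)
}

.template_dark_small <- function(tmpl, config) {
  key <- paste0(.layout_key(tmpl), "|darksmall")
  hit <- .template_cache[[key]]
  if (is.null(hit)) {
    hit <- which(.downsample(render_template(tmpl, config)) < 128)
    .template_cache[[key]] <- hit
  }
  hit
}

.fiducial_cover <- function(page, tmpl) {
  f <- tmpl$fiducial
  if (is.null(f)) return(NA_real_)
  r <- f$size * 0.5
  rows <- max(1L, floor(f$y - r)):min(nrow(page), ceiling(f$y + r))
  cols <- max(1L, floor(f$x - r)):min(ncol(page), ceiling(f$x + r))
  mean(page[rows, cols] < 160)
}

#' Load and normalize a scanned sheet
#'
#' Runs the standardization front end: grayscale conversion, rescaling to
#' the canonical width (aspect preserved), page-orientation recovery, and
#' deskewing. Orientation uses the printed fiducial arrow when the layout
#' defines one (the three-line bisection sheet is nearly 180-degree
#' symmetric, hence the arrow); otherwise the printed-template registration
#' score over the upright and upside-down hypotheses decides.
#' Normalization is idempotent up to interpolation error.
#'
#' @param x File path, page matrix, or `sheet_image`.
#' @param template The sheet's [default_layout()] / `layout_template`.
#' @param config A [pipeline_config()].
#' @return A normalized [sheet_image()].
#' @export
load_and_normalize <- function(x, template, config = pipeline_config()) {
  src <- "<memory>"
  if (is.character(x)) { src <- x; page <- load_sheet(x) }
  else if (inherits(x, "sheet_image")) page <- x$pixels
  else if (is.matrix(x)) page <- x
  else stop("unsupported input to load_and_normalize")
  if (nrow(page) == 0 || ncol(page) == 0) stop("empty image")

  W <- template$canonical_width
  H <- template$canonical_height
  if (ncol(page) != W) {
    page <- t(EBImage::imageData(EBImage::resize(
      EBImage::Image(t(page) / 255), w = W))) * 255
  }
  # pad / crop height to the canonical page
  if (nrow(page) < H) {
    page <- rbind(page, matrix(255, H - nrow(page), ncol(page)))
  } else if (nrow(page) > H) {
    page <- page[seq_len(H), , drop = FALSE]
  }

  # orientation: upright vs rotated 180 degrees
  flipped <- page[rev(seq_len(nrow(page))), rev(seq_len(ncol(page)))]
  if (!is.null(template$fiducial)) {
    cov_up <- .fiducial_cover(page, template)
    cov_fl <- .fiducial_cover(flipped, template)
    if (max(cov_up, cov_fl) < config$fiducial_min_cover) {
      stop(structure(class = c("neglectscore_qc_error", "error", "condition"),
                     list(message = "orientation fiducial not detected (no_fiducial)",
                          call = sys.call(), flag = "no_fiducial")))
    }
    if (cov_fl > cov_up) page <- flipped
  } else {
    s_up <- .registration_score(page, template, config)
    s_fl <- .registration_score(flipped, template, config)
    if (s_fl > s_up) page <- flipped
  }

  # deskew
  dark <- page < 160
  ang <- estimate_skew(dark, range_deg = config$deskew_range)
  if (abs(ang) > config$deskew_tol) {
    page <- rotate_page(page, -ang)
  }
  sheet_image(page, mm_per_px = config$mm_per_px, source_path = src)
}

#' Isolate patient ink from the printed template
#'
#' Binarizes the normalized sheet, subtracts a dilated mask of the rendered
#' printed layer, and removes small speckle components. The result is the
#' patient-added stroke mask on which all scoring operates.
#'
#' @param sheet A normalized [sheet_image()].
#' @param template The sheet's `layout_template`.
#' @param config A [pipeline_config()].
#' @return Logical matrix of class `ink_mask` (TRUE = patient ink), with
#'   attributes `speck_count` (removed speckle components) and
#'   `removed_px`.
#' @export
extract_ink <- function(sheet, template, config = pipeline_config()) {
  page <- if (inherits(sheet, "sheet_image")) sheet$pixels else sheet
  dark <- binarize_page(page, config)
  tm <- .template_mask_dilated(template, config)
  ink <- dark & !tm
  # component cleanup
  lab <- as.integer(EBImage::bwlabel(ink))
  sizes <- tabulate(lab[lab > 0L])
  speck <- sum(sizes <= config$speck_max_px)
  removed <- 0L
  if (any(sizes < config$min_component_px)) {
    keep_lut <- c(TRUE, sizes >= config$min_component_px)  # label 0 = bg
    kept <- keep_lut[lab + 1L]
    removed <- sum(ink) - sum(ink & kept)
    ink <- ink & kept
  }
  structure(ink, class = c("ink_mask", class(ink)),
            speck_count = speck, removed_px = removed)
}

.template_mask_dilated <- function(template, config) {
  key <- paste0(.layout_key(template), "|dil", config$template_dilate)
  hit <- .template_cache[[key]]
  if (is.null(hit)) {
    tdark <- render_template(template, config) < 128
    brush <- EBImage::makeBrush(2L * config$template_dilate + 1L, "disc")
    hit <- EBImage::imageData(EBImage::dilate(EBImage::Image(tdark * 1), brush)) > 0
    .template_cache[[key]] <- hit
  }
  hit
}

#' Quality-control checks on a normalized sheet
#'
#' Deterministic per-sheet flags mirroring the scan-exclusion conditions
#' that make automated scoring unreliable: `low_contrast` (faint ink the
#' binarizer dropped), `excessive_noise` (speckle density),
#' `distorted_print` (poor registration of the printed layer),
#' `out_of_region_drawing` (copy subtests), `multiple_bisection_marks`,
#' and `no_fiducial`. An empty flag set means the sheet is clean.
#'
#' @param sheet A normalized [sheet_image()].
#' @param ink An `ink_mask` from [extract_ink()].
#' @param template The sheet's `layout_template`.
#' @param config A [pipeline_config()].
#' @return List of class `qc_report` with `flags` (character vector) and
#'   `messages` (named).
#' @export
run_qc <- function(sheet, ink, template, config = pipeline_config()) {
  page <- if (inherits(sheet, "sheet_image")) sheet$pixels else sheet
  flags <- character(0); msgs <- character(0)
  add <- function(flag, msg) {
    flags <<- c(flags, flag); msgs <<- c(msgs, stats::setNames(msg, flag))
  }

  # low contrast: faint-band pixels that belong neither to the printed
  # layer nor to the anti-aliased halo of detected dark ink
  band <- page > config$ink_max_intensity &
    page < (255 - config$low_contrast_margin)
  tm <- .template_mask_dilated(template, config)
  idx <- which(band & !tm)
  if (length(idx)) {
    # drop faint pixels adjacent (Chebyshev radius 2) to detected dark ink:
    # those are anti-aliasing halo, not a faint stroke of their own
    h <- nrow(page); npx <- length(page)
    inkv <- unclass(ink)
    near <- rep(FALSE, length(idx))
    for (dx in -2:2) for (dy in -2:2) {
      j <- idx + dy + dx * h
      okj <- j >= 1L & j <= npx
      near[okj] <- near[okj] | inkv[j[okj]]
    }
    n_faint <- sum(!near)
    if (n_faint >= config$low_contrast_min_px)
      add("low_contrast",
          sprintf("%d faint-ink pixels below the detection threshold",
                  n_faint))
  }

  speck <- attr(ink, "speck_count")
  if (is.null(speck)) speck <- 0L
  if (speck / length(ink) > config$noise_density_max)
    add("excessive_noise",
        sprintf("%d speckle components (density %.2g)", speck,
                speck / length(ink)))

  sc_reg <- .registration_score(page, template, config)
  if (sc_reg < config$registration_min)
    add("distorted_print",
        sprintf("printed-template registration %.2f below %.2f",
                sc_reg, config$registration_min))

  dr <- template$drawing_region
  if (!is.null(dr)) {
    m <- config$out_of_region_margin
    out <- unclass(ink)
    r1 <- max(1, floor(dr[2] - m)); r2 <- min(nrow(out), ceiling(dr[4] + m))
    c1 <- max(1, floor(dr[1] - m)); c2 <- min(ncol(out), ceiling(dr[3] + m))
    out[r1:r2, c1:c2] <- FALSE
    if (sum(out) >= config$out_of_region_min_px)
      add("out_of_region_drawing",
          sprintf("%d ink pixels beyond the drawing region", sum(out)))
  }

  if (!is.null(template$bisection_lines)) {
    for (i in seq_len(nrow(template$bisection_lines))) {
      cand <- .bisection_clusters(ink, template$bisection_lines[i, ], config)
      if (length(cand$centers) >= 2) {
        add("multiple_bisection_marks",
            sprintf("line %s has %d separated candidate marks",
                    template$bisection_lines$label[i], length(cand$centers)))
        break
      }
    }
  }

  if (!is.null(template$fiducial)) {
    if (.fiducial_cover(page, template) < config$fiducial_min_cover)
      add("no_fiducial", "orientation arrow not found at expected position")
  }

  structure(list(flags = unique(flags), messages = msgs), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  if (length(x$flags) == 0) {
    cat("<qc_report: clean>\n")
  } else {
    cat("<qc_report>\n")
    for (f in x$flags) cat(sprintf("  %s: %s\n", f, x$messages[[f]]))
  }
  invisible(x)
}
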