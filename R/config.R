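#' Pipeline configuration
#'
#' Central bundle of tunable parameters for sheet normalization, ink
#' isolation, target detection and figure scoring. All geometric thresholds
#' are expressed in canonical pixels: every sheet is rescaled to
#' `canonical_width` pixels wide before any measurement, so the printed
#' pixel thresholds of the scoring criteria have a fixed physical meaning
#' (at the default width of 1240 px an A4 page maps to ~0.169 mm/px and the
#' copy-drawing region is ~1000 px wide).
#'
#' @param canonical_width Page width in pixels after normalization.
#' @param page_mm Physical page width in millimetres (used only to report
#'   the mm-per-pixel scale; A4 portrait by default).
#' @param ink_max_intensity Grayscale cut above which a pixel can never be
#'   counted as ink, even if the automatic threshold is higher. Marks
#'   fainter than this (thin pencil, red pen scanned to light gray) are
#'   deliberately dropped and flagged as `low_contrast` instead of being
#'   half-detected.
#' @param binarize_threshold Manual override for the global Otsu threshold
#'   (`NULL` = automatic).
#' @param low_contrast_margin Intensity margin below paper white that
#'   defines the "faint ink" band used by the `low_contrast` QC flag.
#' @param low_contrast_min_px Minimum number of faint-band pixels (outside
#'   the printed template and outside detected dark ink) that raises
#'   `low_contrast`.
#' @param noise_floor Maximum foreground count an ink mask extracted from a
#'   blank printed template may have and still count as clean.
#' @param speck_max_px Connected components at or below this size are
#'   treated as scanner specks.
#' @param noise_density_max Speck components per pixel above which
#'   `excessive_noise` is raised.
#' @param template_dilate Radius (px) by which the printed-template mask is
#'   dilated before subtraction from the binarized sheet.
#' @param min_component_px Ink components smaller than this are removed
#'   during cleanup.
#' @param registration_min Minimum fraction of printed-template pixels that
#'   must be dark in the scan; below it the print is considered distorted.
#' @param deskew_range Half-range (degrees) of the skew search.
#' @param deskew_tol Residual skews below this magnitude are not corrected.
#' @param window_halfwidth Named vector: half-width (px) of the square
#'   detection window centred on each cancellation target.
#' @param detect_threshold Named vector: minimum fraction of the detection
#'   window that must be patient ink for the target to count as crossed.
#'   Calibrated on the synthetic fixtures shipped with the package.
#' @param bisection_band Half-height (px) of the horizontal band around each
#'   bisection line searched for the patient's mark.
#' @param bisection_merge_gap Ink clusters on the same line closer than this
#'   (px) are merged into one mark; farther apart they count as multiple
#'   marks.
#' @param bisection_min_px Minimum ink pixels for a cluster to count as a
#'   candidate mark.
#' @param zone_fractions Increasing fractions of the half-line length
#'   bounding the 3-, 2- and 1-point bisection zones (inclusive bounds);
#'   beyond the last fraction a mark scores 0.
#' @param corridor_halfwidth Half-width (px) of the corridor around an
#'   archetype edge within which ink counts as covering that edge.
#' @param edge_coverage_min Minimum fraction of an archetype edge that must
#'   be covered by ink.
#' @param closure_gap_max Largest tolerated gap (px) in an edge before it is
#'   reported missing.
#' @param corner_smooth_deg Smoothing window (degrees) applied to the radial
#'   profile before corner peaks are extracted.
#' @param corner_min_sep_deg Minimum angular separation between detected
#'   corners.
#' @param midline_capture Radius (px) of the capture window around the top
#'   and bottom diamond corners within which the midline must terminate.
#' @param out_of_region_margin Tolerated overshoot (px) of drawing ink past
#'   the drawing region before `out_of_region_drawing` is raised.
#' @param out_of_region_min_px Minimum number of overshooting pixels.
#' @param fiducial_min_cover Minimum dark-pixel fraction inside the fiducial
#'   box for the orientation marker to count as present.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(canonical_width = 1240,
                            page_mm = 210,
                            ink_max_intensity = 180,
                            binarize_threshold = NULL,
                            low_contrast_margin = 30,
                            low_contrast_min_px = 150,
                            noise_floor = 60,
                            speck_max_px = 4,
                            noise_density_max = 2e-4,
                            template_dilate = 2,
                            min_component_px = 8,
                            registration_min = 0.70,
                            deskew_range = 5,
                            deskew_tol = 0.1,
                            window_halfwidth = c(line_crossing = 40,
                                                 letter_cancellation = 20,
                                                 star_cancellation = 28),
                            detect_threshold = c(line_crossing = 0.012,
                                                 letter_cancellation = 0.017,
                                                 star_cancellation = 0.02),
                            bisection_band = 30,
                            bisection_merge_gap = 50,
                            bisection_min_px = 15,
                            zone_fractions = c(0.05, 0.125, 0.25),
                            corridor_halfwidth = 9,
                            edge_coverage_min = 0.85,
                            closure_gap_max = 30,
                            corner_smooth_deg = 9,
                            corner_min_sep_deg = 20,
                            midline_capture = 40,
                            out_of_region_margin = 15,
                            out_of_region_min_px = 50,
                            fiducial_min_cover = 0.12) {
  stopifnot(canonical_width > 0,
            length(zone_fractions) == 3L,
            all(diff(zone_fractions) > 0),
            all(zone_fractions > 0))
  cfg <- list(canonical_width = as.integer(canonical_width),
              page_mm = page_mm,
              mm_per_px = page_mm / canonical_width,
              ink_max_intensity = ink_max_intensity,
              binarize_threshold = binarize_threshold,
              low_contrast_margin = low_contrast_margin,
              low_contrast_min_px = low_contrast_min_px,
              noise_floor = noise_floor,
              speck_max_px = speck_max_px,
              noise_density_max = noise_density_max,
              template_dilate = template_dilate,
              min_component_px = min_component_px,
              registration_min = registration_min,
              deskew_range = deskew_range,
              deskew_tol = deskew_tol,
              window_halfwidth = window_halfwidth,
              detect_threshold = detect_threshold,
              bisection_band = bisection_band,
              bisection_merge_gap = bisection_merge_gap,
              bisection_min_px = bisection_min_px,
              zone_fractions = zone_fractions,
              corridor_halfwidth = corridor_halfwidth,
              edge_coverage_min = edge_coverage_min,
              closure_gap_max = closure_gap_max,
              corner_smooth_deg = corner_smooth_deg,
              corner_min_sep_deg = corner_min_sep_deg,
              midline_capture = midline_capture,
              out_of_region_margin = out_of_region_margin,
              out_of_region_min_px = out_of_region_min_px,
              fiducial_min_cover = fiducial_min_cover)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  canonical width: %d px (%.3f mm/px)\n",
              x$canonical_width, x$mm_per_px))
  cat(sprintf("  ink intensity cut: %d; template dilation: %d px\n",
              x$ink_max_intensity, x$template_dilate))
  cat(sprintf("  bisection zones (fractions of half-line): %s\n",
              paste(x$zone_fractions, collapse = " / ")))
  invisible(x)
}

.subtests <- c("line_crossing", "letter_cancellation", "star_cancellation",
               "line_bisection", "copy_star", "copy_diamond")

match_subtest <- function(subtest_id) {
  match.arg(subtest_id, .subtests)
}
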