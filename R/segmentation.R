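#' Extract the perinuclear condensed-chromatin ring
#'
#' Thresholds the calibrated image at `t_peri` (the 146-256 band on the
#' 1-256 scale) inside the nucleus ROI, applies a morphological closing of
#' radius `closing_radius` to absorb hairline staining cracks, and keeps the
#' single 8-connected component with the largest pixel count — the
#' perinuclear rim, which dwarfs any nucleoplasmic particle at this
#' magnification.
#'
#' @param image calibrated [gray_image()] (or DN matrix).
#' @param nucleus_roi logical matrix marking the neighborhood of one nucleus.
#' @param cfg a [threshold_config()].
#' @return Logical ring mask.
#' @export
extract_perinuclear_ring <- function(image, nucleus_roi, cfg = threshold_config()) {
  px <- as_pixels(image)
  check_mask(nucleus_roi, dim(px))
  hot <- (px >= cfg$t_peri) & nucleus_roi
  if (!any(hot))
    stop("NoPerinuclearSignal: no pixel >= ", cfg$t_peri, " inside the ROI")
  hot <- binary_closing(hot, cfg$closing_radius) & nucleus_roi
  largest_component(hot, connectivity = 8L)
}

#' Decide perinuclear-ring continuity (the Group A / Group N step)
#'
#' A ring is continuous when it topologically encloses a nucleoplasm: hole
#' filling the ring yields an interior (fill minus ring) whose largest
#' 4-connected component reaches `min_interior_area` pixels. Nuclei whose
#' rim cannot be closed enclose nothing and are the discontinuous (Group A)
#' phenotype. Equivalent flood-fill reading: background filled from the
#' image border never reaches an interior pixel.
#'
#' @param ring logical ring mask from [extract_perinuclear_ring()].
#' @param cfg a [threshold_config()].
#' @return A list with `continuous` (logical) and `interior` (logical mask;
#'   all-FALSE when discontinuous).
#' @export
assess_continuity <- function(ring, cfg = threshold_config()) {
  check_mask(ring)
  holes <- mask_holes(ring)
  empty <- ring & FALSE
  if (!any(holes)) return(list(continuous = FALSE, interior = empty))
  interior <- largest_component(holes, connectivity = 4L)
  if (sum(interior) < cfg$min_interior_area)
    return(list(continuous = FALSE, interior = empty))
  list(continuous = TRUE, interior = interior)
}

#' Detect the nucleolus inside the nucleoplasm
#'
#' The nucleolus is excluded from both terms of the nucleoplasmic chromatin
#' score. It is taken as the largest 8-connected component of condensed
#' pixels (`DN >= t_cond`) in the interior, accepted only when it covers at
#' least `nucleolus_min_frac` of the interior; scattered chromatin specks
#' never qualify. An externally supplied mask overrides detection.
#'
#' @param image calibrated [gray_image()] (or DN matrix).
#' @param interior logical nucleoplasm mask; non-empty.
#' @param cfg a [threshold_config()].
#' @param nucleolus_mask optional externally supplied mask (subset of the
#'   interior is enforced by intersection).
#' @return Logical nucleolus mask (possibly all-FALSE).
#' @export
detect_nucleolus <- function(image, interior, cfg = threshold_config(),
                             nucleolus_mask = NULL) {
  px <- as_pixels(image)
  check_mask(interior, dim(px))
  if (!any(interior)) stop("empty interior")
  if (!is.null(nucleolus_mask)) {
    check_mask(nucleolus_mask, dim(px))
    return(nucleolus_mask & interior)
  }
  cand <- largest_component((px >= cfg$t_cond) & interior, connectivity = 8L)
  if (sum(cand) >= cfg$nucleolus_min_frac * sum(interior)) cand
  else interior & FALSE
}

#' Inner nuclear perimeter length
#'
#' Length (px) of the closed iso-contour of the nucleoplasm traced at the
#' 0.5 level between inside and outside pixel centers; see
#' [contour_perimeter()] for the numerical convention.
#'
#' @param interior logical mask, one connected component.
#' @return Length in pixels.
#' @export
inner_perimeter_length <- function(interior) {
  check_mask(interior)
  if (!any(interior)) stop("empty interior has no perimeter")
  if (max(label_components(interior, 8L)) > 1L)
    stop("interior must be a single connected component")
  contour_perimeter(interior)
}

#' Segment one cardiomyocyte nucleus
#'
#' Composes ring extraction, continuity assessment, nucleolus detection and
#' inner-perimeter measurement into the per-nucleus segmentation record.
#'
#' @inheritParams extract_perinuclear_ring
#' @param nucleolus_mask optional externally supplied nucleolus mask.
#' @param nucleus_id identifier carried through to downstream tables.
#' @return A `nucleus_segmentation` with fields `ring_mask`, `interior_mask`,
#'   `nucleolus_mask`, `continuous`, `inner_perimeter` (0 when
#'   discontinuous), `nucleus_id`.
#' @export
segment_nucleus <- function(image, nucleus_roi, cfg = threshold_config(),
                            nucleolus_mask = NULL, nucleus_id = "") {
  ring <- extract_perinuclear_ring(image, nucleus_roi, cfg)
  cont <- assess_continuity(ring, cfg)
  if (cont$continuous) {
    nucleolus <- detect_nucleolus(image, cont$interior, cfg, nucleolus_mask)
    perim <- inner_perimeter_length(cont$interior)
  } else {
    nucleolus <- ring & FALSE
    perim <- 0
  }
  structure(list(ring_mask = ring, interior_mask = cont$interior,
                 nucleolus_mask = nucleolus, continuous = cont$continuous,
                 inner_perimeter = perim, nucleus_id = nucleus_id),
            class = "nucleus_segmentation")
}

#' @export
print.nucleus_segmentation <- function(x, ...) {
  cat(sprintf("<nucleus_segmentation %s: %s, ring %d px, interior %d px, nucleolus %d px, inner perimeter %.1f px>\n",
              if (nzchar(x$nucleus_id)) x$nucleus_id else "(unnamed)",
              if (x$continuous) "continuous (N)" else "discontinuous (A)",
              sum(x$ring_mask), sum(x$interior_mask), sum(x$nucleolus_mask),
              x$inner_perimeter))
  invisible(x)
}
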