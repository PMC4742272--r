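#' Construct an 8-bit grayscale image
#'
#' The common currency of the pipeline: a rectangular grid of integer digital
#' numbers (DN) on the standard 8-bit scale 0-255, stored row-major with
#' 0-based (row, col) coordinate conventions in all user-facing functions.
#'
#' @param pixels integer matrix, every value in \[0, 255\].
#' @param pixel_size optional physical size per pixel (nm/px).
#' @param source_id free-text identifier (file name, specimen id).
#' @return An object of class `gray_image` with fields `pixels`,
#'   `pixel_size`, `source_id`.
#' @export
gray_image <- function(pixels, pixel_size = NULL, source_id = "") {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("pixels must be a non-empty matrix")
  if (any(!is.finite(pixels)))
    stop("pixels contain non-finite values")
  if (any(pixels != round(pixels)) || any(pixels < 0) || any(pixels > 255))
    stop("pixels must be integers in [0, 255]")
  structure(
    list(pixels = matrix(as.integer(pixels), nrow(pixels), ncol(pixels)),
         pixel_size = pixel_size, source_id = source_id),
    class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d px, DN range [%d, %d]%s>\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels),
              if (nzchar(x$source_id)) paste0(", ", x$source_id) else ""))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

# coerce anything image-like to the integer pixel matrix
as_pixels <- function(image) {
  if (inherits(image, "gray_image")) return(image$pixels)
  if (is.matrix(image)) return(image)
  stop("expected a gray_image or a matrix")
}

#' Validate a binary mask against an image shape
#'
#' Masks are plain logical matrices; they must match the shape of the image
#' they annotate.
#'
#' @param mask logical matrix.
#' @param shape integer vector `c(nrow, ncol)` or an object with a `dim`.
#' @return The mask, invisibly, after validation.
#' @export
check_mask <- function(mask, shape = NULL) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix")
  if (!is.null(shape)) {
    shape <- if (is.numeric(shape)) as.integer(shape[1:2]) else dim(shape)
    if (!identical(dim(mask), shape))
      stop(sprintf("mask shape %d x %d does not match expected %d x %d",
                   nrow(mask), ncol(mask), shape[1], shape[2]))
  }
  invisible(mask)
}

#' Read an 8-bit grayscale image from PNG or TIFF
#'
#' DN are preserved bit-exactly. Inputs with a bit depth other than 8 are
#' rejected; multi-channel inputs are rejected unless `convert = TRUE`, in
#' which case they are collapsed by ITU-R BT.601 luminance
#' (0.299 R + 0.587 G + 0.114 B, rounded).
#'
#' @param path file path; format inferred from the extension.
#' @param convert allow channel collapse of RGB(A) inputs by luminance.
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path, convert = FALSE) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bps <- attr(arr, "bits.per.sample")
    if (!is.null(bps) && any(bps != 8L))
      stop("not an 8-bit image (bits per sample = ", paste(bps, collapse = ","),
           "); re-encode or supply an 8-bit file")
    px <- collapse_channels(arr, convert, path)
    if (any(px > 255)) stop("not an 8-bit image: ", path)
  } else if (ext == "png") {
    arr <- png::readPNG(path)
    px <- collapse_channels(arr * 255, convert, path)
    # readPNG normalises by the true bit depth; 16-bit content leaves
    # non-integer values after rescaling to 255
    if (max(abs(px - round(px))) > 1e-6)
      stop("not an 8-bit image (likely 16-bit PNG): ", path)
    px <- round(px)
  } else stop("unsupported image format: .", ext)
  gray_image(px, source_id = basename(path))
}

collapse_channels <- function(arr, convert, path) {
  if (length(dim(arr)) == 2L || is.null(dim(arr))) return(as.matrix(arr))
  nch <- dim(arr)[3]
  if (nch == 1L) return(arr[, , 1L])
  if (!convert)
    stop("multi-channel image (", nch, " channels); pass convert = TRUE ",
         "to collapse by luminance: ", path)
  round(0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L])
}

#' Write an 8-bit grayscale image to PNG or TIFF
#'
#' Round-trips with [read_gray_image()] are bit-exact.
#'
#' @param image a [gray_image()].
#' @param path output path (.png, .tif or .tiff).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  px <- as_pixels(image) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) tiff::writeTIFF(px, path, bits.per.sample = 8L)
  else if (ext == "png") png::writePNG(px, path)
  else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Read a binary mask (PNG/TIFF image or polygon file)
#'
#' Image masks follow the nonzero-is-inside convention. Polygon files are
#' plain text: optional `#` comment header lines, then one `row,col` vertex
#' per line in 0-based pixel-center coordinates; the vertex list must be
#' explicitly closed (last vertex equal to the first) and is rasterized with
#' the even-odd rule at pixel centers.
#'
#' @param path mask file path (.png/.tif/.tiff image or .txt/.poly polygon).
#' @param shape required mask shape `c(nrow, ncol)`.
#' @return A logical matrix of the requested shape.
#' @export
read_mask <- function(path, shape) {
  if (!file.exists(path)) stop("cannot read mask: ", path)
  shape <- as.integer(shape[1:2])
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png", "tif", "tiff")) {
    arr <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
    if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
    m <- arr != 0
    check_mask(m, shape)
    return(m)
  }
  verts <- read_polygon(path)
  rasterize_polygon(verts, shape)
}

read_polygon <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 4L) stop("polygon needs at least 3 vertices plus closure: ", path)
  parts <- strsplit(lines, ",")
  if (any(lengths(parts) != 2L)) stop("malformed polygon vertex line in ", path)
  v <- matrix(as.numeric(unlist(parts)), ncol = 2L, byrow = TRUE)
  if (any(!is.finite(v))) stop("malformed polygon vertex line in ", path)
  if (v[1, 1] != v[nrow(v), 1] || v[1, 2] != v[nrow(v), 2])
    stop("unclosed polygon (last vertex must repeat the first): ", path)
  v[-nrow(v), , drop = FALSE]
}

#' Rasterize a closed polygon to a mask by the even-odd rule
#'
#' Pixel centers sit at integer 0-based (row, col) coordinates. A center
#' lying exactly on an edge follows the standard half-open crossing
#' convention, so an axis-aligned rectangle (r0,c0)-(r1,c1) fills exactly
#' `[r0, r1) x [c0, c1)`.
#'
#' @param vertices numeric matrix, one `(row, col)` vertex per row; the
#'   closing edge back to the first vertex is implicit.
#' @param shape mask shape `c(nrow, ncol)`.
#' @return A logical matrix.
#' @export
rasterize_polygon <- function(vertices, shape) {
  shape <- as.integer(shape[1:2])
  pr <- rep(0:(shape[1] - 1L), times = shape[2])   # pixel-center rows
  pc <- rep(0:(shape[2] - 1L), each = shape[1])    # pixel-center cols
  inside <- logical(length(pr))
  n <- nrow(vertices)
  j <- n
  for (i in seq_len(n)) {
    yi <- vertices[i, 1]; xi <- vertices[i, 2]
    yj <- vertices[j, 1]; xj <- vertices[j, 2]
    crosses <- (yi > pr) != (yj > pr)
    if (any(crosses)) {
      xint <- xi + (pr[crosses] - yi) * (xj - xi) / (yj - yi)
      inside[crosses] <- xor(inside[crosses], pc[crosses] < xint)
    }
    j <- i
  }
  matrix(inside, shape[1], shape[2])
}

#' Write a binary mask as an 8-bit PNG (255 = inside)
#'
#' @param mask logical matrix.
#' @param path output .png path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Threshold and segmentation configuration
#'
#' All grayscale thresholds of the method on the internal 0-255 DN scale.
#' The source imaging convention counts 256 grayscale values from 1; every
#' published threshold is converted by subtracting 1 and applied inclusively
#' as `DN >= threshold`, which preserves the "highest quartile" semantics
#' (DN >= 192 spans exactly 64 of 256 values).
#'
#' @param t_peri DN threshold isolating perinuclear condensed chromatin
#'   (default 145, i.e. the published 146-256 band).
#' @param t_cond DN threshold for condensed chromatin, the top grayscale
#'   quartile (default 192, i.e. the published 193-256 band).
#' @param zdisk_lo,zdisk_hi acceptance window for the calibrated Z-disk mean
#'   (defaults 154, 164, i.e. the published 155-165 window).
#' @param zdisk_target calibration target, the window midpoint (default 159).
#' @param closing_radius morphological closing radius (px) applied to the
#'   thresholded ring; absorbs 1-px staining cracks (default 1).
#' @param min_interior_area minimum enclosed nucleoplasm area (px) for a ring
#'   to count as continuous (default 500, tuned to 10,000x magnification).
#' @param nucleolus_min_frac minimum fraction of the interior a condensed
#'   component must cover to be accepted as the nucleolus (default 0.05).
#' @return A named list of class `threshold_config`.
#' @export
threshold_config <- function(t_peri = 145L, t_cond = 192L,
                             zdisk_lo = 154L, zdisk_hi = 164L,
                             zdisk_target = 159L,
                             closing_radius = 1L,
                             min_interior_area = 500L,
                             nucleolus_min_frac = 0.05) {
  cfg <- list(t_peri = as.integer(t_peri), t_cond = as.integer(t_cond),
              zdisk_lo = as.numeric(zdisk_lo), zdisk_hi = as.numeric(zdisk_hi),
              zdisk_target = as.numeric(zdisk_target),
              closing_radius = as.integer(closing_radius),
              min_interior_area = as.integer(min_interior_area),
              nucleolus_min_frac = as.numeric(nucleolus_min_frac))
  if (!(cfg$t_peri > 0 && cfg$t_peri < cfg$t_cond && cfg$t_cond <= 255))
    stop("thresholds must satisfy 0 < t_peri < t_cond <= 255")
  if (!(cfg$zdisk_lo <= cfg$zdisk_target && cfg$zdisk_target <= cfg$zdisk_hi))
    stop("zdisk_target must lie inside [zdisk_lo, zdisk_hi]")
  if (cfg$closing_radius < 0) stop("closing_radius must be >= 0")
  if (cfg$nucleolus_min_frac < 0 || cfg$nucleolus_min_frac > 1)
    stop("nucleolus_min_frac must be in [0, 1]")
  structure(cfg, class = "threshold_config")
}

#' Read / write a threshold configuration file
#'
#' Flat key-value YAML with the keys of [threshold_config()]; missing keys
#' take the defaults.
#'
#' @param path config file path.
#' @rdname config_io
#' @return `read_threshold_config` returns a `threshold_config`;
#'   `write_threshold_config` returns `path` invisibly.
#' @export
read_threshold_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(threshold_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  do.call(threshold_config, vals)
}

#' @param cfg a `threshold_config`.
#' @rdname config_io
#' @export
write_threshold_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
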