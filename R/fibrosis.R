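#' Construct a Masson-trichrome RGB image
#'
#' @param rgb array `nrow x ncol x 3` of 8-bit values (0-255 integers).
#' @param tissue_mask logical matrix marking non-background tissue; default
#'   all pixels.
#' @param endocardium_mask optional logical matrix of endocardium pixels to
#'   exclude from the fibrosis denominator (must lie inside the tissue).
#' @return A `trichrome_image` list.
#' @export
trichrome_image <- function(rgb, tissue_mask = NULL, endocardium_mask = NULL) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("rgb must be an nrow x ncol x 3 array")
  if (any(rgb < 0) || any(rgb > 255)) stop("rgb values must be in [0, 255]")
  shape <- dim(rgb)[1:2]
  if (is.null(tissue_mask)) tissue_mask <- matrix(TRUE, shape[1], shape[2])
  check_mask(tissue_mask, shape)
  if (!is.null(endocardium_mask)) {
    check_mask(endocardium_mask, shape)
    if (any(endocardium_mask & !tissue_mask))
      stop("endocardium_mask must be a subset of tissue_mask")
  }
  structure(list(rgb = rgb, tissue_mask = tissue_mask,
                 endocardium_mask = endocardium_mask),
            class = "trichrome_image")
}

#' Read an RGB trichrome scan from PNG or TIFF
#'
#' @param path image path.
#' @param tissue_mask,endocardium_mask see [trichrome_image()].
#' @return A `trichrome_image`.
#' @export
read_trichrome <- function(path, tissue_mask = NULL, endocardium_mask = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") png::readPNG(path)
         else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else stop("unsupported image format: .", ext)
  if (length(dim(arr)) != 3L) stop("expected an RGB image: ", path)
  trichrome_image(round(arr[, , 1:3] * 255), tissue_mask, endocardium_mask)
}

#' Detect collagen-blue pixels by HSV thresholding
#'
#' Masson's trichrome renders collagen blue. A pixel is blue when its HSV
#' hue lies in `hue_band` (degrees), with saturation and value floors to
#' reject near-gray and near-black pixels. Simple hue-band detection (not
#' stain deconvolution) matches how slide-analysis software flags the stain;
#' the band is configurable for stain variability.
#'
#' @param image a `trichrome_image`.
#' @param hue_band hue interval in degrees (default `c(180, 260)`).
#' @param sat_min,val_min HSV saturation/value floors on \[0, 1\] scales
#'   (defaults 0.2).
#' @return Logical mask of blue pixels.
#' @export
detect_blue <- function(image, hue_band = c(180, 260), sat_min = 0.2, val_min = 0.2) {
  if (!inherits(image, "trichrome_image")) stop("expected a trichrome_image")
  shape <- dim(image$rgb)[1:2]
  hsv <- grDevices::rgb2hsv(r = as.vector(image$rgb[, , 1]),
                            g = as.vector(image$rgb[, , 2]),
                            b = as.vector(image$rgb[, , 3]),
                            maxColorValue = 255)
  hue <- hsv[1, ] * 360
  blue <- hue >= hue_band[1] & hue <= hue_band[2] &
    hsv[2, ] >= sat_min & hsv[3, ] >= val_min
  matrix(blue, shape[1], shape[2])
}

#' Percent interstitial fibrosis
#'
#' `100 * |blue & tissue \ endocardium| / |tissue \ endocardium|`, the
#' fibrotic fraction of the specimen area after anatomical endocardium
#' exclusion.
#'
#' @param image a `trichrome_image` (supplies tissue and endocardium masks).
#' @param blue logical blue-pixel mask, typically from [detect_blue()].
#' @return Percentage in \[0, 100\].
#' @export
fibrosis_fraction <- function(image, blue = detect_blue(image)) {
  if (!inherits(image, "trichrome_image")) stop("expected a trichrome_image")
  check_mask(blue, dim(image$rgb)[1:2])
  denom_mask <- image$tissue_mask
  if (!is.null(image$endocardium_mask)) denom_mask <- denom_mask & !image$endocardium_mask
  denom <- sum(denom_mask)
  if (denom == 0L) stop("no tissue left after endocardium exclusion")
  100 * sum(blue & denom_mask) / denom
}
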