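#' Screening image container
#'
#' An `oc_image` wraps a grayscale matrix or an RGB array of intensities on
#' the unit scale, together with the bit depth of the file it came from (or
#' will be written at) and an optional physical pixel pitch. All arithmetic in
#' the package runs on these unit-scale floats, never on integer pixel codes,
#' so ratio and mean statistics are independent of the source bit depth.
#'
#' Conventions used throughout the package: pixel indexing is `(row, col)`
#' with row 1 at the top of the frame; RGB plane order is R, G, B.
#'
#' @param pixels numeric matrix (grayscale) or `H x W x 3` array (RGB) with
#'   finite values in `[0, 1]`.
#' @param bit_depth integer, 8 or 16; the integer code width used for file
#'   storage.
#' @param pixel_pitch optional numeric, physical pixel pitch in micrometres
#'   per pixel (used only for unit conversion of MTF frequency axes).
#' @return an object of class `oc_image`.
#' @examples
#' img <- oc_image(matrix(seq(0, 1, length.out = 12), 3, 4))
#' dim(img$pixels)
#' @export
oc_image <- function(pixels, bit_depth = 8L, pixel_pitch = NULL) {
  if (!is.numeric(pixels)) stop("`pixels` must be numeric")
  d <- dim(pixels)
  if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] == 3L)))
    stop("`pixels` must be a matrix (grayscale) or an H x W x 3 array (RGB)")
  if (!all(is.finite(pixels))) stop("image intensities must all be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("image intensities must lie in [0, 1]")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  structure(list(pixels = pixels, bit_depth = bit_depth,
                 pixel_pitch = pixel_pitch),
            class = "oc_image")
}

#' @export
print.oc_image <- function(x, ...) {
  d <- dim(x$pixels)
  kind <- if (length(d) == 2L) "grayscale" else "RGB"
  cat(sprintf("<oc_image> %s %d x %d, %d-bit source, range [%.4f, %.4f]\n",
              kind, d[1], d[2], x$bit_depth, min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_rgb <- function(img) length(dim(img$pixels)) == 3L

#' @export
dim.oc_image <- function(x) dim(x$pixels)

as_pixel_matrix <- function(x, what = "input") {
  if (inherits(x, "oc_image")) {
    if (is_rgb(x)) stop(sprintf("%s must be a single image plane, not RGB", what))
    return(x$pixels)
  }
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop(sprintf("%s must be a numeric matrix or grayscale oc_image", what))
}

#' Extract one channel of an RGB image
#'
#' @param img an RGB `oc_image`.
#' @param which `"red"`, `"green"` or `"blue"` (or 1:3).
#' @return a numeric matrix.
#' @export
channel <- function(img, which = c("red", "green", "blue")) {
  if (!inherits(img, "oc_image") || !is_rgb(img))
    stop("`img` must be an RGB oc_image")
  if (is.character(which)) which <- match(match.arg(which),
                                          c("red", "green", "blue"))
  img$pixels[, , which]
}

#' Read a PNG or TIFF image
#'
#' Intensities are scaled to `[0, 1]` by the file's integer full scale
#' (`2^depth - 1`) and the source bit depth is recorded on the returned
#' object. One-channel files load as grayscale matrices, three-channel files
#' as RGB arrays; other channel counts (gray+alpha, RGBA) are rejected.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param pixel_pitch optional micrometres per pixel, attached as metadata.
#' @return an [oc_image].
#' @export
read_image <- function(path, pixel_pitch = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- tryCatch(png::readPNG(path, info = TRUE),
                   error = function(e) stop(sprintf("unreadable PNG '%s': %s",
                                                    path, conditionMessage(e))))
    depth <- attr(px, "info")$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    px <- tryCatch(tiff::readTIFF(path, info = TRUE),
                   error = function(e) stop(sprintf("unreadable TIFF '%s': %s",
                                                    path, conditionMessage(e))))
    depth <- attr(px, "bits.per.sample")
  } else stop(sprintf("unsupported image format '.%s' (PNG or TIFF only)", ext))
  d <- dim(px)
  if (length(d) == 3L) {
    if (d[3] == 1L) px <- px[, , 1L]
    else if (d[3] != 3L)
      stop(sprintf("unsupported channel count %d in '%s' (1 or 3 supported)",
                   d[3], path))
  }
  px <- array(as.numeric(px), dim = dim(px))  # drop reader attributes
  oc_image(px, bit_depth = depth, pixel_pitch = pixel_pitch)
}

# integer quantization at b bits, round half up
quantize <- function(px, bit_depth) {
  full <- 2^bit_depth - 1
  floor(px * full + 0.5) / full
}

#' Write an image losslessly at its source bit depth
#'
#' Pixels are quantized to the image's bit depth (round half away from zero)
#' and encoded without loss, so `read_image(write_image(img))` returns exactly
#' the quantized array. 8-bit images may be written as PNG or TIFF; 16-bit
#' images are written as TIFF (the PNG encoder used is 8-bit only).
#'
#' @param img an [oc_image].
#' @param path output path (.png, .tif, .tiff).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (!inherits(img, "oc_image")) stop("`img` must be an oc_image")
  if (length(img$pixels) == 0L) stop("cannot write an empty image")
  ext <- tolower(tools::file_ext(path))
  q <- quantize(img$pixels, img$bit_depth)
  if (ext == "png") {
    if (img$bit_depth == 16L)
      stop("16-bit PNG writing is not supported; write a .tiff instead")
    png::writePNG(q, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(q, path, bits.per.sample = img$bit_depth,
                    compression = "none")
  } else stop(sprintf("unsupported output format '.%s'", ext))
  invisible(path)
}

#' Default analysis mask: exclude specular highlights
#'
#' A pixel enters the analysis region only if all three channels fall below
#' `highlight_cut`; near-saturated pixels are typically specular reflections
#' from the sheath or saliva and would corrupt ratio and mean statistics.
#'
#' @param img RGB [oc_image].
#' @param highlight_cut exclusion threshold in `(0, 1]` (default 0.98).
#' @return a logical matrix, `TRUE` inside the analysis region.
#' @export
default_mask <- function(img, highlight_cut = 0.98) {
  if (!inherits(img, "oc_image") || !is_rgb(img))
    stop("`img` must be an RGB oc_image")
  if (!is.numeric(highlight_cut) || highlight_cut <= 0 || highlight_cut > 1)
    stop("`highlight_cut` must lie in (0, 1]")
  p <- img$pixels
  m <- p[, , 1] < highlight_cut & p[, , 2] < highlight_cut &
    p[, , 3] < highlight_cut
  if (!any(m))
    stop("degenerate input: analysis mask is empty after highlight exclusion")
  m
}

check_mask <- function(mask, shape) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("`mask` must be a logical matrix")
  if (!identical(dim(mask), shape[1:2]))
    stop("mask shape does not match image shape")
  if (!any(mask)) stop("mask is empty: no pixels to analyze")
  invisible(mask)
}

#' Write a mask as a black/white PNG
#'
#' @param mask logical matrix.
#' @param path output .png path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("`mask` must be a logical matrix")
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Co-registered WLI/AFI image pair for one anatomical site
#'
#' @param wli white-light [oc_image] (RGB).
#' @param afi autofluorescence [oc_image] (RGB), same shape as `wli`.
#' @param case_id non-empty case identifier.
#' @param site anatomical site label.
#' @param mask shared analysis mask; defaults to [default_mask] of the AFI
#'   frame.
#' @return an object of class `image_pair`.
#' @export
image_pair <- function(wli, afi, case_id, site = "unspecified", mask = NULL) {
  if (!inherits(wli, "oc_image") || !inherits(afi, "oc_image"))
    stop("`wli` and `afi` must be oc_image objects")
  if (!identical(dim(wli$pixels), dim(afi$pixels)))
    stop("WLI and AFI shapes differ")
  if (!is.character(case_id) || length(case_id) != 1L || !nzchar(case_id))
    stop("`case_id` must be a non-empty string")
  if (is.null(mask)) mask <- default_mask(afi)
  check_mask(mask, dim(afi$pixels))
  structure(list(wli = wli, afi = afi, case_id = case_id, site = site,
                 mask = mask),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair> case '%s', site '%s', %d x %d, mask %d px\n",
              x$case_id, x$site, dim(x$afi$pixels)[1], dim(x$afi$pixels)[2],
              sum(x$mask)))
  invisible(x)
}
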