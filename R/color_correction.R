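#' 3x3 camera-RGB to CIEXYZ color matrix
#'
#' Rows are the X, Y, Z outputs; columns are the R, G, B inputs, so
#' `XYZ = A %*% RGB` for a column triplet.
#'
#' @param m numeric 3x3 matrix of finite coefficients.
#' @return an object of class `color_matrix` (a plain matrix subclass).
#' @export
color_matrix <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || !identical(dim(m), c(3L, 3L)))
    stop("a color matrix must be numeric 3 x 3")
  if (!all(is.finite(m))) stop("color matrix coefficients must be finite")
  dimnames(m) <- list(c("X", "Y", "Z"), c("R", "G", "B"))
  class(m) <- c("color_matrix", class(m))
  m
}

#' Measure mean patch RGB values from a checker image
#'
#' For each grid cell the mean RGB is taken over the central 50% (linear) of
#' the cell, after excluding near-saturated pixels with the same highlight
#' rule as [default_mask]; the margin keeps patch borders and gloss out of
#' the estimate.
#'
#' @param checker RGB [oc_image] of the 24-patch checker.
#' @param grid data frame with columns `patch_id`, `row0`, `row1`, `col0`,
#'   `col1` (1-based inclusive pixel bounds of each cell).
#' @param highlight_cut saturation exclusion threshold (default 0.98).
#' @return data frame with columns `patch_id`, `R`, `G`, `B`.
#' @export
measure_patches <- function(checker, grid, highlight_cut = 0.98) {
  if (!inherits(checker, "oc_image") || !is_rgb(checker))
    stop("`checker` must be an RGB oc_image")
  need <- c("patch_id", "row0", "row1", "col0", "col1")
  if (!all(need %in% names(grid))) stop("grid must have columns ",
                                        paste(need, collapse = ", "))
  d <- dim(checker$pixels)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    if (g$row0 < 1 || g$col0 < 1 || g$row1 > d[1] || g$col1 > d[2] ||
        g$row0 > g$row1 || g$col0 > g$col1)
      stop(sprintf("grid cell '%s' lies outside the image", g$patch_id))
    h <- g$row1 - g$row0 + 1L; w <- g$col1 - g$col0 + 1L
    rm_ <- floor(h / 4); cm_ <- floor(w / 4)
    rows <- (g$row0 + rm_):(g$row1 - rm_)
    cols <- (g$col0 + cm_):(g$col1 - cm_)
    px <- checker$pixels[rows, cols, , drop = FALSE]
    keep <- px[, , 1] < highlight_cut & px[, , 2] < highlight_cut &
      px[, , 3] < highlight_cut
    if (!any(keep))
      stop(sprintf("patch '%s' has no usable pixels after highlight exclusion",
                   g$patch_id))
    data.frame(patch_id = g$patch_id,
               R = mean(px[, , 1][keep]),
               G = mean(px[, , 2][keep]),
               B = mean(px[, , 3][keep]))
  })
  do.call(rbind, out)
}

#' Fit the RGB to XYZ color matrix from a patch table
#'
#' Solves the overdetermined linear system `C %*% t(A) = T` in the
#' least-squares sense, where `C` holds the measured camera RGB rows and `T`
#' the reference CIEXYZ rows for the same patches. With 24 patches the
#' system is 24x3, so the matrix "inverse" is the Moore-Penrose
#' least-squares solve; when `T` was generated by an exact linear map the
#' fit recovers it to machine precision.
#'
#' @param patches data frame with columns `R`, `G`, `B` (measured) and
#'   `X`, `Y`, `Z` (reference), rows aligned by patch; at least 3 rows.
#' @return a [color_matrix] with attributes `rmse` (per-entry RMS residual)
#'   and `n_patches`.
#' @export
fit_color_matrix <- function(patches) {
  need <- c("R", "G", "B", "X", "Y", "Z")
  if (!all(need %in% names(patches)))
    stop("patches must have columns ", paste(need, collapse = ", "))
  C <- as.matrix(patches[, c("R", "G", "B")])
  T_ <- as.matrix(patches[, c("X", "Y", "Z")])
  if (nrow(C) < 3) stop("at least 3 patches are required to fit the matrix")
  if (!all(is.finite(C)) || !all(is.finite(T_)))
    stop("patch table contains non-finite values")
  qrC <- qr(C)
  if (qrC$rank < 3)
    stop("measured RGB matrix is rank-deficient (patch colors are coplanar ",
         "in RGB); add patches with independent colors")
  At <- qr.coef(qrC, T_)          # 3x3, solves min ||C At - T||_F
  A <- color_matrix(t(At))
  resid <- C %*% At - T_
  attr(A, "rmse") <- sqrt(mean(resid^2))
  attr(A, "n_patches") <- nrow(C)
  A
}

#' Apply a color matrix to a triplet or an RGB image
#'
#' Per-pixel matrix-vector product `XYZ = A %*% RGB`; exactly linear in its
#' input. Output values are returned unclipped (XYZ is not bounded to the
#' unit interval).
#'
#' @param A a [color_matrix].
#' @param rgb length-3 numeric vector, an `N x 3` matrix of triplets, an RGB
#'   `oc_image`, or an `H x W x 3` array.
#' @return object of the same shape holding XYZ values (plain numeric).
#' @export
apply_color_matrix <- function(A, rgb) {
  if (!inherits(A, "color_matrix")) A <- color_matrix(A)
  if (inherits(rgb, "oc_image")) rgb <- rgb$pixels
  if (is.null(dim(rgb))) {
    if (length(rgb) != 3L) stop("triplet input must have length 3")
    return(as.numeric(A %*% rgb))
  }
  d <- dim(rgb)
  if (length(d) == 2L && d[2] == 3L) return(rgb %*% t(unclass(A)))
  if (length(d) == 3L && d[3] == 3L) {
    flat <- matrix(rgb, ncol = 3L)
    out <- flat %*% t(unclass(A))
    return(array(out, dim = d))
  }
  stop("`rgb` must be a triplet, N x 3 matrix, or H x W x 3 array")
}

# sRGB transfer functions and the D65 XYZ <-> linear-sRGB matrices
srgb_decode <- function(v) ifelse(v <= 0.04045, v / 12.92,
                                  ((v + 0.055) / 1.055)^2.4)
srgb_encode <- function(v) ifelse(v <= 0.0031308, 12.92 * v,
                                  1.055 * v^(1 / 2.4) - 0.055)

M_SRGB2XYZ <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                       0.2126729, 0.7151522, 0.0721750,
                       0.0193339, 0.1191920, 0.9503041),
                     3, 3, byrow = TRUE)
M_XYZ2SRGB <- matrix(c( 3.2404542, -1.5371385, -0.4985314,
                       -0.9692660,  1.8760108,  0.0415560,
                        0.0556434, -0.2040259,  1.0572252),
                     3, 3, byrow = TRUE)

#' Color-correct a white-light image for display
#'
#' With `gamma = FALSE` (default) the stored pixel values are treated as the
#' working space and the corrected image is simply the clipped per-pixel
#' matrix product — appropriate when the camera pipeline has already rendered
#' display-referred values. With `gamma = TRUE` the image is sRGB-linearized
#' first, mapped through `A` to CIEXYZ, converted back through the standard
#' D65 XYZ-to-sRGB matrix, re-encoded, and clipped; this is the physically
#' linear pathway. Out-of-gamut results are clipped to `[0, 1]`, never
#' wrapped.
#'
#' @param img RGB [oc_image].
#' @param A a [color_matrix].
#' @param gamma logical; apply the sRGB linearize/encode pathway.
#' @return corrected RGB [oc_image] at the source bit depth.
#' @export
correct_wli <- function(img, A, gamma = FALSE) {
  if (!inherits(img, "oc_image") || !is_rgb(img))
    stop("`img` must be an RGB oc_image")
  if (!inherits(A, "color_matrix")) A <- color_matrix(A)
  px <- img$pixels
  if (gamma) {
    lin <- srgb_decode(px)
    xyz <- apply_color_matrix(A, lin)
    flat <- matrix(xyz, ncol = 3L) %*% t(M_XYZ2SRGB)
    flat <- pmin(pmax(flat, 0), 1)
    out <- srgb_encode(array(flat, dim = dim(px)))
  } else {
    out <- apply_color_matrix(A, px)
  }
  out <- pmin(pmax(out, 0), 1)
  oc_image(out, bit_depth = img$bit_depth, pixel_pitch = img$pixel_pitch)
}

#' Read a patch reference table (CSV)
#'
#' The bundled default, `colorchecker_xyz_synthetic.csv`, is a synthetic
#' stand-in for a measured checker reference: nominal 24-patch sRGB
#' coordinates converted to CIEXYZ under D65 with unit white luminance. Use
#' a vendor-measured table when one is available.
#'
#' @param path CSV with columns `patch_id`, `X`, `Y`, `Z` (extra columns
#'   such as `name`, `R`, `G`, `B` are kept). Defaults to the bundled table.
#' @return data frame.
#' @export
read_patch_reference <- function(path = system.file(
  "extdata", "colorchecker_xyz_synthetic.csv", package = "oralscreen")) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patch_id", "X", "Y", "Z") %in% names(ref)))
    stop("reference table needs columns patch_id, X, Y, Z")
  ref
}

#' Write / read a fitted color matrix
#'
#' @param A a [color_matrix].
#' @param path `.csv` or `.json` output path.
#' @return `path` invisibly (write) or a [color_matrix] (read).
#' @export
write_color_matrix <- function(A, path) {
  if (!inherits(A, "color_matrix")) A <- color_matrix(A)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(as.data.frame(unclass(A)), path, row.names = TRUE)
  } else if (ext == "json") {
    jsonlite::write_json(list(coefficients = unclass(A)), path,
                         digits = NA, matrix = "rowmajor")
  } else stop("color matrix export supports .csv or .json")
  invisible(path)
}

#' @rdname write_color_matrix
#' @export
read_color_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, row.names = 1)
    color_matrix(as.matrix(df))
  } else if (ext == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    color_matrix(x$coefficients)
  } else stop("color matrix import supports .csv or .json")
}
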