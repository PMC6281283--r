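#' Even-asphere surface description
#'
#' @param radius radius of curvature R in mm (`Inf` for a flat surface;
#'   curvature is `c = 1/R`).
#' @param conic conic constant k (unitless).
#' @param alpha2 4th-order even-polynomial coefficient, mm^-3.
#' @param alpha3 6th-order even-polynomial coefficient, mm^-5.
#' @param thickness axial distance to the next surface, mm (nonnegative).
#' @param material material name following the surface (e.g. "air", "PMMA").
#' @param name surface label.
#' @return an object of class `aspheric_surface`.
#' @export
aspheric_surface <- function(radius, conic = 0, alpha2 = 0, alpha3 = 0,
                             thickness = 0, material = "air", name = "") {
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) ||
      radius == 0)
    stop("`radius` must be a nonzero number (Inf for flat)")
  if (thickness < 0) stop("`thickness` must be nonnegative")
  structure(list(radius = radius, conic = conic, alpha2 = alpha2,
                 alpha3 = alpha3, thickness = thickness,
                 material = material, name = name),
            class = "aspheric_surface")
}

#' Sag of an even aspheric surface
#'
#' `z(r) = c r^2 / (1 + sqrt(1 - (1+k) c^2 r^2)) + alpha2 r^4 + alpha3 r^6`
#' with curvature `c = 1/R`. The conic square root restricts the usable
#' aperture: for `(1+k) c^2 > 0` the surface is only defined for
#' `r <= 1 / (c sqrt(1+k))`.
#'
#' @param s an [aspheric_surface].
#' @param r radial distance(s) from the optical axis, mm (vectorized).
#' @return sag z in mm, same length as `r`; `z(0) = 0` and `z(r) = z(-r)`.
#' @export
asphere_sag <- function(s, r) {
  if (!inherits(s, "aspheric_surface")) stop("`s` must be an aspheric_surface")
  cv <- if (is.infinite(s$radius)) 0 else 1 / s$radius
  arg <- 1 - (1 + s$conic) * cv^2 * r^2
  if (any(arg < 0)) {
    rmax <- 1 / (abs(cv) * sqrt(1 + s$conic))
    stop(sprintf(
      "aperture error: conic square root negative for |r| > %.4f mm (max requested %.4f mm)",
      rmax, max(abs(r))))
  }
  cv * r^2 / (1 + sqrt(arg)) + s$alpha2 * r^4 + s$alpha3 * r^6
}

#' Load an optical prescription from CSV
#'
#' The file must have columns `Surface`, `Material`, `Radius`, `Thickness`,
#' `Conic`, `alpha2`, `alpha3`. `Radius` accepts `Inf`/`infinity` for flat
#' surfaces; blank `Conic`/`alpha` cells default to 0; blank `Radius` on an
#' optical row is a schema error. A terminator row whose `Material` contains
#' "camera" marks the sensor-side end of the system and is stored as the
#' `terminator` attribute rather than as a surface. The bundled default is
#' the intraoral probe prescription.
#'
#' @param path CSV path; defaults to the bundled intraoral probe file.
#' @return an object of class `prescription`: a list of [aspheric_surface]
#'   in object-to-image order, with attribute `terminator`.
#' @export
load_prescription <- function(path = system.file(
  "extdata", "intraoral_prescription.csv", package = "oralscreen")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("Surface", "Material", "Radius", "Thickness", "Conic",
            "alpha2", "alpha3")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("prescription file missing column(s): ", paste(miss, collapse = ", "))
  term <- grepl("camera", df$Material, ignore.case = TRUE)
  terminator <- if (any(term)) df$Surface[term][1] else NULL
  df <- df[!term, , drop = FALSE]
  num <- function(x, field, default = NA_real_) {
    x <- trimws(x)
    out <- ifelse(x == "" | is.na(x), NA_real_,
                  suppressWarnings(as.numeric(
                    ifelse(tolower(x) %in% c("inf", "infinity"), "Inf", x))))
    bad <- !(x == "" | is.na(x)) & is.na(out)
    if (any(bad))
      stop(sprintf("non-numeric %s value '%s'", field, x[bad][1]))
    ifelse(is.na(out), default, out)
  }
  radius <- num(df$Radius, "Radius")
  if (any(is.na(radius)))
    stop("schema error: missing Radius for surface '",
         df$Surface[is.na(radius)][1], "'")
  thick <- num(df$Thickness, "Thickness", default = 0)
  if (any(thick < 0)) stop("thicknesses must be nonnegative")
  conic <- num(df$Conic, "Conic", default = 0)
  a2 <- num(df$alpha2, "alpha2", default = 0)
  a3 <- num(df$alpha3, "alpha3", default = 0)
  surf <- lapply(seq_len(nrow(df)), function(i)
    aspheric_surface(radius[i], conic[i], a2[i], a3[i], thick[i],
                     df$Material[i], name = df$Surface[i]))
  structure(surf, class = "prescription", terminator = terminator)
}

#' @export
print.prescription <- function(x, ...) {
  cat(sprintf("<prescription> %d surfaces (object -> image)\n", length(x)))
  for (s in x)
    cat(sprintf("  %-5s %-8s R=%-9.4g t=%-6.4g k=%-8.4g\n",
                s$name, s$material, s$radius, s$thickness, s$conic))
  if (!is.null(attr(x, "terminator")))
    cat(sprintf("  terminated by: surface %s (camera)\n",
                attr(x, "terminator")))
  invisible(x)
}

#' USAF 1951 target spatial frequency
#'
#' Element frequency in line pairs per mm: `f = 2^(group + (element-1)/6)`.
#'
#' @param group integer group number (may be negative).
#' @param element element number, 1 to 6.
#' @return frequency in lp/mm.
#' @examples
#' usaf_frequency(6, 2)   # ~71.8 lp/mm, the intraoral probe cutoff
#' @export
usaf_frequency <- function(group, element) {
  if (!is.numeric(element) || any(element < 1) || any(element > 6) ||
      any(element != round(element)))
    stop("`element` must be an integer in 1..6")
  2^(group + (element - 1) / 6)
}

#' Full line-pair period of a spatial frequency
#'
#' @param freq_lpmm frequency in lp/mm.
#' @return period (one bright + one dark bar) in micrometres.
#' @examples
#' line_pair_period_um(usaf_frequency(6, 2))  # ~14 um feature period
#' @export
line_pair_period_um <- function(freq_lpmm) 1000 / freq_lpmm

#' MTF curve container
#'
#' @param freq strictly increasing frequency axis starting at 0.
#' @param modulation modulation values; must equal 1 at zero frequency.
#' @param unit frequency unit label.
#' @return object of class `mtf_curve` (data frame columns `freq`,
#'   `modulation`).
#' @export
mtf_curve <- function(freq, modulation, unit = "cycles/pixel") {
  if (length(freq) != length(modulation)) stop("axis length mismatch")
  if (any(diff(freq) <= 0)) stop("frequencies must be strictly increasing")
  if (abs(freq[1]) > 1e-12 || abs(modulation[1] - 1) > 1e-9)
    stop("an MTF curve must start at (0, 1)")
  structure(data.frame(freq = freq, modulation = modulation),
            class = c("mtf_curve", "data.frame"), unit = unit)
}

#' Convert an MTF frequency axis from cycles/pixel to lp/mm
#'
#' @param curve an [mtf_curve] in cycles/pixel.
#' @param pixel_pitch_um sensor pixel pitch, micrometres.
#' @param magnification object-to-image magnification (object-side
#'   frequencies are image-side frequencies times |m|).
#' @return an [mtf_curve] in lp/mm at the object plane.
#' @export
mtf_to_lpmm <- function(curve, pixel_pitch_um, magnification = 1) {
  if (!inherits(curve, "mtf_curve")) stop("`curve` must be an mtf_curve")
  f <- curve$freq * 1000 / pixel_pitch_um * abs(magnification)
  mtf_curve(f, curve$modulation, unit = "lp/mm")
}

#' MTF from a measured point-spread function
#'
#' The MTF is the modulus of the discrete Fourier transform of the PSF,
#' normalized to 1 at zero frequency. For a 2-D PSF the rotationally
#' averaged radial profile is returned: modulus values are grouped into
#' radial frequency bins of width 1/N and each bin is reported at the mean
#' radius of its members.
#'
#' @param psf nonnegative numeric matrix (2-D PSF) or vector (1-D LSF) with
#'   a nonzero sum.
#' @return an [mtf_curve] in cycles/pixel (up to 0.5).
#' @export
mtf_from_psf <- function(psf) {
  if (inherits(psf, "oc_image")) psf <- as_pixel_matrix(psf, "psf")
  if (!is.numeric(psf)) stop("`psf` must be numeric")
  if (any(psf < 0)) stop("PSF values must be nonnegative")
  if (sum(psf) == 0) stop("all-zero PSF")
  if (is.matrix(psf)) {
    FT <- Mod(stats::fft(psf))
    FT <- FT / FT[1, 1]
    n1 <- nrow(psf); n2 <- ncol(psf)
    fx <- ifelse(seq_len(n1) - 1 > n1 / 2, (seq_len(n1) - 1 - n1), seq_len(n1) - 1) / n1
    fy <- ifelse(seq_len(n2) - 1 > n2 / 2, (seq_len(n2) - 1 - n2), seq_len(n2) - 1) / n2
    fr <- sqrt(outer(fx^2, fy^2, `+`))
    keep <- fr <= 0.5 + 1e-12
    n <- max(n1, n2)
    bin <- round(fr[keep] * n)
    mods <- as.numeric(tapply(FT[keep], bin, mean))
    freqs <- as.numeric(tapply(fr[keep], bin, mean))
    ord <- order(freqs)
    mtf_curve(freqs[ord], mods[ord] / mods[ord][1])
  } else {
    n <- length(psf)
    FT <- Mod(stats::fft(psf))
    FT <- FT / FT[1]
    k <- 0:floor(n / 2)
    mtf_curve(k / n, FT[k + 1])
  }
}

#' Slanted-edge MTF estimate
#'
#' Implements the standard slanted-edge procedure: the edge is located by
#' per-row centroid regression of the derivative of each row profile; pixel
#' centers are projected onto the edge normal and binned at
#' `oversample`-times the pixel pitch to form an oversampled edge-spread
#' function (ESF); the line-spread function (LSF) is the central finite
#' difference of the ESF under a Hamming apodization window; and the MTF is
#' the modulus of the normalized Fourier transform of the LSF. The known
#' transfer functions of the analysis chain itself (the bin-averaging box
#' and the finite-difference derivative filter) are divided out. The
#' frequency axis is in cycles per original pixel along the edge normal.
#'
#' @param roi numeric matrix or grayscale [oc_image] containing one
#'   near-vertical or near-horizontal edge, ideally 2-15 degrees off axis.
#' @param oversample ESF binning factor (default 4).
#' @param contrast_floor minimum 10-90% intensity spread for edge detection.
#' @return an [mtf_curve] (frequencies up to 1 cycle/pixel) with attributes
#'   `angle_deg` and `flagged` (TRUE when the edge angle is outside the
#'   recommended range).
#' @export
slanted_edge_mtf <- function(roi, oversample = 4L, contrast_floor = 0.05) {
  m <- as_pixel_matrix(roi, "roi")
  if (oversample < 1) stop("`oversample` must be >= 1")
  q <- stats::quantile(m, c(0.1, 0.9), names = FALSE)
  if (diff(q) < contrast_floor)
    stop("no edge detected: ROI contrast below floor")
  # orient so the edge is near-vertical (strong gradient across columns)
  gx <- mean(abs(m[, -1] - m[, -ncol(m)]))
  gy <- mean(abs(m[-1, ] - m[-nrow(m), ]))
  if (gy > gx) m <- t(m)
  nr <- nrow(m); nc <- ncol(m)
  # per-row edge centroid from the absolute row derivative
  pos <- rep(NA_real_, nr)
  xmid <- seq_len(nc - 1) + 0.5
  for (r in seq_len(nr)) {
    d <- abs(diff(m[r, ]))
    s <- sum(d)
    if (s > 0) pos[r] <- sum(xmid * d) / s
  }
  ok <- is.finite(pos)
  if (sum(ok) < max(4, nr / 2)) stop("no edge detected: centroid trace failed")
  fit <- stats::lm.fit(cbind(1, which(ok)), pos[ok])
  a <- unname(fit$coefficients[1]); b <- unname(fit$coefficients[2])
  angle <- atan(abs(b)) * 180 / pi
  flagged <- FALSE
  if (angle < 2 || angle > 15) {
    warning(sprintf("edge angle %.2f deg outside the recommended 2-15 deg range",
                    angle))
    flagged <- TRUE
  }
  cosO <- 1 / sqrt(1 + b^2)
  # signed distance of every pixel center from the edge, along the normal
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  u <- (cols - (a + b * rows)) * cosO
  delta <- 1 / oversample
  bin <- round(as.numeric(u) / delta)
  esf_t <- tapply(as.numeric(m), bin, mean)
  kidx <- as.integer(names(esf_t))
  # keep the widest contiguous run of populated bins around the edge
  full <- seq(min(kidx), max(kidx))
  esf <- rep(NA_real_, length(full))
  esf[match(kidx, full)] <- esf_t
  if (anyNA(esf)) {                     # fill isolated empty bins
    nas <- which(is.na(esf))
    esf[nas] <- stats::approx(full[!is.na(esf)], esf[!is.na(esf)],
                              xout = full[nas], rule = 2)$y
  }
  n <- length(esf)
  if (n < 8 * oversample) stop("ROI too small for a stable ESF")
  # LSF by central differences, Hamming apodization
  lsf <- c(0, (esf[3:n] - esf[1:(n - 2)]) / (2 * delta), 0)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  lsfw <- lsf * w
  FT <- Mod(stats::fft(lsfw))
  if (FT[1] == 0) stop("degenerate LSF (zero net edge step)")
  FT <- FT / FT[1]
  k <- 0:floor(n / 2)
  f <- k / (n * delta)                  # cycles per original pixel
  keep <- f <= 1 + 1e-12
  f <- f[keep]; FT <- FT[k[keep] + 1]
  # divide out the analysis chain: bin box average and derivative filter
  sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
  corr_bin <- sinc(f * delta)
  dd <- 2 * pi * f * delta
  corr_diff <- ifelse(abs(dd) < 1e-12, 1, sin(dd) / dd)
  corr <- pmax(corr_bin * corr_diff, 0.15)
  mod <- FT / corr
  mod[1] <- 1
  out <- mtf_curve(f, mod)
  attr(out, "angle_deg") <- angle
  attr(out, "flagged") <- flagged
  out
}

#' Average several MTF curves
#'
#' Curves are linearly resampled onto the frequency grid of the first curve,
#' restricted to the range all curves cover, and averaged pointwise. The
#' same operation serves for ROI averaging along an edge and for
#' sagittal/tangential averaging.
#'
#' @param curves list of [mtf_curve] objects (at least one).
#' @return an [mtf_curve].
#' @export
average_mtf <- function(curves) {
  if (!length(curves)) stop("empty curve list")
  if (!all(vapply(curves, inherits, TRUE, "mtf_curve")))
    stop("all elements must be mtf_curve objects")
  fmax <- min(vapply(curves, function(cu) max(cu$freq), 0))
  grid <- curves[[1]]$freq[curves[[1]]$freq <= fmax + 1e-12]
  vals <- vapply(curves, function(cu)
    stats::approx(cu$freq, cu$modulation, xout = grid)$y, numeric(length(grid)))
  avg <- if (is.matrix(vals)) rowMeans(vals) else vals
  avg[1] <- 1
  mtf_curve(grid, avg, unit = attr(curves[[1]], "unit"))
}

#' Illumination uniformity by coefficient of variation
#'
#' `uniformity = 1 - cv = 1 - sigma / xbar`, where `sigma` is the sample
#' (N-1 denominator) standard deviation of the in-ROI pixels and `xbar`
#' their mean. When a relative-illumination map is supplied the flat-field
#' frame is divided by it first, removing the imaging system's own
#' vignetting so only the illumination nonuniformity is scored. The score is
#' invariant under any positive rescaling of the frame.
#'
#' @param flat numeric matrix or grayscale [oc_image] of the flat-field
#'   frame.
#' @param roi logical mask; defaults to the central 80% (linear) of the
#'   frame.
#' @param ri_map optional relative-illumination map, same shape, strictly
#'   positive inside the ROI.
#' @return object of class `uniformity_result`: `uniformity`, `cv`, `mean`,
#'   `sd`, `n`.
#' @export
uniformity <- function(flat, roi = NULL, ri_map = NULL) {
  m <- as_pixel_matrix(flat, "flat")
  if (is.null(roi)) roi <- central_roi(dim(m))
  check_mask(roi, dim(m))
  if (!is.null(ri_map)) {
    ri <- as_pixel_matrix(ri_map, "ri_map")
    if (!identical(dim(ri), dim(m))) stop("ri_map shape mismatch")
    if (any(ri[roi] <= 0)) stop("ri_map must be strictly positive in the ROI")
    m <- m / ri
  }
  x <- m[roi]
  xb <- mean(x)
  if (xb == 0) stop("zero mean intensity in ROI; uniformity undefined")
  s <- stats::sd(x)
  cv <- s / xb
  structure(list(uniformity = 1 - cv, cv = cv, mean = xb, sd = s,
                 n = length(x)),
            class = "uniformity_result")
}

#' @export
print.uniformity_result <- function(x, ...) {
  cat(sprintf("<uniformity> %.4f (cv %.4f over %d px)\n",
              x$uniformity, x$cv, x$n))
  invisible(x)
}

#' Central rectangular ROI mask
#'
#' @param shape image dimensions `c(rows, cols)`.
#' @param fraction linear fraction of each dimension retained (default 0.8).
#' @return logical matrix.
#' @export
central_roi <- function(shape, fraction = 0.8) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  h <- shape[1]; w <- shape[2]
  mr <- round(h * (1 - fraction) / 2); mc <- round(w * (1 - fraction) / 2)
  m <- matrix(FALSE, h, w)
  m[(mr + 1):(h - mr), (mc + 1):(w - mc)] <- TRUE
  m
}

#' Write an MTF curve as two-column CSV
#'
#' @param curve an [mtf_curve].
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_mtf <- function(curve, path) {
  if (!inherits(curve, "mtf_curve")) stop("`curve` must be an mtf_curve")
  utils::write.csv(data.frame(freq = curve$freq,
                              modulation = curve$modulation),
                   path, row.names = FALSE)
  invisible(path)
}
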