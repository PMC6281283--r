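#' Green-channel mean-subtraction map
#'
#' Dysplastic oral mucosa shows reduced green autofluorescence under 405 nm
#' excitation. Subtracting the mean green intensity from the green channel
#' yields a signed map in which areas of decreased fluorescence are negative,
#' giving the reviewing specialist a direct rendition of the fluorescence
#' deficit. The map is invariant under any additive offset of the green
#' channel, so global exposure shifts cancel.
#'
#' @param afi RGB autofluorescence [oc_image].
#' @param mask logical analysis mask (see [default_mask]); the mean is taken
#'   over mask pixels and out-of-mask pixels are set to 0 for display.
#' @return an object of class `green_map` with fields `map` (signed matrix)
#'   and `mean_used` (the subtracted scalar).
#' @export
green_mean_subtraction <- function(afi, mask = NULL) {
  if (!inherits(afi, "oc_image") || !is_rgb(afi))
    stop("`afi` must be an RGB oc_image")
  if (is.null(mask)) mask <- default_mask(afi)
  check_mask(mask, dim(afi$pixels))
  g <- afi$pixels[, , 2]
  mu <- mean(g[mask])
  out <- g - mu
  out[!mask] <- 0
  structure(list(map = out, mean_used = mu), class = "green_map")
}

#' Red/green autofluorescence ratio map
#'
#' Porphyrin accumulation in neoplastic tissue adds a 635 nm (red) emission
#' peak while green fluorescence drops, so the pixel-wise red-to-green ratio
#' rises over suspicious tissue. A small stabilizer `eps` keeps the ratio
#' finite where the green channel underflows.
#'
#' @param afi RGB autofluorescence [oc_image].
#' @param eps positive stabilizer added to the green channel (default 1e-6).
#' @return an object of class `ratio_map` with fields `map` (nonnegative
#'   matrix) and `eps`.
#' @export
rg_ratio_map <- function(afi, eps = 1e-6) {
  if (!inherits(afi, "oc_image") || !is_rgb(afi))
    stop("`afi` must be an RGB oc_image")
  if (!is.numeric(eps) || eps <= 0) stop("`eps` must be positive")
  m <- afi$pixels[, , 1] / (afi$pixels[, , 2] + eps)
  structure(list(map = m, eps = eps), class = "ratio_map")
}

#' On-device suspicious / not-suspicious call from the ratio map
#'
#' A pixel is flagged when its red/green ratio exceeds `pixel_factor` times
#' the in-mask median ratio; the site is called suspicious when the flagged
#' fraction of the mask reaches `area_threshold`. The pixel rule is relative
#' to the median rather than absolute so it survives illumination and
#' exposure changes, and the median is robust to the lesion's own pixels.
#' The default multiplier (1.5) and area fraction (0.02) are package choices.
#'
#' @param ratio a [rg_ratio_map] result.
#' @param mask logical analysis mask.
#' @param pixel_factor positive multiplier on the in-mask median ratio.
#' @param area_threshold flagged-area fraction in (0, 1) that triggers the
#'   suspicious call.
#' @return an object of class `afi_result`: `label`
#'   (`"suspicious"`/`"not_suspicious"`), `flagged_fraction`, `flagged`
#'   (logical matrix), `pixel_threshold`, and the thresholds used.
#' @export
classify_afi <- function(ratio, mask, pixel_factor = 1.5,
                         area_threshold = 0.02) {
  if (!inherits(ratio, "ratio_map")) stop("`ratio` must be a ratio_map")
  check_mask(mask, dim(ratio$map))
  if (!is.numeric(pixel_factor) || pixel_factor <= 0)
    stop("`pixel_factor` must be positive")
  if (!is.numeric(area_threshold) || area_threshold <= 0 ||
      area_threshold >= 1)
    stop("`area_threshold` must lie in (0, 1)")
  vals <- ratio$map[mask]
  if (all(vals == 0))
    stop("degenerate ratio map: all in-mask ratios are zero")
  med <- stats::median(vals)
  thr <- pixel_factor * med
  flagged <- ratio$map > thr & mask
  ff <- sum(flagged) / sum(mask)
  structure(list(
    label = if (ff >= area_threshold) "suspicious" else "not_suspicious",
    flagged_fraction = ff,
    flagged = flagged,
    pixel_threshold = thr,
    pixel_factor = pixel_factor,
    area_threshold = area_threshold
  ), class = "afi_result")
}

#' @export
print.afi_result <- function(x, ...) {
  cat(sprintf("<afi_result> %s (flagged %.2f%% of mask, threshold %.2f%%)\n",
              x$label, 100 * x$flagged_fraction, 100 * x$area_threshold))
  invisible(x)
}

#' Summary features of an AFI frame for the baseline classifier
#'
#' Returns, in fixed order: mean red/green ratio, 95th-percentile ratio
#' (type-7 quantile), flagged fraction at the [classify_afi] defaults, mean
#' green deficit (minus the mean of negative mean-subtraction values; 0 when
#' none are negative), and the green coefficient of variation, all over the
#' pair's mask.
#'
#' @param pair an [image_pair].
#' @param eps ratio stabilizer, see [rg_ratio_map].
#' @param pixel_factor,area_threshold thresholds passed to [classify_afi].
#' @return named numeric vector of length 5:
#'   `mean_ratio`, `p95_ratio`, `flagged_fraction`, `green_deficit`,
#'   `green_cv`.
#' @export
extract_afi_features <- function(pair, eps = 1e-6, pixel_factor = 1.5,
                                 area_threshold = 0.02) {
  if (!inherits(pair, "image_pair")) stop("`pair` must be an image_pair")
  mask <- pair$mask
  check_mask(mask, dim(pair$afi$pixels))
  ratio <- rg_ratio_map(pair$afi, eps = eps)
  rv <- ratio$map[mask]
  res <- classify_afi(ratio, mask, pixel_factor = pixel_factor,
                      area_threshold = area_threshold)
  gm <- green_mean_subtraction(pair$afi, mask)
  neg <- gm$map[mask]
  neg <- neg[neg < 0]
  deficit <- if (length(neg)) -mean(neg) else 0
  g <- pair$afi$pixels[, , 2][mask]
  gcv <- if (mean(g) > 0) stats::sd(g) / mean(g) else 0
  c(mean_ratio = mean(rv),
    p95_ratio = unname(stats::quantile(rv, 0.95, names = FALSE)),
    flagged_fraction = res$flagged_fraction,
    green_deficit = deficit,
    green_cv = gcv)
}

#' Export a signed green map as an image or CSV
#'
#' Signed values are offset by +0.5 for image export so a zero deficit maps
#' to mid-gray; values are clipped to `[0, 1]` after the offset.
#'
#' @param gm a [green_mean_subtraction] result.
#' @param path output path: `.png`/`.tif` for an offset image, `.csv` for the
#'   raw signed values.
#' @param bit_depth bit depth for image export (16 recommended; 16 requires
#'   a TIFF path).
#' @return `path`, invisibly.
#' @export
write_green_map <- function(gm, path, bit_depth = 8L) {
  if (!inherits(gm, "green_map")) stop("`gm` must be a green_map")
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(gm$map, path, row.names = FALSE)
  } else {
    v <- pmin(pmax(gm$map + 0.5, 0), 1)
    write_image(oc_image(v, bit_depth = bit_depth), path)
  }
  invisible(path)
}
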