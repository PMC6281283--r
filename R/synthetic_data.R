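#' Parameters of the synthetic oral-tissue phantom
#'
#' The phantom emulates the photometric signatures the screening method
#' relies on: under violet excitation, dysplastic lesions lose green
#' autofluorescence (multiplicative attenuation) and gain a red porphyrin
#' emission (additive boost); a hyperkeratotic confound instead *increases*
#' green fluorescence and carries no porphyrin signal, which is what makes
#' it hard for a red/green classifier. Illumination falls off as a smooth
#' radial Gaussian vignette common to both channels, and sensor noise is
#' additive Gaussian. Defaults are package choices for a testable, plausible
#' phantom; no quantitative lesion-contrast values are taken from clinical
#' data.
#'
#' @param size frame size `c(rows, cols)` in pixels.
#' @param base_green baseline green fluorescence level (unit scale).
#' @param base_red baseline red fluorescence level.
#' @param base_blue residual blue level.
#' @param vignette_strength fractional illumination falloff at the frame
#'   corner, in `[0, 1)`.
#' @param lesion_count integer range `c(min, max)` of lesions per suspicious
#'   case.
#' @param lesion_radius_frac range of lesion semi-axes as a fraction of the
#'   short frame side.
#' @param attenuation multiplicative green attenuation inside dysplastic
#'   lesions, strictly in (0, 1).
#' @param red_boost additive red (porphyrin) level inside dysplastic
#'   lesions, nonnegative.
#' @param hyperkeratosis_prob probability that a suspicious case presents
#'   as hyperkeratotic (brightened green, no red boost), in `[0, 1]`.
#' @param hyper_green_gain green gain of hyperkeratotic lesions (> 1).
#' @param noise_sd additive Gaussian sensor-noise standard deviation.
#' @return an object of class `tissue_params`.
#' @export
tissue_params <- function(size = c(128L, 128L),
                          base_green = 0.55,
                          base_red = 0.15,
                          base_blue = 0.06,
                          vignette_strength = 0.35,
                          lesion_count = c(1L, 2L),
                          lesion_radius_frac = c(0.10, 0.20),
                          attenuation = 0.55,
                          red_boost = 0.20,
                          hyperkeratosis_prob = 0.05,
                          hyper_green_gain = 1.35,
                          noise_sd = 0.01) {
  stopifnot(length(size) == 2L, all(size >= 16),
            base_green > 0, base_green <= 1,
            base_red >= 0, base_red <= 1,
            vignette_strength >= 0, vignette_strength < 1,
            length(lesion_count) == 2L,
            lesion_count[1] <= lesion_count[2], lesion_count[1] >= 0,
            length(lesion_radius_frac) == 2L,
            lesion_radius_frac[1] > 0,
            lesion_radius_frac[2] < 0.5,
            red_boost >= 0, hyper_green_gain > 1,
            hyperkeratosis_prob >= 0, hyperkeratosis_prob <= 1,
            noise_sd >= 0)
  if (attenuation <= 0 || attenuation >= 1)
    stop("`attenuation` must lie strictly in (0, 1)")
  structure(list(size = as.integer(size), base_green = base_green,
                 base_red = base_red, base_blue = base_blue,
                 vignette_strength = vignette_strength,
                 lesion_count = as.integer(lesion_count),
                 lesion_radius_frac = lesion_radius_frac,
                 attenuation = attenuation, red_boost = red_boost,
                 hyperkeratosis_prob = hyperkeratosis_prob,
                 hyper_green_gain = hyper_green_gain,
                 noise_sd = noise_sd),
            class = "tissue_params")
}

# radial Gaussian vignette: 1 at center, (1 - strength) at the corner
vignette_field <- function(h, w, strength) {
  if (strength <= 0) return(matrix(1, h, w))
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r2 <- outer(((seq_len(h) - cy))^2, ((seq_len(w) - cx))^2, `+`)
  rmax2 <- max(r2)
  sig2 <- -rmax2 / (2 * log(1 - strength))
  exp(-r2 / (2 * sig2))
}

ellipse_mask <- function(h, w, cy, cx, ry, rx, phi) {
  y <- matrix(seq_len(h) - cy, h, w)
  x <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  u <- x * cos(phi) + y * sin(phi)
  v <- -x * sin(phi) + y * cos(phi)
  (u / rx)^2 + (v / ry)^2 <= 1
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate one synthetic WLI/AFI tissue pair with ground truth
#'
#' A pure function of `(params, seed)`: the same inputs regenerate
#' bit-identical arrays. Suspicious cases carry 1+ elliptical lesions whose
#' exact pixel mask is returned; with probability
#' `params$hyperkeratosis_prob` a suspicious case presents as
#' hyperkeratotic (green gain instead of attenuation, no porphyrin boost)
#' and is labelled tobacco pouch keratosis. The WLI frame is a cosmetic
#' reflectance rendering (reddened lesion tint under the same vignette);
#' classifier features are derived from the AFI frame only.
#'
#' @param params a [tissue_params]; set `lesion_count = c(0, 0)` for a
#'   normal-class case.
#' @param seed integer seed.
#' @param case_id optional case id (default derived from the seed).
#' @return an object of class `synthetic_case`: `pair` ([image_pair]),
#'   `lesion_mask` (exact logical matrix), `class`
#'   (`"suspicious"`/`"normal"`), `diagnosis`, `hyperkeratotic`, `seed`.
#' @export
generate_tissue_pair <- function(params = tissue_params(), seed = 1L,
                                 case_id = NULL) {
  if (!inherits(params, "tissue_params")) stop("`params` must be tissue_params")
  h <- params$size[1]; w <- params$size[2]
  if (is.null(case_id)) case_id <- sprintf("synth-%06d", seed %% 1000000L)
  with_seed(seed, {
    nles <- if (params$lesion_count[2] == 0) 0L else
      sample(params$lesion_count[1]:params$lesion_count[2], 1L)
    lesion <- matrix(FALSE, h, w)
    short <- min(h, w)
    for (i in seq_len(nles)) {
      ry <- stats::runif(1, params$lesion_radius_frac[1],
                         params$lesion_radius_frac[2]) * short
      rx <- stats::runif(1, params$lesion_radius_frac[1],
                         params$lesion_radius_frac[2]) * short
      if (2 * max(rx, ry) > min(h, w))
        stop("lesion larger than frame")
      cy <- stats::runif(1, 0.25 * h, 0.75 * h)
      cx <- stats::runif(1, 0.25 * w, 0.75 * w)
      phi <- stats::runif(1, 0, pi)
      lesion <- lesion | ellipse_mask(h, w, cy, cx, ry, rx, phi)
    }
    hyper <- nles > 0 && stats::runif(1) < params$hyperkeratosis_prob
    G <- matrix(params$base_green, h, w)
    R <- matrix(params$base_red, h, w)
    B <- matrix(params$base_blue, h, w)
    if (nles > 0) {
      if (hyper) {
        G[lesion] <- G[lesion] * params$hyper_green_gain
      } else {
        G[lesion] <- G[lesion] * params$attenuation
        R[lesion] <- R[lesion] + params$red_boost
      }
    }
    vg <- vignette_field(h, w, params$vignette_strength)
    noise <- function() matrix(stats::rnorm(h * w, 0, params$noise_sd), h, w)
    afi <- array(0, dim = c(h, w, 3))
    afi[, , 1] <- clip01(R * vg + noise())
    afi[, , 2] <- clip01(G * vg + noise())
    afi[, , 3] <- clip01(B * vg + noise())
    # cosmetic reflectance rendering: pink mucosa, reddened / keratotic tint
    wr <- matrix(0.78, h, w); wg <- matrix(0.50, h, w); wb <- matrix(0.46, h, w)
    if (nles > 0) {
      if (hyper) {                      # whitened keratotic plaque
        wr[lesion] <- wr[lesion] + 0.10
        wg[lesion] <- wg[lesion] + 0.12
        wb[lesion] <- wb[lesion] + 0.12
      } else {                          # erythematous tint
        wr[lesion] <- wr[lesion] + 0.08
        wg[lesion] <- wg[lesion] - 0.08
        wb[lesion] <- wb[lesion] - 0.05
      }
    }
    wli <- array(0, dim = c(h, w, 3))
    wli[, , 1] <- clip01(wr * vg + noise())
    wli[, , 2] <- clip01(wg * vg + noise())
    wli[, , 3] <- clip01(wb * vg + noise())
    diagnosis <- if (nles == 0) "normal/variation"
    else if (hyper) "tobacco pouch keratosis"
    else sample(setdiff(SUSPICIOUS_DIAGNOSES, "tobacco pouch keratosis"), 1L)
    pair <- image_pair(oc_image(wli), oc_image(afi), case_id = case_id,
                       site = "buccal mucosa")
    structure(list(pair = pair, lesion_mask = lesion,
                   class = if (nles > 0) "suspicious" else "normal",
                   diagnosis = diagnosis, hyperkeratotic = hyper,
                   seed = seed, params = params),
              class = "synthetic_case")
  })
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case> %s: %s (%s)%s, seed %d\n",
              x$pair$case_id, x$class, x$diagnosis,
              if (x$hyperkeratotic) " [hyperkeratotic]" else "", x$seed))
  invisible(x)
}

#' Generate a synthetic screening cohort
#'
#' Draws `round(n * class_mix)` suspicious and the remainder normal cases,
#' assigns each a diagnosis label from the study vocabulary consistent with
#' its class (so [assign_class] round-trips), and optionally writes images
#' plus a manifest CSV. Deterministic in `(params, seed)`.
#'
#' @param n number of cases (>= 2).
#' @param class_mix fraction of suspicious cases, strictly in (0, 1); both
#'   classes must be non-empty at the given `n`.
#' @param params a [tissue_params] for the suspicious cases; normal cases
#'   use the same parameters with the lesion count zeroed.
#' @param seed integer seed.
#' @param dir optional output directory; when given, WLI/AFI PNGs and
#'   `manifest.csv` are written there.
#' @return list with `cases` (list of [generate_tissue_pair] results) and
#'   `manifest` (data frame: case_id, site, class, diagnosis,
#'   hyperkeratotic, seed, and file paths when written).
#' @export
generate_cohort <- function(n, class_mix = 0.5, params = tissue_params(),
                            seed = 1L, dir = NULL) {
  if (n < 2) stop("`n` must be at least 2")
  if (class_mix <= 0 || class_mix >= 1) stop("`class_mix` must be in (0, 1)")
  n_susp <- round(n * class_mix)
  if (n_susp < 1 || n_susp > n - 1)
    stop("degenerate class mix: one class would be empty")
  normal_params <- params
  normal_params$lesion_count <- c(0L, 0L)
  plan <- with_seed(seed, {
    cls <- sample(c(rep("suspicious", n_susp), rep("normal", n - n_susp)))
    list(cls = cls, seeds = sample.int(.Machine$integer.max - 1L, n))
  })
  cases <- lapply(seq_len(n), function(i)
    generate_tissue_pair(
      if (plan$cls[i] == "suspicious") params else normal_params,
      seed = plan$seeds[i], case_id = sprintf("case-%04d", i)))
  manifest <- data.frame(
    case_id = vapply(cases, function(x) x$pair$case_id, ""),
    site = vapply(cases, function(x) x$pair$site, ""),
    class = vapply(cases, function(x) x$class, ""),
    diagnosis = vapply(cases, function(x) x$diagnosis, ""),
    hyperkeratotic = vapply(cases, function(x) x$hyperkeratotic, TRUE),
    seed = vapply(cases, function(x) x$seed, 1L),
    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest$wli_path <- file.path(dir, paste0(manifest$case_id, "_wli.png"))
    manifest$afi_path <- file.path(dir, paste0(manifest$case_id, "_afi.png"))
    for (i in seq_len(n)) {
      write_image(cases[[i]]$pair$wli, manifest$wli_path[i])
      write_image(cases[[i]]$pair$afi, manifest$afi_path[i])
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(cases = cases, manifest = manifest)
}

#' Render a synthetic 24-patch color checker
#'
#' @param patch_colors 24 x 3 matrix (or data frame with columns R, G, B) of
#'   patch RGB values in `[0, 1]`, in row-major 4 x 6 order; defaults to the
#'   bundled synthetic reference table.
#' @param cell_size square patch edge in pixels.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return list with `image` (RGB [oc_image]) and `grid` (the geometry data
#'   frame accepted by [measure_patches]).
#' @export
generate_checker <- function(patch_colors = NULL, cell_size = 64L,
                             noise_sd = 0, seed = 1L) {
  if (is.null(patch_colors)) {
    ref <- read_patch_reference()
    patch_colors <- as.matrix(ref[, c("R", "G", "B")])
  }
  patch_colors <- as.matrix(patch_colors)
  if (nrow(patch_colors) != 24L || ncol(patch_colors) != 3L)
    stop("`patch_colors` must be 24 x 3")
  cs <- as.integer(cell_size)
  img <- array(0, dim = c(4L * cs, 6L * cs, 3L))
  grid <- data.frame(patch_id = seq_len(24L), row0 = 0L, row1 = 0L,
                     col0 = 0L, col1 = 0L)
  for (p in seq_len(24L)) {
    r <- (p - 1L) %/% 6L; c <- (p - 1L) %% 6L
    rows <- (r * cs + 1L):((r + 1L) * cs)
    cols <- (c * cs + 1L):((c + 1L) * cs)
    for (ch in 1:3) img[rows, cols, ch] <- patch_colors[p, ch]
    grid[p, 2:5] <- c(rows[1], rows[cs], cols[1], cols[cs])
  }
  if (noise_sd > 0)
    img <- with_seed(seed,
                     clip01(img + array(stats::rnorm(length(img), 0, noise_sd),
                                        dim = dim(img))))
  list(image = oc_image(img), grid = grid)
}

#' Closed-form MTF of a Gaussian-blurred, pixel-sampled edge
#'
#' `MTF(f) = exp(-2 pi^2 sigma^2 f^2) * |sinc(f)|` with f in cycles/pixel:
#' the Gaussian optical blur times the pixel-aperture sinc.
#'
#' @param f frequency in cycles/pixel.
#' @param sigma Gaussian blur standard deviation in pixels (0 = none).
#' @return modulation values.
#' @export
edge_mtf_oracle <- function(f, sigma) {
  s <- ifelse(abs(f) < 1e-12, 1, sin(pi * f) / (pi * f))
  exp(-2 * pi^2 * sigma^2 * f^2) * abs(s)
}

#' Generate a synthetic slanted-edge target
#'
#' Renders an analytically antialiased edge: the scene is a step blurred by
#' an isotropic Gaussian (error-function profile) and each pixel integrates
#' the profile over its aperture (approximated by a dense subpixel grid).
#' The true system MTF is therefore the closed form of [edge_mtf_oracle].
#'
#' @param angle edge tilt from vertical, degrees, in (0, 45).
#' @param blur_sigma Gaussian blur sigma in pixels (0 for a sharp edge).
#' @param contrast edge step height (bright minus dark level).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param size frame `c(rows, cols)`.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param low dark-side level.
#' @param supersample subpixel grid order for the pixel-aperture integral.
#' @return list with `image` (grayscale [oc_image]), `sigma`, `angle`, and
#'   `oracle` (function of frequency in cycles/pixel).
#' @export
generate_edge <- function(angle = 5, blur_sigma = 2, contrast = 0.8,
                          noise_sd = 0, size = c(96L, 128L), seed = 1L,
                          low = 0.1, supersample = 8L) {
  if (angle <= 0 || angle >= 45) stop("`angle` must be in (0, 45) degrees")
  h <- size[1]; w <- size[2]
  th <- angle * pi / 180
  # edge line through the frame center; bright side at larger x
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  off <- (seq_len(supersample) - (supersample + 1) / 2) / supersample
  sub <- as.matrix(expand.grid(dy = off, dx = off))
  acc <- matrix(0, h, w)
  ys <- matrix(seq_len(h), h, w)
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(nrow(sub))) {
    x <- xs + sub[i, "dx"]; y <- ys + sub[i, "dy"]
    d <- (x - cx) * cos(th) - (y - cy) * sin(th)   # signed normal distance
    s <- if (blur_sigma > 0) stats::pnorm(d / blur_sigma)
    else as.numeric(d >= 0)
    acc <- acc + s
  }
  img <- low + contrast * acc / nrow(sub)
  if (noise_sd > 0)
    img <- with_seed(seed,
                     img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w))
  img <- clip01(img)
  list(image = oc_image(img), sigma = blur_sigma, angle = angle,
       oracle = function(f) edge_mtf_oracle(f, blur_sigma))
}

#' Generate an LED flat-field frame with an exact uniformity oracle
#'
#' Irradiance at each pixel is the sum over LEDs of
#' `cos(theta)^m * cos(theta) / d^2` contributions (a Lambertian-type
#' emitter of order `m` pointing at the target plane, with the inverse
#' square and obliquity factors), mirroring a plane-symmetric LED layout.
#' The exact coefficient of variation of the noiseless field is returned as
#' an oracle for [uniformity].
#'
#' @param led_positions matrix with columns `x`, `y` of LED positions in the
#'   target plane's coordinates (same units as `height`); defaults to three
#'   plane-symmetric pairs.
#' @param falloff_m Lambertian exponent m (0 = isotropic over the cone).
#' @param size frame `c(rows, cols)` in pixels.
#' @param height LED standoff distance from the target plane.
#' @param extent physical half-width of the imaged area (the frame spans
#'   `[-extent, extent]` in x).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return list with `image` (grayscale [oc_image], noise included),
#'   `field` (noiseless matrix), and `cv_true` (coefficient of variation of
#'   the noiseless field over the full frame).
#' @export
generate_flatfield <- function(led_positions = NULL, falloff_m = 1,
                               size = c(64L, 64L), height = 30,
                               extent = 12, noise_sd = 0, seed = 1L) {
  if (is.null(led_positions))
    led_positions <- cbind(x = c(-10, -10, -10, 10, 10, 10),
                           y = c(-8, 0, 8, -8, 0, 8))
  led_positions <- as.matrix(led_positions)
  if (nrow(led_positions) < 1) stop("at least one LED is required")
  h <- size[1]; w <- size[2]
  xs <- seq(-extent, extent, length.out = w)
  ys <- seq(-extent * h / w, extent * h / w, length.out = h)
  X <- matrix(xs, h, w, byrow = TRUE)
  Y <- matrix(ys, h, w)
  E <- matrix(0, h, w)
  for (i in seq_len(nrow(led_positions))) {
    dx <- X - led_positions[i, 1]; dy <- Y - led_positions[i, 2]
    d2 <- dx^2 + dy^2 + height^2
    cosT <- height / sqrt(d2)
    E <- E + cosT^(falloff_m + 1) / d2
  }
  field <- E / max(E) * 0.9
  cv_true <- stats::sd(field) / mean(field)
  img <- field
  if (noise_sd > 0)
    img <- with_seed(seed,
                     img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w))
  list(image = oc_image(clip01(img)), field = field, cv_true = cv_true)
}
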