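#' Open (or create) a flat-directory case store
#'
#' Cases live as one JSON record each under `dir`, with image files in an
#' `images/` subdirectory and per-case analysis output under `reports/`.
#'
#' @param dir store directory; created if absent.
#' @return an object of class `case_store`.
#' @export
case_store <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  dir.create(file.path(dir, "reports"), showWarnings = FALSE)
  structure(list(dir = dir), class = "case_store")
}

case_path <- function(store, case_id) file.path(store$dir,
                                                paste0(case_id, ".json"))

normalize_metadata <- function(metadata) {
  md <- as.list(metadata)
  if (!is.null(md$habit)) {
    habit <- tolower(md$habit)
    md$smoking <- habit %in% c("smoking", "both")
    md$chewing <- habit %in% c("chewing", "both")
    md$habit <- NULL
  }
  md
}

#' Create a new screening case
#'
#' @param store a [case_store].
#' @param case_id unique case identifier within the store.
#' @param metadata named list of patient metadata (age in years, sex, habit
#'   flags). A `habit` field of `"smoking"`, `"chewing"`, `"both"` or
#'   `"none"` is expanded into `smoking`/`chewing` logical flags (`"both"`
#'   sets both).
#' @param resume reopen an existing record instead of erroring on a
#'   duplicate id.
#' @return the case record (named list), invisibly persisted as JSON.
#' @export
new_case <- function(store, case_id, metadata = list(), resume = FALSE) {
  if (!inherits(store, "case_store")) stop("`store` must be a case_store")
  p <- case_path(store, case_id)
  if (file.exists(p)) {
    if (!resume)
      stop(sprintf("case '%s' already exists (use resume = TRUE to reopen)",
                   case_id))
    return(load_case(store, case_id))
  }
  rec <- list(case_id = case_id,
              metadata = normalize_metadata(metadata),
              sites = list(),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  save_case(store, rec)
  rec
}

save_case <- function(store, rec) {
  jsonlite::write_json(rec, case_path(store, rec$case_id),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(rec)
}

#' @rdname new_case
#' @export
load_case <- function(store, case_id) {
  p <- case_path(store, case_id)
  if (!file.exists(p)) stop(sprintf("no case '%s' in store", case_id))
  jsonlite::read_json(p, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}

#' Attach a WLI/AFI pair to a case
#'
#' Writes both frames into the store's image directory and records their
#' paths on the case.
#'
#' @param store a [case_store].
#' @param case_id existing case id.
#' @param pair an [image_pair].
#' @return the updated case record, invisibly.
#' @export
add_image_pair <- function(store, case_id, pair) {
  rec <- load_case(store, case_id)
  if (!inherits(pair, "image_pair")) stop("`pair` must be an image_pair")
  stem <- file.path(store$dir, "images",
                    sprintf("%s_%s", case_id, gsub("[^A-Za-z0-9]+", "-",
                                                   pair$site)))
  wli_p <- paste0(stem, "_wli.png"); afi_p <- paste0(stem, "_afi.png")
  write_image(pair$wli, wli_p)
  write_image(pair$afi, afi_p)
  rec$sites[[length(rec$sites) + 1L]] <-
    list(site = pair$site, wli = wli_p, afi = afi_p)
  save_case(store, rec)
  invisible(rec)
}

#' Analysis configuration
#'
#' Carries every tunable of the per-case pipeline. Values may be overridden
#' from a YAML file via [read_config]; the resolved configuration is
#' embedded in every report for provenance.
#'
#' @param pixel_factor,area_threshold thresholds of [classify_afi].
#' @param eps ratio stabilizer of [rg_ratio_map].
#' @param highlight_cut saturation threshold of [default_mask].
#' @param color_matrix optional [color_matrix] for WLI correction (identity
#'   when `NULL`).
#' @param gamma logical, sRGB-linearized color pathway (see [correct_wli]).
#' @param pixel_pitch optional micrometres per pixel.
#' @return an object of class `screening_config`.
#' @export
screening_config <- function(pixel_factor = 1.5, area_threshold = 0.02,
                             eps = 1e-6, highlight_cut = 0.98,
                             color_matrix = NULL, gamma = FALSE,
                             pixel_pitch = NULL) {
  structure(list(pixel_factor = pixel_factor,
                 area_threshold = area_threshold, eps = eps,
                 highlight_cut = highlight_cut, color_matrix = color_matrix,
                 gamma = gamma, pixel_pitch = pixel_pitch),
            class = "screening_config")
}

#' @rdname screening_config
#' @param path YAML file whose top-level keys override the defaults
#'   (`color_matrix` may be a 3x3 numeric array).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- screening_config()
  for (k in names(y)) {
    if (!k %in% names(cfg)) stop(sprintf("unknown config key '%s'", k))
    cfg[[k]] <- if (k == "color_matrix")
      color_matrix(matrix(unlist(y[[k]]), 3, 3, byrow = TRUE)) else y[[k]]
  }
  cfg
}

config_as_list <- function(cfg) {
  out <- unclass(cfg)
  if (!is.null(out$color_matrix))
    out$color_matrix <- unclass(out$color_matrix)
  out[!vapply(out, is.null, TRUE)]
}

#' Run the full per-case analysis and write a summary report
#'
#' For every image pair on the case: build the analysis mask, compute the
#' green mean-subtraction map and the red/green ratio map, make the
#' suspicious / not-suspicious call, and color-correct the WLI frame. Four
#' renditions per site are written (original AFI, mean-subtraction enhanced
#' AFI, original WLI, color-corrected WLI) plus a JSON summary report that
#' embeds the resolved configuration. The report carries no timestamps, so
#' re-running with the same configuration is byte-identical.
#'
#' @param store a [case_store].
#' @param case_id case with at least one attached image pair.
#' @param config a [screening_config].
#' @return the report (named list of class `summary_report`); also written
#'   to `reports/<case_id>.json` in the store.
#' @export
analyze_case <- function(store, case_id, config = screening_config()) {
  rec <- load_case(store, case_id)
  if (!length(rec$sites))
    stop(sprintf("case '%s' has no image pairs to analyze", case_id))
  A <- if (is.null(config$color_matrix)) color_matrix(diag(3))
  else config$color_matrix
  outdir <- file.path(store$dir, "reports", case_id)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sites <- lapply(rec$sites, function(s) {
    if (is.null(s$afi) || !file.exists(s$afi))
      stop(sprintf("case '%s' site '%s': AFI image missing", case_id, s$site))
    if (is.null(s$wli) || !file.exists(s$wli))
      stop(sprintf("case '%s' site '%s': WLI image missing", case_id, s$site))
    afi <- read_image(s$afi)
    wli <- read_image(s$wli)
    mask <- default_mask(afi, config$highlight_cut)
    gm <- green_mean_subtraction(afi, mask)
    ratio <- rg_ratio_map(afi, eps = config$eps)
    res <- classify_afi(ratio, mask, pixel_factor = config$pixel_factor,
                        area_threshold = config$area_threshold)
    corrected <- correct_wli(wli, A, gamma = config$gamma)
    stem <- file.path(outdir, gsub("[^A-Za-z0-9]+", "-", s$site))
    write_image(afi, paste0(stem, "_afi_original.png"))
    write_green_map(gm, paste0(stem, "_afi_enhanced.png"))
    write_image(wli, paste0(stem, "_wli_original.png"))
    write_image(corrected, paste0(stem, "_wli_corrected.png"))
    utils::write.csv(
      data.frame(stat = c("mean_green", "flagged_fraction",
                          "pixel_threshold"),
                 value = c(gm$mean_used, res$flagged_fraction,
                           res$pixel_threshold)),
      paste0(stem, "_maps.csv"), row.names = FALSE)
    list(site = s$site,
         label = res$label,
         flagged_fraction = res$flagged_fraction,
         pixel_threshold = res$pixel_threshold,
         mean_green = gm$mean_used,
         renditions = paste0(basename(stem),
                             c("_afi_original.png", "_afi_enhanced.png",
                               "_wli_original.png", "_wli_corrected.png")))
  })
  report <- structure(list(
    schema = "oralscreen-report/1",
    case_id = case_id,
    sites = sites,
    diagnosis = "",
    triage_note = "",
    config = config_as_list(config)
  ), class = "summary_report")
  jsonlite::write_json(unclass(report),
                       file.path(store$dir, "reports",
                                 paste0(case_id, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' Export study metrics for a set of predictions
#'
#' Joins a cohort manifest (gold classes) with per-case predictions on
#' `case_id`, drops `excluded` gold records with a message, and writes the
#' confusion matrix, the four screening metrics (4-decimal presentation),
#' and — when a numeric `score` column is present — the ROC points, as JSON
#' and CSV.
#'
#' @param manifest data frame with columns `case_id` and `class` (or
#'   `diagnosis`, mapped through [assign_class]).
#' @param predictions data frame with columns `case_id`, `label`
#'   (`"suspicious"`/`"not_suspicious"`) and optionally `score`.
#' @param dir output directory.
#' @return list with `confusion`, `metrics`, `roc` (or NULL), invisibly
#'   written to `metrics.json`, `metrics.csv`, `roc.csv`.
#' @export
export_metrics <- function(manifest, predictions, dir) {
  if (!"class" %in% names(manifest)) {
    if (!"diagnosis" %in% names(manifest))
      stop("manifest needs a `class` or `diagnosis` column")
    manifest$class <- assign_class(manifest$diagnosis)
  }
  unmatched <- setdiff(predictions$case_id, manifest$case_id)
  if (length(unmatched))
    stop("predictions without manifest entries: ",
         paste(unmatched, collapse = ", "))
  j <- merge(manifest[, c("case_id", "class")], predictions, by = "case_id")
  if (!nrow(j)) stop("no overlapping case ids between manifest and predictions")
  n_excl <- sum(j$class == "excluded")
  if (n_excl) message(sprintf("dropping %d excluded (benign) record(s)",
                              n_excl))
  j <- j[j$class != "excluded", , drop = FALSE]
  gold <- j$class == "suspicious"
  pred <- j$label == "suspicious"
  cm <- count_confusion(pred, gold)
  m <- confusion_metrics(cm)
  roc <- NULL
  if ("score" %in% names(j) && length(unique(gold)) == 2L)
    roc <- roc_auc(j$score, gold)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep <- metrics_report(m)
  jsonlite::write_json(
    list(counts = as.list(unlist(cm)),
         metrics = as.list(rep),
         auc = if (!is.null(roc)) roc$auc else NULL,
         n_excluded = n_excl),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(metric = names(rep), value = unname(rep)),
                   file.path(dir, "metrics.csv"), row.names = FALSE)
  if (!is.null(roc))
    utils::write.csv(roc$points, file.path(dir, "roc.csv"),
                     row.names = FALSE)
  invisible(list(confusion = cm, metrics = m, roc = roc))
}
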