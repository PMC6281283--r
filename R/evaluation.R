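# Controlled diagnosis vocabulary for the screening study.
SUSPICIOUS_DIAGNOSES <- c(
  "oral squamous cell carcinoma", "lichen planus", "homogeneous leukoplakia",
  "speckled leukoplakia", "tobacco pouch keratosis", "verrucous leukoplakia",
  "oral submucous fibrosis")
NORMAL_DIAGNOSES <- "normal/variation"
EXCLUDED_DIAGNOSES <- "benign"
# alternate spelling seen in print for verrucous leukoplakia
DIAGNOSIS_ALIASES <- c("verruccous leukoplakia" = "verrucous leukoplakia")

#' The diagnosis vocabulary
#'
#' @return character vector of all accepted diagnosis labels.
#' @export
diagnosis_vocabulary <- function()
  c(SUSPICIOUS_DIAGNOSES, NORMAL_DIAGNOSES, EXCLUDED_DIAGNOSES)

#' Map a clinical diagnosis to a screening class
#'
#' The seven potentially-malignant / malignant diagnoses (OSCC, lichen
#' planus, homogeneous and speckled leukoplakia, tobacco pouch keratosis,
#' verrucous leukoplakia, oral submucous fibrosis) map to `suspicious`;
#' `normal/variation` maps to `normal`; `benign` is excluded from both
#' classes. Matching is case-insensitive; unknown labels are an error, never
#' silently dropped.
#'
#' @param diagnosis character vector of diagnosis labels.
#' @return character vector in `{"suspicious", "normal", "excluded"}`.
#' @examples
#' assign_class("Tobacco Pouch Keratosis")
#' @export
assign_class <- function(diagnosis) {
  d <- tolower(trimws(diagnosis))
  alias <- DIAGNOSIS_ALIASES[d]
  d <- ifelse(is.na(alias), d, alias)
  out <- ifelse(d %in% SUSPICIOUS_DIAGNOSES, "suspicious",
                ifelse(d %in% NORMAL_DIAGNOSES, "normal",
                       ifelse(d %in% EXCLUDED_DIAGNOSES, "excluded", NA)))
  if (anyNA(out))
    stop("unknown diagnosis label(s): ",
         paste(unique(diagnosis[is.na(out)]), collapse = ", "))
  out
}

# quarter-turn clockwise rotation of a matrix or HxWx3 array
rot90cw <- function(x) {
  if (is.matrix(x)) return(t(x[nrow(x):1, , drop = FALSE]))
  d <- dim(x)
  out <- array(0, dim = c(d[2], d[1], d[3]))
  for (p in seq_len(d[3])) out[, , p] <- t(x[d[1]:1, , p])
  out
}

fliph <- function(x) {
  if (is.matrix(x)) return(x[, ncol(x):1, drop = FALSE])
  x[, dim(x)[2]:1, , drop = FALSE]
}

orient_array <- function(x, k, flip) {
  if (flip) x <- fliph(x)
  if (k > 0) for (i in seq_len(k)) x <- rot90cw(x)
  x
}

#' Dihedral (rotate/flip) augmentation of an image pair
#'
#' Screening images have no natural orientation, so the dataset can be
#' enlarged 8-fold with the dihedral orbit: rotations by 0/90/180/270
#' degrees, each with and without a horizontal flip. The same transform is
#' applied to the WLI frame, the AFI frame, and the mask; case id, site and
#' any labels are preserved. The first element of the result is the original
#' pair. Non-square frames change shape under 90/270-degree rotations; this
#' is allowed and tracked by each output's own dimensions.
#'
#' @param pair an [image_pair].
#' @return list of 8 [image_pair] objects with attribute `orientation`
#'   (strings like `"rot90"`, `"rot180+flip"`).
#' @export
augment_pair <- function(pair) {
  if (!inherits(pair, "image_pair")) stop("`pair` must be an image_pair")
  out <- vector("list", 8L)
  labs <- character(8L)
  i <- 0L
  for (flip in c(FALSE, TRUE)) for (k in 0:3) {
    i <- i + 1L
    wli <- oc_image(orient_array(pair$wli$pixels, k, flip),
                    pair$wli$bit_depth, pair$wli$pixel_pitch)
    afi <- oc_image(orient_array(pair$afi$pixels, k, flip),
                    pair$afi$bit_depth, pair$afi$pixel_pitch)
    msk <- orient_array(pair$mask, k, flip)
    out[[i]] <- image_pair(wli, afi, pair$case_id, pair$site, mask = msk)
    labs[i] <- paste0("rot", 90 * k, if (flip) "+flip" else "")
  }
  attr(out, "orientation") <- labs
  out
}

#' Confusion matrix from counts
#'
#' @param tp,fn,fp,tn nonnegative integer counts with a positive total; the
#'   positive class is `suspicious` throughout the package.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be nonnegative integers")
  if (sum(v) == 0) stop("confusion matrix total must be positive")
  structure(as.list(v), class = "confusion_matrix")
}

#' Count a confusion matrix from predicted and gold labels
#'
#' @param predicted,gold character or logical vectors; `TRUE` /
#'   `"suspicious"` is the positive class.
#' @return a [confusion_matrix].
#' @export
count_confusion <- function(predicted, gold) {
  as_pos <- function(x) if (is.logical(x)) x else x == "suspicious"
  p <- as_pos(predicted); g <- as_pos(gold)
  if (length(p) != length(g)) stop("length mismatch")
  confusion_matrix(sum(p & g), sum(!p & g), sum(p & !g), sum(!p & !g))
}

#' Screening metrics from a confusion matrix
#'
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN). A metric whose denominator is zero is reported as `NA`
#' (undefined), not an error. Raw fractions are retained; use
#' [metrics_report] for the 4-decimal presentation convention.
#'
#' @param cm a [confusion_matrix].
#' @return object of class `eval_metrics` with fields `sensitivity`,
#'   `specificity`, `ppv`, `npv` and the counts.
#' @export
confusion_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) stop("`cm` must be a confusion_matrix")
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    sensitivity = frac(cm$tp, cm$tp + cm$fn),
    specificity = frac(cm$tn, cm$tn + cm$fp),
    ppv = frac(cm$tp, cm$tp + cm$fp),
    npv = frac(cm$tn, cm$tn + cm$fn),
    counts = unlist(cm)
  ), class = "eval_metrics")
}

# round half away from zero, the convention used for printed tables
round_half_up <- function(x, digits = 4) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Report metrics rounded to table precision
#'
#' @param m an [confusion_metrics] result.
#' @param digits decimal places (default 4, the printed-table convention;
#'   rounding is half away from zero).
#' @return named numeric vector.
#' @export
metrics_report <- function(m, digits = 4) {
  if (!inherits(m, "eval_metrics")) stop("`m` must be eval_metrics")
  round_half_up(c(sensitivity = m$sensitivity, specificity = m$specificity,
                  ppv = m$ppv, npv = m$npv), digits)
}

#' @export
print.eval_metrics <- function(x, ...) {
  r <- metrics_report(x)
  cat(sprintf("<eval_metrics> sens %.4f  spec %.4f  ppv %.4f  npv %.4f\n",
              r[1], r[2], r[3], r[4]))
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Thresholds sweep over the unique scores (prediction positive iff
#' `score >= threshold`), producing one operating point per threshold plus
#' the endpoints (0,0) and (1,1); the AUC is the trapezoidal area, which
#' equals the tie-corrected Mann-Whitney probability that a random positive
#' outscores a random negative (ties counting one half).
#'
#' @param scores numeric per-case scores (higher = more suspicious).
#' @param labels logical, 0/1, or `"suspicious"`/`"normal"` per-case gold
#'   labels; both classes must be present.
#' @return object of class `roc_result`: `points` (data frame `fpr`, `tpr`,
#'   `threshold`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.character(labels)) labels <- labels == "suspicious"
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (anyNA(scores) || anyNA(labels)) stop("missing values not allowed")
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0)
    stop("both classes must be present to build a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))           # tie groups of equal score
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / npos)
  fpr <- c(0, fp[last] / nneg)
  thr <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d operating points)\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

# seed-scoped RNG: evaluate `code` under set.seed(seed), restoring the
# caller's RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# closed-form ridge regression on standardized features
ridge_fit <- function(x, y, lambda = 1e-2) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  p <- ncol(xs)
  beta <- solve(crossprod(xs) + lambda * nrow(xs) * diag(p),
                crossprod(xs, y - mean(y)))
  list(mu = mu, sd = sdv, beta = beta, intercept = mean(y))
}

ridge_score <- function(fit, x) {
  xs <- sweep(sweep(x, 2, fit$mu), 2, fit$sd, "/")
  as.numeric(xs %*% fit$beta) + fit$intercept
}

#' Stratified k-fold cross-validation of the baseline linear classifier
#'
#' The baseline classifier is a linear scorer fit by regularized
#' (ridge) least squares on standardized features; it stands in for the
#' study's transfer-learned network at desk scale while sharing the same
#' folding, metric and ROC machinery. Folds are stratified by class and
#' deterministic given `seed`. When `groups` is supplied (e.g. the original
#' case id of augmented orientations), all rows of a group are kept in the
#' same fold, so augmentation never leaks between training and test folds.
#'
#' @param x numeric feature matrix (rows = cases).
#' @param y labels (logical, 0/1, or `"suspicious"`/`"normal"`).
#' @param k number of folds (default 4); every class must have at least `k`
#'   members (counted over groups).
#' @param seed integer seed controlling the fold shuffle.
#' @param groups optional vector; rows sharing a group value stay together.
#' @param lambda ridge penalty (per-observation scale).
#' @return object of class `crossval_result`: `fold` (per-row assignment),
#'   `fold_metrics` (list of [confusion_metrics] per fold),
#'   `fold_accuracy`, `mean_accuracy`, `scores` (out-of-fold scores), and
#'   `roc` (pooled out-of-fold [roc_auc]).
#' @export
crossval <- function(x, y, k = 4L, seed = 1L, groups = NULL, lambda = 1e-2) {
  x <- as.matrix(x)
  if (is.character(y)) y <- y == "suspicious"
  y <- as.logical(y)
  n <- nrow(x)
  if (length(y) != n) stop("label length mismatch")
  if (k < 2) stop("`k` must be at least 2")
  if (is.null(groups)) groups <- seq_len(n)
  gid <- as.character(groups)
  ug <- unique(gid)
  glab <- vapply(ug, function(g) y[match(g, gid)], TRUE)
  if (min(table(glab)) < k)
    stop(sprintf("each class needs at least k = %d members", k))
  gfold <- stats::setNames(integer(length(ug)), ug)
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      ids <- sample(ug[glab == cls])
      gfold[ids] <- rep_len(seq_len(k), length(ids))
    }
  })
  fold <- gfold[gid]
  scores <- numeric(n)
  fold_metrics <- vector("list", k)
  fold_acc <- numeric(k)
  for (i in seq_len(k)) {
    tr <- fold != i; te <- !tr
    fit <- ridge_fit(x[tr, , drop = FALSE], as.numeric(y[tr]), lambda)
    sc <- ridge_score(fit, x[te, , drop = FALSE])
    scores[te] <- sc
    pred <- sc >= 0.5
    fold_metrics[[i]] <- confusion_metrics(count_confusion(pred, y[te]))
    fold_acc[i] <- mean(pred == y[te])
  }
  structure(list(fold = unname(fold),
                 fold_metrics = fold_metrics,
                 fold_accuracy = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 scores = scores,
                 roc = roc_auc(scores, y)),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval> %d folds, mean accuracy %.4f, pooled AUC %.4f\n",
              length(x$fold_accuracy), x$mean_accuracy, x$roc$auc))
  invisible(x)
}
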