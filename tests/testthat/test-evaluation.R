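test_that("diagnosis labels map to the printed class assignment", {
  expect_identical(assign_class("tobacco pouch keratosis"), "suspicious")
  expect_identical(assign_class("Oral Squamous Cell Carcinoma"), "suspicious")
  expect_identical(assign_class("verrucous leukoplakia"), "suspicious")
  expect_identical(assign_class("verruccous leukoplakia"), "suspicious")
  expect_identical(assign_class("normal/variation"), "normal")
  expect_identical(assign_class("benign"), "excluded")
  expect_error(assign_class("erythroplakia"), "unknown diagnosis")
})

test_that("class mapping over the study diagnosis counts gives 66/33", {
  counts <- c("normal/variation" = 33, "lichen planus" = 8,
              "homogeneous leukoplakia" = 16, "speckled leukoplakia" = 3,
              "tobacco pouch keratosis" = 33,
              "oral squamous cell carcinoma" = 6)
  labels <- rep(names(counts), counts)
  cls <- assign_class(labels)
  expect_equal(sum(cls == "suspicious"), 66)
  expect_equal(sum(cls == "normal"), 33)
})

test_that("dihedral augmentation yields the full 8-element orbit", {
  p <- asym_pair()
  aug <- augment_pair(p)
  expect_length(aug, 8)
  # original first
  expect_equal(aug[[1]]$afi$pixels, p$afi$pixels)
  # pairwise distinct for an asymmetric image
  keys <- vapply(aug, function(q) paste(q$afi$pixels, collapse = ","), "")
  expect_length(unique(keys), 8)
  # labels and ids preserved; wli and afi share each transform
  for (q in aug) {
    expect_identical(q$case_id, "asym")
    expect_equal(dim(q$wli$pixels), dim(q$afi$pixels))
  }
  # constant image: orbit collapses to equal copies (allowed)
  cp <- image_pair(rgb_const(0.3, 0.3, 0.3, 2, 2),
                   rgb_const(0.2, 0.2, 0.2, 2, 2), "const",
                   mask = full_mask(2, 2))
  caug <- augment_pair(cp)
  ckeys <- vapply(caug, function(q) paste(q$afi$pixels, collapse = ","), "")
  expect_length(unique(ckeys), 1)
})

test_that("non-square frames change shape under quarter turns", {
  r <- matrix(runif(6), 2, 3)
  p <- image_pair(rgb_from_planes(r, r, r), rgb_from_planes(r, r, r),
                  "rect", mask = full_mask(2, 3))
  aug <- augment_pair(p)
  dims <- t(vapply(aug, function(q) dim(q$afi$pixels)[1:2], c(1L, 1L)))
  expect_true(all(dims[, 1] %in% c(2L, 3L)))
  expect_equal(sum(dims[, 1] == 3L), 4)  # the four 90/270 orientations
})

test_that("a study-sized set augments 170 -> 1360", {
  r <- matrix(runif(36), 6, 6)
  base <- image_pair(rgb_from_planes(r, r, r), rgb_from_planes(r, r, r),
                     "c", mask = full_mask(6, 6))
  pairs <- replicate(170, base, simplify = FALSE)
  aug <- unlist(lapply(pairs, augment_pair), recursive = FALSE)
  expect_length(aug, 1360)
})

test_that("the minimal matrix consistent with the published metrics is (75,6,4,26)", {
  found <- search_confusion(0.9259, 0.8667, 0.9494, 0.8125)
  expect_equal(found[c("tp", "fn", "fp", "tn")],
               c(tp = 75, fn = 6, fp = 4, tn = 26))
  m <- confusion_metrics(confusion_matrix(75, 6, 4, 26))
  expect_equal(unname(metrics_report(m)),
               c(0.9259, 0.8667, 0.9494, 0.8125))
})

test_that("confusion metrics handle perfect and undefined cases", {
  perfect <- confusion_metrics(confusion_matrix(10, 0, 0, 10))
  expect_equal(unname(metrics_report(perfect)), c(1, 1, 1, 1))
  nopos <- confusion_metrics(confusion_matrix(0, 0, 3, 7))
  expect_true(is.na(nopos$sensitivity))
  expect_equal(nopos$specificity, 0.7)
  expect_error(confusion_matrix(0, 0, 0, 0), "positive")
  expect_error(confusion_matrix(-1, 0, 0, 2), "nonnegative")
})

test_that("confusion metrics agree with direct counting on random instances", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    gold <- runif(n) < 0.5
    if (length(unique(gold)) < 2) next
    pred <- ifelse(runif(n) < 0.8, gold, !gold)
    m <- confusion_metrics(count_confusion(pred, gold))
    expect_equal(m$sensitivity, sum(pred & gold) / sum(gold))
    expect_equal(m$specificity, sum(!pred & !gold) / sum(!gold))
  }
})

test_that("ROC endpoints, AUC and tie conventions are honored", {
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))
  expect_equal(r$auc, 1.0)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(utils::tail(r$points$fpr, 1), 1)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
  expect_true(all(diff(r$points$fpr) >= 0))

  ties <- roc_auc(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(ties$auc, 0.5)

  r2 <- roc_auc(c(3, 2, 1, 0), c(1, 0, 1, 0))
  expect_equal(r2$auc, 0.75)
  expect_equal(r2$auc, pair_count_auc(c(3, 2, 1, 0), c(1, 0, 1, 0)))
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC equals pair counting and flips under score negation", {
  set.seed(33)
  for (i in 1:12) {
    n <- sample(8:50, 1)
    labels <- runif(n) < 0.5
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1)          # rounded: ties occur
    expect_equal(roc_auc(scores, labels)$auc, pair_count_auc(scores, labels),
                 tolerance = 1e-12)
    if (!any(duplicated(scores)))
      expect_equal(roc_auc(-scores, labels)$auc,
                   1 - roc_auc(scores, labels)$auc, tolerance = 1e-12)
  }
})

test_that("our ROC matches an independent implementation", {
  set.seed(34)
  scores <- rnorm(60)
  labels <- runif(60) < 0.4
  ours <- roc_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                           predictor = scores,
                                           quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("cross-validation is deterministic and stratified", {
  set.seed(35)
  x <- matrix(rnorm(200 * 3), 200, 3)
  y <- rep(c(TRUE, FALSE), each = 100)
  a <- crossval(x, y, k = 4, seed = 99)
  b <- crossval(x, y, k = 4, seed = 99)
  expect_identical(a$fold, b$fold)
  expect_equal(a$mean_accuracy, b$mean_accuracy)
  expect_equal(a$roc$auc, b$roc$auc)
  # stratification: every fold holds both classes in near-equal shares
  for (i in 1:4) {
    yi <- y[a$fold == i]
    expect_gte(sum(yi), 20); expect_gte(sum(!yi), 20)
  }
  expect_error(crossval(x[1:5, ], c(TRUE, TRUE, TRUE, FALSE, FALSE), k = 4),
               "at least k")
})

test_that("indistinguishable classes score at chance level", {
  set.seed(36)
  x <- matrix(rnorm(200 * 5), 200, 5)
  y <- rep(c(TRUE, FALSE), 100)
  cv <- crossval(x, y, k = 4, seed = 1)
  expect_gte(cv$mean_accuracy, 0.35)
  expect_lte(cv$mean_accuracy, 0.65)
})

test_that("a strongly separable synthetic cohort is classified accurately", {
  coh <- generate_cohort(60, class_mix = 0.5, seed = 77)
  feats <- t(vapply(coh$cases, function(cs) extract_afi_features(cs$pair),
                    numeric(5)))
  labs <- vapply(coh$cases, function(cs) cs$class, "")
  cv <- crossval(feats, labs, k = 4, seed = 2)
  expect_gte(cv$mean_accuracy, 0.9)
  expect_gte(cv$roc$auc, 0.95)
})

test_that("grouped folding keeps augmented orientations out of training folds", {
  coh <- generate_cohort(12, class_mix = 0.5, seed = 55,
                         params = tissue_params(size = c(48L, 48L)))
  rows <- list(); groups <- character(); labs <- character()
  for (cs in coh$cases) {
    for (q in augment_pair(cs$pair)) {
      rows[[length(rows) + 1L]] <- extract_afi_features(q)
      groups <- c(groups, cs$pair$case_id)
      labs <- c(labs, cs$class)
    }
  }
  x <- do.call(rbind, rows)
  cv <- crossval(x, labs, k = 3, seed = 4, groups = groups)
  # no group may span folds
  spans <- tapply(cv$fold, groups, function(f) length(unique(f)))
  expect_true(all(spans == 1))
})
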