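# The published camera RGB -> CIEXYZ matrix of the intraoral device, used as
# a known linear map in roundtrip tests.
DEVICE_COLOR_MATRIX <- matrix(c(
   0.81795, 0.09584, -0.02293,
  -0.11767, 0.98376,  0.07395,
  -0.19637, 0.57655,  2.28612), 3, 3, byrow = TRUE)

# Smallest-total integer confusion matrix whose four screening metrics round
# (half up, 4 decimals) to the given values. Independent search oracle.
search_confusion <- function(sens, spec, ppv, npv, dmax = 150) {
  r4 <- function(x) floor(x * 1e4 + 0.5) / 1e4
  cand1 <- list(); cand2 <- list()
  for (d in 1:dmax) {
    tp <- which(r4((1:d) / d) == sens)
    for (t in tp) cand1[[length(cand1) + 1L]] <- c(tp = t, fn = d - t)
    tn <- which(r4((1:d) / d) == spec)
    for (t in tn) cand2[[length(cand2) + 1L]] <- c(tn = t, fp = d - t)
  }
  best <- NULL
  for (a in cand1) for (b in cand2) {
    tp <- a["tp"]; fn <- a["fn"]; tn <- b["tn"]; fp <- b["fp"]
    if (tp + fp == 0 || tn + fn == 0) next
    if (r4(tp / (tp + fp)) != ppv || r4(tn / (tn + fn)) != npv) next
    tot <- tp + fn + tn + fp
    if (is.null(best) || tot < best["total"])
      best <- c(tp = unname(tp), fn = unname(fn), fp = unname(fp),
                tn = unname(tn), total = unname(tot))
  }
  best
}

# AUC by brute-force pair counting (ties count one half)
pair_count_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}
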