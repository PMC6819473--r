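#' Confusion counts and truth-aware error rates
#'
#' @param calls,truth logical vectors of equal length (`NA` calls are
#'   counted as negative).
#' @return list with `TP`, `FP`, `TN`, `FN`, `fdr` (false discovery
#'   proportion, `NA` when nothing is called) and `tpr` (true positive
#'   rate, `NA` when there are no true positives).
#' @export
confusion_counts <- function(calls, truth) {
  if (length(calls) != length(truth)) stop("length mismatch")
  calls <- !is.na(calls) & calls
  truth <- as.logical(truth)
  TP <- sum(calls & truth)
  FP <- sum(calls & !truth)
  FN <- sum(!calls & truth)
  TN <- sum(!calls & !truth)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       fdr = if (TP + FP == 0L) NA_real_ else FP / (TP + FP),
       tpr = if (TP + FN == 0L) NA_real_ else TP / (TP + FN))
}

#' ROC curve and partial AUC
#'
#' Sweeps thresholds over the ranking statistic (higher score = more
#' significant; negate p-values before calling) and reports the ROC step
#' curve together with the partial area under it on `[0, fpr_max]`,
#' normalized by `fpr_max` so a perfect ranking scores 1 and a random one
#' 0.5 `*` `fpr_max`.  Tied scores move along a single diagonal segment.
#'
#' @param scores ranking statistic per gene.
#' @param truth logical truth flags.
#' @param fpr_max right end of the false-positive-rate window.
#' @return list with `curve` (data frame `fpr`, `tpr`, starting at (0,0))
#'   and `pauc` (normalized partial AUC).
#' @export
roc_curve <- function(scores, truth, fpr_max = 0.3) {
  truth <- as.logical(truth)
  ok <- !is.na(scores) & !is.na(truth)
  scores <- scores[ok]
  truth <- truth[ok]
  P <- sum(truth)
  N <- sum(!truth)
  if (P == 0L || N == 0L) stop("truth must contain both classes")

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  grp <- cumsum(!duplicated(s))             # tie groups, best first
  tp <- cumsum(t)[!duplicated(grp, fromLast = TRUE)]
  fp <- cumsum(!t)[!duplicated(grp, fromLast = TRUE)]
  curve <- data.frame(fpr = c(0, fp / N), tpr = c(0, tp / P))

  # trapezoid integration of the step/diagonal curve clipped to [0, fpr_max]
  x <- curve$fpr
  y <- curve$tpr
  if (max(x) < fpr_max) {
    x <- c(x, fpr_max)
    y <- c(y, 1)
  }
  auc <- 0
  for (i in seq_len(length(x) - 1L)) {
    x0 <- x[[i]]; x1 <- x[[i + 1L]]
    if (x0 >= fpr_max) break
    y0 <- y[[i]]; y1 <- y[[i + 1L]]
    if (x1 > fpr_max) {
      y1 <- y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0)
      x1 <- fpr_max
    }
    auc <- auc + (x1 - x0) * (y0 + y1) / 2
  }
  list(curve = curve, pauc = auc / fpr_max)
}

# aggregate per-replicate fdr/tpr into a Table-1-shaped summary
summarize_perf <- function(per_rep) {
  agg <- function(v) {
    v_ok <- v[!is.na(v)]
    c(mean = if (length(v_ok)) mean(v_ok) else NA_real_,
      sd = if (length(v_ok) > 1L) stats::sd(v_ok) else NA_real_,
      n_na = length(v) - length(v_ok))
  }
  keys <- unique(per_rep[, c("method", "hypothesis")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- per_rep[per_rep$method == keys$method[[i]] &
                     per_rep$hypothesis == keys$hypothesis[[i]], ]
    f <- agg(sub$fdr)
    t <- agg(sub$tpr)
    p <- agg(sub$pauc)
    data.frame(method = keys$method[[i]], hypothesis = keys$hypothesis[[i]],
               mean_fdr = f[["mean"]], sd_fdr = f[["sd"]],
               mean_tpr = t[["mean"]], sd_tpr = t[["sd"]],
               mean_pauc = p[["mean"]],
               n_sims = nrow(sub), n_na_fdr = as.integer(f[["n_na"]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
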