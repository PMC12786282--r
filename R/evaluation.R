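## Diagnostic evaluation: ROC/AUC with midrank tie handling, precision-recall
## curves, confusion matrices at a threshold policy, dual-marker fusion and
## permutation importance, attention-heatmap export.

#' ROC curve and AUC
#'
#' AUC by trapezoidal integration over all score thresholds, equivalent to
#' the pairwise-comparison probability with ties counted 1/2 (midrank /
#' Mann-Whitney convention).
#'
#' @param scores numeric scores (higher = more positive)
#' @param labels 0/1 labels, both classes present
#' @return list: `auc`, and `curve` (data.frame threshold, fpr, tpr)
#' @examples
#' rocAuc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))$auc  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present for ROC")
  if (any(!is.finite(scores))) stop("scores must be finite")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0, numeric(1))
  list(auc = auc, curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr))
}

#' Precision-recall curve and area
#'
#' Step-wise interpolation: the curve walks thresholds from high to low and
#' the area accumulates precision over recall increments.
#'
#' @inheritParams rocAuc
#' @return list: `pr_auc`, and `curve` (data.frame threshold, recall, precision)
#' @export
prAuc <- function(scores, labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  n1 <- sum(labels == 1)
  if (n1 == 0) stop("at least one positive is required")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # one point per distinct threshold
  tp <- tp[keep]; fp <- fp[keep]; thr <- s[keep]
  recall <- tp / n1
  precision <- tp / (tp + fp)
  area <- sum(diff(c(0, recall)) * precision)
  list(pr_auc = area,
       curve = data.frame(threshold = thr, recall = recall,
                          precision = precision))
}

#' Confusion matrix and diagnostic rates at an operating threshold
#'
#' Threshold policy: a fixed numeric threshold (default 0.5), or
#' `"youden"`, which picks the Youden-optimal threshold
#' (max sensitivity + specificity - 1) on a designated validation set.
#'
#' @param scores,labels evaluation scores and 0/1 labels
#' @param threshold numeric threshold, or "youden"
#' @param val_scores,val_labels validation set used when threshold = "youden"
#' @return list: threshold, confusion counts (TP, FP, TN, FN), sensitivity,
#'   specificity, accuracy, auc, pr_auc
#' @export
confusionAndRates <- function(scores, labels, threshold = 0.5,
                              val_scores = NULL, val_labels = NULL) {
  if (identical(threshold, "youden")) {
    if (is.null(val_scores) || is.null(val_labels))
      stop("the Youden policy requires a validation set")
    rc <- rocAuc(val_scores, val_labels)$curve
    threshold <- rc$threshold[which.max(rc$tpr - rc$fpr)]
    if (!is.finite(threshold)) threshold <- max(val_scores) + 1e-9
  }
  pred <- scores >= threshold
  TP <- sum(pred & labels == 1); FP <- sum(pred & labels == 0)
  TN <- sum(!pred & labels == 0); FN <- sum(!pred & labels == 1)
  list(threshold = threshold,
       confusion = c(TP = TP, FP = FP, TN = TN, FN = FN),
       sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
       accuracy = (TP + TN) / length(labels),
       auc = rocAuc(scores, labels)$auc,
       pr_auc = prAuc(scores, labels)$pr_auc)
}

#' Fuse two per-marker subject score sets
#'
#' Trains a small KAN head (widths 2 -> 4 -> 1) on the paired per-marker
#' scores of a designated fitting partition (typically validation subjects)
#' and applies it to all paired subjects; with `method = "mean"` the fused
#' score is simply the mean of the two marker scores.
#'
#' @param scores_a,scores_b data.frames with subject_id, score, label
#'   (one per marker; identical subject sets)
#' @param method "kan" or "mean"
#' @param fit_subjects subject_ids used to train the fusion head
#'   (default: all; ignored for "mean")
#' @param seed integer seed
#' @return list: `scores` (data.frame subject_id, score, label) and `model`
#'   (the fusion [KANClassifier-class], or NULL for mean fusion)
#' @export
fuseMarkers <- function(scores_a, scores_b, method = c("kan", "mean"),
                        fit_subjects = NULL, seed = 1L) {
  method <- match.arg(method)
  if (!setequal(scores_a$subject_id, scores_b$subject_id))
    stop("marker score sets must cover the same subjects")
  b <- scores_b[match(scores_a$subject_id, scores_b$subject_id), ]
  X <- cbind(a = scores_a$score, b = b$score)
  lab <- scores_a$label
  out <- data.frame(subject_id = scores_a$subject_id, stringsAsFactors = FALSE)
  if (method == "mean") {
    out$score <- rowMeans(X)
    out$label <- lab
    return(list(scores = out, model = NULL))
  }
  if (is.null(fit_subjects)) fit_subjects <- scores_a$subject_id
  fit <- scores_a$subject_id %in% fit_subjects
  ## scores live in [0,1]; center to the spline range
  Xn <- (X - 0.5) * 4
  model <- buildFeatureModel(2L, hidden = 4L, seed = seed)
  model <- trainClassifier(model, Xn[fit, , drop = FALSE], lab[fit],
                           Xn[fit, , drop = FALSE], lab[fit],
                           trainConfig(epochs = 60L, batch_size = 32L,
                                       patience = 60L,
                                       seed = deriveSeed(seed, "fusion")))
  out$score <- as.numeric(modelForward(model, Xn))
  out$label <- lab
  list(scores = out, model = model)
}

#' Relative marker importance by permutation
#'
#' AUC drop of the fused classifier when one marker's subject scores are
#' permuted, averaged over `n_permutations` seeded permutations and
#' normalized so the two importances sum to 1.
#'
#' @param fusion result of [fuseMarkers()] with a trained model
#' @param scores_a,scores_b the paired per-marker subject scores
#' @param n_permutations number of permutations (default 100)
#' @param seed integer seed
#' @return list: `importance` (named, sums to 1), `sd` (resampling s.d. of
#'   the raw AUC drops), `auc_drop` (raw mean drops)
#' @export
relativeImportance <- function(fusion, scores_a, scores_b,
                               n_permutations = 100L, seed = 1L) {
  if (is.null(fusion$model) || !fusion$model@trained)
    stop("permutation importance requires a trained fusion model")
  b <- scores_b[match(scores_a$subject_id, scores_b$subject_id), ]
  X <- cbind(scores_a$score, b$score)
  lab <- scores_a$label
  Xn <- (X - 0.5) * 4
  base_auc <- rocAuc(as.numeric(modelForward(fusion$model, Xn)), lab)$auc
  drops <- matrix(NA_real_, n_permutations, 2)
  withSeed(deriveSeed(seed, "perm-importance"), {
    for (r in seq_len(n_permutations)) {
      for (j in 1:2) {
        Xp <- Xn
        Xp[, j] <- Xp[sample.int(nrow(Xp)), j]
        drops[r, j] <- base_auc -
          rocAuc(as.numeric(modelForward(fusion$model, Xp)), lab)$auc
      }
    }
  })
  mean_drop <- pmax(colMeans(drops), 0)
  if (sum(mean_drop) == 0) mean_drop <- c(0.5, 0.5)
  imp <- mean_drop / sum(mean_drop)
  names(imp) <- c("GPC1", "EphA2")[seq_len(2)]
  list(importance = imp, sd = apply(drops, 2, sd), auc_drop = colMeans(drops))
}

#' Export attention heatmaps of a full-spectrum model
#'
#' Writes one CSV matrix per (layer, head), averaged over the given records,
#' with patch axes annotated by their wavelength ranges, plus an optional PNG
#' rendering per map.
#'
#' @param model a trained full-spectrum [KANClassifier-class]
#' @param X3 patch tensor of the records to average over
#' @param grid the wavelength grid (for axis annotation)
#' @param dir output directory (created if missing)
#' @param png also render PNG heatmaps
#' @return (invisibly) the list of attention maps from [attentionMaps()]
#' @export
exportAttentionHeatmaps <- function(model, X3, grid, dir, png = FALSE) {
  maps <- attentionMaps(model, X3)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pw <- patchWavelengths(grid, model@config$patch_length)
  axis_lab <- sprintf("%.0f-%.0fnm", pw$lo, pw$hi)
  for (l in seq_along(maps)) for (h in seq_along(maps[[l]])) {
    M <- maps[[l]][[h]]
    dimnames(M) <- list(axis_lab, axis_lab)
    f <- file.path(dir, sprintf("attention_layer%d_head%d.csv", l, h))
    write.csv(M, f)
    if (png) {
      grDevices::png(sub("\\.csv$", ".png", f), width = 640, height = 640)
      graphics::image(seq_len(nrow(M)), seq_len(ncol(M)), t(M)[, rev(seq_len(nrow(M)))],
                      xlab = "key patch", ylab = "query patch",
                      main = sprintf("layer %d head %d", l, h),
                      col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
      grDevices::dev.off()
    }
  }
  invisible(maps)
}

#' Which top-attended patches fall inside the mode windows
#'
#' For every layer and head, ranks key patches by mean received attention
#' (column means of the averaged map) and reports how many of the top
#' `n_top` patches intersect the union of the mode windows.
#'
#' @param maps attention maps from [attentionMaps()]
#' @param grid wavelength grid
#' @param patch_length grid points per patch
#' @param windows mode windows (default [defaultModeWindows()])
#' @param n_top patches to inspect per head (default 4)
#' @return data.frame: layer, head, n_top_in_windows, top patch indices
#' @export
attentionModeOverlap <- function(maps, grid, patch_length = 16L,
                                 windows = defaultModeWindows(), n_top = 4L) {
  pw <- patchWavelengths(grid, patch_length)
  in_window <- vapply(seq_len(nrow(pw)), function(p) {
    any(vapply(windows, function(w) pw$lo[p] < w[2] && pw$hi[p] >= w[1],
               logical(1)))
  }, logical(1))
  out <- NULL
  for (l in seq_along(maps)) for (h in seq_along(maps[[l]])) {
    colw <- colMeans(maps[[l]][[h]])
    top <- order(colw, decreasing = TRUE)[seq_len(n_top)]
    out <- rbind(out, data.frame(
      layer = l, head = h, n_top_in_windows = sum(in_window[top]),
      top_patches = paste(top, collapse = ","), stringsAsFactors = FALSE))
  }
  out
}
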