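## End-to-end conveniences tying the modules together: train a conventional
## effect classifier or the full-spectrum model on one marker of a
## SpectrumExperiment, with subject-level partition-aware evaluation.

markerRecords <- function(se, marker) {
  se[, recordData(se)$marker == marker]
}

normalizeFeatures <- function(M, norm) {
  sweep(sweep(M, 2, norm$mean, "-"), 2, norm$sd, "/")
}

#' Train a conventional-effect KAN (or MLP) classifier on one marker
#'
#' Extracts RE/SE/NLE features for all records of the marker, normalizes
#' them with training-partition statistics (frozen), trains on the training
#' partition with the test partition as validation, and evaluates
#' subject-level scores on the external partition.
#'
#' @param se a [SpectrumExperiment-class]
#' @param marker marker name
#' @param effect "RE", "SE" or "NLE"
#' @param mode_set mode labels to fuse (default all four)
#' @param windows mode windows
#' @param hidden hidden widths of the classifier
#' @param architecture "kan" or "mlp"
#' @param config a [trainConfig()]
#' @param eval_partition partition used for reported metrics (default "external")
#' @return list: model, feature norm, per-partition subject scores, `auc`,
#'   `report` (from [confusionAndRates()] with the Youden threshold chosen
#'   on the validation partition)
#' @export
trainEffectClassifier <- function(se, marker, effect = "NLE",
                                  mode_set = names(windows),
                                  windows = defaultModeWindows(),
                                  hidden = c(16L, 8L),
                                  architecture = c("kan", "mlp"),
                                  config = trainConfig(),
                                  eval_partition = "external") {
  architecture <- match.arg(architecture)
  tab <- extractFeatureTable(markerRecords(se, marker), effect,
                             windows = windows, mode_set = mode_set)
  fc <- featureColumns(tab)
  M <- as.matrix(tab[, fc, drop = FALSE])
  tr <- tab$partition == "train"
  va <- tab$partition == "test"
  norm <- list(mean = colMeans(M[tr, , drop = FALSE]),
               sd = pmax(apply(M[tr, , drop = FALSE], 2, sd), 1e-9))
  Mn <- normalizeFeatures(M, norm)
  model <- if (architecture == "kan")
    buildFeatureModel(length(fc), hidden = hidden, seed = config$seed)
  else buildMLPModel(length(fc), seed = config$seed)
  model@norm <- norm
  model <- trainClassifier(model, Mn[tr, , drop = FALSE], tab$label[tr],
                           Mn[va, , drop = FALSE], tab$label[va], config)
  probs <- as.numeric(modelForward(model, Mn))
  parts <- unique(tab$partition)
  scores <- lapply(setNames(parts, parts), function(p) {
    k <- tab$partition == p
    subjectScores(probs[k], tab$subject_id[k], tab$label[k])
  })
  ev <- scores[[eval_partition]]
  vv <- scores[["test"]]
  report <- confusionAndRates(ev$score, ev$label, threshold = "youden",
                              val_scores = vv$score, val_labels = vv$label)
  list(model = model, norm = norm, scores = scores,
       auc = report$auc, report = report, effect = effect, marker = marker)
}

#' Train the full-spectrum KAN classifier on one marker
#'
#' Normalizes the pre/post channels per wavelength with training-partition
#' statistics (frozen), tiles them into patches, trains the attention + KAN
#' model on the training partition with the test partition as validation,
#' and evaluates subject-level scores on the external partition.
#'
#' @inheritParams trainEffectClassifier
#' @param patch_length grid points per patch
#' @param d_model,layers,heads,head_hidden architecture settings
#' @return list as in [trainEffectClassifier()], plus the patch tensor
#'   builder inputs needed for attention export (`norm`, `patch_length`)
#' @export
trainFullSpectrumClassifier <- function(se, marker, patch_length = 16L,
                                        d_model = 64L, layers = 2L,
                                        heads = 4L, head_hidden = 16L,
                                        config = trainConfig(),
                                        eval_partition = "external") {
  sem <- markerRecords(se, marker)
  cd <- as.data.frame(recordData(sem))
  tr <- which(cd$partition == "train")
  va <- which(cd$partition == "test")
  norm <- spectrumNormalization(sem, tr)
  X_tr <- buildPatchTensor(sem, tr, norm, patch_length)
  X_va <- buildPatchTensor(sem, va, norm, patch_length)
  model <- buildFullSpectrumModel(nrow(sem), patch_length, d_model, layers,
                                  heads, head_hidden, seed = config$seed)
  model@norm <- norm
  model <- trainClassifier(model, X_tr, cd$label[tr], X_va, cd$label[va],
                           config)
  parts <- unique(cd$partition)
  scores <- lapply(setNames(parts, parts), function(p) {
    k <- which(cd$partition == p)
    Xp <- buildPatchTensor(sem, k, norm, patch_length)
    subjectScores(as.numeric(modelForward(model, Xp)),
                  cd$subject_id[k], cd$label[k])
  })
  ev <- scores[[eval_partition]]
  vv <- scores[["test"]]
  report <- confusionAndRates(ev$score, ev$label, threshold = "youden",
                              val_scores = vv$score, val_labels = vv$label)
  list(model = model, norm = norm, patch_length = patch_length,
       scores = scores, auc = report$auc, report = report, marker = marker)
}

#' Benchmark the conventional readouts against the full-spectrum model
#'
#' Trains RE, SE and NLE four-mode-fusion KAN classifiers and the
#' full-spectrum KAN on one marker of a dataset and returns their
#' external-partition subject-level AUCs (the qualitative ordering of the
#' conventional-vs-deep comparison).
#'
#' @param se a [SpectrumExperiment-class]
#' @param marker marker name
#' @param config_feature,config_full training configurations (defaults: the
#'   package's standard feature and full-spectrum recipes)
#' @param patch_length patches for the full-spectrum model (default 16)
#' @return list: `auc` (named RE/SE/NLE/full), and the four fit objects
#' @export
benchmarkEffects <- function(se, marker,
                             config_feature = trainConfig(epochs = 60L,
                                                          patience = 15L),
                             config_full = trainConfig(epochs = 30L,
                                                       patience = 8L,
                                                       lr = 1.5e-3,
                                                       weight_decay = 3e-4,
                                                       lr_schedule = "cosine",
                                                       input_noise_sd = 0.15,
                                                       ema_decay = 0.995),
                             patch_length = 16L) {
  fits <- list()
  for (eff in c("RE", "SE", "NLE"))
    fits[[eff]] <- trainEffectClassifier(se, marker, eff,
                                         config = config_feature)
  fits$full <- trainFullSpectrumClassifier(se, marker,
                                           patch_length = patch_length,
                                           config = config_full)
  list(auc = vapply(fits, `[[`, numeric(1), "auc"), fits = fits)
}
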