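## Seeded minibatch training with Adam on the clipped binary cross-entropy,
## early stopping on validation loss, best-checkpoint restoration.

modelForward <- function(model, X, cache = FALSE) {
  switch(model@type,
         feature = featureForward(model, X, cache = cache),
         mlp = featureForward(model, X, cache = cache),
         fullspectrum = fullForward(model, X, cache = cache))
}

modelBackward <- function(model, fwd, dlogit) {
  switch(model@type,
         feature = featureBackward(model, fwd, dlogit),
         mlp = featureBackward(model, fwd, dlogit),
         fullspectrum = fullBackward(model, fwd, dlogit))
}

sliceInput <- function(X, idx) {
  if (is.matrix(X)) X[idx, , drop = FALSE] else X[idx, , , drop = FALSE]
}

#' Training configuration
#'
#' @param epochs maximal epochs
#' @param batch_size minibatch size
#' @param lr Adam learning rate
#' @param weight_decay decoupled weight decay on weight/coefficient arrays
#'   (biases and normalization parameters are exempt)
#' @param lr_schedule "constant" or "cosine" (half-cosine decay to ~0 over
#'   `epochs`)
#' @param input_noise_sd s.d. of Gaussian noise added to (normalized)
#'   training inputs per minibatch, a light augmentation; 0 disables
#' @param ema_decay per-step exponential moving average of the weights;
#'   validation and the returned checkpoint use the averaged weights
#'   (0 disables)
#' @param patience early-stop patience on the validation criterion
#' @param seed mandatory integer seed (shuffling and augmentation are the
#'   only randomness)
#' @return list of settings
#' @export
trainConfig <- function(epochs = 40L, batch_size = 64L, lr = 1e-3,
                        weight_decay = 1e-4, lr_schedule = c("constant", "cosine"),
                        input_noise_sd = 0, ema_decay = 0, patience = 10L,
                        seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0, weight_decay >= 0,
            input_noise_sd >= 0, ema_decay >= 0, ema_decay < 1, patience >= 1L)
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr = lr, weight_decay = weight_decay, lr_schedule = lr_schedule,
       input_noise_sd = input_noise_sd, ema_decay = ema_decay,
       patience = as.integer(patience), seed = as.integer(seed))
}

#' Train a classifier on a labeled set with validation monitoring
#'
#' Minimizes the clipped binary cross-entropy with Adam over seeded
#' minibatches; records the learning curve (training and validation BCE) and
#' per-epoch validation AUC/accuracy; stops early when the validation
#' criterion (AUC when both classes are present, otherwise BCE) has not
#' improved for `patience` epochs and restores the best-epoch parameters.
#' Bit-reproducible for a fixed seed.
#'
#' @param model an untrained [KANClassifier-class]
#' @param X_train,y_train training inputs (feature matrix or patch tensor)
#'   and 0/1 labels
#' @param X_val,y_val disjoint validation inputs and labels
#' @param config a [trainConfig()] list
#' @param val_subjects optional subject of each validation record; when
#'   given, the validation AUC/accuracy driving checkpoint selection are
#'   computed on subject-aggregated scores (the deployment metric)
#' @param verbose print per-epoch progress
#' @return the trained [KANClassifier-class] (history in
#'   [trainingHistory()])
#' @export
trainClassifier <- function(model, X_train, y_train, X_val, y_val,
                            config = trainConfig(), val_subjects = NULL,
                            verbose = FALSE) {
  n <- length(y_train)
  params <- model@params
  mAdam <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  vAdam <- mAdam
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  wd <- config$weight_decay %||% 0
  decayed <- grepl("(\\.W[a-z]?$|\\.coef$|\\.w$)", names(params))
  names(decayed) <- names(params)
  ema_d <- config$ema_decay %||% 0
  ema <- if (ema_d > 0) params
  step <- 0L
  hist <- list(train_loss = numeric(0), val_loss = numeric(0),
               val_auc = numeric(0), val_acc = numeric(0))
  best <- list(loss = Inf, auc = -Inf, params = params, epoch = 0L)
  withSeed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr_e <- if (identical(config$lr_schedule, "cosine"))
        config$lr * 0.5 * (1 + cos(pi * (epoch - 1) / config$epochs))
      else config$lr
      ord <- sample.int(n)
      ep_loss <- 0; ep_n <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        model@params <- params
        Xb <- sliceInput(X_train, idx)
        if ((config$input_noise_sd %||% 0) > 0)
          Xb <- Xb + array(rnorm(length(Xb), sd = config$input_noise_sd),
                           dim = dim(Xb))
        fw <- modelForward(model, Xb, cache = TRUE)
        yb <- y_train[idx]
        loss <- bceLoss(yb, fw$p)
        if (!is.finite(loss))
          stop(sprintf("training diverged at epoch %d (non-finite loss)", epoch))
        ep_loss <- ep_loss + loss * length(idx); ep_n <- ep_n + length(idx)
        pc <- pmin(pmax(fw$p, 1e-7), 1 - 1e-7)
        dlogit <- (pc - yb) / length(idx)
        grads <- modelBackward(model, fw, dlogit)
        step <- step + 1L
        corr <- sqrt(1 - b2^step) / (1 - b1^step)
        for (nm in names(params)) {
          g <- grads[[nm]]
          mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * g
          vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * g^2
          params[[nm]] <- params[[nm]] -
            lr_e * (corr * mAdam[[nm]] / (sqrt(vAdam[[nm]]) + eps) +
                      if (decayed[[nm]]) wd * params[[nm]] else 0)
          if (ema_d > 0)
            ema[[nm]] <- ema_d * ema[[nm]] + (1 - ema_d) * params[[nm]]
        }
      }
      model@params <- if (ema_d > 0) ema else params
      pv <- modelForward(model, X_val)
      vloss <- bceLoss(y_val, pv)
      if (is.null(val_subjects)) { sv <- pv; yv <- y_val }
      else { agg <- subjectScores(pv, val_subjects, y_val)
             sv <- agg$score; yv <- agg$label }
      vauc <- if (length(unique(yv)) == 2L) rocAuc(sv, yv)$auc else NA_real_
      vacc <- mean((sv >= 0.5) == (yv == 1))
      hist$train_loss <- c(hist$train_loss, ep_loss / ep_n)
      hist$val_loss <- c(hist$val_loss, vloss)
      hist$val_auc <- c(hist$val_auc, vauc)
      hist$val_acc <- c(hist$val_acc, vacc)
      if (verbose)
        message(sprintf("epoch %3d  train BCE %.4f  val BCE %.4f  val AUC %.4f",
                        epoch, ep_loss / ep_n, vloss, vauc))
      improved <- if (is.na(vauc)) vloss < best$loss - 1e-9
        else vauc > best$auc + 1e-9 ||
          (abs(vauc - best$auc) <= 1e-9 && vloss < best$loss - 1e-9)
      if (improved)
        best <- list(loss = vloss, auc = if (is.na(vauc)) -Inf else vauc,
                     params = if (ema_d > 0) ema else params, epoch = epoch)
      if (epoch - best$epoch >= config$patience) break
    }
  })
  model@params <- best$params
  hist$best_epoch <- best$epoch
  model@history <- hist
  model@trained <- TRUE
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict record probabilities and subject-level scores
#'
#' Returns one probability per (already normalized) input record; subject
#' scores are the mean over each subject's replicate records.
#'
#' @param model a trained [KANClassifier-class]
#' @param X input (normalized feature matrix or patch tensor)
#' @param subject_id optional subject of each record; when given, a
#'   data.frame of per-subject mean scores is returned alongside
#' @return numeric probabilities, or list(record = probs, subject = data.frame)
#' @export
predictRecords <- function(model, X, subject_id = NULL) {
  p <- modelForward(model, X)
  if (is.null(subject_id)) return(p)
  agg <- tapply(p, subject_id, mean)
  list(record = p,
       subject = data.frame(subject_id = names(agg), score = as.numeric(agg),
                            stringsAsFactors = FALSE))
}

#' Aggregate record probabilities to subject scores
#'
#' @param probs per-record probabilities
#' @param subject_id subject of each record
#' @param labels optional per-record 0/1 labels (constant within subject)
#' @return data.frame subject_id, score, and label when given
#' @export
subjectScores <- function(probs, subject_id, labels = NULL) {
  agg <- tapply(probs, subject_id, mean)
  out <- data.frame(subject_id = names(agg), score = as.numeric(agg),
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    lab <- tapply(labels, subject_id, function(v) {
      u <- unique(v)
      if (length(u) != 1L) stop("labels differ within a subject")
      u
    })
    out$label <- as.numeric(lab[out$subject_id])
  }
  out
}
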