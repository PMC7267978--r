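#' Training hyperparameters
#'
#' Defaults follow the published recipe: Adam with `beta1 = 0.9`,
#' `beta2 = 0.999`, initial learning rate 1e-3, batch size 32, fragments of
#' `k = 27` TRs randomly cropped from each sample every training epoch (the
#' first `k` TRs in validation/testing), the learning rate divided by 10
#' whenever the validation loss has not reached a new minimum for 15 epochs,
#' early stopping on the minimum validation loss, and 30 epochs for initial
#' training (120 for transfer).
#'
#' @param k fragment length in TRs.
#' @param batch_size minibatch size.
#' @param lr0 initial learning rate.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param plateau_patience_epochs epochs without a new validation-loss
#'   minimum before the learning rate is decayed.
#' @param lr_decay_factor factor the learning rate is divided by.
#' @param max_epochs training epoch budget.
#' @param min_delta absolute improvement that counts as a new minimum.
#' @param max_lr_decays early stop after this many decays without improvement.
#' @param seed master seed; fans out to fold assignment, weight
#'   initialization and crop randomness.
#' @return An object of class `train_config`.
#' @export
train_config <- function(k = 27L, batch_size = 32L, lr0 = 1e-3,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         plateau_patience_epochs = 15L, lr_decay_factor = 10,
                         max_epochs = 30L, min_delta = 1e-4,
                         max_lr_decays = 2L, seed = 1L) {
  stopifnot(k >= 1, batch_size >= 1, lr0 > 0, lr_decay_factor > 1,
            max_epochs >= 1)
  structure(
    list(k = as.integer(k), batch_size = as.integer(batch_size), lr0 = lr0,
         adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
         plateau_patience_epochs = as.integer(plateau_patience_epochs),
         lr_decay_factor = lr_decay_factor, max_epochs = as.integer(max_epochs),
         min_delta = min_delta, max_lr_decays = as.integer(max_lr_decays),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Random temporal crop (training augmentation)
#'
#' Cuts a fragment of `k` consecutive frames from the sample, with the start
#' index uniform on `0..(t - k)`.
#'
#' @param sample a [bold_sample()] with at least `k` frames.
#' @param k fragment length in TRs.
#' @return A cropped [bold_sample()].
#' @export
random_temporal_crop <- function(sample, k) {
  nt <- dim(sample$data)[1]
  if (nt < k) {
    stop(sprintf("sample has %d frames, need at least %d", nt, k),
         call. = FALSE)
  }
  start <- sample.int(nt - k + 1L, 1L)  # 1-based start in 1..(t-k+1)
  out <- sample
  out$data <- sample$data[start:(start + k - 1L), , , , drop = FALSE]
  out
}

#' First-k temporal crop (validation/testing)
#'
#' @param sample a [bold_sample()] with at least `k` frames.
#' @param k fragment length in TRs.
#' @return The sample restricted to frames `0..k-1`.
#' @export
deterministic_first_crop <- function(sample, k) {
  nt <- dim(sample$data)[1]
  if (nt < k) {
    stop(sprintf("sample has %d frames, need at least %d", nt, k),
         call. = FALSE)
  }
  if (nt == k) return(sample)
  out <- sample
  out$data <- sample$data[seq_len(k), , , , drop = FALSE]
  out
}

#' Subject-wise cross-validation plan
#'
#' Partitions subjects into `n_folds` test groups and, within each fold,
#' splits the remaining subjects into training and validation sets at the
#' requested ratios. No subject ever appears in two partitions of the same
#' fold, and every subject appears in exactly one test list across folds.
#'
#' @param subject_ids character vector of subjects (>= `n_folds`).
#' @param ratios length-3 numeric `c(train, validation, test)` summing to 1.
#'   The published splits are `c(0.7, 0.1, 0.2)` for initial training and
#'   `c(0.6, 0.2, 0.2)` for transfer.
#' @param n_folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @return An object of class `fold_plan`: a list of folds, each with
#'   `train`, `validation`, `test` character vectors.
#' @export
make_fold_plan <- function(subject_ids, ratios = c(0.7, 0.1, 0.2),
                           n_folds = 5L, seed = 1L) {
  subject_ids <- as.character(subject_ids)
  ns <- length(subject_ids)
  if (ns < n_folds) {
    stop(sprintf("need at least %d subjects for %d folds, got %d",
                 n_folds, n_folds, ns), call. = FALSE)
  }
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-6, all(ratios > 0))
  withr::local_seed(seed)
  perm <- sample(subject_ids)
  test_groups <- split(perm, cut(seq_len(ns), n_folds, labels = FALSE))
  folds <- lapply(seq_len(n_folds), function(f) {
    test <- test_groups[[f]]
    rest <- setdiff(perm, test)
    n_val <- round(ns * ratios[2])
    n_val <- max(1L, min(n_val, length(rest) - 1L))
    val <- sample(rest, n_val)
    train <- setdiff(rest, val)
    list(train = train, validation = val, test = test)
  })
  structure(list(folds = folds, n_folds = as.integer(n_folds),
                 ratios = ratios, seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) {
    sprintf("%d/%d/%d", length(f$train), length(f$validation), length(f$test))
  }, character(1))
  cat(sprintf("<fold_plan: %d folds (train/val/test subjects: %s)>\n",
              x$n_folds, paste(sizes, collapse = ", ")))
  invisible(x)
}

subset_dataset <- function(dataset, subjects) {
  dataset[dataset$subject_id %in% subjects, , drop = FALSE]
}

#' Train the decoder on one fold
#'
#' Minimizes the softmax cross-entropy with Adam. Each epoch draws a fresh
#' random `k`-frame crop of every training sample; validation always uses
#' the first `k` frames. The learning rate is divided by
#' `cfg$lr_decay_factor` when the validation loss has not improved for
#' `cfg$plateau_patience_epochs` epochs; training stops early once the rate
#' has been decayed `cfg$max_lr_decays` times without a new minimum, and the
#' returned model is the checkpoint with minimum validation loss.
#'
#' @param model an `fmri_cnn` whose head matches the dataset labels.
#' @param dataset tibble from [generate_dataset()] (columns `subject_id`,
#'   `label`, `sample`).
#' @param fold list with `train`, `validation` (and optionally `test`)
#'   subject vectors, e.g. one element of a [make_fold_plan()].
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return A list of class `fmri_cnn_fit`: `model` (best checkpoint),
#'   `history` (tibble: epoch, lr, train_loss, train_accuracy, val_loss,
#'   val_accuracy), `best_epoch`, `cfg`, `fold`.
#' @export
train_decoder <- function(model, dataset, fold, cfg = train_config(),
                          verbose = FALSE) {
  stopifnot(inherits(model, "fmri_cnn"))
  labels <- model$labels
  stopifnot(all(dataset$label %in% labels))
  tr <- subset_dataset(dataset, fold$train)
  va <- subset_dataset(dataset, fold$validation)
  stopifnot(nrow(tr) > 0, nrow(va) > 0)

  withr::local_seed(cfg$seed)
  opt <- adam_init(model$params)
  lr <- cfg$lr0
  best <- list(loss = Inf, params = model$params, bn = model$bn, epoch = 0L)
  since_best <- 0L
  decays_since_best <- 0L
  hist <- vector("list", cfg$max_epochs)

  va_x <- batch_from_samples(lapply(va$sample, deterministic_first_crop,
                                    k = cfg$k))
  va_y <- match(va$label, labels)

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(nrow(tr))
    ep_loss <- 0; ep_hits <- 0
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      xs <- lapply(tr$sample[b], random_temporal_crop, k = cfg$k)
      x <- batch_from_samples(xs)
      y <- match(tr$label[b], labels)
      fw <- forward_pass(model, x, training = TRUE, keep_cache = TRUE)
      model <- fw$model
      ce <- cross_entropy(fw$logits, y)
      if (!is.finite(ce$loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
             call. = FALSE)
      }
      bw <- backward_pass(model, fw$cache, ce$dlogits, training = TRUE,
                          need_param_grads = TRUE)
      upd <- adam_step(model$params, bw$grads, opt, lr,
                       cfg$adam_beta1, cfg$adam_beta2)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + ce$loss * length(b)
      ep_hits <- ep_hits + sum(max.col(t(ce$probs)) == y)
    }
    ep_loss <- ep_loss / nrow(tr)
    ep_acc <- ep_hits / nrow(tr)

    vfw <- forward_pass(model, va_x, training = FALSE)
    vce <- cross_entropy(vfw$logits, va_y)
    v_acc <- mean(max.col(t(vce$probs)) == va_y)

    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, train_loss = ep_loss, train_accuracy = ep_acc,
      val_loss = vce$loss, val_accuracy = v_acc)
    if (verbose) {
      message(sprintf(
        "epoch %3d  lr %.2g  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
        epoch, lr, ep_loss, ep_acc, vce$loss, v_acc))
    }

    if (vce$loss < best$loss - cfg$min_delta) {
      best <- list(loss = vce$loss, params = model$params, bn = model$bn,
                   epoch = epoch)
      since_best <- 0L
      decays_since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$plateau_patience_epochs) {
        lr <- lr / cfg$lr_decay_factor
        since_best <- 0L
        decays_since_best <- decays_since_best + 1L
        if (decays_since_best > cfg$max_lr_decays) break
      }
    }
  }

  model$params <- best$params
  model$bn <- best$bn
  structure(
    list(model = model, history = dplyr::bind_rows(hist),
         best_epoch = best$epoch, cfg = cfg, fold = fold),
    class = "fmri_cnn_fit"
  )
}

#' @export
print.fmri_cnn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<fmri_cnn_fit: %d epochs, best epoch %d (val loss %.4f, val acc %.3f)>\n",
    nrow(h), x$best_epoch, h$val_loss[x$best_epoch],
    h$val_accuracy[x$best_epoch]))
  invisible(x)
}

#' @rdname train_decoder
#' @param x an `fmri_cnn_fit`.
#' @param ... unused.
#' @export
tidy.fmri_cnn_fit <- function(x, ...) x$history

#' @rdname train_decoder
#' @export
glance.fmri_cnn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h), best_epoch = x$best_epoch,
    best_val_loss = h$val_loss[x$best_epoch],
    best_val_accuracy = h$val_accuracy[x$best_epoch],
    final_lr = h$lr[nrow(h)])
}

#' Transfer the trained trunk to a new classification task
#'
#' Re-uses every layer of a trained decoder except the output layer, which
#' is re-initialized for the new label set, then runs the same training loop
#' on the new dataset.
#'
#' @param fit an `fmri_cnn_fit` (or bare `fmri_cnn`) trained on the source
#'   task.
#' @param new_labels character vector of target-task labels.
#' @param dataset target-task dataset tibble.
#' @param fold train/validation split for the target task.
#' @param cfg a [train_config()]; the published transfer budget is
#'   `max_epochs = 120`.
#' @param head_seed seed for the fresh head weights.
#' @param verbose print per-epoch progress.
#' @return An `fmri_cnn_fit` for the target task.
#' @export
transfer_decoder <- function(fit, new_labels, dataset, fold,
                             cfg = train_config(max_epochs = 120L),
                             head_seed = 1L, verbose = FALSE) {
  model <- if (inherits(fit, "fmri_cnn_fit")) fit$model else fit
  stopifnot(inherits(model, "fmri_cnn"))
  model <- reset_head(model, new_labels, head_seed)
  train_decoder(model, dataset, fold, cfg, verbose = verbose)
}

reset_head <- function(model, new_labels, head_seed = 1L) {
  k <- length(new_labels)
  stopifnot(k >= 2)
  cfg <- model$cfg
  cfg$n_classes <- as.integer(k)
  withr::local_seed(head_seed)
  model$cfg <- cfg
  model$labels <- as.character(new_labels)
  model$params$fc2.w <- matrix(
    stats::rnorm(k * cfg$fc_width, 0, sqrt(2 / cfg$fc_width)), k, cfg$fc_width)
  model$params$fc2.b <- rep(0, k)
  model
}

#' Decoding accuracy versus number of training subjects
#'
#' Trains one decoder per requested training-set size on the first `n`
#' subjects of the fold's training list and evaluates each on the fixed
#' held-out test set, tracing the learning curve of the decoder on small
#' cohorts.
#'
#' @param dataset dataset tibble.
#' @param fold list with `train`, `validation` and `test` subject vectors.
#' @param n_subj_list training-set sizes; the published experiment used
#'   `c(1, 2, 4, 8, 17, 25, 34)`.
#' @param cfg a [train_config()].
#' @param model_factory function(labels) returning a fresh `fmri_cnn`.
#' @param verbose print progress.
#' @return Tibble: `n_subjects`, `test_accuracy`, `best_epoch`.
#' @export
learning_curve <- function(dataset, fold,
                           n_subj_list = c(1, 2, 4, 8, 17, 25, 34),
                           cfg = train_config(), model_factory, verbose = FALSE) {
  stopifnot(all(n_subj_list >= 1))
  if (any(n_subj_list > length(fold$train))) {
    stop(sprintf("requested %d training subjects but the fold has %d",
                 max(n_subj_list), length(fold$train)), call. = FALSE)
  }
  labels <- sort(unique(dataset$label))
  te <- subset_dataset(dataset, fold$test)
  rows <- lapply(n_subj_list, function(n) {
    sub_fold <- list(train = fold$train[seq_len(n)],
                     validation = fold$validation, test = fold$test)
    model <- model_factory(labels)
    fit <- train_decoder(model, dataset, sub_fold, cfg, verbose = verbose)
    pred <- predict(fit$model, te)
    tibble::tibble(n_subjects = n,
                   test_accuracy = mean(pred$predicted == pred$label),
                   best_epoch = fit$best_epoch)
  })
  dplyr::bind_rows(rows)
}
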