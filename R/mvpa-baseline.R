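#' Build a block-design GLM design matrix
#'
#' One HRF-convolved boxcar regressor per condition (frame-wise block
#' occupancy convolved with the sampled HRF kernel), plus an intercept and
#' low-order cosine drift columns.
#'
#' @param events events tibble (`onset`, `duration`, `trial_type`).
#' @param n_frames number of frames in the run.
#' @param tr_s repetition time (s).
#' @param hrf an [hrf_spec()].
#' @param n_drift number of cosine drift regressors (default 2).
#' @return Numeric matrix `n_frames x (conditions + 1 + n_drift)` with
#'   column names; attribute `conditions` lists the condition columns.
#' @export
design_matrix <- function(events, n_frames, tr_s, hrf = hrf_spec(),
                          n_drift = 2L) {
  conds <- unique(events$trial_type)
  kern <- hrf_kernel(hrf, tr_s)
  reg <- vapply(conds, function(cc) {
    box <- numeric(n_frames)
    rows <- events[events$trial_type == cc, , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      idx <- block_frame_indices(rows$onset[j], rows$onset[j] + rows$duration[j],
                                 tr_s)
      idx <- idx[idx < n_frames]
      box[idx + 1L] <- 1
    }
    stats::convolve(box, rev(kern), type = "open")[seq_len(n_frames)]
  }, numeric(n_frames))
  tgrid <- (seq_len(n_frames) - 0.5) / n_frames
  drift <- if (n_drift > 0) {
    vapply(seq_len(n_drift), function(j) cos(j * pi * tgrid),
           numeric(n_frames))
  } else NULL
  X <- cbind(reg, intercept = 1, drift)
  colnames(X) <- c(conds, "intercept",
                   if (n_drift > 0) paste0("drift", seq_len(n_drift)))
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  attr(X, "conditions") <- conds
  X
}

#' Voxelwise GLM beta images for one run
#'
#' Ordinary least squares of every voxel's time course on the design matrix;
#' returns one 3D beta image per condition.
#'
#' @param run a [bold_run()].
#' @param events events tibble for the run.
#' @param hrf an [hrf_spec()].
#' @param n_drift cosine drift regressors in the design.
#' @return A list of class `beta_images`: `betas` (named list of 3D arrays,
#'   one per condition), `all_betas` (full coefficient matrix,
#'   regressors x voxels), `design`, `subject_id`, `grid`.
#' @export
fit_glm <- function(run, events, hrf = hrf_spec(), n_drift = 2L) {
  stopifnot(inherits(run, "bold_run"))
  d <- dim(run$data)
  nt <- d[1]
  X <- design_matrix(events, nt, run$tr_s, hrf, n_drift)
  Y <- matrix(run$data, nt, prod(d[2:4]))
  B <- qr.coef(qr(X), Y)      # regressors x voxels
  conds <- attr(X, "conditions")
  betas <- lapply(conds, function(cc) array(B[cc, ], d[2:4]))
  names(betas) <- conds
  structure(list(betas = betas, all_betas = B, design = X,
                 subject_id = run$subject_id, grid = run$grid),
            class = "beta_images")
}

#' Run-wise beta images for every subject of a design
#'
#' @param design a [synthetic_design()].
#' @param hrf an [hrf_spec()].
#' @return Tibble: `subject_id`, `label`, `beta` (list of 3D arrays).
#' @export
dataset_betas <- function(design, hrf = hrf_spec()) {
  subjects <- sprintf("sub-%02d", seq_len(design$n_subjects))
  rows <- purrr::map(subjects, function(sid) {
    sim <- simulate_subject_run(design, sid, hrf = hrf)
    g <- fit_glm(sim$run, sim$events, hrf)
    tibble::tibble(subject_id = sid, label = names(g$betas),
                   beta = unname(g$betas))
  })
  dplyr::bind_rows(rows)
}

#' Integer offsets of a voxel sphere
#'
#' All integer displacements `(dx, dy, dz)` with
#' `dx^2 + dy^2 + dz^2 <= radius^2`. A radius of 3 gives 123 offsets.
#'
#' @param radius_voxels sphere radius in voxels (>= 0).
#' @return Integer matrix with columns `dx`, `dy`, `dz`.
#' @export
sphere_offsets <- function(radius_voxels = 3) {
  stopifnot(radius_voxels >= 0)
  r <- floor(radius_voxels)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  keep <- g$dx^2 + g$dy^2 + g$dz^2 <= radius_voxels^2
  m <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

# Flatten a beta tibble into feature matrix (rows = samples) for given voxels.
beta_feature_matrix <- function(betas, voxel_lin) {
  t(vapply(betas$beta, function(b) as.numeric(b)[voxel_lin],
           numeric(length(voxel_lin))))
}

svm_fold_predictions <- function(features, labels, subjects, fold_plan,
                                 cost = 1) {
  folds <- if (inherits(fold_plan, "fold_plan")) fold_plan$folds else fold_plan
  purrr::map(folds, function(f) {
    tr <- subjects %in% f$train | subjects %in% (f$validation %||% character(0))
    te <- subjects %in% f$test
    if (!any(tr) || !any(te)) return(NULL)
    if (length(unique(labels[tr])) < 2) return(NULL)
    fit <- e1071::svm(x = features[tr, , drop = FALSE],
                      y = factor(labels[tr]), kernel = "linear", cost = cost,
                      scale = FALSE)
    pred <- as.character(predict(fit, features[te, , drop = FALSE]))
    tibble::tibble(truth = labels[te], predicted = pred,
                   subject_id = subjects[te])
  })
}

#' Whole-brain linear SVM on beta images
#'
#' Flattens each sample's beta image over the mask and classifies with a
#' multi-class linear support vector machine (one-vs-one voting, cost 1),
#' under subject-wise cross-validation.
#'
#' @param betas tibble from [dataset_betas()] (columns `subject_id`, `label`,
#'   `beta`).
#' @param fold_plan a [make_fold_plan()] (train + validation subjects are
#'   pooled for fitting; test subjects are scored).
#' @param mask optional logical 3D array; defaults to all voxels.
#' @param cost SVM regularization constant.
#' @return Tibble with one row per fold: `fold`, `accuracy`, `n_test`.
#' @export
whole_brain_svm <- function(betas, fold_plan, mask = NULL, cost = 1) {
  d <- dim(betas$beta[[1]])
  lin <- if (is.null(mask)) seq_len(prod(d)) else which(as.logical(mask))
  if (length(lin) == 0) stop("mask selects no voxels", call. = FALSE)
  feats <- beta_feature_matrix(betas, lin)
  preds <- svm_fold_predictions(feats, betas$label, betas$subject_id,
                                fold_plan, cost)
  purrr::imap_dfr(preds, function(p, i) {
    if (is.null(p)) return(NULL)
    tibble::tibble(fold = i, accuracy = mean(p$truth == p$predicted),
                   n_test = nrow(p))
  })
}

#' ROI linear SVM on beta images
#'
#' [whole_brain_svm()] restricted to a region-of-interest mask.
#'
#' @param betas tibble from [dataset_betas()].
#' @param fold_plan a [make_fold_plan()].
#' @param roi_mask logical 3D array or integer voxel-coordinate matrix
#'   selecting the ROI (required).
#' @param cost SVM regularization constant.
#' @return Tibble with one row per fold: `fold`, `accuracy`, `n_test`.
#' @export
roi_svm <- function(betas, fold_plan, roi_mask, cost = 1) {
  d <- dim(betas$beta[[1]])
  if (is.matrix(roi_mask) && ncol(roi_mask) == 3) {
    m <- array(FALSE, d)
    m[roi_mask] <- TRUE
    roi_mask <- m
  }
  if (!any(roi_mask)) stop("ROI mask is empty", call. = FALSE)
  whole_brain_svm(betas, fold_plan, mask = roi_mask, cost = cost)
}

#' Searchlight MVPA with per-condition F1 maps
#'
#' Slides a sphere of `radius` voxels over the mask; at each voxel the
#' features are the beta values within the sphere (clipped at the mask
#' edge), classified with a linear multi-class SVM under subject-wise
#' cross-validation; the per-condition F1 of the pooled test predictions is
#' written at the centre voxel.
#'
#' @param betas tibble from [dataset_betas()].
#' @param fold_plan a [make_fold_plan()].
#' @param radius sphere radius in voxels (default 3).
#' @param mask logical 3D array of voxels to visit; defaults to all.
#' @param cost SVM regularization constant.
#' @return A list of class `searchlight_result`: `f1` (named list of 3D
#'   arrays, one per condition, `NA` outside the mask), `radius`, `labels`.
#' @export
searchlight_classify <- function(betas, fold_plan, radius = 3, mask = NULL,
                                 cost = 1) {
  d <- dim(betas$beta[[1]])
  if (is.null(mask)) mask <- array(TRUE, d)
  offs <- sphere_offsets(radius)
  labels <- sort(unique(betas$label))
  f1_maps <- lapply(labels, function(...) array(NA_real_, d))
  names(f1_maps) <- labels
  centres <- which(mask, arr.ind = TRUE)
  beta_mat <- vapply(betas$beta, as.numeric, numeric(prod(d)))  # vox x samples
  mask_lin <- as.logical(mask)
  for (ci in seq_len(nrow(centres))) {
    cx <- centres[ci, ]
    vx <- sweep(offs, 2, cx, "+")
    keep <- vx[, 1] >= 1 & vx[, 1] <= d[1] & vx[, 2] >= 1 & vx[, 2] <= d[2] &
      vx[, 3] >= 1 & vx[, 3] <= d[3]
    vx <- vx[keep, , drop = FALSE]
    lin <- (vx[, 1] - 1) + d[1] * ((vx[, 2] - 1) + d[2] * (vx[, 3] - 1)) + 1
    lin <- lin[mask_lin[lin]]
    if (length(lin) == 0) next
    feats <- t(beta_mat[lin, , drop = FALSE])
    preds <- svm_fold_predictions(feats, betas$label, betas$subject_id,
                                  fold_plan, cost)
    pooled <- dplyr::bind_rows(preds)
    if (nrow(pooled) == 0) next
    cm <- confusion_matrix(pooled$truth, pooled$predicted, labels = labels)
    for (l in labels) {
      f1_maps[[l]][cx[1], cx[2], cx[3]] <-
        suppressWarnings(f1_score(tally_label(cm, l)))
    }
  }
  structure(list(f1 = f1_maps, radius = radius, labels = labels),
            class = "searchlight_result")
}
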