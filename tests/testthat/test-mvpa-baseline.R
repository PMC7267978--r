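glm_design <- function(noise_sd = 0, amplitude = 2.5, seed = 31,
                       subject_effect_sd = 0, drift_amplitude = 0) {
  tiny_design(n_subjects = 1, labels = c("a", "b"), duration_s = 4,
              amplitude = amplitude, noise_sd = noise_sd,
              subject_effect_sd = subject_effect_sd,
              drift_amplitude = drift_amplitude, seed = seed)
}

test_that("noiseless GLM recovers planted amplitudes to machine precision", {
  d <- glm_design()
  sim <- simulate_subject_run(d, "sub-01")
  g <- fit_glm(sim$run, sim$events)
  for (i in 1:2) {
    fp <- d$conditions$footprint[[i]]
    b <- g$betas[[d$conditions$label[i]]][fp]
    expect_lt(max(abs(b - 2.5) / 2.5), 1e-6)
  }
  # intercept picks up the baseline
  expect_equal(mean(g$all_betas["intercept", ]), d$baseline, tolerance = 1e-6)
})

test_that("zero-signal runs give near-zero betas and constants shift only the intercept", {
  d <- glm_design(noise_sd = 1, amplitude = 1e-12, seed = 33)
  sim <- simulate_subject_run(d, "sub-01", seed = 33)
  g <- fit_glm(sim$run, sim$events)
  # |beta| under the null stays within a few noise standard errors
  expect_lt(max(abs(g$betas[["a"]])), 1.5)

  shifted <- sim$run
  shifted$data <- shifted$data + 7
  g2 <- fit_glm(shifted, sim$events)
  expect_equal(g2$betas[["a"]], g$betas[["a"]], tolerance = 1e-8)
  expect_equal(mean(g2$all_betas["intercept", ] - g$all_betas["intercept", ]),
               7, tolerance = 1e-8)
})

test_that("GLM residuals are orthogonal to the design columns", {
  d <- glm_design(noise_sd = 1, seed = 35)
  sim <- simulate_subject_run(d, "sub-01")
  g <- fit_glm(sim$run, sim$events)
  nt <- dim(sim$run$data)[1]
  Y <- matrix(sim$run$data, nt, prod(d$grid$shape))
  resid <- Y - g$design %*% g$all_betas
  xr <- crossprod(g$design, resid)
  expect_lt(max(abs(xr)) / max(abs(Y)), 1e-8)
})

test_that("degenerate designs are rejected", {
  ev <- tibble::tibble(onset = c(0, 0), duration = c(4, 4),
                       trial_type = c("a", "a2"))
  # two identical regressors -> rank deficient
  expect_error(design_matrix(ev, 40, 0.72), "rank")
})

test_that("sphere offsets match brute-force enumeration and its symmetries", {
  # independent oracle: enumerate the full cube and filter
  oracle_count <- function(r) {
    g <- expand.grid(-r:r, -r:r, -r:r)
    sum(g[, 1]^2 + g[, 2]^2 + g[, 3]^2 <= r^2)
  }
  expect_equal(nrow(sphere_offsets(0)), 1L)
  expect_equal(nrow(sphere_offsets(1)), 7L)
  expect_equal(nrow(sphere_offsets(3)), 123L)
  for (r in 0:4) expect_equal(nrow(sphere_offsets(r)), oracle_count(r))
  counts <- vapply(0:4, function(r) nrow(sphere_offsets(r)), integer(1))
  expect_true(all(diff(counts) > 0))
  off <- sphere_offsets(3)
  key <- function(m) sort(apply(unname(m), 1, paste, collapse = ","))
  expect_equal(key(off), key(off[, c(2, 3, 1)]))  # axis permutation
  expect_equal(key(off), key(-off))               # sign flip
})

baseline_betas <- function(n_subjects = 8, amplitude = 3, seed = 37) {
  d <- tiny_design(n_subjects = n_subjects, labels = c("a", "b", "c", "d"),
                   duration_s = 4, amplitude = amplitude, noise_sd = 1,
                   blocks_per_condition = 1, seed = seed)
  list(design = d, betas = dataset_betas(d))
}

test_that("separable betas decode perfectly; shuffled labels fall to chance", {
  r <- baseline_betas()
  plan <- make_fold_plan(unique(r$betas$subject_id), c(0.6, 0.2, 0.2),
                         n_folds = 4, seed = 37)
  acc <- whole_brain_svm(r$betas, plan)
  expect_equal(nrow(acc), 4L)
  expect_gt(mean(acc$accuracy), 0.95)

  shuffled <- r$betas
  withr::local_seed(38)
  shuffled$label <- sample(shuffled$label)
  acc0 <- whole_brain_svm(shuffled, plan)
  expect_lt(abs(mean(acc0$accuracy) - 0.25), 0.25)
})

test_that("an all-true ROI reproduces the whole-brain result exactly", {
  r <- baseline_betas(n_subjects = 6)
  plan <- make_fold_plan(unique(r$betas$subject_id), c(0.6, 0.2, 0.2),
                         n_folds = 3, seed = 39)
  whole <- whole_brain_svm(r$betas, plan)
  roi <- roi_svm(r$betas, plan, array(TRUE, r$design$grid$shape))
  expect_equal(roi, whole)
  expect_error(roi_svm(r$betas, plan, array(FALSE, r$design$grid$shape)),
               "empty")
})

test_that("searchlight F1 maps localize the planted class", {
  r <- baseline_betas(n_subjects = 8)
  d <- r$design
  plan <- make_fold_plan(unique(r$betas$subject_id), c(0.6, 0.2, 0.2),
                         n_folds = 4, seed = 41)
  fp <- d$conditions$footprint[[1]]
  cls <- d$conditions$label[1]
  # visit the footprint's neighbourhood plus a distant control region
  mask <- array(FALSE, d$grid$shape)
  mask[fp] <- TRUE
  ctr <- round(colMeans(fp))
  mask[max(1, ctr[1] - 2):min(d$grid$shape[1], ctr[1] + 2),
       max(1, ctr[2] - 2):min(d$grid$shape[2], ctr[2] + 2),
       max(1, ctr[3] - 2):min(d$grid$shape[3], ctr[3] + 2)] <- TRUE
  far <- array(FALSE, d$grid$shape)
  far[d$grid$shape[1] - 1, 1:3, 1:3] <- TRUE
  sl <- searchlight_classify(r$betas, plan, radius = 2, mask = mask | far)
  f1 <- sl$f1[[cls]]
  vals <- f1[!is.na(f1)]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_gt(mean(f1[fp], na.rm = TRUE), mean(f1[far], na.rm = TRUE))
})

test_that("radius-0 searchlight degenerates to single-voxel MVPA", {
  r <- baseline_betas(n_subjects = 6)
  plan <- make_fold_plan(unique(r$betas$subject_id), c(0.6, 0.2, 0.2),
                         n_folds = 3, seed = 43)
  mask <- array(FALSE, r$design$grid$shape)
  fp <- r$design$conditions$footprint[[1]]
  mask[fp[1, 1], fp[1, 2], fp[1, 3]] <- TRUE
  sl0 <- searchlight_classify(r$betas, plan, radius = 0, mask = mask)
  # oracle: single-voxel features through the same fold/SVM machinery
  lin <- voxel_linear(fp[1, , drop = FALSE], r$design$grid$shape)
  feats <- matrix(vapply(r$betas$beta, function(b) as.numeric(b)[lin],
                         numeric(1)), ncol = 1)
  preds <- fmridecode:::svm_fold_predictions(feats, r$betas$label,
                                             r$betas$subject_id, plan)
  pooled <- dplyr::bind_rows(preds)
  cm <- confusion_matrix(pooled$truth, pooled$predicted,
                         labels = sort(unique(r$betas$label)))
  want <- suppressWarnings(f1_score(tally_label(cm, r$design$conditions$label[1])))
  expect_equal(sl0$f1[[r$design$conditions$label[1]]][fp[1, 1], fp[1, 2], fp[1, 3]],
               want)
})
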