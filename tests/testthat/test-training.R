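make_fake_sample <- function(nt, label = "a", subject = "sub-01") {
  bold_sample(array(seq_len(nt * 8), c(nt, 2, 2, 2)), label, subject, 0.72)
}

test_that("temporal crops have the right length, content and distribution", {
  s <- make_fake_sample(27)
  expect_identical(random_temporal_crop(s, 27)$data, s$data)  # identity crop

  s50 <- make_fake_sample(50)
  withr::local_seed(1)
  starts <- replicate(10000, {
    cr <- random_temporal_crop(s50, 27)
    cr$data[1, 1, 1, 1] - 1  # frame index is encoded in the data
  })
  expect_true(all(starts %in% 0:23))
  freq <- tabulate(starts + 1, 24) / 10000
  se <- sqrt((1 / 24) * (23 / 24) / 10000)
  expect_true(all(abs(freq - 1 / 24) < 3.5 * se))

  cr <- random_temporal_crop(s50, 10)
  st <- cr$data[1, 1, 1, 1]
  expect_equal(cr$data[, 1, 1, 1], s50$data[st:(st + 9), 1, 1, 1])
  expect_error(random_temporal_crop(make_fake_sample(5), 10), "frames")
})

test_that("the deterministic crop takes the first k frames and is idempotent", {
  s <- make_fake_sample(30)
  cr <- deterministic_first_crop(s, 27)
  expect_equal(dim(cr$data)[1], 27L)
  expect_equal(cr$data[, 1, 1, 1], s$data[1:27, 1, 1, 1])
  expect_identical(deterministic_first_crop(cr, 27)$data, cr$data)
  expect_identical(deterministic_first_crop(s, 30)$data, s$data)
})

test_that("fold plans partition subjects at the requested ratios", {
  subs <- sprintf("s%02d", 1:43)
  plan <- make_fold_plan(subs, ratios = c(0.6, 0.2, 0.2), n_folds = 5, seed = 3)
  tests <- lapply(plan$folds, `[[`, "test")
  expect_setequal(unlist(tests), subs)               # every subject tests once
  expect_equal(sum(lengths(tests)), 43L)             # ... exactly once
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$validation), 0)
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$validation, f$test), 0)
    expect_setequal(c(f$train, f$validation, f$test), subs)
    # 43 subjects at 60/20/20: 25-26 train, 9 validation, 8-9 test per fold
    expect_equal(length(f$validation), 9L)
    expect_true(length(f$test) %in% 8:9)
    expect_true(length(f$train) %in% 25:26)
  }
  # determinism and seed sensitivity
  plan2 <- make_fold_plan(subs, c(0.6, 0.2, 0.2), 5, seed = 3)
  expect_identical(plan, plan2)
  expect_error(make_fold_plan(sprintf("s%d", 1:3), n_folds = 5), "at least")
})

test_that("five subjects in five folds each test exactly once", {
  plan <- make_fold_plan(letters[1:5], ratios = c(0.6, 0.2, 0.2),
                         n_folds = 5, seed = 1)
  expect_setequal(unlist(lapply(plan$folds, `[[`, "test")), letters[1:5])
  expect_true(all(lengths(lapply(plan$folds, `[[`, "test")) == 1))
})

digest_id <- function(x) paste(utf8ToInt(x), collapse = "-")

test_that("no subject leaks across partitions in any fold of a real run", {
  d <- tiny_design(n_subjects = 8)
  ds <- generate_dataset(d, post_window_s = 3)
  plan <- make_fold_plan(unique(ds$subject_id), n_folds = 4, seed = 5)
  for (f in plan$folds) {
    ids <- list(train = unique(ds$subject_id[ds$subject_id %in% f$train]),
                val = unique(ds$subject_id[ds$subject_id %in% f$validation]),
                test = unique(ds$subject_id[ds$subject_id %in% f$test]))
    hashes <- lapply(ids, function(x) vapply(x, digest_id, character(1)))
    expect_length(Reduce(intersect, hashes), 0)
  }
})

train_tiny <- function(max_epochs = 3, seed = 1, noise_sd = 1,
                       patience = 15, n_subjects = 5, amplitude = 3,
                       drift = 0.5, lr0 = 1e-3, batch_size = 8) {
  d <- tiny_design(n_subjects = n_subjects, duration_s = 3, noise_sd = noise_sd,
                   amplitude = amplitude, grid = tiny_grid(c(8, 8, 8)),
                   radii = c(1, 1, 1), seed = 17, drift_amplitude = drift)
  ds <- generate_dataset(d, post_window_s = 3)
  k <- min(ds$n_frames)
  labels <- sort(unique(ds$label))
  plan <- make_fold_plan(unique(ds$subject_id), ratios = c(0.6, 0.2, 0.2),
                         n_folds = n_subjects, seed = seed)
  model <- build_model(tiny_arch(length(labels), input_frames = k), d$grid,
                       labels = labels, seed = seed)
  cfg <- train_config(k = k, batch_size = batch_size, lr0 = lr0,
                      max_epochs = max_epochs,
                      plateau_patience_epochs = patience, seed = seed)
  list(fit = train_decoder(model, ds, plan$folds[[1]], cfg),
       dataset = ds, fold = plan$folds[[1]], cfg = cfg)
}

test_that("training histories are identical under a fixed seed", {
  a <- train_tiny(max_epochs = 2, seed = 4)
  b <- train_tiny(max_epochs = 2, seed = 4)
  expect_identical(a$fit$history, b$fit$history)
})

test_that("the learning rate is divided by 10 after a validation plateau", {
  # near-zero signal: the validation loss cannot keep improving
  r <- train_tiny(max_epochs = 8, seed = 2, patience = 2, amplitude = 0.01)
  h <- r$fit$history
  expect_equal(sort(unique(h$lr), decreasing = TRUE)[1:2], c(1e-3, 1e-4))
  # the decay happens only after `patience` epochs without improvement
  first_drop <- min(which(h$lr < 1e-3))
  expect_gte(first_drop, 3)
})

test_that("the returned checkpoint is the minimum-validation-loss epoch", {
  r <- train_tiny(max_epochs = 6, seed = 3)
  h <- r$fit$history
  expect_lte(h$val_loss[r$fit$best_epoch], min(h$val_loss) + r$cfg$min_delta)
  # the stored weights reproduce the recorded best validation loss
  va <- r$dataset[r$dataset$subject_id %in% r$fold$validation, ]
  x <- fmridecode:::batch_from_samples(
    lapply(va$sample, deterministic_first_crop, k = r$cfg$k))
  y <- match(va$label, r$fit$model$labels)
  fw <- fmridecode:::forward_pass(r$fit$model, x, training = FALSE)
  ce <- fmridecode:::cross_entropy(fw$logits, y)
  expect_equal(ce$loss, h$val_loss[r$fit$best_epoch], tolerance = 1e-6)
})

test_that("training loss collapses on noiseless separable data", {
  # a larger step size suits the tiny network and few steps per epoch here
  r <- train_tiny(max_epochs = 60, seed = 6, noise_sd = 0, drift = 0,
                  lr0 = 0.02, batch_size = 12, patience = 1000)
  expect_lt(min(r$fit$history$train_loss), 1e-2)
})

test_that("transfer re-initializes only the class head", {
  r <- train_tiny(max_epochs = 2, seed = 8)
  src <- r$fit$model
  tgt <- fmridecode:::reset_head(src, c("x", "y", "z"), head_seed = 9)
  expect_equal(tgt$cfg$n_classes, 3L)
  # head parameter count changes by (fc_width + 1) * delta-classes
  expect_equal(count_parameters(tgt) - count_parameters(src),
               (src$cfg$fc_width + 1) * (3 - src$cfg$n_classes))
  trunk <- setdiff(names(src$params), c("fc2.w", "fc2.b"))
  for (nm in trunk) expect_identical(tgt$params[[nm]], src$params[[nm]])
  expect_false(isTRUE(all.equal(dim(tgt$params$fc2.w), dim(src$params$fc2.w))))
})

test_that("the learning curve returns one row per requested size", {
  d <- tiny_design(n_subjects = 6, duration_s = 3, grid = tiny_grid(c(8, 8, 8)),
                   radii = c(1, 1, 1), seed = 19)
  ds <- generate_dataset(d, post_window_s = 3)
  k <- min(ds$n_frames)
  plan <- make_fold_plan(unique(ds$subject_id), ratios = c(0.5, 0.2, 0.3),
                         n_folds = 3, seed = 2)
  cfg <- train_config(k = k, batch_size = 8, max_epochs = 1, seed = 2)
  curve <- learning_curve(ds, plan$folds[[1]], n_subj_list = c(1, 2),
                          cfg = cfg, model_factory = function(lab) {
    build_model(tiny_arch(length(lab), input_frames = k), d$grid,
                labels = lab, seed = 2)
  })
  expect_equal(curve$n_subjects, c(1, 2))
  expect_true(all(curve$test_accuracy >= 0 & curve$test_accuracy <= 1))
  expect_error(
    learning_curve(ds, plan$folds[[1]], n_subj_list = 50, cfg = cfg,
                   model_factory = identity), "training subjects")
})
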