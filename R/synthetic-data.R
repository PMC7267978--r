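#' Haemodynamic response function specification
#'
#' Parameters of the canonical double-gamma HRF: a positive response peaking
#' around 6 s followed by a smaller undershoot around 16 s, with the
#' undershoot scaled to 1/6 of the peak.
#'
#' @param peak_delay_s delay of the positive peak (s).
#' @param undershoot_delay_s delay of the undershoot (s).
#' @param peak_dispersion dispersion (scale) of the peak gamma.
#' @param undershoot_dispersion dispersion of the undershoot gamma.
#' @param undershoot_ratio undershoot amplitude relative to the peak.
#' @param length_s kernel support length (s); must cover the undershoot.
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     undershoot_ratio = 1 / 6, length_s = 32) {
  vals <- c(peak_delay_s, undershoot_delay_s, peak_dispersion,
            undershoot_dispersion, undershoot_ratio, length_s)
  stopifnot(all(vals > 0), length_s >= undershoot_delay_s)
  structure(
    list(peak_delay_s = peak_delay_s, undershoot_delay_s = undershoot_delay_s,
         peak_dispersion = peak_dispersion,
         undershoot_dispersion = undershoot_dispersion,
         undershoot_ratio = undershoot_ratio, length_s = length_s),
    class = "hrf_spec"
  )
}

#' Sample the HRF kernel at the acquisition rate
#'
#' Evaluates the double-gamma response at `t = 0, TR, 2*TR, ...` over the
#' kernel support and normalizes the kernel to unit peak.
#'
#' @param spec an [hrf_spec()].
#' @param tr_s sampling interval in seconds (> 0).
#' @return Numeric vector of kernel weights with `max(kernel) == 1`.
#' @export
hrf_kernel <- function(spec = hrf_spec(), tr_s = 0.72) {
  stopifnot(inherits(spec, "hrf_spec"), tr_s > 0)
  t <- seq(0, spec$length_s, by = tr_s)
  h <- hrf_eval(spec, t)
  h / max(h)
}

# Double-gamma evaluated at arbitrary times (unnormalized).
hrf_eval <- function(spec, t) {
  shape1 <- spec$peak_delay_s / spec$peak_dispersion
  shape2 <- spec$undershoot_delay_s / spec$undershoot_dispersion
  stats::dgamma(t, shape = shape1, scale = spec$peak_dispersion) -
    spec$undershoot_ratio *
      stats::dgamma(t, shape = shape2, scale = spec$undershoot_dispersion)
}

#' Design of a synthetic multi-subject block-design experiment
#'
#' Declares the simulated acquisition: the spatial grid, the task conditions
#' with their block durations, planted spatial activation footprints and
#' effect amplitudes, the subject count, block counts, TR, and the noise
#' model (white Gaussian innovations with AR(1) temporal correlation, plus a
#' slow cosine drift). Per-subject responsiveness is jittered
#' multiplicatively so subject-wise cross-validation is meaningful.
#'
#' @param conditions tibble with columns `label`, `duration_s`, `footprint`
#'   (list of integer matrices of 1-based voxel indices, one row per voxel),
#'   `amplitude` (percent-signal effect height, > 0). Use
#'   [condition_table()] to build one with ellipsoid footprints.
#' @param grid a [volume_grid()]; default 24 x 28 x 24.
#' @param n_subjects number of simulated subjects.
#' @param blocks_per_condition blocks of each condition per run.
#' @param tr_s repetition time (default 0.72 s).
#' @param noise_sd SD of the Gaussian innovation noise (signal units).
#' @param ar1 AR(1) coefficient of the temporal noise (0 <= ar1 < 1).
#' @param drift_amplitude amplitude of the slow cosine drift.
#' @param subject_effect_sd SD of the per-subject multiplicative amplitude
#'   jitter, `gain ~ Normal(1, subject_effect_sd)` truncated at 0.1.
#' @param baseline constant signal offset.
#' @param rest_s rest interval between blocks (s).
#' @param strict_footprints error on overlapping footprints (default TRUE).
#' @param seed integer seed controlling the whole design's randomness.
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(conditions = condition_table(),
                             grid = volume_grid(c(24, 28, 24)),
                             n_subjects = 20, blocks_per_condition = 2,
                             tr_s = 0.72, noise_sd = 1, ar1 = 0.3,
                             drift_amplitude = 0.5, subject_effect_sd = 0.1,
                             baseline = 100, rest_s = 2.16,
                             strict_footprints = TRUE, seed = 1L) {
  stopifnot(inherits(grid, "volume_grid"), n_subjects >= 1,
            blocks_per_condition >= 1, tr_s > 0, noise_sd >= 0,
            ar1 >= 0, ar1 < 1, drift_amplitude >= 0, subject_effect_sd >= 0)
  conditions <- tibble::as_tibble(conditions)
  stopifnot(all(c("label", "duration_s", "footprint", "amplitude") %in%
                  names(conditions)))
  stopifnot(all(conditions$amplitude > 0), all(conditions$duration_s > 0),
            all(nzchar(conditions$label)), !anyDuplicated(conditions$label))
  lin <- lapply(conditions$footprint, function(fp) {
    stopifnot(is.matrix(fp), ncol(fp) == 3, nrow(fp) >= 1)
    stopifnot(all(fp >= 1), all(t(fp) <= grid$shape))
    (fp[, 1] - 1) + grid$shape[1] * ((fp[, 2] - 1) + grid$shape[2] * (fp[, 3] - 1)) + 1
  })
  all_idx <- unlist(lin)
  if (strict_footprints && anyDuplicated(all_idx)) {
    stop("condition footprints overlap; pass strict_footprints = FALSE to allow",
         call. = FALSE)
  }
  structure(
    list(conditions = conditions, footprint_linear = lin, grid = grid,
         n_subjects = as.integer(n_subjects),
         blocks_per_condition = as.integer(blocks_per_condition),
         tr_s = tr_s, noise_sd = noise_sd, ar1 = ar1,
         drift_amplitude = drift_amplitude,
         subject_effect_sd = subject_effect_sd, baseline = baseline,
         rest_s = rest_s, seed = as.integer(seed)),
    class = "synthetic_design"
  )
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf(
    "<synthetic_design: %d conditions x %d subjects x %d blocks on %s, TR %.3g s, noise sd %.3g (AR1 %.2g)>\n",
    nrow(x$conditions), x$n_subjects, x$blocks_per_condition,
    paste(x$grid$shape, collapse = "x"), x$tr_s, x$noise_sd, x$ar1))
  invisible(x)
}

#' Build a condition table with ellipsoid footprints
#'
#' Lays out one axis-aligned ellipsoid per condition, centred on a coarse
#' lattice inside the grid so footprints are pairwise disjoint — a stylized
#' analogue of distinct task topographies (motor strip, language areas, ...).
#'
#' @param labels condition labels.
#' @param duration_s block durations in seconds, recycled across conditions.
#'   The defaults follow the block lengths of the seven classic task
#'   conditions (emotion 18, gambling 28, language 20, motor 12,
#'   relational 16, social 23, working memory 27.5 s) truncated to `labels`.
#' @param amplitude effect heights, recycled.
#' @param grid the target [volume_grid()].
#' @param radii ellipsoid semi-axes in voxels.
#' @return Tibble suitable for [synthetic_design()].
#' @export
condition_table <- function(labels = c("emotion", "gambling", "language", "motor"),
                            duration_s = c(18, 28, 20, 12, 16, 23, 27.5),
                            amplitude = 3,
                            grid = volume_grid(c(24, 28, 24)),
                            radii = c(2, 2, 2)) {
  k <- length(labels)
  duration_s <- rep_len(duration_s, k)
  amplitude <- rep_len(amplitude, k)
  centers <- footprint_centers(k, grid$shape, radii)
  fps <- lapply(seq_len(k), function(i) {
    ellipsoid_footprint(centers[i, ], radii, grid$shape)
  })
  tibble::tibble(label = labels, duration_s = duration_s,
                 footprint = fps, amplitude = amplitude)
}

# Spread k centers on a 2x2x2 (or denser) lattice with margins for the radii.
footprint_centers <- function(k, shape, radii) {
  per_axis <- ceiling(k^(1 / 3))
  per_axis <- max(per_axis, 2L)
  pos <- function(n, extent, r) {
    lo <- r + 2
    hi <- extent - r - 1
    round(seq(lo, hi, length.out = n))
  }
  gx <- pos(per_axis, shape[1], radii[1])
  gy <- pos(per_axis, shape[2], radii[2])
  gz <- pos(per_axis, shape[3], radii[3])
  lattice <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  lattice[seq_len(k), , drop = FALSE]
}

#' Voxel indices of an axis-aligned ellipsoid
#'
#' @param center 1-based voxel center (length 3).
#' @param radii semi-axes in voxels.
#' @param shape grid shape for clipping.
#' @return Integer matrix, one row of (x, y, z) per voxel inside the ellipsoid.
#' @export
ellipsoid_footprint <- function(center, radii, shape) {
  rng <- function(c, r, n) max(1, floor(c - r)):min(n, ceiling(c + r))
  g <- expand.grid(x = rng(center[1], radii[1], shape[1]),
                   y = rng(center[2], radii[2], shape[2]),
                   z = rng(center[3], radii[3], shape[3]))
  d <- ((g$x - center[1]) / radii[1])^2 + ((g$y - center[2]) / radii[2])^2 +
    ((g$z - center[3]) / radii[3])^2
  m <- as.matrix(g[d <= 1, , drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Simulate one subject's continuous run
#'
#' Builds the block schedule (conditions interleaved in a fixed rotation,
#' separated by rest), convolves each condition's boxcar with the HRF, plants
#' the scaled response on that condition's footprint voxels, and adds AR(1)
#' Gaussian noise plus a slow cosine drift on top of the constant baseline.
#' Identical `(design, subject_id, seed)` triples give bit-identical output.
#'
#' @param design a [synthetic_design()].
#' @param subject_id subject identifier (also used in the events table).
#' @param seed integer seed for this run; defaults to a subject-specific
#'   stream derived from `design$seed`.
#' @param hrf an [hrf_spec()].
#' @return A list with elements `run` (a [bold_run()]) and `events` (tibble).
#' @export
simulate_subject_run <- function(design, subject_id, seed = NULL,
                                 hrf = hrf_spec()) {
  stopifnot(inherits(design, "synthetic_design"))
  if (is.null(seed)) {
    sub_i <- suppressWarnings(as.integer(gsub("\\D", "", subject_id)))
    if (is.na(sub_i)) sub_i <- 0L
    seed <- (design$seed * 1000L + sub_i) %% .Machine$integer.max
  }
  shape <- design$grid$shape
  nvox <- prod(shape)
  tr <- design$tr_s
  conds <- design$conditions
  k <- nrow(conds)

  # schedule: rotate through conditions, blocks_per_condition cycles
  sched <- tibble::tibble(
    trial_type = rep(conds$label, times = design$blocks_per_condition),
    duration = rep(conds$duration_s, times = design$blocks_per_condition)
  )
  gaps <- rep(design$rest_s, nrow(sched))
  ends <- cumsum(sched$duration + gaps)
  sched$onset <- c(0, ends[-length(ends)])
  total_s <- ends[length(ends)] + 12  # tail past the last block for the HRF
  nt <- ceiling(total_s / tr)

  kern <- hrf_kernel(hrf, tr)

  withr::local_seed(seed)
  gain <- max(0.1, stats::rnorm(1, 1, design$subject_effect_sd))

  data <- matrix(0, nt, nvox)
  if (design$noise_sd > 0) {
    innov <- matrix(stats::rnorm(nt * nvox, 0, design$noise_sd), nt, nvox)
    if (design$ar1 > 0) {
      noise <- matrix(0, nt, nvox)
      noise[1, ] <- innov[1, ] / sqrt(1 - design$ar1^2)
      for (t in 2:nt) noise[t, ] <- design$ar1 * noise[t - 1, ] + innov[t, ]
      data <- data + noise
    } else {
      data <- data + innov
    }
  }
  if (design$drift_amplitude > 0) {
    # first two discrete-cosine drift terms with random per-voxel phase weights
    tgrid <- (seq_len(nt) - 0.5) / nt
    basis <- cbind(cos(pi * tgrid), cos(2 * pi * tgrid))
    wts <- matrix(stats::rnorm(2 * nvox, 0, design$drift_amplitude), 2, nvox)
    data <- data + basis %*% wts
  }
  data <- data + design$baseline

  # planted responses: per condition, boxcar (frame-wise block occupancy) x HRF
  for (i in seq_len(k)) {
    rows <- sched$trial_type == conds$label[i]
    box <- numeric(nt)
    for (j in which(rows)) {
      on <- sched$onset[j]
      idx <- block_frame_indices(on, on + sched$duration[j], tr)
      idx <- idx[idx < nt]
      box[idx + 1L] <- 1
    }
    resp <- stats::convolve(box, rev(kern), type = "open")[seq_len(nt)]
    fp <- design$footprint_linear[[i]]
    data[, fp] <- data[, fp] + gain * conds$amplitude[i] * resp
  }

  dim(data) <- c(nt, shape)
  run <- bold_run(data, tr_s = tr, subject_id = subject_id, grid = design$grid)
  events <- tibble::tibble(onset = sched$onset, duration = sched$duration,
                           trial_type = sched$trial_type)
  list(run = run, events = events)
}

#' Generate a labeled multi-subject dataset
#'
#' Simulates every subject's run and applies [extract_block_sample()] to each
#' scheduled block, yielding one labeled 4D sample per block. Per-condition
#' sample counts equal `n_subjects * blocks_per_condition`.
#'
#' @param design a [synthetic_design()].
#' @param post_window_s post-block window passed to [extract_block_sample()].
#' @param hrf an [hrf_spec()].
#' @return Tibble with columns `subject_id`, `label`, `n_frames` and `sample`
#'   (list column of [bold_sample()] objects).
#' @export
generate_dataset <- function(design, post_window_s = 8, hrf = hrf_spec()) {
  stopifnot(inherits(design, "synthetic_design"))
  subjects <- sprintf("sub-%02d", seq_len(design$n_subjects))
  rows <- purrr::map(subjects, function(sid) {
    sim <- simulate_subject_run(design, sid, hrf = hrf)
    samples <- purrr::pmap(
      list(sim$events$onset, sim$events$duration, sim$events$trial_type),
      function(on, du, ty) {
        extract_block_sample(sim$run, on, du, label = ty,
                             post_window_s = post_window_s,
                             allow_truncate = TRUE)
      })
    tibble::tibble(
      subject_id = sid,
      label = sim$events$trial_type,
      n_frames = vapply(samples, function(s) dim(s$data)[1], integer(1)),
      sample = samples
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a dataset to disk as NIfTI + events TSV
#'
#' One 4D NIfTI and one events TSV per subject, simulated from the design.
#'
#' @param design a [synthetic_design()].
#' @param dir output directory (created if missing).
#' @return Tibble of written paths, invisibly.
#' @export
write_dataset_nifti <- function(design, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- sprintf("sub-%02d", seq_len(design$n_subjects))
  paths <- purrr::map(subjects, function(sid) {
    sim <- simulate_subject_run(design, sid)
    bold <- file.path(dir, paste0(sid, "_bold.nii.gz"))
    ev <- file.path(dir, paste0(sid, "_events.tsv"))
    write_bold_run(sim$run, bold)
    write_events(sim$events, ev)
    tibble::tibble(subject_id = sid, bold = bold, events = ev)
  })
  invisible(dplyr::bind_rows(paths))
}
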