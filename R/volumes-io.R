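#' Spatial sampling grid of a volume
#'
#' Describes the voxel lattice of a 3D volume: its extent in voxels, the voxel
#' size in millimetres, and the affine matrix mapping 0-based voxel indices to
#' world coordinates (mm). The default corresponds to a 2 mm isotropic grid
#' with the origin at the first voxel.
#'
#' @param shape integer vector of length 3, voxel counts along x, y, z (all >= 1).
#' @param voxel_size_mm positive numeric vector of length 3 (mm per voxel).
#' @param affine 4x4 invertible matrix mapping homogeneous 0-based voxel
#'   indices to world mm. Defaults to a diagonal scaling by `voxel_size_mm`.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size_mm = c(2, 2, 2), affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1L))
  stopifnot(length(voxel_size_mm) == 3, all(voxel_size_mm > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("grid affine must be invertible", call. = FALSE)
  }
  structure(
    list(shape = shape, voxel_size_mm = as.numeric(voxel_size_mm), affine = affine),
    class = "volume_grid"
  )
}

#' @export
format.volume_grid <- function(x, ...) {
  sprintf("<volume_grid %dx%dx%d, voxels %s mm>",
          x$shape[1], x$shape[2], x$shape[3],
          paste(signif(x$voxel_size_mm, 3), collapse = "x"))
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' A continuous BOLD run
#'
#' Bundles a 4D BOLD array with its repetition time, subject identifier and
#' spatial grid. The time axis is always the leading axis internally,
#' regardless of on-disk axis order.
#'
#' @param data numeric 4D array indexed `(t, x, y, z)` with `t >= 1`.
#' @param tr_s repetition time in seconds (> 0).
#' @param subject_id opaque subject identifier.
#' @param grid a [volume_grid()]; defaults to the array's spatial extent at
#'   2 mm isotropic.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, tr_s, subject_id = "sub-01", grid = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  stopifnot(dim(data)[1] >= 1, is.numeric(tr_s), tr_s > 0)
  if (is.null(grid)) grid <- volume_grid(dim(data)[2:4])
  stopifnot(inherits(grid, "volume_grid"))
  if (!all(dim(data)[2:4] == grid$shape)) {
    stop("spatial dimensions of data do not match grid", call. = FALSE)
  }
  structure(
    list(data = data, tr_s = as.numeric(tr_s),
         subject_id = as.character(subject_id), grid = grid),
    class = "bold_run"
  )
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run %s: %d frames of %dx%dx%d, TR %.3g s>\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

#' A labeled 4D BOLD sample
#'
#' One decoding unit: the frames covering a task block plus the haemodynamic
#' tail, together with its condition label and provenance.
#'
#' @param data numeric 4D array `(t, x, y, z)`.
#' @param label condition/task label (non-empty string).
#' @param subject_id subject identifier.
#' @param tr_s repetition time in seconds.
#' @return An object of class `bold_sample`.
#' @export
bold_sample <- function(data, label, subject_id, tr_s) {
  stopifnot(is.array(data), length(dim(data)) == 4, nzchar(label))
  structure(
    list(data = data, label = as.character(label),
         subject_id = as.character(subject_id), tr_s = as.numeric(tr_s)),
    class = "bold_sample"
  )
}

#' @export
print.bold_sample <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_sample '%s' (%s): %d x %dx%dx%d>\n",
              x$label, x$subject_id, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Read a 4D BOLD run and its BIDS-style events table
#'
#' Reads a NIfTI-1 image (time series of 3D volumes) and, optionally, the
#' accompanying events TSV with columns `onset`, `duration` and `trial_type`
#' (onsets/durations in seconds). The repetition time is taken from the NIfTI
#' header time step; event labels are preserved verbatim.
#'
#' @param path path to a `.nii`/`.nii.gz` file with 4 dimensions.
#' @param events_path optional path to a BIDS events TSV.
#' @param subject_id subject identifier attached to the run.
#' @return A list with elements `run` (a [bold_run()]) and `events` (a tibble
#'   with columns `onset`, `duration`, `trial_type`, or `NULL`).
#' @export
read_bold_run <- function(path, events_path = NULL, subject_id = "sub-01") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) {
    stop(sprintf("expected a 4D NIfTI image, got %d dimensions", length(d)),
         call. = FALSE)
  }
  tr_s <- RNifti::pixdim(img)[4]
  if (!is.finite(tr_s) || tr_s <= 0) {
    stop("NIfTI header carries no positive time step (TR)", call. = FALSE)
  }
  vox <- RNifti::pixdim(img)[1:3]
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  # disk order is (x, y, z, t); move time to the front
  data <- aperm(as.array(img), c(4, 1, 2, 3))
  grid <- volume_grid(d[1:3], voxel_size_mm = vox, affine = affine)
  run <- bold_run(data, tr_s = tr_s, subject_id = subject_id, grid = grid)
  events <- if (!is.null(events_path)) read_events(events_path) else NULL
  list(run = run, events = events)
}

#' Write a BOLD run as NIfTI-1
#'
#' @param run a [bold_run()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_bold_run <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  arr <- aperm(run$data, c(2, 3, 4, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(run$grid$voxel_size_mm, run$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a BIDS-style events table
#'
#' @param path TSV file with columns `onset`, `duration`, `trial_type`.
#' @return Tibble with those columns (`onset`, `duration` numeric seconds).
#' @export
read_events <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("onset", "duration", "trial_type")
  missing <- setdiff(need, names(ev))
  if (length(missing) > 0) {
    stop(sprintf("events file lacks required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ev <- tibble::as_tibble(ev)[, need]
  stopifnot(all(ev$onset >= 0), all(ev$duration > 0), all(nzchar(ev$trial_type)))
  ev
}

#' Write a BIDS-style events table
#'
#' @param events tibble/data.frame with `onset`, `duration`, `trial_type`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  readr::write_tsv(events[, c("onset", "duration", "trial_type")], path,
                   progress = FALSE)
  invisible(path)
}

#' Default crop box for a grid
#'
#' Centred crop from the source grid to the target spatial shape: the margin
#' on each axis is split evenly, with the extra voxel (odd margins) going to
#' the trailing side. Ranges are 0-based and half-open, following the
#' package-wide coordinate convention.
#'
#' @param from integer vector of length 3, source shape.
#' @param to integer vector of length 3, target shape (defaults to the
#'   75 x 93 x 81 brain-tight crop of the 91 x 109 x 91 MNI 2 mm grid).
#' @return 3x2 integer matrix; row i is `[start, end)` on axis i.
#' @export
default_crop_box <- function(from = c(91, 109, 91), to = c(75, 93, 81)) {
  stopifnot(all(to <= from), all(to >= 1))
  off <- (from - to) %/% 2
  cbind(start = as.integer(off), end = as.integer(off + to))
}

#' Crop the spatial extent of a run
#'
#' Extracts an exact sub-array along the three spatial axes and translates
#' the grid affine so world coordinates of retained voxels are unchanged.
#' The box uses 0-based, half-open index ranges.
#'
#' @param run a [bold_run()].
#' @param crop_box 3x2 integer matrix of `[start, end)` ranges per axis, as
#'   returned by [default_crop_box()].
#' @return A cropped [bold_run()].
#' @export
crop_volume <- function(run, crop_box = default_crop_box(run$grid$shape)) {
  stopifnot(inherits(run, "bold_run"))
  box <- matrix(as.integer(crop_box), 3, 2)
  shp <- run$grid$shape
  if (any(box[, 1] < 0) || any(box[, 2] > shp) || any(box[, 2] <= box[, 1])) {
    stop("crop box out of bounds for the run's grid", call. = FALSE)
  }
  ix <- (box[1, 1] + 1):box[1, 2]
  iy <- (box[2, 1] + 1):box[2, 2]
  iz <- (box[3, 1] + 1):box[3, 2]
  data <- run$data[, ix, iy, iz, drop = FALSE]
  affine <- run$grid$affine
  shift <- affine %*% c(box[, 1], 1)
  affine[1:3, 4] <- shift[1:3]
  grid <- volume_grid(box[, 2] - box[, 1],
                      voxel_size_mm = run$grid$voxel_size_mm, affine = affine)
  bold_run(data, tr_s = run$tr_s, subject_id = run$subject_id, grid = grid)
}

#' Cut one labeled block sample out of a continuous run
#'
#' Selects the frames covering a task block and a post-block window catching
#' the tail of the haemodynamic response. Frame `t` (0-based) is included iff
#' its whole acquisition interval `[t*TR, (t+1)*TR)` lies inside
#' `[onset, onset + duration + post_window)`.
#'
#' @param run a [bold_run()].
#' @param onset_s block onset in seconds (>= 0).
#' @param duration_s block duration in seconds (> 0).
#' @param label condition label carried by the sample.
#' @param post_window_s seconds past the block end to include (default 8).
#' @param allow_truncate if the window extends past the end of the run,
#'   truncate instead of raising an error.
#' @return A [bold_sample()].
#' @export
extract_block_sample <- function(run, onset_s, duration_s, label,
                                 post_window_s = 8, allow_truncate = FALSE) {
  stopifnot(inherits(run, "bold_run"), onset_s >= 0, duration_s > 0)
  tr <- run$tr_s
  nt <- dim(run$data)[1]
  win_end <- onset_s + duration_s + post_window_s
  idx <- block_frame_indices(onset_s, win_end, tr)
  if (length(idx) == 0) {
    stop("block window contains no complete frame", call. = FALSE)
  }
  if (max(idx) >= nt) {
    if (!allow_truncate) {
      stop(sprintf(
        "block window [%.2f, %.2f) s extends past the end of the run (%d frames); set allow_truncate = TRUE to clip",
        onset_s, win_end, nt), call. = FALSE)
    }
    idx <- idx[idx < nt]
    if (length(idx) == 0) stop("block window lies entirely past the run", call. = FALSE)
  }
  data <- run$data[idx + 1L, , , , drop = FALSE]
  bold_sample(data, label = label, subject_id = run$subject_id, tr_s = tr)
}

# 0-based frames t with [t*TR, (t+1)*TR) inside [start, end).
# A small relative tolerance absorbs floating-point representation of
# onsets/durations that are exact multiples of TR.
block_frame_indices <- function(start_s, end_s, tr_s) {
  eps <- 1e-9 * max(1, abs(end_s))
  t0 <- ceiling(start_s / tr_s - eps)
  t1 <- floor(end_s / tr_s + eps) - 1
  if (t1 < t0) return(integer(0))
  seq.int(t0, t1)
}
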