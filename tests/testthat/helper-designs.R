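# Shared fixture builders and independent oracles for the test suite.

tiny_grid <- function(shape = c(10, 12, 10)) volume_grid(shape)

# A small, fast design: short blocks so samples are short and cheap.
tiny_design <- function(n_subjects = 5, labels = c("a", "b"),
                        duration_s = 4, amplitude = 3, noise_sd = 1,
                        grid = tiny_grid(), blocks_per_condition = 2,
                        radii = c(1.5, 1.5, 1.5), seed = 42, ...) {
  synthetic_design(
    conditions = condition_table(labels = labels, duration_s = duration_s,
                                 amplitude = amplitude, grid = grid,
                                 radii = radii),
    grid = grid, n_subjects = n_subjects,
    blocks_per_condition = blocks_per_condition,
    noise_sd = noise_sd, seed = seed, ...)
}

tiny_arch <- function(n_classes = 2, input_frames = 8) {
  arch_config(n_ch1 = 2, input_frames = input_frames, conv2_channels = 4,
              block_channels = c(3, 4, 4, 6), final_conv_channels = 5,
              fc_width = 4, n_classes = n_classes)
}

# Independent triple-loop 3D convolution oracle (double precision).
naive_conv3 <- function(x, w, stride) {
  d <- dim(x); k <- dim(w)[3]; cout <- dim(w)[1]; pad <- 1
  ox <- (d[2] + 2 * pad - k) %/% stride + 1
  oy <- (d[3] + 2 * pad - k) %/% stride + 1
  oz <- (d[4] + 2 * pad - k) %/% stride + 1
  out <- array(0, c(cout, ox, oy, oz, d[5]))
  for (n in seq_len(d[5])) for (z in seq_len(oz)) for (y in seq_len(oy)) {
    for (xq in seq_len(ox)) {
      acc <- numeric(cout)
      for (kz in 1:k) for (ky in 1:k) for (kx in 1:k) {
        ix <- (xq - 1) * stride - pad + kx
        iy <- (y - 1) * stride - pad + ky
        iz <- (z - 1) * stride - pad + kz
        if (ix >= 1 && ix <= d[2] && iy >= 1 && iy <= d[3] &&
            iz >= 1 && iz <= d[4]) {
          acc <- acc + matrix(w[, , kx, ky, kz], cout, d[1]) %*% x[, ix, iy, iz, n]
        }
      }
      out[, xq, y, z, n] <- acc
    }
  }
  out
}

# Direct discrete convolution oracle: response[t] = sum_s box[s] * kern[t-s+1].
naive_boxcar_hrf <- function(box, kern) {
  nt <- length(box)
  out <- numeric(nt)
  for (t in seq_len(nt)) {
    for (s in seq_len(t)) {
      ki <- t - s + 1
      if (ki <= length(kern)) out[t] <- out[t] + box[s] * kern[ki]
    }
  }
  out
}

# Linear index helper matching the package's (x, y, z) array layout.
voxel_linear <- function(coords, shape) {
  (coords[, 1] - 1) + shape[1] * ((coords[, 2] - 1) +
                                    shape[2] * (coords[, 3] - 1)) + 1
}
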