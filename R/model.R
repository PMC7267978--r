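#' Structural hyperparameters of the 3D residual decoder
#'
#' The network reads a `k x X x Y x Z` BOLD fragment with the time axis as
#' channels. A 1x1x1 convolution first compresses the `input_frames` temporal
#' channels to `n_ch1` temporal descriptors per voxel; a strided 3x3x3
#' convolution and four residual blocks (two 3x3x3 convolutions each, output
#' channels `block_channels`, stride 2 in the strided stages) extract spatial
#' features; a "full convolution" whose kernel equals the incoming feature
#' extent collapses space to 1x1x1; two fully connected layers
#' (`fc_width`, then `n_classes` with softmax) classify. Batch normalization
#' and ReLU follow every convolutional layer.
#'
#' The default width of the strided convolution (`conv2_channels = 63`) and
#' of the full convolution (`final_conv_channels = 123`) are the frozen
#' result of calibrating the two free widths against the published total of
#' 3,981,852 trainable parameters for 27-frame 75x93x81 input with a 7-class
#' head; see [calibrate_architecture()] and the methods vignette.
#'
#' @param n_ch1 channels of the 1x1x1 temporal layer (default 3).
#' @param input_frames temporal length `k` of the input fragment (default 27).
#' @param conv2_channels width of the strided 3x3x3 convolution.
#' @param block_channels output channels of the four residual blocks.
#' @param strided_stages logical flags: stride 2 in conv2 and in each block.
#' @param kernel_size spatial kernel of the 3D convolutions (3).
#' @param final_conv_channels output channels of the full convolution.
#' @param fc_width width of the first fully connected layer (64).
#' @param n_classes number of output classes (>= 2).
#' @param conv_bias logical: biases on conv2/block convolutions (default
#'   FALSE: batch normalization supplies the shift). The full convolution
#'   keeps a bias as the first stage of the classifier head.
#' @param use_projection_shortcuts use 1x1x1 projection shortcuts instead of
#'   the default parameter-free zero-padded identity shortcuts.
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(n_ch1 = 3L, input_frames = 27L,
                        conv2_channels = 63L,
                        block_channels = c(32L, 64L, 64L, 128L),
                        strided_stages = c(conv2 = TRUE, block1 = FALSE,
                                           block2 = TRUE, block3 = TRUE,
                                           block4 = TRUE),
                        kernel_size = 3L,
                        final_conv_channels = 123L,
                        fc_width = 64L, n_classes = 7L,
                        conv_bias = FALSE,
                        use_projection_shortcuts = FALSE) {
  stopifnot(n_ch1 >= 1, input_frames >= 1, length(block_channels) == 4,
            n_classes >= 2, kernel_size %% 2 == 1, length(strided_stages) == 5)
  structure(
    list(n_ch1 = as.integer(n_ch1), input_frames = as.integer(input_frames),
         conv2_channels = as.integer(conv2_channels),
         block_channels = as.integer(block_channels),
         strided_stages = as.logical(strided_stages),
         kernel_size = as.integer(kernel_size),
         final_conv_channels = as.integer(final_conv_channels),
         fc_width = as.integer(fc_width), n_classes = as.integer(n_classes),
         conv_bias = isTRUE(conv_bias),
         use_projection_shortcuts = isTRUE(use_projection_shortcuts)),
    class = "arch_config"
  )
}

# Spatial extents at every stage; errors if a stage empties the volume.
stage_dims <- function(cfg, shape) {
  k <- cfg$kernel_size
  pad <- (k - 1L) %/% 2L
  dims <- list()
  cur <- as.integer(shape)
  st <- function(nm, stride) {
    cur <<- vapply(cur, conv_out_extent, integer(1), k = k,
                   stride = if (stride) 2L else 1L, pad = pad)
    if (any(cur < 1L)) {
      stop(sprintf("input grid too small: stage '%s' leaves extent %s",
                   nm, paste(cur, collapse = "x")), call. = FALSE)
    }
    dims[[nm]] <<- cur
  }
  st("conv2", cfg$strided_stages[1])
  for (i in 1:4) st(paste0("block", i), cfg$strided_stages[i + 1])
  dims
}

#' Build the decoder network
#'
#' Instantiates all weights of the architecture for a given spatial grid.
#' Convolution weights use He-normal initialization; batch-norm scale/shift
#' start at 1/0; fully connected layers use He-normal weights and zero
#' biases.
#'
#' @param cfg an [arch_config()].
#' @param grid a [volume_grid()] (or integer shape of length 3) describing
#'   the spatial extent of the input samples.
#' @param labels optional character vector of class labels
#'   (length `n_classes`).
#' @param seed integer seed for weight initialization.
#' @return An object of class `fmri_cnn`.
#' @export
build_model <- function(cfg = arch_config(), grid, labels = NULL, seed = 1L) {
  if (inherits(grid, "volume_grid")) grid <- grid$shape
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3)
  if (!is.null(labels)) stopifnot(length(labels) == cfg$n_classes)
  dims <- stage_dims(cfg, grid)
  k <- cfg$kernel_size

  withr::local_seed(seed)
  he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
  conv_w <- function(cout, cin) {
    array(he(cin * k^3, cout * cin * k^3), c(cout, cin, k, k, k))
  }

  params <- list()
  params$l1.w <- matrix(he(cfg$input_frames, cfg$n_ch1 * cfg$input_frames),
                        cfg$n_ch1, cfg$input_frames)
  bn <- list(bn1 = bn_init(cfg$n_ch1))
  params$bn1.gamma <- bn$bn1$gamma; params$bn1.beta <- bn$bn1$beta

  params$conv2.w <- conv_w(cfg$conv2_channels, cfg$n_ch1)
  if (cfg$conv_bias) params$conv2.b <- rep(0, cfg$conv2_channels)
  bn$bn2 <- bn_init(cfg$conv2_channels)
  params$bn2.gamma <- bn$bn2$gamma; params$bn2.beta <- bn$bn2$beta

  cin <- cfg$conv2_channels
  for (i in 1:4) {
    cout <- cfg$block_channels[i]
    params[[sprintf("blk%d.convA.w", i)]] <- conv_w(cout, cin)
    params[[sprintf("blk%d.convB.w", i)]] <- conv_w(cout, cout)
    if (cfg$conv_bias) {
      params[[sprintf("blk%d.convA.b", i)]] <- rep(0, cout)
      params[[sprintf("blk%d.convB.b", i)]] <- rep(0, cout)
    }
    bn[[sprintf("blk%d.bnA", i)]] <- bn_init(cout)
    bn[[sprintf("blk%d.bnB", i)]] <- bn_init(cout)
    params[[sprintf("blk%d.bnA.gamma", i)]] <- rep(1, cout)
    params[[sprintf("blk%d.bnA.beta", i)]] <- rep(0, cout)
    params[[sprintf("blk%d.bnB.gamma", i)]] <- rep(1, cout)
    params[[sprintf("blk%d.bnB.beta", i)]] <- rep(0, cout)
    if (cfg$use_projection_shortcuts &&
        (cout != cin || cfg$strided_stages[i + 1])) {
      params[[sprintf("blk%d.proj.w", i)]] <-
        array(he(cin, cout * cin), c(cout, cin, 1, 1, 1))
    }
    cin <- cout
  }

  fdim <- dims$block4
  fin <- cin * prod(fdim)
  params$full.w <- matrix(he(fin, cfg$final_conv_channels * fin),
                          cfg$final_conv_channels, fin)
  params$full.b <- rep(0, cfg$final_conv_channels)
  bn$bnF <- bn_init(cfg$final_conv_channels)
  params$bnF.gamma <- bn$bnF$gamma; params$bnF.beta <- bn$bnF$beta

  params$fc1.w <- matrix(he(cfg$final_conv_channels,
                            cfg$fc_width * cfg$final_conv_channels),
                         cfg$fc_width, cfg$final_conv_channels)
  params$fc1.b <- rep(0, cfg$fc_width)
  params$fc2.w <- matrix(he(cfg$fc_width, cfg$n_classes * cfg$fc_width),
                         cfg$n_classes, cfg$fc_width)
  params$fc2.b <- rep(0, cfg$n_classes)

  structure(
    list(cfg = cfg, grid = grid, dims = dims, params = params, bn = bn,
         labels = labels %||% as.character(seq_len(cfg$n_classes))),
    class = "fmri_cnn"
  )
}

#' @export
print.fmri_cnn <- function(x, ...) {
  cat(sprintf(
    "<fmri_cnn: %d-frame %s input -> %d classes, %s trainable parameters>\n",
    x$cfg$input_frames, paste(x$grid, collapse = "x"), x$cfg$n_classes,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters by enumerating weight arrays
#'
#' Sums the lengths of every trainable array of the model: convolution and
#' fully connected weights, biases, and batch-norm scale/shift. Running
#' batch-norm statistics are buffers, not parameters, and are excluded.
#'
#' @param model an [build_model()] result.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "fmri_cnn"))
  sum(vapply(model$params, length, numeric(1)))
}

#' Count trainable parameters by closed-form arithmetic
#'
#' Independent per-layer formula: each convolution contributes
#' `cout * cin * k^3` weights (+ `cout` bias where present), each batch norm
#' `2 * channels`, the full convolution `cout * cin * prod(extent) + cout`,
#' and each fully connected layer `out * in + out`. Used as the oracle
#' against [count_parameters()].
#'
#' @param cfg an [arch_config()].
#' @param grid spatial input shape (length-3 integer or [volume_grid()]).
#' @return Integer parameter count.
#' @export
count_parameters_formula <- function(cfg = arch_config(), grid) {
  if (inherits(grid, "volume_grid")) grid <- grid$shape
  dims <- stage_dims(cfg, grid)
  k3 <- cfg$kernel_size^3
  bias <- function(n) if (cfg$conv_bias) n else 0
  total <- cfg$n_ch1 * cfg$input_frames + 2 * cfg$n_ch1          # l1 + bn1
  total <- total + cfg$conv2_channels * cfg$n_ch1 * k3 +
    bias(cfg$conv2_channels) + 2 * cfg$conv2_channels            # conv2 + bn2
  cin <- cfg$conv2_channels
  for (i in 1:4) {
    cout <- cfg$block_channels[i]
    total <- total + cout * cin * k3 + bias(cout) + 2 * cout     # convA + bnA
    total <- total + cout * cout * k3 + bias(cout) + 2 * cout    # convB + bnB
    if (cfg$use_projection_shortcuts &&
        (cout != cin || cfg$strided_stages[i + 1])) {
      total <- total + cout * cin
    }
    cin <- cout
  }
  fin <- cin * prod(dims$block4)
  total <- total + cfg$final_conv_channels * fin +
    cfg$final_conv_channels + 2 * cfg$final_conv_channels        # full + bnF
  total <- total + cfg$fc_width * cfg$final_conv_channels + cfg$fc_width
  total <- total + cfg$n_classes * cfg$fc_width + cfg$n_classes
  as.integer(total)
}

#' Resolve the free channel widths against a published parameter total
#'
#' The structural skeleton of the decoder is fixed (temporal 1x1x1 layer,
#' strided 3x3x3 convolution, four two-convolution residual blocks of
#' 32/64/64/128 channels with stride 2 in the stated stages, full-convolution
#' head, FC-64 and the class head, batch norm + ReLU after every
#' convolution), but two integer widths are not: the width of the strided
#' convolution and the channel count of the full convolution. This function
#' enumerates those two widths (optionally also bias and shortcut variants)
#' and returns the configurations whose closed-form parameter count equals
#' `target`. For the default skeleton on the 75x93x81 grid and
#' `target = 3981852` the solution is unique: conv2 = 63, final = 123.
#'
#' @param target published total parameter count to match.
#' @param grid spatial input shape the model is counted on.
#' @param input_frames,n_ch1,fc_width,n_classes fixed structural values.
#' @param conv2_range,final_range integer search ranges for the two widths.
#' @param conv_bias,use_projection_shortcuts candidate flags to scan.
#' @return Tibble of matching configurations (possibly empty), one row per
#'   hit, with columns `conv2_channels`, `final_conv_channels`, `conv_bias`,
#'   `use_projection_shortcuts` and `n_params`.
#' @export
calibrate_architecture <- function(target = 3981852,
                                   grid = c(75, 93, 81),
                                   input_frames = 27L, n_ch1 = 3L,
                                   fc_width = 64L, n_classes = 7L,
                                   conv2_range = 1:128,
                                   final_range = 1:512,
                                   conv_bias = c(FALSE, TRUE),
                                   use_projection_shortcuts = c(FALSE, TRUE)) {
  hits <- list()
  for (cb in conv_bias) {
    for (proj in use_projection_shortcuts) {
      for (c2 in conv2_range) {
        # closed-form in the two widths: total = A + B*c2 + C*f
        cfg0 <- arch_config(n_ch1 = n_ch1, input_frames = input_frames,
                            conv2_channels = c2, final_conv_channels = 1L,
                            fc_width = fc_width, n_classes = n_classes,
                            conv_bias = cb, use_projection_shortcuts = proj)
        base <- count_parameters_formula(cfg0, grid)
        cfg1 <- arch_config(n_ch1 = n_ch1, input_frames = input_frames,
                            conv2_channels = c2, final_conv_channels = 2L,
                            fc_width = fc_width, n_classes = n_classes,
                            conv_bias = cb, use_projection_shortcuts = proj)
        per_f <- count_parameters_formula(cfg1, grid) - base
        rem <- target - (base - per_f)   # base includes f = 1
        if (rem > 0 && rem %% per_f == 0) {
          f <- rem %/% per_f
          if (f >= min(final_range) && f <= max(final_range)) {
            hits[[length(hits) + 1]] <- tibble::tibble(
              conv2_channels = c2, final_conv_channels = f,
              conv_bias = cb, use_projection_shortcuts = proj,
              n_params = target)
          }
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(conv2_channels = integer(), final_conv_channels = integer(),
                          conv_bias = logical(), use_projection_shortcuts = logical(),
                          n_params = integer()))
  }
  dplyr::bind_rows(hits)
}

#' Per-layer description of a model
#'
#' @param model an `fmri_cnn`.
#' @return Tibble with one row per layer: name, output shape and trainable
#'   parameter count.
#' @export
describe_model <- function(model) {
  stopifnot(inherits(model, "fmri_cnn"))
  cfg <- model$cfg
  d <- model$dims
  shp <- function(ch, e) sprintf("%d x %s", ch, paste(e, collapse = "x"))
  np <- function(...) {
    nms <- c(...)
    sum(vapply(model$params[nms], length, numeric(1)), na.rm = TRUE)
  }
  rows <- list(
    tibble::tibble(layer = "temporal_conv_1x1x1",
                   output = shp(cfg$n_ch1, model$grid),
                   n_params = np("l1.w", "bn1.gamma", "bn1.beta")),
    tibble::tibble(layer = "conv2_3x3x3_s2",
                   output = shp(cfg$conv2_channels, d$conv2),
                   n_params = np("conv2.w", "bn2.gamma", "bn2.beta"))
  )
  for (i in 1:4) {
    nms <- sprintf("blk%d.%s", i,
                   c("convA.w", "convB.w", "bnA.gamma", "bnA.beta",
                     "bnB.gamma", "bnB.beta", "proj.w"))
    nms <- nms[nms %in% names(model$params)]
    rows[[length(rows) + 1]] <- tibble::tibble(
      layer = sprintf("resblock%d%s", i,
                      if (model$cfg$strided_stages[i + 1]) "_s2" else ""),
      output = shp(cfg$block_channels[i], d[[paste0("block", i)]]),
      n_params = np(nms))
  }
  rows[[length(rows) + 1]] <- tibble::tibble(
    layer = sprintf("full_conv_%s", paste(d$block4, collapse = "x")),
    output = shp(cfg$final_conv_channels, c(1, 1, 1)),
    n_params = np("full.w", "full.b", "bnF.gamma", "bnF.beta"))
  rows[[length(rows) + 1]] <- tibble::tibble(
    layer = "fc1", output = as.character(cfg$fc_width),
    n_params = np("fc1.w", "fc1.b"))
  rows[[length(rows) + 1]] <- tibble::tibble(
    layer = "fc2_softmax", output = as.character(cfg$n_classes),
    n_params = np("fc2.w", "fc2.b"))
  dplyr::bind_rows(rows)
}
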