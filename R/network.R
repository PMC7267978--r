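# Forward and backward passes of the decoder.
#
# A batch is an array dim c(frames, X, Y, Z, N): the time axis doubles as the
# channel axis of the 1x1x1 temporal layer. forward_pass() optionally keeps
# the caches needed by backward_pass(); backward_pass() serves three callers:
# training (parameter gradients, batch-statistics BN), guided backprop
# (input gradient, frozen BN, guided ReLU rule) and plain input gradients.

forward_pass <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$cfg
  p <- model$params
  stopifnot(length(dim(x)) == 5, dim(x)[1] == cfg$input_frames,
            all(dim(x)[2:4] == model$grid))
  cache <- if (keep_cache) list(x0 = x) else NULL
  keep <- function(nm, val) if (keep_cache) cache[[nm]] <<- val

  # temporal 1x1x1
  a <- dense_chan_fwd(x, p$l1.w)
  r <- bn_fwd(a, bn_with_params(model, "bn1"), training)
  model$bn$bn1 <- strip_bn(r$bn)
  keep("bn1", r$cache); keep("pre1", r$y)
  a <- relu_fwd(r$y)

  # strided conv
  keep("x_conv2", a)
  a <- conv3_fwd(a, p$conv2.w, stride = stride_of(cfg, 1))
  if (!is.null(p$conv2.b)) a <- a + p$conv2.b
  r <- bn_fwd(a, bn_with_params(model, "bn2"), training)
  model$bn$bn2 <- strip_bn(r$bn)
  keep("bn2", r$cache); keep("pre2", r$y)
  a <- relu_fwd(r$y)

  # residual blocks
  for (i in 1:4) {
    s <- stride_of(cfg, i + 1)
    keep(sprintf("x_blk%d", i), a)
    xin <- a
    h <- conv3_fwd(xin, p[[sprintf("blk%d.convA.w", i)]], stride = s)
    if (!is.null(p[[sprintf("blk%d.convA.b", i)]])) {
      h <- h + p[[sprintf("blk%d.convA.b", i)]]
    }
    r <- bn_fwd(h, bn_with_params(model, sprintf("blk%d.bnA", i)), training)
    model$bn[[sprintf("blk%d.bnA", i)]] <- strip_bn(r$bn)
    keep(sprintf("blk%d.bnA", i), r$cache)
    keep(sprintf("blk%d.preA", i), r$y)
    h <- relu_fwd(r$y)
    keep(sprintf("blk%d.xB", i), h)
    h <- conv3_fwd(h, p[[sprintf("blk%d.convB.w", i)]], stride = 1L)
    if (!is.null(p[[sprintf("blk%d.convB.b", i)]])) {
      h <- h + p[[sprintf("blk%d.convB.b", i)]]
    }
    r <- bn_fwd(h, bn_with_params(model, sprintf("blk%d.bnB", i)), training)
    model$bn[[sprintf("blk%d.bnB", i)]] <- strip_bn(r$bn)
    keep(sprintf("blk%d.bnB", i), r$cache)
    proj_nm <- sprintf("blk%d.proj.w", i)
    if (!is.null(p[[proj_nm]])) {
      d <- dim(xin)
      sc <- .conv3d_fwd(xin, as.integer(d), p[[proj_nm]], dim(p[[proj_nm]])[1],
                        NULL, 1L, as.integer(s), 0L)$out
    } else {
      sc <- shortcut_fwd(xin, cout = cfg$block_channels[i], stride = s)
    }
    pre <- r$y + sc
    keep(sprintf("blk%d.pre", i), pre)
    a <- relu_fwd(pre)
  }

  # full convolution head: dense over the flattened feature volume
  d <- dim(a)
  n <- d[5]
  keep("full_dims", d)
  af <- a; dim(af) <- c(prod(d[1:4]), n)
  keep("x_full", af)
  h <- dense_fwd(af, p$full.w, p$full.b)
  dim(h) <- c(nrow(p$full.w), 1, 1, 1, n)
  r <- bn_fwd(h, bn_with_params(model, "bnF"), training)
  model$bn$bnF <- strip_bn(r$bn)
  keep("bnF", r$cache); keep("preF", r$y)
  a <- relu_fwd(r$y)
  am <- a; dim(am) <- c(dim(a)[1], n)

  keep("x_fc1", am)
  h1 <- dense_fwd(am, p$fc1.w, p$fc1.b)
  keep("pre_fc1", h1)
  a1 <- relu_fwd(h1)
  keep("x_fc2", a1)
  logits <- dense_fwd(a1, p$fc2.w, p$fc2.b)
  keep("logits", logits)

  list(logits = logits, probs = softmax_cols(logits), model = model,
       cache = cache)
}

bn_with_params <- function(model, nm) {
  bn <- model$bn[[nm]]
  bn$gamma <- model$params[[paste0(nm, ".gamma")]]
  bn$beta <- model$params[[paste0(nm, ".beta")]]
  bn
}

strip_bn <- function(bn) {
  bn$gamma <- NULL; bn$beta <- NULL
  bn
}

stride_of <- function(cfg, stage) if (cfg$strided_stages[stage]) 2L else 1L

# dlogits: gradient at the logits (n_classes x N).
# Returns list(grads = named list or NULL, gx = input gradient or NULL).
backward_pass <- function(model, cache, dlogits, training = FALSE,
                          guided = FALSE, need_param_grads = TRUE,
                          need_input_grad = FALSE) {
  cfg <- model$cfg
  p <- model$params
  grads <- if (need_param_grads) list() else NULL
  g <- dlogits

  db <- dense_bwd(cache$x_fc2, p$fc2.w, g, has_bias = TRUE)
  if (need_param_grads) { grads$fc2.w <- db$gw; grads$fc2.b <- db$gb }
  g <- relu_bwd(db$gx, cache$pre_fc1, guided)

  db <- dense_bwd(cache$x_fc1, p$fc1.w, g, has_bias = TRUE)
  if (need_param_grads) { grads$fc1.w <- db$gw; grads$fc1.b <- db$gb }
  g <- db$gx

  n <- ncol(g)
  dim(g) <- c(nrow(g), 1, 1, 1, n)
  g <- relu_bwd(g, cache$preF, guided)
  bb <- bn_bwd(g, bn_with_params(model, "bnF"), cache$bnF, training)
  if (need_param_grads) { grads$bnF.gamma <- bb$dgamma; grads$bnF.beta <- bb$dbeta }
  g <- bb$gx
  dim(g) <- c(nrow(p$full.w), n)
  db <- dense_bwd(cache$x_full, p$full.w, g, has_bias = TRUE)
  if (need_param_grads) { grads$full.w <- db$gw; grads$full.b <- db$gb }
  g <- db$gx
  dim(g) <- cache$full_dims

  for (i in 4:1) {
    s <- stride_of(cfg, i + 1)
    xin <- cache[[sprintf("x_blk%d", i)]]
    g <- relu_bwd(g, cache[[sprintf("blk%d.pre", i)]], guided)
    # shortcut branch
    proj_nm <- sprintf("blk%d.proj.w", i)
    if (!is.null(p[[proj_nm]])) {
      pb <- .conv3d_bwd(xin, as.integer(dim(xin)), p[[proj_nm]],
                        dim(p[[proj_nm]])[1], g, FALSE, 1L, as.integer(s),
                        0L, TRUE)
      if (need_param_grads) grads[[proj_nm]] <- pb$gw
      gsc <- pb$gx
    } else {
      gsc <- shortcut_bwd(g, dim(xin), stride = s)
    }
    # main branch
    bb <- bn_bwd(g, bn_with_params(model, sprintf("blk%d.bnB", i)),
                 cache[[sprintf("blk%d.bnB", i)]], training)
    if (need_param_grads) {
      grads[[sprintf("blk%d.bnB.gamma", i)]] <- bb$dgamma
      grads[[sprintf("blk%d.bnB.beta", i)]] <- bb$dbeta
    }
    cb <- conv3_bwd(cache[[sprintf("blk%d.xB", i)]],
                    p[[sprintf("blk%d.convB.w", i)]], bb$gx, stride = 1L)
    if (need_param_grads) {
      grads[[sprintf("blk%d.convB.w", i)]] <- cb$gw
      if (!is.null(p[[sprintf("blk%d.convB.b", i)]])) {
        grads[[sprintf("blk%d.convB.b", i)]] <- rowSums(as_chan_mat(bb$gx))
      }
    }
    g <- relu_bwd(cb$gx, cache[[sprintf("blk%d.preA", i)]], guided)
    bb <- bn_bwd(g, bn_with_params(model, sprintf("blk%d.bnA", i)),
                 cache[[sprintf("blk%d.bnA", i)]], training)
    if (need_param_grads) {
      grads[[sprintf("blk%d.bnA.gamma", i)]] <- bb$dgamma
      grads[[sprintf("blk%d.bnA.beta", i)]] <- bb$dbeta
    }
    cb <- conv3_bwd(xin, p[[sprintf("blk%d.convA.w", i)]], bb$gx, stride = s)
    if (need_param_grads) {
      grads[[sprintf("blk%d.convA.w", i)]] <- cb$gw
      if (!is.null(p[[sprintf("blk%d.convA.b", i)]])) {
        grads[[sprintf("blk%d.convA.b", i)]] <- rowSums(as_chan_mat(bb$gx))
      }
    }
    g <- cb$gx + gsc
  }

  g <- relu_bwd(g, cache$pre2, guided)
  bb <- bn_bwd(g, bn_with_params(model, "bn2"), cache$bn2, training)
  if (need_param_grads) { grads$bn2.gamma <- bb$dgamma; grads$bn2.beta <- bb$dbeta }
  cb <- conv3_bwd(cache$x_conv2, p$conv2.w, bb$gx,
                  stride = stride_of(cfg, 1),
                  need_gx = TRUE)
  if (need_param_grads) {
    grads$conv2.w <- cb$gw
    if (!is.null(p$conv2.b)) grads$conv2.b <- rowSums(as_chan_mat(bb$gx))
  }
  g <- cb$gx

  g <- relu_bwd(g, cache$pre1, guided)
  bb <- bn_bwd(g, bn_with_params(model, "bn1"), cache$bn1, training)
  if (need_param_grads) { grads$bn1.gamma <- bb$dgamma; grads$bn1.beta <- bb$dbeta }
  g <- bb$gx
  db <- dense_chan_bwd(cache$x0, p$l1.w, g, need_gx = need_input_grad)
  if (need_param_grads) grads$l1.w <- db$gw

  list(grads = grads, gx = db$gx)
}

#' Class probabilities for BOLD samples
#'
#' Runs the network in inference mode (frozen batch-norm statistics) on one
#' or more samples. Samples longer than the model's `input_frames` are
#' reduced with [deterministic_first_crop()]; shorter samples are an error.
#'
#' @param object an `fmri_cnn`.
#' @param samples a [bold_sample()], a list of them, or a dataset tibble with
#'   a `sample` list-column as returned by [generate_dataset()].
#' @param ... unused.
#' @return Tibble with one row per sample: `subject_id`, `label` (truth,
#'   `NA` if unknown), `predicted`, and one `p_<class>` column per class.
#' @export
predict.fmri_cnn <- function(object, samples, ...) {
  samples <- as_sample_list(samples)
  k <- object$cfg$input_frames
  x <- batch_from_samples(lapply(samples, deterministic_first_crop, k = k))
  probs <- forward_pass(object, x, training = FALSE)$probs
  lab <- vapply(samples, function(s) s$label %||% NA_character_, character(1))
  pred <- object$labels[max.col(t(probs))]
  out <- tibble::tibble(
    subject_id = vapply(samples, function(s) s$subject_id, character(1)),
    label = lab, predicted = pred)
  pm <- t(probs)
  colnames(pm) <- paste0("p_", object$labels)
  dplyr::bind_cols(out, tibble::as_tibble(pm))
}

as_sample_list <- function(samples) {
  if (inherits(samples, "bold_sample")) return(list(samples))
  if (is.data.frame(samples)) return(samples$sample)
  samples
}

# Stack samples (already equal length) into a (t, X, Y, Z, N) batch.
batch_from_samples <- function(samples) {
  d <- dim(samples[[1]]$data)
  x <- array(0, c(d, length(samples)))
  for (i in seq_along(samples)) x[, , , , i] <- samples[[i]]$data
  x
}
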