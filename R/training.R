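#' Mean squared error over predicted intermediate rows
#'
#' `(1/N) * sum((pred - target)^2)` with N the total pixel count of the
#' target.
#'
#' @param pred,target Numeric arrays of identical shape.
#' @return Scalar loss.
#' @export
mse_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target)) ||
      length(pred) != length(target))
    stop("pred and target shapes differ")
  mean((pred - target)^2)
}

#' Training schedule
#'
#' @param lr_first_two Initial learning rate of layers 1-2 (default 0.01).
#' @param lr_last Initial learning rate of layer 3 (default 0.001); the
#'   last layer linearly assembles the output and is the most
#'   error-sensitive, hence the smaller rate.
#' @param minibatch Patches per backpropagation step (default 10).
#' @param validate_every Validate after this many 'iterations' (sweeps that
#'   draw one patch from every training sinogram; default 16).
#' @param patience Validations without a material improvement of the
#'   validation loss before both learning rates are divided by 10
#'   (default 3).
#' @param min_improvement Relative reduction of the best validation loss
#'   that counts as material progress for the plateau rule (default 0.01,
#'   i.e. 1 percent); the best-snapshot bookkeeping itself uses the raw
#'   minimum.
#' @param max_decays Stop after this many rate decays (default 3).
#' @param max_iterations Hard cap on training iterations.
#' @param val_patches_per_sino Fixed random validation patches drawn once
#'   per validation sinogram (default 10).
#' @param normalize Min-max normalize each input patch (and its target,
#'   with the same affine map) before the network (default TRUE).
#' @param seed Seed for patch sampling and initialization; the validation
#'   set uses a dedicated derived seed so it is frozen across the run.
#' @return Object of class `train_schedule`.
#' @export
train_schedule <- function(lr_first_two = 0.01, lr_last = 0.001,
                           minibatch = 10L, validate_every = 16L,
                           patience = 3L, min_improvement = 0.01,
                           max_decays = 3L, max_iterations = 320L,
                           val_patches_per_sino = 10L,
                           normalize = TRUE, seed = 1L) {
  stopifnot(lr_first_two > 0, lr_last > 0, minibatch >= 1,
            validate_every >= 1, patience >= 1, min_improvement >= 0,
            max_decays >= 0, max_iterations >= 1,
            val_patches_per_sino >= 1)
  structure(list(lr_first_two = lr_first_two, lr_last = lr_last,
                 minibatch = as.integer(minibatch),
                 validate_every = as.integer(validate_every),
                 patience = as.integer(patience),
                 min_improvement = min_improvement,
                 max_decays = as.integer(max_decays),
                 max_iterations = as.integer(max_iterations),
                 val_patches_per_sino = as.integer(val_patches_per_sino),
                 normalize = isTRUE(normalize), seed = as.integer(seed)),
            class = "train_schedule")
}

# prepare a patch for the network under the schedule's normalization policy
prep_patch <- function(patch, normalize) {
  if (!normalize)
    return(list(x = patch$input, target = patch$target,
                params = list(offset = 0, scale = 1, degenerate = FALSE)))
  nz <- normalize_patch(patch$input)
  list(x = nz$x,
       target = (patch$target - nz$params$offset) / nz$params$scale,
       params = nz$params)
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, step, lr12, lr3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    lr <- if (nm %in% c("w3", "b3")) lr3 else lr12
    g <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^step)
    vhat <- state[[nm]]$v / (1 - beta2^step)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# fixed validation patch set: one list entry per patch
make_val_set <- function(val_sinos, geom, schedule) {
  val_seed <- schedule$seed + 90001L
  with_seed(val_seed, {
    out <- list()
    for (s in seq_along(val_sinos)) {
      max_start <- nrow(val_sinos[[s]]) - geom$window
      starts <- sample.int(max_start, schedule$val_patches_per_sino,
                           replace = max_start < schedule$val_patches_per_sino)
      for (st in starts)
        out[[length(out) + 1L]] <- training_patch(val_sinos[[s]], st, geom)
    }
    out
  })
}

#' Validate network parameters on a fixed patch set
#'
#' @param params A [udnn_params][udnn_init()].
#' @param val_patches List of [training_patch()] pairs.
#' @param normalize Apply per-patch min-max normalization as in training.
#' @return List with `loss` (MSE in the network's working space) and
#'   `psnr` (dB, on denormalized predictions against the raw targets, peak
#'   = target data range).
#' @export
udnn_validate <- function(params, val_patches, normalize = TRUE) {
  pps <- lapply(val_patches, prep_patch, normalize = normalize)
  se <- 0; n <- 0
  preds <- vector("list", length(val_patches))
  targs <- lapply(val_patches, `[[`, "target")
  chunk <- 32L
  for (i0 in seq(1L, length(pps), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(pps))
    d <- dim(pps[[idx[1L]]]$x)
    xb <- array(0, c(d[1L], d[2L], length(idx)))
    for (j in seq_along(idx)) xb[, , j] <- pps[[idx[j]]]$x
    ob <- udnn_forward_batch(params, xb)
    for (j in seq_along(idx)) {
      out <- array(ob[, , , j], dim(ob)[1:3])
      pp <- pps[[idx[j]]]
      se <- se + sum((out - pp$target)^2)
      n <- n + length(out)
      preds[[idx[j]]] <- denormalize_patch(out, pp$params)
    }
  }
  pred_all <- unlist(preds); targ_all <- unlist(targs)
  peak <- diff(range(targ_all))
  if (peak <= 0) peak <- 1
  list(loss = se / n, psnr = psnr(pred_all, targ_all, peak = peak))
}

#' Train the upscaling network
#'
#' Optimizes the three-layer network with Adam (beta 0.9/0.999, epsilon
#' 1e-8) under two learning-rate groups: layers 1-2 at
#' `lr_first_two`, layer 3 (weights and biases alike) at `lr_last`.
#' Patches are scheduled in balanced random sweeps over the training
#' sinograms ([sample_iteration_plan()]) and consumed in minibatches;
#' after every `validate_every` iterations the fixed validation set is
#' scored, a parameter snapshot is recorded, and when the validation loss
#' has not improved for `patience` consecutive validations both rates are
#' divided by 10. Training stops after `max_iterations` iterations or
#' `max_decays` decays; the returned parameters are the best-validation
#' snapshot.
#'
#' @param train_sinos,val_sinos Lists of fully sampled sinogram matrices
#'   (T x W).
#' @param config A [udnn_config()].
#' @param geom A [patch_geometry()]; its `n_out` must match `config`.
#' @param schedule A [train_schedule()].
#' @param verbose Print one line per validation.
#' @return Object of class `udnn_fit`: list with `params` (best snapshot),
#'   `final_params`, `history` (data frame, one row per validation) and
#'   the `config`, `geom`, `schedule` used.
#' @export
udnn_train <- function(train_sinos, val_sinos, config = udnn_config(),
                       geom = patch_geometry(n_out = config$n_out),
                       schedule = train_schedule(), verbose = FALSE) {
  stopifnot(length(train_sinos) >= 1L, length(val_sinos) >= 1L)
  if (length(unique(vapply(train_sinos, ncol, 1L))) != 1L)
    stop("training sinograms must share one detector width")
  if (geom$n_out != config$n_out)
    stop("patch geometry n_out must match the network config")
  params <- udnn_init(config, seed = schedule$seed)
  state <- adam_state(params)
  val_set <- make_val_set(val_sinos, geom, schedule)
  plan <- sample_iteration_plan(vapply(train_sinos, nrow, 1L),
                                schedule$max_iterations, geom,
                                seed = schedule$seed + 17L)
  lr12 <- schedule$lr_first_two; lr3 <- schedule$lr_last
  best <- list(loss = Inf, params = params, val_index = 0L)
  plateau_ref <- Inf
  history <- NULL
  step <- 0L; decays <- 0L; since_best <- 0L
  blocks <- split(plan, (plan$iteration - 1L) %/% schedule$validate_every)
  for (bi in seq_along(blocks)) {
    block <- blocks[[bi]]
    batches <- split(seq_len(nrow(block)),
                     (seq_len(nrow(block)) - 1L) %/% schedule$minibatch)
    block_loss <- 0
    for (b in batches) {
      B <- length(b)
      Wd <- ncol(train_sinos[[block$sino[b[1L]]]])
      xb <- array(0, c(geom$n_input, Wd, B))
      tb <- array(0, c(geom$n_input - 1L, Wd, config$n_out, B))
      for (j in seq_len(B)) {
        row <- block[b[j], ]
        patch <- training_patch(train_sinos[[row$sino]], row$start, geom)
        pp <- prep_patch(patch, schedule$normalize)
        xb[, , j] <- pp$x
        tb[, , , j] <- pp$target
      }
      fw <- udnn_forward_batch(params, xb, keep_intermediates = TRUE)
      resid <- fw$out - tb
      npix <- length(resid)
      batch_loss <- sum(resid^2) / npix
      grads <- udnn_backward_batch(params, fw, 2 * resid / npix)
      if (!is.finite(batch_loss))
        stop("non-finite training loss at step ", step + 1L,
             "; aborting (diagnostic: lr12=", lr12, ", lr3=", lr3, ")")
      step <- step + 1L
      upd <- adam_step(params, grads, state, step, lr12, lr3)
      params <- upd$params; state <- upd$state
      block_loss <- block_loss + batch_loss
    }
    val <- udnn_validate(params, val_set, schedule$normalize)
    improved <- val$loss < best$loss
    material <- val$loss < plateau_ref * (1 - schedule$min_improvement)
    if (improved)
      best <- list(loss = val$loss, params = params, val_index = bi)
    if (material) {
      plateau_ref <- val$loss
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    history <- rbind(history, data.frame(
      validation = bi, iteration = max(block$iteration),
      minibatch_steps = step,
      train_loss = block_loss / length(batches),
      val_loss = val$loss, val_psnr = val$psnr,
      lr_first_two = lr12, lr_last = lr3, best = improved))
    if (verbose)
      message(sprintf(
        "validation %d (iter %d, step %d): train %.3g, val %.3g, psnr %.2f dB",
        bi, max(block$iteration), step, history$train_loss[bi],
        val$loss, val$psnr))
    if (since_best >= schedule$patience) {
      decays <- decays + 1L
      if (decays > schedule$max_decays) break
      lr12 <- lr12 / 10; lr3 <- lr3 / 10
      since_best <- 0L
    }
  }
  structure(list(params = best$params, final_params = params,
                 history = history, config = config, geom = geom,
                 schedule = schedule),
            class = "udnn_fit")
}

#' @export
print.udnn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "udnn_fit (%s, n_out %d): %d validations, best val loss %.4g (psnr %.2f dB)\n",
    x$config$variant, x$config$n_out, nrow(h),
    min(h$val_loss), h$val_psnr[which.min(h$val_loss)]))
  invisible(x)
}

#' Plot training history
#'
#' @param x A [udnn_fit][udnn_train()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.udnn_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$minibatch_steps, h$val_loss, type = "b", log = "y",
                 xlab = "minibatch steps", ylab = "loss", ...)
  graphics::lines(h$minibatch_steps, h$train_loss, type = "b", lty = 2,
                  col = "grey40")
  graphics::legend("topright", c("validation", "training (block mean)"),
                   lty = c(1, 2), col = c("black", "grey40"), bty = "n")
  invisible(x)
}
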