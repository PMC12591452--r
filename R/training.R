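#' Training configuration
#'
#' Full-scale reference settings are Adam with learning rate 2e-5, batch size
#' 8, up to 100 epochs with early-stopping patience 10, and a 1:1
#' paired:unpaired batch ratio for semi-supervised runs. Desk-scale harnesses
#' override `learning_rate`, `batch_size` and `max_steps` (see the methods
#' vignette).
#'
#' @param learning_rate Adam step size.
#' @param batch_size patches per optimizer step.
#' @param max_epochs epoch cap.
#' @param patience epochs without validation improvement before stopping.
#' @param max_steps optional cap on total optimizer steps (`Inf` = none).
#' @param val_fraction fraction of training patches held out (seeded) as the
#'   validation set for early stopping.
#' @param seed RNG seed for the validation split and batch shuffling.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-5, batch_size = 8L,
                         max_epochs = 100L, patience = 10L, max_steps = Inf,
                         val_fraction = 0.1, seed = 1L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (patience > max_epochs) stop("patience must be <= max_epochs")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), max_steps = max_steps,
                 val_fraction = val_fraction, seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "train_config")
}

#' Leave-one-subject-out fold plan
#'
#' Each subject serves exactly once as the test subject while all others
#' train the model; the fold order follows the input order, so plans are
#' deterministic.
#'
#' @param subject_ids character or integer vector of at least two distinct
#'   subject identifiers.
#' @return An object of class `fold_plan`: a list of folds, each with `test`
#'   (one id) and `train` (the rest).
#' @export
make_folds <- function(subject_ids) {
  subject_ids <- unique(subject_ids)
  if (length(subject_ids) < 2L) stop("need at least 2 subjects")
  folds <- lapply(seq_along(subject_ids), function(i)
    list(test = subject_ids[i], train = subject_ids[-i]))
  structure(folds, class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d leave-one-subject-out folds\n", length(x)))
  invisible(x)
}

# stack a list of 3D patches into a [d,d,d,1,N] batch
patches_to_batch <- function(patches) {
  if (is.array(patches) && length(dim(patches)) == 5L) return(patches)
  if (is.array(patches) && length(dim(patches)) == 3L) return(as_batch5(patches))
  d <- dim(patches[[1]])
  out <- array(0, dim = c(d, 1L, length(patches)))
  for (i in seq_along(patches)) out[, , , 1L, i] <- patches[[i]]
  out
}

.batch_n <- function(x) dim(x)[5]
.batch_take <- function(x, idx) x[, , , , idx, drop = FALSE]

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      cfg$learning_rate * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + cfg$eps)
  }
  list(params = params, state = state)
}

# one optimizer step; returns updated params/state and the realised losses
.train_step <- function(model, params, xb, yb, ub, w, ssim_cfg, opt_state, cfg) {
  tape <- ad_tape()
  pnodes <- lapply(params, function(p) ad_leaf(tape, p))
  yhat <- model_forward(model, ad_leaf(tape, xb), params = pnodes)
  sup <- hybrid_loss(ad_leaf(tape, yb), yhat, w, ssim_cfg)
  cons_val <- NA_real_
  if (!is.null(ub)) {
    un <- ad_leaf(tape, ub)
    fu <- model_forward(model, un, params = pnodes)
    cons <- consistency_loss(un, fu, w, ssim_cfg)
    cons_val <- ad_val(cons)
    loss <- total_loss(sup, cons, w)
  } else {
    loss <- sup
  }
  lv <- ad_val(loss)
  if (!is.finite(lv))
    stop(sprintf("non-finite loss at step %d (supervised=%g, consistency=%g)",
                 opt_state$t + 1L, ad_val(sup), cons_val))
  grads_by_id <- ad_backward(loss)
  grads <- lapply(pnodes, function(nd) grads_by_id[[nd$id]])
  up <- adam_step(params, grads, opt_state, cfg)
  list(params = up$params, state = up$state,
       loss = lv, supervised = ad_val(sup), consistency = cons_val)
}

.val_loss <- function(model, params, xv, yv, w, ssim_cfg, chunk = 16L) {
  n <- .batch_n(xv)
  tot <- 0
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(n, i0 + chunk - 1L)
    yhat <- model_forward(model, .batch_take(xv, idx), params = params)
    tot <- tot + length(idx) *
      ad_val(hybrid_loss(.batch_take(yv, idx), yhat, w, ssim_cfg))
  }
  tot / n
}

# epoch-wise shuffles for all epochs up-front, under a dedicated seed, so the
# paired stream is identical between supervised and semi-supervised runs
.epoch_perms <- function(n, epochs, seed) {
  with_seed(seed, lapply(seq_len(epochs), function(e) sample.int(n)))
}

.run_training <- function(model, x3t, y7t, unpaired, cfg, w, ssim_cfg, verbose) {
  x3t <- patches_to_batch(x3t); y7t <- patches_to_batch(y7t)
  if (!identical(dim(x3t), dim(y7t))) stop("paired batches differ in shape")
  n <- .batch_n(x3t)
  if (n < 2L) stop("need at least 2 paired patches")
  if (!is.null(unpaired)) unpaired <- patches_to_batch(unpaired)

  nval <- max(1L, round(cfg$val_fraction * n))
  if (nval >= n) stop("validation split leaves no training patches")
  val_idx <- with_seed(cfg$seed, sort(sample.int(n, nval)))
  tr_idx <- setdiff(seq_len(n), val_idx)
  xv <- .batch_take(x3t, val_idx); yv <- .batch_take(y7t, val_idx)
  xt <- .batch_take(x3t, tr_idx); yt <- .batch_take(y7t, tr_idx)
  ntr <- length(tr_idx)

  bs <- min(cfg$batch_size, ntr)
  steps_paired <- ntr %/% bs
  steps_epoch <- steps_paired
  if (!is.null(unpaired)) {
    nu <- .batch_n(unpaired)
    bu <- min(bs, nu)
    steps_epoch <- min(steps_paired, nu %/% bu)
    uperms <- .epoch_perms(nu, cfg$max_epochs, cfg$seed + 2L)
  }
  if (steps_epoch < 1L) stop("not enough patches for one batch")
  perms <- .epoch_perms(ntr, cfg$max_epochs, cfg$seed + 1L)

  params <- model$params
  opt <- adam_init(params)
  best <- list(val = Inf, params = params, epoch = 0L)
  wait <- 0L
  hist <- data.frame(epoch = 0L, steps = 0L, train_loss = NA_real_,
                     val_loss = .val_loss(model, params, xv, yv, w, ssim_cfg))
  if (verbose) message(sprintf("epoch 0: val %.6f", hist$val_loss[1]))
  best$val <- hist$val_loss[1]
  steps_total <- 0L

  for (ep in seq_len(cfg$max_epochs)) {
    perm <- perms[[ep]]
    if (!is.null(unpaired)) uperm <- uperms[[ep]]
    ep_losses <- numeric(0)
    for (s in seq_len(steps_epoch)) {
      bi <- perm[((s - 1L) * bs + 1L):(s * bs)]
      ub <- NULL
      if (!is.null(unpaired)) {
        ubi <- uperm[((s - 1L) * bu + 1L):(s * bu)]
        ub <- .batch_take(unpaired, ubi)
      }
      st <- .train_step(model, params, .batch_take(xt, bi), .batch_take(yt, bi),
                        ub, w, ssim_cfg, opt, cfg)
      params <- st$params; opt <- st$state
      ep_losses <- c(ep_losses, st$loss)
      steps_total <- steps_total + 1L
      if (steps_total >= cfg$max_steps) break
    }
    vl <- .val_loss(model, params, xv, yv, w, ssim_cfg)
    hist <- rbind(hist, data.frame(epoch = ep, steps = steps_total,
                                   train_loss = mean(ep_losses), val_loss = vl))
    if (verbose) message(sprintf("epoch %d: train %.6f val %.6f",
                                 ep, mean(ep_losses), vl))
    if (vl < best$val) {
      best <- list(val = vl, params = params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
    }
    if (wait >= cfg$patience || steps_total >= cfg$max_steps) break
  }
  model$params <- best$params
  list(model = model, history = hist, best_epoch = best$epoch,
       best_val = best$val, steps = steps_total,
       final_params = params)
}

#' Supervised patch training
#'
#' Minimizes the hybrid MSE+SSIM loss over paired (3T, 7T) patches with Adam.
#' A seeded fraction of the patches is held out as the validation set; early
#' stopping monitors its hybrid loss with the configured patience, and the
#' returned model carries the best-validation weights.
#'
#' @param model an `fr_unet` from [build_model()].
#' @param x3t,y7t paired input/target patches: lists of 3D arrays or
#'   `[d,d,d,1,N]` batches, normalized to `[0,1]`.
#' @param cfg a [train_config].
#' @param w a [loss_weights].
#' @param ssim_cfg an [ssim_config].
#' @param verbose print per-epoch losses.
#' @return List with `model` (best weights), `history` (per-epoch data frame;
#'   epoch 0 is the pre-training validation loss), `best_epoch`, `best_val`,
#'   `steps`, and `final_params` (last-step weights, used by equivalence
#'   tests).
#' @export
train_supervised <- function(model, x3t, y7t, cfg = train_config(),
                             w = loss_weights(), ssim_cfg = ssim_config(),
                             verbose = FALSE) {
  .run_training(model, x3t, y7t, NULL, cfg, w, ssim_cfg, verbose)
}

#' Semi-supervised patch training
#'
#' Each optimizer step draws one paired batch and one unpaired 7T batch (1:1
#' ratio), computes the hybrid loss on the paired batch and the consistency
#' loss on the unpaired batch, and updates the model with their
#' `lambda_semi`-weighted sum. Early stopping is evaluated on the supervised
#' validation loss only. Steps per epoch are limited by the smaller pool:
#' `min(floor(n_paired/batch), floor(n_unpaired/batch))`.
#'
#' With `lambda_semi = 0` the parameter trajectory is identical to
#' [train_supervised()] under the same seed: the unpaired forward pass uses no
#' RNG and the model holds no cross-sample state.
#'
#' @inheritParams train_supervised
#' @param unpaired7t unpaired 7T patches (list or batch), normalized per
#'   volume by the same min-max rule as the paired data.
#' @return As [train_supervised()].
#' @export
train_semisupervised <- function(model, x3t, y7t, unpaired7t,
                                 cfg = train_config(), w = loss_weights(),
                                 ssim_cfg = ssim_config(), verbose = FALSE) {
  if (is.null(unpaired7t)) stop("unpaired7t must be non-empty")
  .run_training(model, x3t, y7t, unpaired7t, cfg, w, ssim_cfg, verbose)
}

#' Synthesize a full volume
#'
#' Extracts overlapping patches from a normalized 3T volume, runs each through
#' the model, and reassembles the predictions with uniform-average blending.
#' The result is independent of patch iteration order.
#'
#' @param model a trained `fr_unet`.
#' @param v3t an [mri_volume] with values in `[0,1]`.
#' @param spec a [patch_spec] whose `patch_size` matches the model.
#' @param batch_size patches per forward pass.
#' @return An [mri_volume] of the same dimensions with values in (0, 1).
#' @export
synthesize_volume <- function(model, v3t, spec = patch_spec(), batch_size = 8L) {
  stopifnot(inherits(model, "fr_unet"), inherits(v3t, "mri_volume"))
  rng <- range(v3t$data)
  if (rng[1] < -1e-7 || rng[2] > 1 + 1e-7)
    stop("input volume must be normalized to [0,1]; see normalize_minmax()")
  ex <- extract_patches(v3t, spec)
  np <- length(ex$patches)
  preds <- vector("list", np)
  for (i0 in seq(1L, np, by = batch_size)) {
    idx <- i0:min(np, i0 + batch_size - 1L)
    xb <- patches_to_batch(ex$patches[idx])
    out <- model_forward(model, xb)
    for (j in seq_along(idx)) preds[[idx[j]]] <- array(out[, , , 1L, j],
                                                       dim = dim(out)[1:3])
  }
  mri_volume(reassemble(ex$starts, preds, dim(v3t$data)), v3t$spacing,
             meta = c(v3t$meta, list(synthesized = TRUE)))
}
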