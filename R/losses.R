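#' SSIM configuration
#'
#' Stabilizer constants follow the universal SSIM defaults `C1 = (k1 L)^2`,
#' `C2 = (k2 L)^2` with `k1 = 0.01`, `k2 = 0.03` and data range `L = 1` for
#' min-max normalized volumes. The window policy is either `"global"` (one
#' moment set over the whole patch; has a closed form on constant inputs) or
#' `"local"` (uniform cubic window, default edge 7, mean of the local SSIM
#' map; border windows are edge-truncated).
#'
#' @param k1,k2 stabilizer coefficients.
#' @param L data range of the inputs.
#' @param window `"local"` or `"global"`.
#' @param window_size odd edge length of the local window, in voxels.
#' @return An object of class `ssim_config`.
#' @export
ssim_config <- function(k1 = 0.01, k2 = 0.03, L = 1.0,
                        window = c("local", "global"), window_size = 7L) {
  window <- match.arg(window)
  window_size <- as.integer(window_size)
  if (window_size < 1L || window_size %% 2L == 0L)
    stop("window_size must be odd and >= 1")
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  if (C1 <= 0 || C2 <= 0) stop("stabilizers must be positive")
  structure(list(k1 = k1, k2 = k2, L = L, C1 = C1, C2 = C2,
                 window = window, window_size = window_size),
            class = "ssim_config")
}

#' Loss weights
#'
#' `lambda_hybrid` weights the SSIM term of the supervised hybrid loss
#' (default 0.7). `alpha` weights the SSIM term of the unpaired consistency
#' loss and `lambda_semi` weights the consistency loss in the semi-supervised
#' total; neither has a published reference value, so both are explicit,
#' always-logged configuration (defaults: `alpha = 0.7` mirroring the hybrid
#' weight, `lambda_semi = 1`).
#'
#' @param lambda_hybrid,alpha,lambda_semi non-negative weights.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_hybrid = 0.7, alpha = 0.7, lambda_semi = 1.0) {
  w <- list(lambda_hybrid = lambda_hybrid, alpha = alpha,
            lambda_semi = lambda_semi)
  if (any(unlist(w) < 0)) stop("loss weights must be >= 0")
  structure(w, class = "loss_weights")
}

# coerce a patch / batch to the canonical [d1,d2,d3,C,N] layout
as_batch5 <- function(x) {
  if (is_node(x)) return(x)
  d <- dim(x) %||% length(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 4L) dim(x) <- c(d, 1L)
  else if (length(d) != 5L) stop("expected a 3D patch or 4D/5D batch")
  x
}

.check_same_shape <- function(y, yhat) {
  dy <- dim(ad_val(y)); dh <- dim(ad_val(yhat))
  if (!identical(dy, dh))
    stop("shape mismatch: ", paste(dy, collapse = "x"), " vs ",
         paste(dh, collapse = "x"))
}

#' Mean squared error loss
#'
#' Mean of the squared voxelwise differences over all samples and voxels.
#' Accepts plain arrays or differentiation-tape nodes.
#'
#' @param y,yhat target and prediction, same shape.
#' @return Non-negative scalar; 0 iff the inputs are identical.
#' @export
mse_loss <- function(y, yhat) {
  .check_same_shape(y, yhat)
  d <- op_sub(y, yhat)
  op_mean(op_mul(d, d))
}

# per-sample SSIM for a [d1,d2,d3,C,N] batch pair; returns a length-N vector
# (or node). Population moments (divide by m) are used throughout.
ssim_per_sample <- function(y, yhat, cfg) {
  if (cfg$window == "global") {
    mu_y <- op_sample_mean(y)
    mu_h <- op_sample_mean(yhat)
    var_y <- op_sub(op_sample_mean(op_mul(y, y)), op_mul(mu_y, mu_y))
    var_h <- op_sub(op_sample_mean(op_mul(yhat, yhat)), op_mul(mu_h, mu_h))
    cov <- op_sub(op_sample_mean(op_mul(y, yhat)), op_mul(mu_y, mu_h))
    num <- op_mul(op_add(op_mul(op_mul(mu_y, mu_h), 2), cfg$C1),
                  op_add(op_mul(cov, 2), cfg$C2))
    den <- op_mul(op_add(op_add(op_mul(mu_y, mu_y), op_mul(mu_h, mu_h)), cfg$C1),
                  op_add(op_add(var_y, var_h), cfg$C2))
    op_div(num, den)
  } else {
    h <- (cfg$window_size - 1L) %/% 2L
    mu_y <- op_boxmean(y, h)
    mu_h <- op_boxmean(yhat, h)
    var_y <- op_sub(op_boxmean(op_mul(y, y), h), op_mul(mu_y, mu_y))
    var_h <- op_sub(op_boxmean(op_mul(yhat, yhat), h), op_mul(mu_h, mu_h))
    cov <- op_sub(op_boxmean(op_mul(y, yhat), h), op_mul(mu_y, mu_h))
    num <- op_mul(op_add(op_mul(op_mul(mu_y, mu_h), 2), cfg$C1),
                  op_add(op_mul(cov, 2), cfg$C2))
    den <- op_mul(op_add(op_add(op_mul(mu_y, mu_y), op_mul(mu_h, mu_h)), cfg$C1),
                  op_add(op_add(var_y, var_h), cfg$C2))
    op_sample_mean(op_div(num, den))
  }
}

#' Structural similarity index between two patches
#'
#' Luminance/contrast/structure comparison with stabilizers `C1`, `C2`. With
#' `window = "global"` a single moment set is used (closed forms exist, e.g.
#' two constant patches 0 and 1 give `C1 / (1 + C1)`); with `window = "local"`
#' the mean of the local SSIM map is returned.
#'
#' @param y,yhat patches of the same shape.
#' @param cfg an [ssim_config].
#' @return Scalar in `[-1, 1]`; 1 iff the patches are identical.
#' @export
ssim <- function(y, yhat, cfg = ssim_config()) {
  .check_same_shape(y, yhat)
  v <- ssim_per_sample(as_batch5(y), as_batch5(yhat), cfg)
  op_mean(v)
}

#' SSIM loss over a batch
#'
#' `1 - mean_i SSIM(y_i, yhat_i)` over the N samples of a batch.
#'
#' @param y,yhat batches of the same shape (`[d1,d2,d3,C,N]`, or a single
#'   patch).
#' @param cfg an [ssim_config].
#' @return Scalar in `[0, 2]`; 0 iff every pair is identical.
#' @export
ssim_loss <- function(y, yhat, cfg = ssim_config()) {
  .check_same_shape(y, yhat)
  op_sub(1, op_mean(ssim_per_sample(as_batch5(y), as_batch5(yhat), cfg)))
}

#' Hybrid supervised loss
#'
#' `MSE + lambda_hybrid * (1 - mean SSIM)`, the supervised objective for
#' paired 3T-to-7T patches.
#'
#' @param y,yhat target and predicted batches.
#' @param w a [loss_weights].
#' @param cfg an [ssim_config].
#' @return Non-negative scalar.
#' @export
hybrid_loss <- function(y, yhat, w = loss_weights(), cfg = ssim_config()) {
  m <- mse_loss(y, yhat)
  if (w$lambda_hybrid == 0) return(m)
  op_add(m, op_mul(ssim_loss(y, yhat, cfg), w$lambda_hybrid))
}

#' Unpaired consistency loss
#'
#' Pushes the model toward the identity map on real 7T inputs:
#' `mean_i [ mean|x_i - f(x_i)| + alpha * (1 - SSIM(x_i, f(x_i))) ]`. The L1
#' term is the voxelwise mean absolute difference, so the loss is
#' scale-comparable with the supervised hybrid loss.
#'
#' @param x7t batch of real unpaired 7T patches.
#' @param f_x7t model output on the same batch.
#' @param w a [loss_weights] (uses `alpha`).
#' @param cfg an [ssim_config].
#' @return Non-negative scalar; 0 iff the model acts as the identity.
#' @export
consistency_loss <- function(x7t, f_x7t, w = loss_weights(), cfg = ssim_config()) {
  .check_same_shape(x7t, f_x7t)
  x <- as_batch5(x7t); fx <- as_batch5(f_x7t)
  l1 <- op_mean(op_abs(op_sub(x, fx)))
  if (w$alpha == 0) return(l1)
  op_add(l1, op_mul(op_sub(1, op_mean(ssim_per_sample(x, fx, cfg))), w$alpha))
}

#' Semi-supervised total loss
#'
#' `supervised + lambda_semi * consistency`; `lambda_semi = 0` recovers pure
#' supervision.
#'
#' @param supervised supervised (hybrid) loss value.
#' @param consistency consistency loss value.
#' @param w a [loss_weights] (uses `lambda_semi`).
#' @return Scalar.
#' @export
total_loss <- function(supervised, consistency, w = loss_weights()) {
  sv <- ad_val(supervised); cv <- ad_val(consistency)
  if (!is.finite(sv) || !is.finite(cv)) stop("non-finite loss component")
  if (w$lambda_semi == 0) return(supervised)
  op_add(supervised, op_mul(consistency, w$lambda_semi))
}
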