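test_that("MSE loss matches direct summation and its fixed point", {
  y <- with_test_seed(1, array(stats::runif(4^3 * 2), c(4, 4, 4, 1, 2)))
  yh <- with_test_seed(2, array(stats::runif(4^3 * 2), c(4, 4, 4, 1, 2)))
  expect_equal(mse_loss(y, y), 0)
  expect_equal(mse_loss(array(1, c(4, 4, 4)), array(0.5, c(4, 4, 4))), 0.25)
  # direct-summation oracle
  expect_equal(mse_loss(y, yh), sum((y - yh)^2) / length(y), tolerance = 1e-7)
  expect_error(mse_loss(y, yh[, , , , 1, drop = FALSE]), "mismatch")
})

test_that("global-window SSIM matches the raw-moment closed form", {
  cfgg <- ssim_config(window = "global")
  a <- with_test_seed(3, array(stats::runif(6^3), c(6, 6, 6)))
  b <- with_test_seed(4, array(stats::runif(6^3), c(6, 6, 6)))
  expect_equal(ssim(a, a, cfgg), 1)
  # constant patches 0 and 1: variances and covariance vanish
  z <- array(0, c(4, 4, 4)); o <- array(1, c(4, 4, 4))
  expect_equal(ssim(z, o, cfgg), 1e-4 / 1.0001, tolerance = 1e-12)
  # independent oracle from raw moments
  expect_equal(ssim(a, b, cfgg), ssim_oracle_global(a, b), tolerance = 1e-7)
  # symmetry and joint-shift invariance (L held fixed)
  expect_equal(ssim(a, b, cfgg), ssim(b, a, cfgg), tolerance = 1e-12)
  expect_equal(ssim(a + 0.1, b + 0.1, cfgg),
               (function(y, x) {
                 cv <- mean((y - mean(y)) * (x - mean(x)))
                 vy <- mean((y - mean(y))^2); vx <- mean((x - mean(x))^2)
                 ((2 * mean(y) * mean(x) + 1e-4) * (2 * cv + 9e-4)) /
                   ((mean(y)^2 + mean(x)^2 + 1e-4) * (vy + vx + 9e-4))
               })(a + 0.1, b + 0.1), tolerance = 1e-10)
})

test_that("local-window SSIM is 1 at identity and matches a per-voxel oracle", {
  cfg <- ssim_config(window = "local", window_size = 3)
  a <- with_test_seed(5, array(stats::runif(5^3), c(5, 5, 5)))
  b <- with_test_seed(6, array(stats::runif(5^3), c(5, 5, 5)))
  expect_equal(ssim(a, a, cfg), 1, tolerance = 1e-12)
  # oracle: explicit edge-truncated local moments, then mean of the map
  h <- 1
  lm <- function(x, i, j, k) {
    ii <- max(1, i - h):min(5, i + h); jj <- max(1, j - h):min(5, j + h)
    kk <- max(1, k - h):min(5, k + h)
    x[ii, jj, kk]
  }
  smap <- array(0, c(5, 5, 5))
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    wa <- lm(a, i, j, k); wb <- lm(b, i, j, k)
    smap[i, j, k] <- ssim_oracle_global(wa, wb)
  }
  expect_equal(ssim(a, b, cfg), mean(smap), tolerance = 1e-7)
})

test_that("SSIM loss averages per-sample SSIM over the batch", {
  cfgg <- ssim_config(window = "global")
  a <- with_test_seed(7, array(stats::runif(4^3), c(4, 4, 4)))
  batch_y <- array(0, c(4, 4, 4, 1, 2))
  batch_h <- array(0, c(4, 4, 4, 1, 2))
  batch_y[, , , 1, 1] <- a;  batch_h[, , , 1, 1] <- a        # SSIM 1
  batch_y[, , , 1, 2] <- 0;  batch_h[, , , 1, 2] <- 1        # SSIM ~ 1e-4
  s2 <- 1e-4 / 1.0001
  expect_equal(ssim_loss(batch_y, batch_h, cfgg), 1 - (1 + s2) / 2,
               tolerance = 1e-9)
  expect_equal(ssim_loss(batch_y, batch_y, cfgg), 0, tolerance = 1e-12)
  # loop-over-samples oracle on random batches
  y <- with_test_seed(8, array(stats::runif(4^3 * 3), c(4, 4, 4, 1, 3)))
  yh <- with_test_seed(9, array(stats::runif(4^3 * 3), c(4, 4, 4, 1, 3)))
  per <- vapply(1:3, function(i)
    ssim_oracle_global(y[, , , 1, i], yh[, , , 1, i]), numeric(1))
  expect_equal(ssim_loss(y, yh, cfgg), 1 - mean(per), tolerance = 1e-7)
})

test_that("hybrid loss combines MSE and SSIM with the lambda weight", {
  cfgg <- ssim_config(window = "global")
  y <- with_test_seed(10, array(stats::runif(4^3 * 2), c(4, 4, 4, 1, 2)))
  yh <- with_test_seed(11, array(stats::runif(4^3 * 2), c(4, 4, 4, 1, 2)))
  expect_equal(hybrid_loss(y, y, loss_weights(), cfgg), 0, tolerance = 1e-12)
  expect_equal(hybrid_loss(y, yh, loss_weights(lambda_hybrid = 0), cfgg),
               mse_loss(y, yh))
  # constants 1 vs 0.5: hand evaluation of the closed form
  o <- array(1, c(4, 4, 4)); hlf <- array(0.5, c(4, 4, 4))
  s <- (2 * 1 * 0.5 + 1e-4) * 9e-4 / ((1 + 0.25 + 1e-4) * 9e-4)
  expect_equal(hybrid_loss(o, hlf, loss_weights(lambda_hybrid = 0.7), cfgg),
               0.25 + 0.7 * (1 - s), tolerance = 1e-10)
  # monotone in both components
  expect_gte(hybrid_loss(y, yh, loss_weights(0.7), cfgg),
             hybrid_loss(y, yh, loss_weights(0), cfgg))
})

test_that("consistency loss vanishes at the identity and splits into L1 + SSIM", {
  cfgg <- ssim_config(window = "global")
  x <- with_test_seed(12, array(stats::runif(4^3 * 2), c(4, 4, 4, 1, 2)))
  expect_equal(consistency_loss(x, x, loss_weights(), cfgg), 0, tolerance = 1e-12)
  o <- array(1, c(4, 4, 4)); f <- array(0.75, c(4, 4, 4))
  expect_equal(consistency_loss(o, f, loss_weights(alpha = 0), cfgg), 0.25)
  # independent L1 + SSIM computation on a random batch
  fx <- with_test_seed(13, array(stats::runif(4^3 * 2), c(4, 4, 4, 1, 2)))
  per <- vapply(1:2, function(i) ssim_oracle_global(x[, , , 1, i], fx[, , , 1, i]),
                numeric(1))
  expect_equal(consistency_loss(x, fx, loss_weights(alpha = 0.7), cfgg),
               mean(abs(x - fx)) + 0.7 * (1 - mean(per)), tolerance = 1e-7)
})

test_that("total loss is the weighted sum of its components", {
  expect_equal(total_loss(0.5, 0.2, loss_weights(lambda_semi = 1)), 0.7)
  expect_equal(total_loss(0.5, 0.2, loss_weights(lambda_semi = 0)), 0.5)
  grid <- expand.grid(a = c(0, 0.3, 1.7), b = c(0, 0.4, 2.1), l = c(0, 0.5, 2))
  for (i in seq_len(nrow(grid)))
    expect_identical(total_loss(grid$a[i], grid$b[i],
                                loss_weights(lambda_semi = grid$l[i])),
                     grid$a[i] + grid$l[i] * grid$b[i])
  expect_error(total_loss(NaN, 0.1, loss_weights()), "finite")
})
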