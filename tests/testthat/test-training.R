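test_that("leave-one-subject-out folds partition the subjects", {
  ids <- sprintf("sub-%02d", 1:10)
  plan <- make_folds(ids)
  expect_length(plan, 10)
  expect_true(all(vapply(plan, function(f) length(f$train), integer(1)) == 9))
  tests <- vapply(plan, function(f) f$test, character(1))
  expect_setequal(tests, ids)
  expect_false(any(vapply(plan, function(f) f$test %in% f$train, logical(1))))
  p2 <- make_folds(c("a", "b"))
  expect_length(p2, 2)
  expect_identical(p2[[1]]$train, "b")
  expect_error(make_folds("a"), "at least 2")
})

# small identity-task data: 7T == 3T, so the network must learn the identity
identity_patches <- function(n = 20, edge = 8, seed = 31) {
  with_test_seed(seed, lapply(seq_len(n), function(i)
    array(stats::runif(edge^3), c(edge, edge, edge))))
}

test_that("supervised training reduces loss on a learnable identity task", {
  p <- identity_patches(20, 8)
  m <- tiny_model(patch = 8, base = 2, levels = 2, seed = 13)
  cfg <- train_config(learning_rate = 1e-2, batch_size = 4, max_epochs = 6,
                      patience = 6, seed = 3)
  fit <- train_supervised(m, p, p, cfg, loss_weights(),
                          ssim_config(window = "global"))
  first_train <- fit$history$train_loss[2]
  last_train <- fit$history$train_loss[nrow(fit$history)]
  expect_lt(last_train, first_train)
  expect_lt(fit$best_val, fit$history$val_loss[1])
  # best weights really are the minimal recorded validation loss
  expect_equal(fit$best_val, min(fit$history$val_loss))
})

test_that("seeded runs reproduce the loss history exactly", {
  p <- identity_patches(12, 8)
  cfg <- train_config(learning_rate = 1e-2, batch_size = 4, max_epochs = 2,
                      patience = 2, seed = 5)
  f1 <- train_supervised(tiny_model(patch = 8, base = 2, levels = 2, seed = 1),
                         p, p, cfg, loss_weights(), ssim_config(window = "global"))
  f2 <- train_supervised(tiny_model(patch = 8, base = 2, levels = 2, seed = 1),
                         p, p, cfg, loss_weights(), ssim_config(window = "global"))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("early stopping halts after `patience` stagnant epochs", {
  p <- identity_patches(12, 8)
  # an oversized learning rate makes validation worsen, not improve
  cfg <- train_config(learning_rate = 5, batch_size = 4, max_epochs = 50,
                      patience = 2, seed = 7)
  fit <- train_supervised(tiny_model(patch = 8, base = 2, levels = 2, seed = 2),
                          p, p, cfg, loss_weights(), ssim_config(window = "global"))
  ep_last <- max(fit$history$epoch)
  expect_lt(ep_last, 50)  # early stopping engaged
  # the final `patience` epochs brought no improvement over the best epoch
  expect_lte(fit$best_epoch, ep_last - cfg$patience)
  expect_equal(fit$best_val, min(fit$history$val_loss))
})

test_that("semi-supervised with zero consistency weight matches supervised bitwise", {
  p <- identity_patches(12, 8, seed = 41)
  u <- identity_patches(8, 8, seed = 42)
  cfg <- train_config(learning_rate = 1e-2, batch_size = 4, max_epochs = 2,
                      patience = 2, seed = 9)
  w0 <- loss_weights(lambda_semi = 0)
  sup <- train_supervised(tiny_model(patch = 8, base = 2, levels = 2, seed = 3),
                          p, p, cfg, w0, ssim_config(window = "global"))
  semi <- train_semisupervised(tiny_model(patch = 8, base = 2, levels = 2, seed = 3),
                               p, p, u, cfg, w0, ssim_config(window = "global"))
  expect_identical(semi$final_params, sup$final_params)
  expect_identical(semi$model$params, sup$model$params)
})

test_that("semi-supervised step count follows the 1:1 ratio bookkeeping", {
  p <- identity_patches(13, 8, seed = 51)   # 13 paired
  u <- identity_patches(6, 8, seed = 52)    # 6 unpaired
  cfg <- train_config(learning_rate = 1e-3, batch_size = 3, max_epochs = 1,
                      patience = 1, val_fraction = 0.1, seed = 11)
  fit <- train_semisupervised(tiny_model(patch = 8, base = 2, levels = 2, seed = 4),
                              p, p, u, cfg, loss_weights(),
                              ssim_config(window = "global"))
  # 12 training paired (1 held out) -> 4 paired batches; 6 unpaired -> 2
  expect_equal(fit$steps, min(12 %/% 3, 6 %/% 3))
})

test_that("semi-supervised training reduces the consistency loss on held-out 7T", {
  ds <- tiny_dataset(n = 2, dims = c(32, 32, 32), seed = 19, n_unpaired = 2)
  spec <- patch_spec(16, 16)
  xp <- unlist(lapply(ds$paired, function(s) extract_patches(s$v3t, spec)$patches),
               recursive = FALSE)
  yp <- unlist(lapply(ds$paired, function(s) extract_patches(s$v7t, spec)$patches),
               recursive = FALSE)
  up <- extract_patches(ds$unpaired[[1]], spec)$patches
  hold <- fr$patches_to_batch(extract_patches(ds$unpaired[[2]], spec)$patches)
  m <- tiny_model(patch = 16, base = 2, levels = 2, seed = 6)
  w <- loss_weights()
  scfg <- ssim_config(window = "global")
  cons0 <- frunet::consistency_loss(hold, fr$model_forward(m, hold), w, scfg)
  cfg <- train_config(learning_rate = 3e-3, batch_size = 4, max_epochs = 4,
                      patience = 4, seed = 15)
  fit <- train_semisupervised(m, xp, yp, up, cfg, w, scfg)
  cons1 <- frunet::consistency_loss(hold, fr$model_forward(fit$model, hold), w, scfg)
  expect_lt(cons1, cons0)
})

test_that("synthesize_volume preserves dims and is patch-order free", {
  m <- tiny_model(patch = 16, base = 2, levels = 2, seed = 8)
  v <- rand_volume(c(24, 20, 16), seed = 23)
  syn <- synthesize_volume(m, v, patch_spec(16, 8))
  expect_identical(dim(syn$data), dim(v$data))
  expect_true(all(syn$data > 0 & syn$data < 1))
  # order-free: reassemble the same predictions in reverse order
  ex <- extract_patches(v, patch_spec(16, 8))
  preds <- lapply(ex$patches, function(p) forward(m, p))
  r1 <- reassemble(ex$starts, preds, dim(v$data))
  ord <- rev(seq_along(preds))
  r2 <- reassemble(ex$starts[ord, ], preds[ord], dim(v$data))
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_equal(syn$data, r1, tolerance = 1e-12)
  # unnormalized input is rejected
  bad <- mri_volume(v$data * 2 + 1)
  expect_error(synthesize_volume(m, bad, patch_spec(16, 8)), "normalized")
})

test_that("true pairings are learned better than shuffled pairings", {
  ds <- tiny_dataset(n = 2, dims = c(32, 32, 32), seed = 27, n_unpaired = 0)
  spec <- patch_spec(16, 16)
  xp <- unlist(lapply(ds$paired, function(s) extract_patches(s$v3t, spec)$patches),
               recursive = FALSE)
  yp <- unlist(lapply(ds$paired, function(s) extract_patches(s$v7t, spec)$patches),
               recursive = FALSE)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 4, max_epochs = 3,
                      patience = 3, seed = 17)
  w <- loss_weights(); scfg <- ssim_config(window = "global")
  fit_true <- train_supervised(tiny_model(patch = 16, base = 2, levels = 2, seed = 10),
                               xp, yp, cfg, w, scfg)
  yp_shuf <- with_test_seed(99, sample(yp))
  fit_shuf <- train_supervised(tiny_model(patch = 16, base = 2, levels = 2, seed = 10),
                               xp, yp_shuf, cfg, w, scfg)
  red_true <- 1 - fit_true$best_val / fit_true$history$val_loss[1]
  red_shuf <- 1 - fit_shuf$best_val / fit_shuf$history$val_loss[1]
  expect_gt(red_true, red_shuf)
})
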