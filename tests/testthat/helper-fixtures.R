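# shared tiny fixtures; everything is generated in code under fixed seeds

fr <- asNamespace("frunet")

# a small non-constant random volume
rand_volume <- function(dims = c(8, 8, 8), seed = 1, spacing = c(1, 1, 1)) {
  v <- with_test_seed(seed, array(stats::runif(prod(dims)), dim = dims))
  mri_volume(v, spacing)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# tiny network sharing the full topology
tiny_model <- function(patch = 16L, base = 2L, levels = 3L, seed = 7L) {
  build_model(model_config(base_channels = base, levels = levels,
                           patch_size = patch, seed = seed))
}

# small paired phantom set at reduced dims (fast path for training tests)
tiny_dataset <- function(n = 2, dims = c(48, 48, 48), seed = 11, n_unpaired = 1) {
  make_paired_dataset(n, phantom_config(dims = dims, seed = seed), n_unpaired)
}

# independent SSIM oracle from raw moments (global window, population stats)
ssim_oracle_global <- function(y, x, C1 = 1e-4, C2 = 9e-4) {
  my <- mean(y); mx <- mean(x)
  vy <- mean((y - my)^2); vx <- mean((x - mx)^2)
  cv <- mean((y - my) * (x - mx))
  ((2 * my * mx + C1) * (2 * cv + C2)) /
    ((my^2 + mx^2 + C1) * (vy + vx + C2))
}
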