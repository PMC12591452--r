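#' FR-U-Net architecture configuration
#'
#' A four-level (by default) encoder-decoder with symmetric skip connections.
#' Channel widths double per level (32/64/128/256 at full scale); the patch
#' edge must be divisible by `2^(levels - 1)` so pooling reaches the
#' bottleneck. Tests and desk-scale runs use the identical topology at reduced
#' width and patch size (e.g. width 4, patch 16 or 32).
#'
#' @param base_channels width of encoder level 1.
#' @param levels number of hierarchical levels including the bottleneck.
#' @param convs_per_level convolutions per encoder level.
#' @param msf_kernels odd cubic kernel edges of the multi-scale fusion
#'   branches.
#' @param patch_size input patch edge length in voxels.
#' @param use_residual,use_msf ablation toggles for the decoder residual and
#'   multi-scale fusion blocks.
#' @param seed RNG seed for parameter initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(base_channels = 32L, levels = 4L, convs_per_level = 2L,
                         msf_kernels = c(1L, 3L, 5L), patch_size = 64L,
                         use_residual = TRUE, use_msf = TRUE, seed = 1L) {
  levels <- as.integer(levels); patch_size <- as.integer(patch_size)
  if (levels < 2L) stop("need at least 2 levels")
  if (patch_size %% 2L^(levels - 1L) != 0L)
    stop("patch_size must be divisible by 2^(levels-1) = ", 2L^(levels - 1L))
  if (any(msf_kernels %% 2L == 0L)) stop("msf_kernels must be odd")
  structure(list(base_channels = as.integer(base_channels), levels = levels,
                 convs_per_level = as.integer(convs_per_level),
                 msf_kernels = as.integer(msf_kernels),
                 patch_size = patch_size,
                 level_channels = as.integer(base_channels) * 2L^(seq_len(levels) - 1L),
                 use_residual = isTRUE(use_residual), use_msf = isTRUE(use_msf),
                 seed = as.integer(seed)),
            class = "model_config")
}

# fan-in-scaled normal init for a conv weight matrix (k^3*cin) x cout
.init_conv <- function(k, cin, cout) {
  fan_in <- k^3 * cin
  matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
}

#' Build a 3D multi-scale fusion residual U-Net
#'
#' Encoder: per level, `convs_per_level` 3x3x3 convolutions each followed by
#' PReLU and layer normalization, with 2x2x2 max pooling between levels.
#' Decoder: per stage, a stride-2 transposed convolution, concatenation with
#' the matching encoder level, a residual block (two 3x3x3 convolutions with
#' PReLU and a 1x1x1-projected skip addition), and a multi-scale fusion block
#' (parallel 1/3/5 cubic convolutions, channel concatenation, 1x1x1
#' reduction, PReLU). Head: 1x1x1 convolution + sigmoid to one channel, so
#' outputs lie strictly in (0, 1).
#'
#' Initialization is fan-in-scaled Gaussian under `cfg$seed`; PReLU slopes
#' start at 0.25. Two builds with the same seed are identical.
#'
#' @param cfg a [model_config].
#' @return An object of class `fr_unet` with elements `cfg` and `params`
#'   (named list of numeric arrays).
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  ch <- cfg$level_channels
  L <- cfg$levels
  params <- list()
  with_seed(cfg$seed, {
    # encoder (level L is the bottleneck; no pooling after it)
    for (l in seq_len(L)) {
      cin <- if (l == 1L) 1L else ch[l - 1L]
      for (j in seq_len(cfg$convs_per_level)) {
        cj <- if (j == 1L) cin else ch[l]
        params[[sprintf("enc%d_conv%d_w", l, j)]] <- .init_conv(3L, cj, ch[l])
        params[[sprintf("enc%d_conv%d_b", l, j)]] <- numeric(ch[l])
        params[[sprintf("enc%d_prelu%d", l, j)]] <- rep(0.25, ch[l])
        params[[sprintf("enc%d_ln%d_g", l, j)]] <- rep(1, ch[l])
        params[[sprintf("enc%d_ln%d_b", l, j)]] <- numeric(ch[l])
      }
    }
    # decoder stages s = L-1 .. 1
    for (s in rev(seq_len(L - 1L))) {
      cin <- if (s == L - 1L) ch[L] else ch[s + 1L]
      params[[sprintf("dec%d_up_w", s)]] <-
        matrix(stats::rnorm(8L * ch[s] * cin, sd = sqrt(2 / cin)), 8L * ch[s], cin)
      params[[sprintf("dec%d_up_b", s)]] <- numeric(ch[s])
      cc <- 2L * ch[s]  # after concat with the encoder skip
      if (cfg$use_residual) {
        params[[sprintf("dec%d_res_conv1_w", s)]] <- .init_conv(3L, cc, ch[s])
        params[[sprintf("dec%d_res_conv1_b", s)]] <- numeric(ch[s])
        params[[sprintf("dec%d_res_prelu1", s)]] <- rep(0.25, ch[s])
        params[[sprintf("dec%d_res_conv2_w", s)]] <- .init_conv(3L, ch[s], ch[s])
        params[[sprintf("dec%d_res_conv2_b", s)]] <- numeric(ch[s])
        params[[sprintf("dec%d_res_proj_w", s)]] <- .init_conv(1L, cc, ch[s])
        params[[sprintf("dec%d_res_proj_b", s)]] <- numeric(ch[s])
        params[[sprintf("dec%d_res_prelu2", s)]] <- rep(0.25, ch[s])
        cc <- ch[s]
      }
      if (cfg$use_msf) {
        for (k in cfg$msf_kernels) {
          params[[sprintf("dec%d_msf_k%d_w", s, k)]] <- .init_conv(k, cc, ch[s])
          params[[sprintf("dec%d_msf_k%d_b", s, k)]] <- numeric(ch[s])
        }
        params[[sprintf("dec%d_msf_red_w", s)]] <-
          .init_conv(1L, length(cfg$msf_kernels) * ch[s], ch[s])
        params[[sprintf("dec%d_msf_red_b", s)]] <- numeric(ch[s])
        params[[sprintf("dec%d_msf_prelu", s)]] <- rep(0.25, ch[s])
        cc <- ch[s]
      }
      params[[sprintf("dec%d_out_ch", s)]] <- cc  # bookkeeping, not a tensor
    }
    head_in <- params[[sprintf("dec%d_out_ch", 1L)]]
    params[["head_w"]] <- .init_conv(1L, head_in, 1L)
    params[["head_b"]] <- numeric(1L)
  })
  params <- params[!grepl("_out_ch$", names(params))]
  structure(list(cfg = cfg, params = params), class = "fr_unet")
}

#' @export
print.fr_unet <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<fr_unet> %d levels, widths %s, patch %d^3, %s parameters\n",
              x$cfg$levels, paste(x$cfg$level_channels, collapse = "/"),
              x$cfg$patch_size, format(np, big.mark = ",")))
  invisible(x)
}

# Forward pass through the network. `params` is a named list of arrays or of
# tape nodes (for training); `x` is a [d1,d2,d3,1,N] batch (arrays accepted in
# 3D/4D form). Returns the sigmoid output, same spatial shape, 1 channel.
model_forward <- function(model, x, params = model$params) {
  cfg <- model$cfg
  if (!is_node(x)) x <- as_batch5(x)
  d <- dim(ad_val(x))
  if (!all(d[1:3] %% 2L^(cfg$levels - 1L) == 0L))
    stop("input spatial dims ", paste(d[1:3], collapse = "x"),
         " not divisible by ", 2L^(cfg$levels - 1L))
  p <- params
  L <- cfg$levels
  skips <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    for (j in seq_len(cfg$convs_per_level)) {
      h <- op_conv3d(h, p[[sprintf("enc%d_conv%d_w", l, j)]],
                     p[[sprintf("enc%d_conv%d_b", l, j)]], 3L)
      h <- op_prelu(h, p[[sprintf("enc%d_prelu%d", l, j)]])
      h <- op_layernorm(h, p[[sprintf("enc%d_ln%d_g", l, j)]],
                        p[[sprintf("enc%d_ln%d_b", l, j)]])
    }
    skips[[l]] <- h
    if (l < L) h <- op_maxpool2(h)
  }
  for (s in rev(seq_len(L - 1L))) {
    h <- op_convt2(h, p[[sprintf("dec%d_up_w", s)]], p[[sprintf("dec%d_up_b", s)]])
    h <- op_concat_ch(h, skips[[s]])
    if (cfg$use_residual) {
      r <- op_conv3d(h, p[[sprintf("dec%d_res_conv1_w", s)]],
                     p[[sprintf("dec%d_res_conv1_b", s)]], 3L)
      r <- op_prelu(r, p[[sprintf("dec%d_res_prelu1", s)]])
      r <- op_conv3d(r, p[[sprintf("dec%d_res_conv2_w", s)]],
                     p[[sprintf("dec%d_res_conv2_b", s)]], 3L)
      pr <- op_conv3d(h, p[[sprintf("dec%d_res_proj_w", s)]],
                      p[[sprintf("dec%d_res_proj_b", s)]], 1L)
      h <- op_prelu(op_add(r, pr), p[[sprintf("dec%d_res_prelu2", s)]])
    }
    if (cfg$use_msf) {
      branches <- lapply(cfg$msf_kernels, function(k)
        op_conv3d(h, p[[sprintf("dec%d_msf_k%d_w", s, k)]],
                  p[[sprintf("dec%d_msf_k%d_b", s, k)]], as.integer(k)))
      m <- branches[[1]]
      for (i in seq_along(branches)[-1]) m <- op_concat_ch(m, branches[[i]])
      m <- op_conv3d(m, p[[sprintf("dec%d_msf_red_w", s)]],
                     p[[sprintf("dec%d_msf_red_b", s)]], 1L)
      h <- op_prelu(m, p[[sprintf("dec%d_msf_prelu", s)]])
    }
  }
  h <- op_conv3d(h, p[["head_w"]], p[["head_b"]], 1L)
  op_sigmoid(h)
}

#' Run the network on a batch of patches
#'
#' @param model an [build_model()] result.
#' @param patch a single normalized patch (3D array, values in `[0,1]`) or a
#'   `[d,d,d,1,N]` batch; spatial edges must equal `cfg$patch_size`.
#' @return Array of the same shape with values strictly in (0, 1).
#' @export
forward <- function(model, patch) {
  stopifnot(inherits(model, "fr_unet"))
  x <- as_batch5(patch)
  d <- dim(x)
  if (!all(d[1:3] == model$cfg$patch_size))
    stop("patch edge ", paste(d[1:3], collapse = "x"),
         " does not match configured patch_size ", model$cfg$patch_size)
  out <- model_forward(model, x)
  if (length(dim(patch) %||% 0) == 3L) dim(out) <- d[1:3]
  out
}

#' Save / load a model checkpoint
#'
#' Parameters are serialized with R's native format; the architecture
#' configuration is written alongside as a JSON sidecar for inspection.
#'
#' @param model an `fr_unet`.
#' @param path checkpoint path (the sidecar gets `.json` appended).
#' @return `path` (for `save_checkpoint`); the restored `fr_unet` (for
#'   `load_checkpoint`).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fr_unet"))
  saveRDS(model, path)
  cfg <- model$cfg
  jsonlite::write_json(unclass(cfg), paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  m <- readRDS(path)
  stopifnot(inherits(m, "fr_unet"))
  m
}
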