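#' Peak signal-to-noise ratio
#'
#' `10 log10(M^2 / MSE)` in decibels. By default `M` is the maximum value
#' over both images; `data_range` fixes `M` (e.g. 1.0) for comparability with
#' toolkits that use the nominal range.
#'
#' @param y ground-truth image (any-dimensional numeric array).
#' @param g reconstructed image, same shape.
#' @param data_range optional fixed maximum `M`.
#' @return PSNR in dB. Identical images have no finite PSNR and raise a
#'   condition of class `frunet_identical_images`.
#' @export
psnr <- function(y, g, data_range = NULL) {
  if (!identical(dim(y), dim(g))) stop("shape mismatch")
  mse <- mean((y - g)^2)
  if (mse == 0)
    stop(structure(list(message = "identical images: PSNR is infinite",
                        call = sys.call()),
                   class = c("frunet_identical_images", "error", "condition")))
  M <- if (is.null(data_range)) max(y, g) else data_range
  10 * log10(M^2 / mse)
}

#' Normalized mean squared error
#'
#' Squared error between reconstruction and ground truth normalized by the
#' ground-truth energy: `sum((f - y)^2) / sum(y^2)`. Scale-invariant under
#' joint scaling of both inputs.
#'
#' @param y ground truth (must not be identically zero).
#' @param f reconstruction, same shape.
#' @return Non-negative ratio; 0 iff `f == y`.
#' @export
nmse <- function(y, f) {
  if (!identical(dim(y), dim(f))) stop("shape mismatch")
  e <- sum(y^2)
  if (e == 0) stop("ground truth is identically zero: NMSE undefined")
  sum((f - y)^2) / e
}

# metric on one 2D slice; returns NA when undefined for that slice
.slice_metric <- function(ys, gs, metric, ssim_cfg) {
  switch(metric,
    psnr = tryCatch(psnr(ys, gs),
                    frunet_identical_images = function(e) NA_real_),
    nmse = if (sum(ys^2) == 0) NA_real_ else nmse(ys, gs),
    ssim = {
      d <- dim(ys)
      ssim(array(ys, dim = c(d, 1L)), array(gs, dim = c(d, 1L)), ssim_cfg)
    })
}

#' Per-orientation slice-wise metric report
#'
#' Computes an image-quality metric on every 2D slice of a volume pair,
#' separately for the three anatomical orientations: slices along axis 1 are
#' sagittal, axis 2 coronal, axis 3 transverse. Slices where the metric is
#' undefined (identical slices for PSNR, all-zero ground truth for NMSE) are
#' excluded from the aggregates and counted.
#'
#' @param y,g ground-truth and reconstructed volumes ([mri_volume] or 3D
#'   arrays of equal dimensions).
#' @param metric one of `"psnr"`, `"ssim"`, `"nmse"`.
#' @param ssim_cfg SSIM settings for `metric = "ssim"`; the default local
#'   window gives a 7x7 uniform 2D window per slice.
#' @return A list of three `slice_metric_report` objects (sagittal, coronal,
#'   transverse), each with per-slice `values`, `mean`, `sd`, `n_slices`,
#'   `n_excluded`.
#' @export
per_orientation_report <- function(y, g, metric = c("psnr", "ssim", "nmse"),
                                   ssim_cfg = ssim_config()) {
  metric <- match.arg(metric)
  ya <- if (inherits(y, "mri_volume")) y$data else y
  ga <- if (inherits(g, "mri_volume")) g$data else g
  if (!identical(dim(ya), dim(ga))) stop("volume dimensions differ")
  orientations <- c("sagittal", "coronal", "transverse")
  out <- lapply(1:3, function(ax) {
    nsl <- dim(ya)[ax]
    vals <- vapply(seq_len(nsl), function(i) {
      ys <- switch(ax, ya[i, , ], ya[, i, ], ya[, , i])
      gs <- switch(ax, ga[i, , ], ga[, i, ], ga[, , i])
      .slice_metric(ys, gs, metric, ssim_cfg)
    }, numeric(1))
    ok <- vals[!is.na(vals)]
    structure(list(orientation = orientations[ax], metric = metric,
                   values = vals, mean = mean(ok), sd = stats::sd(ok),
                   n_slices = length(ok), n_excluded = sum(is.na(vals))),
              class = "slice_metric_report")
  })
  names(out) <- orientations
  out
}

#' @export
print.slice_metric_report <- function(x, ...) {
  cat(sprintf("<slice_metric_report> %s %s: %.4f +/- %.4f (%d slices, %d excluded)\n",
              x$orientation, x$metric, x$mean, x$sd, x$n_slices, x$n_excluded))
  invisible(x)
}

#' Write slice-metric reports
#'
#' Per-slice values go to CSV (`orientation, metric, slice, value`);
#' aggregates to JSON (`orientation, metric, mean, sd, n_slices, n_excluded`).
#'
#' @param reports result of [per_orientation_report()] (or a list of such
#'   lists for several metrics).
#' @param csv,json output paths; `NULL` skips that writer.
#' @return Invisibly, the aggregate data frame.
#' @export
write_metric_report <- function(reports, csv = NULL, json = NULL) {
  if (inherits(reports[[1]], "slice_metric_report")) reports <- list(reports)
  flat <- unlist(reports, recursive = FALSE)
  per_slice <- do.call(rbind, lapply(flat, function(r)
    data.frame(orientation = r$orientation, metric = r$metric,
               slice = seq_along(r$values), value = r$values)))
  agg <- do.call(rbind, lapply(flat, function(r)
    data.frame(orientation = r$orientation, metric = r$metric, mean = r$mean,
               sd = r$sd, n_slices = r$n_slices, n_excluded = r$n_excluded)))
  if (!is.null(csv)) utils::write.csv(per_slice, csv, row.names = FALSE)
  if (!is.null(json)) jsonlite::write_json(agg, json, dataframe = "rows",
                                           auto_unbox = TRUE, digits = NA)
  invisible(agg)
}

#' Paired t-test on per-slice metric values
#'
#' Classical paired t-test on the slice-wise differences `a - b`, with slices
#' paired by index: `t = mean(d) / (sd(d) / sqrt(n))`, two-sided p from the
#' t distribution with `n - 1` degrees of freedom.
#'
#' @param values_a,values_b equal-length numeric vectors (length >= 2).
#' @return List with `t`, `p`, `df`, `mean_diff`. Identical lists give
#'   `t = 0`; constant non-zero differences (zero variance) raise an error.
#' @export
paired_ttest <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("length mismatch")
  n <- length(values_a)
  if (n < 2L) stop("need at least 2 paired values")
  d <- values_a - values_b
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = n - 1L, mean_diff = 0))
    stop("zero-variance non-zero differences: t statistic undefined")
  }
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = n - 1L),
       df = n - 1L, mean_diff = mean(d))
}
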