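#' Construct a label volume
#'
#' An integer-labelled segmentation grid (0 = background) with voxel spacing
#' in mm, as produced by multi-class brain segmentation pipelines.
#'
#' @param labels 3D array of non-negative integers.
#' @param spacing voxel edge lengths in mm.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be positive")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = spacing,
                 class_count = length(setdiff(unique(as.vector(labels)), 0L))),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels, %d foreground classes\n",
              d[1], d[2], d[3], x$class_count))
  invisible(x)
}

#' Region mapping table
#'
#' Maps named anatomical regions to one or more label ids, with optional
#' left/right pairing for asymmetry analysis. No label id may appear in two
#' regions.
#'
#' @param df data frame with columns `region`, `label_ids` (comma-separated
#'   ids or an integer), and optionally `side` (`"L"`, `"R"` or `NA`) and
#'   `pair_region` (the name of the contralateral region).
#' @return An object of class `region_table`.
#' @export
region_table <- function(df) {
  stopifnot(all(c("region", "label_ids") %in% names(df)))
  ids <- lapply(as.character(df$label_ids), function(s)
    as.integer(strsplit(s, "[,;[:space:]]+")[[1]]))
  flat <- unlist(ids)
  if (anyDuplicated(flat))
    stop("label id(s) ", paste(unique(flat[duplicated(flat)]), collapse = ", "),
         " appear in more than one region")
  structure(list(region = as.character(df$region), label_ids = ids,
                 side = if ("side" %in% names(df)) as.character(df$side) else rep(NA_character_, nrow(df)),
                 pair_region = if ("pair_region" %in% names(df)) as.character(df$pair_region) else rep(NA_character_, nrow(df))),
            class = "region_table")
}

#' Read a region table from CSV
#'
#' @param path CSV with the columns described in [region_table()].
#' @return A `region_table`.
#' @export
read_region_table <- function(path) {
  region_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Dice similarity coefficient
#'
#' Overlap between two binary masks: `2|A n B| / (|A| + |B|)`.
#'
#' @param a,b logical or 0/1 arrays of equal dimensions.
#' @return Dice in `[0, 1]`; 1 iff identical non-empty masks, 0 iff disjoint.
#'   Two empty masks give `NA` (undefined), not 1.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask dimensions differ")
  a <- a != 0; b <- b != 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(NA_real_)
  2 * sum(a & b) / (sa + sb)
}

# boundary (surface) voxels of a mask under 6-connectivity: voxels of the mask
# with at least one face-neighbour outside it (array edges count as outside)
boundary_voxels <- function(mask) {
  mask <- mask != 0
  d <- dim(mask)
  interior <- array(TRUE, dim = d)
  shift_ok <- function(ax, by) {
    s <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len); idx_dst <- idx_src
    if (by == 1) { idx_dst[[ax]] <- 2:d[ax]; idx_src[[ax]] <- 1:(d[ax] - 1) }
    else { idx_dst[[ax]] <- 1:(d[ax] - 1); idx_src[[ax]] <- 2:d[ax] }
    s[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      mask[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    s
  }
  for (ax in 1:3) for (by in c(1, -1)) interior <- interior & shift_ok(ax, by)
  mask & !interior
}

# 0-based voxel coordinates (n x 3) of TRUE voxels, scaled to mm by spacing
.mask_points <- function(mask, spacing) {
  w <- which(mask != 0, arr.ind = TRUE)
  sweep(w - 1, 2, spacing, `*`)
}

#' Hausdorff distances between two voxel sets
#'
#' Directed distances `h(A,B) = max_a min_b ||a - b||`, the symmetric
#' `H = max(h(A,B), h(B,A))`, and the robust 95th-percentile variant
#' `HD95 = max` of the two directed 95th percentiles of nearest-neighbour
#' distances. Masks are reduced to their boundary (surface) voxels under
#' 6-connectivity; coordinates are scaled by `spacing`, so all distances are
#' in mm.
#'
#' @param a,b binary masks (3D arrays) or `n x 3` matrices of 0-based voxel
#'   coordinates.
#' @param spacing voxel edge lengths in mm.
#' @param boundary reduce masks to boundary voxels first (ignored for
#'   coordinate input).
#' @return List with `h_ab`, `h_ba`, `H`, `hd95` (all in mm).
#' @export
hausdorff <- function(a, b, spacing = c(1, 1, 1), boundary = TRUE) {
  to_pts <- function(x, nm) {
    if (is.matrix(x)) return(sweep(x, 2, spacing, `*`))
    if (boundary) x <- boundary_voxels(x)
    .mask_points(x, spacing)
  }
  pa <- to_pts(a); pb <- to_pts(b)
  if (nrow(pa) == 0) stop("first voxel set is empty")
  if (nrow(pb) == 0) stop("second voxel set is empty")
  dab <- cpp_nn_dists(pa, pb)
  dba <- cpp_nn_dists(pb, pa)
  list(h_ab = max(dab), h_ba = max(dba), H = max(max(dab), max(dba)),
       hd95 = max(stats::quantile(dab, 0.95, names = FALSE),
                  stats::quantile(dba, 0.95, names = FALSE)))
}

#' Per-label Dice and HD95 between two label volumes
#'
#' Computes Dice and HD95 for every foreground label present in either
#' volume. Labels present in only one volume score Dice 0 with `flag = TRUE`
#' (and undefined HD95), keeping family means honest rather than silently
#' dropping them.
#'
#' @param gt,syn co-registered [label_volume]s with identical dims and
#'   spacing.
#' @return Data frame `label, dice, hd95, flag`, with attribute `family_mean`
#'   holding the mean Dice/HD95 over labels present in the ground truth.
#' @export
per_mask_family_report <- function(gt, syn) {
  stopifnot(inherits(gt, "label_volume"), inherits(syn, "label_volume"))
  if (!identical(dim(gt$labels), dim(syn$labels))) stop("dimensions differ")
  if (!isTRUE(all.equal(gt$spacing, syn$spacing))) stop("spacings differ")
  lg <- setdiff(unique(as.vector(gt$labels)), 0L)
  ls <- setdiff(unique(as.vector(syn$labels)), 0L)
  labs <- sort(union(lg, ls))
  rows <- lapply(labs, function(l) {
    in_gt <- l %in% lg; in_syn <- l %in% ls
    if (in_gt && in_syn) {
      mg <- gt$labels == l; ms <- syn$labels == l
      hd <- hausdorff(mg, ms, gt$spacing)$hd95
      data.frame(label = l, dice = dice(mg, ms), hd95 = hd, flag = FALSE)
    } else {
      data.frame(label = l, dice = 0, hd95 = NA_real_, flag = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  in_gt <- out$label %in% lg
  attr(out, "family_mean") <- c(dice = mean(out$dice[in_gt]),
                                hd95 = mean(out$hd95[in_gt], na.rm = TRUE))
  out
}

#' Regional volumetry
#'
#' Per-region volume in cm^3 (`voxel count x voxel volume in mm^3 / 1000`)
#' and percentage of the intracranial cavity volume.
#'
#' @param lv a [label_volume].
#' @param rt a [region_table].
#' @param icv_region name of the region serving as the intracranial cavity
#'   reference (must have non-zero volume).
#' @return Data frame `region, cm3, pct_icv` of class `volumetry_report`.
#' @export
region_volume <- function(lv, rt, icv_region = "Intracranial Cavity") {
  stopifnot(inherits(lv, "label_volume"), inherits(rt, "region_table"))
  if (!icv_region %in% rt$region) stop("ICV region '", icv_region, "' not in table")
  vox_mm3 <- prod(lv$spacing)
  counts <- tabulate(lv$labels + 1L)  # counts[l+1] = voxels with label l
  lab_count <- function(ids) sum(counts[ids + 1L], na.rm = TRUE)
  cm3 <- vapply(rt$label_ids, function(ids) lab_count(ids) * vox_mm3 / 1000,
                numeric(1))
  icv <- cm3[match(icv_region, rt$region)]
  if (icv == 0) stop("ICV region is empty")
  out <- data.frame(region = rt$region, cm3 = cm3, pct_icv = 100 * cm3 / icv)
  class(out) <- c("volumetry_report", "data.frame")
  out
}

#' Signed percent error of a synthetic measurement
#'
#' `100 * (synthetic - ground_truth) / ground_truth`.
#'
#' @param gt_value reference (non-zero) value.
#' @param syn_value measured value.
#' @return Signed percentage.
#' @export
percent_error <- function(gt_value, syn_value) {
  if (any(gt_value == 0)) stop("zero reference value")
  100 * (syn_value - gt_value) / gt_value
}

#' Percent difference between 7T- and 3T-derived values
#'
#' The default (`form = "relative_to_3t"`) reports
#' `100 * (value_7t - value_3t) / value_3t`, the form consistent with
#' published volumetric comparisons of the two field strengths;
#' `form = "relative_to_7t"` gives `100 * (value_3t - value_7t) / value_7t`.
#'
#' @param value_7t,value_3t measurements of the same quantity at the two
#'   field strengths.
#' @param form denominator convention.
#' @return Signed percentage.
#' @export
percent_difference <- function(value_7t, value_3t,
                               form = c("relative_to_3t", "relative_to_7t")) {
  form <- match.arg(form)
  if (form == "relative_to_3t") {
    if (any(value_3t == 0)) stop("zero reference value")
    100 * (value_7t - value_3t) / value_3t
  } else {
    if (any(value_7t == 0)) stop("zero reference value")
    100 * (value_3t - value_7t) / value_7t
  }
}

#' Left/right volumetric asymmetry index
#'
#' The default definition is the signed normalized difference
#' `100 * (right - left) / ((left + right) / 2)`; it is antisymmetric under
#' swapping sides and 0 for equal volumes. The definition used is recorded as
#' an attribute on the result so downstream reports can name the formula.
#'
#' @param left_vol,right_vol structure volumes (cm^3), not both zero.
#' @param method index definition; only `"signed_mean_norm"` is currently
#'   implemented.
#' @return Signed index with attribute `formula`.
#' @export
asymmetry_index <- function(left_vol, right_vol, method = c("signed_mean_norm")) {
  method <- match.arg(method)
  if (any(left_vol + right_vol == 0)) stop("both volumes zero")
  out <- 100 * (right_vol - left_vol) / ((left_vol + right_vol) / 2)
  attr(out, "formula") <- "100 * (R - L) / ((L + R) / 2)"
  out
}

#' Percent error between asymmetry indices
#'
#' `100 * (synthetic - ground_truth) / ground_truth`, applied literally, so
#' sign conventions of negative indices carry through.
#'
#' @param gt_index,syn_index asymmetry indices (ground truth non-zero).
#' @return Signed percentage.
#' @export
asymmetry_error <- function(gt_index, syn_index) {
  if (any(gt_index == 0)) stop("zero reference index")
  100 * (syn_index - gt_index) / gt_index
}
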