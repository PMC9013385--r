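#' Soft dice loss
#'
#' `1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)` with a small
#' smoothing constant so an empty prediction against an empty target is a
#' perfect (zero) loss rather than 0/0. This is the training objective for
#' every head of the network.
#'
#' @param pred Probability array in `[0, 1]`.
#' @param truth Binary array, same shape.
#' @param eps Smoothing constant (default `1e-6`).
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, truth, eps = 1e-6) {
  if (!identical(dim(pred), dim(truth)) &&
      !(is.null(dim(pred)) && is.null(dim(truth)) && length(pred) == length(truth))) {
    abort("`pred` and `truth` must have identical shapes.")
  }
  if (min(pred) < -1e-9 || max(pred) > 1 + 1e-9) abort("`pred` must lie in [0, 1].")
  if (!all(truth %in% c(0, 1))) abort("`truth` must be binary.")
  1 - (2 * sum(pred * truth) + eps) / (sum(pred) + sum(truth) + eps)
}

# gradient of dice_loss w.r.t. pred, used by the training loop
dice_loss_grad <- function(pred, truth, eps = 1e-6) {
  num <- 2 * sum(pred * truth) + eps
  den <- sum(pred) + sum(truth) + eps
  -(2 * truth * den - num) / den^2
}

#' Deep-supervision total loss
#'
#' The training objective with deep supervision enabled is the plain
#' unweighted sum of the per-level dice losses.
#'
#' @param level_losses Non-empty numeric vector or list of scalar losses.
#' @return Their sum.
#' @export
ds_total_loss <- function(level_losses) {
  x <- as.numeric(unlist(level_losses))
  if (length(x) == 0L) abort("`level_losses` must be non-empty.")
  sum(x)
}

#' Voxel confusion counts between two binary maps
#'
#' @param pred,truth Binary arrays of identical shape.
#' @return Named numeric vector `TP`, `FP`, `FN`, `TN`; the four always sum
#'   to the voxel count.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) abort("shape mismatch.")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    abort("confusion counts need binary inputs.")
  }
  c(TP = as.numeric(sum(pred == 1 & truth == 1)),
    FP = as.numeric(sum(pred == 1 & truth == 0)),
    FN = as.numeric(sum(pred == 0 & truth == 1)),
    TN = as.numeric(sum(pred == 0 & truth == 0)))
}

# boundary voxels under 6-connectivity: foreground with at least one face
# neighbour (or the volume edge) in background
boundary_voxels <- function(mask) {
  d <- dim(mask)
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  nb_min <- pmin(
    pad[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L)],
    pad[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L)],
    pad[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L)],
    pad[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L)],
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3]],
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L)]
  )
  which(core == 1 & nb_min == 0, arr.ind = TRUE)
}

# directed Hausdorff h(A, B) = max_a min_b ||a - b||, points in mm
directed_hausdorff <- function(a_mm, b_mm, chunk = 512L) {
  nb <- nrow(b_mm)
  b2 <- rowSums(b_mm^2)
  worst <- 0
  for (i0 in seq(1L, nrow(a_mm), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(a_mm))
    a <- a_mm[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(a^2), b2, "+") - 2 * a %*% t(b_mm)
    mins <- apply(d2, 1, min)
    # the expanded form loses ~1e-13 to cancellation; genuine nonzero voxel
    # separations are >= min(spacing)^2, so sub-1e-6 mm^2 values are exact zeros
    mins[mins < 1e-6] <- 0
    worst <- max(worst, max(mins))
  }
  sqrt(max(worst, 0))
}

#' Symmetric Hausdorff distance between two masks, in millimetres
#'
#' The exact (100th-percentile) Hausdorff distance
#' `max(h(A, B), h(B, A))` between boundary-voxel centre coordinates, with
#' voxel indices scaled by the anisotropic spacing so the result is metric.
#' Boundary points (6-connectivity erosion complement) give the same value as
#' full point sets for solid masks at a fraction of the cost. Cost is
#' O(|bnd A| x |bnd B|), evaluated in vectorised chunks.
#'
#' @param a,b Binary 3D arrays, both non-empty.
#' @param spacing Voxel spacing mm `(slice, row, col)`.
#' @return Distance in mm (`>= 0`).
#' @export
hausdorff_mm <- function(a, b, spacing) {
  if (!identical(dim(a), dim(b))) abort("shape mismatch.")
  if (sum(a) == 0 || sum(b) == 0) {
    abort("Hausdorff distance is undefined for an empty mask.")
  }
  spacing <- as.numeric(spacing)
  pa <- boundary_voxels(a); pb <- boundary_voxels(b)
  a_mm <- sweep(pa, 2L, spacing, `*`)
  b_mm <- sweep(pb, 2L, spacing, `*`)
  max(directed_hausdorff(a_mm, b_mm), directed_hausdorff(b_mm, a_mm))
}

#' Segmentation metrics for one structure
#'
#' Recall, precision, dice similarity coefficient (DSC), intersection over
#' union (IoU) and Hausdorff distance (mm) between the predicted and
#' ground-truth masks of a structure. Empty-mask conventions: both masks
#' empty is vacuous agreement (all fractions 1, HD 0); exactly one empty
#' yields 0 for DSC/IoU and for whichever of recall/precision has an empty
#' denominator the value 0, and the Hausdorff distance is reported `NA`
#' (undefined, surfaced rather than defaulted).
#'
#' @param pred,truth [label_volume()]s on the same grid and spacing.
#' @param structure One of `whole`, `left_lobe`, `right_lobe`, `caudate_lobe`.
#' @return One-row tibble: `structure`, `recall`, `precision`, `dsc`, `iou`,
#'   `hd_mm`.
#' @export
seg_metrics <- function(pred, truth, structure = "whole") {
  stopifnot(inherits(pred, "label_volume"), inherits(truth, "label_volume"))
  if (is.null(pred$masks[[structure]]) || is.null(truth$masks[[structure]])) {
    abort(paste0("structure `", structure, "` absent from prediction or truth."))
  }
  if (!identical(dim(pred), dim(truth))) abort("grids differ.")
  if (max(abs(pred$spacing - truth$spacing)) > 1e-9) abort("spacings differ.")
  p <- pred$masks[[structure]]; t <- truth$masks[[structure]]
  cc <- confusion_counts(p, t)
  np <- cc[["TP"]] + cc[["FP"]]; nt <- cc[["TP"]] + cc[["FN"]]
  if (np == 0 && nt == 0) {
    recall <- precision <- dsc <- iou <- 1; hd <- 0
  } else {
    recall <- if (nt > 0) cc[["TP"]] / nt else 0
    precision <- if (np > 0) cc[["TP"]] / np else 0
    dsc <- 2 * cc[["TP"]] / (2 * cc[["TP"]] + cc[["FP"]] + cc[["FN"]])
    iou <- cc[["TP"]] / (cc[["TP"]] + cc[["FP"]] + cc[["FN"]])
    hd <- if (np > 0 && nt > 0) hausdorff_mm(p, t, truth$spacing) else NA_real_
  }
  tibble::tibble(structure = structure, recall = recall, precision = precision,
                 dsc = dsc, iou = iou, hd_mm = hd)
}

#' Aggregate a per-case metrics table as mean and SD
#'
#' Collapses a long table of per-case segmentation metrics to mean +/- SD per
#' grouping column, the layout segmentation ablation tables are reported in.
#'
#' @param metrics Tibble with numeric metric columns and grouping columns
#'   (e.g. `structure`, `model`).
#' @param by Character vector of grouping columns present in `metrics`.
#' @return Tibble of means and SDs per group.
#' @export
summarise_metrics <- function(metrics, by = intersect(c("model", "structure"),
                                                      names(metrics))) {
  metrics |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      dplyr::across(dplyr::where(is.numeric),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         sd = ~sd(.x, na.rm = TRUE))),
      .groups = "drop"
    )
}
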