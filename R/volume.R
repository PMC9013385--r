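#' @importFrom rlang abort
#' @importFrom stats rnorm runif sd lm coef t.test qnorm predict
#' @importFrom utils head tail
NULL

STRUCTURES <- c("whole", "left_lobe", "right_lobe", "caudate_lobe")

#' CT volume container
#'
#' A CT volume is a 3D intensity array indexed `(slice, row, col)` (0-based in
#' documentation, 1-based in R) with anisotropic voxel spacing
#' `(section_thickness_mm, row_mm, col_mm)`. Intensities are Hounsfield units
#' (HU) before windowing and unitless in `[0, 1]` afterwards; the `windowed`
#' flag records which, so the window transform cannot be applied twice.
#'
#' @param voxels 3D numeric array, dimensions `(n_slices, height, width)`.
#' @param spacing Numeric length-3 vector, strictly positive, in mm:
#'   `(section_thickness, row, col)`.
#' @param windowed Logical; `TRUE` once intensities are window-normalised to
#'   `[0, 1]`.
#' @return An object of class `ct_volume`.
#' @seealso [apply_window()], [resize_inplane()], [to_model_blocks()]
#' @export
ct_volume <- function(voxels, spacing, windowed = FALSE) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3D array (slice, row, col).")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three strictly positive values (mm).")
  }
  windowed <- isTRUE(windowed)
  if (windowed) {
    rng <- range(voxels)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
      abort("windowed volumes must have voxel values in [0, 1].")
    }
  }
  structure(
    list(voxels = voxels, spacing = spacing, windowed = windowed),
    class = "ct_volume"
  )
}

#' Segmentation mask container
#'
#' Voxel-aligned binary masks for the hepatic structures, keyed by structure
#' name among `whole`, `left_lobe`, `right_lobe`, `caudate_lobe`. All masks
#' share one grid and one spacing. When the three lobes are all present they
#' must partition the whole-liver mask: pairwise disjoint with union equal to
#' `whole`.
#'
#' @param masks Named list of 3D arrays with values in `{0, 1}`.
#' @param spacing Voxel spacing in mm, as in [ct_volume()].
#' @param check_partition Verify the lobe-partition invariant when all three
#'   lobes are present (default `TRUE`).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(masks, spacing, check_partition = TRUE) {
  if (!is.list(masks) || is.null(names(masks)) || any(names(masks) == "")) {
    abort("`masks` must be a named list of 3D arrays.")
  }
  bad <- setdiff(names(masks), STRUCTURES)
  if (length(bad)) {
    abort(paste0("unknown structure name(s): ", paste(bad, collapse = ", ")))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be three strictly positive values (mm).")
  }
  dims <- lapply(masks, dim)
  if (any(vapply(dims, length, 1L) != 3L)) abort("each mask must be a 3D array.")
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    abort("all masks must share one grid.")
  }
  for (nm in names(masks)) {
    v <- masks[[nm]]
    if (!all(v %in% c(0, 1))) abort(paste0("mask `", nm, "` is not binary."))
    storage.mode(masks[[nm]]) <- "double"
  }
  lobes <- c("left_lobe", "right_lobe", "caudate_lobe")
  if (check_partition && all(lobes %in% names(masks)) && "whole" %in% names(masks)) {
    s <- masks$left_lobe + masks$right_lobe + masks$caudate_lobe
    if (any(s > 1)) abort("lobe masks overlap; they must be pairwise disjoint.")
    if (any(s != masks$whole)) {
      abort("lobe masks must union exactly to the whole-liver mask.")
    }
  }
  structure(list(masks = masks, spacing = spacing), class = "label_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume> %d x %d x %d (slice x row x col), spacing %.3g/%.3g/%.3g mm, %s\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    if (x$windowed) "windowed [0,1]" else "HU"
  ))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf(
    "<label_volume> %d x %d x %d, structures: %s\n",
    d[1], d[2], d[3], paste(names(x$masks), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' @export
dim.label_volume <- function(x) dim(x$masks[[1]])

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's RNG
# stream is untouched. All stochastic code in the package goes through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a reproducible child seed from (seed, key) without touching the
# caller's RNG; keeps results below 2^31.
derive_seed <- function(seed, key) {
  (as.numeric(seed) * 7919 + as.numeric(key) * 104729) %% 2147483629
}
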