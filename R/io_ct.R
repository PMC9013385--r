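#' Intensity window specification
#'
#' A CT display window: intensities are clipped to
#' `[level - width/2, level + width/2]` and mapped linearly onto `[0, 1]`.
#' The default, level 50 HU and width 180 HU, is a soft-tissue window under
#' which liver parenchyma is well separated from surrounding fat and vessels.
#'
#' @param level Window centre in HU.
#' @param width Window width in HU; must be positive.
#' @export
window_spec <- function(level = 50, width = 180) {
  level <- as.numeric(level); width <- as.numeric(width)
  if (!is.finite(width) || width <= 0) abort("window `width` must be > 0.")
  structure(list(level = level, width = width), class = "window_spec")
}

#' Window-normalise a CT volume
#'
#' Clips Hounsfield intensities to the window and rescales them linearly to
#' `[0, 1]`, the range the segmentation network's sigmoid targets live in.
#' Windowing an already-windowed volume is refused: the transform is not
#' idempotent on its own output and re-applying it would silently corrupt the
#' intensity scale.
#'
#' @param vol A [ct_volume()] with `windowed = FALSE`.
#' @param w A [window_spec()].
#' @return A windowed `ct_volume`; shape and spacing unchanged.
#' @export
apply_window <- function(vol, w = window_spec()) {
  stopifnot(inherits(vol, "ct_volume"), inherits(w, "window_spec"))
  if (vol$windowed) {
    abort("volume is already windowed; refusing to window twice.")
  }
  lo <- w$level - w$width / 2
  hi <- w$level + w$width / 2
  v <- pmin(pmax(vol$voxels, lo), hi)
  v <- (v - lo) / (hi - lo)
  ct_volume(array(v, dim(vol$voxels)), vol$spacing, windowed = TRUE)
}

# Separable resize of a (D, H, W) array onto a (D, th, tw) grid.
# mode "linear": bilinear, pixel centres aligned; mode "nearest": label-safe.
resize_slices <- function(a, th, tw, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(a)
  map_axis <- function(n_src, n_tgt) {
    x <- (seq_len(n_tgt) - 0.5) * (n_src / n_tgt) + 0.5 - 0.5  # src coord, 1-based
    if (mode == "nearest") {
      i0 <- pmin(pmax(round(x), 1L), n_src)
      list(i0 = i0, i1 = i0, f = rep(0, n_tgt))
    } else {
      i0 <- pmin(pmax(floor(x), 1L), n_src)
      i1 <- pmin(i0 + 1L, n_src)
      list(i0 = i0, i1 = i1, f = pmin(pmax(x - i0, 0), 1))
    }
  }
  r <- map_axis(d[2], th)
  cc <- map_axis(d[3], tw)
  # four corner gathers on the separable target grid, blended by outer weights
  blend <- function(wr, wc) rep(as.vector(outer(wr, wc)), each = d[1])
  out <- a[, r$i0, cc$i0, drop = FALSE] * blend(1 - r$f, 1 - cc$f) +
    a[, r$i1, cc$i0, drop = FALSE] * blend(r$f, 1 - cc$f) +
    a[, r$i0, cc$i1, drop = FALSE] * blend(1 - r$f, cc$f) +
    a[, r$i1, cc$i1, drop = FALSE] * blend(r$f, cc$f)
  array(out, c(d[1], th, tw))
}

#' Resample the in-plane grid of a volume or mask
#'
#' Each axial slice is resampled to `target x target`. Intensity volumes use
#' bilinear interpolation; label volumes use nearest-neighbour so masks remain
#' binary. In-plane spacing is rescaled by the size ratio, preserving the
#' physical field of view (512 px at 0.6 mm becomes 256 px at 1.2 mm).
#'
#' @param vol A [ct_volume()] or [label_volume()] with square slices.
#' @param target Target in-plane size in voxels (e.g. 256).
#' @return The same type, resampled, with rescaled in-plane spacing.
#' @export
resize_inplane <- function(vol, target = 256L) {
  target <- as.integer(target)
  if (target < 1L) abort("`target` must be a positive integer.")
  d <- dim(vol)
  if (d[2] != d[3]) abort("in-plane grid must be square to resize.")
  ratio <- d[2] / target
  if (inherits(vol, "ct_volume")) {
    v <- resize_slices(vol$voxels, target, target, "linear")
    sp <- c(vol$spacing[1], vol$spacing[2] * ratio, vol$spacing[3] * ratio)
    if (vol$windowed) v <- pmin(pmax(v, 0), 1)
    ct_volume(v, sp, windowed = vol$windowed)
  } else if (inherits(vol, "label_volume")) {
    masks <- lapply(vol$masks, resize_slices, th = target, tw = target,
                    mode = "nearest")
    sp <- c(vol$spacing[1], vol$spacing[2] * ratio, vol$spacing[3] * ratio)
    # nearest-neighbour resampling cannot create overlaps, but can break exact
    # additivity only through whole-vs-lobe disagreement at shared boundaries;
    # resampling each structure with the same index map preserves the partition.
    label_volume(masks, sp)
  } else {
    abort("`vol` must be a ct_volume or label_volume.")
  }
}

#' Partition a volume into fixed-depth model blocks
#'
#' The network consumes blocks of `depth` consecutive slices with a trailing
#' singleton channel axis, `(depth, H, W, 1)`. The final block is zero-padded
#' up to `depth` and its count of valid slices recorded so predictions can be
#' un-padded exactly by [blocks_to_volume()].
#'
#' @param vol A windowed [ct_volume()].
#' @param depth Block depth in slices (default 64).
#' @return List with `blocks` (list of 4D arrays), `valid` (valid slices per
#'   block), `n_slices`, `spacing`.
#' @export
to_model_blocks <- function(vol, depth = 64L) {
  stopifnot(inherits(vol, "ct_volume"))
  depth <- as.integer(depth)
  if (depth < 1L) abort("`depth` must be >= 1.")
  if (!vol$windowed) abort("volume must be windowed before blocking.")
  d <- dim(vol$voxels)
  n_blocks <- ceiling(d[1] / depth)
  blocks <- vector("list", n_blocks)
  valid <- integer(n_blocks)
  for (b in seq_len(n_blocks)) {
    i0 <- (b - 1L) * depth + 1L
    i1 <- min(b * depth, d[1])
    valid[b] <- i1 - i0 + 1L
    blk <- array(0, c(depth, d[2], d[3], 1L))
    blk[seq_len(valid[b]), , , 1L] <- vol$voxels[i0:i1, , ]
    blocks[[b]] <- blk
  }
  list(blocks = blocks, valid = valid, n_slices = d[1], spacing = vol$spacing)
}

#' Reassemble model blocks into a volume array
#'
#' Inverse of [to_model_blocks()]: concatenates the valid slices of each block
#' and drops the padding, reproducing the original slice count exactly.
#'
#' @param blocked The list returned by [to_model_blocks()] (the `blocks` may
#'   have been replaced by same-shaped predictions).
#' @return 3D array `(n_slices, H, W)`.
#' @export
blocks_to_volume <- function(blocked) {
  stopifnot(is.list(blocked$blocks), length(blocked$valid) == length(blocked$blocks))
  parts <- lapply(seq_along(blocked$blocks), function(b) {
    blk <- blocked$blocks[[b]]
    blk[seq_len(blocked$valid[b]), , , 1L, drop = FALSE]
  })
  d <- dim(blocked$blocks[[1]])
  out <- array(0, c(blocked$n_slices, d[2], d[3]))
  at <- 1L
  for (p in parts) {
    n <- dim(p)[1]
    out[at:(at + n - 1L), , ] <- p[, , , 1L]
    at <- at + n
  }
  out
}

#' Cohort split specification
#'
#' Fractions for train/validation/test plus the seed that fixes the shuffle.
#' The 70:15:15 default mirrors common practice for single-centre CT cohorts.
#'
#' @param ratios Length-3 non-negative fractions summing to 1.
#' @param seed Integer seed for the deterministic shuffle.
#' @export
split_spec <- function(ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  ratios <- as.numeric(ratios)
  if (length(ratios) != 3L || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9) {
    abort("`ratios` must be three non-negative fractions summing to 1.")
  }
  structure(list(ratios = ratios, seed = as.integer(seed)), class = "split_spec")
}

#' Split case identifiers into train/validation/test sets
#'
#' Deterministic given the seed. Sizes follow the floor rule:
#' `floor(n * train)` and `floor(n * val)` cases, with the remainder assigned
#' to test, so the partition is always exhaustive and disjoint. The split is
#' at case (patient) level; blocks from one case never straddle sets.
#'
#' @param ids Character or integer vector of unique case identifiers.
#' @param spec A [split_spec()].
#' @return Named list `train`, `val`, `test`.
#' @export
split_dataset <- function(ids, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  if (length(ids) == 0L) abort("`ids` must be non-empty.")
  if (anyDuplicated(ids)) abort("`ids` contains duplicates.")
  n <- length(ids)
  perm <- with_seed(spec$seed, sample.int(n))
  shuffled <- ids[perm]
  n_train <- floor(n * spec$ratios[1])
  n_val <- floor(n * spec$ratios[2])
  list(
    train = shuffled[seq_len(n_train)],
    val = if (n_val > 0) shuffled[n_train + seq_len(n_val)] else shuffled[0],
    test = if (n_train + n_val < n) shuffled[(n_train + n_val + 1L):n] else shuffled[0]
  )
}

#' Read a CT volume from NIfTI or a DICOM series directory
#'
#' A `.nii`/`.nii.gz` path is read through RNifti; a directory is treated as
#' one DICOM series (uncompressed, explicit VR little endian), with slices
#' sorted by their along-axis position and section thickness inferred from the
#' inter-slice gap. Intensities are returned in HU (DICOM rescale slope and
#' intercept applied); `windowed` is `FALSE`.
#'
#' @param path NIfTI file or DICOM directory.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file or directory: ", path))
  if (dir.exists(path)) {
    return(read_dicom_series(path))
  }
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  ct_volume(array(as.numeric(img), dim(img)[1:3]), sp, windowed = FALSE)
}

#' Write a CT volume to NIfTI
#'
#' @param vol A [ct_volume()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# label encoding used on disk: 0 background, 1 left, 2 right, 3 caudate;
# whole liver = any non-zero voxel.
LABEL_CODES <- c(left_lobe = 1, right_lobe = 2, caudate_lobe = 3)

#' Write a label volume to a label-coded NIfTI mask
#'
#' Lobes are stored as integer codes (1 left, 2 right, 3 caudate); the whole
#' liver is their union. A mask holding only `whole` is stored as 0/1.
#'
#' @param lab A [label_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(lab, path) {
  stopifnot(inherits(lab, "label_volume"))
  lobes <- intersect(names(LABEL_CODES), names(lab$masks))
  if (length(lobes)) {
    coded <- array(0, dim(lab))
    for (nm in lobes) coded <- coded + LABEL_CODES[[nm]] * lab$masks[[nm]]
  } else {
    coded <- lab$masks$whole
  }
  img <- RNifti::asNifti(coded)
  RNifti::pixdim(img) <- lab$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label-coded NIfTI mask
#'
#' @param path Mask path written by [write_mask()].
#' @return A [label_volume()]; lobe channels are present when the file holds
#'   lobe codes, and `whole` is always present.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  coded <- array(as.numeric(img), dim(img)[1:3])
  masks <- list(whole = (coded > 0) * 1)
  if (any(coded > 1)) {
    for (nm in names(LABEL_CODES)) {
      masks[[nm]] <- (coded == LABEL_CODES[[nm]]) * 1
    }
  }
  label_volume(masks, sp)
}

#' Read a case manifest
#'
#' A manifest is a CSV with columns `case_id`, `image_path`, `mask_path`;
#' relative paths are resolved against the manifest's own directory.
#'
#' @param path Manifest CSV path.
#' @return A tibble with absolute paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("no such manifest: ", path))
  m <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("case_id", "image_path", "mask_path")
  if (!all(need %in% names(m))) {
    abort(paste0("manifest must have columns: ", paste(need, collapse = ", ")))
  }
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  m$image_path <- fix(m$image_path)
  m$mask_path <- fix(m$mask_path)
  tibble::as_tibble(m)
}
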