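#' Segmented area of one axial slice
#'
#' Foreground voxel count times the in-plane pixel area, in mm^2.
#'
#' @param mask_slice 2D binary matrix.
#' @param in_plane_spacing `(row_mm, col_mm)`.
#' @return Area in mm^2.
#' @export
slice_area <- function(mask_slice, in_plane_spacing) {
  if (!all(mask_slice %in% c(0, 1))) abort("`mask_slice` must be binary.")
  sp <- as.numeric(in_plane_spacing)
  if (length(sp) != 2L || any(sp <= 0)) abort("in-plane spacing must be two positive mm values.")
  sum(mask_slice) * sp[1] * sp[2]
}

#' Volume of one structure by slice-area summation
#'
#' The CT volumetry estimator: per-slice segmented area times the section
#' thickness, summed over all slices, converted to millilitres
#' (1 mL = 1000 mm^3).
#'
#' @param mask A [label_volume()].
#' @param structure Structure name present in `mask`.
#' @return Volume in mL.
#' @export
mask_volume <- function(mask, structure = "whole") {
  stopifnot(inherits(mask, "label_volume"))
  m <- mask$masks[[structure]]
  if (is.null(m)) abort(paste0("structure `", structure, "` missing from mask."))
  sp <- mask$spacing
  if (length(sp) != 3L || any(!is.finite(sp))) abort("mask spacing missing or invalid.")
  areas <- vapply(seq_len(dim(m)[1]),
                  function(k) slice_area(m[k, , ], sp[2:3]), 1.0)
  sum(areas * sp[1]) / 1000
}

#' Lobe volumetry of a fully labelled mask
#'
#' Volumes (mL) for the whole liver and the three lobes, plus the per-slice
#' area table and an additivity check comparing the whole-liver volume with
#' the sum of the lobes (exact on a true partition; any gap is reported, not
#' hidden).
#'
#' @param masks A [label_volume()] containing `whole`, `left_lobe`,
#'   `right_lobe`, `caudate_lobe`.
#' @return Object of class `volumetry_result`: a list with `volumes` (tibble
#'   `structure`, `volume_mL`, `n_slices`, `thickness_mm`), `slice_areas`
#'   (tibble `structure`, `slice`, `area_mm2`), `additivity_gap_mL`, and
#'   `spacing`.
#' @export
lobe_volumetry <- function(masks) {
  stopifnot(inherits(masks, "label_volume"))
  missing <- setdiff(STRUCTURES, names(masks$masks))
  if (length(missing)) {
    abort(paste0("lobe volumetry needs all structures; missing: ",
                 paste(missing, collapse = ", ")))
  }
  sp <- masks$spacing
  n_slices <- dim(masks)[1]
  slice_areas <- purrr::map_dfr(STRUCTURES, function(s) {
    tibble::tibble(
      structure = s,
      slice = seq_len(n_slices),
      area_mm2 = vapply(seq_len(n_slices),
                        function(k) slice_area(masks$masks[[s]][k, , ], sp[2:3]), 1.0)
    )
  })
  volumes <- slice_areas |>
    dplyr::group_by(structure) |>
    dplyr::summarise(volume_mL = sum(area_mm2) * sp[1] / 1000, .groups = "drop") |>
    dplyr::mutate(n_slices = n_slices, thickness_mm = sp[1]) |>
    dplyr::arrange(match(structure, STRUCTURES))
  gap <- volumes$volume_mL[volumes$structure == "whole"] -
    sum(volumes$volume_mL[volumes$structure != "whole"])
  structure(list(volumes = volumes, slice_areas = slice_areas,
                 additivity_gap_mL = gap, spacing = sp),
            class = "volumetry_result")
}

#' @export
print.volumetry_result <- function(x, ...) {
  cat("<volumetry_result>\n")
  print(x$volumes)
  cat(sprintf("additivity gap (whole - sum of lobes): %.6g mL\n",
              x$additivity_gap_mL))
  invisible(x)
}

#' @rdname lobe_volumetry
#' @param x A `volumetry_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.volumetry_result <- function(x, ...) x$volumes

#' @rdname lobe_volumetry
#' @exportS3Method generics::glance
glance.volumetry_result <- function(x, ...) {
  tibble::tibble(
    whole_mL = x$volumes$volume_mL[x$volumes$structure == "whole"],
    additivity_gap_mL = x$additivity_gap_mL,
    n_slices = x$volumes$n_slices[1],
    thickness_mm = x$spacing[1]
  )
}

#' Volumetry over a manifest of masks
#'
#' Reads each case's mask and tabulates per-structure volumes; the tabular
#' interface the agreement analysis consumes.
#'
#' @param manifest Tibble from [read_manifest()] (or any tibble with
#'   `case_id`, `mask_path`).
#' @return Tibble `case_id`, `structure`, `volume_mL`, `n_slices`,
#'   `thickness_mm`.
#' @export
volumetry_table <- function(manifest) {
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    lab <- read_mask(manifest$mask_path[i])
    have_lobes <- all(STRUCTURES %in% names(lab$masks))
    structs <- if (have_lobes) STRUCTURES else intersect("whole", names(lab$masks))
    tibble::tibble(
      case_id = manifest$case_id[i],
      structure = structs,
      volume_mL = vapply(structs, function(s) mask_volume(lab, s), 1.0),
      n_slices = dim(lab)[1],
      thickness_mm = lab$spacing[1]
    )
  })
}
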