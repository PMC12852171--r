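#' Extract masked voxels from aligned 3-D volumes
#'
#' Bridges already-aligned scalar volumes (e.g. FA or MD maps registered
#' to a standard space) to the feature-matrix world. Features are the
#' voxels with a nonzero label in the mask/atlas volume, ordered by
#' ascending linear index in the volume's native (column-major) array
#' order; values pass through bit-exact, with no resampling or
#' interpolation.
#'
#' @param volumes per-subject volumes on a shared grid: a named list of
#'   3-D arrays, a 4-D array (subject as the 4th dimension), or a
#'   character vector of NIfTI file paths (read with
#'   \pkg{RNifti}).
#' @param mask a 3-D integer-labelled array of the same shape (or a NIfTI
#'   path); any nonzero label is inside the mask, and the label value is
#'   the ROI identity.
#' @param site,covariates optional per-subject metadata forwarded to
#'   [feature_dataset()] (site defaults to a single `"pooled"` label so
#'   the return value is always constructible).
#' @return List with `dataset` (a [feature_dataset()], features named
#'   `"v<linear index>"`), `index_map` (data.frame: feature, linear index,
#'   i/j/k 1-based voxel coordinates) and `atlas` (integer ROI label per
#'   feature, usable with [roi_average()]).
#' @export
volumes_to_features <- function(volumes, mask, site = NULL,
                                covariates = NULL) {
  vols <- as_volume_list(volumes)
  mask <- as_volume(mask)
  dims <- dim(vols[[1]])
  if (!identical(dim(mask), dims))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match volume shape ", paste(dims, collapse = "x"))
  for (v in vols)
    if (!identical(dim(v), dims))
      stop("all volumes must share the same shape")
  lin <- which(mask != 0)
  if (!length(lin)) stop("mask is empty (no nonzero labels)")
  values <- t(vapply(vols, function(v) as.numeric(v)[lin],
                     numeric(length(lin))))
  coords <- arrayInd(lin, dims)
  index_map <- data.frame(feature = paste0("v", lin), linear_index = lin,
                          i = coords[, 1], j = coords[, 2], k = coords[, 3])
  if (is.null(site)) site <- rep("pooled", length(vols))
  dataset <- feature_dataset(values, site = site, covariates = covariates,
                             feature_ids = index_map$feature,
                             subject_ids = names(vols))
  list(dataset = dataset, index_map = index_map,
       atlas = as.integer(mask[lin]))
}

#' Place per-feature values back into volume geometry
#'
#' Inverse of [volumes_to_features()]: writes feature values to their
#' mapped voxel coordinates; voxels outside the map are exactly zero.
#'
#' @param x either a [feature_dataset()] (one output volume per subject)
#'   or a numeric vector of per-feature scalars (e.g. an unharmonized
#'   frequency map; one output volume).
#' @param index_map the `index_map` returned by [volumes_to_features()].
#' @param dim reference volume dimensions (length-3 integer).
#' @param paths optional NIfTI output path(s); when given, volumes are
#'   also written with \pkg{RNifti}.
#' @return A single 3-D array, or a named list of 3-D arrays for a
#'   dataset input.
#' @export
features_to_volumes <- function(x, index_map, dim, paths = NULL) {
  place <- function(vals) {
    if (length(vals) != nrow(index_map))
      stop("value count (", length(vals),
           ") does not match the index map (", nrow(index_map), ")")
    vol <- array(0, dim = dim)
    vol[index_map$linear_index] <- vals
    vol
  }
  if (inherits(x, "feature_dataset")) {
    vols <- lapply(seq_len(nrow(x$values)),
                   function(s) place(x$values[s, ]))
    names(vols) <- x$subject_ids
    if (!is.null(paths)) {
      if (length(paths) != length(vols))
        stop("need one output path per subject")
      for (s in seq_along(vols))
        RNifti::writeNifti(RNifti::asNifti(vols[[s]]), paths[s])
    }
    vols
  } else {
    vol <- place(as.numeric(x))
    if (!is.null(paths))
      RNifti::writeNifti(RNifti::asNifti(vol), paths[1])
    vol
  }
}

as_volume <- function(x) {
  if (is.character(x)) x <- RNifti::readNifti(x)
  v <- unclass(as.array(x))
  if (length(dim(v)) != 3) stop("expected a 3-D volume")
  v
}

as_volume_list <- function(volumes) {
  if (is.character(volumes)) {
    nm <- if (!is.null(names(volumes))) names(volumes)
          else sub("\\.nii(\\.gz)?$", "", basename(volumes))
    vols <- lapply(volumes, as_volume)
    names(vols) <- nm
    return(vols)
  }
  if (is.array(volumes) && length(dim(volumes)) == 4) {
    n <- dim(volumes)[4]
    vols <- lapply(seq_len(n), function(s) volumes[, , , s])
    names(vols) <- paste0("s", seq_len(n))
    return(vols)
  }
  if (is.list(volumes)) {
    vols <- lapply(volumes, as_volume)
    if (is.null(names(vols))) names(vols) <- paste0("s", seq_along(vols))
    return(vols)
  }
  stop("volumes must be a list of 3-D arrays, a 4-D array, or file paths")
}
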