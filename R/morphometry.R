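#' Simple three-class tissue segmentation for phantoms
#'
#' Classifies intracranial voxels into CSF, grey matter and white matter.
#' `method = "kmeans"` clusters intensities with 3 centres and orders the
#' clusters by centre (CSF < GM < WM); `method = "threshold"` cuts at the
#' midpoints of supplied class means. Intended for phantoms with three
#' distinguishable intensity modes, not for real anatomy.
#'
#' @param volume A `brain_volume`.
#' @param atlas A `region_atlas` giving the intracranial extent (all
#'   non-background, non-MCP labels).
#' @param method `"kmeans"` or `"threshold"`.
#' @param class_means Numeric length-3 (CSF, GM, WM) for
#'   `method = "threshold"`.
#' @param min_separation Minimum distance between adjacent class centres,
#'   in units of the largest within-class SD; below it the intensity modes
#'   are deemed indistinguishable and segmentation fails.
#' @return Integer array: 0 outside the intracranial extent, 1 CSF, 2 GM,
#'   3 WM.
#' @export
segment_tissues_simple <- function(volume, atlas,
                                   method = c("kmeans", "threshold"),
                                   class_means = NULL, min_separation = 2) {
  method <- match.arg(method)
  stopifnot(inherits(volume, "brain_volume"), inherits(atlas, "region_atlas"))
  if (!identical(dim(volume$data), dim(atlas$labels)))
    stop("atlas/volume shape mismatch")
  lab <- atlas$label_table
  intracranial <- atlas$labels != lab[["background"]] &
    atlas$labels != lab[["mcp"]]
  v <- volume$data[intracranial]
  out <- array(0L, dim(volume$data))
  if (method == "kmeans") {
    if (length(unique(v)) < 3)
      stop("segmentation failure: fewer than 3 distinguishable intensity modes")
    km <- stats::kmeans(v, centers = 3, nstart = 5)
    ord <- order(km$centers)
    ctr <- sort(as.vector(km$centers))
    wss_sd <- sqrt(max(km$withinss / pmax(km$size - 1, 1)))
    if (min(diff(ctr)) < min_separation * max(wss_sd, .Machine$double.eps))
      stop("segmentation failure: fewer than 3 distinguishable intensity modes")
    cls <- match(km$cluster, ord)
  } else {
    if (is.null(class_means) || length(class_means) != 3)
      stop("method 'threshold' needs class_means of length 3 (CSF, GM, WM)")
    cm <- sort(class_means)
    cuts <- c(mean(cm[1:2]), mean(cm[2:3]))
    cls <- 1L + (v > cuts[1]) + (v > cuts[2])
  }
  out[intracranial] <- cls
  out
}

#' Tissue volumes and brain-atrophy ratio from a class map
#'
#' @param classmap Integer array from [segment_tissues_simple()].
#' @param atlas A `region_atlas` (for voxel geometry).
#' @return A `tissue_volumes` object, see [compute_ba()].
#' @export
tissue_volumes_from_classmap <- function(classmap, atlas) {
  vv_ml <- voxel_volume(atlas) / 1000
  cfv <- sum(classmap == 1L) * vv_ml
  tbv <- sum(classmap %in% c(2L, 3L)) * vv_ml
  compute_ba(tbv, cfv)
}

#' Brain-atrophy ratio from tissue volumes
#'
#' Intracranial volume is the sum of total brain volume and CSF volume;
#' the atrophy ratio is the CSF fraction of the intracranial volume,
#' equivalently `1 - TBV / ICV`.
#'
#' @param tbv Total brain volume in ml (> 0).
#' @param cfv Cerebrospinal-fluid volume in ml (>= 0).
#' @return Object of class `tissue_volumes`: `TBV`, `CFV`, `ICV`, `BA`.
#' @export
compute_ba <- function(tbv, cfv) {
  if (tbv <= 0) stop("invalid tissue volumes: TBV must be > 0")
  if (cfv < 0) stop("invalid tissue volumes: CFV must be >= 0")
  icv <- tbv + cfv
  structure(list(TBV = tbv, CFV = cfv, ICV = icv, BA = 1 - tbv / icv),
            class = "tissue_volumes")
}

#' @export
print.tissue_volumes <- function(x, ...) {
  cat(sprintf("TBV %.2f ml + CFV %.2f ml = ICV %.2f ml; brain atrophy %.4f\n",
              x$TBV, x$CFV, x$ICV, x$BA))
  invisible(x)
}
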