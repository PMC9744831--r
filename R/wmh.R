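#' Intensity-standardization parameters
#'
#' Captures the reference-region (middle cerebellar peduncle) intensity
#' moments and the standardization convention: intensities are mapped so
#' the reference region has mean `target_mean` (1000) and SD `target_sd`
#' (100), and lesions are segmented above `cutoff_sd` (3.5) reference SDs,
#' i.e. above the standardized threshold
#' `target_mean + cutoff_sd * target_sd` = 1350 at the defaults.
#'
#' @param mu_ref,sigma_ref Reference-region mean and SD; `sigma_ref` must
#'   be > 0.
#' @param target_mean,target_sd Standardized reference moments.
#' @param cutoff_sd Segmentation cut-off in reference SD units (> 0).
#' @return Object of class `normalization_params`.
#' @export
normalization_params <- function(mu_ref, sigma_ref, target_mean = 1000,
                                 target_sd = 100, cutoff_sd = 3.5) {
  if (sigma_ref <= 0) stop("sigma_ref must be > 0 (degenerate reference region)")
  if (cutoff_sd <= 0 || target_sd <= 0) stop("cutoff_sd and target_sd must be > 0")
  structure(list(mu_ref = mu_ref, sigma_ref = sigma_ref,
                 target_mean = target_mean, target_sd = target_sd,
                 cutoff_sd = cutoff_sd),
            class = "normalization_params")
}

#' Standardized segmentation threshold of a parameter set
#'
#' @param params A `normalization_params`.
#' @return `target_mean + cutoff_sd * target_sd`.
#' @export
wmh_threshold <- function(params) {
  params$target_mean + params$cutoff_sd * params$target_sd
}

#' Estimate the normal-white-matter intensity distribution from the MCP
#'
#' Plain mean and sample SD (n - 1 denominator) of the intensities inside
#' the middle-cerebellar-peduncle label, the region assumed free of
#' lesions. A trimmed variant (symmetric fraction `trim` per tail) is
#' available for robustness against edge voxels.
#'
#' @param volume A `brain_volume`.
#' @param atlas A `region_atlas` aligned to the volume.
#' @param min_voxels Minimum usable reference size (default 30).
#' @param trim Trimming fraction per tail in `[0, 0.5)`.
#' @return List with `mu_ref`, `sigma_ref`, `n_voxels`, `trim`. A zero
#'   `sigma_ref` is returned as-is; [normalization_params()] rejects it.
#' @export
estimate_reference_stats <- function(volume, atlas, min_voxels = 30, trim = 0) {
  stopifnot(inherits(volume, "brain_volume"), inherits(atlas, "region_atlas"))
  if (!identical(dim(volume$data), dim(atlas$labels)))
    stop("atlas/volume shape mismatch")
  v <- volume$data[atlas$labels == atlas$label_table[["mcp"]]]
  if (length(v) < min_voxels)
    stop("unusable reference region: MCP has ", length(v),
         " voxels (< ", min_voxels, ")")
  if (trim > 0) {
    if (trim >= 0.5) stop("trim must be in [0, 0.5)")
    q <- stats::quantile(v, c(trim, 1 - trim), names = FALSE)
    v <- v[v >= q[1] & v <= q[2]]
  }
  list(mu_ref = mean(v), sigma_ref = stats::sd(v),
       n_voxels = length(v), trim = trim)
}

#' Standardize intensities against the reference distribution
#'
#' Affine map `v' = target_mean + target_sd * (v - mu_ref) / sigma_ref`,
#' so the reference region acquires mean `target_mean` and SD `target_sd`.
#'
#' @param volume A `brain_volume`.
#' @param params A `normalization_params` (or the list returned by
#'   [estimate_reference_stats()], which is promoted with defaults).
#' @return Standardized `brain_volume`.
#' @export
standardize_intensities <- function(volume, params) {
  stopifnot(inherits(volume, "brain_volume"))
  if (!inherits(params, "normalization_params"))
    params <- normalization_params(params$mu_ref, params$sigma_ref)
  v <- params$target_mean +
    params$target_sd * (volume$data - params$mu_ref) / params$sigma_ref
  brain_volume(v, volume$spacing, volume$slice_thickness)
}

label_components <- function(mask) {
  idx <- which(mask)
  dims <- dim(mask)
  pos <- arrayInd(idx, dims)
  key <- (pos[, 3] - 1L) * (dims[1] * dims[2]) + (pos[, 2] - 1L) * dims[1] + pos[, 1]
  lut <- integer(0)
  lut[key] <- seq_along(idx)
  edges <- integer(0)
  for (off in list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))) {
    nb <- sweep(pos, 2, off, `+`)
    keep <- nb[, 1] <= dims[1] & nb[, 2] <= dims[2] & nb[, 3] <= dims[3]
    nbk <- (nb[keep, 3] - 1L) * (dims[1] * dims[2]) +
      (nb[keep, 2] - 1L) * dims[1] + nb[keep, 1]
    hit <- !is.na(lut[nbk]) & lut[nbk] > 0
    edges <- c(edges, rbind(which(keep)[hit], lut[nbk[hit]]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  igraph::components(g)$membership
}

#' Threshold-segment white-matter hyperintensities
#'
#' Voxels of a standardized volume strictly above
#' `target_mean + cutoff_sd * target_sd` (1350 at the defaults), restricted
#' to the lesion search region: the four lobar white-matter compartments
#' plus the four periventricular bands. The MCP and everything
#' infratentorial are excluded. Optionally drops 6-connected components
#' smaller than `min_component_size` voxels (default 0 = off).
#'
#' @param volume Standardized `brain_volume`.
#' @param atlas A `region_atlas`.
#' @param cutoff_sd Cut-off in reference SD units (default 3.5).
#' @param target_mean,target_sd Standardized reference moments.
#' @param min_component_size Minimum lesion component size in voxels.
#' @return Logical 3-D lesion mask.
#' @export
segment_wmh <- function(volume, atlas, cutoff_sd = 3.5, target_mean = 1000,
                        target_sd = 100, min_component_size = 0) {
  stopifnot(inherits(volume, "brain_volume"), inherits(atlas, "region_atlas"))
  if (!identical(dim(volume$data), dim(atlas$labels)))
    stop("atlas/volume shape mismatch")
  if (cutoff_sd <= 0) stop("cutoff_sd must be > 0")
  search <- atlas$labels %in% wmh_search_labels()
  if (!any(search)) stop("atlas lacks white-matter labels")
  mask <- (volume$data > target_mean + cutoff_sd * target_sd) & search
  if (min_component_size > 0 && any(mask)) {
    memb <- label_components(mask)
    small <- which(tabulate(memb) < min_component_size)
    mask[which(mask)[memb %in% small]] <- FALSE
  }
  mask
}

#' Parcellate a lesion mask and quantify volumes per region
#'
#' Per-region lesion volume = voxel count in region x (dx * dy * slice
#' thickness), converted to ml. The four periventricular bands are summed
#' into one periventricular figure; periventricular membership takes
#' precedence over lobar membership (the labels are disjoint by
#' construction, so no voxel is double-counted).
#'
#' @param mask Logical 3-D lesion mask on the atlas grid.
#' @param atlas A `region_atlas`.
#' @param params Optional `normalization_params` recorded as provenance.
#' @return Object of class `wmh_segmentation`: `mask`, `volumes_ml` (named:
#'   total, frontal, temporal, parietal, occipital, periventricular),
#'   `threshold_used`, `params`.
#' @export
parcellate_and_quantify <- function(mask, atlas, params = NULL) {
  stopifnot(inherits(atlas, "region_atlas"))
  if (!identical(dim(mask), dim(atlas$labels)))
    stop("atlas/mask shape mismatch")
  lab <- atlas$label_table
  vv_ml <- voxel_volume(atlas) / 1000
  cnt <- function(codes) sum(mask & (atlas$labels %in% codes))
  pv_codes <- lab[c("pv_ant_left", "pv_ant_right", "pv_post_left", "pv_post_right")]
  vols <- c(frontal = cnt(lab[["wm_frontal"]]),
            temporal = cnt(lab[["wm_temporal"]]),
            parietal = cnt(lab[["wm_parietal"]]),
            occipital = cnt(lab[["wm_occipital"]]),
            periventricular = cnt(pv_codes)) * vv_ml
  vols <- c(total = sum(vols), vols)
  structure(list(mask = mask, volumes_ml = vols,
                 threshold_used = if (is.null(params)) NA_real_ else wmh_threshold(params),
                 params = params),
            class = "wmh_segmentation")
}

#' @export
print.wmh_segmentation <- function(x, ...) {
  cat("wmh_segmentation: volumes (ml)\n")
  print(round(x$volumes_ml, 4))
  invisible(x)
}

#' Full leukoaraiosis volumetry pipeline on one volume
#'
#' Bias-field correction (polynomial log-domain fit over the lesion search
#' region plus MCP), MCP reference estimation, intensity standardization,
#' threshold segmentation and regional quantification.
#'
#' @param volume A `brain_volume`.
#' @param atlas A `region_atlas`.
#' @param cutoff_sd Cut-off in reference SD units.
#' @param bias_order Polynomial order of the bias correction; `NULL` skips
#'   correction.
#' @param min_component_size Passed to [segment_wmh()].
#' @param trim Passed to [estimate_reference_stats()].
#' @return `wmh_segmentation` with provenance `params` attached.
#' @export
quantify_wmh <- function(volume, atlas, cutoff_sd = 3.5, bias_order = 2,
                         min_component_size = 0, trim = 0) {
  if (!is.null(bias_order)) {
    fitmask <- array(atlas$labels %in% c(wmh_search_labels(),
                                         atlas$label_table[["mcp"]]),
                     dim(atlas$labels))
    shift <- 0
    if (any(volume$data[fitmask] <= 0)) {
      # log-domain fit needs positive intensities; lift by a constant
      shift <- abs(min(volume$data[fitmask])) + 1e-6
      volume <- brain_volume(volume$data + shift, volume$spacing,
                             volume$slice_thickness)
    }
    bf <- estimate_bias_field(volume, fitmask, order = bias_order)
    volume <- correct_inhomogeneity(volume, bf)
    if (shift > 0)
      volume <- brain_volume(volume$data - shift, volume$spacing,
                             volume$slice_thickness)
  }
  ref <- estimate_reference_stats(volume, atlas, trim = trim)
  params <- normalization_params(ref$mu_ref, ref$sigma_ref, cutoff_sd = cutoff_sd)
  std <- standardize_intensities(volume, params)
  mask <- segment_wmh(std, atlas, cutoff_sd = cutoff_sd,
                      target_mean = params$target_mean,
                      target_sd = params$target_sd,
                      min_component_size = min_component_size)
  parcellate_and_quantify(mask, atlas, params = params)
}
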