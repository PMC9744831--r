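#' Region labels used by the phantom atlas
#'
#' Integer codes for the twelve region labels of a [region_atlas]:
#' background, CSF, grey matter, four lobar white-matter compartments,
#' four periventricular bands (one per lateral-ventricle horn) and the
#' middle cerebellar peduncle (MCP) reference region.
#'
#' @return Named integer vector mapping region name to label code.
#' @export
atlas_labels <- function() {
  c(background    = 0L,
    csf           = 1L,
    gm            = 2L,
    wm_frontal    = 3L,
    wm_temporal   = 4L,
    wm_parietal   = 5L,
    wm_occipital  = 6L,
    pv_ant_left   = 7L,
    pv_ant_right  = 8L,
    pv_post_left  = 9L,
    pv_post_right = 10L,
    mcp           = 11L)
}

#' Lobar white-matter and periventricular label codes
#'
#' The lesion search region for white-matter hyperintensity segmentation:
#' cerebral white matter of the four lobes plus the four periventricular
#' bands. The MCP and everything infratentorial are excluded.
#'
#' @return Integer vector of label codes.
#' @export
wmh_search_labels <- function() {
  lab <- atlas_labels()
  unname(lab[c("wm_frontal", "wm_temporal", "wm_parietal", "wm_occipital",
               "pv_ant_left", "pv_ant_right", "pv_post_left", "pv_post_right")])
}

#' Build a deterministic layered head phantom atlas
#'
#' Constructs a per-voxel integer label grid with concentric in-plane
#' shells (CSF rim, grey-matter shell, white-matter interior), a central
#' CSF ventricle box surrounded by four quadrant periventricular bands,
#' white matter split into four angular lobar sectors (anterior = frontal,
#' posterior = occipital, left = temporal, right = parietal), and an
#' inferior middle-cerebellar-peduncle block on the lowest slices,
#' spatially disjoint from all cerebral labels.
#'
#' @param shape Integer vector (nx, ny, nz), each at least (16, 16, 8).
#' @param spacing In-plane voxel spacing (dx, dy) in mm.
#' @param slice_thickness Slice thickness in mm.
#' @return An object of class `region_atlas`: list with elements `labels`
#'   (3-D integer array), `label_table` (named integer vector),
#'   `spacing`, `slice_thickness`.
#' @examples
#' atl <- make_atlas(c(32, 32, 12))
#' table(atl$labels)
#' @export
make_atlas <- function(shape = c(64L, 64L, 27L),
                       spacing = c(0.9375, 0.9375),
                       slice_thickness = 5) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < c(16L, 16L, 8L)))
    stop("invalid geometry: shape must be at least (16, 16, 8)")
  if (length(spacing) != 2L || any(spacing <= 0) || slice_thickness <= 0)
    stop("spacing and slice_thickness must be positive")
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  lab <- atlas_labels()
  labels <- array(lab[["background"]], dim = shape)

  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  rx <- (nx - 1) / 2; ry <- (ny - 1) / 2
  ii <- matrix(seq_len(nx), nx, ny)
  jj <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  rho <- sqrt(((ii - cx) / rx)^2 + ((jj - cy) / ry)^2)

  # inferior MCP slab: central block labelled MCP, rest background
  n_mcp <- max(1L, nz %/% 8L)
  mx <- max(2L, round(nx / 5)); my <- max(2L, round(ny / 5))
  mcp_plane <- abs(ii - cx) <= mx / 2 & abs(jj - cy) <= my / 2
  for (k in seq_len(n_mcp)) {
    sl <- labels[, , k]
    sl[mcp_plane] <- lab[["mcp"]]
    labels[, , k] <- sl
  }

  # cerebral slices: concentric shells + ventricle + PV bands + lobar WM
  vx <- max(1L, round(nx * 0.06)); vy <- max(1L, round(ny * 0.12))
  vent <- abs(ii - cx) <= vx & abs(jj - cy) <= vy
  pv_shell <- (abs(ii - cx) <= vx + 1 & abs(jj - cy) <= vy + 1) & !vent
  dx_ <- ii - cx; dy_ <- jj - cy

  plane <- matrix(lab[["background"]], nx, ny)
  plane[rho <= 1] <- lab[["csf"]]
  plane[rho <= 0.92] <- lab[["gm"]]
  wm <- rho <= 0.78
  # angular lobar sectors within WM
  plane[wm & (-dy_ >= abs(dx_))] <- lab[["wm_frontal"]]
  plane[wm & (dy_ >= abs(dx_))]  <- lab[["wm_occipital"]]
  plane[wm & (abs(dx_) > abs(dy_)) & dx_ < 0] <- lab[["wm_temporal"]]
  plane[wm & (abs(dx_) > abs(dy_)) & dx_ > 0] <- lab[["wm_parietal"]]
  # periventricular quadrant bands then the ventricle itself
  pv <- pv_shell & wm
  plane[pv & dx_ <= 0 & dy_ <= 0] <- lab[["pv_ant_left"]]
  plane[pv & dx_ >  0 & dy_ <= 0] <- lab[["pv_ant_right"]]
  plane[pv & dx_ <= 0 & dy_ >  0] <- lab[["pv_post_left"]]
  plane[pv & dx_ >  0 & dy_ >  0] <- lab[["pv_post_right"]]
  plane[vent & wm] <- lab[["csf"]]

  for (k in (n_mcp + 1L):nz) labels[, , k] <- plane

  missing <- setdiff(names(lab), names(lab)[lab %in% unique(as.vector(labels))])
  if (length(missing))
    stop("invalid geometry: shape too small to host region(s): ",
         paste(missing, collapse = ", "))

  structure(list(labels = labels, label_table = lab,
                 spacing = as.numeric(spacing),
                 slice_thickness = as.numeric(slice_thickness)),
            class = "region_atlas")
}

#' Voxel volume of an atlas or brain volume, in cubic millimetres
#'
#' @param x A `region_atlas` or `brain_volume`.
#' @return dx * dy * slice thickness in mm^3.
#' @export
voxel_volume <- function(x) {
  prod(x$spacing) * x$slice_thickness
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("region_atlas:", paste(dim(x$labels), collapse = " x "),
      "voxels,", format(voxel_volume(x), digits = 6), "mm^3/voxel\n")
  tab <- table(factor(as.vector(x$labels), levels = x$label_table,
                      labels = names(x$label_table)))
  print(tab)
  invisible(x)
}
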