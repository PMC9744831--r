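# shared fixtures built in code

small_atlas <- function() make_atlas(c(32L, 32L, 12L))

study_atlas <- function() make_atlas(c(64L, 64L, 27L))

# deterministic lesion centre well inside a lobar WM sector:
# `offset` voxels from the grid centre along the lobe axis, clear of the
# periventricular bands and the grey-matter shell
lobe_center <- function(atlas, region, offset = 12, k = NULL) {
  dims <- dim(atlas$labels)
  cx <- (dims[1] + 1) / 2; cy <- (dims[2] + 1) / 2
  k <- k %||% round(dims[3] * 0.6)
  switch(region,
         wm_frontal   = c(cx, cy - offset, k),
         wm_occipital = c(cx, cy + offset, k),
         wm_temporal  = c(cx - offset, cy, k),
         wm_parietal  = c(cx + offset, cy, k),
         stop("no lobe centre rule for ", region))
}

# brute-force voxel-centre-in-sphere oracle, independent of rasterize_lesion
brute_force_sphere_count <- function(center, radius, dims, spacing, dz) {
  cnt <- 0L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    d2 <- ((i - center[1]) * spacing[1])^2 + ((j - center[2]) * spacing[2])^2 +
      ((k - center[3]) * dz)^2
    if (d2 <= radius^2) cnt <- cnt + 1L
  }
  cnt
}

# voxels of a mask with at least one 6-neighbour outside the mask
surface_voxel_count <- function(mask) {
  dims <- dim(mask)
  pos <- which(mask, arr.ind = TRUE)
  surf <- 0L
  for (r in seq_len(nrow(pos))) {
    i <- pos[r, 1]; j <- pos[r, 2]; k <- pos[r, 3]
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    out <- apply(nb, 1, function(v)
      any(v < 1) || v[1] > dims[1] || v[2] > dims[2] || v[3] > dims[3] ||
        !mask[v[1], v[2], v[3]])
    if (any(out)) surf <- surf + 1L
  }
  surf
}

# a complete all-`score` DSP assessment
flat_assessment <- function(score = 3) {
  cats <- dsp_categories()
  do.call(rbind, lapply(names(cats), function(loc)
    data.frame(location = loc, category = cats[[loc]], score = score)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
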