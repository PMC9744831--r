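#' Construct a brain volume container
#'
#' A minimal 3-D scalar volume with voxel geometry: in-plane spacing in mm
#' and slice thickness in mm.
#'
#' @param data 3-D numeric array.
#' @param spacing In-plane spacing (dx, dy) in mm.
#' @param slice_thickness Slice thickness in mm.
#' @return An object of class `brain_volume`.
#' @export
brain_volume <- function(data, spacing = c(0.9375, 0.9375), slice_thickness = 5) {
  if (length(dim(data)) != 3L) stop("data must be a 3-D array")
  if (any(spacing <= 0) || slice_thickness <= 0)
    stop("spacing and slice_thickness must be positive")
  structure(list(data = data, spacing = as.numeric(spacing),
                 slice_thickness = as.numeric(slice_thickness)),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat("brain_volume:", paste(dim(x$data), collapse = " x "), "voxels, spacing",
      paste(x$spacing, collapse = " x "), "mm, slice", x$slice_thickness, "mm\n")
  cat("intensity range:", paste(format(range(x$data), digits = 6), collapse = " .. "), "\n")
  invisible(x)
}

#' Specify a spherical hyperintense lesion
#'
#' @param region Target region name (a lobar WM or periventricular label of
#'   [atlas_labels()]).
#' @param center Voxel coordinates (i, j, k) of the lesion centre.
#' @param radius Lesion radius in mm.
#' @param contrast Intensity elevation in units of the normal-white-matter
#'   SD of the generator; must be positive.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(region, center, radius, contrast) {
  if (contrast <= 0) stop("lesion contrast must be positive")
  if (radius <= 0) stop("lesion radius must be positive")
  ok <- names(atlas_labels())
  if (!region %in% ok) stop("unknown region: ", region)
  structure(list(region = region, center = as.numeric(center),
                 radius = as.numeric(radius), contrast = as.numeric(contrast)),
            class = "lesion_spec")
}

#' Rasterize a spherical lesion onto an atlas grid
#'
#' A voxel belongs to the lesion when its centre lies within `radius` mm of
#' the lesion centre, in physical coordinates (anisotropic slice thickness
#' respected). This voxel-centre rule is also the ground-truth volume
#' definition: true volume = voxel count x voxel volume.
#'
#' @param lesion A [lesion_spec()].
#' @param atlas A `region_atlas`.
#' @return Logical 3-D array.
#' @export
rasterize_lesion <- function(lesion, atlas) {
  dims <- dim(atlas$labels)
  dx <- atlas$spacing[1]; dy <- atlas$spacing[2]; dz <- atlas$slice_thickness
  ci <- lesion$center[1]; cj <- lesion$center[2]; ck <- lesion$center[3]
  r <- lesion$radius
  # bounding box keeps this cheap on large grids
  irng <- max(1L, floor(ci - r / dx)):min(dims[1], ceiling(ci + r / dx))
  jrng <- max(1L, floor(cj - r / dy)):min(dims[2], ceiling(cj + r / dy))
  krng <- max(1L, floor(ck - r / dz)):min(dims[3], ceiling(ck + r / dz))
  mask <- array(FALSE, dims)
  d2 <- outer(((irng - ci) * dx)^2,
              outer(((jrng - cj) * dy)^2, ((krng - ck) * dz)^2, `+`), `+`)
  mask[irng, jrng, krng] <- d2 <= r^2
  mask
}

# smooth quadratic multiplicative bias with max |deviation from 1| = amplitude
make_bias_field <- function(dims, amplitude, seed = NULL) {
  if (amplitude == 0) return(array(1, dims))
  co <- with_seed_opt(seed, stats::rnorm(9))
  x <- seq(-1, 1, length.out = dims[1])
  y <- seq(-1, 1, length.out = dims[2])
  z <- seq(-1, 1, length.out = dims[3])
  f <- outer(co[1] * x + co[4] * x^2,
             outer(co[2] * y + co[5] * y^2, co[3] * z + co[6] * z^2, `+`), `+`) +
    outer(co[7] * x, outer(co[8] * y, co[9] * z, `+`), `+`)
  1 + amplitude * f / max(abs(f))
}

#' Simulate a FLAIR-like phantom with known lesion ground truth
#'
#' Tissue classes get constant base intensities (CSF 100, GM 300, white
#' matter / periventricular bands / MCP a common `wm_mean`); lesion voxels
#' are elevated by `contrast * wm_sd` before a smooth multiplicative
#' quadratic bias field and additive Gaussian noise are applied. The
#' returned truth is the rasterized lesion mask quantified per region.
#'
#' @param atlas A `region_atlas`.
#' @param lesions List of [lesion_spec()] objects. Lesion centres must lie
#'   in their declared region; lesions touching the MCP reference region
#'   are refused because they would corrupt the reference distribution.
#' @param wm_mean,wm_sd Normal-white-matter mean intensity and the SD unit
#'   in which lesion contrast is expressed.
#' @param bias_amplitude Maximum fractional deviation of the multiplicative
#'   bias field from 1.
#' @param noise_sd SD of additive Gaussian scanner noise (>= 0).
#' @param seed Integer seed; fixed seed gives a bit-identical phantom.
#' @return List with `volume` (`brain_volume`), `truth`
#'   (`wmh_segmentation` built from the rasterized lesions), and
#'   `bias_field` (the multiplicative field actually applied).
#' @export
simulate_flair <- function(atlas, lesions = list(), wm_mean = 500, wm_sd = 50,
                           bias_amplitude = 0, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(atlas, "region_atlas"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stop("bias_amplitude must be in [0, 1)")
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  lab <- atlas$label_table
  dims <- dim(atlas$labels)

  base <- array(0, dims)
  base[atlas$labels == lab[["csf"]]] <- 100
  base[atlas$labels == lab[["gm"]]] <- 300
  wm_like <- atlas$labels %in% c(lab[["wm_frontal"]], lab[["wm_temporal"]],
                                 lab[["wm_parietal"]], lab[["wm_occipital"]],
                                 lab[["pv_ant_left"]], lab[["pv_ant_right"]],
                                 lab[["pv_post_left"]], lab[["pv_post_right"]],
                                 lab[["mcp"]])
  base[wm_like] <- wm_mean

  truth_mask <- array(FALSE, dims)
  for (les in lesions) {
    stopifnot(inherits(les, "lesion_spec"))
    ctr <- round(les$center)
    got <- atlas$labels[ctr[1], ctr[2], ctr[3]]
    if (got != lab[[les$region]])
      stop("lesion centre is not inside its declared region '", les$region,
           "' (found label ", got, ")")
    m <- rasterize_lesion(les, atlas)
    if (any(m & atlas$labels == lab[["mcp"]]))
      stop("lesion overlaps the MCP reference region; refused")
    base[m] <- base[m] + les$contrast * wm_sd
    truth_mask <- truth_mask | m
  }

  bias <- make_bias_field(dims, bias_amplitude,
                          seed = if (is.null(seed)) NULL else seed + 1L)
  vol <- base * bias
  if (noise_sd > 0)
    vol <- vol + with_seed_opt(seed, stats::rnorm(length(vol), 0, noise_sd))

  volume <- brain_volume(vol, atlas$spacing, atlas$slice_thickness)
  truth <- parcellate_and_quantify(truth_mask, atlas)
  list(volume = volume, truth = truth, bias_field = bias)
}

#' Cohort simulation specification
#'
#' @param n Number of participants.
#' @param corr Symmetric correlation matrix with unit diagonal over named
#'   variables; defaults to the packaged printed correlation table. If the
#'   matrix is indefinite (as 2-dp printed rounding can make it), the
#'   nearest positive-semidefinite correlation matrix (eigenvalue floor
#'   1e-6) is substituted and flagged.
#' @param means,sds Named per-variable means and SDs; defaults from the
#'   packaged descriptive tables. All SDs must be > 0.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 101, corr = NULL, means = NULL, sds = NULL,
                        seed = NULL) {
  tabs <- printed_tables()
  if (is.null(corr)) corr <- tabs$corr
  if (is.null(means)) means <- tabs$means
  if (is.null(sds)) sds <- tabs$sds
  vars <- colnames(corr)
  if (is.null(vars)) stop("corr must have variable names")
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-10)))
    stop("corr must be symmetric")
  if (any(abs(diag(corr) - 1) > 1e-10)) stop("corr must have unit diagonal")
  means <- means[vars]; sds <- sds[vars]
  if (anyNA(means) || anyNA(sds)) stop("means/sds missing for some variables")
  if (any(sds <= 0)) stop("all sds must be > 0: ",
                          paste(vars[sds <= 0], collapse = ", "))
  repaired <- FALSE
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6) {
    np <- Matrix::nearPD(corr, corr = TRUE, eig.tol = 1e-10,
                         posd.tol = 1e-6, keepDiag = TRUE)
    if (!np$converged) stop("correlation matrix indefinite beyond repair")
    corr <- as.matrix(np$mat)
    dimnames(corr) <- list(vars, vars)
    repaired <- TRUE
  }
  structure(list(n = as.integer(n), corr = corr, means = means, sds = sds,
                 seed = seed, psd_repaired = repaired),
            class = "cohort_spec")
}

#' Draw a cohort table from a multivariate normal
#'
#' Rows are drawn from N(means, D R D) where R is the (repaired)
#' correlation matrix and D = diag(sds). With `integer_dsp = TRUE` the
#' six per-location driving-safety scores and their total are rounded
#' half-away-from-zero and clipped to their legal ranges (P1 3-9; P2 and
#' P6 4-12; P3-P5 2-6; total 17-51).
#'
#' @param spec A [cohort_spec()].
#' @param integer_dsp Integerize DSP columns.
#' @return `data.frame` with one column per variable; attribute
#'   `psd_repaired` records whether the correlation target was projected.
#' @export
simulate_cohort <- function(spec, integer_dsp = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  sigma <- corr_to_cov(spec$corr, spec$sds)
  x <- with_seed_opt(spec$seed,
                        MASS::mvrnorm(spec$n, mu = spec$means, Sigma = sigma))
  df <- as.data.frame(x)
  if (integer_dsp) {
    lims <- dsp_score_ranges()
    for (v in names(lims)) {
      if (!v %in% names(df)) next
      df[[v]] <- pmin(pmax(round_half_away(df[[v]]), lims[[v]][1]), lims[[v]][2])
    }
  }
  attr(df, "psd_repaired") <- spec$psd_repaired
  df
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Simulate one dynamic-visual-cognition task session
#'
#' Signal trials (closed octagon) are pressed with probability `hit_rate`;
#' noise trials (open octagon) are pressed with probability
#' `false_alarm_rate`. Trial order is shuffled by the seed.
#'
#' @param n_signal,n_noise Trial counts (non-negative).
#' @param hit_rate,false_alarm_rate Response probabilities in `[0, 1]`.
#' @param task `"tracking"` or `"sudden"`.
#' @param seed Integer seed.
#' @return `data.frame` of class `dvc_session` with columns `task`,
#'   `stimulus` (`"signal"`/`"noise"`), `pressed` (logical).
#' @export
simulate_dvc_session <- function(n_signal, n_noise, hit_rate, false_alarm_rate,
                                 task = c("sudden", "tracking"), seed = NULL) {
  task <- match.arg(task)
  if (n_signal < 0 || n_noise < 0) stop("trial counts must be non-negative")
  if (any(c(hit_rate, false_alarm_rate) < 0) ||
      any(c(hit_rate, false_alarm_rate) > 1))
    stop("rates must lie in [0, 1]")
  df <- with_seed_opt(seed, {
    pressed <- c(stats::runif(n_signal) < hit_rate,
                 stats::runif(n_noise) < false_alarm_rate)
    d <- data.frame(task = task,
                    stimulus = rep(c("signal", "noise"), c(n_signal, n_noise)),
                    pressed = pressed, stringsAsFactors = FALSE)
    d[sample.int(nrow(d)), , drop = FALSE]
  })
  rownames(df) <- NULL
  class(df) <- c("dvc_session", "data.frame")
  df
}
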