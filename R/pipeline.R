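#' Write a brain volume or label grid as NIfTI-1
#'
#' @param x A `brain_volume`, `region_atlas`, or 3-D array.
#' @param path Output path (`.nii` or `.nii.gz`). For a `region_atlas` the
#'   label table is written to a JSON sidecar `<path>.labels.json`.
#' @param spacing,slice_thickness Geometry when `x` is a plain array.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path, spacing = c(0.9375, 0.9375),
                               slice_thickness = 5) {
  if (inherits(x, "brain_volume")) {
    arr <- x$data; spacing <- x$spacing; slice_thickness <- x$slice_thickness
  } else if (inherits(x, "region_atlas")) {
    arr <- x$labels; spacing <- x$spacing; slice_thickness <- x$slice_thickness
    jsonlite::write_json(as.list(x$label_table), paste0(path, ".labels.json"),
                         auto_unbox = TRUE)
  } else arr <- x
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(spacing, slice_thickness)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a brain_volume
#'
#' @param path NIfTI file path.
#' @return A `brain_volume`.
#' @export
read_nifti_volume <- function(path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  pd <- RNifti::pixdim(img)
  brain_volume(array(as.numeric(img), dim = dim(img)),
               spacing = pd[1:2], slice_thickness = pd[3])
}

#' Read a NIfTI label map (plus its JSON sidecar) as a region_atlas
#'
#' @param path NIfTI file written by [write_nifti_volume()] from a
#'   `region_atlas`.
#' @return A `region_atlas`.
#' @export
read_nifti_atlas <- function(path) {
  vol <- read_nifti_volume(path)
  side <- paste0(path, ".labels.json")
  lab <- if (file.exists(side))
    unlist(jsonlite::read_json(side)) else atlas_labels()
  structure(list(labels = array(as.integer(round(vol$data)), dim(vol$data)),
                 label_table = stats::setNames(as.integer(lab), names(lab)),
                 spacing = vol$spacing, slice_thickness = vol$slice_thickness),
            class = "region_atlas")
}

provenance <- function(seed, extra = list()) {
  c(list(package = "ladrive",
         version = as.character(utils::packageVersion("ladrive")),
         seed = seed, timestamp = format(Sys.time(), tz = "UTC")), extra)
}

#' Simulate phantom volumes and a cohort table to disk
#'
#' Writes the atlas, one FLAIR-like phantom per requested lesion setting
#' (plus its ground-truth mask), a cohort CSV with the 17 analysis
#' variables, and a provenance JSON. Reruns with the same seed are
#' byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param shape,spacing,slice_thickness Atlas geometry.
#' @param lesions List of [lesion_spec()] for the phantom.
#' @param bias_amplitude,noise_sd Passed to [simulate_flair()].
#' @param integer_dsp Passed to [simulate_cohort()].
#' @return Named list of written paths, invisibly.
#' @export
cli_simulate <- function(out_dir, n = 101, seed = 1, shape = c(64L, 64L, 27L),
                         spacing = c(0.9375, 0.9375), slice_thickness = 5,
                         lesions = list(), bias_amplitude = 0.1,
                         noise_sd = 15, integer_dsp = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  atl <- make_atlas(shape, spacing, slice_thickness)
  sim <- simulate_flair(atl, lesions, bias_amplitude = bias_amplitude,
                        noise_sd = noise_sd, seed = seed)
  cs <- cohort_spec(n = n, seed = seed)
  cohort <- simulate_cohort(cs, integer_dsp = integer_dsp)
  paths <- list(atlas = file.path(out_dir, "atlas.nii.gz"),
                flair = file.path(out_dir, "flair.nii.gz"),
                truth_mask = file.path(out_dir, "truth_mask.nii.gz"),
                cohort = file.path(out_dir, "cohort.csv"),
                truth = file.path(out_dir, "truth.json"),
                provenance = file.path(out_dir, "provenance.json"))
  write_nifti_volume(atl, paths$atlas)
  write_nifti_volume(sim$volume, paths$flair)
  write_nifti_volume(array(as.integer(sim$truth$mask), dim(sim$truth$mask)),
                     paths$truth_mask, spacing, slice_thickness)
  utils::write.csv(cohort, paths$cohort, row.names = FALSE)
  jsonlite::write_json(list(volumes_ml = as.list(sim$truth$volumes_ml),
                            lesions = lapply(lesions, unclass)),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(provenance(seed, list(
    n = n, shape = shape, spacing = spacing,
    slice_thickness = slice_thickness, bias_amplitude = bias_amplitude,
    noise_sd = noise_sd, psd_repaired = attr(cohort, "psd_repaired"))),
    paths$provenance, auto_unbox = TRUE)
  invisible(paths)
}

#' Quantify leukoaraiosis volumes for a set of volumes
#'
#' Runs bias correction, reference standardization, threshold segmentation
#' and parcellation per subject. A subject whose reference region is
#' unusable is skipped with a logged reason rather than aborting the run.
#'
#' @param volume_paths Named character vector of NIfTI paths (names become
#'   subject ids; unnamed paths get basenames).
#' @param atlas_path NIfTI label map path (written by [cli_simulate()]).
#' @param out_dir Output directory.
#' @param cutoff_sd,bias_order,min_component_size Passed to
#'   [quantify_wmh()].
#' @param write_masks Write each lesion mask as NIfTI.
#' @return `data.frame` of per-subject volumes (also written to
#'   `volumetry.csv`), with skipped subjects absent; the provenance JSON
#'   records per-subject reference stats and skip reasons.
#' @export
cli_quantify <- function(volume_paths, atlas_path, out_dir, cutoff_sd = 3.5,
                         bias_order = 2, min_component_size = 0,
                         write_masks = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  atl <- read_nifti_atlas(atlas_path)
  ids <- names(volume_paths) %||% basename(volume_paths)
  if (is.null(names(volume_paths))) ids <- basename(volume_paths)
  rows <- list(); refs <- list(); skipped <- list()
  for (i in seq_along(volume_paths)) {
    id <- ids[i]
    res <- tryCatch({
      vol <- read_nifti_volume(volume_paths[i])
      seg <- quantify_wmh(vol, atl, cutoff_sd = cutoff_sd,
                          bias_order = bias_order,
                          min_component_size = min_component_size)
      if (write_masks)
        write_nifti_volume(array(as.integer(seg$mask), dim(seg$mask)),
                           file.path(out_dir, paste0(id, "_mask.nii.gz")),
                           atl$spacing, atl$slice_thickness)
      seg
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[id]] <- conditionMessage(res)
      message("skipping subject ", id, ": ", conditionMessage(res))
      next
    }
    rows[[id]] <- data.frame(id = id, t(res$volumes_ml))
    refs[[id]] <- list(mu_ref = res$params$mu_ref,
                       sigma_ref = res$params$sigma_ref,
                       threshold = res$threshold_used)
  }
  volumetry <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0))
  rownames(volumetry) <- NULL
  utils::write.csv(volumetry, file.path(out_dir, "volumetry.csv"),
                   row.names = FALSE)
  jsonlite::write_json(provenance(NULL, list(
    cutoff_sd = cutoff_sd, bias_order = bias_order,
    spacing = atl$spacing, slice_thickness = atl$slice_thickness,
    reference_stats = refs, skipped = skipped)),
    file.path(out_dir, "quantify_provenance.json"),
    auto_unbox = TRUE, digits = NA)
  volumetry
}

#' Run the statistical stage and write the report
#'
#' @param cohort_csv Path to a cohort CSV with the 17 analysis variables,
#'   or `NULL` with `from_printed_tables = TRUE` to analyse the packaged
#'   printed tables.
#' @param out_dir Output directory; `report.json` and `report.txt` are
#'   written there.
#' @param from_printed_tables Use the printed correlation/SD tables.
#' @param model A [path_model_spec()].
#' @return The `la_report`, invisibly.
#' @export
cli_analyze <- function(cohort_csv = NULL, out_dir,
                        from_printed_tables = is.null(cohort_csv),
                        model = default_path_model()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- NULL
  if (!from_printed_tables) {
    if (is.null(cohort_csv)) stop("cohort_csv required unless from_printed_tables")
    cohort <- utils::read.csv(cohort_csv)
  }
  rep <- run_paper_analyses(cohort, model = model)
  reg_json <- function(m)
    list(beta = as.list(m$beta), R2 = m$R2, adjR2 = m$adjR2, F = m$F,
         df1 = m$df1, df2 = m$df2, p = m$p_value)
  pf <- rep$path_fit
  jsonlite::write_json(list(
    source = rep$source, n = rep$correlations$n,
    correlations = as.data.frame(rep$correlations$r),
    dsp_regressions = lapply(rep$dsp_regressions, reg_json),
    dvc_regressions = lapply(rep$dvc_regressions, reg_json),
    path_model = list(estimates = pf$estimates,
                      fit = unclass(pf$fit))),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  txt <- utils::capture.output(print(rep))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(rep)
}
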