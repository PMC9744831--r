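#' Variable names of the published analysis, in table order
#'
#' The 17 analysis variables: age, the six per-location driving-safety
#' scores and their total, the two dynamic-visual-cognition task scores,
#' the brain-atrophy ratio, and the five regional plus total leukoaraiosis
#' volumes.
#'
#' @return Character vector of length 17.
#' @export
analysis_variables <- function() {
  c("age", "dsp_p1", "dsp_p2", "dsp_p3", "dsp_p4", "dsp_p5", "dsp_p6",
    "dsp_total", "dvc_tracking", "dvc_sudden", "brain_atrophy",
    "la_frontal", "la_temporal", "la_parietal", "la_occipital",
    "la_periventricular", "la_total")
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "ladrive")
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)
  if (!file.exists(path)) stop("packaged fixture not found: ", file)
  path
}

#' Published descriptive and correlation tables
#'
#' Loads the packaged fixtures transcribing the study's printed descriptive
#' statistics (means, SDs, ranges of the brain-structure, visual-cognition
#' and driving-score variables; n = 101) and the full univariate
#' correlation matrix of all 17 variables.
#'
#' @return List with `means` and `sds` (named vectors over
#'   [analysis_variables()]), `ranges` (data.frame), `corr` (17 x 17
#'   matrix) and `n` (101).
#' @export
printed_tables <- function() {
  t1 <- utils::read.csv(extdata("table1_means_sds.csv"))
  t2 <- utils::read.csv(extdata("table2_means_sds.csv"))
  desc <- rbind(t1, t2)
  c3 <- utils::read.csv(extdata("table3_correlations.csv"), check.names = FALSE)
  corr <- as.matrix(c3[, -1])
  rownames(corr) <- c3$variable
  storage.mode(corr) <- "double"
  vars <- analysis_variables()
  stopifnot(identical(sort(colnames(corr)), sort(vars)),
            identical(sort(desc$variable), sort(vars)))
  corr <- corr[vars, vars]
  means <- stats::setNames(desc$mean, desc$variable)[vars]
  sds <- stats::setNames(desc$sd, desc$variable)[vars]
  list(means = means, sds = sds, ranges = desc, corr = corr, n = 101L)
}

#' Covariance matrix assembled from the printed tables
#'
#' Combines the printed pairwise correlations with the printed per-variable
#' standard deviations into a covariance matrix, the input to the
#' path-model and regression stages when no raw cohort is available.
#'
#' @param variables Optional subset (and ordering) of
#'   [analysis_variables()].
#' @return Covariance matrix with `n` attribute 101.
#' @export
printed_covariance <- function(variables = NULL) {
  tabs <- printed_tables()
  v <- variables %||% analysis_variables()
  stopifnot(all(v %in% analysis_variables()))
  s <- corr_to_cov(tabs$corr[v, v, drop = FALSE], tabs$sds[v])
  attr(s, "n") <- tabs$n
  s
}
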