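#' Rating categories assessed at each driving-course location
#'
#' The six locations are P1 changing lanes while driving straight, P2
#' turning right at an intersection, P3 straight course, P4 turning left at
#' an intersection with a stop sign, P5 large curve with poor visibility,
#' and P6 turning left at an intersection. Each listed category is rated on
#' a three-point scale (1 poor, 2 normal, 3 excellent).
#'
#' @return Named list: location -> character vector of categories.
#' @export
dsp_categories <- function() {
  list(P1 = c("signalling", "searching", "steering"),
       P2 = c("searching", "speeding", "signalling", "positioning"),
       P3 = c("searching", "speeding"),
       P4 = c("searching", "stability"),
       P5 = c("searching", "speeding"),
       P6 = c("searching", "speeding", "signalling", "positioning"))
}

#' Legal ranges of the per-location and total driving-safety scores
#'
#' Each location score is the sum of its category ratings, so its range is
#' (number of categories) x 1 .. x 3; the total ranges 17-51.
#'
#' @return Named list of `c(min, max)` over `dsp_p1..dsp_p6, dsp_total`.
#' @export
dsp_score_ranges <- function() {
  k <- vapply(dsp_categories(), length, integer(1))
  out <- lapply(k, function(m) c(m * 1, m * 3))
  names(out) <- paste0("dsp_p", 1:6)
  out$dsp_total <- c(sum(k), 3 * sum(k))
  out
}

#' Validate a driving-safety-performance assessment
#'
#' @param ratings `data.frame` with columns `location` (P1..P6), `category`
#'   and `score` (integer 1-3), containing exactly the category set of
#'   [dsp_categories()] for every location.
#' @return The validated data.frame, class `dsp_assessment`.
#' @export
dsp_assessment <- function(ratings) {
  need <- c("location", "category", "score")
  if (!all(need %in% names(ratings)))
    stop("assessment must have columns: ", paste(need, collapse = ", "))
  cats <- dsp_categories()
  for (loc in names(cats)) {
    got <- ratings$category[ratings$location == loc]
    miss <- setdiff(cats[[loc]], got)
    if (length(miss))
      stop("validation failure at ", loc, ": missing category ",
           paste(miss, collapse = ", "))
    extra <- setdiff(got, cats[[loc]])
    if (length(extra) || anyDuplicated(got))
      stop("validation failure at ", loc, ": unexpected or duplicated category")
  }
  bad <- !(ratings$score %in% 1:3)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("validation failure at ", ratings$location[i], "/",
         ratings$category[i], ": score ", ratings$score[i],
         " outside the 1-3 scale")
  }
  structure(ratings, class = c("dsp_assessment", "data.frame"))
}

#' Score a driving-safety-performance assessment
#'
#' Sums the three-point category ratings per location and over all six
#' locations.
#'
#' @param assessment A [dsp_assessment()] (or a data.frame that validates).
#' @return Object of class `dsp_scores`: named numeric `P1..P6, total`.
#' @export
score_dsp <- function(assessment) {
  if (!inherits(assessment, "dsp_assessment"))
    assessment <- dsp_assessment(assessment)
  per <- vapply(names(dsp_categories()), function(loc)
    sum(assessment$score[assessment$location == loc]), numeric(1))
  structure(c(per, total = sum(per)), class = "dsp_scores")
}

#' Moving-body recognition (DMD) ratio of a visual-cognition session
#'
#' The published score divides the number of button presses on signal
#' trials plus the number of presses on noise trials by the total trial
#' count (`convention = "verbatim"`, the default, implementing the printed
#' formula literally). Because counting noise presses in the numerator is
#' surprising for a recognition rate, `convention = "corrected"` scores
#' hits plus correct rejections over total trials instead. The convention
#' used is recorded on the result.
#'
#' @param session A `dvc_session` (columns `task`, `stimulus`, `pressed`).
#' @param task `"tracking"` or `"sudden"`; the session must contain at
#'   least one signal and one noise trial for it.
#' @param convention `"verbatim"` or `"corrected"`.
#' @return Ratio in `[0, 1]` with attribute `convention`.
#' @export
dmd_ratio <- function(session, task = c("sudden", "tracking"),
                      convention = c("verbatim", "corrected")) {
  task <- match.arg(task)
  convention <- match.arg(convention)
  s <- session[session$task == task, , drop = FALSE]
  n_sig <- sum(s$stimulus == "signal")
  n_noi <- sum(s$stimulus == "noise")
  if (n_sig < 1 || n_noi < 1)
    stop("task '", task, "' needs at least one signal and one noise trial")
  hits <- sum(s$pressed & s$stimulus == "signal")
  noise_pressed <- sum(s$pressed & s$stimulus == "noise")
  num <- if (convention == "verbatim") hits + noise_pressed
         else hits + (n_noi - noise_pressed)
  structure(num / (n_sig + n_noi), convention = convention)
}

#' Score both visual-cognition tasks of a session
#'
#' @param session A `dvc_session` containing both tasks.
#' @param convention Passed to [dmd_ratio()].
#' @param scale100 Report on the 0-100 scale used in the cohort tables.
#' @return Named numeric `c(tracking, sudden)` with attribute `convention`.
#' @export
dmd_scores <- function(session, convention = c("verbatim", "corrected"),
                       scale100 = TRUE) {
  convention <- match.arg(convention)
  out <- vapply(c("tracking", "sudden"), function(tk)
    as.numeric(dmd_ratio(session, tk, convention)), numeric(1))
  if (scale100) out <- out * 100
  structure(out, convention = convention)
}
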