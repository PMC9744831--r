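poly_design <- function(dims, order) {
  x <- seq(-1, 1, length.out = dims[1])
  y <- seq(-1, 1, length.out = dims[2])
  z <- seq(-1, 1, length.out = dims[3])
  g <- expand.grid(x = x, y = y, z = z)
  pw <- expand.grid(a = 0:order, b = 0:order, c = 0:order)
  pw <- pw[rowSums(pw) <= order, , drop = FALSE]
  X <- mapply(function(a, b, c) g$x^a * g$y^b * g$z^c, pw$a, pw$b, pw$c)
  colnames(X) <- sprintf("x%d y%d z%d", pw$a, pw$b, pw$c)
  X
}

#' Estimate a smooth multiplicative intensity-inhomogeneity field
#'
#' Fits a low-order 3-D polynomial to the log-intensities over a tissue
#' mask by least squares. The returned field is multiplicative
#' (`exp` of the fitted log-field) and strictly positive. With
#' `preserve_mean = TRUE` (default) the log-field is centred to zero mean
#' over the mask, so correction leaves the overall intensity scale of the
#' masked tissue unchanged and an order-0 fit is the identity; with
#' `preserve_mean = FALSE` the raw fit is returned, whose order-0 field is
#' the geometric-mean normalizer.
#'
#' @param volume A `brain_volume` with positive intensities inside the mask.
#' @param tissue_mask Logical array of voxels assumed to share a common
#'   underlying intensity (e.g. normal white matter).
#' @param order Polynomial order (0, 1, 2, ...); default 2.
#' @param preserve_mean Centre the log-field over the mask.
#' @return Object of class `bias_field`: `coefficients`, `order`,
#'   `log_field` (3-D array), `mask`.
#' @export
estimate_bias_field <- function(volume, tissue_mask, order = 2,
                                preserve_mean = TRUE) {
  stopifnot(inherits(volume, "brain_volume"))
  dims <- dim(volume$data)
  if (!identical(dim(tissue_mask), dims)) stop("mask/volume shape mismatch")
  idx <- which(tissue_mask)
  if (!length(idx)) stop("tissue mask is empty")
  v <- volume$data[idx]
  if (any(v <= 0)) stop("non-positive intensities inside the mask")
  X <- poly_design(dims, order)
  fit <- stats::lm.fit(X[idx, , drop = FALSE], log(v))
  if (fit$rank < ncol(X))
    stop("bias-field fit failure: rank-deficient design (degenerate mask geometry)")
  beta <- fit$coefficients
  lf <- array(X %*% beta, dims)
  if (preserve_mean) lf <- lf - mean(lf[idx])
  structure(list(coefficients = beta, order = order, log_field = lf,
                 mask = tissue_mask, preserve_mean = preserve_mean),
            class = "bias_field")
}

#' Divide out a multiplicative bias field
#'
#' @param volume A `brain_volume`.
#' @param field A `bias_field` estimated on the same grid.
#' @return Corrected `brain_volume` (`volume / exp(log_field)`).
#' @export
correct_inhomogeneity <- function(volume, field) {
  stopifnot(inherits(volume, "brain_volume"), inherits(field, "bias_field"))
  if (!identical(dim(volume$data), dim(field$log_field)))
    stop("field/volume shape mismatch")
  brain_volume(volume$data / exp(field$log_field),
               volume$spacing, volume$slice_thickness)
}
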