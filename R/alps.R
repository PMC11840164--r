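#' ROI means of the directional diffusivities
#'
#' Arithmetic means of the diagonal tensor elements Dxx, Dyy, Dzz over the
#' ROI voxels that pass the tensor-fit mask. The number of voxels actually
#' used is always reported.
#'
#' @param field a [tensor_field()].
#' @param roi `n x 3` integer matrix of voxel indices (e.g. one element of a
#'   [roi_set()]).
#' @param roi_name label used in error messages.
#' @return List with `dxx`, `dyy`, `dzz` (mm^2/s) and `n_voxels`.
#' @export
extract_roi_diffusivities <- function(field, roi, roi_name = "roi") {
  stopifnot(inherits(field, "tensor_field"))
  roi <- as.matrix(roi)
  keep <- field$mask[roi]
  if (!any(keep))
    stop("ROI '", roi_name, "' has no voxels passing the tensor-fit mask")
  roi <- roi[keep, , drop = FALSE]
  comp <- function(c_idx) mean(field$D[cbind(roi, c_idx)])
  list(dxx = comp(1L), dyy = comp(3L), dzz = comp(6L), n_voxels = nrow(roi))
}

#' The DTI-ALPS index
#'
#' Ratio of perivascular-axis diffusivity to the fiber-perpendicular
#' diffusivities:
#' `((dxx_proj + dxx_assoc) / 2) / ((dyy_proj + dzz_assoc) / 2)`.
#' In the projection-fiber ROI the fibers run along z, so Dxx and Dyy are
#' both perpendicular to the tract; in the association-fiber ROI the fibers
#' run along y, so Dxx and Dzz are perpendicular. Water moving along the
#' x-oriented perivascular space raises the numerator only, making the index
#' a dimensionless surrogate of glymphatic transport (1 = no preferential
#' x diffusion).
#'
#' @param dxx_proj,dxx_assoc,dyy_proj,dzz_assoc ROI-mean diffusivities,
#'   mm^2/s.
#' @return Dimensionless scalar index.
#' @examples
#' compute_alps(1.2e-3, 1.0e-3, 0.8e-3, 0.6e-3)  # 1.1/0.7
#' @export
compute_alps <- function(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc) {
  vals <- c(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc)
  if (any(!is.finite(vals))) stop("all four diffusivities must be finite")
  denom <- (dyy_proj + dzz_assoc) / 2
  if (denom <= 0)
    stop("non-positive denominator (degenerate tensor field): mean(Dyy_proj, Dzz_assoc) = ",
         format(denom))
  ((dxx_proj + dxx_assoc) / 2) / denom
}

#' Per-subject DTI-ALPS result
#'
#' Computes the index separately in the left and right hemispheres from the
#' four ROIs and averages the two. Returns all ROI-mean diffusivities so the
#' result is fully auditable.
#'
#' @param field a [tensor_field()].
#' @param rois a [roi_set()].
#' @return Object of class `alps_result`: per-hemisphere diffusivity means,
#'   voxel counts, and `alps_left`, `alps_right`, `alps_mean`.
#' @export
compute_subject_alps <- function(field, rois) {
  stopifnot(inherits(rois, "roi_set"))
  ex <- lapply(ROI_NAMES, function(nm)
    extract_roi_diffusivities(field, rois[[nm]], roi_name = nm))
  names(ex) <- ROI_NAMES
  left <- compute_alps(ex$proj_left$dxx, ex$assoc_left$dxx,
                       ex$proj_left$dyy, ex$assoc_left$dzz)
  right <- compute_alps(ex$proj_right$dxx, ex$assoc_right$dxx,
                        ex$proj_right$dyy, ex$assoc_right$dzz)
  structure(list(
    dxx_proj_l = ex$proj_left$dxx, dxx_assoc_l = ex$assoc_left$dxx,
    dyy_proj_l = ex$proj_left$dyy, dzz_assoc_l = ex$assoc_left$dzz,
    dxx_proj_r = ex$proj_right$dxx, dxx_assoc_r = ex$assoc_right$dxx,
    dyy_proj_r = ex$proj_right$dyy, dzz_assoc_r = ex$assoc_right$dzz,
    n_voxels = vapply(ex, function(e) e$n_voxels, 1L),
    alps_left = left, alps_right = right,
    alps_mean = (left + right) / 2
  ), class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf("<alps_result> left %.4f  right %.4f  mean %.4f (%d ROI voxels)\n",
              x$alps_left, x$alps_right, x$alps_mean, sum(x$n_voxels)))
  invisible(x)
}

#' Flatten ALPS results into a one-row-per-subject data frame
#'
#' @param results list of `alps_result` objects.
#' @param ids optional subject identifiers.
#' @return `data.frame` with the seven numeric ALPS fields per subject.
#' @export
alps_results_table <- function(results, ids = seq_along(results)) {
  rows <- lapply(results, function(r)
    data.frame(alps_left = r$alps_left, alps_right = r$alps_right,
               alps_mean = r$alps_mean,
               dxx_proj_l = r$dxx_proj_l, dxx_assoc_l = r$dxx_assoc_l,
               dyy_proj_l = r$dyy_proj_l, dzz_assoc_l = r$dzz_assoc_l))
  out <- do.call(rbind, rows)
  cbind(data.frame(id = ids), out)
}

#' Test-retest intraclass correlation coefficient
#'
#' Two-way mixed-effects, absolute-agreement, single-measure ICC (ICC(A,1)
#' in the McGraw-Wong taxonomy) from the standard mean-squares
#' decomposition of the subjects x sessions table:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The p-value tests the subject effect with `F = MSR / MSE` on
#' `(n-1, (n-1)(k-1))` degrees of freedom. With no between-subject variance
#' the coefficient is undefined and returned as `NA` with a flag.
#'
#' @param values_a,values_b paired measurements (e.g. ALPS at placement 1
#'   and after ROI re-placement), equal length >= 3.
#' @return Object of class `icc_result`: `icc`, `model_label`, `n_subjects`,
#'   `f`, `p_value`, `undefined`.
#' @export
icc_test_retest <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 3)
  y <- cbind(values_a, values_b)
  n <- nrow(y); k <- ncol(y)
  gm <- mean(y)
  ssr <- k * sum((rowMeans(y) - gm)^2)
  ssc <- n * sum((colMeans(y) - gm)^2)
  sse <- sum((y - gm)^2) - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  undefined <- msr <= .Machine$double.eps * max(abs(y), 1)
  if (undefined) {
    icc <- NA_real_; f <- NA_real_; p <- NA_real_
    warning("ICC undefined: no between-subject variance")
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    f <- msr / max(mse, .Machine$double.xmin)
    p <- stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  structure(list(icc = icc,
                 model_label = "two-way mixed, absolute agreement, single measures (ICC(A,1))",
                 n_subjects = n, f = f, p_value = p, undefined = undefined),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC = %.3f (%s; n = %d, p = %.3g)\n",
              x$icc, x$model_label, x$n_subjects, x$p_value))
  invisible(x)
}
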