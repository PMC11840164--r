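# Storage order for compact symmetric tensors (FSL lower-triangular):
# Dxx, Dxy, Dyy, Dxz, Dyz, Dzz.
TENSOR_COMP <- c("Dxx", "Dxy", "Dyy", "Dxz", "Dyz", "Dzz")

tensor_to_vec <- function(D) {
  c(D[1, 1], D[1, 2], D[2, 2], D[1, 3], D[2, 3], D[3, 3])
}

vec_to_tensor <- function(v) {
  matrix(c(v[1], v[2], v[4],
           v[2], v[3], v[5],
           v[4], v[5], v[6]), 3, 3)
}

check_symmetric_tensor <- function(D) {
  if (!is.matrix(D) || !all(dim(D) == c(3L, 3L)))
    stop("tensor must be a 3 x 3 matrix")
  scale <- max(abs(D), 1e-300)
  if (max(abs(D - t(D))) > 1e-8 * scale)
    stop("tensor must be symmetric")
  (D + t(D)) / 2
}

#' Predict diffusion-weighted signals from a tensor
#'
#' Monoexponential tensor signal model: for each measurement with b-value `b`
#' and unit direction `g`, the predicted signal is `s0 * exp(-b * t(g) %*% D %*% g)`.
#' `b = 0` measurements return exactly `s0`.
#'
#' @param tensor symmetric 3 x 3 diffusion tensor, mm^2/s.
#' @param scheme an [acquisition_scheme()].
#' @param s0 positive non-diffusion-weighted signal amplitude.
#' @return Numeric vector of length `scheme$n_meas`.
#' @examples
#' sch <- default_scheme(n_dir = 12)
#' predict_signal(diag(3) * 1e-3, sch, s0 = 100)
#' @export
predict_signal <- function(tensor, scheme, s0 = 1) {
  stopifnot(inherits(scheme, "alps_scheme"))
  if (!is.numeric(s0) || length(s0) != 1L || s0 <= 0)
    stop("s0 must be a positive scalar")
  D <- check_symmetric_tensor(tensor)
  g <- scheme$bvecs
  q <- rowSums((g %*% D) * g)   # g' D g per measurement
  out <- s0 * exp(-scheme$bvals * q)
  out[scheme$bvals == 0] <- s0
  out
}

# Design matrix of the log-linear model:
#   log S = log S0 - b * (gx^2 Dxx + 2 gx gy Dxy + gy^2 Dyy
#                         + 2 gx gz Dxz + 2 gy gz Dyz + gz^2 Dzz)
# Columns: log S0, then the six tensor components in TENSOR_COMP order.
tensor_design <- function(scheme) {
  g <- scheme$bvecs
  b <- scheme$bvals
  cbind(1,
        -b * g[, 1]^2,
        -b * 2 * g[, 1] * g[, 2],
        -b * g[, 2]^2,
        -b * 2 * g[, 1] * g[, 3],
        -b * 2 * g[, 2] * g[, 3],
        -b * g[, 3]^2)
}

#' Fit a diffusion tensor by log-linear least squares
#'
#' Ordinary least squares on log-signals: the six unique tensor elements and
#' `log S0` solve `log S = log S0 - b * t(g) %*% D %*% g`. Non-positive
#' signals cannot be log-transformed; those measurements are dropped with a
#' warning. If fewer than 7 usable measurements remain (or no b = 0, or the
#' remaining directions do not span the tensor space) the fit is flagged as
#' failed. Noise-free signals from [predict_signal()] are recovered to
#' numerical precision. Negative fitted diagonal elements are retained, not
#' clamped, but reported via `flagged`.
#'
#' @param signals numeric vector of measured signals, length `scheme$n_meas`.
#' @param scheme an [acquisition_scheme()].
#' @return A list with `tensor` (symmetric 3 x 3, mm^2/s), `s0`, `ok`
#'   (fit succeeded), `flagged` (negative diagonal), `n_dropped`.
#' @export
fit_tensor <- function(signals, scheme) {
  stopifnot(inherits(scheme, "alps_scheme"))
  if (length(signals) != scheme$n_meas)
    stop("signals length (", length(signals), ") does not match scheme (",
         scheme$n_meas, ")")
  usable <- is.finite(signals) & signals > 0
  if (!all(usable))
    warning(sum(!usable), " non-positive signal(s) dropped from tensor fit")
  fit <- fit_tensor_core(signals, scheme, usable)
  fit
}

fit_tensor_core <- function(signals, scheme, usable) {
  failed <- list(tensor = matrix(NA_real_, 3, 3), s0 = NA_real_,
                 ok = FALSE, flagged = TRUE, n_dropped = sum(!usable))
  if (sum(usable) < 7L) return(failed)
  sub <- acquisition_scheme(scheme$bvals[usable],
                            scheme$bvecs[usable, , drop = FALSE])
  if (!scheme_fittable(sub)) return(failed)
  X <- tensor_design(sub)
  beta <- qr.coef(qr(X), log(signals[usable]))
  D <- vec_to_tensor(beta[-1L])
  list(tensor = D, s0 = exp(beta[1L]), ok = TRUE,
       flagged = any(diag(D) < 0), n_dropped = sum(!usable))
}
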