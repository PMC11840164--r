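#' 4D diffusion-weighted volume
#'
#' Carrier for a 4D signal array (x, y, z, measurement) plus its acquisition
#' scheme and voxel size. The fourth dimension must match `scheme$n_meas` and
#' all signals must be non-negative.
#'
#' @param signal 4D numeric array.
#' @param scheme an [acquisition_scheme()].
#' @param voxel_size length-3 numeric, mm.
#' @return Object of class `dwi_volume`.
#' @export
dwi_volume <- function(signal, scheme, voxel_size = c(2, 2, 2)) {
  stopifnot(inherits(scheme, "alps_scheme"))
  if (length(dim(signal)) != 4L)
    stop("signal must be a 4D array (x, y, z, measurement)")
  if (dim(signal)[4L] != scheme$n_meas)
    stop("fourth dimension (", dim(signal)[4L],
         ") does not match scheme$n_meas (", scheme$n_meas, ")")
  if (any(signal < 0)) stop("signal values must be non-negative")
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(signal = signal, scheme = scheme,
                 voxel_size = as.numeric(voxel_size)),
            class = "dwi_volume")
}

#' Per-voxel diffusion tensor field
#'
#' Compact storage of symmetric tensors on a regular grid: a 4D array with
#' six component volumes in lower-triangular order Dxx, Dxy, Dyy, Dxz, Dyz,
#' Dzz, plus a logical mask of voxels with a valid fit.
#'
#' @param D 4D array `(x, y, z, 6)` of tensor components, mm^2/s.
#' @param mask logical 3D array; `TRUE` where the tensor is valid.
#' @param voxel_size length-3 numeric, mm.
#' @param flagged optional logical 3D array marking fits with negative
#'   diagonal elements (retained in `D` but excluded from the mask by
#'   [fit_volume()]).
#' @return Object of class `tensor_field`.
#' @export
tensor_field <- function(D, mask, voxel_size = c(2, 2, 2), flagged = NULL) {
  stopifnot(length(dim(D)) == 4L, dim(D)[4L] == 6L)
  dims <- dim(D)[1:3]
  stopifnot(is.logical(mask), all(dim(mask) == dims))
  if (is.null(flagged)) flagged <- array(FALSE, dims)
  structure(list(D = D, mask = mask, voxel_size = as.numeric(voxel_size),
                 flagged = flagged, dims = dims),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> ", paste(x$dims, collapse = " x "), " grid, ",
      sum(x$mask), " valid voxels (", sum(x$flagged), " flagged)\n", sep = "")
  invisible(x)
}

#' Extract the 3 x 3 tensor at one voxel
#'
#' @param field a [tensor_field()].
#' @param i,j,k voxel indices (1-based).
#' @return Symmetric 3 x 3 matrix, mm^2/s.
#' @export
tensor_at <- function(field, i, j, k) {
  vec_to_tensor(field$D[i, j, k, ])
}

#' Fit a tensor field to a diffusion-weighted volume
#'
#' Applies the log-linear least-squares tensor fit voxel-wise within a mask.
#' Voxels where every signal is positive share one QR factorization of the
#' common design matrix; voxels with non-positive signals are refit
#' individually with those measurements dropped. Voxels whose fit fails, or
#' whose fitted diagonal contains a negative element, are removed from the
#' output mask (the components are retained for inspection).
#'
#' @param dwi a [dwi_volume()].
#' @param mask logical 3D array matching the spatial dimensions; default all
#'   `TRUE`.
#' @return A [tensor_field()]; the number of failed fits is reported via
#'   `message()`.
#' @export
fit_volume <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  dims <- dim(dwi$signal)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  if (!all(dim(mask) == dims))
    stop("mask dimensions do not match the DWI spatial dimensions")
  mask <- array(as.logical(mask), dims)
  if (!any(mask)) stop("empty mask: no voxels to fit")

  n_meas <- dwi$scheme$n_meas
  sig <- matrix(aperm(dwi$signal, c(4L, 1L, 2L, 3L)), nrow = n_meas)
  idx <- which(mask)
  D <- array(NA_real_, c(dims, 6L))
  Dm <- matrix(NA_real_, length(mask), 6L)
  ok <- logical(length(mask))
  flagged <- logical(length(mask))

  clean <- idx[colSums(sig[, idx, drop = FALSE] <= 0 |
                         !is.finite(sig[, idx, drop = FALSE])) == 0L]
  if (length(clean)) {
    qrX <- qr(tensor_design(dwi$scheme))
    beta <- qr.coef(qrX, log(sig[, clean, drop = FALSE]))
    Dm[clean, ] <- t(beta[-1L, , drop = FALSE])
    ok[clean] <- TRUE
    flagged[clean] <- Dm[clean, 1L] < 0 | Dm[clean, 3L] < 0 | Dm[clean, 6L] < 0
  }
  dirty <- setdiff(idx, clean)
  for (v in dirty) {
    s <- sig[, v]
    usable <- is.finite(s) & s > 0
    fit <- fit_tensor_core(s, dwi$scheme, usable)
    if (fit$ok) {
      Dm[v, ] <- tensor_to_vec(fit$tensor)
      ok[v] <- TRUE
      flagged[v] <- fit$flagged
    }
  }
  n_failed <- sum(mask) - sum(ok)
  if (n_failed > 0 || length(dirty) > 0)
    message("fit_volume: ", n_failed, " voxel(s) failed, ",
            sum(flagged), " flagged (negative diagonal)")
  D <- array(Dm, c(dims, 6L))
  tensor_field(D, mask = array(ok & !flagged, dims),
               voxel_size = dwi$voxel_size, flagged = array(flagged, dims))
}

identity_affine <- function(voxel_size) {
  diag(c(voxel_size, 1))
}

#' NIfTI input/output for volumes, tensor fields and masks
#'
#' Phantoms live in a canonical frame: x = left-right (perivascular axis),
#' y = anterior-posterior (association fibers), z = inferior-superior
#' (projection fibers). Volumes are written with an identity-scaled affine
#' carrying the voxel size; no reorientation is applied on read.
#'
#' @param dwi a [dwi_volume()]; `field` a [tensor_field()].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @name alps_nifti
NULL

#' @rdname alps_nifti
#' @export
write_dwi_nifti <- function(dwi, path) {
  img <- RNifti::asNifti(dwi$signal)
  RNifti::pixdim(img) <- c(dwi$voxel_size, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname alps_nifti
#' @param scheme an [acquisition_scheme()] to attach to the signal read from
#'   `path`.
#' @export
read_dwi_nifti <- function(path, scheme) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  dwi_volume(array(as.numeric(img), dim(img)), scheme, voxel_size = vox)
}

#' @rdname alps_nifti
#' @export
write_tensor_nifti <- function(field, path) {
  img <- RNifti::asNifti(field$D)
  RNifti::pixdim(img) <- c(field$voxel_size, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname alps_nifti
#' @export
read_tensor_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L || dim(img)[4L] != 6L)
    stop("'", path, "' is not a 6-component tensor NIfTI")
  vox <- RNifti::pixdim(img)[1:3]
  D <- array(as.numeric(img), dim(img))
  mask <- array(apply(is.finite(D), c(1, 2, 3), all), dim(img)[1:3])
  tensor_field(D, mask = mask, voxel_size = vox)
}

#' @rdname alps_nifti
#' @param mask logical 3D array.
#' @export
write_mask_nifti <- function(mask, path, voxel_size = c(2, 2, 2)) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)),
                         datatype = "uint8")
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname alps_nifti
#' @param voxel_size length-3 numeric, mm.
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) != 0, dim(img)[1:3])
}
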