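#' Diffusion acquisition scheme
#'
#' Bundles b-values (s/mm^2) and unit gradient directions into a validated
#' scheme object. Directions for `b > 0` measurements must be unit vectors;
#' vectors whose norm deviates from 1 by more than `1e-3` are re-normalized
#' with a warning, smaller deviations silently. `b = 0` rows may carry any
#' vector (conventionally zero).
#'
#' @param bvals numeric vector of b-values, s/mm^2.
#' @param bvecs numeric matrix of gradient directions, either `n x 3` or
#'   `3 x n` (FSL layout); stored internally as `n x 3`.
#' @return An object of class `alps_scheme` with elements `bvals`, `bvecs`
#'   (`n x 3`) and `n_meas`.
#' @examples
#' sch <- acquisition_scheme(c(0, 1000, 1000),
#'                           rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
#' sch$n_meas
#' @export
acquisition_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L && nrow(bvecs) == 3L) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3L)
    stop("bvecs must be an n x 3 (or 3 x n) matrix of gradient directions")
  if (length(bvals) != nrow(bvecs))
    stop("bvals (", length(bvals), ") and bvecs (", nrow(bvecs),
         ") describe different numbers of measurements")
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and non-negative")
  dw <- bvals > 0
  if (any(dw)) {
    nrm <- sqrt(rowSums(bvecs[dw, , drop = FALSE]^2))
    if (any(nrm == 0))
      stop("zero gradient vector for a b > 0 measurement")
    if (any(abs(nrm - 1) > 1e-3))
      warning(sum(abs(nrm - 1) > 1e-3),
              " gradient vector(s) deviate from unit norm by > 1e-3; re-normalized")
    bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / nrm
  }
  structure(list(bvals = bvals, bvecs = bvecs, n_meas = length(bvals)),
            class = "alps_scheme")
}

#' @export
print.alps_scheme <- function(x, ...) {
  cat("<alps_scheme> ", x$n_meas, " measurements: ",
      sum(x$bvals == 0), " b=0, ", sum(x$bvals > 0),
      " diffusion-weighted (b = ",
      paste(unique(x$bvals[x$bvals > 0]), collapse = ", "), " s/mm^2)\n",
      sep = "")
  invisible(x)
}

# Deterministic quasi-uniform unit directions (spherical Fibonacci lattice).
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Default single-shell acquisition scheme
#'
#' One b = 0 reference followed by `n_dir` diffusion-weighted measurements at
#' a single shell, with directions on a deterministic spherical Fibonacci
#' lattice. Defaults mirror a typical clinical glymphatic protocol:
#' 128 directions at b = 1000 s/mm^2.
#'
#' @param n_dir number of diffusion-weighted directions.
#' @param bval shell b-value, s/mm^2.
#' @param n_b0 number of leading b = 0 measurements.
#' @return An `alps_scheme`.
#' @export
default_scheme <- function(n_dir = 128, bval = 1000, n_b0 = 1) {
  stopifnot(n_dir >= 7, n_b0 >= 1, bval > 0)
  acquisition_scheme(
    bvals = c(rep(0, n_b0), rep(bval, n_dir)),
    bvecs = rbind(matrix(0, n_b0, 3), fibonacci_directions(n_dir))
  )
}

#' Read / write FSL-dialect gradient tables
#'
#' `read_gradient_table()` parses the FSL text convention: the bval file holds
#' one whitespace-separated row of b-values; the bvec file holds three rows
#' (x, y and z components). `write_gradient_table()` writes the same layout;
#' a write/read round trip reproduces the scheme up to float formatting.
#'
#' @param bval_path,bvec_path paths to the two text files.
#' @return `read_gradient_table()` returns an `alps_scheme`;
#'   `write_gradient_table()` returns the two paths, invisibly.
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  bval_rows <- count_numeric_rows(bval_path)
  if (length(bval_rows) != 1L)
    stop("bval file '", bval_path, "' must contain exactly one row, found ",
         length(bval_rows))
  bvec_rows <- count_numeric_rows(bvec_path)
  if (length(bvec_rows) != 3L)
    stop("bvec file '", bvec_path, "' must contain exactly three rows ",
         "(x, y, z components), found ", length(bvec_rows))
  bvals <- bval_rows[[1L]]
  if (length(unique(lengths(bvec_rows))) != 1L ||
      length(bvec_rows[[1L]]) != length(bvals))
    stop("bvec file '", bvec_path, "' column count does not match bval file '",
         bval_path, "'")
  acquisition_scheme(bvals, t(do.call(rbind, bvec_rows)))
}

count_numeric_rows <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
    if (any(is.na(v))) stop("non-numeric token in '", path, "'")
    v
  })
}

#' @rdname read_gradient_table
#' @param scheme an `alps_scheme`.
#' @export
write_gradient_table <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "alps_scheme"))
  fmt <- function(v) paste(formatC(v, format = "g", digits = 10), collapse = " ")
  writeLines(fmt(scheme$bvals), bval_path)
  writeLines(c(fmt(scheme$bvecs[, 1]), fmt(scheme$bvecs[, 2]),
               fmt(scheme$bvecs[, 3])), bvec_path)
  invisible(c(bval_path, bvec_path))
}

# A scheme supports tensor fitting if it has >= 1 b0 and >= 6 distinct
# non-collinear DW directions (rank of the quadratic-form design = 6).
scheme_fittable <- function(scheme) {
  dw <- scheme$bvals > 0
  if (sum(!dw) < 1L || sum(dw) < 6L) return(FALSE)
  g <- scheme$bvecs[dw, , drop = FALSE]
  q <- cbind(g[, 1]^2, 2 * g[, 1] * g[, 2], g[, 2]^2,
             2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3], g[, 3]^2)
  qr(q)$rank == 6L
}
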