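#' Specification of a two-compartment diffusion phantom
#'
#' The phantom emulates the geometry the ALPS index reads from at the level
#' of the lateral ventricle body, in a canonical frame: projection fibers run
#' along z (tensor `diag(g + radial, radial, axial)`), association fibers
#' along y (`diag(g + radial, axial, radial)`), and a perivascular
#' diffusivity component `g >= 0` adds to Dxx in both compartments,
#' emulating water transport along the x-oriented perivascular space. The
#' closed-form ALPS ground truth is therefore `(g + radial) / radial`,
#' independent of `axial` (see [alps_ground_truth()]). Each hemisphere holds
#' one projection and one association compartment; `g` may be a single value
#' or per-hemisphere `c(left, right)`.
#'
#' @param dims grid dimensions, default `c(12, 12, 8)`.
#' @param voxel_size voxel edge lengths in mm; default 2 mm isotropic.
#' @param axial,radial fiber diffusivities parallel/perpendicular to the
#'   tract, mm^2/s; must satisfy `axial > radial > 0`.
#' @param g perivascular x-diffusivity increment, mm^2/s (scalar or
#'   `c(left, right)`).
#' @param background isotropic diffusivity outside the compartments, mm^2/s.
#' @param noise `"none"`, `"gaussian"` or `"rician"`.
#' @param snr signal-to-noise ratio at b = 0 (`s0 / sigma`).
#' @param s0 non-diffusion-weighted signal amplitude.
#' @param scheme acquisition scheme; default [default_scheme()] (128
#'   directions, b = 1000 s/mm^2).
#' @param roi_radius half-width of the 3D box ROIs; default 1 (3x3x3 boxes).
#' @param seed integer seed making generation reproducible.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(12, 12, 8), voxel_size = c(2, 2, 2),
                         axial = 1.4e-3, radial = 0.4e-3, g = 0.2e-3,
                         background = 0.8e-3,
                         noise = c("none", "gaussian", "rician"),
                         snr = 30, s0 = 1000,
                         scheme = default_scheme(), roi_radius = 1L,
                         seed = 1L) {
  noise <- match.arg(noise)
  if (!(axial > radial && radial > 0))
    stop("fiber diffusivities must satisfy axial > radial > 0")
  if (any(g < 0)) stop("perivascular parameter g must be >= 0")
  g <- if (length(g) == 1L) c(left = g, right = g)
       else stats::setNames(as.numeric(g), c("left", "right"))
  side <- 2L * roi_radius + 3L   # compartment box: ROI plus 1-voxel margin
  if (any(dims < c(2L * side, 2L * side, side)))
    stop("grid dims ", paste(dims, collapse = "x"),
         " too small for two ", side, "-voxel compartments per axis")
  structure(list(dims = as.integer(dims), voxel_size = voxel_size,
                 axial = axial, radial = radial, g = g,
                 background = background, noise = noise, snr = snr, s0 = s0,
                 scheme = scheme, roi_radius = as.integer(roi_radius),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Closed-form ALPS ground truth of a phantom
#'
#' In both compartments Dxx = g + radial while Dyy(projection) and
#' Dzz(association) both equal `radial`, so the index is
#' `(g + radial) / radial` per hemisphere.
#'
#' @param spec a [phantom_spec()].
#' @return Named vector `c(left, right, mean)`.
#' @export
alps_ground_truth <- function(spec) {
  v <- (spec$g + spec$radial) / spec$radial
  c(left = unname(v["left"]), right = unname(v["right"]),
    mean = unname((v["left"] + v["right"]) / 2))
}

phantom_compartments <- function(spec) {
  d <- spec$dims
  r <- spec$roi_radius + 1L   # compartment half-width (ROI + margin)
  cx <- c(left = max(r + 1L, round(d[1] * 0.25)),
          right = min(d[1] - r, round(d[1] * 0.75)))
  cy <- c(proj = max(r + 1L, round(d[2] * 0.3)),
          assoc = min(d[2] - r, round(d[2] * 0.7)))
  cz <- max(r + 1L, min(d[3] - r, round(d[3] / 2)))
  list(
    proj_left = c(cx["left"], cy["proj"], cz),
    assoc_left = c(cx["left"], cy["assoc"], cz),
    proj_right = c(cx["right"], cy["proj"], cz),
    assoc_right = c(cx["right"], cy["assoc"], cz)
  )
}

#' Generate a diffusion phantom with known ALPS ground truth
#'
#' Builds the compartment tensor field, synthesizes signals with
#' [predict_signal()] under the spec's acquisition scheme, applies the chosen
#' noise model (Rician noise as the magnitude of a complex Gaussian with
#' `sigma = s0 / snr`), and places 3D box ROIs wholly inside the
#' compartments. Identical specs (including seed) yield identical output.
#'
#' @param spec a [phantom_spec()].
#' @return List with `dwi` ([dwi_volume()]), `truth` (ground-truth
#'   [tensor_field()]), `rois` ([roi_set()]), `labels` (compartment label
#'   array) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  centers <- phantom_compartments(spec)
  comp_r <- spec$roi_radius + 1L

  tensors <- list(
    proj_left = diag(c(spec$g[["left"]] + spec$radial, spec$radial, spec$axial)),
    assoc_left = diag(c(spec$g[["left"]] + spec$radial, spec$axial, spec$radial)),
    proj_right = diag(c(spec$g[["right"]] + spec$radial, spec$radial, spec$axial)),
    assoc_right = diag(c(spec$g[["right"]] + spec$radial, spec$axial, spec$radial)),
    background = diag(rep(spec$background, 3))
  )

  labels <- array(0L, d)
  for (nm in ROI_NAMES)
    labels[roi_box(centers[[nm]], comp_r)] <- ROI_CODES[[nm]]

  # ground-truth field
  Dtruth <- array(0, c(d, 6L))
  for (code in 0:4) {
    nm <- if (code == 0L) "background" else ROI_NAMES[code]
    v <- tensor_to_vec(tensors[[nm]])
    sel <- labels == code
    for (cc in 1:6) {
      comp <- Dtruth[, , , cc]
      comp[sel] <- v[cc]
      Dtruth[, , , cc] <- comp
    }
  }
  truth <- tensor_field(Dtruth, mask = array(TRUE, d),
                        voxel_size = spec$voxel_size)

  # signals: one prediction per distinct compartment tensor
  n_meas <- spec$scheme$n_meas
  sig <- array(0, c(d, n_meas))
  for (code in 0:4) {
    nm <- if (code == 0L) "background" else ROI_NAMES[code]
    s <- predict_signal(tensors[[nm]], spec$scheme, s0 = spec$s0)
    sel <- which(labels == code)
    for (m in seq_len(n_meas)) {
      vol <- sig[, , , m]
      vol[sel] <- s[m]
      sig[, , , m] <- vol
    }
  }

  if (spec$noise != "none") {
    set.seed(spec$seed)
    sigma <- spec$s0 / spec$snr
    eps1 <- array(stats::rnorm(length(sig), 0, sigma), dim(sig))
    if (spec$noise == "gaussian") {
      sig <- pmax(sig + eps1, .Machine$double.eps)
    } else {
      eps2 <- array(stats::rnorm(length(sig), 0, sigma), dim(sig))
      sig <- sqrt((sig + eps1)^2 + eps2^2)
    }
  }

  rois <- roi_set(roi_box(centers$proj_left, spec$roi_radius),
                  roi_box(centers$assoc_left, spec$roi_radius),
                  roi_box(centers$proj_right, spec$roi_radius),
                  roi_box(centers$assoc_right, spec$roi_radius),
                  dims = d)
  for (nm in ROI_NAMES)
    if (any(labels[rois[[nm]]] != ROI_CODES[[nm]]))
      stop("internal error: ROI '", nm, "' extends outside its compartment")

  list(dwi = dwi_volume(sig, spec$scheme, spec$voxel_size),
       truth = truth, rois = rois, labels = labels, spec = spec)
}

#' Perivascular parameter yielding a target ALPS value
#'
#' Inverts the phantom's closed form: `g = (alps - 1) * radial`.
#'
#' @param alps target index value (> 0).
#' @param radial radial fiber diffusivity, mm^2/s.
#' @return `g` in mm^2/s.
#' @export
g_for_alps <- function(alps, radial = 0.4e-3) {
  stopifnot(alps > 0)
  (alps - 1) * radial
}

#' Write phantom outputs to disk
#'
#' DWI as 4D NIfTI with FSL bval/bvec text files, ROI labels as NIfTI.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(dwi = file.path(dir, "dwi.nii.gz"),
         bval = file.path(dir, "dwi.bval"),
         bvec = file.path(dir, "dwi.bvec"),
         rois = file.path(dir, "rois.nii.gz"))
  write_dwi_nifti(phantom$dwi, p[["dwi"]])
  write_gradient_table(phantom$dwi$scheme, p[["bval"]], p[["bvec"]])
  lab <- rois_to_labels(phantom$rois)
  img <- RNifti::asNifti(lab)
  RNifti::pixdim(img) <- phantom$dwi$voxel_size
  RNifti::writeNifti(img, p[["rois"]])
  invisible(p)
}
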