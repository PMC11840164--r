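ROI_NAMES <- c("proj_left", "assoc_left", "proj_right", "assoc_right")
ROI_CODES <- stats::setNames(1:4, ROI_NAMES)

#' Four-ROI set for the DTI-ALPS index
#'
#' The index is read from four regions at the level of the lateral ventricle
#' body: a projection-fiber and an association-fiber ROI in each hemisphere.
#' Each ROI is a set of voxel indices (rows of an `n x 3` integer matrix) on
#' the tensor grid. The four sets must be non-empty, pairwise disjoint and
#' within `dims`.
#'
#' @param proj_left,assoc_left,proj_right,assoc_right `n x 3` integer
#'   matrices of 1-based voxel indices.
#' @param dims grid dimensions the indices must respect.
#' @return Object of class `roi_set`: a named list of index matrices.
#' @export
roi_set <- function(proj_left, assoc_left, proj_right, assoc_right, dims) {
  rois <- list(proj_left = proj_left, assoc_left = assoc_left,
               proj_right = proj_right, assoc_right = assoc_right)
  rois <- lapply(rois, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    if (ncol(m) != 3L || nrow(m) == 0L)
      stop("each ROI must be a non-empty n x 3 index matrix")
    m
  })
  for (nm in ROI_NAMES) {
    m <- rois[[nm]]
    if (any(m < 1L) || any(t(m) > dims))
      stop("ROI '", nm, "' has indices outside the ", paste(dims, collapse = "x"),
           " grid")
  }
  keys <- lapply(rois, function(m) paste(m[, 1], m[, 2], m[, 3]))
  if (anyDuplicated(unlist(keys)))
    stop("ROIs overlap: the four sets must be disjoint")
  structure(c(rois, list(dims = as.integer(dims))), class = "roi_set")
}

#' Axis-aligned box ROI
#'
#' @param center length-3 voxel index of the box centre.
#' @param radius half-width in voxels; the box spans `2 * radius + 1` voxels
#'   per axis.
#' @return `n x 3` integer index matrix.
#' @export
roi_box <- function(center, radius = 1L) {
  stopifnot(length(center) == 3L, radius >= 0L)
  rng <- lapply(center, function(c0) (c0 - radius):(c0 + radius))
  as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
}

#' Build an ROI set from an integer label volume
#'
#' Labels follow the convention 1 = proj_left, 2 = assoc_left,
#' 3 = proj_right, 4 = assoc_right; all other values are ignored.
#'
#' @param labels integer 3D array (or path to a label NIfTI).
#' @return A [roi_set()].
#' @export
rois_from_labels <- function(labels) {
  if (is.character(labels)) {
    img <- RNifti::readNifti(labels)
    labels <- array(as.integer(img), dim(img))
  }
  dims <- dim(labels)
  idx <- lapply(ROI_CODES, function(code) {
    which(labels == code, arr.ind = TRUE)
  })
  if (any(vapply(idx, nrow, 1L) == 0L))
    stop("label volume is missing codes: ",
         paste(ROI_NAMES[vapply(idx, nrow, 1L) == 0L], collapse = ", "))
  roi_set(idx[[1]], idx[[2]], idx[[3]], idx[[4]], dims = dims)
}

#' Serialize an ROI set to an integer label volume
#'
#' @param rois a [roi_set()].
#' @return Integer 3D array with codes 1-4.
#' @export
rois_to_labels <- function(rois) {
  stopifnot(inherits(rois, "roi_set"))
  lab <- array(0L, rois$dims)
  for (nm in ROI_NAMES) lab[rois[[nm]]] <- ROI_CODES[[nm]]
  lab
}

#' Build an ROI set from a YAML geometry specification
#'
#' The YAML maps each of the four ROI names to `{center: [i, j, k],
#' radius: r}` boxes, plus a top-level `dims: [nx, ny, nz]`.
#'
#' @param path YAML file path.
#' @return A [roi_set()].
#' @export
rois_from_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$dims)) stop("ROI YAML must give grid 'dims'")
  boxes <- lapply(ROI_NAMES, function(nm) {
    b <- spec[[nm]]
    if (is.null(b)) stop("ROI YAML is missing '", nm, "'")
    roi_box(unlist(b$center), b$radius %||% 1L)
  })
  roi_set(boxes[[1]], boxes[[2]], boxes[[3]], boxes[[4]],
          dims = unlist(spec$dims))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
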