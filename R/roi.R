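#' Label volumes
#'
#' A 3D integer region map on a voxel grid with physical voxel size, plus a
#' label dictionary. Label 0 is reserved for background; every named region
#' must be nonempty.
#'
#' @param data 3D integer array of label ids.
#' @param voxdim voxel size in mm per axis (length 3, all > 0).
#' @param labels data.frame with columns `id`, `name`, and optionally
#'   `hemisphere` (`"L"`, `"R"` or `NA`) and `role`
#'   (`reference|target|extracerebral|other`).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, voxdim = c(2, 2, 2), labels = NULL) {
  if (length(dim(data)) != 3L) stop("label data must be a 3D array")
  if (any(voxdim <= 0)) stop("voxel sizes must be > 0 (mm)")
  if (any(data < 0)) stop("labels must be nonnegative")
  if (is.null(labels)) {
    ids <- setdiff(sort(unique(as.integer(data))), 0L)
    labels <- data.frame(id = ids, name = paste0("region_", ids),
                         hemisphere = NA_character_, role = "other")
  }
  if (!all(c("id", "name") %in% names(labels)))
    stop("label dictionary needs columns 'id' and 'name'")
  if (is.null(labels$hemisphere)) labels$hemisphere <- NA_character_
  if (is.null(labels$role)) labels$role <- "other"
  present <- unique(as.integer(data))
  missing <- setdiff(labels$id, present)
  if (length(missing))
    stop(sprintf("named region(s) empty in volume: %s",
                 paste(labels$name[labels$id %in% missing], collapse = ", ")))
  structure(list(data = data, voxdim = as.numeric(voxdim),
                 labels = labels), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume: %s voxels @ %s mm, %d named regions>\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$voxdim), collapse = "x"), nrow(x$labels)))
  invisible(x)
}

# Felzenszwalb-Huttenlocher 1D squared distance transform with sample
# spacing h; f is the input squared-distance row (0 at sources).
.dt1d <- function(f, h, big) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n); z <- numeric(n + 1L)
  d <- numeric(n)
  k <- 1L; v[1L] <- 1L; z[1L] <- -big; z[2L] <- big
  x <- (seq_len(n)) * h
  for (q in 2:n) {
    s <- ((f[q] + x[q]^2) - (f[v[k]] + x[v[k]]^2)) / (2 * (x[q] - x[v[k]]))
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + x[q]^2) - (f[v[k]] + x[v[k]]^2)) / (2 * (x[q] - x[v[k]]))
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- big
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < x[q]) k <- k + 1L
    d[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance transform of a binary mask
#'
#' Exact voxel-center-to-voxel-center Euclidean distances in mm, aware of
#' anisotropic voxel sizes (separable squared-distance transform applied
#' along each axis with its physical spacing).
#'
#' @param mask 3D logical (or 0/1) array.
#' @param voxdim voxel size in mm per axis.
#' @param from `"mask"`: distance of every voxel to the nearest mask voxel
#'   (zero inside the mask); `"background"`: distance to the nearest
#'   non-mask voxel (zero outside).
#' @return 3D numeric array of distances in mm.
#' @export
distance_transform <- function(mask, voxdim = c(2, 2, 2),
                               from = c("mask", "background")) {
  from <- match.arg(from)
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  src <- if (from == "mask") mask > 0 else !(mask > 0)
  if (!any(src)) return(array(Inf, d))
  big <- (sum(d * voxdim))^2 * 4
  f <- array(ifelse(src, 0, big), d)
  # axis 1
  for (j in seq_len(d[2])) for (k3 in seq_len(d[3]))
    f[, j, k3] <- .dt1d(f[, j, k3], voxdim[1], big)
  # axis 2
  for (i in seq_len(d[1])) for (k3 in seq_len(d[3]))
    f[i, , k3] <- .dt1d(f[i, , k3], voxdim[2], big)
  # axis 3
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    f[i, j, ] <- .dt1d(f[i, j, ], voxdim[3], big)
  sqrt(f)
}

#' Erode a binary mask by a physical distance
#'
#' Removes voxels whose Euclidean distance to the mask boundary is strictly
#' less than `distance`; voxels at exactly the threshold survive. Distances
#' are computed by an exact voxel-center distance transform, and the
#' boundary surface is taken to lie half a voxel beyond the outermost mask
#' voxel centers (threshold `distance + mean(voxdim)/2` on center-to-center
#' distances), which keeps the eroded physical volume stable under voxel
#' refinement.
#'
#' @param mask 3D logical array.
#' @param distance erosion distance in mm (>= 0; 0 is the identity).
#' @param voxdim voxel size in mm per axis.
#' @param name region name used in error messages.
#' @return Eroded logical array. Errors if the result is empty.
#' @export
erode_mask <- function(mask, distance, voxdim = c(2, 2, 2),
                       name = "region") {
  if (distance < 0) stop("erosion distance must be >= 0 (mm)")
  mask <- mask > 0
  if (distance == 0) return(mask)
  dist <- distance_transform(mask, voxdim, from = "background")
  out <- mask & dist >= distance + mean(voxdim) / 2
  if (!any(out))
    stop(sprintf("erosion of '%s' by %g mm leaves no voxels", name, distance))
  out
}

#' Build an extracerebral shell around a brain mask
#'
#' Dilates the cortical/brain mask outward by `thickness` mm and removes all
#' brain voxels, leaving a shell strictly outside the brain: voxels whose
#' distance to the nearest brain voxel is positive and at most `thickness`.
#' Mirrors an extracerebral (meningeal) segmentation built by dilating the
#' pial surface outward.
#'
#' @param cortical_mask 3D logical array (nonempty).
#' @param thickness shell thickness in mm (> 0). Default 5.
#' @param voxdim voxel size in mm per axis.
#' @return Logical array: the shell. Errors if empty (e.g. `thickness` too
#'   small to reach any voxel center).
#' @export
build_extracerebral_shell <- function(cortical_mask, thickness = 5,
                                      voxdim = c(2, 2, 2)) {
  cortical_mask <- cortical_mask > 0
  if (!any(cortical_mask)) stop("cortical mask is empty")
  if (thickness <= 0)
    stop("shell thickness must be > 0 (mm); result would be empty")
  dist <- distance_transform(cortical_mask, voxdim, from = "mask")
  shell <- !cortical_mask & dist <= thickness
  if (!any(shell))
    stop(sprintf("shell of thickness %g mm contains no voxels", thickness))
  shell
}

#' Region specifications and composites
#'
#' A region spec names a set of constituent label ids with an optional
#' morphology operation to apply at sampling time.
#'
#' @param name region name.
#' @param ids integer label ids (must exist in the dictionary when applied).
#' @param op morphology: `"none"`, `"erode"` or `"shell"`.
#' @param distance erosion distance or shell thickness in mm (required and
#'   > 0 when `op != "none"`).
#' @param role one of `reference`, `target`, `extracerebral`, `other`.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, ids, op = c("none", "erode", "shell"),
                        distance = NULL, role = "other") {
  op <- match.arg(op)
  if (op != "none" && (is.null(distance) || distance <= 0))
    stop("morphology distance must be > 0 mm")
  structure(list(name = name, ids = as.integer(ids), op = op,
                 distance = distance, role = role), class = "region_spec")
}

#' Union of labelled regions
#'
#' Builds a composite [region_spec] from constituent label names. The
#' meta-temporal composite preset unions its six constituent temporal-lobe
#' structures (entorhinal, parahippocampal, amygdala, fusiform, inferior
#' temporal, middle temporal); an inferior-cerebellum region is formed by
#' subtracting a supplied superior-cerebellum mask from cerebellar grey.
#'
#' @param labels a [label_volume].
#' @param names character vector of constituent region names from the label
#'   dictionary.
#' @param name name of the composite.
#' @param role role of the composite.
#' @return A [region_spec] whose ids are the union of the constituents'.
#' @export
composite_region <- function(labels, names, name = "composite",
                             role = "target") {
  stopifnot(inherits(labels, "label_volume"))
  unknown <- setdiff(names, labels$labels$name)
  if (length(unknown))
    stop(sprintf("unknown region(s): %s", paste(unknown, collapse = ", ")))
  ids <- labels$labels$id[labels$labels$name %in% names]
  region_spec(name, ids, role = role)
}

#' @rdname composite_region
#' @export
meta_temporal_constituents <- function() {
  c("entorhinal", "parahippocampal", "amygdala", "fusiform",
    "inf_temporal", "mid_temporal")
}

#' Subtract a mask from a region
#'
#' Voxelwise set difference, used e.g. to form an inferior cerebellum as
#' cerebellar grey minus a superior-cerebellum mask. The two outputs
#' partition the parent region.
#'
#' @param parent_mask,subtract_mask 3D logical arrays on one grid.
#' @return Logical array `parent & !subtract`.
#' @export
mask_difference <- function(parent_mask, subtract_mask) {
  stopifnot(isTRUE(all.equal(dim(parent_mask), dim(subtract_mask))))
  (parent_mask > 0) & !(subtract_mask > 0)
}

# resolve a region_spec to a logical voxel mask
.region_mask <- function(labels, spec) {
  stopifnot(inherits(labels, "label_volume"), inherits(spec, "region_spec"))
  bad <- setdiff(spec$ids, labels$labels$id)
  if (length(bad))
    stop(sprintf("region '%s': unknown label id(s) %s", spec$name,
                 paste(bad, collapse = ", ")))
  m <- array(labels$data %in% spec$ids, dim(labels$data))
  if (spec$op == "erode")
    m <- erode_mask(m, spec$distance, labels$voxdim, name = spec$name)
  if (spec$op == "shell")
    m <- build_extracerebral_shell(m, spec$distance, labels$voxdim)
  if (!any(m))
    stop(sprintf("region '%s' is empty after morphology", spec$name))
  m
}

#' Sample a dynamic volume into regional time-activity curves
#'
#' Per frame, the unweighted mean over the region's voxels. Regions spanning
#' both hemispheres (a spec holding the left and right label ids) are merged
#' by pooling voxels before averaging, i.e. the bilateral mean is the
#' voxel-count-weighted mean of the two hemisphere means.
#'
#' @param img 4D array (x, y, z, frame) or 3D array (single frame).
#' @param labels a [label_volume] on the same grid.
#' @param regions a list of [region_spec] objects (or a single one).
#' @param schedule a [frame_schedule] for the output TACs (4D input only).
#' @param masks optional precomputed [resolve_region_masks()] result;
#'   resolving once and reusing guarantees voxel-identical regions across
#'   scans (and skips repeated distance transforms).
#' @return For 4D input, a named list of [tac] objects; for 3D input, a
#'   named numeric vector of regional means.
#' @export
sample_regions <- function(img, labels, regions, schedule = NULL,
                           masks = NULL) {
  if (inherits(regions, "region_spec")) regions <- list(regions)
  d <- dim(img)
  if (!isTRUE(all.equal(d[1:3], dim(labels$data))))
    stop("image and label grids do not match")
  if (is.null(masks)) masks <- resolve_region_masks(labels, regions)
  nm <- names(masks)
  if (length(d) == 3L) {
    v <- vapply(masks, function(ix) mean(img[ix]), numeric(1))
    names(v) <- nm
    return(v)
  }
  stopifnot(inherits(schedule, "frame_schedule"),
            d[4] == length(schedule$starts))
  mat <- matrix(img, prod(d[1:3]), d[4])
  out <- lapply(seq_along(masks), function(i)
    tac(schedule, colMeans(mat[masks[[i]], , drop = FALSE]), nm[i]))
  names(out) <- nm
  out
}

#' Resolve region specs to voxel index sets
#'
#' Applies each spec's morphology once and returns the voxel indices, for
#' reuse across scans.
#'
#' @inheritParams sample_regions
#' @return Named list of integer voxel index vectors.
#' @export
resolve_region_masks <- function(labels, regions) {
  if (inherits(regions, "region_spec")) regions <- list(regions)
  masks <- lapply(regions, function(s) which(.region_mask(labels, s)))
  names(masks) <- vapply(regions, function(s) s$name, character(1))
  masks
}

#' Read or write a label volume
#'
#' The voxel map is stored as NIfTI; the dictionary as a JSON sidecar with
#' fields `id`, `name`, `hemisphere`, `role`.
#'
#' @param labels a [label_volume].
#' @param path NIfTI path; the dictionary goes to `<path>.labels.json`
#'   (with any `.nii`/`.nii.gz` suffix stripped).
#' @return `read_label_volume` returns a [label_volume].
#' @export
write_label_volume <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  img <- RNifti::asNifti(labels$data)
  RNifti::pixdim(img) <- labels$voxdim
  RNifti::writeNifti(img, path)
  jsonlite::write_json(labels$labels, .sidecar_path(path), digits = NA)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  dict <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  label_volume(array(as.integer(img), dim(img)[1:3]),
               RNifti::pixdim(img)[1:3], dict)
}

.sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")
}
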