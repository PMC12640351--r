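#' Construct a cell mask
#'
#' The voxel set of one segmented cell.  Voxels are 1-based integer grid
#' indices; the centroid is the intensity-free arithmetic mean of the
#' physical voxel centers.
#'
#' @param voxels Integer matrix (n x 3) of voxel indices.
#' @param spacing Micrometres per voxel along x, y, z.
#' @param check Verify that the voxels form a single 26-connected component.
#' @return An object of class `cell_mask`.
#' @export
cell_mask <- function(voxels, spacing = c(0.5, 0.5, 1), check = TRUE) {
  voxels <- matrix(as.integer(voxels), ncol = 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(voxels) < 1L) stop("a cell mask needs at least one voxel")
  if (any(voxels < 1L)) stop("voxel indices must be 1-based positives")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("voxel spacing must be three strictly positive values")
  if (check && nrow(voxels) > 1L && n_mask_components(voxels) != 1L)
    stop("mask voxels are not a single 26-connected component")
  centroid <- colMeans(sweep(voxels - 0.5, 2, spacing, `*`))
  structure(list(voxels = voxels, spacing = spacing, centroid = centroid),
            class = "cell_mask")
}

#' @export
#' @method print cell_mask
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d voxels, centroid (%.2f, %.2f, %.2f) um\n",
              nrow(x$voxels), x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

# 26-neighborhood adjacency lists of a voxel coordinate set
skeleton_adjacency <- function(vox) {
  key <- vox[, 1] + 4096 * (vox[, 2] + 4096 * vox[, 3])
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  adj <- vector("list", nrow(vox))
  for (r in seq_len(nrow(offs))) {
    nk <- (vox[, 1] + offs[r, 1]) +
      4096 * ((vox[, 2] + offs[r, 2]) + 4096 * (vox[, 3] + offs[r, 3]))
    m <- match(nk, key)
    hit <- which(!is.na(m))
    for (i in hit) adj[[i]] <- c(adj[[i]], m[i])
  }
  adj
}

# iteratively remove terminal chains shorter than prune_um that attach to a
# junction voxel (degree >= 3); leaves pure paths and isolated voxels alone
prune_spur_voxels <- function(vox, spacing, prune_um, max_iter = 10L) {
  for (it in seq_len(max_iter)) {
    adj <- skeleton_adjacency(vox)
    deg <- lengths(adj)
    eps <- which(deg == 1L)
    if (length(eps) == 0L) break
    del <- integer(0)
    for (e in eps) {
      path <- e
      prev <- 0L
      cur <- e
      len <- 0
      junction <- FALSE
      repeat {
        nbrs <- setdiff(adj[[cur]], prev)
        if (length(nbrs) == 0L) break
        nxt <- nbrs[1]
        len <- len + sqrt(sum(((vox[nxt, ] - vox[cur, ]) * spacing)^2))
        if (len > prune_um) break
        if (deg[nxt] >= 3L) {
          junction <- TRUE
          break
        }
        if (deg[nxt] == 1L) break  # whole component is a short path; keep
        path <- c(path, nxt)
        prev <- cur
        cur <- nxt
      }
      if (junction && len <= prune_um) del <- c(del, path)
    }
    del <- unique(del)
    if (length(del) == 0L) break
    vox <- vox[-del, , drop = FALSE]
  }
  vox
}

# count 26-connected components of a voxel coordinate set
n_mask_components <- function(voxels) {
  off <- apply(voxels, 2, min) - 1L
  loc <- sweep(voxels, 2, off)
  d <- apply(loc, 2, max)
  arr <- array(FALSE, dim = d)
  arr[loc] <- TRUE
  max(cpp_label_components(as.logical(arr), dim(arr)))
}

#' Segment cells from a 3D stack
#'
#' Binarizes the volume (Otsu threshold by default), labels 26-connected
#' components, and keeps whole cells: components with at least `min_voxels`
#' voxels that do not touch the lateral (x/y) image border.  Cells clipped
#' by the stack's thin z extent are tolerated.
#'
#' @param volume A [voxel_volume()].
#' @param min_voxels Minimum component size in voxels; smaller components
#'   are treated as debris.
#' @param threshold `"otsu"` or a numeric threshold value.
#' @param exclude_border Drop components touching the lateral border
#'   (incomplete cells).
#' @return List of [cell_mask()] objects, in scan order.
#' @export
segment_cells <- function(volume, min_voxels = 50L, threshold = "otsu",
                          exclude_border = TRUE) {
  stopifnot(inherits(volume, "voxel_volume"))
  img <- volume$intensities
  thr <- if (identical(threshold, "otsu")) otsu_threshold(img)
         else as.numeric(threshold)
  bin <- img > thr
  labels <- cpp_label_components(as.logical(bin), dim(img))
  dim(labels) <- dim(img)
  n_lab <- max(labels)
  if (n_lab == 0L) return(list())
  sizes <- tabulate(labels[labels > 0L], n_lab)
  masks <- list()
  for (lab in seq_len(n_lab)) {
    if (sizes[lab] < min_voxels) next
    vox <- which(labels == lab, arr.ind = TRUE)
    colnames(vox) <- c("x", "y", "z")
    if (exclude_border &&
        (any(vox[, 1] == 1L) || any(vox[, 1] == dim(img)[1]) ||
         any(vox[, 2] == 1L) || any(vox[, 2] == dim(img)[2]))) next
    masks[[length(masks) + 1L]] <-
      cell_mask(vox, volume$spacing, check = FALSE)
  }
  masks
}

#' Territorial volume of a cell
#'
#' Volume of the 3D convex hull enclosing all extreme points of the cell.
#' The hull is taken over the corner points of every mask voxel (not the
#' centers), so it always contains the voxel union and the ramification
#' index is guaranteed to be at least 1.
#'
#' @param mask A [cell_mask()].
#' @return Volume in cubic micrometres.
#' @export
territorial_volume <- function(mask) {
  stopifnot(inherits(mask, "cell_mask"))
  corners <- cpp_corner_candidates(mask$voxels - 1L)
  cpp_hull_volume_lattice(corners) * prod(mask$spacing)
}

#' Cell volume
#'
#' Voxel count converted to physical units with the voxel spacing.
#'
#' @param mask A [cell_mask()].
#' @return Volume in cubic micrometres.
#' @export
cell_volume <- function(mask) {
  stopifnot(inherits(mask, "cell_mask"))
  nrow(mask$voxels) * prod(mask$spacing)
}

#' Skeletonize a cell mask
#'
#' Homotopic 3D curve thinning (sequential boundary peeling under a
#' 26/6-connectivity simple-point test, with endpoint preservation).
#' Endpoints are skeleton voxels with exactly one 26-neighbor in the
#' skeleton, branchpoints those with three or more; a single-voxel skeleton
#' has neither.
#'
#' @param mask A [cell_mask()].
#' @param prune_um Terminal spurs shorter than this (micrometres) that end
#'   at a junction are pruned; thinning a thick tube can leave sub-voxel
#'   side twigs that would otherwise count as branches.  0 disables.
#' @return An object of class `skeleton3d` with elements `voxels`,
#'   `spacing`, `degree`, `endpoints`, `branchpoints` (row indices into
#'   `voxels`) and the parent mask `centroid`.
#' @export
skeletonize_cell <- function(mask, prune_um = 2) {
  stopifnot(inherits(mask, "cell_mask"))
  off <- apply(mask$voxels, 2, min) - 1L
  loc <- sweep(mask$voxels, 2, off)
  d <- apply(loc, 2, max)
  arr <- array(FALSE, dim = d)
  arr[loc] <- TRUE
  thin <- cpp_thin_3d(as.logical(arr), dim(arr))
  dim(thin) <- dim(arr)
  vox <- which(thin, arr.ind = TRUE)
  colnames(vox) <- c("x", "y", "z")
  vox <- sweep(vox, 2, off, `+`)
  if (prune_um > 0 && nrow(vox) > 2L)
    vox <- prune_spur_voxels(vox, mask$spacing, prune_um)
  geo <- cpp_skeleton_geodesics(vox, mask$spacing, mask$centroid)
  structure(list(
    voxels = vox, spacing = mask$spacing, degree = geo$degree,
    endpoints = which(geo$degree == 1L),
    branchpoints = which(geo$degree >= 3L),
    centroid = mask$centroid
  ), class = "skeleton3d")
}

#' @export
#' @method print skeleton3d
print.skeleton3d <- function(x, ...) {
  cat(sprintf("<skeleton3d> %d voxels, %d endpoints, %d branchpoints\n",
              nrow(x$voxels), length(x$endpoints), length(x$branchpoints)))
  invisible(x)
}

#' Geodesic branch lengths of a skeleton
#'
#' Traces every skeleton endpoint back to the cell centroid along the
#' skeleton: for each endpoint the length is the shortest-path distance on
#' the 26-adjacency voxel graph (edge weight = Euclidean step between voxel
#' centers) to the skeleton voxel nearest the centroid.  Returns the mean,
#' maximum and minimum over endpoints, or all zeros when the skeleton has
#' no endpoints (process-free cells).  A disconnected skeleton is handled
#' per component (own root nearest the centroid) with a warning.
#'
#' @param skel A `skeleton3d` from [skeletonize_cell()].
#' @param centroid Physical reference point; defaults to the parent cell
#'   centroid stored in the skeleton.
#' @param mode `"geodesic"` (along the skeleton) or `"euclidean"`
#'   (straight-line endpoint-to-centroid chords, for sensitivity checks).
#' @return Named numeric vector `c(avg, max, min)` in micrometres.
#' @export
branch_lengths <- function(skel, centroid = NULL,
                           mode = c("geodesic", "euclidean")) {
  stopifnot(inherits(skel, "skeleton3d"))
  mode <- match.arg(mode)
  if (is.null(centroid)) centroid <- skel$centroid
  if (length(skel$endpoints) == 0L)
    return(c(avg = 0, max = 0, min = 0))
  if (mode == "euclidean") {
    cen <- sweep(sweep(skel$voxels[skel$endpoints, , drop = FALSE] - 0.5,
                       2, skel$spacing, `*`), 2, centroid)
    len <- sqrt(rowSums(cen^2))
  } else {
    geo <- cpp_skeleton_geodesics(skel$voxels, skel$spacing, centroid)
    if (geo$n_components > 1L)
      warning(sprintf("skeleton has %d disconnected components; using %s",
                      geo$n_components, "per-component roots"))
    len <- geo$dist[skel$endpoints]
  }
  c(avg = mean(len), max = max(len), min = min(len))
}

#' Extract the eight morphometric features of a cell
#'
#' Assembles territorial volume, cell volume, ramification index
#' (territorial / cell volume), endpoint and branchpoint counts, and the
#' average / maximum / minimum geodesic branch length.
#'
#' @param mask A [cell_mask()].
#' @param branch_mode Passed to [branch_lengths()].
#' @return One-row data frame with the canonical feature columns
#'   ([microglia_features()]).
#' @export
extract_features <- function(mask, branch_mode = "geodesic") {
  tv <- territorial_volume(mask)
  cv <- cell_volume(mask)
  skel <- skeletonize_cell(mask)
  bl <- branch_lengths(skel, mode = branch_mode)
  data.frame(
    territorial_volume = tv,
    cell_volume = cv,
    ramification_index = tv / cv,
    n_endpoints = length(skel$endpoints),
    n_branchpoints = length(skel$branchpoints),
    avg_branch_length = unname(bl["avg"]),
    max_branch_length = unname(bl["max"]),
    min_branch_length = unname(bl["min"])
  )
}

#' Segment a stack and extract features for every cell
#'
#' Convenience wrapper: [segment_cells()] then [extract_features()] per
#' cell, returning one row per segmented cell.
#'
#' @inheritParams segment_cells
#' @param branch_mode Passed to [branch_lengths()].
#' @return Data frame with `cell_id` and the eight feature columns; zero
#'   rows when nothing is segmented.
#' @export
extract_stack_features <- function(volume, min_voxels = 50L,
                                   threshold = "otsu",
                                   exclude_border = TRUE,
                                   branch_mode = "geodesic") {
  masks <- segment_cells(volume, min_voxels, threshold, exclude_border)
  if (length(masks) == 0L) {
    out <- cbind(data.frame(cell_id = integer(0)),
                 as.data.frame(setNames(rep(list(numeric(0)), 8), .FEATURES)))
    return(out)
  }
  rows <- lapply(masks, extract_features, branch_mode = branch_mode)
  cbind(data.frame(cell_id = seq_along(masks)), do.call(rbind, rows))
}
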