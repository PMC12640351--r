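#' Morphology parameters for a synthetic microglia-like cell
#'
#' Describes one of the three morphology classes.  Ramified cells have many
#' long, branching processes; rod-like cells have an elongated soma and few
#' short processes; amoeboid cells are a compact soma with no processes.
#'
#' @param morphology_class One of `"ramified"`, `"rod"`, `"amoeboid"`.
#' @param soma_radius Soma radius in micrometres (> 0).
#' @param soma_elongation Axial stretch factor of the soma (>= 1).
#' @param n_primary_processes Number of processes sprouting from the soma
#'   (integer >= 0; must be 0 for amoeboid).
#' @param mean_process_length Mean total length of a primary process in
#'   micrometres (>= 0).
#' @param branching_prob Probability of spawning a side branch per
#'   micrometre of process growth, in \[0, 1\].
#' @param process_radius Process (tube) radius in micrometres (> 0).
#' @return An object of class `morphology_params`.
#' @export
morphology_params <- function(morphology_class, soma_radius, soma_elongation,
                              n_primary_processes, mean_process_length,
                              branching_prob, process_radius) {
  morphology_class <- match.arg(morphology_class, .CLASSES)
  stopifnot(soma_radius > 0, soma_elongation >= 1,
            n_primary_processes >= 0,
            n_primary_processes == as.integer(n_primary_processes),
            mean_process_length >= 0,
            branching_prob >= 0, branching_prob <= 1, process_radius > 0)
  if (morphology_class == "amoeboid" && n_primary_processes != 0)
    stop("amoeboid cells have no processes (n_primary_processes must be 0)")
  structure(list(
    morphology_class = morphology_class,
    soma_radius = soma_radius,
    soma_elongation = soma_elongation,
    n_primary_processes = as.integer(n_primary_processes),
    mean_process_length = mean_process_length,
    branching_prob = branching_prob,
    process_radius = process_radius
  ), class = "morphology_params")
}

#' Default morphology presets for the three classes
#'
#' Ramified: small soma, six long branching processes.  Rod: elongated
#' soma, two short processes.  Amoeboid: enlarged round soma, no processes.
#' Under these presets the extracted ramification index orders
#' ramified > rod > amoeboid.
#'
#' @return Named list of [morphology_params()] (ramified, rod, amoeboid).
#' @export
morphology_presets <- function() {
  list(
    ramified = morphology_params("ramified", soma_radius = 3,
                                 soma_elongation = 1, n_primary_processes = 6,
                                 mean_process_length = 28,
                                 branching_prob = 0.08, process_radius = 0.8),
    rod = morphology_params("rod", soma_radius = 3.2, soma_elongation = 2.8,
                            n_primary_processes = 2,
                            mean_process_length = 10,
                            branching_prob = 0.02, process_radius = 0.8),
    amoeboid = morphology_params("amoeboid", soma_radius = 4.5,
                                 soma_elongation = 1, n_primary_processes = 0,
                                 mean_process_length = 0,
                                 branching_prob = 0, process_radius = 0.8)
  )
}

# unit vector with damped z component (cells spread mostly in-plane
# because the imaged stacks are thin along z)
rand_direction <- function(z_damp = 0.25) {
  v <- c(rnorm(2), rnorm(1) * z_damp)
  v / sqrt(sum(v^2))
}

# grow one process as a persistent random walk; returns stamp centers and
# recursively spawned branches
grow_process <- function(start, direction, length_total, branching_prob,
                         z_limit = Inf, step = 0.5, persistence = 0.75,
                         z_damp = 0.25, depth = 1L, max_depth = 4L) {
  centers <- list()
  pos <- start
  dir <- direction
  grown <- 0
  while (grown < length_total) {
    jitter <- c(rnorm(2), rnorm(1) * z_damp) * (1 - persistence)
    dir <- dir * persistence + jitter
    dir <- dir / sqrt(sum(dir^2))
    pos <- pos + dir * step
    # keep processes inside the thin optical section (reflecting boundary)
    if (abs(pos[3]) > z_limit) {
      pos[3] <- sign(pos[3]) * (2 * z_limit - abs(pos[3]))
      dir[3] <- -dir[3]
    }
    grown <- grown + step
    centers[[length(centers) + 1L]] <- pos
    if (depth < max_depth && runif(1) < branching_prob * step) {
      rot <- rand_direction(z_damp)
      bdir <- dir * 0.5 + rot * 0.5
      bdir <- bdir / sqrt(sum(bdir^2))
      sub <- grow_process(pos, bdir, (length_total - grown) * 0.7,
                          branching_prob, z_limit, step, persistence,
                          z_damp, depth + 1L, max_depth)
      centers <- c(centers, sub)
    }
  }
  centers
}

#' Generate one synthetic 3D cell mask
#'
#' Builds a soma (possibly elongated ellipsoid) plus a stochastic branching
#' random walk of tubular processes, rasterized onto a voxel grid.  The
#' result is a single 26-connected component; generation is deterministic
#' for a fixed seed.
#'
#' @param params A [morphology_params()].
#' @param spacing Micrometres per voxel along x, y, z.
#' @param seed Integer seed (required for reproducibility).
#' @param z_extent Physical z budget in micrometres; processes stay within
#'   it to mimic thin optical stacks.
#' @return A [cell_mask()] on a local grid just covering the cell.
#' @export
generate_cell <- function(params, spacing = c(0.5, 0.5, 1), seed = 1,
                          z_extent = 16) {
  stopifnot(inherits(params, "morphology_params"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("degenerate spacing: all axes must be > 0")
  with_seed(seed, {
    # soma: ellipsoid stretched along a random in-plane axis
    theta <- runif(1, 0, pi)
    axis1 <- c(cos(theta), sin(theta), 0)
    axis2 <- c(-sin(theta), cos(theta), 0)
    axis3 <- c(0, 0, 1)
    semi <- c(params$soma_radius * params$soma_elongation,
              params$soma_radius,
              min(params$soma_radius, z_extent / 2.5))

    centers <- list()
    radii <- numeric(0)
    if (params$n_primary_processes > 0) {
      for (p in seq_len(params$n_primary_processes)) {
        dir <- rand_direction()
        # start on the soma surface (slightly inset to stay connected)
        surf <- dir * 0.9 * min(semi[1], semi[2])
        len <- max(2, rnorm(1, params$mean_process_length,
                            0.3 * params$mean_process_length))
        centers <- c(centers,
                     grow_process(surf, dir, len, params$branching_prob,
                                  z_limit = z_extent / 2 -
                                    params$process_radius))
      }
      radii <- rep(params$process_radius, length(centers))
    }

    # physical bounding box
    pts <- if (length(centers)) do.call(rbind, centers) else
      matrix(0, 0, 3)
    ext <- max(semi) + params$process_radius + 1
    lo <- pmin(if (nrow(pts)) apply(pts, 2, min) else c(0, 0, 0), -ext) -
      params$process_radius - 1
    hi <- pmax(if (nrow(pts)) apply(pts, 2, max) else c(0, 0, 0), ext) +
      params$process_radius + 1
    dims <- pmax(ceiling((hi - lo) / spacing), 3L)

    arr <- array(FALSE, dim = dims)
    # voxel centers in physical coordinates relative to the soma center
    axc <- lapply(1:3, function(a) lo[a] + (seq_len(dims[a]) - 0.5) * spacing[a])

    stamp_ball <- function(center, radius) {
      rng <- lapply(1:3, function(a) {
        which(abs(axc[[a]] - center[a]) <= radius + spacing[a])
      })
      if (any(lengths(rng) == 0)) return()
      gx <- axc[[1]][rng[[1]]] - center[1]
      gy <- axc[[2]][rng[[2]]] - center[2]
      gz <- axc[[3]][rng[[3]]] - center[3]
      d2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
      arr[rng[[1]], rng[[2]], rng[[3]]] <<-
        arr[rng[[1]], rng[[2]], rng[[3]]] | (d2 <= radius^2)
    }

    # soma ellipsoid
    rngs <- lapply(1:3, function(a) which(abs(axc[[a]]) <= max(semi) + spacing[a]))
    gx <- axc[[1]][rngs[[1]]]
    gy <- axc[[2]][rngs[[2]]]
    gz <- axc[[3]][rngs[[3]]]
    grid <- expand.grid(x = gx, y = gy, z = gz)
    pm <- as.matrix(grid)
    q <- (pm %*% axis1 / semi[1])^2 + (pm %*% axis2 / semi[2])^2 +
      (pm %*% axis3 / semi[3])^2
    sub <- array(q <= 1, dim = lengths(rngs))
    arr[rngs[[1]], rngs[[2]], rngs[[3]]] <-
      arr[rngs[[1]], rngs[[2]], rngs[[3]]] | sub

    if (length(centers))
      for (i in seq_along(centers)) stamp_ball(centers[[i]], radii[i])

    # keep the component containing the soma center
    labels <- cpp_label_components(as.logical(arr), dims)
    dim(labels) <- dims
    soma_idx <- pmin(pmax(ceiling((-lo) / spacing), 1L), dims)
    keep <- labels[soma_idx[1], soma_idx[2], soma_idx[3]]
    if (keep == 0L) keep <- labels[which.max(labels > 0L)]
    vox <- which(labels == keep, arr.ind = TRUE)
    colnames(vox) <- c("x", "y", "z")
    cell_mask(vox, spacing, check = FALSE)
  })
}

#' Render a synthetic ROI stack with ground truth
#'
#' Places cells in a region of interest (default 256 x 256 x 20 um),
#' rejecting soma-soma overlap, and renders an intensity stack: bright
#' cells over dark noisy background, optional Gaussian blur emulating the
#' point-spread function, quantized to the 16-bit grid.
#'
#' @param cells List of [morphology_params()], one per cell to place.
#' @param roi_edge Lateral ROI size in micrometres.
#' @param depth Stack depth in micrometres.
#' @param spacing Micrometres per voxel.
#' @param seed Integer seed.
#' @param foreground,background,noise_sd Intensity model (cells at
#'   `foreground`, Gaussian background noise).
#' @param blur_sigma Gaussian blur sigma in micrometres (0 disables).
#' @param min_separation Factor on the sum of soma radii below which a
#'   placement is rejected.
#' @param max_retries Placement attempts per cell before failing.
#' @return List with `volume` (a [voxel_volume()]), `truth` (data frame:
#'   cell_id, class, centroid), and `masks` (the placed [cell_mask()]s).
#' @export
render_roi <- function(cells, roi_edge = 256, depth = 20,
                       spacing = c(0.5, 0.5, 1), seed = 1,
                       foreground = 0.85, background = 0.08,
                       noise_sd = 0.02, blur_sigma = 0.5,
                       min_separation = 1.5, max_retries = 1000L) {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("degenerate spacing: all axes must be > 0")
  dims <- pmax(round(c(roi_edge / spacing[1], roi_edge / spacing[2],
                       depth / spacing[3])), 1L)
  seeds <- derive_seeds(seed, length(cells) + 1L)
  with_seed(seeds[length(seeds)], {
    placed <- list()
    somas <- matrix(numeric(0), 0, 3)
    radii <- numeric(0)
    truth <- list()
    for (i in seq_along(cells)) {
      p <- cells[[i]]
      mask <- generate_cell(p, spacing, seed = seeds[i],
                            z_extent = min(depth, 16))
      bb <- apply(mask$voxels, 2, range)
      # half-extent plus a blur margin so smoothed tails stay off the border
      half <- (bb[2, ] - bb[1, ] + 1) * spacing / 2 +
        c(2 * blur_sigma + spacing[1], 2 * blur_sigma + spacing[2], 0)
      ok <- FALSE
      extent <- c(roi_edge, roi_edge, depth)
      if (any(half * 2 > extent))
        stop("cell larger than the ROI; enlarge roi_edge/depth")
      for (try in seq_len(max_retries)) {
        pos <- vapply(1:3, function(a) {
          if (half[a] * 2 >= extent[a]) extent[a] / 2
          else runif(1, half[a], extent[a] - half[a])
        }, numeric(1))
        if (nrow(somas) == 0L ||
            all(sqrt(rowSums(sweep(somas, 2, pos)^2)) >
                (radii + p$soma_radius) * min_separation)) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf("could not place %d cells without soma overlap", length(cells)))
      # translate the local mask so that its bounding-box center sits at pos
      ctr_vox <- (bb[1, ] + bb[2, ]) / 2
      shift <- round(pos / spacing - ctr_vox)
      vox <- sweep(mask$voxels, 2, as.integer(shift), `+`)
      inside <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
        vox[, 2] >= 1 & vox[, 2] <= dims[2] &
        vox[, 3] >= 1 & vox[, 3] <= dims[3]
      vox <- vox[inside, , drop = FALSE]
      if (nrow(vox) == 0L)
        stop("cell fell entirely outside the ROI; enlarge the ROI")
      m <- cell_mask(vox, spacing, check = FALSE)
      placed[[i]] <- m
      somas <- rbind(somas, pos)
      radii <- c(radii, p$soma_radius)
      truth[[i]] <- data.frame(
        cell_id = i, class = p$morphology_class,
        centroid_x = m$centroid[1], centroid_y = m$centroid[2],
        centroid_z = m$centroid[3])
    }

    img <- array(rnorm(prod(dims), background, noise_sd), dim = dims)
    for (m in placed)
      img[m$voxels] <- foreground + rnorm(nrow(m$voxels), 0, noise_sd)
    if (blur_sigma > 0) img <- gaussian_blur_3d(img, blur_sigma / spacing)
    img <- pmin(pmax(img, 0), 1)
    img <- round(img * 65535) / 65535  # 16-bit grid; TIFF round trips exactly

    list(volume = voxel_volume(img, spacing),
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(cell_id = integer(0), class = character(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      centroid_z = numeric(0)),
         masks = placed)
  })
}

# separable Gaussian blur; sigma given per axis in voxels
gaussian_blur_3d <- function(img, sigma_vox) {
  d <- dim(img)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    hw <- max(1L, ceiling(2 * s))
    k <- exp(-(seq(-hw, hw))^2 / (2 * s^2))
    k <- k / sum(k)
    out <- array(0, dim = d)
    for (o in seq(-hw, hw)) {
      w <- k[o + hw + 1]
      idx <- pmin(pmax(seq_len(d[ax]) + o, 1L), d[ax])  # replicate edges
      out <- out + w * switch(ax,
                              img[idx, , , drop = FALSE],
                              img[, idx, , drop = FALSE],
                              img[, , idx, drop = FALSE])
    }
    img <- out
  }
  img
}
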