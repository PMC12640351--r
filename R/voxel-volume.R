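#' Construct a voxel volume
#'
#' A single-channel 3D image with physical voxel spacing.  The spacing is
#' the edge length of one voxel along x, y and z in micrometres; all
#' downstream geometry (volumes, branch lengths) is reported in physical
#' units derived from it.
#'
#' @param intensities 3D numeric array (x, y, z).
#' @param spacing Numeric length-3, micrometres per voxel along x, y, z;
#'   strictly positive.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensities, spacing = c(0.5, 0.5, 1)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("'intensities' must be a 3D array")
  if (any(dim(intensities) == 0L)) stop("image grid is empty")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing must be three strictly positive values")
  structure(list(intensities = intensities, spacing = spacing),
            class = "voxel_volume")
}

#' @export
#' @method print voxel_volume
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g um\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Read a multi-page TIFF stack as a voxel volume
#'
#' Each TIFF page is one optical section (z-slice).  The file must be single
#' channel; spacing is supplied by the caller (stacks written by
#' [write_stack()] do not embed calibrated spacing).
#'
#' @param path Path to a multi-page TIFF file.
#' @param spacing Micrometres per voxel along x, y, z.
#' @return A [voxel_volume()].
#' @export
read_stack <- function(path, spacing = c(0.5, 0.5, 1)) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) > 2L)
    stop("multi-channel TIFF without a channel selector: ", path)
  nx <- nrow(pages[[1]]); ny <- ncol(pages[[1]])
  arr <- array(0, dim = c(nx, ny, length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]]
  voxel_volume(arr, spacing)
}

#' Write a voxel volume as a 16-bit multi-page TIFF
#'
#' Intensities must already lie in \[0, 1\]; they are stored at 16-bit
#' depth, one page per z-slice.
#'
#' @param volume A [voxel_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  img <- volume$intensities
  if (min(img) < 0 || max(img) > 1)
    stop("intensities must be in [0, 1] for 16-bit TIFF output")
  pages <- lapply(seq_len(dim(img)[3]), function(z) img[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Otsu threshold of an intensity sample
#'
#' Maximizes the between-class variance over a 256-bin histogram; used as
#' the default automated binarization for segmentation.
#'
#' @param x Numeric vector (or array) of intensities.
#' @param n_bins Number of histogram bins.
#' @return The threshold value (bin midpoint).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  r <- range(x)
  if (diff(r) == 0) stop("no threshold: image intensity is constant")
  bin <- pmin(n_bins, 1L + floor((x - r[1]) / diff(r) * n_bins))
  h <- tabulate(bin, n_bins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(n_bins) - 0.5) * diff(r) / n_bins
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}
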