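# extract the numeric feature matrix used for clustering
cluster_matrix <- function(tab, features = NULL) {
  if (is.matrix(tab)) return(tab)
  fc <- if (is.null(features)) feature_columns(tab) else features
  if (length(fc) == 0L) fc <- names(tab)[vapply(tab, is.numeric, logical(1))]
  as.matrix(tab[, fc, drop = FALSE])
}

#' Partitioning around medoids (PAM)
#'
#' Classic PAM under Euclidean distance: greedy BUILD seeding followed by
#' best-improvement SWAP until no single medoid/non-medoid exchange lowers
#' the total cost (sum of distances of every point to its medoid).  Cells
#' are assigned to the nearest medoid, ties to the lowest medoid index.
#'
#' @param tab Feature table (scaled) or numeric matrix.
#' @param k Number of clusters.
#' @param features Optional feature subset to cluster on.
#' @return An object of class `cluster_model`: `k`, `medoids` (row
#'   indices), `medoid_ids` (cell_id values when present), `assignment`,
#'   `cost`, `medoid_distance`.
#' @export
pam_cluster <- function(tab, k, features = NULL) {
  x <- cluster_matrix(tab, features)
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of cells")
  if (k > nrow(unique(x))) stop("k exceeds the number of distinct points")
  D <- cpp_dist_matrix(x)
  fit <- cpp_pam(D, as.integer(k))
  ids <- if (is.data.frame(tab) && "cell_id" %in% names(tab))
    tab$cell_id[fit$medoids] else fit$medoids
  structure(list(
    k = as.integer(k), medoids = fit$medoids, medoid_ids = ids,
    assignment = fit$assignment, cost = fit$cost,
    medoid_distance = fit$medoid_distance, features = colnames(x)
  ), class = "cluster_model")
}

#' @export
#' @method print cluster_model
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, cost = %.4f\n", x$k, x$cost))
  cat("sizes:", paste(tabulate(x$assignment, x$k), collapse = ", "), "\n")
  invisible(x)
}

# within-cluster sum of squares of a PAM partition (pairwise identity)
partition_wcss <- function(D, assignment, k) {
  cpp_pooled_within_dispersion(D, as.integer(assignment), as.integer(k))
}

#' Within-cluster sum of squares over a range of k
#'
#' WCSS (the elbow-plot dispersion) computed from PAM partitions at each k,
#' via the pairwise identity sum_r D_r / (2 n_r) with squared Euclidean
#' distances, which equals the summed squared distances to cluster means.
#'
#' @param tab Feature table or matrix.
#' @param k_range Integer vector of cluster counts.
#' @param features Optional feature subset.
#' @return Data frame with columns `k` and `wcss`.
#' @export
wcss_curve <- function(tab, k_range = 1:8, features = NULL) {
  x <- cluster_matrix(tab, features)
  if (any(k_range > nrow(x))) stop("k exceeds the number of cells")
  D <- cpp_dist_matrix(x)
  w <- vapply(k_range, function(k) {
    fit <- cpp_pam(D, as.integer(k))
    partition_wcss(D, fit$assignment, k)
  }, numeric(1))
  data.frame(k = as.integer(k_range), wcss = w)
}

#' Gap statistic for choosing the number of clusters
#'
#' Compares the log within-cluster dispersion of PAM partitions of the data
#' to that of B reference datasets drawn uniformly over the per-feature
#' bounding box of the data: Gap(k) = mean_b log W*_kb - log W_k.  The
#' chosen k is the global gap maximum (the "highest gap value" rule); the
#' conservative one-standard-error rule is available via `rule = "1se"`.
#'
#' @param tab Feature table (scaled) or matrix.
#' @param k_range Candidate cluster counts.
#' @param B Number of reference datasets (>= 10).
#' @param seed Integer seed (references are deterministic given it).
#' @param features Optional feature subset.
#' @param rule `"max"` (global maximum) or `"1se"` (smallest k with
#'   Gap(k) >= Gap(k+1) - s_{k+1}).
#' @return An object of class `gap_curve`: data frame of k, wcss, log_w,
#'   mean reference log W, gap, and reference SE, plus the chosen k.
#' @export
gap_statistic <- function(tab, k_range = 1:8, B = 50L, seed = 1L,
                          features = NULL, rule = c("max", "1se")) {
  rule <- match.arg(rule)
  if (length(k_range) == 0L) stop("k_range is empty")
  if (B < 10L) stop("B must be at least 10")
  x <- cluster_matrix(tab, features)
  n <- nrow(x)
  if (any(k_range > n)) stop("k exceeds the number of cells")
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)

  log_w_of <- function(mat) {
    D <- cpp_dist_matrix(mat)
    vapply(k_range, function(k) {
      fit <- cpp_pam(D, as.integer(k))
      log(partition_wcss(D, fit$assignment, k))
    }, numeric(1))
  }

  log_w <- log_w_of(x)
  ref <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      r <- matrix(runif(n * ncol(x)), n, ncol(x))
      r <- sweep(sweep(r, 2, hi - lo, `*`), 2, lo, `+`)
      log_w_of(r)
    }, numeric(length(k_range)))
  })
  ref <- matrix(ref, nrow = length(k_range))
  mean_ref <- rowMeans(ref)
  sd_ref <- apply(ref, 1, sd)
  se <- sd_ref * sqrt(1 + 1 / B)
  gap <- mean_ref - log_w

  chosen <- if (rule == "max") {
    k_range[which.max(gap)]
  } else {
    pick <- length(k_range)
    for (i in seq_len(length(k_range) - 1L))
      if (gap[i] >= gap[i + 1L] - se[i + 1L]) { pick <- i; break }
    k_range[pick]
  }
  # a structureless dataset gives a flat gap curve: the maximum does not
  # rise above the baseline (k = 1) gap by more than the combined noise
  imax <- which.max(gap)
  base <- if (1L %in% k_range) which(k_range == 1L) else 1L
  low_contrast <- gap[imax] - gap[base] <
    3 * sqrt(se[imax]^2 + se[base]^2)
  if (low_contrast)
    warning("gap curve has low contrast; the chosen k is weakly supported")
  structure(list(
    table = data.frame(k = as.integer(k_range), log_w = log_w,
                       mean_ref_log_w = mean_ref, gap = gap, se = se),
    k = chosen, B = as.integer(B), rule = rule,
    low_contrast = low_contrast
  ), class = "gap_curve")
}

#' @export
#' @method print gap_curve
print.gap_curve <- function(x, ...) {
  cat(sprintf("<gap_curve> chosen k = %d (rule: %s, B = %d)\n",
              x$k, x$rule, x$B))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.gap_curve <- function(x, ...) {
  with(x$table, {
    plot(k, gap, type = "b", xlab = "number of clusters k",
         ylab = "gap statistic", ...)
    arrows(k, gap - se, k, gap + se, angle = 90, code = 3, length = 0.04)
  })
  abline(v = x$k, lty = 2)
  invisible(x)
}

#' UMAP embedding of the feature space
#'
#' Two-dimensional uniform manifold approximation and projection of the
#' scaled feature table, used for visualization and outlier display only;
#' clustering itself runs in the scaled feature space.
#'
#' @param tab Feature table (scaled) or matrix.
#' @param n_neighbors Local neighborhood size.
#' @param min_dist Minimum embedding distance (cluster spread).
#' @param seed Integer seed; the embedding is deterministic given it.
#' @param features Optional feature subset.
#' @return An object of class `embedding2d` with `coords` (n x 2) and the
#'   parameters.
#' @export
umap_embed <- function(tab, n_neighbors = 7, min_dist = 0.001, seed = 1L,
                       features = NULL) {
  x <- cluster_matrix(tab, features)
  if (nrow(x) < n_neighbors + 1)
    stop("need at least n_neighbors + 1 cells for a UMAP embedding")
  coords <- with_seed(seed, {
    uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
               metric = "euclidean", n_threads = 1, n_sgd_threads = 0,
               verbose = FALSE)
  })
  colnames(coords) <- c("umap1", "umap2")
  structure(list(coords = coords,
                 params = list(n_neighbors = n_neighbors,
                               min_dist = min_dist, metric = "euclidean",
                               seed = seed)),
            class = "embedding2d")
}

#' @export
plot.embedding2d <- function(x, cluster = NULL, medoids = NULL, ...) {
  col <- if (is.null(cluster)) "grey30" else cluster + 1L
  plot(x$coords, col = col, pch = 16, cex = 0.4,
       xlab = "UMAP 1", ylab = "UMAP 2", ...)
  if (!is.null(medoids))
    points(x$coords[medoids, , drop = FALSE], pch = 8, cex = 1.5, lwd = 2)
  invisible(x)
}

#' Flag and remove per-cluster outliers
#'
#' Within each cluster a cell is an outlier when its distance to the medoid
#' exceeds the cluster median plus 3 robust (MAD-based) standard deviations
#' of the cluster's medoid distances.  Clusters with fewer than 5 cells are
#' skipped with a warning.
#'
#' @param model A `cluster_model` from [pam_cluster()].
#' @param tab The table the model was fitted on (same row order).
#' @param n_sd Robust z cutoff.
#' @return List with `table` (rows kept), `outliers` (report with
#'   distances) and `keep` (logical index).
#' @export
remove_outliers <- function(model, tab, n_sd = 3) {
  stopifnot(inherits(model, "cluster_model"))
  n <- length(model$assignment)
  stopifnot(nrow(tab) == n)
  out_flag <- logical(n)
  for (cl in seq_len(model$k)) {
    idx <- which(model$assignment == cl)
    if (length(idx) < 5L) {
      warning(sprintf("cluster %d has fewer than 5 cells; outlier rule skipped", cl))
      next
    }
    d <- model$medoid_distance[idx]
    cut <- median(d) + n_sd * mad(d)
    out_flag[idx] <- d > cut
  }
  report <- data.frame(
    row = which(out_flag),
    cluster = model$assignment[out_flag],
    medoid_distance = model$medoid_distance[out_flag])
  if ("cell_id" %in% names(tab)) report$cell_id <- tab$cell_id[out_flag]
  kept <- tab[!out_flag, , drop = FALSE]
  rownames(kept) <- NULL
  list(table = kept, outliers = report, keep = !out_flag)
}

#' Map the three clusters to microglial states
#'
#' Rubric: the activated cluster has the lowest median average branch
#' length (amoeboid cells have few or no processes); ties fall to the
#' lower median branchpoint count, then to the higher median cell volume
#' (activated somata are enlarged).  Of the remaining clusters the one
#' with the higher median territorial volume is surveillant (ramified
#' arbors claim the most territory), and the third is primed.
#'
#' @param model A `cluster_model` with k = 3.
#' @param tab The (unscaled) feature table the model rows correspond to;
#'   must contain avg_branch_length, n_branchpoints, cell_volume and
#'   territorial_volume.
#' @return An object of class `state_map`: named character vector
#'   cluster -> state plus an `evidence` attribute of per-cluster feature
#'   medians.
#' @export
assign_states <- function(model, tab) {
  stopifnot(inherits(model, "cluster_model"))
  if (model$k != 3L)
    stop("states are defined only for k = 3 clusters (got k = ", model$k, ")")
  stopifnot(nrow(tab) == length(model$assignment))
  need <- c("avg_branch_length", "n_branchpoints", "cell_volume",
            "territorial_volume")
  if (!all(need %in% names(tab)))
    stop("feature table lacks: ", paste(setdiff(need, names(tab)), collapse = ", "))
  med <- do.call(rbind, lapply(1:3, function(cl) {
    idx <- model$assignment == cl
    vapply(tab[idx, need, drop = FALSE], median, numeric(1))
  }))
  rownames(med) <- paste0("cluster", 1:3)

  ord <- order(med[, "avg_branch_length"], med[, "n_branchpoints"],
               -med[, "cell_volume"])
  activated <- ord[1]
  if (med[ord[1], "avg_branch_length"] == med[ord[2], "avg_branch_length"])
    message("tie on median branch length; resolved by branchpoints/cell volume")
  rest <- setdiff(1:3, activated)
  surveillant <- rest[which.max(med[rest, "territorial_volume"])]
  primed <- setdiff(rest, surveillant)

  map <- character(3)
  map[activated] <- "activated"
  map[surveillant] <- "surveillant"
  map[primed] <- "primed"
  names(map) <- paste0("cluster", 1:3)
  structure(map, evidence = med, class = "state_map")
}

#' @export
#' @method print state_map
print.state_map <- function(x, ...) {
  cat("<state_map>\n")
  for (i in seq_along(x)) cat(" ", names(x)[i], "->", x[i], "\n")
  cat("evidence (per-cluster medians):\n")
  print(attr(x, "evidence"), digits = 4)
  invisible(x)
}

#' Per-cell state labels from a model and state map
#'
#' @param model A `cluster_model`.
#' @param state_map A `state_map` from [assign_states()].
#' @return Character vector of states, one per cell.
#' @export
state_labels <- function(model, state_map) {
  unname(state_map[model$assignment])
}
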