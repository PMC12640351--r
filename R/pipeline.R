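#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline with the published defaults:
#' correlation filter threshold 0.9, gap statistic over k = 1..8 with
#' B = 50 references, UMAP with n_neighbors = 7 and min_dist = 0.001,
#' robust medoid-distance outlier cutoff 3.
#'
#' @param spacing Voxel spacing in micrometres.
#' @param min_voxels Minimum segmented component size.
#' @param threshold `"otsu"` or a numeric value.
#' @param corr_threshold Redundancy filter cutoff.
#' @param k_range Candidate cluster counts for the gap statistic.
#' @param gap_B Reference datasets for the gap statistic.
#' @param k Fixed cluster count; `NULL` selects by gap statistic.
#' @param umap_neighbors,umap_min_dist UMAP parameters.
#' @param cluster_space `"umap"` (PAM on the 2D embedding, the published
#'   order: reduce, then cluster) or `"features"` (PAM on the scaled
#'   feature space).
#' @param outlier_sd Robust z cutoff for per-cluster outliers.
#' @param seed Master seed (every stage derives its own stream from it).
#' @return An object of class `run_config`.
#' @export
run_config <- function(spacing = c(0.5, 0.5, 1), min_voxels = 50L,
                       threshold = "otsu", corr_threshold = 0.9,
                       k_range = 1:8, gap_B = 50L, k = NULL,
                       umap_neighbors = 7, umap_min_dist = 0.001,
                       cluster_space = c("umap", "features"),
                       outlier_sd = 3, seed = 1L) {
  cluster_space <- match.arg(cluster_space)
  structure(list(
    spacing = spacing, min_voxels = min_voxels, threshold = threshold,
    corr_threshold = corr_threshold, k_range = k_range, gap_B = gap_B,
    k = k, umap_neighbors = umap_neighbors, umap_min_dist = umap_min_dist,
    cluster_space = cluster_space,
    outlier_sd = outlier_sd, seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Write / read a feature or result table as CSV
#'
#' Plain CSV with full double precision, so a round trip preserves values
#' to better than 1e-9.
#'
#' @param tab Data frame.
#' @param path File path.
#' @return `read_table` returns the data frame; `write_table` the path.
#' @export
write_table <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Run the full phenotyping pipeline on a feature table
#'
#' Cleaning (missing-value removal), z-scoring, correlation-redundancy
#' filtering, cluster-count selection by gap statistic (unless fixed),
#' PAM clustering, UMAP embedding, per-cluster outlier removal, state
#' assignment, and the statistical battery on per-animal proportions.
#' Writes stage CSVs and a JSON manifest when `out_dir` is given.
#'
#' @param features Per-cell feature table with metadata columns
#'   (animal_id, sex, group, roi_index); e.g. from
#'   [generate_feature_table()] or stack extraction.
#' @param config A [run_config()].
#' @param out_dir Optional output directory for stage CSVs and the
#'   manifest.
#' @return List with the fitted objects, result tables, and `manifest`
#'   (stage row counts that reconcile: segmented - missing - outliers =
#'   analyzed).
#' @export
run_all <- function(features, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 3L)
  n_segmented <- nrow(features)

  complete <- drop_incomplete_cells(features)
  n_missing <- attr(complete, "n_dropped")

  scaled <- zscore_scale(complete)
  corr <- correlation_matrix(scaled)
  retained <- filter_redundant_features(corr, config$corr_threshold)

  gap <- NULL
  k <- config$k
  if (is.null(k)) {
    gap <- gap_statistic(scaled, k_range = config$k_range, B = config$gap_B,
                         seed = seeds[1], features = retained)
    k <- gap$k
  }
  embedding <- umap_embed(scaled, n_neighbors = config$umap_neighbors,
                          min_dist = config$umap_min_dist, seed = seeds[2],
                          features = retained)
  model <- if (config$cluster_space == "umap")
    pam_cluster(embedding$coords, k)
  else
    pam_cluster(scaled, k, features = retained)
  ol <- remove_outliers(model, complete, n_sd = config$outlier_sd)
  n_outliers <- sum(!ol$keep)

  states <- NULL
  assignments <- NULL
  stats <- NULL
  if (k == 3L) {
    states <- assign_states(model, complete)
    assignments <- complete
    assignments$cluster <- model$assignment
    assignments$state <- state_labels(model, states)
    assignments$outlier <- !ol$keep
    analyzed <- assignments[!assignments$outlier, , drop = FALSE]
    if (all(c("animal_id", "sex", "group") %in% names(analyzed))) {
      props <- per_animal_proportions(analyzed, "all")
      stats <- list(
        proportions = props,
        group_means = group_normalize(props),
        comparisons = tryCatch(run_comparisons(props),
                               error = function(e) NULL),
        sex_differences = tryCatch(sex_comparisons(analyzed),
                                   error = function(e) NULL),
        anova = tryCatch(two_way_anova(proportions_long(props)),
                         error = function(e) NULL))
    }
  } else {
    warning("chosen k != 3; state mapping and group statistics skipped")
  }

  manifest <- list(
    config = unclass(config),
    n_segmented = n_segmented,
    n_missing_dropped = n_missing,
    n_outliers_removed = n_outliers,
    n_analyzed = n_segmented - n_missing - n_outliers,
    retained_features = as.character(retained),
    chosen_k = k,
    state_map = if (!is.null(states)) as.list(unclass(states)) else NULL)
  stopifnot(manifest$n_analyzed ==
              n_segmented - n_missing - n_outliers)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(assignments))
      write_table(assignments, file.path(out_dir, "assignments.csv"))
    if (!is.null(gap))
      write_table(gap$table, file.path(out_dir, "gap_curve.csv"))
    write_table(as.data.frame(embedding$coords),
                file.path(out_dir, "umap_coords.csv"))
    if (!is.null(stats)) {
      write_table(stats$proportions, file.path(out_dir, "proportions.csv"))
      write_table(stats$comparisons, file.path(out_dir, "comparisons.csv"))
      if (!is.null(stats$anova))
        write_table(stats$anova, file.path(out_dir, "anova.csv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(scaled = scaled, correlation = corr, retained = retained,
       gap = gap, model = model, embedding = embedding,
       outliers = ol$outliers, states = states,
       assignments = assignments, stats = stats, manifest = manifest)
}

#' Extract features from every TIFF stack in a cohort directory
#'
#' Walks `dir/sex/group/animal/roiN.tif` (the layout written by
#' [generate_cohort()]), segments each stack and extracts per-cell
#' features, attaching the metadata encoded in the path.
#'
#' @param dir Cohort directory.
#' @param config A [run_config()] (spacing, threshold, min_voxels).
#' @return Combined per-cell feature table.
#' @export
extract_cohort_features <- function(dir, config = run_config()) {
  paths <- list.files(dir, pattern = "\\.tif$", recursive = TRUE,
                      full.names = TRUE)
  if (length(paths) == 0L) stop("no TIFF stacks under ", dir)
  out <- list()
  next_id <- 1L
  for (p in paths) {
    rel <- strsplit(sub(paste0("^", dir, "/?"), "", p), "/")[[1]]
    vol <- read_stack(p, config$spacing)
    feats <- extract_stack_features(vol, min_voxels = config$min_voxels,
                                    threshold = config$threshold)
    if (nrow(feats) == 0L) next
    feats$cell_id <- seq.int(next_id, length.out = nrow(feats))
    next_id <- next_id + nrow(feats)
    if (length(rel) >= 4L) {
      feats$sex <- rel[1]
      feats$group <- rel[2]
      feats$animal_id <- paste(rel[1], rel[2],
                               sub("animal", "", rel[3]), sep = "_")
      feats$roi_index <- as.integer(gsub("\\D", "", rel[4]))
      feats$depth_region <- roi_depth_region(feats$roi_index)
    }
    out[[length(out) + 1L]] <- feats
  }
  if (length(out) == 0L) stop("no cells segmented in ", dir)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
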