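#' Cohort design for synthetic data
#'
#' The study layout: two sexes, four treatment groups (SSN, CSN, SSS, CNN),
#' four animals per group, four regions of interest per animal (ROIs 1-2
#' superficial dorsal horn, 3-4 deep), and a per-(sex, group) mixture over
#' the three morphology classes.
#'
#' @param sexes Character vector of sexes.
#' @param groups Character vector of treatment groups.
#' @param animals_per_group Animals per (sex, group) cell.
#' @param rois_per_animal ROIs per animal (1-2 superficial, 3-4 deep).
#' @param cells_per_roi Cells per ROI; the default lands the full design
#'   near 3500 cells in total.
#' @param state_mixture Named list `sex.group` -> probability triple over
#'   (ramified, rod, amoeboid), each summing to 1.
#' @param seed Integer master seed.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(sexes = c("female", "male"),
                          groups = c("SSN", "CSN", "SSS", "CNN"),
                          animals_per_group = 4L, rois_per_animal = 4L,
                          cells_per_roi = 27L,
                          state_mixture = default_state_mixtures(),
                          seed = 1L) {
  stopifnot(animals_per_group >= 1, rois_per_animal >= 1, cells_per_roi >= 0)
  for (sx in sexes) for (g in groups) {
    key <- paste(sx, g, sep = ".")
    mx <- state_mixture[[key]]
    if (is.null(mx))
      stop("state_mixture missing entry for ", key)
    if (length(mx) != 3L || any(mx < 0) || abs(sum(mx) - 1) > 1e-9)
      stop("mixture for ", key, " must be 3 non-negative values summing to 1")
  }
  structure(list(
    sexes = sexes, groups = groups,
    animals_per_group = as.integer(animals_per_group),
    rois_per_animal = as.integer(rois_per_animal),
    cells_per_roi = as.integer(cells_per_roi),
    state_mixture = state_mixture, seed = as.integer(seed)
  ), class = "cohort_design")
}

#' Default per-(sex, group) morphology mixtures
#'
#' Fixture probabilities over (ramified, rod, amoeboid) that plant the
#' study's qualitative group differences -- females richer in ramified
#' (surveillant) cells, males richer in rod/amoeboid, and a stress-priming
#' excess of amoeboid cells in male SSN relative to CSN.  They are derived
#' from per-group cell tallies and are generator fixtures, not biological
#' claims.
#'
#' @return Named list `sex.group` -> probability triple.
#' @export
default_state_mixtures <- function() {
  raw <- list(
    female.SSN = c(250, 196, 34), female.CSN = c(254, 242, 28),
    female.CNN = c(178, 337, 23), female.SSS = c(250, 196, 34),
    male.SSN = c(90, 226, 41), male.CSN = c(172, 160, 25),
    male.CNN = c(92, 290, 53), male.SSS = c(103, 144, 35)
  )
  lapply(raw, function(x) setNames(x / sum(x), .CLASSES))
}

roi_depth_region <- function(roi_index) {
  ifelse(roi_index <= 2L, "superficial", "deep")
}

#' Generate a synthetic imaging cohort on disk
#'
#' Renders one multi-page TIFF stack per ROI under
#' `out_dir/sex/group/animal/roiN.tif` and writes a `truth.csv` with one
#' record per placed cell (cell_id, class, sex, group, animal_id,
#' roi_index, depth_region).
#'
#' @param design A [cohort_design()].
#' @param out_dir Output directory.
#' @param overwrite Allow writing into a non-empty directory.
#' @param ... Passed to [render_roi()] (roi_edge, spacing, ...).
#' @return Invisibly, a list with `truth` (data frame) and `paths`.
#' @export
generate_cohort <- function(design, out_dir, overwrite = FALSE, ...) {
  stopifnot(inherits(design, "cohort_design"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory is not empty (use overwrite = TRUE): ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  presets <- morphology_presets()
  combos <- expand.grid(roi = seq_len(design$rois_per_animal),
                        animal = seq_len(design$animals_per_group),
                        group = design$groups, sex = design$sexes,
                        stringsAsFactors = FALSE)
  seeds <- derive_seeds(design$seed, nrow(combos) + 1L)
  class_draw_seed <- seeds[nrow(combos) + 1L]
  truth <- list()
  paths <- character(0)
  next_id <- 1L
  classes_all <- with_seed(class_draw_seed, {
    lapply(seq_len(nrow(combos)), function(i) {
      key <- paste(combos$sex[i], combos$group[i], sep = ".")
      sample(.CLASSES, design$cells_per_roi, replace = TRUE,
             prob = design$state_mixture[[key]])
    })
  })
  for (i in seq_len(nrow(combos))) {
    sx <- combos$sex[i]; g <- combos$group[i]
    an <- combos$animal[i]; roi <- combos$roi[i]
    cls <- classes_all[[i]]
    roi_out <- render_roi(lapply(cls, function(cl) presets[[cl]]),
                          seed = seeds[i], ...)
    dirp <- file.path(out_dir, sx, g, sprintf("animal%d", an))
    dir.create(dirp, recursive = TRUE, showWarnings = FALSE)
    fp <- file.path(dirp, sprintf("roi%d.tif", roi))
    write_stack(roi_out$volume, fp)
    paths <- c(paths, fp)
    tr <- roi_out$truth
    if (nrow(tr)) {
      tr$cell_id <- seq.int(next_id, length.out = nrow(tr))
      next_id <- next_id + nrow(tr)
      tr$sex <- sx; tr$group <- g
      tr$animal_id <- sprintf("%s_%s_%d", sx, g, an)
      tr$roi_index <- roi
      tr$depth_region <- roi_depth_region(roi)
      truth[[length(truth) + 1L]] <- tr
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame()
  write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(list(truth = truth, paths = paths))
}

#' Class-conditional feature distribution parameters
#'
#' Location and scale per feature per morphology class for the fast
#' feature-table generator, taken from the per-cluster summary statistics
#' of the three microglial states (volumes converted to cubic micrometres).
#' Branch-related features of the amoeboid class are exactly zero, and
#' endpoint counts are derived from branchpoints plus loadings on branch
#' length (see [generate_feature_table()]).
#'
#' @return Nested list: class -> feature -> c(mean, sd).
#' @export
state_reference_params <- function() {
  list(
    ramified = list(
      territorial_volume = c(121.5e3, 79.6e3),
      cell_volume = c(17.6e3, 10.7e3),
      ramification_index = c(7.4, 3.2),
      n_branchpoints = c(16.1, 13.1),
      avg_branch_length = c(104.1, 38.8),
      max_branch_length = c(222.5, 130.9),
      min_branch_length = c(21.4, 11.9)
    ),
    rod = list(
      territorial_volume = c(32.5e3, 22.4e3),
      cell_volume = c(7.1e3, 3.8e3),
      ramification_index = c(4.7, 2.1),
      n_branchpoints = c(5.2, 2.8),
      avg_branch_length = c(59.7, 24.5),
      max_branch_length = c(103.7, 43.7),
      min_branch_length = c(23.9, 16.9)
    ),
    amoeboid = list(
      territorial_volume = c(12.5e3, 9.9e3),
      cell_volume = c(4.6e3, 2.9e3),
      ramification_index = c(2.6, 1.1),
      n_branchpoints = c(0, 0),
      avg_branch_length = c(0, 0),
      max_branch_length = c(0, 0),
      min_branch_length = c(0, 0)
    )
  )
}

# truncated-normal sampler (simple inverse-CDF truncation at `lo`)
rtnorm <- function(n, mean, sd, lo = 0) {
  if (sd < 0) stop("negative scale in class feature parameters")
  if (sd == 0) return(rep(mean, n))
  p_lo <- pnorm(lo, mean, sd)
  qnorm(runif(n, p_lo, 1), mean, sd)
}

#' Generate a calibrated per-cell feature table (no imaging)
#'
#' Draws class-conditional features for every cell of the cohort design,
#' bypassing image synthesis and morphometry; intended for fast clustering
#' and statistics tests.  Territorial volume and ramification index are
#' sampled from truncated normals per class; cell volume is their ratio
#' (which keeps the ramification identity and the class locations of all
#' three volume features); branch features are truncated normals, zero for
#' amoeboid cells.  Endpoint counts are branchpoints plus loadings on
#' branch length plus noise, which reproduces both the near-unit endpoint
#' to branchpoint correlation and the higher mean absolute correlation of
#' endpoints reported for real data.
#'
#' @param design A [cohort_design()].
#' @param class_feature_params As from [state_reference_params()].
#' @param endpoint_noise_sd SD of the endpoint residual noise (calibrated
#'   so that cor(endpoints, branchpoints) is about 0.97).
#' @return Data frame with cell_id, the 8 features, metadata columns
#'   (class, sex, group, animal_id, roi_index, depth_region).
#' @export
generate_feature_table <- function(design,
                                   class_feature_params = state_reference_params(),
                                   endpoint_noise_sd = 3) {
  stopifnot(inherits(design, "cohort_design"))
  for (cl in names(class_feature_params))
    for (f in names(class_feature_params[[cl]]))
      if (class_feature_params[[cl]][[f]][2] < 0)
        stop("negative scale for ", cl, ":", f)
  combos <- expand.grid(roi = seq_len(design$rois_per_animal),
                        animal = seq_len(design$animals_per_group),
                        group = design$groups, sex = design$sexes,
                        stringsAsFactors = FALSE)
  with_seed(design$seed, {
    out <- vector("list", nrow(combos))
    next_id <- 1L
    for (i in seq_len(nrow(combos))) {
      n <- design$cells_per_roi
      if (n == 0L) next
      key <- paste(combos$sex[i], combos$group[i], sep = ".")
      cls <- sample(.CLASSES, n, replace = TRUE,
                    prob = design$state_mixture[[key]])
      rows <- data.frame(
        cell_id = seq.int(next_id, length.out = n),
        territorial_volume = NA_real_, cell_volume = NA_real_,
        ramification_index = NA_real_, n_endpoints = NA_real_,
        n_branchpoints = NA_real_, avg_branch_length = NA_real_,
        max_branch_length = NA_real_, min_branch_length = NA_real_,
        class = cls, sex = combos$sex[i], group = combos$group[i],
        animal_id = sprintf("%s_%s_%d", combos$sex[i], combos$group[i],
                            combos$animal[i]),
        roi_index = combos$roi[i],
        depth_region = roi_depth_region(combos$roi[i]),
        stringsAsFactors = FALSE)
      next_id <- next_id + n
      for (cl in unique(cls)) {
        idx <- which(cls == cl)
        pp <- class_feature_params[[cl]]
        tv <- rtnorm(length(idx), pp$territorial_volume[1],
                     pp$territorial_volume[2], lo = 100)
        # floor the ramification index so the derived cell volume (tv/ri)
        # stays within 3 SD of its calibrated spread: a near-1 index drawn
        # against a large territory would otherwise produce cell volumes
        # far outside the distribution being emulated
        ri_lo <- pmax(1, tv / (pp$cell_volume[1] + 3 * pp$cell_volume[2]))
        ri <- rtnorm(length(idx), pp$ramification_index[1],
                     pp$ramification_index[2], lo = ri_lo)
        bp <- round(rtnorm(length(idx), pp$n_branchpoints[1],
                           pp$n_branchpoints[2], lo = 0))
        abl <- rtnorm(length(idx), pp$avg_branch_length[1],
                      pp$avg_branch_length[2], lo = 0)
        mbl <- rtnorm(length(idx), pp$max_branch_length[1],
                      pp$max_branch_length[2], lo = 0)
        nbl <- rtnorm(length(idx), pp$min_branch_length[1],
                      pp$min_branch_length[2], lo = 0)
        ep <- if (cl == "amoeboid") rep(0, length(idx)) else
          pmax(0, round(1.15 * bp + 1.5 + 0.035 * abl +
                          rnorm(length(idx), 0, endpoint_noise_sd)))
        rows$territorial_volume[idx] <- tv
        rows$ramification_index[idx] <- ri
        rows$cell_volume[idx] <- tv / ri
        rows$n_branchpoints[idx] <- bp
        rows$n_endpoints[idx] <- ep
        rows$avg_branch_length[idx] <- abl
        rows$max_branch_length[idx] <- mbl
        rows$min_branch_length[idx] <- nbl
      }
      out[[i]] <- rows
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0L) {
      return(data.frame(
        cell_id = integer(0), territorial_volume = numeric(0),
        cell_volume = numeric(0), ramification_index = numeric(0),
        n_endpoints = numeric(0), n_branchpoints = numeric(0),
        avg_branch_length = numeric(0), max_branch_length = numeric(0),
        min_branch_length = numeric(0), class = character(0),
        sex = character(0), group = character(0), animal_id = character(0),
        roi_index = integer(0), depth_region = character(0)))
    }
    do.call(rbind, out)
  })
}
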