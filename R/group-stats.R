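#' Per-animal state proportions
#'
#' For every animal (within a scope: all ROIs, superficial = ROIs 1-2, or
#' deep = ROIs 3-4) the percentage of its cells in each state.  Rows sum to
#' 100; each animal carries equal weight in all downstream tests.
#'
#' @param assignments Data frame with one row per cell and columns
#'   `animal_id`, `sex`, `group`, `state`, and `roi_index` (or
#'   `depth_region`) for the depth scopes.
#' @param scope `"all"`, `"superficial"` or `"deep"`.
#' @return Data frame: animal_id, sex, group, scope, per-state percentage
#'   columns, per-state count columns (`n_<state>`) and `n_cells`.
#' @export
per_animal_proportions <- function(assignments,
                                   scope = c("all", "superficial", "deep")) {
  scope <- match.arg(scope)
  need <- c("animal_id", "sex", "group", "state")
  if (!all(need %in% names(assignments)))
    stop("assignments lack: ", paste(setdiff(need, names(assignments)), collapse = ", "))
  df <- assignments
  if (scope != "all") {
    if (!"depth_region" %in% names(df)) {
      if (!"roi_index" %in% names(df))
        stop("need roi_index or depth_region for depth scopes")
      df$depth_region <- roi_depth_region(df$roi_index)
    }
    df <- df[df$depth_region == scope, , drop = FALSE]
  }
  animals <- unique(assignments[, c("animal_id", "sex", "group")])
  out <- list()
  for (i in seq_len(nrow(animals))) {
    sub <- df[df$animal_id == animals$animal_id[i], , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("animal ", animals$animal_id[i], " has no cells in scope '",
              scope, "'; row omitted")
      next
    }
    counts <- vapply(.STATES, function(s) sum(sub$state == s), numeric(1))
    props <- 100 * counts / sum(counts)
    row <- data.frame(animal_id = animals$animal_id[i],
                      sex = animals$sex[i], group = animals$group[i],
                      scope = scope)
    for (s in .STATES) row[[s]] <- props[[s]]
    for (s in .STATES) row[[paste0("n_", s)]] <- counts[[s]]
    row$n_cells <- sum(counts)
    out[[length(out) + 1L]] <- row
  }
  if (length(out) == 0L) stop("no animals have cells in scope '", scope, "'")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group-level mean proportions, normalized to 100
#'
#' Averages per-animal proportions within each (sex, group) and rescales
#' the three state means so they sum to exactly 100 (they can drift when
#' animals were omitted from a scope); the SEM across animals is reported
#' alongside.
#'
#' @param props Output of [per_animal_proportions()].
#' @param by Grouping columns (default sex and group).
#' @return Data frame of group means (per state, summing to 100) and SEMs.
#' @export
group_normalize <- function(props, by = c("sex", "group")) {
  groups <- unique(props[, by, drop = FALSE])
  out <- list()
  for (i in seq_len(nrow(groups))) {
    sel <- rep(TRUE, nrow(props))
    for (b in by) sel <- sel & props[[b]] == groups[[b]][i]
    sub <- props[sel, , drop = FALSE]
    m <- vapply(.STATES, function(s) mean(sub[[s]]), numeric(1))
    sem <- vapply(.STATES, function(s) sd(sub[[s]]) / sqrt(nrow(sub)),
                  numeric(1))
    m <- m * 100 / sum(m)
    row <- groups[i, , drop = FALSE]
    row$n_animals <- nrow(sub)
    for (s in .STATES) row[[s]] <- m[[s]]
    for (s in .STATES) row[[paste0("sem_", s)]] <- sem[[s]]
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Independent two-sample t-test (pooled variance)
#'
#' Student's t with pooled variance, two-tailed; the squared statistic is
#' consistent with the pooled-SD Cohen's d.  Welch's correction is
#' available behind the `welch` flag for sensitivity checks.
#'
#' @param a,b Numeric samples (per-animal proportions; n >= 2 each).
#' @param welch Use Welch's unequal-variance t instead.
#' @return List with `t`, `df`, `p`.
#' @export
independent_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 observations per side")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      message("zero variance on both sides with equal means; p = 1 by convention")
      return(list(t = 0, df = length(a) + length(b) - 2L, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L, p = 0))
  }
  ht <- t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Cohen's d from summary statistics
#'
#' Absolute mean difference divided by the pooled standard deviation
#' sqrt(((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a + n_b - 2)).
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries (n >= 2,
#'   sds >= 0, not both zero).
#' @return Numeric d with attribute `magnitude` (see [d_magnitude()]).
#' @export
cohens_d <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  if (sd_a == 0 && sd_b == 0) stop("both SDs are zero; d is undefined")
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  d <- abs(mean_a - mean_b) / sp
  attr(d, "magnitude") <- d_magnitude(d)
  d
}

#' Cohen's d between two samples
#'
#' @param a,b Numeric samples.
#' @return As [cohens_d()].
#' @export
cohens_d_samples <- function(a, b) {
  cohens_d(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
}

#' Effect-size magnitude band
#'
#' d <= 0.2 negligible, (0.2, 0.5] small, (0.5, 0.8] medium, > 0.8 large.
#'
#' @param d Cohen's d (non-negative).
#' @return Character label.
#' @export
d_magnitude <- function(d) {
  cut(abs(d), c(-Inf, 0.2, 0.5, 0.8, Inf),
      labels = c("negligible", "small", "medium", "large"),
      right = TRUE) |> as.character()
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' One-sample KS against a normal with estimated mean and SD; p-values use
#' the Lilliefors correction (plain KS p-values are anticonservative when
#' the parameters are estimated from the sample).
#'
#' @param x Numeric sample (n >= 4, non-constant).
#' @return List with `D` and `p`.
#' @export
ks_normality <- function(x) {
  if (length(x) < 4L) stop("need at least 4 observations")
  if (sd(x) == 0) stop("constant sample; normality test undefined")
  ht <- nortest::lillie.test(x)
  list(D = unname(ht$statistic), p = unname(ht$p.value))
}

#' Two-way sex-by-state ANOVA on per-animal proportions
#'
#' Type-II sums of squares with factors sex and state on the long-format
#' per-animal proportions; reports F and p for both main effects and the
#' interaction, plus partial eta squared and its d-equivalent conversion
#' d = 2 sqrt(eta2 / (1 - eta2)) (a labelled convention for comparing the
#' interaction strength with the pairwise effect sizes).
#'
#' @param long Data frame with columns `proportion`, `sex`, `state`,
#'   `animal_id` (>= 2 animals per sex-state cell).
#' @return Data frame: effect, df, F, p, partial_eta2, d_equivalent.
#' @export
two_way_anova <- function(long) {
  need <- c("proportion", "sex", "state")
  if (!all(need %in% names(long)))
    stop("long table lacks: ", paste(setdiff(need, names(long)), collapse = ", "))
  tab <- table(long$sex, long$state)
  if (any(tab < 2L)) {
    bad <- which(tab < 2L, arr.ind = TRUE)
    stop("design cells with < 2 animals: ",
         paste(rownames(tab)[bad[, 1]], colnames(tab)[bad[, 2]],
               sep = ":", collapse = ", "))
  }
  long$sex <- factor(long$sex)
  long$state <- factor(long$state, levels = .STATES)
  fit <- lm(proportion ~ sex * state, data = long)
  a2 <- car::Anova(fit, type = 2)
  ss <- a2[["Sum Sq"]]
  res_ss <- ss[rownames(a2) == "Residuals"]
  rows <- setdiff(rownames(a2), "Residuals")
  out <- data.frame(
    effect = rows,
    df = a2[rows, "Df"],
    F = a2[rows, "F value"],
    p = a2[rows, "Pr(>F)"],
    partial_eta2 = a2[rows, "Sum Sq"] / (a2[rows, "Sum Sq"] + res_ss))
  out$d_equivalent <- 2 * sqrt(out$partial_eta2 / (1 - out$partial_eta2))
  rownames(out) <- NULL
  out
}

#' Long-format per-animal proportions
#'
#' One row per animal x state, as consumed by [two_way_anova()].
#'
#' @param props Output of [per_animal_proportions()].
#' @return Data frame with animal_id, sex, group, state, proportion.
#' @export
proportions_long <- function(props) {
  do.call(rbind, lapply(.STATES, function(s) {
    data.frame(animal_id = props$animal_id, sex = props$sex,
               group = props$group, state = s, proportion = props[[s]])
  }))
}

#' Treatment-group comparison battery
#'
#' Runs the planned pairwise group comparisons (priming by stress
#' SSN vs CSN, priming by NGF CNN vs CSN, additive effects SSN vs SSS)
#' per sex and pooled, per state, on per-animal proportions: pooled t-test,
#' Cohen's d with magnitude band, and the group cell counts.  Unadjusted
#' p-values are primary (mirroring single-comparison reporting);
#' Holm-adjusted values are appended as an extra column.
#'
#' @param props Per-animal proportions (scope "all") from
#'   [per_animal_proportions()].
#' @param plan List of 2-element character vectors (group pairs).
#' @param sexes Sex strata; `"pooled"` combines all animals.
#' @return Data frame, one row per comparison x state x sex stratum.
#' @export
run_comparisons <- function(props,
                            plan = list(c("SSN", "CSN"), c("CNN", "CSN"),
                                        c("SSN", "SSS")),
                            sexes = c("female", "male", "pooled")) {
  for (pr in plan)
    if (!all(pr %in% props$group))
      stop("unknown group label(s): ",
           paste(setdiff(pr, props$group), collapse = ", "))
  out <- list()
  for (pr in plan) {
    for (sx in sexes) {
      sub <- if (sx == "pooled") props else props[props$sex == sx, , drop = FALSE]
      a <- sub[sub$group == pr[1], , drop = FALSE]
      b <- sub[sub$group == pr[2], , drop = FALSE]
      if (nrow(a) < 2L || nrow(b) < 2L) next
      for (s in .STATES) {
        tt <- independent_t(a[[s]], b[[s]])
        d <- cohens_d_samples(a[[s]], b[[s]])
        out[[length(out) + 1L]] <- data.frame(
          comparison = paste(pr[1], "vs", pr[2]), sex = sx, state = s,
          n_cells_a = sum(a[[paste0("n_", s)]]),
          n_cells_b = sum(b[[paste0("n_", s)]]),
          n_animals_a = nrow(a), n_animals_b = nrow(b),
          t = tt$t, p = tt$p, d = as.numeric(d),
          magnitude = attr(d, "magnitude"))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p_holm <- p.adjust(res$p, method = "holm")  # extra, not primary
  res
}

#' Sex-difference battery
#'
#' Male vs female comparison of per-animal state proportions across all
#' treatment groups combined, for the pooled field and per depth region.
#'
#' @param assignments Per-cell assignment table (see
#'   [per_animal_proportions()]).
#' @return Data frame, one row per scope x state.
#' @export
sex_comparisons <- function(assignments) {
  out <- list()
  for (scope in c("all", "superficial", "deep")) {
    props <- per_animal_proportions(assignments, scope)
    m <- props[props$sex == "male", , drop = FALSE]
    f <- props[props$sex == "female", , drop = FALSE]
    if (nrow(m) < 2L || nrow(f) < 2L) next
    for (s in .STATES) {
      tt <- independent_t(m[[s]], f[[s]])
      d <- cohens_d_samples(m[[s]], f[[s]])
      out[[length(out) + 1L]] <- data.frame(
        scope = scope, state = s,
        n_cells_male = sum(m[[paste0("n_", s)]]),
        n_cells_female = sum(f[[paste0("n_", s)]]),
        t = tt$t, p = tt$p, d = as.numeric(d),
        magnitude = attr(d, "magnitude"))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
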