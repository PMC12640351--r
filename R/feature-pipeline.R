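#' Drop cells with any missing feature value
#'
#' Removes rows with `NA` in any of the canonical feature columns and
#' reports how many were dropped.
#'
#' @param tab Feature table (data frame containing the feature columns).
#' @return The filtered table; attribute `n_dropped` records the count.
#' @export
drop_incomplete_cells <- function(tab) {
  fc <- feature_columns(tab)
  if (length(fc) == 0L) stop("no feature columns found")
  keep <- complete.cases(tab[, fc, drop = FALSE])
  if (!any(keep)) stop("all cells have missing feature values")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("dropped %d cell(s) with missing feature values", n_drop))
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_drop
  out
}

#' Z-score the feature columns
#'
#' Centers each feature to mean 0 and scales to (sample) standard
#' deviation 1.  The per-column means and SDs are stored in the `scaling`
#' attribute so that the transform can be reused.
#'
#' @param tab Feature table.
#' @return The table with scaled feature columns (class
#'   `scaled_feature_table`); attribute `scaling` holds the parameters.
#' @export
zscore_scale <- function(tab) {
  fc <- feature_columns(tab)
  if (length(fc) == 0L) stop("no feature columns found")
  mu <- vapply(tab[fc], mean, numeric(1))
  sdv <- vapply(tab[fc], sd, numeric(1))
  if (any(sdv == 0))
    stop("zero-variance feature column(s): ",
         paste(fc[sdv == 0], collapse = ", "))
  out <- tab
  for (f in fc) out[[f]] <- (tab[[f]] - mu[f]) / sdv[f]
  attr(out, "scaling") <- data.frame(feature = fc, mean = mu, sd = sdv,
                                     row.names = NULL)
  class(out) <- unique(c("scaled_feature_table", class(out)))
  out
}

#' Pearson correlation matrix of the feature columns
#'
#' For z-scored features the covariance and correlation matrices coincide;
#' this is asserted (to 1e-9) when the input carries scaling parameters.
#'
#' @param tab Feature table (ideally a `scaled_feature_table`).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(tab) {
  fc <- feature_columns(tab)
  x <- as.matrix(tab[, fc, drop = FALSE])
  if (nrow(x) < 3L) stop("need at least 3 rows for a correlation matrix")
  sdv <- apply(x, 2, sd)
  if (any(sdv == 0))
    stop("constant feature column(s): ", paste(fc[sdv == 0], collapse = ", "))
  r <- cor(x)
  if (inherits(tab, "scaled_feature_table")) {
    v <- cov(x)
    if (max(abs(v - r)) > 1e-9)
      stop("internal error: covariance != correlation on scaled features")
  }
  r
}

#' Remove redundant features by pairwise correlation
#'
#' Iteratively examines the most highly correlated feature pair above the
#' threshold and drops the member with the higher mean absolute correlation
#' against all other features, until no pair exceeds the threshold
#' (findCorrelation-style elimination).  Ties are broken by dropping the
#' later feature in canonical order.
#'
#' @param corr Correlation matrix (from [correlation_matrix()]).
#' @param threshold Absolute-correlation cutoff in (0, 1].
#' @return Character vector of retained feature names, in original order;
#'   attribute `dropped` lists the removals with their mean |r|.
#' @export
filter_redundant_features <- function(corr, threshold = 0.9) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  feats <- colnames(corr)
  keep <- feats
  dropped <- data.frame(feature = character(0), mean_abs_corr = numeric(0),
                        partner = character(0))
  repeat {
    r <- abs(corr[keep, keep, drop = FALSE])
    diag(r) <- 0
    if (length(keep) < 2L || max(r) <= threshold) break
    ij <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- keep[ij]
    mac <- vapply(pair, function(f) mean(r[f, setdiff(keep, f)]), numeric(1))
    victim <- if (mac[1] > mac[2]) pair[1]
              else if (mac[2] > mac[1]) pair[2]
              else pair[which.max(match(pair, feats))]  # tie: later in order
    partner <- setdiff(pair, victim)
    dropped <- rbind(dropped, data.frame(
      feature = victim, mean_abs_corr = unname(mac[victim]),
      partner = partner))
    message(sprintf("dropping '%s' (|r|=%.3f with '%s'; mean |r| %.3f vs %.3f)",
                    victim, max(r), partner, mac[victim], mac[partner]))
    keep <- setdiff(keep, victim)
  }
  out <- feats[feats %in% keep]
  attr(out, "dropped") <- dropped
  out
}
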