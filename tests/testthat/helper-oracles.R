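# Independent brute-force oracles used across the suite.  These stay
# deliberately naive (plain R, no package internals) so they check the
# implementation rather than mirror it.

# neighbor-count classification of a skeleton voxel set: for every voxel,
# count voxels at Chebyshev distance 1
oracle_degrees <- function(vox) {
  n <- nrow(vox)
  deg <- integer(n)
  for (i in seq_len(n)) {
    d <- abs(sweep(vox, 2, vox[i, ]))
    deg[i] <- sum(apply(d, 1, max) == 1L)
  }
  deg
}

# geodesic distances on the explicit voxel graph via igraph
oracle_geodesics <- function(vox, spacing, root) {
  n <- nrow(vox)
  edges <- NULL
  w <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- abs(vox[i, ] - vox[j, ])
      if (max(d) == 1L) {
        edges <- rbind(edges, c(i, j))
        w <- c(w, sqrt(sum((d * spacing)^2)))
      }
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::distances(g, v = root, weights = w)[1, ]
}

# exact k-medoid optimum by exhaustive enumeration
oracle_pam_cost <- function(X, k) {
  D <- as.matrix(dist(X))
  best <- Inf
  for (co in utils::combn(nrow(X), k, simplify = FALSE)) {
    cost <- sum(apply(D[, co, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# pooled-SD Cohen's d from first principles
oracle_d <- function(a, b) {
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  abs(mean(a) - mean(b)) / sp
}

# Student pooled-variance t statistic and two-sided p
oracle_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

# a small random 26-connected voxel mask grown from a seed voxel
random_connected_mask <- function(n_vox, seed) {
  set.seed(seed)
  vox <- matrix(c(5L, 5L, 5L), 1)
  while (nrow(vox) < n_vox) {
    base <- vox[sample(nrow(vox), 1), ]
    step <- sample(c(-1L, 0L, 1L), 3, replace = TRUE)
    cand <- base + step
    if (any(cand < 1L) || any(cand > 30L)) next
    if (!any(vox[, 1] == cand[1] & vox[, 2] == cand[2] & vox[, 3] == cand[3]))
      vox <- rbind(vox, cand)
  }
  vox
}
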