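test_that("PAM reproduces hand-checkable partitions", {
  # 1D points {0, 1, 10, 11}, k = 2: clusters {0,1} {10,11}, cost 2
  fit <- pam_cluster(matrix(c(0, 1, 10, 11)), 2)
  expect_equal(fit$cost, 2)
  expect_equal(fit$assignment[1], fit$assignment[2])
  expect_equal(fit$assignment[3], fit$assignment[4])
  expect_false(fit$assignment[1] == fit$assignment[3])

  # two identical points, k = 2 is rejected (distinct-point rule)...
  expect_error(pam_cluster(matrix(c(1, 1), 2), 2), "distinct")
  # ...but duplicated points among distinct ones cost 0 at k = 2
  fit0 <- pam_cluster(matrix(c(1, 1, 5, 5), 4), 2)
  expect_equal(fit0$cost, 0)

  expect_error(pam_cluster(matrix(1:3), 5), "exceeds")
})

test_that("PAM matches the exhaustive enumeration oracle on tiny data", {
  set.seed(10)
  for (r in 1:25) {
    n <- sample(6:12, 1)
    k <- sample(1:3, 1)
    X <- matrix(rnorm(n * 2), n)
    fit <- pam_cluster(X, k)
    expect_equal(fit$cost, oracle_pam_cost(X, k), tolerance = 1e-9)
  }
})

test_that("PAM k = 1 medoid minimizes the summed distance", {
  set.seed(3)
  X <- matrix(rnorm(30 * 3), 30)
  fit <- pam_cluster(X, 1)
  D <- as.matrix(dist(X))
  expect_equal(fit$cost, min(colSums(D)), tolerance = 1e-9)
})

test_that("PAM is locally swap-optimal and matches cluster::pam at scale", {
  skip_if_not_installed("cluster")
  set.seed(8)
  X <- matrix(rnorm(150 * 4), 150)  # large enough for the BUILD+SWAP path
  for (k in c(2, 4)) {
    fit <- pam_cluster(X, k)
    D <- as.matrix(dist(X))
    cost_of <- function(med) sum(apply(D[, med, drop = FALSE], 1, min))
    expect_equal(fit$cost, cost_of(fit$medoids), tolerance = 1e-9)
    # no single medoid / non-medoid exchange lowers the cost
    for (mi in seq_len(k)) {
      for (x in setdiff(seq_len(nrow(X)), fit$medoids)) {
        med2 <- fit$medoids
        med2[mi] <- x
        expect_gte(cost_of(med2), fit$cost - 1e-9)
      }
    }
    cp <- cluster::pam(X, k, pamonce = 0)
    expect_equal(fit$cost, unname(cp$objective["swap"]) * nrow(X),
                 tolerance = 1e-9)
  }
})

test_that("every cell is assigned to its nearest medoid", {
  set.seed(5)
  X <- matrix(rnorm(80 * 3), 80)
  fit <- pam_cluster(X, 3)
  D <- as.matrix(dist(X))
  for (j in seq_len(80)) {
    dists <- unname(D[j, fit$medoids])
    expect_equal(dists[fit$assignment[j]], min(dists), tolerance = 1e-12)
  }
})

test_that("WCSS is zero at k = n, brute-force at k = 1, and elbows at 3 blobs", {
  set.seed(6)
  X <- matrix(rnorm(12 * 2), 12)
  w <- wcss_curve(X, c(1, 12))
  expect_equal(w$wcss[2], 0)
  # k = 1 WCSS equals total sum of squared deviations from the mean
  expect_equal(w$wcss[1], sum(scale(X, scale = FALSE)^2), tolerance = 1e-9)

  blobs <- do.call(rbind, lapply(list(c(0, 0), c(8, 0), c(0, 8)), function(c2)
    sweep(matrix(rnorm(60 * 2, 0, 0.4), 60), 2, c2, `+`)))
  wc <- wcss_curve(blobs, 1:5)$wcss
  drop23 <- wc[2] - wc[3]
  drop34 <- wc[3] - wc[4]
  expect_gt(drop23, 10 * drop34)

  expect_error(wcss_curve(X, 1:20), "exceeds")
})

test_that("gap statistic recovers planted k = 3 across seeds", {
  centers <- list(c(0, 0), c(5, 0), c(0, 5))
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    x <- do.call(rbind, lapply(centers, function(c2)
      sweep(matrix(rnorm(100 * 2, 0, 0.3), 100), 2, c2, `+`)))
    g <- gap_statistic(x, 1:6, B = 12, seed = 1000 + s)
    hits <- hits + (g$k == 3L)
  }
  expect_gte(hits, 19)  # >= 95 % of 20 runs
})

test_that("gap values agree with the clusGap reference on separated blobs", {
  skip_if_not_installed("cluster")
  set.seed(9)
  y <- rbind(matrix(rnorm(60, 0, 0.2), 30), matrix(rnorm(60, 4, 0.2), 30))
  cg <- cluster::clusGap(y, FUNcluster = function(x, k)
    list(cluster = cluster::pam(x, k, cluster.only = TRUE)),
    K.max = 4, B = 50, d.power = 2, spaceH0 = "original", verbose = FALSE)
  mg <- gap_statistic(y, 1:4, B = 200, seed = 2)
  # log W differs by the constant pair-counting convention, which cancels
  # in the gap; the curves must agree within Monte-Carlo error
  expect_equal(mg$table$gap, unname(cg$Tab[, "gap"]), tolerance = 0.06)
  expect_equal(mg$k, 2L)
})

test_that("gap statistic is deterministic per seed and flags flat curves", {
  set.seed(4)
  x <- matrix(runif(150 * 2), 150)  # one uniform blob: no real structure
  expect_warning(g1 <- gap_statistic(x, 1:5, B = 12, seed = 7),
                 "low contrast")
  g2 <- suppressWarnings(gap_statistic(x, 1:5, B = 12, seed = 7))
  expect_identical(g1$table, g2$table)
  expect_error(gap_statistic(x, integer(0)), "empty")
  expect_error(gap_statistic(x, 1:3, B = 5), "at least 10")
})

test_that("UMAP embedding is deterministic and separates planted blobs", {
  set.seed(2)
  x <- do.call(rbind, lapply(list(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0)),
                             function(c3) sweep(matrix(rnorm(60 * 3, 0, 0.3),
                                                       60), 2, c3, `+`)))
  e1 <- umap_embed(x, seed = 5)
  e2 <- umap_embed(x, seed = 5)
  expect_identical(e1$coords, e2$coords)

  skip_if_not_installed("cluster")
  lab <- rep(1:3, each = 60)
  sil <- cluster::silhouette(lab, dist(e1$coords))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  # a duplicated point embeds on top of its twin
  xd <- rbind(x, x[1, ])
  ed <- umap_embed(xd, seed = 5)
  d_twin <- sqrt(sum((ed$coords[181, ] - ed$coords[1, ])^2))
  pair_d <- dist(ed$coords[sample(181, 80), ])
  expect_lt(d_twin, quantile(pair_d, 0.01))

  expect_error(umap_embed(x[1:5, ]), "n_neighbors")
})

test_that("outlier removal flags exactly the planted far points", {
  set.seed(12)
  base <- rbind(matrix(rnorm(200 * 2, 0, 0.5), 200),
                matrix(rnorm(200 * 2, 10, 0.5), 200))
  planted <- rbind(c(30, 30), c(-25, 5), c(5, -28), c(32, -10), c(-20, -20))
  x <- rbind(base, planted)
  fit <- pam_cluster(x, 2)
  out <- remove_outliers(fit, as.data.frame(x))
  # all planted points flagged; Gaussian tails may add a few (< 2 %)
  expect_true(all(401:405 %in% out$outliers$row))
  expect_lt(length(setdiff(out$outliers$row, 401:405)) / 400, 0.02)

  # clean Gaussian clusters: < 2 % flagged
  fit2 <- pam_cluster(base, 2)
  out2 <- remove_outliers(fit2, as.data.frame(base))
  expect_lt(nrow(out2$outliers) / nrow(base), 0.02)

  # tiny cluster is skipped with a warning, table untouched
  tiny <- rbind(matrix(rnorm(40, 0, 0.3), 20), c(9, 9), c(9.1, 9.1),
                c(8.9, 9), c(9, 8.9))
  fit3 <- pam_cluster(tiny, 2)
  expect_warning(out3 <- remove_outliers(fit3, as.data.frame(tiny)),
                 "fewer than 5")
  expect_equal(nrow(out3$table) + nrow(out3$outliers), nrow(tiny))
})

test_that("state assignment follows the morphometric rubric", {
  fix <- calibrated_fixture()
  model <- pam_cluster(fix$embedding$coords, 3)
  sm <- assign_states(model, fix$table)
  expect_setequal(unname(sm), microglia_states())

  # the mapping agrees with the planted classes
  truth_state <- c(ramified = "surveillant", rod = "primed",
                   amoeboid = "activated")[fix$table$class]
  agree <- mean(state_labels(model, sm) == truth_state)
  expect_gt(agree, 0.9)

  # a cluster with all-zero branch features must be activated
  amo_cluster <- unique(model$assignment[fix$table$class == "amoeboid"])
  amo_cluster <- as.integer(names(which.max(table(
    model$assignment[fix$table$class == "amoeboid"]))))
  expect_equal(unname(sm[amo_cluster]), "activated")

  expect_error(assign_states(pam_cluster(fix$embedding$coords, 2),
                             fix$table), "k = 3")
})

test_that("branch-length ties resolve by cell volume (larger = activated)", {
  set.seed(3)
  n <- 30
  tab <- data.frame(
    avg_branch_length = rep(0, 3 * n),               # three-way tie
    n_branchpoints = rep(0, 3 * n),
    cell_volume = rep(c(10, 50, 5), each = n) + runif(3 * n),
    territorial_volume = rep(c(100, 60, 20), each = n) + runif(3 * n))
  x <- cbind(rep(c(0, 10, 20), each = n) + rnorm(3 * n, 0, 0.1),
             rnorm(3 * n, 0, 0.1))
  model <- pam_cluster(x, 3)
  sm <- suppressMessages(assign_states(model, tab))
  big_cv <- as.integer(names(which.max(tapply(
    tab$cell_volume, model$assignment, median))))
  expect_equal(unname(sm[big_cv]), "activated")
})

test_that("end-to-end recovery: calibrated table clusters match truth", {
  fix <- calibrated_fixture()
  model <- pam_cluster(fix$embedding$coords, 3)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(model$assignment, fix$table$class)
  expect_gt(ari, 0.9)
})
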