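test_that("per-animal proportions are exact percentages that sum to 100", {
  asg <- data.frame(
    animal_id = "r1", sex = "female", group = "SSN",
    state = rep(c("surveillant", "primed", "activated"), c(10, 5, 5)),
    roi_index = rep(1:4, 5))
  p <- per_animal_proportions(asg)
  expect_equal(p$surveillant, 50)
  expect_equal(p$primed, 25)
  expect_equal(p$activated, 25)
  expect_equal(p$n_cells, 20)

  # single-state animal
  one <- asg
  one$state <- "surveillant"
  p1 <- per_animal_proportions(one)
  expect_equal(c(p1$surveillant, p1$primed, p1$activated), c(100, 0, 0))

  # every row sums to 100 on a full synthetic cohort
  big <- truth_assignments()
  props <- per_animal_proportions(big)
  expect_true(all(abs(rowSums(props[, microglia_states()]) - 100) < 1e-9))
})

test_that("pooled scope equals the cell-count-weighted mix of depth scopes", {
  asg <- truth_assignments(cells_per_roi = 8, seed = 21)
  p_all <- per_animal_proportions(asg, "all")
  p_sup <- per_animal_proportions(asg, "superficial")
  p_deep <- per_animal_proportions(asg, "deep")
  for (a in p_all$animal_id) {
    s <- p_sup[p_sup$animal_id == a, ]
    d <- p_deep[p_deep$animal_id == a, ]
    w <- (s$surveillant * s$n_cells + d$surveillant * d$n_cells) /
      (s$n_cells + d$n_cells)
    expect_equal(p_all$surveillant[p_all$animal_id == a], w,
                 tolerance = 1e-9)
  }
})

test_that("animals without cells in scope are omitted with a warning", {
  asg <- data.frame(
    animal_id = rep(c("r1", "r2"), c(8, 4)), sex = "male", group = "SSN",
    state = "primed", roi_index = c(rep(1:4, 2), rep(1:2, 2)))
  expect_warning(p <- per_animal_proportions(asg, "deep"), "r2")
  expect_equal(p$animal_id, "r1")
})

test_that("group normalization rescales means to exactly 100", {
  props <- data.frame(
    animal_id = c("a", "b"), sex = "female", group = "SSN", scope = "all",
    surveillant = c(50, 70), primed = c(25, 20), activated = c(25, 10))
  gm <- group_normalize(props)
  expect_equal(c(gm$surveillant, gm$primed, gm$activated),
               c(60, 22.5, 17.5))
  expect_equal(gm$surveillant + gm$primed + gm$activated, 100)

  # drifting input (simulating omitted animals) is rescaled exactly
  drift <- props
  drift$activated <- drift$activated - 0.2
  gmd <- group_normalize(drift)
  expect_equal(gmd$surveillant + gmd$primed + gmd$activated, 100)

  # single-animal group passes through
  single <- props[1, ]
  gs <- group_normalize(single)
  expect_equal(c(gs$surveillant, gs$primed, gs$activated), c(50, 25, 25))
})

test_that("pooled t-test matches the closed-form oracle and symmetries", {
  set.seed(30)
  for (r in 1:50) {
    a <- rnorm(sample(3:9, 1), sample(0:3, 1), runif(1, 0.5, 2))
    b <- rnorm(sample(3:9, 1), sample(0:3, 1), runif(1, 0.5, 2))
    got <- independent_t(a, b)
    ora <- oracle_t(a, b)
    expect_equal(got$t, ora$t, tolerance = 1e-9)
    expect_equal(got$p, ora$p, tolerance = 1e-9)
    d <- cohens_d_samples(a, b)
    expect_equal(as.numeric(d), oracle_d(a, b), tolerance = 1e-9)
  }
  # identical samples: t = 0, p = 1
  x <- c(1, 2, 3, 4)
  expect_equal(independent_t(x, x)$t, 0)
  expect_equal(independent_t(x, x)$p, 1)
  # swapping the samples negates t, keeps p
  y <- x + 10
  expect_equal(independent_t(x, y)$t, -independent_t(y, x)$t)
  expect_equal(independent_t(x, y)$p, independent_t(y, x)$p)
  expect_lt(independent_t(x, y)$p, 1e-3)
  # degenerate equal constants
  expect_equal(suppressMessages(independent_t(c(2, 2), c(2, 2))$p), 1)
})

test_that("Cohen's d follows the pooled-SD formula and its invariances", {
  expect_equal(as.numeric(cohens_d(1, 1, 10, 0, 1, 10)), 1)
  expect_equal(as.numeric(cohens_d(5, 2, 8, 5, 3, 9)), 0)
  expect_error(cohens_d(1, 0, 5, 2, 0, 5), "both SDs")

  # scale and shift invariance: d(a x + b, a y + b) = d(x, y)
  set.seed(14)
  x <- rnorm(8, 2, 1)
  y <- rnorm(9, 3, 1.5)
  d0 <- as.numeric(cohens_d_samples(x, y))
  for (a in c(0.3, -2, 7)) {
    d1 <- as.numeric(cohens_d_samples(a * x + 5, a * y + 5))
    expect_equal(d1, d0, tolerance = 1e-9)
  }

  expect_equal(d_magnitude(c(0.1, 0.3, 0.6, 2)),
               c("negligible", "small", "medium", "large"))
})

test_that("Lilliefors normality test calibrates and detects bimodality", {
  covered <- 0
  for (s in 1:100) {
    set.seed(s)
    covered <- covered + (ks_normality(rnorm(150))$p > 0.05)
  }
  expect_gte(covered, 90)

  set.seed(3)
  bimodal <- c(rnorm(100, -5), rnorm(100, 5))
  r <- ks_normality(bimodal)
  expect_lt(r$p, 0.01)
  expect_gte(r$D, 0)
  expect_lte(r$D, 1)
  expect_error(ks_normality(rep(1, 10)), "constant")
})

test_that("two-way ANOVA detects a planted sex-by-state crossover", {
  # null: identical state profiles in both sexes -> interaction F ~ 0
  set.seed(40)
  mk <- function(m_act_male, m_act_female, noise) {
    do.call(rbind, lapply(c("male", "female"), function(sx) {
      act <- if (sx == "male") m_act_male else m_act_female
      sur <- 70 - act
      do.call(rbind, lapply(1:6, function(a) data.frame(
        animal_id = paste(sx, a), sex = sx,
        state = c("surveillant", "primed", "activated"),
        proportion = c(sur, 30, act) + rnorm(3, 0, noise))))
    }))
  }
  null <- mk(20, 20, 1)
  a0 <- two_way_anova(null)
  expect_lt(a0$F[a0$effect == "sex:state"], 2)

  crossed <- mk(45, 5, 1)
  a1 <- two_way_anova(crossed)
  expect_lt(a1$p[a1$effect == "sex:state"], 1e-3)

  # permuting replicate values within sex-state cells leaves F unchanged
  perm <- crossed
  perm$proportion <- ave(perm$proportion, perm$sex, perm$state,
                         FUN = function(x) sample(x))
  a2 <- two_way_anova(perm)
  expect_equal(a2$F, a1$F, tolerance = 1e-9)

  # hand-computed check on the balanced design: interaction F from
  # first-principles sums of squares
  g <- crossed
  cell_means <- tapply(g$proportion, list(g$sex, g$state), mean)
  grand <- mean(g$proportion)
  n_rep <- 6
  ss_sex <- 3 * n_rep * sum((rowMeans(cell_means) - grand)^2)
  ss_state <- 2 * n_rep * sum((colMeans(cell_means) - grand)^2)
  ss_cells <- n_rep * sum((cell_means - grand)^2)
  ss_int <- ss_cells - ss_sex - ss_state
  ss_res <- sum((g$proportion - cell_means[cbind(g$sex, g$state)])^2)
  f_int <- (ss_int / 2) / (ss_res / (nrow(g) - 6))
  expect_equal(a1$F[a1$effect == "sex:state"], f_int, tolerance = 1e-9)

  # missing design cell errors with its name
  broken <- crossed[!(crossed$sex == "male" & crossed$state == "activated"), ]
  expect_error(two_way_anova(broken), "male:activated")
})

test_that("comparison battery reports the planted male stress effect", {
  asg <- truth_assignments(cells_per_roi = 20, seed = 3)
  props <- per_animal_proportions(asg)
  cmp <- run_comparisons(props)
  # bookkeeping: |plan| x states x (sexes + pooled)
  expect_equal(nrow(cmp), 3 * 3 * 3)
  male_act <- cmp[cmp$comparison == "SSN vs CSN" & cmp$sex == "male" &
                    cmp$state == "activated", ]
  expect_gt(male_act$d, 0)
  expect_gt(mean(props$activated[props$sex == "male" & props$group == "SSN"]),
            mean(props$activated[props$sex == "male" & props$group == "CSN"]))
  expect_true(all(c("p_holm", "magnitude", "n_cells_a") %in% names(cmp)))

  expect_error(run_comparisons(props, plan = list(c("SSN", "XXX"))),
               "unknown group")

  sx <- sex_comparisons(asg)
  expect_equal(nrow(sx), 3 * 3)  # 3 scopes x 3 states
  # planted: females richer in surveillant cells in every scope
  sur <- sx[sx$state == "surveillant", ]
  expect_true(all(sur$n_cells_female / sur$n_cells_male > 1))
})

test_that("null cohorts keep the type-I rate near nominal", {
  # identical mixtures for all groups; repeated synthetic cohorts
  mx <- lapply(default_state_mixtures(), function(x)
    setNames(c(0.5, 0.4, 0.1), names(x)))
  pvals <- c()
  for (s in 1:25) {
    des <- cohort_design(cells_per_roi = 15, state_mixture = mx, seed = 500 + s)
    asg <- generate_feature_table(des)
    asg$state <- c(ramified = "surveillant", rod = "primed",
                   amoeboid = "activated")[asg$class]
    props <- per_animal_proportions(asg)
    cmp <- run_comparisons(props, plan = list(c("SSN", "CSN")),
                           sexes = "pooled")
    pvals <- c(pvals, cmp$p)
  }
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.0)
  expect_lte(rate, 0.12)
})
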