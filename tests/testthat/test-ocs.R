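test_that("male preselection ranks by GEBV with deterministic ties", {
  pop <- make_pop(matrix(0L, 2 * 30, 4), c(rep("M", 20), rep("F", 10)))
  set.seed(40)
  g <- rnorm(30)
  cand <- select_ocs_male_candidates(pop, g, 0.10)
  expect_length(cand$males, 2)
  expect_equal(cand$males, order(-g[1:20])[1:2])
  expect_length(cand$females, 10)

  tied <- select_ocs_male_candidates(pop, rep(0, 30), 0.10)
  expect_equal(tied$males, 1:2)
  all_m <- select_ocs_male_candidates(pop, g, 1)
  expect_length(all_m$males, 20)
})

test_that("symmetric instances give uniform contributions", {
  Ks <- matrix(0.1, 4, 4); diag(Ks) <- 0.5
  sex <- c("M", "M", "F", "F")
  s <- solve_ocs(rep(1, 4), Ks, sex, "minKin", gain_lower_bound = -1,
                 gain_baseline = 1)
  expect_equal(s$c, rep(0.25, 4), tolerance = 1e-6)

  s2 <- solve_ocs(rep(1, 4), Ks, sex, "maxBVE", kinship_upper_bound = 10)
  expect_equal(sum(s2$c[sex == "M"]), 0.5, tolerance = 1e-8)
  expect_equal(sum(s2$c[sex == "F"]), 0.5, tolerance = 1e-8)
})

test_that("an unbounded maxBVE problem loads the best pair", {
  set.seed(41)
  sex <- rep(c("M", "F"), each = 4)
  g <- rnorm(8)
  K <- random_kinship(8)
  s <- solve_ocs(g, K, sex, "maxBVE", kinship_upper_bound = 1e9)
  best_m <- which(sex == "M")[which.max(g[sex == "M"])]
  best_f <- which(sex == "F")[which.max(g[sex == "F"])]
  expect_equal(s$c[best_m], 0.5, tolerance = 1e-6)
  expect_equal(s$c[best_f], 0.5, tolerance = 1e-6)
})

test_that("both OCS modes match the grid-search oracle on 3x3 instances", {
  set.seed(42)
  sex <- rep(c("M", "F"), each = 3)
  for (i in 1:5) {
    g <- rnorm(6); K <- random_kinship(6, 80)
    baseline <- mean(g)

    s_min <- solve_ocs(g, K, sex, "minKin", gain_lower_bound = 0.05,
                       gain_baseline = baseline)
    grid_min <- ocs_grid(g, K + diag(1e-8, 6), sex, "minKin", 0.05, baseline)
    expect_lte(s_min$kinship, grid_min + 1e-3)
    expect_gte(s_min$gain, 0.05 - 1e-6)

    ub <- grid_min + 0.02
    s_max <- solve_ocs(g, K, sex, "maxBVE", kinship_upper_bound = ub,
                       gain_baseline = baseline)
    grid_max <- ocs_grid(g, K + diag(1e-8, 6), sex, "maxBVE", ub, baseline)
    expect_gte(s_max$gain, grid_max - 1e-3)
    expect_lte(s_max$kinship, ub + 1e-6)
  }
})

test_that("constraints hold and objectives are monotone in their bounds", {
  set.seed(43)
  sex <- rep(c("M", "F"), each = 5)
  for (i in 1:3) {
    g <- rnorm(10); K <- random_kinship(10)
    baseline <- mean(g)

    kins <- sapply(c(0.02, 0.05, 0.1, 0.3), function(lb) {
      s <- solve_ocs(g, K, sex, "minKin", gain_lower_bound = lb,
                     gain_baseline = baseline)
      expect_equal(sum(s$c[sex == "M"]), 0.5, tolerance = 1e-6)
      expect_equal(sum(s$c[sex == "F"]), 0.5, tolerance = 1e-6)
      expect_true(all(s$c >= -1e-6))
      expect_gte(s$gain, lb - 1e-6)
      s$kinship
    })
    expect_true(all(diff(kins) >= -1e-7))

    base_kin <- solve_ocs(g, K, sex, "minKin", gain_lower_bound = -Inf,
                          gain_baseline = baseline)$kinship
    gains <- sapply(base_kin + c(0.005, 0.02, 0.05, 0.2), function(ub) {
      s <- solve_ocs(g, K, sex, "maxBVE", kinship_upper_bound = ub,
                     gain_baseline = baseline)
      expect_lte(s$kinship, ub + 1e-6)
      s$gain
    })
    expect_true(all(diff(gains) >= -1e-7))
  }
})

test_that("maxBVE at a minKin solution's kinship recovers at least its gain", {
  set.seed(44)
  sex <- rep(c("M", "F"), each = 4)
  for (i in 1:3) {
    g <- rnorm(8); K <- random_kinship(8)
    baseline <- mean(g)
    s1 <- solve_ocs(g, K, sex, "minKin", gain_lower_bound = 0.1,
                    gain_baseline = baseline)
    s2 <- solve_ocs(g, K, sex, "maxBVE", kinship_upper_bound = s1$kinship + 1e-9,
                    gain_baseline = baseline)
    expect_gte(s2$gain, s1$gain - 1e-4)
  }
})

test_that("infeasible bounds raise informative errors", {
  set.seed(45)
  sex <- rep(c("M", "F"), each = 3)
  g <- rnorm(6); K <- random_kinship(6)
  expect_error(solve_ocs(g, K, sex, "minKin", gain_lower_bound = 100,
                         gain_baseline = 0), "infeasible")
  expect_error(solve_ocs(g, K, sex, "maxBVE", kinship_upper_bound = -10),
               "infeasible")
})

test_that("contribution realization converges to the target contributions", {
  set.seed(46)
  ids <- 1:12
  sex <- rep(c("M", "F"), each = 6)

  # concentrated on one pair: all full sibs
  cc <- numeric(12); cc[1] <- 0.5; cc[7] <- 0.5
  plan <- realize_contributions(cc, sex, ids, 700)
  expect_equal(nrow(plan), 1)
  expect_equal(plan$n_offspring, 700)

  # uniform male contributions: usage within 3 multinomial SE
  cu <- c(rep(0.5 / 6, 6), rep(0.5 / 6, 6))
  plan2 <- realize_contributions(cu, sex, ids, 4200)
  sire_use <- tapply(plan2$n_offspring, plan2$sire, sum)
  se <- sqrt(4200 * (1 / 6) * (5 / 6))
  expect_true(all(abs(sire_use - 700) < 3 * se))

  expect_equal(nrow(realize_contributions(cu, sex, ids, 0)), 0)
  bad <- cu; bad[sex == "M"] <- 0
  expect_error(realize_contributions(bad, sex, ids, 10), "realization error")
})
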