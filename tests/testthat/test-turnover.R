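test_that("a step-function response concentrates importance at the step", {
  # single predictor, response a clean step at x = 20.5; each distinct
  # x value appears 5 times so every bootstrap sees the step's flanks
  x <- rep(1:40, each = 5)
  n <- length(x)
  y <- as.integer(x > 20.5) * 2L
  env <- data.frame(grad = x, row.names = sprintf("s%02d", seq_len(n)))
  m <- make_gm(cbind(y), sites = rownames(env))
  tm <- fit_turnover(m, env, n_trees = 100, seed = 3, min_leaf = 5)

  total <- tm$importance["grad"]
  expect_gt(total, 0)
  # >= 95% of importance accrues within the data interval bracketing the step
  lo <- max(x[x <= 20.5]); hi <- min(x[x > 20.5])
  cc <- cumulative_curve(tm, "grad", c(lo - 1e-9, hi))
  expect_gt((cc$cumulative_importance[2] - cc$cumulative_importance[1]) / total,
            0.95)
  # the midpoint of the bracketing interval already carries the mass
  mid <- cumulative_curve(tm, "grad", (lo + hi) / 2)
  expect_gt(mid$cumulative_importance / total, 0.95)

  # evaluation below all splits is 0; at max(x) it is the total
  ends <- cumulative_curve(tm, "grad", c(min(x) - 1, max(x)))
  expect_equal(ends$cumulative_importance[1], 0)
  expect_equal(ends$cumulative_importance[2], unname(total),
               tolerance = 1e-9)

  expect_error(cumulative_curve(tm, "nope", 1), "unknown predictor")
})

test_that("responses independent of the predictors contribute nothing", {
  set.seed(301)
  n <- 50
  env <- data.frame(a = rnorm(n), b = rnorm(n),
                    row.names = sprintf("s%02d", seq_len(n)))
  y <- sample(0:2, n, replace = TRUE)
  m <- make_gm(cbind(as.integer(y)), sites = rownames(env))
  tm <- fit_turnover(m, env, n_trees = 100, seed = 4, min_leaf = 5)
  expect_lte(tm$r_squared[1], 0)
  expect_length(tm$contributing, 0)
  expect_equal(nrow(predictor_importance(tm)), 0)
})

test_that("curves are monotone with conserved endpoints and seeded determinism", {
  sim <- gen_admixed_genotypes(n_pops = 13, n_per_pop = 10, n_loci = 12,
                               fst = 0.05, seed = 302,
                               site_names = rownames(meadow_env))
  pl <- plant_env_effects(sim$matrix, sim$truth, meadow_env$AvTemp,
                          adaptive_loci = 1:8, beta = 2)
  tm <- fit_turnover(pl$matrix, meadow_env, n_trees = 150, seed = 5)
  for (v in tm$predictors) {
    inc <- tm$curves[[v]]$importance
    expect_true(all(inc >= 0))
    grid <- seq(min(meadow_env[[v]]), max(meadow_env[[v]]), length.out = 25)
    cc <- cumulative_curve(tm, v, grid)$cumulative_importance
    expect_true(all(diff(cc) >= -1e-12))
    expect_equal(cc[25], unname(tm$importance[v]), tolerance = 1e-9)
  }
  tm2 <- fit_turnover(pl$matrix, meadow_env, n_trees = 150, seed = 5)
  expect_identical(tm$importance, tm2$importance)

  # importance ranking is stated descending with deterministic ties
  imp <- predictor_importance(tm)
  expect_true(all(diff(imp$importance) <= 0))
})

test_that("permuting a predictor's site values destroys its importance", {
  # assessed at the site scale (allele-frequency response): a permuted
  # gradient scrambles the frequency cline and shallow trees can no
  # longer recover it. At the individual scale any injective relabelling
  # of site values still identifies sites, so the collapse is a
  # site-level property.
  sim <- gen_admixed_genotypes(n_pops = 13, n_per_pop = 30, n_loci = 10,
                               fst = 0.03, seed = 303,
                               site_names = rownames(meadow_env))
  pl <- plant_env_effects(sim$matrix, sim$truth, meadow_env$AvTemp,
                          adaptive_loci = 1:10, beta = 2.5)
  tm <- fit_turnover(pl$matrix, meadow_env, n_trees = 300, seed = 6,
                     response = "frequency", min_leaf = 2)
  base_imp <- tm$importance["AvTemp"]
  expect_gt(base_imp, 0)

  destroyed <- vapply(1:5, function(k) {
    set.seed(304 + k)
    env_perm <- meadow_env
    env_perm$AvTemp <- sample(env_perm$AvTemp)
    tm_p <- fit_turnover(pl$matrix, env_perm, n_trees = 300, seed = 6,
                         response = "frequency", min_leaf = 2)
    tm_p$importance["AvTemp"] < 0.10 * base_imp
  }, NA)
  expect_gte(sum(destroyed), 3)
})

test_that("planted effect-size ratios order predictor importance", {
  # two informative predictors acting on disjoint locus sets with a 3:1
  # effect ratio
  sim <- gen_admixed_genotypes(n_pops = 13, n_per_pop = 12, n_loci = 24,
                               fst = 0.03, seed = 305,
                               site_names = rownames(meadow_env))
  env2 <- meadow_env[, c("AvTemp", "MinTurb")]
  s1 <- plant_env_effects(sim$matrix, sim$truth, env2$AvTemp,
                          adaptive_loci = 1:12, beta = 3)
  s2 <- plant_env_effects(s1$matrix, s1$truth, env2$MinTurb,
                          adaptive_loci = 13:24, beta = 1)
  tm <- fit_turnover(s2$matrix, env2, n_trees = 200, seed = 7)
  imp <- predictor_importance(tm)
  expect_equal(imp$predictor[1], "AvTemp")
})
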