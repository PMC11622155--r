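# small structured dataset with planted temperature effects, shared
# across the scan tests
scan_fixture <- local({
  sim <- gen_admixed_genotypes(n_pops = 13, n_per_pop = 12, n_loci = 400,
                               fst = 0.05, seed = 201,
                               site_names = rownames(meadow_env))
  pl <- plant_env_effects(sim$matrix, sim$truth, meadow_env$AvTemp,
                          adaptive_loci = 1:20, beta = 2.5)
  list(m = pl$matrix, truth = pl$truth,
       planted = pl$matrix$locus_meta$id[1:20])
})

test_that("RDA loadings equal the brute-force projection/eigendecomposition oracle", {
  set.seed(202)
  G <- matrix(rbinom(10 * 20, 2, 0.5), 10, 20)
  m <- make_gm(G, sites = sprintf("s%d", rep(1:5, each = 2)))
  env <- data.frame(v1 = rnorm(5), v2 = rnorm(5),
                    row.names = sprintf("s%d", 1:5))
  sc <- rda_scan(m, env, n_permutations = 0)

  # oracle: explicit least-squares projection of centred genotypes onto
  # the standardised predictors, then SVD of the fitted values
  E <- apply(env[m$ind_meta$site, ], 2, scale)
  Gc <- scale(G, center = TRUE, scale = FALSE)
  X <- scale(E, center = TRUE, scale = FALSE)
  H <- X %*% solve(crossprod(X), crossprod(X, Gc))
  v_oracle <- svd(H)$v[, 1:2]
  for (k in 1:2) {
    err <- min(max(abs(sc$loadings[, k] - v_oracle[, k])),
               max(abs(sc$loadings[, k] + v_oracle[, k])))
    expect_lt(err, 1e-8)
  }
})

test_that("RDA flags planted cline loci and calibrates its null behaviour", {
  sc <- rda_scan(scan_fixture$m, meadow_env, n_permutations = 0)
  expect_gt(mean(scan_fixture$planted %in% sc$outliers), 0.9)
  expect_true(all(sc$p >= 0 & sc$p <= 1))
  expect_true(all(sc$outliers %in% scan_fixture$m$locus_meta$id))

  # under a pure-noise predictor the per-axis outlier fraction sits near
  # the two-sided 2.5 SD normal tail (~1.24% per axis)
  sim0 <- gen_admixed_genotypes(n_pops = 10, n_per_pop = 20, n_loci = 2000,
                                fst = 0, seed = 203)
  env0 <- data.frame(noise = rnorm(10),
                     row.names = unique(sim0$matrix$ind_meta$site))
  sc0 <- rda_scan(sim0$matrix, env0, n_permutations = 0)
  frac <- length(sc0$outliers) / 2000
  expect_gt(frac, 0.002)
  expect_lt(frac, 0.04)

  # strong planted association reaches the permutation floor
  sc_p <- rda_scan(scan_fixture$m, meadow_env["AvTemp"],
                   n_permutations = 999, seed = 7)
  expect_lte(sc_p$calibration$permutation_p, 0.001)
})

test_that("PC-Mahalanobis scan ranks a fixed-difference locus first and is duplication-invariant", {
  # mild background differentiation so the leading PC is the deme axis,
  # plus one locus fixed-different between the demes
  sim <- gen_admixed_genotypes(n_pops = 2, n_per_pop = 30, n_loci = 300,
                               fst = 0.05, seed = 204)
  G <- sim$matrix$calls
  n <- nrow(G)
  G[, 1] <- rep(c(0L, 2L), each = n / 2)        # fixed difference
  G[, 2] <- G[, 3]                              # duplicated locus columns
  m <- make_gm(G, sites = rep(c("A", "B"), each = n / 2))
  sc <- pcadapt_scan(m, K = 2)
  expect_equal(names(which.min(sc$p)), m$locus_meta$id[1])
  expect_equal(unname(sc$statistic[2]), unname(sc$statistic[3]),
               tolerance = 1e-10)

  # panmictic null: calibrated inflation near 1 and uniform-ish p-values
  sim0 <- gen_admixed_genotypes(n_pops = 1, n_per_pop = 100, n_loci = 1000,
                                fst = 0, seed = 205)
  sc0 <- pcadapt_scan(sim0$matrix, K = 1)
  expect_gt(sc0$calibration$gif, 0.8)
  expect_lt(sc0$calibration$gif, 1.2)
})

test_that("latent-factor ridge scan reduces to per-locus OLS at K = 0", {
  m <- scan_fixture$m
  sc <- lfmm_scan(m, meadow_env["AvTemp"], K = 0)
  xv <- scale(meadow_env[m$ind_meta$site, "AvTemp"])
  beta_ols <- apply(m$calls[, 1:30], 2, function(g) coef(lm(g ~ xv))[2])
  bv <- sc$by_variable$AvTemp
  # recover effects from z and the OLS machinery: compare slope estimates
  Gc <- scale(m$calls[, 1:30], center = TRUE, scale = FALSE)
  slope <- drop(crossprod(Gc, xv)) / sum(xv^2)
  expect_equal(unname(slope), unname(beta_ols), tolerance = 1e-8)
  # z-scores at K = 0 equal the OLS t-statistics
  tstat <- apply(m$calls[, 1:30], 2, function(g) summary(lm(g ~ xv))$coef[2, 3])
  expect_equal(unname(bv$z[1:30]), unname(tstat), tolerance = 1e-8)
})

test_that("latent-factor scan detects planted loci and errors on missing data", {
  sc <- lfmm_scan(scan_fixture$m, meadow_env, K = 5)
  expect_gt(mean(scan_fixture$planted %in% sc$by_variable$AvTemp$outliers), 0.8)
  expect_equal(unname(sc$per_variable["AvTemp"]),
               length(sc$by_variable$AvTemp$outliers))
  expect_true(all(sc$p >= 0 & sc$p <= 1))

  deg <- degrade(scan_fixture$m, missing_rate = 0.1, replicate_pairs = 0,
                 seed = 8)
  expect_error(lfmm_scan(deg, meadow_env), "impute")
})

test_that("consensus keeps loci found by at least min_methods scans", {
  mk <- function(ids, method) {
    structure(list(method = method, outliers = ids), class = "gea_scan")
  }
  # disjoint sets -> empty consensus
  cs0 <- consensus(list(mk(c("a", "b"), "m1"), mk(c("c"), "m2"),
                        mk(c("d"), "m3")))
  expect_length(cs0$consensus, 0)

  # {a,b}, {b,c}, {c} -> {b, c}
  cs1 <- consensus(list(mk(c("a", "b"), "m1"), mk(c("b", "c"), "m2"),
                        mk(c("c"), "m3")))
  expect_setequal(cs1$consensus, c("b", "c"))

  # min_methods = 1 is the union; raising min_methods never adds loci
  sets <- list(mk(c("a", "b"), "m1"), mk(c("b", "c"), "m2"),
               mk(c("b", "c", "d"), "m3"))
  u <- consensus(sets, min_methods = 1)
  expect_setequal(u$consensus, c("a", "b", "c", "d"))
  c2 <- consensus(sets, min_methods = 2)$consensus
  c3 <- consensus(sets, min_methods = 3)$consensus
  expect_true(all(c3 %in% c2))
  expect_true(all(c2 %in% u$consensus))
  expect_setequal(c3, "b")

  expect_error(consensus(list(mk("a", "m1"))), "two scan results")
})
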