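test_that("generator honours shape, missingness and determinism contracts", {
  sim <- gen_admixed_genotypes(n_pops = 13, n_per_pop = 26, n_loci = 300,
                               fst = 0.1, seed = 11)
  expect_s3_class(sim$matrix, "genotype_matrix")
  expect_equal(dim(sim$matrix), c(13 * 26, 300))
  expect_false(anyNA(sim$matrix$calls))
  expect_equal(length(unique(sim$matrix$ind_meta$site)), 13)
  expect_false(anyDuplicated(sim$matrix$locus_meta$id) > 0)
  expect_true(all(grepl("^\\d+-\\d+-[ACGT]/[ACGT]$", sim$matrix$locus_meta$id)))

  sim2 <- gen_admixed_genotypes(n_pops = 13, n_per_pop = 26, n_loci = 300,
                                fst = 0.1, seed = 11)
  expect_identical(sim$matrix$calls, sim2$matrix$calls)

  expect_error(gen_admixed_genotypes(n_pops = 0), "positive")
  expect_error(gen_admixed_genotypes(fst = 1), "fst")
})

test_that("realised differentiation tracks the F_ST knob (Weir-Cockerham oracle)", {
  sim0 <- gen_admixed_genotypes(n_pops = 6, n_per_pop = 30, n_loci = 5000,
                                fst = 0, seed = 21)
  f0 <- wc_fst(sim0$matrix$calls, sim0$matrix$ind_meta$site)
  expect_lt(abs(f0), 0.01)

  sim1 <- gen_admixed_genotypes(n_pops = 6, n_per_pop = 30, n_loci = 5000,
                                fst = 0.1, seed = 22)
  f1 <- wc_fst(sim1$matrix$calls, sim1$matrix$ind_meta$site)
  expect_lt(abs(f1 - 0.1), 0.02)
})

test_that("planted effects shift deme frequencies on the logit scale", {
  # two demes at env -1/+1, p = 0.5, beta = 3 -> plogis(-3)/plogis(3)
  sim <- gen_admixed_genotypes(n_pops = 2, n_per_pop = 400, n_loci = 30,
                               fst = 0, seed = 31, maf_range = c(0.5, 0.5))
  pl <- plant_env_effects(sim$matrix, sim$truth, env_values = c(-1, 1),
                          adaptive_loci = 1:30, beta = 3)
  expect_equal(unname(pl$truth$deme_freq[, 1]),
               plogis(c(-3, 3)), tolerance = 1e-12)
  freqs <- sapply(1:2, function(d) {
    mean(pl$matrix$calls[pl$truth$deme_of == d, 1:30]) / 2
  })
  expect_lt(abs(freqs[1] - plogis(-3)), 0.02)
  expect_lt(abs(freqs[2] - plogis(3)), 0.02)

  # beta = 0 re-draws from the same per-locus stream: bit-identical
  pl0 <- plant_env_effects(sim$matrix, sim$truth, env_values = c(-1, 1),
                           adaptive_loci = 1:30, beta = 0)
  expect_identical(pl0$matrix$calls, sim$matrix$calls)

  expect_error(plant_env_effects(sim$matrix, sim$truth, env_values = 1:3,
                                 adaptive_loci = 1, beta = 1), "one env value")
})

test_that("environmental gradients over 13 meadows induce allele-frequency clines", {
  sim <- gen_admixed_genotypes(n_pops = 13, n_per_pop = 30, n_loci = 200,
                               fst = 0.05, seed = 41,
                               site_names = rownames(meadow_env))
  pl <- plant_env_effects(sim$matrix, sim$truth, meadow_env$AvTemp,
                          adaptive_loci = 1:25, beta = 1.5)
  r <- sapply(1:25, function(l) {
    freq <- tapply(pl$matrix$calls[, l], pl$truth$deme_of, mean) / 2
    cor(freq, meadow_env$AvTemp)
  })
  expect_true(all(r > 0))
  expect_gt(mean(abs(r) > 0.5), 0.5)
})

test_that("degrade reproduces its missingness and replicate-error parameters", {
  sim <- gen_admixed_genotypes(n_pops = 4, n_per_pop = 20, n_loci = 400,
                               fst = 0.1, seed = 51)
  clean <- degrade(sim$matrix, missing_rate = 0, replicate_pairs = 2,
                   replicate_error = 0, seed = 1)
  expect_true(all(clean$locus_meta$call_rate == 1))
  d <- replicate_error_rate(clean)
  expect_true(all(d$distance == 0))

  big <- gen_admixed_genotypes(n_pops = 13, n_per_pop = 26, n_loci = 3277,
                               fst = 0.1, seed = 52)
  deg <- degrade(big$matrix, missing_rate = 0.2, replicate_pairs = 6,
                 replicate_error = 0.002, clone_pairs = 2, seed = 2)
  expect_lt(abs(mean(is.na(deg$calls)) - 0.2), 0.01)
  expect_equal(nrow(deg$calls), 338 + 8)
  expect_equal(deg$locus_meta$call_rate, unname(colMeans(!is.na(deg$calls))))
  # clones are exact copies before missingness; replicate pairs nearly so
  expect_equal(sum(!is.na(deg$ind_meta$clone_of)), 2)
})

test_that("the shipped meadow environmental fixture is the canonical 13 x 9 table", {
  expect_equal(dim(meadow_env), c(13, 9))
  expect_equal(meadow_env["Wallis Lake", "AvTemp"], 23.39)
  expect_equal(meadow_env["Pambula", "pHRange"], 0.19)
  expect_setequal(colnames(meadow_env),
                  c("AvTemp", "MaxTemp", "TempRange", "pHRange", "MinpH",
                    "MaxSal", "AvSal", "TurbRange", "MinTurb"))
  # round-trips through the env CSV writer/reader without loss
  f <- tempfile(fileext = ".csv")
  write_env_csv(meadow_env, f)
  back <- read_env_csv(f)
  expect_equal(back, meadow_env)
})

test_that("VCF and genotype CSV round-trip calls and locus ids", {
  sim <- gen_admixed_genotypes(n_pops = 3, n_per_pop = 8, n_loci = 40,
                               fst = 0.2, seed = 61)
  deg <- degrade(sim$matrix, missing_rate = 0.1, replicate_pairs = 0, seed = 3)

  fv <- tempfile(fileext = ".vcf.gz")
  write_vcf(deg, fv)
  back <- read_vcf(fv)
  expect_identical(unname(back$calls), unname(deg$calls))
  expect_identical(back$locus_meta$id, deg$locus_meta$id)

  fc <- tempfile(fileext = ".csv")
  write_genotype_csv(deg, fc)
  back2 <- read_genotype_csv(fc)
  expect_identical(unname(back2$calls), unname(deg$calls))
  expect_identical(back2$ind_meta$site, deg$ind_meta$site)
})
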