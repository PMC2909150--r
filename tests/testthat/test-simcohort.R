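test_that("simulated genotypes hit their allele frequencies and HWE", {
  expect_error(simulate_genotypes(c(0, 0.2), 10), "\\(0, 0.5\\]")
  gm <- simulate_genotypes(rep(0.2, 5), 4000, seed = 51)
  freq <- colMeans(additive_matrix(gm)) / 2
  expect_true(all(abs(freq - 0.2) < 0.013)) # 3 binomial SEs
  # HWE exact-test rejections at 0.01 stay below 2% over 1000 SNPs
  gm2 <- simulate_genotypes(rep(seq(0.1, 0.5, length.out = 10), 100), 500,
                            seed = 52)
  codes <- additive_matrix(gm2)
  rej <- vapply(seq_len(ncol(codes)), function(j) {
    g <- codes[, j]
    hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2)) <= 0.01
  }, logical(1))
  expect_lte(mean(rej), 0.02)
})

test_that("calibrate_effects satisfies the variance constraint", {
  expect_identical(calibrate_effects(c(0.2, 0.4), 0), c(0, 0))
  # single SNP closed form
  expect_equal(calibrate_effects(0.3, 0.17),
               0.17 / sqrt(2 * 0.3 * 0.7), tolerance = 1e-12)
  mafs <- seq(0.1, 0.5, length.out = 43)
  betas <- calibrate_effects(mafs, 0.179)
  expect_true(all(betas > 0))
  expect_equal(sum(2 * mafs * (1 - mafs) * betas^2), 0.179^2,
               tolerance = 1e-12)
  # equal per-SNP contributions
  contrib <- 2 * mafs * (1 - mafs) * betas^2
  expect_equal(max(contrib) - min(contrib), 0, tolerance = 1e-15)
  expect_error(calibrate_effects(0.3, 1), "\\[0, 1\\)")
})

test_that("simulated traits carry the planted generalist structure", {
  spec <- default_simulation_spec(n_individuals = 4000, seed = 53)
  gm <- simulate_genotypes(spec$snp_mafs, spec$n_individuals, seed = 531,
                           plex = spec$plex_assignment)
  betas <- calibrate_effects(spec$snp_mafs, spec$target_r)
  sim <- simulate_traits(gm, betas, spec, seed = 532)
  ph <- sim$pheno
  # adjust for the injected sex/age effects, then correlate with the score
  prep <- prepare_measures(ph, list(measures = stats::setNames(
    as.list(paste0("age_", spec$traits$age_group)), spec$traits$label)))
  score <- rowSums(additive_matrix(gm))
  r_focal <- pearson_r(score, prep$math10)$r
  expect_lt(abs(r_focal - 0.18), 0.035)
  # genetically null trait: no association with the score
  expect_lt(abs(pearson_r(score, prep$liking12)$r), 0.035)
  # but phenotypically linked to the focal trait at
  # link * sqrt(1 - target_r^2)
  r_p <- pearson_r(prep$liking12, prep$math10)$r
  expect_lt(abs(r_p - 0.448 * sqrt(1 - spec$target_r^2)), 0.05)
  # truth record bookkeeping
  expect_equal(unname(sim$truth$expected_r["math9"]), 0.73 * 0.179)
  expect_lt(abs(sim$truth$realized_focal_r - spec$target_r), 0.04)
})

test_that("missingness injection hits its rates and is monotone", {
  spec0 <- default_simulation_spec(n_individuals = 500, seed = 54)
  gm <- simulate_genotypes(spec0$snp_mafs, 500, seed = 541,
                           plex = spec0$plex_assignment)
  betas <- calibrate_effects(spec0$snp_mafs, spec0$target_r)
  sim <- simulate_traits(gm, betas, spec0, seed = 542)

  # zero rates: inputs unchanged
  none <- inject_missingness(gm, sim$pheno, spec0, seed = 543)
  expect_identical(none$gm$calls, gm$calls)
  expect_identical(none$pheno, sim$pheno)

  # per-call rate on a large matrix is recovered
  spec_m <- default_simulation_spec(n_individuals = 4000, seed = 54,
                                    snp_miss_rate = 0.02)
  gm_big <- simulate_genotypes(spec_m$snp_mafs, 4000, seed = 544,
                               plex = spec_m$plex_assignment)
  deg <- inject_missingness(gm_big, sim$pheno[rep(1, 4000), ], spec_m,
                            seed = 545)
  expect_lt(abs(mean(is.na(deg$gm$calls)) - 0.02), 0.003)

  # raising the genotype missingness rate monotonically lowers the
  # number of individuals eligible under the <=3-missing policy
  defn <- snpset_definition("full", gm_big$snps$snp_id,
                            policy = "mean_substitute", max_missing = 3)
  eligible <- vapply(c(0.01, 0.03, 0.06, 0.1), function(rate) {
    sp <- default_simulation_spec(n_individuals = 4000, seed = 54,
                                  snp_miss_rate = rate)
    d <- inject_missingness(gm_big, sim$pheno[rep(1, 4000), ], sp,
                            seed = 546) # common seed across rates
    sum(build_snpset_scores(d$gm, defn)$eligible)
  }, numeric(1))
  expect_true(all(diff(eligible) < 0))
})

test_that("simulate_cohort is deterministic and io-round-trippable", {
  spec <- default_simulation_spec(n_individuals = 150, seed = 55,
                                  plex_dropout_rate = 0.05,
                                  snp_miss_rate = 0.01,
                                  pheno_miss_rate = 0.1)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$gm$calls, b$gm$calls)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$truth$betas, b$truth$betas)
  # emitted files re-read to the same cohort
  prefix <- file.path(tempdir(), "cohort")
  write_genotypes(a$gm, prefix, "pedmap")
  expect_gm_equal(a$gm, read_genotypes(prefix, "pedmap", a$gm$snps))
  ppath <- file.path(tempdir(), "cohort_pheno.tsv")
  write_phenotypes(a$pheno, ppath)
  expect_equal(read_phenotypes(ppath), a$pheno, tolerance = 1e-12)
})

test_that("invalid simulation specifications are rejected", {
  tr <- trait_spec("t", 1, focal = TRUE)
  expect_error(simulation_spec(100, c(0.2, 0.6), 0.1, tr), "\\(0, 0.5\\]")
  expect_error(simulation_spec(100, 0.2, 1.0, tr), "target_r")
  expect_error(simulation_spec(100, 0.2, 0.1, trait_spec("t", 1)),
               "exactly one trait")
  expect_error(simulation_spec(100, 0.2, 0.1, tr, pheno_miss_rate = 1),
               "rates")
  bad_link <- trait_spec("t", 1, pheno_link = 0.999, focal = TRUE)
  expect_error(simulation_spec(100, 0.2, 0.9, bad_link), "residual variance")
})
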