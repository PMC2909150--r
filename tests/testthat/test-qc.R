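test_that("HWE exact test matches hand-checked and oracle values", {
  expect_equal(hwe_exact_p(25, 50, 25), 1.0)
  expect_equal(hwe_exact_p(100, 0, 0), 1.0) # monomorphic: one table
  # 7 copies of each allele; heterozygote counts {1,3,5,7}
  expect_equal(hwe_exact_p(3, 1, 3), hwe_oracle(3, 1, 3), tolerance = 1e-12)
  expect_equal(hwe_exact_p(3, 1, 3), 0.11888111888, tolerance = 1e-9)
  expect_error(hwe_exact_p(0, 0, 0), "at least one")
  # chi-square flavor flags the same gross departure
  expect_lt(hwe_exact_p(30, 40, 60, test = "chisq"), 0.05)
  expect_lt(hwe_exact_p(30, 40, 60), 0.05)
})

test_that("HWE exact test is conservative under simulated equilibrium", {
  set.seed(11)
  rejections <- vapply(seq_len(1000), function(i) {
    maf <- runif(1, 0.1, 0.5)
    g <- rbinom(500, 2, maf)
    hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2)) <= 0.01
  }, logical(1))
  expect_lte(mean(rejections), 0.02)
})

test_that("within-plex filter masks low-call individuals and drops total failures", {
  set.seed(5)
  gm <- simulate_genotypes(rep(0.3, 52), 6,
                           plex = rep(c("plex26", "plex33"), c(26, 26)))
  calls <- gm$calls
  # i1: 18/26 called on plex26 (0.692 < 0.70) -> plex26 masked
  calls[1, 1:8] <- NA
  # i2 fails both plexes -> removed entirely
  calls[2, ] <- NA
  gm <- genotype_matrix(gm$individual_ids, gm$snps, calls)
  res <- filter_individuals_by_plex(gm, qc_config())
  expect_identical(res$report$removed_individual_ids, "id00002")
  expect_identical(n_individuals(res$gm), 5L)
  i1 <- which(res$gm$individual_ids == "id00001")
  expect_true(all(is.na(res$gm$calls[i1, 1:26])))      # plex26 masked
  expect_true(all(!is.na(res$gm$calls[i1, 27:52])))    # plex33 untouched
  # fully called individuals untouched (compare by ID; one row was removed)
  ids <- paste0("id0000", 3:6)
  expect_identical(res$gm$calls[ids, ], gm$calls[ids, ])
})

test_that("SNP call-rate filter removes strictly-below-threshold SNPs only", {
  set.seed(6)
  gm <- simulate_genotypes(rep(0.3, 3), 100)
  calls <- gm$calls
  calls[1:6, 1] <- NA  # 94/100 -> removed
  calls[1:5, 2] <- NA  # exactly 95/100 -> retained (boundary)
  gm <- genotype_matrix(gm$individual_ids, gm$snps, calls)
  res <- filter_snps_by_call_rate(gm, qc_config())
  expect_identical(res$report$removed_snp_ids, "snp01")
  expect_identical(res$gm$snps$snp_id, c("snp02", "snp03"))
})

test_that("a 46-SNP panel with 3 low-call SNPs is reduced to 43", {
  set.seed(7)
  gm <- simulate_genotypes(rep(0.3, 46), 200)
  calls <- gm$calls
  for (j in c(5, 17, 40)) calls[sample(200, 15), j] <- NA
  gm <- genotype_matrix(gm$individual_ids, gm$snps, calls)
  res <- filter_snps_by_call_rate(gm, qc_config())
  expect_identical(n_snps(res$gm), 43L)
  expect_setequal(res$report$removed_snp_ids, c("snp05", "snp17", "snp40"))
})

test_that("run_qc composes the three rules, reports reasons, is idempotent", {
  set.seed(8)
  gm <- simulate_genotypes(rep(0.3, 40), 200,
                           plex = rep(c("plex26", "plex33"), each = 20))
  calls <- gm$calls
  calls[1, ] <- NA                      # one individual fails everywhere
  calls[2:31, 5] <- NA                  # snp05 call rate 169/199 < 0.95
  # snp10 grossly out of HWE: make it all heterozygotes
  calls[, 10] <- "AG"
  gm <- genotype_matrix(gm$individual_ids, gm$snps, calls)
  res <- run_qc(gm, qc_config())
  expect_identical(res$report$removed_individual_ids, "id00001")
  expect_identical(sort(res$report$removed_snps$snp_id),
                   c("snp05", "snp10"))
  expect_identical(
    res$report$removed_snps$reason[res$report$removed_snps$snp_id == "snp05"],
    "call_rate")
  expect_identical(
    res$report$removed_snps$reason[res$report$removed_snps$snp_id == "snp10"],
    "hwe")
  # surviving calls are unaltered
  keep <- match(res$gm$snps$snp_id, gm$snps$snp_id)
  expect_identical(res$gm$calls,
                   gm$calls[gm$individual_ids != "id00001", keep])
  # idempotence
  res2 <- run_qc(res$gm, qc_config())
  expect_identical(res2$gm$calls, res$gm$calls)
  expect_identical(nrow(res2$report$removed_snps), 0L)
  # clean matrix passes untouched
  clean <- simulate_genotypes(rep(0.4, 10), 100, seed = 9)
  res3 <- run_qc(clean, qc_config())
  expect_identical(res3$gm$calls, clean$calls)

  # JSON serialization round-trips the headline counts
  path <- file.path(tempdir(), "qc.json")
  write_qc_report(res$report, path)
  parsed <- jsonlite::read_json(path)
  expect_identical(parsed$n_individuals_removed, 1L)
})

test_that("plex dropout does not penalize SNP call rates (denominator rule)", {
  set.seed(10)
  gm <- simulate_genotypes(rep(0.3, 20), 300,
                           plex = rep(c("plex26", "plex33"), each = 10))
  calls <- gm$calls
  calls[1:60, 1:10] <- NA  # 20% of individuals drop all of plex26
  gm <- genotype_matrix(gm$individual_ids, gm$snps, calls)
  res <- run_qc(gm, qc_config())
  # the plex26 SNPs are fully called among attempted individuals, so
  # none fails the call-rate rule (batch failures only mask individuals)
  expect_identical(
    sum(res$report$removed_snps$reason == "call_rate"), 0L)
  expect_identical(unname(res$report$per_plex_masked["plex26"]), 60)
})
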