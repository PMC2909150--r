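test_that("additive coding counts increaser-allele copies", {
  snp <- snp_info("rs1", allele_a = "A", allele_b = "G",
                  increaser_allele = "G", plex = "p")
  expect_identical(encode_additive(c("GG", "AG", "GA", "AA", NA), snp[1, ]),
                   c(2L, 1L, 1L, 0L, NA))
  # increaser can be allele_a
  snp2 <- snp_info("rs2", allele_a = "C", allele_b = "T",
                   increaser_allele = "C", plex = "p")
  expect_identical(encode_additive(c("CC", "CT", "TT"), snp2[1, ]),
                   c(2L, 1L, 0L))
  expect_error(encode_additive("AT", snp[1, ]), "foreign")
})

test_that("score bounds are 0..2k", {
  ids <- sprintf("rs%02d", 1:43)
  expect_equal(score_bounds(snpset_definition("s10", ids[1:10])),
               c(min = 0, max = 20))
  expect_equal(score_bounds(snpset_definition("s43", ids,
                                              policy = "mean_substitute",
                                              max_missing = 3)),
               c(min = 0, max = 86))
  expect_equal(score_bounds(snpset_definition("s1", ids[1])),
               c(min = 0, max = 2))
})

test_that("complete-only policy scores complete individuals with integers", {
  gm <- make_random_gm(40, 10, seed = 21, miss_rate = 0.08)
  defn <- snpset_definition("s10", gm$snps$snp_id, policy = "complete_only")
  scores <- build_snpset_scores(gm, defn)
  miss <- rowSums(is.na(gm$calls)) > 0
  expect_identical(scores$eligible, unname(!miss))
  expect_true(all(is.na(scores$score[!scores$eligible])))
  ok <- scores$score[scores$eligible]
  expect_identical(ok, round(ok))
  expect_true(all(ok >= 0 & ok <= 20))
  expect_identical(unique(scores$n_substituted), 0L)
  # all-zero individual scores 0
  calls <- gm$calls
  low_hom <- ifelse(gm$snps$increaser_allele == gm$snps$allele_a,
                    paste0(gm$snps$allele_b, gm$snps$allele_b),
                    paste0(gm$snps$allele_a, gm$snps$allele_a))
  calls[1, ] <- low_hom
  gm0 <- genotype_matrix(gm$individual_ids, gm$snps, calls)
  # LD advisory may fire by chance at this small n; not under test here
  expect_equal(suppressWarnings(build_snpset_scores(gm0, defn))$score[1], 0)
})

test_that("mean substitution: eligibility cutoff, mean invariance, variance shrink", {
  gm <- make_random_gm(200, 43, seed = 22, miss_rate = 0.02)
  defn <- snpset_definition("s43", gm$snps$snp_id,
                            policy = "mean_substitute", max_missing = 3)
  scores <- build_snpset_scores(gm, defn)
  n_miss <- rowSums(is.na(gm$calls))
  expect_identical(scores$eligible, unname(n_miss <= 3))
  expect_identical(scores$n_substituted[scores$eligible],
                   as.integer(n_miss[scores$eligible]))
  expect_true(all(is.na(scores$score[n_miss > 3])))

  # per-SNP mean dosage is invariant under substitution (to 1e-12)
  codes <- additive_matrix(gm)
  filled <- codes
  for (j in seq_len(ncol(codes))) {
    filled[is.na(codes[, j]), j] <- mean(codes[, j], na.rm = TRUE)
  }
  expect_equal(colMeans(filled), colMeans(codes, na.rm = TRUE),
               tolerance = 1e-12)

  # substitution shrinks dispersion: each filled dosage column has
  # variance at most that of its observed calls (artificially reduced
  # variation, never inflated)
  v_filled <- apply(filled, 2, var)
  v_obs <- apply(codes, 2, var, na.rm = TRUE)
  expect_true(all(v_filled <= v_obs + 1e-12))
  expect_true(any(v_filled < v_obs))

  # with no missing data the two policies coincide
  gm_full <- make_random_gm(100, 10, seed = 23)
  d1 <- snpset_definition("a", gm_full$snps$snp_id, "complete_only")
  d2 <- snpset_definition("a", gm_full$snps$snp_id, "mean_substitute",
                          max_missing = 3)
  expect_equal(build_snpset_scores(gm_full, d1)$score,
               build_snpset_scores(gm_full, d2)$score)
})

test_that("every eligible score respects the definition bounds", {
  for (seed in 24:26) {
    gm <- make_random_gm(100, 15, seed = seed, miss_rate = 0.05)
    defn <- snpset_definition("s", gm$snps$snp_id, "mean_substitute",
                              max_missing = 2)
    s <- build_snpset_scores(gm, defn)
    b <- score_bounds(defn)
    expect_true(all(s$score[s$eligible] >= b["min"] &
                      s$score[s$eligible] <= b["max"]))
  }
})

test_that("linkage-disequilibrium advisory fires on duplicated SNPs", {
  gm <- make_random_gm(100, 2, seed = 27)
  calls <- cbind(gm$calls, gm$calls[, 2])
  snps <- rbind(gm$snps, transform(gm$snps[2, ], snp_id = "snpdup"))
  gm_ld <- genotype_matrix(gm$individual_ids, snps, calls)
  defn <- snpset_definition("ld", snps$snp_id)
  expect_warning(build_snpset_scores(gm_ld, defn), "linkage disequilibrium")
})

test_that("snpset YAML config round-trip", {
  path <- file.path(tempdir(), "sets.yaml")
  writeLines(c(
    "- name: 10-SNP set",
    "  policy: complete_only",
    "  snp_ids: [rs1, rs2]",
    "- name: full set",
    "  policy: mean_substitute",
    "  max_missing: 3",
    "  snp_ids: [rs1, rs2, rs3, rs4]"), path)
  sets <- read_snpset_config(path)
  expect_length(sets, 2)
  expect_identical(sets[[2]]$max_missing, 3L)
  expect_identical(sets[[1]]$policy, "complete_only")
})
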