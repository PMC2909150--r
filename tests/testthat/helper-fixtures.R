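# shared fixtures and independent oracles

# small hand-built panel: alleles vary, increaser is sometimes allele_a
make_panel <- function(k = 2) {
  bases <- list(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))
  pick <- rep_len(seq_along(bases), k)
  snp_info(
    snp_id = sprintf("rs%03d", seq_len(k)),
    chrom = as.character(rep_len(1:22, k)),
    pos = seq_len(k) * 100L,
    allele_a = vapply(pick, function(i) bases[[i]][1], ""),
    allele_b = vapply(pick, function(i) bases[[i]][2], ""),
    increaser_allele = vapply(seq_len(k), function(j) {
      bases[[pick[j]]][1 + j %% 2]
    }, ""),
    plex = rep_len(c("plex26", "plex33"), k)
  )
}

# 3 individuals x 2 SNPs with one missing call
make_tiny_gm <- function() {
  panel <- make_panel(2)
  calls <- rbind(c("AG", "CT"),
                 c("AA", NA),
                 c("GG", "TT"))
  genotype_matrix(c("i1", "i2", "i3"), panel, calls)
}

# random valid genotype matrix on the standard simulated panel
make_random_gm <- function(n = 50, k = 10, seed = 42, miss_rate = 0) {
  set.seed(seed)
  gm <- simulate_genotypes(runif(k, 0.1, 0.5), n)
  if (miss_rate > 0) {
    calls <- gm$calls
    calls[matrix(runif(length(calls)) < miss_rate, nrow = n)] <- NA
    gm <- genotype_matrix(gm$individual_ids, gm$snps, calls)
  }
  gm
}

expect_gm_equal <- function(a, b) {
  expect_identical(a$individual_ids, b$individual_ids)
  expect_identical(a$snps$snp_id, b$snps$snp_id)
  expect_identical(a$snps$allele_a, b$snps$allele_a)
  expect_identical(a$snps$plex, b$snps$plex)
  expect_identical(unname(a$calls), unname(b$calls))
}

# independent HWE oracle: enumerate heterozygote counts with
# self-normalizing unnormalized weights 2^h / (nAA! h! naa!)
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  h <- seq(rare %% 2, rare, by = 2)
  log_w <- h * log(2) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((na - h) / 2)
  w <- exp(log_w - max(log_w))
  probs <- w / sum(w)
  p_obs <- probs[h == n_Aa]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}
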