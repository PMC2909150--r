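#' Genotype quality-control configuration
#'
#' Thresholds for the three QC rules applied by [run_qc()]:
#' individuals must call on at least `min_individual_plex_call_rate` of
#' the SNPs within each plex (otherwise their calls on that plex are
#' masked; individuals failing every plex are dropped); SNPs must reach
#' `min_snp_call_rate` across retained individuals; and SNPs must be
#' consistent with Hardy-Weinberg equilibrium at `hwe_alpha` (SNPs with
#' exact-test p <= alpha are removed, i.e. p > alpha is kept). Removal is
#' by strict inequality for the call-rate rules, so a SNP at exactly the
#' threshold is retained.
#'
#' @param min_individual_plex_call_rate Fraction in (0, 1]; default 0.70.
#' @param min_snp_call_rate Fraction in (0, 1]; default 0.95.
#' @param hwe_alpha HWE removal level in (0, 1]; default 0.01.
#' @param hwe_test `"exact"` (default) or `"chisq"`.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_individual_plex_call_rate = 0.70,
                      min_snp_call_rate = 0.95,
                      hwe_alpha = 0.01,
                      hwe_test = c("exact", "chisq")) {
  hwe_test <- match.arg(hwe_test)
  for (x in c(min_individual_plex_call_rate, min_snp_call_rate, hwe_alpha)) {
    if (!is.numeric(x) || length(x) != 1 || x <= 0 || x > 1) {
      stop("QC thresholds must be single numbers in (0, 1]")
    }
  }
  structure(list(
    min_individual_plex_call_rate = min_individual_plex_call_rate,
    min_snp_call_rate = min_snp_call_rate,
    hwe_alpha = hwe_alpha,
    hwe_test = hwe_test
  ), class = "qc_config")
}

#' Mask and drop individuals by within-plex call rate
#'
#' For each individual and each plex, if the fraction of called genotypes
#' among that plex's SNPs falls strictly below the threshold, all of the
#' individual's calls on that plex are set to missing. Individuals below
#' threshold on every plex are removed from the matrix entirely.
#'
#' @param gm A [genotype_matrix()].
#' @param cfg A [qc_config()].
#' @return A list with `gm` (filtered matrix) and `report` (per-plex
#'   masking counts and IDs of fully removed individuals).
#' @export
filter_individuals_by_plex <- function(gm, cfg = qc_config()) {
  plexes <- unique(gm$snps$plex)
  for (p in plexes) {
    if (!any(gm$snps$plex == p)) stop("plex with zero SNPs: ", p)
  }
  thr <- cfg$min_individual_plex_call_rate
  calls <- gm$calls
  failed <- matrix(FALSE, n_individuals(gm), length(plexes),
                   dimnames = list(NULL, plexes))
  for (p in plexes) {
    j <- which(gm$snps$plex == p)
    rate <- rowMeans(!is.na(calls[, j, drop = FALSE]))
    bad <- rate < thr
    calls[bad, j] <- NA_character_
    failed[, p] <- bad
  }
  all_failed <- rowSums(failed) == length(plexes)
  removed_ids <- gm$individual_ids[all_failed]
  keep <- !all_failed
  out <- genotype_matrix(gm$individual_ids[keep], gm$snps,
                         calls[keep, , drop = FALSE])
  report <- list(
    per_plex_masked = colSums(failed),
    removed_individual_ids = removed_ids
  )
  # per-SNP matrix of individuals still attempted (plex not masked),
  # consumed by the SNP call-rate filter's denominator
  attempted <- !failed[keep, match(gm$snps$plex, plexes), drop = FALSE]
  colnames(attempted) <- gm$snps$snp_id
  list(gm = out, report = report, attempted = attempted)
}

#' Remove SNPs by call rate
#'
#' SNPs called in strictly fewer than `min_snp_call_rate` of individuals
#' are removed; a SNP exactly at the threshold is retained.
#'
#' @inheritParams filter_individuals_by_plex
#' @param attempted Optional logical matrix (individuals x SNPs) marking
#'   which calls were actually attempted; individuals whose whole plex
#'   was masked by [filter_individuals_by_plex()] are excluded from a
#'   SNP's call-rate denominator, so a batch failure does not penalize
#'   the SNP itself. Default: all attempted.
#' @return A list with `gm` and `report` (removed SNP IDs and the
#'   per-SNP call rates).
#' @export
filter_snps_by_call_rate <- function(gm, cfg = qc_config(), attempted = NULL) {
  if (n_individuals(gm) == 0L) stop("empty genotype matrix")
  if (is.null(attempted)) {
    attempted <- matrix(TRUE, n_individuals(gm), n_snps(gm))
  }
  n_attempted <- colSums(attempted)
  rate <- ifelse(n_attempted > 0,
                 colSums(!is.na(gm$calls) & attempted) / n_attempted, 0)
  drop <- rate < cfg$min_snp_call_rate
  out <- subset_genotypes(gm, snps = which(!drop))
  list(gm = out,
       report = list(removed_snp_ids = gm$snps$snp_id[drop],
                     call_rates = stats::setNames(rate, gm$snps$snp_id)))
}

#' Hardy-Weinberg exact test p-value
#'
#' Exact conditional test for departure from Hardy-Weinberg proportions
#' at a biallelic SNP. Conditioning on the observed allele counts, the
#' heterozygote count has the distribution
#' \deqn{P(h) = \frac{2^h\, n!}{n_{AA}!\, h!\, n_{aa}!}\;
#'       \frac{n_A!\, n_a!}{(2n)!}}
#' and the p-value is the total probability of all heterozygote counts
#' whose probability does not exceed that of the observed table. This
#' two-sided "probability-ordering" exact test is the standard flavor
#' for SNP quality control and is well defined at small counts. A
#' Pearson chi-square alternative (1 df, no continuity correction) is
#' available via `test = "chisq"`.
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts (sum >= 1).
#' @param test `"exact"` (default) or `"chisq"`.
#' @return A p-value in (0, 1]. Monomorphic tables return 1.
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa, test = c("exact", "chisq")) {
  test <- match.arg(test)
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped individual is required")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1) # monomorphic: single possible table
  if (test == "chisq") {
    p <- nA / (2 * n)
    expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((counts - expected)^2 / expected)
    return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  rare <- min(nA, na)
  # heterozygote count shares parity with the rare-allele count
  h_values <- seq(rare %% 2, rare, by = 2)
  log_p <- h_values * log(2) + lgamma(n + 1) -
    lgamma((nA - h_values) / 2 + 1) - lgamma(h_values + 1) -
    lgamma((na - h_values) / 2 + 1) +
    lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  probs <- exp(log_p)
  p_obs <- probs[match(n_Aa, h_values)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele counts")
  # tolerance absorbs floating-point ties between equal-probability tables
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

#' Remove SNPs out of Hardy-Weinberg equilibrium
#'
#' Computes the HWE p-value per SNP on its non-missing calls and removes
#' SNPs with p <= `hwe_alpha` (keeping, as is conventional, the SNPs
#' with p strictly above the level).
#'
#' @inheritParams filter_individuals_by_plex
#' @return A list with `gm` and `report` (removed SNP IDs, per-SNP p).
#' @export
filter_snps_by_hwe <- function(gm, cfg = qc_config()) {
  pvals <- vapply(seq_len(n_snps(gm)), function(j) {
    g <- count_allele(gm$calls[, j], gm$snps$allele_b[j])
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2), test = cfg$hwe_test)
  }, numeric(1))
  drop <- !is.na(pvals) & pvals <= cfg$hwe_alpha
  out <- subset_genotypes(gm, snps = which(!drop))
  list(gm = out,
       report = list(removed_snp_ids = gm$snps$snp_id[drop],
                     hwe_p = stats::setNames(pvals, gm$snps$snp_id)))
}

#' Run the full genotype QC pipeline
#'
#' Applies, in order: the within-plex individual call-rate filter, the
#' SNP call-rate filter (computed after individual masking), and the
#' Hardy-Weinberg filter. The composition is idempotent: re-running QC
#' on its own output changes nothing.
#'
#' @inheritParams filter_individuals_by_plex
#' @return A list with `gm` (the cleaned matrix) and `report`, a
#'   `qc_report` list recording per-plex masking counts, removed
#'   individual IDs, and removed SNP IDs with reasons (`call_rate` or
#'   `hwe`) alongside the per-SNP call rates and HWE p-values.
#' @export
run_qc <- function(gm, cfg = qc_config()) {
  s1 <- filter_individuals_by_plex(gm, cfg)
  s2 <- filter_snps_by_call_rate(s1$gm, cfg, attempted = s1$attempted)
  s3 <- filter_snps_by_hwe(s2$gm, cfg)
  removed_snps <- data.frame(
    snp_id = c(s2$report$removed_snp_ids, s3$report$removed_snp_ids),
    reason = c(rep("call_rate", length(s2$report$removed_snp_ids)),
               rep("hwe", length(s3$report$removed_snp_ids))),
    stringsAsFactors = FALSE
  )
  report <- structure(list(
    per_plex_masked = s1$report$per_plex_masked,
    removed_individual_ids = s1$report$removed_individual_ids,
    n_individuals_removed = length(s1$report$removed_individual_ids),
    removed_snps = removed_snps,
    snp_call_rates = s2$report$call_rates,
    hwe_p = s3$report$hwe_p,
    config = unclass(cfg)
  ), class = "qc_report")
  list(gm = s3$gm, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat("  individuals masked per plex:",
      paste(names(x$per_plex_masked), x$per_plex_masked, sep = "=",
            collapse = ", "), "\n")
  cat("  individuals removed entirely:", x$n_individuals_removed, "\n")
  cat("  SNPs removed:", nrow(x$removed_snps),
      if (nrow(x$removed_snps)) paste0("(", paste(x$removed_snps$snp_id,
        x$removed_snps$reason, sep = ":", collapse = ", "), ")") else "",
      "\n")
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report A `qc_report` from [run_qc()].
#' @param path Output path for the JSON document.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
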