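#' Define a SNP set and its missing-genotype policy
#'
#' A SNP set is an ordered panel of SNP IDs summed into an unweighted
#' additive score. Two missing-data policies are supported:
#' \describe{
#'   \item{`complete_only`}{Only individuals with a called genotype at
#'     every SNP in the set receive a score (which is then an integer).}
#'   \item{`mean_substitute`}{Individuals missing at most `max_missing`
#'     genotypes receive a score in which each missing additive code is
#'     replaced by that SNP's mean code across individuals with a call;
#'     the score may then be non-integer. Substitution leaves every
#'     per-SNP mean unchanged but shrinks score variance.}
#' }
#'
#' @param name Label for the set (e.g. `"10-SNP set"`).
#' @param snp_ids Unique character vector of member SNP IDs.
#' @param policy `"complete_only"` or `"mean_substitute"`.
#' @param max_missing For `mean_substitute`, the maximum number of
#'   missing genotypes an individual may have and still be scored.
#' @return A list of class `snpset_definition`.
#' @export
snpset_definition <- function(name, snp_ids,
                              policy = c("complete_only", "mean_substitute"),
                              max_missing = 0L) {
  policy <- match.arg(policy)
  snp_ids <- as.character(snp_ids)
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  if (!length(snp_ids)) stop("a SNP set needs at least one SNP")
  max_missing <- as.integer(max_missing)
  if (policy == "mean_substitute" && max_missing >= length(snp_ids)) {
    stop("max_missing must be smaller than the set size")
  }
  if (policy == "complete_only") max_missing <- 0L
  structure(list(name = name, snp_ids = snp_ids, policy = policy,
                 max_missing = max_missing),
            class = "snpset_definition")
}

#' Additive genotype coding
#'
#' Codes a diploid call as the number of copies of the SNP's increaser
#' allele: 0 for the homozygote associated with lower trait values, 1
#' for the heterozygote, 2 for the homozygote associated with higher
#' trait values. Missing calls pass through as `NA`.
#'
#' @param call Character vector of two-letter calls (or `NA`).
#' @param snp A single row of a [snp_info()] table.
#' @return Integer vector of codes in \{0, 1, 2\} with `NA` preserved.
#' @export
encode_additive <- function(call, snp) {
  valid <- allele_pair_strings(snp$allele_a, snp$allele_b)
  bad <- !is.na(call) & !call %in% valid
  if (any(bad)) {
    stop("call '", call[which(bad)[1]], "' uses alleles foreign to SNP ",
         snp$snp_id, " (", snp$allele_a, "/", snp$allele_b, ")")
  }
  as.integer(count_allele(call, snp$increaser_allele))
}

#' Additive dosage matrix for a genotype matrix
#'
#' Applies [encode_additive()] SNP-by-SNP, giving the individuals-by-SNPs
#' matrix of 0/1/2 increaser-allele dosages with `NA` for missing calls.
#'
#' @param gm A [genotype_matrix()].
#' @param snp_ids Optional subset (and ordering) of SNP IDs.
#' @return Numeric matrix with dimnames from `gm`.
#' @export
additive_matrix <- function(gm, snp_ids = gm$snps$snp_id) {
  j <- match(snp_ids, gm$snps$snp_id)
  if (anyNA(j)) {
    stop("SNP(s) absent from genotype matrix: ",
         paste(snp_ids[is.na(j)], collapse = ", "))
  }
  codes <- vapply(j, function(jj) {
    encode_additive(gm$calls[, jj], gm$snps[jj, ])
  }, integer(n_individuals(gm)))
  codes <- matrix(as.numeric(codes), nrow = n_individuals(gm),
                  dimnames = list(gm$individual_ids, snp_ids))
  codes
}

#' Build SNP-set scores
#'
#' Sums additive codes over the SNPs of `defn` for every individual,
#' applying the definition's missing-genotype policy. Under mean
#' substitution, the substitution mean for each SNP is computed from all
#' individuals in `gm` with a call at that SNP (the post-QC analysis
#' sample), and is recomputed on every run so scores are self-contained
#' per dataset.
#'
#' An advisory warning is emitted if any pair of member SNPs shows
#' squared dosage correlation above 0.2, since summing assumes the SNPs
#' are not in linkage disequilibrium.
#'
#' @param gm A [genotype_matrix()].
#' @param defn A [snpset_definition()].
#' @return A `data.frame` with one row per individual: `individual_id`,
#'   `score` (`NA` when ineligible), `n_substituted`, `eligible`.
#' @export
build_snpset_scores <- function(gm, defn) {
  stopifnot(inherits(defn, "snpset_definition"))
  codes <- additive_matrix(gm, defn$snp_ids)
  if (nrow(codes) >= 3 && ncol(codes) >= 2) warn_if_ld(codes)
  n_miss <- rowSums(is.na(codes))
  if (defn$policy == "complete_only") {
    eligible <- n_miss == 0
    score <- ifelse(eligible, rowSums(codes), NA_real_)
    n_sub <- rep(0L, nrow(codes))
  } else {
    eligible <- n_miss <= defn$max_missing
    snp_means <- colMeans(codes, na.rm = TRUE)
    filled <- codes
    for (j in seq_len(ncol(codes))) {
      filled[is.na(codes[, j]), j] <- snp_means[j]
    }
    score <- ifelse(eligible, rowSums(filled), NA_real_)
    n_sub <- ifelse(eligible, n_miss, 0L)
  }
  if (!any(eligible)) {
    warning("no individual is eligible for SNP set '", defn$name, "'")
  }
  data.frame(individual_id = gm$individual_ids, score = score,
             n_substituted = as.integer(n_sub), eligible = eligible,
             stringsAsFactors = FALSE, row.names = NULL)
}

warn_if_ld <- function(codes, r2_limit = 0.2) {
  r <- suppressWarnings(stats::cor(codes, use = "pairwise.complete.obs"))
  r2 <- r^2
  diag(r2) <- 0
  if (any(r2 > r2_limit, na.rm = TRUE)) {
    idx <- which(r2 == max(r2, na.rm = TRUE), arr.ind = TRUE)[1, ]
    warning("possible linkage disequilibrium within SNP set: r^2 = ",
            signif(max(r2, na.rm = TRUE), 3), " between ",
            colnames(codes)[idx[1]], " and ", colnames(codes)[idx[2]])
  }
  invisible(NULL)
}

#' Attainable bounds of a SNP-set score
#'
#' @param defn A [snpset_definition()].
#' @return Named numeric vector `c(min = 0, max = 2 * k)` for a set of
#'   `k` SNPs (e.g. 0-20 for 10 SNPs, 0-86 for 43 SNPs).
#' @export
score_bounds <- function(defn) {
  stopifnot(inherits(defn, "snpset_definition"))
  c(min = 0, max = 2 * length(defn$snp_ids))
}

#' Write SNP-set scores as TSV
#'
#' @param scores A score `data.frame` from [build_snpset_scores()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read SNP-set definitions from a YAML/JSON config
#'
#' The config is a list of entries with fields `name`, `policy`,
#' optional `max_missing`, and `snp_ids`.
#'
#' @param path Path to a YAML (or JSON) file.
#' @return A list of [snpset_definition()] objects.
#' @export
read_snpset_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(e) {
    snpset_definition(e$name, unlist(e$snp_ids),
                      policy = e$policy %||% "complete_only",
                      max_missing = e$max_missing %||% 0L)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
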