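#' SNP panel metadata table
#'
#' Builds and validates the per-SNP metadata used throughout the package:
#' the two segregating alleles, the "increaser" allele (the allele oriented
#' towards higher trait values, which fixes the direction of additive
#' coding), the genotyping plex the SNP was assayed on, and its genomic
#' coordinates (1-based).
#'
#' @param snp_id Character vector of unique SNP identifiers (rs numbers).
#' @param chrom Character vector of chromosome labels.
#' @param pos Integer vector of 1-based positions.
#' @param allele_a,allele_b Single characters from A/C/G/T; the two alleles
#'   observed at the SNP. Calls are validated against this pair.
#' @param increaser_allele For each SNP, which of `allele_a`/`allele_b` is
#'   associated with higher trait values.
#' @param plex Non-empty plex (assay batch) label per SNP, e.g. `"plex26"`.
#'
#' @return A `data.frame` with one row per SNP and the columns above.
#' @export
snp_info <- function(snp_id, chrom = "1", pos = seq_along(snp_id),
                     allele_a, allele_b, increaser_allele, plex = "plex1") {
  n <- length(snp_id)
  info <- data.frame(
    snp_id = as.character(snp_id),
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(rep_len(pos, n)),
    allele_a = rep_len(as.character(allele_a), n),
    allele_b = rep_len(as.character(allele_b), n),
    increaser_allele = rep_len(as.character(increaser_allele), n),
    plex = rep_len(as.character(plex), n),
    stringsAsFactors = FALSE
  )
  validate_snp_info(info)
  info
}

validate_snp_info <- function(info) {
  stopifnot(is.data.frame(info))
  required <- c("snp_id", "chrom", "pos", "allele_a", "allele_b",
                "increaser_allele", "plex")
  missing_cols <- setdiff(required, names(info))
  if (length(missing_cols)) {
    stop("snp_info is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(info$snp_id)) {
    stop("duplicate SNP IDs: ",
         paste(unique(info$snp_id[duplicated(info$snp_id)]), collapse = ", "))
  }
  bases <- c("A", "C", "G", "T")
  if (!all(info$allele_a %in% bases) || !all(info$allele_b %in% bases)) {
    stop("alleles must be single characters from A/C/G/T")
  }
  bad <- info$increaser_allele != info$allele_a &
    info$increaser_allele != info$allele_b
  if (any(bad)) {
    stop("increaser allele not among the declared allele pair for SNP(s): ",
         paste(info$snp_id[bad], collapse = ", "))
  }
  if (any(!nzchar(info$plex)) || anyNA(info$plex)) {
    stop("every SNP needs a non-empty plex label")
  }
  invisible(info)
}

#' Genotype matrix container
#'
#' An individuals-by-SNPs matrix of diploid allele-pair calls ("AG"-style
#' two-letter strings; `NA` = missing) together with the panel metadata
#' from [snp_info()]. Every non-missing call is checked against the two
#' alleles declared for its SNP.
#'
#' @param individual_ids Unique character IDs, one per row of `calls`.
#' @param snps A [snp_info()] data.frame, one row per column of `calls`.
#' @param calls Character matrix (`n_individuals` x `n_snps`) of two-letter
#'   calls or `NA`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `individual_ids`, `snps` and `calls` (dimnames set from the IDs).
#' @export
genotype_matrix <- function(individual_ids, snps, calls) {
  validate_snp_info(snps)
  individual_ids <- as.character(individual_ids)
  if (anyDuplicated(individual_ids)) {
    stop("duplicate individual IDs: ",
         paste(unique(individual_ids[duplicated(individual_ids)]),
               collapse = ", "))
  }
  calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (nrow(calls) != length(individual_ids) || ncol(calls) != nrow(snps)) {
    stop("calls must be ", length(individual_ids), " x ", nrow(snps),
         " (got ", nrow(calls), " x ", ncol(calls), ")")
  }
  dimnames(calls) <- list(individual_ids, snps$snp_id)
  gm <- structure(
    list(individual_ids = individual_ids, snps = snps, calls = calls),
    class = "genotype_matrix"
  )
  validate_calls(gm)
  gm
}

validate_calls <- function(gm) {
  for (j in seq_len(ncol(gm$calls))) {
    cj <- gm$calls[, j]
    ok <- is.na(cj)
    valid <- allele_pair_strings(gm$snps$allele_a[j], gm$snps$allele_b[j])
    ok <- ok | cj %in% valid
    if (!all(ok)) {
      i <- which(!ok)[1L]
      stop("invalid call '", cj[i], "' at SNP ", gm$snps$snp_id[j],
           ", individual ", gm$individual_ids[i],
           " (declared alleles ", gm$snps$allele_a[j], "/",
           gm$snps$allele_b[j], ")")
    }
  }
  invisible(gm)
}

# all two-letter strings writable with alleles {a, b}
allele_pair_strings <- function(a, b) {
  unique(c(paste0(a, a), paste0(a, b), paste0(b, a), paste0(b, b)))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$calls))
  cat("genotype_matrix: ", length(x$individual_ids), " individuals x ",
      nrow(x$snps), " SNPs (", n_miss, " missing calls)\n", sep = "")
  cat("plexes:", paste(sort(unique(x$snps$plex)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of individuals / SNPs in a genotype matrix
#' @param gm A [genotype_matrix()].
#' @return Integer count.
#' @export
n_individuals <- function(gm) length(gm$individual_ids)

#' @rdname n_individuals
#' @export
n_snps <- function(gm) nrow(gm$snps)

# subset rows/columns, keeping metadata in step
subset_genotypes <- function(gm, individuals = NULL, snps = NULL) {
  keep_i <- if (is.null(individuals)) seq_len(n_individuals(gm)) else individuals
  keep_j <- if (is.null(snps)) seq_len(n_snps(gm)) else snps
  genotype_matrix(
    gm$individual_ids[keep_i],
    gm$snps[keep_j, , drop = FALSE],
    gm$calls[keep_i, keep_j, drop = FALSE]
  )
}
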