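#' Read genotypes from PLINK text, VCF or TSV
#'
#' Reads a genotype panel into a [genotype_matrix()]. Three dialects are
#' supported:
#' \describe{
#'   \item{`pedmap`}{PLINK text `.ped`/`.map` pair. `path` is the common
#'     prefix (without extension). The missing code `0 0` maps to `NA`.}
#'   \item{`vcf`}{VCF v4.2, GT field only, biallelic records. `./.` maps
#'     to `NA`. Parsed with \pkg{vcfR}.}
#'   \item{`tsv`}{One row per individual, one column per SNP, calls as
#'     two-letter strings (`"AG"`), `"NN"` = missing.}
#' }
#' Neither PLINK text nor the TSV dialect can carry effect-direction or
#' plex annotation, and a VCF carries no plex either, so `panel` (a
#' [snp_info()] table) always supplies increaser alleles and plex labels;
#' it is matched to the files by SNP ID and must cover every SNP present.
#' No strand flipping is performed: increaser alleles must be stated on
#' the same strand as the calls.
#'
#' @param path File path (`vcf`, `tsv`) or path prefix (`pedmap`).
#' @param format One of `"pedmap"`, `"vcf"`, `"tsv"`.
#' @param panel A [snp_info()] data.frame supplying panel metadata.
#' @return A [genotype_matrix()]. Individuals and SNPs keep file order.
#' @export
read_genotypes <- function(path, format = c("pedmap", "vcf", "tsv"), panel) {
  format <- match.arg(format)
  validate_snp_info(panel)
  switch(format,
    pedmap = read_pedmap(path, panel),
    vcf = read_vcf_genotypes(path, panel),
    tsv = read_tsv_genotypes(path, panel)
  )
}

# align the user-supplied panel to the SNP ids found in a file
panel_for <- function(panel, snp_ids, chrom = NULL, pos = NULL) {
  idx <- match(snp_ids, panel$snp_id)
  if (anyNA(idx)) {
    stop("panel metadata missing for SNP(s): ",
         paste(snp_ids[is.na(idx)], collapse = ", "))
  }
  out <- panel[idx, , drop = FALSE]
  if (!is.null(chrom)) out$chrom <- as.character(chrom)
  if (!is.null(pos)) out$pos <- as.integer(pos)
  rownames(out) <- NULL
  out
}

read_pedmap <- function(prefix, panel) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  if (!file.exists(map_path)) stop("no such file: ", map_path)
  if (!file.exists(ped_path)) stop("no such file: ", ped_path)
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) != 4) stop("malformed .map: expected 4 columns")
  snps <- panel_for(panel, map[[2]], chrom = map[[1]], pos = as.integer(map[[4]]))
  m <- nrow(snps)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  ids <- character(length(lines))
  calls <- matrix(NA_character_, length(lines), m)
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(fields) != 6 + 2 * m) {
      stop("malformed .ped line ", i, ": expected ", 6 + 2 * m,
           " fields, got ", length(fields))
    }
    ids[i] <- fields[2]
    a1 <- fields[seq(7, by = 2, length.out = m)]
    a2 <- fields[seq(8, by = 2, length.out = m)]
    miss <- a1 == "0" | a2 == "0"
    calls[i, ] <- ifelse(miss, NA_character_, paste0(a1, a2))
  }
  genotype_matrix(ids, snps, calls)
}

read_vcf_genotypes <- function(path, panel) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (!is.matrix(fix)) { # single-record files come back as a bare vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  snp_ids <- unname(fix[, "ID"])
  ref <- unname(fix[, "REF"])
  alt <- unname(fix[, "ALT"])
  if (any(nchar(ref) != 1 | nchar(alt) != 1 | grepl(",", alt))) {
    stop("only biallelic SNP records are supported")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gsub("\\|", "/", gt)
  snps <- panel_for(panel, snp_ids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]))
  m <- nrow(snps)
  ids <- colnames(gt)
  calls <- matrix(NA_character_, length(ids), m)
  for (j in seq_len(m)) {
    g <- gt[j, ]
    al <- c(`0` = ref[j], `1` = alt[j])
    parts <- strsplit(g, "/", fixed = TRUE)
    calls[, j] <- vapply(parts, function(p) {
      if (length(p) != 2 || anyNA(p) || any(p == ".")) return(NA_character_)
      if (!all(p %in% names(al))) {
        stop("unsupported GT allele index at SNP ", snp_ids[j])
      }
      paste0(al[p[order(as.integer(p))]], collapse = "")
    }, character(1))
  }
  genotype_matrix(ids, snps, calls)
}

read_tsv_genotypes <- function(path, panel) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE)
  if (names(tab)[1] != "id") stop("TSV genotype file must start with an 'id' column")
  snps <- panel_for(panel, names(tab)[-1])
  calls <- as.matrix(tab[, -1, drop = FALSE])
  calls[calls == "NN" | calls == ""] <- NA_character_
  genotype_matrix(tab$id, snps, calls)
}

#' Write genotypes to PLINK text, VCF or TSV
#'
#' Inverse of [read_genotypes()]: emits files that re-read to an equal
#' matrix, preserving row and column order. Missing calls are written as
#' `0 0` (ped), `./.` (VCF) or `NN` (TSV). Output is deterministic.
#'
#' For VCF, `allele_a` is written as REF and `allele_b` as ALT, and each
#' call is encoded by its count of `allele_b`.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path (`vcf`, `tsv`) or prefix (`pedmap`).
#' @param format One of `"pedmap"`, `"vcf"`, `"tsv"`.
#' @return Invisibly, the path(s) written.
#' @export
write_genotypes <- function(gm, path, format = c("pedmap", "vcf", "tsv")) {
  format <- match.arg(format)
  switch(format,
    pedmap = write_pedmap(gm, path),
    vcf = write_vcf_genotypes(gm, path),
    tsv = write_tsv_genotypes(gm, path)
  )
}

write_pedmap <- function(gm, prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  map <- with(gm$snps, paste(chrom, snp_id, 0, pos, sep = "\t"))
  writeLines(map, map_path)
  m <- n_snps(gm)
  ped <- vapply(seq_len(n_individuals(gm)), function(i) {
    g <- gm$calls[i, ]
    a1 <- ifelse(is.na(g), "0", substr(g, 1, 1))
    a2 <- ifelse(is.na(g), "0", substr(g, 2, 2))
    geno <- paste(a1, a2, collapse = " ")
    paste(gm$individual_ids[i], gm$individual_ids[i], 0, 0, 0, -9, geno)
  }, character(1))
  writeLines(ped, ped_path)
  invisible(c(ped_path, map_path))
}

write_vcf_genotypes <- function(gm, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$individual_ids), collapse = "\t")
  )
  body <- vapply(seq_len(n_snps(gm)), function(j) {
    s <- gm$snps[j, ]
    g <- gm$calls[, j]
    nb <- count_allele(g, s$allele_b)
    gt <- ifelse(is.na(g), "./.", c("0/0", "0/1", "1/1")[nb + 1L])
    paste(c(s$chrom, s$pos, s$snp_id, s$allele_a, s$allele_b, ".", "PASS",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

write_tsv_genotypes <- function(gm, path) {
  calls <- gm$calls
  calls[is.na(calls)] <- "NN"
  tab <- data.frame(id = gm$individual_ids, calls, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# copies of `allele` in each two-letter call (NA propagates)
count_allele <- function(calls, allele) {
  (substr(calls, 1, 1) == allele) + (substr(calls, 2, 2) == allele)
}

#' Read a phenotype table from TSV
#'
#' Expects a header row; an `id` column of unique individual IDs; an
#' optional `sex` column coded 0/1 (or M/F, mapped to 0/1); and numeric
#' columns for ages at testing and trait measures. Empty cells and `NA`
#' are read as missing.
#'
#' @param path TSV file path.
#' @return A `data.frame`, one row per individual.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, na.strings = c("", "NA"))
  if (!"id" %in% names(tab)) stop("phenotype TSV must have an 'id' column")
  if (anyDuplicated(tab$id)) {
    stop("duplicate individual ID(s): ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  for (col in setdiff(names(tab), "id")) {
    x <- tab[[col]]
    if (col == "sex") {
      x[x %in% c("M", "m")] <- "0"
      x[x %in% c("F", "f")] <- "1"
    }
    num <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(num))
    if (length(bad)) {
      stop("non-numeric value '", x[bad[1]], "' in column '", col,
           "', row ", bad[1])
    }
    tab[[col]] <- num
  }
  if ("sex" %in% names(tab) &&
      !all(tab$sex %in% c(0, 1) | is.na(tab$sex))) {
    stop("sex must be coded 0/1 (or M/F)")
  }
  tab
}

#' Write a phenotype table to TSV
#'
#' @param pheno A phenotype `data.frame` as returned by [read_phenotypes()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write an association report as CSV
#'
#' One row per predictor-by-measure cell: predictor, measure, r, N,
#' one-tailed p, and nominal/Bonferroni significance flags. Correlations
#' are reported to 3 decimals and p-values with 3 significant digits.
#'
#' @param results Association result `data.frame` from
#'   [association_table()] or [associate()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_association_csv <- function(results, path) {
  out <- results
  out$r <- sprintf("%.3f", out$r)
  out$p_one_tailed <- ifelse(is.na(out$p_one_tailed), NA,
                             sprintf("%.3g", out$p_one_tailed))
  utils::write.csv(out, path, row.names = FALSE, na = "NA")
  invisible(path)
}
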