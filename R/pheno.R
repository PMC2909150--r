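#' Standardize a measure to mean 0, SD 1
#'
#' Centers and scales the non-missing entries to sample mean 0 and
#' sample standard deviation 1 (n - 1 denominator); missing entries are
#' preserved. Standardization is idempotent.
#'
#' @param x Numeric vector, `NA` allowed.
#' @return Numeric vector of the same length.
#' @export
standardize <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) < 2) stop("need at least 2 non-missing values")
  s <- stats::sd(obs)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (x - mean(obs)) / s
}

#' Residualize a measure on covariates
#'
#' Ordinary least-squares regression of `x` on the given covariates
#' (with intercept) over complete cases; returns the residuals,
#' re-standardized by default. Rows missing `x` or any covariate come
#' back as `NA`. Covariates that are constant on the complete cases are
#' dropped from the design with a warning (e.g. an age column that does
#' not vary); a rank-deficient design after dropping is an error.
#'
#' @param x Numeric vector to adjust.
#' @param covariates A numeric vector, matrix or data.frame of
#'   covariates, row-aligned with `x`.
#' @param restandardize Re-standardize the residuals (default `TRUE`).
#' @return Numeric vector of (standardized) residuals with `NA` where
#'   input was incomplete.
#' @export
residualize <- function(x, covariates, restandardize = TRUE) {
  cov_mat <- as.matrix(as.data.frame(covariates))
  storage.mode(cov_mat) <- "double"
  if (nrow(cov_mat) != length(x)) stop("covariates must align with x")
  complete <- !is.na(x) & stats::complete.cases(cov_mat)
  if (sum(complete) < ncol(cov_mat) + 2) {
    stop("need at least ", ncol(cov_mat) + 2, " complete cases")
  }
  keep <- apply(cov_mat[complete, , drop = FALSE], 2,
                function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(cov_mat)[!keep], collapse = ", "))
    cov_mat <- cov_mat[, keep, drop = FALSE]
  }
  out <- rep(NA_real_, length(x))
  if (ncol(cov_mat) == 0) {
    res <- x[complete] - mean(x[complete])
  } else {
    design <- cbind(1, cov_mat[complete, , drop = FALSE])
    if (qr(design)$rank < ncol(design)) {
      stop("covariate design is rank deficient")
    }
    fit <- stats::lm.fit(design, x[complete])
    res <- fit$residuals
    # covariates explaining (numerically) all variance leave nothing to analyze
    if (stats::var(res) < 1e-12 * stats::var(x[complete])) {
      stop("residuals are (numerically) constant: covariates explain all ",
           "variance in x")
    }
  }
  out[complete] <- res
  if (restandardize) standardize(out) else out
}

#' Composite-score specification
#'
#' Describes how a composite measure is assembled from component
#' measures: each component is standardized, the per-individual mean of
#' the available standardized components is taken, and the result is
#' re-standardized. `fallback_single` admits individuals with only one
#' component available (their single standardized score enters the
#' composite pool); `require_all` instead sets the composite missing
#' unless every component is present. With neither flag, individuals
#' need at least two available components.
#'
#' @param components Character vector (length >= 2) of measure labels.
#' @param fallback_single Accept single-component individuals.
#' @param require_all Demand all components.
#' @return A list of class `composite_spec`.
#' @export
composite_spec <- function(components, fallback_single = FALSE,
                           require_all = FALSE) {
  components <- as.character(components)
  if (length(components) < 2) stop("a composite needs at least 2 components")
  if (fallback_single && require_all) {
    stop("fallback_single and require_all are mutually exclusive")
  }
  structure(list(components = components, fallback_single = fallback_single,
                 require_all = require_all), class = "composite_spec")
}

#' Build a composite measure
#'
#' @param table Phenotype `data.frame` containing the component columns.
#' @param spec A [composite_spec()].
#' @param restandardize Re-standardize the final composite (default `TRUE`).
#' @return Numeric vector, one value per row of `table`.
#' @export
build_composite <- function(table, spec, restandardize = TRUE) {
  stopifnot(inherits(spec, "composite_spec"))
  miss <- setdiff(spec$components, names(table))
  if (length(miss)) {
    stop("component measure(s) missing from table: ",
         paste(miss, collapse = ", "))
  }
  z <- vapply(spec$components, function(m) standardize(table[[m]]),
              numeric(nrow(table)))
  n_avail <- rowSums(!is.na(z))
  comp <- rowMeans(z, na.rm = TRUE)
  # minimum available components: all (require_all), one (fallback_single),
  # or two by default
  min_avail <- if (spec$require_all) length(spec$components)
    else if (spec$fallback_single) 1L else 2L
  comp[n_avail < min_avail] <- NA_real_
  if (!any(!is.na(comp))) stop("no usable rows for composite")
  if (restandardize) standardize(comp) else comp
}

#' Prepare analysis measures: composites, sex/age correction
#'
#' Builds any configured composites, then residualizes every analysis
#' measure on sex and its age-at-testing column and re-standardizes, so
#' each prepared measure has mean 0, SD 1 and zero sample correlation
#' with the covariates. The residualize-then-standardize order makes
#' downstream correlations scale-free.
#'
#' @param table Phenotype `data.frame` with an `id` column, a `sex`
#'   column (0/1) and age/measure columns.
#' @param config A list with elements:
#'   \describe{
#'     \item{`measures`}{Named list mapping each analysis measure to its
#'       age-at-testing column (or `NA`/`NULL` for sex-only
#'       adjustment).}
#'     \item{`composites`}{Optional named list of [composite_spec()]s,
#'       built (and added to the table) before adjustment.}
#'   }
#' @param restandardize Re-standardize residuals (default `TRUE`).
#' @return The phenotype `data.frame` with the analysis measures
#'   replaced by their adjusted versions.
#' @export
prepare_measures <- function(table, config, restandardize = TRUE) {
  if (!"sex" %in% names(table)) stop("phenotype table needs a 'sex' column")
  for (nm in names(config$composites %||% list())) {
    table[[nm]] <- build_composite(table, config$composites[[nm]],
                                   restandardize = FALSE)
  }
  measures <- config$measures
  for (m in names(measures)) {
    if (!m %in% names(table)) stop("measure not in table: ", m)
    age_col <- measures[[m]]
    covs <- data.frame(sex = table$sex)
    if (!is.null(age_col) && !is.na(age_col)) {
      if (!age_col %in% names(table)) stop("age column not in table: ", age_col)
      covs$age <- table[[age_col]]
    }
    table[[m]] <- residualize(table[[m]], covs,
                              restandardize = restandardize)
  }
  table
}
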