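#' Pearson correlation on pairwise-complete cases
#'
#' Sample product-moment correlation between two vectors over the rows
#' where both are observed, together with the complete-pair count.
#'
#' @param x,y Numeric vectors of equal length, `NA` allowed.
#' @return A list with `r` and `N`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  complete <- !is.na(x) & !is.na(y)
  n <- sum(complete)
  if (n < 3) stop("need at least 3 complete pairs (got ", n, ")")
  xs <- x[complete]
  ys <- y[complete]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stop("cannot correlate a constant vector")
  }
  list(r = stats::cor(xs, ys), N = n)
}

#' One-tailed p-value for a correlation in the expected direction
#'
#' Upper-tail p-value of \eqn{t = r\sqrt{(N-2)/(1-r^2)}} on \eqn{N-2}
#' degrees of freedom. The expected direction is positive by
#' construction: additive coding already orients each SNP's increaser
#' allele, so a negative correlation is evidence against the directional
#' hypothesis and yields p > 0.5.
#'
#' @param r Sample correlation.
#' @param N Complete-pair count (>= 3).
#' @return A p-value; boundary values r = 1 (p = 0) and r = -1 (p = 1)
#'   are returned with a warning.
#' @export
one_tailed_p <- function(r, N) {
  if (N < 3) stop("N must be at least 3")
  if (abs(r) > 1) stop("|r| must not exceed 1")
  if (abs(r) == 1) {
    warning("|r| = 1: p-value at the boundary by convention")
    return(if (r > 0) 0 else 1)
  }
  t_stat <- r * sqrt((N - 2) / (1 - r^2))
  stats::pt(t_stat, df = N - 2, lower.tail = FALSE)
}

#' Nominal and Bonferroni significance flags
#'
#' Nominal significance is p < 0.05; Bonferroni significance is
#' p < 0.05/m for `m` simultaneous tests per measure (m = 5 in the
#' headline design: two SNP sets plus three individual SNPs, giving a
#' per-test level of 0.01).
#'
#' @param p P-value(s) in (0, 1].
#' @param m Number of simultaneous tests (>= 1).
#' @return A list with logical `nominal` and `bonferroni`.
#' @export
significance_flags <- function(p, m = 5) {
  if (any(m < 1)) stop("m must be >= 1")
  list(nominal = p < 0.05, bonferroni = p < 0.05 / m)
}

#' Test one predictor-measure association
#'
#' Composes [pearson_r()], [one_tailed_p()] and [significance_flags()]
#' into a single association-result row.
#'
#' @param predictor Numeric predictor vector (SNP-set score or additive
#'   single-SNP dosage), row-aligned with `measure`.
#' @param measure Numeric measure vector.
#' @param m Tests per measure for the Bonferroni flag.
#' @param predictor_label,measure_label Report labels.
#' @return One-row `data.frame`: `predictor`, `measure`, `r`, `N`,
#'   `p_one_tailed`, `nominal`, `bonferroni`.
#' @export
associate <- function(predictor, measure, m = 5,
                      predictor_label = "predictor",
                      measure_label = "measure") {
  est <- pearson_r(predictor, measure)
  p <- one_tailed_p(est$r, est$N)
  flags <- significance_flags(p, m)
  data.frame(predictor = predictor_label, measure = measure_label,
             r = est$r, N = est$N, p_one_tailed = p,
             nominal = flags$nominal, bonferroni = flags$bonferroni,
             stringsAsFactors = FALSE)
}

#' Full association table with a phenotypic-correlation row
#'
#' Runs [associate()] for every predictor-by-measure pair (per-measure
#' Bonferroni correction at `m_tests_per_measure`), then appends one
#' phenotypic-correlation (`r_p`) row per measure: the plain two-sided
#' Pearson correlation of the measure with the focal measure, reported
#' as r and N only. Per-cell N varies with missingness
#' (pairwise-complete, no listwise deletion).
#'
#' @param predictors Named list (or data.frame) of numeric predictor
#'   vectors, all row-aligned with `measures`.
#' @param measures Named list (or data.frame) of numeric measure vectors.
#' @param m_tests_per_measure Tests per measure for Bonferroni (default 5).
#' @param focal_measure Name of the focal measure for the `r_p` row
#'   (default: none, no `r_p` rows).
#' @return A `data.frame` of association rows plus `r_p` rows (the
#'   latter with `predictor = "r_p"` and `NA` p/flags; the focal measure
#'   against itself is reported as `NA`).
#' @export
association_table <- function(predictors, measures, m_tests_per_measure = 5,
                              focal_measure = NULL) {
  predictors <- as.data.frame(predictors, optional = TRUE)
  measures <- as.data.frame(measures, optional = TRUE)
  rows <- list()
  for (meas in names(measures)) {
    for (pred in names(predictors)) {
      rows[[length(rows) + 1L]] <- associate(
        predictors[[pred]], measures[[meas]], m = m_tests_per_measure,
        predictor_label = pred, measure_label = meas)
    }
  }
  if (!is.null(focal_measure)) {
    if (!focal_measure %in% names(measures)) {
      stop("focal measure not found: ", focal_measure)
    }
    for (meas in names(measures)) {
      if (meas == focal_measure) {
        rp <- list(r = NA_real_, N = NA_integer_)
      } else {
        rp <- pearson_r(measures[[meas]], measures[[focal_measure]])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = "r_p", measure = meas, r = rp$r, N = rp$N,
        p_one_tailed = NA_real_, nominal = NA, bonferroni = NA,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Association after regressing controls out of the measure
#'
#' Residualizes the measure on one or more control measures (ordinary
#' least squares, re-standardized) and then tests its association with
#' the predictor. Only the phenotype is residualized, matching the
#' specificity analyses in which other cognitive abilities are regressed
#' out of the focal composite; set `partial = TRUE` to residualize the
#' predictor on the same controls as well (full partial correlation).
#' The effective N shrinks to the jointly complete sample.
#'
#' @inheritParams associate
#' @param controls Numeric vector, matrix or data.frame of control
#'   measures, row-aligned with `measure`.
#' @param partial Also residualize the predictor (default `FALSE`).
#' @return One-row association `data.frame` as from [associate()].
#' @export
regress_out_and_associate <- function(predictor, measure, controls, m = 5,
                                      predictor_label = "predictor",
                                      measure_label = "measure",
                                      partial = FALSE) {
  ctrl <- as.data.frame(controls, optional = TRUE)
  complete <- !is.na(predictor) & !is.na(measure) & stats::complete.cases(ctrl)
  if (sum(complete) < 10) {
    stop("need at least 10 jointly complete cases (got ", sum(complete), ")")
  }
  measure_masked <- ifelse(complete, measure, NA_real_)
  adj_measure <- residualize(measure_masked, ctrl)
  adj_pred <- if (partial) {
    residualize(ifelse(complete, predictor, NA_real_), ctrl)
  } else {
    predictor
  }
  associate(adj_pred, adj_measure, m = m,
            predictor_label = predictor_label,
            measure_label = paste0(measure_label, "|adj"))
}
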