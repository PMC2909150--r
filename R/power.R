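#' Convert a correlation to percent variance explained
#'
#' Under the additive QTL model the squared correlation between a SNP
#' predictor and a quantitative trait is the share of trait variance the
#' predictor explains, so e.g. r = 0.067 corresponds to an effect size
#' of 0.45% of the variance.
#'
#' @param r Correlation(s), |r| <= 1.
#' @return Percent of variance, `100 * r^2`.
#' @export
r_to_pct_variance <- function(r) {
  if (any(abs(r) > 1)) stop("|r| must not exceed 1")
  100 * r^2
}

#' Convert percent variance explained to a correlation
#'
#' Inverse of [r_to_pct_variance()] (round-trips to 1e-12).
#'
#' @param pct Percent of variance in [0, 100].
#' @return Correlation, `sqrt(pct / 100)`.
#' @export
pct_variance_to_r <- function(pct) {
  if (any(pct < 0 | pct > 100)) stop("pct must lie in [0, 100]")
  sqrt(pct / 100)
}

#' Power of a QTL correlation test
#'
#' Analytic power to detect a true correlation `r` between an additively
#' coded SNP predictor and a quantitative trait in a sample of size `n`.
#' Two equivalent parameterizations are available:
#' \describe{
#'   \item{`"t"`}{Noncentral-t formulation of the correlation test, with
#'     noncentrality \eqn{r\sqrt{n}/\sqrt{1-r^2}} on n - 2 degrees of
#'     freedom; supports one- or two-tailed alpha.}
#'   \item{`"chisq"`}{Noncentral chi-square with `df` degrees of freedom
#'     and noncentrality \eqn{n r^2} (the variance-explained
#'     parameterization used by genetic power calculators; df = 1 is
#'     the additive-only 1-df test, df = 2 the additive + dominance
#'     genotypic test). The chi-square is inherently two-sided in the
#'     effect, so `tails` is ignored. MAF does not enter: under the
#'     additive single-SNP test, r^2 fully determines power.}
#' }
#' The df = 1 chi-square at two-tailed alpha and the two-tailed t
#' formulation agree to well within 0.01 at the sample sizes used here.
#'
#' @param r True correlation in (0, 1).
#' @param n Sample size (>= 4).
#' @param alpha Test level (default 0.05).
#' @param tails 1 (default, directional) or 2; `"t"` method only.
#' @param method `"t"` (default) or `"chisq"`.
#' @param df Degrees of freedom for the chi-square method (1 or 2).
#' @return Power in (0, 1).
#' @export
power_correlation_test <- function(r, n, alpha = 0.05, tails = 1,
                                   method = c("t", "chisq"), df = 1) {
  method <- match.arg(method)
  if (any(r <= 0 | r >= 1)) stop("r must lie in (0, 1)")
  if (any(n < 4)) stop("n must be at least 4")
  if (!alpha > 0 || !alpha <= 0.5) stop("alpha must lie in (0, 0.5]")
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2")
  if (method == "chisq") {
    if (!df %in% c(1, 2)) stop("df must be 1 or 2")
    crit <- stats::qchisq(1 - alpha, df = df)
    return(stats::pchisq(crit, df = df, ncp = n * r^2, lower.tail = FALSE))
  }
  ncp <- r * sqrt(n) / sqrt(1 - r^2)
  dfree <- n - 2
  if (tails == 1) {
    crit <- stats::qt(1 - alpha, df = dfree)
    stats::pt(crit, df = dfree, ncp = ncp, lower.tail = FALSE)
  } else {
    crit <- stats::qt(1 - alpha / 2, df = dfree)
    stats::pt(crit, df = dfree, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-crit, df = dfree, ncp = ncp)
  }
}

#' Smallest effect detectable at a target power
#'
#' Bisects on r in (0, 1) for the correlation at which
#' [power_correlation_test()] reaches `target_power` (to within 1e-6 in
#' power), and reports it both as a correlation and as percent variance.
#' The detectable effect shrinks monotonically as n grows.
#'
#' @inheritParams power_correlation_test
#' @param target_power Desired power in (0, 1), e.g. 0.80.
#' @return A list with `r`, `pct_variance` and the achieved `power`.
#' @export
detectable_effect <- function(n, target_power = 0.80, alpha = 0.05,
                              tails = 1, method = c("t", "chisq"), df = 1) {
  method <- match.arg(method)
  if (target_power <= alpha || target_power >= 1) {
    stop("target_power must lie in (alpha, 1)")
  }
  pw <- function(r) power_correlation_test(r, n, alpha = alpha, tails = tails,
                                           method = method, df = df)
  lo <- 1e-9
  hi <- 1 - 1e-9
  if (pw(hi) < target_power) stop("target power unattainable at this n")
  repeat {
    mid <- (lo + hi) / 2
    p_mid <- pw(mid)
    if (abs(p_mid - target_power) < 1e-6 || (hi - lo) < 1e-14) break
    if (p_mid < target_power) lo <- mid else hi <- mid
  }
  list(r = mid, pct_variance = r_to_pct_variance(mid), power = p_mid)
}

#' Tabulate power queries
#'
#' Convenience wrapper evaluating [detectable_effect()] (and the power
#' at a stated r, when given) for a list of query settings; used by the
#' pipeline's power annex.
#'
#' @param queries A list of lists with fields `n`, and optionally
#'   `alpha`, `tails`, `method`, `df`, `target_power`, `r`.
#' @return A `data.frame`, one row per query: the settings, the
#'   detectable `r` and `pct_variance` at `target_power`, and (when `r`
#'   was supplied) the power at that r.
#' @export
power_table <- function(queries) {
  rows <- lapply(queries, function(q) {
    alpha <- q$alpha %||% 0.05
    tails <- q$tails %||% 1
    method <- q$method %||% "t"
    df <- q$df %||% 1
    target <- q$target_power %||% 0.80
    det <- detectable_effect(q$n, target_power = target, alpha = alpha,
                             tails = tails, method = method, df = df)
    data.frame(
      n = q$n, alpha = alpha, tails = tails, method = method, df = df,
      target_power = target, detectable_r = det$r,
      detectable_pct_variance = det$pct_variance,
      r = q$r %||% NA_real_,
      power_at_r = if (is.null(q$r)) NA_real_ else
        power_correlation_test(q$r, q$n, alpha = alpha, tails = tails,
                               method = method, df = df),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
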