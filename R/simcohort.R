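#' Trait specification for the cohort simulator
#'
#' Each simulated trait loads on the shared (pleiotropic) genetic path
#' of the SNP panel with coefficient `rho`, the genetic-generality
#' coefficient: the trait's expected correlation with the SNP-set path
#' is `rho * target_r`. A genetically null trait (`rho = 0`) can still
#' be phenotypically correlated with the focal trait by drawing part of
#' its residual from the focal trait's residual (`pheno_link`), so that
#' the pair correlate phenotypically while the null trait stays
#' uncorrelated with the genotypes.
#'
#' @param label Measure name.
#' @param rho Genetic-generality coefficient in [0, 1].
#' @param pheno_link Share of the focal trait's residual mixed into this
#'   trait's residual, in [0, 1); 0 for none.
#' @param age_group Label of the age-at-testing group (e.g. `"a10"`).
#' @param focal Is this the focal trait? Exactly one trait must be.
#' @return A one-row `data.frame`.
#' @export
trait_spec <- function(label, rho, pheno_link = 0, age_group = "a10",
                       focal = FALSE) {
  data.frame(label = label, rho = rho, pheno_link = pheno_link,
             age_group = age_group, focal = focal,
             stringsAsFactors = FALSE)
}

#' Cohort simulation specification
#'
#' Collects every generative parameter of the synthetic cohort: sample
#' size; per-SNP minor (increaser) allele frequencies; the focal
#' trait's SNP-set correlation `target_r`; the trait list with
#' genetic-generality coefficients; sex and age covariate effects; the
#' three missing-data rates; the SNP-to-plex assignment; and the master
#' seed from which all randomness flows.
#'
#' @param n_individuals Cohort size.
#' @param snp_mafs Increaser-allele frequencies in (0, 0.5].
#' @param target_r Focal-trait SNP-set correlation in [0, 1).
#' @param traits `data.frame` of [trait_spec()] rows (exactly one focal).
#' @param sex_effect Standardized mean difference added to each trait
#'   for sex = 1.
#' @param age_slope Standardized effect per year of (centered)
#'   age-at-testing.
#' @param age_centers Named numeric vector of nominal ages (years) per
#'   age group.
#' @param age_jitter Half-width (years) of the uniform age spread within
#'   a group.
#' @param plex_dropout_rate Probability an individual drops a whole plex.
#' @param snp_miss_rate Per-call genotype missingness probability.
#' @param pheno_miss_rate Per-cell phenotype missingness probability.
#' @param plex_assignment Character vector (length = number of SNPs) of
#'   plex labels; `NULL` spreads SNPs over plex26/plex33/plex36/taqman.
#' @param seed Master integer seed.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_individuals,
                            snp_mafs,
                            target_r,
                            traits,
                            sex_effect = 0.1,
                            age_slope = 0.2,
                            age_centers = c(a7 = 7, a9 = 9, a10 = 10, a12 = 12),
                            age_jitter = 0.5,
                            plex_dropout_rate = 0,
                            snp_miss_rate = 0,
                            pheno_miss_rate = 0,
                            plex_assignment = NULL,
                            seed = 1L) {
  if (any(snp_mafs <= 0 | snp_mafs > 0.5)) {
    stop("snp_mafs must lie in (0, 0.5]")
  }
  if (target_r < 0 || target_r >= 1) stop("target_r must lie in [0, 1)")
  stopifnot(is.data.frame(traits),
            all(c("label", "rho", "pheno_link", "age_group", "focal")
                %in% names(traits)))
  if (any(traits$rho < 0 | traits$rho > 1)) stop("rho must lie in [0, 1]")
  if (sum(traits$focal) != 1) stop("exactly one trait must be focal")
  a <- traits$rho * target_r
  if (any(a^2 + traits$pheno_link^2 >= 1)) {
    stop("rho * target_r and pheno_link jointly leave no residual variance")
  }
  rates <- c(plex_dropout_rate, snp_miss_rate, pheno_miss_rate)
  if (any(rates < 0 | rates >= 1)) stop("missingness rates must lie in [0, 1)")
  if (!all(traits$age_group %in% names(age_centers))) {
    stop("every trait's age_group needs an entry in age_centers")
  }
  if (is.null(plex_assignment)) {
    plex_assignment <- default_plex_assignment(length(snp_mafs))
  }
  if (length(plex_assignment) != length(snp_mafs)) {
    stop("plex_assignment must name a plex per SNP")
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    snp_mafs = as.numeric(snp_mafs),
    target_r = target_r,
    traits = traits,
    sex_effect = sex_effect,
    age_slope = age_slope,
    age_centers = age_centers,
    age_jitter = age_jitter,
    plex_dropout_rate = plex_dropout_rate,
    snp_miss_rate = snp_miss_rate,
    pheno_miss_rate = pheno_miss_rate,
    plex_assignment = as.character(plex_assignment),
    seed = as.integer(seed)
  ), class = "simulation_spec")
}

# spread SNPs over three multiplex batches plus a singleplex assay,
# echoing a typical medium-throughput panel layout
default_plex_assignment <- function(k) {
  pool <- c("plex26", "plex33", "plex36", "taqman")
  sizes <- rep(k %/% 4, 4) + c(rep(1, k %% 4), rep(0, 4 - k %% 4))
  rep(pool, times = sizes)
}

#' Default cohort specification
#'
#' A ready-made specification mirroring the study conditions the
#' package is calibrated against: 4,000 unrelated individuals; 43
#' unlinked SNPs in Hardy-Weinberg equilibrium with increaser-allele
#' frequencies evenly spread over 0.1-0.5; a focal mathematics trait
#' whose SNP-set correlation is 0.179 (3.2% of variance); companion
#' traits attenuated by genetic correlations of 0.84 (within-domain
#' component), 0.73 and 0.62 (adjacent ages), and 0.79, 0.76, 0.52
#' (other abilities), each additionally sharing enough of the focal
#' trait's residual to reproduce realistic phenotypic correlations
#' (roughly 0.5-0.9 within mathematics, ~0.5-0.7 across abilities); and
#' two genetically null behavioural traits that correlate
#' phenotypically with the focal trait at 0.356 and 0.448.
#' Missingness is off by default; pass rates to switch it on.
#'
#' @param n_individuals Cohort size (default 4000).
#' @param n_snps Panel size (default 43).
#' @param target_r Focal SNP-set correlation (default 0.179).
#' @param seed Master seed.
#' @param ... Overrides passed on to [simulation_spec()].
#' @return A `simulation_spec`.
#' @export
default_simulation_spec <- function(n_individuals = 4000, n_snps = 43,
                                    target_r = 0.179, seed = 1L, ...) {
  traits <- rbind(
    trait_spec("math10", 1, age_group = "a10", focal = TRUE),
    trait_spec("math10_component", 0.84, pheno_link = 0.85, age_group = "a10"),
    trait_spec("math9", 0.73, pheno_link = 0.63, age_group = "a9"),
    trait_spec("math7", 0.62, pheno_link = 0.59, age_group = "a7"),
    trait_spec("english10", 0.79, pheno_link = 0.67, age_group = "a10"),
    trait_spec("g10", 0.76, pheno_link = 0.60, age_group = "a10"),
    trait_spec("reading10", 0.52, pheno_link = 0.52, age_group = "a10"),
    trait_spec("motivation12", 0, pheno_link = 0.356, age_group = "a12"),
    trait_spec("liking12", 0, pheno_link = 0.448, age_group = "a12")
  )
  simulation_spec(
    n_individuals = n_individuals,
    snp_mafs = seq(0.1, 0.5, length.out = n_snps),
    target_r = target_r,
    traits = traits,
    seed = seed,
    ...
  )
}

#' Simulate genotypes in Hardy-Weinberg equilibrium
#'
#' Draws each SNP's increaser-allele count i.i.d. Binomial(2, maf), so
#' genotypes are in Hardy-Weinberg proportions by construction and SNPs
#' are mutually independent (no linkage disequilibrium). Alleles are
#' written A (non-increaser) / G (increaser), with `maf` the frequency
#' of the increaser allele.
#'
#' @param mafs Increaser-allele frequencies in (0, 0.5].
#' @param n Number of individuals.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param plex Optional plex label per SNP.
#' @return A [genotype_matrix()] with SNP IDs `snp01`, `snp02`, ...
#' @export
simulate_genotypes <- function(mafs, n, seed = NULL, plex = NULL) {
  if (any(mafs <= 0 | mafs > 0.5)) stop("mafs must lie in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  k <- length(mafs)
  if (is.null(plex)) plex <- default_plex_assignment(k)
  snps <- snp_info(
    snp_id = sprintf("snp%02d", seq_len(k)),
    chrom = as.character(rep_len(1:22, k)),
    pos = seq_len(k) * 1000L,
    allele_a = "A", allele_b = "G", increaser_allele = "G",
    plex = plex
  )
  counts <- vapply(mafs, function(p) stats::rbinom(n, 2, p), integer(n))
  counts <- matrix(counts, nrow = n)
  calls <- matrix(c("AA", "AG", "GG")[counts + 1L], nrow = n)
  genotype_matrix(sprintf("id%05d", seq_len(n)), snps, calls)
}

#' Calibrate equal-contribution SNP effects
#'
#' Returns positive per-SNP effects (increaser orientation) such that
#' each SNP contributes equally to the genetic variance and the total
#' variance explained in a unit-variance phenotype is `target_r^2`:
#' \eqn{\sum_j 2 p_j (1 - p_j) \beta_j^2 = r^2}. For a single SNP this
#' reduces to \eqn{\beta = r / \sqrt{2 p (1 - p)}}.
#'
#' @param mafs Increaser-allele frequencies.
#' @param target_r Target SNP-set correlation in [0, 1).
#' @return Numeric vector of betas.
#' @export
calibrate_effects <- function(mafs, target_r) {
  if (target_r < 0 || target_r >= 1) stop("target_r must lie in [0, 1)")
  k <- length(mafs)
  target_r / sqrt(k * 2 * mafs * (1 - mafs))
}

#' Simulate phenotypes under a generalist-genes structure
#'
#' Builds the latent genetic path \eqn{Z} (the standardized weighted sum
#' \eqn{\sum_j \beta_j (g_j - 2 p_j)}) and generates each trait as
#' \deqn{y_t = a_t Z + \lambda_t \varepsilon_f +
#'       \sqrt{1 - a_t^2 - \lambda_t^2}\, \eta_t,}
#' with \eqn{a_t = \rho_t \cdot} `target_r`, \eqn{\lambda_t} the
#' trait's `pheno_link`, \eqn{\varepsilon_f} the focal trait's own
#' residual and \eqn{\eta_t} independent standard normal. Sex (Bernoulli
#' 0.5) and uniform age-at-testing effects are added afterwards:
#' \eqn{y_t \mathrel{+}=} `sex_effect` \eqn{\cdot} sex + `age_slope`
#' \eqn{\cdot} (age - mean age). The expected correlation of trait t
#' with the SNP-set path is therefore \eqn{\rho_t \cdot} `target_r`,
#' while a `rho = 0, pheno_link = `\eqn{\lambda} trait correlates
#' \eqn{\lambda \sqrt{1 - a_f^2}} with the focal trait but 0 with the
#' genotypes.
#'
#' @param gm A [genotype_matrix()] (complete calls).
#' @param betas Per-SNP effects from [calibrate_effects()].
#' @param spec A [simulation_spec()].
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return A list with `pheno` (data.frame: `id`, `sex`, one
#'   `age_<group>` column per age group, one column per trait) and
#'   `truth` (a `truth_record` list: betas, mafs, expected per-trait r,
#'   the realized focal correlation with Z, covariate effects, seed).
#' @export
simulate_traits <- function(gm, betas, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_individuals(gm)
  traits <- spec$traits
  a <- traits$rho * spec$target_r
  if (any(a^2 + traits$pheno_link^2 >= 1)) {
    stop("rho * target_r and pheno_link jointly leave no residual variance")
  }
  dosage <- additive_matrix(gm)
  centered <- sweep(dosage, 2, 2 * spec$snp_mafs)
  # a null cohort (target_r = 0) has no genetic path: all betas are zero
  # and the weighted sum is constant, so the path contributes nothing
  z <- if (spec$target_r == 0) rep(0, n) else
    standardize(as.numeric(centered %*% betas))
  sex <- stats::rbinom(n, 1, 0.5)
  groups <- unique(traits$age_group)
  ages <- lapply(groups, function(g) {
    stats::runif(n, spec$age_centers[[g]] - spec$age_jitter,
                 spec$age_centers[[g]] + spec$age_jitter)
  })
  names(ages) <- groups
  eps_focal <- stats::rnorm(n)
  pheno <- data.frame(id = gm$individual_ids, sex = sex,
                      stringsAsFactors = FALSE)
  for (g in groups) pheno[[paste0("age_", g)]] <- ages[[g]]
  focal_row <- which(traits$focal)
  realized_focal_r <- NA_real_
  for (t in seq_len(nrow(traits))) {
    lam <- traits$pheno_link[t]
    resid_sd <- sqrt(1 - a[t]^2 - lam^2)
    eps <- if (t == focal_row) eps_focal else stats::rnorm(n)
    y <- a[t] * z + lam * eps_focal + resid_sd * eps
    if (t == focal_row) {
      realized_focal_r <- if (spec$target_r == 0) 0 else stats::cor(z, y)
    }
    age <- ages[[traits$age_group[t]]]
    y <- y + spec$sex_effect * sex + spec$age_slope * (age - mean(age))
    pheno[[traits$label[t]]] <- y
  }
  truth <- structure(list(
    betas = betas,
    mafs = spec$snp_mafs,
    target_r = spec$target_r,
    expected_r = stats::setNames(a, traits$label),
    realized_focal_r = realized_focal_r,
    sex_effect = spec$sex_effect,
    age_slope = spec$age_slope,
    seed = seed
  ), class = "truth_record")
  list(pheno = pheno, truth = truth)
}

#' Inject missing data completely at random
#'
#' Applies three independent missing-completely-at-random mechanisms:
#' whole-plex dropouts per individual (`plex_dropout_rate`), per-call
#' genotype missingness (`snp_miss_rate`), and per-cell phenotype
#' missingness on the trait columns (`pheno_miss_rate`). Sex, age and ID
#' columns are never blanked.
#'
#' @param gm A [genotype_matrix()].
#' @param pheno Phenotype `data.frame` from [simulate_traits()].
#' @param spec A [simulation_spec()].
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return A list with the degraded `gm` and `pheno`.
#' @export
inject_missingness <- function(gm, pheno, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_individuals(gm)
  calls <- gm$calls
  if (spec$plex_dropout_rate > 0) {
    for (p in unique(gm$snps$plex)) {
      drop <- stats::runif(n) < spec$plex_dropout_rate
      calls[drop, gm$snps$plex == p] <- NA_character_
    }
  }
  if (spec$snp_miss_rate > 0) {
    mask <- matrix(stats::runif(length(calls)) < spec$snp_miss_rate,
                   nrow = n)
    calls[mask] <- NA_character_
  }
  gm_out <- genotype_matrix(gm$individual_ids, gm$snps, calls)
  if (spec$pheno_miss_rate > 0) {
    for (m in spec$traits$label) {
      mask <- stats::runif(nrow(pheno)) < spec$pheno_miss_rate
      pheno[[m]][mask] <- NA_real_
    }
  }
  list(gm = gm_out, pheno = pheno)
}

#' Simulate a complete cohort
#'
#' Composes [simulate_genotypes()], [calibrate_effects()],
#' [simulate_traits()] and [inject_missingness()]. All randomness flows
#' from `spec$seed`: the master seed deterministically spawns one
#' sub-seed per stage (drawn up front via `sample.int`), so each stage
#' is independently reproducible and the whole cohort is bit-identical
#' under the same spec.
#'
#' @param spec A [simulation_spec()].
#' @return A list with `gm`, `pheno` and `truth`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 3)
  gm <- simulate_genotypes(spec$snp_mafs, spec$n_individuals,
                           seed = stage_seeds[1],
                           plex = spec$plex_assignment)
  betas <- calibrate_effects(spec$snp_mafs, spec$target_r)
  sim <- simulate_traits(gm, betas, spec, seed = stage_seeds[2])
  degraded <- inject_missingness(gm, sim$pheno, spec, seed = stage_seeds[3])
  list(gm = degraded$gm, pheno = degraded$pheno, truth = sim$truth)
}
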