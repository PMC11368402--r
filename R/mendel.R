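# Permutation tests for the phenotypic manifestation of the sheltered
# load: distorted Mendelian segregation of S-locus homozygotes in families
# designed to unmask a shared recessive S-allele, and homozygote vs
# heterozygote phenotype contrasts with permutation-based covariate
# screening.

#' Expected proportion of S-locus homozygotes in a family
#'
#' Mendelian expectation for offspring homozygous for the focal S-allele:
#' 0.25 when both parents are heterozygous carriers, 0.5 when one parent is
#' homozygous for the focal allele and the other a heterozygous carrier,
#' 1.0 when both parents are homozygous.
#'
#' @param parent1_s,parent2_s character length 2: parental S-genotypes.
#' @param focal_allele the shared S-allele whose homozygotes are counted.
#' @return Expected homozygote proportion.
#' @export
expected_hom_fraction <- function(parent1_s, parent2_s, focal_allele) {
  carry <- function(g) focal_allele %in% g
  if (!carry(parent1_s) || !carry(parent2_s))
    stop("focal allele ", focal_allele, " absent from a parent's S-genotype")
  p_transmit <- function(g) if (g[1L] == focal_allele && g[2L] == focal_allele)
    1 else 0.5
  p_transmit(parent1_s) * p_transmit(parent2_s)
}

#' Permutation test for a deficit of S-locus homozygotes
#'
#' Simulates `n_perm` Mendelian segregations of the family
#' (binomial draws with the expected homozygote probability) and reports
#' the one-sided lower-tail probability of observing at most the observed
#' homozygote count — a deficit indicates differential mortality of
#' homozygotes, i.e. expression of the sheltered load. The exact binomial
#' lower tail is returned alongside as a cross-check.
#'
#' @param n_offspring offspring surviving to the scoring stage.
#' @param n_homozygotes of these, the number homozygous for the focal
#'   S-allele.
#' @param expected_p Mendelian expectation from [expected_hom_fraction()].
#' @param n_perm Monte-Carlo replicates (default 10000).
#' @param seed optional integer seed.
#' @return list of class `segregation_test_result`: `observed_proportion`,
#'   `expected_p`, `ratio` (observed/expected proportion), `p_value`
#'   (Monte-Carlo lower tail), `p_exact` (binomial lower tail),
#'   `p_randomized` (uniform-under-null randomized tail, for calibration
#'   checks), `n_permutations`, `seed`.
#' @export
segregation_test <- function(n_offspring, n_homozygotes, expected_p,
                             n_perm = 10000L, seed = NULL) {
  stopifnot(n_offspring >= 0, n_homozygotes >= 0,
            n_homozygotes <= n_offspring, n_perm >= 1L)
  if (!(expected_p > 0 && expected_p < 1))
    stop("expected_p must be in (0, 1)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  draws <- stats::rbinom(n_perm, n_offspring, expected_p)
  p_mc <- mean(draws <= n_homozygotes)
  p_exact <- stats::pbinom(n_homozygotes, n_offspring, expected_p)
  p_lower <- stats::pbinom(n_homozygotes - 1L, n_offspring, expected_p)
  p_rand <- p_lower + stats::runif(1L) * (p_exact - p_lower)
  obs <- n_homozygotes / n_offspring
  structure(list(observed_proportion = obs, expected_p = expected_p,
                 ratio = obs / expected_p, p_value = p_mc,
                 p_exact = p_exact, p_randomized = p_rand,
                 n_permutations = n_perm, seed = seed),
            class = "segregation_test_result")
}

#' @export
print.segregation_test_result <- function(x, ...) {
  cat("segregation test: observed", signif(x$observed_proportion, 3),
      "vs expected", x$expected_p, "; ratio", signif(x$ratio, 3),
      "(p =", signif(x$p_value, 2), ", exact", signif(x$p_exact, 3), ")\n")
  invisible(x)
}

#' Test of the focal-allele carrier fraction among heterozygotes
#'
#' Among heterozygous offspring of a het x het family sharing one focal
#' allele, 2/3 are expected to carry the focal allele. Two-sided
#' Monte-Carlo test of the observed carrier fraction against this
#' expectation: distinguishes reduced performance of homozygotes from
#' reduced performance of all carriers.
#'
#' @param n_heterozygotes_with_focal heterozygous offspring carrying the
#'   focal allele.
#' @param n_heterozygotes_total all heterozygous offspring.
#' @param expected expected carrier fraction (default 2/3).
#' @param n_perm Monte-Carlo replicates.
#' @param seed optional integer seed.
#' @return list: `observed_fraction`, `expected`, `p_value` (two-sided),
#'   `n_permutations`.
#' @export
carrier_test <- function(n_heterozygotes_with_focal, n_heterozygotes_total,
                         expected = 2 / 3, n_perm = 10000L, seed = NULL) {
  if (n_heterozygotes_total == 0L) stop("no heterozygous offspring")
  stopifnot(n_heterozygotes_with_focal >= 0,
            n_heterozygotes_with_focal <= n_heterozygotes_total)
  if (!is.null(seed)) set.seed(as.integer(seed))
  draws <- stats::rbinom(n_perm, n_heterozygotes_total, expected)
  obs_dev <- abs(n_heterozygotes_with_focal / n_heterozygotes_total - expected)
  dev <- abs(draws / n_heterozygotes_total - expected)
  list(observed_fraction = n_heterozygotes_with_focal / n_heterozygotes_total,
       expected = expected, p_value = mean(dev >= obs_dev - 1e-12),
       n_permutations = n_perm)
}

#' Homozygote vs heterozygote phenotype contrast
#'
#' The homozygote trait mean normalised by the heterozygote mean, with a
#' two-sided permutation p-value for the raw mean difference obtained by
#' redistributing the observed values between the two groups `n_perm`
#' times.
#'
#' @param values numeric trait values.
#' @param genotype character/factor with levels `"hom"` and `"het"`
#'   parallel to `values`.
#' @param n_perm number of label permutations (must be >= 1).
#' @param seed optional integer seed.
#' @return list of class `phenotype_contrast`: `normalized` (mean(hom) /
#'   mean(het); `NA` and `ratio_flagged` when the het mean is 0),
#'   `difference`, `p_value`, `n_hom`, `n_het`.
#' @export
phenotype_contrast <- function(values, genotype, n_perm = 10000L,
                               seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  genotype <- as.character(genotype)
  stopifnot(length(values) == length(genotype),
            all(genotype %in% c("hom", "het")))
  n_hom <- sum(genotype == "hom"); n_het <- sum(genotype == "het")
  if (n_hom < 2L || n_het < 2L) stop("need >= 2 values per group")
  if (!is.null(seed)) set.seed(as.integer(seed))
  mh <- mean(values[genotype == "hom"])
  mz <- mean(values[genotype == "het"])
  diff_obs <- mh - mz
  perm <- replicate(n_perm, {
    g <- sample(genotype)
    mean(values[g == "hom"]) - mean(values[g == "het"])
  })
  p <- mean(abs(perm) >= abs(diff_obs) - 1e-12)
  structure(list(normalized = if (mz != 0) mh / mz else NA_real_,
                 ratio_flagged = mz == 0, difference = diff_obs,
                 p_value = p, n_hom = n_hom, n_het = n_het,
                 n_permutations = n_perm),
            class = "phenotype_contrast")
}

#' @export
print.phenotype_contrast <- function(x, ...) {
  cat("phenotype contrast: hom/het =", signif(x$normalized, 4),
      ", difference", signif(x$difference, 4),
      "(two-sided p =", signif(x$p_value, 3), ")\n")
  invisible(x)
}

#' Permutation screen for a binary covariate effect on a trait
#'
#' Flags a covariate (pathogen attack, phytophagous damage, oxidative
#' stress, family of origin, ...) when the observed between-group mean
#' difference exceeds the 95th percentile of differences obtained by
#' redistributing the trait values between groups of the same sizes.
#' Flagged covariates should be carried as adjustment terms into
#' downstream regressions.
#'
#' @param values numeric trait values.
#' @param covariate binary vector (two levels) parallel to `values`.
#' @param n_perm permutations (default 10000).
#' @param seed optional integer seed.
#' @return list: `flag`, `observed_difference`, `threshold_95`,
#'   `n_permutations`.
#' @export
covariate_screen <- function(values, covariate, n_perm = 10000L,
                             seed = NULL) {
  covariate <- as.character(covariate)
  lv <- unique(covariate)
  if (length(lv) != 2L)
    stop("covariate must have exactly 2 levels (got ", length(lv), ")")
  stopifnot(length(values) == length(covariate))
  if (!is.null(seed)) set.seed(as.integer(seed))
  dobs <- abs(mean(values[covariate == lv[1L]]) -
                mean(values[covariate == lv[2L]]))
  perm <- replicate(n_perm, {
    g <- sample(covariate)
    abs(mean(values[g == lv[1L]]) - mean(values[g == lv[2L]]))
  })
  thr <- stats::quantile(perm, 0.95, names = FALSE)
  list(flag = dobs > thr, observed_difference = dobs, threshold_95 = thr,
       n_permutations = n_perm)
}
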