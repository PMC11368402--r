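#' Parameters of the SSI forward simulator
#'
#' Bundles and validates the configuration of the forward-time simulator:
#' a panmictic population of `N` diploids with non-overlapping generations,
#' each carrying a non-recombining region holding the S-locus and `L` fully
#' linked biallelic positions where fully recessive (`h = 0`) deleterious
#' mutations accumulate. Zygotes survive with probability `(1 - s)^n`, `n`
#' being the number of positions homozygous for the deleterious allele.
#'
#' Defaults follow the published setting: `N = 10000`, `L = 100` linked
#' positions, forward mutation rate `1e-4`, back mutation rate `1e-5`,
#' `s = 0.01`, 100 replicates of 100,000 generations with deleterious allele
#' frequencies recorded every 1,000 generations, and the 14-allele roster
#' (8 class IV, 3 class III, 2 class II, 1 class I).
#'
#' @param N census size (diploid individuals).
#' @param L number of fully linked biallelic positions at the D-locus.
#' @param mu_forward per-position, per-gamete 0 -> 1 mutation rate.
#' @param mu_back per-position, per-gamete 1 -> 0 (reverse) rate.
#' @param s selection coefficient against each homozygous deleterious
#'   position; survival is `(1 - s)^n`.
#' @param h dominance of deleterious mutations; only `h = 0` (fully
#'   recessive) is supported.
#' @param n_generations generations per replicate.
#' @param burn_in generations discarded before any recording.
#' @param record_every sampling interval for allele-frequency recording.
#' @param n_replicates number of independent replicates.
#' @param seed master seed; replicate `r` derives its own stream from
#'   `(seed, r)`.
#' @param hierarchy a [dominance_hierarchy()]; defaults to
#'   [default_s_allele_roster()].
#' @param eq_tolerance convergence threshold for the deterministic S-allele
#'   frequency initialisation (max per-allele change per generation).
#' @param pistil_dominance apply the dominance hierarchy on the pistil side.
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(N = 10000L, L = 100L,
                       mu_forward = 1e-4, mu_back = 1e-5,
                       s = 0.01, h = 0,
                       n_generations = 100000L, burn_in = 0L,
                       record_every = 1000L, n_replicates = 100L,
                       seed = 1L, hierarchy = default_s_allele_roster(),
                       eq_tolerance = 1e-3, pistil_dominance = FALSE) {
  N <- as.integer(N); L <- as.integer(L)
  stopifnot(N > 0L, L >= 1L)
  if (!(mu_back >= 0 && mu_back <= mu_forward && mu_forward < 1))
    stop("require 0 <= mu_back <= mu_forward < 1")
  if (!(s > 0 && s < 1)) stop("require 0 < s < 1")
  if (h != 0) stop("only fully recessive deleterious mutations (h = 0) are supported")
  stopifnot(n_generations >= 1L, burn_in >= 0L, record_every >= 1L,
            n_replicates >= 1L, eq_tolerance > 0)
  if (!inherits(hierarchy, "dominance_hierarchy"))
    stop("`hierarchy` must be a dominance_hierarchy")
  if (nrow(hierarchy) < 2L) stop("need at least 2 S-alleles")
  structure(list(N = N, L = L, mu_forward = mu_forward, mu_back = mu_back,
                 s = s, h = h,
                 n_generations = as.integer(n_generations),
                 burn_in = as.integer(burn_in),
                 record_every = as.integer(record_every),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), hierarchy = hierarchy,
                 eq_tolerance = eq_tolerance,
                 pistil_dominance = isTRUE(pistil_dominance)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("SSI simulator parameters: N =", x$N, ", L =", x$L,
      ", mu =", x$mu_forward, "/", x$mu_back, ", s =", x$s, "\n")
  cat(" ", x$n_replicates, "replicate(s) x", x$n_generations,
      "generations (burn-in", x$burn_in, "), record every",
      x$record_every, "; seed", x$seed, "\n")
  invisible(x)
}

#' Zygote survival probability under recessive deleterious load
#'
#' `p = (1 - s)^n` with `n` the number of D-locus positions homozygous for
#' the deleterious allele; heterozygous positions contribute nothing
#' (`h = 0`).
#'
#' @param hap1,hap2 logical or 0/1 vectors of equal length: the deleterious
#'   allele indicators on the two haplotypes of the zygote.
#' @param s selection coefficient (0 < s < 1).
#' @return Survival probability in (0, 1].
#' @export
zygote_survival_prob <- function(hap1, hap2, s) {
  stopifnot(length(hap1) == length(hap2), s > 0, s < 1)
  n <- sum(as.logical(hap1) & as.logical(hap2))
  (1 - s)^n
}
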