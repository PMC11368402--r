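# Deterministic S-allele genotype-frequency recursion.
#
# Genotypes are unordered allele pairs. One generation: every mother
# contributes an equal seed set; within a mother, fathers are weighted by
# their frequency restricted to SSI-compatible genotypes; both parents
# transmit each of their two alleles with probability 1/2. Mothers with no
# compatible father contribute nothing; the offspring distribution is
# renormalised.

.genotype_table <- function(hierarchy) {
  K <- nrow(hierarchy)
  idx <- which(upper.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  data.frame(a1 = idx[, "row"], a2 = idx[, "col"])
}

.compat_matrix <- function(hierarchy, pistil_dominance = FALSE) {
  gt <- .genotype_table(hierarchy)
  G <- nrow(gt)
  ids <- hierarchy$id
  C <- matrix(FALSE, G, G)
  for (m in seq_len(G)) {
    pis <- c(gt$a1[m], gt$a2[m])
    for (f in seq_len(G)) {
      pol <- c(gt$a1[f], gt$a2[f])
      C[m, f] <- is_compatible(ids[pis], ids[pol], hierarchy,
                               pistil_dominance = pistil_dominance)
    }
  }
  C
}

#' Deterministic S-allele frequency equilibrium
#'
#' Iterates the deterministic genotype-frequency recursion for a population
#' under sporophytic SI (no deleterious mutations, no drift) until the
#' maximum per-allele frequency change between generations falls below
#' `eq_tolerance`. Used to initialise forward simulations: recessive
#' S-alleles equilibrate at higher frequencies than dominant ones because
#' they are masked in pollen and so rejected less often.
#'
#' @param hierarchy a [dominance_hierarchy()] with at least 2 alleles.
#' @param eq_tolerance convergence threshold on allele frequencies
#'   (default `1e-3`).
#' @param max_iter iteration cap; if reached, `converged` is `FALSE` and the
#'   last iterate is returned.
#' @param pistil_dominance apply dominance on the pistil side too.
#' @return A list of class `equilibrium_result`: `allele_freqs` (named, sums
#'   to 1), `genotype_freqs` (data.frame `allele1`, `allele2`, `freq`),
#'   `iterations`, `converged`.
#' @examples
#' eq <- deterministic_equilibrium(default_s_allele_roster())
#' eq$allele_freqs
#' @export
deterministic_equilibrium <- function(hierarchy, eq_tolerance = 1e-3,
                                      max_iter = 100000L,
                                      pistil_dominance = FALSE) {
  if (nrow(hierarchy) < 2L) stop("need at least 2 S-alleles")
  K <- nrow(hierarchy)
  gt <- .genotype_table(hierarchy)
  G <- nrow(gt)
  C <- .compat_matrix(hierarchy, pistil_dominance)
  # offspring genotype index for each (mother transmits a, father transmits b)
  geno_index <- matrix(0L, K, K)
  geno_index[cbind(gt$a1, gt$a2)] <- seq_len(G)
  geno_index[cbind(gt$a2, gt$a1)] <- seq_len(G)
  combos <- cbind(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L))  # (mother hap, father hap)
  off_idx <- array(0L, dim = c(G, G, 4L))
  ma <- cbind(gt$a1, gt$a2)
  for (k in 1:4) {
    a <- ma[, combos[k, 1L]]
    b <- ma[, combos[k, 2L]]
    off_idx[, , k] <- geno_index[cbind(rep(a, times = G),
                                       rep(b, each = G))]
  }

  # start from equal frequencies of all genotypes (homozygotes included:
  # with pure codominant pairs a heterozygote-only start has no compatible
  # mating and the recursion would degenerate)
  g <- rep(1 / G, G)
  dosage <- matrix(0, G, K)
  dosage[cbind(seq_len(G), gt$a1)] <- dosage[cbind(seq_len(G), gt$a1)] + 1
  dosage[cbind(seq_len(G), gt$a2)] <- dosage[cbind(seq_len(G), gt$a2)] + 1
  p <- as.vector(crossprod(dosage, g)) / 2

  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    W <- C * rep(g, each = G)         # W[m, f] = compat * freq(father)
    rs <- rowSums(W)
    ok <- rs > 0
    W[ok, ] <- W[ok, , drop = FALSE] / rs[ok]
    J <- g * W                         # joint mother x father
    gnew <- numeric(G)
    for (k in 1:4) {
      tab <- rowsum(as.vector(J), group = as.vector(off_idx[, , k]))
      gnew[as.integer(rownames(tab))] <- gnew[as.integer(rownames(tab))] + tab / 4
    }
    tot <- sum(gnew)
    if (!is.finite(tot) || tot <= 0) break   # no compatible mating remains
    gnew <- gnew / tot
    pnew <- as.vector(crossprod(dosage, gnew)) / 2
    delta <- max(abs(pnew - p))
    g <- gnew; p <- pnew
    if (delta < eq_tolerance) { converged <- TRUE; break }
  }
  structure(list(
    allele_freqs = stats::setNames(p, hierarchy$id),
    genotype_freqs = data.frame(allele1 = hierarchy$id[gt$a1],
                                allele2 = hierarchy$id[gt$a2],
                                freq = g, stringsAsFactors = FALSE),
    iterations = it, converged = converged
  ), class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat("Deterministic SSI equilibrium:",
      if (x$converged) "converged" else "NOT converged",
      "after", x$iterations, "iterations\n")
  print(round(x$allele_freqs, 4))
  invisible(x)
}
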