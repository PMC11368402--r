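# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: likelihoods are obtained by exhaustive
# summation over internal node states, load summaries by per-position
# tabulation loops, Mendelian resolutions by explicit assignment
# enumeration.

# JC69 transition probability
.jc_p <- function(t, same) {
  e <- exp(-4 * t / 3)
  if (same) 0.25 + 0.75 * e else 0.25 - 0.25 * e
}

# brute-force log likelihood: sum over all internal-node state assignments
oracle_loglik <- function(tree, seqs) {
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = NA_integer_, `-` = NA_integer_)
  n <- length(tree$tip.label)
  states <- as.matrix(expand.grid(rep(list(1:4), tree$Nnode)))
  ll <- 0
  for (s in seq_len(ncol(seqs))) {
    tip <- code[seqs[tree$tip.label, s]]
    tot <- 0
    for (r in seq_len(nrow(states))) {
      st <- c(tip, states[r, ])
      pr <- 0.25
      for (e in seq_len(nrow(tree$edge))) {
        a <- st[tree$edge[e, 1L]]
        b <- st[tree$edge[e, 2L]]
        if (is.na(b)) next                     # missing tip: sum over states = 1
        pr <- pr * .jc_p(tree$edge.length[e], a == b)
      }
      tot <- tot + pr
    }
    ll <- ll + log(tot)
  }
  ll
}

# per-position, per-allele tabulation of the load summary
oracle_load_summary <- function(s_alleles, D) {
  res <- list()
  for (a in sort(unique(s_alleles))) {
    rows <- which(s_alleles == a)
    nf <- ns <- 0L
    for (j in seq_len(ncol(D))) {
      k <- sum(D[rows, j])
      if (length(rows) >= 2L) {
        if (k == length(rows)) nf <- nf + 1L
        else if (k > 0L) ns <- ns + 1L
      }
    }
    res[[length(res) + 1L]] <- data.frame(
      allele = a, n_copies = length(rows),
      n_fixed = if (length(rows) >= 2L) nf else NA_integer_,
      n_segregating = if (length(rows) >= 2L) ns else NA_integer_)
  }
  do.call(rbind, res)
}

# explicit enumeration of Mendelian assignments for one biallelic site
oracle_phase_site <- function(p1, p2, off) {
  if (anyNA(c(p1, p2, off))) return(list(status = "missing"))
  alleles <- function(g) switch(as.character(g), "0" = 0L, "1" = 0:1, "2" = 1L)
  offa <- switch(as.character(off), "0" = c(0L, 0L), "1" = c(0L, 1L),
                 "2" = c(1L, 1L))
  found <- list()
  for (a in alleles(p1)) for (b in alleles(p2)) {
    if (setequal_multiset(c(a, b), offa))
      found[[paste(a, b)]] <- c(a, b)
  }
  if (length(found) == 0L) list(status = "mendel_error")
  else if (length(found) == 1L)
    list(status = "resolved", t1 = found[[1L]][1L], t2 = found[[1L]][2L])
  else list(status = "ambiguous")
}

setequal_multiset <- function(x, y) identical(sort(x), sort(y))

# exhaustive degeneracy of one codon position by translating all variants
oracle_degeneracy <- function(codon, pos) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[[codon]]
  n <- 0L
  for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
    mut <- codon
    substr(mut, pos, pos) <- b
    if (code[[mut]] != aa) n <- n + 1L
  }
  if (n == 3L) "zerofold" else if (n == 0L) "fourfold" else "other"
}

# all-pairs nucleotide diversity via explicit pair loop over combn
oracle_pi <- function(x) {
  pairs <- utils::combn(nrow(x), 2L)
  d <- apply(pairs, 2L, function(ij)
    sum(x[ij[1L], ] != x[ij[2L], ], na.rm = TRUE))
  mean(d) / ncol(x)
}

# two-sided permutation p for a Spearman trend, used on simulation output
perm_spearman_p <- function(cls, v, n_perm = 10000L, seed = 99L,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  set.seed(seed)
  obs <- suppressWarnings(cor(cls, v, method = "spearman"))
  perm <- replicate(n_perm,
    suppressWarnings(cor(sample(cls), v, method = "spearman")))
  switch(alternative,
         two.sided = mean(abs(perm) >= abs(obs) - 1e-12),
         greater = mean(perm >= obs - 1e-12),
         less = mean(perm <= obs + 1e-12))
}

# small default hierarchy used across tests: 8 alleles, 2 per class
test_hierarchy <- function()
  dominance_hierarchy(sprintf("A%d", 1:8), rep(1:4, each = 2L))
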