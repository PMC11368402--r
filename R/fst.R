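# FST profiles along the S-flanking region, grouping haplotypes either by
# population of origin or by linked S-allele. The estimator is the
# frequency-based ratio FST = 1 - piS/piT, where pi is the expected
# heterozygosity per site (average pairwise difference with replacement)
# and piS the group-size-weighted mean of the within-group values; with
# this convention identically composed groups give exactly 0 and groups
# fixed for different alleles give exactly 1.

#' Nucleotide diversity of a haplotype set
#'
#' Mean pairwise difference per site over all distinct sequence pairs.
#'
#' @param x matrix (haplotypes x sites) of bases or 0/1 alleles; `NA`
#'   entries are ignored pairwise.
#' @param n_sites divisor for the per-site scaling; defaults to `ncol(x)`
#'   (pass the window length in bp to express pi per base pair).
#' @return pi, or `NA` with a warning when fewer than 2 sequences.
#' @export
nucleotide_diversity <- function(x, n_sites = ncol(x)) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) {
    warning("nucleotide diversity undefined for fewer than 2 sequences")
    return(NA_real_)
  }
  total <- 0
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      total <- total + sum(x[i, ] != x[j, ], na.rm = TRUE)
  total / choose(n, 2L) / n_sites
}

# expected heterozygosity per column, averaged; the internal pi used by the
# FST ratio (no small-sample correction; see module notes above)
.het_pi <- function(x) {
  if (is.character(x)) {
    h <- apply(x, 2L, function(col) {
      col <- col[!is.na(col) & col != "N" & col != "-"]
      if (length(col) == 0L) return(0)
      p <- table(col) / length(col)
      1 - sum(p^2)
    })
  } else {
    h <- apply(x, 2L, function(col) {
      col <- col[!is.na(col)]
      if (length(col) == 0L) return(0)
      p <- mean(col == 1L)
      2 * p * (1 - p)
    })
  }
  mean(h)
}

#' FST of one window
#'
#' `FST = 1 - piS/piT` with `piS` the group-size-weighted mean within-group
#' expected heterozygosity and `piT` that of the pooled sample. Undefined
#' (`NA`) when `piT = 0` or when fewer than 2 groups have >= 2 sequences.
#'
#' @param x matrix (haplotypes x sites) of bases or 0/1 alleles restricted
#'   to the window.
#' @param groups character vector of group labels, one per haplotype.
#' @return list of class `fst_window_result`: `fst`, `pi_within`,
#'   `pi_total`, `group_sizes`, `defined`.
#' @export
fst_window <- function(x, groups) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(groups))
  sizes <- table(groups)
  if (sum(sizes >= 2L) < 2L)
    return(structure(list(fst = NA_real_, pi_within = NA_real_,
                          pi_total = NA_real_, group_sizes = c(sizes),
                          defined = FALSE),
                     class = "fst_window_result"))
  keep <- groups %in% names(sizes)[sizes >= 2L]
  x <- x[keep, , drop = FALSE]
  groups <- groups[keep]
  sizes <- table(groups)
  pw <- vapply(names(sizes), function(g)
    .het_pi(x[groups == g, , drop = FALSE]), 0)
  pi_within <- sum(pw * as.numeric(sizes)) / sum(sizes)
  pi_total <- .het_pi(x)
  fst <- if (pi_total > 0) 1 - pi_within / pi_total else NA_real_
  structure(list(fst = fst, pi_within = pi_within, pi_total = pi_total,
                 group_sizes = c(sizes), defined = pi_total > 0),
            class = "fst_window_result")
}

#' @export
print.fst_window_result <- function(x, ...) {
  cat("FST =", signif(x$fst, 4), "(pi_within", signif(x$pi_within, 4),
      ", pi_total", signif(x$pi_total, 4), ")\n")
  invisible(x)
}

#' FST profile in non-overlapping windows along the flanking region
#'
#' Tiles 5-kb windows outward from each S-locus boundary (final partial
#' windows dropped), computes per-window FST under both grouping keys
#' (population of origin and linked S-allele), and, when control
#' alignments are given, the 2.5/97.5 percentiles of control-region window
#' FST per key.
#'
#' @param alignment a [haplotype_alignment()].
#' @param s_locus_bounds numeric length 2.
#' @param window_size window width in bp (default 5000).
#' @param control_alignments optional list of control
#'   [haplotype_alignment()]s.
#' @return list of class `fst_profile`: `profile` (data.frame `start`,
#'   `end`, `distance`, `key`, `fst`) and `control_band` (data.frame `key`,
#'   `p2_5`, `p97_5`, `n_windows`, or `NULL`).
#' @export
fst_profile <- function(alignment, s_locus_bounds, window_size = 5000,
                        control_alignments = NULL) {
  b <- sort(as.numeric(s_locus_bounds))
  pos <- alignment$positions
  lo <- min(pos); hi <- max(pos)
  starts <- c(rev(seq.int(b[1L] - window_size, lo, by = -window_size)),
              seq.int(b[2L] + 1, hi - window_size + 1, by = window_size))
  starts <- starts[starts >= lo - window_size + 1]
  keys <- c("population", "s_allele")
  rows <- list()
  for (st in starts) {
    idx <- which(pos >= st & pos < st + window_size)
    if (length(idx) == 0L) next
    dist <- if (st >= b[2L]) st - b[2L] else b[1L] - (st + window_size)
    for (k in keys) {
      f <- fst_window(alignment$seqs[, idx, drop = FALSE],
                      alignment[[k]])
      rows[[length(rows) + 1L]] <- data.frame(
        start = st, end = st + window_size - 1, distance = max(0, dist),
        key = k, n_snps = length(idx), fst = f$fst,
        stringsAsFactors = FALSE)
    }
  }
  profile <- do.call(rbind, rows)
  control_band <- NULL
  if (!is.null(control_alignments)) {
    if (inherits(control_alignments, "haplotype_alignment"))
      control_alignments <- list(control_alignments)
    cb <- list()
    for (k in keys) {
      vals <- unlist(lapply(control_alignments, function(a) {
        p <- a$positions
        st <- seq.int(min(p), max(p) - window_size + 1, by = window_size)
        vapply(st, function(s0) {
          idx <- which(p >= s0 & p < s0 + window_size)
          if (length(idx) == 0L) return(NA_real_)
          fst_window(a$seqs[, idx, drop = FALSE], a[[k]])$fst
        }, 0)
      }))
      vals <- vals[!is.na(vals)]
      cb[[k]] <- data.frame(
        key = k,
        p2_5 = stats::quantile(vals, 0.025, names = FALSE),
        p97_5 = stats::quantile(vals, 0.975, names = FALSE),
        n_windows = length(vals), stringsAsFactors = FALSE)
    }
    control_band <- do.call(rbind, cb)
    rownames(control_band) <- NULL
  }
  structure(list(profile = profile, control_band = control_band),
            class = "fst_profile")
}

#' @export
print.fst_profile <- function(x, ...) {
  cat("fst_profile:", nrow(x$profile) / 2, "windows x 2 grouping keys\n")
  invisible(x)
}
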