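#' Phased haplotype alignment
#'
#' Container for phased S-flanking haplotypes at SNP positions: a base
#' matrix (haplotypes x ordered SNP sites), chromosome coordinates, and the
#' two labels carried by every haplotype — the S-allele to which it is
#' linked and the population it was sampled from.
#'
#' @param seqs character matrix of base calls (`A`, `C`, `G`, `T`, or
#'   `N`/`-` for missing); one row per haplotype.
#' @param positions integer vector of strictly increasing chromosome
#'   coordinates (1-based), one per column.
#' @param s_allele,population character vectors of per-haplotype labels.
#' @param hap_id haplotype identifiers (defaults to rownames of `seqs`).
#' @return An object of class `haplotype_alignment`.
#' @export
haplotype_alignment <- function(seqs, positions, s_allele, population,
                                hap_id = rownames(seqs)) {
  if (is.null(hap_id)) hap_id <- sprintf("hap%03d", seq_len(nrow(seqs)))
  seqs <- as.matrix(seqs)
  positions <- as.integer(positions)
  stopifnot(ncol(seqs) == length(positions),
            nrow(seqs) == length(s_allele),
            nrow(seqs) == length(population))
  if (is.unsorted(positions, strictly = TRUE))
    stop("`positions` must be strictly increasing")
  rownames(seqs) <- hap_id
  structure(list(seqs = seqs, positions = positions,
                 s_allele = as.character(s_allele),
                 population = as.character(population),
                 hap_id = as.character(hap_id)),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat("haplotype_alignment:", nrow(x$seqs), "haplotypes x",
      ncol(x$seqs), "SNPs;", length(unique(x$s_allele)), "S-alleles,",
      length(unique(x$population)), "populations\n")
  invisible(x)
}

# base encoding for the pruning kernel: A,C,G,T -> 0..3; N/-/? -> 4
.encode_bases <- function(mat) {
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L,
            a = 0L, c = 1L, g = 2L, t = 3L,
            N = 4L, n = 4L, `-` = 4L, `?` = 4L)
  v <- code[as.vector(mat)]
  if (anyNA(v)) {
    bad <- unique(as.vector(mat)[is.na(v)])
    stop("unknown character state(s) in alignment: ",
         paste(bad, collapse = ", "))
  }
  matrix(v, nrow = nrow(mat), dimnames = dimnames(mat))
}

#' Constrained grouping topology
#'
#' Builds the deterministic constrained tree used by the scan: a root
#' polytomy with one child clade per group (groups in sorted order), each
#' clade a rake polytomy over its haplotypes (in sorted order). Grouping is
#' either by linked S-allele or by population of origin. All branch lengths
#' start at 0.01 and are later optimised per window.
#'
#' @param labels data.frame with columns `hap_id`, `s_allele`,
#'   `population` (one row per haplotype), e.g. from a
#'   [haplotype_alignment()].
#' @param key grouping key: `"s_allele"` or `"population"`.
#' @return An object of class `grouping_topology`: list with the `ape`
#'   `phylo` tree (`tree`), the grouping `key`, `groups` (named list of
#'   haplotype ids), and pruning index structures.
#' @export
build_grouping_topology <- function(labels, key = c("s_allele", "population")) {
  key <- match.arg(key)
  stopifnot(all(c("hap_id", "s_allele", "population") %in% names(labels)))
  grp <- split(as.character(labels$hap_id), as.character(labels[[key]]))
  grp <- lapply(grp[order(names(grp))], sort)
  if (length(grp) < 2L)
    stop("grouping by ", key, " yields a single group; the two topologies ",
         "would coincide trivially")
  tips <- unlist(grp, use.names = FALSE)
  n <- length(tips)
  G <- length(grp)
  root <- n + 1L
  gnode <- n + 1L + seq_len(G)
  edge <- matrix(0L, n + G, 2L)
  elen <- rep(0.01, n + G)
  r <- 0L
  tip_of <- stats::setNames(seq_len(n), tips)
  for (g in seq_len(G)) {
    r <- r + 1L
    edge[r, ] <- c(root, gnode[g])
    for (tp in grp[[g]]) {
      r <- r + 1L
      edge[r, ] <- c(gnode[g], tip_of[[tp]])
    }
  }
  tree <- structure(list(edge = edge, edge.length = elen,
                         Nnode = G + 1L, tip.label = tips),
                    class = "phylo", order = "cladewise")
  structure(c(list(tree = tree, key = key, groups = grp),
              .pruning_structures(tree)),
            class = "grouping_topology")
}

#' @export
print.grouping_topology <- function(x, ...) {
  cat("grouping_topology by", x$key, ":", length(x$groups), "groups,",
      length(x$tree$tip.label), "haplotypes\n")
  invisible(x)
}

# 0-based children / child-edge / postorder indices for the pruning kernel,
# valid for any rooted phylo (polytomies allowed)
.pruning_structures <- function(tree) {
  n <- length(tree$tip.label)
  M <- n + tree$Nnode
  children <- vector("list", tree$Nnode)
  child_edges <- vector("list", tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L] - n            # internal index 1..Nnode
    children[[p]] <- c(children[[p]], tree$edge[i, 2L] - 1L)
    child_edges[[p]] <- c(child_edges[[p]], i - 1L)
  }
  # postorder over internal nodes: children before parents, root last
  post <- integer(0)
  visit <- function(node) {              # node: 1-based id > n
    for (ch in children[[node - n]]) {
      if (ch + 1L > n) visit(ch + 1L)
    }
    post <<- c(post, node - 1L)          # 0-based
  }
  visit(n + 1L)
  list(children = lapply(children, as.integer),
       child_edges = lapply(child_edges, as.integer),
       postorder = as.integer(post))
}

#' Maximized log likelihood of an alignment window on a fixed topology
#'
#' Felsenstein pruning under JC69 (default) or K80, maximising over branch
#' lengths by coordinate-wise Brent optimisation (bounds
#' `[1e-9, 10]`, tolerance `1e-6`). Missing bases contribute uninformative
#' partial likelihoods. Site patterns are compressed before evaluation.
#'
#' @param window character matrix of bases (haplotypes x sites) with
#'   rownames matching the topology's tip labels.
#' @param topology a [build_grouping_topology()] result, or any rooted
#'   `ape::phylo` tree.
#' @param model substitution model, `"jc69"` or `"k80"`.
#' @param kappa transition/transversion rate ratio for K80.
#' @param optimize if `FALSE`, evaluate at the supplied branch lengths
#'   instead of maximising.
#' @return The log likelihood, with the fitted branch lengths in attribute
#'   `"edge_lengths"`.
#' @export
loglik <- function(window, topology, model = c("jc69", "k80"), kappa = 2,
                   optimize = TRUE) {
  model <- match.arg(model)
  if (inherits(topology, "grouping_topology")) {
    tree <- topology$tree
    str <- topology[c("children", "child_edges", "postorder")]
  } else if (inherits(topology, "phylo")) {
    tree <- topology
    str <- .pruning_structures(tree)
  } else stop("`topology` must be a grouping_topology or phylo")
  tips <- tree$tip.label
  if (!all(tips %in% rownames(window)))
    stop("window rownames must cover all topology tips")
  m <- .encode_bases(window[tips, , drop = FALSE])
  # pattern compression
  pat <- apply(m, 2L, paste, collapse = "\r")
  upat <- unique(pat)
  w <- as.numeric(table(factor(pat, levels = upat)))
  tipstate <- t(m[, match(upat, pat), drop = FALSE])  # npat x ntips
  storage.mode(tipstate) <- "integer"
  len <- tree$edge.length
  if (is.null(len)) len <- rep(0.01, nrow(tree$edge))
  mcode <- if (model == "jc69") 0L else 1L
  if (optimize) {
    fit <- .pruning_optimize_cpp(str$children, str$child_edges,
                                 str$postorder, tipstate, w, len,
                                 mcode, kappa, 1e-9, 10, 1e-6, 25L)
    structure(fit$loglik, edge_lengths = fit$lengths)
  } else {
    structure(.pruning_loglik_cpp(str$children, str$child_edges,
                                  str$postorder, tipstate, w, len,
                                  mcode, kappa),
              edge_lengths = len)
  }
}

#' Log-likelihood difference between the two constrained topologies
#'
#' `logL(grouped by S-allele) - logL(grouped by population)` for one
#' alignment window; positive values mean linkage to the S-allele explains
#' the haplotype phylogeny better than population of origin.
#'
#' @param window character base matrix (haplotypes x sites), rownames =
#'   haplotype ids.
#' @param labels data.frame with `hap_id`, `s_allele`, `population`.
#' @inheritParams loglik
#' @return list with `delta`, `logl_s_allele`, `logl_population`.
#' @export
delta_loglik <- function(window, labels, model = c("jc69", "k80"), kappa = 2) {
  model <- match.arg(model)
  top_s <- build_grouping_topology(labels, "s_allele")
  top_p <- build_grouping_topology(labels, "population")
  ls <- loglik(window, top_s, model, kappa)
  lp <- loglik(window, top_p, model, kappa)
  list(delta = as.numeric(ls) - as.numeric(lp),
       logl_s_allele = as.numeric(ls), logl_population = as.numeric(lp))
}

#' Sliding SNP windows over an alignment
#'
#' Contiguous windows of exactly `size` SNPs advancing by `step`; a final
#' partial window is dropped.
#'
#' @param alignment a [haplotype_alignment()] (or anything with a
#'   `positions` element).
#' @param size window size in SNPs (default 50).
#' @param step step in SNPs (default 10).
#' @return List of integer site-index vectors (possibly empty, with a
#'   warning when the alignment is shorter than one window).
#' @export
window_iter <- function(alignment, size = 50L, step = 10L) {
  if (size < 2L) stop("window `size` must be at least 2 SNPs")
  stopifnot(step >= 1L)
  nsites <- length(alignment$positions)
  if (nsites < size) {
    warning("alignment has ", nsites, " SNPs, fewer than one window of ",
            size, "; no windows")
    return(list())
  }
  starts <- seq.int(1L, nsites - size + 1L, by = step)
  lapply(starts, function(s) seq.int(s, s + size - 1L))
}

#' Topology-shift scan along the S-flanking region
#'
#' Computes [delta_loglik()] in sliding windows and the distance of each
#' window midpoint to the nearest S-locus boundary (0 inside the S-locus).
#'
#' @param alignment a [haplotype_alignment()].
#' @param s_locus_bounds numeric length-2: chromosome coordinates of the
#'   S-locus boundaries (the non-recombining region between the flanks).
#' @inheritParams window_iter
#' @inheritParams loglik
#' @return data.frame of class `scan_result`: `window`, `midpoint`,
#'   `distance`, `logl_s_allele`, `logl_population`, `delta_logl`.
#' @export
topo_scan <- function(alignment, s_locus_bounds, size = 50L, step = 10L,
                      model = c("jc69", "k80"), kappa = 2) {
  model <- match.arg(model)
  stopifnot(length(s_locus_bounds) == 2L)
  b <- sort(as.numeric(s_locus_bounds))
  labels <- data.frame(hap_id = alignment$hap_id,
                       s_allele = alignment$s_allele,
                       population = alignment$population,
                       stringsAsFactors = FALSE)
  wins <- window_iter(alignment, size, step)
  rows <- lapply(seq_along(wins), function(i) {
    idx <- wins[[i]]
    d <- delta_loglik(alignment$seqs[, idx, drop = FALSE], labels,
                      model, kappa)
    mid <- mean(range(alignment$positions[idx]))
    dist <- if (mid >= b[1L] && mid <= b[2L]) 0 else min(abs(mid - b))
    data.frame(window = i, midpoint = mid, distance = dist,
               logl_s_allele = d$logl_s_allele,
               logl_population = d$logl_population,
               delta_logl = d$delta)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Empirical null band for the topology scan
#'
#' Draws contiguous `size`-SNP windows uniformly from control regions
#' (unlinked to the S-locus, population structure only), computes
#' [delta_loglik()] for each, and returns the empirical 2.5 and 97.5
#' percentiles.
#'
#' @param control_alignments list of [haplotype_alignment()] objects for
#'   the control regions; the haplotype labels must match the scanned
#'   alignment.
#' @param size window size in SNPs.
#' @param n_draws number of random control windows (default 1000).
#' @param seed optional integer seed.
#' @inheritParams loglik
#' @return list of class `null_band`: `p2_5`, `p97_5`, `n_draws`, `deltas`.
#' @export
null_band <- function(control_alignments, size = 50L, n_draws = 1000L,
                      seed = NULL, model = c("jc69", "k80"), kappa = 2) {
  model <- match.arg(model)
  if (inherits(control_alignments, "haplotype_alignment"))
    control_alignments <- list(control_alignments)
  nsnp <- vapply(control_alignments, function(a) length(a$positions), 0L)
  usable <- nsnp >= size
  if (!any(usable))
    stop("no control region contains at least ", size, " SNPs")
  control_alignments <- control_alignments[usable]
  nstart <- nsnp[usable] - size + 1L
  if (!is.null(seed)) set.seed(as.integer(seed))
  deltas <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    r <- sample.int(length(control_alignments), 1L, prob = nstart)
    a <- control_alignments[[r]]
    s <- sample.int(length(a$positions) - size + 1L, 1L)
    labels <- data.frame(hap_id = a$hap_id, s_allele = a$s_allele,
                         population = a$population, stringsAsFactors = FALSE)
    deltas[i] <- delta_loglik(a$seqs[, s:(s + size - 1L), drop = FALSE],
                              labels, model, kappa)$delta
  }
  q <- stats::quantile(deltas, c(0.025, 0.975), names = FALSE)
  structure(list(p2_5 = q[1L], p97_5 = q[2L], n_draws = n_draws,
                 deltas = deltas),
            class = "null_band")
}

#' @export
print.null_band <- function(x, ...) {
  cat("null band from", x$n_draws, "control draws: [",
      signif(x$p2_5, 4), ",", signif(x$p97_5, 4), "]\n")
  invisible(x)
}

#' Correlation of the topology shift with distance to the S-locus
#'
#' Pearson correlation between per-window `delta_logl` and the distance of
#' the window midpoint to the nearest S-locus boundary.
#'
#' @param scan a `scan_result` from [topo_scan()].
#' @return list with `r`, `p_value`, `n`, and `undefined` (`TRUE` when
#'   either variable has zero variance).
#' @export
distance_correlation <- function(scan) {
  stopifnot(nrow(scan) >= 3L)
  if (stats::sd(scan$delta_logl) == 0 || stats::sd(scan$distance) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = nrow(scan),
                undefined = TRUE))
  ct <- stats::cor.test(scan$delta_logl, scan$distance, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(scan),
       undefined = FALSE)
}
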