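#' Site filter parameters
#'
#' The variant-site filters applied before load counting: quality >= 60,
#' biallelic SNPs only, per-genotype depth >= 15 and below the per-sample
#' 97.5th percentile estimated from control regions (deeper sites are
#' likely repeats or paralogs), and removal of sites fixed within the
#' population sample.
#'
#' @param min_quality minimum site quality score (default 60).
#' @param min_depth minimum per-genotype read depth (default 15).
#' @param max_depth_percentile per-sample depth percentile above which
#'   genotypes are masked (default 97.5, computed from control depths).
#' @param biallelic_only keep only biallelic SNPs.
#' @param drop_population_fixed drop sites with no genotype variation left.
#' @return list of class `site_filter_params`.
#' @export
site_filter_params <- function(min_quality = 60, min_depth = 15,
                               max_depth_percentile = 97.5,
                               biallelic_only = TRUE,
                               drop_population_fixed = TRUE) {
  stopifnot(min_quality > 0, min_depth > 0,
            max_depth_percentile > 0, max_depth_percentile <= 100)
  structure(list(min_quality = min_quality, min_depth = min_depth,
                 max_depth_percentile = max_depth_percentile,
                 biallelic_only = isTRUE(biallelic_only),
                 drop_population_fixed = isTRUE(drop_population_fixed)),
            class = "site_filter_params")
}

#' Apply variant-site filters
#'
#' @param variants a `variant_table` from [read_vcf()]: list with `sites`
#'   (data.frame `chrom`, `pos`, `id`, `ref`, `alt`, `qual`), `gt` (dosage
#'   matrix sites x samples), `depth` (matrix, same shape).
#' @param params a [site_filter_params()].
#' @param control_depths named list (or matrix) of per-sample depth
#'   observations from control regions, used to estimate each sample's
#'   depth ceiling. If `NULL`, the ceilings are estimated from the variant
#'   depths themselves.
#' @return The filtered `variant_table`; genotypes failing depth bounds are
#'   masked (`NA`), sites failing site-level filters are dropped. The
#'   attrition is recorded in attribute `"filter_log"`.
#' @export
filter_sites <- function(variants, params = site_filter_params(),
                         control_depths = NULL) {
  stopifnot(inherits(variants, "variant_table"))
  if (is.null(variants$depth))
    stop("variant table lacks per-genotype depth (DP); cannot filter")
  sites <- variants$sites
  gt <- variants$gt
  depth <- variants$depth
  log <- c(input = nrow(sites))
  keep <- rep(TRUE, nrow(sites))
  if (params$biallelic_only) {
    ok <- !grepl(",", sites$alt) & nchar(sites$ref) == 1L &
      nchar(sites$alt) == 1L & sites$alt != "."
    log["multiallelic_or_indel"] <- sum(!ok)
    keep <- keep & ok
  }
  ok <- !is.na(sites$qual) & sites$qual >= params$min_quality
  log["low_quality"] <- sum(!ok & keep)
  keep <- keep & ok
  sites <- sites[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  depth <- depth[keep, , drop = FALSE]
  # per-sample depth ceiling from control regions
  samples <- colnames(gt)
  ceil <- vapply(seq_along(samples), function(j) {
    d <- if (is.null(control_depths)) depth[, j]
      else if (is.list(control_depths)) control_depths[[samples[j]]]
      else control_depths[, samples[j]]
    stats::quantile(d, params$max_depth_percentile / 100, na.rm = TRUE,
                    names = FALSE)
  }, 0)
  masked <- 0L
  for (j in seq_along(samples)) {
    bad <- !is.na(depth[, j]) &
      (depth[, j] < params$min_depth | depth[, j] > ceil[j])
    bad <- bad | is.na(depth[, j])
    masked <- masked + sum(bad & !is.na(gt[, j]))
    gt[bad, j] <- NA_integer_
  }
  log["genotypes_masked"] <- masked
  if (params$drop_population_fixed) {
    # fixed = derived allele frequency 0 or 1 among retained genotypes
    vari <- apply(gt, 1L, function(g) {
      g <- g[!is.na(g)]
      length(g) > 0L && mean(g) / 2 > 0 && mean(g) / 2 < 1
    })
    log["population_fixed"] <- sum(!vari)
    sites <- sites[vari, , drop = FALSE]
    gt <- gt[vari, , drop = FALSE]
    depth <- depth[vari, , drop = FALSE]
  }
  log["output"] <- nrow(sites)
  out <- variants
  out$sites <- sites; out$gt <- gt; out$depth <- depth
  attr(out, "filter_log") <- log
  out
}

#' Count fixed and segregating mutations per S-allele lineage
#'
#' For each population x S-allele lineage, counts derived (non-reference)
#' mutations within `window` bp outward of each S-locus boundary, split by
#' site category (degeneracy class, plus any extra annotation categories)
#' into lineage-fixed (carried by all copies; needs >= 2 copies) and
#' lineage-segregating (carried by some but not all). Sites carrying the
#' derived allele on every haplotype of a population are excluded for that
#' population (locally fixed mutations carry no lineage signal).
#'
#' @param haplotypes a `phased_haplotype_set` (see [dedupe_parents()]) or
#'   any list with `haplotypes` (data.frame `hap_id`, `s_allele`,
#'   `population`), `alleles` (0/1/`NA` matrix haplotypes x sites), and
#'   `sites` (data.frame with `pos`).
#' @param degeneracy a [classify_degeneracy()] map (or `NULL` to put every
#'   site in category `"all"`).
#' @param s_locus_bounds numeric length 2: S-locus boundary coordinates.
#' @param window flank width in bp (default 25000); flanks are half-open
#'   intervals extending outward from each boundary.
#' @param dominance named numeric vector mapping S-allele labels to
#'   continuous dominance levels; defaults to parsing nothing and requires
#'   either this argument or a `dominance` column in `haplotypes$haplotypes`.
#' @param annotation optional data.frame (`pos`, `category`) adding
#'   annotation-based categories (e.g. SIFT4G or SNPeff classes).
#' @return data.frame of class `lineage_counts`: `population`, `s_allele`,
#'   `dominance`, `n_copies`, `category`, `n_fixed`, `n_segregating`,
#'   `n_total` (fixed/segregating are `NA` for single-copy lineages).
#' @export
count_lineage_mutations <- function(haplotypes, degeneracy, s_locus_bounds,
                                    window = 25000, dominance = NULL,
                                    annotation = NULL) {
  labs <- haplotypes$haplotypes
  alleles <- haplotypes$alleles
  pos <- haplotypes$sites$pos
  stopifnot(nrow(labs) == nrow(alleles), length(pos) == ncol(alleles),
            length(s_locus_bounds) == 2L)
  if (is.null(dominance)) {
    if (!is.null(labs$dominance))
      dominance <- stats::setNames(labs$dominance, labs$s_allele)
    else stop("supply `dominance` (named vector) or a dominance column")
  }
  b <- sort(as.numeric(s_locus_bounds))
  in_flank <- (pos < b[1L] & pos >= b[1L] - window) |
              (pos > b[2L] & pos <= b[2L] + window)
  cat_of <- rep("all", length(pos))
  if (!is.null(degeneracy)) {
    cat_of <- degeneracy$class[match(pos, degeneracy$pos)]
    cat_of[is.na(cat_of)] <- "noncoding"
    cat_of <- c(zerofold = "S_0f", fourfold = "S_4f", other = "other",
                `excluded-conflict` = "excluded", noncoding = "noncoding")[cat_of]
  }
  rows <- list()
  for (popn in unique(labs$population)) {
    prows <- labs$population == popn
    pa <- alleles[prows, , drop = FALSE]
    carried <- colSums(pa == 1L, na.rm = TRUE)
    informative <- colSums(!is.na(pa))
    pop_fixed <- informative > 0L & carried == informative
    use <- in_flank & !pop_fixed & informative > 0L
    for (sa in unique(labs$s_allele[prows])) {
      lrows <- prows & labs$s_allele == sa
      la <- alleles[lrows, , drop = FALSE]
      nc <- nrow(la)
      for (ct in setdiff(unique(cat_of[use]), c("excluded"))) {
        idx <- which(use & cat_of == ct)
        cs <- colSums(la[, idx, drop = FALSE] == 1L, na.rm = TRUE)
        inf <- colSums(!is.na(la[, idx, drop = FALSE]))
        if (nc >= 2L) {
          nf <- sum(inf >= 2L & cs == inf & cs > 0L)
          ns <- sum(cs > 0L & cs < inf)
          nt <- nf + ns
        } else {
          nf <- NA_integer_; ns <- NA_integer_
          nt <- sum(cs > 0L)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          population = popn, s_allele = sa,
          dominance = unname(dominance[sa]), n_copies = nc, category = ct,
          n_fixed = nf, n_segregating = ns, n_total = nt,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(annotation)) {
    extra <- count_lineage_mutations(
      haplotypes, NULL, s_locus_bounds, window, dominance)
    # recompute per annotation category by masking sites
    ann_rows <- list()
    for (ct in unique(annotation$category)) {
      sel <- pos %in% annotation$pos[annotation$category == ct]
      h2 <- haplotypes
      h2$alleles <- haplotypes$alleles[, sel, drop = FALSE]
      h2$sites <- haplotypes$sites[sel, , drop = FALSE]
      cc <- count_lineage_mutations(h2, NULL, s_locus_bounds, window,
                                    dominance)
      cc$category <- ct
      ann_rows[[ct]] <- cc
    }
    out <- rbind(out, do.call(rbind, ann_rows))
  }
  rownames(out) <- NULL
  class(out) <- c("lineage_counts", "data.frame")
  out
}

#' Poisson regression of lineage load on S-allele dominance
#'
#' Tests whether per-lineage mutation counts (fixed, segregating, or total)
#' increase or decrease with S-allele dominance treated as a continuous
#' covariate, with population as an adjustment term: a fixed-effect
#' covariate by default, or a random intercept (`lme4`) when
#' `population_effect = "random"`. Single-copy lineages (undefined
#' fixed/segregating split) are excluded automatically via their `NA`
#' counts.
#'
#' @param counts a [count_lineage_mutations()] table (or the per-replicate
#'   summary of a simulation, with the same columns).
#' @param response which count to model: `"fixed"`, `"segregating"`, or
#'   `"total"`.
#' @param category site category to subset (default `"S_0f"`; use `"all"`
#'   for degeneracy-free tables).
#' @param population_effect `"fixed"` or `"random"`.
#' @return list of class `dominance_trend`: `slope`, `p_value`, `response`,
#'   `category`, `n_lineages`, `degenerate` (all-zero response), `fit`.
#' @export
fit_dominance_trend <- function(counts,
                                response = c("fixed", "segregating", "total"),
                                category = "S_0f",
                                population_effect = c("fixed", "random")) {
  response <- match.arg(response)
  population_effect <- match.arg(population_effect)
  d <- counts[counts$category == category, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for category ", category)
  ycol <- c(fixed = "n_fixed", segregating = "n_segregating",
            total = "n_total")[[response]]
  d <- d[!is.na(d[[ycol]]), , drop = FALSE]
  if (nrow(d) < 3L || length(unique(d$dominance)) < 2L)
    stop("need >= 3 lineages spanning >= 2 dominance levels")
  d$y <- d[[ycol]]
  if (all(d$y == 0))
    return(structure(list(slope = 0, p_value = NA_real_, response = response,
                          category = category, n_lineages = nrow(d),
                          degenerate = TRUE, fit = NULL),
                     class = "dominance_trend"))
  multi_pop <- length(unique(d$population)) > 1L
  if (population_effect == "random" && multi_pop) {
    if (!requireNamespace("lme4", quietly = TRUE))
      stop("population_effect = 'random' requires the lme4 package")
    fit <- lme4::glmer(y ~ dominance + (1 | population), data = d,
                       family = stats::poisson())
    co <- summary(fit)$coefficients
  } else {
    fml <- if (multi_pop) y ~ dominance + population else y ~ dominance
    fit <- stats::glm(fml, data = d, family = stats::poisson())
    co <- summary(fit)$coefficients
  }
  structure(list(slope = co["dominance", 1L],
                 p_value = co["dominance", 4L],
                 response = response, category = category,
                 n_lineages = nrow(d), degenerate = FALSE, fit = fit),
            class = "dominance_trend")
}

#' @export
print.dominance_trend <- function(x, ...) {
  cat("dominance trend (", x$category, ", ", x$response, "): slope = ",
      signif(x$slope, 4), ", p = ", signif(x$p_value, 3), " on ",
      x$n_lineages, " lineages\n", sep = "")
  invisible(x)
}

#' Zerofold to fourfold mutation ratio per lineage
#'
#' @param counts a [count_lineage_mutations()] table containing categories
#'   `S_0f` and `S_4f`.
#' @return data.frame `population`, `s_allele`, `dominance`, `s0f`, `s4f`,
#'   `ratio` (`NA` with `flagged = TRUE` when `S_4f` is 0).
#' @export
ratio_statistic <- function(counts) {
  f0 <- counts[counts$category == "S_0f", ]
  f4 <- counts[counts$category == "S_4f", ]
  key <- paste(f0$population, f0$s_allele)
  m <- match(key, paste(f4$population, f4$s_allele))
  s4 <- ifelse(is.na(m), 0L, f4$n_total[m])
  data.frame(population = f0$population, s_allele = f0$s_allele,
             dominance = f0$dominance, s0f = f0$n_total, s4f = s4,
             ratio = ifelse(s4 > 0, f0$n_total / s4, NA_real_),
             flagged = s4 == 0, stringsAsFactors = FALSE)
}
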