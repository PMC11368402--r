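make_variant_fixture <- function() {
  # 10 records: 1 multiallelic, 1 low quality, 1 population-fixed -> 7 pass
  sites <- data.frame(
    chrom = "c1", pos = seq(100L, 1000L, by = 100L),
    id = sprintf("v%02d", 1:10),
    ref = "A",
    alt = c("T", "T", "C,G", "T", "G", "T", "T", "C", "T", "T"),
    qual = c(90, 90, 90, 59, 90, 90, 90, 90, 90, 90))
  gt <- matrix(1L, 10L, 4L,
               dimnames = list(NULL, sprintf("s%d", 1:4)))
  gt[7L, ] <- 2L                     # fixed in the population sample
  gt[1L, ] <- c(0L, 0L, 1L, 2L)
  gt[2L, ] <- c(0L, 1L, 1L, 0L)
  depth <- matrix(30L, 10L, 4L, dimnames = dimnames(gt))
  depth[2L, 3L] <- 14L               # low-depth genotype to mask
  structure(list(sites = sites, gt = gt, depth = depth,
                 samples = colnames(gt)),
            class = "variant_table")
}

test_that("filter_sites applies the quality/biallelic/depth/fixed filters", {
  v <- make_variant_fixture()
  f <- filter_sites(v, site_filter_params(),
                    control_depths = matrix(30L, 50L, 4L,
                                            dimnames = list(NULL, v$samples)))
  log <- attr(f, "filter_log")
  expect_identical(unname(log["multiallelic_or_indel"]), 1L)
  expect_identical(unname(log["low_quality"]), 1L)
  expect_identical(unname(log["population_fixed"]), 1L)
  expect_identical(nrow(f$sites), 7L)
  expect_false("v03" %in% f$sites$id)   # multiallelic
  expect_false("v04" %in% f$sites$id)   # quality 59
  expect_false("v07" %in% f$sites$id)   # fixed
  # the low-depth genotype was masked, not the whole site
  expect_true("v02" %in% f$sites$id)
  expect_true(is.na(f$gt[f$sites$id == "v02", "s3"]))
  # control-depth ceiling: depths above the 97.5th percentile are masked
  v2 <- make_variant_fixture()
  v2$depth[5L, 2L] <- 500L
  f2 <- filter_sites(v2, site_filter_params(),
                     control_depths = matrix(30L, 50L, 4L,
                                             dimnames = list(NULL, v$samples)))
  expect_true(is.na(f2$gt[f2$sites$id == "v05", "s2"]))
  v3 <- make_variant_fixture(); v3$depth <- NULL
  expect_error(filter_sites(v3), "depth")
})

test_that("count_lineage_mutations equals brute-force tabulation and drops
           population-fixed sites", {
  set.seed(61)
  nsite <- 40L
  pos <- seq(100L, by = 500L, length.out = nsite)
  labs <- data.frame(
    hap_id = sprintf("h%d", 1:10),
    s_allele = rep(c("A1", "A2", "A3", "A4", "A5"), each = 2L),
    population = "pop1", stringsAsFactors = FALSE)
  alleles <- matrix(rbinom(10L * nsite, 1L, 0.3), 10L, nsite)
  alleles[, 5L] <- 1L                       # population-fixed site
  haps <- list(haplotypes = labs, alleles = alleles,
               sites = data.frame(pos = pos))
  bounds <- c(10000L, 10500L)
  dom <- setNames(1:5, labs$s_allele[seq(1, 10, 2)])
  cnt <- count_lineage_mutations(haps, NULL, bounds, window = 25000L,
                                 dominance = dom)
  in_flank <- (pos < bounds[1L] & pos >= bounds[1L] - 25000L) |
              (pos > bounds[2L] & pos <= bounds[2L] + 25000L)
  for (sa in unique(labs$s_allele)) {
    rows <- which(labs$s_allele == sa)
    nf <- ns <- 0L
    for (j in which(in_flank)) {
      if (all(alleles[, j] == 1L)) next     # population-fixed
      k <- sum(alleles[rows, j])
      if (k == length(rows)) nf <- nf + 1L else if (k > 0L) ns <- ns + 1L
    }
    row <- cnt[cnt$s_allele == sa, ]
    expect_identical(row$n_fixed, nf)
    expect_identical(row$n_segregating, ns)
    expect_identical(row$n_total, nf + ns)
  }
  # fixed + segregating = total invariant
  expect_true(all(cnt$n_total == cnt$n_fixed + cnt$n_segregating))
})

test_that("single-copy lineages keep totals but undefined fixed/segregating", {
  labs <- data.frame(hap_id = c("h1", "h2", "h3"),
                     s_allele = c("A1", "A1", "A2"),
                     population = "pop1")
  alleles <- rbind(c(1L, 0L, 1L), c(1L, 0L, 0L), c(0L, 1L, 1L))
  haps <- list(haplotypes = labs, alleles = alleles,
               sites = data.frame(pos = c(100L, 200L, 300L)))
  cnt <- count_lineage_mutations(haps, NULL, c(5000L, 5100L),
                                 dominance = c(A1 = 1, A2 = 4))
  a2 <- cnt[cnt$s_allele == "A2", ]
  expect_true(is.na(a2$n_fixed) && is.na(a2$n_segregating))
  expect_identical(a2$n_total, 2L)
})

test_that("dominance trend: strong effect detected, constants flat,
           null p-values uniform", {
  counts <- data.frame(population = "pop1", s_allele = sprintf("A%d", 1:8),
                       dominance = rep(1:4, each = 2L), n_copies = 3L,
                       category = "S_0f",
                       n_fixed = c(1L, 2L, 4L, 5L, 9L, 11L, 18L, 21L),
                       n_segregating = 5L, n_total = 0L)
  counts$n_total <- counts$n_fixed + counts$n_segregating
  tr <- fit_dominance_trend(counts, "fixed")
  expect_gt(tr$slope, 0)
  expect_lt(tr$p_value, 0.05)
  # constant response gives a numerically zero slope
  counts2 <- counts
  counts2$n_fixed <- 7L
  expect_lt(abs(fit_dominance_trend(counts2, "fixed")$slope), 1e-6)
  # all-zero response is flagged degenerate
  counts3 <- counts
  counts3$n_fixed <- 0L
  expect_true(fit_dominance_trend(counts3, "fixed")$degenerate)
  # null calibration: dominance-independent Poisson counts over 200 fits
  set.seed(71)
  pvals <- replicate(200L, {
    d <- data.frame(population = rep(c("p1", "p2"), each = 12L),
                    s_allele = sprintf("A%d", 1:24),
                    dominance = rep(rep(1:4, each = 3L), 2L),
                    n_copies = 3L, category = "S_0f",
                    n_fixed = rpois(24L, 8), n_segregating = 0L,
                    n_total = 0L)
    fit_dominance_trend(d, "fixed")$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("ratio statistic divides and flags zero denominators", {
  counts <- rbind(
    data.frame(population = "p", s_allele = c("A1", "A2"),
               dominance = c(1, 4), n_copies = 3L, category = "S_0f",
               n_fixed = c(2L, 1L), n_segregating = c(2L, 1L),
               n_total = c(4L, 2L)),
    data.frame(population = "p", s_allele = c("A1", "A2"),
               dominance = c(1, 4), n_copies = 3L, category = "S_4f",
               n_fixed = c(4L, 0L), n_segregating = c(4L, 0L),
               n_total = c(8L, 0L)))
  rs <- ratio_statistic(counts)
  expect_equal(rs$ratio[rs$s_allele == "A1"], 0.5)
  expect_true(is.na(rs$ratio[rs$s_allele == "A2"]))
  expect_true(rs$flagged[rs$s_allele == "A2"])
})

test_that("synthetic class-dependent data recover the trend signs", {
  # moderate-size check; the 50-dataset property runs in the acceptance suite
  hits <- 0L
  for (sd in 1:10) {
    cfg <- synth_config(preset = "fig45", seed = sd, flank_length = 15000L,
                        d0 = 10000L)
    haps <- generate_haplotypes(cfg)
    cnt <- count_lineage_mutations(
      haps, NULL, synth_s_locus_bounds(cfg), window = 25000L,
      dominance = setNames(haps$haplotypes$dominance,
                           haps$haplotypes$s_allele))
    tf <- fit_dominance_trend(cnt, "fixed", "all")
    tsg <- fit_dominance_trend(cnt, "segregating", "all")
    tt <- fit_dominance_trend(cnt, "total", "all")
    if (tf$slope > 0 && tsg$slope < 0 && tt$p_value > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
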