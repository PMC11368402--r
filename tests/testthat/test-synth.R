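test_that("generators are seed-deterministic", {
  cfg <- synth_config(seed = 37L, flank_length = 5000L, d0 = 2000L,
                      n_trios = 3L, n_families = 2L)
  r1 <- generate_region(cfg); r2 <- generate_region(cfg)
  expect_identical(as.character(r1$reference), as.character(r2$reference))
  expect_identical(r1$truth, r2$truth)
  h1 <- generate_haplotypes(cfg); h2 <- generate_haplotypes(cfg)
  expect_identical(h1$alleles, h2$alleles)
  t1 <- generate_trios(cfg, h1); t2 <- generate_trios(cfg, h2)
  expect_identical(t1$variants$gt, t2$variants$gt)
  p1 <- generate_phenotypes(cfg); p2 <- generate_phenotypes(cfg)
  expect_identical(p1$families, p2$families)
})

test_that("region truth agrees with classify_degeneracy at every CDS site", {
  cfg <- synth_config(seed = 43L, flank_length = 6000L, d0 = 2000L)
  reg <- generate_region(cfg, n_genes = 6L, gene_length = 120L)
  dm <- classify_degeneracy(reg$reference, reg$annotation)
  m <- merge(reg$truth, as.data.frame(dm)[, c("pos", "class")], by = "pos")
  expect_identical(nrow(m), nrow(reg$truth))
  expect_true(all(m$class.x == m$class.y))
  # strand mix present
  expect_setequal(unique(reg$truth$strand), c("+", "-"))
})

test_that("haplotype truth matches counted lineage load exactly", {
  # flank = d0 so that every site is in the lineage zone the truth covers
  cfg <- synth_config(preset = "fig45", seed = 47L, flank_length = 10000L,
                      d0 = 10000L)
  haps <- generate_haplotypes(cfg)
  b <- synth_s_locus_bounds(cfg)
  cnt <- count_lineage_mutations(
    haps, NULL, b, window = 25000L,
    dominance = setNames(haps$haplotypes$dominance, haps$haplotypes$s_allele))
  truth <- haps$truth
  for (i in seq_len(nrow(cnt))) {
    row <- cnt[i, ]
    tr <- truth[truth$population == row$population &
                  truth$s_allele == row$s_allele, ]
    expect_identical(row$n_fixed, sum(tr$kind == "fixed"))
    expect_identical(row$n_segregating, sum(tr$kind == "segregating"))
  }
})

test_that("zero load intensities give all-zero lineage counts", {
  cfg <- synth_config(preset = "fig45", seed = 53L, flank_length = 8000L,
                      d0 = 4000L, fixed_intensity = rep(0, 4L),
                      seg_intensity = rep(0, 4L), pop_divergence = 0,
                      background_poly = 0)
  haps <- generate_haplotypes(cfg)
  expect_identical(nrow(haps$truth), 0L)
  # population-zone founders may still be derived, but they are fixed in
  # every population, so all lineage counts are zero
  cnt <- count_lineage_mutations(
    haps, NULL, synth_s_locus_bounds(cfg), window = 25000L,
    dominance = setNames(haps$haplotypes$dominance, haps$haplotypes$s_allele))
  expect_true(all(cnt$n_total == 0L))
  expect_true(all(cnt$n_fixed == 0L) && all(cnt$n_segregating == 0L))
})

test_that("trio generator: phases recover truth, injected errors match the
           detectability oracle", {
  cfg <- synth_config(seed = 59L, flank_length = 4000L, d0 = 2000L,
                      n_trios = 4L)
  clean <- generate_trios(cfg)
  err_rate <- 0.05
  noisy <- generate_trios(cfg, error_rate = err_rate)
  for (t in seq_along(noisy$trios)) {
    trio <- noisy$trios[[t]]
    pt <- phase_trio(trio, error_threshold = 0.02)
    if (is.null(pt)) next
    # oracle: a corrupted site is detectable iff no Mendelian assignment
    # explains the (possibly corrupted) offspring dosage
    expected_detect <- sum(vapply(seq_along(trio$off), function(j) {
      oracle_phase_site(trio$p1[j], trio$p2[j], trio$off[j])$status ==
        "mendel_error"
    }, logical(1)))
    expect_identical(pt$qc$n_mendel_error, expected_detect)
    # detected errors cannot exceed injected ones, and a 5% injection rate
    # on thousands of sites must be visibly detected
    expect_lte(pt$qc$n_mendel_error, noisy$truth[[t]]$n_injected_errors)
    expect_gt(pt$qc$n_mendel_error, 0L)
    expect_true(pt$qc$flagged)
  }
})

test_that("triple-heterozygous fraction matches the generator prediction", {
  cfg <- synth_config(seed = 61L, flank_length = 20000L, d0 = 5000L,
                      n_trios = 8L)
  tr <- generate_trios(cfg)
  # prediction per trio: fraction of sites with all three members dosage 1
  for (t in seq_along(tr$trios)) {
    trio <- tr$trios[[t]]
    expected <- mean(trio$p1 == 1L & trio$p2 == 1L & trio$off == 1L)
    pt <- phase_trio(trio)
    if (is.null(pt)) next
    observed <- pt$qc$n_ambiguous / pt$qc$n_sites
    expect_equal(observed, expected, tolerance = 1e-9)
  }
})
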