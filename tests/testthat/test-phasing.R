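test_that("transmitted_s_allele resolves the cross designs", {
  expect_identical(
    transmitted_s_allele(c("S1", "S2"), c("S2", "S3"), c("S3", "S4")), "S2")
  # homozygote-producing cross: both parents transmit the shared allele
  expect_identical(
    transmitted_s_allele(c("S1", "S2"), c("S1", "S1"), c("S1", "S3")), "S1")
  expect_identical(
    transmitted_s_allele(c("S1", "S3"), c("S1", "S1"), c("S1", "S2")), "S1")
  # symmetric ambiguity is uninformative
  expect_true(is.na(
    transmitted_s_allele(c("S1", "S2"), c("S1", "S2"), c("S1", "S2"))))
  expect_error(
    transmitted_s_allele(c("S1", "S2"), c("S3", "S4")), "Mendelian")
})

test_that("phase_site matches the exhaustive assignment oracle on all
           dosage combinations", {
  combos <- expand.grid(p1 = c(0:2, NA), p2 = c(0:2, NA), off = c(0:2, NA))
  got <- phase_site(combos$p1, combos$p2, combos$off)
  for (i in seq_len(nrow(combos))) {
    want <- oracle_phase_site(combos$p1[i], combos$p2[i], combos$off[i])
    expect_identical(got$status[i], want$status,
                     info = paste(combos[i, ], collapse = "/"))
    if (want$status == "resolved") {
      expect_identical(got$t1[i], want$t1)
      expect_identical(got$t2[i], want$t2)
    }
  }
  # the worked examples
  expect_identical(unlist(phase_site(1L, 0L, 1L)[1L, 1:2]),
                   c(t1 = 1L, t2 = 0L))
  expect_identical(phase_site(1L, 1L, 1L)$status, "ambiguous")
  expect_identical(phase_site(0L, 0L, 1L)$status, "mendel_error")
})

make_toy_trio <- function() {
  sites <- data.frame(chrom = "c1", pos = c(10L, 20L, 30L, 40L, 50L),
                      ref = "A", alt = "T")
  # sites: resolved / resolved / ambiguous (triple het) / error / missing
  trio_genotypes(sites,
                 p1 = c(1L, 0L, 1L, 0L, 1L),
                 p2 = c(0L, 2L, 1L, 0L, 1L),
                 off = c(1L, 1L, 1L, 1L, NA),
                 s_p1 = c("S1", "S2"), s_p2 = c("S3", "S4"),
                 s_off = c("S2", "S3"), ids = c("P1", "P2", "O1"))
}

test_that("phase_trio matches hand enumeration on the 5-site toy", {
  pt <- phase_trio(make_toy_trio())
  expect_s3_class(pt, "phased_trio")
  # P1 transmitted S2, untransmitted S1; P2 transmitted S3
  expect_identical(pt$haplotypes$s_allele, c("S2", "S1", "S3", "S4"))
  # hand enumeration: site1 P1->1 P2->0; site2 P1->0 P2->1; rest NA
  expect_identical(unname(pt$alleles["P1_T", ]),
                   c(1L, 0L, NA_integer_, NA_integer_, NA_integer_))
  expect_identical(unname(pt$alleles["P1_U", ]),
                   c(0L, 0L, NA_integer_, NA_integer_, NA_integer_))
  expect_identical(unname(pt$alleles["P2_T", ]),
                   c(0L, 1L, NA_integer_, NA_integer_, NA_integer_))
  expect_identical(unname(pt$alleles["P2_U", ]),
                   c(0L, 1L, NA_integer_, NA_integer_, NA_integer_))
  expect_identical(pt$qc$n_mendel_error, 1L)
  expect_identical(pt$qc$n_ambiguous, 1L)
  expect_identical(pt$qc$n_missing, 1L)
  expect_true(pt$qc$flagged)  # 1 error of 5 sites > 5%
})

test_that("unambiguous haplotypes recombine to the parental genotype", {
  cfg <- synth_config(seed = 9L, flank_length = 5000L, d0 = 2000L,
                      n_trios = 5L)
  tr <- generate_trios(cfg)
  for (trio in tr$trios) {
    pt <- phase_trio(trio)
    if (is.null(pt)) next
    for (par in unique(pt$haplotypes$parent)) {
      rows <- which(pt$haplotypes$parent == par)
      s <- pt$alleles[rows[1L], ] + pt$alleles[rows[2L], ]
      gt <- if (par == trio$ids[1L]) trio$p1 else trio$p2
      ok <- !is.na(s)
      expect_identical(unname(s[ok]), unname(gt[ok]))
    }
  }
})

test_that("synthetic trios recover truth at all resolved sites and phasing is
           invariant to site order", {
  cfg <- synth_config(seed = 13L, flank_length = 5000L, d0 = 2000L,
                      n_trios = 6L)
  tr <- generate_trios(cfg)
  for (t in seq_along(tr$trios)) {
    pt <- phase_trio(tr$trios[[t]])
    if (is.null(pt)) next
    truth <- tr$truth[[t]]
    rec <- pt$alleles["T%02d_P1_T" |> sprintf(t), ]
    ok <- !is.na(rec)
    expect_identical(unname(rec[ok]), unname(truth$p1_transmitted[ok]))
    rec2 <- pt$alleles[sprintf("T%02d_P2_T", t), ]
    ok2 <- !is.na(rec2)
    expect_identical(unname(rec2[ok2]), unname(truth$p2_transmitted[ok2]))
  }
  # permuting site order and re-sorting yields the same haplotypes
  trio <- tr$trios[[1L]]
  perm <- sample(nrow(trio$sites))
  shuffled <- trio_genotypes(trio$sites[perm, ], trio$p1[perm],
                             trio$p2[perm], trio$off[perm],
                             trio$s_p1, trio$s_p2, trio$s_off, trio$ids)
  a <- phase_trio(trio)$alleles
  b <- phase_trio(shuffled)$alleles[, order(perm)]
  expect_identical(unname(a), unname(b))
})

test_that("dedupe_parents phases each parent once and reports conflicts", {
  toy <- make_toy_trio()
  # same parents in a second informative trio with one conflicting site
  toy2 <- toy
  toy2$ids <- c("P1", "P2", "O2")
  toy2$p1 <- c(1L, 0L, 1L, 0L, 1L)
  toy2$off <- c(0L, 1L, 1L, 1L, NA)    # site 1 now resolves P1 -> 0
  ph <- dedupe_parents(list(toy, toy2))
  expect_identical(sum(ph$haplotypes$parent == "P1"), 2L)
  expect_identical(nrow(ph$haplotypes), 4L)   # 2 parents x 2 haplotypes
  cons <- ph$consistency
  expect_identical(cons$n_trios[cons$parent == "P1"], 2L)
  expect_gt(cons$n_mismatch[cons$parent == "P1"], 0L)
  # disjoint parent sets: output is 2 haplotypes per parent
  toy3 <- toy
  toy3$ids <- c("P3", "P4", "O3")
  ph2 <- dedupe_parents(list(toy, toy3))
  expect_identical(nrow(ph2$haplotypes), 8L)
  expect_identical(sum(ph2$consistency$n_mismatch), 0L)
})
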