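make_labels <- function() {
  data.frame(hap_id = c("h1", "h2", "h3", "h4"),
             s_allele = c("S1", "S1", "S2", "S2"),
             population = c("P1", "P2", "P1", "P2"),
             stringsAsFactors = FALSE)
}

test_that("constrained topologies are deterministic rakes over sorted groups", {
  labels <- make_labels()
  ts <- build_grouping_topology(labels, "s_allele")
  expect_identical(write_newick(ts), "((h1:0.01,h2:0.01):0.01,(h3:0.01,h4:0.01):0.01);")
  tp <- build_grouping_topology(labels, "population")
  expect_identical(write_newick(tp), "((h1:0.01,h3:0.01):0.01,(h2:0.01,h4:0.01):0.01);")
  # identical partitions under both keys give identical newick strings
  labels2 <- labels
  labels2$population <- c("P1", "P1", "P2", "P2")
  expect_identical(write_newick(build_grouping_topology(labels2, "s_allele")),
                   write_newick(build_grouping_topology(labels2, "population")))
  labels3 <- labels
  labels3$s_allele <- "S1"
  expect_error(build_grouping_topology(labels3, "s_allele"), "single group")
})

test_that("window iteration is exact arithmetic with partial windows dropped", {
  aln <- list(positions = seq_len(120L))
  w <- window_iter(aln, 50L, 10L)
  expect_length(w, 8L)
  expect_identical(vapply(w, `[`, 0L, 1L), seq(1L, 71L, by = 10L))
  expect_length(window_iter(list(positions = 1:50), 50L), 1L)
  expect_warning(w0 <- window_iter(list(positions = 1:49), 50L), "fewer")
  expect_length(w0, 0L)
  expect_error(window_iter(aln, 1L), "at least 2")
})

test_that("loglik reproduces the closed form for identical sequences", {
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")
  n <- 17L
  w <- matrix(sample(c("A", "C", "G", "T"), n, TRUE), 1L)[rep(1L, 2L), ,
                                                          drop = FALSE]
  rownames(w) <- c("a", "b")
  ll <- loglik(w, tr)
  expect_equal(as.numeric(ll), n * log(0.25), tolerance = 1e-6)
  expect_true(all(attr(ll, "edge_lengths") < 1e-6))
})

test_that("pruning kernel equals the exhaustive state-summation oracle", {
  set.seed(17)
  labels5 <- data.frame(hap_id = paste0("h", 1:5),
                        s_allele = c("S1", "S1", "S2", "S2", "S3"),
                        population = c("P1", "P2", "P1", "P2", "P1"))
  for (rep in 1:5) {
    top <- build_grouping_topology(labels5, "s_allele")
    nsites <- sample(4:10, 1L)
    win <- matrix(sample(c("A", "C", "G", "T", "N"), 5L * nsites, TRUE,
                         prob = c(rep(0.23, 4L), 0.08)),
                  5L, nsites, dimnames = list(labels5$hap_id, NULL))
    top$tree$edge.length <- runif(nrow(top$tree$edge), 0.02, 1.5)
    got <- as.numeric(loglik(win, top$tree, optimize = FALSE))
    want <- oracle_loglik(top$tree, win)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("loglik is invariant to leaf order and group relabeling", {
  set.seed(23)
  labels <- make_labels()
  win <- matrix(sample(c("A", "C", "G", "T"), 4L * 30L, TRUE), 4L, 30L,
                dimnames = list(labels$hap_id, NULL))
  l1 <- as.numeric(loglik(win, build_grouping_topology(labels, "s_allele")))
  # permute rows of the window: tips are matched by name
  l2 <- as.numeric(loglik(win[c(3, 1, 4, 2), ],
                          build_grouping_topology(labels, "s_allele")))
  expect_equal(l1, l2, tolerance = 1e-9)
  # relabeling group names preserves the partition, hence the likelihood
  relab <- labels
  relab$s_allele <- c("Zz", "Zz", "Aa", "Aa")
  l3 <- as.numeric(loglik(win, build_grouping_topology(relab, "s_allele")))
  expect_equal(l1, l3, tolerance = 1e-6)
})

test_that("delta_loglik: zero on coinciding partitions, sign by construction,
           exact negation under key swap", {
  labels <- make_labels()
  # identical partitions under the two keys
  lab_same <- labels
  lab_same$population <- c("Q1", "Q1", "Q2", "Q2")  # same split as S-allele
  win <- matrix(sample(c("A", "C", "G", "T"), 4L * 20L, TRUE), 4L, 20L,
                dimnames = list(labels$hap_id, NULL))
  expect_equal(delta_loglik(win, lab_same)$delta, 0, tolerance = 1e-6)
  # monomorphic window: all topologies equally likely
  mono <- matrix("A", 4L, 20L, dimnames = list(labels$hap_id, NULL))
  expect_equal(delta_loglik(mono, labels)$delta, 0, tolerance = 1e-8)
  # sequences identical within S-allele groups, divergent between
  win2 <- rbind(h1 = rep(c("A", "C"), 10L), h2 = rep(c("A", "C"), 10L),
                h3 = rep(c("G", "T"), 10L), h4 = rep(c("G", "T"), 10L))
  expect_gt(delta_loglik(win2, labels)$delta, 0)
  # swapping the grouping keys negates delta exactly
  set.seed(31)
  win3 <- matrix(sample(c("A", "C", "G", "T"), 4L * 25L, TRUE), 4L, 25L,
                 dimnames = list(labels$hap_id, NULL))
  swapped <- labels
  swapped$s_allele <- labels$population
  swapped$population <- labels$s_allele
  d1 <- delta_loglik(win3, labels)$delta
  d2 <- delta_loglik(win3, swapped)$delta
  expect_equal(d1, -d2, tolerance = 1e-9)
})

test_that("unknown character states are reported by symbol", {
  labels <- make_labels()
  win <- matrix("A", 4L, 5L, dimnames = list(labels$hap_id, NULL))
  win[2L, 3L] <- "X"
  expect_error(loglik(win, build_grouping_topology(labels, "s_allele")), "X")
})

test_that("null_band degenerate draws and seed reproducibility", {
  cfg <- synth_config(preset = "control", seed = 5L,
                      hierarchy = test_hierarchy()[1:4, ],
                      copies_per_lineage = 2L, flank_length = 6000L, d0 = 0L)
  ctrl <- generate_haplotypes(cfg)$alignment
  nb1 <- null_band(ctrl, size = 30L, n_draws = 1L, seed = 3L)
  expect_identical(nb1$p2_5, nb1$p97_5)
  nb2 <- null_band(ctrl, size = 30L, n_draws = 10L, seed = 3L)
  nb3 <- null_band(ctrl, size = 30L, n_draws = 10L, seed = 3L)
  expect_identical(nb2$deltas, nb3$deltas)
  expect_error(null_band(ctrl, size = 1000L, n_draws = 1L), "at least")
})

test_that("distance_correlation handles exact and degenerate inputs", {
  scan <- data.frame(delta_logl = c(10, 8, 6, 4), distance = c(0, 10, 20, 30))
  dc <- distance_correlation(scan)
  expect_equal(dc$r, -1, tolerance = 1e-12)
  const <- data.frame(delta_logl = c(1, 1, 1), distance = c(0, 5, 10))
  expect_true(distance_correlation(const)$undefined)
})
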