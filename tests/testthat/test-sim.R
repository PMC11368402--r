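test_that("zygote survival is (1-s)^n over homozygous deleterious positions", {
  expect_equal(zygote_survival_prob(rep(0, 10), rep(0, 10), 0.01), 1)
  expect_equal(zygote_survival_prob(c(1, 1, 0), c(1, 1, 1), 0.01), 0.9801)
  # heterozygous positions contribute nothing (h = 0)
  expect_equal(zygote_survival_prob(c(1, 1, 1), c(0, 0, 0), 0.5), 1)
  expect_equal(zygote_survival_prob(rep(1, 100), rep(1, 100), 0.01),
               0.99^100, tolerance = 1e-12)
})

test_that("sim_params validates the published parameter ranges", {
  p <- sim_params()
  expect_identical(c(p$N, p$L), c(10000L, 100L))
  expect_identical(c(p$mu_forward, p$mu_back, p$s), c(1e-4, 1e-5, 0.01))
  expect_identical(c(p$n_replicates, p$record_every), c(100L, 1000L))
  expect_error(sim_params(mu_forward = 1e-5, mu_back = 1e-4), "mu_back")
  expect_error(sim_params(s = 0), "s")
  expect_error(sim_params(h = 0.5), "recessive")
})

test_that("one generation keeps census and is closed under the null", {
  h <- test_hierarchy()
  p <- sim_params(N = 60L, L = 10L, mu_forward = 0, mu_back = 0, s = 0.5,
                  hierarchy = h, n_generations = 1L, n_replicates = 1L)
  eq <- deterministic_equilibrium(h)
  gt <- shelterload:::.genotype_table(h)
  set.seed(11)
  gidx <- sample.int(nrow(gt), p$N, TRUE, prob = eq$genotype_freqs$freq)
  st <- shelterload:::new_population_state(
    gt$a1[gidx], gt$a2[gidx],
    matrix(FALSE, p$N, p$L), matrix(FALSE, p$N, p$L))
  nxt <- step_generation(st, p)
  expect_identical(length(nxt$s1), p$N)
  expect_identical(nxt$generation, 1L)
  # all-zero D-vectors with mu = 0 stay all-zero
  expect_false(any(nxt$d1) || any(nxt$d2))
})

test_that("one-generation allele-frequency change matches the Wright-Fisher
           mutation expectation over replicates", {
  # L = 1, mu_back = 0, s effectively 0: E(q') = q + mu (1 - q)
  h <- test_hierarchy()
  mu <- 0.05
  p <- sim_params(N = 40L, L = 1L, mu_forward = mu, mu_back = 0, s = 1e-9,
                  hierarchy = h, n_generations = 1L, n_replicates = 1L)
  eq <- deterministic_equilibrium(h)
  gt <- shelterload:::.genotype_table(h)
  set.seed(21)
  gidx <- sample.int(nrow(gt), p$N, TRUE, prob = eq$genotype_freqs$freq)
  pool <- matrix(runif(2L * p$N) < 0.3, 2L * p$N, 1L)
  q0 <- mean(pool)
  expected <- q0 + mu * (1 - q0)
  reps <- 2000L
  # reshuffle which individual carries which D-vector every replicate so
  # that compatibility-weighted father sampling stays uncorrelated with D
  qs <- vapply(seq_len(reps), function(i) {
    perm <- pool[sample.int(2L * p$N), , drop = FALSE]
    st <- shelterload:::new_population_state(
      gt$a1[gidx], gt$a2[gidx],
      perm[seq_len(p$N), , drop = FALSE],
      perm[p$N + seq_len(p$N), , drop = FALSE])
    nx <- step_generation(st, p)
    (sum(nx$d1) + sum(nx$d2)) / (2 * p$N)
  }, 0)
  se <- sd(qs) / sqrt(reps)
  expect_lt(abs(mean(qs) - expected), 3 * se)
})

test_that("per-position allele counts are a martingale under neutrality", {
  h <- test_hierarchy()
  p <- sim_params(N = 40L, L = 5L, mu_forward = 0, mu_back = 0, s = 1e-12,
                  hierarchy = h, n_generations = 1L, n_replicates = 1L)
  eq <- deterministic_equilibrium(h)
  gt <- shelterload:::.genotype_table(h)
  set.seed(31)
  gidx <- sample.int(nrow(gt), p$N, TRUE, prob = eq$genotype_freqs$freq)
  pool <- matrix(runif(2L * p$N * p$L) < 0.4, 2L * p$N, p$L)
  c0 <- colSums(pool)
  reps <- 1000L
  cs <- matrix(0, reps, p$L)
  for (i in seq_len(reps)) {
    perm <- pool[sample.int(2L * p$N), , drop = FALSE]
    st <- shelterload:::new_population_state(
      gt$a1[gidx], gt$a2[gidx],
      perm[seq_len(p$N), , drop = FALSE],
      perm[p$N + seq_len(p$N), , drop = FALSE])
    nx <- step_generation(st, p)
    cs[i, ] <- colSums(nx$d1) + colSums(nx$d2)
  }
  for (j in seq_len(p$L)) {
    se <- sd(cs[, j]) / sqrt(reps)
    expect_lt(abs(mean(cs[, j]) - c0[j]), 3 * se)
  }
})

test_that("summarize_load equals the brute-force per-position oracle", {
  set.seed(41)
  h <- test_hierarchy()
  for (rep in 1:5) {
    n <- 10L
    sa1 <- sample.int(8L, n, TRUE); sa2 <- sample.int(8L, n, TRUE)
    d1 <- matrix(runif(n * 12L) < 0.3, n, 12L)
    d2 <- matrix(runif(n * 12L) < 0.3, n, 12L)
    st <- shelterload:::new_population_state(sa1, sa2, d1, d2)
    got <- summarize_load(st, h)
    want <- oracle_load_summary(c(sa1, sa2), rbind(d1, d2))
    expect_identical(got$s_allele, h$id[want$allele])
    expect_identical(got$n_copies, want$n_copies)
    expect_identical(got$n_fixed, want$n_fixed)
    expect_identical(got$n_segregating, want$n_segregating)
  }
  # single-copy lineage: fixed undefined, total = mutations on the copy
  st1 <- shelterload:::new_population_state(
    c(1L, 2L), c(2L, 2L),
    rbind(c(TRUE, TRUE, FALSE), c(FALSE, FALSE, FALSE)),
    rbind(c(FALSE, TRUE, FALSE), c(FALSE, FALSE, TRUE)))
  got <- summarize_load(st1, h)
  a1 <- got[got$s_allele == "A1", ]
  expect_true(is.na(a1$n_fixed))
  expect_identical(a1$n_total, 2L)
})

test_that("run_replicates is seed-deterministic and respects mu_forward = 0", {
  h <- test_hierarchy()
  p <- sim_params(N = 50L, L = 8L, mu_forward = 1e-2, mu_back = 1e-3,
                  s = 0.05, hierarchy = h, n_generations = 20L,
                  record_every = 10L, n_replicates = 2L, seed = 7L)
  r1 <- run_replicates(p)
  r2 <- run_replicates(p)
  expect_identical(r1$replicates[[1L]]$freq, r2$replicates[[1L]]$freq)
  expect_identical(r1$replicates[[2L]]$load, r2$replicates[[2L]]$load)
  # census recorded at every sampled generation via frequencies in [0,1]
  expect_true(all(r1$replicates[[1L]]$freq >= 0 &
                    r1$replicates[[1L]]$freq <= 1))

  p0 <- sim_params(N = 50L, L = 8L, mu_forward = 0, mu_back = 0, s = 0.05,
                   hierarchy = h, n_generations = 10L, record_every = 5L,
                   n_replicates = 1L, seed = 7L)
  r0 <- run_replicates(p0)
  expect_true(all(r0$replicates[[1L]]$load$n_total == 0L))
})

test_that("pathological configurations error out of father rejection", {
  # a single S-allele shared by everyone: no compatible father exists
  h <- dominance_hierarchy(c("a", "b"), c(1L, 1L))
  p <- sim_params(N = 10L, L = 2L, hierarchy = h,
                  n_generations = 1L, n_replicates = 1L)
  st <- shelterload:::new_population_state(
    rep(1L, 10L), rep(1L, 10L),
    matrix(FALSE, 10L, 2L), matrix(FALSE, 10L, 2L))
  set.seed(1)
  expect_error(step_generation(st, p, max_father_draws = 50L),
               "compatible father")
})
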