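# Forward-time engine. The population is stored column-light: two integer
# vectors of S-allele indices and two N x L logical matrices of deleterious
# indicators (one per haplotype). The S-locus and the D-locus are fully
# linked: a transmitted gamete carries the S-allele and the D-vector of the
# same parental haplotype.

#' Create a population state
#'
#' @param s1,s2 integer vectors (length N) of S-allele indices into the
#'   hierarchy, one per haplotype.
#' @param d1,d2 N x L logical matrices of deleterious-allele indicators.
#' @param generation generation counter.
#' @return An object of class `population_state`.
#' @keywords internal
new_population_state <- function(s1, s2, d1, d2, generation = 0L) {
  N <- length(s1)
  stopifnot(length(s2) == N, nrow(d1) == N, nrow(d2) == N,
            ncol(d1) == ncol(d2))
  structure(list(generation = as.integer(generation),
                 s1 = as.integer(s1), s2 = as.integer(s2),
                 d1 = d1, d2 = d2),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat("SSI population state: N =", length(x$s1),
      ", L =", ncol(x$d1), ", generation", x$generation, "\n")
  invisible(x)
}

#' Advance the population by one generation
#'
#' Produces exactly `N` surviving offspring. For each offspring slot a
#' mother is drawn uniformly; fathers are drawn uniformly and redrawn until
#' SSI-compatible with the mother (sporophytic pollen phenotype vs pistil
#' phenotype); each parent transmits one haplotype uniformly; per-position
#' mutation is applied to each transmitted gamete (0 -> 1 at `mu_forward`,
#' 1 -> 0 at `mu_back`); the zygote survives with probability
#' `(1 - s)^n_hom`, otherwise the whole mating (mother included) is redrawn.
#' Uses the current R random number stream.
#'
#' @param state a `population_state`.
#' @param params a [sim_params()].
#' @param max_father_draws bound on consecutive incompatible father draws
#'   per slot before declaring the configuration pathological.
#' @return The next `population_state` (census exactly `N`).
#' @export
step_generation <- function(state, params, max_father_draws = 1000L) {
  N <- length(state$s1)
  L <- ncol(state$d1)
  stopifnot(N == params$N, L == params$L)
  # class indexed by 0-based allele id for the C++ kernel
  cls <- params$hierarchy$class
  off <- .step_generation_cpp(state$s1, state$s2, state$d1, state$d2,
                              cls, params$mu_forward, params$mu_back,
                              params$s, params$pistil_dominance,
                              as.integer(max_father_draws))
  new_population_state(off$s1, off$s2, off$d1, off$d2,
                       generation = state$generation + 1L)
}

#' Per-lineage load summary of a population state
#'
#' For every S-allele with at least one copy among the `2N` haplotypes,
#' counts D-locus positions where the deleterious allele is carried by all
#' linked copies (`n_fixed`, defined only for lineages with >= 2 copies) or
#' by some but not all (`n_segregating`). `n_total = n_fixed +
#' n_segregating`; for single-copy lineages `n_fixed`/`n_segregating` are
#' `NA` and `n_total` is the mutation count on the single copy.
#'
#' @param state a `population_state`.
#' @param hierarchy the [dominance_hierarchy()] indexing the allele labels.
#' @return data.frame with columns `s_allele`, `dominance_class`,
#'   `n_copies`, `n_fixed`, `n_segregating`, `n_total`.
#' @export
summarize_load <- function(state, hierarchy) {
  sa <- c(state$s1, state$s2)
  D <- rbind(state$d1, state$d2)
  present <- sort(unique(sa))
  res <- lapply(present, function(a) {
    rows <- sa == a
    nc <- sum(rows)
    cs <- colSums(D[rows, , drop = FALSE])
    if (nc >= 2L) {
      nf <- sum(cs == nc)
      ns <- sum(cs > 0L & cs < nc)
      data.frame(s_allele = hierarchy$id[a],
                 dominance_class = hierarchy$class[a],
                 n_copies = nc, n_fixed = nf, n_segregating = ns,
                 n_total = nf + ns, stringsAsFactors = FALSE)
    } else {
      data.frame(s_allele = hierarchy$id[a],
                 dominance_class = hierarchy$class[a],
                 n_copies = nc, n_fixed = NA_integer_,
                 n_segregating = NA_integer_,
                 n_total = sum(cs > 0L), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}

# deterministic replicate seed below 2^31
.mix_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(r) * 69621) %% 2147483562) + 1L
}

#' Run replicate forward simulations of SSI sheltered load
#'
#' Each replicate starts from S-genotypes sampled from the deterministic
#' SSI equilibrium ([deterministic_equilibrium()]) with mutation-free
#' D-vectors, runs `n_generations` generations, records per-position
#' deleterious allele frequencies every `record_every` generations after the
#' burn-in, logs S-allele loss events (the run continues), and summarises
#' the per-lineage load of the final state.
#'
#' @param params a [sim_params()].
#' @param progress print one line per replicate.
#' @return An object of class `ssi_sim_result`: list with `params`,
#'   `equilibrium`, and `replicates` — one element per replicate holding
#'   `freq` (matrix: recorded generations x L positions), `generations`
#'   (recorded generation numbers), `load` (final [summarize_load()] table),
#'   and `losses` (data.frame of lost alleles and first recorded generation
#'   of absence).
#' @export
run_replicates <- function(params, progress = FALSE) {
  eq <- deterministic_equilibrium(params$hierarchy, params$eq_tolerance,
                                  pistil_dominance = params$pistil_dominance)
  gt <- .genotype_table(params$hierarchy)
  rec_gens <- seq.int(params$burn_in + params$record_every,
                      params$n_generations, by = params$record_every)
  rec_gens <- rec_gens[rec_gens <= params$n_generations]
  replicates <- vector("list", params$n_replicates)
  for (r in seq_len(params$n_replicates)) {
    set.seed(.mix_seed(params$seed, r))
    gidx <- sample.int(nrow(gt), params$N, replace = TRUE,
                       prob = eq$genotype_freqs$freq)
    state <- new_population_state(gt$a1[gidx], gt$a2[gidx],
                                  matrix(FALSE, params$N, params$L),
                                  matrix(FALSE, params$N, params$L))
    freq <- matrix(NA_real_, length(rec_gens), params$L)
    present0 <- sort(unique(c(state$s1, state$s2)))
    loss <- stats::setNames(rep(NA_integer_, length(present0)),
                            params$hierarchy$id[present0])
    ri <- 1L
    for (g in seq_len(params$n_generations)) {
      state <- tryCatch(step_generation(state, params),
                        error = function(e)
                          stop("replicate ", r, ", generation ", g, ": ",
                               conditionMessage(e), call. = FALSE))
      if (ri <= length(rec_gens) && g == rec_gens[ri]) {
        freq[ri, ] <- (colSums(state$d1) + colSums(state$d2)) / (2 * params$N)
        here <- unique(c(state$s1, state$s2))
        gone <- setdiff(present0, here)
        for (a in gone) {
          nm <- params$hierarchy$id[a]
          if (is.na(loss[nm])) loss[nm] <- g
        }
        ri <- ri + 1L
      }
    }
    replicates[[r]] <- list(
      freq = freq, generations = rec_gens,
      load = summarize_load(state, params$hierarchy),
      losses = data.frame(s_allele = names(loss)[!is.na(loss)],
                          first_absent_at = unname(loss[!is.na(loss)]),
                          stringsAsFactors = FALSE))
    if (progress)
      message("replicate ", r, "/", params$n_replicates, " done (",
              sum(replicates[[r]]$load$n_total, na.rm = TRUE),
              " total mutations across lineages)")
  }
  structure(list(params = params, equilibrium = eq, replicates = replicates),
            class = "ssi_sim_result")
}

#' @export
print.ssi_sim_result <- function(x, ...) {
  cat("SSI simulation:", length(x$replicates), "replicate(s), N =",
      x$params$N, ", L =", x$params$L, "\n")
  invisible(x)
}

#' Replicate-mean load per S-allele
#'
#' Averages final-state [summarize_load()] counts over replicates; the
#' quantity plotted against dominance class in downstream trend tests.
#'
#' @param result an `ssi_sim_result`.
#' @return data.frame with `s_allele`, `dominance_class`, and replicate
#'   means `mean_fixed`, `mean_segregating`, `mean_total` (single-copy
#'   lineages drop out of fixed/segregating means).
#' @export
mean_load_by_allele <- function(result) {
  all_load <- do.call(rbind, lapply(result$replicates, `[[`, "load"))
  agg <- function(v) tapply(v, all_load$s_allele, mean, na.rm = TRUE)
  out <- data.frame(
    s_allele = names(agg(all_load$n_total)),
    mean_fixed = as.numeric(agg(all_load$n_fixed)),
    mean_segregating = as.numeric(agg(all_load$n_segregating)),
    mean_total = as.numeric(agg(all_load$n_total)),
    stringsAsFactors = FALSE)
  out$dominance_class <- result$params$hierarchy$class[
    match(out$s_allele, result$params$hierarchy$id)]
  out[order(out$dominance_class, out$s_allele), ]
}
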