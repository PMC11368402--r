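# Trio phasing: parental S-flanking haplotypes are resolved from
# parent-offspring trios assuming no recombination between parent and
# offspring. The allelic state shared between parent and offspring is
# attributed to their shared (transmitted) S-allele, the state not shared
# to the parent's other (untransmitted) haplotype.

#' Trio genotype container
#'
#' @param sites data.frame with at least `chrom`, `pos`, `ref`, `alt`
#'   (biallelic SNPs, 1-based VCF coordinates).
#' @param p1,p2,off integer vectors of allele dosages (0, 1, 2, `NA`) for
#'   parent 1, parent 2 and the offspring, parallel to `sites`.
#' @param s_p1,s_p2,s_off character vectors of length 2: S-locus genotypes.
#' @param ids character vector of length 3 naming parent1, parent2,
#'   offspring.
#' @param population optional population label carried through to the
#'   phased haplotypes.
#' @return An object of class `trio_genotypes`.
#' @export
trio_genotypes <- function(sites, p1, p2, off, s_p1, s_p2, s_off,
                           ids = c("P1", "P2", "O"), population = NA_character_) {
  n <- nrow(sites)
  stopifnot(length(p1) == n, length(p2) == n, length(off) == n,
            length(s_p1) == 2L, length(s_p2) == 2L, length(s_off) == 2L,
            length(ids) == 3L)
  ok <- function(g) all(is.na(g) | g %in% 0:2)
  if (!ok(p1) || !ok(p2) || !ok(off))
    stop("genotype dosages must be 0, 1, 2 or NA")
  structure(list(sites = sites, p1 = as.integer(p1), p2 = as.integer(p2),
                 off = as.integer(off),
                 s_p1 = as.character(s_p1), s_p2 = as.character(s_p2),
                 s_off = as.character(s_off), ids = as.character(ids),
                 population = population),
            class = "trio_genotypes")
}

#' S-allele transmitted by a parent to its offspring
#'
#' Resolves which S-allele a parent transmitted, jointly with the other
#' parent's S-genotype: an attribution is valid when the offspring's two
#' alleles can be split so that one comes from each parent. If several
#' distinct attributions are valid the transmission is uninformative
#' (`NA`).
#'
#' @param parent_s character length 2: the focal parent's S-genotype.
#' @param offspring_s character length 2: the offspring's S-genotype.
#' @param other_parent_s optional character length 2: the other parent's
#'   S-genotype, used to discard impossible attributions.
#' @return The transmitted allele label, or `NA_character_` when
#'   uninformative.
#' @export
transmitted_s_allele <- function(parent_s, offspring_s, other_parent_s = NULL) {
  stopifnot(length(parent_s) == 2L, length(offspring_s) == 2L)
  if (length(intersect(parent_s, offspring_s)) == 0L)
    stop("Mendelian inconsistency at the S-locus: parent {",
         paste(parent_s, collapse = ","), "} shares no allele with offspring {",
         paste(offspring_s, collapse = ","), "}")
  splits <- list(offspring_s, rev(offspring_s))   # (from focal, from other)
  valid <- vapply(splits, function(sp) {
    sp[1L] %in% parent_s &&
      (is.null(other_parent_s) || sp[2L] %in% other_parent_s)
  }, logical(1))
  from_focal <- unique(vapply(splits[valid], `[`, character(1), 1L))
  if (length(from_focal) == 1L) from_focal else NA_character_
}

# lookup table over (p1, p2, off) dosages in 0..2: transmitted alleles and
# status; built once at load time
.phase_lookup <- local({
  tab <- expand.grid(p1 = 0:2, p2 = 0:2, off = 0:2)
  alleles <- function(g) if (g == 0L) 0L else if (g == 2L) 1L else 0:1
  res <- t(apply(tab, 1L, function(r) {
    offa <- if (r[["off"]] == 0L) c(0L, 0L) else if (r[["off"]] == 2L)
      c(1L, 1L) else c(0L, 1L)
    splits <- unique(list(offa, rev(offa)))
    valid <- Filter(function(sp) sp[1L] %in% alleles(r[["p1"]]) &&
                      sp[2L] %in% alleles(r[["p2"]]), splits)
    if (length(valid) == 1L) c(valid[[1L]], 0L)          # resolved
    else if (length(valid) > 1L) c(NA, NA, 1L)           # ambiguous
    else c(NA, NA, 2L)                                   # mendelian error
  }))
  list(key = tab, t1 = res[, 1L], t2 = res[, 2L], status = res[, 3L])
})

#' Mendelian phase resolution of one biallelic site
#'
#' Partitions the offspring's two alleles between the parents whenever
#' exactly one attribution is consistent. Triple-heterozygous sites are
#' ambiguous; any missing genotype is ambiguous (reported as `missing`);
#' impossible configurations (e.g. both parents `0/0`, offspring `0/1`)
#' are Mendelian-error records.
#'
#' @param p1_gt,p2_gt,off_gt integer dosage vectors (0, 1, 2, `NA`),
#'   recycled to a common length.
#' @return data.frame with columns `t1`, `t2` (allele transmitted by each
#'   parent; `NA` when unresolved) and `status` (`"resolved"`,
#'   `"ambiguous"`, `"missing"`, `"mendel_error"`).
#' @export
phase_site <- function(p1_gt, p2_gt, off_gt) {
  n <- max(length(p1_gt), length(p2_gt), length(off_gt))
  p1 <- rep_len(as.integer(p1_gt), n)
  p2 <- rep_len(as.integer(p2_gt), n)
  off <- rep_len(as.integer(off_gt), n)
  idx <- p1 + 3L * p2 + 9L * off + 1L
  t1 <- .phase_lookup$t1[idx]
  t2 <- .phase_lookup$t2[idx]
  st <- .phase_lookup$status[idx]
  status <- c("resolved", "ambiguous", "mendel_error")[st + 1L]
  miss <- is.na(p1) | is.na(p2) | is.na(off)
  t1[miss] <- NA; t2[miss] <- NA; status[miss] <- "missing"
  data.frame(t1 = as.integer(t1), t2 = as.integer(t2), status = status,
             stringsAsFactors = FALSE)
}

#' Phase a parent-offspring trio
#'
#' Applies [phase_site()] across all sites and assembles the four parental
#' haplotypes: for each parent, the transmitted haplotype (tagged with the
#' S-allele resolved by [transmitted_s_allele()]) and the untransmitted one
#' (tagged with the parent's other S-allele). Ambiguous, missing, and
#' Mendelian-error sites are emitted as `NA`, not imputed; Mendelian errors
#' are counted and trios with an error fraction above `error_threshold`
#' are flagged.
#'
#' @param trio a [trio_genotypes()].
#' @param error_threshold per-trio Mendelian error fraction above which the
#'   QC flag is raised (default 0.05).
#' @return list of class `phased_trio`: `haplotypes` (data.frame: `hap_id`,
#'   `parent`, `s_allele`, `transmitted`, `population`), `alleles` (matrix
#'   haplotypes x sites, 0/1/`NA`), `sites`, and `qc` (data.frame). If the
#'   S-transmission is uninformative for either parent, returns `NULL`
#'   (invisibly) with an explanatory message.
#' @export
phase_trio <- function(trio, error_threshold = 0.05) {
  stopifnot(inherits(trio, "trio_genotypes"))
  ts1 <- transmitted_s_allele(trio$s_p1, trio$s_off, trio$s_p2)
  ts2 <- transmitted_s_allele(trio$s_p2, trio$s_off, trio$s_p1)
  if (is.na(ts1) || is.na(ts2)) {
    message("skipping trio with offspring ", trio$ids[3L],
            ": uninformative S-transmission")
    return(invisible(NULL))
  }
  ph <- phase_site(trio$p1, trio$p2, trio$off)
  resolved <- ph$status == "resolved"
  h <- function(parent_gt, t) {
    transmitted <- ifelse(resolved, t, NA_integer_)
    untransmitted <- ifelse(resolved & !is.na(parent_gt),
                            parent_gt - t, NA_integer_)
    untransmitted[untransmitted < 0L | untransmitted > 1L] <- NA_integer_
    list(transmitted, untransmitted)
  }
  h1 <- h(trio$p1, ph$t1)
  h2 <- h(trio$p2, ph$t2)
  other <- function(s_gt, transmitted) {
    if (s_gt[1L] == transmitted) s_gt[2L]
    else if (s_gt[2L] == transmitted) s_gt[1L]
    else stop("transmitted allele absent from parent S-genotype")
  }
  haps <- data.frame(
    hap_id = paste0(rep(trio$ids[1:2], each = 2L), "_",
                    rep(c("T", "U"), 2L)),
    parent = rep(trio$ids[1:2], each = 2L),
    s_allele = c(ts1, other(trio$s_p1, ts1), ts2, other(trio$s_p2, ts2)),
    transmitted = c(TRUE, FALSE, TRUE, FALSE),
    population = trio$population,
    stringsAsFactors = FALSE)
  alleles <- rbind(h1[[1L]], h1[[2L]], h2[[1L]], h2[[2L]])
  rownames(alleles) <- haps$hap_id
  n_err <- sum(ph$status == "mendel_error")
  qc <- data.frame(
    offspring = trio$ids[3L], n_sites = nrow(trio$sites),
    n_resolved = sum(resolved),
    n_ambiguous = sum(ph$status == "ambiguous"),
    n_missing = sum(ph$status == "missing"),
    n_mendel_error = n_err,
    ambiguous_fraction = mean(ph$status %in% c("ambiguous", "missing")),
    mendel_error_fraction = n_err / max(1L, nrow(trio$sites)),
    flagged = n_err / max(1L, nrow(trio$sites)) > error_threshold,
    stringsAsFactors = FALSE)
  structure(list(haplotypes = haps, alleles = alleles, sites = trio$sites,
                 qc = qc),
            class = "phased_trio")
}

#' Phase a set of trios, each parent only once
#'
#' Parents used in several crosses are phased from their first informative
#' trio; later trios are used only as a consistency check, reporting the
#' number of sites where the re-phased haplotypes disagree.
#'
#' @param trios list of [trio_genotypes()] objects sharing the same sites.
#' @param error_threshold passed to [phase_trio()].
#' @return list of class `phased_haplotype_set`: `haplotypes`, `alleles`,
#'   `sites` (combined over unique parents), `qc` (per-trio), `skipped`
#'   (reasons), and `consistency` (data.frame `parent`, `n_trios`,
#'   `n_mismatch`).
#' @export
dedupe_parents <- function(trios, error_threshold = 0.05) {
  phased <- list()
  seen <- character(0)
  qc <- list(); skipped <- character(0)
  mismatch <- list()
  sites <- NULL
  for (trio in trios) {
    pt <- suppressMessages(phase_trio(trio, error_threshold))
    if (is.null(pt)) {
      skipped <- c(skipped, paste0(
        "uninformative S-transmission for trio with offspring ",
        trio$ids[3L]))
      next
    }
    if (is.null(sites)) sites <- pt$sites
    qc[[length(qc) + 1L]] <- pt$qc
    for (parent in unique(pt$haplotypes$parent)) {
      rows <- pt$haplotypes$parent == parent
      if (!parent %in% seen) {
        seen <- c(seen, parent)
        phased[[parent]] <- list(haps = pt$haplotypes[rows, , drop = FALSE],
                                 alleles = pt$alleles[rows, , drop = FALSE])
        mismatch[[parent]] <- c(n_trios = 1L, n_mismatch = 0L)
      } else {
        first <- phased[[parent]]
        # align haplotypes by S-allele where possible, else by slot
        new <- pt$alleles[rows, , drop = FALSE]
        new_s <- pt$haplotypes$s_allele[rows]
        ord <- match(first$haps$s_allele, new_s)
        if (anyNA(ord) || anyDuplicated(ord)) ord <- seq_len(nrow(new))
        mm <- sum(first$alleles != new[ord, , drop = FALSE], na.rm = TRUE)
        mismatch[[parent]] <- mismatch[[parent]] +
          c(n_trios = 1L, n_mismatch = as.integer(mm))
      }
    }
  }
  if (length(phased) == 0L)
    stop("no informative trio could be phased")
  haps <- do.call(rbind, lapply(phased, `[[`, "haps"))
  alleles <- do.call(rbind, lapply(phased, `[[`, "alleles"))
  rownames(haps) <- NULL
  haps$hap_id <- paste0(haps$parent, "_", ifelse(haps$transmitted, "T", "U"))
  rownames(alleles) <- haps$hap_id
  structure(list(
    haplotypes = haps, alleles = alleles, sites = sites,
    qc = do.call(rbind, qc), skipped = skipped,
    consistency = data.frame(
      parent = names(mismatch),
      n_trios = vapply(mismatch, `[[`, 0L, "n_trios"),
      n_mismatch = vapply(mismatch, `[[`, 0L, "n_mismatch"),
      row.names = NULL, stringsAsFactors = FALSE)),
    class = "phased_haplotype_set")
}

#' @export
print.phased_haplotype_set <- function(x, ...) {
  cat("phased_haplotype_set:", nrow(x$haplotypes), "haplotypes from",
      length(unique(x$haplotypes$parent)), "parents;",
      nrow(x$sites), "sites\n")
  invisible(x)
}
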