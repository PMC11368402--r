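# Synthetic data with known truth for every pipeline stage. Realism is
# injected structurally (lineage founders copied within a decay distance
# d0 of the S-locus, population pools beyond) rather than via coalescent
# simulation; this is sufficient to exercise every downstream contract
# with a known answer.

#' Synthetic data configuration
#'
#' The stated world of the generators: two populations, eight S-alleles
#' (two per dominance class), lineage-specific variation within `d0` =
#' 10 kb of the S-locus and population structure beyond, SNPs every 100 bp,
#' and class-dependent load intensities under the `"fig45"` preset
#' (per-site probability that a lineage-zone site is lineage-fixed rises
#' with dominance class, the segregating probability falls), calibrated so
#' per-lineage counts fall in the range observed for real S-haplotypes
#' (roughly 0-25 fixed mutations per lineage within 25 kb).
#'
#' @param preset `"fig45"` (class-dependent load architecture), `"topo"`
#'   (strong lineage signal for the topology scan), `"null"` (panmictic,
#'   label-free variation), or `"control"` (population structure only,
#'   for control regions).
#' @param n_populations number of populations.
#' @param hierarchy a [dominance_hierarchy()]; default 8 alleles, 2 per
#'   class.
#' @param copies_per_lineage haplotype copies per lineage per population.
#' @param flank_length flank width in bp on each side of the S-locus.
#' @param s_locus_length width of the S-locus itself (no SNPs inside).
#' @param d0 lineage-association decay distance in bp.
#' @param snp_spacing average distance between SNPs in bp.
#' @param fixed_intensity,seg_intensity per-class (I..IV) per-site
#'   probabilities of lineage-fixed / lineage-segregating derived alleles
#'   in the lineage zone.
#' @param pop_divergence probability that a population-zone site is
#'   differentially fixed between populations.
#' @param background_poly probability that a population-zone site
#'   segregates within a population.
#' @param n_trios number of parent-offspring trios.
#' @param n_families,offspring_per_family phenotype-table dimensions.
#' @param hom_penalty survival penalty of S-locus homozygotes (0 = null).
#' @param trait_shift additive trait shift in homozygotes (Gaussian trait).
#' @param covariate_effect additive effect of the binary stress covariate.
#' @param seed integer seed (every generator is seed-deterministic).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(preset = c("fig45", "topo", "null", "control"),
                         n_populations = 2L,
                         hierarchy = dominance_hierarchy(
                           sprintf("A%02d", 1:8), rep(1:4, each = 2L)),
                         copies_per_lineage = 3L,
                         flank_length = 50000L, s_locus_length = 4000L,
                         d0 = 10000L, snp_spacing = 100L,
                         fixed_intensity = c(0.02, 0.04, 0.06, 0.08),
                         seg_intensity = c(0.08, 0.06, 0.04, 0.02),
                         pop_divergence = 0.5, background_poly = 0.2,
                         n_trios = 10L, n_families = 6L,
                         offspring_per_family = 60L,
                         hom_penalty = 0, trait_shift = 0,
                         covariate_effect = 0, seed = 1L) {
  preset <- match.arg(preset)
  stopifnot(d0 <= flank_length, all(fixed_intensity >= 0),
            all(seg_intensity >= 0), n_populations >= 1L,
            copies_per_lineage >= 1L, flank_length >= 300L)
  structure(as.list(environment()), class = "synth_config")
}

#' S-locus boundary coordinates of a synthetic configuration
#' @param config a [synth_config()].
#' @return numeric length 2 (first/last bp of the S-locus).
#' @export
synth_s_locus_bounds <- function(config) {
  c(config$flank_length + 1, config$flank_length + config$s_locus_length)
}

#' Generate a reference region with annotated genes of known degeneracy
#'
#' Random protein-coding genes (complete codons, alternating strands,
#' ATG...stop-free interiors) placed along the region, with a truth table
#' of per-CDS-site degeneracy computed by explicit enumeration of all nine
#' single-base variants per codon — independently of
#' [classify_degeneracy()].
#'
#' @param config a [synth_config()].
#' @param n_genes number of genes (default 8).
#' @param gene_length CDS length in bp (multiple of 3; default 300).
#' @return list: `reference` (`DNAStringSet`, one chromosome `"synth1"`),
#'   `annotation` (`GRanges` with gene and CDS features), `truth`
#'   (data.frame `pos`, `class`, `gene`, `strand`).
#' @export
generate_region <- function(config, n_genes = 8L, gene_length = 300L) {
  stopifnot(gene_length %% 3L == 0L)
  set.seed(config$seed + 101L)
  total <- 2L * config$flank_length + config$s_locus_length
  bases <- c("A", "C", "G", "T")
  seq <- sample(bases, total, replace = TRUE)
  gap <- floor((total - n_genes * gene_length) / (n_genes + 1L))
  starts <- gap * seq_len(n_genes) + gene_length * (seq_len(n_genes) - 1L) + 1L
  code <- Biostrings::GENETIC_CODE
  sense <- setdiff(names(code), c("TAA", "TAG", "TGA"))
  truth <- list(); feats <- list()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (g in seq_len(n_genes)) {
    strand <- if (g %% 2L == 0L) "-" else "+"
    codons <- sample(sense, gene_length / 3L, replace = TRUE)
    coding <- strsplit(paste(codons, collapse = ""), "")[[1L]]
    gstart <- starts[g]; gend <- gstart + gene_length - 1L
    genomic <- if (strand == "+") coding else rev(unname(comp[coding]))
    seq[gstart:gend] <- genomic
    # truth by exhaustive 9-variant enumeration per codon
    cls <- character(gene_length)
    for (ci in seq_along(codons)) {
      cdn <- codons[ci]
      aa <- code[[cdn]]
      for (p in 1:3) {
        nch <- 0L
        for (b in setdiff(bases, substr(cdn, p, p))) {
          mut <- cdn; substr(mut, p, p) <- b
          if (code[[mut]] != aa) nch <- nch + 1L
        }
        cls[(ci - 1L) * 3L + p] <-
          if (nch == 3L) "zerofold" else if (nch == 0L) "fourfold" else "other"
      }
    }
    coding_pos <- if (strand == "+") gstart:gend else gend:gstart
    truth[[g]] <- data.frame(pos = coding_pos, class = cls,
                             gene = sprintf("gene%02d", g), strand = strand,
                             stringsAsFactors = FALSE)
    feats[[g]] <- data.frame(start = gstart, end = gend, strand = strand,
                             gene = sprintf("gene%02d", g))
  }
  fdf <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = "synth1",
    ranges = IRanges::IRanges(start = rep(fdf$start, 2L),
                              end = rep(fdf$end, 2L)),
    strand = rep(fdf$strand, 2L),
    type = rep(c("gene", "CDS"), each = nrow(fdf)),
    gene_id = rep(fdf$gene, 2L),
    phase = rep(c(NA_integer_, 0L), each = nrow(fdf)))
  ref <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(ref) <- "synth1"
  list(reference = ref, annotation = gr,
       truth = do.call(rbind, truth))
}

#' Generate labeled S-flanking haplotypes with known load truth
#'
#' Within `d0` of the S-locus, sites copy the lineage founder: with the
#' class-dependent `fixed_intensity` a site carries the derived allele on
#' every copy of the lineage (lineage-fixed), with `seg_intensity` on some
#' but not all copies (lineage-segregating). Beyond `d0` (and everywhere
#' under the `"control"` preset), sites follow population founders with
#' between-population divergence and within-population background
#' polymorphism. Under `"topo"` the lineage founders are maximally
#' divergent (p = 0.5 per site); under `"null"` all structure is removed.
#'
#' @param config a [synth_config()].
#' @param region optional `generate_region()` output supplying reference
#'   bases (otherwise random ref/alt bases are drawn).
#' @return list: `alignment` (a [haplotype_alignment()]), `haplotypes`
#'   (label data.frame with `hap_id`, `s_allele`, `dominance`,
#'   `population`), `alleles` (0/1 matrix), `sites` (data.frame `chrom`,
#'   `pos`, `ref`, `alt`), `truth` (data.frame of per-population,
#'   per-lineage site classifications: `population`, `s_allele`, `pos`,
#'   `kind` = fixed/segregating).
#' @export
generate_haplotypes <- function(config, region = NULL) {
  set.seed(config$seed + 202L)
  b <- synth_s_locus_bounds(config)
  pos <- c(seq.int(1L, config$flank_length, by = config$snp_spacing),
           seq.int(b[2L] + config$snp_spacing, b[2L] + config$flank_length,
                   by = config$snp_spacing))
  pos <- as.integer(pos)
  dist <- pmin(abs(pos - b[1L]), abs(pos - b[2L]))
  nsite <- length(pos)
  hier <- config$hierarchy
  pops <- sprintf("pop%d", seq_len(config$n_populations))
  labs <- expand.grid(copy = seq_len(config$copies_per_lineage),
                      s_allele = hier$id, population = pops,
                      stringsAsFactors = FALSE)
  labs$dominance <- hier$class[match(labs$s_allele, hier$id)]
  labs$hap_id <- sprintf("%s_%s_c%d", labs$population, labs$s_allele,
                         labs$copy)
  nhap <- nrow(labs)
  alleles <- matrix(0L, nhap, nsite)
  lineage_zone <- dist <= config$d0 & config$preset %in% c("fig45", "topo")
  truth <- list()
  if (any(lineage_zone)) {
    lz <- which(lineage_zone)
    for (popn in pops) {
      for (sa in hier$id) {
        rows <- which(labs$population == popn & labs$s_allele == sa)
        ncp <- length(rows)
        cl <- hier$class[hier$id == sa]
        if (config$preset == "topo") {
          p_fix <- 0.5; p_seg <- 0.05
        } else {
          p_fix <- config$fixed_intensity[cl]
          p_seg <- config$seg_intensity[cl]
        }
        u <- stats::runif(length(lz))
        kind <- ifelse(u < p_fix, "fixed",
                       ifelse(u < p_fix + p_seg, "segregating", "none"))
        fx <- lz[kind == "fixed"]
        sg <- lz[kind == "segregating"]
        alleles[rows, fx] <- 1L
        for (j in sg) {
          k <- sample.int(ncp - 1L, 1L)          # 1..ncp-1 carriers
          carriers <- rows[sample.int(ncp, k)]
          alleles[carriers, j] <- 1L
        }
        truth[[length(truth) + 1L]] <- if (length(c(fx, sg)) > 0L)
          data.frame(population = popn, s_allele = sa,
                     pos = pos[c(fx, sg)],
                     kind = rep(c("fixed", "segregating"),
                                c(length(fx), length(sg))),
                     stringsAsFactors = FALSE)
          else NULL
      }
    }
  }
  pop_zone <- which(!lineage_zone)
  if (config$preset == "null") {
    for (j in pop_zone) {
      f <- stats::runif(1L, 0.1, 0.9)
      alleles[, j] <- stats::rbinom(nhap, 1L, f)
    }
  } else {
    for (j in pop_zone) {
      diverged <- stats::runif(1L) < config$pop_divergence
      founder <- if (diverged) stats::rbinom(config$n_populations, 1L, 0.5)
        else rep(stats::rbinom(1L, 1L, 0.5), config$n_populations)
      for (pi in seq_along(pops)) {
        rows <- which(labs$population == pops[pi])
        alleles[rows, j] <- founder[pi]
        if (stats::runif(1L) < config$background_poly) {
          f <- stats::runif(1L, 0.1, 0.9)
          flips <- stats::rbinom(length(rows), 1L, f) == 1L
          alleles[rows[flips], j] <- 1L - founder[pi]
        }
      }
    }
  }
  if (!is.null(region)) {
    refseq <- strsplit(as.character(region$reference[[1L]]), "")[[1L]]
    refb <- refseq[pos]
  } else {
    refb <- sample(c("A", "C", "G", "T"), nsite, replace = TRUE)
  }
  altb <- vapply(refb, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
  seqs <- matrix(rep(refb, each = nhap), nhap, nsite)
  seqs[alleles == 1L] <- matrix(rep(altb, each = nhap),
                                nhap, nsite)[alleles == 1L]
  rownames(seqs) <- labs$hap_id
  rownames(alleles) <- labs$hap_id
  aln <- haplotype_alignment(seqs, pos, labs$s_allele, labs$population,
                             labs$hap_id)
  list(alignment = aln,
       haplotypes = labs[, c("hap_id", "s_allele", "dominance",
                             "population")],
       alleles = alleles,
       sites = data.frame(chrom = "synth1", pos = pos, ref = unname(refb),
                          alt = unname(altb), stringsAsFactors = FALSE),
       truth = if (length(truth) > 0L) do.call(rbind, truth) else
         data.frame(population = character(0), s_allele = character(0),
                    pos = integer(0), kind = character(0)))
}

#' Generate parent-offspring trios with known phase
#'
#' Parents are assembled from generated haplotypes (two distinct-S-allele
#' haplotypes of the same population); the offspring receives one parental
#' haplotype from each parent without recombination. Optionally injects
#' Mendelian errors into the offspring genotypes at rate `error_rate`.
#'
#' @param config a [synth_config()].
#' @param haplotypes optional [generate_haplotypes()] output (generated on
#'   the fly otherwise).
#' @param error_rate per-site probability of corrupting the offspring
#'   genotype (default 0).
#' @return list: `trios` (list of [trio_genotypes()]), `variants` (a
#'   `variant_table` over all trio members), `manifest` (data.frame
#'   `offspring`, `parent1`, `parent2`), `s_genotypes` (data.frame
#'   `individual`, `allele1`, `allele2`), `truth` (list per trio:
#'   transmitted haplotype vectors and source hap ids).
#' @export
generate_trios <- function(config, haplotypes = NULL, error_rate = 0) {
  if (is.null(haplotypes)) haplotypes <- generate_haplotypes(config)
  set.seed(config$seed + 303L)
  labs <- haplotypes$haplotypes
  alleles <- haplotypes$alleles
  sites <- haplotypes$sites
  nsite <- nrow(sites)
  trios <- list(); truth <- list()
  manifest <- list(); sgen <- list()
  gt_cols <- list()
  for (t in seq_len(config$n_trios)) {
    popn <- sample(unique(labs$population), 1L)
    pick_parent <- function() {
      repeat {
        i <- sample(which(labs$population == popn), 2L)
        if (labs$s_allele[i[1L]] != labs$s_allele[i[2L]]) return(i)
      }
    }
    p1 <- pick_parent(); p2 <- pick_parent()
    t1 <- sample(1:2, 1L); t2 <- sample(1:2, 1L)
    ids <- sprintf("T%02d_%s", t, c("P1", "P2", "O"))
    p1_gt <- alleles[p1[1L], ] + alleles[p1[2L], ]
    p2_gt <- alleles[p2[1L], ] + alleles[p2[2L], ]
    off_gt <- alleles[p1[t1], ] + alleles[p2[t2], ]
    if (error_rate > 0) {
      err <- stats::runif(nsite) < error_rate
      off_gt[err] <- (off_gt[err] + sample(1:2, sum(err),
                                           replace = TRUE)) %% 3L
      attr(off_gt, "n_injected") <- sum(err)
    }
    trios[[t]] <- trio_genotypes(
      sites, p1_gt, p2_gt, off_gt,
      s_p1 = labs$s_allele[p1], s_p2 = labs$s_allele[p2],
      s_off = c(labs$s_allele[p1][t1], labs$s_allele[p2][t2]),
      ids = ids, population = popn)
    truth[[t]] <- list(
      p1_transmitted = alleles[p1[t1], ], p1_other = alleles[p1[3L - t1], ],
      p2_transmitted = alleles[p2[t2], ], p2_other = alleles[p2[3L - t2], ],
      p1_haps = labs$hap_id[p1], p2_haps = labs$hap_id[p2],
      n_injected_errors = if (error_rate > 0) attr(off_gt, "n_injected") else 0L)
    manifest[[t]] <- data.frame(offspring = ids[3L], parent1 = ids[1L],
                                parent2 = ids[2L], stringsAsFactors = FALSE)
    sgen[[t]] <- data.frame(
      individual = ids,
      allele1 = c(labs$s_allele[p1][1L], labs$s_allele[p2][1L],
                  labs$s_allele[p1][t1]),
      allele2 = c(labs$s_allele[p1][2L], labs$s_allele[p2][2L],
                  labs$s_allele[p2][t2]),
      stringsAsFactors = FALSE)
    gt_cols[[ids[1L]]] <- p1_gt
    gt_cols[[ids[2L]]] <- p2_gt
    gt_cols[[ids[3L]]] <- as.integer(off_gt)
  }
  gt <- do.call(cbind, gt_cols)
  depth <- matrix(stats::rpois(length(gt), 30L) + 5L, nrow(gt), ncol(gt),
                  dimnames = dimnames(gt))
  variants <- structure(list(
    sites = data.frame(chrom = sites$chrom, pos = sites$pos,
                       id = sprintf("snp%05d", seq_len(nsite)),
                       ref = sites$ref, alt = sites$alt, qual = 90,
                       stringsAsFactors = FALSE),
    gt = gt, depth = depth, samples = colnames(gt)),
    class = "variant_table")
  list(trios = trios, variants = variants,
       manifest = do.call(rbind, manifest),
       s_genotypes = unique(do.call(rbind, sgen)),
       truth = truth)
}

#' Generate family phenotype tables with configurable homozygote penalty
#'
#' Families of controlled crosses between parents sharing one focal
#' S-allele (both heterozygous carriers: expected homozygote fraction
#' 0.25). Offspring genotypes follow Mendelian segregation; S-locus
#' homozygotes survive to reproduction with probability
#' `1 - hom_penalty`; a Gaussian and a Poisson trait receive additive
#' homozygote shifts and a binary stress covariate effect.
#'
#' @param config a [synth_config()]; `hom_penalty`, `trait_shift`,
#'   `covariate_effect` control the effects.
#' @return list: `families` (data.frame `offspring_id`, `family`,
#'   `focal_allele`, `s_genotype` (`"hom"`/`"het"`), `carries_focal`,
#'   `survived`, `trait_gauss`, `trait_pois`, `stress`), `parents`
#'   (data.frame of parental S-genotypes), `truth` (the configured
#'   effects).
#' @export
generate_phenotypes <- function(config) {
  set.seed(config$seed + 404L)
  hier <- config$hierarchy
  rows <- list(); parents <- list()
  for (f in seq_len(config$n_families)) {
    focal <- hier$id[(f - 1L) %% nrow(hier) + 1L]
    others <- sample(setdiff(hier$id, focal), 2L)
    p1 <- c(focal, others[1L]); p2 <- c(focal, others[2L])
    parents[[f]] <- data.frame(family = sprintf("F%02d", f),
                               focal_allele = focal,
                               p1_allele1 = p1[1L], p1_allele2 = p1[2L],
                               p2_allele1 = p2[1L], p2_allele2 = p2[2L],
                               stringsAsFactors = FALSE)
    n <- config$offspring_per_family
    from1 <- sample(p1, n, replace = TRUE)
    from2 <- sample(p2, n, replace = TRUE)
    hom <- from1 == focal & from2 == focal
    carries <- from1 == focal | from2 == focal
    survived <- stats::runif(n) >= ifelse(hom, config$hom_penalty, 0)
    stress <- stats::rbinom(n, 1L, 0.3)
    trait_g <- stats::rnorm(n, 10, 1) + config$trait_shift * hom +
      config$covariate_effect * stress
    trait_p <- stats::rpois(n, exp(log(8) + 0.1 * config$trait_shift * hom))
    rows[[f]] <- data.frame(
      offspring_id = sprintf("F%02d_o%03d", f, seq_len(n)),
      family = sprintf("F%02d", f), focal_allele = focal,
      s_genotype = ifelse(hom, "hom", "het"),
      carries_focal = carries, survived = survived,
      trait_gauss = trait_g, trait_pois = trait_p, stress = stress,
      stringsAsFactors = FALSE)
  }
  list(families = do.call(rbind, rows),
       parents = do.call(rbind, parents),
       truth = list(hom_penalty = config$hom_penalty,
                    trait_shift = config$trait_shift,
                    covariate_effect = config$covariate_effect,
                    expected_hom_fraction = 0.25))
}
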