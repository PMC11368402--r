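# Codon degeneracy classification. A CDS site is zerofold degenerate when
# every possible base change alters the encoded amino acid (proxy for
# selected sites), fourfold degenerate when none does (proxy for neutral
# sites). Stop codons are handled through the standard genetic code ('*'
# counts as an amino acid state).

# per-codon, per-position degeneracy classes, computed once from the
# standard genetic code
.codon_degeneracy <- local({
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  out <- matrix(NA_character_, length(code), 3L,
                dimnames = list(names(code), NULL))
  for (codon in names(code)) {
    aa <- code[[codon]]
    for (pos in 1:3) {
      alt <- vapply(setdiff(bases, substr(codon, pos, pos)), function(b) {
        mut <- codon
        substr(mut, pos, pos) <- b
        code[[mut]]
      }, character(1))
      n_change <- sum(alt != aa)
      out[codon, pos] <- if (n_change == 3L) "zerofold"
        else if (n_change == 0L) "fourfold" else "other"
    }
  }
  out
})

#' Classify site degeneracy from a reference and annotation
#'
#' For every CDS site, substitutes each alternative base into the reference
#' codon and translates: `zerofold` if all three changes alter the amino
#' acid, `fourfold` if none does, `other` otherwise. Reverse-strand CDS are
#' handled by reverse complementation; the CDS `phase` column offsets the
#' reading frame. Sites covered by several CDS features with conflicting
#' classes become `excluded-conflict`. Genes whose (phase-adjusted) CDS
#' length is not a multiple of 3 are skipped with a warning.
#'
#' @param reference a `Biostrings::DNAStringSet` (or path to a FASTA file)
#'   with the reference sequences.
#' @param annotation a `GRanges` of GFF3 features (or path to a GFF3 file)
#'   containing `CDS` rows with `strand`, `phase`, and a gene identifier
#'   column (`gene_id`, `Parent`, or `ID`).
#' @return A `degeneracy_map`: data.frame with `seqnames`, `pos` (1-based),
#'   `class` (`zerofold`, `fourfold`, `other`, `excluded-conflict`),
#'   `gene`, `strand`.
#' @export
classify_degeneracy <- function(reference, annotation) {
  if (is.character(reference)) reference <- read_fasta(reference)
  if (is.character(annotation)) annotation <- read_gff3(annotation)
  stopifnot(methods::is(reference, "DNAStringSet"),
            methods::is(annotation, "GRanges"))
  cds <- annotation[annotation$type == "CDS"]
  if (length(cds) == 0L) stop("annotation contains no CDS features")
  meta <- S4Vectors::mcols(cds)
  gene <- if ("gene_id" %in% names(meta)) meta$gene_id
    else if ("Parent" %in% names(meta)) as.character(meta$Parent)
    else if ("ID" %in% names(meta)) meta$ID
    else stop("CDS features need a gene_id, Parent, or ID column")
  gene <- as.character(gene)
  rows <- list()
  for (g in unique(gene)) {
    feat <- cds[gene == g]
    strand <- as.character(BiocGenerics::strand(feat))[1L]
    chrom <- as.character(GenomicRanges::seqnames(feat))[1L]
    feat <- feat[order(BiocGenerics::start(feat))]
    coords <- unlist(lapply(seq_along(feat), function(i)
      seq.int(BiocGenerics::start(feat)[i], BiocGenerics::end(feat)[i])))
    if (strand == "-") coords <- rev(coords)
    phase <- meta$phase[gene == g]
    phase <- if (is.null(phase) || all(is.na(phase))) 0L else {
      ph <- phase[order(BiocGenerics::start(cds[gene == g]) *
                          ifelse(strand == "-", -1L, 1L))][1L]
      if (is.na(ph)) 0L else as.integer(ph)
    }
    if (phase > 0L) coords <- coords[-seq_len(phase)]
    if (length(coords) %% 3L != 0L) {
      warning("gene ", g, ": CDS length ", length(coords),
              " not a multiple of 3 after phase adjustment; skipped")
      next
    }
    seq <- reference[[chrom]][sort(coords)]
    bases <- strsplit(as.character(seq), "")[[1L]]
    names(bases) <- sort(coords)
    bases <- bases[as.character(coords)]           # coding order
    if (strand == "-")
      bases <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[bases]
    codons <- paste0(bases[c(TRUE, FALSE, FALSE)],
                     bases[c(FALSE, TRUE, FALSE)],
                     bases[c(FALSE, FALSE, TRUE)])
    valid <- codons %in% rownames(.codon_degeneracy)
    cls <- rep(NA_character_, length(coords))
    for (p in 1:3) {
      idx <- seq.int(p, length(coords), by = 3L)
      cls[idx] <- ifelse(valid, .codon_degeneracy[
        ifelse(valid, codons, "AAA"), p], NA_character_)
    }
    rows[[g]] <- data.frame(seqnames = chrom, pos = coords, class = cls,
                            gene = g, strand = strand,
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no gene with a valid CDS")
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$class), ]
  # conflicting overlaps -> excluded-conflict
  key <- paste(out$seqnames, out$pos)
  dup <- key[duplicated(key)]
  if (length(dup) > 0L) {
    conflict <- vapply(unique(dup), function(k) {
      length(unique(out$class[key == k])) > 1L
    }, logical(1))
    bad <- unique(dup)[conflict]
    out$class[key %in% bad] <- "excluded-conflict"
    out <- out[!duplicated(paste(key, out$class)), ]
  }
  out <- out[order(out$seqnames, out$pos), ]   # genomic order on both strands
  rownames(out) <- NULL
  class(out) <- c("degeneracy_map", "data.frame")
  out
}
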