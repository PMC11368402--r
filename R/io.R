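# Readers and writers for the standard formats. Parsing is delegated to
# Biostrings (FASTA), rtracklayer (GFF3), VariantAnnotation (VCF) and
# data.table (TSV); writers emit canonical text so that
# write -> read -> write round-trips are byte-identical on files this
# package produced.

#' Read a FASTA file
#' @param path FASTA file.
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  Biostrings::readDNAStringSet(path)
}

#' Write sequences to FASTA
#' @param x a `DNAStringSet` (or named character vector).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a GFF3 annotation
#' @param path GFF3 file.
#' @return A `GRanges` with the usual `type`, `phase`, attribute columns.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  rtracklayer::import(path, format = "gff3")
}

#' Write a GFF3 annotation
#' @param x a `GRanges`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(x, path) {
  rtracklayer::export(x, path, format = "gff3")
  invisible(path)
}

#' Read a VCF into a plain variant table
#'
#' Multiallelic records are excluded with a logged count (attribute
#' `"n_multiallelic"`). Genotypes are surfaced as allele dosages (0, 1, 2,
#' `NA`), per-genotype depth from the `DP` FORMAT field when present.
#'
#' @param path VCF 4.x file (uncompressed or bgzipped).
#' @return list of class `variant_table`: `sites` (data.frame `chrom`,
#'   `pos`, `id`, `ref`, `alt`, `qual`), `gt` (dosage matrix sites x
#'   samples), `depth` (matrix or `NULL`).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt > 1L
  if (any(multi)) {
    message(sum(multi), " multiallelic record(s) excluded")
    vcf <- vcf[!multi]
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt_str <- VariantAnnotation::geno(vcf)$GT
  dos <- matrix(NA_integer_, nrow(gt_str), ncol(gt_str),
                dimnames = dimnames(gt_str))
  map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L,
           "0|1" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  dos[] <- map[gt_str]
  depth <- VariantAnnotation::geno(vcf)$DP
  if (!is.null(depth)) storage.mode(depth) <- "integer"
  altc <- vapply(as(VariantAnnotation::alt(vcf), "CharacterList"),
                 function(a) if (length(a) == 0L) "." else a[[1L]],
                 character(1))
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    id = names(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = altc,
    qual = as.numeric(rr$QUAL),
    stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  structure(list(sites = sites, gt = dos, depth = depth,
                 samples = colnames(gt_str)),
            class = "variant_table",
            n_multiallelic = sum(multi))
}

#' Write a variant table as canonical VCF text
#'
#' @param x a `variant_table` (see [read_vcf()]); `gt` dosages are written
#'   as `0/0`, `0/1`, `1/1`, `./.`, with a `DP` field when depth is
#'   present.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "variant_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  has_dp <- !is.null(x$depth)
  if (has_dp)
    writeLines("##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               con)
  for (chrom in unique(x$sites$chrom))
    writeLines(sprintf("##contig=<ID=%s>", chrom), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", x$samples), collapse = "\t"), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[x$gt + 1L],
                   nrow(x$gt), ncol(x$gt))
  gt_str[is.na(x$gt)] <- "./."
  if (has_dp) {
    dp <- x$depth
    dp_str <- matrix(as.character(dp), nrow(dp), ncol(dp))
    dp_str[is.na(dp)] <- "."
    gt_str <- matrix(paste(gt_str, dp_str, sep = ":"),
                     nrow(gt_str), ncol(gt_str))
  }
  qual <- ifelse(is.na(x$sites$qual), ".",
                 format(x$sites$qual, trim = TRUE, scientific = FALSE))
  id <- x$sites$id
  id[is.na(id) | id == ""] <- "."
  lines <- paste(x$sites$chrom, x$sites$pos, id, x$sites$ref, x$sites$alt,
                 qual, ".", ".", if (has_dp) "GT:DP" else "GT",
                 apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a TSV table with schema validation
#'
#' @param path TSV file.
#' @param schema optional character vector of required column names;
#'   missing columns are an error, unknown extra columns a warning.
#' @return data.frame.
#' @export
read_tsv_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  if (!is.null(schema)) {
    missing <- setdiff(schema, names(d))
    if (length(missing) > 0L)
      stop("missing required column(s) in ", path, ": ",
           paste(missing, collapse = ", "))
    extra <- setdiff(names(d), schema)
    if (length(extra) > 0L)
      warning("unknown column(s) in ", path, ": ",
              paste(extra, collapse = ", "))
  }
  d
}

#' Write a TSV table
#' @param x data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Export a topology as newick
#'
#' @param topology a [build_grouping_topology()] result or `ape::phylo`.
#' @param path optional output file; when `NULL` the newick string is
#'   returned.
#' @return The newick string (invisibly when written to a file).
#' @export
write_newick <- function(topology, path = NULL) {
  tree <- if (inherits(topology, "grouping_topology")) topology$tree
    else topology
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Run manifest
#'
#' JSON-serialisable record of a command-line run: command, parameter echo,
#' seed, package version, input checksums, timestamp. Sufficient to
#' reproduce the run.
#'
#' @param command subcommand name.
#' @param config named list echoed into the manifest.
#' @param seed integer seed used.
#' @param inputs character vector of input file paths (md5-summed).
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(command, config = list(), seed = NA_integer_,
                         inputs = character(0)) {
  structure(list(
    command = command,
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("shelterload")),
    r_version = as.character(getRversion()),
    input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Write a run manifest next to the outputs
#' @param manifest a [run_manifest()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
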