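#' Read biallelic SNP genotypes from a VCF file
#'
#' Loads GT fields via \pkg{vcfR}. Multi-allelic records and non-SNP
#' records (indels, symbolic alleles) are skipped with a message giving
#' the skip count. Half-calls and any non-diploid GT are treated as
#' missing: the downstream allele-count statistics need complete
#' two-allele calls per genotype.
#'
#' @param path a VCF (v4.x) file with GT data.
#' @param samples optional character vector restricting (and ordering)
#'   the samples kept; an absent sample is an error.
#' @return a \code{\link{site_table}}, sites sorted by (contig,
#'   position). The number of skipped records is attached as attribute
#'   `skipped_records`.
#' @export
read_genotypes <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!is_snp)
  if (n_skip > 0)
    message("read_genotypes: skipped ", n_skip,
            " multi-allelic or non-SNP record(s)")
  if (!any(is_snp)) stop("no biallelic SNP records in ", path)

  gt <- vcfR::extract.gt(vcf, element = "GT")[is_snp, , drop = FALSE]
  all_samples <- colnames(gt)
  if (!is.null(samples)) {
    absent <- setdiff(samples, all_samples)
    if (length(absent))
      stop("requested sample(s) absent from VCF: ",
           paste(absent, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
    all_samples <- samples
  }
  # strip phasing, then count ALT alleles; anything not a clean diploid
  # 0/0, 0/1, 1/0, 1/1 call (half-calls, ./., haploid) becomes missing
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  dosage[gt_clean == "0/0"] <- 0L
  dosage[gt_clean %in% c("0/1", "1/0")] <- 1L
  dosage[gt_clean == "1/1"] <- 2L

  contig <- fix[is_snp, "CHROM"]
  position <- as.integer(fix[is_snp, "POS"])
  ord <- order(contig, position)
  st <- site_table(contig[ord], position[ord],
                   ref[is_snp][ord], alt[is_snp][ord],
                   dosage[ord, , drop = FALSE], all_samples)
  attr(st, "skipped_records") <- n_skip
  st
}

#' Write a SiteTable as plain-text VCFv4.2
#'
#' Emits biallelic SNP records with a GT-only FORMAT, unphased diploid
#' calls, and `./.` for missing genotypes, plus contig header lines.
#'
#' @param sites a \code{\link{site_table}}.
#' @param path output file path.
#' @param contig_lengths optional named vector for the contig header
#'   lines; defaults to each contig's largest position.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, path, contig_lengths = NULL) {
  stopifnot(inherits(sites, "site_table"))
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(sites$position, sites$contig, max)
  }
  contigs <- unique(sites$contig)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    sprintf("##contig=<ID=%s,length=%d>", contigs,
            as.integer(contig_lengths[contigs])),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", sites$samples), collapse = "\t")
  )
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix(gt_code[as.character(sites$dosage)],
               nrow = n_sites(sites))
  gt[is.na(gt)] <- "./."
  body <- paste(
    sites$contig, sites$position, ".", sites$ref, sites$alt, ".",
    "PASS", ".", "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample-to-population map from TSV
#'
#' Expects two columns (sample, population), with or without a header
#' line naming them. Duplicate samples are an error; population label
#' order is recorded by first occurrence.
#'
#' @param path a tab-separated two-column file.
#' @return a \code{\link{population_map}}.
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) stop("population map not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  has_header <- identical(tolower(first[1:2]),
                          c("sample", "population"))
  tab <- read.table(path, sep = "\t", header = has_header,
                    colClasses = "character",
                    col.names = c("sample", "population"))
  if (ncol(tab) != 2L)
    stop("population map must have exactly two columns")
  population_map(tab$sample, tab$population)
}

#' Write a population map as TSV
#' @param popmap a \code{\link{population_map}}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_population_map <- function(popmap, path) {
  write.table(as.data.frame(popmap)[, c("sample", "population")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene intervals from BED or GFF3
#'
#' BED input (0-based half-open) is shifted to the package's internal
#' 1-based inclusive convention; GFF3 input (1-based inclusive, records
#' with type `gene` kept) is used as-is. The dialect is detected from
#' the file extension and can be forced with `format`. Overlapping genes
#' are preserved as-is (no merging).
#'
#' @param path a BED3+ (4th column = gene id) or GFF3 file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return a gene `data.frame`: `gene_id`, `contig`, `start`, `end`,
#'   `strand`, sorted by (contig, start); gene ids are unique.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     bed = "bed",
                     gff = "gff3", gff3 = "gff3",
                     stop("cannot infer annotation format from '.", ext,
                          "'; pass format = \"bed\" or \"gff3\""))
  }
  if (format == "bed") {
    gr <- tryCatch(
      rtracklayer::import(path, format = "BED"),
      error = function(e) stop("failed to parse BED file ", path, ": ",
                               conditionMessage(e)))
    ids <- S4Vectors::mcols(gr)$name
    if (is.null(ids) || anyNA(ids))
      ids <- sprintf("gene%04d", seq_along(gr))
    strand <- as.character(GenomicRanges::strand(gr))
  } else {
    gr <- tryCatch(
      rtracklayer::import(path, format = "GFF3"),
      error = function(e) stop("failed to parse GFF3 file ", path, ": ",
                               conditionMessage(e)))
    keep <- S4Vectors::mcols(gr)$type %in% c("gene")
    if (any(keep)) gr <- gr[keep]
    m <- S4Vectors::mcols(gr)
    ids <- m$ID %||% m$Name %||% m$gene_id %||%
      sprintf("gene%04d", seq_along(gr))
    ids[is.na(ids)] <- sprintf("gene%04d", which(is.na(ids)))
    strand <- as.character(GenomicRanges::strand(gr))
  }
  out <- data.frame(
    gene_id = as.character(ids),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = ifelse(strand == "*", NA_character_, strand),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene id(s) in annotation: ",
         paste(unique(out$gene_id[duplicated(out$gene_id)]),
               collapse = ", "))
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write regions as BED (0-based half-open)
#'
#' The internal 1-based inclusive coordinates are converted at this
#' boundary: start becomes start - 1, end stays.
#'
#' @param regions a region or gene `data.frame` with `contig`, `start`,
#'   `end` and optionally a name column (`source` or `gene_id`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  name <- regions$gene_id %||% regions$source %||% rep(".", nrow(regions))
  name[is.na(name)] <- "."
  lines <- paste(regions$contig, regions$start - 1L, regions$end, name,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-variant effect table from TSV
#'
#' A consequence-annotation table (e.g. exported from a variant effect
#' predictor) with columns `contig`, `position`, `gene_id`,
#' `consequence`. Unknown consequence labels are kept verbatim;
#' duplicated rows are kept (deduplication is the caller's choice).
#'
#' @param path a TSV with a header naming at least the four required
#'   columns.
#' @return a `data.frame` with the four columns, types enforced.
#' @export
read_variant_effects <- function(path) {
  if (!file.exists(path)) stop("effect table not found: ", path)
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = "character")
  required <- c("contig", "position", "gene_id", "consequence")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("effect table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  tab <- tab[, required, drop = FALSE]
  tab$position <- as.integer(tab$position)
  tab
}

#' Read a gene-to-term map from TSV
#'
#' Two columns (term, gene_id), with or without a header.
#'
#' @param path a two-column TSV.
#' @return a `data.frame` with columns `term`, `gene_id`.
#' @export
read_term_map <- function(path) {
  if (!file.exists(path)) stop("term map not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  has_header <- identical(tolower(first[1:2]), c("term", "gene_id"))
  tab <- read.table(path, sep = "\t", header = has_header,
                    colClasses = "character",
                    col.names = c("term", "gene_id"))
  tab
}

#' Write a data frame as TSV with a header
#' @param x a `data.frame`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
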