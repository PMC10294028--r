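#' Construct a SiteTable of biallelic SNP genotype dosages
#'
#' The central genotype container: one row per biallelic SNP site, one
#' column per diploid sample, entries counting copies of the ALT allele
#' (0, 1, 2) with `NA` for missing genotypes. Site metadata (contig,
#' 1-based position, REF and ALT alleles) travels alongside the matrix.
#'
#' @param contig character vector of contig names, one per site.
#' @param position integer vector of 1-based positions, strictly
#'   increasing within each contig.
#' @param ref,alt single-base REF and ALT alleles per site.
#' @param dosage integer matrix, sites x samples, values in {0,1,2,NA}.
#' @param samples character vector of sample identifiers (column names).
#'
#' @return An object of class `site_table`: a list with elements
#'   `contig`, `position`, `ref`, `alt`, `dosage`, `samples`.
#' @export
#' @examples
#' st <- site_table(
#'   contig = c("chr1", "chr1"), position = c(100L, 200L),
#'   ref = c("A", "C"), alt = c("G", "T"),
#'   dosage = matrix(c(0L, 1L, 2L, NA), nrow = 2),
#'   samples = c("s1", "s2")
#' )
#' n_sites(st)
site_table <- function(contig, position, ref, alt, dosage, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n <- length(position)
  stopifnot(
    length(contig) == n, length(ref) == n, length(alt) == n,
    nrow(dosage) == n, ncol(dosage) == length(samples),
    !anyDuplicated(samples)
  )
  position <- as.integer(position)
  if (any(!dosage %in% c(0L, 1L, 2L) & !is.na(dosage)))
    stop("dosage values must be 0, 1, 2 or NA")
  for (ctg in unique(contig)) {
    p <- position[contig == ctg]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within contig ", ctg)
  }
  dimnames(dosage) <- list(NULL, samples)
  structure(
    list(contig = as.character(contig), position = position,
         ref = as.character(ref), alt = as.character(alt),
         dosage = dosage, samples = as.character(samples)),
    class = "site_table"
  )
}

#' @export
print.site_table <- function(x, ...) {
  cat("<site_table> ", n_sites(x), " biallelic SNP sites x ",
      length(x$samples), " samples\n", sep = "")
  cat("  contigs: ", paste(unique(x$contig), collapse = ", "), "\n", sep = "")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of sites in a SiteTable
#' @param x a `site_table`.
#' @return integer site count.
#' @export
n_sites <- function(x) {
  stopifnot(inherits(x, "site_table"))
  length(x$position)
}

#' Subset a SiteTable by site index and/or sample
#'
#' @param x a `site_table`.
#' @param sites integer or logical index over sites.
#' @param samples character vector of sample ids to keep, or NULL for all.
#' @return a `site_table`.
#' @export
subset_sites <- function(x, sites = NULL, samples = NULL) {
  stopifnot(inherits(x, "site_table"))
  if (is.null(sites)) sites <- seq_along(x$position)
  keep_samples <- x$samples
  if (!is.null(samples)) {
    absent <- setdiff(samples, x$samples)
    if (length(absent))
      stop("requested sample(s) absent from genotypes: ",
           paste(absent, collapse = ", "))
    keep_samples <- samples
  }
  site_table(
    contig = x$contig[sites], position = x$position[sites],
    ref = x$ref[sites], alt = x$alt[sites],
    dosage = x$dosage[sites, keep_samples, drop = FALSE],
    samples = keep_samples
  )
}

#' Drop sites on blocklisted contigs
#'
#' Sweep scans of autosomal directional selection conventionally exclude
#' sex chromosomes; this removes any site whose contig is blocklisted.
#'
#' @param x a `site_table`.
#' @param contigs character vector of contig names to exclude
#'   (e.g. `c("chrX", "X")`).
#' @return a `site_table` without the excluded contigs.
#' @export
exclude_contigs <- function(x, contigs) {
  stopifnot(inherits(x, "site_table"))
  subset_sites(x, sites = !(x$contig %in% contigs))
}

#' Construct a sample-to-population map
#'
#' @param sample character vector of sample ids (no duplicates).
#' @param population character vector of population labels, parallel to
#'   `sample`. Label order is recorded by first occurrence.
#' @return a `data.frame` with columns `sample`, `population`, of class
#'   `c("population_map", "data.frame")`.
#' @export
population_map <- function(sample, population) {
  stopifnot(length(sample) == length(population))
  if (anyDuplicated(sample))
    stop("duplicate sample id(s) in population map: ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "))
  out <- data.frame(sample = as.character(sample),
                    population = as.character(population),
                    stringsAsFactors = FALSE)
  attr(out, "population_order") <- unique(out$population)
  class(out) <- c("population_map", "data.frame")
  out
}

#' Population labels in first-occurrence order
#' @param popmap a `population_map`.
#' @return character vector of the distinct population labels.
#' @export
population_levels <- function(popmap) {
  attr(popmap, "population_order") %||% unique(popmap$population)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample ids belonging to one population
#' @param popmap a `population_map`.
#' @param population a population label present in the map.
#' @return character vector of sample ids.
#' @export
population_samples <- function(popmap, population) {
  if (!population %in% popmap$population)
    stop("population '", population, "' not present in map")
  popmap$sample[popmap$population == population]
}

# Check a popmap against a site_table for a two-population scan.
check_two_populations <- function(sites, popmap) {
  unmapped <- setdiff(sites$samples, popmap$sample)
  if (length(unmapped))
    stop("sample(s) missing from population map: ",
         paste(unmapped, collapse = ", "))
  pops <- population_levels(popmap)
  pops <- pops[pops %in% popmap$population[popmap$sample %in% sites$samples]]
  if (length(pops) != 2L)
    stop("a scan needs exactly two populations; map provides ",
         length(pops), " (", paste(pops, collapse = ", "), ")")
  pops
}

#' Construct a genomic region table
#'
#' Regions use 1-based inclusive coordinates throughout the package
#' (converted from/to BED's 0-based half-open convention only at file
#' boundaries).
#'
#' @param contig,start,end parallel vectors describing the intervals.
#' @param source evidence label, e.g. `"hp_tail"`, `"fst_tail"`,
#'   `"intersection"`, `"truth"`.
#' @param n_windows integer count of member windows (NA when unknown).
#' @return a `data.frame` with columns `contig`, `start`, `end`,
#'   `source`, `n_windows`, sorted by (contig, start).
#' @export
region_table <- function(contig = character(), start = integer(),
                         end = integer(), source = NA_character_,
                         n_windows = NA_integer_) {
  n <- length(contig)
  out <- data.frame(contig = as.character(contig),
                    start = as.integer(start), end = as.integer(end),
                    source = rep_len(as.character(source), n),
                    n_windows = rep_len(as.integer(n_windows), n),
                    stringsAsFactors = FALSE)
  if (n && any(out$end < out$start)) stop("region end < start")
  out[order(out$contig, out$start), , drop = FALSE]
}

# Internal: region data.frame <-> GRanges
regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$contig,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end)
  )
}

granges_to_regions <- function(gr, source = NA_character_,
                               n_windows = NA_integer_) {
  region_table(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    source = source, n_windows = n_windows
  )
}
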