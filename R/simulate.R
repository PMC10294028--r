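#' Configuration for the two-population genotype simulator
#'
#' Defines the study conditions the simulator emulates: two diploid
#' populations of unequal size (default 12 wild vs 59 domestic) sharing
#' an ancestral allele-frequency spectrum, with population-specific drift
#' (Balding-Nichols model) producing genome-wide background
#' differentiation, and contiguous sweep regions in which the domestic
#' population is driven to near-fixation.
#'
#' @param genome_length_bp total genome length in bp, split evenly over
#'   `n_contigs`.
#' @param n_contigs number of contigs ("chr1", "chr2", ...).
#' @param snp_density expected SNPs per bp (sites are dropped uniformly
#'   at this density along each contig).
#' @param n_wild,n_domestic diploid sample counts per population.
#' @param fst_background Balding-Nichols drift coefficient F in (0,1).
#'   Either a single value used for both populations or a named vector
#'   `c(wild = , domestic = )`. The default gives the domestic population
#'   stronger drift, so its nucleotide diversity is lower than the wild
#'   population's, as in domestication contrasts.
#' @param sweep_regions a `data.frame` with columns `contig`, `start`,
#'   `end` (1-based inclusive) of planted sweep intervals; they must lie
#'   within contig bounds and not overlap one another. `NULL` for none.
#' @param sweep_domestic_freq target ALT-allele frequency in the domestic
#'   population inside sweep regions (near 0 or 1); per-site frequencies
#'   are drawn from a Beta distribution tightly concentrated there.
#' @param missing_rate independent per-genotype missingness probability
#'   in [0, 1).
#' @param ld_mode `"none"` (sites independent, Hardy-Weinberg within
#'   populations) or `"block"` (founder-haplotype mosaic copying, giving
#'   LD that decays with distance; used for LD-curve testing).
#' @param n_founders founder haplotypes per population in block mode.
#' @param block_length_bp expected ancestry-switch distance in block mode.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return a validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(genome_length_bp = 1e6, seed = 1)
#' cfg$n_domestic
sim_config <- function(genome_length_bp = 30e6,
                       n_contigs = 1L,
                       snp_density = 1 / 500,
                       n_wild = 12L,
                       n_domestic = 59L,
                       fst_background = c(wild = 0.05, domestic = 0.15),
                       sweep_regions = NULL,
                       sweep_domestic_freq = 0.99,
                       missing_rate = 0.02,
                       ld_mode = c("none", "block"),
                       n_founders = 10L,
                       block_length_bp = 50000L,
                       seed = 1L) {
  ld_mode <- match.arg(ld_mode)
  genome_length_bp <- as.numeric(genome_length_bp)
  n_contigs <- as.integer(n_contigs)
  stopifnot(
    genome_length_bp >= 1, n_contigs >= 1L, snp_density > 0,
    n_wild >= 1L, n_domestic >= 1L,
    missing_rate >= 0, missing_rate < 1,
    sweep_domestic_freq >= 0, sweep_domestic_freq <= 1,
    n_founders >= 2L, block_length_bp >= 1L
  )
  if (length(fst_background) == 1L)
    fst_background <- c(wild = unname(fst_background),
                        domestic = unname(fst_background))
  if (!all(c("wild", "domestic") %in% names(fst_background)))
    names(fst_background) <- c("wild", "domestic")
  if (any(fst_background <= 0) || any(fst_background >= 1))
    stop("fst_background must lie strictly in (0, 1)")
  contig_len <- floor(genome_length_bp / n_contigs)
  contig_lengths <- setNames(rep(contig_len, n_contigs),
                             paste0("chr", seq_len(n_contigs)))
  if (!is.null(sweep_regions)) {
    sweep_regions <- region_table(sweep_regions$contig, sweep_regions$start,
                                  sweep_regions$end, source = "truth")
    bad_contig <- setdiff(sweep_regions$contig, names(contig_lengths))
    if (length(bad_contig))
      stop("sweep region on unknown contig: ",
           paste(bad_contig, collapse = ", "))
    if (any(sweep_regions$start < 1) ||
        any(sweep_regions$end > contig_lengths[sweep_regions$contig]))
      stop("sweep regions must lie within contig bounds")
    by_contig <- split(sweep_regions, sweep_regions$contig)
    for (rg in by_contig) {
      if (nrow(rg) > 1L && any(rg$start[-1L] <= rg$end[-nrow(rg)]))
        stop("sweep regions must not overlap each other")
    }
  }
  structure(
    list(genome_length_bp = genome_length_bp, n_contigs = n_contigs,
         contig_lengths = contig_lengths, snp_density = snp_density,
         n_wild = as.integer(n_wild), n_domestic = as.integer(n_domestic),
         fst_background = fst_background, sweep_regions = sweep_regions,
         sweep_domestic_freq = sweep_domestic_freq,
         missing_rate = missing_rate, ld_mode = ld_mode,
         n_founders = as.integer(n_founders),
         block_length_bp = as.integer(block_length_bp),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default planted sweep layout
#'
#' Evenly spaced sweep intervals of a fixed width on the first contig of
#' a config's genome — the standard layout for parameter-recovery
#' experiments (10 sweeps of 300 kb on a 30 Mb genome).
#'
#' @param config a `sim_config` (used for contig names and bounds).
#' @param n_sweeps number of sweep intervals.
#' @param sweep_length_bp width of each interval in bp.
#' @return a region `data.frame` suitable for `sim_config(sweep_regions=)`.
#' @export
default_sweep_layout <- function(config, n_sweeps = 10L,
                                 sweep_length_bp = 300000L) {
  contig <- names(config$contig_lengths)[1L]
  len <- config$contig_lengths[[1L]]
  if (n_sweeps * sweep_length_bp > len)
    stop("sweeps do not fit on the first contig")
  gap <- floor((len - n_sweeps * sweep_length_bp) / (n_sweeps + 1))
  starts <- gap * seq_len(n_sweeps) + sweep_length_bp * (seq_len(n_sweeps) - 1L) + 1
  region_table(contig = rep(contig, n_sweeps), start = starts,
               end = starts + sweep_length_bp - 1L, source = "truth")
}

# Draw Balding-Nichols population frequencies: Beta(p(1-F)/F, (1-p)(1-F)/F)
rbalding_nichols <- function(p, f) {
  shape_scale <- (1 - f) / f
  rbeta(length(p), p * shape_scale, (1 - p) * shape_scale)
}

#' Simulate a two-population genotype dataset with planted sweeps
#'
#' SNP positions are dropped along each contig at the configured density.
#' Each site receives an ancestral ALT frequency p ~ Uniform(0.05, 0.95),
#' then per-population frequencies from the Balding-Nichols Beta with the
#' population's drift coefficient F. Inside planted sweep regions the
#' domestic frequency is replaced by a draw tightly concentrated at
#' `sweep_domestic_freq`. Genotypes are Binomial(2, p_pop) per diploid
#' individual (Hardy-Weinberg within populations) and masked missing
#' independently at `missing_rate`. With `ld_mode = "block"` genotypes
#' instead come from founder-haplotype mosaics, producing LD that decays
#' with distance.
#'
#' @param config a `sim_config`.
#' @return a list with elements:
#'   \describe{
#'     \item{sites}{a \code{\link{site_table}} of all simulated SNPs}
#'     \item{popmap}{a \code{\link{population_map}} with labels
#'       `"wild"` and `"domestic"`}
#'     \item{truth}{a `simulation_truth`: the planted sweep regions plus
#'       the generating config}
#'   }
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(genome_length_bp = 2e5, seed = 42))
#' sim$sites
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_w <- config$n_wild
  n_d <- config$n_domestic
  samples <- c(sprintf("wild_%02d", seq_len(n_w)),
               sprintf("dom_%02d", seq_len(n_d)))
  popmap <- population_map(samples,
                           c(rep("wild", n_w), rep("domestic", n_d)))

  contigs <- names(config$contig_lengths)
  pos_list <- lapply(contigs, function(ctg) {
    len <- config$contig_lengths[[ctg]]
    n_snp <- rbinom(1L, len, min(1, config$snp_density))
    sort(sample.int(len, n_snp))
  })
  contig_vec <- rep(contigs, lengths(pos_list))
  position <- unlist(pos_list, use.names = FALSE)
  n_site <- length(position)
  if (n_site == 0L) stop("no SNPs simulated; raise snp_density or genome size")

  bases <- c("A", "C", "G", "T")
  ref_i <- sample.int(4L, n_site, replace = TRUE)
  alt_i <- (ref_i - 1L + sample.int(3L, n_site, replace = TRUE)) %% 4L + 1L
  ref <- bases[ref_i]
  alt <- bases[alt_i]

  p_anc <- runif(n_site, 0.05, 0.95)
  p_wild <- rbalding_nichols(p_anc, config$fst_background[["wild"]])
  p_dom <- rbalding_nichols(p_anc, config$fst_background[["domestic"]])

  in_sweep <- rep(FALSE, n_site)
  if (!is.null(config$sweep_regions) && nrow(config$sweep_regions)) {
    rg <- config$sweep_regions
    for (i in seq_len(nrow(rg))) {
      in_sweep <- in_sweep | (contig_vec == rg$contig[i] &
                              position >= rg$start[i] &
                              position <= rg$end[i])
    }
    # near-fixation draw: Beta concentrated at the target frequency
    f <- config$sweep_domestic_freq
    conc <- 400
    n_sw <- sum(in_sweep)
    p_dom[in_sweep] <- rbeta(n_sw, f * conc + 1e-6, (1 - f) * conc + 1e-6)
  }

  if (config$ld_mode == "none") {
    g_wild <- matrix(rbinom(n_site * n_w, 2L, rep(p_wild, n_w)),
                     nrow = n_site)
    g_dom <- matrix(rbinom(n_site * n_d, 2L, rep(p_dom, n_d)),
                    nrow = n_site)
  } else {
    g_wild <- sim_block_genotypes(contig_vec, position, p_wild, n_w, config)
    g_dom <- sim_block_genotypes(contig_vec, position, p_dom, n_d, config)
  }
  dosage <- cbind(g_wild, g_dom)
  if (config$missing_rate > 0) {
    mask <- matrix(runif(length(dosage)) < config$missing_rate,
                   nrow = n_site)
    dosage[mask] <- NA_integer_
  }

  sites <- site_table(contig_vec, position, ref, alt, dosage, samples)
  truth <- structure(
    list(sweep_regions = config$sweep_regions %||%
           region_table(source = "truth"),
         config = config),
    class = "simulation_truth"
  )
  list(sites = sites, popmap = popmap, truth = truth)
}

# Founder-haplotype mosaic ("block copying"): each haploid genome copies a
# founder haplotype, switching to a random founder at Exponential(1/block)
# distances. Founder alleles are Bernoulli(p_site). Yields first-order LD.
sim_block_genotypes <- function(contig_vec, position, p_site, n_ind, config) {
  n_site <- length(position)
  founders <- matrix(rbinom(n_site * config$n_founders, 1L,
                            rep(p_site, config$n_founders)),
                     nrow = n_site)
  hap <- function() {
    h <- integer(n_site)
    for (ctg in unique(contig_vec)) {
      idx <- which(contig_vec == ctg)
      cur <- sample.int(config$n_founders, 1L)
      last_pos <- position[idx[1L]]
      for (i in idx) {
        d <- position[i] - last_pos
        p_switch <- 1 - exp(-d / config$block_length_bp)
        if (runif(1L) < p_switch) cur <- sample.int(config$n_founders, 1L)
        h[i] <- founders[i, cur]
        last_pos <- position[i]
      }
    }
    h
  }
  g <- matrix(0L, nrow = n_site, ncol = n_ind)
  for (j in seq_len(n_ind)) g[, j] <- hap() + hap()
  g
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("<simulation_truth> ", nrow(x$sweep_regions),
      " planted sweep region(s); seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate gene annotations and a gene-to-term map
#'
#' Tiles non-overlapping genes of fixed length over the simulated genome
#' (one gene every `gene_spacing_bp`, default twice the gene length) and
#' assigns each gene to zero or more functional terms at random, so the
#' annotation and enrichment stages can be exercised without a reference
#' annotation.
#'
#' @param config a `sim_config` (supplies contig names/lengths and seed).
#' @param gene_length_bp gene length in bp; must fit within a contig.
#' @param n_terms number of distinct terms; 0 gives an empty term map.
#' @param gene_spacing_bp distance between successive gene starts.
#' @param term_prob probability a given gene is annotated to a given term.
#' @return a list with `genes` (a gene `data.frame`: `gene_id`, `contig`,
#'   `start`, `end`, `strand`) and `term_map` (a `data.frame` with columns
#'   `term`, `gene_id`).
#' @export
simulate_annotations <- function(config, gene_length_bp = 10000L,
                                 n_terms = 20L,
                                 gene_spacing_bp = 2L * gene_length_bp,
                                 term_prob = 0.05) {
  stopifnot(inherits(config, "sim_config"),
            gene_spacing_bp >= gene_length_bp, n_terms >= 0L)
  if (gene_length_bp >= min(config$contig_lengths))
    stop("gene_length_bp must be smaller than the contig length")
  set.seed(config$seed + 1L)
  genes <- do.call(rbind, lapply(names(config$contig_lengths), function(ctg) {
    len <- config$contig_lengths[[ctg]]
    starts <- seq(1L, len, by = gene_spacing_bp)
    starts <- starts[starts + gene_length_bp - 1L <= len]
    if (!length(starts)) return(NULL)
    data.frame(contig = ctg, start = as.integer(starts),
               end = as.integer(starts + gene_length_bp - 1L),
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$contig, genes$start), , drop = FALSE]
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(nrow(genes))),
    genes,
    strand = sample(c("+", "-"), nrow(genes), replace = TRUE),
    stringsAsFactors = FALSE
  )
  if (n_terms > 0L) {
    hits <- which(matrix(runif(nrow(genes) * n_terms) < term_prob,
                         nrow = nrow(genes)), arr.ind = TRUE)
    term_map <- data.frame(
      term = sprintf("TERM%03d", hits[, "col"]),
      gene_id = genes$gene_id[hits[, "row"]],
      stringsAsFactors = FALSE
    )
    term_map <- term_map[order(term_map$term, term_map$gene_id), ,
                         drop = FALSE]
    rownames(term_map) <- NULL
  } else {
    term_map <- data.frame(term = character(), gene_id = character(),
                           stringsAsFactors = FALSE)
  }
  list(genes = genes, term_map = term_map)
}

#' Score detected sweep regions against simulated truth
#'
#' Recall is the fraction of truth regions overlapped by at least 1 bp of
#' any detected region; precision is the fraction of detected regions
#' overlapping at least 1 bp of truth.
#'
#' @param detected a region `data.frame` (`contig`, `start`, `end`).
#' @param truth a `simulation_truth` or a region `data.frame` of true
#'   sweep intervals. Must be non-empty: recall against an empty truth is
#'   undefined and raises an error.
#' @return a list with `recall`, `precision` (NA when no regions were
#'   detected), `n_truth`, `n_detected`.
#' @export
#' @examples
#' truth <- region_table("chr1", 1, 100)
#' det <- region_table(c("chr1", "chr1"), c(90, 300), c(200, 400))
#' evaluate_detection(det, truth) # recall 1, precision 0.5
evaluate_detection <- function(detected, truth) {
  if (inherits(truth, "simulation_truth")) truth <- truth$sweep_regions
  if (is.null(truth) || nrow(truth) == 0L)
    stop("truth region set is empty: recall is undefined")
  if (nrow(detected) == 0L) {
    return(list(recall = 0, precision = NA_real_,
                n_truth = nrow(truth), n_detected = 0L))
  }
  gr_t <- regions_to_granges(truth)
  gr_d <- regions_to_granges(detected)
  ov <- GenomicRanges::countOverlaps(gr_t, gr_d, minoverlap = 1L)
  ov_d <- GenomicRanges::countOverlaps(gr_d, gr_t, minoverlap = 1L)
  list(recall = mean(ov > 0), precision = mean(ov_d > 0),
       n_truth = nrow(truth), n_detected = nrow(detected))
}
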