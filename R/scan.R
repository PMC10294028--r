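#' Configuration for a sweep scan
#'
#' @param window_size_bp sliding window size in bp (default 150 kb).
#' @param step_bp step between window starts (default 50 kb; must not
#'   exceed the window size).
#' @param z_cutoff positive normal-quantile cutoff on the Z-transformed
#'   window statistics. The default 2.326 is the upper 1% quantile:
#'   windows with Z(Hp) < -2.326 or Z(Fst) > 2.326 are called.
#' @param min_snps_per_window windows with fewer SNPs are excluded before
#'   the Z-transformation (sparse windows have high-variance Hp/Fst and
#'   would dominate the tails artifactually).
#' @param hp_population population whose Hp enters the Hp tail test;
#'   `NULL` picks the second population in map order, the conventional
#'   slot for the domestic/selected population.
#' @param fst_method window Fst summary: `"mean_site"` (default) or
#'   `"ratio_of_averages"` (see \code{\link{window_fst}}).
#' @param fst_weighting `"unweighted"` (default) or `"weighted"` per-site
#'   population weighting (see \code{\link{site_fst}}).
#' @param exclude_contigs contigs dropped before scanning (e.g. a sex
#'   chromosome when targeting autosomal selection). Default `c("chrX",
#'   "X")`.
#' @return a list of class `scan_config`.
#' @export
scan_config <- function(window_size_bp = 150000L, step_bp = 50000L,
                        z_cutoff = 2.326, min_snps_per_window = 10L,
                        hp_population = NULL,
                        fst_method = c("mean_site", "ratio_of_averages"),
                        fst_weighting = c("unweighted", "weighted"),
                        exclude_contigs = c("chrX", "X")) {
  stopifnot(window_size_bp >= 1L, step_bp >= 1L,
            step_bp <= window_size_bp, z_cutoff > 0,
            min_snps_per_window >= 0L)
  structure(
    list(window_size_bp = as.integer(window_size_bp),
         step_bp = as.integer(step_bp), z_cutoff = z_cutoff,
         min_snps_per_window = as.integer(min_snps_per_window),
         hp_population = hp_population,
         fst_method = match.arg(fst_method),
         fst_weighting = match.arg(fst_weighting),
         exclude_contigs = exclude_contigs),
    class = "scan_config"
  )
}

#' Generate sliding-window shells over contigs
#'
#' Windows start at 1, 1 + step, 1 + 2*step, ... and only windows lying
#' entirely inside the contig are emitted; a partial trailing window is
#' dropped, not clipped, so every window has the same span. Contigs
#' shorter than one window contribute no windows.
#'
#' @param contig_lengths named numeric vector, contig -> length in bp.
#' @param config a \code{\link{scan_config}}.
#' @return a `data.frame`: `contig`, `start`, `end` (1-based inclusive),
#'   ordered by (contig, start).
#' @export
#' @examples
#' make_windows(c(chr1 = 250000), scan_config())
make_windows <- function(contig_lengths, config = scan_config()) {
  stopifnot(all(contig_lengths > 0), !is.null(names(contig_lengths)))
  out <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    if (len < config$window_size_bp)
      return(data.frame(contig = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    starts <- seq(1L, len - config$window_size_bp + 1L,
                  by = config$step_bp)
    data.frame(contig = ctg, start = as.integer(starts),
               end = as.integer(starts + config$window_size_bp - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Assign sites to windows
#'
#' A site belongs to every window whose [start, end] contains its
#' position; with overlapping windows a site is shared by several.
#'
#' @param windows window `data.frame` from \code{\link{make_windows}}.
#' @param sites a \code{\link{site_table}}.
#' @return `windows` with an added `n_snps` column and an attribute
#'   `site_index`: a list (one element per window) of member site rows.
#' @export
assign_sites <- function(windows, sites) {
  stopifnot(inherits(sites, "site_table"))
  gr_w <- GenomicRanges::GRanges(
    windows$contig, IRanges::IRanges(windows$start, windows$end))
  gr_s <- GenomicRanges::GRanges(
    sites$contig, IRanges::IRanges(sites$position, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_w, gr_s)
  idx <- split(S4Vectors::subjectHits(hits),
               factor(S4Vectors::queryHits(hits),
                      levels = seq_len(nrow(windows))))
  idx <- lapply(idx, as.integer)
  windows$n_snps <- lengths(idx)
  attr(windows, "site_index") <- unname(idx)
  windows
}

#' Per-window population-genetic statistics
#'
#' Computes, for every window: SNP count, pooled heterozygosity Hp per
#' population, window Fst between the two populations, and nucleotide
#' diversity pi per population.
#'
#' @param sites a \code{\link{site_table}} (two-population data).
#' @param popmap a \code{\link{population_map}} covering all samples and
#'   using exactly two labels.
#' @param config a \code{\link{scan_config}}.
#' @param contig_lengths optional named vector of contig lengths; when
#'   omitted, each contig's largest site position is used.
#' @return a `data.frame` with one row per window: `contig`, `start`,
#'   `end`, `n_snps`, `hp_<pop1>`, `hp_<pop2>`, `fst`, `pi_<pop1>`,
#'   `pi_<pop2>`, plus `z_hp` and `z_fst` columns initialised to NA
#'   (populated by \code{\link{sweep_scan}}).
#' @export
window_stats <- function(sites, popmap, config = scan_config(),
                         contig_lengths = NULL) {
  stopifnot(inherits(sites, "site_table"))
  sites <- exclude_contigs(sites, config$exclude_contigs)
  pops <- check_two_populations(sites, popmap)
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(sites$position, sites$contig, max)
    contig_lengths <- setNames(as.numeric(contig_lengths),
                               names(contig_lengths))
  }
  windows <- make_windows(contig_lengths, config)
  windows <- assign_sites(windows, sites)
  site_idx <- attr(windows, "site_index")

  st1 <- pop_site_stats(sites, intersect(
    population_samples(popmap, pops[1]), sites$samples))
  st2 <- pop_site_stats(sites, intersect(
    population_samples(popmap, pops[2]), sites$samples))
  comp <- fst_components_vec(st1$p_alt, st2$p_alt, st1$n_chr, st2$n_chr,
                             config$fst_weighting)

  agg <- function(i) {
    w1 <- pooled_het_quiet(st1$n_maj[i], st1$n_min[i])
    w2 <- pooled_het_quiet(st2$n_maj[i], st2$n_min[i])
    fst <- if (config$fst_method == "mean_site") {
      f <- comp$fst[i]
      if (all(is.na(f))) NA_real_ else mean(f, na.rm = TRUE)
    } else {
      keep <- !is.na(comp$h_t[i]) & comp$h_t[i] > 0
      if (!any(keep)) NA_real_ else {
        ht <- comp$h_t[i][keep]; hs <- comp$h_s[i][keep]
        (mean(ht) - mean(hs)) / mean(ht)
      }
    }
    c(w1, w2, fst,
      nucleotide_diversity(st1$n_maj[i], st1$n_min[i], st1$n_chr[i],
                           config$window_size_bp),
      nucleotide_diversity(st2$n_maj[i], st2$n_min[i], st2$n_chr[i],
                           config$window_size_bp))
  }
  vals <- vapply(site_idx, agg, numeric(5))
  out <- data.frame(windows[, c("contig", "start", "end", "n_snps")],
                    hp1 = vals[1, ], hp2 = vals[2, ], fst = vals[3, ],
                    pi1 = vals[4, ], pi2 = vals[5, ],
                    z_hp = NA_real_, z_fst = NA_real_,
                    stringsAsFactors = FALSE)
  names(out)[names(out) == "hp1"] <- paste0("hp_", pops[1])
  names(out)[names(out) == "hp2"] <- paste0("hp_", pops[2])
  names(out)[names(out) == "pi1"] <- paste0("pi_", pops[1])
  names(out)[names(out) == "pi2"] <- paste0("pi_", pops[2])
  attr(out, "populations") <- pops
  rownames(out) <- NULL
  out
}

# Hp without the empty-window warning (empty -> NA silently); used in
# bulk aggregation where empty windows are expected and filtered later.
pooled_het_quiet <- function(n_maj, n_min) {
  keep <- !is.na(n_maj) & !is.na(n_min)
  if (!any(keep)) return(NA_real_)
  s_maj <- sum(n_maj[keep]); s_min <- sum(n_min[keep])
  2 * s_maj * s_min / (s_maj + s_min)^2
}

#' Z-transform a genome-wide window statistic
#'
#' Standardises to mean 0, sample standard deviation 1 (denominator
#' n - 1), computed jointly over all supplied windows. A constant vector
#' has no tails and raises an error.
#'
#' @param values numeric vector (all retained windows genome-wide).
#' @return numeric vector of Z-scores.
#' @export
#' @examples
#' z_transform(c(1, 2, 3)) # -1 0 1
z_transform <- function(values) {
  values <- as.numeric(values)
  if (sum(is.finite(values)) < 2L)
    stop("Z-transformation needs at least two finite values")
  s <- sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("Z-transformation undefined for zero-spread values")
  (values - mean(values, na.rm = TRUE)) / s
}

#' Call extreme-tail outlier windows
#'
#' Windows with Z(Hp) strictly below `-z_cutoff` form the low-diversity
#' (Hp) tail; windows with Z(Fst) strictly above `+z_cutoff` form the
#' high-differentiation (Fst) tail. Boundary values are not selected.
#'
#' @param windows a window `data.frame` with populated `z_hp`, `z_fst`.
#' @param config a \code{\link{scan_config}}.
#' @return a list `(hp_windows, fst_windows)` of window subsets.
#' @export
call_outlier_windows <- function(windows, config = scan_config()) {
  stopifnot(all(c("z_hp", "z_fst") %in% names(windows)))
  list(
    hp_windows = windows[!is.na(windows$z_hp) &
                           windows$z_hp < -config$z_cutoff, , drop = FALSE],
    fst_windows = windows[!is.na(windows$z_fst) &
                            windows$z_fst > config$z_cutoff, , drop = FALSE]
  )
}

#' Merge selected windows into regions
#'
#' Windows on one contig that overlap or abut (0 bp gap) are merged into
#' a single region spanning their union; the number of member windows is
#' recorded. Merging is idempotent.
#'
#' @param selected a window or region `data.frame` (`contig`, `start`,
#'   `end`).
#' @param source evidence label stored in the output.
#' @return a region `data.frame` (see \code{\link{region_table}}),
#'   non-overlapping and sorted.
#' @export
merge_windows <- function(selected, source = NA_character_) {
  if (nrow(selected) == 0L)
    return(region_table(source = source))
  gr <- regions_to_granges(selected)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 1L, with.revmap = TRUE)
  granges_to_regions(
    red, source = source,
    n_windows = lengths(S4Vectors::mcols(red)$revmap)
  )
}

#' Intersect two region sets
#'
#' The genomic intersection: every maximal interval covered by both
#' inputs. Inputs must each be internally non-overlapping.
#'
#' @param a,b region `data.frame`s.
#' @return a region `data.frame` with `source = "intersection"`.
#' @export
#' @examples
#' intersect_region_sets(region_table("chr1", 1, 200000),
#'                       region_table("chr1", 150001, 300000))
intersect_region_sets <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(region_table(source = "intersection"))
  gr <- GenomicRanges::intersect(regions_to_granges(a),
                                 regions_to_granges(b))
  granges_to_regions(gr, source = "intersection")
}

#' Run a full sweep scan
#'
#' Computes window statistics, excludes windows below the SNP-count
#' threshold, Z-transforms the Hp track of the target population and the
#' Fst track jointly across all retained windows, calls extreme-tail
#' windows at the configured cutoff, merges each tail into regions, and
#' intersects the two evidence tracks into the final candidate sweep
#' regions.
#'
#' @inheritParams window_stats
#' @return a list of class `sweep_scan_result`:
#'   \describe{
#'     \item{windows}{retained windows with `z_hp`, `z_fst` populated}
#'     \item{excluded_windows}{count dropped for low SNP count}
#'     \item{hp_regions, fst_regions}{merged regions per evidence tail}
#'     \item{regions}{their intersection — the candidate sweep regions}
#'     \item{config, populations, hp_population}{scan provenance}
#'   }
#' @export
#' @examples
#' cfg <- sim_config(genome_length_bp = 3e6, seed = 7,
#'                   sweep_regions = data.frame(contig = "chr1",
#'                                              start = 1e6, end = 1.3e6))
#' sim <- simulate_dataset(cfg)
#' res <- sweep_scan(sim$sites, sim$popmap)
#' res$regions
sweep_scan <- function(sites, popmap, config = scan_config(),
                       contig_lengths = NULL) {
  w <- window_stats(sites, popmap, config, contig_lengths)
  pops <- attr(w, "populations")
  hp_pop <- config$hp_population %||% pops[2]
  if (!hp_pop %in% pops)
    stop("hp_population '", hp_pop, "' is not one of the scanned ",
         "populations (", paste(pops, collapse = ", "), ")")
  hp_col <- paste0("hp_", hp_pop)

  keep <- w$n_snps >= config$min_snps_per_window &
    !is.na(w[[hp_col]]) & !is.na(w$fst)
  excluded <- sum(!keep)
  w <- w[keep, , drop = FALSE]
  if (nrow(w) < 2L)
    stop("fewer than two windows retained; genome too small for the ",
         "window/step configuration")
  w$z_hp <- z_transform(w[[hp_col]])
  w$z_fst <- z_transform(w$fst)
  rownames(w) <- NULL

  tails <- call_outlier_windows(w, config)
  hp_regions <- merge_windows(tails$hp_windows, source = "hp_tail")
  fst_regions <- merge_windows(tails$fst_windows, source = "fst_tail")
  regions <- intersect_region_sets(hp_regions, fst_regions)

  structure(
    list(windows = w, excluded_windows = excluded,
         hp_regions = hp_regions, fst_regions = fst_regions,
         regions = regions, config = config, populations = pops,
         hp_population = hp_pop),
    class = "sweep_scan_result"
  )
}

#' @export
print.sweep_scan_result <- function(x, ...) {
  cat("<sweep_scan_result>\n")
  cat("  populations: ", paste(x$populations, collapse = " vs "),
      " (Hp tail on ", x$hp_population, ")\n", sep = "")
  cat("  windows retained: ", nrow(x$windows),
      " (excluded for low SNP count or no data: ", x$excluded_windows,
      ")\n", sep = "")
  cat("  Hp-tail regions: ", nrow(x$hp_regions),
      ", Fst-tail regions: ", nrow(x$fst_regions),
      ", intersection: ", nrow(x$regions), "\n", sep = "")
  invisible(x)
}
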