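#' Per-site allele counts within one population
#'
#' Counts REF and ALT allele copies over the non-missing genotypes of one
#' population at one site, and classifies the within-population major and
#' minor allele. A tie (equal counts) is broken by calling the REF allele
#' major; pooled heterozygosity is invariant to the choice at a tied site.
#'
#' @param sites a \code{\link{site_table}}.
#' @param site integer site index (row of the table).
#' @param popmap a \code{\link{population_map}}.
#' @param population population label whose samples are counted.
#' @return a list of class `allele_counts`: `n_maj`, `n_min`, `n_called`
#'   (= n_maj + n_min, in allele copies), `n_ref`, `n_alt`, and `no_data`
#'   (TRUE when zero genotypes were called — counts are then NA, not 0).
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(genome_length_bp = 1e5, seed = 3))
#' site_allele_counts(sim$sites, 1, sim$popmap, "wild")
site_allele_counts <- function(sites, site, popmap, population) {
  stopifnot(inherits(sites, "site_table"), length(site) == 1L)
  ids <- population_samples(popmap, population)
  ids <- intersect(ids, sites$samples)
  d <- sites$dosage[site, ids]
  called <- sum(!is.na(d))
  if (called == 0L) {
    return(structure(list(n_maj = NA_integer_, n_min = NA_integer_,
                          n_called = 0L, n_ref = NA_integer_,
                          n_alt = NA_integer_, no_data = TRUE),
                     class = "allele_counts"))
  }
  n_alt <- sum(d, na.rm = TRUE)
  n_ref <- 2L * called - n_alt
  n_maj <- if (n_alt > n_ref) n_alt else n_ref   # tie -> REF is major
  structure(list(n_maj = as.integer(n_maj),
                 n_min = as.integer(n_ref + n_alt - n_maj),
                 n_called = as.integer(n_ref + n_alt),
                 n_ref = as.integer(n_ref), n_alt = as.integer(n_alt),
                 no_data = FALSE),
            class = "allele_counts")
}

#' Within-population allele frequency at a site
#'
#' @inheritParams site_allele_counts
#' @param allele `"ref"` or `"alt"`: which allele's frequency to return.
#' @return frequency in [0, 1]; errors if no genotype is called.
#' @export
allele_frequency <- function(sites, site, popmap, population,
                             allele = c("alt", "ref")) {
  allele <- match.arg(allele)
  ac <- site_allele_counts(sites, site, popmap, population)
  if (ac$no_data)
    stop("no called genotypes at site ", site, " in population ", population)
  (if (allele == "alt") ac$n_alt else ac$n_ref) / ac$n_called
}

#' Pooled heterozygosity (Hp) of a window
#'
#' The Rubin-style window statistic
#' \deqn{H_p = \frac{2\,\Sigma n_{Maj}\,\Sigma n_{Min}}
#'   {(\Sigma n_{Maj} + \Sigma n_{Min})^2},}
#' where the sums run over the window's SNP sites and \eqn{n_{Maj}},
#' \eqn{n_{Min}} are the within-population major and minor allele counts
#' at each site. Hp lies in [0, 0.5]; low values flag diversity losses
#' consistent with a selective sweep.
#'
#' @param n_maj,n_min integer vectors of per-site major/minor allele
#'   counts (sites with no data may be NA and are dropped pairwise).
#' @return Hp in [0, 0.5], or NA (with a warning) for an empty window.
#' @export
#' @examples
#' pooled_heterozygosity(c(90, 70), c(10, 30)) # 2*160*40/200^2 = 0.32
pooled_heterozygosity <- function(n_maj, n_min) {
  stopifnot(length(n_maj) == length(n_min))
  keep <- !is.na(n_maj) & !is.na(n_min)
  if (!any(keep)) {
    warning("no sites with called data in window; Hp undefined")
    return(NA_real_)
  }
  s_maj <- sum(n_maj[keep])
  s_min <- sum(n_min[keep])
  2 * s_maj * s_min / (s_maj + s_min)^2
}

# Vectorized Fst components from per-population ALT frequencies.
# h_s: mean within-population expected heterozygosity, h_t: expected
# heterozygosity at the mean frequency. "weighted" weights the two
# populations by called chromosome counts instead of equally.
fst_components_vec <- function(p_a, p_b, n_a = NULL, n_b = NULL,
                               weighting = c("unweighted", "weighted")) {
  weighting <- match.arg(weighting)
  if (weighting == "unweighted" || is.null(n_a)) {
    w_a <- w_b <- 0.5
  } else {
    tot <- n_a + n_b
    w_a <- n_a / tot
    w_b <- n_b / tot
  }
  h_a <- 2 * p_a * (1 - p_a)
  h_b <- 2 * p_b * (1 - p_b)
  h_s <- w_a * h_a + w_b * h_b
  p_bar <- w_a * p_a + w_b * p_b
  h_t <- 2 * p_bar * (1 - p_bar)
  fst <- ifelse(h_t > 0, (h_t - h_s) / h_t, NA_real_)
  fst[is.na(p_a) | is.na(p_b)] <- NA_real_
  list(h_t = h_t, h_s = h_s, fst = fst)
}

#' Per-site fixation index between two populations
#'
#' The heterozygosity-based estimator
#' \deqn{F_{ST} = (H_T - H_S)/H_T,} where \eqn{H_S} is the mean
#' within-population expected heterozygosity \eqn{2p(1-p)} and \eqn{H_T}
#' the expected heterozygosity at the pooled (mean) ALT-allele frequency.
#' Populations are weighted equally by default; `weighting = "weighted"`
#' weights by called chromosome counts. Sites monomorphic in the pool
#' (\eqn{H_T = 0}) have undefined Fst and return NA.
#'
#' @param counts_a,counts_b `allele_counts` for the same site in the two
#'   populations (see \code{\link{site_allele_counts}}).
#' @param weighting `"unweighted"` (default) or `"weighted"`.
#' @return a list of class `fst_components`: `h_t`, `h_s`, `fst`
#'   (all NA when either population has no data or H_T = 0).
#' @export
#' @examples
#' a <- structure(list(n_alt = 18L, n_ref = 2L, n_called = 20L,
#'                     no_data = FALSE), class = "allele_counts")
#' b <- structure(list(n_alt = 10L, n_ref = 10L, n_called = 20L,
#'                     no_data = FALSE), class = "allele_counts")
#' site_fst(a, b)$fst # (0.42 - 0.34)/0.42
site_fst <- function(counts_a, counts_b,
                     weighting = c("unweighted", "weighted")) {
  weighting <- match.arg(weighting)
  if (isTRUE(counts_a$no_data) || isTRUE(counts_b$no_data)) {
    return(structure(list(h_t = NA_real_, h_s = NA_real_, fst = NA_real_),
                     class = "fst_components"))
  }
  p_a <- counts_a$n_alt / counts_a$n_called
  p_b <- counts_b$n_alt / counts_b$n_called
  comp <- fst_components_vec(p_a, p_b, counts_a$n_called, counts_b$n_called,
                             weighting)
  structure(list(h_t = comp$h_t, h_s = comp$h_s, fst = comp$fst),
            class = "fst_components")
}

#' Window-level fixation index
#'
#' Summarises per-site Fst over a window. The default averages the
#' defined per-site ratios; `method = "ratio_of_averages"` instead forms
#' one ratio \eqn{(\bar H_T - \bar H_S)/\bar H_T} from the window means
#' of the heterozygosity components.
#'
#' @param components a list of `fst_components` (one per site), or a
#'   numeric vector of per-site fst values for `method = "mean_site"`.
#' @param method `"mean_site"` (default) or `"ratio_of_averages"`.
#' @return mean window Fst, or NA (with a warning) when no site is
#'   defined.
#' @export
window_fst <- function(components, method = c("mean_site",
                                              "ratio_of_averages")) {
  method <- match.arg(method)
  if (is.numeric(components)) {
    fst <- components
    h_t <- h_s <- NULL
  } else {
    if (inherits(components, "fst_components")) components <- list(components)
    fst <- vapply(components, `[[`, numeric(1), "fst")
    h_t <- vapply(components, `[[`, numeric(1), "h_t")
    h_s <- vapply(components, `[[`, numeric(1), "h_s")
  }
  if (method == "mean_site") {
    if (all(is.na(fst))) {
      warning("no defined Fst sites in window")
      return(NA_real_)
    }
    return(mean(fst, na.rm = TRUE))
  }
  if (is.null(h_t))
    stop("ratio_of_averages needs fst_components, not bare fst values")
  keep <- !is.na(h_t) & h_t > 0
  if (!any(keep)) {
    warning("no defined Fst sites in window")
    return(NA_real_)
  }
  (mean(h_t[keep]) - mean(h_s[keep])) / mean(h_t[keep])
}

#' Nucleotide diversity (pi) of a window
#'
#' Unbiased per-site heterozygosity summed over the window's SNPs and
#' divided by the window span:
#' \deqn{\pi = \frac{1}{L}\sum_{sites} \frac{2\,n_{Maj} n_{Min}}
#'   {n_{called}(n_{called}-1)},}
#' with \eqn{n_{called}} the number of called allele copies at the site.
#' Invariant (monomorphic) sites contribute zero, so only SNPs need to be
#' supplied. Sites with fewer than two called copies are skipped.
#'
#' @param n_maj,n_min,n_called parallel per-site allele counts.
#' @param window_span_bp window length L in bp (> 0).
#' @return pi per bp (>= 0); 0 for a window with no variable sites.
#' @export
#' @examples
#' nucleotide_diversity(10, 10, 20, 1000) # (200/380)/1000
nucleotide_diversity <- function(n_maj, n_min, n_called, window_span_bp) {
  stopifnot(window_span_bp > 0,
            length(n_maj) == length(n_min),
            length(n_maj) == length(n_called))
  keep <- !is.na(n_called) & n_called >= 2
  if (!any(keep)) return(0)
  sum(2 * n_maj[keep] * n_min[keep] /
        (n_called[keep] * (n_called[keep] - 1))) / window_span_bp
}

#' Squared dosage correlation (LD r2) between two sites
#'
#' Unphased linkage disequilibrium: the squared Pearson correlation of
#' ALT-dosage vectors (Rogers-Huff style) over the samples called at both
#' sites, within one population.
#'
#' @param sites a \code{\link{site_table}}.
#' @param i,j site indices; must lie on the same contig.
#' @param popmap a \code{\link{population_map}}.
#' @param population population label.
#' @return a list `(distance_bp, r2, n)`; `r2` is NA when either site has
#'   zero dosage variance among the jointly-called samples or fewer than
#'   two samples are called at both.
#' @export
genotype_r2 <- function(sites, i, j, popmap, population) {
  stopifnot(inherits(sites, "site_table"))
  if (sites$contig[i] != sites$contig[j])
    stop("LD is only defined within a contig")
  ids <- intersect(population_samples(popmap, population), sites$samples)
  x <- sites$dosage[i, ids]
  y <- sites$dosage[j, ids]
  keep <- !is.na(x) & !is.na(y)
  d <- abs(sites$position[i] - sites$position[j])
  if (sum(keep) < 2L || sd(x[keep]) == 0 || sd(y[keep]) == 0)
    return(list(distance_bp = d, r2 = NA_real_, n = sum(keep)))
  list(distance_bp = d, r2 = cor(x[keep], y[keep])^2, n = sum(keep))
}

#' LD decay curve: mean r2 by physical distance bin
#'
#' Computes r2 for every within-contig site pair with distance at most
#' `max_dist_bp` and minor-allele frequency at least `maf_min` in the
#' chosen population, then averages within distance bins. Bins with no
#' pairs are reported with `n_pairs = 0` and NA mean.
#'
#' @param sites a \code{\link{site_table}}.
#' @param popmap a \code{\link{population_map}}.
#' @param population population label.
#' @param max_dist_bp maximum pair distance.
#' @param bin_width_bp distance bin width; bins tile (0, max_dist_bp].
#' @param maf_min minimum within-population minor allele frequency.
#' @return a `data.frame`: `bin_start`, `bin_end`, `bin_mid`, `mean_r2`,
#'   `n_pairs`.
#' @export
ld_decay_curve <- function(sites, popmap, population,
                           max_dist_bp = 100000L, bin_width_bp = 10000L,
                           maf_min = 0.05) {
  stopifnot(inherits(sites, "site_table"), max_dist_bp > 0,
            bin_width_bp > 0)
  ids <- intersect(population_samples(popmap, population), sites$samples)
  dos <- sites$dosage[, ids, drop = FALSE]
  called <- rowSums(!is.na(dos))
  alt <- rowSums(dos, na.rm = TRUE)
  freq <- ifelse(called > 0, alt / (2 * called), NA_real_)
  maf <- pmin(freq, 1 - freq)
  keep <- which(!is.na(maf) & maf >= maf_min)

  n_bins <- ceiling(max_dist_bp / bin_width_bp)
  bin_start <- (seq_len(n_bins) - 1L) * bin_width_bp
  bin_end <- pmin(bin_start + bin_width_bp, max_dist_bp)
  sum_r2 <- num <- numeric(n_bins)

  for (ctg in unique(sites$contig)) {
    idx <- keep[sites$contig[keep] == ctg]
    if (length(idx) < 2L) next
    pos <- sites$position[idx]
    for (a in seq_len(length(idx) - 1L)) {
      b <- a + 1L
      while (b <= length(idx) && pos[b] - pos[a] <= max_dist_bp) {
        x <- dos[idx[a], ]
        y <- dos[idx[b], ]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) >= 2L && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
          r2 <- cor(x[ok], y[ok])^2
          bin <- ceiling((pos[b] - pos[a]) / bin_width_bp)
          bin <- min(bin, n_bins)
          sum_r2[bin] <- sum_r2[bin] + r2
          num[bin] <- num[bin] + 1L
        }
        b <- b + 1L
      }
    }
  }
  data.frame(
    bin_start = bin_start, bin_end = bin_end,
    bin_mid = (bin_start + bin_end) / 2,
    mean_r2 = ifelse(num > 0, sum_r2 / num, NA_real_),
    n_pairs = as.integer(num)
  )
}

# Vectorized per-site statistics for one population: called chromosome
# counts, ALT counts and major/minor classification (tie -> REF major).
pop_site_stats <- function(sites, sample_ids) {
  dos <- sites$dosage[, sample_ids, drop = FALSE]
  called <- rowSums(!is.na(dos))
  n_chr <- 2L * called
  n_alt <- as.integer(rowSums(dos, na.rm = TRUE))
  n_ref <- as.integer(n_chr - n_alt)
  n_maj <- as.integer(ifelse(n_alt > n_ref, n_alt, n_ref))
  list(n_chr = as.integer(n_chr), n_alt = n_alt, n_ref = n_ref,
       n_maj = n_maj, n_min = as.integer(n_chr - n_maj),
       p_alt = ifelse(n_chr > 0, n_alt / n_chr, NA_real_))
}
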