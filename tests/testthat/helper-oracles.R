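# Independent brute-force oracles and small fixture builders.
# Everything here is deliberately naive and shares no code with R/.

# --- fixture builders ------------------------------------------------------

make_st <- function(dosage, positions = NULL, contig = "chr1",
                    samples = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  if (is.null(positions)) positions <- seq_len(n) * 100L
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(dosage)))
  site_table(contig = rep(contig, n), position = positions,
             ref = rep("A", n), alt = rep("G", n),
             dosage = dosage, samples = samples)
}

make_popmap_all <- function(samples, label = "pop1") {
  population_map(samples, rep(label, length(samples)))
}

# random small two-population dataset for oracle-equivalence loops
random_small_dataset <- function(seed, n_sites = 15, n_a = 5, n_b = 8,
                                 miss = 0.1) {
  set.seed(seed)
  n <- n_a + n_b
  dos <- matrix(sample(c(0:2, NA), n_sites * n, replace = TRUE,
                       prob = c((1 - miss) / 3, (1 - miss) / 3,
                                (1 - miss) / 3, miss)),
                nrow = n_sites)
  st <- make_st(dos, positions = sort(sample.int(5000L, n_sites)))
  pm <- population_map(st$samples,
                       c(rep("A", n_a), rep("B", n_b)))
  list(sites = st, popmap = pm)
}

# --- naive statistic oracles ----------------------------------------------

# per-site counts for one population from a raw dosage vector
naive_counts <- function(d) {
  d <- d[!is.na(d)]
  n_alt <- sum(d)
  n_ref <- 2 * length(d) - n_alt
  n_maj <- max(n_ref, n_alt)          # tie -> ref, and max() gives the same
  list(n_ref = n_ref, n_alt = n_alt, n_maj = n_maj,
       n_min = n_ref + n_alt - n_maj, n_called = n_ref + n_alt)
}

naive_hp <- function(dosage_rows) {
  s_maj <- s_min <- 0
  for (i in seq_len(nrow(dosage_rows))) {
    cts <- naive_counts(dosage_rows[i, ])
    if (cts$n_called == 0) next
    s_maj <- s_maj + cts$n_maj
    s_min <- s_min + cts$n_min
  }
  if (s_maj + s_min == 0) return(NA_real_)
  2 * s_maj * s_min / (s_maj + s_min)^2
}

naive_site_fst <- function(p_a, p_b) {
  h_s <- (2 * p_a * (1 - p_a) + 2 * p_b * (1 - p_b)) / 2
  p_bar <- (p_a + p_b) / 2
  h_t <- 2 * p_bar * (1 - p_bar)
  if (h_t == 0) return(NA_real_)
  (h_t - h_s) / h_t
}

naive_window_fst <- function(dos_a, dos_b) {
  fst <- rep(NA_real_, nrow(dos_a))
  for (i in seq_len(nrow(dos_a))) {
    ca <- naive_counts(dos_a[i, ]); cb <- naive_counts(dos_b[i, ])
    if (ca$n_called == 0 || cb$n_called == 0) next
    fst[i] <- naive_site_fst(ca$n_alt / ca$n_called,
                             cb$n_alt / cb$n_called)
  }
  if (all(is.na(fst))) NA_real_ else mean(fst, na.rm = TRUE)
}

naive_pi <- function(dosage_rows, span) {
  tot <- 0
  for (i in seq_len(nrow(dosage_rows))) {
    cts <- naive_counts(dosage_rows[i, ])
    if (cts$n_called < 2) next
    tot <- tot + 2 * cts$n_maj * cts$n_min /
      (cts$n_called * (cts$n_called - 1))
  }
  tot / span
}

naive_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  mx <- mean(x); my <- mean(y)
  num <- sum((x - mx) * (y - my))
  (num / sqrt(sum((x - mx)^2) * sum((y - my)^2)))^2
}

# --- interval oracles on a toy contig -------------------------------------

# per-bp occupancy vector of 1-based inclusive intervals
region_bitmap <- function(regions, len, contig = "chr1") {
  bit <- logical(len)
  rg <- regions[regions$contig == contig, , drop = FALSE]
  for (i in seq_len(nrow(rg))) bit[rg$start[i]:rg$end[i]] <- TRUE
  bit
}

# maximal runs of TRUE -> region data.frame
bitmap_to_regions <- function(bit, contig = "chr1") {
  r <- rle(bit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(contig = contig, start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

# union-find merge of possibly-overlapping/abutting intervals
unionfind_merge <- function(regions, contig = "chr1") {
  rg <- regions[regions$contig == contig, , drop = FALSE]
  n <- nrow(rg)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    touch <- rg$start[i] <= rg$end[j] + 1L && rg$start[j] <= rg$end[i] + 1L
    if (touch) parent[find(i)] <- find(j)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(unique(roots), function(r) {
    m <- roots == r
    data.frame(contig = contig, start = min(rg$start[m]),
               end = max(rg$end[m]), n = sum(m))
  }))
  out[order(out$start), , drop = FALSE]
}

# exhaustive-enumeration hypergeometric upper tail:
# P(#{study genes in term} >= k_obs) over all equally-likely study draws
enum_hyper_p <- function(n_bg, m_term, n_study, k_obs) {
  if (k_obs == 0) return(1)
  combos <- utils::combn(n_bg, n_study)
  in_term <- combos <= m_term   # label genes 1..m_term as the term members
  mean(colSums(in_term) >= k_obs)
}

# Monte-Carlo expectation of the mean per-site Fst estimator under the
# Balding-Nichols background (independent of the package's simulator)
mc_fst_expectation <- function(n_sites, f, n_chr_a, n_chr_b, seed) {
  set.seed(seed)
  p <- runif(n_sites, 0.05, 0.95)
  shp <- (1 - f) / f
  p_a <- rbeta(n_sites, p * shp, (1 - p) * shp)
  p_b <- rbeta(n_sites, p * shp, (1 - p) * shp)
  c_a <- rbinom(n_sites, n_chr_a, p_a)
  c_b <- rbinom(n_sites, n_chr_b, p_b)
  fst <- mapply(function(ka, kb) naive_site_fst(ka / n_chr_a, kb / n_chr_b),
                c_a, c_b)
  list(mean = mean(fst, na.rm = TRUE), sd = sd(fst, na.rm = TRUE))
}
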