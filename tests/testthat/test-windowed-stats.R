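test_that("allele counts classify major/minor with the REF-major tie rule", {
  pm <- make_popmap_all(sprintf("s%02d", 1:10))
  st <- make_st(matrix(2L, nrow = 1, ncol = 10))       # all hom ALT
  ac <- site_allele_counts(st, 1, pm, "pop1")
  expect_equal(ac$n_maj, 20L)
  expect_equal(ac$n_min, 0L)
  expect_equal(ac$n_called, 20L)

  pm4 <- make_popmap_all(sprintf("s%02d", 1:4))
  tie <- make_st(matrix(c(0L, 1L, 1L, 2L), nrow = 1))  # 4 ref, 4 alt
  ac_tie <- site_allele_counts(tie, 1, pm4, "pop1")
  expect_equal(ac_tie$n_maj, 4L)
  expect_equal(ac_tie$n_maj, ac_tie$n_ref)             # tie -> REF major

  # 12 diploids, 7 of 24 alleles carry ALT
  dos <- matrix(c(rep(1L, 7), rep(0L, 5)), nrow = 1)
  pm12 <- make_popmap_all(sprintf("s%02d", 1:12))
  ac12 <- site_allele_counts(make_st(dos), 1, pm12, "pop1")
  expect_equal(ac12$n_maj, 17L)
  expect_equal(ac12$n_min, 7L)
})

test_that("zero called genotypes give an explicit no-data result", {
  pm <- make_popmap_all(c("s01", "s02"))
  st <- make_st(matrix(NA_integer_, nrow = 1, ncol = 2))
  ac <- site_allele_counts(st, 1, pm, "pop1")
  expect_true(ac$no_data)
  expect_true(is.na(ac$n_maj))
  expect_equal(ac$n_called, 0L)
  expect_error(allele_frequency(st, 1, pm, "pop1"), "no called")
})

test_that("allele frequencies reproduce the wild 0.292 / domestic 1.0 pattern", {
  # wild population: 7 of 24 chromosomes carry the minor allele
  pm12 <- make_popmap_all(sprintf("s%02d", 1:12), "wild")
  wild <- make_st(matrix(c(rep(1L, 7), rep(0L, 5)), nrow = 1))
  f <- allele_frequency(wild, 1, pm12, "wild", allele = "alt")
  expect_equal(f, 7 / 24)
  expect_equal(round(f, 3), 0.292)
  # domestic population: all 118 chromosomes of 59 diploids fixed
  pm59 <- make_popmap_all(sprintf("d%02d", 1:59), "domestic")
  dom <- make_st(matrix(2L, nrow = 1, ncol = 59),
                 samples = sprintf("d%02d", 1:59))
  expect_equal(allele_frequency(dom, 1, pm59, "domestic", "alt"), 1)
  none <- make_st(matrix(0L, nrow = 1, ncol = 12))
  expect_equal(allele_frequency(none, 1, pm12, "wild", "alt"), 0)
})

test_that("pooled heterozygosity follows the windowed count formula", {
  expect_equal(pooled_heterozygosity(10, 10), 0.5)   # maximal
  expect_equal(pooled_heterozygosity(20, 0), 0)      # fixed window
  expect_equal(pooled_heterozygosity(c(90, 70), c(10, 30)), 0.32)
  expect_warning(out <- pooled_heterozygosity(NA_integer_, NA_integer_),
                 "undefined")
  expect_true(is.na(out))
})

test_that("per-site Fst matches the heterozygosity-ratio definition", {
  mk <- function(alt, n) structure(
    list(n_alt = alt, n_ref = n - alt, n_called = n, no_data = FALSE),
    class = "allele_counts")
  expect_equal(site_fst(mk(6, 20), mk(6, 20))$fst, 0)   # identical freqs
  expect_equal(site_fst(mk(20, 20), mk(0, 20))$fst, 1)  # fixed difference
  comp <- site_fst(mk(18, 20), mk(10, 20))              # p = 0.9 vs 0.5
  expect_equal(comp$h_s, 0.34)
  expect_equal(comp$h_t, 0.42)
  expect_equal(comp$fst, 8 / 42)
  # monomorphic pool: undefined
  expect_true(is.na(site_fst(mk(0, 20), mk(0, 24))$fst))
  # one population uncallable: undefined
  nodata <- structure(list(no_data = TRUE), class = "allele_counts")
  expect_true(is.na(site_fst(mk(6, 20), nodata)$fst))
})

test_that("window Fst averages defined sites; ratio-of-averages variant agrees on one site", {
  expect_equal(window_fst(c(0, 1)), 0.5)
  expect_equal(window_fst(0.1905), 0.1905)
  expect_equal(window_fst(c(0.2, NA, 0.4)), 0.3)
  expect_warning(out <- window_fst(NA_real_), "no defined")
  expect_true(is.na(out))
  mk <- function(alt, n) structure(
    list(n_alt = alt, n_ref = n - alt, n_called = n, no_data = FALSE),
    class = "allele_counts")
  comp <- site_fst(mk(18, 20), mk(10, 20))
  expect_equal(window_fst(list(comp), method = "ratio_of_averages"),
               comp$fst)
})

test_that("nucleotide diversity uses the unbiased per-site estimator", {
  expect_equal(nucleotide_diversity(integer(), integer(), integer(), 1000), 0)
  expect_equal(nucleotide_diversity(10, 10, 20, 1000),
               (2 * 100 / (20 * 19)) / 1000)
  # span scaling: pi scales as 1/c
  pi1 <- nucleotide_diversity(c(15, 12), c(5, 8), c(20, 20), 1000)
  expect_equal(nucleotide_diversity(c(15, 12), c(5, 8), c(20, 20), 3000),
               pi1 / 3)
})

test_that("dosage r2 handles perfect, anti- and degenerate correlation", {
  pm <- make_popmap_all(sprintf("s%02d", 1:4))
  st <- make_st(rbind(c(0L, 0L, 2L, 2L),
                      c(2L, 2L, 0L, 0L),
                      c(0L, 1L, 2L, 1L),
                      c(1L, 1L, 1L, 2L),
                      c(1L, 1L, 1L, 1L)))
  expect_equal(genotype_r2(st, 1, 1, pm, "pop1")$r2, 1)
  expect_equal(genotype_r2(st, 1, 2, pm, "pop1")$r2, 1)  # (-1)^2
  expect_equal(genotype_r2(st, 1, 2, pm, "pop1")$distance_bp, 100L)
  expect_equal(genotype_r2(st, 3, 4, pm, "pop1")$r2,
               naive_r2(c(0, 1, 2, 1), c(1, 1, 1, 2)))
  expect_true(is.na(genotype_r2(st, 1, 5, pm, "pop1")$r2))  # zero variance
})

test_that("Hp, window Fst and pi match a naive reimplementation to 1e-12", {
  for (seed in 1:8) {
    d <- random_small_dataset(seed)
    ids_a <- population_samples(d$popmap, "A")
    ids_b <- population_samples(d$popmap, "B")
    dos_a <- d$sites$dosage[, ids_a, drop = FALSE]
    dos_b <- d$sites$dosage[, ids_b, drop = FALSE]
    span <- 5000

    cfg <- scan_config(window_size_bp = span, step_bp = span,
                       min_snps_per_window = 0L, exclude_contigs = character())
    w <- window_stats(d$sites, d$popmap, cfg,
                      contig_lengths = c(chr1 = span))
    expect_equal(nrow(w), 1L)
    expect_equal(w$hp_A, naive_hp(dos_a), tolerance = 1e-12)
    expect_equal(w$hp_B, naive_hp(dos_b), tolerance = 1e-12)
    expect_equal(w$fst, naive_window_fst(dos_a, dos_b), tolerance = 1e-12)
    expect_equal(w$pi_A, naive_pi(dos_a, span), tolerance = 1e-12)
    expect_equal(w$pi_B, naive_pi(dos_b, span), tolerance = 1e-12)
  }
})

test_that("Hp and Fst respect their analytic ranges on random data", {
  for (seed in 11:16) {
    d <- random_small_dataset(seed, n_sites = 20)
    cfg <- scan_config(window_size_bp = 5000, step_bp = 5000,
                       min_snps_per_window = 0L)
    w <- window_stats(d$sites, d$popmap, cfg,
                      contig_lengths = c(chr1 = 5000))
    hp <- c(w$hp_A, w$hp_B)
    expect_true(all(hp >= 0 & hp <= 0.5, na.rm = TRUE))
    expect_true(all(w$fst >= 0 & w$fst <= 1, na.rm = TRUE))
    expect_true(all(c(w$pi_A, w$pi_B) >= 0))
  }
})

test_that("LD decay curve bins pairs and stays empty for a lone site", {
  pm <- make_popmap_all(sprintf("s%02d", 1:6))
  lone <- make_st(matrix(c(0L, 1L, 2L, 0L, 1L, 2L), nrow = 1))
  curve <- ld_decay_curve(lone, pm, "pop1", max_dist_bp = 1000,
                          bin_width_bp = 100)
  expect_true(all(curve$n_pairs == 0L))

  two <- make_st(rbind(c(0L, 1L, 2L, 0L, 1L, 2L),
                       c(0L, 1L, 2L, 0L, 1L, 2L)),
                 positions = c(100L, 200L))
  curve2 <- ld_decay_curve(two, pm, "pop1", max_dist_bp = 1000,
                           bin_width_bp = 1000, maf_min = 0.05)
  expect_equal(sum(curve2$n_pairs), 1L)
  expect_equal(curve2$mean_r2[curve2$n_pairs == 1], 1)
})

test_that("block-copying simulation produces decaying LD", {
  ok <- 0L
  n_rep <- 10L
  for (s in 1:n_rep) {
    cfg <- sim_config(genome_length_bp = 4e5, snp_density = 1 / 400,
                      n_wild = 20, n_domestic = 20, missing_rate = 0,
                      ld_mode = "block", block_length_bp = 20000L,
                      seed = 100 + s)
    sim <- simulate_dataset(cfg)
    curve <- ld_decay_curve(sim$sites, sim$popmap, "wild",
                            max_dist_bp = 50000, bin_width_bp = 10000,
                            maf_min = 0.1)
    r2 <- curve$mean_r2[1:5]
    if (!anyNA(r2) && all(diff(r2) <= 1e-9)) ok <- ok + 1L
  }
  expect_gte(ok, 0.9 * n_rep)
})
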