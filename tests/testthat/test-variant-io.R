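vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
}

test_that("VCF reader keeps biallelic SNPs and skips other records", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    vcf_header(c("s1", "s2")),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t200\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1\t1/1",   # indel
    "chr1\t300\t.\tC\tT\t.\tPASS\t.\tGT\t1/1\t1/1",
    "chr1\t400\t.\tG\tA,C\t.\tPASS\t.\tGT\t1/2\t0/0",  # multi-allelic
    "chr1\t500\t.\tT\tC\t.\tPASS\t.\tGT\t./.\t0|1"
  ), path)
  expect_message(st <- read_genotypes(path), "skipped 2")
  expect_equal(n_sites(st), 3L)
  expect_equal(attr(st, "skipped_records"), 2L)
  expect_equal(st$position, c(100L, 300L, 500L))
  # ./., phased and half calls
  expect_identical(st$dosage[3, ], c(s1 = NA_integer_, s2 = 1L))
})

test_that("half-calls and non-diploid GTs read as missing", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    vcf_header(c("s1", "s2", "s3")),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t./1\t1\t1/1"
  ), path)
  st <- read_genotypes(path)
  expect_identical(unname(st$dosage[1, ]), c(NA_integer_, NA_integer_, 2L))
})

test_that("requested samples subset and order the matrix; absent ones error", {
  sim <- simulate_dataset(sim_config(genome_length_bp = 5e4, seed = 6))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$sites, path)
  pick <- c("dom_03", "wild_01")
  st <- read_genotypes(path, samples = pick)
  expect_identical(st$samples, pick)
  expect_identical(st$dosage, sim$sites$dosage[, pick])
  expect_error(read_genotypes(path, samples = "nosuch"), "absent")
  expect_error(read_genotypes("does-not-exist.vcf"), "not found")
})

test_that("simulate -> write_vcf -> read_genotypes is the identity", {
  sim <- simulate_dataset(sim_config(genome_length_bp = 2e5, n_contigs = 2,
                                     seed = 8))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$sites, path)
  st <- read_genotypes(path)
  expect_identical(st$dosage, sim$sites$dosage)
  expect_identical(st$contig, sim$sites$contig)
  expect_identical(st$position, sim$sites$position)
  expect_identical(st$ref, sim$sites$ref)
  expect_identical(st$alt, sim$sites$alt)
})

test_that("population map reading enforces shape and records label order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ids <- c(sprintf("hu%02d", 1:59), sprintf("mf%02d", 1:12))
  writeLines(c("sample\tpopulation",
               paste(ids, rep(c("HU", "MOUFLON"), c(59, 12)), sep = "\t")),
             path)
  pm <- read_population_map(path)
  expect_equal(nrow(pm), 71L)
  expect_equal(population_levels(pm), c("HU", "MOUFLON"))
  expect_length(population_samples(pm, "HU"), 59L)
  expect_length(population_samples(pm, "MOUFLON"), 12L)

  writeLines(c("a\tp1", "a\tp2"), path)
  expect_error(read_population_map(path), "duplicate")
})

test_that("a scan rejects maps with more or fewer than two populations", {
  sim <- simulate_dataset(sim_config(genome_length_bp = 2e5, seed = 3))
  pm3 <- population_map(sim$popmap$sample,
                        c("a", "b", rep(c("wild", "domestic"), c(10, 59))))
  expect_error(window_stats(sim$sites, pm3), "exactly two")
  pm1 <- population_map(sim$popmap$sample, rep("one", 71))
  expect_error(window_stats(sim$sites, pm1), "exactly two")
  pm_missing <- population_map("wild_01", "wild")
  expect_error(window_stats(sim$sites, pm_missing), "missing from")
})

test_that("BED and GFF3 gene coordinates normalise to 1-based inclusive", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t2000\tgeneA", "chr1\t2999\t4000\tgeneB"), bed)
  genes <- read_gene_annotation(bed)
  expect_equal(genes$start, c(1000L, 3000L))
  expect_equal(genes$end, c(2000L, 4000L))
  expect_equal(genes$gene_id, c("geneA", "geneB"))

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "src", "gene", "1000", "2000", ".", "+", ".",
                     "ID=geneA", sep = "\t"),
               paste("chr1", "src", "exon", "1000", "1500", ".", "+", ".",
                     "Parent=geneA", sep = "\t"),
               paste("chr1", "src", "gene", "1500", "2500", ".", "-", ".",
                     "ID=geneB", sep = "\t")), gff)
  genes_g <- read_gene_annotation(gff)
  expect_equal(nrow(genes_g), 2L)          # exon dropped, overlap preserved
  expect_equal(genes_g$start, c(1000L, 1500L))
  expect_equal(genes_g$end, c(2000L, 2500L))
})

test_that("BED round trip through internal coordinates is the identity", {
  bed <- withr::local_tempfile(fileext = ".bed")
  orig <- c("chr1\t0\t1500\tg1", "chr2\t999\t2000\tg2")
  writeLines(orig, bed)
  genes <- read_gene_annotation(bed)
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(genes, out)
  expect_identical(readLines(out), orig)
})

test_that("variant effect tables keep labels verbatim and demand their columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig\tposition\tgene_id\tconsequence",
               "chr1\t722\tRDH5\tmissense_variant",
               "chr1\t722\tRDH5\tmissense_variant",
               "chr1\t900\tRDH5\tweird_new_label"), path)
  eff <- read_variant_effects(path)
  expect_equal(nrow(eff), 3L)              # duplicates kept
  expect_true("weird_new_label" %in% eff$consequence)
  expect_type(eff$position, "integer")

  writeLines("contig\tposition\tgene_id\tconsequence", path)
  expect_equal(nrow(read_variant_effects(path)), 0L)

  writeLines(c("contig\tposition\tgene_id", "chr1\t1\tX"), path)
  expect_error(read_variant_effects(path), "consequence")
})

test_that("the contig blocklist drops sex-chromosome sites before scanning", {
  st <- make_st(matrix(c(0L, 1L, 2L, 1L), nrow = 2))
  st$contig <- c("chr1", "chrX")
  st2 <- exclude_contigs(st, c("chrX", "X"))
  expect_equal(st2$contig, "chr1")
  expect_equal(n_sites(st2), 1L)
})
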