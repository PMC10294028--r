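#' Configuration for a full pipeline run
#'
#' Bundles the simulator and scan configurations with annotation
#' parameters and the output location for a reproducible
#' simulate - scan - annotate - enrich run.
#'
#' @param sim a \code{\link{sim_config}}; its planted sweeps default to
#'   \code{\link{default_sweep_layout}} when unset.
#' @param scan a \code{\link{scan_config}}.
#' @param gene_length_bp,n_terms,term_prob annotation-simulation
#'   parameters (see \code{\link{simulate_annotations}}).
#' @param fdr enrichment significance threshold.
#' @param seed run seed; overrides `sim$seed` so one number controls the
#'   whole run.
#' @return a list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), scan = scan_config(),
                       gene_length_bp = 10000L, n_terms = 20L,
                       term_prob = 0.05, fdr = 0.05, seed = sim$seed) {
  stopifnot(inherits(sim, "sim_config"), inherits(scan, "scan_config"))
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, scan = scan,
                 gene_length_bp = as.integer(gene_length_bp),
                 n_terms = as.integer(n_terms), term_prob = term_prob,
                 fdr = fdr, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full simulate - scan - annotate - enrich pipeline
#'
#' Simulates a two-population dataset with planted sweeps, writes the
#' interchange files (VCF, population map, truth BED), scans for sweep
#' regions, maps them to simulated gene annotations, runs hypergeometric
#' enrichment over the simulated term map, scores detection against the
#' planted truth, and writes every stage output plus a manifest of file
#' checksums. Identical config + seed reproduces identical checksums.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory (created if absent).
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list: `scan` (the
#'   \code{\link{sweep_scan}} result), `genes`, `study_genes`,
#'   `enrichment`, `detection` (recall/precision vs truth), `manifest`
#'   (a `data.frame` of file paths and md5 checksums), `log` (named
#'   per-stage counts).
#' @export
run_full_pipeline <- function(config = run_config(), out_dir,
                              quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[sweepscan] ", ...)
  sim_cfg <- config$sim
  if (is.null(sim_cfg$sweep_regions)) {
    cfg_args <- sim_cfg[setdiff(names(sim_cfg),
                                c("contig_lengths", "sweep_regions"))]
    cfg_args$sweep_regions <- default_sweep_layout(sim_cfg)
    sim_cfg <- do.call(sim_config, cfg_args)
  }

  say("simulate: ", sim_cfg$genome_length_bp, " bp, ",
      sim_cfg$n_wild, " wild + ", sim_cfg$n_domestic,
      " domestic diploids, seed ", sim_cfg$seed)
  sim <- simulate_dataset(sim_cfg)
  ann <- simulate_annotations(sim_cfg, config$gene_length_bp,
                              config$n_terms, term_prob = config$term_prob)

  paths <- c(
    vcf = file.path(out_dir, "genotypes.vcf"),
    popmap = file.path(out_dir, "popmap.tsv"),
    truth = file.path(out_dir, "truth_sweeps.bed"),
    genes_bed = file.path(out_dir, "genes.bed"),
    term_map = file.path(out_dir, "term_map.tsv"),
    windows = file.path(out_dir, "window_stats.tsv"),
    regions = file.path(out_dir, "sweep_regions.tsv"),
    regions_bed = file.path(out_dir, "sweep_regions.bed"),
    gene_list = file.path(out_dir, "candidate_genes.tsv"),
    enrichment = file.path(out_dir, "enrichment.tsv")
  )
  write_vcf(sim$sites, paths[["vcf"]], sim_cfg$contig_lengths)
  write_population_map(sim$popmap, paths[["popmap"]])
  write_bed(sim$truth$sweep_regions, paths[["truth"]])
  write_bed(ann$genes, paths[["genes_bed"]])
  write_tsv(ann$term_map, paths[["term_map"]])

  say("scan: ", config$scan$window_size_bp, " bp windows, step ",
      config$scan$step_bp, ", |Z| cutoff ", config$scan$z_cutoff)
  scan <- sweep_scan(sim$sites, sim$popmap, config$scan,
                     contig_lengths = sim_cfg$contig_lengths)
  write_tsv(scan$windows, paths[["windows"]])
  all_regions <- rbind(scan$hp_regions, scan$fst_regions, scan$regions)
  write_tsv(all_regions, paths[["regions"]])
  write_bed(scan$regions, paths[["regions_bed"]])

  say("annotate: ", nrow(ann$genes), " simulated genes")
  study <- genes_in_regions(scan$regions, ann$genes)
  write_tsv(data.frame(gene_id = study), paths[["gene_list"]])

  say("enrich: ", length(unique(ann$term_map$term)), " terms")
  enr <- hypergeometric_enrichment(study, ann$genes$gene_id,
                                   ann$term_map, fdr = config$fdr)
  write_tsv(enr, paths[["enrichment"]])

  detection <- evaluate_detection(scan$regions, sim$truth)
  manifest <- data.frame(
    file = basename(unname(paths)),
    md5 = unname(tools::md5sum(unname(paths))),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  log <- c(
    n_sites = n_sites(sim$sites),
    n_windows_retained = nrow(scan$windows),
    n_windows_excluded = scan$excluded_windows,
    n_hp_regions = nrow(scan$hp_regions),
    n_fst_regions = nrow(scan$fst_regions),
    n_intersection_regions = nrow(scan$regions),
    n_candidate_genes = length(study),
    n_significant_terms = sum(enr$significant),
    recall = detection$recall,
    precision = detection$precision
  )
  say("done: ", log[["n_intersection_regions"]],
      " candidate regions, ", log[["n_candidate_genes"]], " genes")
  invisible(list(scan = scan, genes = ann$genes, study_genes = study,
                 enrichment = enr, detection = detection,
                 manifest = manifest, log = log))
}
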