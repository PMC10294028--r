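#' Genes overlapping sweep regions
#'
#' A gene is selected when any candidate region overlaps it by at least
#' 1 bp (both in 1-based inclusive coordinates). The result is
#' deduplicated — a gene spanning several regions appears once — and
#' sorted by (contig, start).
#'
#' @param regions a region `data.frame` (`contig`, `start`, `end`).
#' @param genes a gene `data.frame` (`gene_id`, `contig`, `start`,
#'   `end`), e.g. from \code{\link{read_gene_annotation}}.
#' @return character vector of gene ids.
#' @export
genes_in_regions <- function(regions, genes) {
  if (nrow(regions) == 0L || nrow(genes) == 0L) return(character())
  gr_g <- GenomicRanges::GRanges(
    genes$contig, IRanges::IRanges(genes$start, genes$end))
  gr_r <- regions_to_granges(regions)
  hit <- GenomicRanges::countOverlaps(gr_g, gr_r, minoverlap = 1L) > 0
  sel <- genes[hit, , drop = FALSE]
  sel <- sel[order(sel$contig, sel$start), , drop = FALSE]
  unique(sel$gene_id)
}

#' Filter candidate genes to those with in-region missense variants
#'
#' Keeps the subset of candidate genes carrying at least one variant
#' whose consequence is `missense_variant` and whose position lies
#' inside a sweep region.
#'
#' @param gene_ids character vector of candidate gene ids.
#' @param effects an effect `data.frame` from
#'   \code{\link{read_variant_effects}}.
#' @param regions a region `data.frame`.
#' @param consequence the consequence label defining a missense variant.
#' @return character vector: the retained subset of `gene_ids`, in the
#'   input order.
#' @export
missense_gene_filter <- function(gene_ids, effects, regions,
                                 consequence = "missense_variant") {
  if (length(gene_ids) == 0L || nrow(effects) == 0L ||
      nrow(regions) == 0L) return(character())
  eff <- effects[effects$consequence == consequence &
                   effects$gene_id %in% gene_ids, , drop = FALSE]
  if (nrow(eff) == 0L) return(character())
  gr_e <- GenomicRanges::GRanges(
    eff$contig, IRanges::IRanges(eff$position, width = 1L))
  inside <- GenomicRanges::countOverlaps(gr_e,
                                         regions_to_granges(regions)) > 0
  gene_ids[gene_ids %in% unique(eff$gene_id[inside])]
}

#' Hypergeometric gene-set over-representation test
#'
#' For each term, tests whether the study gene set contains more genes
#' annotated to the term than expected from its share of the background:
#' the upper-tail hypergeometric probability of observing at least the
#' realised number of in-term study genes. Terms with zero study genes
#' are reported with p = 1 by convention. P-values are corrected with
#' the Benjamini-Hochberg step-up procedure and a `significant` flag is
#' set at the chosen FDR; nothing is filtered out of the table.
#'
#' @param study character vector of study gene ids; must be a subset of
#'   `background`.
#' @param background character vector of background gene ids (the gene
#'   universe, e.g. all annotated genes on the scanned contigs).
#' @param term_map a `data.frame` (`term`, `gene_id`); genes outside the
#'   background are ignored.
#' @param fdr significance threshold on the adjusted p-value.
#' @return a `data.frame`, one row per term, sorted by p-value:
#'   `term`, `n_study`, `n_study_in_term`, `n_background`,
#'   `n_background_in_term`, `p_value`, `q_value`, `significant`.
#' @export
#' @examples
#' bg <- sprintf("g%02d", 1:20)
#' tm <- data.frame(term = "T1", gene_id = bg[1:5])
#' hypergeometric_enrichment(bg[1:5], bg, tm) # p = 1/choose(20, 5)
hypergeometric_enrichment <- function(study, background, term_map,
                                      fdr = 0.05) {
  study <- unique(study)
  background <- unique(background)
  extra <- setdiff(study, background)
  if (length(extra))
    stop("study gene(s) not in background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  terms <- sort(unique(tm$term))
  n_bg <- length(background)
  n_st <- length(study)
  rows <- lapply(terms, function(t) {
    in_term <- unique(tm$gene_id[tm$term == t])
    k <- sum(study %in% in_term)
    m <- length(in_term)
    p <- if (k == 0L) 1 else
      phyper(k - 1L, m, n_bg - m, n_st, lower.tail = FALSE)
    data.frame(term = t, n_study = n_st, n_study_in_term = k,
               n_background = n_bg, n_background_in_term = m,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(), n_study = integer(),
               n_study_in_term = integer(), n_background = integer(),
               n_background_in_term = integer(), p_value = numeric(),
               stringsAsFactors = FALSE)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < fdr
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' The standard step-up procedure: for sorted p-values,
#' q_(i) = min over j >= i of m * p_(j) / j, capped at 1 and mapped back
#' to the input order.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.04)) # 0.02 0.04
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}
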