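#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated
#' object: per-layer calling thresholds, the two-level integration and
#' network-level anti-correlation cutoffs, the co-expression minimum, the
#' promoter half-width, methylation tile size, and the master seed. The
#' configuration is echoed verbatim (as JSON) into every output directory.
#'
#' @param output_dir directory stage outputs are written to.
#' @param seed master integer seed; all stage randomness derives from it.
#' @param thresholds named list of [threshold_set]s for `deg`, `demir`,
#'   `dmr` (default [default_thresholds]).
#' @param pcc_2level,p_2level strict cutoffs for anticorrelation at the
#'   integration level (defaults -0.5, 0.05).
#' @param pcc_network,p_network permissive cutoffs for the miRNA network
#'   (defaults -0.1, 0.1).
#' @param coexpr_min minimum co-expression score (default 0.1).
#' @param promoter_half_width promoter window half-width in bp.
#' @param tile_size methylation tile size in bp.
#' @param keep_nonsignificant keep (flagged) network edges failing the
#'   network p cutoff.
#' @param simulate `NULL`, or a list of arguments to [build_scenario]
#'   (e.g. `list(category_spec = c(red = 1))`); when set, inputs are
#'   simulated.
#' @param records_path `NULL`, or a path to a worked-example record table
#'   (see [read_multiomics_records]); when set, the pipeline runs the
#'   integration stage directly on those records.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, seed = 1,
                            thresholds = default_thresholds(),
                            pcc_2level = -0.5, p_2level = 0.05,
                            pcc_network = -0.1, p_network = 0.1,
                            coexpr_min = 0.1, promoter_half_width = 2000,
                            tile_size = 100, keep_nonsignificant = TRUE,
                            simulate = NULL, records_path = NULL) {
  stopifnot(pcc_2level >= -1, pcc_2level <= 0, p_2level > 0, p_2level <= 1,
            pcc_network >= -1, pcc_network <= 0, p_network > 0,
            p_network <= 1, coexpr_min >= -1, coexpr_min <= 1,
            promoter_half_width > 0, tile_size >= 1)
  stopifnot(all(c("deg", "demir", "dmr") %in% names(thresholds)))
  if (is.null(simulate) && is.null(records_path))
    stop("configure either 'simulate' or 'records_path'")
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 thresholds = thresholds, pcc_2level = pcc_2level,
                 p_2level = p_2level, pcc_network = pcc_network,
                 p_network = p_network, coexpr_min = coexpr_min,
                 promoter_half_width = promoter_half_width,
                 tile_size = tile_size,
                 keep_nonsignificant = keep_nonsignificant,
                 simulate = simulate, records_path = records_path),
            class = "pipeline_config")
}

# summarize triples into the category report
.category_report <- function(triples) {
  genes <- unique(triples[c("gene_id", "category")])
  counts <- table(factor(genes$category,
                         levels = c("red", "blue", "green", "orange")))
  list(n_triples = nrow(triples),
       n_unique_genes = length(unique(triples$gene_id)),
       category_counts = as.list(counts),
       n_consistent = sum(genes$category %in% c("red", "blue")),
       n_inconsistent = sum(genes$category %in% c("green", "orange")))
}

#' Run the integration stages on an input bundle
#'
#' The in-memory core of [run_pipeline]: calls differential features on
#' every layer, filters and annotates methylated regions, applies the
#' anti-correlation filter, and builds the three-level integration triples
#' and the miRNA network.
#'
#' @param bundle a `scenario_bundle` (or a list with the same elements,
#'   e.g. assembled from files).
#' @param config a [pipeline_config].
#' @return list with `degs`, `demirs`, `dmrs`, `assignments`,
#'   `promoter_dmrs`, `dmr_deg_pairs`, `anticorr`, `triples`, `network`,
#'   `report`.
#' @export
run_multiomics <- function(bundle, config) {
  th <- config$thresholds
  degs <- classify_records(test_counts(bundle$gene_counts, layer = "gene"),
                           th$deg)
  demirs <- classify_records(test_counts(bundle$mirna_counts,
                                         layer = "mirna"), th$demir)
  meth <- coverage_filter(filter_low_coverage_regions(bundle$meth))
  dmrs <- classify_records(test_methylation(meth), th$dmr)
  assignments <- annotate_regions(meth$regions, bundle$annotation,
                                  config$promoter_half_width)
  promoter_dmrs <- promoter_dmr_table(dmrs, assignments)
  dmr_deg_pairs <- link_dmr_deg(
    cbind(promoter_dmrs[c("gene_id", "region_id", "log2fc", "p_value",
                          "fdr", "direction")]), degs)
  anticorr <- link_demir_targets(demirs, bundle$targets, degs,
                                 bundle$gene_expr, bundle$mirna_expr,
                                 pcc_cut = config$pcc_2level,
                                 p_cut = config$p_2level)
  triples <- integrate_three_level(promoter_dmrs, degs, anticorr)
  network_input <- link_demir_targets(demirs, bundle$targets, degs,
                                      bundle$gene_expr, bundle$mirna_expr,
                                      pcc_cut = config$pcc_network,
                                      p_cut = 1)
  network <- build_mirna_network(network_input,
                                 pcc_cut = config$pcc_network,
                                 p_cut = config$p_network,
                                 keep_nonsignificant =
                                   config$keep_nonsignificant)
  report <- c(.category_report(triples),
              list(n_degs = sum(degs$direction != "ns"),
                   n_demirs = sum(demirs$direction != "ns"),
                   n_dmrs = sum(dmrs$direction != "ns"),
                   n_regions_tested = nrow(dmrs),
                   n_anticorr = nrow(anticorr),
                   n_network_edges = nrow(network$edges)))
  list(degs = degs, demirs = demirs, dmrs = dmrs, assignments = assignments,
       promoter_dmrs = promoter_dmrs, dmr_deg_pairs = dmr_deg_pairs,
       anticorr = anticorr, triples = triples, network = network,
       report = report)
}

#' Run the pipeline end to end
#'
#' Either simulates a full input bundle (`simulate` mode) and runs every
#' stage, or runs the integration stage directly on a worked-example record
#' table (`records_path` mode). Stage outputs are written with stable
#' filenames under the configured output directory; reruns with an
#' identical configuration and seed are byte-identical. The configuration
#' itself is echoed to `config.json` and a summary report with per-stage
#' record counts and the category table to `report.json`.
#'
#' @param config a [pipeline_config].
#' @return invisibly, the result list (for `simulate` mode the value of
#'   [run_multiomics] plus `bundle`; for `records_path` mode the triples
#'   and report).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  echo <- config
  echo$thresholds <- lapply(echo$thresholds, unclass)
  jsonlite::write_json(unclass(echo),
                       file.path(config$output_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  out_tsv <- function(df, name)
    write_records(df, file.path(config$output_dir, name))

  if (!is.null(config$records_path)) {
    records <- read_multiomics_records(config$records_path)
    inputs <- records_as_integration_inputs(records)
    triples <- integrate_three_level(inputs$promoter_dmrs, inputs$degs,
                                     inputs$anticorr)
    report <- .category_report(triples)
    out_tsv(triples, "triples.tsv")
    jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(list(triples = triples, report = report)))
  }

  sim_args <- config$simulate
  sim_args$seed <- config$seed
  bundle <- do.call(build_scenario, sim_args)
  res <- run_multiomics(bundle, config)
  out_tsv(res$degs, "degs.tsv")
  out_tsv(res$demirs, "demirs.tsv")
  out_tsv(res$dmrs, "dmrs.tsv")
  out_tsv(res$assignments, "assignments.tsv")
  out_tsv(res$anticorr, "anticorr.tsv")
  out_tsv(res$triples, "triples.tsv")
  write_edge_list(res$network, file.path(config$output_dir, "network.tsv"))
  jsonlite::write_json(res$report,
                       file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(res, list(bundle = bundle)))
}
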