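#' Pearson correlation with t-test p-value
#'
#' Sample Pearson correlation with the two-sided p-value from the t
#' transform on n - 2 degrees of freedom. Constant vectors have no defined
#' correlation and return `NA` for both values.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with elements `pcc` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("vectors of unequal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(pcc = NA_real_, p = NA_real_))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(pcc = unname(ct$estimate), p = ct$p.value)
}

#' Link promoter DMRs to inversely changed genes (two-level integration)
#'
#' Pairs each significant promoter methylation change with a significant
#' gene change in the opposite direction on the same gene: hypermethylated
#' promoter with downregulated gene, or hypomethylated promoter with
#' upregulated gene. Pairs with concordant directions are not emitted here;
#' they surface later as the inconsistent categories of the three-level
#' integration.
#'
#' @param promoter_dmrs data.frame of DMR records restricted to promoter
#'   regions, carrying `gene_id`, `log2fc`, `p_value`, `direction`
#'   (`up` = hypermethylated, `down` = hypomethylated); see
#'   [promoter_dmr_table].
#' @param degs data.frame of classified gene differential records.
#' @return data.frame with one row per inverse pair: `gene_id`,
#'   `region_id`, `dmr_log2fc`, `dmr_p`, `deg_log2fc`, `deg_fdr`,
#'   `dmr_direction`, `deg_direction`.
#' @export
link_dmr_deg <- function(promoter_dmrs, degs) {
  degs <- degs[degs$direction %in% c("up", "down"), , drop = FALSE]
  dm <- promoter_dmrs[promoter_dmrs$direction %in% c("up", "down"), ,
                      drop = FALSE]
  j <- merge(dm, degs, by.x = "gene_id", by.y = "feature_id",
             suffixes = c(".dmr", ".deg"))
  inv <- (j$direction.dmr == "up" & j$direction.deg == "down") |
         (j$direction.dmr == "down" & j$direction.deg == "up")
  j <- j[inv, , drop = FALSE]
  out <- data.frame(gene_id = j$gene_id, region_id = j$region_id,
                    dmr_log2fc = j$log2fc.dmr, dmr_p = j$p_value.dmr,
                    deg_log2fc = j$log2fc.deg, deg_fdr = j$fdr.deg,
                    dmr_direction = ifelse(j$direction.dmr == "up",
                                           "hyper", "hypo"),
                    deg_direction = j$direction.deg,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene_id, out$region_id), , drop = FALSE]
}

#' Link promoter DMRs at miRNA host loci to inversely changed miRNAs
#'
#' The same inverse-relationship rule as [link_dmr_deg], applied with the
#' miRNA as the regulated feature. Because the relationship between a
#' methylation mark and the miRNA it hosts is treated as reciprocal, both
#' inverse orientations (hyper + down and hypo + up) are emitted, each row
#' flagged with its orientation.
#'
#' @param promoter_dmrs data.frame of DMR records at miRNA host promoters,
#'   with `gene_id` holding the miRNA id.
#' @param demirs data.frame of classified miRNA differential records.
#' @return data.frame analogous to [link_dmr_deg] with `mirna_id` and an
#'   `orientation` column.
#' @export
link_dmr_demir <- function(promoter_dmrs, demirs) {
  pairs <- link_dmr_deg(promoter_dmrs, demirs)
  if (!nrow(pairs)) {
    pairs$orientation <- character(0)
  } else {
    pairs$orientation <- ifelse(pairs$dmr_direction == "hyper",
                                "hyper_down", "hypo_up")
  }
  names(pairs)[names(pairs) == "gene_id"] <- "mirna_id"
  names(pairs)[names(pairs) == "deg_log2fc"] <- "demir_log2fc"
  names(pairs)[names(pairs) == "deg_fdr"] <- "demir_fdr"
  names(pairs)[names(pairs) == "deg_direction"] <- "demir_direction"
  pairs
}

#' Anti-correlation filtering of miRNA-target interactions
#'
#' For every (miRNA, gene) pair of the target table where both features are
#' significantly changed in opposite directions, the Pearson correlation of
#' their expression across all samples (both groups pooled) is computed;
#' interactions are retained iff `pcc < pcc_cut` and `p < p_cut`, both
#' strict.
#'
#' @param demirs,degs classified differential record data.frames.
#' @param target_table data.frame with `mirna_id`, `gene_id`.
#' @param gene_expr,mirna_expr normalized expression matrices (features x
#'   samples) sharing the same sample order.
#' @param pcc_cut,p_cut strict retention cutoffs (defaults -0.5 and 0.05).
#' @return data.frame of anticorrelated interactions: `mirna_id`,
#'   `gene_id`, `pcc`, `pcc_p`, `mirna_direction`, `gene_direction`,
#'   `mirna_log2fc`, `gene_log2fc`, `mirna_fdr`, `gene_fdr`.
#' @export
link_demir_targets <- function(demirs, target_table, degs, gene_expr,
                               mirna_expr, pcc_cut = -0.5, p_cut = 0.05) {
  if (!identical(colnames(gene_expr), colnames(mirna_expr)))
    stop("gene and miRNA expression matrices must share sample ordering")
  demirs <- demirs[demirs$direction %in% c("up", "down"), , drop = FALSE]
  degs <- degs[degs$direction %in% c("up", "down"), , drop = FALSE]
  tt <- target_table[target_table$mirna_id %in% demirs$feature_id &
                     target_table$gene_id %in% degs$feature_id, ,
                     drop = FALSE]
  if (!nrow(tt)) return(.empty_anticorr())
  mi <- match(tt$mirna_id, demirs$feature_id)
  gi <- match(tt$gene_id, degs$feature_id)
  opposite <- demirs$direction[mi] != degs$direction[gi]
  tt <- tt[opposite, , drop = FALSE]
  mi <- mi[opposite]; gi <- gi[opposite]
  if (!nrow(tt)) return(.empty_anticorr())
  missing <- c(setdiff(tt$gene_id, rownames(gene_expr)),
               setdiff(tt$mirna_id, rownames(mirna_expr)))
  if (length(missing))
    stop("feature absent from its expression matrix: ",
         paste(unique(missing), collapse = ", "))
  res <- lapply(seq_len(nrow(tt)), function(i)
    pearson_with_p(mirna_expr[tt$mirna_id[i], ], gene_expr[tt$gene_id[i], ]))
  pcc <- vapply(res, `[[`, numeric(1), "pcc")
  pv <- vapply(res, `[[`, numeric(1), "p")
  keep <- !is.na(pcc) & pcc < pcc_cut & pv < p_cut
  out <- data.frame(mirna_id = tt$mirna_id, gene_id = tt$gene_id,
                    pcc = pcc, pcc_p = pv,
                    mirna_direction = demirs$direction[mi],
                    gene_direction = degs$direction[gi],
                    mirna_log2fc = demirs$log2fc[mi],
                    gene_log2fc = degs$log2fc[gi],
                    mirna_fdr = demirs$fdr[mi], gene_fdr = degs$fdr[gi],
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_anticorr <- function() {
  data.frame(mirna_id = character(), gene_id = character(), pcc = numeric(),
             pcc_p = numeric(), mirna_direction = character(),
             gene_direction = character(), mirna_log2fc = numeric(),
             gene_log2fc = numeric(), mirna_fdr = numeric(),
             gene_fdr = numeric(), stringsAsFactors = FALSE)
}

#' Four-way regulatory category of a (promoter DMR, gene, miRNA) triple
#'
#' Pure sign logic on the three direction calls. Consistent patterns:
#' hypermethylated promoter + downregulated gene + upregulated miRNA
#' (`red`), hypomethylated + upregulated gene + downregulated miRNA
#' (`blue`). Inconsistent patterns (methylation concordant with the gene):
#' hypermethylated + upregulated gene + downregulated miRNA (`green`),
#' hypomethylated + downregulated gene + upregulated miRNA (`orange`).
#' Combinations where the miRNA is not opposite to the gene are not
#' admissible triples and raise an error, as does any `ns` direction.
#'
#' @param dmr_dir `"hyper"` or `"hypo"` (also accepts `"up"`/`"down"`).
#' @param deg_dir,demir_dir `"up"` or `"down"`.
#' @return character vector of categories (`red`, `blue`, `green`,
#'   `orange`). Vectorized over its arguments.
#' @export
classify_category <- function(dmr_dir, deg_dir, demir_dir) {
  dmr_dir <- ifelse(dmr_dir == "up", "hyper",
                    ifelse(dmr_dir == "down", "hypo", dmr_dir))
  ok <- dmr_dir %in% c("hyper", "hypo") & deg_dir %in% c("up", "down") &
        demir_dir %in% c("up", "down")
  if (!all(ok))
    stop("all three directions must be significant calls (no 'ns')")
  if (any(deg_dir == demir_dir))
    stop("gene and miRNA directions must be opposite for an admissible triple")
  ifelse(dmr_dir == "hyper" & deg_dir == "down", "red",
  ifelse(dmr_dir == "hypo"  & deg_dir == "up",   "blue",
  ifelse(dmr_dir == "hyper" & deg_dir == "up",   "green", "orange")))
}

#' Build the promoter DMR table used by the integration stages
#'
#' Joins classified methylation records with region-to-gene assignments,
#' keeps significant promoter regions, and when a gene carries several
#' significant promoter DMRs retains the one with the smallest p-value.
#'
#' @param dmr_records classified methylation differential records.
#' @param assignments data.frame from [annotate_regions].
#' @return data.frame with `gene_id`, `region_id`, `log2fc`, `p_value`,
#'   `fdr`, `direction` (one row per gene).
#' @export
promoter_dmr_table <- function(dmr_records, assignments) {
  prom <- assignments[assignments$feature_class == "promoter", , drop = FALSE]
  sig <- dmr_records[dmr_records$direction %in% c("up", "down"), ,
                     drop = FALSE]
  j <- merge(sig, prom, by.x = "feature_id", by.y = "region_id")
  if (!nrow(j))
    return(data.frame(gene_id = character(), region_id = character(),
                      log2fc = numeric(), p_value = numeric(),
                      fdr = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  j <- j[order(j$gene_id, j$p_value, j$feature_id), , drop = FALSE]
  j <- j[!duplicated(j$gene_id), , drop = FALSE]
  out <- data.frame(gene_id = j$gene_id, region_id = j$feature_id,
                    log2fc = j$log2fc, p_value = j$p_value, fdr = j$fdr,
                    direction = j$direction, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Three-level multi-omics integration
#'
#' One triple is emitted per (gene, miRNA) combination where the gene has a
#' significant promoter DMR, is itself a significant differential gene, and
#' appears in an anticorrelated miRNA interaction; the four-way regulatory
#' category is attached. A gene targeted by several anticorrelated miRNAs
#' appears in several triples.
#'
#' @param promoter_dmrs data.frame from [promoter_dmr_table] (one row per
#'   gene, `direction` up = hypermethylated).
#' @param degs classified gene differential records.
#' @param anticorr data.frame of anticorrelated interactions from
#'   [link_demir_targets].
#' @return data.frame of integration triples: `gene_id`, `mirna_id`,
#'   `dmr_log2fc`, `dmr_p`, `deg_log2fc`, `deg_fdr`, `demir_log2fc`,
#'   `demir_fdr`, `category`.
#' @export
integrate_three_level <- function(promoter_dmrs, degs, anticorr) {
  degs <- degs[degs$direction %in% c("up", "down"), , drop = FALSE]
  if (!nrow(anticorr) || !nrow(promoter_dmrs) || !nrow(degs))
    return(.empty_triples())
  j <- merge(anticorr, promoter_dmrs, by = "gene_id",
             suffixes = c("", ".dmr"))
  j <- merge(j, degs[c("feature_id", "log2fc", "fdr", "direction")],
             by.x = "gene_id", by.y = "feature_id",
             suffixes = c(".dmr", ".deg"))
  if (!nrow(j)) return(.empty_triples())
  out <- data.frame(
    gene_id = j$gene_id, mirna_id = j$mirna_id,
    dmr_log2fc = j$log2fc.dmr, dmr_p = j$p_value,
    deg_log2fc = j$log2fc.deg, deg_fdr = j$fdr.deg,
    demir_log2fc = j$mirna_log2fc, demir_fdr = j$mirna_fdr,
    category = classify_category(j$direction.dmr, j$direction.deg,
                                 j$mirna_direction),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_triples <- function() {
  data.frame(gene_id = character(), mirna_id = character(),
             dmr_log2fc = numeric(), dmr_p = numeric(),
             deg_log2fc = numeric(), deg_fdr = numeric(),
             demir_log2fc = numeric(), demir_fdr = numeric(),
             category = character(), stringsAsFactors = FALSE)
}

#' Turn a worked-example record table into integration inputs
#'
#' Records read by [read_multiomics_records] already passed their layers'
#' calling thresholds in the originating analysis, so directions are taken
#' from the printed log2FC signs. The interactions are supplied as
#' threshold-passing anticorrelated pairs.
#'
#' @param records data.frame from [read_multiomics_records].
#' @return list with `promoter_dmrs`, `degs`, `anticorr`, ready for
#'   [integrate_three_level].
#' @export
records_as_integration_inputs <- function(records) {
  dir_of <- function(x) ifelse(x >= 0, "up", "down")
  gene_rows <- !duplicated(records$gene_id)
  promoter_dmrs <- data.frame(
    gene_id = records$gene_id[gene_rows],
    region_id = paste0("promoter:", records$gene_id[gene_rows]),
    log2fc = records$dmr_log2fc[gene_rows],
    p_value = records$dmr_p[gene_rows],
    fdr = records$dmr_p[gene_rows],
    direction = dir_of(records$dmr_log2fc[gene_rows]),
    stringsAsFactors = FALSE)
  degs <- data.frame(
    feature_id = records$gene_id[gene_rows], layer = "gene",
    base_mean = NA_real_,
    log2fc = records$deg_log2fc[gene_rows],
    p_value = records$deg_fdr[gene_rows],
    fdr = records$deg_fdr[gene_rows],
    direction = dir_of(records$deg_log2fc[gene_rows]),
    stringsAsFactors = FALSE)
  anticorr <- data.frame(
    mirna_id = records$mirna_id, gene_id = records$gene_id,
    pcc = NA_real_, pcc_p = NA_real_,
    mirna_direction = dir_of(records$mirna_log2fc),
    gene_direction = dir_of(records$deg_log2fc),
    mirna_log2fc = records$mirna_log2fc,
    gene_log2fc = records$deg_log2fc,
    mirna_fdr = records$mirna_fdr, gene_fdr = records$deg_fdr,
    stringsAsFactors = FALSE)
  list(promoter_dmrs = promoter_dmrs, degs = degs, anticorr = anticorr)
}
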