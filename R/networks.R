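#' Build the miRNA-centric regulatory network
#'
#' Directed miRNA -> gene edges from anti-correlated interactions at the
#' permissive network-level cutoffs. An edge must satisfy `pcc < pcc_cut`;
#' edges failing `p < p_cut` are dropped unless `keep_nonsignificant` is
#' set, in which case they are retained but flagged `significant = FALSE`.
#'
#' @param anticorr data.frame with at least `mirna_id`, `gene_id`, `pcc`,
#'   `pcc_p` (and optionally `mirna_log2fc`, `gene_log2fc` used to annotate
#'   nodes).
#' @param pcc_cut,p_cut network-level cutoffs (defaults -0.1 and 0.1,
#'   strict).
#' @param keep_nonsignificant keep edges failing the p cutoff, flagged.
#' @return an object of class `omics_network`: list with `nodes`
#'   (`id`, `kind`, `log2fc`) and `edges` (`source`, `target`, `weight`,
#'   `p_value`, `significant`, `type`).
#' @export
build_mirna_network <- function(anticorr, pcc_cut = -0.1, p_cut = 0.1,
                                keep_nonsignificant = FALSE) {
  keep <- !is.na(anticorr$pcc) & anticorr$pcc < pcc_cut
  sig <- !is.na(anticorr$pcc_p) & anticorr$pcc_p < p_cut
  if (!keep_nonsignificant) keep <- keep & sig
  e <- anticorr[keep, , drop = FALSE]
  edges <- data.frame(source = e$mirna_id, target = e$gene_id,
                      weight = e$pcc, p_value = e$pcc_p,
                      significant = sig[keep],
                      type = rep_len("mirna_target", nrow(e)),
                      stringsAsFactors = FALSE)
  if (any(edges$source == edges$target)) stop("self-edge in network")
  mir_lfc <- if ("mirna_log2fc" %in% names(e))
    tapply(e$mirna_log2fc, e$mirna_id, `[`, 1) else NULL
  gene_lfc <- if ("gene_log2fc" %in% names(e))
    tapply(e$gene_log2fc, e$gene_id, `[`, 1) else NULL
  mirnas <- sort(unique(edges$source)); genes <- sort(unique(edges$target))
  nodes <- data.frame(
    id = c(mirnas, genes),
    kind = rep(c("mirna", "gene"), c(length(mirnas), length(genes))),
    log2fc = c(if (is.null(mir_lfc)) rep(NA_real_, length(mirnas))
               else as.numeric(mir_lfc[mirnas]),
               if (is.null(gene_lfc)) rep(NA_real_, length(genes))
               else as.numeric(gene_lfc[genes])),
    stringsAsFactors = FALSE)
  rownames(edges) <- rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "omics_network")
}

#' @export
print.omics_network <- function(x, ...) {
  cat(sprintf("omics_network: %d nodes (%d miRNAs), %d edges\n",
              nrow(x$nodes), sum(x$nodes$kind == "mirna"), nrow(x$edges)))
  invisible(x)
}

# internal: directed igraph from an omics_network
.as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges[c("source", "target")],
                                directed = TRUE,
                                vertices = network$nodes$id)
}

#' Rank miRNA hubs by out-degree
#'
#' Hub strength is the number of targeted genes (out-degree in the directed
#' miRNA -> gene network); ties are broken lexicographically by id.
#'
#' @param network an `omics_network`.
#' @return data.frame with `mirna_id` and `degree`, ordered by decreasing
#'   degree.
#' @export
hub_ranking <- function(network) {
  if (!nrow(network$edges)) stop("empty network")
  g <- .as_igraph(network)
  deg <- igraph::degree(g, mode = "out")
  mirnas <- network$nodes$id[network$nodes$kind == "mirna"]
  deg <- deg[mirnas]
  o <- order(-deg, names(deg))
  data.frame(mirna_id = names(deg)[o], degree = as.integer(deg[o]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Shared targets of two miRNAs
#'
#' @param network an `omics_network`.
#' @param mirna_a,mirna_b miRNA ids present in the network.
#' @return sorted character vector of genes targeted by both.
#' @export
shared_targets <- function(network, mirna_a, mirna_b) {
  mirnas <- network$nodes$id[network$nodes$kind == "mirna"]
  missing <- setdiff(c(mirna_a, mirna_b), mirnas)
  if (length(missing))
    stop("unknown miRNA id(s): ", paste(missing, collapse = ", "))
  ta <- network$edges$target[network$edges$source == mirna_a]
  tb <- network$edges$target[network$edges$source == mirna_b]
  sort(intersect(ta, tb))
}

#' Co-expression edges among genes
#'
#' Scores candidate gene-gene edges by the Pearson correlation of their
#' normalized expression (e.g. FPKM) across samples and retains edges with
#' `pcc >= pcc_min`. Edges with a constant expression vector are dropped
#' with a warning. The returned data.frame carries a `summary` attribute
#' with the fraction of retained edges scoring above 0.5 versus at or
#' below 0.5.
#'
#' @param seed_genes character vector of genes of interest (at least one
#'   endpoint of every candidate edge should be in it; informational only).
#' @param candidate_edges data.frame with columns `source`, `target`.
#' @param expr normalized expression matrix (genes x samples).
#' @param pcc_min minimum co-expression score (default 0.1, inclusive).
#' @return data.frame `source`, `target`, `weight`, `p_value`,
#'   `significant`, `type = "coexpression"`.
#' @export
coexpression_edges <- function(seed_genes, candidate_edges, expr,
                               pcc_min = 0.1) {
  missing <- setdiff(unique(c(candidate_edges$source,
                              candidate_edges$target)), rownames(expr))
  if (length(missing))
    stop("edge endpoint absent from expression matrix: ",
         paste(missing, collapse = ", "))
  n <- nrow(candidate_edges)
  pcc <- pv <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    x <- expr[candidate_edges$source[i], ]
    y <- expr[candidate_edges$target[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    r <- pearson_with_p(x, y)
    pcc[i] <- r$pcc; pv[i] <- r$p
  }
  dropped <- sum(is.na(pcc))
  if (dropped)
    warning(dropped, " edge(s) dropped: constant expression vector")
  keep <- !is.na(pcc) & pcc >= pcc_min
  out <- data.frame(source = candidate_edges$source[keep],
                    target = candidate_edges$target[keep],
                    weight = pcc[keep], p_value = pv[keep],
                    significant = pv[keep] < 0.05,
                    type = rep_len("coexpression", sum(keep)),
                    stringsAsFactors = FALSE, row.names = NULL)
  strong <- if (nrow(out)) mean(out$weight > 0.5) else NA_real_
  attr(out, "summary") <- c(frac_above_0.5 = strong,
                            frac_at_or_below_0.5 = 1 - strong)
  out
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each gene set against a query gene
#' list: with the universe as the population, the set's members in the
#' universe as successes and the query as draws, p = P(X >= overlap). Gene
#' sets are intersected with the universe first; only sets overlapping the
#' query by at least one gene are reported. Adjustment is
#' Benjamini-Hochberg or Bonferroni over all tested sets.
#'
#' @param query character vector of genes of interest (must be a subset of
#'   the universe).
#' @param gene_sets named list of character vectors, e.g. from [read_gmt].
#' @param universe character vector of all assayed genes.
#' @param correction `"bh"` or `"bonferroni"`.
#' @return data.frame with `set_name`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `adjusted_p`, ordered by p.
#' @export
hypergeometric_ora <- function(query, gene_sets, universe,
                               correction = c("bh", "bonferroni")) {
  correction <- match.arg(correction)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query genes outside the universe: ",
         paste(outside, collapse = ", "))
  sets <- lapply(gene_sets, intersect, universe)
  overlap <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
  K <- lengths(sets)
  N <- length(universe); n <- length(query)
  p <- stats::phyper(overlap - 1, K, N - K, n, lower.tail = FALSE)
  adj <- if (correction == "bh") bh_adjust(p) else pmin(1, p * length(p))
  out <- data.frame(set_name = names(sets), overlap = overlap,
                    set_size = K, query_size = n, universe_size = N,
                    p = p, adjusted_p = adj, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[out$overlap >= 1, , drop = FALSE]
  out[order(out$p, out$set_name), , drop = FALSE]
}
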