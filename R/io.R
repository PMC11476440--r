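#' Read a tab-separated count matrix
#'
#' The file must carry a header row of sample ids; the first column holds
#' feature ids. Counts must be non-negative integers; duplicated feature ids
#' and rows of the wrong length are rejected.
#'
#' @param path path to a TSV file.
#' @param group_map named character vector mapping every sample id in the
#'   header to `control` or `treated`.
#' @return a [count_matrix] object.
#' @export
read_count_matrix <- function(path, group_map) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty count matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  samples <- header[-1]
  ncol_expected <- length(header)
  for (i in seq_along(fields)[-1]) {
    if (length(fields[[i]]) != ncol_expected)
      stop(sprintf("malformed row at line %d of %s: expected %d fields, got %d",
                   i, path, ncol_expected, length(fields[[i]])))
  }
  body <- fields[-1]
  ids <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- vapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) stop("non-numeric count in ", path)
    v
  }, numeric(length(samples)))
  m <- if (is.null(dim(vals))) matrix(vals, nrow = 1) else t(vals)
  dimnames(m) <- list(ids, samples)
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers in ", path)
  unknown <- setdiff(samples, names(group_map))
  if (length(unknown))
    stop("samples missing from group_map: ", paste(unknown, collapse = ", "))
  count_matrix(m, group_map)
}

#' Write a count matrix as TSV
#'
#' @param x a [count_matrix] object or a plain matrix with dimnames.
#' @param path output path.
#' @export
write_count_matrix <- function(x, path) {
  m <- if (inherits(x, "count_matrix")) x$counts else x
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Bismark-style coverage file
#'
#' Expects the 6-column coverage dialect: chromosome, start, end (1-based
#' inclusive), methylation percentage, count methylated, count unmethylated.
#' Coordinates are converted to the internal 0-based half-open convention.
#' A methylation percentage inconsistent with the counts by more than 0.1
#' is flagged with a warning (the counts win); negative counts are fatal.
#' Positions with zero total reads are retained with an `NA` fraction.
#'
#' @param path path to the coverage file (whitespace- or tab-separated).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `meth_count`, `unmeth_count`, `fraction`.
#' @export
read_bismark_coverage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 6)
    stop("expected 6 columns in Bismark coverage file ", path,
         ", got ", ncol(df))
  names(df) <- c("chrom", "start1", "end1", "pct", "meth_count", "unmeth_count")
  if (any(df$meth_count < 0) || any(df$unmeth_count < 0))
    stop("negative counts in ", path)
  total <- df$meth_count + df$unmeth_count
  frac <- ifelse(total > 0, df$meth_count / total, NA_real_)
  bad <- which(total > 0 & abs(df$pct - 100 * frac) > 0.1)
  if (length(bad))
    warning(sprintf(
      "%d record(s) in %s have a methylation %% inconsistent with counts (first at line %d: %.1f reported, %.1f expected)",
      length(bad), path, bad[1], df$pct[bad[1]], 100 * frac[bad[1]]))
  data.frame(chrom = df$chrom, start = df$start1 - 1L, end = df$end1,
             meth_count = df$meth_count, unmeth_count = df$unmeth_count,
             fraction = frac, stringsAsFactors = FALSE)
}

#' Write per-sample Bismark-style coverage files
#'
#' One file per sample of a [methylation_experiment], with 1-based inclusive
#' coordinates spanning each region (the inverse of [read_bismark_coverage]
#' followed by [tile_methylation] on per-position data).
#'
#' @param exp a [methylation_experiment].
#' @param dir output directory; files are named `<sample>.cov`.
#' @return invisibly, the vector of paths written.
#' @export
write_bismark_coverage <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in colnames(exp$M)) {
    M <- exp$M[, s]; U <- exp$U[, s]
    total <- M + U
    pct <- ifelse(total > 0, round(100 * M / total, 4), 0)
    df <- data.frame(exp$regions$chrom, exp$regions$start + 1L,
                     exp$regions$end, pct, M, U)
    p <- file.path(dir, paste0(s, ".cov"))
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Aggregate per-position methylation records into fixed-width tiles
#'
#' Differential methylation is tested on regions; per-position coverage
#' records are summed into non-overlapping genomic tiles of `tile_size`
#' base pairs anchored at position 0 of each chromosome.
#'
#' @param records data.frame as returned by [read_bismark_coverage].
#' @param tile_size tile width in bp (default 100).
#' @return data.frame with columns `region_id`, `chrom`, `start`, `end`,
#'   `meth_count`, `unmeth_count`.
#' @export
tile_methylation <- function(records, tile_size = 100) {
  stopifnot(tile_size >= 1)
  tile <- floor(records$start / tile_size)
  key <- paste(records$chrom, tile, sep = ":")
  M <- tapply(records$meth_count, key, sum)
  U <- tapply(records$unmeth_count, key, sum)
  parts <- strsplit(names(M), ":", fixed = TRUE)
  chrom <- vapply(parts, `[[`, character(1), 1)
  t0 <- as.integer(vapply(parts, `[[`, character(1), 2))
  out <- data.frame(chrom = chrom, start = t0 * tile_size,
                    end = (t0 + 1L) * tile_size,
                    meth_count = as.numeric(M), unmeth_count = as.numeric(U),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(region_id = sprintf("%s:%d-%d", out$chrom, out$start, out$end),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a miRNA-to-target-gene interaction table
#'
#' Requires at least two columns (miRNA id, gene id); a third column, when
#' present, is kept as a free-text evidence tag. Pairs are de-duplicated on
#' (miRNA, gene), keeping the first occurrence, so the same interaction
#' listed under several evidence classes counts once.
#'
#' @param path path to a TSV file with a header row.
#' @return data.frame with columns `mirna_id`, `gene_id`, `evidence_tag`.
#' @export
read_target_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    return(data.frame(mirna_id = character(), gene_id = character(),
                      evidence_tag = character(), stringsAsFactors = FALSE))
  if (ncol(df) < 2) stop("target table needs at least 2 columns")
  out <- data.frame(mirna_id = as.character(df[[1]]),
                    gene_id = as.character(df[[2]]),
                    evidence_tag = if (ncol(df) >= 3) as.character(df[[3]])
                                   else NA_character_,
                    stringsAsFactors = FALSE)
  bad <- function(x) anyNA(x) | any(!nzchar(x[!is.na(x)]))
  if (bad(out$mirna_id) || bad(out$gene_id))
    stop("empty id field in target table ", path)
  out[!duplicated(out[c("mirna_id", "gene_id")]), , drop = FALSE]
}

#' Read gene sets in GMT format
#'
#' @param path path to a GMT file (set name, description, then members,
#'   tab-separated).
#' @return named list of character vectors of member ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm))
    stop("duplicate gene-set names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  sets
}

#' Write / read a network edge list
#'
#' Edge lists are TSV with the fixed column order `source`, `target`,
#' `weight`, `p_value`, `significant`, `type`; writer and reader are exact
#' inverses on valid data.
#'
#' @param network an `omics_network` (see [build_mirna_network]) or a bare
#'   edge data.frame with those columns.
#' @param path file path.
#' @return `read_edge_list` returns the edge data.frame.
#' @export
write_edge_list <- function(network, path) {
  edges <- if (inherits(network, "omics_network")) network$edges else network
  cols <- c("source", "target", "weight", "p_value", "significant", "type")
  missing <- setdiff(cols, names(edges))
  for (m in missing) edges[[m]] <- NA
  utils::write.table(edges[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a differential-record table as TSV
#'
#' @param records data.frame of differential records.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a worked-example table of integrated multi-omics records
#'
#' Reads a TSV holding one row per (gene, miRNA) association with the three
#' layers of printed evidence: promoter DMR log2FC and p-value, gene log2FC
#' and FDR, and targeting miRNA log2FC and FDR, plus the published category
#' colour. Such tables encode records that already passed each layer's
#' calling thresholds, so directions are taken from the log2FC signs.
#'
#' The package ships one such table
#' (`system.file("extdata", "il6_kidney_multiomics_records.tsv",
#' package = "triomix")`): the 21 promoter-DMR / DEG / DEmiR associations
#' over 19 genes reported in a perinatal IL-6 newborn mouse kidney study,
#' used as the worked example throughout the documentation.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `category`, `gene_id`, `dmr_log2fc`,
#'   `dmr_p`, `deg_log2fc`, `deg_fdr`, `mirna_id`, `mirna_log2fc`,
#'   `mirna_fdr`.
#' @export
read_multiomics_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("category", "gene_id", "dmr_log2fc", "dmr_p", "deg_log2fc",
            "deg_fdr", "mirna_id", "mirna_log2fc", "mirna_fdr")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("multi-omics record table missing columns: ",
         paste(missing, collapse = ", "))
  df
}
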