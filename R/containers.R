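#' Construct a validated count matrix
#'
#' The basic expression container used throughout the package: an integer
#' matrix of read counts (features in rows, samples in columns) together with
#' a `control`/`treated` group label for every sample.
#'
#' @param counts integer matrix with feature ids as rownames and sample ids
#'   as colnames. All values must be non-negative integers.
#' @param groups named character vector mapping every sample id to
#'   `"control"` or `"treated"`.
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   and `groups`.
#' @export
count_matrix <- function(counts, groups) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids in count matrix")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  groups <- groups[colnames(counts)]
  if (!all(groups %in% c("control", "treated")))
    stop("group labels must be 'control' or 'treated'")
  storage.mode(counts) <- "double"
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%d control, %d treated)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$groups == "control"), sum(x$groups == "treated")))
  invisible(x)
}

#' Construct a methylation experiment
#'
#' Holds per-region, per-sample methylated/unmethylated read counts. Region
#' coordinates are 0-based half-open, the package-wide internal convention.
#'
#' @param regions data.frame with columns `region_id`, `chrom`, `start`,
#'   `end`, `context` (one of CpG, CHG, CHH, mixed).
#' @param M,U numeric matrices (regions x samples) of methylated and
#'   unmethylated read counts; rownames must match `regions$region_id`.
#' @param groups named character vector mapping sample ids to
#'   `control`/`treated`.
#' @return an object of class `methylation_experiment`.
#' @export
methylation_experiment <- function(regions, M, U, groups) {
  stopifnot(is.data.frame(regions),
            all(c("region_id", "chrom", "start", "end", "context") %in%
                  names(regions)))
  if (any(regions$end <= regions$start)) stop("empty methylation region")
  if (anyDuplicated(regions$region_id)) stop("duplicate region ids")
  if (!identical(dim(M), dim(U))) stop("M and U dimensions differ")
  if (any(M < 0) || any(U < 0)) stop("negative methylation counts")
  if (!identical(rownames(M), regions$region_id))
    stop("M rownames must match regions$region_id")
  missing <- setdiff(colnames(M), names(groups))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  structure(list(regions = regions, M = M, U = U,
                 groups = groups[colnames(M)]),
            class = "methylation_experiment")
}

#' @export
print.methylation_experiment <- function(x, ...) {
  cat(sprintf("methylation_experiment: %d regions x %d samples\n",
              nrow(x$regions), ncol(x$M)))
  invisible(x)
}

#' Threshold set for differential calling
#'
#' Bundles the absolute log2 fold-change cutoff with the significance cutoff
#' and which column (raw p or BH FDR) it applies to. Defaults per layer:
#' genes and miRNAs are called at |log2FC| >= 0.5 and FDR <= 0.05;
#' methylated regions at |log2FC| >= 1 and raw p <= 0.05.
#'
#' @param lfc_cut non-negative absolute log2 fold-change cutoff.
#' @param sig_cut significance cutoff in (0, 1].
#' @param sig_kind `"fdr"` or `"p"`: which significance column the cutoff
#'   applies to.
#' @return an object of class `threshold_set`.
#' @export
threshold_set <- function(lfc_cut = 0.5, sig_cut = 0.05, sig_kind = c("fdr", "p")) {
  sig_kind <- match.arg(sig_kind)
  stopifnot(is.numeric(lfc_cut), lfc_cut >= 0,
            is.numeric(sig_cut), sig_cut > 0, sig_cut <= 1)
  structure(list(lfc_cut = lfc_cut, sig_cut = sig_cut, sig_kind = sig_kind),
            class = "threshold_set")
}

#' Default per-layer thresholds
#'
#' @return named list of `threshold_set` objects for the `deg`, `demir` and
#'   `dmr` layers.
#' @export
default_thresholds <- function() {
  list(deg   = threshold_set(0.5, 0.05, "fdr"),
       demir = threshold_set(0.5, 0.05, "fdr"),
       dmr   = threshold_set(1.0, 0.05, "p"))
}

# empty differential record table with canonical columns
empty_records <- function() {
  data.frame(feature_id = character(), layer = character(),
             base_mean = numeric(), log2fc = numeric(),
             p_value = numeric(), fdr = numeric(),
             direction = character(), stringsAsFactors = FALSE)
}
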