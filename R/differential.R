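#' Median-of-ratios library size factors
#'
#' Computes per-sample size factors against a geometric-mean pseudo-reference
#' built from features observed in every sample, the standard normalization
#' for two-group count comparisons. Factors are rescaled to geometric mean 1.
#'
#' @param counts a [count_matrix] or a bare counts matrix.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
normalize_libraries <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (all(m == 0)) stop("all-zero count matrix cannot be normalized")
  loggeo <- rowMeans(log(m))
  usable <- is.finite(loggeo)
  if (!any(usable))
    stop("no feature is observed in every sample; cannot form a reference")
  sf <- apply(m, 2, function(col)
    exp(stats::median((log(col) - loggeo)[usable & col > 0])))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("degenerate size factor; check for samples with no usable counts")
  sf / exp(mean(log(sf)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in rank and capped at 1. Input values
#' outside [0, 1] are an error.
#'
#' @param p_values numeric vector of p-values.
#' @return adjusted values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Negative-binomial differential test for count data
#'
#' Per-layer differential calling for genes or miRNAs: libraries are
#' normalized by median-of-ratios, features with normalized mean below
#' `min_norm_mean` are removed first (the independent low-count filter),
#' log2 fold-changes (treated vs control) use a pseudocount, and a Wald
#' statistic on the log mean ratio uses a moderated dispersion: the
#' per-feature method-of-moments estimate is shrunk towards the
#' across-feature median (weight `dispersion_shrink`) and floored at
#' `dispersion_floor`. Because moderation adds information beyond the
#' per-feature replicates, the statistic is referred to a t distribution
#' with `2 * (n1 + n2 - 2)` degrees of freedom, which calibrates the test
#' to its nominal level in small designs. FDR is Benjamini-Hochberg over
#' the tested features.
#'
#' @param counts a [count_matrix]; both groups need >= 2 samples.
#' @param layer label stored in the output records (`"gene"` or `"mirna"`).
#' @param pseudocount added to group means for the fold-change.
#' @param dispersion_floor lower bound on the dispersion estimate.
#' @param dispersion_shrink weight in [0, 1] pulling each per-feature
#'   dispersion towards the across-feature median.
#' @param min_norm_mean independent filter: features with normalized mean
#'   below this are dropped before testing.
#' @return data.frame of differential records: `feature_id`, `layer`,
#'   `base_mean`, `log2fc`, `p_value`, `fdr`, `direction` (all `"ns"` until
#'   [classify_records] is applied).
#' @export
test_counts <- function(counts, layer = "gene", pseudocount = 0.5,
                        dispersion_floor = 0.01, dispersion_shrink = 0.7,
                        min_norm_mean = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  g1 <- names(counts$groups)[counts$groups == "control"]
  g2 <- names(counts$groups)[counts$groups == "treated"]
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs at least 2 samples")
  sf <- normalize_libraries(counts)
  nc <- sweep(counts$counts, 2, sf, "/")
  keep <- rowMeans(nc) >= min_norm_mean
  nc <- nc[keep, , drop = FALSE]
  if (!nrow(nc)) return(empty_records())
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(nc[, g1, drop = FALSE])
  m2 <- rowMeans(nc[, g2, drop = FALSE])
  v1 <- apply(nc[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(nc[, g2, drop = FALSE], 1, stats::var)
  # method-of-moments NB dispersion per group, averaged, then moderated
  # towards the across-feature median and floored
  dmom <- ((v1 - m1) / pmax(m1, 0.5)^2 + (v2 - m2) / pmax(m2, 0.5)^2) / 2
  dcommon <- stats::median(dmom, na.rm = TRUE)
  disp <- pmax(dispersion_floor,
               (1 - dispersion_shrink) * dmom + dispersion_shrink * dcommon)
  log2fc <- log2((m2 + pseudocount) / (m1 + pseudocount))
  # delta-method variance of the log mean ratio under the NB model
  se_log <- sqrt((1 / pmax(m1, 0.5) + disp) / n1 +
                 (1 / pmax(m2, 0.5) + disp) / n2)
  tstat <- (log2fc * log(2)) / se_log
  p <- 2 * stats::pt(-abs(tstat), df = 2 * (n1 + n2 - 2))
  data.frame(feature_id = rownames(nc), layer = layer,
             base_mean = (m1 * n1 + m2 * n2) / (n1 + n2),
             log2fc = log2fc, p_value = p, fdr = bh_adjust(p),
             direction = "ns", stringsAsFactors = FALSE, row.names = NULL)
}

#' Set up/down/ns directions from a threshold set
#'
#' A record is `up` iff `log2fc >= +lfc_cut` and its significance value
#' (p or FDR, per the threshold set) is `<= sig_cut`; `down` with the
#' mirrored fold-change condition; otherwise `ns`. All comparisons are
#' inclusive.
#'
#' @param records differential record data.frame (from [test_counts] or
#'   [test_methylation]).
#' @param thresholds a [threshold_set].
#' @return the records with `direction` filled in.
#' @export
classify_records <- function(records, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  if (!nrow(records)) return(records)
  sig <- if (thresholds$sig_kind == "fdr") records$fdr else records$p_value
  up <- records$log2fc >= thresholds$lfc_cut & sig <= thresholds$sig_cut
  down <- records$log2fc <= -thresholds$lfc_cut & sig <= thresholds$sig_cut
  records$direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
  records
}

#' Remove regions with widespread low coverage
#'
#' A region is removed iff the number of samples whose total reads
#' (methylated + unmethylated) fall below `min_reads` is at least
#' `frac_samples` of all samples.
#'
#' @param exp a [methylation_experiment].
#' @param min_reads per-sample read total below which a sample counts as
#'   low (default 4).
#' @param frac_samples fraction of low samples at which the region is
#'   dropped (default 0.5).
#' @return the experiment restricted to retained regions.
#' @export
filter_low_coverage_regions <- function(exp, min_reads = 4,
                                        frac_samples = 0.5) {
  stopifnot(inherits(exp, "methylation_experiment"))
  total <- exp$M + exp$U
  n_low <- rowSums(total < min_reads)
  keep <- n_low < frac_samples * ncol(total)
  subset_methylation(exp, keep)
}

# restrict a methylation experiment to a logical/index vector of regions
subset_methylation <- function(exp, keep) {
  methylation_experiment(exp$regions[keep, , drop = FALSE],
                         exp$M[keep, , drop = FALSE],
                         exp$U[keep, , drop = FALSE], exp$groups)
}

#' Likelihood-ratio differential methylation test
#'
#' Per region, counts are pooled within groups; the log2 fold-change is the
#' log2 odds ratio of methylation (treated vs control) with a 0.5
#' pseudocount on all four cells, and the p-value comes from a
#' likelihood-ratio test of a two-group binomial-logistic model against the
#' pooled single-proportion model (1 df chi-square). BH FDR is reported
#' alongside, though region calling conventionally uses the raw p-value.
#'
#' @param exp a [methylation_experiment] that already passed the coverage
#'   filters; both groups need >= 2 samples.
#' @param pseudocount added to each cell of the pooled 2x2 table for the
#'   odds ratio.
#' @return data.frame of differential records with `layer =
#'   "methyl-region"`.
#' @export
test_methylation <- function(exp, pseudocount = 0.5) {
  stopifnot(inherits(exp, "methylation_experiment"))
  g1 <- names(exp$groups)[exp$groups == "control"]
  g2 <- names(exp$groups)[exp$groups == "treated"]
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs at least 2 samples")
  M1 <- rowSums(exp$M[, g1, drop = FALSE])
  U1 <- rowSums(exp$U[, g1, drop = FALSE])
  M2 <- rowSums(exp$M[, g2, drop = FALSE])
  U2 <- rowSums(exp$U[, g2, drop = FALSE])
  if (any(M1 + U1 == 0) || any(M2 + U2 == 0))
    stop("zero total reads in a group; apply coverage filters first")
  log2fc <- log2(((M2 + pseudocount) / (U2 + pseudocount)) /
                 ((M1 + pseudocount) / (U1 + pseudocount)))
  ll <- function(M, U) {
    p <- M / (M + U)
    ifelse(M > 0, M * log(p), 0) + ifelse(U > 0, U * log(1 - p), 0)
  }
  stat <- 2 * (ll(M1, U1) + ll(M2, U2) - ll(M1 + M2, U1 + U2))
  p <- stats::pchisq(pmax(stat, 0), df = 1, lower.tail = FALSE)
  data.frame(feature_id = exp$regions$region_id, layer = "methyl-region",
             base_mean = (M1 + U1 + M2 + U2) / ncol(exp$M),
             log2fc = log2fc, p_value = p, fdr = bh_adjust(p),
             direction = "ns", stringsAsFactors = FALSE, row.names = NULL)
}
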