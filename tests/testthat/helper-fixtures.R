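# shared fixture builders (everything generated in code; no stored data)

# tiny count matrix with explicit values
tiny_counts <- function(values, n_control = ncol(values) / 2) {
  samples <- c(paste0("control_", seq_len(n_control)),
               paste0("treated_", seq_len(ncol(values) - n_control)))
  colnames(values) <- samples
  groups <- stats::setNames(sub("_[0-9]+$", "", samples), samples)
  count_matrix(values, groups)
}

# methylation experiment from explicit M and U matrices
tiny_meth <- function(M, U, regions = NULL, n_control = ncol(M) / 2) {
  samples <- c(paste0("control_", seq_len(n_control)),
               paste0("treated_", seq_len(ncol(M) - n_control)))
  if (is.null(regions))
    regions <- data.frame(region_id = paste0("r", seq_len(nrow(M))),
                          chrom = "chr1",
                          start = (seq_len(nrow(M)) - 1L) * 100L,
                          end = seq_len(nrow(M)) * 100L,
                          context = "CpG", stringsAsFactors = FALSE)
  dimnames(M) <- dimnames(U) <- list(regions$region_id, samples)
  groups <- stats::setNames(sub("_[0-9]+$", "", samples), samples)
  methylation_experiment(regions, M, U, groups)
}

# hand-built gene annotation (coordinates 0-based half-open)
tiny_annotation <- function(genes, exons = NULL, chrom_len = 1e6) {
  if (is.null(exons))
    exons <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                        start = genes$start, end = genes$end,
                        stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons, chrom_len = chrom_len),
            class = "gene_annotation")
}

# independent step-up FDR oracle (direct formula, no p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# brute-force Mann-Whitney U null distribution by enumerating all
# C(n1+n2, n1) assignments of distinct ranks
mw_bruteforce <- function(n1, n2) {
  ranks <- seq_len(n1 + n2)
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(ix) sum(outer(ranks[ix], ranks[-ix], `<`)))
  tab <- table(factor(us, levels = 0:(n1 * n2)))
  as.numeric(tab) / sum(tab)
}

# brute-force hypergeometric upper tail by enumerating all draws
hyper_bruteforce <- function(overlap, set_size, universe_size, query_size) {
  universe <- seq_len(universe_size)
  set <- seq_len(set_size)
  draws <- utils::combn(universe_size, query_size)
  hits <- apply(draws, 2, function(d) length(intersect(d, set)))
  mean(hits >= overlap)
}

# expression vector with exact sample correlation r to a base vector
vector_with_cor <- function(x, r) {
  n <- length(x)
  z <- stats::rnorm(n)
  z <- stats::residuals(stats::lm(z ~ x))
  xs <- as.numeric(scale(x)); zs <- as.numeric(scale(z))
  r * xs + sqrt(1 - r^2) * zs
}
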