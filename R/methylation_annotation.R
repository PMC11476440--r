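#' Per-base methylation fraction
#'
#' methylated / (methylated + unmethylated); positions with zero total reads
#' get `NA` (a missing value, never 0). Vectorized.
#'
#' @param methylated,unmethylated non-negative read counts.
#' @return fraction in [0, 1] or `NA` where the total is zero.
#' @export
methylation_fraction <- function(methylated, unmethylated) {
  if (any(methylated < 0) || any(unmethylated < 0))
    stop("negative read counts")
  total <- methylated + unmethylated
  ifelse(total > 0, methylated / total, NA_real_)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify cytosine sequence context
#'
#' Classifies a cytosine as CpG, CHG or CHH (H = A, C or T) from the two
#' bases 3' of it on its own strand. `position` is a 1-based index into the
#' plus-strand reference sequence; for minus-strand cytosines the reference
#' base is G and the downstream bases are read leftwards, complemented.
#' At a contig edge where the needed downstream base is absent, the site
#' falls back to CpG only if the first downstream base is G, and otherwise
#' to CHH.
#'
#' @param sequence reference sequence as a character string (plus strand,
#'   5' to 3').
#' @param position integer vector of 1-based positions (cytosines on the
#'   requested strand).
#' @param strand `"+"` or `"-"` (scalar or vector).
#' @return character vector of `"CpG"`, `"CHG"`, `"CHH"`.
#' @export
classify_context <- function(sequence, position, strand = "+") {
  n <- nchar(sequence)
  strand <- rep_len(strand, length(position))
  base_at <- function(pos) {
    out <- rep(NA_character_, length(pos))
    ok <- pos >= 1 & pos <= n
    if (any(ok)) out[ok] <- substring(sequence, pos[ok], pos[ok])
    out
  }
  b0 <- base_at(position)
  minus <- strand == "-"
  own0 <- ifelse(minus, unname(.complement[b0]), b0)
  if (any(own0 != "C", na.rm = TRUE) || anyNA(own0))
    stop("position ",
         paste(position[which(is.na(own0) | own0 != "C")[1]]),
         " is not a cytosine on the requested strand")
  p1 <- ifelse(minus, position - 1L, position + 1L)
  p2 <- ifelse(minus, position - 2L, position + 2L)
  b1 <- base_at(p1); b2 <- base_at(p2)
  own1 <- ifelse(minus, unname(.complement[b1]), b1)
  own2 <- ifelse(minus, unname(.complement[b2]), b2)
  ifelse(!is.na(own1) & own1 == "G", "CpG",
         ifelse(!is.na(own2) & own2 == "G", "CHG", "CHH"))
}

#' Coverage filter on methylated regions
#'
#' Retains a region iff at least one replicate in the control group AND at
#' least one replicate in the treated group has total reads strictly
#' greater than `min_reads`.
#'
#' @param exp a [methylation_experiment].
#' @param min_reads read-count bound (default 5; "exceeding" it means > 5).
#' @return the experiment restricted to retained regions.
#' @export
coverage_filter <- function(exp, min_reads = 5) {
  stopifnot(inherits(exp, "methylation_experiment"))
  total <- exp$M + exp$U
  g1 <- names(exp$groups)[exp$groups == "control"]
  g2 <- names(exp$groups)[exp$groups == "treated"]
  keep <- apply(total[, g1, drop = FALSE] > min_reads, 1, any) &
          apply(total[, g2, drop = FALSE] > min_reads, 1, any)
  subset_methylation(exp, keep)
}

# internal: GRanges from 0-based half-open coordinates
.granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
}

#' Assign methylated regions to genes and genomic feature classes
#'
#' Every region receives exactly one assignment with precedence
#' promoter > exon > intron > intergenic. The promoter window is
#' `[TSS - half_width, TSS + half_width)`; overlapping any window by at
#' least 1 bp makes a region a promoter region, attributed to the gene with
#' the smallest absolute TSS distance (region midpoint to TSS, signed so
#' that negative means upstream in gene orientation), ties broken by
#' lexicographic gene id. Regions overlapping a gene span outside all
#' promoter windows are exon or intron regions of the closest overlapped
#' gene; everything else is intergenic but still reports the nearest gene
#' and distance.
#'
#' @param regions data.frame with `region_id`, `chrom`, `start`, `end`
#'   (0-based half-open), e.g. the `regions` of a [methylation_experiment].
#' @param annotation a `gene_annotation`.
#' @param promoter_half_width half-width of the promoter window in bp
#'   (default 2000).
#' @return data.frame with `region_id`, `gene_id`, `feature_class`
#'   (promoter/exon/intron/intergenic), `tss_distance`.
#' @export
annotate_regions <- function(regions, annotation, promoter_half_width = 2000) {
  genes <- annotation$genes
  unknown <- setdiff(unique(regions$chrom), unique(genes$chrom))
  if (length(unknown))
    stop("regions on chromosome(s) absent from the annotation: ",
         paste(unknown, collapse = ", "))
  nr <- nrow(regions)
  mid <- floor((regions$start + regions$end) / 2)

  # signed midpoint-to-TSS distance for a (region, gene) index pair
  tss_dist <- function(ri, gi) {
    d <- mid[ri] - genes$tss[gi]
    ifelse(genes$strand[gi] == "+", d, -d)
  }
  # among candidate hits, pick per region the gene with min |distance|,
  # ties by lexicographic gene id
  pick_best <- function(ri, gi) {
    d <- tss_dist(ri, gi)
    o <- order(ri, abs(d), genes$gene_id[gi])
    first <- !duplicated(ri[o])
    list(region = ri[o][first], gene = gi[o][first], dist = d[o][first])
  }

  gr_reg <- .granges0(regions$chrom, regions$start, regions$end)
  win <- .granges0(genes$chrom,
                   pmax(0L, genes$tss - promoter_half_width),
                   genes$tss + promoter_half_width)
  hits <- GenomicRanges::findOverlaps(gr_reg, win)
  prom <- pick_best(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))

  span <- .granges0(genes$chrom, genes$start, genes$end)
  hits_g <- GenomicRanges::findOverlaps(gr_reg, span)
  genic <- pick_best(S4Vectors::queryHits(hits_g),
                     S4Vectors::subjectHits(hits_g))
  gr_ex <- .granges0(annotation$exons$chrom, annotation$exons$start,
                     annotation$exons$end)
  ex_gene <- annotation$exons$gene_id
  hits_e <- GenomicRanges::findOverlaps(gr_reg, gr_ex)
  exon_key <- unique(paste(S4Vectors::queryHits(hits_e),
                           ex_gene[S4Vectors::subjectHits(hits_e)]))

  gene_id <- rep(NA_character_, nr)
  feature_class <- rep("intergenic", nr)
  tss_distance <- rep(NA_real_, nr)

  # genic (exon/intron) first, promoter overwrites by precedence
  if (length(genic$region)) {
    gene_id[genic$region] <- genes$gene_id[genic$gene]
    tss_distance[genic$region] <- genic$dist
    is_exon <- paste(genic$region, genes$gene_id[genic$gene]) %in% exon_key
    feature_class[genic$region] <- ifelse(is_exon, "exon", "intron")
  }
  if (length(prom$region)) {
    gene_id[prom$region] <- genes$gene_id[prom$gene]
    tss_distance[prom$region] <- prom$dist
    feature_class[prom$region] <- "promoter"
  }
  # intergenic: nearest gene on the same chromosome by |tss distance|
  left <- which(feature_class == "intergenic")
  if (length(left)) {
    for (ch in unique(regions$chrom[left])) {
      ri <- left[regions$chrom[left] == ch]
      gi <- which(genes$chrom == ch)
      dmat <- outer(mid[ri], genes$tss[gi], `-`)
      sign_fix <- matrix(rep(ifelse(genes$strand[gi] == "+", 1, -1),
                             each = length(ri)), nrow = length(ri))
      dmat <- dmat * sign_fix
      ord <- apply(abs(dmat), 1, function(r) {
        cand <- which(r == min(r))
        cand[order(genes$gene_id[gi][cand])][1]
      })
      gene_id[ri] <- genes$gene_id[gi][ord]
      tss_distance[ri] <- dmat[cbind(seq_along(ri), ord)]
    }
  }
  data.frame(region_id = regions$region_id, gene_id = gene_id,
             feature_class = feature_class, tss_distance = tss_distance,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Feature-class proportions of region assignments
#'
#' @param assignments data.frame from [annotate_regions].
#' @return named numeric vector of proportions over
#'   promoter/exon/intron/intergenic, summing to 1.
#' @export
feature_class_distribution <- function(assignments) {
  if (!nrow(assignments)) stop("no assignments")
  classes <- c("promoter", "exon", "intron", "intergenic")
  tab <- table(factor(assignments$feature_class, levels = classes))
  stats::setNames(as.numeric(tab) / nrow(assignments), classes)
}

#' FPKM normalization
#'
#' Fragments per kilobase of feature per million mapped fragments:
#' `count / (length/1000 * library_total/1e6)`, with the library total the
#' per-sample column sum.
#'
#' @param counts a [count_matrix] or bare matrix.
#' @param feature_lengths named vector of feature lengths in bp (> 0),
#'   covering every feature in `counts`.
#' @return numeric matrix of FPKM values with the same dimnames.
#' @export
fpkm <- function(counts, feature_lengths) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  missing <- setdiff(rownames(m), names(feature_lengths))
  if (length(missing))
    stop("no length for feature(s): ", paste(missing, collapse = ", "))
  len <- feature_lengths[rownames(m)]
  if (any(len <= 0)) stop("feature lengths must be positive")
  lib <- colSums(m)
  if (any(lib == 0)) stop("zero library total")
  sweep(m / (len / 1000), 2, lib / 1e6, "/")
}
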