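test_that("methylation_fraction is exact and bounded", {
  expect_equal(methylation_fraction(5, 0), 1)
  expect_equal(methylation_fraction(0, 7), 0)
  expect_equal(methylation_fraction(3, 1), 0.75)
  expect_true(is.na(methylation_fraction(0, 0)))
  expect_error(methylation_fraction(-1, 2), "negative")
  withr::with_seed(1, {
    m <- stats::rpois(500, 5); u <- stats::rpois(500, 5)
    f <- methylation_fraction(m, u)
    expect_true(all(is.na(f) | (f >= 0 & f <= 1)))
  })
})

test_that("classify_context follows the CpG/CHG/CHH definitions", {
  expect_equal(classify_context("ACGT", 2, "+"), "CpG")
  expect_equal(classify_context("ACTG", 2, "+"), "CHG")
  expect_equal(classify_context("ACTT", 2, "+"), "CHH")
  # minus strand: the C sits opposite a plus-strand G, context read leftwards
  expect_equal(classify_context("AACGTT", 4, "-"), "CpG")
  expect_equal(classify_context("CAGT", 3, "-"), "CHG")  # own strand: C,T,G
  # contig edge: second downstream base missing cannot complete CHG
  expect_equal(classify_context("AACT", 3, "+"), "CHH")
  expect_equal(classify_context("AACG", 3, "+"), "CpG")
  expect_error(classify_context("ACGT", 1, "+"), "not a cytosine")
})

test_that("context classes on random sequence match combinatorial rates", {
  # P(CpG) = 1/4; P(CHG) = 3/4 * 1/4; P(CHH) = 3/4 * 3/4
  withr::with_seed(99, {
    seq <- paste(sample(c("A", "C", "G", "T"), 4.2e5, replace = TRUE),
                 collapse = "")
    pos <- which(strsplit(seq, "")[[1]] == "C")
    pos <- pos[pos <= nchar(seq) - 2]
    pos <- pos[seq_len(min(1e5, length(pos)))]
    ctx <- classify_context(seq, pos, "+")
    prop <- table(ctx) / length(ctx)
    expect_lt(abs(prop[["CpG"]] - 1 / 4), 0.02)
    expect_lt(abs(prop[["CHG"]] - 3 / 16), 0.02)
    expect_lt(abs(prop[["CHH"]] - 9 / 16), 0.02)
  })
})

test_that("coverage_filter requires coverage exceeding the bound in both groups", {
  mk <- function(...) {
    rows <- list(...)
    tiny_meth(matrix(unlist(rows), nrow = length(rows), byrow = TRUE),
              matrix(0, length(rows), 4))
  }
  ex <- mk(c(5, 5, 5, 5),    # never exceeds 5 -> dropped
           c(6, 0, 9, 0),    # exceeds in both groups -> kept
           c(6, 6, 5, 5))    # control only -> dropped
  kept <- coverage_filter(ex, min_reads = 5)
  expect_equal(kept$regions$region_id, "r2")
})

test_that("annotate_regions applies window, precedence and tie rules", {
  genes <- data.frame(
    gene_id = c("geneA", "geneB", "geneC"),
    chrom = "chr1", strand = c("+", "-", "+"),
    start = c(10000, 30000, 50000), end = c(20000, 32000, 52000),
    tss = c(10000, 31999, 50000), stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("geneA", "geneA", "geneB", "geneC"),
                      chrom = "chr1",
                      start = c(10000, 14000, 30000, 50000),
                      end = c(10500, 16000, 32000, 52000),
                      stringsAsFactors = FALSE)
  ann <- tiny_annotation(genes, exons, chrom_len = 1e5)
  regions <- data.frame(
    region_id = c("prom", "exonic", "intronic", "far"),
    chrom = "chr1",
    start = c(8100, 14500, 12500, 40000),
    end = c(8200, 14600, 12600, 40100), stringsAsFactors = FALSE)
  a <- annotate_regions(regions, ann)

  expect_equal(a$feature_class[a$region_id == "prom"], "promoter")
  expect_equal(a$gene_id[a$region_id == "prom"], "geneA")
  expect_equal(a$tss_distance[a$region_id == "prom"], -1850)

  # inside geneA span, in an exon, outside every promoter window
  expect_equal(a$feature_class[a$region_id == "exonic"], "exon")
  # inside geneA span between exons, past the promoter window
  expect_equal(a$feature_class[a$region_id == "intronic"], "intron")

  expect_equal(a$feature_class[a$region_id == "far"], "intergenic")
  expect_false(anyNA(a$gene_id))  # intergenic regions still report a gene

  expect_error(annotate_regions(
    data.frame(region_id = "x", chrom = "chrZ", start = 1, end = 2), ann),
    "chromosome")
})

test_that("equidistant regions resolve to the lexicographically first gene", {
  genes <- data.frame(gene_id = c("geneD", "geneE"), chrom = "chr1",
                      strand = "+", start = c(10000, 50000),
                      end = c(12000, 52000), tss = c(10000, 50000),
                      stringsAsFactors = FALSE)
  ann <- tiny_annotation(genes, chrom_len = 1e5)
  tie <- data.frame(region_id = "tie", chrom = "chr1",
                    start = 29950, end = 30050, stringsAsFactors = FALSE)
  a <- annotate_regions(tie, ann)  # midpoint 30000, 20000 bp from both TSSs
  expect_equal(a$gene_id, "geneD")
  expect_equal(a$feature_class, "intergenic")
})

test_that("every region gets exactly one feature class", {
  ann <- generate_annotation(30, chrom_len = 3e5, seed = 17)
  ms <- simulate_methylation(ann, n_background = 100, seed = 17)
  a <- annotate_regions(ms$experiment$regions, ann)
  expect_equal(nrow(a), nrow(ms$experiment$regions))
  expect_true(all(a$feature_class %in%
                    c("promoter", "exon", "intron", "intergenic")))
  # promoter regions sit within a window of the assigned TSS (up to half a
  # region width beyond the edge, since membership needs only 1 bp overlap)
  prom <- a[a$feature_class == "promoter", ]
  expect_true(all(abs(prom$tss_distance) <= 2000 + 50))
  d <- feature_class_distribution(a)
  expect_equal(sum(d), 1)
  expect_error(feature_class_distribution(a[0, ]), "no assignments")
})

test_that("tss_distance sign tracks gene orientation", {
  genes <- data.frame(gene_id = c("plus", "minus"),
                      chrom = c("chr1", "chr2"), strand = c("+", "-"),
                      start = c(10000, 10000), end = c(12000, 12000),
                      tss = c(10000, 11999), stringsAsFactors = FALSE)
  ann <- tiny_annotation(genes, chrom_len = 5e4)
  regions <- data.frame(region_id = c("left_plus", "right_minus"),
                        chrom = c("chr1", "chr2"),
                        start = c(9000, 13000), end = c(9100, 13100),
                        stringsAsFactors = FALSE)
  a <- annotate_regions(regions, ann)
  # both regions lie upstream in gene orientation -> negative distances
  expect_lt(a$tss_distance[a$region_id == "left_plus"], 0)
  expect_lt(a$tss_distance[a$region_id == "right_minus"], 0)
})

test_that("fpkm follows the standard formula", {
  m <- matrix(c(10, 999990, 0, 10, 1999980, 10), ncol = 2,
              dimnames = list(c("a", "filler", "z"), c("s1", "s2")))
  cm <- tiny_counts(m, n_control = 1)
  lens <- c(a = 1000, filler = 500, z = 2000)
  f <- fpkm(cm, lens)
  expect_equal(unname(f["a", 1]), 10)   # 10 reads, 1 kb, 1e6 library
  expect_equal(unname(f["z", 1]), 0)
  # doubling every count of a library leaves FPKM unchanged
  m2 <- m; m2[, 2] <- m[, 1] * 2
  f2 <- fpkm(tiny_counts(m2, n_control = 1), lens)
  expect_equal(f2[, 2], f2[, 1])
  expect_error(fpkm(cm, c(a = 1000)), "no length")
  expect_error(fpkm(cm, c(a = 0, filler = 1, z = 1)), "positive")
})
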