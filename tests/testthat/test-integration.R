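test_that("pearson_with_p matches the t-transform", {
  expect_equal(pearson_with_p(1:4, -(1:4))$pcc, -1)
  expect_equal(pearson_with_p(1:4, 2 * (1:4))$pcc, 1)
  r <- pearson_with_p(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r$pcc, 0.5)
  expect_equal(r$p, 2 / 3, tolerance = 1e-6)
  expect_true(is.na(pearson_with_p(c(1, 1, 1), c(1, 2, 3))$pcc))
  expect_error(pearson_with_p(1:3, 1:4), "unequal")
})

make_dmrs <- function(gene_ids, dirs, lfcs = NULL) {
  n <- length(gene_ids)
  data.frame(gene_id = gene_ids, region_id = paste0("r_", gene_ids),
             log2fc = if (is.null(lfcs))
               ifelse(dirs == "up", 1.5, -1.5) else lfcs,
             p_value = 0.01, fdr = 0.01, direction = dirs,
             stringsAsFactors = FALSE)
}
make_degs <- function(ids, dirs, lfcs = NULL) {
  data.frame(feature_id = ids, layer = "gene", base_mean = 10,
             log2fc = if (is.null(lfcs))
               ifelse(dirs == "up", 1, -1) else lfcs,
             p_value = 0.001, fdr = 0.001, direction = dirs,
             stringsAsFactors = FALSE)
}

test_that("link_dmr_deg keeps only inverse promoter/gene pairs", {
  dm <- make_dmrs(c("g1", "g2", "g3"), c("up", "up", "down"))
  de <- make_degs(c("g1", "g2", "g3", "g4"), c("down", "up", "up", "down"))
  pairs <- link_dmr_deg(dm, de)
  expect_equal(pairs$gene_id, c("g1", "g3"))
  expect_equal(pairs$dmr_direction, c("hyper", "hypo"))
  expect_equal(pairs$deg_direction, c("down", "up"))

  # planted inverse links are recovered exactly
  n <- 12
  dm <- make_dmrs(sprintf("h%02d", 1:n), rep("up", n))
  de <- make_degs(sprintf("h%02d", 1:n), rep("down", n))
  expect_equal(nrow(link_dmr_deg(dm, de)), n)
})

test_that("link_dmr_demir emits reciprocal orientations", {
  dm <- make_dmrs(c("miR-a", "miR-b"), c("down", "up"))
  de <- make_degs(c("miR-a", "miR-b"), c("up", "down"))
  pairs <- link_dmr_demir(dm, de)
  expect_equal(nrow(pairs), 2)
  expect_setequal(pairs$orientation, c("hypo_up", "hyper_down"))
  expect_true(all(c("mirna_id", "demir_log2fc") %in% names(pairs)))
  empty <- link_dmr_demir(dm[0, ], de)
  expect_equal(nrow(empty), 0)
})

test_that("anticorrelation filter applies strict cutoffs and preconditions", {
  samples <- paste0("s", 1:6)
  gene_expr <- rbind(gUp = c(1, 2, 3, 10, 11, 12),
                     gDown = c(10, 11, 12, 1, 2, 3),
                     gFlat = c(5, 6, 5, 6, 5, 6))
  mirna_expr <- rbind(mUp = c(1, 2, 3, 10, 12, 11),
                      mDown = c(12, 11, 10, 3, 2, 1))
  colnames(gene_expr) <- colnames(mirna_expr) <- samples
  demirs <- make_degs(c("mUp", "mDown"), c("up", "down"))
  degs <- make_degs(c("gUp", "gDown", "gFlat"), c("up", "down", "ns"))
  tt <- data.frame(mirna_id = c("mUp", "mDown", "mUp", "mUp"),
                   gene_id = c("gDown", "gUp", "gUp", "gFlat"),
                   stringsAsFactors = FALSE)
  ac <- link_demir_targets(demirs, tt, degs, gene_expr, mirna_expr)
  # mUp/gUp has same-direction calls, mUp/gFlat a non-significant gene:
  # neither is ever tested; the two opposite pairs are strongly negative
  expect_setequal(paste(ac$mirna_id, ac$gene_id),
                  c("mUp gDown", "mDown gUp"))
  expect_true(all(ac$pcc < -0.5 & ac$pcc_p < 0.05))

  # a pair at exactly the cutoff is rejected (strict inequality)
  ge <- rbind(g = c(1, 3, 2))
  me <- rbind(m = c(-1, -2, -3))
  colnames(ge) <- colnames(me) <- paste0("s", 1:3)
  # cor(m, g) = -0.5 exactly
  expect_equal(stats::cor(me["m", ], ge["g", ]), -0.5)
  ac2 <- link_demir_targets(make_degs("m", "up"),
                            data.frame(mirna_id = "m", gene_id = "g"),
                            make_degs("g", "down"), ge, me,
                            pcc_cut = -0.5, p_cut = 1)
  expect_equal(nrow(ac2), 0)

  expect_error(link_demir_targets(demirs, tt, degs,
                                  gene_expr[, 6:1], mirna_expr),
               "sample ordering")
})

test_that("relaxing the anticorrelation cutoffs never shrinks the output", {
  withr::with_seed(31, {
    n <- 40
    samples <- paste0("s", 1:10)
    mirna_expr <- matrix(stats::rnorm(n * 10, 100, 10), n,
                         dimnames = list(paste0("m", 1:n), samples))
    gene_expr <- matrix(0, n, 10, dimnames = list(paste0("g", 1:n), samples))
    for (i in 1:n)
      gene_expr[i, ] <- vector_with_cor(mirna_expr[i, ],
                                        stats::runif(1, -1, 0.5)) + 100
    demirs <- make_degs(paste0("m", 1:n), rep(c("up", "down"), n / 2))
    degs <- make_degs(paste0("g", 1:n), rep(c("down", "up"), n / 2))
    tt <- data.frame(mirna_id = paste0("m", 1:n), gene_id = paste0("g", 1:n))
    sizes <- sapply(c(-0.9, -0.5, -0.3, -0.1), function(cut)
      nrow(link_demir_targets(demirs, tt, degs, gene_expr, mirna_expr,
                              pcc_cut = cut, p_cut = 1)))
    expect_true(all(diff(sizes) >= 0))
    psizes <- sapply(c(0.01, 0.05, 0.2, 1), function(pc)
      nrow(link_demir_targets(demirs, tt, degs, gene_expr, mirna_expr,
                              pcc_cut = -0.1, p_cut = pc)))
    expect_true(all(diff(psizes) >= 0))
  })
})

test_that("classify_category implements the four-way sign logic", {
  # the four published sign patterns
  expect_equal(classify_category("hyper", "down", "up"), "red")
  expect_equal(classify_category("hypo", "up", "down"), "blue")
  expect_equal(classify_category("hyper", "up", "down"), "green")
  expect_equal(classify_category("hypo", "down", "up"), "orange")
  # total over the 4 admissible combinations, vectorized
  combos <- expand.grid(dmr = c("hyper", "hypo"), deg = c("up", "down"),
                        stringsAsFactors = FALSE)
  out <- classify_category(combos$dmr, combos$deg,
                           ifelse(combos$deg == "up", "down", "up"))
  expect_setequal(out, c("red", "blue", "green", "orange"))
  # inadmissible inputs
  expect_error(classify_category("hyper", "up", "up"), "opposite")
  expect_error(classify_category("ns", "up", "down"), "ns")
})

test_that("promoter_dmr_table keeps the best DMR per gene", {
  dm <- data.frame(feature_id = c("r1", "r2", "r3"),
                   layer = "methyl-region", base_mean = 50,
                   log2fc = c(2, -1.5, 1.2), p_value = c(0.04, 0.001, 0.01),
                   fdr = c(0.1, 0.01, 0.05),
                   direction = c("up", "down", "up"),
                   stringsAsFactors = FALSE)
  asg <- data.frame(region_id = c("r1", "r2", "r3"),
                    gene_id = c("gA", "gA", "gB"),
                    feature_class = c("promoter", "promoter", "promoter"),
                    tss_distance = c(-100, 300, 10),
                    stringsAsFactors = FALSE)
  tab <- promoter_dmr_table(dm, asg)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$region_id[tab$gene_id == "gA"], "r2")  # smaller p wins
})

test_that("three-level triples need all three evidence layers", {
  prom <- data.frame(gene_id = c("g1", "g2"), region_id = c("r1", "r2"),
                     log2fc = c(1.5, -1.2), p_value = 0.01, fdr = 0.02,
                     direction = c("up", "down"), stringsAsFactors = FALSE)
  degs <- make_degs(c("g1", "g3"), c("down", "up"))
  ac <- data.frame(mirna_id = "m1", gene_id = "g1", pcc = -0.9,
                   pcc_p = 0.001, mirna_direction = "up",
                   gene_direction = "down", mirna_log2fc = 0.8,
                   gene_log2fc = -1, mirna_fdr = 0.01, gene_fdr = 0.001,
                   stringsAsFactors = FALSE)
  tr <- integrate_three_level(prom, degs, ac)
  expect_equal(nrow(tr), 1)   # g2 lacks DEG+miRNA, g3 lacks DMR
  expect_equal(tr$gene_id, "g1")
  expect_equal(tr$category, "red")
  # closure: triples only reference genes present in all inputs
  expect_true(all(tr$gene_id %in% intersect(prom$gene_id, degs$feature_id)))
  expect_true(all(tr$gene_id %in% ac$gene_id))

  expect_equal(nrow(integrate_three_level(prom, degs, ac[0, ])), 0)
})
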