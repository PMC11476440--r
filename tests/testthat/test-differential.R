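test_that("median-of-ratios size factors behave as expected", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), 3,
              dimnames = list(c("a", "b", "c"), NULL))
  cm <- tiny_counts(m, n_control = 1)
  expect_equal(unname(normalize_libraries(cm)), c(1, 1))

  m2 <- matrix(c(10, 20, 30, 20, 40, 60), 3,
               dimnames = list(c("a", "b", "c"), NULL))
  sf <- normalize_libraries(tiny_counts(m2, n_control = 1))
  expect_equal(unname(sf[2] / sf[1]), 2)

  zero <- matrix(0, 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_error(normalize_libraries(tiny_counts(zero)), "all-zero")
})

test_that("bh_adjust matches an independent step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")

  withr::with_seed(42, {
    for (i in 1:20) {
      p <- stats::runif(sample(1:50, 1))
      expect_equal(bh_adjust(p), bh_oracle(p))
    }
  })
  # adjusted values are monotone in the rank of sorted inputs
  p <- sort(stats::runif(30))
  adj <- bh_adjust(p)
  expect_true(all(diff(adj) >= 0))
})

test_that("test_counts handles null, filtered and degenerate inputs", {
  m <- matrix(rep(c(5, 9, 40, 0), 4), nrow = 4,
              dimnames = list(paste0("f", 1:4), NULL))
  cm <- tiny_counts(m)  # both groups identical
  rec <- test_counts(cm)
  expect_false("f4" %in% rec$feature_id)  # all-zero feature dropped
  expect_equal(rec$log2fc, rep(0, nrow(rec)))
  expect_true(all(rec$p_value > 0.99))

  one <- tiny_counts(matrix(c(5, 6, 7), 1,
                            dimnames = list("f1", NULL)), n_control = 2)
  expect_error(test_counts(one), "2 samples")
})

test_that("swapping group labels negates log2FC and preserves p", {
  sim <- simulate_counts(sprintf("f%03d", 1:200),
                         planted = c(f001 = 2, f002 = -1), seed = 13)
  cm <- sim$counts
  flipped <- count_matrix(cm$counts,
                          stats::setNames(ifelse(cm$groups == "control",
                                                 "treated", "control"),
                                          names(cm$groups)))
  a <- test_counts(cm); b <- test_counts(flipped)
  expect_equal(b$log2fc, -a$log2fc)
  expect_equal(b$p_value, a$p_value)
})

test_that("planted fold-changes are recovered with controlled FDR", {
  ids <- sprintf("f%03d", 1:500)
  hits <- sapply(1:20, function(s) {
    planted <- stats::setNames(rep(3, 20), ids[1:20])
    sim <- simulate_counts(ids, n_per_group = 5, planted = planted,
                           baseline_mean = 200, dispersion = 0.02, seed = s,
                           feature_mean_sdlog = 0)
    rec <- test_counts(sim$counts)
    mean(rec$fdr[rec$feature_id %in% names(planted)] < 0.05)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("classify_records applies inclusive thresholds per layer", {
  rec <- data.frame(feature_id = c("a", "b", "c", "d"), layer = "gene",
                    base_mean = 10,
                    log2fc = c(1.224, 0.49, -0.6, 0.5),
                    p_value = c(0.002, 0.001, 0.2, 0.01),
                    fdr = c(0.01, 0.001, 0.01, 0.05),
                    direction = "ns", stringsAsFactors = FALSE)
  dmr <- classify_records(rec, threshold_set(1, 0.05, "p"))
  expect_equal(dmr$direction, c("up", "ns", "ns", "ns"))
  deg <- classify_records(rec, threshold_set(0.5, 0.05, "fdr"))
  # 0.49 misses the fold-change cutoff despite tiny FDR; boundary 0.5 is in
  expect_equal(deg$direction, c("up", "ns", "down", "up"))

  # exhaustive and mutually exclusive over random records
  withr::with_seed(7, {
    r <- data.frame(feature_id = paste0("f", 1:200), layer = "gene",
                    base_mean = 1, log2fc = stats::rnorm(200),
                    p_value = stats::runif(200), fdr = stats::runif(200),
                    direction = "ns", stringsAsFactors = FALSE)
    out <- classify_records(r, threshold_set(0.5, 0.05, "fdr"))
    expect_true(all(out$direction %in% c("up", "down", "ns")))
    up <- out$log2fc >= 0.5 & out$fdr <= 0.05
    down <- out$log2fc <= -0.5 & out$fdr <= 0.05
    expect_equal(out$direction == "up", up)
    expect_equal(out$direction == "down", down & !up)
  })
})

test_that("low-coverage region filter applies the 50% rule", {
  mk <- function(totals) {
    M <- matrix(unlist(totals), nrow = length(totals), byrow = TRUE)
    tiny_meth(M, matrix(0, nrow(M), 12))
  }
  # region 1: 6 of 12 samples below 4 -> removed
  # region 2: 5 below 4 -> kept; region 3: all >= 4 -> kept
  totals <- list(c(rep(3, 6), rep(10, 6)),
                 c(rep(0, 5), rep(10, 7)),
                 rep(4, 12))
  ex <- mk(totals)
  kept <- filter_low_coverage_regions(ex)
  expect_equal(kept$regions$region_id, c("r2", "r3"))
})

test_that("test_methylation computes pooled odds ratios and a calibrated LRT", {
  # identical pooled fractions: log2FC exactly 0
  M <- matrix(c(10, 10, 10, 10), 1); U <- matrix(c(30, 30, 30, 30), 1)
  rec <- test_methylation(tiny_meth(M, U))
  expect_equal(rec$log2fc, 0)

  # pooled control M/U = 10/90, treated 50/50
  M <- matrix(c(5, 5, 25, 25), 1); U <- matrix(c(45, 45, 25, 25), 1)
  rec <- test_methylation(tiny_meth(M, U))
  expect_equal(rec$log2fc, log2((50.5 / 50.5) / (10.5 / 90.5)))
  expect_lt(rec$p_value, 1e-6)

  zero <- tiny_meth(matrix(c(0, 0, 3, 3), 1), matrix(c(0, 0, 3, 3), 1))
  expect_error(test_methylation(zero), "zero total")
})

test_that("planted methylation shifts are called as DMRs", {
  ann <- generate_annotation(40, chrom_len = 4e5, seed = 21)
  rate <- sapply(1:10, function(s) {
    planted <- stats::setNames(rep(2, 30), ann$genes$gene_id[1:30])
    ms <- simulate_methylation(ann, planted_dmrs = planted,
                               coverage_mean = 30, n_per_group = 6,
                               seed = s, n_background = 50)
    rec <- classify_records(test_methylation(ms$experiment),
                            threshold_set(1, 0.05, "p"))
    called <- rec$feature_id[rec$direction == "up"]
    mean(ms$truth$gene_region %in% called)
  })
  expect_gte(mean(rate), 0.90)
})
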