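#' Generate a synthetic gene annotation
#'
#' Places non-overlapping gene models with random strand, lengths and exon
#' structure on one or more chromosomes, separated by at least
#' `intergenic_gap` bp. Coordinates are 0-based half-open; the TSS is the
#' span start on the + strand and span end - 1 on the - strand.
#'
#' @param n_genes number of genes (>= 1).
#' @param n_chroms number of chromosomes; genes are distributed round-robin.
#' @param chrom_len chromosome length in bp.
#' @param intergenic_gap minimum gap between adjacent genes in bp.
#' @param seed integer seed; the same seed reproduces the annotation exactly.
#' @param gene_len_range range of gene span lengths to draw from.
#' @return an object of class `gene_annotation`: list with data.frames
#'   `genes` (gene_id, chrom, strand, start, end, tss) and `exons`
#'   (gene_id, chrom, start, end).
#' @export
generate_annotation <- function(n_genes, n_chroms = 1, chrom_len = 1e6,
                                intergenic_gap = 1000, seed = 1,
                                gene_len_range = c(500, 3000)) {
  stopifnot(n_genes >= 1, n_chroms >= 1, chrom_len > 0, intergenic_gap >= 0)
  withr::with_seed(seed, {
    gene_id <- sprintf("gene_%04d", seq_len(n_genes))
    chrom <- paste0("chr", ((seq_len(n_genes) - 1L) %% n_chroms) + 1L)
    len <- sample(gene_len_range[1]:gene_len_range[2], n_genes, replace = TRUE)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    start <- integer(n_genes)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos <- 0L
      for (i in idx) {
        start[i] <- pos
        pos <- pos + len[i] + as.integer(intergenic_gap)
      }
      last <- idx[length(idx)]
      if (start[last] + len[last] > chrom_len)
        stop(sprintf(
          "capacity: cannot place %d genes of total span %d bp on %s (len %d bp) with %d bp gaps",
          length(idx), sum(len[idx]), ch, as.integer(chrom_len),
          as.integer(intergenic_gap)))
    }
    end <- start + len
    tss <- ifelse(strand == "+", start, end - 1L)
    # exon structure: 1-4 exons per gene from sorted internal breakpoints
    exon_list <- lapply(seq_len(n_genes), function(i) {
      k <- sample(1:4, 1)
      if (k == 1 || len[i] < 4 * k)
        return(data.frame(gene_id = gene_id[i], chrom = chrom[i],
                          start = start[i], end = end[i],
                          stringsAsFactors = FALSE))
      cuts <- sort(sample(seq_len(len[i] - 1L), 2L * k - 2L))
      bounds <- c(0L, cuts, len[i])
      es <- start[i] + bounds[seq(1, 2 * k - 1, by = 2)]
      ee <- start[i] + bounds[seq(2, 2 * k, by = 2)]
      keep <- ee > es
      data.frame(gene_id = gene_id[i], chrom = chrom[i],
                 start = es[keep], end = ee[keep], stringsAsFactors = FALSE)
    })
    structure(list(
      genes = data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                         start = start, end = end, tss = tss,
                         stringsAsFactors = FALSE),
      exons = do.call(rbind, exon_list),
      chrom_len = chrom_len),
      class = "gene_annotation")
  })
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Simulate a two-group negative-binomial count matrix
#'
#' Counts follow the gamma-mixture negative-binomial model underlying
#' standard RNA-seq differential tools: per-feature baseline means are
#' log-normal around `baseline_mean`, library sizes are log-normal
#' (sd 0.1 on the log scale) around 1, and a feature planted at log2
#' fold-change `f` has treated-group mean `baseline x 2^f`.
#'
#' @param features a `gene_annotation` (its gene ids are used) or a
#'   character vector of feature ids.
#' @param n_per_group samples per group (>= 2).
#' @param planted named numeric vector of log2 fold-changes (treated vs
#'   control) for planted features; others are null.
#' @param baseline_mean expected baseline count.
#' @param dispersion negative-binomial dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`.
#' @param seed integer seed.
#' @param feature_mean_sdlog log-scale sd of per-feature baseline means.
#' @param libsize_sdlog log-scale sd of library-size factors.
#' @return list with elements `counts` (a [count_matrix]) and `truth`
#'   (list with `de_features` and `seed`).
#' @export
simulate_counts <- function(features, n_per_group = 5, planted = numeric(0),
                            baseline_mean = 100, dispersion = 0.05, seed = 1,
                            feature_mean_sdlog = 1, libsize_sdlog = 0.1) {
  stopifnot(dispersion > 0, n_per_group >= 2, baseline_mean > 0)
  ids <- if (inherits(features, "gene_annotation")) features$genes$gene_id
         else as.character(features)
  if (length(planted)) {
    unknown <- setdiff(names(planted), ids)
    if (length(unknown))
      stop("planted features not in feature set: ",
           paste(unknown, collapse = ", "))
  }
  withr::with_seed(seed, {
    nf <- length(ids); ns <- 2L * n_per_group
    base <- stats::rlnorm(nf, log(baseline_mean) - feature_mean_sdlog^2 / 2,
                          feature_mean_sdlog)
    lib <- stats::rlnorm(ns, 0, libsize_sdlog)
    lfc <- stats::setNames(numeric(nf), ids)
    lfc[names(planted)] <- planted
    grp <- rep(c("control", "treated"), each = n_per_group)
    mu <- outer(base, lib) * 2^(lfc %o% as.numeric(grp == "treated"))
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                  nrow = nf)
    dimnames(cnt) <- list(ids, paste0(grp, "_", rep(seq_len(n_per_group), 2)))
    groups <- stats::setNames(grp, colnames(cnt))
    list(counts = count_matrix(cnt, groups),
         truth = list(de_features = planted, seed = seed))
  })
}

#' Simulate a two-group whole-genome bisulfite methylation experiment
#'
#' Generates one candidate region per gene promoter (centred on the TSS,
#' wholly inside the +/- 2 kb promoter window) plus background regions at
#' random positions. Per region and sample, coverage is Poisson and
#' methylated counts are binomial with success probability the logistic of
#' a context-specific baseline log-odds; planted promoter regions receive
#' an additional log-odds shift in the treated group. Sequence contexts are
#' assigned CpG/CHG/CHH with proportions emulating mammalian WGBS
#' (~74/12/14).
#'
#' @param annotation a `gene_annotation`.
#' @param region_size region width in bp.
#' @param coverage_mean mean per-region, per-sample read coverage.
#' @param baseline_meth named fractions in (0,1) per context.
#' @param context_prop CpG/CHG/CHH assignment proportions (summing to 1).
#' @param planted_dmrs named numeric vector: gene id -> natural-log-odds
#'   shift applied to that gene's promoter region in the treated group.
#' @param planted_baseline baseline methylation fraction used for planted
#'   promoter regions (context forced to CpG), so hyper- and hypo-shifts
#'   are symmetric.
#' @param n_per_group samples per group.
#' @param n_background number of additional unplanted random regions.
#' @param seed integer seed.
#' @return list with `experiment` (a [methylation_experiment]) and `truth`
#'   (planted region shifts keyed by region id, plus the gene -> region map).
#' @export
simulate_methylation <- function(annotation, region_size = 100,
                                 coverage_mean = 30,
                                 baseline_meth = c(CpG = 0.70, CHG = 0.30,
                                                   CHH = 0.25),
                                 context_prop = c(CpG = 0.74, CHG = 0.12,
                                                  CHH = 0.14),
                                 planted_dmrs = numeric(0),
                                 planted_baseline = 0.5,
                                 n_per_group = 6, n_background = 200,
                                 seed = 1) {
  stopifnot(all(baseline_meth > 0), all(baseline_meth < 1),
            coverage_mean > 0, region_size >= 1)
  genes <- annotation$genes
  if (length(planted_dmrs)) {
    unknown <- setdiff(names(planted_dmrs), genes$gene_id)
    if (length(unknown))
      stop("planted DMR gene(s) without a promoter in the annotation: ",
           paste(unknown, collapse = ", "))
  }
  withr::with_seed(seed, {
    # one region per promoter, centred on the TSS (inside the 2 kb window)
    half <- floor(region_size / 2)
    pstart <- pmax(0L, genes$tss - half)
    prom <- data.frame(chrom = genes$chrom, start = pstart,
                       end = pstart + as.integer(region_size),
                       gene_id = genes$gene_id, stringsAsFactors = FALSE)
    bg_chrom <- sample(unique(genes$chrom), n_background, replace = TRUE)
    bg_start <- vapply(bg_chrom, function(ch)
      sample.int(max(1L, annotation$chrom_len - as.integer(region_size)), 1L),
      integer(1))
    bg <- data.frame(chrom = bg_chrom, start = bg_start,
                     end = bg_start + as.integer(region_size),
                     gene_id = NA_character_, stringsAsFactors = FALSE)
    reg <- rbind(prom, bg)
    reg$region_id <- sprintf("%s:%d-%d", reg$chrom, reg$start, reg$end)
    if (anyDuplicated(reg$region_id)) {
      reg <- reg[!duplicated(reg$region_id), , drop = FALSE]
    }
    nreg <- nrow(reg)
    ctx <- sample(names(context_prop), nreg, replace = TRUE,
                  prob = context_prop)
    shift <- stats::setNames(numeric(nreg), reg$region_id)
    base_p <- baseline_meth[ctx]
    if (length(planted_dmrs)) {
      ridx <- match(names(planted_dmrs), reg$gene_id)
      ctx[ridx] <- "CpG"
      base_p[ridx] <- planted_baseline
      shift[ridx] <- planted_dmrs
    }
    ns <- 2L * n_per_group
    grp <- rep(c("control", "treated"), each = n_per_group)
    samples <- paste0(grp, "_", rep(seq_len(n_per_group), 2))
    cov <- matrix(stats::rpois(nreg * ns, coverage_mean), nreg, ns)
    pm <- matrix(stats::plogis(
      stats::qlogis(rep(base_p, ns)) +
        rep(shift, ns) * rep(as.numeric(grp == "treated"), each = nreg)),
      nreg, ns)
    M <- matrix(stats::rbinom(nreg * ns, as.vector(cov), as.vector(pm)),
                nreg, ns)
    U <- cov - M
    dimnames(M) <- dimnames(U) <- list(reg$region_id, samples)
    regions <- data.frame(region_id = reg$region_id, chrom = reg$chrom,
                          start = reg$start, end = reg$end, context = ctx,
                          stringsAsFactors = FALSE)
    exp <- methylation_experiment(regions, M, U,
                                  stats::setNames(grp, samples))
    planted_regions <- shift[shift != 0]
    gene_region <- stats::setNames(reg$region_id[match(names(planted_dmrs),
                                                       reg$gene_id)],
                                   names(planted_dmrs))
    list(experiment = exp,
         truth = list(dmr_regions = planted_regions,
                      gene_region = gene_region, seed = seed))
  })
}

#' Simulate a miRNA-to-target interaction table
#'
#' Builds planted anti-correlation-consistent pairs (each differential gene
#' is matched to a differential miRNA of opposite log2FC sign, cycling over
#' the available miRNAs) plus decoy pairs with no planted expression
#' relationship, drawn from the given universes.
#'
#' @param de_mirnas named numeric vector of planted miRNA log2FCs.
#' @param de_genes named numeric vector of planted gene log2FCs.
#' @param n_decoys number of decoy pairs to add.
#' @param seed integer seed.
#' @param pairs optional data.frame (`mirna_id`, `gene_id`) of planted pairs
#'   overriding the automatic opposite-sign matching.
#' @param mirna_universe,gene_universe id pools decoys are drawn from;
#'   default to the names of the planted vectors.
#' @return list with `table` (data.frame `mirna_id`, `gene_id`,
#'   `evidence_tag`) and `truth` (the planted pair data.frame).
#' @export
simulate_target_table <- function(de_mirnas, de_genes, n_decoys = 0, seed = 1,
                                  pairs = NULL,
                                  mirna_universe = names(de_mirnas),
                                  gene_universe = names(de_genes)) {
  if (is.null(pairs)) {
    rows <- list()
    for (g in names(de_genes)) {
      opp <- names(de_mirnas)[sign(de_mirnas) == -sign(de_genes[[g]])]
      if (!length(opp)) next
      k <- (length(rows) %% length(opp)) + 1L
      rows[[length(rows) + 1L]] <- data.frame(mirna_id = opp[k], gene_id = g,
                                              stringsAsFactors = FALSE)
    }
    pairs <- if (length(rows)) do.call(rbind, rows)
             else data.frame(mirna_id = character(), gene_id = character(),
                             stringsAsFactors = FALSE)
  }
  bad_m <- setdiff(pairs$mirna_id, mirna_universe)
  bad_g <- setdiff(pairs$gene_id, gene_universe)
  if (length(bad_m) || length(bad_g))
    stop("planted pair references unknown feature(s): ",
         paste(c(bad_m, bad_g), collapse = ", "))
  tab <- pairs
  tab$evidence_tag <- if (nrow(tab)) "planted" else character(0)
  if (n_decoys > 0) {
    n_possible <- length(mirna_universe) * length(gene_universe) - nrow(pairs)
    if (n_decoys > n_possible)
      stop("cannot draw ", n_decoys, " distinct decoy pairs from a ",
           length(mirna_universe), " x ", length(gene_universe),
           " universe with ", nrow(pairs), " planted pairs")
    withr::with_seed(seed, {
      planted_key <- paste(pairs$mirna_id, pairs$gene_id)
      got <- 0L; rows <- list()
      while (got < n_decoys) {
        m <- sample(mirna_universe, 1); g <- sample(gene_universe, 1)
        if (paste(m, g) %in% planted_key) next
        planted_key <- c(planted_key, paste(m, g))
        rows[[length(rows) + 1L]] <- data.frame(mirna_id = m, gene_id = g,
                                                evidence_tag = "decoy",
                                                stringsAsFactors = FALSE)
        got <- got + 1L
      }
      tab <- rbind(tab, do.call(rbind, rows))
    })
  }
  rownames(tab) <- NULL
  list(table = tab, truth = pairs)
}

# direction signs per regulatory category: c(dmr, deg, demir)
.category_signs <- list(
  red    = c(dmr = +1, deg = -1, demir = +1),
  blue   = c(dmr = -1, deg = +1, demir = -1),
  green  = c(dmr = +1, deg = +1, demir = -1),
  orange = c(dmr = -1, deg = -1, demir = +1))

#' Build a complete synthetic multi-omics scenario
#'
#' Generates one coherent input bundle - gene annotation, gene and miRNA
#' count matrices, a methylation experiment, a miRNA-target table and
#' normalized expression matrices - in which a chosen number of genes is
#' planted in each of the four regulatory categories (see
#' [classify_category]). Each planted gene gets its own dedicated miRNA, a
#' promoter region with a planted methylation shift, and expression effects
#' whose signs follow the category. At the default effect sizes (10x the
#' calling thresholds) and low noise the full pipeline recovers the planted
#' category assignment exactly.
#'
#' @param category_spec named integer vector with counts of genes per
#'   category (`red`, `blue`, `green`, `orange`); missing names count 0.
#' @param seed master integer seed; per-stage child seeds derive from it.
#' @param n_background_genes unplanted genes added to the annotation.
#' @param n_decoy_mirnas unplanted miRNAs added to the miRNA layer.
#' @param n_decoy_pairs decoy rows added to the target table.
#' @param effect_lfc absolute planted gene log2FC.
#' @param mirna_lfc absolute planted miRNA log2FC.
#' @param dmr_shift absolute planted promoter methylation shift in natural
#'   log-odds (the default `log(2) * 10` is a log2 odds-ratio of 10).
#' @param n_per_group_expr,n_per_group_meth replicates per group for the
#'   expression layers and the methylation layer.
#' @param baseline_mean,dispersion,coverage_mean,region_size,n_background_regions
#'   forwarded to [simulate_counts] and [simulate_methylation].
#' @return an object of class `scenario_bundle`: list with `annotation`,
#'   `gene_counts`, `mirna_counts`, `meth`, `targets`, `gene_expr`,
#'   `mirna_expr` and `truth` (a simulation-truth list with `de_genes`,
#'   `de_mirnas`, `dmr_regions`, `anticorr_pairs`, `category_genes`, `seed`).
#' @export
build_scenario <- function(category_spec = c(red = 2, blue = 9, green = 2,
                                             orange = 6),
                           seed = 1, n_background_genes = 180,
                           n_decoy_mirnas = 20, n_decoy_pairs = 100,
                           effect_lfc = 5, mirna_lfc = 5,
                           dmr_shift = log(2) * 10,
                           n_per_group_expr = 5, n_per_group_meth = 6,
                           baseline_mean = 100, dispersion = 0.02,
                           coverage_mean = 30, region_size = 100,
                           n_background_regions = 150) {
  spec <- stats::setNames(numeric(4), names(.category_signs))
  if (length(category_spec)) {
    bad <- setdiff(names(category_spec), names(spec))
    if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
    stopifnot(all(category_spec >= 0))
    spec[names(category_spec)] <- category_spec
  }
  n_planted <- sum(spec)
  child <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1, 6))

  n_genes <- n_planted + n_background_genes
  ann <- generate_annotation(n_genes, n_chroms = 2,
                             chrom_len = max(1e6, n_genes * 5000),
                             intergenic_gap = 1500, seed = child[1])
  gene_ids <- ann$genes$gene_id
  mirna_ids <- sprintf("mir_%03d", seq_len(n_planted + n_decoy_mirnas))

  pick <- withr::with_seed(child[2], list(
    genes = sample(gene_ids, n_planted),
    mirnas = sample(mirna_ids, n_planted)))
  category <- rep(names(spec), times = spec)
  cat_genes <- stats::setNames(category, pick$genes)

  sg <- vapply(.category_signs[category], `[[`, numeric(1), "deg")
  sm <- vapply(.category_signs[category], `[[`, numeric(1), "demir")
  sd_ <- vapply(.category_signs[category], `[[`, numeric(1), "dmr")
  de_genes <- stats::setNames(sg * effect_lfc, pick$genes)
  de_mirnas <- stats::setNames(sm * mirna_lfc, pick$mirnas)
  dmr_genes <- stats::setNames(sd_ * dmr_shift, pick$genes)

  gene_sim <- simulate_counts(ann, n_per_group_expr, planted = de_genes,
                              baseline_mean = baseline_mean,
                              dispersion = dispersion, seed = child[3],
                              feature_mean_sdlog = 0.5)
  mirna_sim <- simulate_counts(mirna_ids, n_per_group_expr,
                               planted = de_mirnas,
                               baseline_mean = baseline_mean,
                               dispersion = dispersion, seed = child[4],
                               feature_mean_sdlog = 0.5)
  meth_sim <- simulate_methylation(ann, region_size = region_size,
                                   coverage_mean = coverage_mean,
                                   planted_dmrs = dmr_genes,
                                   n_per_group = n_per_group_meth,
                                   n_background = n_background_regions,
                                   seed = child[5])
  pairs <- data.frame(mirna_id = pick$mirnas, gene_id = pick$genes,
                      stringsAsFactors = FALSE)
  tt <- simulate_target_table(de_mirnas, de_genes, n_decoys = n_decoy_pairs,
                              seed = child[6], pairs = pairs,
                              mirna_universe = mirna_ids,
                              gene_universe = gene_ids)

  lengths <- stats::setNames(ann$genes$end - ann$genes$start,
                             ann$genes$gene_id)
  gene_expr <- fpkm(gene_sim$counts, lengths)
  # miRNAs have no meaningful length; counts-per-million serve as the
  # normalized expression used for correlation
  mcnt <- mirna_sim$counts$counts
  mirna_expr <- sweep(mcnt, 2, colSums(mcnt), "/") * 1e6

  structure(list(
    annotation = ann,
    gene_counts = gene_sim$counts,
    mirna_counts = mirna_sim$counts,
    meth = meth_sim$experiment,
    targets = tt$table,
    gene_expr = gene_expr,
    mirna_expr = mirna_expr,
    truth = list(de_genes = de_genes, de_mirnas = de_mirnas,
                 dmr_regions = meth_sim$truth$dmr_regions,
                 gene_region = meth_sim$truth$gene_region,
                 anticorr_pairs = pairs, category_genes = cat_genes,
                 seed = seed)),
    class = "scenario_bundle")
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat(sprintf(
    "scenario_bundle: %d genes, %d miRNAs, %d methylation regions, %d planted category genes\n",
    nrow(x$gene_counts$counts), nrow(x$mirna_counts$counts),
    nrow(x$meth$regions), length(x$truth$category_genes)))
  invisible(x)
}
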