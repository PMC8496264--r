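# RPKM, expression maps, half splits, quartile contrasts.

make_expr_fixture <- function(n = 9, L = 9000L, counts = NULL, len = 1000L) {
  spec <- toy_replicon(length_bp = L)
  mids <- seq(L / (2 * n), L - L / (2 * n), length.out = n)
  genes <- toy_genes(mids, spec, len = len)
  if (is.null(counts)) counts <- rep(100L, n)
  list(spec = spec, genes = genes,
       counts = data.frame(genome_id = "g1", gene_id = genes$gene_id,
                           read_count = as.integer(counts),
                           stringsAsFactors = FALSE))
}

test_that("RPKM follows its unit definition", {
  spec <- toy_replicon(length_bp = 100000L)
  genes <- toy_genes(c(5000, 15000), spec, len = 1000L)
  counts <- data.frame(genome_id = "g1", gene_id = genes$gene_id,
                       read_count = c(1000L, 0L))
  rec <- compute_rpkm(counts, genes, spec, library_size = 1e6)
  expect_equal(rec$rpkm, c(1000, 0))    # 1000 reads / 1 kb / 1 M reads
  # random fixture against direct arithmetic, auto library
  set.seed(31)
  fx <- make_expr_fixture(counts = rpois(9, 200))
  rec2 <- compute_rpkm(fx$counts, fx$genes, fx$spec)
  lib <- sum(fx$counts$read_count)
  expect_equal(rec2$rpkm, fx$counts$read_count * 1e9 / (1000 * lib))
  expect_error(compute_rpkm(fx$counts, fx$genes, fx$spec, library_size = 0),
               "positive")
})

test_that("expression map centres on the median and flattens equal input", {
  fx <- make_expr_fixture(n = 9)
  rec <- compute_rpkm(fx$counts, fx$genes, fx$spec)
  em <- expression_map(rec, window = 3)
  expect_equal(em$log2_ratio, rep(0, 9))
  expect_equal(em$trend, rep(0, 9))
  # odd count, distinct values: the median gene sits exactly at 0
  fx2 <- make_expr_fixture(n = 9, counts = c(10, 20, 30, 40, 50, 60, 70, 80, 90))
  rec2 <- compute_rpkm(fx2$counts, fx2$genes, fx2$spec)
  em2 <- expression_map(rec2, window = 1)
  expect_equal(em2$log2_ratio[em2$read_count == 50], 0)
})

test_that("oversized windows shrink with a warning; zero rpkm maps to NA", {
  fx <- make_expr_fixture(n = 5, counts = c(10, 20, 0, 40, 50))
  rec <- compute_rpkm(fx$counts, fx$genes, fx$spec)
  expect_warning(em <- expression_map(rec, window = 100), "shrunk")
  expect_true(is.na(em$log2_ratio[em$read_count == 0]))
  expect_true(all(!is.na(em$trend)))    # circular mean over the rest
})

test_that("a planted two-fold ori->ter gradient shows in the trend", {
  set.seed(77)
  n <- 2000; L <- 1e6L
  spec <- toy_replicon(length_bp = L)   # bidirectional chromosome
  mids <- floor(runif(n, 0, L))
  genes <- toy_genes(mids, spec, len = 1000L)
  d <- pmin(mids, L - mids) / (L / 2)
  lambda <- 200 * 2^(-d) * exp(rnorm(n, 0, 0.5))
  counts <- data.frame(genome_id = "g1", gene_id = genes$gene_id,
                       read_count = rpois(n, lambda))
  rec <- compute_rpkm(counts, genes, spec)
  em <- expression_map(rec, window = 100)
  dist_ori <- pmin(em$position, L - em$position)
  expect_lte(cor(dist_ori, em$trend, method = "spearman"), -0.8)
})

test_that("half splits follow the circular-map geometry and partition genes", {
  spec <- toy_replicon(length_bp = 4000L, ori_pos = 0L)
  genes <- toy_genes(c(100, 2000, 3500, 999.5), spec, len = 1L)
  ul <- split_halves(genes, spec, "upper_lower")
  lr <- split_halves(genes, spec, "left_right")
  expect_equal(ul$half, c("upper", "lower", "upper", "upper"))
  expect_equal(lr$half, c("right", "left", "left", "right"))
  # p = L/2 exactly: lower and left (half-open boundaries)
  mid_gene <- toy_genes(2000, spec, len = 2L, prefix = "m")
  expect_equal(split_halves(mid_gene, spec, "upper_lower")$half, "lower")
  expect_equal(split_halves(mid_gene, spec, "left_right")$half, "left")
  # partition on a random fixture, with a rotated origin
  set.seed(12)
  spec2 <- toy_replicon(length_bp = 4000L, ori_pos = 1234L)
  rg <- toy_genes(floor(runif(300, 0, 4000)), spec2, len = 2L)
  for (scheme in c("upper_lower", "left_right")) {
    sp <- split_halves(rg, spec2, scheme)
    expect_equal(nrow(sp), 300)
    expect_equal(length(unique(sp$half)), 2)
    expect_false(anyNA(sp$half))
  }
})

test_that("quartiles use linear interpolation and contrasts rank-test the halves", {
  expect_equal(unname(quantile(c(1, 2, 3, 4), c(.25, .5, .75), type = 7)),
               c(1.75, 2.5, 3.25))
  L <- 4000L
  spec <- toy_replicon(length_bp = L)
  upper_mids <- seq(50, 950, length.out = 10)        # ori-proximal
  lower_mids <- seq(1050, 2950, length.out = 10)
  genes <- toy_genes(c(upper_mids, lower_mids), spec, len = 1000L)
  split <- split_halves(genes, spec, "upper_lower")
  # identical distributions in both halves: p_adj 1, identical quartiles
  c_same <- data.frame(genome_id = "g1", gene_id = genes$gene_id,
                       read_count = rep(c(10L, 20L, 30L, 40L, 50L,
                                          60L, 70L, 80L, 90L, 100L), 2))
  rec <- compute_rpkm(c_same, genes, spec, library_size = 1e6)
  hc <- half_contrast(rec, split, by_category = FALSE)
  expect_equal(hc$p_adj, 1)
  expect_equal(hc[, c("q1_a", "q2_a", "q3_a", "max_a")],
               setNames(hc[, c("q1_b", "q2_b", "q3_b", "max_b")],
                        c("q1_a", "q2_a", "q3_a", "max_a")))
  # fully separated halves: {101..110} vs {1..10}, U = 0, p < 0.001
  c_sep <- data.frame(genome_id = "g1", gene_id = genes$gene_id,
                      read_count = c(101:110, 1:10))
  rec2 <- compute_rpkm(c_sep, genes, spec, library_size = 1e6)
  hc2 <- half_contrast(rec2, split, by_category = FALSE)
  expect_lt(hc2$p_raw, 0.001)
  expect_equal(hc2$half_b, "upper")
  expect_equal(hc2$q2_b, median(101:110) * 1e9 / (1000 * 1e6))
})

test_that("log2 ratios and rank tests are invariant to count scaling", {
  set.seed(91)
  fx <- make_expr_fixture(n = 30, L = 30000L, counts = rpois(30, 80))
  rec1 <- compute_rpkm(fx$counts, fx$genes, fx$spec)
  scaled <- fx$counts; scaled$read_count <- scaled$read_count * 10L
  rec2 <- compute_rpkm(scaled, fx$genes, fx$spec)
  expect_equal(rec2$rpkm, rec1$rpkm)   # auto library absorbs depth
  em1 <- expression_map(rec1, window = 5)
  em2 <- expression_map(rec2, window = 5)
  expect_equal(em2$log2_ratio, em1$log2_ratio)
  split <- split_halves(fx$genes, fx$spec, "left_right")
  expect_equal(half_contrast(rec2, split, by_category = FALSE)$p_raw,
               half_contrast(rec1, split, by_category = FALSE)$p_raw)
})

test_that("replicon contrast reports medians and a planted shift", {
  set.seed(101)
  L <- 50000L
  chr <- toy_replicon(replicon_id = "chr", length_bp = L)
  chd <- toy_replicon(replicon_id = "chd", role = "chromid", length_bp = L,
                      replication_mode = "unidirectional")
  replicons <- rbind(chr, chd)
  g1 <- toy_genes(floor(runif(400, 0, L)), chr, len = 1000L, prefix = "a")
  g2 <- toy_genes(floor(runif(400, 0, L)), chd, len = 1000L, prefix = "b")
  genes <- rbind(g1, g2)
  counts <- data.frame(genome_id = "g1", gene_id = genes$gene_id,
                       read_count = c(rpois(400, 200), rpois(400, 100)))
  rec <- compute_rpkm(counts, genes, replicons)
  rc <- replicon_contrast(rec)
  expect_equal(rc$median_rpkm[rc$replicon_id == "chd"],
               median(rec$rpkm[rec$replicon_id == "chd"]))
  expect_gt(rc$median_rpkm[rc$replicon_id == "chr"],
            rc$median_rpkm[rc$replicon_id == "chd"])
  expect_lte(rc$p_adj[1], 0.05)
  # identical distributions: p near 1
  counts2 <- counts; counts2$read_count <- rep(rpois(400, 150), 2)
  rc2 <- replicon_contrast(compute_rpkm(counts2, genes, replicons))
  expect_gt(rc2$p_raw[1], 0.5)
})
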