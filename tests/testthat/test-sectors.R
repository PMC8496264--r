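# Sector binning, enrichment ratios, clade summaries, significance flags
# and replication-timing ranks.

test_that("sector assignment follows the rotation arithmetic", {
  spec <- toy_replicon(length_bp = 6000L, ori_pos = 0L)
  genes <- toy_genes(c(0, 500, 1500, 5999), spec, len = 2L)
  sc <- assign_sectors(genes, spec, S = 6)
  got <- rep(sc$sector, sc$count)
  expect_equal(sort(got), sort(c(1, 1, 2, 6)))  # ori gene lands in sector 1
  expect_equal(sum(sc$count), 4)
})

test_that("sector counts are conserved and rotation-invariant", {
  set.seed(14)
  L <- 50000L
  for (rep in 1:5) {
    mids <- floor(runif(200, 0, L))
    shift <- sample(0:(L - 1), 1)
    spec0 <- toy_replicon(length_bp = L, ori_pos = 0L)
    spec1 <- toy_replicon(length_bp = L, ori_pos = shift)
    cats <- sample(c("core", "softcore", "shell", "cloud"), 200, TRUE)
    cl <- sprintf("CL%03d", seq_along(mids))
    g0 <- toy_genes(mids, spec0, len = 2L, cluster_id = cl)
    g1 <- toy_genes((mids + shift) %% L, spec1, len = 2L, cluster_id = cl)
    assignment <- toy_categories(setNames(cats, cl))
    s0 <- assign_sectors(g0, spec0, 6, assignment)
    s1 <- assign_sectors(g1, spec1, 6, assignment)
    expect_equal(s1$count, s0$count)
    expect_equal(unname(tapply(s0$count, s0$category, sum)[
      sort(unique(cats))]),
      unname(table(cats)[sort(unique(cats))]),
      ignore_attr = TRUE)
  }
})

test_that("genes without a category are skipped or rejected as configured", {
  spec <- toy_replicon()
  genes <- toy_genes(c(100, 200, 300), spec,
                     cluster_id = c("CL1", "CL2", NA))
  assignment <- toy_categories(c(CL1 = "core", CL2 = "cloud"))
  expect_message(sc <- assign_sectors(genes, spec, 4, assignment), "skipped")
  expect_equal(sum(sc$count), 2)
  expect_error(assign_sectors(genes, spec, 4, assignment,
                              on_missing = "error"), "without")
})

test_that("enrichment ratio matches the log10 formula, sentinels included", {
  spec <- toy_replicon(length_bp = 6000L)
  # uniform: one gene per sector -> ratio 0 everywhere
  uni <- toy_genes(seq(500, 5500, by = 1000), spec, len = 2L,
                   cluster_id = rep("CL1", 6))
  assignment <- toy_categories(c(CL1 = "core", CL2 = "cloud"))
  er <- enrichment_ratio(assign_sectors(uni, spec, 6, assignment))
  expect_equal(er$log10_ratio[er$category == "core"], rep(0, 6))
  # full concentration in one of 6 sectors -> log10(6) there, -Inf elsewhere
  conc <- toy_genes(rep(250, 8), spec, len = 2L, cluster_id = rep("CL2", 8),
                    prefix = "h")
  er2 <- enrichment_ratio(assign_sectors(conc, spec, 6, assignment))
  cloud <- er2[er2$category == "cloud", ]
  expect_equal(cloud$log10_ratio[cloud$sector == 1], log10(6))
  expect_true(all(cloud$log10_ratio[cloud$sector != 1] == -Inf))
  # random counts: direct arithmetic oracle, both denominators
  set.seed(2)
  mids <- floor(runif(120, 0, 6000))
  cl <- sprintf("CL%03d", seq_along(mids))
  cats <- sample(c("core", "shell"), 120, TRUE)
  genes <- toy_genes(mids, spec, len = 2L, cluster_id = cl)
  sc <- assign_sectors(genes, spec, 6, toy_categories(setNames(cats, cl)))
  for (denom in c("category", "all")) {
    er3 <- suppressMessages(enrichment_ratio(sc, denominator = denom))
    for (i in seq_len(nrow(er3))) {
      n_cs <- sum(sc$count[sc$category == er3$category[i] &
                             sc$sector == er3$sector[i]])
      N <- if (denom == "category") sum(sc$count[sc$category == er3$category[i]])
           else sum(sc$count)
      expect_equal(er3$log10_ratio[i], log10((n_cs / N) / (1 / 6)))
    }
  }
})

test_that("summary ratio reduces to the per-genome ratio and matches brute force", {
  spec <- toy_replicon(length_bp = 6000L)
  assignment <- toy_categories(c(CL1 = "core"))
  one <- assign_sectors(toy_genes(c(100, 700, 1300, 200), spec, len = 2L,
                                  cluster_id = rep("CL1", 4)),
                        spec, 6, assignment)
  single <- summary_ratio(list(one))
  er <- enrichment_ratio(one)
  expect_equal(single$summary_log10_ratio, er$log10_ratio)
  expect_equal(summary_ratio(list(one, one))$summary_log10_ratio,
               er$log10_ratio)           # identical genomes: same ratio
  # 5 synthetic genomes vs direct recomputation of the averaged formula
  set.seed(6)
  counts <- lapply(1:5, function(g) {
    spec_g <- toy_replicon(genome_id = sprintf("g%d", g), length_bp = 6000L)
    mids <- floor(runif(40, 0, 6000))
    assign_sectors(toy_genes(mids, spec_g, len = 2L,
                             cluster_id = rep("CL1", 40)),
                   spec_g, 6, assignment)
  })
  summ <- summary_ratio(counts)
  core <- summ[summ$category == "core", ]
  mat <- sapply(counts, function(cc) cc$count[cc$category == "core"][
    order(cc$sector[cc$category == "core"])])
  mean_n <- rowMeans(mat)
  expect_equal(core$summary_log10_ratio[order(core$sector)],
               log10((mean_n / mean(colSums(mat))) / (1 / 6)))
})

test_that("planted 3x density in sector 6 is flagged overrepresented", {
  set.seed(33)
  assignment <- toy_categories(c(CL1 = "core"))
  counts <- lapply(1:20, function(g) {
    spec <- toy_replicon(genome_id = sprintf("g%02d", g), length_bp = 6000L)
    # 3x gene density in sector 6 versus sectors 1-5
    n <- c(rep(20, 5), 60)
    mids <- unlist(lapply(1:6, function(s) {
      floor(runif(n[s], (s - 1) * 1000, s * 1000))
    }))
    assign_sectors(toy_genes(mids, spec, len = 2L,
                             cluster_id = rep("CL1", length(mids))),
                   spec, 6, assignment)
  })
  st <- sector_tests(counts, "core", alpha = 0.05)
  expect_equal(st$flags$flag[6], "over")
  expect_lt(st$kw$p_raw, 0.001)
  # and a uniform null stays unflagged
  null_counts <- lapply(1:20, function(g) {
    spec <- toy_replicon(genome_id = sprintf("n%02d", g), length_bp = 6000L)
    mids <- floor(runif(120, 0, 6000))
    assign_sectors(toy_genes(mids, spec, len = 2L,
                             cluster_id = rep("CL1", 120)),
                   spec, 6, assignment)
  })
  st0 <- sector_tests(null_counts, "core")
  expect_true(all(st0$dunn$p_adj >= st0$dunn$p_raw))
})

test_that("identical counts across sectors give KW p = 1 and no flags", {
  assignment <- toy_categories(c(CL1 = "core"))
  counts <- lapply(1:4, function(g) {
    spec <- toy_replicon(genome_id = sprintf("g%d", g), length_bp = 6000L)
    mids <- rep(seq(500, 5500, by = 1000), each = 3)
    assign_sectors(toy_genes(mids, spec, len = 2L,
                             cluster_id = rep("CL1", length(mids))),
                   spec, 6, assignment)
  })
  st <- suppressWarnings(sector_tests(counts, "core"))
  expect_equal(st$kw$p_raw, 1)
  expect_true(all(st$flags$flag == "none"))
})

test_that("uniform placement fills sectors within the binomial envelope", {
  set.seed(55)
  L <- 1e6L
  spec <- toy_replicon(length_bp = L)
  S <- 8
  mids <- floor(runif(1000, 0, L))
  sc <- assign_sectors(toy_genes(mids, spec, len = 2L), spec, S)
  expect_true(all(abs(sc$count - 1000 / S) <= 5 * sqrt(1000 / S)))
})

test_that("replication timing ranks encode uni- and bidirectional order", {
  expect_equal(replication_timing_rank(6, "unidirectional"), 0:5)
  expect_equal(replication_timing_rank(6, "bidirectional"),
               c(0L, 1L, 2L, 2L, 1L, 0L))
  for (S in 2:12) {                       # mirror symmetry about the origin
    r <- replication_timing_rank(S, "bidirectional")
    expect_equal(r, r[S:1])
    expect_equal(replication_timing_rank(S, "unidirectional"), 0:(S - 1))
  }
})
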