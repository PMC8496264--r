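# Sector binning from the replication origin and per-category enrichment.
#
# A circular replicon is cut into S equal sectors clockwise from ori
# (sector 1 starts at the origin). Genes land in sectors by midpoint. The
# enrichment statistic is the log10 ratio of the observed probability of a
# gene of a category falling in a sector over the uniform expectation 1/S;
# significance across genomes comes from Kruskal-Wallis plus Dunn's post
# hoc pairwise z tests, Bonferroni-corrected within each category.

#' Bin one replicon's genes into S sectors from the origin
#'
#' The rotated position of a gene is `(midpoint - ori_pos) mod L` and its
#' sector is `floor(rotated * S / L) + 1`, so a gene sitting exactly on the
#' origin falls in sector 1.
#'
#' @param genes gene records of a single replicon of a single genome.
#' @param spec the matching one-row replicon table entry.
#' @param S number of sectors (>= 2; the field convention uses 4, 6, 8, 10
#'   or 12).
#' @param categories optional [classify_clusters()] result; when given,
#'   counts are tallied per pangene category, otherwise a single `all`
#'   category is used.
#' @param on_missing what to do with genes lacking a cluster/category when
#'   `categories` is given: `"skip"` (default, with a message) or `"error"`.
#' @return object of class `sector_counts`: data.frame with columns
#'   category, sector, count covering the full category x sector grid,
#'   with attributes `genome_id`, `replicon_id`, `S`, `role`, `mode`.
#' @export
assign_sectors <- function(genes, spec, S, categories = NULL,
                           on_missing = c("skip", "error")) {
  on_missing <- match.arg(on_missing)
  S <- as.integer(S)
  pr_assert(S >= 2, "S must be >= 2")
  pr_assert(nrow(spec) == 1, "spec must be a single replicon row")
  pr_assert(all(genes$genome_id == spec$genome_id) &&
              all(genes$replicon_id == spec$replicon_id),
            "genes must belong to the replicon described by spec")
  mid <- gene_midpoints(genes, spec)
  rotated <- (mid - spec$ori_pos) %% spec$length_bp
  sector <- pmin(floor(rotated * S / spec$length_bp) + 1, S)

  if (is.null(categories)) {
    cat_levels <- "all"
    gene_cat <- rep("all", nrow(genes))
  } else {
    cat_levels <- PANGENE_CATEGORIES
    gene_cat <- categories$category[match(genes$cluster_id,
                                          categories$cluster_id)]
    missing <- is.na(gene_cat)
    if (any(missing)) {
      if (on_missing == "error") {
        pr_stop("%d gene(s) without a pangene category on %s",
                sum(missing), spec$replicon_id)
      }
      message(sum(missing), " gene(s) without a category skipped on ",
              spec$genome_id, "/", spec$replicon_id)
      sector <- sector[!missing]
      gene_cat <- gene_cat[!missing]
    }
  }
  tab <- table(factor(gene_cat, levels = cat_levels),
               factor(sector, levels = seq_len(S)))
  out <- data.frame(category = rep(cat_levels, times = S),
                    sector = rep(seq_len(S), each = length(cat_levels)),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  structure(out, class = c("sector_counts", "data.frame"),
            genome_id = spec$genome_id, replicon_id = spec$replicon_id,
            S = S, role = spec$role, mode = spec$replication_mode)
}

#' @noRd
counts_matrix <- function(counts, category) {
  # one sector_counts -> named count vector of one category
  sel <- counts$category == category
  stats::setNames(counts$count[sel], counts$sector[sel])[as.character(seq_len(attr(counts, "S")))]
}

#' Per-genome log10 enrichment ratios
#'
#' `ratio[c][s] = log10((n[c][s] / N[c]) / (1 / S))` with `N[c]` the
#' replicon's gene total for category c (default) or, with
#' `denominator = "all"`, the replicon's all-category gene total. Zero
#' counts give `-Inf` (no pseudocount is applied); categories with no genes
#' are omitted with a message.
#'
#' @param counts a [assign_sectors()] result.
#' @param denominator `"category"` (default) or `"all"`.
#' @return data.frame with columns category, sector, count, log10_ratio.
#' @export
enrichment_ratio <- function(counts, denominator = c("category", "all")) {
  denominator <- match.arg(denominator)
  S <- attr(counts, "S")
  totals <- tapply(counts$count, counts$category, sum)
  n_all <- sum(counts$count)
  keep <- names(totals)[totals > 0]
  dropped <- setdiff(names(totals), keep)
  if (length(dropped) > 0) {
    message("category with no genes omitted: ", paste(dropped, collapse = ", "))
  }
  out <- counts[counts$category %in% keep, , drop = FALSE]
  denom <- if (denominator == "category") as.numeric(totals[out$category])
           else n_all
  out$log10_ratio <- as.numeric(log10((out$count / denom) / (1 / S)))
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}

#' Clade-averaged summary log10 enrichment ratios
#'
#' Across the genomes of one replicon class:
#' `summary[c][s] = log10((mean_g n_g[c][s] / mean_g N_g[c]) / (1 / S))`,
#' i.e. the probability of a gene belonging to a sector on average over the
#' uniform expectation. For a single genome this reduces to
#' [enrichment_ratio()].
#'
#' @param counts_list list of [assign_sectors()] results sharing S.
#' @param denominator `"category"` (default) or `"all"`.
#' @return data.frame with columns category, sector, mean_count,
#'   summary_log10_ratio.
#' @export
summary_ratio <- function(counts_list, denominator = c("category", "all")) {
  denominator <- match.arg(denominator)
  pr_assert(length(counts_list) >= 1, "need at least one sector_counts")
  S_all <- vapply(counts_list, attr, integer(1), which = "S")
  pr_assert(length(unique(S_all)) == 1, "all sector counts must share S")
  S <- S_all[1]
  cats <- unique(counts_list[[1]]$category)
  stack <- vapply(counts_list, function(cc) cc$count,
                  numeric(nrow(counts_list[[1]])))   # cells x genomes
  mean_count <- rowMeans(stack)
  grid <- counts_list[[1]][, c("category", "sector")]
  mean_total <- tapply(mean_count, grid$category, sum)[cats]
  keep <- cats[mean_total[cats] > 0]
  if (length(keep) < length(cats)) {
    message("category with zero mean total omitted: ",
            paste(setdiff(cats, keep), collapse = ", "))
  }
  sel <- grid$category %in% keep
  denom <- if (denominator == "category")
             as.numeric(mean_total[grid$category[sel]])
           else sum(mean_count)
  out <- data.frame(category = grid$category[sel],
                    sector = grid$sector[sel],
                    mean_count = mean_count[sel],
                    summary_log10_ratio =
                      as.numeric(log10((mean_count[sel] / denom) / (1 / S))),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Sector-wise significance for one category across genomes
#'
#' Treats the S sectors as groups and the per-genome gene counts as
#' observations: a Kruskal-Wallis omnibus test, Dunn's post hoc z tests
#' over all S(S-1)/2 sector pairs (Bonferroni within this family), and a
#' per-sector flag. A sector is flagged over- (under-)represented when its
#' summary log10 ratio is positive (negative) and at least one Dunn
#' pairwise adjusted p involving it is at most `alpha`; with
#' `flag_rule = "all"` every pairwise test involving the sector must pass.
#'
#' @param counts_list list of [assign_sectors()] results (one per genome)
#'   sharing S. Fewer than 3 genomes draws a warning.
#' @param category the pangene category to test.
#' @param alpha significance level for flags (default 0.05).
#' @param denominator passed to [summary_ratio()].
#' @param flag_rule `"any"` (default) or `"all"` significant pairwise
#'   comparisons required to flag a sector.
#' @return list with `kw` (a `rank_test`), `dunn` (pairwise data.frame) and
#'   `flags` (data.frame: sector, summary_log10_ratio, flag in
#'   over/under/none).
#' @export
sector_tests <- function(counts_list, category, alpha = 0.05,
                         denominator = c("category", "all"),
                         flag_rule = c("any", "all")) {
  denominator <- match.arg(denominator)
  flag_rule <- match.arg(flag_rule)
  if (length(counts_list) < 3) {
    warning("fewer than 3 genomes; sector tests will have little power",
            call. = FALSE)
  }
  S <- attr(counts_list[[1]], "S")
  obs <- lapply(seq_len(S), function(s) {
    vapply(counts_list, function(cc) {
      cc$count[cc$category == category & cc$sector == s]
    }, numeric(1))
  })
  names(obs) <- as.character(seq_len(S))
  if (length(unique(unlist(obs))) == 1) {
    kw <- rank_test_result(0, 1, "kruskal_wallis")
    dunn <- dunn_posthoc(obs)        # all-tied: z = 0, p = 1 throughout
  } else {
    kw <- suppressWarnings(kruskal_wallis(obs))
    dunn <- suppressWarnings(dunn_posthoc(obs))
  }
  summ <- summary_ratio(counts_list, denominator)
  summ <- summ[summ$category == category, , drop = FALSE]
  flags <- data.frame(sector = seq_len(S),
                      summary_log10_ratio = summ$summary_log10_ratio[
                        match(seq_len(S), summ$sector)],
                      flag = "none", stringsAsFactors = FALSE)
  for (s in seq_len(S)) {
    involved <- dunn$group_i == as.character(s) | dunn$group_j == as.character(s)
    hit <- if (flag_rule == "any") any(dunn$p_adj[involved] <= alpha)
           else all(dunn$p_adj[involved] <= alpha)
    r <- flags$summary_log10_ratio[s]
    if (isTRUE(hit) && !is.na(r) && r != 0) {
      flags$flag[s] <- if (r > 0) "over" else "under"
    }
  }
  list(kw = kw, dunn = dunn, flags = flags)
}

#' Replication-timing rank of each sector
#'
#' Maps sectors to replication order. Unidirectional replicons are
#' traversed once clockwise from ori, so `rank(s) = s - 1` (sector 1
#' earliest, sector S latest). Bidirectional replicons replicate both arms
#' simultaneously towards the terminus opposite ori, so
#' `rank(s) = min(s - 1, S - s)` (sectors flanking ori earliest, sectors
#' opposite latest).
#'
#' @param S number of sectors (>= 2).
#' @param mode `"unidirectional"` or `"bidirectional"`.
#' @return integer vector of length S.
#' @export
replication_timing_rank <- function(S, mode = REPLICATION_MODES) {
  mode <- match.arg(mode)
  S <- as.integer(S)
  pr_assert(S >= 2, "S must be >= 2")
  s <- seq_len(S)
  if (mode == "unidirectional") s - 1L else pmin(s - 1L, S - s)
}

#' Replicon-class sector enrichment maps with significance flags
#'
#' The full heatmap computation: genes of every replicon are binned into S
#' sectors per genome, replicons are grouped into classes (`chromosome`,
#' `chromid_unidirectional`, `chromid_bidirectional`), and per class x
#' category the clade-averaged summary log10 ratio, the replication-timing
#' rank and the Kruskal-Wallis/Dunn significance flags are assembled.
#'
#' @param genes gene table with cluster ids.
#' @param replicons replicon table.
#' @param categories [classify_clusters()] result.
#' @param S number of sectors (default 6).
#' @param alpha significance level (default 0.05).
#' @param clamp floor applied to `-Inf` (zero-count) summary ratios in the
#'   exported table (default -2).
#' @param denominator,flag_rule passed to the underlying operations.
#' @return list with `enrichment` (replicon_class, category, S, sector,
#'   mean_count, summary_log10_ratio, timing_rank, flag) and `tests`
#'   (replicon_class, category, test, sector_i, sector_j, statistic,
#'   p_raw, p_adj).
#' @export
sector_enrichment <- function(genes, replicons, categories, S = 6,
                              alpha = 0.05, clamp = -2,
                              denominator = c("category", "all"),
                              flag_rule = c("any", "all")) {
  denominator <- match.arg(denominator)
  flag_rule <- match.arg(flag_rule)
  replicons$class <- ifelse(replicons$role == "chromosome", "chromosome",
                            paste0("chromid_", replicons$replication_mode))
  enr <- list(); tst <- list()
  for (cls in unique(replicons$class)) {
    rs <- replicons[replicons$class == cls, , drop = FALSE]
    modes <- unique(rs$replication_mode)
    pr_assert(length(modes) == 1,
              "replicon class %s mixes replication modes", cls)
    counts_list <- lapply(seq_len(nrow(rs)), function(i) {
      spec <- rs[i, , drop = FALSE]
      gsel <- genes[genes$genome_id == spec$genome_id &
                      genes$replicon_id == spec$replicon_id, , drop = FALSE]
      assign_sectors(gsel, spec, S, categories)
    })
    summ <- summary_ratio(counts_list, denominator)
    timing <- replication_timing_rank(S, modes)
    for (category in intersect(PANGENE_CATEGORIES, unique(summ$category))) {
      st <- suppressWarnings(
        sector_tests(counts_list, category, alpha, denominator, flag_rule))
      sc <- summ[summ$category == category, , drop = FALSE]
      ratio <- pmax(sc$summary_log10_ratio, clamp)
      enr[[length(enr) + 1]] <- data.frame(
        replicon_class = cls, category = category, S = S,
        sector = sc$sector, mean_count = sc$mean_count,
        summary_log10_ratio = ratio,
        timing_rank = timing[sc$sector],
        flag = st$flags$flag[match(sc$sector, st$flags$sector)],
        stringsAsFactors = FALSE)
      tst[[length(tst) + 1]] <- rbind(
        data.frame(replicon_class = cls, category = category,
                   test = "kruskal_wallis", sector_i = NA_character_,
                   sector_j = NA_character_, statistic = st$kw$statistic,
                   p_raw = st$kw$p_raw, p_adj = st$kw$p_adj,
                   stringsAsFactors = FALSE),
        data.frame(replicon_class = cls, category = category,
                   test = "dunn", sector_i = st$dunn$group_i,
                   sector_j = st$dunn$group_j, statistic = st$dunn$z,
                   p_raw = st$dunn$p_raw, p_adj = st$dunn$p_adj,
                   stringsAsFactors = FALSE))
    }
  }
  list(enrichment = do.call(rbind, enr), tests = do.call(rbind, tst))
}
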