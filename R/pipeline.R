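# End-to-end orchestration: classify, map sectors, score expression,
# census the chromid — from in-memory tables, from files, or from a fresh
# simulation. One call produces the full set of plot-ready result tables.

#' Run the complete replicon-architecture analysis on tables
#'
#' @param replicons,genes,clusters validated input tables (see the
#'   `read_*_table` readers).
#' @param counts optional per-gene read-count table; expression results
#'   are skipped when absent.
#' @param S number of sectors (default 6).
#' @param alpha significance level for flags and contrasts (default 0.05).
#' @param window sliding-window size of the expression trend (default 100).
#' @param softcore_min,cloud_max classification thresholds (defaults
#'   [default_softcore_min()] and 2).
#' @param window_fraction terminus-proximity window (default 0.10).
#' @param denominator sector probability denominator, `"category"`
#'   (default) or `"all"`.
#' @return named list of result data.frames: `cluster_categories`,
#'   `pangenome_summary`, `sector_enrichment`, `sector_tests`,
#'   `chromid_association`, `association_summary`, `hallmark_summary`,
#'   `hallmark_members`, and with counts `expression_map`,
#'   `quartile_table`, `replicon_contrast`.
#' @export
analyze_dataset <- function(replicons, genes, clusters, counts = NULL,
                            S = 6, alpha = 0.05, window = 100,
                            softcore_min = NULL, cloud_max = 2L,
                            window_fraction = 0.10,
                            denominator = c("category", "all")) {
  denominator <- match.arg(denominator)
  mat <- pangenome_matrix(clusters,
                          genomes = sort(unique(replicons$genome_id)))
  categories <- classify_clusters(mat, softcore_min, cloud_max)
  summ <- pangenome_summary(categories)
  res <- list(
    cluster_categories = as.data.frame(categories),
    pangenome_summary = data.frame(category = names(summ),
                                   n_clusters = as.integer(summ),
                                   stringsAsFactors = FALSE)
  )
  sect <- sector_enrichment(genes, replicons, categories, S = S,
                            alpha = alpha, denominator = denominator)
  res$sector_enrichment <- sect$enrichment
  res$sector_tests <- sect$tests

  assoc <- associate_clusters(clusters, genes, replicons)
  res$chromid_association <- assoc
  res$association_summary <- association_summary(assoc, categories)
  hallmarks <- find_hallmarks(assoc, categories)
  if (length(hallmarks) > 0) {
    prox <- terminus_proximity(hallmarks, clusters, genes, replicons,
                               window_fraction)
    res$hallmark_summary <- prox$summary
    res$hallmark_members <- prox$members
  } else {
    res$hallmark_summary <- data.frame(cluster_id = character(),
                                       median_distance_bp = numeric(),
                                       median_distance_fraction = numeric(),
                                       within_window = logical())
    res$hallmark_members <- data.frame(cluster_id = character(),
                                       genome_id = character(),
                                       gene_id = character(),
                                       replicon_id = character(),
                                       distance_to_ter_bp = numeric(),
                                       distance_fraction = numeric())
  }

  if (!is.null(counts) && nrow(counts) > 0) {
    maps <- list(); quart <- list(); contrasts <- list()
    for (gid in unique(counts$genome_id)) {
      cc <- counts[counts$genome_id == gid, , drop = FALSE]
      records <- compute_rpkm(cc, genes, replicons, categories)
      emap <- expression_map(records, window = window)
      maps[[gid]] <- emap[, c("genome_id", "gene_id", "replicon_id",
                              "position", "rpkm", "log2_ratio", "trend")]
      reps <- replicons[replicons$genome_id == gid, , drop = FALSE]
      for (i in seq_len(nrow(reps))) {
        spec <- reps[i, , drop = FALSE]
        rrec <- records[records$replicon_id == spec$replicon_id, ,
                        drop = FALSE]
        if (nrow(rrec) == 0) next
        gsel <- genes[genes$genome_id == gid &
                        genes$replicon_id == spec$replicon_id, , drop = FALSE]
        schemes <- if (spec$role == "chromid") {
          c("upper_lower", "left_right")
        } else "upper_lower"
        for (scheme in schemes) {
          hc <- half_contrast(rrec, split_halves(gsel, spec, scheme))
          hc <- cbind(genome_id = gid, replicon_id = spec$replicon_id,
                      scheme = scheme, hc, stringsAsFactors = FALSE)
          quart[[length(quart) + 1]] <- hc
        }
      }
      if (length(unique(records$replicon_id)) == 2) {
        rc <- replicon_contrast(records)
        contrasts[[gid]] <- cbind(genome_id = gid, rc,
                                  stringsAsFactors = FALSE)
      }
    }
    res$expression_map <- do.call(rbind, c(maps, list(make.row.names = FALSE)))
    res$quartile_table <- do.call(rbind, c(quart, list(make.row.names = FALSE)))
    if (length(contrasts) > 0) {
      res$replicon_contrast <- do.call(rbind, c(contrasts,
                                                list(make.row.names = FALSE)))
    }
  }
  res
}

#' Run the pipeline on a synthetic dataset or on input files
#'
#' With a [sim_config()] the dataset is simulated first (and, when
#' `out_dir` is given, the simulated input tables and the truth table are
#' written next to the results). Alternatively pass the four input file
#' paths.
#'
#' @param config a [sim_config()] (simulation route), or NULL.
#' @param replicon_table,gene_table,cluster_table,count_table input file
#'   paths (file route; `count_table` optional).
#' @param out_dir optional output directory; results are written as TSVs
#'   plus a `manifest.json` via [write_results()].
#' @param overwrite passed to [write_results()].
#' @param ... analysis parameters passed to [analyze_dataset()].
#' @return the [analyze_dataset()] result list, invisibly when writing.
#' @export
run_pipeline <- function(config = NULL, replicon_table = NULL,
                         gene_table = NULL, cluster_table = NULL,
                         count_table = NULL, out_dir = NULL,
                         overwrite = FALSE, ...) {
  inputs <- character()
  dots <- list(...)
  if (!is.null(config)) {
    pr_assert(inherits(config, "sim_config"),
              "config must come from sim_config()")
    # analyse with the thresholds the dataset was generated under
    if (is.null(dots$softcore_min)) dots$softcore_min <- config$softcore_min
    if (is.null(dots$cloud_max)) dots$cloud_max <- config$cloud_max
    sim <- simulate_dataset(config)
    replicons <- sim$replicons; genes <- sim$genes
    clusters <- sim$clusters; counts <- sim$counts
    truth <- sim$truth
    seed <- config$seed
  } else {
    pr_assert(!is.null(replicon_table) && !is.null(gene_table) &&
                !is.null(cluster_table),
              "need either a sim_config or replicon/gene/cluster table paths")
    replicons <- read_replicon_table(replicon_table)
    genes <- read_gene_table(gene_table, "tsv", replicons)
    clusters <- read_cluster_table(cluster_table, genes)
    counts <- if (!is.null(count_table)) read_count_table(count_table, genes)
    truth <- NULL
    seed <- NULL
    inputs <- c(replicon_table, gene_table, cluster_table, count_table)
  }
  res <- do.call(analyze_dataset,
                 c(list(replicons, genes, clusters, counts), dots))
  if (!is.null(out_dir)) {
    tables <- res
    if (!is.null(truth)) {
      tables$sim_replicons <- replicons
      tables$sim_genes <- genes
      tables$sim_clusters <- clusters
      tables$sim_counts <- counts
      tables$sim_truth <- truth
    }
    params <- dots
    write_results(tables, out_dir, inputs = inputs, params = params,
                  seed = seed, overwrite = overwrite)
    return(invisible(res))
  }
  res
}
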