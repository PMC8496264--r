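# Pangenome prevalence classification and a desk-scale protein clustering
# stand-in for a full BLAST+MCL orthology run.

#' Build a cluster x genome presence matrix
#'
#' @param clusters cluster membership table (cluster_id, genome_id, gene_id),
#'   as returned by [read_cluster_table()].
#' @param genomes optional character vector fixing the genome universe (and
#'   order); defaults to the genomes observed in `clusters`. Genomes that
#'   encode no clustered gene still count toward N when listed here.
#' @return object of class `pangenome_matrix`: list with `genomes`,
#'   `clusters` and a logical `presence` matrix (clusters x genomes).
#' @export
pangenome_matrix <- function(clusters, genomes = NULL) {
  if (is.null(genomes)) genomes <- sort(unique(clusters$genome_id))
  pr_assert(all(clusters$genome_id %in% genomes),
            "cluster table contains genomes absent from the genome universe")
  cl <- sort(unique(clusters$cluster_id))
  presence <- matrix(FALSE, nrow = length(cl), ncol = length(genomes),
                     dimnames = list(cl, genomes))
  presence[cbind(match(clusters$cluster_id, cl),
                 match(clusters$genome_id, genomes))] <- TRUE
  pr_assert(all(rowSums(presence) > 0), "every cluster must be non-empty")
  structure(list(genomes = genomes, clusters = cl, presence = presence),
            class = "pangenome_matrix")
}

#' @export
print.pangenome_matrix <- function(x, ...) {
  cat("pangenome_matrix:", length(x$clusters), "clusters x",
      length(x$genomes), "genomes\n")
  invisible(x)
}

#' Default softcore prevalence threshold
#'
#' `ceiling(0.92 * N)` genomes; for N = 25 this is 23, i.e. softcore =
#' present in at least 23 of 25 genomes.
#'
#' @param n_genomes number of genomes N.
#' @return integer threshold.
#' @export
default_softcore_min <- function(n_genomes) as.integer(ceiling(0.92 * n_genomes))

#' Classify clusters into core / softcore / shell / cloud
#'
#' A cluster present in k of N genomes is `core` if k = N, `softcore` if
#' `softcore_min <= k < N`, `cloud` if `k <= cloud_max`, and `shell`
#' otherwise. With the defaults (softcore_min = ceiling(0.92 N), cloud_max =
#' 2) and N = 25 this reproduces the usual boundaries: core = 25 genomes,
#' softcore = 23-24, shell = 3-22, cloud = 1-2.
#'
#' @param matrix a [pangenome_matrix()].
#' @param softcore_min minimum prevalence for softcore; default
#'   [default_softcore_min()].
#' @param cloud_max maximum prevalence for cloud (default 2).
#' @return object of class `category_assignment`: data.frame with columns
#'   cluster_id, prevalence, category, carrying the thresholds and N as
#'   attributes.
#' @export
classify_clusters <- function(matrix, softcore_min = NULL, cloud_max = 2L) {
  pr_assert(inherits(matrix, "pangenome_matrix"),
            "matrix must be a pangenome_matrix")
  n <- length(matrix$genomes)
  if (is.null(softcore_min)) softcore_min <- default_softcore_min(n)
  softcore_min <- as.integer(softcore_min)
  cloud_max <- as.integer(cloud_max)
  pr_assert(cloud_max >= 0 && cloud_max < softcore_min && softcore_min <= n,
            "need 0 <= cloud_max < softcore_min <= N (got cloud_max=%d, softcore_min=%d, N=%d)",
            cloud_max, softcore_min, n)
  k <- rowSums(matrix$presence)
  category <- ifelse(k == n, "core",
              ifelse(k >= softcore_min, "softcore",
              ifelse(k <= cloud_max, "cloud", "shell")))
  out <- data.frame(cluster_id = matrix$clusters,
                    prevalence = as.integer(k),
                    category = category,
                    stringsAsFactors = FALSE)
  structure(out, class = c("category_assignment", "data.frame"),
            n_genomes = n, softcore_min = softcore_min, cloud_max = cloud_max)
}

#' Category counts of a classification
#'
#' @param assignment a [classify_clusters()] result.
#' @return named integer vector with core, softcore, shell, cloud and total.
#' @export
pangenome_summary <- function(assignment) {
  counts <- vapply(PANGENE_CATEGORIES,
                   function(cat) sum(assignment$category == cat), integer(1))
  c(counts, total = nrow(assignment))
}

#' Cluster protein sequences by pairwise global alignment
#'
#' A deliberately simple orthology stand-in: all-vs-all ends-free global
#' alignment (BLOSUM62), an edge where identity (matches / alignment columns
#' excluding terminal gaps) reaches `min_identity` and the aligned span
#' covers at least `min_coverage` of *both* sequences, then single-linkage
#' connected components. Quadratic in the number of sequences — intended for
#' small inputs, not genome-scale runs. Deterministic and symmetric in input
#' order; each cluster is named after its lexicographically smallest member.
#'
#' @param sequences named character vector (or `Biostrings::AAStringSet`) of
#'   amino-acid sequences over the 20-letter alphabet.
#' @param min_identity minimum fractional identity (default 0.50).
#' @param min_coverage minimum mutual coverage (default 0.75).
#' @return data.frame with columns cluster_id, member.
#' @export
cluster_proteins <- function(sequences, min_identity = 0.50,
                             min_coverage = 0.75) {
  if (inherits(sequences, "AAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  pr_assert(length(sequences) > 0, "no sequences supplied")
  pr_assert(!is.null(names(sequences)) && all(nzchar(names(sequences))) &&
              !anyDuplicated(names(sequences)),
            "sequences must have unique non-empty names")
  pr_assert(all(nchar(sequences) > 0), "empty sequence(s): %s",
            paste(names(sequences)[nchar(sequences) == 0], collapse = ", "))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", sequences)
  pr_assert(!any(bad), "non amino-acid characters in: %s",
            paste(names(sequences)[bad], collapse = ", "))

  nm <- sort(names(sequences))          # canonical order: input-order invariant
  sequences <- sequences[nm]
  n <- length(sequences)
  edges <- list()
  if (n >= 2) {
    aa <- Biostrings::AAStringSet(sequences)
    data("BLOSUM62", package = "Biostrings", envir = environment())
    mat <- get("BLOSUM62", envir = environment())
    for (i in seq_len(n - 1)) {
      alns <- Biostrings::pairwiseAlignment(
        aa[(i + 1):n], aa[[i]], type = "overlap",
        substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5)
      # "overlap" alignments exclude terminal gaps by construction
      ident <- Biostrings::nmatch(alns) / Biostrings::nchar(alns)
      span_q <- Biostrings::width(Biostrings::pattern(alns))
      span_s <- Biostrings::width(Biostrings::subject(alns))
      cov_q <- span_q / nchar(sequences[(i + 1):n])
      cov_s <- span_s / nchar(sequences[i])
      hit <- !is.nan(ident) & ident >= min_identity &
        cov_q >= min_coverage & cov_s >= min_coverage
      if (any(hit)) {
        edges[[length(edges) + 1]] <-
          cbind(nm[i], nm[(i + 1):n][hit])
      }
    }
  }
  edge_df <- if (length(edges) > 0) {
    stats::setNames(as.data.frame(do.call(rbind, edges),
                                  stringsAsFactors = FALSE), c("from", "to"))
  } else {
    data.frame(from = character(), to = character())
  }
  g <- igraph::graph_from_data_frame(edge_df, directed = FALSE, vertices = nm)
  comp <- igraph::components(g)$membership[nm]
  rep_member <- vapply(split(nm, comp), min, character(1))
  data.frame(cluster_id = paste0("C_", unname(rep_member[as.character(comp)])),
             member = nm, stringsAsFactors = FALSE)
}
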