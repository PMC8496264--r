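# Chromid-associated clusters, chromid hallmark genes (core clusters found
# on the chromid in every genome) and their replication-terminus proximity.

#' Classify clusters by replicon association
#'
#' A cluster is `chromid_only` when every member gene lies on a chromid in
#' every genome, `chromosome_only` when every member lies on a chromosome,
#' and `mixed` otherwise. Chromid-associated clusters (found at least once
#' on a chromid) are `chromid_only` plus `mixed`.
#'
#' @param clusters cluster membership table.
#' @param genes gene table.
#' @param replicons replicon table.
#' @return data.frame with columns cluster_id, association, n_members,
#'   n_chromid_members.
#' @export
associate_clusters <- function(clusters, genes, replicons) {
  gidx <- match(paste(clusters$genome_id, clusters$gene_id),
                paste(genes$genome_id, genes$gene_id))
  pr_assert(!anyNA(gidx), "cluster member(s) missing from the gene table")
  ridx <- match(paste(genes$genome_id[gidx], genes$replicon_id[gidx]),
                paste(replicons$genome_id, replicons$replicon_id))
  pr_assert(!anyNA(ridx), "cluster member(s) on an unknown replicon")
  on_chromid <- replicons$role[ridx] == "chromid"
  n_members <- tapply(on_chromid, clusters$cluster_id, length)
  n_chromid <- tapply(on_chromid, clusters$cluster_id, sum)
  association <- ifelse(n_chromid == n_members, "chromid_only",
                 ifelse(n_chromid == 0, "chromosome_only", "mixed"))
  out <- data.frame(cluster_id = names(n_members),
                    association = unname(association),
                    n_members = as.integer(n_members),
                    n_chromid_members = as.integer(n_chromid),
                    stringsAsFactors = FALSE)
  out[order(out$cluster_id), , drop = FALSE]
}

#' Per-category census of chromid association
#'
#' Tallies, per pangene category, the chromid_only / mixed /
#' chromosome_only cluster counts, the chromid-associated cluster count
#' (chromid_only + mixed) and the corresponding count of chromidal gene
#' occurrences — both resolutions of "genes associated with the chromid".
#'
#' @param association an [associate_clusters()] result.
#' @param categories a [classify_clusters()] result over the same clusters.
#' @return data.frame with one row per category.
#' @export
association_summary <- function(association, categories) {
  cat_of <- categories$category[match(association$cluster_id,
                                      categories$cluster_id)]
  pr_assert(!anyNA(cat_of),
            "association and categories must cover the same clusters")
  rows <- lapply(PANGENE_CATEGORIES, function(cat) {
    a <- association[cat_of == cat, , drop = FALSE]
    data.frame(category = cat,
               chromid_only = sum(a$association == "chromid_only"),
               mixed = sum(a$association == "mixed"),
               chromosome_only = sum(a$association == "chromosome_only"),
               chromid_associated_clusters =
                 sum(a$association %in% c("chromid_only", "mixed")),
               chromid_gene_occurrences = sum(a$n_chromid_members),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Chromid hallmark clusters
#'
#' Hallmark genes of the chromid: clusters that are `core` (present in all
#' genomes) *and* `chromid_only` (on the chromid in every genome) — the
#' strictest reading of "always located on the chromid". Returned sorted by
#' cluster_id.
#'
#' @param association an [associate_clusters()] result.
#' @param categories a [classify_clusters()] result.
#' @return character vector of hallmark cluster ids.
#' @export
find_hallmarks <- function(association, categories) {
  cat_of <- categories$category[match(association$cluster_id,
                                      categories$cluster_id)]
  pr_assert(!anyNA(cat_of),
            "association and categories must cover the same clusters")
  sort(association$cluster_id[cat_of == "core" &
                                association$association == "chromid_only"])
}

#' Replicon terminus position
#'
#' Bidirectional replication ends opposite the origin
#' (`(ori + L/2) mod L`); unidirectional replication traverses the whole
#' circle once and ends where it began (`ori`).
#'
#' @param replicons replicon table.
#' @return numeric vector of terminus positions, parallel to rows.
#' @export
terminus_position <- function(replicons) {
  ifelse(replicons$replication_mode == "bidirectional",
         (replicons$ori_pos + replicons$length_bp / 2) %% replicons$length_bp,
         replicons$ori_pos)
}

#' Terminus proximity of hallmark clusters
#'
#' For every member gene of each hallmark cluster, the minimal circular
#' distance from its midpoint to the replicon terminus (bp and as a
#' fraction of replicon length); per cluster, the median across genomes;
#' and the count of clusters whose median fractional distance is within
#' `window_fraction` of the terminus.
#'
#' @param hallmarks character vector of hallmark cluster ids
#'   (from [find_hallmarks()]).
#' @param clusters cluster membership table.
#' @param genes gene table.
#' @param replicons replicon table.
#' @param window_fraction "close to the terminus" cutoff as a fraction of
#'   replicon length (default 0.10).
#' @return list with `members` (per member gene: cluster_id, genome_id,
#'   gene_id, replicon_id, distance_to_ter_bp, distance_fraction),
#'   `summary` (per cluster medians plus a within-window flag) and
#'   `n_within` (clusters with median distance inside the window).
#' @export
terminus_proximity <- function(hallmarks, clusters, genes, replicons,
                               window_fraction = 0.10) {
  pr_assert(window_fraction > 0 && window_fraction <= 0.5,
            "window_fraction must be in (0, 0.5]")
  m <- clusters[clusters$cluster_id %in% hallmarks, , drop = FALSE]
  gidx <- match(paste(m$genome_id, m$gene_id),
                paste(genes$genome_id, genes$gene_id))
  pr_assert(!anyNA(gidx), "hallmark member(s) missing from the gene table")
  g <- genes[gidx, , drop = FALSE]
  rkey <- paste(replicons$genome_id, replicons$replicon_id)
  ridx <- match(paste(g$genome_id, g$replicon_id), rkey)
  pr_assert(!anyNA(ridx), "hallmark member(s) on an unknown replicon")
  L <- replicons$length_bp[ridx]
  ter <- terminus_position(replicons)[ridx]
  mid <- gene_midpoints(g, replicons)
  d <- circular_distance(mid, ter, L)
  members <- data.frame(cluster_id = m$cluster_id,
                        genome_id = m$genome_id,
                        gene_id = m$gene_id,
                        replicon_id = g$replicon_id,
                        distance_to_ter_bp = d,
                        distance_fraction = d / L,
                        stringsAsFactors = FALSE)
  members <- members[order(members$cluster_id, members$genome_id), ,
                     drop = FALSE]
  rownames(members) <- NULL
  med_bp <- tapply(members$distance_to_ter_bp, members$cluster_id,
                   stats::median)
  med_fr <- tapply(members$distance_fraction, members$cluster_id,
                   stats::median)
  summary <- data.frame(cluster_id = names(med_bp),
                        median_distance_bp = unname(med_bp),
                        median_distance_fraction = unname(med_fr),
                        within_window = unname(med_fr) <= window_fraction,
                        stringsAsFactors = FALSE)
  summary <- summary[order(summary$cluster_id), , drop = FALSE]
  rownames(summary) <- NULL
  list(members = members, summary = summary,
       n_within = sum(summary$within_window),
       window_fraction = window_fraction)
}
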