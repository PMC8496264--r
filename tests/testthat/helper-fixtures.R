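# In-code fixture builders shared across the suite.

# A replicon table row (defaults: one chromosome, ori at 0, bidirectional).
toy_replicon <- function(genome_id = "g1", replicon_id = "chr",
                         role = "chromosome", length_bp = 6000L,
                         ori_pos = 0L, replication_mode = "bidirectional") {
  data.frame(genome_id = genome_id, replicon_id = replicon_id, role = role,
             length_bp = as.integer(length_bp), ori_pos = as.integer(ori_pos),
             replication_mode = replication_mode, stringsAsFactors = FALSE)
}

# Genes placed by midpoint on one replicon (fixed short length).
toy_genes <- function(midpoints, spec, len = 100L, cluster_id = NA,
                      prefix = "g") {
  L <- spec$length_bp
  start <- (round(midpoints - len / 2)) %% L
  end_lin <- start + len
  data.frame(genome_id = spec$genome_id,
             replicon_id = spec$replicon_id,
             gene_id = sprintf("%s%03d", prefix, seq_along(midpoints)),
             start = as.integer(start),
             end = as.integer(ifelse(end_lin > L, end_lin - L, end_lin)),
             strand = "+",
             cluster_id = if (length(cluster_id) == 1 && is.na(cluster_id))
               NA_character_ else cluster_id,
             wraps = end_lin > L,
             stringsAsFactors = FALSE)
}

# A presence/absence cluster table: cluster i present in genomes[members[[i]]].
toy_cluster_table <- function(members, genomes) {
  do.call(rbind, lapply(seq_along(members), function(i) {
    data.frame(cluster_id = sprintf("CL%03d", i),
               genome_id = genomes[members[[i]]],
               gene_id = sprintf("CL%03d_%s", i, genomes[members[[i]]]),
               stringsAsFactors = FALSE)
  }))
}

# A category_assignment-shaped data.frame from a named vector
# cluster_id -> category (for operations that only need the mapping).
toy_categories <- function(mapping) {
  structure(data.frame(cluster_id = names(mapping),
                       prevalence = NA_integer_,
                       category = unname(mapping),
                       stringsAsFactors = FALSE),
            class = c("category_assignment", "data.frame"))
}

# Scaled-down simulation config for fast unit tests.
small_sim_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_genomes = 8L,
             chromosome_length = 4e5, chromid_length = 1e5,
             genes_per_chromosome = 300L, genes_per_chromid = 120L,
             softcore_min = 7L, cloud_max = 2L, ...)
}

# Independent sector assignment oracle: plain arithmetic per gene.
oracle_sector <- function(midpoint, ori, L, S) {
  floor((((midpoint - ori) %% L) * S / L)) + 1
}
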