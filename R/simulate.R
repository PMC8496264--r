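# Synthetic multipartite genome collections: N exchangeable genomes, each
# one chromosome plus one chromid, with a controllable cluster prevalence
# spectrum, category-specific spatial placement bias and an expression
# model with a multiplicative dosage gradient from the origin plus
# lognormal noise. Everything is deterministic under the config seed.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Default per-category placement bias
#'
#' Chromosomes get a weak (1.3x) origin bias for core/softcore and a weak
#' terminus bias for shell/cloud; chromids get a strong (3x) terminus bias
#' for core/softcore and uniform shell/cloud — the qualitative architecture
#' this family of multipartite genomes shows.
#'
#' @return data.frame with columns role, category, focal, multiplier.
#' @export
default_placement_bias <- function() {
  data.frame(
    role = rep(REPLICON_ROLES, each = 4),
    category = rep(PANGENE_CATEGORIES, 2),
    focal = c("ori", "ori", "ter", "ter", "ter", "ter", "none", "none"),
    multiplier = c(1.3, 1.3, 1.3, 1.3, 3, 3, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the generator. Category mixes are
#' per-replicon fractions of the *per-genome gene complement*; the number
#' of clusters per category is derived so that the expected per-genome
#' gene counts match `genes_per_chromosome` / `genes_per_chromid` under the
#' prevalence model (softcore prevalence uniform on
#' `softcore_min..N-1`, shell uniform on `cloud_max+1..softcore_min-1`,
#' cloud uniform on `1..cloud_max`).
#'
#' @param seed integer RNG seed; the same seed reproduces every output
#'   byte for byte.
#' @param n_genomes number of genomes N (default 25).
#' @param chromosome_length,chromid_length replicon lengths in bp
#'   (defaults 4,000,000 and 1,000,000).
#' @param genes_per_chromosome,genes_per_chromid expected per-genome gene
#'   counts (defaults 3,500 and 800).
#' @param category_mix named list with `chromosome` and `chromid` fraction
#'   vectors over core/softcore/shell/cloud, each summing to 1.
#' @param softcore_min,cloud_max classification thresholds; defaults
#'   [default_softcore_min()] and 2.
#' @param placement_bias data.frame (role, category, focal, multiplier);
#'   default [default_placement_bias()]. `focal` is `ori`, `ter` or
#'   `none`; mass `(multiplier - 1) / multiplier` of each category's genes
#'   is drawn from a wrapped triangular peak of half-width L/6 at the
#'   focal point, the rest uniformly.
#' @param chromid_replication_mode `"unidirectional"`, `"bidirectional"`,
#'   or a fraction in \[0,1\] giving the proportion of genomes whose
#'   chromid replicates bidirectionally.
#' @param mixed_fraction fraction of clusters whose members are placed on
#'   chromosome or chromid per genome at random (association "mixed");
#'   default 0.05.
#' @param category_base named lognormal-median RPKM per category
#'   (defaults core 80, softcore 70, shell 30, cloud 20).
#' @param dosage_fold named ori-to-ter expression fold change per replicon
#'   role (defaults chromosome 2, chromid 1 = no chromidal gradient).
#' @param noise_sigma lognormal noise sd on the log scale (default 0.5).
#' @param library_size expected sequencing depth used to draw Poisson
#'   counts (default 5,000,000).
#' @param expression_genomes which genomes get simulated RNA-seq counts;
#'   default the first genome only (a single sequenced strain).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genomes = 25L,
                       chromosome_length = 4e6,
                       chromid_length = 1e6,
                       genes_per_chromosome = 3500L,
                       genes_per_chromid = 800L,
                       category_mix = list(
                         chromosome = c(core = 0.45, softcore = 0.15,
                                        shell = 0.25, cloud = 0.15),
                         chromid = c(core = 0.10, softcore = 0.10,
                                     shell = 0.35, cloud = 0.45)),
                       softcore_min = NULL,
                       cloud_max = 2L,
                       placement_bias = default_placement_bias(),
                       chromid_replication_mode = "unidirectional",
                       mixed_fraction = 0.05,
                       category_base = c(core = 80, softcore = 70,
                                         shell = 30, cloud = 20),
                       dosage_fold = c(chromosome = 2, chromid = 1),
                       noise_sigma = 0.5,
                       library_size = 5e6,
                       expression_genomes = NULL) {
  n_genomes <- as.integer(n_genomes)
  pr_assert(n_genomes >= 1, "n_genomes must be >= 1")
  if (is.null(softcore_min)) softcore_min <- default_softcore_min(n_genomes)
  pr_assert(chromosome_length > 0 && chromid_length > 0, "lengths must be positive")
  pr_assert(genes_per_chromosome > 0 && genes_per_chromid > 0,
            "gene counts must be positive")
  for (role in REPLICON_ROLES) {
    mix <- category_mix[[role]]
    pr_assert(!is.null(mix) && setequal(names(mix), PANGENE_CATEGORIES),
              "category_mix$%s must name all four categories", role)
    pr_assert(all(mix >= 0) && abs(sum(mix) - 1) < 1e-8,
              "category_mix$%s must be non-negative and sum to 1", role)
  }
  pr_assert(all(c("role", "category", "focal", "multiplier") %in%
                  names(placement_bias)), "malformed placement_bias")
  pr_assert(all(placement_bias$focal %in% c("ori", "ter", "none")),
            "placement_bias focal must be ori, ter or none")
  pr_assert(all(placement_bias$multiplier >= 1),
            "placement multipliers must be >= 1")
  if (is.numeric(chromid_replication_mode)) {
    pr_assert(chromid_replication_mode >= 0 && chromid_replication_mode <= 1,
              "bidirectional fraction must lie in [0, 1]")
  } else {
    pr_assert(chromid_replication_mode %in% REPLICATION_MODES,
              "chromid_replication_mode must be a mode or a fraction")
  }
  pr_assert(mixed_fraction >= 0 && mixed_fraction < 1,
            "mixed_fraction must lie in [0, 1)")
  pr_assert(setequal(names(category_base), PANGENE_CATEGORIES) &&
              all(category_base > 0), "malformed category_base")
  pr_assert(setequal(names(dosage_fold), REPLICON_ROLES) &&
              all(dosage_fold > 0), "malformed dosage_fold")
  pr_assert(noise_sigma >= 0, "noise_sigma must be >= 0")
  pr_assert(library_size > 0, "library_size must be positive")
  genome_ids <- sprintf("G%02d", seq_len(n_genomes))
  if (is.null(expression_genomes)) expression_genomes <- genome_ids[1]
  pr_assert(all(expression_genomes %in% genome_ids),
            "expression_genomes outside the simulated genome set")
  structure(list(
    seed = as.integer(seed), n_genomes = n_genomes,
    genome_ids = genome_ids,
    chromosome_length = chromosome_length, chromid_length = chromid_length,
    genes_per_chromosome = genes_per_chromosome,
    genes_per_chromid = genes_per_chromid,
    category_mix = category_mix,
    softcore_min = as.integer(softcore_min), cloud_max = as.integer(cloud_max),
    placement_bias = placement_bias,
    chromid_replication_mode = chromid_replication_mode,
    mixed_fraction = mixed_fraction,
    category_base = category_base, dosage_fold = dosage_fold,
    noise_sigma = noise_sigma, library_size = library_size,
    expression_genomes = expression_genomes
  ), class = "sim_config")
}

#' @noRd
prevalence_band <- function(category, n, softcore_min, cloud_max) {
  switch(category,
         core = n,
         softcore = softcore_min:(n - 1),
         shell = (cloud_max + 1):(softcore_min - 1),
         cloud = 1:cloud_max)
}

#' Simulate a pangenome: clusters, prevalence and replicon homes
#'
#' Draws clusters per replicon and category, assigns each a prevalence
#' from its category's band, picks the member genomes uniformly, and fixes
#' each occurrence's replicon role (the cluster's home replicon, or a coin
#' flip per genome for the `mixed_fraction` of clusters).
#'
#' @param config a [sim_config()].
#' @return list of class `sim_pangenome` with `matrix` (a
#'   [pangenome_matrix()]), `membership` (cluster_id, genome_id, role) and
#'   `truth` (cluster_id, true_category, home_role, true_association).
#' @export
simulate_pangenome <- function(config) {
  pr_assert(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  n <- config$n_genomes
  specs <- list()
  for (role in REPLICON_ROLES) {
    g_total <- if (role == "chromosome") config$genes_per_chromosome
               else config$genes_per_chromid
    mix <- config$category_mix[[role]][PANGENE_CATEGORIES]
    for (category in PANGENE_CATEGORIES) {
      if (mix[[category]] == 0) next
      if ((category == "softcore" && config$softcore_min > n - 1) ||
          (category == "shell" && config$cloud_max + 1 > config$softcore_min - 1)) {
        pr_stop("prevalence band for %s is empty at N=%d with the given thresholds",
                category, n)
      }
      band <- prevalence_band(category, n, config$softcore_min,
                              config$cloud_max)
      expected_prev <- mean(band)
      n_clusters <- max(1L, round(mix[[category]] * g_total * n / expected_prev))
      specs[[length(specs) + 1]] <- data.frame(
        home_role = role, true_category = category,
        prevalence = if (length(band) == 1) rep(band, n_clusters)
                     else sample(band, n_clusters, replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  spec <- do.call(rbind, specs)
  spec$cluster_id <- sprintf("CL%05d", seq_len(nrow(spec)))
  spec$mixed <- stats::runif(nrow(spec)) < config$mixed_fraction

  member_sets <- lapply(spec$prevalence, function(k) {
    if (k == n) config$genome_ids else sort(sample(config$genome_ids, k))
  })
  sizes <- lengths(member_sets)
  role <- rep(spec$home_role, sizes)
  mixed_occ <- rep(spec$mixed, sizes)
  role[mixed_occ] <- sample(REPLICON_ROLES, sum(mixed_occ), replace = TRUE)
  membership <- data.frame(cluster_id = rep(spec$cluster_id, sizes),
                           genome_id = unlist(member_sets),
                           role = role, stringsAsFactors = FALSE)

  realized <- tapply(membership$role == "chromid", membership$cluster_id,
                     function(x) {
                       if (all(x)) "chromid_only"
                       else if (!any(x)) "chromosome_only" else "mixed"
                     })
  truth <- data.frame(cluster_id = spec$cluster_id,
                      true_category = spec$true_category,
                      home_role = spec$home_role,
                      true_association = unname(realized[spec$cluster_id]),
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$cluster_id), , drop = FALSE]
  rownames(truth) <- NULL
  mat <- pangenome_matrix(membership[, c("cluster_id", "genome_id")],
                          genomes = config$genome_ids)
  structure(list(matrix = mat, membership = membership, truth = truth),
            class = "sim_pangenome")
}

#' @noRd
sample_wrapped_triangular <- function(n, focal, half_width, L) {
  # sum of two uniforms gives a symmetric triangle on [-hw, hw]
  (focal + half_width * (stats::runif(n) + stats::runif(n) - 1)) %% L
}

#' Simulate replicon specs and gene coordinates
#'
#' Each genome gets one chromosome (bidirectional, ori at 0) and one
#' chromid (mode per config, ori at 0). Every cluster occurrence becomes
#' one gene; midpoints are drawn per the category x role placement bias
#' (uniform, or a `(m-1)/m` : `1/m` mixture of a wrapped triangular peak
#' of half-width L/6 at the focal point and the uniform background); gene
#' lengths are uniform on 300-3,000 bp.
#'
#' @param config a [sim_config()].
#' @param pangenome a [simulate_pangenome()] result.
#' @return list with `replicons`, `genes` and `clusters` tables in the
#'   exact shapes the readers produce.
#' @export
simulate_genomes <- function(config, pangenome) {
  pr_assert(inherits(pangenome, "sim_pangenome"),
            "pangenome must come from simulate_pangenome")
  set.seed(config$seed + 1L)
  n <- config$n_genomes
  mode_frac <- config$chromid_replication_mode
  chromid_mode <- if (is.numeric(mode_frac)) {
    ifelse(stats::runif(n) < mode_frac, "bidirectional", "unidirectional")
  } else rep(mode_frac, n)
  replicons <- rbind(
    data.frame(genome_id = config$genome_ids, replicon_id = "chr",
               role = "chromosome", length_bp = config$chromosome_length,
               ori_pos = 0L, replication_mode = "bidirectional",
               stringsAsFactors = FALSE),
    data.frame(genome_id = config$genome_ids, replicon_id = "chd",
               role = "chromid", length_bp = config$chromid_length,
               ori_pos = 0L, replication_mode = chromid_mode,
               stringsAsFactors = FALSE))
  replicons <- replicons[order(replicons$genome_id, replicons$replicon_id), ,
                         drop = FALSE]
  rownames(replicons) <- NULL

  mem <- pangenome$membership
  mem <- mem[order(mem$genome_id, mem$cluster_id), , drop = FALSE]
  category <- pangenome$truth$true_category[
    match(mem$cluster_id, pangenome$truth$cluster_id)]
  replicon_id <- ifelse(mem$role == "chromosome", "chr", "chd")
  rkey <- paste(mem$genome_id, replicon_id)
  ridx <- match(rkey, paste(replicons$genome_id, replicons$replicon_id))
  L <- replicons$length_bp[ridx]
  mode <- replicons$replication_mode[ridx]
  ter <- terminus_position(replicons)[ridx]

  bias_key <- paste(mem$role, category)
  bidx <- match(bias_key, paste(config$placement_bias$role,
                                config$placement_bias$category))
  pr_assert(!anyNA(bidx), "placement_bias missing a role x category entry")
  focal_kind <- config$placement_bias$focal[bidx]
  mult <- config$placement_bias$multiplier[bidx]
  focal_pos <- ifelse(focal_kind == "ter", ter, 0)
  w_peak <- ifelse(focal_kind == "none", 0, (mult - 1) / mult)

  m <- nrow(mem)
  use_peak <- stats::runif(m) < w_peak
  mid <- numeric(m)
  mid[!use_peak] <- stats::runif(sum(!use_peak)) * L[!use_peak]
  if (any(use_peak)) {
    mid[use_peak] <- sample_wrapped_triangular(
      sum(use_peak), focal_pos[use_peak], L[use_peak] / 6, L[use_peak])
  }
  len <- floor(stats::runif(m, 300, 3001))
  start <- round(mid - len / 2) %% L
  end_lin <- start + len
  end <- ifelse(end_lin > L, end_lin - L, end_lin)
  genes <- data.frame(genome_id = mem$genome_id,
                      replicon_id = replicon_id,
                      gene_id = NA_character_,
                      start = as.integer(start), end = as.integer(end),
                      strand = sample(c("+", "-"), m, replace = TRUE),
                      cluster_id = mem$cluster_id,
                      wraps = end_lin > L,
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$genome_id, genes$replicon_id, genes$start,
                       genes$cluster_id), , drop = FALSE]
  idx_in_genome <- stats::ave(seq_len(m), genes$genome_id,
                              FUN = seq_along)
  genes$gene_id <- sprintf("%s_g%05d", genes$genome_id, idx_in_genome)
  rownames(genes) <- NULL
  clusters <- data.frame(cluster_id = genes$cluster_id,
                         genome_id = genes$genome_id,
                         gene_id = genes$gene_id,
                         stringsAsFactors = FALSE)
  clusters <- clusters[order(clusters$cluster_id, clusters$genome_id), ,
                       drop = FALSE]
  rownames(clusters) <- NULL
  list(replicons = replicons, genes = genes, clusters = clusters)
}

#' Simulate per-gene read counts with a dosage gradient
#'
#' Expected RPKM of a gene is
#' `category_base * dosage_fold^(-d) * exp(noise)` with `d` the circular
#' distance from the origin as a fraction of L/2 (bidirectional) or L
#' (unidirectional) and `noise ~ Normal(0, noise_sigma^2)`; read counts
#' are Poisson with mean `expected_rpkm * length_kb * library_size / 1e6`.
#'
#' @param config a [sim_config()].
#' @param genomes a [simulate_genomes()] result.
#' @param truth the `truth` table of the matching [simulate_pangenome()].
#' @return count table (genome_id, gene_id, read_count) for the genomes in
#'   `config$expression_genomes`.
#' @export
simulate_expression <- function(config, genomes, truth) {
  set.seed(config$seed + 2L)
  g <- genomes$genes[genomes$genes$genome_id %in% config$expression_genomes, ,
                     drop = FALSE]
  pr_assert(nrow(g) > 0, "no genes in the expression genome(s)")
  rkey <- paste(g$genome_id, g$replicon_id)
  ridx <- match(rkey, paste(genomes$replicons$genome_id,
                            genomes$replicons$replicon_id))
  L <- genomes$replicons$length_bp[ridx]
  mode <- genomes$replicons$replication_mode[ridx]
  role <- genomes$replicons$role[ridx]
  ori <- genomes$replicons$ori_pos[ridx]
  mid <- gene_midpoints(g, genomes$replicons)
  pos <- (mid - ori) %% L
  d <- ifelse(mode == "bidirectional",
              circular_distance(pos, 0, L) / (L / 2),
              pos / L)
  category <- truth$true_category[match(g$cluster_id, truth$cluster_id)]
  base <- config$category_base[category]
  fold <- config$dosage_fold[role]
  noise <- stats::rnorm(nrow(g), 0, config$noise_sigma)
  expected_rpkm <- base * fold^(-d) * exp(noise)
  len <- ifelse(g$end < g$start, g$end + L - g$start, g$end - g$start)
  lambda <- expected_rpkm * (len / 1000) * config$library_size / 1e6
  data.frame(genome_id = g$genome_id,
             gene_id = g$gene_id,
             read_count = stats::rpois(nrow(g), lambda),
             stringsAsFactors = FALSE)
}

#' Simulate a complete analysis-ready dataset
#'
#' Convenience wrapper chaining [simulate_pangenome()],
#' [simulate_genomes()] and [simulate_expression()].
#'
#' @param config a [sim_config()].
#' @return list with `config`, `pangenome`, `replicons`, `genes`,
#'   `clusters`, `counts` and `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  pangenome <- simulate_pangenome(config)
  genomes <- simulate_genomes(config, pangenome)
  counts <- simulate_expression(config, genomes, pangenome$truth)
  list(config = config, pangenome = pangenome,
       replicons = genomes$replicons, genes = genomes$genes,
       clusters = genomes$clusters, counts = counts,
       truth = pangenome$truth)
}

#' Simulate mutated protein families
#'
#' Small helper to exercise [cluster_proteins()]: draws random amino-acid
#' ancestor sequences and emits mutated copies (i.i.d. substitutions at
#' `substitution_rate` per site).
#'
#' @param n_families number of families.
#' @param members_per_family copies per family.
#' @param length sequence length in residues.
#' @param substitution_rate per-site substitution probability per copy.
#' @param seed RNG seed.
#' @return named character vector of sequences (`F<i>_m<j>`).
#' @export
simulate_protein_families <- function(n_families = 2, members_per_family = 3,
                                      length = 120, substitution_rate = 0.05,
                                      seed = 1L) {
  set.seed(seed)
  out <- character(0)
  for (f in seq_len(n_families)) {
    ancestor <- sample(AA_ALPHABET, length, replace = TRUE)
    for (j in seq_len(members_per_family)) {
      seq <- ancestor
      hit <- stats::runif(length) < substitution_rate
      seq[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
      out[sprintf("F%d_m%d", f, j)] <- paste(seq, collapse = "")
    }
  }
  out
}
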