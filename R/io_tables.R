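# Readers and writers for the plain-text tables the pipeline exchanges.
# TSV dialect: tab-separated, UTF-8, '#' comment lines ignored, header
# mandatory. Coordinates are converted to 0-based half-open here and
# nowhere else.

#' @noRd
read_tsv_table <- function(path, required, optional = character()) {
  if (!file.exists(path)) pr_stop("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    pr_stop("%s: missing required column(s): %s", path,
            paste(missing, collapse = ", "))
  }
  df[, c(required, intersect(optional, names(df))), drop = FALSE]
}

#' @noRd
coerce_int_column <- function(df, col, path) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) | v != floor(v))
  if (length(bad) > 0) {
    pr_stop("%s: column '%s' is not an integer at data row(s) %s", path, col,
            paste(utils::head(bad, 5), collapse = ", "))
  }
  df[[col]] <- as.integer(v)
  df
}

#' Read a replicon table
#'
#' One row per circular replicon: `genome_id`, `replicon_id`,
#' `role` (chromosome|chromid), `length_bp`, `ori_pos` (0-based offset of the
#' replication origin, the sector-1 anchor: *gidA*-proximal on chromosomes,
#' *parA*-proximal on chromids), and `replication_mode`
#' (unidirectional|bidirectional).
#'
#' Each genome must declare exactly one chromosome; replicon ids must be
#' unique within a genome; `0 <= ori_pos < length_bp`.
#'
#' @param path TSV file path.
#' @return data.frame of validated replicon specifications.
#' @export
read_replicon_table <- function(path) {
  df <- read_tsv_table(path, c("genome_id", "replicon_id", "role",
                               "length_bp", "ori_pos", "replication_mode"))
  df <- coerce_int_column(df, "length_bp", path)
  df <- coerce_int_column(df, "ori_pos", path)
  validate_replicons(df)
}

#' @noRd
validate_replicons <- function(df) {
  bad_role <- setdiff(unique(df$role), REPLICON_ROLES)
  if (length(bad_role) > 0) {
    pr_stop("unknown replicon role(s) %s; allowed: %s",
            paste(bad_role, collapse = ", "),
            paste(REPLICON_ROLES, collapse = ", "))
  }
  bad_mode <- setdiff(unique(df$replication_mode), REPLICATION_MODES)
  if (length(bad_mode) > 0) {
    pr_stop("unknown replication_mode(s) %s; allowed: %s",
            paste(bad_mode, collapse = ", "),
            paste(REPLICATION_MODES, collapse = ", "))
  }
  pr_assert(all(df$length_bp >= 1), "length_bp must be >= 1")
  bad <- df$ori_pos < 0 | df$ori_pos >= df$length_bp
  if (any(bad)) {
    pr_stop("ori_pos outside [0, length_bp) for replicon(s): %s",
            paste(df$replicon_id[bad], collapse = ", "))
  }
  n_chr <- tapply(df$role == "chromosome", df$genome_id, sum)
  if (any(n_chr != 1)) {
    pr_stop("each genome needs exactly one chromosome; offending genome(s): %s",
            paste(names(n_chr)[n_chr != 1], collapse = ", "))
  }
  dup <- duplicated(df[, c("genome_id", "replicon_id")])
  if (any(dup)) {
    pr_stop("duplicate replicon_id within genome: %s",
            paste(unique(df$replicon_id[dup]), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Read a gene table (TSV or GFF3)
#'
#' TSV columns: `genome_id`, `replicon_id`, `gene_id`, `start`, `end`,
#' `strand` (+|-) and optionally `cluster_id`. Coordinates are 0-based
#' half-open `[start, end)`. A gene spanning the circular junction is stored
#' with `end < start` (it occupies `[start, L)` then `[0, end)`); readers
#' also accept the linear overhang form `end > length_bp` and normalise it.
#'
#' For GFF3 input, rows of type `CDS` are used; `seqid` becomes
#' `replicon_id`, the `ID` attribute becomes `gene_id`, and 1-based
#' inclusive coordinates are converted to 0-based half-open. GFF3 carries no
#' genome identifier, so `genome_id` must be supplied.
#'
#' @param path input file.
#' @param format `"tsv"` or `"gff3"`.
#' @param replicons optional replicon table; when given, coordinates are
#'   validated against replicon lengths and junction-spanning genes are
#'   normalised.
#' @param genome_id genome identifier, required for GFF3 input.
#' @return data.frame of gene records.
#' @export
read_gene_table <- function(path, format = c("tsv", "gff3"),
                            replicons = NULL, genome_id = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read_tsv_table(path, c("genome_id", "replicon_id", "gene_id",
                                 "start", "end", "strand"), "cluster_id")
    df <- coerce_int_column(df, "start", path)
    df <- coerce_int_column(df, "end", path)
    if (is.null(df$cluster_id)) df$cluster_id <- NA_character_
    df$cluster_id[df$cluster_id %in% c("", "NA")] <- NA_character_
  } else {
    pr_assert(!is.null(genome_id),
              "genome_id is required when reading GFF3 (the format carries none)")
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
    pr_assert(length(gr) > 0, "%s: no CDS features found", path)
    ids <- as.character(gr$ID)
    pr_assert(!anyNA(ids), "%s: CDS feature without ID attribute", path)
    df <- data.frame(
      genome_id = genome_id,
      replicon_id = as.character(GenomicRanges::seqnames(gr)),
      gene_id = ids,
      start = GenomicRanges::start(gr) - 1L,  # 1-based incl -> 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      cluster_id = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  validate_genes(df, replicons)
}

#' @noRd
validate_genes <- function(df, replicons = NULL) {
  bad_strand <- !df$strand %in% c("+", "-")
  if (any(bad_strand)) {
    pr_stop("invalid strand at data row(s) %s (must be + or -)",
            paste(utils::head(which(bad_strand), 5), collapse = ", "))
  }
  dup <- duplicated(df[, c("genome_id", "gene_id")])
  if (any(dup)) {
    pr_stop("duplicate gene_id within genome: %s",
            paste(unique(df$gene_id[dup]), collapse = ", "))
  }
  if (!is.null(replicons)) {
    key <- paste(df$genome_id, df$replicon_id)
    idx <- match(key, paste(replicons$genome_id, replicons$replicon_id))
    if (anyNA(idx)) {
      pr_stop("gene(s) on unknown replicon: %s",
              paste(unique(df$gene_id[is.na(idx)]), collapse = ", "))
    }
    L <- replicons$length_bp[idx]
    # normalise the linear overhang form (end > L) to the wrapped form
    over <- df$end > L
    df$end[over] <- df$end[over] - L[over]
    wraps <- df$end < df$start
    lin_len <- ifelse(wraps, df$end + L - df$start, df$end - df$start)
    bad <- df$start < 0 | df$start >= L | df$end < 0 | lin_len <= 0 |
      lin_len > L
    if (any(bad)) {
      pr_stop("invalid coordinates for gene(s): %s",
              paste(unique(df$gene_id[bad]), collapse = ", "))
    }
    df$wraps <- wraps
  } else {
    bad <- df$start < 0 | df$end <= df$start
    if (any(bad)) {
      pr_stop("invalid coordinates (need 0 <= start < end) for gene(s): %s",
              paste(unique(df$gene_id[bad]), collapse = ", "))
    }
    df$wraps <- FALSE
  }
  rownames(df) <- NULL
  df
}

#' Read an orthologous-cluster membership table
#'
#' TSV columns `cluster_id`, `genome_id`, `gene_id` — the output format of a
#' pangenome clustering run. Exact duplicate rows are dropped silently (with
#' a message); a gene assigned to two different clusters is an error.
#'
#' @param path TSV file path.
#' @param genes optional gene table for cross-validation: every
#'   (genome_id, gene_id) must then exist.
#' @return data.frame with columns cluster_id, genome_id, gene_id.
#' @export
read_cluster_table <- function(path, genes = NULL) {
  df <- read_tsv_table(path, c("cluster_id", "genome_id", "gene_id"))
  dup <- duplicated(df)
  if (any(dup)) {
    message(sum(dup), " duplicate cluster membership row(s) dropped")
    df <- df[!dup, , drop = FALSE]
  }
  key <- paste(df$genome_id, df$gene_id)
  multi <- unique(key[duplicated(key)])
  if (length(multi) > 0) {
    pr_stop("gene(s) assigned to more than one cluster: %s",
            paste(utils::head(multi, 5), collapse = "; "))
  }
  if (!is.null(genes)) {
    known <- paste(genes$genome_id, genes$gene_id)
    unknown <- setdiff(key, known)
    if (length(unknown) > 0) {
      pr_stop("cluster table references unknown gene(s): %s",
              paste(utils::head(unknown, 5), collapse = "; "))
    }
  }
  rownames(df) <- NULL
  df
}

#' Read a per-gene read-count table
#'
#' TSV columns `genome_id`, `gene_id`, `read_count` (non-negative integers).
#'
#' @param path TSV file path.
#' @param genes optional gene table; every counted gene must then resolve.
#' @return data.frame with the three columns above.
#' @export
read_count_table <- function(path, genes = NULL) {
  df <- read_tsv_table(path, c("genome_id", "gene_id", "read_count"))
  df <- coerce_int_column(df, "read_count", path)
  pr_assert(all(df$read_count >= 0), "read_count must be non-negative")
  if (!is.null(genes)) {
    unknown <- setdiff(paste(df$genome_id, df$gene_id),
                       paste(genes$genome_id, genes$gene_id))
    if (length(unknown) > 0) {
      pr_stop("count table references unknown gene(s): %s",
              paste(utils::head(unknown, 5), collapse = "; "))
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a data.frame as a pipeline TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write result tables plus a run manifest
#'
#' Writes one TSV per named table in `tables` into `out_dir`, then a
#' `manifest.json` recording input paths, parameters, seed, package version
#' and the list of files written. The manifest contains no timestamps, so a
#' rerun with the same seed reproduces every output byte for byte.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if absent).
#' @param inputs character vector of input paths to record.
#' @param params named list of run parameters to record.
#' @param seed integer seed to record (or NULL).
#' @param overwrite overwrite existing files? Collisions error otherwise.
#' @return invisibly, the manifest as a list.
#' @export
write_results <- function(tables, out_dir, inputs = character(),
                          params = list(), seed = NULL, overwrite = FALSE) {
  pr_assert(is.list(tables) && length(names(tables)) == length(tables) &&
              all(nzchar(names(tables))),
            "tables must be a fully named list of data.frames")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(out_dir, paste0(names(tables), ".tsv"))
  manifest_path <- file.path(out_dir, "manifest.json")
  existing <- c(files, manifest_path)[file.exists(c(files, manifest_path))]
  if (!overwrite && length(existing) > 0) {
    pr_stop("output file(s) already exist (use overwrite = TRUE): %s",
            paste(basename(existing), collapse = ", "))
  }
  for (i in seq_along(tables)) write_tsv_table(tables[[i]], files[i])
  manifest <- list(
    tool = "panreplicon",
    version = as.character(utils::packageVersion("panreplicon")),
    seed = seed,
    inputs = as.list(inputs),
    params = params,
    outputs = as.list(basename(files))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
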