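# RPKM, median-centred log2 expression maps with circular sliding-window
# trends, half-replicon contrasts and per-category quartile tables — the
# machinery for detecting replication-associated gene dosage gradients.

#' Compute RPKM expression records
#'
#' `rpkm = read_count * 1e9 / (gene_length_bp * library_size)`; with
#' `library_size = "auto"` the library is the per-genome sum of counts over
#' all counted CDS. Gene positions are reported as rotated midpoints
#' (origin at 0) when a replicon table is supplied.
#'
#' @param counts count table (genome_id, gene_id, read_count).
#' @param genes gene table.
#' @param replicons optional replicon table (adds rotated `position` and
#'   replication metadata).
#' @param categories optional [classify_clusters()] result (adds a
#'   `category` column via each gene's cluster).
#' @param library_size positive number or `"auto"` (default).
#' @return data.frame of expression records: genome_id, gene_id,
#'   replicon_id, position, length_bp, read_count, rpkm (+ category).
#' @export
compute_rpkm <- function(counts, genes, replicons = NULL, categories = NULL,
                         library_size = "auto") {
  idx <- match(paste(counts$genome_id, counts$gene_id),
               paste(genes$genome_id, genes$gene_id))
  pr_assert(!anyNA(idx), "count table references gene(s) missing from the gene table")
  g <- genes[idx, , drop = FALSE]
  if (!is.null(replicons)) {
    rkey <- paste(replicons$genome_id, replicons$replicon_id)
    ridx <- match(paste(g$genome_id, g$replicon_id), rkey)
    L <- replicons$length_bp[ridx]
    ori <- replicons$ori_pos[ridx]
    position <- (gene_midpoints(g, replicons) - ori) %% L
  } else {
    position <- (g$start + g$end) / 2
  }
  len <- g$end - g$start
  if (!is.null(replicons)) {   # genes wrapped across the origin junction
    wraps <- g$end < g$start
    len[wraps] <- g$end[wraps] + L[wraps] - g$start[wraps]
  }
  pr_assert(all(len > 0), "non-positive gene length(s) in count table join")
  if (identical(library_size, "auto")) {
    lib <- tapply(counts$read_count, counts$genome_id, sum)[counts$genome_id]
  } else {
    lib <- rep(as.numeric(library_size), nrow(counts))
  }
  pr_assert(all(lib > 0), "library size must be positive")
  out <- data.frame(genome_id = counts$genome_id,
                    gene_id = counts$gene_id,
                    replicon_id = g$replicon_id,
                    position = position,
                    length_bp = as.numeric(len),
                    read_count = counts$read_count,
                    rpkm = counts$read_count * 1e9 / (as.numeric(len) * as.numeric(lib)),
                    stringsAsFactors = FALSE)
  if (!is.null(categories)) {
    out$category <- categories$category[match(g$cluster_id,
                                              categories$cluster_id)]
  }
  rownames(out) <- NULL
  out
}

#' @noRd
circular_window_mean <- function(x, window) {
  n <- length(x)
  if (window > n) {
    warning("window (", window, ") larger than number of CDS (", n,
            "); shrunk to ", n, call. = FALSE)
    window <- n
  }
  left <- floor((window - 1) / 2)
  right <- window - 1 - left
  xx <- c(x[(n - left + 1):n], x, x[1:right])
  if (left == 0) xx <- c(x, x[seq_len(right)])
  if (right == 0) xx <- c(x[(n - left + 1):n], x)
  if (left == 0 && right == 0) xx <- x
  vals <- ifelse(is.na(xx), 0, xx)
  ok <- as.numeric(!is.na(xx))
  csum <- cumsum(c(0, vals))
  cok <- cumsum(c(0, ok))
  i <- seq_len(n)
  tot <- csum[i + window] - csum[i]
  cnt <- cok[i + window] - cok[i]
  ifelse(cnt > 0, tot / cnt, NA_real_)
}

#' Global expression map with median-centred log2 ratios and trend line
#'
#' For each replicon, CDS are ordered by rotated position (ori at 0);
#' `log2_ratio = log2(rpkm / centering median)` with the median taken over
#' all CDS with rpkm > 0 of the genome (default) or of each replicon; the
#' trend at a CDS is the arithmetic mean of log2 ratios in the circular
#' window of `window` consecutive CDS centred there.
#'
#' @param records expression records from [compute_rpkm()].
#' @param centering `"genome"` (default) or `"replicon"`.
#' @param window sliding-window size in data points (default 100).
#' @return data.frame: records ordered by (replicon_id, position) with
#'   log2_ratio and trend columns added; the centering median(s) are kept
#'   in the `centering_median` attribute.
#' @export
expression_map <- function(records, centering = c("genome", "replicon"),
                           window = 100) {
  centering <- match.arg(centering)
  window <- as.integer(window)
  pr_assert(window >= 1, "window must be >= 1")
  pr_assert(length(unique(records$genome_id)) == 1,
            "expression_map works on one genome at a time")
  expressed <- records$rpkm > 0
  pr_assert(any(expressed), "no CDS with rpkm > 0")
  if (centering == "genome") {
    med <- stats::median(records$rpkm[expressed])
    records$log2_ratio <- ifelse(expressed, log2(records$rpkm / med), NA_real_)
    med_attr <- c(genome = med)
  } else {
    med_attr <- tapply(records$rpkm[expressed], records$replicon_id[expressed],
                       stats::median)
    records$log2_ratio <- ifelse(
      expressed, log2(records$rpkm / med_attr[records$replicon_id]), NA_real_)
  }
  ord <- order(records$replicon_id, records$position)
  records <- records[ord, , drop = FALSE]
  records$trend <- NA_real_
  for (rid in unique(records$replicon_id)) {
    sel <- records$replicon_id == rid
    records$trend[sel] <- circular_window_mean(records$log2_ratio[sel], window)
  }
  rownames(records) <- NULL
  attr(records, "centering_median") <- med_attr
  records
}

#' Split a replicon's genes into halves
#'
#' With rotated position `p` in `[0, L)` and the circular map drawn with
#' ori at 12 o'clock: the `upper` half is the ori-proximal half
#' (`p < L/4` or `p >= 3L/4`), `lower` its complement; the `right` half is
#' the first half clockwise from ori (`p < L/2`), `left` its complement.
#'
#' @param genes gene records of one replicon.
#' @param spec the matching one-row replicon table entry.
#' @param scheme `"upper_lower"` or `"left_right"`.
#' @return data.frame with columns gene_id, half.
#' @export
split_halves <- function(genes, spec, scheme = c("upper_lower", "left_right")) {
  scheme <- match.arg(scheme)
  pr_assert(nrow(spec) == 1, "spec must be a single replicon row")
  L <- spec$length_bp
  p <- (gene_midpoints(genes, spec) - spec$ori_pos) %% L
  half <- if (scheme == "upper_lower") {
    ifelse(p < L / 4 | p >= 3 * L / 4, "upper", "lower")
  } else {
    ifelse(p < L / 2, "right", "left")
  }
  data.frame(gene_id = genes$gene_id, half = half, stringsAsFactors = FALSE)
}

#' @noRd
quartile_row <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(q1 = q[1], q2 = q[2], q3 = q[3], max = max(x))
}

#' Compare expression between the two halves of a replicon
#'
#' RPKM quartiles (linear-interpolation rule) and maxima per half, plus a
#' two-sided unpaired rank-sum test between halves, per pangene category
#' when `by_category` and records carry categories. P-values are
#' Bonferroni-adjusted across the tests performed in this call.
#'
#' @param records expression records of one replicon (must include rpkm).
#' @param split a [split_halves()] result covering the records' genes.
#' @param by_category compute per category (default TRUE when a category
#'   column is present)?
#' @return data.frame, one row per (category x) test: category, halves,
#'   n and q1/q2/q3/max per half, p_raw, p_adj. An empty half yields NA
#'   statistics and p-values.
#' @export
half_contrast <- function(records, split,
                          by_category = "category" %in% names(records)) {
  half <- split$half[match(records$gene_id, split$gene_id)]
  pr_assert(!anyNA(half), "split does not cover all expression records")
  halves <- sort(unique(split$half))
  pr_assert(length(halves) == 2, "split must define exactly two halves")
  cats <- if (isTRUE(by_category)) {
    intersect(PANGENE_CATEGORIES, unique(records$category))
  } else "all"
  rows <- lapply(cats, function(cat) {
    sel <- if (cat == "all") rep(TRUE, nrow(records))
           else !is.na(records$category) & records$category == cat
    a <- records$rpkm[sel & half == halves[1]]
    b <- records$rpkm[sel & half == halves[2]]
    qa <- if (length(a) > 0) quartile_row(a) else rep(NA_real_, 4)
    qb <- if (length(b) > 0) quartile_row(b) else rep(NA_real_, 4)
    p <- if (length(a) > 0 && length(b) > 0) {
      mann_whitney(a, b)$p_raw
    } else NA_real_
    data.frame(category = cat,
               half_a = halves[1], half_b = halves[2],
               n_a = length(a), n_b = length(b),
               q1_a = qa[1], q2_a = qa[2], q3_a = qa[3], max_a = qa[4],
               q1_b = qb[1], q2_b = qb[2], q3_b = qb[3], max_b = qb[4],
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p_raw)
  out$p_adj <- NA_real_
  out$p_adj[tested] <- bonferroni(out$p_raw[tested], sum(tested))
  rownames(out) <- NULL
  out
}

#' Compare expression levels between two replicons
#'
#' Median RPKM per replicon and a two-sided unpaired rank-sum test between
#' the two (e.g. chromosome vs chromid).
#'
#' @param records expression records covering exactly two replicons.
#' @return data.frame with one row per replicon (replicon_id, n,
#'   median_rpkm) plus p_raw / p_adj columns (identical on both rows).
#' @export
replicon_contrast <- function(records) {
  rids <- sort(unique(records$replicon_id))
  pr_assert(length(rids) == 2, "need records from exactly two replicons")
  a <- records$rpkm[records$replicon_id == rids[1]]
  b <- records$rpkm[records$replicon_id == rids[2]]
  mw <- mann_whitney(a, b)
  data.frame(replicon_id = rids,
             n = c(length(a), length(b)),
             median_rpkm = c(stats::median(a), stats::median(b)),
             p_raw = mw$p_raw, p_adj = mw$p_adj,
             stringsAsFactors = FALSE)
}
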