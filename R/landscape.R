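# Physical gene clusters and tandem duplication arrays from genomic
# coordinates, plus the survey summary statistics. Clustering follows the
# single-linkage chaining rule: genes on the same chromosome whose
# start-to-start distance is within 250 kb belong to the same cluster.
# Tandem arrays are maximal runs of consecutive cluster members spanning
# less than 150 kb. Strand is ignored by both rules.

#' Assign NBS genes to physical clusters
#'
#' Per chromosome, genes are sorted by start coordinate and chained by
#' single linkage: consecutive genes whose start-to-start distance is at
#' most `max_gap_bp` join the same chain. Chains of two or more genes
#' become clusters; the rest are singletons. Cluster IDs are
#' deterministic: chromosomes in sorted label order, clusters numbered by
#' position.
#'
#' @param genes gene-model data frame (`gene_id`, `chromosome`, `start`,
#'   `end`); these should be the NBS-positive survey genes.
#' @param max_gap_bp chaining distance in bp (default 250,000).
#' @return List with `clusters` (data frame: `cluster_id`, `chromosome`,
#'   `n_members`, `first_start`, `last_end`, `span_bp` and a `members`
#'   list-column ordered by start) and `membership` (named vector mapping
#'   every gene ID to its cluster ID, `NA` for singletons).
#' @examples
#' g <- data.frame(gene_id = c("a", "b", "c"), chromosome = "chr1",
#'                 start = c(1e5, 2e5, 9e5), end = c(1e5, 2e5, 9e5) + 3000,
#'                 strand = "+")
#' assign_clusters(g)$clusters
#' @export
assign_clusters <- function(genes, max_gap_bp = 250000L) {
  if (!is.numeric(max_gap_bp) || length(max_gap_bp) != 1L || max_gap_bp < 0) {
    stop("max_gap_bp must be a non-negative number", call. = FALSE)
  }
  membership <- stats::setNames(rep(NA_character_, nrow(genes)), genes$gene_id)
  rows <- list()
  k <- 0L
  for (chrom in sort(unique(genes$chromosome))) {
    g <- genes[genes$chromosome == chrom, , drop = FALSE]
    g <- g[order(g$start, g$gene_id), , drop = FALSE]
    if (nrow(g) == 0L) next
    gap_break <- c(TRUE, diff(g$start) > max_gap_bp)
    chain <- cumsum(gap_break)
    ci <- 0L
    for (ch in split(seq_len(nrow(g)), chain)) {
      if (length(ch) < 2L) next
      ci <- ci + 1L
      k <- k + 1L
      id <- sprintf("%s_cl%02d", chrom, ci)
      members <- g$gene_id[ch]
      membership[members] <- id
      rows[[k]] <- data.frame(
        cluster_id = id, chromosome = chrom,
        n_members = length(ch),
        first_start = g$start[ch[1L]],
        last_end = g$end[ch[length(ch)]],
        span_bp = g$end[ch[length(ch)]] - g$start[ch[1L]] + 1L,
        stringsAsFactors = FALSE
      )
      rows[[k]]$members <- I(list(members))
    }
  }
  clusters <- if (k > 0L) do.call(rbind, rows) else
    data.frame(cluster_id = character(), chromosome = character(),
               n_members = integer(), first_start = integer(),
               last_end = integer(), span_bp = integer(),
               members = I(list()), stringsAsFactors = FALSE)
  list(clusters = clusters, membership = membership)
}

#' Detect tandem duplication arrays within clusters
#'
#' Within each cluster, every maximal run of two or more consecutive
#' members whose genomic span (last end minus first start plus one) is
#' strictly below `max_span_bp` is reported once. Observed arrays
#' typically involve two to eight genes; runs exceeding eight members are
#' reported whole with an `over_limit` flag rather than split.
#'
#' @param clusters result of [assign_clusters()] on the same genes.
#' @param genes the gene-model data frame.
#' @param max_span_bp span ceiling in bp, exclusive (default 150,000).
#' @return Data frame with `array_id`, `cluster_id`, `span_bp`,
#'   `over_limit` and a `members` list-column.
#' @export
detect_tandem_arrays <- function(clusters, genes, max_span_bp = 150000L) {
  ctab <- clusters$clusters
  unknown <- setdiff(unlist(ctab$members), genes$gene_id)
  if (length(unknown)) {
    stop("cluster references unknown gene(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  starts <- stats::setNames(genes$start, genes$gene_id)
  ends <- stats::setNames(genes$end, genes$gene_id)

  rows <- list()
  k <- 0L
  for (r in seq_len(nrow(ctab))) {
    members <- ctab$members[[r]]
    n <- length(members)
    s <- starts[members]
    e <- ends[members]
    span <- function(i, j) e[j] - s[i] + 1
    ai <- 0L
    for (i in seq_len(n - 1L)) {
      j <- i + 1L
      if (span(i, j) >= max_span_bp) next
      while (j < n && span(i, j + 1L) < max_span_bp) j <- j + 1L
      # maximal: cannot extend left either
      if (i > 1L && span(i - 1L, j) < max_span_bp) next
      ai <- ai + 1L
      k <- k + 1L
      rows[[k]] <- data.frame(
        array_id = sprintf("%s_t%02d", ctab$cluster_id[r], ai),
        cluster_id = ctab$cluster_id[r],
        span_bp = unname(span(i, j)),
        over_limit = (j - i + 1L) > 8L,
        stringsAsFactors = FALSE
      )
      rows[[k]]$members <- I(list(unname(members[i:j])))
    }
  }
  if (k == 0L) {
    return(data.frame(array_id = character(), cluster_id = character(),
                      span_bp = numeric(), over_limit = logical(),
                      members = I(list()), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Summarize a survey
#'
#' Computes the headline statistics of the survey: total genes, per-class
#' and per-chromosome counts, clustered and tandem gene counts with
#' percentages rounded to the survey's printed precision (whole percent
#' for headline figures, one decimal for class fractions), TNL and
#' coiled-coil tallies and the CNL-to-TNL ratio.
#'
#' @param genes gene-model data frame.
#' @param labels data frame of per-gene class labels (`gene_id`,
#'   `class_name`, `subfamily`, `cc_containing`).
#' @param clusters result of [assign_clusters()].
#' @param arrays result of [detect_tandem_arrays()].
#' @return Named list of class `nlr_summary`. `cnl_to_tnl_ratio` is `NA`
#'   (undefined) when there are no TNL genes. `per_class_pct_total` and
#'   `per_class_pct_ntnl` give each class's share of all genes and of the
#'   nTNL genes respectively (both denominators are reported because
#'   published tallies have used either).
#' @export
summarize_survey <- function(genes, labels, clusters, arrays) {
  total <- nrow(genes)
  per_class <- as.list(table(labels$class_name))
  per_chromosome <- as.list(table(genes$chromosome))
  clustered <- sum(!is.na(clusters$membership))
  tandem_genes <- length(unique(unlist(arrays$members)))
  n_tnl <- sum(labels$subfamily == "TNL")
  n_ntnl <- sum(labels$subfamily == "nTNL")
  cc_containing <- sum(labels$cc_containing)

  structure(list(
    total_genes = total,
    per_class = per_class,
    per_chromosome = per_chromosome,
    clustered_genes = clustered,
    n_clusters = nrow(clusters$clusters),
    clustered_pct = pct(clustered, total, digits = 0),
    tandem_genes = tandem_genes,
    n_arrays = nrow(arrays),
    tandem_pct = pct(tandem_genes, total, digits = 0),
    n_tnl = n_tnl,
    n_ntnl = n_ntnl,
    cc_containing = cc_containing,
    cnl_to_tnl_ratio = if (n_tnl == 0) NA_real_ else cc_containing / n_tnl,
    per_class_pct_total = lapply(per_class, function(k) pct(k, total)),
    per_class_pct_ntnl = lapply(per_class, function(k) pct(k, n_ntnl))
  ), class = "nlr_summary")
}

#' @export
print.nlr_summary <- function(x, ...) {
  cat(sprintf("NLR survey: %d genes\n", x$total_genes))
  cat(sprintf("  clustered: %d in %d clusters (%g%%)\n",
              x$clustered_genes, x$n_clusters, x$clustered_pct))
  cat(sprintf("  tandem:    %d in %d arrays (%g%%)\n",
              x$tandem_genes, x$n_arrays, x$tandem_pct))
  cat(sprintf("  subfamilies: %d nTNL, %d TNL; %d CC-containing\n",
              x$n_ntnl, x$n_tnl, x$cc_containing))
  invisible(x)
}
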