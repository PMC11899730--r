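# Shared fixtures and small independent oracles used across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal gene-model table
make_genes <- function(starts, chrom = "chr1", ids = NULL, len = 3000L) {
  n <- length(starts)
  if (is.null(ids)) ids <- sprintf("g%02d", seq_len(n))
  data.frame(gene_id = ids,
             chromosome = rep_len(chrom, n),
             start = as.integer(starts),
             end = as.integer(starts) + len - 1L,
             strand = rep_len("+", n),
             stringsAsFactors = FALSE)
}

domain_hit <- function(gene_id, domain, aa_start, aa_end, score = 100) {
  data.frame(gene_id = gene_id, domain = domain, aa_start = aa_start,
             aa_end = aa_end, score = score, stringsAsFactors = FALSE)
}

# brute-force clustering oracle: connected components of the
# "same chromosome and start-to-start distance <= gap" graph
oracle_clusters <- function(genes, gap) {
  comp <- seq_len(nrow(genes))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(genes))) {
      for (j in seq_len(nrow(genes))) {
        if (genes$chromosome[i] == genes$chromosome[j] &&
            abs(genes$start[i] - genes$start[j]) <= gap &&
            comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- split(genes$gene_id, comp)
  out <- out[lengths(out) >= 2]
  lapply(unname(out), sort)
}

# brute-force tandem-array oracle: all maximal runs of >= 2 consecutive
# cluster members with span strictly below max_span
oracle_arrays <- function(members, starts, ends, max_span) {
  n <- length(members)
  feasible <- function(i, j) (ends[j] - starts[i] + 1) < max_span
  runs <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (!feasible(i, j)) next
      left_max <- (i == 1) || !feasible(i - 1, j)
      right_max <- (j == n) || !feasible(i, j + 1)
      if (left_max && right_max) runs[[length(runs) + 1L]] <- members[i:j]
    }
  }
  runs
}

# brute-force best-window motif scan for short proteins
oracle_scan <- function(motif, protein) {
  w <- motif$width
  chars <- strsplit(protein, "")[[1]]
  n_win <- length(chars) - w + 1L
  if (n_win < 1L) return(NULL)
  lo <- log2(sweep(motif$pwm, 2, motif$background, "/"))
  scores <- vapply(seq_len(n_win), function(o) {
    sum(vapply(seq_len(w), function(i) {
      ch <- chars[o + i - 1L]
      if (ch %in% colnames(lo)) lo[i, ch] else 0
    }, numeric(1)))
  }, numeric(1))
  best <- max(scores)
  if (best < 0) return(NULL)
  list(aa_start = which(scores == best)[1L], score = best)
}

# exhaustive global-alignment oracle for tiny sequences: enumerate every
# alignment recursively and return the maximum affine-gap score
oracle_align_score <- function(a, b, submat, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, submat[ca[i], cb[j]] + rec(i + 1, j + 1, "M"))
    }
    if (j <= length(cb)) {  # gap in a
      cost <- if (prev == "GA") gap_extend else gap_open
      best <- max(best, -cost + rec(i, j + 1, "GA"))
    }
    if (i <= length(ca)) {  # gap in b
      cost <- if (prev == "GB") gap_extend else gap_open
      best <- max(best, -cost + rec(i + 1, j, "GB"))
    }
    best
  }
  rec(1, 1, "M")
}

# all internal bipartitions of an unrooted tree, as canonical strings
tree_splits <- function(tree) {
  bp <- ape::prop.part(tree)
  labs <- attr(bp, "labels")
  all_tips <- sort(labs)
  keys <- vapply(bp, function(idx) {
    side <- sort(labs[idx])
    other <- setdiff(all_tips, side)
    a <- paste(side, collapse = ",")
    b <- paste(other, collapse = ",")
    paste(sort(c(a, b))[1], sort(c(a, b))[2], sep = "|")
  }, character(1))
  sort(unique(keys[vapply(bp, function(idx) {
    length(idx) >= 2 && length(idx) <= length(labs) - 2
  }, logical(1))]))
}

same_topology <- function(t1, t2) {
  identical(tree_splits(ape::unroot(t1)), tree_splits(ape::unroot(t2)))
}
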