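# Conserved-NBS phylogeny: P-loop -> GLPL region extraction, progressive
# multiple alignment (affine-gap Needleman-Wunsch pairwise and
# profile-profile steps over BLOSUM62, UPGMA guide tree), p-distance with
# pairwise gap deletion, canonical Saitou-Nei neighbor joining with
# deterministic tie-breaking, and column-bootstrap support.

#' Extract the conserved NBS region (P-loop to GLPL)
#'
#' The region runs from the start of the P-loop motif hit to the end of
#' the GLPL motif hit. Genes missing either motif, or whose GLPL lies
#' before the P-loop, are excluded with a reason code; exclusion is a
#' reported outcome, not an error, and explains why only a subset of
#' survey genes enters the phylogeny.
#'
#' @param protein amino-acid string.
#' @param hits motif hits for this gene from [scan_motifs()].
#' @param gene_id identifier carried through.
#' @return List with `gene_id` and either `sequence`, `aa_start`,
#'   `aa_end` (`excluded = FALSE`) or `excluded = TRUE` plus `reason`
#'   (`"missing P-loop"`, `"missing GLPL"`, `"disordered motifs"`).
#' @export
extract_nbs_region <- function(protein, hits, gene_id = NA_character_) {
  excl <- function(reason) list(gene_id = gene_id, excluded = TRUE,
                                reason = reason)
  p <- hits[hits$motif_name == "P-loop", , drop = FALSE]
  g <- hits[hits$motif_name == "GLPL", , drop = FALSE]
  if (nrow(p) == 0L) return(excl("missing P-loop"))
  if (nrow(g) == 0L) return(excl("missing GLPL"))
  aa_start <- p$aa_start[1L]
  aa_end <- g$aa_start[1L] + nchar(g$matched[1L]) - 1L
  if (aa_end <= aa_start) return(excl("disordered motifs"))
  list(gene_id = gene_id, excluded = FALSE,
       sequence = substr(protein, aa_start, aa_end),
       aa_start = aa_start, aa_end = aa_end)
}

#' Global pairwise alignment with affine gaps
#'
#' Optimal Needleman-Wunsch alignment under affine gap costs with
#' deterministic tie-breaking (match/mismatch preferred over gaps, then a
#' gap in `a`).
#'
#' @param a,b amino-acid strings.
#' @param submat substitution matrix (default BLOSUM62 over the canonical
#'   letters, `X` scoring 0).
#' @param gap_open,gap_extend gap penalties (positive values).
#' @return List with aligned strings `a_aln`, `b_aln` and the alignment
#'   `score`.
#' @export
global_align_pair <- function(a, b, submat = blosum62(),
                              gap_open = 10, gap_extend = 0.5) {
  assert_protein(a, "a")
  assert_protein(b, "b")
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  s <- submat[ca, cb, drop = FALSE]
  path <- dp_affine_align(s, gap_open, gap_extend)
  a_chars <- ifelse(path$a == 0L, "-", ca[pmax(path$a, 1L)])
  b_chars <- ifelse(path$b == 0L, "-", cb[pmax(path$b, 1L)])
  list(a_aln = paste(a_chars, collapse = ""),
       b_aln = paste(b_chars, collapse = ""),
       score = path$score)
}

# 21 x L profile (20 residue frequencies + gap fraction) of aligned rows.
msa_profile <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(mat)
  prof <- matrix(0, nrow = 21L, ncol = L)
  rownames(prof) <- c(AA20, "-")
  for (j in seq_len(L)) {
    tab <- table(factor(mat[, j], levels = c(AA20, "-")))
    prof[, j] <- tab / nrow(mat)  # X drops out; renormalize below
    tot <- sum(prof[, j])
    if (tot > 0) prof[, j] <- prof[, j] / tot
  }
  prof
}

#' Progressive multiple sequence alignment
#'
#' Builds a UPGMA guide tree from pairwise p-distances (each pair aligned
#' with [global_align_pair()]) and merges alignments up the tree with
#' affine-gap profile-profile alignment. De-gapping any output row
#' recovers its input sequence exactly; column order is deterministic.
#'
#' @param regions named character vector of sequences (e.g. NBS regions
#'   keyed by gene ID), or a list of non-excluded results of
#'   [extract_nbs_region()].
#' @param submat,gap_open,gap_extend alignment parameters.
#' @return List of class `nlr_msa` with `ids` and `rows` (equal-length
#'   aligned strings).
#' @export
progressive_msa <- function(regions, submat = blosum62(),
                            gap_open = 10, gap_extend = 0.5) {
  if (is.list(regions) && !is.null(regions[[1L]]$sequence)) {
    regions <- stats::setNames(
      vapply(regions, `[[`, character(1), "sequence"),
      vapply(regions, `[[`, character(1), "gene_id"))
  }
  n <- length(regions)
  if (n == 0L) stop("no sequences to align", call. = FALSE)
  ids <- names(regions) %||% paste0("seq", seq_len(n))
  if (n == 1L) {
    return(structure(list(ids = ids, rows = unname(regions)),
                     class = "nlr_msa"))
  }

  # guide distances from pairwise alignments
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- global_align_pair(regions[[i]], regions[[j]], submat,
                              gap_open, gap_extend)
      D[i, j] <- D[j, i] <- aligned_p_distance(al$a_aln, al$b_aln)
    }
  }
  if (n == 2L) {
    al <- global_align_pair(regions[[1L]], regions[[2L]], submat,
                            gap_open, gap_extend)
    return(structure(list(ids = ids, rows = c(al$a_aln, al$b_aln)),
                     class = "nlr_msa"))
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")

  groups <- lapply(seq_len(n), function(i) {
    list(ids = ids[i], rows = unname(regions[[i]]))
  })
  merged <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    pick <- function(k) if (k < 0) groups[[-k]] else merged[[k]]
    ga <- pick(hc$merge[step, 1L])
    gb <- pick(hc$merge[step, 2L])
    merged[[step]] <- align_profiles(ga, gb, submat, gap_open, gap_extend)
  }
  res <- merged[[n - 1L]]
  # restore input order
  ord <- match(ids, res$ids)
  structure(list(ids = ids, rows = res$rows[ord]), class = "nlr_msa")
}

align_profiles <- function(ga, gb, submat, gap_open, gap_extend) {
  pa <- msa_profile(ga$rows)
  pb <- msa_profile(gb$rows)
  S <- submat[c(AA20, "X"), c(AA20, "X")]
  S21 <- matrix(0, 21, 21)
  S21[1:20, 1:20] <- S[AA20, AA20]  # gap row/col scores 0
  sm <- t(pa) %*% S21 %*% pb
  path <- dp_affine_align(sm, gap_open, gap_extend)

  expand <- function(rows, idx) {
    mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    out <- matrix("-", nrow = nrow(mat), ncol = length(idx))
    take <- idx > 0L
    out[, take] <- mat[, idx[take], drop = FALSE]
    apply(out, 1L, paste, collapse = "")
  }
  list(ids = c(ga$ids, gb$ids),
       rows = c(expand(ga$rows, path$a), expand(gb$rows, path$b)))
}

aligned_p_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) return(NA_real_)
  sum(ca[keep] != cb[keep]) / sum(keep)
}

#' p-distance matrix from a multiple alignment
#'
#' For each pair of rows, sites where either row has a gap are skipped
#' (pairwise deletion); the distance is the fraction of differing sites
#' among those compared. A pair with no comparable sites is an error.
#'
#' @param msa an `nlr_msa` (or list with `ids` and `rows`).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
p_distance_matrix <- function(msa) {
  rows <- msa$rows
  ids <- msa$ids
  n <- length(rows)
  stopifnot(n >= 2L, length(unique(nchar(rows))) == 1L)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  gap <- mat == "-"
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      keep <- !gap[i, ] & !gap[j, ]
      nk <- sum(keep)
      if (nk == 0L) {
        stop(sprintf("no comparable sites between '%s' and '%s'",
                     ids[i], ids[j]), call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(mat[i, keep] != mat[j, keep]) / nk
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration: at each step the pair minimizing
#' the Q criterion is joined (ties broken toward the lexicographically
#' smallest pair of subtree labels), branch lengths follow the standard
#' formulas, and negative branch lengths are clamped to zero with the
#' deficit moved to the sister branch. The result is unrooted.
#'
#' @param d symmetric distance matrix with taxon dimnames.
#' @return An [ape::phylo] tree.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' nj_tree(d)$edge.length  # A:1, B:1, C:3
#' @export
nj_tree <- function(d) {
  ids <- rownames(d)
  n <- length(ids)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  stopifnot(isSymmetric(unname(d)), all(diag(d) == 0))

  # newick fragments + smallest contained leaf label for tie-breaking
  frag <- ids
  tielab <- ids
  D <- d
  fmt <- function(x) sprintf("%.10g", x)

  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      lab <- sort(c(tielab[ij[1L]], tielab[ij[2L]]))
      paste(lab, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]

    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + (-vi); vi <- 0 }
    if (vj < 0) { vi <- vi + (-vj); vj <- 0 }

    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(vi), frag[j], fmt(vj))
    new_tie <- min(tielab[i], tielab[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dk <- pmax(dk, 0)

    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    tielab <- c(tielab[keep], new_tie)
  }

  # final 3-way join
  dAB <- D[1, 2]; dAC <- D[1, 3]; dBC <- D[2, 3]
  vA <- max((dAB + dAC - dBC) / 2, 0)
  vB <- max((dAB + dBC - dAC) / 2, 0)
  vC <- max((dAC + dBC - dAB) / 2, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(vA), frag[2], fmt(vB), frag[3], fmt(vC))
  ape::read.tree(text = nwk)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate and reports, for every internal edge of the full-data
#' tree, the percentage of replicates containing the same bipartition
#' (stored in `node.label`). A majority-rule (>50%) consensus of the
#' replicate trees is attached as attribute `"consensus"`. Deterministic
#' given `seed`.
#'
#' @param msa an `nlr_msa` with at least 4 rows.
#' @param n_reps number of bootstrap replicates (>= 1); surveys
#'   conventionally use 1000.
#' @param seed integer RNG seed.
#' @return The NJ tree of the full alignment with per-edge support values
#'   in \[0, 100\] as `node.label`.
#' @export
bootstrap_support <- function(msa, n_reps = 1000L, seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (length(msa$rows) < 4L) stop("bootstrap needs at least 4 sequences",
                                  call. = FALSE)
  main <- nj_tree(p_distance_matrix(msa))
  mat <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  L <- ncol(mat)
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rmsa <- list(ids = msa$ids,
                 rows = apply(mat[, cols, drop = FALSE], 1L, paste,
                              collapse = ""))
    reps[[b]] <- nj_tree(p_distance_matrix(rmsa))
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$node.label <- as.character(round_half_up(100 * counts / n_reps, 1))
  attr(main, "consensus") <- ape::consensus(reps, p = 0.5)
  main
}

#' Write a tree in Newick format
#'
#' @param tree an [ape::phylo] tree (support values, if any, travel as
#'   internal node labels).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Parse a Newick tree file
#'
#' @param path path to a Newick file.
#' @return An [ape::phylo] tree. Malformed input (including unbalanced
#'   parentheses, reported with a character offset) is an error.
#' @export
parse_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(trimws(txt))) stop("parse error: empty Newick file",
                                 call. = FALSE)
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop(sprintf("parse error: unbalanced ')' at character %d", k),
           call. = FALSE)
    }
  }
  if (depth != 0L) {
    stop(sprintf("parse error: %d unclosed '(' at end of input", depth),
         call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tree)) stop("parse error: not a valid Newick tree",
                          call. = FALSE)
  tree
}
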