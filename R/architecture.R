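# Domain-architecture assembly and subclass classification. Domain hits
# (TIR/NB-ARC/LRR/RPW8) plus predicted coiled-coils become an ordered
# token string over {C, T, N, L, R}, which maps onto the survey's
# subclass grammar (N, NL, ..., CNLNLN, TN, RN) and the nTNL/TNL
# subfamily split.

# Token strings recognized by the survey grammar; everything else is
# reported as OTHER.
CLASS_GRAMMAR <- c("N", "NL", "NLL", "NLN", "NLNLN", "NN",
                   "CN", "CNL", "CNN", "CNLN", "CNLNLN", "TN", "RN")

DOMAIN_TOKEN <- c("TIR" = "T", "NB-ARC" = "N", "LRR" = "L", "RPW8" = "R")

#' Condition signalled for genes without an NB-ARC domain
#'
#' [build_architecture()] signals an error of class `nlr_not_nbs` for
#' genes lacking any NB-ARC hit: such genes are outside the NBS-gene
#' definition and are excluded from the survey (an explicit signal, not a
#' silent drop).
#'
#' @param gene_id offending gene.
#' @keywords internal
not_nbs_error <- function(gene_id) {
  stop(structure(
    class = c("nlr_not_nbs", "error", "condition"),
    list(message = sprintf("gene '%s' has no NB-ARC domain hit; not an NBS gene",
                           gene_id),
         call = NULL)))
}

#' Build a gene's ordered domain architecture
#'
#' Converts TIR/NB-ARC/LRR/RPW8 domain hits into tokens ordered by
#' protein coordinate, merging overlapping hits of the same type (overlap
#' greater than half the shorter hit). A coiled-coil token `C` is added
#' only when a predicted segment starts before the first NB-ARC hit
#' (N-terminal coiled-coil semantics) and the gene has no TIR domain.
#'
#' @param gene_id gene identifier (used in error messages and the result).
#' @param hits domain-hit data frame rows for this gene.
#' @param cc coiled-coil segments from [predict_coiled_coil()] on the same
#'   protein (may have zero rows).
#' @return List of class `nlr_architecture` with elements `gene_id`,
#'   `tokens` (character vector over C/T/N/L/R) and `aa_start` (the
#'   anchoring coordinate of each token).
#' @export
build_architecture <- function(gene_id, hits, cc = NULL) {
  hits <- hits[hits$domain %in% names(DOMAIN_TOKEN), , drop = FALSE]
  if (!any(hits$domain == "NB-ARC")) not_nbs_error(gene_id)

  merged <- do.call(rbind, lapply(split(hits, hits$domain), merge_same_type))
  merged <- merged[order(merged$aa_start, merged$aa_end), , drop = FALSE]

  tokens <- unname(DOMAIN_TOKEN[merged$domain])
  starts <- merged$aa_start

  has_tir <- "T" %in% tokens
  if (!has_tir && !is.null(cc) && nrow(cc) > 0L) {
    first_n <- min(starts[tokens == "N"])
    cc_before <- cc$aa_start < first_n
    if (any(cc_before)) {
      tokens <- c("C", tokens)
      starts <- c(min(cc$aa_start[cc_before]), starts)
      ord <- order(starts)
      tokens <- tokens[ord]
      starts <- starts[ord]
    }
  }

  structure(list(gene_id = gene_id, tokens = tokens, aa_start = starts),
            class = "nlr_architecture")
}

# Merge same-type hits whose overlap exceeds 50% of the shorter hit;
# distinct LRR hits stay separate (needed to tell NL from NLL).
merge_same_type <- function(h) {
  h <- h[order(h$aa_start, h$aa_end), , drop = FALSE]
  if (nrow(h) <= 1L) return(h[, c("domain", "aa_start", "aa_end")])
  out <- h[1L, , drop = FALSE]
  for (i in 2L:nrow(h)) {
    last <- nrow(out)
    ov <- min(out$aa_end[last], h$aa_end[i]) - max(out$aa_start[last], h$aa_start[i]) + 1L
    shorter <- min(out$aa_end[last] - out$aa_start[last],
                   h$aa_end[i] - h$aa_start[i]) + 1L
    if (ov > shorter / 2) {
      out$aa_end[last] <- max(out$aa_end[last], h$aa_end[i])
    } else {
      out <- rbind(out, h[i, , drop = FALSE])
    }
  }
  out[, c("domain", "aa_start", "aa_end")]
}

#' Classify a domain architecture into the survey grammar
#'
#' The class name is the literal concatenation of the token string, with
#' two overrides: any RPW8-containing gene is `RN`, and architectures
#' outside the recognized grammar are `OTHER`. The subfamily is `TNL`
#' exactly when a TIR token is present; a coiled-coil token co-occurring
#' with TIR is dropped from the name (the taxonomy has no CT classes).
#'
#' @param arch an `nlr_architecture` from [build_architecture()].
#' @return List with `gene_id`, `class_name`, `subfamily` (`nTNL`/`TNL`)
#'   and `cc_containing` (logical: gene carries an N-terminal coiled-coil,
#'   counted separately from the class name).
#' @examples
#' a <- build_architecture("g1",
#'   data.frame(gene_id = "g1", domain = c("TIR", "NB-ARC"),
#'              aa_start = c(5, 150), aa_end = c(120, 430), score = 100))
#' classify_architecture(a)
#' @export
classify_architecture <- function(arch) {
  tokens <- arch$tokens
  stopifnot(length(tokens) >= 1L, "N" %in% tokens)
  has_tir <- "T" %in% tokens
  has_cc <- "C" %in% tokens
  if (has_tir) tokens <- tokens[tokens != "C"]
  name <- if ("R" %in% tokens) "RN" else paste(tokens, collapse = "")
  if (!name %in% CLASS_GRAMMAR) name <- "OTHER"
  list(gene_id = arch$gene_id,
       class_name = name,
       subfamily = if (has_tir) "TNL" else "nTNL",
       cc_containing = has_cc)
}

#' Subfamily marker from the kinase-2 terminal residue
#'
#' The final residue of the kinase-2 motif is a subfamily marker in
#' NBS-LRR proteins: tryptophan (W) marks nTNL genes and aspartate (D)
#' marks TNL genes. Any other terminal residue is reported as `unknown`
#' rather than guessed.
#'
#' @param kinase2_hit the amino-acid substring matched by the kinase-2
#'   motif.
#' @return One of `"nTNL"`, `"TNL"`, `"unknown"`.
#' @examples
#' kinase2_marker("RYLIVLDDVWSTDAW")  # nTNL
#' @export
kinase2_marker <- function(kinase2_hit) {
  if (!is.character(kinase2_hit) || length(kinase2_hit) != 1L ||
      is.na(kinase2_hit) || nchar(kinase2_hit) == 0L) {
    stop("kinase2_hit must be a non-empty string", call. = FALSE)
  }
  last <- substr(kinase2_hit, nchar(kinase2_hit), nchar(kinase2_hit))
  switch(last, W = "nTNL", D = "TNL", "unknown")
}
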