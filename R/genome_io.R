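# Readers and writers for every external representation the survey
# touches: gene models (GFF3), proteins (FASTA), domain hits (TSV) and the
# survey output tables. Coordinates are GFF3-style 1-based inclusive
# throughout.

DOMAIN_VOCAB <- c("TIR", "NB-ARC", "LRR", "RPW8", "CC")

#' Read gene models from a GFF3 file
#'
#' Parses `gene` features (all other feature types are ignored) into a
#' gene-model table. Each feature must carry an `ID` attribute, unique
#' within the file.
#'
#' @param path path to a GFF3 file.
#' @return A data frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand` (1-based inclusive coordinates).
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tdemo\tgene\t1000\t2000\t.\t+\t.\tID=g1"), gff)
#' read_gene_models(gff)
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != 9L) {
      stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, found %d",
                   i, nf), call. = FALSE)
    }
  }
  if (length(body) == 0L) {
    return(data.frame(gene_id = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) {
    return(data.frame(gene_id = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  ids <- as.character(gr$ID)
  if (anyNA(ids)) stop("gene feature without an ID attribute", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate gene ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  data.frame(
    gene_id    = ids,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start      = GenomicRanges::start(gr),
    end        = GenomicRanges::end(gr),
    strand     = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    stringsAsFactors = FALSE
  )
}

#' Write gene models to a GFF3 file
#'
#' Inverse of [read_gene_models()]; emits one `gene` feature per row with
#' the `gene_id` as the `ID` attribute.
#'
#' @param genes gene-model data frame (`gene_id`, `chromosome`, `start`,
#'   `end`, `strand`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  validate_gene_models(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chromosome,
    ranges   = IRanges::IRanges(start = genes$start, end = genes$end),
    strand   = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$source <- "nlrsurvey"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

validate_gene_models <- function(genes) {
  need <- c("gene_id", "chromosome", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene ID(s): ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- genes$start < 1 | genes$end < genes$start
  if (any(bad)) {
    stop("invalid coordinates (need 1 <= start <= end) for: ",
         paste(genes$gene_id[bad], collapse = ", "), call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  invisible(genes)
}

#' Read protein sequences from a FASTA file
#'
#' Sequence IDs are the first whitespace-delimited token of each header.
#' Sequences are uppercased and a single trailing stop (`*`) is stripped.
#' Characters outside the 20 canonical amino acids plus `X` are rejected.
#'
#' @param path path to a protein FASTA file.
#' @return Named character vector mapping gene ID to protein sequence.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # Biostrings silently drops invalid letters, so validate the raw lines
  # first to honor the "error naming the record" contract
  lines <- readLines(path, warn = FALSE)
  current <- "(none)"
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      current <- strsplit(sub("^>", "", ln), "\\s+")[[1]][1]
      next
    }
    body <- toupper(gsub("[\\s*]", "", ln, perl = TRUE))
    bad <- gsub("[ACDEFGHIKLMNPQRSTVWYX]", "", body)
    if (nchar(bad) > 0L) {
      stop(sprintf("record '%s' contains non-amino-acid character(s): %s",
                   current,
                   paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")),
           call. = FALSE)
    }
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  names(seqs) <- ids
  for (id in ids) {
    bad <- gsub("[ACDEFGHIKLMNPQRSTVWYX]", "", seqs[[id]])
    if (nchar(bad) > 0L) {
      stop(sprintf("record '%s' contains non-amino-acid character(s): %s",
                   id, paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")),
           call. = FALSE)
    }
    if (nchar(seqs[[id]]) < 1L) {
      stop(sprintf("record '%s' is empty", id), call. = FALSE)
    }
  }
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), path)
  invisible(path)
}

#' Read domain hits from a TSV file
#'
#' The table is the package's minimal five-column dialect of a Pfam/
#' InterPro-style per-gene domain report: `gene_id`, `domain`, `aa_start`,
#' `aa_end`, `score`, with a header line. Domain tokens are restricted to
#' the closed vocabulary `TIR`, `NB-ARC`, `LRR`, `RPW8`, `CC`.
#'
#' @param path path to the TSV file.
#' @return Data frame of domain hits (protein coordinates, 1-based
#'   inclusive).
#' @export
read_domain_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hits <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "domain", "aa_start", "aa_end", "score")
  miss <- setdiff(need, names(hits))
  if (length(miss)) {
    stop("domain-hit table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  hits <- hits[need]
  validate_domain_hits(hits)
  hits
}

validate_domain_hits <- function(hits) {
  bad <- !hits$domain %in% DOMAIN_VOCAB
  if (any(bad)) {
    stop(sprintf("unknown domain token(s) %s; allowed: %s",
                 paste(unique(hits$domain[bad]), collapse = ", "),
                 paste(DOMAIN_VOCAB, collapse = ", ")), call. = FALSE)
  }
  if (any(hits$aa_start < 1 | hits$aa_end < hits$aa_start)) {
    stop("domain hits must satisfy 1 <= aa_start <= aa_end", call. = FALSE)
  }
  invisible(hits)
}

#' Write domain hits to a TSV file
#'
#' @param hits domain-hit data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble a survey dataset
#'
#' Bundles gene models, protein sequences and domain hits into one
#' validated object: every domain hit must resolve to a known gene and
#' fall inside its protein.
#'
#' @param genes gene-model data frame from [read_gene_models()].
#' @param proteins named character vector from [read_protein_fasta()].
#' @param hits domain-hit data frame from [read_domain_hits()].
#' @param provenance free-form metadata list (source paths, seed).
#' @return An object of class `nlr_survey`.
#' @export
survey_dataset <- function(genes, proteins, hits, provenance = list()) {
  validate_gene_models(genes)
  validate_domain_hits(hits)
  unknown <- setdiff(hits$gene_id, genes$gene_id)
  if (length(unknown)) {
    stop("domain hits for unknown gene(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  no_prot <- setdiff(unique(hits$gene_id), names(proteins))
  if (length(no_prot)) {
    stop("no protein sequence for gene(s) with domain hits: ",
         paste(no_prot, collapse = ", "), call. = FALSE)
  }
  plen <- nchar(proteins)[hits$gene_id]
  over <- hits$aa_end > plen
  if (any(over)) {
    stop("domain hit(s) extend past the protein for: ",
         paste(unique(hits$gene_id[over]), collapse = ", "), call. = FALSE)
  }
  structure(list(genes = genes, proteins = proteins, hits = hits,
                 provenance = provenance),
            class = "nlr_survey")
}

#' @export
print.nlr_survey <- function(x, ...) {
  cat(sprintf("nlr_survey: %d genes, %d domain hits, %d proteins\n",
              nrow(x$genes), nrow(x$hits), length(x$proteins)))
  invisible(x)
}

#' Write the survey output tables
#'
#' Writes `genes.tsv` (per-gene class, subfamily, cluster and tandem-array
#' assignment), `clusters.tsv`, `arrays.tsv`, `summary.json` and a plain-
#' text per-chromosome gene map (`chromosome_map.txt`) in which cluster
#' members are bracketed.
#'
#' @param dataset an `nlr_survey` object.
#' @param results list with elements `labels` (from
#'   [classify_architecture()] applied per gene), `clusters` (from
#'   [assign_clusters()]), `arrays` (from [detect_tandem_arrays()]) and
#'   `summary` (from [summarize_survey()]).
#' @param out_dir output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_survey_tables <- function(dataset, results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  genes <- dataset$genes
  labels <- results$labels
  clusters <- results$clusters
  arrays <- results$arrays

  gene_tab <- data.frame(
    gene_id = genes$gene_id, chromosome = genes$chromosome,
    start = genes$start, end = genes$end, strand = genes$strand,
    stringsAsFactors = FALSE
  )
  idx <- match(gene_tab$gene_id, labels$gene_id)
  gene_tab$class <- labels$class_name[idx]
  gene_tab$subfamily <- labels$subfamily[idx]
  gene_tab$cluster_id <- unname(clusters$membership[gene_tab$gene_id])
  array_member <- stats::setNames(
    rep(arrays$array_id, lengths(arrays$members)), unlist(arrays$members))
  gene_tab$tandem_id <- unname(array_member[gene_tab$gene_id])

  files <- character()
  f <- file.path(out_dir, "genes.tsv")
  utils::write.table(gene_tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  ctab <- clusters$clusters
  ctab_out <- data.frame(
    cluster_id = ctab$cluster_id, chromosome = ctab$chromosome,
    n_members = ctab$n_members, span_bp = ctab$span_bp,
    members = vapply(ctab$members, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  f <- file.path(out_dir, "clusters.tsv")
  utils::write.table(ctab_out, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  atab_out <- data.frame(
    array_id = arrays$array_id, cluster_id = arrays$cluster_id,
    n_members = lengths(arrays$members), span_bp = arrays$span_bp,
    over_limit = arrays$over_limit,
    members = vapply(arrays$members, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  f <- file.path(out_dir, "arrays.tsv")
  utils::write.table(atab_out, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(out_dir, "summary.json")
  jsonlite::write_json(unclass(results$summary), f, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  files <- c(files, f)

  f <- file.path(out_dir, "chromosome_map.txt")
  writeLines(chromosome_map_text(gene_tab), f)
  files <- c(files, f)

  invisible(files)
}

# Text analogue of a chromosome map figure: genes in coordinate order,
# cluster members bracketed.
chromosome_map_text <- function(gene_tab) {
  out <- character()
  for (chrom in sort(unique(gene_tab$chromosome))) {
    g <- gene_tab[gene_tab$chromosome == chrom, , drop = FALSE]
    g <- g[order(g$start, g$gene_id), , drop = FALSE]
    out <- c(out, sprintf("== %s (%d genes) ==", chrom, nrow(g)))
    cl <- ifelse(is.na(g$cluster_id), "", g$cluster_id)
    cls <- ifelse(is.na(g$class), "", g$class)
    for (i in seq_len(nrow(g))) {
      bracket <- " "
      if (nzchar(cl[i])) {
        first <- !duplicated(cl)[i]
        last <- !duplicated(cl, fromLast = TRUE)[i]
        bracket <- if (first && last) "-" else if (first) "[" else if (last) "]" else "|"
      }
      out <- c(out, sprintf("%s %10d  %-18s %-8s %s", bracket, g$start[i],
                            g$gene_id[i], cls[i], cl[i]))
    }
  }
  if (length(out) == 0L) out <- "(no genes)"
  out
}
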