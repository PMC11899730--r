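# End-to-end survey orchestration: classify -> map/cluster -> motifs ->
# phylogeny -> summarize, with deterministic seeding and a run manifest.
# The CLI wrapper in inst/cli/nlrsurvey.R exposes the same stages as
# subcommands.

#' Run the full NLR survey pipeline
#'
#' Stages, in dependency order: load (or simulate) the dataset, predict
#' coiled-coils, assemble and classify domain architectures, assign
#' clusters and tandem arrays, scan the six NBS motifs, extract P-loop to
#' GLPL regions and build the bootstrap NJ phylogeny, then summarize and
#' write every output table. One global seed fans out to the per-stage
#' seeds by fixed offsets so stages are independently reproducible.
#'
#' @param config a configuration list, or the path of a YAML file holding
#'   one. Exactly one of `input` (list with `gff3`, `fasta`, `domains`
#'   paths) or `simulate` (arguments to [simulation_config()]) must be
#'   present. Optional entries with defaults: `max_gap_bp` (250000),
#'   `max_span_bp` (150000), `cc_threshold` (0.8), `bootstrap` (1000,
#'   set 0 to skip), `seed` (1).
#' @param out_dir output directory.
#' @return Invisibly, a list with the per-stage results (`dataset`,
#'   `labels`, `clusters`, `arrays`, `motif_hits`, `regions`, `tree`,
#'   `summary`, `manifest`). Output files: `genes.tsv`, `clusters.tsv`,
#'   `arrays.tsv`, `motifs.tsv`, `distances.tsv`, `tree.nwk`,
#'   `summary.json`, `chromosome_map.txt`, `manifest.json`.
#' @export
run_survey <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    stop("config must contain exactly one of 'input' or 'simulate'",
         call. = FALSE)
  }
  max_gap_bp <- config$max_gap_bp %||% 250000L
  max_span_bp <- config$max_span_bp %||% 150000L
  cc_threshold <- config$cc_threshold %||% 0.8
  n_boot <- config$bootstrap %||% 1000L
  seed <- as.integer(config$seed %||% 1L)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(package = "nlrsurvey",
                   version = as.character(utils::packageVersion("nlrsurvey")),
                   seed = seed,
                   parameters = list(max_gap_bp = max_gap_bp,
                                     max_span_bp = max_span_bp,
                                     cc_threshold = cc_threshold,
                                     bootstrap = n_boot))
  fail <- function(stage, e) {
    manifest$FAILED <- list(stage = stage, message = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  # -- load / simulate ------------------------------------------------
  dataset <- tryCatch({
    if (has_sim) {
      sim_args <- config$simulate
      if (isTRUE(sim_args) || length(sim_args) == 0L) sim_args <- list()
      sim_args$seed <- sim_args$seed %||% seed
      sim <- simulate_survey(do.call(simulation_config, sim_args))
      jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, pretty = TRUE, na = "null")
      sim$dataset
    } else {
      survey_dataset(read_gene_models(config$input$gff3),
                     read_protein_fasta(config$input$fasta),
                     read_domain_hits(config$input$domains),
                     provenance = config$input)
    }
  }, error = function(e) fail("load", e))
  message(sprintf("loaded %d genes, %d domain hits", nrow(dataset$genes),
                  nrow(dataset$hits)))
  manifest$counts <- list(identified = nrow(dataset$genes))

  # -- classify -------------------------------------------------------
  labels <- tryCatch(
    classify_dataset(dataset, cc_threshold = cc_threshold),
    error = function(e) fail("classify", e))
  manifest$counts$classified <- nrow(labels)
  excluded_ids <- setdiff(dataset$genes$gene_id, labels$gene_id)
  nbs_genes <- dataset$genes[dataset$genes$gene_id %in% labels$gene_id, ,
                             drop = FALSE]
  message(sprintf("classified %d NBS genes (%d excluded: no NB-ARC hit)",
                  nrow(labels), length(excluded_ids)))

  # -- clusters and arrays -------------------------------------------
  clusters <- tryCatch(assign_clusters(nbs_genes, max_gap_bp = max_gap_bp),
                       error = function(e) fail("clusters", e))
  arrays <- tryCatch(
    detect_tandem_arrays(clusters, nbs_genes, max_span_bp = max_span_bp),
    error = function(e) fail("arrays", e))
  manifest$counts$clustered <- sum(!is.na(clusters$membership))

  # -- motifs ---------------------------------------------------------
  motifs <- nbs_motifs()
  motif_hits <- tryCatch({
    hits <- lapply(labels$gene_id, function(id) {
      scan_motifs(dataset$proteins[[id]], motifs, gene_id = id)
    })
    do.call(rbind, c(hits, list(make.row.names = FALSE)))
  }, error = function(e) fail("motifs", e))
  utils::write.table(motif_hits, file.path(out_dir, "motifs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # -- phylogeny ------------------------------------------------------
  phylo <- tryCatch({
    regions <- lapply(labels$gene_id, function(id) {
      extract_nbs_region(dataset$proteins[[id]],
                         motif_hits[motif_hits$gene_id == id, , drop = FALSE],
                         gene_id = id)
    })
    kept <- regions[!vapply(regions, `[[`, logical(1), "excluded")]
    tree <- NULL
    msa <- NULL
    if (length(kept) >= 3L) {
      msa <- progressive_msa(kept)
      d <- p_distance_matrix(msa)
      utils::write.table(round(d, 6), file.path(out_dir, "distances.tsv"),
                         sep = "\t", quote = FALSE)
      tree <- if (length(kept) >= 4L && n_boot >= 1L) {
        bootstrap_support(msa, n_reps = n_boot, seed = seed + 1L)
      } else {
        nj_tree(d)
      }
      write_newick(tree, file.path(out_dir, "tree.nwk"))
    }
    list(regions = regions, kept = kept, msa = msa, tree = tree)
  }, error = function(e) fail("phylogeny", e))
  manifest$counts$phylogeny_eligible <- length(phylo$kept)
  message(sprintf("phylogeny: %d of %d genes carry both P-loop and GLPL",
                  length(phylo$kept), nrow(labels)))

  # -- summary --------------------------------------------------------
  summary <- tryCatch(
    summarize_survey(nbs_genes, labels, clusters, arrays),
    error = function(e) fail("summary", e))
  write_survey_tables(dataset, list(labels = labels, clusters = clusters,
                                    arrays = arrays, summary = summary),
                      out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  print(summary)

  invisible(list(dataset = dataset, labels = labels, clusters = clusters,
                 arrays = arrays, motif_hits = motif_hits,
                 regions = phylo$regions, msa = phylo$msa, tree = phylo$tree,
                 summary = summary, manifest = manifest))
}

#' Classify every gene of a survey dataset
#'
#' Runs [predict_coiled_coil()], [build_architecture()] and
#' [classify_architecture()] per gene. Genes without an NB-ARC hit are
#' excluded (they fail the NBS-gene definition) and simply absent from
#' the result.
#'
#' @param dataset an `nlr_survey`.
#' @param cc_threshold coiled-coil detection probability threshold.
#' @return Data frame with `gene_id`, `class_name`, `subfamily`,
#'   `cc_containing`.
#' @export
classify_dataset <- function(dataset, cc_threshold = 0.8) {
  rows <- lapply(dataset$genes$gene_id, function(id) {
    hits <- dataset$hits[dataset$hits$gene_id == id, , drop = FALSE]
    protein <- if (id %in% names(dataset$proteins))
      dataset$proteins[[id]] else NULL
    cc <- if (is.null(protein)) NULL else
      predict_coiled_coil(protein, threshold = cc_threshold)
    lab <- tryCatch({
      arch <- build_architecture(id, hits, cc)
      classify_architecture(arch)
    }, nlr_not_nbs = function(e) NULL)
    if (is.null(lab)) return(NULL)
    data.frame(gene_id = id, class_name = lab$class_name,
               subfamily = lab$subfamily, cc_containing = lab$cc_containing,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(), class_name = character(),
                      subfamily = character(), cc_containing = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
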