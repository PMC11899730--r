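# Synthetic survey generator: complete gene-model/protein/domain-hit
# datasets with planted subclasses, clusters, tandem arrays, NBS motifs
# and (separately) sequences evolved along a known tree, so that every
# pipeline stage can be checked against known ground truth.

# Fixed N-terminal module sequences. The coiled-coil module is a perfect
# heptad repeat (hydrophobics at a/d) that predict_coiled_coil() must
# find; TIR and RPW8 stubs are fixed pseudo-sequences reported as domain
# hits (they carry no signal beyond their envelopes).
CC_UNIT <- "LQELEEK"
TIR_STUB <- paste0("MASSSSRFDVFPSFSGVDVRKTFLSHLLKEFDRKLINTFMDN",
                   "EIERSRSIGPELKEAIRESRIAIVLLSRNYASSSWCLNELLEIHK")
RPW8_STUB <- paste0("MAEAILFDIASGALNSLLGKLGELLEEEYKLQKGVRKEVRSLS",
                    "RELEMIQAFLEKMSEEEDPDVQDKV")
LRR_STUB <- paste0("PLSLKSLDLSNNKLTGSIPSELGNLKNLQVLDLSNNSLSGEIP",
                   "ASLGNLTNLEELYLS")

#' Configuration for the synthetic survey generator
#'
#' Defaults emulate the published pepper survey: 252 genes mixed across
#' the 11 reference subclasses in proportion to [pepper_class_inventory],
#' placed on 12 chromosomes plus an unassigned `chr00`, with 47 planted
#' clusters holding 136 genes (start-to-start spacing 200 kb, within the
#' 250-kb chaining rule) of which 30 head runs totalling 77 genes are
#' tandem arrays (spacing 20 kb, spans under 150 kb); remaining genes are
#' singletons spaced 400 kb apart (violating the chaining rule by
#' construction). Motif instances are sampled from the consensus PWMs at
#' `motif_divergence` per-residue substitution probability (default 0.1,
#' the package's noisy study condition; 0 plants exact consensuses).
#'
#' @param n_genes number of genes (default 252).
#' @param class_frequencies named numeric vector of class weights
#'   (default: reference inventory counts).
#' @param n_chromosomes number of assembled chromosomes (default 12; an
#'   unassigned `chr00` additionally receives singletons).
#' @param cluster_plan optional data frame (`size`, `tandem_head`) to
#'   override the planted cluster composition; `tandem_head` members at
#'   the start of each cluster get tandem spacing.
#' @param motif_divergence per-residue substitution probability in
#'   \[0, 0.5\] applied to motif instances and N-terminal modules.
#' @param linker_length_range min/max length of random inter-motif
#'   linkers.
#' @param tandem_gap_bp,cluster_gap_bp,singleton_gap_bp start-to-start
#'   spacings for tandem runs, non-tandem cluster links, and between
#'   units; defaults 20 kb, 200 kb and 400 kb.
#' @param seed integer RNG seed.
#' @return List of class `nlr_sim_config`.
#' @export
simulation_config <- function(n_genes = 252L,
                              class_frequencies = NULL,
                              n_chromosomes = 12L,
                              cluster_plan = NULL,
                              motif_divergence = 0.1,
                              linker_length_range = c(15L, 40L),
                              tandem_gap_bp = 20000L,
                              cluster_gap_bp = 200000L,
                              singleton_gap_bp = 400000L,
                              seed = 42L) {
  if (is.null(class_frequencies)) {
    class_frequencies <- stats::setNames(pepper_class_inventory$count,
                                         pepper_class_inventory$class_name)
  }
  if (any(class_frequencies < 0) || sum(class_frequencies) == 0) {
    stop("class_frequencies must be non-negative and not all zero",
         call. = FALSE)
  }
  if (motif_divergence < 0 || motif_divergence > 0.5) {
    stop("motif_divergence must lie in [0, 0.5]", call. = FALSE)
  }
  if (tandem_gap_bp >= 150000L) {
    stop("tandem_gap_bp must keep planted arrays under the 150-kb span rule",
         call. = FALSE)
  }
  if (cluster_gap_bp > 250000L || singleton_gap_bp <= 250000L) {
    stop(paste("cluster_gap_bp must respect and singleton_gap_bp must",
               "violate the 250-kb chaining rule"), call. = FALSE)
  }
  if (is.null(cluster_plan)) cluster_plan <- default_cluster_plan(n_genes)
  structure(list(n_genes = as.integer(n_genes),
                 class_frequencies = class_frequencies,
                 n_chromosomes = as.integer(n_chromosomes),
                 cluster_plan = cluster_plan,
                 motif_divergence = motif_divergence,
                 linker_length_range = as.integer(linker_length_range),
                 tandem_gap_bp = as.integer(tandem_gap_bp),
                 cluster_gap_bp = as.integer(cluster_gap_bp),
                 singleton_gap_bp = as.integer(singleton_gap_bp),
                 seed = as.integer(seed)),
            class = "nlr_sim_config")
}

# Planted cluster composition. At the reference scale (252 genes) this is
# the published landscape exactly: 47 clusters / 136 clustered genes with
# 30 tandem events / 77 tandem genes (18 pairs, 11 triples, one
# eight-gene array). Other scales keep roughly the same proportions.
default_cluster_plan <- function(n_genes) {
  if (n_genes >= 252L) {
    sizes <- c(rep(2L, 23), rep(3L, 13), rep(4L, 7), rep(5L, 3), 8L)
    heads <- c(rep(2L, 18), rep(0L, 5),      # 18 of the pairs are tandem
               rep(3L, 11), rep(0L, 2),      # 11 of the triples
               rep(0L, 7), rep(0L, 3), 8L)   # the 8-gene cluster
    return(data.frame(size = sizes, tandem_head = heads))
  }
  clustered <- floor(0.54 * n_genes)
  sizes <- integer()
  pattern <- c(2L, 3L, 2L, 4L, 2L, 3L, 2L, 5L)
  k <- 0L
  while (sum(sizes) + 2L <= clustered) {
    k <- k + 1L
    sizes <- c(sizes, min(pattern[(k - 1L) %% length(pattern) + 1L],
                          clustered - sum(sizes)))
  }
  sizes <- sizes[sizes >= 2L]
  heads <- ifelse(seq_along(sizes) %% 3L != 0L, sizes, 0L)
  data.frame(size = sizes, tandem_head = as.integer(heads))
}

#' Simulate a complete synthetic NLR survey
#'
#' Generates gene coordinates, domain hits and protein sequences with
#' known ground truth. Each gene draws a subclass from the configured
#' mixture; its protein is assembled module by module (TIR stub,
#' coiled-coil heptad repeat, or RPW8 stub at the N-terminus as the class
#' dictates, then NBS blocks carrying the six conserved motifs in
#' canonical order separated by random linkers, and LRR stubs), with
#' matching TIR/NB-ARC/LRR/RPW8 domain hits. Coiled-coils are *not*
#' emitted as hits: they must be rediscovered by [predict_coiled_coil()].
#' Genes are placed on chromosomes according to the planted
#' cluster/tandem plan. Deterministic given `config$seed`.
#'
#' @param config an `nlr_sim_config` from [simulation_config()].
#' @return List with `dataset` (an `nlr_survey`) and `truth` (per-gene
#'   classes, cluster and array memberships with member lists, planted
#'   motif offsets per NBS block, and coiled-coil ranges).
#' @export
simulate_survey <- function(config = simulation_config()) {
  stopifnot(inherits(config, "nlr_sim_config"))
  set.seed(config$seed)
  n <- config$n_genes

  empty <- function() {
    genes <- data.frame(gene_id = character(), chromosome = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE)
    hits <- data.frame(gene_id = character(), domain = character(),
                       aa_start = integer(), aa_end = integer(),
                       score = numeric(), stringsAsFactors = FALSE)
    list(dataset = survey_dataset(genes, character(), hits,
                                  provenance = list(seed = config$seed)),
         truth = list(classes = character(), cluster_membership = character(),
                      clusters = list(), arrays = list(),
                      array_membership = character(),
                      motif_offsets = list(), cc_ranges = list()))
  }
  if (n == 0L) return(empty())

  classes <- sample(names(config$class_frequencies), n, replace = TRUE,
                    prob = config$class_frequencies)
  gene_ids <- sprintf("nbs%04d", seq_len(n))

  prot <- vector("list", n)
  for (i in seq_len(n)) {
    prot[[i]] <- build_synthetic_protein(gene_ids[i], classes[i], config)
  }
  proteins <- stats::setNames(vapply(prot, `[[`, character(1), "protein"),
                              gene_ids)
  hits <- do.call(rbind, lapply(prot, `[[`, "hits"))

  place <- place_genes(gene_ids, nchar(proteins), config)

  genes <- place$genes
  truth <- list(
    classes = stats::setNames(classes, gene_ids),
    cluster_membership = place$cluster_membership,
    clusters = place$clusters,
    arrays = place$arrays,
    array_membership = place$array_membership,
    motif_offsets = stats::setNames(lapply(prot, `[[`, "motif_offsets"),
                                    gene_ids),
    cc_ranges = stats::setNames(lapply(prot, `[[`, "cc_range"), gene_ids)
  )
  dataset <- survey_dataset(genes, proteins, hits,
                            provenance = list(seed = config$seed,
                                              generator = "simulate_survey"))
  list(dataset = dataset, truth = truth)
}

# One synthetic protein with its domain hits and planted truth.
build_synthetic_protein <- function(gene_id, class_name, config) {
  div <- config$motif_divergence
  lnk <- config$linker_length_range
  rand_linker <- function() {
    paste(sample(AA20, sample(lnk[1L]:lnk[2L], 1L), replace = TRUE),
          collapse = "")
  }
  tokens <- if (class_name == "RN") c("R", "N") else
    strsplit(class_name, "")[[1]]

  parts <- character()
  hit_rows <- list()
  motif_offsets <- list()
  cc_range <- NULL
  pos <- 0L
  add <- function(seqpart) {
    parts <<- c(parts, seqpart)
    at <- pos + 1L
    pos <<- pos + nchar(seqpart)
    at
  }
  add_hit <- function(domain, at, len) {
    hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
      gene_id = gene_id, domain = domain, aa_start = at,
      aa_end = at + len - 1L, score = round(stats::runif(1, 50, 300), 1),
      stringsAsFactors = FALSE)
  }

  add(rand_linker())  # N-terminal leader
  nbs_block_i <- 0L
  for (tok in tokens) {
    if (tok == "T") {
      s <- mutate_protein(TIR_STUB, div)
      at <- add(s)
      add_hit("TIR", at, nchar(s))
    } else if (tok == "C") {
      s <- mutate_protein(strrep(CC_UNIT, 6L), div)
      at <- add(s)
      cc_range <- c(at, at + nchar(s) - 1L)  # no CC hit emitted
    } else if (tok == "R") {
      s <- mutate_protein(RPW8_STUB, div)
      at <- add(s)
      add_hit("RPW8", at, nchar(s))
    } else if (tok == "L") {
      s <- mutate_protein(LRR_STUB, div)
      at <- add(s)
      add_hit("LRR", at, nchar(s))
    } else if (tok == "N") {
      nbs_block_i <- nbs_block_i + 1L
      block_start <- pos + 1L
      offs <- stats::setNames(integer(length(NBS_MOTIF_ORDER)),
                              NBS_MOTIF_ORDER)
      for (k in seq_along(NBS_MOTIF_ORDER)) {
        inst <- sample_motif_instance(NBS_MOTIF_ORDER[k], div)
        offs[k] <- add(inst)
        if (k < length(NBS_MOTIF_ORDER)) add(rand_linker())
      }
      add_hit("NB-ARC", block_start, pos - block_start + 1L)
      motif_offsets[[nbs_block_i]] <- offs
    }
    add(rand_linker())
  }

  list(protein = paste(parts, collapse = ""),
       hits = do.call(rbind, hit_rows),
       motif_offsets = motif_offsets,
       cc_range = cc_range)
}

# Consensus instance with per-residue substitution at probability div;
# ambiguity codes are resolved by sampling their pair, X by background.
sample_motif_instance <- function(motif_name, div) {
  chars <- strsplit(nbs_motif_consensus[[motif_name]], "")[[1]]
  out <- vapply(chars, function(ch) {
    if (ch %in% names(AA_AMBIG)) {
      sample(strsplit(AA_AMBIG[[ch]], "")[[1]], 1L)
    } else if (ch == "X") {
      sample(AA20, 1L)
    } else ch
  }, character(1))
  paste(mutate_chars(out, div), collapse = "")
}

mutate_protein <- function(s, div) {
  paste(mutate_chars(strsplit(s, "")[[1]], div), collapse = "")
}

mutate_chars <- function(chars, div) {
  if (div <= 0) return(chars)
  hit <- stats::runif(length(chars)) < div
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(ch) {
      sample(setdiff(AA20, ch), 1L)
    }, character(1))
  }
  chars
}

# Place clusters and singletons on chromosomes; record planted truth.
place_genes <- function(gene_ids, protein_len, config) {
  n <- length(gene_ids)
  plan <- config$cluster_plan
  # drop clusters that no longer fit the gene count
  while (nrow(plan) > 0L && sum(plan$size) > n) {
    plan <- plan[-nrow(plan), , drop = FALSE]
  }
  gene_len <- 3L * protein_len + 1500L  # coding length plus introns

  chroms <- sprintf("chr%02d", seq_len(config$n_chromosomes))
  n_clustered <- if (nrow(plan)) sum(plan$size) else 0L

  # units: clusters (round-robin over assembled chromosomes), then
  # singletons (round-robin including chr00)
  unit_chrom <- character()
  unit_kind <- integer()  # row of plan, or 0 for singleton
  if (nrow(plan) > 0L) {
    unit_chrom <- chroms[(seq_len(nrow(plan)) - 1L) %% length(chroms) + 1L]
    unit_kind <- seq_len(nrow(plan))
  }
  n_single <- n - n_clustered
  if (n_single > 0L) {
    schroms <- c("chr00", chroms)
    unit_chrom <- c(unit_chrom,
                    schroms[(seq_len(n_single) - 1L) %% length(schroms) + 1L])
    unit_kind <- c(unit_kind, rep(0L, n_single))
  }

  cursor <- stats::setNames(rep(100000L, length(c("chr00", chroms))),
                            c("chr00", chroms))
  gi <- 0L
  rows <- vector("list", n)
  cluster_membership <- stats::setNames(rep(NA_character_, n), gene_ids)
  array_membership <- stats::setNames(rep(NA_character_, n), gene_ids)
  clusters <- list()
  arrays <- list()
  ci <- stats::setNames(integer(length(c("chr00", chroms))),
                        c("chr00", chroms))

  for (u in seq_along(unit_chrom)) {
    chrom <- unit_chrom[u]
    kind <- unit_kind[u]
    size <- if (kind == 0L) 1L else plan$size[kind]
    head_k <- if (kind == 0L) 0L else plan$tandem_head[kind]
    members <- character(size)
    for (s in seq_len(size)) {
      gi <- gi + 1L
      id <- gene_ids[gi]
      members[s] <- id
      start <- cursor[[chrom]]
      rows[[gi]] <- data.frame(
        gene_id = id, chromosome = chrom, start = start,
        end = start + gene_len[gi] - 1L,
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
      gap <- if (s < size) {
        if (s < head_k) config$tandem_gap_bp else config$cluster_gap_bp
      } else config$singleton_gap_bp
      cursor[[chrom]] <- start + gap
    }
    if (size >= 2L) {
      ci[[chrom]] <- ci[[chrom]] + 1L
      cid <- sprintf("%s_cl%02d", chrom, ci[[chrom]])
      cluster_membership[members] <- cid
      clusters[[cid]] <- members
      if (head_k >= 2L) {
        aid <- sprintf("%s_t01", cid)
        array_membership[members[seq_len(head_k)]] <- aid
        arrays[[aid]] <- members[seq_len(head_k)]
      }
    }
  }

  genes <- do.call(rbind, rows)
  list(genes = genes, cluster_membership = cluster_membership,
       clusters = clusters, arrays = arrays,
       array_membership = array_membership)
}

#' Random binary tree
#'
#' Uniform coalescent-style topology: lineages are joined in random pairs
#' until one remains; every branch gets an independent shifted-exponential
#' length (`min_branch` floor plus an exponential excess), the floor
#' keeping simulated topologies identifiable — zero-length internal
#' branches are unrecoverable by any method. Deterministic given `seed`.
#'
#' @param n_leaves number of leaves (>= 3); leaves are labelled `t1..tn`.
#' @param seed integer RNG seed.
#' @param mean_branch mean branch length (default 0.1).
#' @param min_branch minimum branch length (default 0.03).
#' @return A rooted binary [ape::phylo] tree.
#' @export
random_tree <- function(n_leaves, seed = 1L, mean_branch = 0.1,
                        min_branch = 0.03) {
  if (n_leaves < 3L) stop("n_leaves must be >= 3", call. = FALSE)
  stopifnot(min_branch >= 0, mean_branch > min_branch)
  set.seed(seed)
  frag <- paste0("t", seq_len(n_leaves))
  bl <- function() min_branch + stats::rexp(1, rate = 1 / (mean_branch - min_branch))
  while (length(frag) > 1L) {
    pick <- sample.int(length(frag), 2L)
    merged <- sprintf("(%s:%.8f,%s:%.8f)", frag[pick[1L]], bl(),
                      frag[pick[2L]], bl())
    frag <- c(frag[-pick], merged)
  }
  ape::read.tree(text = paste0(frag, ";"))
}

#' Evolve sequences along a tree
#'
#' Independent per-site substitution along each branch: a site mutates
#' with probability `1 - exp(-rate * length)` and then changes uniformly
#' to one of the other 19 letters. Indel-free, so the site homology map
#' is the identity. Deterministic given `seed`.
#'
#' @param root root amino-acid sequence.
#' @param tree rooted [ape::phylo] tree (e.g. [random_tree()]).
#' @param rate substitutions per site per unit branch length (> 0).
#' @param seed integer RNG seed.
#' @return List with `sequences` (named by leaf label) and `homology`
#'   (`"identity"`).
#' @export
evolve_sequences_on_tree <- function(root, tree, rate, seed = 1L) {
  assert_protein(root, "root")
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  set.seed(seed)
  ntip <- length(tree$tip.label)
  root_node <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root_node]] <- strsplit(root, "")[[1]]
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1L]
    child <- edges[e, 2L]
    p_sub <- 1 - exp(-rate * lens[e])
    chars <- seqs[[parent]]
    hit <- stats::runif(length(chars)) < p_sub
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(ch) {
        sample(setdiff(AA20, ch), 1L)
      }, character(1))
    }
    seqs[[child]] <- chars
  }
  leaves <- stats::setNames(
    vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
           character(1)),
    tree$tip.label)
  list(sequences = leaves, homology = "identity")
}
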