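# NBS-region extraction, alignment, p-distance, neighbor joining,
# bootstrap and Newick round-trips.

test_that("NBS regions run from the P-loop start to the GLPL end", {
  sim <- simulate_survey(simulation_config(n_genes = 10L, seed = 3L,
                                           motif_divergence = 0))
  id <- names(sim$truth$classes)[sim$truth$classes == "N"][1]
  protein <- sim$dataset$proteins[[id]]
  hits <- scan_motifs(protein, gene_id = id)
  reg <- extract_nbs_region(protein, hits, gene_id = id)
  offs <- sim$truth$motif_offsets[[id]][[1]]
  expect_false(reg$excluded)
  expect_equal(reg$aa_start, unname(offs[["P-loop"]]))
  expect_equal(reg$aa_end, unname(offs[["GLPL"]]) + 21L - 1L)
  expect_equal(reg$sequence, substr(protein, reg$aa_start, reg$aa_end))

  # missing GLPL and disordered motifs are reported exclusions
  no_glpl <- hits[hits$motif_name != "GLPL", ]
  expect_equal(extract_nbs_region(protein, no_glpl)$reason, "missing GLPL")
  dis <- hits
  dis$aa_start[dis$motif_name == "GLPL"] <- 1L
  expect_equal(extract_nbs_region(protein, dis)$reason, "disordered motifs")
})

test_that("pairwise alignment is optimal and deterministic", {
  id <- global_align_pair("MKV", "MKV")
  expect_equal(id$a_aln, "MKV")
  expect_equal(id$b_aln, "MKV")

  g <- global_align_pair("MKV", "MV")
  expect_equal(g$a_aln, "MKV")
  expect_equal(g$b_aln, "M-V")
  # exhaustive enumeration oracle for the score
  expect_equal(g$score,
               oracle_align_score("MKV", "MV", nlrsurvey:::blosum62(), 10, 0.5))

  set.seed(8)
  for (k in 1:5) {
    a <- paste(sample(AA20, sample(3:6, 1), TRUE), collapse = "")
    b <- paste(sample(AA20, sample(3:6, 1), TRUE), collapse = "")
    ab <- global_align_pair(a, b)
    expect_equal(ab$score,
                 oracle_align_score(a, b, nlrsurvey:::blosum62(), 10, 0.5))
    # score symmetry
    expect_equal(ab$score, global_align_pair(b, a)$score)
  }
  expect_error(global_align_pair("MK1", "MK"), "non-amino-acid")
})

test_that("progressive alignment de-gaps back to its inputs", {
  set.seed(21)
  seqs <- stats::setNames(vapply(1:6, function(i) {
    paste(sample(AA20, sample(40:60, 1), TRUE), collapse = "")
  }, character(1)), paste0("s", 1:6))
  msa <- progressive_msa(seqs)
  expect_equal(length(unique(nchar(msa$rows))), 1L)
  degapped <- gsub("-", "", msa$rows, fixed = TRUE)
  expect_equal(stats::setNames(degapped, msa$ids), seqs)

  # identical sequences align without gaps
  same <- stats::setNames(rep(paste(rep("MKVLDD", 5), collapse = ""), 4),
                          paste0("t", 1:4))
  msa2 <- progressive_msa(same)
  expect_false(any(grepl("-", msa2$rows, fixed = TRUE)))
})

test_that("alignment of low-divergence sequences recovers true homology", {
  # indel-free evolution: the true homology map is the identity, so every
  # aligned pair of equal positions must line up column-by-column
  tr <- random_tree(6, seed = 14)
  set.seed(15)
  root <- paste(sample(AA20, 120, TRUE), collapse = "")
  ev <- evolve_sequences_on_tree(root, tr, rate = 0.15, seed = 16)
  msa <- progressive_msa(ev$sequences)
  # correct recovery means no aligner-introduced gaps at all here
  match_frac <- mean(!grepl("-", msa$rows, fixed = TRUE))
  expect_gte(match_frac, 0.95)
})

test_that("p-distance uses pairwise deletion", {
  msa <- list(ids = c("a", "b"), rows = c("AAAA", "AATT"))
  expect_equal(p_distance_matrix(msa)["a", "b"], 0.5)
  msa2 <- list(ids = c("a", "b"), rows = c("A-AA", "AGAA"))
  expect_equal(p_distance_matrix(msa2)["a", "b"], 0)
  msa3 <- list(ids = c("a", "b", "c"), rows = c("AA--", "AA--", "--AA"))
  expect_error(p_distance_matrix(msa3), "a.*c|no comparable")
  ident <- list(ids = c("a", "b"), rows = c("MKV", "MKV"))
  expect_equal(p_distance_matrix(ident)["a", "b"], 0)
})

test_that("3-taxon neighbor joining matches the closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 1, tolerance = 1e-9)
  expect_equal(bl[["B"]], 1, tolerance = 1e-9)
  expect_equal(bl[["C"]], 3, tolerance = 1e-9)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining reconstructs additive matrices exactly", {
  # 4-taxon additive matrix: split AB|CD with internal branch 2
  ids <- c("A", "B", "C", "D")
  d <- matrix(c(0, 2, 4, 4, 2, 0, 4, 4, 4, 4, 0, 2, 4, 4, 2, 0), 4,
              dimnames = list(ids, ids))
  tr <- nj_tree(d)
  expect_equal(tree_splits(tr), "A,B|C,D")
  coph <- ape::cophenetic.phylo(tr)[ids, ids]
  expect_equal(coph, d, tolerance = 1e-9)

  # random additive matrices up to 8 taxa reproduce the generating tree
  for (s in 1:6) {
    n <- sample(5:8, 1)
    set.seed(s)
    gen <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(gen)
    ids <- sort(rownames(D))
    D <- D[ids, ids]
    rec <- nj_tree(D)
    expect_true(same_topology(gen, rec))
    expect_lt(max(abs(ape::cophenetic.phylo(rec)[ids, ids] - D)), 1e-9)
  }
})

test_that("NJ topology on additive data is the unique one, by enumeration", {
  # exhaustive oracle: among all unrooted topologies, exactly one fits an
  # additive matrix with zero residual, and NJ finds it
  for (s in 1:3) {
    set.seed(100 + s)
    n <- 6
    gen <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.2, 1))
    D <- ape::cophenetic.phylo(gen)
    ids <- sort(rownames(D))
    D <- D[ids, ids]
    all_tops <- phangorn::allTrees(n, rooted = FALSE, tip.label = ids)
    resid <- vapply(all_tops, function(tp) {
      fit <- phangorn::nnls.tree(D, tp)
      max(abs(ape::cophenetic.phylo(fit)[ids, ids] - D))
    }, numeric(1))
    zero <- which(resid < 1e-8)
    expect_length(zero, 1L)
    expect_true(same_topology(all_tops[[zero]], nj_tree(D)))
  }
})

test_that("taxon order does not change the NJ tree", {
  set.seed(33)
  n <- 7
  gen <- ape::rtree(n, rooted = FALSE)
  D <- ape::cophenetic.phylo(gen)
  D2 <- D + matrix(runif(n * n, 0, 0.02), n)
  D2 <- (D2 + t(D2)) / 2
  diag(D2) <- 0
  t1 <- nj_tree(D2)
  perm <- sample(rownames(D2))
  t2 <- nj_tree(D2[perm, perm])
  expect_true(same_topology(t1, t2))
})

test_that("bootstrap gives full support to an unambiguous split", {
  msa <- list(ids = c("A", "B", "C", "D"),
              rows = c(strrep("A", 30), strrep("A", 30),
                       strrep("C", 30), strrep("C", 30)))
  tr <- bootstrap_support(msa, n_reps = 50L, seed = 1L)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(any(sup == 100, na.rm = TRUE))
  # determinism
  tr2 <- bootstrap_support(msa, n_reps = 50L, seed = 1L)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  expect_error(bootstrap_support(msa, n_reps = 0L), "n_reps")
})

test_that("bootstrap recovers well-separated splits on simulated data", {
  # 6 taxa from a tree with a long internal branch
  tr <- ape::read.tree(text = paste0(
    "(((t1:0.05,t2:0.05):0.4,t3:0.1):0.05,((t4:0.05,t5:0.05):0.4,t6:0.1):0.05);"))
  set.seed(7)
  root <- paste(sample(AA20, 400, TRUE), collapse = "")
  ev <- evolve_sequences_on_tree(root, tr, rate = 0.3, seed = 7L)
  msa <- list(ids = names(ev$sequences), rows = unname(ev$sequences))
  bt <- bootstrap_support(msa, n_reps = 200L, seed = 7L)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  # the t1t2 vs t4t5 separation is strongly supported
  expect_true(same_topology(bt, tr))
  expect_gte(min(sup[sup > 0], na.rm = TRUE), 80)
})

test_that("Newick output round-trips topology, lengths and supports", {
  d <- matrix(c(0, 2, 4, 4, 2, 0, 4, 4, 4, 4, 0, 2, 4, 4, 2, 0), 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  tr$node.label <- c("", "97")
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- parse_newick(path)
  expect_true(same_topology(tr, back))
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-6)
  expect_true("97" %in% back$node.label)

  # the documented example tree parses to the expected 4-taxon shape
  p2 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1,(C:1,D:1):2);", p2)
  t2 <- parse_newick(p2)
  expect_equal(sort(t2$tip.label), c("A", "B", "C", "D"))
  expect_equal(tree_splits(t2), "A,B|C,D")

  # malformed input errors
  empty <- withr::local_tempfile(fileext = ".nwk")
  writeLines("", empty)
  expect_error(parse_newick(empty), "empty")
  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1:1);", bad)
  expect_error(parse_newick(bad), "parse error")
})
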