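# Coiled-coil prediction, architecture assembly, grammar classification
# and the kinase-2 subfamily marker.

test_that("coiled-coil prediction behaves at its contract boundaries", {
  # too short for the window
  expect_equal(nrow(predict_coiled_coil(strrep("M", 10))), 0L)
  # parameter validation
  expect_error(predict_coiled_coil("MKVMKVMKV", window = 5), "window")
  # poly-glycine is invisible to the heptad table
  expect_equal(nrow(predict_coiled_coil(strrep("G", 28))), 0L)
})

test_that("an ideal heptad repeat is detected as one confident segment", {
  seg <- predict_coiled_coil(strrep("IQELEEK", 5))  # 35 residues
  expect_equal(nrow(seg), 1L)
  expect_gte(seg$aa_end - seg$aa_start + 1L, 28L)
  expect_gte(seg$probability, 0.8)
  # brute-force window oracle: recompute the best register geometric mean
  # of the first window and its logistic probability
  chars <- strsplit(strrep("IQELEEK", 5), "")[[1]][1:21]
  lp <- log(cc_heptad_propensity)
  best <- max(vapply(0:6, function(ph) {
    mean(lp[cbind(match(chars, AA20), ((seq_len(21) - 1 + ph) %% 7) + 1)])
  }, numeric(1)))
  p_expected <- stats::plogis(25 * (best - 0.48))
  expect_equal(seg$probability, p_expected, tolerance = 1e-9)
})

test_that("uniform-random sequence stays below detection", {
  set.seed(123)
  for (k in 1:5) {
    rp <- paste(sample(AA20, 300, replace = TRUE), collapse = "")
    expect_equal(nrow(predict_coiled_coil(rp)), 0L)
  }
})

test_that("inserting extra ideal repeats never decreases the probability", {
  probs <- vapply(3:8, function(k) {
    s <- predict_coiled_coil(strrep("LQELEEK", k))
    max(s$probability)
  }, numeric(1))
  expect_true(all(diff(probs) >= -1e-12))
})

test_that("architectures assemble tokens in protein order", {
  n_only <- build_architecture("g", domain_hit("g", "NB-ARC", 150, 430))
  expect_equal(n_only$tokens, "N")

  tn <- build_architecture("g", rbind(domain_hit("g", "TIR", 5, 120),
                                      domain_hit("g", "NB-ARC", 150, 430)))
  expect_equal(tn$tokens, c("T", "N"))

  nll <- build_architecture("g", rbind(domain_hit("g", "NB-ARC", 150, 430),
                                       domain_hit("g", "LRR", 500, 560),
                                       domain_hit("g", "LRR", 570, 630)))
  expect_equal(nll$tokens, c("N", "L", "L"))

  cn <- build_architecture("g", domain_hit("g", "NB-ARC", 150, 430),
                           cc = data.frame(aa_start = 10, aa_end = 45,
                                           probability = 0.95))
  expect_equal(cn$tokens, c("C", "N"))

  # a coiled-coil after the NB-ARC does not become a token
  late_cc <- build_architecture("g", domain_hit("g", "NB-ARC", 150, 430),
                                cc = data.frame(aa_start = 500, aa_end = 540,
                                                probability = 0.95))
  expect_equal(late_cc$tokens, "N")

  # overlapping same-type hits merge; genes without NB-ARC are signalled
  merged <- build_architecture("g", rbind(domain_hit("g", "NB-ARC", 150, 430),
                                          domain_hit("g", "NB-ARC", 200, 440)))
  expect_equal(merged$tokens, "N")
  expect_error(build_architecture("g", domain_hit("g", "LRR", 10, 60)),
               class = "nlr_not_nbs")
})

test_that("classification follows the subclass grammar", {
  cls <- function(tokens) {
    classify_architecture(structure(
      list(gene_id = "g", tokens = tokens,
           aa_start = seq_along(tokens)), class = "nlr_architecture"))
  }
  expect_equal(cls(c("T", "N"))[c("class_name", "subfamily")],
               list(class_name = "TN", subfamily = "TNL"))
  expect_equal(cls(c("C", "N", "L"))[c("class_name", "subfamily")],
               list(class_name = "CNL", subfamily = "nTNL"))
  expect_equal(cls(c("R", "N"))[c("class_name", "subfamily")],
               list(class_name = "RN", subfamily = "nTNL"))
  expect_equal(cls(c("N", "L", "N", "L", "N"))$class_name, "NLNLN")
  expect_equal(cls(c("N", "L", "L"))$class_name, "NLL")
  # TIR dominance: the C token is dropped from the name
  expect_equal(cls(c("C", "T", "N"))[c("class_name", "subfamily")],
               list(class_name = "TN", subfamily = "TNL"))
  expect_true(cls(c("C", "T", "N"))$cc_containing)
})

test_that("every token string maps to exactly one class label", {
  # exhaustive enumeration of all N-containing token strings up to length 6
  tokens <- c("C", "T", "N", "L", "R")
  inventory <- c("N", "NL", "NLL", "NLN", "NLNLN", "NN", "CN", "CNL",
                 "CNN", "CNLN", "CNLNLN", "TN", "RN", "OTHER")
  all_names <- character()
  named_ok <- TRUE
  subfamily_ok <- TRUE
  for (len in 1:6) {
    combos <- do.call(expand.grid,
                      c(rep(list(tokens), len), stringsAsFactors = FALSE))
    for (r in seq_len(nrow(combos))) {
      tk <- as.character(combos[r, ])
      if (!"N" %in% tk) next
      lab <- classify_architecture(structure(
        list(gene_id = "g", tokens = tk, aa_start = seq_along(tk)),
        class = "nlr_architecture"))
      named_ok <- named_ok && lab$class_name %in% inventory
      # subfamily consistency: TNL iff a TIR token is present
      subfamily_ok <- subfamily_ok &&
        ((lab$subfamily == "TNL") == ("T" %in% tk))
      all_names <- c(all_names, lab$class_name)
    }
  }
  expect_true(named_ok)
  expect_true(subfamily_ok)
  # the named classes and OTHER all occur across the enumeration
  expect_setequal(unique(all_names),
                  c("N", "NL", "NLL", "NLN", "NLNLN", "NN", "CN", "CNL",
                    "CNN", "CNLN", "CNLNLN", "TN", "RN", "OTHER"))
})

test_that("kinase-2 terminal residue marks the subfamily", {
  expect_equal(kinase2_marker("RYLIVLDDVWSTDAW"), "nTNL")
  expect_equal(kinase2_marker("RWKKVLFILDDVNHRD"), "TNL")
  expect_equal(kinase2_marker("RYLIVLDDVWSTDAA"), "unknown")
  # the TN-class consensus ends in E: reported unknown, not guessed
  expect_equal(kinase2_marker(kinase2_reference[["class-TN"]]), "unknown")
  expect_error(kinase2_marker(""), "non-empty")
})
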