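# PWM construction, scanning, motif-order checking, ZOOPS EM discovery
# and PWM similarity.

test_that("PWMs from printed consensuses have the right shape and mass", {
  motifs <- nbs_motifs()
  expect_equal(vapply(motifs, `[[`, 0L, "width"),
               c("P-loop" = 15L, "RNBS-A" = 21L, "kinase-2" = 15L,
                 "RNBS-B" = 15L, "RNBS-C" = 15L, "GLPL" = 21L))
  for (m in motifs) {
    expect_true(all(abs(rowSums(m$pwm) - 1) < 1e-9))
    expect_true(abs(sum(m$background) - 1) < 1e-9)
  }
  # J at P-loop position 2 splits the match mass over I and L
  pl <- motifs[["P-loop"]]
  expect_equal(unname(pl$pwm[2, "I"]), 0.35)
  expect_equal(unname(pl$pwm[2, "L"]), 0.35)
  # Z in GLPL splits over E and Q
  gl <- motifs[["GLPL"]]
  zpos <- which(strsplit(nbs_motif_consensus[["GLPL"]], "")[[1]] == "Z")
  expect_equal(unname(gl$pwm[zpos, "E"]), 0.35)
  expect_equal(unname(gl$pwm[zpos, "Q"]), 0.35)
})

test_that("consensus recovery and input validation work", {
  m <- pwm_from_consensus("AAAA", match_prob = 0.9)
  expect_equal(m$consensus, "AAAA")
  expect_error(pwm_from_consensus("AB1A"), "position 3")
  expect_error(pwm_from_consensus("AAAA", match_prob = 0.01), "match_prob")
  expect_error(pwm_from_consensus("AAAA", match_prob = 1), "match_prob")
  # X takes the background row
  mx <- pwm_from_consensus("AXA", background = rep(1 / 20, 20))
  expect_true(all(abs(mx$pwm[2, ] - 1 / 20) < 1e-12))
})

test_that("scanning finds a planted consensus at its offset", {
  m <- pwm_from_consensus("GIGKTTLARKVYNDP", name = "P-loop")
  set.seed(1)
  flank <- function(n) paste(sample(AA20, n, TRUE), collapse = "")
  protein <- paste0(flank(30), "GIGKTTLARKVYNDP", flank(40))
  hit <- scan_best_hit(m, protein)
  expect_equal(hit$aa_start, 31L)
  expect_equal(hit$matched, "GIGKTTLARKVYNDP")
  # the consensus achieves the maximum possible score
  max_score <- sum(log2(apply(m$pwm, 1, max) / (1 / 20)))
  expect_equal(hit$score, max_score, tolerance = 1e-9)

  # two identical copies: leftmost wins
  protein2 <- paste0(flank(10), m$consensus, flank(10), m$consensus, flank(5))
  expect_equal(scan_best_hit(m, protein2)$aa_start, 11L)

  # shorter than the motif: NULL with a warning
  expect_warning(res <- scan_best_hit(m, "MKV"), "shorter")
  expect_null(res)
})

test_that("background-only proteins give no or only weak hits", {
  m <- pwm_from_consensus("GIGKTTLARKVYNDP")
  max_score <- sum(log2(apply(m$pwm, 1, max) / (1 / 20)))
  set.seed(77)
  for (k in 1:10) {
    protein <- paste(sample(AA20, 200, TRUE), collapse = "")
    hit <- scan_best_hit(m, protein)
    if (!is.null(hit)) expect_lt(hit$score, 0.25 * max_score)
  }
})

test_that("scanning equals exhaustive window enumeration on short proteins", {
  motifs <- nbs_motifs()
  set.seed(31)
  for (k in 1:12) {
    protein <- paste(sample(c(AA20, "X"), sample(20:60, 1), TRUE),
                     collapse = "")
    m <- motifs[[sample(length(motifs), 1)]]
    if (nchar(protein) < m$width) next
    want <- oracle_scan(m, protein)
    got <- scan_best_hit(m, protein)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$aa_start, want$aa_start)
      expect_equal(got$score, want$score, tolerance = 1e-9)
    }
  }
})

test_that("motif order checking follows the canonical N-to-C order", {
  hits <- data.frame(
    gene_id = "g",
    motif_name = c("P-loop", "RNBS-A", "kinase-2", "RNBS-B", "RNBS-C", "GLPL"),
    aa_start = c(10, 40, 75, 110, 150, 190),
    score = 1, matched = "x", stringsAsFactors = FALSE)
  expect_true(check_motif_order(hits)$ok)

  swapped <- hits[hits$motif_name %in% c("P-loop", "GLPL"), ]
  swapped$aa_start <- c(190, 10)
  res <- check_motif_order(swapped)
  expect_false(res$ok)
  expect_equal(res$violations$first, "P-loop")
  expect_equal(res$violations$second, "GLPL")

  solo <- hits[1, ]
  expect_true(check_motif_order(solo)$ok)
})

test_that("ZOOPS EM recovers a planted motif and its sites", {
  planted <- integer()
  set.seed(42)
  seqs <- vapply(1:20, function(i) {
    bg <- sample(AA20, 100, TRUE)
    inst <- strsplit(nlrsurvey:::sample_motif_instance("P-loop", 0.1), "")[[1]]
    o <- sample.int(86, 1)
    bg[o:(o + 14)] <- inst
    planted[i] <<- o
    paste(bg, collapse = "")
  }, character(1))
  m <- discover_motif_em(seqs, width = 15L, n_starts = 5L, seed = 42L)
  expect_gte(mean(m$offsets == planted, na.rm = TRUE), 0.9)
  # log-likelihood never decreases within a run
  expect_true(all(diff(m$ll_trace) >= -1e-6))
  expect_true(all(abs(rowSums(m$pwm) - 1) < 1e-9))
  # determinism
  m2 <- discover_motif_em(seqs, width = 15L, n_starts = 5L, seed = 42L)
  expect_identical(m$pwm, m2$pwm)
  expect_identical(m$ll, m2$ll)
})

test_that("EM separates planted signal from signal-free sequences", {
  set.seed(9)
  nullseqs <- vapply(1:20, function(i) {
    paste(sample(AA20, 100, TRUE), collapse = "")
  }, character(1))
  m_null <- discover_motif_em(nullseqs, width = 15L, n_starts = 3L, seed = 7L)
  set.seed(10)
  sig <- vapply(1:20, function(i) {
    bg <- sample(AA20, 100, TRUE)
    bg[40:54] <- strsplit("GIGKTTLARKVYNDP", "")[[1]]
    paste(bg, collapse = "")
  }, character(1))
  m_sig <- discover_motif_em(sig, width = 15L, n_starts = 3L, seed = 7L)
  # planted signal saturates the site prior; the null stays clearly lower
  # and its per-sequence likelihood is far smaller
  expect_gte(m_sig$site_prior, 0.9)
  expect_lt(m_null$site_prior, 0.7)
  expect_lt(m_null$ll, 0.5 * m_sig$ll)
  expect_true(all(diff(m_null$ll_trace) >= -1e-6))

  # degenerate case: two sequences sharing only the planted copy
  set.seed(5)
  two <- vapply(1:2, function(i) {
    paste0(paste(sample(AA20, 30, TRUE), collapse = ""),
           "GIGKTTLARKVYNDP",
           paste(sample(AA20, 30, TRUE), collapse = ""))
  }, character(1))
  m_two <- discover_motif_em(two, width = 15L, n_starts = 6L, seed = 3L)
  expect_equal(m_two$consensus, "GIGKTTLARKVYNDP")
  expect_equal(m_two$offsets, c(31L, 31L))

  expect_error(discover_motif_em(c("MKV", "MKW"), width = 15L), "shorter")
})

test_that("PWM similarity is symmetric, bounded and discriminating", {
  motifs <- nbs_motifs()
  a <- motifs[["P-loop"]]
  b <- motifs[["GLPL"]]
  expect_equal(pwm_similarity(a, a), 1)
  expect_equal(pwm_similarity(a, b), pwm_similarity(b, a))
  expect_lte(pwm_similarity(pwm_from_consensus("AAAA", match_prob = 0.95),
                            pwm_from_consensus("CCCC", match_prob = 0.95)),
             0.05)
  set.seed(17)
  for (k in 1:5) {
    ra <- pwm_from_consensus(paste(sample(AA20, 8, TRUE), collapse = ""))
    rb <- pwm_from_consensus(paste(sample(AA20, 12, TRUE), collapse = ""))
    s <- pwm_similarity(ra, rb)
    expect_gte(s, 0)
    expect_lte(s, 1)
    expect_equal(s, pwm_similarity(rb, ra))
  }
})
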