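# Reference constants: the published pepper (Capsicum annuum, Zunla-1)
# NLR survey tallies that anchor the package defaults, the six conserved
# NBS motif consensuses, and the coiled-coil heptad propensity table.

#' The 20 canonical amino-acid letters
#'
#' Alphabetical one-letter codes used for every position weight matrix,
#' propensity table and sequence validation in the package.
#'
#' @format Character vector of length 20.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity codes accepted in motif consensus strings.
AA_AMBIG <- c(J = "IL", Z = "EQ", B = "ND")

#' Reference NLR subclass inventory for the pepper genome
#'
#' Per-subclass gene counts from the published genome-wide survey of
#' NBS-LRR genes in *Capsicum annuum* (Zunla-1). The class names follow the
#' domain-architecture grammar used throughout the package: `N` = NB-ARC
#' only, `L` = LRR, `C` = N-terminal coiled-coil, `T` = TIR. The counts sum
#' to the 252 genes of the survey and are the default class mixture of
#' [simulate_survey()].
#'
#' @format A data frame with 11 rows and 4 columns: `class_id`,
#'   `class_name`, `count`, `subfamily` (`nTNL` or `TNL`).
#' @seealso [classify_architecture()], [simulation_config()]
#' @export
pepper_class_inventory <- data.frame(
  class_id   = 1:11,
  class_name = c("N", "NL", "NLN", "NLL", "NN", "CN",
                 "CNL", "CNN", "CNLN", "CNLNLN", "TN"),
  count      = c(172L, 11L, 7L, 2L, 8L, 37L, 2L, 3L, 5L, 1L, 4L),
  subfamily  = c(rep("nTNL", 10), "TNL"),
  stringsAsFactors = FALSE
)

#' Reference genome-landscape tallies for the pepper NLR survey
#'
#' Headline counts of the published pepper survey: total genes, genes in
#' physical clusters (250-kb rule), tandemly duplicated genes (<150-kb
#' rule), coiled-coil-containing genes and TNL genes. Used for the
#' printed-arithmetic worked examples (54% clustered, 31% tandem, CNL:TNL
#' ratio of 12).
#'
#' @format Named list of integer counts.
#' @export
pepper_survey_landscape <- list(
  total_genes     = 252L,
  clustered_genes = 136L,
  n_clusters      = 47L,
  tandem_genes    = 77L,
  n_tandem_events = 30L,
  cc_containing   = 48L,
  n_tnl           = 4L,
  n_ntnl          = 248L
)

#' Consensus sequences of the six conserved NBS motifs
#'
#' MEME-derived consensus strings for the P-loop, RNBS-A, kinase-2,
#' RNBS-B, RNBS-C and GLPL motifs of the pepper NB-ARC domain, in their
#' canonical N-to-C order. `J` (I/L) and `Z` (E/Q) are standard ambiguity
#' codes handled by [pwm_from_consensus()].
#'
#' @format Named character vector of length 6 (widths 15, 21, 15, 15, 15,
#'   21).
#' @seealso [nbs_motifs()]
#' @export
nbs_motif_consensus <- c(
  "P-loop"   = "GJGKTTLARKVYNDP",
  "RNBS-A"   = "SHFDIRAWVTVSQEYNRRELL",
  "kinase-2" = "RYLIVLDDVWSTDAW",
  "RNBS-B"   = "NGSRIJLTTRNEEVA",
  "RNBS-C"   = "LSEEESWKLLRKKVF",
  "GLPL"     = "CPPELEEIGKZIAKKCGGLPL"
)

# Canonical N->C motif order within one NB-ARC domain.
NBS_MOTIF_ORDER <- names(nbs_motif_consensus)

#' Reference kinase-2 motif instances
#'
#' Kinase-2 consensus strings from the pepper survey: the family-wide
#' MEME consensus (terminal W, the nTNL marker residue) and the per-class
#' consensi of the most abundant nTNL subclass and of the TN (TNL)
#' subclass. Used as fixtures for [kinase2_marker()].
#'
#' @format Named character vector.
#' @export
kinase2_reference <- c(
  "family"  = "RYLIVLDDVWSTDAW",
  "class-N" = "KGPRYLVVVDDIWRID",
  "class-TN" = "RWKKVLFILDDVNHRE"
)

#' Coiled-coil heptad propensity table
#'
#' Per-residue propensities for the seven heptad positions (a-g) used by
#' [predict_coiled_coil()]. Hydrophobic residues (L, I, V, M, A, F) are
#' favoured at the core positions a and d; charged and polar residues at
#' the solvent-exposed positions; helix breakers (G, P) are penalized
#' everywhere. Values are calibrated so that canonical leucine-zipper-like
#' heptad repeats score above the 0.8 detection probability while
#' uniform-random sequence stays well below it.
#'
#' @format A 20 x 7 numeric matrix; rows are [AA20] letters, columns the
#'   heptad positions `a`-`g`.
#' @export
cc_heptad_propensity <- local({
  pos <- c("a", "b", "c", "d", "e", "f", "g")
  m <- matrix(NA_real_, nrow = 20, ncol = 7, dimnames = list(AA20, pos))
  set_row <- function(aa, a, d, other) {
    m[aa, ] <<- other
    m[aa, "a"] <<- a
    m[aa, "d"] <<- d
  }
  set_row("L", 3.2, 3.0, 0.9)
  set_row("I", 3.0, 2.4, 0.8)
  set_row("V", 2.2, 1.8, 0.8)
  set_row("M", 2.0, 1.9, 0.9)
  set_row("F", 1.6, 1.4, 0.7)
  set_row("A", 1.6, 1.5, 1.1)
  m["E", ] <- c(0.5, 1.5, 1.5, 0.4, 1.8, 1.4, 1.7)
  m["K", ] <- c(0.5, 1.4, 1.3, 0.4, 1.6, 1.4, 1.7)
  m["Q", ] <- c(0.6, 1.5, 1.4, 0.5, 1.5, 1.3, 1.4)
  m["R", ] <- c(0.5, 1.3, 1.2, 0.4, 1.5, 1.3, 1.5)
  m["N", ] <- c(0.5, 1.2, 1.2, 0.4, 1.2, 1.2, 1.2)
  m["D", ] <- c(0.4, 1.2, 1.2, 0.35, 1.2, 1.2, 1.2)
  set_row("S", 0.6, 0.6, 1.0)
  set_row("T", 0.7, 0.6, 1.0)
  set_row("H", 0.6, 0.5, 1.0)
  set_row("Y", 1.0, 0.9, 0.8)
  set_row("W", 0.9, 0.8, 0.6)
  set_row("C", 1.0, 0.9, 0.7)
  m["G", ] <- 0.2
  m["P", ] <- 0.05
  m
})

# Logistic calibration mapping the best log-mean heptad propensity of the
# windows covering a residue to a detection probability. Midpoint and slope
# are fixed package constants (see the methods vignette).
CC_LOGISTIC_MID   <- 0.48
CC_LOGISTIC_SLOPE <- 25
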