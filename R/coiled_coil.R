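# Heptad-register coiled-coil prediction. A sliding window is scored by
# the best of the seven possible heptad registers, each register scoring
# the geometric mean of per-residue, per-heptad-position propensities
# (cc_heptad_propensity). The best window score covering each residue is
# mapped to a probability by a fixed logistic calibration, and maximal
# runs of residues at or above the detection threshold are reported as
# segments.

#' Predict coiled-coil segments in a protein
#'
#' Scans the protein with a sliding window; each window is scored under
#' all seven heptad registers against [cc_heptad_propensity] and the best
#' register's geometric-mean propensity is kept. The per-residue
#' probability is a logistic transform of the best score among windows
#' covering that residue; residues with probability at or above
#' `threshold` are merged into maximal segments.
#'
#' @param protein amino-acid string (canonical letters plus `X`).
#' @param window sliding-window width in residues; must be at least 7
#'   (one full heptad). Default 21 (three heptads), the conventional
#'   window of coiled-coil scanners.
#' @param threshold detection probability in (0, 1); default 0.8.
#' @return Data frame with columns `aa_start`, `aa_end`, `probability`
#'   (the maximum per-residue probability inside the segment). Zero rows
#'   when nothing is detected or the protein is shorter than `window`.
#' @examples
#' predict_coiled_coil(strrep("LQELEEK", 6))
#' predict_coiled_coil(strrep("G", 40))
#' @export
predict_coiled_coil <- function(protein, window = 21L, threshold = 0.8) {
  assert_protein(protein)
  if (window < 7L) stop("window must be >= 7 residues", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)", call. = FALSE)
  }
  empty <- data.frame(aa_start = integer(), aa_end = integer(),
                      probability = numeric())
  len <- nchar(protein)
  if (len < window) return(empty)

  prob <- cc_residue_probability(protein, window)
  hit <- prob >= threshold
  if (!any(hit)) return(empty)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    aa_start = starts[keep],
    aa_end = ends[keep],
    probability = vapply(which(keep), function(k) {
      max(prob[starts[k]:ends[k]])
    }, numeric(1))
  )
}

# Per-residue coiled-coil probability: logistic transform of the best
# log-mean propensity among the windows covering each residue.
cc_residue_probability <- function(protein, window = 21L) {
  codes <- encode_aa(protein)
  len <- length(codes)
  lp <- log(cc_heptad_propensity)
  # residues outside the table (X) score neutrally low
  x_row <- log(0.55)

  # For each of the 7 global heptad phases, per-residue log propensity.
  n_win <- len - window + 1L
  win_best <- rep(-Inf, n_win)
  for (phase in 0:6) {
    hpos <- ((seq_len(len) - 1L + phase) %% 7L) + 1L
    v <- ifelse(is.na(codes), x_row, lp[cbind(codes, hpos)])
    cs <- c(0, cumsum(v))
    wm <- (cs[(window + 1L):(len + 1L)] - cs[seq_len(n_win)]) / window
    win_best <- pmax(win_best, wm)
  }

  # best covering-window score per residue
  best <- rep(-Inf, len)
  for (s in seq_len(n_win)) {
    idx <- s:(s + window - 1L)
    best[idx] <- pmax(best[idx], win_best[s])
  }
  stats::plogis(CC_LOGISTIC_SLOPE * (best - CC_LOGISTIC_MID))
}
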