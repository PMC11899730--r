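# Position-weight-matrix machinery for the six conserved NBS motifs:
# building PWMs from printed consensus strings (with J/Z/B/X ambiguity
# codes), log-odds scanning, canonical-order checking, de novo ZOOPS EM
# discovery and a defined PWM-PWM similarity.

#' Build a position weight matrix from a consensus string
#'
#' Each unambiguous position puts `match_prob` on the consensus letter and
#' spreads the remainder evenly over the other 19 letters. Ambiguity
#' codes split `match_prob` equally over their two letters (`J` = I/L,
#' `Z` = E/Q, `B` = N/D, the remainder over the other 18); the wildcard
#' `X` takes the background row.
#'
#' @param consensus consensus string over the 20 amino acids plus
#'   J/Z/B/X.
#' @param match_prob probability mass on the consensus letter(s); must lie
#'   in (0.05, 1).
#' @param name motif name carried in the model.
#' @param background length-20 background probability vector (default
#'   uniform).
#' @return An object of class `motif_model`: list with `name`, `width`,
#'   `pwm` (width x 20, rows sum to 1), `background`, `consensus` (argmax
#'   string) and `source_consensus` (the input string).
#' @examples
#' m <- pwm_from_consensus(nbs_motif_consensus[["P-loop"]], name = "P-loop")
#' m$width
#' @export
pwm_from_consensus <- function(consensus, match_prob = 0.7,
                               name = "motif",
                               background = rep(1 / 20, 20)) {
  if (!is.character(consensus) || length(consensus) != 1L ||
      nchar(consensus) < 1L) {
    stop("consensus must be a non-empty string", call. = FALSE)
  }
  if (match_prob <= 0.05 || match_prob >= 1) {
    stop("match_prob must lie in (0.05, 1)", call. = FALSE)
  }
  stopifnot(length(background) == 20, abs(sum(background) - 1) < 1e-9)
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  w <- length(chars)
  pwm <- matrix(0, nrow = w, ncol = 20, dimnames = list(NULL, AA20))
  for (i in seq_len(w)) {
    ch <- chars[i]
    if (ch %in% AA20) {
      pwm[i, ] <- (1 - match_prob) / 19
      pwm[i, ch] <- match_prob
    } else if (ch %in% names(AA_AMBIG)) {
      pair <- strsplit(AA_AMBIG[[ch]], "")[[1]]
      pwm[i, ] <- (1 - match_prob) / 18
      pwm[i, pair] <- match_prob / 2
    } else if (ch == "X") {
      pwm[i, ] <- background
    } else {
      stop(sprintf("illegal consensus character '%s' at position %d", ch, i),
           call. = FALSE)
    }
  }
  new_motif_model(name, pwm, background, source_consensus = consensus)
}

new_motif_model <- function(name, pwm, background,
                            source_consensus = NULL, extra = list()) {
  stopifnot(ncol(pwm) == 20,
            all(abs(rowSums(pwm) - 1) < 1e-9),
            abs(sum(background) - 1) < 1e-9)
  colnames(pwm) <- AA20
  obj <- c(list(name = name, width = nrow(pwm), pwm = pwm,
                background = stats::setNames(background, AA20),
                consensus = paste(AA20[max.col(pwm, ties.method = "first")],
                                  collapse = ""),
                source_consensus = source_consensus),
           extra)
  structure(obj, class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model '%s': width %d, consensus %s\n",
              x$name, x$width, x$consensus))
  invisible(x)
}

#' The six conserved NBS motif models
#'
#' PWMs built from the published consensus strings of the P-loop, RNBS-A,
#' kinase-2, RNBS-B, RNBS-C and GLPL motifs ([nbs_motif_consensus]), in
#' canonical N-to-C order.
#'
#' @param match_prob probability on the consensus letter (see
#'   [pwm_from_consensus()]).
#' @param background length-20 background vector.
#' @return Named list of six `motif_model` objects.
#' @export
nbs_motifs <- function(match_prob = 0.7, background = rep(1 / 20, 20)) {
  stats::setNames(
    lapply(NBS_MOTIF_ORDER, function(nm) {
      pwm_from_consensus(nbs_motif_consensus[[nm]], match_prob = match_prob,
                         name = nm, background = background)
    }),
    NBS_MOTIF_ORDER)
}

# width x 20 log2-odds matrix; proteins letters outside AA20 (X) score 0.
motif_logodds <- function(motif) {
  log2(sweep(motif$pwm, 2, motif$background, "/"))
}

#' Scan a protein for the best motif hit
#'
#' Scores every window of the motif's width with the summed log2-odds of
#' PWM over background and returns the best-scoring window (ties broken
#' toward the smallest start). Windows containing `X` score those
#' positions neutrally (0 bits).
#'
#' @param motif a `motif_model`.
#' @param protein amino-acid string.
#' @param gene_id optional identifier carried into the hit.
#' @return One-row data frame (`gene_id`, `motif_name`, `aa_start`,
#'   `score`, `matched`) or `NULL` when the protein is shorter than the
#'   motif (with a warning) or the best score is negative.
#' @export
scan_best_hit <- function(motif, protein, gene_id = NA_character_) {
  assert_protein(protein)
  w <- motif$width
  len <- nchar(protein)
  if (len < w) {
    warning(sprintf("protein shorter than motif '%s' (%d < %d)",
                    motif$name, len, w))
    return(NULL)
  }
  codes <- encode_aa(protein)
  lo <- motif_logodds(motif)
  n_win <- len - w + 1L
  # scores[o] = sum_i lo[i, codes[o + i - 1]]
  scores <- numeric(n_win)
  for (i in seq_len(w)) {
    v <- lo[i, ][codes[i:(i + n_win - 1L)]]
    v[is.na(v)] <- 0
    scores <- scores + v
  }
  best <- max(scores)
  if (best < 0) return(NULL)
  o <- which(scores == best)[1L]
  data.frame(gene_id = gene_id, motif_name = motif$name,
             aa_start = o, score = best,
             matched = substr(protein, o, o + w - 1L),
             stringsAsFactors = FALSE)
}

#' Scan a protein with all six NBS motifs
#'
#' @param protein amino-acid string.
#' @param motifs named list of `motif_model`s (default [nbs_motifs()]).
#' @param gene_id optional identifier.
#' @return Data frame of best hits (motifs without a non-negative-scoring
#'   window are absent).
#' @export
scan_motifs <- function(protein, motifs = nbs_motifs(),
                        gene_id = NA_character_) {
  out <- lapply(motifs, function(m) {
    if (nchar(protein) < m$width) return(NULL)
    scan_best_hit(m, protein, gene_id = gene_id)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(), motif_name = character(),
                      aa_start = integer(), score = numeric(),
                      matched = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Check the canonical N-to-C motif order
#'
#' True when the start coordinates of the motifs present follow the
#' canonical NBS order (P-loop, RNBS-A, kinase-2, RNBS-B, RNBS-C, GLPL)
#' strictly increasingly; missing motifs are skipped (a single motif is
#' vacuously ordered).
#'
#' @param hits motif-hit data frame for one gene ([scan_motifs()]).
#' @return List with `ok` (logical) and `violations` (data frame of
#'   offending motif pairs).
#' @export
check_motif_order <- function(hits) {
  present <- NBS_MOTIF_ORDER[NBS_MOTIF_ORDER %in% hits$motif_name]
  starts <- hits$aa_start[match(present, hits$motif_name)]
  viol <- list()
  if (length(present) >= 2L) {
    for (i in seq_len(length(present) - 1L)) {
      if (starts[i + 1L] <= starts[i]) {
        viol[[length(viol) + 1L]] <- data.frame(
          first = present[i], second = present[i + 1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(first = character(), second = character(),
               stringsAsFactors = FALSE)
  list(ok = nrow(violations) == 0L, violations = violations)
}

#' Discover a motif de novo by ZOOPS expectation maximization
#'
#' MEME-style EM under the ZOOPS model (zero or one motif occurrence per
#' sequence; OOPS forces exactly one). The E-step computes each
#' sequence's posterior over "no site" and every offset; the M-step
#' re-estimates the PWM (pseudocount 0.01) and the site prior.
#' Initialization seeds the PWM from `n_starts` randomly chosen data
#' substrings; the run with the best final log-likelihood wins. Fully
#' deterministic given `seed`.
#'
#' @param proteins character vector of sequences (at least two of length
#'   `width` or more).
#' @param width motif width (>= 4).
#' @param mode `"zoops"` (default) or `"oops"`.
#' @param n_starts number of seeded restarts.
#' @param seed integer RNG seed.
#' @param max_iter,tol convergence controls: stop when the relative
#'   log-likelihood change drops below `tol` or after `max_iter`
#'   iterations.
#' @param background length-20 background vector.
#' @return A `motif_model` with extra elements `site_prior`, `ll` (final
#'   log-likelihood), `ll_trace` (per-iteration log-likelihoods of the
#'   winning run, non-decreasing), `offsets` (per-sequence best-posterior
#'   offset, `NA` for "no site").
#' @export
discover_motif_em <- function(proteins, width, mode = c("zoops", "oops"),
                              n_starts = 5L, seed = 1L, max_iter = 500L,
                              tol = 1e-6, background = rep(1 / 20, 20)) {
  mode <- match.arg(mode)
  if (width < 4L) stop("width must be >= 4", call. = FALSE)
  usable <- nchar(proteins) >= width
  if (!any(usable)) stop("all sequences shorter than width", call. = FALSE)
  if (sum(usable) < 2L) stop("need at least 2 sequences of length >= width",
                             call. = FALSE)
  seqs <- lapply(proteins[usable], encode_aa)
  lens <- lengths(seqs)
  log_bg <- log(background)

  run_em <- function(init_pwm) {
    pwm <- init_pwm
    # conservative site-prior initialization: on signal-free data the
    # likelihood is nearly flat in lambda, so lambda stays near its start;
    # genuine planted signal drives it toward 1 regardless
    lambda <- 0.1
    ll_trace <- numeric()
    prev_ll <- -Inf
    zs <- vector("list", length(seqs))
    for (iter in seq_len(max_iter)) {
      lpwm <- log(pwm)
      ll <- 0
      counts <- matrix(0.01, nrow = width, ncol = 20)  # pseudocount
      lam_num <- 0
      for (s in seq_along(seqs)) {
        x <- seqs[[s]]
        m <- lens[s] - width + 1L
        # log ratio of motif vs background for each offset
        r <- numeric(m)
        for (i in seq_len(width)) {
          xi <- x[i:(i + m - 1L)]
          v <- lpwm[i, xi] - log_bg[xi]
          v[is.na(v)] <- 0
          r <- r + v
        }
        if (mode == "zoops") {
          lp <- c(log1p(-lambda), log(lambda / m) + r)
        } else {
          lp <- log(1 / m) + r
        }
        mx <- max(lp)
        lse <- mx + log(sum(exp(lp - mx)))
        ll <- ll + lse  # background term is constant; omitted throughout
        z <- exp(lp - lse)
        if (mode == "zoops") {
          z_off <- z[-1L]
        } else {
          z_off <- z
        }
        zs[[s]] <- z_off
        lam_num <- lam_num + sum(z_off)
        for (i in seq_len(width)) {
          xi <- x[i:(i + m - 1L)]
          ok <- !is.na(xi)
          if (any(ok)) {
            counts[i, ] <- counts[i, ] +
              tabulate_weighted(xi[ok], z_off[ok])
          }
        }
      }
      ll_trace <- c(ll_trace, ll)
      pwm <- counts / rowSums(counts)
      if (mode == "zoops") {
        lambda <- min(max(lam_num / length(seqs), 1e-4), 1 - 1e-4)
      }
      if (is.finite(prev_ll) &&
          abs(ll - prev_ll) < tol * (abs(prev_ll) + 1e-12)) break
      prev_ll <- ll
    }
    offsets <- vapply(seq_along(seqs), function(s) {
      z_off <- zs[[s]]
      z_none <- if (mode == "zoops") 1 - sum(z_off) else 0
      if (z_none >= max(z_off)) NA_integer_ else which.max(z_off)
    }, integer(1))
    list(pwm = pwm, lambda = if (mode == "zoops") lambda else 1,
         ll = ll_trace[length(ll_trace)], ll_trace = ll_trace,
         offsets = offsets)
  }

  init_from_substring <- function(sub) {
    init <- matrix((1 - 0.5) / 19, nrow = width, ncol = 20)
    for (i in seq_len(width)) {
      if (!is.na(sub[i])) init[i, sub[i]] <- 0.5
      init[i, ] <- init[i, ] / sum(init[i, ])
    }
    init
  }
  init_from_offsets <- function(offsets) {
    counts <- matrix(0.5, nrow = width, ncol = 20)
    for (s in seq_along(seqs)) {
      o <- offsets[s]
      if (is.na(o) || o < 1L || o > lens[s] - width + 1L) next
      sub <- seqs[[s]][o:(o + width - 1L)]
      for (i in seq_len(width)) {
        if (!is.na(sub[i])) counts[i, sub[i]] <- counts[i, sub[i]] + 1
      }
    }
    counts / rowSums(counts)
  }

  set.seed(seed)
  best <- NULL
  for (st in seq_len(n_starts)) {
    s <- sample.int(length(seqs), 1L)
    o <- sample.int(lens[s] - width + 1L, 1L)
    res <- run_em(init_from_substring(seqs[[s]][o:(o + width - 1L)]))
    if (is.null(best) || res$ll > best$ll) best <- res
  }

  # phase-shift refinement: EM often converges to a column-shifted copy
  # of the true motif; restarting from the current site alignment shifted
  # left/right and keeping the best likelihood resolves the phase
  shifts <- setdiff(-(width %/% 2):(width %/% 2), 0L)
  repeat {
    improved <- FALSE
    for (sh in shifts) {
      if (all(is.na(best$offsets))) break
      res <- run_em(init_from_offsets(best$offsets + sh))
      if (res$ll > best$ll + 1e-9) {
        best <- res
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }

  full_offsets <- rep(NA_integer_, length(proteins))
  full_offsets[usable] <- best$offsets
  new_motif_model(
    name = sprintf("discovered-%d", width),
    pwm = best$pwm, background = background,
    extra = list(site_prior = best$lambda, ll = best$ll,
                 ll_trace = best$ll_trace, offsets = full_offsets))
}

# weighted tabulate over the 20-letter alphabet
tabulate_weighted <- function(codes, w) {
  out <- numeric(20)
  agg <- rowsum(w, codes)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Similarity between two position weight matrices
#'
#' The package's defined PWM-PWM similarity: over all relative offsets
#' with at least `min_overlap` aligned columns, the mean per-column
#' Pearson correlation of probability rows (negative correlations floored
#' at zero), maximized over offsets. Symmetric, in \[0, 1\], and 1 for a
#' motif against itself.
#'
#' @param a,b `motif_model` objects.
#' @param min_overlap minimum aligned columns (default 4).
#' @return Similarity in \[0, 1\].
#' @export
pwm_similarity <- function(a, b, min_overlap = 4L) {
  wa <- a$width
  wb <- b$width
  min_overlap <- min(min_overlap, wa, wb)
  best <- 0
  for (off in -(wb - min_overlap):(wa - min_overlap)) {
    ia <- max(1L, 1L + off):min(wa, wb + off)
    ib <- ia - off
    if (length(ia) < min_overlap) next
    cors <- vapply(seq_along(ia), function(k) {
      r <- suppressWarnings(stats::cor(a$pwm[ia[k], ], b$pwm[ib[k], ]))
      if (is.na(r)) 0 else max(0, r)
    }, numeric(1))
    best <- max(best, mean(cors))
  }
  best
}
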