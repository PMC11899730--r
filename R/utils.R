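# Internal helpers shared across modules.

.pkg_cache <- new.env(parent = emptyenv())

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published gene-family surveys round
#' half up (53.97 -> 54, 69.35 -> 69.4), so summary percentages use this.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage at the survey's printed precision
#'
#' @param k numerator count.
#' @param n denominator count.
#' @param digits decimal places (0 for headline percentages, 1 for
#'   per-class fractions).
#' @return `100 * k / n` rounded half-up; 0 when `n == 0`.
#' @export
pct <- function(k, n, digits = 1) {
  if (n == 0) return(0)
  round_half_up(100 * k / n, digits)
}

# Integer-encode an amino-acid string against AA20; letters outside the
# alphabet (e.g. X) become NA and score neutrally downstream.
encode_aa <- function(protein) {
  match(strsplit(protein, "", fixed = TRUE)[[1]], AA20)
}

assert_protein <- function(protein, what = "protein") {
  if (!is.character(protein) || length(protein) != 1L || is.na(protein) ||
      nchar(protein) < 1L) {
    stop(sprintf("%s must be a single non-empty string", what), call. = FALSE)
  }
  bad <- gsub("[ACDEFGHIKLMNPQRSTVWYX]", "", protein)
  if (nchar(bad) > 0L) {
    stop(sprintf("%s contains non-amino-acid characters: %s", what,
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(protein)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# BLOSUM62 restricted to the 20 canonical letters plus a neutral X row/col.
blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[c(AA20, "X"), c(AA20, "X")]
    m["X", ] <- 0
    m[, "X"] <- 0
    .pkg_cache$blosum62 <- m
  }
  .pkg_cache$blosum62
}
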