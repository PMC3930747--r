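#' Amino-acid alphabet and background composition
#'
#' `aa_alphabet()` returns the 20 standard one-letter amino-acid codes in
#' alphabetical order. `aa_background()` returns a default background
#' amino-acid composition (a normalised Swiss-Prot-style database
#' frequency table) used by the conservation and coupling statistics.
#' Both are plain named vectors so a different background can be supplied
#' wherever these defaults are accepted.
#'
#' @return `aa_alphabet()`: character vector of length 20.
#'   `aa_background()`: named numeric vector of length 20 summing to 1.
#' @examples
#' aa_alphabet()
#' sum(aa_background())
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @export
aa_background <- function() {
  ## database amino-acid composition (percent), normalised below
  q <- c(
    A = 8.26, C = 1.37, D = 5.46, E = 6.74, F = 3.86,
    G = 7.08, H = 2.27, I = 5.93, K = 5.82, L = 9.65,
    M = 2.41, N = 4.06, P = 4.72, Q = 3.93, R = 5.53,
    S = 6.61, T = 5.35, V = 6.87, W = 1.09, Y = 2.92
  )
  q <- q[aa_alphabet()]
  q / sum(q)
}

## gap and gap-like symbols after normalisation
.gap_symbol <- "-"

## symbols treated as gaps in the 20-state frequency model
## (ambiguity codes B, Z, J, X and non-residue characters)
.normalise_aa <- function(mat) {
  mat <- toupper(mat)
  mat[mat == "."] <- .gap_symbol
  bad <- !(mat %in% c(aa_alphabet(), .gap_symbol))
  n_bad <- sum(bad)
  mat[bad] <- .gap_symbol
  attr(mat, "n_normalised") <- n_bad
  mat
}
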