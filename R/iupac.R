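# Internal integer encoding of per-site IUPAC state-sets.
#
# 1..14 : bitmask over bases (A = 1, C = 2, G = 4, T = 8); two or more bits
#         set marks an intra-individual site polymorphism (2ISP).
# 15    : missing data ('N' or '?'), treated as all four bases but never
#         counted as a 2ISP nor compared in distances.
# 0     : alignment gap ('-').
# < 0   : opaque indel-2ISP code (a gap-plus-base superposition, for which
#         no IUPAC symbol exists); digits '0'-'9' in the input map to codes
#         -1 .. -10.

.BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.IUPAC_CODE <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L,
  N = 15L, `?` = 15L, `-` = 0L
)

# canonical symbol for each bitmask 0..15 (index = code + 1)
.CODE_SYMBOL <- c("-", "A", "C", "M", "G", "R", "S", "V",
                  "T", "W", "Y", "H", "K", "D", "B", "N")

.code_bases <- function(code) {
  names(.BASE_BITS)[bitwAnd(code, .BASE_BITS) > 0L]
}

.is_2isp_code <- function(code) {
  code >= 1L & code <= 14L & .POPCOUNT[code + 1L] >= 2L
}

.POPCOUNT <- c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L, 1L, 2L, 2L, 3L, 2L, 3L, 3L, 4L)

#' Expand an alignment symbol into its state-set
#'
#' Maps one alignment character onto the set of nucleotide states it
#' represents. Extended IUPAC symbols with two or more bases are
#' intra-individual site polymorphisms (2ISPs): superimposed bases observed
#' in a direct-PCR trace, not uncertainty. `N` and `?` are missing data,
#' `-` is a gap, and digits are opaque codes for gap-plus-base
#' superpositions (indel 2ISPs), for which no IUPAC symbol exists.
#'
#' @param symbol a single character: an IUPAC nucleotide code (case
#'   insensitive, `U` maps to `T`), `-`, `?`, or a digit.
#' @return an object of class `state_set`: a list with elements `bases`
#'   (subset of A,C,G,T), `kind` (one of `"standard"`, `"gap"`, `"missing"`,
#'   `"indel2isp"`) and `code` (the internal integer code).
#' @examples
#' expand_iupac("Y")  # {C, T}, a 2ISP
#' expand_iupac("N")  # missing
#' @export
expand_iupac <- function(symbol) {
  stopifnot(is.character(symbol), length(symbol) == 1L, nchar(symbol) == 1L)
  code <- .encode_symbol(symbol)
  .state_set(code)
}

.encode_symbol <- function(symbol) {
  s <- toupper(symbol)
  if (s %in% names(.IUPAC_CODE)) return(unname(.IUPAC_CODE[s]))
  if (grepl("^[0-9]$", s)) return(-(as.integer(s) + 1L))
  stop("unknown alignment symbol: '", symbol, "'", call. = FALSE)
}

.state_set <- function(code) {
  if (code < 0L) {
    out <- list(bases = character(0), kind = "indel2isp", code = code)
  } else if (code == 0L) {
    out <- list(bases = character(0), kind = "gap", code = 0L)
  } else if (code == 15L) {
    out <- list(bases = c("A", "C", "G", "T"), kind = "missing", code = 15L)
  } else {
    out <- list(bases = .code_bases(code), kind = "standard", code = code)
  }
  class(out) <- "state_set"
  out
}

#' @export
print.state_set <- function(x, ...) {
  b <- if (length(x$bases)) paste(x$bases, collapse = ",") else "-"
  cat(sprintf("<state_set %s {%s}>\n", x$kind, b))
  invisible(x)
}

#' Collapse a state-set back to its canonical symbol
#'
#' Inverse of [expand_iupac()] for standard, gap and missing states
#' (missing always renders as `N`); indel-2ISP codes render as the digit
#' they were read from.
#'
#' @param code internal integer state code, vectorised.
#' @return character vector of alignment symbols.
#' @export
iupac_symbol <- function(code) {
  vapply(code, function(cd) {
    if (cd < 0L) as.character(-cd - 1L) else .CODE_SYMBOL[cd + 1L]
  }, character(1))
}
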