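#' Construct a 2ISP-aware alignment from character sequences
#'
#' Low-level constructor used by [read_alignment()] and the simulator.
#' Sequences are encoded site-by-site into integer state-set codes; see
#' [expand_iupac()] for the symbol grammar.
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @param locus locus label.
#' @return an object of class `twoisp_alignment`: a list with `locus`,
#'   `ids`, `states` (integer matrix, samples x sites), `indels` (binary
#'   indel character matrix, populated by [code_indels()]), `site_use`
#'   (logical; `FALSE` for columns absorbed into coded indel characters)
#'   and `length` (alignment length in bp).
#' @export
twoisp_alignment <- function(seqs, locus = "locus") {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop("alignment-shape error: sequences have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")", call. = FALSE)
  L <- lens[[1]]
  chars <- matrix(toupper(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)),
                  nrow = length(seqs), ncol = L, byrow = TRUE)
  lookup <- .symbol_lookup()
  states <- matrix(lookup[chars], nrow = nrow(chars), ncol = L)
  if (anyNA(states)) {
    bad <- which(is.na(states), arr.ind = TRUE)[1, ]
    stop("parse error: invalid symbol '", chars[bad[1], bad[2]],
         "' in sequence '", names(seqs)[bad[1]], "' at column ", bad[2],
         call. = FALSE)
  }
  rownames(states) <- names(seqs)
  structure(
    list(locus = locus, ids = names(seqs), states = states,
         indels = matrix(NA_integer_, nrow = length(seqs), ncol = 0,
                         dimnames = list(names(seqs), NULL)),
         site_use = rep(TRUE, L), length = L),
    class = "twoisp_alignment")
}

# full symbol -> code table, including digits for indel-2ISP codes
.symbol_lookup <- function() {
  syms <- c(names(.IUPAC_CODE), as.character(0:9))
  codes <- c(unname(.IUPAC_CODE), -(1:10))
  setNames(codes, syms)
}

#' Read a multi-FASTA alignment
#'
#' Reads an aligned multi-FASTA file into a [twoisp_alignment()]. Symbols
#' are case-insensitive; `U` maps to `T`; `N`/`?` are missing; `-` is a
#' gap; digits are opaque indel-2ISP codes.
#'
#' @param path path to a FASTA file of equal-length sequences.
#' @param locus locus label stored on the alignment.
#' @return a `twoisp_alignment`.
#' @export
read_alignment <- function(path, locus = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  twoisp_alignment(seqs, locus = locus)
}

#' Write an alignment back to multi-FASTA
#'
#' Renders each state-set to its canonical symbol (missing always as `N`),
#' so `read_alignment(write_alignment(a))` reproduces identical state-sets
#' at every site.
#'
#' @param a a `twoisp_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(a, path) {
  seqs <- apply(a$states, 1, function(row) paste(iupac_symbol(row), collapse = ""))
  ss <- Biostrings::BStringSet(setNames(seqs, a$ids))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @export
print.twoisp_alignment <- function(x, ...) {
  cat(sprintf("<twoisp_alignment '%s': %d sequences x %d bp, %d indel characters>\n",
              x$locus, length(x$ids), x$length, ncol(x$indels)))
  invisible(x)
}

#' Per-site 2ISP and segregation summary
#'
#' Tabulates, for every alignment column, the number of sequences carrying
#' a 2ISP (two or more superimposed bases, or an indel-2ISP code), the
#' number of distinct non-missing, non-gap state-sets, and whether the
#' column is segregating; plus a per-sequence 2ISP tally.
#'
#' @param a a `twoisp_alignment`.
#' @return list with `sites` (data frame: site, n_2isp, n_states,
#'   is_segregating) and `per_sequence` (data frame: id, n_2isp).
#' @export
twoisp_site_summary <- function(a) {
  st <- a$states
  if (length(st) == 0L) stop("empty alignment", call. = FALSE)
  is2 <- (st >= 1L & st <= 14L & matrix(.POPCOUNT[pmax(st, 0L) + 1L] >= 2L,
                                        nrow(st), ncol(st)) ) | st < 0L
  n_2isp <- colSums(is2)
  n_states <- apply(st, 2, function(col) length(unique(col[col != 0L & col != 15L])))
  sites <- data.frame(site = seq_len(a$length), n_2isp = n_2isp,
                      n_states = n_states, is_segregating = n_states >= 2L)
  per_seq <- data.frame(id = a$ids, n_2isp = rowSums(is2))
  list(sites = sites, per_sequence = per_seq)
}

#' Code alignment gaps as binary indel characters
#'
#' Applies simple indel coding: every maximal gap run with identical start
#' and end positions across the sequences sharing it becomes one binary
#' character (1 = gap present, 0 = no overlapping gap, NA = the region sits
#' inside a longer gap). Runs immediately flanked, in any gapless sequence,
#' by a mononucleotide repeat of `homopolymer_min` or more identical bases
#' are not coded (homopolymer slippage is not treated as informative).
#' Columns inside coded runs are removed from site-wise distance
#' computation (`site_use` set to `FALSE`). Idempotent.
#'
#' @param a a `twoisp_alignment`.
#' @param homopolymer_min minimum flanking mononucleotide run length that
#'   disqualifies a gap run from coding.
#' @return the alignment with `indels` populated and `site_use` updated.
#' @export
code_indels <- function(a, homopolymer_min = 4L) {
  st <- a$states
  n <- nrow(st); L <- ncol(st)
  runs_by_seq <- lapply(seq_len(n), function(i) .gap_runs(st[i, ]))
  all_runs <- unique(do.call(rbind, runs_by_seq))
  if (is.null(all_runs) || nrow(all_runs) == 0L) {
    a$indels <- matrix(NA_integer_, n, 0, dimnames = list(a$ids, NULL))
    a$site_use <- rep(TRUE, L)
    return(a)
  }
  all_runs <- all_runs[order(all_runs[, 1], all_runs[, 2]), , drop = FALSE]
  keep <- !apply(all_runs, 1, function(r)
    .homopolymer_flanked(st, r[1], r[2], homopolymer_min))
  coded <- all_runs[keep, , drop = FALSE]
  m <- nrow(coded)
  ind <- matrix(NA_integer_, n, m,
                dimnames = list(a$ids, if (m) sprintf("indel_%d_%d", coded[, 1], coded[, 2])))
  site_use <- rep(TRUE, L)
  for (k in seq_len(m)) {
    s <- coded[k, 1]; e <- coded[k, 2]
    site_use[s:e] <- FALSE
    for (i in seq_len(n)) {
      ri <- runs_by_seq[[i]]
      if (nrow(ri) == 0L) { ind[i, k] <- 0L; next }
      exact <- any(ri[, 1] == s & ri[, 2] == e)
      overlap <- any(ri[, 1] <= e & ri[, 2] >= s)
      ind[i, k] <- if (exact) 1L else if (overlap) NA_integer_ else 0L
    }
  }
  a$indels <- ind
  a$site_use <- site_use
  a
}

# maximal runs of gap code (0) in one encoded sequence
.gap_runs <- function(row) {
  r <- rle(row == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# TRUE if, in any sequence gapless across [s, e], the run is immediately
# flanked by a mononucleotide repeat of >= hp_min identical single bases
.homopolymer_flanked <- function(st, s, e, hp_min) {
  singleton <- function(code) code %in% c(1L, 2L, 4L, 8L)
  for (i in seq_len(nrow(st))) {
    if (any(st[i, s:e] == 0L)) next
    for (side in c("left", "right")) {
      pos <- if (side == "left") s - 1L else e + 1L
      step <- if (side == "left") -1L else 1L
      if (pos < 1L || pos > ncol(st)) next
      anchor <- st[i, pos]
      if (!singleton(anchor)) next
      len <- 0L
      while (pos >= 1L && pos <= ncol(st) && st[i, pos] == anchor) {
        len <- len + 1L
        pos <- pos + step
      }
      if (len >= hp_min) return(TRUE)
    }
  }
  FALSE
}
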