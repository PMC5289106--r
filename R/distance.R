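#' Site-wise distance between two state-sets
#'
#' The per-site kernel of the polymorphism p-distance. For two standard
#' state-sets it is the Jaccard distance `1 - |A ∩ B| / |A ∪ B|`, so a
#' 2ISP contributes graded information (Y vs Y = 0, Y vs C = 0.5, Y vs R =
#' 1) instead of being discarded. Missing data on either side, or a gap on
#' either side, makes the site not comparable (`NA`; indels are carried by
#' the coded binary characters). Indel-2ISP codes compare 0 to an identical
#' code and 1 to anything else.
#'
#' @param a,b state-sets: `state_set` objects, single characters, or
#'   internal integer codes.
#' @return a number in `[0, 1]`, or `NA` if the site is not comparable.
#' @export
site_distance <- function(a, b) {
  ca <- .as_code(a); cb <- .as_code(b)
  if (ca == 15L || cb == 15L) return(NA_real_)
  if (ca < 0L || cb < 0L) {
    if (ca == 0L || cb == 0L) return(NA_real_)
    return(if (ca == cb) 0 else 1)
  }
  if (ca == 0L || cb == 0L) return(NA_real_)
  1 - .POPCOUNT[bitwAnd(ca, cb) + 1L] / .POPCOUNT[bitwOr(ca, cb) + 1L]
}

.as_code <- function(x) {
  if (inherits(x, "state_set")) return(x$code)
  if (is.character(x)) return(.encode_symbol(x))
  as.integer(x)
}

#' Pairwise genetic distance matrix
#'
#' Uncorrected pairwise distances with 2ISP-aware state-set comparison:
#' for each pair, the sum of site distances over comparable sites plus
#' mismatches of shared coded indel characters, divided by the number of
#' comparable sites plus shared indel characters. `method = "p"` is the
#' plain uncorrected p-distance, the special case where every state-set is
#' a singleton (suitable for cpDNA); `method = "poly_p"` names the general
#' 2ISP-aware case used for nuclear loci. Both run the same kernel.
#'
#' @param a a `twoisp_alignment` (run [code_indels()] first if gaps should
#'   contribute as characters).
#' @param method `"poly_p"` or `"p"` (label recorded on the result).
#' @param samples optional character vector restricting to a sample subset.
#' @return a symmetric numeric matrix with sample ids as dimnames and
#'   attributes `units = "substitutions/site"` and `method`.
#' @export
genetic_distance_matrix <- function(a, method = c("poly_p", "p"),
                                    samples = NULL) {
  method <- match.arg(method)
  st <- a$states; ind <- a$indels
  if (!is.null(samples)) {
    missing_ids <- setdiff(samples, a$ids)
    if (length(missing_ids))
      stop("samples not in alignment: ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    st <- st[samples, , drop = FALSE]
    ind <- ind[samples, , drop = FALSE]
  }
  if (nrow(st) < 2L) stop("need at least 2 sequences", call. = FALSE)
  d <- .poly_p_distmat(st, a$site_use, ind)
  dimnames(d) <- list(rownames(st), rownames(st))
  if (anyNA(d)) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)[1, ]
    stop("no comparable sites between '", rownames(st)[bad[1]], "' and '",
         rownames(st)[bad[2]], "'", call. = FALSE)
  }
  structure(d, units = "substitutions/site", method = method)
}

#' Great-circle geographic distance matrix
#'
#' Haversine distances in kilometres (Earth radius 6371 km) between sample
#' localities.
#'
#' @param table a `sample_table` (or any data frame with `sample_id`,
#'   `lat`, `lon`).
#' @param samples optional subset of sample ids.
#' @return symmetric matrix of distances in km, attribute `units = "km"`.
#' @export
geographic_distance_matrix <- function(table, samples = NULL) {
  tab <- as.data.frame(table)
  if (!is.null(samples)) tab <- tab[match(samples, tab$sample_id), , drop = FALSE]
  bad <- tab$sample_id[is.na(tab$lat) | is.na(tab$lon)]
  if (length(bad) || anyNA(tab$sample_id))
    stop("missing coordinates for: ", paste(bad, collapse = ", "), call. = FALSE)
  m <- geosphere::distm(cbind(tab$lon, tab$lat),
                        fun = function(p1, p2) geosphere::distHaversine(p1, p2, r = 6371))
  dimnames(m) <- list(tab$sample_id, tab$sample_id)
  structure(m, units = "km")
}

#' Read / write a square distance matrix as TSV
#'
#' Square tab-separated format with sample ids in the header row and first
#' column.
#'
#' @param d symmetric matrix with id dimnames.
#' @param path file path.
#' @return `read_distance_matrix` returns the matrix; `write_distance_matrix`
#'   returns `path` invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}
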