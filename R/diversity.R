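#' Number of distinct haplotypes
#'
#' Counts equivalence classes of sequences under exact state-set identity
#' at every site plus identical indel-character vectors. A 2ISP `{C,T}` is
#' a different haplotype from `{C}` (within-individual copy variation is
#' itself informative), and missing matches only missing.
#'
#' @param a a `twoisp_alignment`.
#' @param samples optional character vector of sample ids (default: all).
#' @return integer number of haplotypes `h`.
#' @export
count_haplotypes <- function(a, samples = NULL) {
  idx <- .sample_idx(a, samples)
  if (!length(idx)) stop("empty sample subset", call. = FALSE)
  key <- apply(cbind(a$states[idx, , drop = FALSE],
                     a$indels[idx, , drop = FALSE]),
               1, paste, collapse = ",")
  length(unique(key))
}

#' Number of segregating sites
#'
#' Counts alignment columns (outside coded indel runs) showing two or more
#' distinct non-missing, non-gap state-sets among the chosen samples —
#' a column with only `{C}` and `{C,T}` segregates — plus coded indel
#' characters with both 0 and 1 present.
#'
#' @inheritParams count_haplotypes
#' @return integer number of segregating sites `s`.
#' @export
segregating_sites <- function(a, samples = NULL) {
  idx <- .sample_idx(a, samples)
  if (!length(idx)) stop("empty sample subset", call. = FALSE)
  st <- a$states[idx, , drop = FALSE]
  seg_site <- vapply(which(a$site_use), function(j) {
    v <- st[, j]
    length(unique(v[v != 0L & v != 15L])) >= 2L
  }, logical(1))
  ind <- a$indels[idx, , drop = FALSE]
  seg_ind <- if (ncol(ind)) vapply(seq_len(ncol(ind)), function(k) {
    v <- ind[, k]
    any(v == 0L, na.rm = TRUE) && any(v == 1L, na.rm = TRUE)
  }, logical(1)) else logical(0)
  sum(seg_site) + sum(seg_ind)
}

#' Nucleotide diversity
#'
#' Mean per-site pairwise genetic distance over all unordered pairs of the
#' chosen samples, on the same 2ISP-aware kernel as
#' [genetic_distance_matrix()].
#'
#' @inheritParams count_haplotypes
#' @param method distance method passed to [genetic_distance_matrix()].
#' @return nucleotide diversity `pi` (per site).
#' @export
nucleotide_diversity <- function(a, samples = NULL, method = "poly_p") {
  idx <- .sample_idx(a, samples)
  if (length(idx) < 2L) stop("need at least 2 samples", call. = FALSE)
  d <- genetic_distance_matrix(a, method = method, samples = a$ids[idx])
  mean(d[upper.tri(d)])
}

.sample_idx <- function(a, samples) {
  if (is.null(samples)) return(seq_along(a$ids))
  missing_ids <- setdiff(samples, a$ids)
  if (length(missing_ids))
    stop("samples not in alignment: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  match(samples, a$ids)
}

#' Per-group diversity and isolation-by-distance summary
#'
#' The multilocus summary table: one row per locus and group (and pooled
#' group) with sample size `n`, haplotypes `h`, segregating sites `s`,
#' nucleotide diversity `pi`, and the Mantel test of isolation by distance
#' (`mt_r`, Spearman; `mt_p`, permutation). Pooled groups (e.g.
#' `"Gro + Oli" = c("Groot", "Olifants")`) are computed on the union of
#' their members. Groups with fewer than two members report only what is
#' defined; the Mantel test needs at least four samples and non-constant
#' distances, and is otherwise NA.
#'
#' @param loci named list of `twoisp_alignment` objects; the per-locus
#'   distance method is taken from `methods` (default `poly_p` for all).
#' @param table a `sample_table` after [apply_sample_rules()]; only
#'   ingroup, non-excluded samples are summarised.
#' @param pooled named list of character vectors defining pooled groups.
#' @param methods named character vector, locus -> `"p"` or `"poly_p"`.
#' @param n_perm Mantel permutations (default 10000).
#' @param seed seed for the Mantel permutations.
#' @return data frame with columns locus, group, n, h, s, pi, mt_r, mt_p.
#' @export
diversity_summary <- function(loci, table, pooled = list(),
                              methods = NULL, n_perm = 10000, seed = NULL) {
  stopifnot(is.list(loci), !is.null(names(loci)))
  active <- .active_samples(table)
  groups <- unique(table$group[table$sample_id %in% active])
  members <- c(
    list(Overall = active),
    setNames(lapply(groups, function(g)
      table$sample_id[table$group == g & table$sample_id %in% active]), groups),
    lapply(pooled, function(parts)
      table$sample_id[table$group %in% parts & table$sample_id %in% active])
  )
  rows <- list()
  for (locus in names(loci)) {
    a <- loci[[locus]]
    method <- if (!is.null(methods) && locus %in% names(methods))
      methods[[locus]] else "poly_p"
    for (grp in names(members)) {
      ids <- intersect(members[[grp]], a$ids)
      n <- length(ids)
      h <- if (n >= 1) count_haplotypes(a, ids) else NA_integer_
      s <- if (n >= 1) segregating_sites(a, ids) else NA_integer_
      pi <- if (n >= 2) nucleotide_diversity(a, ids, method = method) else NA_real_
      mt_r <- mt_p <- NA_real_
      if (n >= 4) {
        dg <- genetic_distance_matrix(a, method = method, samples = ids)
        dx <- geographic_distance_matrix(table, samples = ids)
        mt <- tryCatch(mantel_test(dg, dx, n_perm = n_perm, seed = seed),
                       error = function(e) NULL)
        if (!is.null(mt)) { mt_r <- mt$r; mt_p <- mt$p }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus = locus, group = grp, n = n, h = h, s = s, pi = pi,
        mt_r = mt_r, mt_p = mt_p)
    }
  }
  do.call(rbind, rows)
}
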