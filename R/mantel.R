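#' Permutation Mantel test with Spearman's R
#'
#' Tests the correlation between two distance matrices (here genetic vs
#' geographic distance, the isolation-by-distance prediction). The
#' statistic is Spearman's rank correlation over the `n(n-1)/2`
#' upper-triangle pairs; the null distribution is obtained by jointly
#' permuting rows and columns of the second matrix, and the one-sided
#' (greater) p-value is `(1 + #{R_perm >= R_obs}) / (1 + n_perm)`.
#'
#' @param d1,d2 symmetric distance matrices with matching id dimnames
#'   (`d2` is reordered to `d1`'s ids if necessary).
#' @param n_perm number of permutations (default 10000).
#' @param seed optional integer seed for reproducible permutations.
#' @param tail only `"greater"` is offered: isolation by distance predicts
#'   a positive correlation.
#' @return list with `r` (Spearman correlation), `p` (permutation
#'   p-value), `n` (number of samples) and `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 10000, seed = NULL,
                        tail = "greater") {
  tail <- match.arg(tail, "greater")
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2)))
      stop("distance matrices have different sample ids", call. = FALSE)
    ord <- match(rownames(d1), rownames(d2))
    d2 <- d2[ord, ord, drop = FALSE]
  }
  n <- nrow(d1)
  if (n < 4L) stop("Mantel test needs at least 4 samples", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be positive", call. = FALSE)
  ut <- upper.tri(d1)
  x <- d1[ut]; y <- d2[ut]
  if (var(rank(x)) == 0 || var(rank(y)) == 0)
    stop("undefined statistic: constant distance matrix", call. = FALSE)
  rx <- rank(x)
  r_obs <- cor(rx, rank(y))
  idx <- which(ut, arr.ind = TRUE)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    yp <- d2[cbind(p[idx[, 1]], p[idx[, 2]])]
    if (cor(rx, rank(yp)) >= r_obs) hits <- hits + 1L
  }
  list(r = r_obs, p = (1 + hits) / (1 + n_perm), n = n, n_perm = n_perm)
}
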