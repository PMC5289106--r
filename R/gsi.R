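#' Genealogical sorting index
#'
#' Quantifies how exclusively a predefined group of tips clusters on a
#' rooted genealogy, from 0 (complete lack of genealogical divergence) to
#' 1 (monophyly). Let U be the internal nodes of the minimal subtree
#' connecting the group's tips through their MRCA; with n_min = |group| - 1
#' (the minimum number of uniting nodes on a fully resolved tree) and
#' deg(u) the node degree in the whole tree,
#' `gs = n_min / sum_{u in U} (deg(u) - 2)`, `gs_min` the same sum over
#' ALL internal nodes, and `gsi = (gs - gs_min) / (1 - gs_min)`, clamped
#' to `[0, 1]`. The index depends on topology only, never on branch
#' lengths; a degree-2 root contributes 0 to both sums so the endpoints
#' are exact.
#'
#' @param t a rooted `phylo` tree.
#' @param group character vector of tip labels, `2 <= |group| < n_tips`.
#' @return gsi value in `[0, 1]`.
#' @export
gsi <- function(t, group) {
  if (!ape::is.rooted(t)) stop("gsi needs a rooted tree", call. = FALSE)
  ntip <- ape::Ntip(t)
  tips <- match(group, t$tip.label)
  if (anyNA(tips)) stop("group tips not in tree: ",
                        paste(group[is.na(tips)], collapse = ", "), call. = FALSE)
  g <- length(tips)
  if (g < 2L) stop("group must contain at least 2 tips", call. = FALSE)
  if (g >= ntip) stop("group may not contain all tips (normalization undefined)",
                      call. = FALSE)
  nnode <- t$Nnode
  deg <- tabulate(t$edge, nbins = ntip + nnode)
  # group-tip count below each node, by postorder accumulation
  po <- ape::reorder.phylo(t, "postorder")
  cnt <- integer(ntip + nnode)
  cnt[tips] <- 1L
  for (k in seq_len(nrow(po$edge)))
    cnt[po$edge[k, 1]] <- cnt[po$edge[k, 1]] + cnt[po$edge[k, 2]]
  mrca <- if (g == ntip) ntip + 1L else ape::getMRCA(t, tips)
  # ancestors strictly above the MRCA carry all g tips but sit off the
  # minimal connecting subtree
  parent <- integer(ntip + nnode)
  parent[t$edge[, 2]] <- t$edge[, 1]
  above <- integer(0)
  v <- mrca
  while (parent[v] != 0L) { v <- parent[v]; above <- c(above, v) }
  internal <- (ntip + 1L):(ntip + nnode)
  U <- setdiff(internal[cnt[internal] >= 1L], above)
  du <- sum(deg[U] - 2L)
  dall <- sum(deg[internal] - 2L)
  n_min <- g - 1L
  gs <- if (du == 0L) 1 else n_min / du
  gs_min <- n_min / dall
  if (gs_min >= 1)
    stop("normalization undefined: every internal node unites the group ",
         "(group too large for this tree)", call. = FALSE)
  val <- (gs - gs_min) / (1 - gs_min)
  min(max(val, 0), 1)
}

#' Permutation p-value for the genealogical sorting index
#'
#' Permutes the group labels uniformly over tips and recomputes gsi;
#' `p = (1 + #{gsi_perm >= gsi_obs}) / (1 + n_perm)`.
#'
#' @inheritParams gsi
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @return list with `gsi`, `p`, `n_perm`.
#' @export
gsi_permutation_p <- function(t, group, n_perm = 1000, seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be positive", call. = FALSE)
  obs <- gsi(t, group)
  g <- length(group)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(t$tip.label, g)
    if (gsi(t, perm) >= obs) hits <- hits + 1L
  }
  list(gsi = obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm)
}

#' Ensemble genealogical sorting index
#'
#' Computes gsi for one group on every tree of a bootstrap ensemble
#' (rooting each tree with the recorded outgroup when present, otherwise
#' at the midpoint), and summarises the ensemble mean and sample standard
#' deviation against a sorting threshold.
#'
#' @param e a `multiPhylo` ensemble (see [bootstrap_ensemble()]).
#' @param group character vector of tip labels.
#' @param threshold sorting threshold on the ensemble mean (default 0.6).
#' @param outgroup outgroup tip labels used to root unrooted ensemble
#'   trees; defaults to the ensemble's recorded provenance.
#' @return an object of class `gsi_result`: list with `group`, `values`
#'   (per-tree gsi), `mean`, `sd`, `passes_threshold`, `threshold`.
#' @export
ensemble_gsi <- function(e, group, threshold = 0.6, outgroup = NULL) {
  if (!length(e)) stop("empty tree ensemble", call. = FALSE)
  if (is.null(outgroup)) outgroup <- attr(e, "provenance")$outgroup
  vals <- vapply(e, function(tr) {
    tryCatch({
      if (!ape::is.rooted(tr)) {
        tr <- if (length(outgroup) && all(outgroup %in% tr$tip.label))
          root_with_outgroup(tr, outgroup)
        else phangorn::midpoint(tr)
      }
      gsi(tr, intersect(group, tr$tip.label))
    }, error = function(err) NA_real_)
  }, numeric(1))
  if (mean(is.na(vals)) > 0.1)
    stop("gsi failed on more than 10% of ensemble trees", call. = FALSE)
  vals_ok <- vals[!is.na(vals)]
  structure(
    list(group = group, values = vals, mean = mean(vals_ok),
         sd = if (length(vals_ok) > 1L) sd(vals_ok) else 0,
         threshold = threshold,
         passes_threshold = mean(vals_ok) > threshold),
    class = "gsi_result")
}

#' @export
print.gsi_result <- function(x, ...) {
  cat(sprintf("<gsi_result: mean %.3f (sd %.3f) over %d trees; %s threshold %.2f>\n",
              x$mean, x$sd, length(x$values),
              if (x$passes_threshold) "above" else "below", x$threshold))
  invisible(x)
}
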