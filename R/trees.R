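#' Neighbour-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}); negative branch lengths,
#' an NJ artefact on noisy matrices, are clamped to zero. On an additive
#' matrix the generating topology and branch lengths are recovered
#' exactly.
#'
#' @param d symmetric distance matrix with id dimnames, n >= 3.
#' @return an unrooted `phylo` tree with branch lengths in the input units.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbour joining needs at least 3 taxa", call. = FALSE)
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' UPGMA chronogram from a distance matrix
#'
#' Average-linkage clustering yielding a rooted ultrametric tree; each
#' node sits at half the average between-cluster distance, so on an
#' ultrametric input the node heights are reproduced exactly. A
#' lightweight, deterministic chronogram for rate-based time scaling.
#'
#' @param d symmetric distance matrix with id dimnames, n >= 2.
#' @return a rooted ultrametric `phylo` tree.
#' @export
upgma_chronogram <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (nrow(d) == 2L) {
    h <- d[1, 2] / 2
    tr <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                        rownames(d)[1], h, rownames(d)[2], h))
    return(tr)
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # as.phylo.hclust already places each tip at half the merge height
  ape::as.phylo(hc)
}

#' Bootstrap ensemble of NJ trees
#'
#' Resamples alignment columns and coded indel characters jointly with
#' replacement, recomputes the 2ISP-aware distance matrix, and builds an
#' NJ tree per replicate. A replicate whose resampled columns leave some
#' pair with no comparable site is redrawn (at most 10 retries).
#'
#' @param a a `twoisp_alignment` with at least 3 sequences.
#' @param n_reps number of bootstrap replicates (default 1000).
#' @param seed integer seed; replicates are reproducible given the seed.
#' @param method distance method, as in [genetic_distance_matrix()].
#' @param samples optional sample subset.
#' @param outgroup optional outgroup ids recorded for later rooting.
#' @return a `multiPhylo` list of trees with attribute `provenance`
#'   (method, n_reps, seed, outgroup).
#' @export
bootstrap_ensemble <- function(a, n_reps = 1000, seed = NULL,
                               method = "poly_p", samples = NULL,
                               outgroup = NULL) {
  ids <- if (is.null(samples)) a$ids else samples
  if (length(ids) < 3L) stop("bootstrap needs at least 3 sequences", call. = FALSE)
  st <- a$states[ids, , drop = FALSE]
  ind <- a$indels[ids, , drop = FALSE]
  use_cols <- which(a$site_use)
  n_ind <- ncol(ind)
  M <- length(use_cols) + n_ind
  if (!is.null(seed)) set.seed(seed)
  trees <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    for (try in seq_len(11L)) {
      if (try == 11L) stop("bootstrap replicate kept producing a pair with no comparable sites",
                           call. = FALSE)
      take <- sample.int(M, M, replace = TRUE)
      site_take <- use_cols[take[take <= length(use_cols)]]
      ind_take <- take[take > length(use_cols)] - length(use_cols)
      rb <- list(locus = a$locus,
                 ids = ids,
                 states = st[, site_take, drop = FALSE],
                 indels = ind[, ind_take, drop = FALSE],
                 site_use = rep(TRUE, length(site_take)),
                 length = length(site_take))
      class(rb) <- "twoisp_alignment"
      d <- tryCatch(genetic_distance_matrix(rb, method = method),
                    error = function(e) NULL)
      if (!is.null(d)) break
    }
    trees[[b]] <- nj_tree(d)
  }
  class(trees) <- "multiPhylo"
  attr(trees, "provenance") <- list(method = paste0("NJ/", method),
                                    n_reps = n_reps, seed = seed,
                                    outgroup = outgroup)
  trees
}

#' Root a tree with an outgroup
#'
#' Places the root on the edge separating the outgroup from the ingroup,
#' splitting that edge's length evenly. If the outgroup is not
#' bipartition-compatible (not a clade on the unrooted tree), the tree is
#' rooted on the first outgroup tip's pendant edge with a warning.
#'
#' @param t a `phylo` tree.
#' @param outgroup_ids tip labels of the outgroup.
#' @return a rooted `phylo` tree.
#' @export
root_with_outgroup <- function(t, outgroup_ids) {
  if (!length(outgroup_ids)) stop("no outgroup tips given", call. = FALSE)
  missing_tips <- setdiff(outgroup_ids, t$tip.label)
  if (length(missing_tips))
    stop("outgroup tips not in tree: ", paste(missing_tips, collapse = ", "),
         call. = FALSE)
  ok <- length(outgroup_ids) == 1L ||
    ape::is.monophyletic(t, outgroup_ids) ||
    ape::is.monophyletic(t, setdiff(t$tip.label, outgroup_ids))
  if (!ok) {
    warning("outgroup is not bipartition-compatible; rooting on '",
            outgroup_ids[1], "' pendant edge")
    outgroup_ids <- outgroup_ids[1]
  }
  rt <- ape::root(t, outgroup = outgroup_ids, resolve.root = TRUE)
  root_node <- ape::Ntip(rt) + 1L
  kids <- which(rt$edge[, 1] == root_node)
  if (length(kids) == 2L && !is.null(rt$edge.length)) {
    tot <- sum(rt$edge.length[kids])
    rt$edge.length[kids] <- tot / 2
  }
  rt
}

#' Scale an ultrametric tree to absolute time under bracketing rates
#'
#' Divides node heights (substitutions/site) by a slow and a fast
#' substitution rate, bracketing the plausible range for non-coding
#' chloroplast DNA, and flags nodes older than the Pliocene-Pleistocene
#' boundary under each rate.
#'
#' @param t rooted ultrametric `phylo` with branch lengths in
#'   substitutions/site.
#' @param rate_slow,rate_fast substitution rates in substitutions per site
#'   per year (defaults 1.0e-9 and 31e-9).
#' @param boundary_ma age threshold in Ma flagged in the report
#'   (default 2.6, the Pliocene-Pleistocene boundary).
#' @return list with `slow` and `fast` (trees with branch lengths in
#'   years) and `ages` (data frame: node, height, age_slow_yr,
#'   age_fast_yr, pre_boundary_slow, pre_boundary_fast).
#' @export
scale_to_time <- function(t, rate_slow = 1.0e-9, rate_fast = 31e-9,
                          boundary_ma = 2.6) {
  stopifnot(rate_slow > 0, rate_fast > 0)
  if (!ape::is.rooted(t)) stop("tree must be rooted", call. = FALSE)
  if (!ape::is.ultrametric(t, option = 2))
    stop("tree is not ultrametric", call. = FALSE)
  depth <- ape::node.depth.edgelength(t)
  height <- max(depth) - depth
  nodes <- (ape::Ntip(t) + 1L):(ape::Ntip(t) + t$Nnode)
  ages <- data.frame(
    node = nodes,
    height = height[nodes],
    age_slow_yr = height[nodes] / rate_slow,
    age_fast_yr = height[nodes] / rate_fast)
  ages$pre_boundary_slow <- ages$age_slow_yr > boundary_ma * 1e6
  ages$pre_boundary_fast <- ages$age_fast_yr > boundary_ma * 1e6
  slow <- fast <- t
  slow$edge.length <- t$edge.length / rate_slow
  fast$edge.length <- t$edge.length / rate_fast
  list(slow = slow, fast = fast, ages = ages)
}

#' Minimum spanning haplotype network
#'
#' All edges belonging to any minimum spanning tree of the haplotype
#' distance matrix: a Kruskal sweep where, within each distinct weight,
#' every edge joining two still-separate components is retained before
#' the components are merged (so equal-weight alternatives all appear).
#'
#' @param d symmetric haplotype distance matrix with id dimnames.
#' @return data frame with columns `from`, `to`, `weight`; zero rows for a
#'   single haplotype.
#' @export
msn_haplotype_network <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n < 2L)
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0)))
  ut <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[ut]
  ord <- order(w, ut[, 1], ut[, 2])
  ut <- ut[ord, , drop = FALSE]; w <- w[ord]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- list()
  for (wt in unique(w)) {
    at <- which(w == wt)
    keepers <- at[vapply(at, function(k)
      find(ut[k, 1]) != find(ut[k, 2]), logical(1))]
    for (k in keepers)
      edges[[length(edges) + 1L]] <- data.frame(
        from = ids[ut[k, 1]], to = ids[ut[k, 2]], weight = wt)
    for (k in keepers) {
      ra <- find(ut[k, 1]); rb <- find(ut[k, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  do.call(rbind, edges)
}
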