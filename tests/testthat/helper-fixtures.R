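# Shared fixtures and independent oracles, built in code at test time.

# --- exhaustive enumeration of labelled rooted binary trees -----------------
# Trees are nested pairlists (leaf = tip label). Adding tip t at every node
# of every (k)-tip tree yields all (2k-1) * N_k trees with k+1 tips, i.e. the
# full (2n-3)!! labelled rooted binary topologies.

.insert_tip_everywhere <- function(tr, tip) {
  out <- list(list(tr, tip))
  if (is.list(tr)) {
    for (L in .insert_tip_everywhere(tr[[1]], tip))
      out <- c(out, list(list(L, tr[[2]])))
    for (R in .insert_tip_everywhere(tr[[2]], tip))
      out <- c(out, list(list(tr[[1]], R)))
  }
  out
}

.tree_to_newick <- function(tr) {
  if (!is.list(tr)) return(tr)
  sprintf("(%s,%s)", .tree_to_newick(tr[[1]]), .tree_to_newick(tr[[2]]))
}

# all labelled rooted binary trees on tips t1..tn, as one multiPhylo
all_rooted_trees <- function(n) {
  tips <- paste0("t", seq_len(n))
  trees <- list(tips[1])
  for (k in 2:n) {
    trees <- unlist(lapply(trees, .insert_tip_everywhere, tip = tips[k]),
                    recursive = FALSE)
  }
  txt <- paste0(vapply(trees, .tree_to_newick, character(1)), ";",
                collapse = "\n")
  ape::read.tree(text = txt)
}

# --- brute-force gsi oracle -------------------------------------------------
# Independent route: the uniting node set U is built as the union of the
# tip-to-MRCA node paths, and node degrees are counted directly off the edge
# matrix.

gsi_oracle <- function(tr, group) {
  ntip <- ape::Ntip(tr)
  tips <- match(group, tr$tip.label)
  mrca <- ape::getMRCA(tr, tips)
  U <- integer(0)
  for (tp in tips) U <- union(U, ape::nodepath(tr, tp, mrca))
  U <- setdiff(U, seq_len(ntip))
  degree <- function(v) sum(tr$edge == v)
  internal <- (ntip + 1L):(ntip + tr$Nnode)
  n_min <- length(tips) - 1L
  du <- sum(vapply(U, degree, numeric(1)) - 2)
  gs <- if (du == 0) 1 else n_min / du
  gs_min <- n_min / sum(vapply(internal, degree, numeric(1)) - 2)
  min(max((gs - gs_min) / (1 - gs_min), 0), 1)
}

# --- small simulation configs ----------------------------------------------

tiny_sim_config <- function(seed = 1L, ...) {
  args <- list(
    n_per_catchment = 5,
    split_times = c(4e5, 8e5),
    Ne = 2000,
    loci = list(list(name = "cp", L = 1200, mu = 4e-9, copies = 1),
                list(name = "nuc", L = 800, mu = 8e-9, copies = 3)),
    grid_nrow = 24, grid_ncol = 36, grid_cellsize_km = 5,
    n_models = 12,
    seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}
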